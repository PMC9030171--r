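# Operational and productivity indicators computed from an event log.
#
# Operational indicators decompose each patient's stay into direct care,
# indirect care, transit, idle and sanitizing time. Productivity indicators
# cover weekly throughput, MRI utilization over the 12 h operating window,
# a seven-category attribution of scanner downtime, and staff utilization
# against each role's working calendar.

# --- interval set helpers (start/end matrices, seconds) ---------------------

int_empty <- function() matrix(numeric(), ncol = 2L)

int_norm <- function(m) {
  if (is.null(m) || !nrow(m)) return(int_empty())
  m <- m[m[, 2L] > m[, 1L], , drop = FALSE]
  if (!nrow(m)) return(int_empty())
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  s <- m[, 1L]; e <- m[, 2L]
  out_s <- out_e <- numeric(length(s)); k <- 1L
  out_s[1L] <- s[1L]; out_e[1L] <- e[1L]
  for (i in seq_along(s)[-1L]) {
    if (s[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], e[i])
    } else {
      k <- k + 1L; out_s[k] <- s[i]; out_e[k] <- e[i]
    }
  }
  cbind(out_s[seq_len(k)], out_e[seq_len(k)])
}

int_inter <- function(a, b) {
  a <- int_norm(a); b <- int_norm(b)
  if (!nrow(a) || !nrow(b)) return(int_empty())
  out <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1L], b[, 1L]); e <- pmin(a[i, 2L], b[, 2L])
    keep <- e > s
    if (any(keep)) out[[length(out) + 1L]] <- cbind(s[keep], e[keep])
  }
  int_norm(do.call(rbind, c(out, list(int_empty()))))
}

int_diff <- function(a, b) {
  a <- int_norm(a); b <- int_norm(b)
  if (!nrow(a)) return(int_empty())
  if (!nrow(b)) return(a)
  out <- list()
  for (i in seq_len(nrow(a))) {
    cur_s <- a[i, 1L]; cur_e <- a[i, 2L]
    pieces <- list()
    for (j in seq_len(nrow(b))) {
      bs <- b[j, 1L]; be <- b[j, 2L]
      if (be <= cur_s || bs >= cur_e) next
      if (bs > cur_s) pieces[[length(pieces) + 1L]] <- c(cur_s, bs)
      cur_s <- max(cur_s, be)
      if (cur_s >= cur_e) break
    }
    if (cur_s < cur_e) pieces[[length(pieces) + 1L]] <- c(cur_s, cur_e)
    if (length(pieces)) out[[length(out) + 1L]] <- do.call(rbind, pieces)
  }
  int_norm(do.call(rbind, c(out, list(int_empty()))))
}

int_len <- function(m) if (is.null(m) || !nrow(m)) 0 else sum(m[, 2L] - m[, 1L])

# --- MRI utilization --------------------------------------------------------

mri_busy_by_day <- function(x) {
  ev <- x$events
  busy <- ev[ev$entity_role == "mri_machine" & ev$state_label == "busy", ]
  days <- seq_len(x$scenario$days)
  vapply(days, function(d) {
    b <- busy[busy$day == d, ]
    int_len(int_inter(cbind(b$start_s, b$end_s), cbind(0, SEC_DAY))) / 60
  }, 0)
}

#' MRI utilization
#'
#' Daily scanner busy time (patient positioning plus examination; the patient
#' occupies the bore during both) as hours per day and as a percentage of the
#' 12 h operating window.
#'
#' @param x A `clinic_sim` from [clinic_run()].
#' @return List with `busy_h_per_day` (mean over the horizon), `pct`
#'   (= busy / 720 min x 100) and `busy_min_by_day`.
#' @export
mri_utilization <- function(x) {
  by_day <- mri_busy_by_day(x)
  list(busy_h_per_day = mean(by_day) / 60,
       pct = mean(by_day) / 720 * 100,
       busy_min_by_day = by_day)
}

# --- downtime attribution ---------------------------------------------------

#' Attribute MRI downtime to its causes
#'
#' Partitions each day's 12 h scanner timeline into busy time and seven
#' exclusive idle categories:
#' \describe{
#'   \item{public_closure}{8:30-9:00 and 8:00-8:30 p.m., the mismatch between
#'     the 12 h operating window and the 11 h public-access window.}
#'   \item{first_patient}{9:00 a.m. to the first busy interval of the day.}
#'   \item{last_patient}{end of the last busy interval to 8:00 p.m.}
#'   \item{sanitation}{idle overlapped by an MRI cleaning activity.}
#'   \item{staff_consultation}{remaining idle overlapped by the
#'     technician-physician consultation.}
#'   \item{cmi}{remaining idle during which the next patient to use the
#'     scanner was undergoing the contrast-medium injection.}
#'   \item{other}{everything else (late arrivals, staff unavailability,
#'     patients turned away at screening).}
#' }
#' Sanitation takes precedence over staff consultation, which takes precedence
#' over CMI; intervals are split exactly at label boundaries, so busy plus the
#' seven categories always sums to 720 min per day. A day with no scanner use
#' has its whole public window labelled `other` (convention).
#'
#' @param x A `clinic_sim` from [clinic_run()].
#' @return A data.frame of class `clinic_downtime`, one row per day, minutes
#'   per category plus `busy_min`.
#' @export
attribute_downtime <- function(x) {
  ev <- x$events
  days <- seq_len(x$scenario$days)
  rows <- lapply(days, function(d) {
    e <- ev[ev$day == d, ]
    braw <- e[e$entity_role == "mri_machine" & e$state_label == "busy", ]
    braw <- braw[order(braw$start_s), ]
    busy <- int_norm(cbind(braw$start_s, braw$end_s))
    idle <- int_diff(cbind(0, SEC_DAY), busy)
    closure <- int_len(int_inter(idle, rbind(c(0, PUBLIC_OPEN),
                                             c(PUBLIC_CLOSE, SEC_DAY)))) / 60
    out <- c(public_closure = closure, first_patient = 0, last_patient = 0,
             cmi = 0, staff_consultation = 0, sanitation = 0, other = 0)
    if (!nrow(busy)) {
      out["other"] <- int_len(int_inter(idle, cbind(PUBLIC_OPEN, PUBLIC_CLOSE))) / 60
      return(data.frame(day = d, busy_min = 0, t(out)))
    }
    fs <- busy[1L, 1L]; le <- busy[nrow(busy), 2L]
    out["first_patient"] <- int_len(int_inter(idle, cbind(PUBLIC_OPEN, fs))) / 60
    out["last_patient"] <- int_len(int_inter(idle, cbind(le, PUBLIC_CLOSE))) / 60
    # closure has precedence over the in-between categories
    mid <- int_inter(idle, cbind(max(fs, PUBLIC_OPEN), min(le, PUBLIC_CLOSE)))
    clean <- e[e$entity_role == "mri_machine" & e$state_label == "blocked", ]
    clean_iv <- cbind(clean$start_s, clean$end_s)
    out["sanitation"] <- int_len(int_inter(mid, clean_iv)) / 60
    rem <- int_diff(mid, clean_iv)
    cons <- e[e$entity_role == "technician" &
                e$activity == "check_mri_correctness", ]
    cons_iv <- cbind(cons$start_s, cons$end_s)
    out["staff_consultation"] <- int_len(int_inter(rem, cons_iv)) / 60
    rem <- int_diff(rem, cons_iv)
    if (nrow(rem)) {
      cmi_rows <- e[e$activity == "cmi" & e$entity_role == "patient", ]
      for (i in seq_len(nrow(rem))) {
        g <- rem[i, , drop = FALSE]
        nxt <- which(braw$start_s >= g[1L, 2L] - 1e-9)
        if (length(nxt)) {
          pid <- braw$entity_id[nxt[1L]]
          civ <- cmi_rows[cmi_rows$entity_id == pid, ]
          ov <- int_len(int_inter(g, cbind(civ$start_s, civ$end_s)))
          out["cmi"] <- out["cmi"] + ov / 60
          out["other"] <- out["other"] + (int_len(g) - ov) / 60
        } else {
          out["other"] <- out["other"] + int_len(g) / 60
        }
      }
    }
    data.frame(day = d, busy_min = int_len(busy) / 60, t(out))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("clinic_downtime", "data.frame")
  out
}

# --- patient time decomposition ---------------------------------------------

#' Decompose one patient's stay
#'
#' Maps every recorded interval of a patient to the state its activity
#' accrues (direct care, indirect care, transit, sanitizing) and books the
#' gaps between consecutive activities as idle time. The components always
#' sum to the facility time (first arrival to last recorded instant).
#'
#' @param x A `clinic_sim` from [clinic_run()].
#' @param patient_id Patient identifier as found in `x$patients$patient_id`.
#' @return A one-row data.frame: `patient_id`, `facility_min`,
#'   `direct_care_min`, `indirect_care_min`, `transit_min`, `idle_min`,
#'   `sanitizing_min`, `outcome`, `partial` (TRUE unless the pathway was
#'   completed).
#' @export
decompose_patient_time <- function(x, patient_id) {
  res <- patient_times(x, ids = patient_id)
  if (!nrow(res)) stop("unknown patient: ", patient_id, call. = FALSE)
  res
}

#' Stay decomposition for all patients
#'
#' @param x A `clinic_sim` from [clinic_run()].
#' @param ids Optional subset of patient identifiers.
#' @return A data.frame, one row per patient (see [decompose_patient_time()]).
#' @export
patient_times <- function(x, ids = NULL) {
  pts <- x$patients
  if (!is.null(ids)) pts <- pts[pts$patient_id %in% ids, ]
  ev <- x$events
  ev <- ev[ev$entity_role %in% c("patient", "booker"), ]
  ev_by_id <- split(seq_len(nrow(ev)), ev$entity_id)
  state_of <- c(receiving_direct_care = "direct", receiving_indirect_care = "indirect",
                in_transit = "transit", sanitizing = "sanitizing")
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    id <- pts$patient_id[i]
    idx <- ev_by_id[[id]]
    comp <- c(direct = 0, indirect = 0, transit = 0, sanitizing = 0)
    fac <- 0
    if (!is.null(idx)) {
      e <- ev[idx, ]
      dur <- e$end_s - e$start_s
      grp <- state_of[e$state_label]
      agg <- tapply(dur, grp, sum)
      comp[names(agg)] <- agg
      last_end <- max(e$end_s)
      fac <- last_end - pts$arrival_s[i]
    } else if (!is.na(pts$depart_s[i])) {
      fac <- max(0, pts$depart_s[i] - pts$arrival_s[i])
    }
    idle <- fac - sum(comp)
    data.frame(patient_id = id, facility_min = fac / 60,
               direct_care_min = comp[["direct"]] / 60,
               indirect_care_min = comp[["indirect"]] / 60,
               transit_min = comp[["transit"]] / 60,
               idle_min = idle / 60,
               sanitizing_min = comp[["sanitizing"]] / 60,
               outcome = pts$outcome[i],
               partial = pts$outcome[i] != "completed",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame())))
  rownames(out) <- NULL
  out
}

# --- throughput and staff utilization ---------------------------------------

#' Weekly throughput
#'
#' Counts exam patients over the whole simulated horizon: those completing
#' the full diagnostic pathway (treated), the contrast-medium subset of the
#' treated, those rejected at entrance screening, and those flushed by the
#' end-of-day policy. Together with arrivals these satisfy
#' arrivals = completed + rejected + flushed.
#'
#' @param x A `clinic_sim` from [clinic_run()].
#' @return List with `patients_week`, `cmi_patients_week`, `rejected`,
#'   `flushed`, `arrivals`.
#' @export
throughput <- function(x) {
  p <- x$patients[x$patients$role == "patient", ]
  done <- p$outcome == "completed"
  list(patients_week = sum(done),
       cmi_patients_week = sum(done & p$needs_cmi),
       rejected = sum(p$outcome == "rejected"),
       flushed = sum(p$outcome == "flushed"),
       arrivals = nrow(p))
}

#' Staff utilization
#'
#' Busy minutes per role (all logged working states) divided by the length of
#' that role's working calendar over the horizon.
#'
#' @param x A `clinic_sim` from [clinic_run()].
#' @return Named numeric vector of percentages, one per rostered role.
#' @export
staff_utilization <- function(x) {
  roster <- x$scenario$roster
  ev <- x$events
  days <- x$scenario$days
  out <- vapply(seq_len(nrow(roster)), function(i) {
    role <- roster$role[i]
    e <- ev[ev$entity_role == role, ]
    busy <- sum(e$end_s - e$start_s) / 60
    cal <- (roster$close_s[i] - roster$open_s[i]) / 60 * days * roster$count[i]
    100 * busy / cal
  }, 0)
  names(out) <- roster$role
  out
}

# --- report and comparison --------------------------------------------------

#' Full KPI report for one replication
#'
#' @param x A `clinic_sim` from [clinic_run()].
#' @return An object of class `clinic_kpi`.
#' @export
kpi_report <- function(x) {
  mri <- mri_utilization(x)
  dt <- attribute_downtime(x)
  thr <- throughput(x)
  st <- staff_utilization(x)
  ops <- patient_times(x)
  ops <- ops[ops$outcome == "completed" & grepl("^p_", ops$patient_id), ]
  cats <- c("public_closure", "first_patient", "last_patient", "cmi",
            "staff_consultation", "sanitation", "other")
  dt_mean <- colMeans(dt[, c("busy_min", cats)])
  downtime_total <- 720 - dt_mean[["busy_min"]]
  structure(list(
    scenario_id = x$scenario$scenario_id,
    days = x$scenario$days,
    throughput = thr,
    mri = mri,
    downtime_min = dt_mean[cats],
    downtime_pct_of_downtime = 100 * dt_mean[cats] / downtime_total,
    downtime_pct_of_time = 100 * dt_mean[cats] / 720,
    downtime_by_day = dt,
    staff_utilization_pct = st,
    operational_means = if (nrow(ops)) colMeans(ops[, c(
      "facility_min", "direct_care_min", "indirect_care_min", "transit_min",
      "idle_min", "sanitizing_min")]) else NULL
  ), class = "clinic_kpi")
}

# Flatten a report into one named numeric vector (replication statistics).
metric_vector <- function(r) {
  out <- c(throughput_week = r$throughput$patients_week,
           cmi_throughput_week = r$throughput$cmi_patients_week,
           rejected_week = r$throughput$rejected,
           flushed_week = r$throughput$flushed,
           mri_utilization_pct = r$mri$pct,
           mri_busy_h_per_day = r$mri$busy_h_per_day)
  dt <- r$downtime_min
  names(dt) <- paste0("downtime_", names(dt), "_min")
  st <- r$staff_utilization_pct
  names(st) <- paste0("staff_", names(st), "_pct")
  ops <- r$operational_means
  if (!is.null(ops)) names(ops) <- paste0("op_", names(ops))
  c(out, dt, st, ops)
}

round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Compare two KPI reports
#'
#' Relative change from `a` to `b`, (b - a) / a x 100, for every shared
#' numeric metric. Metrics that are zero in `a` are flagged (`undefined`)
#' rather than returned as NaN. Values are kept at full precision; the print
#' method rounds half-up to integer percentages, as deltas are conventionally
#' quoted.
#'
#' @param a,b `clinic_kpi` reports over the same horizon.
#' @return A data.frame of class `clinic_comparison`: `metric`, `a`, `b`,
#'   `delta_pct`, `undefined`.
#' @export
compare_scenarios <- function(a, b) {
  stopifnot(inherits(a, "clinic_kpi"), inherits(b, "clinic_kpi"))
  if (a$days != b$days) stop("reports cover different horizons", call. = FALSE)
  va <- metric_vector(a); vb <- metric_vector(b)
  common <- intersect(names(va), names(vb))
  va <- va[common]; vb <- vb[common]
  undef <- va == 0
  delta <- ifelse(undef, NA_real_, (vb - va) / va * 100)
  structure(data.frame(metric = common, a = unname(va), b = unname(vb),
                       delta_pct = unname(delta), undefined = unname(undef),
                       stringsAsFactors = FALSE),
            class = c("clinic_comparison", "data.frame"))
}

#' @export
print.clinic_comparison <- function(x, ...) {
  cat("Scenario comparison (relative change, %):\n")
  d <- x[!x$undefined, ]
  for (i in seq_len(nrow(d))) {
    cat(sprintf("  %-32s %8.1f -> %8.1f   %+d%%\n", d$metric[i], d$a[i], d$b[i],
                as.integer(round_half_up(d$delta_pct[i]))))
  }
  if (any(x$undefined)) {
    cat("  undefined (zero base):", paste(x$metric[x$undefined], collapse = ", "), "\n")
  }
  invisible(x)
}
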