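# Independent oracles and fixture generators shared across the test files.

# Brute-force downtime labeller: classify every second of the 12 h day by the
# attribution rules, independently of the interval arithmetic in the package.
# Exact for logs whose interval endpoints are whole seconds.
oracle_downtime <- function(log) {
  ev <- log$events
  days <- seq_len(log$scenario$days)
  mark <- function(t, iv) {
    f <- rep(FALSE, length(t))
    for (i in seq_len(nrow(iv))) f <- f | (t > iv[i, 1L] & t < iv[i, 2L])
    f
  }
  rows <- lapply(days, function(d) {
    e <- ev[ev$day == d, ]
    br <- e[e$entity_role == "mri_machine" & e$state_label == "busy", ]
    br <- br[order(br$start_s), ]
    t <- seq_len(43200) - 0.5
    busy <- mark(t, cbind(br$start_s, br$end_s))
    lab <- ifelse(busy, "busy", "other")
    closure <- !busy & (t < 1800 | t > 41400)
    lab[closure] <- "public_closure"
    if (nrow(br)) {
      fs <- min(br$start_s); le <- max(br$end_s)
      lab[!busy & !closure & t < fs] <- "first_patient"
      lab[!busy & !closure & t > le] <- "last_patient"
      mid <- !busy & !closure & t > fs & t < le
      # precedence: cmi assigned first, then consultation, then sanitation,
      # each overwriting, so the final order is sanitation > consultation > cmi
      cmi_rows <- e[e$activity == "cmi" & e$entity_role == "patient", ]
      nxt <- findInterval(t, br$start_s) + 1L
      for (j in seq_len(nrow(br))) {
        sel <- mid & (nxt == j)
        if (!any(sel)) next
        civ <- cmi_rows[cmi_rows$entity_id == br$entity_id[j], ]
        if (!nrow(civ)) next
        incmi <- mark(t, cbind(civ$start_s, civ$end_s))
        lab[sel & incmi] <- "cmi"
      }
      cons <- e[e$entity_role == "technician" &
                  e$activity == "check_mri_correctness", ]
      lab[mid & mark(t, cbind(cons$start_s, cons$end_s))] <- "staff_consultation"
      cl <- e[e$entity_role == "mri_machine" & e$state_label == "blocked", ]
      lab[mid & mark(t, cbind(cl$start_s, cl$end_s))] <- "sanitation"
    }
    cats <- c("busy", "public_closure", "first_patient", "last_patient", "cmi",
              "staff_consultation", "sanitation", "other")
    counts <- vapply(cats, function(cc) sum(lab == cc) / 60, 0)
    names(counts) <- cats
    counts
  })
  do.call(rbind, rows)
}

# Random small downtime instance with whole-second endpoints: a handful of
# exam blocks with optional cleaning, consultation and CMI overlays in the
# gaps.
random_day_log <- function(seed) {
  set.seed(seed)
  k <- sample(2:6, 1L)
  s <- sort(sample(seq(2200L, 36000L, by = 1L), k))
  e <- integer(k)
  for (i in seq_len(k)) {
    if (i > 1L) s[i] <- max(s[i], e[i - 1L] + sample(200:900, 1L))
    e[i] <- min(s[i] + sample(400:1800, 1L), 40500L)
  }
  rows <- list()
  add <- function(id, role, act, state, a, b) {
    rows[[length(rows) + 1L]] <<- data.frame(
      entity_id = id, entity_role = role, activity = act, state_label = state,
      start_s = a, end_s = b, stringsAsFactors = FALSE)
  }
  for (i in seq_len(k)) {
    pid <- sprintf("p_d1_%02d", i)
    add(pid, "mri_machine", "mri_exam_single", "busy", s[i], e[i])
    gap_end <- if (i < k) s[i + 1L] else 41000L
    glen <- gap_end - e[i]
    if (glen > 400L) {
      if (stats::runif(1) < 0.7) {
        g0 <- e[i] + sample(0:60, 1L)
        add(sprintf("task_cl_%d", i), "mri_machine", "mri_cleaning", "blocked",
            g0, g0 + sample(60:min(300L, glen %/% 3L), 1L))
      }
      if (stats::runif(1) < 0.7) {
        c0 <- e[i] + glen %/% 2L
        add(sprintf("task_co_%d", i), "technician", "check_mri_correctness",
            "staff_consultation", c0, c0 + sample(30:min(180L, glen %/% 4L), 1L))
      }
      if (i < k && stats::runif(1) < 0.5) {
        m0 <- e[i] + glen %/% 5L
        add(sprintf("p_d1_%02d", i + 1L), "patient", "cmi",
            "receiving_direct_care", m0, m0 + sample(60:(glen %/% 2L), 1L))
      }
    }
  }
  make_fixture_log(do.call(rbind, rows))
}

# Catalogue with every duration law collapsed to its mean (degenerate
# uniform), for deterministic hand-sum checks.
collapsed_catalogue <- function() {
  cat_ <- clinicdes:::activity_catalogue()
  lapply(cat_, function(a) {
    m <- mean(a$duration)
    a$duration <- dist_spec("uniform", m, m)
    a
  })
}

with_collapsed_durations <- function(code) {
  old <- clinicdes:::set_activity_catalogue(collapsed_catalogue())
  on.exit(clinicdes:::set_activity_catalogue(old))
  force(code)
}

# Scenario shrunk for fast property loops.
tiny_scenario <- function(id = "baseline", ...) {
  clinic_scenario(id, days = 1L, n_day = 5L, booking_per_day = 1L, ...)
}
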