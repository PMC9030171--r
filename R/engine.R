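# Process-interaction discrete-event kernel.
#
# The kernel is deliberately small: a future-event queue ordered by
# (time, insertion sequence), resource tokens with capacities and working
# calendars, and a ready-list dispatcher that starts a stage as soon as every
# resource it needs is free, open, and able to finish it within its calendar.
# Each simulated day is an independent 12 h window; there is no overnight
# carry-over.

# --- future-event queue -----------------------------------------------------

#' Create a future-event queue
#'
#' A deterministic priority queue: events dequeue in nondecreasing time order,
#' with ties broken by insertion sequence. Scheduling an event before the
#' current clock (the time of the last dequeued event) is an error, since it
#' would mean the model tried to act in the past.
#'
#' @return An event-queue object (environment).
#' @export
#' @examples
#' q <- event_queue()
#' eq_schedule(q, 10); eq_schedule(q, 5); eq_schedule(q, 10)
#' eq_pop(q)$time  # 5
event_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$time <- rep(Inf, 64L)
  q$kind <- integer(64L)
  q$ent <- integer(64L)
  q$n <- 0L
  q$clock <- 0
  q
}

#' Schedule an event
#'
#' @param q An [event_queue()].
#' @param time Event time in seconds; must not precede the queue clock.
#' @param kind Integer event tag (free for the caller).
#' @param ent Integer entity reference (free for the caller).
#' @return The insertion sequence number, invisibly.
#' @export
eq_schedule <- function(q, time, kind = 0L, ent = 0L) {
  if (time < q$clock) {
    stop(sprintf("event scheduled in the past (t=%g < clock=%g): model bug",
                 time, q$clock), call. = FALSE)
  }
  n <- q$n + 1L
  if (n > length(q$time)) {
    grow <- length(q$time) * 2L
    q$time <- c(q$time, rep(Inf, grow - length(q$time)))
    q$kind <- c(q$kind, integer(grow - length(q$kind)))
    q$ent <- c(q$ent, integer(grow - length(q$ent)))
  }
  q$time[n] <- time
  q$kind[n] <- kind
  q$ent[n] <- ent
  q$n <- n
  invisible(n)
}

#' Dequeue the next event
#'
#' @param q An [event_queue()].
#' @return A list with `time`, `kind`, `ent`, `seq`, or `NULL` when the queue
#'   is exhausted (end of simulation).
#' @export
eq_pop <- function(q) {
  if (q$n == 0L) return(NULL)
  i <- which.min(q$time[seq_len(q$n)])
  t <- q$time[i]
  if (!is.finite(t)) return(NULL)
  q$time[i] <- Inf
  q$clock <- t
  list(time = t, kind = q$kind[i], ent = q$ent[i], seq = i)
}

# --- resource tokens --------------------------------------------------------

#' Create a resource token
#'
#' A staffed resource (or the scanner, or the pool of dressing rooms) with a
#' capacity, a daily working calendar, and a FIFO queue of waiting requests.
#'
#' @param role Resource role label.
#' @param capacity Positive integer number of interchangeable units.
#' @param open_s,close_s Working calendar, seconds since 8:30 a.m.
#' @return An object of class `resource_token` (environment).
#' @export
resource_token <- function(role, capacity = 1L, open_s = 0, close_s = SEC_DAY) {
  stopifnot(capacity >= 1L, open_s < close_s)
  r <- new.env(parent = emptyenv())
  r$role <- role
  r$capacity <- as.integer(capacity)
  r$open_s <- open_s
  r$close_s <- close_s
  r$n_busy <- 0L
  r$waiting <- list()
  class(r) <- "resource_token"
  r
}

#' Request a unit of a resource
#'
#' If a unit is free and the calendar is open at `at`, the unit is granted
#' immediately; otherwise the request joins a FIFO queue (waiting is the
#' normal outcome, not an error). Queued requests are granted by
#' [release()] or, for requests ahead of opening time, by [release()] at or
#' after the opening.
#'
#' @param resource A [resource_token()].
#' @param entity_id Identifier of the requester.
#' @param at Request time in seconds.
#' @return A list with `granted` (logical) and, when granted, `at` (the grant
#'   time).
#' @export
#' @examples
#' r <- resource_token("nurse", 1, open_s = 1800)
#' seize(r, "p1", at = 0)     # before opening: queued
#' release(r, at = 1800)      # grants p1 at opening
seize <- function(resource, entity_id, at) {
  r <- resource
  if (r$n_busy < r$capacity && at >= r$open_s && at < r$close_s) {
    r$n_busy <- r$n_busy + 1L
    list(granted = TRUE, at = at)
  } else {
    r$waiting <- c(r$waiting, list(list(entity_id = entity_id, at = at)))
    list(granted = FALSE)
  }
}

#' Release a unit of a resource
#'
#' Frees one unit at time `at`; if requests are waiting and the calendar is
#' open, the head of the FIFO queue is granted the unit.
#'
#' @param resource A [resource_token()].
#' @param at Release time in seconds.
#' @return `NULL`, or a list with `entity_id` and `at` (grant time, never
#'   before the calendar opening) for the request just granted.
#' @export
release <- function(resource, at) {
  r <- resource
  if (r$n_busy > 0L) r$n_busy <- r$n_busy - 1L
  if (length(r$waiting) && r$n_busy < r$capacity && at < r$close_s) {
    grant_at <- max(at, r$open_s)
    if (grant_at < r$close_s) {
      head <- r$waiting[[1L]]
      r$waiting <- r$waiting[-1L]
      r$n_busy <- r$n_busy + 1L
      return(list(entity_id = head$entity_id, at = grant_at))
    }
  }
  NULL
}

# --- simulation run ---------------------------------------------------------

new_logbuf <- function() {
  b <- new.env(parent = emptyenv())
  b$day <- integer(1024L); b$ent <- character(1024L); b$role <- character(1024L)
  b$act <- character(1024L); b$state <- character(1024L)
  b$start <- numeric(1024L); b$end <- numeric(1024L)
  b$n <- 0L
  b
}

log_row <- function(b, day, ent, role, act, state, start, end) {
  n <- b$n + 1L
  if (n > length(b$day)) {
    m <- length(b$day)
    b$day <- c(b$day, integer(m)); b$ent <- c(b$ent, character(m))
    b$role <- c(b$role, character(m)); b$act <- c(b$act, character(m))
    b$state <- c(b$state, character(m)); b$start <- c(b$start, numeric(m))
    b$end <- c(b$end, numeric(m))
  }
  b$day[n] <- day; b$ent[n] <- ent; b$role[n] <- role; b$act[n] <- act
  b$state[n] <- state; b$start[n] <- start; b$end[n] <- end
  b$n <- n
  invisible(NULL)
}

#' Run one seeded replication of a scenario
#'
#' Simulates `scenario$days` independent working days of the MRI ward and
#' returns the complete event log (every activity interval for patients,
#' booking visitors, staff and the scanner) plus one record per patient with
#' attributes and outcome (`completed`, `rejected` at entrance screening, or
#' `flushed` by the end-of-day policy). The same scenario and seed always
#' produce an identical log.
#'
#' @param scenario A validated [clinic_scenario()].
#' @param seed Integer replication seed.
#' @param validate Re-validate the scenario before running (default). Disable
#'   only for sensitivity experiments that deliberately step outside the three
#'   shipped policies (e.g. a pandemic pathway without cleaning stages).
#' @return An object of class `clinic_sim`: list with `events` (data.frame:
#'   `day`, `entity_id`, `entity_role`, `activity`, `state_label`, `start_s`,
#'   `end_s`), `patients` (data.frame of patient records), `scenario`, `seed`.
#' @export
#' @examples
#' sim <- clinic_run(clinic_scenario("baseline", days = 1), seed = 1)
#' summary(sim)
clinic_run <- function(scenario, seed = 1L, validate = TRUE) {
  if (!inherits(scenario, "clinic_scenario")) {
    stop("scenario must be a clinic_scenario", call. = FALSE)
  }
  if (validate) validate_scenario(scenario)
  seed <- as.integer(seed)
  s <- scenario

  rcap <- integer(8L); ropen <- numeric(8L); rclose <- numeric(8L)
  names(rcap) <- ROLE_NAMES
  for (i in seq_len(nrow(s$roster))) {
    j <- match(s$roster$role[i], ROLE_NAMES)
    rcap[j] <- s$roster$count[i]
    ropen[j] <- s$roster$open_s[i]
    rclose[j] <- s$roster$close_s[i]
  }
  j <- match("mri_machine", ROLE_NAMES)
  rcap[j] <- 1L; ropen[j] <- 0; rclose[j] <- SEC_DAY
  j <- match("dressing_room", ROLE_NAMES)
  # Dressing rooms have no staff: patients may finish dressing after the
  # last staffed activity of their day.
  rcap[j] <- s$dressing_rooms; ropen[j] <- 0; rclose[j] <- Inf

  mri_latest <- mri_latest_end(s)
  attrs_stream <- new_stream(mix_seed(seed, "attrs"))
  logs <- new_logbuf()

  p_day <- p_id <- p_arr <- p_dep <- p_out <- p_role <- p_exam <- NULL
  p_cmi <- p_temp <- NULL
  prec <- list()

  for (day in seq_len(s$days)) {
    ents <- vector("list", 256L)
    n_ents <- 0L
    pending <- integer()
    rbusy <- integer(8L)
    q <- event_queue()

    arr_p <- generate_arrival_times(s$n_day)
    attrs <- assign_attributes(length(arr_p), s, stream = attrs_stream)
    arr_b <- if (s$booking_only_stream) {
      generate_arrival_times(s$booking_per_day, offset = 0.5)
    } else numeric()

    specs <- list()
    for (i in seq_along(arr_p)) {
      specs[[length(specs) + 1L]] <- list(kind = "patient", idx = i, at = arr_p[i])
    }
    for (i in seq_along(arr_b)) {
      specs[[length(specs) + 1L]] <- list(kind = "booker", idx = i, at = arr_b[i])
    }
    for (i in seq_along(specs)) eq_schedule(q, specs[[i]]$at, kind = 1L, ent = i)
    for (tt in unique(c(ropen[rcap > 0], PUBLIC_OPEN))) {
      if (tt > 0) eq_schedule(q, tt, kind = 3L)
    }

    new_ent <- function(id, role, chain, arrival, attrs_row = NULL) {
      e <- new.env(parent = emptyenv())
      e$id <- id; e$role <- role; e$stages <- chain$stages
      e$final <- chain$outcome; e$k <- 1L; e$outcome <- "active"
      e$past_mri <- FALSE; e$arrival <- arrival; e$depart <- NA_real_
      e$last_end <- arrival
      e$attrs <- attrs_row
      n_ents <<- n_ents + 1L
      if (n_ents > length(ents)) length(ents) <<- 2L * n_ents
      ents[[n_ents]] <<- e
      n_ents
    }

    flush_ent <- function(e, t) {
      e$outcome <- "flushed"
      e$depart <- max(t, e$last_end)
    }

    start_stage <- function(ei, t) {
      e <- ents[[ei]]
      st <- e$stages[[e$k]]
      res <- st$res
      endt <- t + st$dur
      e$last_end <- endt
      if (length(res)) rbusy[res] <<- rbusy[res] + 1L
      if (is.null(st$parts)) {
        if (e$role != "task") {
          log_row(logs, day, e$id, e$role, st$act, st$pstate, t, endt)
        }
        for (ri in seq_along(res)) {
          log_row(logs, day, e$id, ROLE_NAMES[res[ri]],
                  st$act, st$rstate[ri], t, endt)
        }
        if (st$mri == 2L) {
          log_row(logs, day, e$id, "mri_machine", st$act, "blocked", t, endt)
        }
      } else {
        # positioning + exam block: split the log at the part boundary
        cut <- t + st$parts$durs[1L]
        bounds <- c(t, cut, endt)
        for (pi in 1:2) {
          nm <- st$parts$names[pi]
          log_row(logs, day, e$id, e$role, nm, st$pstate, bounds[pi], bounds[pi + 1L])
          log_row(logs, day, e$id, "technician", nm, "examination",
                  bounds[pi], bounds[pi + 1L])
          log_row(logs, day, e$id, "mri_machine", nm, "busy",
                  bounds[pi], bounds[pi + 1L])
        }
      }
      eq_schedule(q, endt, kind = 2L, ent = ei)
    }

    dispatch <- function(t) {
      j <- 1L
      while (j <= length(pending)) {
        ei <- pending[j]
        e <- ents[[ei]]
        st <- e$stages[[e$k]]
        res <- st$res
        if (length(res) && (any(rbusy[res] >= rcap[res]) || any(ropen[res] > t))) {
          j <- j + 1L
          next
        }
        endt <- t + st$dur
        if (length(res) && any(endt > rclose[res])) {
          # cannot finish within some required calendar today
          if (e$role == "task") e$outcome <- "dropped" else flush_ent(e, t)
          pending <<- pending[-j]
          next
        }
        if (st$gate && endt > mri_latest) {
          flush_ent(e, t)
          pending <<- pending[-j]
          next
        }
        if (st$gate) e$past_mri <- TRUE
        start_stage(ei, t)
        pending <<- pending[-j]
      }
    }

    handle_end <- function(ei, t) {
      e <- ents[[ei]]
      st <- e$stages[[e$k]]
      if (length(st$res)) rbusy[st$res] <<- rbusy[st$res] - 1L
      if (!is.null(st$spawn)) {
        spawned <- integer()
        for (sp in st$spawn) {
          ti <- new_ent(sprintf("task_d%d_%d", day, n_ents + 1L), "task",
                        list(stages = list(task_stage(sp$act, sp$dur)),
                             outcome = "completed"), t)
          spawned <- c(spawned, ti)
        }
        # staff follow-up tasks (consultation, sanitation) take precedence
        # over waiting patients for the staff and the scanner
        pending <<- c(spawned, pending)
      }
      e$k <- e$k + 1L
      if (e$k > length(e$stages)) {
        e$outcome <- e$final
        e$depart <- t
      } else {
        pending <<- c(pending, ei)
      }
    }

    repeat {
      ev <- eq_pop(q)
      if (is.null(ev)) break
      t <- ev$time
      if (ev$kind == 1L) {
        sp <- specs[[ev$ent]]
        if (sp$kind == "patient") {
          streams <- list(
            dur = new_stream(mix_seed(seed, day, sp$idx, "patient")),
            consult = new_stream(mix_seed(seed, day, sp$idx, "consult")),
            clean = new_stream(mix_seed(seed, day, sp$idx, "clean"))
          )
          chain <- patient_chain(s, attrs[sp$idx, ], streams)
          ei <- new_ent(sprintf("p_d%d_%02d", day, sp$idx), "patient", chain,
                        t, attrs_row = sp$idx)
          pending <- c(pending, ei)
        } else {
          stream <- new_stream(mix_seed(seed, day, sp$idx, "booker"))
          ei <- new_ent(sprintf("b_d%d_%02d", day, sp$idx), "booker",
                        booker_chain(stream), t)
          pending <- c(pending, ei)
        }
      } else if (ev$kind == 2L) {
        handle_end(ev$ent, t)
      }
      dispatch(t)
    }

    # end-of-day sweep: whoever is still active did not finish the pathway
    day_rows <- vector("list", n_ents)
    for (i in seq_len(n_ents)) {
      e <- ents[[i]]
      if (e$outcome == "active") {
        if (e$role == "task") {
          e$outcome <- "dropped"
        } else {
          flush_ent(e, if (e$past_mri) SEC_DAY else PUBLIC_CLOSE)
        }
      }
      if (e$role %in% c("patient", "booker")) {
        ai <- e$attrs
        day_rows[[i]] <- list(
          e$id, e$role, e$arrival,
          if (is.null(ai)) NA_character_ else attrs$exam_type[ai],
          if (is.null(ai)) NA else attrs$needs_cmi[ai],
          if (is.null(ai)) NA_real_ else attrs$temperature_c[ai],
          e$outcome, e$depart
        )
      }
    }
    day_rows <- day_rows[!vapply(day_rows, is.null, TRUE)]
    if (length(day_rows)) {
      prec[[day]] <- data.frame(
        day = day,
        patient_id = vapply(day_rows, function(r) r[[1L]], ""),
        role = vapply(day_rows, function(r) r[[2L]], ""),
        arrival_s = vapply(day_rows, function(r) r[[3L]], 0),
        exam_type = vapply(day_rows, function(r) r[[4L]], ""),
        needs_cmi = vapply(day_rows, function(r) r[[5L]], NA),
        temperature_c = vapply(day_rows, function(r) r[[6L]], 0),
        outcome = vapply(day_rows, function(r) r[[7L]], ""),
        depart_s = vapply(day_rows, function(r) r[[8L]], 0),
        stringsAsFactors = FALSE
      )
    }
  }

  n <- logs$n
  events <- data.frame(
    day = logs$day[seq_len(n)], entity_id = logs$ent[seq_len(n)],
    entity_role = logs$role[seq_len(n)], activity = logs$act[seq_len(n)],
    state_label = logs$state[seq_len(n)], start_s = logs$start[seq_len(n)],
    end_s = logs$end[seq_len(n)], stringsAsFactors = FALSE
  )
  events <- events[order(events$day, events$start_s, events$end_s), ]
  rownames(events) <- NULL
  patients <- if (length(prec)) do.call(rbind, prec) else data.frame(
    day = integer(), patient_id = character(), role = character(),
    arrival_s = numeric(), exam_type = character(), needs_cmi = logical(),
    temperature_c = numeric(), outcome = character(), depart_s = numeric(),
    stringsAsFactors = FALSE
  )
  structure(list(events = events, patients = patients, scenario = s,
                 seed = seed),
            class = c("clinic_sim", "clinic_log"))
}
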