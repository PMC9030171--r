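# Configuration files, log serialisation, fixtures and run manifests.

scenario_scalar_fields <- function() {
  c("scenario_id", "days", "n_day", "booking_per_day", "p_single", "p_cmi",
    "p_fever", "p_self_escort", "walk_time_s", "dressing_rooms",
    "entrance_screening", "cleaning_after_exam", "onsite_diagnosis",
    "booking_only_stream", "nurse_in_anamnesis", "nurse_escort")
}

#' Save a scenario configuration to YAML
#'
#' @param scenario A [clinic_scenario()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_scenario_config <- function(scenario, path) {
  cfg <- lapply(scenario_scalar_fields(), function(f) scenario[[f]])
  names(cfg) <- scenario_scalar_fields()
  cfg$roster <- lapply(seq_len(nrow(scenario$roster)), function(i) {
    as.list(scenario$roster[i, ])
  })
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Load and validate a scenario configuration from YAML
#'
#' Unknown keys are rejected; the loaded configuration passes the full
#' [validate_scenario()] check, with errors naming the offending field.
#'
#' @param path A YAML file written by [save_scenario_config()] (the package
#'   ships `baseline.yaml`, `covid.yaml` and `covid_improved.yaml` under
#'   `extdata`).
#' @return A validated [clinic_scenario()].
#' @export
#' @examples
#' p <- system.file("extdata", "baseline.yaml", package = "clinicdes")
#' load_scenario_config(p)$scenario_id
load_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c(scenario_scalar_fields(), "roster")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$scenario_id)) stop("configuration lacks scenario_id", call. = FALSE)
  int_fields <- c("days", "n_day", "booking_per_day", "dressing_rooms")
  num_fields <- c("p_single", "p_cmi", "p_fever", "p_self_escort", "walk_time_s")
  overrides <- list()
  for (f in setdiff(names(cfg), c("scenario_id", "roster"))) {
    v <- cfg[[f]]
    if (f %in% int_fields) v <- as.integer(v)
    if (f %in% num_fields) v <- as.numeric(v)
    overrides[[f]] <- v
  }
  if (!is.null(cfg$roster)) {
    overrides$roster <- do.call(rbind, lapply(cfg$roster, function(r) {
      data.frame(role = as.character(r$role), count = as.integer(r$count),
                 open_s = as.numeric(r$open_s), close_s = as.numeric(r$close_s),
                 stringsAsFactors = FALSE)
    }))
  }
  clinic_scenario(cfg$scenario_id, overrides = overrides)
}

#' Write an event log to CSV
#'
#' Columns: `replication`, `day`, `entity_id`, `entity_role`, `activity`,
#' `state_label`, `start_s`, `end_s`.
#'
#' @param x A `clinic_sim` from [clinic_run()].
#' @param path Output CSV path.
#' @param replication Replication identifier column value (defaults to the
#'   run seed).
#' @return `path`, invisibly.
#' @export
write_event_log <- function(x, path, replication = x$seed) {
  ev <- cbind(replication = replication, x$events)
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' Write per-patient records to CSV
#'
#' @param x A `clinic_sim` from [clinic_run()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patient_records <- function(x, path) {
  utils::write.csv(x$patients, path, row.names = FALSE)
  invisible(path)
}

#' Write a KPI report to JSON
#'
#' @param report A `clinic_kpi` from [kpi_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_kpi_json <- function(report, path) {
  out <- list(
    scenario_id = report$scenario_id,
    days = report$days,
    throughput = report$throughput,
    mri = report$mri[c("busy_h_per_day", "pct")],
    downtime_min_per_day = as.list(report$downtime_min),
    downtime_pct_of_downtime = as.list(report$downtime_pct_of_downtime),
    downtime_pct_of_time = as.list(report$downtime_pct_of_time),
    staff_utilization_pct = as.list(report$staff_utilization_pct),
    operational_means_min = as.list(report$operational_means)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Build a hand-specified event log
#'
#' Turns a compact interval description into a syntactically valid simulation
#' log so that KPI computations can be checked against hand arithmetic.
#' Overlapping intervals on a single-capacity resource (any staffed role or
#' the scanner) are rejected.
#'
#' @param intervals A data.frame with columns `entity_id`, `entity_role`,
#'   `activity`, `state_label`, `start_s`, `end_s` and optionally `day`
#'   (default 1).
#' @param patients Optional patient-record data.frame; when omitted, minimal
#'   records (arrival at first interval, outcome `"completed"`) are derived
#'   from rows whose `entity_role` is `"patient"`.
#' @param scenario_id Scenario whose roster/flags the log should be read
#'   under.
#' @param days Horizon; defaults to the largest `day` present.
#' @return A `clinic_sim`-compatible object of class `clinic_log`.
#' @export
#' @examples
#' iv <- data.frame(entity_id = "p_d1_01", entity_role = "patient",
#'                  activity = "registration",
#'                  state_label = "receiving_indirect_care",
#'                  start_s = 1800, end_s = 2100)
#' log <- make_fixture_log(iv)
#' patient_times(log)
make_fixture_log <- function(intervals, patients = NULL,
                             scenario_id = "baseline", days = NULL) {
  need <- c("entity_id", "entity_role", "activity", "state_label",
            "start_s", "end_s")
  if (nrow(intervals) && !all(need %in% names(intervals))) {
    stop("intervals must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(intervals$day)) intervals$day <- if (nrow(intervals)) 1L else integer()
  if (nrow(intervals) && any(intervals$end_s < intervals$start_s)) {
    stop("malformed interval: end before start", call. = FALSE)
  }
  single_cap <- setdiff(ROLE_NAMES, "dressing_room")
  for (d in unique(intervals$day)) {
    for (r in intersect(unique(intervals$entity_role), single_cap)) {
      iv <- intervals[intervals$day == d & intervals$entity_role == r, ]
      iv <- iv[order(iv$start_s), ]
      if (nrow(iv) > 1L && any(iv$start_s[-1L] < iv$end_s[-nrow(iv)] - 1e-9)) {
        stop("overlapping intervals for capacity-1 resource '", r, "' on day ",
             d, call. = FALSE)
      }
    }
  }
  scenario <- clinic_scenario(scenario_id,
                              days = max(c(intervals$day, 1L)))
  if (!is.null(days)) scenario$days <- as.integer(days)
  if (is.null(patients)) {
    pids <- unique(intervals$entity_id[intervals$entity_role == "patient"])
    patients <- do.call(rbind, c(lapply(pids, function(id) {
      iv <- intervals[intervals$entity_id == id &
                        intervals$entity_role == "patient", ]
      data.frame(day = iv$day[1L], patient_id = id, role = "patient",
                 arrival_s = min(iv$start_s),
                 exam_type = "single",
                 needs_cmi = any(iv$activity == "cmi"),
                 temperature_c = 36.5, outcome = "completed",
                 depart_s = max(iv$end_s), stringsAsFactors = FALSE)
    }), list(data.frame())))
  }
  ev <- intervals[, c("day", need)]
  structure(list(events = ev, patients = patients, scenario = scenario,
                 seed = NA_integer_),
            class = c("clinic_sim", "clinic_log"))
}

#' Write a run manifest
#'
#' Records tool version, scenario identity and fingerprint, seed, timestamp
#' and output paths alongside every CLI run, sufficient to reproduce it.
#'
#' @param path Output JSON path.
#' @param scenario A [clinic_scenario()].
#' @param seed Integer seed used.
#' @param outputs Character vector of produced file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, scenario, seed, outputs = character()) {
  cfg <- lapply(scenario_scalar_fields(), function(f) scenario[[f]])
  fp <- mix_seed(0L, paste(vapply(cfg, function(v) paste(format(v), collapse = ","),
                                  ""), collapse = ";"))
  out <- list(
    tool = "clinicdes",
    version = as.character(utils::packageVersion("clinicdes")),
    scenario_id = scenario$scenario_id,
    config_fingerprint = fp,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
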