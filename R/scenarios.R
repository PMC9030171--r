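# Operating-policy scenarios as declarative deltas on a common base.
#
# Three policies are shipped:
#   baseline       - ordinary operations: four staffed roles, on-site
#                    diagnosis communication, walk-in booking visitors.
#   covid          - pandemic infection control: entrance screening (hand
#                    sanitation, temperature check, mask and gloves) run by an
#                    added clerk, post-exam sanitation run by an added
#                    cleaner, fever rejection at 37.5 degrees C.
#   covid_improved - pandemic policy plus three organisational changes:
#                    booking moves to phone/online (no walk-in bookers),
#                    diagnosis is communicated telematically (no on-site
#                    reporting stage), and the nurse is relieved from the
#                    anamnesis and (mostly) from escorting.

scenario_ids <- function() c("baseline", "covid", "covid_improved")

base_roster <- function(scenario_id) {
  r <- data.frame(
    role = c("receptionist", "nurse", "physician", "technician"),
    count = 1L,
    open_s = c(0, PUBLIC_OPEN, PUBLIC_OPEN, 0),
    close_s = c(SEC_DAY, PUBLIC_CLOSE, PUBLIC_CLOSE, SEC_DAY),
    stringsAsFactors = FALSE
  )
  if (scenario_id != "baseline") {
    r <- rbind(r, data.frame(
      role = c("clerk", "cleaner"),
      count = 1L,
      open_s = c(PUBLIC_OPEN, PUBLIC_OPEN),
      close_s = c(PUBLIC_CLOSE, SEC_DAY),
      stringsAsFactors = FALSE
    ))
  }
  r
}

scenario_defaults <- function(scenario_id) {
  common <- list(
    scenario_id = scenario_id,
    days = 7L,
    # Arrivals/day and fever prevalence are the two calibrated knobs; their
    # values come from scripts/calibrate_defaults.R (see the methods vignette).
    n_day = 20L,
    booking_per_day = 4L,
    p_single = 0.80,
    p_cmi = 0.30,
    p_fever = 0.21,
    p_self_escort = 0.80,
    walk_time_s = 30,
    dressing_rooms = 2L,
    entrance_screening = TRUE,
    cleaning_after_exam = TRUE,
    onsite_diagnosis = TRUE,
    booking_only_stream = TRUE,
    nurse_in_anamnesis = TRUE,
    nurse_escort = TRUE,
    roster = base_roster(scenario_id)
  )
  deltas <- switch(scenario_id,
    baseline = list(entrance_screening = FALSE, cleaning_after_exam = FALSE,
                    p_fever = 0),
    covid = list(),
    covid_improved = list(onsite_diagnosis = FALSE, booking_only_stream = FALSE,
                          nurse_in_anamnesis = FALSE, nurse_escort = FALSE),
    stop("unknown scenario_id: ", scenario_id, call. = FALSE)
  )
  utils::modifyList(common, deltas)
}

#' Construct an operating-policy scenario
#'
#' Builds a fully validated scenario configuration: staff roster with working
#' calendars, pathway flags, arrival plan and attribute probabilities. The
#' shipped defaults encode the three studied policies; any field can be
#' overridden (overrides are applied last, then the whole configuration is
#' re-validated).
#'
#' @param scenario_id `"baseline"`, `"covid"` or `"covid_improved"`.
#' @param overrides Named list of fields to override (e.g. `list(days = 1)`).
#' @param ... Individual overrides, a convenience alternative to `overrides`.
#' @return An object of class `clinic_scenario`.
#' @export
#' @examples
#' clinic_scenario("baseline", days = 1)
#' clinic_scenario("covid")$roster
clinic_scenario <- function(scenario_id = c("baseline", "covid", "covid_improved"),
                            overrides = list(), ...) {
  scenario_id <- match.arg(scenario_id)
  cfg <- scenario_defaults(scenario_id)
  overrides <- utils::modifyList(overrides, list(...))
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop("unknown scenario field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg <- utils::modifyList(cfg, overrides)
  }
  cfg <- structure(cfg, class = "clinic_scenario")
  validate_scenario(cfg)
  cfg
}

#' @rdname clinic_scenario
#' @export
make_scenario <- clinic_scenario

# Latest admissible end of an MRI positioning+exam block. The last patient
# always leaves the scanner before the 8:00 p.m. public close (the half hour
# to clinic close is never scanned, in any policy). When diagnosis is
# communicated on site the block must additionally leave room for the mean
# post-exam chain (two walks, dress, diagnosis) plus a small allowance for
# sampling variation, so the reporting fits the physician's calendar.
mri_latest_end <- function(scenario) {
  if (scenario$onsite_diagnosis) {
    post_chain <- 2 * scenario$walk_time_s + 180 + 300 + 60
    PUBLIC_CLOSE - post_chain
  } else {
    PUBLIC_CLOSE
  }
}

#' Validate a scenario configuration
#'
#' Checks field types and ranges and the per-policy structural invariants
#' (e.g. the pandemic policy requires the clerk and the cleaner on the roster
#' and entrance screening enabled). Errors name the violated rule.
#'
#' @param scenario A [clinic_scenario()].
#' @return The scenario, invisibly, if valid.
#' @export
validate_scenario <- function(scenario) {
  s <- scenario
  fail <- function(rule) stop("invalid scenario '", s$scenario_id, "': ", rule,
                              call. = FALSE)
  for (p in c("p_single", "p_cmi", "p_fever", "p_self_escort")) {
    v <- s[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      fail(paste0(p, " must be a probability in [0, 1]"))
    }
  }
  if (!is.numeric(s$days) || s$days < 1) fail("days must be >= 1")
  if (!is.numeric(s$n_day) || s$n_day < 0) fail("n_day must be >= 0")
  if (s$walk_time_s < 0) fail("walk_time_s must be >= 0")
  if (s$dressing_rooms < 1) fail("dressing_rooms must be >= 1")
  count_of <- function(role) {
    i <- match(role, s$roster$role)
    if (is.na(i)) 0L else s$roster$count[i]
  }
  if (s$scenario_id == "baseline") {
    if (count_of("clerk") != 0L) fail("baseline requires clerk count 0")
    if (count_of("cleaner") != 0L) fail("baseline requires cleaner count 0")
    if (s$entrance_screening) fail("baseline has no entrance screening")
    if (s$cleaning_after_exam) fail("baseline has no post-exam cleaning")
    if (!s$onsite_diagnosis) fail("baseline communicates diagnosis on site")
    if (!s$booking_only_stream) fail("baseline keeps the walk-in booking stream")
    if (!s$nurse_in_anamnesis) fail("baseline keeps the nurse in the anamnesis")
  } else {
    if (count_of("clerk") != 1L) fail("pandemic policies require clerk count 1")
    if (count_of("cleaner") != 1L) fail("pandemic policies require cleaner count 1")
    if (!s$entrance_screening) fail("pandemic policies require entrance screening")
    if (!s$cleaning_after_exam) fail("pandemic policies require post-exam cleaning")
  }
  if (s$scenario_id == "covid_improved") {
    if (s$onsite_diagnosis) fail("covid_improved discards on-site diagnosis")
    if (s$booking_only_stream) fail("covid_improved removes walk-in booking")
    if (s$nurse_in_anamnesis) fail("covid_improved relieves the nurse from anamnesis")
  }
  required <- c("receptionist", "nurse", "physician", "technician")
  if (!all(required %in% s$roster$role)) fail("roster must staff the four core roles")
  if (any(s$roster$open_s >= s$roster$close_s)) fail("roster calendars must open before they close")
  invisible(scenario)
}

#' Structured difference between two scenarios
#'
#' Lists every field whose value differs between two configurations; the delta
#' is empty if and only if the configurations are equal.
#'
#' @param a,b [clinic_scenario()] objects.
#' @return A data.frame with columns `field`, `a`, `b` (values deparsed to
#'   character).
#' @export
#' @examples
#' diff_scenarios(clinic_scenario("covid"), clinic_scenario("covid_improved"))
diff_scenarios <- function(a, b) {
  stopifnot(inherits(a, "clinic_scenario"), inherits(b, "clinic_scenario"))
  fields <- union(names(a), names(b))
  rows <- lapply(fields, function(f) {
    va <- a[[f]]; vb <- b[[f]]
    if (identical(va, vb)) return(NULL)
    fmt <- function(v) {
      if (is.data.frame(v)) paste(apply(v, 1L, paste, collapse = "/"), collapse = "; ")
      else paste(format(v), collapse = ",")
    }
    data.frame(field = f, a = fmt(va), b = fmt(vb), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(field = character(),
                                                a = character(), b = character(),
                                                stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' @export
print.clinic_scenario <- function(x, ...) {
  cat(sprintf("<clinic_scenario> %s: %d day(s), %d exam arrivals/day\n",
              x$scenario_id, x$days, x$n_day))
  flags <- c(screening = x$entrance_screening, cleaning = x$cleaning_after_exam,
             onsite_diagnosis = x$onsite_diagnosis,
             booking_stream = x$booking_only_stream,
             nurse_in_anamnesis = x$nurse_in_anamnesis)
  cat("  flags:", paste(names(flags), ifelse(flags, "on", "off"), sep = "=",
                        collapse = " "), "\n")
  cat(sprintf("  p_single=%.2f p_cmi=%.2f p_fever=%.2f walk=%gs\n",
              x$p_single, x$p_cmi, x$p_fever, x$walk_time_s))
  cat("  roster:", paste(x$roster$role, collapse = ", "), "\n")
  invisible(x)
}
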