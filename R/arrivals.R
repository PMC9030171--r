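# The elective patient stream: equally spaced arrivals and stochastic patient
# attributes. The arrival interval is the model's single input factor; the
# weekly patient volume is an output of the simulation, not an input.

#' Equally spaced elective arrival times
#'
#' Elective MRI appointments are booked on a regular grid: `n_day` arrivals per
#' day, the first at public opening (9:00 a.m.), then equally spaced across the
#' 11 h public-access window. Timing is deterministic; only patient attributes
#' are stochastic.
#'
#' @param n_day Arrivals per day (>= 0).
#' @param days Number of working days.
#' @param offset Fraction of one spacing by which to shift the whole grid
#'   (used for the booking-only visitor stream so it interleaves with, rather
#'   than coincides with, exam patients). Default 0.
#' @return Numeric vector of `n_day * days` times in seconds since 8:30 a.m.
#'   of day 1; consecutive days are offset by 43200 s (the 12 h window).
#' @export
#' @examples
#' generate_arrival_times(1)            # 1800 s = 9:00 a.m.
#' diff(generate_arrival_times(18))[1:3]
generate_arrival_times <- function(n_day, days = 1L, offset = 0) {
  if (n_day < 0) stop("n_day must be >= 0", call. = FALSE)
  if (n_day == 0L) return(numeric())
  span <- PUBLIC_CLOSE - PUBLIC_OPEN
  spacing <- span / n_day
  if (spacing < 1) stop("n_day too large: arrival spacing below 1 s", call. = FALSE)
  within_day <- PUBLIC_OPEN + (seq_len(n_day) - 1L + offset) * spacing
  as.vector(outer(within_day, (seq_len(days) - 1L) * SEC_DAY, `+`))
}

#' Draw stochastic patient attributes
#'
#' Attributes are independent Bernoulli draws per patient: examination type
#' (single body region with probability `p_single`, else multiple), need for a
#' contrast-medium injection (`p_cmi`), and fever (`p_fever`, body temperature
#' at or above 37.5 degrees C). A body temperature in degrees C is synthesized
#' for the record (38.0 if fevered, else 36.5) since only the threshold
#' crossing affects the pathway. Under the improved pandemic organisation a
#' self-escort indicator is also drawn (`p_self_escort`); in the other
#' scenarios the nurse always escorts.
#'
#' @param n Number of patients.
#' @param scenario A [clinic_scenario()].
#' @param stream Optional private RNG stream; defaults to the session RNG.
#' @return A data.frame with columns `exam_type`, `needs_cmi`,
#'   `temperature_c`, `self_escort`.
#' @export
assign_attributes <- function(n, scenario, stream = NULL) {
  draw <- function() {
    data.frame(
      exam_type = ifelse(stats::runif(n) < scenario$p_single, "single", "multiple"),
      needs_cmi = stats::runif(n) < scenario$p_cmi,
      temperature_c = ifelse(stats::runif(n) < scenario$p_fever, 38.0, 36.5),
      self_escort = stats::runif(n) < scenario$p_self_escort &
        !scenario$nurse_escort,
      stringsAsFactors = FALSE
    )
  }
  if (n == 0L) {
    return(data.frame(exam_type = character(), needs_cmi = logical(),
                      temperature_c = numeric(), self_escort = logical()))
  }
  if (is.null(stream)) draw() else with_stream(stream, draw)
}

#' Entrance temperature screening decision
#'
#' In the pandemic scenarios every entering patient is screened and turned
#' away if the measured body temperature is at or above 37.5 degrees C
#' (threshold inclusive). The ordinary scenario has no screening stage, so
#' every patient is admitted regardless of temperature.
#'
#' @param temperature_c Body temperature(s) in degrees C.
#' @param scenario A [clinic_scenario()].
#' @return Character vector, `"admit"` or `"reject"` per patient.
#' @export
#' @examples
#' s <- clinic_scenario("covid")
#' screen_temperature(c(36.6, 37.5), s)
screen_temperature <- function(temperature_c, scenario) {
  if (!scenario$entrance_screening) return(rep("admit", length(temperature_c)))
  ifelse(temperature_c >= FEVER_THRESHOLD_C, "reject", "admit")
}
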