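# Monte-Carlo replication statistics and knob calibration.

#' Run seeded replications and summarise KPI distributions
#'
#' Runs `n` independent replications of a scenario. Replication `k` uses the
#' seed `mix_seed(base_seed, k, "rep")`, so the whole experiment is
#' reproducible from `(scenario, n, base_seed)` and two scenarios replicated
#' from the same `base_seed` share their seed list (paired comparisons).
#'
#' @param scenario A [clinic_scenario()].
#' @param n Number of replications (>= 1).
#' @param base_seed Integer experiment seed.
#' @return An object of class `clinic_replication`: `summary` (data.frame
#'   with per-metric mean, sd and Student-t 95% confidence bounds; sd and the
#'   interval are 0-width when `n = 1`), `reps` (n x metric matrix), `seeds`,
#'   `scenario_id`, `n`.
#' @export
#' @examples
#' \donttest{
#' r <- run_replications(clinic_scenario("baseline", days = 1), n = 2, base_seed = 1)
#' r$summary[r$summary$metric == "mri_utilization_pct", ]
#' }
run_replications <- function(scenario, n, base_seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  seeds <- vapply(seq_len(n), function(k) mix_seed(base_seed, k, "rep"), 0L)
  mats <- lapply(seeds, function(sd) metric_vector(kpi_report(clinic_run(scenario, sd))))
  metrics <- names(mats[[1L]])
  reps <- do.call(rbind, lapply(mats, function(v) v[metrics]))
  rownames(reps) <- NULL
  mu <- colMeans(reps)
  sdv <- if (n > 1) apply(reps, 2L, stats::sd) else rep(0, length(mu))
  half <- if (n > 1) stats::qt(0.975, n - 1) * sdv / sqrt(n) else rep(0, length(mu))
  summary <- data.frame(metric = metrics, mean = unname(mu), sd = unname(sdv),
                        ci_low = unname(mu - half), ci_high = unname(mu + half),
                        stringsAsFactors = FALSE)
  structure(list(scenario_id = scenario$scenario_id, n = n, seeds = seeds,
                 summary = summary, reps = reps),
            class = "clinic_replication")
}

#' @export
print.clinic_replication <- function(x, ...) {
  cat(sprintf("<clinic_replication> %s: %d replication(s)\n", x$scenario_id, x$n))
  key <- c("throughput_week", "mri_utilization_pct", "mri_busy_h_per_day")
  s <- x$summary[x$summary$metric %in% key, ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-22s mean %8.2f  sd %6.2f  95%% CI [%.2f, %.2f]\n",
                s$metric[i], s$mean[i], s$sd[i], s$ci_low[i], s$ci_high[i]))
  }
  invisible(x)
}

#' Simulate replications of a scenario
#'
#' S3 [stats::simulate()] method: `simulate(scenario, nsim, seed)` is
#' equivalent to [run_replications()].
#'
#' @param object A [clinic_scenario()].
#' @param nsim Number of replications.
#' @param seed Integer experiment seed.
#' @param ... Unused.
#' @return A `clinic_replication` object.
#' @export
simulate.clinic_scenario <- function(object, nsim = 1, seed = 1L, ...) {
  run_replications(object, n = nsim, base_seed = seed)
}

#' Calibrate a scenario knob against a KPI target
#'
#' Bisection on a single scalar (optionally integer) scenario field so that
#' the replicated mean of a KPI matches a target. The response must be
#' monotone over the bounds; this is checked empirically at the two bounds
#' before searching. Used by the shipped calibration of the arrival volume
#' (`n_day` against the ordinary weekly throughput) and of the fever
#' prevalence (`p_fever` against the pandemic weekly throughput).
#'
#' @param scenario A [clinic_scenario()]; the knob is overridden in place.
#' @param knob Name of the scenario field to tune.
#' @param target_metric Metric name as in `run_replications()$summary$metric`.
#' @param target_value Desired replicated mean.
#' @param bounds Length-2 numeric search interval.
#' @param n_reps Replications per evaluation.
#' @param base_seed Experiment seed.
#' @param tol Acceptable |achieved - target|.
#' @param integer_knob Restrict the knob to integers.
#' @param max_iter Bisection iteration cap.
#' @return List with `knob`, `value`, `achieved`, `trace` (evaluation log).
#' @export
calibrate <- function(scenario, knob, target_metric, target_value, bounds,
                      n_reps = 5L, base_seed = 1L, tol = 1, integer_knob = FALSE,
                      max_iter = 25L) {
  stopifnot(length(bounds) == 2L, bounds[1L] < bounds[2L])
  trace <- list()
  f <- function(v) {
    if (integer_knob) v <- as.integer(round(v))
    sc <- scenario
    sc[[knob]] <- v
    validate_scenario(sc)
    r <- run_replications(sc, n = n_reps, base_seed = base_seed)
    m <- r$summary$mean[r$summary$metric == target_metric]
    trace[[length(trace) + 1L]] <<- data.frame(knob_value = v, metric = m)
    m
  }
  lo <- bounds[1L]; hi <- bounds[2L]
  flo <- f(lo); fhi <- f(hi)
  if (abs(fhi - flo) < 1e-9) {
    stop("knob '", knob, "' has no detectable effect on ", target_metric,
         " over the given bounds", call. = FALSE)
  }
  sgn <- if (fhi > flo) 1 else -1
  if (abs(flo - target_value) <= tol) {
    return(list(knob = knob, value = lo, achieved = flo,
                trace = do.call(rbind, trace)))
  }
  if (abs(fhi - target_value) <= tol) {
    return(list(knob = knob, value = hi, achieved = fhi,
                trace = do.call(rbind, trace)))
  }
  if ((flo - target_value) * (fhi - target_value) > 0) {
    stop("bounds do not bracket the target: f(", lo, ")=", round(flo, 2),
         ", f(", hi, ")=", round(fhi, 2), ", target=", target_value,
         call. = FALSE)
  }
  best_v <- lo; best_f <- flo
  if (abs(fhi - target_value) < abs(flo - target_value)) { best_v <- hi; best_f <- fhi }
  for (it in seq_len(max_iter)) {
    if (integer_knob && (hi - lo) <= 1) break
    mid <- if (integer_knob) floor((lo + hi) / 2) else (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target_value) < abs(best_f - target_value)) {
      best_v <- mid; best_f <- fm
    }
    if (abs(fm - target_value) <= tol && !integer_knob) break
    if (sgn * (fm - target_value) < 0) lo <- mid else hi <- mid
    if (!integer_knob && (hi - lo) < 1e-6) break
  }
  list(knob = knob, value = if (integer_knob) as.integer(best_v) else best_v,
       achieved = best_f, trace = do.call(rbind, trace))
}
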