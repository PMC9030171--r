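# Print, summary and plot methods for simulation objects.

#' @export
print.clinic_sim <- function(x, ...) {
  thr <- throughput(x)
  cat(sprintf("<clinic_sim> %s, %d day(s), seed %d\n",
              x$scenario$scenario_id, x$scenario$days, x$seed))
  cat(sprintf("  patients: %d arrived, %d completed, %d rejected, %d flushed\n",
              thr$arrivals, thr$patients_week, thr$rejected, thr$flushed))
  mri <- mri_utilization(x)
  cat(sprintf("  MRI: %.2f h busy/day (%.1f%% of the 12 h window)\n",
              mri$busy_h_per_day, mri$pct))
  invisible(x)
}

#' Summarise a replication as a KPI report
#'
#' @param object A `clinic_sim` from [clinic_run()].
#' @param ... Unused.
#' @return A `clinic_kpi` report (see [kpi_report()]).
#' @export
summary.clinic_sim <- function(object, ...) kpi_report(object)

#' @export
print.clinic_kpi <- function(x, ...) {
  cat(sprintf("MRI diagnostic ward KPIs - scenario %s (%d days)\n",
              x$scenario_id, x$days))
  cat("Productivity:\n")
  cat(sprintf("  throughput           %d patients/week (%d CMI), %d rejected, %d flushed\n",
              x$throughput$patients_week, x$throughput$cmi_patients_week,
              x$throughput$rejected, x$throughput$flushed))
  cat(sprintf("  MRI utilization      %.2f h/day = %.1f%%\n",
              x$mri$busy_h_per_day, x$mri$pct))
  cat("  MRI downtime (min/day; % of downtime; % of the 12 h window):\n")
  for (nm in names(x$downtime_min)) {
    cat(sprintf("    %-19s %6.1f  %5.1f%%  %5.1f%%\n", nm, x$downtime_min[[nm]],
                x$downtime_pct_of_downtime[[nm]], x$downtime_pct_of_time[[nm]]))
  }
  cat("  staff utilization   ",
      paste(sprintf("%s %.1f%%", names(x$staff_utilization_pct),
                    x$staff_utilization_pct), collapse = ", "), "\n")
  if (!is.null(x$operational_means)) {
    cat("Operational (means over treated patients, min):\n")
    cat(sprintf("  facility %.1f = direct %.1f + indirect %.1f + transit %.1f + idle %.1f + sanitizing %.1f\n",
                x$operational_means[["facility_min"]],
                x$operational_means[["direct_care_min"]],
                x$operational_means[["indirect_care_min"]],
                x$operational_means[["transit_min"]],
                x$operational_means[["idle_min"]],
                x$operational_means[["sanitizing_min"]]))
  }
  invisible(x)
}

#' Plot the daily MRI timeline decomposition
#'
#' Stacked bars, one per simulated day: scanner busy time plus the seven
#' downtime categories (720 min total per day).
#'
#' @param x A `clinic_sim` from [clinic_run()].
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the matrix plotted.
#' @export
plot.clinic_sim <- function(x, ...) {
  dt <- attribute_downtime(x)
  cats <- c("busy_min", "public_closure", "first_patient", "last_patient",
            "cmi", "staff_consultation", "sanitation", "other")
  m <- t(as.matrix(dt[, cats]))
  colnames(m) <- paste("day", dt$day)
  cols <- c("grey25", "grey85", "skyblue3", "steelblue4", "goldenrod2",
            "darkolivegreen4", "indianred3", "grey60")
  graphics::barplot(m, col = cols, ylab = "minutes per day",
                    main = sprintf("MRI timeline - %s", x$scenario$scenario_id),
                    legend.text = c("busy", "public closure", "first patient",
                                    "last patient", "CMI", "staff consultation",
                                    "sanitation", "other"),
                    args.legend = list(x = "topright", cex = 0.7, bg = "white"),
                    ...)
  invisible(m)
}
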