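#!/usr/bin/env Rscript
# Calibration of the two free arrival-model knobs against the two reference
# weekly patient volumes (the weekly volume is a model output, not an input;
# only the arrival frequency is an input, and the fever prevalence is a free
# parameter):
#   1. n_day   - elective exam arrivals per day, bisected so the ordinary
#                scenario's mean weekly completed pathways match 123;
#   2. p_fever - fever prevalence at entrance screening, bisected so the
#                pandemic scenario's mean weekly completed pathways match 100.
# n_day is an integer knob and the target falls between the n_day = 19 (~121)
# and n_day = 20 (~125) responses; 20 is adopted because it simultaneously
# reproduces the companion reference output (9.12 h mean daily scanner busy
# time), while 19 gives ~8.9 h. The resulting values are recorded as package
# defaults and in inst/extdata/*.yaml; this script documents and reproduces
# the procedure (it does not rewrite the configs).
#
# Usage: Rscript scripts/calibrate_defaults.R [--reps N] [--seed S]

suppressPackageStartupMessages(library(clinicdes))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(reps = 30L, seed = 42L)
i <- 1L
while (i <= length(args)) {
  if (args[i] == "--reps") { opt$reps <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else stop("unknown argument: ", args[i])
}

cat("Knob 1: n_day vs ordinary weekly volume (target 123)\n")
c1 <- calibrate(clinic_scenario("baseline"), "n_day", "throughput_week",
                target_value = 123, bounds = c(14, 26), n_reps = opt$reps,
                base_seed = opt$seed, tol = 1.5, integer_knob = TRUE)
print(c1$trace)
cat("  bisection result:", c1$value, "(achieved", round(c1$achieved, 1), ")\n")

for (nd in c(19L, 20L)) {
  r <- run_replications(clinic_scenario("baseline", n_day = nd), n = opt$reps,
                        base_seed = opt$seed)
  s <- r$summary
  cat(sprintf("  n_day=%d: throughput %.1f, busy %.2f h/day\n", nd,
              s$mean[s$metric == "throughput_week"],
              s$mean[s$metric == "mri_busy_h_per_day"]))
}
n_day <- 20L
cat("  adopted n_day =", n_day, "(tie-break on the 9.12 h busy-time output)\n\n")

cat("Knob 2: p_fever vs pandemic weekly volume (target 100)\n")
c2 <- calibrate(clinic_scenario("covid", n_day = n_day), "p_fever",
                "throughput_week", target_value = 100, bounds = c(0.02, 0.40),
                n_reps = opt$reps, base_seed = opt$seed, tol = 0.5)
print(c2$trace)
cat("  adopted p_fever =", round(c2$value, 3), "(achieved",
    round(c2$achieved, 1), ")\n")
cat("\nShipped defaults: n_day = 20, p_fever = 0.21\n")
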