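# Duration laws and the per-scenario activity graphs.

test_that("duration laws reproduce their stated parameters", {
  set.seed(1)
  u <- sample_duration(dist_spec("uniform", 900, 1800), 10000L)
  expect_true(all(u >= 900 & u <= 1800))
  expect_lt(abs(mean(u) - 1350), 10)
  n <- sample_duration(dist_spec("normal", 300, 13), 10000L)
  expect_lt(abs(mean(n) - 300), 1)
  expect_lt(abs(stats::sd(n) - 13), 1)
})

test_that("degenerate uniform is constant and normal draws are truncated at zero", {
  expect_equal(sample_duration(dist_spec("uniform", 42, 42), 5L), rep(42, 5))
  set.seed(2)
  x <- sample_duration(dist_spec("normal", 10, 50), 2000L)
  expect_true(all(x >= 0))
})

test_that("invalid duration specifications are rejected", {
  expect_error(dist_spec("normal", 300, 0), "positive")
  expect_error(dist_spec("uniform", 10, 5), "p1 <= p2")
  expect_error(dist_spec("lognormal", 1, 2))
})

test_that("the catalogue carries every tabulated activity exactly once", {
  cat_ <- clinicdes:::activity_catalogue()
  base_rows <- c("appointment_booking", "registration", "anamnesis",
                 "undress_cmi", "cmi", "undress", "patient_positioning",
                 "mri_exam_single", "mri_exam_multiple", "dress",
                 "check_mri_correctness", "diagnosis")
  covid_rows <- c("hand_sanitizing", "temperature_scanning", "wear_mask_gloves",
                  "cmi_site_cleaning", "mri_cleaning", "dressing_room_cleaning")
  expect_setequal(names(cat_), c(base_rows, covid_rows))
  expect_equal(anyDuplicated(names(cat_)), 0L)
})

test_that("scenario pathways add screening/cleaning and drop on-site diagnosis as configured", {
  base <- build_pathway("baseline")
  covid <- build_pathway("covid")
  impr <- build_pathway("covid_improved")
  expect_true("diagnosis" %in% names(base$activities))
  expect_false("diagnosis" %in% names(impr$activities))
  # pandemic set = ordinary set + screening/cleaning additions - nothing else
  additions <- c("hand_sanitizing", "temperature_scanning", "wear_mask_gloves",
                 "cmi_site_cleaning", "mri_cleaning", "dressing_room_cleaning")
  expect_setequal(setdiff(names(covid$activities), names(base$activities)),
                  additions)
  expect_length(setdiff(names(base$activities), names(covid$activities)), 0L)
  expect_error(build_pathway("weekend"), "unknown")
})

test_that("patient chains branch on contrast need and examination type", {
  streams <- function() list(dur = clinicdes:::new_stream(1),
                             consult = clinicdes:::new_stream(2),
                             clean = clinicdes:::new_stream(3))
  s <- clinic_scenario("covid")
  acts <- function(ch) vapply(ch$stages, `[[`, "", "act")
  cmi_attrs <- data.frame(exam_type = "single", needs_cmi = TRUE,
                          temperature_c = 36.5, self_escort = FALSE)
  ch <- clinicdes:::patient_chain(s, cmi_attrs, streams())
  expect_equal(acts(ch)[1:3],
               c("hand_sanitizing", "temperature_scanning", "wear_mask_gloves"))
  expect_true(all(c("undress_cmi", "cmi") %in% acts(ch)))
  expect_false("undress" %in% acts(ch))
  plain <- data.frame(exam_type = "multiple", needs_cmi = FALSE,
                      temperature_c = 36.5, self_escort = FALSE)
  ch2 <- clinicdes:::patient_chain(s, plain, streams())
  expect_true("undress" %in% acts(ch2))
  expect_false("cmi" %in% acts(ch2))
  blk <- ch2$stages[[which(acts(ch2) == "mri_block")]]
  expect_equal(blk$parts$names[2L], "mri_exam_multiple")
  # a feverish patient's chain stops at the temperature check
  fever <- data.frame(exam_type = "single", needs_cmi = FALSE,
                      temperature_c = 38, self_escort = FALSE)
  ch3 <- clinicdes:::patient_chain(s, fever, streams())
  expect_equal(ch3$outcome, "rejected")
  expect_equal(tail(acts(ch3), 1L), "temperature_scanning")
})

test_that("the consultation follows every completed exam and cleaning exists only under the pandemic policies", {
  sim <- clinic_run(tiny_scenario("covid", n_day = 6L), seed = 8)
  ev <- sim$events
  exams <- ev[ev$entity_role == "mri_machine" & ev$state_label == "busy" &
                grepl("^mri_exam", ev$activity), ]
  consults <- ev[ev$entity_role == "technician" &
                   ev$activity == "check_mri_correctness", ]
  cleanings <- ev[ev$activity == "mri_cleaning" & ev$entity_role == "cleaner", ]
  expect_equal(nrow(consults), nrow(exams))
  expect_equal(nrow(cleanings), nrow(exams))
  simb <- clinic_run(tiny_scenario("baseline", n_day = 6L), seed = 8)
  expect_equal(sum(simb$events$activity == "mri_cleaning"), 0L)
})
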