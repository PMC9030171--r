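# KPI computations checked against hand interval arithmetic and a
# brute-force per-second labeller.

test_that("patient time decomposition matches hand arithmetic", {
  iv <- data.frame(
    entity_id = "p_d1_01", entity_role = "patient",
    activity = c("registration", "walk_to_studio", "anamnesis",
                 "walk_to_exit"),
    state_label = c("receiving_indirect_care", "in_transit",
                    "receiving_direct_care", "in_transit"),
    start_s = c(1800, 2100, 2250, 2550),
    end_s = c(2100, 2130, 2550, 2580),
    stringsAsFactors = FALSE
  )
  # 300 s indirect + 300 s direct + 2 x 30 s transit + a 120 s wait
  # between the first walk and the anamnesis = 780 s inside the facility
  log <- make_fixture_log(iv)
  d <- decompose_patient_time(log, "p_d1_01")
  expect_equal(d$indirect_care_min, 5)
  expect_equal(d$direct_care_min, 5)
  expect_equal(d$transit_min, 1)
  expect_equal(d$idle_min, 2)
  expect_equal(d$facility_min, 13)
  expect_equal(d$facility_min,
               d$direct_care_min + d$indirect_care_min + d$transit_min +
                 d$idle_min + d$sanitizing_min)
  expect_error(decompose_patient_time(log, "nobody"), "unknown")
})

test_that("a patient with back-to-back activities has zero idle time", {
  iv <- data.frame(
    entity_id = "p_d1_01", entity_role = "patient",
    activity = c("registration", "anamnesis"),
    state_label = c("receiving_indirect_care", "receiving_direct_care"),
    start_s = c(1800, 2100), end_s = c(2100, 2400), stringsAsFactors = FALSE
  )
  expect_equal(decompose_patient_time(make_fixture_log(iv), "p_d1_01")$idle_min, 0)
})

test_that("pandemic patients accrue sanitizing time at least the screening chain", {
  sim <- clinic_run(tiny_scenario("covid"), seed = 4)
  comp <- sim$patients[sim$patients$outcome == "completed" &
                         sim$patients$role == "patient", ]
  pt <- patient_times(sim, ids = comp$patient_id)
  expect_true(all(pt$sanitizing_min > 0))
  # hand sanitizing (>=5 s) + temperature scan (>=8 s) + mask (normal 300,13)
  expect_true(all(pt$sanitizing_min * 60 >= 5 + 8))
})

test_that("utilization is busy time over the 12 h window", {
  empty <- make_fixture_log(data.frame(
    entity_id = character(), entity_role = character(), activity = character(),
    state_label = character(), start_s = numeric(), end_s = numeric(),
    stringsAsFactors = FALSE))
  expect_equal(mri_utilization(empty)$pct, 0)
  one <- function(a, b) make_fixture_log(data.frame(
    entity_id = "p_d1_01", entity_role = "mri_machine",
    activity = "mri_exam_single", state_label = "busy",
    start_s = a, end_s = b, stringsAsFactors = FALSE))
  # the two reference figures are the same number in different units:
  # 9.12 h of 12 h = 76%
  u <- mri_utilization(one(3000, 3000 + 9.12 * 3600))
  expect_equal(u$busy_h_per_day, 9.12)
  expect_equal(u$pct, 76)
  expect_equal(mri_utilization(one(0, 43200))$pct, 100)
})

test_that("hand-built downtime day partitions as expected", {
  # first exam 9:25 (25 min after opening), last ends 19:30 (30 min before
  # public close), one 5-min cleaning gap and one 10-min unexplained gap
  iv <- data.frame(
    entity_id = c("p1", "t1", "p2", "p3"),
    entity_role = c("mri_machine", "mri_machine", "mri_machine", "mri_machine"),
    activity = c("mri_exam_single", "mri_cleaning", "mri_exam_single",
                 "mri_exam_single"),
    state_label = c("busy", "blocked", "busy", "busy"),
    start_s = c(3300, 20000, 20300, 30900),
    end_s = c(20000, 20300, 30300, 39600),
    stringsAsFactors = FALSE
  )
  dt <- attribute_downtime(make_fixture_log(iv))
  expect_equal(dt$public_closure, 60)
  expect_equal(dt$first_patient, 25)
  expect_equal(dt$last_patient, 30)
  expect_equal(dt$sanitation, 5)
  expect_equal(dt$other, 10)
  expect_equal(dt$staff_consultation, 0)
  expect_equal(dt$busy_min + rowSums(dt[, 3:9]), 720)
})

test_that("a day with no scanner use is public closure plus other", {
  s <- clinic_scenario("baseline", days = 1L, n_day = 0L, booking_per_day = 0L)
  dt <- attribute_downtime(clinic_run(s, seed = 1))
  expect_equal(dt$public_closure, 60)
  expect_equal(dt$other, 660)
  expect_equal(dt$busy_min, 0)
})

test_that("consultations inside cleaning intervals are absorbed by sanitation", {
  iv <- data.frame(
    entity_id = c("p1", "cl", "co", "p2"),
    entity_role = c("mri_machine", "mri_machine", "technician", "mri_machine"),
    activity = c("mri_exam_single", "mri_cleaning", "check_mri_correctness",
                 "mri_exam_single"),
    state_label = c("busy", "blocked", "staff_consultation", "busy"),
    start_s = c(5000, 10000, 10060, 10300),
    end_s = c(10000, 10300, 10180, 15000),
    stringsAsFactors = FALSE
  )
  dt <- attribute_downtime(make_fixture_log(iv))
  expect_equal(dt$staff_consultation, 0)
  expect_equal(dt$sanitation, 5)
})

test_that("idle time spent waiting on the next patient's injection is CMI downtime", {
  iv <- data.frame(
    entity_id = c("p1", "p2", "p2"),
    entity_role = c("mri_machine", "patient", "mri_machine"),
    activity = c("mri_exam_single", "cmi", "mri_exam_single"),
    state_label = c("busy", "receiving_direct_care", "busy"),
    start_s = c(5000, 13000, 15000),
    end_s = c(12000, 14000, 20000),
    stringsAsFactors = FALSE
  )
  dt <- attribute_downtime(make_fixture_log(iv))
  expect_equal(dt$cmi, 1000 / 60)
  # the rest of the 12000..15000 gap is unattributed
  expect_equal(dt$other, 2000 / 60)
})

test_that("interval attribution equals the per-second labeller on random instances", {
  cats <- c("busy_min", "public_closure", "first_patient", "last_patient",
            "cmi", "staff_consultation", "sanitation", "other")
  for (seed in 1:40) {
    log <- random_day_log(seed)
    a <- as.matrix(attribute_downtime(log)[, cats])
    b <- oracle_downtime(log)
    expect_equal(unname(a), unname(b), tolerance = 1e-9)
  }
})

test_that("throughput counts treated, rejected and flushed patients", {
  pts <- data.frame(
    day = 1L, patient_id = sprintf("p_d1_%02d", 1:10), role = "patient",
    arrival_s = 1800, exam_type = "single",
    needs_cmi = c(TRUE, TRUE, rep(FALSE, 8)), temperature_c = 36.5,
    outcome = c(rep("completed", 8), "rejected", "flushed"),
    depart_s = 5000, stringsAsFactors = FALSE
  )
  log <- make_fixture_log(data.frame(
    entity_id = character(), entity_role = character(), activity = character(),
    state_label = character(), start_s = numeric(), end_s = numeric(),
    stringsAsFactors = FALSE), patients = pts)
  thr <- throughput(log)
  expect_equal(thr$patients_week, 8L)
  expect_equal(thr$cmi_patients_week, 2L)
  expect_equal(thr$rejected, 1L)
  expect_equal(thr$flushed, 1L)
})

test_that("staff utilization is busy time over the role calendar", {
  iv <- data.frame(
    entity_id = "p_d1_01", entity_role = "nurse", activity = "anamnesis",
    state_label = "anamnesis", start_s = 1800, end_s = 1800 + 66 * 60,
    stringsAsFactors = FALSE
  )
  u <- staff_utilization(make_fixture_log(iv))
  expect_equal(u[["nurse"]], 10)     # 66 min of an 11 h calendar
  expect_equal(u[["physician"]], 0)
})

test_that("scenario comparison reports relative changes and flags zero bases", {
  mk <- function(thr, util) {
    structure(list(scenario_id = "x", days = 7L,
                   throughput = list(patients_week = thr, cmi_patients_week = 0L,
                                     rejected = 0L, flushed = 0L),
                   mri = list(busy_h_per_day = util * 12 / 100, pct = util),
                   downtime_min = c(public_closure = 60),
                   staff_utilization_pct = c(technician = 50),
                   operational_means = NULL),
              class = "clinic_kpi")
  }
  cmp <- compare_scenarios(mk(123, 76), mk(100, 60))
  expect_equal(cmp$delta_pct[cmp$metric == "throughput_week"], -18.699, tolerance = 1e-3)
  expect_equal(cmp$delta_pct[cmp$metric == "mri_utilization_pct"], -21.0526, tolerance = 1e-3)
  # presentation rounding: -18.7 prints as a 19% reduction
  expect_equal(clinicdes:::round_half_up(-18.699), -19)
  same <- compare_scenarios(mk(123, 76), mk(123, 76))
  expect_true(all(same$delta_pct[!same$undefined] == 0))
  z <- compare_scenarios(mk(0, 0), mk(10, 10))
  expect_true(all(z$undefined[z$metric %in% c("throughput_week",
                                              "mri_utilization_pct")]))
})
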