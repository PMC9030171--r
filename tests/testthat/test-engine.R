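# Event-queue discipline, resource tokens, determinism and structural
# invariants of full simulation runs.

test_that("event queue dequeues in (time, insertion) order", {
  q <- event_queue()
  eq_schedule(q, 10); eq_schedule(q, 5); eq_schedule(q, 10, kind = 2L)
  e1 <- eq_pop(q); e2 <- eq_pop(q); e3 <- eq_pop(q)
  expect_equal(e1$time, 5)
  expect_equal(e2$time, 10)
  expect_equal(e2$kind, 0L)   # first-inserted of the tied pair
  expect_equal(e3$kind, 2L)
  expect_null(eq_pop(q))      # exhausted queue signals end of simulation
})

test_that("a thousand random inserts dequeue in sorted order", {
  set.seed(99)
  q <- event_queue()
  times <- round(stats::runif(1000, 0, 1e5), 3)
  for (tt in times) eq_schedule(q, tt)
  out <- numeric(0)
  repeat {
    ev <- eq_pop(q)
    if (is.null(ev)) break
    out <- c(out, ev$time)
  }
  expect_equal(out, sort(times))
})

test_that("scheduling in the past is a model bug", {
  q <- event_queue()
  eq_schedule(q, 50)
  eq_pop(q)
  expect_error(eq_schedule(q, 10), "past")
})

test_that("resource tokens grant immediately, queue FIFO, respect calendars", {
  r <- resource_token("technician", capacity = 1L)
  g <- seize(r, "a", at = 0)
  expect_true(g$granted)
  expect_equal(g$at, 0)
  # busy until released: two queued requests come back in FIFO order
  expect_false(seize(r, "b", at = 50)$granted)
  expect_false(seize(r, "c", at = 60)$granted)
  g2 <- release(r, at = 100)
  expect_equal(g2$entity_id, "b")
  expect_equal(g2$at, 100)
  g3 <- release(r, at = 100 + 30)
  expect_equal(g3$entity_id, "c")
  expect_equal(g3$at, 130)
  # a request before opening waits until the calendar opens
  n <- resource_token("nurse", open_s = 1800)
  expect_false(seize(n, "early", at = 0)$granted)
  g4 <- release(n, at = 1800)
  expect_equal(g4$entity_id, "early")
  expect_gte(g4$at, 1800)
})

test_that("identical scenario and seed give bit-identical logs", {
  s <- tiny_scenario("covid", days = 2L)
  a <- clinic_run(s, seed = 123)
  b <- clinic_run(s, seed = 123)
  expect_identical(a$events, b$events)
  expect_identical(a$patients, b$patients)
  c_ <- clinic_run(s, seed = 124)
  expect_false(identical(a$events, c_$events))
})

test_that("zero arrivals produce an idle scanner and no patient records", {
  s <- clinic_scenario("baseline", days = 1L, n_day = 0L,
                       booking_per_day = 0L)
  sim <- clinic_run(s, seed = 1)
  expect_equal(mri_utilization(sim)$busy_h_per_day, 0)
  expect_equal(nrow(sim$patients[sim$patients$role == "patient", ]), 0L)
})

test_that("with durations collapsed to their means, one lone patient's stay equals the hand-summed chain", {
  with_collapsed_durations({
    # ordinary pathway, single-region, no contrast: registration 300 +
    # anamnesis 300 + undress 180 + positioning 120 + exam 1350 + dress 180 +
    # diagnosis 300 + six 30 s walks = 2910 s
    s <- clinic_scenario("baseline", days = 1L, n_day = 1L,
                         booking_per_day = 0L, p_cmi = 0, p_single = 1)
    sim <- clinic_run(s, seed = 5)
    p <- sim$patients[sim$patients$role == "patient", ]
    expect_equal(p$outcome, "completed")
    expect_equal(p$depart_s - p$arrival_s, 2910)
    expect_equal(patient_times(sim)$idle_min, 0)
    # contrast branch replaces the dressing-room undress with undress at the
    # triage (180) plus the injection (450): 300+30+300+30+180+450+30+120+
    # 1350+30+180+30+300+30 = 3360 s
    s2 <- clinic_scenario("baseline", days = 1L, n_day = 1L,
                          booking_per_day = 0L, p_cmi = 1, p_single = 1)
    sim2 <- clinic_run(s2, seed = 5)
    p2 <- sim2$patients[sim2$patients$role == "patient", ]
    expect_equal(p2$depart_s - p2$arrival_s, 3360)
  })
})

test_that("per-entity intervals are causal: chronological and non-overlapping", {
  sim <- clinic_run(tiny_scenario("covid", n_day = 8L), seed = 21)
  ev <- sim$events[sim$events$entity_role %in% c("patient", "booker"), ]
  for (id in unique(ev$entity_id)) {
    e <- ev[ev$entity_id == id, ]
    e <- e[order(e$start_s), ]
    expect_true(all(e$end_s >= e$start_s))
    if (nrow(e) > 1L) {
      expect_true(all(e$start_s[-1L] >= e$end_s[-nrow(e)] - 1e-9))
    }
  }
})

test_that("no staff interval lies outside that role's working calendar", {
  for (id in c("baseline", "covid")) {
    s <- clinic_scenario(id, days = 2L)
    sim <- clinic_run(s, seed = 31)
    for (i in seq_len(nrow(s$roster))) {
      e <- sim$events[sim$events$entity_role == s$roster$role[i], ]
      if (!nrow(e)) next
      expect_gte(min(e$start_s), s$roster$open_s[i])
      expect_lte(max(e$end_s), s$roster$close_s[i])
    }
  }
})

test_that("every arrival is accounted for: completed + rejected + flushed", {
  for (seed in c(3, 14, 159)) {
    for (id in c("baseline", "covid", "covid_improved")) {
      sim <- clinic_run(clinic_scenario(id, days = 2L), seed = seed)
      thr <- throughput(sim)
      expect_identical(thr$arrivals,
                       thr$patients_week + thr$rejected + thr$flushed)
    }
  }
})
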