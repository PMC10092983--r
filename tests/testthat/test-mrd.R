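# False-positive rates, the positive / trace-positive / negative decision
# cascade, sample-level status and LoD assessment.

nc12 <- function(events = integer(12)) {
  lapply(seq_len(12), function(i)
    fix_classified(events[i], 16000, role = "NC_cfDNA",
                   well_id = sprintf("N%02d", i), sample_id = "NC"))
}

test_that("FPR is total events over wells, displayed to two decimals", {
  expect_equal(estimate_fpr(nc12(), "T1")$fpr_events_per_well, 0)
  one <- estimate_fpr(nc12(c(1, rep(0, 11))), "T1")
  expect_equal(one$fpr_events_per_well, 1 / 12)
  expect_equal(display_fpr(one), "0.08")
  nineteen <- estimate_fpr(nc12(c(rep(2, 7), rep(1, 5))), "T1")
  expect_equal(nineteen$total_events, 19L)
  expect_equal(display_fpr(nineteen), "1.58")
  expect_error(estimate_fpr(list(), "T1"), "at least one")
})

test_that("decision cascade orders its rules correctly", {
  fpr0 <- estimate_fpr(nc12(), "T1")
  nc_est <- merge_replicates(nc12(), "T1")

  # 200 droplets vs a clean NC: unambiguous positive
  strong <- merge_replicates(list(fix_classified(70, 16000),
                                  fix_classified(65, 16000),
                                  fix_classified(65, 16000)), "T1")
  expect_equal(call_target(strong, nc_est, fpr0)$call, "positive")

  # >= 3 droplets, overlapping intervals, zero FPR: trace positive
  # (NC wells here have fewer accepted droplets, widening the NC bound)
  nc_small <- lapply(1:12, function(i)
    fix_classified(0, 11000, role = "NC_cfDNA",
                   well_id = sprintf("N%02d", i)))
  nc_small_est <- merge_replicates(nc_small, "T1")
  four <- merge_replicates(list(fix_classified(2, 16000),
                                fix_classified(1, 16000),
                                fix_classified(1, 16000)), "T1")
  tc <- call_target(four, nc_small_est, estimate_fpr(nc_small, "T1"))
  expect_false(tc$ci_nonoverlap)
  expect_equal(tc$call, "trace_positive")

  # same evidence but a nonzero FPR: negative
  nc_fp <- nc12(c(1, rep(0, 11)))
  nc_fp[[1]]$total_droplets <- 11000L
  for (i in 2:12) nc_fp[[i]]$total_droplets <- 11000L
  tc2 <- call_target(four, merge_replicates(nc_fp, "T1"),
                     estimate_fpr(nc_fp, "T1"))
  expect_equal(tc2$call, "negative")

  # fewer than 3 droplets: negative regardless of anything else
  two <- merge_replicates(list(fix_classified(1, 16000),
                               fix_classified(1, 16000),
                               fix_classified(0, 16000)), "T1")
  expect_equal(call_target(two, nc_small_est,
                           estimate_fpr(nc_small, "T1"))$call, "negative")

  expect_error(call_target(four, NULL, fpr0), "required")
})

test_that("CI separation is tested before the zero-FPR trace rule", {
  # a strongly positive sample on a zero-FPR assay must be positive,
  # never downgraded to trace
  nc <- nc12()
  strong <- merge_replicates(list(fix_classified(300, 16000),
                                  fix_classified(310, 16000),
                                  fix_classified(290, 16000)), "T1")
  tc <- call_target(strong, merge_replicates(nc, "T1"),
                    estimate_fpr(nc, "T1"))
  expect_true(tc$ci_nonoverlap)
  expect_equal(tc$call, "positive")
})

test_that("every decision input yields exactly one of three calls", {
  nc <- nc12()
  nc_est <- merge_replicates(nc, "T1")
  fpr0 <- estimate_fpr(nc, "T1")
  fpr1 <- estimate_fpr(nc12(c(2, rep(0, 11))), "T1")
  for (k in c(0, 1, 2, 3, 4, 10, 200)) {
    for (f in list(fpr0, fpr1)) {
      est <- merge_replicates(list(fix_classified(k, 16000)), "T1")
      call <- call_target(est, nc_est, f)$call
      expect_true(call %in% c("positive", "trace_positive", "negative"))
    }
  }
})

test_that("sample status aggregates target calls", {
  tc <- function(call) structure(list(call = call), class = "target_call")
  expect_equal(call_sample(list(tc("negative"), tc("positive"))),
               "positive")
  expect_equal(call_sample(list(tc("negative"), tc("trace_positive"))),
               "trace_positive")
  expect_equal(call_sample(list(tc("negative"), tc("negative"))),
               "negative")
  expect_equal(call_sample(list(tc("positive"), tc("trace_positive"))),
               "positive")
  expect_error(call_sample(list()), "no target calls")
})

test_that("LoD is the smallest mass with all larger masses positive", {
  r <- assess_lod(c(1000, 100, 10, 1),
                  c("positive", "positive", "negative", "negative"))
  expect_equal(r$lod_mass_pg, 100)
  expect_true(r$monotone)
  r2 <- assess_lod(c(1000, 100, 10, 1),
                   c("positive", "positive", "positive", "negative"))
  expect_equal(r2$lod_mass_pg, 10)
  r3 <- assess_lod(c(1000, 100, 10, 1), rep("negative", 4))
  expect_true(is.na(r3$lod_mass_pg))
  expect_equal(r3$lod_label, "> 1000 pg")
  r4 <- assess_lod(c(1000, 100, 10, 1),
                   c("positive", "negative", "positive", "negative"))
  expect_false(r4$monotone)
  expect_equal(r4$lod_mass_pg, 1000)
  expect_error(assess_lod(c(100), "positive"), "two dilution")
  expect_error(assess_lod(c(10, 100), c("positive", "positive")),
               "decreasing")
})

test_that("no false calls arise when the generator injects no false positives", {
  # 50 simulated MRD-negative samples on a clean zero-FPR assay
  am <- fix_amp_model(1)
  g <- fix_gates(1)
  ws <- well_spec(n_droplets = 4000)
  nc_cw <- classify_plate(
    simulate_nc_plate(12, 0, am, ws, seed = 1000), g)
  nc_est <- merge_replicates(nc_cw, "T1")
  fpr <- estimate_fpr(nc_cw, "T1")
  expect_equal(fpr$fpr_events_per_well, 0)
  calls <- vapply(1:50, function(i) {
    trip <- lapply(1:3, function(r)
      simulate_well(c(T1 = 0), 40, am, ws, seed = 2000 + 3 * i + r))
    est <- merge_replicates(classify_plate(trip, g), "T1")
    call_target(est, nc_est, fpr)$call
  }, "")
  expect_true(all(calls == "negative"))
})
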