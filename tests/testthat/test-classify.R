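# Gate derivation from control wells and droplet classification.

test_that("derived threshold and gate bracket a single PC band", {
  nc <- fix_well(16000, role = "NC_gDNA", seed = 1)
  pc <- fix_well(15000, band_counts = 1000, band_means = 5000,
                 role = "PC_gDNA", seed = 2)
  g <- derive_gates(list(nc, pc), panel = "T1")
  expect_gt(g$fam_threshold, 1700)
  expect_lt(g$fam_threshold, 5000)
  expect_true(g$target_gates$fam_low <= 5000 &
                g$target_gates$fam_high > 5000)
})

test_that("three PC bands yield three disjoint gates containing their medians", {
  nc <- fix_well(16000, role = "NC_gDNA", seed = 3)
  pc <- fix_well(13000, band_counts = c(1000, 1000, 1000),
                 band_means = c(3000, 5000, 7000), role = "PC_gDNA",
                 seed = 4)
  g <- derive_gates(list(nc, pc), panel = c("T1", "T2", "T3"))
  expect_equal(nrow(g$target_gates), 3)
  for (i in 1:3) {
    expect_true(g$target_gates$fam_low[i] <= c(3000, 5000, 7000)[i])
    expect_true(g$target_gates$fam_high[i] > c(3000, 5000, 7000)[i])
  }
  tg <- g$target_gates
  expect_true(all(tg$fam_high[-3] <= tg$fam_low[-1]))
  expect_true(all(tg$fam_low > g$fam_threshold))
})

test_that("an NTC well classifies with zero positives in any gate", {
  nc <- fix_well(16000, role = "NC_gDNA", seed = 5)
  pc <- fix_well(15000, band_counts = 1000, band_means = 5000,
                 role = "PC_gDNA", seed = 6)
  g <- derive_gates(list(nc, pc), panel = "T1")
  ntc <- fix_well(16000, role = "NTC", hex_ref_frac = 0, seed = 7)
  cw <- classify_droplets(ntc, g)
  expect_equal(sum(cw$counts$target_only + cw$counts$target_and_reference),
               0)
  expect_equal(cw$empty + cw$reference_only + cw$unassigned +
                 sum(cw$counts$target_only +
                       cw$counts$target_and_reference),
               cw$total_droplets)
})

test_that("single constructed droplet lands in its gate", {
  w <- droplet_well("A01", "s", "sample",
                    data.frame(fam = 5000, hex = 900))
  g <- gate_set(2000, 2000,
                data.frame(target_id = "t", fam_low = 4500,
                           fam_high = 5500))
  cw <- classify_droplets(w, g)
  expect_equal(cw$counts$target_only, 1L)
  expect_equal(cw$total_droplets, 1L)
})

test_that("an amplitude exactly at the FAM threshold is negative", {
  w <- droplet_well("A01", "s", "sample",
                    data.frame(fam = c(2000, 2000.001), hex = c(100, 100)))
  g <- gate_set(2000, 2000,
                data.frame(target_id = "t", fam_low = 2000.0005,
                           fam_high = 5500))
  cw <- classify_droplets(w, g)
  expect_equal(cw$empty, 1L)        # the droplet at the threshold
  expect_equal(cw$unassigned +
                 sum(cw$counts$target_only), 1L)
})

test_that("counts conserve totals and are order-independent", {
  am <- fix_amp_model(2, rain = 0.05, fp = 2)
  g <- fix_gates(2)
  for (seed in c(9, 19, 29)) {
    w <- simulate_well(c(T1 = 4, T2 = 1), 80, am, seed = seed)
    cw <- classify_droplets(w, g)
    expect_equal(cw$empty + cw$reference_only + cw$unassigned +
                   sum(cw$counts$target_only +
                         cw$counts$target_and_reference),
                 cw$total_droplets)
    perm <- withr::with_seed(seed, sample.int(nrow(w$droplets)))
    w2 <- w
    w2$droplets <- w$droplets[perm, ]
    cw2 <- classify_droplets(w2, g)
    expect_equal(cw2$counts, cw$counts)
    expect_equal(cw2$unassigned, cw$unassigned)
  }
})

test_that("raising the FAM threshold never increases a target count", {
  am <- fix_amp_model(1, rain = 0.1)
  w <- simulate_well(c(T1 = 10), 50, am, seed = 13)
  counts <- vapply(c(1500, 2000, 2500, 3000), function(thr) {
    g <- gate_set(thr, 2700,
                  data.frame(target_id = "T1", fam_low = 3200,
                             fam_high = 4800))
    target_fam_count(classify_droplets(w, g), "T1")
  }, 0)
  expect_true(all(diff(counts) <= 0))
})

test_that("classified positives match the partition model envelope", {
  am <- fix_amp_model(1)
  g <- fix_gates(1)
  cc <- 6
  p <- 1 - exp(-cc * VD)
  env <- stats::qbinom(c(0.0005, 0.9995), 16000, p)
  for (seed in c(31, 41, 51)) {
    w <- simulate_well(c(T1 = cc), 40, am, seed = seed)
    k <- target_fam_count(classify_droplets(w, g), "T1")
    expect_gte(k, env[1])
    expect_lte(k, env[2])
  }
})

test_that("gate derivation reports unresolvable or inseparable assays", {
  nc <- fix_well(16000, role = "NC_gDNA", seed = 8)
  pc1 <- fix_well(15000, band_counts = 1000, band_means = 5000,
                  role = "PC_gDNA", seed = 9)
  expect_error(derive_gates(list(nc, pc1), panel = c("T1", "T2")),
               "unresolvable")
  pc2 <- fix_well(15000, band_counts = 1000, band_means = 1500,
                  role = "PC_gDNA", seed = 10)
  expect_error(derive_gates(list(nc, pc2), panel = "T1"), "inseparable")
  expect_error(derive_gates(list(nc), panel = "T1"), "PC_gDNA")
})

test_that("gate set invariants are enforced", {
  expect_error(gate_set(2000, 2000,
                        data.frame(target_id = c("a", "b"),
                                   fam_low = c(3000, 3500),
                                   fam_high = c(4000, 4500))),
               "disjoint")
  expect_error(gate_set(2000, 2000,
                        data.frame(target_id = "a", fam_low = 1500,
                                   fam_high = 4000)),
               "exceed")
  expect_error(classify_droplets(
    droplet_well("A", "s", "sample",
                 data.frame(fam = 1, hex = 1))[c("well_id")],
    fix_gates(1)))
})
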