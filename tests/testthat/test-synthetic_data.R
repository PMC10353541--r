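test_that("cohorts are bit-reproducible from (spec, seed)", {
  spec <- synthetic_spec(panel_id = 1, n_events = 2000, seed = 99)
  a <- simulate_cohort(spec, 2, c("unstimulated", "PMA/Ionomycin"), 1,
                       panel = panel1())
  b <- simulate_cohort(spec, 2, c("unstimulated", "PMA/Ionomycin"), 1,
                       panel = panel1())
  expect_identical(a, b)
  # substream independence: adding a condition does not perturb the others
  c3 <- simulate_cohort(spec, 2,
                        c("unstimulated", "PMA/Ionomycin", "LPS/PHA-M"), 1,
                        panel = panel1())
  expect_identical(a[[1]], c3[[names(a)[1]]])
})

test_that("truth-label counts follow the requested mixture", {
  # multinomial oracle: expected count n*p, binomial sd sqrt(n*p*(1-p))
  spec <- synthetic_spec(
    panel_id = 2, n_events = 100000, seed = 7,
    population_fractions = list(tcell = 0.6, bcell = 0.1, nk = 0.1,
                                mono = 0.2, pdc = 0, mdc = 0, nkt = 0,
                                other = 0),
    donor_effect_sd = 0, dead_fraction = 0, debris_fraction = 0,
    doublet_fraction = 0)
  s <- simulate_sample(spec, panel2(), "D1", "unstimulated")
  n <- length(s$truth)
  for (cl in c("tcell", "bcell", "nk", "mono")) {
    p <- spec$classes[[cl]]$frac
    expect_lt(abs(sum(s$truth == cl) - n * p), 3 * sqrt(n * p * (1 - p)))
  }
})

test_that("dead fraction shows up on the viability channel", {
  spec <- synthetic_spec(panel_id = 1, n_events = 40000, seed = 21,
                         dead_fraction = 0.25, debris_fraction = 0,
                         doublet_fraction = 0)
  s <- simulate_sample(spec, panel1(), "D1", "unstimulated")
  # the live/dead components are orders of magnitude apart; 2000 a.u. sits
  # between them
  viab <- s$fluorescence[, "Viability-ZombieAqua"]
  frac_high <- mean(viab > 2000)
  expect_lt(abs(frac_high - 0.25), 3 * sqrt(0.25 * 0.75 / length(viab)) + 0.01)
  expect_equal(mean(s$truth == "dead"), frac_high, tolerance = 0.02)
})

test_that("event types are conserved and labelled", {
  spec <- synthetic_spec(panel_id = 1, n_events = 10000, seed = 5,
                         debris_fraction = 0.08, doublet_fraction = 0.04)
  s <- simulate_sample(spec, panel1(), "D1", "unstimulated")
  expect_equal(nrow(s$scatter), spec$n_events)
  n_debris <- sum(s$truth == "debris")
  n_doublet <- sum(s$truth == "doublet")
  n_singlet <- sum(!s$truth %in% c("debris", "doublet"))
  expect_equal(n_debris + n_doublet + n_singlet, spec$n_events)
  # doublets double FSC-A but stay sub-additive in FSC-H
  dbl <- s$truth == "doublet"
  ratio <- s$scatter[dbl, "FSC-H"] / s$scatter[dbl, "FSC-A"]
  expect_true(all(ratio < 0.8))
})

test_that("isotype samples share the cell draw but carry only background", {
  pair <- gated_pair1()
  s <- pair$sample
  iso <- pair$isotype
  expect_identical(iso$truth, s$truth)
  expect_identical(iso$scatter, s$scatter)
  # viability staining is real in the isotype sample
  expect_identical(iso$fluorescence[, "Viability-ZombieAqua"],
                   s$fluorescence[, "Viability-ZombieAqua"])
  # marker channels are pure background: even in a class that is positive
  # for the marker, the isotype median matches the background scale
  tcell <- s$truth %in% c("tc_naive", "tc_mem")
  expect_gt(median(s$fluorescence[tcell, "CD3-BV570"]), 3000)
  expect_lt(median(iso$fluorescence[tcell, "CD3-BV570"]), 300)
})

test_that("activation effects raise true positive fractions", {
  spec <- synthetic_spec(panel_id = 1, n_events = 30000, seed = 31)
  s0 <- simulate_sample(spec, panel1(), "D1", "unstimulated")
  s1 <- simulate_sample(spec, panel1(), "D1", "PMA/Ionomycin")
  for (cl in c("bcell", "th_conv", "tc_mem")) {
    f0 <- mean(s0$fluorescence[s0$truth == cl, "CD25-BV650"] > 1000)
    f1 <- mean(s1$fluorescence[s1$truth == cl, "CD25-BV650"] > 1000)
    expect_gt(f1, f0)
  }
})

test_that("apply_spillover is the declared linear forward model", {
  p <- panel1()
  dets <- panel_detectors(p)
  spec <- synthetic_spec(panel_id = 1, n_events = 500, seed = 3)
  s <- simulate_sample(spec, p, "D1", "unstimulated")
  expect_equal(apply_spillover(s, identity_spillover(dets))$fluorescence,
               s$fluorescence)

  # one event, two effective channels: true (1000, 0), FITC -> PE 0.1
  md <- sample_metadata("d", "unstimulated")
  fl <- matrix(0, 1, length(dets), dimnames = list(NULL, dets))
  fl[1, "CD8a-FITC"] <- 1000
  ev <- event_matrix(md, matrix(c(1, 1, 1), 1, 3,
                                dimnames = list(NULL,
                                                c("FSC-A", "FSC-H", "SSC-A"))),
                     fl)
  S <- diag(length(dets)); dimnames(S) <- list(dets, dets)
  S["CD8a-FITC", "CD4-PE"] <- 0.1
  out <- apply_spillover(ev, spillover_matrix(S, dets))
  expect_equal(unname(out$fluorescence[1, "CD4-PE"]), 100)
  expect_equal(unname(out$fluorescence[1, "CD8a-FITC"]), 1000)
})

test_that("interfering drug perturbs only the listed channels, monotonically", {
  spec <- synthetic_spec(panel_id = 1, n_events = 5000, seed = 17)
  un <- simulate_sample(spec, panel1(), "D1", "unstimulated",
                        stain_type = "unstained")
  expect_identical(simulate_interfering_drug(un, c("CD4-PE" = 1000), 0), un)

  set.seed(1)
  hi <- simulate_interfering_drug(un, c("CD4-PE" = 1000), 10)
  expect_gt(median(hi$fluorescence[, "CD4-PE"]),
            median(un$fluorescence[, "CD4-PE"]))
  expect_identical(hi$scatter, un$scatter)
  expect_identical(hi$fluorescence[, "CD3-BV570"],
                   un$fluorescence[, "CD3-BV570"])
  expect_error(simulate_interfering_drug(un, c("CD4-PE" = 1), -1),
               "concentration")

  # ten-fold dilution series: median shift monotone nonincreasing
  set.seed(2)
  meds <- vapply(10 / serial_dilution_factors(10, 3), function(conc) {
    d <- simulate_interfering_drug(un, c("CD4-PE" = 1000), conc)
    median(d$fluorescence[, "CD4-PE"])
  }, numeric(1))
  expect_true(all(diff(meds) <= 0))
})

test_that("dose arithmetic matches the printed protocol numbers", {
  expect_equal(final_concentration(10, 10), 1)    # 10 mg/ml at MRD 10
  expect_equal(final_concentration(42.5, 1), 42.5)
  expect_error(final_concentration(1, 0.5), "mrd")
  expect_equal(serial_dilution_factors(5, 5), c(1, 5, 25, 125, 625, 3125))
  expect_equal(serial_dilution_factors(7, 0), 1)
  expect_equal(serial_dilution_factors(10, 3), c(1, 10, 100, 1000))
  expect_error(serial_dilution_factors(1, 3), "fold")
})

test_that("invalid specs are rejected naming the field", {
  expect_error(synthetic_spec(population_fractions = list(bcell = 1.2)),
               "population_fractions")
  expect_error(synthetic_spec(dead_fraction = 1.5), "dead_fraction")
  expect_error(synthetic_spec(n_events = 0), "n_events")
  expect_error(synthetic_spec(population_fractions = list(zz = 0.1)),
               "unknown class")
})
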