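test_that("spillover estimation recovers the generating matrix", {
  p <- panel1()
  dets <- panel_detectors(p)

  # zero off-target signal -> identity (within Monte-Carlo noise)
  ss0 <- simulate_single_stains(p, NULL, n_events = 5000, seed = 11)
  S0 <- estimate_spillover(ss0$single_stains, ss0$unstained)
  expect_lt(max(abs(S0$S - diag(length(dets)))), 0.005)

  # planted FITC -> PE = 0.15 recovered within +-0.01 at 10k events
  S_true <- planted_spillover(p)
  ss <- simulate_single_stains(p, S_true, n_events = 10000, seed = 12)
  S_hat <- estimate_spillover(ss$single_stains, ss$unstained)
  fitc <- dets[grepl("-FITC$", dets)][1]
  pe <- dets[grepl("-PE$", dets)][1]
  expect_lt(abs(S_hat$S[fitc, pe] - 0.15), 0.01)
  expect_lt(max(abs(S_hat$S - S_true$S)), 0.01)

  # relabeling invariance: permuting detector order permutes the estimate
  perm <- rev(dets)
  permute <- function(s) {
    s$fluorescence <- s$fluorescence[, perm, drop = FALSE]
    s
  }
  S_perm <- estimate_spillover(lapply(ss$single_stains, permute)[perm],
                               permute(ss$unstained))
  expect_equal(S_perm$S[dets, dets], S_hat$S, tolerance = 1e-12)

  # estimation error shrinks with event count
  ss_big <- simulate_single_stains(p, S_true, n_events = 60000, seed = 13)
  ss_small <- simulate_single_stains(p, S_true, n_events = 1000, seed = 13)
  err_big <- max(abs(estimate_spillover(ss_big$single_stains,
                                        ss_big$unstained)$S - S_true$S))
  err_small <- max(abs(estimate_spillover(ss_small$single_stains,
                                          ss_small$unstained)$S - S_true$S))
  expect_lt(err_big, err_small)
})

test_that("estimate_spillover errors when no positive population separates", {
  p <- panel1()
  ss <- simulate_single_stains(p, NULL, n_events = 2000, seed = 14)
  dets <- panel_detectors(p)
  # replace one single stain by an unstained draw: nothing above background
  broken <- ss$single_stains
  broken[[dets[1]]] <- ss$unstained
  expect_error(estimate_spillover(broken, ss$unstained), dets[1],
               fixed = TRUE)
})

test_that("compensation solves the linear system and inverts spillover", {
  p <- panel1()
  dets <- panel_detectors(p)
  spec <- synthetic_spec(panel_id = 1, n_events = 2000, seed = 15)
  s <- simulate_sample(spec, p, "D1", "unstimulated")

  expect_equal(compensate(s, identity_spillover(dets))$fluorescence,
               s$fluorescence)

  # 2-channel event observed (110, 25) with FITC->PE 0.1 and PE->FITC 0.05:
  # closed-form 2x2 inverse as the independent oracle
  fitc <- "CD8a-FITC"; pe <- "CD4-PE"
  md <- sample_metadata("d", "unstimulated")
  fl <- matrix(10, 1, length(dets), dimnames = list(NULL, dets))
  fl[1, fitc] <- 110; fl[1, pe] <- 25
  ev <- event_matrix(md, matrix(1, 1, 3,
                                dimnames = list(NULL,
                                                c("FSC-A", "FSC-H", "SSC-A"))),
                     fl)
  S <- diag(length(dets)); dimnames(S) <- list(dets, dets)
  S[fitc, pe] <- 0.1; S[pe, fitc] <- 0.05
  comp <- compensate(ev, spillover_matrix(S, dets))
  # hand-solved: [x, y] %*% [[1, .1], [.05, 1]] = [110, 25]
  det2 <- 1 - 0.1 * 0.05
  x <- (110 - 0.05 * 25) / det2
  y <- (25 - 0.1 * 110) / det2
  expect_equal(unname(comp$fluorescence[1, fitc]), x, tolerance = 1e-12)
  expect_equal(unname(comp$fluorescence[1, pe]), y, tolerance = 1e-12)

  # round trip: compensate(apply_spillover(x)) == x
  S_true <- planted_spillover(p)
  rt <- compensate(apply_spillover(s, S_true), S_true)
  rel <- abs(rt$fluorescence - s$fluorescence) /
    pmax(abs(s$fluorescence), 1e-9)
  expect_lt(max(rel), 1e-6)

  # linearity on stacked samples
  s2 <- simulate_sample(spec, p, "D2", "unstimulated")
  mix <- s
  mix$fluorescence <- 2 * s$fluorescence + 3 * s2$fluorescence
  lhs <- compensate(mix, S_true)$fluorescence
  rhs <- 2 * compensate(s, S_true)$fluorescence +
    3 * compensate(s2, S_true)$fluorescence
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("stain index follows the median / 2 rSD formula", {
  # identical distributions -> 0
  set.seed(8)
  neg <- rlnorm(5000, log(100), 0.3)
  expect_equal(stain_index(neg, neg), 0)

  # constructed: negative median 100, robust-SD 10, positive median 1100
  d <- 10 / 1.4826
  negative <- rep(100 + c(-d, 0, d), times = 400)
  stained <- c(negative, rep(1100, 600))
  expect_equal(stain_index(stained, negative), 50, tolerance = 1e-9)

  # scale invariance
  expect_equal(stain_index(3.7 * stained, 3.7 * negative),
               stain_index(stained, negative), tolerance = 1e-9)

  # degenerate negative spread is flagged
  expect_warning(si <- stain_index(c(1, 2, 3), rep(5, 10)), "robust SD")
  expect_true(is.na(si))
  expect_error(stain_index(numeric(0), neg), "nonempty")
})

test_that("optimal dilution is the stain-index argmax, ties to less antibody", {
  tc <- titration_curve("CD8a-FITC", c(1, 5, 25, 125, 625, 3125),
                        c(30, 50, 45, 20, 5, 1))
  expect_equal(select_optimal_dilution(tc), 5)
  expect_equal(tc$optimal_dilution, 5)

  tie <- titration_curve("CD8a-FITC", c(1, 5, 25, 125, 625, 3125),
                         c(10, 20, 45, 45, 5, 1))
  expect_equal(select_optimal_dilution(tie), 125)

  mono <- titration_curve("CD8a-FITC", c(1, 5, 25),
                          c(50, 40, 30))
  expect_equal(select_optimal_dilution(mono), 1)

  expect_error(titration_curve("x", c(1, 5, 5), c(1, 2, 3)),
               "strictly increasing")
  expect_error(select_optimal_dilution(list(dilution_factors = c(1, 5),
                                            stain_indices = c(NA, NA))),
               "undefined")
})

test_that("interference screen flags only the shifted channels", {
  spec <- synthetic_spec(panel_id = 1, n_events = 8000, seed = 19)
  un <- simulate_sample(spec, panel1(), "D1", "unstimulated",
                        stain_type = "unstained")
  rep0 <- interference_screen(un, un)
  expect_true(all(rep0$score == 0))
  expect_false(any(rep0$flag))

  # +5 robust-SD synthetic shift on the PE detector only
  shifted <- un
  pe <- "CD4-PE"
  rsd <- mad(un$fluorescence[, pe], constant = 1.4826)
  shifted$fluorescence[, pe] <- shifted$fluorescence[, pe] + 5 * rsd
  rep1 <- interference_screen(shifted, un)
  expect_true(rep1$flag[rep1$detector == pe])
  expect_false(any(rep1$flag[rep1$detector != pe]))

  # score equivariance: adding a constant to both samples changes nothing
  both <- function(s) {
    s$fluorescence <- s$fluorescence + 500
    s
  }
  rep2 <- interference_screen(both(shifted), both(un))
  expect_equal(rep2$score, rep1$score, tolerance = 1e-9)
})

test_that("spillover matrices round-trip through CSV", {
  S <- planted_spillover(panel1())
  f <- tempfile(fileext = ".csv")
  write_spillover_csv(S, f)
  S2 <- read_spillover_csv(f)
  expect_equal(S2$S, S$S, tolerance = 1e-15)
  expect_identical(S2$detectors, S$detectors)
})
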