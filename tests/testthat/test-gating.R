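test_that("isotype thresholds behave like background quantiles", {
  pair <- gated_pair1()
  p <- panel1()
  thr <- pair$thresholds

  # monotone nondecreasing in the quantile
  thr_lo <- fit_isotype_thresholds(pair$isotype, p, quantile = 0.9)
  thr_hi <- fit_isotype_thresholds(pair$isotype, p, quantile = 1.0)
  keys <- names(thr)
  expect_true(all(thr_lo[keys] <= unclass(thr)[keys]))
  expect_true(all(unclass(thr)[keys] <= thr_hi[keys]))

  # at quantile 1.0 the threshold is the maximum isotype background, so
  # gating the isotype sample with its own thresholds selects nothing at
  # the first marker gate
  gs_iso <- apply_gate_tree(pair$isotype, p, thr_hi)
  cd45 <- gs_iso$gate_counts
  expect_equal(cd45$selected[cd45$gate == "cd45_pos"], 0)

  # normal-quantile oracle: thresholds sit near the 99.5th percentile of
  # the log-normal background, qlnorm(0.995, meanlog, 0.5) up to the donor
  # location shift shared by all channels
  ratio <- thr[["cd19_pos"]] / thr[["cd3_pos"]]
  expect_lt(abs(log(ratio)), 0.2)  # same background law on both channels
})

test_that("gate tree recovers ground truth on well-separated mixtures", {
  for (pair in list(gated_pair1(), gated_pair2())) {
    gs <- pair$stats
    tf <- truth_fractions(pair$sample)
    m <- merge(gs$populations, tf)
    expect_equal(nrow(m), nrow(gs$populations))
    expect_true(all(abs(m$pct_of_live - 100 * m$true_fraction) < 2))
    # percentages are percentages
    expect_true(all(m$pct_of_live >= 0 & m$pct_of_live <= 100))
    expect_true(all(m$pct_of_parent >= 0 & m$pct_of_parent <= 100))
  }
})

test_that("per-population precision and recall reach 0.95 at defaults", {
  for (px in list(list(pair = gated_pair1(), panel = panel1()),
                  list(pair = gated_pair2(), panel = panel2()))) {
    gs <- px$pair$stats
    truth <- px$pair$sample$truth
    pmap <- immunogate:::panel_population_map(px$panel$panel_id)
    live <- !truth %in% c("dead", "debris", "doublet")
    for (pop in px$panel$populations) {
      pred <- gs$membership[[pop$path[length(pop$path)]]]
      is_pop <- truth %in% pmap[[pop$name]] & live
      if (sum(is_pop) < 50) next
      recall <- sum(pred & is_pop) / sum(is_pop)
      precision <- sum(pred & is_pop) / sum(pred)
      expect_gt(recall, 0.95)
      expect_gt(precision, 0.95)
    }
  }
})

test_that("gate nesting, live/dead partition and branch disjointness hold", {
  pair <- gated_pair2()
  p <- panel2()
  gs <- pair$stats

  # nesting along every population path
  for (pop in p$populations) {
    counts <- vapply(pop$path, function(id) sum(gs$membership[[id]]),
                     numeric(1))
    expect_true(all(diff(counts) <= 0))
  }

  # live + dead = singlets, per branch
  gc <- gs$gate_counts
  for (br in c("mono", "lymph")) {
    singlet <- gc$selected[gc$gate == paste0(br, "_singlet")]
    dead <- gc$selected[gc$gate == paste0(br, "_viability")]
    live <- sum(gs$membership[[paste0(br, "_viability")]])
    expect_equal(live + dead, singlet)
  }

  # the two scatter branches partition the main-cells region
  mono <- gs$membership[["mono_scatter"]]
  lymph <- gs$membership[["lymph_scatter"]]
  main <- gs$membership[["main"]]
  expect_false(any(mono & lymph))
  expect_identical(mono | lymph, main)

  # monocytes land in the monocyte branch
  truth_mono <- pair$sample$truth == "mono"
  expect_gt(sum(mono & truth_mono) / sum(truth_mono), 0.95)
})

test_that("raising a positive threshold never grows the population", {
  pair <- gated_pair1()
  p <- panel1()
  thr <- pair$thresholds
  b0 <- pair$stats$populations
  b0 <- b0$count[b0$population == "B cells"]
  for (bump in c(2, 10, 1e6)) {
    thr2 <- thr
    thr2[["cd19_pos"]] <- thr[["cd19_pos"]] * bump
    b1 <- apply_gate_tree(pair$sample, p, thr2)$populations
    b1 <- b1$count[b1$population == "B cells"]
    expect_lte(b1, b0)
    b0 <- b1
  }
})

test_that("empty parents yield zero percentages with an explicit flag", {
  pair <- gated_pair1()
  p <- panel1()
  thr <- pair$thresholds
  thr[["cd3_pos"]] <- Inf  # kills the T-cell branch
  gs <- apply_gate_tree(pair$sample, p, thr)
  pops <- gs$populations
  treg <- pops[pops$population == "Regulatory T cells", ]
  expect_equal(treg$count, 0)
  expect_equal(treg$pct_of_parent, 0)
  expect_true(treg$empty_parent)
  # the B-cell branch is untouched
  expect_gt(pops$count[pops$population == "B cells"], 0)
})

test_that("quadrant stats partition events by the two thresholds", {
  expect_equal(quadrant_stats(c(1, 2, 3), c(1, 2, 3), 10, 10),
               c(nn = 100, pn = 0, np = 0, pp = 0))
  # independent markers, each 50% positive -> about 25% per quadrant
  set.seed(4)
  n <- 100000
  a <- runif(n); b <- runif(n)
  q <- quadrant_stats(a, b, 0.5, 0.5)
  expect_true(all(abs(q - 25) < 3 * 100 * sqrt(0.25 * 0.75 / n) + 0.2))
  expect_equal(sum(q), 100)
  # boundary rule: value equal to the threshold is negative
  expect_equal(quadrant_stats(c(0.5), c(0.7), 0.5, 0.5),
               c(nn = 0, pn = 0, np = 100, pp = 0))
  expect_error(quadrant_stats(numeric(0), numeric(0), 1, 1), "empty")
  expect_error(quadrant_stats(1:3, 1:2, 1, 1), "equal length")
})

test_that("quadrant rows always sum to 100 and gMFIs are positive", {
  for (pair in list(gated_pair1(), gated_pair2())) {
    a <- pair$stats$activation
    sums <- a$pct_nn + a$pct_pn + a$pct_np + a$pct_pp
    expect_true(all(abs(sums - 100) < 1e-9))
    expect_true(all(a$gmfi_a > 0 & a$gmfi_b > 0))
  }
})

test_that("missing thresholds and unknown channels are reported", {
  pair <- gated_pair1()
  p <- panel1()
  thr <- pair$thresholds
  thr2 <- unclass(thr)
  thr2 <- thr2[names(thr2) != "cd19_pos"]
  class(thr2) <- "threshold_set"
  expect_error(apply_gate_tree(pair$sample, p, thr2), "cd19_pos")
})
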