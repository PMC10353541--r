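test_that("control correlation matches Pearson and clusters donor groups", {
  v <- c(10, 20, 30, 5, 8)
  cc <- control_correlation(list(a = v, b = v, c = -v))
  expect_equal(cc$R["a", "b"], 1)
  expect_equal(cc$R["a", "c"], -1)
  expect_equal(cc$R, t(cc$R))
  expect_true(all(diag(cc$R) == 1))
  # PSD up to numerical tolerance
  expect_gt(min(eigen(cc$R, symmetric = TRUE)$values), -1e-9)

  # two synthetic donor groups: high within-group R, low between
  set.seed(12)
  base1 <- rnorm(20); base2 <- rnorm(20)
  runs <- c(lapply(1:3, function(i) base1 + rnorm(20, 0, 0.05)),
            lapply(1:3, function(i) base2 + rnorm(20, 0, 0.05)))
  names(runs) <- paste0("r", 1:6)
  cc2 <- control_correlation(runs)
  grp <- cutree(cc2$linkage, k = 2)
  expect_equal(length(unique(grp[1:3])), 1)
  expect_equal(length(unique(grp[4:6])), 1)
  expect_false(grp[1] == grp[4])

  expect_warning(control_correlation(list(a = c(1, 1, 1), b = c(1, 2, 3))),
                 "zero-variance")
  expect_error(control_correlation(list(a = 1:3)), "at least 2")
})

test_that("paired t matches the closed form and t.test", {
  # differences (1, 2, 3): t = mean/ (sd/sqrt(3)) = 2/(1/sqrt(3)) = 3.4641
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$t, 3.4641016, tolerance = 1e-6)
  expect_equal(r$p, 0.0742, tolerance = 1e-3)
  ref <- t.test(c(2, 4, 6), c(1, 2, 3), paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)

  # swapping labels negates t, keeps p
  r2 <- paired_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)

  expect_warning(rz <- paired_t(c(2, 3, 4), c(1, 2, 3)), "zero variance")
  expect_true(rz$degenerate)
  expect_error(paired_t(c(1, NA, NA), c(1, 2, 3)), "at least 2")
})

test_that("sign-flip enumeration is exhaustive and negation-unique", {
  expect_length(enumerate_sign_flips(3), 3)   # the three-donor design
  expect_length(enumerate_sign_flips(1), 0)
  f4 <- enumerate_sign_flips(4)
  expect_length(f4, 7)                        # 2^(4-1) - 1

  # brute force over all 16 sign vectors: flips + identity + global
  # negations reconstruct every vector exactly once
  all_vecs <- as.matrix(expand.grid(rep(list(c(1, -1)), 4)))
  reconstructed <- rbind(do.call(rbind, f4), -do.call(rbind, f4),
                         rep(1, 4), rep(-1, 4))
  key <- function(m) apply(m, 1, paste, collapse = ",")
  expect_setequal(key(reconstructed), key(all_vecs))
  expect_equal(anyDuplicated(key(reconstructed)), 0)
  # pairwise non-equivalent under negation
  k <- c(key(do.call(rbind, f4)), key(-do.call(rbind, f4)))
  expect_equal(anyDuplicated(k), 0)
})

test_that("permutation p-value agrees with brute-force counting", {
  expect_equal(permutation_pvalue(0.01, c(0.2, 0.5, 0.9)), 0.25)  # b=0, m=3
  expect_equal(permutation_pvalue(0.99, c(0.2, 0.5, 0.9)), 1)     # above all

  set.seed(33)
  pooled <- runif(1000)
  for (rp in runif(25)) {
    b <- 0
    for (x in pooled) if (x < rp) b <- b + 1   # explicit counting oracle
    expect_equal(permutation_pvalue(rp, pooled), (b + 1) / 1001)
  }
  # monotone in real_p; floor at 1/(m+1)
  probes <- sort(runif(50))
  ps <- vapply(probes, permutation_pvalue, numeric(1), pooled = pooled)
  expect_true(all(diff(ps) >= 0))
  expect_true(all(ps >= 1 / 1001) && all(ps <= 1))
  # tie handling differs between strict and lte counting
  expect_equal(permutation_pvalue(0.5, c(0.5, 0.5, 0.1), "strict"), 2 / 4)
  expect_equal(permutation_pvalue(0.5, c(0.5, 0.5, 0.1), "lte"), 4 / 4)
})

test_that("value_to_beat is verified by exhaustive scan", {
  # m = 3 cannot beat alpha = 0.05: minimum attainable perm p is 0.25
  expect_true(is.na(value_to_beat(c(0.1, 0.2, 0.3), 0.05)))

  set.seed(44)
  pooled99 <- runif(99)
  expect_equal(value_to_beat(pooled99, 0.05), sort(pooled99)[4])  # b_max = 3

  for (rep in 1:5) {
    pooled <- runif(sample(50:400, 1))
    alpha <- runif(1, 0.01, 0.2)
    v <- value_to_beat(pooled, alpha)
    if (is.na(v)) {
      expect_gte(1 / (length(pooled) + 1), alpha)
      next
    }
    # under strict counting the pass region is closed at v: a real p beats
    # alpha exactly when it is at or below the returned threshold
    probes <- sort(unique(c(pooled, v, v * 0.999999, runif(100))))
    for (rp in probes) {
      beats <- permutation_pvalue(rp, pooled) < alpha
      expect_equal(beats, rp <= v)
    }
  }
})

test_that("minimum exact signed-rank p matches enumeration and psignrank", {
  expect_equal(wilcoxon_min_p(3), 0.25)
  expect_equal(wilcoxon_min_p(5), 0.0625)
  expect_equal(wilcoxon_min_p(1), 1)
  for (n in c(2, 4, 8, 12)) {
    expect_equal(wilcoxon_min_p(n), 2 / 2^n)                  # closed form
    expect_equal(wilcoxon_min_p(n), 2 * psignrank(0, n))       # stats oracle
  }
  expect_error(wilcoxon_min_p(0), "1..20")
})

test_that("permutation analysis pools 3 values per included test at n = 3", {
  set.seed(55)
  G <- 8
  mk <- function() matrix(rnorm(G * 3), G, 3,
                          dimnames = list(paste0("e", 1:G),
                                          paste0("D", 1:3)))
  tests <- list(trtA = list(treated = mk(), control = mk()),
                trtB = list(treated = mk(), control = mk()))
  res <- permutation_analysis(tests)
  expect_equal(length(res$pooled), 3 * G * 2)
  expect_true(all(res$tests$included))
  expect_true(all(res$tests$perm_p >= 1 / (length(res$pooled) + 1)))
  expect_true(all(res$tests$perm_p <= 1))

  # a test with only 2 complete pairs is excluded and contributes nothing
  tests2 <- tests
  tests2$trtA$treated[1, 1] <- NA
  res2 <- permutation_analysis(tests2)
  row1 <- res2$tests[res2$tests$treatment == "trtA" &
                     res2$tests$endpoint == "e1", ]
  expect_false(row1$included)
  expect_true(is.na(row1$perm_p))
  expect_equal(length(res2$pooled), 3 * (G * 2 - 1))
})

test_that("under a global null the real p is exchangeable with permuted", {
  # rank of the real p among its 3 permuted values is uniform on 4 positions
  set.seed(66)
  n_rep <- 400
  ranks <- integer(n_rep)
  for (i in seq_len(n_rep)) {
    tests <- list(t = list(treated = matrix(rnorm(3), 1, 3),
                           control = matrix(rnorm(3), 1, 3)))
    res <- permutation_analysis(tests, min_pairs = 3)
    perms <- res$per_test_permuted[[1]]
    ranks[i] <- 1 + sum(perms < res$tests$real_p[1])
  }
  freqs <- tabulate(ranks, nbins = 4) / n_rep
  expect_true(all(abs(freqs - 0.25) < 0.08))
})
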