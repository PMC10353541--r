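# Statistics layer: negative-control reproducibility, paired t-tests vs
# reference, and the exhaustive donor-label-swap permutation correction.
#
# With N = 3 donors, parametric or rank tests have almost no power (the
# minimum two-sided exact signed-rank p is 0.25) and classical multiplicity
# corrections assume independence the endpoints do not have. The layer
# therefore swaps treated/control labels within donor pairs — the only
# exchangeable operation that keeps donor pairing and the endpoint
# correlation structure intact — recomputes every paired t, pools the
# permuted p-values into one null, and reports (b + 1) / (m + 1).

#' Reproducibility of negative-control runs
#'
#' Pearson correlation of gate-percentage vectors across control runs, then
#' complete-linkage agglomerative clustering on the Euclidean distance
#' matrix of the correlation rows — the standard heat-map ordering.
#'
#' @param control_vectors Named list, run id -> numeric gate-percentage
#'   vector (equal lengths).
#' @return A `control_correlation`: `runs`, symmetric matrix `R`, the
#'   `hclust` linkage, and ids of zero-variance runs (their correlations are
#'   `NA` and flagged).
#' @export
control_correlation <- function(control_vectors) {
  if (length(control_vectors) < 2)
    stopf("need at least 2 control runs")
  lens <- lengths(control_vectors)
  if (length(unique(lens)) != 1)
    stopf("control vectors must have equal length")
  V <- do.call(rbind, control_vectors)
  zero_var <- apply(V, 1, stats::sd) == 0
  if (any(zero_var))
    warning(sprintf("zero-variance control run(s): %s",
                    paste(rownames(V)[zero_var], collapse = ", ")))
  R <- suppressWarnings(stats::cor(t(V)))
  diag(R) <- 1
  linkage <- if (any(!is.finite(R))) NULL else
    stats::hclust(stats::dist(R), method = "complete")
  structure(list(runs = rownames(V), R = R, linkage = linkage,
                 zero_variance = rownames(V)[zero_var]),
            class = "control_correlation")
}

#' @export
print.control_correlation <- function(x, ...) {
  off <- x$R[row(x$R) != col(x$R)]
  cat(sprintf("<control_correlation> %d runs, mean off-diagonal R %.3f\n",
              length(x$runs), mean(off, na.rm = TRUE)))
  invisible(x)
}

# Paired t on a vector of donor-wise differences. Returns p = 1 for
# degenerate (zero-variance) differences so permuted values can be retained
# in the pool without silently shrinking it.
t_p_of_diff <- function(d) {
  n <- length(d)
  s <- stats::sd(d)
  if (n < 2 || s == 0) return(c(t = NA_real_, p = 1, degenerate = 1))
  t <- mean(d) / (s / sqrt(n))
  c(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), degenerate = 0)
}

#' Paired t-test of treated vs control donor values
#'
#' Classical paired t on donor-wise differences with `n - 1` degrees of
#' freedom, two-sided. Donors with a missing value on either side are
#' dropped pairwise.
#'
#' @param treated,control Per-donor values in the same donor order.
#' @return List with `t`, `p`, `df`, `n` and a `degenerate` flag (zero
#'   difference variance).
#' @export
paired_t <- function(treated, control) {
  if (length(treated) != length(control))
    stopf("treated and control must pair the same donors")
  ok <- is.finite(treated) & is.finite(control)
  d <- treated[ok] - control[ok]
  if (length(d) < 2) stopf("paired t needs at least 2 complete pairs")
  r <- t_p_of_diff(d)
  if (r[["degenerate"]] == 1)
    warning("zero variance of paired differences; test degenerate")
  list(t = r[["t"]], p = r[["p"]], df = length(d) - 1, n = length(d),
       degenerate = r[["degenerate"]] == 1)
}

#' Exhaustive unique sign-flip permutations of a paired design
#'
#' All treated/control label swaps over `n` donor pairs, collapsed into
#' equivalence classes under global negation (two-sided tests cannot tell a
#' flip from its complement) with the identity class excluded — leaving
#' `2^(n-1) - 1` unique permutations; 3 for the three-donor design.
#'
#' @param n_donors Number of donor pairs.
#' @return List of sign vectors in `{-1, +1}^n`; empty for `n = 1`.
#' @export
enumerate_sign_flips <- function(n_donors) {
  if (n_donors < 1) stopf("n_donors must be >= 1")
  if (n_donors == 1) return(list())
  # fix the first donor's sign to +1 to collapse global negation, then drop
  # the identity (all +1)
  tails <- expand.grid(rep(list(c(1, -1)), n_donors - 1))
  flips <- lapply(seq_len(nrow(tails)), function(i)
    c(1, as.numeric(tails[i, ])))
  Filter(function(f) any(f == -1), flips)
}

#' Exhaustive permutation analysis of paired endpoint tests
#'
#' For every treatment, every endpoint with at least `min_pairs` complete
#' donor pairs gets a real paired-t p-value; then each unique sign flip is
#' applied jointly across all endpoints of that treatment (one flip vector
#' per permutation replicate, preserving the endpoint correlation
#' structure), the paired t is recomputed, and all permuted p-values from
#' all treatments and endpoints are pooled into one null. Each real p is
#' compared to the pool via [permutation_pvalue()]. Endpoints with fewer
#' complete pairs are excluded and contribute nothing to the pool.
#'
#' @param tests Named list (one element per treatment), each a list with
#'   numeric matrices `treated` and `control` of shape endpoints x donors
#'   with matching dimnames.
#' @param min_pairs Minimum complete pairs for inclusion (default 3).
#' @param count `"strict"` counts permuted p-values strictly below the real
#'   one (the printed formula's wording); `"lte"` counts ties as well
#'   (the Phipson-Smyth construction).
#' @param alpha Level used to report the pooled "value to beat".
#' @return A `permutation_result`: per-test data frame (`treatment`,
#'   `endpoint`, `mean_diff`, `t`, `real_p`, `n_pairs`, `included`,
#'   `n_below`, `perm_p`), the pooled permuted p-values, and the value to
#'   beat at `alpha`.
#' @export
permutation_analysis <- function(tests, min_pairs = 3, count = "strict",
                                 alpha = 0.05) {
  if (length(tests) == 0) stopf("empty test collection")
  rows <- list()
  permuted_all <- numeric(0)
  per_test_perms <- list()
  for (trt in names(tests)) {
    Tr <- as.matrix(tests[[trt]]$treated)
    Co <- as.matrix(tests[[trt]]$control)
    if (!identical(dim(Tr), dim(Co)))
      stopf("treated/control shape mismatch for treatment '%s'", trt)
    D <- Tr - Co
    n_donors <- ncol(D)
    flips <- enumerate_sign_flips(n_donors)
    eps <- rownames(D) %||% paste0("endpoint", seq_len(nrow(D)))
    for (i in seq_len(nrow(D))) {
      d <- D[i, ]
      complete <- is.finite(d)
      n_pairs <- sum(complete)
      included <- n_pairs >= min_pairs
      real <- if (n_pairs >= 2) t_p_of_diff(d[complete]) else
        c(t = NA_real_, p = NA_real_, degenerate = 1)
      perms <- numeric(0)
      if (included) {
        perms <- vapply(flips, function(f)
          t_p_of_diff((d * f)[complete])[["p"]], numeric(1))
        permuted_all <- c(permuted_all, perms)
      }
      key <- paste(trt, eps[i], sep = "|")
      per_test_perms[[key]] <- perms
      rows[[key]] <- data.frame(
        treatment = trt, endpoint = eps[i],
        mean_diff = mean(d[complete]),
        t = real[["t"]], real_p = real[["p"]],
        n_pairs = n_pairs, included = included,
        n_below = NA_real_, perm_p = NA_real_)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  m <- length(permuted_all)
  for (i in seq_len(nrow(res))) {
    if (!res$included[i] || !is.finite(res$real_p[i])) next
    res$n_below[i] <- if (count == "strict")
      sum(permuted_all < res$real_p[i]) else
      sum(permuted_all <= res$real_p[i])
    res$perm_p[i] <- permutation_pvalue(res$real_p[i], permuted_all, count)
  }
  structure(list(tests = res, pooled = permuted_all,
                 per_test_permuted = per_test_perms,
                 count = count, alpha = alpha,
                 value_to_beat = if (m > 0)
                   value_to_beat(permuted_all, alpha) else NA_real_),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %d tests (%d included), pooled null of %d values\n",
    nrow(x$tests), sum(x$tests$included), length(x$pooled)))
  vb <- x$value_to_beat
  cat(sprintf("  value to beat at alpha = %.2f: %s\n", x$alpha,
              if (is.na(vb)) "unattainable" else format(vb)))
  invisible(x)
}

#' Pooled permutation p-value
#'
#' `(b + 1) / (m + 1)` where `b` counts pooled permuted p-values below the
#' real one and `m` is the pool size. Strict counting follows the published
#' formula's wording; `count = "lte"` switches to counting ties too.
#'
#' @param real_p The real paired-t p-value.
#' @param pooled Numeric vector of pooled permuted p-values.
#' @param count `"strict"` or `"lte"`.
#' @return A value in `(0, 1]`, never smaller than `1 / (m + 1)`.
#' @export
permutation_pvalue <- function(real_p, pooled, count = "strict") {
  if (length(pooled) == 0) stopf("pooled null is empty")
  b <- if (count == "strict") sum(pooled < real_p) else sum(pooled <= real_p)
  (b + 1) / (length(pooled) + 1)
}

#' Largest real p-value that still beats the pooled null
#'
#' The "value to beat": the largest threshold `v` such that any real p-value
#' below `v` attains a pooled permutation p-value below `alpha`. With
#' `b_max` the largest count satisfying `(b_max + 1) / (m + 1) < alpha`,
#' this is the `(b_max + 1)`-th smallest pooled value. Under the default
#' strict counting the pass region is closed at `v` (a real p exactly equal
#' to `v` still beats `alpha`, since pooled values below it number `b_max`);
#' under `"lte"` counting the boundary itself no longer passes.
#'
#' @param pooled Pooled permuted p-values.
#' @param alpha Significance level.
#' @return The threshold, or `NA` when no real p-value can reach `alpha`
#'   (e.g. a pool of 3 values cannot beat 0.05: the minimum attainable
#'   permutation p is 0.25).
#' @export
value_to_beat <- function(pooled, alpha = 0.05) {
  if (length(pooled) == 0) stopf("pooled null is empty")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  m <- length(pooled)
  bs <- 0:m
  ok <- (bs + 1) / (m + 1) < alpha
  if (!any(ok)) return(NA_real_)  # unattainable
  b_max <- max(bs[ok])
  sort(pooled)[min(b_max + 1, m)]
}

#' Minimum attainable two-sided exact Wilcoxon signed-rank p-value
#'
#' Enumerates the exact null distribution of the signed-rank statistic over
#' all `2^n` sign assignments (dynamic-programming convolution over ranks)
#' and returns the smallest attainable two-sided p. For `n = 3` this is
#' 0.25 — the power ceiling that motivates the permutation design over
#' rank tests at three donors.
#'
#' @param n Number of pairs, `1 <= n <= 20`.
#' @return The minimum two-sided exact p-value, `2 / 2^n`.
#' @export
wilcoxon_min_p <- function(n) {
  if (n < 1 || n > 20) stopf("n must lie in 1..20")
  # counts[w + 1] = number of sign assignments with positive-rank sum w
  counts <- 1
  for (r in seq_len(n)) {
    shifted <- c(rep(0, r), counts)
    counts <- c(counts, rep(0, r)) + shifted
  }
  total <- 2^n
  cum <- cumsum(counts)
  min_p <- Inf
  for (w in seq_along(counts) - 1) {
    if (counts[w + 1] == 0) next
    lower <- cum[w + 1] / total
    upper <- (total - if (w == 0) 0 else cum[w]) / total
    min_p <- min(min_p, min(1, 2 * min(lower, upper)))
  }
  min_p
}
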