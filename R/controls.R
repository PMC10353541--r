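# Control-sample computations: spillover estimation and compensation,
# stain-index titration, and the intrinsic-fluorescence interference screen.

#' Spillover matrix
#'
#' `S[i, j]` is the fraction of fluorophore `i`'s signal read in detector
#' `j`; the diagonal is 1 by construction.
#'
#' @param S Square numeric matrix with detector dimnames.
#' @param detectors Ordered detector ids (defaults to `rownames(S)`).
#' @return A `spillover_matrix` object.
#' @export
spillover_matrix <- function(S, detectors = rownames(S)) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stopf("spillover matrix must be square")
  dimnames(S) <- list(detectors, detectors)
  if (any(abs(diag(S) - 1) > 1e-12))
    stopf("spillover matrix must have a unit diagonal")
  if (any(S < 0 | S > 1)) stopf("spillover entries must lie in [0, 1]")
  if (abs(det(S)) < 1e-12) stopf("spillover matrix is singular")
  structure(list(detectors = detectors, S = S), class = "spillover_matrix")
}

#' Identity spillover over a set of detectors
#'
#' @param detectors Detector ids.
#' @return A [spillover_matrix()] with no spectral overlap.
#' @export
identity_spillover <- function(detectors) {
  spillover_matrix(diag(length(detectors)), detectors)
}

#' @export
print.spillover_matrix <- function(x, ...) {
  off <- x$S[row(x$S) != col(x$S)]
  cat(sprintf("<spillover_matrix> %d detectors, max off-diagonal %.4f\n",
              length(x$detectors), if (length(off)) max(off) else 0))
  invisible(x)
}

#' Write / read a spillover matrix as CSV
#'
#' Detectors form both the header row and the first column, so the file is
#' self-describing and round-trips exactly at full double precision.
#'
#' @param S A [spillover_matrix()].
#' @param path CSV file path.
#' @return `path` (write) or a [spillover_matrix()] (read).
#' @export
write_spillover_csv <- function(S, path) {
  df <- data.frame(detector = S$detectors,
                   format(S$S, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("detector", S$detectors)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spillover_csv
#' @export
read_spillover_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  dets <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- dets
  spillover_matrix(M[, dets, drop = FALSE], dets)
}

# Positive/negative split against an unstained background: events above the
# given quantile of the background on the primary channel form the positive
# component (stand-in for the instrument software's bead classification).
# A stained sample indistinguishable from background puts ~(1 - q) of its
# events above the cut by construction; `separable` therefore requires the
# positive fraction to exceed that floor fourfold.
split_pos_neg <- function(values, background, q = 0.995) {
  cut <- stats::quantile(background, q, names = FALSE, type = 7)
  pos <- values > cut
  list(pos = pos, cut = cut, separable = mean(pos) >= 4 * (1 - q))
}

#' Estimate spillover from single-stain controls
#'
#' For each stained fluorophore `i`, events of its single-stain sample are
#' split into positive/negative on the primary detector against the
#' unstained background; the coefficient into detector `j` is the ratio of
#' median differences
#' `(median_pos_j - median_neg_j) / (median_pos_i - median_neg_i)`.
#' The diagonal is forced to 1 and negative estimates clipped to 0.
#'
#' @param single_stains Named list, detector -> single-stain
#'   [event_matrix()]; one entry per panel detector.
#' @param unstained Unstained [event_matrix()] on the same detectors.
#' @param split_quantile Background quantile of the positive/negative split.
#' @return A [spillover_matrix()].
#' @export
estimate_spillover <- function(single_stains, unstained,
                               split_quantile = 0.995) {
  dets <- colnames(unstained$fluorescence)
  missing <- setdiff(dets, names(single_stains))
  if (length(missing) > 0)
    stopf("no single-stain sample for detector '%s'", missing[1])
  S <- diag(length(dets))
  dimnames(S) <- list(dets, dets)
  for (i in dets) {
    fl <- single_stains[[i]]$fluorescence[, dets, drop = FALSE]
    sp <- split_pos_neg(fl[, i], unstained$fluorescence[, i], split_quantile)
    n_pos <- sum(sp$pos)
    if (!sp$separable || n_pos < 10 || n_pos > length(sp$pos) - 10)
      stopf("no separable positive population on detector '%s'", i)
    med_pos <- apply(fl[sp$pos, , drop = FALSE], 2, stats::median)
    med_neg <- apply(fl[!sp$pos, , drop = FALSE], 2, stats::median)
    denom <- med_pos[i] - med_neg[i]
    if (denom <= 0)
      stopf("no separable positive population on detector '%s'", i)
    S[i, ] <- pmin(1, pmax(0, (med_pos - med_neg) / denom))
    S[i, i] <- 1
  }
  spillover_matrix(S, dets)
}

#' Compensate a sample for spectral spillover
#'
#' Per event, solves `observed = true %*% S` for the true signal; scatter
#' channels and truth labels are untouched. Inverse of
#' [apply_spillover()].
#'
#' @param sample An [event_matrix()].
#' @param S A [spillover_matrix()] over the sample's detectors.
#' @return The compensated sample.
#' @export
compensate <- function(sample, S) {
  stopifnot(inherits(sample, "event_matrix"), inherits(S, "spillover_matrix"))
  dets <- colnames(sample$fluorescence)
  if (!setequal(dets, S$detectors))
    stopf("spillover detectors do not match sample detectors")
  M <- S$S[dets, dets]
  out <- sample
  # observed = true %*% M  =>  true = observed %*% M^-1, solved without
  # forming the inverse explicitly: t(true) = solve(t(M), t(observed))
  out$fluorescence <- t(solve(t(M), t(sample$fluorescence)))
  dimnames(out$fluorescence) <- dimnames(sample$fluorescence)
  out
}

#' Stain index of a titration point
#'
#' Separation of the stained-positive component from the negative
#' population, normalized by the robust spread of the negatives:
#' `(median(positive) - median(negative)) / (2 * rSD(negative))` with
#' `rSD = 1.4826 * MAD`. The positive component is identified by a quantile
#' split of the stained events against the negative distribution.
#'
#' @param stained Numeric vector of stained-sample intensities on the
#'   titrated channel.
#' @param negative Numeric vector of negative-control intensities on the
#'   same channel.
#' @param split_quantile Quantile of `negative` above which stained events
#'   count as positive.
#' @return A single score; 0 when no positive component separates from the
#'   background (the staining adds nothing); `NA` with a warning when the
#'   negative robust SD is zero.
#' @export
stain_index <- function(stained, negative, split_quantile = 0.995) {
  if (length(stained) == 0 || length(negative) == 0)
    stopf("stained and negative must be nonempty")
  rsd <- robust_sd(negative)
  if (rsd == 0) {
    warning("zero robust SD of the negative population; stain index undefined")
    return(NA_real_)
  }
  sp <- split_pos_neg(stained, negative, split_quantile)
  if (!sp$separable || !any(sp$pos)) return(0)
  (stats::median(stained[sp$pos]) - stats::median(negative)) / (2 * rsd)
}

#' Titration curve of one antibody
#'
#' @param channel Detector id being titrated.
#' @param dilution_factors Strictly increasing cumulative dilution factors.
#' @param stain_indices Stain index per dilution point.
#' @return A `titration_curve` with the optimal dilution attached.
#' @seealso [select_optimal_dilution()]
#' @export
titration_curve <- function(channel, dilution_factors, stain_indices) {
  if (length(dilution_factors) != length(stain_indices))
    stopf("dilution_factors and stain_indices must have equal length")
  if (any(diff(dilution_factors) <= 0))
    stopf("dilution_factors must be strictly increasing")
  tc <- structure(list(channel = channel,
                       dilution_factors = dilution_factors,
                       stain_indices = stain_indices,
                       optimal_dilution = NA_real_),
                  class = "titration_curve")
  tc$optimal_dilution <- select_optimal_dilution(tc)
  tc
}

#' Optimal antibody dilution from a titration curve
#'
#' The dilution with the maximum stain index; ties are broken toward the
#' larger dilution factor (less antibody).
#'
#' @param curve A [titration_curve()] (or any list with
#'   `dilution_factors` and `stain_indices`).
#' @return The selected dilution factor.
#' @export
select_optimal_dilution <- function(curve) {
  si <- curve$stain_indices
  if (length(si) < 2) stopf("titration needs at least 2 points")
  ok <- is.finite(si)
  if (!any(ok)) stopf("all stain indices are undefined")
  best <- max(si[ok])
  candidates <- curve$dilution_factors[ok][si[ok] == best]
  max(candidates)
}

#' Interference report of an unstained treated-vs-untreated comparison
#'
#' @param scores Named numeric vector of robust standardized median shifts
#'   per detector.
#' @param cutoff Flagging cutoff in robust SDs.
#' @return An `interference_report` data frame: `detector`, `score`, `flag`.
#' @export
interference_report <- function(scores, cutoff = 3) {
  structure(data.frame(detector = names(scores), score = unname(scores),
                       flag = unname(scores) >= cutoff, row.names = NULL),
            class = c("interference_report", "data.frame"),
            cutoff = cutoff)
}

#' Screen a test article for intrinsic-fluorescence interference
#'
#' Compares an unstained drug-treated sample with an unstained untreated
#' sample, per detector:
#' `score = (median(treated) - median(untreated)) / rSD(untreated)`.
#' Detectors whose score reaches the cutoff (default 3 robust SDs) are
#' flagged as interfered; flagged channels cannot be read reliably at that
#' drug concentration.
#'
#' @param treated_unstained,untreated_unstained Unstained [event_matrix()]
#'   samples on the same detectors.
#' @param detectors Detectors to screen (default: all shared).
#' @param cutoff Flagging cutoff in robust SDs.
#' @return An [interference_report()].
#' @export
interference_screen <- function(treated_unstained, untreated_unstained,
                                detectors = NULL, cutoff = 3) {
  dets <- detectors %||% colnames(untreated_unstained$fluorescence)
  scores <- vapply(dets, function(d) {
    u <- untreated_unstained$fluorescence[, d]
    rsd <- robust_sd(u)
    if (rsd == 0) stopf("zero robust SD on control channel '%s'", d)
    (stats::median(treated_unstained$fluorescence[, d]) - stats::median(u)) /
      rsd
  }, numeric(1))
  interference_report(scores, cutoff = cutoff)
}
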