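# Derived quantities: geometric MFI, stimulation indices, and assembly of
# the per-donor endpoint tables that feed the statistics layer.

#' Geometric mean fluorescence intensity
#'
#' `exp(mean(log(x)))` over the positive values. Compensation can push a
#' minority of events at or below zero; those are excluded (the log is
#' undefined there) rather than shifted, because additive shifts distort
#' fold changes. If more than half the values are non-positive the gMFI is
#' undefined and `NA` is returned with a warning.
#'
#' @param values Numeric vector of intensities.
#' @return The geometric mean, or `NA` when undefined.
#' @export
gmfi <- function(values) {
  if (length(values) == 0) stopf("gmfi of an empty vector")
  pos <- values > 0
  if (sum(pos) < length(values) / 2) {
    warning(sprintf("gMFI undefined: %d of %d values non-positive",
                    sum(!pos), length(values)))
    return(NA_real_)
  }
  exp(mean(log(values[pos])))
}

#' Stimulation index (fold change vs a reference condition)
#'
#' Ratio of replicate means — technical replicates are averaged before
#' division, so the SI is the fold change of the replicate-averaged readout,
#' not the average of per-replicate ratios.
#'
#' @param treated_reps Endpoint values of the treated/stimulated replicates.
#' @param reference_reps Endpoint values of the reference replicates
#'   (unstimulated or vehicle control).
#' @return `mean(treated) / mean(reference)`; `NA` with a warning when the
#'   reference mean is zero.
#' @export
stimulation_index <- function(treated_reps, reference_reps) {
  if (length(treated_reps) == 0 || length(reference_reps) == 0)
    stopf("stimulation_index needs nonempty inputs")
  ref <- mean(reference_reps)
  if (ref == 0) {
    warning("reference mean is zero; stimulation index undefined")
    return(NA_real_)
  }
  mean(treated_reps) / ref
}

#' Endpoint vector of one gated sample
#'
#' Flattens a `gate_stats` into the named endpoints the statistics layer
#' works on: percent-of-live per population, the four activation-quadrant
#' percentages per activation-flagged population, and the per-marker gMFIs
#' of those populations.
#'
#' @param gs A `gate_stats`.
#' @return Named numeric vector; names look like `"pct_live|B cells"`,
#'   `"quad_pp|CD4 T cells"`, `"gmfi_CD25|CD4 T cells"`.
#' @export
endpoint_values <- function(gs) {
  out <- stats::setNames(gs$populations$pct_of_live,
                         paste0("pct_live|", gs$populations$population))
  if (!is.null(gs$activation)) {
    a <- gs$activation
    for (i in seq_len(nrow(a))) {
      nm <- a$population[i]
      q <- stats::setNames(
        as.numeric(a[i, c("pct_nn", "pct_pn", "pct_np", "pct_pp")]),
        paste0("quad_", c("nn", "pn", "np", "pp"), "|", nm))
      g <- stats::setNames(as.numeric(a[i, c("gmfi_a", "gmfi_b")]),
                           paste0("gmfi_", c(a$marker_a[i], a$marker_b[i]),
                                  "|", nm))
      out <- c(out, q, g)
    }
  }
  out
}

#' Assemble stimulation-index tables for a gated cohort
#'
#' For every donor and treatment (any non-reference condition), each
#' endpoint's technical replicates are averaged and divided by the
#' replicate-averaged value of the donor-matched reference condition. The
#' reference is the treatment's vehicle control where one is defined and the
#' unstimulated control otherwise.
#'
#' @param stats List of `gate_stats` of fully-stained samples (one per
#'   donor x condition x replicate).
#' @param reference_rule Named character vector mapping a treatment to its
#'   reference condition; unlisted treatments fall back to `default_reference`.
#' @param default_reference Condition used as reference when no rule matches.
#' @return An `si_table` data frame: `donor`, `treatment`, `reference`,
#'   `endpoint`, `si`, `mean_treated`, `mean_reference`, replicate counts and
#'   a `flag` column (`"ok"`, `"undefined"`, `"missing_reference"`); no
#'   (donor, treatment, endpoint) cell is silently dropped.
#' @export
assemble_si_tables <- function(stats, reference_rule = character(),
                               default_reference = "unstimulated") {
  md <- lapply(stats, `[[`, "metadata")
  donors <- vapply(md, `[[`, character(1), "donor_id")
  conds <- vapply(md, `[[`, character(1), "condition")
  panels <- vapply(md, function(m) m$panel_id, integer(1))
  if (length(unique(panels)) > 1)
    stopf("mixed panels in one SI table (found panels %s)",
          paste(unique(panels), collapse = ", "))
  ep <- lapply(stats, endpoint_values)
  ep_names <- names(ep[[1]])

  references <- unique(c(reference_rule, default_reference))
  treatments <- setdiff(unique(conds), references)
  rows <- list()
  for (donor in unique(donors)) {
    for (trt in treatments) {
      ref_cond <- if (trt %in% names(reference_rule))
        reference_rule[[trt]] else default_reference
      t_idx <- which(donors == donor & conds == trt)
      r_idx <- which(donors == donor & conds == ref_cond)
      for (e in ep_names) {
        tv <- vapply(ep[t_idx], `[[`, numeric(1), e)
        rv <- if (length(r_idx)) vapply(ep[r_idx], `[[`, numeric(1), e)
          else numeric(0)
        tv <- tv[is.finite(tv)]
        rv <- rv[is.finite(rv)]
        flag <- "ok"
        si <- NA_real_
        if (length(r_idx) == 0) {
          flag <- "missing_reference"
        } else if (length(tv) == 0 || length(rv) == 0 || mean(rv) == 0) {
          flag <- "undefined"
        } else {
          si <- mean(tv) / mean(rv)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          donor = donor, treatment = trt, reference = ref_cond,
          endpoint = e, si = si,
          mean_treated = if (length(tv)) mean(tv) else NA_real_,
          mean_reference = if (length(rv)) mean(rv) else NA_real_,
          n_treated_reps = length(tv), n_reference_reps = length(rv),
          flag = flag)
      }
    }
  }
  res <- if (length(rows) == 0) {
    data.frame(donor = character(), treatment = character(),
               reference = character(), endpoint = character(),
               si = numeric(), mean_treated = numeric(),
               mean_reference = numeric(), n_treated_reps = integer(),
               n_reference_reps = integer(), flag = character())
  } else {
    do.call(rbind, rows)
  }
  rownames(res) <- NULL
  class(res) <- c("si_table", "data.frame")
  res
}

#' Replicate-averaged endpoint matrix of a gated cohort
#'
#' One row per endpoint, one column per donor, for a single condition —
#' the shape consumed by the paired statistics.
#'
#' @param stats List of `gate_stats`.
#' @param condition Condition to extract.
#' @return Numeric matrix endpoints x donors of replicate means.
#' @export
endpoint_matrix <- function(stats, condition) {
  md <- lapply(stats, `[[`, "metadata")
  keep <- vapply(md, function(m) m$condition == condition, logical(1))
  if (!any(keep)) stopf("no samples for condition '%s'", condition)
  stats <- stats[keep]
  donors <- vapply(stats, function(s) s$metadata$donor_id, character(1))
  ep <- lapply(stats, endpoint_values)
  ep_names <- names(ep[[1]])
  u_donors <- unique(donors)
  M <- matrix(NA_real_, length(ep_names), length(u_donors),
              dimnames = list(ep_names, u_donors))
  for (d in u_donors) {
    vals <- do.call(cbind, ep[donors == d])
    M[, d] <- rowMeans(vals)
  }
  M
}
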