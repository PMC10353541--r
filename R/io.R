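# Event-table I/O (CSV and FCS) and the cohort manifest.

#' Write an event matrix to CSV
#'
#' Scatter and fluorescence columns with a header row; comma delimiter,
#' `.` decimal, UTF-8, full double precision (the file round-trips
#' bit-exactly). Truth labels, when present, go into a trailing `truth`
#' column.
#'
#' @param sample An [event_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(sample, path) {
  M <- cbind(sample$scatter, sample$fluorescence)
  df <- as.data.frame(M, check.names = FALSE)
  df[] <- lapply(df, function(x)
    format(x, digits = 17, trim = TRUE, scientific = TRUE))
  if (!is.null(sample$truth)) df$truth <- sample$truth
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cytometry sample from FCS or CSV
#'
#' The format is chosen by file extension (`.fcs` vs anything else = CSV
#' with a header). Channel columns are mapped by the panel's
#' `"Marker-Fluorophore"` naming; a file missing a panel channel is an
#' error naming that channel. An FCS `$SPILLOVER` keyword, when present, is
#' attached as attribute `"spillover"`.
#'
#' @param path Input file.
#' @param metadata A [sample_metadata()] for the sample (FCS `$FIL` is not
#'   trusted to encode the cohort coordinates).
#' @param panel Optional `panel_definition`; when given, all panel detectors
#'   must be present.
#' @return An [event_matrix()].
#' @export
read_events <- function(path, metadata, panel = NULL) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  if (grepl("\\.fcs$", path, ignore.case = TRUE)) {
    parsed <- read_fcs(path)
    M <- parsed$data
    truth <- NULL
    spill <- parsed$spillover
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    truth <- if ("truth" %in% names(df)) as.character(df$truth) else NULL
    df$truth <- NULL
    M <- as.matrix(df)
    storage.mode(M) <- "double"
    spill <- NULL
  }
  scatter_cols <- intersect(c("FSC-A", "FSC-H", "SSC-A"), colnames(M))
  if (length(scatter_cols) < 3)
    stopf("file '%s' is missing scatter channel '%s'", path,
          setdiff(c("FSC-A", "FSC-H", "SSC-A"), colnames(M))[1])
  fl_cols <- setdiff(colnames(M), scatter_cols)
  if (!is.null(panel)) {
    missing <- setdiff(panel_detectors(panel), fl_cols)
    if (length(missing) > 0)
      stopf("file '%s' is missing panel channel '%s'", path, missing[1])
    fl_cols <- panel_detectors(panel)
  }
  out <- event_matrix(metadata, M[, scatter_cols, drop = FALSE],
                      M[, fl_cols, drop = FALSE], truth = truth)
  attr(out, "spillover") <- spill
  out
}

#' Build a cohort manifest from samples
#'
#' One row per sample with its cohort coordinates plus, for every
#' fully-stained sample, the id of its condition-matched isotype control
#' (the sample that sets its gates) and nothing else — pairing by donor and
#' condition is how isotype gating is matched to the samples it thresholds.
#'
#' @param samples Named list of [event_matrix()] objects.
#' @return A `cohort_manifest` data frame with columns `sample_id`,
#'   `donor_id`, `condition`, `stain_type`, `replicate_index`, `panel_id`,
#'   `isotype_id` (`NA` where unpaired).
#' @export
cohort_manifest <- function(samples) {
  md <- lapply(samples, `[[`, "metadata")
  df <- data.frame(
    sample_id = vapply(md, `[[`, character(1), "sample_id"),
    donor_id = vapply(md, `[[`, character(1), "donor_id"),
    condition = vapply(md, `[[`, character(1), "condition"),
    stain_type = vapply(md, `[[`, character(1), "stain_type"),
    replicate_index = vapply(md, `[[`, integer(1), "replicate_index"),
    panel_id = vapply(md, `[[`, integer(1), "panel_id"),
    row.names = NULL)
  iso <- df[df$stain_type == "isotype", ]
  df$isotype_id <- NA_character_
  for (i in which(df$stain_type == "fully-stained")) {
    hit <- iso$donor_id == df$donor_id[i] & iso$condition == df$condition[i]
    if (any(hit)) df$isotype_id[i] <- iso$sample_id[which(hit)[1]]
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Validate a cohort manifest
#'
#' @param manifest A [cohort_manifest()].
#' @return Character vector of diagnostics (empty when every fully-stained
#'   sample has an isotype pairing).
#' @export
validate_manifest <- function(manifest) {
  diags <- character()
  fs <- manifest[manifest$stain_type == "fully-stained", ]
  bad <- fs$sample_id[is.na(fs$isotype_id)]
  if (length(bad) > 0)
    diags <- c(diags, sprintf(
      "fully-stained sample '%s' has no condition-matched isotype control",
      bad))
  diags
}
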