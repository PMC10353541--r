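# End-to-end orchestration: compensation -> isotype thresholds -> gating ->
# stimulation indices -> reproducibility and permutation statistics.

#' Pipeline configuration
#'
#' @param isotype_quantile Quantile of the isotype background used for all
#'   marker thresholds.
#' @param gating A [gating_config()].
#' @param reference_rule Named character vector, treatment -> reference
#'   condition (vehicle controls); anything unlisted falls back to
#'   `default_reference`.
#' @param default_reference Reference condition (unstimulated control).
#' @param min_pairs Minimum complete donor pairs for a permutation test.
#' @param count Permuted-p counting rule, `"strict"` or `"lte"`.
#' @param alpha Level for the reported value to beat.
#' @param quadrant_gmfi Restrict gMFIs to marker-positive events.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(isotype_quantile = 0.995,
                            gating = gating_config(),
                            reference_rule = character(),
                            default_reference = "unstimulated",
                            min_pairs = 3,
                            count = "strict",
                            alpha = 0.05,
                            quadrant_gmfi = FALSE) {
  structure(list(isotype_quantile = isotype_quantile, gating = gating,
                 reference_rule = reference_rule,
                 default_reference = default_reference,
                 min_pairs = min_pairs, count = count, alpha = alpha,
                 quadrant_gmfi = quadrant_gmfi),
            class = "pipeline_config")
}

#' Serialize / load a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  doc <- unclass(config)
  # named atomic vectors would lose their names under auto_unbox
  doc$reference_rule <- as.list(doc$reference_rule)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  for (nm in names(doc)) {
    if (nm == "gating") {
      for (g in names(doc$gating)) cfg$gating[[g]] <- doc$gating[[g]]
    } else if (nm == "reference_rule") {
      cfg$reference_rule <- unlist(doc$reference_rule) %||% character()
    } else {
      cfg[[nm]] <- doc[[nm]]
    }
  }
  cfg
}

#' Run the full immunophenotyping pipeline on a cohort
#'
#' Stages: (1) resolve the spillover matrix — supplied, estimated from
#' single-stain controls, or identity; (2) compensate all stained samples;
#' (3) fit isotype thresholds per (donor, condition) from each fully-stained
#' sample's condition-matched isotype control; (4) execute the gate tree;
#' (5) assemble stimulation indices vs vehicle/unstimulated references;
#' (6) negative-control Pearson reproducibility; (7) paired-t + exhaustive
#' sign-flip permutation analysis per treatment. Deterministic given inputs
#' and config. Samples that cannot be processed are recorded in the
#' exclusion table with a reason, never dropped silently.
#'
#' @param samples Named list of [event_matrix()] objects (a simulated cohort
#'   or samples loaded with [read_events()]).
#' @param panel A `panel_definition`.
#' @param config A [pipeline_config()].
#' @param spillover Optional known [spillover_matrix()].
#' @param single_stains,unstained Optional compensation controls for
#'   [estimate_spillover()] when `spillover` is not supplied.
#' @param out_dir Optional directory: tidy CSVs of every stage plus a JSON
#'   run log (config, package version, sample inventory) are written there;
#'   reruns with identical inputs produce byte-identical CSVs.
#' @return A `pipeline_result` list: `gate_stats`, `si_table`,
#'   `permutation`, `control_correlation`, `spillover`, `thresholds`,
#'   `exclusions`, `manifest`.
#' @export
run_pipeline <- function(samples, panel, config = pipeline_config(),
                         spillover = NULL, single_stains = NULL,
                         unstained = NULL, out_dir = NULL) {
  manifest <- cohort_manifest(samples)
  exclusions <- data.frame(sample_id = character(), reason = character())
  exclude <- function(id, reason) {
    exclusions[nrow(exclusions) + 1L, ] <<- list(id, reason)
  }

  dets <- panel_detectors(panel)
  S <- spillover %||%
    (if (!is.null(single_stains))
       estimate_spillover(single_stains, unstained)
     else identity_spillover(dets))

  stained_types <- c("fully-stained", "isotype")
  comped <- lapply(samples, function(s) {
    if (s$metadata$stain_type %in% stained_types) compensate(s, S) else s
  })

  # isotype thresholds per (donor, condition)
  thresholds <- list()
  iso_rows <- manifest[manifest$stain_type == "isotype", ]
  for (i in seq_len(nrow(iso_rows))) {
    key <- paste(iso_rows$donor_id[i], iso_rows$condition[i], sep = "|")
    if (!is.null(thresholds[[key]])) next
    thresholds[[key]] <- fit_isotype_thresholds(
      comped[[iso_rows$sample_id[i]]], panel,
      quantile = config$isotype_quantile, config = config$gating)
  }

  gate_stats <- list()
  fs_rows <- manifest[manifest$stain_type == "fully-stained", ]
  for (i in seq_len(nrow(fs_rows))) {
    id <- fs_rows$sample_id[i]
    key <- paste(fs_rows$donor_id[i], fs_rows$condition[i], sep = "|")
    if (is.null(thresholds[[key]])) {
      exclude(id, "no condition-matched isotype control")
      next
    }
    gate_stats[[id]] <- tryCatch(
      apply_gate_tree(comped[[id]], panel, thresholds[[key]],
                      config = config$gating,
                      quadrant_gmfi = config$quadrant_gmfi),
      error = function(e) {
        exclude(id, conditionMessage(e))
        NULL
      })
  }
  gate_stats <- Filter(Negate(is.null), gate_stats)
  for (id in manifest$sample_id[!manifest$stain_type %in%
                                c("fully-stained", "isotype")]) {
    exclude(id, "control sample: not gated")
  }
  if (length(gate_stats) == 0) stopf("no sample could be gated")

  si <- assemble_si_tables(gate_stats,
                           reference_rule = config$reference_rule,
                           default_reference = config$default_reference)

  # negative-control reproducibility across unstimulated runs
  ctrl <- NULL
  ref_ids <- names(gate_stats)[vapply(gate_stats, function(g)
    g$metadata$condition == config$default_reference, logical(1))]
  if (length(ref_ids) >= 2) {
    vecs <- lapply(gate_stats[ref_ids], function(g)
      stats::setNames(g$populations$pct_of_live, g$populations$population))
    ctrl <- control_correlation(vecs)
  }

  # permutation statistics per treatment
  perm <- NULL
  references <- unique(c(config$reference_rule, config$default_reference))
  gated_conds <- unique(vapply(gate_stats, function(g)
    g$metadata$condition, character(1)))
  treatments <- setdiff(intersect(unique(fs_rows$condition), gated_conds),
                        references)
  if (length(treatments) > 0) {
    tests <- list()
    for (trt in treatments) {
      ref_cond <- if (trt %in% names(config$reference_rule))
        config$reference_rule[[trt]] else config$default_reference
      if (!ref_cond %in% gated_conds) next
      Tr <- endpoint_matrix(gate_stats, trt)
      Co <- endpoint_matrix(gate_stats, ref_cond)
      donors <- intersect(colnames(Tr), colnames(Co))
      tests[[trt]] <- list(treated = Tr[, donors, drop = FALSE],
                           control = Co[, donors, drop = FALSE])
    }
    if (length(tests) > 0)
      perm <- permutation_analysis(tests, min_pairs = config$min_pairs,
                                   count = config$count, alpha = config$alpha)
  }

  result <- structure(list(gate_stats = gate_stats, si_table = si,
                           permutation = perm, control_correlation = ctrl,
                           spillover = S, thresholds = thresholds,
                           exclusions = exclusions, manifest = manifest,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, panel, out_dir)
  result
}

#' Write every pipeline artifact to a directory
#'
#' Tidy CSVs (`gate_stats.csv`, `si_table.csv`, `permutation_tests.csv`,
#' `pooled_null.csv`, `control_correlation.csv`, `exclusions.csv`,
#' `manifest.csv`), a JSON threshold audit per (donor, condition), the
#' spillover matrix CSV, and `run_log.json`.
#'
#' @param result A `pipeline_result`.
#' @param panel The `panel_definition` used.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, panel, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(gate_stats_table(result$gate_stats), p("gate_stats.csv"),
                   row.names = FALSE)
  utils::write.csv(result$si_table, p("si_table.csv"), row.names = FALSE)
  utils::write.csv(result$manifest, p("manifest.csv"), row.names = FALSE)
  utils::write.csv(result$exclusions, p("exclusions.csv"), row.names = FALSE)
  if (!is.null(result$permutation)) {
    utils::write.csv(result$permutation$tests, p("permutation_tests.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(permuted_p = result$permutation$pooled),
                     p("pooled_null.csv"), row.names = FALSE)
  }
  if (!is.null(result$control_correlation)) {
    R <- result$control_correlation$R
    utils::write.csv(data.frame(run = rownames(R), R, check.names = FALSE),
                     p("control_correlation.csv"), row.names = FALSE)
  }
  write_spillover_csv(result$spillover, p("spillover.csv"))
  for (key in names(result$thresholds)) {
    write_thresholds_json(result$thresholds[[key]], panel,
                          p(paste0("thresholds_", gsub("[^A-Za-z0-9._-]", "_",
                                                       key), ".json")))
  }
  log <- list(
    package = "immunogate",
    version = as.character(utils::packageVersion("immunogate")),
    panel_id = panel$panel_id,
    config = unclass(result$config),
    n_samples = nrow(result$manifest),
    n_gated = length(result$gate_stats),
    n_excluded = nrow(result$exclusions))
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Heat-map of a stimulation-index table
#'
#' Cosmetic reporting extra: endpoints x donors for one treatment, rendered
#' with pheatmap when available (base [stats::heatmap()] otherwise).
#'
#' @param si An `si_table`.
#' @param treatment Treatment to plot.
#' @param ... Passed to the heat-map engine.
#' @return The heat-map object, invisibly.
#' @export
plot_si_heatmap <- function(si, treatment, ...) {
  sub <- si[si$treatment == treatment & si$flag == "ok", ]
  if (nrow(sub) == 0) stopf("no plottable SI rows for '%s'", treatment)
  M <- stats::xtabs(si ~ endpoint + donor, data = sub)
  M <- matrix(as.numeric(M), nrow(M), ncol(M), dimnames = dimnames(M))
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    ph <- pheatmap::pheatmap(M, cluster_cols = FALSE, ...)
    invisible(ph)
  } else {
    stats::heatmap(M, Colv = NA, ...)
    invisible(M)
  }
}
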