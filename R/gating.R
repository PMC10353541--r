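# Gate-tree execution: data-driven scatter/singlet/viability gates,
# isotype-quantile marker thresholds, population membership, activation
# quadrants and gMFIs.

#' Gating configuration
#'
#' @param scatter_trim Percentile window kept on FSC-A and SSC-A by the
#'   main-cells gate (reproducible surrogate for a hand-drawn region).
#' @param fsc_floor Fixed FSC-A floor of the main-cells gate; removes the
#'   low-scatter debris cloud.
#' @param singlet_ratio Allowed FSC-H / FSC-A window of the singlet gate;
#'   doublets are sub-additive in FSC-H and fall below it.
#' @param isotype_quantile Quantile of the isotype background that sets each
#'   marker threshold (0.995 keeps the conventional 0.5% false-positive
#'   rate).
#' @return A plain list of settings.
#' @export
gating_config <- function(scatter_trim = c(0.02, 0.995),
                          fsc_floor = 20000,
                          singlet_ratio = c(0.8, 1.2),
                          isotype_quantile = 0.995) {
  list(scatter_trim = scatter_trim, fsc_floor = fsc_floor,
       singlet_ratio = singlet_ratio, isotype_quantile = isotype_quantile)
}

# Deterministic 2-means (Lloyd iterations from quantile-based starting
# centers); used for the viability split and the monocyte/lymphocyte
# scatter split so gating never consumes RNG.
two_means <- function(X, iters = 30) {
  X <- as.matrix(X)
  qs <- apply(X, 2, stats::quantile, probs = c(0.15, 0.85), names = FALSE)
  centers <- rbind(qs[1, ], qs[2, ])
  for (it in seq_len(iters)) {
    d1 <- rowSums((X - matrix(centers[1, ], nrow(X), ncol(X),
                              byrow = TRUE))^2)
    d2 <- rowSums((X - matrix(centers[2, ], nrow(X), ncol(X),
                              byrow = TRUE))^2)
    grp <- d2 < d1
    if (!any(grp) || all(grp)) break
    new_centers <- rbind(colMeans(X[!grp, , drop = FALSE]),
                         colMeans(X[grp, , drop = FALSE]))
    if (max(abs(new_centers - centers)) < 1e-8) {
      centers <- new_centers
      break
    }
    centers <- new_centers
  }
  list(cluster = grp + 1L, centers = centers)
}

# Main-cells gate: percentile-trimmed rectangle on (FSC-A, SSC-A) plus a
# fixed FSC floor.
main_cells_members <- function(sample, config) {
  fsc <- sample$scatter[, "FSC-A"]
  ssc <- sample$scatter[, "SSC-A"]
  qf <- stats::quantile(fsc, config$scatter_trim, names = FALSE)
  qs <- stats::quantile(ssc, config$scatter_trim, names = FALSE)
  fsc >= max(qf[1], config$fsc_floor) & fsc <= qf[2] &
    ssc >= qs[1] & ssc <= qs[2]
}

# Monocyte/lymphocyte split of panel 2: 2-means location model on scaled
# (FSC-A, SSC-A) among main-cell members; the cluster with the larger SSC-A
# center is the monocyte region. Returns membership by branch label.
scatter_branch_members <- function(sample, members, config) {
  X <- sample$scatter[members, c("FSC-A", "SSC-A"), drop = FALSE]
  Xs <- scale(X)
  km <- two_means(Xs)
  ssc_means <- tapply(X[, "SSC-A"], km$cluster, mean)
  mono_cl <- as.integer(names(ssc_means)[which.max(ssc_means)])
  mono <- lymph <- logical(length(members))
  mono[members] <- km$cluster == mono_cl
  lymph[members] <- km$cluster != mono_cl
  list(monocyte = mono, lymphocyte = lymph)
}

singlet_members <- function(sample, members, config) {
  ratio <- sample$scatter[, "FSC-H"] / pmax(sample$scatter[, "FSC-A"], 1e-9)
  members & ratio >= config$singlet_ratio[1] & ratio <= config$singlet_ratio[2]
}

# Live/dead threshold: the viability dye is bimodal on the log scale in any
# stained sample, so the cut is the geometric midpoint of a deterministic
# 1-D 2-means on log intensity. Events above the cut are dead (excluded).
viability_threshold <- function(values) {
  lv <- log(pmax(values, 1e-9))
  km <- two_means(matrix(lv, ncol = 1))
  exp(mean(range(km$centers)))
}

# Pre-marker gating shared by threshold fitting and tree execution: per
# branch, the live singlet sets plus bookkeeping counts.
gate_trunk <- function(sample, panel, config) {
  gates <- panel$gates
  has_branches <- any(vapply(gates, function(g) !is.null(g$branch),
                             logical(1)))
  main <- main_cells_members(sample, config)
  res <- list(members = list(), down = list())
  root_id <- names(gates)[vapply(gates, function(g) is.null(g$parent),
                                 logical(1))]
  res$members[[root_id]] <- main
  res$down[[root_id]] <- main
  if (has_branches) {
    branches <- scatter_branch_members(sample, main, config)
    for (g in gates) {
      if (!is.null(g$branch)) {
        res$members[[g$id]] <- branches[[g$branch]]
        res$down[[g$id]] <- branches[[g$branch]]
      }
    }
  }
  res
}

# Branch label of a gate (label of the nearest branch-tagged ancestor).
gate_branch <- function(panel, gid) {
  cur <- gid
  while (!is.null(cur)) {
    g <- panel$gates[[cur]]
    if (!is.null(g$branch)) return(g$branch)
    cur <- g$parent
  }
  NULL
}

#' Fit isotype-referenced marker thresholds
#'
#' The isotype control is first taken through the scatter, singlet and
#' live/dead gates (per branch for the two-branch panel); every marker
#' threshold is then the given quantile of the isotype background on that
#' gate's channel among the resulting live singlets. Activation-marker
#' channels get thresholds the same way (keyed `"act:<detector>"`), shared
#' with any tree gate on the same channel.
#'
#' The isotype sample must come from the same culture condition as the
#' samples it will gate; the pipeline enforces that pairing.
#'
#' @param isotype Compensated isotype [event_matrix()].
#' @param panel A `panel_definition`.
#' @param quantile Isotype quantile (default 0.995).
#' @param config A [gating_config()].
#' @return A `threshold_set`: numeric thresholds keyed by gate id plus
#'   `"act:<detector>"`, with provenance attributes.
#' @export
fit_isotype_thresholds <- function(isotype, panel,
                                   quantile = 0.995,
                                   config = gating_config()) {
  trunk <- gate_trunk(isotype, panel, config)
  gates <- panel$gates
  # live singlets per branch
  live_of_branch <- function(branch) {
    for (g in gates) {
      if (g$kind != "viability-exclusion") next
      if (!identical(gate_branch(panel, g$id), branch) &&
          !is.null(branch)) next
      # walk trunk: parent chain root/branch -> singlet -> viability
      par <- gates[[g$parent]]
      stopifnot(par$kind == "singlet")
      base <- trunk$down[[par$parent]]
      sing <- singlet_members(isotype, base, config)
      thr <- viability_threshold(
        isotype$fluorescence[sing, g$channels[1]])
      return(sing & isotype$fluorescence[, g$channels[1]] <= thr)
    }
    stopf("no viability gate found for branch '%s'", branch %||% "<none>")
  }
  branches <- unique(unlist(lapply(names(gates), function(id)
    gate_branch(panel, id)))) %||% list(NULL)
  if (length(branches) == 0) branches <- list(NULL)
  live_sets <- lapply(branches, live_of_branch)
  names(live_sets) <- vapply(branches, function(b) b %||% ".all",
                             character(1))

  thr <- list()
  for (g in gates) {
    if (!g$kind %in% c("threshold-positive", "threshold-negative",
                       "threshold-low")) next
    br <- gate_branch(panel, g$id) %||% ".all"
    live <- live_sets[[br]]
    if (!any(live))
      stopf("parent population empty in isotype sample for gate '%s'", g$id)
    thr[[g$id]] <- stats::quantile(isotype$fluorescence[live, g$channels[1]],
                                   quantile, names = FALSE, type = 7)
  }
  live_all <- Reduce(`|`, live_sets)
  for (m in panel$activation_markers) {
    det <- marker_detector(panel, m)
    thr[[paste0("act:", det)]] <-
      stats::quantile(isotype$fluorescence[live_all, det], quantile,
                      names = FALSE, type = 7)
  }
  structure(unlist(thr), class = "threshold_set",
            isotype_id = isotype$metadata$sample_id, quantile = quantile)
}

#' Export a threshold set (with the gate tree it covers) as JSON
#'
#' @param thresholds A `threshold_set`.
#' @param panel The `panel_definition` the thresholds belong to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_thresholds_json <- function(thresholds, panel, path) {
  doc <- list(panel_id = panel$panel_id,
              isotype_id = attr(thresholds, "isotype_id"),
              quantile = attr(thresholds, "quantile"),
              thresholds = as.list(thresholds),
              gates = lapply(unname(panel$gates), function(g)
                list(id = g$id, parent = g$parent, kind = g$kind,
                     channels = as.list(g$channels))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' Quadrant percentages of two activation markers
#'
#' Partitions events into (-/-), (+/-), (-/+), (+/+) by comparing each event
#' to the two thresholds; positivity is strictly greater-than, consistent
#' with every other gate in the package.
#'
#' @param values_a,values_b Equal-length intensity vectors for the two
#'   markers.
#' @param thr_a,thr_b The two thresholds.
#' @return Named numeric vector `c(nn, pn, np, pp)` of percentages summing
#'   to 100; `pn` is positive on `a` only.
#' @export
quadrant_stats <- function(values_a, values_b, thr_a, thr_b) {
  if (length(values_a) != length(values_b))
    stopf("values_a and values_b must have equal length")
  if (length(values_a) == 0) stopf("empty input to quadrant_stats")
  pa <- values_a > thr_a
  pb <- values_b > thr_b
  n <- length(values_a)
  100 * c(nn = sum(!pa & !pb), pn = sum(pa & !pb),
          np = sum(!pa & pb), pp = sum(pa & pb)) / n
}

#' Execute a panel's gate tree on a compensated sample
#'
#' Events are assigned top-down. Inclusive gates pass their members to their
#' children; the live/dead gate is exclusive — its members (dead cells) are
#' removed from all downstream gating. Populations are read off their gate
#' paths; populations flagged with activation markers additionally get
#' quadrant percentages and per-marker gMFIs.
#'
#' @param sample Compensated [event_matrix()].
#' @param panel A `panel_definition`.
#' @param thresholds A `threshold_set` from [fit_isotype_thresholds()] (or
#'   fixed values with the same keys).
#' @param config A [gating_config()].
#' @param quadrant_gmfi If `TRUE`, gMFIs are restricted to marker-positive
#'   events instead of the whole population.
#' @return A `gate_stats` object: per-population counts, percent-of-parent
#'   and percent-of-live (empty parents reported as 0 with a flag), per-gate
#'   in/out counts, and activation quadrants + gMFIs.
#' @export
apply_gate_tree <- function(sample, panel, thresholds,
                            config = gating_config(),
                            quadrant_gmfi = FALSE) {
  gates <- panel$gates
  dets <- colnames(sample$fluorescence)
  trunk <- gate_trunk(sample, panel, config)
  members <- trunk$members   # events selected by each gate
  down <- trunk$down         # events available to each gate's children
  n <- n_events_of(sample)

  # order gates so parents are processed first
  ordered <- character()
  remaining <- names(gates)
  while (length(remaining) > 0) {
    ready <- vapply(remaining, function(id) {
      p <- gates[[id]]$parent
      is.null(p) || p %in% ordered
    }, logical(1))
    if (!any(ready)) stopf("gate tree is not a forest rooted at the root")
    ordered <- c(ordered, remaining[ready])
    remaining <- remaining[!ready]
  }

  viability_cuts <- list()
  for (id in ordered) {
    g <- gates[[id]]
    if (!is.null(members[[id]])) next  # root / branch scatter, precomputed
    parent_down <- down[[g$parent]]
    sel <- switch(g$kind,
      "singlet" = singlet_members(sample, parent_down, config),
      "viability-exclusion" = {
        vals <- sample$fluorescence[, g$channels[1]]
        cut <- viability_threshold(vals[parent_down])
        viability_cuts[[id]] <- cut
        parent_down & vals > cut  # members = dead cells
      },
      "threshold-positive" = ,
      "threshold-negative" = ,
      "threshold-low" = {
        if (!g$channels[1] %in% dets)
          stopf("unknown channel '%s' in gate '%s'", g$channels[1], id)
        if (!id %in% names(thresholds))
          stopf("missing threshold for gate '%s'", id)
        vals <- sample$fluorescence[, g$channels[1]]
        if (g$kind == "threshold-positive")
          parent_down & vals > thresholds[[id]]
        else
          parent_down & vals <= thresholds[[id]]
      },
      stopf("unsupported gate kind '%s'", g$kind))
    members[[id]] <- sel
    down[[id]] <- if (g$polarity == "exclusive") parent_down & !sel else sel
  }

  viab_ids <- names(gates)[vapply(gates, function(g)
    g$kind == "viability-exclusion", logical(1))]
  live <- Reduce(`|`, lapply(viab_ids, function(id) down[[id]]))
  n_live <- sum(live)

  pops <- do.call(rbind, lapply(panel$populations, function(p) {
    last <- p$path[length(p$path)]
    parent_gate <- p$path[length(p$path) - 1]
    count <- sum(down[[last]])
    parent_count <- sum(down[[parent_gate]])
    empty_parent <- parent_count == 0
    data.frame(population = p$name, count = count,
               parent_count = parent_count,
               pct_of_parent = if (empty_parent) 0 else
                 100 * count / parent_count,
               pct_of_live = if (n_live == 0) 0 else 100 * count / n_live,
               empty_parent = empty_parent)
  }))
  rownames(pops) <- NULL

  act <- NULL
  flagged <- Filter(function(p) length(p$activation_markers) == 2,
                    panel$populations)
  if (length(flagged) > 0) {
    act <- do.call(rbind, lapply(flagged, function(p) {
      ma <- p$activation_markers[1]
      mb <- p$activation_markers[2]
      da <- marker_detector(panel, ma)
      db <- marker_detector(panel, mb)
      ka <- paste0("act:", da)
      kb <- paste0("act:", db)
      if (!all(c(ka, kb) %in% names(thresholds)))
        stopf("missing activation threshold for '%s' or '%s'", ma, mb)
      ev <- down[[p$path[length(p$path)]]]
      if (!any(ev)) {
        data.frame(population = p$name, marker_a = ma, marker_b = mb,
                   pct_nn = 0, pct_pn = 0, pct_np = 0, pct_pp = 0,
                   gmfi_a = NA_real_, gmfi_b = NA_real_, empty = TRUE)
      } else {
        va <- sample$fluorescence[ev, da]
        vb <- sample$fluorescence[ev, db]
        q <- quadrant_stats(va, vb, thresholds[[ka]], thresholds[[kb]])
        ga <- if (quadrant_gmfi) va[va > thresholds[[ka]]] else va
        gb <- if (quadrant_gmfi) vb[vb > thresholds[[kb]]] else vb
        data.frame(population = p$name, marker_a = ma, marker_b = mb,
                   pct_nn = q[["nn"]], pct_pn = q[["pn"]],
                   pct_np = q[["np"]], pct_pp = q[["pp"]],
                   gmfi_a = if (length(ga)) gmfi(ga) else NA_real_,
                   gmfi_b = if (length(gb)) gmfi(gb) else NA_real_,
                   empty = FALSE)
      }
    }))
    rownames(act) <- NULL
  }

  gate_counts <- data.frame(
    gate = ordered,
    available = vapply(ordered, function(id) {
      p <- gates[[id]]$parent
      if (is.null(p)) n else sum(down[[p]])
    }, numeric(1)),
    selected = vapply(ordered, function(id) sum(members[[id]]), numeric(1)),
    row.names = NULL)

  structure(list(sample_id = sample$metadata$sample_id,
                 metadata = sample$metadata,
                 n_events = n, n_live = n_live,
                 populations = pops, activation = act,
                 gate_counts = gate_counts,
                 viability_cuts = viability_cuts,
                 membership = down),
            class = "gate_stats")
}

#' @export
print.gate_stats <- function(x, ...) {
  cat(sprintf("<gate_stats> %s: %d events, %d live\n",
              x$sample_id, x$n_events, x$n_live))
  print(x$populations[, c("population", "count", "pct_of_parent",
                          "pct_of_live")], digits = 4)
  invisible(x)
}

#' Tidy per-population table of one or more gate_stats
#'
#' @param stats A `gate_stats` or list of them.
#' @return Tidy data frame with one row per sample x population, including
#'   quadrant and gMFI columns where available.
#' @export
gate_stats_table <- function(stats) {
  if (inherits(stats, "gate_stats")) stats <- list(stats)
  res <- do.call(rbind, lapply(stats, function(gs) {
    d <- cbind(sample_id = gs$sample_id, gs$populations)
    if (!is.null(gs$activation)) {
      d <- merge(d, gs$activation, by = "population", all.x = TRUE,
                 sort = FALSE)
    }
    d
  }))
  rownames(res) <- NULL
  res
}
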