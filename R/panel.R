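# Declarative panel model: reagent channels, hierarchical gate tree, and
# population definitions for the two built-in PBMC immunophenotyping panels.

GATE_KINDS <- c("scatter-region", "singlet", "viability-exclusion",
                "threshold-positive", "threshold-negative", "threshold-low",
                "quadrant")

#' Define a panel channel
#'
#' A channel couples an antigen (or dye) to a fluorophore and to the detector
#' it is read on. Detector ids follow the `"Marker-Fluorophore"` convention
#' (e.g. `"CD3-BV570"`) used for all fluorescence column headers, which keeps
#' the join between reagent tables and population definitions unambiguous.
#'
#' @param marker Antigen or dye name, e.g. `"CD3"` or `"Viability"`.
#' @param fluorophore Conjugate label, e.g. `"BV570"` or `"ZombieAqua"`.
#' @param detector Instrument channel id; defaults to `"marker-fluorophore"`.
#' @return A `channel_def` list with fields `marker`, `fluorophore`,
#'   `detector`.
#' @export
channel_def <- function(marker, fluorophore,
                        detector = paste(marker, fluorophore, sep = "-")) {
  structure(list(marker = as.character(marker),
                 fluorophore = as.character(fluorophore),
                 detector = as.character(detector)),
            class = "channel_def")
}

#' Define a node of a hierarchical gate tree
#'
#' @param id Unique gate id within the tree.
#' @param parent Parent gate id, or `NULL` for the root.
#' @param kind One of `"scatter-region"`, `"singlet"`,
#'   `"viability-exclusion"`, `"threshold-positive"`, `"threshold-negative"`,
#'   `"threshold-low"`, `"quadrant"`.
#' @param channels Character vector of 1-2 detector/scatter channel names the
#'   gate reads.
#' @param threshold_source `"isotype-quantile"` for marker thresholds set from
#'   condition-matched isotype controls, `"fixed-value"` for user-supplied
#'   cutoffs, `"auto"` for data-driven scatter/singlet/viability gates.
#' @param polarity `"inclusive"` (members continue downstream) or
#'   `"exclusive"` (members are removed from downstream gating; used by the
#'   live/dead gate).
#' @param branch Optional branch label (used by the monocyte/lymphocyte
#'   scatter split of panel 2).
#' @return A `gate_node` list.
#' @export
gate_node <- function(id, parent = NULL, kind, channels,
                      threshold_source = "isotype-quantile",
                      polarity = "inclusive", branch = NULL) {
  kind <- match.arg(kind, GATE_KINDS)
  structure(list(id = as.character(id),
                 parent = if (is.null(parent)) NULL else as.character(parent),
                 kind = kind,
                 channels = as.character(channels),
                 threshold_source = threshold_source,
                 polarity = match.arg(polarity, c("inclusive", "exclusive")),
                 branch = branch),
            class = "gate_node")
}

#' Define a cell population as a root-connected gate path
#'
#' @param name Population label, e.g. `"Regulatory T cells"`.
#' @param path Ordered character vector of gate ids from the root.
#' @param activation_markers Zero to two marker names whose activation
#'   quadrants and gMFIs are reported for this population.
#' @return A `population_rule` list.
#' @export
population_rule <- function(name, path, activation_markers = character()) {
  structure(list(name = as.character(name),
                 path = as.character(path),
                 activation_markers = as.character(activation_markers)),
            class = "population_rule")
}

#' Assemble a panel definition
#'
#' @param panel_id Integer panel number.
#' @param channels List of [channel_def()] objects.
#' @param gates List of [gate_node()] objects forming a single-rooted tree.
#' @param populations List of [population_rule()] objects.
#' @param name Free-text panel name.
#' @param activation_markers The panel's two activation markers.
#' @return A `panel_definition` object.
#' @seealso [build_panel1()], [build_panel2()], [validate_panel()],
#'   [read_panel()]
#' @export
panel_definition <- function(panel_id, channels, gates, populations,
                             name = paste("Panel", panel_id),
                             activation_markers = character()) {
  gates <- stats::setNames(gates, vapply(gates, `[[`, character(1), "id"))
  structure(list(panel_id = as.integer(panel_id),
                 name = name,
                 channels = channels,
                 gates = gates,
                 populations = populations,
                 activation_markers = as.character(activation_markers)),
            class = "panel_definition")
}

#' @export
print.panel_definition <- function(x, ...) {
  cat(sprintf("<panel_definition> #%d: %s\n", x$panel_id, x$name))
  cat(sprintf("  %d channels, %d gates, %d populations\n",
              length(x$channels), length(x$gates), length(x$populations)))
  act <- vapply(x$populations, function(p) length(p$activation_markers) > 0,
                logical(1))
  cat(sprintf("  activation markers [%s] on: %s\n",
              paste(x$activation_markers, collapse = ", "),
              paste(vapply(x$populations[act], `[[`, character(1), "name"),
                    collapse = ", ")))
  invisible(x)
}

#' Fluorescence detector ids of a panel
#'
#' @param panel A `panel_definition`.
#' @return Character vector of detector ids in panel order.
#' @export
panel_detectors <- function(panel) {
  vapply(panel$channels, `[[`, character(1), "detector")
}

# Detector id carrying a given marker, or error.
marker_detector <- function(panel, marker) {
  for (ch in panel$channels) if (ch$marker == marker) return(ch$detector)
  stopf("marker '%s' is not in panel %d", marker, panel$panel_id)
}

viability_detector <- function(panel) marker_detector(panel, "Viability")

#' Load a panel from its declarative JSON schema
#'
#' Panels are described by a JSON document listing `channels` (marker +
#' fluorophore), `gates` (the tree) and `populations` (gate paths). The two
#' built-in panels ship as schema files under `inst/extdata/` and are loaded
#' through this same reader, so user-defined panels are first-class.
#'
#' @param path Path to a panel schema JSON file.
#' @return A validated `panel_definition`.
#' @export
read_panel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  channels <- lapply(doc$channels, function(ch) {
    channel_def(ch$marker, ch$fluorophore,
                detector = ch$detector %||%
                  paste(ch$marker, ch$fluorophore, sep = "-"))
  })
  gates <- lapply(doc$gates, function(g) {
    gate_node(g$id, parent = g$parent, kind = g$kind,
              channels = unlist(g$channels),
              threshold_source = g$threshold_source %||% "isotype-quantile",
              polarity = g$polarity %||% "inclusive",
              branch = g$branch)
  })
  pops <- lapply(doc$populations, function(p) {
    population_rule(p$name, unlist(p$path),
                    activation_markers = unlist(p$activation_markers) %||%
                      character())
  })
  panel <- panel_definition(doc$panel_id, channels, gates, pops,
                            name = doc$name %||% paste("Panel", doc$panel_id),
                            activation_markers =
                              unlist(doc$activation_markers) %||% character())
  diags <- validate_panel(panel)
  if (length(diags) > 0) {
    stopf("panel schema '%s' failed validation:\n%s", path,
          paste(" -", unlist(diags), collapse = "\n"))
  }
  panel
}

#' Write a panel definition back to its JSON schema
#'
#' @param panel A `panel_definition`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  doc <- list(
    panel_id = panel$panel_id,
    name = panel$name,
    activation_markers = panel$activation_markers,
    channels = lapply(panel$channels, function(ch)
      list(marker = ch$marker, fluorophore = ch$fluorophore,
           detector = ch$detector)),
    gates = lapply(unname(panel$gates), function(g)
      list(id = g$id, parent = g$parent, kind = g$kind,
           channels = as.list(g$channels),
           threshold_source = g$threshold_source, polarity = g$polarity,
           branch = g$branch)),
    populations = lapply(panel$populations, function(p)
      list(name = p$name, path = as.list(p$path),
           activation_markers = as.list(p$activation_markers)))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Built-in immunophenotyping panel 1 (lymphocyte panel)
#'
#' Twelve channels (eleven antibodies plus the amine-reactive viability dye)
#' resolving B cells, total/cytotoxic/naive-cytotoxic/CD4/regulatory T cells
#' and gamma-delta T cells, with CD25 (proliferation) and CD154
#' (co-stimulation) activation read-outs on B, cytotoxic T and CD4 T cells.
#' The trunk of the gate tree is main-cells scatter, singlet, then an
#' exclusive live/dead gate; CD127-low is modelled as a below-threshold
#' ("lo") gate rather than a negative gate.
#'
#' @return A validated `panel_definition`.
#' @export
build_panel1 <- function() {
  read_panel(system.file("extdata", "panel1.json", package = "immunogate",
                         mustWork = TRUE))
}

#' Built-in immunophenotyping panel 2 (monocyte / DC / NK panel)
#'
#' Eleven channels resolving CD14+ monocytes (on a monocyte scatter branch)
#' and pDC, mDC, NK and NKT cells (on a lymphocyte scatter branch), with CD54
#' (adhesion) and CD69 (early activation) read-outs on monocytes, pDC, mDC
#' and NK cells. The two scatter branches sit under a shared debris-excluding
#' root and each carries its own singlet and live/dead gate.
#'
#' @return A validated `panel_definition`.
#' @export
build_panel2 <- function() {
  read_panel(system.file("extdata", "panel2.json", package = "immunogate",
                         mustWork = TRUE))
}

#' Validate a panel definition
#'
#' Checks every structural invariant of the panel model: unique channels and
#' detectors, a single-rooted acyclic gate tree, gate channels resolving to
#' panel detectors (or scatter channels), exactly one live/dead exclusion
#' gate on every root-to-leaf path, root-connected population paths, and
#' activation markers present among the panel's channels.
#'
#' @param panel A `panel_definition`.
#' @return A character vector of diagnostics; empty when the panel is valid.
#'   Violations never raise errors here, so a panel under construction can be
#'   inspected incrementally.
#' @export
validate_panel <- function(panel) {
  diags <- character()
  say <- function(fmt, ...) diags[[length(diags) + 1L]] <<- sprintf(fmt, ...)

  mk <- vapply(panel$channels, function(ch)
    paste(ch$marker, ch$fluorophore), character(1))
  if (anyDuplicated(mk))
    say("duplicated (marker, fluorophore) pair: %s", mk[duplicated(mk)][1])
  dets <- panel_detectors(panel)
  if (anyDuplicated(dets))
    say("duplicated detector id: %s", dets[duplicated(dets)][1])

  ids <- names(panel$gates)
  if (anyDuplicated(ids)) say("duplicated gate id: %s", ids[duplicated(ids)][1])
  roots <- ids[vapply(panel$gates, function(g) is.null(g$parent), logical(1))]
  if (length(roots) != 1)
    say("gate tree must have exactly one root, found %d (%s)",
        length(roots), paste(roots, collapse = ", "))
  for (g in panel$gates) {
    if (!is.null(g$parent) && !g$parent %in% ids)
      say("gate '%s' references unknown parent '%s'", g$id, g$parent)
    if (g$kind == "quadrant" && length(g$channels) != 2)
      say("quadrant gate '%s' must reference exactly 2 channels", g$id)
    scatter_ok <- c("FSC-A", "FSC-H", "SSC-A")
    for (ch in g$channels) {
      if (!ch %in% c(dets, scatter_ok))
        say("gate '%s' references channel '%s' absent from the panel",
            g$id, ch)
    }
  }
  # cycle check by walking to the root from every node
  for (g in panel$gates) {
    seen <- character()
    cur <- g$id
    while (!is.null(cur)) {
      if (cur %in% seen) {
        say("gate tree contains a cycle through: %s",
            paste(c(seen, cur), collapse = " -> "))
        break
      }
      seen <- c(seen, cur)
      nxt <- panel$gates[[cur]]
      cur <- if (is.null(nxt)) NULL else nxt$parent
    }
  }
  # exactly one viability-exclusion gate on each root-to-leaf path
  children <- split(ids, vapply(panel$gates, function(g)
    g$parent %||% NA_character_, character(1)))
  leaves <- ids[!ids %in% unlist(lapply(panel$gates, function(g) g$parent))]
  if (length(roots) == 1) {
    for (leaf in leaves) {
      n_viab <- 0
      cur <- leaf
      guard <- 0
      while (!is.null(cur) && guard < length(ids) + 1) {
        g <- panel$gates[[cur]]
        if (is.null(g)) break  # dangling parent: already reported above
        if (g$kind == "viability-exclusion") n_viab <- n_viab + 1
        cur <- g$parent
        guard <- guard + 1
      }
      if (n_viab != 1)
        say("path to leaf '%s' crosses %d viability-exclusion gates (need 1)",
            leaf, n_viab)
    }
  }

  markers <- vapply(panel$channels, `[[`, character(1), "marker")
  for (p in panel$populations) {
    for (gid in p$path) if (!gid %in% ids)
      say("population '%s' references unknown gate '%s'", p$name, gid)
    if (all(p$path %in% ids)) {
      # path must be root-connected and consecutive parent links
      if (!is.null(panel$gates[[p$path[1]]]$parent))
        say("population '%s' path does not start at the root", p$name)
      if (length(p$path) > 1) {
        for (k in seq(2, length(p$path))) {
          par <- panel$gates[[p$path[k]]]$parent
          if (is.null(par) || par != p$path[k - 1])
            say("population '%s' path broken at '%s' (parent is '%s')",
                p$name, p$path[k], par %||% "<root>")
        }
      }
    }
    for (m in p$activation_markers) if (!m %in% markers)
      say("population '%s' activation marker '%s' absent from channels",
          p$name, m)
    if (length(p$activation_markers) > 0 &&
        !setequal(p$activation_markers, panel$activation_markers))
      say("population '%s' must carry the panel activation markers (%s)",
          p$name, paste(panel$activation_markers, collapse = ", "))
  }
  diags
}
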