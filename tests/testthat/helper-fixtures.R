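# Shared fixtures, built once per test run and cached in-process so the
# suite stays fast. Everything is generated in code; nothing binary ships.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

panel1 <- function() fixture("panel1", build_panel1)
panel2 <- function() fixture("panel2", build_panel2)

# Small stained + isotype pair for gating tests (20k events, no spillover).
gated_pair1 <- function() {
  fixture("gated_pair1", function() {
    spec <- synthetic_spec(panel_id = 1, n_events = 20000, seed = 42)
    s <- simulate_sample(spec, panel1(), "D1", "unstimulated")
    iso <- simulate_sample(spec, panel1(), "D1", "unstimulated",
                           stain_type = "isotype")
    thr <- fit_isotype_thresholds(iso, panel1())
    list(spec = spec, sample = s, isotype = iso, thresholds = thr,
         stats = apply_gate_tree(s, panel1(), thr))
  })
}

gated_pair2 <- function() {
  fixture("gated_pair2", function() {
    spec <- synthetic_spec(panel_id = 2, n_events = 20000, seed = 43)
    s <- simulate_sample(spec, panel2(), "D1", "unstimulated")
    iso <- simulate_sample(spec, panel2(), "D1", "unstimulated",
                           stain_type = "isotype")
    thr <- fit_isotype_thresholds(iso, panel2())
    list(spec = spec, sample = s, isotype = iso, thresholds = thr,
         stats = apply_gate_tree(s, panel2(), thr))
  })
}

# Spillover matrix with a planted FITC -> PE coefficient of 0.15.
planted_spillover <- function(panel) {
  dets <- panel_detectors(panel)
  S <- diag(length(dets))
  dimnames(S) <- list(dets, dets)
  fitc <- dets[grepl("-FITC$", dets)][1]
  pe <- dets[grepl("-PE$", dets)][1]
  S[fitc, pe] <- 0.15
  S[pe, fitc] <- 0.05
  S[dets[3], dets[4]] <- 0.08
  spillover_matrix(S, dets)
}
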