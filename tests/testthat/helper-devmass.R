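# shared fixtures for the test suite; everything is generated in code

# a synthetic change-detector envelope with controllable level change and
# edge transients, shaped like the canonical On/Off exemplars: baseline 1,
# stimulus on [0, 2] s, analysis span [-0.5, 4] s
make_envelope <- function(inc = TRUE, on = FALSE, off = FALSE,
                          dt = 0.005) {
  t <- seq(-0.5, 4, by = dt)
  base <- 1
  # level change below the 0.5 spikes/s edge thresholds, so the level
  # shift itself never counts as an onset or offset transient
  during <- if (inc) base + 0.4 else base - 0.4
  v <- rep(base, length(t))
  v[t > 0 & t < 2] <- during
  bump <- function(v, center) {
    sel <- abs(t - center) < 0.1
    v[sel] <- pmax(v[sel], during + 1.5 * exp(-((t[sel] - center) / 0.03)^2))
    v
  }
  if (on) v <- bump(v, 0.15)
  if (off) v <- bump(v, 2.15)
  list(time = t, trace = v)
}

# all eight On/Off exemplar envelopes, named by their expected label
eight_envelopes <- function() {
  combos <- expand.grid(inc = c(TRUE, FALSE), on = c(FALSE, TRUE),
                        off = c(FALSE, TRUE))
  out <- list()
  for (i in seq_len(nrow(combos))) {
    cc <- combos[i, ]
    edge <- paste0(if (cc$on) "On" else "", if (cc$off) "Off" else "")
    if (edge == "") edge <- "None"
    lbl <- paste(if (cc$inc) "Inc" else "Dec", edge, sep = "-")
    out[[lbl]] <- make_envelope(cc$inc, cc$on, cc$off)
  }
  out
}

# deterministic subsample of the weight grid shared by the acceptance
# blocks; scans are computed once on first use
acceptance_cache <- new.env(parent = emptyenv())

grid_subsample <- function(n = 4000, seed = 20240901) {
  g <- devmass::enumerate_grid()
  set.seed(seed)
  g[sample(nrow(g), n), , drop = FALSE]
}

get_condition_scan <- function(cond, n = 4000) {
  key <- paste0("scan_", cond)
  if (is.null(acceptance_cache[[key]])) {
    if (is.null(acceptance_cache$grid))
      acceptance_cache$grid <- grid_subsample(n)
    acceptance_cache[[key]] <- devmass::run_scan(acceptance_cache$grid, cond)
  }
  acceptance_cache[[key]]
}
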