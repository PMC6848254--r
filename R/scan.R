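#' Enumerate the inter-node weight grid
#'
#' Cartesian grid over the eight free inter-node gains of the two-node
#' change-detector network.  E-to-E and E-to-I gains take values
#' `135 * {0, 0.1, ..., 0.5}`, I-to-E and I-to-I gains
#' `135 * {0, 0.1, 0.2}`; with both coupling directions free this yields
#' `6^4 * 3^4 = 104976` points.  Order is deterministic lexicographic (the
#' last column varies fastest); the first point is the all-zero vector.
#'
#' @param dims `"8d"` (both directions scanned, the default) or `"4d"`
#'   (only the node-1-to-node-2 direction scanned, reverse fixed at zero).
#' @return A numeric matrix with one row per grid point and columns
#'   `w21_EE, w21_IE, w21_EI, w21_II, w12_EE, w12_IE, w12_EI, w12_II`
#'   (absolute gains; `w21` couples node 1 onto the detector node 2).
#' @export
enumerate_grid <- function(dims = c("8d", "4d")) {
  dims <- match.arg(dims)
  ee <- .gain_scale * seq(0, 0.5, by = 0.1)
  ii <- .gain_scale * c(0, 0.1, 0.2)
  vals <- list(w21_EE = ee, w21_IE = ee, w21_EI = ii, w21_II = ii,
               w12_EE = ee, w12_IE = ee, w12_EI = ii, w12_II = ii)
  if (dims == "4d") vals[5:8] <- list(0, 0, 0, 0)
  g <- expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE)[, 8:1]
  as.matrix(g)
}

#' Pharmacological / plasticity scan conditions
#'
#' Transforms applied to the two-node network before a scan:
#' * `I` - default (identity);
#' * `II` - no external input to inhibitory populations (`W_IX = 0`);
#' * `III` - NMDA-antagonist emulation: the inter-node E-to-E gains reduced
#'   by 25% and the inter-node E-to-I gains by 50% (the intra-node gains are
#'   left untouched: reducing them saturates an isolated node at the
#'   standard background drive, abolishing all responses);
#' * `IV` - synaptic adaptation enabled on all E-to-E connections
#'   (`tau_a = 200` ms, `kappa = 2`).
#'
#' @param label one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @return A list describing the condition: multiplicative factors for the
#'   E-to-E / E-to-I gains, the `W_IX` override, and the adaptation setting.
#' @export
scan_condition <- function(label = c("I", "II", "III", "IV")) {
  label <- match.arg(label)
  cond <- list(label = label, f_EE = 1, f_IE = 1, zero_WIX = FALSE,
               adaptation = NULL)
  if (label == "II") cond$zero_WIX <- TRUE
  if (label == "III") { cond$f_EE <- 0.75; cond$f_IE <- 0.5 }
  if (label == "IV") cond$adaptation <- adaptation_params()
  cond
}

#' Apply a scan condition to a network configuration
#'
#' The weight-reduction factors of condition III act on the inter-node
#' (off-diagonal) gains only.
#'
#' @param config a [network_config()].
#' @param condition a [scan_condition()] or its label.
#' @return A list with the transformed `config` and the `adaptation`
#'   parameters to pass to [simulate_network()] (or `NULL`).
#' @export
apply_condition <- function(config, condition = "I") {
  if (is.character(condition)) condition <- scan_condition(condition)
  off <- 1 - diag(config$N)
  config$W_EE <- config$W_EE * (1 + off * (condition$f_EE - 1))
  config$W_IE <- config$W_IE * (1 + off * (condition$f_IE - 1))
  if (condition$zero_WIX) config$W_IX <- config$W_IX * 0
  list(config = config, adaptation = condition$adaptation)
}

# window sample-index bounds (0-based, strict interior) for the scan kernel
window_index_bounds <- function(windows, t0, dt) {
  t(vapply(windows, function(w)
    c(as.integer(round((w[1] - t0) / dt)) + 1L,
      as.integer(round((w[2] - t0) / dt)) - 1L), integer(2)))
}

#' Scan inter-node weight settings and classify the detector response
#'
#' For every row of `grid`, integrates the two-node network (node 1 driven
#' by a prolonged 2000-ms step stimulus, settle period discarded) under the
#' requested condition and categorizes the detector trace `m_2^E` into one
#' of the nine response types from its analysis-window maxima.  The grid
#' points are integrated in a batched compiled kernel; per-point results are
#' identical to individual [simulate_network()] runs.  Integration failures
#' are recorded as `"others"` and counted.
#'
#' @param grid matrix from [enumerate_grid()] (or any subset of rows).
#' @param condition a condition label or [scan_condition()] object.
#' @param dt solver step (seconds).
#' @param settle discarded equilibration interval (seconds).
#' @param stim_amplitude stimulus plateau (spikes/s).
#' @param thresholds a [response_thresholds()] object.
#' @return An object of class `"scan_result"`: list with `grid`, `labels`
#'   (factor over [response_types()]), `metrics` (four columns), `maxima`
#'   (five columns), `condition`, `n_diverged`.
#' @export
run_scan <- function(grid, condition = "I", dt = 5e-4, settle = 2,
                     stim_amplitude = 1.5,
                     thresholds = response_thresholds()) {
  if (is.character(condition)) condition <- scan_condition(condition)
  grid <- as.matrix(grid)
  stopifnot(ncol(grid) == 8)
  g <- .gain_scale * .intra_ratio
  wEE <- g[["EE"]]; wIE <- g[["IE"]]
  wEI <- g[["EI"]]; wII <- g[["II"]]
  grid_eff <- grid
  grid_eff[, c(1, 5)] <- grid_eff[, c(1, 5)] * condition$f_EE
  grid_eff[, c(2, 6)] <- grid_eff[, c(2, 6)] * condition$f_IE
  wEX1 <- 220 * 0.2
  wIX1 <- if (condition$zero_WIX) 0 else 220 * 0.1

  t0 <- -0.5; t1 <- 4
  n_settle <- as.integer(round(settle / dt))
  n_out <- as.integer(round((t1 - t0) / dt))
  half_times <- (t0 - settle) + (0:(2 * (n_settle + n_out))) * (dt / 2)
  x <- as.vector(sample_stimuli(step_stimulus(0, 2, stim_amplitude), half_times))
  windows <- response_windows()
  win <- window_index_bounds(windows, t0, dt)
  adapt <- !is.null(condition$adaptation)
  raw <- scan_twonode_cpp(grid_eff, wEE, wIE, wEI, wII, wEX1, wIX1, 220 * 2.5,
                          3.25, 0.010, 22, 0.020, 2.5, 0.56, 6,
                          x, dt, n_settle, n_out, win,
                          adapt,
                          if (adapt) condition$adaptation$tau_a else 1,
                          if (adapt) condition$adaptation$kappa else 0)
  mx <- raw$maxima
  colnames(mx) <- names(windows)
  metrics <- cbind(dm_prepost = abs(mx[, 1] - mx[, 5]),
                   dm_stim = mx[, 3] - pmax(mx[, 1], mx[, 5]),
                   dm_on = mx[, 2] - mx[, 1],
                   dm_off = mx[, 4] - mx[, 3])
  lab <- ifelse(metrics[, "dm_stim"] > thresholds$theta_stim, "Inc", "Dec")
  edge <- paste0(ifelse(metrics[, "dm_on"] > thresholds$theta_on, "On", ""),
                 ifelse(metrics[, "dm_off"] > thresholds$theta_off, "Off", ""))
  edge[edge == ""] <- "None"
  labels <- paste(lab, edge, sep = "-")
  labels[metrics[, "dm_prepost"] >= thresholds$theta_prepost] <- "others"
  bad <- raw$diverged == 1 | apply(!is.finite(mx), 1, any)
  labels[bad] <- "others"
  structure(list(grid = grid, labels = factor(labels, response_types()),
                 metrics = metrics, maxima = mx,
                 condition = condition$label,
                 n_diverged = sum(raw$diverged)),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> condition %s, %d points (%d diverged)\n",
              x$condition, length(x$labels), x$n_diverged))
  print(round(100 * prop.table(table(x$labels)), 2))
  invisible(x)
}

#' Cross-condition contingency table of response types
#'
#' Percentages (of all scanned points) of each label pair between two
#' conditions run on the same grid; cells sum to 100 and the margins equal
#' the per-condition type proportions.
#'
#' @param labels_a,labels_b equal-length label factors/vectors over the same
#'   grid (or two `"scan_result"` objects).
#' @return A 9 x 9 matrix of percentages (rows = condition A).
#' @export
contingency <- function(labels_a, labels_b) {
  if (inherits(labels_a, "scan_result")) labels_a <- labels_a$labels
  if (inherits(labels_b, "scan_result")) labels_b <- labels_b$labels
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  labels_a <- factor(labels_a, response_types())
  labels_b <- factor(labels_b, response_types())
  100 * table(A = labels_a, B = labels_b) / length(labels_a)
}

#' Per-condition response-type proportions
#'
#' @param labels label vector/factor or `"scan_result"`.
#' @return named percentage vector over the nine types.
#' @export
type_proportions <- function(labels) {
  if (inherits(labels, "scan_result")) labels <- labels$labels
  100 * prop.table(table(factor(labels, response_types())))
}

#' Count On-type and Off-type solutions
#'
#' On types are the labels with an onset transient (`*-On`, `*-OnOff`); Off
#' types those with an offset transient (`*-Off`, `*-OnOff`).
#'
#' @param labels label vector/factor or `"scan_result"`.
#' @return named integer vector `c(On = ..., Off = ...)`.
#' @export
onoff_counts <- function(labels) {
  if (inherits(labels, "scan_result")) labels <- labels$labels
  labels <- as.character(labels)
  c(On = sum(grepl("-On$|-OnOff$", labels)),
    Off = sum(grepl("-Off$|-OnOff$", labels)))
}

#' 2-D embedding of weight-grid points
#'
#' Cosmetic neighborhood-preserving projection of selected grid points
#' (e.g. the solutions of one response type) onto a plane for
#' visualization; deterministic principal components by default, classical
#' multidimensional scaling as an alternative.
#'
#' @param points matrix of grid rows (n x 8).
#' @param method `"pca"` or `"mds"`.
#' @return An `n x 2` coordinate matrix.
#' @export
embed_2d <- function(points, method = c("pca", "mds")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty selection")
  if (nrow(points) == 1) return(matrix(0, 1, 2))
  if (method == "pca") {
    p <- stats::prcomp(points, center = TRUE, scale. = FALSE)
    k <- ncol(p$x)
    out <- cbind(p$x[, 1], if (k >= 2) p$x[, 2] else 0)
  } else {
    out <- stats::cmdscale(stats::dist(points), k = 2)
  }
  unname(out[, 1:2, drop = FALSE])
}
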