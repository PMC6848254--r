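#' Cortical On/Off response survey (two-node scan with exemplars)
#'
#' Scans inter-node weight settings of the two-node change-detector
#' network under one condition, classifies every detector trace, and
#' re-simulates one exemplar trace per realized response type.
#'
#' @param grid weight grid (rows of [enumerate_grid()]); the full grid by
#'   default.
#' @param condition condition label (see [scan_condition()]).
#' @param n_exemplar_points number of exemplar traces to keep per type.
#' @param dt,settle solver settings for the scan.
#' @return list of class `"onoff_survey"`: the `"scan_result"` (`scan`),
#'   `proportions` (percentage per type), and `exemplars` (named list of
#'   data.frames `time`/`mE` for one grid point per realized type, with the
#'   weight rows in `exemplar_weights`).
#' @export
example1_onoff <- function(grid = enumerate_grid(), condition = "I",
                           n_exemplar_points = 1, dt = 5e-4, settle = 2) {
  sc <- run_scan(grid, condition, dt = dt, settle = settle)
  labs <- as.character(sc$labels)
  exemplars <- list(); exw <- list()
  for (ty in setdiff(response_types(), "others")) {
    idx <- which(labs == ty)
    if (!length(idx)) next
    idx <- idx[seq_len(min(n_exemplar_points, length(idx)))]
    for (k in idx) {
      w <- grid[k, ]
      cond <- scan_condition(if (is.character(condition)) condition
                             else condition$label)
      cfgA <- apply_condition(two_node_config(w21 = w[1:4], w12 = w[5:8]),
                              cond)
      r <- simulate_network(cfgA$config, step_stimulus(0, 2),
                            t_span = c(-0.5, 4), dt = dt, settle = settle,
                            adaptation = cfgA$adaptation)
      exemplars[[ty]] <- data.frame(time = r$time, mE = r$mE[, 2])
      exw[[ty]] <- w
    }
  }
  structure(list(scan = sc, proportions = type_proportions(sc),
                 exemplars = exemplars, exemplar_weights = exw,
                 condition = sc$condition),
            class = "onoff_survey")
}

#' @export
print.onoff_survey <- function(x, ...) {
  cat(sprintf("<onoff_survey> condition %s, %d points\n", x$condition,
              length(x$scan$labels)))
  print(round(x$proportions, 2))
  cat("exemplars:", paste(names(x$exemplars), collapse = ", "), "\n")
  invisible(x)
}

#' Default tone-to-input-ratio table for the receptive-field example
#'
#' Each simulated tone reaches the two nodes with strengths scaled by
#' `ratio1` (node 1, the surround) and `ratio2` (node 2, the recorded
#' cell); the profiles emulate a tonotopic gradient in which low tones
#' drive the surround strongly and high tones drive it weakly, with the
#' recorded cell's direct input peaked at mid-to-high tones.
#'
#' @param n_tones number of simulated tone frequencies.
#' @return data.frame with columns `tone`, `ratio1`, `ratio2`.
#' @export
frf_ratio_table <- function(n_tones = 13) {
  tone <- seq_len(n_tones)
  x <- (tone - 1) / (n_tones - 1)
  ratio1 <- round(pmax(0, 1 - x^1.5), 3)
  ratio2 <- round(0.35 * exp(-((x - 0.75) / 0.25)^2), 3)
  data.frame(tone = tone, ratio1 = ratio1, ratio2 = ratio2)
}

#' Onset/offset frequency-receptive-field simulation
#'
#' Simulates the response of the detector node to a 500-ms tone per row of
#' a ratio table: the stimulus reaches node 1 with weights
#' `(44, 22) * ratio1` and node 2 with `(44, 22) * ratio2`, with a fixed
#' inter-node weight setting drawn from the On/Off solution set.  Returns
#' the peri-stimulus, baseline-subtracted firing rate of the detector's
#' excitatory population per tone, from which distinct onset and offset
#' receptive fields can be read off.
#'
#' @param W length-8 inter-node weight vector (as one row of
#'   [enumerate_grid()]); the default is a suppression-with-offset-peak
#'   (Dec-Off) solution of the standard scan.
#' @param ratio_table data.frame with columns `ratio1`, `ratio2` in
#'   `[0, 1]` (one row per tone); defaults to [frf_ratio_table()].
#' @param stim_duration tone duration (seconds).
#' @param t_post recorded time after tone offset (seconds).
#' @param dt,settle solver settings.
#' @return An object of class `"frf_matrix"`: `values` (tone x time matrix
#'   of baseline-subtracted rates), `time` (peri-stimulus grid),
#'   `ratio_table`, `W`.
#' @export
example2_frf <- function(W = c(13.5, 27, 27, 0, 27, 27, 0, 0),
                         ratio_table = frf_ratio_table(),
                         stim_duration = 0.5, t_post = 0.5,
                         dt = 5e-4, settle = 2) {
  stopifnot(length(W) == 8,
            all(c("ratio1", "ratio2") %in% names(ratio_table)))
  if (any(ratio_table$ratio1 < 0 | ratio_table$ratio1 > 1 |
          ratio_table$ratio2 < 0 | ratio_table$ratio2 > 1))
    stop("ratios must lie in [0, 1]")
  out <- NULL
  for (i in seq_len(nrow(ratio_table))) {
    r1 <- ratio_table$ratio1[i]; r2 <- ratio_table$ratio2[i]
    cfg <- two_node_config(w21 = W[1:4], w12 = W[5:8],
                           w_EX1 = 44 * r1, w_IX1 = 22 * r1)
    cfg$W_EX[2, 1] <- 44 * r2
    cfg$W_IX[2, 1] <- 22 * r2
    res <- simulate_network(cfg, step_stimulus(0, stim_duration),
                            t_span = c(-0.2, stim_duration + t_post),
                            dt = dt, settle = settle)
    base <- mean(res$mE[res$time < 0, 2])
    v <- res$mE[, 2] - base
    if (is.null(out)) out <- matrix(NA_real_, nrow(ratio_table), length(v))
    out[i, ] <- v
    tgrid <- res$time
  }
  structure(list(values = out, time = tgrid, ratio_table = ratio_table,
                 W = W), class = "frf_matrix")
}

#' @export
print.frf_matrix <- function(x, ...) {
  cat(sprintf("<frf_matrix> %d tones x %d time points, value range [%.2f, %.2f]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}
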