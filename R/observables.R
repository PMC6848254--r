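#' Per-node MEG mixing weights
#'
#' Non-negative weights, summing to one, that mix the per-node current sums
#' into the simulated MEG signal; used to highlight specific nodes (the
#' change detector in the deviance-detection examples).
#'
#' @param b numeric vector of non-negative weights; must sum to 1 (within
#'   `1e-8`).
#' @return An object of class `"meg_weights"`.
#' @export
meg_weights <- function(b) {
  if (any(b < 0)) stop("MEG weights must be non-negative")
  if (abs(sum(b) - 1) > 1e-8) stop("MEG weights must sum to 1")
  structure(list(b = as.numeric(b)), class = "meg_weights")
}

#' Simulated MEG signal
#'
#' The weighted sum of the currents at the excitatory populations:
#' active sinks (excitatory input through the E-to-E gains, including the
#' adaptation efficacy when enabled) plus active sources (inhibitory input
#' through the I-to-E gains):
#' `R(t) = sum_j b_j [ sum_k a_jk w^EE_jk m^E_k + sum_k w^EI_jk m^I_k ]`.
#'
#' @param result a `"simulation_result"` (which records the per-node sink
#'   and source sums at every step, so time-varying efficacies and plastic
#'   weights are handled exactly).
#' @param b a [meg_weights()] object, or `NULL` for uniform weights.
#' @return numeric time series (same grid as `result$time`).
#' @export
meg_signal <- function(result, b = NULL) {
  stopifnot(inherits(result, "simulation_result"))
  N <- ncol(result$mE)
  if (is.null(b)) b <- meg_weights(rep(1 / N, N))
  stopifnot(inherits(b, "meg_weights"))
  if (length(b$b) != N) stop("length of MEG weights must equal node count")
  as.vector((result$sink + result$source) %*% b$b)
}

#' Detect the omitted-stimulus-response peak
#'
#' Finds the primary post-omission peak of a signal: the largest local
#' maximum within `[due_time, due_time + search_window]` (ties broken by
#' earliest time), plus the largest local maximum before the due time as the
#' entrainment reference and a flag for a secondary "expectation" bump
#' preceding the primary peak.  Invariant to adding a constant to the
#' signal.
#'
#' For oscillatory signals the heights of successive post-omission cycles
#' can be nearly equal; `tie_tol` treats all local maxima within that
#' relative fraction of the window maximum as ties, and the earliest tied
#' peak is reported as primary.
#'
#' @param time,R sampled signal.
#' @param due_time the time the omitted stimulus was due (seconds).
#' @param search_window length of the post-due search window (seconds).
#' @param tie_tol relative height tolerance for declaring peak ties.
#' @return A list of class `"peak_report"`: `found`, `peak_time`, `latency`
#'   (peak time minus due time), `peak_amplitude`, `pre_due_peak_time`,
#'   `pre_due_peak_amplitude`, `has_pre_peak` (a local maximum between the
#'   due time and the primary peak).  When no local maximum exists in the
#'   window, `found = FALSE` and the peak fields are `NA` (not an error).
#' @export
detect_osr_peak <- function(time, R, due_time, search_window = 0.5,
                            tie_tol = 0.15) {
  stopifnot(length(time) == length(R))
  if (due_time < time[1] || due_time + search_window > time[length(time)])
    stop("search window not inside the sampled range")
  locmax <- function(i) R[i] > R[i - 1] & R[i] >= R[i + 1]
  idx <- 2:(length(R) - 1)
  lm <- idx[locmax(idx)]
  inwin <- lm[time[lm] >= due_time & time[lm] <= due_time + search_window]
  pre <- lm[time[lm] < due_time]
  pre_t <- if (length(pre)) time[pre[which.max(R[pre])]] else NA_real_
  pre_a <- if (length(pre)) max(R[pre]) else NA_real_
  if (!length(inwin)) {
    out <- list(found = FALSE, peak_time = NA_real_, latency = NA_real_,
                peak_amplitude = NA_real_, pre_due_peak_time = pre_t,
                pre_due_peak_amplitude = pre_a, has_pre_peak = FALSE)
    return(structure(out, class = "peak_report"))
  }
  lo <- min(R[time >= due_time & time <= due_time + search_window])
  top <- max(R[inwin])
  tied <- inwin[R[inwin] >= top - tie_tol * (top - lo)]
  best <- tied[1]                       # earliest among (toleranced) ties
  secondary <- inwin[time[inwin] < time[best]]
  structure(list(found = TRUE, peak_time = time[best],
                 latency = time[best] - due_time, peak_amplitude = R[best],
                 pre_due_peak_time = pre_t, pre_due_peak_amplitude = pre_a,
                 has_pre_peak = length(secondary) > 0),
            class = "peak_report")
}

#' @export
print.peak_report <- function(x, ...) {
  if (x$found)
    cat(sprintf("<peak_report> peak at %.3f s (latency %.0f ms, amplitude %.3f)\n",
                x$peak_time, 1000 * x$latency, x$peak_amplitude))
  else cat("<peak_report> no peak found\n")
  invisible(x)
}

#' Sliding root-mean-square envelope
#'
#' Centered sliding RMS of a signal; the window is truncated at the series
#' edges.  A constant signal returns itself; a unit sinusoid over whole
#' periods returns `1/sqrt(2)`.
#'
#' @param R numeric series.
#' @param window window length (seconds).
#' @param dt sampling step (seconds).
#' @return numeric series of the same length.
#' @export
rms_envelope <- function(R, window, dt) {
  stopifnot(window > 0, dt > 0)
  n <- length(R)
  half <- as.integer(round(window / dt / 2))
  if (2 * half + 1 > n) stop("window exceeds series length")
  cs <- cumsum(c(0, R^2))
  lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
  sqrt((cs[hi + 1] - cs[lo]) / (hi - lo + 1))
}
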