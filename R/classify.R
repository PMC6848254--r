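#' Analysis windows for response categorization
#'
#' The five windows (seconds, relative to stimulus onset) over which window
#' maxima of the change detector's excitatory firing rate are taken, for a
#' 2000-ms stimulus: pre-onset [-0.5, 0], post-onset [0, 0.5], pre-offset
#' [1.5, 2], post-offset-1 [2, 2.5] and post-offset-2 [3.5, 4].
#'
#' @param t_on,t_off stimulus onset/offset (seconds).
#' @return An object of class `"response_windows"`: a named list of
#'   length-2 windows.
#' @export
response_windows <- function(t_on = 0, t_off = 2) {
  stopifnot(t_off > t_on)
  w <- list(pre_onset   = c(t_on - 0.5, t_on),
            post_onset  = c(t_on, t_on + 0.5),
            pre_offset  = c(t_off - 0.5, t_off),
            post_offset1 = c(t_off, t_off + 0.5),
            post_offset2 = c(t_off + 1.5, t_off + 2.0))
  structure(w, class = "response_windows")
}

#' Categorization thresholds
#'
#' @param theta_prepost bistability threshold on the absolute pre/post
#'   baseline difference (spikes/s).
#' @param theta_stim level-change threshold (spikes/s); the during-stimulus
#'   maximum must *strictly* exceed both baselines by more than this for an
#'   "Inc" label.
#' @param theta_on,theta_off edge-transient thresholds (spikes/s).
#' @return An object of class `"response_thresholds"`.
#' @export
response_thresholds <- function(theta_prepost = 0.1, theta_stim = 0,
                                theta_on = 0.5, theta_off = 0.5) {
  stopifnot(theta_prepost >= 0, theta_on >= 0, theta_off >= 0)
  structure(list(theta_prepost = theta_prepost, theta_stim = theta_stim,
                 theta_on = theta_on, theta_off = theta_off),
            class = "response_thresholds")
}

#' The nine response-type labels
#' @return character vector of the nine labels in canonical order.
#' @export
response_types <- function() {
  c("Inc-None", "Inc-On", "Inc-Off", "Inc-OnOff",
    "Dec-None", "Dec-On", "Dec-Off", "Dec-OnOff", "others")
}

#' Window maxima of a firing-rate trace
#'
#' Maximum of the sampled trace strictly inside each analysis window
#' (samples on a window boundary are excluded).
#'
#' @param time,trace the sampled trace (seconds, spikes/s); `time` must
#'   cover every window.
#' @param windows a [response_windows()] object.
#' @return named numeric vector of five maxima.
#' @export
window_maxima <- function(time, trace, windows = response_windows()) {
  stopifnot(length(time) == length(trace))
  vapply(windows, function(w) {
    sel <- time > w[1] & time < w[2]
    if (!any(sel)) stop(sprintf("trace does not cover window [%g, %g] s", w[1], w[2]))
    max(trace[sel])
  }, 0)
}

#' Response metrics from window maxima
#'
#' `dm_prepost = |max(pre-onset) - max(post-offset-2)|` (bistability check,
#' direction-agnostic); `dm_stim = max(pre-offset) - max(both baselines)`
#' (the during-stimulus level must exceed *both* baselines to count as
#' increased); `dm_on = max(post-onset) - max(pre-onset)`;
#' `dm_off = max(post-offset-1) - max(pre-offset)`.
#'
#' @param maxima named vector from [window_maxima()].
#' @return named numeric vector with `dm_prepost`, `dm_stim`, `dm_on`,
#'   `dm_off` (spikes/s).
#' @export
response_metrics <- function(maxima) {
  c(dm_prepost = abs(maxima[["pre_onset"]] - maxima[["post_offset2"]]),
    dm_stim = maxima[["pre_offset"]] -
      max(maxima[["pre_onset"]], maxima[["post_offset2"]]),
    dm_on = maxima[["post_onset"]] - maxima[["pre_onset"]],
    dm_off = maxima[["post_offset1"]] - maxima[["pre_offset"]])
}

categorize_metrics <- function(m, thresholds = response_thresholds()) {
  if (any(!is.finite(m))) return("others")
  if (m[["dm_prepost"]] >= thresholds$theta_prepost) return("others")
  level <- if (m[["dm_stim"]] > thresholds$theta_stim) "Inc" else "Dec"
  edge <- paste0(if (m[["dm_on"]] > thresholds$theta_on) "On" else "",
                 if (m[["dm_off"]] > thresholds$theta_off) "Off" else "")
  if (edge == "") edge <- "None"
  paste(level, edge, sep = "-")
}

#' Categorize a change-detector firing-rate trace
#'
#' Assigns exactly one of the nine response-type labels
#' (`{Inc, Dec} x {None, On, Off, OnOff}` plus `"others"`) to a trace of
#' `m^E` around a prolonged stimulus.  Bistable traces (pre/post baselines
#' differing by at least `theta_prepost`) and non-finite traces are
#' `"others"`; otherwise the level flag (Inc/Dec) and the edge-transient
#' flags (On/Off) compose the label.  Adding a constant to the whole trace
#' changes neither the metrics nor the label; a perfectly flat trace is
#' `Dec-None` (zero does not strictly exceed the level threshold).
#'
#' @param time,trace sampled `m^E` (seconds, spikes/s), covering all windows.
#' @param windows a [response_windows()] object.
#' @param thresholds a [response_thresholds()] object.
#' @return A list with `type` (character label), `metrics` and `maxima`.
#' @export
categorize <- function(time, trace, windows = response_windows(),
                       thresholds = response_thresholds()) {
  if (any(!is.finite(trace))) {
    m <- c(dm_prepost = NA_real_, dm_stim = NA_real_,
           dm_on = NA_real_, dm_off = NA_real_)
    return(list(type = "others", metrics = m, maxima = NULL))
  }
  mx <- window_maxima(time, trace, windows)
  m <- response_metrics(mx)
  list(type = categorize_metrics(m, thresholds), metrics = m, maxima = mx)
}

#' Classify traces stored in a two-column CSV file
#'
#' Standalone classifier entry point: reads `time, value` pairs (seconds,
#' spikes/s) and emits the label plus metrics, optionally as a JSON line.
#'
#' @param path CSV file with columns `time` and `value`.
#' @param windows,thresholds see [categorize()].
#' @param json if `TRUE`, return a one-line JSON string; otherwise the list
#'   from [categorize()].
#' @export
classify_trace_file <- function(path, windows = response_windows(),
                                thresholds = response_thresholds(),
                                json = FALSE) {
  d <- utils::read.csv(path)
  if (!all(c("time", "value") %in% names(d)))
    stop("CSV must have columns 'time' and 'value'")
  res <- categorize(d$time, d$value, windows, thresholds)
  if (json)
    jsonlite::toJSON(list(file = path, type = res$type,
                          metrics = as.list(res$metrics)), auto_unbox = TRUE)
  else res
}
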