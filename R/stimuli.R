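#' @name stimuli
#' @title External stimulus protocols
#'
#' @description Stimulus channels are stored as piecewise-linear breakpoint
#' functions (exact under time shifts and exact to sample at any solver
#' resolution), together with protocol metadata (onsets, offsets, SOA, due
#' time).  All stimuli are non-negative firing-rate envelopes; the standard
#' amplitude is 1.5 spikes/s with linear 10-ms rise/fall ramps.
NULL

new_stimulus_set <- function(channels, meta) {
  structure(list(channels = channels, meta = meta), class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d channel(s)\n", length(x$channels)))
  for (i in seq_along(x$channels)) {
    m <- x$meta[[i]]
    cat(sprintf("  [%d] %s: %d onset(s)%s\n", i,
                if (!is.null(m$label)) m$label else "channel",
                length(m$onsets),
                if (!is.null(m$due_time)) sprintf(", due time %g s", m$due_time) else ""))
  }
  invisible(x)
}

# breakpoints of one trapezoidal pulse; rise starts at onset, fall ends at
# offset, so the plateau spans [onset + ramp, offset - ramp]
pulse_breaks <- function(onset, offset, amplitude, ramp) {
  if (offset <= onset + 2 * ramp)
    stop("pulse too short: offset must exceed onset + 2*ramp")
  data.frame(t = c(onset, onset + ramp, offset - ramp, offset),
             v = c(0, amplitude, amplitude, 0))
}

#' Single trapezoidal step stimulus
#'
#' Zero before `onset`, linear rise over `ramp`, plateau at `amplitude`,
#' linear fall over `ramp` ending at `offset`, zero after.
#'
#' @param onset,offset stimulus edges in seconds (`offset > onset + 2*ramp`).
#' @param amplitude plateau rate (spikes/s).
#' @param ramp rise/fall time (seconds).
#' @param label optional channel label.
#' @return A one-channel `"stimulus_set"`.
#' @export
step_stimulus <- function(onset = 0, offset = 2, amplitude = 1.5,
                          ramp = 0.010, label = "step") {
  stopifnot(ramp > 0, amplitude >= 0)
  br <- pulse_breaks(onset, offset, amplitude, ramp)
  new_stimulus_set(list(br),
                   list(list(label = label, onsets = onset, offsets = offset,
                             amplitude = amplitude, ramp = ramp)))
}

#' Periodic pulse train with optional omission
#'
#' `n_stim` trapezoidal pulses with onsets spaced `soa` apart.  An omission
#' is represented simply by the train ending: the metadata records the *due
#' time* of the next (omitted) stimulus, `last onset + soa`, which anchors
#' all omitted-stimulus-response analyses.
#'
#' @param soa stimulus-onset asynchrony in seconds (`soa >= stim_duration`;
#'   at equality the pulses are contiguous apart from the ramp dips).
#' @param stim_duration pulse duration (seconds).
#' @param n_stim number of pulses actually presented.
#' @param onset0 onset of the first pulse (seconds).
#' @param amplitude,ramp as in [step_stimulus()].
#' @return A one-channel `"stimulus_set"`; `meta[[1]]$due_time` holds the
#'   omitted-stimulus time.
#' @export
periodic_train <- function(soa, stim_duration = 0.050, n_stim,
                           onset0 = 0, amplitude = 1.5, ramp = 0.010) {
  if (soa < stim_duration) stop("soa must be at least stim_duration")
  stopifnot(n_stim >= 1)
  onsets <- onset0 + (seq_len(n_stim) - 1) * soa
  br <- do.call(rbind, lapply(onsets, function(on)
    pulse_breaks(on, on + stim_duration, amplitude, ramp)))
  new_stimulus_set(list(br),
                   list(list(label = sprintf("train soa=%g", soa),
                             onsets = onsets, offsets = onsets + stim_duration,
                             soa = soa, stim_duration = stim_duration,
                             amplitude = amplitude, ramp = ramp,
                             due_time = onsets[n_stim] + soa)))
}

#' Regular/random sequence envelope pair
#'
#' Two step-envelope channels marking when a regular (REG) and a random
#' (RAND) sequence are being presented, used by the sequence-MMN example.
#' Spans within one channel must not overlap; amplitude and ramps default to
#' the standard step stimulus.
#'
#' @param reg_spans,rand_spans lists (or n x 2 matrices) of `c(onset, offset)`
#'   spans in seconds; may be empty.
#' @param amplitude,ramp as in [step_stimulus()].
#' @return A two-channel `"stimulus_set"`; channel 1 is REG, channel 2 RAND.
#' @export
sequence_pair <- function(reg_spans, rand_spans, amplitude = 1.5, ramp = 0.010) {
  as_spans <- function(x) {
    if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
    x
  }
  mk <- function(spans, label) {
    spans <- as_spans(spans)
    if (length(spans) == 0)
      return(list(br = data.frame(t = numeric(), v = numeric()),
                  meta = list(label = label, onsets = numeric(),
                              offsets = numeric(), amplitude = amplitude,
                              ramp = ramp)))
    ons <- vapply(spans, `[[`, 0, 1L); offs <- vapply(spans, `[[`, 0, 2L)
    o <- order(ons); ons <- ons[o]; offs <- offs[o]
    if (any(ons[-1] < offs[-length(offs)]))
      stop(sprintf("overlapping spans in %s channel", label))
    br <- do.call(rbind, Map(function(on, off)
      pulse_breaks(on, off, amplitude, ramp), ons, offs))
    list(br = br, meta = list(label = label, onsets = ons, offsets = offs,
                              amplitude = amplitude, ramp = ramp))
  }
  reg <- mk(reg_spans, "REG"); rand <- mk(rand_spans, "RAND")
  new_stimulus_set(list(reg$br, rand$br), list(reg$meta, rand$meta))
}

#' Stack stimulus sets into a multi-channel set
#'
#' @param ... `"stimulus_set"` objects.
#' @return A `"stimulus_set"` whose channels are the concatenation of the
#'   inputs' channels, in order.
#' @export
combine_stimuli <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, TRUE, "stimulus_set")))
  new_stimulus_set(do.call(c, lapply(sets, `[[`, "channels")),
                   do.call(c, lapply(sets, `[[`, "meta")))
}

#' A silent (all-zero) stimulus channel
#' @return A one-channel `"stimulus_set"` that is identically zero.
#' @export
null_stimulus <- function() {
  new_stimulus_set(list(data.frame(t = numeric(), v = numeric())),
                   list(list(label = "silence", onsets = numeric(),
                             offsets = numeric())))
}

#' Shift all protocol times of a stimulus set
#'
#' @param stimuli a `"stimulus_set"`.
#' @param by time shift in seconds.
#' @return The shifted `"stimulus_set"` (waveform shifted exactly).
#' @export
shift_stimuli <- function(stimuli, by) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  stimuli$channels <- lapply(stimuli$channels, function(br) {
    br$t <- br$t + by; br
  })
  stimuli$meta <- lapply(stimuli$meta, function(m) {
    for (f in c("onsets", "offsets", "due_time"))
      if (!is.null(m[[f]])) m[[f]] <- m[[f]] + by
    m
  })
  stimuli
}

#' Sample stimulus channels on a time grid
#'
#' Evaluates each piecewise-linear channel at the requested times; exact for
#' the trapezoidal protocols used throughout.
#'
#' @param stimuli a `"stimulus_set"`.
#' @param times numeric vector of times (seconds).
#' @return An `M x length(times)` matrix of rates (spikes/s).
#' @export
sample_stimuli <- function(stimuli, times) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  out <- matrix(0, length(stimuli$channels), length(times))
  for (i in seq_along(stimuli$channels)) {
    br <- stimuli$channels[[i]]
    if (nrow(br) >= 2)
      out[i, ] <- stats::approx(br$t, br$v, xout = times,
                                yleft = 0, yright = 0, ties = "ordered")$y
  }
  out
}
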