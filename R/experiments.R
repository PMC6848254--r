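#' Measure the intrinsic oscillation frequency of the standard node
#'
#' Simulates an isolated standard node under background drive only and
#' estimates its limit-cycle frequency from the mean interval between
#' upward mean-crossings.  Deterministic; used to calibrate oscillator
#' banks.
#'
#' @param B background drive (spikes/s).
#' @param dt solver step (seconds).
#' @return frequency in Hz (about 9.7 Hz at the standard `B = 550`).
#' @export
reference_frequency <- function(B = 550, dt = 5e-4) {
  cfg <- default_node_config(input = FALSE)
  cfg$B <- B
  r <- simulate_network(cfg, t_span = c(0, 6), dt = dt, settle = 4)
  m <- r$mE[, 1] - mean(r$mE[, 1])
  z <- which(diff(sign(m)) > 0)
  if (length(z) < 3) stop("reference node did not oscillate")
  1 / (mean(diff(z)) * dt)
}

#' Damped resonance period of the standard node below its oscillation onset
#'
#' For background drives below the oscillation onset (about 115 spikes/s)
#' the standard node is a damped resonator; this measures the period of its
#' post-pulse ringing, which calibrates the resonance frequencies of
#' sub-threshold oscillator banks.
#'
#' @param B background drive (spikes/s), below the oscillation onset.
#' @param dt solver step (seconds).
#' @return ringing period in seconds (about 153 ms at `B = 114`).
#' @export
damped_period <- function(B = 114, dt = 5e-4) {
  cfg <- default_node_config()
  cfg$B <- B
  r <- simulate_network(cfg, step_stimulus(0, 0.071, amplitude = 0.5),
                        t_span = c(-0.1, 1.5), dt = dt, settle = 4)
  m <- r$mE[, 1]
  pk <- which(diff(sign(diff(m))) < 0) + 1
  pk <- pk[r$time[pk] > 0.08]
  if (length(pk) < 4) stop("no ringing detected; is B below the onset?")
  mean(diff(r$time[pk[1:4]]))
}

#' Build an oscillator bank with a change-detector node
#'
#' Constructs an `N_b + 1`-node network: `N_b` regularity (R) nodes whose
#' resonance frequencies rise strictly monotonically with node index, plus
#' one change-detector (C) node (index `N_b + 1`) reciprocally coupled to
#' every bank node.
#'
#' Each bank node is a time-rescaled copy of the standard node (both
#' synaptic time constants multiplied by a per-node factor, both gains
#' divided by it, preserving the rate-to-potential DC gain), operated just
#' below the oscillation onset (`B_bank`, default 114 spikes/s) so that it
#' behaves as a high-Q damped resonator: a periodic pulse train
#' selectively and reproducibly entrains the nodes whose resonance period
#' matches the stimulus-onset asynchrony.  Bank nodes are mutually coupled
#' only through short-term plasticity (inter-bank gains start at zero); the
#' covariance rule transiently binds the co-resonating group, which
#' sustains the group resonance for a few hundred milliseconds beyond the
#' train — the network's memory of the input periodicity.
#'
#' The C node is a slow copy of the standard node (time scale `s_C`) at the
#' standard supercritical drive, so at rest it oscillates autonomously.
#' Bank excitatory populations project onto its inhibitory population
#' (gain `w_RC[2]`, a bank total), which quenches the detector whenever the
#' bank holds a continuous stimulus-driven representation; while quenched,
#' the adaptation efficacy of its recurrent excitation recovers, so when
#' the sustained resonance collapses the detector fires an over-shooting
#' rebound burst — the omitted-stimulus response.  For SOAs beyond the
#' slowest bank resonance no sustained representation forms, the detector
#' keeps free-running, and the post-omission peak time becomes unstable
#' across trials.
#'
#' @param N_b bank size.
#' @param freq_range length-2 vector of bank resonance frequencies (Hz);
#'   node periods are spaced linearly between `1/freq_range[2]` and
#'   `1/freq_range[1]`.  The default covers periods 50-200 ms, which sets
#'   the stability boundary of the omitted-stimulus response at 200 ms.
#' @param B_bank background drive of the bank nodes (spikes/s), below the
#'   oscillation onset.
#' @param B_C background drive of the detector node (spikes/s).
#' @param s_C time-scale factor of the detector node.
#' @param w_EX,w_IX external input weights per bank node; the default
#'   routes the stimulus to the excitatory populations only.
#' @param w_RC length-4 gains `(EE, IE, EI, II)` from the bank onto the C
#'   node, as bank totals (each connection carries `w_RC / N_b`).
#' @param w_CR length-4 gains from the C node back onto each bank node,
#'   also bank totals.
#' @param stp an [stp_params()] object for the bank-internal plasticity.
#' @param adaptation an [adaptation_params()] object for the detector's
#'   recurrent excitation (`NULL` disables the rebound-burst mechanism).
#' @param per_ref damped resonance period of the unscaled node at `B_bank`
#'   (seconds); measured via [damped_period()] when `NULL`.
#' @return An object of class `"oscillator_bank"`: list with the
#'   `network_config` (`config`), `N_b`, C-node index `c_node`, per-node
#'   resonance `freqs` (Hz), the `stp` and `adaptation` parameters and the
#'   detector adaptation mask.
#' @export
build_bank <- function(N_b = 21, freq_range = c(5, 20), B_bank = 114,
                       B_C = 550, s_C = 4.12, w_EX = 40, w_IX = 0,
                       w_RC = c(0, 270, 0, 0), w_CR = c(13.5, 0, 0, 0),
                       stp = stp_params(N_b = N_b, tau_w = 0.3,
                                        gain_scale = 67.5),
                       adaptation = adaptation_params(),
                       per_ref = NULL) {
  stopifnot(N_b >= 2, length(freq_range) == 2, all(freq_range > 0),
            freq_range[2] > freq_range[1], length(w_RC) == 4,
            length(w_CR) == 4, s_C > 0)
  if (is.null(per_ref))
    per_ref <- if (B_bank == 114) 0.153 else damped_period(B_bank)
  periods <- rev(seq(1 / freq_range[2], 1 / freq_range[1], length.out = N_b))
  freqs <- 1 / periods                     # ascending with node index
  if (any(diff(freqs) <= 0)) stop("resonance frequencies must be strictly increasing")
  s <- periods / per_ref
  M <- N_b + 1
  mk <- function(intra, rc, cr) {
    W <- diag(rep(intra, M))
    W[M, 1:N_b] <- rc / N_b
    W[1:N_b, M] <- cr / N_b
    W
  }
  g <- .gain_scale * .intra_ratio
  cfg <- network_config(
    W_EE = mk(g[["EE"]], w_RC[1], w_CR[1]),
    W_IE = mk(g[["IE"]], w_RC[2], w_CR[2]),
    W_EI = mk(g[["EI"]], w_RC[3], w_CR[3]),
    W_II = mk(g[["II"]], w_RC[4], w_CR[4]),
    W_EX = matrix(c(rep(w_EX, N_b), 0), M, 1),
    W_IX = matrix(c(rep(w_IX, N_b), 0), M, 1),
    B = c(rep(B_bank, N_b), B_C),
    H_e = c(3.25 / s, 3.25 / s_C), tau_e = c(0.010 * s, 0.010 * s_C),
    H_i = c(22 / s, 22 / s_C), tau_i = c(0.020 * s, 0.020 * s_C))
  amask <- matrix(0L, M, M)
  amask[M, M] <- 1L                        # detector self-excitation only
  structure(list(config = cfg, N_b = N_b, c_node = M, freqs = freqs,
                 periods = periods, stp = stp, adaptation = adaptation,
                 adapt_mask = amask, per_ref = per_ref),
            class = "oscillator_bank")
}

#' @export
print.oscillator_bank <- function(x, ...) {
  cat(sprintf("<oscillator_bank> %d R nodes (%.1f-%.1f Hz) + 1 C node\n",
              x$N_b, min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Simulate one omission trial
#'
#' Runs a periodic train (or a prolonged CONST stimulus) into the bank,
#' forms the simulated MEG signal (weight `b_C` on the detector, remainder
#' spread over the bank), and detects the post-omission peak on the
#' baseline-subtracted RMS envelope of the MEG.
#'
#' @param bank an [build_bank()] object.
#' @param soa stimulus-onset asynchrony (seconds).
#' @param n_stim number of pulses before the train ends (the omission).
#' @param const if `TRUE`, present one prolonged step over the same span
#'   instead of a train (control condition).
#' @param b_C MEG weight on the detector node.
#' @param tail_s simulated time after the due time (seconds).
#' @param dt,settle solver settings.
#' @param search_window post-due window for peak detection (seconds).
#' @param smooth RMS envelope window (seconds).
#' @return list with `result`, `meg`, `envelope`, `time`, `due`, `peak`
#'   (a [detect_osr_peak()] report on the envelope), `soa`, `n_stim`.
#' @export
osr_trial <- function(bank, soa, n_stim, const = FALSE, b_C = 0.7,
                      tail_s = 1.1, dt = 5e-4, settle = 2.5,
                      search_window = 0.5, smooth = 0.13) {
  stopifnot(inherits(bank, "oscillator_bank"))
  if (const) {
    span <- (n_stim - 1) * soa + 0.05
    st <- step_stimulus(0, span)
    due <- span
  } else {
    st <- periodic_train(soa, 0.05, n_stim)
    due <- st$meta[[1]]$due_time
  }
  r <- simulate_network(bank$config, st, t_span = c(-0.5, due + tail_s),
                        dt = dt, settle = settle, stp = bank$stp,
                        stp_nodes = seq_len(bank$N_b),
                        adaptation = bank$adaptation,
                        adapt_mask = bank$adapt_mask)
  b <- meg_weights(c(rep((1 - b_C) / bank$N_b, bank$N_b), b_C))
  R <- meg_signal(r, b)
  base <- mean(R[r$time < -0.05])
  env <- rms_envelope(R - base, smooth, dt)
  pk <- detect_osr_peak(r$time, env, due, search_window)
  list(result = r, meg = R, envelope = env, time = r$time, due = due,
       peak = pk, soa = soa, n_stim = n_stim, const = const)
}

# train lengths used across omission trials: at least 8 pulses and at
# least ~1 s of entrainment before the earliest omission
osr_trial_lengths <- function(soa, n_trials)
  max(8, ceiling(1 / soa)) + seq_len(n_trials) - 1L

#' Omitted-stimulus-response experiment
#'
#' For each SOA, runs several trials that differ in the train length (and
#' hence the omission position), detects the post-omission MEG envelope
#' peak of the change detector, and tabulates peak latencies and
#' amplitudes.  The key readouts: peak latency grows linearly (slope about
#' one) with SOA when measured from the train offset for SOAs within the
#' bank's resonance range, i.e. the latency after the due time is
#' approximately constant; peak amplitude falls with SOA over that range;
#' and the across-trial latency spread explodes once the SOA exceeds the
#' slowest bank resonance period.
#'
#' @param bank an [build_bank()] object.
#' @param soas SOAs to test (seconds).
#' @param n_trials trials per SOA (train lengths
#'   `max(8, ceiling(1/soa)) + 0:(n_trials-1)`).
#' @param keep_traces keep the MEG/envelope trace of the first trial per
#'   SOA.
#' @param ... passed to [osr_trial()].
#' @return An object of class `"osr_experiment"`: `trials` (one row per
#'   trial: soa, n_stim, due, latency, amplitude, found, has_pre_peak),
#'   `summary` (per SOA: mean latency, across-trial SD, mean amplitude),
#'   and `slope_vs_soa` (regression slope of the offset-referenced peak
#'   time on SOA over the stable SOAs).
#' @export
example3_osr <- function(bank = build_bank(),
                         soas = c(0.075, 0.125, 0.175, 0.250),
                         n_trials = 8, keep_traces = TRUE,
                         spread_tol = 0.020, ...) {
  rows <- list(); traces <- list()
  for (soa in soas) {
    for (n_stim in osr_trial_lengths(soa, n_trials)) {
      tr <- osr_trial(bank, soa, n_stim, ...)
      rows[[length(rows) + 1]] <- data.frame(
        soa = soa, n_stim = n_stim, due = tr$due,
        found = tr$peak$found, latency = tr$peak$latency,
        amplitude = tr$peak$peak_amplitude,
        has_pre_peak = tr$peak$has_pre_peak)
      if (keep_traces && n_stim == osr_trial_lengths(soa, 1)) {
        traces[[sprintf("soa%03.0f", soa * 1000)]] <-
          data.frame(time = tr$time - tr$due, meg = tr$meg,
                     envelope = tr$envelope, soa = soa)
      }
    }
  }
  trials <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(trials, trials$soa), function(d) {
    lat <- d$latency[d$found]
    data.frame(soa = d$soa[1], n_found = sum(d$found),
               mean_latency = if (length(lat)) mean(lat) else NA_real_,
               latency_sd = if (all(d$found)) stats::sd(lat) else Inf,
               mean_amplitude = if (length(lat)) mean(d$amplitude[d$found])
                                else NA_real_)
  }))
  rownames(summ) <- NULL
  stable <- summ$soa[summ$latency_sd <= spread_tol]
  ok <- trials$found & trials$soa %in% stable
  slope <- if (sum(ok) >= 4 && length(unique(trials$soa[ok])) >= 2) {
    off_lat <- trials$latency[ok] + trials$soa[ok] - 0.05
    unname(stats::coef(stats::lm(off_lat ~ trials$soa[ok]))[2])
  } else NA_real_
  structure(list(trials = trials, summary = summ, slope_vs_soa = slope,
                 spread_tol = spread_tol,
                 traces = if (keep_traces) traces else NULL, bank = bank),
            class = "osr_experiment")
}

#' @export
print.osr_experiment <- function(x, ...) {
  cat("<osr_experiment>\n")
  s <- x$summary
  print(data.frame(soa_ms = 1000 * s$soa, n_found = s$n_found,
                   mean_latency_ms = round(1000 * s$mean_latency),
                   latency_sd_ms = round(1000 * s$latency_sd, 1),
                   mean_amplitude = round(s$mean_amplitude)))
  cat(sprintf("slope of offset-referenced peak time vs SOA: %.2f\n",
              x$slope_vs_soa))
  invisible(x)
}

#' Stability boundary of the omitted-stimulus response
#'
#' Sweeps SOAs, runs several omission trials per SOA with varying train
#' offset, and reports the largest SOA on the grid such that the
#' across-trial spread (standard deviation) of the post-due peak latency
#' stays within `tol` for it and for every smaller SOA on the grid (trials
#' without a detectable peak count as unstable).  With the default bank
#' (resonance periods up to 200 ms) the boundary falls at the slowest
#' resonance period, 200 ms.
#'
#' @param bank an [build_bank()] object.
#' @param soas SOA grid (seconds).
#' @param n_trials trials per SOA.
#' @param tol latency-spread tolerance (seconds).
#' @param ... passed to [osr_trial()] via [example3_osr()].
#' @return list with `boundary` (seconds; `NA` if even the smallest SOA is
#'   unstable), `spread` (per-SOA latency SD table) and the underlying
#'   `"osr_experiment"`.
#' @export
osr_boundary <- function(bank = build_bank(),
                         soas = seq(0.050, 0.300, by = 0.025),
                         n_trials = 8, tol = 0.020, ...) {
  ex <- example3_osr(bank, soas = soas, n_trials = n_trials,
                     keep_traces = FALSE, spread_tol = tol, ...)
  s <- ex$summary
  stable <- s$latency_sd <= tol
  boundary <- NA_real_
  for (i in seq_along(soas)) {
    if (!isTRUE(stable[i])) break
    boundary <- soas[i]
  }
  list(boundary = boundary,
       spread = data.frame(soa = s$soa, latency_sd = s$latency_sd,
                           n_found = s$n_found, stable = stable),
       experiment = ex)
}
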