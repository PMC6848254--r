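#' Integrate a neural-mass network
#'
#' Solves the coupled kernel ODEs of every population in the network with a
#' fixed-step 4th-order Runge-Kutta scheme (default step 0.5 ms, well below
#' the fastest synaptic time constant of 10 ms).  Integration starts from
#' the all-zero state at `t_span[1] - settle`; the settle interval lets the
#' network reach its attractor and is discarded from the outputs unless
#' `keep_settle = TRUE`.  Identical inputs produce bit-identical
#' trajectories.
#'
#' @param config a [network_config()].
#' @param stimuli a [stimulus_set()][stimuli] with `config$M` channels, or
#'   `NULL` for no external input.
#' @param t_span length-2 vector, reported time window in seconds.
#' @param dt solver step (seconds).
#' @param settle discarded equilibration interval before `t_span[1]`
#'   (seconds).
#' @param adaptation an [adaptation_params()] object to enable synaptic
#'   adaptation of the E-to-E connections, or `NULL`.
#' @param adapt_mask optional `N x N` logical matrix restricting adaptation
#'   to a subset of E-to-E connections (`NULL` adapts all of them).
#' @param stp an [stp_params()] object to enable covariance-driven
#'   short-term plasticity, or `NULL`.
#' @param stp_nodes integer vector of node indices forming the plastic bank
#'   (required when `stp` is given); plasticity acts on all ordered pairs of
#'   distinct bank nodes.
#' @param keep_settle retain the settle interval in the outputs.
#' @param keep_components also return the four underlying PSP components
#'   per population.
#' @return An object of class `"simulation_result"`: a list with the time
#'   grid `time`, matrices `mE`, `mI`, `vE`, `vI` (rows = time, columns =
#'   nodes), the per-node excitatory-current (`sink`) and
#'   inhibitory-current (`source`) sums entering the simulated MEG signal,
#'   per-presynaptic-node minimum adaptation efficacy `a_min`, mean plastic
#'   gains `stp_wee_mean`/`stp_wei_mean`, and the final weight/efficacy
#'   matrices.
#' @examples
#' cfg <- default_node_config()
#' res <- simulate_network(cfg, step_stimulus(0, 1), t_span = c(-0.5, 2),
#'                         dt = 1e-3, settle = 1)
#' range(res$mE)
#' @export
simulate_network <- function(config, stimuli = NULL, t_span = c(0, 2),
                             dt = 5e-4, settle = 2,
                             adaptation = NULL, adapt_mask = NULL,
                             stp = NULL, stp_nodes = NULL,
                             keep_settle = FALSE, keep_components = FALSE) {
  stopifnot(inherits(config, "network_config"), dt > 0, settle >= 0,
            length(t_span) == 2L, t_span[2] > t_span[1])
  if (is.null(stimuli)) {
    stimuli <- null_stimulus()
    if (config$M > 1)
      stimuli$channels <- rep(stimuli$channels, config$M)
  }
  stopifnot(inherits(stimuli, "stimulus_set"))
  if (length(stimuli$channels) != config$M)
    stop(sprintf("stimulus set has %d channel(s) but config expects M = %d",
                 length(stimuli$channels), config$M))
  n_settle <- as.integer(round(settle / dt))
  n_out <- as.integer(round((t_span[2] - t_span[1]) / dt))
  n_total <- n_settle + n_out
  t0 <- t_span[1] - settle
  half_times <- t0 + (0:(2 * n_total)) * (dt / 2)
  X <- sample_stimuli(stimuli, half_times)

  adapt <- !is.null(adaptation)
  if (adapt) stopifnot(inherits(adaptation, "adaptation_params"))
  if (is.null(adapt_mask)) adapt_mask <- matrix(1L, config$N, config$N)
  else {
    stopifnot(is.matrix(adapt_mask), nrow(adapt_mask) == config$N,
              ncol(adapt_mask) == config$N)
    adapt_mask <- matrix(as.integer(adapt_mask != 0), config$N, config$N)
  }
  use_stp <- !is.null(stp)
  N <- config$N
  alpha <- beta <- matrix(0, N, N); mask <- matrix(0L, N, N)
  stp_win <- 1L
  if (use_stp) {
    stopifnot(inherits(stp, "stp_params"))
    if (is.null(stp_nodes) || length(stp_nodes) < 2)
      stop("stp requires stp_nodes (>= 2 bank node indices)")
    idx <- as.integer(stp_nodes)
    for (aj in seq_along(idx)) for (ak in seq_along(idx)) {
      if (aj == ak) next
      j <- idx[aj]; k <- idx[ak]
      alpha[j, k] <- gaussian_mask(aj, ak, stp$sigma_alpha)
      beta[j, k] <- gaussian_mask(aj, ak, stp$sigma_beta)
      mask[j, k] <- 1L
    }
    stp_win <- max(2L, as.integer(round(stp$delta_t / dt)))
  }

  raw <- sim_network_cpp(config$W_EE, config$W_IE, config$W_EI, config$W_II,
                         config$W_EX, config$W_IX, config$B,
                         config$H_e, config$tau_e, config$H_i, config$tau_i,
                         config$sigmoid$e0, config$sigmoid$r, config$sigmoid$v0,
                         X, dt, n_settle, n_out,
                         adapt,
                         if (adapt) adaptation$tau_a else 1,
                         if (adapt) adaptation$kappa else 0,
                         adapt_mask,
                         use_stp,
                         if (use_stp) stp$eta else 0,
                         if (use_stp) stp$gain_scale else 1,
                         if (use_stp) stp$tau_w else 1,
                         stp_win, alpha, beta, mask,
                         keep_settle, keep_components)
  first <- if (keep_settle) t0 else t_span[1]
  raw$time <- first + (0:(nrow(raw$mE) - 1)) * dt
  raw$dt <- dt
  raw$settle <- settle
  raw$config <- config
  raw$stimuli <- stimuli
  raw$adaptation <- adaptation
  raw$stp <- if (use_stp) stp else NULL
  class(raw) <- "simulation_result"
  raw
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %d node(s), t in [%g, %g] s, dt = %g s\n",
              ncol(x$mE), x$time[1], x$time[length(x$time)], x$dt))
  cat(sprintf("  m^E range: [%.3f, %.3f] spikes/s\n", min(x$mE), max(x$mE)))
  invisible(x)
}

#' Tidy long-format trajectory table
#'
#' @param result a `"simulation_result"`.
#' @param variables subset of `c("mE", "mI", "vE", "vI")`.
#' @return A data.frame with columns `time`, `node`, `population`,
#'   `variable`, `value`.
#' @export
trajectory_table <- function(result, variables = c("mE", "mI", "vE", "vI")) {
  stopifnot(inherits(result, "simulation_result"))
  variables <- match.arg(variables, several.ok = TRUE)
  do.call(rbind, lapply(variables, function(v) {
    m <- result[[v]]
    data.frame(time = rep(result$time, ncol(m)),
               node = rep(seq_len(ncol(m)), each = nrow(m)),
               population = if (substr(v, 2, 2) == "E") "E" else "I",
               variable = v, value = as.vector(m))
  }))
}

#' Phase portrait of one node
#'
#' Extracts the trajectory of `(v^E, v^I)` pairs of a node over a time
#' window, with the signed (shoelace) area of the closed polygon through the
#' samples; positive area means counter-clockwise rotation in the
#' `(v^E, v^I)` plane.
#'
#' @param result a `"simulation_result"`.
#' @param node node index.
#' @param window length-2 time window (seconds) within the simulated range.
#' @return A list with a data.frame `trajectory` (`time`, `vE`, `vI`),
#'   `signed_area` (mV^2) and `orientation`
#'   (`"counter-clockwise"`, `"clockwise"` or `"degenerate"`).
#' @export
phase_portrait <- function(result, node = 1, window = range(result$time)) {
  stopifnot(inherits(result, "simulation_result"),
            node >= 1, node <= ncol(result$vE))
  sel <- result$time >= window[1] & result$time <= window[2]
  if (!any(sel)) stop("empty window")
  x <- result$vE[sel, node]; y <- result$vI[sel, node]
  n <- length(x)
  area <- 0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  orientation <- if (abs(area) < 1e-9) "degenerate" else
    if (area > 0) "counter-clockwise" else "clockwise"
  list(trajectory = data.frame(time = result$time[sel], vE = x, vI = y),
       signed_area = area, orientation = orientation)
}
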