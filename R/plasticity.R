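#' Synaptic adaptation parameters
#'
#' Activity-dependent depression of E-to-E connections.  Each connection
#' carries an efficacy `a` in `[0, 1]` obeying
#' `da/dt = (1 - a)/tau_a - kappa * a * m_pre`,
#' so efficacy recovers toward 1 with time constant `tau_a` and decays at a
#' rate proportional to the pre-synaptic firing rate.  Defaults
#' (`tau_a = 200` ms, `kappa = 2`) put the fixed point at `a* = 0.5` for a
#' pre-synaptic rate of 2.5 spikes/s.  External drive through `W_EX` and the
#' background input are never adapted.
#'
#' @param tau_a recovery time constant (seconds).
#' @param kappa decay-rate constant (dimensionless; multiplies the rate).
#' @return An object of class `"adaptation_params"`.
#' @export
adaptation_params <- function(tau_a = 0.200, kappa = 2) {
  if (!(tau_a > 0)) stop("tau_a must be > 0")
  if (kappa < 0) stop("kappa must be >= 0")
  structure(list(tau_a = tau_a, kappa = kappa), class = "adaptation_params")
}

#' Adaptation right-hand side
#'
#' @param a current efficacy in `[0, 1]`.
#' @param m_pre pre-synaptic excitatory firing rate (spikes/s).
#' @param params an [adaptation_params()] object.
#' @return `da/dt` (1/s).  The closed-form fixed point under constant rate
#'   `m` is `a* = 1 / (1 + tau_a * kappa * m)`.
#' @export
adaptation_rhs <- function(a, m_pre, params = adaptation_params()) {
  (1 - a) / params$tau_a - params$kappa * a * m_pre
}

#' Short-term plasticity parameters
#'
#' Covariance-driven plasticity that binds co-active nodes in an oscillator
#' bank.  For a node pair `(j, k)` with trailing-window covariance `Cov` of
#' their excitatory rates, the E-to-E gain relaxes toward
#' `gain_scale * eta * alpha_jk * max(Cov, 0)` and the I-to-E gain toward
#' `gain_scale * eta * beta_jk * |min(Cov, 0)|`, each with decay time
#' constant `tau_w`; positively covarying pairs strengthen mutual
#' excitation, negatively covarying pairs strengthen cross-inhibition, never
#' both at once.  The Gaussian index masks `alpha` (width `0.2 * N_b`) and
#' `beta` (width `0.4 * N_b`) restrict binding to nodes of similar resonance
#' frequency.  Weight targets are expressed on the same normalized scale as
#' all other connection gains, hence the global `gain_scale` of 135.
#'
#' @param eta learning rate (dimensionless).
#' @param sigma_alpha,sigma_beta Gaussian mask widths in node-index units;
#'   defaults `0.2 * N_b` and `0.4 * N_b`.
#' @param delta_t trailing covariance window length (seconds); the
#'   covariance is defined as 0 while less than one full window of history
#'   exists.
#' @param N_b bank size (number of plastic nodes).
#' @param tau_w weight relaxation time constant (seconds); weight dynamics
#'   are slow compared to the oscillation period.
#' @param gain_scale global connectivity gain scale.
#' @return An object of class `"stp_params"`.
#' @export
stp_params <- function(eta = 0.05, N_b = 21,
                       sigma_alpha = 0.2 * N_b, sigma_beta = 0.4 * N_b,
                       delta_t = 0.200, tau_w = 1, gain_scale = 135) {
  stopifnot(eta > 0, sigma_alpha > 0, sigma_beta > 0, delta_t > 0,
            tau_w > 0, N_b >= 2, gain_scale > 0)
  structure(list(eta = eta, N_b = N_b, sigma_alpha = sigma_alpha,
                 sigma_beta = sigma_beta, delta_t = delta_t, tau_w = tau_w,
                 gain_scale = gain_scale),
            class = "stp_params")
}

#' Gaussian node-index mask
#'
#' `exp(-(j - k)^2 / (2 * sigma^2))`: the plasticity weight between two bank
#' nodes as a function of their index distance.
#'
#' @param j,k node indices (vectorized).
#' @param sigma mask width in index units.
#' @return mask value(s) in `(0, 1]`.
#' @export
gaussian_mask <- function(j, k, sigma) {
  stopifnot(sigma > 0)
  exp(-(j - k)^2 / (2 * sigma^2))
}

#' Trailing-window covariance of two rate series
#'
#' Sample covariance of `m_j` and `m_k` over `[t - delta_t, t]` on the
#' sampling grid; defined as 0 when less than one full window of history is
#' available (no plasticity before one full window).
#'
#' @param m_j,m_k numeric series sampled on a uniform grid.
#' @param delta_t window length (seconds).
#' @param t evaluation time (seconds), measured from the first sample.
#' @param dt sampling step (seconds).
#' @return scalar covariance ((spikes/s)^2).
#' @export
windowed_covariance <- function(m_j, m_k, delta_t, t, dt) {
  stopifnot(length(m_j) == length(m_k))
  n_win <- round(delta_t / dt)
  i_end <- round(t / dt) + 1L
  if (i_end > length(m_j)) stop("window end beyond sampled range")
  i_start <- i_end - n_win + 1L
  if (i_start < 1L || n_win < 2L) return(0)
  stats::cov(m_j[i_start:i_end], m_k[i_start:i_end])
}

#' Short-term plasticity right-hand side for one node pair
#'
#' @param w_EE,w_EI current gains (non-negative).
#' @param cov trailing-window covariance of the pair's excitatory rates.
#' @param alpha,beta Gaussian mask values for the pair.
#' @param params an [stp_params()] object.
#' @return named vector `c(dw_EE, dw_EI)` (gain per second).
#' @export
stp_rhs <- function(w_EE, w_EI, cov, alpha, beta, params = stp_params()) {
  g <- params$gain_scale * params$eta
  c(dw_EE = (-w_EE + g * alpha * max(cov, 0)) / params$tau_w,
    dw_EI = (-w_EI + g * beta * abs(min(cov, 0))) / params$tau_w)
}
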