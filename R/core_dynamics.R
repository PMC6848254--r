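#' Synaptic kernel parameters
#'
#' Parameters of the synaptic impulse response (rate-to-potential operator)
#' of one neural population: `h(t) = (H/tau) * t * exp(-t/tau)` for `t >= 0`.
#' Defaults are the classical excitatory values (`H = 3.25` mV,
#' `tau = 10` ms); the inhibitory kernel uses `H = 22` mV, `tau = 20` ms.
#' All quantities are kept in SI units internally (seconds, mV); the
#' constructor accepts seconds.
#'
#' @param H average synaptic gain in mV (peak of the kernel is `H/e`).
#' @param tau synaptic time constant in seconds (kernel peaks at `t = tau`).
#' @return An object of class `"synapse_params"` with fields `H` and `tau`.
#' @examples
#' synapse_params()                  # excitatory defaults
#' synapse_params(H = 22, tau = 0.02)  # inhibitory defaults
#' @export
synapse_params <- function(H = 3.25, tau = 0.010) {
  stopifnot(is.numeric(H), is.numeric(tau), length(H) == 1L, length(tau) == 1L)
  if (!(H > 0)) stop("synaptic gain H must be > 0")
  if (!(tau > 0)) stop("time constant tau must be > 0")
  structure(list(H = H, tau = tau), class = "synapse_params")
}

#' Sigmoid (potential-to-rate) parameters
#'
#' The firing-rate nonlinearity `S(v) = 2*e0 / (1 + exp(r*(v0 - v)))`, a
#' logistic curve with half-maximum `e0` at the threshold potential `v0`.
#'
#' @param e0 half-maximum firing rate (spikes/s); the rate saturates at `2*e0`.
#' @param r sigmoid slope (1/mV).
#' @param v0 firing threshold potential (mV).
#' @return An object of class `"sigmoid_params"`.
#' @export
sigmoid_params <- function(e0 = 2.5, r = 0.56, v0 = 6) {
  stopifnot(length(e0) == 1L, length(r) == 1L, length(v0) == 1L)
  if (!(e0 > 0)) stop("e0 must be > 0")
  if (!(r > 0)) stop("r must be > 0")
  structure(list(e0 = e0, r = r, v0 = v0), class = "sigmoid_params")
}

#' Potential-to-rate sigmoid
#'
#' Converts a mean membrane potential into a mean population firing rate.
#' Strictly increasing in `v` and bounded in `(0, 2*e0)`.
#'
#' @param v membrane potential (mV); vectorized.
#' @param params a [sigmoid_params()] object.
#' @return firing rate(s) in spikes/s.
#' @examples
#' sigmoid_rate(6)    # at threshold: exactly e0 = 2.5 spikes/s
#' sigmoid_rate(0)    # far below threshold: ~0.168 spikes/s
#' @export
sigmoid_rate <- function(v, params = sigmoid_params()) {
  2 * params$e0 / (1 + exp(params$r * (params$v0 - v)))
}

#' Synaptic impulse response (PSP kernel)
#'
#' The post-synaptic potential evoked by a unit pre-synaptic impulse:
#' `h(t) = (H/tau) * t * exp(-t/tau)` gated by the Heaviside step, so exactly
#' zero for `t < 0`.  Unimodal with maximum `H/e` at `t = tau`; its integral
#' over `[0, Inf)` is `H*tau`, which fixes the steady-state gain of the
#' rate-to-potential transformation.
#'
#' @param t time in seconds; vectorized.
#' @param params a [synapse_params()] object.
#' @return kernel value(s) in mV.
#' @export
psp_kernel <- function(t, params = synapse_params()) {
  ifelse(t >= 0, params$H / params$tau * t * exp(-t / params$tau), 0)
}

#' Right-hand side of the synaptic kernel ODE pair
#'
#' The convolution `v = x (*) h` is equivalent to the linear second-order
#' system `dv/dt = u`, `du/dt = (H/tau)*x - (2/tau)*u - v/tau^2`, which is
#' what the network integrator solves.  Exposed for testing and for building
#' custom integrators.
#'
#' @param state numeric vector `c(v, u)` (mV, mV/s).
#' @param input_rate pre-synaptic firing rate `x` (spikes/s).
#' @param params a [synapse_params()] object.
#' @return numeric vector `c(dv/dt, du/dt)`.
#' @export
kernel_ode_rhs <- function(state, input_rate, params = synapse_params()) {
  v <- state[[1]]; u <- state[[2]]
  c(u, params$H / params$tau * input_rate - 2 / params$tau * u - v / params$tau^2)
}
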