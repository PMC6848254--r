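#' Network configuration
#'
#' Assembles an `N`-node, `M`-input network of two-population (one
#' excitatory, one inhibitory) neural masses.  Populations interact through
#' firing rates via four `N x N` non-negative gain matrices and receive up to
#' `M` external rate inputs through `W_EX` (to the excitatory population) and
#' `W_IX` (to the inhibitory population).  All excitatory populations are
#' driven by a constant background rate `B`.
#'
#' Matrix element `W[j, k]` is the gain from node `k` to node `j`
#' (`W_EI[j, k]`: inhibitory population of `k` onto the excitatory population
#' of `j`).  Synaptic kernels may be heterogeneous across nodes (needed for
#' oscillator banks); scalars are recycled.
#'
#' @param W_EE,W_IE,W_EI,W_II `N x N` non-negative weight matrices
#'   (E-to-E, E-to-I, I-to-E, I-to-I).
#' @param W_EX,W_IX `N x M` non-negative external input weight matrices.  If
#'   `W_IX` is `NULL` it defaults to `0.5 * W_EX`.
#' @param B constant background drive to the excitatory populations
#'   (spikes/s); scalar or length-`N` vector.
#' @param H_e,tau_e,H_i,tau_i synaptic kernel parameters, each a scalar or
#'   length-`N` vector (mV and seconds).
#' @param sigmoid a [sigmoid_params()] object shared by all populations.
#' @return An object of class `"network_config"`.
#' @seealso [default_node_config()], [two_node_config()], [simulate_network()]
#' @export
network_config <- function(W_EE, W_IE, W_EI, W_II,
                           W_EX = NULL, W_IX = NULL, B = 550,
                           H_e = 3.25, tau_e = 0.010,
                           H_i = 22, tau_i = 0.020,
                           sigmoid = sigmoid_params()) {
  W_EE <- as.matrix(W_EE)
  N <- nrow(W_EE)
  chk <- function(W, nm, nc = N) {
    W <- as.matrix(W)
    if (nrow(W) != N || ncol(W) != nc)
      stop(sprintf("%s must be %d x %d, got %d x %d", nm, N, nc, nrow(W), ncol(W)))
    if (any(!is.finite(W)) || any(W < 0))
      stop(sprintf("%s must be finite and non-negative", nm))
    W
  }
  W_EE <- chk(W_EE, "W_EE"); W_IE <- chk(W_IE, "W_IE")
  W_EI <- chk(W_EI, "W_EI"); W_II <- chk(W_II, "W_II")
  if (is.null(W_EX)) W_EX <- matrix(0, N, 1)
  W_EX <- as.matrix(W_EX)
  M <- ncol(W_EX)
  W_EX <- chk(W_EX, "W_EX", M)
  if (is.null(W_IX)) W_IX <- 0.5 * W_EX
  W_IX <- chk(W_IX, "W_IX", M)
  rep_n <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, N)
    if (length(x) != N || any(!is.finite(x)) || any(x <= 0 & nm != "B") ||
        (nm == "B" && any(x < 0)))
      stop(sprintf("%s must be positive scalar or length-%d vector", nm, N))
    x
  }
  B <- rep_n(B, "B")
  H_e <- rep_n(H_e, "H_e"); tau_e <- rep_n(tau_e, "tau_e")
  H_i <- rep_n(H_i, "H_i"); tau_i <- rep_n(tau_i, "tau_i")
  stopifnot(inherits(sigmoid, "sigmoid_params"))
  structure(list(N = N, M = M,
                 W_EE = W_EE, W_IE = W_IE, W_EI = W_EI, W_II = W_II,
                 W_EX = W_EX, W_IX = W_IX, B = B,
                 H_e = H_e, tau_e = tau_e, H_i = H_i, tau_i = tau_i,
                 sigmoid = sigmoid),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> %d node(s), %d input channel(s)\n", x$N, x$M))
  cat(sprintf("  intra/inter E->E gain range: [%.3g, %.3g]\n",
              min(x$W_EE), max(x$W_EE)))
  cat(sprintf("  background drive B: %s spikes/s\n",
              paste(unique(signif(x$B, 4)), collapse = ", ")))
  invisible(x)
}

# Global connectivity gain scale: all connection gains in the standard
# configuration are multiples of this number.
.gain_scale <- 135

# Standard intra-node gain ratios (E->E, E->I, I->E, I->I).
.intra_ratio <- c(EE = 0.8, IE = 0.6, EI = 0.2, II = 0.05)

#' Standard single-node configuration
#'
#' One node with the standard parameter set: intra-node gains
#' `135 * (0.8, 0.6, 0.2, 0.05)`, excitatory kernel (3.25 mV, 10 ms),
#' inhibitory kernel (22 mV, 20 ms), sigmoid (2.5 spikes/s, 0.56 /mV, 6 mV),
#' external weights `w_EX = 220 * 0.2 = 44`, `w_IX = 0.5 * w_EX = 22`, and
#' background drive `B = 220 * 2.5 = 550` spikes/s.  With these values an
#' isolated node sits near a Hopf bifurcation: it is quiescent under weak
#' excitatory drive and oscillates as the drive grows.
#'
#' @param input whether to attach the standard external input channel.
#' @return A single-node `"network_config"`.
#' @export
default_node_config <- function(input = TRUE) {
  g <- .gain_scale * .intra_ratio
  network_config(W_EE = matrix(g[["EE"]]), W_IE = matrix(g[["IE"]]),
                 W_EI = matrix(g[["EI"]]), W_II = matrix(g[["II"]]),
                 W_EX = matrix(if (input) 220 * 0.2 else 0),
                 W_IX = matrix(if (input) 220 * 0.1 else 0),
                 B = 220 * 2.5)
}

#' Two-node change-detector configuration
#'
#' Builds the canonical two-node network used to study change detection:
#' node 1 (the regularity node) receives the external stimulus with the
#' standard external weights, node 2 (the change detector) receives no
#' direct input, and the eight inter-node gains are free parameters.
#'
#' @param w21 length-4 vector of gains from node 1 onto node 2, in order
#'   `(EE, IE, EI, II)` (absolute gains, i.e. already multiplied by 135).
#' @param w12 length-4 vector of gains from node 2 onto node 1, same order.
#' @param w_EX1,w_IX1 external weights onto node 1.
#' @return A two-node `"network_config"` with one input channel.
#' @export
two_node_config <- function(w21 = c(0, 0, 0, 0), w12 = c(0, 0, 0, 0),
                            w_EX1 = 220 * 0.2, w_IX1 = 220 * 0.1) {
  stopifnot(length(w21) == 4L, length(w12) == 4L)
  g <- .gain_scale * .intra_ratio
  mk <- function(intra, a21, a12)
    matrix(c(intra, a21, a12, intra), 2, 2)   # [j,k]: column k = source
  network_config(
    W_EE = mk(g[["EE"]], w21[1], w12[1]),
    W_IE = mk(g[["IE"]], w21[2], w12[2]),
    W_EI = mk(g[["EI"]], w21[3], w12[3]),
    W_II = mk(g[["II"]], w21[4], w12[4]),
    W_EX = matrix(c(w_EX1, 0), 2, 1),
    W_IX = matrix(c(w_IX1, 0), 2, 1))
}
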