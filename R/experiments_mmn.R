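#' Sequence mismatch-negativity (roving paradigm) simulation
#'
#' A three-node network mimics cortical responses to transitions between
#' random (RAND) and regular (REG) sound sequences: node 1 receives the
#' RAND envelope, node 2 the REG envelope (identical amplitude and ramps by
#' construction), and node 3 is the change detector coupled to both.  The
#' detector-side weights are drawn from the On/Off solution set of the
#' two-node scan; the connections between the two regularity nodes are
#' asymmetric and shape both the level difference between REG and RAND
#' blocks and the elimination of the transient at the RAND-to-REG
#' transition, so that the simulated MEG shows (1) onset/offset
#' transients, (2) a transient at REG-to-RAND, (3) no transient at
#' RAND-to-REG, and (4) higher RMS amplitude during REG than during RAND.
#'
#' @param w_reg_C length-8 weight vector coupling the REG node and the
#'   detector (`[1:4]` REG onto C as `(EE, IE, EI, II)`, `[5:8]` C onto
#'   REG); default drawn from the scan's Inc-OnOff solutions.
#' @param w_rand_C length-8 weight vector coupling the RAND node and the
#'   detector, same layout.
#' @param w_12,w_21 length-4 gain vectors between the regularity nodes
#'   (node 1 RAND, node 2 REG; `w_21` is RAND onto REG); deliberately
#'   asymmetric.
#' @param spans list with elements `rand` and `reg`, each a list of
#'   `c(onset, offset)` spans (seconds), non-overlapping across channels.
#' @param b_C MEG weight on the detector node.
#' @param rms_window RMS envelope window (seconds).
#' @param dt,settle solver settings.
#' @return An object of class `"mmn_experiment"`: `time`, `meg`, `rms`
#'   (baseline-subtracted RMS envelope), `events` (transition times), and
#'   `metrics` with the REG->RAND / RAND->REG transition prominences and
#'   the REG / RAND plateau RMS levels.
#' @export
example4_mmn <- function(w_reg_C = c(27, 0, 27, 0, 27, 0, 0, 13.5),
                         w_rand_C = c(0, 0, 27, 0, 13.5, 0, 13.5, 13.5),
                         w_12 = c(0, 0, 0, 0), w_21 = c(0, 0, 0, 0),
                         spans = list(rand = list(c(0, 3), c(6, 9)),
                                      reg = list(c(3, 6))),
                         b_C = 0.8, rms_window = 0.3,
                         dt = 5e-4, settle = 2) {
  stopifnot(length(w_reg_C) == 8, length(w_rand_C) == 8,
            length(w_12) == 4, length(w_21) == 4)
  g <- .gain_scale * .intra_ratio
  mk <- function(nm, i) {
    W <- diag(rep(g[[nm]], 3))
    W[3, 1] <- w_rand_C[i]; W[1, 3] <- w_rand_C[i + 4]
    W[3, 2] <- w_reg_C[i]; W[2, 3] <- w_reg_C[i + 4]
    W[2, 1] <- w_21[i]; W[1, 2] <- w_12[i]
    W
  }
  cfg <- network_config(
    W_EE = mk("EE", 1), W_IE = mk("IE", 2), W_EI = mk("EI", 3),
    W_II = mk("II", 4),
    W_EX = rbind(c(0, 44), c(44, 0), c(0, 0)),   # ch1 = REG, ch2 = RAND
    W_IX = rbind(c(0, 22), c(22, 0), c(0, 0)),
    B = 220 * 2.5)
  st <- sequence_pair(spans$reg, spans$rand)
  all_t <- c(unlist(spans$reg), unlist(spans$rand))
  t0 <- min(all_t) - 1; t1 <- max(all_t) + 1.5
  r <- simulate_network(cfg, st, t_span = c(t0, t1), dt = dt, settle = settle)
  R <- meg_signal(r, meg_weights(c((1 - b_C) / 2, (1 - b_C) / 2, b_C)))
  base <- mean(R[r$time < min(all_t) - 0.2])
  rms <- rms_envelope(R - base, rms_window, dt)

  # transition events: REG->RAND when a reg span ends where a rand span
  # starts, and vice versa
  ends <- function(ch) vapply(spans[[ch]], `[[`, 0, 2L)
  starts <- function(ch) vapply(spans[[ch]], `[[`, 0, 1L)
  reg_to_rand <- intersect(ends("reg"), starts("rand"))
  rand_to_reg <- intersect(ends("rand"), starts("reg"))

  win_max <- function(a, b) if (a < b) max(rms[r$time > a & r$time < b]) else NA_real_
  win_mean <- function(a, b) mean(rms[r$time > a & r$time < b])
  plateau <- function(ch) mean(vapply(spans[[ch]], function(sp)
    win_mean(sp[1] + 0.8, sp[2] - 0.3), 0))
  prominence <- function(tt) {
    # transition transient: peak RMS within 0.5 s after the switch minus
    # the larger of the two flanking plateau levels
    pk <- win_max(tt, tt + 0.5)
    fl <- max(win_mean(tt - 1.0, tt - 0.3), win_mean(tt + 0.8, tt + 1.5))
    pk - fl
  }
  metrics <- list(
    reg_to_rand_prominence = if (length(reg_to_rand))
      max(vapply(reg_to_rand, prominence, 0)) else NA_real_,
    rand_to_reg_prominence = if (length(rand_to_reg))
      max(vapply(rand_to_reg, prominence, 0)) else NA_real_,
    reg_rms = plateau("reg"), rand_rms = plateau("rand"),
    onset_prominence = win_max(min(all_t), min(all_t) + 0.5) -
      win_mean(min(all_t) - 0.8, min(all_t) - 0.1),
    offset_prominence = win_max(max(all_t), max(all_t) + 0.5) -
      win_mean(max(all_t) + 0.8, max(all_t) + 1.4))
  structure(list(time = r$time, meg = R, rms = rms, result = r,
                 events = list(reg_to_rand = reg_to_rand,
                               rand_to_reg = rand_to_reg),
                 metrics = metrics, config = cfg),
            class = "mmn_experiment")
}

#' @export
print.mmn_experiment <- function(x, ...) {
  m <- x$metrics
  cat("<mmn_experiment>\n")
  cat(sprintf("  REG->RAND transient prominence: %.2f\n", m$reg_to_rand_prominence))
  cat(sprintf("  RAND->REG transient prominence: %.2f\n", m$rand_to_reg_prominence))
  cat(sprintf("  plateau RMS: REG %.2f vs RAND %.2f\n", m$reg_rms, m$rand_rms))
  invisible(x)
}
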