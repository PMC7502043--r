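# Sequence propagation.
#
# Every building block of the sequence (pulse sample, gap, spoiler, RF
# rotation, free evolution) is affine in the 4-component state,
# M_out = Phi %*% M_in + b, so modules are composed once per parameter set
# and replayed cheaply across heartbeats.

affine_identity <- function() list(Phi = diag(4), b = numeric(4))

# apply a1 first, then a2
affine_compose <- function(a2, a1) {
  list(Phi = a2$Phi %*% a1$Phi, b = as.numeric(a2$Phi %*% a1$b) + a2$b)
}

affine_apply <- function(a, M) {
  out <- as.numeric(a$Phi %*% as.numeric(M)) + a$b
  names(out) <- c("MxA", "MyA", "MzA", "MzB")
  structure(out, class = "mag_state")
}

affine_spoil <- function() list(Phi = diag(c(0, 0, 1, 1)), b = numeric(4))

# instantaneous rotation of the free pool; bound pool untouched
affine_rotation <- function(flip_deg, phase_deg = 0) {
  a <- flip_deg * pi / 180
  p <- phase_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a), sin(a)), c(0, -sin(a), cos(a)))
  rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                          c(0, 0, 1))
  r3 <- rz(p) %*% rx %*% rz(-p)
  Phi <- diag(4)
  Phi[1:3, 1:3] <- r3
  list(Phi = Phi, b = numeric(4))
}

free_affine <- function(tissue, b0, duration) {
  .bmc_free_affine(tissue_vec(tissue), b0, duration)
}

pulse_affine <- function(pulse, tissue, b0) {
  f_eff <- pulse$offset + b0
  G <- super_lorentzian_G(f_eff, tissue$T2_bound)
  .bmc_pulse_affine(tissue_vec(tissue), Re(pulse$omega1), Im(pulse$omega1),
                    f_eff, G, pulse$dt)
}

#' Propagate the two-pool state over one interval
#'
#' Exact solution of the two-pool Bloch-McConnell system over an interval
#' `dt` with constant RF amplitude, via the matrix exponential of the
#' augmented linear system.  The free pool precesses at `delta_f + b0`; the
#' bound-pool saturation rate uses the super-Lorentzian lineshape at the
#' same effective offset.
#'
#' @param state A [mag_state].
#' @param tissue A [tissue_params].
#' @param omega1 Complex RF amplitude (rad/s), constant over the interval.
#' @param delta_f RF carrier offset (Hz).
#' @param b0 Additional B0 off-resonance (Hz).
#' @param dt Interval length (seconds), at most 100 us when `omega1 != 0`.
#' @return The propagated [mag_state].
#' @export
propagate <- function(state, tissue, omega1 = 0 + 0i, delta_f = 0, b0 = 0,
                      dt = 50e-6) {
  if (!all(is.finite(state))) stop("non-finite magnetization state")
  if (Mod(omega1) > 0 && dt > 100e-6)
    stop("dt must be at most 100 us while RF is on")
  f_eff <- delta_f + b0
  G <- if (Mod(omega1) > 0) super_lorentzian_G(f_eff, tissue$T2_bound) else 0
  a <- .bmc_pulse_affine(tissue_vec(tissue), Re(omega1), Im(omega1),
                         f_eff, G, dt)
  affine_apply(a, state)
}

# affine map of the whole MT preparation train (cached by callers)
mt_prep_affine <- function(prep, tissue, b0) {
  if (prep$n_pulses == 0L) return(affine_identity())
  a_pulse <- pulse_affine(prep$pulse, tissue, b0)
  a_gap <- if (prep$gap > 0) free_affine(tissue, b0, prep$gap) else
    affine_identity()
  if (prep$spoil_in_gap) a_gap <- affine_compose(affine_spoil(), a_gap)
  a_unit <- affine_compose(a_gap, a_pulse)
  a <- affine_identity()
  for (i in seq_len(prep$n_pulses)) a <- affine_compose(a_unit, a)
  a
}

mt_prep_duration <- function(prep) {
  if (is.null(prep)) 0 else
    prep$n_pulses * (prep$pulse$duration + prep$gap)
}

#' Apply an MT preparation train to a state
#'
#' Propagates the state through `n_pulses` shaped off-resonance pulses with
#' piecewise-constant amplitude, each followed by a gap of relaxation and
#' exchange; with `spoil_in_gap` the free-pool transverse components are
#' zeroed at the end of each gap.
#'
#' @param state A [mag_state].
#' @param prep An [mt_preparation].
#' @inheritParams propagate
#' @return The propagated [mag_state].
#' @export
apply_mt_preparation <- function(state, prep, tissue, b0 = 0) {
  if (!all(is.finite(state))) stop("non-finite magnetization state")
  affine_apply(mt_prep_affine(prep, tissue, b0), state)
}

# Precomputed per-TR operators for the imaging module.
imaging_ops <- function(imaging, tissue, b0) {
  n <- imaging$n_startup + imaging$profiles_per_beat
  flips <- rep(imaging$flip, n)
  if (imaging$variant == "bSSFP" && imaging$startup_ramp &&
      imaging$n_startup > 0) {
    flips[seq_len(imaging$n_startup)] <-
      imaging$flip * seq_len(imaging$n_startup) / imaging$n_startup
  }
  phases <- (seq_len(n) - 1) * imaging$rf_phase_cycling
  list(
    n = n,
    rots = lapply(seq_len(n), function(i) affine_rotation(flips[i], phases[i])),
    a_te = free_affine(tissue, b0, imaging$TE),
    a_rest = free_affine(tissue, b0, imaging$TR - imaging$TE),
    spoil = imaging$variant == "SPGR",
    echo = imaging$echo_index,
    duration = n * imaging$TR)
}

run_imaging_ops <- function(M, ops) {
  signal <- NA_real_
  sp <- affine_spoil()
  for (i in seq_len(ops$n)) {
    M <- affine_apply(ops$rots[[i]], M)
    M <- affine_apply(ops$a_te, M)
    if (i == ops$echo) signal <- sqrt(M[1]^2 + M[2]^2)
    M <- affine_apply(ops$a_rest, M)
    if (ops$spoil) M <- affine_apply(sp, M)
  }
  list(signal = unname(signal), state = M)
}

#' Run one imaging module
#'
#' RF pulses are instantaneous rotations of the free pool only (the bound
#' pool is untouched during the rotation, a single-pool assumption for the
#' short imaging pulses); between pulses the full two-pool system relaxes,
#' exchanges and precesses at `b0`.  SPGR spoils the transverse free pool at
#' the end of every TR; bSSFP does not and alternates the RF phase.  The
#' signal is the free-pool transverse magnitude at TE after the
#' `echo_index`-th pulse.
#'
#' @param state A [mag_state].
#' @param imaging An [imaging_module].
#' @inheritParams propagate
#' @return A list with `signal` (dimensionless) and the post-module `state`.
#' @export
run_imaging_module <- function(state, imaging, tissue, b0 = 0) {
  ops <- imaging_ops(imaging, tissue, b0)
  run_imaging_ops(state, ops)
}

#' Simulate the full MTR acquisition
#'
#' Per heartbeat: the MT preparation (if any), the imaging module, then free
#' evolution for the remainder of the RR interval.  Returns the echo signal
#' from `protocol$measure_beat` (the fifth beat by default, where the
#' sequence has settled into its pseudo steady state).
#'
#' @param tissue A [tissue_params].
#' @param prep An [mt_preparation], or `NULL` for the reference (REF)
#'   acquisition without preparation.
#' @param imaging An [imaging_module].
#' @param protocol A [sim_protocol].
#' @return The echo signal (dimensionless scalar).
#' @examples
#' tis <- myocardium_tissue()
#' s_ref <- simulate_sequence(tis, NULL, spgr_module(), sim_protocol())
#' s_mt  <- simulate_sequence(tis, human_mt_prep(), spgr_module(), sim_protocol())
#' compute_mtr(s_mt, s_ref)
#' @export
simulate_sequence <- function(tissue, prep, imaging, protocol) {
  rr <- 60 / protocol$heart_rate
  b0 <- protocol$b0_offset
  ops <- imaging_ops(imaging, tissue, b0)
  t_prep <- mt_prep_duration(prep)
  t_rest <- rr - t_prep - ops$duration
  if (t_rest < 0)
    stop("heart period shorter than preparation plus imaging module")
  a_prep <- if (is.null(prep)) NULL else mt_prep_affine(prep, tissue, b0)
  a_rest <- free_affine(tissue, b0, t_rest)
  M <- equilibrium_state(tissue)
  signal <- NA_real_
  for (beat in seq_len(protocol$n_heartbeats)) {
    if (!is.null(a_prep)) M <- affine_apply(a_prep, M)
    res <- run_imaging_ops(M, ops)
    M <- res$state
    if (beat == protocol$measure_beat) signal <- res$signal
    M <- affine_apply(a_rest, M)
  }
  signal
}

#' Magnetization transfer ratio
#'
#' `MTR = 100 * (1 - S_MT / S_REF)` in percent, from the MT-prepared and
#' reference signals.
#'
#' @param signal_mt,signal_ref Signals (same arbitrary units); vectorized.
#' @return MTR in percent.
#' @examples
#' compute_mtr(0.75, 1.0)
#' @export
compute_mtr <- function(signal_mt, signal_ref) {
  if (any(signal_ref <= 0)) stop("reference signal must be positive")
  100 * (1 - signal_mt / signal_ref)
}
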