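#' Two-pool tissue parameters
#'
#' Constants of the two-pool magnetization-transfer model: a free (liquid)
#' pool `A` with relaxation times `T1_free`/`T2_free` and a semisolid bound
#' pool `B` with microsecond-scale `T2_bound`.  The equilibrium convention is
#' `M0A = 1 - psr`, `M0B = psr`, so `psr = M0B / (M0A + M0B)` is the pool
#' size ratio.  `exchange_rate` is the fundamental exchange rate constant R
#' (Hz); the pseudo-first-order rates are `R * M0B` (free to bound) and
#' `R * M0A` (bound to free).
#'
#' @param T1_free,T2_free Free-pool relaxation times (seconds).
#' @param psr Pool size ratio, in `[0, 1)`.
#' @param exchange_rate Exchange rate constant R (Hz), `>= 0`.
#' @param T1_bound Bound-pool T1 (seconds).  Not measurable in tissue and
#'   conventionally fixed at 1 s.
#' @param T2_bound Bound-pool T2 (seconds); default 14 microseconds.
#' @return A `tissue_params` list.
#' @examples
#' myocardium_tissue()
#' @export
tissue_params <- function(T1_free, T2_free, psr, exchange_rate,
                          T1_bound = 1.0, T2_bound = 14e-6) {
  stopifnot(T1_free > 0, T2_free > 0, T1_bound > 0, T2_bound > 0,
            psr >= 0, psr < 1, exchange_rate >= 0)
  structure(list(T1_free = T1_free, T2_free = T2_free,
                 T1_bound = T1_bound, T2_bound = T2_bound,
                 psr = psr, exchange_rate = exchange_rate),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf(
    "<tissue_params> T1/T2 free = %.0f/%.1f ms, PSR = %.1f%%, R = %.0f Hz, T2 bound = %.1f us\n",
    1e3 * x$T1_free, 1e3 * x$T2_free, 100 * x$psr, x$exchange_rate,
    1e6 * x$T2_bound))
  invisible(x)
}

#' @rdname tissue_params
#' @details `myocardium_tissue()` returns the myocardium-like reference
#'   parameter set used throughout the simulations: T1/T2 = 1100/55 ms,
#'   PSR 15%, R = 50 Hz, bound-pool T2 = 14 us.
#' @export
myocardium_tissue <- function() {
  tissue_params(T1_free = 1.1, T2_free = 0.055, psr = 0.15, exchange_rate = 50)
}

# internal: parameter vector for the compiled core
tissue_vec <- function(tissue) {
  c(tissue$T1_free, tissue$T2_free, tissue$T1_bound, tissue$T2_bound,
    tissue$psr, tissue$exchange_rate)
}

#' Magnetization state
#'
#' The 4-component state propagated through the sequence: free-pool
#' transverse (`MxA`, `MyA`) and longitudinal (`MzA`) components plus the
#' bound-pool longitudinal component (`MzB`), as fractions of the total
#' equilibrium magnetization.
#'
#' @param MxA,MyA,MzA,MzB Components (dimensionless).
#' @return A named numeric vector of class `mag_state`.
#' @export
mag_state <- function(MxA = 0, MyA = 0, MzA = 1, MzB = 0) {
  m <- c(MxA = MxA, MyA = MyA, MzA = MzA, MzB = MzB)
  if (!all(is.finite(m))) stop("magnetization state must be finite")
  structure(m, class = "mag_state")
}

#' @rdname mag_state
#' @param tissue A [tissue_params] object.
#' @details `equilibrium_state()` returns thermal equilibrium
#'   `(0, 0, 1 - psr, psr)`.
#' @export
equilibrium_state <- function(tissue) {
  mag_state(0, 0, 1 - tissue$psr, tissue$psr)
}

#' Shaped RF pulse
#'
#' `make_sinc_pulse()` builds a Hann-apodized symmetric sinc pulse with
#' time-bandwidth product `duration * bandwidth`, sampled at step `dt`.
#' The amplitude is scaled so that `sum(abs(omega1)) * dt` equals the
#' nominal flip angle in radians.  The carrier offset is carried as
#' metadata; precession at the effective offset is applied during
#' propagation.
#'
#' @param flip Nominal flip angle (degrees).
#' @param duration Pulse length (seconds).
#' @param bandwidth Pulse bandwidth (Hz).
#' @param dt Sample step (seconds), at most 100 us.
#' @param offset Carrier off-resonance frequency (Hz).
#' @return An `rf_pulse` list with complex samples `omega1` (rad/s).
#' @examples
#' p <- make_sinc_pulse(flip = 720, duration = 20.48e-3, bandwidth = 270)
#' sum(abs(p$omega1)) * p$dt / pi  # integral of |omega1| dt, in units of pi
#' @export
make_sinc_pulse <- function(flip, duration, bandwidth, dt = 50e-6,
                            offset = 0) {
  if (duration <= 0 || bandwidth <= 0 || dt <= 0)
    stop("duration, bandwidth and dt must be positive")
  if (dt > 100e-6)
    stop("dt must be at most 100 us for piecewise-constant propagation")
  n <- max(2L, as.integer(ceiling(duration / dt)))
  dt_eff <- duration / n
  t <- (seq_len(n) - 0.5) / n * duration - duration / 2  # sample centres
  x <- bandwidth * t
  shape <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
  hann <- 0.5 * (1 + cos(2 * pi * t / duration))
  w <- shape * hann
  flip_rad <- flip * pi / 180
  area <- sum(abs(w)) * dt_eff
  omega1 <- if (flip_rad == 0) complex(real = w * 0) else
    as.complex(w * flip_rad / area)
  structure(list(omega1 = omega1, dt = dt_eff, flip = flip,
                 duration = duration, bandwidth = bandwidth,
                 shape = "sinc", offset = offset),
            class = "rf_pulse")
}

#' MT preparation module
#'
#' A train of identical off-resonance pulses separated by gaps in which only
#' relaxation and exchange act; with `spoil_in_gap` the free-pool transverse
#' magnetization is zeroed at the end of each gap (ideal spoiler gradients).
#'
#' @param pulse An [make_sinc_pulse] `rf_pulse`.
#' @param n_pulses Number of pulses (`>= 0`).
#' @param gap Pause between pulses (seconds).
#' @param spoil_in_gap Zero transverse free-pool magnetization in each gap.
#' @return An `mt_preparation` list.
#' @export
mt_preparation <- function(pulse, n_pulses = 20, gap = 1.5e-3,
                           spoil_in_gap = TRUE) {
  stopifnot(inherits(pulse, "rf_pulse"), n_pulses >= 0, gap >= 0)
  structure(list(pulse = pulse, n_pulses = as.integer(n_pulses), gap = gap,
                 spoil_in_gap = spoil_in_gap),
            class = "mt_preparation")
}

#' @rdname mt_preparation
#' @param delta_f Off-resonance frequency of the pulses (Hz).
#' @param mt_flip Per-pulse flip angle (degrees).
#' @details `human_mt_prep()` and `animal_mt_prep()` return the two study
#'   protocols: 20 pulses at 3000 Hz / 800 deg, and 10 pulses at
#'   1500 Hz / 720 deg, both 20.48 ms sinc pulses of 270 Hz bandwidth with
#'   1.5 ms spoiled gaps.
#' @export
human_mt_prep <- function(delta_f = 3000, mt_flip = 800) {
  mt_preparation(make_sinc_pulse(mt_flip, 20.48e-3, 270, offset = delta_f),
                 n_pulses = 20)
}

#' @rdname mt_preparation
#' @export
animal_mt_prep <- function(delta_f = 1500, mt_flip = 720) {
  mt_preparation(make_sinc_pulse(mt_flip, 20.48e-3, 270, offset = delta_f),
                 n_pulses = 10)
}

#' Imaging module
#'
#' Cartesian readout segment played each heartbeat: `n_startup` preparation
#' RF pulses followed by `profiles_per_beat` imaging excitations.  SPGR
#' spoils the free-pool transverse magnetization at the end of every TR;
#' bSSFP keeps it and alternates the RF phase by `rf_phase_cycling` each TR.
#' The reported signal is the free-pool transverse magnitude at TE after the
#' pulse with index `echo_index` (the k-space-centre profile).
#'
#' @param variant `"SPGR"` or `"bSSFP"`.
#' @param TR,TE Repetition and echo time (seconds).
#' @param flip Imaging flip angle (degrees).
#' @param n_startup Start-up pulses before sampling (default 14).
#' @param echo_index 1-based index of the measured echo (default 15, the
#'   first sampled profile).
#' @param profiles_per_beat Sampled profiles per heartbeat (default 30).
#' @param startup_ramp bSSFP only: linear flip-angle ramp over the start-up
#'   pulses.
#' @param rf_phase_cycling RF phase increment per TR (degrees; bSSFP: 180).
#' @return An `imaging_module` list.
#' @export
imaging_module <- function(variant = c("SPGR", "bSSFP"), TR, TE, flip,
                           n_startup = 14, echo_index = 15,
                           profiles_per_beat = 30,
                           startup_ramp = (variant[1] == "bSSFP"),
                           rf_phase_cycling = if (variant[1] == "bSSFP") 180 else 0) {
  variant <- match.arg(variant)
  stopifnot(TR > 0, TE > 0, TE < TR, flip >= 0)
  if (echo_index > n_startup + profiles_per_beat)
    stop("echo_index exceeds the number of pulses in the module")
  structure(list(variant = variant, TR = TR, TE = TE, flip = flip,
                 n_startup = as.integer(n_startup),
                 echo_index = as.integer(echo_index),
                 profiles_per_beat = as.integer(profiles_per_beat),
                 startup_ramp = isTRUE(startup_ramp),
                 rf_phase_cycling = rf_phase_cycling),
            class = "imaging_module")
}

#' @rdname imaging_module
#' @details `spgr_module()` (TR/TE 3.8/1.6 ms, 15 deg) and `bssfp_module()`
#'   (TR/TE 3.2/1.4 ms, 70 deg) are the two study configurations.
#' @export
spgr_module <- function(flip = 15, profiles_per_beat = 30) {
  imaging_module("SPGR", TR = 3.8e-3, TE = 1.6e-3, flip = flip,
                 profiles_per_beat = profiles_per_beat)
}

#' @rdname imaging_module
#' @export
bssfp_module <- function(flip = 70, profiles_per_beat = 30) {
  imaging_module("bSSFP", TR = 3.2e-3, TE = 1.4e-3, flip = flip,
                 profiles_per_beat = profiles_per_beat)
}

#' Simulation protocol
#'
#' ECG-gated timing of the simulated acquisition: constant heart rate, the
#' number of simulated heartbeats, a global B0 offset, and the heartbeat
#' whose echo is reported (the fifth by default, giving pseudo steady-state
#' conditions).
#'
#' @param heart_rate Heart rate (beats per minute).
#' @param n_heartbeats Number of simulated heartbeats.
#' @param b0_offset Global off-resonance (Hz).
#' @param measure_beat Heartbeat whose echo is reported.
#' @return A `sim_protocol` list.
#' @export
sim_protocol <- function(heart_rate = 65, n_heartbeats = 5, b0_offset = 0,
                         measure_beat = 5) {
  stopifnot(heart_rate > 0, n_heartbeats >= 1,
            measure_beat >= 1, measure_beat <= n_heartbeats)
  structure(list(heart_rate = heart_rate,
                 n_heartbeats = as.integer(n_heartbeats),
                 b0_offset = b0_offset,
                 measure_beat = as.integer(measure_beat)),
            class = "sim_protocol")
}
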