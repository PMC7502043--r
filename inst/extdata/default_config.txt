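# mtprep run configuration (SI units: seconds, Hz, mm, fractions)
seed = 1234

# two-pool tissue (myocardium-like)
tissue.T1_free = 1.1
tissue.T2_free = 0.055
tissue.T1_bound = 1.0
tissue.T2_bound = 14e-6
tissue.psr = 0.15
tissue.exchange_rate = 50

# MT preparation: sinc pulses
prep.delta_f = 3000
prep.mt_flip = 800
prep.n_pulses = 20
prep.duration = 20.48e-3
prep.bandwidth = 270
prep.gap = 1.5e-3
prep.dt = 50e-6
prep.spoil_in_gap = true

# imaging module
imaging.variant = SPGR
imaging.TR = 3.8e-3
imaging.TE = 1.6e-3
imaging.flip = 15
imaging.n_startup = 14
imaging.echo_index = 15
imaging.profiles_per_beat = 30

# gating
protocol.heart_rate = 65
protocol.n_heartbeats = 5
protocol.b0_offset = 0
protocol.measure_beat = 5

# synthetic acquisition
acquisition.n_coils = 4
acquisition.noise_sd = 0
acquisition.profiles_per_beat = 30

# respiratory motion model
motion.period = 4
motion.amplitude_FH = 8
motion.amplitude_LR = 2
motion.drift = 0
motion.nonrigid_amplitude = 0
motion.nonrigid_scale = 60

# analysis
analysis.floor = 0.05
analysis.smooth_kernel = 5
analysis.smooth_sigma = 3
analysis.n_bins = 4
analysis.max_bin_width = 3.5
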