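# mtprep

Contrast-free assessment of myocardial scar and cardiac vein anatomy with
3D magnetization-transfer-ratio (MTR) MRI — as a fully simulated, tested
toolkit. The package is aimed at MR physicists and image-analysis
developers who want to study or extend the method without scanner access:
every stage, from spin physics to scar statistics, runs on digital
phantoms with ground truth.

Magnetization transfer probes macromolecular (collagen-rich or
protein-rich) tissue without contrast agent: off-resonance RF saturates a
bound proton pool, exchange transfers that saturation to free water, and
the ratio

```
MTR = 100 * (1 - I_MT / I_REF)   [%]
```

between an MT-prepared and an unprepared (REF) acquisition drops where the
bound pool shrinks — notably in myocardial scar.

The package provides:

* **Two-pool Bloch-McConnell simulator** (`simulate_sequence()`,
  `mtr_sweep()`): the coupled free/bound-pool equations with a
  super-Lorentzian bound-pool lineshape (`super_lorentzian_G()`,
  `R_RFB = pi * omega1^2 * G`), solved exactly per 50 µs interval by
  matrix exponentials (compiled core), for the ECG-gated MT-prepared
  sequence with SPGR or bSSFP readouts.
* **Motion-corrected reconstruction** (`phase_shift_correct()`,
  `assign_bins()`, `cg_sense()`, `gmd_reconstruct()`,
  `coregister_pair()`): beat-to-beat translational k-space correction
  `K_cor = K_acq * exp(2i pi k·d)`, respiratory binning (3-5 bins,
  3.5 mm cap), iterative SENSE and a motion-compensated generalized
  matrix description solved by conjugate gradient.
* **Analysis metrics** (`mtr_map()`, `smooth_map()`,
  `scar_threshold_segmentation()`, `overlap_percent()`,
  `false_positive_percent()`, `aha16_labels()`, `segment_stats()`,
  `contrast_ratio()`, `vessel_sharpness()`, `cnr()`): mean-2SD scar
  thresholding, AHA 16-segment statistics, and vessel metrics.
* **Digital phantoms** (`make_agar_phantom()`, `make_cardiac_phantom()`,
  `simulate_acquisition()`): agar vials and a short-axis cardiac phantom
  with an infarct sector, veins, respiratory motion and ground truth for
  every downstream operator.
* **Workflows and CLI** (`reproduce_simulation_figures()`,
  `end_to_end_demo()`, `exec/mtprep`): reproducible sensitivity tables and
  an end-to-end phantom demonstration with a JSON metric report.

## Worked example

Simulate the human study protocol on myocardium-like tissue and sweep the
pool size ratio:

```r
library(mtprep)

tis  <- myocardium_tissue()       # T1/T2 1100/55 ms, PSR 15%, R 50 Hz
prep <- human_mt_prep()           # 20 x 20.48 ms sinc, 270 Hz BW,
                                  # 3000 Hz off-resonance, 800 deg
s_ref <- simulate_sequence(tis, NULL, spgr_module(), sim_protocol())
s_mt  <- simulate_sequence(tis, prep, spgr_module(), sim_protocol())
compute_mtr(s_mt, s_ref)
#> [1] 55.55432

sw <- mtr_sweep(tis, prep, spgr_module(), sim_protocol(),
                "psr", c(0.05, 0.10, 0.15))
sw
#>   value  signal_mt signal_ref mtr_percent
#> 1  0.05 0.06900550 0.09463721    27.08418
#> 2  0.10 0.05184605 0.09251188    43.95742
#> 3  0.15 0.04009474 0.09021067    55.55432
```

The echo signal is the free-pool transverse magnitude at the k-space
centre profile (echo 15) of the fifth heartbeat; MTR rises steeply — and
nearly linearly over the 5-15% muscle range — with the bound-pool
fraction, which is the contrast mechanism the sequence exploits.
`autoplot(sw)` draws the curve; `glance(sw)` summarizes its range.

The same engine drives the full chain on a phantom:

```r
rep <- end_to_end_demo(out_dir = "demo", grid = c(32, 32, 8))
rep$translational$overlap_percent   # thresholded scar vs ground truth
#> [1] 100
```

From a shell, the same steps are available as subcommands:

```sh
mtprep sweep --axis delta_f --min 200 --max 8000 --n 25 --out deltaf.csv
mtprep simulate-acq --out-dir acq --seed 9
mtprep moco-translational --acq-dir acq --out rec.nii
```

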