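# rrmtether

Quantitative analyses for comparing tandemly **tethered** versus
**isolated** RNA-recognition-motif (RRM) domains, the construct pair at the
heart of studies of TDP-43 and hnRNPA1 — proteins whose aggregation marks
ALS and related diseases. Tethering two RRM domains changes their
stability, dynamics and ATP binding; this package implements the analysis
chain that quantifies those changes:

* **NMR titrations** — residue-specific chemical shift perturbation
  CSD = √((Δδ_H)² + (Δδ_N)²/4) from assigned HSQC peak lists
  (Sparky-style), significance by the mean + 1 sd rule, and per-residue
  ATP dissociation constants from the one-site ligand-depletion isotherm
  CSD_obs = CSD_max · [(P + L + K_d) − √((P + L + K_d)² − 4PL)] / 2P,
  fitted by bounded Levenberg–Marquardt with multi-start.
* **Structure comparison** — Kabsch Cα superposition of tethered vs
  isolated forms over a domain's structured range, reporting per-domain
  RMSD.
* **Trajectory analysis** — per-replica RMSD series (full selection and
  domain-only overlays that expose inter-domain hinge motion),
  replica-averaged RMSF, and tethered-minus-isolated RMSF significance.
* **Correlated motions** — backbone-dihedral mutual-information matrices
  (24-bin circular histograms, shuffle-null bias correction), normalized by
  marginal entropy and thresholded at 0.3 into intra- and inter-domain
  coupling reports.
* **Thermal stability** — melting temperatures from dF/dT derivative peaks
  of DSF or fluorescence melt curves, including multi-transition curves.
* **Synthetic data** — seeded generators for titrations, replica
  trajectories (with plantable hinge motion and torsion couplings),
  correlated circular variables with analytically known mutual information,
  and two-state melt curves, each returning ground truth for recovery
  testing.

## Worked example

Simulate a titration at the standard design (50 µM protein; ATP at
0.5–20 mM over 12 points) with a true K_d of 16.7 mM, then run the analysis
chain:

```r
library(rrmtether)

tt   <- gen_titration(titration_spec(n_residues = 20, true_kd = 16.7,
                                     noise_sd = 0.005, seed = 42))
prof <- csd_profile(tt$series, at_conc = 20)
prof
#> CSD profile at 20 mM ligand: 20 residues, 0 disappeared
#>   max CSD 0.325 ppm (residue 209)

sig <- select_significant(prof)
sig
#> Significance rule: mean 0.2237 + sd 0.0728 = threshold 0.2965
#> Selected residues: 193, 194, 205, 208, 209

fit <- fit_kd_profile(tt$series, sig$selected)
fit
#> Kd fits over 5 residues (5 converged), mode 'per_residue_mean'
#> Aggregate Kd = 16.3 +/- 1.73 mM
```

The CSD profile gives each residue's peak displacement at 20 mM ATP in ppm;
the significance rule picks the five residues shifted beyond mean + 1 sd;
their independent depletion-model fits average to 16.3 ± 1.7 mM, recovering
the generating 16.7 mM within the per-residue fit scatter. Individual fits
are classed objects with the usual methods (`coef`, `predict`, `plot`,
`summary`):

```r
fit$fits[[1]]
#> One-site ligand-depletion fit (residue 193): Kd = 13.36 +/- 1.011 mM, CSDmax = 0.5122 ppm
#>   n = 12 points, [P] = 0.05 mM, RSS = 0.000299
```

A melt curve with the two-transition pattern seen for an isolated RRM1
(midpoints 51 and 57 °C) is resolved by the derivative criterion:

```r
find_tm(gen_meltcurve(melt_spec(tm_values = c(51, 57),
                                amplitudes = c(1, 1)))$curve)
#> 2 thermal unfolding transition(s): Tm = 51.2, 56.7 degC
```

End-to-end runs are config-driven and deterministic:

```r
rec <- run_titration_pipeline(list(
  out_dir   = "out",
  synthetic = list(n_residues = 8, true_kd = 7.7, noise_sd = 0, seed = 7),
  residues  = 193:200))
rec$fit$aggregate_kd   # 7.7
```

See the methods vignette (`vignettes/tandem-rrm-analyses.Rmd`) for the
models, parameter choices and the generators' scope.

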