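---
title: "Methods: tethered versus isolated tandem RRM domain analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tethered versus isolated tandem RRM domain analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmtether)
```

Tandemly tethered RNA-recognition-motif (RRM) domains, as found in TDP-43
and hnRNPA1, behave differently from the same domains expressed in
isolation: the tethered constructs are more dynamic, can couple into a
single unfolding unit, and bind ATP with slightly higher affinity. This
package implements the quantitative analyses needed to make that comparison
from four kinds of data: assigned HSQC peak lists across a ligand titration,
deposited structure coordinates, replica molecular-dynamics ensembles, and
thermal denaturation curves. A synthetic-data module generates all four with
known ground truth, so every estimator is testable end to end without any
experimental input.

## Chemical shift perturbation and significance

An amide peak's perturbation is summarised by the combined index

$$\mathrm{CSD} = \sqrt{(\Delta\delta_H)^2 + (\Delta\delta_N)^2/4},$$

in ppm, with the nitrogen difference down-weighted by two inside the square
to compensate for the wider ^15^N dispersion. Residues are called
significantly shifted when their CSD strictly exceeds the mean plus one
standard deviation of all observed CSDs. We use the sample (n − 1) standard
deviation: with the few dozen residues of a single domain the population
formula would shrink the threshold and admit borderline residues, and the
conservative choice is the safer default when the two cannot be
distinguished from published thresholds alone. Peaks that disappear during
a titration (exchange broadening) are tracked as explicit state: they are
excluded from CSD statistics and from fitting, never imputed, because
position information for them simply does not exist.

## The one-site ligand-depletion binding model

Millimolar ATP affinities are measured at 50 µM protein, so ligand depletion
is negligible — but the model does not assume it. The observed CSD at
protein concentration $P$ and total ligand $L$ is the quadratic solution
for the complex concentration:

$$\mathrm{CSD}_{obs} = \mathrm{CSD}_{max}
  \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4PL}}{2P}.$$

`fit_kd_residue()` fits $K_d$ and $\mathrm{CSD}_{max}$ by bounded
Levenberg–Marquardt least squares. Initialisation is deterministic:
$K_d^{(0)}$ = the median non-zero ligand concentration,
$\mathrm{CSD}_{max}^{(0)}$ = 1.5 × the largest observed CSD, with a
multi-start over $\{0.1, 1, 10\} \times K_d^{(0)}$; if no start converges
the result is a flagged failure, never a silent default. A flat trace is
rejected up front as unidentifiable.

Reported affinities of the form "$K_d \pm x$" can come either from
averaging independent per-residue fits or from one global fit with a shared
$K_d$; which convention produced a published number is often unstated. Both
are provided: `per_residue_mean` (the default) reports the mean ± sample sd
of converged per-residue $K_d$ values, `global_shared_kd` fits one $K_d$
with residue-specific $\mathrm{CSD}_{max}$ (via `nls` with the port
algorithm, which supports the vector-parameter bound constraints) and
reports its standard error. On clean shared-$K_d$ data the two agree; on
heterogeneous residues they answer different questions, which is why the
mode is explicit in the output.

In the weak-depletion regime the quadratic model must collapse to the
hyperbola $\mathrm{CSD}_{max} L/(L+K_d)$. We quantify agreement on the
saturation scale: the deviation $|{\rm full} - {\rm hyperbola}|$ relative
to $\mathrm{CSD}_{max}$ is bounded by $P/(4K_d)$, i.e. at most 0.25% when
$P \le K_d/100$. The pointwise ratio of the two curves is the wrong metric
here: as $L \to 0$ both predictions vanish and their ratio degrades to
$\sim P/K_d$ even though the curves are indistinguishable on any plot.

## Structure superposition

`domain_rmsd_report()` compares the fold of one domain between two
structures: intersect residue numbers inside the domain's structured range,
take Cα atoms only, superpose by Kabsch least squares (reflection-corrected
through the SVD determinant) and report the RMSD. For NMR ensembles model 1
is the default comparison model — deposited ensembles do not say which
member best represents the bundle, so the model index is exposed and users
can scan all members; published tethered-vs-isolated RMSD values
(1.63 / 0.82 Å for the TDP-43 domains) are model-choice sensitive at the
±0.3 Å level. Numbering mismatches between constructs are reconciled by a
fixed user-supplied offset; no sequence alignment is attempted, because the
constructs are the same sequence by design. Rank-degenerate coordinate sets
(collinear or coincident points) produce a warning rather than an error:
the optimal rotation is then not unique, but the minimum RMSD still is, and
it is the RMSD that is reported.

## Trajectory RMSD and RMSF

Replica trajectories are multi-model PDB files, one MODEL per frame, one
file per replica. For RMSD, every frame is superposed onto the replica's
first frame over the selection (Cα by default); the reference is a flag
(`ref = "first"` or `"mean"`) because the convention behind published MD
RMSD traces is rarely stated, and first-frame referencing is the common
default of analysis tools. The "±" accompanying a mean RMSD is the pooled
sample sd over all frames of all replicas — again one of several possible
conventions (across replica means, across time blocks), so the per-replica
series are retained in the result. No burn-in is discarded by default;
`burn_in_ns` drops a leading stretch when equilibration is visible.

Domain-overlay RMSD restricts the superposition to one domain's structured
range, excluding unstructured termini and the linker. On a two-domain
construct whose domains are internally rigid but reorient about the linker,
the full-construct RMSD is large while each overlay RMSD stays at the
thermal-noise floor — this separation is what identifies inter-domain hinge
motion as the source of elevated RMSD in a tethered construct.

RMSF is computed per replica by superposing frames onto the replica's mean
structure (obtained after an initial first-frame superposition), taking the
root time-averaged squared deviation of each atom from its mean position,
then averaging profiles over replicas. For isotropic Gaussian jitter of
per-coordinate sd $\sigma$ the closed form is
$\mathrm{RMSF} = \sqrt{3}\,\sigma$, up to a deficit of order $2/N_{atoms}$
from the six rigid-body degrees of freedom absorbed by the fit — with 100
residues that is under 1% and the closed form holds to within 3% at 2000
frames. The tethered-minus-isolated RMSF difference is thresholded with the
same mean + 1 sd rule as the CSD analysis, computed over domain residues
only; linker and terminal residues have no isolated-form counterpart and
are reported separately rather than silently dropped.

## Dihedral mutual-information coupling

Correlated motions are detected on internal coordinates: backbone
$\varphi$/$\psi$ torsions (IUPAC sign convention), computed per frame and
concatenated across replicas. Side-chain torsions are excluded by default
so the estimator runs on backbone-only data; this narrows the torsion set
relative to entropy-expansion tools that include $\chi_1$, which is one
reason fixed thresholds do not transfer exactly between implementations.

Mutual information between two torsions is the plug-in histogram estimate
$MI = H(x) + H(y) - H(x,y)$ in nats with 24 equal-width circular bins
(15°) — wide enough that a folded backbone's ~20° fluctuations span several
bins, fine enough that 1500 concatenated frames keep ≥ 10 samples per bin.
The finite-sample bias of the plug-in estimator is removed by a shuffle
null: the mean MI of 10 seeded permutations of one series is subtracted, so
independent torsions score zero on average and the null sd gives a
detection floor. This replaces the adaptive higher-order corrections of
entropy-expansion packages with a simpler, transparent construction — a
deliberate reimplementation choice, since only a normalized matrix and a
0.3 threshold are needed downstream.

The residue-pair matrix sums the four torsion-pair MIs between two
residues' $\{\varphi,\psi\}$ sets and normalizes by the smaller of the two
residues' summed marginal entropies, clipped to $[0,1]$. Normalizing by the
matrix maximum instead would force the largest element to 1 even for pure
noise and make any fixed threshold meaningless; the marginal-entropy bound
keeps 0.3 interpretable as "30% of the information one residue's backbone
state can carry". Pairs above threshold are classified intra-domain,
inter-domain or linker-involving, and the inter/intra coupling strength is
compared as a ratio of class means — the quantity behind the claim that a
tethered construct moves as one coupled dynamic unit.

## Melt-curve Tm extraction

Thermal unfolding curves are reduced to their first derivative dF/dT after
a centered moving average (default window 3 at 1 °C sampling; endpoints use
shrinking windows and one-sided differences). Transitions are derivative
peaks with prominence ≥ 0.2 × the maximum derivative, refined by parabolic
interpolation through the peak and its neighbours; a curve with no
qualifying peak reports zero transitions rather than erroring, because
"no transition in range" is a scientific result. Tm is invariant under
affine rescaling of the signal and tracks temperature-axis shifts exactly.

## What the generators emulate — and what they do not

Each generator is a pure function of its spec, seed included: identical
specs give byte-identical outputs, and the returned ground truth scores the
downstream estimator without reference to generator internals.

* **Titrations** (`gen_titration`): peaks drift from random reference
  positions along per-residue directions by the depletion-model CSD at each
  ligand concentration. Defaults follow the study design: 0.05 mM protein,
  ligand at 0.5–20 mM in 12 steps plus the 0 mM reference, shift noise
  0.005 ppm (a typical HSQC peak-position uncertainty), saturating CSDs
  drawn from 0.1–0.6 ppm. Noise is isotropic in the $(\Delta H, \Delta N/2)$
  metric, so CSD noise is approximately chi-distributed with a known scale —
  which is what makes recovery tolerances calculable.
* **Trajectories** (`gen_trajectory`): an idealised backbone (N, CA, C per
  residue, ideal bond geometry) rebuilt every frame from base torsions plus
  Gaussian torsion fluctuations (default sd 20°, the scale of backbone
  dihedral fluctuations in folded proteins). Optional features: a
  rigid-body hinge rotating everything beyond the linker midpoint about a
  fixed perpendicular axis, driven by an AR(1) angle series (correlation
  time 50 frames); Gaussian-copula coupling between chosen residue pairs'
  torsions; Cartesian jitter for closed-form RMSF checks. Desk-scale
  defaults are 100 residues and 3 replicas × 500 frames.
* **Correlated angles** (`gen_correlated_angles`): a Gaussian copula mapped
  to uniform angles, with $MI = -\tfrac12\ln(1-\rho^2)$ exactly — the
  estimator's analytic benchmark. Binning discards a few percent of this
  (3–5% at 24 bins for $\rho$ = 0.5–0.9), which is inside the estimator
  tolerance used throughout.
* **Melt curves** (`gen_meltcurve`): two-state transitions
  $f(T) = (1 + \exp[(\Delta H/R)(1/T - 1/T_m)])^{-1}$ with linear baseline
  and optional high-temperature decay mimicking dye dissociation. The
  default apparent van 't Hoff enthalpy is 700 kJ/mol, chosen so that
  dF/dT peaks have the ~5 °C widths real dye-based melts of small domains
  show — in particular, transitions 6 °C apart (the 51/57 °C pattern) are
  resolvable at 1 °C sampling, as they are on the instrument.

None of this is molecular physics: there is no force field, no solvent, no
anharmonicity, no chemical-shift prediction from structure, and no line
shapes. Passing tests therefore demonstrate that the estimators recover
known statistical structure under realistic noise — not that they would
agree with any particular experimental system.

## Numerical and design notes

* Concentrations are mM throughout; 50 µM protein enters as 0.05.
* Peak matching across titration points is by assignment (residue number),
  never spectral proximity — the lists are assigned, so no peak-tracking
  heuristic exists to go wrong. Sparky column order is w1 = ^15^N,
  w2 = ^1^H, with a flag for the flipped dialect; the on-disk format is a
  choice, as published work rarely states one.
* MI permutations are seeded and one permutation set is shared across all
  torsion pairs of a matrix — the null depends only on marginals, and
  sharing keeps a 100-residue matrix (≈ 20k torsion-pair estimates plus 10
  nulls each) around ten seconds.
* Pipelines (`run_titration_pipeline`, `run_coupling_pipeline`) are
  config-driven (R list or JSON), write CSVs plus a manifest, and are
  deterministic: the manifest omits the timestamp and output location so a
  rerun of one config is byte-identical.
* Problem sizes used in the test suite — 12-point titrations, 100-replicate
  noise studies, 3 × 500-frame ensembles, 50,000-sample MI benchmarks,
  2000-frame RMSF checks — are the package's chosen desk-scale versions of
  the study design, sized so the full suite runs in a couple of minutes.

## Known limitations

* The tethered-vs-isolated benchmark against deposited NMR structures needs
  the PDB coordinate files on disk (`inst/extdata/pdb/`); they are not
  bundled. Expect model-choice sensitivity of a few tenths of an Å.
* The 0.3 coupling threshold is calibrated to this package's
  normalization; numbers from other MI implementations are not directly
  comparable.
* Melts are treated as equilibrium two-state readouts; irreversible
  aggregation-coupled unfolding shifts apparent Tm in ways the model does
  not capture, and instrument smoothing differs from ours.
* The depletion model is single-site and non-cooperative by scope.
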