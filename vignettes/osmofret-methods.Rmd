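---
title: "Methods: quantifying disordered-protein FRET osmolarity biosensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying disordered-protein FRET osmolarity biosensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmofret)
```

# The measurement problem

Genetically encoded FRET biosensors built on an intrinsically disordered
region (IDR) sandwiched between a cyan donor (mCerulean3-class) and a yellow
acceptor (Citrine-class) report intracellular crowding and osmolarity:
hyperosmotic water loss compacts the disordered linker, shortens the
donor–acceptor distance, and raises transfer efficiency. `osmofret`
implements the complete quantitative workflow around such sensors:

* **plate-reader ratiometrics** — DxAm/DxDm ratios, control normalization,
  emission-spectrum anchoring and band ratios, donor bleedthrough
  correction, dose–response sensitivity, loess time-course smoothing;
* **FLIM/TCSPC analysis** — Poisson maximum-likelihood mono-exponential
  lifetime fits, FRET efficiency from donor lifetimes, phasor transforms;
* **single-cell image quantification** — the ratiometric-image recipe, cell
  and vacuole segmentation, vacuolar-ratio statistics and correlations;
* **sequence design** — charge-patterning (kappa) descriptors, helix and
  disorder proxies, and selection of composition-preserving scrambles;
* **a coarse-grained chain sampler** — Monte Carlo ensembles of a
  bead-per-residue chain under a tunable solution-repulsion axis,
  summarized as normalized radii of gyration.

Every stage can be exercised on synthetic data generated in-package with
known ground truth, so the whole pipeline is testable without any external
acquisition.

# Channel conventions

`DxDm` is donor-excitation/donor-emission, `DxAm`
donor-excitation/acceptor-emission (sensitized emission), `AxAm`
acceptor-excitation/acceptor-emission. The ratiometric readout is
R = DxAm/DxDm, normalized to the mean of the in-run zero-treatment
(control) group so the control mean is exactly 1. Normalization grouping
(per plate, per time point) is exposed via the `group` argument of
`fret_ratio_normalize()`; the default is one reference per table.

# Plate-reader analysis

**Dose–response model.** The synthetic generator `gen_plate_dataset()` uses
a linear-with-saturation expectation
$R(c) = R_0\,(1 + m\,\min(c, c_{sat}))$ — the simplest model consistent
with near-linear osmolarity responses. Noise is multiplicative lognormal
with a user-set coefficient of variation on the ratio, plus an independent
lognormal intensity factor common to the channels of a well, so the ratio
CV equals the planted CV exactly and total donor-excitation intensity is
conserved in expectation.

**Sensitivity.** Solution-scan figures color conditions by how strongly the
normalized ratio responds to solute. No closed definition of that number
exists in common use, so `dose_response_sensitivity()` defines it as the
ordinary-least-squares slope of normalized ratio versus concentration, with
a dead-band: slopes within 0.01 per unit concentration of zero are "none",
positive slopes "compaction", negative "expansion". At the package's
reference conditions (planted slope 0.5/M, 5% noise, 9 replicates at 5
doses) the OLS slope standard error is about 0.026/M, so recovery is
asserted at ±0.05/M (≈2 SE).

**Band ratios.** In-vitro spectra are summarized as the sum of sampled
intensities in the acceptor band (500–600 nm, inclusive bounds) over the
donor band (460–499 nm, inclusive). Emission scans are anchored by
dividing by the intensity at the sample nearest 515 nm (ties toward the
lower wavelength).

**Bleedthrough.** The donor-into-acceptor-channel coefficient is the
least-squares slope of DxAm on DxDm over acceptor-photobleached cells,
where all sensitized emission is bleedthrough. The regression fits an
intercept (residual background, reported) but only the slope is applied,
because additive background is handled by ROI subtraction upstream.

**Smoothing.** `smooth_timecourse()` is degree-1 loess (tricube weights
over the span-nearest neighbours, `stats::loess` with `surface =
"direct"`), evaluated at the input times with a 95% band from the local
residual variance. Local-linear fits reproduce constant and exactly linear
series to machine precision, which the tests assert. The default span of
0.3 is a conventional choice for 50–150-point time courses.

# FLIM and phasors

**Decay model.** Under pulsed excitation with repetition period $T$
(25 ns at 40 MHz) the steady-state arrival-time density is the wrapped
exponential $f(t) = e^{-t/\tau} / [\tau (1 - e^{-T/\tau})]$ on $[0, T)$;
the geometric previous-pulse sum is always included, which removes the
truncation bias that a plain truncated exponential suffers when $T$ is not
many lifetimes long. Bin probabilities are exact integrals of this density,
optionally convolved circularly with a Gaussian instrument response and
mixed with a uniform background. `gen_decay()` draws the histogram as one
multinomial sample, so counts sum to the photon budget exactly and are
reproducible bit-for-bit from the seed.

**Fitting.** Photon counts are Poisson, so `fit_monoexp()` maximizes the
Poisson log-likelihood of $m_k = A\,q_k(\tau) + B$ rather than least
squares — correct at the low counts typical of per-cell ROIs. The
optimizer works in log-parameters (L-BFGS-B), initialized from a log-linear
regression on background-subtracted counts restricted to the first 80% of
the period; the standard error of $\tau$ comes from the observed
information, falling back to the $(\tau, A)$ block when the background
sits on its zero bound. The Pearson reduced chi-square is reported as a
lack-of-fit diagnostic; a bi-exponential decay inflates it far beyond the
parametric-bootstrap null of the fitted mono-exponential model, which is
how model violation is detected.

**Efficiency.** $E = 1 - \tau_{DA}/\tau_D$. Values outside $[0, 1]$ are
returned with a warning flag, never clamped — negative efficiencies are a
diagnostic of fitting problems and hiding them would mask exactly the
failures one needs to see. The unquenched donor lifetime is an explicit
argument: per-experiment donor-only fits are the default usage in this
package, and per-image values can be passed instead. Published population
means of donor-only and sensor lifetimes are generally not mutually
consistent with published efficiencies under this formula when the
underlying per-image donor lifetimes are unreported, so the package makes
no attempt to reproduce any specific printed efficiency from printed
lifetimes; recovery is demonstrated on simulated acquisitions with planted
efficiencies instead.

**Phasors.** `phasor_transform()` projects a histogram at harmonic $h$ of
the repetition rate, $\omega = 2\pi h / T$ with $h = 1$ by default:
$g = \sum c_k \cos(\omega t_k) / \sum c_k$,
$s = \sum c_k \sin(\omega t_k) / \sum c_k$. Noiseless mono-exponential
decays land on the universal semicircle
$s^2 + (g - \tfrac12)^2 = \tfrac14$ with
$g = 1/(1 + (\omega\tau)^2)$; the discrete transform at 512 bins deviates
from the closed form by less than $10^{-4}$, and longer lifetimes move
points left (smaller $g$).

# Single-cell quantification

**Ratiometric recipe.** All channels are Gaussian-blurred ($\sigma = 1$ px
by default), a binary mask is thresholded from the blurred AxAm channel
(Otsu by default, manual threshold accepted), and the ratio image is
blurred DxAm over blurred DxDm inside the mask, zero outside. The mask is
stored as {0, 1}; storing it 8-bit as {0, 255} and dividing by 255 is the
same arithmetic. The blur is pinned explicitly — separable discretized
Gaussian, kernel radius $\lceil 3\sigma \rceil$, reflected boundaries — so
the whole recipe is reproducible from its description alone; the test
suite checks pixel-level equality against an independently coded direct
2-D convolution of the same definition. Masked pixels with zero DxDm are
set to zero and counted in a warning.

**Segmentation.** Manual ROI drawing is replaced by a documented automatic
rule: Otsu threshold on blurred AxAm, hole filling (vacuoles must remain
part of their cell), removal of objects under 50 px², and a
distance-transform watershed to split touching cells (EBImage primitives
throughout). All thresholds are arguments because no universal values
exist.

**Vacuoles.** Within each cell the vacuole is the largest connected region
with AxAm below $\theta$ times the cell median ($\theta = 0.5$ by default
— the sensor is excluded from the vacuole, so vacuole pixels are far
darker than cytoplasm) that does not touch the cell boundary; the
boundary-exclusion rule prevents off-cell darkness bleeding into a cell's
edge from masquerading as a vacuole. The vacuolar ratio is vacuole area
over cell area, zero when no region qualifies, and mean lifetime/ratio are
computed over cytoplasm (cell minus vacuole). Pixel convention: row-major,
origin top-left, areas in px²; `pixel_size` is carried for µm reporting
only.

**Correlations.** `pearson_correlate()` wraps the sample Pearson r with
the exact two-sided t-test on $n - 2$ degrees of freedom. The single-cell
workflow correlates vacuolar ratio with baseline donor lifetime (positive:
cells with larger vacuoles have less crowded cytoplasm) and with the
fractional lifetime change after shock,
$\Delta = (\tau_{final} - \tau_{initial})/\tau_{initial}$ (negative under
the planted buffering model).

# Sequence descriptors and scramble design

**Kappa.** Charges are +1 for K/R, −1 for D/E, histidine and termini
neutral. For blob sizes $g \in \{5, 6\}$ the window charge asymmetry
$\sigma_i = \mathrm{NCPR}_i^2 / \mathrm{FCR}_i$ is computed on every
length-$g$ window; $\delta_g$ is the mean squared deviation from the global
$\sigma$, and $\kappa$ averages $\delta_g / \delta^{max}_g$ over blob
sizes. $\delta^{max}$ is defined by a deterministic construction: the
maximum of $\delta_g$ over all arrangements
$0^{o_1} A^i\, 0^{a} B^{n_B} 0^{b} A^{n_A - i}\, 0^{o_2}$ (either charge
type as $A$, all splits of the $A$ block, all distributions of the
neutrals over the four gaps). Published kappa implementations differ in
how they search for the maximally segregated arrangement; this family was
chosen because exhaustive enumeration over all distinct charge
arrangements of twenty short compositions — including asymmetric ones,
where simple three-block orderings demonstrably fall short of the true
maximum — reproduces its value exactly, and the test suite re-verifies
that equality by brute force. The construction is $O(n_A k^3)$ per
composition and cached, since every member of a scramble pool shares one
composition. For sequences much longer than the validated range the
construction is a documented pinned rule rather than a proven maximum;
$\kappa$ is not clamped, so a violation would be visible as $\kappa > 1$.

**Helix and disorder proxies.** Helix propensity is a sliding-window mean
(window 6) of the Chou–Fasman $P_\alpha$ scale; disorder is the Uversky
charge–hydropathy plane (mean absolute net charge versus mean
Kyte–Doolittle hydropathy normalized to $[0,1]$, boundary
$H = (R + 1.151)/2.785$). Both are ranking/filtering proxies for the
dedicated predictors used in sensor-design work (AGADIR, PONDR); they are
never compared numerically to those predictors' outputs.

**Selection.** `select_scrambles()` keeps candidates with strictly larger
kappa (less charge mixing), strictly lower mean helix score, and the same
disorder flag as the reference, ranked by kappa. Because scrambles are
exact permutations, composition-only quantities (disorder flag, FCR, NCPR)
are constant across the pool, which the implementation exploits.

# The coarse-grained chain scan

A bead-per-residue chain with fixed 3.8 Å bonds carries residue charges
and normalized Kyte–Doolittle hydropathies. The Hamiltonian (kT units) is

$$E_{total} = W_{solv} + U_{lj} + W_{el}$$

* $U_{lj}$: a purely repulsive WCA core (1 kT, bead diameter 4.5 Å) for
  excluded volume plus an attractive Lennard-Jones tail whose depth is
  `eps0` (0.2 kT) times the pair's mean hydropathy, cut off at 2.5
  diameters. The core is kept separate from the hydropathy scaling so a
  zero-hydropathy chain is still self-avoiding — an ideal chain would
  otherwise masquerade as the excluded-volume reference.
* $W_{el}$: Debye–Hückel screening,
  $q_i q_j\, l_B\, e^{-r/\kappa_D}/r$ with Bjerrum length 7.1 Å (water,
  298 K) and Debye length 10 Å (≈150 mM monovalent salt) by default.
* $W_{solv} = -\lambda\, \varepsilon_c\, n_{contacts}$: the
  solution-repulsion stand-in. Each non-bonded contact (r < 1.5 diameters)
  is rewarded by $\lambda \varepsilon_c$, so a solution that repels the
  chain ($\lambda > 0$) drives compaction. $\lambda$ is the dimensionless
  scan axis (not calibrated to specific osmolytes); $\varepsilon_c$
  defaults to 0.2 kT, matched to `eps0`, so the grid
  $\lambda \in \{0, 1, 2, 4, 8\}$ spans the coil–globule transition
  gradually instead of collapsing completely at the first non-zero level.

Sampling is Metropolis at kT = 1 with bond-preserving pivot and crankshaft
moves in equal proportion, starting each repeat from a distinct
random-walk conformation grown with overlap avoidance. Move energies are
evaluated incrementally on the fixed-versus-moved cross pairs; the running
total is checked against a full recomputation every 1000 steps, and the
maximum drift (typically $10^{-12}$ kT) is reported — an honest guard on
the bookkeeping. Determinism is per-repeat via seeds derived from the call
seed, with the C++ engine using its own generator so the R session state
is never touched.

`solution_scan()` runs 5 independent repeats per condition at the default
scaled-down protocol of $10^5$ proposals with $2\times 10^4$ equilibration
and snapshots every 125 proposals — sized so a 5-condition scan of a
30-mer completes in well under a minute on one core, while the original
cluster-scale protocol ($5\times 10^7$ steps, $10^7$ equilibration,
snapshots every 12,500) remains available through the same arguments.
Mean Rg per condition is the mean of repeat means and the SD is taken
across the 5 repeat means; normalized Rg divides by the most expanding
condition (always $\lambda = 0$ on the default grid), so normalized Rg ≤ 1
with equality at the reference, and the scalar sensitivity is
$1 - \min(\text{normalized Rg})$. Comparing a native sequence against its
scrambles is exposed through the same functions but deliberately not
asserted as a test: a coarse-grained model is not guaranteed to reproduce
atomistic sensitivity orderings.

# The synthetic cell population

`gen_cell_population()` emulates the single-cell experiment's structure:
disk cells (radius 12–18 px) with strictly interior disk vacuoles, placed
without overlap by rejection sampling in a 512×512 field. Per-cell baseline
lifetime is $2.85 + 0.8\,\mathrm{VR} + \mathcal N(0, 0.19)$ ns and the
fractional shock response is
$-(0.20 - b\,\mathrm{VR}) + \mathcal N(0, 0.05)$ with $b = -0.23$, chosen
once from the closed-form correlation
$r = \beta\,\mathrm{sd(VR)} / \sqrt{\beta^2 \mathrm{var(VR)} + \sigma^2}$
so the planted correlations are +0.44 (vacuolar ratio vs baseline
lifetime) and −0.47 (vacuolar ratio vs Δlifetime) at the default VR range
[0.05, 0.45] — the magnitudes single-cell FLIM studies of vacuolated yeast
report, with larger vacuoles buffering crowding at baseline and (under the
negative-slope default) losing proportionally more lifetime after shock.
With the donor-only lifetime at 3.62 ns, the implied mean baseline sensor
lifetime is ≈3.05 ns. Channel intensities follow the lifetime through
$E = 1 - \tau/\tau_D$ with the donor-excitation budget split as
$DxDm \propto 1 - E$, $DxAm \propto E$ (ratio monotone in $E$; $E$ floored
at 0.02 for rendering only, affecting the few cells whose noisy lifetime
exceeds the donor-only value), 5% multiplicative pixel noise, and a dim
additive background.

What the generator does **not** emulate: membrane rendering, out-of-focus
light, photobleaching, cell-shape irregularity, cell movement or division,
multiple/lobed vacuoles, and shock-induced shrinkage. Passing recovery
tests therefore demonstrates the pipeline's correctness on geometrically
clean fields, not robustness to every real-microscopy artifact; the
segmentation and vacuole rules are config-exposed precisely because real
data will need retuning.

# Numerical choices and degenerate inputs

* Decay bin probabilities are exact integrals (no midpoint approximation);
  phasors evaluate trigonometry at bin centers.
* The lifetime fit requires ≥100 photons and errors below that; all-zero
  histograms and zero-total phasor inputs raise typed errors.
* Spectrum anchoring snaps to the nearest sampled wavelength, ties toward
  the lower; zero anchor intensity is an error, as is a zero donor-band
  sum in band ratios.
* Out-of-range efficiencies warn and flag, never clamp. Division by zero
  DxDm errors in tables (with the well named) and zeroes-with-warning in
  images.
* All generators draw from one explicit integer seed per call through an
  isolated RNG scope; no global state is consumed or leaked.
* Vacuolar ratios are in $[0, 1]$ by construction (vacuole ⊆ cell is
  enforced geometrically at generation and by the containment rule at
  measurement).

# Known limitations

* Mono- and bi-exponential decays only; no anisotropy, no reference-dye
  IRF deconvolution, no per-pixel full-image FLIM fitting (per-ROI only).
* Single-coefficient bleedthrough; no spectral unmixing or 3-cube E-FRET.
* The kappa δ-max rule is exhaustively validated only for short
  compositions; very long sequences rely on the pinned construction.
* The chain model has no torsional term, no explicit osmolyte particles,
  and an uncalibrated solution axis; it reproduces qualitative
  compaction behaviour, not atomistic ensembles.
* No cell tracking across large displacements and no LLPS/granule
  analysis.
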