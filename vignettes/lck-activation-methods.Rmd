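---
title: "Models and methods behind lckcycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lckcycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lckcycle)
```

# Scope

`lckcycle` bundles four computational pieces used to study how T cells
maintain a steady pool of active Lck kinase (Lck_A, phosphorylated at
Y394) at the plasma membrane (PM):

1. a stochastic three-state trans-autophosphorylation model with a
   grid-search fit of its two reaction probabilities;
2. a flow-cytometry (FCM) pipeline turning per-event two-colour data into
   background-subtracted, binned dose curves with nonlinear regression;
3. an image-quantification pipeline that converts three-channel cell
   z-stacks into PM/cytoplasm (CP) intensity ratios and percent-PM-resident
   estimates;
4. a conserved-order-parameter (Kawasaki) Ising simulation of a
   near-critical lipid mixture carrying frozen "protein anchor" discs.

Each piece is paired with a synthetic-data generator that knows its own
ground truth, so every stage is testable without external data.

# The kinase activation model

Lck switches between three conformers: inactive (`I`, closed, pY505),
primed (`P`, dephosphorylated) and active (`A`, pY394). Priming is driven
by the phosphatase CD45, which also reverses activation; because CD45 acts
on both sides of the cycle it is treated as a *hidden variable* — its net
effect is folded into per-encounter reaction probabilities rather than
modelled explicitly.

The simulation places N molecules in an arena of M slots. Each cycle draws
two distinct slots uniformly; if both are occupied:

* any inactive partner converts to primed with probability `p_prime`
  (default 0.99 — priming is strongly favoured);
* a P+P pair produces one active molecule with probability `p_PA`;
* a P+A pair produces a second active molecule with probability `p_AA`.

Pair-encounter probability scales as N(N-1)/(M(M-1)), so activation is
second order in density at low expression and crosses over to a linear,
near-saturating regime at high occupancy — the two regimes seen in
measured dose curves.

## Key parameter choices

* **`arena_size` (M = 100)** and the molecule grid are not stated by any
  source; they set only the resolution of the occupancy axis.
* **`n_cycles` (default 10·M).** An earlier draft used 2·M, but at that
  encounter budget even a full arena reaches only ~30 % activation and the
  dose-curve *shape* carries almost no information about (`p_PA`, `p_AA`)
  once a free amplitude is fitted — the parameters sit on a ridge. At
  10·M, high-occupancy runs approach saturation (consistent with the
  observation that at least half of cellular Lck is active), and the grid
  fit becomes well posed. This is the package's own calibration choice.
* **Irreversibility.** No reverse reactions are implemented; with CD45
  hidden, the probabilities encode *net* conversion. Consequently the
  all-active state is absorbing and every curve is a fixed-budget kinetic
  read-out, not a steady state.
* **(I, I) pairs.** Both inactive partners convert independently with
  probability `p_prime`; the enumeration oracle in the test suite encodes
  the same convention.

## The grid fit

`grid_fit()` evaluates the simulated mean curve at every pair of a 19 × 19
probability grid (0.10–1.00, step 0.05), maps observed total-Lck values
linearly onto molecule numbers, fits a single scalar amplitude per pair
(counts → fluorescence), and minimizes the residual sum of squares. Three
numerical choices matter:

* **Common random numbers.** Every grid pair is simulated from the same
  seed, so a noise-free curve generated at a grid point is recovered
  *exactly* (SSE = 0) and neighbouring pairs are compared at reduced
  Monte-Carlo variance.
* **Variance weighting.** Residuals are weighted by the inverse of
  `(noise_cv * y)^2` plus a count-scale Monte-Carlo floor. Measurement
  noise on fluorescence medians is multiplicative, so plain SSE lets the
  large high-occupancy values drown the low-expression shape information;
  the weighted objective is the corresponding likelihood. Unweighted SSE
  remains available (`weighting = "uniform"`).
* **Tie-breaking** is towards the lowest (`p_PA`, then `p_AA`).

Identifiability is not uniform over the grid: in the saturated corner
(both probabilities large) many pairs produce nearly identical curves, and
`p_AA` is determined only to about two grid steps. At the
experimentally relevant optimum (0.3, 0.1) recovery within one grid step
succeeds in ≥ 95 % of seeded repetitions; the test suite asserts the
saturated regime at its measured resolution instead of hiding it.

The fit also reports the *realized* number of P+P and P+A firings. Note
that a smaller per-encounter probability (`p_AA` = 0.1 < `p_PA` = 0.3)
can still dominate total flux once active molecules are abundant — the
package reports both quantities and asserts neither interpretation.

# Flow-cytometry pipeline

The pipeline mirrors a standard two-colour workflow: linearize, optionally
demultiplex dye-barcoded populations, bin the total-Lck axis, summarize
each bin, subtract background, restrict to a physiological expression
range, and fit the dose curve.

* **"Geometric median"** is implemented as the median on the log scale per
  channel, `exp(median(log x))` — for one-dimensional data the geometric
  median *is* the median, and the log-scale reading matches cytometry
  convention. Whether the original procedure meant the geometric mean is
  unknowable from the text; `type = "mean"` switches to it.
* **Binning** uses equal-count (quantile) bins, default n = 73. Total-Lck
  signals are log-normal, so equal-width bins would leave the upper bins
  too sparse for stable medians; only the bin *count* is prescribed.
* **Background subtraction** is a per-channel scalar (the control sample's
  geometric median), because control samples carry no induced expression
  structure. Negative net values are kept, not clamped — clamping would
  bias the low-expression quadratic regime — and flagged.
* **The default regression form** is the crossover
  $y = \alpha x^2 / (x + \kappa)$: the simplest smooth function that is
  quadratic as $x \to 0$ and linear with slope $\alpha$ as
  $x \to \infty$. The original source never prints its functional form, so
  a quadratic-plus-linear polynomial is selectable and the form identifier
  is embedded in every fit object.
* **Demultiplexing** fits a 1-D Gaussian mixture on log dye intensity (EM,
  deterministic quantile initialization, k-means fallback) and orders
  labels by component median. If adjacent fitted components are separated
  by less than two pooled standard deviations the function fails loudly
  rather than mislabeling.
* **FCS input.** The pre-installed stack has no FCS reader, so the package
  carries a deliberately minimal FCS 3.0/3.1 list-mode parser (float,
  double or integer data, both byte orders, `$PnE` log-amplification
  conversion). CSV remains the canonical interchange format.

## What the FCM generator emulates

`gen_fcm_events()` draws log-normal total-Lck expression
(`lckT_log_sd = 0.9`, spanning > 1.5 orders of magnitude as in a
doxycycline-induced titration), pushes each cell's true expression through
a known mean curve (the analytic crossover form by default, or the
stochastic kinase model), applies multiplicative log-normal measurement
noise (`noise_cv = 0.1`) to both channels, adds log-normal
autofluorescence background, and attaches dye-barcode intensities around
three levels roughly a log-decade apart (1:1:1 mix).

Two honesty notes. First, binning on a noisy x-channel causes classic
errors-in-variables attenuation of downstream curve fits; at 10 % channel
noise and the default expression spread this bias is ~2 %, but at 20 %
noise it reaches ~10–15 % on $(\alpha, \kappa)$ — a property of the
*procedure*, not a code defect, and the reason the round-trip tests at 20 %
noise compare bin medians against per-bin ground truth rather than global
fit parameters. Second, the generator does not emulate spectral spillover,
instrument-specific scaling, doublets or debris; a green test establishes
pipeline correctness on clean single-cell events, not robustness to
uncompensated raw data.

# Image quantification

The pipeline reproduces an ImageJ-style workflow: per-channel modal
(most-frequent) intensity subtraction with clipping and 16-bit rescale;
average projection of the four central z-planes (ties biased one plane
towards the lower index); Gaussian blur (sigma 3 px) of the segmentation
channels; Otsu thresholding of the nuclear-dye and membrane-marker
channels; fill-holes, one 3 × 3 erosion, largest connected component; CP
defined as the filled membrane contour minus the membrane ring minus the
nucleus. The PM/CP ratio is the mean target intensity over the PM mask
divided by that over the CP mask.

Choices where the source is silent:

* Otsu runs on the *blurred* projection (blur precedes ROI definition in
  the stated step order), but the **ratio is measured on the unblurred
  projection** — smoothing is for mask geometry only, so thin-ring
  intensity is not diluted into the cytoplasm at measurement time.
* Ratios are computed **per cell** and then aggregated (matching "n ≥ 10
  cells" error bars), not on pooled pixels.
* The erosion element defaults to the 3 × 3 square (ImageJ's default);
  `"cross"` is selectable.
* **Ratio → percent conversion.** The mapping
  $100\,r/(1+r)$ is *inferred*: no formula is printed anywhere, but this
  one reproduces every printed conversion (2.2–2.3 → ≈ 70 %, 2.5 → 71 %,
  2.0 → 66–67 %, 1.7 → 63 %). It equates mean-intensity ratio with signal
  fraction, exact when the two compartments have comparable projected
  areas.

## What the stack generator emulates

`gen_image_stack()` builds one suspension cell as concentric spheres
(anisotropic in z by the axial/lateral voxel ratio, default 3): a nuclear
dye filling the nucleus, a membrane marker on a spherical shell, and a
target channel split between shell and cytoplasm with a known fraction.
PSF blur, a constant camera baseline and Poisson noise follow. The
*pre-noise, pre-blur* PM/CP mean-intensity ratio and the compartment masks
are stored as ground truth; 2-D truth masks keep only pixels that belong
to the compartment in all four central planes, so compartment intensities
project exactly onto them in the noiseless limit.

The default membrane band is 8 px (~0.5 µm at SIM-like sampling —
membrane plus primary/secondary antibody layers at the resolution limit).
This is deliberately wide relative to the fixed sigma-3 analysis blur: a
2–3 px band would be physically more literal but makes ring segmentation
ill-posed at the prescribed blur (the detected ridge widens to the blur
FWHM and no threshold recovers a thin ring with Dice ≥ 0.9). The
generator states a world in which the published procedure is well-posed;
it does not emulate structured-illumination reconstruction artifacts,
multi-cell fields, or chromatic misalignment.

# The Ising membrane module

A ferromagnetic Ising model (J = 1, k_B = 1) on a periodic square lattice
with **Kawasaki** spin-exchange dynamics: composition, not magnetization,
is the conserved quantity appropriate for a binary lipid mixture. The
default temperature is T = 2.28 J/k_B, just above the exact critical
temperature $T_c = 2/\ln(1+\sqrt2) \approx 2.269$ — the weak-segregation,
near-critical regime in which composition fluctuations are large but no
macroscopic phase separation occurs. The critical composition (half black,
half white, exact by construction) is the default.

A protein anchor is a frozen disc whose sites are pinned to one phase;
frozen sites still contribute bonds to the Hamiltonian (that is the stated
boundary condition) but are excluded from exchange proposals, and mobile
composition is re-balanced after placement. Near criticality such a disc
nucleates an annulus of its preferred phase whose extent tracks the
correlation length; `radial_composition()` measures it against a bulk
reference taken beyond L/4.

`correlation_length()` fits the radially averaged connected correlation to
$C(r) = A\,r^{-1/4} e^{-r/\xi}$ (the 2-D Ising $\eta = 1/4$), discarding
separations where $C$ has decayed below ~1 % of its nearest-neighbour
value — fitting into the noise floor otherwise inflates $\xi$. Near $T_c$
conserved dynamics relax slowly, so single-run $\xi$ estimates are noisy
and the monotonicity tests average over seeds.

`pair_contact_stats()` is an **extension beyond the single-disc
simulation**: two discs perform rigid-translation Metropolis moves (same
Hamiltonian; lipids displaced by the advancing edge refill the wake, so
composition stays exact) between Kawasaki sweeps. Like-phase discs share
one annulus and sit at contact more often than unlike-phase discs, which
pay an interfacial energy — the mechanism proposed for why a kinase
bearing the phosphatase's own anchor suffers excess dephosphorylation.
Defaults (burn-in, sweep counts, lattice sizes) are repo choices sized so
a 64² run completes in seconds; no source states them.

# Degenerate inputs and numerical conventions

* Equal-count binning distributes remainders to the lowest bins; an
  all-identical x-channel collapses to one effective bin and warns.
* Background-subtracted negatives are retained and flagged; range
  restriction and normalization drop (with a report) only bins that make
  their output undefined.
* The crossover fit initializes from the large-x linearization
  $y \approx \alpha (x - \kappa)$ and retries from quantile starts;
  "singular convergence" on an exactly fitting dataset is accepted.
* Otsu's between-class variance is flat across an empty inter-mode gap;
  any threshold in the gap is correct, and tests compare induced
  partitions, not raw thresholds.
* All generators are pure functions of (spec, seed): they save and restore
  the caller's RNG state.
* T = 0 and T = ∞ are handled explicitly in the Metropolis rule (reject
  uphill / accept everything).

# Known limitations

* The kinase model has no spatial structure, no explicit CD45/Csk
  kinetics, no reverse reactions and no doubly phosphorylated species; it
  is a phenomenological encounter model.
* The FCM pipeline performs no spectral compensation or polygon gating.
* The image pipeline assumes one cell per field (largest component) and
  does not model SIM reconstruction; PM/CP ratios printed for real cells
  are not reproducible from desk data and are covered only through the
  synthetic round trip plus the ratio-conversion worked examples.
* Ising observables are measured on modest lattices; no finite-size
  scaling beyond the $T_c$ sanity check is attempted, and Kawasaki
  dynamics near $T_c$ equilibrate slowly by construction.
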