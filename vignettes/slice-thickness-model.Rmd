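---
title: "Choosing a section thickness for block-face cryo-imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing a section thickness for block-face cryo-imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryosect)
```

## The problem

Block-face cryo-imaging alternates microtome sectioning and epifluorescence
imaging of the freshly exposed surface of a frozen specimen. Fluorescent
cells (or microspheres) below the block-face remain visible through the
overlying tissue as *subsurface fluorescence* — a comet-tail artifact along
depth — until the slab containing them is cut away. Sectioning thinner than
necessary wastes acquisition time and mechanical wear; sectioning too thick
misses the dimmest cells at the bottom of each slab and biases cell counts
downward. `cryosect` implements a quantitative model of this trade-off, the
simulators that probe it when its assumptions fail, and the calibration
pipeline that estimates its parameters from thin-slice data.

## The detection model

A fluorophore of unattenuated intensity $I_{fluo}$ (gray level) at depth $x$
(µm) below the block-face is imaged at

$$I(x) = I_{fluo}\, e^{-\mu_T x},$$

a single-exponential Beer–Lambert law whose effective attenuation
coefficient $\mu_T$ (cm$^{-1}$) pools excitation- and emission-side
absorption and scattering. We deliberately do not separate a scattering
point-spread function from the attenuation term; the model tracks only
on-axis intensity. Detection is a hard threshold: the cell is seen iff
$I(x) \ge T$ (inclusive boundary).

Setting $I(X) = T$ at the bottom of a slab of thickness $X$ gives the two
closed forms around which everything else is built:

$$X_{optimal} = -\ln(T / I_{fluo}) / \mu_T, \qquad
  I_{optimal} = T\, e^{\mu_T X}.$$

$X_{optimal}$ is the largest section thickness at which *every* cell in a
slab still reaches threshold at the block-face; it equals the subsurface
fluorescence length $e$ of a single cell. For cells uniformly distributed in
depth the detection sensitivity (detected fraction $n/N$) is piecewise:

$$\mathrm{Sens}(X) = \begin{cases} 1 & X \le X_{optimal} \\
  X_{optimal}/X & X > X_{optimal},\end{cases}$$

so on log–log axes the sub-optimal decline is a line of slope $-1$ (a
$-45^\circ$ relationship), and an observed count can be corrected by
$\mathrm{Count}(X_{optimal}) = \mathrm{Count}(X)/\mathrm{Sens}(X)$.
Two generalisations are provided: `distribution_sensitivity()` replaces the
uniform depth density by an arbitrary one (ratio of its partial integrals
over $[0, X_{optimal}]$ and $[0, X]$, trapezoidal quadrature on the stored
grid, default resolution 0.1 µm), and `mixture_sensitivity()` averages the
piecewise curve over a discrete intensity mixture, with sub-threshold groups
contributing zero at every thickness.

### Units

$\mu_T$ is stored in cm$^{-1}$, exactly as such coefficients are reported
for tissue, while all depths and thicknesses are µm; a single internal
constant ($10^4$ µm/cm) performs the conversion. This keeps published
parameter values usable verbatim: `optimal_thickness(30, 314, 10)` returns
34.99 µm.

## Virtual volumes and the sectioning simulator

`build_compliant_volume(S, I, mu)` places one cell per 1-µm depth bin at the
bin centre ($i - 0.5$ µm), so a slab of thickness $S$ holds $N = S$ cells,
all equally bright, equally attenuated, and at unique lateral grid
positions. These are precisely the model's three compliance assumptions
(homogeneous tissue, equal brightness, no overlap), and they are
machine-checkable on the object. Bin-centre placement makes the discrete
breakpoint of a simulated sweep equal to the number of bin centres within
$X_{optimal}$ — `discrete_optimal_thickness()` — reproducing integer
breakpoints (35, 51, 66, 44 µm) from continuous optima (34.99, 51.26,
66.22, 44.15 µm).

`run_digital_sectioning()` images block-faces at depths $0, X, 2X, \dots$
(the first image precedes the first cut) until the slab is consumed. A cell
at depth $d$ is present at face $z$ iff $d \ge z$ — a cell exactly at the
cut plane is just exposed at $x = 0$ and maximally bright — so its closest
look is the face at $\lfloor d/X \rfloor X$ and the whole simulation
vectorises over cells. De-duplication is by cell identity, which is exact
when lateral positions are unique. Tests verify the engine against a
brute-force oracle that walks the faces one by one.

### Edge effects worth knowing about

When $S$ is not a multiple of $X$ the final partial slab is shallower than
$X$ and may be entirely within the detectable depth, so simulated
sensitivity sits slightly *above* $X_{optimal}/X$ (by at most $e/S$). Two
consequences:

* the ceiling-formula count $\lceil (e/X) N\rceil$ matches the simulation
  exactly only when $X$ divides $S$ (e.g. 75 of 140 cells at $X = 70$ µm,
  $S = 140$); at $S = 150$ the 10-µm remainder slab adds its cells in full.
* log–log slope estimates are biased toward 0 on arbitrary thickness grids.
  Where a slope is asserted quantitatively we sweep thicknesses that divide
  the slab (divisors of 2520 µm within (70, 150]); on that grid the
  compliant slope is $-1$ to machine precision.

## Non-compliant regimes

Three perturbations probe the assumptions, mirrored on the corresponding
simulated sensitivity–thickness curves:

* **Tissue inhomogeneity** — `perturb_attenuation()` adds zero-mean Gaussian
  deviates (sd $\sigma$) to each cell's $\mu_T$, clipped below at
  1 cm$^{-1}$ since the notation $314 \pm N(\sigma)$ taken literally permits
  unphysical negatives. The sensitivity decline starts before the nominal
  optimum and the log–log slope flattens toward 0 (cells with low $\mu_T$
  stay visible arbitrarily deep); at $\sigma = 150$ we measure a slope of
  about $-0.77$.
* **Brightness variation** — `perturb_intensity()` perturbs $I_{fluo}$
  (clipped at 0); cells below $T$ become permanently undetectable. The curve
  loses its sharp breakpoint but keeps the $-45^\circ$ sub-optimal slope:
  over thickness windows beyond every cell's subsurface length the mixture
  sensitivity is $\mathbb{E}[X_{opt}]/X$, exactly reciprocal. We fit over
  (70, 150] µm, where for base intensity 40 and $\sigma \le 15$ the
  sub-window condition holds to a negligible tail probability.
* **Signal overlap** — `build_overlap_volume()` places
  $N = \mathrm{round}(\mathrm{Density} \times \mathrm{area})$ cells at
  uniform depths and random positions on a *discrete* lateral grid, so
  distinct cells can share a column. `run_overlap_sectioning()` counts by
  disappearance events: within a column, detectable cells are counted once
  per distinct last-visible face index. The merge operator for overlapping
  comet tails is not uniquely defined by the physics; this rule was chosen
  because it provably resolves every placement with $\ge 1$ µm depth
  separation at $X = 1$ µm and yields the linear-then-hyperbolic curve
  shape, with the breakpoint fixed at the discretized optimum (44 µm for
  $I_{fluo} = 40$, $\mu_T = 314$, $T = 10$) independent of density.

No canonical slab thickness, area or lateral extent exists for these
regimes; we default to $S = 1000$ µm, area 1 cm², lateral pitch 100 µm for
overlap volumes. These are configuration choices, not
claims — the asserted results (curve shapes, slopes, breakpoints) are
insensitive to them, but the *rate* of the overlap-induced decline scales
with the number of lateral sites and so is only qualitatively comparable.
Stochastic assertions use 10 fixed-seed replicates and compare means.

## The section-and-image pipeline

Given a thinly sliced stack (or a rendered synthetic one),
`sensitivity_vs_skip()` simulates thicker sectioning by keeping every
$k$-th slice (anchor slice 0; the anchor shifts counts by a few cells, so
it is an explicit argument), counts cells by thresholding plus 3-D
connected-component analysis, and normalises by the skip-1 reference. CCA
uses 26-connectivity by default (6 available) so that the multi-slice comet
tail of one cell collapses to a single component. The labelling builds the
voxel adjacency graph and takes `igraph` components; stacks here are sparse,
so this is far from the bottleneck.

Parameter estimation follows the calibration recipe: $I_{fluo}$ as the mean
of per-component *peak* intensities (the brightest voxel approximates the
cell's most exposed look; for bin-centre placements that look is at
$x = d \bmod X$, so the estimate carries an attenuation bias bounded by
$e^{-\mu_T X}$ — exact only for cells exposed at a face), and $\mu_T$ by
exponential regression of a component's decay profile, i.e. an OLS fit of
log intensity against depth above the brightest slice. The slice where the
cell is cut is the profile's zero point; nothing below it exists to fit.
Noiseless profiles recover $\mu_T$ to $10^{-6}$ relative; with 5%
multiplicative noise the mean over 100 replicates stays within 5%.
Note that 16-bit quantisation of dim tails (when profiles come from written
TIFFs rather than in-memory stacks) limits practical accuracy to a few
percent.

The detection threshold $T$ is a required input throughout: the heuristic
used in practice (trading detections against false positives on real data)
is not reproducible from first principles, so the package does not guess it.

## Rendering synthetic stacks

`render_image_stack()` emulates acquisition on a virtual volume: one image
per block-face, each still-present cell contributing its attenuated
intensity at its lateral pixel (single-pixel footprint by default, optional
disc radius), shared-pixel contributions summed, optional additive Gaussian
noise clipped at zero. What it deliberately does *not* model: optical blur,
vignetting, tiling/registration, autofluorescence background and lateral
scattering. Passing tests on rendered stacks therefore validate the
counting and calibration logic, not robustness to those real-data
artifacts.

## Worked example

```{r example}
# Stem-cell parameters: I_fluo = 38, mu_T = 314 cm^-1, T = 10
optimal_thickness(38, 314, 10)

# Calibration on a synthetic stack sliced at 10 um
vol <- build_compliant_volume(200, 38, 314)
stack <- render_image_stack(vol, 10)
report <- sensitivity_vs_skip(stack, 1:10, 10)
find_optimal_thickness(report)

# Counting at 100 um would miss cells; the correction recovers them
sens <- sensitivity_piecewise(100, optimal_thickness(38, 314, 10))
corrected_count(report$count[report$sweep_value == 100], sens)
```

```{r plot, fig.width = 6, fig.height = 4}
autoplot(report)
```

## Problem sizes and determinism

Every simulation in the test-suite and acceptance script runs at desk scale:
compliant slabs of 150–3600 µm (equal numbers of cells), rendered stacks up
to 1000 cells × 100 slices, 10 replicates for stochastic properties, 100
replicates for estimator-bias checks. All generators are pure functions of
their parameters and a seed, applied locally so library calls never disturb
the caller's RNG stream.

## Limitations

* The model is 1-D in depth; lateral scattering, blur and the finite extent
  of real cells are outside it.
* The overlap merge operator is a formalisation choice (see above), not a
  reverse-engineered replica of any particular acquisition software.
* Real-data quantities (recovery rates, correlations with animal datasets)
  require data that are not redistributable and are out of scope; the
  package validates against closed forms, brute-force oracles and its own
  synthetic renderer instead.
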