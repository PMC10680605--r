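---
title: "Methods: quantifying growth, shape robustness and spatiotemporal averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying growth, shape robustness and spatiotemporal averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepaldyn)
```

## The problem

Sepals — the outermost floral organs — reach highly reproducible sizes and
shapes although their epidermal cells grow very unevenly: nearby cells can
differ several-fold in growth rate, cell division rates can be pushed up or
down genetically (LGO dosage), and a subpopulation of endoreduplicated
giant cells never divides at all. Robustness is explained by
*spatiotemporal averaging*: when the cell-level growth fluctuations are
spatially fine-grained and re-drawn over time, their cumulative effect on
any lineage averages out, so organ growth is even; when fluctuations are
spatially coarse and temporally persistent (the *ftsh4*-like situation),
they accumulate into patchy growth and variable organs.

`sepaldyn` implements the measurement side (lineage tracking algebra,
growth tensors, axis fields, shape statistics, distribution comparisons)
and a generative side (a growing-tissue simulator) so every measurement can
be exercised and validated without microscopy data. This vignette records
the models, the tunable parameters, and the numerical and design choices.

## Data model

A tissue snapshot is a set of labelled, simple, counter-clockwise polygons
in the plane, with coordinates in micrometres and the y axis running from
the proximal base to the distal tip. Geometry is deliberately flat 2-D: the
quantities computed here — areas, areal ratios, in-plane directions — are
intrinsic to the curved epidermal surface, so treating the projected
surface as planar changes no formula while removing all mesh-curvature
machinery. Each polygon vertex carries a stable junction identifier shared
with the neighbouring cells that meet there; two cells are adjacent iff
they share at least two junctions (one wall). Lineage is recorded as a
parent map per 24 h interval: every later-time label maps to its ancestor's
label. Files use line-oriented `.cells` snapshots and plain CSVs
(`Label,Value` heat maps, `Label,Parent` lineages) with a header row, `.`
decimal separator and no quoting; coordinates are written with 17
significant digits so round trips are exact to well below 1e-9 µm.

## Growth quantification

The growth ratio of a lineage over a span is the summed area of its
descendants divided by the ancestor's area. Because multi-interval maps are
composed by path-following, the cumulative ratio telescopes exactly into
the product of per-interval ratios — a property the test suite checks to
1e-10 on every simulated lineage.

The deformation tensor of a lineage is fitted from its wall junctions that
persist between the two time points (walls created by divisions inside the
lineage do not exist earlier and are excluded). We minimise
$\sum_i \lVert F p_i + t - q_i \rVert^2$ in closed form; the growth tensor
$C = F^\top F$ gives principal stretches $s_1 \ge s_2$ (square roots of the
eigenvalues) and the principal direction of growth $\theta_{\max}$, the
angle of the $s_1$ eigenvector mod $\pi$. Rotations contribute no stretch;
the fit is exact on affine data (checked to 1e-8 over random proper
affines). When $s_1 - s_2 < 10^{-9} s_1$ the direction is meaningless and
we report $\theta_{\max} = 0$ with an `isotropic` flag. The landmark fit is
unweighted least squares; mesh-geometry-weighted variants exist in imaging
software, and this unweighted choice is a documented divergence.

The proximal–distal axis is built from a graph distance field: shortest
paths from the distal-most cell row (or any explicit source set) in the
adjacency graph with centroid-to-centroid edge weights. Each cell's axis is
the unit gradient of that field from a least-squares plane fit over the
cell and its neighbours, followed by sign-aligned neighbourhood averaging
(optionally area-weighted). The PD/ML ratio
$r = \sqrt{a^\top C a} / \sqrt{a_\perp^\top C a_\perp}$ satisfies
$r(a)\,r(a_\perp) = 1$ and is maximised at $\theta_{\max}$ with value
$s_1/s_2$. Stored values are never clipped; the conventional display range
1–1.7 (and the optional floor at 1) is applied only when rendering, so
medial-lateral-dominant growth ($r < 1$) remains analysable.

## Shape robustness

Contours come from binary masks (largest component, Moore-neighbour
boundary tracing) or any ordered point list. Normalisation fixes size and
pose using exact area moments of the polygon — centroid to the origin,
unit enclosed area, principal axis to +y with the wider half proximal,
reflection fixed by a nonnegative third moment of x — and only then
resamples to `n_points` equal-arclength points starting from the vertex
nearest the distal tip. Because pose and starting point are computed from
the polygon rather than the point list, similarity-transformed and
cyclically re-indexed copies normalise to identical point sets (≤ 1e-6).

The mean shape aligns each contour to the running mean over cyclic start
offsets and traversal direction, iterating to convergence; the starting
reference is the shortest-perimeter contour, which makes the result
invariant to input order. The variability statistic $S_2$ is the mean
squared point distance to the mean shape, averaged over contours. Whether
the original statistic used pointwise distances or area differences is not
determinable from the source material; the pointwise definition is fixed
here and is what the package's $S_2$ means. Within-flower size variability
is the sample SD (n−1) of the sepal areas of each flower, summarised as
mean ± SEM across flowers.

## Statistics layer

Distribution comparisons use the exact order-1 Wasserstein distance
(quantile-function integration over the merged probability grid; verified
against a transport oracle and for metric axioms), embedded by classical
PCoA — double-centred squared distances, eigendecomposition, negative
eigenvalues reported rather than clipped. Kendall's $\tau_b$ uses the
standard tie corrections with exact permutation p-values for $n \le 8$ and
the tie-corrected normal approximation otherwise. Group comparisons use
one-way ANOVA with Tukey HSD and an insert-and-absorb compact letter
display; letters are validated in tests against the defining properties
(no letter joins a significantly different pair; every non-significant
pair shares one).

## The simulator

`simulate_series()` grows a jittered quadrilateral tessellation for
`n_steps` 24-h steps. Per step, each cell's target areal growth ratio is

$$ g(c,t) = \left[1 + A\,e^{-(y_c - \mu_t)^2 / 2\sigma^2}\right] e^{\varepsilon_{c,t}}, $$

a basipetal Gaussian band (centre $\mu_t$ moving tip→base by `band_speed`
rows per step) times log-normal noise. The noise field has marginal SD
`noise_sd`, Gaussian spatial correlation with length `corr_len` cell
diameters (the kernel bandwidth is `corr_len`/√2, so `corr_len` is the
correlation length of the *field*, not of the kernel), and AR(1) temporal
persistence $\rho$: $\varepsilon_t = \rho\,\varepsilon_{t-1} +
\sqrt{1-\rho^2}\,\eta_t$, with daughters inheriting their parent's state.
$\rho = 0$ resamples every step (wild-type-like); $\rho \to 1$ with large
`corr_len` produces persistent patches (*ftsh4*-like).

Growth is realised as a smooth junction displacement of the form
$x' = F(x)$, $y' = G(x, y)$: the medial-lateral stretch $F'(x)$ is the
column-mean ML log stretch and the PD stretch absorbs the remainder of the
locally interpolated log growth, so the Jacobian equals the interpolated
growth field — strictly positive, hence the map cannot fold, and shared
junctions move once so the tessellation stays crack-free. A damped
fixed-point correction (cumulatively clamped at ±0.35 log units) then
refines per-cell areas: because the correction passes through the same
interpolation kernel, growth structure coarser than the kernel scale
(`kernel_bw`, default 1.75 cell diameters) is realised accurately —
median |realised/target − 1| ≈ 3–4% at `corr_len` = 2 — while
cell-to-cell fluctuations finer than the kernel remain mechanically
filtered, as they are in a real tissue where neighbouring cells share
walls. Fraction `pd_bias` of each cell's log-area growth is realised along
the PD axis.

After growth, every non-giant cell above `a_div`/κ divides once along the
shortest wall through its centroid perpendicular to its longest principal
axis (area-moment eigenvector), with ±5° jitter to avoid lattice
artefacts. Cuts that graze a junction, produce a <5% area share, or
produce daughters thinner than 0.1 × (longest edge)² in area are rejected
and retried; already-thin cells may divide into daughters not much thinner
than themselves, which is what rescues them. Giant-cell fate is assigned
once at t = 0 with probability `p_giant`; κ modulates division only, never
growth — the central premise that changing division does not change
growth. Degenerate geometry is handled in three layers: fall back to the
uncorrected (fold-free) map, straighten near-collinear wall vertices in
place, and as a last resort apply a global affine stretch for that step,
which can neither fold nor tangle any polygon. One RNG stream, seeded from
`seed`, drives everything; reruns are byte-identical.

### Default conditions

The defaults encode the study conditions: 6 snapshots at 24 h (`n_steps`
5); a 12 × 10 starting grid at 10 µm pitch (100 µm² starting cells,
matching early sepal epidermal areas of ~100–160 µm²; the organ must span
several noise correlation lengths for coarse-grained patchiness to be
measurable at all); band peak `A` = 1 so band-centre 24 h ratios reach ~2
(interval growth maps are displayed on a 1–3 scale); band width 1.5 rows;
`noise_sd` = 0.3, consistent with up-to-four-fold growth-rate differences
between nearby cells; `corr_len` 1 vs 4 and $\rho$ 0 vs 0.95 as the
wild-type-like vs *ftsh4*-like noise regimes; `pd_bias` 0.6 (growth
mildly PD-dominant); `a_div` = 200 µm² (divide at about double the
starting area); `p_giant` = 0.1.

## Measuring spatiotemporal averaging

`growth_heterogeneity_sd()` quantifies cumulative growth unevenness at
fixed band position: starting lineages are stratified into bins one cell
diameter tall, each stratum is linearly detrended in y (the deterministic
band has a finite gradient across a stratum, which would otherwise add a
noise-independent floor), per-stratum SDs of log cumulative growth are
pooled as the RMS, and two strata at each margin are dropped. Under the
paired default regimes the persistent mode retains a median ≥ 2× more
cumulative heterogeneity than the resampled mode (median over 20 paired
seeds).

`averaging_decay()` fits the power law of per-step heterogeneity
(SD of cumulative log growth divided by T) against T. With resampled noise
the exponent is close to −1/2; with fully persistent noise it is close
to 0. This fit is run on uniform-growth simulations (`band_peak = 0`): a
travelling band interacts with each lineage's accumulated positional
displacement, adding a persistent deterministic term that in-stratum
detrending cannot remove and that biases the fitted exponent upward; the
power law concerns the stochastic component, so the band is removed at the
source. Giant cells are retained in these measurements; they are few and
their growth noise follows the same law.

## What the simulator does and does not emulate

It reproduces the statistical structure the analysis depends on — banded
basipetal growth, tunable spatiotemporal growth noise, division/growth
colocalisation through threshold divisions, giant cells, PD-biased
anisotropy — on a flat polygonal tissue. It does not model mechanics
(turgor, wall stiffness), surface curvature, trichomes, cell types beyond
giant/non-giant, or organ outline shape; simulated tissues stay roughly
rectangular, so passing tests demonstrate correctness of the measurement
pipeline and the averaging mechanism, not fidelity to sepal geometry, and
genotype-specific numeric results from real imaging are outside what
simulation can reproduce.

## Numerical choices and limitations

Tolerances: round trips 1e-9 µm; telescoping identity 1e-10; affine
recovery 1e-8; isotropy tie-break at relative 1e-9 with θ reported as 0.
Heat-map display ranges (daughter counts 1–15, per-interval proliferation
1–4, areas 0–4000 µm², 24 h growth 1–3, 72 h growth 1–10, PD/ML 1–1.7)
clip at render time only. The shrunk-cell threshold is inclusive at 0.999,
flagging segmentation artefacts for curation rather than silently imputing
them; cells lost at the image edge are reported, never imputed. Problem
sizes in the test suite (grids of 4×3 to 12×10 cells, 20–50 seeds per
Monte-Carlo property) were chosen so each statistical check stabilises at
a few percent; all are package choices and can be scaled up by the user.
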