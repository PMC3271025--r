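---
title: "Methods: ommatidium segmentation, photoreceptor quantification, and two-state expression models"
author: "ommaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, quantification, expression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ommaquant)
```

This vignette documents the models and procedures in `ommaquant`, the
assumptions behind them, the tunable parameters, and the numerical
choices made where the design was genuinely open.

## Image model and assumptions

The pipeline assumes 8-bit multi-channel confocal stacks with ~250 nm
optical sections and ~160 nm pixels; one structural channel (a
phalloidin-like actin stain that renders all rhabdomeres bright) plus one
or two reporter channels. Slice 1 is the deepest section. Geometry
assumptions: ommatidial centers 12–15 µm apart, ommatidium radii 3–5 µm,
photoreceptor centers ~2 µm apart; rhabdomeres are near-vertical
cylinders over the usable z-range, so clustering can work in (y, x) alone
within a short window of slices.

## Segmentation (per-slice thresholding + 3D linking)

Each structural slice is max-filtered over 5×5-pixel windows. Two
semantics are provided: `tiled` (the default; one maximum per
non-overlapping window, written to every pixel of the window) and
`sliding` (the conventional moving-window filter). The filter erases
intra-ommatidial structure while keeping the ommatidium/background
contrast.

Thresholds then sweep 20 equally spaced levels of the 0–255 range from
high to low. At each level, 8-connected components are measured; a
growing region is frozen the first time its area enters the acceptable
range (default 500–1000 px). A component that contains a frozen region is
that region's continued growth and is skipped, so stopped regions do not
spawn annular duplicates. Because each region stops at its own level,
dim peripheral and bright central ommatidia are detected alike — the
point of local thresholding.

Linking slides a 5-slice window from the deepest slice upward: a region
that shares at least one (y, x) pixel with a nascent ommatidium's recent
footprint joins it; otherwise it seeds a new nascent ommatidium. A
running mean/SD of region sizes (20-slice window) drives the fused-region
correction: an incoming region larger than mean + SD donates only its
directly overlapping pixels; the remainder is re-assigned to adjacent
ommatidia it overlaps, or seeds a new volume. Two numerical guards keep
this correction from misfiring on noise: the tolerance never falls below
5% of the running mean (a tiny SD otherwise makes ordinary jitter look
like fusion), and a split remainder below 200 px is treated as ordinary
growth rather than a new ommatidium. Volumes are trimmed to their longest
contiguous z-run, and volumes spanning fewer than 5 slices (the linking
window) are dropped — an isolated single-slice region is not an
ommatidium. Ommatidia touching the image border are kept but flagged.

## Photoreceptor tracing and identity

Within each volume, the 800 most intense structural pixels in a 5-slice
window are clustered by k-means with k = 7 on their (y, x) positions.
Candidate pixels come from the padded bounding box of the volume's
regions (pad 8 px), so a rhabdomere partially clipped by the region mask
still contributes. The first window is seeded randomly (default 10
restarts, best within-cluster sum of squares kept) plus one deterministic
farthest-point start, which reliably places one seed per well-separated
rhabdomere; subsequent windows are seeded with the previous centers, so
cluster lineages trace cells. An emptied cluster is re-seeded at the most
intense unclaimed point.

Clustering quality is the maximal center displacement between consecutive
slices. The quantification range maximizes
(number of ommatidia whose maximal displacement ≤ cap) × (interval
length), ties broken toward longer intervals; the displacement cap
defaults to 2 px and is exposed in the configuration. The selection is
fully automatic (a landscape over all contiguous intervals is also
returned for inspection); a manual range can be imposed by quantifying
with an explicit `z_range`.

Identities follow a distance chain on the mean centers: the cell nearest
the centroid of all seven is the central R7/8 (the central pair is
reported jointly); the outer cell furthest from it is R3; R3's two
nearest neighbors are R2/R4; their remaining nearest partners are R1/R5,
distinguished because R5 — not R1 — has a neighbor (R6) among the
unlabeled cells; the candidate paired with R5 is R4, the other is R2.
The chain uses pairwise distances only, so labels are invariant under
rigid motions and uniform scaling; since real adjacency (R6 closer to R5
than to R1) breaks mirror symmetry, the chain resolves both eye
chiralities without a flag. Any decisive comparison closer than a 5%
relative margin renders the ommatidium `undetermined`, and it is excluded
rather than guessed.

## Quantification

For each ommatidium-slice, iso-intensity contours of the raw reporter
crop are classified against seven circular masks (radius 0.45 × the
minimal center distance, so masks never meet): contours enclosing all
seven mask centers form the background set B; contours overlapping
exactly one mask form that cell's exclusive set A_x; contours touching
two or more cells are the signature of light scattered from a bright
neighbor and are discarded; the rest are ignored (their counts logged).
A photoreceptor left without contours triggers one retry with its mask
grown by at most 3 px. "Overlap" means a polyline vertex inside the mask
disc or the mask center inside the polygon; "encloses" means all seven
centers inside.

Per-slice levels are length-weighted means of contour levels,
`Σ l_j I_j / Σ l_j`, over B (giving `I_omma`) and over A_x (giving
`I_pr`); the local relative intensity is `I_l = ⟨I_pr / I_omma⟩` over the
slices where both are defined. Because a change of illumination scales
every contour level in the crop, the ratio is invariant under
per-ommatidium intensity scaling — this is what corrects the curvature
and depth attenuation. Slices with an empty B set are skipped, not
imputed.

**Contour quantization.** Detection uses the 20-level convention on the
0–255 range. Quantification defaults to all integer levels (1…255,
configurable via `n_levels_quant`): with only 20 levels the lowest
representable background would be ~12.75 intensity units and the
length-weighted `I_pr` at most ~200, capping `I_l` near 15 — whereas
cells at `I_l` > 26 are a documented part of the on-state tail. Fine
levels on the raw 8-bit data resolve low backgrounds and preserve that
dynamic range.

## Synthetic retina generator

The generator is the package's test bed and defines the study
conditions. Defaults: 37 ommatidia (a three-ring hexagonal spiral),
13 µm lattice spacing, 4 µm ommatidium radius, 2 µm photoreceptor
spacing, 0.85 µm rhabdomere radius (PR centers ~2 µm apart with
sub-250 nm gaps imply ~1.7 µm rhabdomere diameters), voxels
0.25 × 0.16 × 0.16 µm, 60 slices (~15 µm of imaged depth — real stacks
are deeper, but quantification happens in an algorithm-chosen interval of
comparable length), curvature radius 250 µm with the cap concave toward
the objective (so peripheral light paths are longer and the center of a
section is brightest), attenuation 0.01 µm⁻¹, scatter fraction 0.05 with
a 1 µm Gaussian halo, sensor noise SD 2, cytoplasm level 12.3 of 255.
Per-ommatidium orientation jitter is ±8°; an optional helical twist
models the deep twisted region. Expression defaults to the reference
Rh6 two-week two-state parameters.

Rhabdomeres are rendered as linear radial (cone) profiles. For a cone
the image gradient is constant, so the length-weighted mean over
iso-contours equals the area mean of the profile (coarea); the generator
exploits this to program expression directly in `I_l` units: it inverts
the exact discrete forward map (which integer levels a peak crosses, with
ring-length weights) so that a cell's contour readout, normalized by the
closed-form expected background `expected_background_level()`, equals its
programmed level. Levels below the representable floor render as
intensity dips — rhabdomeres darker than the surrounding cytoplasm, as an
unlabeled rhabdomere appears — and the contour assignment handles bright
and dark cells identically. Programmed levels outside the 8-bit
representable range (roughly 1.3–15 `I_l` units at the default
brightness) are clamped and flagged `clipped` in the ground truth; within
one quantization step of the cytoplasm level there is a narrow dead zone
where the nearest renderable readout is used. The ground truth records
both the sampled and the rendered level.

What the generator does **not** emulate: a realistic optical PSF (only
Gaussian scatter halos), photobleaching, mechanical rhabdomere twist
beyond the parametric helix, pigment granules, staining variability
between retinae, and segmentation-relevant tissue pathology. Passing the
synthetic benchmarks therefore demonstrates the correctness of the
algorithmic chain under the stated geometry and noise, not performance on
every real-world artifact.

## Expression models

The off (basal) state and on (high) state each yield a gamma-distributed
protein level; shape `α = λ_m/γ_p` and scale `β = λ_p/γ_m` are the burst
parameters. The off density is shifted by `Δx`, the lowest level
detected (estimated as the sample minimum backed off by the first
order-statistic gap so the minimum keeps positive likelihood); the on
density is shifted to the mode of the off density,
`Δx + (α_off − 1) β_off` for `α_off > 1` and `Δx` otherwise (the mode
sits at the support boundary). The mixture weight `p_on` is the fraction
of cells in the on state.

Fitting is joint maximum likelihood over
(α_off, β_off, α_on, β_on, p_on) with `Δx` fixed: parameters are
log-transformed (logit for `p_on`), optimized by bounded L-BFGS-B from
seven quantile-split starts plus randomized ones, each polished with a
Nelder–Mead pass (the quasi-Newton step can stall on this surface), best
log-likelihood kept. Two identifiability rules are enforced. First, the
off component is the smaller-mean component; a label-switched optimum is
re-optimized from the swapped start. Second, shifted-gamma mixtures have
an unbounded likelihood — a J-shaped (α < 1) component can spike onto the
few points nearest its shift — so the mixture is kept only when its
advantage over the nested single-gamma fit survives trimming the three
largest per-point contributions and still clears an AIC margin;
otherwise the degenerate `p_on = 0` single-gamma solution is reported.
On data simulated from the reference parameter columns at their published
sample sizes, `p_on` is recovered within ±0.05 across seeds (±0.01–0.02
for the well-separated columns).

A caveat on `Δx`: estimating the shift from the sample minimum is biased
upward by the order-statistic offset, which scales like `n^{-1/α}` — for
steep off shapes (α ≈ 5–9) this is a substantial fraction of β, and shape
and scale estimates absorb the error. `p_on` is insensitive to this, but
parameter-recovery tests for α and β condition on the true shift. The
shift is computed per pooled dataset (a per-replicate alternative simply
means calling the fitter per replicate).

Auxiliary tools follow the field's conventions: two-normal mixtures by EM
with restarts and ordered means (component SDs floored at 10⁻³ of the
data SD, so atom-like data remain representable without divergence); a
one-parameter weight refit against fixed components for per-retina
variation; one-sample and one-sided two-sample Kolmogorov–Smirnov tests
(`D⁺ = sup(ECDF_a − ECDF_b)`: large when the first sample is
stochastically smaller — i.e. more repressed); Spearman correlations;
Gaussian-kernel smoothed densities evaluated as the direct sum
(reference bandwidths 0.3 for Rh3/Rh6/phalloidin, 0.5 for Rh5); the
molecule conversion (2.5×10⁵ molecules/µm³ at full rhabdomere density,
divided by the mean on-state level); and half-life → rate conversion,
`ln 2 / t½`, used to bound the on↔off switching rate below one event per
day given hours-scale Rhodopsin turnover. p-values are reported raw
(−log₁₀ transform for tables); no multiple-testing correction is applied
by default.

## Toy bistable network

Rhodopsin protein P induces its own production machinery through a
Hill-type positive feedback, `m (basal + v_max P^h / (P*^h + P^h))`,
against linear degradation `δP`; `m` is the Rhodopsin mRNA level. The
published account does not fix the functional form, so the Hill form and
its defaults (`h = 4`, `basal = 0.05 v_max`, `v_max = 1`, `P* = 1`,
`δ = 0.45`) are this package's choices, exposed in
`toy_network_params()`; the rate balance is analyzed in the protein
coordinate. Fixed points come from sign-change bracketing on a 4000-point
grid refined by bisection; stability from the sign of the net-rate
derivative. For low or high `m` the system is monostable; in an
intermediate window it is bistable, and the window empties as `h → 1`.
Reducing `m` from a bistable parameterization restores monostable-low:
the repressor acts as a buffer, controlling the stability of the network
rather than its state.

## Problem sizes used in the test suite

Unit tests run on small flat noiseless retinae (7–19 ommatidia, 20
slices). The end-to-end identity benchmark uses 20 seeded default stacks
(37 ommatidia, 60 slices each); recovery benchmarks use the published
sample sizes (n = 672–4,422). These sizes were chosen to exercise every
code path at realistic geometry while keeping a full run in the tens of
minutes on one CPU.
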