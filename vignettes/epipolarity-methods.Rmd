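---
title: "Quantifying planar polarity, topological events, FRAP and ablation recoil in segmented epithelia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planar polarity, topological events, FRAP and ablation recoil in segmented epithelia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipolarity)
```

## Scope and conventions

`epipolarity` implements the quantitative chain used to study planar cell
polarity and its mechanical context in the *Drosophila* pupal wing: per-cell
polarity scoring on segmented label maps, orientation statistics of cell
divisions and T1 neighbor exchanges, FRAP recovery-curve analysis of
junctional protein stability, and laser-ablation recoil velocimetry of
tissue tension. It consumes segmentation artifacts (integer label maps,
junction and tracking tables), never raw microscopy: watershed segmentation
is out of scope, as are vertex-model mechanics and any biological
interpretation of the outputs.

One angle convention is used end to end. Coordinates are pixel-centered and
0-based with x rightward and y downward; orientations are axial (defined
modulo 180 degrees) and measured from +x counterclockwise on screen. Every
user-facing angle is normalized against the reference axis drawn through
the line of sensory organ precursor (SOP) cells, so that 0 degrees is the
proximodistal (PD, hinge-to-tip) axis and 90 degrees the anteroposterior
(AP) axis. Orientations in `[45, 135)` are classified AP, the complement
PD; the lower bound is inclusive and the upper exclusive, a measure-zero
choice fixed once for determinism. Because axial data wrap at 180 degrees,
all averaging uses the nematic (double-angle) representation
$Q = \langle m\,(\cos 2\theta, \sin 2\theta)\rangle$; naive angle means
would be wrong.

## PCA polarity

The polarity of a cell is estimated from intensities attached to its
boundary. Two normalizations precede the measurement. First, the boundary
is *shape-normalized*: centered boundary points are mapped through the
inverse principal square root of their second-moment tensor, which whitens
any cell to isotropic second moments. This is what makes the score robust
to cell eccentricity — an elongated cell would otherwise read as polarized
along its own long axis regardless of the signal. Second, each cell's
boundary intensities are divided by their own mean, removing
cell-to-cell illumination differences.

The polarity angle is then the direction maximizing the intensity-weighted
variance of boundary-point displacement from the centroid, i.e. the
principal axis of $M = \tfrac1n \sum_i w_i\, u_i u_i^\top$ over whitened
displacements $u_i$ with normalized weights $w_i$. The magnitude is the
normalized anisotropy $(\lambda_1 - \lambda_2)/(\lambda_1 + \lambda_2)$
of $M$, a dimensionless score in $[0, 1]$; the bounded, scale-free form was
chosen so magnitudes are comparable across cells and samples. A cell with
isotropic signal reports magnitude 0 and, by convention, angle 0 rather
than NA. For the reference pattern
$I(\varphi) = 1 + m \cos 2(\varphi - \theta_0)$ on a circle the magnitude
is exactly $m/2$, which the tests exploit.

Note the geometry this produces: signal enriched on PD-*oriented* junctions
sits on a cell's anterior/posterior sides, so the displacement variance is
maximal along AP and the cell polarity angle reads 90 degrees. The
synthetic end-to-end check (junction enrichment axis 0 degrees yields
median cell polarity in `[85, 95]` degrees) encodes exactly this.

Coarse-graining averages per-cell polarities as nematic tensors over square
spatial tiles whose side is `block_cells` (default 3) times the median cell
diameter. In an irregular tissue "3 x 3 cells" can only be approximate;
spatial tiles of that scale are the deterministic equivalent. Circular
histograms use fixed 10-degree bins over `[0, 180)`. Two weighting modes
are provided because sum-of-magnitudes and mean-magnitude-per-bin are both
defensible readings of magnitude-weighted histograms; `magnitude_sum` is
the default, and `count` serves event histograms.

## Junction graphs

Junctions are enumerated from 4-connected label adjacency. A junction's
orientation is the angle of the chord between its two most distant
interface points — the automated equivalent of drawing a line along the
junction — not a per-pixel tangent average, which is noise-dominated for
short junctions. Junction intensity is averaged over a band (default 3
pixels wide, matching the typical junctional signal width at 210 nm
pixels) centered on the shared boundary, excluding pixels that fall in the
band of a junction with any third cell so vertex signal is not double
counted. The band width is exposed as a parameter since no canonical value
exists.

## Divisions and T1 transitions

The tracking table is the single source of lineage truth; label maps are
per-frame only. A division is a lineage replaced in one frame by exactly
two child lineages; its new-junction angle is the orientation of the
junction between the daughters in their first shared frame, and the
*division angle* adds 90 degrees (modulo 180) — the division axis is
perpendicular to the new interface. Daughters without a shared junction
are flagged, not dropped, so event counts stay auditable.

T1 detection contracts junctions shorter than the bond cutoff (default 4
pixels, interpreted as junction length in pixels) into 4-way vertices. An
event is emitted when a previously adjacent pair (junction at or above
cutoff) loses contact while a diagonal pair of common neighbors gains a
junction at or above cutoff. Events involving a cell that divides within
one frame are excluded: divisions produce local rearrangements that mimic
neighbor exchanges, and the one-frame window is this package's explicit
operationalization of the manual screening such data normally receive.
AP:PD ratios use the `[45, 135)` band; with zero PD events the ratio is
reported as undefined rather than infinity.

## FRAP analysis

Traces follow the standard two-channel protocol: per pupa and
junction-orientation class, four bleached ROIs and four unbleached control
ROIs, three pre-bleach images, an immediate post-bleach image at $t = 0$,
then recovery images at 5 x 5 s, 10 x 10 s, 10 x 15 s and 7 x 30 s (last
at 485 s), with a scalar background per wing. Quality control gates:
initial bleaching $100 - 100\,(\bar I_0 / \bar I_{-1})$ must lie in
$[50, 75]$ percent and acquisition bleaching
$100\,(\bar U_{-1} - \bar U_{end})/(\bar U_{-1} - bg)$ below 25 percent.
Gate failures warn and flag rather than abort, so batch runs complete.

Each ROI is corrected for acquisition bleaching and background,

$$A_n = \frac{\bar U_{-1} - bg}{U_n - bg} \cdot \frac{I_n - bg}{\bar I_{-1} - bg},$$

then normalized to $N(n) = (A_n - A_0)/(1 - A_0)$ so the bleach floor maps
to 0 and the pre-bleach level to 1. The reference denominator is the
pre-bleach mean $\bar I_{-1}$: dividing by the first post-bleach intensity
$I_0$ instead would force $A_0 = $ a bleaching-only ratio near 1 and make
the normalization degenerate, while the pre-bleach reference is the only
reading under which pre-bleach intensities sit at 1 and post-bleach at 0.
A `literal_i0` flag implements the $I_0$ reading for comparison. Whether
bleached and control ROIs share one background is not standardized; a
single scalar per wing is assumed. The correction exactly cancels any
bleaching profile shared multiplicatively by both channels, and the whole
chain is invariant to rescaling all intensities and the background by a
common factor — both enforced as tests.

Recovery is fitted by nonlinear least squares to the one-phase model
$y = y_{max}(1 - e^{-\alpha t})$, with $y_{max}$ the mobile fraction
(lower plateau = more stable protein) and half-life $\ln 2 / \alpha$.
Start values are taken from the data ($y_{max}^0$ = last observation,
$\alpha^0$ from the time to half plateau), with bounds
$y_{max} \in (0, 1.5]$ and $\alpha \in (0, 10]$ s$^{-1}$. A two-phase
variant $A_1(1 - e^{-\alpha_1 t}) + A_2(1 - e^{-\alpha_2 t})$,
$\alpha_1 > \alpha_2$, is provided; on one-phase data it collapses (an
amplitude near zero or coincident rates) and its confidence intervals are
frequently undefined — these are reported as NA, never as a crash.
Aggregation follows the replicate structure: technical replicates (ROIs)
are averaged into one curve per pupa, each pupa is fitted, a group-level
curve is fitted to the cross-pupa mean, and plateaus are compared between
two groups by an unpaired Student's t-test on per-pupa $y_{max}$ values
(N = pupae).

Confidence intervals are 95 percent Wald intervals from the asymptotic
covariance of the NLS estimate. A calibration caveat found while testing:
on curves with independent noise these intervals cover the truth at their
nominal rate (the Monte-Carlo tests require at least 90 percent), but for
group-level fits to pipeline-normalized curves they undercover, because
every timepoint shares the same noisy pre-bleach reference and bleach
floor, correlating residuals that the asymptotic formula assumes
independent. Inference between groups therefore rests on the per-pupa
t-test, which is immune to this correlation; the group-fit intervals
describe curve uncertainty under the fit's own assumptions.

## Ablation recoil

Tracked vertex clouds around the ablated hole are fitted per frame with a
direct least-squares conic fit constrained to an ellipse (a generalized
eigenproblem; exact point sets are interpolated to numerical precision,
and the fit is equivariant under rotation and translation). The initial
recoil velocity of each axis is the ordinary least-squares slope of axis
length against time over frames $t = 1..6$ s at 1 frame per second — the
operational "first 5 s" definition, used verbatim rather than a model
derivative, so it is invariant to length offsets and linear in stretch.
Axis dynamics over the 180 s window are additionally fitted with the
saturating relaxation $L(t) = L_\infty - (L_\infty - L_0)e^{-t/\tau}$.
No functional form is canonical for this step; the Kelvin-Voigt-type
saturating exponential is the standard viscoelastic choice and matches the
plateauing opening of circular ablations. It is a documented assumption,
kept separate from the velocity readout, which does not depend on it.
Major and minor velocities are compared across pupae with a Student's
t-test; tension is called isotropic when the test is not significant.
Configuration defaults use a 24.3 micrometer ablation diameter.

## Statistics

Angle distributions are compared with the standard linear two-sample
Kolmogorov-Smirnov test on `[0, 180)` with the origin pinned to the SOP
axis. For genuinely circular data this statistic depends on the chosen
origin; an origin-free alternative (Kuiper) is deliberately out of scope
because the reference workflow uses the linear test with exactly this
origin. Exact p-values are used for small tie-free samples
($n_1 n_2 \le 10^4$), the asymptotic approximation otherwise — the scope's
sample sizes (hundreds to thousands of events) make the asymptotic branch
the operative one. Raw angles, not binned histograms, are tested; binning
exists only for plotting. Group values (e.g. per-pupa AP:PD ratios) are
compared by Student's t-test for two groups and one-way ANOVA with
Tukey-Kramer pairwise comparisons for three or more, with raw
pooled-variance pairwise p-values reported alongside the adjusted ones.

## Synthetic data: what it emulates and what it does not

Raw data behind this kind of study are typically available only on
request, so every input has a seeded generator with recorded ground truth,
and the package's evidence is round-trip parameter recovery:

* **Tissue**: a rasterized Voronoi tessellation with two Lloyd relaxation
  iterations at 3 micrometer mean cell diameter and 210 nm pixels
  (realistic for pupal wing apical sections), with an optional global
  anisotropic stretch for cell elongation. Mean elongation anisotropy of
  the isotropic tissue is about 0.3 on the eigenvalue scale (aspect ratio
  about 1.35), typical of Lloyd-relaxed tessellations.
* **Polarity**: junction intensities
  $base\,(1 + c \cos 2(\theta_j - \theta_{enrich}))$ painted into the
  junction bands, defaults $c = 0.5$ on the PD axis.
* **Events**: scripted division splits (daughter interface through the
  mother centroid at an axial von Mises angle) and T1 pixel surgeries
  (the corridor around a junction is reassigned to the diagonal pair,
  split along the scripted new-junction angle). Every T1 surgery is
  validated on the local adjacency pattern — only the intended bond is
  lost and only the diagonal bond gained at the cutoff — and reverted and
  re-placed otherwise, so the generator's ground truth is exact by
  construction. Division axes and new-junction angles are drawn from an
  axial von Mises distribution sampled by the doubling trick (sample the
  circular distribution on `[0, 360)`, halve), the correct construction
  for axial data.
* **FRAP**: the recovery signal
  $pre\,[(1 - d) + d\,y_{max}(1 - e^{-\alpha t})]$ with bleach depth $d$,
  multiplied by a per-frame geometric photobleaching factor calibrated so
  end-to-end acquisition bleaching equals the requested percentage, plus
  background and optional Gaussian noise. Defaults: $y_{max}$ 0.6 (PD)
  vs 0.8 (AP), $\alpha = 0.02\,$s$^{-1}$, 60 percent initial and 15
  percent acquisition bleaching — plateaus differing across orientation
  classes with a shared rate, the regime the assay is designed to resolve.
* **Recoil**: ellipse axes following the saturating relaxation with the
  total opening calibrated so the frames-1-to-6 OLS slope equals the
  requested velocity exactly; vertices sampled on the outline with
  positional noise. Defaults $\tau = 20$ s, $L_0 = 24.3$ micrometers,
  velocities of order 0.1-0.2 micrometers per second, and the study-like
  designs of 7 (isotropic) and 11 (anisotropic) pupae.

Each generator draws from its own stream derived from the master seed by a
stable sub-key, so adding a generator never perturbs existing fixtures,
and every output is a pure function of its parameters and seed.

The generators deliberately omit: point-spread blur and detector noise
statistics (additive Gaussian only), segmentation errors, tracking errors,
cell growth and rearrangement dynamics between scripted events,
out-of-plane movement, and biological covariance between readouts.
Passing tests therefore demonstrate that the estimators are correct and
calibrated on clean, known-truth data of realistic geometry — not that
they are robust to segmentation artifacts or imaging pathologies of real
microscopy.

## Numerical choices and degenerate inputs

* NLS: Levenberg-Marquardt, `ftol` 1e-10 (FRAP) / 1e-12 (recoil), up to
  500-1000 iterations; data-driven starts as above; recoil fits retry from
  range-based starts before failing.
* Zero-magnitude polarity and circle ellipses report angle 0 by
  convention; collinear boundaries, all-zero intensities, empty label
  maps, missing recoil frames and insufficient pre-bleach points raise
  errors naming the problem; FRAP QC violations warn and flag.
* Problem sizes in the test suite: the event-extraction check runs 60
  divisions plus 30 T1s in a 1000-cell, 8-frame tissue; FRAP calibration
  uses 200 replicates of the 10-pupae x 8-ROI design; recoil calibration
  200 nulls and 200 anisotropic designs at 6 post-ablation frames; the KS
  oracle is exhaustive over all sample pairs of size at most 6 from a
  5-angle alphabet. These sizes were chosen to estimate the relevant rates
  with useful precision while keeping the default suite fast.

## Known limitations

* The linear KS test on angles is origin-dependent; results are only
  meaningful relative to the SOP-anchored frame.
* Group-level Wald confidence bands on FRAP fits undercover under the
  pipeline's shared-reference noise (see above); use the per-pupa t-test
  for inference.
* T1 detection assumes the tracking table is correct; it does not attempt
  to repair tracking errors, and higher-order rosette resolutions and T2
  extrusions are out of scope.
* The recoil dynamics model is an assumption; absolute stress inference
  would additionally require a viscosity scale and is out of scope.
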