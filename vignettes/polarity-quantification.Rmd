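---
title: "Quantifying cortical PAR polarity: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical PAR polarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parquant)
```

## The measurement problem

In the *C. elegans* zygote, anterior PAR proteins (PAR-3, PAR-6, PKC-3,
CDC-42) and posterior PAR proteins (PAR-1, PAR-2, LGL-1, CHIN-1) partition
the cell cortex into two complementary membrane domains. Quantifying that
partition from fluorescence microscopy comes down to a small set of
recurring measurements: how bright is the membrane along the perimeter,
where are the domain boundaries, how big are the domains, how asymmetric is
a signal between the two cell halves, how punctate versus diffuse is a
cortical pool, how fast does the cortex flow, and how mobile is a
cytoplasmic protein. `parquant` implements each of these as a small,
composable operation, and pairs them with a synthetic-embryo generator that
knows the true value of every quantity, so the whole pipeline can be
validated end to end.

## Membrane profiles and their normalization

The substrate of most measurements is the *membrane profile*: intensity as
a function of normalized arclength $x \in [0, 1)$ around the cell
perimeter. From a midsection image and a user- or generator-supplied
contour, `extract_stripe()` straightens a 60-pixel-wide band centered on
the membrane by sampling along the local inward normal with bilinear
interpolation, one row per pixel of perimeter. `membrane_from_stripe()`
then takes, at each arclength position, the mean of the 4 brightest pixels
within the central third of the depth — the membrane is the locally
brightest structure, and a fixed small $k$ makes the estimate robust to
where exactly the membrane sits within the band. The outermost and
innermost sixths of the band estimate local background and cytoplasm.
`normalize_profile()` computes

$$\tilde I(x) = \frac{I(x) - B(x)}{C(x) - B(x)},$$

so pure background maps to 0 and pure cytoplasm to 1, after smoothing
$B$ and $C$ with a circular moving average (window 5% of the perimeter) so
that noise in the denominator is not amplified. The band fractions
(central 1/3, edges 1/6) are configurable; the defaults are a reasonable
reading of "central pixels" and "inner and outer edges" for a 60-pixel
stripe, and the validation suite shows they reproduce generator truth to
within 2% away from domain boundaries.

## Error-function boundary models

Domain boundaries in PAR profiles are sigmoidal, and are modeled with the
error function. A single boundary is

$$I(x) = a + \tfrac{b}{2}\,\mathrm{erf}\!\big(m\,(x - c)\big),$$

with baseline $a$, signed amplitude $b$, steepness $m$ (units of
1/arclength) and boundary position $c$. A two-boundary domain is

$$I(x) = a + \tfrac{b}{2}\left[\mathrm{erf}\!\big(m(x - c_1)\big) -
\mathrm{erf}\!\big(m(x - c_2)\big)\right].$$

We parameterize the erf argument as $m(x - c)$ so that $c$ is directly the
boundary *position* in arclength units; with the alternative grouping
$mx - c$ the position would be $c/m$, which makes the fitted parameters
awkward to compare across embryos with different boundary steepness.
Likewise we treat the posterior domain center as $(c_1 + c_2)/2$ — the
midpoint of the two boundaries — rather than $(c_2 - c_1)/2$, which is half
the domain *size* and cannot be a position. The signed amplitude $b$
replaces a $\pm$ choice of model: $b > 0$ describes a marker enriched
inside $[c_1, c_2]$ (posterior-type), $b < 0$ one depleted there
(anterior-type), and the sign is a fit output.

Domain metrics follow directly: posterior size $(c_2 - c_1)/L$, anterior
size $1 - (c_2 - c_1)/L$ (with $L = 1$ for normalized profiles; the two
sizes sum to 1 exactly by construction), segregation efficiency of an
anterior marker as its relative anterior domain size (smaller = more
efficient), and the domain-size change ratio across a treatment as
after/before.

### Fitting: initialization, multi-start, and the circular sign degeneracy

Both fits use trust-region nonlinear least squares (`minpack.lm::nls.lm`)
with tolerances of $10^{-14}$ on the residual and parameter changes, which
on noiseless data recovers parameters to better than $10^{-6}$. The single
fit initializes $c$ at the half-maximum crossing and falls back to a
multi-start over a coarse $9 \times 3 \times 2$ grid of
$(c, m, \mathrm{sign}\,b)$ when the first attempt stalls. The double fit
must handle circular data in which the domain may straddle the profile
origin: it scans 8 circular phases, detects the largest contiguous
above-threshold (or below-threshold, for depleted markers) run in each
shifted frame to initialize $(c_1, c_2)$, fits with the domain
parameterized as center $\pm$ half-width (which enforces $c_1 < c_2$), and
maps the best solution back to the input frame. `c1` is reported in
$[0, 1)$; `c2` may exceed 1 when the domain wraps the origin, and domain
sizes are unaffected by circular shifts of the input.

One genuine ambiguity deserves note: on circular data, a domain enriched
on $[c_1, c_2]$ with amplitude $+b$ is nearly indistinguishable from a
domain depleted on the complementary arc with amplitude $-b$; only the
unsaturated erf tails break the tie, and at realistic noise the residual
difference is smaller than the noise. When the marker's polarity is known
— which it always is in practice — `fit_double_boundary(...,
amplitude_sign = "positive")` (or `"negative"`) restricts the fit to the
correct representation. The default `"auto"` keeps whichever residual is
lower.

Degenerate inputs are flagged rather than mis-fit: a profile whose range is
below a floor ($10^{-8}$, relative) returns `converged = FALSE` with
undefined boundaries, and downstream metric functions refuse unconverged
fits.

### Registration and fixed-embryo comparisons

For co-stained embryos, `register_profiles()` circularly shifts both
channels of each pair so the reference channel's fitted inflection point
sits at a common position; `boundary_offset()` then converts the residual
boundary difference of the second channel to micrometers, signed positive
toward the posterior. For fixed immunofluorescence images annotated by
hand, `retraction()` intersects the pole-to-pole equatorial line with the
line joining the cortical domain ends and reports the distance from that
intersection to the posterior pole; parallel lines are an error and
intersections outside the pole segment are flagged, not silently accepted.
Fits used in fixed-cell profile comparisons min-max normalize each segment
to $[0, 1]$ first (boundary position and steepness are invariant to that
affine rescaling); live profiles instead use cytoplasm normalization as
above.

## Asymmetry and cluster indices

The asymmetry index of a feature with anterior signal $A$ and posterior
signal $P$ is

$$\mathrm{ASI} = \frac{A - P}{2(A + P)} \in [-0.5, 0.5],$$

antisymmetric under swapping the halves. Raw values are normalized to the
mean raw ASI of the matched control group, so 1 means wild-type asymmetry
and 0 complete loss; by construction the normalized control mean is exactly
1. Halves are defined by the perpendicular bisector of the pole axis
(image inputs) or, for aligned profiles in the canonical orientation
(posterior domain centered at $x = 0$), by $x \in [0.25, 0.75)$ versus the
rest. $A$ and $P$ may be membrane means, cytoplasm means, cross-sectional
areas, or focus densities, depending on the assay.

The cluster index is the population variance of background-subtracted,
mean-normalized intensity over an ROI: zero for a uniform signal, growing
as signal concentrates into puncta, and invariant under affine intensity
transforms when the supplied background tracks the offset. Population
rather than sample variance is used deliberately — the index is a
descriptor of the specific image region, not an estimator of a parent
distribution — and the choice is fixed for cross-implementation agreement.

## Punctum detection and density asymmetry

`detect_foci()` follows the classical band-pass / local-maximum /
centroid-refinement scheme of particle-tracking pipelines: Gaussian
smoothing at the noise scale minus a boxcar background at the feature
scale (negatives clipped), local maxima above a threshold (default: mean +
3 sd of the band-passed image), sub-pixel centroids by intensity-weighted
mean within the feature window, and greedy suppression of duplicates
closer than half the feature diameter, keeping the brighter. The
intensity-weighted centroid (rather than a Gaussian fit) is deterministic
and accurate to well under half a pixel at the signal-to-noise ratios where
focus counting is meaningful. `partition_thirds()` cuts the embryo mask at
1/3 and 2/3 of the pole-axis projection; `foci_density_asi()` compares
anterior and posterior focus counts *per unit area* of their thirds — the
middle third is excluded because the comparison is anterior versus
posterior — and an empty detection yields ASI 0 by convention, with a
warning, rather than an undefined ratio.

## Membrane signal, flow, and recovery kinetics

For total-membrane-signal estimation, `cross_section()` projects a
straightened stripe along arclength to a depth profile running
background → membrane → cytoplasm, rescaled so the outer edge band
averages 0 and the inner 1 (idempotent). A mean reference from
membrane-free embryos (`reference_cross_section()`, with a per-depth
dispersion report) defines the bare outside-to-inside step;
`total_membrane_signal()` is the sum of the difference over the full depth
range, negative deviations included — noise cancels in expectation and
clipping would bias the estimate. The validation suite confirms the
measure is additive across bumps and linear in the generator's membrane
amplitude ($R^2 > 0.99$ over a 10-point ladder). PAR-2 retention is the
after/before ratio of membrane signal from cytoplasm-normalized profiles:
1 for full retention, 0 for complete clearance.

Cortical flow speed uses the straight line connecting a granule's start
and end points on a kymograph — total distance over time, converted
through the pixel size and frame interval to μm/min — deliberately
ignoring intermediate wiggle, and `embryo_flow_speed()` averages at least
10 traces per embryo (fewer triggers a warning). FRAP analysis normalizes
the mean of the measurement box to the pre-bleach mean (no whole-cell
photobleaching correction is applied) and, as a convenience, fits a single
exponential $I(t) = p - (p - f)e^{-kt}$ whose half-time $\ln 2 / k$
summarizes mobility.

## The synthetic-embryo generator

Every stage above is validated against `ground_truth()` records rendered
by the generator, which emulates exactly the statistical structure the
analysis assumes — no more:

- **Midsection embryos**: an axis-aligned ellipse (default semi-axes
  55 × 35 px in a 240 × 180 image) with a 5-px membrane ring whose
  intensity along arclength equals the double-erf model, over uniform
  cytoplasm (500 AU) and background (100 AU). The default profile —
  baseline 550 AU, amplitude 900 AU, steepness 30, boundaries at 0.3 and
  0.7 — describes a wild-type-like posterior domain covering 40% of the
  perimeter.
- **Cortical images**: a diffuse level (300 AU) plus Gaussian puncta
  (sd 2 px, peak 200 AU) at uniform positions; optional per-third weights
  bias placement to create known density asymmetries. Overlapping spots
  are permitted.
- **Kymographs**: linear traces at the ground-truth velocity; the default
  7.1 μm/min matches measured wild-type cortical flow. Exact sub-pixel
  endpoints are recorded, so endpoint-based speed recovery is exact by
  construction.
- **FRAP stacks**: a uniform field with a central 20-px stripe bleached to
  a floor (default 20%) that recovers exponentially with a known
  half-time; five pre-bleach frames by default, 2 s frame interval.
- **Noise**: Poisson shot noise on (signal × `poisson_scale`) photons plus
  additive Gaussian read noise — the standard fluorescence camera model.
  Setting `poisson_scale` to 0 (or `Inf`) disables the shot-noise
  component, `noise_gaussian_sd = 0` the read noise. Where validation
  tests quote an SNR, it is amplitude / Gaussian sd with shot noise off,
  which keeps the noise level exactly controlled.

Generators are pure functions of (truth, shape arguments): the seed lives
in the record, outputs are bit-reproducible, and the global RNG state is
left untouched.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: optical blur beyond the Gaussian spot shape
(no PSF model), reaction–diffusion–advection dynamics of the PAR system,
cluster size distributions (real cortical clusters are heterogeneous),
out-of-focus light, uneven illumination, or segmentation error (contours
are exact). Recovery accuracies quoted here are upper bounds for real
embryos, where contour placement and background structure dominate the
error budget.

## Validation problem sizes

The shipped validation suite exercises: 100 seeded noiseless single-erf
segments (maximum parameter error below $10^{-6}$) and 100 at SNR 10
(median boundary error below 0.005 perimeter units); 50 double-erf fits
checked against a 50 × 50 brute-force $(c_1, c_2)$ grid oracle with
analytic linear parameters (the optimizer never loses); 50 rendered
embryos at SNR 10 carried through stripe extraction, normalization, and
the double fit (median posterior-size error under 0.02, typically under
0.005); 20 spot fields of 50 well-separated high-SNR puncta (precision =
recall = 1); 200 seeded 4:1-biased placements (mean density ASI within
0.02 of the binomial expectation −0.3); and exact unit-conversion,
half-time, and retention checks for the kinetics module. The acceptance
script (`scripts/acceptance.R`) recomputes the same quantities from
scratch at 30 embryos for the image pipeline, which keeps a full run
under a minute without changing any conclusion.

## Known limitations

- Contours are supplied, not segmented; all geometric accuracy statements
  assume the contour traces the membrane.
- The double-erf model assumes a single contiguous domain; profiles with
  fragmented domains will fit poorly (high `rss`) rather than fail loudly.
- The exact stripe band fractions and the cluster-index background region
  are conventions; both are exposed as arguments and should be held fixed
  within a study.
- Focus detection assumes roughly isotropic puncta near the chosen
  diameter; elongated or strongly overlapping clusters are counted as
  single foci.
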