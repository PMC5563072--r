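# parquant

Image quantification for cortical cell-polarity studies in the
*C. elegans* zygote. The package turns midsection and cortical-plane
fluorescence images into the standard polarity measurements: membrane
intensity profiles, error-function domain-boundary fits, domain sizes and
segregation efficiency, asymmetry and cluster indices, punctum density
asymmetry, kymograph cortical-flow speeds, photobleach-recovery curves,
and total-membrane-signal estimates. It is written for researchers
quantifying PAR protein localization, but the operations are generic to
any cell with a membrane domain read out along its perimeter.

A synthetic-embryo generator ships with the package and knows the ground
truth of everything it renders, so every stage of the pipeline is
validated by parameter recovery rather than by eye.

## The models

Membrane intensity along normalized arclength *x* ∈ [0, 1) is modeled
with error-function boundaries. One boundary (e.g. when comparing
co-stained markers):

    I(x) = a + (b/2) · erf(m (x − c))

Two boundaries delimiting a domain:

    I(x) = a + (b/2) · [erf(m (x − c1)) − erf(m (x − c2))]

with baseline *a*, signed amplitude *b* (positive = enriched inside
[c1, c2], as for a posterior marker; negative = depleted, as for an
anterior marker), boundary steepness *m*, and boundary positions *c*.
Posterior domain size is (c2 − c1)/L, anterior size 1 − (c2 − c1)/L.

The asymmetry index of a feature with anterior signal A and posterior
signal P is

    ASI = (A − P) / (2 (A + P))   ∈ [−0.5, 0.5]

normalized to the mean of a control group so that 1 is wild-type
asymmetry and 0 complete loss. The cluster index is the population
variance of background-subtracted, mean-normalized intensity in an ROI.
Cortical flow speed is endpoint distance over time on a kymograph trace,
in μm/min.

## Worked example

Render a noisy synthetic embryo with a posterior domain spanning 40% of
the perimeter, extract and normalize its membrane profile, fit the
two-boundary model, and compute domain metrics and the membrane ASI:

```r
library(parquant)

truth <- ground_truth(boundary_c1 = 0.30, boundary_c2 = 0.70,
                      noise_gaussian_sd = 45, poisson_scale = 1, seed = 11)
emb    <- gen_midsection_image(truth)
stripe <- extract_stripe(emb$image, emb$contour, width = 60)
prof   <- normalize_profile(membrane_from_stripe(stripe))

fit <- fit_double_boundary(prof, amplitude_sign = "positive")
fit
#> <double_boundary_fit> a=1.148 b=2.204 m=28.47 c1=0.29876 c2=0.69871 (rss=1.11)

dm <- domain_metrics(fit)
dm
#> <domain_metrics> posterior 0.4, anterior 0.6, center 0.4987

aligned <- align_profile(prof, dm$posterior_center)
inp <- halves_from_profile(aligned)
asi_raw(inp)
#> A = 1.150, P = 2.910, raw ASI = -0.217
```

The fitted boundaries (0.299, 0.699) recover the generating values (0.30,
0.70) through the full image pipeline, the posterior domain size is 0.400,
and the negative ASI says the marker is posterior-enriched — the raw
membrane ASI of a feature is negative when the posterior half is
brighter. A kymograph trace covering 20 px in 200 frames at 0.1 μm/px and
1 s/frame gives the unit-conversion check:

```r
flow_speed_from_trace(kymo_trace(10, 1, 30, 201,
                                 pixel_size = 0.1, frame_interval = 1))
#> [1] 0.6      # μm/min
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/parquant.R` (subcommands `synth`, `extract`, `fit-single`,
`fit-double`, `asi`, `foci`, `frap`).

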