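---
title: "Methods: quantitative skeletal phenotyping with skelphen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative skeletal phenotyping with skelphen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelphen)
```

# Scope

skelphen implements the quantitative analysis arm of a skeletal
phenotyping screen for knockout mouse models: biomechanical feature
extraction from destructive-test curves, bone-quality scoring against a
wild-type reference regression, calibrated gray-level densitometry with
percent-scaled Kolmogorov–Smirnov comparison, ASBMR histomorphometry,
and supporting statistics (ΔΔCT expression, group comparisons, CV-based
power). Because screens of this kind rarely deposit raw instrument data,
every input can be generated synthetically with known ground truth; the
test suite exercises the full pipeline against that truth.

# Biomechanics

A destructive three-point-bend or compression record is a
load–displacement trace sampled at a fixed rate (default 20 Hz) under a
constant displacement rate (default 0.03 mm/s). Four parameters are
extracted:

* **stiffness** — slope (N/mm) of the linear elastic phase;
* **yield load** — load where the curve departs from elasticity;
* **maximum load** — the global post-contact maximum;
* **fracture load** — load at terminal failure.

## Contact and the elastic window

Contact is the first sample whose load reaches `contact_fraction`
(default 1%) of the curve maximum. The elastic window is sought among
windows between contact and the load maximum of length at least
`min_window_fraction` (default 10%) of that span. A window qualifies if
its linear-fit R² clears

```
threshold = max(r2_min, 1 - r2_relax * (1 - R2_best))
```

with `r2_min = 0.995`, `r2_relax = 2`, and `R2_best` the best R²
achieved by any candidate window. The selected window is the **longest
passing window anchored at the earliest start position from which any
window passes**; stiffness is the least-squares slope over it.

Two details of this rule are deliberate and worth stating. First, a
ductile curve's post-yield (hardening) segment is also linear and is
often *longer* than the elastic segment, so an unanchored
"longest linear window" rule would return the hardening slope; anchoring
at the earliest passing start selects the first linear region after
contact, which is the elastic phase by definition. Second, on noiseless
data a plain fixed threshold of 0.995 admits windows contaminated by a
few post-yield points (a handful of points barely dent R² when the
window variance is dominated by the elastic rise), which biases the
slope; the adaptive term tightens the threshold toward the best
achievable R², so noiseless curves recover the elastic slope to machine
precision while noisy curves fall back to the fixed floor.

## Yield and fracture

The yield criterion in the field is rarely stated precisely; we adopt an
offset rule exposed in configuration: yield is the load at the first
post-window sample where the extrapolated elastic line exceeds the
observed load by `yield_offset_fraction` (default 2%) of the maximum
load. If no sample qualifies, yield is set to the maximum load and the
record is flagged `"no distinct yield"` (brittle limit). Fracture is the
load immediately preceding the largest single-step post-peak drop,
provided that drop is at least `fracture_drop_fraction` (default 30%) of
the maximum load; otherwise the final load is reported with a
`"no clean fracture"` flag. An optional centred moving average (off by
default) is used for event detection only; reported loads always come
from the raw trace.

```{r biomech-example}
cv <- gen_load_displacement(curve_params(noise_sd = 0.05), seed = 1)
unlist(extract_biomech_params(cv)[c("yield_load", "max_load",
                                    "fracture_load", "stiffness")])
```

# Bone quality

Bone quality denotes the material and structural properties contributing
to strength *independently* of bone mineral content. Operationally: over
a large sex-matched wild-type cohort (n = 320 in the motivating screen),
each biomechanical parameter is regressed on BMC (ordinary least
squares, parameter-on-BMC, i.e. BMC is the predictor). A mutant group's
quality score per parameter is

\[ \mathrm{score} = \frac{\bar{y}_{\mathrm{obs}} -
   \hat{y}(\bar{\mathrm{BMC}})}{s_{\mathrm{res}}} \]

in units of the reference residual SD (`n − 2` denominator). Scores
outside ±2 SD are flagged; the plotted band is a constant ±2·residual-SD
band about the line (a parallel "gray box", not a leverage-dependent
prediction interval, which at n = 320 would be visually
indistinguishable anyway). The group mean is scored (matching how such
screens plot group means against the reference band); per-specimen
scores are attached for diagnostics. Mixed-sex cohorts are refused
unless explicitly overridden, because the reference is sex-matched.

Published deficit values from any particular screen are not
reproducible without the underlying reference cohort; the testable
surface is recovery of *injected* deficits in synthetic cohorts, plus
the null (zero deficit scores near zero, unflagged). At group size
n = 100 each parameter's score carries a sampling sd of ≈ 0.12–0.15
(group residual noise plus residual-SD estimation error), so recovery to
±0.2 SD is asserted on the mean score across the four parameters.

# Densitometry

Gray levels are calibrated against imaging standards of known material
density — steel/aluminum/polyester for digital X-ray microradiography,
halogenated dimethacrylate standards for quantitative BSE-SEM. The
median gray level of each standard region is paired with its density and
an affine gray→density map is fit through the anchors by least squares
(exact for two anchors; the RMS anchor residual is reported for more).
Anchors must be strictly monotone (gray increasing with density).
Numeric standard densities are configuration inputs — instrument
standard sets differ and the defaults here (800/1100/1400
mg/cm³-equivalent) merely bracket murine bone mineralization at
1100 ± 66 (6% CV).

Calibrated bone-mask pixels are summarized as relative-frequency
histograms: 16 equal intervals for microradiographic BMC (the
specimen's *relative BMC* is its median calibrated value), 8 equal
intervals spanning the bracketing standard densities for qBSE
micromineralization density, with out-of-range pixels clipped into the
end bins and counted. Binning is over a fixed, configured range — never
per-image — so histograms of different genotypes share edges and are
KS-comparable. Whole-raster affine gray drifts (detector gain/offset)
cancel exactly because the standards transform with the specimen.

# Kolmogorov–Smirnov comparison, percent scale

Density distributions are compared with the two-sample KS statistic on a
percent scale, `D% = 100 · sup|ECDF₁ − ECDF₂|`, with analytic critical
values

\[ D\%_{\mathrm{crit}} = 100\, c(\alpha)
   \sqrt{\tfrac{n_1 + n_2}{n_1 n_2}},\qquad
   c = \{1.36, 1.63, 1.95\} \text{ at } \alpha = \{0.05, 0.01, 0.001\}. \]

The tabulated coefficients are used rather than the exact asymptotic
`sqrt(-ln(α/2)/2)` because only they reproduce the canonical printed
thresholds for 1024-pixel data sets (6.01/7.20/8.62) at two decimals;
1024 is per-sample (`n1 = n2 = 1024`), the convention under which those
three numbers are recovered. Ties are handled by evaluating ECDF gaps at
pooled unique values only, and the implementation keeps counts as
integers until one final division so it is bit-identical to the
brute-force definition. Histogram inputs must share bin edges; D is then
the maximum absolute difference of cumulative relative frequencies and
n₁, n₂ are the pixel counts.

```{r ks-example}
round(c(ks_critical_percent(0.05, 1024, 1024),
        ks_critical_percent(0.01, 1024, 1024),
        ks_critical_percent(0.001, 1024, 1024)), 2)
```

# Histomorphometry

Inputs are trace tables (segment lengths with flags, osteoid seam
widths, calcein inter-label distances) as produced by manual/ImageJ
tracing; image segmentation is out of scope. ASBMR conventions:
Oc.N/B.Pm and Oc.S/B.Pm normalize osteoclast count and covered length to
total bone perimeter; MS = 100·(dL + sL/2)/B.Pm (double-labelled surface
plus half the single-labelled surface — a pure-double mode is a switch);
MAR = mean inter-label distance divided by the label interval (default
2 days, from calcein injections 5 and 3 days before euthanasia);
BFR = (MS/100)·MAR, an identity re-imposed even after averaging section
replicates. Osteoclast perimeter is emitted as raw length only, since
reported values normalize to B.Pm. Growth-plate zone heights (reserve,
proliferative, hypertrophic) are means over four x-locations;
chondrocyte counts refer to a 200-μm-wide central counting region;
relative fractions sum to 100 by construction.

# Supporting statistics

**ΔΔCT.** Per sample, ΔCT = CT(target) − mean CT(reference genes);
per gene, ΔΔCT = ΔCT − mean ΔCT over the calibrator group; fold =
2^(−ΔΔCT). Multiple reference genes ("and/or" in common protocols) are
resolved as *all provided*, aggregated by the arithmetic mean of CTs —
equivalent to the geometric mean of expression. The calibrator group's
folds are therefore centred on 1 in log₂ space.

**Group comparisons.** One-way ANOVA with two-sided Tukey post hoc,
Kruskal–Wallis with Dunn all-pairs z-tests (Holm-adjusted), unpaired
two-sided Student's t, or rank-sum, dispatched by a declared design.

**Power.** For a measurement with coefficient of variation `cv` and a
detectable difference `diff` (both fractions of the mean), the
standardized effect is d = diff/cv and the minimal per-group n reaching
the target power is found from the noncentral-t distribution of the
chosen design. Note a screen's quoted "n = 4 for 90% power at a 20%
difference, CV 10%" is certified by neither standard design: the
two-sample noncentral-t computation gives n = 7 per group and a
one-sample comparison against a fixed reference gives n = 5. Both
computations are implemented; the quoted figure is documented as
irreproducible rather than emulated.

# Synthetic data: the stated world

The generators encode the screen's stated conditions, not tunable
knobs:

* **Curves** — piecewise bilinear-elastic/plastic template (toe,
  elastic, hardening, decline, single-step failure drop) sampled on the
  0.03/20 = 1.5-μm displacement grid; additive i.i.d. Gaussian noise on
  load only (the actuator is displacement-controlled). The toe default
  (0.05 mm) and noise default (0.05 N) are choices — the source screen
  does not characterize its load frame's toe or noise — stated once
  here; contact detection is genuinely exercised.
* **Cohorts** — BMC ~ Normal with CV 2%; each parameter linear in BMC
  plus residual noise; marginal CVs 9% (max load), 20% (fracture load)
  from the screen's catalogue, 10% (yield, stiffness) chosen where the
  catalogue is silent; parameter–BMC correlations derived from the
  printed n = 320 regression p-values (r ≈ 0.16–0.24). Mutant groups
  shift every parameter by `deficit_sd · residual_sd`, leaving BMC
  untouched — a pure quality deficit.
* **Gray fields** — affine density→gray detector (nonlinearity
  deliberately excluded; no detector model is available), optional
  Gaussian gray noise, integer quantization by default
  (`quantize = FALSE` gives the idealized continuous field that
  round-trips calibration exactly), standards laid out as disjoint
  rectangles with 0-based half-open coordinates.
* **Histomorphometry tables** — segment splits per flag class with
  relative jitter on class totals, splits, widths, label distances, zone
  heights and counts; noiseless configurations round-trip every
  downstream parameter exactly.

All randomness flows from one integer seed, split per sub-generator by a
fixed Lehmer step (so adding a generator never perturbs existing
streams), and the RNG is pinned to Mersenne–Twister with inversion
normals: fixed seeds give bit-identical artifacts.

What a green test does *not* establish: the generators have no
trabecular texture, no detector nonlinearity, no heteroscedastic curve
noise, no correlated multi-parameter residuals beyond the shared BMC
term. They validate the analysis algebra and its calibration behaviour,
not instrument realism.

# Numerical choices and degenerate inputs

* Elastic-fit failure reports the best achieved R²; flat or pure-noise
  curves error with "no elastic region", non-monotone displacement is
  rejected.
* An exact regression fit (residual SD below 1e-10 of the response SD)
  is treated as degenerate: residual SD 0, slope p-value NA, scoring
  against it refused.
* Histogram medians are computed on raw calibrated values, so they are
  invariant to binning; frequencies always sum to 1.
* KS with fewer than 2 observations (or non-shared histogram edges) is
  rejected; critical values are defined only at the three tabulated α
  levels.
* Percentages are validated into [0, 100]; covered lengths exceeding the
  bone perimeter (beyond 1e-9 mm slack) are errors, not clamps.

# Known limitations

Stress/strain normalization, energy to fracture, leverage-dependent
prediction bands, exact small-sample KS p-values, automated image
segmentation and 3-D (μCT) analysis are out of scope. The power module
covers the two classical designs only. The CLI is a thin wrapper over
the exported functions; instrument-native binary formats are not read.
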