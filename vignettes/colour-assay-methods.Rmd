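---
title: "Methods: quantifying chromatophore-based colour change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying chromatophore-based colour change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Many crustaceans adapt their body darkness to the substrate within minutes
to hours by dispersing or concentrating pigment inside chromatophores,
under the control of pigment-dispersing and pigment-concentrating
hormones. Background-adaptation assays exploit this: an animal is placed
on a white and then a black substrate, and the darkness of a defined body
region (here the second abdominal segment) is measured on each. This
package implements the two standard readouts of such an assay, the
statistics used to analyse them, and a fully seeded synthetic generator
that lets every stage be validated end-to-end without laboratory data.

## The chromatophore coefficient

Each chromatophore is graded on the ordinal dispersion scale 1 (small,
fully concentrated) to 5 (large, fully dilated). With $n_k$ the number of
cells at stage $k$ and $T_c = \sum_k n_k$, the coefficient is

$$C \;=\; \sum_{k=1}^{5} \frac{n_k}{T_c} \times 20 \times k
      \;=\; 20 \times \overline{\text{stage}},$$

ranging from 20 (all cells concentrated; a very light animal) to 100 (all
dispersed; very dark). Standardising by $T_c$ makes the score comparable
across animals that carry different numbers of chromatophores on the
segment. The scheme descends from classroom protocols that subsample 20
cells; grading *every* cell, as here, removes the subsampling variance
while keeping the familiar 20–100 scale.

A note on the formula: the coefficient is sometimes written as a plain
sum of the five proportions each multiplied by 20, which would always
evaluate to 20 and contradicts the stated 20–100 range. The stage-weighted
form above is the only reading consistent with that range and with the
20-cell scheme it adapts (where scores of 1–5 per cell over 20 cells give
20–100), so `chromatophore_coefficient()` implements it, and the identity
$C = 20\times\text{mean stage}$ is enforced by test against a per-cell
enumeration oracle.

Useful consequences, all covered by property tests: moving one cell up
one stage changes $C$ by exactly $20/T_c$; multiplying all counts by a
constant changes nothing; the extremes 20 and 100 are attained only by
pure stage-1 or stage-5 populations.

## Percent dark cover from images

The image readout reproduces, as deterministic operators, the common
ImageJ recipe for "percent of the segment covered by pigment":

1. **Greyscale.** Multi-channel images are collapsed with ITU-R 601
   luminance weights (0.299, 0.587, 0.114), rounded, clipped to 8-bit.
   The fixed weights make results reproducible against an ImageJ
   cross-check.
2. **Median filter, 2-pixel radius.** A *disk*-shaped neighbourhood
   (13 pixels at radius 2), matching the radius semantics of ImageJ's
   rank filters, with reflection padding at the borders (border pixel
   included in the mirror). The disk always holds an odd number of
   pixels, so the median is an exact order statistic and the image stays
   8-bit. `median_smooth()` is verified pixel-for-pixel against a
   brute-force neighbourhood-sorting oracle.
3. **Threshold.** In the manual protocol a human adjusts the threshold
   "until the pixels cover the cells". For unattended, blind operation
   the package substitutes Otsu's criterion computed *within the ROI
   only* (`otsu_threshold()`); pixels strictly below the threshold count
   as dark. A fixed threshold can be supplied instead (and should be for
   frames that may contain no pigment at all — Otsu assumes a bimodal
   histogram and will split pure background noise).
4. **Percent cover.** $100 \times$ dark ROI pixels / ROI pixels.

The ROI is supplied as a binary mask (hand-drawn segment outlines,
rasterised); automatic segment detection is out of scope. Cover is
computed within the ROI, not its bounding box. Note one deliberate
consequence of filtering before thresholding: pixels within the filter
radius *outside* the ROI influence smoothed values just inside it, so
only pixels beyond that reach are provably irrelevant.

## The synthetic cohort generator

Real assay data for this design are not publicly deposited, so validation
runs on a generator that emulates the study design: 3 trials, nominal
doses 0/10/100/1000 ng/L of a serotonergic compound, exposures of 1 h,
1 day and 1 week, and each animal photographed on white then black
substrate (10–15 replicates per treatment; `cohort_design()` defaults to
15).

Stage grades come from a latent ordered-category (probit-style) model.
Observation $j$ of specimen $i$ has latent dispersion

$$L_{ij} = \mu_0 + \beta_{\text{bg}}\,[\text{black}] + \beta_{\text{time}}
 + \beta_{\text{trial}} + \beta_{\text{conc}} + u_i + e_{ij},
 \qquad u_i \sim N(0, \sigma_s^2),\; e_{ij} \sim N(0, \sigma_o^2),$$

and each of its $N_i$ chromatophores is graded
$1 + \#\{\tau_k < L_{ij} + \varepsilon\}$ with cell noise
$\varepsilon \sim N(0, \sigma_c^2)$ and cutpoints
$\tau = (-1.5, -0.5, 0.5, 1.5)$. Defaults: $\sigma_s = 0.3$,
$\sigma_o = 0.15$, $\sigma_c = 0.6$; $N_i \sim$ Poisson(40) truncated at
10 (cell counts per segment vary between animals — the very reason the
coefficient is standardised — and are held fixed across an animal's
repeated photos). Stage counts are drawn multinomially, which is exactly
the i.i.d. per-cell model.

Two parameters are not set directly but *calibrated analytically*
(`effect_model()` solves them with `uniroot` on the closed-form mean
stage): $\mu_0$ so that the population mean coefficient on white is 45 —
mid-range, leaving room to move in both directions — and
$\beta_{\text{bg}}$ so that the black-background mean is 20% higher, the
magnitude of background darkening repeatedly reported for sand shrimp.
All dose, trial and time effects default to zero (a null drug effect);
tests inject non-zero values where power is the point.

Rendering: a 512×512 8-bit canvas with a bright elliptical ROI
(intensity 230, Gaussian noise SD 5; semi-axes 28%/42% of the canvas), on
which each cell is a dark disk of radius $2 + 1.5 \times \text{stage}$
pixels, full 160-level drop out to radius−1 and a linear two-pixel soft
edge, overlaps combining by maximum drop. The pixels whose drawn drop
reaches half the core drop form the stored ground-truth dark mask.
Coordinates are 0-based, row-major, origin top-left, in every writer.

What the generator does *not* emulate — so green tests here say nothing
about these aspects of real photographs: colour-resolved pigments (black,
red, yellow, white chromatophores are not distinguished), uneven
illumination and specular reflections, moult-cycle or seasonal state,
within-animal persistence of cell positions across photos (placements are
re-drawn per observation; statistically equivalent for every measure
computed here), and any true pharmacodynamics of the dosed compound.

All randomness flows from explicit integer seeds through `withr`
(`generate_cohort()` is bit-reproducible from `design$seed`); no function
perturbs the caller's RNG stream when given a `seed` argument.

## Statistical battery

Both responses are natural-log transformed before ANOVA (coefficient
with no offset, as it is ≥ 20; percent cover with +1, as it can be 0).
`mixed_anova()` fits the mixed design: background (white/black) as the
two-level within-subject factor; concentration, trial and exposure time
as between-subject fixed factors with Type-III sums of squares (the
trials are unbalanced by design), within-subject error strata, the
Greenhouse–Geisser adjustment for within-subject effects, and partial
eta squared $SS_e/(SS_e + SS_{err})$ per effect. The Type-III machinery
is delegated to `car::Anova` (multivariate repeated-measures route,
sum-to-zero contrasts); the package owns validation, reshaping,
`greenhouse_geisser_epsilon()` (tested against an eigenvalue-form
oracle) and the assembled table.

Design choices worth stating:

* **Exposure time is between-unit.** Although each animal is photographed
  at all three exposure times, time is modelled as a fixed between-unit
  factor; the ANOVA unit is the specimen × time pair of (white, black)
  observations. This mirrors how such assays are conventionally analysed;
  a fully within-subject time model would need its own sphericity
  handling and is not attempted. The cost is worth knowing: the three
  units of one animal share its random effect, so tests of animal-level
  factors (trial, dose) are mildly anti-conservative under this
  convention. The background test is immune — it is computed from
  within-unit differences, which cancel the shared effect.
* **Post hocs.** Pairwise comparisons of marginal means on the pooled
  one-way error with Bonferroni adjustment (family = number of pairs),
  run for each significant between factor; raw p values are retained so a
  Tukey-HSD cross-check is possible. "Tukey with Bonferroni correction"
  is internally contradictory as a recipe; the Bonferroni clause wins.
* **Greenhouse–Geisser.** $\varepsilon$ is 1 exactly for the two-level
  background factor (sphericity is trivial at $k = 2$), so adjusted and
  raw p coincide for the headline test; the adjustment matters only for
  within-subject factors with 3+ levels. Note that for $F < 1$ the
  df-shrinkage can *lower* the p value — "adjusted p ≥ raw p" is a
  theorem only for $F \ge 1$.
* **Sequential removal.** `analyze_dataset()` re-fits the model with each
  trial removed, the standard way of localising trial interactions.
* Two-sided tests throughout; reporting threshold $\alpha = 0.05$.

`pearson_correlation()` relates the two readouts; $R^2$ is computed as
$r^2$ exactly (published values occasionally disagree with the square of
their own $r$ in the third decimal — this package never rounds before
squaring).

Blinding (`blinding_key()`, `blind_images()`) renumbers observations with
a seeded random permutation, zero-padded; the key is written as CSV and
is refused a location inside the blinded image directory.

## Validation benchmarks and problem sizes

The shipped suite exercises, among others: the coefficient extremes and
the $20 \times$ mean-stage identity on 1,000 random count vectors; the
median filter against brute-force oracles on 9×9 patches; noise-free
renders recovering the drawn-area truth within 2 percentage points;
$F \equiv t^2$ for the paired design; the type-I error of the background
test across 200 null cohorts of 60 specimens (within 3 binomial SEs of
5%); a 120-specimen dispersion sweep on which the coefficient and percent
cover correlate at $r \approx 0.93$; and recovery of the calibrated +20%
background shift from 90 paired specimens within Monte-Carlo error
(estimator: relative change of cohort means; the mean of per-specimen
ratios is also reported but is upward-biased by ~2 points, a plain
Jensen effect of dividing by each animal's own white score). These sizes
keep the full suite around a minute on one core while leaving the
Monte-Carlo checks adequately powered.

## Known limitations

* Otsu thresholding assumes pigment is actually present; use a fixed
  threshold for possibly-blank frames.
* Touching chromatophores merge into one connected component and are
  graded by combined area (components larger than any plausible single
  cell raise a warning); at realistic densities this costs a few percent
  of cells, which is why automated grading is validated on sparse
  renders.
* The ANOVA requires complete (white, black) pairs per unit and rejects
  units missing a level rather than imputing.
* The generator's defaults are stand-ins chosen once for realism (cell
  count, geometry, noise scales) — not estimates of any particular
  population.
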