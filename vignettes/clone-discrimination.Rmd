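---
title: "Discriminating sugarcane clones from leaf images and NIR spectra"
author: "leafclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating sugarcane clones from leaf images and NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafclone)
```

## The problem

In the Simplified System (SS) of early-stage sugarcane selection, whole
families of seedlings are transplanted densely, forming a carpet of stalks.
When two vigorous stalks grow close together inside a family plot, the
breeder cannot tell by eye whether they are tillers of one individual (a
single clone) or two genetically distinct full sibs. Selecting both when
they are the same individual wastes a selection slot; the question is
answerable from cheap phenotypes: RGB photographs of the `+1` leaf (the
first fully detached leaf) and, optionally, near-infrared (NIR) absorbance
spectra of the same leaf.

`leafclone` implements a two-stage workflow around this question.

**Stage 1 (screening).** For every pair of leaf samples in a trial, compute
the Euclidean distance between standardized attribute vectors under a
scenario — the three band means (`RGB`), the red band alone (`R`), the
pretreated NIR spectrum (`NIR`), or concatenations (`RGB+NIR`, `R+NIR`) —
and ask how well small distances identify pairs of leaves from the *same*
individual. Pairs are classed from the trial design: `C1` = same family and
block (one clone per plot, so the same individual), `C2` = same family,
different block (different individuals of one family), `C3` = different
families. Discrimination of `C1` against the rest is summarised by the area
under the ROC curve (AUC), computed as the midrank Mann–Whitney probability
that a `C1` pair has the smaller distance.

**Stage 2 (decision protocol).** For a single suspicious pair of images,
the package runs a pixel-resampling protocol: draw `P` pseudo-images of `n`
pixels from each leaf (bootstrap draws from the segmented leaf region),
take each pseudo-image's mean attribute vector, and form "within"
difference vectors by differencing disjoint consecutive resamples of the
same image. The "between" vector is the difference of the two full-image
attribute means. The statistic
\[
D^2 = (\bar d_B - \bar d_W)^\top S^{-1} (\bar d_B - \bar d_W)
\]
weights the between-vs-within discrepancy by the combined covariance
\(S\) of the within differences, and is referred to \(\chi^2(p)\) with
\(p\) = number of attributes. A large p-value says the between-image
difference looks like resampling noise — the two leaves are consistent
with one individual; a small p-value indicates distinct individuals. The
package deliberately reports \(D^2\) and the p-value without fixing a
decision threshold: the statistic's scale depends on the number of
attributes, and thresholding is left to the user's risk tolerance.

## Design choices in the protocol

Several steps of the protocol admit more than one literal reading; the
package fixes defaults and keeps the alternatives behind flags.

**Within pairing.** "Differences between attributes of pairs of
pixel-resampling images" could mean pairs across the two images or pairs
within each image. Cross-image pairing makes the mean of the within
differences converge to the between difference itself, forcing
\(D^2 \to 0\) for *any* pair of images — a degenerate statistic. The ANOVA
analogy that motivates the protocol (between-treatment variability judged
against within-treatment variability) requires the within pool to measure
variability *inside* each image, so the default pairs disjoint consecutive
resamples of the same image (1–2, 3–4, ...) and pools both images, giving
`2 * floor(P/2)` independent difference vectors. `pairing = "cross"`
retains the literal alternative for auditing.

**Resample size and the chi-squared reference.** A bootstrap mean of `n`
pixels from an image with pixel variance \(\sigma^2\) has variance
\(\sigma^2/n\), so a within difference has variance \(2\sigma^2/n\). Under
the null hypothesis that both images are samples of \(N_A\) and \(N_B\)
pixels from one distribution, the between difference has variance
\(\sigma^2(1/N_A + 1/N_B)\). These match — and only then is \(D^2\)
comparable to \(\chi^2(p)\) — when \(n\) equals the harmonic mean of the
two mask sizes. The default therefore resolves `n_pixels` to
`floor(2 / (1/N_A + 1/N_B))`, capped one below the smaller mask (the
resample must stay smaller than the image). Smaller `n` is accepted but
makes the test conservative by the factor `n / harmonic mean`; the
calibration tests in the suite exercise the default.

**Covariance membership.** The "combined" covariance uses the within
differences only by default: the single between vector is one observation
that adds no stable information and, under the alternative, biases the
estimate upward. `cov_mode = "pooled"` appends it for the literal reading.

**Attributes.** The default attribute is the red band mean alone
(`attrs = "R"`, so \(p = 1\)): the screening stage shows the red band
carries most of the image signal, and a univariate statistic keeps the
covariance estimate stable at `P = 100` resamples. `P` defaults to 100;
values of 50–1000 behave similarly, with the covariance estimate (and
hence the \(\chi^2\) approximation) improving in `P`.

**Resampling is with replacement** (a bootstrap), keeping the `P` resample
means i.i.d. so the sample covariance of their differences is unbiased.

## Pretreatments and the screening stage

NIR spectra (absorbance over 900–1700 nm, 605 channels in the study-like
grid) are dominated by leaf-to-leaf multiplicative scatter before any
genetic signal is visible. The package implements the standard
chemometric operators: Savitzky–Golay smoothing and derivatives
(`sg_filter`, delegating to the `signal` package's filter, window 5 and
degree 2 by default, one-sided polynomial fits at the edges so the channel
count is stable), multiplicative scatter correction (`msc`, per-spectrum
OLS against the mean spectrum), and mean centering (`mean_center`).
Pipelines are written left to right, e.g. `"SG(5,2)+D1+MSC+MC"` — the
combination found best in the motivating study — and `D1`/`D2` are
realised as SG derivatives sharing the pipeline's window and degree
(finite differences are available via `derivative_method = "fd"`).
Derivatives are scaled per channel step by default; per-nm scaling is a
pure rescaling with no effect on standardized distances.

All attributes are standardized to mean 0, sd 1 (denominator `n - 1`)
across the full sample-by-feature table before any distance is taken;
standardization is *not* per pair. Zero-variance columns are an error
rather than silently dropped. ROC curves pool both blocks; ties in the
AUC are handled by midranks.

Note the study-like grid: 900–1700 nm at 1.32 nm steps implies ~607
points, but 605 variables is the attribute count the workflow targets; the
generator uses 605 channels and an even grid over the range.

## The synthetic generator

No field dataset ships with the package, so `generate_bundle()` creates
study-like data with known ground truth. The default design is the
second-stage subset — 7 families present in both of 2 blocks, 3 leaves per
plot (42 samples, 861 pairs: 42 `C1`, 63 `C2`, 756 `C3`); `ss_design()`
with its defaults gives the full 31-family layout (14 plots in block 1, 24
in block 2; which families overlap blocks is made explicit rather than
inferred).

Images follow a hierarchical Gaussian model per channel: clone mean =
base + family effect + clone effect; leaf mean adds a leaf effect; pixels
add noise and are clipped to `[0, 255]` and rounded. Clones of one family
in different blocks share the family effect but draw independent clone
effects, so `C1` pairs differ only through leaf and pixel variation. The
leaf is an axis-aligned ellipse on a bright (245–255) background so the
default brightness-threshold segmentation works end to end. Defaults
(`sd_family = 3`, `sd_clone = 2`, `sd_leaf = 2`, `sd_pixel = 12` on the
8-bit scale, base RGB (110, 150, 60)) were chosen once to put the red band
in a moderately informative regime — pairwise AUC around 0.7–0.8, clearly
above chance and clearly below perfect, the qualitative regime reported
for real leaf images — with clipping affecting well under 1% of pixels.

Spectra are a smooth baseline plus five Gaussian absorbance peaks (970,
1150, 1300, 1450, 1650 nm, width 30 nm — water and carbohydrate overtone
regions). Peak amplitudes carry relative family/clone/leaf perturbations
(defaults 0.10 / 0.08 / 0.01); each leaf's spectrum is observed through
multiplicative scatter `a*s + b` (`a` sd 0.05, `b` sd 0.02) plus additive
channel noise (sd 0.001 absorbance, an instrument-level noise floor).
These values spread the genetic signal across many channels while leaving
raw spectra scatter-dominated, so the pretreatment pipeline has real work
to do: with them, pretreated NIR out-discriminates the single red band,
mirroring the motivating study's qualitative finding, while raw spectra do
not.

Reproducibility: family and clone effects are drawn from the bundle seed
in design order; each leaf then uses a substream derived from its plot and
leaf index, so adding leaves never reshuffles existing ones, and two calls
with one seed are byte-identical.

**What the generator does not emulate:** leaf shape and venation, disease
spots, nutritional gradients, camera vignetting or white-balance drift,
and wavelength-dependent scatter. Tests passing on synthetic bundles
demonstrate the *machinery* and the statistic's calibration, not field
performance; the study's own AUCs and median statistics are properties of
an undeposited dataset and are treated only as orderings to reproduce
qualitatively.

## Numerical notes and known limitations

* Segmentation is a brightness threshold (default: background when the
  minimum channel exceeds 240) plus largest connected component; it
  presumes the bright-plane acquisition setup and will fail (loudly) on
  dark backgrounds.
* The within covariance needs at least `p + 1` difference vectors; with
  constant images it is exactly singular and the protocol raises an error
  (a Moore–Penrose fallback is available via `singular =
  "pseudoinverse"`).
* On synthetic bundles the absolute scale of \(D^2\) for `C2`/`C3` pairs
  is driven by the ratio of genetic effects to the standard error of an
  image mean, and is orders of magnitude above the null; only the ordering
  of per-class medians is meaningful, matching how the field results are
  read.
* Problem sizes used by the validation suite: the class-ordering check
  runs all 861 pairs of the default 42-sample bundle at `P = 100`; null
  calibration uses 500 replicate pairs of 64×64 images; the
  variance-recovery check uses 50 families at 60×60. These sizes keep the
  full suite to a few minutes while leaving Monte-Carlo error well inside
  the asserted bands.

## A worked example

```{r example, eval = FALSE}
bundle <- generate_bundle(synthetic_config(), seed = 1)
pairs <- enumerate_pairs(bundle$samples)
table(pairs$pair_class)

# Stage 1: screening
at <- bundle_attributes(bundle)
roc_r <- pair_roc(pair_distances(scenario_features(at$rgb, NULL, "R"), pairs))
roc_nir <- pair_roc(pair_distances(
  scenario_features(at$rgb, at$nir, "NIR", "SG(5,2)+D1+MSC+MC"), pairs))
roc_r$auc; roc_nir$auc

# Stage 2: one suspicious pair
d2_test(bundle$images[[1]], bundle$images[[2]],
        config = protocol_config(seed = 7))
```
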