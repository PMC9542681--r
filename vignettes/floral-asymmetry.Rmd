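---
title: "Quantifying directional asymmetry in flowers with complex symmetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying directional asymmetry in flowers with complex symmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floralsym)
```

## The problem

Directional asymmetry (DA) is a population-consistent difference between
repeated parts of a structure — left versus right in a bilateral organ, or
the several organs of a whorl in a flower with rotational symmetry.
Fluctuating asymmetry (FA), by contrast, is the small random,
individually varying deviation from symmetry with zero population mean.
In a flower like *Iris*, whose perianth repeats three falls, three
standards and three petaloid style branches around the floral axis,
several distinct *direction-giving factors* can each impose its own DA:

* **anatomical position** within the flower, referenced to the bract-like
  outer spathe that subtends it (the orientation of an organ *relative* to
  the spathe);
* **a consistent environmental gradient**, such as solar irradiance, which
  is referenced to *compass* orientation;
* **the packing of organs in the bud**, which can stamp the same
  left–right asymmetry onto every organ of a whorl, producing a "pinwheel"
  pattern at the whole-flower level.

If flower orientations are not recorded, all of these collapse into the FA
estimate. `floralsym` implements the full analysis chain needed to
separate them, together with a synthetic-data generator in which each
factor has a known, controllable amplitude, so that every stage of the
chain can be validated by parameter recovery.

## Shape quantification

Each organ is digitized as an ordered set of 2D landmarks (18 for falls,
19 for standards, 18 for style branches), in millimeters. Size is measured
as **centroid size**, the square root of the summed squared distances of
the landmarks from their centroid.

`gpa()` performs a partial generalized Procrustes superimposition: each
configuration is translated to a zero centroid, scaled to unit centroid
size, and iteratively rotated to the consensus, which is re-estimated as
the normalized mean until it changes by less than `1e-10` (at most 100
iterations; non-convergence is an error, and the iteration count and
objective trace are returned). No extra cosine rescaling is applied, so
centroid sizes remain interpretable in mm. After convergence, shapes are
projected orthogonally onto the linear tangent space at the consensus; all
downstream statistics operate in that single linear space, with
coordinates stored landmark-major (`x1, y1, x2, y2, ...`).

## Bilateral object symmetry

Every organ here is internally bilaterally symmetric, so its asymmetry is
analyzed under *object symmetry*: a reflected copy of each configuration
is produced by negating the x coordinates and relabeling the paired
landmarks (`reflect_relabel()`; the choice of reflection axis is
immaterial because the joint Procrustes fit absorbs orientation). The
pairing of landmarks and the midline indices form a `pairing_scheme()`;
the index lists for real data depend on the digitization protocol and must
be supplied by the user, while the built-in synthetic templates ship with
matching default schemes.

`symmetry_decompose()` runs one joint GPA over the originals *and* their
reflected copies — both scaled to unit centroid size, a convention this
package adopts and documents — with the consensus symmetrized under
reflect-and-relabel at every iteration and brought into a canonical
orientation (reflection-invariant, "tip up") at the end. For each organ,

* the **symmetric component** is the average of its aligned original and
  aligned reflected copy, and
* the **asymmetric component** is the aligned original minus the
  symmetric component, i.e. half the original-vs-reflection difference.

This sign convention gives exact additivity: symmetric + asymmetric equals
the aligned original to machine precision. On noise-free symmetric input
the asymmetric component vanishes (below `1e-10`), and reflecting an
entire dataset flips asymmetric components while leaving symmetric ones
unchanged — both properties are exercised in the test suite. For p
landmark pairs and l midline points in 2D, the symmetric and asymmetric
components each span a subspace of dimension 2p + l − 2, and together they
partition the 2k − 4 dimensions of tangent shape space; the suite verifies
the empirical ranks (16 + 16 = 32 for an 18-landmark fall).

## Orientations

Orientations are integers in degrees, clockwise-positive, 0° = south,
discretized to the six 60° sectors as recorded in the field. The relative
orientation of an organ is `(compass − spathe) mod 360`
(`relative_orientation()`), i.e. the clockwise angle from the outer spathe
to the organ. A flower is in the **expected** alignment when its falls
have relative orientations {0°, 120°, 240°} (a fall directly above the
outer spathe) and **rotated60** when they are at {60°, 180°, 300°};
classification uses the falls, with standards serving as a consistency
check (`classify_alignment()`). `orientation_uniformity_test()` is the
Pearson chi-square test of the six spathe-sector counts against equal
expectations (df = 5). Continuous-angle statistics are out of scope.

## Inference

Size differences among orientation groups are tested with a classical
one-way ANOVA per organ type (`anova_centroid_size()`), reported with
per-group means and standard errors.

Shape differences among the six orientation groups are tested separately
for the symmetric and asymmetric components with a permutation test
(`permutation_test()`) using two statistics:

* **Goodall's F** — the ratio of between-group to within-group mean
  squared Procrustes distance in tangent space;
* **Pillai's trace** — tr[H(H+E)⁻¹] from the between- and within-group
  cross-product matrices.

Because object-symmetry components are rank-deficient by construction,
Pillai's trace is computed after projecting the data onto the principal
subspace of the total scatter H + E (relative eigenvalue tolerance
`1e-8`). Whenever the within-group covariance has full rank on that
subspace — every realistic sample — this equals the value obtained by
reducing on the within-group covariance, and it remains defined in the
degenerate limit of zero within-group variance, where the statistic
correctly attains its upper bound. Goodall's F needs no reduction
(projection onto the span of the data preserves all distances involved).

Permutation p-values use the add-one convention
p = (#{F* ≥ F} + 1)/(n + 1), so p is never zero, and the default is
10,000 iterations. When fewer distinct label arrangements exist than
requested iterations, all arrangements are enumerated and the p-value is
exact (with a note). The default exchangeable unit is the **organ**;
because the organs of one flower may be correlated, labels can instead be
permuted in whole-flower blocks (`unit = "flower"`). Which unit the
original field analysis used is not determinable, so both are offered.
Tests for multiple organs and components are reported separately without
multiplicity correction, matching the reporting style of the field; the
number of tests run is visible in the output objects.

`cva()` pre-projects onto the principal subspace of the pooled
within-group covariance (same `1e-8` relative tolerance), solves the
generalized eigenproblem there, and whitens the scores so the pooled
within-group covariance of the scores is the identity. Axis signs are
fixed deterministically (largest-magnitude loading positive). Group-mean
uncertainty on CV1–CV2 is drawn as 95% confidence ellipses computed from
each group's score covariance scaled by 1/n and the 0.95 quantile of the
chi-square distribution with 2 df — a large-sample convention, chosen and
documented in preference to the F-based small-sample ellipse.

Mean-shape differences are visualized by warping an outline through a
thin-plate spline (`tps_warp()`) that maps the reference landmarks to
reference + exaggeration × (target − reference). The exaggeration defaults
to 15, which renders sub-percent shape effects visible; landmarks are
interpolated exactly, affine differences produce zero bending energy, and
collinear or duplicated reference landmarks are rejected because they make
the TPS system singular.

## The synthetic generator

`simulation_params()` + `generate_dataset()` emulate the study design:
each flower has a spathe orientation drawn from six sector weights
(uniform by default), carries a fall directly above the outer spathe with
probability `p_expected_alignment` (default 315/462 ≈ 0.68, the observed
split) or is rotated 60°, and contributes three organs per whorl whose
compass orientations follow from the floral ground plan (standards offset
60° from falls). Each organ's shape is

> template + compass field(sector) + relative field(sector) +
> pinwheel field + FA draw,

built in the organ's unit-centroid-size frame, then scaled to a centroid
size drawn per organ, placed at a random position and orientation, and
perturbed by mm-scale digitizing noise. Defaults:

* **templates** — symmetric petal-like polygons with the real landmark
  counts; they are visually interpretable and require no external data.
* **sizes** — means 350/354/217 mm and SDs 43/44/24 mm for
  falls/standards/style branches, the magnitudes of the published size
  tables; compass-linked size offsets alternate ±4, ±4.5, ±2.5 mm with the
  fall-parity of the flower, reproducing the observed ~2% alternating
  pattern and an ANOVA F of roughly 3 at 462 flowers.
* **compass field** — mostly an antisymmetric lateral bend (RMS per-sector
  tangent amplitude 0.008) plus a smaller symmetric widening (0.004),
  because the field study found the compass effect clearest in the
  asymmetric shape component; sector multipliers are sinusoidal and sum to
  zero.
* **relative field** — zero, the study's observed negative result.
* **pinwheel field** — an antisymmetric bend of tangent norm 0.01 shared
  by all organs of a type.
* **FA** — independent isotropic draws per organ, `fa_sd = 0.01` per
  coordinate in shape units; **noise** — 0.05 mm per landmark coordinate.

The compass amplitude was fixed by a noncentrality argument rather than
trial: with G = 6 sectors of n_g organs, per-sector mean offsets d_s and
asymmetric-component noise σ² = fa_sd²/2 per coordinate, Goodall's F has
noncentrality λ ≈ n_g Σ_s d_s²/σ². At 0.008 RMS amplitude and 48 flowers
(144 falls) λ ≈ 180, which puts the analytic power of the 5%-level test
well above 0.9 — comfortably detectable, yet still a sub-percent shape
effect of the same order as the FA, like the real phenomenon.

Fields are orthogonalized against translation, rotation and scale at the
template, so injected amplitudes are directly commensurate with the
tangent-space estimates recovered downstream. FA draws are independent
across the organs of a flower; the within-flower correlation structure of
real FA is unknown, and this independence assumption is the right target
for sensitivity analyses. The generator does not emulate image synthesis,
continuous orientation angles, irradiance physics, or genet-level
(clonal) covariance — so passing tests demonstrate correctness of the
estimation chain, not realism of every covariance detail of field data.

## Validation experiments

The package's own validation (in `tests/testthat/test-acceptance.R`) uses
problem sizes chosen to balance Monte-Carlo resolution against runtime:

* **Null calibration**: 500 datasets of 24 flowers with *all* directional
  fields zeroed, 199 permutations each; the 5%-level rejection rate of
  both statistics must lie in [0.03, 0.07] and the p-values must pass a
  Kolmogorov uniformity check (band at α = 0.01 plus the 1/200 grid
  offset of discrete permutation p-values).
* **Dissociation**: with only the compass field injected (48 flowers,
  500 datasets), the compass-grouped test has power > 0.9 for both
  statistics while the relative-orientation test stays at its nominal
  level — the qualitative headline of the study reproduced as a testable
  property. With only the pinwheel field injected, the mean asymmetric
  component recovers the injected field within an analytic Monte-Carlo
  bound, and orientation-group tests stay at nominal level.
* **Oracle equivalence**: every statistic (Goodall's F, Pillai's trace,
  ANOVA F, chi-square, CVA eigenstructure) is checked against an
  independent brute-force computation on small instances to 1e-8.

## Worked example

```{r example, eval = FALSE}
params <- simulation_params(n_flowers = 462, seed = 1)
dataset <- generate_dataset(params)
organs <- join_metadata(dataset$configs, dataset$records)

table(dataset$records$alignment)
orientation_uniformity_test(
  table(factor(dataset$records$spathe_orientation, seq(0, 300, 60))))

dec <- decompose_organ(dataset, "fall")
res <- orientation_shape_test(dec, "asymmetric", "compass",
                              n_permutations = 10000, seed = 2)
res$test
cv_ellipse_plot(res$cva)

gm <- group_mean_shapes(res$sample$x, res$sample$groups)
warp <- tps_warp(dec$consensus,
                 matrix(gm$means[1, ] + as.vector(t(dec$consensus)) -
                          gm$grand_mean, ncol = 2, byrow = TRUE),
                 exaggeration = 15)
plot(warp)
```

## Known limitations

* Only 2D landmarks and the bilateral object-symmetry group are handled;
  rotational-symmetry-group Procrustes at the whole-flower level is
  deliberately replaced by orientation-grouped comparisons of separately
  superimposed organs (matching symmetry), as in the field protocol.
* Pairing/midline index lists for real digitization protocols are not
  published and must be supplied by the user.
* The permutation framework treats genets as unstructured; plant-level
  random effects and mixed-model Procrustes ANOVA (individual × side
  designs) are out of scope.
* Missing organs are tolerated (available-case analysis per organ type)
  but no imputation is attempted.
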