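---
title: "ltpmob: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ltpmob: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltpmob)
```

This vignette documents the statistical models, the tunable parameters and
the design choices behind `ltpmob`, in the spirit of a methods section: what
each stage computes, why the defaults are what they are, and what the
synthetic-data tests do and do not demonstrate about real screen data.

## Co-elution ligand calling

In an SEC-based LTP screen, a lipid bound by a protein co-elutes with it:
the lipid's intensity profile across fractions tracks the protein's.
`call_ligands` operationalizes "present in protein-containing fractions
with a similar elution profile" as two filters:

* **Presence.** Fractions "containing" the protein are those with protein
  intensity at or above a detection floor, default 5% of the protein's own
  peak. A lipid passes when at least `min_presence` (default 0.5) of its
  total intensity lies in those fractions.
* **Similarity.** Pearson correlation between lipid and protein profiles
  over all shared fractions, threshold `min_similarity` (default τ = 0.8).

Both defaults are declared conventions, exposed as arguments: the screen
literature states the filtering idea but not a metric or cutoff, and any
reproduction against a published ligand table should expect to re-tune
them. Pearson correlation makes acceptance invariant to positive affine
rescaling of either profile (ionization efficiency, loading), which is the
property that matters; it is blind to peak shape differences at equal
correlation. Acceptance is monotone in both thresholds, which the test
suite checks as a property.

Constant profiles min–max scale to all zeros (`normalize_minmax`): a
constant vector carries no elution information and is treated as "not
observed above floor". The fraction axis is 1-based, following
chromatography convention.

## Lipid shorthand and molecular volumes

The parser accepts the grammar `SUBCLASS[-O] '(' chain (('/'|'_') chain)* ')'`
with an optional sphingoid prefix `d` / `t` / `DH` on the first chain,
over a closed subclass vocabulary shipped as TSV. `/` and `_` (known vs
unknown sn-position) are both accepted and recorded, but species
comparison ignores the distinction — positional information plays no
computational role here. A single chain entry for a multi-chain subclass
(e.g. `PI(38:4)`) is a species-total record; the expected chain count of
the subclass then supplies the number of chain termini for the volume
model. Ether subclasses (`PC-O`) stay distinct from their ester
counterparts at subclass level and merge at class level.

Molecular volumes are group contributions:

$$V = V_{head} + \sum_{chains} \left( n_C \cdot V_{CH_2} + V_{term} - n_{db} \cdot V_{db} \right) (+ \text{ether, phytosphingoid terms})$$

with $V_{CH_2} = 26.9$ Å³, $V_{term} = 27.0$ Å³, $V_{db} = 20.4$ Å³ and
per-subclass head-group volumes in `inst/extdata/`. These are
literature-plausible constants, declared rather than fitted: the
structural benchmark consumes volume *ratios* and needs strict
monotonicity (more carbons → larger, more double bonds → smaller), not a
particular absolute scale. The whole table is swappable via the `path`
arguments. Retinol and sterols are fixed whole-molecule volumes, outside
the chain grammar.

## Pocket volumes

`pocket_volume` voxelizes space at `grid_spacing` (default 0.5 Å), marks
voxels whose centre lies inside any atom sphere inflated by
`probe_radius` (default 1.4 Å, water-sized), flood-fills the free space
6-connectedly from outside the bounding box, and counts the unreached
free voxels. This counts *interior* cavities only; open grooves reachable
from the exterior contribute nothing. The grid is anchored to the
structure's own bounding box, so the estimate is exactly invariant to
rigid translation and axis permutation — a property tested as identity,
not approximately.

The hollow-sphere fixture (`gen_cavity_fixture`) provides an analytic
oracle: shell atoms on a Fibonacci lattice of radius $R$ with radius $r$
enclose, for a zero-radius probe, a cavity of approximately
$\tfrac{4}{3}\pi (R - r)^3$. The true cavity of the discrete shell is
slightly larger (the surface bulges outward between atoms), about +1.4%
at the default lattice density, so grid refinement converges to that
limit rather than to the ideal-sphere closed form; the refinement test
therefore asserts shrinking successive differences, and the closed-form
test a 5% band. The fixture flags itself `leaky` when its estimated
lattice spacing reaches 1.9 × atom radius — the point at which
neighbouring atom spheres stop overlapping reliably and the "cavity"
connects to the exterior.

The benchmark itself is small algebra: `fit_ratio` forms lipid/pocket
volume ratios, and `buffer_zone_threshold` takes the maximum ratio over
known pairs — everything above it lies in the buffer zone (pocket space
no known ligand uses). Outlier proteins with unusually small pockets are
excluded by listing them in `exclude_ltps`, a config choice, never
hard-coded. `pocket_model_from_table` wraps externally published volumes
so the benchmark can run on deposited tables unchanged; whether such
tables used probe-excluded or van-der-Waals-only cavities does not then
matter to the ratios.

## Gain-of-function statistics

Overexpression panels are tested per species with Welch's two-sided
t-test on log2-transformed intensities (MS intensities are multiplicative;
log2 makes arm differences effect sizes in doublings). The implementation
is the vectorized row-wise form (means, variances, Satterthwaite df,
`pt`), which the unit tests pin to `stats::t.test` at 1e-12 tolerance.
The Bonferroni family defaults to *all species across all panels analysed
together* (`perturb_screen(family = "global")`), with a per-panel option;
α = 0.05 on adjusted p.

Degenerate species — zero variance in both arms — are never silently
dropped: equal means give p = 1 by convention, unequal means are flagged
`degenerate`, reported with NA p, and excluded from the family count.

Two consequences of tiny replicate numbers are worth stating plainly.
First, with n = 3 per arm the Satterthwaite df can collapse toward 2 when
one arm's variance dominates, so even a 4-fold planted effect at 0.1 log2
sd is recovered in only ~70% of simulation runs under a 200-test family;
the tests assert that simulated rate, not certainty. Second, the
family-wise error guarantee survives this: on null panels (1,000 species,
no effects) the observed FWER over 200 fixed-seed runs is ≈ 0.01–0.02,
within the 0.05 bound.

`weight_multiplicity` implements the declared down-weighting of
promiscuously responding species: weight 1/k for a species affected in k
panels, applied to the log2 fold change (`weighted_fc`). The affected/not
calls themselves stay unweighted so that count-level summaries remain
comparable across weighting choices. `subclass_affected` lifts species
calls to subclass level by OR — one affected member affects the subclass
— and exposes the full LTP × subclass matrix (43 panels × 24 subclasses
= 1,032 pairs in the demo configuration). `fisher_enrichment` is the
standard two-sided exact test on the subset/complement × affected/not
table, cross-checked in the tests against an exhaustive hypergeometric
enumeration oracle.

## Co-regulation and co-localization of lipid pairs

`coregulation_score` averages directional agreement (+1 same sign, −1
opposite) over the perturbations where *both* lipids respond
significantly; pairs never jointly significant are reported missing
rather than scored 0, since absence of evidence is not mutual exclusion.
The "all perturbations" denominator is a deliberate non-choice: including
joint non-responses would reward shared insensitivity.

`manders_overlap` is the single symmetric overlap coefficient
$\sum a_i b_i / \sqrt{\sum a_i^2 \sum b_i^2}$ — not the split M1/M2 pair —
matching the anchors 1.0 (always co-localize) and 0.0 (never). It is
scale-invariant and Cauchy–Schwarz-bounded in [0, 1] for non-negative
input; all-zero vectors are reported missing.

`pair_enrichment` tests whether co-mobilized pairs score higher than
chance two ways: a Fisher exact test after binarizing at the pooled 75th
percentile (a scale-free cut, since no principled threshold exists for
these scores), and a permutation p against `n_random` equally sized
random pair sets drawn without replacement from the non-co-mobilized
pairs, with the add-one correction so p ∈ (0, 1]. Null calibration —
random subsets give p spread over (0, 1] — is a test-suite property.

## Mobilome profiles

`chain_profile` bins intensity by total chain length or total double
bonds, min–max scales within the profile, and by default profiles
glycerophospholipids and sphingolipids separately (scaling after the
class split, the default order, keeps each class's profile on its own
[0, 1] scale; the pre-split order is available by passing
`split_by_class = FALSE` on a filtered table). For sphingolipids, total
chain length is sphingoid base plus fatty-acid carbons — exactly what the
parser's `total_carbons` sums. Profile comparison reports signed per-bin
differences and the shift of the intensity-weighted mean (mobilized −
reference): negative = preference for shorter chains.
`subclass_max_normalize` rescales within (LTP, subclass) groups to the
group maximum, with an optional merge map (e.g. pooling all
hexosyl-containing sphingolipids as `xHexCer`).

## Synthetic data: what it emulates, and what it does not

All generators draw from one explicit seed and restore the RNG state, so
fixed seeds give bit-identical outputs, and zero-noise settings reduce
every generator to an exactly checkable deterministic case.

* `gen_sec_run`: Gaussian chromatographic peaks (width 1.5 fractions, 40
  fractions); planted ligands are the protein profile × a log-normal
  positive scale + Gaussian noise of `noise_sd` × peak; background lipids
  peak at least 2 fractions away. The displacement guarantee makes
  planted-vs-background unambiguous for scoring — real backgrounds are
  not so obliging, so the recall/FDP numbers are upper bounds on what the
  thresholds achieve on real runs.
* `gen_oe_panel`: log-normal intensities (normal in log2, baseline mean
  20, sd 0.25 by default, 3 replicates as in a typical biological
  triplicate design); induced arms shift by planted log2 effects.
  No batch effects, no missingness, no correlation between species — so
  calibration results certify the statistics, not robustness to
  real-world artefacts.
* `gen_coloc_maps`: co-localized pairs observe one shared latent support
  (30% of pixels, log-normal intensities) under independent
  multiplicative noise; independent lipids get independent supports.
  Random supports overlap by chance, so independent pairs have nonzero
  Manders scores — the enrichment tests work against that realistic-ish
  null rather than an artificial zero.
* `gen_cavity_fixture`: see pocket section. The default lattice density
  (spacing ≈ 0.6 × atom radius) keeps the inter-atom bulge bias near 1%.
* `gen_lipidome_pair`: Gaussian intensity profile over total carbons
  (centre 36, width 3, double-bond profile centred at 2), with the
  mobilized lipidome's centre shifted by the planted preference. Because
  min–max scaling is linear and the truncation of the carbon grid is
  mild, the intensity-weighted mean shift recovers the planted value to
  within a few percent plus species-level noise.

## Numerical and interface choices

* Tables are TSV, UTF-8, `.` decimal separator, lipid names never quoted;
  all writes are atomic (write-then-rename). `run_pipeline` embeds an md5
  hash of its configuration in the results directory, and reruns with the
  same config produce byte-identical files.
* The acceptance script scales its simulations to desk size — 200 null
  panels of 1,000 species, 25 lipidome pairs, a 1,552-atom fixture at
  0.5 Å — sizes chosen so the whole script completes in seconds while
  keeping Monte-Carlo error well inside the asserted tolerances.
* This package deliberately does not model raw spectra, isotope patterns
  or ionization efficiency (intensities are generated directly), does not
  deconvolve overlapping SEC peaks, and does not reproduce any published
  pocket-volume tool — the grid method here is an independent, transparent
  definition, and published volume tables can be consumed via
  `pocket_model_from_table` when exact reproduction of printed counts is
  the goal.
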