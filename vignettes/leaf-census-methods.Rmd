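---
title: "Quantifying plant and insect-herbivore community change from fossil leaf censuses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plant and insect-herbivore community change from fossil leaf censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleocensus)
```

## The problem this package addresses

Fossil leaf censuses are the workhorse of terrestrial paleoecology across
abrupt climate events such as the Paleocene–Eocene Thermal Maximum (PETM).
A census records, for every semi-intact dicot leaf excavated at a quarry,
its morphospecies (an operational taxon delimited from shape, margin and
venation), its Raunkiaer leaf-size class, and the insect damage types (DTs
— stereotyped, numbered categories of feeding damage: hole feeding,
skeletonization, mining, galling, ...) present on the blade. From such
tables one asks how floral diversity, insect-herbivore damage diversity,
damage frequency, and community composition changed through a stratigraphic
section, and what the flora implies about paleoclimate.

`paleocensus` implements that pipeline end to end: validated census input,
quarry-to-level pooling, diversity and evenness, rank abundance,
individual-based rarefaction of both plant species and DTs, damage
frequency and specialization ratios, leaf-physiognomy climate proxies, and
nonmetric multidimensional scaling (NMDS) of count matrices — plus a
synthetic census generator so every stage is testable without specimen
data.

## Data model

A census is four tibbles (`census()`):

* **records** — one row per leaf, or per *field-tally batch*: field crews
  commonly tally undamaged leaves of an already-known morphospecies on the
  outcrop and discard them, keeping only vouchers. Batches are first-class
  rows with `tally_count > 1` and an empty DT set. They count in floral
  abundances and in damage-frequency denominators, and they expand into
  individual undamaged leaves wherever the leaf is the resampling unit.
  Because the same field data can be deposited either way, every metric is
  invariant to splitting a batch into single rows (this is tested).
* **species registry** — margin state per morphospecies
  (`toothed`/`untoothed`/`unknown`), the input to leaf-margin analysis.
  Margin state is a species-level property, not a leaf-level one.
* **DT registry** — feeding group and `generalized`/`specialized` class per
  DT. The guide literature assigns these classes, but census files rarely
  embed them, so they travel as a sidecar configuration rather than being
  hard-coded.
* **unit map** — quarry → stratigraphic level, driving `pool_units()`.
  Level pooling is a disjoint union of quarry record sets; unit labels are
  opaque text ordered lexicographically so all outputs are deterministic.

Leaves that could not be assigned a morphospecies carry the sentinel
`UNIDENTIFIED`: they stay in the table but are excluded from species
abundances, from P and r in leaf-margin analysis, and from herbivory
metrics, which are defined on identifiable leaves.

Two DT encodings are accepted on input (`read_census()`): wide 0/1 columns
named like `DT38`, and a single `;`-separated list column. Deposited
datasets use both dialects, and the round trip through `write_census()` is
exact.

## Diversity and evenness

Richness S, Shannon–Wiener diversity $H = -\sum_i p_i \ln p_i$ and
Pielou's evenness $J = H / \ln S$ use the natural logarithm throughout.
The choice is not cosmetic: published census tables that report H, S and J
together are mutually consistent only under natural logs (e.g. H = 1.30
with S = 13 gives J = 0.51 at two decimals), and the package's acceptance
suite checks exactly that identity. `pielou()` refuses vectors with fewer
than two species rather than returning a conventional value, because J is
genuinely undefined there; `diversity_summary()` converts that refusal to
`NA` so one thin unit does not abort a whole table.

Rank abundance (`rank_abundance()`) sorts by relative abundance with ties
broken lexicographically by species id — a deliberate determinism choice,
since tied proportions are common in small quarries.

## Rarefaction

All rarefaction is individual-based and Monte Carlo: the drawable unit is
the leaf. At each subsample size $m$, $m$ leaves are drawn without
replacement `n_resamples` times; the curve reports the mean and the
2.5/97.5 percentile band of the richness of the draw. Percentile rather
than normal-approximation intervals are used because richness counts at
small $m$ are markedly skewed.

Implementation detail with statistical consequences: each resample draws
one random permutation of the leaves and reads richness cumulatively at
every requested size. The first $m$ entries of a random permutation are a
uniform without-replacement subset, so each size's marginal distribution is
the same as for independent draws, while each resample's accumulation is
monotone — hence the mean curve is monotone by construction, not just in
expectation. It is also an order of magnitude cheaper than independent
redraws per size.

For plant species (`rarefy_species()`), richness of a draw is the number
of distinct morphospecies. For damage types (`rarefy_dts()`), the universe
is *every* identifiable leaf, damaged or not, and a drawn leaf contributes
its whole DT set — this is the accounting that handles leaves with no
damage and leaves with multiple DTs correctly. With
`dt_filter = "specialized"` only registry-classed specialized DTs count
toward richness, giving the specialized-damage curves.

The Monte-Carlo mean has an exact oracle, the hypergeometric expectation
$E[S_m] = \sum_d \left(1 - \binom{N - n_d}{m}\big/\binom{N}{m}\right)$
with $n_d$ the number of leaves carrying id $d$; the test suite implements
it independently (and cross-checks it against `vegan::rarefy` for the
species case) and requires the engine's means to sit within three standard
errors at every size, alongside exhaustive-enumeration checks on three-leaf
examples.

Per-host curves (`per_host_curves()`) restrict DT rarefaction to the
leaves of one morphospecies within one unit, including only hosts with at
least 20 identifiable leaves there — below that, DT richness curves are
dominated by noise. Requested sizes above a host's leaf count are dropped
for that host, since a curve cannot extend past its own sample.

Defaults: `n_resamples = 1000`, seeds mandatory everywhere randomness
enters, and curves carry their seed and resample count as attributes and
in written file headers.

## Damage frequency and specialization

`damage_frequency()` is the proportion of identifiable leaves bearing at
least one DT of a category (total, specialized, generalized); a leaf
counts once per category no matter how many qualifying DTs it carries, so
`freq_total ≤ freq_specialized + freq_generalized` with equality only when
no leaf mixes categories. `spec_gen_ratio()` divides
specialized-damaged leaves by generalized-damaged leaves and returns `NA`
— a flag, not an error — when the denominator is zero. DTs appearing in
records but missing from the registry raise a mapping error rather than
silently vanishing from a category.

## Paleoclimate proxies

**Leaf-margin analysis (MAT).** With $P$ the proportion of margin-scored
morphospecies in a unit that are untoothed and $r$ their number,

$$\mathrm{MAT} = 30.6\,P + 1.14 \quad (^\circ\mathrm{C}), \qquad
\sigma = 30.6\sqrt{P(1-P)/r}.$$

$\sigma$ is the binomial sampling deviation: maximal at $P = 0.5$,
shrinking as $1/\sqrt{r}$. Species present only as unidentified leaves
never enter $P$ or $r$, and unknown-margin species are excluded from both
numerator and denominator.

**Leaf-area analysis (MAP).** With $p_i$ the proportion of leaves in
Raunkiaer size class $i$ (unknown-class leaves excluded before
normalisation) and $a_i$ the class's representative natural-log area,

$$\mathrm{MAP} = e^{0.548 \sum_i a_i p_i + 0.768} \quad (\mathrm{cm/yr}).$$

The calibration's standard error (0.359) lives on the log scale, so the
cm/yr bounds are asymmetric: $+\,\mathrm{MAP}(e^{0.359}-1)$ and
$-\,\mathrm{MAP}(1-e^{-0.359})$. The log-scale reading is adopted because
it regenerates published asymmetric bounds exactly (145 cm/yr → +62.6/−43.7;
a symmetric, linear-scale SE cannot produce asymmetry at all); the
acceptance suite checks those bounds to 0.1–0.2 cm/yr.

The $a_i$ values are not universal constants; `size_class_scheme()` ships
the conventional ln-midpoints of the factor-9 Raunkiaer–Webb area series
(leptophyll ≤ 25 mm² ... megaphyll > 164 025 mm², notophyll splitting
mesophyll at 4 500 mm²) and is an explicit, overridable input
(`read_size_class_scheme()`) rather than a buried constant, because
different calibrations of leaf-area analysis use slightly different class
means.

## Ordination

`nmds()` performs global nonmetric MDS on Euclidean distances of the raw
unit-by-species or unit-by-DT count matrix. Raw counts — not relative
abundances or transformed counts — are the default because census
ordinations of this kind are run on count data; a `transform` hook exists
on `distance_matrix()` for users who want otherwise, but it defaults off.

The stress minimised is Kruskal's stress-1,
$\sqrt{\sum_{i<j}(\hat d_{ij} - f(d_{ij}))^2 / \sum_{i<j} \hat d_{ij}^2}$,
with $f$ fit by isotonic regression (primary/averaging tie treatment), via
`vegan::monoMDS` as the inner engine. Around it the package adds what a
reproducible pipeline needs: restart 0 initialised from classical (metric)
scaling and subsequent restarts from Gaussian configurations, best-of-`n_restarts`
selection (20 by default; stress is non-increasing in the number of
restarts by construction), and a deterministic final orientation — scores
centred, rotated to principal axes, axis signs fixed — because NMDS axes
are otherwise arbitrary up to rotation and reflection and no two runs
would be comparable. `variable_scores()` places each morphospecies or DT
at the abundance-weighted average of the site scores where it occurs, the
standard way of showing which variables pull the units apart; variables
occurring nowhere are flagged rather than silently dropped. Ordinations
default to stratigraphic-level resolution (quarry resolution is available
through `by = "quarry"`), since level labels are what such ordinations are
read by.

With as few units as a five-level section, 2-D nonmetric stress is
routinely below 0.01 — ten rank constraints leave ample freedom — and the
tests assert exactly that on study-shaped matrices, as well as
configuration recovery (Procrustes residual < 1e-3) when the distances come
from genuinely planar point clouds.

## The synthetic census generator

`generate_census()` draws a census from an explicit
`simulation_config()`: each leaf draws a morphospecies from a fixed pool
under a geometric rank-abundance law ($p_{\mathrm{rank}} \propto
k^{\mathrm{rank}-1}$, default $k = 0.8$, pool 40) or a uniform law; a size
class from a named probability vector (default centred on microphyll–
notophyll, the usual mode in Paleogene floras); and, with probability
`damage_prob` (default 0.2, a typical bulk-flora damage frequency), a DT
set sampled by weight without replacement from a configurable pool whose
default spans the common feeding groups with generalized types weighted
heavier. The number of DTs on a damaged leaf follows a truncated geometric
law (halving per extra DT, capped at `max_dts_per_leaf = 4`): most damaged
leaves carry a single DT, as in real censuses. Margin state is fixed per
species at pool creation (probability `p_untoothed`, default 0.6), because
leaf-margin analysis scores species, not leaves.

The generator is a pure function of its configuration: the same seed gives
a byte-identical census, the caller's RNG stream is left untouched, and
`recovery_report()` closes the loop by checking the realised damage
frequency, untoothed share and size-class frequencies against the
configured rates with exact (Clopper–Pearson) binomial intervals.

What the generator deliberately does **not** emulate: taphonomic and
transport bias between depositional environments, spatial autocorrelation
within a quarry, host-specific DT targeting (DT draws are
species-independent by default; a per-species affinity extension is left
to the user via the weights), temporal autocorrelation between levels, and
field-tally behaviour (all simulated rows are single leaves; tally
handling is exercised by constructed fixtures instead). Tests passing on
synthetic censuses therefore validate the *computations*, not the
ecological realism of any particular reconstruction.

## Numerical and design choices

* Seeds are explicit arguments everywhere randomness enters; internal
  seeding is scoped so library calls never perturb the session RNG.
* Ties: rank abundance and host/unit orderings break ties
  lexicographically; isotonic regression uses the primary (averaging)
  approach to tied dissimilarities.
* Degenerate inputs fail loudly and specifically: all-zero abundance
  vectors, J with S < 2, rarefaction sizes beyond the sample, MAP with no
  known-size leaves, k ≥ number of units in NMDS, damaged field-tally
  batches. Classed conditions (`paleocensus_value_error`,
  `paleocensus_schema_error`, `paleocensus_mapping_error`,
  `paleocensus_config_error`, `paleocensus_io_error`) make them testable.
* NMDS convergence: per-start iteration cap 300, stress tolerance 1e-7;
  non-convergence is flagged on the result, with the best configuration
  still returned.
* `run_*` writers never overwrite without `overwrite = TRUE`, and every
  file starts with a provenance header (package version, configuration
  hash, seed) so curves and scores are traceable to their run.
* Presentation rounding (2 decimals for H and J, 1 for climate) lives in
  separate `*_print` columns of the summary tables; computation is never
  rounded.

Test and example problem sizes are chosen to exercise the asymptotics that
matter while staying quick: censuses of 1 500–2 000 leaves across 4–5
units for recovery and ordination checks, 1 000 resamples for rarefaction
(matching the default), and exhaustive enumeration only at n ≤ 12 where it
is exact.

## Known limitations

* Replicating a particular study's full tables requires its deposited
  census and margin-state assignments; the package validates its methods
  against closed forms, enumeration oracles and synthetic data, and
  replays published identities (evenness, MAP bounds) from printed values.
* No extrapolating richness estimators (Chao, ACE): the pipeline
  interpolates (rarefies) only.
* No leaf-area-damaged (percent of blade area removed) herbivory metrics;
  frequencies and DT richness only.
* The sigma printed alongside a published MAT depends on which species
  count r its authors used; where a table's richness and its text's
  species count disagree, sigma cannot be reproduced exactly and this
  package simply computes it from the r you supply.
* No significance testing of group separation in ordination space
  (PERMANOVA and kin are out of scope).
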