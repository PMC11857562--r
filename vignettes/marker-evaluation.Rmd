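---
title: "Evaluating a DNA marker's species-level resolution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a DNA marker's species-level resolution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The question the package answers

A DNA barcode marker resolves species when variation *between* species
exceeds variation *within* them. For many protist groups — the motivating
case is the dictyostelid social amoebae, whose genus-level taxonomy was
rebuilt around 18S rDNA clades — the marker that cleanly separates genera
may fail at the species level because intraspecific and interspecific
divergence overlap. This package implements the standard battery used to
diagnose that failure mode from an alignment plus a reference taxonomy:

1. **distance-class comparison** — are intraspecific, within-genus
   interspecific and between-genus interspecific distances separated?
2. **barcoding-gap analysis** — per sample, does the nearest
   non-conspecific lie beyond the farthest conspecific?
3. **delimitation scoring** — how often does an automatic delimitation
   (a partition from any tool, or monophyly on a tree) recover the named
   species?
4. **signature classification** — which alignment columns are fixed within
   and diagnostic between higher taxa, and how well do they classify?

A sequence simulator generates data with a controlled three-scale
divergence structure so every stage can be validated end to end without
any external sequence database.

## Distances

Pairwise distances use **pairwise deletion**: for each pair, alignment
columns where either sequence carries a gap or any code outside
`A/C/G/T` are dropped. Ambiguity codes are excluded rather than
probabilistically resolved, which keeps every result deterministic.
Pairwise (not complete) deletion matches common practice in
barcoding-distance tools; per-pair comparable-site counts are retained in
the `dist_matrix` object so the information loss is visible.

The Kimura 2-parameter distance is

$$d = -\tfrac12 \ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big),$$

with $P$ and $Q$ the transition (`A↔G`, `C↔T`) and transversion
proportions among comparable sites. When $1-2P-Q \le 0$ or $1-2Q \le 0$
(saturation) the distance is undefined: such pairs are flagged `NA` and
counted in a warning, never silently dropped, and downstream summaries
ignore them explicitly.

**Haplotypes** are the connected components of the zero-distance graph,
not exact string-equality classes. Under pairwise deletion zero distance
is not transitive (an `N`-masked site can hide a difference), so the
component definition is the honest one; a warning reports any component
containing a pair at positive distance. Connected components at a general
threshold (single-linkage clustering via `hclust`/`cutree`) double as a
minimal distance-based delimiter (`threshold_cluster()`), which lets the
scoring machinery run end to end without external delimitation software.

## Distance classes and their reconciliation

Each defined pair receives exactly one finest class: intraspecific
(same species label, which takes precedence over an inconsistent genus
field), within-genus interspecific, between-genus within-order, or
between-order. Two reporting conventions coexist in the literature and
both are supported:

* the **two-way interspecific split** (within-genus vs between-genus,
  the latter including cross-order pairs) used for violin-plot style
  comparisons;
* the **three-level averages**, where "between genera" means *all*
  different-genus pairs while "between orders" is its cross-order subset.
  These two rows overlap by construction; reporting them this way is what
  reproduces conventionally quoted three-level averages, and it is the
  only reading consistent with the bundled 16-isolate table (within-genus
  0.012, between-genus 0.281, between-order 0.321).

Class comparisons use the Kruskal–Wallis rank-sum test plus pairwise
Wilcoxon rank-sum tests with **Holm** adjustment (a conservative default;
no particular adjustment is canonical here). Pairwise distances are
treated as independent observations, as such studies implicitly do; each
sample contributes to many pairs, so the p-values are anti-conservative
under pseudo-replication. The report carries a note to that effect.

## Barcoding gaps

For each sample, `gap = min_nonconspecific − max_conspecific`, computed
from the distance matrix row. The non-conspecific minimum is taken over
all other species, including other genera (the per-genus grouping below
concerns the gap values, not the comparison set); a `within_genus_only`
switch restricts it for sensitivity analyses.

**Singleton species** have no conspecific distance. The default excludes
their samples from gap records (they are logged), because the alternative
convention of substituting `max_conspecific = 0` biases gaps upward; that
convention remains available via `singleton_zero = TRUE` for parity with
tools that use it.

Gaps are aggregated by genus (species-level testing is typically
underpowered at realistic sample sizes). The test against zero is the
**one-sample Wilcoxon signed-rank** test: for a one-sample location
question it is the defensible rank test, although reports in this area
sometimes name the rank-sum test; a `method = "rank_sum"` reading (gaps
versus a zero vector) is implemented for comparison. A Kruskal–Wallis
test across genera accompanies the per-genus table.

## Delimitation scoring

Given any partition of samples into groups (transcribed from a
delimitation tool's output as two-column text), each species with at
least two samples receives one verdict:

| pattern | occupied groups | group purity |
|---|---|---|
| `MONO` | 1 | only this species |
| `MERGE` | 1 | shared with ≥ 1 other species |
| `SPLIT` | ≥ 2 | every group pure |
| `multi-SPLIT` | ≥ 2 | ≥ 1 group shared |

The `multi-SPLIT` rule is deliberately "*at least one* occupied group
shared", not "every group shared": the bundled reference table contains
species printed as multi-SPLIT whose group sets include pure groups
(e.g. a species in groups 26–28 with 27–28 pure), and the
at-least-one-shared rule is the only operational reading that reproduces
every printed verdict. Group ids are opaque labels; every report is
invariant under relabelling, and groups occupied only by unscored
(singleton) samples do not count toward the group total.

**Denominators.** The success rate is the percentage of scored
(multi-sample) species classified `MONO`; the weighted rate is the
percentage of scored samples belonging to `MONO` species. Singleton
species are excluded from both — with the bundled 44-species table this
is the only denominator that reproduces the published 22.73% and 43.18%.
Recomputing the sample-weighted monophyly rate from the bundled
per-species rows gives 32.24% (69/214); the 31.31% printed alongside the
original table is not derivable from its rows, and this package reports
the recomputed value.

**Monophyly** on a rooted tree uses MRCA purity: a species is
monophyletic iff the smallest clade containing all its tips contains no
other sample tips. Polytomies are supported; an outgroup tip used for
rooting never counts as a member. Bootstrap supports are reported where
present but never filtered on.

The bundled 214-sample tree is **synthetic**: a constructed topology in
which exactly the species recorded as monophyletic form pure clades
(non-monophyletic congeners are interleaved in a caterpillar, or have a
monophyletic clade nested inside their span). It reproduces the
published per-species monophyly calls and success rates, not the original
branching order or branch lengths, and is labelled accordingly.

## Signature classification

`derive_signatures()` scans for **fully diagnostic columns**: positions
where every member of a group carries one identical unambiguous state
that occurs in no sequence of any other group. Derivation is
group-versus-rest rather than per-sibling-pair; for two groups the two
formulations coincide, and for more groups group-versus-rest is their
conservative intersection, which keeps a single signature per clade.
Positions are 1-based. Queries must already be aligned to the reference
coordinates (alignment itself is out of scope — any aligner can be used);
match fractions count query gaps and ambiguities as mismatches, the
default threshold of 1.0 treats signatures as fixed differences, and ties
return an explicit `ambiguous` verdict. Published motif sets can be
supplied as configuration files (`read_signatures()`) rather than being
hard-coded.

## The simulator

`sim_config()` fixes three expected K2P divergence scales — `d_intra`
within species, `d_inter_species` between congeneric species,
`d_inter_genus` between genera — and the tree is *constructed* so that
every tip-pair path length equals its class target exactly: conspecific
tips form a star (branches `d_intra/2`), species stems are
`(d_inter_species − d_intra)/2`, genus stems
`(d_inter_genus − d_inter_species)/2`, genera joined by a zero-length
ladder so the root is binary. Within-species structure is a star rather
than a coalescent because only the pairwise distance scales matter to
every downstream statistic.

Sequences evolve site-independently under **K80** with
transition/transversion *rate* ratio `kappa` (default 2.0, the
conventional setting for this marker; note some tools quote the ts/tv
*count* ratio instead, which is `kappa/2` at equilibrium). Branch lengths
are in expected-substitutions units with the rate matrix normalized to
unit total rate, so the generating and estimating models coincide and
K2P estimates are directly comparable to the configured distances. The
root sequence is uniform over `A/C/G/T` and everything is reproducible:
one seed determines the output byte-for-byte, and the caller's RNG state
is left untouched.

Defaults (`seq_length = 1800`, `d_intra = 0.002`,
`d_inter_species = 0.012`, `d_inter_genus = 0.28`, 9 genera × 5 species
× 3 samples) mirror the scales of an 18S rDNA survey: a marker length of
about 1.8 kb, shallow intraspecific diversity, within-genus interspecific
divergence around 0.01 and deep between-genus divergence around 0.28.
`samples_per_species = "tableshape"` replays the bundled 44-species
sample-count imbalance (2–29 per species) for experiments on sampling
bias.

**Overlap scenarios** (`allow_overlap = TRUE`) invert the scales, e.g.
`d_inter_species < d_intra`. Negative branch lengths cannot exist, so the
corresponding stems are clamped at zero: the smaller scale collapses onto
the larger, expected interspecific divergence equals intraspecific
diversity, and sampling noise then produces genuinely negative barcoding
gaps and merged species — the qualitative mechanism by which a marker
loses species-level resolution.

What the simulator does **not** emulate: indels and alignment error (the
alignment is exact by construction), rate heterogeneity across sites or
lineages, base-composition bias, within-species genealogy, and
model-misspecified tree inference. Passing the synthetic end-to-end
checks therefore demonstrates the correctness of the statistics, not that
any real marker behaves this way; the bundled reference tables are the
desk-scale real-data anchor.

## Numerical choices and degenerate inputs

* Undefined distances (`n_compared = 0`, or K2P saturation) are `NA` with
  a warning and a count; summaries, gaps and clustering treat them as
  "no information" (unlinked, excluded from means and extrema).
* Tiny negative K2P values from floating point at `P = Q = 0` are clamped
  to zero.
* All rank tests use the normal approximation (`exact = FALSE`) so ties —
  ubiquitous in rounded published tables and in all-equal degenerate
  cases — are handled uniformly; an all-tied comparison reports p = 1
  with a warning rather than failing.
* Empty classes are reported as absent rather than zero; empty reports
  (no multi-sample species) warn and return a zero-row report.
* `U` is normalized to `T` on FASTA input; `-` and all IUPAC ambiguity
  codes are accepted and excluded pairwise.

## Problem sizes used by the test suite

The packaged checks run on the bundled tables (16 isolates; 214 samples,
44 species), on exhaustive enumerations (all 203 set partitions of 6
samples over 3 species), and on simulations sized for quick, stable runs:
10 kb two-tip alignments for estimator consistency, 5 kb × 20 replicates
for parameter recovery (three-standard-error criterion), and 1.2–1.5 kb
multi-genus alignments for the end-to-end separated and overlap
scenarios. These sizes were chosen so each statistical check has clear
resolution while the whole suite stays fast.

## Known limitations

* Rank tests on pairwise distances pseudo-replicate samples (see above).
* The signature deriver requires fully fixed diagnostic states; nearly
  fixed columns (one aberrant sequence) are ignored rather than scored
  probabilistically.
* `MERGE`/`SPLIT` verdicts depend on the scored sample set: excluding
  singletons can turn a would-be shared group into a pure one. The same
  convention was applied when validating against the bundled table.
* The threshold delimiter is single linkage only — it stands in for
  distance-based delimitation tools in pipelines and tests, not as a
  reimplementation of any of them.
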