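---
title: "Methods: dual-threshold overlap and colocalization analysis of sperm epimutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-threshold overlap and colocalization analysis of sperm epimutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epioverlap)
```

## The analysis

Environmental exposures of a gestating female can alter the sperm epigenome
of her offspring, and some of those alterations persist into the F3
generation — the first generation never directly exposed. Three kinds of
sperm epimutations are catalogued per exposure lineage (e.g. vinclozolin or
DDT) and per generation (F1, F2, F3): differential DNA methylation regions
(DMR), differentially expressed non-coding RNA loci (ncRNA, pooling small
and large ncRNA subtypes), and differential histone retention sites (DHR).
Each catalogued feature is a kilobase-scale genomic interval with a raw
p-value from its upstream differential test.

At stringent per-mark significance (DMR and DHR at p < 1e-06, ncRNA at
p < 1e-04) the sets barely intersect. The question this package formalises
is whether the *same genomic locations* recur across marks and generations
once each stringent set is compared against the other sets at a relaxed
p < 0.05 threshold. The package computes:

1. **The extended overlap matrix.** Rows are the nine (generation, mark)
   sets at their stringent cutoffs; columns are the same sets at p < 0.05.
   Cell (i, j) is the number of distinct row features overlapping at least
   one column feature, and the percentage of the row set that number
   represents. Because every stringent set is a subset of its relaxed
   counterpart and every interval overlaps itself, the nine diagonal cells
   are identically 100% — a built-in correctness check.
2. **The 10 kb-window variant.** Every feature on both sides of the
   comparison is extended by 5 kb per side (so an interior feature's span
   grows by exactly 10 kb) before the same matrix is computed. This
   captures regional colocalization of features that are near but not
   touching.
3. **Venn partitions.** Two or three sets are pooled, clustered into
   connected components under single-linkage interval overlap, and each
   component is counted once under the signature of the sets contributing
   to it.
4. **Colocalization scans.** Within each generation, each stringent
   feature is an anchor, and relaxed features of the *other* marks
   overlapping it are its partners; anchors with at least one partner are
   the reported multi-epimutation sites.
5. **Permutation significance.** Observed overlap statistics are compared
   with a null in which the non-anchor set(s) are re-placed uniformly on
   the genome as size-matched fixed-width sites.

All coordinates are 0-based half-open; overlap means at least one shared
base pair (`a$start < b$end && b$start < a$end`), so abutting intervals do
not overlap. Strand is ignored: epimutations are unstranded genomic sites.
Chromosome names match by exact string equality; the readers can convert
1-based input at the boundary but never rename chromosomes silently,
because silent renaming manufactures false non-overlap.

## Thresholds

Cutoffs are applied strictly (`p < cutoff`), matching how the candidate
sets are defined upstream. p-values are used as given — no multiple-testing
adjustment — because the dual-threshold design deliberately contrasts a
stringent raw cutoff with a permissive raw cutoff rather than controlling
an error rate. Duplicate or overlapping members within a set are never
merged: counts are per catalogued feature, and merging would silently
change every percentage's denominator. ncRNA subtypes (sncRNA, lncRNA) are
pooled into the single ncRNA set by default, with the subtype kept as
metadata, since the figures the analysis mirrors treat ncRNA jointly.

## Design choices that were genuinely open

**Which side gets the 5 kb flank.** "A 5 kb distance on either side" of the
features, giving a 10 kb window, does not say whether one or both sets in a
comparison are extended. The package extends **both** sides, for symmetry:
the windowed relation then stays symmetric as a relation (only denominators
differ between directions), and the windowed matrix dominates the direct
matrix cellwise, a property the tests enforce. Row-only extension can be
emulated by pre-extending one set with `extend_window()`.

**Venn counting unit.** Features of different marks differ in width, so
"one shared site" is ambiguous when a wide feature bridges two narrow ones.
The package counts **connected components** (regions) of the pooled
features; a per-feature mode (`unit = "feature"`) is provided for
cross-checks. Component counts are conserved by construction: signature
counts always sum to the number of components.

**The permutation null.** The randomization scheme behind the published
significance claim is not specified beyond naming 1 kb and 10 kb
overlapping sites. The package therefore uses the simplest defensible
null: size-matched sites of exactly `site_size_bp` (1 kb or 10 kb) placed
uniformly over the genome, chromosome chosen with probability proportional
to its number of valid start positions, per-chromosome counts *not*
preserved, and only the non-anchor set(s) randomized (the anchor set
conditions the test). The empirical p-value uses the add-one estimator
(1 + #{null >= observed}) / (1 + n_perm), which is conservative, never
zero, and bounded below by 1/(n_perm + 1); n_perm defaults to 999. With
discrete overlap counts the estimator is slightly conservative under the
null — the calibration test in the suite verifies the realised type-I
error stays inside the exact binomial band around the nominal 5% level.

**Gene association.** The rule linking epimutations to genes in the
supplementary tables is inherited from upstream work and not restated, so
the package adopts a standard convention: link to every overlapping gene,
otherwise to the nearest gene within 10 kb (the same scale as the window
analysis). An abutting gene is reported as `within_distance` at distance 0.

## The synthetic-data generator

Real catalogs derive from deposited raw sequencing data whose processing
lives outside this package, so validation uses synthetic catalogs with the
same *structure*: 2 lineages x 3 generations x 3 marks, kilobase features
(DMR/DHR 1000 bp, ncRNA 500 bp), and p-values in three constructed tiers —
planted features at 10^-U(6,12) (DMR/DHR) or 10^-U(4,10) (ncRNA), always
below the stringent cutoffs; near-misses uniform between the mark's
stringent cutoff and 0.05; background uniform on [0.05, 1]. The tiering is
what makes the stringent-vs-relaxed contrast testable: planted features
survive both cutoffs, near-misses only the relaxed one, background
neither.

The planted biology mirrors the transgenerational pattern the analysis is
designed to detect, with defaults chosen once as the study conditions:

* a 20-chromosome, 10 Mb-per-chromosome genome (200 Mb — a uniform
  one-order-of-magnitude reduction of the rat genome that keeps chance
  overlap rates realistically low at desk scale);
* 400 F1 DMR loci, of which **35%** are retained (re-emitted in F2 and
  F3), plus 200/400 fresh F2/F3 DMR loci;
* **30%** of F1 DMR loci carry a colocalized F1 ncRNA (the RNA-directed
  DNA methylation pattern);
* **25%** of F3 DMR loci carry a colocalized F3 DHR and F3 ncRNA (the
  tri-mark colocalization pattern), with DHRs otherwise confined to F3 —
  F1/F2 DHR sets contain only background features, so their stringent rows
  are empty;
* 300 fresh ncRNA loci per generation, 300 fresh F3 DHR loci, and 100
  near-miss plus 150 background features per active set;
* `jitter_bp` displaces each feature's centre uniformly around its latent
  locus; the default 0 makes planted colocalization exact, while a few kb
  of jitter separates what direct overlap and the 10 kb window can each
  recover.

Per-set counts in real catalogs vary by an order of magnitude between
marks and generations; the defaults above are round numbers at the low end
of that range, large enough that binomial noise on the planted fractions
is a few percentage points. Two lineages are emitted with independent
loci, mirroring the observation that each exposure induces its own sites.

What the generator does **not** emulate: clustered or GC-biased genomic
placement (placement is uniform), correlated p-values, chromosome-specific
feature density, width variation within a mark, and any relationship
between p-value and effect size. Passing tests therefore demonstrate that
the *machinery* recovers planted structure and is calibrated under its own
null — not that real sperm catalogs have these properties.

## Numerical and algorithmic notes

* Pair enumeration uses an event-based sweep line, O((n+m) log(n+m) + k);
  end events are processed before start events at the same coordinate,
  which realises half-open semantics. The test suite proves it equal to a
  quadratic brute-force oracle on 100 random instances (up to 500x500)
  and to an interval-tree implementation from an independent library.
* Membership queries ("does this feature hit the set at all?") run against
  a precomputed merged disjoint union of the subject set via binary
  search, so a 999-permutation test re-places and re-queries in
  milliseconds.
* Ties are broken deterministically everywhere by sorting on
  (chromosome, start, end, id).
* Empty stringent sets produce 0-count rows with percentages reported as
  missing (`NA`), never as 0%, since the denominator is undefined.
* All randomized stages take an explicit integer seed, restore the
  caller's RNG state, and are byte-identical across runs given the same
  seed — including serialized outputs.

## Validation problem sizes

The shipped test suite validates on: catalogs of roughly 300-900 features
per lineage under the default study conditions (planted-fraction recovery,
permutation power at n_perm = 999); 100 random instances up to 500x500
features for oracle equivalence; and 200 replicate null datasets at
n_perm = 199 for type-I-error calibration. These sizes put the binomial
sampling error of each planted fraction at 2-3 percentage points, which is
the tolerance the recovery tests assert.

## Limitations

* Percentages depend on upstream feature *definitions* (width conventions,
  pre-merging): two catalogs of the same biology with different feature
  widths will give different matrix values, especially under windows.
* The uniform null ignores mappability, assembly gaps and CpG density; a
  width-preserving or chromosome-preserving shuffle can be emulated by
  supplying pre-built sets, but annotation-matched nulls are out of scope.
* The Venn component convention can merge planted loci that happen to lie
  within a feature width of each other, so region counts are a lower bound
  on locus counts.
* Pathway/pathology linkage of associated genes is out of scope.
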