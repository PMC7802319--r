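# epioverlap

Integration analysis of multi-generation sperm epimutation catalogs.

## The problem

Transient environmental exposure of a gestating female (e.g. to the
fungicide vinclozolin or the pesticide DDT) alters the sperm epigenome of
her descendants, and some alterations persist to the transgenerational F3
generation. Three kinds of epimutations are catalogued per exposure lineage
and generation: **DMRs** (differential DNA methylation regions), **ncRNA**
loci (differentially expressed non-coding RNAs) and **DHRs** (differential
histone retention sites). Each is a kilobase-scale genomic interval with a
raw p-value. At stringent significance the nine per-lineage sets barely
intersect; the scientific question is whether the *same genomic locations*
recur across marks and generations once each stringent set is compared
against the others at a relaxed threshold — the pattern expected under
RNA-directed DNA methylation and DNA methylation-directed histone
retention.

`epioverlap` is for epigenomics analysts who have such processed catalogs
(BED/TSV interval tables with p-values) and want the full dual-threshold
integration analysis with permutation significance, reproducibly.

## The core computation

For a lineage, let S<sub>gm</sub> be the (generation g, mark m) set at its
stringent cutoff (DMR/DHR p < 1e−06, ncRNA p < 1e−04, strict) and
R<sub>g'm'</sub> the same sets at p < 0.05. The **extended overlap matrix**
has cells

> count(g,m → g',m') = #{ x ∈ S<sub>gm</sub> : x overlaps ≥ 1 feature of R<sub>g'm'</sub> },
> percent = 100 · count / |S<sub>gm</sub>|

with overlap meaning ≥ 1 shared bp under 0-based half-open coordinates.
Since S<sub>gm</sub> ⊆ R<sub>gm</sub>, diagonal cells are exactly 100%.
The **10 kb-window** variant extends every feature by 5 kb per side first.
Venn partitions count connected components of pooled features by
membership signature, and permutation tests compare observed overlap
statistics with size-matched 1 kb / 10 kb sites placed uniformly on the
genome, using the add-one empirical p-value
(1 + #{null ≥ obs}) / (1 + n_perm).

## Worked example

Every stage runs on synthetic catalogs with planted structure, so the
pipeline is demonstrable without any download:

```r
library(epioverlap)

sim <- generate_catalog(synthetic_config(seed = 1))
m <- extended_overlap_matrix(sim$catalog, "vinclozolin")
print(m)
#> Extended overlap matrix, lineage vinclozolin, flank 0 bp (rows stringent, columns p < 0.05)
#>          F1 DMR       F1 ncRNA     ...  F3 DMR       F3 ncRNA     F3 DHR
#> F1 DMR   400 (100.0%) 126 (31.5%)  ...  159 (39.8%)  39 (9.8%)    38 (9.5%)
#> F1 ncRNA 125 (29.5%)  424 (100.0%) ...  45 (10.6%)   10 (2.4%)    11 (2.6%)
#> F1 DHR   0 (-%)       0 (-%)       ...  0 (-%)       0 (-%)       0 (-%)
#> ...
#> F3 DMR   159 (28.6%)  44 (7.9%)    ...  556 (100.0%) 137 (24.6%)  136 (24.5%)
```

Reading the numbers: the diagonal is 100% by construction; the F1 DMR row
meets the relaxed F3 DMR column at 39.8% — the generator's 35% planted
retention plus a little incidental overlap; 31.5% of stringent F1 DMRs
carry a relaxed F1 ncRNA (30% planted); the F1/F2 DHR rows are empty
(percent undefined) because DHRs only arise in F3; and the F3 DMR row
shows the ~25% planted tri-mark colocalization against ncRNA and DHR.
With 5 kb flanks (`flank_bp = 5000`) the F1→F3 DMR cell rises to 42.8%,
illustrating how the 10 kb window captures near-but-not-touching sites.

The tri-mark colocalization is significant against random placement:

```r
pt <- multiway_colocalization_test(sim$catalog, "vinclozolin",
                                   assembly = sim$assembly,
                                   n_perm = 999, seed = 2)
print(pt)
#> Permutation overlap test (overlap regions containing DMR, DHR and ncRNA)
#>   observed = 136, null mean = 0.02 (sd 0.13), n_perm = 999
#>   site size = 1000 bp, flank = 0 bp, seed = 2
#>   empirical p = 0.001
```

136 genomic regions carry all three stringent F3 marks, versus ~0 under
the uniform null — the minimum attainable p at 999 permutations.

`run_pipeline(out_dir)` orchestrates the whole analysis (direct and
windowed matrices, Venn partitions, colocalization scan, permutation
tests, gene association) and writes CSV/JSON/TSV/BED reports plus a
manifest; `inst/cli/epioverlap.R` wraps it for shell use
(`Rscript inst/cli/epioverlap.R run-all --seed 7 --out results/`).
Observed catalogs are read with `read_epimutation_table()` /
`read_catalog_dir()` in place of the simulator.

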