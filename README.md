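# nfkbcodep

Integrative analysis of **NF-κB p50 / IκBζ codependent gene regulation** in
stimulated macrophages.

A small set of key inflammatory genes (*Il6*, *Il1b*, *Lcn2*, ...) requires
both the NF-κB p50 subunit (*Nfkb1*) and the nuclear IκB protein IκBζ
(*Nfkbiz*) for induction. `nfkbcodep` implements, as a tested and reusable
pipeline, the genomics analysis that identifies these genes and the binding
events behind them:

* **Gene dependence** — for each knockout genotype, a gene is dependent
  when its KO/WT nascent-transcript ratio at the minimum-ratio timepoint is
  `< 0.33` with a BH-adjusted NB exact-test p `< 0.01` (WT RPKM `> 3`);
  codependence requires both regulators to pass independently.
* **Peak kinetics** — reproducible-peak filtering (PS `> 19`, RPKM `> 3` in
  k-of-n replicates), peak-set union, six-cluster k-means on max-normalized
  0/0.5/1/2 h binding profiles, 0 h ATAC accessibility overlay, rank-ordered
  signal matrices.
* **Binding preference and dependence** — 1 h p50:RelA RPKM ratios over the
  combined p50 + top-N RelA sets with equal-size binning; KO/WT binding
  ratios banded into strong (`< 0.33`) / mild (0.33–1.0) / independent
  (`> 1.0`); nearest-TSS annotation with one-peak-per-gene enrichment.
* **Motif content** — scanning for the p50-homodimer κB element (three G:C
  base pairs per half-site, 5 bp spacer: `GGGNNNNNCCC`), PWM scanning, and
  hypergeometric per-bin enrichment.
* **Stimulus selectivity** — lipid A vs TNF expression ratios tiered at 1:3
  and 1:60, crossed with dependence classes.
* **Synthetic data** — a seeded generator producing the full study design
  (5 genotypes × 2 stimuli × 5 timepoints × 2 replicates, multi-factor
  peaks, sequences, ATAC) with planted ground truth for every classifier.

## Worked example

```r
library(nfkbcodep)

ds <- simulate_dataset(generator_params(n_genes = 500, n_peaks = 800,
                                        rng_seed = 42))
calls_p50  <- classify_dependence(ds$expression, "Nfkb1")
calls_ikbz <- classify_dependence(ds$expression, "Nfkbiz")
co <- codependence_join(calls_p50, calls_ikbz)
table(co$label)
#> codependent     neither  Nfkb1_only Nfkbiz_only
#>           8         471           9          12
table(planted = ds$truth$gene_class[co$gene_id], called = co$label)[
  c("codependent", "p50_only", "ikbz_only"), ]
#>              called
#> planted       codependent neither Nfkb1_only Nfkbiz_only
#>   codependent           8       0          0           0
#>   p50_only              0       0          9           0
#>   ikbz_only             0       0          0          12
```

Every planted dependence class is recovered exactly: 8 codependent genes, 9
p50-only, 12 IκBζ-only, and no false calls among 471 null genes. The same
dataset carries planted binding dependence and stimulus selectivity:

```r
b <- ds$peaks$binding$IkBzeta
ikbz <- ds$peaks$peaks[ds$peaks$peaks$is_ikbz, ]
dep <- binding_dependence(b$wt[ikbz$peak_id], b$ko[ikbz$peak_id], "IkBzeta")
table(dep$band)
#> independent        mild      strong
#>          59          69          12
cd <- classify_differential(stimulus_ratio(ds$expression))
table(cd$tier[cd$included])
#>     differential not_differential           strong
#>               12              132                8
```

Strong p50-dependent IκBζ binding is a small minority of IκBζ peaks (12 of
140), and the 8 genes in the strongest TNF-vs-lipid A differential tier are
exactly the codependent ones — the qualitative signature the pipeline is
built to expose.

A command-line interface wraps the same functions
(`inst/scripts/nfkbcodep.R`): `simulate`, `classify-expression`, `peaks`,
`preference`, `dependence`, `motif`, `stimulus`, `report`.

## Package layout

```
R/                     implementation (io, config, simulate, dependence,
                       peak-kinetics, preference, motif, stimulus, cli)
tests/testthat/        unit, property and acceptance suites with
                       brute-force oracles
vignettes/             methods vignette (model, parameters, design choices)
scripts/acceptance.R   end-to-end reproduction script
inst/scripts/          CLI wrapper
```
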