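# radpair

Quality control for paired ddRAD libraries prepared with and without
whole-genome amplification.

## What it is for

Multiple displacement amplification (MDA) makes double-digest RAD
sequencing possible for samples that yield very little DNA, but it
introduces artifacts: fewer assembled loci per read (worse at low input
DNA), overdispersed read depth across loci, allelic dropout (apparent
homozygosity), and amplified contamination.  The decisive quality check is
a *paired* design — for the same individuals, one library from genomic DNA
(gDNA) and one from MDA product — with every statistic compared within
pairs.  radpair is for researchers running or evaluating such designs:
it reads ipyrad-style `.loci` files and relaxed-phylip SNP matrices,
computes the per-library statistics, distance matrices, contamination
classifications, models and population-genetics endpoints of that
analysis, and ships a simulator that generates paired studies with known
truth.

The statistical core:

* **MDMR** — multivariate distance matrix regression.  With squared
  dissimilarities `A`, Gower-centered `G = -1/2 C A C`, and design hat
  matrix `H`, the omnibus pseudo-R² is `tr(HGH)/tr(G)`; per-predictor
  effects are drop-one differences, and p-values come from jointly
  permuting rows/columns of the distance matrix.
* **Linear mixed models** with random intercepts and backward elimination
  by Satterthwaite F-tests (α = 0.05), with the transforms used for
  bounded responses (`logit(x/30000)` for locus counts,
  `logit(x + 0.001)` for proportions).
* **Weir–Cockerham F_ST** combined across loci as a ratio of summed
  variance components `θ = Σa / Σ(a+b+c)`, linearized as `θ/(1−θ)` for
  Mantel tests of isolation by distance against great-circle distances.
* **A problematic-sample rule**: flag a sample when its gDNA–MDA genetic
  distance is at least the distance from its gDNA library to the nearest
  conspecific gDNA library.
* **Matrix condensing**: choose a min-samples-per-locus threshold and a
  sample subset bounding per-sample missing data at 50% while keeping as
  many samples, then loci, as possible.

## Worked example

Simulate a two-taxon paired study at the default conditions, compute the
per-library statistics, and ask whether library preparation (rather than
population membership) structures the genetic distances:

```r
library(radpair)

cfg   <- sim_config(seed = 42)          # 2 taxa x 2 pops x 6 individuals, paired
study <- simulate_paired_study(cfg)
stats <- library_stats(study$datasets$taxonA, cfg$filter)
head(stats[, c("library_id", "method", "n_assembled_loci", "sd_depth",
               "heterozygosity")], 4)
#>          library_id method n_assembled_loci sd_depth heterozygosity
#> 1 taxonA_p1_i1_gDNA   gDNA              200 12.08672    0.006111111
#> 2  taxonA_p1_i1_MDA    MDA              200 47.68476    0.004833333
#> 3 taxonA_p1_i2_gDNA   gDNA              200 10.26187    0.006222222
#> 4  taxonA_p1_i2_MDA    MDA              200 21.76974    0.005111111
```

The MDA libraries show the expected artifacts: much higher depth
dispersion across loci and slightly depressed observed heterozygosity.
Do those artifacts overwhelm the real population signal?

```r
gd   <- genetic_distance(study$datasets$taxonA, cfg$filter)
pred <- data.frame(method = stats$method, population = stats$population,
                   log_final_loci = log1p(stats$n_final_loci),
                   row.names = stats$library_id)
mdmr(gd, pred, n_permutations = 999, seed = 1)
#> Multivariate distance matrix regression (n = 24, 999 permutations)
#>       predictor pseudo_r2     p
#>       (omnibus)    0.2358 0.001
#>          method    0.0170 1.000
#>      population    0.1817 0.001
#>  log_final_loci    0.0441 0.440
```

No: population membership explains ~18% of the distance structure
(p = 0.001) while preparation method explains ~2% and is not significant —
amplification artifacts stay well below natural genetic variation here.
`flag_problematic_samples(gd, study$datasets$taxonA$libraries)` confirms
every pair is closer within-individual than to its nearest conspecific.

A full workflow (statistics, both distance matrices with MDMR,
contamination report, models, condensing, clustering) runs from one
config: `run_all(run_config(sim = cfg), "outdir")`, or from the shell via
`Rscript inst/cli/radpair.R run --config run.yaml --out outdir`.

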