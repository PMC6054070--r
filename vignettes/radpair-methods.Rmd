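---
title: "Methods: assessing whole-genome amplification artifacts in paired ddRAD libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing whole-genome amplification artifacts in paired ddRAD libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radpair)
```

## The problem

Multiple displacement amplification (MDA) lets double-digest RAD sequencing
(ddRAD) be applied to samples — small insects, museum material, larvae —
that yield too little DNA for direct library preparation.  The price is a
set of amplification artifacts: libraries built from amplified DNA tend to
recover fewer loci for a given sequencing effort, with the deficit growing
as the amount of template DNA in the amplification reaction shrinks; read
depth becomes overdispersed across loci; one allele of a heterozygote can be
over-amplified until the genotype caller reports an apparent homozygote; and
the reaction can amplify non-templated DNA (reagent contaminants or carried
over material from other samples).

radpair implements the study design that quantifies these artifacts: for a
set of individuals, one library is prepared directly from genomic DNA
(gDNA) and a second from MDA product of the same extraction, and every
statistic is compared within those pairs.  The package also provides the
downstream checks that matter to practitioners — does the amplification bias
*which* loci are recovered, does it corrupt genetic distances, clustering,
F~ST~ and isolation-by-distance — and a simulator that generates such paired
studies with known ground truth.

## The simulator

`sim_config()` / `simulate_paired_study()` generate multi-taxon datasets of
short (default 90 bp) loci.

**Genotypes.** Population structure follows the Balding–Nichols island
model: each polymorphic site has an ancestral frequency
$\bar p \sim U(0.05, 0.95)$ and population frequencies
$p_k \sim \mathrm{Beta}\big(\bar p\,(1-F)/F,\ (1-\bar p)(1-F)/F\big)$, so
$\mathrm{Var}(p_k) = F\,\bar p(1-\bar p)$ and the taxon-level `fst` knob is
the expected Weir–Cockerham differentiation.  Individuals are diploid and in
Hardy–Weinberg proportions within populations.  Sites are placed by a
per-site polymorphism probability `theta` (default 0.02, about 1.8 variable
sites per 90-bp locus — a typical level for within-species ddRAD data).

**Coverage.** Per library, locus weights are Dirichlet with a scalar
concentration $\alpha$ and read depths are multinomial over loci with the
library's read budget (depths therefore sum exactly to the budget).  For
gDNA libraries $\alpha$ is large (default 200: nearly even coverage).  For
MDA libraries

$$\alpha = \alpha_\mathrm{ref} \cdot \frac{\text{input ng}}{\text{ref ng}},$$

with $\alpha_\mathrm{ref} = 5$ at 100 ng, floored at 0.05.  This single
interpretable knob reproduces the observed phenomenology — low input gives
low concentration, hence heavy-tailed coverage, loci dropping below the
assembly depth threshold, and a higher SD of depth across assembled loci —
without modelling the amplification branching process explicitly.  Input
amounts are drawn log-uniformly on 6–360 ng by default, the span of
whole-body extractions of small beetles.  Read budgets are lognormal
(`reads_sd_log = 0.4`) because pooled sequencing yields very uneven
per-sample read counts.

**Genotype calling and allelic dropout.** At a heterozygous site covered at
depth $D$, the allele split is $\mathrm{Binomial}(D, 1/2)$ for gDNA and
beta-binomial with shape `imbalance_beta` (default 0.5; smaller = stronger
imbalance) for MDA.  A heterozygote is called only when the minor allele is
seen in at least `min_minor_reads` (default 2) reads; otherwise the major
allele is reported homozygous.  Dropout is therefore a property of the
*calling* step, matching the "apparent homozygosity" interpretation of the
artifact, rather than a sequence-error process.

**Contamination.** `inject_contamination()` replaces a
$\mathrm{Binomial}(n_\mathrm{assembled}, f)$ draw of a library's locus slots
with sequences from a donor taxon, in one of two modes:

* `"separate"` — the contaminant slots assemble into their own loci (keyed
  by donor locus, so two libraries hit by the same donor locus share it).
  This is how non-homologous cross-taxon reads behave in a real assembly,
  and it is why the minimum-samples-per-locus filter removes most
  contamination: with donors drawn independently per library, contaminant
  loci are rarely shared by four samples.
* `"co_assemble"` — the donor sequence replaces the member sequence inside
  the locus alignment, emulating a mis-assembled (chimeric) stack.  This is
  the mode that corrupts genetic distances and is what the
  problematic-sample rule detects.

Both modes record their draws in the simulation truth for recovery tests.

**What the simulator does not emulate.** Read-level data (FASTQ, quality,
sequencing error), the clustering/assembly algorithm itself, locus length
variation and size selection, linkage between loci, GC-dependent
amplification bias, and DNA *quality*: real studies cannot separate
quantity from quality of input DNA (samples that yield little DNA also tend
to yield degraded DNA), and the simulator deliberately exposes only a
quantity knob.  Passing tests on simulated data therefore demonstrate that
the estimators and rules recover the truth under the stated generative
model, not that the model captures every failure mode of real libraries.

**Determinism.** All randomness derives from one master seed; per-library
substreams are derived by a stable string hash of the library id, so
results are independent of simulation order and any library can be
regenerated alone.

## Per-library statistics

`library_stats()` computes the model inputs: assembled-locus count (depth ≥
`min_coverage`, default 7), final-locus count (locus shared by ≥
`min_samples_per_locus` libraries, default 4), mean and SD of depth across
assembled loci (sample SD, $n-1$), observed heterozygosity, and GC content.
Observed heterozygosity is the *pooled* proportion of heterozygous IUPAC
codes among called sites in final-dataset loci (not a per-locus average):
"proportion of heterozygous sites" is a ratio of pooled counts.  GC content
is computed over assembled loci (an option switches to final loci, since the
choice is not fixed by convention) and counts S as 1 and each of R/Y/K/M as
0.5 — unbiased under random phase, a convention we document because none is
standard.

## Distances and the problematic-sample rule

Two library-by-library matrices (`rad_dist` objects; undefined pairs are
`NA`, never 0):

* **Locus-overlap dissimilarity** $1 - p$, where $p$ is the proportion of
  final loci shared.  "Proportion shared for both libraries" is ambiguous
  between Jaccard ($|A \cap B| / |A \cup B|$) and the min-denominator
  variant; we default to Jaccard (symmetric, bounded, standard) and expose
  `denominator = "min"`.
* **Genetic distance**: over final-dataset SNP sites where both libraries
  have a called base, each IUPAC genotype expands to its two alleles and
  the site score is the mean of the four cross-library allele comparisons;
  the distance is the mean site score.  Site-averaging (not summing) makes
  pairs with different overlap comparable.  Identical heterozygotes score
  0.5 under cross-comparison; the diagonal is nevertheless forced to 0 by
  convention.  Pairs sharing fewer than `min_shared_for_distance` (default
  35) final loci are `NA`.

`flag_problematic_samples()` flags a paired sample when its gDNA–MDA
distance is at least the distance from its gDNA library to the most similar
conspecific gDNA library (margin ≤ 0, an inclusive boundary).  The logic:
absent contamination, two libraries from the same DNA must be more similar
than libraries from different individuals; within-species contamination is
invisible to the cross-taxon classifier but inflates exactly this
within-pair distance.

`neighbor_joining()` (Saitou–Nei, via ape) drops libraries with undefined
pairs greedily before tree building and serializes to newick.

## Contamination classification

`build_reference()` mimics the reference-from-own-data strategy used when no
genome is available: all gDNA sequences in the final dataset, de-replicated
per taxon at 95% global identity by greedy length-sorted clustering, plus
optional non-self records (e.g. a human decoy) — the minimum-samples filter
applied *first* keeps contaminants out of the reference.  De-replication
processes sequences longest-first and absorbs, per representative, all
unassigned sequences within the identity threshold (batched global
alignments); each sequence therefore joins the earliest representative that
accepts it.  `classify_sequences()` assigns each query to the best-scoring
entry found by shared-k-mer lookup (k = 13) followed by local alignment,
requiring identity ≥ 0.85 over ≥ 50% of the query; categories are
correct-taxon / incorrect-taxon / human / no-match, with ties broken toward
the query's own taxon and then lexicographically.  Matching is
forward-strand only (ddRAD loci are orientation-consistent after assembly).
This is an approximation of short-read mapping with a sensitive preset, not
a reimplementation of it; users who prefer an external mapper can classify
outside and summarize the result themselves.

## Inference

**Transforms** (`transform_response()`): `log`; `logit_capped`, the logit of
$x/\mathrm{cap}$ for responses with a ceiling (locus counts, default cap
30,000); `logit_offset`, $\mathrm{logit}(x + 0.001)$ for proportions that
can be exactly zero.

**Mixed models** (`fit_mixed()`): REML linear mixed models with random
intercepts (lme4), simplified by backward elimination — at each step the
least-significant *eliminable* fixed effect (interactions before their main
effects) with F-test p > α (default 0.05) is dropped and the model refit.
F-tests use Satterthwaite denominator degrees of freedom (lmerTest); a
formula without random effects falls back to ordinary least squares with
marginal F-tests, which the tests verify reproduces closed-form OLS.
Singular fits are flagged, and the elimination trail is kept in the result.

**MDMR** (`mdmr()`): with $A_{ij} = d_{ij}^2$ and centering matrix $C$, the
Gower inner-product matrix is $G = -\tfrac12 C A C$; for a design hat
matrix $H$ (intercept included) the omnibus pseudo-$R^2$ is
$\mathrm{tr}(HGH)/\mathrm{tr}(G)$, and per-predictor effects are marginal
(drop-one): $[\mathrm{tr}(HGH) - \mathrm{tr}(H_{-j} G H_{-j})]/\mathrm{tr}(G)$.
p-values permute rows and columns of the distance matrix jointly,
$p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + B)$, default $B = 999$.
Negative eigenvalue mass of $G$ (non-Euclidean dissimilarities) is retained
in the traces rather than truncated; a consequence worth knowing is that on
degenerate inputs (e.g. an overlap matrix in which almost every pair shares
almost every locus) pseudo-$R^2$ can come out slightly negative — that is a
property of the trace formulation, not an error, and such values should be
read as "no signal".  Rank-deficient designs error out naming the aliased
columns.

## Population-genetics endpoints

**Matrix condensing** (`condense()`): choose a minimum-samples-per-locus
threshold and a sample subset so that every kept sample has ≤ 50% missing
data over the loci passing the threshold, maximizing first the number of
samples kept and then the number of loci — removal decisions use
missingness only, never sample identity or preparation method.  For
matrices up to 15 samples the subset is found by exhaustive search over
removal sets of increasing size, which *guarantees* the samples-first
objective; larger matrices use the greedy rule (repeatedly drop the sample
with the worst missingness; ties → fewer loci present, then id).  We made
the exact branch the default for small inputs after observing that the
greedy rule can strand one extra removable sample on unfavourable matrices;
the greedy path remains for realistically sized studies, and the output is
audited against its own constraints either way.

**PCA + k-means** (`pca_kmeans()`): IUPAC genotypes are encoded as 0/1/2
alt-allele dosages (sites with more than two alleles are dropped and
counted; missing values are mean-imputed), PCA is computed on centered
dosages, k-means runs on the PCs explaining ≥ 90% of variance (capped at
20), and k is chosen by the minimum of
$\mathrm{BIC}(k) = n\log(\mathrm{WSS}_k/n) + k\log n$ with 20 seeded
restarts per k — the standard genotype-clustering recipe.  The number of
retained PCs is a tunable because no convention fixes it.

**F~ST~** (`wc_fst()`): per biallelic site the Weir–Cockerham (1984)
variance components $a$ (among populations), $b$ (among individuals within)
and $c$ (within individuals) are computed from sample sizes, allele
frequencies and heterozygote counts; the combined estimate is the ratio of
sums $\hat\theta = \sum_s a_s / \sum_s (a_s + b_s + c_s)$ (not a mean of
per-site ratios), the standard way to combine across loci.  Monomorphic
sites are skipped; the linearized value is $\hat\theta/(1-\hat\theta)$.
A finite-sample caveat verified in the tests: feeding the *same* genotype
table to both populations does not give 0 but exactly $-1/(2n-2)$, because
the among-population variance is then forced below its null expectation.

**Isolation by distance** (`ibd_analysis()`): pairwise linearized F~ST~
against great-circle distances (haversine, sphere radius 6371.0088 km)
between population coordinate means, tested with a one-tailed Mantel test
(positive association is the scientific alternative; a two-tailed flag is
provided), $p = (1 + \#\{r_\mathrm{perm} \ge r\})/(1+B)$.  Populations
without libraries in the requested subset (all / gDNA / MDA) are dropped;
fewer than three populations is an error.

## Numerical and edge-case policy

Missing distances propagate as `NA` and are never imputed; MDMR requires a
complete matrix, and neighbor joining prunes incomplete libraries with a
warning.  Zero called sites, all-monomorphic data, and empty inputs signal
errors rather than returning 0.  All permutation procedures reproduce
exactly under a fixed seed.  Boundary conventions are inclusive where the
underlying rule is: depth exactly at the assembly threshold counts, and a
problematic-sample margin of exactly 0 flags.

## Problem sizes used by the test suite

The packaged checks run the machinery at deliberately compact sizes chosen
to keep Monte-Carlo error small relative to the tested effect: the default
two-taxon study (2 × 2 populations × 6 individuals, 200 loci), F~ST~
recovery at 2 × 50 diploids × 500 loci over 20 seeds (±0.02), MDMR null
calibration with 1,000 simulations × 199 permutations, 50-replicate
directional checks for the amplification artifacts, and a fixed grid of
matrices up to 12 × 20 for the condenser's exhaustive cross-check.

## Known limitations

The aligner-based classifier approximates, and will not bit-match, any
specific external mapper; the simulator's contamination is cross-taxon only
(conspecific contamination is represented through the `co_assemble` mode's
effect on distances, not as a mixture of reads); per-site depth is not
modelled (only per-locus); and the mixed-model machinery covers Gaussian
responses only — proportions are handled by transforms, as in the analyses
this package supports, not by generalized models.
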