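# ervmine

Mining, annotation, dating and comparative analysis of endogenous
retrovirus (ERV) insertions in host genome assemblies — with a built-in
provirus-evolution simulator so every stage can be benchmarked against
ground truth.

## The problem

Endogenous retroviruses are germline-integrated proviruses
(5'LTR–*gag*–*pol*–*env*–3'LTR) inherited as host alleles. Characterizing
an ERV lineage such as the endogenous feline leukemia virus (enFeLV) of
the *Felis* genus means answering, per genome: where are the copies, how
structurally complete are they (full provirus, solo LTR, paired solo LTR,
atypical duplication, or truncated assembly segment), when did each
insert, which copies recombined with each other, which loci are shared
across individuals or species, and how do the copies relate
phylogenetically. `ervmine` implements that pipeline as composable,
deterministic R functions for people studying ERV/transposable-element
biology at desk scale.

The core quantitative tool is the LTR molecular clock. The two LTRs of a
provirus are identical at integration and diverge neutrally afterwards,
so the insertion age is

    T = K / (2 r)

where `K` is the Kimura two-parameter (K2P) distance between the LTRs,

    K = 1/2 ln( 1 / (1 − 2P − Q) ) + 1/4 ln( 1 / (1 − 2Q) ),

`P` and `Q` the transition and transversion proportions, and `r` the
per-site yearly substitution rate (default 2.3 × 10⁻⁹, with a
[2.0, 2.5] × 10⁻⁹ interval for age bounds). Around it sit: a native
seed-and-extend homology miner with 50% identity / 50% coverage screening
modes and multi-query locus merging; 4-nt target-site-duplication
signature extraction; projection-based gene/peptide annotation with a 25%
identity cutoff, peptide rescue and ORF scanning; a five-class structural
taxonomy; MaxChi/Chimaera/RDP-style recombination screens with a
consensus removal rule; orthologous-locus matching by flank identity;
Fisher exact count comparisons with Bonferroni correction; and
neighbor-joining phylogenies on K2P distances with bootstrap support,
midpoint rooting and monophyly tests.

## Worked example

Simulate a small host pedigree (two domestic-cat-like individuals, a
black-footed-cat-like and a jungle-cat-like tip; 300 kb scaffolds), then
mine, annotate, date, screen and compare — all from one seed:

```r
library(ervmine)

cfg <- pipeline_config(
  seed = 3,
  sim = sim_config(seed = 3, background_length = 300000,
                   endogenization_rate = 2,
                   tree = list(topology = "felis", chaus_split = 2,
                               nigripes_split = 1.5, catus_split = 0.1,
                               n_catus = 2)),
  bootstrap_B = 20)
res <- run_pipeline(cfg)

res$report$class_counts
#>          catus_1 catus_2 chaus nigripes
#> solo_ltr       0       0     2        0
#> typical        4       4     0        4

res$report$dating_summary
#> $n_dated
#> [1] 12
#> $median_T
#> [1] 1092049
#> $pct_identical_ltrs
#> [1] 0

head(res$dating[, c("locus_id", "K", "n_sites", "T_years", "identical_ltrs")])
#>                     locus_id           K n_sites   T_years identical_ltrs
#> nigripes1 nigripes_locus_001 0.003344494     600  727063.9          FALSE
#> nigripes2 nigripes_locus_002 0.011764320     600 2557460.8          FALSE
#> nigripes3 nigripes_locus_003 0.008391544     600 1824248.7          FALSE
#> nigripes4 nigripes_locus_004 0.001669451     600  362924.1          FALSE
#> catus_11   catus_1_locus_001 0.006702353     600 1457033.4          FALSE
#> catus_12   catus_1_locus_002 0.010103315     598 2196372.8          FALSE
```

Each dated row is one typical copy: `K` is the LTR-pair K2P distance over
`n_sites` comparable columns, and `T_years = K/(2r)` its point age (here
0.36–2.6 My — recent insertions, as expected for copies drawn on this
pedigree). Because the input was simulated, the run can be scored against
truth:

```r
ev <- evaluate_against_truth(res)
ev$confusion
#>           called
#> truth      solo_ltr typical
#>   solo_ltr        2       0
#>   typical         0      12
c(sensitivity = ev$sensitivity, precision = ev$precision)
#> sensitivity   precision
#>           1           1
```

Every mined locus matches an implanted copy within 50 bp and every copy
is classified correctly. Real genomes enter the same pipeline via
`pipeline_config(sim = NULL, genome_fastas = c(ind1 = "ind1.fasta", ...))`
plus a `provirus_reference` built from your query provirus and feature
table.

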