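---
title: "ervmine: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ervmine: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervmine)
```

# Scope

`ervmine` characterizes endogenous retrovirus (ERV) insertions in host
genome assemblies: it mines proviral loci by native homology search,
detects LTR pairs and target-site duplications (TSDs), annotates genes and
peptides, assigns each copy to a five-class structural taxonomy, dates
insertions from LTR divergence, screens for inter-copy recombination,
matches orthologous loci across genomes, runs exact count comparisons, and
builds distance-based phylogenies. A provirus-evolution simulator with
machine-readable ground truth makes every stage benchmarkable without
external assemblies. The motivating system is the endogenous feline
leukemia virus (enFeLV) of the *Felis* genus, and defaults throughout are
chosen for that regime: recent insertions (≤ ~3.5 My), low divergence,
4-nt TSDs.

# The simulator

## Substitution model

Copies evolve neutrally under the Kimura two-parameter (K80) model with
total rate `r` (default 2.3e-9 substitutions/site/year, the domestic-cat
germline rate commonly used for LTR dating) and transition/transversion
rate ratio `kappa` (default 2, a typical mammalian nuclear value). Rather
than event-by-event simulation, each site is resolved with the exact
closed-form K80 transition probabilities

$$P_{ts}(t) = \tfrac14 + \tfrac14 e^{-4\beta t} - \tfrac12 e^{-2(\alpha+\beta)t},
\qquad
P_{tv}(t) = \tfrac12 - \tfrac12 e^{-4\beta t},$$

with $\alpha + 2\beta = r$ and $\alpha/\beta = \kappa$. This is
distributionally identical to simulating the continuous-time chain and
vectorizes over sites. Because the generating process is exactly the model
the downstream K2P estimator assumes, dating recovery is a true
parameter-recovery test.

## Host pedigree, inheritance and divergence

The default pedigree has five tips: one early-splitting lineage (oldest
split 2.0 My, matching the minimum divergence of the jungle cat within
*Felis*), one mid-splitting lineage (1.5 My, a plausible black-footed-cat
split), and three conspecific individuals splitting at 0.1 My. Insertions
arrive as a Poisson process per branch (default 2 events/branch/My, which
yields copy counts per genome of the same order as real enFeLV loads at
desk scale) and are inherited by all tip descendants of their branch. An
optional introgression edge transfers all copies present in the donor
lineage at the transfer time into the recipient subtree.

Host divergence uses a **star approximation**: each individual's
background receives independent substitutions at half the configured
pairwise divergence (default 0.5%, a within-genus scale). Element
instances are evolved **independently per carrier** for the copy's full
age: shared loci therefore show per-individual divergence (and can date
slightly differently in different carriers, as real shared loci do), at
the cost of discarding substitutions shared on internal branches. TSD
copies evolve with the copy's age, so an age-0 insertion always shows a
perfect 4-mer signature; the test suite relies on this.

## Structural events

Per copy: LTR–LTR ejection with per-My hazard 0.3 (chosen so roughly half
of copies of a few-My age collapse, matching the observed solo-LTR
fraction of about half of all copies), leaving one LTR (solo) or — with
probability `paired_solo_frac` = 0.1 — both LTRs (paired solo; the class
exists in the taxonomy but no config parameter for it was otherwise
defined, so this knob is the package's own addition); otherwise an
internal duplication with probability 0.03 (the atypical architecture:
the internal region repeated around an LTR-like spacer) or one internal
deletion with probability 0.3, sizes log-uniform on [50, 3000] bp so that
deletions > 1000 nt occur regularly. Recombination replaces a structurally
intact copy by a two-parent mosaic at a uniform breakpoint with
probability 0.05. End-truncation (class `incomplete_segment`) is produced
on request by clipping the element at a scaffold boundary.

What the simulator does **not** emulate: repeats and low-complexity
background (backgrounds are iid nucleotides, which isolates miner
behavior), selection on copies, rate heterogeneity across sites, indel
micro-evolution (the mutation model is substitution-only), and realistic
chromosome structure. Passing benchmarks on this generator therefore
demonstrates algorithmic correctness under the stated model, not
performance on repeat-rich real assemblies.

# Mining

Searching is native seed-and-extend: exact k-mer seeding (k = 11) on an
indexed genome, ungapped X-drop extension (match +1, mismatch −2, X-drop
20), then chaining of colinear HSPs whose diagonals drift by at most the
band width (50) across gaps of at most 200 bp, penalized with the
affine-gap costs (−5 open, −2 extend). Chaining takes the place of a
banded gapped-extension DP: it bridges short indels identically in effect,
and under the substitution-only mutation model gapped DP adds nothing.
E-value statistics are deliberately absent — filtering is on identity (host-range
screening, ≥ 50%) or per-query coverage (locus mining, ≥ 50%), the two
printed cutoffs.

Multiple queries (LTR, *gag*, *pol*, *env*, full provirus) are searched
separately, filtered on their own coverage (so a solo LTR survives via the
LTR query), and merged into loci when subject intervals lie within
`max_gap` = 2000 bp — wide enough to tolerate internal deletions,
narrow enough to separate neighboring copies. Flanks (default 16 kb)
are clipped at scaffold ends and flagged. Coordinates are 0-based
half-open internally and in BED output; GFF3 output is 1-based inclusive.

# Annotation and classification

Each element is globally aligned once to the reference provirus and
projected onto reference coordinates. Feature identity is defined as
**identical columns / reference feature length**, so a fully deleted gene
scores near zero and the 25% emission cutoff behaves as a
presence/absence detector; a gene failing the cutoff is still emitted,
flagged `rescued`, when one of its peptides passes (an automated version
of what is otherwise a manual curation step — reproducibility requires
removing the human from the loop). Annotations are trimmed by dropping
terminal columns until a 20-column window reaches 50% identity, a
deterministic analog of trimming to high-identity regions.

LTR detection is greedy best-first local alignment of the reference LTR
(≥ 70% identity, ≥ 50% of LTR length; both configurable — the source
analyses fix no threshold here). Classification order: clipped at a
scaffold end → `incomplete_segment`; one LTR, no genes → `solo_ltr`; ≥ 2
LTRs closer than 200 bp with no genes → `paired_solo_ltr`; an LTR pair
with genes in reference order (whole-gene deletions allowed — "typical"
encompasses complete and reduced copies) → `typical`; anything else →
`atypical`. The 200 bp paired-solo gap and the decision that `typical`
tolerates missing genes are package decisions, exposed as options, since
the class definitions leave both open.

ORF scanning translates each annotated gene in the reference frame from
the projected row; `intact_orf` means no internal stop, and deletions
over 1000 nt are flagged even when the residual frame stays open (an
in-frame deletion truncates the peptide without stopping translation).

# Dating

Insertion age is `T = K/(2r)`: the two LTRs of a provirus are identical at
integration and diverge independently afterwards. K is the K2P distance
over non-gap, non-N columns of a global LTR-pair alignment,

$$K = \tfrac12 \ln\frac{1}{1-2P-Q} + \tfrac14 \ln\frac{1}{1-2Q}.$$

`K = 0` is reported as `identical_ltrs` — an age lower bound of zero, not
a precise date. Saturation (`1-2P-Q ≤ 0` or `1-2Q ≤ 0`) is flagged and
propagated, never patched with a simpler model: the method is only
trustworthy for recent, unsaturated LTRs, and silently substituting a
Jukes–Cantor fallback would hide that. The rate interval
[2.0e-9, 2.5e-9] gives `T_low`/`T_high` bounds (larger rate, younger
bound).

# Recombination screening

Three triplet scans are implemented natively: MaxChi (max chi-square
contrast of pair match counts in windows of `w` = 30 variable sites around
a sliding breakpoint), a Chimaera variant (same statistic on the
candidate's match vector restricted to parent-informative sites), and an
RDP-style sliding-window identity scan (longest run of windows whose
locally closest parent differs from the globally closest). All p-values
are permutation-based (variable-site or column order, 200 draws by
default, seeded). Per method, p-values are Bonferroni-corrected over the
scans that method performed; a copy flagged by `min_methods` methods is
removed from phylogeny input. The default is 2 of the 3 implemented
methods — proportionally equivalent to the published 3-of-7 rule — with
3-of-3 available to mirror that rule verbatim. Breakpoint polishing and
disentangling of overlapping events are out of scope; overlapping calls
are reported raw.

# Comparative statistics

Orthologous loci are matched by global alignment of the flanks adjacent to
the element (default: 600 bp per side evaluated, ≥ 90% identity on both
sides, ≥ 500 bp available per side), joined by single linkage. Copies
sharing only a 4-mer signature are reported as convergence coincidences
and never merged — the same-signature/different-locus distinction is an
observable of interest, not noise. Count tables (classes × genomes; gene
presence over nonrecombinant typical copies; peptide presence per
polypeptide) feed two-sided Fisher exact tests computed by direct
hypergeometric enumeration (probability-mass criterion, ties included),
Bonferroni-corrected within each family, with the family size equal to
the number of tests actually run — the most conservative reading. The
exact 2×2 constructions are package decisions (the comparisons' printed
descriptions do not fix them); they are logged in the output tables.

# Phylogenetics

A reference-projected multiple alignment (each copy globally aligned to
the reference; insertions relative to the reference dropped and counted)
replaces progressive MSA: it is deterministic, fast, and accurate at the
low within-lineage divergences involved (projection-induced distance error
is bounded by an oracle comparison in the tests). Trees are
neighbor-joining on pairwise K2P distances — maximum-likelihood inference,
model selection and topology tests are explicitly out of scope; NJ is an
adequate stand-in at high sequence similarity. Negative NJ branch lengths
are clamped to zero and counted. Support is nonparametric bootstrap over
alignment columns; rooting is midpoint; monophyly is tested on the rooted
tree. Per-gene trees are slices of the projected alignment at annotated
reference gene intervals, and gene-vs-genome topology differences are
reported descriptively as shared/unique bipartitions.

# Numerical and reproducibility choices

* All randomness flows from a single seed, fanned out into named
  per-stage substreams; identical config + seed give byte-identical FASTA
  and truth tables.
* Alignment tie-breaking is delegated to a deterministic pairwise aligner;
  NJ ties resolve by tip order, which is fixed by locus naming.
* Saturated K2P pairs make a distance matrix unusable for NJ; the matrix
  reports NA rather than imputing. (Bootstrap replicates cap NA at twice
  the largest finite distance, logged, since column resampling can starve
  a pair of comparable sites.)
* Scenario configs are written as YAML; truth tables as TSV (0-based
  half-open) and GFF3 (1-based).
* Benchmark problem sizes (3 × 1 Mb mining genomes, 30-copy
  classification benchmark, 200 LTR pairs, 500 clonal triplets, 100
  single-origin replicates) are the package's benchmark conditions;
  they keep the full suite in the minutes range on a laptop CPU.

# Known limitations

* The miner is tuned for low-divergence, repeat-free backgrounds; on real
  repeat-rich assemblies it would need masking and E-value control, both
  out of scope.
* The empirical fraction of identical-LTR pairs at old ages is a rare
  event (per-pair probability ~6e-5 at 3.5 My); monotonicity checks on it
  therefore allow one-pair Monte-Carlo slack.
* Per-carrier independent element evolution overstates divergence between
  carriers of old shared loci by omitting shared internal-branch
  substitutions; flank-based ortholog matching is unaffected.
* The recombination consensus uses 3 methods, not 7; per-copy method
  counts from the full RDP4 battery are not reproducible, only the
  removal semantics.
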