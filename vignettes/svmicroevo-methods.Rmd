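---
title: "Methods: coverage-based SV detection and its downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based SV detection and its downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmicroevo)
```

## The problem

Large copy-number changes — deletions and duplications of two kilobases
and more — are a major source of gene loss and gain between natural
isolates of a species.  `svmicroevo` implements a complete desk-scale
analysis of such variants in resequenced inbred nematode strains: it
calls them from differential read coverage against a reference control,
polarizes them into derived events using an outgroup genome, and
quantifies their consequences for gene expression, duplicate-copy usage,
homology classes and gene families.  Because the original sequencing
data are not required, every stage is driven and scored by a seeded
simulator with planted ground truth.

## The coverage model and the exact conditional test

Reads falling into a genomic window are modelled as Poisson: with mean
coverage $d$, window width $w$ and read length $r$, the expected count
is $dw/r$.  For a window with counts $x$ (control) and $y$ (test strain)
and library totals $N_x$, $N_y$, conditioning on the sum $n = x + y$
removes the nuisance rates and leaves

$$ y \mid n \;\sim\; \mathrm{Binomial}\!\left(n,\; q\right),
   \qquad q = \frac{N_y}{N_x + N_y}, $$

which `window_test()` evaluates exactly.  Two-sided p-values use the
minimum-likelihood convention (the sum of all outcome probabilities not
exceeding the observed one), the same rule as `stats::binom.test`; it is
deterministic and reproducible against an enumeration oracle, which is
how the test suite verifies it to $10^{-12}$ for all $n \le 200$.

The reported effect size is the log2 fold change
$\log_2\frac{(y + 0.5)/N_y}{(x + 0.5)/N_x}$.  The pseudocount of 0.5
only keeps the ratio finite at zero coverage; it never enters the
p-value.

Windows slide by half a window by default, and the default window of
2 kb gives an expected control count of 320 at 16X coverage with 100 bp
reads — comfortably inside the regime where the conditional binomial is
well behaved.  Windows passing a per-strain, per-type threshold policy
(p-value cutoff plus a signed fold-change cutoff) are merged when they
overlap or are bookended; a single non-significant window breaks a run;
merged spans under 2 kb are discarded.  The four published policy pairs
for the original strains ship as `paper_threshold_policies()`.

## Threshold calibration

The original analysis chose its cutoffs from a receiver operating
characteristic over manually curated calls.  `calibrate_and_call()`
formalizes that step: candidate calls at permissive thresholds are
labelled against truth (or curation), `roc_curve()` scans a cutoff grid,
and `pick_operating_point()` returns the point with maximal TPR subject
to a false-positive-rate cap (ties resolved towards smaller FPR, then a
more stringent p cutoff).  This is a deliberate formalization of a
subjective published choice: it makes the operating point reproducible
and testable, at the cost of not reproducing the original cutoffs
exactly.

## Polarization by perfect collinearity

With an outgroup at hand, a deletion or duplication found inside a
region whose gene order is perfectly conserved between reference and
outgroup can be read as a derived event.  The gene-order alignment
regime of interest uses gap and mismatch penalties so punishing that any
break ends an alignment; under that regime scored alignment reduces to
exact maximal-run detection, which is what `collinear_blocks()`
implements: maximal runs of ortholog pairs whose indices advance by +1
in both genomes, or by −1 in the outgroup throughout (inversions count
as collinear by default, switchable via `allow_reversed`).  Runs shorter
than two genes are dropped.  Each gene belongs to at most one run, so
coverage-1 holds by construction.  `polarize_svs()` flags a call as
polarized when it overlaps the union of block spans by at least one
base, the literal reading of the published "overlapped" rule; a
fractional-overlap knob is provided for stricter use.

## Expression consequences

Gene spans run from first to last exon.  A gene counts as deleted or
duplicated only when its whole span lies inside one call (`complete`
mode) — a conservative rule that tolerates the imprecise breakpoints of
coverage-based calls; `half` mode additionally marks genes whose span is
at least half covered by deletions.  Expression is consumed as FPKM and
binned into `{zero, (0,1], (1,10], (10,100], >100}`; the published
account fixes only "orders of magnitude" and the zero class, so the
interior edges are a package choice, overridable via `breaks`.
"Expressed" means FPKM strictly greater than zero, no epsilon.

Three tests mirror the published contrasts: `loss_of_expression_test()`
(two-sided Fisher's exact test on zero/nonzero expression for affected
versus background genes), `dosage_fold_change_test()` (two-sided
Wilcoxon rank-sum on log2 test/reference ratios of duplicated versus
unaffected genes, restricted to genes expressed in both samples) and
`transcriptome_correlation()` (Spearman).

## Allele-biased expression of duplicate copies

In a strain inbred for many generations, heterozygous variant calls are
better explained as sites segregating between two collapsed duplicate
copies than as true heterozygosity.  Sites are kept when the variant
quality is at least 20, the heterozygosity support (FQ-like) score is
strictly positive, and both DNA and RNA pileups reach 10 reads.  The
minor allele is decided once, from the DNA counts (smaller count, ties
to the lexicographically smaller nucleotide), and that same allele's
frequency is compared between DNA and RNA per gene with a two-sample
rank-sum test, Benjamini–Hochberg corrected across genes.

Two numerical choices deserve a note.  First, the published method
description leaves paired-versus-two-sample ambiguous; with the typical
2–5 sites per gene a paired signed-rank test cannot reach p < 0.05, yet
twelve significant genes were reported, so the two-sample reading is the
default (`paired = TRUE` is available).  Second, for up to 20 sites in
total the p-value is an exact permutation enumeration (doubled smaller
tail over all group assignments, midranks for ties); beyond that the
normal approximation with ties correction takes over.  One property of
the published design is worth knowing: because the minor allele is
selected as the smaller DNA count, DNA frequencies are folded below 0.5
while null RNA frequencies are symmetric around it, so raw per-gene
p-values are mildly anti-conservative under the null.  The
Benjamini–Hochberg step absorbs this at the defaults (the acceptance
suite verifies flagged fractions under a pure null), but single-gene
raw p-values should not be over-read.

## Homology classes and enrichment

From tabular protein hits (e-value < 0.001, bitscore-ordered), genes
are classified into five exhaustive classes: one-to-one orthologs with
a designated species (reciprocal best hits where a bitscore tie breaks
reciprocity and neither member has an inparalog), one-to-many
singletons with homologs, conserved genes with paralogs, orphan
singletons and orphans with paralogs.  An intra-species pair is an
inparalog pair when its bitscore reaches either member's best
inter-species bitscore — the permissive `>=` reading, with `strict`
available — and genes without inter-species hits treat that bound as
−∞.  Paralogy is connected components of the intra-species subgraph.
The multi-species panel of the original study reduces here to focal
versus pooled others plus the designated ortholog species.

Enrichment statistics are deliberately classical: per homology class a
two-sided Fisher's exact test of class membership against SV status;
per PFAM-defined family an upper-tail hypergeometric with
Benjamini–Hochberg across families (a seeded label-permutation
alternative is provided since the published "random expectation" is not
named); and for nucleotide diversity a two-sided Wilcoxon rank-sum
between 100 kb windows with and without SV overlap.  A gene carrying
several domains counts once per domain, so family tests are not
independent — the FDR correction is pragmatic, not exact.

## What the simulator states, and what it does not

The generator's defaults are the stated world of the analysis: a 16X
control against a 12X test library of 100 bp reads; 50 deletions and 30
duplications per run, uniform on 2–75 kb, mutually disjoint; homozygous
events only (copy factors 0 and 2 — the strains are inbred lines);
Poisson window counts without overdispersion (a negative-binomial
`dispersion` knob exists because real coverage is overdispersed);
log-normal baseline FPKM (meanlog log 10, sdlog 1.2) with 15%
multiplicative noise, since no effect-size distribution is published;
deletion forcing test FPKM to zero and duplication either doubling it
(`additive_dosage`) or leaving it unchanged (`silent_copy`, the
default, matching the observed absence of dosage response); segregating
sites at Binomial(depth, 1/2) DNA counts with the silent copy tied to
the DNA-minor allele; and a ten-fold median diversity contrast between
windows with and without SVs.

The simulator does not model GC or mappability bias, sequencing error,
partial-gene breakpoints within exons, diploid heterozygosity, or
read-level data at all.  A green truth-recovery test therefore
establishes that the algorithms implement their contracts on data obeying
the stated model — not that the model captures every artefact of real
resequencing runs (the differential design against a control removes
assembly artefacts, which is why the plain Poisson world is the right
null here).

## Degenerate inputs and tie-breaks

Windows with zero total count get p = 1, fold change 0 and a `no-data`
flag.  Multiallelic variant records are skipped (the bias model is
two-allele).  Sites lacking an FQ-like score are excluded by the site
filter.  Empty gene sets, single-label ROC inputs and empty diversity
strata raise errors rather than returning silent NAs.  All interval
arithmetic is 0-based half-open; `[0,10)` and `[10,20)` do not overlap.

## Known limitations

Breakpoints inherit window resolution; no split-read refinement is
attempted.  The ROC formalization will not reproduce the original
hand-picked cutoffs.  The homology classifier is graph-based and
tree-blind.  The acceptance suite runs the full stack only at desk
scale (10 Mb genomes); the published genome-scale counts are not
reproducible without the original data and are not targeted.
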