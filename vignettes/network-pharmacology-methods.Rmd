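---
title: "Methods: network-pharmacology target identification with netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology target identification with netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

# The analysis netpharm implements

Multi-herb traditional-medicine formulas act through many chemical
ingredients hitting many protein targets at once. Network pharmacology
turns that into a testable computational procedure:

1. **ADME screening.** Each herb's catalogued ingredients carry an oral
   bioavailability (OB, percent) and a drug-likeness score (DL, unitless
   in $[0,1]$). An ingredient is retained when $\mathrm{OB} \ge 30$ and
   $\mathrm{DL} \ge 0.18$, the TCMSP-convention cutoffs; both
   comparisons are inclusive. Herbs on an exemption list (by default the
   mineral herb coded ML, whose constituents are inorganic salts with
   intrinsically low DL) bypass *both* criteria — the screening rule was
   designed for organic small molecules and would discard such herbs
   wholesale.
2. **Tripartite network.** Retained ingredients and their predicted gene
   targets form a typed herb → ingredient → target graph. The herb-target
   projection (a target belongs to a herb iff some ingredient of that
   herb hits it) yields each target's *herb-degree*; the exact-mode
   shared-target histogram bins targets by herb-degree and partitions the
   target universe.
3. **Three gene sets.** (A) disease genes from a relevance-scored
   database list, retained when score $> 5$ (strict, matching the
   database's convention); (B) differentially expressed genes between two
   sample groups, called at raw $P < 0.05$; (C) the network's target
   universe. The candidate-target list is the triple intersection
   $A \cap B \cap C$.
4. **Over-representation.** Each annotation term is tested with the
   upper-tail hypergeometric probability
   $$P \;=\; 1 - \sum_{i=0}^{m-1}
     \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},$$
   the probability of at least the observed overlap $m$ when $n$ query
   genes are drawn from a universe of $N$ annotated genes of which $M$
   carry the term. Benjamini–Hochberg FDR is applied across tested terms
   and significance is $\mathrm{FDR} \le 0.05$ (inclusive). The test is
   run under two backgrounds — all genes, and the $A \cap B$
   intersection — and a consistency table records whether each term is
   significant under both. The restricted background asks whether the
   enrichment is driven by the candidate genes themselves rather than by
   the composition of the wider universe; no ordering between the two
   p-values is implied.
5. **GSEA.** Genes are ranked by a two-group metric (signal-to-noise by
   default); each gene set's enrichment score is the signed
   maximum-magnitude excursion of the weighted Kolmogorov–Smirnov running
   sum (hits add $|r_i|^p$ normalised over hits, misses subtract
   $1/(N-N_h)$); significance comes from phenotype-label permutation with
   NES normalisation and a pooled-null FDR.

# Statistical and numerical choices

**DEG test.** The default is Welch's $t$ per gene with the significant
set defined by *raw* $P < 0.05$ — the convention of GEO2R-style quick
calls. Because GEO2R actually fits limma underneath, a
`method = "moderated_t"` flag runs limma's empirical-Bayes moderated $t$
behind the same interface; the two can disagree at small $n$, which is
why the choice is exposed rather than hidden. `use_adjusted = TRUE`
switches the significance criterion to BH-adjusted p. Genes with zero
variance in both groups are untestable: they are flagged degenerate and
assigned $p = 1$ rather than raising an error, so one flat probe cannot
abort a run. Probe-level matrices collapse to genes by keeping the
smallest-p probe per gene.

**Annotation universe.** $N$ counts only background genes annotated to
at least one term of the collection; unannotated genes can never
contribute to an overlap and would only dilute $N$. Terms are tested
when they intersect the query ($m \ge 1$) and have at least 3
in-universe members (`min_term_size`); smaller terms produce
uninformative p-values that only burden the FDR correction.

**Hypergeometric evaluation.** The printed sum is evaluated through the
hypergeometric survival function (`stats::phyper`), which computes the
same upper tail in log-space-stable form; the test suite checks it
against an exact integer-arithmetic enumeration of the formula for every
$(N \le 40, n, M, m)$ to $10^{-12}$. $m = 0$ is the empty sum and
returns exactly 1.

**GSEA conventions.** Phenotype permutation (not gene-set permutation)
is the null, the standard choice when each group has enough samples to
permute; with tiny samples the full set of distinct labelings is
enumerated instead and the result flagged exhaustive. Nominal p uses the
pseudo-count convention $(b+1)/(n_{\mathrm{same\,sign}}+1)$ with the
null restricted to permutation scores of the observed sign, so p is
never exactly zero and stays calibrated when the sign split is uneven.
NES divides each score by the mean |null ES| of its sign for its set;
the FDR q compares the pooled signed null-NES tail with the observed
NES tail, capped at 1. The signal-to-noise metric floors each group SD
at $0.2 \times |\mathrm{mean}|$ (0.2 when the mean is 0), the reference
implementation's guard against vanishing denominators. Two
deterministic tie rules make runs bit-reproducible: equal metrics order
by gene symbol, and an exact tie between the positive and negative
extremes of the running sum (possible in the unweighted walk) resolves
to the positive side, with a $10^{-9}$ tolerance so floating-point
accumulation order cannot flip the sign between equivalent
implementations. If every hit has metric exactly 0 the weighted
increments are undefined and equal weights (the $p = 0$ walk) are used.

**Symbols.** Gene symbols are uppercased and whitespace-stripped at
every ingestion point so the three sources agree in set operations. No
alias resolution is attempted — symbols from different nomenclature
eras will not be merged, a documented limitation of any offline
pipeline.

**Duplicates.** Duplicate (herb, ingredient) rows are rejected at load
rather than silently deduplicated — provenance tables should be clean
and a silent merge would hide upstream errors. Duplicate disease-gene
records collapse to the maximum relevance score, with a message.

# The synthetic-data generators

Every pipeline input can be generated with a seed and a truth record, so
each stage is testable end to end without touching TCMSP, GeneCards, GEO
or MSigDB. One master seed fans out to per-generator sub-seeds through a
fixed-offset splitting rule (`seed + 104729 * k` reduced modulo the
integer maximum, one offset per generator), so changing one generator's
draws never perturbs another's.

- `gen_herb_table()` decides each row's pass/fail status up-front
  (Bernoulli with the requested passing fraction, or exact per-herb
  counts) and then draws OB and DL from uniform mixtures on the passing
  or failing side of the 30 / 0.18 cutoffs. Failing draws stop just
  short of the thresholds so that rounding to table precision can never
  promote a failing row. Exempt herbs get the inorganic-compound
  profile: low DL, any OB.
- `gen_target_map()` plants an exact shared-target histogram: a profile
  entry $(k, c)$ creates $c$ targets assigned to exactly $k$ distinct
  herbs. With a per-herb quota the $k$ herbs are chosen
  largest-remaining-demand first (processing targets in decreasing $k$),
  which realises an exact per-herb degree sequence when one is feasible;
  without a quota, herbs are sampled uniformly. Within a herb, targets
  are spread shuffled-round-robin over its ingredients so every
  ingredient is covered whenever the herb has at least as many target
  links as ingredients.
- `gen_expression()` draws i.i.d. Normal(8, 1) log2 intensities (so the
  within-group SD is 1) and mean-shifts each planted DEG in group 2 by
  the requested number of SDs.
- `gen_gene_sets()` samples random terms uniformly from a supplied
  universe and appends one planted term with exactly the given members.

`gen_full_study()` assembles a complete miniature study whose defaults
*are* the canonical conditions of the motivating ten-herb formula
analysis: per-herb retained ingredient counts (23, 6, 9, 38, 3, 3, 8, 6,
5, 4 — 105 in all, the ML herb retained purely through the exemption),
an 806-target universe whose per-herb target counts are (246, 198, 215,
115, 69, 32, 223, 358, 149, 182), the shared-target histogram bins 4–9 =
(69, 65, 30, 23, 9, 2), and an 81-gene candidate overlap. The histogram
below bin 4 is not pinned down by those conditions; the remaining 608
targets must carry 755 herb-links, and the generator splits them
461 / 147 / 0 over degrees 1 / 2 / 3 — the simplest decreasing-with-
degree split consistent with the per-herb totals.

Three structural guarantees make recovery exact rather than
probabilistic where exactness is asserted:

- disease genes $\cap$ targets is constructed to equal the planted
  81-gene overlap, and every overlap gene carries a 5-SD expression
  shift; with 10 samples per group the per-gene power at $P<0.05$ is
  $1 - 10^{-9}$, so the *computed* triple intersection equals the plant
  (false-positive DEGs cannot enter it because the other two sets
  already pin the intersection).
- the planted over-representation term holds 30 of the 81 candidates
  plus 10 genes outside every other set, so it dominates both
  backgrounds.
- the planted GSEA set is 30 *separate* genes given a coherent 1-SD
  up-shift — a subtle pathway-level signal, which is the regime GSEA is
  designed for. A coherent 5-SD set would be a poor plant: its members
  stay bimodal under label permutation, fattening its own permutation
  null and capping its NES. For the same reason the GSEA collection's
  null terms are drawn from genes with no planted effect: a "random"
  term containing strong DEGs is genuinely phenotype-associated, and a
  generator that planted such terms would be planting more than one
  enriched set.

**What the generators do not emulate:** gene-gene correlation,
array-specific noise and batch effects, probe redundancy, realistic
chemistry (no structures behind the OB/DL values), and real annotation
structure (terms are flat random sets; no GO DAG propagation). Passing
recovery tests on this synthetic data therefore demonstrates the
*machinery* — screening logic, graph arithmetic, tail probabilities,
permutation procedure — not performance on real microarray data, where
correlated genes widen null distributions and annotation overlap induces
dependent tests.

# Problem sizes and reproducibility

The shipped tests and the acceptance script run the full study at 3 000
genes, 10 + 10 samples, 50 random terms per collection and 1 000 GSEA
permutations — large enough that every planted structure is recovered
with a comfortable margin, small enough that the whole suite runs in
well under a minute on one core. The DEG calibration check uses a
1 000-gene null matrix, where three binomial SDs around the nominal 0.05
is a ±0.021 band. All randomness flows through explicit seeds; the same
seed reproduces every result bit for bit.

# Interpreting the dual-background wording

Protocols describing the restricted-background comparison sometimes read
as using *random subsets* of each background rather than the full sets.
The package implements full-set backgrounds as the default — that is the
statistically standard choice — and exposes `subsample_n` +
`subsample_seed` in `dual_background_enrich()` for the subsampling
reading, without asserting that either is what any particular published
analysis did.

# Known limitations

- No gene-identifier alias resolution; inputs must share a nomenclature.
- Gene-set collections are taken flat; no ontology propagation or
  pathway topology.
- The moderated-t option is limma's; at two samples per group neither
  test is reliable and the package refuses groups smaller than 2.
- Reported database-scale counts (disease-list sizes, DEG counts from a
  specific accession) depend on external snapshots and unstated analysis
  settings; the package reproduces the *procedure* and verifies it on
  planted data, not those snapshot-dependent numbers.
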