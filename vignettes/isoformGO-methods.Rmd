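---
title: "Isoform-specific GO annotation by expectation-maximization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform-specific GO annotation by expectation-maximization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoformGO)
```

## The problem

Gene Ontology (GO) annotations are overwhelmingly made at gene level,
yet most human genes produce several protein isoforms through
alternative splicing, and those isoforms can differ in enzymatic
activity, localization and interaction partners. isoformGO
redistributes a gene's GO annotations to its individual protein-coding
isoforms, so that downstream analyses (isoform-level over-representation,
differential-splicing interpretation) have a per-transcript functional
vocabulary to work with.

The method rests on three assumptions:

1. every GO term of a gene is a function of at least one of its
   isoforms (isoform function sets are subsets of the gene's);
2. the mean pairwise sequence-alignment score of two isoforms increases
   with the number of functions they share;
3. given their assigned terms, the alignment scores of distinct
   isoform pairs are independent.

## The model

Let $\phi$ be the binary isoform-by-term assignment matrix ($TI$), and
for a pair of isoforms $(i_j, i_k)$ let
$\tau_{ijk} = |\phi(i_j) \cap \phi(i_k)|$ be their shared-term count.
The standardized Smith-Waterman similarity of the pair is modelled as

$$S(i_j,i_k) = \beta_2\,\tau_{ijk}^2 + \beta_1\,\tau_{ijk} + \beta_0 +
  \varepsilon, \qquad \varepsilon \sim N(0, 1).$$

The noise standard deviation is fixed at 1 and never re-estimated
(scores are standardized, so the scale is absorbed by the
coefficients); `residual_normality_check()` reports a one-sample
Kolmogorov-Smirnov diagnostic against $N(0,1)$ but never gates a run.
With Gaussian unit-variance noise, maximizing the total log-likelihood
over $(\phi, \beta)$ is equivalent to minimizing the sum of squared
residuals, which the package optimizes by alternating:

* **E-step** — for fixed $\hat\beta$, a genetic algorithm searches the
  mutable bits of $\phi$ (an NP-complete combinatorial problem, hence
  the heuristic);
* **M-step** — for fixed $\hat\phi$, ordinary least squares on the
  design $[1, \tau, \tau^2]$ refits $\hat\beta$.

Quadratic degree is the package's (and the model's) default; the OLS
fit generalizes trivially but only degree 2 is exercised.

## Pipeline and initialization

Inputs: gene-level GAF annotations, the GO namespace structure (OBO),
protein FASTA keyed by transcript accession (version suffixes
stripped), an isoform-to-InterPro-domain table, and the InterPro2GO
mapping. Domain-derived GO terms absent from a gene's annotation set
are first merged into it, so the candidate universe is the combined
gene-level vocabulary.

Only *specific* terms — those annotating strictly fewer than 10% of
genes (`filter_specific_terms()`, strict inequality, so a term at
exactly 10% is excluded) — are assignable. For each isoform, candidate
cells are the specific terms of its gene in the active subontology; a
cell is *seeded* (initially set) when the term is additionally implied
by one of the isoform's own InterPro domains. Gene terms unrelated to
the isoform's domains start unassigned and are left to the search, so
isoform annotations never leave the gene's vocabulary.

Initial coefficients are fitted on the eligible pairs of one random
isoform subset, with $\tau$ taken from the seed assignment
(`initialize_beta()`). The subset defaults to `p / 200` isoforms with
a floor of 30 so that small corpora still produce enough pairs. Two
degenerate regimes are handled explicitly:

* a rank-deficient subset (fewer than three distinct $\tau$) is
  resampled with the next seed, up to 25 times;
* if every subset is rank-deficient — typical when the seed is very
  sparse and shared-term counts barely leave 0 — the initializer falls
  back to a linear fit, and in the last resort to
  $\beta_0 = \bar S$, $\beta_1 = \mathrm{sd}(S)$, $\beta_2 = 0$. The
  positive slope encodes assumption 2 directly and gives the first
  E-step a gradient; without it a constant model makes every
  assignment equally good and the EM cannot start.

## Alignment and normalization

Raw similarities are Smith-Waterman local alignment scores with
BLOSUM62, gap open 10 and gap extension 4 (a gap of length $L$ costs
$10 + 4L$) — the defaults of the alignment backend the package
delegates to. Selenocysteine (`U`) is scored as `X` because BLOSUM62
carries no `U` row. Raw scores are cached by unordered pair, so
repeated partitions never recompute an alignment.

Normalization is $y = \log_{10}(x + a)$ with $a = 0$ when all scores
are positive and $a = 10^{-6} - \min(x)$ otherwise, followed by a
z-score with the sample standard deviation. Standardization is
computed *within each mini-batch subset*: the objective only ever
compares scores inside one subset, and per-batch standardization keeps
every batch on the $N(\mu, 1)$ scale the likelihood assumes. (Global
standardization is a configuration away — supply a precomputed score
table — but per-subset is the default and the tested path.) Same-gene
pairs are scored exactly like cross-gene pairs.

## The genetic algorithm

One chromosome is the vector of mutable candidate cells of one subset,
laid out isoform-by-isoform with terms in GO-id order. Fitness is the
negated subset sum of squared residuals, recomputed from the decoded
bits plus any frozen bits. Operators:

* initial population: the current assignment plus mutated copies
  (per-bit flip probability 0.1);
* selection: roulette with probability proportional to the
  individual's rank in increasing fitness order;
* uniform crossover with probability 0.8 (the crossover operator type
  is the package's choice), otherwise parents are copied;
* per-bit mutation at 0.1 after crossover;
* single-individual elitism, so the best fitness trace is
  non-decreasing and the result is never worse than the input
  assignment.

Population size and generation count default to 50/50. Ties in
`brute_force_min_ssr()` (the exhaustive test oracle, capped at 20
bits) break toward the lexicographically smallest bitstring; GA ties
resolve to the first-found individual.

## Mini-batch EM and convergence

Each E-iteration draws a fresh uniform partition of the isoforms into
`K` subsets (default 200; sizes deliberately not equalized). Within a
subset, eligible pairs are those whose genes share at least one GO
term of the combined gene-level map (same-gene pairs qualify whenever
the gene is annotated). After the GA updates the subset's bits, the
iteration accumulates

$$\sigma_i = \sum_{\text{subsets}} \lambda / \lambda^*,$$

the sum over subsets of the mean pair log-likelihood ($\lambda$ the
subset log-likelihood, $\lambda^*$ its pair count) — a quantity
comparable across differently sized partitions. Subsets with fewer
than two isoforms, no eligible pairs, or (on the sequence pathway)
fewer than two scorable pairs contribute 0. $\sigma_0$ is computed on
the seed assignment over one initial partition so the first change is
defined.

Convergence of the E-phase is declared when the cumulative change over
a window of 25 iterations is below 1/3. "Change" is read as the signed
telescoped difference $\sigma_{\text{last}} - \sigma_{\text{last}-25}$
(an absolute-value variant is selectable); the signed reading means a
plateau or decline converges, which matches the trace's behaviour
under resampled partitions. The M-step then refits $\beta$ on the
union of pairs from the final E-pass partition — the mini-batch
analogue of a full refit. When that pass's shared-term counts are
collapsed (fewer than three distinct values), the M-step fits the
highest identifiable degree instead of keeping a stale model: a slope
correction from a degenerate pass is frequently what allows the next
E-phase to re-diversify the counts. The outer loop stops when the
relative coefficient change $\max |\Delta\beta| / (1 + |\beta|)$ drops
below $10^{-4}$ or after 10 cycles.

Gene-term coverage (assumption 1) is *not* enforced during the search
— no enforcement mechanism is part of the model — but
`uncovered_gene_terms()` reports the gene terms left unassigned after
a run.

## Subontology schedule

The three GO subontologies run separately, in the order MF, BP, CC.
For CC, the finished BP assignment is added to the initial state as
*frozen* bits: they raise shared-term counts (similar sequences share
MF/BP terms more readily than CC terms, so the BP signal sharpens pair
similarity) but are excluded from the GA search and stripped from the
CC output. Freezing is the default because re-optimizing the BP bits
inside the CC run would let the CC objective corrupt the finished BP
assignment; a switch disables the surrogate scheme entirely.

## Synthetic corpora

`simulate_universe()` generates genes, isoforms, gene term sets and a
planted assignment (each gene term planted on each isoform with
probability `assign_prob`, then repaired so every gene term covers at
least one isoform — the planted truth satisfies assumption 1 even
though the search does not enforce it). Two score pathways decouple
the stages:

* `simulate_scores()` draws standardized scores directly from the
  quadratic model at the planted $\tau$ (noise sd 1, or 0 for the
  noiseless pathway), bypassing alignment;
* `simulate_sequences()` realizes assumption 2 mechanically: each term
  gets a random amino-acid motif, and an isoform's sequence is the
  concatenation of its planted terms' motifs interleaved with
  per-isoform filler, so raw alignment scores rise with shared-term
  count.

`emit_corpus()` writes GAF/OBO/FASTA/TSV files that parse back into
the same structures, with one synthetic InterPro accession per term
and a configurable fraction of planted bits made domain-derivable
(the InterPro seeding rate).

What the generator does *not* emulate: realistic domain architectures,
GO graph structure beyond namespaces, annotation evidence codes,
genome-scale term-frequency distributions, or correlated noise between
pairs sharing an isoform (assumption 3 is built in). Passing tests
therefore demonstrate internal correctness and recovery under the
model's own assumptions, not performance on real annotation corpora.

## Problem sizes and test design

The packaged checks run at desk scale, chosen so that exhaustive
oracles remain feasible: recovery corpora of 20 genes x 4 isoforms
with 30 single-gene (hence specific) terms, 16 mini-batch subsets (so
a final-pass subset carries at most ~20 mutable bits and can be
verified against `brute_force_min_ssr()`), GA at 50x50, convergence
window 25 at threshold 1/3, and coefficient-recovery designs of 2,000
pairs with $\tau \in \{0..10\}$. With that last design the intercept's
OLS standard error is about 0.057, so single-draw recovery within
$\pm 0.1$ is a ~90% event; the tests assert recovery across ten fixed
seeds (mean error and a 8-of-10 majority) next to exact agreement with
the normal-equations solution.

## Known limitations

* The E-step is a heuristic for an NP-complete problem; optimality is
  only verified exhaustively at oracle scale.
* At desk scale with very sparse seeds, the EM can reach a
  self-consistent under-assigning fixed point: a too-steep initial
  slope makes the E-step remove shared terms, and the subsequent refit
  reproduces the slope. Some synthetic draws therefore end at their
  seed accuracy. Richer seeds (higher InterPro coverage) and larger
  corpora make this regime progressively less likely.
* Per-batch standardization means a pair's standardized score depends
  on its batch; scores are comparable within, not across, batches.
* Isoforms of genes with no specific terms keep empty candidate rows;
  they still align and anchor the $\tau = 0$ part of the fit but can
  receive no annotation.
* No GO-graph propagation is applied to assignments (annotations are
  taken and returned as given); information-content calculations
  propagate through is_a ancestors only when explicitly requested.
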