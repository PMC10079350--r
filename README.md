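# isoformGO

Most human genes express several protein isoforms, but GO annotation
is made almost exclusively at gene level, so every isoform of a gene
inherits the same functional profile. isoformGO redistributes a gene's
GO annotations to its individual protein-coding isoforms, producing a
per-transcript annotation suitable for isoform-level
over-representation analysis and for interpreting differential
splicing. It is aimed at transcriptomics practitioners who have
gene-level GAF annotations, isoform protein sequences and InterPro
domain calls, and want isoform-resolved GO terms without any
supervised training data.

## The model

Let $\phi$ be the binary isoform x GO-term assignment matrix and
$\tau_{jk} = |\phi(i_j) \cap \phi(i_k)|$ the number of terms shared by
isoforms $i_j, i_k$. Standardized Smith-Waterman similarity is
modelled as

$$S(i_j, i_k) = \beta_2 \tau_{jk}^2 + \beta_1 \tau_{jk} + \beta_0 +
\varepsilon,\qquad \varepsilon \sim N(0,1),$$

and the assignment and coefficients are estimated jointly by
maximizing the Gaussian likelihood — equivalently minimizing
$\sum (\hat S - S)^2$ — with an EM scheme:

* **E-step**: a genetic algorithm (rank selection, uniform crossover
  0.8, mutation 0.1, elitism) searches the binary assignment for fixed
  $\hat\beta$; the search runs per mini-batch over a random partition
  of the isoforms into subsets, with convergence declared when the
  change of the summed mean pair log-likelihood over a 25-iteration
  window falls below 1/3;
* **M-step**: ordinary least squares on $[1, \tau, \tau^2]$ refits
  $\hat\beta$ for the fixed assignment.

Candidates are restricted to each gene's *specific* terms (annotating
< 10% of genes), and the assignment is seeded from InterPro2GO: a cell
starts set when the isoform's own domains imply the term. The three
subontologies run separately (MF, BP, CC), with the finished BP
assignment carried into the CC run as frozen surrogate bits. See
`vignette("isoformGO-methods")` for the full account.

## Worked example

Everything below runs on a synthetic corpus with planted ground truth
— no downloads. The generator writes the same GAF/OBO/FASTA/TSV
formats the real pipeline reads.

```r
library(isoformGO)

truth <- simulate_universe(n_genes = 20, isoforms_per_gene = 4,
                           n_terms = 30, terms_per_gene = 2,
                           assign_prob = 0.5, seed = 7,
                           unique_gene_terms = TRUE)
scores <- simulate_scores(truth, beta = c(0.5, 0.2, 0.05),
                          seed = 3, noise_sd = 0)
paths <- emit_corpus(truth, tempfile("corpus"), seed_fraction = 0.3, seed = 5)

genes    <- read_gene_isoforms(paths$gene_isoforms)
tg       <- read_gene_annotations(paths$gaf)
specific <- filter_specific_terms(tg, threshold = 0.10)
am <- build_candidates(genes, tg,
                       read_isoform_domains(paths$domains),
                       read_interpro2go(paths$ipr2go),
                       specific, "MF", read_ontology(paths$obo))
am
#> assignment_matrix [MF]: 80 isoforms x 30 terms, 18 bits set (120 candidate, 0 frozen)

cfg <- em_config(subsets = 16, window = 25, max_e_iterations = 60,
                 ga = ga_params(50, 50), seed = 11, init_subset_size = 40)
res <- run_subontology(am, make_table_scorer(scores), cfg)
res$model
#> quadratic_model: mu(tau) = 0 tau^2 + 0.25 tau + 0.5  (sd = 1)

assignment_accuracy(am, truth$assignment)            # 0.675 (InterPro seed)
assignment_accuracy(res$assignment, truth$assignment) # 0.733 (after EM)
```

The candidate structure starts with 18 of 120 candidate cells set by
the InterPro seed (30% of the planted bits). After the EM run the
Hamming accuracy against the planted truth rises from 0.675 to 0.733,
and the refitted model reproduces the planted score increments
exactly on the shared-term counts present in the final pass
($\mu(0)=0.50$, $\mu(1)=0.75$ — the planted values). With sequences
instead of model-derived scores, pass
`make_sequence_scorer(read_protein_fasta(paths$fasta))`, or run all
three subontologies at once with `run_full()`. A command-line wrapper
lives at `inst/scripts/isoformgo-infer.R`.

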