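---
title: "Phenotype-driven variant prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-driven variant prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankvar)
```

# The problem

Given a patient's exome variants (a VCF) and a clinical description as HPO
terms, a diagnostic analyst must find the one gene — among the roughly a
thousand that carry candidate variants after basic filtration — that explains
the phenotype. `rankvar` implements a desk-scale version of this workflow:
variant filtration, phenotype-aware feature construction, a learned
per-mutation pathogenicity score, gene-level ranking, literature-evidence
lookup, and an evaluation harness, with a synthetic-cohort generator so the
whole pipeline is testable without any controlled-access data.

# The score model

## Rank-decay training labels

The ranker is trained as a regression, not a classifier. For each training
case the known causal mutation is a positive example with target exactly 1.
Negative ("decoy") examples come from reference gene prioritizers run on the
same case: the `n_decoys` (default 40) non-causal genes with the smallest
average external rank are selected, each represented by its most deleterious
mutation, and labelled

$$\mathrm{label}(m) = \gamma^{\,x - 1}, \qquad
  x = \frac{1}{|R_m|}\sum_{r \in R_m} \mathrm{Rank}(r, m),$$

where $R_m$ is the set of configured reference rankers that rank the gene of
mutation $m$ and $\gamma$ (default 0.99) is the decay factor. The label is 1
exactly at $x = 1$ and decays strictly with rank, so the network learns a
smooth preference rather than a hard boundary. The reference-ranker set is
configuration, not code: the construction is well defined with one, two or
three external tools, and a ranker that does not cover a gene is simply
excluded from the average.

Two details of decoy selection are deliberately annotation-only and
deterministic: "most deleterious mutation" of a decoy gene means the highest
mean of available predictor scores (ties broken by variant key), which avoids
any circularity with the model being trained; and ties in average rank break
by gene symbol so training sets are byte-stable.

## Features

Each mutation is described by 12 numeric features: direct phenotype
similarity between the patient's HPO terms and the diseases of the mutated
gene; the same similarity propagated one hop through the protein
interactome; a conservation score; a ClinVar code (pathogenic 1,
unknown/absent 0.5, benign 0); the maximum population allele frequency; the
six predictor scores (SIFT, PolyPhen2, MutationTaster, PrimateAI, DANN,
CADD); and `log1p` of the number of literature-mined mutation–disease
relations. Missing values are imputed (conservation 0, predictor scores 0.5,
frequency 0) and every imputation is recorded in a missingness mask, so
absence of evidence is visible and never silently favors or penalizes a
variant.

## Phenotype similarity

Term-to-term similarity is Resnik's measure: the information content (IC) of
the most informative common ancestor in the HPO is-a DAG. IC is computed
from the supplied disease corpus as the negative log annotation frequency
with annotations propagated to ancestors (so an ancestor is never more
informative than its descendant), falling back to term depth for toy
ontologies with no corpus. Patient-to-disease similarity is the symmetric
best-match average of term similarities, normalized by the mean of the two
term sets' self-similarities; a gene scores the maximum over its diseases,
clipped to $[0, 1]$. A patient whose terms equal a disease's terms scores
exactly 1.

One property of this family is worth stating plainly: the *unnormalized*
best-match score can only decrease when a patient term is replaced by its
ancestor (the property tests assert this), but the *normalized* ratio can
occasionally increase, because replacing a deep term by its parent shrinks
the normalizer while leaving the best-match numerator unchanged whenever the
common ancestor sits above both. This is inherent to self-similarity
normalization, not an implementation artifact.

Interactome propagation is one-hop: a gene inherits `damping` (default 0.5)
times the best neighbor evidence, `weight × similarity(neighbor)`. A full
random walk is a documented extension point; the one-hop form is
deterministic, cheap, and sufficient for the neighbor-rescue effect the
feature exists to capture.

## The network

The score model is a single-hidden-layer network (default 16 units) with a
logistic output unit, fitted by least squares on the rank-decay labels with
L2 weight decay (default `1e-3`), via `nnet`. The logistic output bounds
every score to $[0, 1]$ by construction. Features are standardized with
constants stored in the model; examples are sorted into a canonical order
before fitting, so training is reproducible under a seed and invariant to
input row order. Weight decay serves as the regularizer in place of a
validation-split early-stopping loop: it is deterministic, has no extra
randomness to control, and on cohorts of this size (thousands of examples,
12 features) the two regularizers are interchangeable in effect.

A gene's score is the **maximum** over its mutations' scores, genes sort by
descending score with ties broken by gene symbol, and a gene's mutations by
descending score then variant key — every ordering in the package is total
and deterministic, so exported CSVs are byte-stable.

# Filtration semantics

Baseline filtration keeps coding non-synonymous and splice-region variants
and removes synonymous, non-coding and deep-intronic records. The nine
optional filters are pure predicates combined as a conjunction; enabling one
more filter can only shrink the kept set, and filtering is idempotent.
Boundary conventions are pinned by tests:

* splice region: kept iff intronic distance ≤ `splice_distance` (default 10,
  inclusive) **and** $|z| >$ `splice_z_min` (default 1.8, strict); a missing
  z-score is never kept;
* predictor scores: kept iff the maximum selected score is **strictly**
  above the threshold; if every selected score is missing the variant is
  kept — absent evidence never removes;
* allele frequency: an **inclusive** ceiling on the maximum over selected
  populations; all-missing is kept;
* ClinVar class, literature membership, OMIM and panels are set-membership
  filters; here — and only here — a variant with no record fails, because
  the user explicitly asked for known records.

Zygosity calls are 0/1 heterozygous, 1/1 homozygous, and hemizygous for any
alt-carrying call on the male non-pseudo-autosomal X or Y (pseudo-autosomal
coordinates are a configurable table, hg19/hg38 built in). Trio inheritance
modes follow Mendelian case analysis — de novo (both parents 0/0), dominant
(exactly one carrier parent, transmitted het), recessive (1/1 with both
parents het), X-linked, and compound heterozygous in trans, which requires
at least one proband het inherited from each parent within one gene.
Singletons produce no inheritance output; in singletons, two or more hets in
a gene are reported as a compound-het *candidate* without trans
confirmation.

# The synthetic cohort generator

The generator emulates the structure of a diagnostic exome cohort — it is
the package's study condition, not a tuning dial. Per cohort it builds a
random is-a DAG of ~200 terms (depth ≥ 4), 1–3 diseases per gene with 3–8
terms each, a preferential-attachment interactome, an OMIM-style gene list
and gene panels. Per case it draws a Poisson number (default mean 1200,
matching the order of magnitude of genes per exome in real cohorts) of
background variants with predictor scores ~ Beta(2, 5), population
frequencies concentrated in 0.01–0.2 with a rare tail, conservation
~ N(0, 1) and ClinVar mostly absent; one planted causal SNV whose predictor
scores are shifted by `causal_effect` background standard deviations, whose
frequency is shrunk by $e^{-2 \cdot \mathrm{effect}}$ and whose ClinVar
class is pathogenic with probability $0.3\min(1, \mathrm{effect}/1.5)$ — so
every causal shift vanishes continuously at zero effect, which is what makes
the zero-effect indistinguishability test meaningful. Patient phenotypes are
the causal gene's disease terms with a `phenotype_noise` fraction replaced
by random terms; trio genotypes follow a drawn inheritance mode. Synthetic
reference rankers displace the causal gene from rank 1 by an Exponential
with mean `noise` (default 10 rank units), calibrated once so the reference
tools' top-5 accuracy lands near one third, the accuracy regime real
phenotype-driven prioritizers report.

What the generator does **not** emulate: linkage structure between variants,
realistic functional-class/frequency correlations, the true size and shape
of the HPO, indel and structural alleles, or annotation error. Passing the
recovery tests therefore demonstrates that the pipeline learns and ranks as
designed under a known signal — not that it reaches any particular accuracy
on real patients.

## The recovery experiment and circularity

The end-to-end check trains and evaluates leave-one-out on 50 cases
(`causal_effect` 1.5, `phenotype_noise` 0.2, fixed seed) and requires top-5
recovery of at least 40% and a one-sided binomial rejection (α = 0.05) of
the rate achieved with patient phenotypes deranged across cases. Two scales
were chosen once: 50 cases × 300 genes × ~1200 variants keeps the full
double leave-one-out under a couple of minutes on one CPU while leaving the
baseline comparison well-powered. The fixture knowledge base is deliberately
**excluded** from this experiment: it assigns literature relations to causal
variants *by construction from the truth table*, so using it to recover
those same variants would test the oracle, not the method. It is exercised
instead by the knowledge-base, popularity-ranking and feature-assembly
tests, where it is not circular.

# The scheduler

The literature-mining workload that produces the knowledge base is driven by
a FIFO task-queue protocol, re-implemented here in-process with identical
semantics: a queue initialized with all task IDs; workers request tasks
(head of queue) and receive a `NO_TASK` sentinel when it is empty; a failed
worker's in-flight tasks are reloaded at the queue tail (fair to fresh
tasks — head-or-tail is not dictated by the protocol); results are collected
idempotently, so the at-least-once dispatch that failure recovery implies
still yields exactly one result per task. A task whose worker function
errors three consecutive times is marked failed and the run continues. The
conservation invariant — pending, in-flight and completed partition the
initial task set — is asserted after every operation in the simulated pool.

# Numerical and degenerate-input choices

* Multi-allelic VCF rows are split per alternate allele with genotypes
  recoded against that allele; no left-alignment beyond the shared padding
  base. Chromosome labels are normalized (`chr` stripped, `MT` → `M`).
* Coordinates are 1-based inclusive throughout.
* An empty filtered case scores to an empty, valid result; a gene with no
  disease annotation has phenotype similarity 0; an isolated gene has
  interactome similarity 0.
* Reference-build detection falls back from `##reference` tokens to contig
  lengths of chromosomes 1–3, and returns `unknown` rather than guessing.
* All-identical training features produce a convergence warning but still a
  model.
* Every stochastic component takes an explicit integer seed; derived seeds
  stay far below 2³¹.

# Known limitations

The phenotype-similarity and interactome formulas are this package's own
reconstructions of the method family used by phenotype-driven prioritizers
(Resnik/best-match averaging behind Phenomizer-style tools; interactome
vicinity behind Exomiser-style tools); production systems in this space do
not disclose their exact forms, and no claim of equivalence is made. The
trained network is a small reference implementation, not a tuned model.
GVCF reference blocks, structural variants, mosaicism, mitochondrial
heteroplasmy and pedigrees beyond trios are out of scope.
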