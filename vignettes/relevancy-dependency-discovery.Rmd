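---
title: "Kernel-guided discovery of feature relevancy and dependency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kernel-guided discovery of feature relevancy and dependency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kiedra)
```

## The problem

In biomarker discovery one wants two things at once from a labelled data
matrix: the subset of features that discriminates the outcome, and the
interactions among those features. Filter scores (correlation, information
gain) are cheap but myopic to interactions; the wrapper approach — scoring
feature subsets by the accuracy of a trained classifier — sees non-linear
and joint effects, at the price of many classifier trainings. This package
implements a wrapper that additionally *models* pairwise dependencies while
it searches, so the output is both a relevance vector and a dependency
forest. Epistasis is the motivating case: in a pure k-way interaction no
single SNP (nor any proper subset of the k) carries signal, which defeats
every marginal method by construction.

## The model

A candidate is a relevance indicator vector $w \in \{0,1\}^\ell$. The
search maintains a probability distribution over candidates, factored over
a dependency forest with roots $\mathbf{R}$ and directed edges
$\mathbf{E}$:

$$P(X;\theta) = \prod_{i \in \mathbf{R}} P(X_i;\rho_i)
  \prod_{(j,i) \in \mathbf{E}} P(X_i \mid X_j; \rho_j, \rho_{ij}).$$

Each iteration samples half a pool from this distribution, unites it with
the elite half from the previous iteration, ranks everything by wrapper
fitness, truncates, and re-fits both the forest structure and the counts
from the new elite. The structure step computes, for all feature pairs over
the elite's bits, the Pearson $\chi^2$ statistic, the plug-in mutual
information (bits), or the combined SIM indicator; firing pairs become
weighted candidate edges; a Kruskal scan keeps the maximum-strength
spanning forest; each component is rooted at its minimum-marginal-entropy
node (information-rich positions make good independent parents — the same
rationale as MIMIC's ordering heuristic). The univariate variant (wKiera)
skips the structure step entirely, leaving independent Bernoulli marginals
(UMDA); it is literally the same code path with an empty edge set, and a
test pins this degeneration equivalence.

The fitness of a candidate is the mean 5-fold cross-validated accuracy of
a soft-margin SVM on the candidate-rescaled data. The rescaling uses the
additive-kernel identity
$\kappa(x,z;w) = \kappa(\sqrt{w} \otimes x, \sqrt{w} \otimes z)$, which
holds exactly for the RBF and polynomial families, so the "weighted kernel
machine" is implemented as plain preprocessing in front of a standard
solver. The solver here is a compact SMO dual optimizer compiled from
`src/` (maximal-violating-pair selection on a precomputed Gram matrix);
this choice was forced by the deployment environment, which ships no R SVM
package, and is deliberately minimal — pool sizes are small, so an
$O(n^2)$-per-iteration solver is ample. Multiclass data is handled
one-vs-rest with plain accuracy as fitness.

## Parameters that matter

| Parameter | Default | Meaning / why this default |
|---|---|---|
| `pool_size` (n) | 20 | candidates per iteration; the published epistasis protocol value |
| `max_iters` | 80 | iteration budget (protocol value); recovery batteries use 40 to stay in desk-scale time |
| `criterion` | `"sim"` | SIM = ($\chi^2$ p-value $\le \alpha$) **and** (MI > tol); the protocol's choice. `"mi"` alone fires on almost any finite sample and is deliberately permissive |
| `C` | 100 | SVM soft margin (protocol value) |
| `sigma` | 10 | RBF width multiplier, $\exp(-\sigma\|x-z\|^2)$ convention, on [0,1]-normalized features |
| `elite_fraction` | 0.5 | the only size for which `sample(P, n/2) ∪ B` keeps the pool at n |
| `smoothing` | 1 | Laplace pseudo-count; raw frequentist counts divide by zero on unseen parent values and freeze the search at exact 0/1 marginals. `0` is allowed for purists |
| `convergence_delta` | 0.01 | early stop when every marginal is within delta of saturation; with smoothing 1 and an elite of 10 this never fires before `max_iters`, making `max_iters` the effective stop — matching a protocol that states only an iteration count |
| cutoff | 0.7 / 0.5 | relevance threshold after averaging; strictly-greater comparison (the protocols say "greater than") |
| accuracy floor | 0 / 0.8 | held-out accuracy filter before averaging; applies to the test split, strictly greater |

## What the generator emulates — and what it does not

`generate_epistasis_dataset()` draws k genotype columns (0/1/2, binomial
under Hardy–Weinberg with allele frequency 0.5) and labels each instance
by the parity of its genotypes. Parity is the canonical "pure interaction"
construction: every proper subset of the k loci has exactly zero mutual
information with the class in expectation, while the full set determines
it. This reproduces the *statistical* structure of model-free "NoLow"
epistasis testbeds — balanced classes, no marginal or lower-order effects,
maximal k-way effect — without redistributing any original testbed files.
A configurable `leak` mixes back a single-SNP marginal signal to emulate
the non-NoLow variants. Irrelevant features are i.i.d. Uniform(0,10), as
in the published pollution protocol.

It does **not** emulate linkage disequilibrium, covariates, genotyping
error, unbalanced designs, or penetrance tables with partial effect sizes.
A green recovery test therefore establishes that the method finds clean,
balanced, noise-free-genotype interactions at moderate dimension — not
that it would on real GWAS data.

One protocol decision deserves a note: the epistasis pipeline min-max
normalizes features (genotypes map to {0, 0.5, 1}) before splitting. With
raw U(0,10) noise and $\sigma = 10$, a single included noise feature
collapses the Gram matrix to near-identity and the fitness landscape to a
needle — no gradient exists toward the optimum, and the search could only
succeed by blind luck. Normalization keeps noise damping graded, so
candidates carrying all k SNPs plus some noise score between the optimum
and chance, which is the gradient the evolution climbs. The same
normalization is applied to real datasets in the benchmark protocol, so
this unifies rather than forks the preprocessing.

## Numerical and degenerate-input conventions

* $\chi^2$ cells with zero expected count contribute 0 (degenerate-margin
  convention); constant elite positions thus yield statistic 0, not NaN.
* MI uses $0\log 0 = 0$ and is clamped at 0 against round-off; all
  entropies and informations are in bits (the root argmin is
  base-invariant).
* The `chi2` edge criterion uses the literal 3.84 threshold as printed in
  the classic rule; SIM uses the exact 1-df p-value at $\alpha = 0.05$, so
  SIM firing always implies the 3.84 rule fires too.
* Kruskal ties break by lexicographic pair after sorting by decreasing
  strength; component roots tie-break to the lowest index; sampling visits
  nodes in BFS order from the roots, lowest index first. Every tie-break is
  deterministic, so a (dataset, config, seed) triple reproduces runs
  bit-identically.
* Candidate ranking breaks fitness ties by pool position, with the elite
  listed before fresh samples — a stable elite under ties.
* All-zero candidates short-circuit to the majority-class rate; constant
  features normalize to 0; a class with fewer instances than folds reduces
  the fold count with a warning.
* The consensus tree on aggregated counts excludes zero-count pairs
  entirely (cost $1/\text{count}$ is undefined there), yielding a forest
  when the count graph is disconnected.
* Naive-Bayes imputation discretizes into 5 equal-width bins over observed
  values and fills with the predicted bin's midpoint; a feature with no
  complete co-observed rows falls back to mode/mean with a warning.

## Open design decisions

* **SIM's exact formula** is not published alongside the rule it entered;
  it is implemented here as the minimal faithful reading — statistical
  significance *and* positive information — and flagged as an
  interpretation.
* **Split orientation**: "25%/75%" is read as 25% training (the split
  feeding cross-validation) and 75% held out for reporting; it is
  configurable via `train_fraction`.
* **Fitness CV runs on the training split only**; the held-out split is
  reserved for the accuracy floor and reporting.
* **Elite size and convergence rule** are unstated in the protocol; the
  choices (half the pool; marginal saturation or the iteration cap) are the
  only ones consistent with the stated pool arithmetic.
* **Relevance semantics**: a run's reported vector is the best candidate's
  bits (not the final model marginals, which are also emitted for
  diagnostics); averaging across repetitions happens over best-candidate
  bits.
* **"Chain" recovery on parity problems**: the parity construction makes
  the k relevant loci pairwise exchangeable, so there is no distinguished
  chain ordering; the consensus-recovery acceptance test asks that the
  consensus tree connect the relevant loci using only edges internal to
  the relevant set.

## Known limitations

* The dependency model is strictly bivariate: interactions of order three
  and higher are visible to the *wrapper* (the SVM sees them) but not
  representable in the forest, and the hardest pure 5-way problems are
  expected to defeat the structure recovery — a limitation inherited from
  the model class.
* Spurious dependencies among noise features do occur (a 5% test applied
  to many pairs over many iterations must fire sometimes); dependency
  matrices are meant to be read jointly with the relevance factors, and
  aggregate counts concentrate on relevant pairs rather than excluding
  noise pairs outright. The acceptance battery checks exactly this
  concentration, not absence of noise edges.
* Wall-clock cost is dominated by classifier trainings; the bitstring
  fitness cache removes exact duplicates (frequent late in convergence)
  but the method remains much more expensive than filter scores at high
  dimension.
* The SMO solver is adequate for wrapper-scale problems (hundreds of
  training rows); it is not a general-purpose SVM for large data.
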