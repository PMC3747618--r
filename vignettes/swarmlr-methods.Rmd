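---
title: "Fish-swarm logic regression: model, search, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fish-swarm logic regression: model, search, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swarmlr)
```

## The model

`swarmlr` fits logic-regression models to binary SNP data. A *logic
tree* is a strictly binary tree whose leaves are SNP literals — a SNP or
its negation — and whose internal nodes carry AND/OR. Negation lives
only on leaves; De Morgan rewriting keeps that closed under every edit
the search makes. A model links k trees to the case/control phenotype
through the sigmoid:

$$g(E(P)) = \beta_0 + \sum_{i=1}^{k}\beta_i L_i,\qquad
  g(\eta) = \frac{1}{1+e^{-\eta}},$$

and its *score* is the number of individuals whose phenotype it
predicts correctly (prediction thresholded at 1/2; for a bare
single-tree model this is the plain Boolean match count). The swarm
itself searches single-tree models — each fish agent holds one tree —
while the regression layer supports general k for scoring, priors and
reporting.

Splitting a tree recursively at its OR nodes yields a *forest* of
AND-only conjunctions whose disjunction is evaluation-equivalent to the
tree. Conjunctions are the natural epistatic unit: the solution-space
coordinate used for swarm communication is (number of conjunctions,
their sizes, score), and reported interactions are SNP pairs/triples
co-occurring within single conjunctions.

### Prior over models

The size-penalized model prior factorizes as: a uniform prior on the
number of trees over `1..n_max`; a geometric prior
$\theta(1-\alpha)\alpha^{s}$ on the total size s, with $\theta$ chosen
so the prior normalizes over $s \in [1, n_{max} s_{max}]$; a uniform
prior over the compositions of s into per-tree sizes within
`[1, s_max]`; and a uniform prior over the $\binom{N}{s_i}$
SNP-indicator vectors of each tree. Written this way the prior sums to
exactly 1 over the model space (the unit test enumerates the N = 4,
s_max = 2 space and checks this); treating the total-size factor and
per-tree-size factors as independent would double-count size and break
normalization. The default $\alpha = 0.5$ halves the prior per extra
leaf.

### Acceptance probability

A proposal that improves an agent's (bootstrap) score is always
accepted. Otherwise it is accepted with

$$Q=\min\Bigl\{1,\;
  v^{(k-k^*)/2}\,\frac{|\hat V^*|^{1/2}}{|\hat V|^{1/2}}\,
  e^{\,a-a^*}\Bigr\},$$

where, under the Gaussian working model with coefficient prior variance
v on the tree-output design $\Omega$,
$\hat V=(\Omega'\Omega + I/v)^{-1}$, $\hat\beta=\hat V\,\Omega'y$, and
the error term $a = y'y-\hat\beta'\hat V^{-1}\hat\beta$ is the residual
misfit. Identical proposals give Q = 1 and a smaller error term raises
Q. Everything is computed in log space so large error terms cannot
overflow; for the swarm's single-tree models the sufficient statistics
reduce to two scalars per tree, which is what the inner loop uses. The
default v = 10 is a weak prior; it is exposed in `fslr_control()`.

This package reads "rejected with probability Q" in the standard
Metropolis sense — accepted with probability Q — because the min{1, ...}
form is an acceptance ratio; the comparison is made against the agent's
own current model (the local reading). Both points were genuinely open
in the method's description; the code isolates the rule in one place so
alternatives can be swapped.

### Importance, selection distributions, and distance

Each agent trains on a bootstrap resample of the rows (size M, drawn
with replacement); the never-drawn rows form its out-of-bag (OOB) set,
on average a fraction $1-(1-1/M)^M \to e^{-1}$ of the data. The
importance of SNP j is the mean OOB damage of removing it:

$$V(j) = \frac{1}{F}\sum_{k=1}^{F}\bigl(N_k - N_k^{-j}\bigr),$$

with $N_k$ the correctly classified OOB rows of agent k and
$N_k^{-j}$ the same after pruning every leaf of SNP j from its tree (a
tree pruned to nothing predicts the majority class of the agent's
bootstrap rows — a deliberate convention so the quantity stays
defined). SNPs held by no agent have V = 0 by construction.
Importances map to SNP-selection probabilities
$P(j)\propto\max(V(j),\epsilon)+\epsilon$; the floor
($\epsilon$ = 0.01) keeps every SNP reachable and makes equal
importances exactly uniform. The distance between two agents is the
absolute difference of the importance mass carried by their SNP sets.

### Behaviors

The best agent HOLDs. Every other agent draws RANDOM / FOLLOW / KPDIST
with probabilities (0.2, 0.5, 0.3) — a package default; the method's
description leaves the mixture open. Size preferences use the normal
density $f(s)$ centered at the best agent's size with variance the mean
squared size deviation across the school, clamped to [0, 1] so it can
serve directly as a probability, and floored at 0.25 so it stays proper
when all agents share one size.

* **RANDOM**: one of the four edits with probability 1/4 each
  (infeasible edits resampled), uniform SNP choices.
* **FOLLOW**: above the best size, DEL with probability f(s) (victim
  drawn with weight 1 − P(j)), else ALT; below, ADD with probability
  1 − f(s) (new SNP from P), else ALT; at equal size, always ALT.
  Replacement SNPs come from P over SNPs outside the tree. The
  behavior description is internally inconsistent about whether
  replacements follow P or 1 − P; the importance rationale favors P,
  which is the default, with `strict_literal_alt = TRUE` giving the
  literal reading.
* **KPDIST**: the mirror image in size (above: ADD with probability
  1 − f(s); below: ALT with f(s), else DEL; equal: ADD or DEL with
  probability 1/2, so the proposal always leaves the best size). As
  the school's diversity behavior its SNP draws use weights 1 − P(j),
  steering toward SNPs the school is not already exploiting — the
  description fixes KPDIST's move probabilities but not its SNP
  distribution, and the anti-importance choice both matches the
  keep-distance rationale and prevents the whole school from being
  trapped on already-found SNPs.

Every `i_max = 10` iterations the importances are refreshed and a
stepwise sweep computes each active SNP's partial F statistic (the
linear regression of the phenotype on the model's SNP columns, each
column dropped in turn) and prunes SNPs with $F \le F_{out} = 4$; a
model is never pruned to empty (the max-F SNP survives), and the
best agent is exempt from mid-run pruning, consistent with HOLD. The
run stops when the best score has not improved for `b_stable`
iterations. The default window scales with the search space,
`max(100, 0.6 N)`: with F = 12 agents proposing one edit each per
iteration, a window proportional to N lets the school try every SNP a
handful of times in varied contexts between improvements; a fixed
small window systematically under-searches thousand-SNP panels. The
reported *selection* is the union of SNPs over all agents' final
(stepwise-pruned) trees — the school's full output — with
`selection = "best"` restricting to the global-best model.

## The simulator and what passing tests mean

`simulate_epistasis()` draws a pool of haplotypes (default 40,000) with
a fixed number of segregating sites (default 1,000) whose derived-allele
counts follow the neutral site-frequency spectrum
$P(\text{count}=i)\propto 1/i$, sites independent. A causal expression
is planted over randomly chosen sites, phenotypes agree with its output
with probability *risk*, a balanced case/control subsample is drawn
(default 1,000 + 1,000), and allele *noise* flips entries of the sampled
matrix.

Design choices worth knowing:

* **Expression shape.** The default planted expression is a pure
  disjunction over the causal sites (each site independently confers
  risk — the dominant genetic model). Measured against alternatives,
  this is the only shape under which identified-causal counts scale
  with the number of causal sites: with uniformly random AND/OR trees,
  most causal sites sit under AND branches and have *no* marginal
  signal at M = 2,000, so no method could recover them. For many
  causal sites a pure disjunction saturates the pool prevalence, so
  `"dnf"` (OR of 1–3-site AND units — exactly the forest structure the
  method itself fits) is provided and used for the 100-causal-site
  experiment. A prevalence guard resamples sites and shapes until
  5–95% of the pool evaluates to 1, redrawing the pool itself if no
  workable site set exists.
* **Subsampled generation.** By default non-causal columns are
  realized only for the sampled rows, by hypergeometric subsampling of
  each site's pool allele count. Because sites are independent and row
  selection depends only on the causal columns, this is exactly the
  same distribution as materializing the full pool
  (`method = "full"`), at a fraction of the cost.
* **Risk is the agreement probability**; risk = 1 gives deterministic
  phenotypes, risk = 0.5 complete independence. Risk levels below 0.5
  anti-correlate phenotype and expression; site identification is
  direction-agnostic, so the 5–15% grid remains meaningful.
* **Noise is applied after sampling**, matching the protocol's
  ordering.

What the generator does *not* emulate: linkage disequilibrium and
haplotype block structure (sites are independent; an ms-style
coalescent with recombination would add LD), population structure,
genotyping-error structure beyond i.i.d. flips, and covariates. Tests
passing on these simulations therefore certify the search and the
statistics under clean, LD-free signal — not performance on real
panels, where LD can both help (tags) and hurt (false proxies).

## Error-rate conventions

Several conventions circulate for simulation accuracy and they disagree
substantially; `type_errors()` reports all of them side by side:
`type_i` (missed causal sites as a percentage of *all* sites — the
convention whose algebra reproduces published type-I columns of this
style of study row for row), `type_i_literal` (missed causal over
selected SNPs, which can exceed 100%), `type_ii` (non-causal selections
among selected — a false-discovery percentage), and `miss_rate` (missed
causal over causal). Empty selections yield NA rates with a warning
rather than a crash.

## Numerical and degenerate-input choices

* Coefficients are MAP estimates under independent N(0, v) priors via
  Newton iteration; separation is handled by the prior, and a
  numerically singular Hessian falls back to a ridge-stabilized step
  and flags the fit.
* Partial F statistics are computed from one pass of normal-equation
  sufficient statistics (each drop-one fit is a small solve, not a new
  n-row regression); rank-deficient subsets are handled by pivoted QR,
  so an exactly duplicated column gets F = 0.
* Ties for the best agent break toward the lowest agent id; equal
  importances give uniform selection; ALT never redraws the identical
  literal; DEL on a single-leaf tree and ALT-operator on a leaf are
  infeasible and resampled at the behavior level.
* All randomness flows through R's RNG: one seed makes an entire
  simulate–fit–evaluate run bit-reproducible. Agents advance
  sequentially in id order; the importance refresh and best-agent
  announcement are the per-iteration synchronization points.

## Problem sizes used in the shipped checks

The packaged tests run the full protocol at its native data scale
(1,000 sites, 1,000 + 1,000 individuals) with 5–10 repeats per
configuration, and the smaller component checks at 4–20 sites with
60–100 seeded runs; `scripts/acceptance.R` uses 10 repeats per
configuration cell. These repeat counts are the package's chosen
desk-scale design; the estimates they produce are means over seeds and
carry Monte-Carlo error of a few percent.

## Known limitations

* Single-host, single-thread execution; the swarm is embarrassingly
  parallel in principle, but this implementation advances agents
  sequentially.
* The search is stochastic: on thousand-SNP panels, causal sites whose
  marginal score gain is within sampling noise (roughly, fewer than
  ~40 of 2,000 rows affected) are found rarely, and the stepwise
  sweep deliberately discards them even when found.
* Only binary phenotypes; quantitative traits are out of scope.
* Diploid input is handled by recoding (dominant/recessive bits), not
  by genotype-aware likelihoods.

```{r example, eval = FALSE}
sim <- simulate_epistasis(sim_config(n_pool = 2000, n_sites = 12,
                                     n_causal = 2, n_cases = 150,
                                     n_controls = 150), seed = 7)
fit <- fslr(sim$data, seed = 7)
glance(fit)
evaluate_fit(fit, sim)
autoplot(fit)
```
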