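---
title: "Inferring tumor clone migration histories: models, simulator and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tumor clone migration histories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneMig)
```

## The problem

Metastasis is the migration and colonization of tumor clones between
anatomical sites. Because clones accumulate somatic mutations, the clones
sampled from a patient's primary tumor (P) and metastases (M1, M2, ...) are
related by a phylogeny, and every tree edge whose two endpoint clones resided
in different sites witnesses a migration event. Collecting those edges over
sites gives the *migration graph*, a directed multigraph whose edge
multiplicities record polyclonal seeding. The data, however, only locate the
*sampled* clones at the leaves; the ancestral clones' sites — and hence the
migration graph — must be inferred.

cloneMig implements and compares the two families of estimators used for this
problem, embedded in a simulation benchmark whose true migration histories
are known:

* **Parsimony** (`infer_pmh()`, `resolve_polytomies_pmh_tr()`): ancestral
  sites minimizing, lexicographically, the number of migrations $\mu$,
  comigrations $\gamma$, and distinct seeding source sites $\sigma$.
* **Bayesian ancestral-site inference** (`infer_bbm()`): a discrete-state
  Markov model of site changes along branches, in the spirit of Bayesian
  biogeographic ancestral-range reconstruction, with per-node posterior
  probabilities.

## Parsimony model

For a tree $T$ with leaf sites fixed, every full labeling $\ell$ of the nodes
costs $\mu(\ell) = \#\{(u,v) \in E(T) : \ell(u) \neq \ell(v)\}$. The minimum
over $\ell$ is computed by Sankoff dynamic programming with unit change cost
(`sankoff_min_migrations()`), either with the root constrained to the primary
site — the biologically motivated default, since the founding clone resided
in the primary tumor — or unconstrained, in which case any site may be
ancestral and co-optimal solutions can be numerous (the solution count is
reported, and `enumerate_optimal_labelings()` lists them up to a cap, default
10000, with an explicit truncation flag).

Among the $\mu$-optimal labelings we select the one minimizing the
comigration count $\gamma$ and then the source count $\sigma$. The objective
order $(\mu, \gamma, \sigma)$ follows the order in which the three criteria
are conventionally stated for this problem. Two definitions needed care:

* **Comigrations.** A comigration is a polyclonal seeding event: several
  clones moving together between the same ordered site pair. Migration edges
  between the same pair that lie on one root-to-leaf path cannot be
  simultaneous (one is ancestral to the other), so we count, per ordered site
  pair, the length of the longest ancestor–descendant chain among that
  pair's migration edges — by Mirsky's theorem, the minimum number of
  antichains ("waves of seeding") covering them. This makes the verbal notion
  "number of simultaneous group migrations" exact and testable.
* **Ties.** Remaining ties are broken by a deterministic enumeration order
  (canonical site order — primary first, then metastases by index — within a
  fixed preorder traversal), so results are reproducible run to run.

`resolve_polytomies_pmh_tr()` additionally searches over binary refinements
of every polytomy, minimizing $(\mu, \gamma, \sigma)$ jointly over
refinements and labelings. Polytomies with at most 6 children are searched
exhaustively (all $(2c-3)!!$ resolutions); larger ones are resolved by a
greedy pairwise-join local search; when several polytomies would make the
joint space larger than 3000 combinations they are handled sequentially.
Resolution edges carry zero mutations, so the resolved tree refines the
input topology without inventing evidence.

## Bayesian model

`mk_model()` defines a $k$-state Markov process over tumor sites with equal
exchange rates — the $k$-state generalization of the Jukes–Cantor model —
normalized to one expected change per unit branch length. The equal-rate
assumption mirrors the working hypothesis that seeding is equally probable
between any pair of sites; it also yields a useful symmetry (permuting site
labels permutes posteriors identically) that is verified in the tests.

Branch lengths are mutation counts. The model multiplies them by a
`scale` parameter, the expected number of site changes per somatic mutation
(default 0.05, configurable): there is no canonical clock linking mutation
accumulation to migration, so this constant is an explicit modeling choice
rather than something fitted. Zero-length branches (e.g. polytomy resolution
edges, the germline attachment) receive a pseudo-length `eps` (default 0.01
mutations) so transition matrices stay non-degenerate.

Posteriors are computed two ways:

* **Exact** (`marginal_posteriors()`, the default): two-pass belief
  propagation — Felsenstein pruning upward, a downward pass for marginals —
  under a uniform root prior. Exact, deterministic, and fast.
* **MCMC** (`mcmc_sample()`): Gibbs sampling of full ancestral labelings,
  one generation being a full sweep of single-node updates from their exact
  full conditionals. Several chains are run (default 3), post-burn-in
  samples pooled, and the largest across-chain spread of any per-node site
  frequency reported as a convergence diagnostic. The sampler exists for
  fidelity to the MCMC-based reference workflow and for users who want
  posterior samples; for point estimates it can only approximate what the
  exact pass computes, which is why exact is the default.

The reference biogeographic tool cannot constrain the root state directly;
the same effect is obtained through the data, by including the germline
(normal-cell) taxon as an outgroup leaf labeled with the primary site. Its
short branch anchors the root posterior at P; the root's MAP site is P on
every simulated dataset (a tested invariant).

`infer_bbm()` assigns each internal node its maximum-a-posteriori site.
Posterior ties are broken toward the parent's assigned site — the choice
that fabricates no extra migration — then by canonical site order.
`annotate_events()` reinterprets per-node site *ranges* (all sites with
posterior mass above a threshold, default 0.15, plus the MAP site) as
biogeographic events: dispersal (a branch gains a site), extinction (a
branch loses one), diversification (children retain the node's site),
serialized in a compact arrow/caret notation (`M1->M1M7`, `M2^M2`). Only the
MAP sites enter the migration graph; ranges serve event annotation.

## Perfect phylogeny reconstruction

The simulated clone genotypes are binary (0 = germline base,
1 = substitution) and homoplasy-free: each character mutates exactly once,
never reverting — the infinite-sites regime of clonal evolution. Under that
regime maximum parsimony is guaranteed to recover the true tree, and the
optimum is the *perfect phylogeny*, which `reconstruct_mp_tree()` builds
directly: characters with identical clone sets merge onto one edge (branch
length = number of such characters), the distinct clone sets must form a
laminar family (checked; violations raise an error naming the conflicting
character pair), and the containment order of that family *is* the tree.
The parsimony score of the result always equals the number of characters,
and the sum of branch lengths equals the matrix width — both tested.

## What the simulator emulates

`simulate_dataset()` generates datasets with the statistical shape of the
published clone-phylogeny benchmark: 5–7 (`m5`) or 8–11 (`m8`) tumor sites,
7–28 sampled clones, 9–99 homoplasy-free characters, under four seeding
scenarios of increasing complexity — `mS` (every metastasis founded by a
single clone from a single source), `pS` (some metastasis seeded by several
clones from one source), `pM` (some metastasis seeded from several distinct
sources), `pR` (at least one clone reseeds the primary). The generator:

1. draws the per-site sampled-clone budget (1–4 clones per site, primary at
   least 2 — the primary is the oldest and largest tumor);
2. draws a site-level seeding skeleton — a random tree over sites rooted at
   P with seeding sources chosen **proportional to the sites' clone
   budgets**, the clone-level analogue of seeding probability proportional
   to tumor cell counts — plus scenario extras, which are cumulative:
   polyclonal arrivals from `pS` on (each metastasis gains an extra
   same-source arrival with probability 0.4, at least one forced),
   multisource edges from `pM` on (one forced, a second with probability
   0.3), and reseeding edges for `pR` (one forced, extras with probability
   `reseed_prob`, default 0.2);
3. embeds the skeleton into a growing clone tree. Each migration splits a
   lineage into a resident and a migrating daughter; within-site
   diversifications supply the remaining clones (with probability
   `polytomy_prob`, default 0.1, a diversification yields three daughters,
   creating a true polytomy). Two scheduling rules emulate tumor growth:
   a site spends its diversifications **before** emitting onward
   migrations, and successive emigrants leave from distinct resident
   lineages where possible. Without them, a seeding source's clones
   collapse into a single clade, the parsimony optimum ties with the
   all-primary labeling, and no method (nor any amount of data of that
   shape) could recover the source — an artifact of naive event ordering,
   not a property of tumor evolution;
4. assigns each branch 1–6 mutations (clamped so totals stay within 9–99),
   so every branch carries private characters and the true topology is
   exactly recoverable from the matrix;
5. rejection-samples (up to 1000 attempts) until the realized migration
   graph classifies as the requested scenario via `classify_scenario()` —
   so the scenario tag is guaranteed correct by construction.

What it does **not** emulate: cell-population dynamics (no tumor sizes,
growth rates or driver fitness — clone counts are the only size proxy),
sequencing noise or subclonal mixture deconvolution (genotypes are observed
directly), unsampled extinct clones, and within-site spatial structure.
Passing benchmarks on these data therefore demonstrates correct *inference
given the correct clone phylogeny*, the same conditioning used in the
published comparison, not robustness to upstream reconstruction error.

## Evaluation framework

`compare_graphs()` scores an inferred graph $G$ against the truth $G^*$ per
ordered site pair: $TP = \min(m_G, m_{G^*})$, the excesses counting as FP or
FN. Multiset semantics is the default — polyclonal seeding is represented
precisely by edge multiplicity, and the scenario definitions distinguish
double from single seeding — with set semantics available as an option.
Precision, recall and their harmonic mean F1 (`f1_score()`) are computed per
dataset; `path_type_rates()` decomposes errors by path type (P→M, M→M,
M→P), and `pooled_path_rates()` micro-averages the counts over datasets
(macro-averages are emitted alongside for transparency).
`aggregate_benchmark()` reports mean F1 per method × scenario and per
method × size class, with two-sample Z-tests (unpooled variances) between
scenario pairs and Welch's t-test between size classes; both statistics are
reported because either convention is defensible and they can disagree at
small n. Degenerate groups (identical values) return $z = 0, p = 1$;
groups with fewer than two datasets skip the test with a notice.

## Problem sizes and numerical choices

The shipped benchmark (`run_benchmark()`, and `scripts/acceptance.R`) uses
5 datasets per scenario × size-class cell — 10 per scenario, 40 in all —
with the exact estimators; this reproduces the published accuracy regime in
seconds. The test suite additionally checks the parsimony optimum against
exhaustive enumeration on all small trees (≤ 8 nodes, ≤ 3 sites, several
hundred cases), the pruning posteriors against likelihood-weighted
enumeration (≤ 6 leaves, tolerance $10^{-9}$), and the Gibbs sampler
against the exact posteriors ($3 \times 10^5$ pooled samples, maximum
per-node error < 0.02). MCMC defaults mirror the reference workflow's
published settings (3 chains, 5,000,000 generations, sampling interval
1000, burn-in 1000 samples) and should be scaled down for routine use, as
`infer_migration(..., "bbm-mcmc")` does (3 × 50,000, interval 10).

Known limitations: the $(\gamma, \sigma)$ selection is applied over at most
`cap` co-optimal labelings, so on pathological inputs with more than 10000
optima the reported history is lexicographically best only among those
enumerated (the truncation is flagged); the comigration definition via
antichain covers is one operationalization of "simultaneous polyclonal
seeding" and other tools may count differently; and the branch-length scale
of the Bayesian model is a fixed constant, not estimated, so its posterior
probabilities should be read as model-conditional confidences rather than
calibrated frequencies.

## A worked example

```{r example}
ds <- simulate_dataset(sim_config("pM", size_class = "m5", seed = 1))
ds$graph

pmh <- infer_migration(ds, "pmh-con")
bbm <- infer_migration(ds, "bbm-exact")
pmh$counts
evaluate_inference(pmh, ds$graph)[, c("tp", "fp", "fn", "f1")]
evaluate_inference(bbm, ds$graph)[, c("tp", "fp", "fn", "f1")]
```

```{r benchmark, eval = FALSE}
res <- run_benchmark(benchmark_config(n_per_cell = 5, seed = 42))
res$summary$by_scenario
pooled_path_rates(res)
```
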