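---
title: "Models and methods in defenseflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in defenseflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

defenseflux quantifies how prokaryotic defense systems (restriction–
modification, CRISPR-Cas, Abi, CBASS, DRT, Gabija and DISARM-like systems)
relate to mobile genetic element (MGE) abundance and horizontal gene
transfer within bacterial and archaeal species. The inputs are a rooted
per-species strain tree with branch lengths in substitutions per site in
core genes, a Roary-style gene-family presence/absence matrix, a per-genome
defense-system table, and a per-family annotation (MGE marker class, COG
category, defense membership, MGE residency, singleton status). This
vignette explains the models, their assumptions, the tunable parameters,
and the design decisions taken where the methodology was genuinely open.

## The Poisson phylogenetic GLMM

For one species, genome $i$ and a response count $Y_i$ (total genes, genes
of one COG category, or MGE marker genes — always excluding the defense
systems' own genes), the model is

$$Y_i \sim \mathrm{Poisson}(\mu_i), \qquad
  \log \mu_i = \beta_0 + \sum_j \beta_j X_{ij} + \epsilon_i,$$

with $X_{ij} \in \{0,1\}$ the presence of defense system $j$ and
$\epsilon \sim \mathcal{N}(0, \sigma^2_{\mathrm{phy}} C)$. $C$ is the
Brownian-motion covariance of the strain tree: `C[i, j]` is the root-to-MRCA
shared path length (`brownian_covariance()`, via `ape::vcv`). Before
fitting, $C$ is rescaled to unit mean diagonal; this only improves
conditioning — $\beta$ and its Wald p-values are invariant and
$\sigma^2_{\mathrm{phy}}$ rescales accordingly (disable with
`rescale = FALSE`).

Estimation (`fit_poisson_pglmm()`) maximizes the Laplace-approximate
marginal likelihood: an inner Newton solve for the random effects (to
1e-8, with step halving) nested in a BFGS search over
$(\beta, \log \sigma^2_{\mathrm{phy}})$, with an explicit boundary check at
$\sigma^2_{\mathrm{phy}} = 0$ where the model collapses to the Poisson GLM.
Laplace was chosen over PQL or MCMC because it is deterministic, fast
enough for hundreds of refits in calibration experiments, and standard for
Poisson GLMMs; on identity covariance it agrees with `lme4::glmer`'s
observation-level-random-effect fit to three to four digits (this is one of
the package's cross-implementation tests). Wald p-values
($2\Phi(-|\beta/\mathrm{se}|)$) mirror the reporting convention of
comparative-methods packages. **No multiple-testing correction is applied
anywhere**; classifications use raw $P < 0.05$.

The identity-covariance counterpart (`fit_poisson_glmm_identity()`) runs
the same code path with $C = I$ and captures non-phylogenetic
overdispersion. Models are compared with the conditional AIC (`caic()`):
$-2$ times the conditional log-likelihood at the fitted random effects
plus twice the effective degrees of freedom, the trace of the hat matrix
of the augmented working-response regression (Vaida–Blanchard). At the
$\sigma^2 = 0$ boundary this is exactly the GLM's AIC. Differences under 2
are read as model equivalence.

`fit_species_battery()` fits either one model per defense system
(`"single"`, a single binary predictor — immune to overfitting in small
species and the default) or one joint model per response with all estimable
systems. Systems present in all or none of the genomes are skipped as
inestimable. The count of other defense systems can be added as a
covariate (`other_defense_covariate = TRUE`).

## Effect sizes and the SSES criterion

Effect sizes are relative differences on the response scale:
$\mathrm{ES} = e^{\beta} - 1$ (`effect_size()`). An alternative reading —
the raw relative difference of group means — is available as
`relative_difference()`. Associations are classified under two criteria
(`associate_battery()`):

* **significance**: sign of ES where $P < 0.05$, otherwise null;
* **SSES**: within each response × system group across species, the
  smallest $|\mathrm{ES}|$ that reached significance anywhere defines a
  threshold; species with $|\mathrm{ES}|$ *strictly greater* classify by
  sign, the rest as null. This makes species with very different sample
  sizes comparable: a large species with a tiny but significant effect
  stays null under SSES.

With strict inequality the species that itself achieves the SSES always
classifies as null even when significant; ties therefore break toward
null, and the "significant implies above-threshold" implication holds for
every species except that achiever.

## Gene gain/loss inference

Each family's phyletic pattern evolves by a two-state continuous-time
Markov chain with gain rate $g$ (0→1) and loss rate $l$ (1→0) per
substitution/site, shared across families, with a $K = 4$ category
discretized-gamma multiplier (mean one, shape $\alpha$) scaling $g$ and $l$
jointly per category and a stationary root prior
$\pi_1 = g/(g+l)$. A single shared gamma keeps $g/l$ identifiable; whether
the reference tooling uses one shared or two independent mixtures is not
documented, and this is the simplest reading. The likelihood is the
category-averaged Felsenstein pruning likelihood (`family_loglik()`, with
the hot loop in C++); `fit_gainloss()` maximizes it by L-BFGS-B on the log
scale from a fixed data-scaled multi-start grid (rates
$\{0.1, 1, 10\} \times$ a tree-scale factor, $\alpha \in \{0.5, 1, 5\}$),
making the optimum deterministic.

`branch_expected_events()` computes, per branch and family, the posterior
expected number of gains and losses and the posterior probability of at
least one event: endpoint joint posteriors by inside–outside pruning, and
conditional expected transition counts by uniformization with the Poisson
series truncated at $10^{-10}$ tail mass. Uniformization (rather than an
endpoint-change approximation) was chosen because it is exact and testable:
the suite checks it against a fine-discretization jump-time integral
oracle and against the pathwise identity
$E[N_{01} - N_{10} \mid a, b] = b - a$. Binary per-branch event *calls*
(for linkage statistics) use $P(\geq 1\ \text{event}) > 0.5$ by default
(`call_branch_events()`); the calling threshold used by the original
analysis is not documented, so it is exposed as a parameter.

## Sister-clade flux comparison

`find_def_clades()` returns, for one defense system, the clades in which at
least 80% of leaves carry (DEF+) or lack (DEF−) the system. "Narrowest
possible clades" is interpreted as *maximal* qualifying clades — qualifying
nodes with no qualifying ancestor — because a literal narrowest reading
degenerates to single leaves; this is the single riskiest interpretive
decision in the package. The maximal reading also guarantees disjoint
clades, which a parent-fails-only rule does not. `pair_sisters()` keeps
pairs that are children of the same node, discarding pairs in which both
clades are single genomes.

Rates (`clade_rates()`) are expected events summed over the clade's
internal branches divided by their summed length, excluding species-wise
singleton families (likely annotation artifacts or ultra-fast-turnover
genes) and excluding the clade's stem branch — events on the stem include
the defense acquisition itself. DEF+/DEF− comparisons use log-ratios;
ratios with a zero rate on either side are excluded and counted in an
`n_undefined` column. `test_logratios()` applies the two-sided Wilcoxon
signed-rank test against zero.

Pair depth is the mean path length from the pair's parent node to its
descendant leaves (a maximum-distance variant sits behind
`method = "max"`); depth is not formally defined in the source
methodology, and the mean reading is the least outlier-sensitive.
`stratify()` cuts at $10^{-5}$ and $10^{-3}$ substitutions/site with open
intervals. Skewness of stratum distributions uses d'Agostino's
transformation of the biased sample skewness (`skewness_test()`,
requiring $n \geq 8$). The implementation matches scipy's `skewtest` to
$10^{-10}$ on non-degenerate input but returns $z = 0, p = 1$ at exactly
zero skewness, where scipy's guard (`y == 0` replaced by 1) produces a
spurious nonzero statistic; the asinh transform is continuous through
zero, so this is the mathematically consistent choice.

## Branch-level linkage statistics

From a per-branch table of binary defense/MGE gain and loss calls
(`branch_event_table_from_history()` for simulated truth,
`call_branch_events()` for inferred posteriors), the package computes: the
fraction of defense-event branches that also carry the matching MGE event
with exact Clopper–Pearson intervals (`cogain_fraction()`); the null
expectation when defense events are placed on branches proportionally to
branch length (`independence_expectation()`; a branch-count-uniform
variant sits behind `weight = "count"` since the original "random
expectation given the rates" is ambiguous between the two); exact binomial
deviation tests; conditional probabilities; risk ratios with the standard
log-method 95% CI ($z = 1.96$); and Fisher's exact test. Events are binary
per branch — at least one event — matching the per-branch co-occurrence
framing; the analysis cannot and does not distinguish a single joint
transfer from same-branch independent events. `split_by_branch_type()`
recomputes everything on terminal and internal branches separately, the
standard control against incomplete-genome artifacts.

## The synthetic-data generator

The generator exists because the real inputs (tens of thousands of
genomes) are out of desk-scale reach; it emulates the statistical
structure the analysis assumes, with full ground truth. It is explicitly a
stand-in, not a fitted model of any real dataset.

* **Tree**: birth–death conditioned on `n_genomes` tips (`ape::rphylo`),
  rescaled to a target mean root-to-tip depth. Defaults (birth 1, death
  0.9, height 0.02) give the high-turnover, shallow-node-rich shape of
  well-sampled bacterial species trees.
* **MGE elements**: `n_mge_families = 10` independent two-state chains
  (gain 100, loss 200 per substitution/site; stationary occupancy 1/3).
  The rates were calibrated so that MGE-gain branches cover roughly 70% of
  total branch length on a default tree — the regime reported for real
  species — and are deliberately fast relative to the core-gene clock.
* **Defense system**: starts absent at the root; on each branch with at
  least one MGE gain an absent defense is gained with probability
  `defense_linkage` (default 0.95) at the first MGE-gain position;
  background gains arrive at rate `defense_independent_gain_rate`
  (default 2, so that essentially all acquisitions are MGE-linked); on
  each branch with an MGE loss a present defense is lost with probability
  `defense_loss_linkage` (default 0.9). Linkage is modelled at branch
  granularity, not as physical carriage, because the downstream analysis
  only ever observes branch-level co-events.
* **Gene families**: pre-declared families per class (prophage 150,
  plasmid 100, transposon 100, neutral 250 by default) evolve as two-state
  chains whose gain rate is multiplied by `defense_effect` ($\phi$,
  default 0.5) on tree segments where the defense is present. Class base
  rates (gains 40/30/30/15, losses three times that; stationary prevalence
  0.25) put MGE-class turnover above housekeeping turnover. Singleton
  families are injected at `singleton_fraction = 0.1`, and
  `n_defense_genes = 3` families carry the defense system's own presence
  pattern (these are excluded from response counts downstream, as in the
  analysis). Root states are drawn from the stationary frequencies,
  mirroring the inference model's root prior.

What the generator does **not** emulate: physical carriage of defense
genes inside specific MGEs, cargo genes co-transferred with a defense
acquisition, epidemic reinfection dynamics within young clades,
recombination, or within-branch population processes. The main observable
consequence: in real data, recently acquired defense systems sit inside
clades that just received an MGE influx, producing strongly elevated
gene-gain rates in very recent DEF+ clades (positive log-ratio outliers).
Here, a recent DEF+ clade has the *same* suppressed gain rate as an old
one, so the positive-skew signal in the recent depth stratum arises only
from the small-count asymmetry of zero-truncated event counts — a much
weaker and seed-sensitive effect. Calibration experiments that pass on
this generator therefore validate the statistical machinery, not the
biological mechanism behind recent-clade outliers.

## Study conditions used by the calibration experiments

The test suite and `scripts/acceptance.R` use these fixed problem sizes,
chosen to exercise each method at realistic scale:

* **Oracle equivalence**: pruning vs exhaustive enumeration on 200 random
  trees with up to 5 leaves; transition probabilities vs matrix
  exponentials to $10^{-10}$; uniformization vs the jump-time-integral
  oracle on a $(g, l, t)$ grid.
* **PGLMM calibration**: type-I error of the Wald test on 250–400
  phylogenetic Poisson null replicates ($n = 100$,
  $\sigma^2_{\mathrm{phy}} = 0.3$, a phylogenetically evolved binary
  predictor); effect recovery at $\beta_1 = \ln 1.3$ over 50 replicates.
* **Flux recovery**: 200-genome datasets with 1000 families and
  $\phi = 0.5$; the DEF+/DEF− median gain ratio over sister pairs pooled
  across 6–10 seeds recovers $\phi$ from ground-truth counts and keeps its
  sign and significance through the full inference pipeline (the inferred
  ratio is attenuated toward 1 by roughly 15% — posterior expectations
  under a single global model smooth clade-specific signal).
* **Timescale stratification**: pair depths below $10^{-5}$ and above
  $10^{-3}$ substitutions/site cannot coexist in a single fixed-rate
  simulated species (defense structure concentrates at the turnover
  scale), so the experiment pools 30 simulated species whose depths span
  $2\times10^{-5}$ to $5\times10^{-2}$, with MGE turnover scaling as
  1/depth (self-similar defense structure) and gene turnover as
  depth$^{-0.6}$ (weakly faster in shallow, clonal species — so recent
  clades carry genuinely small event counts). This mirrors the
  cross-species pooling of the original analysis.

## Numerical choices and degenerate inputs

Pruning partials are rescaled per node with log-scale accumulators;
likelihood optimization tolerances are $10^{-8}$ (inner Newton and
L-BFGS-B factr equivalent); the uniformization series truncates at
$10^{-10}$ Poisson tail mass; semi-definite covariances receive a
$10^{-8}$-scaled ridge only if Cholesky fails. All-constant presence
matrices, all-singleton family sets, single-leaf clades, empty strata,
zero-length branch sums and empty event margins are rejected or flagged
explicitly rather than silently dropped — the only silent behavior anywhere
is the documented exclusion of non-finite log-ratios, which is always
reported alongside as a count.

## Known limitations

* The PGLMM is Laplace-approximate; numerical equality with other
  mixed-model implementations is promised only at the contract level
  (same model, matching estimates to optimizer precision).
* One defense system per simulated dataset; multi-system data are produced
  by independent runs sharing a tree.
* The gain/loss model shares one $(g, l, \alpha)$ across families; strong
  between-class rate differences are absorbed by the gamma mixture and by
  per-family category posteriors, at the cost of the ratio attenuation
  noted above.
* Negative-binomial responses, defense-system interactions, and
  multi-species joint fitting are out of scope; the per-species reduction
  is exact for the block-diagonal covariance structure the joint model
  would use.
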