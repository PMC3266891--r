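---
title: "Latent genetic-profile models for gene-environment interaction"
author: "gepotts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent genetic-profile models for gene-environment interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A case-control study has measured an established environmental risk factor
$E$ (binary or continuous), optional covariates $X$, and genotypes at $J$
SNPs in one candidate region, coded 0/1/2 as minor-allele counts. The
question is whether the effect of $E$ on disease risk varies with the
genetic background in the region — gene-environment (G-E) interaction at
the *region* level. Testing each SNP against $E$ one at a time
misrepresents the genetic contribution when several (possibly ungenotyped)
functional loci act together; `gepotts` instead treats the *joint*
multilocus genotype as the genetic unit.

## The model

Let $H$ be the number of distinct multilocus genotypes observed in the
sample and $c_i \in \{1,\dots,H\}$ subject $i$'s genotype id. A latent
allocation vector $z = (z_1,\dots,z_H)$, $z_h \in \{1,\dots,K\}$, assigns
every distinct genotype to one of $K$ risk clusters (the latent genetic
profile $L$). Subjects whose genotypes share a cluster share a logistic
risk model:

$$\operatorname{logit} P(D_i = 1) =
  \alpha_{z(c_i)} + \beta_{z(c_i)} E_i + \gamma' X_i ,$$

so each cluster has its own baseline log odds $\alpha_k$ and exposure log
odds ratio $\beta_k$. G-E interaction is exactly the statement that the
$\beta_k$ are not all equal; the companion *no-interaction* form shares a
single $\beta$ across clusters. The prospective likelihood is used for the
retrospectively sampled data: odds-ratio parameters are validly estimated,
while the intercept *levels* are not identified — only intercept contrasts
are interpreted, and recovery checks always compare $\alpha$ differences
after re-centring (we shift per-subject posterior medians so the reference
cluster's median is zero).

### Genotype space and the Potts prior

Similar genotypes should tend to share a cluster. Distance between
distinct genotypes $h, h'$ is the variance-standardized squared distance
$d(h,h') = \sum_j (g_{hj} - g_{h'j})^2 / s_j^2$, with $s_j^2$ the sample
variance (divide-by-$n$) of SNP $j$'s code over all subjects; the
standardization stops common SNPs from dominating the geometry, and the
upstream tag-SNP thinning (pairwise $r^2 < 0.8$; a convenience pruner
`prune_r2()` is included) stops a block of redundant SNPs from doing the
same. Each genotype's neighbourhood is its 4 nearest distinct genotypes;
the weight is $w_{hh'} = 2$ for mutual neighbours, 1 for one-way
neighbours, 0 otherwise. Ties at the $k$-th-nearest distance are broken by
ascending genotype id, so the graph is reproducible without a seed.

The allocation vector gets the Potts prior
$\pi(z \mid \psi) \propto \exp\{\psi U(z)\}$, with
$U(z) = \sum_{h<h'} w_{hh'} I(z_h = z_{h'})$. The coupling $\psi \ge 0$
regulates spatial dependence: at $\psi = 0$ labels are independent uniform
(neighbour co-assignment probability exactly $1/K$), and co-assignment
rises towards 1 as $\psi$ grows. Past a critical coupling the Potts model
collapses into one label (phase transition) and chains freeze, so $\psi$
gets a uniform prior on $[0, \psi_{\max}]$ with $\psi_{\max} = 1.2$ by
default — near the value where the co-assignment probability saturates
(about 0.97 on graphs of this type) — and configurable.

Coefficients get independent normal(0, variance 4) priors by default; a
uniform prior on $[-10, 10]$ is available (`prior = "uniform"`), the
half-width configurable because reasonable choices are equivalent in
practice for these data sizes.

## Posterior computation

Each MCMC sweep updates three blocks:

1. **Coefficients** — Gaussian random-walk Metropolis-Hastings per
   coefficient. An optional burn-in tuner (on by default) nudges each
   proposal scale toward a 20-45% acceptance window and freezes it after
   burn-in, preserving the invariant distribution.
2. **Allocations** — single-site Metropolized Gibbs: the full conditional
   over clusters is computed from the Potts term $\psi u_{hk}$ (summed
   neighbour weight into cluster $k$) times the Bernoulli likelihood of
   the genotype's subjects; the proposal is the conditional restricted to
   non-current clusters, accepted with the usual ratio, which mixes faster
   than plain Gibbs on discrete spaces.
3. **Coupling** — Monte Carlo Metropolis-Hastings (MCMH). The acceptance
   ratio for a reflected random-walk proposal $\psi'$ needs the
   intractable normalizing-constant ratio $Z(\psi)/Z(\psi')$; it is
   replaced by the importance-sampling estimate
   $\frac{1}{m}\sum_{s} \exp\{(\psi'-\psi)\,U(z_s)\}$ over $m$ auxiliary
   draws $z_s$ from the Potts prior at the current $\psi$ (default
   $m = 50$; 50-100 works well).

Two implementation choices matter enough to state. First, the auxiliary
draws come from a single prior-only Gibbs chain *started at the current
allocation state* and thinned by `aux_sweeps` sweeps, not from fresh
uniform starts: in the strongly coupled regime a short chain from a
uniform start cannot reach the ordered phase, the ratio estimate is biased
low, upward moves of $\psi$ are systematically over-accepted, and the
sampler freezes at $\psi_{\max}$ with a collapsed allocation — we observed
exactly this failure before adopting the current scheme, and the MCMH
update is validated against an exact-normalizer sampler by enumeration on
small graphs in the test suite. Second, coefficients initialize at the
cluster-wise logistic MLE given the initial partition (k-medoids on the
genotype distance by default) rather than at zero: a zero start makes all
labels likelihood-equivalent, and the Potts prior then collapses the
allocation before the coefficients can differentiate. $\psi$ starts at
$\psi_{\max}/2$.

When the exposure is binary and there are no covariates, the Bernoulli
likelihood factorizes through per-genotype counts of the four
$(D, E)$ cells, and all three blocks reduce to table arithmetic; the
general per-subject path handles continuous exposure and covariates. On
integral-weight graphs the prior-only sweeps use an $\exp(\psi u)$ lookup
table. Chains are fully reproducible given `seed`.

Default schedule: 200,000 iterations, the first 100,000 discarded,
thinning 10. Chains on data of the sizes studied here converge well before
100,000 iterations; the desk preset (`gep_control(preset = "desk")`) and
the per-test configurations below use much shorter runs.

## Choosing the number of clusters

For each $K$ the deviance information criterion is computed as
$\mathrm{DIC} = 2\bar D - \hat D$, where $\bar D$ is the posterior mean
deviance and $\hat D$ the deviance at the plug-in built from *per-subject*
posterior means of the assigned intercept and slope (plus posterior-mean
$\gamma$). The per-subject plug-in makes DIC exactly invariant under
cluster relabelling, so no relabelling post-processing is needed; where
the alternative (cluster-level means after relabelling) could be meant
instead, we adopt and state the per-subject reading. With one run per $K$
the **+1 rule** picks the smallest $K$ whose DIC is within 1 of the
minimum (the Monte Carlo SE of a converged chain's DIC is typically below
1); with repeated runs per $K$ the **+1 SE rule** replaces 1 by the Monte
Carlo standard error of the mean DIC at the minimizing $K$.

## Consensus clustering

Posterior allocation draws are summarized by the co-assignment matrix
$\pi_{hh'}$ (fraction of draws with $z_h = z_{h'}$), which is invariant to
label switching. Genotypes are then partitioned into $K^*$ clusters by
partitioning around medoids (PAM) with dissimilarity $1 - \pi$. PAM is
implemented in-package (BUILD then best-improvement SWAP with the standard
nearest/second-nearest delta formula) so that an arbitrary precomputed
dissimilarity is always accepted; ties break by lowest index, making the
partition deterministic. The exhaustive-search oracle in the tests
confirms the objective on small instances, and `cluster::pam` serves as an
independent cross-check.

## The interaction test

The test statistic is the nominal p-value $p_{\text{obs}}$ of the
likelihood-ratio test (on $K_1^*-1$ df) comparing logistic models with and
without $L \times E$ terms, where $L$ is the consensus assignment from the
interaction-form fit with $K_1^* \ge 2$ chosen by the +1 rule. Because $L$
is estimated from the data, $p_{\text{obs}}$ is anti-conservative, so it
is calibrated by a parametric bootstrap: fit the no-interaction Bayesian
model, build its consensus assignment $L_0$ and the MLE logistic null
(cluster main effect + exposure + covariates), regenerate every outcome
from the fitted null probabilities $B$ times, rerun the entire interaction
arm on each replicate, and report
$$p = \frac{1 + \#\{T_b \le p_{\text{obs}}\}}{B + 1},$$
the add-one estimator, which never returns zero and is valid by
construction. Replicate evidence is compared on the p-value scale (smaller
is more extreme). $K_1^*$ is re-selected on every replicate by default —
the replicate must run the same procedure as the observed data — with
`reselect_k = FALSE` available to freeze it. If the +1 rule restricted to
the grid prefers its lower bound, $K = 2$ is used, since the test is
undefined at $K = 1$.

The comparators are the two standard region-level tests: **minP-SNP**
(per SNP, a 2-df LRT of SNP$\times E$ with the SNP as a three-level
categorical variable; statistic = minimum nominal p over SNPs) and
**minP-PC** (per principal component of the centred code matrix, a 1-df
LRT of PC$\times E$). Both minima are calibrated by the same parametric
bootstrap under a main-effects null; for minP-SNP we use additive
(per-allele) SNP main effects in the null — the original procedure's
calibration null is not spelled out, and the additive choice avoids the
separation problems of 30 categorical main-effect columns. PC scores are
fixed across replicates because genotypes never change; loading signs are
fixed by making the largest-absolute loading positive.

## The simulator

`simulate_case_control()` reproduces the design of the method's simulation
studies: draw genotypes, draw genotype-dependent exposure, then fill
case/control quotas by rejection sampling of outcomes under a
cluster-structured logistic risk model.

* **Population.** Individual-level data from the motivating study are not
  public, so `default_population()` is a synthetic surrogate: three 5-SNP
  LD blocks, each carrying a pool of 5 common haplotypes whose patterns
  come from a latent AR(1) Gaussian copula (correlation 0.9) and whose
  frequencies are fitted so block allele frequencies match the published
  15 tag-SNP MAFs (0.32, 0.22, ..., 0.24); 5% of haplotypes are drawn
  fresh from the copula as a rare-haplotype tail. Subjects are two
  independent pool haplotypes (Hardy-Weinberg at the haplotype level).
  The pool sizes were chosen so the genotype-space diversity matches a
  real candidate region — roughly 650-700 distinct genotypes per 3,000
  subjects, against 766 in the motivating data — because diversity drives
  both the difficulty of the latent clustering and the cost of the MCMC.
  What this surrogate does *not* emulate: the exact joint LD structure of
  the real region, genotyping error, and missingness; absolute simulation
  numbers from the original study are therefore only approximately
  transferable, and all acceptance checks are property-based.
* **Cluster rules.** Built-ins cover the published designs: the
  three-region rule on the total risk-allele count at functional SNPs 2,
  6, 10 (regions $\le 1$ / $= 2$ / $> 2$), two-cluster threshold rules,
  and single-SNP dominant/additive rules; arbitrary labelling functions
  are accepted.
* **Exposure.** Bernoulli given the true cluster: probability 0.3 of
  exposure in region I, 0.6 elsewhere — the published G-dependent
  exposure model.
* **Sampling.** The working baseline (default: 5% risk for an unexposed
  reference-cluster subject) is absorbed into the non-identified
  intercept, so it only affects rejection efficiency; quotas are exact and
  the generating truth (labels, coefficients) travels with the dataset.
  The generating coefficients of the original simulation tables are not
  recoverable from the source, so they are explicit user inputs; the
  defaults used in our own studies are stated below.

## Study configurations used by the package's checks

The test-suite studies run at desk scale; sizes were fixed as the
package's own choices and are stated here so the checks are
interpretable:

* *Potts calibration*: graph from 1,200 simulated subjects (about 450
  distinct genotypes), 10,000 Gibbs draws at $\psi = 0$, $K = 2$; the
  neighbour co-assignment probability must equal 1/2 within three Monte
  Carlo standard errors.
* *Type-I calibration*: null model with genetic main effect OR 4 (regions
  II and III vs I) and exposure OR 4; 40 datasets of 600 cases / 600
  controls; $B = 19$ bootstrap replicates with 1,200-iteration chains and
  the candidate grid $\{2\}$ ($\{1,2\}$ for the null arm). With $B = 19$
  the add-one p-value attains the nominal 0.05 and 0.10 exactly, and the
  nominal level must fall inside the 95% binomial interval of the
  estimated rejection rate. The original validation used 1,000 datasets
  and 1,000 bootstrap replicates on a cluster; the reduced design checks
  the same property with correspondingly wider Monte Carlo bands.
* *Oracle equivalences*: the MCMH ratio estimator against enumeration;
  the $K = 1$ chain against the logistic MLE; PAM against exhaustive
  medoid search; DIC against per-draw relabelling.
* *Recovery*: two clusters (threshold rule on SNPs 2, 6, 10), intercept
  contrast 1.6, slope contrast 2.0 ($\beta = 0.2$ vs 2.2) — the "strong
  effects" design; 20 replicates of 750 cases / 750 controls,
  6,000-iteration chains over $K \in \{1,2,3\}$. Checks: the +1 rule
  selects $K = 2$ in the majority of replicates; cluster-wise median
  absolute error of per-subject slope medians below 25% of the contrast;
  mean consensus agreement with the generating partition at least 0.9.
* *Power ordering*: interaction clusters from a 6-SNP threshold rule
  (no single SNP expresses the partition), slope 0.2 vs 1.6; 12 datasets
  of 600 + 600; the bootstrap test's empirical power at the 0.05 level
  must exceed both minP comparators'.

## Numerical and degenerate-input policy

Bernoulli log-likelihoods are computed through `log1p` branches stable for
extreme linear predictors. Monomorphic SNPs are rejected at load time
(they have no variance to standardize by); missing genotypes are rejected,
with `impute_genotypes()` offering rounded-mean imputation upstream. A
zero proposal scale yields a well-defined degenerate chain (useful for
freezing blocks in tests). Quasi-separated logistic fits in the test layer
are reported with a convergence flag rather than an error; bootstrap
replicates that fail entirely are dropped and the effective $B$ reported.
`regroup_genotypes()` can cap the Potts lattice size by merging genotypes
into pseudo-genotype subgroups (medoid codes, remapped subjects) for very
large genotype spaces, at a cost in cluster resolution — our own studies
run on the full genotype space.

## Known limitations

The number of clusters is selected, not sampled: a reversible-jump
treatment of $K$ is out of scope. The bootstrap test is computationally
heavy by construction ($B$ full refits); the short per-replicate preset
trades posterior polish for calibration validity, which is preserved
because observed and replicate data run the identical procedure. The
consensus partition is a point summary — uncertainty lives in the
co-assignment matrix, which is exported. The exposure enters linearly on
the log-odds scale within cluster; categorical exposures with more than
two levels are not yet supported.
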