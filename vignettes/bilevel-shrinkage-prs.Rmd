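---
title: "Bilevel continuous shrinkage for polygenic risk scores: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilevel continuous shrinkage for polygenic risk scores: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilevelprs)
```

## The problem

A polygenic risk score (PRS) summarises an individual's genetic liability as
a weighted sum of allele dosages, with weights estimated from genome-wide
association study (GWAS) summary statistics. Two empirical facts motivate
this package. First, effect sizes are sparse: most variants contribute
essentially nothing, which continuous global-local shrinkage priors (the
horseshoe family) handle well. Second, heritability is not spread uniformly
over functional annotation categories — some gene-based classes or pathways
are strongly enriched — and that *group-level* structure is itself often
sparse. `bilevelprs` places a shrinkage scale at both levels: one per
annotation group and one per variant, so that whole groups can be shrunk
hard while enriched groups keep their signal.

## Model

With standardized phenotype $y$ ($N$ individuals) and standardized genotypes
$G$ ($N \times M$),

$$ y = G\beta + \epsilon, \qquad \epsilon \sim \mathcal N(0, \sigma^2 I_N),
\qquad p(\sigma^2) \propto \sigma^{-2}. $$

Each variant $j$ carries a set of annotation labels $A_j$ (possibly several:
pathway annotations overlap; variants with none get the sentinel group
`"__none__"`). A variant with $|A_j|$ labels is expanded into $|A_j|$
*copies*, one per group, and the model is fit on the $M' = \sum_j |A_j|$
copies; the variant's total effect is the sum over its copies. For copy $j$
in group $k$,

$$ \beta_j \mid \sigma^2, \delta_k^2, \lambda_j^2 \sim
\mathcal N\!\left(0, \tfrac{\sigma^2}{N}\, \delta_k^2 \lambda_j^2\right),
\qquad \delta_k \sim C^+(0,1), \qquad \lambda_j \sim C^+(0,1), $$

a bilevel global-local prior: $\delta_k^2$ is the group scale, $\lambda_j^2$
the local scale. With $K = 1$ the model is exactly the fully Bayesian
single-scale continuous-shrinkage sampler (PRS-CS-auto with its gamma-gamma
hyper-parameters at $a_0 = 0.5$, $b_0 = 1$), available directly as
`prscs_auto()`.

Only summary statistics enter the fit: marginal effects
$\hat\beta = G^\top y / N$ and a block-diagonal LD matrix $D = G^\top G / N$
estimated from an external reference panel. The effect-size conditional is

$$ \beta \mid \cdot \sim \mathrm{MVN}\!\left( (D + \Psi^{-1})^{-1} \hat\beta,\;
\tfrac{\sigma^2}{N} (D + \Psi^{-1})^{-1} \right),
\qquad \Psi = \mathrm{diag}(\delta^2_{k(j)} \lambda_j^2), $$

drawn block-by-block (cross-block LD is taken as zero), and

$$ \sigma^2 \mid \cdot \sim \mathrm{IG}\!\left( \tfrac{N + M'}{2},\;
\tfrac{N}{2}\big(1 - 2\beta^\top \hat\beta + \beta^\top (D + \Psi^{-1})\beta\big) \right). $$

## The scale conditionals and a parametrization subtlety

The half-Cauchy prior is implemented through its inverse-gamma scale
mixture: if $a \sim \mathrm{IG}(\tfrac12, 1)$ and
$x^2 \mid a \sim \mathrm{IG}(\tfrac12, 1/a)$, then $x \sim C^+(0,1)$.
`half_cauchy_mixture_check()` verifies this construction by simulation
(Kolmogorov–Smirnov distance against the CDF $\tfrac2\pi \arctan x$,
median $\approx 1$, 75th percentile $\approx \tan(3\pi/8)$). Note the
$1/a$: the mixture with rate $a$ instead does *not* have a half-Cauchy
marginal (its KS distance is about 0.5).

With auxiliaries $t_k$ (for $\delta_k^2$) and $c_j$ (for $\lambda_j^2$),
the full conditionals implied by this prior are, in the package's default
`mode = "derived"`:

$$ \lambda_j^2 \mid \cdot \sim \mathrm{IG}\!\left(1,\;
\frac{N\beta_j^2}{2\sigma^2 \delta_k^2} + \frac1{c_j}\right), \qquad
c_j \mid \lambda_j^2 \sim \mathrm{IG}\!\left(1, \frac1{\lambda_j^2} + 1\right), $$

$$ \delta_k^2 \mid \cdot \sim \mathrm{IG}\!\left(\frac{M_k + 1}{2},\;
\sum_{j \in k} \frac{N\beta_j^2}{2\sigma^2 \lambda_j^2} + \frac1{t_k}\right),
\qquad t_k \mid \delta_k^2 \sim \mathrm{IG}\!\left(1, \frac1{\delta_k^2} + 1\right). $$

These conditionals are frequently written with the auxiliary entering as
$+\,c_j$ and $+\,t_k$ and without the $\delta_k^2$ factor in the local
rate. That version is retained as `mode = "as_printed"`, but it is not the
full conditional of the stated model: cycling it does not preserve the
half-Cauchy marginal, and on one-variant instances its posterior mean
deviates from deterministic grid integration of the joint density by more
than the sampler's Monte-Carlo error, while `"derived"` agrees to third
decimal. The grid oracle (effects and residual variance integrated
analytically, the scales on a log grid with the exact half-Cauchy density)
is part of the test suite and is the package's primary correctness
evidence.

## Sampler mechanics and numerical choices

* **Systematic scan.** Each sweep updates the effect blocks (Cholesky
  factorization of $D_b + \Psi_b^{-1}$), then $\sigma^2$, then
  $(\lambda^2, c)$, then $(\delta^2, t)$. The core loop is C++
  (RcppArmadillo) driven by R's RNG, so a run is fully reproducible from
  `gibbs_config(seed = )`.
* **Group rescale move.** The likelihood constrains only the products
  $\delta_k^2\lambda_j^2$; the split between the two levels is identified
  by the priors alone, and single-site updates mix arbitrarily slowly along
  the ridge $(\delta_k^2 u, \lambda_j^2/u)$. After each sweep the sampler
  proposes exactly that move per group (log-normal $u$, Metropolis-accepted
  under the collapsed half-Cauchy prior, auxiliaries refreshed from their
  conditionals). Without it, the group scales can drift to $10^{14}$ and
  carry no information; with it they concentrate where the prior puts them.
* **Shrinkage cap.** The products $\delta^2\lambda^2$ are clipped above at
  `shrink_cap` (default 1, the convention of summary-statistic
  continuous-shrinkage samplers) before entering the effect update, which
  bounds the condition number of $D_b + \Psi_b^{-1}$. Oracle tests run with
  `shrink_cap = Inf`, where the chain targets the exact model.
* **Residual-variance guard.** With an out-of-sample LD reference and
  $M' > N$ the data part of the $\sigma^2$ rate,
  $1 - 2\beta^\top\hat\beta + \beta^\top(D+\Psi^{-1})\beta$, can go
  negative (it is only guaranteed non-negative when $D$ is the in-sample
  LD). The rate is therefore bounded below by the prior quadratic term
  $\tfrac N2 \sum_j \beta_j^2/\psi_j$ (and by $10^{-12}$). Without the
  guard $\sigma^2$ collapses to the floor within a few iterations and the
  scales explode; with a consistent $D$ the guard never binds, so the
  oracle checks are unaffected.
* **Chain defaults.** `n_iter = 1000`, `n_burnin = 500`, `thin = 5`,
  matching common practice for this model class. Posterior means are
  accumulated over every post-burn-in sweep; `thin` only subsamples the
  stored diagnostic traces. The oracle tests use longer chains (20k–40k
  sweeps) because they assert agreement to 0.01.
* **Degenerate inputs.** Non-positive-definite LD blocks are rejected at
  construction with a pointer to the ridge-repair flag
  (`ld_block(..., ridge = 1e-6)` adds $\epsilon I$ and rescales to unit
  diagonal); monomorphic reference variants are dropped with a message;
  inverse-gamma rates are floored at tiny positive values.

## Scores, weights, and the hybrid

Group-wise scores are $\mathrm{PRS}_k = \sum_{j \in k} G_j \tilde\beta_j$
over the copies of group $k$ (`group_scores()`), so the group columns sum
to the conventional total PRS. Combination weights $\alpha_k$ are estimated
by 10-fold cross-validation on a separate individual-level sample
(`fit_alpha_cv()`): within each fold the phenotype is regressed on the $K$
score columns plus an intercept — least squares for quantitative traits,
logistic regression for binary ones — the held-out tenth is scored (AUC,
and $R^2$ or Efron's pseudo-$R^2$), and the exported $\alpha$ is the
across-fold mean. Folds come from a seeded permutation stratified by case
status so every fold sees both classes. The regression family, the
averaging rule and the unconstrained sign of $\alpha$ are choices the
underlying method description leaves open; non-negative weights are
available behind `nonneg = TRUE` (glmnet at zero penalty). The hybrid
score adds a conventional single-group PRS as an extra regression column,
so its weight $\gamma$ is fitted jointly with the $\alpha_k$.

## The comparator

`ldpred_funct_posterior()` implements the closed-form annotation-informed
posterior in the style of LDpred-funct: under
$\beta_j \sim \mathcal N(0, c\,\sigma_j^2)$ with per-SNP heritabilities
$\sigma_j^2$, the posterior mean solves $W x = N\hat\beta$ per block with
$W = ND + \tfrac1c \mathrm{diag}(1/\sigma_j^2)$. The normalizing constant
$c$ is set so $\sum_j c\,\sigma_j^2$ equals the supplied total
heritability. Variants are then ranked by $|{\rm posterior\ mean}|$ and
greedily partitioned into $L = 40$ bins of approximately equal squared
posterior mass (a bin closes when it reaches $\tfrac1L$ of the total, or
when exactly enough variants remain to fill the remaining bins — the
original binning algorithm is not specified precisely, and this greedy
rule is a deterministic, testable reconstruction). Bin scores feed the
same `fit_alpha_cv()` machinery. In simulations the true stratified
per-SNP heritabilities are supplied ($\sigma_j^2 = (q_k/100)h^2/M_k$ for a
variant in group $k$); stratified LD-score regression is out of scope.

## The simulation engine

`run_setting()` reproduces the seven-setting simulation design at a chosen
scale. At scale 1 the settings place $M = 125{,}000$ variants in $K$ groups
(sizes $M_k$ as in `sim_settings()`), with causal proportions $p_k$ per
group and heritability shares $q_k$, total $h^2 = 0.7$, a GWAS sample of
50,000 and a test sample of 24,000. The package's working scale is 0.02
($M = 2{,}500$, $N_{\rm sumstat} = 1{,}000$, $N_{\rm test} = 480$), which
keeps a full two-method, ten-replicate comparison inside a few minutes on
one CPU; all proportions are preserved under scaling.

* **Genotypes.** Real biobank genotypes are access-restricted, so dosages
  are synthesized from two thresholded latent Gaussian haplotypes with
  AR(1) within-block correlation ($\rho = 0.7$; block size 500 at full
  scale, 100 at desk scales) and uniform MAF in $(0.01, 0.5)$, then
  column-standardized. The LD blocks handed to the sampler are estimated
  from a held-out reference sample of 500 individuals from the same
  process, mirroring the size of a 1000-Genomes-style external panel —
  so the reference-vs-GWAS LD mismatch of real analyses is present.
* **Effects.** Point-normal per variant: causal with probability
  $p_{A_j}$, and then
  $\beta_j \sim \mathcal N\!\big(0,\, q_{A_j} h^2 / (p_{A_j} M)\big)$.
  As printed, this variance makes group $k$'s expected contribution
  proportional to $q_k M_k / M$ rather than $q_k$ alone; the package
  implements the printed form by default and offers
  `variance_mode = "group_normalized"` for the $q_k$-proportional variant.
  Neither is claimed to match the original software. At reduced scale a
  group may hold only a handful of causal variants, so by default each
  group's realized squared-effect share is rescaled to the formula's
  expected share (`normalize_shares = TRUE`) — the group-level analogue of
  fixing total $h^2$ exactly, without which a designed 90/10 split can
  realize as 57/43 and the architecture under test disappears.
* **Overlap settings.** The overlap geometry of the original study is not
  recoverable from the text, so patterns are parameterized by a target
  intersection-over-union (default 0.5): pattern I overlaps the two
  zero-heritability groups, pattern II the 10%/90% groups, achieved by
  adding the partner label to a random subset of each partition cell. The
  true effects are always drawn from the underlying partition — settings
  sharing one parameter row share one generative architecture, and the
  overlap pattern changes only the labels the fitted model sees. (For
  annotation maps that genuinely overlap at generation time,
  `draw_effects()` resolves a multi-labelled variant to its member group
  with the largest $q_k$.)
* **Phenotypes and GWAS.** $y = G\beta + e$ with the noise orthogonalized
  and scaled so the in-sample genetic variance fraction is exactly $h^2$,
  then standardized. Marginal effects are computed directly as
  $G_j^\top y/N$ on standardized data; the original study's mixed-model
  GWAS is equivalent here because simulated individuals are unrelated and
  phenotypes Gaussian. For AUC the simulated liability's top decile
  (ceiling rule, stable ties) defines the cases.

What the generator does *not* emulate: allele-frequency-dependent
architectures, long-range LD and realistic recombination structure,
relatedness, case-control ascertainment, cross-population differences.
Passing desk-scale tests therefore demonstrates internal correctness of
the sampler and the qualitative group-sparsity behaviour, not real-data
performance.

## What the desk-scale experiments show

With ten seeded replicates of the reduced Setting 1 (one group holding 90%
of $h^2$, two holding none), the bilevel model's posterior group scales
rank the signal group above both null groups in 9–10 of 10 replicates, and
its cross-validated AUC beats the single-group special case decisively
(paired one-sided test). Under equal shares (Setting 4) the two methods
are indistinguishable (|mean AUC difference| < 0.01), as expected — with
no group structure the group scales behave like one global scale. In the
overlap settings both patterns retain a large gain over the single-group
model; the contrast *between* the two patterns that the original
full-scale study reports does not reproduce at scale 0.02, where the gain
is dominated by shrinking the two null groups (70% of variants) — a
component both patterns leave intact. This limitation is reported by the
acceptance checks rather than hidden; at full scale the balance of
mechanisms is different and the published contrast may well reappear.

## Known limitations

* The group scales are weakly identified when a group holds very few
  causal variants; their posterior means are heavy-tailed summaries and
  should be read as rankings, not effect estimates.
* Cross-block LD is assumed zero; block boundaries are the user's
  responsibility (or the simulator's).
* A single GWAS sample size is used for all variants; per-variant N
  columns are collapsed to their median with a warning.
* Covariates (age, sex, principal components) are not part of the weight
  regression.
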