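---
title: "Whole-genome regression with spike-plus-Laplace priors: model, test and simulator"
author: "gsbayes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome regression with spike-plus-Laplace priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

A quantitative trait of $n$ individuals, centred by the population mean, is
regressed jointly on standardized genotype codes at $p$ SNPs:

$$y = Wb + Xg + e, \qquad e \sim N(0, I\sigma_e^2).$$

The design matrix has up to three blocks, $X = (X_a, X_d, X_e)$:

* **Additive.** With minor allele frequency $f_j \le 1/2$, raw codes
  $\{1, 0, -1\}$ (AA, Aa, BB) map to $2(1-f_j)/s_j$, $(1-2f_j)/s_j$,
  $-2f_j/s_j$.  The scaling is $s_j = \sqrt{2f_j(1-f_j)}$, so that the
  column has mean 0 and variance 1 under Hardy–Weinberg proportions.  The
  square-root convention matters: dividing by $2f_j(1-f_j)$ itself would
  leave the columns with unequal variances and a single $(\gamma,\lambda)$
  prior would no longer be exchangeable across loci.  (The dominance
  denominator, by the same argument, is $s_j^2 = 2f_j(1-f_j)$.)
* **Dominance** (Falconer parameterization in a random-mating population):
  AA $\to -2(1-f_j)^2/s_j^2$, Aa $\to 2f_j(1-f_j)/s_j^2$, BB $\to
  -2f_j^2/s_j^2$.  Under HWE this column also has mean 0, variance 1, and
  is exactly orthogonal to the additive column of the same locus — the unit
  tests assert all three identities to $10^{-12}$ across a grid of $f$.
* **Epistasis.** Four kinds of pairwise interactions (a×a, a×d, d×a, d×d),
  each column the elementwise product of the two main-effect columns,
  giving $2p(p-1)$ coordinates in total.

Minor allele frequencies are taken from the supplied table when available
(e.g. the simulator's training-set frequencies) and otherwise estimated by
the method of moments $f_j = \frac{1}{2n}\sum_i (X_{ij}+1)$; when the raw
estimate exceeds $1/2$ the allele labels are swapped by negating the codes,
so $f_j \le 1/2$ always holds downstream.

Every genetic effect carries an independent spike-plus-Laplace prior

$$p(g\mid\gamma) = \tfrac{\gamma\lambda}{2} e^{-\lambda |g|} + (1-\gamma)\,\delta_0 .$$

Defaults follow the hyperparameter rule used throughout the simulation
study: $\gamma = 0.005$, $\lambda = 2p\gamma$ for main effects and
$\gamma = 10^{-6}$, $\lambda = p(p-1)\gamma$ for epistatic effects, with
$p$ the panel size after MAF filtering.  `tune_gamma()` implements the
alternative of choosing $\gamma$ by a random half split, refitting over a
grid and keeping the value with the best held-out accuracy.

## One-locus posterior and the solver

Conditionally on the trait residualized for all other effects, each
coordinate reduces to the one-locus model $y_j = x g + e$ with sufficient
statistics $Y = (x'x)^{-1}x'y_j$ and $\sigma^2 = (x'x)^{-1}\sigma_e^2$.
The posterior expectation is available in closed form through the weights
$T_1 = e^{-\lambda Y}(1-\Phi(0; Y_-,\sigma^2))$,
$T_2 = e^{\lambda Y}\Phi(0; Y_+,\sigma^2)$,
$T_3 = \frac{2(1-\gamma)}{\gamma\lambda} e^{-\lambda^2\sigma^2/2}\phi(0; Y,\sigma^2)$
and the zero-truncated normal means $\Theta_U,\Theta_L$, with
$Y_\pm = Y \pm \lambda\sigma^2$.

The `gsbayes()` solver visits coordinates in sweeps — additive, then
dominance, then the four epistatic kinds in pair-lexicographic order —
maintaining a running residual: each visit forms $Y$ from the residual,
replaces the effect by its posterior mean, and updates the residual by the
change.  Epistatic columns are recomputed on each visit and never stored,
so model M3 runs in $O(np^2)$ time per sweep and $O(np)$ memory.  With
covariates present, $b$ and $\sigma_e^2$ are re-estimated once per sweep by
the empirical-Bayes updates $b = (W'W)^{-1}W'(y - X\hat g)$ and
$\sigma_e^2 = e'e/(n-q)$.

Numerical choices:

* All weights and Gaussian tails live on the log scale and are combined by
  log-sum-exp; differences of Gaussian CDFs switch to the complementary
  tail whenever both arguments are positive, since lower-tail log
  probabilities underflow there.  The implementation is overflow-free for
  $|Y|/\sigma$ up to 40 and $\lambda\sigma$ up to about $10^3$, and in
  practice well beyond.
* Zero-truncated normal means use the log-scale Mills ratio, switching to
  the asymptotic series $(\sigma/a)(1 - 2/a^2 + 10/a^4 - 74/a^6)$ for
  truncation depths $a > 30$, where the direct form cancels
  catastrophically and rounding of the huge log tail is amplified.
* **Convergence** is declared when
  $\lVert \hat g^{(k)} - \hat g^{(k-1)}\rVert / \lVert \hat g^{(k)}\rVert < 10^{-4}$
  (configurable), with the norm taken over the full stacked effect vector
  of all kinds.  Per-coordinate ratios would be undefined at the many
  exact zeros produced by degenerate columns, and a whole-vector criterion
  also settles the open choice of when to assess convergence in M3.  A
  zero-over-zero ratio counts as converged.  Default `max_sweeps` is 500;
  a non-converged fit is returned with a warning and
  `converged = FALSE`, never silently.
* $x'x$ uses the realized sample columns, not the HWE expectation $n$,
  since standardization only guarantees unit variance in expectation.
* Without covariates and without a user-supplied value, $\sigma_e^2$ is
  initialized at the centred-trait variance and re-estimated as $e'e/n$
  after every sweep.  The empirical-Bayes update is only defined in the
  fixed-effects context, so this extension is a package choice; a fixed
  known $\sigma_e^2$ can be supplied and left untouched
  (`update_sigma = FALSE`).

## The significance test

For each coordinate, after convergence, the trait is residualized for all
other effects and two rules are evaluated.

**Measure of evidence.** The posterior of a single effect is a mixture of
a spike at zero and a continuous two-piece Gaussian slab
($f_1$ on $g<0$, $f_3$ on $g>0$, continuous at 0).  $\kappa$ is the
posterior mass of the HPD interval tangent to zero on the side of
$\hat g$: for $\hat g > 0$, $t_1 = 0$ and
$t_2 = \max\{g > 0 : p(g\mid y) \ge p(0\mid y)\}$.  Significance is
declared when $\mathrm{MOE} = 1-\kappa \le \alpha$.  The spike is excluded
from the comparison and from the interval mass: the CDF's jump at zero of
height $f_2(0)/p(y)$ does not move an interval tangent to zero.

The border search follows a grid over $[10\min(\hat g), 10\max(\hat g)]$
(min/max over the fitted effect vector of the coordinate's kind) with
2000 steps, falling back to a per-locus grid
$\pm 10(|\hat g_j| + \sigma)$ when the whole-vector bounds do not straddle
zero.  A closed-form border is also available (`exact = TRUE`): the
density equation on the positive side solves to $t_2 = 2(Y -
\lambda\sigma^2)$, clamped at zero.  Because
$\kappa \le P(g \ne 0 \mid y)$, any coordinate with
$P(g \ne 0\mid y) < 1 - \max(\alpha)$ can never be significant; for these
— the overwhelming majority under the spike prior, and all of the
$2p(p-1)$ epistatic null coordinates in M3 — `significance()` uses the
vectorized closed-form border instead of the grid.  Every significance
*decision* is identical to a full grid search; only the numerical
$\kappa$ of hopeless coordinates (reported for completeness) uses the
closed form.  Coordinates with $\hat g = 0$ exactly get $\kappa = 0$,
MOE $=1$ by convention, since the defining interval is empty.

One property worth knowing: $\kappa$ is *not* perfectly monotone in
$\lambda$.  Independent quadrature confirms genuine increases of order
$10^{-6}$ near $\kappa \approx 1$ (the tangent interval and the spike mass
shift together); the property tests therefore assert monotonicity with a
$10^{-5}$ slack.

**Bayes factor.** $B_j = \exp\{-(2\sigma_e^2)^{-1}(-2 y_j'x_j\hat g_j +
\hat g_j^2 x_j'x_j)\}$, the ratio of marginal likelihoods of the fitted
against the null one-locus model, computed and stored on the log scale;
$B_j > 3$ is reported as substantial.  Empirically the BF set contains the
MOE set; this is summarized by `moe_bf_agreement()` but not enforced.

No multiplicity correction is applied across loci: the evaluation design
works with raw per-effect $\alpha$ levels and measures specificity
directly.

## The simulator

`simulate_dataset()` emulates a dairy-cattle-like study design:

* ~52,773 SNPs on a 30-Morgan genome at full scale (30 chromosomes of 1
  Morgan — total map length is the stated quantity; the split into equal
  chromosomes is a package choice and configurable);
* founder haplotypes Bernoulli(1/2), then 400 burn-in generations of
  random mating among 100 individuals.  Meioses place crossovers as a
  Poisson process along the genetic map (Haldane, no interference) and
  flip each SNP allele with probability `mutation_rate` per meiosis;
* 4 final generations of 50 sires × 20 dams (1,000 offspring each;
  generations 1–2 are the n = 2,000 training set, 3–4 the validation
  set), giving paternal half-sib families;
* panel thinning to every 10th SNP with the causative variants forced in,
  then removal of SNPs with MAF ≤ 0.05 (training-set frequencies);
* 23 causative variants drawn among SNPs segregating above the MAF
  threshold, each with additive and dominance effects; 6 interacting
  pairs per epistatic kind drawn from the causatives.  Raw effects are
  standard normal; the dominance and epistasis blocks are rescaled so
  that their realized variance shares on the training genotypes are 10%
  and 29% of the genetic variance (the effect-size law and the
  per-replicate — rather than on-average — targeting of the shares are
  package choices); Gaussian residuals scale so the realized broad-sense
  heritability matches `h2` (0.3 or 0.5 in the study design).

Two stand-ins deserve emphasis.  First, physical positions: no base-pair
coordinates are part of the design, so the map adopts 1 cM ≡ 1 Mbp with
jittered-uniform SNP placement; the 100-kbp evaluation window is 0.1 cM,
which after 10× thinning almost always contains only the causative SNP
itself.  Second, the mutation rate: the default 2×10⁻³ per SNP per meiosis
is deliberately high — it substitutes for founder haplotype diversity so
that, after 400 generations of drift at population size 100, about 85% of
the thinned panel still segregates at MAF > 0.05, matching the marker
density the design describes (a Wright–Fisher frequency calculation puts
retention at ~19% under a biologically realistic 10⁻⁵).  Consequences for
realism: LD is generated by drift and pedigree rather than by a
coalescent-exact process, allele-frequency spectra are flatter than real
chip data, and there is no selection or demography.  Passing tests on this
generator show the estimator and test behave correctly under linked,
family-structured genotypes with the stated architecture — not that the
numbers transfer to any particular real population.

`permute_genotypes()` yields the matching null: genotype rows randomly
reassigned to animals, trait untouched, each shuffle reproducible from
(seed, index).

## Evaluation

* **Sensitivity/specificity** (`score_detection()`): a significant
  main-effect SNP is a true positive for its kind if it lies within
  100 kbp (configurable) of a causative variant on the same chromosome; a
  significant epistatic pair must match both windows of a truly
  interacting pair *of the same kind* (the kind-matching requirement is
  the stricter of the two defensible readings and can be relaxed with
  `match_kind = FALSE`).  Overall sensitivity counts a causative as found
  if any kind — including membership in a significant pair — hits its
  window.  Overall specificity is computed over all tested coordinates
  outside windows; for M3 the enormous negative class makes it
  numerically close to 1, which is why the study design reports it to
  four digits.
* **Explained genetic variance** (`explained_variance()`): variance of
  the significant-coordinates-only genetic values over training
  individuals, divided by the variance of the true simulated genetic
  values; it may exceed 1 and is not capped.
* **Prediction accuracy** (`prediction_accuracy()`): Pearson correlation
  between $X_{val}\hat g$ (all fitted coordinates, not only significant
  ones — the configurable default) and the true genetic values.

## Problem sizes used by the tests and the acceptance script

Full-fidelity replication of the study (52,773 SNPs, 100 replicates, M3
with ~39 million interaction coordinates) is cluster-scale.  The package's
own validation uses a reduced instance of the same design, chosen once:
5,000 SNPs on 3 Morgan — preserving the per-Morgan marker density and
hence the thinned-panel spacing of the full design — which yields ~450
analyzed SNPs after thinning and filtering, with n = 2,000 kept at full
size.  The acceptance script averages 10 replicates per heritability
level with models M1/M2 and runs 20 permutation-null shuffles; the test
suite uses 5 replicates plus a 2-replicate directional check that overall
sensitivity rises from M1 through M2 to M3.  Two scale effects are known
and documented rather than corrected: $\lambda = 2p\gamma$ is ~10× smaller
at the reduced $p$, so per-effect shrinkage is weaker and sensitivities
run a few points above the full-scale values; and M3's interaction space
is ~100× smaller, so epistasis recovery (and with it M3's overall
sensitivity and accuracy) is noticeably better than at full scale, which
is why M3 appears in the directional check rather than in level
comparisons.

## Limitations

* No population-structure or kinship correction: frequencies and effects
  assume exchangeable individuals beyond the modeled family structure;
  stratification biases the standardization.
* Genotypes must be complete; imputation is the caller's responsibility
  (the importer counts and reports missing entries).
* The significance machinery is marginal per coordinate; joint credible
  statements across loci are out of scope, as are FDR-style corrections.
* The locus-weighting extension (per-locus weights $w_j$ entering the
  one-locus covariate) and hierarchical priors on $\gamma$ are not
  implemented.
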