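# gsbayes

Approximate Bayesian whole-genome regression with a marginal significance
test for SNP effects.

## What it is for

In genomic evaluations (animal and plant breeding, and GWAS-style analyses
of unrelated individuals), a quantitative trait is regressed on all `p`
markers jointly:

    y = W b + X g + e,        e ~ N(0, I sigma_e^2),

where `y` is the trait of `n` individuals centred by the population mean,
`W b` are optional fixed effects, and `X` holds standardized genotype codes
for three kinds of effects — additive, dominance (Falconer coding under
Hardy–Weinberg proportions) and the four pairwise epistatic products
(a×a, a×d, d×a, d×d; `2p(p-1)` interaction coordinates in all.  Every effect
`g_j` carries a spike-plus-Laplace prior

    p(g | gamma) = (gamma * lambda / 2) exp(-lambda |g|) + (1 - gamma) delta_0.

The model is fitted by a marginalized Gauss–Seidel scheme: each coordinate
is re-estimated from the trait residualized for all other current
estimates, using the closed-form one-locus posterior expectation

    E(g | y) = [T1 ThetaU(0; Y-, s2) + T2 ThetaL(0; Y+, s2)] / (T1 + T2 + T3),

with `Y = (x'x)^-1 x'y`, `s2 = (x'x)^-1 sigma_e^2`, `Y± = Y ± lambda s2`,
and log-scale mixture weights `T1, T2, T3`.  Epistatic design columns are
built on the fly, so interaction scans of billions of coordinates need no
stored design matrix.

Two per-effect decision rules are computed after convergence:

* **Measure of evidence (MOE).** `kappa` is the posterior credibility of
  the highest-posterior-density interval tangent to zero on the side of the
  estimate (`(0, t2]` for `ghat > 0`); an effect is significant when
  `MOE = 1 - kappa <= alpha`.  The posterior CDF is available analytically,
  including its jump of height `f2(0)/p(y)` at zero.
* **Bayes factor.** `B = exp(-(1/2 sigma_e^2)(-2 y_j' x_j ghat + ghat^2 x_j' x_j))`
  against the null model `g_j = 0`; `B > 3` is reported as substantial.

The package also ships a forward-in-time population simulator (burn-in
random mating with recombination and mutation to build linkage
disequilibrium, then sire–dam generations giving half-sib families, and a
trait with configurable additive/dominance/epistasis variance shares and
heritability) plus evaluation utilities: window-based sensitivity and
specificity against the simulated causative variants, genetic variance
explained by significant effects, validation-set prediction accuracy, and
resampling-based tuning of `gamma`.

## Worked example

Simulate a cattle-like dataset at reduced genome size (5,000 SNPs on 3
Morgan, thinned to every 10th SNP plus the 23 causative variants, MAF >
0.05, n = 2,000 training and 2,000 validation individuals, broad-sense
heritability 0.5), fit the additive + dominance model and test every
effect:

```r
library(gsbayes)
cfg <- sim_config(n_snps = 5000, genome_morgan = 3, n_chr = 3,
                  h2 = 0.5, seed = 101)
ds  <- simulate_dataset(cfg)
fit <- gsbayes(ds$geno_train, ds$trait, model = "M2")
fit
#> Whole-genome regression fit (model M2)
#>   n = 2000  SNPs = 444
#>   nonzero effects: additive=444  dominance=444  epistasis=0
#>   sigma_e2 = 56.39  sweeps = 12 (converged)

ts <- significance(fit)
head(subset(as.data.frame(ts), sig_moe_0.05))   # 10 significant effects
#>         kind snp_i  ghat      moe log10_bf
#> 215 additive   215  2.31 0.00e+00     47.0
#> 301 additive   301  1.73 0.00e+00     26.5
#> 401 additive   401  1.73 0.00e+00     25.5
#> ...

score_detection(ts, ds$truth, alpha = 0.05)
#> detection at MOE <= 0.05 (window 100000 bp)
#>   sensitivity: a=0.391 d=0.043 e=NA overall=0.435
#>   specificity (overall): 1.0000  (FP=0 of 828 outside)

prediction_accuracy(fit, ds$geno_val, ds$truth$gv_val)
#> [1] 0.8286712
```

Reading: 39% of the causative variants are recovered through their additive
effects at MOE ≤ 0.05 with no false positives, and the fitted effects
predict the true genetic values of the held-out generations with
correlation 0.83.  `explained_variance()` reports the share of the
simulated genetic variance captured by the significant effects (0.52 here).

Model presets are nested: `"M1"` additive only, `"M2"` + dominance, `"M3"`
+ all pairwise epistasis.  `gsbayes()` objects support `print`, `summary`,
`coef`, `predict` (estimated genetic values for new genotypes),
`residuals`, `fitted`, `simulate` and `plot`.

A thin command-line interface over the same functions is installed at
`inst/scripts/wgr-cli.R` with subcommands `simulate`, `fit`, `test`,
`evaluate`, `permute-null` and `tune-gamma`; every run writes a JSON
manifest for reproducibility.

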