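# helpers: small genotype tables with controlled structure
orth_gt <- function() {
  # two SNPs whose realized additive columns are exactly orthogonal at f=1/2
  codes <- cbind(c(1L, 1L, -1L, -1L), c(1L, -1L, 1L, -1L))
  genotype_table(rbind(codes, codes), maf = c(0.5, 0.5))
}

test_that("single-SNP fit equals one application of the closed-form
           posterior mean", {
  set.seed(21)
  codes <- matrix(hwe_genotypes(200, 0.3), ncol = 1)
  gt <- genotype_table(codes, maf = 0.3)
  x <- code_additive(codes[, 1], 0.3)
  y <- x * 2 + rnorm(200, 0, 0.1)
  yc <- y - mean(y)
  se2 <- 0.25
  fit <- gsbayes(gt, y, model = "M1", gamma_main = 0.5, lambda_main = 1,
                 sigma_e2 = se2, update_sigma = FALSE)
  post <- locus_posterior(sum(x * yc) / sum(x * x), se2 / sum(x * x),
                          prior_spec(0.5, 1))
  expect_equal(fit$effects$additive[1], post$ghat, tolerance = 1e-10)
  expect_true(fit$converged)
  # noiseless signal on a balanced (zero-mean) column with a nearly flat
  # prior recovers the effect essentially exactly
  gt2 <- genotype_table(matrix(rep(c(1L, -1L), 100), ncol = 1), maf = 0.5)
  x2 <- code_additive(gt2$codes[, 1], 0.5)
  fit2 <- gsbayes(gt2, x2 * 2, model = "M1", gamma_main = 0.5,
                  lambda_main = 1e-6, sigma_e2 = se2, update_sigma = FALSE)
  expect_lt(abs(fit2$effects$additive[1] - 2), 1e-3)
  expect_lt(sum(fit2$residual^2), 1e-6)
})

test_that("orthogonal columns decouple into independent one-locus fits", {
  gt <- orth_gt()
  des <- gsbayes:::build_design(gt, need_dom = FALSE)
  expect_lt(abs(crossprod(des$Xa[, 1], des$Xa[, 2])), 1e-12)
  set.seed(8)
  y <- des$Xa %*% c(1.5, -0.7) + rnorm(8, 0, 0.2)
  se2 <- 0.3
  joint <- gsbayes(gt, as.numeric(y), model = "M1", gamma_main = 0.3,
                   lambda_main = 2, sigma_e2 = se2, update_sigma = FALSE)
  yc <- y - mean(y)
  for (j in 1:2) {
    x <- des$Xa[, j]
    post <- locus_posterior(sum(x * yc) / sum(x^2), se2 / sum(x^2),
                            prior_spec(0.3, 2))
    expect_equal(joint$effects$additive[j], post$ghat, tolerance = 1e-8)
  }
})

test_that("all-zero trait gives all-zero effects in one sweep", {
  gt <- orth_gt()
  fit <- gsbayes(gt, rep(0, 8), model = "M2", sigma_e2 = 1,
                 update_sigma = FALSE)
  expect_true(all(fit$effects$additive == 0))
  expect_true(all(fit$effects$dominance == 0))
  expect_true(fit$converged)
  expect_equal(fit$sweeps, 1L)
})

test_that("residual bookkeeping matches recomputation from scratch", {
  set.seed(31)
  p <- 30; n <- 120
  gt <- genotype_table(hwe_genotypes(n, runif(p, 0.1, 0.5)))
  des <- gsbayes:::build_design(gt, need_dom = TRUE)
  beta <- rnorm(p) * rbinom(p, 1, 0.2)
  y <- as.numeric(des$Xa %*% beta + rnorm(n, 0, 0.5))
  fit <- gsbayes(gt, y, model = "M2")
  yc <- y - mean(y)
  recomputed <- yc - des$Xa %*% fit$effects$additive -
    des$Xd %*% fit$effects$dominance
  expect_lt(max(abs(recomputed - fit$residual)), 1e-8 * sqrt(sum(yc^2)))
})

test_that("epistatic sweep order enumerates 2p(p-1) coordinates", {
  ord3 <- epistatic_sweep_order(3, "aa")
  expect_equal(nrow(ord3), 3L)
  expect_equal(ord3$i, c(1L, 1L, 2L))
  expect_equal(ord3$j, c(2L, 3L, 3L))
  expect_equal(nrow(epistatic_sweep_order(3)), 12L)
  expect_equal(nrow(epistatic_sweep_order(100)), 2L * 100L * 99L)
  expect_error(epistatic_sweep_order(1))
})

test_that("M3 recovers a planted epistatic interaction", {
  set.seed(13)
  p <- 12; n <- 400
  gt <- genotype_table(hwe_genotypes(n, runif(p, 0.2, 0.5)))
  des <- gsbayes:::build_design(gt, need_dom = TRUE)
  col <- des$Xa[, 3] * des$Xa[, 7]
  y <- as.numeric(2 * col + rnorm(n, 0, 0.3))
  fit <- gsbayes(gt, y, model = "M3", gamma_epi = 1e-4)
  ord <- epistatic_sweep_order(p)
  top <- which.max(abs(fit$effects$epistasis))
  expect_equal(ord$kind[top], "aa")
  expect_equal(c(ord$i[top], ord$j[top]), c(3L, 7L))
  expect_lt(abs(fit$effects$epistasis[top] - 2), 0.2)
})

test_that("empirical-Bayes fixed-effect updates and covariate handling", {
  set.seed(17)
  y <- rnorm(40, 5)
  # intercept-only, no genetic signal
  up <- update_fixed_effects(y, matrix(1, 40, 1), rep(0, 40))
  expect_equal(up$b, mean(y))
  expect_equal(up$sigma_e2, var(y), tolerance = 1e-12)
  # exact recovery of the nongenetic part
  W <- cbind(1, rnorm(40))
  b_true <- c(2, -1)
  g_true <- rnorm(40)
  up2 <- update_fixed_effects(as.numeric(W %*% b_true + g_true), W, g_true)
  expect_equal(up2$b, b_true, tolerance = 1e-10)
  # no covariates: divisor n
  up3 <- update_fixed_effects(y, NULL, rep(0, 40))
  expect_equal(up3$sigma_e2, sum((y - 0)^2) / 40)

  # full fit with covariates estimates both parts
  p <- 20; n <- 300
  gt <- genotype_table(hwe_genotypes(n, runif(p, 0.2, 0.5)))
  des <- gsbayes:::build_design(gt, need_dom = FALSE)
  covs <- data.frame(batch = factor(sample(c("a", "b"), n, TRUE)))
  Wd <- stats::model.matrix(~ ., covs)
  yy <- as.numeric(des$Xa[, 5] * 1.5 + Wd %*% c(3, -2) + rnorm(n, 0, 0.4))
  fit <- gsbayes(gt, yy, covariates = covs, model = "M1")
  expect_equal(length(fit$fixed), 2L)
  expect_lt(abs(fit$fixed[2] - (-2)), 0.3)
  expect_lt(abs(fit$effects$additive[5] - 1.5), 0.3)
  # rank-deficient design errors with the offending column named
  covs$dup <- as.integer(covs$batch == "b")
  expect_error(gsbayes(gt, yy, covariates = covs, model = "M1"),
               "collinear")
})

test_that("non-convergence is reported, not silent", {
  set.seed(2)
  gt <- genotype_table(hwe_genotypes(60, runif(10, 0.2, 0.5)))
  y <- rnorm(60)
  expect_warning(fit <- gsbayes(gt, y, model = "M1", max_sweeps = 1),
                 "converge")
  expect_false(fit$converged)
})

test_that("noiseless orthogonal designs have nonincreasing residual sums of
           squares over sweeps", {
  gt <- orth_gt()
  des <- gsbayes:::build_design(gt, need_dom = FALSE)
  y <- as.numeric(des$Xa %*% c(2, -1))
  rss <- numeric(0)
  for (k in 1:4) {
    fit <- suppressWarnings(gsbayes(gt, y, model = "M1", max_sweeps = k,
                                    sigma_e2 = 0.5, update_sigma = FALSE))
    rss <- c(rss, sum(fit$residual^2))
  }
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("fitted + residual reconstructs the trait; predict matches the
           training design", {
  set.seed(9)
  p <- 15; n <- 100
  gt <- genotype_table(hwe_genotypes(n, runif(p, 0.2, 0.5)))
  des <- gsbayes:::build_design(gt, need_dom = FALSE)
  y <- as.numeric(des$Xa[, 2] * 1.2 + rnorm(n, 0, 0.3))
  fit <- gsbayes(gt, y, model = "M1")
  expect_equal(fitted(fit) + residuals(fit), y, tolerance = 1e-10)
  egv <- predict(fit, gt)
  expect_equal(egv, as.numeric(des$Xa %*% fit$effects$additive),
               tolerance = 1e-10)
})
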