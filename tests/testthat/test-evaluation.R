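# Construct a minimal significance-record object directly, in the format
# documented for wgr_tests, so that window scoring can be enumerated by
# hand.
fake_tests <- function(sig_idx, p, map, alphas = 0.05,
                       kind = rep("additive", length(sig_idx))) {
  df <- data.frame(kind = "additive", snp_i = seq_len(p),
                   snp_j = NA_integer_, ghat = 0, kappa = 0, moe = 1,
                   log10_bf = 0)
  for (a in alphas) df[[sprintf("sig_moe_%g", a)]] <- FALSE
  df$sig_bf <- FALSE
  for (k in seq_along(sig_idx)) {
    r <- which(df$snp_i == sig_idx[k] & df$kind == kind[k])
    df$ghat[r] <- 1
    df$moe[r] <- 0
    df[[sprintf("sig_moe_%g", alphas[1])]][r] <- TRUE
    df$sig_bf[r] <- TRUE
  }
  structure(df, class = c("wgr_tests", "data.frame"),
            n_tested = c(additive = p), map = map, sigma_e2 = 1,
            alphas = alphas, p = p)
}

toy_map <- data.frame(id = paste0("s", 1:5), chrom = 1L,
                      cM = c(0, 0.5, 2, 4, 6),
                      bp = c(0, 5e4, 2e5, 4e5, 6e5))
toy_truth <- list(causative = data.frame(index = 3L, id = "s3", chrom = 1L,
                                         cM = 2, bp = 2e5))

test_that("window matching follows hand enumeration on the toy map", {
  # significant SNP2 at 50 kbp is 150 kbp from the causative: false positive
  ev_fp <- score_detection(fake_tests(2, 5, toy_map), toy_truth,
                           window_bp = 1e5)
  expect_equal(ev_fp$sens_additive, 0)
  expect_equal(ev_fp$n_false_positive, 1)
  expect_equal(ev_fp$spec_overall, 3 / 4)  # 4 SNPs outside the window
  # the causative itself: true positive, no false positives
  ev_tp <- score_detection(fake_tests(3, 5, toy_map), toy_truth,
                           window_bp = 1e5)
  expect_equal(ev_tp$sens_additive, 1)
  expect_equal(ev_tp$spec_overall, 1)
  # SNP4 at 400 kbp: outside the window, false positive
  ev4 <- score_detection(fake_tests(4, 5, toy_map), toy_truth,
                         window_bp = 1e5)
  expect_equal(ev4$sens_additive, 0)
  expect_equal(ev4$n_false_positive, 1)
})

test_that("degenerate significant sets give the boundary rates", {
  ev_none <- score_detection(fake_tests(integer(0), 5, toy_map), toy_truth)
  expect_equal(ev_none$sens_overall, 0)
  expect_equal(ev_none$spec_overall, 1)
})

test_that("sensitivity is nondecreasing in alpha on a fitted dataset", {
  set.seed(61)
  cfg <- sim_config(n_snps = 400, genome_morgan = 1, n_chr = 1,
                    burnin_generations = 60, burnin_popsize = 60,
                    final_generations = 2, n_sires = 10, dams_per_sire = 10,
                    thin = 4, n_causative = 8, epi_pairs_per_kind = 2,
                    h2 = 0.8, seed = 61)
  ds <- simulate_dataset(cfg)
  ts <- significance(gsbayes(ds$geno_train, ds$trait, model = "M1"))
  sens <- vapply(c(0.01, 0.05, 0.1, 0.2), function(a)
    score_detection(ts, ds$truth, alpha = a)$sens_additive, numeric(1))
  expect_true(all(diff(sens) >= 0))
})

test_that("explained variance is 0 with no detections and ~1 under perfect
           recovery", {
  set.seed(67)
  p <- 30; n <- 600
  gt <- genotype_table(hwe_genotypes(n, runif(p, 0.2, 0.5)))
  des <- gsbayes:::build_design(gt, need_dom = FALSE)
  idx <- c(4, 11, 27)
  gv <- as.numeric(des$Xa[, idx] %*% c(1, -1, 0.8))
  y <- gv + rnorm(n, 0, 0.1)
  fit <- gsbayes(gt, y, model = "M1")
  ts <- significance(fit)
  truth <- list(gv_train = gv)
  expect_gt(explained_variance(fit, ts, truth, alpha = 0.05), 0.9)
  # all-null fit
  fit0 <- gsbayes(gt, rep(0, n), model = "M1", sigma_e2 = 1,
                  update_sigma = FALSE)
  expect_equal(explained_variance(fit0, significance(fit0),
                                  list(gv_train = gv)), 0)
  expect_error(explained_variance(fit, ts, list(gv_train = rep(1, n))),
               "zero")
})

test_that("prediction accuracy is the validation correlation, with the
           zero-variance convention", {
  set.seed(71)
  p <- 20; n <- 400
  gt <- genotype_table(hwe_genotypes(n, runif(p, 0.2, 0.5)))
  des <- gsbayes:::build_design(gt, need_dom = FALSE)
  gv <- as.numeric(des$Xa[, 7] * 2)
  fit <- gsbayes(gt, gv + rnorm(n, 0, 0.1), model = "M1")
  gt_val <- genotype_table(hwe_genotypes(200, runif(p, 0.2, 0.5)))
  gt_val$maf <- gt$maf
  gv_val <- as.numeric(gsbayes:::build_design(gt_val, FALSE)$Xa[, 7] * 2)
  expect_gt(prediction_accuracy(fit, gt_val, gv_val), 0.95)
  expect_lt(prediction_accuracy(fit, gt_val, -gv_val), -0.95)
  fit0 <- gsbayes(gt, rep(0, n), model = "M1", sigma_e2 = 1,
                  update_sigma = FALSE)
  expect_warning(a0 <- prediction_accuracy(fit0, gt_val, gv_val),
                 "zero-variance")
  expect_equal(a0, 0)
})

test_that("gamma tuning returns the grid point with the best held-out
           accuracy", {
  set.seed(73)
  p <- 30; n <- 300
  gt <- genotype_table(hwe_genotypes(n, runif(p, 0.2, 0.5)))
  des <- gsbayes:::build_design(gt, need_dom = FALSE)
  y <- as.numeric(des$Xa[, c(3, 17)] %*% c(1.2, -1) + rnorm(n, 0, 0.5))
  tg <- tune_gamma(gt, y, gamma_grid = 0.01)
  expect_equal(tg$best_gamma, 0.01)
  tg2 <- suppressWarnings(tune_gamma(gt, y, gamma_grid = c(0.001, 0.01, 0.1)))
  expect_gte(max(tg2$table$accuracy),
             tg2$table$accuracy[which.min(tg2$table$accuracy)])
  expect_true(tg2$best_gamma %in% c(0.001, 0.01, 0.1))
  # pure-noise trait: flat profile warning
  expect_warning(tune_gamma(gt, rnorm(n), gamma_grid = c(0.005, 0.05)),
                 "flat")
})
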