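#' Score detections against simulation truth
#'
#' A significant main-effect SNP is a true positive for its kind when it
#' lies within `window_bp` of a causative variant on the same chromosome;
#' a significant epistatic pair is a true positive when its two members lie
#' within the windows of the two members of a truly interacting pair of the
#' same kind (kind matching can be relaxed).  Overall sensitivity counts a
#' causative variant as detected when any significant SNP of any kind --
#' including membership in a significant epistatic pair -- falls inside its
#' window.  Overall specificity is the proportion of tested coordinates
#' outside all windows that are not significant.
#'
#' @param tests a [significance()] result.
#' @param truth the `truth` element of a `wgr_dataset` (or compatible list
#'   with `causative`, `epistasis`).
#' @param window_bp matching window around a causative variant (default
#'   100,000 bp).
#' @param alpha type-I error level for the MOE rule.
#' @param rule `"moe"` or `"bf"`.
#' @param match_kind require the detected epistatic kind to equal the
#'   simulated kind (default TRUE).
#' @return Object of class `wgr_eval`: list with per-kind sensitivities
#'   (`sens_additive`, `sens_dominance`, `sens_epistasis`), `sens_overall`,
#'   `spec_overall`, counts and the decision rule used.
#' @export
score_detection <- function(tests, truth, window_bp = 1e5, alpha = 0.05,
                            rule = c("moe", "bf"), match_kind = TRUE) {
  stopifnot(inherits(tests, "wgr_tests"))
  rule <- match.arg(rule)
  if (is.null(truth$causative)) stop("truth with causative positions required")
  map <- attr(tests, "map")
  p <- attr(tests, "p")
  n_tested <- attr(tests, "n_tested")
  sig_col <- if (rule == "moe") sprintf("sig_moe_%g", alpha) else "sig_bf"
  if (!sig_col %in% names(tests)) stop("level not present: ", sig_col)

  # panel SNPs inside the window of each causative variant
  caus <- truth$causative
  nc <- nrow(caus)
  win <- lapply(seq_len(nc), function(k)
    which(map$chrom == caus$chrom[k] & abs(map$bp - caus$bp[k]) <= window_bp))
  in_any_window <- sort(unique(unlist(win)))

  main_kinds <- intersect(c("additive", "dominance"), unique(tests$kind))
  epi_kinds <- intersect(c("aa", "ad", "da", "dd"), unique(tests$kind))

  sig_main <- lapply(main_kinds, function(k)
    tests$snp_i[tests$kind == k & tests[[sig_col]]])
  names(sig_main) <- main_kinds
  sig_epi <- if (length(epi_kinds))
    tests[tests$kind %in% epi_kinds & tests[[sig_col]],
          c("kind", "snp_i", "snp_j")]
  else data.frame(kind = character(), snp_i = integer(), snp_j = integer())

  hit <- function(sig_snps) vapply(win, function(w) any(sig_snps %in% w),
                                   logical(1))
  sens_a <- if ("additive" %in% main_kinds) mean(hit(sig_main$additive))
            else NA_real_
  sens_d <- if ("dominance" %in% main_kinds) mean(hit(sig_main$dominance))
            else NA_real_

  # epistatic pair matching
  sens_e <- NA_real_
  n_matched_pairs <- setNames(integer(length(epi_kinds)), epi_kinds)
  if (length(epi_kinds) && !is.null(truth$epistasis) &&
      nrow(truth$epistasis)) {
    tp <- truth$epistasis
    # panel indices of the causative loci of each true pair
    wi <- win[tp$ci]
    wj <- win[tp$cj]
    detected <- vapply(seq_len(nrow(tp)), function(r) {
      s <- if (match_kind) sig_epi[sig_epi$kind == tp$kind[r], ] else sig_epi
      if (!nrow(s)) return(FALSE)
      any((s$snp_i %in% wi[[r]] & s$snp_j %in% wj[[r]]) |
          (s$snp_i %in% wj[[r]] & s$snp_j %in% wi[[r]]))
    }, logical(1))
    sens_e <- mean(detected)
    # pairs of panel SNPs that would count as a true positive, per kind
    for (k in epi_kinds) {
      rows <- which(if (match_kind) tp$kind == k else rep(TRUE, nrow(tp)))
      prs <- unique(do.call(rbind, lapply(rows, function(r) {
        ij <- rbind(expand.grid(i = wi[[r]], j = wj[[r]]),
                    expand.grid(i = wj[[r]], j = wi[[r]]))
        ij <- ij[ij$i != ij$j, , drop = FALSE]
        unique(cbind(pmin(ij$i, ij$j), pmax(ij$i, ij$j)))
      })))
      n_matched_pairs[k] <- if (is.null(prs)) 0L else nrow(prs)
    }
  }

  # overall sensitivity: causative detected by any kind (incl. pair member)
  all_sig_snps <- unique(c(unlist(sig_main),
                           sig_epi$snp_i, sig_epi$snp_j))
  sens_overall <- mean(vapply(win, function(w) any(all_sig_snps %in% w),
                              logical(1)))

  # overall specificity over tested coordinates outside windows
  fp <- 0; n_out <- 0
  for (k in main_kinds) {
    sig <- sig_main[[k]]
    fp <- fp + sum(!(sig %in% in_any_window))
    n_out <- n_out + p - length(in_any_window)
  }
  for (k in epi_kinds) {
    s <- sig_epi[sig_epi$kind == k, ]
    ok <- logical(nrow(s))
    if (nrow(s) && !is.null(truth$epistasis) && nrow(truth$epistasis)) {
      tp <- truth$epistasis
      rows <- which(if (match_kind) tp$kind == k else rep(TRUE, nrow(tp)))
      for (r in rows) {
        ok <- ok | (s$snp_i %in% win[[tp$ci[r]]] &
                    s$snp_j %in% win[[tp$cj[r]]]) |
                   (s$snp_i %in% win[[tp$cj[r]]] &
                    s$snp_j %in% win[[tp$ci[r]]])
      }
    }
    fp <- fp + sum(!ok)
    n_out <- n_out + n_tested[[k]] - n_matched_pairs[[k]]
  }
  spec_overall <- if (n_out > 0) (n_out - fp) / n_out else NA_real_

  structure(list(sens_additive = sens_a, sens_dominance = sens_d,
                 sens_epistasis = sens_e, sens_overall = sens_overall,
                 spec_overall = spec_overall, n_causative = nc,
                 n_false_positive = fp, n_outside = n_out,
                 alpha = alpha, rule = rule, window_bp = window_bp),
            class = "wgr_eval")
}

#' @export
print.wgr_eval <- function(x, ...) {
  cat(sprintf("detection at %s = %g (window %g bp)\n",
              if (x$rule == "moe") "MOE <=" else "BF rule, alpha",
              x$alpha, x$window_bp))
  cat(sprintf("  sensitivity: a=%.3f d=%.3f e=%.3f overall=%.3f\n",
              x$sens_additive, x$sens_dominance, x$sens_epistasis,
              x$sens_overall))
  cat(sprintf("  specificity (overall): %.4f  (FP=%d of %d outside)\n",
              x$spec_overall, x$n_false_positive, x$n_outside))
  invisible(x)
}

#' Genetic variance explained by significant effects
#'
#' Variance (over training individuals) of the genetic values built from
#' the significant coordinates only, divided by the variance of the true
#' simulated genetic values.
#'
#' @param fit a [gsbayes()] fit.
#' @param tests the matching [significance()] result.
#' @param truth truth list with `gv_train`.
#' @param alpha,rule decision rule (as in [score_detection()]).
#' @return Proportion (may exceed 1 when effects are overestimated).
#' @export
explained_variance <- function(fit, tests, truth, alpha = 0.05,
                               rule = c("moe", "bf")) {
  rule <- match.arg(rule)
  if (is.null(truth$gv_train)) stop("truth with gv_train required")
  vg <- var(truth$gv_train)
  if (vg == 0) stop("zero simulated genetic variance")
  sig_col <- if (rule == "moe") sprintf("sig_moe_%g", alpha) else "sig_bf"
  sig <- tests[tests[[sig_col]], , drop = FALSE]
  if (!nrow(sig)) return(0)
  des <- build_design(fit$genotypes,
                      need_dom = any(sig$kind != "additive"))
  pred <- numeric(fit$n)
  for (r in seq_len(nrow(sig))) {
    k <- sig$kind[r]
    col <- if (k == "additive") des$Xa[, sig$snp_i[r]]
      else if (k == "dominance") des$Xd[, sig$snp_i[r]]
      else {
        u <- if (substr(k, 1, 1) == "a") des$Xa[, sig$snp_i[r]]
             else des$Xd[, sig$snp_i[r]]
        v <- if (substr(k, 2, 2) == "a") des$Xa[, sig$snp_j[r]]
             else des$Xd[, sig$snp_j[r]]
        u * v
      }
    pred <- pred + col * sig$ghat[r]
  }
  var(pred) / vg
}

#' Accuracy of genetic value prediction
#'
#' Pearson correlation between the estimated genetic values of the
#' validation individuals (all fitted coordinates, [predict.gsbayes()]) and
#' their true simulated genetic values.
#'
#' @param fit a [gsbayes()] fit.
#' @param val_genotypes validation [genotype_table()].
#' @param true_gv true genetic values of the validation individuals.
#' @return Correlation in \[-1, 1\]; 0 with a warning when the prediction
#'   has zero variance.
#' @export
prediction_accuracy <- function(fit, val_genotypes, true_gv) {
  egv <- predict(fit, val_genotypes)
  if (sd(egv) == 0 || sd(true_gv) == 0) {
    warning("zero-variance prediction; accuracy reported as 0")
    return(0)
  }
  cor(egv, true_gv)
}

#' Choose the prior inclusion probability by resampling
#'
#' Splits the data into random halves, fits the model on one half for every
#' value on the grid (with the Laplace rate re-derived from gamma:
#' 2 p gamma for main effects, p (p - 1) gamma for epistasis), predicts
#' genetic values on the held-out half, and returns the gamma with the
#' highest correlation between predicted values and the held-out trait.
#'
#' @param genotypes a [genotype_table()].
#' @param trait numeric trait vector.
#' @param covariates optional fixed-effect design.
#' @param gamma_grid values to evaluate (main grid default
#'   c(0.001, 0.005, 0.01, 0.05, 0.1); epistasis default 10^(-7:-3)).
#' @param kind tune the main-effect prior (`"main"`, model M2) or the
#'   epistasis prior (`"epi"`, model M3 with `gamma_main` fixed).
#' @param gamma_main fixed main-effect gamma when `kind = "epi"`.
#' @param split_seed RNG seed for the random half split.
#' @param ... passed to [gsbayes()].
#' @return List with `best_gamma` and `table` (gamma, accuracy); a warning
#'   is issued when the accuracy profile is flat.
#' @export
tune_gamma <- function(genotypes, trait, covariates = NULL,
                       gamma_grid = NULL, kind = c("main", "epi"),
                       gamma_main = 0.005, split_seed = 1, ...) {
  kind <- match.arg(kind)
  if (!inherits(genotypes, "genotype_table"))
    genotypes <- genotype_table(genotypes)
  if (is.null(gamma_grid))
    gamma_grid <- if (kind == "main") c(0.001, 0.005, 0.01, 0.05, 0.1)
                  else 10^seq(-7, -3)
  n <- nrow(genotypes$codes)
  if (n < 20) stop("too few individuals to split")
  set.seed(split_seed)
  idx <- sample.int(n, floor(n / 2))
  sub <- function(gt, rows) {
    gt$codes <- gt$codes[rows, , drop = FALSE]
    gt
  }
  gt_tr <- sub(genotypes, idx)
  gt_te <- sub(genotypes, -idx)
  acc <- vapply(gamma_grid, function(g) {
    fit <- if (kind == "main")
      gsbayes(gt_tr, trait[idx], covariates = covariates_rows(covariates, idx),
              model = "M2", gamma_main = g, ...)
    else
      gsbayes(gt_tr, trait[idx], covariates = covariates_rows(covariates, idx),
              model = "M3", gamma_main = gamma_main, gamma_epi = g, ...)
    egv <- predict(fit, gt_te)
    if (sd(egv) == 0) 0 else cor(egv, trait[-idx])
  }, numeric(1))
  if (length(acc) > 1 && diff(range(acc)) < 0.01)
    warning("accuracy profile is nearly flat over the gamma grid")
  list(best_gamma = gamma_grid[which.max(acc)],
       table = data.frame(gamma = gamma_grid, accuracy = acc))
}

covariates_rows <- function(covariates, idx) {
  if (is.null(covariates)) return(NULL)
  covariates[idx, , drop = FALSE]
}
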