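#' Fit a whole-genome regression by marginalized Gauss-Seidel
#'
#' Jointly estimates SNP effects of the requested kinds under independent
#' spike-plus-Laplace priors.  Coordinates are visited in sweeps (additive,
#' then dominance, then the four epistatic kinds, pair-lexicographic); each
#' visit computes the one-locus sufficient statistics from the current
#' residual and replaces the effect by its closed-form posterior expectation
#' ([posterior_mean()]).  Epistatic product columns are built on the fly and
#' never stored.  When covariates are present, fixed effects and the
#' residual variance are re-estimated once per sweep by empirical Bayes
#' (b = (W'W)^-1 W'(y - X ghat), sigma_e^2 = e'e/(n - q)); without
#' covariates the trait is centered by its mean and sigma_e^2 is updated as
#' e'e/n each sweep unless a fixed value is supplied.
#'
#' Model presets follow the usual nesting: `"M1"` additive only, `"M2"`
#' additive + dominance, `"M3"` additive + dominance + all four pairwise
#' epistatic kinds (2 p (p - 1) interaction coordinates).
#'
#' Hyperparameter defaults: `gamma_main = 0.005` with
#' `lambda_main = 2 p gamma_main`, and `gamma_epi = 1e-6` with
#' `lambda_epi = p (p - 1) gamma_epi`, where p is the number of SNPs in
#' `genotypes`.
#'
#' Convergence is declared when the relative change
#' ||ghat_k - ghat_(k-1)|| / ||ghat_k|| of the full stacked effect vector
#' (2-norm over all kinds) falls below `tol`.
#'
#' @param genotypes a [genotype_table()] or a code matrix accepted by it.
#' @param trait numeric trait vector (centered internally when no
#'   covariates are given) or the result of [center_trait()].
#' @param covariates optional fixed-effect design: a numeric matrix or a
#'   data frame (expanded via `model.matrix(~ ., .)` with reference levels).
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param gamma_main,gamma_epi prior mixing probabilities P(g != 0) for
#'   main and epistatic effects.
#' @param lambda_main,lambda_epi Laplace rates; derived from gamma and p
#'   when `NULL`.
#' @param sigma_e2 residual variance; when `NULL` it is initialized from
#'   the (covariate-corrected) trait variance and re-estimated each sweep.
#' @param update_sigma logical; override the default residual-variance
#'   updating rule (`TRUE` unless a fixed `sigma_e2` was supplied).
#' @param tol relative-change convergence threshold (default 1e-4).
#' @param max_sweeps maximum number of sweeps (default 500); a
#'   non-converged fit is returned with `converged = FALSE` and a warning.
#' @param verbose print one progress line per sweep.
#' @return An object of class `gsbayes`; see Details.  Components include
#'   `effects` (list with `additive`, `dominance`, `epistasis` vectors; the
#'   epistatic vector is ordered as [epistatic_sweep_order()]), `fixed`,
#'   `sigma_e2`, `sweeps`, `converged`, `residual`, and per-coordinate
#'   sufficient statistics `stats` used by [significance()].
#' @seealso [significance()], [predict.gsbayes()], [simulate_dataset()]
#' @export
gsbayes <- function(genotypes, trait, covariates = NULL,
                    model = c("M1", "M2", "M3"),
                    gamma_main = 0.005, gamma_epi = 1e-6,
                    lambda_main = NULL, lambda_epi = NULL,
                    sigma_e2 = NULL, update_sigma = NULL,
                    tol = 1e-4, max_sweeps = 500, verbose = FALSE) {
  model <- match.arg(model)
  if (!inherits(genotypes, "genotype_table"))
    genotypes <- genotype_table(genotypes)
  p <- ncol(genotypes$codes)
  n <- nrow(genotypes$codes)
  if (any(genotypes$maf <= 0))
    stop("monomorphic SNPs present; apply filter_maf() first")
  if (tol <= 0) stop("tol must be positive")

  use_dom <- model %in% c("M2", "M3")
  use_epi <- model == "M3"
  if (use_epi && p < 2) stop("epistasis requires at least two SNPs")

  if (is.null(lambda_main)) lambda_main <- 2 * p * gamma_main
  if (is.null(lambda_epi))
    lambda_epi <- if (p > 1) p * (p - 1) * gamma_epi else gamma_epi
  prior_main <- prior_spec(gamma_main, lambda_main)
  prior_epi <- prior_spec(gamma_epi, lambda_epi)

  # trait / covariates
  center <- 0
  if (inherits(trait, "trait_vector")) {
    y <- trait$values
    center <- trait$center
  } else {
    y <- as.numeric(trait)
  }
  if (length(y) != n) stop("trait length does not match genotype rows")
  if (any(!is.finite(y))) stop("non-finite trait values")
  W <- matrix(numeric(0), n, 0)
  if (is.null(covariates)) {
    if (!inherits(trait, "trait_vector")) {
      ct <- center_trait(y)
      y <- ct$values
      center <- ct$center
    }
  } else {
    W <- expand_covariates(covariates, n)
  }

  fixed_sigma <- !is.null(sigma_e2)
  if (is.null(update_sigma)) update_sigma <- !fixed_sigma
  if (is.null(sigma_e2)) {
    y0 <- if (ncol(W) > 0) stats::lm.fit(W, y)$residuals else y
    sigma_e2 <- sum(y0^2) / max(1, length(y0) - ncol(W))
  }
  if (sigma_e2 <= 0) stop("sigma_e2 must be positive")

  des <- build_design(genotypes, need_dom = use_dom || use_epi)
  Xd <- if (is.null(des$Xd)) matrix(numeric(0), n, 0) else des$Xd

  fit <- gs_fit_cpp(y, des$Xa, Xd, use_dom, use_epi, W,
                    gamma_main, lambda_main, gamma_epi, lambda_epi,
                    tol, as.integer(max_sweeps), sigma_e2,
                    update_sigma, verbose)
  if (!fit$converged)
    warning("Gauss-Seidel solver did not converge in ", max_sweeps,
            " sweeps (last relative change ", signif(fit$rel_change, 3), ")")

  structure(list(
    effects = list(additive = as.numeric(fit$ga),
                   dominance = if (use_dom) as.numeric(fit$gd) else NULL,
                   epistasis = if (use_epi) as.numeric(fit$ge) else NULL),
    fixed = as.numeric(fit$b),
    fixed_names = colnames(W),
    sigma_e2 = fit$sigma_e2,
    sweeps = fit$sweeps,
    converged = fit$converged,
    rel_change = as.numeric(fit$rel_history),
    residual = as.numeric(fit$residual),
    stats = list(
      xtx_a = as.numeric(fit$xtx_a), xty_a = as.numeric(fit$xty_a),
      xtx_d = if (use_dom) as.numeric(fit$xtx_d) else NULL,
      xty_d = if (use_dom) as.numeric(fit$xty_d) else NULL,
      xtx_e = if (use_epi) as.numeric(fit$xtx_e) else NULL,
      xty_e = if (use_epi) as.numeric(fit$xty_e) else NULL),
    genotypes = genotypes,
    y = y,
    trait_center = center,
    n = n, p = p, model = model,
    prior_main = prior_main, prior_epi = prior_epi,
    update_sigma = update_sigma,
    call = match.call()),
    class = "gsbayes")
}

# Expand a covariate specification into a full-rank fixed-effect design.
expand_covariates <- function(covariates, n) {
  if (is.data.frame(covariates)) {
    W <- stats::model.matrix(~ ., data = covariates)
  } else {
    W <- as.matrix(covariates)
    if (!any(apply(W, 2, function(x) all(x == x[1]))))
      W <- cbind(`(Intercept)` = 1, W)
  }
  if (nrow(W) != n) stop("covariate rows do not match genotype rows")
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    bad <- colnames(W)[qrW$pivot[(qrW$rank + 1):ncol(W)]]
    stop("covariate design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  if (n <= ncol(W)) stop("more covariate columns than observations")
  W
}

#' Enumerate epistatic coordinates
#'
#' Deterministic order in which the solver visits pairwise interaction
#' coordinates: kind-major (`"aa"`, `"ad"`, `"da"`, `"dd"`), pairs i < j in
#' lexicographic order, giving 4 * p (p - 1) / 2 = 2 p (p - 1) coordinates
#' for all four kinds.
#'
#' @param p number of SNPs (>= 2).
#' @param kinds subset of the four epistatic kinds.
#' @return Data frame with columns `kind`, `i`, `j` in sweep order.
#' @export
epistatic_sweep_order <- function(p, kinds = c("aa", "ad", "da", "dd")) {
  if (p < 2) stop("p must be at least 2")
  kinds <- match.arg(kinds, c("aa", "ad", "da", "dd"), several.ok = TRUE)
  ij <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  data.frame(kind = rep(kinds, each = nrow(ij)),
             i = rep(ij[, 1], length(kinds)),
             j = rep(ij[, 2], length(kinds)))
}

#' Empirical-Bayes update of fixed effects and residual variance
#'
#' One update step given the current genetic fit:
#' b = (W'W)^-1 W'(y - X ghat) and sigma_e^2 = e'e/(n - q) with
#' e = y - W b - X ghat.  Without covariates (q = 0) only the residual
#' variance is returned, with divisor n.
#'
#' @param trait numeric trait vector.
#' @param W fixed-effect design matrix (may have zero columns).
#' @param genetic numeric vector X ghat of current genetic values.
#' @return List with `b` and `sigma_e2`.
#' @export
update_fixed_effects <- function(trait, W, genetic) {
  n <- length(trait)
  ystar <- trait - genetic
  if (is.null(W) || ncol(as.matrix(W)) == 0) {
    return(list(b = numeric(0), sigma_e2 = sum(ystar^2) / n))
  }
  W <- as.matrix(W)
  if (n <= ncol(W)) stop("need more observations than covariates")
  b <- as.numeric(solve(crossprod(W), crossprod(W, ystar)))
  e <- ystar - W %*% b
  list(b = b, sigma_e2 = sum(e^2) / (n - ncol(W)))
}

## ---- S3 methods -----------------------------------------------------------

#' @export
print.gsbayes <- function(x, ...) {
  cat("Whole-genome regression fit (model ", x$model, ")\n", sep = "")
  cat("  n =", x$n, " SNPs =", x$p, "\n")
  nz <- vapply(x$effects, function(g) if (is.null(g)) 0L else sum(g != 0),
               integer(1))
  cat("  nonzero effects:", paste(names(nz), nz, sep = "=", collapse = "  "),
      "\n")
  cat("  sigma_e2 =", signif(x$sigma_e2, 4), " sweeps =", x$sweeps,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}

#' @export
summary.gsbayes <- function(object, top = 5, ...) {
  out <- list(model = object$model, n = object$n, p = object$p,
              sigma_e2 = object$sigma_e2, sweeps = object$sweeps,
              converged = object$converged,
              rel_change = utils::tail(object$rel_change, 1))
  eff <- coef(object)
  eff <- eff[order(-abs(eff$estimate)), ]
  out$top_effects <- utils::head(eff[eff$estimate != 0, ], top)
  class(out) <- "summary.gsbayes"
  out
}

#' @export
print.summary.gsbayes <- function(x, ...) {
  cat("Model", x$model, ":", x$n, "individuals,", x$p, "SNPs\n")
  cat("sigma_e2 =", signif(x$sigma_e2, 4), "; sweeps =", x$sweeps,
      "; converged =", x$converged,
      "; final rel. change =", signif(x$rel_change, 3), "\n")
  cat("largest effects:\n")
  print(x$top_effects, row.names = FALSE)
  invisible(x)
}

#' Extract fitted effects
#'
#' Returns main effects for every SNP and, for model M3, the nonzero
#' epistatic effects (the full epistatic vector lives in
#' `object$effects$epistasis` in [epistatic_sweep_order()] order).
#'
#' @param object a [gsbayes()] fit.
#' @param ... unused.
#' @return Data frame with columns `kind`, `snp_i`, `snp_j`, `estimate`.
#' @export
coef.gsbayes <- function(object, ...) {
  ids <- object$genotypes$map$id
  out <- data.frame(kind = "additive", snp_i = ids, snp_j = NA_character_,
                    estimate = object$effects$additive)
  if (!is.null(object$effects$dominance))
    out <- rbind(out, data.frame(kind = "dominance", snp_i = ids,
                                 snp_j = NA_character_,
                                 estimate = object$effects$dominance))
  if (!is.null(object$effects$epistasis)) {
    ord <- epistatic_sweep_order(object$p)
    nz <- which(object$effects$epistasis != 0)
    if (length(nz))
      out <- rbind(out, data.frame(kind = ord$kind[nz],
                                   snp_i = ids[ord$i[nz]],
                                   snp_j = ids[ord$j[nz]],
                                   estimate = object$effects$epistasis[nz]))
  }
  out
}

#' Predict genetic values
#'
#' Estimated genetic values X ghat for new individuals, using the training
#' allele frequencies stored in the fit to standardize the new genotype
#' codes.  All fitted coordinates of all kinds contribute (not only the
#' significant ones).
#'
#' @param object a [gsbayes()] fit.
#' @param newdata a [genotype_table()] or code matrix over the same SNPs.
#' @param ... unused.
#' @return Numeric vector of estimated genetic values.
#' @export
predict.gsbayes <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    gt <- object$genotypes
  } else if (inherits(newdata, "genotype_table")) {
    gt <- newdata
  } else {
    gt <- genotype_table(newdata)
  }
  if (ncol(gt$codes) != object$p)
    stop("newdata must contain the same ", object$p, " SNPs as the fit")
  # standardize with the training frequencies
  gt$maf <- object$genotypes$maf
  use_dom <- !is.null(object$effects$dominance)
  use_epi <- !is.null(object$effects$epistasis)
  des <- build_design(gt, need_dom = use_dom || use_epi)
  egv <- as.numeric(des$Xa %*% object$effects$additive)
  if (use_dom)
    egv <- egv + as.numeric(des$Xd %*% object$effects$dominance)
  if (use_epi) {
    ge <- object$effects$epistasis
    nz <- which(ge != 0)
    if (length(nz)) {
      ord <- epistatic_sweep_order(object$p)
      for (k in nz) {
        a1 <- substr(ord$kind[k], 1, 1) == "a"
        a2 <- substr(ord$kind[k], 2, 2) == "a"
        col <- (if (a1) des$Xa[, ord$i[k]] else des$Xd[, ord$i[k]]) *
               (if (a2) des$Xa[, ord$j[k]] else des$Xd[, ord$j[k]])
        egv <- egv + col * ge[k]
      }
    }
  }
  egv
}

#' @export
fitted.gsbayes <- function(object, ...) {
  # W b + X ghat on the original trait scale
  object$trait_center + object$y - object$residual
}

#' @export
residuals.gsbayes <- function(object, ...) object$residual

#' Simulate traits from a fitted model
#'
#' Draws new trait vectors y* = X ghat + W b + center + N(0, sigma_e2)
#' on the training genotypes.
#'
#' @param object a [gsbayes()] fit.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return Matrix n x nsim of simulated traits.
#' @export
simulate.gsbayes <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- fitted(object)
  matrix(rnorm(object$n * nsim, mean = mu, sd = sqrt(object$sigma_e2)),
         object$n, nsim)
}

#' Plot fitted effects
#'
#' Main-effect estimates against SNP index, one panel per kind, with
#' nonzero epistatic effects marked at their first locus for model M3.
#'
#' @param x a [gsbayes()] fit.
#' @param ... passed to [plot()].
#' @export
plot.gsbayes <- function(x, ...) {
  use_dom <- !is.null(x$effects$dominance)
  op <- par(mfrow = c(if (use_dom) 2 else 1, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(seq_len(x$p), x$effects$additive, pch = 16, cex = 0.5,
       xlab = "SNP index", ylab = "additive effect",
       main = paste("model", x$model), ...)
  abline(h = 0, col = "grey")
  if (use_dom) {
    plot(seq_len(x$p), x$effects$dominance, pch = 16, cex = 0.5,
         xlab = "SNP index", ylab = "dominance effect", ...)
    abline(h = 0, col = "grey")
  }
  invisible(x)
}
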