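## One-locus closed-form posterior under the spike-plus-Laplace prior:
## posterior expectation, analytic CDF and continuous density, the
## HPD-tangent-to-zero credibility (measure of evidence) and the marginal
## Bayes factor.  All mixture weights are kept on the log scale; products of
## exponentials and Gaussian tail probabilities are combined by log-sum-exp
## so that no overflow occurs for |Y|/sigma up to 40 and lambda*sigma up to
## about 1e3.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b
logspace_sub <- function(a, b) {
  if (b > a) stop("logspace_sub: negative difference")
  if (b == -Inf) return(a)
  a + log1p(-exp(b - a))
}

# log(Phi(zhi) - Phi(zlo)) for zlo <= zhi; switches to the complementary
# tail when both points sit in the far right tail, where lower-tail log
# probabilities are no longer representable
log_pnorm_diff <- function(zlo, zhi) {
  if (zlo > zhi) stop("log_pnorm_diff: zlo > zhi")
  if (zlo > 0) {
    logspace_sub(pnorm(zlo, lower.tail = FALSE, log.p = TRUE),
                 pnorm(zhi, lower.tail = FALSE, log.p = TRUE))
  } else {
    logspace_sub(pnorm(zhi, log.p = TRUE), pnorm(zlo, log.p = TRUE))
  }
}

#' Spike-plus-Laplace prior specification
#'
#' The prior on a single genetic effect is
#' p(g | gamma) = (gamma * lambda / 2) exp(-lambda |g|) + (1 - gamma) delta_0,
#' i.e. a Laplace slab with rate `lambda` mixed with a point mass at zero
#' with weight 1 - `gamma`.
#'
#' @param gamma mixing probability P(g != 0), in (0, 1].
#' @param lambda Laplace rate, > 0.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(gamma, lambda) {
  stopifnot(is.finite(gamma), is.finite(lambda))
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  if (lambda <= 0) stop("lambda must be positive")
  structure(list(gamma = gamma, lambda = lambda), class = "prior_spec")
}

#' Mean of a zero-truncated normal distribution
#'
#' Expected value of N(mu, sigma2) conditioned on the positive (`"upper"`)
#' or negative (`"lower"`) half line, evaluated through log-scale Mills
#' ratios so that extreme truncations (|mu|/sigma large) stay accurate.
#'
#' @param side `"upper"` (condition on g > 0) or `"lower"` (g < 0).
#' @param mu mean of the untruncated normal.
#' @param sigma2 variance, > 0.
#' @return The truncated mean (positive for `"upper"`, negative for
#'   `"lower"`).
#' @export
truncnorm_mean <- function(side = c("upper", "lower"), mu, sigma2) {
  side <- match.arg(side)
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  sd <- sqrt(sigma2)
  z <- mu / sd
  if (side == "lower") return(-truncnorm_mean("upper", -mu, sigma2))
  if (z < -30) {
    # deep truncation: mu + sd phi/Phi cancels catastrophically and the
    # log-scale Mills ratio amplifies rounding of the huge log tail, so use
    # the asymptotic series E = (sd/a)(1 - 2/a^2 + 10/a^4 - 74/a^6), a = -z
    a <- -z
    (sd / a) * (1 - 2 / a^2 + 10 / a^4 - 74 / a^6)
  } else {
    mu + sd * exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
  }
}

#' One-locus posterior under the spike-plus-Laplace prior
#'
#' Given the sufficient statistics of the one-locus model (Y = (x'x)^-1 x'y
#' and sigma2 = (x'x)^-1 sigma_e^2) and a [prior_spec()], computes the
#' log-scale mixture weights T1, T2, T3, the posterior expectation
#' ghat = E(g | y), the log marginal density p(y) (up to the common
#' likelihood constant) and the posterior probability that g is nonzero.
#'
#' @param Y generalized least-squares estimate (x'x)^-1 x'y.
#' @param sigma2 its sampling variance (x'x)^-1 sigma_e^2, > 0.
#' @param prior a [prior_spec()].
#' @param xtx,xty,sigma_e2 optional raw sufficient statistics, stored for
#'   downstream Bayes factors.
#' @return Object of class `locus_posterior` with elements `Y`, `sigma2`,
#'   `prior`, `log_T1`, `log_T2`, `log_T3`, `log_py`, `log_pnz`
#'   (log P(g != 0 | y)) and `ghat`.
#' @export
locus_posterior <- function(Y, sigma2, prior, xtx = NA_real_, xty = NA_real_,
                            sigma_e2 = NA_real_) {
  stopifnot(inherits(prior, "prior_spec"))
  if (!is.finite(Y) || !is.finite(sigma2) || sigma2 <= 0)
    stop("Y must be finite and sigma2 positive")
  gam <- prior$gamma
  lam <- prior$lambda
  sd <- sqrt(sigma2)
  muU <- Y - lam * sigma2  # Y-
  muL <- Y + lam * sigma2  # Y+
  lT1 <- -lam * Y + pnorm(muU / sd, log.p = TRUE)
  lT2 <- lam * Y + pnorm(-muL / sd, log.p = TRUE)
  lT3 <- log(2) + log1p(-gam) - log(gam) - log(lam) - 0.5 * lam^2 * sigma2 +
    dnorm(Y / sd, log = TRUE) - log(sd)
  lZ <- logsumexp(c(lT1, lT2, lT3))
  ghat <- exp(lT1 - lZ) * truncnorm_mean("upper", muU, sigma2) +
    exp(lT2 - lZ) * truncnorm_mean("lower", muL, sigma2)
  # log p(y) up to the common constant of the likelihood kernel
  lslab <- log(gam * lam / 2) + 0.5 * lam^2 * sigma2 + logsumexp(c(lT1, lT2))
  lspike <- log1p(-gam) + dnorm(Y / sd, log = TRUE) - log(sd)
  structure(list(Y = Y, sigma2 = sigma2, prior = prior,
                 log_T1 = lT1, log_T2 = lT2, log_T3 = lT3,
                 log_py = logsumexp(c(lslab, lspike)),
                 log_pnz = lslab - logsumexp(c(lslab, lspike)),
                 ghat = ghat, xtx = xtx, xty = xty, sigma_e2 = sigma_e2),
            class = "locus_posterior")
}

#' Closed-form posterior expectation of a single effect
#'
#' Convenience wrapper around [locus_posterior()] returning only
#' ghat = E(g | y).
#'
#' @inheritParams locus_posterior
#' @return Numeric scalar.
#' @export
posterior_mean <- function(Y, sigma2, prior) {
  locus_posterior(Y, sigma2, prior)$ghat
}

# log of the unnormalized continuous posterior piece at g (f1 for g < 0,
# f3 for g > 0; the two one-sided limits at 0 coincide).
log_fcont <- function(g, post) {
  gam <- post$prior$gamma
  lam <- post$prior$lambda
  s2 <- post$sigma2
  sd <- sqrt(s2)
  base <- log(gam * lam / 2) + 0.5 * lam^2 * s2
  ifelse(g < 0,
         base + lam * post$Y + dnorm((g - (post$Y + lam * s2)) / sd,
                                     log = TRUE) - log(sd),
         base - lam * post$Y + dnorm((g - (post$Y - lam * s2)) / sd,
                                     log = TRUE) - log(sd))
}

#' Analytic posterior distribution function
#'
#' P(g < t | y) for the one-locus posterior.  The distribution has a jump of
#' height f2(0) / p(y) at t = 0 (the spike); the value returned at t = 0 is
#' the limit from the left, i.e. the spike is included only for t > 0.
#'
#' @param t evaluation point(s).
#' @param post a [locus_posterior()].
#' @return Probabilities in \[0, 1\].
#' @export
posterior_cdf <- function(t, post) {
  stopifnot(inherits(post, "locus_posterior"))
  gam <- post$prior$gamma
  lam <- post$prior$lambda
  s2 <- post$sigma2
  sd <- sqrt(s2)
  base <- log(gam * lam / 2) + 0.5 * lam^2 * s2
  muU <- post$Y - lam * s2
  muL <- post$Y + lam * s2
  lspike <- log1p(-gam) + dnorm(post$Y / sd, log = TRUE) - log(sd)
  vapply(t, function(ti) {
    if (ti <= 0) {
      lnum <- base + lam * post$Y + pnorm((ti - muL) / sd, log.p = TRUE)
      min(1, exp(lnum - post$log_py))
    } else {
      l_neg <- base + lam * post$Y + pnorm(-muL / sd, log.p = TRUE)
      l_pos <- base - lam * post$Y +
        log_pnorm_diff(-muU / sd, (ti - muU) / sd)
      min(1, exp(logsumexp(c(l_neg, lspike, l_pos)) - post$log_py))
    }
  }, numeric(1))
}

#' Continuous part of the posterior density
#'
#' Normalized density of the slab component: f1(g)/p(y) for g < 0,
#' f3(g)/p(y) for g > 0, and the common one-sided limit at g = 0.  The spike
#' at zero is not included.
#'
#' @param g evaluation point(s).
#' @param post a [locus_posterior()].
#' @return Nonnegative densities.
#' @export
posterior_density <- function(g, post) {
  stopifnot(inherits(post, "locus_posterior"))
  exp(log_fcont(g, post) - post$log_py)
}

#' HPD-tangent-to-zero credibility (measure of evidence)
#'
#' Credibility kappa of the highest posterior density interval adjacent to
#' zero on the side of the effect estimate: for ghat > 0 the interval is
#' (0, t2\] with t2 the largest g > 0 whose continuous posterior density is
#' at least the density at zero; mirrored for ghat < 0.  The spike at zero
#' is excluded, so kappa <= P(g != 0 | y).  Significance is declared when
#' the measure of evidence MOE = 1 - kappa falls at or below the chosen
#' type-I error level.
#'
#' The border search is a grid search over \[mL, mU\] with 2000 steps; by
#' default mL = -10(|ghat| + sigma), mU = 10(|ghat| + sigma) for the single
#' locus, but the caller (the significance module) passes the whole-vector
#' bounds 10 min(ghat), 10 max(ghat).  With `exact = TRUE` the border is
#' instead the closed-form solution of the Gaussian density equation
#' (t2 = 2(Y - lambda sigma^2) for ghat > 0, clamped at 0).
#'
#' @param post a [locus_posterior()].
#' @param grid optional numeric length-2 vector c(mL, mU) of search bounds
#'   (mL < 0 < mU).
#' @param steps number of grid steps (default 2000).
#' @param exact use the closed-form border instead of the grid search.
#' @return Object of class `evidence_result`: list with `kappa`, `moe`,
#'   `t1`, `t2`.
#' @export
hpd_credibility <- function(post, grid = NULL, steps = 2000, exact = FALSE) {
  stopifnot(inherits(post, "locus_posterior"))
  ghat <- post$ghat
  if (ghat == 0)
    return(structure(list(kappa = 0, moe = 1, t1 = 0, t2 = 0),
                     class = "evidence_result"))
  lam <- post$prior$lambda
  s2 <- post$sigma2
  if (is.null(grid)) {
    half <- 10 * (abs(ghat) + sqrt(s2))
    grid <- c(-half, half)
  }
  if (length(grid) != 2 || grid[1] >= grid[2]) stop("invalid grid bounds")
  if (!(grid[1] < 0 && grid[2] > 0)) {
    half <- 10 * (abs(ghat) + sqrt(s2))
    grid <- c(-half, half)
  }
  ld0 <- log_fcont(0, post)
  if (exact) {
    if (ghat > 0) {
      t1 <- 0; t2 <- max(0, 2 * (post$Y - lam * s2))
    } else {
      t2 <- 0; t1 <- min(0, 2 * (post$Y + lam * s2))
    }
  } else {
    gg <- seq(grid[1], grid[2], length.out = steps + 1)
    if (ghat > 0) {
      gg <- gg[gg > 0]
      ok <- gg[log_fcont(gg, post) >= ld0]
      t1 <- 0; t2 <- if (length(ok)) max(ok) else 0
    } else {
      gg <- gg[gg < 0]
      ok <- gg[log_fcont(gg, post) >= ld0]
      t2 <- 0; t1 <- if (length(ok)) min(ok) else 0
    }
  }
  kappa <- kappa_interval(post, t1, t2)
  structure(list(kappa = kappa, moe = 1 - kappa, t1 = t1, t2 = t2),
            class = "evidence_result")
}

# P(t1 < g < t2 | y) for an interval with one border at zero, continuous
# part only, evaluated in log space.
kappa_interval <- function(post, t1, t2) {
  if (t1 == t2) return(0)
  lam <- post$prior$lambda
  s2 <- post$sigma2
  sd <- sqrt(s2)
  base <- log(post$prior$gamma * lam / 2) + 0.5 * lam^2 * s2
  if (t1 == 0) {  # (0, t2]
    mu <- post$Y - lam * s2
    lk <- base - lam * post$Y + log_pnorm_diff(-mu / sd, (t2 - mu) / sd)
  } else {        # [t1, 0)
    mu <- post$Y + lam * s2
    lk <- base + lam * post$Y + log_pnorm_diff((t1 - mu) / sd, (0 - mu) / sd)
  }
  min(1, exp(lk - post$log_py))
}

#' Marginal Bayes factor for a single effect
#'
#' Ratio of marginal likelihoods of the one-locus model with the fitted
#' effect against the null model (g = 0), evaluated on the residualized
#' trait:
#' B = exp( -(1 / 2 sigma_e^2) ( -2 y_j' x_j ghat + ghat^2 x_j' x_j ) ).
#' Computed on the log scale.  An effect is conventionally called
#' substantial when B > 3.
#'
#' @param y_j residualized trait vector (trait corrected for all other
#'   fitted effects).
#' @param x_j design column of the tested effect.
#' @param ghat fitted effect.
#' @param sigma_e2 residual variance, > 0.
#' @return List with `log_bf` and `bf`.
#' @export
bayes_factor <- function(y_j, x_j, ghat, sigma_e2) {
  if (sigma_e2 <= 0) stop("sigma_e2 must be positive")
  if (length(y_j) != length(x_j)) stop("vectors of unequal length")
  xty <- sum(y_j * x_j)
  xtx <- sum(x_j * x_j)
  log_bf <- log_bf_stats(xty, xtx, ghat, sigma_e2)
  list(log_bf = log_bf, bf = exp(log_bf))
}

# log Bayes factor from sufficient statistics (vectorized)
log_bf_stats <- function(xty, xtx, ghat, sigma_e2) {
  (ghat / sigma_e2) * (xty - 0.5 * ghat * xtx)
}
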