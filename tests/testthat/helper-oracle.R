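# Independent quadrature oracle for the one-locus posterior under the
# spike-plus-Laplace prior.  Works directly from the unnormalized
# posterior kernel p(y|g) p(g|gamma) with adaptive quadrature on each half
# line, each piece scaled by the maximum of its log integrand so that
# extreme parameter draws stay representable.

oracle_logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log unnormalized continuous posterior kernel (slab part)
oracle_lkern <- function(g, Y, s2, gamma, lambda) {
  log(gamma * lambda / 2) - lambda * abs(g) +
    dnorm((g - Y) / sqrt(s2), log = TRUE) - log(sqrt(s2))
}

# scaled integrals over one half line; returns log of integral of
# exp(lkern) and the (signed) first-moment integral relative to that scale
oracle_halfline <- function(side, Y, s2, gamma, lambda) {
  sgn <- if (side == "pos") 1 else -1
  gstar <- Y - sgn * lambda * s2          # unconstrained max of the exponent
  if (sgn * gstar < 0) gstar <- 0          # clamp to the half line
  M <- oracle_lkern(gstar, Y, s2, gamma, lambda)
  f0 <- function(g) exp(oracle_lkern(g, Y, s2, gamma, lambda) - M)
  f1 <- function(g) g * f0(g)
  # finite bounds: when the exponent's maximum is clamped at the boundary
  # the integrand decays at rate |slope|, else on the Gaussian scale
  slope <- (if (side == "pos") -lambda else lambda) - (gstar - Y) / s2
  wid <- if (gstar == 0 && abs(slope) > 0) min(sqrt(s2), 1 / abs(slope))
         else sqrt(s2)
  # window centered on the peak so narrow interior modes are not missed
  w <- 60 * wid
  if (side == "pos") {
    lo <- max(0, gstar - w); hi <- gstar + w
  } else {
    hi <- min(0, gstar + w); lo <- gstar - w
  }
  I0 <- integrate(f0, lo, hi, rel.tol = 1e-12, abs.tol = 0,
                  subdivisions = 1000L)$value
  I1 <- integrate(f1, lo, hi, rel.tol = 1e-12, abs.tol = 1e-300,
                  subdivisions = 1000L)$value
  list(M = M, I0 = I0, I1 = I1, lo = lo, hi = hi)
}

# normalized posterior summaries by quadrature: mean, log normalizer,
# spike mass, and P(g < t | y)
oracle_posterior <- function(Y, s2, gamma, lambda, t = NULL) {
  neg <- oracle_halfline("neg", Y, s2, gamma, lambda)
  pos <- oracle_halfline("pos", Y, s2, gamma, lambda)
  lspike <- log(1 - gamma) + dnorm(Y / sqrt(s2), log = TRUE) - log(sqrt(s2))
  lZ <- oracle_logsumexp(c(neg$M + log(max(neg$I0, 0)),
                           lspike,
                           pos$M + log(max(pos$I0, 0))))
  mean <- exp(neg$M - lZ) * neg$I1 + exp(pos$M - lZ) * pos$I1
  out <- list(mean = mean, lZ = lZ,
              spike_mass = exp(lspike - lZ),
              mass_neg = exp(neg$M + log(max(neg$I0, 0)) - lZ),
              mass_pos = exp(pos$M + log(max(pos$I0, 0)) - lZ))
  if (!is.null(t)) {
    out$cdf <- vapply(t, function(ti) {
      if (ti <= 0) {
        if (ti <= neg$lo) return(0)
        M <- neg$M
        I <- integrate(function(g)
          exp(oracle_lkern(g, Y, s2, gamma, lambda) - M), neg$lo, ti,
          rel.tol = 1e-12, abs.tol = 0, subdivisions = 1000L)$value
        exp(M + log(max(I, 0)) - lZ)
      } else {
        M <- pos$M
        I <- if (ti <= pos$lo) 0 else
          integrate(function(g)
            exp(oracle_lkern(g, Y, s2, gamma, lambda) - M), pos$lo,
            min(ti, pos$hi), rel.tol = 1e-12, abs.tol = 0,
            subdivisions = 1000L)$value
        exp(neg$M + log(max(neg$I0, 0)) - lZ) + exp(lspike - lZ) +
          exp(M + log(max(I, 0)) - lZ)
      }
    }, numeric(1))
  }
  out
}

# HWE genotype sampler used across tests
hwe_genotypes <- function(n, freqs) {
  sapply(freqs, function(f)
    sample(c(1L, 0L, -1L), n, replace = TRUE,
           prob = c(f^2, 2 * f * (1 - f), (1 - f)^2)))
}
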