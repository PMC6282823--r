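#' Genotype table
#'
#' Container for raw per-individual genotype codes together with the SNP map
#' and minor allele frequencies.  Codes are integers in \{-1, 0, 1\}: 1 for
#' the homozygote of the minor allele A, -1 for the homozygote of the major
#' allele B and 0 for the heterozygote.  If frequencies are not supplied
#' they are estimated by the method of moments and alleles are re-oriented
#' so that the frequency of the labeled A allele never exceeds 1/2.
#'
#' @param codes integer matrix (individuals x SNPs) with entries in
#'   \{-1, 0, 1\}, or \{0, 1, 2\} minor-allele dosages when
#'   `dialect = "dosage"`.
#' @param map optional data frame with columns `id`, `chrom`, `cM`, `bp`
#'   (one row per SNP).  A default map with unit spacing is created when
#'   missing.
#' @param maf optional numeric vector of per-SNP allele frequencies in
#'   (0, 0.5]; estimated from `codes` when `NULL`.
#' @param dialect `"code"` for \{-1, 0, 1\} input or `"dosage"` for PLINK-raw
#'   style \{0, 1, 2\} dosages (converted by subtracting 1).
#' @return An object of class `genotype_table` with elements `codes`, `map`,
#'   `maf` and a logical `monomorphic` flag per SNP.
#' @export
genotype_table <- function(codes, map = NULL, maf = NULL,
                           dialect = c("code", "dosage")) {
  dialect <- match.arg(dialect)
  codes <- as.matrix(codes)
  if (any(is.na(codes)))
    stop("missing genotype codes: ", sum(is.na(codes)),
         " entries; impute before import")
  if (dialect == "dosage") codes <- codes - 1L
  storage.mode(codes) <- "integer"
  if (!all(codes %in% c(-1L, 0L, 1L)))
    stop("genotype codes must be in {-1, 0, 1} (or {0, 1, 2} dosages)")
  p <- ncol(codes)
  if (is.null(map)) {
    map <- data.frame(id = paste0("snp", seq_len(p)), chrom = 1L,
                      cM = seq_len(p), bp = seq_len(p) * 1e6)
  }
  stopifnot(nrow(map) == p)
  if (is.null(maf)) {
    f <- estimate_maf(codes)
    flip <- attr(f, "flipped")
    if (any(flip)) codes[, flip] <- -codes[, flip]
    maf <- as.numeric(f)
  } else {
    stopifnot(length(maf) == p)
    if (any(maf < 0 | maf > 0.5)) stop("supplied maf must lie in [0, 0.5]")
  }
  structure(list(codes = codes, map = map, maf = maf,
                 monomorphic = maf <= 0),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$codes), "individuals x", ncol(x$codes),
      "SNPs\n")
  cat("  MAF range:", format(range(x$maf), digits = 3),
      " monomorphic:", sum(x$monomorphic), "\n")
  invisible(x)
}

#' Method-of-moments minor allele frequency
#'
#' Estimates the frequency of the labeled A allele as
#' f_j = (1 / 2n) * sum_i (X_ij + 1).  SNPs whose raw estimate exceeds 1/2
#' are marked for allele re-orientation (code negation) and the frequency is
#' replaced by 1 - f, so the returned values always lie in \[0, 0.5\].
#'
#' @param codes integer matrix or vector of genotype codes in \{-1, 0, 1\}.
#' @return Numeric vector of minor allele frequencies with attributes
#'   `flipped` (logical, allele labels swapped) and `monomorphic`.
#' @export
estimate_maf <- function(codes) {
  codes <- as.matrix(codes)
  if (nrow(codes) < 1L || ncol(codes) < 1L) stop("empty genotype matrix")
  if (any(is.na(codes))) stop("missing genotype codes")
  f <- colMeans(codes + 1) / 2
  flip <- f > 0.5
  f[flip] <- 1 - f[flip]
  structure(f, flipped = flip, monomorphic = f <= 0)
}

#' Remove SNPs at or below a minor allele frequency threshold
#'
#' Keeps SNPs with f_j > `threshold` (a SNP with f exactly equal to the
#' threshold is removed), preserving SNP order.  When the table's map carries
#' a `causative` column, the identities of removed causative SNPs are
#' recorded in the `dropped_causative` attribute.
#'
#' @param table a [genotype_table()].
#' @param threshold frequency threshold in \[0, 0.5).
#' @return The filtered `genotype_table`.
#' @export
filter_maf <- function(table, threshold = 0.05) {
  stopifnot(inherits(table, "genotype_table"))
  if (threshold < 0 || threshold >= 0.5)
    stop("threshold must lie in [0, 0.5)")
  keep <- table$maf > threshold
  dropped <- NULL
  if (!is.null(table$map$causative))
    dropped <- table$map$id[!keep & table$map$causative]
  out <- structure(list(codes = table$codes[, keep, drop = FALSE],
                        map = table$map[keep, , drop = FALSE],
                        maf = table$maf[keep],
                        monomorphic = table$monomorphic[keep]),
                   class = "genotype_table")
  attr(out, "dropped_causative") <- dropped
  out
}

check_freq <- function(f) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("allele frequency must lie strictly in (0, 1); monomorphic SNPs ",
         "have zero code variance and must be filtered out")
  invisible(f)
}

#' Standardized additive genotype codes
#'
#' Maps codes 1, 0, -1 to 2(1-f)/s, (1-2f)/s and -2f/s with
#' s = sqrt(2 f (1-f)), so that the column has mean zero and variance one
#' under Hardy-Weinberg proportions at frequency f.
#'
#' @param codes vector of genotype codes in \{-1, 0, 1\}.
#' @param f minor allele frequency in (0, 0.5].
#' @return Numeric vector of standardized codes.
#' @export
code_additive <- function(codes, f) {
  check_freq(f)
  s <- sqrt(2 * f * (1 - f))
  (codes + 1 - 2 * f) / s
}

#' Standardized dominance genotype codes (Falconer parameterization)
#'
#' Maps codes 1, 0, -1 (AA, Aa, BB) to -2(1-f)^2/s^2, 2f(1-f)/s^2 and
#' -2f^2/s^2 with s^2 = 2 f (1-f).  Under Hardy-Weinberg proportions the
#' column has mean zero, variance one, and is orthogonal to the additive
#' column of the same locus.
#'
#' @inheritParams code_additive
#' @return Numeric vector of standardized dominance codes.
#' @export
code_dominance <- function(codes, f) {
  check_freq(f)
  s2 <- 2 * f * (1 - f)
  out <- numeric(length(codes))
  out[codes == 1L] <- -2 * (1 - f)^2 / s2
  out[codes == 0L] <- 2 * f * (1 - f) / s2
  out[codes == -1L] <- -2 * f^2 / s2
  out
}

#' Epistatic product codes
#'
#' A pairwise epistatic design column is the elementwise product of the two
#' kind-appropriate main-effect columns: `"aa"` = additive(i) x additive(j),
#' `"ad"` = additive(i) x dominance(j), `"da"` = dominance(i) x additive(j),
#' `"dd"` = dominance(i) x dominance(j).
#'
#' @param kind one of `"aa"`, `"ad"`, `"da"`, `"dd"`.
#' @param codes_i,codes_j genotype code vectors of the two loci.
#' @param f_i,f_j their minor allele frequencies.
#' @return Numeric vector of standardized epistatic codes.
#' @export
code_epistatic <- function(kind = c("aa", "ad", "da", "dd"), codes_i, codes_j,
                           f_i, f_j) {
  kind <- match.arg(kind)
  if (length(codes_i) != length(codes_j))
    stop("code vectors must have equal length")
  ci <- if (substr(kind, 1, 1) == "a") code_additive(codes_i, f_i)
        else code_dominance(codes_i, f_i)
  cj <- if (substr(kind, 2, 2) == "a") code_additive(codes_j, f_j)
        else code_dominance(codes_j, f_j)
  ci * cj
}

#' Center a trait by its population mean
#'
#' @param raw numeric vector of trait values, length >= 2.
#' @return Object of class `trait_vector` with elements `values` (centered)
#'   and `center` (the subtracted mean).
#' @export
center_trait <- function(raw) {
  if (length(raw) < 2L) stop("need at least two observations")
  if (any(!is.finite(raw))) stop("non-finite trait values")
  m <- mean(raw)
  structure(list(values = raw - m, center = m), class = "trait_vector")
}

# Standardized design matrices for a genotype table; used by the solver and
# by predict().  Returns list(Xa, Xd) of n x p numeric matrices.
build_design <- function(gt, need_dom = TRUE) {
  codes <- gt$codes
  f <- gt$maf
  check_freq(f)
  n <- nrow(codes)
  s <- sqrt(2 * f * (1 - f))
  Xa <- sweep(codes + 1, 2, 2 * f, "-")
  Xa <- sweep(Xa, 2, s, "/")
  Xd <- NULL
  if (need_dom) {
    s2 <- 2 * f * (1 - f)
    hetv <- 2 * f * (1 - f) / s2           # = 1
    aav <- -2 * (1 - f)^2 / s2
    bbv <- -2 * f^2 / s2
    Xd <- matrix(0, n, ncol(codes))
    for (j in seq_len(ncol(codes))) {
      x <- codes[, j]
      Xd[, j] <- ifelse(x == 1L, aav[j], ifelse(x == 0L, hetv[j], bbv[j]))
    }
  }
  list(Xa = Xa, Xd = Xd)
}
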