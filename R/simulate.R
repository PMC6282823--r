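#' Simulation configuration
#'
#' Parameters of the forward-in-time population and trait simulator.  The
#' defaults describe a dairy-cattle-like design: ~52,773 SNPs on a 30-Morgan
#' genome (30 chromosomes of 1 Morgan), 400 burn-in generations of random
#' mating among 100 individuals with recombination and mutation to build up
#' linkage disequilibrium, then 4 generations in which 50 sires are each
#' mated to 20 dams (half-sib families; 1,000 offspring per generation, the
#' first two generations forming the training set of n = 2,000 and the last
#' two the validation set), a marker panel thinned to every 10th SNP with
#' the causative variants forced in and SNPs with MAF <= 0.05 removed, 23
#' causative variants carrying additive and dominance effects, 6 interacting
#' pairs for each of the four epistatic kinds, with dominance contributing
#' about 10% and epistasis about 29% of the total genetic variance, and a
#' broad-sense heritability of 0.3 or 0.5.
#'
#' The per-SNP mutation rate (default 2e-3 per meiosis) acts as a stand-in
#' for founder haplotype diversity: it is set so that after the burn-in
#' about 85% of the thinned panel segregates at MAF > 0.05, matching the
#' marker density the design describes.  Physical positions use 1 cM = 1 Mbp.
#'
#' @param n_snps number of simulated SNPs.
#' @param genome_morgan total genetic map length in Morgan.
#' @param n_chr number of chromosomes (equal length).
#' @param burnin_generations,burnin_popsize random-mating burn-in.
#' @param final_generations number of sire-dam generations (first half
#'   training, second half validation).
#' @param n_sires,dams_per_sire mating design of the final generations.
#' @param thin keep every `thin`-th SNP (causatives always kept).
#' @param maf_threshold remove SNPs with MAF at or below this value.
#' @param n_causative number of causative variants.
#' @param epi_pairs_per_kind interacting pairs per epistatic kind.
#' @param dominance_var_fraction,epistasis_var_fraction target shares of
#'   the total genetic variance.
#' @param h2 broad-sense heritability of the simulated trait.
#' @param mutation_rate per-SNP allele flip probability per meiosis.
#' @param seed optional RNG seed applied by [simulate_population()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_snps = 52773, genome_morgan = 30, n_chr = 30,
                       burnin_generations = 400, burnin_popsize = 100,
                       final_generations = 4, n_sires = 50,
                       dams_per_sire = 20, thin = 10, maf_threshold = 0.05,
                       n_causative = 23, epi_pairs_per_kind = 6,
                       dominance_var_fraction = 0.10,
                       epistasis_var_fraction = 0.29, h2 = 0.5,
                       mutation_rate = 2e-3, seed = NULL) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[c("n_snps", "genome_morgan", "n_chr",
                       "burnin_generations", "burnin_popsize",
                       "final_generations", "n_sires", "dams_per_sire",
                       "thin", "n_causative", "epi_pairs_per_kind")]) <= 0))
    stop("all counts must be positive")
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  if (dominance_var_fraction + epistasis_var_fraction >= 1)
    stop("variance fractions must sum to less than 1")
  if (final_generations %% 2 != 0)
    stop("final_generations must be even (training/validation split)")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a structured population (genotypes only)
#'
#' Forward-in-time simulation: founder haplotypes are Bernoulli(1/2),
#' burn-in generations mate randomly at constant population size, then the
#' sire-dam generations create half-sib families.  Meioses place crossovers
#' as a Poisson process along the genetic map (Haldane, no interference)
#' and flip alleles at the mutation rate.  Afterwards allele labels are
#' oriented to the minor allele (frequencies estimated on the training
#' generations), causative variants are drawn among SNPs segregating above
#' the MAF threshold, the panel is thinned to every `thin`-th SNP plus the
#' causatives, and the MAF filter is applied.
#'
#' @param config a [sim_config()].
#' @return Object of class `wgr_population`: list with `geno_train` and
#'   `geno_val` ([genotype_table()]s over the analyzed panel, training-set
#'   frequencies attached to both), `causative` (panel indices and map
#'   rows), `pedigree` (generation, sire, dam per final individual) and
#'   `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$n_snps
  n_chr <- config$n_chr
  chr_len_m <- config$genome_morgan / n_chr

  # SNP map: jittered-uniform genetic positions, 1 cM = 1 Mbp
  per_chr <- diff(round(seq(0, p, length.out = n_chr + 1)))
  chrom <- rep(seq_len(n_chr), per_chr)
  pos <- unlist(lapply(per_chr, function(k) sort(runif(k, 0, chr_len_m))))
  chr_first <- match(seq_len(n_chr), chrom)
  chr_last <- p + 1L - match(seq_len(n_chr), rev(chrom))
  map <- data.frame(id = sprintf("snp%05d", seq_len(p)), chrom = chrom,
                    cM = round(pos * 100, 4), bp = round(pos * 1e8))

  N <- config$burnin_popsize
  hap <- matrix(as.integer(runif(p * 2 * N) < 0.5), p, 2 * N)

  new_gen <- function(hap, fathers, mothers) {
    gam <- drop_gametes_cpp(hap, c(fathers, mothers) - 1L, pos,
                            chr_first - 1L, chr_last - 1L,
                            rep(chr_len_m, n_chr), config$mutation_rate)
    n_off <- length(fathers)
    out <- matrix(0L, p, 2 * n_off)
    out[, seq(1, 2 * n_off, 2)] <- gam[, seq_len(n_off)]
    out[, seq(2, 2 * n_off, 2)] <- gam[, n_off + seq_len(n_off)]
    out
  }

  for (g in seq_len(config$burnin_generations)) {
    fathers <- sample.int(N, N, replace = TRUE)
    mothers <- sample.int(N, N, replace = TRUE)
    clash <- fathers == mothers
    while (any(clash)) {  # no selfing
      mothers[clash] <- sample.int(N, sum(clash), replace = TRUE)
      clash <- fathers == mothers
    }
    hap <- new_gen(hap, fathers, mothers)
  }

  n_off <- config$n_sires * config$dams_per_sire
  codes_gen <- vector("list", config$final_generations)
  ped <- vector("list", config$final_generations)
  prev_n <- N
  for (g in seq_len(config$final_generations)) {
    sires <- sample.int(prev_n, config$n_sires)
    dams <- if (prev_n >= n_off) sample.int(prev_n, n_off)
            else sample.int(prev_n, n_off, replace = TRUE)
    fathers <- rep(sires, each = config$dams_per_sire)
    hap <- new_gen(hap, fathers, dams)
    prev_n <- n_off
    codes_gen[[g]] <- t(hap[, seq(1, 2 * n_off, 2)] +
                          hap[, seq(2, 2 * n_off, 2)] - 1L)
    ped[[g]] <- data.frame(generation = g, sire = fathers, dam = dams)
  }

  half <- config$final_generations / 2
  train <- do.call(rbind, codes_gen[seq_len(half)])
  val <- do.call(rbind, codes_gen[half + seq_len(half)])

  # orient to the minor allele using training frequencies
  f <- colMeans(train + 1L) / 2
  flip <- f > 0.5
  if (any(flip)) {
    train[, flip] <- -train[, flip]
    val[, flip] <- -val[, flip]
    f[flip] <- 1 - f[flip]
  }

  eligible <- which(f > config$maf_threshold)
  if (length(eligible) < config$n_causative)
    stop("fewer than ", config$n_causative,
         " SNPs segregate above the MAF threshold")
  causative <- sort(sample(eligible, config$n_causative))

  panel <- sort(union(seq(1, p, by = config$thin), causative))
  keep <- panel[f[panel] > config$maf_threshold]
  map_keep <- map[keep, , drop = FALSE]
  map_keep$causative <- keep %in% causative
  rownames(map_keep) <- NULL

  gt <- function(codes) structure(
    list(codes = codes[, keep, drop = FALSE], map = map_keep, maf = f[keep],
         monomorphic = rep(FALSE, length(keep))),
    class = "genotype_table")

  structure(list(
    geno_train = gt(train), geno_val = gt(val),
    causative = data.frame(index = match(causative, keep),
                           map[causative, c("id", "chrom", "cM", "bp")],
                           row.names = NULL),
    pedigree = do.call(rbind, ped),
    n_panel_prefilter = length(panel),
    config = config), class = "wgr_population")
}

#' Attach a simulated trait
#'
#' Draws additive and dominance effects (standard normal) for every
#' causative variant and one effect per interacting pair, builds true
#' genetic values from the standardized design columns, rescales the
#' dominance and epistasis blocks so their realized variance shares match
#' the configured fractions, and adds Gaussian noise so that the realized
#' broad-sense heritability equals `config$h2` on the training set.
#'
#' @param population a [simulate_population()] result.
#' @param config the same [sim_config()] (defaults to the one stored in the
#'   population).
#' @return Object of class `wgr_dataset`: the population plus `trait`
#'   (training phenotypes) and `truth` (effect vectors, interacting pairs,
#'   true genetic values of both sets, realized variance shares, residual
#'   variance).
#' @export
attach_trait <- function(population, config = population$config) {
  stopifnot(inherits(population, "wgr_population"))
  nc <- config$n_causative
  ci <- population$causative$index
  gt <- population$geno_train
  gv <- population$geno_val
  f <- gt$maf[ci]

  a_raw <- rnorm(nc)
  d_raw <- rnorm(nc)
  kinds <- c("aa", "ad", "da", "dd")
  all_pairs <- t(utils::combn(nc, 2))
  epi <- do.call(rbind, lapply(kinds, function(k) {
    sel <- all_pairs[sample.int(nrow(all_pairs), config$epi_pairs_per_kind), ,
                     drop = FALSE]
    data.frame(kind = k, ci = sel[, 1], cj = sel[, 2], effect = rnorm(nrow(sel)))
  }))

  cols <- function(codes) {
    Xa <- sapply(seq_len(nc), function(k) code_additive(codes[, ci[k]], f[k]))
    Xd <- sapply(seq_len(nc), function(k) code_dominance(codes[, ci[k]], f[k]))
    Xe <- sapply(seq_len(nrow(epi)), function(r) {
      k <- epi$kind[r]
      u <- if (substr(k, 1, 1) == "a") Xa[, epi$ci[r]] else Xd[, epi$ci[r]]
      v <- if (substr(k, 2, 2) == "a") Xa[, epi$cj[r]] else Xd[, epi$cj[r]]
      u * v
    })
    list(Ga = Xa %*% a_raw, Gd = Xd %*% d_raw, Ge = Xe %*% epi$effect)
  }
  tr <- cols(gt$codes)
  add_frac <- 1 - config$dominance_var_fraction - config$epistasis_var_fraction
  Va <- var(as.numeric(tr$Ga)); Vd <- var(as.numeric(tr$Gd))
  Ve <- var(as.numeric(tr$Ge))
  if (Va == 0 || Vd == 0 || Ve == 0)
    stop("degenerate genotypes: a variance component is zero")
  c_d <- sqrt(config$dominance_var_fraction / add_frac * Va / Vd)
  c_e <- sqrt(config$epistasis_var_fraction / add_frac * Va / Ve)
  d_eff <- d_raw * c_d
  epi$effect <- epi$effect * c_e

  G_train <- as.numeric(tr$Ga + c_d * tr$Gd + c_e * tr$Ge)
  vl <- cols(gv$codes)
  # validation genetic values reuse the rescaled effects
  G_val <- as.numeric(vl$Ga + c_d * vl$Gd + c_e * vl$Ge)

  Vg <- var(G_train)
  sigma_e2 <- if (config$h2 == 1) 0 else Vg * (1 - config$h2) / config$h2
  trait <- G_train + rnorm(length(G_train), 0, sqrt(sigma_e2))

  epi$i <- ci[epi$ci]
  epi$j <- ci[epi$cj]
  truth <- list(
    causative = population$causative,
    additive = a_raw, dominance = d_eff, epistasis = epi,
    gv_train = G_train, gv_val = G_val,
    sigma_e2 = sigma_e2, h2 = config$h2,
    shares = c(additive = var(as.numeric(tr$Ga)) / Vg,
               dominance = var(as.numeric(c_d * tr$Gd)) / Vg,
               epistasis = var(as.numeric(c_e * tr$Ge)) / Vg))

  out <- population
  out$trait <- trait
  out$truth <- truth
  class(out) <- c("wgr_dataset", "wgr_population")
  out
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: [simulate_population()] followed by
#' [attach_trait()] under a single seed, so that identical configurations
#' give bit-identical datasets.
#'
#' @param config a [sim_config()].
#' @return A `wgr_dataset`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  attach_trait(simulate_population(config), config)
}

#' Permutation-null datasets
#'
#' Destroys the genotype-phenotype association by randomly reassigning the
#' rows of the training genotype matrix to the animals (the trait is left
#' unchanged).  Each permutation is reproducible from `(seed, index)`.
#'
#' @param dataset a `wgr_dataset`.
#' @param n_permutations number of shuffles.
#' @param seed base RNG seed; permutation k uses `seed + k`.
#' @return List of `wgr_dataset` objects with permuted training genotypes.
#' @export
permute_genotypes <- function(dataset, n_permutations, seed = 1) {
  stopifnot(inherits(dataset, "wgr_dataset"))
  n <- nrow(dataset$geno_train$codes)
  lapply(seq_len(n_permutations), function(k) {
    set.seed(seed + k)
    perm <- sample.int(n)
    out <- dataset
    out$geno_train$codes <- dataset$geno_train$codes[perm, , drop = FALSE]
    out$permutation <- perm
    out
  })
}
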