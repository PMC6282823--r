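#' Read a genotype matrix
#'
#' Supported formats: (a) TSV with a header of SNP ids, a first column of
#' individual ids and one row per individual, codes in \{-1, 0, 1\}
#' (`dialect = "code"`) or minor-allele dosages \{0, 1, 2\}
#' (`dialect = "dosage"`, converted by subtracting 1); (b) PLINK-raw style
#' whitespace-separated files with columns FID IID PAT MAT SEX PHENOTYPE
#' followed by per-SNP dosages (`dialect = "plink-raw"`; IID becomes the
#' individual id).  Missing genotypes are rejected with a count (impute
#' beforehand).
#'
#' @param path file path.
#' @param dialect input dialect, see Details.
#' @param map optional SNP map data frame (id, chrom, cM, bp) or path to a
#'   TSV readable by [read_snp_map()].
#' @return A [genotype_table()] with individual ids in
#'   `rownames(x$codes)`.
#' @export
read_genotypes <- function(path, dialect = c("code", "dosage", "plink-raw"),
                           map = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "plink-raw") {
    tab <- read.table(path, header = TRUE, check.names = FALSE)
    meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
    if (!all(meta %in% names(tab)))
      stop("plink-raw dialect requires columns ",
           paste(meta, collapse = " "))
    ids <- as.character(tab$IID)
    codes <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
    conv <- "dosage"
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    ids <- as.character(tab[[1]])
    codes <- as.matrix(tab[, -1, drop = FALSE])
    conv <- dialect
  }
  if (anyDuplicated(ids))
    stop("duplicated individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.numeric(codes)) stop("non-numeric genotype codes in ", path)
  if (any(is.na(codes)))
    stop(sum(is.na(codes)), " missing genotypes in ", path,
         "; impute before import")
  if (is.character(map)) map <- read_snp_map(map)
  if (!is.null(map)) {
    if (!all(colnames(codes) %in% map$id))
      stop("SNP ids missing from map: ",
           paste(head(setdiff(colnames(codes), map$id)), collapse = ", "))
    map <- map[match(colnames(codes), map$id), , drop = FALSE]
  }
  gt <- genotype_table(codes, map = map, dialect = conv)
  rownames(gt$codes) <- ids
  gt
}

#' Read a SNP map
#'
#' TSV with columns `id`, `chrom`, `cM`, `bp`.
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_snp_map <- function(path) {
  map <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("id", "chrom", "cM", "bp")
  if (!all(need %in% names(map)))
    stop("SNP map must have columns ", paste(need, collapse = ", "))
  map
}

#' Read phenotypes keyed by individual id
#'
#' TSV with columns `id` and a single trait column.  When `ids` is given,
#' the file must cover exactly those individuals; set differences are
#' reported.
#'
#' @param path file path.
#' @param ids optional character vector of expected individual ids.
#' @return Named numeric vector ordered like `ids` when supplied.
#' @export
read_phenotypes <- function(path, ids = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (ncol(tab) < 2) stop("phenotype file needs id and value columns")
  y <- setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
  if (anyDuplicated(names(y)))
    stop("duplicated individual ids in ", path)
  if (!is.null(ids)) {
    extra <- setdiff(names(y), ids)
    missing <- setdiff(ids, names(y))
    if (length(extra) || length(missing))
      stop("phenotype/genotype id mismatch; extra: ",
           paste(extra, collapse = ", "), "; missing: ",
           paste(missing, collapse = ", "))
    y <- y[ids]
  }
  y
}

#' Read a covariate table
#'
#' TSV keyed by individual id; remaining columns become fixed effects
#' (factors are expanded with reference levels by [gsbayes()]).
#'
#' @param path file path.
#' @param ids optional expected individual ids (order enforced).
#' @return Data frame without the id column, rows ordered like `ids`.
#' @export
read_covariates <- function(path, ids = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = TRUE)
  rid <- as.character(tab[[1]])
  if (anyDuplicated(rid)) stop("duplicated individual ids in ", path)
  tab <- tab[, -1, drop = FALSE]
  if (!is.null(ids)) {
    missing <- setdiff(ids, rid)
    if (length(missing))
      stop("covariates missing for: ", paste(missing, collapse = ", "))
    tab <- tab[match(ids, rid), , drop = FALSE]
  }
  tab
}

#' Write an effect-test table
#'
#' TSV with columns kind, snp_i, snp_j (SNP ids; empty for main effects),
#' ghat, kappa, moe, log10_bf and the per-level significance flags.
#'
#' @param tests a [significance()] result.
#' @param path output path.
#' @param all_coordinates write every tested coordinate (default) or only
#'   rows with a nonzero estimate.
#' @export
write_effect_table <- function(tests, path, all_coordinates = TRUE) {
  stopifnot(inherits(tests, "wgr_tests"))
  map <- attr(tests, "map")
  out <- as.data.frame(tests)
  if (!all_coordinates) out <- out[out$ghat != 0, , drop = FALSE]
  out$snp_i <- map$id[out$snp_i]
  out$snp_j <- ifelse(is.na(out$snp_j), "", map$id[out$snp_j])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report
#'
#' @param report a `wgr_eval` (or any named list of scalars).
#' @param path output path.
#' @param format `"tsv"` or `"json"` (requires the jsonlite package).
#' @export
write_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  flat <- unclass(report)
  flat <- flat[vapply(flat, function(x) is.atomic(x) && length(x) == 1,
                      logical(1))]
  if (format == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON output")
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    write.table(data.frame(metric = names(flat),
                           value = unlist(flat)),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write a genotype table and companion files
#'
#' Writes the genotype codes (TSV, \{-1,0,1\} codes, id column first), the
#' SNP map and optionally a phenotype file, in the formats read back by
#' [read_genotypes()], [read_snp_map()] and [read_phenotypes()].
#'
#' @param gt a [genotype_table()].
#' @param prefix output path prefix; writes `<prefix>_geno.tsv`,
#'   `<prefix>_map.tsv` and (when `trait` is given) `<prefix>_pheno.tsv`.
#' @param trait optional numeric trait vector.
#' @return The written paths, invisibly.
#' @export
write_genotypes <- function(gt, prefix, trait = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  ids <- rownames(gt$codes)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(gt$codes)))
  gfile <- paste0(prefix, "_geno.tsv")
  out <- data.frame(id = ids, gt$codes, check.names = FALSE)
  colnames(out) <- c("id", gt$map$id)
  write.table(out, gfile, sep = "\t", quote = FALSE, row.names = FALSE)
  mfile <- paste0(prefix, "_map.tsv")
  write.table(gt$map, mfile, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(gfile, mfile)
  if (!is.null(trait)) {
    pfile <- paste0(prefix, "_pheno.tsv")
    write.table(data.frame(id = ids, value = trait), pfile, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, pfile)
  }
  invisible(paths)
}
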