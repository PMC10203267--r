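# The genotype matrix is the substrate of every population statistic in the
# package: a samples x sites matrix of alt-allele dosages (0/1/2, NA for
# missing) plus per-site metadata (chrom, pos, ref, alt, DP, qual) and
# per-sample labels (sex, subgroup).

#' Construct a genotype matrix
#'
#' @param geno integer matrix of alt-allele dosages, samples in rows, sites in
#'   columns; `NA` encodes a missing genotype
#' @param sites data.frame with columns `chrom`, `pos` and optionally `ref`,
#'   `alt`, `dp`, `qual`; one row per column of `geno`
#' @param samples data.frame with columns `id` and optionally `sex`
#'   (`"F"`/`"M"`/`"unknown"`) and `subgroup`; one row per row of `geno`
#' @return an object of class `geno_matrix`
#' @export
geno_matrix <- function(geno, sites, samples) {
  geno <- as.matrix(geno)
  stopifnot(is.data.frame(sites), is.data.frame(samples))
  if (nrow(samples) != nrow(geno))
    stop("samples table has ", nrow(samples), " rows but geno has ",
         nrow(geno), " sample rows")
  if (nrow(sites) != ncol(geno))
    stop("sites table has ", nrow(sites), " rows but geno has ",
         ncol(geno), " site columns")
  stopifnot(all(c("chrom", "pos") %in% names(sites)),
            "id" %in% names(samples))
  if (!"sex" %in% names(samples)) samples$sex <- "unknown"
  if (!"subgroup" %in% names(samples)) samples$subgroup <- "other"
  for (col in c("ref", "alt")) if (!col %in% names(sites)) sites[[col]] <- NA_character_
  for (col in c("dp", "qual")) if (!col %in% names(sites)) sites[[col]] <- NA_real_
  ok <- is.na(geno) | (geno %in% 0:2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  rownames(geno) <- samples$id
  structure(list(geno = geno, sites = sites, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$geno), "samples x", ncol(x$geno), "sites\n")
  cat("  sex:", paste(names(table(x$samples$sex)),
                      table(x$samples$sex), sep = "=", collapse = " "), "\n")
  cat("  subgroup:", paste(names(table(x$samples$subgroup)),
                           table(x$samples$subgroup), sep = "=", collapse = " "), "\n")
  cat("  chroms:", paste(unique(x$sites$chrom), collapse = " "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param gm a [geno_matrix()]
#' @param sites logical or integer index over sites
#' @param samples logical or integer index over samples, or a character vector
#'   of sample ids
#' @return a `geno_matrix`
#' @export
gm_subset <- function(gm, sites = NULL, samples = NULL) {
  stopifnot(inherits(gm, "geno_matrix"))
  geno <- gm$geno; st <- gm$sites; sm <- gm$samples
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, sm$id)
    geno <- geno[samples, , drop = FALSE]
    sm <- sm[samples, , drop = FALSE]
  }
  if (!is.null(sites)) {
    geno <- geno[, sites, drop = FALSE]
    st <- st[sites, , drop = FALSE]
  }
  rownames(st) <- NULL; rownames(sm) <- NULL
  geno_matrix(geno, st, sm)
}

#' Select samples by label
#'
#' @param gm a [geno_matrix()]
#' @param subgroup subgroup label(s) to keep, or `NULL`
#' @param sex sex label(s) to keep, or `NULL`
#' @return a `geno_matrix` restricted to the matching samples
#' @export
gm_samples <- function(gm, subgroup = NULL, sex = NULL) {
  keep <- rep(TRUE, nrow(gm$samples))
  if (!is.null(subgroup)) keep <- keep & gm$samples$subgroup %in% subgroup
  if (!is.null(sex)) keep <- keep & gm$samples$sex %in% sex
  if (!any(keep)) stop("no samples match the requested labels")
  gm_subset(gm, samples = which(keep))
}

# Per-site allele bookkeeping used by every estimator: number of observed
# alleles (2 x non-missing genotypes), alt-allele count, alt frequency, and
# observed heterozygote count.
#' @noRd
site_allele_counts <- function(gm) {
  g <- gm$geno
  n_obs <- 2L * colSums(!is.na(g))
  alt <- colSums(g, na.rm = TRUE)
  het <- colSums(g == 1L, na.rm = TRUE)
  list(n = n_obs, alt = alt, het = het,
       p = ifelse(n_obs > 0, alt / n_obs, NA_real_))
}
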