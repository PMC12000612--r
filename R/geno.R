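#' Genotype matrix container
#'
#' Bundles an individuals-by-SNPs allele-count matrix with its SNP map and
#' individual identifiers. Calls count copies of allele A1 and take values
#' 0, 1 or 2, with `NA` as the missing sentinel.
#'
#' @param calls Integer matrix, individuals in rows, SNPs in columns. Entries
#'   must be 0, 1, 2 or `NA`.
#' @param map Data frame with one row per SNP and columns `snp`, `chr`, `bp`,
#'   `a1`, `a2`. Positions are 1-based; windows elsewhere in the package are
#'   inclusive on both ends.
#' @param ids Character vector of unique individual identifiers.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, map, ids) {
  calls <- as.matrix(calls)
  if (!is.numeric(calls)) stop("`calls` must be numeric")
  rng <- range(calls, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("genotype calls must lie in {0, 1, 2}")
  map <- as.data.frame(map)
  need <- c("snp", "chr", "bp", "a1", "a2")
  if (!all(need %in% names(map))) {
    stop("`map` must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(map) != ncol(calls)) stop("map rows must match SNP columns")
  if (any(map$bp < 0)) stop("positions must be non-negative")
  ids <- as.character(ids)
  if (length(ids) != nrow(calls)) stop("ids must match rows of `calls`")
  if (anyDuplicated(ids)) stop("individual ids must be unique")
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(ids, map$snp)
  structure(list(calls = calls, map = map, ids = ids), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d SNPs\n",
              nrow(x$calls), ncol(x$calls)))
  cat(sprintf("  chromosomes: %s; missing calls: %d\n",
              paste(unique(x$map$chr), collapse = ","),
              sum(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Minor allele frequency per SNP
#'
#' A1 frequency folded to the minor side, computed on non-missing calls.
#'
#' @param g A [geno_matrix()].
#' @param fold If `FALSE`, return the raw A1 allele frequency instead of the
#'   folded minor-allele frequency.
#' @return Numeric vector, one entry per SNP.
#' @export
geno_maf <- function(g, fold = TRUE) {
  f <- colMeans(g$calls, na.rm = TRUE) / 2
  if (fold) pmin(f, 1 - f) else f
}

#' Subset a genotype matrix
#'
#' @param g A [geno_matrix()].
#' @param i Row (individual) index, any form accepted by matrix indexing.
#' @param j Column (SNP) index.
#' @return A `geno_matrix` restricted to the selected individuals and SNPs.
#' @export
geno_subset <- function(g, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(g$calls))
  if (is.null(j)) j <- seq_len(ncol(g$calls))
  geno_matrix(g$calls[i, j, drop = FALSE], g$map[j, , drop = FALSE],
              g$ids[i])
}

#' Observed heterozygosity per individual
#'
#' Fraction of non-missing calls that are heterozygous, over an optional SNP
#' subset.
#'
#' @param g A [geno_matrix()].
#' @param snps Optional SNP column index used for the computation.
#' @return Named numeric vector, one entry per individual.
#' @export
geno_heterozygosity <- function(g, snps = NULL) {
  calls <- if (is.null(snps)) g$calls else g$calls[, snps, drop = FALSE]
  rowMeans(calls == 1L, na.rm = TRUE)
}
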