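fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.15g", x))
}

write_tsv_lines <- function(header_cols, body_lines, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) {
    writeLines(paste0("# ", comments), con)
  }
  writeLines(paste(header_cols, collapse = "\t"), con)
  writeLines(body_lines, con)
  invisible(path)
}

read_tsv_skip_comments <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write / read an association table as a sumstats TSV
#'
#' Tab-separated summary statistics with the ldsc-compatible header
#' `SNP CHR BP A1 A2 BETA SE Z P N`. Numeric fields are written with 15
#' significant digits (p-values in scientific notation with 6 significant
#' digits, enough to survive round-trips at genome-wide scales).
#'
#' @param assoc An `assoc_table`.
#' @param path Output file path.
#' @param n Per-SNP `N` column; defaults to `n_used`. Pass an
#'   [effective_sample_size()] result (or vector) to export effective
#'   sample sizes for LD-score regression.
#' @param comments Optional character vector written as leading `#` lines.
#' @return `write_sumstats` returns `path` invisibly; `read_sumstats`
#'   returns a data frame with lower-case `assoc_table`-style columns.
#' @export
write_sumstats <- function(assoc, path, n = NULL, comments = NULL) {
  if (is.null(n)) {
    n <- assoc$n_used
  } else if (inherits(n, "neff_summary")) {
    n <- n$per_snp$n_eff[match(assoc$snp, n$per_snp$snp)]
  }
  body <- paste(assoc$snp, assoc$chr, assoc$bp, toupper(assoc$a1),
                toupper(assoc$a2), fmt_num(assoc$beta), fmt_num(assoc$se),
                fmt_num(assoc$z),
                ifelse(is.na(assoc$p), "NA", sprintf("%.6e", assoc$p)),
                fmt_num(n), sep = "\t")
  write_tsv_lines(c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "Z",
                    "P", "N"), body, path, comments)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  df <- read_tsv_skip_comments(path)
  need <- c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "Z", "P", "N")
  if (!all(need %in% names(df))) {
    stop("malformed sumstats header; expected columns ",
         paste(need, collapse = " "))
  }
  out <- data.frame(snp = as.character(df$SNP), chr = df$CHR, bp = df$BP,
                    a1 = as.character(df$A1), a2 = as.character(df$A2),
                    beta = df$BETA, se = df$SE, z = df$Z, p = df$P,
                    n_used = df$N, stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' Write / read a genotype matrix as plain-text TSV
#'
#' Two files: `<stem>.geno.tsv` holds the calls (rows = individuals, first
#' column `ID`, one column per SNP, missing coded `NA`) and
#' `<stem>.snps.tsv` holds the SNP map.
#'
#' @param g A [geno_matrix()].
#' @param stem Path stem without extension.
#' @param comments Optional `#` header lines for both files.
#' @return `write_genotypes_tsv` returns the stem invisibly;
#'   `read_genotypes_tsv` returns the reconstructed [geno_matrix()].
#' @export
write_genotypes_tsv <- function(g, stem, comments = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  body <- vapply(seq_len(nrow(g$calls)), function(i) {
    paste(c(g$ids[i], ifelse(is.na(g$calls[i, ]), "NA", g$calls[i, ])),
          collapse = "\t")
  }, character(1))
  write_tsv_lines(c("ID", g$map$snp), body,
                  paste0(stem, ".geno.tsv"), comments)
  map_body <- do.call(paste, c(lapply(g$map, as.character), sep = "\t"))
  write_tsv_lines(names(g$map), map_body, paste0(stem, ".snps.tsv"),
                  comments)
  invisible(stem)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(stem) {
  geno_path <- paste0(stem, ".geno.tsv")
  map_path <- paste0(stem, ".snps.tsv")
  if (!file.exists(geno_path) || !file.exists(map_path)) {
    stop("expected files ", geno_path, " and ", map_path)
  }
  df <- read_tsv_skip_comments(geno_path)
  if (names(df)[1] != "ID") stop("malformed genotype TSV: first column ",
                                 "must be ID")
  map <- read_tsv_skip_comments(map_path)
  calls <- as.matrix(df[, -1, drop = FALSE])
  if (ncol(calls) != nrow(map)) {
    stop("genotype columns do not match the SNP map")
  }
  geno_matrix(calls, map, as.character(df$ID))
}

#' Write / read PLINK bed/bim/fam
#'
#' Binary PLINK 1 format, SNP-major: magic bytes `0x6c 0x1b 0x01`, then
#' `ceil(n/4)` bytes per SNP with two bits per genotype (`00` = two copies
#' of A1, `10` = heterozygote, `11` = zero copies, `01` = missing).
#'
#' @param g A [geno_matrix()].
#' @param stem Path stem; `.bed`, `.bim` and `.fam` siblings are written
#'   or expected.
#' @return `write_plink` returns the stem invisibly; `read_plink` the
#'   reconstructed [geno_matrix()].
#' @export
write_plink <- function(g, stem) {
  stopifnot(inherits(g, "geno_matrix"))
  n <- nrow(g$calls); m <- ncol(g$calls)
  utils::write.table(
    data.frame(g$map$chr, g$map$snp, 0, g$map$bp, g$map$a1, g$map$a2),
    paste0(stem, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(g$ids, g$ids, 0, 0, 0, -9),
    paste0(stem, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  # allele-count -> 2-bit code
  code_lut <- c(3L, 2L, 0L)                 # counts 0, 1, 2
  codes <- matrix(1L, ((n + 3L) %/% 4L) * 4L, m)   # pad with "missing"
  obs <- g$calls
  cd <- matrix(code_lut[obs + 1L], n, m)
  cd[is.na(obs)] <- 1L
  codes[seq_len(n), ] <- cd
  dim(codes) <- c(4L, length(codes) %/% 4L)
  bytes <- as.raw(codes[1, ] + 4L * codes[2, ] + 16L * codes[3, ] +
                    64L * codes[4, ])
  con <- file(paste0(stem, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(stem)
}

#' @rdname write_plink
#' @export
read_plink <- function(stem) {
  bim <- utils::read.table(paste0(stem, ".bim"), sep = "\t",
                           stringsAsFactors = FALSE)
  names(bim) <- c("chr", "snp", "cm", "bp", "a1", "a2")
  fam <- utils::read.table(paste0(stem, ".fam"), sep = "\t",
                           stringsAsFactors = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  bed_path <- paste0(stem, ".bed")
  raw <- readBin(bed_path, "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3 || !identical(as.integer(raw[1:3]),
                                    c(0x6cL, 0x1bL, 0x01L))) {
    stop("not a SNP-major PLINK .bed file: ", bed_path)
  }
  per_snp <- (n + 3L) %/% 4L
  expected <- 3L + per_snp * m
  if (length(raw) != expected) {
    stop("truncated or oversized .bed payload: expected ", expected,
         " bytes, found ", length(raw))
  }
  b <- as.integer(raw[-(1:3)])
  codes <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L,
                 (b %/% 64L) %% 4L)
  dim(codes) <- c(per_snp * 4L, m)
  codes <- codes[seq_len(n), , drop = FALSE]
  count_lut <- c(2L, NA_integer_, 1L, 0L)   # codes 0, 1, 2, 3
  calls <- matrix(count_lut[codes + 1L], n, m)
  geno_matrix(calls,
              data.frame(snp = bim$snp, chr = bim$chr, bp = bim$bp,
                         a1 = bim$a1, a2 = bim$a2,
                         stringsAsFactors = FALSE),
              as.character(fam[[2]]))
}

#' Read genotypes in either supported format
#'
#' @param path Path stem (PLINK) or stem of the TSV pair.
#' @param format `"plink_bed"` or `"tsv"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("plink_bed", "tsv")) {
  format <- match.arg(format)
  if (format == "plink_bed") read_plink(path) else read_genotypes_tsv(path)
}

#' Write / read an IP weight file
#'
#' TSV with columns `ID` and `W`; when a fitted participation model is
#' supplied its selected terms are serialised to a JSON sidecar
#' `<path>.json`.
#'
#' @param ipw An [compute_ip_weights()] result.
#' @param path Output TSV path.
#' @param model Optional [fit_participation_model()] result.
#' @param comments Optional `#` header lines.
#' @return `write_weights` returns `path` invisibly; `read_weights` a data
#'   frame with columns `ID` and `W`.
#' @export
write_weights <- function(ipw, path, model = NULL, comments = NULL) {
  stopifnot(inherits(ipw, "ip_weight_set"))
  body <- paste(ipw$ids, fmt_num(ipw$w), sep = "\t")
  write_tsv_lines(c("ID", "W"), body, path, comments)
  if (!is.null(model)) {
    jsonlite::write_json(
      list(link = model$link, lambda = model$lambda,
           selected_terms = model$selected_terms,
           intercept = model$intercept,
           coefficients = as.list(model$coefficients[
             model$coefficients != 0])),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- read_tsv_skip_comments(path)
  if (!all(c("ID", "W") %in% names(df))) {
    stop("weight file must have columns ID and W")
  }
  df$ID <- as.character(df$ID)
  df
}
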