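align_assoc <- function(assoc_g, assoc_w) {
  ord <- match(assoc_g$snp, assoc_w$snp)
  if (anyNA(ord) || length(assoc_g$snp) != length(assoc_w$snp)) {
    stop("the two association tables must cover the same SNP set")
  }
  aw <- assoc_w[ord, ]
  bad <- which(assoc_g$a1 != aw$a1 | assoc_g$a2 != aw$a2)
  if (length(bad) > 0) {
    stop("allele mismatch between tables for SNP(s): ",
         paste(utils::head(assoc_g$snp[bad], 5), collapse = ", "))
  }
  aw
}

#' Per-SNP Hausman test between an unweighted and a weighted scan
#'
#' Contrasts the unweighted estimator (efficient under the null of no
#' volunteer bias) with the IP-weighted estimator (consistent under
#' selection): `H = (beta_g - beta_w)^2 / (se_w^2 - se_g^2)`, referred to a
#' chi-squared distribution with one degree of freedom. Where the variance
#' of the difference is not positive the statistic is marked invalid and
#' the p-value left missing, never clamped.
#'
#' @param assoc_g,assoc_w Unweighted and weighted `assoc_table`s over the
#'   same SNPs with identical allele orientation.
#' @return A `hausman_table` data frame with columns `snp`, `delta`,
#'   `var_delta`, `h`, `p_h` and `valid`.
#' @export
hausman_test <- function(assoc_g, assoc_w) {
  aw <- align_assoc(assoc_g, assoc_w)
  delta <- assoc_g$beta - aw$beta
  var_delta <- aw$se^2 - assoc_g$se^2
  valid <- is.finite(var_delta) & var_delta > 0 & is.finite(delta)
  h <- ifelse(valid, delta^2 / var_delta, NA_real_)
  p_h <- ifelse(valid, stats::pchisq(h, df = 1, lower.tail = FALSE),
                NA_real_)
  out <- data.frame(snp = assoc_g$snp, delta = delta,
                    var_delta = var_delta, h = h, p_h = p_h,
                    valid = valid, stringsAsFactors = FALSE)
  class(out) <- c("hausman_table", "data.frame")
  out
}

#' Per-SNP effective sample size
#'
#' `N_eff = sigma2_y / (SE^2 * 2 MAF (1 - MAF))`: the size of a simple
#' random sample that would produce the observed standard error given the
#' phenotype variance and the allele frequency. The scan-level summary is
#' the mean over SNPs.
#'
#' @param assoc An `assoc_table`.
#' @param sigma2_y Variance of the (residualised, possibly weighted)
#'   phenotype; defaults to the value recorded on the table.
#' @return An object of class `neff_summary` with the per-SNP table
#'   (`$per_snp`) and the mean (`$mean_neff`).
#' @export
effective_sample_size <- function(assoc, sigma2_y = NULL) {
  if (is.null(sigma2_y)) sigma2_y <- attr(assoc, "sigma2_y")
  if (is.null(sigma2_y) || !is.finite(sigma2_y) || sigma2_y <= 0) {
    stop("sigma2_y must be a positive variance")
  }
  if (any(assoc$maf <= 0 | assoc$maf >= 1, na.rm = TRUE)) {
    stop("MAF must lie strictly in (0, 1) for the effective sample size")
  }
  n_eff <- sigma2_y / (assoc$se^2 * 2 * assoc$maf * (1 - assoc$maf))
  structure(list(per_snp = data.frame(snp = assoc$snp, n_eff = n_eff,
                                      stringsAsFactors = FALSE),
                 mean_neff = mean(n_eff, na.rm = TRUE),
                 sigma2_y = sigma2_y),
            class = "neff_summary")
}

#' @export
print.neff_summary <- function(x, ...) {
  cat(sprintf("<neff_summary> mean N_eff = %.1f over %d SNPs\n",
              x$mean_neff, nrow(x$per_snp)))
  invisible(x)
}

#' Effective-sample-size shrinkage of the weighted scan
#'
#' `1 - mean N_eff(weighted) / mean N_eff(unweighted)`.
#'
#' @param neff_g,neff_w [effective_sample_size()] results for the
#'   unweighted and weighted scans.
#' @return Shrinkage fraction (1 means all power lost, 0 none).
#' @export
neff_shrinkage <- function(neff_g, neff_w) {
  1 - neff_w$mean_neff / neff_g$mean_neff
}

#' Mean standard-error inflation, in percent
#'
#' Mean over SNPs of `se_w / se_g - 1`, expressed in percent.
#'
#' @param assoc_g,assoc_w Matched unweighted/weighted `assoc_table`s.
#' @return A single percentage value.
#' @export
se_inflation <- function(assoc_g, assoc_w) {
  aw <- align_assoc(assoc_g, assoc_w)
  if (any(assoc_g$se == 0, na.rm = TRUE)) stop("zero unweighted SE")
  100 * mean(aw$se / assoc_g$se - 1, na.rm = TRUE)
}

#' Greedy LD clumping of an association scan
#'
#' PLINK-style clumping: SNPs with `p < p1` are sorted by p-value (ties
#' broken by chromosome, position, then SNP id); repeatedly the best
#' unassigned SNP becomes an index, and every unassigned SNP on the same
#' chromosome within `window_kb` (inclusive) with squared allele-count
#' correlation `>= r2_min` to it joins its clump. The secondary p-value
#' threshold is 1, so any SNP may be absorbed as a member.
#'
#' @param assoc An `assoc_table`.
#' @param g Genotypes for the same SNPs, used for the pairwise-complete
#'   r^2 computation on the analysis sample.
#' @param p1 Index significance threshold (default 5e-8).
#' @param r2_min LD threshold (default 0.1).
#' @param window_kb Physical window half-width in kb, inclusive
#'   (default 250).
#' @return An object of class `clump_set`: a list of clumps (each with
#'   `index`, `index_p`, `members`) plus the parameters.
#' @export
clump <- function(assoc, g, p1 = 5e-8, r2_min = 0.1, window_kb = 250) {
  stopifnot(inherits(g, "geno_matrix"))
  pos <- match(assoc$snp, g$map$snp)
  if (anyNA(pos)) {
    stop("SNP(s) in the association table missing from the genotype map: ",
         paste(utils::head(assoc$snp[is.na(pos)], 5), collapse = ", "))
  }
  cand <- which(!is.na(assoc$p) & assoc$p < p1)
  ord <- cand[order(assoc$p[cand], assoc$chr[cand], assoc$bp[cand],
                    assoc$snp[cand])]
  assigned <- rep(FALSE, nrow(assoc))
  clumps <- list()
  win_bp <- window_kb * 1000
  for (i in ord) {
    if (assigned[i]) next
    assigned[i] <- TRUE
    near <- which(!assigned & assoc$chr == assoc$chr[i] &
                    abs(assoc$bp - assoc$bp[i]) <= win_bp)
    members <- character(0)
    if (length(near) > 0) {
      xi <- g$calls[, pos[i]]
      r2 <- vapply(near, function(j) {
        r <- suppressWarnings(
          stats::cor(xi, g$calls[, pos[j]],
                     use = "pairwise.complete.obs"))
        if (is.na(r)) 0 else r^2
      }, numeric(1))
      take <- near[r2 >= r2_min]
      assigned[take] <- TRUE
      members <- assoc$snp[take]
    }
    clumps[[length(clumps) + 1]] <- list(index = assoc$snp[i],
                                         index_p = assoc$p[i],
                                         members = members)
  }
  structure(list(clumps = clumps,
                 params = list(p1 = p1, r2_min = r2_min,
                               window_kb = window_kb)),
            class = "clump_set")
}

#' @export
print.clump_set <- function(x, ...) {
  cat(sprintf("<clump_set> %d clumps (p1 = %.3g, r2 >= %.2f, %g kb)\n",
              length(x$clumps), x$params$p1, x$params$r2_min,
              x$params$window_kb))
  invisible(x)
}

#' Index SNP ids of a clump set
#' @param cs A [clump()] result.
#' @return Character vector of index SNP ids, best p first.
#' @export
clump_index_snps <- function(cs) {
  vapply(cs$clumps, `[[`, character(1), "index")
}

#' Slope of weighted on unweighted effect sizes over top hits
#'
#' Bivariate OLS of the weighted SNP effects on the unweighted effects
#' (with intercept) over a supplied set of top-hit SNPs; a slope above one
#' means weighting moves effect sizes away from the null on average
#' (attenuation in the unweighted scan). The p-value tests the null that
#' the slope equals one, by a two-sided t test.
#'
#' @param assoc_g,assoc_w Matched `assoc_table`s.
#' @param tophit_ids SNP ids (>= 3) present in both tables.
#' @return An object of class `slope_result`: `slope`, `ci` (95%), `p`,
#'   `se`, `n_snps`.
#' @export
tophit_slope <- function(assoc_g, assoc_w, tophit_ids) {
  if (length(tophit_ids) < 3) stop("need at least 3 top hits")
  ig <- match(tophit_ids, assoc_g$snp)
  iw <- match(tophit_ids, assoc_w$snp)
  if (anyNA(ig) || anyNA(iw)) stop("top-hit ids missing from a table")
  bg <- assoc_g$beta[ig]
  bw <- assoc_w$beta[iw]
  ok <- is.finite(bg) & is.finite(bw)
  if (sum(ok) < 3) stop("fewer than 3 top hits with finite estimates")
  fit <- stats::lm(bw[ok] ~ bg[ok])
  # suppressed: identical scans give an "essentially perfect fit" warning
  sm <- suppressWarnings(summary(fit))$coefficients
  slope <- sm[2, 1]; se <- sm[2, 2]
  df <- fit$df.residual
  tstat <- (slope - 1) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  ci <- slope + c(-1, 1) * stats::qt(0.975, df) * se
  structure(list(slope = slope, se = se, ci = ci, p = p,
                 n_snps = sum(ok)),
            class = "slope_result")
}

#' @export
print.slope_result <- function(x, ...) {
  cat(sprintf(
    "<slope_result> slope = %.3f [%.3f; %.3f], p(slope = 1) = %.3g, n = %d\n",
    x$slope, x$ci[1], x$ci[2], x$p, x$n_snps))
  invisible(x)
}

#' Screen for loci discovered only by the weighted scan
#'
#' Returns the weighted-scan clump indices that are insignificant in the
#' unweighted scan (`p_g >= p_sig`), genome-wide significant in the
#' weighted scan (`p_w < p_sig`), and whose weighted/unweighted difference
#' is itself genome-wide significant by the Hausman test
#' (`p_h < p_sig`) — the stringent definition of a locus previously
#' attenuated below detection by volunteer bias.
#'
#' @param assoc_g,assoc_w Matched `assoc_table`s.
#' @param ht A [hausman_test()] result for the same SNPs.
#' @param clumps_w A [clump()] result on the weighted scan.
#' @param p_sig Significance threshold (default 5e-8).
#' @return Data frame of qualifying loci (possibly 0 rows) with the three
#'   p-values per index SNP.
#' @export
novel_locus_screen <- function(assoc_g, assoc_w, ht, clumps_w,
                               p_sig = 5e-8) {
  idx <- clump_index_snps(clumps_w)
  ig <- match(idx, assoc_g$snp)
  iw <- match(idx, assoc_w$snp)
  ih <- match(idx, ht$snp)
  if (anyNA(ig) || anyNA(iw) || anyNA(ih)) {
    stop("clump index SNPs missing from an input table")
  }
  out <- data.frame(snp = idx, p_g = assoc_g$p[ig], p_w = assoc_w$p[iw],
                    p_h = ht$p_h[ih], stringsAsFactors = FALSE)
  keep <- !is.na(out$p_g) & !is.na(out$p_w) & !is.na(out$p_h) &
    out$p_g >= p_sig & out$p_w < p_sig & out$p_h < p_sig
  out[keep, , drop = FALSE]
}
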