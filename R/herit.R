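#' LD scores from a genotype panel
#'
#' For each SNP j, `l_j` is the sum of squared allele-count correlations
#' with every SNP within `window_kb` on the same chromosome, including
#' itself. With `adjusted = TRUE` each squared sample correlation is
#' bias-corrected as `r2 - (1 - r2) / (n - 2)` and floored at 0 per pair
#' before summation, removing the `(K - 1)/(n - 1)` inflation that
#' finite-sample noise adds over K in-window SNPs. Missing calls are
#' mean-imputed for the correlation computation.
#'
#' @param g A post-QC [geno_matrix()].
#' @param window_kb Window half-width in kb, inclusive (default 1000).
#' @param adjusted Apply the finite-sample bias correction (default
#'   `TRUE`; requires `n >= 3`).
#' @param chunk_size SNP columns per vectorised block.
#' @return An object of class `ld_score_track`: data frame `$scores`
#'   (`snp`, `chr`, `bp`, `l2`), plus `window_kb`, `adjusted`, `M` (number
#'   of SNPs) and `n`.
#' @export
ld_scores <- function(g, window_kb = 1000, adjusted = TRUE,
                      chunk_size = 500L) {
  stopifnot(inherits(g, "geno_matrix"))
  n <- nrow(g$calls)
  if (adjusted && n < 3) stop("adjusted LD scores require n >= 3")
  m <- ncol(g$calls)
  x <- g$calls
  storage.mode(x) <- "double"
  if (anyNA(x)) {
    mu <- colMeans(x, na.rm = TRUE)
    for (j in which(colSums(is.na(x)) > 0)) {
      x[is.na(x[, j]), j] <- mu[j]
    }
  }
  xs <- scale(x)
  sd0 <- attr(xs, "scaled:scale") == 0 | is.na(attr(xs, "scaled:scale"))
  win_bp <- window_kb * 1000
  l2 <- rep(NA_real_, m)
  for (cc in unique(g$map$chr)) {
    jj_all <- which(g$map$chr == cc & !sd0)
    if (length(jj_all) == 0) next
    bp <- g$map$bp
    for (start in seq(1, length(jj_all), by = chunk_size)) {
      jj <- jj_all[start:min(start + chunk_size - 1, length(jj_all))]
      lo <- min(bp[jj]) - win_bp
      hi <- max(bp[jj]) + win_bp
      kk <- jj_all[bp[jj_all] >= lo & bp[jj_all] <= hi]
      r <- crossprod(xs[, jj, drop = FALSE], xs[, kk, drop = FALSE]) /
        (n - 1)
      r2 <- r^2
      if (adjusted) r2 <- pmax(r2 - (1 - r2) / (n - 2), 0)
      inwin <- abs(outer(bp[jj], bp[kk], `-`)) <= win_bp
      l2[jj] <- rowSums(r2 * inwin)
    }
  }
  structure(list(scores = data.frame(snp = g$map$snp, chr = g$map$chr,
                                     bp = g$map$bp, l2 = l2,
                                     stringsAsFactors = FALSE),
                 window_kb = window_kb, adjusted = adjusted, M = m, n = n),
            class = "ld_score_track")
}

#' @export
print.ld_score_track <- function(x, ...) {
  cat(sprintf(
    "<ld_score_track> M = %d SNPs, window = %g kb, %s, mean l2 = %.2f\n",
    x$M, x$window_kb, if (x$adjusted) "adjusted" else "unadjusted",
    mean(x$scores$l2, na.rm = TRUE)))
  invisible(x)
}

# closed-form WLS of y on [1, x] from (optionally masked) weighted sums
wls_sums <- function(y, x, w) {
  cbind(sw = w, swx = w * x, swx2 = w * x^2, swy = w * y,
        swxy = w * x * y)
}

wls_solve <- function(s) {
  # s: totals vector of the five weighted sums
  det <- s["sw"] * s["swx2"] - s["swx"]^2
  slope <- (s["sw"] * s["swxy"] - s["swx"] * s["swy"]) / det
  intercept <- (s["swy"] - slope * s["swx"]) / s["sw"]
  c(slope = unname(slope), intercept = unname(intercept))
}

# two-stage LDSC weighting: 1/max(l,1), then divided by 2*fitted^2
ldsc_weights <- function(y, x, ld) {
  w1 <- 1 / pmax(ld, 1)
  s <- colSums(wls_sums(y, x, w1))
  names(s) <- c("sw", "swx", "swx2", "swy", "swxy")
  co <- wls_solve(s)
  fitted <- co["intercept"] + co["slope"] * x
  w1 / (2 * pmax(abs(fitted), 0.1)^2)
}

# delete-one-block jackknife of a WLS slope/intercept with fixed weights
ldsc_jack <- function(y, x, w, block) {
  contrib <- wls_sums(y, x, w)
  colnames(contrib) <- c("sw", "swx", "swx2", "swy", "swxy")
  tot <- colSums(contrib)
  blk <- rowsum(contrib, block)
  est <- wls_solve(tot)
  nb <- nrow(blk)
  jack <- matrix(NA_real_, nb, 2, dimnames = list(NULL,
                                                  c("slope", "intercept")))
  for (b in seq_len(nb)) {
    jack[b, ] <- wls_solve(tot - blk[b, ])
  }
  se <- sqrt((nb - 1) / nb * colSums(sweep(jack, 2, colMeans(jack))^2))
  list(est = est, jack = jack, se = se, n_blocks = nb)
}

contiguous_blocks <- function(m, n_blocks) {
  if (m < n_blocks) stop("fewer SNPs than jackknife blocks")
  as.integer(cut(seq_len(m), breaks = n_blocks, labels = FALSE))
}

align_ld <- function(assoc, ld) {
  ord <- match(ld$scores$snp, assoc$snp)
  if (anyNA(ord)) stop("association table does not cover the LD-score SNPs")
  ord
}

neff_vector <- function(neff, snps) {
  if (inherits(neff, "neff_summary")) {
    v <- neff$per_snp$n_eff[match(snps, neff$per_snp$snp)]
    if (anyNA(v)) stop("effective sample sizes missing for some SNPs")
    v
  } else if (length(neff) == 1) {
    rep(as.numeric(neff), length(snps))
  } else {
    if (length(neff) != length(snps)) stop("N_eff length mismatch")
    as.numeric(neff)
  }
}

#' SNP heritability by LD-score regression
#'
#' Regresses per-SNP chi-square statistics `z^2` on `N_eff * l / M` by
#' weighted least squares with a free intercept; the slope is the
#' observed-scale SNP heritability and an intercept above one signals
#' confounding such as population stratification. Weights start at
#' `1 / max(l, 1)` and are updated once with the heteroskedasticity factor
#' `1 / (2 * fitted^2)`. Standard errors come from a delete-one jackknife
#' over contiguous SNP blocks in map order.
#'
#' @param assoc An `assoc_table` (or any data frame with `snp` and `z`).
#' @param neff Per-SNP effective sample sizes: an
#'   [effective_sample_size()] result, a vector aligned with the LD-score
#'   SNPs, or a single number.
#' @param ld An [ld_scores()] track.
#' @param n_blocks Jackknife blocks (default 200; lower it for small SNP
#'   counts).
#' @return An object of class `h2_estimate`: `h2`, `se_h2`, `intercept`,
#'   `se_intercept`, `ci` (95% for h2), `n_blocks`, `mean_chi2`, `M`.
#' @export
ldsc_h2 <- function(assoc, neff, ld, n_blocks = 200) {
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  ord <- align_ld(assoc, ld)
  z <- assoc$z[ord]
  ok <- is.finite(z) & is.finite(ld$scores$l2)
  chi2 <- z[ok]^2
  l2 <- ld$scores$l2[ok]
  nv <- neff_vector(neff, ld$scores$snp)[ok]
  x <- nv * l2 / ld$M
  w <- ldsc_weights(chi2, x, l2)
  block <- contiguous_blocks(length(chi2), n_blocks)
  jk <- ldsc_jack(chi2, x, w, block)
  structure(list(h2 = unname(jk$est["slope"]),
                 se_h2 = unname(jk$se["slope"]),
                 intercept = unname(jk$est["intercept"]),
                 se_intercept = unname(jk$se["intercept"]),
                 ci = unname(jk$est["slope"] +
                               c(-1, 1) * 1.96 * jk$se["slope"]),
                 n_blocks = jk$n_blocks, mean_chi2 = mean(chi2),
                 M = ld$M, n_snps = length(chi2)),
            class = "h2_estimate")
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf(
    "<h2_estimate> h2 = %.4f (SE %.4f), intercept = %.3f (SE %.3f), M = %d\n",
    x$h2, x$se_h2, x$intercept, x$se_intercept, x$M))
  invisible(x)
}

#' Cross-scan LD-score regression and genetic correlation
#'
#' Regresses the per-SNP product `z_1 z_2` on `sqrt(N_1 N_2) * l / M`; the
#' slope estimates the genetic covariance between the two scans and the
#' intercept (`cross_intercept`) captures correlated estimation error from
#' sample overlap — the quantity used as `cor(h2_1, h2_2)` in the
#' heritability-difference test. The genetic correlation is
#' `slope / sqrt(h2_1 h2_2)` with the single-scan heritabilities estimated
#' by [ldsc_h2()] on the same track; its SE comes from jackknifing all
#' three regressions over shared blocks.
#'
#' @param assoc_1,assoc_2 `assoc_table`s over aligned SNPs and alleles.
#' @param neff_1,neff_2 Effective sample sizes for each scan (see
#'   [ldsc_h2()]).
#' @param ld An [ld_scores()] track.
#' @param n_blocks Jackknife blocks.
#' @return An object of class `rg_estimate`: `r_g`, `se_rg`, `gencov`,
#'   `cross_intercept`, `se_cross_intercept`, `h2_1`, `h2_2`, and
#'   `defined` (`FALSE` when either heritability is non-positive, in which
#'   case `r_g` is `NA`).
#' @export
ldsc_cross <- function(assoc_1, assoc_2, neff_1, neff_2, ld,
                       n_blocks = 200) {
  a2 <- align_assoc(assoc_1, assoc_2)
  ord <- align_ld(assoc_1, ld)
  z1 <- assoc_1$z[ord]
  z2 <- a2$z[ord]
  ok <- is.finite(z1) & is.finite(z2) & is.finite(ld$scores$l2)
  l2 <- ld$scores$l2[ok]
  n1 <- neff_vector(neff_1, ld$scores$snp)[ok]
  n2 <- neff_vector(neff_2, ld$scores$snp)[ok]
  z1 <- z1[ok]; z2 <- z2[ok]
  M <- ld$M
  x1 <- n1 * l2 / M
  x2 <- n2 * l2 / M
  xc <- sqrt(n1 * n2) * l2 / M
  y1 <- z1^2; y2 <- z2^2; yc <- z1 * z2
  w1 <- ldsc_weights(y1, x1, l2)
  w2 <- ldsc_weights(y2, x2, l2)
  wc <- ldsc_weights(yc, xc, l2)
  block <- contiguous_blocks(length(yc), n_blocks)
  j1 <- ldsc_jack(y1, x1, w1, block)
  j2 <- ldsc_jack(y2, x2, w2, block)
  jc <- ldsc_jack(yc, xc, wc, block)
  h2_1 <- unname(j1$est["slope"]); h2_2 <- unname(j2$est["slope"])
  gencov <- unname(jc$est["slope"])
  defined <- h2_1 > 0 && h2_2 > 0
  r_g <- if (defined) gencov / sqrt(h2_1 * h2_2) else NA_real_
  se_rg <- NA_real_
  if (defined) {
    valid <- j1$jack[, "slope"] > 0 & j2$jack[, "slope"] > 0
    rg_b <- jc$jack[valid, "slope"] /
      sqrt(j1$jack[valid, "slope"] * j2$jack[valid, "slope"])
    nb <- sum(valid)
    if (nb >= 2) {
      se_rg <- sqrt((nb - 1) / nb * sum((rg_b - mean(rg_b))^2))
    }
  }
  structure(list(r_g = r_g, se_rg = se_rg, gencov = gencov,
                 cross_intercept = unname(jc$est["intercept"]),
                 se_cross_intercept = unname(jc$se["intercept"]),
                 h2_1 = h2_1, h2_2 = h2_2, defined = defined,
                 n_blocks = jc$n_blocks),
            class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf(
    "<rg_estimate> r_g = %.4f (SE %.4f), cross intercept = %.3f\n",
    x$r_g, x$se_rg, x$cross_intercept))
  invisible(x)
}

#' Z-test for a heritability difference between two scans
#'
#' `Z = (h2_g - h2_w) / sqrt(se_g^2 + se_w^2 - 2 cov)`, with
#' `cov = cor(h2_g, h2_w) * se_g * se_w` and the correlation estimated by
#' the cross-scan LD-score-regression intercept (clamped to `[-1, 1]`).
#' The denominator uses variances (squared standard errors), the only
#' dimensionally consistent form.
#'
#' @param e_g,e_w [ldsc_h2()] estimates for the unweighted and weighted
#'   scans.
#' @param cross_intercept Intercept of [ldsc_cross()] between the scans
#'   (default 0, the conservative independent-estimates bound).
#' @return An object of class `h2_diff_result`: `z`, `p` (two-sided
#'   normal) and `cov_h2`.
#' @export
h2_difference_test <- function(e_g, e_w, cross_intercept = 0) {
  if (e_g$se_h2 <= 0 || e_w$se_h2 <= 0) stop("standard errors must be > 0")
  ci <- min(max(cross_intercept, -1), 1)
  cov_h2 <- ci * e_g$se_h2 * e_w$se_h2
  v <- e_g$se_h2^2 + e_w$se_h2^2 - 2 * cov_h2
  num <- e_g$h2 - e_w$h2
  if (v <= 0) {
    if (abs(num) < 1e-12) {
      # identical estimates with perfectly correlated errors: no evidence
      # of a difference
      return(structure(list(z = 0, p = 1, cov_h2 = cov_h2),
                       class = "h2_diff_result"))
    }
    stop("non-positive variance of the heritability difference")
  }
  z <- num / sqrt(v)
  structure(list(z = z, p = 2 * stats::pnorm(-abs(z)), cov_h2 = cov_h2),
            class = "h2_diff_result")
}

#' @export
print.h2_diff_result <- function(x, ...) {
  cat(sprintf("<h2_diff_result> Z = %.3f, p = %.3g\n", x$z, x$p))
  invisible(x)
}
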