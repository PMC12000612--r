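#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the total probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed configuration
#' (Wigginton-style enumeration). Preferred over the chi-square
#' approximation, which misbehaves at low minor-allele frequency.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Two-sided exact p-value in `[0, 1]`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("total genotype count must be positive")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa     # rare allele count
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalised probabilities via the standard ratio recursion
  logp <- numeric(length(hets))
  mid_i <- which.min(abs(hets - n_rare / 2))
  logp[mid_i] <- 0
  if (mid_i < length(hets)) {
    for (i in mid_i:(length(hets) - 1)) {
      h <- hets[i]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      # P(h+2)/P(h) = 4 * hom_r * hom_c / ((h+2)(h+1))
      logp[i + 1] <- logp[i] + log(4 * hom_r * hom_c) -
        log((h + 2) * (h + 1))
    }
  }
  if (mid_i > 1) {
    for (i in mid_i:2) {
      h <- hets[i]
      hom_r <- (n_rare - h) / 2
      hom_c <- n - h - hom_r
      # P(h-2)/P(h) = h(h-1) / (4 (hom_r+1)(hom_c+1))
      logp[i - 1] <- logp[i] + log(h * (h - 1)) -
        log(4 * (hom_r + 1) * (hom_c + 1))
    }
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- match(n_Aa, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-7)]))
}

#' Genotype and sample quality control
#'
#' Applies the standard GWAS filters in sample-first order: individuals are
#' dropped for call-rate missingness above `ind_miss_max` or for
#' heterozygosity outside `mean +/- het_sd` SD (heterozygosity is computed
#' on the SNPs passing a provisional MAF screen); then SNPs are dropped for
#' MAF below `maf_min`, exact Hardy-Weinberg p-value at or below
#' `hwe_p_min`, or missingness above `snp_miss_max`, all recomputed on the
#' retained individuals.
#'
#' @param g A [geno_matrix()].
#' @param maf_min,hwe_p_min,snp_miss_max,ind_miss_max,het_sd Thresholds;
#'   defaults follow common GWAS practice (MAF 0.01, HWE 1e-6, 2%
#'   missingness, 3 SD heterozygosity).
#' @return List with the filtered `geno_matrix` (`$geno`) and a `$report`
#'   of per-filter drop counts in application order.
#' @export
apply_qc <- function(g, maf_min = 0.01, hwe_p_min = 1e-6,
                     snp_miss_max = 0.02, ind_miss_max = 0.02, het_sd = 3) {
  stopifnot(inherits(g, "geno_matrix"))
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")

  ind_miss <- rowMeans(is.na(g$calls))
  drop_miss <- ind_miss > ind_miss_max

  maf0 <- geno_maf(g)
  het_snps <- which(maf0 >= maf_min)
  het <- geno_heterozygosity(g, het_snps)
  mu <- mean(het); s <- stats::sd(het)
  drop_het <- if (is.na(s) || s == 0) rep(FALSE, length(het))
              else abs(het - mu) > het_sd * s
  keep_ind <- !(drop_miss | drop_het)
  if (!any(keep_ind)) stop("QC removed every individual")
  g1 <- geno_subset(g, i = which(keep_ind))

  maf <- geno_maf(g1)
  snp_miss <- colMeans(is.na(g1$calls))
  hwe_p <- vapply(seq_len(ncol(g1$calls)), function(j) {
    x <- g1$calls[, j]
    hwe_test(sum(x == 2L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
             sum(x == 0L, na.rm = TRUE))
  }, numeric(1))
  fail_maf <- maf < maf_min
  fail_hwe <- hwe_p <= hwe_p_min
  fail_smiss <- snp_miss > snp_miss_max
  keep_snp <- !(fail_maf | fail_hwe | fail_smiss)
  if (!any(keep_snp)) stop("QC removed every SNP")
  g2 <- geno_subset(g1, j = which(keep_snp))

  list(geno = g2,
       report = list(
         n_ind_in = nrow(g$calls), n_snp_in = ncol(g$calls),
         ind_dropped_missing = sum(drop_miss),
         ind_dropped_heterozygosity = sum(drop_het & !drop_miss),
         snp_dropped_maf = sum(fail_maf),
         snp_dropped_hwe = sum(fail_hwe & !fail_maf),
         snp_dropped_missing = sum(fail_smiss & !fail_maf & !fail_hwe),
         n_ind_out = nrow(g2$calls), n_snp_out = ncol(g2$calls)))
}

#' Residualise the phenotype on confounders
#'
#' Auxiliary (weighted) least-squares regression of the phenotype on the
#' covariate table plus intercept; the per-SNP scans are then run on the
#' residual. When weights are supplied the same weights are used here, so
#' the residual is orthogonal to the covariates under the weighted inner
#' product. The (weighted) variance of the residual is recorded as
#' `sigma2_y` for the effective-sample-size computation.
#'
#' @param y Phenotype vector.
#' @param cov Data frame of covariates (factors and/or numerics), or `NULL`
#'   for intercept-only centring.
#' @param w Optional [compute_ip_weights()] result or positive weight
#'   vector aligned with `y`.
#' @param ids Optional identifiers aligned with `y`.
#' @return An object of class `residual_phenotype` with fields `y_tilde`,
#'   `weighted`, `w`, `sigma2_y` and `ids`.
#' @export
residualize <- function(y, cov = NULL, w = NULL, ids = NULL) {
  n <- length(y)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  weighted <- !is.null(w)
  if (inherits(w, "ip_weight_set")) {
    if (!identical(w$ids, as.character(ids))) {
      ord <- match(as.character(ids), w$ids)
      if (anyNA(ord)) stop("weight ids do not cover the phenotype ids")
      w <- w$w[ord]
    } else {
      w <- w$w
    }
  }
  if (is.null(w)) w <- rep(1, n)
  if (any(w <= 0)) stop("weights must be positive")
  if (length(w) != n) stop("weights/phenotype length mismatch")

  if (is.null(cov) || ncol(as.data.frame(cov)) == 0) {
    x <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    cov <- as.data.frame(cov)
    cov <- cov[, setdiff(names(cov), "id"), drop = FALSE]
    for (col in names(cov)) {
      if (is.character(cov[[col]])) cov[[col]] <- factor(cov[[col]])
    }
    x <- stats::model.matrix(~ ., data = cov)
  }
  fit <- stats::lm.wfit(x, y, w)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    warning("dropping ", sum(is.na(beta)),
            " collinear covariate column(s) from the auxiliary regression")
    beta[is.na(beta)] <- 0
  }
  y_tilde <- y - as.numeric(x %*% beta)
  mu <- sum(w * y_tilde) / sum(w)
  sigma2_y <- sum(w * (y_tilde - mu)^2) / sum(w)
  structure(list(y_tilde = y_tilde, weighted = weighted, w = w,
                 sigma2_y = sigma2_y, ids = as.character(ids)),
            class = "residual_phenotype")
}

#' Per-SNP association scan
#'
#' Fits `y_tilde = alpha + beta * SNP` for every SNP by ordinary (no
#' weights) or weighted least squares, with heteroskedasticity-robust
#' (White, HC0) standard errors: bread `(X'WX)^-1`, meat
#' `X'W diag(e^2) W X`. Unweighted scans are the unit-weight special case
#' of the same arithmetic, so a weighted scan with constant weights is
#' bit-identical to the unweighted scan. P-values are two-sided normal
#' (Z) tails. Missing genotypes are dropped pairwise per SNP; monomorphic
#' SNPs in the analysis sample are reported as `NA` with a reason code.
#'
#' @param yt A [residualize()] result.
#' @param g A post-QC [geno_matrix()] whose ids cover `yt$ids`.
#' @param w Optional weights; defaults to the weights stored in `yt` (unit
#'   weights for an unweighted residual).
#' @param hc1 Apply the `n/(n-2)` small-sample factor to the robust
#'   variance (off by default; HC0 is the White estimator).
#' @param chunk_size SNP columns processed per vectorised block.
#' @return An `assoc_table` data frame with columns `snp`, `chr`, `bp`,
#'   `a1`, `a2`, `beta`, `se`, `z`, `p`, `n_used`, `maf`, `alpha`,
#'   `reason`, and attributes `weighted` and `sigma2_y`.
#' @export
assoc_scan <- function(yt, g, w = NULL, hc1 = FALSE, chunk_size = 500L) {
  stopifnot(inherits(yt, "residual_phenotype"), inherits(g, "geno_matrix"))
  ord <- match(yt$ids, g$ids)
  if (anyNA(ord)) stop("genotype ids do not cover the phenotype ids")
  calls <- g$calls[ord, , drop = FALSE]
  y <- yt$y_tilde
  w_given <- !is.null(w)
  w <- if (is.null(w)) yt$w else if (inherits(w, "ip_weight_set")) {
    ww <- w$w[match(yt$ids, w$ids)]
    if (anyNA(ww)) stop("weight ids do not cover the phenotype ids")
    ww
  } else w
  n <- length(y)
  m <- ncol(calls)

  sw <- sum(w)
  ybar <- sum(w * y) / sw
  yc <- y - ybar
  wyc <- w * yc

  beta <- se <- alpha <- maf <- rep(NA_real_, m)
  n_used <- rep(n, m)
  reason <- rep(NA_character_, m)

  one_snp <- function(x) {
    ok <- !is.na(x)
    xs <- x[ok]; ys <- y[ok]; ws <- w[ok]
    swl <- sum(ws)
    xb <- sum(ws * xs) / swl
    yb <- sum(ws * ys) / swl
    xcl <- xs - xb; ycl <- ys - yb
    sxx <- sum(ws * xcl^2)
    if (sxx <= 0) return(c(NA, NA, NA, NA, sum(ok), 1))
    b <- sum(ws * xcl * ycl) / sxx
    e <- ycl - b * xcl
    meat <- sum((ws * xcl * e)^2)
    list(b = b, se = sqrt(meat) / sxx, a = yb - b * xb,
         maf = min(mean(xs) / 2, 1 - mean(xs) / 2), n = sum(ok),
         mono = FALSE)
  }

  has_na_col <- colSums(is.na(calls)) > 0L
  idx_clean <- which(!has_na_col)
  for (start in seq(1, length(idx_clean), by = chunk_size)) {
    jj <- idx_clean[start:min(start + chunk_size - 1, length(idx_clean))]
    X <- calls[, jj, drop = FALSE]
    storage.mode(X) <- "double"
    s1 <- colSums(w * X)
    c0 <- s1 / sw
    sxx <- colSums(w * X^2) - s1^2 / sw
    sxy <- colSums(X * wyc)
    b <- sxy / sxx
    Xc <- sweep(X, 2, c0)
    E <- yc - sweep(Xc, 2, b, `*`)
    meat <- colSums((w * Xc * E)^2)
    sej <- sqrt(meat) / sxx
    mono <- !(sxx > 0)
    b[mono] <- NA_real_; sej[mono] <- NA_real_
    beta[jj] <- b
    se[jj] <- sej
    alpha[jj] <- ifelse(mono, NA_real_, ybar - b * c0)
    f <- colMeans(X) / 2
    maf[jj] <- pmin(f, 1 - f)
    reason[jj][mono] <- "monomorphic"
  }
  for (j in which(has_na_col)) {
    r <- one_snp(calls[, j])
    if (is.list(r)) {
      beta[j] <- r$b; se[j] <- r$se; alpha[j] <- r$a
      maf[j] <- r$maf; n_used[j] <- r$n
    } else {
      n_used[j] <- r[5]
      maf[j] <- {
        x <- calls[, j]; f <- mean(x, na.rm = TRUE) / 2; min(f, 1 - f)
      }
      reason[j] <- "monomorphic"
    }
  }
  if (hc1) se <- se * sqrt(n_used / pmax(n_used - 2, 1))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))

  out <- data.frame(snp = g$map$snp, chr = g$map$chr, bp = g$map$bp,
                    a1 = g$map$a1, a2 = g$map$a2,
                    beta = beta, se = se, z = z, p = p, n_used = n_used,
                    maf = maf, alpha = alpha, reason = reason,
                    stringsAsFactors = FALSE)
  attr(out, "weighted") <- yt$weighted || w_given
  attr(out, "sigma2_y") <- yt$sigma2_y
  class(out) <- c("assoc_table", "data.frame")
  out
}
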