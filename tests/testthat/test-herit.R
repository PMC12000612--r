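mk_sumstats <- function(z, n) {
  out <- data.frame(snp = sprintf("rs%06d", seq_along(z)), chr = 1,
                    bp = seq_along(z) * 5000, a1 = "A", a2 = "G",
                    beta = z / sqrt(n), se = 1 / sqrt(n), z = z,
                    p = 2 * pnorm(-abs(z)), n_used = n, maf = 0.3,
                    alpha = 0, reason = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  out
}

# ld-score track with chosen scores, for model-generated sumstats
mk_ld <- function(l2, n = 10000, window_kb = 1000) {
  structure(list(scores = data.frame(snp = sprintf("rs%06d",
                                                   seq_along(l2)),
                                     chr = 1, bp = seq_along(l2) * 5000,
                                     l2 = l2, stringsAsFactors = FALSE),
                 window_kb = window_kb, adjusted = TRUE,
                 M = length(l2), n = n),
            class = "ld_score_track")
}

test_that("LD scores behave at the independence and perfect-LD extremes", {
  # duplicated column: both SNPs see each other with r^2 = 1
  g0 <- simulate_genotypes(500, 2, maf_low = 0.3, seed = 231)
  calls <- cbind(g0$calls[, 1], g0$calls[, 1])
  g <- geno_matrix(calls, data.frame(snp = c("sA", "sB"), chr = 1,
                                     bp = c(1000, 2000), a1 = "A",
                                     a2 = "G"), g0$ids)
  ld <- ld_scores(g, adjusted = FALSE)
  expect_equal(ld$scores$l2, c(2, 2), tolerance = 1e-10)

  # independent SNPs, unadjusted: E[l] = 1 + (K - 1)/(n - 1)
  n <- 2000; m <- 40
  gi <- simulate_genotypes(n, m, maf_low = 0.2, seed = 232)
  ldu <- ld_scores(gi, adjusted = FALSE)
  expect_equal(mean(ldu$scores$l2), 1 + (m - 1) / (n - 1),
               tolerance = 0.01)

  # the adjustment removes that inflation
  gj <- simulate_genotypes(10000, 40, maf_low = 0.2, seed = 233)
  lda <- ld_scores(gj, adjusted = TRUE)
  expect_gt(mean(lda$scores$l2), 0.98)
  expect_lt(mean(lda$scores$l2), 1.05)

  # scores only accumulate inside the physical window
  gw <- simulate_genotypes(300, 4, maf_low = 0.3, seed = 234,
                           bp_spacing = 2e6)
  ldw <- ld_scores(gw, window_kb = 1000, adjusted = FALSE)
  expect_equal(ldw$scores$l2, rep(1, 4), tolerance = 1e-10)
})

test_that("LDSC regression recovers null and model-generated heritabilities", {
  set.seed(241)
  l2 <- runif(3000, 1, 15)
  # null chi-square: slope 0, intercept 1
  a0 <- mk_sumstats(z = rep(1, 3000), n = 5000)
  a0$z <- sample(c(-1, 1), 3000, TRUE)    # chi2 exactly 1 throughout
  h0 <- ldsc_h2(a0, 5000, mk_ld(l2), n_blocks = 50)
  expect_equal(h0$h2, 0, tolerance = 1e-10)
  expect_equal(h0$intercept, 1, tolerance = 1e-10)

  # generative model matches the regression model exactly
  h2_true <- 0.4; N <- 10000; M <- 3000
  sd_j <- sqrt(1 + N * h2_true * l2 / M)
  z <- rnorm(3000, 0, sd_j)
  hh <- ldsc_h2(mk_sumstats(z, N), N, mk_ld(l2), n_blocks = 50)
  expect_lt(abs(hh$h2 - h2_true), 4 * hh$se_h2)
  expect_gt(hh$se_h2, 0)
})

test_that("LDSC slope is unbiased over replicates of its own model", {
  set.seed(251)
  l2 <- runif(2000, 1, 12)
  h2_true <- 0.4; N <- 8000; M <- 2000
  est <- replicate(50, {
    z <- rnorm(M, 0, sqrt(1 + N * h2_true * l2 / M))
    ldsc_h2(mk_sumstats(z, N), N, mk_ld(l2), n_blocks = 40)$h2
  })
  expect_lt(abs(mean(est) - h2_true), 0.05 * h2_true)
})

test_that("cross-scan regression is exact for self and null for independence", {
  set.seed(261)
  l2 <- runif(1500, 1, 10)
  N <- 6000
  z <- rnorm(1500, 0, sqrt(1 + N * 0.3 * l2 / 1500))
  a <- mk_sumstats(z, N)
  ld <- mk_ld(l2)
  h <- ldsc_h2(a, N, ld, n_blocks = 30)
  cr <- ldsc_cross(a, a, N, N, ld, n_blocks = 30)
  expect_equal(cr$r_g, 1, tolerance = 1e-10)
  expect_equal(cr$cross_intercept, h$intercept, tolerance = 1e-10)

  # two scans of independent traits on disjoint samples
  z2 <- rnorm(1500, 0, sqrt(1 + N * 0.3 * l2 / 1500))
  cr2 <- ldsc_cross(a, mk_sumstats(z2, N), N, N, ld, n_blocks = 30)
  expect_lt(abs(cr2$r_g), 3 * cr2$se_rg)
})

test_that("scans of the same trait under random selection have r_g near 1", {
  cohort <- fix_cohort(n = 9000, m = 600, h2 = 0.5, seed = 271,
                       scenario = scenario_spec("random",
                                                target_rate = 0.5),
                       block_size = 5, within_block_corr = c(0, 0.9))
  part <- cohort$part
  gp <- geno_subset(cohort$g, i = part)
  covs <- cohort$pop$covariates[part, -1]
  y <- cohort$pop$phenotype[part]
  yt_g <- residualize(y, covs, ids = gp$ids)
  set.seed(272)
  w <- runif(length(part), 0.5, 2)   # arbitrary y-independent weights
  yt_w <- residualize(y, covs, w = w, ids = gp$ids)
  ag <- assoc_scan(yt_g, gp)
  aw <- assoc_scan(yt_w, gp)
  ld <- ld_scores(gp)
  cr <- ldsc_cross(ag, aw, effective_sample_size(ag),
                   effective_sample_size(aw), ld, n_blocks = 40)
  expect_true(cr$defined)
  expect_lt(abs(cr$r_g - 1), 3 * cr$se_rg + 0.02)
})

test_that("heritability-difference Z-test follows its formula and error paths", {
  e1 <- structure(list(h2 = 0.1, se_h2 = 0.01), class = "h2_estimate")
  d0 <- h2_difference_test(e1, e1, cross_intercept = 0.5)
  expect_equal(d0$z, 0)
  expect_equal(d0$p, 1)

  # published T1D row, zero-covariance bound: |Z| ~ 10.03
  eg <- structure(list(h2 = 0.0054, se_h2 = 0.0014), class = "h2_estimate")
  ew <- structure(list(h2 = 0.0432, se_h2 = 0.0035), class = "h2_estimate")
  d <- h2_difference_test(eg, ew, cross_intercept = 0)
  expect_equal(abs(d$z), 10.03, tolerance = 1e-3)
  expect_equal(d$p, 1.15e-23, tolerance = 1e-2)
  expect_equal(d$cov_h2, 0)

  # degenerate perfect correlation with equal SEs: zero variance
  ea <- structure(list(h2 = 0.1, se_h2 = 0.01), class = "h2_estimate")
  eb <- structure(list(h2 = 0.2, se_h2 = 0.01), class = "h2_estimate")
  expect_error(h2_difference_test(ea, eb, cross_intercept = 1),
               "non-positive")
  # but identical estimates under the same degeneracy are simply "no
  # evidence of difference"
  dd <- h2_difference_test(ea, ea, cross_intercept = 1)
  expect_equal(dd$z, 0)
  expect_equal(dd$p, 1)
})
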