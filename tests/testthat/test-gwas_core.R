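test_that("exact HWE test matches known configurations and the enumeration oracle", {
  expect_equal(hwe_test(25, 50, 25), 1)
  expect_lt(hwe_test(50, 0, 50), 1e-6)
  expect_equal(hwe_test(10, 20, 5), hwe_oracle(10, 20, 5),
               tolerance = 1e-12)
  # parameterised sweep against the brute-force oracle
  set.seed(5)
  for (i in 1:25) {
    cnt <- rmultinom(1, sample(20:200, 1), prob = runif(3, 0.05, 1))
    expect_equal(hwe_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]), tolerance = 1e-9)
  }
  expect_error(hwe_test(-1, 2, 3), ">= 0")
})

test_that("QC passes a clean panel untouched and drops targeted violations", {
  g <- fix_panel(n = 1500, m = 40, seed = 121)
  # at the default 3 SD rule a continuous heterozygosity distribution
  # always has a small tail; the SNP filters must still be no-ops and the
  # individual tail tiny
  res <- apply_qc(g)
  expect_equal(res$report$snp_dropped_maf +
                 res$report$snp_dropped_hwe +
                 res$report$snp_dropped_missing, 0)
  expect_equal(res$report$ind_dropped_missing, 0)
  expect_lte(res$report$ind_dropped_heterozygosity, ceiling(0.005 * 1500))
  # with the tail rule relaxed the clean panel passes through exactly
  res45 <- apply_qc(g, het_sd = 4.5)
  expect_equal(dim(res45$geno), dim(g))

  # inject 5% missingness into one SNP of a wide panel (so no individual
  # crosses its own 2% missingness limit): that SNP and only it is dropped
  g2 <- fix_panel(n = 800, m = 200, seed = 123)
  set.seed(122)
  g2$calls[sample(800, 40), 5] <- NA
  res2 <- apply_qc(g2, het_sd = 4.5)
  expect_equal(setdiff(g2$map$snp, res2$geno$map$snp), g2$map$snp[5])
  expect_equal(res2$report$snp_dropped_missing, 1)
  expect_equal(res2$report$ind_dropped_missing, 0)

  # one individual forced to extreme heterozygosity is dropped exactly
  g3 <- g
  g3$calls[7, ] <- 1L
  het <- geno_heterozygosity(g3)
  stopifnot(het[7] > mean(het) + 5 * sd(het))
  res3 <- apply_qc(g3, het_sd = 4.5)
  expect_equal(setdiff(g$ids, res3$geno$ids), g$ids[7])
  expect_equal(res3$report$ind_dropped_heterozygosity, 1)
})

test_that("residualisation centres, respects weights, and zeroes perfect fits", {
  y <- rnorm(50, 3, 2)
  r0 <- residualize(y)
  expect_equal(r0$y_tilde, y - mean(y))
  w <- runif(50, 0.5, 2)
  rw <- residualize(y, w = w)
  expect_equal(rw$y_tilde, y - sum(w * y) / sum(w))
  cov <- data.frame(a = rnorm(50), b = factor(rep(c("u", "v"), 25)))
  y_lin <- 2 + 0.5 * cov$a + 3 * (cov$b == "v")
  rp <- residualize(y_lin, cov)
  expect_lt(max(abs(rp$y_tilde)), 1e-10)
  # weighted residual is orthogonal to the covariates under the weighted
  # inner product
  y2 <- y_lin + rnorm(50)
  rw2 <- residualize(y2, cov, w = w)
  x <- model.matrix(~ ., cov)
  expect_lt(max(abs(crossprod(x, w * rw2$y_tilde))) /
              max(abs(crossprod(x, w * y2))), 1e-8)
})

test_that("per-SNP OLS matches hand arithmetic and the sandwich oracle", {
  g <- geno_matrix(matrix(c(0L, 1L, 1L, 2L), 4, 1),
                   data.frame(snp = "s1", chr = 1, bp = 100,
                              a1 = "A", a2 = "G"),
                   paste0("i", 1:4))
  yt <- structure(list(y_tilde = c(0, 1, 2, 3), weighted = FALSE,
                       w = rep(1, 4), sigma2_y = var(c(0, 1, 2, 3)),
                       ids = paste0("i", 1:4)),
                  class = "residual_phenotype")
  a <- assoc_scan(yt, g)
  expect_equal(a$beta, 1.5)   # cov/var = 3/2

  skip_if_not_installed("sandwich")
  cohort <- fix_cohort(n = 1200, m = 15, seed = 131)
  part <- cohort$part
  gp <- geno_subset(cohort$g, i = part)
  covs <- cohort$pop$covariates[part, -1]
  y <- cohort$pop$phenotype[part]
  yt_g <- residualize(y, covs, ids = gp$ids)
  ag <- assoc_scan(yt_g, gp)
  w <- runif(length(part), 0.3, 3)
  yt_w <- residualize(y, covs, w = w, ids = gp$ids)
  aw <- assoc_scan(yt_w, gp)
  for (j in c(1, 7, 15)) {
    x <- gp$calls[, j]
    fit <- lm(yt_g$y_tilde ~ x)
    expect_equal(ag$beta[j], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(ag$se[j],
                 sqrt(sandwich::vcovHC(fit, type = "HC0")[2, 2]),
                 tolerance = 1e-8)
    fw <- lm(yt_w$y_tilde ~ x, weights = w)
    expect_equal(aw$beta[j], unname(coef(fw)[2]), tolerance = 1e-10)
    expect_equal(aw$se[j],
                 sqrt(sandwich::vcovHC(fw, type = "HC0")[2, 2]),
                 tolerance = 1e-8)
  }
})

test_that("unit weights reproduce the unweighted scan bit for bit", {
  cohort <- fix_cohort(n = 1500, m = 25, seed = 141)
  part <- cohort$part
  gp <- geno_subset(cohort$g, i = part)
  covs <- cohort$pop$covariates[part, -1]
  y <- cohort$pop$phenotype[part]
  yt_g <- residualize(y, covs, ids = gp$ids)
  yt_w <- residualize(y, covs, w = rep(1, length(part)), ids = gp$ids)
  ag <- assoc_scan(yt_g, gp)
  aw <- assoc_scan(yt_w, gp)
  expect_identical(ag$beta, aw$beta)
  expect_identical(ag$se, aw$se)
  expect_identical(ag$p, aw$p)
  # positive rescaling of the weights changes nothing (to rounding)
  yt_c <- residualize(y, covs, w = rep(3.7, length(part)), ids = gp$ids)
  ac <- assoc_scan(yt_c, gp)
  expect_equal(ag$beta, ac$beta, tolerance = 1e-12)
  expect_equal(ag$se, ac$se, tolerance = 1e-12)
})

test_that("integer weights equal physical row duplication for point estimates", {
  set.seed(151)
  n <- 400
  g <- fix_panel(n = n, m = 10, seed = 152)
  y <- rnorm(n) + 0.1 * g$calls[, 3]
  w <- sample(1:2, n, replace = TRUE)
  yt_w <- residualize(y, w = w, ids = g$ids)
  aw <- assoc_scan(yt_w, g)
  dup <- rep(seq_len(n), w)
  gd <- geno_matrix(g$calls[dup, ], g$map, sprintf("d%05d", seq_along(dup)))
  yt_d <- residualize(y[dup], ids = gd$ids)
  ad <- assoc_scan(yt_d, gd)
  expect_equal(aw$beta, ad$beta, tolerance = 1e-10)
})

test_that("monomorphic SNPs are flagged, never silently zero", {
  g <- fix_panel(n = 300, m = 5, seed = 161)
  g$calls[, 2] <- 1L
  yt <- residualize(rnorm(300), ids = g$ids)
  a <- assoc_scan(yt, g)
  expect_true(is.na(a$beta[2]))
  expect_equal(a$reason[2], "monomorphic")
  expect_true(all(!is.na(a$beta[-2])))
  # missing genotypes are dropped pairwise with per-SNP n recorded
  g$calls[1:30, 4] <- NA
  a2 <- assoc_scan(yt, g)
  expect_equal(a2$n_used[4], 270)
  expect_equal(a2$n_used[1], 300)
  x <- g$calls[31:300, 4]
  fit <- lm(yt$y_tilde[31:300] ~ x)
  expect_equal(a2$beta[4], unname(coef(fit)[2]), tolerance = 1e-10)
})

test_that("robust-SE p-values are calibrated under the null", {
  g <- simulate_genotypes(800, 1500, maf_low = 0.1, seed = 171)
  set.seed(172)
  yt <- residualize(rnorm(800), ids = g$ids)
  a <- assoc_scan(yt, g)
  rej <- mean(a$p < 0.05)
  expect_gt(rej, 0.04)
  expect_lt(rej, 0.06)
})
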