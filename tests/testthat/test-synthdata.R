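test_that("genotype simulation respects its defining distribution", {
  g <- simulate_genotypes(4, 2, maf_low = 0.5, maf_high = 0.5, seed = 3)
  expect_equal(dim(g), c(4L, 2L))
  expect_true(all(g$calls %in% 0:2))
  # same inputs and seed give bit-identical output
  g2 <- simulate_genotypes(4, 2, maf_low = 0.5, maf_high = 0.5, seed = 3)
  expect_identical(g$calls, g2$calls)
  expect_identical(g$map, g2$map)
  # large-n marginal check: entries Binomial(2, 0.5)
  gl <- simulate_genotypes(20000, 3, maf_low = 0.5, maf_high = 0.5,
                           seed = 4)
  expect_equal(unname(colMeans(gl$calls)), rep(1, 3), tolerance = 0.03)
  frac_het <- mean(gl$calls == 1)
  expect_equal(frac_het, 0.5, tolerance = 0.02)
  expect_error(simulate_genotypes(10, 5, maf_low = 0, maf_high = 0.5),
               "maf_low")
  expect_error(simulate_genotypes(0, 5), "positive")
})

test_that("empirical MAF stays inside the requested band", {
  g <- simulate_genotypes(5000, 100, maf_low = 0.05, maf_high = 0.4,
                          seed = 9)
  maf <- geno_maf(g)
  expect_true(all(maf >= 0.05 * 0.5))
  expect_true(all(maf <= 0.4 * 1.5))
})

test_that("within-block correlation matches the parameter and blocks are independent", {
  # no LD requested: neighbouring r^2 at the sampling-noise floor
  g0 <- simulate_genotypes(50000, 10, within_block_corr = 0,
                           block_size = 2, seed = 5)
  r2_0 <- sapply(seq(1, 9, by = 2), function(j) {
    cor(g0$calls[, j], g0$calls[, j + 1])^2
  })
  expect_true(all(r2_0 < 0.01))
  # strong LD requested: block partners correlated, r^2 > 0.5
  g1 <- simulate_genotypes(20000, 10, within_block_corr = 0.9,
                           block_size = 2, seed = 6)
  r2_1 <- sapply(seq(1, 9, by = 2), function(j) {
    cor(g1$calls[, j], g1$calls[, j + 1])^2
  })
  expect_true(all(r2_1 > 0.5))
  # genotype correlation tracks the parameter itself (0.9) closely
  expect_equal(mean(sqrt(r2_1)), 0.9, tolerance = 0.05)
  # SNPs of different blocks stay independent
  r_across <- cor(g1$calls[, 2], g1$calls[, 3])^2
  expect_lt(r_across, 0.01)
})

test_that("phenotype construction hits the requested variance decomposition", {
  g <- fix_panel(n = 20000, m = 1000, seed = 31)
  pop <- simulate_phenotype(g, n_causal = 100, h2 = 0.5, seed = 32)
  ratio <- var(pop$components$genetic) / var(pop$phenotype)
  expect_gt(ratio, 0.45)
  expect_lt(ratio, 0.55)
  # genetic component is reproducible from genotypes and true_beta
  xc <- sweep(g$calls[, pop$causal], 2, colMeans(g$calls[, pop$causal]))
  expect_equal(drop(xc %*% pop$true_beta[pop$causal]),
               pop$components$genetic, tolerance = 1e-10)

  # degenerate limits
  p0 <- simulate_phenotype(g, n_causal = 10, h2 = 0, seed = 33)
  expect_true(all(p0$true_beta == 0))
  p1 <- simulate_phenotype(g, n_causal = 50, h2 = 1,
                           covariate_effect_sd = 0, seed = 34)
  expect_equal(p1$phenotype, p1$components$genetic, tolerance = 1e-12)
  expect_error(simulate_phenotype(g, 10, h2 = 1.2), "h2")
})

test_that("random participation is independent of the phenotype and calibrated", {
  g <- simulate_genotypes(100000, 5, seed = 41)
  pop <- simulate_phenotype(g, n_causal = 3, h2 = 0.3, seed = 42)
  sel <- simulate_participation(pop, scenario_spec("random",
                                                   target_rate = 0.055),
                                seed = 43)
  expect_lt(abs(cor(as.numeric(sel$participated), pop$phenotype)), 0.02)
  expect_equal(mean(sel$p_true), 0.055, tolerance = 1e-6)
  expect_lt(abs(mean(sel$participated) - 0.055), 0.1 * 0.055)
  expect_true(all(sel$p_true > 0 & sel$p_true < 1))
  # determinism
  sel2 <- simulate_participation(pop, scenario_spec("random",
                                                    target_rate = 0.055),
                                 seed = 43)
  expect_identical(sel$participated, sel2$participated)
})

test_that("phenotype-related selection lowers participant phenotype means", {
  g <- simulate_genotypes(100000, 5, seed = 44)
  pop <- simulate_phenotype(g, n_causal = 3, h2 = 0.3, seed = 45)
  scn <- scenario_spec("phenotype", coef_y = -0.5, target_rate = 0.1)
  sel <- simulate_participation(pop, scn, seed = 46)
  tt <- t.test(pop$phenotype[sel$participated], pop$phenotype,
               alternative = "less")
  expect_lt(tt$p.value, 0.001)
})

test_that("oracle 1/p weights rebalance participants to population margins", {
  cohort <- fix_cohort(
    n = 20000, m = 20, seed = 51,
    scenario = scenario_spec(
      "phenotype", coef_y = -0.6, target_rate = 0.3,
      coef_cov = list(education = c(-0.4, -0.1, 0.1, 0.4))))
  pop <- cohort$pop; sel <- cohort$sel; part <- cohort$part
  w <- 1 / sel$p_true[part]
  for (col in c("education", "health", "sex")) {
    f <- pop$covariates[[col]]
    for (lev in levels(f)) {
      pop_m <- mean(f == lev)
      wm <- sum(w * (f[part] == lev)) / sum(w)
      # Monte-Carlo SE of the weighted margin via linearisation
      se <- sqrt(sum((w * ((f[part] == lev) - wm))^2)) / sum(w)
      expect_lt(abs(wm - pop_m), 3 * se + 1e-12)
    }
  }
})

test_that("collider selection distorts the naive scan but not the weighted one", {
  g <- simulate_genotypes(60000, 6, maf_low = 0.3, seed = 61)
  pop <- simulate_phenotype(g, n_causal = 2, h2 = 0.3, seed = 62)
  null_snp <- g$map$snp[setdiff(seq_len(6), pop$causal)[1]]
  scn <- scenario_spec("phenotype_genotype", coef_y = -0.7,
                       coef_g = -0.5, snp = null_snp, target_rate = 0.2)
  sel <- simulate_participation(pop, scn, seed = 63)
  part <- which(sel$participated)
  gp <- geno_subset(g, i = part)
  yt_g <- residualize(pop$phenotype[part], ids = gp$ids)
  ipw <- oracle_ip_weights(sel)
  yt_w <- residualize(pop$phenotype[part], w = ipw, ids = gp$ids)
  ag <- assoc_scan(yt_g, gp)
  aw <- assoc_scan(yt_w, gp)
  j <- match(null_snp, ag$snp)
  # naive participant-only association at the null SNP is non-zero
  expect_gt(abs(ag$z[j]), 3)
  # the oracle-weighted association is consistent with zero
  expect_lt(abs(aw$beta[j]), 3 * aw$se[j])
})

test_that("scenario specs validate and round-trip through YAML", {
  expect_error(scenario_spec("random", coef_y = 0.5), "forces")
  expect_error(scenario_spec("phenotype_genotype", coef_g = 1), "snp")
  expect_error(scenario_spec("phenotype", target_rate = 0), "target_rate")
  spec <- scenario_spec("phenotype_genotype", coef_y = -0.4, coef_g = 0.2,
                        snp = "rs000004", target_rate = 0.1,
                        coef_cov = list(health = c(0.1, 0, -0.1)))
  path <- withr::local_tempfile(fileext = ".yaml")
  scenario_to_yaml(spec, path)
  back <- scenario_from_yaml(path)
  expect_equal(unclass(back), unclass(spec))
})
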