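# Derive a function-specific RNG stream from a user seed, so that calls to
# different simulate_* functions with nearby seeds never share a stream.
mix_seed <- function(seed, salt) {
  v <- (as.double(seed) %% 2147483647) * 48271 + salt * 9973
  as.integer(v %% 2147483647)
}

#' Simulate genotypes with block LD structure
#'
#' Generates an individuals-by-SNPs allele-count panel in which SNPs belong
#' to contiguous blocks. Within a block, haplotypes are built by the
#' shared-ancestral-haplotype construction: each SNP copies a block-level
#' ancestral allele with probability `sqrt(within_block_corr)` and otherwise
#' draws a fresh allele, so the pairwise allele (and genotype) correlation
#' between any two SNPs of a block equals `within_block_corr` regardless of
#' allele frequency. SNPs in a block share one allele frequency, drawn
#' uniformly from `[maf_low, maf_high]`; blocks are mutually independent.
#'
#' @param n_individuals,n_snps Panel dimensions.
#' @param maf_low,maf_high Allele-frequency range for the A1 allele,
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param block_size SNPs per LD block (the last block may be smaller).
#' @param within_block_corr Pairwise genotype correlation inside a block,
#'   in `[0, 1)`. A length-2 vector gives the range of a per-block uniform
#'   draw, producing the heterogeneous LD-score distribution real genomes
#'   show (needed for LD-score regression to have identifying variation).
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @param bp_spacing Base-pair distance between adjacent SNPs (positions are
#'   1-based).
#' @param n_chrom Number of chromosomes; blocks are split into `n_chrom`
#'   contiguous runs and positions restart on each chromosome.
#' @return A [geno_matrix()].
#' @export
simulate_genotypes <- function(n_individuals, n_snps, maf_low = 0.05,
                               maf_high = 0.5, block_size = 1L,
                               within_block_corr = 0, seed = 1L,
                               bp_spacing = 5000L, n_chrom = 1L) {
  if (n_individuals < 1 || n_snps < 1) stop("dimensions must be positive")
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("require 0 < maf_low <= maf_high <= 0.5")
  }
  if (block_size < 1) stop("block_size must be >= 1")
  if (!length(within_block_corr) %in% 1:2 ||
      any(within_block_corr < 0) || any(within_block_corr >= 1)) {
    stop("within_block_corr must be one or two values in [0, 1)")
  }
  set.seed(mix_seed(seed, 1L))
  n <- as.integer(n_individuals)
  m <- as.integer(n_snps)
  block_of <- (seq_len(m) - 1L) %/% as.integer(block_size) + 1L
  n_block <- max(block_of)
  p_block <- stats::runif(n_block, maf_low, maf_high)
  p_snp <- p_block[block_of]
  rho_block <- if (length(within_block_corr) == 2) {
    stats::runif(n_block, within_block_corr[1], within_block_corr[2])
  } else {
    rep(within_block_corr, n_block)
  }

  calls <- matrix(0L, n, m)
  if (all(rho_block == 0) || block_size == 1L) {
    # independent SNPs: two haplotype draws per entry, chunked over SNPs
    # (uniform comparison is much faster than a vector-prob rbinom)
    step <- max(1L, 2e7 %/% n)
    for (start in seq(1L, m, by = step)) {
      jj <- start:min(start + step - 1L, m)
      pr <- rep(p_snp[jj], each = n)
      chunk <- (stats::runif(n * length(jj)) < pr) +
        (stats::runif(n * length(jj)) < pr)
      calls[, jj] <- chunk
    }
  } else {
    for (b in seq_len(n_block)) {
      jj <- which(block_of == b)
      B <- length(jj)
      p <- p_block[b]
      gam <- sqrt(rho_block[b])
      g <- matrix(0L, n, B)
      for (h in 1:2) {
        anc <- stats::rbinom(n, 1L, p)
        fresh <- matrix(stats::rbinom(n * B, 1L, p), n, B)
        copy <- matrix(stats::rbinom(n * B, 1L, gam), n, B)
        g <- g + copy * anc + (1L - copy) * fresh
      }
      calls[, jj] <- g
    }
  }

  chrom_of_block <- if (n_chrom <= 1) rep(1L, n_block) else
    as.integer(cut(seq_len(n_block), breaks = n_chrom, labels = FALSE))
  chr <- chrom_of_block[block_of]
  bp <- integer(m)
  for (cc in unique(chr)) {
    idx <- which(chr == cc)
    bp[idx] <- seq_along(idx) * as.integer(bp_spacing)
  }
  map <- data.frame(snp = sprintf("rs%06d", seq_len(m)), chr = chr, bp = bp,
                    a1 = "A", a2 = "G", block = block_of,
                    stringsAsFactors = FALSE)
  geno_matrix(calls, map, sprintf("ind%06d", seq_len(n)))
}

#' Simulate categorical covariates
#'
#' Draws the covariate table the participation and phenotype models use:
#' sex, birth-cohort bin, region of residence, education band and
#' self-rated-health band, all categorical with 2-5 levels.
#'
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return Data frame of factors with `n` rows.
#' @export
simulate_covariates <- function(n, seed = 1L) {
  set.seed(mix_seed(seed, 2L))
  draw <- function(labels, prob) {
    factor(sample(labels, n, replace = TRUE, prob = prob), levels = labels)
  }
  data.frame(
    sex = draw(c("F", "M"), c(0.54, 0.46)),
    cohort = draw(paste0("c", 1:5), c(0.15, 0.2, 0.25, 0.22, 0.18)),
    region = draw(paste0("r", 1:4), c(0.3, 0.28, 0.22, 0.2)),
    education = draw(paste0("e", 1:4), c(0.25, 0.3, 0.25, 0.2)),
    health = draw(c("good", "fair", "poor"), c(0.55, 0.3, 0.15))
  )
}

#' Simulate a polygenic phenotype
#'
#' Builds `y = sum_j beta_j (g_j - 2 MAF_j) + covariate effects + noise`,
#' with causal SNPs drawn uniformly among SNPs with MAF >= 0.05 and effect
#' sizes rescaled so the realised genetic variance share equals `h2`.
#' Genotypes are centred at twice the (unfolded) A1 frequency so the scale
#' of `y` does not depend on allele coding. The phenotype is standardised to
#' unit total variance up to Monte-Carlo noise: the genetic component has
#' sample variance exactly `h2`, the covariate component exactly
#' `covariate_effect_sd^2`, and the noise is drawn with the complementary
#' variance.
#'
#' @param g A [geno_matrix()].
#' @param n_causal Number of causal SNPs (0 allowed only with `h2 = 0`).
#' @param h2 Target genetic variance share, in `[0, 1]`.
#' @param covariate_effect_sd Standard deviation of the total covariate
#'   contribution to `y`; per-level effects are drawn Gaussian and rescaled.
#'   Requires `h2 + covariate_effect_sd^2 <= 1`.
#' @param seed Integer seed.
#' @return An object of class `true_population` with fields `genotypes`,
#'   `true_beta`, `phenotype`, `covariates`, `h2_true`, `causal` and
#'   `components` (the realised genetic/covariate/noise pieces of `y`).
#' @export
simulate_phenotype <- function(g, n_causal, h2 = 0.5,
                               covariate_effect_sd = 0.2, seed = 1L) {
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  m <- ncol(g$calls)
  n <- nrow(g$calls)
  if (n_causal > m) stop("n_causal exceeds the number of SNPs")
  if (h2 > 0 && n_causal < 1) stop("h2 > 0 requires at least one causal SNP")
  cvar <- covariate_effect_sd^2
  if (h2 + cvar > 1 + 1e-12) stop("h2 + covariate_effect_sd^2 must be <= 1")
  covs <- simulate_covariates(n, seed = seed)
  set.seed(mix_seed(seed, 3L))
  cov_effect <- numeric(n)
  if (covariate_effect_sd > 0) {
    for (col in names(covs)) {
      eff <- stats::rnorm(nlevels(covs[[col]]), 0, covariate_effect_sd)
      cov_effect <- cov_effect + eff[as.integer(covs[[col]])]
    }
    sdc <- stats::sd(cov_effect)
    if (sdc > 0) cov_effect <- cov_effect * (covariate_effect_sd / sdc)
    cov_effect <- cov_effect - mean(cov_effect)
  }

  true_beta <- numeric(m)
  genetic <- numeric(n)
  causal <- integer(0)
  if (h2 > 0) {
    eligible <- which(geno_maf(g) >= 0.05)
    if (length(eligible) < n_causal) {
      stop("not enough SNPs with MAF >= 0.05 to place ", n_causal,
           " causal effects")
    }
    causal <- sort(sample(eligible, n_causal))
    beta_raw <- stats::rnorm(n_causal)
    xc <- sweep(g$calls[, causal, drop = FALSE], 2,
                colMeans(g$calls[, causal, drop = FALSE]))
    g_raw <- drop(xc %*% beta_raw)
    v <- stats::var(g_raw)
    if (v <= 0) stop("degenerate genetic component; increase n or MAF range")
    s <- sqrt(h2 / v)
    true_beta[causal] <- beta_raw * s
    genetic <- g_raw * s
  }
  noise_sd <- sqrt(max(0, 1 - h2 - cvar))
  noise <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
  y <- genetic + cov_effect + noise

  structure(list(
    genotypes = g, true_beta = true_beta, phenotype = y,
    covariates = data.frame(id = g$ids, covs, stringsAsFactors = FALSE),
    h2_true = h2, causal = causal,
    components = list(genetic = genetic, covariate = cov_effect,
                      noise = noise)
  ), class = "true_population")
}

#' @export
print.true_population <- function(x, ...) {
  cat(sprintf("<true_population> n = %d, m = %d, causal = %d, h2 = %.3f\n",
              length(x$phenotype), length(x$true_beta), length(x$causal),
              x$h2_true))
  invisible(x)
}

#' Participation scenario specification
#'
#' Describes how individuals select into the cohort. `random` participation
#' depends at most on covariates; `phenotype` adds a coefficient on the
#' standardised phenotype (attenuation-bias scenario); `phenotype_genotype`
#' additionally conditions on the allele count of a designated SNP
#' (collider-bias scenario).
#'
#' @param kind One of `"random"`, `"phenotype"`, `"phenotype_genotype"`.
#' @param coef_y Selection coefficient on the standardised phenotype
#'   (probit/logit scale). Must be 0 for `kind = "random"`.
#' @param coef_g Selection coefficient on the designated SNP's allele count.
#'   Only allowed for `kind = "phenotype_genotype"`.
#' @param snp SNP id or column index carrying `coef_g`.
#' @param coef_cov Optional named list of per-level covariate effects on the
#'   link scale; names must match covariate columns.
#' @param target_rate Participation rate the intercept is calibrated to;
#'   defaults to 0.0545, the acceptance rate of the UK Biobank invitation.
#' @param link Selection link, `"probit"` (default) or `"logit"`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("random", "phenotype",
                                   "phenotype_genotype"),
                          coef_y = 0, coef_g = 0, snp = NULL,
                          coef_cov = NULL, target_rate = 0.0545,
                          link = c("probit", "logit")) {
  kind <- match.arg(kind)
  link <- match.arg(link)
  if (!is.finite(coef_y) || !is.finite(coef_g)) {
    stop("scenario coefficients must be finite")
  }
  if (target_rate <= 0 || target_rate >= 1) {
    stop("target_rate must lie strictly in (0, 1)")
  }
  if (kind == "random" && (coef_y != 0 || coef_g != 0)) {
    stop("kind = 'random' forces coef_y = coef_g = 0")
  }
  if (kind == "phenotype" && coef_g != 0) {
    stop("kind = 'phenotype' forces coef_g = 0")
  }
  if (kind == "phenotype_genotype" && is.null(snp)) {
    stop("kind = 'phenotype_genotype' requires a designated `snp`")
  }
  if (!is.null(coef_cov)) {
    if (is.null(names(coef_cov)) || any(names(coef_cov) == "")) {
      stop("`coef_cov` must be a named list of per-level effects")
    }
  }
  structure(list(kind = kind, coef_y = coef_y, coef_g = coef_g, snp = snp,
                 coef_cov = coef_cov, target_rate = target_rate,
                 link = link),
            class = "scenario_spec")
}

#' Write / read a scenario specification as YAML
#'
#' @param spec A [scenario_spec()].
#' @param path File path.
#' @return `scenario_to_yaml` returns `path` invisibly; `scenario_from_yaml`
#'   returns the reconstructed [scenario_spec()].
#' @export
scenario_to_yaml <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname scenario_to_yaml
#' @export
scenario_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  coef_cov <- x$coef_cov
  if (!is.null(coef_cov)) coef_cov <- lapply(coef_cov, as.numeric)
  scenario_spec(kind = x$kind, coef_y = x$coef_y %||% 0,
                coef_g = x$coef_g %||% 0, snp = x$snp,
                coef_cov = coef_cov, target_rate = x$target_rate,
                link = x$link %||% "probit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate participation into the cohort
#'
#' Computes the true participation probability
#' `p_i = link^{-1}(intercept + coef_y z(y_i) + coef_g g_i + covariate
#' effects)` with the intercept calibrated by root finding so that
#' `mean(p)` matches the scenario's target rate, then draws Bernoulli
#' participation indicators.
#'
#' @param pop A `true_population` from [simulate_phenotype()].
#' @param scenario A [scenario_spec()].
#' @param seed Integer seed for the Bernoulli draws.
#' @return An object of class `selection_outcome` with fields
#'   `participated` (logical), `p_true` (strictly inside (0, 1)),
#'   `intercept`, `ids` and the echoed `scenario`.
#' @export
simulate_participation <- function(pop, scenario, seed = 1L) {
  stopifnot(inherits(pop, "true_population"),
            inherits(scenario, "scenario_spec"))
  set.seed(mix_seed(seed, 4L))
  n <- length(pop$phenotype)
  eta <- numeric(n)
  if (scenario$coef_y != 0) {
    eta <- eta + scenario$coef_y * as.numeric(scale(pop$phenotype))
  }
  if (scenario$kind == "phenotype_genotype") {
    j <- scenario$snp
    if (is.character(j)) {
      j <- match(j, pop$genotypes$map$snp)
      if (is.na(j)) stop("designated SNP not found in the genotype map")
    }
    eta <- eta + scenario$coef_g * pop$genotypes$calls[, j]
  }
  if (!is.null(scenario$coef_cov)) {
    for (col in names(scenario$coef_cov)) {
      if (!col %in% names(pop$covariates)) {
        stop("coef_cov names a covariate not present: ", col)
      }
      f <- pop$covariates[[col]]
      eff <- scenario$coef_cov[[col]]
      if (length(eff) != nlevels(f)) {
        stop("coef_cov for '", col, "' must have one effect per level")
      }
      eta <- eta + eff[as.integer(f)]
    }
  }
  linkinv <- if (scenario$link == "probit") stats::pnorm else stats::plogis
  f <- function(a) mean(linkinv(a + eta)) - scenario$target_rate
  lo <- -20; hi <- 20
  if (f(lo) > 0 || f(hi) < 0) {
    stop("intercept calibration fails to bracket the target rate")
  }
  a <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  p_true <- pmin(pmax(linkinv(a + eta), 1e-12), 1 - 1e-12)
  participated <- stats::runif(n) < p_true
  structure(list(participated = participated, p_true = p_true,
                 intercept = a, ids = pop$genotypes$ids,
                 scenario = scenario),
            class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat(sprintf(
    "<selection_outcome> kind = %s, rate = %.4f (target %.4f), n = %d\n",
    x$scenario$kind, mean(x$participated), x$scenario$target_rate,
    length(x$participated)))
  invisible(x)
}
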