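run_config_defaults <- function() {
  list(
    seed = 1L,
    n_individuals = 10000L, n_snps = 1000L,
    maf_low = 0.05, maf_high = 0.5,
    block_size = 1L, within_block_corr = 0,
    bp_spacing = 5000L, n_chrom = 1L,
    n_causal = 100L, h2 = 0.5, covariate_effect_sd = 0.2,
    scenario = list(kind = "random", target_rate = 0.0545),
    weights = "estimated",
    proxy_reliability = 0.7, proxy_bins = 5L,
    winsor_lo = 1, winsor_hi = 99,
    maf_min = 0.01, hwe_p_min = 1e-6,
    snp_miss_max = 0.02, ind_miss_max = 0.02, het_sd = 3,
    clump_r2 = 0.1, clump_window_kb = 250,
    p_sig = 5e-8, tophit_p = 1e-5,
    ld_window_kb = 1000, n_blocks = 200L,
    out_dir = NULL, verbose = TRUE
  )
}

#' Build a pipeline run configuration
#'
#' All thresholds default to standard GWAS practice: MAF 0.01, exact HWE
#' p 1e-6, 2% missingness, weight winsorisation at the 1st/99th
#' percentiles, clumping at r^2 0.1 within 250 kb, genome-wide
#' significance 5e-8 and the 1e-5 top-hit cutoff. Unknown keys are
#' rejected.
#'
#' @param ... Overrides of the default fields (see
#'   `wgwas:::run_config_defaults()`); `scenario` may be a
#'   [scenario_spec()] or an equivalent list.
#' @return An object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  if (inherits(cfg$scenario, "scenario_spec")) {
    cfg$scenario <- unclass(cfg$scenario)
  }
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param cfg A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   the reconstructed [run_config()], rejecting unknown keys.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x)
}

config_hash <- function(cfg) {
  x <- unclass(cfg)
  x$out_dir <- NULL      # execution details, not scientific configuration
  x$verbose <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(x, tmp)
  unname(tools::md5sum(tmp))
}

as_scenario <- function(x) {
  if (inherits(x, "scenario_spec")) return(x)
  coef_cov <- x$coef_cov
  if (!is.null(coef_cov)) coef_cov <- lapply(coef_cov, as.numeric)
  scenario_spec(kind = x$kind, coef_y = x$coef_y %||% 0,
                coef_g = x$coef_g %||% 0, snp = x$snp,
                coef_cov = coef_cov,
                target_rate = x$target_rate %||% 0.0545,
                link = x$link %||% "probit")
}

#' Run the full simulate-weight-scan-compare-heritability pipeline
#'
#' Executes, in order: cohort simulation (genotypes, polygenic phenotype,
#' participation), IP-weight construction (estimated by penalised probit
#' or oracle `1/p_true`), genotype QC, the unweighted and weighted
#' association scans, all scan contrasts (Hausman, effective sample
#' sizes, SE inflation, clumping, top-hit slope over the causal SNPs,
#' novel-locus screen), and LD-score-regression heritability with the
#' heritability-difference test. All randomness derives from
#' `config$seed`; two runs with equal configs produce identical reports.
#'
#' @param config A [run_config()].
#' @return The report list (also written to `report.json`, along with
#'   sumstats, weight and clump artifacts, when `config$out_dir` is set).
#'   Any stage failure aborts with the stage name and a manifest of the
#'   artifacts written so far.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  hash <- config_hash(cfg)
  written <- character(0)
  say <- function(...) if (isTRUE(cfg$verbose)) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           if (length(written) > 0) {
             paste0("\npartial artifacts: ",
                    paste(written, collapse = ", "))
           } else "",
           call. = FALSE)
    })
  }
  out_path <- function(name) file.path(cfg$out_dir, name)
  hdr <- function() c(paste0("wgwas ",
                             as.character(utils::packageVersion("wgwas"))),
                      paste0("config ", hash))

  say("[simulate] n = ", cfg$n_individuals, ", m = ", cfg$n_snps,
      ", seed = ", cfg$seed)
  sim <- stage("simulate", {
    g <- simulate_genotypes(cfg$n_individuals, cfg$n_snps, cfg$maf_low,
                            cfg$maf_high, cfg$block_size,
                            cfg$within_block_corr, seed = cfg$seed,
                            bp_spacing = cfg$bp_spacing,
                            n_chrom = cfg$n_chrom)
    pop <- simulate_phenotype(g, cfg$n_causal, cfg$h2,
                              cfg$covariate_effect_sd,
                              seed = cfg$seed + 1L)
    scn <- as_scenario(cfg$scenario)
    sel <- simulate_participation(pop, scn, seed = cfg$seed + 2L)
    list(pop = pop, sel = sel, scn = scn)
  })
  part <- which(sim$sel$participated)
  say("[simulate] participation rate ", round(mean(sim$sel$participated), 4),
      " (", length(part), " participants)")

  ipw <- stage("weights", {
    if (identical(cfg$weights, "oracle")) {
      oracle_ip_weights(sim$sel)
    } else {
      covs <- sim$pop$covariates[, -1, drop = FALSE]
      # When selection acts on the phenotype itself, covariate-only
      # weights can only remove the share of selection the covariates
      # explain. Population registers share outcome-proxy variables with
      # cohorts (self-rated health, education); emulate one as a binned
      # noisy transform of the phenotype, available for the whole
      # population like any census variable.
      if (cfg$proxy_reliability > 0 && sim$scn$coef_y != 0) {
        set.seed(mix_seed(cfg$seed, 6L))
        rel <- cfg$proxy_reliability
        proxy <- sqrt(rel) * as.numeric(scale(sim$pop$phenotype)) +
          sqrt(1 - rel) * stats::rnorm(length(sim$pop$phenotype))
        covs$outcome_proxy <- cut(proxy,
                                  breaks = stats::quantile(
                                    proxy,
                                    probs = seq(0, 1,
                                                length.out =
                                                  cfg$proxy_bins + 1)),
                                  include.lowest = TRUE,
                                  labels = paste0("q",
                                                  seq_len(cfg$proxy_bins)))
      }
      model <- fit_participation_model(covs, sim$sel$participated,
                                       seed = cfg$seed + 3L)
      p_hat <- predict(model, covs[part, , drop = FALSE])
      w <- compute_ip_weights(p_hat, ids = sim$pop$genotypes$ids[part],
                              lo_pct = cfg$winsor_lo,
                              hi_pct = cfg$winsor_hi)
      attr(w, "model") <- model
      w
    }
  })
  say("[weights] ", cfg$weights, " weights, range [",
      round(min(ipw$w), 3), ", ", round(max(ipw$w), 3), "]")

  qc <- stage("qc", {
    apply_qc(geno_subset(sim$pop$genotypes, i = part),
             maf_min = cfg$maf_min, hwe_p_min = cfg$hwe_p_min,
             snp_miss_max = cfg$snp_miss_max,
             ind_miss_max = cfg$ind_miss_max, het_sd = cfg$het_sd)
  })
  say("[qc] kept ", qc$report$n_ind_out, " individuals, ",
      qc$report$n_snp_out, " SNPs")

  scans <- stage("scan", {
    keep <- match(qc$geno$ids, sim$pop$genotypes$ids)
    y <- sim$pop$phenotype[keep]
    covs <- sim$pop$covariates[keep, -1, drop = FALSE]
    ids <- qc$geno$ids
    yt_g <- residualize(y, covs, ids = ids)
    yt_w <- residualize(y, covs, w = ipw, ids = ids)
    list(gwas = assoc_scan(yt_g, qc$geno),
         wgwas = assoc_scan(yt_w, qc$geno))
  })
  say("[scan] scanned ", nrow(scans$gwas), " SNPs both ways")

  cmp <- stage("compare", {
    ht <- hausman_test(scans$gwas, scans$wgwas)
    neff_g <- effective_sample_size(scans$gwas)
    neff_w <- effective_sample_size(scans$wgwas)
    cl_w <- clump(scans$wgwas, qc$geno, p1 = cfg$p_sig,
                  r2_min = cfg$clump_r2, window_kb = cfg$clump_window_kb)
    cl_g <- clump(scans$gwas, qc$geno, p1 = cfg$p_sig,
                  r2_min = cfg$clump_r2, window_kb = cfg$clump_window_kb)
    causal_snps <- sim$pop$genotypes$map$snp[sim$pop$causal]
    hits <- intersect(causal_snps, scans$gwas$snp)
    slope <- if (length(hits) >= 3) {
      tophit_slope(scans$gwas, scans$wgwas, hits)
    } else NULL
    list(hausman = ht, neff_g = neff_g, neff_w = neff_w,
         clumps_w = cl_w, clumps_g = cl_g, slope = slope,
         novel = novel_locus_screen(scans$gwas, scans$wgwas, ht, cl_w,
                                    p_sig = cfg$p_sig))
  })

  her <- stage("heritability", {
    nb <- max(2L, min(cfg$n_blocks, nrow(scans$gwas) %/% 5L))
    ld <- ld_scores(qc$geno, window_kb = cfg$ld_window_kb)
    h2_g <- ldsc_h2(scans$gwas, cmp$neff_g, ld, n_blocks = nb)
    h2_w <- ldsc_h2(scans$wgwas, cmp$neff_w, ld, n_blocks = nb)
    cross <- ldsc_cross(scans$gwas, scans$wgwas, cmp$neff_g, cmp$neff_w,
                        ld, n_blocks = nb)
    diff <- h2_difference_test(h2_g, h2_w, cross$cross_intercept)
    list(ld = ld, h2_g = h2_g, h2_w = h2_w, cross = cross, diff = diff)
  })
  say("[heritability] h2 GWAS = ", round(her$h2_g$h2, 4),
      ", h2 WGWAS = ", round(her$h2_w$h2, 4))

  report <- list(
    seed = cfg$seed, config_hash = hash,
    scenario = cfg$scenario,
    n_participants = length(part),
    participation_rate = mean(sim$sel$participated),
    n_snps_scanned = nrow(scans$gwas),
    mean_neff_gwas = cmp$neff_g$mean_neff,
    mean_neff_wgwas = cmp$neff_w$mean_neff,
    neff_shrinkage = neff_shrinkage(cmp$neff_g, cmp$neff_w),
    se_inflation_pct = se_inflation(scans$gwas, scans$wgwas),
    sig_hits_gwas = length(cmp$clumps_g$clumps),
    sig_hits_wgwas = length(cmp$clumps_w$clumps),
    tophit_slope = if (is.null(cmp$slope)) NULL else
      list(slope = cmp$slope$slope, ci = cmp$slope$ci, p = cmp$slope$p,
           n_snps = cmp$slope$n_snps),
    h2_gwas = her$h2_g$h2, h2_gwas_se = her$h2_g$se_h2,
    h2_wgwas = her$h2_w$h2, h2_wgwas_se = her$h2_w$se_h2,
    ldsc_intercept_gwas = her$h2_g$intercept,
    ldsc_intercept_wgwas = her$h2_w$intercept,
    rg = her$cross$r_g, cross_intercept = her$cross$cross_intercept,
    h2_diff_z = her$diff$z, h2_diff_p = her$diff$p,
    novel_loci = cmp$novel$snp
  )

  if (!is.null(cfg$out_dir)) {
    stage("artifacts", {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_sumstats(scans$gwas, out_path("gwas.sumstats.tsv"),
                     n = cmp$neff_g, comments = hdr())
      written <<- c(written, out_path("gwas.sumstats.tsv"))
      write_sumstats(scans$wgwas, out_path("wgwas.sumstats.tsv"),
                     n = cmp$neff_w, comments = hdr())
      written <<- c(written, out_path("wgwas.sumstats.tsv"))
      write_weights(ipw, out_path("weights.tsv"),
                    model = attr(ipw, "model"), comments = hdr())
      written <<- c(written, out_path("weights.tsv"))
      jsonlite::write_json(report, out_path("report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      written <<- c(written, out_path("report.json"))
    })
    say("[artifacts] wrote ", length(written), " files to ", cfg$out_dir)
  }
  invisible(report)
}
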