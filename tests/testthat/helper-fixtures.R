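# Small simulated objects reused across test files. Sizes are kept modest;
# statistically demanding checks build their own larger fixtures locally.

fix_panel <- function(n = 2000, m = 60, seed = 7, ...) {
  simulate_genotypes(n, m, maf_low = 0.1, maf_high = 0.5, seed = seed, ...)
}

fix_cohort <- function(n = 4000, m = 80, h2 = 0.4, seed = 21,
                       scenario = scenario_spec("random",
                                                target_rate = 0.4),
                       ...) {
  g <- simulate_genotypes(n, m, maf_low = 0.1, seed = seed, ...)
  pop <- simulate_phenotype(g, n_causal = max(1, m %/% 4), h2 = h2,
                            seed = seed + 1)
  sel <- simulate_participation(pop, scenario, seed = seed + 2)
  list(g = g, pop = pop, sel = sel, part = which(sel$participated))
}

# independent brute-force HWE oracle: enumerate all heterozygote counts
# compatible with the allele counts and sum the probabilities of
# configurations no more likely than the observed one
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- 2 * n_AA + n_Aa      # count of the A allele
  hets <- seq(if (na %% 2 == 0) 0 else 1, min(na, 2 * n - na), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (na - h) / 2
    bb <- n - h - aa
    lchoose(n, aa) + lchoose(n - aa, h) + h * log(2) -
      lchoose(2 * n, na)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[hets == n_Aa]
  sum(p[p <= obs * (1 + 1e-7)])
}

# independent greedy-clumping oracle written directly from the definition,
# with explicit loops and a plain r^2 matrix
clump_oracle <- function(assoc, g, p1, r2_min, window_kb) {
  r2 <- suppressWarnings(stats::cor(g$calls))^2
  pos <- match(assoc$snp, g$map$snp)
  remaining <- seq_len(nrow(assoc))
  idx <- character(0)
  repeat {
    cand <- remaining[!is.na(assoc$p[remaining]) &
                        assoc$p[remaining] < p1]
    if (length(cand) == 0) break
    o <- order(assoc$p[cand], assoc$chr[cand], assoc$bp[cand],
               assoc$snp[cand])
    i <- cand[o[1]]
    idx <- c(idx, assoc$snp[i])
    drop <- i
    for (j in setdiff(remaining, i)) {
      if (assoc$chr[j] == assoc$chr[i] &&
          abs(assoc$bp[j] - assoc$bp[i]) <= window_kb * 1000 &&
          !is.na(r2[pos[i], pos[j]]) && r2[pos[i], pos[j]] >= r2_min) {
        drop <- c(drop, j)
      }
    }
    remaining <- setdiff(remaining, drop)
  }
  idx
}
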