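#' Published UK Biobank effective-sample-size pairs
#'
#' Reference values for ten UK Biobank phenotypes from a published
#' volunteer-bias-weighted GWAS analysis: the mean per-SNP effective sample
#' size of the unweighted scan (`neff_gwas`) and of the IP-weighted scan
#' (`neff_wgwas`). Used by the package's arithmetic consistency checks,
#' which recompute the published average effective-sample-size shrinkage
#' and the power-equivalent representative cohort size from these pairs.
#'
#' @return Data frame with columns `phenotype`, `neff_gwas`, `neff_wgwas`,
#'   and attribute `n_sample` (the analysis sample size, 376,900).
#' @export
ukb_printed_neff <- function() {
  out <- data.frame(
    phenotype = c("Age at First Birth", "BMI", "Breast cancer",
                  "Drinks per Week", "Self-rated health", "Height",
                  "Physical activity", "Severe Obesity",
                  "Type 1 Diabetes", "Years of Education"),
    neff_gwas = c(139093, 372969, 197857, 265696, 372714, 374175,
                  334570, 373834, 373786, 392433),
    neff_wgwas = c(51949, 135238, 90492, 96008, 136982, 151328,
                   123017, 136396, 132605, 160707),
    stringsAsFactors = FALSE)
  attr(out, "n_sample") <- 376900
  out
}

#' Average effective-sample-size shrinkage and power-equivalent cohort
#'
#' Averages the per-phenotype shrinkage `1 - neff_wgwas / neff_gwas` over
#' a table of effective-sample-size pairs, and converts it into the size
#' of a hypothetical representative cohort with equivalent GWAS power:
#' `n_sample * (1 - shrinkage)`. The reported power-equivalent size uses
#' the shrinkage rounded to `digits` decimals, matching the precision at
#' which such shrinkage figures are conventionally quoted.
#'
#' @param tbl Data frame with columns `neff_gwas` and `neff_wgwas`
#'   (default [ukb_printed_neff()]).
#' @param n_sample Analysis sample size; defaults to the table's
#'   `n_sample` attribute.
#' @param digits Decimals the shrinkage is rounded to before the
#'   power-equivalent conversion (default 2).
#' @return List with `mean_shrinkage` (unrounded fraction),
#'   `mean_shrinkage_pct`, `power_equivalent_n`.
#' @export
neff_shrinkage_summary <- function(tbl = ukb_printed_neff(),
                                   n_sample = attr(tbl, "n_sample"),
                                   digits = 2) {
  if (is.null(n_sample)) stop("n_sample must be supplied")
  shr <- mean(1 - tbl$neff_wgwas / tbl$neff_gwas)
  list(mean_shrinkage = shr,
       mean_shrinkage_pct = 100 * shr,
       power_equivalent_n = n_sample * (1 - round(shr, digits)))
}
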