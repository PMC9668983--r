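# SNP-loss versus mismatch-removal trade-off of marker QC filters.
#
# A SNP is removed when it fails ANY enabled criterion:
#   maf_max  - minor allele frequency <= maf_max,
#   hw_p_max - exact Hardy-Weinberg p <= hw_p_max,
#   fis_min  - F_IS defined and >= fis_min (heterozygote deficiency).
# Loci with undefined F_IS (monomorphic) are never removed by the F_IS
# criterion.

#' Define a filter scenario
#'
#' @param name Scenario label; built from the thresholds when `NULL`.
#' @param maf_max Remove SNPs with MAF at or below this value (disabled when
#'   `NULL`).
#' @param hw_p_max Remove SNPs with exact Hardy-Weinberg p at or below this
#'   value.
#' @param fis_min Remove SNPs with F_IS at or above this value.
#' @return An object of class `filter_scenario`.
#' @export
filter_scenario <- function(name = NULL, maf_max = NULL, hw_p_max = NULL,
                            fis_min = NULL) {
  if (is.null(maf_max) && is.null(hw_p_max) && is.null(fis_min)) {
    stop("a filter scenario needs at least one enabled criterion")
  }
  if (!is.null(maf_max) && (maf_max < 0 || maf_max > 0.5)) {
    stop("maf_max must be in [0, 0.5]")
  }
  if (!is.null(hw_p_max) && (hw_p_max <= 0 || hw_p_max > 1)) {
    stop("hw_p_max must be in (0, 1]")
  }
  if (!is.null(fis_min) && (fis_min < -1 || fis_min > 1)) {
    stop("fis_min must be in [-1, 1]")
  }
  if (is.null(name)) {
    name <- paste(c(
      if (!is.null(maf_max)) sprintf("MAF<=%g", maf_max),
      if (!is.null(hw_p_max)) sprintf("HW<=%g", hw_p_max),
      if (!is.null(fis_min)) sprintf("FIS>=%g", fis_min)), collapse = "+")
  }
  structure(list(name = name, maf_max = maf_max, hw_p_max = hw_p_max,
                 fis_min = fis_min), class = "filter_scenario")
}

#' The default scenario grid
#'
#' MAF at 0.05, Hardy-Weinberg at p <= 0.001 and p <= 0.0001, heterozygote
#' deficiency at F_IS >= 0.2, and the MAF + Hardy-Weinberg combination.
#'
#' @return List of [filter_scenario()] objects.
#' @export
default_scenarios <- function() {
  list(filter_scenario(maf_max = 0.05),
       filter_scenario(hw_p_max = 0.001),
       filter_scenario(hw_p_max = 0.0001),
       filter_scenario(fis_min = 0.2),
       filter_scenario(maf_max = 0.05, hw_p_max = 0.001))
}

#' Evaluate one filter scenario
#'
#' @param locus_summaries Per-locus summary for the whole SNP panel
#'   ([summarize_loci()]).
#' @param meset An `me_set` from [mendel_scan()].
#' @param scenario A [filter_scenario()].
#' @return One-row data frame: `scenario`, `snps_removed`, `snps_removed_frac`,
#'   `snps_retained`, `me_loci_removed`, `mismatches_removed`,
#'   `mismatches_removed_frac` and `mismatches_per_snp_lost`.
#' @export
apply_scenario <- function(locus_summaries, meset, scenario) {
  stopifnot(inherits(scenario, "filter_scenario"))
  ls <- locus_summaries
  removed <- rep(FALSE, nrow(ls))
  if (!is.null(scenario$maf_max)) {
    removed <- removed | ls$maf <= scenario$maf_max
  }
  if (!is.null(scenario$hw_p_max)) {
    removed <- removed | ls$hw_p <= scenario$hw_p_max
  }
  if (!is.null(scenario$fis_min)) {
    removed <- removed | (!is.na(ls$F_IS) & ls$F_IS >= scenario$fis_min)
  }
  removed_ids <- ls$locus_id[removed]
  ev <- meset$events
  mism_removed <- sum(ev$locus_id %in% removed_ids)
  n_mism <- nrow(ev)
  data.frame(
    scenario = scenario$name,
    snps_removed = sum(removed),
    snps_removed_frac = sum(removed) / nrow(ls),
    snps_retained = sum(!removed),
    me_loci_removed = sum(meset$loci %in% removed_ids),
    mismatches_removed = mism_removed,
    mismatches_removed_frac = if (n_mism) mism_removed / n_mism else 0,
    mismatches_per_snp_lost = if (sum(removed)) mism_removed / sum(removed)
                              else NA_real_,
    stringsAsFactors = FALSE)
}

#' Evaluate a grid of filter scenarios
#'
#' @param locus_summaries,meset See [apply_scenario()].
#' @param scenarios List of [filter_scenario()] objects
#'   (default: [default_scenarios()]).
#' @return Data frame with one row per scenario, sorted by mismatches removed
#'   per SNP lost (best trade-off first).
#' @export
scenario_grid <- function(locus_summaries, meset,
                          scenarios = default_scenarios()) {
  rows <- lapply(scenarios, function(s) apply_scenario(locus_summaries,
                                                       meset, s))
  out <- do.call(rbind, rows)
  out <- out[order(-out$mismatches_per_snp_lost, out$scenario, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
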