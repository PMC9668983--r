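# Allele-drop classification of error-set loci.
#
# Three literal patterns, evaluated on called genotypes only:
#   ADO      - no heterozygote anywhere in the typed population, both
#              homozygote classes present, and the called reproductive
#              individuals are NOT all fixed for one allele (a locus with
#              fixed reproducers and opposite-homozygote offspring is an
#              allele-drop-IN pattern, not a missing-allele pattern);
#   ADI_het  - every called reproductive individual homozygous for one same
#              allele and at least one non-reproductive individual
#              heterozygous;
#   ADI_hom  - every called reproductive individual homozygous for one same
#              allele and at least one non-reproductive individual
#              homozygous for the other allele.
# Precedence when patterns could co-trigger: ADO > ADI_het > ADI_hom.

.DROP_LEVELS <- c("ADO", "ADI_het", "ADI_hom", "none")

#' Classify loci into allele-drop-out / allele-drop-in patterns
#'
#' @param genotypes A [genotype_table()].
#' @param pedigree A pedigree from [build_pedigree()]; its `is_reproductive`
#'   flag (has at least one offspring in the pedigree) defines the
#'   reproducer set.
#' @param locus_ids Loci to classify (defaults to all loci; typically the
#'   error-set loci).
#' @return Data frame with columns `locus_id` and `drop` (factor with levels
#'   ADO, ADI_het, ADI_hom, none). Loci with no called reproductive
#'   individual are classified `none` with a warning.
#' @export
classify_allele_drop <- function(genotypes, pedigree,
                                 locus_ids = genotypes$loci$locus_id) {
  calls <- genotypes$calls
  idx <- match(locus_ids, rownames(calls))
  if (anyNA(idx)) stop("unknown locus id: ", locus_ids[which(is.na(idx))[1]])
  repro_ids <- intersect(pedigree$id[pedigree$is_reproductive],
                         colnames(calls))
  off_ids <- setdiff(colnames(calls), repro_ids)
  rc <- calls[idx, repro_ids, drop = FALSE]
  oc <- calls[idx, off_ids, drop = FALSE]
  all_calls <- calls[idx, , drop = FALSE]

  any_het <- rowSums(all_calls == 1L, na.rm = TRUE) > 0
  both_hom <- rowSums(all_calls == 0L, na.rm = TRUE) > 0 &
              rowSums(all_calls == 2L, na.rm = TRUE) > 0
  r0 <- rowSums(rc == 0L, na.rm = TRUE)
  r1 <- rowSums(rc == 1L, na.rm = TRUE)
  r2 <- rowSums(rc == 2L, na.rm = TRUE)
  n_rep_called <- r0 + r1 + r2
  rep_fixed <- n_rep_called > 0 & r1 == 0 & (r0 == 0 | r2 == 0)
  # the allele reproducers are fixed for: 1 when all hom allele1
  fixed_allele1 <- rep_fixed & r2 == 0
  off_het <- rowSums(oc == 1L, na.rm = TRUE) > 0
  off_hom1 <- rowSums(oc == 0L, na.rm = TRUE) > 0
  off_hom2 <- rowSums(oc == 2L, na.rm = TRUE) > 0
  off_hom_other <- (fixed_allele1 & off_hom2) | (!fixed_allele1 & off_hom1)

  if (any(n_rep_called == 0)) {
    warning(sum(n_rep_called == 0),
            " locus/loci with no called reproductive individual; ",
            "classified as 'none'")
  }
  drop <- rep("none", length(idx))
  drop[rep_fixed & off_hom_other] <- "ADI_hom"
  drop[rep_fixed & off_het] <- "ADI_het"
  drop[!any_het & both_hom & !rep_fixed] <- "ADO"
  drop[n_rep_called == 0] <- "none"
  data.frame(locus_id = locus_ids,
             drop = factor(drop, levels = .DROP_LEVELS),
             stringsAsFactors = FALSE)
}

#' Cross-tabulate error classes against allele-drop classes
#'
#' Counts loci and mismatches per (error class x drop class) cell. An
#' internal invariant is checked: ADO loci (no heterozygote in the
#' population) cannot carry Trio-class events, since those require a
#' heterozygous offspring.
#'
#' @param meset An `me_set` from [mendel_scan()].
#' @param drop_classes Output of [classify_allele_drop()] covering the
#'   error-set loci.
#' @return List with matrices `loci` and `mismatches`
#'   (rows = the eight error classes, columns = drop classes) and
#'   `per_drop` totals (loci and mismatches per drop class).
#' @export
drop_report <- function(meset, drop_classes) {
  ev <- meset$events
  dr <- drop_classes$drop[match(ev$locus_id, drop_classes$locus_id)]
  if (anyNA(dr) && nrow(ev)) {
    stop("drop_classes does not cover all error-set loci")
  }
  dr <- factor(dr, levels = .DROP_LEVELS)
  mism <- table(me_class = ev$me_class, drop = dr)
  lk <- unique(data.frame(locus_id = ev$locus_id, me_class = ev$me_class,
                          drop = dr))
  loci <- table(me_class = factor(lk$me_class, levels = .ME_CLASSES),
                drop = factor(lk$drop, levels = .DROP_LEVELS))
  if (sum(mism[c("TrioA", "TrioB"), "ADO"]) > 0) {
    stop("internal invariant violated: Trio-class events at an ADO locus")
  }
  per_locus <- unique(data.frame(locus_id = ev$locus_id, drop = dr))
  per_drop <- data.frame(
    drop = .DROP_LEVELS,
    n_loci = as.integer(table(factor(per_locus$drop, levels = .DROP_LEVELS))),
    n_mismatches = as.integer(table(dr)),
    stringsAsFactors = FALSE)
  list(loci = unclass(loci), mismatches = unclass(mism), per_drop = per_drop)
}
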