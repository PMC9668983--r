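# End-to-end audit orchestration and the two summary tables: a dataset
# structure summary (counts, means and ranges) and a per-error-class table
# (loci, mismatches and fraction, per-individual and per-family means, mean
# F_IS, allele-drop composition).

#' Dataset structure summary
#'
#' Counts and reporting means describing the pedigree, the panel and the
#' error set: individuals, trios, families, litters, distinct sires/dams,
#' offspring per family and per litter, loci totals and per-autosome means,
#' mismatch totals and per-individual means. All values are recomputable from
#' the trio and event tables.
#'
#' @param genotypes A [genotype_table()].
#' @param trios,families From [extract_trios_and_families()].
#' @param meset An `me_set` from [mendel_scan()].
#' @param litters Optional litter map (offspring_id, litter_id).
#' @return A two-column data frame (`variable`, `value`).
#' @export
structure_summary <- function(genotypes, trios, families, meset,
                              litters = NULL) {
  ev <- meset$events
  per_ind <- table(factor(ev$offspring_id, levels = trios$offspring_id))
  n_chrom <- length(unique(genotypes$loci$chrom))
  me_per_chrom <- table(factor(ev$chrom[!duplicated(ev$locus_id)],
                               levels = unique(genotypes$loci$chrom)))
  fmt_rng <- function(m, lo, hi) sprintf("%.1f [%s; %s]", m, lo, hi)
  rows <- list(
    c("n_individuals", ncol(genotypes$calls)),
    c("n_individuals_with_me", length(unique(ev$offspring_id))),
    c("n_trios", nrow(trios)),
    c("n_families", nrow(families)),
    c("n_sires", length(unique(trios$father_id))),
    c("n_dams", length(unique(trios$mother_id))),
    c("mean_offspring_per_family",
      fmt_rng(mean(families$size), min(families$size), max(families$size))),
    c("n_loci", nrow(genotypes$calls)),
    c("n_me_loci", length(meset$loci)),
    c("n_unique_me_loci", length(meset$unique_loci)),
    c("mean_sites_per_autosome", sprintf("%.0f", nrow(genotypes$calls) / n_chrom)),
    c("mean_me_sites_per_autosome",
      sprintf("%.0f", length(meset$loci) / n_chrom)),
    c("n_mismatches", nrow(ev)),
    c("mean_me_per_individual",
      if (nrow(trios)) fmt_rng(nrow(ev) / nrow(trios), min(per_ind),
                               max(per_ind)) else NA)
  )
  if (!is.null(litters)) {
    ls <- table(litters$litter_id)
    rows <- append(rows, list(
      c("n_litters", length(ls)),
      c("mean_offspring_per_litter",
        fmt_rng(mean(ls), min(ls), max(ls)))), after = 7)
  }
  out <- data.frame(variable = vapply(rows, `[`, "", 1),
                    value = vapply(rows, `[`, "", 2),
                    stringsAsFactors = FALSE)
  out
}

#' Per-error-class summary table
#'
#' One row per error class: number of loci, number of mismatches and its
#' fraction of the total, mean mismatches per offspring carrying the class,
#' mean number of distinct families per class locus, mean (sd) F_IS of the
#' class loci, and the fraction of class loci in each allele-drop class.
#' Class fractions sum to 1 over the eight classes; loci carrying several
#' classes appear in each of their rows, so the loci column can sum to more
#' than the error-set size.
#'
#' @param meset An `me_set` from [mendel_scan()].
#' @param locus_summaries Panel-wide [summarize_loci()] output.
#' @param drop_classes Optional [classify_allele_drop()] output for the
#'   error-set loci.
#' @return Data frame with one row per class plus a `Total` row.
#' @export
class_summary <- function(meset, locus_summaries, drop_classes = NULL) {
  ev <- meset$events
  n_total <- nrow(ev)
  rows <- lapply(.ME_CLASSES, function(cl) {
    e <- ev[ev$me_class == cl, , drop = FALSE]
    loci <- unique(e$locus_id)
    fis <- locus_summaries$F_IS[match(loci, locus_summaries$locus_id)]
    fam_per_locus <- if (nrow(e)) {
      mean(tapply(e$family_key, e$locus_id, function(x) length(unique(x))))
    } else NA_real_
    r <- data.frame(
      me_class = cl,
      n_loci = length(loci),
      n_mismatches = nrow(e),
      mismatch_fraction = if (n_total) nrow(e) / n_total else 0,
      mean_mismatches_per_individual =
        if (nrow(e)) nrow(e) / length(unique(e$offspring_id)) else NA_real_,
      mean_families_per_locus = fam_per_locus,
      mean_F_IS = if (length(loci)) mean(fis, na.rm = TRUE) else NA_real_,
      sd_F_IS = if (length(loci) > 1) stats::sd(fis, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(drop_classes)) {
      dr <- drop_classes$drop[match(loci, drop_classes$locus_id)]
      for (d in c("ADO", "ADI_het", "ADI_hom")) {
        r[[paste0("frac_", d)]] <- if (length(loci)) mean(dr == d, na.rm = TRUE)
                                   else NA_real_
      }
    }
    r
  })
  out <- do.call(rbind, rows)
  tot <- out[1, ]
  tot$me_class <- "Total"
  tot$n_loci <- length(meset$loci)
  tot$n_mismatches <- n_total
  tot$mismatch_fraction <- if (n_total) 1 else 0
  tot$mean_mismatches_per_individual <-
    if (n_total) n_total / length(unique(ev$offspring_id)) else NA_real_
  tot$mean_families_per_locus <- if (n_total) {
    mean(tapply(ev$family_key, ev$locus_id, function(x) length(unique(x))))
  } else NA_real_
  fis_all <- locus_summaries$F_IS[match(meset$loci,
                                        locus_summaries$locus_id)]
  tot$mean_F_IS <- if (length(fis_all)) mean(fis_all, na.rm = TRUE) else NA_real_
  tot$sd_F_IS <- if (length(fis_all) > 1) stats::sd(fis_all, na.rm = TRUE)
                 else NA_real_
  if (!is.null(drop_classes)) {
    dr <- drop_classes$drop[match(meset$loci, drop_classes$locus_id)]
    for (d in c("ADO", "ADI_het", "ADI_hom")) {
      tot[[paste0("frac_", d)]] <- if (length(dr)) mean(dr == d, na.rm = TRUE)
                                   else NA_real_
    }
  }
  out <- rbind(out, tot)
  rownames(out) <- NULL
  out
}

#' Run the complete Mendelian-error audit from files
#'
#' Reads PED/MAP genotypes, enumerates trios and families, scans for
#' Mendelian errors, computes locus summaries and error rates, classifies
#' allele drop, overlaps the error set with any supplied interval tracks,
#' evaluates the filter scenario grid, and writes all tables to `out_dir`
#' (TSV, plus a JSON rate summary).
#'
#' @param ped_path,map_path PLINK text genotype files.
#' @param cnv_bed,sine_bed,line_bed Optional BED tracks.
#' @param litters_path Optional litter TSV ([read_litter_map()]).
#' @param scenarios Filter scenarios (default [default_scenarios()]).
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, the report bundle: `structure`, `class_table`,
#'   `locus_summaries`, `meset`, `rates`, `drop_classes`, `drop_table`,
#'   `annotations`, `feature_table`, `filter_reports`, `counts`.
#' @export
run_audit <- function(ped_path, map_path, cnv_bed = NULL, sine_bed = NULL,
                      line_bed = NULL, litters_path = NULL,
                      scenarios = default_scenarios(), out_dir = NULL,
                      verbose = FALSE) {
  say <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
                                            ...)
  say("reading genotypes")
  inp <- read_ped_map(ped_path, map_path)
  litters <- if (!is.null(litters_path)) read_litter_map(litters_path)
  tf <- extract_trios_and_families(inp$pedigree, inp$genotypes, litters)
  say(nrow(tf$trios), " trios in ", nrow(tf$families), " families")

  say("locus summaries")
  ls <- summarize_loci(inp$genotypes)
  say("scanning for Mendelian errors")
  meset <- mendel_scan(inp$genotypes, tf$trios, major = ls$major_allele)
  rates <- error_rates(meset)
  counts <- mismatch_counts(meset, tf$trios, tf$families)

  say("allele-drop classification")
  drops <- classify_allele_drop(inp$genotypes, inp$pedigree, meset$loci)
  dtab <- drop_report(meset, drops)

  tracks <- list()
  if (!is.null(cnv_bed)) tracks$CNV <- read_bed_track(cnv_bed, "CNV")
  if (!is.null(sine_bed)) tracks$SINE <- read_bed_track(sine_bed, "SINE")
  if (!is.null(line_bed)) tracks$LINE <- read_bed_track(line_bed, "LINE")
  ann <- NULL
  ftab <- NULL
  if (length(tracks)) {
    say("interval overlap")
    me_loci_df <- inp$genotypes$loci[inp$genotypes$loci$locus_id %in%
                                       meset$loci, , drop = FALSE]
    ann <- annotate_loci(me_loci_df, tracks)
    ftab <- class_feature_table(meset, ann)
  }

  say("filter scenarios")
  freports <- scenario_grid(ls, meset, scenarios)
  struct <- structure_summary(inp$genotypes, tf$trios, tf$families, meset,
                              litters)
  ctab <- class_summary(meset, ls, drops)

  bundle <- list(structure = struct, class_table = ctab,
                 locus_summaries = ls, meset = meset, rates = rates,
                 drop_classes = drops, drop_table = dtab, annotations = ann,
                 feature_table = ftab, filter_reports = freports,
                 counts = counts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
    w(struct, "structure_summary.tsv")
    w(ctab, "class_table.tsv")
    w(merge(ls, drops, by = "locus_id", all.x = TRUE), "locus_summary.tsv")
    w(meset$events, "events.tsv")
    if (!is.null(ann)) w(ann, "annotations.tsv")
    w(freports, "filter_reports.tsv")
    jsonlite::write_json(rates, file.path(out_dir, "rates.json"),
                         auto_unbox = TRUE, digits = NA)
    say("wrote report bundle to ", out_dir)
  }
  invisible(bundle)
}
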