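# Overlap of error-set SNPs with CNV / SINE / LINE interval tracks.
#
# SNPs are treated as single-bp points at their 1-based position; tracks are
# GRanges (converted from 0-based half-open BED on read), so a SNP at
# position p overlaps a BED record (start, end] exactly when start < p <= end.
# Chromosome matching is by name; names present in only one side simply never
# overlap.

.loci_granges <- function(loci) {
  GenomicRanges::GRanges(loci$chrom,
                         IRanges::IRanges(start = loci$pos, end = loci$pos))
}

#' Overlap loci with one interval track
#'
#' @param loci Data frame with columns `locus_id`, `chrom`, `pos` (1-based),
#'   e.g. the `loci` slot of a [genotype_table()] or a locus summary.
#' @param track A `GRanges` track from [read_bed_track()].
#' @return Data frame with `locus_id`, `overlaps` (logical), `kind` (the
#'   `kind` of the first overlapping interval, NA otherwise) and `n_intervals`
#'   (number of overlapping intervals).
#' @export
overlap_loci <- function(loci, track) {
  snp <- .loci_granges(loci)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snp, track))
  q <- S4Vectors::queryHits(hits)
  out <- data.frame(locus_id = loci$locus_id,
                    overlaps = FALSE, kind = NA_character_,
                    n_intervals = 0L, stringsAsFactors = FALSE)
  if (length(q)) {
    out$n_intervals <- as.integer(table(factor(q, levels = seq_len(nrow(loci)))))
    out$overlaps <- out$n_intervals > 0L
    first <- !duplicated(q)
    kinds <- S4Vectors::mcols(track)$kind
    if (!is.null(kinds)) {
      out$kind[q[first]] <- kinds[S4Vectors::subjectHits(hits)[first]]
    }
  }
  out
}

#' Annotate loci against several tracks at once
#'
#' @param loci Locus data frame (see [overlap_loci()]).
#' @param tracks Named list of `GRanges` tracks, e.g.
#'   `list(CNV = ..., SINE = ..., LINE = ...)`.
#' @return Data frame with `locus_id`, one logical column per track, and
#'   `cnv_kind` when a `CNV` track is present. A locus may belong to several
#'   features (multi-membership).
#' @export
annotate_loci <- function(loci, tracks) {
  stopifnot(is.list(tracks), !is.null(names(tracks)))
  out <- data.frame(locus_id = loci$locus_id, stringsAsFactors = FALSE)
  for (nm in names(tracks)) {
    ov <- overlap_loci(loci, tracks[[nm]])
    out[[nm]] <- ov$overlaps
    if (nm == "CNV") out$cnv_kind <- ov$kind
  }
  out
}

#' Carrier-aware overlap of error events with a per-individual CNV track
#'
#' An event overlaps when its locus lies inside an interval AND the
#' interval's `carrier_id` is one of the trio members (offspring, father or
#' mother); intervals without a carrier id match any trio.
#'
#' @param meset An `me_set` from [mendel_scan()].
#' @param track A `GRanges` CNV track with a `carrier_id` metadata column.
#' @return Logical vector, one element per event row of `meset$events`.
#' @export
overlap_events <- function(meset, track) {
  ev <- meset$events
  out <- rep(FALSE, nrow(ev))
  if (!nrow(ev) || !length(track)) return(out)
  snp <- GenomicRanges::GRanges(ev$chrom,
                                IRanges::IRanges(start = ev$pos, end = ev$pos))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snp, track))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  carrier <- S4Vectors::mcols(track)$carrier_id
  if (is.null(carrier)) carrier <- rep(NA_character_, length(track))
  match_member <- is.na(carrier[s]) |
    carrier[s] == ev$offspring_id[q] |
    carrier[s] == ev$father_id[q] |
    carrier[s] == ev$mother_id[q]
  out[unique(q[match_member])] <- TRUE
  out
}

#' Contingency table of error classes against genomic features
#'
#' Counts error-set loci and mismatches per error class and per feature
#' (locus-level overlap). A locus inside two features is counted once per
#' feature column; the `none` column holds loci overlapping no feature, so
#' `none` plus the union of the features partitions the error set.
#'
#' @param meset An `me_set` from [mendel_scan()].
#' @param annotations Output of [annotate_loci()] covering the error-set loci.
#' @return List with matrices `loci` and `mismatches` (rows = the eight error
#'   classes plus a `Total` row, columns = features plus `none`), and
#'   `feature_fraction`, the fraction of error-set loci inside each feature.
#' @export
class_feature_table <- function(meset, annotations) {
  ev <- meset$events
  feats <- setdiff(names(annotations), c("locus_id", "cnv_kind"))
  ai <- match(ev$locus_id, annotations$locus_id)
  if (anyNA(ai) && nrow(ev)) {
    stop("annotations do not cover all error-set loci")
  }
  cols <- c(feats, "none")
  mk <- function(count_loci) {
    m <- matrix(0L, length(.ME_CLASSES) + 1L, length(cols),
                dimnames = list(c(.ME_CLASSES, "Total"), cols))
    flags <- as.matrix(annotations[ai, feats, drop = FALSE])
    flags <- cbind(flags, none = rowSums(flags) == 0)
    for (cl in .ME_CLASSES) {
      in_class <- ev$me_class == cl
      for (co in cols) {
        if (count_loci) {
          m[cl, co] <- length(unique(ev$locus_id[in_class & flags[, co]]))
        } else {
          m[cl, co] <- sum(in_class & flags[, co])
        }
      }
    }
    for (co in cols) {
      if (count_loci) {
        m["Total", co] <- length(unique(ev$locus_id[flags[, co]]))
      } else {
        m["Total", co] <- sum(flags[, co])
      }
    }
    m
  }
  loci_tab <- mk(TRUE)
  mism_tab <- mk(FALSE)
  n_me_loci <- length(meset$loci)
  feature_fraction <- if (n_me_loci) loci_tab["Total", ] / n_me_loci else
    setNames(rep(NA_real_, length(cols)), cols)
  list(loci = loci_tab, mismatches = mism_tab,
       feature_fraction = feature_fraction)
}
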