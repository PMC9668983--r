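# Trio Mendelian-inconsistency detection and eight-class assignment.
#
# Calls are additive codes (copies of allele2). Of the 27 complete trio
# configurations of a biallelic locus, 12 are inconsistent. The error origin
# is assigned from the parental genotypes:
#   * child heterozygous, both parents homozygous for the same allele
#     -> "Trio" (unassignable), violating allele = the one absent in parents;
#   * child homozygous for allele k, exactly one parent homozygous for the
#     other allele -> that parent, violating allele k;
#   * child homozygous for k, both parents homozygous for the other allele
#     -> "Offspring", violating allele k.
# The frequency class is A when the violating allele is the locus major
# allele and B when it is the minor allele.

.ME_MEMBERS <- c("Trio", "Father", "Mother", "Offspring")
.ME_CLASSES <- c("TrioA", "TrioB", "FatherA", "FatherB",
                 "MotherA", "MotherB", "OffspringA", "OffspringB")

# Vectorised decision table. f, m, c: integer vectors of additive calls.
# Returns integer member codes (0 consistent/unevaluable, 1 Trio, 2 Father,
# 3 Mother, 4 Offspring) and violating allele index (1 or 2).
.classify_calls <- function(f, m, c) {
  member <- integer(length(f))
  viol <- integer(length(f))
  ok <- !is.na(f) & !is.na(m) & !is.na(c)

  i <- ok & c == 0L & (f == 2L | m == 2L)        # child hom allele1
  member[i & f == 2L & m == 2L] <- 4L
  member[i & f == 2L & m != 2L] <- 2L
  member[i & f != 2L & m == 2L] <- 3L
  viol[i] <- 1L

  i <- ok & c == 2L & (f == 0L | m == 0L)        # child hom allele2
  member[i & f == 0L & m == 0L] <- 4L
  member[i & f == 0L & m != 0L] <- 2L
  member[i & f != 0L & m == 0L] <- 3L
  viol[i] <- 2L

  i <- ok & c == 1L & f == m & (f == 0L | f == 2L)  # het child, parents fixed
  member[i] <- 1L
  viol[i & f == 0L] <- 2L
  viol[i & f == 2L] <- 1L

  list(member = member, viol = viol)
}

#' Check one trio genotype at one locus for Mendelian consistency
#'
#' @param father_call,mother_call,child_call Additive calls (copies of
#'   allele2): 0, 1 or 2. All three must be non-missing; callers must skip
#'   loci with any missing member.
#' @param major_allele Which allele index (1 or 2) is the locus major allele.
#' @return `"consistent"`, or a list with `member` (`"Trio"`, `"Father"`,
#'   `"Mother"`, `"Offspring"`), `violating_allele` (1 or 2), `freq_class`
#'   (`"A"` or `"B"`) and `me_class` (one of the eight class labels).
#' @examples
#' check_trio_locus(0, 0, 1, major_allele = 1)  # TrioB
#' check_trio_locus(1, 1, 0, major_allele = 1)  # consistent
#' @export
check_trio_locus <- function(father_call, mother_call, child_call,
                             major_allele = 1L) {
  if (is.na(father_call) || is.na(mother_call) || is.na(child_call)) {
    stop("check_trio_locus requires three non-missing calls")
  }
  stopifnot(major_allele %in% c(1L, 2L))
  r <- .classify_calls(as.integer(father_call), as.integer(mother_call),
                       as.integer(child_call))
  if (r$member == 0L) return("consistent")
  freq_class <- if (r$viol == major_allele) "A" else "B"
  member <- .ME_MEMBERS[r$member]
  list(member = member, violating_allele = r$viol, freq_class = freq_class,
       me_class = paste0(member, freq_class))
}

# Major allele index per locus from allele frequencies over all called
# genotypes; ties at 0.5 resolve to allele1.
major_allele_index <- function(genotypes) {
  calls <- genotypes$calls
  n1 <- rowSums(calls == 1L, na.rm = TRUE)
  n2 <- rowSums(calls == 2L, na.rm = TRUE)
  n <- rowSums(!is.na(calls))
  q2 <- (n1 + 2 * n2) / (2 * pmax(n, 1L))  # frequency of allele2
  ifelse(q2 > 0.5, 2L, 1L)
}

#' Scan all trios and loci for Mendelian errors
#'
#' Iterates over every (trio, locus) pair, skipping pairs with any missing
#' call, and records one event per inconsistency. Scanning is locus-major
#' within trio and the event table is sorted deterministically (locus order,
#' then trio order).
#'
#' @param genotypes A [genotype_table()].
#' @param trios Trio data frame from [extract_trios_and_families()].
#' @param major Optional integer vector of major-allele indices per locus
#'   (1 or 2); computed from the whole dataset when `NULL`.
#' @return An object of class `me_set`: list with `events` (one row per
#'   inconsistent trio-locus), `loci` (locus ids with at least one event),
#'   `unique_loci` (subset with events in exactly one trio),
#'   `n_loci_scanned`, `n_trios` and `n_individuals`.
#' @export
mendel_scan <- function(genotypes, trios, major = NULL) {
  calls <- genotypes$calls
  loci <- genotypes$loci
  ids <- colnames(calls)
  missing_members <- setdiff(unique(c(trios$offspring_id, trios$father_id,
                                      trios$mother_id)), ids)
  if (length(missing_members)) {
    bad <- trios[trios$offspring_id %in% missing_members |
                 trios$father_id %in% missing_members |
                 trios$mother_id %in% missing_members, , drop = FALSE]
    stop("trio member(s) absent from genotype table, e.g. trio for offspring ",
         bad$offspring_id[1])
  }
  if (is.null(major)) major <- major_allele_index(genotypes)
  stopifnot(length(major) == nrow(calls), all(major %in% c(1L, 2L)))

  acc <- vector("list", nrow(trios))
  for (t in seq_len(nrow(trios))) {
    f <- calls[, trios$father_id[t]]
    m <- calls[, trios$mother_id[t]]
    c_ <- calls[, trios$offspring_id[t]]
    r <- .classify_calls(f, m, c_)
    hit <- which(r$member > 0L)
    if (length(hit)) {
      acc[[t]] <- data.frame(locus_idx = hit, trio_idx = t,
                             member = r$member[hit], viol = r$viol[hit])
    }
  }
  ev <- do.call(rbind, acc)
  if (is.null(ev)) {
    ev <- data.frame(locus_idx = integer(0), trio_idx = integer(0),
                     member = integer(0), viol = integer(0))
  }
  ev <- ev[order(ev$locus_idx, ev$trio_idx), , drop = FALSE]
  allele_sym <- cbind(loci$allele1, loci$allele2)
  freq_class <- ifelse(ev$viol == major[ev$locus_idx], "A", "B")
  member <- .ME_MEMBERS[ev$member]
  events <- data.frame(
    locus_id = loci$locus_id[ev$locus_idx],
    chrom = loci$chrom[ev$locus_idx],
    pos = loci$pos[ev$locus_idx],
    offspring_id = trios$offspring_id[ev$trio_idx],
    father_id = trios$father_id[ev$trio_idx],
    mother_id = trios$mother_id[ev$trio_idx],
    family_key = trios$family_key[ev$trio_idx],
    member = member,
    violating_allele = allele_sym[cbind(ev$locus_idx, ev$viol)],
    freq_class = freq_class,
    me_class = factor(paste0(member, freq_class), levels = .ME_CLASSES),
    stringsAsFactors = FALSE
  )
  rownames(events) <- NULL
  per_locus_trios <- table(events$locus_id)
  structure(list(events = events,
                 loci = names(per_locus_trios),
                 unique_loci = names(per_locus_trios)[per_locus_trios == 1],
                 n_loci_scanned = nrow(calls),
                 n_trios = nrow(trios),
                 n_individuals = ncol(calls)),
            class = "me_set")
}

#' @export
print.me_set <- function(x, ...) {
  cat("me_set: ", nrow(x$events), " mismatches at ", length(x$loci),
      " loci (", length(x$unique_loci), " unique) over ", x$n_trios,
      " trios and ", x$n_loci_scanned, " loci scanned\n", sep = "")
  if (nrow(x$events)) print(table(x$events$me_class))
  invisible(x)
}

#' Mismatch counts per offspring, family, locus, chromosome and class
#'
#' Also reports the Pearson and Spearman correlation between family size and
#' the per-family mismatch count (`NA` when fewer than three families or when
#' either variable is constant).
#'
#' @param meset An `me_set` from [mendel_scan()].
#' @param trios,families As returned by [extract_trios_and_families()].
#' @return List with `per_offspring`, `per_family` (joined with family size),
#'   `per_locus`, `per_chrom`, `per_class` and `family_size_cor`.
#' @export
mismatch_counts <- function(meset, trios, families) {
  ev <- meset$events
  per_offspring <- data.frame(
    offspring_id = trios$offspring_id,
    n_mismatches = as.integer(table(factor(ev$offspring_id,
                                           levels = trios$offspring_id))),
    stringsAsFactors = FALSE)
  per_family <- data.frame(
    family_key = families$family_key,
    size = families$size,
    n_mismatches = as.integer(table(factor(ev$family_key,
                                           levels = families$family_key))),
    stringsAsFactors = FALSE)
  count_by <- function(x, nm) {
    if (!length(x)) {
      out <- data.frame(key = character(0), n_mismatches = integer(0),
                        stringsAsFactors = FALSE)
    } else {
      tab <- table(x)
      out <- data.frame(key = names(tab), n_mismatches = as.integer(tab),
                        stringsAsFactors = FALSE)
    }
    names(out)[1] <- nm
    out
  }
  per_locus <- count_by(ev$locus_id, "locus_id")
  per_chrom <- count_by(ev$chrom, "chrom")
  per_class <- as.data.frame(table(me_class = ev$me_class),
                             stringsAsFactors = FALSE)
  names(per_class)[2] <- "n_mismatches"

  fc <- c(pearson = NA_real_, spearman = NA_real_)
  if (nrow(per_family) >= 3 && stats::var(per_family$size) > 0 &&
      stats::var(per_family$n_mismatches) > 0) {
    fc["pearson"] <- cor(per_family$size, per_family$n_mismatches)
    fc["spearman"] <- cor(per_family$size, per_family$n_mismatches,
                          method = "spearman")
  }
  list(per_offspring = per_offspring, per_family = per_family,
       per_locus = per_locus, per_chrom = per_chrom, per_class = per_class,
       family_size_cor = fc)
}
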