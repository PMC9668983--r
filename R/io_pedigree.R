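# File input/output and pedigree structure: PLINK text PED/MAP, BED interval
# tracks, litter maps, trio/family enumeration and structural validation.

#' Construct a genotype table
#'
#' A genotype table couples a locus map with an integer call matrix. Calls are
#' coded as the number of copies of `allele2` (0, 1, 2) with `NA` for missing,
#' the usual additive coding for biallelic SNPs.
#'
#' @param calls Integer matrix, loci in rows, individuals in columns. Row names
#'   are locus ids, column names individual ids.
#' @param loci Data frame with columns `locus_id`, `chrom`, `pos` (1-based),
#'   `allele1`, `allele2`. `allele2` may be `NA` for loci where only one allele
#'   was ever observed.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(calls, loci) {
  stopifnot(is.matrix(calls), nrow(calls) == nrow(loci))
  required <- c("locus_id", "chrom", "pos", "allele1", "allele2")
  if (!all(required %in% names(loci))) {
    stop("loci must have columns: ", paste(required, collapse = ", "))
  }
  if (anyDuplicated(loci$locus_id)) stop("duplicated locus_id in locus map")
  if (any(loci$pos < 1, na.rm = TRUE)) stop("locus positions must be 1-based (>= 1)")
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  rownames(calls) <- loci$locus_id
  structure(list(calls = calls, loci = as.data.frame(loci)),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table: ", nrow(x$calls), " loci x ", ncol(x$calls),
      " individuals\n", sep = "")
  cr <- mean(!is.na(x$calls))
  cat(sprintf("  call rate %.4f\n", cr))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

.as_sex <- function(code) {
  out <- rep("unknown", length(code))
  out[code %in% c("1", "M", "m")] <- "male"
  out[code %in% c("2", "F", "f")] <- "female"
  out
}

#' Read genotypes and pedigree from PLINK text PED/MAP files
#'
#' Whitespace-delimited PED (six header columns, then two allele columns per
#' MAP locus; allele code `"0"` is missing) and four-column MAP
#' (chromosome, locus id, genetic position, 1-based physical position).
#' Per-locus allele symbols are inferred from the observed alleles in file
#' order: the first allele seen becomes `allele1`.
#'
#' @param ped_path,map_path Paths to the PED and MAP files.
#' @return A list with elements `pedigree` (see [build_pedigree()]) and
#'   `genotypes` (a [genotype_table()]).
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) < 4) stop("MAP file must have 4 columns")
  loci <- data.frame(locus_id = map[[2]], chrom = map[[1]],
                     pos = as.integer(map[[4]]),
                     allele1 = NA_character_, allele2 = NA_character_,
                     stringsAsFactors = FALSE)
  n_loci <- nrow(loci)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6L + 2L * n_loci
  len <- lengths(toks)
  if (any(len != expected)) {
    stop(sprintf("malformed PED row at line %d: %d fields, expected %d",
                 which(len != expected)[1], len[len != expected][1], expected))
  }
  m <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  ids <- m[, 2]
  ped <- data.frame(id = ids,
                    sire = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
                    dam = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
                    sex = .as_sex(m[, 5]),
                    stringsAsFactors = FALSE)
  al <- m[, -(1:6), drop = FALSE]                # individuals x (2*loci)
  a1 <- t(al[, seq(1L, 2L * n_loci, by = 2L), drop = FALSE])  # loci x ind
  a2 <- t(al[, seq(2L, 2L * n_loci, by = 2L), drop = FALSE])
  calls <- matrix(NA_integer_, n_loci, length(ids),
                  dimnames = list(loci$locus_id, ids))
  for (l in seq_len(n_loci)) {
    row1 <- a1[l, ]; row2 <- a2[l, ]
    obs <- c(rbind(row1, row2))                  # file order across individuals
    seen <- unique(obs[obs != "0"])
    if (length(seen) > 2) {
      stop("polyallelic locus ", loci$locus_id[l], ": alleles ",
           paste(seen, collapse = ","))
    }
    loci$allele1[l] <- if (length(seen) >= 1) seen[1] else NA_character_
    loci$allele2[l] <- if (length(seen) == 2) seen[2] else NA_character_
    miss <- row1 == "0" | row2 == "0"
    cl <- (row1 == loci$allele2[l] & !is.na(loci$allele2[l])) +
          (row2 == loci$allele2[l] & !is.na(loci$allele2[l]))
    cl[miss] <- NA_integer_
    calls[l, ] <- as.integer(cl)
  }
  list(pedigree = build_pedigree(ped), genotypes = genotype_table(calls, loci))
}

#' Write genotypes and pedigree to PLINK text PED/MAP files
#'
#' Heterozygous calls are written as `allele1 allele2`; missing as `0 0`.
#'
#' @param genotypes A [genotype_table()].
#' @param pedigree A pedigree data frame ([build_pedigree()]); individuals
#'   absent from it are written with unknown parents and sex.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ped_map <- function(genotypes, pedigree, ped_path, map_path) {
  loci <- genotypes$loci
  write.table(data.frame(loci$chrom, loci$locus_id, 0, loci$pos),
              map_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  ids <- colnames(genotypes$calls)
  idx <- match(ids, pedigree$id)
  sire <- ifelse(is.na(idx) | is.na(pedigree$sire[idx]), "0", pedigree$sire[idx])
  dam <- ifelse(is.na(idx) | is.na(pedigree$dam[idx]), "0", pedigree$dam[idx])
  sex <- rep("0", length(ids))
  sex[!is.na(idx)] <- c(male = "1", female = "2",
                        unknown = "0")[pedigree$sex[idx[!is.na(idx)]]]
  a1 <- ifelse(is.na(loci$allele1), "0", loci$allele1)
  a2 <- ifelse(is.na(loci$allele2), "0", loci$allele2)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (j in seq_along(ids)) {
    cl <- genotypes$calls[, j]
    first <- ifelse(is.na(cl), "0", ifelse(cl == 2L, a2, a1))
    second <- ifelse(is.na(cl), "0", ifelse(cl == 0L, a1, a2))
    writeLines(paste(c("FAM", ids[j], sire[j], dam[j], sex[j], "-9",
                       c(rbind(first, second))), collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Build and validate a pedigree
#'
#' Checks id uniqueness, acyclicity (no individual is its own ancestor) and
#' sex consistency of recorded sires/dams, and flags reproductive individuals
#' (those appearing as sire or dam of at least one other individual).
#'
#' @param df Data frame with columns `id`, `sire`, `dam` (NA = unknown) and
#'   optionally `sex` (`"male"`, `"female"`, `"unknown"`).
#' @return A data frame of class `pedigree` with columns `id`, `sire`, `dam`,
#'   `sex`, `is_reproductive`, sorted in a parents-before-offspring
#'   (topological) order.
#' @export
build_pedigree <- function(df) {
  stopifnot(all(c("id", "sire", "dam") %in% names(df)))
  if (anyDuplicated(df$id)) {
    stop("duplicated individual id: ", df$id[duplicated(df$id)][1])
  }
  if (is.null(df$sex)) df$sex <- "unknown"
  sires <- unique(df$sire[!is.na(df$sire)])
  dams <- unique(df$dam[!is.na(df$dam)])
  sx <- df$sex[match(sires, df$id)]
  if (any(sx == "female", na.rm = TRUE)) {
    stop("individual recorded as sire but female: ",
         sires[which(sx == "female")[1]])
  }
  sx <- df$sex[match(dams, df$id)]
  if (any(sx == "male", na.rm = TRUE)) {
    stop("individual recorded as dam but male: ",
         dams[which(sx == "male")[1]])
  }
  df$is_reproductive <- df$id %in% c(sires, dams)

  # Kahn topological order; leftover nodes indicate an ancestry cycle.
  n <- nrow(df)
  parent_idx <- cbind(match(df$sire, df$id), match(df$dam, df$id))
  indeg <- rowSums(!is.na(parent_idx))
  order_out <- integer(0)
  ready <- which(indeg == 0)
  done <- rep(FALSE, n)
  child_of <- split(rep(seq_len(n), 2)[!is.na(parent_idx)],
                    parent_idx[!is.na(parent_idx)])
  while (length(ready)) {
    order_out <- c(order_out, ready)
    done[ready] <- TRUE
    next_ready <- integer(0)
    for (p in ready) {
      kids <- child_of[[as.character(p)]]
      for (k in kids) {
        indeg[k] <- indeg[k] - 1L
        if (indeg[k] == 0L) next_ready <- c(next_ready, k)
      }
    }
    ready <- next_ready
  }
  if (!all(done)) {
    stop("pedigree contains an ancestry cycle involving: ",
         paste(df$id[!done], collapse = ", "))
  }
  out <- df[order_out, c("id", "sire", "dam", "sex", "is_reproductive")]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Enumerate parent-offspring trios and families
#'
#' A trio is formed for every individual whose sire and dam are both recorded
#' and (when `genotypes` is supplied) all three members are genotyped.
#' Families group trios sharing the exact (father, mother) couple.
#'
#' @param pedigree A pedigree from [build_pedigree()].
#' @param genotypes Optional [genotype_table()]; restricts trios to fully
#'   genotyped ones.
#' @param litters Optional data frame with columns `offspring_id`,
#'   `litter_id`; joined onto the trios.
#' @return List with `trios` (offspring_id, father_id, mother_id, family_key,
#'   litter_id) and `families` (family_key, father_id, mother_id, size).
#' @export
extract_trios_and_families <- function(pedigree, genotypes = NULL,
                                       litters = NULL) {
  keep <- !is.na(pedigree$sire) & !is.na(pedigree$dam)
  tr <- pedigree[keep, , drop = FALSE]
  if (!is.null(genotypes)) {
    g <- colnames(genotypes$calls)
    tr <- tr[tr$id %in% g & tr$sire %in% g & tr$dam %in% g, , drop = FALSE]
  }
  trios <- data.frame(offspring_id = tr$id, father_id = tr$sire,
                      mother_id = tr$dam,
                      family_key = if (nrow(tr)) paste(tr$sire, tr$dam,
                                                       sep = "x")
                                   else character(0),
                      litter_id = rep(NA_character_, nrow(tr)),
                      stringsAsFactors = FALSE)
  if (!is.null(litters)) {
    trios$litter_id <- litters$litter_id[match(trios$offspring_id,
                                               litters$offspring_id)]
  }
  rownames(trios) <- NULL
  if (nrow(trios)) {
    fam <- as.data.frame(table(family_key = trios$family_key),
                         stringsAsFactors = FALSE)
    names(fam)[2] <- "size"
    i <- match(fam$family_key, trios$family_key)
    families <- data.frame(family_key = fam$family_key,
                           father_id = trios$father_id[i],
                           mother_id = trios$mother_id[i],
                           size = as.integer(fam$size),
                           stringsAsFactors = FALSE)
  } else {
    families <- data.frame(family_key = character(0), father_id = character(0),
                           mother_id = character(0), size = integer(0))
  }
  list(trios = trios, families = families)
}

#' Read a BED interval track
#'
#' BED3+ with optional column 4 (`kind`, e.g. duplication / het_deletion /
#' hom_deletion / SINE / LINE) and column 5 (`carrier_id` for per-individual
#' CNV calls). BED coordinates are 0-based half-open; they are converted to
#' the 1-based closed convention of [GenomicRanges::GRanges] on read, so a
#' record `chrom 100 200` covers 1-based positions 101..200. Overlapping
#' intervals are retained unmerged.
#'
#' @param bed_path Path to the BED file.
#' @param name Track name (e.g. `"CNV"`, `"SINE"`, `"LINE"`).
#' @return A `GRanges` with metadata columns `kind` and `carrier_id` and a
#'   `track_name` metadata slot.
#' @export
read_bed_track <- function(bed_path, name = "track") {
  if (!file.exists(bed_path)) stop("BED file not found: ", bed_path)
  lines <- readLines(bed_path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    gr <- GenomicRanges::GRanges(kind = character(0),
                                 carrier_id = character(0))
    S4Vectors::metadata(gr)$track_name <- name
    return(gr)
  }
  toks <- strsplit(lines, "[ \t]+")
  if (any(lengths(toks) < 3)) stop("BED line with fewer than 3 columns")
  chrom <- vapply(toks, `[`, "", 1)
  start0 <- as.numeric(vapply(toks, `[`, "", 2))
  end0 <- as.numeric(vapply(toks, `[`, "", 3))
  if (any(is.na(start0)) || any(is.na(end0))) stop("non-numeric BED coordinates")
  if (any(start0 >= end0)) {
    bad <- which(start0 >= end0)[1]
    stop(sprintf("invalid interval (start >= end) at line %d: %s", bad,
                 lines[bad]))
  }
  kind <- vapply(toks, function(x) if (length(x) >= 4) x[4] else NA_character_, "")
  carrier <- vapply(toks, function(x) if (length(x) >= 5) x[5] else NA_character_, "")
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = start0 + 1, end = end0),
                               kind = kind, carrier_id = carrier)
  S4Vectors::metadata(gr)$track_name <- name
  gr
}

#' Write a BED interval track
#'
#' Inverse of [read_bed_track()]: 1-based closed `GRanges` are written back as
#' 0-based half-open BED, preserving coordinates exactly.
#'
#' @param track A `GRanges` as returned by [read_bed_track()].
#' @param bed_path Output path.
#' @return Invisibly, `bed_path`.
#' @export
write_bed_track <- function(track, bed_path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(track)),
                   start = GenomicRanges::start(track) - 1,
                   end = GenomicRanges::end(track))
  mc <- S4Vectors::mcols(track)
  if (!is.null(mc$kind)) {
    df$kind <- ifelse(is.na(mc$kind), ".", mc$kind)
    if (!is.null(mc$carrier_id) && any(!is.na(mc$carrier_id))) {
      df$carrier <- ifelse(is.na(mc$carrier_id), ".", mc$carrier_id)
    }
  }
  write.table(df, bed_path, quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(bed_path)
}

#' Read a litter map
#'
#' Two-column TSV (`offspring_id`, `litter_id`) attaching litter membership to
#' trio offspring; litters are side metadata, PED carries no litter column.
#'
#' @param path Path to the TSV file (with header).
#' @return Data frame with columns `offspring_id` and `litter_id`.
#' @export
read_litter_map <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = "character")
  stopifnot(all(c("offspring_id", "litter_id") %in% names(df)))
  df
}
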