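# Per-locus population statistics and dataset-level error rates.
#
# Frequencies are computed over all called genotypes (founders plus
# offspring). He is 2pq without small-sample correction, so a locus with both
# homozygote classes and no heterozygotes gives F_IS exactly 1. F_IS is
# undefined (NA) for monomorphic loci.

# Exact conditional Hardy-Weinberg test on the heterozygote count (the
# standard SNP exact test): given n genotypes and the minor-allele count, the
# two-sided p-value sums the conditional probabilities of every heterozygote
# count no more likely than the observed one. Relative probabilities are
# built by the ratio recurrence
#   P(h + 2) / P(h) = 4 * nAA(h) * nBB(h) / ((h + 2) * (h + 1))
# starting from the most heterozygous configuration, then normalised.
.hw_exact_one <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  n_minor <- min(2L * n_AA + n_AB, 2L * n_BB + n_AB)
  if (n_minor == 0L) return(1)
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  lp <- numeric(length(hets))
  for (k in seq_along(lp)[-length(lp)]) {
    h <- hets[length(hets) - k + 1L]          # walk down from h = n_minor
    naa <- (n_minor - h + 2L) / 2L            # rare-hom count at h - 2
    nbb <- n - naa - (h - 2L)
    # log P(h-2) - log P(h)
    lp[length(lp) - k] <- lp[length(lp) - k + 1L] +
      log(h) + log(h - 1) - log(4) - log(naa) - log(nbb)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_AB, hets)
  min(1, sum(p[p <= p[obs] * (1 + 1e-10)]))
}

#' Exact Hardy-Weinberg test p-value
#'
#' Two-sided exact test conditional on the observed minor-allele count; the
#' p-value is the summed conditional probability of all heterozygote counts
#' whose probability does not exceed that of the observed count. Monomorphic
#' loci return 1. Vectorised over the three count vectors.
#'
#' @param n_AA,n_AB,n_BB Non-negative integer genotype counts.
#' @return Numeric vector of p-values in (0, 1].
#' @export
hw_exact_p <- function(n_AA, n_AB, n_BB) {
  if (any(n_AA < 0 | n_AB < 0 | n_BB < 0, na.rm = TRUE)) {
    stop("genotype counts must be non-negative")
  }
  if (any(n_AA + n_AB + n_BB < 1)) stop("at least one genotype required")
  mapply(.hw_exact_one, as.integer(n_AA), as.integer(n_AB), as.integer(n_BB))
}

#' Summarise one locus from its genotype calls
#'
#' @param calls_at_locus Integer vector of additive calls (0/1/2, NA missing).
#' @return One-row data frame with `n_called`, genotype counts, allele
#'   frequencies `p` (allele1) and `q` (allele2), `major_allele` index, `maf`,
#'   `Ho`, `He`, `F_IS` and `hw_p`.
#' @examples
#' summarize_locus(rep(c(0, 1, 2), c(25, 50, 25)))  # perfect HWE, F_IS = 0
#' @export
summarize_locus <- function(calls_at_locus) {
  g <- genotype_table(matrix(as.integer(calls_at_locus), nrow = 1,
                             dimnames = list("L", NULL)),
                      data.frame(locus_id = "L", chrom = "1", pos = 1L,
                                 allele1 = "A", allele2 = "B"))
  summarize_loci(g)[, -(1:3)]
}

#' Per-locus summary statistics for a whole genotype table
#'
#' @param genotypes A [genotype_table()].
#' @param hw Compute the exact Hardy-Weinberg p-value (set `FALSE` to skip
#'   the most expensive column).
#' @return Data frame with one row per locus: `locus_id`, `chrom`, `pos`,
#'   `n_called`, `n_AA`, `n_AB`, `n_BB` (AA meaning homozygous allele1),
#'   `p`, `q`, `major_allele` (1 or 2), `maf`, `Ho`, `He`, `F_IS`, `hw_p`.
#' @export
summarize_loci <- function(genotypes, hw = TRUE) {
  calls <- genotypes$calls
  n0 <- rowSums(calls == 0L, na.rm = TRUE)
  n1 <- rowSums(calls == 1L, na.rm = TRUE)
  n2 <- rowSums(calls == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  if (any(n == 0)) {
    stop("locus with no called genotypes: ",
         genotypes$loci$locus_id[which(n == 0)[1]])
  }
  q <- (n1 + 2 * n2) / (2 * n)
  p <- 1 - q
  Ho <- n1 / n
  He <- 2 * p * q
  F_IS <- ifelse(He > 0, (He - Ho) / He, NA_real_)
  out <- data.frame(locus_id = genotypes$loci$locus_id,
                    chrom = genotypes$loci$chrom,
                    pos = genotypes$loci$pos,
                    n_called = n, n_AA = n0, n_AB = n1, n_BB = n2,
                    p = p, q = q,
                    major_allele = ifelse(q > 0.5, 2L, 1L),
                    maf = pmin(p, q), Ho = Ho, He = He, F_IS = F_IS,
                    stringsAsFactors = FALSE)
  if (hw) {
    # identical count triples share one exact-test evaluation
    key <- paste(n0, n1, n2)
    u <- !duplicated(key)
    pu <- hw_exact_p(n0[u], n1[u], n2[u])
    out$hw_p <- pu[match(key, key[u])]
  } else {
    out$hw_p <- NA_real_
  }
  rownames(out) <- NULL
  out
}

#' Dataset-level Mendelian error rates from component counts
#'
#' The mean error rate per locus is the number of loci carrying at least one
#' mismatch divided by the panel size; the mean error rate per allele is the
#' mismatch count divided by twice the number of replicated single-locus
#' genotypes (panel size times individuals).
#'
#' @param m_l Number of loci with at least one mismatch.
#' @param m_a Total number of allelic mismatches.
#' @param n_loci_total SNP panel size.
#' @param n_individuals Number of genotyped individuals.
#' @param n_unique Number of loci with mismatches in exactly one trio
#'   (optional).
#' @return List with `m_l`, `m_a`, `nt`, `e_l`, `e_a`, `unique_loci_count`
#'   and `unique_contribution` (unique loci / panel size).
#' @export
rate_summary <- function(m_l, m_a, n_loci_total, n_individuals,
                         n_unique = NA_integer_) {
  if (n_loci_total < 1 || n_individuals < 1) {
    stop("panel size and individual count must be positive")
  }
  nt <- as.numeric(n_loci_total) * n_individuals
  list(m_l = m_l, m_a = m_a, nt = nt,
       e_l = m_l / n_loci_total,
       e_a = m_a / (2 * nt),
       unique_loci_count = n_unique,
       unique_contribution = n_unique / n_loci_total)
}

#' Dataset-level Mendelian error rates for a scanned error set
#'
#' @param meset An `me_set` from [mendel_scan()].
#' @param n_loci_total,n_individuals Panel size and number of genotyped
#'   individuals; default to the totals recorded in the scan.
#' @return See [rate_summary()].
#' @export
error_rates <- function(meset, n_loci_total = meset$n_loci_scanned,
                        n_individuals = meset$n_individuals) {
  rate_summary(m_l = length(meset$loci), m_a = nrow(meset$events),
               n_loci_total = n_loci_total, n_individuals = n_individuals,
               n_unique = length(meset$unique_loci))
}
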