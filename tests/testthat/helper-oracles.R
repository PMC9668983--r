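# Independent oracles and small fixture builders shared across tests.

# Brute-force Mendelian consistency: try all four parental transmission
# combinations of explicit allele pairs.
oracle_trio_consistent <- function(f, m, c) {
  pair <- function(g) switch(g + 1L, c(1L, 1L), c(1L, 2L), c(2L, 2L))
  cf <- pair(f); cm <- pair(m); cc <- sort(pair(c))
  for (i in 1:2) {
    for (j in 1:2) {
      if (identical(sort(c(cf[i], cm[j])), cc)) return(TRUE)
    }
  }
  FALSE
}

# Exact Hardy-Weinberg p by explicit enumeration: every genotype
# configuration compatible with the observed allele count, weighted by its
# multinomial coefficient times 2^hets, computed directly from factorials.
oracle_hw_p <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  n_minor <- min(2 * n_AA + n_AB, 2 * n_BB + n_AB)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  w <- vapply(hets, function(h) {
    naa <- (n_minor - h) / 2
    nbb <- n - naa - h
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
          h * log(2))
  }, 0)
  pr <- w / sum(w)
  obs <- pr[match(n_AB, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Genotype table from an additive call matrix (loci x individuals).
make_genotypes <- function(calls, chrom = "1",
                           pos = seq_len(nrow(calls)) * 1000L) {
  n <- nrow(calls)
  loci <- data.frame(locus_id = sprintf("L%03d", seq_len(n)),
                     chrom = rep(chrom, length.out = n), pos = pos,
                     allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("i%02d", seq_len(ncol(calls)))
  }
  genotype_table(calls, loci)
}

# One-couple pedigree: f1 x m1 with the given offspring ids.
make_trio_pedigree <- function(offspring = "c1") {
  build_pedigree(data.frame(
    id = c("f1", "m1", offspring),
    sire = c(NA, NA, rep("f1", length(offspring))),
    dam = c(NA, NA, rep("m1", length(offspring))),
    sex = c("male", "female", rep("unknown", length(offspring))),
    stringsAsFactors = FALSE))
}

# Small, fast generator configuration for module tests.
small_sim_config <- function(seed = 42, ...) {
  defaults <- list(seed = seed, n_loci = 800L, n_boars = 6L, n_sows = 9L,
                   n_couples = 12L, cnv_n = 10L, adi_het_loci = 6L,
                   adi_hom_loci = 2L, sine_n_background = 20L,
                   line_n_background = 20L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}
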