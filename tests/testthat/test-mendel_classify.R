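# Trio inconsistency detection, eight-class assignment, dataset scanning and
# mismatch counting.

test_that("single-trio classification matches the documented examples", {
  # both parents fixed for the major allele, heterozygous child: Trio class,
  # minor allele violates
  r <- check_trio_locus(0, 0, 1, major_allele = 1)
  expect_equal(r$me_class, "TrioB")
  expect_equal(r$member, "Trio")
  expect_equal(r$violating_allele, 2L)

  # opposite homozygous child with both parents fixed: Offspring class
  r <- check_trio_locus(0, 0, 2, major_allele = 1)
  expect_equal(r$me_class, "OffspringB")

  # heterozygous parents can produce anything
  expect_equal(check_trio_locus(1, 1, 0, major_allele = 1), "consistent")

  # child homozygous minor with exactly the father fixed for the other allele
  r <- check_trio_locus(0, 1, 2, major_allele = 1)
  expect_equal(r$me_class, "FatherB")
  expect_equal(r$member, "Father")

  expect_error(check_trio_locus(NA, 0, 1), "non-missing")
})

test_that("decision table agrees with the brute-force transmission oracle", {
  grid <- expand.grid(f = 0:2, m = 0:2, c = 0:2)
  verdict <- mapply(function(f, m, c) {
    r <- check_trio_locus(f, m, c, major_allele = 1)
    if (identical(r, "consistent")) NA_character_ else r$me_class
  }, grid$f, grid$m, grid$c)
  oracle <- mapply(oracle_trio_consistent, grid$f, grid$m, grid$c)
  # exactly 12 of the 27 complete configurations are inconsistent, and the
  # classifier flags precisely those
  expect_equal(sum(!oracle), 12L)
  expect_equal(is.na(verdict), oracle)

  # allele-swap symmetry: relabelling alleles (g -> 2 - g, major -> other)
  # swaps A and B classes and keeps the member
  for (i in which(!oracle)) {
    a <- check_trio_locus(grid$f[i], grid$m[i], grid$c[i], major_allele = 1)
    b <- check_trio_locus(2 - grid$f[i], 2 - grid$m[i], 2 - grid$c[i],
                          major_allele = 2)
    expect_equal(a$member, b$member)
    expect_equal(a$freq_class, b$freq_class)
    # parent-swap symmetry: Father and Mother exchange, Trio/Offspring stay
    s <- check_trio_locus(grid$m[i], grid$f[i], grid$c[i], major_allele = 1)
    expected <- c(Trio = "Trio", Father = "Mother", Mother = "Father",
                  Offspring = "Offspring")[a$member]
    expect_equal(s$member, unname(expected))
  }

  # idempotence: re-checking an event's genotypes reproduces it
  for (i in which(!oracle)) {
    a <- check_trio_locus(grid$f[i], grid$m[i], grid$c[i], major_allele = 1)
    b <- check_trio_locus(grid$f[i], grid$m[i], grid$c[i], major_allele = 1)
    expect_identical(a, b)
  }
})

test_that("dataset scan finds events, skips missing calls and sorts output", {
  # one locus, one trio with (AA, AA, AB): one event, one (unique) locus
  calls <- matrix(c(0L, 0L, 1L), nrow = 1,
                  dimnames = list(NULL, c("f1", "m1", "c1")))
  g <- make_genotypes(calls)
  ped <- make_trio_pedigree("c1")
  tf <- extract_trios_and_families(ped, g)
  ms <- mendel_scan(g, tf$trios)
  expect_equal(nrow(ms$events), 1L)
  expect_equal(ms$loci, "L001")
  expect_equal(ms$unique_loci, "L001")
  expect_equal(as.character(ms$events$me_class), "TrioB")

  # missing member call: the locus is skipped for that trio
  calls2 <- matrix(c(0L, 0L, 1L, NA, 0L, 1L), nrow = 2, byrow = TRUE,
                   dimnames = list(NULL, c("f1", "m1", "c1")))
  ms2 <- mendel_scan(make_genotypes(calls2), tf$trios)
  expect_equal(nrow(ms2$events), 1L)

  # member absent from the genotype table is a structural error
  g3 <- make_genotypes(matrix(0L, 1, 2, dimnames = list(NULL, c("f1", "m1"))))
  expect_error(mendel_scan(g3, tf$trios), "absent from genotype table")

  # deterministic ordering: locus-major, then trio order
  ped4 <- make_trio_pedigree(c("c1", "c2"))
  g4 <- make_genotypes(matrix(c(0L, 0L, 1L, 1L,
                                0L, 0L, 1L, 1L), nrow = 2, byrow = TRUE,
                              dimnames = list(NULL,
                                              c("f1", "m1", "c1", "c2"))))
  tf4 <- extract_trios_and_families(ped4, g4)
  ms4 <- mendel_scan(g4, tf4$trios)
  expect_equal(ms4$events$locus_id, c("L001", "L001", "L002", "L002"))
  expect_equal(ms4$events$offspring_id, c("c1", "c2", "c1", "c2"))
  expect_equal(length(ms4$unique_loci), 0L)
})

test_that("clean gene-drop data contains zero Mendelian errors", {
  cfg <- small_sim_config(seed = 5)
  ped <- simulate_pedigree(cfg)
  tg <- gene_drop(ped$pedigree, cfg)
  ms <- mendel_scan(tg, ped$trios)
  expect_equal(nrow(ms$events), 0L)
  expect_equal(length(ms$loci), 0L)
})

test_that("mismatch counts are additive and correlate with family size", {
  # 2 families of sizes 1 and 3 with 5 events per trio
  ped <- build_pedigree(data.frame(
    id = c("b1", "b2", "s1", "s2", "k1", "k2", "k3", "k4"),
    sire = c(NA, NA, NA, NA, "b1", "b2", "b2", "b2"),
    dam = c(NA, NA, NA, NA, "s1", "s2", "s2", "s2"),
    sex = c("male", "male", "female", "female", rep("unknown", 4)),
    stringsAsFactors = FALSE))
  calls <- matrix(0L, 5, 8, dimnames = list(NULL, ped$id))
  calls[, c("k1", "k2", "k3", "k4")] <- 1L   # every child het at every locus
  g <- make_genotypes(calls)
  tf <- extract_trios_and_families(ped, g)
  ms <- mendel_scan(g, tf$trios)
  cnt <- mismatch_counts(ms, tf$trios, tf$families)
  expect_equal(sort(cnt$per_family$n_mismatches), c(5L, 15L))
  expect_equal(cnt$per_offspring$n_mismatches, rep(5L, 4))
  expect_equal(sum(cnt$per_class$n_mismatches), 20L)

  # empty error set: zero counts, undefined correlations
  g0 <- make_genotypes(matrix(0L, 5, 8, dimnames = list(NULL, ped$id)))
  ms0 <- mendel_scan(g0, tf$trios)
  cnt0 <- mismatch_counts(ms0, tf$trios, tf$families)
  expect_true(all(cnt0$per_family$n_mismatches == 0L))
  expect_true(all(is.na(cnt0$family_size_cor)))
})

test_that("systematic per-trio error rates give family counts that scale with size", {
  # Monte-Carlo: children corrupted to het at fixed rate at parent-fixed loci
  set.seed(31)
  n_fam <- 30
  sizes <- sample(1:10, n_fam, replace = TRUE)
  ids <- c(sprintf("b%02d", 1:n_fam), sprintf("s%02d", 1:n_fam))
  kid_ids <- unlist(lapply(1:n_fam, function(i) sprintf("k%02d_%d", i,
                                                        seq_len(sizes[i]))))
  ped <- build_pedigree(data.frame(
    id = c(ids, kid_ids),
    sire = c(rep(NA, 2 * n_fam), rep(sprintf("b%02d", 1:n_fam), sizes)),
    dam = c(rep(NA, 2 * n_fam), rep(sprintf("s%02d", 1:n_fam), sizes)),
    sex = c(rep(c("male", "female"), each = n_fam),
            rep("unknown", sum(sizes))), stringsAsFactors = FALSE))
  n_loci <- 200
  calls <- matrix(0L, n_loci, nrow(ped), dimnames = list(NULL, ped$id))
  kid_cols <- match(kid_ids, colnames(calls))
  err <- matrix(runif(n_loci * length(kid_cols)) < 0.05, n_loci)
  calls[, kid_cols][err] <- 1L
  g <- make_genotypes(calls)
  tf <- extract_trios_and_families(ped, g)
  ms <- mendel_scan(g, tf$trios)
  cnt <- mismatch_counts(ms, tf$trios, tf$families)
  # family count ~ rate x loci x size
  fit <- lm(n_mismatches ~ size, data = cnt$per_family)
  expect_gt(cnt$family_size_cor["pearson"], 0.5)
  expect_equal(unname(coef(fit)["size"]), 0.05 * n_loci, tolerance = 0.15)
})
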