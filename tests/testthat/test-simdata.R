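# Generator: pedigree structure, gene drop, error mechanisms, truth table.

test_that("configuration is validated", {
  expect_error(sim_config(n_boars = 2, n_sows = 2, n_couples = 5),
               "impossible design")
  expect_error(sim_config(base_error = 1.5), "probabilities")
  cfg <- small_sim_config()
  expect_s3_class(cfg, "sim_config")
})

test_that("pedigree simulation is deterministic and matches the design", {
  cfg <- small_sim_config(seed = 4)
  a <- simulate_pedigree(cfg)
  b <- simulate_pedigree(cfg)
  expect_identical(a, b)
  expect_false(identical(a$pedigree,
                         simulate_pedigree(small_sim_config(seed = 5))$pedigree))

  expect_equal(nrow(a$families), cfg$n_couples)
  expect_equal(sum(a$families$size), nrow(a$trios))
  # every trio offspring has both parents inside the pedigree
  expect_true(all(a$trios$father_id %in% a$pedigree$id))
  expect_true(all(a$trios$mother_id %in% a$pedigree$id))
  # family sizes within the configured range; litters within the cap
  expect_true(all(a$families$size >= cfg$family_size_range[1]))
  expect_true(all(a$families$size <= cfg$family_size_range[2]))
  expect_true(all(table(a$litters$litter_id) <= cfg$litter_size_max))
  # all offspring assigned to exactly one litter
  expect_setequal(a$litters$offspring_id, a$trios$offspring_id)
})

test_that("full-scale design reproduces the target family-size distribution", {
  cfg <- sim_config(seed = 8)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped$families), 61L)
  # mean offspring per family near 7.8 within sampling error of 61 draws
  expect_equal(mean(ped$families$size), 7.8,
               tolerance = 3 * 7 / sqrt(61) / 7.8)
})

test_that("gene drop is Mendelian-consistent with frequencies conserved", {
  cfg <- small_sim_config(seed = 6)
  ped <- simulate_pedigree(cfg)
  tg <- gene_drop(ped$pedigree, cfg)
  expect_identical(tg, gene_drop(ped$pedigree, cfg))

  # zero Mendelian errors by construction
  ms <- mendel_scan(tg, ped$trios)
  expect_equal(nrow(ms$events), 0L)

  # founders are in HWE: mean F_IS across loci near 0
  founders <- ped$pedigree$id[is.na(ped$pedigree$sire)]
  fg <- genotype_table(tg$calls[, founders, drop = FALSE], tg$loci)
  fs <- summarize_loci(fg, hw = FALSE)
  expect_lt(abs(mean(fs$F_IS, na.rm = TRUE)), 0.04)

  # offspring allele frequencies track founder frequencies
  q0 <- attr(tg, "founder_q")
  kids <- ped$trios$offspring_id
  qk <- rowMeans(tg$calls[, kids, drop = FALSE]) / 2
  dev <- qk - q0
  poly <- q0 > 0 & q0 < 1
  expect_lt(abs(mean(dev[poly])), 3 * sd(dev[poly]) / sqrt(sum(poly)))
})

test_that("error models build an exhaustive, exclusive truth table", {
  cfg <- small_sim_config(seed = 10)
  sim <- simulate_dataset(cfg)
  expect_identical(sim$truth, simulate_dataset(cfg)$truth)

  # one mechanism per discrepant cell
  key <- paste(sim$truth$locus_id, sim$truth$individual_id)
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(sim$truth$mechanism %in%
                    c("null", "cnv", "adi_het", "adi_hom", "base")))

  # every observed-vs-true difference outside null loci is recorded
  null_loci <- sim$locus_roles$locus_id[sim$locus_roles$role == "null"]
  tru <- sim$truth_genotypes$calls
  obs <- sim$genotypes$calls
  plain <- !(rownames(tru) %in% null_loci)
  differ <- which(plain & (tru != obs | is.na(tru) != is.na(obs)),
                  arr.ind = TRUE)
  got <- paste(rownames(tru)[differ[, 1]], colnames(tru)[differ[, 2]])
  expect_setequal(got, setdiff(key, paste(sim$truth$locus_id,
                                          sim$truth$individual_id)[
                                 sim$truth$mechanism == "null"]))

  # mechanisms act on their designated loci
  mech_by_locus <- tapply(sim$truth$mechanism, sim$truth$locus_id,
                          function(x) paste(sort(unique(x)), collapse = ","))
  roles <- sim$locus_roles
  adi_loci <- roles$locus_id[roles$role %in% c("adi_het", "adi_hom")]
  expect_true(all(mech_by_locus[adi_loci] == roles$role[match(adi_loci,
                                                              roles$locus_id)]))
  expect_true(all(mech_by_locus[intersect(names(mech_by_locus),
                                          null_loci)] == "null"))
})

test_that("null-allele observation model matches its closed form", {
  # pure hidden-null loci without partial dropout: expected called-het
  # proportion is 2pq / (1 - r^2) with p, q the visible allele frequencies
  cfg <- small_sim_config(seed = 15, null_frac = 1, null_d = 0,
                          n_loci = 300L, cnv_miscall = 0,
                          adi_het_loci = 0L, adi_hom_loci = 0L,
                          base_error = 0, founder_freq_range = c(0.3, 0.7))
  sim <- simulate_dataset(cfg)
  q0 <- attr(sim$truth_genotypes, "founder_q")
  r <- sim$locus_roles$null_r
  p <- (1 - r) * (1 - q0)
  q <- (1 - r) * q0
  expected <- 2 * p * q / (1 - r^2)
  obs <- sim$genotypes$calls
  het_prop <- rowSums(obs == 1L, na.rm = TRUE) / rowSums(!is.na(obs))
  dev <- het_prop - expected
  # Monte-Carlo check: mean deviation within 3 empirical standard errors
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(length(dev)))
})

test_that("CNV corruption stays inside carried segments", {
  cfg <- small_sim_config(seed = 19, null_frac = 0, adi_het_loci = 0L,
                          adi_hom_loci = 0L, base_error = 0,
                          cnv_miscall = 0.05)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$truth$mechanism == "cnv"))
  # corrupted cells lie at in_cnv loci and in carrier individuals
  expect_true(all(sim$truth$locus_id %in%
                    sim$locus_roles$locus_id[sim$locus_roles$in_cnv]))
  carriers <- unique(S4Vectors::mcols(sim$tracks$CNV)$carrier_id)
  expect_true(all(sim$truth$individual_id %in% carriers))
})

test_that("written simulated datasets audit end to end from disk", {
  cfg <- small_sim_config(seed = 23, n_loci = 300L)
  dir <- tempfile("simout")
  sim <- simulate_to_files(cfg, dir)
  expect_true(all(file.exists(file.path(dir, c("sim.ped", "sim.map",
                                               "cnv.bed", "sine.bed",
                                               "line.bed", "litters.tsv",
                                               "truth.tsv")))))
  back <- read_ped_map(file.path(dir, "sim.ped"), file.path(dir, "sim.map"))
  expect_equal(dim(back$genotypes$calls), dim(sim$genotypes$calls))
  # error scan agrees between the in-memory and on-disk representations
  tf1 <- extract_trios_and_families(sim$pedigree, sim$genotypes)
  tf2 <- extract_trios_and_families(back$pedigree, back$genotypes)
  ms1 <- mendel_scan(sim$genotypes, tf1$trios)
  ms2 <- mendel_scan(back$genotypes, tf2$trios)
  expect_equal(nrow(ms1$events), nrow(ms2$events))
  expect_equal(sort(ms1$loci), sort(ms2$loci))
  expect_equal(as.vector(table(ms1$events$me_class)),
               as.vector(table(ms2$events$me_class)))
})
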