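# Allele-drop-out / allele-drop-in classification and cross-tabulation.

# population with named groups of reproducers and offspring at one locus
drop_fixture <- function(repro_calls, off_calls) {
  ids <- c(sprintf("p%02d", seq_along(repro_calls)),
           sprintf("o%02d", seq_along(off_calls)))
  ped <- build_pedigree(data.frame(
    id = c(ids, "zz"),
    sire = c(rep(NA, length(repro_calls) + length(off_calls)), "p01"),
    dam = c(rep(NA, length(repro_calls) + length(off_calls)),
            sprintf("p%02d", length(repro_calls))),
    sex = c(rep(c("male", "female"), length.out = length(repro_calls)),
            rep("unknown", length(off_calls) + 1)),
    stringsAsFactors = FALSE))
  # every pXX individual a parent of zz would be wrong; instead mark all
  # repro ids as parents of synthetic offspring
  ped$is_reproductive <- ped$id %in% sprintf("p%02d", seq_along(repro_calls))
  calls <- matrix(c(repro_calls, off_calls, NA_integer_), nrow = 1,
                  dimnames = list(NULL, c(ids, "zz")))
  list(g = make_genotypes(calls), ped = ped)
}

test_that("literal drop definitions classify the documented patterns", {
  # both homozygote classes, no heterozygote, both alleles in reproducers
  fx <- drop_fixture(rep(c(0L, 2L), c(6, 2)), rep(c(0L, 2L), c(4, 2)))
  expect_equal(as.character(classify_allele_drop(fx$g, fx$ped)$drop), "ADO")

  # reproducers fixed, one heterozygous offspring
  fx <- drop_fixture(rep(0L, 8), c(rep(0L, 5), 1L))
  expect_equal(as.character(classify_allele_drop(fx$g, fx$ped)$drop),
               "ADI_het")

  # reproducers fixed, one opposite-homozygote offspring, no hets
  fx <- drop_fixture(rep(0L, 8), c(rep(0L, 5), 2L))
  expect_equal(as.character(classify_allele_drop(fx$g, fx$ped)$drop),
               "ADI_hom")

  # ordinary polymorphic locus
  fx <- drop_fixture(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L))
  expect_equal(as.character(classify_allele_drop(fx$g, fx$ped)$drop), "none")

  # heterozygous reproducer blocks every drop class
  fx <- drop_fixture(c(0L, 1L), c(0L, 2L))
  expect_equal(as.character(classify_allele_drop(fx$g, fx$ped)$drop), "none")

  # no called reproducer: none, with warning
  fx <- drop_fixture(c(NA_integer_, NA_integer_), c(0L, 1L))
  expect_warning(dr <- classify_allele_drop(fx$g, fx$ped),
                 "no called reproductive")
  expect_equal(as.character(dr$drop), "none")
})

test_that("classification is invariant to permutations within groups", {
  repro <- rep(c(0L, 2L), c(6, 2))
  off <- rep(c(0L, 2L), c(4, 2))
  base <- drop_fixture(repro, off)
  d0 <- as.character(classify_allele_drop(base$g, base$ped)$drop)
  set.seed(3)
  for (k in 1:5) {
    fx <- drop_fixture(sample(repro), sample(off))
    expect_equal(as.character(classify_allele_drop(fx$g, fx$ped)$drop), d0)
  }
})

test_that("drop patterns produce the expected error classes downstream", {
  # ADI_het pattern inside real trios: parents fixed AA, one child AB
  ped <- make_trio_pedigree(c("c1", "c2", "c3"))
  calls <- matrix(0L, 2, 5, dimnames = list(NULL,
                                            c("f1", "m1", "c1", "c2", "c3")))
  calls[1, "c2"] <- 1L   # ADI_het locus
  calls[2, "c3"] <- 2L   # ADI_hom locus
  g <- make_genotypes(calls)
  tf <- extract_trios_and_families(ped, g)
  ms <- mendel_scan(g, tf$trios)
  dr <- classify_allele_drop(g, ped, ms$loci)
  expect_equal(as.character(dr$drop[dr$locus_id == "L001"]), "ADI_het")
  expect_equal(as.character(dr$drop[dr$locus_id == "L002"]), "ADI_hom")
  expect_equal(as.character(ms$events$me_class[ms$events$locus_id == "L001"]),
               "TrioB")
  expect_equal(as.character(ms$events$me_class[ms$events$locus_id == "L002"]),
               "OffspringB")

  rep_tab <- drop_report(ms, dr)
  expect_equal(rep_tab$mismatches["TrioB", "ADI_het"], 1L)
  expect_equal(rep_tab$mismatches["OffspringB", "ADI_hom"], 1L)
  expect_equal(sum(rep_tab$mismatches), nrow(ms$events))
})

test_that("ADO loci imply F_IS = 1 and carry no Trio-class mismatches", {
  # family where parents carry both alleles as homozygotes and children are
  # homozygous: classic null-allele footprint
  ped <- build_pedigree(data.frame(
    id = c("f1", "m1", "c1", "c2"),
    sire = c(NA, NA, "f1", "f1"), dam = c(NA, NA, "m1", "m1"),
    sex = c("male", "female", "unknown", "unknown"),
    stringsAsFactors = FALSE))
  calls <- matrix(c(0L, 2L, 0L, 2L), nrow = 1,
                  dimnames = list(NULL, c("f1", "m1", "c1", "c2")))
  g <- make_genotypes(calls)
  tf <- extract_trios_and_families(ped, g)
  ms <- mendel_scan(g, tf$trios)
  expect_gt(nrow(ms$events), 0)
  expect_false(any(ms$events$member == "Trio"))
  s <- summarize_locus(calls[1, ])
  expect_equal(s$F_IS, 1)
  dr <- classify_allele_drop(g, ped, ms$loci)
  expect_equal(as.character(dr$drop), "ADO")
  rep_tab <- drop_report(ms, dr)
  expect_equal(sum(rep_tab$mismatches[c("TrioA", "TrioB"), "ADO"]), 0L)
})

test_that("empty error sets give empty cross-tabulations", {
  calls <- matrix(0L, 1, 3, dimnames = list(NULL, c("f1", "m1", "c1")))
  g <- make_genotypes(calls)
  tf <- extract_trios_and_families(make_trio_pedigree("c1"), g)
  ms <- mendel_scan(g, tf$trios)
  dr <- classify_allele_drop(g, make_trio_pedigree("c1"), character(0))
  rep_tab <- drop_report(ms, dr)
  expect_equal(sum(rep_tab$mismatches), 0L)
  expect_equal(sum(rep_tab$per_drop$n_loci), 0L)
})
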