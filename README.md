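# mendelaudit

Auditing Mendelian errors (ME) in SNP-array genotypes of parent–offspring
trios.

When a pedigree is reliable, genotype calls in which an offspring's alleles
cannot be explained by one allele from each parent are almost always calling
errors rather than de novo mutations, and they are not all of one kind:
null and partial-null alleles produce heterozygote-deficient loci whose
errors track one parent; copy-number variants (CNV) and interspersed
repeats (SINE/LINE) distort calls in single trio members; and a residual of
non-systematic miscalls remains. `mendelaudit` separates these signatures
for biallelic autosomal SNP panels typed in multi-family pedigrees
(livestock-style data: few reproducers, large variable families), and
quantifies what standard marker QC filters would do about them.

## What it computes

* **Eight-class ME classification.** Every inconsistent (trio, locus) pair
  is one mismatch, assigned to a member — *Father*, *Mother*, *Offspring*,
  or *Trio* when unassignable — crossed with the frequency class of the
  violating allele (*A* = locus major allele, *B* = minor):
  child heterozygous with both parents homozygous for one allele → Trio;
  child homozygous for *k* with exactly one parent homozygous for the other
  allele → that parent, allele *k*; with both parents opposite homozygous →
  Offspring.
* **Per-locus statistics.** MAF, observed heterozygosity Ho, expected
  heterozygosity He = 2pq, heterozygote deficiency
  F_IS = (He − Ho)/He, and the two-sided exact Hardy–Weinberg test on the
  heterozygote count.
* **Error rates** in the Pompanon framework: mean rate per locus
  e_l = m_l / n·t and per allele e_a = m_a / 2n·t, with m_l the loci
  carrying mismatches, m_a the mismatch count and n·t the number of
  replicated single-locus genotypes.
* **Allele-drop classes.** ADO (both homozygote classes, zero heterozygotes
  population-wide — the null-allele footprint, F_IS = 1), ADI_het and
  ADI_hom (spurious heterozygous / opposite-homozygous offspring calls on a
  background fixed in all reproducers).
* **Genomic-feature overlap.** Locus- and carrier-aware intersection of the
  ME set with CNV/SINE/LINE BED tracks, summarised as class × feature
  contingency tables.
* **Filter trade-offs.** For any grid of MAF / HW-p / F_IS thresholds, the
  number of SNPs lost versus mismatches removed.
* **A synthetic-data generator** — multi-family pedigree, gene-drop
  transmission, and parameterised null-allele, CNV, allele-drop-in and
  baseline error mechanisms with a per-cell truth table — so every stage is
  testable without external data.

## Worked example

```r
library(mendelaudit)

cfg <- sim_config(seed = 11, n_loci = 5000)   # 61 families, ~490 individuals
sim <- simulate_dataset(cfg)
tf  <- extract_trios_and_families(sim$pedigree, sim$genotypes)
ls  <- summarize_loci(sim$genotypes)
ms  <- mendel_scan(sim$genotypes, tf$trios, major = ls$major_allele)
ms
#> me_set: 11468 mismatches at 340 loci (188 unique) over 442 trios and 5000 loci scanned
#>
#>      TrioA      TrioB    FatherA    FatherB    MotherA    MotherB OffspringA
#>        177        668       2499       2292       2622       2343        228
#> OffspringB
#>        639

er <- error_rates(ms)
#> e_l = 0.0680   e_a = 0.00236   unique contribution = 0.0376

scenario_grid(ls, ms)[, c(1:3, 6:7)]
#>              scenario snps_removed snps_removed_frac mismatches_removed mismatches_removed_frac
#> 1            FIS>=0.2          138            0.0276              10980                  0.9574
#> 2          HW<=0.0001          238            0.0476              10979                  0.9574
#> 3           HW<=0.001          399            0.0798              11030                  0.9618
#> 4 MAF<=0.05+HW<=0.001          597            0.1194              11127                  0.9703
#> 5           MAF<=0.05          210            0.0420                261                  0.0228
```

Reading the output: most mismatches sit in the parental classes — the
signature of the simulated null alleles — and the heterozygote-deficiency
filter (F_IS ≥ 0.2) removes 96% of all mismatches at the cost of only 2.8%
of the panel, while the MAF filter removes eight times as many SNPs per
mismatch. `classify_allele_drop()` recovers the injected allele-drop-in
loci exactly (41 ADI_het, 5 ADI_hom in this run), and
`class_feature_table()` shows the Trio-class errors concentrating inside
the emitted CNV track.

File-based pipelines use `run_audit()` (PED/MAP + BED tracks in, TSV/JSON
report bundle out) and `simulate_to_files()` to generate those inputs.

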