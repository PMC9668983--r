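---
title: "Auditing Mendelian errors in SNP-array trio data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing Mendelian errors in SNP-array trio data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mendelaudit)
```

## The problem

In a genotyped pedigree with verified parentage, a Mendelian error (ME) — a
trio genotype in which the offspring's two alleles cannot be formed by one
allele from each parent — is, with overwhelming probability, a genotype
calling error: de novo mutation rates (~1e-8 per site) are orders of
magnitude below observed ME rates on SNP arrays. ME are therefore a window
into *why* calls go wrong. This package implements an audit that separates
three broad causes and measures what marker-based QC would do about each:

1. **Null and partial-null alleles** — variants that produce no (or a weak)
   probe signal, so heterozygotes are called homozygous for the visible
   allele. They leave a locus-level footprint: heterozygote deficiency
   (positive F_IS), Hardy–Weinberg departures, and mismatches that follow a
   specific parent.
2. **Genomic alterations** — CNV, SINEs and LINEs distort hybridisation
   intensity in individual carriers, producing spurious alleles in single
   trio members.
3. **Non-systematic miscalls** — a thin background with no locus- or
   family-level pattern.

## The classification model

Calls are additive codes (copies of the second allele) at biallelic
autosomal SNPs. Of the 27 complete trio configurations, 12 are
inconsistent. Each inconsistent (trio, locus) pair is **one mismatch**, and
its origin is assigned from the parental genotypes alone:

| pattern | member | violating allele |
|---|---|---|
| child heterozygous, both parents homozygous for the same allele | Trio (unassignable) | the allele absent from the parents |
| child homozygous for *k*, exactly one parent homozygous for the other allele | that parent | *k* |
| child homozygous for *k*, both parents homozygous for the other allele | Offspring | *k* |

Crossing the member with the frequency class of the violating allele
(A = locus major allele, B = minor; frequencies over all called genotypes,
ties resolved to the first map allele) yields the eight classes TrioA …
OffspringB. The table is the unique total assignment consistent with the
drop-in signatures below (a spurious heterozygote on a fixed parental
background must be unassignable; a spurious opposite homozygote must
implicate the offspring); the suite verifies it exhaustively against a
brute-force transmission checker, together with its allele-swap and
parent-swap symmetries.

Counting one mismatch per inconsistent trio-locus (rather than per
unexplainable allele) makes per-individual means reproduce
dataset-total / trio-count arithmetic exactly. Trios with a missing call at
a locus are skipped there; no imputation is attempted. Scanning is
deterministic (locus-major order) — the module draws no random numbers.

## Locus statistics

Allele frequencies come from all called genotypes (reproducers and
offspring). He = 2pq deliberately omits the small-sample correction: with
the correction, a locus with both homozygote classes and zero heterozygotes
would not give F_IS = (He − Ho)/He exactly 1, and that exact value is the
allele-drop-out signature the audit keys on. F_IS is reported missing (not
0) for monomorphic loci, where 0/0 is undefined.

The Hardy–Weinberg test is the exact conditional test on the heterozygote
count: given the sample size and minor-allele count, the two-sided p sums
the conditional probabilities of all heterozygote counts no more likely
than the observed one (no mid-p). The implementation walks the probability
ratio recurrence between adjacent heterozygote counts; the tests recompute
every p for n ≤ 50 by explicit enumeration of genotype configurations from
factorial ratios — an independent route to the same distribution.

Dataset-level rates follow the per-locus / per-allele convention:
e_l = m_l/(panel size) and e_a = m_a/(2 · panel size · individuals). Note
that e_l here uses the panel size as the denominator (loci × 1), not the
full genotype count; this matches the reporting convention of the summary
tables this audit emulates rather than the stricter per-genotype reading of
the same symbol in the error-rate literature.

## Allele-drop classes

Evaluated on called genotypes only, with reproducers defined structurally
(any individual with at least one offspring in the pedigree):

* **ADO**: zero heterozygotes population-wide, both homozygote classes
  present, and the reproducers *not* all fixed for one allele.
* **ADI_het**: all called reproducers homozygous for one allele, at least
  one non-reproducing individual heterozygous.
* **ADI_hom**: all called reproducers homozygous for one allele, at least
  one non-reproducing individual homozygous for the other.

The third ADO condition is this package's disambiguation of otherwise
overlapping literal definitions: a locus fixed in reproducers whose only
variation is an opposite-homozygote offspring satisfies the bare ADO wording
(no hets, both homozygote classes) *and* the ADI_hom wording, and under an
ADO-first precedence ADI_hom could never occur. Requiring both alleles among
reproducers restricts ADO to loci where a null allele demonstrably
segregates through the pedigree — which is also the only reading under which
the three classes have the distinct empirical profiles (moderate-MAF ADO
versus very-low-MAF ADI) reported for real arrays. Precedence
ADO > ADI_het > ADI_hom is kept for any residual pathological input.

Two consequences are checked as invariants: ADO forces F_IS = 1 exactly,
and ADO loci can never carry Trio-class mismatches (those need a
heterozygous offspring).

## Interval overlap

SNPs are single-bp points; BED tracks are 0-based half-open on disk and
converted to 1-based closed `GRanges` on read, so a SNP at position p
overlaps a BED record (start, end] iff start < p ≤ end. No flanking window
is added and intervals are never merged: a locus inside two features counts
once per feature column, and the `none` column plus the feature union
partitions the ME set. Carrier-aware overlap (CNV calls per individual)
restricts matches to events whose trio contains the carrier; class tables
default to locus-level overlap.

## Filter evaluation

A SNP is removed when it fails **any** enabled criterion: MAF ≤ maf_max,
exact-HW p ≤ hw_p_max, or F_IS ≥ fis_min (the ≤ readings are used for the
two thresholds whose conventional description mixes "lower than" and "≤"; both
are configurable). Loci with undefined F_IS are never removed by the F_IS
criterion. Removal is monotone in every threshold and the combined scenario
is the set union of its components — both properties are tested. The
default grid is MAF 0.05, HW 0.001 and 0.0001, F_IS 0.2, and MAF + HW.

## The generator

`sim_config()` defaults encode the study conditions the audit targets:
15 founder boars and 28 sows forming 61 couples; offspring per couple
`1 + NegBin(mu = 6.8, size = 1.1)` truncated to [1, 34] (mean ≈ 7.8, the
long right tail giving the few very large families that drive family-size
covariation); a 15% chance per couple of first recruiting a born offspring
into the breeding pool (multi-generation structure); litters of mean 5
capped at 12; 20,000 SNPs on 18 autosomes; founder frequencies uniform on
[0.05, 0.95]. The negative-binomial shape and the recruitment rate are the
two structural values not fixed by the emulated design; they were chosen
once to give the target mean, range and a realistic minority of
second-generation parents, and are exposed as parameters.

Gene drop is standard: founders in Hardy–Weinberg proportions, each
offspring one uniform allele per parent, loci independent (no linkage map —
positions only matter for interval overlap). Error mechanisms are applied
to disjoint targets, in a fixed order, so the truth table attributes every
discrepancy to exactly one mechanism:

* **Null alleles** (2% of loci; r ~ U(0.2, 0.35); d = 0.5): a hidden third
  allele redrawn through the pedigree. Visible/null heterozygotes are
  called homozygous for the visible allele, null homozygotes are missing,
  and visible/visible heterozygotes drop one allele with probability d.
  With d = 0 the called-heterozygote proportion has the closed form
  2pq/(1 − r²) (p, q the visible-allele frequencies), which the tests check
  against simulation within 3 Monte-Carlo standard errors; the implied
  locus-level deficiency is F_IS ≈ 2r/(1 + r), comfortably above the 0.2
  filter threshold for the default r. With d = 1 no heterozygote survives
  and the locus presents the full ADO pattern.
* **CNV** (60 segments of 1–6 Mb, 3% carrier probability, 2% per-SNP
  miscall in carriers): corruption is copy-number-faithful rather than a
  uniform relabeling — duplications add a spurious second allele
  (homozygote → heterozygote), heterozygous deletions drop one allele
  (heterozygote → random homozygote), homozygous deletions give missing
  calls, with the duplication-dominated mix (76/17/7%) reported by
  intensity-based CNV callers on this kind of array. This choice is what
  makes CNV errors concentrate in the Trio classes, as observed in real
  data: a uniform random relabeling would spread them across the parental
  classes in expectation (working through the 27-configuration table over a
  uniform frequency spectrum puts more mass on parental + offspring classes
  than on Trio).
* **Allele-drop-in** (40 het + 5 hom loci, monomorphic in founders, 1–3
  injected offspring each): the minimal generative model of the two ADI
  definitions; recovery must be exact (TrioB and OffspringB respectively),
  and is tested as such.
* **Base errors** (1e-4 per genotype): uniform flips on cells untouched by
  the mechanisms above.

SINE/LINE tracks are emitted as fixed BED annotations co-located with 30% /
40% of CNV-segment loci plus random background intervals, so the
class × feature table can show the repeat/CNV covariation without
simulating hybridisation chemistry.

What the generator does *not* emulate: intensity-level (LRR/BAF) structure,
linkage and recombination, inbreeding or selection, batch effects, and
platform-specific cluster-calling artefacts. Passing recovery tests
therefore demonstrates that the audit's inference logic is correct under
its own mechanism models, not that those models exhaust real array error
processes.

## Reproducibility and numerical choices

One configuration seed; each generator stage re-seeds with a fixed offset
(seed, +1, +2) with a documented draw order, so stages are individually and
jointly bit-reproducible. Major-allele ties at frequency 0.5 resolve to the
first map allele. The exact-test recurrence is normalised from the most
heterozygous configuration and compares probabilities with a 1e-10 relative
guard when summing the two-sided tail. Monomorphic loci: HW p = 1, F_IS
missing. Family-size correlations are reported missing below three families
or under zero variance.

Problem sizes used by the checks: the recovery analysis runs the full
default design (20,000 loci, 61 families, ~490 individuals — the scale the
defaults emulate); module tests use 200–800 loci and ~12 couples, large
enough for every mechanism to appear while keeping the suite quick.

## Known limitations

* Duos (one genotyped parent) are not scanned; the audit requires full
  trios.
* The eight-class table is a reconstruction from the drop-in signatures,
  not a table taken from any genotyping tool; alternative member attributions exist for
  software that zeroes out errors rather than classifying them.
* e_l inherits the summary-table convention described above.
* Carrier-aware CNV overlap is available but class tables use locus-level
  overlap, so a locus counts as CNV-covered even for trios outside the
  carrier's family.
* The ADO refinement (reproducers must carry both alleles) makes the
  classes disjoint at the cost of relabelling as ADI any true null allele
  that happens to be absent from every reproducer — rare in pedigrees where
  reproducers are many, but possible.
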