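# Synthetic pedigree + genotype generator with parameterised error
# mechanisms and a per-cell truth table.
#
# Reproducibility: one seed in the configuration; each stage
# (simulate_pedigree, gene_drop, apply_error_models) re-seeds with a fixed
# stage offset (seed, seed + 1, seed + 2) so stages are individually
# deterministic and the composed pipeline is bit-reproducible. Draw order
# within each stage is fixed and documented in the function bodies.

#' Simulation configuration
#'
#' Defaults emulate a livestock multi-family SNP-array design: a few dozen
#' reproducers, 61 couples with highly variable family size (range 1-34,
#' mean about 7.8 offspring), some offspring recruited as parents of later
#' litters, and an observation layer with null/partial-null alleles,
#' CNV-segment miscalls, rare allele-drop-in events and a baseline miscall
#' rate.
#'
#' @param seed Integer seed; makes every run bit-reproducible.
#' @param n_boars,n_sows,n_couples Founder males/females and number of
#'   parental couples (families).
#' @param family_size_range,family_size_mean,family_size_shape Offspring per
#'   couple: `1 + NegBin(mu = mean - 1, size = shape)` truncated to the range.
#' @param recruit_prob Probability, per couple formed, of first recruiting a
#'   previously born offspring into the breeding pool (multi-generation
#'   pedigree).
#' @param litter_size_mean,litter_size_max Litter chunking of each family's
#'   offspring.
#' @param n_loci,n_chrom,chrom_length SNP panel size, autosome count and
#'   autosome length in bp (positions are uniform per chromosome).
#' @param founder_freq_range Founder allele2 frequency drawn uniformly from
#'   this range at ordinary loci.
#' @param null_frac Fraction of loci carrying a hidden null allele.
#' @param null_r Range of the null-allele frequency r (uniform per locus).
#' @param null_d Partial-null dropout probability: a visible heterozygote at
#'   a null locus loses one allele (is called homozygous) with this
#'   probability.
#' @param cnv_n,cnv_length,cnv_kind_probs,carrier_frac,cnv_miscall CNV
#'   segments: count, length range (bp), mix of duplication / heterozygous /
#'   homozygous deletion, per-individual carrier probability per segment, and
#'   per-SNP miscall probability inside a carried segment.
#' @param adi_het_loci,adi_hom_loci,adi_carriers Allele-drop-in injections:
#'   number of loci (monomorphic in the founders) receiving spurious
#'   heterozygous / opposite-homozygous offspring calls, and the range of
#'   injected offspring per locus.
#' @param base_error Per-genotype random miscall probability at loci not
#'   governed by another mechanism.
#' @param sine_cnv_frac,line_cnv_frac,sine_n_background,line_n_background
#'   SINE/LINE track construction: fraction of CNV-segment loci co-located
#'   with a repeat interval, plus random background intervals.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_boars = 15L, n_sows = 28L, n_couples = 61L,
                       family_size_range = c(1L, 34L),
                       family_size_mean = 7.8, family_size_shape = 1.1,
                       recruit_prob = 0.15,
                       litter_size_mean = 5, litter_size_max = 12L,
                       n_loci = 20000L, n_chrom = 18L, chrom_length = 1.4e8,
                       founder_freq_range = c(0.05, 0.95),
                       null_frac = 0.02, null_r = c(0.2, 0.35), null_d = 0.5,
                       cnv_n = 60L, cnv_length = c(1e6, 6e6),
                       cnv_kind_probs = c(duplication = 0.763,
                                          het_deletion = 0.165,
                                          hom_deletion = 0.072),
                       carrier_frac = 0.03, cnv_miscall = 0.02,
                       adi_het_loci = 40L, adi_hom_loci = 5L,
                       adi_carriers = c(1L, 3L),
                       base_error = 1e-4,
                       sine_cnv_frac = 0.3, line_cnv_frac = 0.4,
                       sine_n_background = 200L, line_n_background = 300L) {
  cfg <- as.list(environment())
  probs <- c(null_frac, null_d, recruit_prob, carrier_frac, cnv_miscall,
             base_error, sine_cnv_frac, line_cnv_frac, null_r)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_couples > n_boars * n_sows) {
    stop("impossible design: more couples than distinct boar x sow pairs")
  }
  if (family_size_range[1] < 1) stop("family sizes must be >= 1")
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-family pedigree with litters
#'
#' Founder boars and sows are paired into couples; each couple's offspring
#' count is drawn from the configured distribution and chunked into litters.
#' Before forming each couple, a previously born offspring may be recruited
#' into the breeding pool, yielding a multi-generation pedigree.
#'
#' @param config A [sim_config()].
#' @return List with `pedigree` ([build_pedigree()] output), `litters`
#'   (offspring_id, litter_id), `trios` and `families`
#'   (as in [extract_trios_and_families()]).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  boars <- sprintf("b%02d", seq_len(config$n_boars))
  sows <- sprintf("s%02d", seq_len(config$n_sows))
  ped <- data.frame(id = c(boars, sows), sire = NA_character_,
                    dam = NA_character_,
                    sex = rep(c("male", "female"),
                              c(config$n_boars, config$n_sows)),
                    stringsAsFactors = FALSE)
  boar_pool <- boars
  sow_pool <- sows
  used_pairs <- character(0)
  litters <- list()
  n_off <- 0L
  for (i in seq_len(config$n_couples)) {
    # 1) optional recruitment of an earlier offspring into the pool
    if (n_off > 0 && runif(1) < config$recruit_prob) {
      born <- ped$id[!is.na(ped$sire)]
      cand <- born[!(born %in% c(boar_pool, sow_pool))]
      if (length(cand)) {
        pick <- sample(cand, 1)
        if (ped$sex[match(pick, ped$id)] == "male") {
          boar_pool <- c(boar_pool, pick)
        } else {
          sow_pool <- c(sow_pool, pick)
        }
      }
    }
    # 2) draw a not-yet-used couple
    for (try in 1:1000) {
      b <- sample(boar_pool, 1)
      s <- sample(sow_pool, 1)
      key <- paste(b, s, sep = "x")
      if (!key %in% used_pairs) break
    }
    if (key %in% used_pairs) stop("could not draw a fresh parental couple")
    used_pairs <- c(used_pairs, key)
    # 3) family size and offspring
    size <- 1L + rnbinom(1, size = config$family_size_shape,
                         mu = config$family_size_mean - 1)
    size <- max(config$family_size_range[1],
                min(config$family_size_range[2], size))
    kids <- sprintf("o%04d", n_off + seq_len(size))
    n_off <- n_off + size
    ped <- rbind(ped, data.frame(id = kids, sire = b, dam = s,
                                 sex = sample(c("male", "female"), size,
                                              replace = TRUE),
                                 stringsAsFactors = FALSE))
    # 4) chunk into litters
    left <- size
    j <- 0L
    at <- 1L
    while (left > 0) {
      j <- j + 1L
      ls <- min(left, config$litter_size_max,
                1L + rpois(1, config$litter_size_mean - 1))
      litters[[length(litters) + 1L]] <- data.frame(
        offspring_id = kids[at:(at + ls - 1L)],
        litter_id = sprintf("%s_L%d", key, j), stringsAsFactors = FALSE)
      at <- at + ls
      left <- left - ls
    }
  }
  pedigree <- build_pedigree(ped)
  litters <- do.call(rbind, litters)
  tf <- extract_trios_and_families(pedigree, litters = litters)
  list(pedigree = pedigree, litters = litters, trios = tf$trios,
       families = tf$families)
}

# sample() without the scalar-expansion surprise on length-1 integer vectors
.sample_vec <- function(x, k) x[sample.int(length(x), k)]

# Locus map, founder frequencies and mechanism roles. Draw order: positions,
# founder frequencies, null subset, null r, ADI subsets.
.sim_loci <- function(config) {
  n <- config$n_loci
  per_chrom <- diff(round(seq(0, n, length.out = config$n_chrom + 1)))
  chrom <- rep(as.character(seq_len(config$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k)
    sort(sample.int(config$chrom_length, k))))
  loci <- data.frame(locus_id = sprintf("snp%05d", seq_len(n)),
                     chrom = chrom, pos = as.integer(pos),
                     allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)
  q0 <- runif(n, config$founder_freq_range[1], config$founder_freq_range[2])
  role <- rep("none", n)
  n_null <- round(config$null_frac * n)
  pool <- seq_len(n)
  null_idx <- sort(.sample_vec(pool, n_null))
  role[null_idx] <- "null"
  null_r <- rep(NA_real_, n)
  null_r[null_idx] <- runif(n_null, config$null_r[1], config$null_r[2])
  pool <- setdiff(pool, null_idx)
  adi_het_idx <- sort(.sample_vec(pool, config$adi_het_loci))
  role[adi_het_idx] <- "adi_het"
  pool <- setdiff(pool, adi_het_idx)
  adi_hom_idx <- sort(.sample_vec(pool, config$adi_hom_loci))
  role[adi_hom_idx] <- "adi_hom"
  q0[role %in% c("adi_het", "adi_hom")] <- 0  # monomorphic in founders
  list(loci = loci, q0 = q0, role = role, null_r = null_r)
}

#' Gene-drop simulation of true genotypes down a pedigree
#'
#' Founder genotypes are sampled in Hardy-Weinberg proportions from per-locus
#' founder frequencies; every offspring receives one uniformly chosen allele
#' from each parent. The output contains zero Mendelian errors by
#' construction. Locus mechanism roles (null / allele-drop-in / none) and
#' founder frequencies are attached as attributes for
#' [apply_error_models()].
#'
#' @param pedigree A pedigree in parents-before-offspring order
#'   ([build_pedigree()] output, e.g. from [simulate_pedigree()]).
#' @param config A [sim_config()].
#' @return A [genotype_table()] of true genotypes with attributes
#'   `founder_q`, `locus_roles` and `sim_config`.
#' @export
gene_drop <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  sl <- .sim_loci(config)
  n <- config$n_loci
  ids <- pedigree$id
  calls <- matrix(NA_integer_, n, length(ids),
                  dimnames = list(sl$loci$locus_id, ids))
  inherit <- function(g) (g == 2L) + (g == 1L) * rbinom(n, 1L, 0.5)
  for (j in seq_along(ids)) {
    if (is.na(pedigree$sire[j])) {          # founder
      calls[, j] <- rbinom(n, 2L, sl$q0)
    } else {
      fa <- match(pedigree$sire[j], ids)
      mo <- match(pedigree$dam[j], ids)
      calls[, j] <- as.integer(inherit(calls[, fa]) + inherit(calls[, mo]))
    }
  }
  g <- genotype_table(calls, sl$loci)
  attr(g, "founder_q") <- sl$q0
  attr(g, "locus_roles") <- data.frame(locus_id = sl$loci$locus_id,
                                       role = sl$role, null_r = sl$null_r,
                                       stringsAsFactors = FALSE)
  attr(g, "sim_config") <- config
  g
}

# Allele-level three-allele gene drop at null loci. Codes: 0 = allele1,
# 1 = allele2, 2 = null. Returns two allele matrices (loci x individuals).
.null_allele_drop <- function(pedigree, q0, r) {
  nn <- length(q0)
  ids <- pedigree$id
  p_vis <- (1 - r) * (1 - q0)
  q_vis <- (1 - r) * q0
  A <- matrix(NA_integer_, nn, length(ids), dimnames = list(NULL, ids))
  B <- A
  draw <- function() {
    u <- runif(nn)
    ifelse(u < p_vis, 0L, ifelse(u < p_vis + q_vis, 1L, 2L))
  }
  for (j in seq_along(ids)) {
    if (is.na(pedigree$sire[j])) {
      A[, j] <- draw()
      B[, j] <- draw()
    } else {
      fa <- match(pedigree$sire[j], ids)
      mo <- match(pedigree$dam[j], ids)
      pick <- rbinom(nn, 1L, 0.5)
      A[, j] <- ifelse(pick == 1L, A[, fa], B[, fa])
      pick <- rbinom(nn, 1L, 0.5)
      B[, j] <- ifelse(pick == 1L, A[, mo], B[, mo])
    }
  }
  list(A = A, B = B)
}

#' Apply the observation-layer error models to true genotypes
#'
#' Four mechanisms, applied in a fixed order to disjoint targets so that
#' every observed-vs-true discrepancy is attributed to exactly one
#' mechanism:
#'
#' 1. **Null alleles** (per-locus): a hidden third allele at frequency `r`
#'    segregates through the pedigree; visible/null heterozygotes are called
#'    homozygous for the visible allele, null/null genotypes become missing,
#'    and visible/visible heterozygotes lose one allele (partial null) with
#'    probability `d`.
#' 2. **CNV segments** (per carrier cell): inside a carried segment each SNP
#'    call is corrupted with probability `cnv_miscall`; duplications add a
#'    spurious second allele (homozygote -> heterozygote), heterozygous
#'    deletions drop one allele (heterozygote -> random homozygote),
#'    homozygous deletions give a missing call.
#' 3. **Allele-drop-in** (per-locus): at loci monomorphic in the founders,
#'    one to a few offspring receive a call carrying a novel minor allele
#'    (heterozygous for `adi_het` loci, opposite-homozygous for `adi_hom`).
#' 4. **Base errors**: remaining cells at unaffected loci flip to a uniformly
#'    chosen different call with probability `base_error`.
#'
#' @param true_genotypes Output of [gene_drop()] (attributes required).
#' @param pedigree The pedigree used for the gene drop.
#' @param config The same [sim_config()].
#' @return List with `genotypes` (observed [genotype_table()]), `truth`
#'   (per-cell data frame: locus_id, individual_id, true, observed,
#'   mechanism), `locus_roles` (per-locus mechanism labels, null r, CNV
#'   co-location flag), `tracks` (list of `GRanges`: CNV with carrier ids,
#'   SINE, LINE) and `cnv_segments` (data frame of the generated segments).
#' @export
apply_error_models <- function(true_genotypes, pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  roles <- attr(true_genotypes, "locus_roles")
  q0 <- attr(true_genotypes, "founder_q")
  if (is.null(roles) || is.null(q0)) {
    stop("true_genotypes must come from gene_drop() (attributes missing)")
  }
  set.seed(config$seed + 2L)
  loci <- true_genotypes$loci
  obs <- true_genotypes$calls
  n <- nrow(obs)
  ids <- colnames(obs)
  touched <- matrix(FALSE, n, length(ids))
  cells <- list()
  note <- function(locus_idx, ind_idx, true, observed, mech) {
    cells[[length(cells) + 1L]] <<- data.frame(
      locus_id = loci$locus_id[locus_idx], individual_id = ids[ind_idx],
      true = true, observed = observed, mechanism = mech,
      stringsAsFactors = FALSE)
  }

  ## 1. null alleles: three-allele redraw down the pedigree
  null_idx <- which(roles$role == "null")
  if (length(null_idx)) {
    nd <- .null_allele_drop(pedigree, q0[null_idx], roles$null_r[null_idx])
    A <- nd$A[, ids, drop = FALSE]
    B <- nd$B[, ids, drop = FALSE]
    n_null_alleles <- (A == 2L) + (B == 2L)
    vis_sum <- ifelse(A == 2L, 0L, A) + ifelse(B == 2L, 0L, B)
    call_new <- matrix(NA_integer_, length(null_idx), length(ids))
    # both alleles visible
    i2 <- n_null_alleles == 0L
    call_new[i2] <- (A + B)[i2]
    # partial-null dropout in visible heterozygotes
    het <- i2 & (A + B) == 1L
    dropm <- het & matrix(rbinom(length(het), 1L, config$null_d) == 1L,
                          nrow(het))
    kept <- matrix(rbinom(length(het), 1L, 0.5), nrow(het))  # kept allele
    call_new[dropm] <- 2L * ifelse(kept[dropm] == 1L, A[dropm], B[dropm])
    # one null allele: called homozygous for the visible allele
    i1 <- n_null_alleles == 1L
    call_new[i1] <- 2L * vis_sum[i1]
    # null homozygote: missing call
    obs[null_idx, ] <- call_new
    touched[null_idx, ] <- TRUE
    a1m <- matrix(loci$allele1[null_idx], nrow(A), ncol(A))
    a2m <- matrix(loci$allele2[null_idx], nrow(A), ncol(A))
    labA <- ifelse(A == 2L, "N", ifelse(A == 1L, a2m, a1m))
    labB <- ifelse(B == 2L, "N", ifelse(B == 1L, a2m, a1m))
    true_lab <- matrix(paste(labA, labB, sep = "/"), nrow(A))
    diff <- which(n_null_alleles > 0L | dropm, arr.ind = TRUE)
    if (nrow(diff)) {
      note(null_idx[diff[, 1]], diff[, 2], true_lab[diff],
           as.character(call_new[diff]), "null")
    }
  }

  ## 2. CNV segments, carriers and per-cell corruption
  seg_chrom <- sample(as.character(seq_len(config$n_chrom)), config$cnv_n,
                      replace = TRUE)
  seg_len <- round(runif(config$cnv_n, config$cnv_length[1],
                         config$cnv_length[2]))
  seg_start <- vapply(seg_len, function(L)
    sample.int(max(1, config$chrom_length - L), 1), 1L)
  seg_kind <- sample(names(config$cnv_kind_probs), config$cnv_n,
                     replace = TRUE,
                     prob = config$cnv_kind_probs / sum(config$cnv_kind_probs))
  carrier_list <- lapply(seq_len(config$cnv_n), function(s) {
    carriers <- ids[runif(length(ids)) < config$carrier_frac]
    if (!length(carriers)) carriers <- sample(ids, 1)
    carriers
  })
  cnv_loci <- rep(FALSE, n)
  for (s in seq_len(config$cnv_n)) {
    in_seg <- which(loci$chrom == seg_chrom[s] &
                    loci$pos > seg_start[s] &
                    loci$pos <= seg_start[s] + seg_len[s] &
                    roles$role == "none")
    if (!length(in_seg)) next
    cnv_loci[in_seg] <- TRUE
    for (cid in carrier_list[[s]]) {
      jj <- match(cid, ids)
      hit <- in_seg[runif(length(in_seg)) < config$cnv_miscall]
      hit <- hit[!touched[hit, jj] & !is.na(obs[hit, jj])]
      if (!length(hit)) next
      old <- obs[hit, jj]
      new <- old
      if (seg_kind[s] == "duplication") {
        new[old != 1L] <- 1L                       # spurious second allele
      } else if (seg_kind[s] == "het_deletion") {
        is_het <- old == 1L
        new[is_het] <- 2L * rbinom(sum(is_het), 1L, 0.5)
      } else {                                     # hom_deletion
        new[] <- NA_integer_
      }
      changed <- which(new != old | (is.na(new) & !is.na(old)))
      if (length(changed)) {
        obs[hit[changed], jj] <- new[changed]
        touched[hit[changed], jj] <- TRUE
        note(hit[changed], rep(jj, length(changed)),
             as.character(old[changed]), as.character(new[changed]), "cnv")
      }
    }
  }
  cnv_segments <- data.frame(chrom = seg_chrom, start = seg_start,
                             end = seg_start + seg_len, kind = seg_kind,
                             n_carriers = lengths(carrier_list),
                             stringsAsFactors = FALSE)

  ## 3. allele-drop-in injections into non-reproductive offspring
  off_ids <- pedigree$id[!pedigree$is_reproductive]
  off_ids <- intersect(off_ids, ids)
  for (kind in c("adi_het", "adi_hom")) {
    for (l in which(roles$role == kind)) {
      k <- sample(seq(config$adi_carriers[1], config$adi_carriers[2]), 1)
      who <- sample(off_ids, min(k, length(off_ids)))
      jj <- match(who, ids)
      newcall <- if (kind == "adi_het") 1L else 2L
      note(rep(l, length(jj)), jj, as.character(obs[l, jj]),
           as.character(newcall), kind)
      obs[l, jj] <- newcall
      touched[l, jj] <- TRUE
    }
    touched[roles$role == kind, ] <- TRUE   # shield from base errors
  }

  ## 4. baseline random miscalls on untouched cells
  eligible <- which(!touched & !is.na(obs))
  n_hits <- rbinom(1, length(eligible), config$base_error)
  if (n_hits > 0) {
    hit <- .sample_vec(eligible, n_hits)
    old <- obs[hit]
    shift <- sample(1:2, n_hits, replace = TRUE)
    new <- (old + shift) %% 3L
    obs[hit] <- as.integer(new)
    li <- (hit - 1L) %% n + 1L
    jj <- (hit - 1L) %/% n + 1L
    note(li, jj, as.character(old), as.character(new), "base")
  }

  ## tracks: per-carrier CNV BED, SINE/LINE co-located with CNV loci
  cnv_gr <- GenomicRanges::GRanges(
    rep(seg_chrom, lengths(carrier_list)),
    IRanges::IRanges(start = rep(seg_start + 1, lengths(carrier_list)),
                     end = rep(seg_start + seg_len, lengths(carrier_list))),
    kind = rep(seg_kind, lengths(carrier_list)),
    carrier_id = unlist(carrier_list))
  S4Vectors::metadata(cnv_gr)$track_name <- "CNV"
  mk_repeat <- function(frac, n_bg, up, down, nm) {
    host <- which(cnv_loci)
    host <- host[runif(length(host)) < frac]
    bg_chrom <- sample(as.character(seq_len(config$n_chrom)), n_bg,
                       replace = TRUE)
    bg_pos <- sample.int(config$chrom_length - down - 1, n_bg)
    gr <- GenomicRanges::GRanges(
      c(loci$chrom[host], bg_chrom),
      IRanges::IRanges(start = pmax(1, c(loci$pos[host], bg_pos) - up),
                       end = c(loci$pos[host], bg_pos) + down),
      kind = nm, carrier_id = NA_character_)
    S4Vectors::metadata(gr)$track_name <- nm
    gr
  }
  sine_gr <- mk_repeat(config$sine_cnv_frac, config$sine_n_background,
                       75, 75, "SINE")
  line_gr <- mk_repeat(config$line_cnv_frac, config$line_n_background,
                       500, 2500, "LINE")

  truth <- if (length(cells)) do.call(rbind, cells) else
    data.frame(locus_id = character(0), individual_id = character(0),
               true = character(0), observed = character(0),
               mechanism = character(0), stringsAsFactors = FALSE)
  roles$in_cnv <- cnv_loci
  list(genotypes = genotype_table(obs, loci), truth = truth,
       locus_roles = roles,
       tracks = list(CNV = cnv_gr, SINE = sine_gr, LINE = line_gr),
       cnv_segments = cnv_segments)
}

#' Run the full generator: pedigree, gene drop and error models
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset`: `config`, `pedigree`, `litters`,
#'   `trios`, `families`, `truth_genotypes` (error-free gene-drop table),
#'   `genotypes` (observed), `truth` (per-cell discrepancy table),
#'   `locus_roles`, `tracks` and `cnv_segments`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  tg <- gene_drop(ped$pedigree, config)
  em <- apply_error_models(tg, ped$pedigree, config)
  structure(c(list(config = config), ped,
              list(truth_genotypes = tg, genotypes = em$genotypes,
                   truth = em$truth, locus_roles = em$locus_roles,
                   tracks = em$tracks, cnv_segments = em$cnv_segments)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset: ", nrow(x$pedigree), " individuals, ",
      nrow(x$trios), " trios in ", nrow(x$families), " families, ",
      nrow(x$genotypes$calls), " loci\n", sep = "")
  print(table(x$locus_roles$role))
  invisible(x)
}

#' Write a simulated dataset to disk in the standard formats
#'
#' Emits `sim.ped` / `sim.map`, one BED per track (`cnv.bed`, `sine.bed`,
#' `line.bed`), `litters.tsv`, the per-cell `truth.tsv` and per-locus
#' `locus_roles.tsv`.
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_ped_map(sim$genotypes, sim$pedigree, p("sim.ped"), p("sim.map"))
  write_bed_track(sim$tracks$CNV, p("cnv.bed"))
  write_bed_track(sim$tracks$SINE, p("sine.bed"))
  write_bed_track(sim$tracks$LINE, p("line.bed"))
  write.table(sim$litters, p("litters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$locus_roles, p("locus_roles.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(setNames(
    p(c("sim.ped", "sim.map", "cnv.bed", "sine.bed", "line.bed",
        "litters.tsv", "truth.tsv", "locus_roles.tsv")),
    c("ped", "map", "cnv", "sine", "line", "litters", "truth",
      "locus_roles")))
}

#' Simulate and write in one step
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return The `sim_dataset`, invisibly; files are written to `dir`.
#' @export
simulate_to_files <- function(config = sim_config(), dir) {
  sim <- simulate_dataset(config)
  write_sim_dataset(sim, dir)
  invisible(sim)
}
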