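# Synthetic amplicon data with the statistical structure the genotyping
# cascade assumes: a pool of 247-bp and 244-bp (3-bp deletion) exon-3-like
# alleles with elevated nonsynonymous diversity at PBR codons, multi-locus
# genotypes, overdispersed per-amplicon depths, PCR substitution artefacts,
# PCR chimeras, and technical duplicates -- plus full truth bookkeeping.

# Alignment frame: the amplicon's first complete codon sits at amino-acid
# position 93 of the domain alignment; long fragments cover codons 93-173
# (81 codons) flanked by a 2-nt incomplete codon at each end (247 nt).
# Short alleles lack the codon at position 147 (244 nt).
AA_FRAME_START <- 93L
AA_FRAME_END <- 173L

#' Exon-3 peptide-binding residue (PBR) masks
#'
#' Alignment amino-acid positions of the peptide-binding residues used to
#' partition codons for dN/dS. `dnds` is the 12-codon set used in the
#' selection analysis, `full` the complete exon-3 PBR set including peptide
#' main-chain contacts, and `exon2` the alpha-1 domain set for reference.
#'
#' @param which One of "dnds", "full", "exon2".
#' @return Integer vector of alignment positions.
#' @export
pbr_mask <- function(which = c("dnds", "full", "exon2")) {
  which <- match.arg(which)
  switch(which,
    dnds = c(96L, 98L, 112L, 114L, 121L, 149L, 151L, 154L, 155L, 159L,
             162L, 166L),
    full = c(96L, 98L, 112L, 114L, 121L, 141L, 144L, 145L, 149L, 151L,
             154L, 155L, 158L, 159L, 162L, 166L, 170L),
    exon2 = c(5L, 7L, 9L, 24L, 25L, 34L, 43L, 58L, 62L, 65L, 66L, 68L,
              69L, 72L, 73L, 75L, 76L, 79L, 80L, 83L))
}

#' Simulation configuration
#'
#' Defaults mirror the study conditions the pipeline is designed for: 38
#' long (247 nt) and 9 short (244 nt) alleles, 84 individuals with 1-4 MHC-I
#' loci each, per-amplicon depths around 11000 reads, and 6 technical
#' duplicate pairs.
#'
#' @param n_long_alleles,n_short_alleles Pool sizes per length class.
#' @param deletion_codon Alignment amino-acid position deleted in short
#'   alleles (default 147).
#' @param n_individuals Number of genotyped individuals.
#' @param loci_range Two integers in [1, 4]: range of locus counts drawn
#'   uniformly per individual.
#' @param depth_mean Mean per-amplicon read depth.
#' @param depth_dispersion Negative-binomial size parameter; smaller means
#'   more overdispersion.
#' @param pcr_error_rate Per-read probability of a 1-2 bp substitution
#'   artefact.
#' @param chimera_rate Per-read probability of a PCR chimera.
#' @param amplification_bias_sd Log-scale SD of per-amplicon, per-allele
#'   multiplicative amplification bias.
#' @param n_duplicate_pairs Number of individuals sequenced twice.
#' @param seed Master seed; every substream derives from it.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_long_alleles = 38L, n_short_alleles = 9L,
                              deletion_codon = 147L, n_individuals = 84L,
                              loci_range = c(1L, 4L), depth_mean = 11000,
                              depth_dispersion = 12, pcr_error_rate = 0.02,
                              chimera_rate = 0.003,
                              amplification_bias_sd = 0.3,
                              n_duplicate_pairs = 6L, seed = 1L) {
  cfg <- list(n_long_alleles = as.integer(n_long_alleles),
              n_short_alleles = as.integer(n_short_alleles),
              deletion_codon = as.integer(deletion_codon),
              n_individuals = as.integer(n_individuals),
              loci_range = as.integer(loci_range),
              depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              pcr_error_rate = pcr_error_rate,
              chimera_rate = chimera_rate,
              amplification_bias_sd = amplification_bias_sd,
              n_duplicate_pairs = as.integer(n_duplicate_pairs),
              seed = as.integer(seed))
  stopifnot(cfg$n_long_alleles >= 0, cfg$n_short_alleles >= 0,
            cfg$n_individuals >= 0, cfg$depth_mean > 0,
            cfg$depth_dispersion > 0,
            cfg$pcr_error_rate >= 0, cfg$pcr_error_rate <= 1,
            cfg$chimera_rate >= 0, cfg$chimera_rate <= 1,
            cfg$amplification_bias_sd >= 0,
            length(cfg$loci_range) == 2L,
            cfg$loci_range[1] >= 1L, cfg$loci_range[2] <= 4L,
            cfg$loci_range[1] <= cfg$loci_range[2],
            cfg$n_duplicate_pairs <= cfg$n_individuals)
  class(cfg) <- "simulation_config"
  cfg
}

# Derive a reproducible substream seed from the master seed.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483629)
}

# Pick a sense codon encoding a different amino acid (nonsynonymous) or the
# same one (synonymous) by random single/double substitutions.
random_codon_variant <- function(codon, synonymous) {
  aa0 <- codon_aa(codon)
  cand <- sense_codons()
  cand <- cand[cand != codon]
  aa <- codon_aa(cand)
  cand <- if (synonymous) cand[aa == aa0] else cand[aa != aa0]
  if (length(cand) == 0L) return(NULL)
  sample(cand, 1L)
}

#' Generate a synthetic allele pool
#'
#' Builds `n_long_alleles` 247-nt and `n_short_alleles` 244-nt sequences,
#' translatable without stop codons in the declared frame (2-nt incomplete
#' codon at each end). Polymorphism is concentrated at the 12-codon PBR
#' mask, drawn from per-position codon repertoires whose alternatives are
#' mostly nonsynonymous; a sparse set of non-PBR positions carries mostly
#' synonymous low-level polymorphism. Long alleles carry the "EDGTV" motif
#' at positions 147-151, short alleles "GENE" at 148-151, and all alleles a
#' tyrosine at 170. Pool-level guarantees needed for identifiable
#' genotyping: all alleles pairwise distinct, same-length alleles at
#' Hamming distance >= 3, and no allele an exact breakpoint splice of two
#' others of its length class.
#'
#' @param cfg A `simulation_config`.
#' @return List with `alleles` (named character vector), `length_class`
#'   (named "long"/"short"), `pbr` (the dN/dS mask), `aa_start`.
#' @export
generate_allele_pool <- function(cfg = simulation_config()) {
  set.seed(substream_seed(cfg$seed, 1L))
  n_codons <- AA_FRAME_END - AA_FRAME_START + 1L
  positions <- AA_FRAME_START:AA_FRAME_END
  base <- sample(sense_codons(), n_codons, replace = TRUE)
  names(base) <- positions
  # class-diagnostic motifs and the conserved main-chain tyrosine
  motif_codon <- c(E = "GAA", D = "GAT", G = "GGA", T = "ACA", V = "GTA",
                   N = "AAC", Y = "TAT")
  base[as.character(147:151)] <- motif_codon[c("E", "D", "G", "T", "V")]
  base["170"] <- motif_codon["Y"]
  short_base <- base
  short_base[as.character(148:151)] <- motif_codon[c("G", "E", "N", "E")]

  pbr <- pbr_mask("dnds")
  poly_pbr <- setdiff(pbr, 147:151)  # keep motif region invariant per class
  rep_sizes <- 3L
  repertoire <- lapply(poly_pbr, function(p) {
    alt <- character(0)
    while (length(alt) < rep_sizes) {
      v <- random_codon_variant(base[as.character(p)], synonymous = FALSE)
      if (!is.null(v) && !(v %in% alt)) alt <- c(alt, v)
    }
    c(base[[as.character(p)]], alt)
  })
  names(repertoire) <- as.character(poly_pbr)
  nonpbr_all <- setdiff(positions, c(pbr, 147:151, 170))
  poly_nonpbr <- sort(sample(nonpbr_all, min(10L, length(nonpbr_all))))
  rep_nonpbr <- lapply(poly_nonpbr, function(p) {
    syn <- stats::runif(1) < 0.7
    v <- random_codon_variant(base[as.character(p)], synonymous = syn)
    if (is.null(v))
      v <- random_codon_variant(base[as.character(p)], synonymous = !syn)
    c(base[[as.character(p)]], v)
  })
  names(rep_nonpbr) <- as.character(poly_nonpbr)

  draw_allele <- function(class_base, drop147) {
    cod <- class_base
    for (p in names(repertoire))
      cod[p] <- sample(repertoire[[p]], 1L, prob = c(0.45, rep(0.55 / rep_sizes,
                                                               rep_sizes)))
    for (p in names(rep_nonpbr))
      cod[p] <- sample(rep_nonpbr[[p]], 1L, prob = c(0.85, 0.15))
    if (drop147) cod <- cod[names(cod) != as.character(cfg$deletion_codon)]
    paste0("CA", paste(cod, collapse = ""), "GG")
  }

  n_total <- cfg$n_long_alleles + cfg$n_short_alleles
  if (n_total == 0L) stop("generation error: empty pool requested")
  alleles <- character(0); classes <- character(0)
  want <- c(rep("long", cfg$n_long_alleles), rep("short", cfg$n_short_alleles))
  for (cls in want) {
    ok <- FALSE
    for (try in 1:500) {
      cand <- draw_allele(if (cls == "long") base else short_base,
                          drop147 = (cls == "short"))
      same <- alleles[classes == cls]
      if (cand %in% alleles) next
      if (length(same) && min(vapply(same, seq_hamming, numeric(1),
                                     b = cand)) < 3) next
      ok <- TRUE
      break
    }
    if (!ok) stop("generation error: could not draw a distinct allele ",
                  "(requested pool too large for the polymorphism settings)")
    alleles <- c(alleles, cand); classes <- c(classes, cls)
  }

  # break exact splice relations with private synonymous substitutions so no
  # true allele can masquerade as a chimera of two others
  invariant <- setdiff(positions, c(poly_pbr, poly_nonpbr,
                                    147:151, 170, cfg$deletion_codon))
  guard <- 0L
  repeat {
    off <- splice_offenders(alleles, classes)
    if (length(off) == 0L || guard > 5L * n_total) break
    guard <- guard + 1L
    i <- off[1]
    pos <- sample(invariant, 1L)
    a <- alleles[i]
    idx <- codon_nt_offset(pos, classes[i] == "short", cfg$deletion_codon)
    cod <- substr(a, idx, idx + 2L)
    v <- random_codon_variant(cod, synonymous = TRUE)
    if (is.null(v)) v <- random_codon_variant(cod, synonymous = FALSE)
    substr(a, idx, idx + 2L) <- v
    if (a %in% alleles) next
    alleles[i] <- a
  }
  if (length(splice_offenders(alleles, classes)))
    stop("generation error: could not remove splice-ambiguous alleles")

  names(alleles) <- sprintf("SIM%02d", seq_along(alleles))
  names(classes) <- names(alleles)
  list(alleles = alleles, length_class = classes, pbr = pbr,
       aa_start = AA_FRAME_START)
}

# 1-based nt offset of the codon at alignment position `pos` inside a
# fragment with 2-nt overhang (long: codons 93..173; short lacks 147).
codon_nt_offset <- function(pos, short, deletion_codon = 147L) {
  k <- pos - AA_FRAME_START  # 0-based codon index in the long frame
  if (short) {
    if (pos == deletion_codon) return(NA_integer_)
    if (pos > deletion_codon) k <- k - 1L
  }
  3L + 3L * k
}

# Indices of alleles that equal prefix(A)+suffix(B) of two other same-length
# alleles at some breakpoint.
splice_offenders <- function(alleles, classes) {
  off <- integer(0)
  for (cls in unique(classes)) {
    idx <- which(classes == cls)
    if (length(idx) < 3L) next
    seqs <- alleles[idx]
    len <- nchar(seqs[1])
    n <- length(seqs)
    lcp <- matrix(0L, n, n); lcs <- matrix(0L, n, n)
    for (i in 1:n) for (j in 1:n) if (i != j) {
      lcp[i, j] <- seq_lcp(seqs[i], seqs[j])
      lcs[i, j] <- seq_lcs(seqs[i], seqs[j])
    }
    for (t in 1:n) {
      found <- FALSE
      for (a in setdiff(1:n, t)) {
        if (found) break
        for (b in setdiff(1:n, c(t, a))) {
          lo <- max(1L, len - lcs[t, b]); hi <- min(lcp[t, a], len - 1L)
          if (lo <= hi) { found <- TRUE; break }
        }
      }
      if (found) off <- c(off, idx[t])
    }
  }
  off
}

#' Simulate multi-locus genotypes
#'
#' Each individual draws a locus count uniformly from `loci_range`, then two
#' allele draws per locus with replacement from the pool under a fixed set
#' of population allele frequencies (symmetric Dirichlet, giving a
#' common-to-rare spread). Technical duplicate individuals get two amplicons
#' referencing the same genotype.
#'
#' @param pool Output of [generate_allele_pool()].
#' @param cfg A `simulation_config`.
#' @return A truth list: `genotypes` (individual -> allele ids), `dosage`
#'   (individual -> named allele copy counts), `freqs` (population allele
#'   frequencies), `amplicons` (data frame amplicon_id, individual_id,
#'   duplicate_group).
#' @export
simulate_genotypes <- function(pool, cfg = simulation_config()) {
  if (length(pool$alleles) == 0L) stop("empty allele pool")
  set.seed(substream_seed(cfg$seed, 2L))
  ids <- sprintf("ind%03d", seq_len(cfg$n_individuals))
  freqs <- stats::rgamma(length(pool$alleles), shape = 1)
  freqs <- freqs / sum(freqs)
  names(freqs) <- names(pool$alleles)
  dosage <- lapply(ids, function(ind) {
    loci <- sample(seq(cfg$loci_range[1], cfg$loci_range[2]), 1L)
    draws <- sample(names(pool$alleles), 2L * loci, replace = TRUE,
                    prob = freqs)
    tab <- table(draws)
    stats::setNames(as.integer(tab), names(tab))
  })
  names(dosage) <- ids
  genotypes <- lapply(dosage, names)
  dup_inds <- if (cfg$n_duplicate_pairs > 0L)
    sample(ids, cfg$n_duplicate_pairs) else character(0)
  rows <- lapply(ids, function(ind) {
    if (ind %in% dup_inds)
      data.frame(amplicon_id = paste0(ind, c(".1", ".2")),
                 individual_id = ind, duplicate_group = ind,
                 stringsAsFactors = FALSE)
    else
      data.frame(amplicon_id = paste0(ind, ".1"), individual_id = ind,
                 duplicate_group = "", stringsAsFactors = FALSE)
  })
  list(genotypes = genotypes, dosage = dosage, freqs = freqs,
       amplicons = do.call(rbind, rows))
}

# Apply nmut random substitutions to a sequence.
mutate_read <- function(seq, nmut) {
  len <- nchar(seq)
  pos <- sample.int(len, nmut)
  for (p in pos) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(BASES, cur), 1L)
  }
  seq
}

#' Simulate amplicon read sets
#'
#' Per amplicon: depth is negative-binomial around `depth_mean`; clean reads
#' are multinomial over the individual's alleles with dosage times lognormal
#' amplification bias as weights; with `pcr_error_rate` a read instead
#' carries 1-2 random substitutions from a parent allele (never indels);
#' with `chimera_rate` a read is a prefix/suffix splice of two distinct
#' equal-length alleles at a uniform breakpoint. A chimera drawn for an
#' individual without two equal-length alleles falls back to a 2-substitution
#' error read, recorded as such. Duplicate amplicons are independent redraws
#' from the same genotype.
#'
#' @param truth Output of [simulate_genotypes()].
#' @param pool Output of [generate_allele_pool()].
#' @param cfg A `simulation_config`.
#' @return List with `amplicons` (an `amplicon_set`) and `origins`: one data
#'   frame per amplicon with columns sequence, depth, origin (allele |
#'   artefact | chimera | chimera_fallback), parent, parent2, breakpoint.
#' @export
simulate_amplicons <- function(truth, pool, cfg = simulation_config()) {
  tallies <- vector("list", nrow(truth$amplicons))
  origins <- vector("list", nrow(truth$amplicons))
  for (i in seq_len(nrow(truth$amplicons))) {
    row <- truth$amplicons[i, ]
    set.seed(substream_seed(cfg$seed, 100L + i))
    dos <- truth$dosage[[row$individual_id]]
    seqs <- pool$alleles[names(dos)]
    lens <- nchar(seqs)
    depth <- max(1L, stats::rnbinom(1L, mu = cfg$depth_mean,
                                    size = cfg$depth_dispersion))
    w <- dos * exp(stats::rnorm(length(dos), 0, cfg$amplification_bias_sd))
    n_chim <- stats::rbinom(1L, depth, cfg$chimera_rate)
    n_err <- stats::rbinom(1L, depth - n_chim, cfg$pcr_error_rate)
    n_clean <- depth - n_chim - n_err
    clean <- as.integer(stats::rmultinom(1L, n_clean, w))
    org <- data.frame(sequence = unname(seqs), depth = clean,
                      origin = "allele", parent = names(dos),
                      parent2 = NA_character_, breakpoint = NA_integer_,
                      stringsAsFactors = FALSE)
    if (n_err > 0L) {
      parents <- sample(names(dos), n_err, replace = TRUE, prob = w)
      nmut <- sample(1:2, n_err, replace = TRUE, prob = c(0.7, 0.3))
      reads <- vapply(seq_len(n_err), function(k)
        mutate_read(seqs[[parents[k]]], nmut[k]), character(1))
      org <- rbind(org, aggregate_origin(reads, "artefact", parents))
    }
    if (n_chim > 0L) {
      ca <- sample(names(dos), n_chim, replace = TRUE, prob = w)
      reads <- character(n_chim); typ <- character(n_chim)
      p2 <- rep(NA_character_, n_chim); bp <- rep(NA_integer_, n_chim)
      for (k in seq_len(n_chim)) {
        mates <- names(dos)[lens == lens[[ca[k]]] & names(dos) != ca[k]]
        if (length(mates) == 0L) {
          reads[k] <- mutate_read(seqs[[ca[k]]], 2L)
          typ[k] <- "chimera_fallback"
        } else {
          mate <- if (length(mates) == 1L) mates else
            sample(mates, 1L, prob = w[mates])
          len <- lens[[ca[k]]]
          brk <- sample.int(len - 1L, 1L)
          reads[k] <- paste0(substr(seqs[[ca[k]]], 1L, brk),
                             substr(seqs[[mate]], brk + 1L, len))
          typ[k] <- "chimera"; p2[k] <- mate; bp[k] <- brk
        }
      }
      df <- data.frame(sequence = reads, depth = 1L, origin = typ,
                       parent = ca,
                       parent2 = ifelse(is.na(p2), "", p2),
                       breakpoint = ifelse(is.na(bp), -1L, bp),
                       stringsAsFactors = FALSE)
      agg <- stats::aggregate(depth ~ sequence + origin + parent + parent2 +
                                breakpoint, df, sum)
      agg$parent2[agg$parent2 == ""] <- NA_character_
      agg$breakpoint[agg$breakpoint == -1L] <- NA_integer_
      org <- rbind(org, agg[, names(org)])
    }
    org <- org[org$depth > 0L, , drop = FALSE]
    tally <- stats::aggregate(depth ~ sequence, org, sum)
    tallies[[i]] <- list(amplicon_id = row$amplicon_id,
                         individual_id = row$individual_id,
                         duplicate_group = row$duplicate_group,
                         variants = tally)
    origins[[i]] <- org
  }
  names(origins) <- truth$amplicons$amplicon_id
  list(amplicons = amplicon_set_from_tallies(tallies), origins = origins)
}

aggregate_origin <- function(reads, origin, parents) {
  df <- data.frame(sequence = reads, parent = parents, depth = 1L,
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(depth ~ sequence + parent, df, sum)
  data.frame(sequence = agg$sequence, depth = agg$depth, origin = origin,
             parent = agg$parent, parent2 = NA_character_,
             breakpoint = NA_integer_, stringsAsFactors = FALSE)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper chaining [generate_allele_pool()],
#' [simulate_genotypes()] and [simulate_amplicons()].
#'
#' @param cfg A `simulation_config`.
#' @return An object of class `mhc_simulation` with elements `pool`,
#'   `truth`, `amplicons`, `origins`, `config`.
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  pool <- generate_allele_pool(cfg)
  truth <- simulate_genotypes(pool, cfg)
  amp <- simulate_amplicons(truth, pool, cfg)
  structure(list(pool = pool, truth = truth, amplicons = amp$amplicons,
                 origins = amp$origins, config = cfg),
            class = "mhc_simulation")
}

#' Write a simulated dataset to disk
#'
#' Writes one FASTA of reads per amplicon (each read an individual record),
#' a sample sheet TSV, the allele pool FASTA, and truth tables (genotypes
#' and per-amplicon read origins) as TSV. Intended for small configurations;
#' in-memory hand-off via the returned `amplicon_set` is the native path.
#'
#' @param sim An `mhc_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the sample sheet path.
#' @export
write_simulated_reads <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet <- sim$truth$amplicons
  sheet$reads_path <- paste0(sheet$amplicon_id, ".fasta")
  for (i in seq_along(sim$origins)) {
    org <- sim$origins[[i]]
    reads <- rep(org$sequence, org$depth)
    names(reads) <- sprintf("r%06d", seq_along(reads))
    write_fasta(reads, file.path(dir, sheet$reads_path[i]))
  }
  write_fasta(sim$pool$alleles, file.path(dir, "allele_pool.fasta"))
  geno <- do.call(rbind, lapply(names(sim$truth$genotypes), function(ind)
    if (length(sim$truth$genotypes[[ind]]))
      data.frame(individual_id = ind, allele = sim$truth$genotypes[[ind]],
                 stringsAsFactors = FALSE)))
  utils::write.table(geno, file.path(dir, "truth_genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  org_all <- do.call(rbind, lapply(names(sim$origins), function(a) {
    d <- sim$origins[[a]]; d$amplicon_id <- a; d
  }))
  utils::write.table(org_all, file.path(dir, "truth_origins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(sheet_path)
}
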