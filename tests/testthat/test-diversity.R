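# Diversity and divergence statistics against independent oracles: naive
# recomputation for S and pi, the closed-form Kimura formula and ape's
# implementation for distances, hand-enumerated pathway counts for
# Nei-Gojobori.

test_that("segregating sites match an exhaustive column scan", {
  expect_equal(segregating_sites(c(a = "AAAA", b = "AAAA")), 0L)
  expect_equal(segregating_sites(c(a = "AAAA", b = "ACGT")), 3L)
  set.seed(5)
  for (r in 1:10) {
    seqs <- vapply(1:6, function(i) random_nt(40), character(1))
    # sprinkle gaps
    for (i in seq_along(seqs))
      for (p in sample(40, 3)) substr(seqs[i], p, p) <- "-"
    names(seqs) <- paste0("s", 1:6)
    expect_equal(segregating_sites(seqs), oracle_segregating(seqs))
  }
  expect_error(segregating_sites(c(a = "AAAA")), "at least 2")
})

test_that("nucleotide diversity equals naive double-loop recomputation", {
  expect_equal(nucleotide_diversity(c(a = "AAAA", b = "AAAA")), 0)
  two <- c(a = "AAAAAAAAAA", b = "AAAAAAAAAC")
  expect_equal(nucleotide_diversity(two), 0.1)
  set.seed(6)
  for (r in 1:10) {
    seqs <- stats::setNames(vapply(1:5, function(i) random_nt(60),
                                   character(1)), paste0("s", 1:5))
    expect_equal(nucleotide_diversity(seqs), oracle_pi(seqs))
  }
})

test_that("K2P matches the closed form and ape's implementation", {
  # construct P = 0.1, Q = 0.05 exactly over 100 sites
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  expect_equal(pairwise_distance(a, b, "p"), 0.15)
  expect_equal(pairwise_distance(a, b, "k2p"), oracle_k2p(0.1, 0.05))
  expect_equal(pairwise_distance(a, b, "k2p", gamma_alpha = 1),
               oracle_k2p(0.1, 0.05, alpha = 1))
  expect_equal(pairwise_distance(a, a, "p"), 0)
  expect_equal(pairwise_distance(a, a, "k2p"), 0)
  set.seed(7)
  for (r in 1:10) {
    x <- random_nt(300)
    y <- x
    for (p in sample(300, 25))
      substr(y, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(y, p, p)), 1)
    bin <- ape::as.DNAbin(list(x = strsplit(tolower(x), "")[[1]],
                               y = strsplit(tolower(y), "")[[1]]))
    expect_equal(pairwise_distance(x, y, "k2p"),
                 as.numeric(ape::dist.dna(bin, model = "K80")),
                 tolerance = 1e-12)
    expect_equal(pairwise_distance(x, y, "k2p", gamma_alpha = 1),
                 as.numeric(ape::dist.dna(bin, model = "K80", gamma = 1)),
                 tolerance = 1e-12)
    expect_equal(pairwise_distance(x, y, "p"),
                 as.numeric(ape::dist.dna(bin, model = "raw")),
                 tolerance = 1e-12)
  }
})

test_that("p <= K2P <= K2P(gamma=1) wherever defined", {
  set.seed(8)
  for (r in 1:20) {
    x <- random_nt(200)
    y <- x
    for (p in sample(200, sample(5:40, 1)))
      substr(y, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(y, p, p)), 1)
    p0 <- pairwise_distance(x, y, "p")
    k <- pairwise_distance(x, y, "k2p")
    kg <- pairwise_distance(x, y, "k2p", gamma_alpha = 1)
    expect_lte(p0, k + 1e-12)
    expect_lte(k, kg + 1e-12)
  }
})

test_that("mean divergence is reorder-invariant; SE shrinks on replication", {
  set.seed(9)
  seqs <- stats::setNames(vapply(1:6, function(i) random_nt(90),
                                 character(1)), paste0("s", 1:6))
  base <- seqs[[1]]
  for (i in 2:6) {
    s <- base
    for (p in sample(90, 8))
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    seqs[[i]] <- s
  }
  d1 <- mean_divergence(seqs, "k2p", gamma_alpha = 1, bootstrap = 300,
                        seed = 1)
  d2 <- mean_divergence(rev(seqs), "k2p", gamma_alpha = 1, bootstrap = 300,
                        seed = 1)
  expect_equal(d1$d, d2$d)
  expect_equal(mean_divergence(c(a = "ACGT", b = "ACGT"), "p",
                               bootstrap = 50)$d, 0)
  # duplicating columns k-fold shrinks the site-bootstrap SE
  seqs20 <- vapply(seqs, function(s) strrep(s, 20L), character(1))
  se1 <- mean_divergence(seqs, "p", bootstrap = 300, seed = 2)$se
  se20 <- mean_divergence(seqs20, "p", bootstrap = 300, seed = 2)$se
  expect_lt(se20, se1 / 2)
})

test_that("codon partition respects the mask and conserves codons", {
  pool <- generate_allele_pool(simulation_config(seed = 4))
  caln <- make_codon_alignment(align_exon3(pool$alleles))
  parts <- partition_codons(caln, pbr_mask("dnds"))
  expect_equal(ncol(parts$pbr$codons), 12L)
  expect_equal(ncol(parts$pbr$codons) + ncol(parts$nonpbr$codons),
               ncol(caln$codons))
  empty <- partition_codons(caln, integer(0))
  expect_equal(ncol(empty$nonpbr$codons), ncol(caln$codons))
  expect_error(partition_codons(caln, c(96L, 999L)), "outside")
})

test_that("NG potential sites and pathway counts match hand enumeration", {
  ng <- amplimhc:::ng_tables()
  idx <- function(c) amplimhc:::codon_index(c)
  # TTT (Phe): only position 3 T->C is synonymous; 1/3 of a site
  expect_equal(ng$s[idx("TTT")], 1 / 3)
  # AAA (Lys): pos 3 A->G syn (1/3); pos 1 T** would be TAA stop, excluded,
  # so denominator 2, no synonymous -> 0
  expect_equal(ng$s[idx("AAA")], 1 / 3)
  # per-codon potential sites sum to 3
  sense <- which(!is.na(ng$s))
  expect_true(all(ng$s[sense] >= 0 & ng$s[sense] <= 3))
  # single-step pairs
  expect_equal(ng$SD[idx("TTT"), idx("TTC")], 1)
  expect_equal(ng$ND[idx("TTT"), idx("TTC")], 0)
  expect_equal(ng$SD[idx("AAA"), idx("AGA")], 0)
  expect_equal(ng$ND[idx("AAA"), idx("AGA")], 1)
  # two-step pair TTT <-> GTA: pathways via GTT (nonsyn, syn) and TTA
  # (nonsyn, nonsyn) average to sd = 0.5, nd = 1.5
  expect_equal(ng$SD[idx("TTT"), idx("GTA")], 0.5)
  expect_equal(ng$ND[idx("TTT"), idx("GTA")], 1.5)
  # random pairs against the independent enumerator
  set.seed(11)
  sense_codons <- ng$codons[sense]
  for (r in 1:25) {
    pair <- sample(sense_codons, 2)
    expected <- oracle_ng_pair(pair[1], pair[2])
    expect_equal(ng$SD[idx(pair[1]), idx(pair[2])], expected[1])
    expect_equal(ng$ND[idx(pair[1]), idx(pair[2])], expected[2])
  }
})

test_that("dN is zero for purely synonymous variation", {
  # GCT/GCC/GCA all encode alanine; vary a minority of codons so the
  # synonymous proportion stays below the Jukes-Cantor ceiling
  seqs <- c(a = paste0("CA", strrep("GCT", 81), "GG"),
            b = paste0("CA", strrep("GCC", 15), strrep("GCT", 66), "GG"),
            c = paste0("CA", strrep("GCT", 66), strrep("GCA", 15), "GG"))
  caln <- make_codon_alignment(align_exon3(seqs))
  res <- nei_gojobori_dnds(caln, bootstrap = 50, seed = 1)
  expect_equal(res$dN, 0)
  expect_gt(res$dS, 0)
  expect_true(is.na(res$ratio) || res$ratio == 0)
})

test_that("NG pairwise estimates agree with a direct per-pair recomputation", {
  set.seed(12)
  pool <- generate_allele_pool(simulation_config(n_long_alleles = 4,
                                                 n_short_alleles = 0,
                                                 seed = 31))
  caln <- make_codon_alignment(align_exon3(pool$alleles))
  res <- nei_gojobori_dnds(caln, bootstrap = 20, seed = 1)
  # oracle: loop over pairs and codons with the independent enumerator
  code <- Biostrings::GENETIC_CODE
  n <- nrow(caln$codons)
  dN <- c(); dS <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    S <- 0; N <- 0; Sd <- 0; Nd <- 0
    for (col in seq_len(ncol(caln$codons))) {
      c1 <- caln$codons[i, col]; c2 <- caln$codons[j, col]
      if (grepl("-", c1) || grepl("-", c2)) next
      if (code[c1] == "*" || code[c2] == "*") next
      s1 <- amplimhc:::ng_syn_sites_codon(c1)
      s2 <- amplimhc:::ng_syn_sites_codon(c2)
      S <- S + (s1 + s2) / 2
      N <- N + 3 - (s1 + s2) / 2
      d <- oracle_ng_pair(c1, c2)
      Sd <- Sd + d[1]; Nd <- Nd + d[2]
    }
    dS <- c(dS, -0.75 * log(1 - 4 * (Sd / S) / 3))
    dN <- c(dN, -0.75 * log(1 - 4 * (Nd / N) / 3))
  }
  expect_equal(res$dN, mean(dN), tolerance = 1e-12)
  expect_equal(res$dS, mean(dS), tolerance = 1e-12)
})
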