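# NJ trees, bootstrap support, parsimony ancestral codons, and the
# counting-based per-site selection test.

test_that("distance matrix is symmetric, zero-diagonal, matches per-pair calls", {
  set.seed(3)
  base <- random_nt(120)
  seqs <- stats::setNames(vapply(1:5, function(i) {
    s <- base
    for (p in sample(120, 15))
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    s
  }, character(1)), paste0("t", 1:5))
  dm <- build_distance_matrix(seqs)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(dm[i, j],
                 pairwise_distance(seqs[[i]], seqs[[j]], "k2p"),
                 tolerance = 1e-12)
  }
  expect_error(build_distance_matrix(seqs[1:2]), "at least 3")
  ident <- stats::setNames(rep(strrep("ACGT", 20), 3), paste0("t", 1:3))
  expect_true(all(build_distance_matrix(ident) == 0))
})

test_that("NJ solves the 3-taxon point equations exactly", {
  dm <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(dm)
  bl <- stats::setNames(tree$edge.length,
                        c(tree$tip.label, "")[tree$edge[, 2]])
  expect_equal(bl[["A"]], 0.5)
  expect_equal(bl[["B"]], 1.5)
  expect_equal(bl[["C"]], 2.5)
})

test_that("NJ is exact on additive matrices from random trees", {
  set.seed(14)
  for (r in 1:8) {
    n <- sample(5:12, 1)
    true <- ape::rtree(n, rooted = FALSE)
    true$edge.length <- stats::runif(length(true$edge.length), 0.05, 1)
    dm <- ape::cophenetic.phylo(true)
    est <- nj_tree(dm[true$tip.label, true$tip.label])
    expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    # pairwise path lengths reproduced
    expect_equal(ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-8)
  }
})

test_that("bootstrap support is high for a well-separated split", {
  set.seed(15)
  a <- random_nt(150)
  b <- a
  for (p in 1:40) substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                                    substr(b, p, p)), 1)
  jitter <- function(s, k) {
    for (p in sample(100:150, k))
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1)
    s
  }
  seqs <- c(a1 = jitter(a, 2), a2 = jitter(a, 2),
            b1 = jitter(b, 2), b2 = jitter(b, 2))
  tree <- bootstrap_support(seqs, reps = 100, seed = 1)
  expect_gt(max(tree$node.label, na.rm = TRUE), 95)
  tree1 <- bootstrap_support(seqs, reps = 1, seed = 2)
  expect_true(all(tree1$node.label %in% c(0, 100) |
                    is.na(tree1$node.label)))
  t_a <- bootstrap_support(seqs, reps = 20, seed = 3)
  t_b <- bootstrap_support(seqs, reps = 20, seed = 3)
  expect_identical(t_a$node.label, t_b$node.label)
})

test_that("ancestral codons: invariant sites and two-leaf behaviour", {
  seqs <- c(t1 = "CAATGGCTGG", t2 = "CAATGGCTGG", t3 = "CAATGGCTGG")
  caln <- make_codon_alignment(seqs, aa_start = 1)
  tree <- nj_tree(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
                         dimnames = list(names(seqs), names(seqs))))
  anc <- ancestral_codons(tree, caln)
  expect_true(all(anc == rep(c("ATG", "GCT"), each = nrow(anc))))
})

test_that("parsimony change counts equal brute-force minimal assignments", {
  set.seed(16)
  ng <- amplimhc:::ng_tables()
  sense <- ng$codons[!is.na(ng$s)]
  for (r in 1:6) {
    n <- sample(4:6, 1)
    tree <- ape::rtree(n, rooted = FALSE)
    tree$tip.label <- paste0("t", seq_len(n))
    states <- sample(sense[1:8], n, replace = TRUE)
    names(states) <- tree$tip.label
    seqs <- stats::setNames(paste0("CA", states, "GG"), tree$tip.label)
    caln <- make_codon_alignment(seqs, aa_start = 1)
    anc <- ancestral_codons(tree, caln)
    edge <- attr(anc, "edge")
    implied <- sum(anc[edge[, 1], 1] != anc[edge[, 2], 1])
    expect_equal(implied, oracle_fitch_count(tree, states))
  }
})

test_that("tie-breaking prefers assignments minimizing nonsynonymous changes", {
  # two leaves with synonymous codons: any ancestor equal to one of them is
  # minimal in changes; the synonymous tie-break keeps changes synonymous
  tree <- ape::read.tree(text = "(t1:1,t2:1,t3:1);")
  seqs <- c(t1 = "CAGCTGG", t2 = "CAGCCGG", t3 = "CAGCTGG")
  caln <- make_codon_alignment(seqs, aa_start = 1)
  anc <- ancestral_codons(tree, caln)
  edge <- attr(anc, "edge")
  changes <- sum(anc[edge[, 1], 1] != anc[edge[, 2], 1])
  expect_equal(changes, 1)
  expect_true(anc[4, 1] %in% c("GCT", "GCC"))
})

test_that("per-site test: no changes means neutral with p = 1", {
  seqs <- c(t1 = "CAGCTGG", t2 = "CAGCTGG", t3 = "CAGCTGG")
  caln <- make_codon_alignment(seqs, aa_start = 1)
  tree <- ape::read.tree(text = "(t1:1,t2:1,t3:1);")
  res <- slac_test(tree, caln, mask = integer(0))
  expect_equal(res$class, "neutral")
  expect_equal(res$p_value, 1)
  expect_equal(res$syn + res$nonsyn, 0)
})

test_that("per-site binomial p-values equal the closed-form tail", {
  # three leaves, all-different amino acids at one codon: two nonsynonymous
  # changes, none synonymous
  tree <- ape::read.tree(text = "(t1:1,t2:1,t3:1);")
  seqs <- c(t1 = "CAAAAGG", t2 = "CAAGAGG", t3 = "CAACAGG")
  caln <- make_codon_alignment(seqs, aa_start = 1)
  res <- slac_test(tree, caln, mask = integer(0))
  expect_equal(res$nonsyn, 2)
  expect_equal(res$syn, 0)
  s_site <- mean(vapply(c("AAA", "AGA", "ACA"),
                        amplimhc:::ng_syn_sites_codon, numeric(1)))
  expect_equal(res$p_value, oracle_binom_two_sided(0, 2, s_site / 3),
               tolerance = 1e-9)
})

test_that("classification is monotone in the p threshold", {
  pool <- generate_allele_pool(simulation_config(seed = 25))
  caln <- make_codon_alignment(align_exon3(pool$alleles))
  tree <- nj_tree(build_distance_matrix(align_exon3(pool$alleles)))
  r05 <- slac_test(tree, caln, p_threshold = 0.05)
  r10 <- slac_test(tree, caln, p_threshold = 0.1)
  pos05 <- r05$position[r05$class == "positive"]
  pos10 <- r10$position[r10$class == "positive"]
  expect_true(all(pos05 %in% pos10))
  neg05 <- r05$position[r05$class == "negative"]
  expect_true(all(neg05 %in% r10$position[r10$class == "negative"]))
})

test_that("nonsynonymous excess concentrates at PBR codons in the pool", {
  pool <- generate_allele_pool(simulation_config(seed = 7))
  aligned <- align_exon3(pool$alleles)
  caln <- make_codon_alignment(aligned)
  tree <- nj_tree(build_distance_matrix(aligned))
  res <- slac_test(tree, caln)
  pbr <- res[res$pbr, ]
  nonpbr <- res[!res$pbr, ]
  # per-site nonsynonymous change counts are enriched at PBR sites
  expect_gt(mean(pbr$nonsyn), mean(nonpbr$nonsyn))
  # normalized dN-dS is positive at the polymorphic PBR sites overall
  expect_gt(mean(pbr$dn_minus_ds), mean(nonpbr$dn_minus_ds))
})
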