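# The four-step filtering cascade: depth gate, artefact clustering, chimera
# screening, duplicate calibration, genotype calling.

make_test_amplicon <- function(variants, id = "amp1", ind = "i1", grp = "") {
  v <- data.frame(sequence = names(variants), depth = unname(variants),
                  stringsAsFactors = FALSE)
  v <- v[order(-v$depth, v$sequence), , drop = FALSE]
  rownames(v) <- NULL
  list(amplicon_id = id, individual_id = ind, duplicate_group = grp,
       variants = v, total_depth = sum(v$depth), n_excluded = 0L)
}

test_that("depth gate keeps 4000 and drops 3999", {
  a <- make_test_amplicon(c(AAAA = 3999L), id = "low")
  b <- make_test_amplicon(c(CCCC = 4000L), id = "ok")
  set <- structure(list(a, b), class = "amplicon_set")
  res <- filter_amplicon_depth(set)
  expect_equal(vapply(res$kept, `[[`, character(1), "amplicon_id"), "ok")
  expect_equal(res$dropped$amplicon_id, "low")
  expect_equal(res$dropped$total_depth, 3999)
  empty <- filter_amplicon_depth(structure(list(), class = "amplicon_set"))
  expect_length(empty$kept, 0L)
  expect_equal(nrow(empty$dropped), 0L)
})

test_that("1-2 bp low-depth variants merge; >25% forms a subdominant", {
  base <- strrep("ACGT", 10)
  one_off <- base; substr(one_off, 5, 5) <- "G"
  cl <- cluster_variants(make_test_amplicon(
    stats::setNames(c(1000L, 200L), c(base, one_off))))
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$cluster_depth, 1200)
  expect_equal(cl[[1]]$frequency, 1)
  cl <- cluster_variants(make_test_amplicon(
    stats::setNames(c(1000L, 260L), c(base, one_off))))
  expect_length(cl, 2L)
  expect_true(cl[[2]]$subdominant)
  expect_false(cl[[1]]$subdominant)
})

test_that("variants beyond 2 mismatches or different length never merge", {
  base <- strrep("ACGT", 10)
  three_off <- base
  substr(three_off, 1, 1) <- "T"; substr(three_off, 9, 9) <- "G"
  substr(three_off, 17, 17) <- "C"
  cl <- cluster_variants(make_test_amplicon(
    stats::setNames(c(1000L, 50L), c(base, three_off))))
  expect_length(cl, 2L)
  expect_false(cl[[2]]$subdominant)
  shorter <- substr(base, 1, 37)
  cl <- cluster_variants(make_test_amplicon(
    stats::setNames(c(1000L, 50L), c(base, shorter))))
  expect_length(cl, 2L)
})

test_that("clustering conserves read depth and matches the oracle", {
  set.seed(101)
  base <- random_nt(60)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    seqs <- vapply(seq_len(n), function(i) {
      s <- base
      nmut <- sample(0:4, 1)
      for (p in sample(60, nmut)) {
        substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(s, p, p)), 1)
      }
      s
    }, character(1))
    seqs <- unique(seqs)
    depths <- sample(c(sample(20:80, length(seqs), TRUE)))
    amp <- make_test_amplicon(stats::setNames(depths, seqs))
    cl <- cluster_variants(amp)
    expect_equal(sum(vapply(cl, `[[`, numeric(1), "cluster_depth")),
                 amp$total_depth)
    ref <- oracle_cluster(amp$variants)
    expect_equal(length(cl), length(ref))
    for (k in seq_along(cl)) {
      expect_equal(cl[[k]]$dominant, ref[[k]]$dominant)
      expect_equal(cl[[k]]$cluster_depth, ref[[k]]$cluster_depth)
      expect_equal(sort(c(cl[[k]]$dominant, cl[[k]]$merged$sequence)),
                   sort(ref[[k]]$members))
      expect_equal(cl[[k]]$subdominant, ref[[k]]$subdominant)
    }
  }
})

test_that("exact splices of two deeper parents are flagged chimeric", {
  set.seed(7)
  a <- random_nt(200)
  b <- random_nt(200)
  k <- 100L
  chimera <- paste0(substr(a, 1, k), substr(b, k + 1, 200))
  amp <- make_test_amplicon(stats::setNames(c(5000L, 4000L, 300L),
                                            c(a, b, chimera)))
  cl <- detect_chimeras(cluster_variants(amp))
  doms <- vapply(cl, `[[`, character(1), "dominant")
  flags <- vapply(cl, `[[`, logical(1), "chimera")
  expect_true(flags[doms == chimera])
  expect_false(any(flags[doms != chimera]))
  # verify by exhaustive breakpoint scan
  hits <- sapply(1:199, function(kk)
    identical(chimera, paste0(substr(a, 1, kk), substr(b, kk + 1, 200))))
  expect_true(any(hits))
})

test_that("chimera flag requires two deeper parents and a true splice", {
  set.seed(8)
  a <- random_nt(200); b <- random_nt(200)
  chim <- paste0(substr(a, 1, 80), substr(b, 81, 200))
  # single cluster: nothing to flag
  cl <- detect_chimeras(cluster_variants(make_test_amplicon(
    stats::setNames(5000L, a))))
  expect_false(any(vapply(cl, `[[`, logical(1), "chimera")))
  # deeper than one parent: not flagged
  amp <- make_test_amplicon(stats::setNames(c(5000L, 900L, 1000L),
                                            c(a, b, chim)))
  cl <- detect_chimeras(cluster_variants(amp))
  doms <- vapply(cl, `[[`, character(1), "dominant")
  expect_false(vapply(cl, `[[`, logical(1), "chimera")[doms == chim])
})

test_that("thresholding keeps clusters at or above the cutoff", {
  set.seed(9)
  seqs <- vapply(1:4, function(i) random_nt(100), character(1))
  amp <- make_test_amplicon(stats::setNames(c(4000L, 3000L, 2000L, 500L),
                                            seqs))
  set <- structure(list(amp), class = "amplicon_set")
  g1 <- call_genotypes(set, threshold = 0.034)
  expect_equal(nrow(g1$genotypes), 4L)
  g2 <- call_genotypes(set, threshold = 0.25)
  expect_equal(nrow(g2$genotypes), 2L)
})

test_that("raising the threshold never increases an allele count", {
  cfg <- simulation_config(n_long_alleles = 8, n_short_alleles = 3,
                           n_individuals = 12, depth_mean = 6000,
                           n_duplicate_pairs = 2, seed = 17)
  sim <- simulate_dataset(cfg)
  kept <- filter_amplicon_depth(sim$amplicons)$kept
  inds <- names(sim$truth$genotypes)
  count_at <- function(t) {
    g <- call_genotypes(kept, threshold = t)
    tab <- table(g$genotypes$individual_id)
    out <- stats::setNames(rep(0L, length(inds)), inds)
    out[names(tab)] <- as.integer(tab)
    out
  }
  counts <- sapply(c(0.005, 0.02, 0.05, 0.1, 0.2), count_at)
  for (r in seq_len(nrow(counts)))
    expect_true(all(diff(as.numeric(counts[r, ])) <= 0))
})

test_that("calibration returns the smallest optimal threshold", {
  cfg <- simulation_config(n_long_alleles = 6, n_short_alleles = 2,
                           n_individuals = 10, depth_mean = 6000,
                           pcr_error_rate = 0, chimera_rate = 0,
                           amplification_bias_sd = 0,
                           n_duplicate_pairs = 3, seed = 23)
  sim <- simulate_dataset(cfg)
  kept <- filter_amplicon_depth(sim$amplicons)$kept
  cal <- calibrate_threshold(kept)
  # zero noise: every threshold below the rarest allele frequency is
  # perfect, so the smallest grid value wins
  expect_equal(cal$threshold, 0.005)
  expect_equal(max(cal$curve$n_exact), cal$n_pairs)
  # single-value grid returns that value
  cfg1 <- calling_config(threshold_grid = 0.03)
  expect_equal(calibrate_threshold(kept, cfg1)$threshold, 0.03)
})

test_that("calibration errors without duplicate pairs", {
  amp <- make_test_amplicon(stats::setNames(5000L, strrep("ACGT", 25)))
  set <- structure(list(amp), class = "amplicon_set")
  expect_error(calibrate_threshold(set), "duplicate pairs")
})

test_that("disagreeing duplicates fall back to the deeper amplicon", {
  set.seed(31)
  a <- random_nt(100); b <- random_nt(100)
  amp1 <- make_test_amplicon(stats::setNames(c(6000L, 4000L), c(a, b)),
                             id = "x.1", ind = "x", grp = "x")
  amp2 <- make_test_amplicon(stats::setNames(5000L, a),
                             id = "x.2", ind = "x", grp = "x")
  set <- structure(list(amp1, amp2), class = "amplicon_set")
  g <- call_genotypes(set, threshold = 0.05)
  expect_false(g$duplicate_report$match)
  expect_equal(g$duplicate_report$used_amplicon, "x.1")
  expect_equal(sort(g$genotypes$sequence), sort(c(a, b)))
})
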