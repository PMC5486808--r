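# The four-step filtering cascade turning per-amplicon read tallies into
# verified per-individual genotypes:
#   1. minimum read-depth gate per amplicon,
#   2. greedy depth-ordered clustering reassigning 1-2 bp artefacts to
#      their presumed parent sequences,
#   3. per-amplicon frequency threshold calibrated on technical duplicates,
#   4. exhaustive-breakpoint chimera screening.

#' Calling configuration
#'
#' @param min_amplicon_depth Minimum reads per amplicon (default 4000).
#' @param max_merge_mismatches Maximum substitutions for artefact merging
#'   (default 2; equal-length sequences only).
#' @param merge_depth_ratio Maximum depth relative to the dominant for a
#'   variant to be merged rather than form a subdominant cluster (0.25).
#' @param frequency_threshold A fraction, or "auto" to calibrate from
#'   technical duplicates.
#' @param threshold_grid Candidate thresholds for calibration.
#' @return A `calling_config` list.
#' @export
calling_config <- function(min_amplicon_depth = 4000L,
                           max_merge_mismatches = 2L,
                           merge_depth_ratio = 0.25,
                           frequency_threshold = "auto",
                           threshold_grid = seq(0.005, 0.10, by = 0.001)) {
  stopifnot(merge_depth_ratio > 0, merge_depth_ratio < 1,
            length(threshold_grid) >= 1L, !is.unsorted(threshold_grid))
  structure(list(min_amplicon_depth = min_amplicon_depth,
                 max_merge_mismatches = as.integer(max_merge_mismatches),
                 merge_depth_ratio = merge_depth_ratio,
                 frequency_threshold = frequency_threshold,
                 threshold_grid = threshold_grid),
            class = "calling_config")
}

#' Depth-gate amplicons
#'
#' Keeps amplicons with total read depth at or above the minimum; dropped
#' amplicons are reported with their ids and depths.
#'
#' @param set An `amplicon_set`.
#' @param cfg A `calling_config`.
#' @return List with `kept` (an `amplicon_set`) and `dropped` (data frame
#'   amplicon_id, individual_id, total_depth).
#' @export
filter_amplicon_depth <- function(set, cfg = calling_config()) {
  depths <- vapply(set, function(a) a$total_depth, numeric(1))
  keep <- depths >= cfg$min_amplicon_depth
  dropped <- data.frame(
    amplicon_id = vapply(set[!keep], `[[`, character(1), "amplicon_id"),
    individual_id = vapply(set[!keep], `[[`, character(1), "individual_id"),
    total_depth = depths[!keep], stringsAsFactors = FALSE)
  list(kept = structure(set[keep], class = "amplicon_set"), dropped = dropped)
}

#' Cluster variants within one amplicon
#'
#' Greedy pass over variants in depth order (ties broken lexicographically):
#' a variant within `max_merge_mismatches` substitutions of an existing
#' cluster's dominant (equal lengths only) and with depth at most
#' `merge_depth_ratio` times that dominant's depth is merged into the
#' deepest eligible cluster; a variant within the distance rule but above
#' the depth ratio founds a new cluster flagged subdominant; anything else
#' founds a new unflagged cluster. Cluster frequency is cluster depth over
#' amplicon total depth.
#'
#' @param amplicon One element of an `amplicon_set`.
#' @param cfg A `calling_config`.
#' @return List of clusters, each with `dominant`, `dominant_depth`,
#'   `merged` (data frame sequence, depth, mismatches), `cluster_depth`,
#'   `frequency`, `subdominant`, `chimera`.
#' @export
cluster_variants <- function(amplicon, cfg = calling_config()) {
  v <- amplicon$variants
  total <- amplicon$total_depth
  clusters <- list()
  doms <- character(0); dom_depths <- numeric(0); dom_len <- integer(0)
  for (i in seq_len(nrow(v))) {
    s <- v$sequence[i]; d <- v$depth[i]; len <- nchar(s)
    mm <- rep(NA_integer_, length(clusters))
    cand <- which(dom_len == len)
    for (j in cand) mm[j] <- seq_hamming(s, doms[j])
    near <- which(!is.na(mm) & mm <= cfg$max_merge_mismatches & mm > 0L)
    mergeable <- near[d <= cfg$merge_depth_ratio * dom_depths[near]]
    if (length(mergeable)) {
      pick <- mergeable[order(-dom_depths[mergeable], doms[mergeable])][1]
      cl <- clusters[[pick]]
      cl$merged <- rbind(cl$merged,
                         data.frame(sequence = s, depth = d,
                                    mismatches = mm[pick],
                                    stringsAsFactors = FALSE))
      cl$cluster_depth <- cl$cluster_depth + d
      clusters[[pick]] <- cl
    } else {
      clusters[[length(clusters) + 1L]] <- list(
        dominant = s, dominant_depth = d,
        merged = data.frame(sequence = character(), depth = numeric(),
                            mismatches = integer(), stringsAsFactors = FALSE),
        cluster_depth = d, frequency = NA_real_,
        subdominant = length(near) > 0L, chimera = FALSE)
      doms <- c(doms, s); dom_depths <- c(dom_depths, d)
      dom_len <- c(dom_len, len)
    }
  }
  lapply(clusters, function(cl) {
    cl$frequency <- cl$cluster_depth / total
    cl
  })
}

#' Flag chimeric clusters
#'
#' A cluster is flagged chimeric iff its dominant sequence equals, for some
#' breakpoint k (1 <= k < length), the prefix of one parent cluster's
#' dominant joined to the suffix of another's, where both parents have the
#' same length as, greater cluster depth than, and different dominants from
#' the candidate. Every breakpoint is examined via longest common
#' prefix/suffix bounds.
#'
#' @param clusters Cluster list from [cluster_variants()].
#' @return The cluster list with `chimera` flags set.
#' @export
detect_chimeras <- function(clusters) {
  n <- length(clusters)
  if (n < 3L) return(clusters)
  doms <- vapply(clusters, `[[`, character(1), "dominant")
  depth <- vapply(clusters, `[[`, numeric(1), "cluster_depth")
  lens <- nchar(doms)
  for (t in seq_len(n)) {
    len <- lens[t]
    parents <- which(depth > depth[t] & lens == len & doms != doms[t])
    if (length(parents) < 2L) next
    found <- FALSE
    for (a in parents) {
      if (found) break
      hi <- min(seq_lcp(doms[t], doms[a]), len - 1L)
      if (hi < 1L) next
      for (b in setdiff(parents, a)) {
        lo <- max(1L, len - seq_lcs(doms[t], doms[b]))
        if (lo <= hi) { found <- TRUE; break }
      }
    }
    if (found) clusters[[t]]$chimera <- TRUE
  }
  clusters
}

# Cluster all amplicons once; chimera flags computed here so calibration and
# calling share the same cluster objects.
cluster_amplicon_set <- function(set, cfg) {
  lapply(set, function(a) detect_chimeras(cluster_variants(a, cfg)))
}

# Provisional allele set of one amplicon at threshold t: dominants of
# unflagged clusters with frequency >= t.
alleles_at_threshold <- function(clusters, t) {
  keep <- vapply(clusters, function(cl) !cl$chimera && cl$frequency >= t,
                 logical(1))
  sort(vapply(clusters[keep], `[[`, character(1), "dominant"))
}

#' Calibrate the per-amplicon frequency threshold from technical duplicates
#'
#' For each candidate threshold, genotypes are provisionally called for
#' every duplicate amplicon; the objective is lexicographic (number of
#' duplicate pairs with identical allele sets, then mean Jaccard similarity
#' across pairs). The smallest grid value attaining the maximum is
#' returned, together with the full objective curve.
#'
#' @param set An `amplicon_set` (after depth gating).
#' @param cfg A `calling_config`.
#' @param clusters Optional precomputed output of the internal clustering
#'   pass over `set`.
#' @return List with `threshold`, `curve` (data frame threshold, n_exact,
#'   mean_jaccard), `n_pairs`.
#' @export
calibrate_threshold <- function(set, cfg = calling_config(),
                                clusters = NULL) {
  if (is.null(clusters)) clusters <- cluster_amplicon_set(set, cfg)
  grp <- vapply(set, `[[`, character(1), "duplicate_group")
  groups <- split(seq_along(set), grp)
  groups <- groups[nzchar(names(groups))]
  groups <- groups[vapply(groups, length, integer(1)) == 2L]
  if (length(groups) == 0L)
    stop("no complete technical duplicate pairs available; ",
         "set frequency_threshold manually")
  grid <- cfg$threshold_grid
  n_exact <- integer(length(grid)); jacc <- numeric(length(grid))
  for (g in seq_along(grid)) {
    t <- grid[g]
    ex <- 0L; js <- numeric(length(groups))
    for (p in seq_along(groups)) {
      a <- alleles_at_threshold(clusters[[groups[[p]][1]]], t)
      b <- alleles_at_threshold(clusters[[groups[[p]][2]]], t)
      if (identical(a, b)) ex <- ex + 1L
      u <- length(union(a, b))
      js[p] <- if (u == 0L) 1 else length(intersect(a, b)) / u
    }
    n_exact[g] <- ex; jacc[g] <- mean(js)
  }
  best <- which(n_exact == max(n_exact))
  best <- best[jacc[best] == max(jacc[best])]
  list(threshold = grid[best[1]],
       curve = data.frame(threshold = grid, n_exact = n_exact,
                          mean_jaccard = jacc),
       n_pairs = length(groups))
}

#' Call genotypes from clustered amplicons
#'
#' Applies the frequency threshold to every amplicon's unflagged clusters,
#' reconciles technical duplicates (on disagreement the deeper amplicon's
#' set is used and the individual flagged), and assigns stable allele names
#' across individuals in canonical order (total called depth descending,
#' then lexicographic).
#'
#' @param set An `amplicon_set` (after depth gating).
#' @param threshold Frequency threshold, or "auto" for duplicate
#'   calibration.
#' @param cfg A `calling_config`.
#' @param registry Optional existing allele registry (data frame with
#'   `allele_name`, `sequence`) whose names are preserved.
#' @return An object of class `mhc_genotypes`: `genotypes` (long data frame
#'   individual_id, allele_name), `registry` (allele_name, sequence,
#'   total_depth, n_individuals), `duplicate_report`, `threshold`,
#'   `calibration` (NULL unless auto), `clusters` (per-amplicon cluster
#'   lists), `amplicon_calls`.
#' @export
call_genotypes <- function(set, threshold = "auto", cfg = calling_config(),
                           registry = NULL) {
  clusters <- cluster_amplicon_set(set, cfg)
  calibration <- NULL
  if (identical(threshold, "auto")) {
    calibration <- calibrate_threshold(set, cfg, clusters)
    threshold <- calibration$threshold
  }
  stopifnot(is.numeric(threshold), threshold >= 0, threshold <= 1)
  calls <- lapply(clusters, alleles_at_threshold, t = threshold)
  names(calls) <- vapply(set, `[[`, character(1), "amplicon_id")
  inds <- vapply(set, `[[`, character(1), "individual_id")
  depths <- vapply(set, function(a) a$total_depth, numeric(1))
  per_ind <- split(seq_along(set), inds)

  dup_report <- list()
  genotype_of <- list()
  for (ind in names(per_ind)) {
    idx <- per_ind[[ind]]
    if (length(idx) == 1L) {
      genotype_of[[ind]] <- calls[[idx]]
    } else {
      sets <- lapply(idx, function(i) calls[[i]])
      match_ok <- all(vapply(sets[-1], identical, logical(1),
                             y = sets[[1]]))
      pick <- idx[which.max(depths[idx])]
      genotype_of[[ind]] <- calls[[pick]]
      dup_report[[ind]] <- data.frame(
        individual_id = ind, match = match_ok,
        used_amplicon = set[[pick]]$amplicon_id, stringsAsFactors = FALSE)
    }
  }
  dup_report <- if (length(dup_report)) do.call(rbind, dup_report) else
    data.frame(individual_id = character(), match = logical(),
               used_amplicon = character(), stringsAsFactors = FALSE)

  allele_seqs <- unique(unlist(genotype_of, use.names = FALSE))
  depth_of <- stats::setNames(numeric(length(allele_seqs)), allele_seqs)
  ninds <- stats::setNames(integer(length(allele_seqs)), allele_seqs)
  for (ind in names(genotype_of)) {
    idx <- per_ind[[ind]]
    for (i in idx) {
      for (cl in clusters[[i]]) {
        if (cl$dominant %in% allele_seqs)
          depth_of[cl$dominant] <- depth_of[cl$dominant] + cl$cluster_depth
      }
    }
    ninds[genotype_of[[ind]]] <- ninds[genotype_of[[ind]]] + 1L
  }
  canon <- allele_seqs[order(-depth_of[allele_seqs], allele_seqs)]
  naming <- assign_allele_names(canon, registry = registry)
  name_of <- stats::setNames(naming$allele_name, naming$sequence)

  geno <- do.call(rbind, lapply(names(genotype_of), function(ind) {
    g <- genotype_of[[ind]]
    if (length(g) == 0L) return(NULL)
    data.frame(individual_id = ind, allele_name = unname(name_of[g]),
               sequence = g, stringsAsFactors = FALSE)
  }))
  if (is.null(geno))
    geno <- data.frame(individual_id = character(),
                       allele_name = character(), sequence = character(),
                       stringsAsFactors = FALSE)
  registry_out <- data.frame(allele_name = unname(name_of[canon]),
                             sequence = canon,
                             total_depth = unname(depth_of[canon]),
                             n_individuals = unname(ninds[canon]),
                             stringsAsFactors = FALSE)
  structure(list(genotypes = geno, registry = registry_out,
                 duplicate_report = dup_report, threshold = threshold,
                 calibration = calibration, clusters = clusters,
                 amplicon_calls = calls),
            class = "mhc_genotypes")
}

#' @export
print.mhc_genotypes <- function(x, ...) {
  cat("mhc_genotypes:", nrow(x$registry), "alleles across",
      length(unique(x$genotypes$individual_id)), "individuals; threshold",
      format(x$threshold), "\n")
  invisible(x)
}
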