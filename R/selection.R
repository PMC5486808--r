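# Counting-based per-site selection inference: K2P distances -> a
# neighbor-joining tree -> parsimony ancestral codon states -> per-site
# synonymous/nonsynonymous change counts along branches -> a binomial test
# against the Nei-Gojobori expectation, classifying sites at a p-value
# threshold. This is the counting (SLAC-style) member of the selection-test
# family; likelihood fixed/random-effects variants are out of scope.

#' Pairwise distance matrix over an aligned sequence set
#'
#' K2P with pairwise gap deletion; pairs for which the K2P logarithms are
#' undefined fall back to the p-distance (recorded in the `fallback`
#' attribute).
#'
#' @param seqs Named character vector of aligned nucleotide sequences.
#' @param model "k2p" or "p".
#' @param gamma_alpha Optional gamma shape for K2P.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
build_distance_matrix <- function(seqs, model = c("k2p", "p"),
                                  gamma_alpha = NULL) {
  model <- match.arg(model)
  n <- length(seqs)
  if (n < 3L) stop("need at least 3 taxa")
  ids <- names(seqs)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  fallback <- character(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- tryCatch(pairwise_distance(seqs[[i]], seqs[[j]], model,
                                    gamma_alpha),
                  error = function(e) NA_real_)
    if (is.na(d) && model == "k2p") {
      d <- pairwise_distance(seqs[[i]], seqs[[j]], "p")
      fallback <- c(fallback, paste0(ids[i], ":", ids[j]))
    }
    m[i, j] <- m[j, i] <- d
  }
  attr(m, "fallback") <- fallback
  m
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (exact on additive matrices); negative branch
#' length estimates are clamped to zero and the clamped total recorded in
#' the `clamped` attribute.
#'
#' @param dm Symmetric distance matrix with taxon dimnames.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  tree <- ape::nj(stats::as.dist(dm))
  neg <- tree$edge.length < 0
  clamped <- -sum(tree$edge.length[neg])
  tree$edge.length[neg] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap support for NJ tree bipartitions
#'
#' Column-resampled replicates; support for each internal edge is the
#' percentage of replicate trees containing the corresponding bipartition.
#'
#' @param seqs Named character vector of aligned nucleotide sequences.
#' @param reps Number of replicates (default 1000).
#' @param seed Optional seed.
#' @param model,gamma_alpha Passed to [build_distance_matrix()].
#' @return The NJ tree with `node.label` set to support percentages (the
#'   root label is NA).
#' @export
bootstrap_support <- function(seqs, reps = 1000L, seed = NULL,
                              model = "k2p", gamma_alpha = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- nj_tree(build_distance_matrix(seqs, model, gamma_alpha))
  L <- nchar(seqs[[1]])
  boot <- vector("list", reps)
  for (r in seq_len(reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    res <- vapply(seqs, function(s)
      paste(strsplit(s, "")[[1]][cols], collapse = ""), character(1))
    boot[[r]] <- nj_tree(build_distance_matrix(res, model, gamma_alpha))
  }
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- round(100 * counts / reps, 1)
  tree$node.label[1] <- NA  # root of the unrooted representation
  tree
}

# Edge weight for the ancestral-state DP: a state change costs CHANGE_W, a
# nonsynonymous change 1 extra; CHANGE_W dominates so total changes are
# minimized first and nonsynonymous changes only break ties.
CHANGE_W <- 1e6

#' Parsimony ancestral codon states
#'
#' Fitch-style parsimony treating each codon site as a 64-state character,
#' solved by dynamic programming over the tree. Ties among
#' minimum-change assignments are resolved by minimizing the implied number
#' of nonsynonymous changes, then lexicographically by codon. Leaves with a
#' gap or incomplete codon at a site are unconstrained there (their pendant
#' branches contribute no changes).
#'
#' @param tree An `ape::phylo` tree whose tip labels match `caln$ids`.
#' @param caln A `codon_alignment`.
#' @return Character matrix (tree nodes x sites) of codon states; rows
#'   1..Ntip are the (possibly imputed) leaf states, the rest internal
#'   nodes.
#' @export
ancestral_codons <- function(tree, caln) {
  stopifnot(setequal(tree$tip.label, caln$ids))
  ng <- ng_tables()
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- ntip + nnode
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  L <- ncol(caln$codons)
  leaf_idx <- match(tree$tip.label, caln$ids)
  out <- matrix(NA_character_, total, L)
  root <- edge[nrow(edge), 1]
  for (site in seq_len(L)) {
    obs <- caln$codons[leaf_idx, site]
    obs_idx <- codon_index(obs)
    obs_idx[!is.na(obs_idx) & is.na(ng$s[obs_idx])] <- NA_integer_
    states <- sort(unique(obs_idx[!is.na(obs_idx)]))
    if (length(states) == 0L) next
    if (length(states) == 1L) {
      out[, site] <- ng$codons[states]
      next
    }
    ns <- length(states)
    aa <- ng$aa[states]
    w <- CHANGE_W * outer(states, states, "!=") +
      outer(aa, aa, "!=") * 1
    cost <- matrix(0, total, ns)
    for (i in seq_len(ntip)) {
      if (is.na(obs_idx[i])) next
      cost[i, ] <- ifelse(states == obs_idx[i], 0, Inf)
    }
    # postorder accumulation: cost[parent, s] += min_t cost[child, t] + w[s, t]
    for (e in seq_len(nrow(edge))) {
      par <- edge[e, 1]; child <- edge[e, 2]
      inc <- vapply(seq_len(ns), function(s)
        min(cost[child, ] + w[s, ]), numeric(1))
      cost[par, ] <- cost[par, ] + inc
    }
    assign <- integer(total)
    best <- which(cost[root, ] == min(cost[root, ]))
    assign[root] <- best[1]  # states sorted, so first = lexicographic
    # preorder resolution
    for (e in rev(seq_len(nrow(edge)))) {
      par <- edge[e, 1]; child <- edge[e, 2]
      sc <- cost[child, ] + w[assign[par], ]
      best <- which(sc == min(sc))
      assign[child] <- best[1]
    }
    out[, site] <- ng$codons[states[assign]]
    # leaves keep their own observed state where present
    present <- !is.na(obs_idx)
    out[seq_len(ntip)[present], site] <- ng$codons[obs_idx[present]]
  }
  rownames(out) <- c(tree$tip.label, paste0("node", seq_len(nnode) + ntip))
  attr(out, "edge") <- edge
  out
}

#' Counting-based per-site selection test
#'
#' For every codon site, synonymous and nonsynonymous changes are counted
#' along all branches between reconstructed states (pathway-averaged for
#' multi-step codon changes, using the same Nei-Gojobori machinery as the
#' diversity layer). The expected synonymous fraction comes from the
#' potential-site counts of the codons observed at that site; a two-tailed
#' binomial test of the observed synonymous count against that expectation
#' yields the p-value, and sites are classified positive/negative/neutral
#' at threshold `p_threshold`.
#'
#' @param tree An `ape::phylo` tree.
#' @param caln A `codon_alignment`.
#' @param p_threshold Classification threshold (default 0.1).
#' @param mask Optional PBR mask for the report.
#' @return Data frame with one row per site: `position` (alignment
#'   amino-acid frame), `syn`, `nonsyn`, `dn_minus_ds` (normalized),
#'   `p_value`, `class`, `pbr`.
#' @export
slac_test <- function(tree, caln, p_threshold = 0.1, mask = pbr_mask("dnds")) {
  anc <- ancestral_codons(tree, caln)
  edge <- attr(anc, "edge")
  ng <- ng_tables()
  L <- ncol(caln$codons)
  res <- vector("list", L)
  for (site in seq_len(L)) {
    st <- anc[, site]
    sd <- 0; nd <- 0
    for (e in seq_len(nrow(edge))) {
      a <- st[edge[e, 1]]; b <- st[edge[e, 2]]
      if (is.na(a) || is.na(b) || a == b) next
      ia <- codon_index(a); ib <- codon_index(b)
      sd <- sd + ng$SD[ia, ib]
      nd <- nd + ng$ND[ia, ib]
    }
    obs <- caln$codons[, site]
    oi <- codon_index(obs)
    oi <- oi[!is.na(oi)]
    oi <- oi[!is.na(ng$s[oi])]
    s_site <- if (length(oi)) mean(ng$s[oi]) else NA_real_
    n_site <- 3 - s_site
    total <- sd + nd
    if (total == 0 || is.na(s_site)) {
      p <- 1; diff <- 0
    } else {
      diff <- nd / n_site - sd / s_site
      x <- round(sd); ntr <- max(round(total), x)
      p <- if (s_site == 0 || s_site == 3) 1 else
        stats::binom.test(x, ntr, p = s_site / 3)$p.value
    }
    cls <- if (total > 0 && p <= p_threshold && diff > 0) "positive"
           else if (total > 0 && p <= p_threshold && diff < 0) "negative"
           else "neutral"
    res[[site]] <- data.frame(position = caln$aa_positions[site],
                              syn = sd, nonsyn = nd, dn_minus_ds = diff,
                              p_value = p, class = cls,
                              pbr = caln$aa_positions[site] %in% mask,
                              stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}
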