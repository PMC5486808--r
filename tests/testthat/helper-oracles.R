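# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain double loops, exhaustive
# enumeration, and closed forms.

# Naive per-site p-distance diversity: mean over pairs of mismatches/overlap.
oracle_pi <- function(seqs) {
  chars <- strsplit(unname(seqs), "")
  n <- length(chars)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- chars[[i]]; b <- chars[[j]]
    keep <- a != "-" & b != "-"
    vals <- c(vals, mean(a[keep] != b[keep]))
  }
  mean(vals)
}

# Naive segregating-site count by explicit column scan.
oracle_segregating <- function(seqs) {
  chars <- strsplit(unname(seqs), "")
  L <- length(chars[[1]])
  count <- 0L
  for (col in seq_len(L)) {
    states <- unique(unlist(lapply(chars, `[[`, col)))
    states <- states[states != "-"]
    if (length(states) >= 2L) count <- count + 1L
  }
  count
}

# Closed-form K2P from transition/transversion proportions.
oracle_k2p <- function(P, Q, alpha = NULL) {
  if (is.null(alpha))
    -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
  else
    alpha / 2 * ((1 - 2 * P - Q)^(-1 / alpha) - 1) +
      alpha / 4 * ((1 - 2 * Q)^(-1 / alpha) - 1)
}

# Reference greedy clustering on a variant table (sequence, depth), using
# character-vector comparisons throughout.
oracle_cluster <- function(variants, max_mm = 2L, ratio = 0.25) {
  ord <- order(-variants$depth, variants$sequence)
  variants <- variants[ord, , drop = FALSE]
  clusters <- list()
  for (i in seq_len(nrow(variants))) {
    s <- variants$sequence[i]; d <- variants$depth[i]
    sc <- strsplit(s, "")[[1]]
    near <- c(); mergeable <- c()
    for (k in seq_along(clusters)) {
      dom <- clusters[[k]]$dominant
      if (nchar(dom) != nchar(s)) next
      mm <- sum(strsplit(dom, "")[[1]] != sc)
      if (mm >= 1 && mm <= max_mm) {
        near <- c(near, k)
        if (d <= ratio * clusters[[k]]$dominant_depth)
          mergeable <- c(mergeable, k)
      }
    }
    if (length(mergeable)) {
      dd <- sapply(mergeable, function(k) clusters[[k]]$dominant_depth)
      ds <- sapply(mergeable, function(k) clusters[[k]]$dominant)
      pick <- mergeable[order(-dd, ds)][1]
      clusters[[pick]]$members <- c(clusters[[pick]]$members, s)
      clusters[[pick]]$cluster_depth <- clusters[[pick]]$cluster_depth + d
    } else {
      clusters[[length(clusters) + 1]] <- list(
        dominant = s, dominant_depth = d, cluster_depth = d,
        members = s, subdominant = length(near) > 0)
    }
  }
  clusters
}

# Exhaustive minimal-change parsimony on a rooted/unrooted ape tree for one
# 64-state character: tries every assignment of observed states to internal
# nodes and returns the minimum number of edges whose endpoints differ.
oracle_fitch_count <- function(tree, leaf_states) {
  states <- sort(unique(leaf_states))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  node_states <- character(ntip + nnode)
  node_states[seq_len(ntip)] <- leaf_states[tree$tip.label]
  grid <- expand.grid(rep(list(states), nnode), stringsAsFactors = FALSE)
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    node_states[(ntip + 1):(ntip + nnode)] <- unlist(grid[g, ])
    changes <- sum(node_states[edge[, 1]] != node_states[edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# Two-sided binomial test p-value as an explicit pmf sum (the "small p"
# convention used by stats::binom.test).
oracle_binom_two_sided <- function(x, n, p) {
  pmf <- dbinom(0:n, n, p)
  sum(pmf[pmf <= dbinom(x, n, p) * (1 + 1e-7)])
}

# Enumerate syn/nonsyn steps over all substitution orderings between two
# codons, skipping orderings that pass through a stop codon (using all
# orderings if every one is blocked).
oracle_ng_pair <- function(c1, c2) {
  code <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  perms <- if (length(pos) == 1) list(pos) else {
    out <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { out[[length(out) + 1]] <<- prefix; return() }
      for (r in rest) rec(c(prefix, r), setdiff(rest, r))
    }
    rec(integer(0), pos)
    out
  }
  walk <- function(ord, allow_stop) {
    cur <- c1; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (code[nxt] == "*" && !allow_stop) return(NULL)
      if (code[nxt] == code[cur]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (!length(res)) res <- lapply(perms, walk, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

# Random nucleotide sequence helper.
random_nt <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Compare a called genotype set against the simulator's truth. Individuals
# whose amplicons were all removed by the depth gate are out of scope: pass
# the gated amplicon set to restrict the comparison.
genotype_recovery <- function(sim, geno, kept = NULL) {
  inds <- names(sim$truth$genotypes)
  if (!is.null(kept))
    inds <- intersect(inds, unique(vapply(kept, `[[`, character(1),
                                          "individual_id")))
  ok <- logical(0)
  for (ind in inds) {
    true_seqs <- sort(unname(sim$pool$alleles[sim$truth$genotypes[[ind]]]))
    called <- sort(geno$genotypes$sequence[
      geno$genotypes$individual_id == ind])
    ok[ind] <- identical(true_seqs, called)
  }
  ok
}
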