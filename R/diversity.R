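# Diversity and divergence statistics over aligned allele sets: segregating
# sites, nucleotide diversity, p-distance and Kimura two-parameter (K2P)
# divergence with site-bootstrap standard errors, and Nei-Gojobori dN/dS
# over PBR vs non-PBR codon partitions. Gaps are handled by pairwise
# deletion throughout, so the 3-bp deletion column does not erase
# information from long x long pairs.

# Character matrix (sequences x columns) from equal-length strings.
aln_matrix <- function(seqs) {
  if (length(unique(nchar(seqs))) > 1L)
    stop("alignment error: unequal sequence lengths")
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Align exon-3 alleles into the common coordinate frame
#'
#' Ungapped anchoring: long alleles are used as-is; short alleles get a
#' 3-nt gap inserted at the deletion codon so every sequence spans the same
#' 247 columns.
#'
#' @param seqs Named character vector of 244/247-nt sequences.
#' @param length_class Named "long"/"short" vector (computed with
#'   [classify_length()] when missing).
#' @param deletion_codon Alignment position of the deleted codon (147).
#' @return Named character vector of aligned 247-nt sequences.
#' @export
align_exon3 <- function(seqs, length_class = NULL, deletion_codon = 147L) {
  if (is.null(length_class))
    length_class <- vapply(seqs, classify_length, character(1))
  gap_at <- codon_nt_offset(deletion_codon, short = FALSE)
  out <- vapply(seq_along(seqs), function(i) {
    if (length_class[[i]] == "long") return(seqs[[i]])
    paste0(substr(seqs[[i]], 1L, gap_at - 1L), "---",
           substr(seqs[[i]], gap_at, nchar(seqs[[i]])))
  }, character(1))
  names(out) <- names(seqs)
  out
}

#' Count segregating sites
#'
#' Number of alignment columns with at least two distinct non-gap states;
#' columns that are gapped in some sequences are counted by their non-gap
#' states.
#'
#' @param seqs Named character vector of aligned sequences (nucleotide or
#'   amino acid).
#' @return Integer count.
#' @export
segregating_sites <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  m <- aln_matrix(seqs)
  sum(apply(m, 2, function(col) {
    states <- unique(col[col != "-"])
    length(states) >= 2L
  }))
}

#' Nucleotide diversity (pi)
#'
#' Mean over all unordered sequence pairs of the per-site p-distance, with
#' pairwise deletion of gap positions.
#'
#' @param seqs Named character vector of aligned nucleotide sequences.
#' @return Numeric pi.
#' @export
nucleotide_diversity <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  m <- aln_matrix(seqs)
  n <- nrow(m)
  acc <- 0; npair <- 0L
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    valid <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(valid)) {
      warning("pair with no overlapping sites skipped")
      next
    }
    acc <- acc + sum(m[i, valid] != m[j, valid]) / sum(valid)
    npair <- npair + 1L
  }
  acc / npair
}

# Transition (A<->G, C<->T) indicator for two base vectors.
is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# K2P distance from transition/transversion proportions; gamma-corrected
# when alpha is finite.
k2p_from_pq <- function(P, Q, gamma_alpha = NULL) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  bad <- !is.finite(w1) | !is.finite(w2) | w1 <= 0 | w2 <= 0
  w1[bad] <- NA_real_; w2[bad] <- NA_real_
  d <- if (is.null(gamma_alpha)) {
    -0.5 * log(w1) - 0.25 * log(w2)
  } else {
    a <- gamma_alpha
    a / 2 * (w1^(-1 / a) - 1) + a / 4 * (w2^(-1 / a) - 1)
  }
  d[bad] <- NA_real_
  d
}

#' Pairwise distance between two aligned sequences
#'
#' p-distance (mismatches over overlap) or Kimura two-parameter distance,
#' optionally gamma-rate corrected, with pairwise deletion of gaps.
#'
#' @param a,b Aligned sequences of equal length.
#' @param model "p" or "k2p".
#' @param gamma_alpha Gamma shape for rate variation (K2P only; NULL for
#'   uniform rates).
#' @return Numeric distance; error if the K2P logarithms are undefined or
#'   there is no overlap.
#' @export
pairwise_distance <- function(a, b, model = c("p", "k2p"),
                              gamma_alpha = NULL) {
  model <- match.arg(model)
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  valid <- ca != "-" & cb != "-"
  n <- sum(valid)
  if (n == 0L) stop("no overlapping sites after pairwise gap deletion")
  ca <- ca[valid]; cb <- cb[valid]
  if (model == "p") return(sum(ca != cb) / n)
  P <- sum(is_transition(ca, cb)) / n
  Q <- sum(ca != cb & !is_transition(ca, cb)) / n
  d <- k2p_from_pq(P, Q, gamma_alpha)
  if (is.na(d)) stop("K2P distance undefined for this pair (P=", P,
                     ", Q=", Q, ")")
  d
}

# Per-pair per-column indicator arrays used by the bootstrap machinery.
pair_arrays_nt <- function(m) {
  n <- nrow(m); L <- ncol(m)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  valid <- ts <- tv <- matrix(FALSE, np, L)
  for (k in seq_len(np)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    v <- m[i, ] != "-" & m[j, ] != "-"
    diff <- v & m[i, ] != m[j, ]
    t1 <- diff & is_transition(m[i, ], m[j, ])
    valid[k, ] <- v; ts[k, ] <- t1; tv[k, ] <- diff & !t1
  }
  list(valid = valid, ts = ts, tv = tv)
}

pair_arrays_mismatch <- function(m) {
  n <- nrow(m); L <- ncol(m)
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs)
  valid <- mis <- matrix(FALSE, np, L)
  for (k in seq_len(np)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    v <- m[i, ] != "-" & m[j, ] != "-"
    valid[k, ] <- v
    mis[k, ] <- v & m[i, ] != m[j, ]
  }
  list(valid = valid, mis = mis)
}

mean_pair_distance <- function(arr, model, gamma_alpha, cols) {
  if (model == "p") {
    d <- rowSums(arr$mis[, cols, drop = FALSE]) /
      rowSums(arr$valid[, cols, drop = FALSE])
  } else {
    nv <- rowSums(arr$valid[, cols, drop = FALSE])
    P <- rowSums(arr$ts[, cols, drop = FALSE]) / nv
    Q <- rowSums(arr$tv[, cols, drop = FALSE]) / nv
    d <- k2p_from_pq(P, Q, gamma_alpha)
  }
  mean(d[is.finite(d)])
}

#' Mean evolutionary divergence with bootstrap standard error
#'
#' Average pairwise distance over all sequence pairs; the standard error is
#' the standard deviation of the statistic over site-resampled bootstrap
#' replicates.
#'
#' @param seqs Named character vector of aligned sequences.
#' @param model "p" or "k2p" (K2P valid for nucleotides only).
#' @param gamma_alpha Optional gamma shape (K2P).
#' @param bootstrap Number of replicates (default 1000).
#' @param seed Optional seed for the resampling.
#' @return List with `d`, `se`, `model`, `n`.
#' @export
mean_divergence <- function(seqs, model = c("p", "k2p"), gamma_alpha = NULL,
                            bootstrap = 1000L, seed = NULL) {
  model <- match.arg(model)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  m <- aln_matrix(seqs)
  arr <- if (model == "p") pair_arrays_mismatch(m) else pair_arrays_nt(m)
  L <- ncol(m)
  d <- mean_pair_distance(arr, model, gamma_alpha, seq_len(L))
  if (!is.null(seed)) set.seed(seed)
  reps <- vapply(seq_len(bootstrap), function(r)
    mean_pair_distance(arr, model, gamma_alpha,
                       sample.int(L, L, replace = TRUE)), numeric(1))
  list(d = d, se = stats::sd(reps, na.rm = TRUE), model = model,
       n = length(seqs))
}

#' Build a codon alignment
#'
#' Trims the incomplete-codon overhang from an aligned nucleotide set and
#' splits it into codon columns tagged with alignment amino-acid positions.
#'
#' @param aligned Named character vector of aligned sequences (see
#'   [align_exon3()]).
#' @param aa_start Alignment amino-acid position of the first complete
#'   codon (default 93).
#' @param frame_offset Overhang trimmed from each end (default 2).
#' @return An object of class `codon_alignment`: `codons` (character matrix
#'   sequences x codon columns; "---" marks a gap codon), `aa_positions`,
#'   `ids`.
#' @export
make_codon_alignment <- function(aligned, aa_start = AA_FRAME_START,
                                 frame_offset = 2L) {
  lens <- unique(nchar(aligned))
  if (length(lens) > 1L) stop("alignment error: unequal aligned lengths")
  core_len <- lens - 2L * frame_offset
  if (core_len %% 3L != 0L)
    stop("alignment error: core length ", core_len, " not a multiple of 3")
  n_codon <- core_len %/% 3L
  starts <- frame_offset + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- matrix(vapply(aligned, function(s)
    substring(s, starts, starts + 2L), character(n_codon)),
    ncol = n_codon, byrow = TRUE)
  rownames(codons) <- names(aligned)
  structure(list(codons = codons,
                 aa_positions = seq(aa_start, length.out = n_codon),
                 ids = names(aligned)),
            class = "codon_alignment")
}

#' Partition a codon alignment into PBR and non-PBR sub-alignments
#'
#' @param caln A `codon_alignment`.
#' @param mask Integer vector of alignment amino-acid positions (see
#'   [pbr_mask()]).
#' @return List with `pbr` and `nonpbr` codon alignments; every codon is
#'   assigned to exactly one partition.
#' @export
partition_codons <- function(caln, mask) {
  outside <- setdiff(mask, caln$aa_positions)
  if (length(outside))
    stop("mask position(s) outside the covered frame: ",
         paste(outside, collapse = ", "))
  sel <- caln$aa_positions %in% mask
  sub <- function(keep) {
    structure(list(codons = caln$codons[, keep, drop = FALSE],
                   aa_positions = caln$aa_positions[keep], ids = caln$ids),
              class = "codon_alignment")
  }
  list(pbr = sub(sel), nonpbr = sub(!sel))
}

# Integer codon indices (NA for gaps, ambiguity, stops).
codon_index_matrix <- function(caln) {
  ng <- ng_tables()
  idx <- matrix(codon_index(caln$codons), nrow = nrow(caln$codons))
  idx[!is.na(idx) & is.na(ng$s[idx])] <- NA_integer_
  dimnames(idx) <- dimnames(caln$codons)
  idx
}

#' Nei-Gojobori dN/dS with codon-bootstrap standard errors
#'
#' Pathway-counting estimates of synonymous (dS) and nonsynonymous (dN)
#' substitution rates: per sequence pair, potential sites and
#' pathway-averaged differences are summed over codons complete in both
#' sequences (pairwise codon deletion), proportions are Jukes-Cantor
#' corrected, and the estimates averaged over all pairs. Standard errors
#' come from resampling codon columns; a one-tailed Z-test for dN > dS uses
#' the bootstrap variance of the difference.
#'
#' @param caln A `codon_alignment`.
#' @param bootstrap Number of codon-bootstrap replicates (default 1000).
#' @param seed Optional seed.
#' @return An object of class `dnds_result`: `dN`, `dS`, `dN_se`, `dS_se`,
#'   `ratio` (NA when dS is 0), `z_p` (one-tailed p for dN > dS), `n`.
#' @export
nei_gojobori_dnds <- function(caln, bootstrap = 1000L, seed = NULL) {
  idx <- codon_index_matrix(caln)
  n <- nrow(idx)
  if (n < 2L) stop("need at least 2 sequences")
  ng <- ng_tables()
  pairs <- utils::combn(n, 2)
  np <- ncol(pairs); L <- ncol(idx)
  Sv <- SDm <- NDm <- Vm <- matrix(0, np, L)
  for (k in seq_len(np)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    v <- !is.na(idx[i, ]) & !is.na(idx[j, ])
    ii <- idx[i, v]; jj <- idx[j, v]
    Sv[k, v] <- (ng$s[ii] + ng$s[jj]) / 2
    SDm[k, v] <- ng$SD[cbind(ii, jj)]
    NDm[k, v] <- ng$ND[cbind(ii, jj)]
    Vm[k, v] <- 1
  }
  est <- function(cols) {
    S <- rowSums(Sv[, cols, drop = FALSE])
    V <- rowSums(Vm[, cols, drop = FALSE])
    N <- 3 * V - S
    Sd <- rowSums(SDm[, cols, drop = FALSE])
    Nd <- rowSums(NDm[, cols, drop = FALSE])
    dS <- jc_correct(ifelse(S > 0, Sd / S, NA_real_))
    dN <- jc_correct(ifelse(N > 0, Nd / N, NA_real_))
    c(dN = mean(dN[is.finite(dN)]), dS = mean(dS[is.finite(dS)]))
  }
  point <- est(seq_len(L))
  if (!is.null(seed)) set.seed(seed)
  reps <- t(vapply(seq_len(bootstrap), function(r)
    est(sample.int(L, L, replace = TRUE)), numeric(2)))
  se <- apply(reps, 2, stats::sd, na.rm = TRUE)
  diff_sd <- stats::sd(reps[, "dN"] - reps[, "dS"], na.rm = TRUE)
  z <- if (!is.na(diff_sd) && diff_sd > 0 && is.finite(point["dN"]) &&
           is.finite(point["dS"]))
    (point["dN"] - point["dS"]) / diff_sd else NA_real_
  structure(list(dN = unname(point["dN"]), dS = unname(point["dS"]),
                 dN_se = unname(se["dN"]), dS_se = unname(se["dS"]),
                 ratio = if (is.finite(point["dS"]) && point["dS"] > 0 &&
                             is.finite(point["dN"]))
                   unname(point["dN"] / point["dS"]) else NA_real_,
                 z_p = if (is.na(z)) NA_real_ else
                   stats::pnorm(z, lower.tail = FALSE),
                 n = n), class = "dnds_result")
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("dN = %.3f +/- %.3f, dS = %.3f +/- %.3f, dN/dS = %s (n = %d)\n",
              x$dN, x$dN_se, x$dS, x$dS_se,
              if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio), x$n))
  invisible(x)
}

#' Diversity and selection summary for one allele set
#'
#' Computes the full per-set statistics block: segregating nucleotide and
#' amino-acid sites, nucleotide diversity, mean K2P (gamma = 1) nucleotide
#' divergence and amino-acid p-distance divergence with bootstrap SEs, and
#' Nei-Gojobori dN/dS for the PBR and non-PBR codon partitions.
#'
#' @param seqs Named character vector of unaligned 244/247-nt alleles.
#' @param proteins Named character vector of their fragment proteins
#'   (aligned via the same frame; gaps inserted for short alleles).
#' @param mask PBR mask (default the 12-codon dN/dS set).
#' @param bootstrap Bootstrap replicates.
#' @param seed Optional seed.
#' @return List with `S_nt`, `S_aa`, `pi`, `d_nt`, `d_nt_se`, `d_aa`,
#'   `d_aa_se`, `pbr` and `nonpbr` (`dnds_result`s), `n_nt`, `n_aa`.
#' @export
diversity_summary <- function(seqs, proteins = NULL, mask = pbr_mask("dnds"),
                              bootstrap = 1000L, seed = NULL) {
  aligned <- align_exon3(seqs)
  caln <- make_codon_alignment(aligned)
  if (is.null(proteins)) {
    proteins <- vapply(caln$ids, function(id)
      paste(codon_aa(caln$codons[id, ]), collapse = ""), character(1))
    proteins <- gsub("X", "-", proteins, fixed = TRUE)
  }
  parts <- partition_codons(caln, mask)
  d_nt <- mean_divergence(aligned, "k2p", gamma_alpha = 1,
                          bootstrap = bootstrap, seed = seed)
  d_aa <- mean_divergence(proteins, "p", bootstrap = bootstrap, seed = seed)
  list(S_nt = segregating_sites(aligned),
       S_aa = segregating_sites(proteins),
       pi = nucleotide_diversity(aligned),
       d_nt = d_nt$d, d_nt_se = d_nt$se,
       d_aa = d_aa$d, d_aa_se = d_aa$se,
       pbr = nei_gojobori_dnds(parts$pbr, bootstrap, seed),
       nonpbr = nei_gojobori_dnds(parts$nonpbr, bootstrap, seed),
       n_nt = length(seqs), n_aa = length(unique(proteins)))
}
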