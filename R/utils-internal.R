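# Internal sequence and codon utilities shared across modules.

.amplimhc_cache <- new.env(parent = emptyenv())

#' @importFrom Biostrings GENETIC_CODE
NULL

# Hamming distance between two equal-length strings.
seq_hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# Longest common prefix / suffix length of two equal-length strings.
seq_lcp <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  d <- which(ra != rb)
  if (length(d) == 0L) length(ra) else d[1L] - 1L
}

seq_lcs <- function(a, b) {
  ra <- rev(charToRaw(a)); rb <- rev(charToRaw(b))
  d <- which(ra != rb)
  if (length(d) == 0L) length(ra) else d[1L] - 1L
}

BASES <- c("A", "C", "G", "T")

# Translate an in-frame nucleotide string using the standard genetic code.
translate_nt <- function(nt) {
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3: ", n)
  codons <- substring(nt, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
}

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

# Lexicographic codon list (AAA, AAC, ..., TTT).
codon_universe <- function() {
  g <- expand.grid(p3 = BASES, p2 = BASES, p1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

# Integer index (1..64) of codon strings; NA for anything not pure ACGT.
codon_index <- function(codons) {
  m <- match(codons, codon_universe())
  m
}

# --- Nei-Gojobori machinery ------------------------------------------------
#
# Potential-site counts use the convention that substitutions creating stop
# codons are disregarded: at each codon position the synonymous fraction is
# (synonymous changes) / (changes not producing a stop), so the synonymous
# plus nonsynonymous potential per codon always sums to 3.
#
# Pairwise difference counts average the synonymous/nonsynonymous step
# classification over all orderings (pathways) of the differing positions,
# excluding pathways that pass through a stop codon (falling back to all
# pathways when every one is blocked).

ng_syn_sites_codon <- function(codon) {
  aa0 <- codon_aa(codon)
  if (aa0 == "*" || aa0 == "X") return(NA_real_)
  s <- 0
  ch <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    syn <- 0L; considered <- 0L
    for (b in setdiff(BASES, ch[pos])) {
      mut <- ch; mut[pos] <- b
      aa1 <- codon_aa(paste(mut, collapse = ""))
      if (aa1 == "*") next
      considered <- considered + 1L
      if (aa1 == aa0) syn <- syn + 1L
    }
    if (considered > 0L) s <- s + syn / considered
  }
  s
}

# Pathway-averaged (syn, nonsyn) differences between two sense codons.
ng_pair_diff <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  pos <- which(ch1 != ch2)
  perms <- if (length(pos) == 1L) list(pos) else {
    if (length(pos) == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
      lapply(idx, function(i) pos[i])
    }
  }
  tally <- function(order, allow_stop) {
    cur <- ch1; sd <- 0; nd <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- ch2[p]
      aa_cur <- codon_aa(paste(cur, collapse = ""))
      aa_nxt <- codon_aa(paste(nxt, collapse = ""))
      if (aa_nxt == "*" && !allow_stop) return(NULL)
      if (aa_nxt == aa_cur) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, tally, allow_stop = FALSE))
  if (length(res) == 0L) res <- lapply(perms, tally, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

# Cached lookup tables over the 64-codon universe:
#   s[i]      synonymous potential sites of codon i (NA for stop/invalid)
#   SD[i, j]  pathway-averaged synonymous differences between codons i, j
#   ND[i, j]  nonsynonymous differences
ng_tables <- function() {
  if (!is.null(.amplimhc_cache$ng)) return(.amplimhc_cache$ng)
  univ <- codon_universe()
  aa <- codon_aa(univ)
  sense <- which(aa != "*")
  s <- rep(NA_real_, 64L)
  for (i in sense) s[i] <- ng_syn_sites_codon(univ[i])
  SD <- matrix(NA_real_, 64L, 64L)
  ND <- matrix(NA_real_, 64L, 64L)
  for (i in sense) {
    for (j in sense) {
      if (j < i) { SD[i, j] <- SD[j, i]; ND[i, j] <- ND[j, i]; next }
      d <- ng_pair_diff(univ[i], univ[j])
      SD[i, j] <- d[1]; ND[i, j] <- d[2]
    }
  }
  .amplimhc_cache$ng <- list(codons = univ, aa = aa, s = s, SD = SD, ND = ND)
  .amplimhc_cache$ng
}

# Jukes-Cantor correction of a proportion of differences.
jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  out
}
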