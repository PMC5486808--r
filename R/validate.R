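# Classification, translation and annotation of called exon-3 alleles:
# length classes (247 nt "long" vs 244 nt "short" with a 3-bp deletion at
# alignment codon 147), frame-offset translation, collapsing to protein
# classes, motif annotation, and stable Klein-style allele naming.

#' Classify an exon-3 allele by length
#'
#' @param seq Nucleotide sequence.
#' @param long_length,short_length Expected lengths (247 / 244 nt).
#' @return "long" or "short"; any other length is rejected with an error.
#' @export
classify_length <- function(seq, long_length = 247L, short_length = 244L) {
  n <- nchar(seq)
  if (n == long_length) return("long")
  if (n == short_length) return("short")
  stop("validation error: off-length sequence (", n, " nt; expected ",
       long_length, " or ", short_length, ")")
}

#' Translate an exon-3 fragment
#'
#' Trims `frame_offset` nucleotides of incomplete codon at each end and
#' translates the remainder (243 nt / 81 residues for long alleles, 240 nt /
#' 80 residues for short ones). An internal stop codon flags the allele
#' non-functional rather than raising an error.
#'
#' @param seq Nucleotide sequence.
#' @param frame_offset Incomplete-codon overhang at each end (default 2).
#' @return List with `protein` and `functional` (FALSE if the translation
#'   contains a stop).
#' @export
translate_exon3 <- function(seq, frame_offset = 2L) {
  core <- substr(seq, frame_offset + 1L, nchar(seq) - frame_offset)
  if (nchar(core) %% 3L != 0L)
    stop("validation error: trimmed sequence length ", nchar(core),
         " not a multiple of 3")
  protein <- translate_nt(core)
  list(protein = protein, functional = !grepl("*", protein, fixed = TRUE))
}

#' Collapse nucleotide alleles into identical-protein classes
#'
#' @param proteins Named character vector of protein sequences (names are
#'   allele names).
#' @return List with `class_id` (named integer vector), `members` (list of
#'   allele-name vectors per class), `n_classes`.
#' @export
collapse_proteins <- function(proteins) {
  uniq <- sort(unique(proteins))
  class_id <- match(proteins, uniq)
  names(class_id) <- names(proteins)
  members <- split(names(proteins), class_id)
  list(class_id = class_id, members = unname(members),
       n_classes = length(uniq))
}

# Map an alignment amino-acid position to the residue index within a
# translated fragment (long: positions 93-173; short lacks 147).
aa_index_in_fragment <- function(pos, length_class, aa_start = AA_FRAME_START,
                                 deletion_codon = 147L) {
  if (pos < aa_start || pos > AA_FRAME_END) return(NA_integer_)
  idx <- pos - aa_start + 1L
  if (length_class == "short") {
    if (pos == deletion_codon) return(NA_integer_)
    if (pos > deletion_codon) idx <- idx - 1L
  }
  idx
}

#' Annotate class-diagnostic motifs and conserved-site deviations
#'
#' Reports the residue at alignment position 170 (a conserved main-chain
#' tyrosine in classical MHC-I, seen replaced by histidine or
#' phenylalanine), the presence of the short-allele motif "GENE" at
#' positions 148-151, the long-allele motif "EDGTV" at 147-151, and any
#' deviations from a supplied position -> consensus-residue map.
#'
#' @param protein Fragment protein sequence.
#' @param length_class "long" or "short".
#' @param consensus Named character vector, names = alignment positions;
#'   default checks the main-chain tyrosine at 170.
#' @param aa_start Alignment position of the first fragment residue.
#' @return List with `residue_170`, `has_GENE`, `has_EDGTV`, `deviations`
#'   (data frame position, expected, observed).
#' @export
annotate_motifs <- function(protein, length_class,
                            consensus = c("170" = "Y"),
                            aa_start = AA_FRAME_START) {
  res_at <- function(pos) {
    idx <- aa_index_in_fragment(pos, length_class, aa_start)
    if (is.na(idx) || idx > nchar(protein)) NA_character_
    else substr(protein, idx, idx)
  }
  span <- function(from, to) {
    paste(vapply(from:to, function(p) {
      r <- res_at(p); if (is.na(r)) "" else r
    }, character(1)), collapse = "")
  }
  dev <- do.call(rbind, lapply(names(consensus), function(p) {
    obs <- res_at(as.integer(p))
    if (!is.na(obs) && obs != consensus[[p]])
      data.frame(position = as.integer(p), expected = consensus[[p]],
                 observed = obs, stringsAsFactors = FALSE)
  }))
  if (is.null(dev))
    dev <- data.frame(position = integer(), expected = character(),
                      observed = character(), stringsAsFactors = FALSE)
  list(residue_170 = res_at(170L),
       has_GENE = identical(span(148L, 151L), "GENE"),
       has_EDGTV = identical(span(147L, 151L), "EDGTV"),
       deviations = dev)
}

#' Assign stable allele names
#'
#' Klein-style naming: sequences already in the registry keep their names;
#' novel sequences receive the next free number with the configured prefix,
#' zero-padded to two digits, in the order supplied (callers pass canonical
#' depth-then-lexicographic order).
#'
#' @param seqs Character vector of nucleotide sequences in canonical order.
#' @param registry Optional data frame with `allele_name`, `sequence`.
#' @param prefix Name prefix (default "UA*").
#' @return Data frame `allele_name`, `sequence` covering registry and new
#'   alleles.
#' @export
assign_allele_names <- function(seqs, registry = NULL, prefix = "UA*") {
  if (is.null(registry))
    registry <- data.frame(allele_name = character(), sequence = character(),
                           stringsAsFactors = FALSE)
  if (anyDuplicated(registry$sequence)) {
    d <- registry$sequence[duplicated(registry$sequence)][1]
    conflicting <- unique(registry$allele_name[registry$sequence == d])
    if (length(conflicting) > 1L)
      stop("registry error: sequence carries conflicting names ",
           paste(conflicting, collapse = ", "))
    registry <- registry[!duplicated(registry$sequence), , drop = FALSE]
  }
  nums <- suppressWarnings(as.integer(sub(paste0("^", gsub("([*])", "\\\\\\1",
                                                           prefix)), "",
                                          registry$allele_name)))
  next_num <- if (all(is.na(nums))) 1L else max(nums, na.rm = TRUE) + 1L
  new_seqs <- setdiff(seqs, registry$sequence)
  new_names <- sprintf(paste0(prefix, "%02d"),
                       seq(next_num, length.out = length(new_seqs)))
  out <- rbind(registry,
               data.frame(allele_name = new_names, sequence = new_seqs,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Validate a set of called alleles
#'
#' Runs length classification, translation, protein collapsing and motif
#' annotation over a named vector of allele sequences, mirroring the
#' validation applied to verified exon-3 alleles.
#'
#' @param seqs Named character vector (names = allele names).
#' @param frame_offset Incomplete-codon overhang (default 2).
#' @param consensus Conserved-site map passed to [annotate_motifs()].
#' @return An object of class `allele_validation`: data frame `alleles`
#'   (name, sequence, length, length_class, protein, functional,
#'   protein_class, residue_170, has_GENE, has_EDGTV, n_deviations),
#'   `rejected` (name, length, reason), `classes` (protein class members),
#'   `n_classes`.
#' @export
validate_alleles <- function(seqs, frame_offset = 2L,
                             consensus = c("170" = "Y")) {
  stopifnot(!is.null(names(seqs)))
  rows <- list(); rejected <- list()
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    cls <- tryCatch(classify_length(s), error = function(e) NA_character_)
    if (is.na(cls)) {
      rejected[[nm]] <- data.frame(name = nm, length = nchar(s),
                                   reason = "off-length",
                                   stringsAsFactors = FALSE)
      next
    }
    tr <- translate_exon3(s, frame_offset)
    mot <- annotate_motifs(tr$protein, cls, consensus)
    rows[[nm]] <- data.frame(
      name = nm, sequence = s, length = nchar(s), length_class = cls,
      protein = tr$protein, functional = tr$functional,
      residue_170 = mot$residue_170, has_GENE = mot$has_GENE,
      has_EDGTV = mot$has_EDGTV, n_deviations = nrow(mot$deviations),
      stringsAsFactors = FALSE)
  }
  alleles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), sequence = character(),
               length = integer(), length_class = character(),
               protein = character(), functional = logical(),
               residue_170 = character(), has_GENE = logical(),
               has_EDGTV = logical(), n_deviations = integer(),
               stringsAsFactors = FALSE)
  rownames(alleles) <- NULL
  collapsed <- if (nrow(alleles))
    collapse_proteins(stats::setNames(alleles$protein, alleles$name))
  else list(class_id = integer(), members = list(), n_classes = 0L)
  alleles$protein_class <- if (nrow(alleles))
    unname(collapsed$class_id[alleles$name]) else integer(0)
  rej <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(name = character(), length = integer(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(rej) <- NULL
  structure(list(alleles = alleles, rejected = rej,
                 classes = collapsed$members,
                 n_classes = collapsed$n_classes),
            class = "allele_validation")
}

#' @export
print.allele_validation <- function(x, ...) {
  cat("allele_validation:", nrow(x$alleles), "alleles (",
      sum(x$alleles$length_class == "long"), "long /",
      sum(x$alleles$length_class == "short"), "short ),",
      x$n_classes, "protein classes;", nrow(x$rejected), "rejected\n")
  invisible(x)
}
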