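# Readers and writers for every external representation the pipeline touches:
# FASTA/FASTQ reads, the TSV sample sheet, genotype tables, and Newick trees.

#' Read a FASTA file
#'
#' Returns records in file order with sequences upper-cased. Record ids are
#' the first whitespace-delimited token of the header; the remainder is kept
#' as the description.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `sequence`, `description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path, format = "fasta")
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(headers)))
    stop("malformed FASTA header in ", path)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record '", ids[which(empty)[1]], "' in ", path)
  if (anyDuplicated(ids))
    stop("duplicate record id '", ids[anyDuplicated(ids)], "' in ", path)
  data.frame(id = ids, sequence = unname(seqs), description = unname(desc),
             stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences, or a data frame with
#'   `id` and `sequence` columns (and optionally `description`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    desc <- if ("description" %in% names(seqs)) seqs$description else ""
    ss <- seqs$sequence
  } else {
    ids <- names(seqs)
    desc <- rep("", length(seqs))
    ss <- unname(seqs)
  }
  if (is.null(ids) || any(!nzchar(ids))) stop("all sequences must be named")
  desc <- rep_len(desc, length(ids))
  hdr <- ifelse(nzchar(desc), paste(ids, desc), ids)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ss)) {
    writeLines(paste0(">", hdr[i]), con)
    s <- ss[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet is a TSV with columns `amplicon_id`, `individual_id`,
#' `duplicate_group` (empty for unpaired amplicons) and `reads_path`
#' (resolved relative to the sheet's directory when not absolute).
#'
#' Validation enforces unique amplicon ids, duplicate groups of exactly two
#' rows, and resolvable read paths.
#'
#' @param path Path to the TSV sample sheet.
#' @return A validated data frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  required <- c("amplicon_id", "individual_id", "duplicate_group", "reads_path")
  missing <- setdiff(required, names(sheet))
  if (length(missing))
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  sheet$duplicate_group[is.na(sheet$duplicate_group)] <- ""
  base <- dirname(normalizePath(path))
  abs <- grepl("^(/|[A-Za-z]:)", sheet$reads_path)
  sheet$reads_path[!abs] <- file.path(base, sheet$reads_path[!abs])
  validate_sample_sheet(sheet)
}

#' Validate a sample sheet data frame
#'
#' @param sheet Data frame with sample-sheet columns.
#' @return The sheet, classed `sample_sheet`, if valid.
#' @export
validate_sample_sheet <- function(sheet) {
  if (anyDuplicated(sheet$amplicon_id))
    stop("duplicate amplicon_id in sample sheet")
  grp <- sheet$duplicate_group[nzchar(sheet$duplicate_group)]
  bad <- names(which(table(grp) != 2L))
  if (length(bad))
    stop("duplicate_group values must occur in exactly 2 rows: ",
         paste(bad, collapse = ", "))
  missing <- !file.exists(sheet$reads_path)
  if (any(missing))
    stop("reads_path not resolvable: ",
         paste(sheet$reads_path[missing], collapse = ", "))
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

# Read per-amplicon reads (FASTA or FASTQ; qualities are ignored).
read_reads <- function(path) {
  first <- readLines(path, n = 1L)
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  toupper(as.character(Biostrings::readBStringSet(path, format = fmt)))
}

#' Tally per-amplicon read variants
#'
#' Builds an amplicon set from a sample sheet: each amplicon's reads are
#' collapsed to unique sequence variants with read depths, sorted by depth
#' descending (ties broken lexicographically). Reads containing N are
#' excluded from the tallies (they cannot be alleles); their count is kept
#' in the amplicon's `n_excluded` field.
#'
#' @param sheet A `sample_sheet` (see [read_sample_sheet()]).
#' @return An object of class `amplicon_set`: a list of amplicons, each with
#'   `amplicon_id`, `individual_id`, `duplicate_group`, `variants` (data
#'   frame `sequence`, `depth`), `total_depth`, `n_excluded`.
#' @export
read_amplicons <- function(sheet) {
  sheet <- validate_sample_sheet(as.data.frame(sheet))
  amps <- lapply(seq_len(nrow(sheet)), function(i) {
    reads <- read_reads(sheet$reads_path[i])
    make_amplicon(sheet$amplicon_id[i], sheet$individual_id[i],
                  sheet$duplicate_group[i], reads)
  })
  structure(amps, class = "amplicon_set")
}

# Construct one amplicon from a vector of read strings.
make_amplicon <- function(amplicon_id, individual_id, duplicate_group, reads) {
  has_n <- grepl("N", reads, fixed = TRUE)
  n_excluded <- sum(has_n)
  reads <- reads[!has_n]
  if (length(reads)) {
    tab <- table(reads)
    v <- data.frame(sequence = names(tab), depth = as.integer(tab),
                    stringsAsFactors = FALSE)
    v <- v[order(-v$depth, v$sequence), , drop = FALSE]
    rownames(v) <- NULL
  } else {
    v <- data.frame(sequence = character(), depth = integer(),
                    stringsAsFactors = FALSE)
  }
  list(amplicon_id = amplicon_id, individual_id = individual_id,
       duplicate_group = duplicate_group, variants = v,
       total_depth = sum(v$depth), n_excluded = n_excluded)
}

# Build an amplicon_set directly from pre-tallied variants (used by the
# simulator, which tracks depths rather than materialising every read).
amplicon_set_from_tallies <- function(tallies) {
  amps <- lapply(tallies, function(t) {
    v <- t$variants[order(-t$variants$depth, t$variants$sequence), ,
                    drop = FALSE]
    rownames(v) <- NULL
    list(amplicon_id = t$amplicon_id, individual_id = t$individual_id,
         duplicate_group = t$duplicate_group, variants = v,
         total_depth = sum(v$depth), n_excluded = 0L)
  })
  structure(amps, class = "amplicon_set")
}

#' @export
print.amplicon_set <- function(x, ...) {
  cat("amplicon_set:", length(x), "amplicons;",
      sum(vapply(x, function(a) a$total_depth, numeric(1))), "reads\n")
  invisible(x)
}

#' Write a genotype table
#'
#' Writes a long TSV with one row per (individual, allele) pair and,
#' optionally, a wide presence/absence matrix (individuals x alleles).
#'
#' @param genotypes A `mhc_genotypes` object (see [call_genotypes()]) or a
#'   data frame with `individual_id` and `allele_name` columns.
#' @param path Output TSV path for the long table.
#' @param matrix_path Optional path for the presence/absence matrix.
#' @return Invisibly, `path`.
#' @export
write_genotype_table <- function(genotypes, path, matrix_path = NULL) {
  df <- if (inherits(genotypes, "mhc_genotypes")) genotypes$genotypes
        else genotypes
  utils::write.table(df[, c("individual_id", "allele_name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(matrix_path)) {
    inds <- unique(df$individual_id)
    alleles <- sort(unique(df$allele_name))
    m <- matrix(0L, length(inds), length(alleles),
                dimnames = list(inds, alleles))
    if (nrow(df)) m[cbind(df$individual_id, df$allele_name)] <- 1L
    out <- data.frame(individual_id = inds, m, check.names = FALSE)
    utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a genotype table written by [write_genotype_table()]
#'
#' @param path TSV path.
#' @return Data frame with `individual_id`, `allele_name`.
#' @export
read_genotype_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' Read an aligned FASTA file
#'
#' Like [read_fasta()] but enforces equal aligned lengths.
#'
#' @param path FASTA path.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  recs <- read_fasta(path)
  lens <- nchar(recs$sequence)
  if (length(unique(lens)) > 1L)
    stop("alignment error: unequal aligned lengths (",
         paste(unique(lens), collapse = ", "), ") in ", path)
  stats::setNames(recs$sequence, recs$id)
}

#' Write a phylogenetic tree to Newick
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file path.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
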