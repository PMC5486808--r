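# End-to-end orchestration: simulate (or load) -> depth gate -> cluster ->
# calibrate -> call -> validate -> diversity -> per-site selection, with a
# consolidated, fully recomputable run report.

#' Pipeline configuration
#'
#' @param sim A `simulation_config` (ignored when `sheet` is supplied to
#'   [run_pipeline()]).
#' @param calling A `calling_config`.
#' @param bootstrap Bootstrap replicates for the statistics layer.
#' @param p_threshold Per-site selection classification threshold.
#' @param mask PBR mask for partitioned dN/dS and the selection report.
#' @param seed Seed for the statistics-layer resampling.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            calling = calling_config(),
                            bootstrap = 1000L, p_threshold = 0.1,
                            mask = pbr_mask("dnds"), seed = 1L) {
  structure(list(sim = sim, calling = calling, bootstrap = bootstrap,
                 p_threshold = p_threshold, mask = mask,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Summarize called genotypes
#'
#' Per-individual total / long / short allele counts with population
#' summaries, and the population allele-frequency table (fraction of
#' individuals carrying each allele), split by length class.
#'
#' @param genotypes A `mhc_genotypes` object.
#' @param length_class Named "long"/"short" vector over allele names (from
#'   the validation layer).
#' @return List with `per_individual` (data frame), `mean_alleles`,
#'   `sd_alleles`, `n_only_long`, `n_with_short`, `allele_freq` (data
#'   frame allele_name, length_class, frequency).
#' @export
summarize_genotypes <- function(genotypes, length_class) {
  df <- genotypes$genotypes
  inds <- unique(df$individual_id)
  per <- do.call(rbind, lapply(inds, function(ind) {
    al <- df$allele_name[df$individual_id == ind]
    cls <- length_class[al]
    data.frame(individual_id = ind, n_alleles = length(al),
               n_long = sum(cls == "long", na.rm = TRUE),
               n_short = sum(cls == "short", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per))
    per <- data.frame(individual_id = character(), n_alleles = integer(),
                      n_long = integer(), n_short = integer(),
                      stringsAsFactors = FALSE)
  freq <- if (nrow(df)) {
    tab <- table(df$allele_name)
    data.frame(allele_name = names(tab),
               length_class = unname(length_class[names(tab)]),
               frequency = as.numeric(tab) / length(inds),
               stringsAsFactors = FALSE)
  } else data.frame(allele_name = character(), length_class = character(),
                    frequency = numeric(), stringsAsFactors = FALSE)
  list(per_individual = per,
       mean_alleles = if (nrow(per)) mean(per$n_alleles) else NA_real_,
       sd_alleles = if (nrow(per)) stats::sd(per$n_alleles) else NA_real_,
       n_only_long = sum(per$n_alleles > 0 & per$n_short == 0),
       n_with_short = sum(per$n_short > 0),
       allele_freq = freq)
}

#' Run the full pipeline
#'
#' Either simulates a dataset from `cfg$sim` or loads amplicons from a
#' sample sheet, then runs the four-step filtering cascade, allele
#' validation, diversity/divergence statistics, and the per-site selection
#' test. All stage outputs are collected in the returned report; when
#' `outdir` is given, genotype tables, allele FASTA, the calibration curve,
#' the selection table and a JSON summary are written there.
#'
#' @param cfg A `pipeline_config`.
#' @param sheet Optional `sample_sheet` to use instead of simulation.
#' @param outdir Optional output directory.
#' @return An object of class `mhc_run_report`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), sheet = NULL,
                         outdir = NULL) {
  sim <- NULL
  if (is.null(sheet)) {
    sim <- simulate_dataset(cfg$sim)
    amps <- sim$amplicons
  } else {
    amps <- read_amplicons(sheet)
  }
  gate <- filter_amplicon_depth(amps, cfg$calling)
  geno <- call_genotypes(gate$kept, cfg$calling$frequency_threshold,
                         cfg$calling)
  val <- validate_alleles(stats::setNames(geno$registry$sequence,
                                          geno$registry$allele_name))
  length_class <- stats::setNames(val$alleles$length_class, val$alleles$name)
  summary <- summarize_genotypes(geno, length_class)

  accepted <- stats::setNames(val$alleles$sequence, val$alleles$name)
  stats_block <- selection <- tree <- NULL
  if (length(accepted) >= 3L) {
    stats_block <- diversity_summary(accepted, mask = cfg$mask,
                                     bootstrap = cfg$bootstrap,
                                     seed = cfg$seed)
    aligned <- align_exon3(accepted)
    caln <- make_codon_alignment(aligned)
    tree <- nj_tree(build_distance_matrix(aligned))
    selection <- slac_test(tree, caln, cfg$p_threshold, cfg$mask)
  }

  clusters <- geno$clusters
  n_merged <- sum(vapply(clusters, function(cl)
    sum(vapply(cl, function(c) nrow(c$merged), integer(1))), integer(1)))
  n_subdom <- sum(vapply(clusters, function(cl)
    sum(vapply(cl, `[[`, logical(1), "subdominant")), integer(1)))
  chimera_freqs <- unlist(lapply(clusters, function(cl)
    vapply(Filter(function(c) c$chimera, cl), `[[`, numeric(1),
           "frequency")))
  report <- structure(list(
    n_amplicons_in = length(amps),
    n_amplicons_dropped = nrow(gate$dropped),
    dropped = gate$dropped,
    mean_depth = mean(vapply(gate$kept, function(a) a$total_depth,
                             numeric(1))),
    n_variants_merged = n_merged,
    n_subdominants = n_subdom,
    n_chimera_clusters = length(chimera_freqs),
    max_chimera_frequency = if (length(chimera_freqs))
      max(chimera_freqs) else 0,
    threshold = geno$threshold,
    calibration = geno$calibration,
    duplicate_report = geno$duplicate_report,
    genotypes = geno,
    validation = val,
    summary = summary,
    stats = stats_block,
    selection = selection,
    tree = tree,
    sim = sim,
    config = cfg), class = "mhc_run_report")

  if (!is.null(outdir)) write_run_report(report, outdir)
  report
}

#' @export
print.mhc_run_report <- function(x, ...) {
  cat("MHC amplicon genotyping run\n")
  cat(sprintf("  amplicons: %d in, %d dropped by depth gate\n",
              x$n_amplicons_in, x$n_amplicons_dropped))
  cat(sprintf("  variants merged as artefacts: %d; subdominants: %d\n",
              x$n_variants_merged, x$n_subdominants))
  cat(sprintf("  chimera clusters: %d (max frequency %.4f)\n",
              x$n_chimera_clusters, x$max_chimera_frequency))
  cat(sprintf("  frequency threshold: %.3f%s\n", x$threshold,
              if (!is.null(x$calibration)) " (auto-calibrated)" else ""))
  if (nrow(x$duplicate_report))
    cat(sprintf("  duplicate pairs matching: %d/%d\n",
                sum(x$duplicate_report$match), nrow(x$duplicate_report)))
  cat(sprintf("  alleles: %d (%d long / %d short), %d protein classes\n",
              nrow(x$validation$alleles),
              sum(x$validation$alleles$length_class == "long"),
              sum(x$validation$alleles$length_class == "short"),
              x$validation$n_classes))
  cat(sprintf("  alleles per individual: %.2f +/- %.2f\n",
              x$summary$mean_alleles, x$summary$sd_alleles))
  if (!is.null(x$stats))
    cat(sprintf("  dN/dS: PBR %s, non-PBR %s\n",
                format(round(x$stats$pbr$ratio, 3)),
                format(round(x$stats$nonpbr$ratio, 3))))
  invisible(x)
}

# Serialize the report: TSVs for the tabular pieces, JSON for the scalars.
write_run_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_genotype_table(report$genotypes,
                       file.path(outdir, "genotypes.tsv"),
                       file.path(outdir, "genotype_matrix.tsv"))
  write_fasta(stats::setNames(report$genotypes$registry$sequence,
                              report$genotypes$registry$allele_name),
              file.path(outdir, "alleles.fasta"))
  utils::write.table(report$validation$alleles,
                     file.path(outdir, "allele_validation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$calibration))
    utils::write.table(report$calibration$curve,
                       file.path(outdir, "calibration_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$selection))
    utils::write.table(report$selection,
                       file.path(outdir, "site_selection.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(report$tree))
    write_newick(report$tree, file.path(outdir, "nj_tree.nwk"))
  scalars <- list(
    n_amplicons_in = report$n_amplicons_in,
    n_amplicons_dropped = report$n_amplicons_dropped,
    mean_depth = report$mean_depth,
    n_variants_merged = report$n_variants_merged,
    n_subdominants = report$n_subdominants,
    n_chimera_clusters = report$n_chimera_clusters,
    max_chimera_frequency = report$max_chimera_frequency,
    threshold = report$threshold,
    n_alleles = nrow(report$validation$alleles),
    n_long = sum(report$validation$alleles$length_class == "long"),
    n_short = sum(report$validation$alleles$length_class == "short"),
    n_protein_classes = report$validation$n_classes,
    mean_alleles_per_individual = report$summary$mean_alleles,
    sd_alleles_per_individual = report$summary$sd_alleles)
  jsonlite::write_json(scalars, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
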