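#' Configuration for an end-to-end pipeline run
#'
#' Collects the analysis thresholds (all overridable, defaults are the
#' documented pipeline conventions: ANI 99.9, coverage 95, completeness
#' 95, contamination 5, identity 40, silhouette scan 2..20, matched panels
#' of 95, 999 permutations) together with either a [sim_config()] block or
#' paths to pre-computed inputs.
#'
#' @param sim a [sim_config()] describing the synthetic cohort, or NULL
#'   when `paths` supplies real inputs.
#' @param paths named list of input files (`genomes`, `tree`, `ortho`,
#'   `ani`, `features`) used when `sim` is NULL.
#' @param ani_min,cov_min,min_completeness,max_contamination QC thresholds.
#' @param min_identity family-assignment identity threshold (percent).
#' @param k_min,k_max silhouette scan range.
#' @param n_per_group matched-subsample panel size (clipped to the
#'   smallest habitat pool).
#' @param n_perm PERMANOVA permutations.
#' @param seed root seed; per-stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), paths = NULL,
                            ani_min = 99.9, cov_min = 95,
                            min_completeness = 95, max_contamination = 5,
                            min_identity = 40,
                            k_min = 2, k_max = 20,
                            n_per_group = 95, n_perm = 999, seed = 1) {
  if (is.null(sim) && is.null(paths)) .fail("either sim or paths must be given")
  if (!is.null(paths)) {
    need <- c("genomes", "tree", "ortho", "ani", "features")
    miss <- setdiff(need, names(paths))
    if (length(miss)) .fail("paths missing entries: %s", paste(miss, collapse = ", "))
    gone <- unlist(paths[need])[!file.exists(unlist(paths[need]))]
    if (length(gone)) .fail("input files not found: %s", paste(gone, collapse = ", "))
  }
  structure(list(sim = sim, paths = paths, ani_min = ani_min,
                 cov_min = cov_min, min_completeness = min_completeness,
                 max_contamination = max_contamination,
                 min_identity = min_identity, k_min = k_min, k_max = k_max,
                 n_per_group = n_per_group, n_perm = n_perm, seed = seed),
            class = "pipeline_config")
}

#' Run the full habitat-comparison pipeline
#'
#' Stages, in order: cohort acquisition (simulation or file input), genome
#' QC (completeness/contamination filter, ANI dereplication), cophenetic
#' distances from the strain tree, PAM clustering with silhouette-selected
#' k plus habitat composition and concordance, pan-genome partitioning and
#' phylogenetically matched subsampling, per-Mb feature normalisation, and
#' the statistical layer (PERMANOVA of per-Mb profiles by habitat,
#' habitat-enrichment scan). Re-running with the same config reproduces
#' the report exactly.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, stage artifacts
#'   (TSV/Newick) and `report.json` are written there.
#' @return the run report (list), invisibly classed `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "input"
  report <- list(seed = config$seed)
  tryCatch({
    if (!is.null(config$sim)) {
      cohort <- simulate_cohort(config$sim)
      records <- cohort$records
      tree <- cohort$tree
      ortho <- cohort$ortho
      ani <- cohort$ani_pairs
      features <- cohort$features
    } else {
      records <- read_genomes_tsv(config$paths$genomes)
      tree <- parse_newick(paste(readLines(config$paths$tree), collapse = ""))
      ortho <- read_matrix_tsv(config$paths$ortho)
      ani <- read_genomes_tsv(config$paths$ani)
      features <- read_matrix_tsv(config$paths$features)
    }

    stage <- "qc"
    qf <- quality_filter(records, config$min_completeness, config$max_contamination)
    derep <- dereplicate(qf$kept, ani, config$ani_min, config$cov_min,
                         seed = stage_seed(config$seed, "derep"))
    kept <- derep$kept
    records_kept <- records[records$id %in% kept, , drop = FALSE]
    report$qc <- list(n_input = nrow(records),
                      n_quality_removed = nrow(qf$removed),
                      n_redundant_removed = length(derep$removed),
                      n_kept = length(kept))

    stage <- "distances"
    dmat <- cophenetic_matrix(tree)[kept, kept]

    stage <- "clustering"
    k_max <- min(config$k_max, length(kept) - 1L)
    sel <- select_k(dmat, config$k_min, k_max,
                    seed = stage_seed(config$seed, "pam"))
    assignment <- sel$assignments[[paste0("k", sel$k_best)]]
    habitats <- stats::setNames(records_kept$habitat, records_kept$id)
    taxa <- stats::setNames(records_kept$taxon, records_kept$id)
    report$clustering <- list(k_best = sel$k_best,
                              silhouette = sel$curve,
                              medoids = assignment$medoids,
                              composition = cluster_composition(assignment, habitats),
                              concordance = habitat_concordance(assignment, habitats))

    stage <- "pangenome"
    ortho_kept <- ortho[kept, , drop = FALSE]
    ortho_kept <- ortho_kept[, colSums(ortho_kept) > 0, drop = FALSE]
    units <- stats::setNames(paste(taxa, habitats, sep = "_"), names(taxa))
    part <- partition_pangenome(ortho_kept, units)
    n_pg <- min(config$n_per_group, min(table(habitats)))
    panels <- matched_subsample(dmat, habitats, reference_habitat = "OA",
                                n_per_group = n_pg,
                                seed = stage_seed(config$seed, "match"))
    report$pangenome <- list(summary = part$summary,
                             n_single_copy = length(single_copy_core_families(ortho_kept)),
                             matched_panel_size = n_pg,
                             matched_panels = panels)

    stage <- "profiles"
    sizes <- stats::setNames(records_kept$size_bp, records_kept$id)
    feat_mb <- per_mb(features[kept, , drop = FALSE], sizes)

    stage <- "stats"
    dfeat <- as.matrix(stats::dist(feat_mb))
    adonis <- permanova(dfeat, habitats, n_perm = config$n_perm,
                        seed = stage_seed(config$seed, "permanova"))
    enr <- enrichment_scan(feat_mb, habitats, taxa)
    report$stats <- list(
      permanova = adonis[c("statistic", "df", "p_value", "n_perm", "tier")],
      enrichment = enr)

    if (!is.null(out_dir)) {
      stage <- "write"
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_genomes_tsv(records_kept, file.path(out_dir, "kept_genomes.tsv"))
      write_matrix_tsv(dmat, file.path(out_dir, "cophenetic.tsv"))
      write_genomes_tsv(report$clustering$silhouette,
                        file.path(out_dir, "silhouette_curve.tsv"))
      write_genomes_tsv(data.frame(id = names(assignment$cluster),
                                   cluster = assignment$cluster),
                        file.path(out_dir, "assignment.tsv"))
      write_genomes_tsv(report$clustering$composition,
                        file.path(out_dir, "composition.tsv"))
      write_matrix_tsv(feat_mb, file.path(out_dir, "features_per_mb.tsv"))
      write_genomes_tsv(enr, file.path(out_dir, "enrichment.tsv"))
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = 10, force = TRUE)
    }
    invisible(structure(report, class = "pipeline_report"))
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  cat(sprintf("  QC: %d genomes in, %d kept (%d quality, %d redundant removed)\n",
              x$qc$n_input, x$qc$n_kept, x$qc$n_quality_removed,
              x$qc$n_redundant_removed))
  cat(sprintf("  clustering: k_best = %d (mean silhouette %.3f)\n",
              x$clustering$k_best,
              max(x$clustering$silhouette$silhouette)))
  s <- x$pangenome$summary
  cat(sprintf("  pan-genome: %d families (core %d [%.2f%%], accessory %d [%.2f%%], specific %d [%.2f%%])\n",
              s$n_total, s$n_core, s$core_pct, s$n_accessory,
              s$accessory_pct, s$n_specific, s$specific_pct))
  cat(sprintf("  PERMANOVA habitat effect: pseudo-F = %.3f, p = %.4g\n",
              x$stats$permanova$statistic, x$stats$permanova$p_value))
  invisible(x)
}
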