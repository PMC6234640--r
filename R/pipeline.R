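## run one named stage, aborting with the stage name on error
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## deterministic manifest: inputs, seed, and md5 of every written file
.write_manifest <- function(out_dir, files, seed, inputs) {
  manifest <- list(
    package = "ascertainr",
    version = as.character(utils::packageVersion("ascertainr")),
    seed = seed,
    inputs = inputs,
    files = lapply(stats::setNames(files, basename(files)),
                   function(f) unname(tools::md5sum(f))))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

#' End-to-end empirical analysis of a panel and disease-locus table
#'
#' Runs the empirical summaries on a (real or synthetic) panel: category
#' summaries, African/non-African frequency differences by risk-allele
#' state, DAF-binned differences, joint site frequency spectra of the
#' disease loci (pooled non-African vs African, by risk state), and --
#' when genotypes are supplied -- uncorrected and corrected genetic risk
#' scores. All outputs are tab-separated files plus a JSON manifest with
#' md5 checksums; reruns with the same inputs and seed are byte-identical.
#'
#' @param panel an `asc_panel`.
#' @param disease_table disease-locus data frame.
#' @param genotypes optional `asc_genotypes` for risk scores.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the manifest (the empirical path
#'   is deterministic).
#' @param constants [correction_constants()] used for corrected scores.
#' @param sfs_bins bins for the joint SFS matrices.
#' @return invisibly, a list of the computed tables.
#' @export
run_empirical_analysis <- function(panel, disease_table, genotypes = NULL,
                                   out_dir, seed = 1L,
                                   constants = correction_constants(),
                                   sfs_bins = 10L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  cats <- .stage("category_summaries", category_summaries(disease_table, panel))
  files <- c(files, .write_tsv(cats, file.path(out_dir, "category_summaries.tsv")))

  state <- .stage("state_differences",
                  frequency_difference_by_state(disease_table, panel))
  files <- c(files, .write_tsv(state, file.path(out_dir, "state_differences.tsv")))

  bins <- .stage("daf_bin_differences", daf_bin_differences(disease_table, panel))
  files <- c(files, .write_tsv(bins, file.path(out_dir, "daf_bin_differences.tsv")))

  sfs <- .stage("joint_sfs", {
    idx <- .join_loci(disease_table, panel)
    lapply(stats::setNames(c("ancestral", "derived"), c("ancestral", "derived")),
           function(state) {
             sub <- as.data.frame(panel)[idx[disease_table$risk_state == state], ,
                                         drop = FALSE]
             joint_sfs_counts(as_panel(sub), "nonAFR", "AFR", bins = sfs_bins)
           })
  })
  for (sfs_state in names(sfs)) {
    f <- file.path(out_dir, paste0("joint_sfs_", sfs_state, ".tsv"))
    utils::write.table(sfs[[sfs_state]], f, sep = "\t", quote = FALSE,
                       col.names = NA)
    files <- c(files, f)
  }

  scores <- NULL
  if (!is.null(genotypes)) {
    scores <- .stage("risk_scores",
                     grs_table(genotypes, disease_table, constants))
    files <- c(files, .write_tsv(scores, file.path(out_dir, "grs.tsv")))
  }

  .write_manifest(out_dir, files, seed, inputs = list(
    n_panel_snps = nrow(panel),
    n_disease_loci = nrow(disease_table),
    n_individuals = if (is.null(genotypes)) 0L else nrow(genotypes$counts),
    panel_provenance = attr(panel, "provenance")))
  invisible(list(category_summaries = cats, state_differences = state,
                 daf_bin_differences = bins, joint_sfs = sfs, grs = scores))
}

#' Simulation study over study cohorts and risk-allele states
#'
#' Runs [run_replicates()] for every combination of study cohort and
#' risk-allele state on a fixed platform and writes a summary table (one
#' row per cell, with across-replicate means and SDs of the per-population
#' risk-allele frequencies and African/non-African differences), a
#' representative replicate's accepted-locus table, and a manifest.
#'
#' @param panel an `asc_panel`.
#' @param config base [sim_config()]; its `study_pop` and `risk_state` are
#'   overridden by the grid, its `seed` drives all cells deterministically.
#' @param study_pops study cohorts to simulate.
#' @param risk_states risk-allele states to simulate.
#' @param n_reps replicates per cell.
#' @param out_dir output directory.
#' @return invisibly, the summary data frame.
#' @export
run_simulation_study <- function(panel, config,
                                 study_pops = c(ASC_POPULATIONS, "MIX"),
                                 risk_states = c("ancestral", "derived"),
                                 n_reps = 10L, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- expand.grid(study_pop = study_pops, risk_state = risk_states,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  example <- NULL
  for (k in seq_len(nrow(grid))) {
    cfg <- config
    cfg$study_pop <- grid$study_pop[k]
    cfg$risk_state <- grid$risk_state[k]
    cfg$seed <- .child_seed(config$seed, 200000L + k)
    s <- .stage(paste0("simulate[", cfg$study_pop, ",", cfg$risk_state, "]"),
                run_replicates(panel, cfg, n_reps))
    row <- data.frame(study_pop = cfg$study_pop, risk_state = cfg$risk_state,
                      platform = cfg$platform, n_reps = n_reps,
                      stringsAsFactors = FALSE)
    row[names(s$mean)] <- as.list(s$mean)
    row[paste0("sd_", names(s$sd))] <- as.list(s$sd)
    rows[[k]] <- row
    if (is.null(example)) {
      cfg1 <- cfg
      cfg1$seed <- .child_seed(cfg$seed, 1L)
      example <- rejection_sample_associations(panel, cfg1)$loci
    }
  }
  summary <- do.call(rbind, rows)
  files <- c(.write_tsv(summary, file.path(out_dir, "simulation_summary.tsv")),
             .write_tsv(example, file.path(out_dir, "example_replicate_loci.tsv")))
  .write_manifest(out_dir, files, config$seed, inputs = list(
    n_panel_snps = nrow(panel), platform = config$platform,
    n_target = config$n_target, n_reps = n_reps,
    effect_model = config$effect_model))
  invisible(summary)
}
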