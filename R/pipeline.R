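#' Study-level summary statistics
#'
#' The headline descriptive numbers of a strain-resolved
#' metatranscriptome experiment: the detected-gene universe, strains
#' detected per sample, per-phylogroup strain detection counts, detected
#' photosynthetic-eukaryote RuBisCO targets, the NMDS stress, and median
#' treatment-to-reference distances.
#'
#' @param pas a [PhytoArraySet].
#' @param design the [ArrayDesign].
#' @param config an [analysisConfig()].
#' @return list of summaries.
#' @export
summarizeStudy <- function(pas, design, config = analysisConfig()) {
  sheet <- as.data.frame(SummarizedExperiment::colData(pas))
  flags <- detected(pas)
  sp <- detectStrains(flags, design, half_rule = config$half_rule)
  cat_ <- strainCatalog(design)
  per_group <- data.frame(
    phylogroup = sort(unique(cat_$phylogroup_id)),
    stringsAsFactors = FALSE)
  pres_any <- rowSums(sp$presence) >= 1
  pres_most <- rowSums(sp$presence) >= max(1, ncol(flags) - 3)
  per_group$detected_ge1 <- vapply(per_group$phylogroup, function(g)
    sum(pres_any[cat_$phylogroup_id == g]), 0L)
  per_group$detected_most <- vapply(per_group$phylogroup, function(g)
    sum(pres_most[cat_$phylogroup_id == g]), 0L)
  per_group$total <- as.vector(table(cat_$phylogroup_id)[
    per_group$phylogroup])
  tg <- targetInfo(design)
  pe_rbcL <- tg$target_id[tg$phylogroup_id == "PE" &
                          tg$gene_symbol == "rbcL"]
  D <- euclideanDistances(pas)
  ord <- nmds(D, dim = config$nmds_dim, restarts = config$nmds_restarts,
              seed = config$rng_seed)
  list(
    n_detected_genes = sum(rowSums(flags) > 0),
    strains_per_sample_mean = mean(colSums(sp$presence)),
    strains_per_sample_sd = stats::sd(colSums(sp$presence)),
    strain_detection_by_group = per_group,
    n_pe_rbcL_detected = sum(rowSums(flags[
      rownames(flags) %in% pe_rbcL, , drop = FALSE]) > 0),
    nmds_stress = ord$stress,
    median_distances = groupDistanceSummary(D, sheet)
  )
}

#' Run the full pipeline and emit every result table
#'
#' Orchestrates all stages on supplied data, or on a freshly simulated
#' synthetic community when \code{raw} is \code{NULL}. Every stage's
#' result table is written to \code{outdir} as tab-delimited text, and
#' the effective configuration is logged verbatim for provenance.
#'
#' @param outdir output directory (created if needed).
#' @param raw probe x sample intensity matrix, or \code{NULL} to
#'   simulate.
#' @param design,sheet design and sample sheet (required with
#'   \code{raw}).
#' @param truth a [truthConfig()] used when simulating (default
#'   [defaultTruthConfig()] seeded from the config).
#' @param config an [analysisConfig()].
#' @return invisible list with all intermediate objects.
#' @export
runPipeline <- function(outdir, raw = NULL, design = NULL, sheet = NULL,
                        truth = NULL, config = analysisConfig()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  writeConfig(config, file.path(outdir, "config_used.yaml"))
  truth_out <- NULL
  if (is.null(raw)) {
    if (is.null(design)) design <- simulateDesign(seed = config$rng_seed)
    if (is.null(truth)) truth <- defaultTruthConfig(seed = config$rng_seed)
    sim <- simulateExperiment(design, truth)
    raw <- sim$intensities
    sheet <- sim$sheet
    truth_out <- sim$truth
    writeTruth(truth_out, file.path(outdir, "truth.tsv"))
  }
  stopifnot(!is.null(design), !is.null(sheet))
  writeDesign(design, file.path(outdir, "design.tsv"))
  writeSampleSheet(sheet, file.path(outdir, "samples.tsv"))
  writeIntensities(raw, file.path(outdir, "intensities.tsv"))

  pas <- preprocessExperiment(raw, design, sheet, config)
  writeMatrixTSV(log2Values(pas), file.path(outdir, "expression.tsv"),
                 "target_id")
  writeMatrixTSV(detected(pas) + 0L, file.path(outdir, "detected.tsv"),
                 "target_id")

  sp <- detectStrains(detected(pas), design, half_rule = config$half_rule)
  writeMatrixTSV(sp$presence + 0L, file.path(outdir, "strain_presence.tsv"),
                 "strain_id")
  ab <- strainAbundance(pas, design)
  writeMatrixTSV(ab, file.path(outdir, "strain_abundance.tsv"), "strain_id")
  pp <- phylogroupProportions(pas, design)
  writeMatrixTSV(pp$per_condition,
                 file.path(outdir, "phylogroup_proportions.tsv"),
                 "phylogroup")

  de_list <- fitAllContrasts(pas, config)
  for (nm in names(de_list))
    .writeTSV(de_list[[nm]], file.path(outdir, paste0("de_", nm, ".tsv")))

  sets <- buildGeneSets(design, scope_mode = "phylogroup")
  set_results <- testGeneSets(de_list, sets, config)
  .writeTSV(set_results, file.path(outdir, "set_results.tsv"))
  .writeTSV(summarizeResponses(set_results),
            file.path(outdir, "fig2_table.tsv"))

  mod <- detectModules(pas, config)
  .writeTSV(data.frame(target_id = names(mod$modules),
                       module = mod$modules, row.names = NULL),
            file.path(outdir, "modules.tsv"))
  if (!is.null(mod$eigengenes))
    writeMatrixTSV(mod$eigengenes, file.path(outdir, "eigengenes.tsv"),
                   "module")

  D <- euclideanDistances(pas)
  med <- groupDistanceSummary(D, sheet)
  ord_samples <- unlist(lapply(seq_len(nrow(med)), function(i)
    sheet$sample_id[sheet$timepoint == med$timepoint[i] &
                    sheet$treatment == med$treatment[i]]))
  writeMatrixTSV(D[ord_samples, ord_samples],
                 file.path(outdir, "distances.tsv"), "sample_id")
  .writeTSV(med, file.path(outdir, "median_distances.tsv"))
  ord <- nmds(D, dim = config$nmds_dim, restarts = config$nmds_restarts,
              seed = config$rng_seed)
  writeMatrixTSV(ord$points, file.path(outdir, "nmds_coords.tsv"),
                 "sample_id")
  writeLines(format(ord$stress, digits = 15),
             file.path(outdir, "nmds_stress.txt"))

  invisible(list(design = design, sheet = sheet, raw = raw,
                 truth = truth_out, pas = pas, strain_presence = sp,
                 strain_abundance = ab, phylogroup_proportions = pp,
                 de = de_list, sets = sets, set_results = set_results,
                 modules = mod, distances = D, median_distances = med,
                 nmds = ord))
}
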