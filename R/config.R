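#' Analysis configuration
#'
#' Collects the tunable parameters of the pipeline with their defaults:
#' the fold-change threshold of the single-gene test (1.2), the
#' single-gene and set-level significance cutoffs (BH-adjusted 0.05 and
#' 0.01), the order statistic used by Wilkinson's combination (r = 2),
#' the negative-control SD multiplier for detection calling (k = 2), the
#' scale-free fit target for soft-power selection, minimum co-expression
#' module size, NMDS dimensionality and restarts, and the RNG seed.
#'
#' @param fc_threshold fold change the single-gene test must exceed
#'   (dimensionless, >= 1).
#' @param alpha_gene BH-adjusted significance level for single genes.
#' @param alpha_set BH-adjusted significance level for gene sets.
#' @param wilkinson_r order statistic for Wilkinson's method.
#' @param detection_k SD multiplier over negative-control mean.
#' @param soft_power_target_r2 scale-free topology fit target R^2.
#' @param min_module_size smallest reportable co-expression module.
#' @param cut_height_frac static tree-cut height as a fraction of the
#'   maximum merge height.
#' @param network_detect_frac fraction of T24 samples in which a target
#'   must be detected to enter the co-expression network.
#' @param nmds_dim,nmds_restarts NMDS embedding dimension and number of
#'   random restarts.
#' @param normalize_level \code{"target"} (summarize probes, then
#'   quantile-normalize target columns) or \code{"probe"} (normalize
#'   probe-level columns first).
#' @param n_perm permutation draws shared by the base set statistics
#'   and the ensemble calibration.
#' @param bh_scope \code{"per_contrast"} or \code{"global"} BH adjustment
#'   for single-gene p-values.
#' @param half_rule \code{"ceiling"} or \code{"floor"} reading of the
#'   "at least half of their targets" strain-presence rule.
#' @param rng_seed integer seed driving every stochastic step.
#' @return A named list of class \code{"AnalysisConfig"}.
#' @examples
#' cfg <- analysisConfig(rng_seed = 1)
#' cfg$fc_threshold
#' @export
analysisConfig <- function(fc_threshold = 1.2,
                           alpha_gene = 0.05,
                           alpha_set = 0.01,
                           wilkinson_r = 2,
                           detection_k = 2,
                           soft_power_target_r2 = 0.8,
                           min_module_size = 10,
                           cut_height_frac = 0.98,
                           network_detect_frac = 0.75,
                           nmds_dim = 2,
                           nmds_restarts = 20,
                           normalize_level = c("target", "probe"),
                           n_perm = 10000,
                           bh_scope = c("per_contrast", "global"),
                           half_rule = c("ceiling", "floor"),
                           rng_seed = 1L) {
  normalize_level <- match.arg(normalize_level)
  bh_scope <- match.arg(bh_scope)
  half_rule <- match.arg(half_rule)
  stopifnot(fc_threshold >= 1,
            alpha_gene > 0, alpha_gene < 1,
            alpha_set > 0, alpha_set < 1,
            wilkinson_r >= 1,
            detection_k >= 0,
            min_module_size >= 2,
            nmds_dim >= 1, nmds_restarts >= 0)
  cfg <- list(fc_threshold = fc_threshold, alpha_gene = alpha_gene,
              alpha_set = alpha_set, wilkinson_r = wilkinson_r,
              detection_k = detection_k,
              soft_power_target_r2 = soft_power_target_r2,
              min_module_size = min_module_size,
              cut_height_frac = cut_height_frac,
              network_detect_frac = network_detect_frac,
              nmds_dim = nmds_dim, nmds_restarts = nmds_restarts,
              normalize_level = normalize_level,
              n_perm = n_perm,
              bh_scope = bh_scope, half_rule = half_rule,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "AnalysisConfig"
  cfg
}

#' Read an analysis configuration from a flat YAML file
#'
#' Keys absent from the file keep their [analysisConfig()] defaults;
#' unknown keys are an error so typos do not silently fall back.
#'
#' @param path path to a flat key-value YAML file.
#' @param ... overrides applied after the file (e.g. from command-line
#'   flags).
#' @return An \code{AnalysisConfig}.
#' @export
readConfig <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(analysisConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(analysisConfig, vals)
}

#' @export
print.AnalysisConfig <- function(x, ...) {
  cat("AnalysisConfig\n")
  for (k in names(x)) cat(sprintf("  %-22s %s\n", k, format(x[[k]])))
  invisible(x)
}

writeConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
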