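#' Call strain presence from detection flags
#'
#' A strain is present in a sample when at least five of its gene
#' targets are detected there, or — for strains with fewer than five
#' targets — at least half of them ("half" read as the ceiling, so 2 of
#' 3; config-exposed via \code{half_rule}).
#'
#' @param flags target x sample logical detection matrix (rows named by
#'   target id).
#' @param design an [ArrayDesign].
#' @param half_rule \code{"ceiling"} (default) or \code{"floor"}.
#' @return list with \code{presence} (strain x sample logical matrix)
#'   and \code{counts} (strain x sample detected-target counts).
#' @examples
#' d <- simulateDesign(2, 3, c(6, 8), c(2, 2), seed = 4)
#' sim <- simulateExperiment(d, truthConfig(seed = 4))
#' pas <- preprocessExperiment(sim$intensities, d, sim$sheet)
#' sp <- detectStrains(detected(pas), d)
#' colSums(sp$presence)  # strains present per sample
#' @export
detectStrains <- function(flags, design, half_rule = c("ceiling", "floor")) {
  half_rule <- match.arg(half_rule)
  tg <- targetInfo(design)
  cat_ <- strainCatalog(design)
  if (any(cat_$n_targets == 0))
    stop("design integrity error: strain with zero targets")
  strain_of <- tg$strain_id[match(rownames(flags), tg$target_id)]
  if (anyNA(strain_of)) stop("detection flags not aligned to design")
  counts <- rowsum(flags + 0L, strain_of)
  counts <- counts[cat_$strain_id, , drop = FALSE]
  half <- if (half_rule == "ceiling") ceiling(cat_$n_targets / 2)
          else floor(cat_$n_targets / 2)
  required <- ifelse(cat_$n_targets < 5, half, 5)
  presence <- sweep(counts, 1, required, FUN = ">=")
  list(presence = presence, counts = counts)
}

## linear-scale transcript signal of detected cells, 0 otherwise
.detectedLinear <- function(pas) {
  2^log2Values(pas) * detected(pas)
}

#' Per-strain relative transcript abundance
#'
#' For strain \code{s} in sample \code{j}: the strain's share of the
#' sample's total detected linear-scale transcript signal, divided by
#' the strain's number of gene targets on the array, scaled to 1e5.
#' Undetected cells contribute nothing. The score is invariant to a
#' global rescaling of a sample's intensities.
#'
#' @param pas a [PhytoArraySet].
#' @param design an [ArrayDesign].
#' @return strain x sample numeric matrix.
#' @export
strainAbundance <- function(pas, design) {
  lin <- .detectedLinear(pas)
  tot <- colSums(lin)
  if (any(tot == 0))
    stop("sample(s) with zero detected transcripts: ",
         paste(colnames(lin)[tot == 0], collapse = ", "))
  tg <- targetInfo(design)
  cat_ <- strainCatalog(design)
  strain_of <- tg$strain_id[match(rownames(lin), tg$target_id)]
  ssum <- rowsum(lin, strain_of)[cat_$strain_id, , drop = FALSE]
  sweep(sweep(ssum, 2, tot, "/"), 1, cat_$n_targets, "/") * 1e5
}

#' Phylogroup transcript proportions
#'
#' Per sample, each phylogroup's share of total detected transcript
#' signal (shares sum to 1 across phylogroups), then averaged over
#' replicates of each (timepoint, treatment) condition. The per-sample
#' shares also feed the set-level abundance-artifact term.
#'
#' @param pas a [PhytoArraySet] with the sample sheet as column data.
#' @param design an [ArrayDesign].
#' @return list with \code{per_sample} (phylogroup x sample) and
#'   \code{per_condition} (phylogroup x condition means).
#' @export
phylogroupProportions <- function(pas, design) {
  lin <- .detectedLinear(pas)
  tot <- colSums(lin)
  if (any(tot == 0))
    stop("sample(s) with zero detected transcripts: ",
         paste(colnames(lin)[tot == 0], collapse = ", "))
  tg <- targetInfo(design)
  group_of <- tg$phylogroup_id[match(rownames(lin), tg$target_id)]
  gsum <- rowsum(lin, group_of)
  per_sample <- sweep(gsum, 2, tot, "/")
  sheet <- as.data.frame(SummarizedExperiment::colData(pas))
  cond <- .conditionOf(sheet)[match(colnames(per_sample), sheet$sample_id)]
  per_condition <- t(rowsum(t(per_sample), cond) / as.vector(table(cond)[
    sort(unique(cond))]))
  list(per_sample = per_sample, per_condition = per_condition)
}
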