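#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ArrayDesign: probe-to-taxon hierarchy of a functional-gene microarray
#'
#' An \code{ArrayDesign} describes the layout of a multi-strain
#' functional-gene array: each probe interrogates exactly one gene target,
#' each target belongs to one strain, and each strain to one phylogroup.
#' Negative-control and spike-in probes are carried separately and map to
#' no target.
#'
#' @slot probes data.frame with columns \code{probe_id}, \code{target_id}.
#' @slot targets data.frame with columns \code{target_id},
#'   \code{gene_symbol}, \code{process_label}, \code{strain_id},
#'   \code{phylogroup_id} and optional \code{ecotype_label}.
#' @slot controls data.frame with columns \code{probe_id},
#'   \code{control_role} (one of \code{"negative"}, \code{"spike_in"}).
#'
#' @seealso [readDesign()], [simulateDesign()], [strainCatalog()]
#' @export
setClass("ArrayDesign",
  representation(
    probes = "data.frame",
    targets = "data.frame",
    controls = "data.frame"
  )
)

.validArrayDesign <- function(object) {
  msg <- character(0)
  pr <- object@probes
  tg <- object@targets
  ct <- object@controls
  need_p <- c("probe_id", "target_id")
  need_t <- c("target_id", "gene_symbol", "process_label", "strain_id",
              "phylogroup_id")
  if (!all(need_p %in% names(pr)))
    msg <- c(msg, "probes must have columns probe_id, target_id")
  if (!all(need_t %in% names(tg)))
    msg <- c(msg, paste("targets must have columns",
                        paste(need_t, collapse = ", ")))
  if (length(msg)) return(msg)
  if (anyDuplicated(pr$probe_id))
    msg <- c(msg, "duplicate probe ids")
  if (anyDuplicated(tg$target_id))
    msg <- c(msg, "duplicate target ids")
  if (!all(pr$target_id %in% tg$target_id))
    msg <- c(msg, "probe mapped to a target absent from the target table")
  # one strain per target and one phylogroup per strain are structural:
  # targets has one row per target; check strain -> phylogroup is a function
  sp <- unique(tg[, c("strain_id", "phylogroup_id")])
  if (anyDuplicated(sp$strain_id))
    msg <- c(msg, "a strain maps to more than one phylogroup")
  if (nrow(ct)) {
    if (!all(c("probe_id", "control_role") %in% names(ct)))
      msg <- c(msg, "controls must have columns probe_id, control_role")
    else {
      if (!all(ct$control_role %in% c("negative", "spike_in")))
        msg <- c(msg, "control_role must be 'negative' or 'spike_in'")
      if (any(ct$probe_id %in% pr$probe_id))
        msg <- c(msg, "control probes must map to no target")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("ArrayDesign", .validArrayDesign)

#' Construct an ArrayDesign
#'
#' @param probes data.frame mapping \code{probe_id} to \code{target_id}.
#' @param targets data.frame of target annotation (see
#'   \linkS4class{ArrayDesign}).
#' @param controls data.frame of control probes; may be empty.
#' @return A validated \linkS4class{ArrayDesign}.
#' @examples
#' d <- ArrayDesign(
#'   probes = data.frame(probe_id = c("p1", "p2", "p3"),
#'                       target_id = c("t1", "t1", "t2")),
#'   targets = data.frame(target_id = c("t1", "t2"),
#'                        gene_symbol = c("ntcA", "rbcL"),
#'                        process_label = c("N", "C"),
#'                        strain_id = c("s1", "s2"),
#'                        phylogroup_id = c("Pro", "Syn")))
#' strainCatalog(d)
#' @export
ArrayDesign <- function(probes, targets,
                        controls = data.frame(probe_id = character(0),
                                              control_role = character(0))) {
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  controls <- as.data.frame(controls, stringsAsFactors = FALSE)
  if (is.null(targets$ecotype_label)) targets$ecotype_label <- NA_character_
  rownames(probes) <- NULL
  rownames(targets) <- NULL
  rownames(controls) <- NULL
  new("ArrayDesign", probes = probes, targets = targets, controls = controls)
}

setMethod("show", "ArrayDesign", function(object) {
  cat("ArrayDesign with", nrow(object@probes), "probes,",
      nrow(object@targets), "targets,",
      length(unique(object@targets$strain_id)), "strains,",
      length(unique(object@targets$phylogroup_id)), "phylogroups,",
      nrow(object@controls), "control probes\n")
})

#' PhytoArraySet: normalized target-level expression with detection flags
#'
#' Extends \linkS4class{SummarizedExperiment} with two mandatory assays:
#' \code{"log2"} (normalized log2 target intensities) and \code{"detected"}
#' (per-cell logical detection calls against negative-control probes).
#' Row data carry the target annotation from the [ArrayDesign]; column
#' data carry the sample sheet. Normalization provenance is stored in
#' \code{metadata(x)$provenance}.
#'
#' @seealso [preprocessExperiment()], [detected()], [log2Values()]
#' @export
setClass("PhytoArraySet", contains = "SummarizedExperiment")

.validPhytoArraySet <- function(object) {
  msg <- character(0)
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("log2", "detected") %in% an))
    msg <- c(msg, "assays 'log2' and 'detected' are required")
  else {
    v <- SummarizedExperiment::assay(object, "log2")
    d <- SummarizedExperiment::assay(object, "detected")
    if (!all(is.finite(v))) msg <- c(msg, "log2 values must be finite")
    if (!is.logical(d)) msg <- c(msg, "'detected' assay must be logical")
  }
  if (length(msg)) msg else TRUE
}
setValidity("PhytoArraySet", .validPhytoArraySet)

#' Construct a PhytoArraySet
#'
#' @param log2 target x sample matrix of normalized log2 intensities.
#' @param detected logical matrix of the same shape.
#' @param rowData target annotation (one row per target).
#' @param colData sample sheet (one row per sample).
#' @param provenance list of normalization parameters, stored in metadata.
#' @return A \linkS4class{PhytoArraySet}.
#' @export
PhytoArraySet <- function(log2, detected, rowData = NULL, colData = NULL,
                          provenance = list()) {
  args <- list(assays = list(log2 = log2, detected = detected))
  if (!is.null(rowData)) args$rowData <- rowData
  if (!is.null(colData)) args$colData <- S4Vectors::DataFrame(colData)
  se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
  out <- new("PhytoArraySet", se)
  S4Vectors::metadata(out)$provenance <- provenance
  out
}

setMethod("show", "PhytoArraySet", function(object) {
  cat("PhytoArraySet:", nrow(object), "targets x", ncol(object), "samples;",
      sum(SummarizedExperiment::assay(object, "detected")),
      "detected cells\n")
  callNextMethod()
})
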