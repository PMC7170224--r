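#' Accessors for design and expression objects
#'
#' \code{probeInfo}, \code{targetInfo} and \code{controlInfo} return the
#' annotation tables of an [ArrayDesign]; \code{strainCatalog} tabulates
#' strains with their phylogroup and number of gene targets;
#' \code{log2Values} and \code{detected} return the two assays of a
#' [PhytoArraySet].
#'
#' @param x An \linkS4class{ArrayDesign} or \linkS4class{PhytoArraySet}.
#' @return A data.frame (design accessors) or matrix (assay accessors).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("probeInfo", function(x) standardGeneric("probeInfo"))
#' @rdname accessors
#' @export
setGeneric("targetInfo", function(x) standardGeneric("targetInfo"))
#' @rdname accessors
#' @export
setGeneric("controlInfo", function(x) standardGeneric("controlInfo"))
#' @rdname accessors
#' @export
setGeneric("strainCatalog", function(x) standardGeneric("strainCatalog"))
#' @rdname accessors
#' @export
setGeneric("log2Values", function(x) standardGeneric("log2Values"))
#' @rdname accessors
#' @export
setGeneric("detected", function(x) standardGeneric("detected"))

#' @rdname accessors
setMethod("probeInfo", "ArrayDesign", function(x) x@probes)
#' @rdname accessors
setMethod("targetInfo", "ArrayDesign", function(x) x@targets)
#' @rdname accessors
setMethod("controlInfo", "ArrayDesign", function(x) x@controls)

#' @rdname accessors
setMethod("strainCatalog", "ArrayDesign", function(x) {
  tg <- x@targets
  tab <- table(tg$strain_id)
  sp <- unique(tg[, c("strain_id", "phylogroup_id")])
  sp <- sp[order(sp$strain_id), , drop = FALSE]
  data.frame(strain_id = sp$strain_id,
             phylogroup_id = sp$phylogroup_id,
             n_targets = as.integer(tab[sp$strain_id]),
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname accessors
setMethod("log2Values", "PhytoArraySet", function(x)
  SummarizedExperiment::assay(x, "log2"))
#' @rdname accessors
setMethod("detected", "PhytoArraySet", function(x)
  SummarizedExperiment::assay(x, "detected"))
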