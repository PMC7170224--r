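#' Summarize probe intensities to target level
#'
#' Probe rows of each gene target are log2-transformed (after flooring at
#' 1 so the log stays defined) and combined by median polish: an
#' additive fit of overall + probe + sample effects, whose overall +
#' sample effects are the robust multi-array summary of the target.
#' Single-probe targets pass through as \code{log2(intensity)}. Probe
#' affinities are absorbed into the probe (row) effects, so a constant
#' per-probe offset does not bias the summary.
#'
#' @param raw probe x sample matrix of positive linear intensities.
#' @param design an [ArrayDesign]; only annotated probes present in
#'   \code{raw} are used. A target all of whose probes are missing from
#'   \code{raw} is dropped with a message.
#' @return target x sample matrix of log2 summaries.
#' @examples
#' d <- simulateDesign(2, 2, c(3, 3), c(2, 2), seed = 1)
#' sim <- simulateExperiment(d, truthConfig(seed = 1))
#' m <- summarizeProbes(sim$intensities, d)
#' @export
summarizeProbes <- function(raw, design) {
  pr <- probeInfo(design)
  pr <- pr[pr$probe_id %in% rownames(raw), , drop = FALSE]
  targets <- unique(probeInfo(design)$target_id)
  missing <- setdiff(targets, pr$target_id)
  if (length(missing)) {
    message(length(missing), " target(s) had no probes with data; dropped")
    targets <- setdiff(targets, missing)
  }
  lm2 <- log2(pmax(raw, 1))
  out <- matrix(NA_real_, length(targets), ncol(raw),
                dimnames = list(targets, colnames(raw)))
  idx <- split(pr$probe_id, pr$target_id)
  for (t in targets) {
    rows <- lm2[idx[[t]], , drop = FALSE]
    if (nrow(rows) == 1L) {
      out[t, ] <- rows[1, ]
    } else {
      mp <- stats::medpolish(rows, eps = 1e-9, maxiter = 100L,
                             trace.iter = FALSE, na.rm = TRUE)
      out[t, ] <- mp$overall + mp$col
    }
  }
  out
}

#' Quantile-normalize sample columns
#'
#' Forces every column to the same empirical distribution: the
#' across-column mean of order statistics. Ties within a column receive
#' the mean of the quantile values they span. Single-column input is
#' returned unchanged with a warning.
#'
#' @param m numeric matrix without missing values.
#' @return matrix of the same shape.
#' @export
quantileNormalize <- function(m) {
  if (anyNA(m)) stop("missing cells must be handled before normalization")
  if (ncol(m) < 2L) {
    warning("fewer than 2 samples; returning input unchanged")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Call per-cell detection against negative-control probes
#'
#' A target is detected in a sample when its summarized log2 value
#' strictly exceeds \code{mean + k * sd} of that sample's
#' negative-control probe log2 intensities. The rule is a documented
#' stand-in for the unpublished criterion of the original array software
#' and is exposed through \code{k} (config \code{detection_k}).
#'
#' @param m target x sample log2 matrix.
#' @param raw probe x sample linear intensity matrix holding the
#'   negative-control probes.
#' @param design an [ArrayDesign] with negative-control probes.
#' @param k SD multiplier (default 2).
#' @return logical matrix shaped like \code{m}; attribute
#'   \code{"thresholds"} carries the per-sample cutoffs.
#' @export
callDetection <- function(m, raw, design, k = 2) {
  ct <- controlInfo(design)
  neg <- intersect(ct$probe_id[ct$control_role == "negative"], rownames(raw))
  if (!length(neg))
    stop("design has no negative-control probes with data; ",
         "supply a fixed threshold by constructing flags directly")
  ctrl <- log2(pmax(raw[neg, colnames(m), drop = FALSE], 1))
  thr <- colMeans(ctrl) + k * apply(ctrl, 2, stats::sd)
  flags <- sweep(m, 2, thr, FUN = ">")
  attr(flags, "thresholds") <- thr
  flags
}

#' Run the preprocessing stage
#'
#' Summarizes probes to targets, calls detection against the
#' negative-control probes on the summarized (pre-normalization) scale,
#' then quantile-normalizes across samples. With
#' \code{normalize_level = "probe"} the probe-level columns (including
#' controls) are quantile-normalized first and detection thresholds come
#' from the normalized controls.
#'
#' @param raw probe x sample linear intensity matrix.
#' @param design an [ArrayDesign].
#' @param sheet a validated sample sheet covering \code{colnames(raw)}.
#' @param config an [analysisConfig()].
#' @return A [PhytoArraySet] with assays \code{log2} and \code{detected},
#'   target annotation as row data, the sample sheet as column data, and
#'   normalization provenance in the metadata.
#' @export
preprocessExperiment <- function(raw, design, sheet,
                                 config = analysisConfig()) {
  stopifnot(all(sheet$sample_id %in% colnames(raw)))
  raw <- raw[, sheet$sample_id, drop = FALSE]
  message("preprocess: ", nrow(raw), " probes x ", ncol(raw), " samples; ",
          "normalize_level=", config$normalize_level,
          ", detection_k=", config$detection_k)
  if (config$normalize_level == "probe") {
    lin <- 2^quantileNormalize(log2(pmax(raw, 1)))
    summarized <- summarizeProbes(lin, design)
    flags <- callDetection(summarized, lin, design, k = config$detection_k)
    values <- summarized
  } else {
    summarized <- summarizeProbes(raw, design)
    flags <- callDetection(summarized, raw, design, k = config$detection_k)
    values <- quantileNormalize(summarized)
  }
  tg <- targetInfo(design)
  rd <- tg[match(rownames(values), tg$target_id), , drop = FALSE]
  rownames(rd) <- rd$target_id
  thr <- attr(flags, "thresholds")
  attr(flags, "thresholds") <- NULL
  message("preprocess: ", sum(flags), " of ", length(flags),
          " target cells detected")
  PhytoArraySet(log2 = values, detected = flags, rowData = rd,
                colData = sheet,
                provenance = list(normalize_level = config$normalize_level,
                                  detection_k = config$detection_k,
                                  detection_thresholds = thr))
}
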