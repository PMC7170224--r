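## Single-gene differential expression: a TREAT-style test of
## H0: |fold change| <= fc_threshold, with empirical-Bayes variance
## moderation (moment-matched scaled inverse-chi-square prior on gene
## variances, as in the limma tradition).

## Newton solve of trigamma(x) = y, vectorized; used to moment-match the
## prior degrees of freedom from the spread of log sample variances.
.trigammaInverse <- function(y) {
  out <- y
  lo <- y < 1e-7
  hi <- y > 1e7
  out[lo] <- 1 / sqrt(y[lo])
  out[hi] <- 1 / y[hi]
  mid <- which(!lo & !hi)
  x <- 0.5 + 1 / y[mid]
  for (i in seq_len(50)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y[mid]) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-8) break
  }
  out[mid] <- x
  out
}

## Moment-match a scaled inverse-chi-square prior to gene variances s2
## on d residual df. Returns prior df d0 (possibly Inf), prior scale
## s02, posterior variances and total df.
.squeezeVariances <- function(s2, d) {
  ok <- s2 > 0
  if (sum(ok) < 2) {
    return(list(df_prior = 0, s2_prior = NA_real_, s2_post = s2,
                df_total = rep(d, length(s2))))
  }
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + d * s2) / (d0 + d)
  } else {
    d0 <- Inf
    s02 <- exp(emean)
    s2_post <- rep(s02, length(s2))
  }
  list(df_prior = d0, s2_prior = s02, s2_post = s2_post,
       df_total = rep(d + d0, length(s2)))
}

#' Define the standard study contrasts
#'
#' Every T24 treatment against the T24 controls, plus T24 controls
#' against T0 controls.
#'
#' @param sheet a validated sample sheet.
#' @return data.frame with columns \code{name}, \code{case}, \code{ref}
#'   (condition labels \code{"timepoint.treatment"}).
#' @export
defaultContrasts <- function(sheet) {
  conds <- unique(.conditionOf(sheet))
  trts <- setdiff(conds[startsWith(conds, "T24.")], "T24.control")
  rbind(
    data.frame(name = sub("^T24\\.", "", trts), case = trts,
               ref = "T24.control", stringsAsFactors = FALSE),
    data.frame(name = "T24_vs_T0", case = "T24.control",
               ref = "T0.control", stringsAsFactors = FALSE))
}

#' Fit the fold-change-threshold test for one contrast
#'
#' Per gene target the log2 fold change is the case-mean minus
#' reference-mean of normalized log2 levels. Gene variances are pooled
#' within the contrast and shrunk toward a moment-matched prior
#' (empirical Bayes); the test statistic
#' \code{(|log2FC| - log2(fc_threshold)) / SE} is referred one-sided to
#' a t distribution on the moderated degrees of freedom, giving a p for
#' H0: |FC| <= fc_threshold. Targets detected in no sample of the
#' contrast are excluded from testing (and from the BH family).
#'
#' @param pas a [PhytoArraySet].
#' @param case,ref condition labels (\code{"T24.urea"}, \code{"T24.control"},
#'   ...); both need >= 2 replicates.
#' @param fc_threshold fold-change null bound (>= 1), default 1.2.
#' @param alpha_gene BH-adjusted significance level for the DE flag.
#' @param moderation if \code{FALSE}, prior weight zero: a plain
#'   pooled-variance threshold t-test.
#' @return data.frame, one row per tested target: annotation,
#'   \code{log2FC}, moderated \code{se}, signed moderated \code{t}
#'   (log2FC / se), threshold-test \code{stat}, \code{df}, \code{p},
#'   BH-adjusted \code{adj_p}, logical \code{de} and \code{direction}.
#' @export
fitContrast <- function(pas, case, ref, fc_threshold = 1.2,
                        alpha_gene = 0.05, moderation = TRUE) {
  sheet <- as.data.frame(SummarizedExperiment::colData(pas))
  cond <- .conditionOf(sheet)
  ci <- which(cond == case)
  ri <- which(cond == ref)
  if (length(ci) < 2) stop("condition '", case, "' has < 2 replicates")
  if (length(ri) < 2) stop("condition '", ref, "' has < 2 replicates")
  v <- log2Values(pas)
  dflag <- detected(pas)
  tested <- rowSums(dflag[, c(ci, ri), drop = FALSE]) > 0
  v <- v[tested, , drop = FALSE]
  n1 <- length(ci); n2 <- length(ri)
  m1 <- rowMeans(v[, ci, drop = FALSE])
  m2 <- rowMeans(v[, ri, drop = FALSE])
  lfc <- m1 - m2
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * .rowVars(v[, ci, drop = FALSE]) +
         (n2 - 1) * .rowVars(v[, ri, drop = FALSE])) / d
  if (moderation) {
    sq <- .squeezeVariances(s2, d)
    s2_use <- sq$s2_post
    df_use <- pmin(sq$df_total, 1e6)
  } else {
    s2_use <- s2
    df_use <- rep(d, length(s2))
  }
  se <- sqrt(s2_use * (1 / n1 + 1 / n2))
  stat <- (abs(lfc) - log2(fc_threshold)) / se
  p <- stats::pt(stat, df = df_use, lower.tail = FALSE)
  res <- data.frame(target_id = rownames(v), log2FC = lfc, se = se,
                    t = lfc / se, stat = stat, df = df_use, p = p,
                    row.names = NULL, stringsAsFactors = FALSE)
  rd <- as.data.frame(SummarizedExperiment::rowData(pas))
  ann_cols <- intersect(c("gene_symbol", "process_label", "strain_id",
                          "phylogroup_id", "ecotype_label"), names(rd))
  res <- cbind(res, rd[match(res$target_id, rd$target_id), ann_cols,
                       drop = FALSE])
  rownames(res) <- NULL
  res$adj_p <- bhAdjust(res$p)
  callDE(res, alpha_gene = alpha_gene, fc_threshold = fc_threshold)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: ascending p-values get
#' \code{min_{k >= i} p_(k) * m / k}, capped at 1, mapped back to input
#' order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order as input.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Flag differentially expressed targets
#'
#' DE requires BH-adjusted p below \code{alpha_gene} \emph{and}
#' \code{|fold change| > fc_threshold}; direction is the sign of the
#' log2 fold change.
#'
#' @param res a result frame from [fitContrast()] (columns \code{log2FC},
#'   \code{adj_p}).
#' @param alpha_gene significance level.
#' @param fc_threshold fold-change threshold.
#' @return \code{res} with columns \code{de} and \code{direction}.
#' @export
callDE <- function(res, alpha_gene = 0.05, fc_threshold = 1.2) {
  res$de <- res$adj_p < alpha_gene & abs(res$log2FC) > log2(fc_threshold)
  res$direction <- sign(res$log2FC)
  res
}

#' Fit all standard contrasts
#'
#' @param pas a [PhytoArraySet].
#' @param config an [analysisConfig()]; with \code{bh_scope = "global"}
#'   the BH family spans all contrasts jointly.
#' @param contrasts optional contrast frame as from [defaultContrasts()].
#' @return named list of [fitContrast()] result frames.
#' @export
fitAllContrasts <- function(pas, config = analysisConfig(),
                            contrasts = NULL) {
  sheet <- as.data.frame(SummarizedExperiment::colData(pas))
  if (is.null(contrasts)) contrasts <- defaultContrasts(sheet)
  out <- lapply(seq_len(nrow(contrasts)), function(i)
    fitContrast(pas, contrasts$case[i], contrasts$ref[i],
                fc_threshold = config$fc_threshold,
                alpha_gene = config$alpha_gene))
  names(out) <- contrasts$name
  if (config$bh_scope == "global") {
    all_p <- unlist(lapply(out, `[[`, "p"))
    adj <- bhAdjust(all_p)
    k <- 0L
    for (i in seq_along(out)) {
      n <- nrow(out[[i]])
      out[[i]]$adj_p <- adj[k + seq_len(n)]
      out[[i]] <- callDE(out[[i]], config$alpha_gene, config$fc_threshold)
      k <- k + n
    }
  }
  out
}
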