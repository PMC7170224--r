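## Weighted co-expression network analysis over the T24 samples:
## unsigned soft-thresholded correlation adjacency, topological overlap,
## average-linkage clustering with a static tree cut, and per-module
## eigengenes.

#' Choose the soft-thresholding power
#'
#' Scans candidate powers and returns the smallest whose unsigned
#' adjacency \code{|cor|^beta} yields an approximately scale-free degree
#' distribution: the signed R^2 of the log-log regression of frequency
#' on connectivity must reach \code{target_r2}. If no candidate
#' qualifies, the power with the best fit is returned with a warning.
#' Constant gene rows are dropped with a warning before correlation.
#'
#' By default the candidate grid starts at the smallest power that
#' suppresses background sampling correlation: with n samples a null
#' correlation sits around \code{2/sqrt(n)} at two sigma, and the floor
#' is the smallest beta with \code{(2/sqrt(n))^beta <= 0.01}, so that
#' noise edges carry at most 1% adjacency (6 at n = 20). The scale-free
#' fit alone cannot exclude such under-thresholded powers on small
#' sample sizes. Pass \code{powers} explicitly to scan an arbitrary
#' grid.
#'
#' @param expr gene x sample matrix (>= 8 samples).
#' @param powers candidate integer powers; default
#'   \code{floor:20} as described above.
#' @param target_r2 scale-free fit target (default 0.8).
#' @param n_breaks connectivity histogram bins for the fit.
#' @return integer power; attributes \code{"fit"} (data.frame of power,
#'   signed R^2, mean connectivity) for inspection.
#' @export
pickSoftPower <- function(expr, powers = NULL, target_r2 = 0.8,
                          n_breaks = 10) {
  if (ncol(expr) < 8) stop("need >= 8 samples for network construction")
  if (is.null(powers)) {
    r_null <- min(0.9, 2 / sqrt(ncol(expr)))
    floor_beta <- max(1, ceiling(log(0.01) / log(r_null)))
    powers <- seq(min(floor_beta, 20), 20)
  }
  keep <- apply(expr, 1, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant gene row(s) dropped")
    expr <- expr[keep, , drop = FALSE]
  }
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  fit <- data.frame(power = powers, r2 = NA_real_, mean_k = NA_real_)
  for (i in seq_along(powers)) {
    k <- rowSums(ac^powers[i])
    fit$mean_k[i] <- mean(k)
    fit$r2[i] <- .scaleFreeR2(k, n_breaks)
  }
  ok <- which(fit$r2 >= target_r2)
  if (length(ok)) {
    beta <- powers[ok[1]]
  } else {
    beta <- powers[which.max(fit$r2)]
    warning("no candidate power reached R^2 ", target_r2,
            "; using best fit at power ", beta)
  }
  structure(beta, fit = fit)
}

## signed scale-free topology fit index: R^2 of log10 p(k) ~ log10 k,
## negated when the slope is positive (scale-free implies decreasing)
.scaleFreeR2 <- function(k, n_breaks) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(0)
  cuts <- cut(k, n_breaks)
  dk <- tapply(k, cuts, mean)
  pk <- tabulate(cuts, nbins = n_breaks) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(0)
  x <- log10(dk[ok])
  y <- log10(pk[ok])
  f <- stats::lm(y ~ x)
  r2 <- summary(f)$r.squared
  -sign(stats::coef(f)[2]) * r2
}

#' Unsigned adjacency matrix
#'
#' @param expr gene x sample matrix.
#' @param beta soft power.
#' @return gene x gene matrix \code{|cor|^beta} with unit diagonal.
#' @export
adjacencyMatrix <- function(expr, beta) {
  a <- abs(stats::cor(t(expr)))^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)}
#' with the shared-neighbour sum over \code{u != i, j} and connectivity
#' \code{k_i = sum_{u != i} a_iu}; the diagonal is 1.
#'
#' @param a symmetric adjacency in [0, 1] with unit diagonal.
#' @return TOM similarity matrix.
#' @export
computeTOM <- function(a) {
  if (!isSymmetric(unname(a), tol = 1e-10))
    stop("adjacency must be symmetric")
  if (any(a < 0) || any(a > 1)) stop("adjacency entries must lie in [0, 1]")
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  shared <- a %*% a - 2 * a  # removes the u = i and u = j terms (diag 1)
  num <- shared + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Cut the co-expression dendrogram into modules
#'
#' Average-linkage hierarchical clustering of \code{1 - TOM}
#' dissimilarity, cut statically at \code{cut_height_frac} of the
#' maximum merge height; clusters smaller than \code{min_module_size}
#' are left unassigned (module 0). Assigned modules are renumbered 1, 2,
#' ... by decreasing size.
#'
#' @param tom TOM similarity matrix.
#' @param min_module_size smallest reportable module.
#' @param cut_height_frac static cut height as a fraction of the
#'   maximum merge height (default 0.98: TOM dissimilarities concentrate
#'   near 1, so the cut sits just below the top of the tree).
#' @return integer vector of module labels named by gene.
#' @export
cutModules <- function(tom, min_module_size = 10, cut_height_frac = 0.98) {
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  h <- cut_height_frac * max(hc$height)
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- integer(length(cl))
  if (length(keep)) {
    keep <- keep[order(-sizes[keep])]
    for (i in seq_along(keep)) labels[cl == as.integer(keep[i])] <- i
  }
  names(labels) <- rownames(tom)
  labels
}

#' Module eigengene
#'
#' The first principal component of the standardized member-gene
#' submatrix: a unit-norm score vector across samples, sign-fixed so its
#' correlation with the module's mean expression profile is positive.
#'
#' @param expr gene x sample matrix.
#' @param members gene ids of one module (>= 2).
#' @return numeric vector of per-sample scores (unit norm).
#' @export
moduleEigengene <- function(expr, members) {
  stopifnot(length(members) >= 2)
  x <- expr[members, , drop = FALSE]
  xs <- t(scale(t(x)))
  sv <- svd(xs, nu = 0, nv = 1)
  e <- sv$v[, 1]
  profile <- colMeans(xs)
  s <- sum(e * profile)
  if (s == 0) s <- sum(e * xs[1, ])  # balanced anti-correlated module
  if (s < 0) e <- -e
  names(e) <- colnames(expr)
  e
}

#' Detect co-expression modules over T24 samples
#'
#' End-to-end network stage: restricts to T24 samples and to targets
#' detected in at least \code{network_detect_frac} of them, picks the
#' soft power, computes TOM, cuts modules and derives eigengenes.
#'
#' @param pas a [PhytoArraySet].
#' @param config an [analysisConfig()].
#' @return list with \code{modules} (named label vector), \code{beta},
#'   \code{fit} (soft-power scan), \code{eigengenes} (module x sample
#'   matrix), and \code{genes} (the network universe).
#' @export
detectModules <- function(pas, config = analysisConfig()) {
  sheet <- as.data.frame(SummarizedExperiment::colData(pas))
  t24 <- sheet$sample_id[sheet$timepoint == "T24"]
  expr <- log2Values(pas)[, t24, drop = FALSE]
  dfrac <- rowMeans(detected(pas)[, t24, drop = FALSE])
  expr <- expr[dfrac >= config$network_detect_frac, , drop = FALSE]
  message("network: ", nrow(expr), " targets x ", length(t24),
          " T24 samples")
  sds <- apply(expr, 1, stats::sd)
  expr <- expr[sds > 0, , drop = FALSE]
  beta <- pickSoftPower(expr, target_r2 = config$soft_power_target_r2)
  tom <- computeTOM(adjacencyMatrix(expr, as.integer(beta)))
  modules <- cutModules(tom, min_module_size = config$min_module_size,
                        cut_height_frac = config$cut_height_frac)
  labs <- setdiff(sort(unique(modules)), 0L)
  eig <- do.call(rbind, lapply(labs, function(l)
    moduleEigengene(expr, names(modules)[modules == l])))
  if (!is.null(eig)) rownames(eig) <- paste0("ME", labs)
  list(modules = modules, beta = as.integer(beta),
       fit = attr(beta, "fit"), eigengenes = eig, genes = rownames(expr))
}
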