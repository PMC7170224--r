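#' Euclidean distances between sample metatranscriptomes
#'
#' Pairwise Euclidean distances over normalized log2 levels of the
#' detected gene universe (targets detected in at least one sample).
#' Undetected cells enter at their normalized values rather than being
#' masked, matching a whole-profile distance over the detected universe.
#'
#' @param pas a [PhytoArraySet] (or a plain target x sample matrix).
#' @return sample x sample symmetric distance matrix.
#' @export
euclideanDistances <- function(pas) {
  m <- if (is(pas, "PhytoArraySet")) {
    universe <- rowSums(detected(pas)) > 0
    log2Values(pas)[universe, , drop = FALSE]
  } else pas
  if (ncol(m) < 2) stop("need >= 2 samples")
  as.matrix(stats::dist(t(m)))
}

#' Isotonic (monotone) regression
#'
#' Pool-adjacent-violators solution minimizing squared error subject to
#' the fitted values being non-decreasing along \code{ord}.
#'
#' @param values numeric vector.
#' @param ord permutation giving the target order (default: as given).
#' @return fitted values aligned with the input.
#' @examples
#' monotoneRegression(c(3, 1, 2))  # 2 2 2
#' @export
monotoneRegression <- function(values, ord = seq_along(values)) {
  fit <- stats::isoreg(seq_along(ord), values[ord])$yf
  out <- numeric(length(values))
  out[ord] <- fit
  out
}

## one majorization pass: monotone fit of embedded distances against the
## dissimilarity order, then a Guttman transform of the configuration
.nmdsIterate <- function(X, dvec, ij, max_iter, tol) {
  n <- nrow(X)
  stress_prev <- Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    demb <- sqrt(rowSums((X[ij[, 1], , drop = FALSE] -
                          X[ij[, 2], , drop = FALSE])^2))
    ord <- order(dvec, demb)  # primary tie approach: ties unconstrained
    dhat <- monotoneRegression(demb, ord)
    denom <- sum(demb^2)
    stress <- if (denom > 0) sqrt(sum((dhat - demb)^2) / denom) else 1
    trace <- c(trace, stress)
    if (is.finite(stress_prev) && stress_prev - stress < tol) break
    stress_prev <- stress
    ratio <- ifelse(demb > 1e-12, dhat / demb, 0)
    B <- matrix(0, n, n)
    B[cbind(ij[, 1], ij[, 2])] <- -ratio
    B[cbind(ij[, 2], ij[, 1])] <- -ratio
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
  }
  list(X = X, stress = trace[length(trace)], trace = trace,
       converged = it < max_iter)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal-style NMDS by SMACOF majorization: embedded distances are
#' monotone-regressed against the rank order of the input
#' dissimilarities (primary tie treatment) and the configuration is
#' updated by the Guttman transform until the stress-1 change falls
#' below \code{tol}. The best of one classical-scaling start plus
#' \code{restarts} seeded random starts is returned.
#'
#' @param d sample x sample distance matrix (or \code{dist}).
#' @param dim embedding dimension.
#' @param restarts number of random restarts.
#' @param seed integer seed for the random starts.
#' @param tol stress convergence tolerance.
#' @param max_iter iteration cap per start.
#' @return list with \code{points} (sample x dim coordinates),
#'   \code{stress} (Kruskal stress-1 of the best start), \code{best_start}
#'   (0 = classical-scaling start), \code{restarts}, \code{converged},
#'   and \code{trace} (per-iteration stress of the best start).
#' @export
nmds <- function(d, dim = 2, restarts = 20, seed = 1L, tol = 1e-6,
                 max_iter = 500) {
  D <- as.matrix(d)
  if (!isSymmetric(unname(D), tol = 1e-8) || any(D < 0))
    stop("d must be a symmetric nonnegative distance matrix")
  n <- nrow(D)
  ij <- which(upper.tri(D), arr.ind = TRUE)
  dvec <- D[upper.tri(D)]

  starts <- vector("list", restarts + 1)
  cs <- suppressWarnings(stats::cmdscale(D, k = dim))
  if (ncol(cs) < dim)
    cs <- cbind(cs, matrix(0, n, dim - ncol(cs)))
  starts[[1]] <- cs
  scale0 <- mean(dvec)
  .withSeed(seed, {
    for (r in seq_len(restarts))
      starts[[r + 1]] <- matrix(stats::rnorm(n * dim, sd = scale0 / 2),
                                n, dim)
  })
  best <- NULL
  for (r in seq_along(starts)) {
    res <- .nmdsIterate(starts[[r]], dvec, ij, max_iter, tol)
    if (is.null(best) || res$stress < best$stress) {
      best <- res
      best$best_start <- r - 1L
    }
  }
  if (!best$converged)
    warning("NMDS did not converge in any restart within ", max_iter,
            " iterations")
  pts <- best$X
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("NMDS", seq_len(dim))
  list(points = pts, stress = best$stress, best_start = best$best_start,
       restarts = restarts, converged = best$converged,
       trace = best$trace)
}

#' Median distances from each treatment to a reference group
#'
#' For every (timepoint, treatment) group other than the reference, the
#' median of all pairwise distances between the group's samples and the
#' reference samples; for the reference against itself, zero self-pairs
#' are excluded. Output rows are ordered by increasing median distance.
#'
#' @param D sample x sample distance matrix.
#' @param sheet a validated sample sheet.
#' @param ref_timepoint,ref_treatment the reference group (default T0
#'   controls).
#' @return data.frame with columns \code{timepoint}, \code{treatment},
#'   \code{median_distance}, \code{n_pairs}.
#' @export
groupDistanceSummary <- function(D, sheet, ref_timepoint = "T0",
                                 ref_treatment = "control") {
  D <- as.matrix(D)
  ref <- sheet$sample_id[sheet$timepoint == ref_timepoint &
                         sheet$treatment == ref_treatment]
  if (!length(ref)) stop("reference group is empty")
  groups <- unique(sheet[, c("timepoint", "treatment")])
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    gs <- sheet$sample_id[sheet$timepoint == groups$timepoint[i] &
                          sheet$treatment == groups$treatment[i]]
    dd <- D[gs, ref, drop = FALSE]
    self <- outer(gs, ref, "==")
    vals <- dd[!self]
    if (!length(vals)) {
      warning("group ", groups$timepoint[i], " ", groups$treatment[i],
              " has no non-self pairs with the reference; omitted")
      next
    }
    rows[[i]] <- data.frame(timepoint = groups$timepoint[i],
                            treatment = groups$treatment[i],
                            median_distance = stats::median(vals),
                            n_pairs = length(vals),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$median_distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}
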