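#' Response gene-set rosters
#'
#' The controlled vocabulary of functional response sets and their member
#' gene symbols: iron stress, nitrogen stress, phosphorus stress,
#' photosynthesis, RuBisCO (carbon fixation) and light stress marker
#' genes as used on strain-resolved phytoplankton functional-gene
#' arrays.
#'
#' @return named list of character vectors (label -> gene symbols).
#' @export
geneSetRosters <- function() {
  list(
    "Fe stress" = c("fur", "isiA", "isiP", "isiB", "idiA", "dpsA"),
    "N stress" = c("ntcA", "urtA", "cynA", "amt", "glnA", "ureA", "nirA",
                   "nrtP"),
    "P stress" = c("psiP", "pstS", "phoH", "mfs", "phoB", "pstA", "pstB",
                   "pstC"),
    "photosynthesis" = c("psaB", "psbA", "psbB", "psaA"),
    "RuBisCO" = "rbcL",
    "light stress" = c("phrB", "nudix", "pmm1359")
  )
}

#' Build response gene sets from the array annotation
#'
#' One set per (scope, response label) with at least one member target.
#' With \code{scope_mode = "phylogroup"} a set collects every annotated
#' target of the label's genes across all strains of the phylogroup;
#' with \code{"strain"} membership is restricted to one strain's
#' targets.
#'
#' @param design an [ArrayDesign].
#' @param scope_mode \code{"phylogroup"} or \code{"strain"}.
#' @param labels response labels to build; defaults to all rosters.
#' @return data.frame in long form: \code{set_id}, \code{scope_mode},
#'   \code{scope_id}, \code{phylogroup}, \code{response_label},
#'   \code{target_id}.
#' @examples
#' d <- simulateDesign(2, 3, c(8, 10), c(2, 2), seed = 2)
#' sets <- buildGeneSets(d)
#' table(sets$set_id)
#' @export
buildGeneSets <- function(design, scope_mode = c("phylogroup", "strain"),
                          labels = names(geneSetRosters())) {
  scope_mode <- match.arg(scope_mode)
  rosters <- geneSetRosters()
  unknown <- setdiff(labels, names(rosters))
  if (length(unknown))
    stop("unknown response label(s): ", paste(unknown, collapse = ", "))
  tg <- targetInfo(design)
  scope_col <- if (scope_mode == "phylogroup") "phylogroup_id" else
    "strain_id"
  out <- list()
  for (scope in unique(tg[[scope_col]])) {
    in_scope <- tg[tg[[scope_col]] == scope, , drop = FALSE]
    for (lab in labels) {
      members <- in_scope$target_id[in_scope$gene_symbol %in% rosters[[lab]]]
      if (!length(members)) next
      out[[paste(scope, lab)]] <- data.frame(
        set_id = paste(scope, lab, sep = ":"),
        scope_mode = scope_mode, scope_id = scope,
        phylogroup = unique(in_scope$phylogroup_id),
        response_label = lab, target_id = members,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no gene sets constructible from this annotation")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## two-sample KS statistic given all values and a member indicator,
## computed on the pooled sort order
.ksStat <- function(z_sorted, m, n) {
  cm <- cumsum(z_sorted) / m
  cn <- cumsum(1 - z_sorted) / n
  max(abs(cm - cn))
}

## one-sided-large permutation p for every draw against the draw
## distribution itself: p_b = (1 + #{c: s_c >= s_b}) / (B + 1)
.drawPValues <- function(s) {
  B <- length(s)
  (B - rank(s, ties.method = "min") + 2) / (B + 1)
}

## observed one-sided-large p against the draws (add-one estimator)
.obsPValue <- function(s_obs, s_draws) {
  (1 + sum(s_draws >= s_obs)) / (length(s_draws) + 1)
}

## r-th smallest across the columns of a B x K matrix, vectorized for
## the common K = 4 cases
.rthSmallest <- function(P, r) {
  K <- ncol(P)
  if (r == 1) return(do.call(pmin, as.data.frame(P)))
  if (r == K) return(do.call(pmax, as.data.frame(P)))
  if (K == 4 && r == 2) {
    # second smallest = min over pairs of pairwise maxima
    cols <- as.data.frame(P)
    pairs <- utils::combn(4, 2)
    mins <- lapply(seq_len(ncol(pairs)), function(j)
      pmax(cols[[pairs[1, j]]], cols[[pairs[2, j]]]))
    return(do.call(pmin, mins))
  }
  apply(P, 1, function(x) sort(x)[r])
}

#' Ensemble set test with permutation-calibrated Wilkinson combination
#'
#' Runs four competitive base statistics of a gene set against the
#' non-member targets of the same universe — (1) the Wilcoxon rank-sum
#' of member t statistics, (2) the mean member t, (3) the count of DE
#' members, (4) the two-sample Kolmogorov-Smirnov statistic — on one
#' shared scheme of \code{n_perm} random member draws (gene permutation,
#' the competitive null). Each draw's statistics are converted to
#' empirical p-values against the draw distribution, combined by
#' Wilkinson's r-th smallest p, and the observed combination is referred
#' to the per-draw combinations: the resulting ensemble p-value is
#' uniform under the competitive null by construction, which a direct
#' Beta-transform of dependent base p-values is not.
#'
#' @param t_stats signed moderated t statistics of the universe.
#' @param member logical member mask (>= 2 TRUE and >= 2 FALSE).
#' @param de logical DE flags aligned with \code{t_stats}.
#' @param n_perm permutation draws.
#' @param r Wilkinson order statistic.
#' @return list with \code{base} (named reportable base p-values:
#'   \code{ranksum} exact Wilcoxon, \code{perm_mean} add-one
#'   permutation, \code{fisher} exact on the DE 2x2, \code{ks}
#'   permutation), \code{p_wilkinson} (Beta-transformed combination of
#'   the base p-values) and \code{p_combined} (the calibrated ensemble
#'   p used for significance).
#' @export
ensembleSetTest <- function(t_stats, member, de, n_perm = 10000, r = 2) {
  stopifnot(length(member) == length(t_stats), sum(member) >= 2,
            sum(!member) >= 2)
  G <- length(t_stats)
  m <- sum(member)
  n <- G - m
  mt <- t_stats[member]
  nt <- t_stats[!member]
  tab <- matrix(c(sum(member & de), sum(member & !de),
                  sum(!member & de), sum(!member & !de)), 2, 2)
  p_fisher <- min(stats::fisher.test(tab)$p.value, 1)
  if (length(unique(t_stats)) == 1L) {
    message("degenerate set universe (all statistics equal); rank-based ",
            "p-values set to 1")
    base <- c(ranksum = 1, perm_mean = 1, fisher = p_fisher, ks = 1)
    return(list(base = base,
                p_wilkinson = wilkinsonCombine(base, r), p_combined = 1))
  }
  p_rank <- suppressWarnings(
    stats::wilcox.test(mt, nt, alternative = "two.sided")$p.value)

  rk <- rank(t_stats)
  ctr <- mean(t_stats)
  ord <- order(t_stats)
  z_sorted <- member[ord]
  pos_in_sorted <- integer(G)
  pos_in_sorted[ord] <- seq_len(G)

  # shared draw scheme: each row of IDX is a random member set
  IDX <- t(vapply(seq_len(n_perm), function(b) sample.int(G, m),
                  integer(m)))
  TS <- matrix(t_stats[IDX], n_perm, m)
  dev_mean <- abs(rowMeans(TS) - ctr)
  RK <- matrix(rk[IDX], n_perm, m)
  dev_rank <- abs(rowSums(RK) - m * (G + 1) / 2)
  DE_b <- rowSums(matrix(de[IDX], n_perm, m))
  # KS per draw: 0/1 membership in sorted order, row cumsums by an
  # upper-triangular multiply
  Z <- matrix(0, n_perm, G)
  Z[cbind(rep(seq_len(n_perm), m), as.vector(pos_in_sorted[IDX]))] <- 1
  U <- upper.tri(matrix(0, G, G), diag = TRUE) * 1
  CS <- Z %*% U[seq_len(G), , drop = FALSE]
  pos_all <- matrix(rep(seq_len(G), each = n_perm), n_perm, G)
  Dmat <- abs(CS / m - (pos_all - CS) / n)
  D_b <- do.call(pmax, as.data.frame(Dmat))

  d_obs_mean <- abs(mean(mt) - ctr)
  d_obs_rank <- abs(sum(rk[member]) - m * (G + 1) / 2)
  d_obs_de <- sum(member & de)
  d_obs_ks <- .ksStat(z_sorted, m, n)

  p_perm <- .obsPValue(d_obs_mean, dev_mean)
  p_ks <- .obsPValue(d_obs_ks, D_b)

  # per-draw and observed empirical p's on the shared scheme; the
  # observed combination is exchangeable with the draws under the null
  P <- cbind(.drawPValues(dev_rank), .drawPValues(dev_mean),
             .drawPValues(DE_b), .drawPValues(D_b))
  p_obs4 <- c(.obsPValue(d_obs_rank, dev_rank), p_perm,
              .obsPValue(d_obs_de, DE_b), p_ks)
  s_b <- .rthSmallest(P, r)
  s_obs <- sort(p_obs4)[r]
  p_combined <- (1 + sum(s_b <= s_obs)) / (n_perm + 1)

  base <- c(ranksum = p_rank, perm_mean = p_perm, fisher = p_fisher,
            ks = p_ks)
  list(base = base, p_wilkinson = wilkinsonCombine(base, r),
       p_combined = p_combined)
}

#' Base set-test battery
#'
#' The four reportable base p-values of [ensembleSetTest()]: Wilcoxon
#' rank-sum of member vs non-member t statistics (exact two-sided where
#' feasible), gene-permutation test of the mean member t (add-one
#' estimator), Fisher's exact test on the 2x2 DE-by-membership table,
#' and a Kolmogorov-Smirnov statistic with a gene-permutation p. All
#' are two-sided in direction; the set's direction is reported
#' separately.
#'
#' @inheritParams ensembleSetTest
#' @return named numeric vector \code{c(ranksum, perm_mean, fisher, ks)}.
#' @export
baseSetTests <- function(t_stats, member, de, n_perm = 10000) {
  ensembleSetTest(t_stats, member, de, n_perm = n_perm)$base
}

#' Combine p-values by Wilkinson's method
#'
#' The combined p is the probability that the r-th order statistic of K
#' independent uniforms falls at or below the observed r-th smallest
#' p-value: \code{pbeta(p_(r), r, K - r + 1)}.
#'
#' @param p numeric vector of K >= 1 p-values.
#' @param r order statistic, 1 <= r <= K.
#' @return combined p-value.
#' @examples
#' wilkinsonCombine(c(0.1, 0.5), r = 1)  # 1 - 0.9^2 = 0.19
#' wilkinsonCombine(c(0.2, 0.3, 0.5), r = 3)  # 0.5^3 = 0.125
#' @export
wilkinsonCombine <- function(p, r = 2) {
  K <- length(p)
  if (K < 1) stop("need at least one p-value")
  if (r < 1 || r > K) stop("r must lie in [1, ", K, "]")
  stats::pbeta(unname(sort(p)[r]), r, K - r + 1)
}

#' Abundance-artifact retention rule
#'
#' A set called "up" is retained only when its average member fold
#' change exceeds the phylogroup's total-transcript fold change
#' (\code{a_g / a_tot > 1}); a set called "down" only when the ratio is
#' below 1. Calls inconsistent with the ratio are normalization
#' artifacts of a whole-taxon abundance change and are flagged
#' \code{retained = FALSE} (they stay in the output).
#'
#' @param direction +1 or -1 per set.
#' @param a_g average member fold change (linear scale, > 0).
#' @param a_tot average phylogroup-wide fold change (linear scale, > 0).
#' @return logical vector.
#' @export
applyArtifactFilter <- function(direction, a_g, a_tot) {
  if (any(a_tot <= 0) || any(a_g <= 0))
    stop("a_g and a_tot must be positive linear fold changes")
  ratio <- a_g / a_tot
  (direction > 0 & ratio > 1) | (direction < 0 & ratio < 1)
}

#' Magnitude (thick-arrow) classification
#'
#' A set's response is "large" when its average member fold change
#' exceeds the threshold in its own direction: \code{a_g > fc} for
#' up-sets, \code{a_g < 1/fc} for down-sets.
#'
#' @param a_g average member fold change (linear).
#' @param direction +1 or -1.
#' @param fc_threshold fold-change threshold (default 1.2).
#' @return logical vector.
#' @export
classifyMagnitude <- function(a_g, direction, fc_threshold = 1.2) {
  (direction > 0 & a_g > fc_threshold) |
    (direction < 0 & a_g < 1 / fc_threshold)
}

#' Ensemble gene-set testing across contrasts
#'
#' For every (set, contrast) with at least two detected members: runs
#' the [ensembleSetTest()] against the set's phylogroup universe,
#' BH-adjusts the calibrated combined p-values across all (set,
#' contrast) pairs, and annotates direction, average member and
#' phylogroup fold changes (geometric means, computed as
#' \code{2^mean(log2FC)}), the artifact-retention flag and the magnitude
#' flag.
#'
#' @param de_list named list of [fitContrast()] frames (one per
#'   contrast), as from [fitAllContrasts()].
#' @param sets long-form set frame from [buildGeneSets()].
#' @param config an [analysisConfig()]; uses \code{wilkinson_r},
#'   \code{alpha_set}, \code{fc_threshold}, \code{n_perm}
#'   and \code{rng_seed}.
#' @return data.frame with one row per tested (set, contrast).
#' @export
testGeneSets <- function(de_list, sets, config = analysisConfig()) {
  set_ids <- unique(sets$set_id)
  rows <- list()
  .withSeed(config$rng_seed, {
    for (contrast in names(de_list)) {
      de <- de_list[[contrast]]
      for (sid in set_ids) {
        sdef <- sets[sets$set_id == sid, , drop = FALSE]
        universe <- de[de$phylogroup_id == sdef$phylogroup[1], ,
                       drop = FALSE]
        member <- universe$target_id %in% sdef$target_id
        if (sum(member) < 2) {
          message("set ", sid, " has < 2 detected members in contrast ",
                  contrast, "; skipped")
          next
        }
        if (sum(!member) < 2) {
          message("set ", sid, " has < 2 non-members in contrast ",
                  contrast, "; skipped")
          next
        }
        et <- ensembleSetTest(universe$t, member, universe$de,
                              n_perm = config$n_perm,
                              r = config$wilkinson_r)
        mean_lfc <- mean(universe$log2FC[member])
        a_g <- 2^mean_lfc
        a_tot <- 2^mean(universe$log2FC)
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = contrast, set_id = sid,
          scope_mode = sdef$scope_mode[1], scope_id = sdef$scope_id[1],
          phylogroup = sdef$phylogroup[1],
          response_label = sdef$response_label[1],
          n_members = sum(member),
          p_ranksum = et$base[["ranksum"]], p_perm = et$base[["perm_mean"]],
          p_fisher = et$base[["fisher"]], p_ks = et$base[["ks"]],
          p_wilkinson = et$p_wilkinson,
          p_combined = et$p_combined,
          direction = if (mean_lfc >= 0) 1 else -1,
          a_g = a_g, a_tot = a_tot, artifact_ratio = a_g / a_tot,
          stringsAsFactors = FALSE)
      }
    }
  })
  if (!length(rows)) stop("no (set, contrast) pair was testable")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$adj_p <- bhAdjust(res$p_combined)
  res$significant <- res$adj_p < config$alpha_set
  res$retained <- applyArtifactFilter(res$direction, res$a_g, res$a_tot)
  res$magnitude_gt_fc <- classifyMagnitude(res$a_g, res$direction,
                                           config$fc_threshold)
  res
}

#' Arrow-table summary of set responses
#'
#' One row per (scope, treatment, set): the machine-readable version of
#' a direction/significance arrow figure — direction, significance at
#' \code{alpha_set}, magnitude (thick vs thin) and the artifact-filter
#' retention flag.
#'
#' @param results frame from [testGeneSets()].
#' @return data.frame.
#' @export
summarizeResponses <- function(results) {
  data.frame(scope_id = results$scope_id,
             phylogroup = results$phylogroup,
             treatment = results$contrast,
             response_label = results$response_label,
             direction = ifelse(results$direction > 0, "up", "down"),
             significant = results$significant,
             thick = results$magnitude_gt_fc,
             retained = results$retained,
             adj_p = results$adj_p,
             stringsAsFactors = FALSE)
}
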