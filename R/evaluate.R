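## Recovery scoring of pipeline output against a SyntheticTruth ledger.

#' Adjusted Rand index
#'
#' Hubert-Arabie adjusted Rand index between two labelings.
#'
#' @param a,b label vectors of equal length.
#' @return numeric in [-1, 1], 1 for identical partitions.
#' @export
adjRandIndex <- function(a, b) {
  tab <- table(a, b)
  ni <- rowSums(tab)
  nj <- colSums(tab)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(ni, 2))
  sum_j <- sum(choose(nj, 2))
  expected <- sum_i * sum_j / choose(n, 2)
  mx <- (sum_i + sum_j) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}

#' Score recovery of implanted set-level responses
#'
#' For every implanted (phylogroup, response set, treatment) effect in
#' the truth ledger, checks whether the ensemble set analysis called it
#' significant, retained it through the artifact filter, and got the
#' direction right.
#'
#' @param truth a \code{SyntheticTruth}.
#' @param set_results frame from [testGeneSets()] (phylogroup scope).
#' @return list with \code{table} (per-effect outcomes) and \code{rate}
#'   (fraction recovered).
#' @export
scoreSetRecovery <- function(truth, set_results) {
  eff <- truth$config$set_effects
  if (!nrow(eff)) stop("truth has no implanted set effects")
  rows <- lapply(seq_len(nrow(eff)), function(i) {
    hit <- set_results[set_results$contrast == eff$treatment[i] &
                       set_results$scope_id == eff$phylogroup[i] &
                       set_results$response_label ==
                         eff$response_label[i], , drop = FALSE]
    recovered <- nrow(hit) == 1 && hit$significant && hit$retained &&
      hit$direction == sign(eff$lfc[i])
    data.frame(phylogroup = eff$phylogroup[i],
               response_label = eff$response_label[i],
               treatment = eff$treatment[i], lfc = eff$lfc[i],
               tested = nrow(hit) == 1, recovered = recovered,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, rate = mean(tab$recovered))
}

#' Score suppression of pure-abundance-shift artifacts
#'
#' A pure abundance shift moves every target of a phylogroup equally and
#' must produce no significant-and-retained set call. Returns the
#' fraction of that phylogroup's (set, treatment) results that survive
#' as significant and retained (0 is a full suppression).
#'
#' @param truth a \code{SyntheticTruth}.
#' @param set_results frame from [testGeneSets()].
#' @return list with \code{table} and \code{surviving_rate}.
#' @export
scoreAbundanceArtifact <- function(truth, set_results) {
  ab <- truth$config$abundance_shifts
  if (!nrow(ab)) stop("truth has no abundance shifts")
  rows <- list()
  for (i in seq_len(nrow(ab))) {
    hit <- set_results[set_results$contrast == ab$treatment[i] &
                       set_results$scope_id == ab$phylogroup[i], ,
                       drop = FALSE]
    rows[[i]] <- hit
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       surviving_rate = mean(tab$significant & tab$retained))
}

#' Score recovery of the cross-strain urtA module
#'
#' The implanted urtA effect gives urea-transporter targets across
#' picocyanobacterial strains a shared expression profile distinct from
#' other N-stress genes. This scorer asks whether the network stage
#' recovers that block as one module: the adjusted Rand index between
#' the binary truth labeling (urtA-block member or not, over the network
#' gene universe) and the binary prediction (member of the module
#' holding the most urtA targets). Also reports the fraction of
#' non-urtA N-stress targets inside that module.
#'
#' @param truth a \code{SyntheticTruth}.
#' @param design the [ArrayDesign].
#' @param mod result of [detectModules()].
#' @return list with \code{ari}, \code{n_stress_contamination},
#'   \code{module} (the chosen label), \code{n_urtA_in_network}.
#' @export
scoreUrtAModule <- function(truth, design, mod) {
  tg <- targetInfo(design)
  ge <- truth$config$gene_effects
  urtA_groups <- unique(ge$phylogroup[ge$gene_symbol == "urtA"])
  urtA <- tg$target_id[tg$gene_symbol == "urtA" &
                       tg$phylogroup_id %in% urtA_groups]
  genes <- names(mod$modules)
  is_urtA <- genes %in% urtA
  if (sum(is_urtA) < 2) stop("fewer than 2 urtA targets in the network")
  labs <- mod$modules
  counts <- table(labs[is_urtA])
  counts <- counts[names(counts) != "0"]
  if (!length(counts))
    return(list(ari = 0, n_stress_contamination = NA_real_,
                module = NA_integer_, n_urtA_in_network = sum(is_urtA)))
  m_star <- as.integer(names(counts)[which.max(counts)])
  pred <- labs == m_star
  n_stress <- geneSetRosters()[["N stress"]]
  in_mod <- genes[pred]
  sym <- tg$gene_symbol[match(in_mod, tg$target_id)]
  contam <- mean(sym %in% setdiff(n_stress, "urtA"))
  list(ari = adjRandIndex(is_urtA, pred),
       n_stress_contamination = contam, module = m_star,
       n_urtA_in_network = sum(is_urtA))
}
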