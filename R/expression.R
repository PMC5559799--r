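# Stress-candidate classification and efficiency-corrected relative
# expression (Pfaffl ratio with a randomization test).

#' Classify candidate stress-responsive transcripts
#'
#' Given a best-hit table of transcripts searched against a declared set of
#' stress-related proteins, candidates are the transcripts with an accepted
#' hit and coverage is the number of distinct stress proteins hit.  A hit
#' subject outside the declared set raises an error (guards against mixing
#' databases).
#'
#' @param best_hit_table a `best_hit_table` (see [best_hits()]) against the
#'   stress protein set.
#' @param stress_protein_ids character vector: the full stress protein set.
#' @return list of class `stress_candidate_report`: candidates, covered,
#'   n_candidates, n_covered, n_reference_proteins.
#' @export
stress_candidates <- function(best_hit_table, stress_protein_ids) {
  bad <- setdiff(unique(best_hit_table$subject), stress_protein_ids)
  if (length(bad))
    stop_("hit subject not in the stress protein set: %s", bad[[1]])
  candidates <- unique(best_hit_table$query)
  covered <- unique(best_hit_table$subject)
  structure(list(candidates = candidates, covered = covered,
                 n_candidates = length(candidates),
                 n_covered = length(covered),
                 n_reference_proteins = length(stress_protein_ids)),
            class = "stress_candidate_report")
}

ct_efficiency <- function(ct_table, gene, efficiency = NULL) {
  e <- if (!is.null(efficiency)) {
    if (is.null(names(efficiency)) && length(efficiency) == 1) efficiency
    else efficiency[[gene]]
  } else {
    eff <- attr(ct_table, "efficiency")
    if (!is.null(eff) && gene %in% names(eff)) eff[[gene]] else 2
  }
  if (is.null(e) || is.na(e)) e <- 2
  if (e <= 1) stop_("amplification efficiency for %s must exceed 1", gene)
  e
}

ct_means <- function(ct_table, gene, timepoint) {
  rows <- ct_table$gene == gene & ct_table$timepoint == timepoint
  ctl <- ct_table$ct[rows & ct_table$condition == "control"]
  trt <- ct_table$ct[rows & ct_table$condition == "treated"]
  if (!length(ctl) || !length(trt))
    stop_("gene %s lacks a condition at timepoint %s", gene, timepoint)
  c(control = mean(ctl), treated = mean(trt))
}

#' Efficiency-corrected relative expression (Pfaffl ratio)
#'
#' `ratio = E_gene^dCt_gene / E_ref^dCt_ref` with
#' `dCt = mean Ct(control) - mean Ct(treated)` (means over replicates), so a
#' ratio above 1 means up-regulation under treatment.  Amplification
#' efficiencies default to 2 (perfect doubling) unless carried by the Ct
#' table or passed explicitly.
#'
#' @param ct_table a `ct_table` data frame (gene, condition, timepoint,
#'   replicate, ct), e.g. from [simulate_ct_table()] or read from TSV.
#' @param gene target gene.
#' @param ref_gene reference (normaliser) gene.
#' @param timepoint timepoint label.
#' @param efficiency optional named vector of per-gene efficiencies in
#'   (1, 2].
#' @return the expression ratio (positive scalar).
#' @examples
#' ct <- simulate_ct_table(c("g1", "ref"), c(g1 = 2, ref = 1),
#'                         ref_gene = "ref", noise_sd = 0, seed = 1)
#' pfaffl_ratio(ct, "g1", "ref", "t1")   # 2
#' @export
pfaffl_ratio <- function(ct_table, gene, ref_gene, timepoint,
                         efficiency = NULL) {
  e_g <- ct_efficiency(ct_table, gene, efficiency)
  e_r <- ct_efficiency(ct_table, ref_gene, efficiency)
  m_g <- ct_means(ct_table, gene, timepoint)
  m_r <- ct_means(ct_table, ref_gene, timepoint)
  dct_g <- m_g[["control"]] - m_g[["treated"]]
  dct_r <- m_r[["control"]] - m_r[["treated"]]
  e_g^dct_g / e_r^dct_r
}

#' Signed fold change
#'
#' Maps a ratio to the signed convention of expression bar plots: the ratio
#' itself when >= 1, otherwise `-1/ratio`, so magnitudes are always >= 1 and
#' down-regulation is negative (a halving is a -2 fold change).
#'
#' @param ratio positive expression ratio(s).
#' @return signed fold change(s).
#' @examples
#' signed_fold(c(2, 1, 0.5))   # 2, 1, -2
#' @export
signed_fold <- function(ratio) {
  if (any(ratio <= 0)) stop_("ratio must be positive")
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Randomization test for a relative-expression ratio
#'
#' Permutes condition labels jointly for target and reference gene (paired
#' by replicate within the timepoint) and compares `|log ratio|` of each
#' permuted dataset against the observed one.  When the number of distinct
#' label assignments `choose(n, n_control)` does not exceed
#' `n_permutations`, all assignments are enumerated and the p-value is
#' exact; otherwise `n_permutations` random shuffles are drawn and the
#' `+1/(n+1)` correction applied.
#'
#' @param ct_table a `ct_table`.
#' @param gene,ref_gene target and reference genes.
#' @param timepoint timepoint label.
#' @param n_permutations permutation budget (>= 100).
#' @param seed integer seed for the shuffles.
#' @param efficiency optional efficiencies, see [pfaffl_ratio()].
#' @return list: p_value, n_permutations (assignments actually used),
#'   exact (logical), ratio (the observed ratio).
#' @export
randomization_test <- function(ct_table, gene, ref_gene, timepoint,
                               n_permutations = 1999L, seed,
                               efficiency = NULL) {
  stopifnot(n_permutations >= 100)
  e_g <- ct_efficiency(ct_table, gene, efficiency)
  e_r <- ct_efficiency(ct_table, ref_gene, efficiency)
  take <- function(g) {
    rows <- ct_table$gene == g & ct_table$timepoint == timepoint
    df <- ct_table[rows, c("condition", "replicate", "ct")]
    df[order(df$condition, df$replicate), ]
  }
  tg <- take(gene)
  tr <- take(ref_gene)
  if (!identical(paste(tg$condition, tg$replicate),
                 paste(tr$condition, tr$replicate)))
    stop_("target and reference replicates do not pair up")
  labels <- tg$condition
  n1 <- sum(labels == "control")
  n2 <- sum(labels == "treated")
  if (n1 < 2 || n2 < 2) stop_("need at least 2 replicates per condition")
  stat <- function(lab) {
    dct_g <- mean(tg$ct[lab == "control"]) - mean(tg$ct[lab == "treated"])
    dct_r <- mean(tr$ct[lab == "control"]) - mean(tr$ct[lab == "treated"])
    abs(dct_g * log(e_g) - dct_r * log(e_r))   # |log ratio|
  }
  obs <- stat(labels)
  tol <- 1e-12
  n_total <- choose(n1 + n2, n1)
  if (n_total <= n_permutations) {
    combos <- combn(n1 + n2, n1)
    stats <- apply(combos, 2, function(ix) {
      lab <- rep("treated", n1 + n2)
      lab[ix] <- "control"
      stat(lab)
    })
    p <- sum(stats >= obs - tol) / n_total
    list(p_value = p, n_permutations = as.integer(n_total), exact = TRUE,
         ratio = pfaffl_ratio(ct_table, gene, ref_gene, timepoint,
                              efficiency))
  } else {
    stats <- withr::with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) stat(sample(labels)), 0)
    })
    p <- (1 + sum(stats >= obs - tol)) / (n_permutations + 1)
    list(p_value = p, n_permutations = as.integer(n_permutations),
         exact = FALSE,
         ratio = pfaffl_ratio(ct_table, gene, ref_gene, timepoint,
                              efficiency))
  }
}

#' Relative expression of several genes with significance
#'
#' Convenience wrapper combining [pfaffl_ratio()], [signed_fold()] and
#' [randomization_test()] over genes and timepoints.
#'
#' @param ct_table a `ct_table`.
#' @param ref_gene reference gene.
#' @param genes genes to quantify; default all non-reference genes present.
#' @param timepoints timepoints; default all present.
#' @param n_permutations,seed see [randomization_test()].
#' @param efficiency optional efficiencies.
#' @return data frame: gene, timepoint, ratio, signed_fold, p_value,
#'   n_permutations.
#' @export
relative_expression <- function(ct_table, ref_gene, genes = NULL,
                                timepoints = NULL, n_permutations = 1999L,
                                seed = 1L, efficiency = NULL) {
  if (is.null(genes))
    genes <- setdiff(unique(ct_table$gene), ref_gene)
  if (is.null(timepoints)) timepoints <- unique(ct_table$timepoint)
  rows <- list()
  for (tp in timepoints) {
    for (g in genes) {
      ratio <- pfaffl_ratio(ct_table, g, ref_gene, tp, efficiency)
      rt <- randomization_test(ct_table, g, ref_gene, tp, n_permutations,
                               seed = seed, efficiency = efficiency)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, timepoint = tp, ratio = ratio,
        signed_fold = signed_fold(ratio), p_value = rt$p_value,
        n_permutations = rt$n_permutations, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
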