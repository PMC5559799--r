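# One-shot comparison of several assemblies across all quality metrics.

#' Compare assemblies across length, mapping and annotation metrics
#'
#' Aggregates every in-scope quality metric into one table with metrics as
#' rows and assemblies as columns, mirroring the conventional evaluation
#' grid (contig counts and lengths, N50/N90, mapping-back percentages,
#' unique proteins, RBH counts, full-length OHR counts, core completeness).
#' Metrics whose inputs are missing are reported as `NA` with a warning
#' rather than failing the whole comparison.
#'
#' @param runs named list, one element per assembly; each element is a list
#'   that may contain `assembly` (an [assembly_set]), `alignments`
#'   (alignment records), `forward_hits` / `reverse_hits` (hit data frames),
#'   `core_hits` plus `core_lengths`, and `protein_lengths` (named vector,
#'   for OHR).
#' @param thresholds list of thresholds: min_len (300), length_fraction
#'   (0.75), similarity (0.90), evalue (1e-5), full_threshold (0.8),
#'   complete_fraction (0.7).
#' @return data frame with a `metric` column and one numeric column per
#'   assembly; deterministic given its inputs.
#' @export
run_compare <- function(runs, thresholds = list()) {
  thr <- utils::modifyList(list(min_len = 300L, length_fraction = 0.75,
                                similarity = 0.90, evalue = 1e-5,
                                full_threshold = 0.8, complete_fraction = 0.7),
                           thresholds)
  metrics <- c("n_contigs", "mean_len", "min_len", "max_len", "n50", "n90",
               "pct_ge_1kb", "pct_mapped", "pct_in_pairs", "pct_broken",
               "n_unique_proteins", "n_unique_contigs_hit", "n_rbh",
               "n_ohr_full", "pct_complete_core", "pct_partial_core")
  out <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (name in names(runs)) {
    run <- runs[[name]]
    col <- setNames(rep(NA_real_, length(metrics)), metrics)
    asm <- run$assembly
    if (!is.null(asm)) {
      asm <- filter_contigs(asm, thr$min_len)
      lr <- length_report(asm)
      col[c("n_contigs", "mean_len", "min_len", "max_len", "n50", "n90",
            "pct_ge_1kb")] <-
        c(lr$n_contigs, lr$mean_len, lr$min_len, lr$max_len, lr$n50, lr$n90,
          lr$pct_ge_1kb)
    } else {
      warning(sprintf("%s: no assembly; length metrics NA", name),
              call. = FALSE)
    }
    if (!is.null(run$alignments)) {
      mr <- mapping_report(run$alignments, thr$length_fraction,
                           thr$similarity)
      col[c("pct_mapped", "pct_in_pairs", "pct_broken")] <-
        c(mr$pct_mapped, mr$pct_in_pairs, mr$pct_broken)
    } else {
      warning(sprintf("%s: no alignments; mapping metrics NA", name),
              call. = FALSE)
    }
    if (!is.null(run$forward_hits) && !is.null(run$reverse_hits)) {
      fwd <- best_hits(run$forward_hits, thr$evalue, "forward")
      rev <- best_hits(run$reverse_hits, thr$evalue, "reverse")
      col["n_unique_proteins"] <- unique_subject_count(fwd)
      col["n_unique_contigs_hit"] <- unique_subject_count(rev)
      rbh <- reciprocal_best_hits(fwd, rev)
      col["n_rbh"] <- nrow(rbh)
      if (!is.null(run$protein_lengths)) {
        ohr <- ohr_records(rbh, fwd, run$protein_lengths,
                           thr$full_threshold)
        col["n_ohr_full"] <- sum(ohr$is_full)
      } else {
        warning(sprintf("%s: no protein lengths; OHR NA", name),
                call. = FALSE)
      }
    } else {
      warning(sprintf("%s: no hit tables; annotation metrics NA", name),
              call. = FALSE)
    }
    if (!is.null(run$core_hits) && !is.null(run$core_lengths)) {
      cc <- core_completeness(run$core_hits, run$core_lengths,
                              thr$complete_fraction)
      col["pct_complete_core"] <- cc$pct_complete
      col["pct_partial_core"] <- cc$pct_partial
    } else {
      warning(sprintf("%s: no core-set hits; completeness NA", name),
              call. = FALSE)
    }
    out[[name]] <- unname(col)
  }
  out
}
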