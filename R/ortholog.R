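# Annotation-based assembly quality metrics: best hits, reciprocal best
# hits, ortholog hit ratio, core-gene completeness.

#' Best hit per query at an e-value cutoff
#'
#' Hits above the cutoff are discarded; per query the hit with the highest
#' bit score is kept.  Ties are resolved by minimum e-value, then longest
#' subject span (`send - sstart + 1`), then lexicographically smallest
#' subject id — a total order, so the result is invariant to input row
#' order.
#'
#' @param hits hit data frame ([read_hits_tabular()] layout).
#' @param evalue_cutoff maximum e-value retained (default 1e-5).
#' @param direction `"forward"` (contig vs. protein) or `"reverse"`
#'   (protein vs. contig); recorded as an attribute and checked by
#'   [reciprocal_best_hits()].
#' @return a `best_hit_table`: one row per query with the winning hit,
#'   ordered by query id.
#' @export
best_hits <- function(hits, evalue_cutoff = 1e-5, direction = "forward") {
  stopifnot(evalue_cutoff > 0)
  direction <- match.arg(direction, c("forward", "reverse"))
  h <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(h)) {
    sspan <- h$send - h$sstart + 1
    ord <- order(h$query, -h$bitscore, h$evalue, -sspan, h$subject,
                 method = "radix")
    h <- h[ord, , drop = FALSE]
    h <- h[!duplicated(h$query), , drop = FALSE]
    rownames(h) <- NULL
  }
  structure(h, direction = direction, evalue_cutoff = evalue_cutoff,
            class = c("best_hit_table", "data.frame"))
}

#' Number of distinct subjects in a best-hit table
#'
#' For a forward table this is the number of unique reference proteins
#' recovered by the assembly.
#'
#' @param table a `best_hit_table`.
#' @return integer count.
#' @export
unique_subject_count <- function(table) {
  length(unique(table$subject))
}

#' Reciprocal best hits between two best-hit tables
#'
#' A (contig, protein) pair is a reciprocal best hit when the contig's best
#' forward hit is the protein and the protein's best reverse hit is the
#' contig.  Each contig and each protein appears at most once (the result is
#' a matching).
#'
#' @param forward forward `best_hit_table` (contig -> protein).
#' @param reverse reverse `best_hit_table` (protein -> contig).
#' @return data frame with columns `contig`, `protein`.
#' @export
reciprocal_best_hits <- function(forward, reverse) {
  if (!identical(attr(forward, "direction"), "forward") ||
      !identical(attr(reverse, "direction"), "reverse"))
    stop_("direction mismatch: need one forward and one reverse table")
  if (!nrow(forward) || !nrow(reverse))
    return(data.frame(contig = character(0), protein = character(0),
                      stringsAsFactors = FALSE))
  rev_map <- setNames(reverse$subject, reverse$query)
  keep <- !is.na(rev_map[forward$subject]) &
    rev_map[forward$subject] == forward$query
  out <- data.frame(contig = forward$query[keep],
                    protein = forward$subject[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Ortholog hit ratio of one reciprocal-best-hit contig
#'
#' The OHR is the fraction of the ortholog protein covered by the contig's
#' best hit: `(send - sstart + 1) / protein_len` in amino acids.  An OHR of
#' 1 marks a full-length reconstruction; values of at least 0.8 are counted
#' as (near) full length.
#'
#' @param best_hit_entry one row of the forward `best_hit_table` (the
#'   contig's best hit against its RBH partner).
#' @param protein_len ortholog protein length in amino acids (> 0).
#' @param full_threshold OHR above which a contig counts as full length.
#' @return list: contig, protein, ohr, is_full.
#' @export
ortholog_hit_ratio <- function(best_hit_entry, protein_len,
                               full_threshold = 0.8) {
  if (protein_len <= 0) stop_("protein_len must be positive")
  ohr <- (best_hit_entry$send - best_hit_entry$sstart + 1) / protein_len
  list(contig = best_hit_entry$query, protein = best_hit_entry$subject,
       ohr = ohr, is_full = ohr >= full_threshold)
}

#' Ortholog hit ratios for every reciprocal best hit
#'
#' Only contigs with an RBH partner contribute (assessing transcript
#' integrity requires contig and best hit to be orthologs).
#'
#' @param rbh RBH pairs from [reciprocal_best_hits()].
#' @param forward forward `best_hit_table`.
#' @param protein_lengths named vector of protein lengths (amino acids).
#' @param full_threshold OHR full-length threshold, default 0.8.
#' @return data frame: contig, protein, ohr, is_full.
#' @export
ohr_records <- function(rbh, forward, protein_lengths, full_threshold = 0.8) {
  if (!nrow(rbh))
    return(data.frame(contig = character(0), protein = character(0),
                      ohr = numeric(0), is_full = logical(0),
                      stringsAsFactors = FALSE))
  idx <- match(rbh$contig, forward$query)
  missing <- rbh$protein[!rbh$protein %in% names(protein_lengths)]
  if (length(missing))
    stop_("no protein length for: %s", missing[[1]])
  plen <- protein_lengths[rbh$protein]
  if (any(plen <= 0)) stop_("protein_len must be positive")
  ohr <- (forward$send[idx] - forward$sstart[idx] + 1) / plen
  data.frame(contig = rbh$contig, protein = rbh$protein, ohr = unname(ohr),
             is_full = unname(ohr >= full_threshold),
             stringsAsFactors = FALSE)
}

#' Histogram of ortholog hit ratios
#'
#' Bins are right-open `[k*w, (k+1)*w)`; the last bin absorbs all values
#' >= 1.  Also reports the count and percentage of records at or above the
#' full-length threshold.
#'
#' @param records data frame from [ohr_records()] (or numeric OHR vector).
#' @param bin_width bin width (> 0), default 0.1.
#' @param full_threshold threshold for the full-length count, default 0.8.
#' @return list of class `ohr_distribution`: `histogram` (data frame
#'   bin_low, bin_high, count), `count_full`, `pct_full`, `n`.
#' @export
ohr_distribution <- function(records, bin_width = 0.1, full_threshold = 0.8) {
  stopifnot(bin_width > 0)
  ohr <- if (is.data.frame(records)) records$ohr else as.numeric(records)
  n_bins <- ceiling(1 / bin_width)
  idx <- pmin(floor(ohr / bin_width), n_bins - 1L)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  hist <- data.frame(bin_low = (seq_len(n_bins) - 1L) * bin_width,
                     bin_high = seq_len(n_bins) * bin_width,
                     count = counts)
  hist$bin_high[[n_bins]] <- Inf
  structure(list(histogram = hist,
                 count_full = sum(ohr >= full_threshold),
                 pct_full = if (length(ohr))
                   round(100 * sum(ohr >= full_threshold) / length(ohr), 2)
                 else 0,
                 n = length(ohr)),
            class = "ohr_distribution")
}

#' Core-gene completeness of an assembly
#'
#' Given hits of the assembly against a universal core protein set (already
#' filtered at the e-value cutoff), a core protein is *complete* when a
#' single hit covers at least `complete_fraction` of its length (inclusive)
#' and *partial* when it has any hit at all, so partial counts include
#' complete ones.  Percentages are over the full core set.
#'
#' @param hits_vs_core hit data frame with core proteins as subjects.
#' @param core_lengths named vector: core protein id -> length (aa).
#' @param complete_fraction coverage needed to call a protein complete,
#'   default 0.7.
#' @return list of class `completeness_report`: n_core, n_complete,
#'   n_partial, pct_complete, pct_partial.
#' @export
core_completeness <- function(hits_vs_core, core_lengths,
                              complete_fraction = 0.7) {
  stopifnot(complete_fraction > 0, complete_fraction <= 1)
  h <- hits_vs_core
  unknown <- setdiff(unique(h$subject), names(core_lengths))
  if (length(unknown))
    stop_("hit subject not in core set: %s", unknown[[1]])
  n_core <- length(core_lengths)
  cover <- (h$send - h$sstart + 1) / core_lengths[h$subject]
  complete_ids <- unique(h$subject[cover >= complete_fraction])
  partial_ids <- unique(h$subject)
  structure(list(n_core = n_core,
                 n_complete = length(complete_ids),
                 n_partial = length(partial_ids),
                 pct_complete = round(100 * length(complete_ids) / n_core, 2),
                 pct_partial = round(100 * length(partial_ids) / n_core, 2)),
            class = "completeness_report")
}

#' @export
print.completeness_report <- function(x, ...) {
  cat(sprintf("Core completeness: %d/%d complete (%.2f%%), %d partial (%.2f%%)\n",
              x$n_complete, x$n_core, x$pct_complete, x$n_partial,
              x$pct_partial))
  invisible(x)
}
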