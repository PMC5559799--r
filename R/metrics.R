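# Length-based and read-mapping assembly quality metrics.

#' Discard contigs below a minimum length
#'
#' De Bruijn assemblies are conventionally pruned of very short contigs
#' (default 300 bp) before evaluation.
#'
#' @param assembly an [assembly_set].
#' @param min_len minimum retained length in bases (>= 1).
#' @return an [assembly_set] with only contigs of length >= `min_len`,
#'   input order preserved.
#' @export
filter_contigs <- function(assembly, min_len = 300L) {
  stopifnot(inherits(assembly, "assembly_set"), min_len >= 1)
  keep <- contig_lengths(assembly) >= min_len
  out <- assembly
  out$seqs <- assembly$seqs[keep]
  out
}

#' Length statistics of an assembly
#'
#' N50 (N90) is the length of the contig at which the cumulative length of
#' contigs sorted in descending order first reaches 50% (90%) of the total
#' assembly size.  The mean is reported to 0.01 bp and the >= 1 kb
#' percentage to 0.01%.
#'
#' @param assembly a nonempty [assembly_set].
#' @return a list of class `length_report`: n_contigs, total_len, mean_len,
#'   min_len, max_len, n50, n90, pct_ge_1kb.
#' @examples
#' asm <- assembly_set(setNames(strrep("A", c(8, 8, 4, 3, 3, 2, 2, 2)),
#'                              paste0("c", 1:8)))
#' length_report(asm)$n50   # 8
#' @export
length_report <- function(assembly) {
  stopifnot(inherits(assembly, "assembly_set"))
  if (n_contigs(assembly) == 0) stop_("empty assembly")
  lens <- sort(contig_lengths(assembly), decreasing = TRUE)
  total <- sum(as.numeric(lens))
  cum <- cumsum(as.numeric(lens))
  n50 <- lens[[which(cum >= 0.5 * total)[[1]]]]
  n90 <- lens[[which(cum >= 0.9 * total)[[1]]]]
  structure(list(n_contigs = length(lens),
                 total_len = total,
                 mean_len = round(total / length(lens), 2),
                 min_len = min(lens), max_len = max(lens),
                 n50 = n50, n90 = n90,
                 pct_ge_1kb = round(100 * sum(lens >= 1000) / length(lens), 2)),
            class = "length_report")
}

#' @export
print.length_report <- function(x, ...) {
  cat(sprintf(paste0("Length report: %d contigs, mean %.2f bp ",
                     "[%d-%d], N50 %d, N90 %d, %.2f%% >= 1 kb\n"),
              x$n_contigs, x$mean_len, x$min_len, x$max_len,
              x$n50, x$n90, x$pct_ge_1kb))
  invisible(x)
}

#' Acceptance rule for a read placement
#'
#' A mapped record is accepted when it aligns over at least `length_fraction`
#' of the read and at least `similarity` identity over the aligned columns;
#' both comparisons are inclusive.  Records with unknown identity (missing
#' NM tag) are rejected.
#'
#' @param record one alignment record or a data frame of records.
#' @param length_fraction minimum aligned_len/read_len, in (0, 1].
#' @param similarity minimum identity, in (0, 1].
#' @return logical vector, one element per record.
#' @export
accept_alignment <- function(record, length_fraction = 0.75,
                             similarity = 0.90) {
  stopifnot(length_fraction > 0, length_fraction <= 1,
            similarity > 0, similarity <= 1)
  ok <- record$mapped &
    record$aligned_len / record$read_len >= length_fraction &
    !is.na(record$identity) & record$identity >= similarity
  ok & !is.na(ok)
}

#' Read mapping-back percentages of an assembly
#'
#' Computes, over all reads (mapped or not), the percentage with at least
#' one accepted placement (mapped back), the percentage whose two mates are
#' accepted on the same contig (in pairs), and the percentage whose mates
#' are accepted on two different contigs (broken pairs).  A mate with
#' several placements counts once, through its best accepted placement
#' (highest identity, then longest alignment).  Every read id must have
#' records for exactly mates 1 and 2.
#'
#' @param alignments alignment record data frame ([read_sam_minimal()] /
#'   [simulate_alignments()]).
#' @param length_fraction,similarity acceptance thresholds, see
#'   [accept_alignment()].
#' @return a list of class `mapping_report`: pct_mapped, pct_in_pairs,
#'   pct_broken, pct_singletons (percentages to 0.01), and the underlying
#'   counts in `counts`.
#' @export
mapping_report <- function(alignments, length_fraction = 0.75,
                           similarity = 0.90) {
  a <- alignments
  if (!nrow(a)) stop_("no alignment records")
  n_unknown <- sum(a$mapped & is.na(a$identity))
  if (n_unknown > 0)
    message(sprintf("%d mapped record(s) with unknown identity rejected",
                    n_unknown))
  a$accepted <- accept_alignment(a, length_fraction, similarity)
  # best accepted placement per (read, mate); unaccepted records only tell
  # us the mate exists
  key <- paste(a$read_id, a$mate, sep = "\r")
  ord <- order(key, !a$accepted, -ifelse(is.na(a$identity), -1, a$identity),
               -a$aligned_len)
  a <- a[ord, ]
  key <- key[ord]
  best <- a[!duplicated(key), ]
  tab <- table(best$read_id, best$mate)
  if (!all(dim(tab) == c(nrow(tab), 2L)) || any(tab != 1L)) {
    bad <- rownames(tab)[which(rowSums(tab == 1L) != 2L)]
    if (!length(bad)) bad <- rownames(tab)[[1]]
    stop_("read id without exactly one record per mate: %s", bad[[1]])
  }
  m1 <- best[best$mate == 1L, ]
  m2 <- best[best$mate == 2L, ]
  m2 <- m2[match(m1$read_id, m2$read_id), ]
  total_reads <- 2L * nrow(m1)
  both <- m1$accepted & m2$accepted
  in_pair <- both & m1$contig_id == m2$contig_id
  broken <- both & m1$contig_id != m2$contig_id
  n_mapped <- sum(m1$accepted) + sum(m2$accepted)
  n_in_pairs <- 2L * sum(in_pair)
  n_broken <- 2L * sum(broken)
  n_single <- n_mapped - n_in_pairs - n_broken
  pct <- function(x) round(100 * x / total_reads, 2)
  structure(list(pct_mapped = pct(n_mapped),
                 pct_in_pairs = pct(n_in_pairs),
                 pct_broken = pct(n_broken),
                 pct_singletons = pct(n_single),
                 counts = c(total_reads = total_reads, mapped = n_mapped,
                            in_pairs = n_in_pairs, broken = n_broken,
                            singletons = n_single,
                            unknown_identity = n_unknown)),
            class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat(sprintf(paste0("Mapping report: %.2f%% mapped back, %.2f%% in pairs, ",
                     "%.2f%% broken pairs (%d reads)\n"),
              x$pct_mapped, x$pct_in_pairs, x$pct_broken,
              x$counts[["total_reads"]]))
  invisible(x)
}
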