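# Microsatellite (SSR) mining: perfect di- to hexanucleotide repeat
# detection, canonical motif classes, flanking primer design, in-silico PCR
# and summary statistics.

DEFAULT_MIN_REPEATS <- c(`2` = 6L, `3` = 5L, `4` = 5L, `5` = 5L, `6` = 5L)

# TRUE when the motif is not a whole-number repetition of a shorter motif.
is_primitive_motif <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1)) {
    if (u %% d == 0 && strrep(substr(motif, 1, d), u / d) == motif)
      return(FALSE)
  }
  TRUE
}

#' Find perfect SSR loci in DNA sequences
#'
#' Scans for maximal perfect tandem repeats with primitive motifs of 2-6
#' bases meeting per-unit minimum repeat counts (default 6 for
#' dinucleotides, 5 otherwise).  Each repeated region is reported once, at
#' its smallest primitive unit and leftmost phase: an `(AT)8` run is a
#' dinucleotide SSR starting at the first AT, never a tetranucleotide ATAT
#' repeat nor a shifted TA report.  Mononucleotide runs are excluded.
#'
#' @param x an [assembly_set], a named character vector of sequences, or a
#'   single sequence.
#' @param min_repeats named integer vector of minimum repeat counts for unit
#'   lengths "2".."6".
#' @return data frame: contig_id, start, end (0-based half-open), motif,
#'   unit_len, repeats, class (canonical motif class).
#' @examples
#' find_ssrs(c(c1 = paste0("CCT", strrep("AG", 7), "TCC")))
#' @export
find_ssrs <- function(x, min_repeats = DEFAULT_MIN_REPEATS) {
  seqs <- if (inherits(x, "assembly_set")) x$seqs else {
    nm <- names(x) %||% sprintf("seq%d", seq_along(x))
    setNames(as.character(x), nm)
  }
  stopifnot(all(c("2", "3", "4", "5", "6") %in% names(min_repeats)))
  out <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    sr <- charToRaw(s)
    n <- length(sr)
    for (u in 2:6) {
      thr <- min_repeats[[as.character(u)]]
      if (n < u * thr) next
      eq <- sr[seq_len(n - u)] == sr[(u + 1L):n]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values & r$lengths >= u * (thr - 1L))
      for (k in runs) {
        i <- starts[[k]]                       # first position of the run
        run_len <- r$lengths[[k]] + u          # bases in the period-u run
        reps <- run_len %/% u
        if (reps < thr) next
        motif <- substr(s, i, i + u - 1L)
        if (!is_primitive_motif(motif)) next
        out[[length(out) + 1L]] <- data.frame(
          contig_id = id, start = i - 1L, end = i - 1L + reps * u,
          motif = motif, unit_len = u, repeats = reps,
          stringsAsFactors = FALSE)
      }
    }
  }
  loci <- if (length(out)) do.call(rbind, out) else
    data.frame(contig_id = character(0), start = integer(0),
               end = integer(0), motif = character(0),
               unit_len = integer(0), repeats = integer(0),
               stringsAsFactors = FALSE)
  loci <- loci[order(match(loci$contig_id, names(seqs)), loci$start,
                     loci$unit_len), , drop = FALSE]
  rownames(loci) <- NULL
  loci$class <- if (nrow(loci))
    vapply(loci$motif, canonical_class, "") else character(0)
  loci
}

#' Canonical class of an SSR motif
#'
#' A motif and its reverse complement are one class, written
#' `"smaller/revcomp"` with the lexicographically smaller member first.
#' Rotational variants are *not* merged: GA/TC and AG/CT are distinct
#' classes.
#'
#' @param motif primitive DNA motif, length 2-6.
#' @return class label such as `"GA/TC"` or `"AT/AT"`.
#' @examples
#' canonical_class("GA")  # "GA/TC"
#' canonical_class("TC")  # "GA/TC"
#' canonical_class("AG")  # "AG/CT"
#' @export
canonical_class <- function(motif) {
  rc <- revcomp(motif)
  smaller <- if (motif <= rc) motif else rc
  paste(smaller, revcomp(smaller), sep = "/")
}

primer_gc_count <- function(p) {
  sum(charToRaw(p) %in% charToRaw("GC"))
}

primer_tm <- function(p) {
  64.9 + 41 * (primer_gc_count(p) - 16.4) / nchar(p)
}

primer_ok <- function(p, constraints) {
  gc <- 100 * primer_gc_count(p) / nchar(p)
  tm <- primer_tm(p)
  gc >= constraints$gc_range[[1]] && gc <= constraints$gc_range[[2]] &&
    tm >= constraints$tm_range[[1]] && tm <= constraints$tm_range[[2]]
}

#' Default primer design constraints
#'
#' Primer length 18-24 nt, GC 40-60%, melting temperature 50-65 degrees C by
#' the GC-count formula `Tm = 64.9 + 41 (GC - 16.4) / len`, product size
#' 100-300 bp, at most 5 degrees difference between the two primers.
#'
#' @return a list of constraint values.
#' @export
primer_constraints <- function() {
  list(len_range = c(18L, 24L), gc_range = c(40, 60), tm_range = c(50, 65),
       product_range = c(100L, 300L), max_tm_diff = 5)
}

#' Design a flanking primer pair for an SSR locus
#'
#' Scans candidate windows in the flanks nearest the locus outward and
#' returns the first pair meeting every constraint (length, GC, Tm, Tm
#' difference, product size), or `NULL` when the flanking sequence is
#' insufficient.  The right primer is the reverse complement of its
#' plus-strand window, so it anneals downstream of the locus.
#'
#' @param contig_seq the contig sequence (character scalar).
#' @param locus one row of a [find_ssrs()] data frame (needs `start`,
#'   `end`; 0-based half-open on the contig).
#' @param constraints see [primer_constraints()].
#' @return a list of class `primer_pair` (left, right, left_start,
#'   right_end, tm_left, tm_right, gc_left, gc_right, expected_product,
#'   locus) or `NULL`.
#' @export
design_primers <- function(contig_seq, locus, constraints = primer_constraints()) {
  n <- nchar(contig_seq)
  lstart <- locus$start + 1L                   # 1-based first base of locus
  lend <- locus$end                            # 1-based last base of locus
  if (lstart < 1L || lend > n) stop_("locus not on contig")
  lr <- constraints$len_range
  pr <- constraints$product_range
  for (lo in 0:(pr[[2]] - 1L)) {               # left primer 3' end offset
    le <- lstart - 1L - lo
    if (le < lr[[1]]) break
    for (llen in lr[[1]]:lr[[2]]) {
      ls <- le - llen + 1L
      if (ls < 1L) break
      left <- substr(contig_seq, ls, le)
      if (!primer_ok(left, constraints)) next
      tm_l <- primer_tm(left)
      for (ro in 0:(pr[[2]] - 1L)) {           # right primer window offset
        rs <- lend + 1L + ro
        for (rlen in lr[[1]]:lr[[2]]) {
          re <- rs + rlen - 1L
          if (re > n) break
          product <- re - ls + 1L
          if (product > pr[[2]]) break
          if (product < pr[[1]]) next
          window <- substr(contig_seq, rs, re)
          if (!primer_ok(window, constraints)) next
          right <- revcomp(window)
          tm_r <- primer_tm(right)
          if (abs(tm_l - tm_r) > constraints$max_tm_diff) next
          return(structure(
            list(left = left, right = right, left_start = ls,
                 right_end = re, tm_left = tm_l, tm_right = tm_r,
                 gc_left = 100 * primer_gc_count(left) / llen,
                 gc_right = 100 * primer_gc_count(right) / rlen,
                 expected_product = product, locus = locus),
            class = "primer_pair"))
        }
        if (rs + lr[[1]] - 1L - ls + 1L > pr[[2]]) break
      }
    }
  }
  NULL
}

#' In-silico PCR of a primer pair against an assembly
#'
#' An amplicon is produced wherever the left primer matches a template
#' strand and the reverse complement of the right primer matches downstream
#' on the same strand, each with at most `max_mismatches` mismatches but an
#' exact 3'-terminal base, within `max_product` bases.  Both strands of
#' every contig are searched.  A marker producing exactly one amplicon is a
#' putative single-locus marker.
#'
#' @param primer_pair a `primer_pair` (or list with `left`, `right`).
#' @param assembly an [assembly_set] of template sequences.
#' @param max_mismatches allowed mismatches per primer, default 0.
#' @param max_product maximum product length in bases, default 3000.
#' @return list of class `amplicon_set`: `amplicons` (data frame contig_id,
#'   strand, start, end (1-based inclusive, plus-strand coordinates),
#'   product_len) and `single_locus` (exactly one amplicon).
#' @export
virtual_pcr <- function(primer_pair, assembly, max_mismatches = 0L,
                        max_product = 3000L) {
  stopifnot(max_mismatches >= 0, max_product >= 1)
  left <- primer_pair$left
  right_rc <- revcomp(primer_pair$right)
  ll <- nchar(left)
  lr <- nchar(right_rc)
  hits <- list()
  match_pos <- function(primer, template, anchor) {
    # positions (1-based) where primer matches with <= max_mismatches and
    # the 3'-anchor base matches exactly; anchor is "last" for the left
    # primer, "first" for the reverse-complemented right primer
    m <- Biostrings::matchPattern(primer, Biostrings::DNAString(template),
                                  max.mismatch = max_mismatches)
    pos <- Biostrings::start(m)
    if (!length(pos) || max_mismatches == 0L) return(pos)
    np <- nchar(primer)
    keep <- vapply(pos, function(p) {
      tb <- if (anchor == "last")
        substr(template, p + np - 1L, p + np - 1L) else substr(template, p, p)
      pb <- if (anchor == "last") substr(primer, np, np) else
        substr(primer, 1L, 1L)
      tb == pb
    }, TRUE)
    pos[keep]
  }
  for (i in seq_len(n_contigs(assembly))) {
    cid <- contig_ids(assembly)[[i]]
    plus <- assembly$seqs[[i]]
    clen <- nchar(plus)
    for (strand in c("+", "-")) {
      tmpl <- if (strand == "+") plus else revcomp(plus)
      lpos <- match_pos(left, tmpl, "last")
      rpos <- match_pos(right_rc, tmpl, "first")
      for (p in lpos) {
        for (q in rpos) {
          if (q < p + ll) next
          prod <- q + lr - 1L - p + 1L
          if (prod > max_product) next
          s <- p
          e <- q + lr - 1L
          if (strand == "-") {                 # map back to plus strand
            s_plus <- clen - e + 1L
            e_plus <- clen - p + 1L
            s <- s_plus
            e <- e_plus
          }
          hits[[length(hits) + 1L]] <- data.frame(
            contig_id = cid, strand = strand, start = s, end = e,
            product_len = prod, stringsAsFactors = FALSE)
        }
      }
    }
  }
  amp <- if (length(hits)) unique(do.call(rbind, hits)) else
    data.frame(contig_id = character(0), strand = character(0),
               start = integer(0), end = integer(0),
               product_len = integer(0), stringsAsFactors = FALSE)
  rownames(amp) <- NULL
  structure(list(amplicons = amp, single_locus = nrow(amp) == 1L),
            class = "amplicon_set")
}

#' Summary statistics of an SSR scan
#'
#' @param loci data frame from [find_ssrs()].
#' @param assembly the scanned [assembly_set].
#' @return list of class `ssr_summary`: n_sequences, n_ssrs,
#'   n_containing (sequences with >= 1 SSR), n_multi (sequences with > 1),
#'   by_unit (data frame unit_len, count, pct to 0.1%), class_freq (data
#'   frame class, count, pct), freq_kb (kilobases of assembly per SSR).
#' @export
ssr_summary <- function(loci, assembly) {
  total_bases <- sum(as.numeric(contig_lengths(assembly)))
  per_contig <- table(loci$contig_id)
  by_unit <- data.frame(unit_len = 2:6,
                        count = vapply(2:6, function(u)
                          sum(loci$unit_len == u), 0L))
  by_unit$pct <- if (nrow(loci))
    round(100 * by_unit$count / nrow(loci), 1) else 0
  cls <- sort(table(loci$class), decreasing = TRUE)
  class_freq <- data.frame(class = names(cls), count = as.integer(cls),
                           pct = if (nrow(loci))
                             round(100 * as.integer(cls) / nrow(loci), 2)
                           else numeric(0),
                           stringsAsFactors = FALSE)
  structure(list(n_sequences = n_contigs(assembly),
                 n_ssrs = nrow(loci),
                 n_containing = length(per_contig),
                 n_multi = sum(per_contig > 1L),
                 by_unit = by_unit,
                 class_freq = class_freq,
                 freq_kb = if (nrow(loci))
                   round(total_bases / 1000 / nrow(loci), 2) else NA_real_),
            class = "ssr_summary")
}

#' @export
print.ssr_summary <- function(x, ...) {
  cat(sprintf(paste0("SSR summary: %d SSRs in %d of %d sequences ",
                     "(%d with >1); one SSR per %.2f kb\n"),
              x$n_ssrs, x$n_containing, x$n_sequences, x$n_multi, x$freq_kb))
  invisible(x)
}
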