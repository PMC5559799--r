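# Independent oracles and fixture builders.  Each oracle re-derives the
# expected result by a different route than the implementation (exhaustive
# enumeration, regex engine, closed form) so agreement is informative.

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rnd_assembly <- function(n, len_range = c(50L, 2000L), prefix = "c") {
  lens <- sample(len_range[[1]]:len_range[[2]], n, replace = TRUE)
  assembly_set(setNames(vapply(lens, rnd_dna, ""),
                        sprintf("%s%03d", prefix, seq_len(n))),
               label = "random")
}

# --- length statistics: independent cumulative walk ----------------------

oracle_length_stats <- function(lens) {
  sorted <- sort(lens, decreasing = TRUE)
  total <- sum(as.numeric(sorted))
  acc <- 0
  n50 <- NA_integer_
  n90 <- NA_integer_
  for (l in sorted) {
    acc <- acc + l
    if (is.na(n50) && acc >= total / 2) n50 <- l
    if (is.na(n90) && acc >= 0.9 * total) n90 <- l
  }
  list(n50 = n50, n90 = n90, mean_len = round(total / length(lens), 2),
       pct_ge_1kb = round(100 * mean(lens >= 1000), 2))
}

# --- modified-Mott trimming: exhaustive O(n^2) segment search ------------

oracle_trim_segment <- function(qual, cutoff) {
  n <- length(qual)
  if (n == 0L) return(c(0L, -1L))
  s <- 10^(-cutoff / 10) - 10^(-qual / 10)
  b_score <- 0
  b_len <- 0L
  b_start <- 0L
  b_end <- -1L
  for (i in seq_len(n)) {
    for (j in i:n) {
      sc <- sum(s[i:j])
      len <- j - i + 1L
      if (sc > b_score ||
          (sc == b_score && (len > b_len ||
                             (len == b_len && i < b_start)))) {
        b_score <- sc
        b_len <- len
        b_start <- i
        b_end <- j
      }
    }
  }
  c(b_start, b_end)
}

# --- SSR scan: regex-lookahead enumeration -------------------------------

oracle_primitive <- function(m) {
  u <- nchar(m)
  for (d in seq_len(u - 1)) {
    if (u %% d == 0 && strrep(substr(m, 1, d), u / d) == m) return(FALSE)
  }
  TRUE
}

oracle_ssr <- function(seq, min_repeats = c(`2` = 6L, `3` = 5L, `4` = 5L,
                                            `5` = 5L, `6` = 5L)) {
  sr <- charToRaw(seq)
  n <- length(sr)
  out <- list()
  for (u in 2:6) {
    thr <- min_repeats[[as.character(u)]]
    pat <- sprintf("(?=((.{%d})\\2{%d,}))", u, thr - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (m[[1]] == -1L) next
    cs <- attr(m, "capture.start")
    cl <- attr(m, "capture.length")
    for (k in seq_along(m)) {
      i <- cs[k, 1L]
      len <- cl[k, 1L]
      if (i > 1L && i - 1L + u <= n && sr[[i - 1L]] == sr[[i - 1L + u]]) next
      motif <- substr(seq, i, i + u - 1L)
      if (!oracle_primitive(motif)) next
      reps <- len %/% u
      out[[length(out) + 1L]] <- data.frame(
        start = i - 1L, end = i - 1L + reps * u, motif = motif,
        unit_len = u, repeats = reps, stringsAsFactors = FALSE)
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(0), end = integer(0), motif = character(0),
               unit_len = integer(0), repeats = integer(0),
               stringsAsFactors = FALSE)
  df <- df[order(df$start, df$unit_len), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# --- RBH: exhaustive enumeration over the provenance truth table ---------

oracle_truth_overlaps <- function(reference, truth) {
  cds_start <- setNames(nchar(reference$utr5), reference$id)
  cds_len <- setNames(nchar(reference$cds), reference$id)
  plen <- setNames(nchar(reference$protein), reference$id)
  rows <- lapply(seq_len(nrow(truth)), function(r) {
    g <- truth$gene_id[[r]]
    a <- max(truth$t_start[[r]], cds_start[[g]])
    b <- min(truth$t_end[[r]], cds_start[[g]] + cds_len[[g]])
    if (b <= a) return(NULL)
    ss <- floor((a - cds_start[[g]]) / 3) + 1L
    se <- min(ceiling((b - cds_start[[g]]) / 3), plen[[g]])
    if (se < ss) return(NULL)
    data.frame(contig = truth$contig_id[[r]], gene = g,
               ov_aa = se - ss + 1L, ov_nt = b - a,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

oracle_rbh <- function(reference, truth, evalue_cutoff = 1e-5) {
  ov <- oracle_truth_overlaps(reference, truth)
  # e-value from coverage: 10^(-ov_aa/2) <= cutoff  <=>  ov_aa >= -2 log10(cutoff)
  ov <- ov[ov$ov_aa >= -2 * log10(evalue_cutoff), , drop = FALSE]
  if (is.null(ov) || !nrow(ov))
    return(data.frame(contig = character(0), protein = character(0),
                      stringsAsFactors = FALSE))
  # forward tie chain: bitscore (ov_aa), evalue (ov_aa), protein-side span
  # (ov_aa again), then lexicographically smallest subject
  fwd_best <- lapply(split(ov, ov$contig), function(df) {
    df <- df[order(-df$ov_aa, df$gene), , drop = FALSE]
    df[1, ]
  })
  rev_best <- lapply(split(ov, ov$gene), function(df) {
    df <- df[order(-df$ov_aa, -df$ov_nt, df$contig), , drop = FALSE]
    df[1, ]
  })
  pairs <- lapply(fwd_best, function(f) {
    rb <- rev_best[[f$gene]]
    if (!is.null(rb) && rb$contig == f$contig)
      data.frame(contig = f$contig, protein = f$gene,
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, pairs)
  if (is.null(out))
    out <- data.frame(contig = character(0), protein = character(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$contig), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- in-silico PCR: brute-force position-pair scan -----------------------

oracle_mismatches <- function(primer, window) {
  if (nchar(primer) != nchar(window)) return(Inf)
  sum(charToRaw(primer) != charToRaw(window))
}

oracle_epcr <- function(left, right, assembly, max_mismatches = 0L,
                        max_product = 3000L) {
  right_rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(right)))
  ll <- nchar(left)
  lr <- nchar(right_rc)
  hits <- list()
  for (i in seq_along(assembly$seqs)) {
    cid <- contig_ids(assembly)[[i]]
    plus <- assembly$seqs[[i]]
    clen <- nchar(plus)
    for (strand in c("+", "-")) {
      tmpl <- if (strand == "+") plus else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(plus)))
      for (p in seq_len(max(0L, clen - ll + 1L))) {
        wl <- substr(tmpl, p, p + ll - 1L)
        if (oracle_mismatches(left, wl) > max_mismatches) next
        if (substr(wl, ll, ll) != substr(left, ll, ll)) next
        for (q in seq_len(max(0L, clen - lr + 1L))) {
          if (q < p + ll) next
          prod <- q + lr - 1L - p + 1L
          if (prod > max_product) next
          wr <- substr(tmpl, q, q + lr - 1L)
          if (oracle_mismatches(right_rc, wr) > max_mismatches) next
          if (substr(wr, 1L, 1L) != substr(right_rc, 1L, 1L)) next
          s <- p
          e <- q + lr - 1L
          if (strand == "-") {
            s <- clen - e + 1L
            e <- clen - p + 1L
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
  amp
}

# sorted view of an amplicon table for set comparison
amp_key <- function(amp) {
  k <- sprintf("%s:%s:%d-%d", amp$contig_id, amp$strand, amp$start, amp$end)
  sort(k)
}

# sorted view of an SSR locus table for set comparison
ssr_key <- function(df) {
  k <- sprintf("%s:%d-%d:%s", df$contig_id, df$start, df$end, df$motif)
  sort(k)
}

# one well-formed outfmt-6 row to be overridden field-by-field
empty_hits_row <- function() {
  data.frame(query = "q", subject = "s", pct_identity = 100, align_len = 100,
             mismatches = 0, gap_opens = 0, qstart = 1, qend = 300,
             sstart = 1, send = 100, evalue = 1e-30, bitscore = 200,
             qstrand = "+", stringsAsFactors = FALSE)
}

# random outfmt-6 hit table with deliberate ties in bitscore/evalue
rnd_hits <- function(n_queries = 20, n_subjects = 10, n_rows = 60) {
  data.frame(
    query = sprintf("q%02d", sample.int(n_queries, n_rows, TRUE)),
    subject = sprintf("s%02d", sample.int(n_subjects, n_rows, TRUE)),
    pct_identity = round(runif(n_rows, 70, 100), 2),
    align_len = sample(30:300, n_rows, TRUE),
    mismatches = sample(0:10, n_rows, TRUE),
    gap_opens = sample(0:3, n_rows, TRUE),
    qstart = sample(1:50, n_rows, TRUE),
    qend = sample(200:400, n_rows, TRUE),
    sstart = sample(1:20, n_rows, TRUE),
    send = sample(40:200, n_rows, TRUE),
    evalue = 10^(-sample(0:60, n_rows, TRUE) / 2),
    bitscore = sample(seq(50, 500, by = 25), n_rows, TRUE),
    qstrand = "+", stringsAsFactors = FALSE)
}

# brute-force per-query best hit under the documented total order
oracle_best_hits <- function(hits, cutoff) {
  h <- hits[hits$evalue <= cutoff, , drop = FALSE]
  out <- lapply(split(h, h$query), function(df) {
    sspan <- df$send - df$sstart + 1
    best <- which(df$bitscore == max(df$bitscore))
    best <- best[df$evalue[best] == min(df$evalue[best])]
    best <- best[sspan[best] == max(sspan[best])]
    best <- best[order(df$subject[best])][[1]]
    df[best, , drop = FALSE]
  })
  df <- do.call(rbind, out)
  if (is.null(df)) return(NULL)
  df <- df[order(df$query), , drop = FALSE]
  rownames(df) <- NULL
  df
}
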