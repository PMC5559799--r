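# Sequence and tabular I/O: FASTA, FASTQ, minimal SAM, BLAST outfmt-6.
# Parsing is deliberately fail-loud: wrong shapes raise errors carrying ids,
# positions or line numbers rather than being silently repaired.

#' Read a FASTA file into an assembly_set
#'
#' Sequences are uppercased, `U` is mapped to `T` and whitespace inside
#' sequence lines is stripped.  Record order is preserved.  Malformed input
#' (duplicate ids, headers without sequence, non-IUPAC characters) raises an
#' error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @param label assembly label; defaults to the file name.
#' @return an [assembly_set].
#' @export
read_fasta <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[[1]])
    stop_("not FASTA: first line does not start with '>'")
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), function(t) t[[1]] %||% "", "")
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, "", collapse = "")
  # records whose header is not followed by any sequence line
  have <- as.character(seq_along(ids)) %in% names(seqs)
  if (any(!have))
    stop_("empty record (header with no sequence): %s", ids[!have][[1]])
  seqs <- seqs[as.character(seq_along(ids))]
  seqs <- chartr("u", "T", chartr("U", "T", toupper(gsub("\\s", "", seqs))))
  names(seqs) <- ids
  if (anyDuplicated(ids))
    stop_("duplicate id: %s", ids[duplicated(ids)][[1]])
  assembly_set(seqs, label = label)
}

#' Write an assembly_set as FASTA
#'
#' @param assembly an [assembly_set].
#' @param path output path.
#' @param line_width wrap width for sequence lines (>= 1).
#' @return the path, invisibly.
#' @export
write_fasta <- function(assembly, path, line_width = 60L) {
  stopifnot(inherits(assembly, "assembly_set"))
  if (line_width < 1) stop_("line_width must be >= 1")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(assembly$seqs)) {
    s <- assembly$seqs[[i]]
    writeLines(paste0(">", names(assembly$seqs)[[i]]), con)
    starts <- seq(1L, nchar(s), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read FASTQ reads
#'
#' Minimal four-line-record FASTQ reader for quality-trimming input.  Phred
#' scores are decoded from the Sanger (+33) encoding.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return a list of reads; each read is a list with elements `id`, `seq`,
#'   `qual` (integer Phred scores) and `mate` (1 or 2, parsed from a trailing
#'   `/1` / `/2` id suffix when present, else 1).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) %% 4 != 0)
    stop_("truncated FASTQ: %d lines is not a multiple of 4", length(lines))
  n <- length(lines) / 4
  lapply(seq_len(n), function(i) {
    id <- sub("^@", "", lines[[4 * i - 3]])
    seq <- toupper(lines[[4 * i - 2]])
    qual <- as.integer(charToRaw(lines[[4 * i]])) - 33L
    if (nchar(seq) != length(qual))
      stop_("read %s: sequence and quality lengths differ", id)
    mate <- if (grepl("/2$", id)) 2L else 1L
    list(id = sub("/[12]$", "", id), seq = seq, qual = qual, mate = mate)
  })
}

#' Quality-trim a read (modified-Mott algorithm)
#'
#' Retains the contiguous subread maximising `sum(L - p_i)` where
#' `p_i = 10^(-q_i/10)` is the per-base error probability and
#' `L = 10^(-cutoff/10)` the error limit implied by the Phred cutoff.  Bases
#' above the cutoff contribute positively, bases below negatively; the
#' optimum is found in one pass over prefix sums.  Ties are broken towards
#' the longer segment, then the leftmost start.  The result may be empty when
#' every base is below the cutoff.
#'
#' @param read a read as returned by [read_fastq()] (elements `seq`, `qual`).
#' @param phred_cutoff Phred threshold, default 20.
#' @return the read with `seq` and `qual` replaced by the retained segment.
#' @examples
#' r <- list(id = "r1", seq = "ACGTACGT", qual = rep(30L, 8), mate = 1L)
#' quality_trim(r, 20)$seq
#' @export
quality_trim <- function(read, phred_cutoff = 20) {
  stopifnot(phred_cutoff >= 0)
  n <- length(read$qual)
  if (n == 0L) return(read)
  p <- 10^(-read$qual / 10)
  lim <- 10^(-phred_cutoff / 10)
  s <- lim - p
  pref <- c(0, cumsum(s))
  # best segment [i, e]: score pref[e+1] - pref[i]; track earliest minimum
  # prefix so equal scores resolve to the longest / leftmost segment.
  best <- c(score = 0, len = 0, start = 0L, end = -1L)
  minval <- pref[[1]]
  minidx <- 0L
  for (e in seq_len(n)) {
    sc <- pref[[e + 1]] - minval
    len <- e - minidx
    if (sc > best[["score"]] ||
        (sc == best[["score"]] &&
         (len > best[["len"]] ||
          (len == best[["len"]] && minidx + 1L < best[["start"]])))) {
      best <- c(score = sc, len = len, start = minidx + 1L, end = e)
    }
    if (pref[[e + 1]] < minval) {
      minval <- pref[[e + 1]]
      minidx <- e
    }
  }
  if (best[["len"]] == 0) {
    read$seq <- ""
    read$qual <- integer(0)
  } else {
    read$seq <- substr(read$seq, best[["start"]], best[["end"]])
    read$qual <- read$qual[best[["start"]]:best[["end"]]]
  }
  read
}

HIT_COLS <- c("query", "subject", "pct_identity", "align_len", "mismatches",
              "gap_opens", "qstart", "qend", "sstart", "send",
              "evalue", "bitscore")
HIT_NUM_COLS <- HIT_COLS[3:12]

#' Read a 12-column BLAST tabular (outfmt 6) hit file
#'
#' Exactly twelve tab-separated columns per line are required; extra or
#' missing columns raise an error with the line number (fail-loud dialect).
#' Rows with `qstart > qend` (minus-strand nucleotide queries) are normalised
#' by swapping the two coordinates; the original orientation is kept in a
#' `qstrand` column so downstream span arithmetic can assume
#' `qstart <= qend`.
#'
#' @param path path to the tab-separated hit table.
#' @return a data frame with columns query, subject, pct_identity,
#'   align_len, mismatches, gap_opens, qstart, qend, sstart, send, evalue,
#'   bitscore, qstrand.
#' @export
read_hits_tabular <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[[1]]
    stop_("line %d: expected 12 tab-separated columns, got %d", i, nf[[i]])
  }
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  df <- data.frame(query = m[, 1], subject = m[, 2], stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      i <- which(is.na(v))[[1]]
      stop_("line %d: unparseable numeric in column %d ('%s')", i, j, m[i, j])
    }
    df[[HIT_COLS[[j]]]] <- v
  }
  if (any(df$evalue < 0)) stop_("negative e-value")
  if (any(df$align_len < 1)) stop_("alignment length < 1")
  minus <- df$qstart > df$qend
  df$qstrand <- ifelse(minus, "-", "+")
  if (any(minus)) {
    tmp <- df$qstart[minus]
    df$qstart[minus] <- df$qend[minus]
    df$qend[minus] <- tmp
  }
  df
}

empty_hits <- function() {
  df <- data.frame(query = character(0), subject = character(0),
                   stringsAsFactors = FALSE)
  for (col in HIT_NUM_COLS) df[[col]] <- numeric(0)
  df$qstrand <- character(0)
  df
}

#' Write hit records as 12-column BLAST tabular (outfmt 6)
#'
#' Numeric fields are written with enough significant digits to round-trip
#' through [read_hits_tabular()] exactly.
#'
#' @param hits a hit data frame (see [read_hits_tabular()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_hits_tabular <- function(hits, path) {
  stopifnot(all(HIT_COLS %in% c(names(hits), "qstrand") |
                HIT_COLS %in% names(hits)))
  fmt <- function(x) sprintf("%.15g", x)
  lines <- paste(hits$query, hits$subject, fmt(hits$pct_identity),
                 fmt(hits$align_len), fmt(hits$mismatches),
                 fmt(hits$gap_opens), fmt(hits$qstart), fmt(hits$qend),
                 fmt(hits$sstart), fmt(hits$send), fmt(hits$evalue),
                 fmt(hits$bitscore), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a minimal subset of a SAM file
#'
#' Parses the fields the mapping metrics need: FLAG (mapped bit 0x4, mate
#' bits 0x40/0x80), RNAME, CIGAR, RNEXT and the `NM:i:` edit-distance tag.
#' Per record: `aligned_len` is the summed length of M/=/X CIGAR operations,
#' `read_len` additionally includes I and S, and identity is taken as
#' `1 - NM/aligned_len` (NM counts mismatches plus indel bases; the aligned
#' columns are used as denominator).  Records without an NM tag get
#' `identity = NA` and are flagged.
#'
#' @param path path to a SAM text file.
#' @return a data frame of alignment records with columns read_id, mate,
#'   mapped, contig_id, aligned_len, read_len, identity, mate_contig_id,
#'   missing_nm.
#' @export
read_sam_minimal <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  lines <- readLines(path)
  aln <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (!length(aln)) return(empty_alignments())
  parts <- strsplit(aln, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L)) {
    i <- which(nf < 11L)[[1]]
    stop_("SAM line %d: fewer than 11 fields", i)
  }
  recs <- lapply(seq_along(parts), function(i) {
    f <- parts[[i]]
    flag <- as.integer(f[[2]])
    mapped <- bitwAnd(flag, 4L) == 0L
    mate <- if (bitwAnd(flag, 128L) != 0L) 2L else 1L
    cig <- parse_cigar(f[[6]], i)
    read_len <- sum(cig$len[cig$op %in% c("M", "I", "S", "=", "X")])
    aligned_len <- sum(cig$len[cig$op %in% c("M", "=", "X")])
    if (!mapped && read_len == 0L) read_len <- nchar(f[[10]])
    tags <- f[-(1:11)]
    nm_tag <- grep("^NM:i:", tags, value = TRUE)
    nm <- if (length(nm_tag)) as.integer(sub("^NM:i:", "", nm_tag[[1]])) else NA_integer_
    identity <- if (mapped && !is.na(nm) && aligned_len > 0)
      1 - nm / aligned_len else NA_real_
    rnext <- f[[7]]
    mate_contig <- if (rnext == "=") f[[3]] else if (rnext == "*") NA_character_ else rnext
    list(read_id = f[[1]], mate = mate, mapped = mapped,
         contig_id = if (mapped) f[[3]] else NA_character_,
         aligned_len = as.integer(aligned_len), read_len = as.integer(read_len),
         identity = identity,
         mate_contig_id = if (mapped) mate_contig else NA_character_,
         missing_nm = mapped && is.na(nm))
  })
  df <- do.call(rbind, lapply(recs, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  if (any(df$missing_nm))
    warning(sprintf("%d mapped record(s) without NM tag: identity unknown",
                    sum(df$missing_nm)), call. = FALSE)
  df
}

empty_alignments <- function() {
  data.frame(read_id = character(0), mate = integer(0), mapped = logical(0),
             contig_id = character(0), aligned_len = integer(0),
             read_len = integer(0), identity = numeric(0),
             mate_contig_id = character(0), missing_nm = logical(0),
             stringsAsFactors = FALSE)
}

parse_cigar <- function(cigar, line = NA) {
  if (cigar == "*") return(list(op = character(0), len = integer(0)))
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  if (m[[1]] == -1L || sum(attr(m, "match.length")) != nchar(cigar))
    stop_("SAM line %s: malformed CIGAR '%s'", as.character(line), cigar)
  list(op = substring(toks, nchar(toks), nchar(toks)),
       len = as.integer(substring(toks, 1, nchar(toks) - 1L)))
}

#' Write alignment records as a SAM file
#'
#' Emits a header (`@SQ` per contig) and one minimal alignment line per
#' record, with the fields [read_sam_minimal()] consumes (FLAG, RNAME,
#' CIGAR, RNEXT, `NM:i:` tag).  Sequence and quality strings are synthesized
#' as the CIGAR implies.
#'
#' @param alignments alignment record data frame (see [read_sam_minimal()]).
#' @param assembly the [assembly_set] the records refer to (for `@SQ` lines).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_sam <- function(alignments, assembly, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  lens <- contig_lengths(assembly)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", contig_ids(assembly), lens), con)
  a <- alignments
  flag <- 1L +
    ifelse(a$mate == 2L, 128L, 64L) +
    ifelse(a$mapped, 0L, 4L)
  nm <- ifelse(a$mapped, as.integer(round((1 - a$identity) * a$aligned_len)), 0L)
  cigar <- ifelse(a$mapped, sprintf("%dM", a$aligned_len), "*")
  rname <- ifelse(a$mapped, a$contig_id, "*")
  rnext <- ifelse(a$mapped & !is.na(a$mate_contig_id),
                  ifelse(a$mate_contig_id == a$contig_id, "=", a$mate_contig_id),
                  "*")
  seqs <- vapply(a$read_len, function(n) strrep("A", n), "")
  qual <- vapply(a$read_len, function(n) strrep("I", n), "")
  lines <- paste(a$read_id, flag, rname,
                 ifelse(a$mapped, 1L, 0L), ifelse(a$mapped, 60L, 0L),
                 cigar, rnext, 0L, 0L, seqs, qual,
                 sprintf("NM:i:%d", nm), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}
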