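# Synthetic ground-truth generators.  Every generator is seed-deterministic:
# identical arguments produce byte-identical output.  The generated artifacts
# satisfy the preconditions of the consuming modules, so downstream metrics
# can be tested against planted truth without any external dataset.

SENSE_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
})
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate a ground-truth reference transcriptome with ortholog proteins
#'
#' Each gene is a transcript `utr5 + cds + utr3`: the CDS starts with ATG,
#' ends with a single stop codon, contains no internal stops, and translates
#' (standard genetic code) to the recorded protein.  UTRs are uniform random
#' DNA.  This plays the role of the related-species proteome that ortholog
#' metrics are computed against.
#'
#' @param n_genes number of genes (>= 1).
#' @param cds_len_range integer range (nt) the CDS length is drawn from;
#'   must admit a multiple of 3 that is >= 9.
#' @param utr_len_range integer range (nt) for each UTR.
#' @param seed integer seed fixing all randomness.
#' @return a data frame of class `reference_set` with columns id, utr5, cds,
#'   utr3, protein; transcripts are obtained with [ref_transcripts()].
#' @examples
#' ref <- generate_reference(5, seed = 1)
#' nchar(ref$protein)
#' @export
generate_reference <- function(n_genes, cds_len_range = c(300, 900),
                               utr_len_range = c(50, 200), seed) {
  stopifnot(n_genes >= 1, length(cds_len_range) == 2, length(utr_len_range) == 2)
  lo <- max(9, cds_len_range[[1]])
  hi <- cds_len_range[[2]]
  aa_lo <- ceiling(lo / 3)
  aa_hi <- floor(hi / 3)
  if (aa_lo > aa_hi)
    stop_("cds_len_range [%d, %d] admits no multiple of 3 >= 9", lo, hi)
  withr::with_seed(seed, {
    genes <- lapply(seq_len(n_genes), function(i) {
      n_codons <- sample1(aa_lo:aa_hi)            # includes the stop codon
      body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
      codons <- c("ATG", body, sample1(STOP_CODONS))
      cds <- paste(codons, collapse = "")
      protein <- paste(Biostrings::GENETIC_CODE[codons[-length(codons)]],
                       collapse = "")
      data.frame(id = sprintf("gene_%04d", i),
                 utr5 = random_dna(sample1(utr_len_range[[1]]:utr_len_range[[2]])),
                 cds = cds,
                 utr3 = random_dna(sample1(utr_len_range[[1]]:utr_len_range[[2]])),
                 protein = protein, stringsAsFactors = FALSE)
    })
    ref <- do.call(rbind, genes)
    class(ref) <- c("reference_set", "data.frame")
    ref
  })
}

#' Full transcripts of a reference set
#'
#' @param reference a `reference_set` from [generate_reference()].
#' @return named character vector of `utr5 + cds + utr3` transcripts.
#' @export
ref_transcripts <- function(reference) {
  setNames(paste0(reference$utr5, reference$cds, reference$utr3), reference$id)
}

#' Proteome of a reference set as an assembly-like FASTA writable object
#'
#' @param reference a `reference_set`.
#' @return named character vector of protein sequences.
#' @export
ref_proteins <- function(reference) {
  setNames(reference$protein, reference$id)
}

#' Derive a corrupted candidate assembly from a reference transcriptome
#'
#' Emulates assemblies of graded quality: each gene yields one contig
#' retaining a controlled fraction of its transcript; a fraction of contigs
#' is reverse-complemented; chimeric contigs concatenate fragments of two
#' genes; duplicate contigs are exact copies.  All provenance is recorded in
#' a truth table (one row per contig segment, 0-based half-open intervals on
#' the source transcript) enabling parameter-recovery tests downstream.
#'
#' Fragment lengths are drawn as `Uniform(0.8 f, min(1, 1.2 f))` of the
#' transcript length (exactly full length when `fragmentation = 1`), so the
#' mean retained fraction tracks `f`.  Fractions of contigs are converted to
#' whole counts by rounding half away from zero.
#'
#' @param reference a `reference_set`.
#' @param fragmentation fraction in (0, 1] of the transcript each contig
#'   retains (1 = full-length contigs).
#' @param duplication_rate fraction of contigs duplicated.
#' @param revcomp_rate fraction of contigs reverse-complemented.
#' @param chimera_rate fraction (of genes) of additional two-gene chimeras.
#' @param seed integer seed.
#' @param label assembly label.
#' @return list with `assembly` (an [assembly_set]) and `truth` (data frame:
#'   contig_id, segment, gene_id, t_start, t_end, strand, is_chimera,
#'   duplicate_of).
#' @export
corrupt_assembly <- function(reference, fragmentation = 1,
                             duplication_rate = 0, revcomp_rate = 0,
                             chimera_rate = 0, seed,
                             label = sprintf("synth_f%.2f", fragmentation)) {
  stopifnot(fragmentation > 0, fragmentation <= 1,
            duplication_rate >= 0, duplication_rate <= 1,
            revcomp_rate >= 0, revcomp_rate <= 1,
            chimera_rate >= 0, chimera_rate <= 1)
  tx <- ref_transcripts(reference)
  n <- length(tx)
  withr::with_seed(seed, {
    frag_interval <- function(len) {
      f <- if (fragmentation == 1) 1 else
        runif(1, 0.8 * fragmentation, min(1, 1.2 * fragmentation))
      clen <- max(1L, round_half_away(f * len))
      s0 <- sample.int(len - clen + 1L, 1) - 1L
      c(s0, s0 + clen)
    }
    seqs <- character(0)
    truth <- list()
    add_truth <- function(contig, segment, gene, iv, strand, chim, dup) {
      truth[[length(truth) + 1L]] <<- data.frame(
        contig_id = contig, segment = segment, gene_id = gene,
        t_start = iv[[1]], t_end = iv[[2]], strand = strand,
        is_chimera = chim, duplicate_of = dup, stringsAsFactors = FALSE)
    }
    n_rc <- round_half_away(revcomp_rate * n)
    rc_idx <- if (n_rc > 0) sample.int(n, n_rc) else integer(0)
    for (i in seq_len(n)) {
      gene <- names(tx)[[i]]
      iv <- frag_interval(nchar(tx[[i]]))
      s <- substr(tx[[i]], iv[[1]] + 1L, iv[[2]])
      strand <- "+"
      if (i %in% rc_idx) {
        s <- revcomp(s)
        strand <- "-"
      }
      id <- paste0("ctg_", gene)
      seqs[[id]] <- s
      add_truth(id, 1L, gene, iv, strand, FALSE, NA_character_)
    }
    n_chim <- round_half_away(chimera_rate * n)
    for (k in seq_len(n_chim)) {
      pair <- sample.int(n, 2)
      id <- sprintf("chim_%03d", k)
      parts <- character(2)
      for (j in 1:2) {
        gi <- pair[[j]]
        iv <- frag_interval(nchar(tx[[gi]]))
        parts[[j]] <- substr(tx[[gi]], iv[[1]] + 1L, iv[[2]])
        add_truth(id, j, names(tx)[[gi]], iv, "+", TRUE, NA_character_)
      }
      seqs[[id]] <- paste0(parts[[1]], parts[[2]])
    }
    n_dup <- round_half_away(duplication_rate * n)
    dup_src <- if (n_dup > 0) resample(names(seqs)[seq_len(n)], n_dup) else character(0)
    truth_df <- do.call(rbind, truth)
    for (k in seq_along(dup_src)) {
      src <- dup_src[[k]]
      id <- sprintf("%s_dup%02d", src, k)
      seqs[[id]] <- seqs[[src]]
      src_rows <- truth_df[truth_df$contig_id == src, , drop = FALSE]
      src_rows$contig_id <- id
      src_rows$duplicate_of <- src
      truth_df <- rbind(truth_df, src_rows)
    }
    rownames(truth_df) <- NULL
    list(assembly = assembly_set(seqs, label = label), truth = truth_df)
  })
}

#' Plant perfect SSR loci at known coordinates
#'
#' Replaces a window of each selected contig with `motif` repeated `k` times,
#' choosing insertion sites whose flanking bases cannot extend the repeat
#' (the base left of the locus differs from the motif base one period
#' earlier, and symmetrically on the right), which guarantees the planted
#' locus is maximal.  Contigs too short to host a locus with flanks are
#' skipped with a message.
#'
#' @param assembly an [assembly_set].
#' @param motif_pool character vector of primitive motifs, lengths 2-6.
#' @param repeats_range integer range the repeat count is drawn from.
#' @param per_contig_rate fraction of contigs receiving one planted locus.
#' @param seed integer seed.
#' @return list with `assembly` (sequences modified in place) and `truth`
#'   (data frame: contig_id, start, end (0-based half-open), motif, repeats).
#' @export
plant_ssrs <- function(assembly, motif_pool = c("AG", "GA", "AT", "ATG",
                                                "AAG", "AAAG", "AAAAG",
                                                "AAAAAG"),
                       repeats_range = c(6, 10), per_contig_rate = 1, seed) {
  stopifnot(inherits(assembly, "assembly_set"))
  if (any(nchar(motif_pool) < 2 | nchar(motif_pool) > 6))
    stop_("motifs must have length 2-6")
  if (any(!vapply(motif_pool, is_primitive_motif, TRUE)))
    stop_("motif pool contains a non-primitive motif")
  withr::with_seed(seed, {
    n <- n_contigs(assembly)
    n_sel <- round_half_away(per_contig_rate * n)
    sel <- if (n_sel > 0) sort(sample.int(n, n_sel)) else integer(0)
    truth <- list()
    seqs <- assembly$seqs
    for (i in sel) {
      id <- names(seqs)[[i]]
      s <- seqs[[i]]
      motif <- sample1(motif_pool)
      u <- nchar(motif)
      reps <- sample1(repeats_range[[1]]:repeats_range[[2]])
      span <- reps * u
      if (nchar(s) < span + 2L) {
        message(sprintf("contig %s too short for a %d-bp locus; skipped",
                        id, span))
        next
      }
      first <- substr(motif, 1, 1)
      last <- substr(motif, u, u)
      cand <- resample(seq(2L, nchar(s) - span),
                       min(50L, nchar(s) - span - 1L))
      placed <- FALSE
      for (p in cand) {               # 1-based start of the locus
        left_ok <- substr(s, p - 1L, p - 1L) != last
        right_ok <- substr(s, p + span, p + span) != first
        if (left_ok && right_ok) {
          substr(s, p, p + span - 1L) <- strrep(motif, reps)
          truth[[length(truth) + 1L]] <- data.frame(
            contig_id = id, start = p - 1L, end = p - 1L + span,
            motif = motif, repeats = reps, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        message(sprintf("no maximal insertion site found on contig %s; skipped", id))
      seqs[[i]] <- s
    }
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(contig_id = character(0), start = integer(0),
                 end = integer(0), motif = character(0),
                 repeats = integer(0), stringsAsFactors = FALSE)
    list(assembly = assembly_set(seqs, label = assembly$label),
         truth = truth_df)
  })
}

#' Simulate paired-read alignment records with controlled fractions
#'
#' Produces exactly `round(n_pairs * unmapped_frac)` fully unmapped pairs
#' (rounding half away from zero), `round(n_pairs * broken_frac)` pairs with
#' mates on two different contigs, and proper pairs (both mates on one
#' contig) for the remainder.  All mapped records align over their full
#' length at identity 1, so they pass any acceptance rule up to
#' length-fraction/similarity 1/1 by construction.
#'
#' @param assembly an [assembly_set]; contigs must be at least `read_len`
#'   long, and at least two are needed when `broken_frac > 0`.
#' @param n_pairs number of read pairs.
#' @param unmapped_frac,broken_frac fractions in `[0, 1]` with sum <= 1.
#' @param seed integer seed.
#' @param read_len read length in bases.
#' @param sam_path optional path; when given the records are also written as
#'   a SAM file via [write_sam()].
#' @return alignment record data frame (same shape as [read_sam_minimal()]).
#' @export
simulate_alignments <- function(assembly, n_pairs, unmapped_frac = 0,
                                broken_frac = 0, seed, read_len = 100L,
                                sam_path = NULL) {
  stopifnot(unmapped_frac >= 0, broken_frac >= 0,
            unmapped_frac + broken_frac <= 1)
  ids <- contig_ids(assembly)[contig_lengths(assembly) >= read_len]
  if (!length(ids)) stop_("no contig is at least read_len bases long")
  n_un <- round_half_away(n_pairs * unmapped_frac)
  n_br <- round_half_away(n_pairs * broken_frac)
  n_pr <- n_pairs - n_un - n_br
  if (n_pr < 0) stop_("rounded unmapped + broken pairs exceed n_pairs")
  if (n_br > 0 && length(ids) < 2)
    stop_("broken pairs require at least two contigs of sufficient length")
  withr::with_seed(seed, {
    rec <- function(pair_id, mate, mapped, contig, mate_contig) {
      data.frame(read_id = pair_id, mate = mate, mapped = mapped,
                 contig_id = contig,
                 aligned_len = if (mapped) read_len else 0L,
                 read_len = read_len,
                 identity = if (mapped) 1 else NA_real_,
                 mate_contig_id = mate_contig, missing_nm = FALSE,
                 stringsAsFactors = FALSE)
    }
    out <- vector("list", 2L * n_pairs)
    k <- 0L
    add <- function(r) { k <<- k + 1L; out[[k]] <<- r }
    for (i in seq_len(n_pr)) {
      ctg <- sample1(ids)
      id <- sprintf("pair_%05d", i)
      add(rec(id, 1L, TRUE, ctg, ctg))
      add(rec(id, 2L, TRUE, ctg, ctg))
    }
    for (i in seq_len(n_br)) {
      ctgs <- resample(ids, 2L)
      id <- sprintf("pair_%05d", n_pr + i)
      add(rec(id, 1L, TRUE, ctgs[[1]], ctgs[[2]]))
      add(rec(id, 2L, TRUE, ctgs[[2]], ctgs[[1]]))
    }
    for (i in seq_len(n_un)) {
      id <- sprintf("pair_%05d", n_pr + n_br + i)
      add(rec(id, 1L, FALSE, NA_character_, NA_character_))
      add(rec(id, 2L, FALSE, NA_character_, NA_character_))
    }
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    if (!is.null(sam_path)) write_sam(df, assembly, sam_path)
    df
  })
}

#' Synthetic homology hit tables derived from assembly provenance
#'
#' Builds the forward (contig vs. protein) and reverse (protein vs. contig)
#' hit tables an aligner would produce, computed arithmetically from the
#' truth table rather than by alignment: each contig hits the protein(s) of
#' its source gene(s) over exactly the part of the CDS it covers.  E-values
#' decrease and bit scores increase monotonically with the covered length
#' (in amino acids), so best-hit selection reflects coverage.  Chimeras hit
#' both source proteins.
#'
#' @param reference a `reference_set`.
#' @param truth truth table from [corrupt_assembly()].
#' @return list with `forward` and `reverse` hit data frames in the
#'   [read_hits_tabular()] layout.
#' @export
hits_from_truth <- function(reference, truth) {
  cds_start <- nchar(reference$utr5)            # 0-based CDS start
  cds_len <- nchar(reference$cds)
  prot_len <- nchar(reference$protein)
  names(cds_start) <- names(cds_len) <- names(prot_len) <- reference$id
  fwd <- list()
  rev <- list()
  seg_offset <- integer(nrow(truth))
  # contig-local offset of each truth segment (chimera segment 2 starts
  # after segment 1)
  for (cid in unique(truth$contig_id)) {
    rows <- which(truth$contig_id == cid)
    off <- 0L
    for (r in rows[order(truth$segment[rows])]) {
      seg_offset[[r]] <- off
      off <- off + (truth$t_end[[r]] - truth$t_start[[r]])
    }
  }
  for (r in seq_len(nrow(truth))) {
    gene <- truth$gene_id[[r]]
    a <- max(truth$t_start[[r]], cds_start[[gene]])
    b <- min(truth$t_end[[r]], cds_start[[gene]] + cds_len[[gene]])
    if (b <= a) next
    sstart <- floor((a - cds_start[[gene]]) / 3) + 1L
    send <- min(ceiling((b - cds_start[[gene]]) / 3), prot_len[[gene]])
    if (send < sstart) next
    ov_aa <- send - sstart + 1L
    seg_len <- truth$t_end[[r]] - truth$t_start[[r]]
    qs_local <- a - truth$t_start[[r]]          # 0-based within segment
    qe_local <- b - truth$t_start[[r]]
    if (truth$strand[[r]] == "-") {
      tmp <- qs_local
      qs_local <- seg_len - qe_local
      qe_local <- seg_len - tmp
    }
    qstart <- seg_offset[[r]] + qs_local + 1L
    qend <- seg_offset[[r]] + qe_local
    evalue <- 10^(-pmin(180, ov_aa / 2))
    bitscore <- 2 * ov_aa
    fwd[[length(fwd) + 1L]] <- data.frame(
      query = truth$contig_id[[r]], subject = gene, pct_identity = 100,
      align_len = ov_aa, mismatches = 0, gap_opens = 0,
      qstart = qstart, qend = qend, sstart = sstart, send = send,
      evalue = evalue, bitscore = bitscore,
      qstrand = truth$strand[[r]], stringsAsFactors = FALSE)
    rev[[length(rev) + 1L]] <- data.frame(
      query = gene, subject = truth$contig_id[[r]], pct_identity = 100,
      align_len = ov_aa, mismatches = 0, gap_opens = 0,
      qstart = sstart, qend = send, sstart = qstart, send = qend,
      evalue = evalue, bitscore = bitscore,
      qstrand = "+", stringsAsFactors = FALSE)
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else empty_hits()
  list(forward = bind(fwd), reverse = bind(rev))
}

#' Simulate a qRT-PCR Ct table from known expression ratios
#'
#' Ct values follow `Ct = base - log_E(expression) + Normal(0, noise_sd)`
#' with control expression 1 and treated expression equal to the true ratio,
#' so with `noise_sd = 0` the efficiency-corrected ratio recovers the truth
#' exactly.  The reference gene must have true ratio 1.
#'
#' @param genes character vector of gene names (including `ref_gene`).
#' @param true_ratios named numeric vector of treated/control expression
#'   ratios per gene.
#' @param efficiencies named numeric vector of amplification efficiencies in
#'   (1, 2]; defaults to 2 for every gene.
#' @param ref_gene name of the reference (normaliser) gene.
#' @param n_replicates biological replicates per condition.
#' @param noise_sd Gaussian noise on Ct, in cycles.
#' @param seed integer seed.
#' @param timepoint timepoint label for all rows.
#' @return a `ct_table` data frame (gene, condition, timepoint, replicate,
#'   ct) with the efficiencies attached as attribute `efficiency`.
#' @export
simulate_ct_table <- function(genes, true_ratios, efficiencies = NULL,
                              ref_gene, n_replicates = 3, noise_sd = 0,
                              seed, timepoint = "t1") {
  stopifnot(noise_sd >= 0, n_replicates >= 1)
  if (!ref_gene %in% genes) stop_("reference gene %s not in genes", ref_gene)
  if (is.null(efficiencies)) efficiencies <- setNames(rep(2, length(genes)), genes)
  if (any(efficiencies <= 1) || any(efficiencies > 2))
    stop_("efficiencies must lie in (1, 2]")
  if (is.na(true_ratios[[ref_gene]]) || true_ratios[[ref_gene]] != 1)
    stop_("reference gene must have true ratio 1")
  withr::with_seed(seed, {
    rows <- list()
    for (g in genes) {
      base_ct <- runif(1, 18, 26)
      e <- efficiencies[[g]]
      for (cond in c("control", "treated")) {
        expr <- if (cond == "treated") true_ratios[[g]] else 1
        mu <- base_ct - log(expr, base = e)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, condition = cond, timepoint = timepoint,
          replicate = seq_len(n_replicates),
          ct = mu + rnorm(n_replicates, 0, noise_sd),
          stringsAsFactors = FALSE)
      }
    }
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL
    attr(ct, "efficiency") <- efficiencies
    class(ct) <- c("ct_table", "data.frame")
    ct
  })
}
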