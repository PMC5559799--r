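test_that("repeat-count thresholds are exact per unit length", {
  flank <- "CCTTC"
  hit6 <- paste0(flank, strrep("AG", 6), flank)
  miss5 <- paste0(flank, strrep("AG", 5), flank)
  expect_equal(nrow(find_ssrs(c(x = hit6))), 1L)
  expect_equal(find_ssrs(c(x = hit6))$repeats, 6L)
  expect_equal(nrow(find_ssrs(c(x = miss5))), 0L)
  tri <- paste0(flank, strrep("ATG", 5), flank)
  loci <- find_ssrs(c(x = tri))
  expect_equal(loci$unit_len, 3L)
  expect_equal(loci$repeats, 5L)
})

test_that("runs are reported once, at the smallest unit and leftmost phase", {
  s <- paste0("CC", strrep("AT", 8), "GG")
  loci <- find_ssrs(c(x = s))
  expect_equal(nrow(loci), 1L)       # never an ATAT tetranucleotide report
  expect_equal(loci$unit_len, 2L)
  expect_equal(loci$motif, "AT")
  expect_equal(loci$start, 2L)
  # (AG)x7 also contains (GA)x6 one base in; only the run start reports
  s2 <- paste0("CCT", strrep("AG", 7), "TCC")
  loci2 <- find_ssrs(c(x = s2))
  expect_equal(nrow(loci2), 1L)
  expect_equal(loci2$start, 3L)
  expect_equal(loci2$motif, "AG")
  # mononucleotide runs are excluded
  expect_equal(nrow(find_ssrs(c(x = strrep("A", 40)))), 0L)
})

test_that("the scan equals the regex oracle on random and planted sequences", {
  withr::local_seed(70)
  pool <- c("AG", "GA", "AT", "CT", "ATG", "AAG", "CCG", "AATG", "AAAAG",
            "AACGTG")
  for (i in 1:150) {
    s <- rnd_dna(2000)
    if (i %% 3 == 0) {
      # plant one or two repeats so nonempty cases are well represented
      for (k in seq_len(sample(1:2, 1))) {
        m <- sample(pool, 1)
        reps <- sample(5:9, 1)
        p <- sample(seq(10, 1800), 1)
        substr(s, p, p + nchar(m) * reps - 1) <- strrep(m, reps)
      }
    }
    got <- find_ssrs(c(x = s))
    want <- oracle_ssr(s)
    expect_equal(got$start, want$start, info = sprintf("iter %d", i))
    expect_equal(got$end, want$end, info = sprintf("iter %d", i))
    expect_equal(got$motif, want$motif, info = sprintf("iter %d", i))
    expect_equal(got$repeats, want$repeats, info = sprintf("iter %d", i))
  }
})

test_that("loci are strand-covariant under reverse complement", {
  withr::local_seed(71)
  for (i in 1:25) {
    s <- rnd_dna(500)
    m <- sample(c("AG", "ATG", "AATG"), 1)
    reps <- sample(6:8, 1)
    p <- sample(100:300, 1)
    # C guards stop the run from extending a partial period into the flanks
    substr(s, p, p + nchar(m) * reps + 1) <-
      paste0("C", strrep(m, reps), "C")
    fw <- find_ssrs(c(x = s))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    rv <- find_ssrs(c(x = rc))
    expect_equal(nrow(fw), nrow(rv))
    if (nrow(fw)) {
      n <- nchar(s)
      mirrored <- data.frame(start = n - rev(fw$end), end = n - rev(fw$start))
      expect_equal(rv$start, mirrored$start)
      expect_equal(rv$end, mirrored$end)
      expect_equal(rv$class, rev(fw$class))
    }
  }
})

test_that("canonical classes pair a motif with its reverse complement only", {
  expect_equal(canonical_class("GA"), "GA/TC")
  expect_equal(canonical_class("TC"), "GA/TC")
  expect_equal(canonical_class("AG"), "AG/CT")
  expect_equal(canonical_class("CT"), "AG/CT")
  expect_equal(canonical_class("AT"), "AT/AT")
  # idempotent and strand-symmetric over all primitive di/tri motifs
  bases <- c("A", "C", "G", "T")
  motifs <- c(outer(bases, bases, paste0),
              outer(outer(bases, bases, paste0), bases, paste0))
  motifs <- motifs[vapply(motifs, asmeval:::is_primitive_motif, TRUE)]
  for (m in motifs) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
    expect_equal(canonical_class(m), canonical_class(rc))
    first <- strsplit(canonical_class(m), "/")[[1]][[1]]
    expect_equal(canonical_class(first), canonical_class(m))
  }
})

test_that("primer design enforces the flank-sufficiency gate", {
  withr::local_seed(72)
  s <- paste0(rnd_dna(300), strrep("AG", 7), rnd_dna(10))
  loci <- find_ssrs(c(x = s))
  loci <- loci[loci$motif == "AG", , drop = FALSE]
  expect_null(design_primers(s, loci[1, ]))   # 10 bp of right flank only
})

test_that("designed primers satisfy every constraint they were designed under", {
  withr::local_seed(73)
  cons <- primer_constraints()
  n_found <- 0
  for (i in 1:60) {
    s <- paste0(rnd_dna(150), strrep("ATG", 6), rnd_dna(150))
    loci <- find_ssrs(c(x = s))
    loci <- loci[loci$motif == "ATG", , drop = FALSE]
    if (!nrow(loci)) next
    pp <- design_primers(s, loci[1, ], cons)
    if (is.null(pp)) next
    n_found <- n_found + 1
    for (p in c(pp$left, pp$right)) {
      gc <- 100 * asmeval:::primer_gc_count(p) / nchar(p)
      tm <- asmeval:::primer_tm(p)
      expect_gte(nchar(p), cons$len_range[[1]])
      expect_lte(nchar(p), cons$len_range[[2]])
      expect_gte(gc, cons$gc_range[[1]])
      expect_lte(gc, cons$gc_range[[2]])
      expect_gte(tm, cons$tm_range[[1]])
      expect_lte(tm, cons$tm_range[[2]])
    }
    expect_lte(abs(pp$tm_left - pp$tm_right), cons$max_tm_diff)
    expect_gte(pp$expected_product, cons$product_range[[1]])
    expect_lte(pp$expected_product, cons$product_range[[2]])
    # primers actually flank the locus on the contig
    expect_equal(substr(s, pp$left_start, pp$left_start + nchar(pp$left) - 1),
                 pp$left)
    expect_lte(pp$left_start + nchar(pp$left) - 1, loci$start[[1]])
    expect_gt(pp$right_end, loci$end[[1]])
  }
  expect_gte(n_found, 20)
})

test_that("virtual PCR is sound for designed pairs and counts duplicates", {
  withr::local_seed(74)
  found <- 0
  for (i in 1:20) {
    s <- paste0(rnd_dna(150), strrep("AG", 7), rnd_dna(150))
    loci <- find_ssrs(c(x = s))
    loci <- loci[loci$motif == "AG", , drop = FALSE]
    if (!nrow(loci)) next
    pp <- design_primers(s, loci[1, ])
    if (is.null(pp)) next
    found <- found + 1
    asm <- assembly_set(c(t1 = s))
    amp <- virtual_pcr(pp, asm)
    expect_gte(nrow(amp$amplicons), 1L)
    dup <- assembly_set(c(t1 = s, t2 = s))
    amp2 <- virtual_pcr(pp, dup)
    expect_equal(nrow(amp2$amplicons), 2L * nrow(amp$amplicons))
    expect_false(amp2$single_locus)
  }
  expect_gte(found, 10)
})

test_that("virtual PCR equals the exhaustive position-pair oracle", {
  withr::local_seed(75)
  for (i in 1:12) {
    asm <- rnd_assembly(3, c(120, 300), prefix = "t")
    left <- rnd_dna(18)
    right <- rnd_dna(18)
    # half the iterations use primers guaranteed to bind
    if (i %% 2 == 0) {
      tmpl <- asm$seqs[[1]]
      left <- substr(tmpl, 5, 24)
      right <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(tmpl, 80, 99))))
    }
    pair <- list(left = left, right = right)
    mm <- sample(0:1, 1)
    got <- virtual_pcr(pair, asm, max_mismatches = mm, max_product = 500)
    want <- oracle_epcr(left, right, asm, max_mismatches = mm,
                        max_product = 500)
    expect_equal(amp_key(got$amplicons), amp_key(want),
                 info = sprintf("iter %d mm %d", i, mm))
  }
})

test_that("the SSR summary tallies sequences, units and planted truth", {
  withr::local_seed(76)
  seqs <- setNames(vapply(1:5, function(i) rnd_dna(400), ""), paste0("s", 1:5))
  seqs[["s1"]] <- paste0(rnd_dna(50), strrep("AG", 6), rnd_dna(50),
                         strrep("ATG", 5), rnd_dna(50))
  seqs[["s2"]] <- paste0(rnd_dna(50), strrep("AAG", 6), rnd_dna(100))
  asm <- assembly_set(seqs)
  loci <- find_ssrs(asm)
  # guard against accidental SSRs in the random filler
  loci <- loci[loci$contig_id %in% c("s1", "s2"), ]
  sm <- ssr_summary(loci, asm)
  expect_equal(sm$n_ssrs, 3L)
  expect_equal(sm$n_containing, 2L)
  expect_equal(sm$n_multi, 1L)
  expect_equal(sum(sm$by_unit$count), 3L)
  expect_equal(sum(sm$by_unit$pct), 100, tolerance = 0.2)
  expect_equal(sm$freq_kb,
               round(sum(contig_lengths(asm)) / 1000 / 3, 2))
})
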