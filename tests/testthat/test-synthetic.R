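test_that("reference generation is seed-deterministic with valid gene models", {
  r1 <- generate_reference(50, seed = 7)
  r2 <- generate_reference(50, seed = 7)
  expect_identical(r1, r2)
  expect_equal(anyDuplicated(r1$id), 0L)
  expect_true(all(nchar(r1$cds) %% 3 == 0))
  expect_true(all(substr(r1$cds, 1, 3) == "ATG"))
  stops <- substr(r1$cds, nchar(r1$cds) - 2, nchar(r1$cds))
  expect_true(all(stops %in% c("TAA", "TAG", "TGA")))
})

test_that("generated proteins equal independent re-translation of the CDS", {
  ref <- generate_reference(25, seed = 3)
  for (i in seq_len(nrow(ref))) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(ref$cds[[i]])))
    expect_equal(aa, paste0(ref$protein[[i]], "*"))
    expect_false(grepl("*", ref$protein[[i]], fixed = TRUE))
  }
})

test_that("an impossible CDS range is rejected", {
  expect_error(generate_reference(5, cds_len_range = c(4, 8), seed = 1),
               "no multiple of 3")
})

test_that("fragmentation 1 with zero rates reproduces full transcripts", {
  ref <- generate_reference(15, seed = 2)
  ca <- corrupt_assembly(ref, fragmentation = 1, seed = 5)
  tx <- ref_transcripts(ref)
  expect_equal(n_contigs(ca$assembly), 15L)
  expect_equal(unname(ca$assembly$seqs), unname(tx[ca$truth$gene_id]))
  expect_true(all(ca$truth$t_start == 0))
  expect_equal(ca$truth$t_end, unname(nchar(tx[ca$truth$gene_id])))
})

test_that("duplicate bookkeeping matches the truth table", {
  ref <- generate_reference(100, seed = 4)
  ca <- corrupt_assembly(ref, duplication_rate = 0.5, seed = 6)
  truth_dups <- sum(!is.na(ca$truth$duplicate_of))
  expect_equal(truth_dups, 50L)
  expect_equal(n_contigs(ca$assembly), 150L)
  # duplicates are exact copies of their source
  dups <- ca$truth[!is.na(ca$truth$duplicate_of), ]
  expect_true(all(ca$assembly$seqs[dups$contig_id] ==
                    ca$assembly$seqs[dups$duplicate_of]))
})

test_that("mean retained fraction tracks the fragmentation parameter", {
  ref <- generate_reference(500, utr_len_range = c(50, 100), seed = 8)
  ca <- corrupt_assembly(ref, fragmentation = 0.5, seed = 9)
  tx_len <- nchar(ref_transcripts(ref))
  base <- ca$truth[!ca$truth$is_chimera & is.na(ca$truth$duplicate_of), ]
  ratio <- (base$t_end - base$t_start) / tx_len[base$gene_id]
  expect_gt(mean(ratio), 0.45)
  expect_lt(mean(ratio), 0.55)
})

test_that("chimeras record two source segments in contig order", {
  ref <- generate_reference(40, seed = 10)
  ca <- corrupt_assembly(ref, chimera_rate = 0.25, seed = 11)
  chim <- ca$truth[ca$truth$is_chimera, ]
  expect_equal(nrow(chim), 2L * 10L)
  for (cid in unique(chim$contig_id)) {
    segs <- chim[chim$contig_id == cid, ]
    segs <- segs[order(segs$segment), ]
    tx <- ref_transcripts(ref)
    expected <- paste0(
      substr(tx[[segs$gene_id[[1]]]], segs$t_start[[1]] + 1, segs$t_end[[1]]),
      substr(tx[[segs$gene_id[[2]]]], segs$t_start[[2]] + 1, segs$t_end[[2]]))
    expect_equal(unname(ca$assembly$seqs[[cid]]), expected)
  }
})

test_that("planted SSR loci satisfy their truth records and are maximal", {
  withr::local_seed(1)
  host <- rnd_assembly(30, c(200, 800), prefix = "h")
  ps <- plant_ssrs(host, motif_pool = c("AG", "ATG"),
                   repeats_range = c(6, 6), seed = 13)
  expect_true(all(ps$truth$repeats == 6L))
  for (r in seq_len(nrow(ps$truth))) {
    tr <- ps$truth[r, ]
    s <- ps$assembly$seqs[[tr$contig_id]]
    expect_equal(substr(s, tr$start + 1, tr$end),
                 strrep(tr$motif, tr$repeats))
    u <- nchar(tr$motif)
    # flanks cannot extend the repeat at its period
    expect_false(substr(s, tr$start, tr$start) ==
                   substr(s, tr$start + u, tr$start + u))
    expect_false(substr(s, tr$end + 1, tr$end + 1) ==
                   substr(s, tr$end + 1 - u, tr$end + 1 - u))
  }
})

test_that("contigs too short to host a locus are skipped with a message", {
  tiny <- assembly_set(c(t1 = "ACGTACGTAC"))
  expect_message(
    ps <- plant_ssrs(tiny, motif_pool = "AG", repeats_range = c(8, 8),
                     seed = 1),
    "too short")
  expect_equal(nrow(ps$truth), 0L)
})

test_that("simulated alignment fractions convert to exact whole-pair counts", {
  withr::local_seed(2)
  asm <- rnd_assembly(4, c(150, 300))
  al <- simulate_alignments(asm, 10, 0.1, 0.1, seed = 3)
  expect_equal(nrow(al), 20L)
  expect_equal(sum(!al$mapped), 2L)
  per_read <- split(al, al$read_id)
  broken <- vapply(per_read, function(p)
    all(p$mapped) && p$contig_id[[1]] != p$contig_id[[2]], TRUE)
  expect_equal(sum(broken), 1L)

  al2 <- simulate_alignments(asm, 10, 1, 0, seed = 3)
  expect_true(all(!al2$mapped))

  one <- assembly_set(c(c1 = rnd_dna(200)))
  expect_error(simulate_alignments(one, 10, 0, 0.5, seed = 1),
               "at least two contigs")
})

test_that("truth-derived hits cover the protein exactly as provenance implies", {
  ref <- generate_reference(10, seed = 14)
  ca <- corrupt_assembly(ref, fragmentation = 1, seed = 15)
  h <- hits_from_truth(ref, ca$truth)
  plen <- setNames(nchar(ref$protein), ref$id)
  expect_true(all(h$forward$sstart == 1))
  expect_equal(unname(h$forward$send), unname(plen[h$forward$subject]))
  # contig covering exactly the first 50 codons of the CDS
  truth <- data.frame(contig_id = "part", segment = 1L,
                      gene_id = ref$id[[1]],
                      t_start = nchar(ref$utr5[[1]]),
                      t_end = nchar(ref$utr5[[1]]) + 150L,
                      strand = "+", is_chimera = FALSE,
                      duplicate_of = NA_character_, stringsAsFactors = FALSE)
  hp <- hits_from_truth(ref, truth)
  expect_equal(hp$forward$send - hp$forward$sstart + 1, 50)
})

test_that("reverse-complemented contigs keep plus-orientation hit coordinates", {
  ref <- generate_reference(30, seed = 16)
  ca <- corrupt_assembly(ref, fragmentation = 1, revcomp_rate = 0.5, seed = 17)
  h <- hits_from_truth(ref, ca$truth)
  expect_true(all(h$forward$qstart <= h$forward$qend))
  expect_true(all(h$forward$qend <= nchar(ca$assembly$seqs[h$forward$query])))
})

test_that("noise-free Ct tables encode the closed-form cycle shifts", {
  ct <- simulate_ct_table(c("g1", "ref"), c(g1 = 2, ref = 1),
                          ref_gene = "ref", noise_sd = 0, seed = 18)
  mean_ct <- function(g, cond)
    mean(ct$ct[ct$gene == g & ct$condition == cond])
  expect_equal(mean_ct("g1", "control") - mean_ct("g1", "treated"), 1)
  expect_equal(mean_ct("ref", "control") - mean_ct("ref", "treated"), 0)
  expect_identical(ct, simulate_ct_table(c("g1", "ref"), c(g1 = 2, ref = 1),
                                         ref_gene = "ref", noise_sd = 0,
                                         seed = 18))
  expect_error(
    simulate_ct_table(c("g1", "ref"), c(g1 = 2, ref = 2),
                      ref_gene = "ref", noise_sd = 0, seed = 1),
    "true ratio 1")
})

test_that("generators are byte-identical under a fixed seed", {
  ref <- generate_reference(20, seed = 19)
  a1 <- corrupt_assembly(ref, 0.6, 0.2, 0.2, 0.1, seed = 20)
  a2 <- corrupt_assembly(ref, 0.6, 0.2, 0.2, 0.1, seed = 20)
  expect_identical(a1, a2)
  s1 <- simulate_alignments(a1$assembly, 100, 0.05, 0.1, seed = 21)
  s2 <- simulate_alignments(a2$assembly, 100, 0.05, 0.1, seed = 21)
  expect_identical(s1, s2)
  p1 <- plant_ssrs(a1$assembly, seed = 22)
  p2 <- plant_ssrs(a2$assembly, seed = 22)
  expect_identical(p1, p2)
})
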