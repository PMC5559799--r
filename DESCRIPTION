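Package: asmeval
Title: Quality Evaluation, Meta-Assembly and Marker Mining for De Novo
    Transcriptome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing and improving de novo transcriptome
    assemblies of non-model organisms. Computes length-based statistics
    (N50, N90, contig length distributions), read-mapping completeness
    (mapped-back, paired and broken-pair percentages under length-fraction
    and similarity acceptance thresholds), and annotation-based quality
    metrics against a related reference proteome (best hits, reciprocal
    best hits, ortholog hit ratio, core-gene completeness). Implements a
    multi-k merge strategy (pooling, greedy longest-first clustering at an
    identity threshold on both strands, overlap meta-assembly into
    consensus sequences), perfect microsatellite (SSR) mining with primer
    design and in-silico PCR, and efficiency-corrected relative expression
    from qRT-PCR Ct tables (Pfaffl ratio with a randomization test). A
    seed-deterministic synthetic-data generator produces ground-truth
    transcriptomes, corrupted candidate assemblies, alignments, planted SSR
    loci and Ct tables so every stage can be verified against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
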