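test_that("CDS loading validates the transcript-model invariants", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">G1 some description", "ATGGGGTAA",
    ">G2", "ATGGGGTATA",        # length 10, not a multiple of 3
    ">G3", "ATGNNNTAA",         # ambiguous bases
    ">G4", "ATGTAAGGGTAA"       # internal stop
  ), fa)
  expect_warning(tx <- read_cds(fa), "Invalid CDS")
  expect_s3_class(tx, "negsel_transcripts")
  expect_equal(tx$gene_id, "G1")
  expect_equal(tx$n_codons, 3L)
  expect_error(suppressWarnings(read_cds(fa, strict = TRUE)))
  expect_error(read_cds(withr::local_tempfile(fileext = ".fa")),
               "not found")
})

test_that("duplicate gene ids are kept-first by default and error in strict mode", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">G1", "ATGGGGTAA", ">G1", "ATGCCCTAA"), fa)
  expect_warning(tx <- read_cds(fa), "Duplicate")
  expect_equal(nrow(tx), 1L)
  expect_match(tx$cds, "GGG")
  expect_error(read_cds(fa, strict = TRUE), "Duplicate")
})

test_that("site counts match hand-derived NG86 values", {
  # ATG: Met has no synonym -> all 9 changes non-synonymous
  sc <- count_sites(transcript_models(c(G = "ATG")))
  expect_equal(sc$n_sites, 3.0)
  expect_equal(sc$s_sites, 0.0)
  # GGG: third-position changes all encode Gly
  sc <- count_sites(transcript_models(c(G = "GGG")))
  expect_equal(sc$n_sites, 2.0)
  expect_equal(sc$s_sites, 1.0)
  # additivity over codons
  sc <- count_sites(transcript_models(c(G = "ATGGGG")))
  expect_equal(sc$n_sites, 5.0)
  expect_equal(sc$s_sites, 1.0)
})

test_that("site counts agree with the brute-force enumerator and conserve total sites", {
  set.seed(101)
  for (i in 1:120) {
    n_codons <- sample(2:30, 1)
    cds <- random_cds(n_codons)
    tx <- transcript_models(setNames(cds, "G"))
    sc <- count_sites(tx)
    oracle <- oracle_site_counts(cds)
    expect_equal(sc$n_sites, oracle$n_sites, tolerance = 1e-12)
    expect_equal(sc$s_sites, oracle$s_sites, tolerance = 1e-12)
    expect_identical(sc$n_sites + sc$s_sites, 3 * n_codons)
  }
})

test_that("SNV classification agrees with translate-and-compare for all sense-codon changes", {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  checked <- 0L
  for (codon in sense) {
    tx <- transcript_models(setNames(paste0(codon, "TAA"), "G"))
    for (pos in 1:3) {
      ref <- substr(codon, pos, pos)
      for (alt in setdiff(ORACLE_BASES, ref)) {
        expect_identical(
          classify_snv(tx, "G", pos, ref, alt),
          oracle_consequence(codon, pos, alt)
        )
        checked <- checked + 1L
      }
    }
  }
  expect_identical(checked, 549L)
})

test_that("terminal stop-codon changes are stop_loss or synonymous", {
  tx <- transcript_models(c(G = "ATGTAA"))
  expect_identical(classify_snv(tx, "G", 6, "A", "G"), "synonymous") # TAA->TAG
  expect_identical(classify_snv(tx, "G", 5, "A", "T"), "stop_loss")  # TAA->TTA
})

test_that("classification enforces the reference-allele contract", {
  tx <- transcript_models(c(G1 = "ATGGGGTAA"))
  expect_error(classify_snv(tx, "G1", 1, "G", "C"), "mismatch")
  expect_error(classify_snv(tx, "G1", 1, "A", "A"), "differ")
  expect_error(classify_snv(tx, "G1", 99, "A", "C"), "range")
  expect_error(classify_snv(tx, "G9", 1, "A", "C"), "Unknown gene")
})

test_that("splice windows override codon-level calls near declared exon boundaries", {
  cds <- paste(rep("GGG", 10), collapse = "")
  tx <- transcript_models(setNames(cds, "G"), exon_boundaries = list(G = 15L))
  # positions 13..17 are within 2 nt of the boundary
  expect_identical(classify_snv(tx, "G", 15, "G", "A"), "splice_site")
  expect_identical(classify_snv(tx, "G", 13, "G", "A"), "splice_site")
  expect_identical(classify_snv(tx, "G", 17, "G", "A"), "splice_site")
  # outside the window the codon effect returns
  expect_identical(classify_snv(tx, "G", 18, "G", "A"), "synonymous")
  # no declared boundaries: splice never computed
  tx2 <- transcript_models(setNames(cds, "G"))
  expect_identical(classify_snv(tx2, "G", 15, "G", "A"), "synonymous")
})

test_that("classify_variants respects pre-annotation and fills the rest", {
  tx <- transcript_models(c(G1 = "ATGGGGTAA"))
  v <- tibble::tibble(
    cohort = "somatic", gene_id = "G1",
    cds_pos = c(6L, 6L, 2L, NA),
    ref = c("G", "G", "T", "-"),
    alt = c("A", "A", "C", "TT"),
    variant_class = c("snv", "snv", "snv", "insertion"),
    consequence = c("splice_site", NA, NA, NA),
    score_a = NA_real_, score_b = NA_real_
  )
  out <- classify_variants(v, tx)
  expect_identical(out$consequence,
                   c("splice_site", "synonymous", "missense",
                     "frameshift_indel"))
})
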