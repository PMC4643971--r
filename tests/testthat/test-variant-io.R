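write_fixture_maf <- function(rows, path) {
  header <- paste("Hugo_Symbol", "Variant_Classification", "Variant_Type",
                  "Reference_Allele", "Tumor_Seq_Allele2", "CDS_Position",
                  sep = "\t")
  writeLines(c(header, rows), path)
}

test_that("MAF rows normalize to canonical variants", {
  maf <- withr::local_tempfile(fileext = ".tsv")
  write_fixture_maf(c(
    "G1\tSilent\tSNP\tG\tA\t3",
    "G1\tFrame_Shift_Del\tDEL\tG\t-\t7",
    "G2\tMissense_Mutation\tSNP\tC\tT\t10",
    "\tSilent\tSNP\tG\tA\t3"          # no gene: dropped
  ), maf)
  expect_message(v <- read_maf(maf), "dropped")
  expect_equal(nrow(v), 3L)
  expect_identical(v$variant_class, c("snv", "deletion", "snv"))
  expect_identical(v$consequence, c("synonymous", "frameshift_indel",
                                    "missense"))
  expect_identical(unique(v$cohort), "somatic")
  prov <- provenance(v)
  expect_equal(prov$n_kept, 3L)
  expect_equal(prov$n_dropped, 1L)
})

test_that("variant class falls back to allele lengths and missing columns error by role", {
  maf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Hugo_Symbol\tReference_Allele\tTumor_Seq_Allele2",
               "G1\tG\t-", "G1\t-\tTT", "G1\tG\tA"), maf)
  v <- read_maf(maf)
  expect_identical(v$variant_class, c("deletion", "insertion", "snv"))

  maf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Reference_Allele\tTumor_Seq_Allele2", "G\tA"), maf2)
  expect_error(read_maf(maf2), "gene")
})

test_that("VCF reading splits multi-allelic records and assigns genes from INFO tags", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    "chr1\t105\t.\tG\tA,T\t.\tPASS\tGENE=G1;CDSPOS=5",
    "chr1\t300\t.\tC\tT\t.\tPASS\tDP=10",     # no gene: dropped
    "chr1\t110\t.\tC\tCAT\t.\tPASS\tGENE=G1;CDSPOS=10"
  ), vcf)
  expect_message(v <- read_vcf(vcf), "outside any CDS")
  expect_equal(nrow(v), 3L)                    # 2 alts + 1 insertion
  expect_identical(unique(v$cohort), "germline")
  expect_identical(v$variant_class, c("snv", "snv", "insertion"))
  expect_equal(v$cds_pos, c(5L, 5L, 10L))
  expect_equal(provenance(v)$n_dropped, 1L)
})

test_that("cds_map lift-over handles a two-exon gene on both strands", {
  # plus strand: exon1 genomic 101-106 -> CDS 1-6, exon2 201-203 -> CDS 7-9
  # minus strand gene G2: exon genomic 501-509, CDS 1 at genomic 509
  map <- cds_map(
    gene_id = c("G1", "G1", "G2"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "+", "-"),
    start = c(101L, 201L, 501L),
    end = c(106L, 203L, 509L),
    cds_start = c(1L, 7L, 1L)
  )
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    "chr1\t103\t.\tA\tG\t.\tPASS\t.",   # CDS pos 3
    "chr1\t202\t.\tT\tC\t.\tPASS\t.",   # exon 2, CDS pos 8
    "chr1\t150\t.\tG\tA\t.\tPASS\t.",   # intronic: dropped
    "chr2\t509\t.\tG\tA\t.\tPASS\t."    # minus strand, CDS pos 1, C->T
  ), vcf)
  expect_message(v <- read_vcf(vcf, map = map), "outside any CDS")
  expect_equal(v$cds_pos, c(3L, 8L, 1L))
  # minus-strand alleles are reverse-complemented onto the coding strand
  expect_identical(v$ref[3], "C")
  expect_identical(v$alt[3], "T")
})

test_that("score attachment joins by site key and counts unscored variants", {
  v <- tibble::tibble(
    cohort = "somatic", gene_id = c("G1", "G1", "G2"),
    cds_pos = c(3L, 6L, 9L), ref = "G", alt = "A",
    variant_class = "snv",
    consequence = c("missense", "missense", "synonymous"),
    score_a = NA_real_, score_b = NA_real_
  )
  scores <- tibble::tibble(
    gene_id = "G1", cds_pos = 3L, ref = "G", alt = "A",
    score_a = 0.9, score_b = 0.8
  )
  expect_message(out <- attach_scores(v, scores), "1 non-synonymous")
  expect_equal(out$score_a, c(0.9, NA, NA))

  # duplicate key with equal scores: silent; conflicting: strict error
  dup_equal <- dplyr::bind_rows(scores, scores)
  expect_no_warning(attach_scores(v, dup_equal, strict = TRUE))
  dup_conflict <- dplyr::bind_rows(scores,
                                   dplyr::mutate(scores, score_a = 0.1))
  expect_error(attach_scores(v, dup_conflict, strict = TRUE), "Conflicting")
  expect_warning(out2 <- attach_scores(v, dup_conflict), "Conflicting")
  expect_equal(out2$score_a[1], 0.9)
})

test_that("minimum-variant filter requires support in both cohorts", {
  mk <- function(gene, n, cohort) {
    tibble::tibble(cohort = cohort, gene_id = rep(gene, n), cds_pos = 1L,
                   ref = "G", alt = "A", variant_class = "snv",
                   consequence = NA_character_,
                   score_a = NA_real_, score_b = NA_real_)
  }
  somatic <- dplyr::bind_rows(mk("A", 11, "somatic"), mk("B", 10, "somatic"),
                              mk("C", 30, "somatic"))
  germline <- dplyr::bind_rows(mk("A", 11, "germline"),
                               mk("B", 500, "germline"),
                               mk("C", 5, "germline"))
  expect_identical(min_variant_filter(somatic, germline), "A")
  expect_identical(min_variant_filter(somatic, germline, min_n = 1),
                   c("A", "B", "C"))
})

test_that("canonical variant TSV round-trips the variant multiset", {
  set.seed(11)
  cfg <- sim_config(n_genes = 8, somatic_mean = 15, random_seed = 11,
                    cds_length_range = c(60, 80))
  st <- simulate_study(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants(st$somatic, path)
  back <- read_variants(path)
  key <- function(v) {
    sort(paste(v$cohort, v$gene_id, v$cds_pos, v$ref, v$alt,
               v$variant_class, v$consequence,
               round(v$score_a, 9), round(v$score_b, 9)))
  }
  expect_identical(key(back), key(st$somatic))
})
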