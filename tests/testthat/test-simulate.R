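test_that("simulated CDS honor lengths, start/stop structure and determinism", {
  cfg <- sim_config(n_genes = 3, cds_length_range = c(100, 100),
                    random_seed = 5)
  set.seed(5)
  tx <- simulate_cds(cfg)
  expect_equal(nchar(tx$cds), rep(300L, 3))
  expect_true(all(substr(tx$cds, 1, 3) == "ATG"))
  code <- Biostrings::GENETIC_CODE
  for (s in tx$cds) {
    codons <- substring(s, seq(1, 298, 3), seq(3, 300, 3))
    expect_identical(unname(code[codons[100]]), "*")
    expect_false(any(code[codons[-100]] == "*"))
  }
  set.seed(5)
  tx2 <- simulate_cds(cfg)
  expect_identical(tx$cds, tx2$cds)
  expect_error(sim_config(cds_length_range = c(0, 0)))
})

test_that("a fixed seed reproduces the full study byte-for-byte", {
  cfg <- sim_config(n_genes = 15, somatic_mean = 12, germline_mean = 15,
                    cds_length_range = c(60, 90), random_seed = 23)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$transcripts$cds, s2$transcripts$cds)
  expect_identical(as.data.frame(s1$somatic), as.data.frame(s2$somatic))
  expect_identical(as.data.frame(s1$germline), as.data.frame(s2$germline))
  expect_identical(as.data.frame(s1$expression), as.data.frame(s2$expression))
  expect_identical(s1$edges, s2$edges)
})

test_that("omega = 0 emits no non-synonymous SNVs and count 0 genes stay empty", {
  cfg <- sim_config(n_genes = 10, prop_essential = 1, omega_essential = 0,
                    somatic_mean = 20, p_indel = 0, p_splice = 0,
                    cds_length_range = c(60, 90), random_seed = 3)
  st <- simulate_study(cfg)
  expect_true(all(st$somatic$consequence == "synonymous"))

  cfg0 <- sim_config(n_genes = 5, somatic_mean = 0,
                     cds_length_range = c(60, 90), random_seed = 3)
  st0 <- simulate_study(cfg0)
  expect_equal(nrow(st0$somatic), 0L)
})

test_that("a site carries identical scores wherever it recurs across cohorts", {
  cfg <- sim_config(n_genes = 10, somatic_mean = 60, germline_mean = 60,
                    cds_length_range = c(40, 60), random_seed = 13)
  st <- simulate_study(cfg)
  both <- dplyr::bind_rows(st$somatic, st$germline)
  per_site <- both |>
    dplyr::filter(!is.na(.data$score_a)) |>
    dplyr::group_by(.data$gene_id, .data$cds_pos, .data$ref, .data$alt) |>
    dplyr::summarise(n_a = dplyr::n_distinct(.data$score_a),
                     n_b = dplyr::n_distinct(.data$score_b),
                     .groups = "drop")
  expect_true(all(per_site$n_a == 1L))
  expect_true(all(per_site$n_b == 1L))
  # the emitted score table covers every scored variant
  keyed <- dplyr::anti_join(
    dplyr::filter(both, !is.na(.data$score_a)),
    st$scores, by = c("gene_id", "cds_pos", "ref", "alt")
  )
  expect_equal(nrow(keyed), 0L)
})

test_that("near-zero expression component puts about the configured fraction in the lowest 20%", {
  cfg <- sim_config(n_genes = 400, prop_essential = 0,
                    low_expr_fraction = 0.2, random_seed = 29)
  set.seed(29)
  truth <- tibble::tibble(gene_id = sprintf("B%03d", 1:400),
                          class = "background")
  expr <- simulate_expression(truth, cfg)
  prof <- expression_filter(expr, quantile = 0.20)
  # the removed 20% should be almost exactly the near-zero component
  removed <- prof$gene_id[!prof$kept]
  means <- prof$mean_expression
  expect_equal(length(removed), 80L)
  expect_gt(mean(means[prof$kept]), 50 * mean(means[!prof$kept]))
})

test_that("simulated files land in the pipeline's input formats and read back", {
  cfg <- sim_config(n_genes = 12, somatic_mean = 15, germline_mean = 18,
                    cds_length_range = c(60, 90), random_seed = 37)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  paths <- write_study(st, dir)
  expect_true(all(file.exists(paths)))

  tx <- read_cds(paths[["cds"]])
  expect_identical(tx$cds, st$transcripts$cds)

  som <- read_maf(paths[["maf"]])
  expect_equal(nrow(som), nrow(st$somatic))
  expect_equal(sort(table(som$consequence)),
               sort(table(st$somatic$consequence)))

  germ <- read_vcf(paths[["vcf"]],
                   map = cds_map(st$cds_map$gene_id, st$cds_map$chrom,
                                 st$cds_map$strand, st$cds_map$start,
                                 st$cds_map$end, st$cds_map$cds_start))
  expect_equal(nrow(germ), nrow(st$germline))
  g_snv <- dplyr::filter(germ, .data$variant_class == "snv") |>
    dplyr::arrange(.data$gene_id, .data$cds_pos, .data$ref, .data$alt)
  s_snv <- dplyr::filter(st$germline, .data$variant_class == "snv") |>
    dplyr::arrange(.data$gene_id, .data$cds_pos, .data$ref, .data$alt)
  expect_equal(g_snv[, c("gene_id", "cds_pos", "ref", "alt")],
               s_snv[, c("gene_id", "cds_pos", "ref", "alt")],
               ignore_attr = TRUE)

  # scores re-attach losslessly onto the re-read germline SNVs
  germ2 <- classify_variants(germ, tx)
  germ2 <- attach_scores(germ2, paths[["scores"]])
  merged <- dplyr::inner_join(
    dplyr::filter(germ2, !is.na(.data$score_a)),
    st$scores, by = c("gene_id", "cds_pos", "ref", "alt"),
    suffix = c("", ".sim")
  )
  expect_equal(merged$score_a, merged$score_a.sim)

  sets <- read_gmt(paths[["gmt"]])
  expect_true("ESSENTIAL_MODULE" %in% sets$set)
  edges <- read_string_edges(paths[["edges"]])
  expect_true(all(edges$combined_score >= 0 & edges$combined_score <= 1))
})
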