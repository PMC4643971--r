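test_that("pipeline_config validates its ranges", {
  expect_s3_class(pipeline_config(), "pipeline_config")
  expect_error(pipeline_config(expression_quantile = 1.2))
  expect_error(pipeline_config(dnds_threshold = -1))
  expect_silent(pipeline_config(dnds_threshold = "auto"))
})

test_that("expression filter removes the lowest quantile and ranks strictly", {
  expr <- tibble::tibble(gene_id = paste0("G", 1:5), S1 = c(1, 2, 3, 4, 5))
  out <- expression_filter(expr, quantile = 0.20)
  expect_identical(out$kept, c(FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(out$quantile_rank, c(0, 0.2, 0.4, 0.6, 0.8))
  expect_true(all(expression_filter(expr, quantile = 0)$kept))
  # single sample: means equal the column
  expect_equal(out$mean_expression, expr$S1)
  expect_error(expression_filter(tibble::tibble(gene_id = "G")), "sample")
  expect_error(
    expression_filter(tibble::tibble(gene_id = "G", S1 = "high")),
    "non-numeric"
  )
})

test_that("the six-gene fixture yields exactly its hand-checked decisions", {
  scan <- run_fixture_scan()
  d <- scan$decisions

  expect_identical(essential_genes(scan), "G1")

  expected <- tibble::tribble(
    ~gene_id, ~pass_min_variants, ~pass_dnds, ~pass_expression, ~pass_depletion,
    "G1", TRUE,  TRUE,  TRUE,  TRUE,
    "G2", FALSE, FALSE, FALSE, FALSE,
    "G3", TRUE,  FALSE, TRUE,  TRUE,
    "G4", TRUE,  TRUE,  FALSE, TRUE,
    "G5", TRUE,  TRUE,  TRUE,  FALSE,
    "G6", TRUE,  FALSE, TRUE,  FALSE
  )
  expect_identical(
    d[, c("gene_id", "pass_min_variants", "pass_dnds", "pass_expression",
          "pass_depletion")],
    expected
  )
  # hand-computed omegas: n_obs / (2 * s_obs) with N = 60, S = 30
  expect_equal(d$omega[d$gene_id == "G1"], 2 / 12)
  expect_equal(d$omega[d$gene_id == "G3"], 0.5)
  expect_true(is.na(d$omega[d$gene_id == "G6"]))   # no synonymous variants
  expect_true(is.na(d$omega[d$gene_id == "G2"]))   # below support: not computed
  # hand-computed fractions: deletions are the only high-impact variants
  expect_equal(d$f_germline[d$gene_id == "G1"], 0.25)
  expect_equal(d$f_somatic[d$gene_id == "G1"], 0)
  expect_equal(d$f_germline[d$gene_id == "G5"], 0)
})

test_that("degenerate thresholds behave as contracts say", {
  cfg0 <- pipeline_config(min_variants = 5, dnds_threshold = 0,
                          expression_quantile = 0.2)
  scan <- run_selection(fixture_somatic(), fixture_germline(),
                        fixture_transcripts(), fixture_expression(),
                        config = cfg0)
  expect_false(any(scan$decisions$pass_dnds))   # omega >= 0 always

  # a gene absent from the expression matrix fails with a warning
  expr <- fixture_expression()[-1, ]
  expect_warning(
    scan2 <- run_selection(fixture_somatic(), fixture_germline(),
                           fixture_transcripts(), expr,
                           config = fixture_config()),
    "absent from the expression"
  )
  expect_false(scan2$decisions$pass_expression[scan2$decisions$gene_id == "G1"])
  expect_identical(essential_genes(scan2), character(0))
})

test_that("relaxing any single threshold yields a superset of essential genes", {
  cfg <- sim_config(n_genes = 120, prop_essential = 0.1,
                    somatic_mean = 25, germline_mean = 35,
                    cds_length_range = c(80, 120), random_seed = 99)
  st <- simulate_study(cfg)
  base_cfg <- pipeline_config()
  run_with <- function(config) {
    essential_genes(run_selection(st$somatic, st$germline, st$transcripts,
                                  st$expression, config = config))
  }
  base <- run_with(base_cfg)
  relaxed <- list(
    pipeline_config(dnds_threshold = 0.5),
    pipeline_config(min_variants = 5),
    pipeline_config(expression_quantile = 0.05)
  )
  for (cfg_r in relaxed) {
    expect_true(all(base %in% run_with(cfg_r)))
  }
})

test_that("auto threshold mode wires the histogram minimum into the cascade", {
  # bimodal omega layout: purifying mode near 0.1, neutral mode near 1
  cfg <- sim_config(n_genes = 150, prop_essential = 0.4,
                    omega_essential = 0.08, somatic_mean = 60,
                    germline_mean = 60, cds_length_range = c(100, 150),
                    random_seed = 17)
  st <- simulate_study(cfg)
  scan <- run_selection(st$somatic, st$germline, st$transcripts,
                        st$expression,
                        config = pipeline_config(dnds_threshold = "auto"))
  expect_s3_class(scan$omega_hist, "negsel_omega_hist")
  expect_gt(scan$dnds_threshold_used, 0.05)
  expect_lt(scan$dnds_threshold_used, 0.75)
})

test_that("tidy, glance and the S1-style export expose the decision table", {
  scan <- run_fixture_scan()
  expect_identical(tidy(scan), scan$decisions)
  g <- glance(scan)
  expect_equal(g$n_genes, 6L)
  expect_equal(g$n_essential, 1L)
  expect_equal(g$n_pass_min_variants, 5L)

  s1 <- as_s1_table(scan)
  expect_identical(names(s1), c("Gene", "skcm.dnds", "quantile.expression",
                                "norm.neutral", "norm.high", "skcm.neutral",
                                "skcm.high"))
  expect_identical(s1$Gene, "G1")
  expect_equal(s1$norm.high, 2L)       # the two germline deletions
  expect_equal(s1$norm.neutral, 6L)    # 8 germline variants - 2 high
  expect_equal(s1$skcm.high, 0L)
  expect_equal(s1$skcm.neutral, 8L)

  p <- autoplot(scan)
  expect_s3_class(p, "ggplot")
})
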