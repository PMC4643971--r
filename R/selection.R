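#' Pipeline configuration
#'
#' Houses the cascade's tunable constants: minimum variant support per
#' cohort (11), the dN/dS negative-selection threshold (0.25, or `"auto"`
#' to detect it from the genome-wide histogram's local minimum), the
#' expression quantile below which genes are removed (0.20), the impact
#' score percentile (0.70), and the interaction-score cutoff (0.9).
#'
#' @param min_variants Minimum variants per gene required in both cohorts.
#' @param dnds_threshold Numeric threshold, or `"auto"` for data-driven
#'   detection via [find_negative_selection_threshold()].
#' @param expression_quantile Genes with mean expression in this lowest
#'   quantile are removed.
#' @param impact_percentile Percentile defining high-impact score cutoffs.
#' @param interaction_score_min Minimum interaction score for network
#'   summaries.
#' @param random_seed Seed recorded in the run manifest.
#' @param percentile_population `"pooled"` or `"per_cohort"` score
#'   population for [derive_thresholds()].
#' @param dnds_numerator `"nonsynonymous"` or `"missense"` (see
#'   [estimate_dnds()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_variants = 11L,
                            dnds_threshold = 0.25,
                            expression_quantile = 0.20,
                            impact_percentile = 0.70,
                            interaction_score_min = 0.9,
                            random_seed = 1L,
                            percentile_population = c("pooled", "per_cohort"),
                            dnds_numerator = c("nonsynonymous", "missense")) {
  percentile_population <- match.arg(percentile_population)
  dnds_numerator <- match.arg(dnds_numerator)
  auto <- identical(dnds_threshold, "auto")
  if (!auto) {
    stopifnot(is.numeric(dnds_threshold), dnds_threshold >= 0)
  }
  stopifnot(
    min_variants >= 0,
    expression_quantile >= 0, expression_quantile < 1,
    impact_percentile >= 0, impact_percentile < 1,
    interaction_score_min >= 0, interaction_score_min <= 1
  )
  structure(
    list(
      min_variants = as.integer(min_variants),
      dnds_threshold = dnds_threshold,
      expression_quantile = expression_quantile,
      impact_percentile = impact_percentile,
      interaction_score_min = interaction_score_min,
      random_seed = as.integer(random_seed),
      percentile_population = percentile_population,
      dnds_numerator = dnds_numerator
    ),
    class = "pipeline_config"
  )
}

#' Expression filter and enrichment universe
#'
#' Computes each gene's mean expression across samples and removes genes
#' in the lowest `quantile` of that distribution: a gene is kept when its
#' mean is strictly greater than the empirical `quantile` of all gene
#' means (type-7); `quantile = 0` keeps everything. `quantile_rank` is the
#' fraction of genes with strictly smaller mean. The kept set doubles as
#' the reference universe for enrichment analysis.
#'
#' @param expr Expression data: a matrix with gene rownames, or a data
#'   frame whose first column (or a column named `gene_id`) holds gene ids
#'   and remaining columns hold per-sample numeric values.
#' @param quantile Lowest-expression quantile to remove (default 0.20).
#' @return A tibble with `gene_id`, `mean_expression`, `quantile_rank`,
#'   `kept`.
#' @export
expression_filter <- function(expr, quantile = 0.20) {
  if (is.data.frame(expr)) {
    id_col <- if ("gene_id" %in% names(expr)) "gene_id" else names(expr)[1]
    ids <- as.character(expr[[id_col]])
    mat <- as.matrix(expr[setdiff(names(expr), id_col)])
  } else {
    ids <- rownames(expr)
    mat <- as.matrix(expr)
  }
  if (ncol(mat) < 1L) abort("Expression matrix needs at least one sample.")
  if (!is.numeric(mat)) abort("Expression matrix contains non-numeric cells.")
  stopifnot(quantile >= 0, quantile < 1)

  means <- rowMeans(mat)
  cutoff <- unname(stats::quantile(means, quantile, type = 7))
  n <- length(means)
  rank_strict <- vapply(means, function(m) sum(means < m), numeric(1)) / n
  tibble(
    gene_id = ids,
    mean_expression = unname(means),
    quantile_rank = rank_strict,
    kept = if (quantile == 0) rep(TRUE, n) else means > cutoff
  )
}

#' Run the essential-gene selection cascade
#'
#' Applies, conjunctively, the four filters defining an essential cancer
#' protein: (1) variant support of at least `min_variants` in both the
#' somatic and germline cohorts; (2) somatic dN/dS strictly below the
#' negative-selection threshold (undefined omegas fail); (3) expression
#' above the lowest `expression_quantile` of gene means; (4) depletion of
#' high-impact variants in the tumor, `f_germline > f_somatic`. All flags
#' are reported for every gene present in both cohorts; genes failing the
#' support filter get no omega or f (insufficient data).
#'
#' @param somatic,germline Canonical variant tibbles.
#' @param transcripts A `negsel_transcripts` tibble covering the genes.
#' @param expression Expression matrix or data frame (see
#'   [expression_filter()]).
#' @param config A [pipeline_config()].
#' @param scores Optional score table/path applied to both cohorts via
#'   [attach_scores()].
#' @return An object of class `essential_scan`: list with `decisions`
#'   (per-gene tibble of flags and carried values), `estimates`,
#'   `summaries`, `thresholds`, `expression`, `omega_hist`,
#'   `dnds_threshold_used`, `config`, and `manifest`.
#' @export
run_selection <- function(somatic, germline, transcripts, expression,
                          config = pipeline_config(), scores = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(transcripts, "negsel_transcripts"))
  if (!is.null(scores)) {
    somatic <- attach_scores(somatic, scores)
    germline <- attach_scores(germline, scores)
  }

  somatic <- classify_variants(somatic, transcripts)
  germline <- classify_variants(germline, transcripts)

  genes <- intersect(unique(somatic$gene_id), unique(germline$gene_id))
  if (length(genes) == 0L) {
    abort("No gene is present in both the somatic and germline cohorts.")
  }
  genes <- sort(genes)

  counts <- dplyr::full_join(
    dplyr::count(somatic, .data$gene_id, name = "n_somatic"),
    dplyr::count(germline, .data$gene_id, name = "n_germline"),
    by = "gene_id"
  )
  decisions <- tibble(gene_id = genes) |>
    dplyr::left_join(counts, by = "gene_id") |>
    dplyr::mutate(
      n_somatic = dplyr::coalesce(.data$n_somatic, 0L),
      n_germline = dplyr::coalesce(.data$n_germline, 0L),
      pass_min_variants = .data$n_somatic >= config$min_variants &
        .data$n_germline >= config$min_variants
    )
  supported <- decisions$gene_id[decisions$pass_min_variants]

  # dN/dS on supported genes only
  sites <- count_sites(transcripts)
  som_sup <- dplyr::filter(somatic, .data$gene_id %in% supported)
  estimates <- if (nrow(som_sup) > 0L) {
    estimate_dnds(som_sup, sites, numerator = config$dnds_numerator)
  } else {
    estimate_dnds(somatic[0, ], sites)
  }

  omega_hist <- NULL
  threshold <- config$dnds_threshold
  if (identical(threshold, "auto")) {
    omega_hist <- omega_histogram(estimates)
    threshold <- find_negative_selection_threshold(omega_hist)
  }

  decisions <- decisions |>
    dplyr::left_join(
      dplyr::select(estimates, "gene_id", "omega", "defined"),
      by = "gene_id"
    ) |>
    dplyr::mutate(
      defined = dplyr::coalesce(.data$defined, FALSE),
      pass_dnds = .data$pass_min_variants & .data$defined &
        .data$omega < threshold
    ) |>
    dplyr::mutate(pass_dnds = dplyr::coalesce(.data$pass_dnds, FALSE))

  # expression
  expr_profiles <- expression_filter(expression, config$expression_quantile)
  unprofiled <- setdiff(genes, expr_profiles$gene_id)
  if (length(unprofiled) > 0L) {
    warn(paste0(length(unprofiled), " gene(s) absent from the expression ",
                "matrix fail the expression filter: ",
                paste(head(unprofiled, 5), collapse = ", ")))
  }
  decisions <- decisions |>
    dplyr::left_join(
      dplyr::select(expr_profiles, "gene_id", "mean_expression",
                    quantile_expression = "quantile_rank", "kept"),
      by = "gene_id"
    ) |>
    dplyr::mutate(pass_expression = dplyr::coalesce(.data$kept, FALSE)) |>
    dplyr::select(-"kept")

  # impact fractions on supported genes
  pooled <- dplyr::bind_rows(
    dplyr::filter(somatic, .data$gene_id %in% supported),
    dplyr::filter(germline, .data$gene_id %in% supported)
  )
  thresholds <- NULL
  summaries <- tibble(gene_id = character(), cohort = character(),
                      n_total = integer(), n_high = integer(), f = double())
  depl <- tibble(gene_id = character(), f_somatic = double(),
                 f_germline = double(), depleted = logical())
  if (nrow(pooled) > 0L) {
    # cutoffs come from the full pooled score population so that relaxing
    # the support filter cannot shift them
    thresholds <- derive_thresholds(dplyr::bind_rows(somatic, germline),
                                    config$impact_percentile,
                                    config$percentile_population)
    summaries <- compute_f(pooled, thresholds)
    depl <- depletion_test(
      dplyr::filter(summaries, .data$cohort == unique(somatic$cohort)[1]),
      dplyr::filter(summaries, .data$cohort == unique(germline$cohort)[1])
    )
  }
  decisions <- decisions |>
    dplyr::left_join(depl, by = "gene_id") |>
    dplyr::mutate(
      pass_depletion = dplyr::coalesce(.data$depleted, FALSE),
      essential = .data$pass_min_variants & .data$pass_dnds &
        .data$pass_expression & .data$pass_depletion
    ) |>
    dplyr::select(-"depleted")

  scan <- structure(
    list(
      decisions = decisions,
      estimates = estimates,
      summaries = summaries,
      thresholds = thresholds,
      expression = expr_profiles,
      omega_hist = omega_hist,
      dnds_threshold_used = threshold,
      config = config,
      manifest = NULL
    ),
    class = "essential_scan"
  )
  scan$manifest <- run_manifest(scan, somatic, germline)
  scan
}

#' @export
print.essential_scan <- function(x, ...) {
  g <- glance(x)
  cat("Essential-gene selection scan\n")
  cat("  genes in both cohorts : ", g$n_genes, "\n", sep = "")
  cat("  pass variant support  : ", g$n_pass_min_variants, "\n", sep = "")
  cat("  pass dN/dS < ", format(g$dnds_threshold), "  : ",
      g$n_pass_dnds, "\n", sep = "")
  cat("  pass expression       : ", g$n_pass_expression, "\n", sep = "")
  cat("  pass depletion        : ", g$n_pass_depletion, "\n", sep = "")
  cat("  essential             : ", g$n_essential, "\n", sep = "")
  invisible(x)
}

#' Tidy the per-gene decision table of a scan
#'
#' @param x An `essential_scan` object.
#' @param ... Unused.
#' @return The per-gene decisions tibble.
#' @method tidy essential_scan
#' @export
tidy.essential_scan <- function(x, ...) x$decisions

#' One-row summary of a scan
#'
#' @param x An `essential_scan` object.
#' @param ... Unused.
#' @return A one-row tibble of cascade counts and the threshold used.
#' @method glance essential_scan
#' @export
glance.essential_scan <- function(x, ...) {
  d <- x$decisions
  tibble(
    n_genes = nrow(d),
    n_pass_min_variants = sum(d$pass_min_variants),
    n_pass_dnds = sum(d$pass_min_variants & d$pass_dnds),
    n_pass_expression = sum(d$pass_min_variants & d$pass_dnds &
                              d$pass_expression),
    n_pass_depletion = sum(d$pass_min_variants & d$pass_dnds &
                             d$pass_expression & d$pass_depletion),
    n_essential = sum(d$essential),
    dnds_threshold = x$dnds_threshold_used
  )
}

#' Essential gene ids of a scan
#'
#' @param scan An `essential_scan` object.
#' @return Character vector of genes passing all four filters.
#' @export
essential_genes <- function(scan) {
  stopifnot(inherits(scan, "essential_scan"))
  scan$decisions$gene_id[scan$decisions$essential]
}

#' Export the scan as an S1-style report table
#'
#' Columns mirror the published per-gene report: `Gene`, `skcm.dnds`,
#' `quantile.expression`, `norm.neutral`, `norm.high`, `skcm.neutral`,
#' `skcm.high` (neutral = total minus high-impact), restricted to the
#' essential genes unless `essential_only = FALSE`.
#'
#' @param scan An `essential_scan` object.
#' @param essential_only Restrict to essential genes (default `TRUE`).
#' @return A tibble in the S1-style column layout.
#' @export
as_s1_table <- function(scan, essential_only = TRUE) {
  stopifnot(inherits(scan, "essential_scan"))
  d <- scan$decisions
  if (essential_only) d <- d[d$essential, ]
  counts <- scan$summaries |>
    dplyr::mutate(neutral = .data$n_total - .data$n_high) |>
    tidyr::pivot_wider(
      id_cols = "gene_id",
      names_from = "cohort",
      values_from = c("neutral", "n_high")
    )
  germ <- grep("germline", names(counts), value = TRUE)
  som <- grep("somatic", names(counts), value = TRUE)
  out <- d |>
    dplyr::left_join(counts, by = "gene_id") |>
    dplyr::transmute(
      Gene = .data$gene_id,
      skcm.dnds = .data$omega,
      quantile.expression = .data$quantile_expression,
      norm.neutral = .data[[grep("^neutral", germ, value = TRUE)]],
      norm.high = .data[[grep("^n_high", germ, value = TRUE)]],
      skcm.neutral = .data[[grep("^neutral", som, value = TRUE)]],
      skcm.high = .data[[grep("^n_high", som, value = TRUE)]]
    )
  out
}

#' Plot the genome-wide omega distribution of a scan
#'
#' Histogram of defined per-gene dN/dS values with the selection threshold
#' marked.
#'
#' @param object An `essential_scan` object.
#' @param bin_width,range Histogram controls (see [omega_histogram()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot essential_scan
#' @export
autoplot.essential_scan <- function(object, bin_width = 0.05,
                                    range = c(0, 2), ...) {
  hist <- object$omega_hist %||%
    omega_histogram(object$estimates, bin_width = bin_width, range = range)
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$center, y = .data$count)) +
    ggplot2::geom_col(width = hist$bin_right[1] - hist$bin_left[1],
                      fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$dnds_threshold_used,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "dN/dS", y = "genes",
                  title = "Genome-wide dN/dS distribution") +
    ggplot2::theme_minimal()
}
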