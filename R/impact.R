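#' Derive high-impact score cutoffs from the data
#'
#' The cutoffs are empirical percentiles (linear-interpolation definition,
#' R quantile type 7) of the two ensemble impact-score channels over the
#' scored non-synonymous SNVs. With `population = "pooled"` (default) both
#' cohorts' scored variants are pooled into one score population, so a
#' single pair of cutoffs applies to every variant; `"per_cohort"` derives
#' cohort-specific cutoffs.
#'
#' @param variants Canonical variant tibble (both cohorts together when
#'   pooling, see [dplyr::bind_rows()]).
#' @param percentile Percentile in (0, 1); default 0.70.
#' @param population `"pooled"` or `"per_cohort"`.
#' @return An object of class `impact_thresholds`: list with `percentile`,
#'   `population`, and `cutoffs` (tibble with `cohort`, `cutoff_a`,
#'   `cutoff_b`; cohort is `"pooled"` for the pooled population).
#' @export
derive_thresholds <- function(variants, percentile = 0.70,
                              population = c("pooled", "per_cohort")) {
  population <- match.arg(population)
  stopifnot(percentile >= 0, percentile < 1)
  scored <- dplyr::filter(
    variants,
    .data$variant_class == "snv",
    is.na(.data$consequence) | .data$consequence != "synonymous",
    !is.na(.data$score_a) | !is.na(.data$score_b)
  )
  if (nrow(scored) == 0L) abort("No scored non-synonymous SNVs.")

  one <- function(df, label) {
    tibble(
      cohort = label,
      cutoff_a = unname(quantile(df$score_a, percentile, na.rm = TRUE,
                                 type = 7)),
      cutoff_b = unname(quantile(df$score_b, percentile, na.rm = TRUE,
                                 type = 7))
    )
  }
  cutoffs <- if (population == "pooled") {
    one(scored, "pooled")
  } else {
    dplyr::bind_rows(lapply(split(scored, scored$cohort), function(df) {
      one(df, df$cohort[[1]])
    }))
  }
  structure(
    list(percentile = percentile, population = population, cutoffs = cutoffs),
    class = "impact_thresholds"
  )
}

#' @export
print.impact_thresholds <- function(x, ...) {
  cat("Impact-score thresholds (percentile ", x$percentile, ", ",
      x$population, " population)\n", sep = "")
  print(x$cutoffs)
  invisible(x)
}

#' Flag high-functional-impact variants
#'
#' A variant is high-impact if it is an insertion/deletion, a stop
#' gain/loss, or a splice-site variant (categorically, independent of any
#' score), or a non-synonymous SNV whose score in either channel is
#' strictly greater than the corresponding percentile cutoff. Synonymous
#' SNVs are never high-impact; unscored non-synonymous SNVs are not
#' high-impact (conservative). Start-loss SNVs are treated like missense.
#'
#' @param variants Canonical variant tibble with consequences resolved.
#' @param thresholds An `impact_thresholds` object from
#'   [derive_thresholds()].
#' @return Logical vector along the rows of `variants`.
#' @export
is_high_impact <- function(variants, thresholds) {
  stopifnot(inherits(thresholds, "impact_thresholds"))
  cut <- thresholds$cutoffs
  if (thresholds$population == "pooled") {
    cutoff_a <- rep(cut$cutoff_a, nrow(variants))
    cutoff_b <- rep(cut$cutoff_b, nrow(variants))
  } else {
    i <- match(variants$cohort, cut$cohort)
    if (anyNA(i)) {
      abort("Per-cohort thresholds missing for some cohorts in `variants`.")
    }
    cutoff_a <- cut$cutoff_a[i]
    cutoff_b <- cut$cutoff_b[i]
  }

  categorical <- variants$variant_class %in% c("insertion", "deletion") |
    (!is.na(variants$consequence) &
       variants$consequence %in% HIGH_IMPACT_CLASSES)
  synonymous <- !is.na(variants$consequence) &
    variants$consequence == "synonymous"
  by_score <-
    (!is.na(variants$score_a) & variants$score_a > cutoff_a) |
    (!is.na(variants$score_b) & variants$score_b > cutoff_b)

  categorical | (!synonymous & variants$variant_class == "snv" & by_score)
}

#' Per-gene fraction of high-impact mutations
#'
#' For each gene and cohort, `f = n_high / n_total`, where the denominator
#' counts every variant of the gene in that cohort (synonymous included)
#' and the numerator counts those flagged by [is_high_impact()].
#'
#' @param variants Canonical variant tibble (one or both cohorts).
#' @param thresholds An `impact_thresholds` object.
#' @return A tibble with columns `gene_id`, `cohort`, `n_total`, `n_high`,
#'   `f`.
#' @export
compute_f <- function(variants, thresholds) {
  if (nrow(variants) == 0L) abort("Empty variant set.")
  variants$.high <- is_high_impact(variants, thresholds)
  variants |>
    dplyr::group_by(.data$gene_id, .data$cohort) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_high = sum(.data$.high),
      f = .data$n_high / .data$n_total,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$gene_id, .data$cohort)
}

#' Germline-vs-somatic depletion test
#'
#' A gene passes when its high-impact fraction in the germline cohort is
#' strictly greater than in the somatic cohort (`f_germline > f_somatic`);
#' ties fail. Genes missing from either summary get `NA` for the missing
#' fraction and fail.
#'
#' @param somatic,germline Per-gene summaries from [compute_f()] for the
#'   two cohorts.
#' @return A tibble with `gene_id`, `f_somatic`, `f_germline`, `depleted`.
#' @export
depletion_test <- function(somatic, germline) {
  out <- dplyr::full_join(
    dplyr::select(somatic, "gene_id", f_somatic = "f"),
    dplyr::select(germline, "gene_id", f_germline = "f"),
    by = "gene_id"
  )
  out$depleted <- !is.na(out$f_somatic) & !is.na(out$f_germline) &
    out$f_germline > out$f_somatic
  dplyr::arrange(out, .data$gene_id)
}
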