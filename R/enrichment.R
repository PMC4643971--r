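#' Upper-tail hypergeometric over-representation p-value
#'
#' `P[X >= k]` for `X ~ Hypergeometric(M, K, n)`: drawing `n` genes from a
#' universe of `M` of which `K` belong to the set, the probability of at
#' least `k` hits. Vectorised over its arguments.
#'
#' @param k Observed hits in the target list.
#' @param K Set members in the universe.
#' @param n Target-list size in the universe.
#' @param M Universe size.
#' @return Numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' hypergeometric_overrep(3, 4, 5, 10)  # 66/252
hypergeometric_overrep <- function(k, K, n, M) {
  ok <- k <= K & K <= M & k <= n & n <= M & k >= 0
  if (any(!ok)) abort("Inconsistent hypergeometric counts (need k <= K <= M, k <= n <= M).")
  stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, order-preserving with the input and
#' capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Read gene sets from a GMT file
#'
#' Tab-delimited: set name, description, then member genes. Duplicate
#' members within a set are dropped; empty sets are skipped.
#'
#' @param path Path to a GMT file.
#' @param source Label recorded in the `source` column (defaults to the
#'   file name), used for within-collection multiple-testing correction.
#' @return A tibble with columns `set`, `source`, `description`, `genes`
#'   (list-column of character vectors).
#' @export
read_gmt <- function(path, source = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- lengths(fields) >= 3L
  fields <- fields[keep]
  if (length(fields) == 0L) abort(paste0("No gene sets in ", path))
  tibble(
    set = vapply(fields, `[[`, character(1), 1L),
    source = source %||% basename(path),
    description = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(x) unique(x[-(1:2)]))
  )
}

#' Write gene sets to a GMT file
#'
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_len(nrow(sets)), function(i) {
    paste(c(sets$set[[i]],
            if ("description" %in% names(sets)) sets$description[[i]] else "na",
            sets$genes[[i]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Gene-set over-representation analysis
#'
#' For each gene set, members are first intersected with the reference
#' universe (the expression-filtered gene list); `k` is the overlap with
#' the target list, and the p-value is the exact upper-tail hypergeometric
#' probability. Sets with no member in the universe are skipped.
#' Benjamini-Hochberg correction is applied within each `source`
#' collection by default (`scope = "global"` corrects across all sets at
#' once).
#'
#' @param target Character vector of target genes (must be a subset of
#'   `universe`; in strict mode offenders are an error, otherwise they are
#'   dropped with a warning).
#' @param universe Character vector: the reference universe.
#' @param collections Gene-set tibble from [read_gmt()] (rows from several
#'   files can be combined with [dplyr::bind_rows()]).
#' @param scope `"within_collection"` or `"global"` BH correction.
#' @param strict Error when `target` is not a subset of `universe`.
#' @return A tibble with `set`, `source`, `k`, `K`, `n`, `M`, `p_value`,
#'   `p_adjusted`, sorted by `p_value`.
#' @export
enrich <- function(target, universe, collections,
                   scope = c("within_collection", "global"),
                   strict = TRUE) {
  scope <- match.arg(scope)
  universe <- unique(universe)
  target <- unique(target)
  stray <- setdiff(target, universe)
  if (length(stray) > 0L) {
    msg <- paste0("Target genes outside the universe: ",
                  paste(head(stray, 10), collapse = ", "))
    if (strict) abort(msg)
    warn(paste0(msg, "; dropped."))
    target <- intersect(target, universe)
  }
  if (nrow(collections) == 0L) {
    return(tibble(set = character(), source = character(), k = integer(),
                  K = integer(), n = integer(), M = integer(),
                  p_value = double(), p_adjusted = double()))
  }

  M <- length(universe)
  n <- length(target)
  res <- collections |>
    dplyr::mutate(
      members = lapply(.data$genes, intersect, y = universe),
      K = lengths(.data$members),
      k = vapply(.data$members, function(g) length(intersect(g, target)),
                 integer(1))
    ) |>
    dplyr::filter(.data$K > 0L) |>
    dplyr::mutate(
      n = n, M = M,
      p_value = hypergeometric_overrep(.data$k, .data$K, n, M)
    ) |>
    dplyr::select("set", "source", "k", "K", "n", "M", "p_value")

  if (nrow(res) == 0L) {
    res$p_adjusted <- double(0)
    return(res)
  }
  res <- if (scope == "global") {
    dplyr::mutate(res, p_adjusted = bh_adjust(.data$p_value))
  } else {
    res |>
      dplyr::group_by(.data$source) |>
      dplyr::mutate(p_adjusted = bh_adjust(.data$p_value)) |>
      dplyr::ungroup()
  }
  dplyr::arrange(res, .data$p_value, .data$set)
}

#' Bar plot of enrichment results
#'
#' @param results Tibble from [enrich()].
#' @param top_n Number of top sets (by adjusted p) to show.
#' @param alpha Significance line drawn at this adjusted-p level.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(results, top_n = 15, alpha = 0.05) {
  df <- head(dplyr::arrange(results, .data$p_adjusted), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_adjusted),
    y = stats::reorder(.data$set, -.data$p_adjusted),
    fill = .data$source
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$k), hjust = -0.2,
                       size = 3) +
    ggplot2::geom_vline(xintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL) +
    ggplot2::theme_minimal()
}
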