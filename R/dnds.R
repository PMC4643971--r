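#' Per-gene dN/dS from somatic SNVs
#'
#' The per-gene omega is the ratio of per-site substitution rates,
#' `omega = (n_obs / n_sites) / (s_obs / s_sites)`, with expected site
#' counts from [count_sites()] (NG86 per-position fractions). By default
#' `n_obs` counts all non-synonymous SNVs (missense, stop gain/loss, start
#' loss), keeping the numerator consistent with the site counting, in which
#' stop-creating changes occupy non-synonymous sites; `numerator =
#' "missense"` restricts to missense. Splice-site SNVs and indels never
#' enter either count. `omega` is undefined (`defined = FALSE`) when a gene
#' has no synonymous observations; no pseudocounts are added.
#'
#' Each variant record is one observation; recurrent identical mutations
#' across samples count once per record unless `distinct_sites = TRUE`
#' deduplicates by `(gene_id, cds_pos, ref, alt)`.
#'
#' @param variants Somatic variant tibble with consequences resolved
#'   (via [classify_variants()] or pre-annotated input).
#' @param sites Site-count tibble from [count_sites()].
#' @param numerator `"nonsynonymous"` (default) or `"missense"`.
#' @param distinct_sites Deduplicate identical variants before counting.
#' @return A tibble with columns `gene_id`, `n_obs`, `s_obs`, `n_sites`,
#'   `s_sites`, `omega`, `defined`, one row per gene present in both
#'   `variants` and `sites`.
#' @export
estimate_dnds <- function(variants, sites,
                          numerator = c("nonsynonymous", "missense"),
                          distinct_sites = FALSE) {
  numerator <- match.arg(numerator)
  stopifnot(is.data.frame(variants), is.data.frame(sites))
  missing_genes <- setdiff(unique(variants$gene_id), sites$gene_id)
  if (length(missing_genes) > 0L) {
    abort(paste0("No site counts for gene(s): ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  if (distinct_sites) {
    variants <- dplyr::distinct(variants, .data$gene_id, .data$cds_pos,
                                .data$ref, .data$alt, .keep_all = TRUE)
  }
  num_classes <- if (numerator == "nonsynonymous") NONSYN_SNV else "missense"

  snvs <- dplyr::filter(variants, .data$variant_class == "snv",
                        !is.na(.data$consequence))
  obs <- snvs |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_obs = sum(.data$consequence %in% num_classes),
      s_obs = sum(.data$consequence == "synonymous"),
      .groups = "drop"
    )

  out <- dplyr::left_join(obs, sites, by = "gene_id") |>
    dplyr::mutate(
      defined = .data$s_obs > 0 & .data$n_sites > 0 & .data$s_sites > 0,
      omega = ifelse(.data$defined,
                     (.data$n_obs / .data$n_sites) /
                       (.data$s_obs / .data$s_sites),
                     NA_real_)
    ) |>
    dplyr::select("gene_id", "n_obs", "s_obs", "n_sites", "s_sites",
                  "omega", "defined") |>
    dplyr::arrange(.data$gene_id)
  out
}

#' Genome-wide histogram of dN/dS values
#'
#' Left-closed binning (`[edge, edge + bin_width)`; a value landing exactly
#' on an edge goes to the bin starting there) of the defined omegas, clipped
#' to `range`. Values at or beyond the upper range limit are excluded.
#'
#' @param estimates Tibble from [estimate_dnds()].
#' @param bin_width Bin width (default 0.05).
#' @param range Two-element numeric range (default `c(0, 2)`).
#' @return A tibble of class `negsel_omega_hist` with columns `bin_left`,
#'   `bin_right`, `center`, `count`.
#' @export
omega_histogram <- function(estimates, bin_width = 0.05, range = c(0, 2)) {
  stopifnot(bin_width > 0, length(range) == 2L, range[2] > range[1])
  omegas <- estimates$omega[estimates$defined]
  if (length(omegas) == 0L) abort("No defined dN/dS estimates to bin.")
  omegas <- omegas[omegas >= range[1] & omegas < range[2]]
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  bin <- findInterval(omegas, edges, rightmost.closed = FALSE)
  out <- tibble(
    bin_left = edges[-length(edges)],
    bin_right = edges[-1],
    center = (edges[-length(edges)] + edges[-1]) / 2,
    count = tabulate(bin, nbins = length(edges) - 1L)
  )
  class(out) <- c("negsel_omega_hist", class(out))
  out
}

#' Data-driven negative-selection threshold from the omega histogram
#'
#' Scans the histogram for strict local minima (bins whose count is smaller
#' than both neighbours) with centers inside `search_interval`, and returns
#' the center of the lowest such bin; ties break toward the smaller omega.
#' When no strict interior minimum exists the configured `fallback`
#' (default 0.25, the value at which genome-wide tumor omega distributions
#' typically dip between the purifying mode and the neutral mode) is
#' returned with a warning.
#'
#' @param dist A `negsel_omega_hist` tibble from [omega_histogram()].
#' @param search_interval Interval of omega centers to search
#'   (default `c(0.05, 0.75)`).
#' @param fallback Threshold returned when no strict local minimum exists.
#' @return A single numeric threshold.
#' @export
find_negative_selection_threshold <- function(dist,
                                              search_interval = c(0.05, 0.75),
                                              fallback = 0.25) {
  stopifnot(inherits(dist, "negsel_omega_hist"))
  in_int <- dist$center >= search_interval[1] & dist$center <= search_interval[2]
  if (sum(in_int) < 3L) {
    abort("Fewer than 3 histogram bins intersect the search interval.")
  }
  # local-minimum plateaus: runs of equal counts flanked on both sides by
  # strictly larger counts; the run's leftmost bin is the candidate
  r <- rle(dist$count)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  nr <- length(r$values)
  cand <- integer(0)
  if (nr >= 3L) {
    for (j in 2:(nr - 1L)) {
      if (r$values[j] < r$values[j - 1L] && r$values[j] < r$values[j + 1L]) {
        bins <- run_start[j]:run_end[j]
        bins <- bins[in_int[bins]]
        if (length(bins) > 0L) cand <- c(cand, min(bins))
      }
    }
  }
  if (length(cand) == 0L) {
    warn(paste0("No strict local minimum in [", search_interval[1], ", ",
                search_interval[2], "]; using fallback threshold ",
                fallback, "."))
    return(fallback)
  }
  best <- cand[dist$count[cand] == min(dist$count[cand])]
  dist$center[min(best)]
}

#' Write per-gene dN/dS estimates to TSV
#'
#' @param estimates Tibble from [estimate_dnds()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dnds <- function(estimates, path) {
  readr::write_tsv(estimates, path)
  invisible(path)
}
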