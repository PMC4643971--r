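#' Load protein-interaction edges from a STRING-style TSV
#'
#' Expects at least three columns: the two proteins and a combined score.
#' Edges are undirected: each pair is stored in canonical (sorted) order
#' and duplicates keep the maximum score. `score_scale = "milli"` divides
#' scores by 1000 (STRING's integer convention); scores outside \[0, 1\]
#' after normalization are an error. An optional `physical` column
#' (logical or 0/1) flags known direct physical interactions.
#'
#' @param path TSV path with header.
#' @param score_scale `"unit"` or `"milli"`.
#' @return A tibble with `protein_a`, `protein_b`, `combined_score`,
#'   `physical`.
#' @export
read_string_edges <- function(path, score_scale = c("unit", "milli")) {
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(raw) < 3L) abort("Edge table needs at least three columns.")
  edges <- tibble(
    protein_a = as.character(raw[[1]]),
    protein_b = as.character(raw[[2]]),
    combined_score = as.numeric(raw[[3]]),
    physical = if ("physical" %in% names(raw)) {
      as.logical(raw[["physical"]])
    } else {
      NA
    }
  )
  normalize_edges(edges, score_scale)
}

normalize_edges <- function(edges, score_scale = "unit") {
  if (score_scale == "milli") {
    edges$combined_score <- edges$combined_score / 1000
  }
  if (any(edges$combined_score < 0 | edges$combined_score > 1)) {
    abort("Interaction scores outside [0, 1] after normalization.")
  }
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  edges$protein_a <- a
  edges$protein_b <- b
  edges |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(
      combined_score = max(.data$combined_score),
      physical = if (all(is.na(.data$physical))) NA else
        any(.data$physical, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

#' Summarize high-confidence interactions for a bait set
#'
#' Keeps edges with score strictly greater than `min_score`, then reports
#' for each bait (query gene) its prey count (graph degree, self-loops
#' excluded; preys may themselves be baits), for each bait pair the number
#' of common partners, and whether the two baits share a direct physical
#' edge. Baits with zero preys are omitted from the main table and listed
#' in the `zero_prey` sidecar.
#'
#' @param edges Edge tibble from [read_string_edges()] (or any tibble with
#'   `protein_a`, `protein_b`, `combined_score`, optional `physical`).
#' @param baits Character vector of query genes (non-empty).
#' @param min_score Strict lower bound on the combined score (default 0.9).
#' @return An object of class `bait_summary`: list with `baits` (tibble
#'   `bait`, `n_prey`), `pairs` (tibble `bait_a`, `bait_b`, `n_common`,
#'   `physical_link`), `zero_prey` (character), `min_score`.
#' @export
summarize_baits <- function(edges, baits, min_score = 0.9) {
  baits <- unique(baits)
  if (length(baits) == 0L) abort("Empty bait set.")
  stopifnot(min_score >= 0, min_score <= 1)
  if (!"physical" %in% names(edges)) edges$physical <- NA

  kept <- edges[edges$combined_score > min_score &
                  edges$protein_a != edges$protein_b, ]

  neighbors <- function(g) {
    unique(c(kept$protein_b[kept$protein_a == g],
             kept$protein_a[kept$protein_b == g]))
  }
  nb <- lapply(baits, neighbors)
  names(nb) <- baits
  n_prey <- lengths(nb)

  bait_tbl <- tibble(bait = baits, n_prey = as.integer(n_prey)) |>
    dplyr::filter(.data$n_prey > 0L) |>
    dplyr::arrange(dplyr::desc(.data$n_prey), .data$bait)
  zero_prey <- sort(baits[n_prey == 0L])

  pairs <- tibble(bait_a = character(), bait_b = character(),
                  n_common = integer(), physical_link = logical())
  active <- bait_tbl$bait
  if (length(active) >= 2L) {
    combos <- utils::combn(sort(active), 2L)
    pairs <- tibble(
      bait_a = combos[1, ],
      bait_b = combos[2, ],
      n_common = vapply(seq_len(ncol(combos)), function(i) {
        length(intersect(nb[[combos[1, i]]], nb[[combos[2, i]]]))
      }, integer(1)),
      physical_link = vapply(seq_len(ncol(combos)), function(i) {
        a <- min(combos[, i]); b <- max(combos[, i])
        hit <- kept$protein_a == a & kept$protein_b == b
        any(hit & !is.na(kept$physical) & kept$physical)
      }, logical(1))
    ) |>
      dplyr::filter(.data$n_common > 0L | .data$physical_link) |>
      dplyr::arrange(dplyr::desc(.data$n_common))
  }

  structure(
    list(baits = bait_tbl, pairs = pairs, zero_prey = zero_prey,
         min_score = min_score),
    class = "bait_summary"
  )
}

#' @export
print.bait_summary <- function(x, ...) {
  cat("Bait interaction summary (score > ", x$min_score, ")\n", sep = "")
  cat("  baits with preys: ", nrow(x$baits),
      "; without: ", length(x$zero_prey), "\n", sep = "")
  print(x$baits, n = 10)
  invisible(x)
}

#' Write the bait summary tables
#'
#' Emits a Table-2-style TSV (bait, prey count), the bait-pair
#' common-partner table, and the zero-prey sidecar.
#'
#' @param summary A `bait_summary` object.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_bait_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "bait_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(summary$baits, file.path(dir, "bait_prey_counts.tsv"))
  readr::write_tsv(summary$pairs, file.path(dir, "bait_common_partners.tsv"))
  readr::write_lines(summary$zero_prey, file.path(dir, "baits_without_preys.txt"))
  invisible(dir)
}
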