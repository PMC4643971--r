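#' Build the run manifest of a selection scan
#'
#' Records the configuration snapshot, content digests of the inputs,
#' per-stage gene counts (cumulative through the conjunctive cascade, so
#' non-increasing), the package version and the seed. Deliberately free of
#' timestamps and absolute paths: identical inputs and config give a
#' byte-identical manifest.
#'
#' @param scan An `essential_scan` object (its `manifest` slot may still be
#'   unset).
#' @param somatic,germline The variant tibbles the scan consumed.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(scan, somatic = NULL, germline = NULL) {
  g <- glance(scan)
  counts <- list(
    genes_in_both_cohorts = g$n_genes,
    pass_min_variants = g$n_pass_min_variants,
    pass_dnds = g$n_pass_dnds,
    pass_expression = g$n_pass_expression,
    pass_depletion = g$n_pass_depletion,
    essential = g$n_essential
  )
  digests <- list(
    somatic = if (is.null(somatic)) NA_character_ else
      rlang::hash(as.data.frame(somatic)),
    germline = if (is.null(germline)) NA_character_ else
      rlang::hash(as.data.frame(germline)),
    expression = rlang::hash(as.data.frame(scan$expression))
  )
  structure(
    list(
      tool = "negsel",
      version = as.character(utils::packageVersion("negsel")),
      seed = scan$config$random_seed,
      config = unclass(scan$config),
      dnds_threshold_used = scan$dnds_threshold_used,
      input_digests = digests,
      counts = counts
    ),
    class = "run_manifest"
  )
}

validate_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  cascade <- unlist(manifest$counts)
  if (any(diff(cascade) > 0)) {
    abort("Inconsistent manifest: cascade gene counts increase.")
  }
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("negsel run manifest (v", x$version, ", seed ", x$seed, ")\n",
      sep = "")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}

#' Write the human-readable report bundle
#'
#' One plain-text summary (counts per filter, the essential list, top
#' enriched sets, the bait table) plus machine-readable TSVs and the JSON
#' manifest. Pure: nothing is recomputed, so re-running on the same stage
#' outputs is byte-identical. An empty essential list is a finding, not an
#' error.
#'
#' @param scan An `essential_scan` object.
#' @param dir Output directory (created if needed).
#' @param enrichments Optional tibble from [enrich()].
#' @param bait_summary Optional `bait_summary` from [summarize_baits()].
#' @param manifest Manifest to write (defaults to the scan's own).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(scan, dir, enrichments = NULL, bait_summary = NULL,
                         manifest = NULL) {
  stopifnot(inherits(scan, "essential_scan"))
  manifest <- manifest %||% scan$manifest
  validate_manifest(manifest)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  paths <- c(
    summary = file.path(dir, "summary.txt"),
    decisions = file.path(dir, "decisions.tsv"),
    s1 = file.path(dir, "essential_genes.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  readr::write_tsv(scan$decisions, paths[["decisions"]])
  readr::write_tsv(as_s1_table(scan), paths[["s1"]])
  jsonlite::write_json(unclass(manifest), paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ess <- essential_genes(scan)
  lines <- c(
    "negsel selection report",
    "=======================",
    "",
    "Filter cascade (cumulative gene counts):",
    vapply(names(manifest$counts), function(nm) {
      sprintf("  %-22s %d", nm, manifest$counts[[nm]])
    }, character(1)),
    "",
    sprintf("dN/dS threshold used: %s",
            format(manifest$dnds_threshold_used)),
    "",
    sprintf("Essential genes (%d):", length(ess)),
    if (length(ess) > 0) paste0("  ", ess) else "  (none)",
    ""
  )

  if (!is.null(enrichments)) {
    readr::write_tsv(enrichments, file.path(dir, "enrichment.tsv"))
    paths <- c(paths, enrichment = file.path(dir, "enrichment.tsv"))
    top <- head(dplyr::arrange(enrichments, .data$p_adjusted), 10)
    lines <- c(lines, "Top enriched sets (BH-adjusted p):",
               if (nrow(top) == 0) "  (none tested)" else
                 sprintf("  %-30s k=%d/%d  p.adj=%.3g",
                         top$set, top$k, top$K, top$p_adjusted),
               "")
  } else {
    lines <- c(lines, "Enrichment: not run", "")
  }

  if (!is.null(bait_summary)) {
    write_bait_summary(bait_summary, dir)
    paths <- c(paths, baits = file.path(dir, "bait_prey_counts.tsv"))
    lines <- c(lines,
               sprintf("Interaction baits with preys (score > %s): %d; without: %d",
                       format(bait_summary$min_score),
                       nrow(bait_summary$baits),
                       length(bait_summary$zero_prey)),
               if (nrow(bait_summary$baits) > 0)
                 sprintf("  %-12s %d preys", bait_summary$baits$bait,
                         bait_summary$baits$n_prey),
               "")
  } else {
    lines <- c(lines, "Network summary: not run", "")
  }

  readr::write_lines(lines, paths[["summary"]])
  invisible(paths)
}
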