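# Readers normalising somatic (MAF-dialect TSV) and germline (VCF) calls
# into one canonical variant tibble:
#   cohort, gene_id, cds_pos, ref, alt, variant_class, consequence,
#   score_a, score_b
# Provenance (source path, kept/dropped counts) travels as an attribute.

VARIANT_COLS <- c("cohort", "gene_id", "cds_pos", "ref", "alt",
                  "variant_class", "consequence", "score_a", "score_b")

new_cohort_table <- function(df, cohort, source, n_kept, n_dropped) {
  out <- as_tibble(df)[, VARIANT_COLS]
  attr(out, "provenance") <- list(
    cohort = cohort, source = source,
    n_kept = n_kept, n_dropped = n_dropped
  )
  out
}

#' Provenance of a cohort table
#'
#' @param x A variant tibble produced by [read_maf()], [read_vcf()] or
#'   [simulate_cohort()].
#' @return A list with elements `cohort`, `source`, `n_kept`, `n_dropped`,
#'   or `NULL` when the attribute has been dropped by data wrangling.
#' @export
provenance <- function(x) attr(x, "provenance")

infer_variant_class <- function(ref, alt) {
  r <- nchar(gsub("-", "", ref))
  a <- nchar(gsub("-", "", alt))
  ifelse(r == 1L & a == 1L & ref != "-" & alt != "-", "snv",
         ifelse(a > r, "insertion", "deletion"))
}

# MAF vocabulary -> canonical consequence
MAF_CONSEQUENCE_MAP <- c(
  Silent = "synonymous",
  Missense_Mutation = "missense",
  Nonsense_Mutation = "stop_gain",
  Nonstop_Mutation = "stop_loss",
  Translation_Start_Site = "start_loss",
  Splice_Site = "splice_site",
  Frame_Shift_Del = "frameshift_indel",
  Frame_Shift_Ins = "frameshift_indel",
  In_Frame_Del = "inframe_indel",
  In_Frame_Ins = "inframe_indel"
)

#' Column-role map for MAF-dialect tables
#'
#' Maps the roles the reader needs onto column names. `position` is
#' interpreted as a CDS-relative coordinate; `consequence`, `score_a` and
#' `score_b` are optional (set to `NA` to ignore).
#'
#' @param gene,class,ref,alt,position,consequence,score_a,score_b Column
#'   names in the input table.
#' @return Named character vector of roles.
#' @export
maf_column_map <- function(gene = "Hugo_Symbol", class = "Variant_Type",
                           ref = "Reference_Allele",
                           alt = "Tumor_Seq_Allele2",
                           position = "CDS_Position",
                           consequence = "Variant_Classification",
                           score_a = NA, score_b = NA) {
  c(gene = gene, class = class, ref = ref, alt = alt, position = position,
    consequence = consequence, score_a = score_a, score_b = score_b)
}

#' Read somatic variant calls from a MAF-dialect table
#'
#' Tab-delimited with header; the `column_map` resolves the required roles
#' (gene, alleles, position; variant class and consequence when present).
#' Rows with an unresolvable gene or alleles are dropped and counted in the
#' provenance attribute. The variant class is inferred from allele lengths
#' when the class column is absent; `"-"` denotes the empty allele.
#'
#' @param path Path to the tab-delimited file.
#' @param column_map Role map from [maf_column_map()].
#' @param cohort Cohort label for the resulting variants.
#' @param position_base Coordinate convention of the position column
#'   (`1` or `0`; 0-based input is shifted up by one).
#' @return Canonical variant tibble with a provenance attribute.
#' @export
read_maf <- function(path, column_map = maf_column_map(),
                     cohort = "somatic", position_base = 1L) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0L) abort(paste0("Empty table: ", path))

  required <- c("gene", "ref", "alt")
  missing_roles <- required[!column_map[required] %in% names(raw)]
  if (length(missing_roles) > 0L) {
    abort(paste0(
      "Missing required column(s) for role(s) ",
      paste(missing_roles, collapse = ", "), ": expected ",
      paste(column_map[missing_roles], collapse = ", ")
    ))
  }

  get_col <- function(role) {
    nm <- column_map[[role]]
    if (is.na(nm) || !nm %in% names(raw)) rep(NA_character_, nrow(raw))
    else raw[[nm]]
  }

  gene <- get_col("gene")
  ref <- toupper(get_col("ref"))
  alt <- toupper(get_col("alt"))
  pos <- suppressWarnings(as.integer(get_col("position")))
  if (position_base == 0L) pos <- pos + 1L

  bad <- is.na(gene) | !nzchar(gene) | is.na(ref) | is.na(alt) |
    !nzchar(ref) | !nzchar(alt)
  n_dropped <- sum(bad)
  if (n_dropped > 0L) {
    inform(paste0(n_dropped, " unparseable row(s) dropped from ", path))
  }

  cls_raw <- get_col("class")
  cls <- dplyr::case_when(
    toupper(cls_raw) %in% c("SNP", "SNV", "DNP", "SUB") ~ "snv",
    toupper(cls_raw) == "INS" ~ "insertion",
    toupper(cls_raw) == "DEL" ~ "deletion",
    TRUE ~ NA_character_
  )
  cls <- ifelse(is.na(cls), infer_variant_class(ref, alt), cls)

  cons_raw <- get_col("consequence")
  cons <- ifelse(cons_raw %in% names(MAF_CONSEQUENCE_MAP),
                 MAF_CONSEQUENCE_MAP[cons_raw],
                 ifelse(cons_raw %in% CONSEQUENCES, cons_raw, NA_character_))

  out <- tibble(
    cohort = cohort,
    gene_id = gene,
    cds_pos = pos,
    ref = ref,
    alt = alt,
    variant_class = cls,
    consequence = unname(cons),
    score_a = suppressWarnings(as.numeric(get_col("score_a"))),
    score_b = suppressWarnings(as.numeric(get_col("score_b")))
  )[!bad, ]

  new_cohort_table(out, cohort, path, nrow(out), n_dropped)
}

#' Exon-level map from genomic to CDS coordinates
#'
#' One row per exon segment: genomic interval `[start, end]` on `chrom`
#' maps to CDS positions starting at `cds_start`; on the minus strand the
#' genomic `end` corresponds to `cds_start` and alleles are
#' reverse-complemented on lift-over.
#'
#' @param gene_id,chrom,strand,start,end,cds_start Parallel vectors.
#' @return A validated tibble of class `negsel_cds_map`.
#' @export
cds_map <- function(gene_id, chrom, strand, start, end, cds_start) {
  out <- tibble(
    gene_id = gene_id, chrom = chrom, strand = strand,
    start = as.integer(start), end = as.integer(end),
    cds_start = as.integer(cds_start)
  )
  stopifnot(all(out$strand %in% c("+", "-")), all(out$end >= out$start),
            all(out$cds_start >= 1L))
  class(out) <- c("negsel_cds_map", class(out))
  out
}

revcomp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Read germline variants from a VCF file
#'
#' Multi-allelic records are split into one variant per alternate allele.
#' Gene assignment and CDS positions come either from a [cds_map()]
#' (exon-aware genomic lift, both strands) or, when `map` is `NULL`, from
#' `GENE=`/`CDSPOS=` tags in the INFO field. Records outside any CDS are
#' dropped and counted in the provenance attribute (a warning, not an
#' error, when nothing overlaps).
#'
#' @param path Path to a VCF 4.x file.
#' @param map Optional [cds_map()] tibble.
#' @param cohort Cohort label (default `"germline"`).
#' @return Canonical variant tibble with a provenance attribute.
#' @export
read_vcf <- function(path, map = NULL, cohort = "germline") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    warn(paste0("No records in VCF: ", path))
    return(new_cohort_table(
      tibble(cohort = character(), gene_id = character(),
             cds_pos = integer(), ref = character(), alt = character(),
             variant_class = character(), consequence = character(),
             score_a = double(), score_b = double()),
      cohort, path, 0L, 0L
    ))
  }

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  long <- tibble(
    chrom = fix$CHROM[idx],
    pos = as.integer(fix$POS[idx]),
    ref = toupper(fix$REF[idx]),
    alt = toupper(unlist(alts)),
    info = if ("INFO" %in% names(fix)) fix$INFO[idx] else NA_character_
  )

  if (!is.null(map)) {
    stopifnot(inherits(map, "negsel_cds_map"))
    hit <- dplyr::inner_join(
      dplyr::mutate(long, .row = dplyr::row_number()),
      map, by = "chrom", relationship = "many-to-many"
    )
    hit <- dplyr::filter(hit, .data$pos >= .data$start, .data$pos <= .data$end)
    hit <- dplyr::mutate(
      hit,
      cds_pos = ifelse(.data$strand == "+",
                       .data$cds_start + .data$pos - .data$start,
                       .data$cds_start + .data$end - .data$pos)
    )
    is_snv <- nchar(hit$ref) == 1L & nchar(hit$alt) == 1L
    flip <- hit$strand == "-" & is_snv
    hit$ref[flip] <- revcomp_base(hit$ref[flip])
    hit$alt[flip] <- revcomp_base(hit$alt[flip])
    long <- dplyr::distinct(hit, .data$.row, .keep_all = TRUE)
    gene <- long$gene_id
    cds_pos <- as.integer(long$cds_pos)
    n_dropped <- length(idx) - nrow(long)
  } else {
    gene <- stringr::str_match(long$info, "(?:^|;)GENE=([^;]+)")[, 2]
    cds_pos <- suppressWarnings(
      as.integer(stringr::str_match(long$info, "(?:^|;)CDSPOS=([^;]+)")[, 2])
    )
    keep <- !is.na(gene)
    n_dropped <- sum(!keep)
    long <- long[keep, ]
    gene <- gene[keep]
    cds_pos <- cds_pos[keep]
  }

  if (nrow(long) == 0L) {
    warn(paste0("No VCF records overlap any CDS: ", path))
  } else if (n_dropped > 0L) {
    inform(paste0(n_dropped, " VCF record(s) outside any CDS dropped."))
  }

  out <- tibble(
    cohort = cohort,
    gene_id = gene,
    cds_pos = cds_pos,
    ref = long$ref,
    alt = long$alt,
    variant_class = infer_variant_class(long$ref, long$alt),
    consequence = NA_character_,
    score_a = NA_real_,
    score_b = NA_real_
  )
  new_cohort_table(out, cohort, path, nrow(out), n_dropped)
}

#' Attach functional-impact scores to variants
#'
#' Joins a score table keyed by `(gene_id, cds_pos, ref, alt)` onto the
#' variant tibble, filling `score_a`/`score_b`. Duplicate keys with equal
#' scores are collapsed silently; conflicting duplicates are an error in
#' strict mode (first wins otherwise, with a warning). Unmatched
#' non-synonymous SNVs are counted and reported; they remain unscored (and
#' will never be called high-impact via the score route).
#'
#' @param variants Canonical variant tibble.
#' @param scores A data frame or TSV path with columns `gene_id`, `cds_pos`,
#'   `ref`, `alt`, `score_a`, `score_b`.
#' @param strict Error on conflicting duplicate keys.
#' @return `variants` with scores filled where matched.
#' @export
attach_scores <- function(variants, scores, strict = FALSE) {
  if (!is.data.frame(scores)) {
    scores <- readr::read_tsv(scores, show_col_types = FALSE)
  }
  scores <- as_tibble(scores)
  stopifnot(all(c("gene_id", "cds_pos", "ref", "alt",
                  "score_a", "score_b") %in% names(scores)))
  scores$cds_pos <- as.integer(scores$cds_pos)

  key <- paste(scores$gene_id, scores$cds_pos, scores$ref, scores$alt)
  if (anyDuplicated(key)) {
    conflict <- vapply(split(seq_along(key), key), function(i) {
      length(unique(scores$score_a[i])) > 1L ||
        length(unique(scores$score_b[i])) > 1L
    }, logical(1))
    if (any(conflict)) {
      msg <- paste0("Conflicting duplicate score keys: ",
                    paste(head(names(conflict)[conflict], 5), collapse = "; "))
      if (strict) abort(msg)
      warn(paste0(msg, "; keeping first."))
    }
    scores <- scores[!duplicated(key), ]
  }

  prov <- attr(variants, "provenance")
  joined <- dplyr::left_join(
    dplyr::select(variants, -"score_a", -"score_b"),
    dplyr::select(scores, "gene_id", "cds_pos", "ref", "alt",
                  "score_a", "score_b"),
    by = c("gene_id", "cds_pos", "ref", "alt")
  )
  unscored <- sum(
    joined$variant_class == "snv" &
      !is.na(joined$consequence) & joined$consequence != "synonymous" &
      is.na(joined$score_a) & is.na(joined$score_b)
  )
  if (unscored > 0L) {
    inform(paste0(unscored, " non-synonymous SNV(s) left unscored."))
  }
  out <- joined[, VARIANT_COLS]
  attr(out, "provenance") <- prov
  out
}

#' Genes with sufficient variant support in both cohorts
#'
#' Mirrors the support filter used before dN/dS estimation: genes carrying
#' fewer than `min_n` variants in either the somatic or the germline cohort
#' are excluded. All variant classes count.
#'
#' @param somatic,germline Canonical variant tibbles.
#' @param min_n Minimum variant count required in each cohort (default 11,
#'   i.e. genes with fewer than 11 variants in either cohort are removed).
#' @return Character vector of gene ids passing in both cohorts.
#' @export
min_variant_filter <- function(somatic, germline, min_n = 11L) {
  cs <- dplyr::count(somatic, .data$gene_id)
  cg <- dplyr::count(germline, .data$gene_id)
  both <- dplyr::inner_join(cs, cg, by = "gene_id", suffix = c("_s", "_g"))
  sort(both$gene_id[both$n_s >= min_n & both$n_g >= min_n])
}

#' Write / read the canonical variant TSV
#'
#' Round-trip safe: writing then re-reading reproduces the same variant
#' multiset.
#'
#' @param variants Canonical variant tibble.
#' @param path TSV path.
#' @return `path` (write) or the variant tibble (read).
#' @export
write_variants <- function(variants, path) {
  readr::write_tsv(variants[, VARIANT_COLS], path)
  invisible(path)
}

#' @rdname write_variants
#' @export
read_variants <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(
    cohort = "c", gene_id = "c", cds_pos = "i", ref = "c", alt = "c",
    variant_class = "c", consequence = "c", score_a = "d", score_b = "d"
  ))
  new_cohort_table(out, unique(out$cohort), path, nrow(out), 0L)
}
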