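#' Build a validated table of transcript models
#'
#' A transcript model is one coding sequence (CDS) per gene, the substrate
#' for expected-site counting and SNV consequence calls. Coordinates are
#' CDS-relative, 1-based, on the coding strand.
#'
#' Validation enforces: length a positive multiple of 3; alphabet restricted
#' to A/C/G/T; no stop codon inside the CDS body (a terminal stop codon is
#' allowed); `exon_boundaries` strictly increasing and within the CDS.
#'
#' @param cds Named character vector of CDS sequences (names are gene ids),
#'   or a data frame with columns `gene_id` and `cds`.
#' @param exon_boundaries Optional named list of integer vectors: for each
#'   gene, the CDS positions immediately preceding an intron (used for
#'   splice-window classification).
#' @param codon_table_id NCBI genetic-code id; `"1"` is the standard table.
#' @param strict If `TRUE`, invalid or duplicated records are errors;
#'   otherwise they are skipped with a warning.
#'
#' @return A tibble of class `negsel_transcripts` with columns `gene_id`,
#'   `cds`, `n_codons`, `exon_boundaries` (list-column), `codon_table_id`.
#' @export
#' @examples
#' transcript_models(c(G1 = "ATGGGGTAA"))
transcript_models <- function(cds, exon_boundaries = NULL,
                              codon_table_id = "1", strict = FALSE) {
  if (is.data.frame(cds)) {
    stopifnot(all(c("gene_id", "cds") %in% names(cds)))
    seqs <- setNames(toupper(cds$cds), cds$gene_id)
  } else {
    if (is.null(names(cds)) || any(!nzchar(names(cds)))) {
      abort("`cds` must be named by gene_id.")
    }
    seqs <- toupper(cds)
  }
  if (length(seqs) == 0L) abort("No CDS records supplied.")

  dup <- duplicated(names(seqs))
  if (any(dup)) {
    msg <- paste0("Duplicate gene_id: ",
                  paste(unique(names(seqs)[dup]), collapse = ", "))
    if (strict) abort(msg)
    warn(paste0(msg, "; keeping first occurrence."))
    seqs <- seqs[!dup]
  }

  code <- genetic_code(codon_table_id)
  problems <- character(0)
  ok <- vapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    id <- names(seqs)[[i]]
    if (nchar(s) == 0L || nchar(s) %% 3L != 0L) {
      problems <<- c(problems, paste0(id, ": length not a positive multiple of 3"))
      return(FALSE)
    }
    if (grepl("[^ACGT]", s)) {
      problems <<- c(problems, paste0(id, ": non-ACGT characters"))
      return(FALSE)
    }
    codons <- split_codons(s)
    body <- codons[-length(codons)]
    if (any(code[body] == "*")) {
      problems <<- c(problems, paste0(id, ": internal stop codon"))
      return(FALSE)
    }
    TRUE
  }, logical(1))

  if (length(problems) > 0L) {
    msg <- paste0("Invalid CDS records (",
                  length(problems), "): ",
                  paste(problems, collapse = "; "))
    if (strict) abort(msg) else warn(paste0(msg, "; skipped."))
  }
  seqs <- seqs[ok]
  if (length(seqs) == 0L) abort("No valid CDS records remain.")

  eb <- lapply(names(seqs), function(id) {
    b <- exon_boundaries[[id]]
    if (is.null(b)) return(integer(0))
    b <- as.integer(b)
    if (is.unsorted(b, strictly = TRUE) || any(b < 1L) ||
        any(b > nchar(seqs[[id]]))) {
      abort(paste0("exon_boundaries for ", id,
                   " must be strictly increasing within [1, CDS length]."))
    }
    b
  })

  out <- tibble(
    gene_id = names(seqs),
    cds = unname(seqs),
    n_codons = nchar(unname(seqs)) %/% 3L,
    exon_boundaries = eb,
    codon_table_id = codon_table_id
  )
  class(out) <- c("negsel_transcripts", class(out))
  out
}

#' Load coding sequences from a FASTA file
#'
#' One CDS per gene; the first whitespace-delimited token of each FASTA
#' header is taken as the gene id. Records violating the transcript-model
#' invariants are skipped with a warning (`strict = TRUE` turns them into
#' errors).
#'
#' @inheritParams transcript_models
#' @param path Path to a FASTA file.
#' @return A `negsel_transcripts` tibble (see [transcript_models()]).
#' @export
read_cds <- function(path, exon_boundaries = NULL, codon_table_id = "1",
                     strict = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) abort(paste0("Empty FASTA file: ", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- setNames(as.character(set), ids)
  transcript_models(seqs, exon_boundaries = exon_boundaries,
                    codon_table_id = codon_table_id, strict = strict)
}

#' Expected synonymous and non-synonymous site counts (NG86)
#'
#' For every codon position, the fraction of the three possible
#' single-nucleotide changes that preserve the amino acid contributes to the
#' synonymous site count `s_sites`; the remainder to `n_sites`. Changes
#' creating a stop codon from a sense codon count as non-synonymous; a
#' terminal stop codon's stop-preserving changes count as synonymous. The
#' counts are exact fractions satisfying
#' `n_sites + s_sites == 3 * n_codons`.
#'
#' @param transcripts A `negsel_transcripts` tibble.
#' @return A tibble with columns `gene_id`, `n_sites`, `s_sites`.
#' @export
#' @examples
#' count_sites(transcript_models(c(G1 = "ATGGGG")))
count_sites <- function(transcripts) {
  stopifnot(inherits(transcripts, "negsel_transcripts"))
  syn <- syn_change_counts(transcripts$codon_table_id[[1]])
  s_sites <- vapply(transcripts$cds, function(s) {
    sum(syn[split_codons(s)]) / 3
  }, numeric(1), USE.NAMES = FALSE)
  tibble(
    gene_id = transcripts$gene_id,
    n_sites = 3 * transcripts$n_codons - s_sites,
    s_sites = s_sites
  )
}

#' Write site counts to TSV
#'
#' @param sites Tibble from [count_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_counts <- function(sites, path) {
  readr::write_tsv(sites, path)
  invisible(path)
}

# Vectorised consequence call for SNVs described by parallel vectors.
# Internal workhorse behind classify_snv() and classify_variants().
classify_snv_impl <- function(transcripts, gene_id, cds_pos, ref, alt) {
  idx <- match(gene_id, transcripts$gene_id)
  if (anyNA(idx)) {
    abort(paste0("Unknown gene_id: ",
                 paste(unique(gene_id[is.na(idx)]), collapse = ", ")))
  }
  cds_pos <- as.integer(cds_pos)
  len <- nchar(transcripts$cds)[idx]
  if (any(is.na(cds_pos)) || any(cds_pos < 1L) || any(cds_pos > len)) {
    abort("cds_pos out of range for its transcript.")
  }
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(ref == alt)) abort("ref and alt must differ.")
  if (any(!ref %in% BASES) || any(!alt %in% BASES)) {
    abort("ref and alt must be single A/C/G/T bases.")
  }

  seq_ref <- substr(transcripts$cds[idx], cds_pos, cds_pos)
  bad <- seq_ref != ref
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0(
      "Reference allele mismatch at ", gene_id[i], ":", cds_pos[i],
      " (CDS has ", seq_ref[i], ", variant claims ", ref[i],
      "); check coordinates/strand."
    ))
  }

  code <- genetic_code(transcripts$codon_table_id[[1]])
  codon_idx <- (cds_pos - 1L) %/% 3L + 1L
  within <- (cds_pos - 1L) %% 3L + 1L
  ref_codon <- substr(transcripts$cds[idx], 3L * codon_idx - 2L, 3L * codon_idx)
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt
  ref_aa <- unname(code[ref_codon])
  alt_aa <- unname(code[alt_codon])

  out <- ifelse(
    ref_aa == alt_aa, "synonymous",
    ifelse(ref_aa == "*", "stop_loss",
      ifelse(alt_aa == "*", "stop_gain", "missense")
    )
  )

  # splice window: within 2 nt of a declared exon boundary overrides the
  # codon-level call
  has_b <- lengths(transcripts$exon_boundaries)[idx] > 0L
  if (any(has_b)) {
    near <- vapply(which(has_b), function(k) {
      b <- transcripts$exon_boundaries[[idx[k]]]
      any(abs(cds_pos[k] - b) <= 2L)
    }, logical(1))
    out[which(has_b)[near]] <- "splice_site"
  }
  out
}

#' Classify a single-nucleotide variant by its codon-level consequence
#'
#' Returns one of `synonymous`, `missense`, `stop_gain`, `stop_loss`, or
#' `splice_site`, by translate-and-compare against the codon table (an
#' amino-acid-changing start-codon variant is therefore `missense`; the
#' `start_loss` label is reserved for pre-annotated input, where it is
#' treated like missense downstream). Positions within 2 nt of a declared exon
#' boundary are `splice_site` regardless of codon effect; if no boundaries
#' were declared for the transcript, splice calls are never computed.
#' A declared `ref` that does not match the CDS is an error (it signals a
#' coordinate or strand problem upstream).
#'
#' @param transcripts A `negsel_transcripts` tibble.
#' @param gene_id,cds_pos,ref,alt Parallel vectors describing the SNVs
#'   (CDS-relative 1-based positions, coding-strand alleles).
#' @return Character vector of consequences.
#' @export
#' @examples
#' tx <- transcript_models(c(G1 = "ATGTGGGGGTAA"))
#' classify_snv(tx, "G1", 5, "G", "A")  # TGG -> TAG: stop_gain
classify_snv <- function(transcripts, gene_id, cds_pos, ref, alt) {
  stopifnot(inherits(transcripts, "negsel_transcripts"))
  classify_snv_impl(transcripts, gene_id, cds_pos, ref, alt)
}

#' Resolve consequences for a variant table
#'
#' Fills the `consequence` column of a variant tibble: rows that already
#' carry a consequence (pre-annotated input) keep it; un-annotated SNVs with
#' a CDS position are classified against the transcripts; indels get
#' `frameshift_indel`/`inframe_indel` from their allele-length difference.
#'
#' @param variants Variant tibble (see [read_maf()] for the schema).
#' @param transcripts A `negsel_transcripts` tibble.
#' @return `variants` with `consequence` filled where resolvable.
#' @export
classify_variants <- function(variants, transcripts) {
  stopifnot(is.data.frame(variants))
  if (!"consequence" %in% names(variants)) variants$consequence <- NA_character_

  need_indel <- is.na(variants$consequence) &
    variants$variant_class %in% c("insertion", "deletion")
  if (any(need_indel)) {
    rl <- nchar(gsub("-", "", variants$ref[need_indel]))
    al <- nchar(gsub("-", "", variants$alt[need_indel]))
    variants$consequence[need_indel] <-
      ifelse(abs(al - rl) %% 3L == 0L, "inframe_indel", "frameshift_indel")
  }

  need_snv <- is.na(variants$consequence) & variants$variant_class == "snv" &
    !is.na(variants$cds_pos) & variants$gene_id %in% transcripts$gene_id
  if (any(need_snv)) {
    variants$consequence[need_snv] <- classify_snv_impl(
      transcripts,
      variants$gene_id[need_snv], variants$cds_pos[need_snv],
      variants$ref[need_snv], variants$alt[need_snv]
    )
  }
  variants
}
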