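# Codon-level utilities shared by site counting, consequence calls and the
# simulator. All work on CDS-relative, 1-based coordinates on the coding
# strand.

BASES <- c("A", "C", "G", "T")

.codon_cache <- new.env(parent = emptyenv())

# Named character vector codon -> amino acid ("*" = stop) for an NCBI
# genetic-code id ("1" = standard).
genetic_code <- function(codon_table_id = "1") {
  key <- as.character(codon_table_id)
  if (is.null(.codon_cache[[key]])) {
    code <- Biostrings::getGeneticCode(key)
    .codon_cache[[key]] <- setNames(as.character(code), names(code))
  }
  .codon_cache[[key]]
}

all_codons <- function() {
  grid <- expand.grid(b1 = BASES, b2 = BASES, b3 = BASES,
                      stringsAsFactors = FALSE)
  paste0(grid$b1, grid$b2, grid$b3)
}

sense_codons <- function(codon_table_id = "1") {
  code <- genetic_code(codon_table_id)
  names(code)[code != "*"]
}

stop_codons <- function(codon_table_id = "1") {
  code <- genetic_code(codon_table_id)
  names(code)[code == "*"]
}

# For every codon, the number of its 9 single-nucleotide neighbours that
# preserve the encoded amino acid (stop -> stop counts as preserving).
# Divided by 3 this is the NG86 synonymous-site count of the codon.
syn_change_counts <- function(codon_table_id = "1") {
  key <- paste0("syn_", codon_table_id)
  if (!is.null(.codon_cache[[key]])) {
    return(.codon_cache[[key]])
  }
  code <- genetic_code(codon_table_id)
  codons <- all_codons()
  counts <- vapply(codons, function(cod) {
    aa <- code[[cod]]
    n_syn <- 0L
    for (pos in 1:3) {
      ref <- substr(cod, pos, pos)
      for (alt in setdiff(BASES, ref)) {
        mut <- cod
        substr(mut, pos, pos) <- alt
        if (code[[mut]] == aa) n_syn <- n_syn + 1L
      }
    }
    n_syn
  }, integer(1))
  .codon_cache[[key]] <- counts
  counts
}

# Split a CDS string into its codon vector.
split_codons <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

mutate_codon <- function(codon, within_pos, alt) {
  substr(codon, within_pos, within_pos) <- alt
  codon
}
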