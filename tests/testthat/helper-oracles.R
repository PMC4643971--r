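# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: translation goes through Biostrings, probabilities
# through explicit combinatorial sums.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_translate <- function(codon) {
  as.character(Biostrings::GENETIC_CODE[[codon]])
}

# enumerate all 9 single-nucleotide changes of every codon of a CDS and
# count the fraction that preserve the amino acid
oracle_site_counts <- function(cds) {
  n <- nchar(cds) / 3
  s_sites <- 0
  for (ci in seq_len(n)) {
    codon <- substr(cds, 3 * ci - 2, 3 * ci)
    aa <- oracle_translate(codon)
    for (pos in 1:3) {
      ref <- substr(codon, pos, pos)
      for (alt in setdiff(ORACLE_BASES, ref)) {
        mut <- codon
        substr(mut, pos, pos) <- alt
        if (oracle_translate(mut) == aa) s_sites <- s_sites + 1 / 3
      }
    }
  }
  list(n_sites = 3 * n - s_sites, s_sites = s_sites)
}

# translate-and-compare consequence for a single codon substitution
oracle_consequence <- function(codon, pos, alt) {
  mut <- codon
  substr(mut, pos, pos) <- alt
  ref_aa <- oracle_translate(codon)
  alt_aa <- oracle_translate(mut)
  if (ref_aa == alt_aa) return("synonymous")
  if (ref_aa == "*") return("stop_loss")
  if (alt_aa == "*") return("stop_gain")
  "missense"
}

# exact upper-tail hypergeometric by explicit summation
oracle_hypergeom <- function(k, K, n, M) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(M - K, n - js)) / choose(M, n)
}

# independent BH step-up: sort, scale by m/i, enforce monotonicity from the
# right, cap at 1, restore input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  scaled <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

random_cds <- function(n_codons, with_stop = TRUE) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  stops <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]
  body <- sample(sense, n_codons - if (with_stop) 1 else 0, replace = TRUE)
  paste(c(body, if (with_stop) sample(stops, 1)), collapse = "")
}
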