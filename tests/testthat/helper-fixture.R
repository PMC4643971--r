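# Hand-checkable six-gene cascade fixture. Every CDS is 30 repeats of the
# codon GGG, so per gene n_sites = 60 and s_sites = 30 and
# omega = n_obs / (2 * s_obs). All missense scores equal 1, so the 70th
# percentile cutoff is exactly 1 and the strict ">" rule makes the score
# route contribute nothing: high-impact variants are exactly the
# deletions. Expected hand calculation (config: min_variants = 5,
# dnds_threshold = 0.25, expression_quantile = 0.2, percentile 0.7):
#
# gene somatic            germline          omega  expr  f_som f_1KG  flags
# G1   6 syn + 2 mis      4 syn+2 mis+2 del 0.167  50    0     0.25   TTTT -> essential
# G2   2 syn + 1 mis      3 syn + 3 mis     (na)   10    -     -      F... (3 < 5 variants)
# G3   5 syn + 5 mis      4 syn+2 mis+2 del 0.5    20    0     0.25   TFTT
# G4   6 syn + 2 mis      4 syn+2 mis+2 del 0.167  1     0     0.25   TTFT (lowest 20%)
# G5   6 syn + 2 mis      8 syn             0.167  30    0     0      TTTF (tie 0 = 0)
# G6   6 mis, 0 syn       4 syn + 4 mis     undef  40    0     0      TFTF
#
# Expression means [50, 10, 20, 1, 30, 40]: 20th-percentile cutoff
# (type 7) is 10, so G4 (1) and G2 (10, not > 10) fail; only G4 matters.

fixture_transcripts <- function() {
  cds <- paste(rep("GGG", 30), collapse = "")
  transcript_models(setNames(rep(cds, 6), paste0("G", 1:6)))
}

fixture_variants <- function(gene, cohort, n_syn = 0, n_mis = 0, n_del = 0) {
  n <- n_syn + n_mis + n_del
  tibble::tibble(
    cohort = cohort,
    gene_id = gene,
    cds_pos = seq_len(n) * 3L,
    ref = c(rep("G", n_syn + n_mis), rep("G", n_del)),
    alt = c(rep("A", n_syn + n_mis), rep("-", n_del)),
    variant_class = c(rep("snv", n_syn + n_mis), rep("deletion", n_del)),
    consequence = c(rep("synonymous", n_syn), rep("missense", n_mis),
                    rep("frameshift_indel", n_del)),
    score_a = c(rep(NA_real_, n_syn), rep(1, n_mis), rep(NA_real_, n_del)),
    score_b = c(rep(NA_real_, n_syn), rep(1, n_mis), rep(NA_real_, n_del))
  )
}

fixture_somatic <- function() {
  dplyr::bind_rows(
    fixture_variants("G1", "somatic", n_syn = 6, n_mis = 2),
    fixture_variants("G2", "somatic", n_syn = 2, n_mis = 1),
    fixture_variants("G3", "somatic", n_syn = 5, n_mis = 5),
    fixture_variants("G4", "somatic", n_syn = 6, n_mis = 2),
    fixture_variants("G5", "somatic", n_syn = 6, n_mis = 2),
    fixture_variants("G6", "somatic", n_mis = 6)
  )
}

fixture_germline <- function() {
  dplyr::bind_rows(
    fixture_variants("G1", "germline", n_syn = 4, n_mis = 2, n_del = 2),
    fixture_variants("G2", "germline", n_syn = 3, n_mis = 3),
    fixture_variants("G3", "germline", n_syn = 4, n_mis = 2, n_del = 2),
    fixture_variants("G4", "germline", n_syn = 4, n_mis = 2, n_del = 2),
    fixture_variants("G5", "germline", n_syn = 8),
    fixture_variants("G6", "germline", n_syn = 4, n_mis = 4)
  )
}

fixture_expression <- function() {
  tibble::tibble(
    gene_id = paste0("G", 1:6),
    S001 = c(50, 10, 20, 1, 30, 40)
  )
}

fixture_config <- function() {
  pipeline_config(min_variants = 5, dnds_threshold = 0.25,
                  expression_quantile = 0.2, impact_percentile = 0.7)
}

run_fixture_scan <- function() {
  run_selection(fixture_somatic(), fixture_germline(),
                fixture_transcripts(), fixture_expression(),
                config = fixture_config())
}
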