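# Fully controlled synthetic study generator. Every pipeline input (CDS,
# two variant cohorts, impact scores, expression, gene sets, interaction
# edges) is simulated with known ground truth so each stage is testable
# without external downloads.

#' Simulation configuration
#'
#' Defines the synthetic study conditions. Defaults plant 5% of genes as
#' "essential" (somatic omega 0.1 versus 1.0 background; germline is
#' neutral for every gene), with per-gene variant counts Poisson(40)
#' somatic and Poisson(60) germline, CDS lengths of 150-250 codons, a 4%
#' indel and 1% splice-site admixture (scaled down by omega in the somatic
#' cohort: purifying selection removes high-impact classes too), impact
#' scores drawn per site from overlapping damaging/benign normals (the
#' 70th-percentile rule is imperfect by design), and log-normal expression
#' in which essential genes are always expressed while 20% of background
#' genes sit in a near-zero component.
#'
#' @param n_genes Number of genes.
#' @param n_samples Expression samples.
#' @param cds_length_range Codon-count range (inclusive).
#' @param prop_essential Fraction of genes planted essential.
#' @param omega_essential,omega_background Somatic dN/dS used for
#'   acceptance sampling per gene class.
#' @param somatic_mean,germline_mean Poisson means of per-gene variant
#'   counts.
#' @param p_indel,p_splice Per-variant probabilities of indel and
#'   (pre-annotated) splice-site classes, before omega scaling.
#' @param p_damaging Intrinsic probability that a missense site is
#'   damaging.
#' @param score_mean_damaging,score_mean_benign,score_sd Score-channel
#'   normal components; both channels share the site's class mean, which
#'   induces their correlation.
#' @param expr_meanlog_essential,expr_meanlog_background,expr_meanlog_low,
#'   expr_sdlog Log-normal expression parameters.
#' @param low_expr_fraction Fraction of background genes drawn from the
#'   near-zero expression component.
#' @param random_seed Seed; a fixed seed reproduces the full study.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L,
                       n_samples = 40L,
                       cds_length_range = c(150L, 250L),
                       prop_essential = 0.05,
                       omega_essential = 0.1,
                       omega_background = 1.0,
                       somatic_mean = 40,
                       germline_mean = 60,
                       p_indel = 0.04,
                       p_splice = 0.01,
                       p_damaging = 0.35,
                       score_mean_damaging = 1.5,
                       score_mean_benign = -0.5,
                       score_sd = 1,
                       expr_meanlog_essential = 6,
                       expr_meanlog_background = 5,
                       expr_meanlog_low = 0,
                       expr_sdlog = 1,
                       low_expr_fraction = 0.2,
                       random_seed = 1L) {
  stopifnot(
    n_genes >= 1, n_samples >= 1,
    length(cds_length_range) == 2L, cds_length_range[1] >= 2L,
    cds_length_range[2] >= cds_length_range[1],
    prop_essential >= 0, prop_essential <= 1,
    omega_essential >= 0, omega_background >= 0,
    somatic_mean >= 0, germline_mean >= 0,
    p_indel >= 0, p_splice >= 0, p_indel + p_splice <= 1,
    p_damaging >= 0, p_damaging <= 1,
    low_expr_fraction >= 0, low_expr_fraction <= 1
  )
  structure(
    list(
      n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
      cds_length_range = as.integer(cds_length_range),
      prop_essential = prop_essential,
      omega_essential = omega_essential,
      omega_background = omega_background,
      somatic_mean = somatic_mean, germline_mean = germline_mean,
      p_indel = p_indel, p_splice = p_splice, p_damaging = p_damaging,
      score_mean_damaging = score_mean_damaging,
      score_mean_benign = score_mean_benign, score_sd = score_sd,
      expr_meanlog_essential = expr_meanlog_essential,
      expr_meanlog_background = expr_meanlog_background,
      expr_meanlog_low = expr_meanlog_low, expr_sdlog = expr_sdlog,
      low_expr_fraction = low_expr_fraction,
      random_seed = as.integer(random_seed)
    ),
    class = "sim_config"
  )
}

#' Simulate coding sequences
#'
#' Random sense-codon sequences: an ATG start, internal codons drawn
#' uniformly from the 61 sense codons, and a terminal stop; lengths uniform
#' over `cds_length_range` (in codons). Draws from the current RNG state;
#' call `set.seed()` (or use [simulate_study()]) for reproducibility.
#'
#' @param cfg A [sim_config()].
#' @return A `negsel_transcripts` tibble with genes `SG0001`, ...
#' @export
simulate_cds <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sense <- sense_codons()
  stops <- stop_codons()
  len_choices <- seq(cfg$cds_length_range[1], cfg$cds_length_range[2])
  lens <- len_choices[sample.int(length(len_choices), cfg$n_genes,
                                 replace = TRUE)]
  seqs <- vapply(lens, function(L) {
    paste0("ATG",
           paste(sample(sense, L - 2L, replace = TRUE), collapse = ""),
           sample(stops, 1L))
  }, character(1))
  names(seqs) <- sprintf("SG%04d", seq_len(cfg$n_genes))
  transcript_models(seqs)
}

# Plant gene classes and per-cohort omegas.
plant_truth <- function(transcripts, cfg) {
  n <- nrow(transcripts)
  n_ess <- round(cfg$prop_essential * n)
  ess <- sample(transcripts$gene_id, n_ess)
  tibble(
    gene_id = transcripts$gene_id,
    class = ifelse(transcripts$gene_id %in% ess, "essential", "background"),
    omega_somatic = ifelse(transcripts$gene_id %in% ess,
                           cfg$omega_essential, cfg$omega_background),
    omega_germline = 1.0
  )
}

# Acceptance-sampled SNVs for all genes at once: propose a uniform CDS
# position and uniform alternate base, classify, accept synonymous changes
# always and non-synonymous ones with probability omega. Matches the NG86
# counting model by construction.
sample_snvs <- function(transcripts, n_snv, omega) {
  total <- sum(n_snv)
  if (total == 0L) {
    return(tibble(gene_id = character(), cds_pos = integer(),
                  ref = character(), alt = character(),
                  consequence = character()))
  }
  lens <- nchar(transcripts$cds)
  # row = ref base, column = which of its 3 alternates
  alt_lookup <- t(vapply(BASES, function(b) setdiff(BASES, b),
                         character(3)))
  acc <- list()
  remaining <- n_snv
  round_i <- 0L
  while (sum(remaining) > 0L && round_i < 50L) {
    round_i <- round_i + 1L
    p_acc <- pmax(0.15, 0.2 + 0.8 * omega)
    n_prop <- ifelse(remaining > 0L, ceiling(remaining / p_acc) + 5L, 0L)
    gi <- rep(seq_len(nrow(transcripts)), n_prop)
    pos <- 1L + as.integer(floor(runif(length(gi)) * lens[gi]))
    ref <- substr(transcripts$cds[gi], pos, pos)
    alt_choice <- 1L + as.integer(floor(runif(length(gi)) * 3))
    alt <- alt_lookup[cbind(match(ref, BASES), alt_choice)]
    cons <- classify_snv_impl(transcripts, transcripts$gene_id[gi],
                              pos, ref, alt)
    keep <- cons == "synonymous" | runif(length(gi)) < omega[gi]
    df <- tibble(
      .gi = gi[keep], gene_id = transcripts$gene_id[gi][keep],
      cds_pos = pos[keep], ref = ref[keep], alt = alt[keep],
      consequence = cons[keep]
    )
    # take at most the still-needed number per gene
    df <- df |>
      dplyr::group_by(.data$.gi) |>
      dplyr::mutate(.k = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$.k <= remaining[.data$.gi])
    taken <- tabulate(df$.gi, nbins = length(remaining))
    remaining <- remaining - taken
    acc[[round_i]] <- dplyr::select(df, -".k", -".gi")
  }
  if (sum(remaining) > 0L) {
    abort("Acceptance sampling failed to reach the requested variant counts.")
  }
  dplyr::bind_rows(acc)
}

#' Simulate one variant cohort with controlled per-gene dN/dS
#'
#' SNVs are produced by acceptance sampling (see [sim_config()]): a uniform
#' CDS position and alternate base are proposed, classified against the
#' transcript, and accepted always if synonymous, with probability equal to
#' the gene's omega if non-synonymous. Indel and pre-annotated splice-site
#' variants are admixed with probabilities scaled by the gene's omega
#' (high-impact classes are purged along with non-synonymous SNVs).
#' The construction makes the expected observed dN/dS equal the planted
#' omega under NG86 counting; this property is verified by tests, not
#' assumed. Only acceptance sampling toward omega <= 1 is supported.
#'
#' @param transcripts Simulated transcripts from [simulate_cds()].
#' @param truth Ground-truth tibble from [simulate_study()] (or built the
#'   same way), with `gene_id`, `omega_somatic`, `omega_germline`.
#' @param cfg A [sim_config()].
#' @param cohort `"somatic"` or `"germline"`.
#' @param score_variants Draw impact scores for missense sites (disable to
#'   assign scores jointly across cohorts, as [simulate_study()] does).
#' @return Canonical variant tibble with a provenance attribute.
#' @export
simulate_cohort <- function(transcripts, truth, cfg,
                            cohort = c("somatic", "germline"),
                            score_variants = TRUE) {
  cohort <- match.arg(cohort)
  stopifnot(inherits(cfg, "sim_config"),
            inherits(transcripts, "negsel_transcripts"))
  truth <- truth[match(transcripts$gene_id, truth$gene_id), ]
  omega <- if (cohort == "somatic") truth$omega_somatic else truth$omega_germline
  if (any(omega > 1)) {
    abort("Acceptance sampling supports omega <= 1 only.")
  }
  mean_n <- if (cohort == "somatic") cfg$somatic_mean else cfg$germline_mean

  n_total <- rpois(nrow(transcripts), mean_n)
  # omega-scaled high-impact admixture
  p_ind <- cfg$p_indel * omega
  p_spl <- cfg$p_splice * omega
  n_indel <- rbinom(length(n_total), n_total, p_ind)
  n_splice <- rbinom(length(n_total), n_total - n_indel,
                     ifelse(p_ind < 1, p_spl / (1 - p_ind), 0))
  n_snv <- n_total - n_indel - n_splice

  snvs <- sample_snvs(transcripts, n_snv, omega)
  snvs$variant_class <- "snv"

  lens <- nchar(transcripts$cds)
  make_extra <- function(counts, maker) {
    gi <- rep(seq_along(counts), counts)
    if (length(gi) == 0L) {
      return(tibble(gene_id = character(), cds_pos = integer(),
                    ref = character(), alt = character(),
                    consequence = character(), variant_class = character()))
    }
    maker(gi)
  }
  splices <- make_extra(n_splice, function(gi) {
    pos <- 1L + as.integer(floor(runif(length(gi)) * lens[gi]))
    ref <- substr(transcripts$cds[gi], pos, pos)
    alt <- vapply(seq_along(gi), function(i) {
      sample(setdiff(BASES, ref[i]), 1L)
    }, character(1))
    tibble(gene_id = transcripts$gene_id[gi], cds_pos = pos, ref = ref,
           alt = alt, consequence = "splice_site", variant_class = "snv")
  })
  indels <- make_extra(n_indel, function(gi) {
    # positions >= 2 so a VCF anchor base always exists upstream
    pos <- 2L + as.integer(floor(runif(length(gi)) * (lens[gi] - 4L)))
    is_del <- runif(length(gi)) < 0.5
    inframe <- runif(length(gi)) < 0.2
    width <- ifelse(inframe, 3L, 1L)
    ref <- ifelse(is_del,
                  substr(transcripts$cds[gi], pos, pos + width - 1L), "-")
    rand_bases <- vapply(width, function(w) {
      paste(sample(BASES, w, replace = TRUE), collapse = "")
    }, character(1))
    alt <- ifelse(is_del, "-", rand_bases)
    tibble(
      gene_id = transcripts$gene_id[gi], cds_pos = pos, ref = ref, alt = alt,
      consequence = ifelse(inframe, "inframe_indel", "frameshift_indel"),
      variant_class = ifelse(is_del, "deletion", "insertion")
    )
  })

  out <- dplyr::bind_rows(snvs, splices, indels) |>
    dplyr::mutate(cohort = cohort, score_a = NA_real_, score_b = NA_real_) |>
    dplyr::arrange(.data$gene_id, .data$cds_pos, .data$ref, .data$alt)
  out <- out[, VARIANT_COLS]
  if (score_variants) {
    scored <- assign_site_scores(out, cfg)
    out <- scored$variants
  }
  new_cohort_table(out, cohort, paste0("simulate_cohort(", cohort, ")"),
                   nrow(out), 0L)
}

# Draw damaging status and the two score channels once per unique missense
# site, so the same site always carries the same scores (across cohorts
# too, when called on their combined rows). Returns the scored variant
# rows and the site-keyed score table.
assign_site_scores <- function(variants, cfg) {
  scoreable <- variants$variant_class == "snv" &
    !is.na(variants$consequence) &
    variants$consequence %in% c("missense", "start_loss")
  sites <- variants[scoreable, c("gene_id", "cds_pos", "ref", "alt")] |>
    dplyr::distinct() |>
    dplyr::arrange(.data$gene_id, .data$cds_pos, .data$ref, .data$alt)
  if (nrow(sites) > 0L) {
    dam <- runif(nrow(sites)) < cfg$p_damaging
    mu <- ifelse(dam, cfg$score_mean_damaging, cfg$score_mean_benign)
    sites$damaging <- dam
    sites$score_a <- mu + rnorm(nrow(sites), sd = cfg$score_sd)
    sites$score_b <- mu + rnorm(nrow(sites), sd = cfg$score_sd)
  } else {
    sites$damaging <- logical(0)
    sites$score_a <- double(0)
    sites$score_b <- double(0)
  }
  joined <- variants |>
    dplyr::select(-"score_a", -"score_b") |>
    dplyr::left_join(
      dplyr::select(sites, -"damaging"),
      by = c("gene_id", "cds_pos", "ref", "alt")
    )
  # synonymous SNVs sharing a site key with nothing keep NA scores; make
  # sure non-scoreable rows stay unscored even on key collisions
  joined$score_a[!scoreable] <- NA_real_
  joined$score_b[!scoreable] <- NA_real_
  list(variants = joined[, VARIANT_COLS], sites = sites)
}

#' Simulate a gene-by-sample expression matrix
#'
#' Log-normal expression; essential genes draw from the expressed
#' component, background genes from the near-zero component with
#' probability `low_expr_fraction` (so the lowest-20% filter has real
#' effect), otherwise from the expressed component.
#'
#' @param truth Ground-truth tibble (`gene_id`, `class`).
#' @param cfg A [sim_config()].
#' @return A tibble: `gene_id` plus `n_samples` numeric sample columns.
#' @export
simulate_expression <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(truth)
  low <- truth$class == "background" & runif(n) < cfg$low_expr_fraction
  meanlog <- ifelse(truth$class == "essential", cfg$expr_meanlog_essential,
                    ifelse(low, cfg$expr_meanlog_low,
                           cfg$expr_meanlog_background))
  mat <- matrix(
    rlnorm(n * cfg$n_samples, meanlog = rep(meanlog, cfg$n_samples),
           sdlog = cfg$expr_sdlog),
    nrow = n
  )
  colnames(mat) <- sprintf("S%03d", seq_len(cfg$n_samples))
  dplyr::bind_cols(tibble(gene_id = truth$gene_id), as_tibble(mat))
}

#' Simulate gene-set collections
#'
#' Random sets drawn from the gene universe across two mock collection
#' sources, plus (optionally) one planted set concentrating the essential
#' genes, so over-representation analysis has a recoverable signal.
#'
#' @param truth Ground-truth tibble.
#' @param n_sets Number of random sets.
#' @param set_size_range Uniform range of set sizes.
#' @param planted Add the `ESSENTIAL_MODULE` set.
#' @return A gene-set tibble in the [read_gmt()] layout.
#' @export
simulate_gene_sets <- function(truth, n_sets = 15L,
                               set_size_range = c(10L, 50L),
                               planted = TRUE) {
  genes <- truth$gene_id
  sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                  replace = TRUE)
  sets <- tibble(
    set = sprintf("RANDOM_SET_%02d", seq_len(n_sets)),
    source = rep(c("GO_sim", "KEGG_sim"), length.out = n_sets),
    description = "random set",
    genes = lapply(sizes, function(s) sample(genes, min(s, length(genes))))
  )
  if (planted) {
    ess <- truth$gene_id[truth$class == "essential"]
    module <- unique(c(ess, sample(genes, max(5L, length(ess) %/% 4L))))
    sets <- dplyr::bind_rows(
      tibble(set = "ESSENTIAL_MODULE", source = "GO_sim",
             description = "planted essential module",
             genes = list(module)),
      sets
    )
  }
  sets
}

#' Simulate a protein-interaction edge table
#'
#' Random background edges with uniform scores, plus a planted
#' high-confidence module: the first few essential genes are wired to a
#' shared set of partner proteins (and to each other, flagged physical)
#' with scores above 0.9, so bait/prey summaries have known structure.
#'
#' @param truth Ground-truth tibble.
#' @param n_edges Background edge count.
#' @param n_hub_baits,n_hub_partners Planted module dimensions.
#' @return An edge tibble (`protein_a`, `protein_b`, `combined_score`,
#'   `physical`).
#' @export
simulate_edges <- function(truth, n_edges = 1500L, n_hub_baits = 4L,
                           n_hub_partners = 8L) {
  genes <- truth$gene_id
  a <- sample(genes, n_edges, replace = TRUE)
  b <- sample(genes, n_edges, replace = TRUE)
  keep <- a != b
  bg <- tibble(
    protein_a = a[keep], protein_b = b[keep],
    combined_score = runif(sum(keep)),
    physical = FALSE
  )
  ess <- truth$gene_id[truth$class == "essential"]
  hub <- tibble(protein_a = character(), protein_b = character(),
                combined_score = double(), physical = logical())
  if (length(ess) >= 2L) {
    baits <- head(sort(ess), n_hub_baits)
    partners <- sprintf("PARTNER_%02d", seq_len(n_hub_partners))
    hub <- dplyr::bind_rows(
      tidyr::expand_grid(protein_a = baits, protein_b = partners) |>
        dplyr::mutate(combined_score = runif(dplyr::n(), 0.92, 0.99),
                      physical = FALSE),
      tibble(protein_a = baits[1], protein_b = baits[2],
             combined_score = 0.95, physical = TRUE)
    )
  }
  normalize_edges(dplyr::bind_rows(bg, hub))
}

#' Simulate a complete synthetic study
#'
#' Generates every pipeline input under one seed: transcripts, ground
#' truth, somatic and germline cohorts (scores assigned jointly so a site
#' carries the same scores in both cohorts), the site-keyed score table,
#' expression, gene sets, interaction edges, and a genomic [cds_map()]
#' placing each gene's CDS on its own contig (plus strand, CDS starting at
#' genomic position 101).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `negsel_study` with elements `transcripts`,
#'   `truth`, `somatic`, `germline`, `scores`, `expression`, `gene_sets`,
#'   `edges`, `cds_map`, `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$random_seed)
  transcripts <- simulate_cds(cfg)
  truth <- plant_truth(transcripts, cfg)
  somatic <- simulate_cohort(transcripts, truth, cfg, "somatic",
                             score_variants = FALSE)
  germline <- simulate_cohort(transcripts, truth, cfg, "germline",
                              score_variants = FALSE)

  prov_s <- attr(somatic, "provenance")
  prov_g <- attr(germline, "provenance")
  both <- dplyr::bind_rows(somatic, germline)
  scored <- assign_site_scores(both, cfg)
  is_som <- scored$variants$cohort == "somatic"
  somatic <- new_cohort_table(scored$variants[is_som, ], "somatic",
                              prov_s$source, sum(is_som), 0L)
  germline <- new_cohort_table(scored$variants[!is_som, ], "germline",
                               prov_g$source, sum(!is_som), 0L)

  expression <- simulate_expression(truth, cfg)
  gene_sets <- simulate_gene_sets(truth)
  edges <- simulate_edges(truth)
  map <- cds_map(
    gene_id = transcripts$gene_id,
    chrom = transcripts$gene_id,
    strand = "+",
    start = 101L,
    end = 100L + nchar(transcripts$cds),
    cds_start = 1L
  )
  structure(
    list(transcripts = transcripts, truth = truth, somatic = somatic,
         germline = germline,
         scores = dplyr::select(scored$sites, -"damaging"),
         expression = expression, gene_sets = gene_sets, edges = edges,
         cds_map = map, config = cfg),
    class = "negsel_study"
  )
}

#' Write a simulated study in the pipeline's input file formats
#'
#' Emits `cds.fasta`, `somatic.maf.tsv` (MAF dialect), `germline.vcf`,
#' `scores.tsv`, `expression.tsv`, `gene_sets.gmt`, `edges.tsv`,
#' `cds_map.tsv`, and the `ground_truth.tsv` sidecar (never read by the
#' pipeline).
#'
#' @param study A `negsel_study` list from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "negsel_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    cds = file.path(dir, "cds.fasta"),
    maf = file.path(dir, "somatic.maf.tsv"),
    vcf = file.path(dir, "germline.vcf"),
    scores = file.path(dir, "scores.tsv"),
    expression = file.path(dir, "expression.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    edges = file.path(dir, "edges.tsv"),
    cds_map = file.path(dir, "cds_map.tsv"),
    truth = file.path(dir, "ground_truth.tsv")
  )

  seqs <- Biostrings::DNAStringSet(
    setNames(study$transcripts$cds, study$transcripts$gene_id)
  )
  Biostrings::writeXStringSet(seqs, paths[["cds"]])

  maf <- tibble(
    Hugo_Symbol = study$somatic$gene_id,
    Variant_Classification = names(MAF_CONSEQUENCE_MAP)[
      match(study$somatic$consequence, MAF_CONSEQUENCE_MAP)
    ],
    Variant_Type = c(snv = "SNP", insertion = "INS", deletion = "DEL")[
      study$somatic$variant_class
    ],
    Reference_Allele = study$somatic$ref,
    Tumor_Seq_Allele2 = study$somatic$alt,
    CDS_Position = study$somatic$cds_pos
  )
  readr::write_tsv(maf, paths[["maf"]])

  write_vcf_cohort(study$germline, study$cds_map, study$transcripts,
                   paths[["vcf"]])
  readr::write_tsv(study$scores, paths[["scores"]])
  readr::write_tsv(study$expression, paths[["expression"]])
  write_gmt(study$gene_sets, paths[["gmt"]])
  readr::write_tsv(study$edges, paths[["edges"]])
  readr::write_tsv(study$cds_map, paths[["cds_map"]])
  readr::write_tsv(study$truth, paths[["truth"]])
  invisible(paths)
}

# Minimal VCF 4.2 writer for simulated germline calls on plus-strand
# single-exon contigs. Indels are written with the upstream anchor base.
write_vcf_cohort <- function(variants, map, transcripts, path) {
  m <- map[match(variants$gene_id, map$gene_id), ]
  stopifnot(all(m$strand == "+"))
  tx <- transcripts$cds[match(variants$gene_id, transcripts$gene_id)]

  pos <- m$start + variants$cds_pos - m$cds_start
  ref <- variants$ref
  alt <- variants$alt
  is_ins <- variants$variant_class == "insertion"
  is_del <- variants$variant_class == "deletion"
  anchor <- substr(tx, variants$cds_pos - 1L, variants$cds_pos - 1L)
  # deletions: anchor + deleted bases; insertions: anchor then inserted bases
  ref[is_del] <- paste0(anchor[is_del], variants$ref[is_del])
  alt[is_del] <- anchor[is_del]
  ref[is_ins] <- anchor[is_ins]
  alt[is_ins] <- paste0(anchor[is_ins], variants$alt[is_ins])
  pos[is_del | is_ins] <- pos[is_del | is_ins] - 1L

  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene id">',
    '##INFO=<ID=CDSPOS,Number=1,Type=Integer,Description="CDS position">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  body <- paste(
    m$chrom, pos, ".", ref, alt, ".", "PASS",
    paste0("GENE=", variants$gene_id, ";CDSPOS=", variants$cds_pos),
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}
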