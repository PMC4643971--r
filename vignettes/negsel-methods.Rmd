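---
title: "Methods: detecting proteins under negative selection in tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting proteins under negative selection in tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negsel)
```

## The model

`negsel` screens protein-coding genes for purifying (negative) selection
in tumor somatic mutation data. The underlying population-genetic logic:
synonymous substitutions are treated as selectively (near-)neutral
markers of the local mutation process, so the per-site non-synonymous
rate divided by the per-site synonymous rate,

$$\omega = \frac{n_{obs}/N}{s_{obs}/S},$$

estimates the fraction of amino-acid-changing mutations that survive
selection in the expanding tumor cell population. $\omega \approx 1$ is
neutrality, $\omega < 1$ purifying selection.

### Site counting

$N$ and $S$ are *expected* site counts in the Nei–Gojobori (1986) sense,
unweighted: every codon position contributes, out of its three possible
single-nucleotide changes, the fraction preserving the amino acid to $S$
and the remainder to $N$. Two consequences of this definition matter:

* Conservation is exact: $N + S = 3 \times (\text{codon count})$ for
  every CDS, and the test suite asserts this as an identity, not within
  a tolerance.
* Changes creating a stop codon from a sense codon occupy
  *non-synonymous* sites. For consistency, the default numerator
  $n_{obs}$ therefore counts **all** non-synonymous SNVs — missense and
  stop gain/loss alike. Counting missense only while keeping
  stop-creating changes in $N$ (a combination one sometimes sees) makes
  even a perfectly neutral process register $\omega \approx 0.95$,
  because roughly 23 of the 438 non-synonymous single-nucleotide changes
  among sense codons are nonsense changes whose observations would be
  discarded while their sites are not. The package exposes
  `estimate_dnds(..., numerator = "missense")` for comparison, but the
  default keeps numerator and denominator on the same footing, and the
  neutral-recovery property test (pooled $\omega \to 1$ under uniform
  mutation) holds only under that default. Splice-site SNVs and indels
  enter neither count: they have no site-model counterpart.

No mutation-spectrum weighting is applied; the counting is deliberately
the reproducible, unweighted NG86 variant. A spectrum-aware weighting
would change $N/S$ by a gene-specific factor but requires a trusted
context model, which is out of scope here.

### Definedness, pseudocounts, recurrences

A gene with $s_{obs} = 0$ has undefined $\omega$ and can never pass the
threshold filter — a conservative choice preferred over pseudocounts,
whose magnitude would dominate exactly in the low-count genes the
support filter is meant to protect. Each variant record counts once:
recurrent identical mutations across samples are repeated observations
of selection's tolerance at that site (`distinct_sites = TRUE`
collapses them for sensitivity analyses).

### The threshold

The default threshold is $\omega < 0.25$ (strict). In `"auto"` mode the
package histograms defined per-gene omegas (left-closed bins of width
0.05 on $[0, 2]$) and takes the center of the lowest interior
local-minimum bin within $[0.05, 0.75]$ — the dip between the purifying
mode near zero and the neutral mode near one. Detection is on the raw
histogram, not a smoothed density, for determinism. A *plateau* of equal
counts flanked by strictly larger neighbours counts as one minimum and
resolves to its leftmost bin (ties break toward smaller $\omega$); if no
interior minimum exists the fallback 0.25 is returned with a warning.
Bins at the histogram edge are never minima (no outer neighbour).

## The impact-fraction filter

High-impact status is categorical for insertions/deletions, stop
gain/loss and splice-site variants, and score-based for non-synonymous
SNVs: strictly greater than the 70th percentile (linear-interpolation
empirical quantile, R type 7) of either of the two ensemble score
channels. Synonymous SNVs are never high-impact, and unscored
non-synonymous SNVs are conservatively treated as not high-impact. Per
gene and cohort $f = n_{high}/n_{total}$ with *all* variants in the
denominator, and the depletion filter is the strict comparison
$f_{germline} > f_{somatic}$ — ties fail, in keeping with the strictness
of every other cutoff in the cascade.

The percentile population defaults to the two cohorts pooled. Pooling
keeps a single pair of cutoffs for the $f$ comparison in both cohorts;
per-cohort cutoffs (supported via `percentile_population =
"per_cohort"`) would let a cohort's own score distribution shift its
cutoff and silently bias the comparison. Cutoffs are derived from the
full pooled cohorts, not only from support-passing genes, so relaxing
the support filter cannot move them (this preserves the monotonicity
property below).

## The cascade

Four conjunctive filters define an essential call: variant support
$\ge$ 11 in *both* cohorts (all variant classes count, matching the $f$
denominator), defined $\omega$ strictly below the threshold, mean
expression strictly above the empirical 20% quantile of gene means, and
the depletion test. Since the filters are conjunctive, their order only
affects logging; all four verdicts are reported for every gene present
in both cohorts. Genes below the support threshold get no $\omega$ or
$f$ (insufficient data); genes absent from the expression matrix fail
the expression filter with a warning (what is unmeasured cannot be
called expressed). The expression rule compares each gene's mean to the
type-7 empirical quantile of all gene means; with quantile 0 nothing is
removed. The kept gene set doubles as the enrichment universe.

A useful sanity property, covered by tests: relaxing any single
threshold (larger $\omega$ cutoff, smaller support minimum, smaller
expression quantile) can only grow the essential set.

## Enrichment and network summaries

Over-representation uses the exact upper-tail hypergeometric probability
$P[X \ge k]$ (via `stats::phyper`; tests cross-check an explicit
combinatorial enumeration to $10^{-12}$), with set members intersected
with the universe first and $K = 0$ sets skipped. Benjamini–Hochberg
correction (`stats::p.adjust`) is applied within each collection source
by default, mirroring per-category reporting; a global mode exists. Only
the over-representation tail is tested — depletion of a set is not a
question this pipeline asks.

Interaction edges are undirected with canonical ordering; duplicates
keep the maximum score, and the milli scale (STRING's integer
convention) divides by 1000. The bait summary keeps edges with score
strictly greater than 0.9, reports each bait's degree (self-loops
excluded; baits may be each other's preys), common-partner counts per
bait pair, and direct physical links; zero-prey baits move to a sidecar
rather than cluttering the main table.

## The synthetic study generator

The simulator emulates the full input suite of a tumor-vs-germline
scan: CDS sequences (ATG start, 61-sense-codon body, terminal stop),
two variant cohorts, per-site impact scores, a log-normal expression
matrix, gene sets with one planted module, and an interaction table
with a planted high-confidence hub.

**Omega control by acceptance sampling.** A proposed SNV (uniform CDS
position, uniform alternate base) is classified against the transcript
and accepted always if synonymous, with probability equal to the gene's
planted $\omega$ if non-synonymous. This matches the NG86 counting model
by construction, so the expected *observed* dN/dS equals the planted
value — a property the tests verify rather than assume (pooled recovery
within 5% at $\sim$10,000 SNVs). Only $\omega \le 1$ is supported this
way; simulating positive selection would require rejecting synonymous
proposals instead, which is out of scope.

**Default study conditions** (fixed in `sim_config()`): 500 genes of
150–250 codons, 5% planted essential with somatic $\omega = 0.1$
(background 1.0; germline neutral for every gene), Poisson(40) somatic
and Poisson(60) germline variants per gene, 4% indel and 1%
splice-site admixture scaled by the gene's somatic $\omega$ (purifying
selection removes high-impact classes along with non-synonymous SNVs),
and 40 expression samples. The per-gene counts are desk-scale versions
of the per-gene averages implied by large public somatic and germline
callsets (on the order of 12 and 26 variants per gene), raised moderately
so that the $\ge$11-in-both-cohorts rule and per-gene $\omega$ estimates
are informative at 500 genes.

**Scores are site properties.** Each missense site is intrinsically
damaging with probability 0.35; damaging sites draw both score channels
around mean 1.5, benign around $-0.5$ (SD 1, the shared class mean
inducing the channel correlation). A site therefore carries identical
scores wherever it recurs — including across cohorts — which mirrors how
precomputed impact databases work and keeps the emitted score table free
of conflicting keys. The overlap between the two score distributions
makes the 70th-percentile rule deliberately imperfect, like a real
classifier. Crucially, the somatic high-impact depletion of essential
genes is *emergent*, not painted on: acceptance sampling shifts their
somatic variant composition toward synonymous (never high-impact)
variants and suppresses indels, stop gains and splice variants, so
$f_{somatic}$ falls while $f_{germline}$ stays at baseline.

**Expression.** Essential genes draw log-normal expression with meanlog
6; background genes with meanlog 5, except a 20% near-zero component
(meanlog 0) that gives the lowest-20% filter something real to remove.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: mutational signatures and
trinucleotide context (UV signatures make real somatic spectra highly
non-uniform, which NG86 unweighted counting does not correct),
sample-level clonal structure, copy-number events, multi-isoform
transcripts, mapping/calling artifacts, and the ascertainment quirks of
real germline panels. The pipeline's statistical machinery is validated
here; its biological conclusions on real cohorts inherit all the usual
caveats of those inputs.

## Numerical and interface choices

* Coordinates are CDS-relative, 1-based, coding strand. Genomic
  lift-over happens at VCF ingestion via an exon-level map (both
  strands, minus-strand alleles reverse-complemented); indels are taken
  as keyed, without left-alignment.
* The splice window is $\pm 2$ nt around a declared exon boundary,
  mirroring canonical donor/acceptor dinucleotides; without declared
  boundaries splice calls only ever come from pre-annotated input.
* A declared reference allele that contradicts the CDS is an error, not
  a silent skip — it almost always signals a coordinate or strand bug
  upstream.
* Consequence calls are translate-and-compare: an amino-acid-changing
  start-codon SNV is missense (the `start_loss` label is accepted from
  pre-annotated input and treated as missense for impact purposes).
  Terminal-stop changes are `stop_loss` when they destroy the stop,
  synonymous when stop maps to stop.
* Histogram binning is left-closed; a value exactly on an edge belongs
  to the bin starting there, and values at or beyond the upper range
  limit are excluded.
* Empty results are findings: a scan with zero essential genes still
  writes its full report and manifest. The manifest carries no
  timestamps or absolute paths, so identical seed and config produce
  byte-identical output bundles.

## Problem sizes used in validation

The test suite validates site counting against brute-force enumeration
on 1,000 random CDS (150 of them enumerated exhaustively), all 549
sense-codon single-nucleotide changes, dN/dS recovery on 50-gene /
$\sim$10,000-SNV cohorts, the full cascade on the 500-gene default
study, hypergeometric tails exhaustively to universe size 30, and BH
against an independent step-up on 1,000 random vectors. These sizes keep
the whole suite under a minute while leaving the Monte-Carlo bands
(e.g. pooled $\omega$ within $[0.95, 1.05]$ at 10,000 SNVs) comfortably
wider than the simulation's standard error.

## Known limitations

* One transcript per gene; isoform reconciliation is the caller's
  problem.
* Unweighted NG86 counting ignores mutation-spectrum bias; on real
  UV-driven melanoma data absolute $\omega$ values shift, though the
  genome-wide histogram minimum partly absorbs this.
* The depletion test is a sign test without an error model; genes with
  few variants pass or fail $f_{germline} > f_{somatic}$ noisily, which
  is why the support filter precedes it.
* The score-percentile rule inherits whatever biases the upstream
  ensemble scores carry; the package consumes scores, it does not
  compute them.
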