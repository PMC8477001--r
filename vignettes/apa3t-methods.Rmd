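---
title: "Methods: calling 3'UTR shortening from 3'-end tag sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling 3'UTR shortening from 3'-end tag sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`apa3t` analyses alternative polyadenylation (APA) from 3'-end tag
sequencing protocols in which each read's 3' end marks a cleavage/poly(A)
site (PAS). Between two conditions (for example an APA-factor knockdown such
as CPSF6 depletion versus control), the pipeline calls, per gene, whether
poly(A)-site usage shifted toward the proximal site (3'UTR shortening) or
the distal site (lengthening). The stages are:

1. reduce each mapped read to its strand-aware 3'-end position;
2. remove internal-priming artifacts at genomic A-rich stretches;
3. cluster the remaining positions into PAS clusters ("snowball"
   clustering);
4. annotate clusters against gene models and a known-PAS database;
5. per gene, order PAS proximal to distal, compute a signed 3'UTR length
   index (CULI), test for a usage trend with a Cochran-Armitage linear
   trend test, adjust p-values by Benjamini-Hochberg, and call shifts at
   FDR < 0.05.

# The internal-priming filter

Oligo(dT)-primed protocols can prime on genomic adenosine stretches rather
than a real poly(A) tail. Such events leave read 3' ends immediately
upstream of the A-rich stretch. A read is therefore discarded when the 20-nt
window strictly downstream of its 3' end - read in the sense orientation of
the read, so on the minus strand the reference bases 5' of the position,
reverse-complemented - contains **more than 12 'A's in total or a run of 8
or more consecutive 'A's**. The comparison is case-insensitive; `N` never
counts as A; at a chromosome edge only the available bases are examined. We
take "downstream" as strictly after the mapped position: the cleavage base
itself is not part of the window. All three thresholds (window length,
count, run) are exposed as parameters (`ip_window`, `ip_max_a`, `ip_run_a`).

# Snowball clustering

True cleavage positions are heterogeneous over a few nucleotides, so
per-base positions are grouped per (chromosome, strand): repeatedly the
position with the highest remaining read count becomes a seed (ties broken
to the leftmost coordinate), absorbs every remaining position within ±24 nt
(`cluster_window`), and is emitted as one cluster whose representative
position is the seed - the modal cleavage base. Clusters with fewer than
`min_cluster_reads = 5` total reads are discarded (0 disables the
threshold). The procedure is deterministic, depends only on the
position/count multiset (never on input order), partitions the kept reads,
and never merges sense with antisense signal. The seed-accretion scheme is
one member of the family of "snowball" cluster builders used for 3'-end
data; the absorption window is the parameter that matters, and 24 nt was
chosen to be comfortably wider than cleavage jitter yet narrower than the
spacing of distinct annotated sites.

# Annotation

Categories are assigned with precedence **TTS > 3'UTR > exon > intron >
intergenic**, using only same-strand gene models: a cluster within
`tts_window = 100` nt of an annotated transcription terminal site is `TTS`;
otherwise inside an annotated 3'UTR it is `UTR3`; and so on. Because
annotated TTSs lie inside annotated 3'UTRs, the package also reports the
overlapping (non-exclusive) TTS and 3'UTR percentages in its report tables;
the exclusive categorization is what downstream testing uses. A cluster is
`known` when a same-strand database site lies within `match_tol = 24` nt of
its representative position. Both windows are stated in every run's
parameter log; neither has a canonical published value, so both are
configurable.

# Per-gene testing

Only `TTS`/`UTR3` clusters count as a gene's PAS; genes need at least two to
be testable. PAS are ordered by distance from the stop codon
(strand-aware), and replicate counts are summed into one 2 × k
condition-by-PAS table; the replicate-level matrix is retained so the two
treated libraries of a knockdown design can also each be run separately
against control.

**CULI.** For each condition the usage-weighted normalized 3'UTR length is
$L = \sum_i u_i \, d_i / d_{\max}$, with $u_i$ the condition's usage
fraction of PAS $i$ and $d_i$ its distance from the stop codon. The index is

$$\mathrm{CULI} = L(\text{treated}) - L(\text{control})$$

so positive values mean the treated condition uses longer 3'UTRs
(lengthening) and negative values shortening. The definition is bounded,
$|\mathrm{CULI}| \le 1 - d_{\min}/d_{\max}$, and exactly antisymmetric under
swapping the condition labels. No closed formula for this index is in
general circulation; this definition was chosen as the simplest one that is
bounded, antisymmetric and carries the standard sign semantics.

**Trend test.** The canonical linear trend test for a 2 × k ordered count
table is Cochran-Armitage with rank scores $1 \dots k$. We use the
conditional (fixed-margin) variance, so the squared statistic equals the
classical trend chi-square times $N/(N-1)$. For tables with total count at
most `exact_max_total = 200` the two-sided p-value is computed exactly: the
null distribution of the score sum over all tables with the observed margins
(multivariate hypergeometric) is built by dynamic programming over columns,
and the p-value is the probability of tables at least as extreme in
$|T - \mu|$. On 2 × 2 tables this reproduces the two-sided hypergeometric
tail to machine precision. Larger tables use the normal reference; the two
branches agree to well under 0.01 by the time a table holds a few hundred
reads. Columns with zero total are dropped with re-ranking; a table that
collapses below two columns, or has an empty condition row, is untestable
and the gene is skipped with a log entry.

**FDR and calls.** P-values are adjusted by the Benjamini-Hochberg step-up
procedure (`stats::p.adjust`). A gene is called `shortened` when
$q < 0.05$ and CULI < 0, `lengthened` when $q < 0.05$ and CULI > 0,
otherwise `unchanged`. The report also gives, per gene, the distal/proximal
isoform expression ratio per condition (with +0.5 added to both terms when
either count is zero) and its treated/control fold change.

# The synthetic-data generator

`simulate_apa_experiment()` builds a complete experiment with known ground
truth: a two-chromosome genome with non-overlapping two-exon genes on both
strands, 1-4 true PAS per gene (defaults 30/40/20/10%, putting ~30% of
genes at three or more sites), the most distal PAS at the annotated TTS,
one third of true sites entered in the known-PAS database, and per-sample
reads whose 3' ends are a true PAS plus rounded Gaussian jitter
(`jitter_sd = 3` nt, a plausible cleavage heterogeneity; the protocol's
positional precision is not established, so this is a free parameter).
Per-gene read totals are Poisson (mean 200 per sample), PAS choice is
multinomial with the condition's planted usage fractions, and two replicates
per condition are generated.

20% of genes carry a planted shift; 85% of shifts are shortenings,
implemented by moving the proximal site's usage from 0.30 (baseline) to
0.80 in the treated condition (lengthened genes mirror this), with the
remaining mass split evenly over the other sites. 30 genes receive a 16-nt
A stretch (sense orientation) in their 3'UTR at least 30 nt from every true
PAS, and 5% of such a gene's reads are emitted exactly one base upstream of
the stretch - planted internal-priming artifacts. So that *only* planted
traps trigger the filter, 3'UTR sequence (plus a 30-nt margin past the TTS)
is generated A-depleted: no A run above 3 and at most 10 A's per 20-nt
window in the sense orientation. True PAS of one gene are spaced at least
`pas_spacing_min = 100` nt apart, which must exceed the clustering window so
distinct sites never merge by construction.

What the generator does **not** emulate: expression-level differences
between conditions, sequencing errors, mappability artifacts, the composite
base composition of real 3'UTRs (real internal priming is more graded than
the planted traps), overlapping genes and antisense transcription. Passing
the end-to-end tests therefore demonstrates the statistical machinery -
filter specificity, clustering fidelity, test calibration, directionality
of calls - not performance on real libraries.

# Numerical and design choices

- **Coordinates** are 0-based half-open everywhere internally (the BED/BAM
  native convention); conversion happens only at FASTA/SAM boundaries.
  This minimizes off-by-one surface across the many BED files involved.
- **Duplicates** are never collapsed; counts are read counts.
- **Only primary, non-supplementary alignments** contribute a 3' end - one
  cleavage event per read.
- **Replicates** are summed into condition rows for the headline test; the
  per-replicate matrix is retained in each profile.
- **Determinism.** The simulator is fully determined by its seed, pipeline
  outputs are sorted, and numeric fields are written at fixed precision, so
  a rerun with identical config and inputs reproduces every data artifact
  byte for byte. The only exception is `run.log`, which carries wall-clock
  stage timings and is excluded from that contract.
- **Ties** in clustering go to the leftmost coordinate; ties in TTS
  assignment go to the nearest TTS.
- **Problem sizes.** The package's own validation uses 300-gene
  simulations with ~200 reads/gene/sample for end-to-end recovery, a
  1,000-gene null simulation for test calibration, and exhaustive
  enumeration of all 2 × 2 fixed-margin families with totals up to 40 for
  the exact branch - sizes at which every property is checked in minutes on
  one core while leaving the per-gene count regime (tens to hundreds of
  reads) representative of real 3'-end libraries.

# A worked run

```{r, eval = FALSE}
library(apa3t)
sim <- simulate_apa_experiment(sim_config(seed = 1), "sim")
out <- run_pipeline("sim/config.json")
out$summary$n_genes_tested
out$summary$n_altered
out$summary$frac_shortened
rep <- make_report(out$out_dir)
rep$genes_per_pas
```

On this seed the pipeline tests 209 genes with two or more detected sites,
calls 63 altered at FDR < 0.05, and 84% of the altered genes are shortened -
recovering the planted 20% shift rate and 85% shortened fraction, with
every planted shift detected and an empirical FDR below 0.05 against the
ground truth (`scripts/acceptance.R` recomputes these numbers).

# Limitations

Two conditions only; no isoform-level expression normalization across
genes; no de novo poly(A)-signal motif analysis; no strand inference for
unstranded data; the exact trend test is conditional on table margins, so
its rejection rate under the null is slightly conservative on very small
tables.
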