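---
title: "Promoter TFBS overrepresentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter TFBS overrepresentation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promenrich)
```

# The problem and the model

Co-expressed genes often share upstream regulators, and the footprint of
shared regulation is an excess of binding sites for the responsible
transcription factors in their promoters. `promenrich` formalizes this as a
counting problem: scan each query gene's promoter windows with a repertoire
of position weight matrices, count the matches that survive a set of
biological filters, and compare each matrix's count with the count expected
from a calibrated background rate.

Three ideas carry the method:

1. **Per-matrix score thresholds.** Matrices differ enormously in
   information content; a fixed relative-score cutoff makes high-IC
   matrices invisible and low-IC matrices ubiquitous. Instead the user
   chooses a *random occurrence* rate (expected chance hits per Mbp), and
   each matrix receives the integer threshold in 60–100 whose precomputed
   background frequency is closest to that rate. All matrices then operate
   at (approximately) the same false-positive rate.
2. **Phylogenetic footprinting.** Per-base conservation scores in [0, 1]
   gate both the hits (a hit's footprint-mean conservation must reach the
   threshold) and the effective sequence length used for expected counts,
   so observed and expected are measured on the same filtered territory.
3. **Alternative promoters as first-class objects.** Transcripts are
   clustered by start position; each TSS can be refined by CAGE tag
   clusters and carries its own promoter window, TPM (promoter strength)
   and CpG island content. Selection modes (`all`, `most_distal`,
   `highest_tpm`, `with_cpg`, `without_cpg`) decide which promoters enter
   the pool; hits from one gene's selected promoters are pooled, with
   physically identical sites from overlapping windows counted once.

## Scoring

A PFM column with counts $n_b$ and total $N$ becomes log-odds weights
$w_b = \log_2 \frac{(n_b + p/4)/(N + p)}{1/4}$ with pseudocount
$p = \sqrt{N}$ (the convention of the classical Perl TFBS toolchain;
configurable). A window's relative score is
$100\,(S - S_{\min})/(S_{\max} - S_{\min})$, where $S_{\min}$ and
$S_{\max}$ sum the column minima and maxima. `N` bases score the column
minimum — the conservative choice, so ambiguity can never create a hit.
Both strands are scanned; reverse-strand matches are reported at the
forward offset of their footprint. Ties at exactly the threshold are kept.

Information content is computed from the raw count frequencies (no
pseudocount), $\mathrm{IC} = \sum_i (2 + \sum_b f_{bi}\log_2 f_{bi})$, so a
uniform matrix scores 0 bits and a one-hot column 2 bits.

## The statistics

For matrix $m$, with pooled filtered count $O_m$, effective length
$L_g$ per gene (bases inside the analysis window, passing the coding-mode
and per-base conservation filters, deduplicated across overlapping
promoters) and background rate $f_m$ at the optimized threshold:

* expected hits $E_m = f_m \sum_g L_g / 10^6$; fold $F_m = O_m/E_m$;
* expected genes $\sum_g (1 - e^{-\lambda_g})$, $\lambda_g = f_m L_g/10^6$
  — a per-gene Poisson model for "at least one chance hit";
* $z_m = (F_m - \bar F)/s_F$ over the whole repertoire (sample sd,
  $n-1$), p-value $1 - \Phi(z_m)$, upper tail only: the tool reports
  overrepresentation, a fold below the mean never becomes significant;
* proportion p-value $\min(1, E_m/O_m)$ (1 when nothing was observed).

The z-device makes each matrix's excess relative to the behavior of the
whole repertoire on the same query — an internal control that absorbs
query-wide biases (composition, length, conservation structure) that would
fool a pure Poisson test. Its cost is the Gaussian assumption on the fold
distribution, which is reasonable when per-matrix expected counts are
roughly ≥ 20 and poor in the sparse regime; this drives the default
calibration scale below. Hit-fold and gene-fold p-values are computed
separately but by the same device. No multiple-testing correction is
applied to the primary p-values (raw values are what the method reports); a
Bonferroni column is emitted as a convenience.

## CpG islands

Islands follow the Gardiner-Garden definition with all three inequalities
strict: length > 200 bp, GC > 50 %, CpG obs/exp > 0.6, where
$\mathrm{obs/exp} = N_{CG} \cdot L / (N_C N_G)$ with overlapping CG
dinucleotides counted. Detection slides 200-bp frames at 1-bp step
(configurable; 1 bp is maximal sensitivity and still cheap), merges runs of
*overlapping* qualifying frames, and — a deliberately stricter reading of
an ambiguous rule — re-validates the merged region's own aggregate
statistics, so two barely-passing frames bridged by AT-rich sequence cannot
become one island. A single qualifying frame (exactly 200 bp) is not an
island under the strict length inequality. The island window is 5 kb
upstream / 10 kb downstream of the TSS — note the opposite asymmetry to the
promoter scan window (10 kb up / 5 kb down); both windows are oriented and
truncated, never padded, at chromosome ends. Per gene, island content is
the summed island length over the gene's selected TSS windows, zero when
none; the query set is compared against the genome by a one-sided z-test of
the query mean against the genome per-gene distribution.

# Parameters

| parameter | range | default | meaning |
|---|---|---|---|
| `conservation_threshold` | 60–90 % | 60 | minimum footprint-mean (and per-base, for effective length) conservation |
| `top_percent_conserved` | 1–100 % | 100 | keep only this top share of surviving hits per promoter, by conservation |
| `max_conserved_tfbs` | ≥ 1 or unlimited | unlimited | per-promoter cap, equalizing promoter contributions |
| `coding_mode` | coding / noncoding / both | both | exon-overlap filter (all exons, UTRs included) |
| `upstream_len` | 0–10000 bp | 10000 | analyzed window upstream of the TSS |
| `downstream_len` | 0–5000 bp | 5000 | analyzed window downstream of the TSS |
| `random_occurrence` | 1–10000 hits/Mbp | 100 | target chance hit rate for threshold optimization |
| `background_type` | random / core / conserved | random | which frequency table calibrates thresholds |
| `tss_mode` | all / most_distal / highest_tpm / with_cpg / without_cpg | all | alternative-promoter selection |

The rank filters (top-percent, cap) rank hits by conservation with a
deterministic tie-break (conservation, then score, matrix id, offset,
strand), pooled over all matrices of a promoter, so every promoter
contributes an equal number of sites when the cap binds. The top-percent
count is the ceiling of percent × n.

# Numerical choices

* Score-threshold comparisons use `rel >= t − 1e-9` and integer bucketing
  uses `floor(rel + 1e-9)`: a consensus window whose relative score
  evaluates to 99.999…9 in double arithmetic still counts at threshold
  100. The two rules are consistent for integer thresholds.
* Threshold optimization minimizes the absolute difference on the
  hits-per-Mbp scale (a log-scale distance was considered and rejected for
  opacity); exact ties resolve to the *higher* threshold — the restrictive
  choice, fewer false positives.
* A degenerate matrix (min raw score = max) scores every window 100, with
  a warning.
* If a matrix's background frequency at its optimized threshold is zero
  (a matrix too specific ever to hit the background), the rate is floored
  at half a hit over the background length so folds stay finite; the
  affected matrix is then conservatively overrepresented rather than
  undefined.
* "Most distal" means the 5'-most TSS in gene orientation; ties take the
  smallest genomic coordinate. `highest_tpm` ranks the −1 no-CAGE sentinel
  below any real TPM, falls back to `most_distal` (with a warning) when no
  TSS has CAGE support, and breaks TPM ties toward the more distal TSS.
* CAGE cluster distance is the minimum distance from the TSS to the
  cluster interval (0 inside); equidistant clusters resolve by total tag
  count, in-cluster count ties by the most 5' position. Remapping is
  restricted to same-strand clusters (the alternative — strand-agnostic
  matching — was considered and rejected: a tag cluster on the opposite
  strand describes a different promoter). Two TSSs collapsing onto one
  position after remapping are merged, keeping the larger TPM.
* The fold distribution needs at least 3 matrices; with a zero-variance
  fold distribution every p is 0.5.

# The synthetic data generator

`fixture_spec()` / `make_genome()` build deterministic toy genomes whose
defaults are the package's standard benchmark conditions: 50 genes on 2
chromosomes at 16-kb spacing (room for the full 10 + 5 kb windows), GC
fraction 0.5 chosen to match the equal-nucleotide random background model,
1–4 alternative TSSs per gene (cycling, so a four-TSS gene always exists),
two-exon transcripts per TSS, conservation 0.2 ± 0.05 background with a
500-bp 0.9-level stretch at [−600, −100) of every TSS, CpG-island blocks
(600 bp, GC 0.7, obs/exp ≈ 1) on half the genes, and CAGE clusters peaked
on the primary TSS for 60 % of genes. Background sequence is generated at
*exact* base composition and then CpG-depleted by composition-preserving
swaps until the dinucleotide is rare — mimicking the genome-wide CpG
depletion of mammalian DNA, without which every GC-balanced window would
qualify as an island. All randomness flows from one seed through
per-component child seeds, so adding genes never perturbs earlier genes.

`plant_motifs()` writes consensus (or PFM-sampled) words at TSS-relative
offsets inside the conserved stretch, raises footprint conservation to
0.95, and returns a manifest; `make_decoy_pwms()` draws random PFMs with
varied information content. The bundled CRE-like example matrix uses the
non-palindromic TGACG-core consensus `TGACGTAA`: the canonical palindromic
CRE would match both strands at every planted site by symmetry, making
"exactly k sites" untestable.

What the generator deliberately does **not** emulate: repeats and
isochores, realistic CAGE tag distributions, splice structure beyond two
exons, and inter-gene conservation heterogeneity. Passing tests on these
fixtures therefore demonstrate the correctness of the machinery and its
calibration under the stated model, not performance on real mammalian
genomes, where composition bias, repeat-driven motif clustering and
annotation errors add noise the null model does not capture.

# Calibration and power checks

The test suite measures the engine at a fixed study scale, chosen once:
promoter windows of 1000 bp upstream / 200 bp downstream (the compact
window typical of focused promoter analyses), conservation threshold 60 %,
and a random occurrence of 1000 hits/Mbp, which puts per-matrix expected
counts near 25 so the Gaussian fold approximation is sound. Backgrounds of
100–200 kb keep frequency-table sampling error a few percent. Under these
conditions, across seeds: the fraction of the 30-matrix repertoire
reaching a nominal fold-p < 0.05 on unplanted fixtures stays in [0, 0.15];
no matrix reaches proportion-p < 0.05 on null data; and a motif planted
twice per promoter in 20 query genes ranks first by fold-p in ≥ 90 % of
replicates.

# Known limitations

* Uniform mononucleotide background in PWM scoring; no dinucleotide or
  higher-order models, and no per-site p-values.
* The Gaussian z-device degrades when expected counts are very small
  (restrictive `random_occurrence` plus short windows); the proportion
  p-value is the more robust of the two readouts in that regime.
* The effective length counts bases surviving the region-level filters
  only; the rank filters (top-percent, cap) have no natural length and do
  not feed back into expected counts. This is the largest interpretive gap
  in the expected-count accounting and is deliberate: with the cap
  binding, expected counts are conservative (overstated), not optimistic.
* Coding masks use all exons of all transcripts, UTRs included.
* Gene identifiers must match the annotation; probe-set or symbol mapping
  is out of scope.
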