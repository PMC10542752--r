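---
title: "Curating TE annotations and relating them to genome features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating TE annotations and relating them to genome features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tescape)
```

## The problem

RepeatMasker reports transposable elements (TEs) as *hit fragments*: a
single insertion that was later interrupted by a nested element, or eroded
by deletions, appears as several rows. Counting fragments inflates copy
numbers (disproportionately for old, fragmented elements), and
per-fragment divergences are noisy. tescape rebuilds *copies* from
fragments, filters them by the 80-80-80 retention rule, dates them through
their divergence from the family consensus, and relates the resulting
annotation to gene density, GC content, CpG-island coverage and
recombination rate in fixed-width genome windows — the analysis layout
used for avian genomes, where a handful of LTR and LINE families dominate
a small (5–10%) repeat complement.

All interval arithmetic inside the package is 0-based half-open; every
reader and writer converts at the file boundary only (`.out`, `.align` and
GFF3 are 1-based inclusive on disk; BED and the recombination map are
half-open).

## Divergence: CpG-adjusted Kimura 2-parameter distance

For one copy-versus-consensus alignment we classify each column as match,
transition ($A \leftrightarrow G$, $C \leftrightarrow T$), transversion,
gap or ambiguous; gap and ambiguous columns are excluded from the usable
site count $n$ (substitutions are undefined there). With transition
proportion $P$ and transversion proportion $Q$, the distance (in percent)
is

$$K = 100\left[-\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q)\right].$$

Outside the domain ($1-2P-Q \le 0$ or $1-2Q \le 0$) the distance is
saturated and the package raises an error rather than returning a number.

Methylated CpG dinucleotides are transition hotspots, so un-weighted
transitions at CpG sites would overestimate the age of a copy. The
adjustment follows the convention of the standard landscape toolchain: a
transition whose consensus column belongs to a `CG` dinucleotide counts
1/10, and when *both* columns of one consensus CpG are transitions the
pair counts exactly 1 transition in total. Transversions are never
reweighted. The adjustment is exposed as a flag (`cpg_adjust`) so the
plain K2P distance remains available.

A merged copy's divergence is the length-weighted mean of its fragment
divergences, weighted by usable aligned length.

## Insertion age and the recent/ancient split

Divergence accumulates on the copy lineage relative to a consensus that
proxies the ancestral state, so per-site distance grows at $2\mu$ per
year and

$$T \;=\; \frac{K/100}{2\mu}\,,$$

reported in million years. The default $\mu = 2.3\times10^{-9}$
substitutions/site/year (collared flycatcher estimate) maps the recent
threshold $K \le 7$ to $\approx 15.2$ My; dividing by $\mu$ instead would
double this and contradict the ~16 My bound the threshold is meant to
represent, which is why the $2\mu$ form is used. Copies at or below the
threshold are *recent*, all others *ancient*; the boundary is inclusive.
Both $\mu$ and the threshold are fields of `age_model()`.

## Defragmentation and the 80-80-80 rule

`merge_fragments()` is a deterministic greedy left-to-right merge. Two
hits join one copy when

* (a) they share a RepeatMasker run id on one chromosome — this rejoins
  fragments split by a nested insertion regardless of the gap; or
* (b) they share family, chromosome and strand, the genomic gap is at most
  `max_gap` (default 2,500 bp), and the consensus coordinates continue
  collinearly: on `+`, the next fragment's `cons_start` may backtrack at
  most `cons_overlap_tol` (default 15 bp) below the previous `cons_end`;
  mirrored on `-`.

When several open copies could absorb a hit, the copy with the nearest
genomic end wins — an arbitrary but deterministic tie-break. Every hit
belongs to exactly one copy (asserted as a partition invariant in the
tests). The cited defragmentation tooling is script-based and not
re-implemented bug-for-bug; the gap and tolerance defaults are exposed
precisely because they are conventions, not published constants.

Full LTR retrotransposons are reassembled from adjacent `X_LTR` /
`X_I` / `X_LTR` copies of one stem and strand (gaps at most `max_gap`),
scanning leftmost-first; solo LTRs stay solo.

The retention rule keeps a copy when

1. its merged length (summed fragment bp, gaps excluded) is >= 80 bp;
2. it is at least 80% identical to its consensus — expressed on the
   divergence scale as $K < 20$;
3. its fragments cover at least 80% of the consensus length
   (`cons_span_frac >= 0.80`, strict mode only).

The second criterion's published phrasing ("identity to the reference")
is ambiguous between a percent-identity and a divergence reading; the
package uses $K < 20$, which is what the toolchain's strict mode enforces
and what makes "divergence of 20 and more is filtered out" literally
true. Unclassified repeats are always dropped from the curated set.
Copy *coverage* is always computed from fragment unions, never the
envelope, so the bp of a nested foreign element is not attributed to its
host; the envelope is reported for display only.

## Repeat landscapes

`build_landscape()` accrues each fragment's (raw mode) or copy's (final
mode) length to the divergence bin $\lfloor K \rfloor$, with 1%-wide bins
from 0 to 50 and empty bins emitted. Conservation — the landscape sums
exactly to the annotation's total coverage — is asserted on every fixture.
Family-level groups are supported because single families (e.g. ERVK) can
carry a burst that the class-level landscape dilutes. A secondary axis
maps bin edges through the age model.

## Windowed genome features

`make_windows()` tiles each chromosome into non-overlapping windows
(default 200 kb), keeping the trailing partial window but flagging it;
partial windows are excluded from correlation analyses by default because
their shorter support would enter rank statistics with equal weight.
Per window, `feature_table()` computes: TE coverage (union bp, clipped at
window edges) overall, per repeat type and per age class; gene and
CpG-island coverage from the interval tracks; GC content over unambiguous
bases; and the recombination rate as the overlap-bp-weighted mean of the
map intervals intersecting the window (missing when no interval
overlaps). Because recent and ancient copy sets are disjoint and coverage
is fragment-union based, recent + ancient coverage equals total TE
coverage in every window — an identity the tests assert.

Gene coverage uses gene-body unions (the exon/gene-body choice is not
determined by the published description; gene bodies are the
implemented reading).

## The statistical battery

Pairwise association uses Kendall's $\tau_b$ with tie corrections. The
partial correlation between $x$ and $y$ given controls is read off the
inverse of the pairwise $\tau_b$ matrix $M$:
$\tau_{xy\cdot z} = -M^{-1}_{xy} / \sqrt{M^{-1}_{xx} M^{-1}_{yy}}$, which
for one control reduces to the textbook recursion
$(\tau_{xy} - \tau_{xz}\tau_{yz}) / \sqrt{(1-\tau_{xz}^2)(1-\tau_{yz}^2)}$
(the equivalence is verified to $10^{-12}$ on random tables). The
two-sided p-value uses the normal approximation
$z = \tau / \sqrt{2(2(n-g)+5)/(9(n-g)(n-g-1))}$ with $g$ controls —
the convention of the R packages commonly used for Kendall-type partial
correlation. Its finite-sample type-I rate at $n = 500$ windows sits
close to the nominal 5% (asserted to lie in $[0.02, 0.09]$).

The windowed report (`te_feature_correlations()`) tests each TE category
(all / ancient / recent) against each feature, controlling for the other
three features, with complete-case rows per correlation (the partial
statistic needs complete vectors). Bonferroni families are formed per
genomic feature — the family is the set of TE categories tested against
that feature — so `p_adj = min(1, 3 p)` under the default three
categories. Non-autosomal windows are excluded from correlations (sex
chromosomes have strongly atypical TE loads and no comparable
recombination), though they stay in the feature table.

Macro/microchromosomes split at 20 Mb, with microchromosomes strictly
below and the exact boundary counted macro. Coverage comparisons between
the two groups use tie-corrected Kruskal–Wallis tests on per-chromosome
relative coverage (per-chromosome values, not pooled windows, are the
implemented reading of the published comparison; pooling is available by
passing pooled window values to `kruskal_wallis()` directly). The
coverage-versus-length relationship is an OLS fit of
$\log_{10}(\text{coverage})$ on length; chromosomes with zero coverage
cannot be log-transformed and are dropped with a warning, and a
zero-residual fit returns the boundary p-value (1 for a flat fit, 0 for
an exact non-flat one) instead of NaN.

## The synthetic genome generator

`plant_genome()` is first-class, tested code, not a fixture: it emits
every input the pipeline reads (genome FASTA, `.out`, `.align`, consensus
library, gene GFF3, CpG BED, recombination TSV, chromosome sizes) plus a
truth table, so the full parse → merge → filter → window → correlate path
can be checked against planted ground truth.

Design choices, in the package's own terms:

* **Substitutions** are per-site categorical draws with
  transition:transversion odds $\kappa$:1 (default 2) and the CpG-context
  transition rate multiplied by `cpg_multiplier` (default 10, capped so a
  site's substitution probability stays below 1). A continuous-time
  matrix exponential would allow multiple hits per site; at the
  divergences involved (K <= 40) the categorical scheme with numerical
  calibration is simpler and has an explicit oracle.
* **Calibration** solves (by `uniroot`) for the rate scale at which the
  *expected CpG-adjusted* Kimura distance of the alignment equals the
  planted `K_true`. Calibrating the plain-K2P expectation instead would
  make the adjusted estimator read systematically low whenever the CpG
  multiplier is active (the adjustment is designed to remove exactly that
  excess), so the planted value is put on the scale the estimator
  reports. Unbiasedness of the median estimate to within 0.5 divergence
  units at 2 kb is asserted over 200 replicates per divergence level.
* **Placement** draws copy positions from a smoothed latent field (moving
  average of white noise, 20 kb tiles) passed through monotone links:
  recent and ancient copies have separate placement coefficients, and
  gene density, CpG-island density, GC background and recombination rate
  are links of the same field. Monotone links plant *rank* associations —
  exactly what Kendall statistics measure — without committing to linear
  effects. `plant_correlations()` reports the expected sign of every
  TE-feature association as the product of the two coefficients.
* **Structure**: LTR-family copies are planted as LTR–internal–LTR
  triplets (each part evolved independently; the two LTRs diverge from
  insertion time as they do in real elements) or as solo LTRs; LINEs are
  5'-truncated with uniform retained fraction on [0.2, 1], keeping the 3'
  consensus end, which mirrors the target-primed reverse transcription
  bias; nested young insertions split an eligible host into two
  fragments sharing the host's run id.
* **Determinism**: everything derives from one seed; the same
  configuration reproduces byte-identical files.
* **Indels are off**: truth alignments are gapless. The `.align` parser
  accepts gapped alignments, but the generator does not currently stress
  it with indels, real assemblies' sequencing errors, segmental
  duplications, tandem repeats or consensus misassignment. Passing tests
  therefore demonstrate correctness of the bookkeeping and the estimator
  under the model's assumptions, not robustness to every artefact of a
  real RepeatMasker run.

Default scale: four chromosomes totalling 1 Mb, ~80 copies across two LTR
families (one a low-divergence ERVK-like burst), two LINE families, and
minor SINE/DNA/unclassified components — a deliberately small replica of
the avian landscape shape that keeps a full pipeline run around a second.
The test suite uses 100–250 kb genomes for seed sweeps, 200 replicates
per divergence level for estimator calibration, 100 seeds for
defragmentation recovery, and 100–200 replicates of 500 windows for the
correlation properties.

## Known limitations

* The defragmenter is a clean-room greedy reimplementation of the cited
  merging behaviour, not a replica; pathological fragment layouts can be
  attributed differently than the original scripts would.
* Consensus span uses `cons_end + cons_left` from the hit table as the
  consensus length; corrupt `(left)` fields would distort the third
  80-80-80 criterion.
* The normal approximation for the partial-Kendall p-value is asymptotic;
  at small window counts (tens) it is only indicative, and the package
  refuses to compute with fewer than 10 complete rows.
* Relating window features by rank correlation ignores spatial
  autocorrelation along chromosomes; p-values should be read as
  descriptive, as in the analyses this package supports.
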