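---
title: "Epiallele analysis of targeted bisulfite amplicons: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epiallele analysis of targeted bisulfite amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A targeted bisulfite amplicon experiment reads one short region — here a
promoter of a few hundred bp with *k* scored CpG sites — in thousands of
individual molecules per sample. Bisulfite treatment deaminates unmethylated
cytosine to uracil, sequenced as T; methylated cytosine resists conversion
and is sequenced as C. After PCR of the converted top strand and paired-end
sequencing, each read pair represents one molecule, and the C/T states at
the *k* CpG positions form that molecule's **epiallele**, a binary string
with `1` = methylated. The leftmost character is the most 5' CpG; TSS-relative
labels (e.g. −118 ... +131) are display names only and never enter a
computation.

Three error processes separate the called profile from the molecule's true
state:

* **incomplete conversion** — an unmethylated C stays C with probability
  `1 - conversion_rate`, producing a false `1`;
* **inappropriate conversion** — a methylated CpG C reads T with probability
  `inappropriate_conversion_rate`, producing a false `0`;
* **substitution sequencing error** — any base is replaced by one of the
  other three uniformly, with per-base probability `seq_error_rate`; at a
  CpG this can yield A/G, an uncallable state.

Every cytosine of the reference that is *not* a scored CpG is expected to
read T; the fraction of those positions read as T in one read is the
per-read conversion QC, and the same fraction pooled over reads of a fully
unmethylated spike-in fragment is the assay-level conversion-efficiency
estimate (with an exact binomial 95% interval). Real assays spike in
unmethylated phage DNA for this purpose; the bundled control reference is a
synthetic C-rich stand-in with the same role.

## The synthetic-data generator

`make_amplicon_spec()` draws a reference with exactly *k* CpGs at
well-separated interior positions, at least *k* further non-CpG cytosines
(the conversion-QC positions), and 24-bp primer anchors at both ends. The
background alphabet is arranged so no accidental CpG arises, making the
scored CpG set exactly the requested one. The demo geometries are a 7-CpG
amplicon of 388 bp and an 8-CpG amplicon of 403 bp, the typical size of
promoter panels around alternative TSSs.

`simulate_bisulfite_reads()` draws molecules from a named epiallele
probability vector (`mixture_spec`), applies the three error processes, and
emits 251-bp mates from the two ends of the amplicon (a 251 × 2-cycle run),
so any amplicon up to 462 bp overlaps by at least the 40-residue merge
threshold. Error-model defaults are `conversion_rate = 0.995`,
`inappropriate_conversion_rate = 0.005`, `seq_error_rate = 0.001` — the
order of magnitude of a good commercial bisulfite kit and an Illumina
amplicon run. Both mates are cut from the same simulated molecule string, so
sequencing errors are shared between mates rather than drawn independently;
merging therefore never sees a within-pair conflict at error positions. This
is a deliberate simplification (see *Limitations*).

The demo study design is two tissues (brain, heart) × three post-natal
stages (P1, P15, P60) × 3 replicates, 10^4 molecules per sample per
amplicon. Stage targets move mean methylation *up* over time in brain and
*down* in heart, and each tissue × stage group gets its own fixed per-CpG
weighting of the target (a product-Bernoulli mixture with per-CpG
probabilities), so groups differ in epiallele support and not only in mean —
the situation in which epiallele distributions are informative beyond
average methylation. The per-group probabilities are configuration, not
claims about any particular gene. Replicate counts are not a measured
quantity either; 3 per group is the package's default assumption and is
configurable.

Expression is generated so that *true* relative expression is **linear** in
mean methylation: `rel_true = base_expr + coupling × methylation`, with
negative `coupling` for promoter silencing. Target Ct is then
`mean(housekeeping Ct) − log2(rel_true)` plus Gaussian noise *on the Ct
scale* (cycles), and housekeeping Ct is a constant plus the same noise.
Linearity on the expression scale was chosen deliberately: it makes the
noise-free Pearson correlation between methylation and 2^−ΔCt exactly −1,
giving the correlation-recovery tests a sharp reference point. An
exponential coupling (linear in ΔCt) would be equally defensible
biologically but has no such exact invariant.

## Read processing

**Merging.** The reverse mate is reverse-complemented and every
suffix(forward)/prefix(reverse) overlap of length ≥ `min_overlap` (default
40) is scored by its mismatch fraction. The candidate with the smallest
fraction wins, ties going to the longest overlap, and is accepted if the
fraction is ≤ `max_mismatch_frac` (default 0.1); overlap disagreements are
resolved in favour of the forward read. Rejection is a value, not an error.
This is the package's own documented consensus contract — assembler tools
differ in their tie-breaking and quality arithmetic, and no attempt is made
to emulate any of them bit-for-bit. The kernel is a short C++ routine with
early termination; an exhaustive R implementation serves as its oracle in
the tests.

**Filtering.** A merged read fails on (in order) length deviation
> `max_len_dev` (default 10% — generous because indels are not simulated),
N fraction > `max_n_frac` (default 2%), or primer-anchor identity. Anchor
identity is computed against the converted reference with C/T tolerance at
every original-cytosine position, mirroring degenerate bisulfite primers; a
read fails only when *neither* anchor reaches `min_primer_score` (default
0.8), so a read with one damaged end but an unambiguous origin is kept. The
filter report partitions the input exactly (pass + each failure reason =
total). Published pipelines do not print their filter thresholds; these
defaults are permissive and fully exposed.

## Calling

Reads whose length equals the reference length are scored by direct position
lookup (the generator produces no indels); other lengths are globally
aligned (affine gaps) against the converted reference in which CpG cytosines
are the ambiguity code Y, so C and T both score as matches there. Reads
below `min_identity` (default 0.8, C/T-tolerant) are rejected.

Per CpG, C calls `1`, T calls `0`, anything else is ambiguous. The default
`max_ambiguous = 0` rejects any read with an uncallable CpG: an incomplete
string has no place in the 2^k epiallele space, and a count table mixing
complete and masked profiles would double-count classes. Setting
`max_ambiguous > 0` instead masks the position with `?`; masked reads are
excluded from the count table but remain in the per-read output for
per-CpG-level use.

Reads with per-read conversion below `min_read_conversion` (default 0.95)
are discarded: a molecule that escaped bisulfite conversion would otherwise
inflate apparent methylation. With the default 14+ QC positions this
threshold removes reads carrying one or more unconverted non-CpG cytosines
at conversion rates near 0.99, and the discarded fraction follows the
corresponding binomial tail, which the tests check.

## Count tables, rarefaction, ordination

The count table enumerates all 2^k epialleles (lexicographic order) per
sample. Rarefaction subsamples each sample uniformly without replacement to
a common depth — by default the minimum retained-read count across samples —
as a *single* draw with a recorded seed, the convention of the classic
profile-table toolchains; samples below depth are dropped and reported. Row
sums after rarefaction equal the depth exactly, and epiallele frequencies
are preserved in expectation (hypergeometric), both covered by tests.

Ordination defaults to principal coordinates analysis (PCoA) of Bray–Curtis
dissimilarities between rarefied count rows. The classic beta-diversity
scripts that popularised this treatment of profile tables are commonly
labelled "PCA" although they perform PCoA on a distance matrix; this package
defaults to what those scripts actually compute, and offers plain PCA of
frequency rows by flag. Variance-explained fractions are ratios of positive
eigenvalues (negative eigenvalues, expected for a non-Euclidean
dissimilarity, are excluded from the denominator); axis signs are fixed by
making the largest-magnitude coordinate on each axis positive; all-identical
samples yield the degenerate result of zero coordinates and zero variance
fractions rather than an error.

## Expression and statistics

Relative expression is 2^−ΔCt with ΔCt = target Ct − mean housekeeping Ct;
technical replicates are averaged on the Ct scale before the difference
(common practice where the published convention is silent). The statistical
layer is classical: one-way ANOVA (between/within mean squares) across
stages, pairwise two-sample t tests per stage pair, and Pearson correlation.
Pairwise t defaults to Welch's unequal-variance form — the safer modern
default where the original convention is unstated — with a pooled-variance
option under which the two-group identity F = t² holds exactly. No
multiple-testing correction is applied by default, matching the common
reporting of raw pairwise p-values; Holm is available by flag. Degenerate
inputs are explicit: zero within-group variance flags the p → 0 limit, and a
constant vector yields an explicit NA correlation rather than an error.

The correlation heatmaps compute, per tissue with stages pooled, Pearson r
between expression and each epiallele-class proportion, or each retained
epiallele's frequency. Epialleles below `min_mean_freq` (default 1% mean
frequency across samples) are excluded and listed; published heatmaps show a
finite epiallele subset without stating their floor, so the floor here is an
explicit, configurable choice.

## Numerical and validation choices

* **Coordinates** are 1-based inside the package, R's native convention.
* **Determinism**: every stochastic function takes a seed and uses it via
  `withr::with_seed`, so nothing disturbs the caller's RNG state; the
  pipeline derives per-sample sub-seeds from the master seed and records
  them in the manifest. Re-running a configuration reproduces every output
  table byte for byte (the BIOM timestamp field is pinned for this reason).
* **Noisy-mixture validation** compares called epiallele frequencies not to
  the raw truth mixture but to the truth mixture pushed through the per-CpG
  read channel (conversion, inappropriate conversion, substitution error,
  conditioning on complete profiles), which is available in closed form.
  At `conversion_rate = 0.99` the channel moves abundant profiles by several
  binomial standard errors — e.g. a 40% fully unmethylated epiallele loses
  ≈ 7% of its reads to one-off false `1`s — so the channel expectation is
  the correct reference for a sampling-error-sized tolerance, and the
  deviation from the raw mixture is a property of the assay, not of the
  implementation.
* **Problem sizes** in the tests and the acceptance script are the study
  conditions at analysis scale: 10^4 reads per sample for round-trip and
  mixture recovery, 5 000 spike-in reads, 100–200 seed replicates for the
  Monte-Carlo rates, and the full demo design (2 amplicons × 18 samples ×
  10^4 reads) for the end-to-end and determinism checks.

## What passing tests do and do not show

The generator emulates mixture sampling, the bisulfite error channel,
substitution error and paired-read geometry. It does **not** emulate indels,
PCR duplicates or amplification bias, chimeric reads, quality-score
structure, opposite-strand (OT/OB) reads, or cell-type composition as such —
an epiallele mixture is the *marginal* molecule population, with no claim
about which cells carry which profile. Consequently, green tests demonstrate
that the analysis chain is correct under its stated measurement model, not
that any particular biological dataset will satisfy that model; with real
data, indel-bearing reads fall to the alignment/identity stage and
PCR-duplicated molecules will violate the binomial sampling assumptions
behind the rarefaction and recovery checks.

## Known limitations

* Only the converted top strand is modelled and analysed, matching
  directional amplicon bisulfite PCR designs; non-directional libraries
  would need the complementary-strand logic.
* Shared-between-mates sequencing errors (see above) make merging slightly
  easier than in real data; the merge contract itself is exercised
  separately with constructed disagreeing pairs.
* `k` is capped at 12 CpGs: the dense 2^k column space is the point of the
  design (complete epiallele accounting) and stops being sensible beyond
  amplicon scale.
* The expression model couples to *mean* methylation; epiallele-specific
  regulatory effects (specific arrangements silencing a promoter more than
  their class average) are not generated, only detected if present.
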