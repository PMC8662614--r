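---
title: "Methods: macrosatellite architecture, copy number, methylation and fine-mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: macrosatellite architecture, copy number, methylation and fine-mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterileX)
```

# Scope and model

`sterileX` implements the computational procedures used to dissect an
X-linked hybrid male sterility locus centred on a DXZ4-like compound
macrosatellite: a repeat locus made of two divergent tandem arrays (RA,
with one reverse-strand CTCF motif per ~4.5 kb unit, and RB, with two
opposed motifs per ~4.6 kb unit) separated by a conserved ~33 kb spacer
carrying five motifs of mixed orientation. Around that locus the package
covers read-depth copy-number estimation over collapsed arrays,
female-coverage-based Y-contig classification, RRBS differential
methylation with a lambda spike-in, chromosome-level differential-expression
enrichment, and ancestry fine-mapping in a hemizygous backcross cohort.
External heavy machinery (read alignment, bisulfite calling, DE model
fitting, mixed-model association) is out of scope: the package consumes
their standard text outputs (FASTA, BED, bedGraph/depth TSV, per-cytosine
call tables, 12-column hit tables, DE tables) and owns everything
downstream.

All internal coordinates are 0-based half-open; conversion to the 1-based
conventions of GFF3 and depth TSV happens only at the format boundary.
Positions absent from a depth file take depth 0, matching the `-bga`
semantics of standard genome-coverage tools.

# The synthetic-data generator

Every stage is exercisable without downloads because the generator emits
each input the pipeline consumes, together with truth annotations that
downstream accuracy tests read exclusively.

**Locus geometry.** Defaults are the felid values: unit lengths 4,554 (RA)
and 4,607 bp (RB), a 33 kb spacer, the 34-bp CTCF consensus
`GAGTTTCGCTTGATGGCAGTGTTGCACCACGAAT` (IUPAC form
`VVNYTYYKSTKGRYGGCRVYRBWGYHCYRSVAAT`), nine RA and twelve RB units. A
single `scale` knob shrinks all lengths (x0.1 in the tests and analysis
scripts) while keeping the motif intact. Spacer motifs sit at irregular
fractional positions (0.05, 0.33, 0.61, 0.89, 0.97) so they can never form
a three-unit periodic run that the segmenter would mistake for an array.

**Divergence.** Substitutions are single-hit per site, uniform over the
three alternative bases. Each unit is mutated from its array consensus at
rate `div/2`, so the expected pairwise p-distance between units is
approximately `div`; the defaults (0.028 within RA, 0.013 within RB,
0.424 between arrays) are the values reported for the real locus. The most
proximal RA unit receives a configurable divergence multiplier, emulating
its divergent clade. Because divergence is substitution-only, units within
an array are born aligned; across arrays the shorter units are right-padded
with gaps, a truth alignment adequate for these low-divergence units —
general multiple alignment is deliberately not this package's problem.

**Depth.** Per-base depth is Poisson with expectation
`mean_depth * ploidy / 2` (ploidy 2 on autosomes, 1/2 on the male/female X,
1/0 on Y contigs); a collapse map multiplies the representative-unit
expectation by the per-haplotype copy count, emulating multi-mapped pileup
on a collapsed reference. Depth is simulated directly — no reads, no
aligner — because every in-scope computation consumes depth, not
alignments.

**Methylation.** Each site draws one Beta-distributed random effect shared
by both groups, shifted by the group means (defaults 0.220 fertile vs
0.194 sterile, the study-design genome-wide means). Equal means therefore
give an *exact* null — identical per-site truths — which is what the null
calibration tests require; unequal means give a constant shift. Counts are
Binomial(depth, clamp(mf + non-conversion, 0, 1)); lambda spike-in sites
have true MF 0 so their observed MF estimates the non-conversion rate.
Non-conversion is additive and clamped, with no context-specific rates.

**Cohort.** 23 fertile and 16 sterile X-hemizygous backcross males, 27
markers, a causal block delimited by markers placed exactly at 93.74 and
94.24 Mb, exactly 14/16 sterile individuals carrying Jungle-cat ancestry
there (two discordant), all fertile individuals domestic. Ancestry extends
outward from the causal block with a per-step switch probability (default
0.1). The generator makes no attempt to match genome-wide ancestry
fractions of a multi-generation pedigree; only the single-interval
backcross structure matters to the fine-mapping scan.

**DE table.** X genes are upregulated with probability 0.22 at mean log2
fold change 2.45; a fixed subset of 22 X up-genes is flagged unexpressed in
fertile testes with mean lfc 3.28; autosomes get a mild down-bias. These
defaults reproduce the study's qualitative pattern (X-wide upregulation,
autosomal downregulation) without modelling counts.

What passing tests on these simulations do **not** show: robustness to
alignment artefacts, GC bias, coverage waves, context-specific bisulfite
failure, population structure in the cohort, or DE model misspecification —
all of which live upstream of this package's inputs.

# Repeat architecture

**Motif scanning.** Literal scanning reports every offset within Hamming
distance `max_mismatch` (default 13, the tolerance used for the 34-bp
consensus) on both strands, N counting as mismatch; IUPAC scanning counts
non-membership of the subject base in the pattern class. Both strands are
scanned by default since motif orientation is the array signature of
interest.

**Segmentation** formalises what was originally a manual procedure (GC
traces, motif annotations, dot plots). Hits closer than `unit_min/2` are
collapsed into per-unit groups; consecutive groups with start-to-start lag
in `[unit_min, unit_max]` (defaults 3–8 kb, scaled) and a constant strand
signature form an array (at least `min_units = 3`); a gap of at least
`spacer_min` (20 kb, scaled) between the two arrays is the spacer; the
array nearer the anchor gene is RA. Unit boundaries come from the periodic
lattice: the fitted period is the median inter-group lag and each unit
starts `round(0.3 * period)` before its group. The 0.3 offset is a
convention shared with the generator — the published material gives no
boundary rule, and a single shared convention is what makes exact truth
recovery a well-defined test.

**CpG islands.** A two-state (island/background) HMM with first-order
dinucleotide emissions (the classic CpG-island tables: the background state
suppresses the CpG dinucleotide), transition persistence `1 - 1e-4`,
evaluated by forward–backward in log space; islands are maximal runs of
island posterior > 0.5 of at least 200 bp. A Gardiner–Garden rule screen
(GC > 50%, obs/exp CpG > 0.6, length ≥ 200) is provided as a secondary
detector. The tests verify the posterior against an independent scaled
(non-log) forward–backward implementation.

**Distances and trees.** p-distances are computed after removing columns
whose gap fraction exceeds 10%, over pairwise-ungapped columns; group
summaries average unordered same-group and cross-group pairs. Trees are
standard neighbour joining (via `ape::nj`, exact on additive matrices);
bootstrap resamples alignment columns, recomputes masked distances and
trees, and reports per-split support in [0, 100].

# Copy number

Each array is replaced by the unit minimising mean p-distance to its peers
(ties leftmost), with all downstream coordinates shifted. For a depth
track over the collapsed reference, `raw_ratio` is mean unit depth over
genome mean, `control_ratio` the same for a single-copy X control gene
(~0.5 in hemizygous males, ~1.0 in diploid females), and the per-haplotype
copy number is `cn = raw_ratio / control_ratio`. The division by the
control makes the ploidy correction explicit: it reproduces the
divide-by-two convention for females while also correcting the male X for
hemizygosity; `raw_ratio` is emitted alongside so the uncorrected
convention stays recoverable. Whether that correction is applied before or
after any other normalisation is immaterial here because `cn` is invariant
to uniform depth scaling. Note that on the desk-scale simulated genome the
X is a large genome fraction, so raw control ratios deviate from their
asymptotic values; `cn` cancels that shared factor, and the asymptotic
0.5/1.0 behaviour is checked on a genome with a 1 Mb autosome.

# Y-contig classification

For each contig and threshold T in {0, 5, 10, 15}, the profile records the
fraction of positions with female-read depth ≤ T (non-decreasing in T, an
asserted invariant). The cutoff is the mean fraction of seed contigs of
known Y homology at 15x minus 25 percentage points, clipped to (0, 1] —
the interpretation of the published "±25%" on the fraction scale, which
reproduces the 70–100% extraction band from seed means near 0.95. A
fraction histogram is returned for the bimodality check. The final manual
curation step is replaced by an explicit three-way rule: Y-candidate at or
above the cutoff, or within 0.1 below it with a best homology hit to the
Y class; not-Y below the band with non-Y (or, absent any evidence table,
no) homology support; ambiguous otherwise. All inputs to the original
judgment (fraction, best hit, length) are preserved in the output table.
Calls gate on the 15x threshold; the other thresholds are reported, not
gated on.

# Methylation

MF is methylated count over depth, per cytosine. Conversion is 1 − mean
lambda MF over spike-in sites at ≥ 10x. Uniting keeps the intersection of
sites present in all samples, then applies the coverage filter — at least
10x and at most the sample's 99.9th depth percentile (linear
interpolation; sites strictly above are removed) — in every sample. All
contexts are retained by default (a CG-only flag exists); opposite-strand
CpG calls stay distinct sites.

Per-cytosine group tests are Welch two-sample t-tests, two-sided. The
region-level statistics reported for the real data carry fractional
degrees of freedom, which identifies the Welch form; it is applied
uniformly at both scales. Windows hold exactly 20 cytosines and advance by
10; a window is significant when its mean per-cytosine p is ≤ 0.05. No
multiple-testing correction is applied at window level, matching the
window-averaged-p definition; a Benjamini–Hochberg option exists but
defaults off.

The power check on window tests needs a concrete reading of "low
dispersion": with 4 vs 2 samples and a 0.026 MF difference, per-cytosine
t-tests only gain power once counting noise is small, so the test fixes
depth 5,000 and Beta precision 1e5, where ≥ 80% of replicates flag at
least one window. At the study-realistic default depth (30x) the same
contrast is detectable at region level (per-sample means over hundreds of
sites) but not per cytosine — which mirrors how the region tests, not
individual windows, carry the genome-scale comparison.

# Expression enrichment

Per chromosome, a chi-squared goodness-of-fit of (up, down) against an
equal split of that chromosome's DE genes — the denominator is DE genes
only, matching the up/down framing — plus an exact binomial p for small
counts. The X-vs-autosome contrast is the 2x2 Fisher exact test
(hypergeometric, two-sided). The published "Monte Carlo" enrichment null is
under-specified; it is implemented as label permutation preserving totals,
with the add-one empirical p `(1 + #{perm ≥ obs}) / (n_perm + 1)` — a
valid, slightly conservative p whose discreteness the calibration test
accounts for by using large counts. Log fold changes are taken as log2
(the upstream DE convention). The zero-in-fertile summary compares |lfc|
of up-genes unexpressed in fertile testes with the remaining up-genes by a
pooled-variance Student t-test.

# Fine-mapping

Per marker, concordance is the fraction of individuals whose ancestry
matches the phenotype-predicted state (J if sterile, D if fertile), with
missing calls excluded pairwise (never imputed); the 2x2 Fisher exact p is
reported alongside (monomorphic markers get p = 1). The critical interval
is the maximal run of consecutive markers achieving the cohort-wide
maximum concordance — ties broken by longest run, then leftmost — and its
bounds are the run's first and last marker positions — marker-delimited,
as the published bounds are, rather than extrapolated to flanking
recombination breakpoints.
Counts and the Fisher p are reported for the run's consensus ancestry.
The GWAS utility transforms p values to −log10 and flags the uncorrected
5e-5 threshold (−log10 p = 4.30); the mixed-model association itself is an
upstream tool's job.

# Numerical choices and degenerate inputs

* Welch statistics are computed vectorised from closed forms (verified
  against `stats::t.test` to 1e-10); groups with identical values give
  t = 0, p = 1 rather than an error.
* The HMM runs entirely in log space with a two-term log-sum-exp; N bases
  emit uniformly in both states.
* NJ ties and representative-unit ties break to the leftmost/lowest label,
  making outputs deterministic.
* Every generator draws from a stream seed derived from the single run
  seed (`seed * 7919 + stream`, mod 2^31 − 1), so module outputs are
  independent of execution order and byte-reproducible.
* Problem sizes in tests and the analysis scripts are desk-scale by
  design: locus at x0.1, depth tracks of ~1 Mb, 2,000–2,500 methylation
  sites, 20 copy-number replicates per truth value.

# Known limitations

* The segmenter assumes motif-bearing units; motif-free repeat families
  would need the dotplot/GC evidence it does not consume.
* The truth alignment strategy (padding) is only adequate because
  divergence is substitution-only; with indels an external aligner would
  be required upstream of the distance module.
* The conservative add-one permutation p is biased upward by ties at small
  counts.
* The cohort model is a single-interval backcross; multi-generation
  pedigree structure and genotyping error are not modelled.
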