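---
title: "Methods: back-spliced junction quantification and circRNA differential analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: back-spliced junction quantification and circRNA differential analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its models and the design
choices behind them: what is computed, under which assumptions, which
parameters matter, and what the bundled simulator can and cannot tell you
about real data.

## 1. Quantification model

### Pseudo-circular references

A circRNA candidate is an interval `[start, end)` (BED convention, 0-based
half-open — the convention used internally everywhere; GTF input is
converted on read). Its *unit* sequence is the spliced exon chain inside the
interval when annotation covers it, otherwise the raw genomic slice;
minus-strand candidates are reverse-complemented first. The pseudo-reference
is the unit concatenated with itself. Because the result is exactly periodic,
every single-pass read from the circle — including any read crossing the
back-spliced junction (BSJ) — has a contiguous, ungapped image in the
pseudo-reference, and reads crossing the BSJ are exactly those whose image
crosses the internal fusion offset. Reads making more than one full pass
(circles shorter than the read) have no such image; the simulator therefore
refuses circles shorter than the read length unless explicitly allowed, and
the quantifier does not attempt multi-pass alignment.

The choice to default to *spliced* units (where annotation allows) rather
than the raw genomic span is forced by the internal aligner being unspliced:
reads from a multi-exon circle are spliced sequences and would not align
end-to-end to a genomic-span reference. Genomic mode remains available for
annotation-free or intergenic candidates.

### Candidate filtering and alignment

The aligner is a deliberate minimal design: exact k-mer seeds (k = 20,
sampled every 10 bp along the read, plus the final position) nominate
reference diagonals, and each diagonal is scored by a full-length Hamming
comparison — every reported hit is an end-to-end, ungapped placement.
Substitutions only; indels are out of scope, matching the simulator's error
model. Ties break deterministically: fewest mismatches, plus strand,
lowest reference id, leftmost position. This makes the whole pipeline
invariant to read order, which the test suite asserts.

A read pair is removed from the candidate pool (deemed linear) only when
*both* mates align end-to-end to some spliced transcript at `min_identity`
or better. The default is 0.98, and the reason is quantitative: a
BSJ-crossing read whose wrapped segment is m bases long differs from the
linear transcript in only those m positions (about 3/4 of them mismatch on
average). At a 0.95 cutoff over 100-bp reads, wraps of 5–9 bp are usually
absorbed as "linear", silently discarding about 3% of countable BSJ pairs;
at 0.98 the loss is below 0.5% while true linear reads (error-free, or with
the ≤2 substitutions a realistic error rate produces) still pass. The same
cutoff is used when counting forward-spliced junction (FSJ) reads, which are
linear evidence by definition — this also stops circular reads wrapping
≤5 bp from being miscounted as boundary-spanning.

### Counting rules

A pair counts as a BSJ pair for a candidate when both mates hit the same
pseudo-reference in convergent orientation (plus-strand mate leftmost) with
fragment span ≤ `max_insert` (default 1000 bp ≈ mean + 6 sd of the larger
insert component), and at least one mate's alignment fully covers a 10-bp
window centred on the fusion offset. The "10-bp region" criterion is read
as ≥ `span_flank` = 5 bp of aligned sequence on each side of the junction;
the alternative reading (10 bp per side) would discard reads the
pseudo-reference places unambiguously. Because the reference is periodic,
each mate's placement is expanded with its in-bounds period-shifted image
before pairing, so an interior mate may sit in either copy; without this, a
junction-crossing mate and its interior partner can end up in inconsistent
copies and a true pair is lost to the orientation check. Each pair is
credited to at most one candidate: best summed identity, then lowest
reference id.

FSJ reads are counted against two linear context references per candidate,
±250 bp around each boundary (comfortably more than twice the read length,
so no spanning read is truncated), spliced through the annotation when the
boundary is exonic in some transcript, genomic otherwise. A non-BSJ read
counts once per boundary whose junction it covers by ≥ 5 bp on both sides;
`fsj` is the sum over the two boundaries. Reads from pairs already counted
as BSJ pairs are excluded — they are circular reads.

### Expression and junction ratio

Expression is CPM: BSJ pairs per million mapped fragments, where "mapped"
counts linearly-filtered pairs plus BSJ pairs. The junction ratio defaults
to `2B / (2B + F)`: F sums spanning reads over the circle's *two* boundary
sites while B counts its *one* fused site, so B is doubled to put both
isoforms on a per-junction scale. The plain `B / (B + F)` variant is
available (`ratio_method = "simple"`); the choice of denominator is a
genuine open point and both are exposed. When `B + F = 0` the ratio is
undefined and reported as NA — never as 0, which would assert a measured
absence of circular splicing.

Candidates with no concordant BSJ pair after re-alignment are flagged
`filtered` (threshold `min_bsj`, default 1). This is the false-discovery
control the re-alignment buys: a candidate whose putative junction attracts
no read pair under the stringent window rule is marked rather than
propagated.

Gene-level counts (used only for TMM normalization, where relative counts
suffice) credit a fragment to a gene when the top-identity transcript hits
of both mates agree on exactly one gene; ties across genes and disagreeing
mates are discarded as ambiguous.

## 2. RNase R enrichment correction

RNase R degrades linear RNA with locus-dependent efficiency, so a treated
library distorts relative circRNA abundances. For circRNAs observed in both
a treated (r) and an untreated (m) library, the enrichment coefficient is
the odds ratio `Eff = (BSJ_r/FSJ_r) / (BSJ_m/FSJ_m)`; 1 means null
enrichment. Coefficients are undefined (and excluded from fitting) when any
denominator count is zero.

The coefficient distribution across circRNAs is fitted with a 1-D Gaussian
mixture by EM, k = 1..5 components, selected by BIC
(`-2·loglik + (3k−1)·log n`). Numerical choices:

* quantile-based initialization (means at the `i/(k+1)` quantiles), making
  the fit deterministic for a given coefficient vector;
* convergence when the log-likelihood changes by < 1e-6 (relative), at most
  500 iterations; the per-iteration likelihood trace is retained and tested
  for monotonicity;
* a standard-deviation floor of 1e-4 guards degenerate (constant) input;
* coefficients above the 99th percentile are winsorized before fitting —
  the coefficient is a ratio of count ratios and heavy-tailed at low
  counts;
* multi-component fits in which a component's sd collapses onto the floor
  are excluded from BIC selection: such a component is a spike on tied
  values (typically the winsorization cap), not population structure.

Fitting is on the natural coefficient scale; log-transformed displays are a
plotting convention. The "main" component is the one with the highest
mixing weight. Correction inverts the coefficient equation at the main
mean: `corrected BSJ_m = FSJ_m · (BSJ_r/FSJ_r) / main_mean`. For posterior
propagation, draws of the coefficient from the fitted mixture (truncated to
positive values, by rejection) replace the main mean, giving the induced
posterior of corrected counts that the DE-score integrates over
(Monte-Carlo; closed forms for the induced distribution do not exist).

What the correction can and cannot fix: the per-circRNA odds ratio cancels
locus-specific *linear* survival exactly, which is the dominant treatment
bias; residual error is each circRNA's deviation of `Eff` from the main
component mean, which a single regression coefficient cannot remove. The
deviation ratio `(CPM_r − CPM_m) / (0.5·(CPM_r + CPM_m))`, bounded in
(−2, 2) and antisymmetric, is the evaluation metric; its interquartile
range on simulated paired libraries shrinks after correction, which the
acceptance suite asserts.

## 3. Differential expression and splicing

Without replicates, the BSJ count k is modeled as Poisson with rate
`n·x` (n = mapped fragments / 1e6, so x is on the CPM scale); the posterior
of the rate under the implicit flat prior is Gamma(k+1, scale 1). The
DE-score of `z = log2(x2/x1)` is the posterior 5% quantile clipped at zero
when the mean change is non-negative, else the 95% quantile clipped from
above — a conservative generalized fold change: zero means not significant,
and |score| never exceeds |mean z| (asserted as an invariant). Quantiles
default to Monte-Carlo (10,000 draws, seeded); an exact route uses the fact
that a ratio of Gamma variables is a scaled F distribution, so
`z_q = log2((n1/n2)·(a2/a1)·qF(q; 2a2, 2a1))` with `a_i = k_i + 1`. The
clipping direction uses the analytic posterior mean (digamma differences),
keeping the sign decision deterministic even in Monte-Carlo mode.

The DS-score applies the same rule to `y = log2(r2/r1)` with junction-ratio
posteriors `Beta(c + ½, l + ½)`. The Jeffreys ½ offsets keep the posterior
proper at zero counts; the plain Beta(c, l) posterior is available behind
`offset = 0` for positive counts. The score is defined on y (the log fold
change of the ratio), the evident intent of the quantile rule.

P-values: Fisher's exact test on the 2×2 table of BSJ reads vs remaining
mapped reads (via `stats::fisher.test`), and an exact conditional
rate-ratio test for junction-ratio change — given `N = b1 + b2`, under the
null `b1 ~ Binomial(N, f1/(f1+f2))`, two-sided by summing outcome
probabilities not exceeding the observed one (`stats::binom.test`
implements exactly this rule). FSJ counts are the exposure because the test
targets splicing choice, not sequencing depth. Both tests are verified
against exhaustive enumeration in the test suite. Multiple testing is
controlled by Benjamini–Hochberg throughout.

With replicates: TMM normalization factors from gene-level counts (30%
trim on M-values, 5% on A, precision weights, reference library by
upper-quartile rule, factors rescaled to geometric mean 1 — the edgeR
implementation, cross-checked in the tests against an independent
straight-line implementation of the recipe), then a negative-binomial GLM
with log link and `log(lib.size · factor)` offsets. A *single common
dispersion* is estimated by Cox–Reid adjusted profile likelihood across
circRNAs — a deliberate simplification of tagwise/trended shrinkage,
appropriate because circRNA count matrices are shallow and the test suite
checks the resulting likelihood-ratio test holds its nominal type-I error
(0.05 within [0.03, 0.07] on null simulations, 2000 circRNAs, 3 vs 3).

## 4. Switching events

LC switching: |Δ junction ratio| > 0.3 *and* the ratio crosses 0.5 between
conditions. Both thresholds are strict inequalities; comparisons carry a
1e-9 numeric guard so count-derived ratios landing exactly on a boundary
(e.g. 22/40 − 10/40 in floating point) do not round into events.

CTU (circular transcript usage): among a gene's two highest-BSJ circRNAs,
the count share of the one with the longer genomic span; undefined for
genes with fewer than two supported circRNAs. CTU switching reuses the LC
rule (Δ > 0.3, 0.5 crossing) — no published numeric threshold exists for
it, so the symmetric convention is an artifact decision. With replicates,
the two major circRNAs are fixed from counts summed over *all* samples so
both groups rank the same pair (otherwise the two groups' CTU values could
describe different isoform pairs and be incomparable); per-group CTU is
computed on per-group summed counts, which is more stable than averaging
per-sample ratios, and a gene is eligible only when both major circRNAs are
detected in more than half of the samples of each group.

## 5. The simulator: what it emulates, and what it does not

`simulate_genome()` packs non-overlapping multi-exon genes (one transcript
each) onto random-sequence chromosomes. `simulate_circrnas()` draws exonic
circRNAs as runs of consecutive annotated exons, so circles can be nested
within genes — deliberately, because overlapping candidates are the hard
case for read assignment. `simulate_reads()` samples fragments from linear
transcripts at a fixed fold coverage and from circles with a rolling
origin; insert lengths come from the two-normal mixture
N(320, 70)/N(550, 70) with equal weights (the component weights are an
artifact default; only the components themselves are standard), clamped to
`[read_length, template length]`. Per-circRNA fragment abundance follows a
log-normal law (meanlog log 20, sdlog 1 by default) — a documented stand-in
for the long-tailed empirical abundance distributions of real circRNA data,
under which most circRNAs are low-expressed. Defaults are PE100, 10× linear
coverage, zero sequencing error.

Ground truth defines a junction-spanning read exactly as the quantifier's
window does (≥ 5 bp on each side of the junction); the any-overlap crossing
count is stored alongside. FSJ truth counts linear reads spanning each
candidate boundary *and* interior reads of other circles on the same
transcript — a non-wrapping circular read is a contiguous transcript
segment and is genuine linear evidence for a nested candidate's boundary;
any alignment-based quantifier sees it as such. Fragments detectable as BSJ
pairs are excluded from FSJ truth, mirroring the quantifier. Read names
encode provenance (origin, template start, insert), so tests recount the
truth independently; the quantifier never parses read names.

In-silico RNase R (`apply_rnase_r()`) draws a per-circRNA coefficient from
a configurable mixture (default 0.7·N(0.95, 0.02) + 0.3·N(0.7, 0.1),
clipped to (0, 1]) and retains circular fragments with probability
`Eff · linear_survival` while linear fragments survive at
`linear_survival` — binomial thinning whose realized odds ratio matches the
drawn coefficient in expectation, never inventing reads.

The count-level generator `simulate_paired_counts()` draws deep paired
BSJ/FSJ counts (log-normal means around 2000) with *heterogeneous*
per-circRNA linear survival (log-odds sd 0.5 around a median of 0.25) and
thins them binomially. The enrichment-correction studies run on this
generator rather than on read-level libraries: an Eq.-style coefficient
estimate has relative sampling noise ≈ sqrt(Σ 1/count) over four counts,
so separating mixture components 0.25 apart requires per-circRNA counts in
the thousands — orders of magnitude beyond what a read-level simulation of
sensible size produces. The survival heterogeneity is the biologically
motivated bias (RNase R digests linear RNA with locus-dependent
efficiency) that the odds-ratio correction removes; without it, pre- and
post-correction deviations carry identical residuals and no dispersion
improvement is possible for any method of this form.

What the simulator does *not* emulate — and hence what green tests do not
certify about real data: indels and quality-dependent errors, rRNA
carry-over, intron retention and alternative internal splicing of circles,
multi-pass (rolling-circle) reads, genomic repeats and paralogy (reference
sequences are i.i.d. random, so seed uniqueness is optimistic), fragment
GC bias, and multiple transcripts per gene.

## 6. Problem sizes and runtime envelopes

The test suite and acceptance script choose desk-scale sizes: the headline
simulation uses one 800-kb chromosome, 70 genes, 220 circRNAs and roughly
12,000 read pairs (tens of seconds end to end); correction studies use 500
circRNAs at count level; GLM calibration uses 2000 × 6 count matrices;
exact-test enumeration covers all 2×2 tables with row sums ≤ 30. These
sizes were picked so each property is measured with comfortable
statistical margin while the whole suite stays interactive.

## 7. Known limitations

* The aligner is ungapped and transcriptome-bound; spliced genome
  alignment, indels and novel-junction discovery are out of scope (BSJ
  *detection* is upstream of this package by design).
* Unknown-strand candidates are processed as plus-strand; junction counting
  is strand-agnostic.
* The correction model shares one regression coefficient (the main mixture
  component mean) across circRNAs; circRNAs from minor components retain a
  proportional bias after correction.
* The replicate GLM uses a common dispersion; strong per-circRNA dispersion
  heterogeneity will make the test anticonservative for the most variable
  loci.
* With fewer than 20 finite enrichment coefficients the mixture fit refuses
  to run; the error message points to supplying a model fitted on
  comparable paired libraries (no empirical prior library ships with the
  package).
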