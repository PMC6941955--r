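# bsjquant

Accurate quantification and differential analysis of circular RNAs
(circRNAs) from paired-end RNA-seq.

## The problem

A circRNA is defined by its back-spliced junction (BSJ), the non-canonical
3′→5′ junction formed when a downstream splice donor joins an upstream
acceptor. Standard RNA-seq aligners cannot place reads across this fused
site, so BSJ-read counts — the only direct evidence of circRNA expression —
are systematically underestimated and contaminated by false positives.
Two further biases complicate quantification: RNase R, the exonuclease used
to enrich circRNAs by degrading linear RNA, works with locus-dependent
efficiency; and the circular isoform competes with its linear counterpart
for the same splice sites, so expression alone misses regulatory shifts in
*splicing choice*.

`bsjquant` addresses all three with the pipeline idiom used by
re-alignment-based circRNA quantifiers:

1. **Pseudo-circular re-alignment.** For each candidate BSJ (a BED interval
   from any upstream detector), the back-spliced region — the spliced exon
   chain when annotation covers it, otherwise the genomic slice — is
   duplicated head-to-tail. Any single-pass read crossing the BSJ then has a
   contiguous, gap-free image crossing the internal fusion point. Read pairs
   without end-to-end linear evidence are re-aligned to these
   pseudo-references with an internal seed-and-extend (ungapped) aligner; a
   pair counts as a BSJ pair when it maps concordantly with one mate
   covering a 10-bp window centred on the fusion point.
2. **Junction ratio.** With *B* BSJ pairs and *F* forward-spliced junction
   (FSJ) reads spanning the circle's two boundaries, the fraction of
   splicing going to the circular isoform is `2B / (2B + F)`
   (FSJ is summed over two boundary sites, BSJ has one fused site).
   Expression is reported as CPM: BSJ counts per million mapped reads.
3. **RNase R correction.** For libraries sequenced with and without RNase R,
   the per-circRNA enrichment coefficient
   `Eff = (BSJ_r / FSJ_r) / (BSJ_m / FSJ_m)` is fitted across circRNAs with
   a 1-D Gaussian mixture (EM, BIC model selection). The mean of the
   highest-weight component inverts the equation to recover untreated-scale
   counts, `corrected = FSJ_m · (BSJ_r / FSJ_r) / main_mean`, and the fitted
   mixture serves as the coefficient posterior for downstream scoring.
4. **DE/DS scores and tests.** Without replicates, expression change is
   scored by a generalized fold change: the Poisson count posterior is
   Gamma(k+1, 1), and the DE-score is the 5% posterior quantile of
   `z = log2(x2/x1)` clipped at zero (95% quantile when the mean change is
   negative) — a conservative fold change where 0 means "not significant".
   The DS-score applies the same rule to `y = log2(r2/r1)` with
   Beta-posterior junction ratios. Exact tests (Fisher on BSJ vs library
   totals; an exact conditional rate-ratio test on BSJ-per-FSJ rates)
   give p-values; with replicates, a TMM-normalized negative-binomial GLM
   with likelihood-ratio tests is used.
5. **Switching events.** Linear-circular (LC) switching: the junction ratio
   changes by more than 0.3 *and* crosses 0.5 (major ↔ minor isoform flip).
   Circular-transcript-usage (CTU) switching applies the same rule to the
   BSJ share of the longest-span circRNA among a gene's two major circRNAs.

A paired-end read simulator with full per-fragment ground truth (read names
carry provenance) backs every claim with testable oracles.

## Worked example

```r
library(bsjquant)
library(data.table)

genome <- simulate_genome(n_chrom = 1, chrom_len = 3e5, n_genes = 30,
                          exons_per_gene = c(3, 8), seed = 1)
#> genome_sim: 1 chromosome(s) (300000 bp), 30 genes, 168 exons
circs <- simulate_circrnas(genome, n_circ = 50, seed = 2)
reads <- simulate_reads(genome, circs, sim_config(seed = 3))
#> sim_reads: 3472 read pairs (50 circRNAs)

quant <- quantify_library(reads, genome, circs, library_id = "demo")
quant[1:5, .(id, chrom, start, end, bsj, fsj, cpm, junction_ratio)]
#>          id  chrom start   end   bsj   fsj       cpm junction_ratio
#> 1: circ0001   chr1  3935  5245     3    12  869.3132      0.3333333
#> 2: circ0002   chr1  5799  8607     2     0  579.5422      1.0000000
#> 3: circ0003   chr1  6847  7237    13    32 3767.0241      0.4482759
#> 4: circ0004   chr1 10386 11913     2    33  579.5422      0.1081081
#> 5: circ0005   chr1 11675 12538    12    33 3477.2530      0.4210526
```

`circ0003` has 13 BSJ pairs and 32 boundary-spanning linear reads, so
2·13/(2·13+32) ≈ 0.45 of splicing at that locus goes circular; its CPM of
3767 reflects the small demo library (3451 mapped fragments). Estimates
track the simulator's truth:

```r
m <- merge(quant[, .(id, junction_ratio)], reads$truth, by = "id")
cor(m$junction_ratio, m$junction_ratio_true, use = "complete.obs")
#> [1] 1.0000
```

RNase R correction on paired treated/untreated junction counts:

```r
fit <- correct_paired_counts(simulate_paired_counts(n_circ = 500, seed = 5))
fit$model
#> enrichment_model: 2 component(s) fitted on 500 coefficients
#>   main component mean: 0.9511
#>         mean         sd    weight
#> 1: 0.9511117 0.04811794 0.6760642
#> 2: 0.7000687 0.10655688 0.3239358
```

The fit recovers the simulated coefficient mixture (0.95 / 0.70 at weights
0.7 / 0.3), and correction tightens the deviation ratio between treated and
untreated expression from an IQR of 0.560 to 0.203.

Scoring an expression change (12 vs 85 BSJ reads at comparable depth):

```r
de_score(12, 1.2, 85, 1.1, seed = 6)
#> $score
#> [1] 2.210991
#> $mean_log2fc
#> [1] 2.898899
```

The posterior mean change is 2.9 log2 units; the conservative DE-score
(posterior 5% quantile) is 2.2 — strongly supported upregulation.

The full chain (simulate → quantify → correct → DE → switching) runs from a
YAML configuration via `run_pipeline()`, or from the shell through the thin
dispatcher in `exec/bsjquant`.

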