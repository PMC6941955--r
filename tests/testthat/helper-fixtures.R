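## Shared fixtures, built in code.

## deterministic toy genome: one chromosome, one plus-strand and one
## minus-strand gene with known exon structure
toy_genome <- function(seed = 421L) {
  set.seed(seed)
  chrom <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
                 collapse = "")
  exons <- data.table::data.table(
    gene_id = c(rep("gA", 3), rep("gB", 2)),
    tx_id = c(rep("gA.t1", 3), rep("gB.t1", 2)),
    chrom = "chr1",
    strand = c(rep("+", 3), rep("-", 2)),
    start = c(200L, 700L, 1300L, 3000L, 3800L),
    end = c(500L, 1000L, 1700L, 3500L, 4300L),
    exon_rank = c(1L, 2L, 3L, 1L, 2L)
  )
  genes <- exons[, .(chrom = chrom[1], strand = strand[1],
                     start = min(start), end = max(end)), by = gene_id]
  g <- list(chroms = c(chr1 = chrom), genes = genes, exons = exons)
  class(g) <- "genome_sim"
  g
}

## candidate on consecutive exons of the toy genome
toy_candidate <- function(genome, gene = "gA", from = 1L, to = 2L,
                          id = "c1") {
  te <- genome$exons[gene_id == gene][order(start)][from:to]
  data.table::data.table(
    id = id, chrom = te$chrom[1], start = min(te$start), end = max(te$end),
    strand = te$strand[1], gene_id = gene, tx_id = te$tx_id[1],
    exons = list(as.matrix(te[, .(start, end)]))
  )
}

## small simulated scene reused by classifier/quantifier tests
small_scene <- function(n_genes = 12L, n_circ = 20L, chrom_len = 15e4,
                        seed = 71L, cfg = NULL) {
  g <- simulate_genome(1, chrom_len, n_genes, c(3, 8), seed = seed)
  circs <- simulate_circrnas(g, n_circ, seed = seed + 1L)
  if (is.null(cfg)) cfg <- sim_config(seed = seed + 2L)
  sr <- simulate_reads(g, circs, cfg)
  list(genome = g, circs = circs, reads = sr)
}

## independent recomputation of junction-spanning truth from provenance tags
## (never uses the simulator's stored tables)
recount_bsj_from_names <- function(reads, circ_lens, flank = 5L) {
  nm <- names(reads$r1)
  parts <- data.table::tstrsplit(nm, ":", fixed = TRUE)
  circ <- grepl("^C:", nm)
  out <- integer(0)
  ids <- character(0)
  rl <- nchar(reads$r1[1])
  for (cid in names(circ_lens)) {
    sel <- circ & parts[[2]] == cid
    if (!any(sel)) { out <- c(out, 0L); ids <- c(ids, cid); next }
    s <- as.integer(parts[[3]][sel])
    ins <- as.integer(parts[[4]][sel])
    L <- circ_lens[[cid]]
    crosses <- function(a, b) a <= L - flank & b >= L + flank
    n <- sum(crosses(s, s + rl) | crosses(s + ins - rl, s + ins))
    out <- c(out, n); ids <- c(ids, cid)
  }
  stats::setNames(out, ids)
}
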