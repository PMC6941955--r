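## Synthetic genome/annotation generator. Genes are packed left to right
## along each chromosome with random intergenic gaps; one transcript per
## gene carries the full exon chain. Coordinates: 0-based half-open.

#' Simulate a genome with gene annotation
#'
#' Generates random chromosome sequences and places non-overlapping multi-exon
#' genes on them. Each gene carries one transcript spanning its full exon
#' chain. Deterministic for a fixed seed.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in bp.
#' @param n_genes total number of genes to place.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param seed integer RNG seed.
#' @param exon_len range of exon lengths (bp).
#' @param intron_len range of intron lengths (bp).
#' @param intergenic_len range of gaps between genes (bp).
#' @return object of class `genome_sim`: list with `chroms` (named character
#'   vector of sequences), `genes` and `exons` data.tables.
#' @examples
#' g <- simulate_genome(1, 50000, 5, c(3, 5), seed = 1)
#' g
#' @export
simulate_genome <- function(n_chrom = 1L, chrom_len = 1e5, n_genes = 20L,
                            exons_per_gene = c(3L, 8L), seed = 1L,
                            exon_len = c(120L, 400L),
                            intron_len = c(200L, 1200L),
                            intergenic_len = c(200L, 800L)) {
  stopifnot(n_chrom >= 1, chrom_len > 0, n_genes >= 1,
            length(exons_per_gene) == 2, exons_per_gene[1] >= 1)
  set.seed(seed)
  chroms <- setNames(vapply(seq_len(n_chrom), function(i) random_dna(chrom_len),
                            character(1)),
                     paste0("chr", seq_len(n_chrom)))

  genes <- list()
  exons <- list()
  ci <- 1L
  cursor <- 0L
  for (gi in seq_len(n_genes)) {
    ne <- sample(seq(exons_per_gene[1], exons_per_gene[2]), 1L)
    elen <- sample(seq(exon_len[1], exon_len[2]), ne, replace = TRUE)
    ilen <- if (ne > 1) sample(seq(intron_len[1], intron_len[2]), ne - 1L,
                               replace = TRUE) else integer(0)
    gap <- sample(seq(intergenic_len[1], intergenic_len[2]), 1L)
    span <- sum(elen) + sum(ilen)
    placed <- FALSE
    while (!placed) {
      if (cursor + gap + span <= chrom_len) {
        gstart <- cursor + gap
        placed <- TRUE
      } else if (ci < n_chrom) {
        ci <- ci + 1L
        cursor <- 0L
      } else {
        stop(sprintf(paste0("cannot place %d genes: chromosome space exhausted ",
                            "at gene %d (need %d bp more on %s)"),
                     n_genes, gi, cursor + gap + span - chrom_len,
                     names(chroms)[ci]), call. = FALSE)
      }
    }
    starts <- gstart + cumsum(c(0L, head(elen, -1L) + ilen))
    gid <- sprintf("gene%04d", gi)
    strand <- sample(c("+", "-"), 1L)
    genes[[gi]] <- data.table(gene_id = gid, chrom = names(chroms)[ci],
                              strand = strand, start = gstart,
                              end = gstart + span)
    exons[[gi]] <- data.table(gene_id = gid, tx_id = paste0(gid, ".t1"),
                              chrom = names(chroms)[ci], strand = strand,
                              start = as.integer(starts),
                              end = as.integer(starts + elen),
                              exon_rank = seq_len(ne))
    cursor <- gstart + span
  }
  out <- list(chroms = chroms, genes = rbindlist(genes), exons = rbindlist(exons))
  class(out) <- "genome_sim"
  out
}

#' @export
print.genome_sim <- function(x, ...) {
  cat(sprintf("genome_sim: %d chromosome(s) (%s bp), %d genes, %d exons\n",
              length(x$chroms),
              paste(nchar(x$chroms), collapse = "+"),
              nrow(x$genes), nrow(x$exons)))
  invisible(x)
}

#' Spliced transcript sequences of a simulated genome
#'
#' @param genome a `genome_sim` object.
#' @return named character vector, one spliced (strand-corrected) sequence
#'   per transcript.
#' @export
transcript_sequences <- function(genome) {
  ex <- genome$exons
  txs <- unique(ex$tx_id)
  out <- vapply(txs, function(tid) {
    te <- ex[tx_id == tid][order(start)]
    splice_seq(genome$chroms[[te$chrom[1]]],
               as.matrix(te[, .(start, end)]), te$strand[1])
  }, character(1))
  names(out) <- txs
  out
}

#' Assemble a `genome_sim` object from FASTA + GTF files
#'
#' @param fasta_path genome FASTA.
#' @param gtf_path annotation GTF.
#' @return `genome_sim` object.
#' @export
genome_from_files <- function(fasta_path, gtf_path) {
  chroms <- read_fasta(fasta_path)
  ann <- read_gtf(gtf_path)
  ex <- ann$exons
  ex[, chrom := as.character(chrom)]
  bad <- ex[end > nchar(chroms[chrom]) | start < 0]
  if (nrow(bad) > 0) stop("GTF exon outside chromosome bounds", call. = FALSE)
  out <- list(chroms = chroms, genes = ann$genes, exons = ex)
  class(out) <- "genome_sim"
  out
}

#' Sample exonic circRNA candidates from a simulated genome
#'
#' Each candidate is a run of consecutive annotated exons of one transcript;
#' its back-spliced region runs from the first exon's start to the last
#' exon's end.
#'
#' @param genome a `genome_sim` object.
#' @param n_circ number of distinct candidates to draw.
#' @param seed RNG seed.
#' @param min_spliced_len minimum spliced circle length (bp); must be at least
#'   the read length used downstream.
#' @param max_exons maximum exons per circle.
#' @return data.table of class `circ_candidates`: id, chrom, start, end,
#'   strand, gene_id, tx_id, n_exons, spliced_len, plus a list column `exons`
#'   of 0-based half-open exon interval matrices.
#' @export
simulate_circrnas <- function(genome, n_circ = 200L, seed = 1L,
                              min_spliced_len = 150L, max_exons = 4L) {
  set.seed(seed)
  ex <- genome$exons
  txs <- unique(ex$tx_id)
  picked <- list()
  seen <- character(0)
  attempts <- 0L
  max_attempts <- 200L * n_circ
  while (length(picked) < n_circ && attempts < max_attempts) {
    attempts <- attempts + 1L
    tid <- sample(txs, 1L)
    te <- ex[tx_id == tid][order(start)]
    ne <- nrow(te)
    k <- sample(seq_len(min(max_exons, ne)), 1L)
    i0 <- sample(seq_len(ne - k + 1L), 1L)
    run <- te[i0:(i0 + k - 1L)]
    splen <- sum(run$end - run$start)
    if (splen < min_spliced_len) next
    key <- paste(run$chrom[1], min(run$start), max(run$end))
    if (key %in% seen) next
    seen <- c(seen, key)
    picked[[length(picked) + 1L]] <- data.table(
      chrom = run$chrom[1], start = min(run$start), end = max(run$end),
      strand = run$strand[1], gene_id = run$gene_id[1], tx_id = tid,
      n_exons = k, spliced_len = splen,
      exons = list(as.matrix(run[, .(start, end)]))
    )
  }
  if (length(picked) < n_circ) {
    stop(sprintf("could only draw %d distinct circRNA candidates (asked %d)",
                 length(picked), n_circ), call. = FALSE)
  }
  out <- rbindlist(picked)
  setorder(out, chrom, start, end)
  out[, id := sprintf("circ%04d", seq_len(.N))]
  setcolorder(out, "id")
  class(out) <- c("circ_candidates", class(out))
  out[]
}
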