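## Expression values and junction ratios from junction counts, plus
## gene-level fragment counting (feeds TMM normalization only).

#' BSJ counts per million mapped reads
#'
#' @param bsj BSJ count(s).
#' @param total_mapped total mapped fragments in the library (> 0).
#' @return numeric CPM.
#' @export
compute_cpm <- function(bsj, total_mapped) {
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0", call. = FALSE)
  bsj * 1e6 / total_mapped
}

#' Junction ratio of a circRNA
#'
#' Default (`method = "paired"`) is 2B / (2B + F): FSJ reads are summed over
#' the two boundary sites of the circle while BSJ reads have a single fused
#' site, so BSJ counts are doubled to put both isoforms on the same
#' per-junction scale. `method = "simple"` gives B / (B + F). When both
#' counts are zero the ratio is undefined and returned as NA.
#'
#' @param bsj,fsj junction counts (vectorized).
#' @param method `"paired"` (default) or `"simple"`.
#' @return numeric in `[0, 1]`, or NA where undefined.
#' @export
compute_junction_ratio <- function(bsj, fsj, method = c("paired", "simple")) {
  method <- match.arg(method)
  check_counts(bsj, fsj)
  num <- if (method == "paired") 2 * bsj else bsj
  den <- num + fsj
  ifelse(den == 0, NA_real_, num / den)
}

#' BSJ-equivalent of an abundance/effective-length estimate
#'
#' Compatibility utility for external estimators that report transcript
#' abundance instead of junction read counts.
#'
#' @param num_reads estimated read abundance.
#' @param effective_length effective transcript length (> 0).
#' @return `num_reads / effective_length`.
#' @export
sailfish_bsj_equivalent <- function(num_reads, effective_length) {
  if (any(effective_length <= 0)) {
    stop("effective_length must be > 0", call. = FALSE)
  }
  num_reads / effective_length
}

#' Gene-level fragment counts from linear alignments
#'
#' A fragment is credited to a gene when the top-identity transcript hits of
#' both mates agree on that single gene; fragments whose best hits tie
#' across two genes, or whose mates disagree, are discarded as ambiguous.
#'
#' @param hits1,hits2 per-(read, reference) hit tables from [align_pool()]
#'   over the spliced transcriptome.
#' @param tx_genes character vector mapping reference index to gene id.
#' @param gene_ids universe of gene ids for the output.
#' @return named integer vector of fragment counts per gene.
#' @export
count_genes <- function(hits1, hits2, tx_genes, gene_ids = sort(unique(tx_genes))) {
  counts <- setNames(integer(length(gene_ids)), gene_ids)
  top_genes <- function(h) {
    if (nrow(h) == 0) {
      return(data.table(read = integer(0), gene = character(0)))
    }
    h <- copy(h)[, gene := tx_genes[ref]]
    h[, best := max(identity), by = read]
    unique(h[identity == best, .(read, gene)])
  }
  g1 <- top_genes(hits1)
  g2 <- top_genes(hits2)
  both <- merge(g1, g2, by = c("read", "gene"))
  ## also require uniqueness: exactly one shared gene per fragment
  nshared <- both[, .N, by = read]
  uni <- nshared[N == 1L]$read
  tab <- both[read %in% uni, .N, by = gene]
  counts[tab$gene] <- tab$N
  counts
}

#' Quantify circRNA expression in one library
#'
#' Runs the full per-library chain: linear-evidence filtering of read pairs,
#' pseudo-circular re-alignment, BSJ/FSJ counting, CPM and junction-ratio
#' computation, and gene-level counting for normalization.
#'
#' @param reads list with `r1`/`r2` named character vectors (one library).
#' @param genome `genome_sim` object.
#' @param cands candidate table (BED-derived or simulated).
#' @param span_flank junction window half-width (bp).
#' @param max_insert maximum fragment span on the pseudo-reference.
#' @param min_bsj candidates below this BSJ count are flagged `filtered`.
#' @param filter_min_identity identity cutoff of the linear-evidence filter.
#' @param align_min_identity identity cutoff for pseudo-reference and
#'   boundary-context hits.
#' @param ratio_method junction-ratio formula, see [compute_junction_ratio()].
#' @param mode pseudo-reference mode, see [build_pseudo_ref()].
#' @param k,stride aligner seeding parameters.
#' @param library_id label recorded on the output.
#' @return data.table of class `circ_quant`: id, chrom, start, end, strand,
#'   bsj, fsj, cpm, junction_ratio, filtered; attributes `total_mapped`,
#'   `n_pairs`, `gene_counts`, `library_id`.
#' @export
quantify_library <- function(reads, genome, cands, span_flank = 5L,
                             max_insert = 1000L, min_bsj = 1L,
                             filter_min_identity = 0.98,
                             align_min_identity = 0.95,
                             ratio_method = "paired", mode = "auto",
                             k = 20L, stride = 10L, library_id = "lib1") {
  if (inherits(reads, "sim_reads")) reads <- list(r1 = reads$r1, r2 = reads$r2)
  linear_refs <- transcript_sequences(genome)
  sel <- select_candidate_reads(reads, linear_refs,
                                min_identity = filter_min_identity,
                                k = k, stride = stride)
  prefs <- build_pseudo_refs(cands, genome, mode)
  hits <- align_to_pseudo(sel$pool, prefs, k = k, stride = stride,
                          min_identity = align_min_identity)
  bsj <- count_bsj(hits, prefs, sel$pool, span_flank = span_flank,
                   max_insert = max_insert)
  contexts <- build_boundary_contexts(genome, cands)
  fsj <- count_fsj(reads, genome, cands, span_flank = span_flank,
                   exclude_pairs = bsj$assignments$read_id,
                   min_identity = filter_min_identity, k = k, stride = stride,
                   contexts = contexts)
  n_linear <- sum(!sel$keep)
  total_mapped <- n_linear + nrow(bsj$assignments)

  tx_ids <- names(linear_refs)
  tx_genes <- genome$exons[match(tx_ids, tx_id)]$gene_id
  gene_counts <- count_genes(sel$linear_hits$r1, sel$linear_hits$r2, tx_genes,
                             sort(unique(genome$genes$gene_id)))

  out <- data.table(
    id = cands$id, chrom = cands$chrom, start = cands$start, end = cands$end,
    strand = cands$strand,
    bsj = as.integer(bsj$counts[cands$id]),
    fsj = as.integer(fsj[cands$id])
  )
  out[, cpm := compute_cpm(bsj, total_mapped)]
  out[, junction_ratio := compute_junction_ratio(bsj, fsj, ratio_method)]
  out[, filtered := bsj < min_bsj]
  if ("gene_id" %in% names(cands)) out[, gene_id := cands$gene_id]
  setattr(out, "total_mapped", total_mapped)
  setattr(out, "n_pairs", length(reads$r1))
  setattr(out, "gene_counts", gene_counts)
  setattr(out, "library_id", library_id)
  setattr(out, "class", c("circ_quant", class(out)))
  out[]
}

#' @export
print.circ_quant <- function(x, ...) {
  ## subsets lose the library attributes; fall through to the table print
  if (!is.null(attr(x, "total_mapped"))) {
    cat(sprintf(
      "circ_quant [%s]: %d candidates, %d with BSJ support, %s mapped fragments\n",
      attr(x, "library_id") %||% "?", nrow(x), sum(x$bsj > 0, na.rm = TRUE),
      format(attr(x, "total_mapped"), big.mark = ",")))
  }
  NextMethod()
}

#' Write a per-library quantification table
#'
#' @param quant `circ_quant` table.
#' @param path output TSV.
#' @param seed,cfg_hash provenance for the header line.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(quant, path, seed = NA, cfg_hash = NA) {
  x <- as.data.frame(quant)
  x$library_id <- attr(quant, "library_id")
  write_tsv(x, path, seed = seed, cfg_hash = cfg_hash)
}
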