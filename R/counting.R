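## BSJ and FSJ counting.
##
## BSJ: a candidate read pair counts once for a circRNA when both mates hit
## the same pseudo-reference in convergent orientation with a plausible
## insert, and at least one mate's alignment fully covers the 10-bp window
## centred on the fusion point (span_flank bp on each side). Each pair is
## credited to at most one candidate (best summed identity, then lowest
## reference id).
##
## FSJ: reads aligned linearly across a circRNA boundary. Two linear context
## references (+/- 250 bp around the 5' and 3' boundary, spliced through the
## annotation when available) are built per candidate; a non-BSJ read counts
## once per boundary whose junction it covers by >= span_flank bp on both
## sides. fsj = count at 5' boundary + count at 3' boundary.

#' Count back-spliced junction read pairs
#'
#' @param hits list from [align_to_pseudo()] (`hits1`, `hits2`, `ref_ids`).
#' @param pseudo_refs named list of `pseudo_ref` objects (fusion offsets).
#' @param pool the candidate pool the hits were computed from (for read ids).
#' @param span_flank bases required on each side of the fusion point
#'   (default 5: a 10-bp window).
#' @param max_insert maximum plausible fragment span on the pseudo-reference.
#' @return list: `counts` (named integer per candidate), `assignments`
#'   (data.table pair index / read name -> candidate).
#' @export
count_bsj <- function(hits, pseudo_refs, pool, span_flank = 5L,
                      max_insert = 1000L) {
  ids <- names(pseudo_refs)
  counts <- setNames(integer(length(ids)), ids)
  h1 <- hits$hits1
  h2 <- hits$hits2
  empty <- data.table(pair = integer(0), read_id = character(0),
                      cand = character(0))
  if (nrow(h1) == 0 || nrow(h2) == 0) {
    return(list(counts = counts, assignments = empty))
  }
  ## the pseudo-reference is exactly periodic with period = unit length, so
  ## every end-to-end placement has an equivalent image shifted by one unit;
  ## expand hits with in-bounds images so mate pairing can choose consistent
  ## copies (an interior mate must be allowed to sit in either copy).
  ul <- vapply(pseudo_refs, function(p) p$unit_length, numeric(1))
  expand_period <- function(h) {
    up <- copy(h)[, `:=`(start = start + as.integer(ul[ref]),
                         end = end + as.integer(ul[ref]))]
    dn <- copy(h)[, `:=`(start = start - as.integer(ul[ref]),
                         end = end - as.integer(ul[ref]))]
    out <- rbind(h, up[end <= 2L * ul[ref]], dn[start >= 1L])
    unique(out)
  }
  m <- merge(expand_period(h1), expand_period(h2), by = c("read", "ref"),
             suffixes = c("1", "2"), allow.cartesian = TRUE)
  if (nrow(m) == 0) return(list(counts = counts, assignments = empty))
  fo <- vapply(pseudo_refs, function(p) p$fusion_offset, numeric(1))
  m[, `:=`(
    convergent = strand1 != strand2,
    span = pmax(end1, end2) - pmin(start1, start2) + 1L
  )]
  ## the plus-strand mate must be the leftmost of the pair
  m[, plus_left := (strand1 == "+" & start1 <= start2) |
                   (strand2 == "+" & start2 <= start1)]
  w_lo <- fo[m$ref] - span_flank + 1L  # 1-based first window position
  w_hi <- fo[m$ref] + span_flank       # 1-based last window position
  m[, covers := (start1 <= w_lo & end1 >= w_hi) | (start2 <= w_lo & end2 >= w_hi)]
  m <- m[convergent & plus_left & span <= max_insert & covers == TRUE]
  if (nrow(m) == 0) return(list(counts = counts, assignments = empty))
  ## one candidate per pair: best summed identity, then lowest reference id
  m[, score := identity1 + identity2]
  setorder(m, read, -score, ref, start1, start2)
  m <- m[, .SD[1L], by = read]
  tab <- m[, .N, by = ref]
  counts[tab$ref] <- tab$N
  assignments <- data.table(pair = m$read,
                            read_id = names(pool$r1)[m$read],
                            cand = ids[m$ref])
  list(counts = counts, assignments = assignments)
}

## transcript-coordinate cut point of a genomic boundary.
## gpos: 0-based genomic cut (junction lies between gpos-1 and gpos).
## Returns the 0-based cut index within the spliced (strand-corrected)
## transcript string, or NA when the flanking exonic base is absent.
tx_cutpoint <- function(exons, strand, gpos, side) {
  exons <- exons[order(exons$start), ]
  ## base that must be exonic: first circle base (5' side) / last (3' side)
  need <- if (side == "5p") gpos else gpos - 1L
  inside <- any(exons$start <= need & need < exons$end)
  if (!inside) return(NA_integer_)
  plus_cut <- sum(pmax(0L, pmin(exons$end, gpos) - exons$start))
  txlen <- sum(exons$end - exons$start)
  if (identical(strand, "-")) txlen - plus_cut else plus_cut
}

#' Build linear boundary context references for FSJ counting
#'
#' @param genome `genome_sim` object.
#' @param cands candidate table.
#' @param flank context half-width in bp (250 by default, comfortably more
#'   than twice the read length).
#' @return data.table: cand, boundary (5p/3p), seq, bo (0-based cut index of
#'   the junction inside the context), mode (spliced/genomic).
#' @export
build_boundary_contexts <- function(genome, cands, flank = 250L) {
  tx_seqs <- transcript_sequences(genome)
  ex <- genome$exons
  rows <- list()
  for (i in seq_len(nrow(cands))) {
    cd <- cands[i, ]
    for (side in c("5p", "3p")) {
      gpos <- if (side == "5p") cd$start else cd$end
      ctx_seq <- NULL
      ## prefer a spliced context from a transcript carrying the boundary
      tids <- unique(ex[chrom == cd$chrom & start <= gpos + 1L &
                        end >= gpos - 1L]$tx_id)
      if (!is.null(cd$tx_id) && !is.na(cd$tx_id) && cd$tx_id %in% names(tx_seqs)) {
        tids <- unique(c(cd$tx_id, tids))
      }
      for (tid in tids) {
        te <- ex[tx_id == tid]
        cut <- tx_cutpoint(as.data.frame(te[, .(start, end)]), te$strand[1],
                           gpos, side)
        if (is.na(cut)) next
        ## tx_cutpoint returns the cut on the strand-corrected string
        txs <- tx_seqs[[tid]]
        lo <- max(0L, cut - flank)
        hi <- min(nchar(txs), cut + flank)
        if (cut - lo < 1L || hi - cut < 1L) next  # junction at transcript edge
        ctx_seq <- seq_slice(txs, lo, hi)
        rows[[length(rows) + 1L]] <- data.table(
          cand = cd$id, boundary = side, seq = ctx_seq, bo = cut - lo,
          mode = "spliced")
        break
      }
      if (is.null(ctx_seq)) {
        chrom_seq <- genome$chroms[[cd$chrom]]
        lo <- max(0L, gpos - flank)
        hi <- min(nchar(chrom_seq), gpos + flank)
        if (gpos - lo >= 1L && hi - gpos >= 1L) {
          rows[[length(rows) + 1L]] <- data.table(
            cand = cd$id, boundary = side,
            seq = seq_slice(chrom_seq, lo, hi), bo = gpos - lo,
            mode = "genomic")
        }
      }
    }
  }
  rbindlist(rows)
}

#' Count forward-spliced junction reads
#'
#' @param reads list with `r1`/`r2` named character vectors (the full
#'   library).
#' @param genome `genome_sim` object.
#' @param cands candidate table.
#' @param span_flank bases required on each side of the boundary.
#' @param exclude_pairs read names of pairs already counted as BSJ.
#' @param min_identity,k,stride alignment parameters; the default identity
#'   cutoff matches the linear-evidence filter (FSJ reads are linear
#'   evidence), keeping back-spliced reads with short wrapped overhangs from
#'   passing as boundary-spanning.
#' @param contexts optionally precomputed [build_boundary_contexts()] output.
#' @return named integer vector of FSJ counts per candidate.
#' @export
count_fsj <- function(reads, genome, cands, span_flank = 5L,
                      exclude_pairs = character(0), min_identity = 0.98,
                      k = 20L, stride = 10L, contexts = NULL) {
  if (is.null(contexts)) contexts <- build_boundary_contexts(genome, cands)
  counts <- setNames(integer(nrow(cands)), cands$id)
  if (nrow(contexts) == 0) return(counts)
  keep <- !(names(reads$r1) %in% exclude_pairs)
  mates <- c(reads$r1[keep], reads$r2[keep])
  mate_id <- c(paste0(names(reads$r1)[keep], "/1"),
               paste0(names(reads$r2)[keep], "/2"))
  if (length(mates) == 0) return(counts)
  ctx_seqs <- contexts$seq
  names(ctx_seqs) <- sprintf("ctx%05d", seq_len(nrow(contexts)))
  hits <- align_pool(mates, ctx_seqs, k, stride, min_identity)
  if (nrow(hits) == 0) return(counts)
  bo <- contexts$bo[hits$ref]
  ok <- hits$start <= bo - span_flank + 1L & hits$end >= bo + span_flank
  hits <- hits[ok]
  if (nrow(hits) == 0) return(counts)
  ## one count per (mate, candidate, boundary), across duplicate contexts
  cr <- data.table(mate = mate_id[hits$read],
                   cand = contexts$cand[hits$ref],
                   boundary = contexts$boundary[hits$ref])
  cr <- unique(cr)
  tab <- cr[, .N, by = cand]
  counts[tab$cand] <- tab$N
  counts
}
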