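## Internal seed-and-extend read aligner. Exact k-mer seeds (default k = 20,
## sampled every `stride` bp along the read) nominate reference diagonals;
## each diagonal is scored by full-length ungapped (Hamming) comparison, so
## every reported hit is an end-to-end placement of the read. Substitution
## errors only; gapped alignment is out of scope.

## k-mer position index over a set of reference sequences
kmer_index <- function(refs, k = 20L) {
  pieces <- lapply(seq_along(refs), function(i) {
    s <- refs[[i]]
    n <- nchar(s)
    if (n < k) return(NULL)
    data.table(kmer = substring(s, 1:(n - k + 1L), k:n),
               ref = i, pos = 1:(n - k + 1L))
  })
  idx <- rbindlist(pieces)
  if (nrow(idx) == 0) stop("empty reference set (all sequences < k)", call. = FALSE)
  setkey(idx, kmer)
  idx
}

reads_as_matrix <- function(reads, rl) {
  matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
         nrow = length(reads), ncol = rl, byrow = TRUE)
}

## candidate diagonals for one strand of the read set
seed_diagonals <- function(reads, idx, k, stride, rl) {
  off <- unique(c(seq(1L, rl - k + 1L, by = stride), rl - k + 1L))
  seeds <- rbindlist(lapply(off, function(o) {
    data.table(kmer = substring(reads, o, o + k - 1L),
               read = seq_along(reads), off = o)
  }))
  m <- idx[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(m) == 0) return(m)
  m[, diag_ := pos - off + 1L]
  unique(m[, .(read, ref, diag_)])
}

## full-length Hamming verification of candidate placements
verify_diagonals <- function(cand, read_mat, refs, ref_len, rl) {
  cand <- cand[diag_ >= 1L & diag_ + rl - 1L <= ref_len[ref]]
  if (nrow(cand) == 0) {
    return(data.table(read = integer(0), ref = integer(0), start = integer(0),
                      mismatches = integer(0)))
  }
  setorder(cand, ref, diag_, read)
  out <- cand[, {
    S <- strsplit(refs[[.BY$ref]], "", fixed = TRUE)[[1]]
    idxmat <- outer(diag_, 0:(rl - 1L), "+")
    refchars <- matrix(S[idxmat], nrow = .N)
    mm <- as.integer(rowSums(refchars != read_mat[read, , drop = FALSE]))
    .(read = read, start = diag_, mismatches = mm)
  }, by = ref]
  out[, .(read, ref, start, mismatches)]
}

#' Align a pool of reads end-to-end against reference sequences
#'
#' Exact k-mer seeding with ungapped full-length extension. Both strands are
#' searched; the best placement per (read, reference) pair is reported, with
#' ties broken deterministically (fewest mismatches, then plus strand, then
#' leftmost position).
#'
#' @param reads named character vector of equal-length reads.
#' @param refs named character vector (or list of `pseudo_ref`) of references.
#' @param k seed length (must not exceed the read length).
#' @param stride spacing between seed start positions along the read.
#' @param min_identity minimum full-length identity for a reported hit.
#' @return data.table with columns read (index into `reads`), ref (index into
#'   `refs`), strand, start/end (1-based inclusive reference coordinates),
#'   mismatches, identity.
#' @export
align_pool <- function(reads, refs, k = 20L, stride = 10L, min_identity = 0.95) {
  if (length(refs) == 0) stop("empty reference set", call. = FALSE)
  if (length(reads) == 0) {
    return(data.table(read = integer(0), ref = integer(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), identity = numeric(0)))
  }
  rl <- unique(nchar(reads))
  if (length(rl) != 1) stop("align_pool requires uniform read length", call. = FALSE)
  if (k > rl) stop("seed length k exceeds read length", call. = FALSE)
  refs <- vapply(refs, function(r) if (is.list(r)) r$seq else r, character(1))
  ref_len <- nchar(refs)
  idx <- kmer_index(refs, k)

  hits <- list()
  for (str in c("+", "-")) {
    rr <- if (str == "+") reads else revcomp(reads)
    cand <- seed_diagonals(rr, idx, k, stride, rl)
    if (nrow(cand) == 0) next
    v <- verify_diagonals(cand, reads_as_matrix(rr, rl), refs, ref_len, rl)
    if (nrow(v) > 0) {
      v[, strand := str]
      hits[[str]] <- v
    }
  }
  hits <- rbindlist(hits)
  if (nrow(hits) == 0) {
    return(data.table(read = integer(0), ref = integer(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), identity = numeric(0)))
  }
  ## best placement per (read, ref): fewest mismatches, '+' first, leftmost
  setorder(hits, read, ref, mismatches, strand, start)
  best <- hits[, .SD[1L], by = .(read, ref)]
  best[, end := start + rl - 1L]
  best[, identity := (rl - mismatches) / rl]
  best <- best[identity >= min_identity]
  setcolorder(best, c("read", "ref", "strand", "start", "end",
                      "mismatches", "identity"))
  best[]
}

## best single hit per read (lowest ref id, then leftmost, on identity ties)
best_per_read <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  setorder(hits, read, mismatches, ref, start)
  hits[, .SD[1L], by = read]
}

#' Filter read pairs with end-to-end linear alignments
#'
#' A pair is deemed linear — and removed from the candidate pool — only when
#' both mates align end-to-end to some linear transcript at
#' `min_identity` or better. All other pairs enter the pool used for
#' pseudo-reference re-alignment.
#'
#' The default identity cutoff is strict (0.98) so that back-spliced reads
#' with a short wrapped segment, whose few wrapped bases mismatch the linear
#' transcript, are not absorbed as linear evidence; see the methods vignette.
#'
#' @param reads list with `r1` and `r2` named character vectors.
#' @param linear_refs named character vector of spliced transcript sequences.
#' @param min_identity identity at or above which a mate counts as linearly
#'   aligned.
#' @param k,stride seeding parameters, see [align_pool()].
#' @return list: `pool` (list r1/r2 of retained pairs), `keep` (logical),
#'   `linear_hits` (best linear hit per mate, for gene counting).
#' @export
select_candidate_reads <- function(reads, linear_refs, min_identity = 0.98,
                                   k = 20L, stride = 10L) {
  if (length(linear_refs) == 0) stop("linear reference set is empty", call. = FALSE)
  if (length(reads$r1) != length(reads$r2)) {
    stop("mismatched mate counts between R1 and R2", call. = FALSE)
  }
  h1 <- best_per_read(align_pool(reads$r1, linear_refs, k, stride, min_identity))
  h2 <- best_per_read(align_pool(reads$r2, linear_refs, k, stride, min_identity))
  n <- length(reads$r1)
  lin1 <- lin2 <- rep(FALSE, n)
  lin1[h1$read] <- TRUE
  lin2[h2$read] <- TRUE
  keep <- !(lin1 & lin2)
  list(pool = list(r1 = reads$r1[keep], r2 = reads$r2[keep]),
       keep = keep, linear_hits = list(r1 = h1, r2 = h2))
}

#' Align the candidate pool to pseudo-circular references
#'
#' @param pool list with `r1`/`r2` named character vectors (candidate pairs).
#' @param pseudo_refs named list of `pseudo_ref` objects.
#' @param k,stride,min_identity see [align_pool()].
#' @return list of hit tables `hits1`, `hits2` (per-mate, per-reference best
#'   placements) plus the reference id vector.
#' @export
align_to_pseudo <- function(pool, pseudo_refs, k = 20L, stride = 10L,
                            min_identity = 0.95) {
  if (length(pseudo_refs) == 0) stop("empty pseudo-reference set", call. = FALSE)
  seqs <- vapply(pseudo_refs, function(p) p$seq, character(1))
  list(hits1 = align_pool(pool$r1, seqs, k, stride, min_identity),
       hits2 = align_pool(pool$r2, seqs, k, stride, min_identity),
       ref_ids = names(pseudo_refs))
}
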