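## Pseudo-circular reference construction: the back-spliced region (genomic
## slice or spliced exon chain), duplicated head-to-tail so that any
## single-pass read crossing the back-spliced junction has a contiguous,
## gap-free representation crossing the internal fusion point.

#' Build the pseudo-circular reference for one candidate
#'
#' The unit sequence is the candidate's back-spliced region: in `spliced`
#' mode the concatenated exonic sequence, in `genomic` mode the raw genomic
#' slice. Minus-strand candidates are reverse-complemented before
#' duplication. The returned sequence is the unit repeated twice; the fusion
#' offset (0-based position where the second copy begins) marks the single
#' internal image of the back-spliced junction.
#'
#' @param cand one-row candidate (data.frame/data.table with chrom, start,
#'   end, strand, and for spliced mode a list column `exons`).
#' @param genome `genome_sim` object (or list with `chroms`).
#' @param mode `"auto"` (spliced when an exon chain is available, else
#'   genomic), `"spliced"`, or `"genomic"`.
#' @return object of class `pseudo_ref`: list(id, seq, unit_length,
#'   fusion_offset, mode).
#' @export
build_pseudo_ref <- function(cand, genome, mode = c("auto", "spliced", "genomic")) {
  mode <- match.arg(mode)
  chrom_seq <- genome$chroms[[cand$chrom]]
  if (is.null(chrom_seq)) stop("unknown chromosome: ", cand$chrom, call. = FALSE)
  if (cand$start < 0 || cand$end > nchar(chrom_seq) || cand$start >= cand$end) {
    stop("candidate interval out of chromosome bounds: ", cand$id, call. = FALSE)
  }
  exons <- if ("exons" %in% names(cand)) cand$exons[[1]] else NULL
  if (mode == "auto") mode <- if (!is.null(exons)) "spliced" else "genomic"
  strand <- if (identical(cand$strand, "-")) "-" else "+"
  unit <- if (mode == "spliced") {
    if (is.null(exons)) {
      stop("spliced mode requires an exon chain for candidate ", cand$id,
           call. = FALSE)
    }
    stopifnot(all(exons[, 1] >= cand$start), all(exons[, 2] <= cand$end))
    splice_seq(chrom_seq, exons, strand)
  } else {
    s <- seq_slice(chrom_seq, cand$start, cand$end)
    if (strand == "-") revcomp(s) else s
  }
  out <- list(id = as.character(cand$id), seq = paste0(unit, unit),
              unit_length = nchar(unit), fusion_offset = nchar(unit),
              mode = mode)
  class(out) <- "pseudo_ref"
  out
}

#' Build pseudo-references for a candidate set
#'
#' @param cands candidate table (one row per circRNA).
#' @param genome `genome_sim` object.
#' @param mode see [build_pseudo_ref()].
#' @return named list of `pseudo_ref` objects, keyed by candidate id.
#' @export
build_pseudo_refs <- function(cands, genome, mode = "auto") {
  out <- lapply(seq_len(nrow(cands)), function(i) {
    build_pseudo_ref(cands[i, ], genome, mode)
  })
  names(out) <- cands$id
  out
}

#' @export
print.pseudo_ref <- function(x, ...) {
  cat(sprintf("pseudo_ref %s: unit %d bp (%s mode), fusion offset %d\n",
              x$id, x$unit_length, x$mode, x$fusion_offset))
  invisible(x)
}

#' Write pseudo-references to multi-FASTA
#'
#' Record ids follow `<candidate>::<mode>`.
#'
#' @param prefs list of `pseudo_ref` objects.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_pseudo_fasta <- function(prefs, path) {
  seqs <- vapply(prefs, function(p) p$seq, character(1))
  names(seqs) <- vapply(prefs, function(p) paste0(p$id, "::", p$mode), character(1))
  write_fasta(seqs, path)
}
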