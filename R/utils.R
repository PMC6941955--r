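## internal helpers

DNA_ALPHABET <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_ALPHABET, n, replace = TRUE), collapse = "")
}

## slice a sequence using 0-based half-open coordinates
seq_slice <- function(seq, start0, end0) {
  stopifnot(start0 >= 0, end0 <= nchar(seq), start0 < end0)
  substr(seq, start0 + 1L, end0)
}

## splice exon intervals (0-based half-open, sorted) out of a chromosome;
## minus strand returns the reverse complement of the concatenation
splice_seq <- function(chrom_seq, exons, strand = "+") {
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  s <- paste(vapply(seq_len(nrow(exons)), function(i) {
    seq_slice(chrom_seq, exons[i, 1L], exons[i, 2L])
  }, character(1)), collapse = "")
  if (identical(strand, "-")) revcomp(s) else s
}

check_counts <- function(..., allow_zero = TRUE) {
  vals <- c(...)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (!allow_zero && any(vals == 0)) stop("counts must be positive", call. = FALSE)
  invisible(TRUE)
}

## derive a deterministic sub-seed (kept well below .Machine$integer.max)
sub_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 10007L) %% 2147483L
}
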