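## Readers and writers for the standard formats used across the pipeline.
## All internal coordinates are 0-based half-open; GTF is converted on
## read/write (1-based inclusive on disk), BED is passed through unchanged.

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read one FASTQ file
#'
#' Gzip input is handled transparently.
#'
#' @param path FASTQ(.gz) file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Read a FASTQ pair with mate-id validation
#'
#' @param path1,path2 R1 and R2 FASTQ files.
#' @return list with `r1` and `r2` named character vectors.
#' @export
read_fastq_pair <- function(path1, path2) {
  r1 <- read_fastq(path1)
  r2 <- read_fastq(path2)
  core <- function(x) sub("/[12]$", "", names(x))
  if (length(r1) != length(r2) || !identical(core(r1), core(r2))) {
    stop("mismatched mate ids between R1 and R2 files", call. = FALSE)
  }
  names(r1) <- core(r1)
  names(r2) <- core(r2)
  list(r1 = r1, r2 = r2)
}

#' Write a read pair to two FASTQ files
#'
#' Constant Phred-33 quality 'I' (Q40) is emitted; the simulator does not
#' model quality scores.
#'
#' @param reads list with named character vectors `r1`, `r2`.
#' @param prefix output prefix; files are `<prefix>_1.fastq`, `<prefix>_2.fastq`.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(reads, prefix) {
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (i in 1:2) {
    x <- if (i == 1) reads$r1 else reads$r2
    dss <- Biostrings::DNAStringSet(x)
    names(dss) <- paste0(names(x), "/", i)
    qual <- Biostrings::BStringSet(strrep("I", nchar(x)))
    Biostrings::writeXStringSet(dss, paths[i], format = "fastq", qualities = qual)
  }
  invisible(paths)
}

#' Read gene annotation from GTF
#'
#' Exon records are converted from 1-based inclusive to the package's
#' 0-based half-open convention.
#'
#' @param path GTF file (Ensembl dialect; requires gene_id and transcript_id
#'   attributes on exon lines).
#' @return list with `genes` and `exons` data.tables.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0) stop("no exon records in GTF: ", path, call. = FALSE)
  exons <- data.table(
    gene_id = as.character(ex$gene_id),
    tx_id = as.character(ex$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex)
  )
  setorder(exons, gene_id, tx_id, start)
  exons[, exon_rank := seq_len(.N), by = tx_id]
  genes <- exons[, .(
    chrom = chrom[1L], strand = strand[1L],
    start = min(start), end = max(end)
  ), by = gene_id]
  list(genes = genes, exons = exons)
}

#' Write gene models to GTF
#'
#' @param genome a `genome_sim` object (or any list with `genes`/`exons`
#'   tables in internal coordinates).
#' @param path output GTF file.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(genome, path) {
  g <- genome$genes
  e <- genome$exons
  lines <- character(0)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    ge <- e[gene_id == gid]
    attr_g <- sprintf('gene_id "%s";', gid)
    lines <- c(lines, paste(g$chrom[i], "bsjquant", "gene", g$start[i] + 1L,
                            g$end[i], ".", g$strand[i], ".", attr_g, sep = "\t"))
    for (tid in unique(ge$tx_id)) {
      te <- ge[tx_id == tid][order(start)]
      attr_t <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
      lines <- c(lines, paste(g$chrom[i], "bsjquant", "transcript",
                              min(te$start) + 1L, max(te$end), ".",
                              g$strand[i], ".", attr_t, sep = "\t"))
      for (j in seq_len(nrow(te))) {
        attr_e <- sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                          gid, tid, j)
        lines <- c(lines, paste(te$chrom[j], "bsjquant", "exon",
                                te$start[j] + 1L, te$end[j], ".",
                                g$strand[i], ".", attr_e, sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read circRNA candidates from BED6
#'
#' BED is 0-based half-open, matching the internal convention; records pass
#' through unchanged.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @return data.table of candidates (id, chrom, start, end, strand).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  out <- data.table(
    id = as.character(gr$name),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  out[strand == "*", strand := "+"]
  if (any(out$start >= out$end)) {
    stop("BED interval with start >= end in ", path, call. = FALSE)
  }
  out
}

#' Write circRNA candidates to BED6
#'
#' @param cands candidate table (id, chrom, start, end, strand).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(cands, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = cands$chrom,
    ranges = IRanges::IRanges(start = cands$start + 1L, end = cands$end),
    strand = cands$strand
  )
  gr$name <- cands$id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Load a YAML run configuration
#'
#' @param path YAML file; see [run_pipeline()] for the recognized fields.
#' @param check_paths validate that referenced input files exist.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path, check_paths = TRUE) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (check_paths) {
    for (f in c("genome_fasta", "gtf", "bed")) {
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
        stop("configured path does not exist: ", f, " = ", cfg[[f]], call. = FALSE)
      }
    }
    for (lib in cfg$libraries) {
      for (f in c("fastq1", "fastq2")) {
        if (!is.null(lib[[f]]) && !file.exists(lib[[f]])) {
          stop("configured path does not exist: ", lib[[f]], call. = FALSE)
        }
      }
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

## header comment stamped on every output table
output_header <- function(seed = NA, cfg_hash = NA) {
  sprintf("# bsjquant %s | seed=%s | config=%s",
          as.character(packageVersion("bsjquant")),
          as.character(seed), as.character(cfg_hash))
}

#' Write a result table as TSV with a provenance header
#'
#' @param x data.frame.
#' @param path output file.
#' @param seed,cfg_hash recorded in the header comment line.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, seed = NA, cfg_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed, cfg_hash), con)
  suppressWarnings(write.table(x, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA"))
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path input file.
#' @return data.table.
#' @export
read_tsv <- function(path) {
  fread(path, skip = 1L, header = TRUE, sep = "\t")
}
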