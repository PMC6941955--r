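## Paired-end read simulator with full ground truth.
##
## Fragments are sampled from linear transcripts (uniform start, fixed fold
## coverage) and from circular transcripts (rolling origin on the circle).
## Insert length is drawn from a two-component normal mixture and clamped to
## [read_length, template length]. Read names carry provenance (origin locus,
## template start, insert), so classifier accuracy is directly checkable;
## the quantifier never consults them.

#' Simulation configuration
#'
#' @param read_length read length in bp.
#' @param insert_components matrix/list of insert mixture components, each
#'   `(mean, sd, weight)`; weights must sum to 1.
#' @param linear_coverage fold coverage of linear transcripts.
#' @param error_rate per-base substitution probability.
#' @param expr_meanlog,expr_sdlog log-normal law for per-circRNA fragment
#'   abundance.
#' @param span_flank junction overhang (bp per side) defining a
#'   junction-spanning read in the ground truth; matches the quantifier's
#'   10-bp window default.
#' @param allow_short permit circles shorter than the read length (their
#'   multi-pass reads are not representable on the two-copy pseudo-reference,
#'   so they are excluded by default).
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(read_length = 100L,
                       insert_components = rbind(c(320, 70, 0.5),
                                                 c(550, 70, 0.5)),
                       linear_coverage = 10, error_rate = 0,
                       expr_meanlog = log(20), expr_sdlog = 1,
                       span_flank = 5L, allow_short = FALSE, seed = 1L) {
  comps <- do.call(rbind, lapply(asplit(as.matrix(insert_components), 1), c))
  colnames(comps) <- c("mean", "sd", "weight")
  stopifnot(read_length > 0, all(comps[, "sd"] >= 0),
            abs(sum(comps[, "weight"]) - 1) < 1e-8,
            linear_coverage >= 0, error_rate >= 0, error_rate < 1)
  out <- list(read_length = as.integer(read_length), insert_components = comps,
              linear_coverage = linear_coverage, error_rate = error_rate,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              span_flank = as.integer(span_flank),
              allow_short = isTRUE(allow_short), seed = as.integer(seed))
  class(out) <- "sim_config"
  out
}

draw_inserts <- function(n, comps, lo, hi) {
  ki <- sample.int(nrow(comps), n, replace = TRUE, prob = comps[, "weight"])
  x <- round(rnorm(n, comps[ki, "mean"], comps[ki, "sd"]))
  pmin(pmax(x, lo), hi)
}

add_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(runif(n) < rate)
    if (length(hit) == 0) return(r)
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(DNA_ALPHABET, b), 1L)
    }, character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## overhang-qualified coverage of a cut point c by interval [a, b)
spans_cut <- function(a, b, cut, flank) a <= cut - flank & b >= cut + flank

#' Simulate a paired-end library with ground truth
#'
#' @param genome `genome_sim` object.
#' @param circs candidate table from [simulate_circrnas()]; a numeric column
#'   `n_frag` may preset per-circRNA fragment counts, otherwise they are drawn
#'   from the configured log-normal law.
#' @param cfg a [sim_config()].
#' @return object of class `sim_reads`: list(r1, r2, truth, n_pairs, cfg).
#'   `truth` holds per circRNA: spliced length, fragment count, coverage fold,
#'   junction-spanning BSJ fragment count (`bsj_true`, overhang >=
#'   `span_flank` bp), any-overlap crossing count (`bsj_cross`), linear
#'   FSJ-spanning read count (`fsj_true`) and the true junction ratio.
#' @export
simulate_reads <- function(genome, circs, cfg = sim_config()) {
  set.seed(cfg$seed)
  rl <- cfg$read_length
  flank <- cfg$span_flank
  tx_seqs <- transcript_sequences(genome)
  ex <- genome$exons

  circ_seq <- vapply(seq_len(nrow(circs)), function(i) {
    cd <- circs[i, ]
    splice_seq(genome$chroms[[cd$chrom]], cd$exons[[1]], cd$strand)
  }, character(1))
  L <- nchar(circ_seq)
  if (any(L < rl) && !cfg$allow_short) {
    stop("circRNA spliced length below read length: ",
         paste(circs$id[L < rl], collapse = ", "),
         " (set allow_short to keep them)", call. = FALSE)
  }

  if ("n_frag" %in% names(circs)) {
    n_frag <- as.integer(circs$n_frag)
  } else {
    n_frag <- as.integer(round(rlnorm(nrow(circs), cfg$expr_meanlog,
                                      cfg$expr_sdlog)))
  }

  ## per-transcript boundary cut points of every candidate hosted on it
  cuts <- rbindlist(lapply(seq_len(nrow(circs)), function(i) {
    cd <- circs[i, ]
    te <- ex[tx_id == cd$tx_id]
    if (nrow(te) == 0) return(NULL)
    exm <- as.data.frame(te[, .(start, end)])
    rbindlist(lapply(c("5p", "3p"), function(side) {
      gpos <- if (side == "5p") cd$start else cd$end
      cut <- tx_cutpoint(exm, te$strand[1], gpos, side)
      if (is.na(cut)) return(NULL)
      data.table(tx = cd$tx_id, cand = cd$id, boundary = side, cut = cut)
    }))
  }))

  ## strand-corrected transcript offset of each circle's first base
  circ_lo <- vapply(circs$id, function(cid) {
    cc <- cuts[cand == cid]
    if (nrow(cc) < 2) NA_integer_ else min(cc$cut)
  }, integer(1))

  r1 <- r2 <- character(0)
  nm <- character(0)
  frag_circ <- list()   # per-fragment circRNA provenance
  span_tab <- list()    # reads spanning candidate boundaries linearly
  serial <- 0L

  ## --- circular fragments -------------------------------------------------
  for (i in seq_len(nrow(circs))) {
    nf <- n_frag[i]
    if (nf == 0 || L[i] < rl) next
    s <- sample.int(L[i], nf, replace = TRUE) - 1L
    ins <- draw_inserts(nf, cfg$insert_components, rl, L[i])
    dbl <- paste0(circ_seq[i], circ_seq[i])
    a1 <- s; b1 <- s + rl
    a2 <- s + ins - rl; b2 <- s + ins
    cr1 <- spans_cut(a1, b1, L[i], flank)
    cr2 <- spans_cut(a2, b2, L[i], flank)
    any1 <- a1 < L[i] & b1 > L[i]
    any2 <- a2 < L[i] & b2 > L[i]
    ids <- sprintf("C:%s:%d:%d:%07d", circs$id[i], s, ins, serial + seq_len(nf))
    serial <- serial + nf
    r1 <- c(r1, substr(rep(dbl, nf), a1 + 1L, b1))
    r2 <- c(r2, revcomp(substr(rep(dbl, nf), a2 + 1L, b2)))
    nm <- c(nm, ids)
    frag_circ[[i]] <- data.table(name = ids, cand = circs$id[i],
                                 spans = cr1 | cr2, crosses = any1 | any2)
    ## a non-wrapping read from this circle is a contiguous transcript
    ## segment: it is linear FSJ evidence for any *other* candidate whose
    ## boundary it covers (e.g. a nested circRNA on the same transcript)
    oc <- cuts[tx == circs$tx_id[i] & cand != circs$id[i]]
    if (nrow(oc) > 0 && !is.na(circ_lo[i])) {
      for (mi in 1:2) {
        a <- if (mi == 1) a1 else a2
        b <- if (mi == 1) b1 else b2
        shift <- ifelse(a >= L[i], -L[i], 0L)  # fully wrapped segment
        whole <- (b + shift) <= L[i]           # read does not straddle the BSJ
        ta <- circ_lo[i] + a + shift
        tb <- circ_lo[i] + b + shift
        for (j in seq_len(nrow(oc))) {
          ## fragments detectable as BSJ pairs are circular reads and are
          ## excluded from FSJ evidence, mirroring the quantifier
          hit <- whole & spans_cut(ta, tb, oc$cut[j], flank) & !(cr1 | cr2)
          if (any(hit)) {
            span_tab[[length(span_tab) + 1L]] <- data.table(
              name = ids[hit], mate = sprintf("/%d", mi), cand = oc$cand[j],
              boundary = oc$boundary[j])
          }
        }
      }
    }
  }

  ## --- linear fragments ---------------------------------------------------
  if (cfg$linear_coverage > 0) {
    for (tid in names(tx_seqs)) {
      tlen <- nchar(tx_seqs[[tid]])
      if (tlen < rl) next
      nf <- as.integer(round(cfg$linear_coverage * tlen / (2 * rl)))
      if (nf == 0) next
      ins <- draw_inserts(nf, cfg$insert_components, rl, tlen)
      s <- vapply(tlen - ins, function(m) sample.int(m + 1L, 1L) - 1L, integer(1))
      a1 <- s; b1 <- s + rl
      a2 <- s + ins - rl; b2 <- s + ins
      ids <- sprintf("L:%s:%d:%d:%07d", tid, s, ins, serial + seq_len(nf))
      serial <- serial + nf
      r1 <- c(r1, substr(rep(tx_seqs[[tid]], nf), a1 + 1L, b1))
      r2 <- c(r2, revcomp(substr(rep(tx_seqs[[tid]], nf), a2 + 1L, b2)))
      nm <- c(nm, ids)
      tc <- cuts[tx == tid]
      if (nrow(tc) > 0) {
        for (j in seq_len(nrow(tc))) {
          m1 <- spans_cut(a1, b1, tc$cut[j], flank)
          m2 <- spans_cut(a2, b2, tc$cut[j], flank)
          hitn <- c(ids[m1], ids[m2])
          hitm <- c(rep("/1", sum(m1)), rep("/2", sum(m2)))
          if (length(hitn) > 0) {
            span_tab[[length(span_tab) + 1L]] <- data.table(
              name = hitn, mate = hitm, cand = tc$cand[j],
              boundary = tc$boundary[j])
          }
        }
      }
    }
  }

  r1 <- add_errors(r1, cfg$error_rate)
  r2 <- add_errors(r2, cfg$error_rate)
  names(r1) <- names(r2) <- nm

  frag_circ <- rbindlist(frag_circ)
  span_tab <- rbindlist(span_tab)
  truth <- build_truth(circs$id, L, n_frag, rl, frag_circ, span_tab)
  out <- list(r1 = r1, r2 = r2, truth = truth, n_pairs = length(r1),
              treated = FALSE, cfg = cfg,
              frag_circ = frag_circ, span_tab = span_tab)
  class(out) <- "sim_reads"
  out
}

build_truth <- function(ids, L, n_frag, rl, frag_circ, span_tab) {
  truth <- data.table(id = ids, spliced_len = L, n_frag = n_frag,
                      coverage = n_frag * 2 * rl / L)
  bs <- if (nrow(frag_circ) > 0) {
    frag_circ[, .(bsj_true = sum(spans), bsj_cross = sum(crosses)), by = cand]
  } else data.table(cand = character(0), bsj_true = integer(0),
                    bsj_cross = integer(0))
  fs <- if (nrow(span_tab) > 0) span_tab[, .(fsj_true = .N), by = cand] else
    data.table(cand = character(0), fsj_true = integer(0))
  truth <- merge(truth, bs, by.x = "id", by.y = "cand", all.x = TRUE)
  truth <- merge(truth, fs, by.x = "id", by.y = "cand", all.x = TRUE)
  for (cl in c("bsj_true", "bsj_cross", "fsj_true")) {
    truth[is.na(get(cl)), (cl) := 0L]
  }
  truth[, junction_ratio_true := ifelse(
    bsj_true + fsj_true == 0, NA_real_,
    2 * bsj_true / (2 * bsj_true + fsj_true))]
  truth[]
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf("sim_reads: %d read pairs (%d circRNAs%s)\n", x$n_pairs,
              nrow(x$truth), if (isTRUE(x$treated)) ", RNase R-treated" else ""))
  invisible(x)
}

#' Apply in-silico RNase R treatment to a simulated library
#'
#' Each circRNA draws an enrichment coefficient from the given normal
#' mixture (clipped to (0, 1]); its circular fragments are retained with
#' probability `coefficient * linear_survival` while linear fragments are
#' retained independently with probability `linear_survival`, so the
#' post/pre junction-odds ratio of each circRNA matches its drawn
#' coefficient in expectation. Thinning never creates reads.
#'
#' @param reads a `sim_reads` object (untreated).
#' @param eff_mixture components `(mean, sd, weight)` of the coefficient
#'   distribution.
#' @param linear_survival retention probability of linear fragments, in (0, 1].
#' @param seed RNG seed.
#' @return a `sim_reads` object for the treated library; its `truth` table
#'   gains `eff` (drawn coefficient) and reflects post-treatment counts.
#' @export
apply_rnase_r <- function(reads, eff_mixture = rbind(c(0.95, 0.02, 0.7),
                                                     c(0.7, 0.1, 0.3)),
                          linear_survival = 0.25, seed = 1L) {
  stopifnot(inherits(reads, "sim_reads"))
  if (reads$n_pairs == 0) stop("empty input library", call. = FALSE)
  stopifnot(linear_survival > 0, linear_survival <= 1)
  comps <- as.matrix(eff_mixture)
  set.seed(seed)
  ids <- reads$truth$id
  ki <- sample.int(nrow(comps), length(ids), replace = TRUE,
                   prob = comps[, 3])
  eff <- rnorm(length(ids), comps[ki, 1], comps[ki, 2])
  eff <- pmin(pmax(eff, 1e-6), 1)
  names(eff) <- ids

  nm <- names(reads$r1)
  typ <- substr(nm, 1, 1)
  locus <- vapply(strsplit(nm, ":", fixed = TRUE), `[`, character(1), 2L)
  p <- ifelse(typ == "C", eff[locus] * linear_survival, linear_survival)
  keep <- runif(length(nm)) < p

  frag_circ <- reads$frag_circ[name %in% nm[keep]]
  span_tab <- reads$span_tab[name %in% nm[keep]]
  nf_kept <- setNames(integer(length(ids)), ids)
  if (nrow(frag_circ) > 0) {
    tab <- frag_circ[, .N, by = cand]
    nf_kept[tab$cand] <- tab$N
  }
  truth <- build_truth(ids, reads$truth$spliced_len, as.integer(nf_kept),
                       reads$cfg$read_length, frag_circ, span_tab)
  truth[, eff := eff[id]]
  truth[, linear_survival := linear_survival]
  out <- list(r1 = reads$r1[keep], r2 = reads$r2[keep], truth = truth,
              n_pairs = sum(keep), treated = TRUE, cfg = reads$cfg,
              frag_circ = frag_circ, span_tab = span_tab)
  class(out) <- "sim_reads"
  out
}

#' Simulate paired junction-count libraries under RNase R thinning
#'
#' Count-level counterpart of [simulate_reads()] + [apply_rnase_r()]: deep
#' per-circRNA BSJ/FSJ counts are drawn for an untreated (RiboMinus) library
#' and binomially thinned into a treated (RNase R) library, bypassing
#' read-level sampling. Used to study the enrichment-correction model where
#' coefficient estimates need count depths beyond read-level desk scale.
#'
#' @param n_circ number of circRNAs.
#' @param mean_bsj log-normal median of untreated BSJ counts.
#' @param sdlog log-normal sdlog of untreated BSJ counts.
#' @param fsj_factor untreated FSJ mean as a multiple of the BSJ mean.
#' @param eff_mixture enrichment-coefficient mixture `(mean, sd, weight)`.
#' @param linear_survival median linear fragment survival under treatment.
#' @param survival_sd per-circRNA spread of linear survival on the log-odds
#'   scale: RNase R digests linear RNA with locus-dependent efficiency, the
#'   dominant bias the odds-ratio correction removes.
#' @param lib_background extra mapped fragments per library (sets totals for
#'   CPM).
#' @param seed RNG seed.
#' @return data.table of class `paired_counts`: per circRNA the true
#'   coefficient, untreated (`bsj_m`, `fsj_m`) and treated (`bsj_r`, `fsj_r`)
#'   counts, with attributes `total_m`, `total_r`.
#' @export
simulate_paired_counts <- function(n_circ = 500L, mean_bsj = 2000,
                                   sdlog = 0.5, fsj_factor = 2,
                                   eff_mixture = rbind(c(0.95, 0.02, 0.7),
                                                       c(0.7, 0.1, 0.3)),
                                   linear_survival = 0.25, survival_sd = 0.5,
                                   lib_background = 2e6, seed = 1L) {
  set.seed(seed)
  comps <- as.matrix(eff_mixture)
  mu <- rlnorm(n_circ, log(mean_bsj), sdlog)
  bsj_m <- rpois(n_circ, mu)
  fsj_m <- rpois(n_circ, fsj_factor * mu)
  ki <- sample.int(nrow(comps), n_circ, replace = TRUE, prob = comps[, 3])
  eff <- pmin(pmax(rnorm(n_circ, comps[ki, 1], comps[ki, 2]), 1e-6), 1)
  surv <- stats::plogis(stats::qlogis(linear_survival) +
                        rnorm(n_circ, 0, survival_sd))
  bsj_r <- rbinom(n_circ, bsj_m, pmin(1, eff * surv))
  fsj_r <- rbinom(n_circ, fsj_m, surv)
  out <- data.table(id = sprintf("circ%04d", seq_len(n_circ)), eff = eff,
                    survival = surv, bsj_m = bsj_m, fsj_m = fsj_m,
                    bsj_r = bsj_r, fsj_r = fsj_r)
  setattr(out, "total_m", sum(bsj_m) + sum(fsj_m) + lib_background)
  setattr(out, "total_r", sum(bsj_r) + sum(fsj_r) +
                          round(lib_background * linear_survival))
  setattr(out, "class", c("paired_counts", class(out)))
  out[]
}
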