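## Isoform-switching detection.
##
## LC (linear-circular) switching: a circRNA whose junction ratio changes by
## more than 0.3 between conditions *and* crosses 0.5, i.e. the locus flips
## between major (> 0.5) and minor (< 0.5) circular splicing. CTU (circular
## transcript usage): among a gene's two most-expressed circRNAs, the BSJ
## proportion of the one with the longer genomic span; CTU switching applies
## the same (> 0.3 change, 0.5 crossing) rule. Both thresholds are strict
## inequalities.

switch_events <- function(ids, v_ctrl, v_case, kind, delta_min = 0.3,
                          crossing = 0.5) {
  delta <- v_case - v_ctrl
  ## strict thresholds with a numeric guard: count-derived ratios landing
  ## exactly on the boundary (e.g. 0.55 - 0.25) must not round into an event
  eps <- 1e-9
  ok <- !is.na(delta) & abs(delta) > delta_min + eps &
    pmin(v_case, v_ctrl) < crossing - eps & pmax(v_case, v_ctrl) > crossing + eps
  data.table(
    kind = kind, feature_id = ids[ok],
    value_ctrl = v_ctrl[ok], value_case = v_case[ok], delta = delta[ok],
    direction = ifelse(delta[ok] < 0, "major->minor", "minor->major")
  )
}

#' Detect linear-circular switching events
#'
#' @param records_case,records_ctrl `circ_quant` tables (or data.frames with
#'   id and junction_ratio), matched by candidate id; missing ratios are
#'   excluded.
#' @param delta_min minimum absolute junction-ratio change (strict).
#' @param crossing major/minor boundary the ratio must cross (strict).
#' @return data.table of events: kind, feature_id, value_ctrl, value_case,
#'   delta, direction.
#' @export
detect_lc_switching <- function(records_case, records_ctrl, delta_min = 0.3,
                                crossing = 0.5) {
  m <- merge(as.data.table(records_ctrl)[, .(id, jr_ctrl = junction_ratio)],
             as.data.table(records_case)[, .(id, jr_case = junction_ratio)],
             by = "id")
  m <- m[!is.na(jr_ctrl) & !is.na(jr_case)]
  switch_events(m$id, m$jr_ctrl, m$jr_case, "LC", delta_min, crossing)
}

#' Circular transcript usage of one gene
#'
#' Takes the gene's two circRNAs with the highest BSJ counts and returns the
#' BSJ proportion of the one with the longer genomic span (end - start).
#' Undefined (NA) when fewer than two circRNAs have BSJ support.
#'
#' @param gene_circs data.frame with columns bsj, start, end (one row per
#'   circRNA of the gene); ties in BSJ rank are broken by span then id.
#' @return CTU value in `[0, 1]`, or NA.
#' @export
compute_ctu <- function(gene_circs) {
  g <- as.data.table(gene_circs)
  g <- g[bsj > 0]
  if (nrow(g) < 2) return(NA_real_)
  g[, span := end - start]
  if (!("id" %in% names(g))) g[, id := as.character(seq_len(.N))]
  setorder(g, -bsj, -span, id)
  top <- g[1:2]
  longest <- which.max(top$span)
  top$bsj[longest] / sum(top$bsj)
}

#' Detect circular-transcript-usage switching events
#'
#' With replicates, per-group junction counts are summed across samples; a
#' gene is eligible only when each of its two major circRNAs (ranked on
#' counts summed over *all* samples, so both groups compare the same pair)
#' is detected (bsj > 0) in more than half of the samples of each group.
#'
#' @param quants_case,quants_ctrl a single `circ_quant` table or a list of
#'   per-sample tables (replicates); rows need id, gene_id, bsj, start, end.
#' @param delta_min,crossing switching thresholds (strict), as for
#'   [detect_lc_switching()].
#' @param presence minimum fraction of samples per group in which both major
#'   circRNAs must be detected (strict).
#' @return data.table of events (kind "CTU", feature_id = gene id).
#' @export
detect_ctu_switching <- function(quants_case, quants_ctrl, delta_min = 0.3,
                                 crossing = 0.5, presence = 0.5) {
  as_list <- function(x) if (is.data.frame(x)) list(x) else x
  lc <- lapply(as_list(quants_case), as.data.table)
  lt <- lapply(as_list(quants_ctrl), as.data.table)
  need <- c("id", "gene_id", "bsj", "start", "end")
  stopifnot(all(need %in% names(lc[[1]])), all(need %in% names(lt[[1]])))

  pool <- function(l) {
    rbindlist(lapply(l, function(x) x[, .(id, gene_id, bsj, start, end)]))[
      , .(bsj = sum(bsj), start = start[1], end = end[1],
          gene_id = gene_id[1]), by = id]
  }
  all_sum <- pool(c(lc, lt))
  case_sum <- pool(lc)
  ctrl_sum <- pool(lt)

  detect_frac <- function(l, ids) {
    vapply(ids, function(i) {
      mean(vapply(l, function(x) any(x$id == i & x$bsj > 0), logical(1)))
    }, numeric(1))
  }

  genes <- unique(all_sum$gene_id)
  rows <- lapply(genes, function(g) {
    ga <- all_sum[gene_id == g & bsj > 0]
    if (nrow(ga) < 2) return(NULL)
    setorder(ga, -bsj, id)
    major <- ga$id[1:2]
    if (any(detect_frac(lc, major) <= presence) ||
        any(detect_frac(lt, major) <= presence)) {
      return(NULL)
    }
    ctu_of <- function(s) {
      sub <- s[id %in% major]
      if (nrow(sub) < 2 || any(sub$bsj == 0)) return(NA_real_)
      compute_ctu(sub)
    }
    data.table(gene = g, ctu_ctrl = ctu_of(ctrl_sum), ctu_case = ctu_of(case_sum))
  })
  rows <- rbindlist(rows)
  if (nrow(rows) == 0) {
    return(switch_events(character(0), numeric(0), numeric(0), "CTU",
                         delta_min, crossing))
  }
  switch_events(rows$gene, rows$ctu_ctrl, rows$ctu_case, "CTU",
                delta_min, crossing)
}
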