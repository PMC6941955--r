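## Differential expression (DE) and differential splicing (DS) of circRNAs.
##
## Without replicates, change is scored by a generalized fold change: the
## BSJ count is Poisson, so the posterior of the rate is Gamma(k + 1, scale
## 1); expression x = lambda / n (n = depth factor, CPM scale) and z =
## log2(x2 / x1). The DE-score is the posterior 5% quantile of z clipped at
## zero (or the 95% quantile when the mean change is negative): a
## conservative fold change that balances magnitude and uncertainty, zero
## meaning no significant change. The DS-score applies the same rule to y =
## log2(r2 / r1) with Beta posteriors on the junction ratio. Exact tests
## (Fisher on BSJ-vs-total tables; exact conditional rate-ratio on
## BSJ-per-FSJ rates) provide p-values; with replicates, a TMM-normalized
## negative-binomial GLM with likelihood-ratio tests is used.

#' DE-score: generalized fold change of circRNA expression
#'
#' @param k1,k2 BSJ counts in condition 1 and 2 (non-negative integers).
#' @param n1,n2 depth factors (> 0), e.g. mapped fragments / 1e6 so that
#'   expression is on the CPM scale.
#' @param draws Monte-Carlo draws (`method = "mc"`).
#' @param seed RNG seed.
#' @param method `"mc"` (default) or `"exact"` (Gamma-ratio / log-F
#'   quantiles; only without samplers).
#' @param alpha posterior tail probability used for the score quantile.
#' @param sampler1,sampler2 optional functions `n -> n` posterior draws of a
#'   *corrected* count for the respective condition (see [correct_bsj()]);
#'   each draw replaces the fixed count as the Gamma shape parameter minus
#'   one, propagating RNase R correction uncertainty.
#' @return list: `score`, `mean_log2fc`, `method`.
#' @export
de_score <- function(k1, n1, k2, n2, draws = 10000L, seed = NULL,
                     method = c("mc", "exact"), alpha = 0.05,
                     sampler1 = NULL, sampler2 = NULL) {
  method <- match.arg(method)
  stopifnot(n1 > 0, n2 > 0)
  if (is.null(sampler1) && is.null(sampler2)) check_counts(k1, k2)
  a1 <- k1 + 1
  a2 <- k2 + 1
  if (method == "exact") {
    if (!is.null(sampler1) || !is.null(sampler2)) {
      stop("exact method is only available without correction samplers",
           call. = FALSE)
    }
    mean_z <- (digamma(a2) - digamma(a1)) / log(2) + log2(n1 / n2)
    qz <- function(p) log2((n1 / n2) * (a2 / a1) * qf(p, 2 * a2, 2 * a1))
    score <- if (mean_z >= 0) max(qz(alpha), 0) else min(qz(1 - alpha), 0)
    return(list(score = score, mean_log2fc = mean_z, method = "exact"))
  }
  if (!is.null(seed)) set.seed(seed)
  sh1 <- if (is.null(sampler1)) rep(a1, draws) else sampler1(draws) + 1
  sh2 <- if (is.null(sampler2)) rep(a2, draws) else sampler2(draws) + 1
  x1 <- rgamma(draws, shape = sh1, scale = 1) / n1
  x2 <- rgamma(draws, shape = sh2, scale = 1) / n2
  z <- log2(x2 / x1)
  mean_z <- mean(z)
  score <- if (mean_z >= 0) {
    max(as.numeric(quantile(z, alpha, type = 7)), 0)
  } else {
    min(as.numeric(quantile(z, 1 - alpha, type = 7)), 0)
  }
  list(score = score, mean_log2fc = mean_z, method = "mc")
}

#' DS-score: generalized fold change of the junction ratio
#'
#' The junction ratio posterior is Beta(c + offset, l + offset); the default
#' Jeffreys offset 1/2 keeps the posterior proper at zero counts. Setting
#' `offset = 0` recovers the plain Beta(c, l) posterior (requires c, l > 0).
#'
#' @param c1,l1,c2,l2 BSJ (c) and FSJ (l) counts per condition.
#' @param draws Monte-Carlo draws.
#' @param seed RNG seed.
#' @param alpha posterior tail probability for the score quantile.
#' @param offset prior offset added to both shape parameters.
#' @return list: `score`, `mean_log2fc`.
#' @export
ds_score <- function(c1, l1, c2, l2, draws = 10000L, seed = NULL,
                     alpha = 0.05, offset = 0.5) {
  check_counts(c1, l1, c2, l2)
  if (offset == 0 && (c1 == 0 || l1 == 0 || c2 == 0 || l2 == 0)) {
    stop("offset = 0 requires positive counts", call. = FALSE)
  }
  a1 <- c1 + offset; b1 <- l1 + offset
  a2 <- c2 + offset; b2 <- l2 + offset
  mean_y <- ((digamma(a2) - digamma(a2 + b2)) -
             (digamma(a1) - digamma(a1 + b1))) / log(2)
  if (!is.null(seed)) set.seed(seed)
  r1 <- rbeta(draws, a1, b1)
  r2 <- rbeta(draws, a2, b2)
  y <- log2(r2 / r1)
  score <- if (mean_y >= 0) {
    max(as.numeric(quantile(y, alpha, type = 7)), 0)
  } else {
    min(as.numeric(quantile(y, 1 - alpha, type = 7)), 0)
  }
  list(score = score, mean_log2fc = mean_y)
}

#' Fisher's exact test on BSJ counts vs total mapped reads
#'
#' @param bsj1,total1,bsj2,total2 BSJ counts and library totals.
#' @return two-sided p-value.
#' @export
fisher_de_test <- function(bsj1, total1, bsj2, total2) {
  if (any(c(bsj1, total1 - bsj1, bsj2, total2 - bsj2) < 0)) {
    stop("negative cell in 2x2 table", call. = FALSE)
  }
  tab <- matrix(c(bsj1, total1 - bsj1, bsj2, total2 - bsj2), nrow = 2,
                byrow = TRUE)
  fisher.test(tab)$p.value
}

#' Exact conditional rate-ratio test on junction ratios
#'
#' Conditional on N = bsj1 + bsj2, under the null of equal BSJ rate per unit
#' FSJ exposure, bsj1 ~ Binomial(N, fsj1 / (fsj1 + fsj2)); the two-sided
#' p-value sums outcome probabilities not exceeding the observed one.
#'
#' @param bsj1,fsj1,bsj2,fsj2 junction counts per condition (fsj > 0).
#' @return two-sided p-value (1 when N = 0).
#' @export
rate_ratio_test <- function(bsj1, fsj1, bsj2, fsj2) {
  if (fsj1 <= 0 || fsj2 <= 0) stop("zero FSJ exposure", call. = FALSE)
  n <- bsj1 + bsj2
  if (n == 0) return(1)
  binom.test(bsj1, n, p = fsj1 / (fsj1 + fsj2))$p.value
}

#' TMM normalization factors from gene-level counts
#'
#' Trimmed mean of M-values (30% trim on M, 5% on A, precision weights),
#' reference library chosen by upper-quartile CPM closest to the mean,
#' factors rescaled to geometric mean 1.
#'
#' @param gene_counts genes-by-libraries count matrix (>= 2 libraries).
#' @return named numeric factors; attribute `reference` holds the reference
#'   library.
#' @export
tmm_factors <- function(gene_counts) {
  gene_counts <- as.matrix(gene_counts)
  if (ncol(gene_counts) < 2) stop("need >= 2 libraries", call. = FALSE)
  lib <- colSums(gene_counts)
  if (any(lib == 0)) stop("library with zero total count", call. = FALSE)
  f <- edgeR::calcNormFactors(gene_counts, method = "TMM")
  if (any(!is.finite(f))) {
    stop("TMM failed: a library shares no expressed genes with the reference",
         call. = FALSE)
  }
  uq <- vapply(seq_len(ncol(gene_counts)), function(j) {
    as.numeric(quantile(gene_counts[, j], 0.75)) / lib[j]
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))
  names(f) <- colnames(gene_counts)
  attr(f, "reference") <- colnames(gene_counts)[ref] %||% ref
  f
}

#' Replicate-aware differential expression of circRNAs
#'
#' Negative-binomial GLM with log link and offsets log(library size x TMM
#' factor); a single common dispersion is estimated by Cox-Reid adjusted
#' profile likelihood across circRNAs, and each circRNA is tested for the
#' condition coefficient by likelihood-ratio test. All-zero circRNAs are
#' reported as NA rows. P-values are BH-adjusted.
#'
#' @param counts circRNAs-by-libraries count matrix.
#' @param group condition labels (two levels, >= 2 libraries each).
#' @param norm_factors optional TMM factors (defaults to [tmm_factors()] of
#'   `counts` itself when no gene counts are supplied).
#' @param lib_sizes optional library sizes (default column sums).
#' @return data.table: id, logFC, logCPM, lr, pvalue, fdr; attribute
#'   `dispersion`.
#' @export
replicate_de <- function(counts, group, norm_factors = NULL, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  group <- factor(group)
  if (nlevels(group) != 2 || any(table(group) < 2)) {
    stop("need two conditions with >= 2 libraries each", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("circ%05d", seq_len(nrow(counts)))
  }
  design <- stats::model.matrix(~group)
  if (qr(design)$rank < ncol(design)) stop("singular design", call. = FALSE)
  keep <- rowSums(counts) > 0
  out <- data.table(id = rownames(counts), logFC = NA_real_,
                    logCPM = NA_real_, lr = NA_real_, pvalue = NA_real_)
  disp <- NA_real_
  if (any(keep)) {
    d <- edgeR::DGEList(counts = counts[keep, , drop = FALSE], group = group)
    if (!is.null(lib_sizes)) d$samples$lib.size <- lib_sizes
    if (is.null(norm_factors)) norm_factors <- tmm_factors(counts[keep, , drop = FALSE])
    d$samples$norm.factors <- as.numeric(norm_factors)
    d <- edgeR::estimateGLMCommonDisp(d, design)
    fit <- edgeR::glmFit(d, design)
    lrt <- edgeR::glmLRT(fit, coef = 2)
    tab <- lrt$table
    idx <- match(rownames(tab), out$id)
    out[idx, `:=`(logFC = tab$logFC, logCPM = tab$logCPM, lr = tab$LR,
                  pvalue = tab$PValue)]
    disp <- d$common.dispersion
  }
  out[, fdr := p.adjust(pvalue, method = "BH")]
  setattr(out, "dispersion", disp)
  out[]
}

#' Replicate-free differential table for two libraries
#'
#' Combines DE/DS scores with the exact tests for a pair of quantified
#' libraries matched by candidate id.
#'
#' @param quant1,quant2 `circ_quant` tables (condition 1 = control,
#'   condition 2 = case).
#' @param draws,seed Monte-Carlo controls for the scores.
#' @param eff_model optional `enrichment_model`; when given, library 2 is
#'   treated as RNase R data whose counts are corrected through the model's
#'   posterior sampler before DE scoring.
#' @return data.table: id, de_score, ds_score, log2fc_expr, log2fc_ratio,
#'   p_de, p_ds, fdr_de, fdr_ds, method.
#' @export
differential_table <- function(quant1, quant2, draws = 10000L, seed = 1L,
                               eff_model = NULL) {
  m <- merge(as.data.table(quant1)[, .(id, bsj, fsj)],
             as.data.table(quant2)[, .(id, bsj, fsj)],
             by = "id", suffixes = c("1", "2"))
  t1 <- attr(quant1, "total_mapped")
  t2 <- attr(quant2, "total_mapped")
  n1 <- t1 / 1e6
  n2 <- t2 / 1e6
  res <- lapply(seq_len(nrow(m)), function(i) {
    b1 <- m$bsj1[i]; f1 <- m$fsj1[i]
    b2 <- m$bsj2[i]; f2 <- m$fsj2[i]
    s2 <- NULL
    if (!is.null(eff_model) && f2 > 0 && f1 >= 0) {
      cb <- correct_bsj(b2, f2, f1, eff_model)
      s2 <- function(n) as.numeric(cb$sample(n))
    }
    de <- de_score(b1, n1, b2, n2, draws = draws,
                   seed = sub_seed(seed, i), sampler2 = s2)
    ds <- ds_score(b1, f1, b2, f2, draws = draws, seed = sub_seed(seed, i))
    p_de <- fisher_de_test(b1, t1, b2, t2)
    p_ds <- if (f1 > 0 && f2 > 0) rate_ratio_test(b1, f1, b2, f2) else NA_real_
    data.table(id = m$id[i], de_score = de$score, ds_score = ds$score,
               log2fc_expr = de$mean_log2fc, log2fc_ratio = ds$mean_log2fc,
               p_de = p_de, p_ds = p_ds)
  })
  out <- rbindlist(res)
  out[, fdr_de := p.adjust(p_de, "BH")]
  out[, fdr_ds := p.adjust(p_ds, "BH")]
  out[, method := if (is.null(eff_model)) "gfold" else "gfold+rnaser"]
  out[]
}
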