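## RNase R enrichment-bias correction.
##
## The per-circRNA enrichment coefficient is the post/pre-treatment change in
## BSJ-to-FSJ odds: Eff = (BSJ_r / FSJ_r) / (BSJ_m / FSJ_m), where r denotes
## the RNase R-treated and m the untreated (RiboMinus) library; Eff = 1 is a
## null enrichment effect. Coefficients across circRNAs are fitted with a
## one-dimensional Gaussian mixture by EM, the component count selected by
## BIC, and the mean of the main (highest-weight) component inverts the
## coefficient equation to recover untreated-scale BSJ counts from treated
## ones. Coefficients are modeled on the natural scale; log-scale displays
## are a plotting convention only.

#' Per-circRNA RNase R enrichment coefficient
#'
#' @param bsj_r,fsj_r BSJ/FSJ counts in the RNase R-treated library.
#' @param bsj_m,fsj_m BSJ/FSJ counts in the untreated (RiboMinus) library.
#' @return numeric coefficient(s); NA where any denominator term is zero
#'   (such circRNAs are excluded from mixture fitting).
#' @export
enrichment_coefficient <- function(bsj_r, fsj_r, bsj_m, fsj_m) {
  check_counts(bsj_r, fsj_r, bsj_m, fsj_m)
  out <- (bsj_r / fsj_r) / (bsj_m / fsj_m)
  out[fsj_r == 0 | bsj_m == 0 | fsj_m == 0] <- NA_real_
  out
}

## one EM run at fixed k; quantile-based initialization, sd floor 1e-4
em_gmm_1d <- function(x, k, tol = 1e-6, maxit = 500L, sd_floor = 1e-4) {
  n <- length(x)
  mu <- if (k == 1) mean(x) else
    as.numeric(quantile(x, probs = seq_len(k) / (k + 1), type = 7))
  sg <- rep(max(sd(x) / k, sd_floor), k)
  if (is.na(sg[1])) sg <- rep(sd_floor, k)
  w <- rep(1 / k, k)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, mu[j], sg[j]),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_d <- rowSums(dens)
    rowsum_d[rowsum_d < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / rowsum_d
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / n
    mu <- colSums(resp * x) / nk
    sg <- sqrt(colSums(resp * (outer(x, mu, "-"))^2) / nk)
    sg <- pmax(sg, sd_floor)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
  }
  list(mean = mu, sd = sg, weight = w, loglik = ll, ll_trace = ll_trace,
       iterations = length(ll_trace))
}

#' Fit a Gaussian mixture to enrichment coefficients
#'
#' EM is run for k = 1..`k_max` components with quantile-based
#' initialization; the model minimizing BIC is returned. The fit is
#' deterministic for a given coefficient vector. Coefficients above the
#' `winsorize` quantile are capped before fitting: the coefficient is a ratio
#' of count ratios and heavy-tailed at low counts.
#'
#' @param effs numeric enrichment coefficients (NA/Inf dropped).
#' @param k_max maximum number of components.
#' @param seed RNG seed (accepted for interface stability; the fit itself is
#'   deterministic).
#' @param min_n minimum number of finite coefficients required.
#' @param winsorize upper-quantile cap applied before fitting (NULL to skip).
#' @param tol,maxit EM convergence controls.
#' @return object of class `enrichment_model`: components (mean, sd, weight),
#'   n_components, main_mean, bic_trace, fit_n, loglik.
#' @export
fit_gmm <- function(effs, k_max = 5L, seed = NULL, min_n = 20L,
                    winsorize = 0.99, tol = 1e-6, maxit = 500L) {
  x <- effs[is.finite(effs)]
  if (length(x) < min_n) {
    stop(sprintf(paste0(
      "only %d finite enrichment coefficients (< %d): too few to fit a ",
      "mixture; supply an empirical coefficient model fitted on comparable ",
      "paired libraries instead"), length(x), min_n), call. = FALSE)
  }
  if (!is.null(winsorize)) {
    cap <- as.numeric(quantile(x, winsorize, type = 7))
    x <- pmin(x, cap)
  }
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(seq_len(k_max), function(k) em_gmm_1d(x, k, tol, maxit))
  bic <- vapply(seq_len(k_max), function(k) {
    -2 * fits[[k]]$loglik + (3 * k - 1) * log(length(x))
  }, numeric(1))
  ## a multi-component fit whose sd collapsed onto the floor is a spike on
  ## tied values (e.g. the winsorization cap), not population structure;
  ## exclude such fits from selection unless nothing else is available
  degen <- vapply(seq_len(k_max), function(k) {
    k > 1 && any(fits[[k]]$sd <= 1e-4 * 1.0001)
  }, logical(1))
  sel_bic <- ifelse(degen, Inf, bic)
  if (all(is.infinite(sel_bic))) sel_bic <- bic
  kbest <- which.min(sel_bic)
  f <- fits[[kbest]]
  comp <- data.table(mean = f$mean, sd = f$sd, weight = f$weight)
  setorder(comp, -weight)
  out <- list(components = comp, n_components = kbest,
              main_mean = comp$mean[1L],
              bic_trace = setNames(bic, paste0("k", seq_len(k_max))),
              fit_n = length(x), loglik = f$loglik, ll_trace = f$ll_trace)
  class(out) <- "enrichment_model"
  out
}

#' @export
print.enrichment_model <- function(x, ...) {
  cat(sprintf("enrichment_model: %d component(s) fitted on %d coefficients\n",
              x$n_components, x$fit_n))
  cat(sprintf("  main component mean: %.4f\n", x$main_mean))
  print(x$components)
  invisible(x)
}

#' @export
summary.enrichment_model <- function(object, ...) {
  cat(sprintf("Gaussian mixture over RNase R enrichment coefficients (n = %d)\n",
              object$fit_n))
  print(object$components)
  cat("BIC by component count:\n")
  print(round(object$bic_trace, 2))
  invisible(object)
}

#' Mixture density of a fitted enrichment model
#'
#' @param model `enrichment_model`.
#' @param x evaluation points.
#' @return numeric density values.
#' @export
enrichment_density <- function(model, x) {
  comp <- model$components
  dens <- vapply(seq_len(nrow(comp)), function(j) {
    comp$weight[j] * dnorm(x, comp$mean[j], comp$sd[j])
  }, numeric(length(x)))
  rowSums(matrix(dens, nrow = length(x)))
}

#' Draw enrichment coefficients from a fitted model
#'
#' Draws are truncated to (`lower`, Inf) by rejection.
#'
#' @param model `enrichment_model`.
#' @param n number of draws.
#' @param lower lower truncation bound (default 0: coefficients are
#'   positive).
#' @return numeric vector of length `n`.
#' @export
sample_enrichment <- function(model, n, lower = 0) {
  comp <- model$components
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    ki <- sample.int(nrow(comp), m, replace = TRUE, prob = comp$weight)
    x <- rnorm(m, comp$mean[ki], comp$sd[ki])
    out <- c(out, x[x > lower])
  }
  out[seq_len(n)]
}

#' Correct treated-library BSJ counts to the untreated scale
#'
#' Point estimate: `fsj_m * (bsj_r / fsj_r) / main_mean`, the algebraic
#' inversion of the coefficient equation at the main-component mean. The
#' returned sampler propagates the full fitted coefficient distribution:
#' each draw replaces `main_mean` by a coefficient drawn from the mixture
#' truncated to positive values, yielding the induced posterior of corrected
#' counts for DE-score integration.
#'
#' @param bsj_r,fsj_r treated-library junction counts (`fsj_r` > 0).
#' @param fsj_m untreated-library FSJ count(s).
#' @param model fitted `enrichment_model` (main_mean > 0).
#' @return list with `estimate` (numeric, same length as inputs) and
#'   `sample(n)` (function returning an n-by-length(estimate) matrix of
#'   posterior corrected counts).
#' @export
correct_bsj <- function(bsj_r, fsj_r, fsj_m, model) {
  if (any(fsj_r <= 0)) stop("fsj_r must be > 0", call. = FALSE)
  if (model$main_mean <= 0) stop("main_mean must be > 0", call. = FALSE)
  odds <- bsj_r / fsj_r
  est <- fsj_m * odds / model$main_mean
  sampler <- function(n) {
    eff <- sample_enrichment(model, n)
    outer(1 / eff, fsj_m * odds)
  }
  list(estimate = est, sample = sampler)
}

#' Deviation ratio between treated and untreated expression
#'
#' Symmetric relative difference of CPM values, bounded in (-2, 2); zero
#' means the expression estimate is unchanged by the treatment.
#'
#' @param cpm_treated,cpm_untreated CPM values (vectorized).
#' @return numeric deviation ratio(s); NA where both CPMs are zero.
#' @export
deviation_ratio <- function(cpm_treated, cpm_untreated) {
  s <- cpm_treated + cpm_untreated
  out <- (cpm_treated - cpm_untreated) / (0.5 * s)
  out[s == 0] <- NA_real_
  out
}

#' Fit and apply RNase R correction on paired junction counts
#'
#' Convenience wrapper around [enrichment_coefficient()], [fit_gmm()],
#' [correct_bsj()] and [deviation_ratio()] for a table of paired
#' treated/untreated junction counts.
#'
#' @param counts data.table with columns bsj_m, fsj_m, bsj_r, fsj_r (e.g.
#'   from [simulate_paired_counts()]); attributes `total_m`/`total_r` set the
#'   library totals for CPM (falling back to column sums).
#' @param k_max,min_n,winsorize passed to [fit_gmm()].
#' @return list: `model` (enrichment_model) and `table` (input plus eff_hat,
#'   corrected_bsj, cpm_m, cpm_r, corrected_cpm, deviation_pre,
#'   deviation_post).
#' @export
correct_paired_counts <- function(counts, k_max = 5L, min_n = 20L,
                                  winsorize = 0.99) {
  x <- as.data.table(counts)
  total_m <- attr(counts, "total_m") %||% sum(x$bsj_m + x$fsj_m)
  total_r <- attr(counts, "total_r") %||% sum(x$bsj_r + x$fsj_r)
  x[, eff_hat := enrichment_coefficient(bsj_r, fsj_r, bsj_m, fsj_m)]
  model <- fit_gmm(x$eff_hat, k_max = k_max, min_n = min_n,
                   winsorize = winsorize)
  usable <- x$fsj_r > 0
  x[, corrected_bsj := NA_real_]
  x[usable, corrected_bsj := correct_bsj(bsj_r, fsj_r, fsj_m, model)$estimate]
  x[, cpm_m := compute_cpm(bsj_m, total_m)]
  x[, cpm_r := compute_cpm(bsj_r, total_r)]
  x[, corrected_cpm := compute_cpm(corrected_bsj, total_m)]
  x[, deviation_pre := deviation_ratio(cpm_r, cpm_m)]
  x[, deviation_post := deviation_ratio(corrected_cpm, cpm_m)]
  list(model = model, table = x[])
}

#' Serialize a fitted enrichment model to YAML
#'
#' @param model `enrichment_model`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
write_enrichment_model <- function(model, path) {
  yaml::write_yaml(list(
    n_components = model$n_components,
    main_mean = model$main_mean,
    fit_n = model$fit_n,
    components = lapply(seq_len(nrow(model$components)), function(i) {
      as.list(model$components[i, ])
    })
  ), path, precision = 15)
  invisible(path)
}

#' Load an enrichment model from YAML
#'
#' @param path YAML file written by [write_enrichment_model()].
#' @return `enrichment_model` object.
#' @export
read_enrichment_model <- function(path) {
  y <- yaml::read_yaml(path)
  comp <- rbindlist(y$components)
  out <- list(components = comp, n_components = y$n_components,
              main_mean = y$main_mean, bic_trace = NULL, fit_n = y$fit_n,
              loglik = NA_real_, ll_trace = NULL)
  class(out) <- "enrichment_model"
  out
}
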