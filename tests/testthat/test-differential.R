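test_that("DE-score is zero for identical inputs and clipped toward zero", {
  expect_equal(de_score(25, 1, 25, 1, seed = 1)$score, 0)
  expect_equal(de_score(25, 1, 25, 1, method = "exact")$score, 0)
  up <- de_score(10, 1, 1000, 1, seed = 2)
  expect_gt(up$score, 0)
  expect_lte(up$score, up$mean_log2fc)
  dn <- de_score(1000, 1, 10, 1, seed = 2)
  expect_lt(dn$score, 0)
  ## antisymmetry within Monte-Carlo tolerance
  expect_lt(abs(abs(dn$score) - abs(up$score)), 0.05)
})

test_that("Monte-Carlo DE-scores agree with the exact Gamma-ratio quantiles", {
  cases <- list(c(10, 1000), c(5, 50), c(100, 30), c(3, 3), c(0, 20))
  for (cs in cases) {
    mc <- de_score(cs[1], 1, cs[2], 1, draws = 2e5, seed = 3)
    ex <- de_score(cs[1], 1, cs[2], 1, method = "exact")
    expect_lt(abs(mc$score - ex$score), 0.05)
    expect_lt(abs(mc$mean_log2fc - ex$mean_log2fc), 0.05)
  }
})

test_that("DE-score is monotone in the second count (exact quantiles)", {
  grid <- c(1, 5, 10, 50, 200, 1000)
  scores <- vapply(grid, function(k2) de_score(20, 1, k2, 1,
                                               method = "exact")$score,
                   numeric(1))
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("correction samplers shift the treated-side posterior", {
  model <- structure(list(
    components = data.table::data.table(mean = 0.5, sd = 0.05, weight = 1),
    n_components = 1L, main_mean = 0.5, fit_n = 50L),
    class = "enrichment_model")
  cb <- correct_bsj(50, 100, 100, model)   # estimate = 100
  s2 <- function(n) as.numeric(cb$sample(n))
  plain <- de_score(50, 1, 50, 1, seed = 4)
  corr <- de_score(50, 1, 50, 1, seed = 4, sampler2 = s2)
  expect_equal(plain$score, 0)
  expect_gt(corr$score, 0)   # corrected treated count ~100 vs 50
})

test_that("DS-score handles identical, shifted and boundary counts", {
  expect_equal(ds_score(30, 70, 30, 70, seed = 5)$score, 0)
  expect_lt(ds_score(50, 50, 5, 95, seed = 6)$score, 0)
  bnd <- ds_score(0, 100, 100, 0, seed = 7)
  expect_gt(bnd$score, 0)
  expect_true(is.finite(bnd$score))
  expect_error(ds_score(0, 100, 100, 0, offset = 0), "positive")
  sw <- ds_score(5, 95, 50, 50, seed = 6)
  expect_lt(abs(abs(sw$score) -
                abs(ds_score(50, 50, 5, 95, seed = 6)$score)), 0.05)
})

test_that("Fisher test equals hypergeometric enumeration on small tables", {
  expect_equal(fisher_de_test(5, 100, 5, 100), 1)
  expect_equal(fisher_de_test(5, 100, 5, 100), 1)
  oracle <- function(b1, t1, b2, t2) {
    m <- b1 + b2; n <- (t1 - b1) + (t2 - b2)
    x <- max(0, t1 - n):min(t1, m)
    p <- dhyper(x, m, n, t1)
    sum(p[p <= dhyper(b1, m, n, t1) * (1 + 1e-7)])
  }
  expect_equal(fisher_de_test(1, 10, 9, 10), oracle(1, 10, 9, 10),
               tolerance = 1e-12)
  expect_error(fisher_de_test(5, 3, 1, 10), "negative")
})

test_that("rate-ratio test equals conditional binomial enumeration", {
  expect_equal(rate_ratio_test(10, 100, 10, 100), 1)
  expect_equal(rate_ratio_test(0, 100, 0, 100), 1)
  oracle <- function(b1, f1, b2, f2) {
    n <- b1 + b2
    p0 <- f1 / (f1 + f2)
    pr <- dbinom(0:n, n, p0)
    sum(pr[pr <= dbinom(b1, n, p0) * (1 + 1e-7)])
  }
  expect_equal(rate_ratio_test(10, 100, 10, 300), oracle(10, 100, 10, 300),
               tolerance = 1e-12)
  expect_error(rate_ratio_test(10, 0, 10, 100), "exposure")
})

## straight-line implementation of the published TMM recipe, independent of
## the package route
tmm_oracle <- function(mat) {
  lib <- colSums(mat)
  uq <- apply(mat, 2, quantile, 0.75) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(mat)), function(j) {
    keep <- mat[, j] > 0 & mat[, ref] > 0
    y <- mat[keep, j] / lib[j]
    r <- mat[keep, ref] / lib[ref]
    M <- log2(y / r)
    A <- (log2(y) + log2(r)) / 2
    w <- 1 / ((lib[j] - mat[keep, j]) / (lib[j] * mat[keep, j]) +
              (lib[ref] - mat[keep, ref]) / (lib[ref] * mat[keep, ref]))
    loM <- quantile(M, 0.3, type = 7); hiM <- quantile(M, 0.7, type = 7)
    loA <- quantile(A, 0.05, type = 7); hiA <- quantile(A, 0.95, type = 7)
    use <- M >= loM & M <= hiM & A >= loA & A <= hiA
    2^(sum(w[use] * M[use]) / sum(w[use]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

test_that("TMM factors behave on identity, depth and composition changes", {
  set.seed(301)
  base <- rnbinom(1000, mu = 100, size = 2) + 1L
  two_same <- cbind(a = base, b = base)
  expect_equal(as.numeric(tmm_factors(two_same)), c(1, 1))
  doubled <- cbind(a = base, b = 2L * base)
  expect_equal(as.numeric(tmm_factors(doubled)), c(1, 1), tolerance = 1e-8)
  ## composition change needs biological noise between libraries: with
  ## exactly proportional columns every M-value ties and trimming is moot
  mu <- rlnorm(1000, log(100), 0.8)
  noisy <- cbind(a = rpois(1000, mu), b = rpois(1000, mu)) + 1L
  spiked <- noisy
  idx <- seq_len(100)
  spiked[idx, "b"] <- spiked[idx, "b"] * 50L
  f <- tmm_factors(spiked)
  expect_lt(as.numeric(f["b"]), 1)
  o <- tmm_oracle(spiked)
  expect_equal(as.numeric(f), as.numeric(o), tolerance = 0.03)
  expect_error(tmm_factors(base), "2 libraries")
})

test_that("replicate GLM is calibrated under the null", {
  set.seed(302)
  mu <- rlnorm(1500, log(50), 1)
  cnt <- vapply(1:6, function(j) rnbinom(1500, mu = mu, size = 10),
                numeric(1500))
  de <- replicate_de(cnt, rep(c("a", "b"), each = 3))
  expect_true(mean(de$pvalue < 0.05, na.rm = TRUE) > 0.02)
  expect_true(mean(de$pvalue < 0.05, na.rm = TRUE) < 0.08)
  ## all-zero circRNA rows are reported as NA, not an error
  cnt[1, ] <- 0L
  de2 <- replicate_de(cnt, rep(c("a", "b"), each = 3))
  expect_true(is.na(de2$pvalue[1]))
  expect_false(any(is.na(de2$pvalue[-1])))
  expect_error(replicate_de(cnt, rep("a", 6)), "two conditions")
})

test_that("a strong fold change is detected with high power (3 vs 3)", {
  ## true 4-fold change, mean 100, dispersion 0.1; power claim checked
  ## against its Monte-Carlo error over the replications
  set.seed(303)
  reps <- 120
  hits <- vapply(seq_len(reps), function(r) {
    y <- rbind(matrix(rnbinom(199 * 6, mu = 50, size = 10), ncol = 6),
               rnbinom(6, mu = c(rep(100, 3), rep(400, 3)), size = 10))
    d <- replicate_de(y, rep(c("a", "b"), each = 3))
    d$fdr[200] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9 - 1.645 * sqrt(0.9 * 0.1 / reps))
})

test_that("the replicate-free differential table combines scores and tests", {
  sc <- small_scene(seed = 304)
  q1 <- quantify_library(sc$reads, sc$genome, sc$circs, library_id = "a")
  tr <- apply_rnase_r(sc$reads, eff_mixture = rbind(c(1, 0, 1)),
                      linear_survival = 1, seed = 5)
  q2 <- quantify_library(tr, sc$genome, sc$circs, library_id = "b")
  de <- differential_table(q1, q2, draws = 2000, seed = 6)
  expect_equal(nrow(de), nrow(sc$circs))
  expect_true(all(de$p_de >= 0 & de$p_de <= 1))
  ## identical libraries: scores vanish, Fisher p-values are 1
  expect_true(all(de$de_score == 0))
  expect_equal(de$p_de, rep(1, nrow(de)))
})
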