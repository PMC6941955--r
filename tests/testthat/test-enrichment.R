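test_that("enrichment coefficient follows the odds-ratio definition", {
  expect_equal(enrichment_coefficient(20, 10, 5, 20), 8)
  expect_equal(enrichment_coefficient(10, 5, 20, 10), 1)  # null enrichment
  expect_true(is.na(enrichment_coefficient(10, 0, 5, 20)))
  expect_true(is.na(enrichment_coefficient(10, 5, 0, 20)))
  expect_true(is.na(enrichment_coefficient(10, 5, 20, 0)))
  ## vectorized
  expect_equal(enrichment_coefficient(c(20, 10), c(10, 5), c(5, 20), c(20, 10)),
               c(8, 1))
})

test_that("the mixture fit recovers single-component parameters", {
  set.seed(201)
  x <- rnorm(2000, 0.9, 0.05)
  m <- fit_gmm(x, winsorize = NULL)
  expect_equal(m$n_components, 1L)
  expect_lt(abs(m$main_mean - 0.9), 0.01)
  expect_lt(abs(m$components$sd[1] - 0.05), 0.01)
})

test_that("the mixture fit recovers two components and the main mean", {
  set.seed(202)
  x <- c(rnorm(1400, 0.95, 0.02), rnorm(600, 0.6, 0.05))
  m <- fit_gmm(x, winsorize = NULL)
  expect_equal(m$n_components, 2L)
  expect_lt(abs(m$main_mean - 0.95), 0.02)
  expect_lt(abs(m$components$weight[1] - 0.7), 0.05)
})

test_that("mixture fitting agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(withr::local_package("mclust"))
  set.seed(203)
  x <- c(rnorm(1400, 0.95, 0.02), rnorm(600, 0.6, 0.05))
  m <- fit_gmm(x, winsorize = NULL)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  main_mc <- mc$parameters$mean[which.max(mc$parameters$pro)]
  expect_lt(abs(m$main_mean - main_mc), 0.01)
})

test_that("degenerate and undersized inputs are handled explicitly", {
  m <- fit_gmm(rep(0.9, 100))
  expect_equal(m$n_components, 1L)
  expect_equal(m$components$sd[1], 1e-4)   # sd floor
  expect_error(fit_gmm(rnorm(10, 0.9, 0.1)), "empirical")
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(204)
  x <- c(rnorm(300, 0.95, 0.02), rnorm(150, 0.6, 0.05))
  for (k in 1:4) {
    f <- bsjquant:::em_gmm_1d(x, k)
    expect_true(all(diff(f$ll_trace) >= -1e-8))
  }
})

test_that("count correction inverts the coefficient equation", {
  model <- structure(list(
    components = data.table::data.table(mean = 2, sd = 0.1, weight = 1),
    n_components = 1L, main_mean = 2, fit_n = 100L), class = "enrichment_model")
  cb <- correct_bsj(80, 20, 100, model)
  expect_equal(cb$estimate, 200)
  ## main_mean = 1: corrected equals fsj_m x treated junction odds
  model1 <- model; model1$main_mean <- 1
  expect_equal(correct_bsj(80, 20, 100, model1)$estimate, 100 * 80 / 20)
  model0 <- model; model0$main_mean <- -1
  expect_error(correct_bsj(80, 20, 100, model0), "main_mean")
  expect_error(correct_bsj(80, 0, 100, model), "fsj_r")
  ## sampler draws are positive and centred near the point estimate
  draws <- cb$sample(2000)
  expect_equal(dim(draws), c(2000L, 1L))
  expect_true(all(draws > 0))
  expect_lt(abs(stats::median(draws) / cb$estimate - 1), 0.2)
})

test_that("deviation ratio is bounded, antisymmetric and anchored at zero", {
  expect_equal(deviation_ratio(5, 5), 0)
  expect_equal(deviation_ratio(3, 1), 1)
  expect_equal(deviation_ratio(0, 1), -2)
  expect_true(is.na(deviation_ratio(0, 0)))
  set.seed(205)
  a <- runif(200, 0, 50)
  b <- runif(200, 0, 50)
  d <- deviation_ratio(a, b)
  expect_true(all(d > -2 - 1e-12 & d < 2 + 1e-12))
  expect_equal(deviation_ratio(b, a), -d)
})

test_that("correction tightens deviation ratios and tracks true counts", {
  pc <- simulate_paired_counts(n_circ = 400, seed = 206)
  res <- correct_paired_counts(pc)
  tb <- res$table
  expect_lt(stats::IQR(tb$deviation_post, na.rm = TRUE),
            stats::IQR(tb$deviation_pre, na.rm = TRUE))
  rel <- abs(tb$corrected_bsj - tb$bsj_m) / tb$bsj_m
  expect_lte(stats::median(rel[tb$bsj_m >= 20], na.rm = TRUE), 0.15)
})

test_that("enrichment models round-trip through YAML", {
  set.seed(207)
  m <- fit_gmm(rnorm(200, 0.9, 0.05))
  f <- tempfile(fileext = ".yaml")
  write_enrichment_model(m, f)
  m2 <- read_enrichment_model(f)
  expect_equal(m2$main_mean, m$main_mean)
  expect_equal(as.data.frame(m2$components), as.data.frame(m$components))
  expect_equal(m2$fit_n, m$fit_n)
})
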