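test_that("boundary expression regimes give the expected true junction ratios", {
  g <- simulate_genome(1, 1e5, 8, c(3, 6), seed = 51)
  circs <- simulate_circrnas(g, 4, seed = 52)

  ## zero circular expression, 10x linear coverage -> ratio 0
  c0 <- data.table::copy(circs)
  c0$n_frag <- c(0L, 10L, 10L, 10L)
  sr0 <- simulate_reads(g, c0, sim_config(seed = 53))
  expect_equal(sr0$truth[id == c0$id[1]]$junction_ratio_true, 0)

  ## zero linear coverage, expressed circRNAs -> ratio 1 where BSJ exists
  ## (one candidate per gene: a larger co-hosted circle would contribute
  ## linear-type FSJ evidence across a nested candidate's boundary)
  circs <- circs[!duplicated(gene_id)]
  sr1 <- simulate_reads(g, circs, sim_config(linear_coverage = 0, seed = 54))
  with_bsj <- sr1$truth[bsj_true > 0]
  expect_gt(nrow(with_bsj), 0)
  expect_true(all(with_bsj$junction_ratio_true == 1))
})

test_that("read simulation is reproducible under a fixed seed", {
  g <- simulate_genome(1, 1e5, 8, c(3, 6), seed = 55)
  circs <- simulate_circrnas(g, 6, seed = 56)
  a <- simulate_reads(g, circs, sim_config(seed = 7))
  b <- simulate_reads(g, circs, sim_config(seed = 7))
  expect_identical(a$r1, b$r1)
  expect_identical(a$r2, b$r2)
  expect_equal(as.data.frame(a$truth), as.data.frame(b$truth))
})

test_that("circles shorter than the read length are rejected unless allowed", {
  g <- toy_genome()
  short <- data.table::data.table(
    id = "s", chrom = "chr1", start = 200L, end = 260L, strand = "+",
    gene_id = "gA", tx_id = "gA.t1", n_exons = 1L, spliced_len = 60L,
    exons = list(matrix(c(200L, 260L), nrow = 1)))
  expect_error(simulate_reads(g, short, sim_config(seed = 1)), "allow_short")
  sr <- simulate_reads(g, short, sim_config(seed = 1, allow_short = TRUE))
  expect_equal(sr$truth$bsj_true, 0)
})

test_that("stored truth equals an independent provenance recount", {
  sc <- small_scene(seed = 61)
  circ_lens <- stats::setNames(sc$reads$truth$spliced_len, sc$reads$truth$id)
  recount <- recount_bsj_from_names(sc$reads, as.list(circ_lens))
  expect_equal(unname(recount[sc$reads$truth$id]), sc$reads$truth$bsj_true)
  ## ratio recomputes exactly from stored counts
  tt <- sc$reads$truth
  ok <- tt$bsj_true + tt$fsj_true > 0
  expect_equal(tt$junction_ratio_true[ok],
               2 * tt$bsj_true[ok] / (2 * tt$bsj_true[ok] + tt$fsj_true[ok]))
})

test_that("identity RNase R treatment returns the library unchanged", {
  sc <- small_scene(n_genes = 6, n_circ = 5, chrom_len = 8e4, seed = 62)
  tr <- apply_rnase_r(sc$reads, eff_mixture = rbind(c(1, 0, 1)),
                      linear_survival = 1, seed = 1)
  expect_identical(sort(names(tr$r1)), sort(names(sc$reads$r1)))
  expect_identical(tr$r1[names(sc$reads$r1)], sc$reads$r1)
  expect_true(all(tr$truth$eff == 1))
})

test_that("thinning is a subset of the input and never invents reads", {
  sc <- small_scene(n_genes = 6, n_circ = 5, chrom_len = 8e4, seed = 63)
  tr <- apply_rnase_r(sc$reads, linear_survival = 0.3, seed = 2)
  expect_true(all(names(tr$r1) %in% names(sc$reads$r1)))
  expect_lt(tr$n_pairs, sc$reads$n_pairs)
  expect_error(apply_rnase_r(
    structure(list(n_pairs = 0), class = "sim_reads")), "empty")
})

test_that("realized enrichment matches the drawn coefficient (thinning oracle)", {
  ## coefficient fixed at 1, linear survival 0.25: the realized junction
  ## odds ratio estimates 1 within binomial sampling error
  g <- simulate_genome(1, 1e5, 10, c(3, 6), seed = 64)
  circs <- simulate_circrnas(g, 5, seed = 65)[1]
  circs$n_frag <- 3000L
  sr <- simulate_reads(g, circs, sim_config(seed = 66))
  tr <- apply_rnase_r(sr, eff_mixture = rbind(c(1, 0, 1)),
                      linear_survival = 0.25, seed = 3)
  t_m <- sr$truth[id == circs$id]
  t_r <- tr$truth[id == circs$id]
  expect_gte(t_m$bsj_true, 500)
  eff_hat <- (t_r$bsj_true / t_r$fsj_true) / (t_m$bsj_true / t_m$fsj_true)
  ## binomial error of the four counts, 3 standard errors
  se <- eff_hat * sqrt(1 / t_r$bsj_true + 1 / t_r$fsj_true)
  expect_lt(abs(eff_hat - 1), 3 * se)
})

test_that("drawn coefficients follow the configured mixture", {
  g <- simulate_genome(2, 3e5, 40, c(3, 8), seed = 67)
  circs <- simulate_circrnas(g, 200, seed = 68)
  circs$n_frag <- rep(5L, 200)
  sr <- simulate_reads(g, circs, sim_config(linear_coverage = 1, seed = 69))
  tr <- apply_rnase_r(sr, eff_mixture = rbind(c(0.95, 0.02, 0.7),
                                              c(0.7, 0.1, 0.3)),
                      linear_survival = 0.5, seed = 4)
  effs <- tr$truth$eff
  expect_true(all(effs > 0 & effs <= 1))
  ## closed-form mixture mean 0.875, sd of the mean over 200 draws
  mix_var <- 0.7 * (0.02^2 + 0.95^2) + 0.3 * (0.1^2 + 0.7^2) - 0.875^2
  expect_lt(abs(mean(effs) - 0.875), 3 * sqrt(mix_var / 200))
})
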