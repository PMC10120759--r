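test_that("closed-form posterior matches the independence-case formula", {
  m <- 6
  ids <- paste0("v", 1:m)
  set.seed(1)
  bh <- rnorm(m, 0, 0.05)
  ss <- toy_ss(bh, n_gwas = 500L, ids = ids)
  blocks <- toy_identity_blocks(ids)
  sig <- seq(0.01, 0.06, length.out = m)
  h <- per_snp_heritability(sig)          # c = 1
  eff <- ldpred_funct_posterior(ss, blocks, h, n = 500)
  expect_equal(eff, 500 * bh / (500 + 1 / sig), tolerance = 1e-10)
})

test_that("closed-form posterior limits behave", {
  ids <- c("a", "b")
  D <- matrix(c(1, 0.6, 0.6, 1), 2)
  ss <- toy_ss(c(0.2, -0.1), n_gwas = 1000L, ids = ids)
  blocks <- list(ld_block(ids, D))
  # huge per-SNP heritability -> vanishing penalty -> D^{-1} beta_hat
  h_inf <- per_snp_heritability(c(1e8, 1e8))
  expect_equal(ldpred_funct_posterior(ss, blocks, h_inf),
               drop(solve(D, c(0.2, -0.1))), tolerance = 1e-4)
  # null effects -> null posterior
  ss0 <- toy_ss(c(0, 0), n_gwas = 1000L, ids = ids)
  expect_equal(ldpred_funct_posterior(ss0, blocks, h_inf), c(0, 0))
  # zero-heritability variants are excluded with effect 0
  h_z <- per_snp_heritability(c(0.1, 0))
  expect_warning(out <- ldpred_funct_posterior(ss, blocks, h_z), "zero")
  expect_equal(out[2], 0)
})

test_that("uniform per-SNP heritability reduces to a plain ridge solve", {
  m <- 9
  ids <- paste0("v", 1:m)
  set.seed(3)
  G <- matrix(rnorm(400 * m), 400, m, dimnames = list(NULL, ids))
  blocks <- ld_blocks_from_genotypes(G, tibble::tibble(start = c(1, 6), end = c(6, 10)))
  bh <- rnorm(m, 0, 0.1)
  ss <- toy_ss(bh, n_gwas = 800L, ids = ids)
  h <- per_snp_heritability(rep(0.02, m))
  eff <- ldpred_funct_posterior(ss, blocks, h)
  # oracle: direct block-diagonal ridge solve, assembled independently
  Dfull <- matrix(0, m, m)
  Dfull[1:5, 1:5] <- blocks[[1]]$D; Dfull[6:9, 6:9] <- blocks[[2]]$D
  direct <- solve(800 * Dfull + diag(1 / 0.02, m), 800 * bh)
  expect_equal(eff, drop(direct), tolerance = 1e-10)
})

test_that("normalizing constant scales per-SNP heritability to the total", {
  h <- per_snp_heritability(c(0.1, 0.3), h2_total = 0.2)
  expect_equal(h$c * sum(h$sigma_j2), 0.2)
})

test_that("greedy binning follows the rank-and-fill rule", {
  eff <- c(3, 2, 1, 1, 1, 1, 1, 1)
  bins <- bin_by_posterior(eff, L = 2)
  expect_equal(bins, c(1, 1, 2, 2, 2, 2, 2, 2))
  expect_equal(sum(eff[bins == 1]^2), 13)
  expect_equal(sum(eff[bins == 2]^2), 6)

  expect_equal(bin_by_posterior(c(0.5, 1, 2), L = 1), rep(1, 3))
  even <- bin_by_posterior(rep(2, 8), L = 4)
  expect_equal(as.integer(table(even)), rep(2L, 4))
  expect_warning(b <- bin_by_posterior(c(1, 0, 0), L = 3), "reduced")
  expect_equal(max(b), 1)
})

test_that("bin sums of squares stay within the factor-2 bound", {
  set.seed(5)
  eff <- rnorm(500) * rbinom(500, 1, 0.4)
  L <- 10
  bins <- bin_by_posterior(eff, L)
  expect_equal(sort(unique(bins)), 1:L)
  target <- sum(eff^2) / L
  ssq <- vapply(1:L, function(b) sum(eff[bins == b]^2), numeric(1))
  expect_true(all(ssq[-L] <= 2 * target + max(eff^2)))
  expect_true(all(ssq[-L] >= target / 2 | table(bins)[-L] == 1))
})

test_that("the binned comparator feeds the shared weighting machinery", {
  set.seed(6)
  m <- 30; n <- 250
  ids <- paste0("v", 1:m)
  G <- matrix(rnorm(n * m), n, m, dimnames = list(NULL, ids))
  beta <- rnorm(m, 0, 0.1)
  y <- drop(G %*% beta) + rnorm(n, sd = 0.5)
  ss <- marginal_gwas(bilevelprs:::standardize_genotypes(G), (y - mean(y)) / sd(y))
  blocks <- toy_identity_blocks(ids, block_size = 10)
  h <- per_snp_heritability(rep(1 / m, m), h2_total = 0.5)
  lf <- ldpred_funct(ss, blocks, h, G, y, L = 5, seed = 2)
  expect_length(lf$final, n)
  expect_equal(max(lf$bins), 5)
  expect_gt(mean(lf$weights$fold_metrics$r2), 0.2)
})
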