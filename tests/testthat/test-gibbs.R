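test_that("chain configuration is validated", {
  expect_error(gibbs_config(n_iter = 100, n_burnin = 100))
  expect_error(gibbs_config(thin = 0))
  expect_equal(gibbs_config()$mode, "derived")
})

test_that("full-conditional rates match the worked examples", {
  # sigma2: beta = 0 -> rate N/2; the 1-SNP plug-in gives N/2 at N = 100
  expect_equal(bilevelprs:::sigma2_rate(0, 0.5, quad = 0, n = 100), 50)
  quad <- 0.5 * 1 * 0.5 + 0.5^2 / 1   # beta' D beta + beta^2/psi
  expect_equal(bilevelprs:::sigma2_rate(0.5, 0.5, quad = quad, n = 100), 50)

  # delta2, printed form: rate = sum N beta^2/(2 sigma2 lambda2) + t
  expect_equal(bilevelprs:::delta2_rate(c(0, 0, 0), c(1, 1, 1), 1, t_k = 2,
                                        n = 100, mode = "as_printed"), 2)
  expect_equal(bilevelprs:::delta2_rate(0.1, 0.5, 1, t_k = 1, n = 100,
                                        mode = "as_printed"), 2)
  # derived form replaces t with 1/t (equal at t = 1)
  expect_equal(bilevelprs:::delta2_rate(0.1, 0.5, 1, t_k = 1, n = 100,
                                        mode = "derived"), 2)
  expect_equal(bilevelprs:::delta2_rate(c(0, 0), c(1, 1), 1, t_k = 2, n = 100,
                                        mode = "derived"), 0.5)

  # lambda2: both modes agree at delta2 = c = 1
  expect_equal(bilevelprs:::lambda2_rate(0.1, 1, 1, 1, 100, "derived"), 1.5)
  expect_equal(bilevelprs:::lambda2_rate(0.1, 1, 1, 1, 100, "as_printed"), 1.5)
  expect_equal(bilevelprs:::lambda2_rate(0, 1, 1, 4, 100, "as_printed"), 4)
  expect_equal(bilevelprs:::lambda2_rate(0, 1, 1, 4, 100, "derived"), 0.25)
  # derived mode carries the group scale in the data term
  expect_equal(bilevelprs:::lambda2_rate(0.1, 1, delta2 = 2, c_aux = 1, 100,
                                         "derived"), 0.25 + 1)
})

test_that("auxiliary draws match a direct inverse-gamma sampler in distribution", {
  set.seed(7)
  t_draws <- replicate(4000, sample_t(1))
  set.seed(8)
  ref <- 1 / rgamma(4000, shape = 1, rate = 2)   # IG(1, 1/1 + 1)
  expect_gt(suppressWarnings(stats::ks.test(t_draws, ref))$p.value, 0.01)
  expect_true(all(t_draws > 0))

  set.seed(9)
  c_draws <- sample_c(rep(4, 4000))               # IG(1, 1/4 + 1)
  set.seed(10)
  ref_c <- 1 / rgamma(4000, shape = 1, rate = 1.25)
  expect_gt(suppressWarnings(stats::ks.test(c_draws, ref_c))$p.value, 0.01)
})

test_that("all shrinkage conditionals produce strictly positive draws", {
  set.seed(11)
  expect_true(all(sample_lambda2(rnorm(100), 1, 1, rep(1, 100), 50) > 0))
  expect_true(all(replicate(100, sample_delta2(rnorm(5), rep(1, 5), 1, 1, 50)) > 0))
  blocks <- list(list(D = diag(2), idx = 1:2))
  expect_true(all(replicate(100,
    sample_sigma2(c(0.1, -0.2), c(0.1, -0.1), blocks, c(1, 1), 50)) > 0))
})

test_that("beta block draw has the stated mean and covariance", {
  # sigma2 -> 0 isolates the conditional mean (I + I)^{-1} beta_hat
  m <- sample_beta_block(diag(2), c(1, 0), psi_block = c(1, 1),
                         sigma2 = 0, n = 100)
  expect_equal(m, c(0.5, 0))

  # no-shrinkage limit: psi capped high, D = I -> mean = beta_hat
  m2 <- sample_beta_block(diag(3), c(0.3, -0.2, 0.1), psi_block = rep(1e10, 3),
                          sigma2 = 0, n = 100)
  expect_equal(m2, c(0.3, -0.2, 0.1), tolerance = 1e-8)

  # Monte-Carlo covariance against sigma2/n (D + Psi^-1)^{-1}
  D <- matrix(c(1, 0.4, 0.4, 1), 2)
  psi <- c(0.5, 2); sigma2 <- 1.3; n <- 50
  set.seed(12)
  draws <- t(replicate(2e4, sample_beta_block(D, c(0.2, 0.1), psi, sigma2, n)))
  target <- sigma2 / n * solve(D + diag(1 / psi))
  expect_equal(stats::cov(draws), target, tolerance = 0.05)
  expect_equal(colMeans(draws), drop(solve(D + diag(1 / psi), c(0.2, 0.1))),
               tolerance = 0.01)
})

test_that("conditional shrinkage is monotone in psi and strictly toward zero", {
  psis <- c(0.1, 0.5, 1, 5, 50)
  means <- vapply(psis, function(p)
    sample_beta_block(diag(1), 0.4, p, sigma2 = 0, n = 100), numeric(1))
  expect_true(all(diff(means) > 0))
  expect_true(all(means < 0.4 & means > 0))
  expect_equal(means, 0.4 / (1 + 1 / psis))
})

test_that("factorization failure points at ridge repair", {
  D <- matrix(c(1, 1.5, 1.5, 1), 2)  # indefinite even with modest psi
  expect_error(sample_beta_block(D, c(0, 0), c(1e8, 1e8), 1, 100), "ridge")
})

test_that("chains are reproducible and shrink a null signal", {
  ids <- paste0("v", 1:60)
  ss <- toy_ss(rep(0, 60), n_gwas = 1000L, ids = ids)
  blocks <- toy_identity_blocks(ids, block_size = 20)
  design <- expand_overlap(one_group_map(ids), ss)
  cfg <- gibbs_config(n_iter = 400, n_burnin = 200, seed = 3)
  fit1 <- run_gibbs(ss, blocks, design, cfg)
  fit2 <- run_gibbs(ss, blocks, design, cfg)
  expect_identical(fit1$beta_tilde_copies, fit2$beta_tilde_copies)
  expect_true(all(abs(fit1$beta_tilde_copies) < 0.01))
  expect_s3_class(glance(fit1), "tbl_df")
  expect_equal(nrow(tidy(fit1)), 60)
})

test_that("misaligned inputs are rejected", {
  ids <- paste0("v", 1:4)
  ss <- toy_ss(rep(0, 4), ids = rev(ids))
  blocks <- toy_identity_blocks(ids)
  design <- expand_overlap(one_group_map(rev(ids)), ss)
  expect_error(run_gibbs(ss, blocks, design, gibbs_config(n_iter = 10, n_burnin = 5)),
               "aligned")
})
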