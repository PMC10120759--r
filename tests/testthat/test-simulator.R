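test_that("the seven study presets carry the published architecture", {
  st <- sim_settings()
  expect_equal(nrow(st), 7)
  expect_equal(st$m_k[[1]], c(49750, 37500, 25125, 12625))
  expect_equal(st$q_k[[4]], c(25, 25, 25, 25))
  expect_equal(st$q_k[[5]], c(rep(0, 8), 10, 90))
  expect_equal(st$k[5], 10)
  expect_equal(st$overlap[6:7], c("overlap_I", "overlap_II"))
  expect_true(all(vapply(st$q_k, sum, numeric(1)) == 100))
  expect_true(all(vapply(st$m_k, sum, numeric(1)) == 125000))
  expect_equal(unique(st$h2), 0.7)
})

test_that("simulated genotypes are standardized with block-local LD", {
  gen <- make_genotypes(n = 800, m = 30, block_size = 10, rho = 0.7, seed = 2)
  G <- gen$genotypes
  expect_equal(unname(colMeans(G)), rep(0, 30), tolerance = 1e-12)
  expect_equal(unname(colSums(G^2)), rep(800, 30), tolerance = 1e-8)
  expect_length(gen$blocks, 3)
  # adjacent within-block correlation is strong, cross-block is weak
  r_adj <- mean(vapply(gen$blocks, function(b) b$D[1, 2], numeric(1)))
  expect_gt(r_adj, 0.3)
  expect_lt(abs(cor(G[, 10], G[, 11])), 4.5 / sqrt(800))
})

test_that("independent columns show only sampling-level correlation", {
  gen <- make_genotypes(n = 2000, m = 12, block_size = 1, rho = 0, seed = 3)
  C <- cor(gen$genotypes)
  offdiag <- abs(C[upper.tri(C)])
  expect_lt(max(offdiag), 4.5 / sqrt(2000))
  expect_lt(median(offdiag), 2 / sqrt(2000))
})

test_that("reference-panel LD matches a large-sample oracle of the process", {
  gen <- make_genotypes(n = 50, m = 2, block_size = 2, rho = 0.9,
                        maf_range = c(0.2, 0.2000001), seed = 4, n_ref = 800)
  # oracle: the same thresholded-haplotype process at large n, separate seed
  big <- make_genotypes(n = 2e5, m = 2, block_size = 2, rho = 0.9,
                        maf_range = c(0.2, 0.2000001), seed = 99, n_ref = 2)
  r_oracle <- cor(big$genotypes)[1, 2]
  expect_lt(abs(gen$blocks[[1]]$D[1, 2] - r_oracle), 0.1)
})

test_that("effect draws follow the group-structured point-normal model", {
  st <- sim_settings()[1, ]
  scale <- 0.2
  m_k <- round(st$m_k[[1]] * scale)
  st$m_k <- list(m_k)
  ids <- paste0("v", seq_len(sum(m_k)))
  am <- make_overlap_assignment(ids, m_k, "none")
  eff <- draw_effects(st, am, seed = 5, normalize_shares = FALSE)
  expect_true(all(eff$beta_true[!eff$causal_mask] == 0))
  # zero-heritability groups carry exactly zero effects
  g12 <- unlist(am$assignment) %in% c("g1", "g2")
  expect_true(all(eff$beta_true[g12] == 0))
  # causal count in group 1 within 4 SD of Binomial(m_1, 0.5%)
  n1 <- sum(eff$causal_mask[unlist(am$assignment) == "g1"])
  expect_lt(abs(n1 - m_k[1] * 0.005), 4 * sqrt(m_k[1] * 0.005 * 0.995))
  # causal effect variance in the signal group matches the printed formula
  b4 <- eff$beta_true[unlist(am$assignment) == "g4" & eff$causal_mask]
  v4 <- 0.9 * 0.7 / (0.02 * sum(m_k))
  expect_lt(abs(var(b4) / v4 - 1), 0.5)
})

test_that("share normalization pins realized group contributions", {
  st <- sim_settings()[3, ]   # q = (10, 20, 30, 40)
  scale <- 0.02
  m_k <- round(st$m_k[[1]] * scale)
  st$m_k <- list(m_k)
  ids <- paste0("v", seq_len(sum(m_k)))
  am <- make_overlap_assignment(ids, m_k, "none")
  eff <- draw_effects(st, am, seed = 6)
  grp <- unlist(am$assignment)
  shares <- vapply(paste0("g", 1:4), function(g)
    sum(eff$beta_true[grp == g]^2), numeric(1))
  shares <- shares / sum(shares)
  target <- st$q_k[[1]] * m_k / sum(st$q_k[[1]] * m_k)
  expect_equal(unname(shares), target, tolerance = 1e-10)
})

test_that("phenotypes fix the in-sample heritability exactly", {
  gen <- make_genotypes(n = 400, m = 50, block_size = 10, seed = 7)
  beta <- rnorm(50, 0, 0.1)
  y <- make_phenotype(gen$genotypes, beta, h2 = 0.7, seed = 8)
  g <- drop(gen$genotypes %*% beta)
  expect_equal(cor(g, y)^2, 0.7, tolerance = 1e-10)
  expect_equal(mean(y), 0, tolerance = 1e-12)
  expect_error(make_phenotype(gen$genotypes, beta, h2 = 1), "h2")
  expect_error(make_phenotype(gen$genotypes, rep(0, 50), h2 = 0.5), "causal")
})

test_that("marginal GWAS returns G'y/N on the standardized scale", {
  gen <- make_genotypes(n = 500, m = 10, block_size = 5, seed = 9)
  G <- gen$genotypes
  y <- G[, 1]
  ss <- marginal_gwas(G, y)
  expect_equal(ss$beta_hat[1], 1)               # unit self-correlation
  expect_equal(ss$n_gwas[1], 500L)
  # a duplicated column gets an identical estimate
  G2 <- cbind(G, G[, 1, drop = FALSE])
  colnames(G2)[11] <- "dup"
  ss2 <- marginal_gwas(G2, y)
  expect_equal(ss2$beta_hat[11], ss2$beta_hat[1])
  # independent noise stays within sampling error
  set.seed(10)
  ssn <- marginal_gwas(G, rnorm(500))
  expect_true(all(abs(ssn$beta_hat) < 4.5 / sqrt(500)))
})

test_that("run_setting preserves the scaled architecture and is deterministic", {
  b1 <- run_setting(5, scale = 0.02, seed = 11)
  expect_length(b1$setting$q_k[[1]], 10)
  expect_equal(b1$setting$q_k[[1]], c(rep(0, 8), 10, 90))
  expect_equal(sum(b1$setting$m_k[[1]]), 2500)
  expect_equal(b1$setting$n_sumstat, 1000)
  expect_equal(b1$setting$n_test, 480)
  # relative group sizes within rounding of the published ratios
  expect_equal(b1$setting$m_k[[1]] / 2500,
               sim_settings()$m_k[[5]] / 125000, tolerance = 0.01)
  b2 <- run_setting(5, scale = 0.02, seed = 11)
  expect_identical(b1$ss$beta_hat, b2$ss$beta_hat)
  expect_identical(b1$y_test, b2$y_test)
  expect_error(run_setting(1, scale = 1e-5, seed = 1), "scale")
})

test_that("overlap settings attach multi-label annotations over one architecture", {
  b6 <- run_setting(6, scale = 0.02, seed = 12)
  expect_gt(iou(b6$am, "g1", "g2"), 0.4)
  expect_lt(iou(b6$am, "g3", "g4"), 0.05)
  b7 <- run_setting(7, scale = 0.02, seed = 12)
  expect_gt(iou(b7$am, "g3", "g4"), 0.4)
  # same seed, same underlying architecture: identical true effects
  expect_identical(b6$effects$beta_true, b7$effects$beta_true)
})
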