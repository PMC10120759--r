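# Deterministic grid-integration oracles for the 1-SNP and 2-SNP bilevel
# shrinkage posteriors. beta is integrated out analytically (Gaussian),
# sigma2 analytically (inverse-gamma), and the shrinkage scales on a log
# grid with the half-Cauchy (in the variance) prior
# p(s2) propto s2^{-1/2} / (1 + s2). Independent of the sampler code path.

hc_log_density_var <- function(s2) -0.5 * log(s2) - log1p(s2)

grid_oracle_1snp <- function(beta_hat, n, n_grid = 160, lim = c(1e-7, 1e7)) {
  lg <- seq(log(lim[1]), log(lim[2]), length.out = n_grid)
  d2 <- exp(lg)
  D2 <- matrix(d2, n_grid, n_grid)
  L2 <- matrix(d2, n_grid, n_grid, byrow = TRUE)
  psi <- D2 * L2
  shrink <- 1 / (1 + 1 / psi)
  a_rate <- 0.5 * n * (1 - beta_hat^2 * shrink)
  lw <- -0.5 * log(psi) - 0.5 * log1p(1 / psi) - (n / 2) * log(a_rate) +
    hc_log_density_var(D2) + hc_log_density_var(L2) + log(D2) + log(L2)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  m <- shrink * beta_hat
  e_sigma2 <- a_rate / (n / 2 - 1)
  vb <- e_sigma2 * shrink / n
  eb <- sum(w * m)
  list(mean = eb, sd = sqrt(sum(w * (vb + m^2)) - eb^2))
}

grid_oracle_2snp <- function(beta_hat, r, n, n_grid = 90, lim = c(1e-6, 1e6)) {
  lg <- seq(log(lim[1]), log(lim[2]), length.out = n_grid)
  g <- expand.grid(d2 = exp(lg), l1 = exp(lg), l2 = exp(lg))
  psi1 <- g$d2 * g$l1; psi2 <- g$d2 * g$l2
  a11 <- 1 + 1 / psi1; a22 <- 1 + 1 / psi2
  det <- a11 * a22 - r^2
  quad <- (a22 * beta_hat[1]^2 - 2 * r * prod(beta_hat) + a11 * beta_hat[2]^2) / det
  a_rate <- 0.5 * n * (1 - quad)
  lw <- -0.5 * (log(psi1) + log(psi2)) - 0.5 * log(det) - (n / 2) * log(a_rate) +
    hc_log_density_var(g$d2) + hc_log_density_var(g$l1) + hc_log_density_var(g$l2) +
    log(g$d2) + log(g$l1) + log(g$l2)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  m1 <- (a22 * beta_hat[1] - r * beta_hat[2]) / det
  m2 <- (a11 * beta_hat[2] - r * beta_hat[1]) / det
  e_sigma2 <- a_rate / (n / 2 - 1)
  v1 <- e_sigma2 / n * a22 / det; v2 <- e_sigma2 / n * a11 / det
  list(mean = c(sum(w * m1), sum(w * m2)),
       sd = c(sqrt(sum(w * (v1 + m1^2)) - sum(w * m1)^2),
              sqrt(sum(w * (v2 + m2^2)) - sum(w * m2)^2)))
}
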