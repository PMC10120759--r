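#' Single-group continuous-shrinkage fit (PRS-CS-auto special case)
#'
#' Runs the bilevel Gibbs sampler with all variants in a single group,
#' which is exactly the fully Bayesian single-scale continuous-shrinkage
#' model (PRS-CS-auto with gamma-gamma hyper-parameters a0 = 0.5, b0 = 1).
#' Given the same seed this is bit-identical to [run_gibbs()] under a
#' one-group annotation map.
#'
#' @param ss Aligned summary statistics.
#' @param blocks List of [ld_block()] objects.
#' @param cfg A [gibbs_config()].
#' @param keep_traces Keep delta2 traces.
#' @return A `prs_posterior` (see [run_gibbs()]).
#' @export
prscs_auto <- function(ss, blocks, cfg = gibbs_config(), keep_traces = FALSE) {
  am <- annotation_map(setNames(as.list(rep("all", nrow(ss))), ss$variant_id),
                       groups = "all")
  design <- expand_overlap(am, ss)
  run_gibbs(ss, blocks, design, cfg, keep_traces = keep_traces)
}

#' Per-SNP heritability table for the closed-form comparator
#'
#' @param sigma_j2 Non-negative per-SNP heritabilities (at least one > 0).
#' @param h2_total Total heritability used to set the normalizing constant
#'   `c` so that `sum(c * sigma_j2) = h2_total`; `NULL` leaves `c = 1`.
#' @return List with `sigma_j2` and `c`.
#' @export
per_snp_heritability <- function(sigma_j2, h2_total = NULL) {
  stopifnot(all(sigma_j2 >= 0), any(sigma_j2 > 0))
  c_norm <- if (is.null(h2_total)) 1 else h2_total / sum(sigma_j2)
  list(sigma_j2 = as.numeric(sigma_j2), c = c_norm)
}

#' Closed-form annotation-informed posterior effects (LDpred-funct style)
#'
#' Under the prior `beta_j ~ N(0, c * sigma_j^2)` with per-SNP
#' heritabilities from stratified heritability estimates, the posterior
#' mean solves `W x = N beta_hat` per LD block, with
#' `W = N D + (1/c) diag(1/sigma_j^2)`. Variants with zero heritability are
#' excluded with a warning and get effect 0.
#'
#' @param ss Aligned summary statistics.
#' @param blocks List of [ld_block()] objects.
#' @param h A [per_snp_heritability()] list (ordered as the blocks).
#' @param n GWAS sample size (defaults to `ss$n_gwas`).
#' @return Numeric vector of posterior-mean effects, one per variant.
#' @export
ldpred_funct_posterior <- function(ss, blocks, h, n = NULL) {
  ids <- block_variant_ids(blocks)
  if (!identical(ids, ss$variant_id)) abort("summary statistics not aligned to blocks")
  stopifnot(length(h$sigma_j2) == nrow(ss))
  n <- n %||% unique(ss$n_gwas)[1]
  zero <- h$sigma_j2 <= 0
  if (any(zero)) {
    warn(paste0(sum(zero), " variant(s) with zero heritability excluded (effect set to 0)"))
  }
  out <- numeric(nrow(ss))
  offset <- 0
  for (b in blocks) {
    m <- length(b$variant_ids)
    gl <- offset + seq_len(m)
    keep <- !zero[gl]
    if (any(keep)) {
      gk <- gl[keep]
      W <- n * b$D[keep, keep, drop = FALSE] +
        diag(1 / (h$c * h$sigma_j2[gk]), sum(keep))
      x <- tryCatch(solve(W, n * ss$beta_hat[gk]), error = function(e) {
        abort("singular W in closed-form posterior; consider ridge repair of the LD reference")
      })
      out[gk] <- x
    }
    offset <- offset + m
  }
  out
}

#' Partition effects into bins of similar squared posterior mass
#'
#' Ranks variants by absolute posterior-mean effect (descending) and
#' greedily assigns them to `L` bins so each bin accumulates approximately
#' `sum(effects^2) / L` of squared effect mass: a bin is closed once its
#' cumulative sum of squares reaches the target (or just enough variants
#' remain to populate the remaining bins). Every variant lands in exactly
#' one bin; bin sums of squares stay within a factor 2 of the target except
#' possibly the last bin.
#'
#' @param effects Numeric posterior-mean effects.
#' @param L Number of bins (default 40). Reduced with a warning when it
#'   exceeds the number of nonzero effects.
#' @return Integer bin assignment (1..L), in the order of `effects`.
#' @export
bin_by_posterior <- function(effects, L = 40) {
  m <- length(effects)
  stopifnot(L >= 1, m >= 1)
  n_nonzero <- sum(effects != 0)
  if (L > max(n_nonzero, 1)) {
    warn(paste0("L exceeds the number of nonzero effects; reduced to ", max(n_nonzero, 1)))
    L <- max(n_nonzero, 1)
  }
  ord <- order(abs(effects), decreasing = TRUE)
  target <- sum(effects^2) / L
  bin <- integer(m)
  b <- 1L; acc <- 0
  for (i in seq_len(m)) {
    j <- ord[i]
    bin[j] <- b
    acc <- acc + effects[j]^2
    remaining_items <- m - i
    remaining_bins <- L - b
    if (b < L && (acc >= target || remaining_items <= remaining_bins)) {
      b <- b + 1L
      acc <- 0
    }
  }
  bin
}

#' Full closed-form comparator pipeline
#'
#' Computes the closed-form posterior ([ldpred_funct_posterior()]), bins
#' variants by posterior effect ([bin_by_posterior()]), builds bin-wise
#' scores and estimates bin weights by the same 10-fold cross-validation as
#' the group-wise method.
#'
#' @inheritParams ldpred_funct_posterior
#' @param G Test genotype matrix (columns aligned to `ss`).
#' @param y Test phenotypes.
#' @param L Number of bins.
#' @param trait,n_folds,seed Passed to [fit_alpha_cv()].
#' @return List with `effects`, `bins`, `scores`, `weights`, `final`.
#' @export
ldpred_funct <- function(ss, blocks, h, G, y, L = 40,
                         trait = "quantitative", n_folds = 10, seed = 1) {
  eff <- ldpred_funct_posterior(ss, blocks, h)
  bins <- bin_by_posterior(eff, L)
  am <- annotation_map(setNames(as.list(sprintf("bin%02d", bins)), ss$variant_id))
  design <- expand_overlap(am, ss)
  eff_copies <- eff[design$variant_index]
  scores <- group_scores(G, eff_copies, design)
  w <- fit_alpha_cv(scores, y, trait = trait, n_folds = n_folds, seed = seed)
  list(effects = eff, bins = bins, scores = scores, weights = w,
       final = combine_scores(scores, w))
}
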