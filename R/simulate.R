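#' Simulation-study parameter presets
#'
#' The seven study settings: total M = 125,000 variants in K annotation
#' groups of sizes `M_k`, per-group causal proportions `p_k` (%), per-group
#' heritability shares `q_k` (%), total heritability 0.7, GWAS sample
#' 50,000 and test sample 24,000. Settings 6 and 7 reuse the Setting-1
#' architecture with overlap patterns I and II.
#'
#' @return A tibble with one row per setting; `m_k`, `p_k`, `q_k` are
#'   list-columns.
#' @export
sim_settings <- function() {
  mk4 <- c(49750, 37500, 25125, 12625)
  p4 <- c(0.5, 1, 1.5, 2)
  tibble::tibble(
    setting = 1:7,
    k = c(4, 4, 4, 4, 10, 4, 4),
    m_k = list(mk4, mk4, mk4, mk4,
               c(rep(12375, 6), 12625, 12625, 12750, 12750),
               mk4, mk4),
    p_k = list(p4, p4, p4, p4, c(rep(0, 6), 2, 2, 3, 3), p4, p4),
    q_k = list(c(0, 0, 10, 90), c(0, 0, 50, 50), c(10, 20, 30, 40),
               c(25, 25, 25, 25), c(rep(0, 8), 10, 90),
               c(0, 0, 10, 90), c(0, 0, 10, 90)),
    overlap = c("none", "none", "none", "none", "none",
                "overlap_I", "overlap_II"),
    h2 = 0.7,
    n_sumstat = 50000L,
    n_test = 24000L
  )
}

#' Simulate standardized genotypes with block-wise LD
#'
#' Dosages are generated from two thresholded latent Gaussian haplotypes
#' with within-block AR(1) correlation `rho^|i-j|` and minor-allele
#' frequencies drawn uniformly from `maf_range`, then column-standardized
#' so that each column has mean 0 and `sum(g^2) = n`. The LD blocks `D` are
#' estimated from a held-out reference sample of `n_ref` individuals drawn
#' from the same process, mimicking an external reference panel.
#'
#' @param n Number of individuals.
#' @param m Number of variants.
#' @param block_size Variants per LD block (last block may be short).
#' @param rho AR(1) latent correlation within blocks, in `[0, 1)`.
#' @param maf_range Range for the uniform MAF draw.
#' @param seed Integer seed.
#' @param n_ref Reference-panel size for the LD estimate.
#' @return List with `genotypes` (n x m standardized matrix, columns
#'   `snp00001...`), `dosages` (the raw 0/1/2 matrix), `blocks` (list of
#'   [ld_block()]), `bim` (synthetic variant table), `maf`.
#' @export
make_genotypes <- function(n, m, block_size = 500, rho = 0.7,
                           maf_range = c(0.01, 0.5), seed = 1, n_ref = 500) {
  stopifnot(rho >= 0, rho < 1, n >= 2, m >= 1)
  starts <- seq(1, m, by = block_size)
  ends <- pmin(starts + block_size - 1, m)
  ids <- sprintf("snp%05d", seq_len(m))

  withr_seed(seed, {
    maf <- runif(m, maf_range[1], maf_range[2])
    tau <- qnorm(maf)
    raw <- matrix(0, n + n_ref, m)
    for (b in seq_along(starts)) {
      cols <- starts[b]:ends[b]
      for (h in 1:2) {
        z <- matrix(0, n + n_ref, length(cols))
        z[, 1] <- rnorm(n + n_ref)
        if (length(cols) > 1) {
          sd_inn <- sqrt(1 - rho^2)
          for (j in 2:length(cols)) {
            z[, j] <- rho * z[, j - 1] + sd_inn * rnorm(n + n_ref)
          }
        }
        raw[, cols] <- raw[, cols] + (z < matrix(tau[cols], n + n_ref,
                                                 length(cols), byrow = TRUE))
      }
    }
  })
  colnames(raw) <- ids
  dosages <- raw[seq_len(n), , drop = FALSE]
  storage.mode(dosages) <- "integer"
  G <- standardize_genotypes(raw[seq_len(n), , drop = FALSE])
  ref <- raw[n + seq_len(n_ref), , drop = FALSE]
  blocks <- lapply(seq_along(starts), function(b) {
    cols <- starts[b]:ends[b]
    D <- suppressWarnings(cor(ref[, cols, drop = FALSE]))
    bad <- !is.finite(D)
    if (any(bad)) { D[bad] <- 0; diag(D) <- 1 }
    ld_block(ids[cols], D)
  })
  bim <- tibble::tibble(chrom = "1", variant_id = ids, cm = 0,
                        pos = seq_len(m) * 1000L,
                        a1 = "A", a2 = "G")
  list(genotypes = G, dosages = dosages, blocks = blocks, bim = bim, maf = maf)
}

# mean 0, sum of squares n per column (so D = G'G/n has unit diagonal);
# monomorphic columns are left at zero
standardize_genotypes <- function(G) {
  n <- nrow(G)
  ctr <- scale(G, center = TRUE, scale = FALSE)
  ss <- sqrt(colSums(ctr^2) / n)
  ss[ss == 0] <- Inf
  sweep(ctr, 2, ss, "/")
}

#' Draw group-structured point-normal effect sizes
#'
#' Each variant is causal with its group's probability `p_k` and, if causal,
#' draws `beta_j ~ N(0, (q_k/100) h2 / ((p_k/100) M))` — the point-normal
#' architecture in which group k explains about `q_k`% of the heritability.
#' A variant in several groups takes the parameters of its member group
#' with the largest heritability share. Groups with `q_k = 0` (or
#' `p_k = 0`) contribute exactly zero effects.
#'
#' @param setting One row of [sim_settings()] (or a list with `m_k`, `p_k`,
#'   `q_k`, `h2`).
#' @param am An [annotation_map()] covering the variants, groups ordered as
#'   the setting's `m_k`.
#' @param seed Integer seed.
#' @param variance_mode `"printed"` (default) uses the per-variant variance
#'   above with `M` = total variants; `"group_normalized"` replaces `M`
#'   with `M_k`, making each group's expected heritability contribution
#'   proportional to `q_k` alone. See the methods vignette.
#' @param normalize_shares Rescale each group's causal effects so the
#'   realized squared-effect share equals the share the variance formula
#'   targets in expectation (default `TRUE`). At reduced scales a group may
#'   hold only a handful of causal variants, and without this the realized
#'   architecture can drift far from the designed one; the same exact
#'   enforcement is applied to total heritability in [make_phenotype()].
#' @return List with `beta_true` (length M) and `causal_mask`.
#' @export
draw_effects <- function(setting, am, seed = 1,
                         variance_mode = c("printed", "group_normalized"),
                         normalize_shares = TRUE) {
  variance_mode <- match.arg(variance_mode)
  p_k <- setting$p_k[[1]]; q_k <- setting$q_k[[1]]; h2 <- setting$h2[1]
  m_k <- setting$m_k[[1]]
  ids <- names(am$assignment)
  M <- length(ids)
  grp_idx <- vapply(am$assignment, function(g) {
    gi <- match(g, am$groups)
    gi[which.max(q_k[gi])]
  }, integer(1))
  p <- p_k[grp_idx] / 100
  denom <- if (variance_mode == "printed") M else m_k[grp_idx]
  v <- ifelse(p > 0, (q_k[grp_idx] / 100) * h2 / (p * denom), 0)
  withr_seed(seed, {
    causal <- rbinom(M, 1, p) == 1
    beta <- numeric(M)
    beta[causal] <- rnorm(sum(causal), 0, sqrt(v[causal]))
  })
  if (normalize_shares) {
    # expected squared-effect share of group k under the variance formula
    target <- vapply(seq_along(q_k), function(k) {
      sum(v[grp_idx == k]) * p_k[k] / 100
    }, numeric(1))
    target <- target / sum(target)
    realized <- vapply(seq_along(q_k), function(k) {
      sum(beta[grp_idx == k]^2)
    }, numeric(1))
    tot <- sum(realized)
    for (k in seq_along(q_k)) {
      if (realized[k] > 0 && target[k] > 0) {
        beta[grp_idx == k] <- beta[grp_idx == k] *
          sqrt(target[k] * tot / realized[k])
      }
    }
  }
  list(beta_true = setNames(beta, ids), causal_mask = setNames(causal, ids))
}

#' Simulate phenotypes at fixed heritability
#'
#' `y = G beta + e`, where the noise is drawn, orthogonalized in-sample
#' against the genetic value and rescaled so the realized genetic-variance
#' fraction equals `h2` exactly; `y` is then standardized.
#'
#' @param G Standardized genotype matrix.
#' @param effects Output of [draw_effects()] (or a numeric effect vector).
#' @param h2 Target heritability, in `(0, 1)`.
#' @param seed Integer seed.
#' @return Standardized phenotype vector.
#' @export
make_phenotype <- function(G, effects, h2, seed = 1) {
  stopifnot(h2 > 0, h2 < 1)
  beta <- if (is.list(effects)) effects$beta_true else as.numeric(effects)
  g <- drop(G %*% beta)
  vg <- var(g)
  if (!is.finite(vg) || vg == 0) abort("genetic values are constant; no causal variants?")
  withr_seed(seed, e <- rnorm(length(g)))
  gc_ <- g - mean(g)
  e <- e - mean(e) - sum(e * gc_) / sum(gc_^2) * gc_   # orthogonal to g in-sample
  e <- e * sqrt(vg * (1 - h2) / h2 / var(e))
  y <- g + e
  (y - mean(y)) / sqrt(mean((y - mean(y))^2))
}

#' Marginal GWAS from individual-level data
#'
#' Computes `beta_hat_j = G_j' y / N` on standardized genotypes and
#' phenotype — the marginal least-squares effect per variant.
#'
#' @param G Standardized genotype matrix with variant ids as column names.
#' @param y Standardized phenotype.
#' @param bim Optional variant table supplying chrom/pos/alleles.
#' @return A summary-statistics tibble (see [read_sumstats()]).
#' @export
marginal_gwas <- function(G, y, bim = NULL) {
  n <- nrow(G)
  stopifnot(length(y) == n)
  beta_hat <- drop(crossprod(G, y)) / n
  ids <- colnames(G) %||% sprintf("snp%05d", seq_len(ncol(G)))
  tibble::tibble(
    variant_id = ids,
    chrom = if (!is.null(bim)) bim$chrom else "1",
    pos = if (!is.null(bim)) bim$pos else seq_len(ncol(G)),
    a1 = if (!is.null(bim)) bim$a1 else "A",
    a2 = if (!is.null(bim)) bim$a2 else "G",
    beta_hat = unname(beta_hat),
    n_gwas = n
  )
}

#' Run one simulation setting end to end
#'
#' Scales a [sim_settings()] preset down by `scale` (variant count, group
#' sizes and sample sizes shrink proportionally; causal proportions,
#' heritability shares and h2 are preserved), simulates genotypes with
#' block LD, group-structured effects, phenotypes and marginal GWAS
#' statistics, and returns the full experiment bundle.
#'
#' @param setting_id Setting 1-7.
#' @param scale Scale factor in `(0, 1]` (default 0.02).
#' @param seed Integer seed; the bundle is reproducible from it.
#' @param block_size LD block size; defaults to 100 at desk scales
#'   (`scale < 0.1`) and 500 otherwise.
#' @param rho AR(1) latent LD correlation.
#' @param n_ref LD reference-panel size.
#' @param target_iou Target IOU for the overlap settings.
#' @return List with `ss` (summary statistics), `blocks`, `am`
#'   (annotation map), `effects`, `genotypes_test`, `y_test`, `setting`
#'   (scaled parameters), `seed`.
#' @export
run_setting <- function(setting_id, scale = 0.02, seed = 1, block_size = NULL,
                        rho = 0.7, n_ref = 500, target_iou = 0.5) {
  stopifnot(setting_id %in% 1:7, scale > 0, scale <= 1)
  preset <- sim_settings()[setting_id, ]
  m_k <- round(preset$m_k[[1]] * scale)
  if (any(m_k < 1)) abort("scale too small: an annotation group would be empty")
  # keep the total at round(M_full * scale) despite per-group rounding
  m_k[which.max(m_k)] <- m_k[which.max(m_k)] +
    round(sum(preset$m_k[[1]]) * scale) - sum(m_k)
  M <- sum(m_k)
  n_sumstat <- max(round(preset$n_sumstat * scale), 50)
  n_test <- max(round(preset$n_test * scale), 50)
  if (is.null(block_size)) block_size <- if (scale < 0.1) 100 else 500

  gen <- make_genotypes(n_sumstat + n_test, M, block_size = block_size,
                        rho = rho, seed = seed, n_ref = n_ref)
  ids <- colnames(gen$genotypes)
  # group membership scattered across the genome (and so across LD blocks)
  perm <- withr_seed(seed + 1L, sample.int(M))
  am <- make_overlap_assignment(ids[perm], m_k, pattern = preset$overlap,
                                target_iou = target_iou, seed = seed + 2L)
  setting <- preset
  setting$m_k <- list(m_k)
  setting$n_sumstat <- n_sumstat
  setting$n_test <- n_test
  # the true architecture always follows the underlying partition (settings
  # sharing a Table row share a generative model); an overlap pattern only
  # changes the annotation labels the fitted model sees
  am_true <- if (preset$overlap == "none") am else {
    make_overlap_assignment(ids[perm], m_k, pattern = "none")
  }
  effects <- draw_effects(setting, complete_annotations(am_true, ids),
                          seed = seed + 3L)
  y <- make_phenotype(gen$genotypes, effects, preset$h2, seed = seed + 4L)
  train <- seq_len(n_sumstat)
  ss <- marginal_gwas(gen$genotypes[train, , drop = FALSE], y[train], bim = gen$bim)
  list(
    ss = ss,
    blocks = gen$blocks,
    am = am,
    effects = effects,
    genotypes_test = gen$genotypes[-train, , drop = FALSE],
    dosages_test = gen$dosages[-train, , drop = FALSE],
    y_test = y[-train],
    setting = setting,
    seed = seed
  )
}
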