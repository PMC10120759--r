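#' Fit the bilevel shrinkage model from files or in-memory inputs
#'
#' Convenience pipeline: optionally aligns the summary statistics to the
#' LD panel's alleles, expands the annotation map into (variant, group)
#' copies and runs the Gibbs sampler.
#'
#' @param ss Summary-statistics tibble ([read_sumstats()]).
#' @param blocks List of [ld_block()] objects.
#' @param am An [annotation_map()]; `NULL` fits the single-group model.
#' @param cfg A [gibbs_config()].
#' @param panel Optional panel allele table ([panel_alleles()]); when given,
#'   [align_alleles()] is applied first.
#' @param remove_ambiguous Drop strand-ambiguous variants during alignment.
#' @return A `prs_posterior`.
#' @export
fit_prs <- function(ss, blocks, am = NULL, cfg = gibbs_config(),
                    panel = NULL, remove_ambiguous = FALSE) {
  if (!is.null(panel)) {
    ss <- align_alleles(ss, panel, remove_ambiguous = remove_ambiguous)
  }
  if (is.null(am)) return(prscs_auto(ss, blocks, cfg))
  design <- expand_overlap(am, ss)
  run_gibbs(ss, blocks, design, cfg)
}

#' Write a fitted posterior to disk
#'
#' Writes the per-copy effect table (`effects_copies.tsv`: one row per
#' (variant, group) copy), the aggregated per-variant table
#' (`effects_variant.tsv`) and a JSON manifest recording the seed and chain
#' configuration, sufficient to reproduce the run.
#'
#' @param post A `prs_posterior`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit <- function(post, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  copies <- tidy(post, per = "copy")
  copies <- dplyr::left_join(copies, post$ss, by = "variant_id")
  write_posterior_effects(
    copies[, c("variant_id", "chrom", "pos", "a1", "beta_tilde", "group")],
    file.path(dir, "effects_copies.tsv"))
  write_posterior_effects(tidy(post, per = "variant"),
                          file.path(dir, "effects_variant.tsv"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- c(post$cfg,
                  list(m_variants = nrow(post$beta_tilde_variant),
                       m_copies = length(post$beta_tilde_copies),
                       groups = names(post$delta2_mean),
                       package_version = as.character(utils::packageVersion("bilevelprs"))))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

#' Compare PRS methods on simulated data
#'
#' For each replicate: simulates one scaled study setting
#' ([run_setting()]), fits the bilevel group-wise model, the single-group
#' special case, optionally the hybrid combination and the closed-form
#' annotation-informed comparator (non-overlapping settings only), then
#' evaluates every method by 10-fold cross-validation on the test sample.
#' Reported AUC uses top-decile case labels of the simulated liability;
#' reported R-squared is against the quantitative phenotype, both averaged
#' over held-out folds.
#'
#' @param setting_id Simulation setting 1-7.
#' @param scale Down-scaling factor passed to [run_setting()].
#' @param n_replicates Number of seeded replicates.
#' @param seed Base seed; replicate r uses `seed + 1000 * (r - 1)` offsets.
#' @param methods Subset of `c("bils", "prscs", "hybrid", "ldpredfunct")`.
#' @param cfg Base [gibbs_config()]; its seed is re-derived per replicate.
#' @param n_folds Cross-validation folds.
#' @param target_iou Overlap target for settings 6-7.
#' @return A tibble of class `prs_compare` with columns `setting`,
#'   `replicate`, `method`, `auc`, `r2`; attribute `"delta2"` holds the
#'   per-replicate posterior group scales next to the true heritability
#'   shares.
#' @export
compare_methods <- function(setting_id, scale = 0.02, n_replicates = 1,
                            seed = 1,
                            methods = c("bils", "prscs", "hybrid"),
                            cfg = gibbs_config(), n_folds = 10,
                            target_iou = 0.5) {
  methods <- match.arg(methods, c("bils", "prscs", "hybrid", "ldpredfunct"),
                       several.ok = TRUE)
  rows <- list(); d2 <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- as.integer(seed + 1000 * (r - 1))
    bundle <- run_setting(setting_id, scale = scale, seed = rep_seed,
                          target_iou = target_iou)
    cfg_r <- gibbs_config(n_iter = cfg$n_iter, n_burnin = cfg$n_burnin,
                          thin = cfg$thin, seed = rep_seed + 7L,
                          shrink_cap = cfg$shrink_cap, mode = cfg$mode)
    G <- bundle$genotypes_test; y <- bundle$y_test
    need_prscs <- any(c("prscs", "hybrid") %in% methods)

    fit_b <- NULL
    if (any(c("bils", "hybrid") %in% methods)) {
      design <- expand_overlap(bundle$am, bundle$ss)
      fit_b <- run_gibbs(bundle$ss, bundle$blocks, design, cfg_r)
      d2[[length(d2) + 1]] <- tibble::tibble(
        setting = setting_id, replicate = r,
        group = names(fit_b$delta2_mean),
        q = c(bundle$setting$q_k[[1]],
              rep(NA_real_, length(fit_b$delta2_mean) -
                    length(bundle$setting$q_k[[1]]))),
        delta2_mean = unname(fit_b$delta2_mean))
    }
    fit_c <- if (need_prscs) prscs_auto(bundle$ss, bundle$blocks, cfg_r) else NULL

    add_row <- function(method, w) {
      m <- w$fold_metrics
      rows[[length(rows) + 1]] <<- tibble::tibble(
        setting = setting_id, replicate = r, method = method,
        auc = mean(m$auc), r2 = mean(m$r2))
    }
    if ("bils" %in% methods) {
      sc_b <- group_scores(G, fit_b)
      add_row("bils", fit_alpha_cv(sc_b, y, "quantitative", n_folds, seed = rep_seed))
    }
    if ("prscs" %in% methods) {
      sc_c <- group_scores(G, fit_c)
      add_row("prscs", fit_alpha_cv(sc_c, y, "quantitative", n_folds, seed = rep_seed))
    }
    if ("hybrid" %in% methods) {
      sc_b <- group_scores(G, fit_b)
      ext <- drop(score_matrix(group_scores(G, fit_c)))
      add_row("hybrid", fit_alpha_cv(sc_b, y, "quantitative", n_folds,
                                     seed = rep_seed, external = ext))
    }
    if ("ldpredfunct" %in% methods) {
      if (bundle$setting$overlap != "none") {
        warn("closed-form comparator skipped for an overlapping setting")
      } else {
        h <- true_per_snp_h2(bundle)
        lf <- ldpred_funct(bundle$ss, bundle$blocks, h, G, y,
                           trait = "quantitative", n_folds = n_folds,
                           seed = rep_seed)
        add_row("ldpredfunct", lf$weights)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "delta2") <- dplyr::bind_rows(d2)
  class(out) <- c("prs_compare", class(out))
  out
}

# expected per-SNP heritability under the setting's group shares
true_per_snp_h2 <- function(bundle) {
  st <- bundle$setting
  q_k <- st$q_k[[1]]; m_k <- st$m_k[[1]]; h2 <- st$h2[1]
  am <- complete_annotations(bundle$am, bundle$ss$variant_id)
  gi <- vapply(am$assignment, function(g) match(g[1], am$groups), integer(1))
  sig <- (q_k[gi] / 100) * h2 / m_k[gi]
  per_snp_heritability(sig, h2_total = h2)
}

#' Summarize a method comparison
#'
#' @param object A `prs_compare` tibble.
#' @param ... Unused.
#' @return Per-method means with normal-theory 95% intervals across
#'   replicates.
#' @export
summary.prs_compare <- function(object, ...) {
  object |>
    dplyr::group_by(.data$setting, .data$method) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_auc = mean(.data$auc),
      auc_lo = mean(.data$auc) - 1.96 * sd(.data$auc) / sqrt(dplyr::n()),
      auc_hi = mean(.data$auc) + 1.96 * sd(.data$auc) / sqrt(dplyr::n()),
      mean_r2 = mean(.data$r2),
      .groups = "drop")
}
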