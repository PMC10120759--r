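#' Group-wise polygenic scores
#'
#' `PRS_k = sum over copies in group k of G_j * beta_tilde_copy` — each
#' annotation group contributes the part of the posterior effect that lives
#' on its copies, so summing the group columns reproduces the conventional
#' total PRS `G %*% beta_tilde_variant`.
#'
#' @param G n x M standardized genotype matrix, columns aligned to (and
#'   named as) the design's variants.
#' @param post A `prs_posterior` from [run_gibbs()] (or a numeric vector of
#'   per-copy effects).
#' @param design The [expand_overlap()] design (taken from `post` when
#'   omitted).
#' @return A tibble with `sample_id` and one column per group, carrying the
#'   group labels in map order as attribute `"groups"`.
#' @export
group_scores <- function(G, post, design = NULL) {
  if (inherits(post, "prs_posterior")) {
    if (is.null(design)) design <- post$design
    beta_copies <- post$beta_tilde_copies
  } else {
    beta_copies <- as.numeric(post)
  }
  if (is.null(design)) abort("a design is required")
  if (length(beta_copies) != nrow(design)) abort("effects do not match the design")
  if (!is.null(colnames(G))) {
    want <- unique(design$variant_id)
    if (!identical(colnames(G), want)) {
      if (!all(want %in% colnames(G))) {
        abort("genotype columns do not cover the design variants")
      }
      G <- G[, want, drop = FALSE]
    }
  } else if (ncol(G) != attr(design, "m_variants")) {
    abort("genotype columns do not match the design variants")
  }
  groups <- design_groups(design)
  out <- matrix(0, nrow(G), length(groups),
                dimnames = list(NULL, groups))
  for (k in seq_along(groups)) {
    rows <- design$group_index == k
    if (!any(rows)) next
    out[, k] <- G[, design$variant_index[rows], drop = FALSE] %*%
      beta_copies[rows]
  }
  ids <- rownames(G) %||% paste0("I", seq_len(nrow(G)))
  res <- tibble::as_tibble(out)
  res <- dplyr::bind_cols(tibble::tibble(sample_id = ids), res)
  attr(res, "groups") <- groups
  res
}

score_matrix <- function(scores) {
  groups <- attr(scores, "groups") %||% setdiff(names(scores), "sample_id")
  as.matrix(scores[, groups, drop = FALSE])
}

#' Estimate group-combination weights by cross-validation
#'
#' Regresses the phenotype on the K group-wise score columns (plus an
#' optional external conventional PRS column for the hybrid score) within
#' each of `n_folds` cross-validation folds: weights are fit on 9/10 of the
#' individuals by least squares (quantitative trait) or logistic maximum
#' likelihood (binary trait) and evaluated on the held-out 1/10. The
#' exported weights are the across-fold means. Folds are assigned by a
#' seeded permutation, stratified by case status (binary) or by the
#' top-decile label (quantitative) so every fold holds both classes.
#'
#' @param scores Group-score tibble from [group_scores()].
#' @param y Phenotype vector, one value per row of `scores`.
#' @param trait `"quantitative"` or `"binary"`.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed for the fold permutation.
#' @param external Optional external PRS vector; fits its weight `gamma`
#'   jointly with the group weights (hybrid score).
#' @param nonneg Constrain group weights to be non-negative (fits via
#'   glmnet at zero penalty).
#' @return An object of class `alpha_weights`: `alpha` (named, across-fold
#'   mean), `gamma` (or `NA`), `fold_metrics` tibble (per fold: `auc`, and
#'   `r2` or `efron_r2`), `trait`, and `dropped` (constant columns).
#' @export
fit_alpha_cv <- function(scores, y, trait = c("quantitative", "binary"),
                         n_folds = 10, seed = 1, external = NULL,
                         nonneg = FALSE) {
  trait <- match.arg(trait)
  X <- score_matrix(scores)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < n_folds * max(ncol(X), 1)) {
    abort("too few individuals for the requested number of folds")
  }
  if (!is.null(external)) {
    stopifnot(length(external) == length(y))
    X <- cbind(X, .external = external)
  }
  keep <- apply(X, 2, sd) > 0
  if (!all(keep)) {
    warn(paste0("dropping constant score column(s): ",
                paste(colnames(X)[!keep], collapse = ", ")))
  }
  Xf <- X[, keep, drop = FALSE]

  label <- if (trait == "binary") as.integer(y) else binarize_top_decile(y)
  folds <- make_folds(label, n_folds, seed)

  coefs <- matrix(NA_real_, n_folds, ncol(Xf), dimnames = list(NULL, colnames(Xf)))
  fm <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f; te <- !tr
    fit_coef <- fit_weights(Xf[tr, , drop = FALSE], y[tr], trait, nonneg)
    coefs[f, ] <- fit_coef[-1]
    eta <- drop(cbind(1, Xf[te, , drop = FALSE]) %*% fit_coef)
    if (trait == "binary") {
      prob <- stats::plogis(eta)
      fm[[f]] <- tibble::tibble(fold = f, auc = auc(prob, label[te]),
                                efron_r2 = efron_r2(prob, label[te]))
    } else {
      fm[[f]] <- tibble::tibble(fold = f, auc = auc(eta, label[te]),
                                r2 = r2(eta, y[te]))
    }
  }
  alpha_full <- setNames(numeric(ncol(X)), colnames(X))
  alpha_full[colnames(Xf)] <- colMeans(coefs)
  gamma <- if (!is.null(external)) unname(alpha_full[".external"]) else NA_real_
  alpha <- alpha_full[setdiff(names(alpha_full), ".external")]
  structure(list(alpha = alpha, gamma = gamma,
                 fold_metrics = dplyr::bind_rows(fm), trait = trait,
                 dropped = colnames(X)[!keep], n_folds = n_folds),
            class = "alpha_weights")
}

make_folds <- function(label, n_folds, seed) {
  folds <- integer(length(label))
  withr_seed(seed, {
    for (cl in unique(label)) {
      idx <- sample(which(label == cl))
      folds[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  folds
}

fit_weights <- function(X, y, trait, nonneg) {
  if (nonneg) {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      abort("nonneg = TRUE requires the glmnet package")
    }
    fam <- if (trait == "binary") "binomial" else "gaussian"
    fit <- glmnet::glmnet(X, y, family = fam, lambda = 0, lower.limits = 0,
                          standardize = FALSE)
    return(as.numeric(coef(fit, s = 0)))
  }
  df <- data.frame(y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", colnames(X)), collapse = "+")))
  fit <- if (trait == "binary") {
    glm(fml, data = df, family = binomial())
  } else {
    lm(fml, data = df)
  }
  cf <- coef(fit)
  cf[is.na(cf)] <- 0
  cf
}

#' @export
print.alpha_weights <- function(x, ...) {
  cat("<alpha_weights> trait = ", x$trait, ", folds = ", x$n_folds, "\n", sep = "")
  print(round(x$alpha, 4))
  if (is.finite(x$gamma)) cat("gamma =", round(x$gamma, 4), "\n")
  invisible(x)
}

#' @export
tidy.alpha_weights <- function(x, ...) {
  out <- tibble::tibble(group = names(x$alpha), alpha = unname(x$alpha))
  if (is.finite(x$gamma)) {
    out <- dplyr::bind_rows(out, tibble::tibble(group = ".external", alpha = x$gamma))
  }
  out
}

#' @export
glance.alpha_weights <- function(x, ...) {
  m <- x$fold_metrics
  tibble::tibble(
    mean_auc = mean(m$auc),
    mean_r2 = if ("r2" %in% names(m)) mean(m$r2) else mean(m$efron_r2),
    n_folds = x$n_folds,
    trait = x$trait
  )
}

#' Combine group scores into a final PRS
#'
#' `PRS = sum_k alpha_k PRS_k` (mode `"bils"`), or the hybrid
#' `PRS = sum_k alpha_k PRS_k + gamma * external` which adds a conventional
#' single-group PRS weighted by `gamma` (fitted jointly with the alphas in
#' [fit_alpha_cv()]).
#'
#' @param scores Group-score tibble from [group_scores()].
#' @param w An `alpha_weights` object.
#' @param external External PRS vector (required for `mode = "hybrid"`).
#' @param mode `"bils"` or `"hybrid"`.
#' @return Numeric vector of final scores, one per individual.
#' @export
combine_scores <- function(scores, w, external = NULL,
                           mode = c("bils", "hybrid")) {
  mode <- match.arg(mode)
  X <- score_matrix(scores)
  alpha <- w$alpha[colnames(X)]
  alpha[is.na(alpha)] <- 0
  out <- drop(X %*% alpha)
  if (mode == "hybrid") {
    if (is.null(external)) abort("hybrid mode requires an external score vector")
    if (!is.finite(w$gamma)) abort("weights were fitted without an external column")
    out <- out + w$gamma * external
  }
  out
}
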