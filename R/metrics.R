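#' Binarize a quantitative phenotype at the top decile
#'
#' Labels the `ceiling(n/10)` individuals with the largest phenotype values
#' as cases (the "at-risk" population); ties are broken by original index
#' (stable order).
#'
#' @param y Numeric phenotype vector (length >= 10).
#' @return Integer 0/1 label vector.
#' @export
binarize_top_decile <- function(y) {
  n <- length(y)
  stopifnot(n >= 10)
  k <- ceiling(n / 10)
  ord <- order(y, decreasing = TRUE)  # radix sort: stable, earlier index wins ties
  lab <- integer(n)
  lab[ord[seq_len(k)]] <- 1L
  lab
}

#' Binarize a quantitative phenotype at a fixed threshold
#'
#' Alternative labeller for real-trait use (e.g. BMI >= 25 kg/m^2,
#' LDL >= 4.1 mmol/L).
#'
#' @param y Numeric phenotype vector.
#' @param threshold Case threshold; `y >= threshold` are cases.
#' @return Integer 0/1 label vector.
#' @export
binarize_threshold <- function(y, threshold) {
  as.integer(y >= threshold)
}

#' Area under the ROC curve
#'
#' Mann-Whitney U statistic scaled by `n1 * n0`; tied scores contribute 1/2.
#'
#' @param score Numeric risk scores.
#' @param label 0/1 labels; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(score, label) {
  stopifnot(length(score) == length(label))
  label <- as.integer(label)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) abort("both classes must be present to compute AUC")
  r <- rank(score)  # midranks handle ties
  (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Squared Pearson correlation of predictions and outcomes
#'
#' @param pred Predicted values.
#' @param y Observed outcomes (non-constant).
#' @return R-squared; 0 with a warning when `pred` is constant.
#' @export
r2 <- function(pred, y) {
  stopifnot(length(pred) == length(y), length(y) >= 2)
  if (sd(y) == 0) abort("y is constant; R-squared undefined")
  if (sd(pred) == 0) {
    warn("constant predictions; returning R-squared = 0")
    return(0)
  }
  cor(pred, y)^2
}

#' Efron's pseudo R-squared
#'
#' `1 - sum((y - p)^2) / sum((y - mean(y))^2)` for a binary outcome and
#' predicted probabilities.
#'
#' @param prob Predicted probabilities in `[0, 1]`.
#' @param y 0/1 outcomes; both classes must be present.
#' @return Efron's pseudo R-squared (<= 1).
#' @export
efron_r2 <- function(prob, y) {
  stopifnot(length(prob) == length(y), all(prob >= 0 & prob <= 1))
  y <- as.numeric(y)
  if (length(unique(y)) < 2) abort("y must contain both classes")
  1 - sum((y - prob)^2) / sum((y - mean(y))^2)
}
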