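#' Plot a method comparison
#'
#' Box plots of cross-validated AUC (or R-squared) by method across
#' replicates, one panel per setting.
#'
#' @param object A `prs_compare` tibble from [compare_methods()].
#' @param metric `"auc"` or `"r2"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prs_compare <- function(object, metric = c("auc", "r2"), ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$method, y = .data[[metric]],
                                       fill = .data$method)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.8) +
    ggplot2::facet_wrap(~setting, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_bw()
}

#' Plot a fitted posterior
#'
#' Either the posterior group shrinkage scales (`type = "delta2"`, on a log
#' scale — small values mean the group is shrunk hard) or the per-variant
#' posterior effects against the marginal estimates (`type = "effects"`).
#'
#' @param object A `prs_posterior`.
#' @param type `"delta2"` or `"effects"`.
#' @param beta_hat Marginal effects for `type = "effects"` (defaults to
#'   none; the effects panel then shows the posterior alone).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prs_posterior <- function(object, type = c("delta2", "effects"),
                                   beta_hat = NULL, ...) {
  type <- match.arg(type)
  if (type == "delta2") {
    df <- tibble::tibble(group = names(object$delta2_mean),
                         delta2 = unname(object$delta2_mean))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$delta2)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "annotation group",
                    y = expression(paste("posterior mean ", delta^2))) +
      ggplot2::theme_bw()
  } else {
    df <- tidy(object, per = "copy")
    if (!is.null(beta_hat)) {
      df$beta_hat <- beta_hat[match(df$variant_id, names(beta_hat))]
      ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_hat, y = .data$beta_tilde,
                                       colour = .data$group)) +
        ggplot2::geom_point(size = 0.6, alpha = 0.6) +
        ggplot2::geom_abline(linetype = 2) +
        ggplot2::labs(x = "marginal estimate", y = "posterior effect") +
        ggplot2::theme_bw()
    } else {
      ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_tilde, fill = .data$group)) +
        ggplot2::geom_histogram(bins = 60, position = "identity", alpha = 0.5) +
        ggplot2::labs(x = "posterior effect", y = "copies") +
        ggplot2::theme_bw()
    }
  }
}
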