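#' Tidy a nested-CV classification result
#'
#' @param x a [nested_cv_classify()] result.
#' @param ... unused.
#' @return A tibble with one row per repetition: `repetition`, `auc`,
#'   `auc_unweighted`, plus scenario/model metadata columns.
#' @export
tidy.bpd_cv_result <- function(x, ...) {
  dplyr::mutate(x$per_repetition, scenario = x$scenario, model = x$model,
                reduction = x$reduction, selector = x$selector)
}

#' One-row summary of a nested-CV classification result
#'
#' @inheritParams tidy.bpd_cv_result
#' @return A one-row tibble: mean/SD of the per-repetition AUC (SD across
#'   repetitions), scenario and configuration.
#' @export
glance.bpd_cv_result <- function(x, ...) {
  tibble::tibble(
    scenario = x$scenario, selector = x$selector, model = x$model,
    reduction = x$reduction,
    mean_auc = mean(x$per_repetition$auc),
    sd_auc = stats::sd(x$per_repetition$auc),
    mean_auc_unweighted = mean(x$per_repetition$auc_unweighted),
    repetitions = nrow(x$per_repetition), n = x$n, p = x$p
  )
}

#' Tidy a feature set
#'
#' @param x an [extract_features()] result.
#' @param ... unused.
#' @return The feature tibble (name, side, category, units, value).
#' @export
tidy.lung_feature_set <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "lung_feature_set")
  out
}

#' Per-repetition AUC distribution plot
#'
#' @param object a [nested_cv_classify()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.bpd_cv_result <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$scenario, y = .data$auc)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(
      y = "AUC (pooled outer-fold predictions, per repetition)",
      x = NULL,
      title = sprintf("%s | %s | reduction: %s", object$selector,
                      object$model, object$reduction)
    ) +
    ggplot2::theme_minimal()
}

#' Feature overview plot
#'
#' Left/right paired bars of a feature set, facetted by category; useful
#' as a per-subject fingerprint.
#'
#' @param object an [extract_features()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.lung_feature_set <- function(object, ...) {
  dat <- tidy(object)
  dat <- dplyr::group_by(dat, .data$base)
  dat <- dplyr::mutate(dat, rel = .data$value / max(abs(.data$value), 1e-12))
  dat <- dplyr::ungroup(dat)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$base, y = .data$rel,
                                    fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~category, scales = "free_x") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "value (scaled per feature)",
                  title = attr(object, "subject_id") %||% "") +
    ggplot2::theme_minimal()
}

#' Concordance heatmap
#'
#' Tile plot of the volumetric Dice values in a concordance report.
#'
#' @param object an [evaluate_concordance()] report.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.concordance_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$a, y = .data$b,
                                       fill = .data$vdc)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$vdc)),
                       colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "VDC") +
    ggplot2::theme_minimal()
}
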