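#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted signature
#'
#' @param x an `he_signature`.
#' @param ... unused.
#' @return tibble with `term` and `estimate` (standardized log-odds weights),
#'   intercept included.
#' @export
tidy.he_signature <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$variables),
                 estimate = c(x$intercept, unname(x$weights)))
}

#' @rdname tidy.he_signature
#' @return `glance()`: one-row tibble with `n_variables`, `lambda`,
#'   `cv_auc`, `cv_auc_se`.
#' @export
glance.he_signature <- function(x, ...) {
  tibble::tibble(signature = x$name %||% NA_character_,
                 n_variables = length(x$variables), lambda = x$lambda,
                 cv_auc = x$cv_auc_mean, cv_auc_se = x$cv_auc_se)
}

#' Tidy an evaluation report
#'
#' @param x an `he_report`.
#' @param ... unused.
#' @return the long `performance` tibble (one row per signature x cohort).
#' @export
tidy.he_report <- function(x, ...) x$performance

#' @rdname tidy.he_report
#' @export
glance.he_report <- function(x, ...) {
  best <- x$performance[x$performance$cohort == "validation", ]
  best <- best[which.max(best$auc), ]
  tibble::tibble(n_signatures = length(unique(x$performance$signature)),
                 best_signature = best$signature,
                 best_validation_auc = best$auc)
}

#' Forest plot of signature AUCs with DeLong CIs
#'
#' @param object an `he_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.he_report <- function(object, ...) {
  perf <- object$performance
  perf$signature <- factor(perf$signature,
                           levels = rev(unique(perf$signature)))
  ggplot2::ggplot(perf, ggplot2::aes(x = .data$auc, y = .data$signature,
                                     colour = .data$cohort)) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$auc_lo,
                                          xmax = .data$auc_hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "AUC (DeLong 95% CI)", y = NULL, colour = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a fitted signature
#'
#' @param object an `he_signature`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.he_signature <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  td$term <- factor(td$term, levels = td$term[order(abs(td$estimate))])
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "standardized log-odds weight", y = NULL) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
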