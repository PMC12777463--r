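#' Marker-restricted correlation between two genes
#'
#' Correlates two genes' expression across cells, restricted to cells with
#' detectable marker expression (strictly greater than zero), with an
#' optional secondary restriction that also drops cells where the target is
#' zero. Values are used as supplied — the analysis expects log-normalized
#' expression and performs no normalization of its own.
#'
#' Pearson's r uses the product-moment formula; the two-sided p comes from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Spearman's r is the Pearson correlation of average ranks, with p from the
#' same t approximation on the rank correlation.
#'
#' @param data Data frame with one row per cell.
#' @param marker,target Column names (strings) of the marker and target
#'   gene's expression.
#' @param method `"pearson"`, `"spearman"`, or `"both"`. The text and
#'   figure conventions of published analyses differ on which coefficient is
#'   headline; `"both"` reports the two side by side.
#' @param exclude_zero_target Also drop cells with target value 0 (the
#'   secondary, stricter co-expression analysis).
#' @param marker_threshold Strict detection threshold for the marker
#'   (default 0).
#' @return A `coexpr_cor` object; `tidy()` gives one row per method with
#'   `r`, `p_value`, `n_used` and a description of the cell restriction.
#' @export
#' @examples
#' cells <- generate_coexpression(coexpr_config(n_cells = 200, seed = 3))
#' cells$log_marker <- log1p(cells$marker)
#' cells$log_target <- log1p(cells$target)
#' fit <- correlate(cells, "log_marker", "log_target", method = "both")
#' tidy(fit)
correlate <- function(data, marker, target, method = c("pearson",
                                                       "spearman", "both"),
                      exclude_zero_target = FALSE, marker_threshold = 0) {
  method <- match.arg(method)
  for (col in c(marker, target)) {
    if (!col %in% names(data)) {
      stop_validation(sprintf("column '%s' not found", col),
                      "rareniche_parameter_error")
    }
  }
  mv <- data[[marker]]
  tv <- data[[target]]
  keep <- mv > marker_threshold
  restriction <- sprintf("%s > %g", marker, marker_threshold)
  if (exclude_zero_target) {
    keep <- keep & tv > 0
    restriction <- paste0(restriction, sprintf(" & %s > 0", target))
  }
  mv <- mv[keep]
  tv <- tv[keep]
  n <- length(mv)
  if (n < 3) {
    stop_validation(
      sprintf("only %d cell(s) left after restriction (%s); need >= 3",
              n, restriction),
      "rareniche_insufficient_data_error"
    )
  }

  methods_run <- if (method == "both") c("pearson", "spearman") else method
  rows <- purrr::map_dfr(methods_run, function(m) {
    r <- cor(mv, tv, method = m)
    tibble(method = m, r = r, p_value = cor_t_pvalue(r, n), n_used = n)
  })
  rows$restriction <- restriction
  structure(
    list(estimates = rows, marker = marker, target = target,
         data = tibble(marker = mv, target = tv)),
    class = "coexpr_cor"
  )
}

# Two-sided p for a correlation coefficient via the t transform on n - 2 df.
cor_t_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t_stat), df = n - 2)
}

#' @export
print.coexpr_cor <- function(x, ...) {
  cat(sprintf("<coexpr_cor> %s vs %s (%s)\n", x$marker, x$target,
              x$estimates$restriction[1]))
  print(x$estimates)
  invisible(x)
}

#' @method tidy coexpr_cor
#' @export
tidy.coexpr_cor <- function(x, ...) {
  x$estimates
}

#' @method glance coexpr_cor
#' @export
glance.coexpr_cor <- function(x, ...) {
  first <- x$estimates[1, ]
  tibble(method = first$method, r = first$r, p_value = first$p_value,
         n_used = first$n_used, restriction = first$restriction)
}

#' Scatter plot of a co-expression correlation
#'
#' @param object A `coexpr_cor`.
#' @param ... Unused.
#' @return A ggplot of target vs marker over the restricted cells with a
#'   least-squares line and the correlation annotation.
#' @method autoplot coexpr_cor
#' @export
autoplot.coexpr_cor <- function(object, ...) {
  est <- object$estimates[1, ]
  lab <- sprintf("%s r = %.2f, p = %.2g (n = %d)", est$method, est$r,
                 est$p_value, est$n_used)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$marker, y = .data$target)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "firebrick") +
    ggplot2::labs(x = object$marker, y = object$target, subtitle = lab) +
    ggplot2::theme_minimal()
}
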