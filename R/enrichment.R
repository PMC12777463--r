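#' Per-cell compositions for a whole slide
#'
#' Computes every cell's k-neighbour type-count in one compiled pass; the
#' permutation null resamples cells from the full slide, so precomputing all
#' compositions once makes each of the B resamples a cheap row-mean.
#'
#' @param slide A slide tibble.
#' @param k Neighbour count.
#' @return Wide composition tibble (one row per cell).
#' @export
slide_compositions <- function(slide, k) {
  n <- nrow(slide)
  check_number(k, "k", min = 1, integer = TRUE)
  if (k >= n) {
    stop_validation(
      sprintf("k = %d must be smaller than the number of cells (%d)", k, n),
      "rareniche_parameter_error"
    )
  }
  universe <- type_universe(slide)
  code <- match(as.character(slide$cell_type), universe)
  counts <- knn_type_counts_cpp(slide$x, slide$y, code, length(universe),
                                as.integer(k))
  frac <- counts / k
  colnames(frac) <- universe
  out <- dplyr::bind_cols(tibble(cell_id = slide$cell_id), as_tibble(frac))
  attr(out, "type_universe") <- universe
  out
}

#' Permutation null distribution of mean neighbourhood compositions
#'
#' Each of `B` iterations draws `m` distinct cells uniformly from the full
#' slide (positives included — the null asks whether the observed positives
#' look like any random subset of the same size), computes each sampled
#' cell's k-neighbour composition, and stores the mean composition.
#'
#' @param slide A slide tibble.
#' @param m Resample size (the number of positive cells).
#' @param B Number of resamples.
#' @param k Neighbour count.
#' @param seed Integer seed.
#' @param compositions Optional precomputed [slide_compositions()] table.
#' @param replace Sample cells with replacement within a resample; off by
#'   default (a cell appearing twice in one draw has no biological reading).
#' @return A `null_composition`: list with `means` (`B x T` matrix), `m`,
#'   `k`, `B`, `seed`.
#' @export
sample_null <- function(slide, m, B = 1000, k = 20, seed = 1L,
                        compositions = NULL, replace = FALSE) {
  n <- nrow(slide)
  check_number(m, "m", min = 1, integer = TRUE)
  check_number(B, "B", min = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  if (m > n) {
    stop_validation(
      sprintf("m = %d exceeds the number of cells (%d)", m, n),
      "rareniche_parameter_error"
    )
  }
  if (is.null(compositions)) compositions <- slide_compositions(slide, k)
  vals <- comp_values(compositions)

  means <- local_seed(seed, {
    out <- matrix(0, B, ncol(vals))
    for (b in seq_len(B)) {
      s <- sample.int(n, m, replace = replace)
      out[b, ] <- colMeans(vals[s, , drop = FALSE])
    }
    out
  })
  colnames(means) <- colnames(vals)
  structure(
    list(means = means, m = as.integer(m), k = as.integer(k),
         B = as.integer(B), seed = as.integer(seed)),
    class = "null_composition"
  )
}

#' @export
print.null_composition <- function(x, ...) {
  cat(sprintf("<null_composition> B = %d resamples of m = %d cells, k = %d\n",
              x$B, x$m, x$k))
  invisible(x)
}

#' @method tidy null_composition
#' @export
tidy.null_composition <- function(x, ...) {
  as_tibble(x$means) |>
    dplyr::mutate(resample = dplyr::row_number(), .before = 1) |>
    tidyr::pivot_longer(-"resample", names_to = "cell_type",
                        values_to = "mean_fraction")
}

#' Empirical p-values against a permutation null
#'
#' For each type, the proportion of null mean compositions greater than or
#' equal to the observed mean (ties count as extreme, so p is never 0...1
#' exclusive by construction and p = 1 on a constant null). With
#' `add_one = TRUE` the positively biased estimator `(count + 1) / (B + 1)`
#' is used, which cannot return 0.
#'
#' @param observed_mean Named numeric vector of observed mean fractions, or
#'   the tibble returned by [mean_composition()].
#' @param null A `null_composition`.
#' @param add_one Use the `(count + 1) / (B + 1)` estimator.
#' @return Named numeric vector of p-values, one per type.
#' @export
empirical_p <- function(observed_mean, null, add_one = FALSE) {
  stopifnot(inherits(null, "null_composition"))
  if (is.data.frame(observed_mean)) {
    obs <- stats::setNames(observed_mean$mean, observed_mean$cell_type)
  } else {
    obs <- observed_mean
  }
  types <- colnames(null$means)
  if (is.null(names(obs)) || !setequal(names(obs), types)) {
    stop_validation("observed and null type universes differ",
                    "rareniche_validation_error")
  }
  obs <- obs[types]
  count <- colSums(null$means >= rep(obs, each = nrow(null$means)))
  p <- if (add_one) (count + 1) / (null$B + 1) else count / null$B
  stats::setNames(as.numeric(p), types)
}

#' Permutation-based spatial neighbourhood enrichment test
#'
#' Tests whether the neighbourhoods of a rare set of marker-positive cells
#' are enriched for particular cell types. The observed statistic is the
#' mean k-neighbour composition over the positive cells; the null is built
#' by resampling random cell subsets of the same size `B` times
#' ([sample_null()]); empirical one-sided p-values come from
#' [empirical_p()]; a type is called enriched when `p < alpha` (strict).
#'
#' @param slide A slide tibble.
#' @param positive_indices Row indices of the positive cells (e.g. from
#'   [select_positive()]).
#' @param k Neighbour count (default 20).
#' @param B Number of null resamples (default 1000).
#' @param alpha Significance level for the enrichment call (default 0.05).
#' @param seed Integer seed for the resampling.
#' @param add_one Use the `(count + 1)/(B + 1)` p estimator.
#' @param adjust Multiple-testing adjustment across types applied to the
#'   reported `p_adjusted` column (`"none"` or any [stats::p.adjust()]
#'   method, e.g. `"BH"`); the enrichment call always uses the raw p.
#' @return A `niche_enrichment` object; see [tidy.niche_enrichment()].
#' @export
#' @examples
#' cfg <- slide_config(n_cells = 500, m_positive = 5, seed = 7)
#' slide <- generate_null_slide(cfg)
#' fit <- run_enrichment(slide, which(slide$positive), k = 10, B = 100,
#'                       seed = 7)
#' tidy(fit)
run_enrichment <- function(slide, positive_indices, k = 20, B = 1000,
                           alpha = 0.05, seed = 1L, add_one = FALSE,
                           adjust = "none") {
  positive_indices <- as.integer(positive_indices)
  if (length(positive_indices) == 0) {
    stop_validation("no positive cells: the enrichment test needs >= 1",
                    "rareniche_parameter_error")
  }
  check_number(alpha, "alpha", min = 0, max = 1)

  comps <- slide_compositions(slide, k)
  pos_comps <- comps[positive_indices, , drop = FALSE]
  observed <- mean_composition(pos_comps)
  null <- sample_null(slide, m = length(positive_indices), B = B, k = k,
                      seed = seed, compositions = comps)
  p <- empirical_p(observed, null, add_one = add_one)
  p_adj <- if (identical(adjust, "none")) p else p.adjust(p, method = adjust)

  structure(
    list(
      observed = observed,
      positive_compositions = pos_comps,
      null = null,
      p_values = p,
      p_adjusted = p_adj,
      enriched = p < alpha,
      alpha = alpha,
      parameters = list(
        n_cells = nrow(slide), m = length(positive_indices), k = k, B = B,
        alpha = alpha, seed = as.integer(seed), add_one = add_one,
        adjust = adjust
      )
    ),
    class = "niche_enrichment"
  )
}

#' @export
print.niche_enrichment <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "<niche_enrichment> m = %d positives, k = %d, B = %d, alpha = %g\n",
    p$m, p$k, p$B, p$alpha
  ))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a niche enrichment result
#'
#' @param x A `niche_enrichment`.
#' @param ... Unused.
#' @return One row per cell type: observed mean/SD fraction, null mean,
#'   empirical p (raw and adjusted) and the enrichment call.
#' @method tidy niche_enrichment
#' @export
tidy.niche_enrichment <- function(x, ...) {
  tibble(
    cell_type = x$observed$cell_type,
    observed_mean = x$observed$mean,
    observed_sd = x$observed$sd,
    null_mean = colMeans(x$null$means)[x$observed$cell_type],
    p_value = unname(x$p_values[x$observed$cell_type]),
    p_adjusted = unname(x$p_adjusted[x$observed$cell_type]),
    enriched = unname(x$enriched[x$observed$cell_type])
  )
}

#' One-line summary of a niche enrichment run
#'
#' @param x A `niche_enrichment`.
#' @param ... Unused.
#' @return One-row tibble with the run parameters and the number of
#'   enriched types.
#' @method glance niche_enrichment
#' @export
glance.niche_enrichment <- function(x, ...) {
  p <- x$parameters
  tibble(
    n_cells = p$n_cells, n_positive = p$m, k = p$k, B = p$B,
    alpha = p$alpha, seed = p$seed, add_one = p$add_one,
    n_enriched = sum(x$enriched), min_p = min(x$p_values)
  )
}

#' Plot observed vs null neighbourhood composition
#'
#' Bars show the observed mean composition of the positive cells' k-nearest
#' neighbourhoods (error bars: SD over positive cells) next to the null
#' expectation; types called enriched are starred.
#'
#' @param object A `niche_enrichment`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot niche_enrichment
#' @export
autoplot.niche_enrichment <- function(object, ...) {
  td <- tidy(object)
  long <- tidyr::pivot_longer(
    td, c("observed_mean", "null_mean"),
    names_to = "which", values_to = "fraction"
  )
  long$which <- ifelse(long$which == "observed_mean", "observed", "null")
  long$sd <- ifelse(long$which == "observed", long$observed_sd, NA_real_)
  stars <- td[td$enriched, , drop = FALSE]

  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_type,
                                     y = .data$fraction,
                                     fill = .data$which)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$fraction - .data$sd,
                   ymax = .data$fraction + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2,
      na.rm = TRUE
    ) +
    ggplot2::geom_text(
      data = stars,
      ggplot2::aes(x = .data$cell_type,
                   y = .data$observed_mean + .data$observed_sd + 0.02,
                   label = "*"),
      inherit.aes = FALSE, size = 6
    ) +
    ggplot2::labs(x = NULL, y = "mean neighbourhood fraction",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' One-sample t-test variant of the enrichment test
#'
#' A labelled alternative to the permutation p-value: a two-sided one-sample
#' t-test of the positive cells' per-cell focal-type fractions against the
#' null grand mean for that type. Reported alongside the permutation test,
#' not instead of it — with 13 cells of bounded fractions the permutation
#' test is the primary inference.
#'
#' @param enrichment A `niche_enrichment`, or a wide composition tibble of
#'   the positive cells (then `null_mean` must be given).
#' @param type Cell type to test.
#' @param null_mean Null grand mean for `type`; taken from the enrichment's
#'   null distribution when an `niche_enrichment` is supplied.
#' @return Tibble with `cell_type`, `t`, `df`, `p_value`, `null_mean`.
#' @export
enrichment_t_test <- function(enrichment, type, null_mean = NULL) {
  if (inherits(enrichment, "niche_enrichment")) {
    comps <- enrichment$positive_compositions
    null_mean <- null_mean %||%
      unname(colMeans(enrichment$null$means)[type])
  } else {
    comps <- enrichment
    if (is.null(null_mean)) {
      stop_validation("`null_mean` is required without a niche_enrichment",
                      "rareniche_parameter_error")
    }
  }
  if (!type %in% names(comps)) {
    stop_validation(sprintf("type '%s' not found in compositions", type),
                    "rareniche_validation_error")
  }
  x <- comps[[type]]
  if (length(x) < 2) {
    stop_validation("t-test variant needs at least 2 positive cells",
                    "rareniche_parameter_error")
  }
  n <- length(x)
  se <- sd(x) / sqrt(n)
  dev <- mean(x) - null_mean
  # closed form rather than stats::t.test so the degenerate constant-sample
  # case (se = 0) is defined: t = 0 when centred, +/-Inf otherwise
  t_stat <- if (se == 0) {
    if (dev == 0) 0 else sign(dev) * Inf
  } else {
    dev / se
  }
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  tibble(
    cell_type = type,
    t = t_stat,
    df = n - 1,
    p_value = p,
    null_mean = null_mean
  )
}
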