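#' Exact k-nearest-neighbour query on a slide
#'
#' Exact Euclidean kNN in 2D by exhaustive scan (compiled). A cell is never
#' its own neighbour, and distance ties are broken by ascending cell index
#' so results are deterministic across platforms. Results agree with any
#' exact nearest-neighbour structure (e.g. a k-d tree) on tie-free input.
#'
#' @param slide A slide tibble with `x`, `y` columns.
#' @param query Integer row indices of the query cells; default all cells.
#' @param k Number of neighbours; must be smaller than the number of cells.
#' @return A `neighbor_graph`: list with `query` (indices), `idx`
#'   (`length(query) x k` matrix of neighbour row indices, nearest first),
#'   `dist` (matching distances) and `k`.
#' @export
#' @examples
#' slide <- generate_null_slide(slide_config(n_cells = 200, m_positive = 3))
#' g <- knn_query(slide, k = 20)
knn_query <- function(slide, query = seq_len(nrow(slide)), k) {
  n <- nrow(slide)
  check_number(k, "k", min = 1, integer = TRUE)
  if (k >= n) {
    stop_validation(
      sprintf("k = %d must be smaller than the number of cells (%d)", k, n),
      "rareniche_parameter_error"
    )
  }
  query <- as.integer(query)
  if (length(query) == 0 || any(query < 1 | query > n)) {
    stop_validation("`query` must be non-empty row indices into the slide",
                    "rareniche_parameter_error")
  }
  res <- knn_brute_cpp(slide$x, slide$y, query, as.integer(k))
  structure(
    list(query = query, idx = res$idx, dist = res$dist, k = as.integer(k)),
    class = "neighbor_graph"
  )
}

#' Neighbours within a fixed radius (alternative neighbourhood definition)
#'
#' A radius-based variant of [knn_query()], provided because "neighbouring
#' cells within a defined radius" is a common alternative reading of a
#' spatial niche; the k-nearest-neighbour definition is the primary one in
#' this package. Neighbour counts vary per cell, so the result stores lists.
#'
#' @param slide A slide tibble.
#' @param query Query row indices.
#' @param radius Inclusive distance threshold (length units).
#' @return A `neighbor_graph` with list-valued `idx` and `dist`.
#' @export
radius_query <- function(slide, query = seq_len(nrow(slide)), radius) {
  check_number(radius, "radius", min = 0, strict_min = TRUE)
  query <- as.integer(query)
  idx <- vector("list", length(query))
  dst <- vector("list", length(query))
  for (i in seq_along(query)) {
    qi <- query[i]
    d <- sqrt((slide$x - slide$x[qi])^2 + (slide$y - slide$y[qi])^2)
    keep <- which(d <= radius & seq_len(nrow(slide)) != qi)
    ord <- order(d[keep], keep)
    idx[[i]] <- keep[ord]
    dst[[i]] <- d[keep][ord]
  }
  structure(
    list(query = query, idx = idx, dist = dst, k = NA_integer_),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d queries, k = %s\n", length(x$query),
              ifelse(is.na(x$k), "radius-based", x$k)))
  invisible(x)
}

#' Neighbourhood cell-type composition per query cell
#'
#' Fraction of each cell type among a cell's neighbours. Types absent from a
#' neighbourhood get 0; each row lies on the probability simplex.
#'
#' @param slide The slide the graph was built on.
#' @param graph A `neighbor_graph` from [knn_query()] or [radius_query()].
#' @param type_universe Cell-type universe; defaults to the slide's.
#' @return Wide tibble: `cell_id` plus one fraction column per type.
#' @export
composition <- function(slide, graph, type_universe = NULL) {
  stopifnot(inherits(graph, "neighbor_graph"))
  universe <- type_universe %||% type_universe(slide)
  labels <- as.character(slide$cell_type)
  if (!all(labels %in% universe)) {
    stop_validation(
      sprintf("cell_type label(s) outside the type universe: %s",
              paste(setdiff(unique(labels), universe), collapse = ", ")),
      "rareniche_validation_error"
    )
  }
  code <- match(labels, universe)
  frac <- composition_matrix(graph, code, length(universe))
  colnames(frac) <- universe
  out <- as_tibble(frac)
  out <- dplyr::bind_cols(tibble(cell_id = slide$cell_id[graph$query]), out)
  attr(out, "type_universe") <- universe
  out
}

composition_matrix <- function(graph, code, n_types) {
  if (is.matrix(graph$idx)) {
    q <- nrow(graph$idx)
    k <- ncol(graph$idx)
    counts <- matrix(0L, q, n_types)
    neigh_code <- matrix(code[graph$idx], q, k)
    for (t in seq_len(n_types)) {
      counts[, t] <- rowSums(neigh_code == t)
    }
    counts / k
  } else {
    t(vapply(graph$idx, function(ix) {
      if (length(ix) == 0) return(rep(NA_real_, n_types))
      tabulate(code[ix], nbins = n_types) / length(ix)
    }, numeric(n_types)))
  }
}

comp_values <- function(compositions) {
  as.matrix(compositions[setdiff(names(compositions), "cell_id")])
}

#' Mean and SD of a set of composition vectors
#'
#' Arithmetic mean and sample standard deviation per type over the query
#' cells (SD is 0 when a single composition is supplied).
#'
#' @param compositions Wide composition tibble from [composition()].
#' @return Tibble with `cell_type`, `mean`, `sd`, `n`.
#' @export
mean_composition <- function(compositions) {
  vals <- comp_values(compositions)
  n <- nrow(vals)
  if (n == 0) {
    stop_validation("need at least one composition",
                    "rareniche_parameter_error")
  }
  sds <- if (n == 1) rep(0, ncol(vals)) else apply(vals, 2, sd)
  tibble(
    cell_type = colnames(vals),
    mean = unname(colMeans(vals)),
    sd = unname(sds),
    n = n
  )
}

#' Indices of marker-positive cells
#'
#' A cell is positive when its value in `column` is strictly greater than
#' `threshold` (default 0, i.e. "detectable expression"). When the slide
#' carries a logical `positive` column and `use_flag = TRUE`, that flag takes
#' precedence.
#'
#' @param slide A slide tibble.
#' @param column Name of the expression column to threshold.
#' @param threshold Strict lower bound; a value equal to it is excluded.
#' @param use_flag Use the slide's `positive` flag instead of thresholding.
#' @return Integer row indices of the positive cells.
#' @export
select_positive <- function(slide, column = NULL, threshold = 0,
                            use_flag = FALSE) {
  if (use_flag) {
    if (!"positive" %in% names(slide)) {
      stop_validation("slide has no 'positive' column",
                      "rareniche_parameter_error")
    }
    return(which(as.logical(slide$positive)))
  }
  if (is.null(column) || !column %in% names(slide)) {
    stop_validation(
      sprintf("expression column '%s' not found in the slide",
              column %||% "<missing>"),
      "rareniche_parameter_error"
    )
  }
  which(slide[[column]] > threshold)
}

#' Percentage of marker-positive cells per cell type
#'
#' For each type, `100 * (# positive cells of that type) / (# cells of that
#' type)`. Types with no cells on the slide are omitted.
#'
#' @param slide A slide tibble.
#' @param positive_indices Row indices of positive cells.
#' @return Tibble with `cell_type`, `n_cells`, `n_positive`, `percent`.
#' @export
positive_fraction_by_type <- function(slide, positive_indices) {
  labels <- as.character(slide$cell_type)
  counts <- dplyr::count(tibble(cell_type = labels), .data$cell_type,
                         name = "n_cells")
  pos <- dplyr::count(tibble(cell_type = labels[positive_indices]),
                      .data$cell_type, name = "n_positive")
  out <- dplyr::left_join(counts, pos, by = "cell_type")
  out$n_positive[is.na(out$n_positive)] <- 0L
  out$percent <- 100 * out$n_positive / out$n_cells
  out
}
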