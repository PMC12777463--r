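# Independent oracles used across the suite. Each is a deliberately naive
# implementation (full sorts, exhaustive enumeration, direct formulas) kept
# separate from the package code paths it checks.

# Exact kNN by sorting the full distance vector; ties by ascending index.
oracle_knn <- function(slide, query, k) {
  t(vapply(query, function(qi) {
    d <- sqrt((slide$x - slide$x[qi])^2 + (slide$y - slide$y[qi])^2)
    d[qi] <- Inf
    order(d, seq_along(d))[seq_len(k)]
  }, integer(k)))
}

# Upper-tail overlap probability by exhaustive enumeration of all
# choose(universe, n_b) draws of set B against a fixed set A.
oracle_overlap <- function(universe, n_a, n_b, k) {
  a <- seq_len(n_a)
  draws <- utils::combn(universe, n_b)
  hits <- apply(draws, 2, function(b) sum(b %in% a))
  sum(hits >= k) / ncol(draws)
}

# Nearest-peak assignment by scanning every peak for every gene.
oracle_assign <- function(tss, peaks, window) {
  res <- lapply(seq_len(nrow(tss)), function(i) {
    best_d <- Inf
    best_j <- NA_integer_
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != tss$chrom[i]) next
      pos <- tss$tss[i]
      d <- if (pos >= peaks$start[j] && pos < peaks$end[j]) {
        0
      } else if (pos < peaks$start[j]) {
        peaks$start[j] - pos
      } else {
        pos - peaks$end[j] + 1
      }
      if (d > window) next
      if (d < best_d ||
          (d == best_d && peaks$start[j] < peaks$start[best_j])) {
        best_d <- d
        best_j <- j
      }
    }
    c(best_j, if (is.finite(best_d)) best_d else NA)
  })
  m <- do.call(rbind, res)
  data.frame(peak_row = m[, 1], distance = m[, 2])
}

# Small null slide used by several tests.
tiny_slide <- function(n = 200, m = 5, seed = 1, types = NULL) {
  props <- types %||% c(A = 0.5, B = 0.3, C = 0.2)
  generate_null_slide(slide_config(
    n_cells = n, type_proportions = props, m_positive = m, seed = seed
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
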