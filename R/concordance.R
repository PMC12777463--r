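#' Assign each gene its nearest peak within a TSS window
#'
#' For every gene, finds the nearest peak on the same chromosome whose edge
#' distance from the transcription start site is at most `window` bp
#' (inclusive). Distance is 0 when the TSS lies inside the 0-based half-open
#' peak interval, otherwise the number of bases from the TSS to the nearer
#' peak edge. Equidistant ties are broken by the smaller peak start, which
#' makes assignment deterministic. `distance_mode = "midpoint"` instead
#' measures to the peak midpoint (rounded down), as an explicitly labelled
#' alternative.
#'
#' @param tss TSS tibble (`chrom`, `tss`, `strand`, `gene_id`), e.g. from
#'   [read_tss_bed()].
#' @param peaks Interval tibble (`chrom`, `start`, `end`, optional `name`,
#'   `score`), e.g. from [read_bed_intervals()].
#' @param window Inclusive distance threshold in bp (default 5000).
#' @param distance_mode `"edge"` (default) or `"midpoint"`.
#' @return One row per gene: `gene_id`, `chrom`, `tss`, `peak_name`,
#'   `peak_start`, `peak_end`, `peak_score`, `distance`; `NA` columns where
#'   no peak lies within the window.
#' @export
assign_nearest_peak <- function(tss, peaks, window = 5000,
                                distance_mode = c("edge", "midpoint")) {
  distance_mode <- match.arg(distance_mode)
  check_number(window, "window", min = 0)
  peak_name <- peaks$name %||% sprintf("peak_%04d", seq_len(nrow(peaks)))
  peak_score <- peaks$score %||% rep(NA_real_, nrow(peaks))

  assign_one <- function(chrom, pos) {
    on_chr <- which(peaks$chrom == chrom)
    if (length(on_chr) == 0) return(c(NA_integer_, NA_integer_))
    s <- peaks$start[on_chr]
    e <- peaks$end[on_chr]
    d <- if (distance_mode == "edge") {
      pmax(s - pos, pos - e + 1L, 0L)
    } else {
      abs(pos - (s + (e - s) %/% 2L))
    }
    ok <- which(d <= window)
    if (length(ok) == 0) return(c(NA_integer_, NA_integer_))
    # nearest first; equidistant ties go to the smaller start
    best <- ok[order(d[ok], s[ok])][1]
    c(as.integer(on_chr[best]), as.integer(d[best]))
  }

  hits <- vapply(seq_len(nrow(tss)),
                 function(i) assign_one(tss$chrom[i], tss$tss[i]),
                 integer(2))
  pk <- hits[1, ]
  tibble(
    gene_id = tss$gene_id,
    chrom = tss$chrom,
    tss = tss$tss,
    peak_name = ifelse(is.na(pk), NA_character_, peak_name[pk]),
    peak_start = peaks$start[pk],
    peak_end = peaks$end[pk],
    peak_score = peak_score[pk],
    distance = hits[2, ]
  )
}

#' Acetylation-expression log fold-change concordance
#'
#' Correlates per-peak differential signal (e.g. H3K27ac logFC) with the
#' assigned genes' expression logFC over the genes that received a peak
#' assignment, asking whether chromatin and transcriptional changes move
#' together.
#'
#' @param assignments Output of [assign_nearest_peak()] (needs
#'   `peak_score`).
#' @param gene_table Gene table with `gene_id` and `logFC`.
#' @param method Correlation method(s), as in [correlate()].
#' @return A `coexpr_cor` over the assigned (peak logFC, gene logFC) pairs.
#' @export
concordance <- function(assignments, gene_table,
                        method = c("pearson", "spearman", "both")) {
  method <- match.arg(method)
  joined <- dplyr::inner_join(
    dplyr::filter(assignments, !is.na(.data$peak_name)),
    gene_table[, c("gene_id", "logFC")],
    by = "gene_id"
  )
  if (nrow(joined) < 3) {
    stop_validation(
      sprintf("only %d assigned gene-peak pair(s); need >= 3", nrow(joined)),
      "rareniche_insufficient_data_error"
    )
  }
  pairs <- tibble(peak_logFC = joined$peak_score, gene_logFC = joined$logFC)
  out <- correlate(pairs, "peak_logFC", "gene_logFC", method = method,
                   marker_threshold = -Inf)
  out$estimates$restriction <- "assigned gene-peak pairs"
  out$marker <- "peak_logFC"
  out$target <- "gene_logFC"
  out
}

#' Filter a differential-expression table by thresholds
#'
#' Keeps genes with `|logFC|` strictly greater than `lfc_cut` and the chosen
#' significance statistic strictly below `stat_cut` (both bounds strict, so
#' a gene sitting exactly on a threshold is excluded).
#'
#' @param table DEG tibble with `gene_id`, `logFC` and the chosen statistic
#'   column.
#' @param lfc_cut Absolute logFC threshold (strict `>`).
#' @param stat `"fdr"` or `"pvalue"`.
#' @param stat_cut Significance threshold (strict `<`).
#' @return Tibble of the retained rows, in input order.
#' @export
#' @examples
#' degs <- tibble::tibble(gene_id = c("g1", "g2"), logFC = c(0.8, 0.4),
#'                        fdr = c(0.001, 0.2))
#' filter_degs(degs, lfc_cut = 0.5, stat = "fdr", stat_cut = 0.01)
filter_degs <- function(table, lfc_cut = 0.5, stat = c("fdr", "pvalue"),
                        stat_cut = 0.01) {
  stat <- match.arg(stat)
  if (!stat %in% names(table)) {
    stop_validation(sprintf("column '%s' not found in the DEG table", stat),
                    "rareniche_parameter_error")
  }
  check_number(lfc_cut, "lfc_cut", min = 0)
  check_number(stat_cut, "stat_cut", min = 0, max = 1)
  dplyr::filter(table, abs(.data$logFC) > lfc_cut,
                .data[[stat]] < stat_cut)
}

#' Hypergeometric upper-tail test of gene-set overlap
#'
#' Probability of observing at least `k_overlap` shared genes between two
#' sets of sizes `n_a` and `n_b` drawn from a `universe` of genes —
#' equivalent to the one-sided Fisher exact test on the 2x2 table. The tail
#' is evaluated in log space, so p-values far below double underflow of the
#' individual terms remain accurate. The universe size must be supplied
#' explicitly: overlap significance is meaningless without it.
#'
#' @param n_a,n_b Sizes of the two gene sets.
#' @param k_overlap Observed overlap.
#' @param universe Number of genes both sets were drawn from.
#' @return Tibble with `p_value`, `log10_p`, `expected_overlap` and the
#'   inputs.
#' @export
#' @examples
#' overlap_test(n_a = 310, n_b = 383, k_overlap = 47, universe = 15000)
overlap_test <- function(n_a, n_b, k_overlap, universe) {
  check_number(n_a, "n_a", min = 0, integer = TRUE)
  check_number(n_b, "n_b", min = 0, integer = TRUE)
  check_number(k_overlap, "k_overlap", min = 0, integer = TRUE)
  check_number(universe, "universe", min = 1, integer = TRUE)
  if (n_a > universe || n_b > universe) {
    stop_validation("set sizes cannot exceed the universe",
                    "rareniche_validation_error")
  }
  if (k_overlap > min(n_a, n_b)) {
    stop_validation("overlap cannot exceed the smaller set",
                    "rareniche_validation_error")
  }
  if (k_overlap < max(0, n_a + n_b - universe)) {
    stop_validation("overlap below the minimum forced by the set sizes",
                    "rareniche_validation_error")
  }
  # P(X >= k) with X ~ Hypergeometric(universe, n_a, n_b)
  log_p <- phyper(k_overlap - 1, n_a, universe - n_a, n_b,
                  lower.tail = FALSE, log.p = TRUE)
  tibble(
    n_a = n_a, n_b = n_b, k_overlap = k_overlap, universe = universe,
    expected_overlap = n_a * n_b / universe,
    p_value = exp(log_p),
    log10_p = log_p / log(10)
  )
}
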