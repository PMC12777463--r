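#' Configuration for a synthetic spatial slide
#'
#' Bundles and validates the parameters of the slide simulator. The defaults
#' mirror the scale of the motivating study: roughly 50,000 cells of six
#' annotated types on a planar section, of which 13 are positive for a rare
#' marker transcript, and 20-nearest-neighbour composition statistics.
#'
#' @param n_cells Number of cells on the slide.
#' @param type_proportions Named numeric vector of cell-type proportions;
#'   must sum to 1 (within 1e-9). Names define the cell-type universe.
#' @param m_positive Number of marker-positive cells to flag.
#' @param focal_type Cell type whose spatial clusters attract positives when
#'   `enrichment_rho > 0`; `NULL` for a fully exchangeable null slide.
#' @param enrichment_rho Strength of the planted enrichment: positive cells
#'   are drawn without replacement with selection weight
#'   `1 + enrichment_rho * f_i`, where `f_i` is the focal-type fraction among
#'   cell `i`'s `k_local` nearest neighbours. `0` plants nothing.
#' @param n_clusters Number of Gaussian clusters the focal-type cells form.
#' @param cluster_sd Standard deviation of each cluster (length units).
#' @param field_size Side length of the square field (length units).
#' @param k_local Neighbour count used when computing the selection weights.
#' @param seed Integer seed; every draw in the generators runs through a
#'   single stream seeded with it.
#'
#' @return A `slide_config` list.
#' @export
#' @examples
#' cfg <- slide_config(n_cells = 1000, m_positive = 5)
#' slide <- generate_null_slide(cfg)
slide_config <- function(n_cells = 50000,
                         type_proportions = c(
                           "Cancer Epithelial" = 0.40,
                           "Normal Epithelial" = 0.10,
                           "Stromal" = 0.20,
                           "T-cell" = 0.15,
                           "Myeloid" = 0.10,
                           "Endothelial" = 0.05
                         ),
                         m_positive = 13,
                         focal_type = NULL,
                         enrichment_rho = 0,
                         n_clusters = 10,
                         cluster_sd = 30,
                         field_size = 1000,
                         k_local = 20,
                         seed = 1L) {
  check_number(n_cells, "n_cells", min = 1, integer = TRUE)
  check_number(m_positive, "m_positive", min = 0, integer = TRUE)
  check_number(enrichment_rho, "enrichment_rho", min = 0)
  check_number(n_clusters, "n_clusters", min = 1, integer = TRUE)
  check_number(cluster_sd, "cluster_sd", min = 0, strict_min = TRUE)
  check_number(field_size, "field_size", min = 0, strict_min = TRUE)
  check_number(k_local, "k_local", min = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)

  if (is.null(names(type_proportions)) || any(names(type_proportions) == "")) {
    stop_validation("`type_proportions` must be a fully named numeric vector",
                    "rareniche_validation_error")
  }
  if (anyDuplicated(names(type_proportions))) {
    stop_validation("`type_proportions` names must be unique",
                    "rareniche_validation_error")
  }
  if (any(type_proportions < 0) ||
      abs(sum(type_proportions) - 1) > 1e-9) {
    stop_validation("`type_proportions` must be non-negative and sum to 1",
                    "rareniche_validation_error")
  }
  if (m_positive > n_cells) {
    stop_validation("`m_positive` cannot exceed `n_cells`",
                    "rareniche_validation_error")
  }
  if (enrichment_rho > 0 && !is.null(focal_type) &&
      !focal_type %in% names(type_proportions)) {
    stop_validation(
      sprintf("`focal_type` '%s' is not in `type_proportions`", focal_type),
      "rareniche_validation_error"
    )
  }

  structure(
    list(
      n_cells = as.integer(n_cells),
      type_proportions = type_proportions,
      m_positive = as.integer(m_positive),
      focal_type = focal_type,
      enrichment_rho = enrichment_rho,
      n_clusters = as.integer(n_clusters),
      cluster_sd = cluster_sd,
      field_size = field_size,
      k_local = as.integer(k_local),
      seed = as.integer(seed)
    ),
    class = "slide_config"
  )
}

new_slide <- function(cell_id, x, y, cell_type, positive, selection_weight,
                      type_universe) {
  out <- tibble(
    cell_id = cell_id,
    x = x,
    y = y,
    cell_type = factor(cell_type, levels = type_universe),
    positive = positive,
    selection_weight = selection_weight
  )
  attr(out, "type_universe") <- type_universe
  out
}

#' Cell-type universe of a slide
#'
#' The declared universe (set at read/generation time) if present, otherwise
#' the observed labels.
#'
#' @param slide A slide tibble.
#' @return Character vector of cell-type labels.
#' @export
type_universe <- function(slide) {
  u <- attr(slide, "type_universe")
  if (!is.null(u)) return(u)
  if (is.factor(slide$cell_type)) return(levels(slide$cell_type))
  sort(unique(as.character(slide$cell_type)))
}

#' Simulate a null spatial slide
#'
#' Coordinates are i.i.d. uniform on the square, cell-type labels i.i.d. from
#' the configured proportions, and the `m_positive` marker-positive cells are
#' a uniformly random subset of all cells. Under this model the positives'
#' neighbourhoods are exchangeable with those of any random cell subset, which
#' is exactly the null hypothesis of the permutation enrichment test.
#'
#' @param config A [slide_config()].
#' @return A slide tibble (`cell_id`, `x`, `y`, `cell_type`, `positive`,
#'   `selection_weight`); all selection weights are 1 under the null.
#' @export
generate_null_slide <- function(config = slide_config()) {
  stopifnot(inherits(config, "slide_config"))
  n <- config$n_cells
  universe <- names(config$type_proportions)

  local_seed(config$seed, {
    x <- runif(n, 0, config$field_size)
    y <- runif(n, 0, config$field_size)
    labels <- sample(universe, n, replace = TRUE,
                     prob = config$type_proportions)
    pos_idx <- sample.int(n, config$m_positive)
    new_slide(
      cell_id = sprintf("cell_%05d", seq_len(n)),
      x = x, y = y, cell_type = labels,
      positive = seq_len(n) %in% pos_idx,
      selection_weight = rep(1, n),
      type_universe = universe
    )
  })
}

# Draw n points from a mixture of isotropic Gaussians truncated to the field
# by rejection sampling (keeps density finite at the edges).
sample_clustered <- function(n, n_clusters, cluster_sd, field_size) {
  cx <- runif(n_clusters, 0, field_size)
  cy <- runif(n_clusters, 0, field_size)
  out_x <- numeric(n)
  out_y <- numeric(n)
  filled <- 0L
  while (filled < n) {
    need <- n - filled
    comp <- sample.int(n_clusters, need, replace = TRUE)
    px <- rnorm(need, cx[comp], cluster_sd)
    py <- rnorm(need, cy[comp], cluster_sd)
    keep <- px >= 0 & px <= field_size & py >= 0 & py <= field_size
    n_keep <- sum(keep)
    if (n_keep > 0) {
      out_x[filled + seq_len(n_keep)] <- px[keep]
      out_y[filled + seq_len(n_keep)] <- py[keep]
      filled <- filled + n_keep
    }
  }
  list(x = out_x, y = out_y)
}

#' Simulate a slide with planted niche enrichment
#'
#' Focal-type cells are placed as a mixture of `n_clusters` isotropic
#' Gaussian clusters (centres uniform, truncated to the field by rejection
#' sampling); all other cells are uniform. Marker-positive cells are then
#' drawn without replacement with selection weight
#' `w_i = 1 + enrichment_rho * f_i`, where `f_i` is the focal-type fraction
#' among cell `i`'s `k_local` nearest neighbours. Injecting enrichment
#' through selection weights on existing cells (rather than moving cells)
#' keeps the marginal spatial and type distributions identical between null
#' and alternative, isolating the neighbourhood effect. The realised weights
#' are returned in the `selection_weight` column as ground truth.
#'
#' @param config A [slide_config()] with `focal_type` set.
#' @return A slide tibble; `selection_weight` holds the ground-truth weights.
#' @export
generate_enriched_slide <- function(config) {
  stopifnot(inherits(config, "slide_config"))
  if (is.null(config$focal_type)) {
    stop_validation("`focal_type` must be set for an enriched slide",
                    "rareniche_validation_error")
  }
  if (!config$focal_type %in% names(config$type_proportions)) {
    stop_validation(
      sprintf("`focal_type` '%s' is not in `type_proportions`",
              config$focal_type),
      "rareniche_validation_error"
    )
  }
  n <- config$n_cells
  universe <- names(config$type_proportions)
  focal_code <- match(config$focal_type, universe)

  local_seed(config$seed, {
    labels <- sample(universe, n, replace = TRUE,
                     prob = config$type_proportions)
    is_focal <- labels == config$focal_type
    x <- runif(n, 0, config$field_size)
    y <- runif(n, 0, config$field_size)
    n_focal <- sum(is_focal)
    if (n_focal > 0) {
      pts <- sample_clustered(n_focal, config$n_clusters, config$cluster_sd,
                              config$field_size)
      x[is_focal] <- pts$x
      y[is_focal] <- pts$y
    }

    counts <- knn_type_counts_cpp(x, y, match(labels, universe),
                                  length(universe), config$k_local)
    f_local <- counts[, focal_code] / config$k_local
    w <- 1 + config$enrichment_rho * f_local
    pos_idx <- sample.int(n, config$m_positive, prob = w)

    new_slide(
      cell_id = sprintf("cell_%05d", seq_len(n)),
      x = x, y = y, cell_type = labels,
      positive = seq_len(n) %in% pos_idx,
      selection_weight = w,
      type_universe = universe
    )
  })
}

#' Configuration for synthetic co-expressed gene pairs
#'
#' @param n_cells Number of cells.
#' @param r_true Latent correlation between the two genes, in `[-1, 1]`.
#' @param dropout_prob Probability that an observed value is zeroed
#'   (dropout), independently per gene and cell; in `[0, 1)`.
#' @param scale Multiplicative scale of observed expression.
#' @param seed Integer seed.
#' @return A `coexpr_config` list.
#' @export
coexpr_config <- function(n_cells = 2000, r_true = 0.65, dropout_prob = 0.3,
                          scale = 1, seed = 1L) {
  check_number(n_cells, "n_cells", min = 1, integer = TRUE)
  check_number(r_true, "r_true", min = -1, max = 1)
  check_number(dropout_prob, "dropout_prob", min = 0, max = 1 - 1e-12)
  check_number(scale, "scale", min = 0, strict_min = TRUE)
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(n_cells = as.integer(n_cells), r_true = r_true,
         dropout_prob = dropout_prob, scale = scale, seed = as.integer(seed)),
    class = "coexpr_config"
  )
}

#' Simulate a zero-inflated co-expressed gene pair
#'
#' Latent pairs are bivariate normal with correlation `r_true`; the observed
#' value is `scale * exp(latent)` with independent dropout to zero. The
#' latent values are returned as the oracle against which downstream
#' correlation estimates are judged. Note that the observed values are on
#' the natural scale; the correlation analyses in this package expect
#' log-normalized input, so take `log()` of the non-zero observations (an
#' affine transform of the latents) before correlating.
#'
#' @param config A [coexpr_config()].
#' @return Tibble with `cell_id`, `marker`, `target` (observed values) and
#'   `latent_marker`, `latent_target` (oracle).
#' @export
generate_coexpression <- function(config = coexpr_config()) {
  stopifnot(inherits(config, "coexpr_config"))
  n <- config$n_cells
  r <- config$r_true

  local_seed(config$seed, {
    z1 <- rnorm(n)
    e <- rnorm(n)
    z2 <- r * z1 + sqrt(1 - r^2) * e
    obs1 <- config$scale * exp(z1)
    obs2 <- config$scale * exp(z2)
    if (config$dropout_prob > 0) {
      obs1[runif(n) < config$dropout_prob] <- 0
      obs2[runif(n) < config$dropout_prob] <- 0
    }
    tibble(
      cell_id = sprintf("cell_%05d", seq_len(n)),
      marker = obs1,
      target = obs2,
      latent_marker = z1,
      latent_target = z2
    )
  })
}

#' Simulate a peak/TSS/logFC fixture with known assignments
#'
#' Lays out `n_genes` transcription start sites on one synthetic chromosome,
#' spaced far enough apart that each gene's nearest peak within the window is
#' unambiguous by construction. The first `min(n_genes, n_peaks)` genes (in
#' random order) receive a peak within the window (containing the TSS, or
#' offset by a known edge distance of 1..window bp); remaining genes have no
#' peak within the window, and remaining peaks are decoys placed farther than
#' the window from every TSS. Gene and peak log fold-changes for truly
#' assigned pairs are drawn with correlation `r_true`; everything else is
#' independent noise.
#'
#' @param n_genes Number of genes.
#' @param n_peaks Number of peaks (at least 1).
#' @param r_true Correlation between peak and gene logFC for assigned pairs.
#' @param window Assignment window in bp (inclusive).
#' @param seed Integer seed.
#' @return A list with elements `tss` (BED6-style tibble), `peaks`
#'   (interval tibble with `score` = logFC), `degs` (gene table with
#'   `logFC`, `pvalue`, `fdr`) and `truth` (tibble `gene_id`, `peak_name`,
#'   `distance`; `NA` where no peak lies within the window).
#' @export
generate_logfc_fixture <- function(n_genes = 100, n_peaks = 100,
                                   r_true = 0.9, window = 5000, seed = 1L) {
  check_number(n_genes, "n_genes", min = 1, integer = TRUE)
  check_number(n_peaks, "n_peaks", min = 1, integer = TRUE)
  check_number(r_true, "r_true", min = -1, max = 1)
  check_number(window, "window", min = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)

  spacing <- max(50000, 20 * window)
  n_assigned <- min(n_genes, n_peaks)
  n_decoys <- n_peaks - n_assigned

  local_seed(seed, {
    gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    tss_pos <- spacing * seq_len(n_genes)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)

    assigned_genes <- sample.int(n_genes, n_assigned)
    peak_start <- integer(0)
    peak_end <- integer(0)
    truth_peak <- rep(NA_character_, n_genes)
    truth_dist <- rep(NA_integer_, n_genes)

    for (i in seq_len(n_assigned)) {
      g <- assigned_genes[i]
      tss <- tss_pos[g]
      width <- sample(200:1000, 1)
      mode <- sample(c("contain", "right", "left"), 1)
      if (mode == "contain") {
        a <- sample(0:(width - 1), 1)
        s <- tss - a
        e <- s + width
        d <- 0L
      } else if (mode == "right") {
        d <- sample.int(window, 1)
        s <- tss + d
        e <- s + width
      } else {
        d <- sample.int(window, 1)
        e <- tss - d + 1L
        s <- e - width
      }
      peak_start <- c(peak_start, s)
      peak_end <- c(peak_end, e)
      truth_peak[g] <- sprintf("peak_%04d", i)
      truth_dist[g] <- as.integer(d)
    }

    if (n_decoys > 0) {
      host <- sample.int(n_genes, n_decoys, replace = TRUE)
      width <- sample(200:1000, n_decoys, replace = TRUE)
      s <- as.integer(tss_pos[host] + spacing %/% 2)
      peak_start <- c(peak_start, s)
      peak_end <- c(peak_end, s + width)
    }
    peak_name <- sprintf("peak_%04d", seq_len(n_peaks))

    gene_lfc <- rnorm(n_genes, sd = 1)
    peak_lfc <- rnorm(n_peaks, sd = 1)
    # correlate assigned pairs: peak logFC = r * gene logFC + noise
    ai <- seq_len(n_assigned)
    peak_lfc[ai] <- r_true * gene_lfc[assigned_genes] +
      sqrt(1 - r_true^2) * rnorm(n_assigned)

    pvalue <- pmax(2 * stats::pnorm(-abs(gene_lfc) / 0.5), 1e-300)
    fdr <- p.adjust(pvalue, method = "BH")

    ord <- sample.int(n_peaks) # shuffle peak rows; assignment is positional-free
    peaks <- tibble(
      chrom = "chrS",
      start = peak_start[ord],
      end = peak_end[ord],
      name = peak_name[ord],
      score = peak_lfc[ord]
    )
    tss <- tibble(
      chrom = "chrS",
      tss = as.integer(tss_pos),
      strand = strand,
      gene_id = gene_id
    )
    degs <- tibble(gene_id = gene_id, logFC = gene_lfc,
                   pvalue = pvalue, fdr = fdr)
    truth <- tibble(gene_id = gene_id, peak_name = truth_peak,
                    distance = truth_dist)
    list(tss = tss, peaks = peaks, degs = degs, truth = truth,
         window = window, seed = as.integer(seed))
  })
}
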