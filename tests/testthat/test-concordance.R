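test_that("peak assignment handles containment, windows and ties", {
  peaks <- tibble::tibble(chrom = "chr1", start = 100L, end = 200L,
                          name = "p1", score = 0.5)
  tss <- tibble::tibble(chrom = "chr1", tss = 150L, strand = "+",
                        gene_id = "gA")
  res <- assign_nearest_peak(tss, peaks)
  expect_equal(res$peak_name, "p1")
  expect_equal(res$distance, 0L)

  # inclusive window boundary: last peak base at 4999, TSS at 10000
  peaks_b <- tibble::tibble(chrom = "chr1", start = 4000L, end = 5000L,
                            name = "p1", score = 0)
  tss_b <- tibble::tibble(chrom = "chr1", tss = c(10000L, 9999L),
                          strand = "+", gene_id = c("far", "edge"))
  res_b <- assign_nearest_peak(tss_b, peaks_b, window = 5000)
  expect_true(is.na(res_b$peak_name[1])) # 5001 bp away: excluded
  expect_equal(res_b$distance[2], 5000L) # exactly 5000: included

  # equidistant flanking peaks: the smaller start wins
  peaks_t <- tibble::tibble(chrom = "chr1",
                            start = c(2000L, 800L), end = c(2200L, 1000L),
                            name = c("right", "left"), score = c(1, 2))
  tss_t <- tibble::tibble(chrom = "chr1", tss = 1500L, strand = "+",
                          gene_id = "gT")
  # distances: right = 2000-1500 = 500; left = 1500-999 = 501 -> right wins
  res_t <- assign_nearest_peak(tss_t, peaks_t)
  expect_equal(res_t$peak_name, "right")
  # shift left peak to make it exactly equidistant (d = 500 both sides)
  peaks_t$end[2] <- 1001L
  peaks_t$start[2] <- 801L
  res_t2 <- assign_nearest_peak(tss_t, peaks_t)
  expect_equal(res_t2$distance, 500L)
  expect_equal(res_t2$peak_name, "left") # start 801 < 2000

  # wrong chromosome is never assigned
  tss_c <- tibble::tibble(chrom = "chr2", tss = 150L, strand = "+",
                          gene_id = "gC")
  expect_true(is.na(assign_nearest_peak(tss_c, peaks)$peak_name))
})

test_that("assignment equals ground truth and brute force on seeded fixtures", {
  for (seed in 1:20) {
    fx <- generate_logfc_fixture(n_genes = 25, n_peaks = 30, r_true = 0.7,
                                 seed = seed)
    res <- assign_nearest_peak(fx$tss, fx$peaks, window = fx$window)
    expect_equal(res$peak_name, fx$truth$peak_name)
    expect_equal(res$distance, fx$truth$distance)

    brute <- oracle_assign(fx$tss, fx$peaks, fx$window)
    expect_equal(res$peak_name,
                 ifelse(is.na(brute$peak_row), NA_character_,
                        fx$peaks$name[brute$peak_row]))
    expect_equal(res$distance, as.integer(brute$distance))
  }
})

test_that("concordance correlates assigned logFC pairs", {
  fx <- generate_logfc_fixture(n_genes = 100, n_peaks = 100, r_true = 0.9,
                               seed = 33)
  asg <- assign_nearest_peak(fx$tss, fx$peaks, window = fx$window)

  # identity: force gene logFC equal to the assigned peak's logFC
  degs_id <- tibble::tibble(gene_id = asg$gene_id, logFC = asg$peak_score)
  fit_id <- tidy(concordance(asg, degs_id, "pearson"))
  expect_equal(fit_id$r, 1)

  # realised-correlation oracle: r over truly paired logFCs
  joined <- dplyr::inner_join(asg, fx$degs, by = "gene_id")
  r_real <- cor(joined$peak_score, joined$logFC)
  fit <- tidy(concordance(asg, fx$degs, "pearson"))
  expect_equal(fit$r, r_real) # same pairs, so exactly equal
  expect_gt(fit$r, 0.8)

  # permuting the gene column destroys concordance
  set.seed(33)
  shuffled <- fx$degs
  shuffled$logFC <- sample(shuffled$logFC)
  fit_p <- tidy(concordance(asg, shuffled, "pearson"))
  expect_lt(abs(fit_p$r), 0.3)

  expect_error(concordance(asg[0, ], fx$degs), "need >= 3")
})

test_that("DEG filtering applies strict double thresholds", {
  tab <- tibble::tibble(
    gene_id = c("g1", "g2", "g3", "g4"),
    logFC = c(0.6, 0.5, -1.2, 0.8),
    fdr = c(0.005, 0.001, 0.009, 0.02),
    pvalue = c(0.001, 0.0001, 0.002, 0.01)
  )
  res <- filter_degs(tab, lfc_cut = 0.5, stat = "fdr", stat_cut = 0.01)
  expect_equal(res$gene_id, c("g1", "g3")) # g2 on the lfc boundary: out

  # gene exactly on the logFC threshold is excluded
  expect_false("g2" %in%
                 filter_degs(tab, 0.5, "pvalue", 0.001)$gene_id)

  # raising the stat cut never removes genes (monotone)
  for (cut in c(0.001, 0.005, 0.01, 0.05)) {
    lo <- filter_degs(tab, 0.5, "fdr", cut)$gene_id
    hi <- filter_degs(tab, 0.5, "fdr", min(1, cut * 5))$gene_id
    expect_true(all(lo %in% hi))
  }

  # row order invariance
  perm <- tab[c(3, 1, 4, 2), ]
  expect_setequal(filter_degs(perm, 0.5, "fdr", 0.01)$gene_id,
                  filter_degs(tab, 0.5, "fdr", 0.01)$gene_id)

  expect_error(filter_degs(tab[, c("gene_id", "logFC", "pvalue")],
                           0.5, "fdr", 0.01),
               "fdr")
})

test_that("overlap test equals exhaustive enumeration", {
  # worked case: universe 10, sets 4 and 5, overlap 4 -> 6/252
  res <- overlap_test(n_a = 4, n_b = 5, k_overlap = 4, universe = 10)
  expect_equal(res$p_value, 6 / 252)
  expect_equal(res$p_value, oracle_overlap(10, 4, 5, 4))

  # forced complete overlap
  expect_equal(overlap_test(6, 6, 6, 6)$p_value, 1)
  # minimum possible overlap covers the whole support
  expect_equal(overlap_test(7, 8, 3, 12)$p_value, 1) # min = 7+8-12 = 3

  # all feasible configurations for small universes
  for (universe in c(6, 9, 12)) {
    for (n_a in c(2, universe %/% 2)) {
      for (n_b in c(3, universe - 2)) {
        k_min <- max(0, n_a + n_b - universe)
        for (k in k_min:min(n_a, n_b)) {
          expect_equal(
            overlap_test(n_a, n_b, k, universe)$p_value,
            oracle_overlap(universe, n_a, n_b, k),
            tolerance = 1e-12
          )
        }
      }
    }
  }

  # monotone decreasing in k at fixed margins
  ps <- vapply(0:4, function(k) overlap_test(4, 5, k, 10)$p_value,
               numeric(1))
  expect_true(all(diff(ps) < 0))

  # extreme tails stay accurate in log space: perfect overlap of two
  # 50-gene sets in a 10,000-gene universe has p = 1 / choose(10000, 50)
  deep <- overlap_test(50, 50, 50, 10000)
  expect_equal(deep$log10_p, -lchoose(10000, 50) / log(10),
               tolerance = 1e-12)
  expect_lt(deep$log10_p, -100)
  expect_gt(deep$p_value, 0)

  expect_error(overlap_test(4, 5, 5, 10), "smaller set")
  expect_error(overlap_test(7, 8, 2, 12), "minimum")
  expect_error(overlap_test(11, 5, 2, 10), "universe")
})
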