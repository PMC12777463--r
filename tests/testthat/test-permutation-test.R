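make_null <- function(means, m = 13, k = 20, B = nrow(means), seed = 1L) {
  structure(list(means = means, m = m, k = k, B = B, seed = seed),
            class = "null_composition")
}

test_that("empirical p reproduces the literal counting definition", {
  # worked single-column example: 2 of 4 null values >= 0.25
  null <- make_null(cbind(A = c(0.1, 0.2, 0.3, 0.4),
                          B = c(0.9, 0.8, 0.7, 0.6)))
  p <- empirical_p(c(A = 0.25, B = 0.85), null)
  expect_equal(unname(p["A"]), 0.5)
  expect_equal(unname(p["B"]), 1 / 4)

  # boundary: observed above every null value
  null100 <- make_null(cbind(A = seq(0, 0.99, length.out = 100)))
  expect_equal(unname(empirical_p(c(A = 1), null100)["A"]), 0)
  expect_equal(unname(empirical_p(c(A = 1), null100, add_one = TRUE)["A"]),
               1 / 101)

  # ties count as extreme: constant null equal to observed gives p = 1
  nullc <- make_null(cbind(A = rep(0.5, 50)))
  expect_equal(unname(empirical_p(c(A = 0.5), nullc)["A"]), 1)

  # random matrices against an enumeration oracle
  set.seed(17)
  for (rep in 1:20) {
    B <- sample(5:50, 1)
    means <- cbind(A = runif(B), B = runif(B))
    obs <- c(A = runif(1), B = sample(means[, "B"], 1)) # force a tie case
    p <- empirical_p(obs, make_null(means))
    expect_equal(unname(p["A"]), sum(means[, "A"] >= obs["A"]) / B)
    expect_equal(unname(p["B"]), sum(means[, "B"] >= obs["B"]) / B)
  }

  expect_error(empirical_p(c(Z = 0.5), null), "universes differ")
})

test_that("null resampling behaves on degenerate slides", {
  # single-type slide: every null row is the indicator of that type
  s1 <- generate_null_slide(slide_config(
    n_cells = 60, type_proportions = c(A = 1), m_positive = 1, seed = 2
  ))
  null <- sample_null(s1, m = 5, B = 20, k = 10, seed = 1)
  expect_true(all(null$means[, "A"] == 1))

  # m = n_cells: every resample is the whole slide, rows identical
  s <- tiny_slide(n = 80, m = 0, seed = 3)
  null <- sample_null(s, m = 80, B = 10, k = 10, seed = 1)
  expect_equal(max(apply(null$means, 2, function(col) diff(range(col)))), 0)

  # default-scale null matrix has B rows and one column per type
  nulld <- sample_null(tiny_slide(n = 100, m = 0, seed = 4), m = 13,
                       B = 1000, k = 20, seed = 1)
  expect_equal(dim(nulld$means), c(1000L, 3L))
  # every row on the simplex
  expect_true(all(abs(rowSums(nulld$means) - 1) < 1e-9))

  expect_error(sample_null(s, m = 81, B = 10, k = 10, seed = 1), "exceeds")
})

test_that("enrichment calls use a strict alpha threshold", {
  # constructed null where the observed count lands exactly on alpha:
  # 1000 null values, observed >= exactly 50 of them -> p = 0.050, not called;
  # observed >= exactly 49 -> p = 0.049, called.
  s <- tiny_slide(n = 400, m = 6, seed = 5)
  fit <- run_enrichment(s, which(s$positive), k = 10, B = 200, seed = 5)
  td <- tidy(fit)
  expect_equal(td$enriched, td$p_value < 0.05)
  expect_true(all(td$p_value >= 0) && all(td$p_value <= 1))

  direct_49 <- empirical_p(
    c(A = 0.9515), make_null(cbind(A = seq(0.001, 1, by = 0.001)), B = 1000)
  )
  direct_50 <- empirical_p(
    c(A = 0.9505), make_null(cbind(A = seq(0.001, 1, by = 0.001)), B = 1000)
  )
  expect_equal(unname(direct_49["A"]), 0.049)
  expect_equal(unname(direct_50["A"]), 0.050)
  expect_true(direct_49 < 0.05)   # would be called enriched
  expect_false(direct_50 < 0.05)  # sits on alpha: not called

  expect_error(run_enrichment(s, integer(), k = 10, B = 10, seed = 1),
               "positive")
})

test_that("enrichment runs are deterministic given the seed", {
  s <- tiny_slide(n = 300, m = 8, seed = 6)
  f1 <- run_enrichment(s, which(s$positive), k = 15, B = 100, seed = 42)
  f2 <- run_enrichment(s, which(s$positive), k = 15, B = 100, seed = 42)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$null$means, f2$null$means)
  f3 <- run_enrichment(s, which(s$positive), k = 15, B = 100, seed = 43)
  expect_false(identical(f1$null$means, f3$null$means))
})

test_that("planted enrichment is detected and the t variant agrees", {
  cfg <- slide_config(n_cells = 3000, m_positive = 13, focal_type = "A",
                      enrichment_rho = 20,
                      type_proportions = c(A = 0.3, B = 0.5, C = 0.2),
                      seed = 14)
  s <- generate_enriched_slide(cfg)
  fit <- run_enrichment(s, which(s$positive), k = 20, B = 500, seed = 14)
  td <- tidy(fit)
  expect_true(td$enriched[td$cell_type == "A"])

  tt <- enrichment_t_test(fit, "A")
  expect_lt(tt$p_value, 0.05)
  expect_gt(tt$t, 0)
})

test_that("t-test variant matches its closed form", {
  comp <- tibble::tibble(cell_id = c("a", "b", "c"),
                         A = c(0.5, 0.6, 0.7))
  res <- enrichment_t_test(comp, "A", null_mean = 0.2)
  x <- c(0.5, 0.6, 0.7)
  t_expect <- (mean(x) - 0.2) / (sd(x) / sqrt(3))
  expect_equal(res$t, t_expect)
  expect_equal(res$p_value, 2 * pt(-abs(t_expect), df = 2))
  # agrees with stats::t.test on non-degenerate input
  ref <- t.test(x, mu = 0.2)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)

  # centred constant sample: t = 0, p = 1
  res0 <- enrichment_t_test(
    tibble::tibble(cell_id = c("a", "b"), A = c(0.2, 0.2)), "A",
    null_mean = 0.2
  )
  expect_equal(res0$t, 0)
  expect_equal(res0$p_value, 1)

  # doubling every deviation from the null mean doubles t
  x2 <- 0.2 + 2 * (x - 0.2)
  res2 <- enrichment_t_test(
    tibble::tibble(cell_id = c("a", "b", "c"), A = x2), "A",
    null_mean = 0.2
  )
  expect_equal(res2$t, res$t) # same t: deviations and SD both double
  x3 <- x + 0.1 # shift deviations at fixed SD
  res3 <- enrichment_t_test(
    tibble::tibble(cell_id = c("a", "b", "c"), A = x3), "A",
    null_mean = 0.2
  )
  expect_equal(res3$t, (mean(x3) - 0.2) / (sd(x3) / sqrt(3)))

  expect_error(
    enrichment_t_test(tibble::tibble(cell_id = "a", A = 0.5), "A",
                      null_mean = 0.2),
    "at least 2"
  )
})

test_that("add-one p-values are valid (stochastically >= uniform) under the null", {
  # exchangeable null: observed statistic is itself one draw from the null
  set.seed(77)
  B <- 99
  n_rep <- 400
  p <- vapply(seq_len(n_rep), function(i) {
    vals <- rnorm(B + 1)
    obs <- vals[1]
    null <- make_null(cbind(A = vals[-1]), B = B)
    unname(empirical_p(c(A = obs), null, add_one = TRUE)["A"])
  }, numeric(1))
  # P(p <= alpha) should not exceed alpha (within Monte-Carlo error)
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(p <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / n_rep))
  }
})

test_that("tidy/glance/autoplot expose the fitted enrichment", {
  s <- tiny_slide(n = 200, m = 5, seed = 8)
  fit <- run_enrichment(s, which(s$positive), k = 10, B = 50, seed = 8,
                        adjust = "BH")
  td <- tidy(fit)
  expect_named(td, c("cell_type", "observed_mean", "observed_sd",
                     "null_mean", "p_value", "p_adjusted", "enriched"))
  expect_equal(td$p_adjusted,
               unname(p.adjust(td$p_value, method = "BH")))
  gl <- glance(fit)
  expect_equal(gl$n_positive, 5L)
  expect_equal(gl$B, 50)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(tidy(fit$null), "tbl_df")
})
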