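test_that("observed overlap fraction counts each query interval once", {
  expect_equal(
    observed_overlap_fraction(worked_example_peaks(), worked_example_targets()),
    0.2
  )
  withr::with_seed(3, q <- random_intervals(30))
  expect_equal(observed_overlap_fraction(q, q), 1)
  # a query hitting several targets still counts once
  q1 <- tibble::tibble(chrom = "chrI", start = 0L, end = 100L)
  t3 <- tibble::tibble(chrom = "chrI", start = c(0L, 20L, 40L), end = c(10L, 30L, 50L))
  expect_equal(observed_overlap_fraction(q1, t3), 1)
  expect_error(observed_overlap_fraction(q[0, ], q), "non-empty")
})

test_that("observed overlap fraction matches brute force on random instances", {
  withr::with_seed(41, {
    for (i in 1:10) {
      q <- random_intervals(100)
      t <- random_intervals(100)
      expect_identical(
        observed_overlap_fraction(q, t),
        brute_overlap_fraction(q, t)
      )
    }
  })
})

test_that("null sampling is seeded, exact at k = |universe|, and unbiased", {
  withr::with_seed(2, {
    genes <- random_genes(40)
    peaks <- random_intervals(25)
  })
  full <- sample_null(peaks, genes, k = 40, n_perm = 20, seed = 8)
  expect_identical(length(unique(full$fractions)), 1L)
  expect_equal(full$fractions[1], observed_overlap_fraction(peaks, genes))

  a <- sample_null(peaks, genes, k = 10, n_perm = 50, seed = 99)
  b <- sample_null(peaks, genes, k = 10, n_perm = 50, seed = 99)
  expect_identical(a$fractions, b$fractions)

  expect_error(sample_null(peaks, genes, k = 41, n_perm = 5), "universe size")

  # analytic oracle: P(peak i hits >= 1 of k sampled genes) is
  # hypergeometric in the number m_i of universe genes the peak overlaps
  k <- 8
  nd <- sample_null(peaks, genes, k = k, n_perm = 2000, seed = 5)
  m <- vapply(seq_len(nrow(peaks)), function(i) {
    sum(brute_overlaps_any(genes, peaks[i, ]))
  }, numeric(1))
  expected <- mean(1 - choose(40 - m, k) / choose(40, k))
  se <- stats::sd(nd$fractions) / sqrt(nd$n_perm)
  expect_lt(abs(mean(nd$fractions) - expected), 3 * se + 1e-12)
})

test_that("permutation p-value follows the add-one rule with ties as exceedances", {
  null <- structure(
    list(fractions = seq(0, 0.999, length.out = 1000), n_perm = 1000L,
      k = 5L, seed = 1L),
    class = "null_dist"
  )
  res_hi <- permutation_test(1.0, null, tail = "greater")
  expect_equal(res_hi$p_value, 1 / 1001)
  res_lo <- permutation_test(-0.1, null, tail = "greater")
  expect_equal(res_lo$p_value, 1)
  # a tie counts toward the exceedance count
  res_tie <- permutation_test(null$fractions[1000], null, tail = "greater")
  expect_equal(res_tie$n_exceed, 1L)
  # monotone non-increasing in the observed fraction
  obs <- seq(0, 1, by = 0.05)
  ps <- vapply(obs, function(o) permutation_test(o, null)$p_value, numeric(1))
  expect_true(all(diff(ps) <= 0))
  # without the add-one correction the raw proportion is reported
  expect_equal(permutation_test(1.0, null, add_one = FALSE)$p_value, 0)
})

test_that("p-value confidence interval is the shifted exact binomial interval", {
  withr::with_seed(6, fr <- runif(1000))
  null <- structure(list(fractions = fr, n_perm = 1000L, k = 5L, seed = 1L),
    class = "null_dist")
  observed <- sort(fr, decreasing = TRUE)[250] # r = 250 of 1000
  res <- permutation_test(observed, null, ci_level = 0.99)
  expect_identical(res$n_exceed, 250L)
  cp <- clopper_pearson(250, 1000, 0.99)
  expect_equal(res$ci_low, (cp[1] * 1000 + 1) / 1001, tolerance = 1e-10)
  expect_equal(res$ci_high, (cp[2] * 1000 + 1) / 1001, tolerance = 1e-10)
  expect_true(res$ci_low <= res$p_value && res$p_value <= res$ci_high)
  # null summary uses the sample moments of the fractions
  expect_equal(res$null_mean, mean(fr))
  expect_equal(res$null_sd, stats::sd(fr))
})

test_that("enrich of the whole universe against itself is null by construction", {
  withr::with_seed(12, {
    genes <- random_genes(30)
    peaks <- random_intervals(20)
  })
  res <- enrich(peaks, genes, genes, n_perm = 100, seed = 3)
  expect_equal(res$p_value, 1)
  expect_equal(res$observed_fraction, res$null_mean)
  expect_error(
    enrich(peaks, genes, dplyr::mutate(genes, gene_id = paste0("x", gene_id))),
    "universe"
  )
})

test_that("Monte-Carlo null matches exhaustive subset enumeration on a tiny universe", {
  withr::with_seed(19, {
    genes <- random_genes(8, chroms = "chrA", max_pos = 2000)
    peaks <- random_intervals(12, chroms = "chrA", max_pos = 2000)
  })
  k <- 3
  combos <- utils::combn(8, k)
  exact <- apply(combos, 2, function(idx) {
    brute_overlap_fraction(peaks, genes[idx, ])
  })
  observed <- stats::median(exact)
  p_exact <- mean(exact >= observed)
  nd <- sample_null(peaks, genes, k = k, n_perm = 4000, seed = 21)
  p_mc <- mean(nd$fractions >= observed)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(p_mc - p_exact), 4 * se)
})

test_that("the full enrichment pipeline is deterministic given the seed", {
  cfg <- synthetic_config(n_genes = 120, n_peaks = 40,
    enrichment_theta = 0.5, seed = 14)
  ann <- generate_annotation(cfg)
  pk <- generate_peaks(ann$genes, ann$truth, cfg)
  top <- top_fraction_genes(ann$genes, 0.1)
  r1 <- enrich(pk$peaks, ann$genes, top, n_perm = 150, seed = 77)
  r2 <- enrich(pk$peaks, ann$genes, top, n_perm = 150, seed = 77)
  expect_identical(r1$null_fractions, r2$null_fractions)
  expect_identical(tidy(r1), tidy(r2))
  expect_true(r1$p_value >= 1 / 151 && r1$p_value <= 1)
})

test_that("tidy, glance and autoplot expose the enrichment result", {
  withr::with_seed(25, {
    genes <- random_genes(50)
    peaks <- random_intervals(20)
  })
  top <- top_fraction_genes(genes, 0.2)
  res <- enrich(peaks, genes, top, n_perm = 100, seed = 1)
  td <- tidy(res)
  expect_identical(nrow(td), 1L)
  expect_named(td, c("observed_fraction", "null_mean", "null_sd",
    "p_value", "ci_low", "ci_high"))
  gl <- glance(res)
  expect_identical(gl$n_perm, 100L)
  expect_s3_class(autoplot(res), "ggplot")
  tf <- withr::local_tempfile(fileext = ".json")
  write_enrich_json(res, tf)
  parsed <- jsonlite::read_json(tf)
  expect_equal(parsed$p_value, res$p_value)
})
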