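test_that("ChIP percent enrichment matches the closed form", {
  expect_equal(chip_percent_enrichment(20, 20, dilution = 1), 100)
  # IP indistinguishable from mock cancels exactly
  expect_equal(chip_percent_enrichment(18, 24, ct_mock = 24, dilution = 7), 0)
  # frozen closed-form value: 100*2^(20-24-log2(10)) - 100*2^(20-28-log2(10))
  # = 100*(2^-4 - 2^-8)/10 = 0.5859375
  expect_equal(
    chip_percent_enrichment(20, 24, ct_mock = 28, dilution = 10),
    0.5859375,
    tolerance = 1e-12
  )
  expect_error(chip_percent_enrichment(Inf, 20), "finite")
  expect_error(chip_percent_enrichment(20, 20, dilution = 0), "positive")
})

test_that("ChIP percent enrichment is monotone in its Cts", {
  withr::with_seed(8, {
    ct_ip <- sort(runif(20, 18, 30))
    vals <- chip_percent_enrichment(20, ct_ip, dilution = 5)
    expect_true(all(diff(vals) < 0)) # strictly decreasing in ct_ip
    ct_in <- sort(runif(20, 15, 25))
    vals2 <- chip_percent_enrichment(ct_in, 26, dilution = 5)
    expect_true(all(diff(vals2) > 0)) # strictly increasing in ct_input
  })
})

test_that("DRIP fold enrichment matches the printed model", {
  expect_equal(drip_fold_enrichment(20, 20, dilution = 1), 1)
  expect_equal(drip_fold_enrichment(20, 19, dilution = 1), 2)
  # doubling the dilution while adding one input cycle is a no-op
  withr::with_seed(9, {
    ci <- runif(25, 15, 25)
    cd <- runif(25, 15, 25)
    d <- runif(25, 1, 50)
    expect_equal(
      drip_fold_enrichment(ci + 1, cd, dilution = 2 * d),
      drip_fold_enrichment(ci, cd, dilution = d),
      tolerance = 1e-12
    )
  })
})

test_that("2^-ddCt matches direct evaluation", {
  expect_equal(ddct_fold(20, 20, 20, 20), 1)
  expect_equal(ddct_fold(21, 20, 22, 20), 2)
  withr::with_seed(10, {
    for (i in 1:25) {
      cts <- runif(4, 15, 32)
      expect_equal(
        ddct_fold(cts[1], cts[2], cts[3], cts[4]),
        2^(-((cts[1] - cts[2]) - (cts[3] - cts[4]))),
        tolerance = 1e-12
      )
      # identical target/reference pairs always give 1
      expect_equal(ddct_fold(cts[1], cts[2], cts[1], cts[2]), 1)
    }
  })
})

test_that("mock correction subtracts per sample/locus and flags background", {
  raw <- tibble::tibble(sample = "S1", locus = "ADH1-2",
    kind = "fold_over_input", value = 4)
  mock0 <- tibble::tibble(sample = "S1", locus = "ADH1-2",
    kind = "fold_over_input", value = 0)
  expect_equal(mock_corrected_drip(raw, mock0)$value, 4)
  same <- mock_corrected_drip(raw, raw)
  expect_equal(same$value, 0)
  expect_identical(same$flags, "below_background")
  wrong <- tibble::tibble(sample = "S2", locus = "ADH1-2",
    kind = "fold_over_input", value = 1)
  expect_error(mock_corrected_drip(raw, wrong), "mismatch")
  withr::with_seed(30, {
    v <- runif(10, 0, 5)
    m <- runif(10, 0, 5)
    for (i in 1:10) {
      r <- tibble::tibble(sample = "S", locus = "L", kind = "fold_over_input",
        value = v[i])
      k <- tibble::tibble(sample = "S", locus = "L", kind = "fold_over_input",
        value = m[i])
      expect_equal(mock_corrected_drip(r, k)$value, v[i] - m[i])
    }
  })
})

test_that("relative normalization divides per locus by the reference sample", {
  res <- tibble::tibble(
    sample = rep(c("WT", "mut"), each = 2),
    locus = rep(c("L1", "L2"), 2),
    kind = "percent_enrichment",
    value = c(2, 5, 4, 5),
    sd = c(0.2, 0.5, 0.4, 0.5)
  )
  out <- relative_normalize(res, "WT")
  expect_equal(out$value, c(1, 1, 2, 1))
  expect_equal(out$sd, c(0.1, 0.1, 0.2, 0.1))
  expect_true(all(out$kind == "relative_fold"))
  bad <- dplyr::mutate(res, value = dplyr::if_else(sample == "WT" & locus == "L2",
    0, value))
  expect_error(relative_normalize(bad, "WT"), "L2")
  expect_error(relative_normalize(res, "nope"), "no positive value")
})

test_that("linear-range dilution selection picks the in-window Ct", {
  rec <- tibble::tibble(
    sample = "S1", locus = "L1", role = "drip",
    dilution = c(1, 10, 100), ct = c(12, 22, 35), replicate = 1L
  )
  sel <- select_linear_dilution(rec, ct_window = c(15, 32))
  expect_equal(sel$dilution, 10)
  expect_identical(sel$flags, "")

  single <- rec[2, ]
  expect_equal(select_linear_dilution(single)$ct, 22)

  outside <- dplyr::mutate(rec, ct = c(5, 10, 40))
  sel2 <- select_linear_dilution(outside)
  expect_equal(sel2$ct, 10) # nearest to the window
  expect_identical(sel2$flags, "out_of_range")

  expect_error(select_linear_dilution(rec[0, ]), "non-empty")
  expect_error(select_linear_dilution(rec, ct_window = c(30, 15)), "increasing")
})

test_that("noiseless simulated tables invert exactly for every mode", {
  for (f in c(1, 2, 8)) {
    cfg <- synthetic_config(ct_noise_sd = 0, true_folds = c(LOC = f), seed = 2)
    drip <- quantify_qpcr(simulate_ct("drip", cfg), mode = "drip")
    expect_equal(drip$value, f, tolerance = 1e-12)
    chip <- quantify_qpcr(simulate_ct("chip", cfg), mode = "chip")
    expect_equal(chip$value, f, tolerance = 1e-12)
    expect_equal(chip$kind, "percent_enrichment")
    dd <- quantify_qpcr(simulate_ct("ddct", cfg), mode = "ddct",
      reference_sample = "control")
    expect_equal(dd$value[dd$sample == "treated"], f, tolerance = 1e-12)
    expect_equal(dd$value[dd$sample == "control"], 1, tolerance = 1e-12)
  }
})

test_that("replicate handling supports Ct- and value-level averaging", {
  rec <- tibble::tibble(
    sample = "S1", locus = "L1",
    role = rep(c("input", "drip"), each = 3),
    dilution = 1,
    ct = c(20, 20, 20, 19, 18, 20),
    replicate = rep(1:3, 2)
  )
  by_ct <- quantify_qpcr(rec, mode = "drip", average = "ct")
  expect_equal(by_ct$value, 2^(20 - mean(c(19, 18, 20))))
  by_val <- quantify_qpcr(rec, mode = "drip", average = "value")
  per_rep <- 2^(20 - c(19, 18, 20))
  expect_equal(by_val$value, mean(per_rep))
  expect_equal(by_val$sd, stats::sd(per_rep))
  expect_equal(by_ct$sd, stats::sd(per_rep))
})

test_that("quantify_qpcr flags below-background mock-subtracted values", {
  rec <- tibble::tibble(
    sample = "S1", locus = "L1",
    role = c("input", "ip", "mock"),
    dilution = 1, ct = c(20, 26, 24), replicate = 1L
  )
  out <- quantify_qpcr(rec, mode = "chip")
  expect_lt(out$value, 0)
  expect_identical(out$flags, "below_background")
  expect_error(quantify_qpcr(rec[-1, ], mode = "chip"), "missing role 'input'")
})

test_that("Ct tables round-trip through TSV and validate roles", {
  cfg <- synthetic_config(seed = 44)
  ct <- simulate_ct("chip", cfg)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(ct, tf)
  expect_identical(read_ct_table(tf), tibble::as_tibble(ct))
  bad <- dplyr::mutate(ct, role = "antibody")
  write_ct_table(bad, tf)
  expect_error(read_ct_table(tf), "Unknown Ct role")
})
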