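test_that("Bliss expectation follows the closed form and its identities", {
  expect_equal(bliss_expected(0, 0.3), 0.3)
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  expect_equal(bliss_expected(1, 0.42), 1)
  expect_equal(bliss_expected(0.2, 0.7), bliss_expected(0.7, 0.2))
  expect_error(bliss_expected(1.2, 0.1), class = "g4quant_error")
  expect_error(bliss_expected(0.5, -0.3), class = "g4quant_error")
})

test_that("an exactly multiplicative viability matrix scores zero everywhere", {
  va <- c(100, 90, 60, 30)
  vb <- c(100, 80, 50)
  grid <- tidyr::expand_grid(ia = seq_along(va), ib = seq_along(vb))
  tbl <- tibble::tibble(
    dose_a = grid$ia - 1, dose_b = grid$ib - 1,
    viability_pct = va[grid$ia] * vb[grid$ib] / 100
  )
  m <- bliss_score_matrix(tbl)
  expect_true(all(abs(m$scores$score) < 1e-9))
  expect_equal(m$mean_score, 0, tolerance = 1e-9)
  expect_equal(m$n_synergistic, 0L)
})

test_that("scores are bounded and the matrix is label-symmetric", {
  withr::with_seed(66, {
    tbl <- simulate_synergy_matrix(list(ic50 = 20), list(ic50 = 30),
                                   planted_excess = 12, noise_cv = 0.15,
                                   replicates = 3, seed = 8)
    m <- bliss_score_matrix(tbl)
    expect_true(all(m$scores$score >= -100 & m$scores$score <= 100))
    swapped <- dplyr::rename(tbl, dose_a = dose_b, dose_b = dose_a,
                             unit_a = unit_b, unit_b = unit_a)
    m2 <- bliss_score_matrix(swapped)
    expect_equal(sort(m2$scores$score), sort(m$scores$score), tolerance = 1e-12)
    expect_equal(m2$mean_score, m$mean_score, tolerance = 1e-12)
  })
})

test_that("missing monotherapy margins are rejected", {
  tbl <- simulate_synergy_matrix(seed = 1)
  expect_error(bliss_score_matrix(dplyr::filter(tbl, dose_a > 0)),
               class = "g4quant_error")
  expect_error(bliss_score_matrix(dplyr::select(tbl, -viability_pct)),
               class = "g4quant_schema_error")
})

test_that("planted excess is recovered and the >10 threshold drives the synergy call", {
  safe_a <- list(ic50 = 40, hill = 1)
  safe_b <- list(ic50 = 50, hill = 1)
  noise_free <- bliss_score_matrix(simulate_synergy_matrix(
    safe_a, safe_b, planted_excess = 20, noise_cv = 0, replicates = 1, seed = 2))
  expect_equal(noise_free$scores$score, rep(20, nrow(noise_free$scores)),
               tolerance = 1e-9)
  expect_equal(noise_free$n_synergistic, nrow(noise_free$scores))

  antag <- bliss_score_matrix(simulate_synergy_matrix(
    safe_a, safe_b, planted_excess = -5, noise_cv = 0, replicates = 1, seed = 2))
  expect_equal(antag$n_synergistic, 0L)

  # under noise the 100%-viability cap biases near-zero-effect margins, so
  # the planted excess is recovered against an identically simulated null:
  # the planted-minus-null difference is the unbiased estimand
  withr::with_seed(77, {
    diffs <- vapply(1:20, function(i) {
      m20 <- bliss_score_matrix(simulate_synergy_matrix(
        safe_a, safe_b, planted_excess = 20, noise_cv = 0.10,
        replicates = 3, seed = sample.int(1e6, 1)))$mean_score
      m0 <- bliss_score_matrix(simulate_synergy_matrix(
        safe_a, safe_b, planted_excess = 0, noise_cv = 0.10,
        replicates = 3, seed = sample.int(1e6, 1)))$mean_score
      m20 - m0
    }, numeric(1))
    mc_se <- stats::sd(diffs) / sqrt(length(diffs))
    expect_lt(abs(mean(diffs) - 20), 2 * mc_se + 1e-9)
  })
})

test_that("additional lethality is the clipped complement of viability", {
  expect_equal(additional_lethality(100), 0, ignore_attr = TRUE)
  expect_equal(additional_lethality(40), 60, ignore_attr = TRUE)
  v <- c(110, 100, 40, 0)
  al <- additional_lethality(v)
  expect_equal(as.numeric(al), c(0, 0, 60, 100))
  expect_equal(attr(al, "n_clipped"), 1L)
  tbl <- simulate_synergy_matrix(seed = 3, replicates = 2)
  tbl$lethality <- as.numeric(additional_lethality(tbl$viability_pct))
  expect_equal(nrow(tbl), nrow(simulate_synergy_matrix(seed = 3, replicates = 2)))
})

test_that("foci additive comparison reproduces the worked fold examples", {
  mia <- foci_additive_comparison(52.0, 2.5, 22.0)
  expect_equal(mia$additive_expectation, 24.5)
  expect_equal(mia$fold_beyond_additive, 52.0 / 24.5, tolerance = 1e-12)
  expect_equal(mia$classification, "beyond additive")

  hela <- foci_additive_comparison(49.8, 2.3, 13.0)
  expect_equal(hela$fold_beyond_additive, 49.8 / 15.3, tolerance = 1e-12)

  additive <- foci_additive_comparison(10, 4, 6)
  expect_equal(additive$fold_beyond_additive, 1)
  expect_equal(additive$classification, "additive or less")

  expect_warning(neg <- foci_additive_comparison(5, -2, 1), "undefined")
  expect_true(is.na(neg$fold_beyond_additive))
})

test_that("synergy reports are deterministic and summarise the threshold counts", {
  # planted excess of 15: clear of both the 10-point call threshold and the
  # 20-point summary count, so no floating-point ties
  m <- bliss_score_matrix(simulate_synergy_matrix(
    list(ic50 = 40), list(ic50 = 50), planted_excess = 15, noise_cv = 0,
    replicates = 1, seed = 4))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- synergy_report(m, out_dir = d1, provenance = list(seed = 4))
  p2 <- synergy_report(m, out_dir = d2, provenance = list(seed = 4))
  expect_identical(readLines(p1[["json"]]), readLines(p2[["json"]]))
  expect_identical(readLines(p1[["csv"]]), readLines(p2[["csv"]]))
  js <- jsonlite::read_json(p1[["json"]])
  expect_equal(js$n_score_over_10, nrow(m$scores)) # 8 x 7 grid, all at +15
  expect_equal(js$n_score_over_20, 0L)
  expect_equal(js$mean_score, 15, tolerance = 1e-9)

  null_m <- bliss_score_matrix(simulate_synergy_matrix(
    list(ic50 = 40), list(ic50 = 50), planted_excess = 0, noise_cv = 0,
    replicates = 1, seed = 4))
  d3 <- withr::local_tempdir()
  p3 <- synergy_report(null_m, out_dir = d3)
  js0 <- jsonlite::read_json(p3[["json"]])
  expect_equal(js0$n_score_over_10, 0L)
  expect_equal(js0$n_score_over_20, 0L)
  gl <- glance(m)
  expect_equal(gl$n_pairs, 56L)
  expect_s3_class(autoplot(m), "ggplot")
})
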