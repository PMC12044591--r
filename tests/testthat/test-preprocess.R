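# Baseline correction, SNV, temperature offset, TG alignment, Gram-Schmidt,
# and the full pipeline (including the mask-exclusion property).

test_that("asPLS baseline handles flat, zero, and peak-on-ramp spectra", {
  g <- wavenumber_grid(seq(800, 4000, by = 4))
  mask <- build_mask(g)
  x <- as.numeric(g)

  flat <- toy_spectrum(rep(0.3, length(x)), grid = g, mask = mask)
  out <- baseline_correct(flat)
  expect_lt(max(abs(out$absorbance[mask])), 1e-6)

  zero <- toy_spectrum(rep(0, length(x)), grid = g, mask = mask)
  expect_equal(baseline_correct(zero)$absorbance, rep(0, length(x)))

  # single Gaussian on a linear ramp: peak height preserved within 2%
  peak <- 0.8 * exp(-(x - 1500)^2 / (2 * 15^2))
  ramp <- 0.1 + 1e-4 * (x - 800)
  s <- toy_spectrum(peak + ramp, grid = g, mask = mask)
  corr <- baseline_correct(s)$absorbance
  expect_lt(abs(max(corr[mask]) - 0.8) / 0.8, 0.02)

  expect_error(
    baseline_correct(toy_spectrum(1:20, grid = toy_grid(20),
                                  mask = c(rep(TRUE, 5), rep(FALSE, 15)))),
    ">= 10 unmasked")
})

test_that("snv matches the population-SD formula and is idempotent", {
  s <- toy_spectrum(c(1, 2, 3))
  out <- snv(s)
  expect_equal(out$absorbance, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(snv(out)$absorbance, out$absorbance, tolerance = 1e-12)
  expect_error(snv(toy_spectrum(c(5, 5, 5))), "zero variance")
  # masked points are excluded and zeroed
  m <- c(TRUE, TRUE, TRUE, FALSE)
  v <- snv(c(1, 2, 3, 99), mask = m)
  expect_equal(v[1:3], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_identical(v[4], 0)
})

test_that("temperature offset equals dwell x rate / 60", {
  g <- toy_grid(5)
  run <- tga_run(c(200, 300), NULL, matrix(1:10, 2, 5), g)
  out <- apply_temperature_offset(run, preprocess_config())
  expect_equal(run$temperatures - out$temperatures, rep(2.5 * 10 / 60, 2),
               tolerance = 1e-12)
  expect_equal(out$metadata$temperature_offset_c, 0.41666667, tolerance = 1e-6)

  ident <- apply_temperature_offset(run, preprocess_config(dwell_time_s = 0))
  expect_identical(ident$temperatures, run$temperatures)

  big <- apply_temperature_offset(
    run, preprocess_config(dwell_time_s = 60, heating_rate = 60))
  expect_equal(run$temperatures - big$temperatures, rep(60, 2))
})

test_that("TG alignment interpolates and recomputes DTG", {
  g <- toy_grid(5)
  # linear TG 100 -> 90 over 200 -> 300 C, spectrum at 250 C
  run <- tga_run(c(225, 250, 275), NULL, matrix(0, 3, 5), g,
                 metadata = list(tg_table = data.frame(
                   temperature = c(200, 300), tg = c(100, 90))))
  out <- align_tg_to_spectra(run)
  expect_equal(out$tg[2], 95)
  expect_equal(out$dtg, rep(0.1, 3), tolerance = 1e-9)

  # constant TG -> all-zero DTG
  runc <- tga_run(c(225, 250, 275), NULL, matrix(0, 3, 5), g,
                  metadata = list(tg_table = data.frame(
                    temperature = c(200, 300), tg = c(95, 95))))
  expect_equal(align_tg_to_spectra(runc)$dtg, rep(0, 3))

  # quadratic TG -> DTG matches the analytic derivative
  tt <- seq(200, 400, by = 5)
  tg <- 100 - 0.0005 * (tt - 200)^2
  spec_t <- seq(220, 380, by = 5)
  runq <- tga_run(spec_t, NULL, matrix(0, length(spec_t), 5), g,
                  metadata = list(tg_table = data.frame(temperature = tt, tg = tg)))
  outq <- align_tg_to_spectra(runq)
  analytic <- 0.001 * (spec_t - 200)
  inner <- 7:(length(spec_t) - 6)   # away from one-sided-difference edges
  expect_lt(max(abs(outq$dtg[inner] - analytic[inner])), 1e-9)
  expect_lt(max(abs(outq$dtg - analytic)), 3e-3)

  # coverage gap names the missing interval
  expect_error(
    align_tg_to_spectra(tga_run(c(150, 250), NULL, matrix(0, 2, 5), g,
                                metadata = list(tg_table = data.frame(
                                  temperature = c(200, 300), tg = c(100, 90))))),
    "missing interval \\[150")
})

test_that("gram_schmidt trace is a root-sum-square over unmasked points", {
  g <- toy_grid(10)
  mask <- rep(c(TRUE, FALSE), 5)
  v <- c(3, 100, 4, 100, 0, 100, 0, 100, 0, 100)
  run <- tga_run(c(200, 300), NULL, rbind(v, 2 * v), g, mask = mask)
  tr <- unname(gram_schmidt_trace(run))
  expect_equal(tr[1], 5)          # sqrt(3^2 + 4^2), masked 100s ignored
  expect_equal(tr[2], 10)         # homogeneity: doubling doubles
  zero <- tga_run(200, NULL, matrix(0, 1, 10), g, mask = mask)
  expect_equal(gram_schmidt_trace(zero), 0)
})

test_that("preprocess_run keeps ~250 spectra in the analysis window", {
  arch <- default_archetypes()$PE
  raw <- make_fixture_run(arch, temp_step = 2.4, seed = 9)
  run <- suppressWarnings(preprocess_run(raw))
  expect_gt(nrow(run$spectra), 235)
  expect_lt(nrow(run$spectra), 265)
  expect_true(all(run$temperatures >= 150 & run$temperatures <= 750))
  expect_true(all(as.numeric(run$grid) >= 800 & as.numeric(run$grid) <= 4000))
  expect_true(all(diff(run$tg) <= 1e-6))
  expect_true(all(run$gram_schmidt >= 0))
  fixture_cache$pe_full <- run    # reused by the idempotence check below

  # a run with no spectra in the window errors
  empty <- tga_run(c(760, 800), NULL, matrix(rnorm(10), 2, 5),
                   toy_grid(5), metadata = list())
  expect_error(preprocess_run(empty), "no spectra inside")
})

test_that("preprocessing is idempotent apart from the baseline re-fit", {
  run <- fixture_cache$pe_full
  if (is.null(run)) {
    run <- suppressWarnings(preprocess_run(
      make_fixture_run(default_archetypes()$PE, temp_step = 2.4, seed = 9)))
  }
  again <- suppressWarnings(preprocess_run(run))
  expect_equal(again$temperatures, run$temperatures, tolerance = 1e-9)
  expect_equal(again$tg, run$tg, tolerance = 1e-9)
  expect_identical(again$mask, run$mask)
  # baseline re-fit on corrected spectra is a near no-op
  expect_lt(max(abs(again$spectra - run$spectra)),
            0.02 * max(abs(run$spectra)))
})

test_that("masked windows never contribute downstream", {
  w <- fixture_world()
  run <- w$runs$PS
  tampered <- run
  g <- as.numeric(run$grid)
  bad <- (g >= 2200 & g <= 2400) | (g >= 3150 & g <= 3500)
  withr::with_seed(2, {
    tampered$spectra[, bad] <- tampered$spectra[, bad] +
      matrix(rnorm(sum(bad) * nrow(run$spectra), 0, 5), ncol = sum(bad))
  })
  r1 <- match_run(run, w$library)
  r2 <- match_run(tampered, w$library)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$score_trace, r2$score_trace)

  # and Pearson is invariant to SNV (affine invariance)
  s1 <- run$spectra[10, ]; s2 <- run$spectra[11, ]
  expect_equal(pearson(s1, s2, run$mask),
               pearson(snv(s1, run$mask), snv(s2, run$mask), run$mask),
               tolerance = 1e-9)
})
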