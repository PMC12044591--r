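# Spectral matching: Pearson, temperature-penalised hit quality, iterative
# residual matching, run-level matching.

test_that("pearson matches the product-moment formula and validates input", {
  expect_equal(pearson(c(1, 2, 4), c(2, 3, 9)), 0.9799, tolerance = 1e-4)
  expect_equal(pearson(c(1, 2, 4), c(2, 3, 9)),
               cor(c(1, 2, 4), c(2, 3, 9)), tolerance = 1e-12)
  a <- rnorm(20)
  expect_equal(pearson(a, a), 1.0)
  expect_equal(pearson(a, -a), -1.0)
  expect_error(pearson(a, rep(1, 20)), "constant")
  expect_error(pearson(a[1:2], a[1:2]), ">= 3 unmasked")
  # mask restricts the computation
  b <- c(a[1:10], rnorm(10) * 100)
  expect_equal(pearson(a, b, mask = c(rep(TRUE, 10), rep(FALSE, 10))),
               cor(a[1:10], b[1:10]), tolerance = 1e-12)
})

test_that("hit quality combines r0/r1 and penalises temperature gaps", {
  w <- fixture_world()
  lm <- library_matrix(w$library)
  i <- which(lm$class == "PS")[3]
  s <- snv(ftir_spectrum(lm$spectra[i, ], lm$temperatures[i],
                         w$library$grid, w$library$mask))
  cfg <- sma_config()

  # identical spectra at identical temperature -> r_final = 1
  hq <- hit_quality(s, s, cfg)
  expect_equal(hq$r0, 1.0, tolerance = 1e-12)
  expect_equal(hq$r1, 1.0, tolerance = 1e-12)
  expect_equal(hq$r_final, 1.0, tolerance = 1e-12)

  # |dT| = penalty_sigma -> r_final = exp(-1/2)
  s2 <- s; s2$temperature <- s$temperature + cfg$penalty_sigma
  hq2 <- hit_quality(s2, s, cfg)
  expect_equal(hq2$r_final, exp(-0.5), tolerance = 1e-9)

  # penalty monotonicity in |dT|
  dts <- c(0, 5, 20, 50, 120, 300)
  rf <- vapply(dts, function(dt) {
    sd <- s; sd$temperature <- s$temperature + dt
    hit_quality(sd, s, cfg)$r_final
  }, numeric(1))
  expect_true(all(diff(rf) < 0))

  # linear penalty variant: max(0, r - k|dT|), identity at dT = 0
  lin <- sma_config(penalty = "linear", penalty_k = 0.002)
  expect_equal(hit_quality(s, s, lin)$r_final, 1.0, tolerance = 1e-12)
  s3 <- s; s3$temperature <- s$temperature + 100
  expect_equal(hit_quality(s3, s, lin)$r_final, 1 - 0.2, tolerance = 1e-9)
  s4 <- s; s4$temperature <- s$temperature + 1e5
  expect_equal(hit_quality(s4, s, lin)$r_final, 0)
})

test_that("PE/PP pair: raw correlation high, derivative correlation lower", {
  w <- fixture_world()
  lm <- library_matrix(w$library)
  peak_of <- function(cl) {
    i <- which(lm$class == cl)
    i[which.max(rowSums(abs(lm$spectra[i, w$library$mask, drop = FALSE])))]
  }
  mk <- function(i) snv(ftir_spectrum(lm$spectra[i, ], lm$temperatures[i],
                                      w$library$grid, w$library$mask))
  hq <- hit_quality(mk(peak_of("PE")), mk(peak_of("PP")))
  expect_gt(hq$r0, 0.9)
  expect_lt(hq$r1, hq$r0)
  expect_lt(hq$r_final, 0.7)   # distinguishable despite raw confusability
})

test_that("match_spectrum: self match, two-component recovery, noise rejection", {
  w <- fixture_world()
  lib <- w$library
  lm <- library_matrix(lib)

  # a spectrum equal to a library entry -> exactly that label, r_final = 1
  i <- which(lm$class == "PMMA")[4]
  s <- ftir_spectrum(lm$spectra[i, ], lm$temperatures[i], lib$grid, lib$mask)
  res <- match_spectrum(s, lib)
  expect_identical(res$labels, "PMMA")
  expect_equal(res$trace$r_final[1], 1.0, tolerance = 1e-9)
  expect_lt(res$trace$residual_norm[1] / sqrt(sum(lib$mask)), 0.35)

  # constructed two-component mixture of spectrally distinct classes with
  # overlapping decomposition windows -> both labels, residual shrinking
  peak_of <- function(cl) {
    i <- which(lm$class == cl)
    i[which.max(rowSums(abs(lm$spectra[i, lib$mask, drop = FALSE])))]
  }
  ia <- peak_of("PP"); ib <- peak_of("PET")
  mixv <- 0.6 * lm$spectra[ia, ] + 0.4 * lm$spectra[ib, ]
  smix <- ftir_spectrum(mixv, mean(lm$temperatures[c(ia, ib)]), lib$grid, lib$mask)
  resm <- match_spectrum(smix, lib)
  expect_setequal(resm$labels, c("PP", "PET"))
  expect_true(all(diff(resm$trace$residual_norm) < 0))

  # white noise never clears the threshold (100 seeded draws)
  withr::with_seed(31, {
    hits <- vapply(1:100, function(i) {
      noise <- ftir_spectrum(rnorm(length(lib$grid)), 400, lib$grid, lib$mask)
      length(match_spectrum(noise, lib)$labels)
    }, numeric(1))
  })
  expect_identical(sum(hits), 0)

  expect_error(match_spectrum(s, spectral_library(list(), lib$grid)),
               "empty library")
})

test_that("match results are invariant to positive scaling of the spectrum", {
  w <- fixture_world()
  lm <- library_matrix(w$library)
  i <- which(lm$class == "PVC")[2]
  s1 <- ftir_spectrum(lm$spectra[i, ], lm$temperatures[i],
                      w$library$grid, w$library$mask)
  s2 <- ftir_spectrum(37.5 * lm$spectra[i, ], lm$temperatures[i],
                      w$library$grid, w$library$mask)
  r1 <- match_spectrum(s1, w$library)
  r2 <- match_spectrum(s2, w$library)
  expect_identical(r1$labels, r2$labels)
  expect_equal(r1$class_scores, r2$class_scores, tolerance = 1e-9)
})

test_that("match_run recovers run-level labels", {
  w <- fixture_world()
  res <- match_run(w$runs$PMMA, w$library)
  expect_identical(res$labels, "PMMA")
  expect_identical(dim(res$score_trace),
                   c(nrow(w$runs$PMMA$spectra), 11L))

  blank <- match_run(w$runs$BLANK, w$library)
  expect_length(blank$labels, 0)

  mix <- make_mixture(w$runs[c("PS", "PA", "PTFE")], c(0.4, 0.35, 0.25),
                      randomize_absorbance = TRUE, seed = 5)
  resm <- match_run(mix, w$library)
  expect_setequal(resm$labels, c("PS", "PA", "PTFE"))
})
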