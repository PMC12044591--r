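# Domain types, run/library IO, correlation matrix.

test_that("wavenumber grid enforces monotonicity and range", {
  expect_s3_class(wavenumber_grid(c(800, 804, 808)), "wavenumber_grid")
  expect_error(wavenumber_grid(c(800, 800, 804)), "strictly increasing")
  expect_error(wavenumber_grid(c(804, 800)), "strictly increasing")
  expect_error(wavenumber_grid(c(300, 800)), "\\[400, 4500\\]")
  expect_error(wavenumber_grid(c(800, 5000)), "\\[400, 4500\\]")
})

test_that("spectrum and run constructors validate alignment", {
  g <- toy_grid(5)
  expect_error(ftir_spectrum(1:4, 300, g), "does not match grid")
  s <- ftir_spectrum(1:5, 300, g)
  expect_length(s$mask, 5)
  expect_true(all(s$mask))
  expect_error(tga_run(c(300, 200), NULL, matrix(0, 2, 5), g), "ascending")
  expect_error(tga_run(c(200, 300), NULL, matrix(0, 3, 5), g), "rows")
  run <- tga_run(c(200, 300), c(100, 90), matrix(rnorm(10), 2, 5), g)
  expect_identical(get_spectrum(run, 2)$temperature, 300)
})

test_that("csv_matrix round trip is lossless and validates input", {
  withr::local_seed(11)
  g <- toy_grid(5)
  run <- tga_run(c(200, 250, 300), c(100, 95, 90),
                 matrix(runif(15), 3, 5), g,
                 metadata = list(sample_id = "toy"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_run(run, path)
  back <- read_run(path)
  expect_equal(nrow(back$spectra), 3)
  expect_length(back$grid, 5)
  expect_lt(max(abs(back$spectra - run$spectra)), 1e-9)
  expect_lt(max(abs(back$temperatures - run$temperatures)), 1e-9)
  expect_lt(max(abs(back$metadata$tg_table$tg - run$tg)), 1e-9)

  # duplicate wavenumber row -> validation error
  tab <- read.csv(path, check.names = FALSE, colClasses = "character")
  tab[[1]][2] <- tab[[1]][1]
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, bad, row.names = FALSE, quote = FALSE)
  expect_error(read_run(bad), "strictly increasing")

  # malformed header -> parse error naming the column
  tab2 <- read.csv(path, check.names = FALSE, colClasses = "character")
  colnames(tab2)[3] <- "oops"
  bad2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab2, bad2, row.names = FALSE, quote = FALSE)
  expect_error(read_run(bad2), "column 3.*oops")
})

test_that("resampling masks instead of extrapolating", {
  g <- wavenumber_grid(seq(1000, 1100, by = 10))
  run <- tga_run(300, NULL, matrix(sin(seq(0, 1, length.out = 11)), 1), g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_run(run, path)
  wide <- wavenumber_grid(seq(900, 1200, by = 10))
  back <- read_run(path, grid = wide)
  out <- as.numeric(wide) < 1000 | as.numeric(wide) > 1100
  expect_true(all(!back$mask[out]))
  expect_true(all(back$mask[!out]))
})

test_that("jcamp-dx reader parses the AFFN tabular form", {
  path <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c(
    "##TITLE=toy gas-phase spectrum",
    "##JCAMP-DX=4.24",
    "##XUNITS=1/CM", "##YUNITS=ABSORBANCE",
    "##XFACTOR=1", "##YFACTOR=0.001",
    "##FIRSTX=1000", "##LASTX=1016", "##NPOINTS=5",
    "##$TEMPERATURE=410.5",
    "##XYDATA=(X++(Y..Y))",
    "1000 100 200 300",
    "1012 400 500",
    "##END="), path)
  s <- read_jcamp(path)
  expect_equal(as.numeric(s$grid), c(1000, 1004, 1008, 1012, 1016))
  expect_equal(s$absorbance, c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_equal(s$temperature, 410.5)
  run <- read_run(path, dialect = "jcamp_dx")
  expect_equal(nrow(run$spectra), 1)
})

test_that("library bundle round trip preserves entries; schema is validated", {
  g <- toy_grid(20)
  mkentry <- function(cl, tt) {
    library_entry(cl, paste0(cl, "-1"), cbind(tt - 20, tt + 20),
                  matrix(runif(40), 2, 20), c(tt - 5, tt + 5), g)
  }
  withr::local_seed(5)
  lib <- spectral_library(list(mkentry("PE", 470), mkentry("PS", 420)), g,
                          provenance = "toy")
  path <- withr::local_tempfile(fileext = ".json")
  write_library(lib, path)
  back <- read_library(path)
  expect_length(back$entries, 2)
  expect_identical(library_classes(back), c("PE", "PS"))
  for (i in 1:2) {
    expect_lt(max(abs(back$entries[[i]]$spectra - lib$entries[[i]]$spectra)), 1e-9)
    expect_lt(max(abs(back$entries[[i]]$temperatures - lib$entries[[i]]$temperatures)), 1e-9)
    expect_lt(max(abs(back$entries[[i]]$roi - lib$entries[[i]]$roi)), 1e-9)
  }
  expect_lt(max(abs(as.numeric(back$grid) - as.numeric(lib$grid))), 1e-9)

  # empty library is a valid bundle
  p2 <- withr::local_tempfile(fileext = ".json")
  write_library(spectral_library(list(), g), p2)
  expect_length(read_library(p2)$entries, 0)

  # unknown class label -> schema error listing allowed labels
  b <- jsonlite::read_json(path, simplifyVector = FALSE)
  b$entries[[1]]$polymer_class <- "NYLON12"
  p3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(b, p3, auto_unbox = TRUE, digits = NA)
  expect_error(read_library(p3), "unknown class label 'NYLON12'.*PE.*BLANK")

  # missing manifest keys -> schema error
  b2 <- jsonlite::read_json(path, simplifyVector = FALSE)
  b2$entries <- NULL
  p4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(b2, p4, auto_unbox = TRUE, digits = NA)
  expect_error(read_library(p4), "missing keys.*entries")
})

test_that("library entries must keep spectra inside a ROI", {
  g <- toy_grid(10)
  expect_error(
    library_entry("PE", "x", cbind(400, 450), matrix(0, 1, 10), 500, g),
    "outside every ROI")
  expect_error(
    library_entry("XX", "x", cbind(400, 450), matrix(0, 1, 10), 420, g),
    "unknown class label")
})

test_that("correlation_matrix matches analytic values and invariances", {
  g <- toy_grid(60)
  x <- as.numeric(g)
  band1 <- exp(-(x - 1040)^2 / (2 * 8^2))
  band2 <- exp(-(x - 1180)^2 / (2 * 8^2))
  mk <- function(cl, v, tt) {
    library_entry(cl, paste0(cl, "-1"), cbind(tt - 30, tt + 30),
                  matrix(v, 1, 60), tt, g)
  }
  # exact copies across classes -> off-diagonal 1.0
  lib_same <- spectral_library(list(mk("PE", band1, 400), mk("PP", band1, 450)), g)
  cm <- correlation_matrix(lib_same)
  expect_equal(cm["PE", "PP"], 1.0, tolerance = 1e-12)
  expect_equal(diag(cm), c(PE = 1, PP = 1))

  # two-band classes -> off-diagonal equals the direct Pearson of the vectors
  lib2 <- spectral_library(list(mk("PE", band1, 400), mk("PP", band2, 450)), g)
  cm2 <- correlation_matrix(lib2)
  expect_equal(cm2["PE", "PP"], cor(band1, band2), tolerance = 1e-12)
  expect_true(isSymmetric(cm2))

  # single-class library -> 1x1 [[1.0]]
  cm1 <- correlation_matrix(spectral_library(list(mk("PE", band1, 400)), g))
  expect_identical(dim(cm1), c(1L, 1L))
  expect_equal(cm1[1, 1], 1.0)

  # invariance to ordering and uniform scaling of a spectrum
  lib3 <- spectral_library(list(mk("PP", band2, 450), mk("PE", 7.5 * band1, 400)), g)
  expect_equal(correlation_matrix(lib3), cm2, tolerance = 1e-12)
})
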