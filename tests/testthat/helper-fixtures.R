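# Shared fixture machinery. The fixture world (12 pseudo-polymer archetypes,
# coarse 12 C spectrum spacing for speed) is built once per test session and
# cached; the acceptance tests build their own finer-grained world.

fixture_cache <- new.env(parent = emptyenv())

fixture_world <- function() {
  if (is.null(fixture_cache$world)) {
    fixture_cache$world <- suppressWarnings(
      make_fixture_library(temp_step = 12, seed = 1))
  }
  fixture_cache$world
}

# Four well-separated archetypes for the ML unit tests: single strong DTG
# peaks at distinct temperatures and disjoint dominant band sets.
separated_archetypes <- function() {
  default_archetypes()[c("PS", "PE", "PC", "PTFE")]
}

separated_world <- function() {
  if (is.null(fixture_cache$sep)) {
    fixture_cache$sep <- suppressWarnings(make_fixture_library(
      c(separated_archetypes(), default_archetypes()["BLANK"]),
      temp_step = 8, noise_sd = 0.002, seed = 3))
  }
  fixture_cache$sep
}

# A small wavenumber grid in the legal range for toy spectra.
toy_grid <- function(n = 50) {
  wavenumber_grid(seq(1000, 1000 + 4 * (n - 1), by = 4))
}

toy_spectrum <- function(values, temperature = 300, grid = NULL, mask = NULL) {
  grid <- grid %||% toy_grid(length(values))
  ftir_spectrum(values, temperature, grid, mask)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force multilabel metrics used as the independent oracle.
brute_metrics <- function(pred, truth, classes) {
  per <- lapply(classes, function(cl) {
    tp <- fp <- fn <- 0
    for (i in seq_along(pred)) {
      p <- cl %in% pred[[i]]; t <- cl %in% truth[[i]]
      tp <- tp + (p && t); fp <- fp + (p && !t); fn <- fn + (!p && t)
    }
    c(tp = tp, fp = fp, fn = fn)
  })
  names(per) <- classes
  ham <- mean(vapply(seq_along(pred), function(i) {
    agree <- sum(vapply(classes, function(cl) {
      (cl %in% pred[[i]]) == (cl %in% truth[[i]])
    }, logical(1)))
    agree / length(classes)
  }, numeric(1)))
  list(per = per, hamming = ham)
}
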