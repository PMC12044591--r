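# S3 domain types: wavenumber grid, spectrum, TGA-FTIR run, library entry,
# spectral library. Runs store their spectra as a dense matrix (rows =
# spectra) on a shared grid with a shared usability mask; `get_spectrum()`
# extracts the per-spectrum view.

#' Default polymer class vocabulary
#'
#' The ten commodity polymers most often reported in environmental
#' microplastic surveys, plus cellulose (a ubiquitous natural matrix
#' component) and a blank class for plastic-free runs.
#'
#' @return character vector of class labels.
#' @export
polymer_classes <- function() {
  c("PE", "PP", "PS", "PET", "PA", "PVC", "PUR", "PMMA", "PTFE", "PC",
    "CEL", "BLANK")
}

#' Construct a wavenumber grid
#'
#' @param values strictly increasing wavenumbers in cm^-1, all within
#'   \[400, 4500\]. Downstream analysis is restricted to 800-4000 cm^-1.
#' @return numeric vector of class `wavenumber_grid`.
#' @export
wavenumber_grid <- function(values) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("wavenumber grid contains NA", call. = FALSE)
  if (length(values) < 2L) stop("wavenumber grid needs >= 2 points", call. = FALSE)
  if (any(diff(values) <= 0)) {
    stop("wavenumbers must be strictly increasing (duplicate or non-monotone values)",
         call. = FALSE)
  }
  if (min(values) < 400 || max(values) > 4500) {
    stop("wavenumbers must lie within [400, 4500] cm^-1", call. = FALSE)
  }
  structure(values, class = "wavenumber_grid")
}

#' Construct a single evolved-gas FTIR spectrum
#'
#' @param absorbance numeric vector aligned to `grid`.
#' @param temperature temperature (degrees C) at which the spectrum was
#'   recorded.
#' @param grid a [wavenumber_grid()].
#' @param mask logical vector, `TRUE` = usable point. Masked points are
#'   excluded from correlation, feature selection and training.
#' @return object of class `ftir_spectrum`.
#' @export
ftir_spectrum <- function(absorbance, temperature, grid, mask = NULL) {
  absorbance <- as.numeric(absorbance)
  grid <- if (inherits(grid, "wavenumber_grid")) grid else wavenumber_grid(grid)
  if (length(absorbance) != length(grid)) {
    stop("absorbance length (", length(absorbance),
         ") does not match grid length (", length(grid), ")", call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(TRUE, length(grid))
  stopifnot(is.logical(mask), length(mask) == length(grid))
  structure(
    list(absorbance = absorbance, temperature = as.numeric(temperature),
         grid = grid, mask = mask),
    class = "ftir_spectrum"
  )
}

#' Construct a TGA-FTIR run
#'
#' Bundles the thermogravimetric curve with the temperature-resolved
#' evolved-gas FTIR spectra of one measurement.
#'
#' @param temperatures ascending spectrum temperatures (degrees C).
#' @param tg mass remaining (%) aligned to `temperatures` (may be `NULL`
#'   before TG/FTIR alignment).
#' @param spectra numeric matrix, one row per spectrum, columns aligned to
#'   `grid`.
#' @param grid a [wavenumber_grid()].
#' @param mask shared logical usability mask over `grid`.
#' @param dtg positive mass-loss rate (%/degree C), or `NULL`.
#' @param gram_schmidt integrated-absorbance trace, or `NULL`.
#' @param metadata free-form list (sample id, known labels, heating rate
#'   in degrees C/min, dwell time in s, ...).
#' @return object of class `tga_run`.
#' @export
tga_run <- function(temperatures, tg, spectra, grid, mask = NULL,
                    dtg = NULL, gram_schmidt = NULL, metadata = list()) {
  grid <- if (inherits(grid, "wavenumber_grid")) grid else wavenumber_grid(grid)
  spectra <- as.matrix(spectra)
  temperatures <- as.numeric(temperatures)
  n <- length(temperatures)
  if (is.unsorted(temperatures, strictly = FALSE)) {
    stop("spectrum temperatures must be ascending", call. = FALSE)
  }
  if (nrow(spectra) != n) {
    stop("spectra rows (", nrow(spectra), ") != number of temperatures (", n, ")",
         call. = FALSE)
  }
  if (ncol(spectra) != length(grid)) {
    stop("spectra columns do not match grid length", call. = FALSE)
  }
  if (!is.null(tg) && length(tg) != n) {
    stop("tg length does not match number of spectra", call. = FALSE)
  }
  if (!is.null(gram_schmidt) && length(gram_schmidt) != n) {
    stop("gram_schmidt length does not match number of spectra", call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(TRUE, length(grid))
  structure(
    list(temperatures = temperatures, tg = if (is.null(tg)) NULL else as.numeric(tg),
         dtg = if (is.null(dtg)) NULL else as.numeric(dtg),
         gram_schmidt = if (is.null(gram_schmidt)) NULL else as.numeric(gram_schmidt),
         spectra = spectra, grid = grid, mask = mask, metadata = metadata),
    class = "tga_run"
  )
}

#' Extract one spectrum from a run
#'
#' @param run a [tga_run()].
#' @param i spectrum index.
#' @return an [ftir_spectrum()].
#' @export
get_spectrum <- function(run, i) {
  stopifnot(inherits(run, "tga_run"), i >= 1L, i <= nrow(run$spectra))
  ftir_spectrum(run$spectra[i, ], run$temperatures[i], run$grid, run$mask)
}

#' @export
print.tga_run <- function(x, ...) {
  cat("<tga_run> ", nrow(x$spectra), " spectra, ",
      length(x$grid), " wavenumbers (",
      format(min(x$grid)), "-", format(max(x$grid)), " cm^-1), T ",
      format(round(min(x$temperatures), 1)), "-",
      format(round(max(x$temperatures), 1)), " C",
      if (!is.null(x$metadata$sample_id)) paste0(", sample ", x$metadata$sample_id),
      "\n", sep = "")
  invisible(x)
}

#' Construct a spectral-library entry
#'
#' One reference sample: its class label, the temperature region(s) of
#' interest around its decomposition peak(s), and the reference spectra
#' taken inside those regions.
#'
#' @param polymer_class label; must belong to `classes`.
#' @param sample_id free-text sample identifier.
#' @param roi numeric matrix with columns `lo`, `hi` (degrees C); one row
#'   per region of interest. Multi-peak polymers (e.g. PMMA, PVC) carry
#'   several rows.
#' @param spectra matrix of reference spectra (rows) on the library grid.
#' @param temperatures per-spectrum temperatures; every one must fall in a
#'   ROI interval.
#' @param grid the shared [wavenumber_grid()].
#' @param classes allowed label vocabulary.
#' @return object of class `library_entry`.
#' @export
library_entry <- function(polymer_class, sample_id, roi, spectra, temperatures,
                          grid, classes = polymer_classes()) {
  if (!polymer_class %in% classes) {
    stop("unknown class label '", polymer_class, "'; allowed: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  roi <- matrix(as.numeric(roi), ncol = 2L,
                dimnames = list(NULL, c("lo", "hi")))
  if (any(roi[, 1L] >= roi[, 2L])) stop("ROI intervals must have lo < hi", call. = FALSE)
  spectra <- as.matrix(spectra)
  temperatures <- as.numeric(temperatures)
  grid <- if (inherits(grid, "wavenumber_grid")) grid else wavenumber_grid(grid)
  if (nrow(spectra) != length(temperatures)) {
    stop("spectra rows != temperatures length", call. = FALSE)
  }
  if (ncol(spectra) != length(grid)) stop("spectra columns != grid length", call. = FALSE)
  in_roi <- vapply(temperatures, function(tt) {
    any(tt >= roi[, 1L] & tt <= roi[, 2L])
  }, logical(1L))
  if (!all(in_roi)) {
    stop("spectrum temperatures outside every ROI interval: ",
         paste(round(temperatures[!in_roi], 1), collapse = ", "), call. = FALSE)
  }
  structure(
    list(polymer_class = polymer_class, sample_id = as.character(sample_id),
         roi = roi, spectra = spectra, temperatures = temperatures, grid = grid),
    class = "library_entry"
  )
}

#' Construct a spectral library
#'
#' @param entries list of [library_entry()] objects, all on `grid`.
#' @param grid the shared [wavenumber_grid()].
#' @param provenance free text describing where the entries came from.
#' @param mask shared usability mask (optional; defaults to all-true).
#' @param classes allowed label vocabulary.
#' @return object of class `spectral_library`.
#' @export
spectral_library <- function(entries, grid, provenance = "",
                             mask = NULL, classes = polymer_classes()) {
  grid <- if (inherits(grid, "wavenumber_grid")) grid else wavenumber_grid(grid)
  for (e in entries) {
    stopifnot(inherits(e, "library_entry"))
    if (length(e$grid) != length(grid) || any(abs(e$grid - grid) > 1e-9)) {
      stop("library entry '", e$sample_id, "' is not on the shared grid",
           call. = FALSE)
    }
  }
  if (is.null(mask)) mask <- rep(TRUE, length(grid))
  structure(
    list(entries = entries, grid = grid, provenance = provenance,
         mask = mask, classes = classes),
    class = "spectral_library"
  )
}

#' @export
print.spectral_library <- function(x, ...) {
  nspec <- sum(vapply(x$entries, function(e) nrow(e$spectra), integer(1L)))
  cat("<spectral_library> ", length(x$entries), " entries (",
      length(unique(library_classes(x))), " classes), ", nspec,
      " spectra, grid ", length(x$grid), " points\n", sep = "")
  invisible(x)
}

#' Classes present in a library
#' @param lib a [spectral_library()].
#' @return character vector, one label per entry.
#' @export
library_classes <- function(lib) {
  vapply(lib$entries, function(e) e$polymer_class, character(1L))
}

#' Stack all library spectra into one matrix
#'
#' @param lib a [spectral_library()].
#' @return list with `spectra` (matrix), `temperatures`, `class` (per row),
#'   `entry` (entry index per row), `sample_id` (per row).
#' @export
library_matrix <- function(lib) {
  mats <- lapply(lib$entries, function(e) e$spectra)
  ns <- vapply(mats, nrow, integer(1L))
  list(
    spectra = do.call(rbind, mats),
    temperatures = unlist(lapply(lib$entries, function(e) e$temperatures),
                          use.names = FALSE),
    class = rep(library_classes(lib), ns),
    entry = rep(seq_along(lib$entries), ns),
    sample_id = rep(vapply(lib$entries, function(e) e$sample_id, character(1L)), ns)
  )
}
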