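# Readers/writers. Canonical interchange formats are plain text: a CSV
# matrix dialect for runs (first column = wavenumber, one column per
# spectrum, header row = spectrum temperatures, optional sidecar TG table),
# JCAMP-DX for single spectra, and a single-file JSON bundle for libraries.

fmt_num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Read a TGA-FTIR run
#'
#' @param path file path.
#' @param dialect `"csv_matrix"` (default) or `"jcamp_dx"` (single
#'   spectrum, wrapped into a one-spectrum run).
#' @param tg_path optional path of the sidecar TG table (CSV with columns
#'   `temperature`, `tg`). Defaults to `<path minus extension>_tg.csv`
#'   when that file exists.
#' @param grid optional target [wavenumber_grid()]; spectra are linearly
#'   resampled onto it and points outside the source range are masked
#'   (never extrapolated).
#' @param metadata optional metadata list.
#' @return a [tga_run()] with ascending temperatures and an all-true mask
#'   (except resampling-induced masked points).
#' @export
read_run <- function(path, dialect = c("csv_matrix", "jcamp_dx"),
                     tg_path = NULL, grid = NULL, metadata = list()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "jcamp_dx") {
    s <- read_jcamp(path)
    run <- tga_run(s$temperature, NULL, matrix(s$absorbance, nrow = 1L),
                   s$grid, metadata = metadata)
    return(if (is.null(grid)) run else resample_run(run, grid))
  }
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("csv_matrix needs >= 2 columns", call. = FALSE)
  hdr <- colnames(tab)[-1L]
  temps <- suppressWarnings(as.numeric(hdr))
  if (anyNA(temps)) {
    bad <- which(is.na(temps))[1L]
    stop("malformed header: column ", bad + 1L, " ('", hdr[bad],
         "') is not a numeric spectrum temperature", call. = FALSE)
  }
  wn <- suppressWarnings(as.numeric(tab[[1L]]))
  if (anyNA(wn)) stop("non-numeric wavenumber values in column 1", call. = FALSE)
  if (any(diff(wn) <= 0)) {
    stop("wavenumbers must be strictly increasing (duplicate or non-monotone rows)",
         call. = FALSE)
  }
  A <- t(vapply(tab[-1L], as.numeric, numeric(nrow(tab))))  # spectra x wn
  ord <- order(temps)
  run <- tga_run(temps[ord], NULL, A[ord, , drop = FALSE], wavenumber_grid(wn),
                 metadata = metadata)
  if (is.null(tg_path)) {
    cand <- paste0(sub("\\.[^.]*$", "", path), "_tg.csv")
    if (file.exists(cand)) tg_path <- cand
  }
  if (!is.null(tg_path)) {
    tg <- utils::read.csv(tg_path)
    if (!all(c("temperature", "tg") %in% names(tg))) {
      stop("TG sidecar must have columns 'temperature' and 'tg'", call. = FALSE)
    }
    run$metadata$tg_table <- tg[order(tg$temperature), c("temperature", "tg")]
  }
  if (!is.null(grid)) run <- resample_run(run, grid) else run
}

#' Write a run in the CSV-matrix dialect
#'
#' Writes `path` (spectra matrix) and, when TG data is present,
#' `<path minus extension>_tg.csv`. Numeric fields keep full double
#' precision so that a write/read round trip is lossless to < 1e-9.
#'
#' @param run a [tga_run()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "tga_run"))
  tab <- data.frame(wavenumber = fmt_num(as.numeric(run$grid)),
                    check.names = FALSE)
  for (i in seq_along(run$temperatures)) {
    tab[[fmt_num(run$temperatures[i])]] <- fmt_num(run$spectra[i, ])
  }
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  tg_table <- run$metadata$tg_table
  if (is.null(tg_table) && !is.null(run$tg)) {
    tg_table <- data.frame(temperature = run$temperatures, tg = run$tg)
  }
  if (!is.null(tg_table)) {
    tgp <- paste0(sub("\\.[^.]*$", "", path), "_tg.csv")
    utils::write.csv(
      data.frame(temperature = fmt_num(tg_table$temperature),
                 tg = fmt_num(tg_table$tg)),
      tgp, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# Linear resampling onto a target grid; out-of-range points are masked.
resample_run <- function(run, grid) {
  grid <- if (inherits(grid, "wavenumber_grid")) grid else wavenumber_grid(grid)
  src <- as.numeric(run$grid)
  tgt <- as.numeric(grid)
  inside <- tgt >= min(src) & tgt <= max(src)
  S <- matrix(0, nrow(run$spectra), length(tgt))
  for (i in seq_len(nrow(S))) {
    S[i, inside] <- stats::approx(src, run$spectra[i, ], xout = tgt[inside])$y
  }
  mask_src <- stats::approx(src, as.numeric(run$mask), xout = tgt[inside],
                            method = "constant", f = 0)$y >= 1
  mask <- inside
  mask[inside] <- mask[inside] & mask_src
  tga_run(run$temperatures, run$tg, S, grid, mask, run$dtg,
          run$gram_schmidt, run$metadata)
}

#' Read a single spectrum from a JCAMP-DX file
#'
#' Supports the plain AFFN `(X++(Y..Y))` tabular form with `##XFACTOR`,
#' `##YFACTOR`, `##FIRSTX`, `##LASTX`, `##NPOINTS`. The spectrum
#' temperature is taken from a `##$TEMPERATURE` (or `##TEMPERATURE`)
#' record when present, else 25 C.
#'
#' @param path file path.
#' @return an [ftir_spectrum()].
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^##\\$?", key, "="), lines, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1L]))
  }
  xf <- as.numeric(get_field("XFACTOR") %||% "1")
  yf <- as.numeric(get_field("YFACTOR") %||% "1")
  npt <- as.numeric(get_field("NPOINTS") %||% NA)
  firstx <- as.numeric(get_field("FIRSTX") %||% NA)
  lastx <- as.numeric(get_field("LASTX") %||% NA)
  temp <- as.numeric(get_field("TEMPERATURE") %||% "25")
  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (!length(start)) stop("no ##XYDATA block found in ", path, call. = FALSE)
  end <- grep("^##END=", lines, ignore.case = TRUE)
  end <- if (length(end)) min(end[end > start[1L]]) else length(lines) + 1L
  body <- lines[(start[1L] + 1L):(end - 1L)]
  parsed <- lapply(body, function(ln) {
    suppressWarnings(as.numeric(strsplit(trimws(ln), "[[:space:],]+")[[1L]]))
  })
  parsed <- Filter(function(v) length(v) >= 2L && !anyNA(v), parsed)
  if (!length(parsed)) stop("empty ##XYDATA block in ", path, call. = FALSE)
  dx <- if (!is.na(firstx) && !is.na(lastx) && !is.na(npt) && npt > 1) {
    (lastx - firstx) / (npt - 1) / xf
  } else if (length(parsed) >= 2L) {
    (parsed[[2L]][1L] - parsed[[1L]][1L]) / (length(parsed[[1L]]) - 1L)
  } else 1
  xs <- unlist(lapply(parsed, function(v) {
    v[1L] + dx * seq(0L, length(v) - 2L)
  }))
  ys <- unlist(lapply(parsed, function(v) v[-1L]))
  x <- xs * xf
  y <- ys * yf
  if (!is.na(npt) && length(y) != npt) {
    warning("NPOINTS (", npt, ") != parsed points (", length(y), ")", call. = FALSE)
  }
  ord <- order(x)
  ftir_spectrum(y[ord], temp, wavenumber_grid(x[ord]))
}

#' Write a spectral library to a single-file JSON bundle
#'
#' @param lib a [spectral_library()].
#' @param path output path (conventionally `.json`).
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "spectral_library"))
  bundle <- list(
    format = "tgaftir-library",
    version = 1L,
    provenance = lib$provenance,
    classes = lib$classes,
    grid = as.numeric(lib$grid),
    mask = lib$mask,
    entries = lapply(lib$entries, function(e) {
      list(polymer_class = e$polymer_class, sample_id = e$sample_id,
           roi = unclass(e$roi), temperatures = e$temperatures,
           spectra = unclass(e$spectra))
    })
  )
  jsonlite::write_json(bundle, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Read a spectral library bundle
#'
#' @param path path written by [write_library()].
#' @return a [spectral_library()].
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("format", "version", "grid", "entries")
  missing <- setdiff(need, names(b))
  if (length(missing)) {
    stop("library bundle schema error: missing keys ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!identical(b$format, "tgaftir-library")) {
    stop("library bundle schema error: unexpected format '", b$format, "'",
         call. = FALSE)
  }
  classes <- b$classes %||% polymer_classes()
  grid <- wavenumber_grid(b$grid)
  ents <- b$entries
  entry_list <- function(i) {
    if (is.data.frame(ents)) lapply(ents, `[[`, i) else ents[[i]]
  }
  n <- if (is.data.frame(ents)) nrow(ents) else length(ents)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    e <- entry_list(i)
    if (!e$polymer_class %in% classes) {
      stop("library bundle schema error: unknown class label '",
           e$polymer_class, "'; allowed labels: ",
           paste(classes, collapse = ", "), call. = FALSE)
    }
    spec <- e$spectra
    if (is.list(spec) && !is.matrix(spec)) spec <- do.call(rbind, spec)
    if (is.null(dim(spec))) spec <- matrix(spec, nrow = 1L)
    roi <- e$roi
    if (is.list(roi) && !is.matrix(roi)) roi <- do.call(rbind, roi)
    if (is.null(dim(roi))) roi <- matrix(roi, ncol = 2L)
    entries[[i]] <- library_entry(e$polymer_class, e$sample_id, roi, spec,
                                  unlist(e$temperatures), grid, classes)
  }
  mask <- if (is.null(b$mask)) NULL else as.logical(b$mask)
  spectral_library(entries, grid, b$provenance %||% "", mask, classes)
}

#' Class-by-class maximum Pearson correlation matrix
#'
#' For every ordered pair of classes, the maximum Pearson correlation over
#' all pairs of their library spectra, computed over unmasked points on
#' either the raw spectra or their Savitzky-Golay first derivatives. A
#' diagnostic for inherent between-polymer spectral similarity.
#'
#' @param lib a [spectral_library()].
#' @param use_derivative compare first-derivative spectra instead of raw.
#' @param cfg a [preprocess_config()] (supplies the derivative filter).
#' @return symmetric matrix with unit diagonal, dimnames = class labels.
#' @export
correlation_matrix <- function(lib, use_derivative = FALSE,
                               cfg = preprocess_config()) {
  stopifnot(inherits(lib, "spectral_library"))
  lm <- library_matrix(lib)
  cls <- sort(unique(lm$class))
  if (any(!table(factor(lm$class, levels = cls)) > 0)) {
    stop("class with zero spectra", call. = FALSE)
  }
  M <- lm$spectra
  mask <- lib$mask
  if (use_derivative) {
    dx <- mean(diff(as.numeric(lib$grid)))
    M <- t(apply(M, 1L, function(v) {
      savitzky_golay(bridge_masked(v, mask), cfg$sg_window, cfg$sg_order, 1L, dx)
    }))
  }
  Mm <- M[, mask, drop = FALSE]
  mu <- rowMeans(Mm)
  sdv <- sqrt(rowMeans((Mm - mu)^2))
  if (any(sdv < .Machine$double.eps)) {
    stop("constant library spectrum: Pearson undefined", call. = FALSE)
  }
  Z <- (Mm - mu) / sdv
  R <- Z %*% t(Z) / ncol(Z)
  out <- matrix(NA_real_, length(cls), length(cls), dimnames = list(cls, cls))
  idx <- split(seq_len(nrow(Z)), lm$class)
  for (a in cls) for (b in cls) {
    out[a, b] <- max(R[idx[[a]], idx[[b]]])
  }
  diag(out) <- 1.0
  (out + t(out)) / 2
}
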