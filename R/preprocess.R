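# Preprocessing: region masking, asPLS baseline correction, SNV, transfer-line
# temperature offset, TG/FTIR alignment with DTG recomputation, Gram-Schmidt
# trace, and the fixed-order pipeline tying them together.

#' Preprocessing configuration
#'
#' @param baseline_lambda smoothness penalty of the adaptive smoothness
#'   penalised least-squares (asPLS) baseline. Larger = stiffer baseline.
#' @param baseline_max_iter maximum asPLS reweighting iterations.
#' @param baseline_tol convergence tolerance: maximum baseline change per
#'   iteration as a fraction of the spectrum's dynamic range.
#' @param sg_window odd Savitzky-Golay window (points) used for DTG
#'   smoothing and derivative spectra.
#' @param sg_order Savitzky-Golay polynomial order.
#' @param mask_windows list of wavenumber intervals (cm^-1) excluded from
#'   all analysis; defaults to the CO2 (2200-2400) and OH (3150-3500)
#'   atmospheric-leakage windows.
#' @param analysis_range wavenumber interval retained for analysis (cm^-1).
#' @param temp_window temperature window (degrees C) retained for analysis.
#' @param dwell_time_s transfer-line dwell time (s).
#' @param heating_rate furnace heating rate (degrees C/min).
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_lambda = 1e6,
                              baseline_max_iter = 50L,
                              baseline_tol = 1e-2,
                              sg_window = 11L,
                              sg_order = 2L,
                              mask_windows = list(c(2200, 2400), c(3150, 3500)),
                              analysis_range = c(800, 4000),
                              temp_window = c(150, 750),
                              dwell_time_s = 2.5,
                              heating_rate = 10) {
  stopifnot(sg_window > sg_order, sg_window %% 2L == 1L,
            analysis_range[1L] < analysis_range[2L],
            temp_window[1L] < temp_window[2L],
            heating_rate >= 0, dwell_time_s >= 0)
  for (w in mask_windows) stopifnot(length(w) == 2L, w[1L] < w[2L])
  structure(
    list(baseline_lambda = baseline_lambda,
         baseline_max_iter = as.integer(baseline_max_iter),
         baseline_tol = baseline_tol,
         sg_window = as.integer(sg_window), sg_order = as.integer(sg_order),
         mask_windows = mask_windows, analysis_range = analysis_range,
         temp_window = temp_window, dwell_time_s = dwell_time_s,
         heating_rate = heating_rate),
    class = "preprocess_config"
  )
}

#' Build the usability mask implied by a configuration
#'
#' Points are usable when they lie inside `analysis_range` and outside
#' every window in `mask_windows`.
#'
#' @param grid a [wavenumber_grid()].
#' @param cfg a [preprocess_config()].
#' @return logical vector over `grid`.
#' @export
build_mask <- function(grid, cfg = preprocess_config()) {
  g <- as.numeric(grid)
  mask <- g >= cfg$analysis_range[1L] & g <= cfg$analysis_range[2L]
  for (w in cfg$mask_windows) mask <- mask & !(g >= w[1L] & g <= w[2L])
  mask
}

# asPLS on one absorbance vector; weights are zeroed on masked points so the
# baseline is fit through usable points only (penalty still smooths across).
asls_baseline <- function(y, mask, lambda = 1e6, max_iter = 50L, tol = 1e-3) {
  n <- length(y)
  if (sum(mask) < 10L) stop("baseline correction needs >= 10 unmasked points", call. = FALSE)
  if (all(abs(y[mask]) < .Machine$double.eps)) return(numeric(n))
  D <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  w <- as.numeric(mask)
  alpha <- rep(1, n - 2L)
  z <- y
  dyn <- max(diff(range(y[mask])), 1e-3 * max(abs(y[mask])), .Machine$double.eps)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(n, x = w)
    P <- Matrix::t(D) %*% Matrix::Diagonal(n - 2L, x = alpha) %*% D
    z_old <- z
    z <- as.numeric(Matrix::solve(W + lambda * P, w * y))
    # converged when the baseline moves < tol of the spectrum's dynamic range
    if (it > 1L && max(abs(z - z_old)) < tol * dyn) { converged <- TRUE; break }
    d <- y - z
    if (max(abs(d[mask])) < 1e-9 * dyn) { converged <- TRUE; break }
    dn <- d[mask & d < 0]
    s <- stats::sd(dn)
    if (!is.finite(s) || s < .Machine$double.eps) { converged <- TRUE; break }
    w_new <- 1 / (1 + exp(2 * (d - s) / s))
    w_new[!mask] <- 0
    # adaptive penalty (relax smoothness under peaks), frozen after a few
    # iterations so the damped weight iteration can settle
    if (it <= 5L) alpha <- pmax(abs(d[2:(n - 1L)]) / max(abs(d)), 1e-4)
    w <- 0.5 * w + 0.5 * w_new
  }
  if (!converged) {
    warning("asPLS baseline did not converge in ", max_iter,
            " iterations; returning best iterate", call. = FALSE)
  }
  z
}

#' Baseline-correct a spectrum (asPLS)
#'
#' Subtracts an adaptive smoothness penalised least-squares baseline.
#' The baseline is estimated from unmasked points only.
#'
#' @param s an [ftir_spectrum()].
#' @param cfg a [preprocess_config()].
#' @return the corrected [ftir_spectrum()].
#' @export
baseline_correct <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "ftir_spectrum"))
  z <- asls_baseline(s$absorbance, s$mask, cfg$baseline_lambda,
                     cfg$baseline_max_iter, cfg$baseline_tol)
  ftir_spectrum(s$absorbance - z, s$temperature, s$grid, s$mask)
}

#' Standard normal variate normalisation
#'
#' Centres and scales a spectrum to zero mean and unit *population*
#' standard deviation over its unmasked points. Masked points are set to 0
#' (they are never used downstream).
#'
#' @param s an [ftir_spectrum()] or a bare numeric vector.
#' @param mask logical mask when `s` is a bare vector.
#' @return same type as `s`, normalised.
#' @export
snv <- function(s, mask = NULL) {
  if (inherits(s, "ftir_spectrum")) {
    v <- snv_vec(s$absorbance, s$mask)
    return(ftir_spectrum(v, s$temperature, s$grid, s$mask))
  }
  snv_vec(as.numeric(s), mask %||% rep(TRUE, length(s)))
}

snv_vec <- function(x, mask) {
  xm <- x[mask]
  mu <- mean(xm)
  sdp <- sqrt(mean((xm - mu)^2))
  if (sdp < .Machine$double.eps) {
    stop("zero variance: cannot SNV-normalise a constant spectrum", call. = FALSE)
  }
  out <- (x - mu) / sdp
  out[!mask] <- 0
  out
}

# Row-wise SNV of a matrix over a shared column mask.
snv_rows <- function(M, mask = rep(TRUE, ncol(M))) {
  Mm <- M[, mask, drop = FALSE]
  mu <- rowMeans(Mm)
  sdp <- sqrt(rowMeans((Mm - mu)^2))
  bad <- sdp < .Machine$double.eps
  if (any(bad)) stop("zero variance in ", sum(bad), " spectra", call. = FALSE)
  out <- (M - mu) / sdp
  out[, !mask] <- 0
  out
}

#' Correct spectrum temperatures for the transfer-line dwell
#'
#' The gas evolved at furnace temperature T reaches the FTIR cell
#' `dwell_time_s` seconds later, at which point the furnace has advanced by
#' `dwell_time_s * heating_rate / 60` degrees. Recorded FTIR temperatures
#' are reduced by that offset (TG temperatures are left untouched).
#'
#' @param run a [tga_run()].
#' @param cfg a [preprocess_config()].
#' @return the run with shifted spectrum temperatures.
#' @export
apply_temperature_offset <- function(run, cfg = preprocess_config()) {
  stopifnot(inherits(run, "tga_run"))
  offset <- cfg$dwell_time_s * cfg$heating_rate / 60
  run$temperatures <- run$temperatures - offset
  run$metadata$temperature_offset_c <- offset
  run
}

#' Interpolate the TG curve onto the spectrum temperatures
#'
#' Linearly interpolates the thermogravimetric curve onto the (offset
#' corrected) FTIR temperatures and recomputes the DTG as smoothed central
#' differences, stored as a positive mass-loss rate (-dTG/dT).
#'
#' @param run a [tga_run()].
#' @param cfg a [preprocess_config()].
#' @param tg_table optional data frame with columns `temperature`, `tg`;
#'   when `NULL` the table stored in `run$metadata$tg_table` or the run's
#'   own `(temperatures, tg)` pair is used.
#' @return the run with aligned `tg` and recomputed `dtg`.
#' @export
align_tg_to_spectra <- function(run, cfg = preprocess_config(), tg_table = NULL) {
  stopifnot(inherits(run, "tga_run"))
  if (is.null(tg_table)) tg_table <- run$metadata$tg_table
  if (is.null(tg_table)) {
    if (is.null(run$tg)) stop("no TG data available to align", call. = FALSE)
    tg_table <- data.frame(temperature = run$temperatures, tg = run$tg)
  }
  tt <- run$temperatures
  lo <- min(tg_table$temperature); hi <- max(tg_table$temperature)
  if (min(tt) < lo - 1e-9 || max(tt) > hi + 1e-9) {
    miss_lo <- if (min(tt) < lo) sprintf("[%.2f, %.2f)", min(tt), lo) else NULL
    miss_hi <- if (max(tt) > hi) sprintf("(%.2f, %.2f]", hi, max(tt)) else NULL
    stop("TG data does not cover spectrum temperatures; missing interval ",
         paste(c(miss_lo, miss_hi), collapse = " and "), call. = FALSE)
  }
  tg <- stats::approx(tg_table$temperature, tg_table$tg, xout = tt,
                      rule = 1, ties = mean)$y
  run$tg <- tg
  run$dtg <- compute_dtg(tt, tg, cfg)
  run$metadata$tg_table <- NULL
  run
}

# Central-difference -dTG/dT followed by Savitzky-Golay smoothing.
compute_dtg <- function(temperatures, tg, cfg = preprocess_config()) {
  n <- length(tg)
  if (n < 3L) return(rep(0, n))
  d <- numeric(n)
  d[2:(n - 1L)] <- -(tg[3:n] - tg[1:(n - 2L)]) /
    (temperatures[3:n] - temperatures[1:(n - 2L)])
  d[1L] <- -(tg[2L] - tg[1L]) / (temperatures[2L] - temperatures[1L])
  d[n] <- -(tg[n] - tg[n - 1L]) / (temperatures[n] - temperatures[n - 1L])
  savitzky_golay(d, cfg$sg_window, cfg$sg_order)
}

#' Gram-Schmidt total-intensity trace
#'
#' Per-spectrum root-sum-square of unmasked absorbance: a surrogate for
#' the classical Gram-Schmidt reconstruction of total evolved-gas infrared
#' intensity. With blank-corrected, baseline-corrected spectra the two are
#' equivalent in effect.
#'
#' @param run a [tga_run()].
#' @return non-negative numeric vector, one value per spectrum.
#' @export
gram_schmidt_trace <- function(run) {
  stopifnot(inherits(run, "tga_run"))
  M <- run$spectra[, run$mask, drop = FALSE]
  sqrt(rowSums(M^2))
}

#' Full preprocessing pipeline
#'
#' Fixed stage order: mask -> crop to the analysis wavenumber range ->
#' temperature-offset correction -> crop to the analysis temperature
#' window -> asPLS baseline correction -> TG alignment and DTG -> Gram-
#' Schmidt trace. SNV is deliberately deferred to the matching / training
#' stages. Re-running the pipeline on an already preprocessed run is a
#' near no-op (the offset is not applied twice).
#'
#' @param run a raw [tga_run()].
#' @param cfg a [preprocess_config()].
#' @return the preprocessed [tga_run()].
#' @export
preprocess_run <- function(run, cfg = preprocess_config()) {
  stopifnot(inherits(run, "tga_run"))
  g <- as.numeric(run$grid)
  keep <- g >= cfg$analysis_range[1L] & g <= cfg$analysis_range[2L]
  if (sum(keep) < 2L) stop("no grid points inside the analysis range", call. = FALSE)
  grid <- wavenumber_grid(g[keep])
  spectra <- run$spectra[, keep, drop = FALSE]
  mask <- build_mask(grid, cfg)

  temps <- run$temperatures
  already <- isTRUE(run$metadata$preprocessed)
  if (!already) {
    temps <- temps - cfg$dwell_time_s * cfg$heating_rate / 60
  }
  inwin <- temps >= cfg$temp_window[1L] & temps <= cfg$temp_window[2L]
  if (!any(inwin)) {
    stop("no spectra inside the analysis temperature window [",
         cfg$temp_window[1L], ", ", cfg$temp_window[2L], "] C", call. = FALSE)
  }
  temps <- temps[inwin]
  spectra <- spectra[inwin, , drop = FALSE]

  for (i in seq_len(nrow(spectra))) {
    z <- asls_baseline(spectra[i, ], mask, cfg$baseline_lambda,
                       cfg$baseline_max_iter, cfg$baseline_tol)
    spectra[i, ] <- spectra[i, ] - z
  }

  out <- tga_run(temps, NULL, spectra, grid, mask,
                 metadata = run$metadata)
  tg_src <- run$metadata$tg_table
  if (is.null(tg_src) && !is.null(run$tg)) {
    tg_src <- data.frame(temperature = run$temperatures, tg = run$tg)
  }
  if (!is.null(tg_src)) {
    out <- align_tg_to_spectra(out, cfg, tg_table = tg_src)
    # keep the table so preprocessing stays repeatable
    out$metadata$tg_table <- tg_src
  }
  out$gram_schmidt <- gram_schmidt_trace(out)
  out$metadata$preprocessed <- TRUE
  out$metadata$temperature_offset_c <-
    if (already) run$metadata$temperature_offset_c else
      cfg$dwell_time_s * cfg$heating_rate / 60
  out
}
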