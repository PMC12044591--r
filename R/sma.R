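# Spectral matching: temperature-penalised Pearson hit quality combining raw
# and first-derivative correlations, with iterative residual re-matching so
# that mixed spectra can receive several labels.

#' Spectral-matching configuration
#'
#' @param threshold hit-quality threshold for a positive match (r > 0.7).
#' @param penalty temperature penalty form: `"gaussian"` multiplies the
#'   combined correlation by `exp(-dT^2 / (2 sigma^2))`; `"linear"` uses
#'   `max(0, r - k * |dT|)`. The exact published functional form is not
#'   machine-readable; both forms reduce r with growing |dT| and leave it
#'   untouched at dT = 0.
#' @param penalty_sigma Gaussian penalty scale (degrees C).
#' @param penalty_k linear penalty slope (r units per degree C).
#' @param max_components maximum residual-matching iterations per spectrum
#'   (the evaluation's mixture ceiling).
#' @param sg_window,sg_order Savitzky-Golay filter for derivative spectra.
#' @return list of class `sma_config`.
#' @export
sma_config <- function(threshold = 0.7,
                       penalty = c("gaussian", "linear"),
                       penalty_sigma = 50,
                       penalty_k = 0.002,
                       max_components = 4L,
                       sg_window = 7L, sg_order = 2L) {
  penalty <- match.arg(penalty)
  stopifnot(threshold > 0, threshold < 1, penalty_sigma > 0, penalty_k >= 0,
            max_components >= 1L)
  structure(list(threshold = threshold, penalty = penalty,
                 penalty_sigma = penalty_sigma, penalty_k = penalty_k,
                 max_components = as.integer(max_components),
                 sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order)),
            class = "sma_config")
}

#' Masked Pearson correlation
#'
#' @param a,b numeric vectors of equal length.
#' @param mask logical mask; correlation uses unmasked points only.
#' @return r in \[-1, 1\].
#' @export
pearson <- function(a, b, mask = NULL) {
  stopifnot(length(a) == length(b))
  if (is.null(mask)) mask <- rep(TRUE, length(a))
  am <- a[mask]; bm <- b[mask]
  if (length(am) < 3L) stop("pearson needs >= 3 unmasked points", call. = FALSE)
  sa <- stats::sd(am); sb <- stats::sd(bm)
  if (sa < .Machine$double.eps || sb < .Machine$double.eps) {
    stop("pearson undefined for a constant input", call. = FALSE)
  }
  stats::cor(am, bm)
}

penalty_factor <- function(r_comb, dT, cfg) {
  if (cfg$penalty == "gaussian") {
    r_comb * exp(-dT^2 / (2 * cfg$penalty_sigma^2))
  } else {
    pmax(0, r_comb - cfg$penalty_k * abs(dT))
  }
}

#' Temperature-penalised hit quality of one data/reference pair
#'
#' Combines the Pearson correlation of the (SNV-normalised) spectra (`r0`)
#' with the Pearson correlation of their Savitzky-Golay first derivatives
#' (`r1`) as `r_comb = (r0 + r1) / 2`, then penalises the combined value by
#' the temperature difference between data and reference spectrum.
#' Penalisation is applied after averaging.
#'
#' @param data,ref [ftir_spectrum()] objects on a shared grid and mask.
#' @param cfg an [sma_config()].
#' @return list of class `match_score` with fields `r0`, `r1`, `r_comb`,
#'   `t_data`, `t_lib`, `r_final`.
#' @export
hit_quality <- function(data, ref, cfg = sma_config()) {
  stopifnot(inherits(data, "ftir_spectrum"), inherits(ref, "ftir_spectrum"))
  if (length(data$grid) != length(ref$grid)) {
    stop("data and reference are not on a shared grid", call. = FALSE)
  }
  mask <- data$mask & ref$mask
  dx <- mean(diff(as.numeric(data$grid)))
  r0 <- pearson(data$absorbance, ref$absorbance, mask)
  d1 <- savitzky_golay(bridge_masked(data$absorbance, mask),
                       cfg$sg_window, cfg$sg_order, 1L, dx)
  d2 <- savitzky_golay(bridge_masked(ref$absorbance, mask),
                       cfg$sg_window, cfg$sg_order, 1L, dx)
  r1 <- pearson(d1, d2, mask)
  r_comb <- (r0 + r1) / 2
  dT <- data$temperature - ref$temperature
  structure(list(r0 = r0, r1 = r1, r_comb = r_comb,
                 t_data = data$temperature, t_lib = ref$temperature,
                 r_final = penalty_factor(r_comb, dT, cfg)),
            class = "match_score")
}

# Precompute z-scored raw and derivative library matrices over the mask.
# Returned rows have unit population variance so r = Z %*% zx / p.
sma_prepare <- function(lib, cfg = sma_config(), mask = NULL) {
  lm <- library_matrix(lib)
  mask <- mask %||% lib$mask
  dx <- mean(diff(as.numeric(lib$grid)))
  deriv <- t(apply(lm$spectra, 1L, function(v) {
    savitzky_golay(bridge_masked(v, mask), cfg$sg_window, cfg$sg_order, 1L, dx)
  }))
  zs <- function(M) {
    Mm <- M[, mask, drop = FALSE]
    mu <- rowMeans(Mm)
    sdv <- sqrt(rowMeans((Mm - mu)^2))
    if (any(sdv < .Machine$double.eps)) {
      stop("constant library spectrum: Pearson undefined", call. = FALSE)
    }
    (Mm - mu) / sdv
  }
  list(Z = zs(lm$spectra), Zd = zs(deriv), raw = lm$spectra,
       temperatures = lm$temperatures, class = lm$class, entry = lm$entry,
       mask = mask, dx = dx, p = sum(mask))
}

score_against_library <- function(x_raw, t_data, prep, cfg) {
  xm <- x_raw[prep$mask]
  mu <- mean(xm); sdv <- sqrt(mean((xm - mu)^2))
  if (sdv < .Machine$double.eps) return(NULL)
  zx <- (xm - mu) / sdv
  d <- savitzky_golay(bridge_masked(x_raw, prep$mask),
                      cfg$sg_window, cfg$sg_order, 1L, prep$dx)[prep$mask]
  mud <- mean(d); sdd <- sqrt(mean((d - mud)^2))
  if (sdd < .Machine$double.eps) return(NULL)
  zd <- (d - mud) / sdd
  r0 <- drop(prep$Z %*% zx) / prep$p
  r1 <- drop(prep$Zd %*% zd) / prep$p
  r_comb <- (r0 + r1) / 2
  dT <- t_data - prep$temperatures
  list(r0 = r0, r1 = r1, r_comb = r_comb, dT = dT,
       r_final = penalty_factor(r_comb, dT, cfg))
}

#' Match one spectrum against a library, with residual re-matching
#'
#' Scores the spectrum against every reference spectrum. If the best
#' temperature-penalised hit quality exceeds the threshold, the accepted
#' reference (least-squares scaled, non-negative) is subtracted in SNV
#' space, the residual is re-normalised, and matching repeats on the
#' residual - excluding already accepted classes - until no score clears
#' the threshold or `max_components` labels are accepted. Ties at equal
#' `r_final` break toward the smaller |dT|, then library order.
#'
#' @param s an [ftir_spectrum()] (preprocessed; SNV is applied internally,
#'   to which Pearson correlation is invariant).
#' @param lib a [spectral_library()].
#' @param cfg an [sma_config()].
#' @param prep optional precomputed [sma_prepare()] cache.
#' @return list with `labels`, `class_scores` (named per-class best
#'   r_final), and `trace` (one row per iteration: class, entry, sample_id
#'   index, r0, r1, r_comb, r_final, dT, scale, residual_norm).
#' @export
match_spectrum <- function(s, lib, cfg = sma_config(), prep = NULL) {
  stopifnot(inherits(s, "ftir_spectrum"))
  if (!length(lib$entries)) stop("empty library", call. = FALSE)
  if (is.null(prep)) prep <- sma_prepare(lib, cfg, lib$mask & s$mask)
  classes <- unique(prep$class)
  class_scores <- stats::setNames(rep(-Inf, length(classes)), classes)
  labels <- character(0L)
  trace <- list()
  x <- s$absorbance
  prev_norm <- Inf
  for (iter in seq_len(cfg$max_components)) {
    sc <- score_against_library(x, s$temperature, prep, cfg)
    if (is.null(sc)) break  # residual has no variance left
    agg <- tapply(sc$r_final, prep$class, max)
    class_scores[names(agg)] <- pmax(class_scores[names(agg)], agg)
    elig <- !(prep$class %in% labels)
    if (!any(elig)) break
    rf <- sc$r_final
    rf[!elig] <- -Inf
    best_r <- max(rf)
    cand <- which(rf >= best_r - 1e-12)
    best <- cand[order(abs(sc$dT[cand]), cand)][1L]
    if (best_r <= cfg$threshold) break
    # subtract the accepted reference in SNV space
    xm <- x[prep$mask]
    xs <- (xm - mean(xm)) / sqrt(mean((xm - mean(xm))^2))
    ref <- prep$Z[best, ]
    a <- max(0, sum(xs * ref) / sum(ref^2))
    resid_m <- xs - a * ref
    rnorm <- sqrt(sum(resid_m^2))
    labels <- c(labels, prep$class[best])
    trace[[iter]] <- data.frame(
      iteration = iter, class = prep$class[best], ref_index = best,
      entry = prep$entry[best], r0 = sc$r0[best], r1 = sc$r1[best],
      r_comb = sc$r_comb[best], r_final = best_r, dT = sc$dT[best],
      scale = a, residual_norm = rnorm, stringsAsFactors = FALSE)
    if (a <= 0 || rnorm >= prev_norm - 1e-12) break
    prev_norm <- rnorm
    x_new <- numeric(length(x))
    x_new[prep$mask] <- resid_m
    x <- x_new
  }
  class_scores[!is.finite(class_scores)] <- NA_real_
  list(labels = labels, class_scores = class_scores,
       trace = if (length(trace)) do.call(rbind, trace) else NULL)
}

#' Match every spectrum of a run against a library
#'
#' @param run a preprocessed [tga_run()].
#' @param lib a [spectral_library()].
#' @param cfg an [sma_config()].
#' @return object of class `sma_result`: `labels` (run-level union),
#'   `spectrum_labels` (list per spectrum), `score_trace` (spectra x
#'   classes matrix of best r_final, for r-vs-temperature diagnostics),
#'   `temperatures`.
#' @export
match_run <- function(run, lib, cfg = sma_config()) {
  stopifnot(inherits(run, "tga_run"))
  if (!length(lib$entries)) stop("empty library", call. = FALSE)
  prep <- sma_prepare(lib, cfg, lib$mask & run$mask)
  classes <- sort(unique(prep$class))
  n <- nrow(run$spectra)
  score_trace <- matrix(NA_real_, n, length(classes),
                        dimnames = list(NULL, classes))
  spectrum_labels <- vector("list", n)
  for (i in seq_len(n)) {
    s <- ftir_spectrum(run$spectra[i, ], run$temperatures[i], run$grid, run$mask)
    m <- match_spectrum(s, lib, cfg, prep)
    spectrum_labels[[i]] <- m$labels
    score_trace[i, names(m$class_scores)] <- m$class_scores
  }
  structure(
    list(labels = sort(unique(unlist(spectrum_labels))),
         spectrum_labels = spectrum_labels,
         score_trace = score_trace,
         temperatures = run$temperatures,
         config = cfg),
    class = "sma_result"
  )
}

#' @export
print.sma_result <- function(x, ...) {
  cat("<sma_result> ", length(x$spectrum_labels), " spectra; run labels: ",
      if (length(x$labels)) paste(x$labels, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}
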