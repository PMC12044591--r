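# Synthetic data: (i) a parametric pseudo-polymer fixture world (band sets +
# DTG decomposition peaks) so everything builds and tests offline, and (ii)
# the mixture-thermogram generator used for multilabel evaluation.

#' Define a pseudo-polymer archetype
#'
#' @param class_label class label (see [polymer_classes()]).
#' @param bands matrix/data frame with columns `center` (cm^-1), `width`
#'   (Gaussian sd, cm^-1), `intensity` (relative). Centers must lie inside
#'   800-4000 cm^-1 and outside the default masked windows.
#' @param dtg_peaks matrix/data frame with columns `t_max` (degrees C,
#'   inside 150-750), `width` (Gaussian sd, degrees C), `share` (fraction
#'   of volatile mass lost in this event; shares sum to 1).
#' @param residual_frac mass fraction remaining as char at the end of the
#'   run; `residual_frac + volatile fraction = 1`.
#' @return object of class `polymer_archetype`.
#' @export
polymer_archetype <- function(class_label, bands, dtg_peaks, residual_frac = 0) {
  bands <- as.data.frame(bands)
  if (nrow(bands)) {
    stopifnot(all(c("center", "width", "intensity") %in% names(bands)))
    if (any(bands$center < 800 | bands$center > 4000)) {
      stop("band centers must lie within 800-4000 cm^-1", call. = FALSE)
    }
    for (w in list(c(2200, 2400), c(3150, 3500))) {
      if (any(bands$center >= w[1L] & bands$center <= w[2L])) {
        stop("band centers must avoid the masked windows", call. = FALSE)
      }
    }
  }
  dtg_peaks <- as.data.frame(dtg_peaks)
  if (nrow(dtg_peaks)) {
    stopifnot(all(c("t_max", "width", "share") %in% names(dtg_peaks)))
    if (any(dtg_peaks$t_max < 150 | dtg_peaks$t_max > 750)) {
      stop("DTG peaks must lie within 150-750 C", call. = FALSE)
    }
    if (abs(sum(dtg_peaks$share) - 1) > 1e-9) {
      stop("DTG peak shares must sum to 1", call. = FALSE)
    }
  }
  stopifnot(residual_frac >= 0, residual_frac <= 1)
  structure(list(class_label = class_label, bands = bands,
                 dtg_peaks = dtg_peaks, residual_frac = residual_frac),
            class = "polymer_archetype")
}

bandspec <- function(...) {
  m <- matrix(as.numeric(c(...)), ncol = 3L, byrow = TRUE)
  colnames(m) <- c("center", "width", "intensity")
  as.data.frame(m)
}

peakspec <- function(...) {
  m <- matrix(as.numeric(c(...)), ncol = 3L, byrow = TRUE)
  colnames(m) <- c("t_max", "width", "share")
  as.data.frame(m)
}

#' Default twelve-archetype fixture set
#'
#' Pseudo-polymers loosely mimicking the gas-phase band structure and
#' decomposition windows of the ten commodity polymers plus cellulose and
#' a blank. PE and PP deliberately share the aliphatic CH-stretch doublet
#' (their raw-spectrum Pearson correlation exceeds 0.9 at the decomposition
#' peaks) while differing in narrow fingerprint bands, reproducing the
#' classic PE/PP confusability that first-derivative matching resolves.
#'
#' @return named list of [polymer_archetype()] objects.
#' @export
default_archetypes <- function() {
  list(
    PE = polymer_archetype("PE", bandspec(
      2920, 30, 1.00,  2852, 25, 0.85,  1465, 10, 0.50,  909, 8, 0.42,
      1642, 9, 0.28),
      peakspec(478, 22, 1), 0),
    PP = polymer_archetype("PP", bandspec(
      2920, 26, 1.00,  2852, 21, 0.80,  1378, 8, 0.55,  888, 7, 0.50,
      1156, 8, 0.32),
      peakspec(445, 22, 1), 0),
    PS = polymer_archetype("PS", bandspec(
      3030, 20, 0.70,  2920, 24, 0.45,  1600, 10, 0.60,  1495, 10, 0.50,
      908, 11, 0.95,  1450, 10, 0.30),
      peakspec(418, 20, 1), 0),
    PET = polymer_archetype("PET", bandspec(
      1760, 16, 1.00,  1100, 20, 0.50,  1260, 14, 0.45,  2970, 20, 0.30,
      845, 10, 0.35),
      peakspec(432, 18, 1), 0.10),
    PA = polymer_archetype("PA", bandspec(
      1650, 15, 1.00,  1540, 13, 0.70,  2930, 24, 0.45,  930, 10, 0.30,
      1370, 10, 0.20),
      peakspec(446, 20, 1), 0.05),
    PVC = polymer_archetype("PVC", bandspec(
      2820, 32, 0.90,  2680, 28, 0.55,  1600, 11, 0.40,  815, 10, 0.50,
      3030, 16, 0.30),
      peakspec(295, 18, 0.62,  455, 24, 0.38), 0.08),
    PUR = polymer_archetype("PUR", bandspec(
      1730, 15, 0.90,  1598, 11, 0.50,  1220, 13, 0.60,  2932, 22, 0.40,
      1020, 12, 0.30),
      peakspec(330, 18, 0.45,  408, 20, 0.55), 0.05),
    PMMA = polymer_archetype("PMMA", bandspec(
      1735, 13, 1.00,  1150, 15, 0.70,  2952, 20, 0.50,  840, 9, 0.30,
      988, 9, 0.25),
      peakspec(300, 16, 0.25,  378, 18, 0.75), 0),
    PTFE = polymer_archetype("PTFE", bandspec(
      1212, 13, 1.00,  1152, 11, 0.90,  980, 9, 0.20),
      peakspec(580, 18, 1), 0),
    PC = polymer_archetype("PC", bandspec(
      1775, 14, 0.90,  1500, 11, 0.60,  1180, 14, 0.65,  830, 10, 0.40,
      2970, 18, 0.35,  3040, 15, 0.20),
      peakspec(505, 22, 1), 0.20),
    CEL = polymer_archetype("CEL", bandspec(
      1050, 26, 1.00,  1730, 15, 0.30,  2900, 26, 0.35,  900, 10, 0.20,
      1240, 13, 0.25),
      peakspec(345, 20, 0.85,  480, 40, 0.15), 0.15),
    BLANK = polymer_archetype("BLANK", bandspec(), peakspec(), 1)
  )
}

# Band-set spectrum on a grid (unit amplitude before envelope scaling).
archetype_profile <- function(arch, grid) {
  g <- as.numeric(grid)
  prof <- numeric(length(g))
  b <- arch$bands
  for (j in seq_len(nrow(b))) {
    prof <- prof + b$intensity[j] * exp(-(g - b$center[j])^2 / (2 * b$width[j]^2))
  }
  prof
}

# Volatile-loss envelope (sums to `share` weights) and TG curve.
archetype_envelope <- function(arch, temps) {
  env <- numeric(length(temps))
  p <- arch$dtg_peaks
  for (k in seq_len(nrow(p))) {
    env <- env + p$share[k] * exp(-(temps - p$t_max[k])^2 / (2 * p$width[k]^2))
  }
  env
}

archetype_tg <- function(arch, temps) {
  v <- 1 - arch$residual_frac
  lost <- numeric(length(temps))
  p <- arch$dtg_peaks
  for (k in seq_len(nrow(p))) {
    lost <- lost + p$share[k] * stats::pnorm(temps, p$t_max[k], p$width[k])
  }
  100 * (1 - v * lost)
}

#' Simulate one raw single-polymer TGA-FTIR run
#'
#' Spectra are the archetype's band profile amplitude-modulated by its DTG
#' envelope, plus a small linear instrument baseline, a CO2-leakage band
#' inside the masked 2200-2400 cm^-1 window, and white noise. The TG curve
#' is a sum of sigmoidal loss steps. Temperatures mimic a 10 C/min ramp
#' from 40 to 1000 C with a spectrum every `temp_step` degrees, so that
#' roughly 250 spectra fall inside the 150-750 C analysis window at the
#' default spacing.
#'
#' @param arch a [polymer_archetype()].
#' @param grid target [wavenumber_grid()] (default 800-4000 cm^-1, 4 cm^-1
#'   spacing).
#' @param temp_range full furnace range (degrees C).
#' @param temp_step spectrum spacing (degrees C).
#' @param noise_sd absorbance noise SD (a.u.; peak band amplitude is ~1).
#' @param amplitude overall absorbance scale.
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param sample_id sample identifier recorded in metadata.
#' @return a raw [tga_run()] (not yet preprocessed), with the TG table in
#'   `metadata$tg_table` and the true class in `metadata$classes`.
#' @export
make_fixture_run <- function(arch, grid = wavenumber_grid(seq(800, 4000, by = 4)),
                             temp_range = c(40, 1000), temp_step = 2.4,
                             noise_sd = 0.005, amplitude = 1,
                             seed = NULL, sample_id = arch$class_label) {
  build <- function() {
    temps <- seq(temp_range[1L], temp_range[2L], by = temp_step)
    g <- as.numeric(grid)
    prof <- archetype_profile(arch, grid)
    env <- archetype_envelope(arch, temps)
    S <- amplitude * outer(env, prof)
    # instrument baseline: gentle per-spectrum offset + tilt
    off <- stats::runif(length(temps), 0.005, 0.02)
    tilt <- stats::runif(length(temps), -0.01, 0.02)
    ramp <- (g - min(g)) / diff(range(g))
    S <- S + outer(off, rep(1, length(g))) + outer(tilt, ramp)
    # CO2 leakage inside the masked window
    co2 <- exp(-(g - 2350)^2 / (2 * 30^2))
    S <- S + outer(stats::runif(length(temps), 0, 0.3), co2)
    S <- S + matrix(stats::rnorm(length(S), 0, noise_sd), nrow(S))
    tg <- archetype_tg(arch, temps)
    tga_run(temps, NULL, S, grid,
            metadata = list(sample_id = sample_id,
                            classes = if (arch$class_label == "BLANK")
                              character(0L) else arch$class_label,
                            heating_rate = 10, dwell_time_s = 2.5,
                            amplitude = amplitude,
                            tg_table = data.frame(temperature = temps, tg = tg)))
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

#' Build the fixture library (and its source runs)
#'
#' Simulates one raw run per archetype, preprocesses it, and assembles a
#' [spectral_library()] from the spectra inside each archetype's region(s)
#' of interest (DTG peak +- `roi_halfwidth_sd` peak widths). The BLANK
#' archetype contributes a run (for training negatives) but no library
#' entry.
#'
#' @param archetypes list of [polymer_archetype()] (default
#'   [default_archetypes()]).
#' @param cfg a [preprocess_config()].
#' @param temp_step spectrum spacing in degrees C (2.4 mimics ~250 spectra
#'   per analysis window; larger values give faster, smaller fixtures).
#' @param noise_sd absorbance noise SD.
#' @param roi_halfwidth_sd ROI half-width in units of DTG peak width.
#' @param seed RNG seed.
#' @return list with `library` (a [spectral_library()]) and `runs` (named
#'   list of preprocessed [tga_run()]s, one per archetype incl. BLANK).
#' @export
make_fixture_library <- function(archetypes = default_archetypes(),
                                 cfg = preprocess_config(),
                                 temp_step = 2.4, noise_sd = 0.005,
                                 roi_halfwidth_sd = 1.5, seed = 1L) {
  if (length(archetypes) < 2L) stop("need >= 2 archetypes", call. = FALSE)
  labs <- vapply(archetypes, function(a) a$class_label, character(1L))
  if (anyDuplicated(labs)) warning("duplicate archetype class labels", call. = FALSE)
  grid <- wavenumber_grid(seq(800, 4000, by = 4))
  runs <- list()
  entries <- list()
  for (i in seq_along(archetypes)) {
    arch <- archetypes[[i]]
    run <- make_fixture_run(arch, grid, temp_step = temp_step,
                            noise_sd = noise_sd, seed = seed + i)
    run <- preprocess_run(run, cfg)
    runs[[arch$class_label]] <- run
    if (nrow(arch$dtg_peaks) == 0L) next  # blanks carry no ROI
    roi <- cbind(lo = arch$dtg_peaks$t_max - roi_halfwidth_sd * arch$dtg_peaks$width,
                 hi = arch$dtg_peaks$t_max + roi_halfwidth_sd * arch$dtg_peaks$width)
    in_roi <- vapply(run$temperatures, function(tt) {
      any(tt >= roi[, 1L] & tt <= roi[, 2L])
    }, logical(1L))
    entries[[length(entries) + 1L]] <- library_entry(
      arch$class_label, paste0(arch$class_label, "-1"), roi,
      run$spectra[in_roi, , drop = FALSE], run$temperatures[in_roi],
      run$grid)
  }
  lib <- spectral_library(entries, runs[[1L]]$grid,
                          provenance = "synthetic fixture archetypes",
                          mask = runs[[1L]]$mask)
  list(library = lib, runs = runs)
}

#' Compose a synthetic mixture thermogram from single-polymer runs
#'
#' Spectra and TG curves are fraction-weighted sums of the (preprocessed,
#' temperature-aligned) component runs; DTG and the Gram-Schmidt trace are
#' recomputed. The overall infrared absorbance is optionally randomised by
#' a global log-uniform scalar, mimicking sample-size variation. Ground
#' truth (component classes and fractions) is stored in the metadata.
#'
#' @param runs list of component [tga_run()]s on one grid and temperature
#'   axis.
#' @param fractions positive fractions summing to 1 (one per run).
#' @param randomize_absorbance draw a global scale in log-uniform
#'   \[0.5, 2\]? (Applied to spectra only; TG is mass bookkeeping.)
#' @param temp_shift optionally apply a per-component uniform +-`10` C
#'   decomposition-temperature shift (off by default; probes the
#'   experimental shift effect the plain generator lacks).
#' @param cfg a [preprocess_config()] (for DTG recomputation).
#' @param seed optional RNG seed.
#' @return the mixture [tga_run()].
#' @export
make_mixture <- function(runs, fractions, randomize_absorbance = TRUE,
                         temp_shift = FALSE, cfg = preprocess_config(),
                         seed = NULL) {
  build <- function() {
    stopifnot(length(runs) >= 1L, length(fractions) == length(runs))
    if (any(fractions < 0)) stop("fractions must be non-negative", call. = FALSE)
    if (abs(sum(fractions) - 1) > 1e-9) {
      stop("fractions must sum to 1", call. = FALSE)
    }
    base <- runs[[1L]]
    for (r in runs[-1L]) {
      if (length(r$temperatures) != length(base$temperatures) ||
          max(abs(r$temperatures - base$temperatures)) > 1e-6 ||
          length(r$grid) != length(base$grid) ||
          max(abs(as.numeric(r$grid) - as.numeric(base$grid))) > 1e-9) {
        stop("component runs are not on a shared grid/temperature axis",
             call. = FALSE)
      }
    }
    comps <- runs
    if (temp_shift) {
      comps <- lapply(comps, function(r) {
        dT <- stats::runif(1L, -10, 10)
        shift_run_temperatures(r, dT)
      })
    }
    S <- Reduce(`+`, Map(function(r, f) f * r$spectra, comps, fractions))
    tg <- Reduce(`+`, Map(function(r, f) f * r$tg, comps, fractions))
    scale <- if (randomize_absorbance) exp(stats::runif(1L, log(0.5), log(2))) else 1
    classes <- unname(unlist(lapply(runs, function(r) r$metadata$classes)))
    out <- tga_run(base$temperatures, tg, scale * S, base$grid, base$mask,
                   dtg = compute_dtg(base$temperatures, tg, cfg),
                   metadata = list(
                     sample_id = paste0("mix-", paste(classes, collapse = "+")),
                     classes = classes, fractions = fractions,
                     absorbance_scale = scale, preprocessed = TRUE))
    out$gram_schmidt <- gram_schmidt_trace(out)
    out
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# Shift a run's decomposition profile by dT, re-sampled on its own axis.
shift_run_temperatures <- function(run, dT) {
  tt <- run$temperatures
  src <- tt + dT
  run$tg <- stats::approx(src, run$tg, xout = tt, rule = 2)$y
  for (j in seq_len(ncol(run$spectra))) {
    run$spectra[, j] <- stats::approx(src, run$spectra[, j], xout = tt,
                                      rule = 2)$y
  }
  run
}

#' Generate a multilabel mixture evaluation data set
#'
#' Draws `n` mixtures: the number of components `k` is uniform over
#' `k_range`, component classes are sampled without replacement, one
#' source run per chosen class, and fractions come from a flat Dirichlet.
#' The manifest records the ground truth of every thermogram. Mixtures are
#' materialised lazily via [realize_mixture()] to keep memory bounded.
#'
#' @param runs named list of preprocessed single-class [tga_run()]s
#'   (BLANK runs, i.e. empty `metadata$classes`, are never sampled).
#' @param n number of thermograms (the headline protocol uses 1028).
#' @param k_range integer range of component counts (default 2-4).
#' @param seed RNG seed.
#' @param ... passed to [make_mixture()] at materialisation time.
#' @return object of class `mixture_dataset` with `manifest` (data frame:
#'   id, k, classes, fractions, item_seed), `runs`, and `n_unique`
#'   (number of distinct class combinations).
#' @export
make_mixture_dataset <- function(runs, n = 1028L, k_range = c(2L, 4L),
                                 seed = 1L, ...) {
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  pool <- names(runs)[vapply(runs, function(r) length(r$metadata$classes) > 0,
                             logical(1L))]
  if (length(pool) < max(k_range)) {
    stop("need at least ", max(k_range), " distinct source classes", call. = FALSE)
  }
  dots <- list(...)
  man <- with_seed(seed, {
    k <- sample(seq(k_range[1L], k_range[2L]), n, replace = TRUE)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      cls <- sort(sample(pool, k[i]))
      fr <- rdirichlet_flat(k[i])
      rows[[i]] <- data.frame(
        id = i, k = k[i],
        classes = paste(cls, collapse = ";"),
        fractions = paste(format(fr, digits = 17), collapse = ";"),
        item_seed = sample.int(.Machine$integer.max - 1L, 1L),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  structure(list(manifest = man, runs = runs, k_range = k_range, seed = seed,
                 mixture_args = dots,
                 n_unique = length(unique(man$classes))),
            class = "mixture_dataset")
}

#' Materialise one mixture of a [make_mixture_dataset()]
#'
#' @param ds a `mixture_dataset`.
#' @param i thermogram id (manifest row).
#' @return the mixture [tga_run()].
#' @export
realize_mixture <- function(ds, i) {
  stopifnot(inherits(ds, "mixture_dataset"), i >= 1L, i <= nrow(ds$manifest))
  row <- ds$manifest[i, ]
  cls <- strsplit(row$classes, ";")[[1L]]
  fr <- as.numeric(strsplit(row$fractions, ";")[[1L]])
  fr <- fr / sum(fr)  # guard against decimal round-off in the manifest
  args <- c(list(runs = ds$runs[cls], fractions = fr, seed = row$item_seed),
            ds$mixture_args)
  do.call(make_mixture, args)
}

#' Ground-truth label sets of a mixture data set
#' @param ds a `mixture_dataset`.
#' @return list of character vectors, one per thermogram.
#' @export
dataset_truths <- function(ds) {
  strsplit(ds$manifest$classes, ";")
}

#' @export
print.mixture_dataset <- function(x, ...) {
  cat("<mixture_dataset> ", nrow(x$manifest), " thermograms, ",
      x$n_unique, " unique class combinations, k in [",
      x$k_range[1L], ", ", x$k_range[2L], "]\n", sep = "")
  invisible(x)
}
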