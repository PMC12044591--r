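# Semi-quantitative composition estimation: contiguous label-set segments
# of the thermogram, MCR-ALS apportionment of mixed segments, and DTG-area
# mass-loss integration per class.

#' Segment a prediction map into contiguous label-set runs
#'
#' Consecutive spectra with identical positive-label sets form one
#' segment; spans with empty label sets are flagged unassigned.
#'
#' @param pred a `prediction_map` (from [predict_run()]) or `sma_result`
#'   (from [match_run()]); anything with `spectrum_labels` and
#'   `temperatures`.
#' @param run the matching preprocessed [tga_run()] (same temperatures).
#' @return list of segments: each has `t_lo`, `t_hi`, `indices`, `classes`
#'   (character, possibly empty), `unassigned`.
#' @export
assign_segments <- function(pred, run) {
  stopifnot(!is.null(pred$spectrum_labels), inherits(run, "tga_run"))
  if (length(pred$spectrum_labels) != length(run$temperatures)) {
    stop("prediction map is not aligned to the run temperatures", call. = FALSE)
  }
  keys <- vapply(pred$spectrum_labels, function(l) {
    paste(sort(unique(l)), collapse = ";")
  }, character(1L))
  r <- rle(keys)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(r$values), function(i) {
    idx <- starts[i]:ends[i]
    cls <- if (nzchar(r$values[i])) strsplit(r$values[i], ";")[[1L]] else character(0L)
    list(t_lo = run$temperatures[starts[i]], t_hi = run$temperatures[ends[i]],
         indices = idx, classes = cls, unassigned = !length(cls))
  })
}

# Mean library spectrum per class (non-negative, unit norm) on unmasked
# columns - the MCR-ALS initial spectral estimates.
library_class_profiles <- function(lib, classes) {
  lm <- library_matrix(lib)
  mask <- lib$mask
  t(vapply(classes, function(cl) {
    M <- lm$spectra[lm$class == cl, , drop = FALSE]
    if (!nrow(M)) stop("library has no spectra for class ", cl, call. = FALSE)
    v <- pmax(colMeans(M)[mask], 0)
    nv <- sqrt(sum(v^2))
    if (nv < .Machine$double.eps) stop("empty profile for class ", cl, call. = FALSE)
    v / nv
  }, numeric(sum(mask))))
}

#' MCR-ALS apportionment of a mixed segment
#'
#' Alternating least squares with non-negativity on both concentration and
#' spectral factors, initialised from the library mean spectra of the
#' candidate classes. Because the candidate reference spectra are known,
#' the spectral factors additionally carry a similarity constraint: an
#' updated component spectrum is accepted only while it stays strongly
#' correlated (r >= 0.95) with its library initialisation, which pins down
#' the rotational ambiguity that plain ALS suffers under noise.
#'
#' @param segment_spectra matrix of segment spectra (rows) on the library
#'   grid.
#' @param candidates candidate class labels (>= 1).
#' @param lib a [spectral_library()].
#' @param max_iter ALS iteration cap.
#' @param tol relative lack-of-fit change declaring convergence.
#' @return matrix (spectra x candidates) of non-negative fractions, rows
#'   summing to 1; attribute `converged`.
#' @export
mcr_apportion <- function(segment_spectra, candidates, lib,
                          max_iter = 50L, tol = 1e-8) {
  segment_spectra <- as.matrix(segment_spectra)
  k <- length(candidates)
  n <- nrow(segment_spectra)
  if (k == 1L) {
    out <- matrix(1, n, 1L, dimnames = list(NULL, candidates))
    attr(out, "converged") <- TRUE
    return(out)
  }
  if (n < 3L) stop("MCR needs >= 3 spectra in the segment", call. = FALSE)
  mask <- lib$mask
  D <- segment_spectra[, mask, drop = FALSE]
  D[D < 0] <- 0
  ST <- library_class_profiles(lib, candidates)  # k x p, unit-norm rows
  ST0 <- ST
  C <- matrix(0, n, k)
  lof_prev <- Inf
  converged <- FALSE
  ssd <- sum(D^2)
  for (it in seq_len(max_iter)) {
    A <- t(ST)                                   # p x k
    for (i in seq_len(n)) C[i, ] <- nnls_solve(A, D[i, ])
    CtC <- crossprod(C)
    if (rcond(CtC) > 1e-10) {
      ST_new <- solve(CtC, crossprod(C, D))
      ST_new[ST_new < 0] <- 0
      for (j in seq_len(k)) {
        nv <- sqrt(sum(ST_new[j, ]^2))
        if (nv < .Machine$double.eps) next
        cand <- ST_new[j, ] / nv
        # similarity constraint against the library initialisation
        if (stats::cor(cand, ST0[j, ]) >= 0.95) ST[j, ] <- cand
      }
    }
    lof <- sqrt(sum((D - C %*% ST)^2) / ssd)
    if (is.finite(lof_prev) && abs(lof_prev - lof) < tol) { converged <- TRUE; break }
    lof_prev <- lof
  }
  rs <- rowSums(C)
  frac <- matrix(1 / k, n, k, dimnames = list(NULL, candidates))
  pos <- rs > .Machine$double.eps
  frac[pos, ] <- C[pos, , drop = FALSE] / rs[pos]
  if (!converged) {
    warning("MCR-ALS did not converge in ", max_iter,
            " iterations; using last iterate", call. = FALSE)
  }
  attr(frac, "converged") <- converged
  frac
}

#' Integrate DTG mass loss per assigned class
#'
#' Each spectrum carries the trapezoidal integration weight of its
#' temperature point; a segment's mass loss is the sum of its point
#' masses, split between its classes by the DTG-weighted mean of the
#' per-spectrum MCR contribution fractions. Residual (char) mass is not
#' corrected for.
#'
#' @param run a preprocessed [tga_run()] with a DTG curve.
#' @param segments result of [assign_segments()].
#' @param apportionments optional list parallel to `segments`; element i
#'   is the [mcr_apportion()] fraction matrix of segment i (required only
#'   for multi-class segments; single-class segments default to 1).
#' @return object of class `quant_report`: `per_class` data frame
#'   (`class`, `mass_loss_pct`, `composition_pct`), `unassigned_loss_pct`,
#'   `total_loss_pct`.
#' @export
quantify <- function(run, segments, apportionments = NULL) {
  stopifnot(inherits(run, "tga_run"))
  if (is.null(run$dtg)) stop("run has no DTG curve; preprocess it first", call. = FALSE)
  tt <- run$temperatures
  n <- length(tt)
  w <- numeric(n)
  if (n >= 2L) {
    w[1L] <- (tt[2L] - tt[1L]) / 2
    w[n] <- (tt[n] - tt[n - 1L]) / 2
    if (n > 2L) w[2:(n - 1L)] <- (tt[3:n] - tt[1:(n - 2L)]) / 2
  }
  point_mass <- w * pmax(run$dtg, 0)
  total <- sum(point_mass)
  losses <- list()
  unassigned <- 0
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    mass <- point_mass[seg$indices]
    if (seg$unassigned) {
      unassigned <- unassigned + sum(mass)
      next
    }
    k <- length(seg$classes)
    frac <- if (k == 1L) {
      matrix(1, length(seg$indices), 1L, dimnames = list(NULL, seg$classes))
    } else if (!is.null(apportionments) && !is.null(apportionments[[si]])) {
      apportionments[[si]]
    } else {
      matrix(1 / k, length(seg$indices), k, dimnames = list(NULL, seg$classes))
    }
    for (cl in seg$classes) {
      losses[[cl]] <- (losses[[cl]] %||% 0) + sum(mass * frac[, cl])
    }
  }
  classes <- names(losses)
  loss_vec <- unlist(losses) %||% numeric(0L)
  assigned_total <- sum(loss_vec)
  comp <- if (assigned_total > .Machine$double.eps) {
    100 * loss_vec / assigned_total
  } else {
    if (length(loss_vec)) warning("zero total assigned mass loss", call. = FALSE)
    rep(0, length(loss_vec))
  }
  structure(
    list(per_class = data.frame(class = classes %||% character(0L),
                                mass_loss_pct = unname(loss_vec),
                                composition_pct = unname(comp),
                                stringsAsFactors = FALSE),
         unassigned_loss_pct = unassigned,
         total_loss_pct = total),
    class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat("<quant_report> total window mass loss ",
      round(x$total_loss_pct, 2), "%, unassigned ",
      round(x$unassigned_loss_pct, 2), "%\n", sep = "")
  if (nrow(x$per_class)) {
    for (i in seq_len(nrow(x$per_class))) {
      cat(sprintf("  %-5s %6.2f%% of mass, %6.1f%% of assigned loss\n",
                  x$per_class$class[i], x$per_class$mass_loss_pct[i],
                  x$per_class$composition_pct[i]))
    }
  }
  invisible(x)
}

#' End-to-end composition estimate for one run
#'
#' Convenience wrapper: segments the prediction map, apportions mixed
#' segments by MCR-ALS against the library, and integrates DTG mass loss.
#'
#' @param run a preprocessed [tga_run()].
#' @param pred a `prediction_map` or `sma_result` for the run.
#' @param lib a [spectral_library()] (needed only when mixed segments
#'   occur).
#' @return a `quant_report`.
#' @export
quantify_run <- function(run, pred, lib = NULL) {
  segments <- assign_segments(pred, run)
  apport <- vector("list", length(segments))
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    if (length(seg$classes) >= 2L) {
      if (is.null(lib)) stop("mixed segment needs a library for MCR", call. = FALSE)
      if (length(seg$indices) >= 3L) {
        apport[[si]] <- mcr_apportion(
          run$spectra[seg$indices, , drop = FALSE], seg$classes, lib)
      }  # short mixed segments fall back to an equal split in quantify()
    }
  }
  quantify(run, segments, apport)
}
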