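# Multilabel one-vs-rest pipeline: EMSA data augmentation, ANOVA F-test
# feature selection, grid-searched training with a sample-level 75/25
# split, and probability-thresholded per-run prediction maps.

#' Extended multiplicative scatter augmentation (EMSA)
#'
#' Expands a labelled spectrum set with perturbed copies
#' `a + b * x + c * l + d * l^2 + eps`, where `l` is the wavenumber axis
#' rescaled to \[-1, 1\]: a multiplicative factor, an additive offset, a
#' slow polynomial baseline wobble, and white noise. Temperatures are
#' jittered by up to +-2 C. With all ranges zero, augmented spectra equal
#' their sources.
#'
#' @param set labelled set: list with `spectra` (matrix), `temperatures`,
#'   `labels` (character per row; `""` marks the blank/negative class),
#'   and optionally `grid`.
#' @param n_per_class number of new spectra per distinct label (must be
#'   positive).
#' @param seed RNG seed.
#' @param mult_range multiplicative factor range (default 0.9-1.1).
#' @param offset_max additive offset bound (absorbance units).
#' @param poly_frac polynomial term bound as a fraction of each source
#'   spectrum's signal range (default 2%).
#' @param noise_frac noise SD as a fraction of each source spectrum's
#'   maximum absolute value (default 0.5%).
#' @param temp_jitter temperature jitter bound (degrees C).
#' @return the augmented entries only, in the same list layout.
#' @export
emsa_augment <- function(set, n_per_class, seed = 1L,
                         mult_range = c(0.9, 1.1), offset_max = 0.02,
                         poly_frac = 0.02, noise_frac = 0.005,
                         temp_jitter = 2) {
  if (n_per_class <= 0L) stop("n_per_class must be positive", call. = FALSE)
  stopifnot(is.matrix(set$spectra),
            length(set$labels) == nrow(set$spectra),
            length(set$temperatures) == nrow(set$spectra))
  classes <- unique(set$labels)
  p <- ncol(set$spectra)
  l <- if (!is.null(set$grid)) {
    g <- as.numeric(set$grid)
    2 * (g - min(g)) / (max(g) - min(g)) - 1
  } else seq(-1, 1, length.out = p)
  with_seed(seed, {
    n_new <- n_per_class * length(classes)
    S <- matrix(0, n_new, p)
    temps <- numeric(n_new)
    labels <- character(n_new)
    row <- 0L
    for (cl in classes) {
      src_idx <- which(set$labels == cl)
      picks <- sample(src_idx, n_per_class, replace = TRUE)
      for (i in picks) {
        row <- row + 1L
        x <- set$spectra[i, ]
        rng <- diff(range(x))
        mx <- max(abs(x))
        a <- stats::runif(1L, -offset_max, offset_max)
        b <- stats::runif(1L, mult_range[1L], mult_range[2L])
        cd <- stats::runif(2L, -poly_frac * rng, poly_frac * rng)
        eps <- if (noise_frac > 0 && mx > 0)
          stats::rnorm(p, 0, noise_frac * mx) else 0
        S[row, ] <- a + b * x + cd[1L] * l + cd[2L] * l^2 + eps
        temps[row] <- set$temperatures[i] + stats::runif(1L, -temp_jitter, temp_jitter)
        labels[row] <- cl
      }
    }
    list(spectra = S, temperatures = temps, labels = labels, grid = set$grid)
  })
}

# Vectorised one-way ANOVA F statistic per column.
anova_f <- function(X, groups) {
  g <- as.factor(groups)
  k <- nlevels(g)
  n <- nrow(X)
  stopifnot(k >= 2L, n > k)
  grand <- colMeans(X)
  ssb <- numeric(ncol(X))
  ssw <- numeric(ncol(X))
  for (lev in levels(g)) {
    idx <- which(g == lev)
    mu <- colMeans(X[idx, , drop = FALSE])
    ssb <- ssb + length(idx) * (mu - grand)^2
    ssw <- ssw + colSums((X[idx, , drop = FALSE] -
                            matrix(mu, length(idx), ncol(X), byrow = TRUE))^2)
  }
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- msb / msw
  f[msw < .Machine$double.eps & msb < .Machine$double.eps] <- 0
  f[msw < .Machine$double.eps & msb >= .Machine$double.eps] <- Inf
  f
}

#' ANOVA F-test feature selection
#'
#' Ranks unmasked wavenumber columns by their one-way ANOVA F statistic
#' across class groups and keeps the top `k`. The temperature of each
#' spectrum is appended as feature `k + 1` when enabled.
#'
#' @param X spectra matrix (rows = SNV-normalised spectra).
#' @param labels class label per row (`""` = blank/negative group).
#' @param k number of wavenumber features to keep (default 200).
#' @param mask logical column mask; masked columns are never selected.
#' @param include_temperature append temperature as an extra feature?
#' @return object of class `feature_spec`: `selected` (column indices into
#'   the full grid, ordered by decreasing F), `f_values`,
#'   `include_temperature`.
#' @export
select_features <- function(X, labels, k = 200L, mask = rep(TRUE, ncol(X)),
                            include_temperature = TRUE) {
  usable <- which(mask)
  if (k > length(usable)) k <- length(usable)
  f <- anova_f(X[, usable, drop = FALSE], labels)
  if (all(!is.finite(f) | f < .Machine$double.eps)) {
    stop("all per-column F statistics are zero: classes are indistinguishable",
         call. = FALSE)
  }
  ord <- order(f, decreasing = TRUE)
  sel <- usable[ord[seq_len(k)]]
  structure(list(selected = sel, f_values = f[ord[seq_len(k)]],
                 include_temperature = isTRUE(include_temperature)),
            class = "feature_spec")
}

# Raw feature matrix: selected columns (+ temperature). The final scaling
# pass standardises each feature with statistics stored from the training
# matrix (temperature scaled jointly with the spectral features).
build_features <- function(S, temps, fspec) {
  M <- S[, fspec$selected, drop = FALSE]
  if (fspec$include_temperature) M <- cbind(M, temps)
  M
}

fit_scaler <- function(M) {
  mu <- colMeans(M)
  sdv <- sqrt(colMeans((M - matrix(mu, nrow(M), ncol(M), byrow = TRUE))^2))
  sdv[sdv < .Machine$double.eps] <- 1
  list(center = mu, scale = sdv)
}

apply_scaler <- function(M, scaler) {
  sweep(sweep(M, 2L, scaler$center), 2L, scaler$scale, `/`)
}

feature_matrix <- function(S, temps, fspec) {
  M <- build_features(S, temps, fspec)
  if (is.null(fspec$scaler)) stop("feature spec has no fitted scaler", call. = FALSE)
  apply_scaler(M, fspec$scaler)
}

#' Training configuration for the one-vs-rest pipeline
#'
#' @param model_kind `"knn"`, `"mlp"`, `"rf"` or `"svc"`.
#' @param split training fraction of the sample-level split (default 0.75).
#' @param cv_folds cross-validation folds for grid search (default 3).
#' @param grid named list of hyperparameter vectors (default
#'   [default_grid()]).
#' @param k_features number of ANOVA-selected wavenumbers (default 200).
#' @param include_temperature append spectrum temperature as a feature?
#' @param prob_threshold positive-label probability threshold (the source
#'   protocol uses a threshold but does not print it; default 0.5).
#' @param emsa_n EMSA augmentation spectra per class added to the training
#'   portion (0 = off).
#' @param negatives_per_run out-of-ROI negative spectra sampled per run.
#' @param negative_roi_buffer inflation factor applied to each ROI when
#'   drawing same-run negatives, so that peak tails (real signal outside
#'   the nominal ROI) are excluded from the negative class.
#' @param seed RNG seed for the split, grid search and model fits.
#' @return list of class `train_config`.
#' @export
train_config <- function(model_kind = "svc", split = 0.75, cv_folds = 3L,
                         grid = NULL, k_features = 200L,
                         include_temperature = TRUE, prob_threshold = 0.5,
                         emsa_n = 0L, negatives_per_run = 60L,
                         negative_roi_buffer = 2, seed = 1L) {
  stopifnot(split > 0, split < 1, cv_folds >= 2L,
            prob_threshold > 0, prob_threshold < 1)
  structure(list(model_kind = model_kind, split = split,
                 cv_folds = as.integer(cv_folds),
                 grid = grid %||% default_grid(model_kind),
                 k_features = as.integer(k_features),
                 include_temperature = include_temperature,
                 prob_threshold = prob_threshold,
                 emsa_n = as.integer(emsa_n),
                 negatives_per_run = as.integer(negatives_per_run),
                 negative_roi_buffer = negative_roi_buffer,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Assemble the labelled training table from library ROI spectra plus
# out-of-ROI and blank-run spectra as negatives ("" label).
assemble_training_set <- function(lib, runs = NULL, cfg) {
  lm <- library_matrix(lib)
  S <- lm$spectra
  labels <- lm$class
  temps <- lm$temperatures
  sample_ids <- lm$sample_id
  if (!is.null(runs)) {
    roi_by_class <- list()
    for (e in lib$entries) {
      roi_by_class[[e$polymer_class]] <-
        rbind(roi_by_class[[e$polymer_class]], e$roi)
    }
    for (nm in names(runs)) {
      run <- runs[[nm]]
      cls <- run$metadata$classes
      roi <- if (length(cls)) roi_by_class[[cls[1L]]] else NULL
      # negatives must be signal-free: exclude an inflated ROI so that the
      # tails of the decomposition peak are neither positive nor negative
      outside <- if (is.null(roi)) rep(TRUE, length(run$temperatures)) else {
        mid <- (roi[, 1L] + roi[, 2L]) / 2
        half <- cfg$negative_roi_buffer * (roi[, 2L] - roi[, 1L]) / 2
        !vapply(run$temperatures, function(tt) {
          any(tt >= mid - half & tt <= mid + half)
        }, logical(1L))
      }
      idx <- which(outside)
      if (length(idx) > cfg$negatives_per_run) {
        idx <- sort(sample(idx, cfg$negatives_per_run))
      }
      if (!length(idx)) next
      S <- rbind(S, run$spectra[idx, , drop = FALSE])
      labels <- c(labels, rep("", length(idx)))
      temps <- c(temps, run$temperatures[idx])
      sample_ids <- c(sample_ids, rep(paste0("neg-", nm), length(idx)))
    }
  }
  list(spectra = S, labels = labels, temperatures = temps,
       sample_ids = sample_ids)
}

# Sample-level stratified split; classes with a single sample fall back to
# a spectrum-level split (stricter grouping is impossible there).
split_train_test <- function(labels, sample_ids, split) {
  train <- logical(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    sids <- unique(sample_ids[idx])
    if (length(sids) >= 2L) {
      n_tr <- max(1L, round(split * length(sids)))
      if (n_tr == length(sids)) n_tr <- length(sids) - 1L
      tr_s <- sample(sids, n_tr)
      train[idx] <- sample_ids[idx] %in% tr_s
    } else {
      n_tr <- max(1L, round(split * length(idx)))
      if (n_tr == length(idx) && length(idx) > 1L) n_tr <- length(idx) - 1L
      train[sample(idx, n_tr)] <- TRUE
    }
  }
  train
}

#' Train a multilabel one-vs-rest classifier on a spectral library
#'
#' Pipeline: assemble ROI spectra plus out-of-ROI/blank negatives ->
#' per-spectrum SNV -> sample-level stratified 75/25 split -> optional
#' EMSA augmentation of the training portion -> ANOVA F-test feature
#' selection (top `k_features` wavenumbers + temperature) -> per-feature
#' standardisation -> per-class binary fits with grid search (3-fold CV
#' maximising macro F1) -> held-out evaluation.
#'
#' @param lib a [spectral_library()].
#' @param runs optional named list of preprocessed source runs supplying
#'   out-of-ROI and blank negatives.
#' @param cfg a [train_config()].
#' @return object of class `trained_model`: per-class binary models,
#'   `feature_spec`, `prob_threshold`, `classes`, grid-search choice,
#'   held-out `test_metrics`, and the training metadata.
#' @export
train <- function(lib, runs = NULL, cfg = train_config()) {
  stopifnot(inherits(lib, "spectral_library"))
  classes <- sort(unique(library_classes(lib)))
  classes <- setdiff(classes, "BLANK")
  if (length(classes) < 2L) {
    stop("need >= 2 polymer classes to train a one-vs-rest model", call. = FALSE)
  }
  lm0 <- library_matrix(lib)
  spec_counts <- table(lm0$class)
  few <- names(spec_counts)[spec_counts < 3L]
  if (length(few)) {
    stop("class(es) with < 3 spectra: ", paste(few, collapse = ", "), call. = FALSE)
  }
  with_seed(cfg$seed, {
    set <- assemble_training_set(lib, runs, cfg)
    S <- snv_rows(set$spectra, lib$mask)
    tr <- split_train_test(set$labels, set$sample_ids, cfg$split)
    S_tr <- S[tr, , drop = FALSE]; lab_tr <- set$labels[tr]
    tmp_tr <- set$temperatures[tr]
    if (cfg$emsa_n > 0L) {
      aug <- emsa_augment(list(spectra = set$spectra[tr, , drop = FALSE],
                               temperatures = tmp_tr, labels = lab_tr,
                               grid = lib$grid),
                          cfg$emsa_n, seed = cfg$seed + 1L)
      aug_s <- snv_rows(aug$spectra, lib$mask)
      S_tr <- rbind(S_tr, aug_s)
      lab_tr <- c(lab_tr, aug$labels)
      tmp_tr <- c(tmp_tr, aug$temperatures)
    }
    fspec <- select_features(S_tr, lab_tr, cfg$k_features, lib$mask,
                             cfg$include_temperature)
    M_tr <- build_features(S_tr, tmp_tr, fspec)
    fspec$scaler <- fit_scaler(M_tr)
    X_tr <- apply_scaler(M_tr, fspec$scaler)

    combos <- expand.grid(cfg$grid, stringsAsFactors = FALSE)
    best <- NULL
    if (nrow(combos) > 1L) {
      folds <- sample(rep_len(seq_len(cfg$cv_folds), nrow(X_tr)))
      for (ci in seq_len(nrow(combos))) {
        params <- as.list(combos[ci, , drop = FALSE])
        f1s <- numeric(cfg$cv_folds)
        for (fd in seq_len(cfg$cv_folds)) {
          inb <- folds != fd
          P <- matrix(0, sum(!inb), length(classes),
                      dimnames = list(NULL, classes))
          for (cl in classes) {
            m <- fit_binary(cfg$model_kind, X_tr[inb, , drop = FALSE],
                            as.numeric(lab_tr[inb] == cl), params,
                            seed = cfg$seed + fd)
            P[, cl] <- predict_prob(m, X_tr[!inb, , drop = FALSE])
          }
          pred <- apply(P, 1L, function(pr) classes[pr > cfg$prob_threshold],
                        simplify = FALSE)
          truth <- lapply(lab_tr[!inb], function(l) if (nzchar(l)) l else character(0L))
          f1s[fd] <- evaluate(pred, truth, classes)$macro_f1
        }
        score <- mean(f1s)
        if (is.null(best) || score > best$score) {
          best <- list(score = score, params = params)
        }
      }
    } else {
      best <- list(score = NA_real_, params = as.list(combos[1L, , drop = FALSE]))
    }

    models <- stats::setNames(vector("list", length(classes)), classes)
    for (cl in classes) {
      models[[cl]] <- fit_binary(cfg$model_kind, X_tr,
                                 as.numeric(lab_tr == cl), best$params,
                                 seed = cfg$seed)
    }

    # held-out test metrics (spectrum-level label sets)
    S_te <- S[!tr, , drop = FALSE]
    test_metrics <- NULL
    if (nrow(S_te)) {
      X_te <- feature_matrix(S_te, set$temperatures[!tr], fspec)
      P <- vapply(classes, function(cl) predict_prob(models[[cl]], X_te),
                  numeric(nrow(X_te)))
      P <- matrix(P, nrow = nrow(X_te), dimnames = list(NULL, classes))
      pred <- apply(P, 1L, function(pr) classes[pr > cfg$prob_threshold],
                    simplify = FALSE)
      truth <- lapply(set$labels[!tr], function(l) if (nzchar(l)) l else character(0L))
      test_metrics <- evaluate(pred, truth, classes)
    }

    structure(
      list(model_kind = cfg$model_kind, models = models, classes = classes,
           feature_spec = fspec, prob_threshold = cfg$prob_threshold,
           grid_choice = best$params, cv_score = best$score,
           test_metrics = test_metrics,
           grid = as.numeric(lib$grid), mask = lib$mask,
           config = cfg),
      class = "trained_model")
  })
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model> ", x$model_kind, ", ", length(x$classes),
      " one-vs-rest classes, ", length(x$feature_spec$selected),
      " spectral features",
      if (x$feature_spec$include_temperature) " + temperature", "\n", sep = "")
  if (!is.null(x$test_metrics)) {
    cat("  held-out macro F1 ", round(x$test_metrics$macro_f1, 3),
        ", Hamming accuracy ", round(x$test_metrics$hamming_accuracy, 3),
        "\n", sep = "")
  }
  invisible(x)
}

#' Predict per-spectrum class probabilities for a run
#'
#' @param model a [train()]ed model.
#' @param run a preprocessed [tga_run()] on the model's grid.
#' @return object of class `prediction_map`: `probabilities` (spectra x
#'   classes), `temperatures`, `threshold`, `spectrum_labels`, and
#'   run-level `labels` (union over spectra).
#' @export
predict_run <- function(model, run) {
  stopifnot(inherits(model, "trained_model"), inherits(run, "tga_run"))
  if (length(run$grid) != length(model$grid) ||
      max(abs(as.numeric(run$grid) - model$grid)) > 1e-6) {
    stop("run grid does not match the model's training grid; ",
         "resample the run onto the library grid first", call. = FALSE)
  }
  n <- nrow(run$spectra)
  mask <- model$mask
  Mm <- run$spectra[, mask, drop = FALSE]
  mu <- rowMeans(Mm)
  sdv <- sqrt(rowMeans((Mm - mu)^2))
  live <- sdv > .Machine$double.eps
  P <- matrix(0, n, length(model$classes),
              dimnames = list(NULL, model$classes))
  if (any(live)) {
    S <- (run$spectra[live, , drop = FALSE] - mu[live]) / sdv[live]
    S[, !mask] <- 0
    X <- feature_matrix(S, run$temperatures[live], model$feature_spec)
    for (cl in model$classes) {
      P[live, cl] <- predict_prob(model$models[[cl]], X)
    }
  }
  labels_per_spec <- apply(P, 1L, function(pr) {
    model$classes[pr > model$prob_threshold]
  }, simplify = FALSE)
  structure(
    list(probabilities = P, temperatures = run$temperatures,
         threshold = model$prob_threshold,
         spectrum_labels = labels_per_spec,
         labels = sort(unique(unlist(labels_per_spec)))),
    class = "prediction_map")
}

#' @export
print.prediction_map <- function(x, ...) {
  cat("<prediction_map> ", nrow(x$probabilities), " spectra x ",
      ncol(x$probabilities), " classes; run labels: ",
      if (length(x$labels)) paste(x$labels, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}
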