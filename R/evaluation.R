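# Thermogram-level multilabel metrics: per-class precision/recall/F1,
# macro averages, Hamming accuracy (1 - Hamming loss), subset accuracy.

#' Multilabel evaluation of run-level label sets
#'
#' Ground truths and predictions are label *sets* per sample (thermogram).
#' Per-class precision = TP/(TP+FP) and recall = TP/(TP+FN) counted over
#' samples; F1 is their harmonic mean, macro-averaged without weights.
#' Hamming accuracy is the mean over samples of
#' `1 - |predicted symdiff truth| / |classes|` - the average fraction of
#' class presence/absence calls that are correct per sample. BLANK is not
#' a metric class: an empty label set is the blank prediction.
#'
#' @param predictions list of character vectors (one per sample).
#' @param truths list of character vectors, same length.
#' @param classes class universe (defaults to the union of labels seen).
#' @return object of class `eval_report`: `per_class` data frame,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `hamming_accuracy`,
#'   `subset_accuracy`, `n_samples`, `excluded_classes`.
#' @export
evaluate <- function(predictions, truths, classes = NULL) {
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have equal length", call. = FALSE)
  }
  if (is.null(classes)) {
    classes <- sort(unique(c(unlist(predictions), unlist(truths))))
  }
  classes <- setdiff(classes, "BLANK")
  n <- length(predictions)
  tp <- fp <- fn <- stats::setNames(numeric(length(classes)), classes)
  ham <- sub_acc <- numeric(n)
  for (i in seq_len(n)) {
    p <- intersect(unique(predictions[[i]]), classes)
    t <- intersect(unique(truths[[i]]), classes)
    tp[intersect(p, t)] <- tp[intersect(p, t)] + 1
    fp[setdiff(p, t)] <- fp[setdiff(p, t)] + 1
    fn[setdiff(t, p)] <- fn[setdiff(t, p)] + 1
    sym <- length(setdiff(p, t)) + length(setdiff(t, p))
    ham[i] <- 1 - sym / length(classes)
    sub_acc[i] <- as.numeric(sym == 0L)
  }
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  f1 <- numeric(length(classes))
  for (j in seq_along(classes)) {
    if (tp[j] + fp[j] + fn[j] == 0) {
      f1[j] <- NA_real_  # never present, never predicted: undefined
    } else if (tp[j] == 0) {
      f1[j] <- 0
    } else {
      f1[j] <- 2 * precision[j] * recall[j] / (precision[j] + recall[j])
    }
  }
  excluded <- classes[tp + fp + fn == 0]
  structure(
    list(per_class = data.frame(class = classes, tp = unname(tp),
                                fp = unname(fp), fn = unname(fn),
                                precision = unname(precision),
                                recall = unname(recall), f1 = f1,
                                stringsAsFactors = FALSE),
         macro_precision = mean(precision[!classes %in% excluded], na.rm = TRUE),
         macro_recall = mean(recall[!classes %in% excluded], na.rm = TRUE),
         macro_f1 = mean(f1[!classes %in% excluded], na.rm = TRUE),
         hamming_accuracy = mean(ham),
         subset_accuracy = mean(sub_acc),
         n_samples = n,
         excluded_classes = excluded),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n = ", x$n_samples,
      "; macro P/R/F1 = ", round(x$macro_precision, 3), "/",
      round(x$macro_recall, 3), "/", round(x$macro_f1, 3),
      "; Hamming accuracy = ", round(x$hamming_accuracy, 3),
      "; subset accuracy = ", round(x$subset_accuracy, 3), "\n", sep = "")
  if (length(x$excluded_classes)) {
    cat("  excluded from macro average (never present nor predicted): ",
        paste(x$excluded_classes, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Identifier factory: spectral matching
#'
#' @param lib a [spectral_library()].
#' @param cfg an [sma_config()].
#' @return function mapping a [tga_run()] to its run-level label set.
#' @export
sma_identifier <- function(lib, cfg = sma_config()) {
  force(lib); force(cfg)
  function(run) match_run(run, lib, cfg)$labels
}

#' Identifier factory: trained ML model
#'
#' @param model a [train()]ed model.
#' @return function mapping a [tga_run()] to its run-level label set.
#' @export
ml_identifier <- function(model) {
  force(model)
  function(run) predict_run(model, run)$labels
}

#' Benchmark identifiers on a mixture data set
#'
#' Streams every thermogram of the data set through each identifier and
#' scores run-level label sets against the manifest ground truths,
#' producing one metrics row per identifier. Identifier failures on a
#' thermogram are recorded and that thermogram is skipped for that
#' identifier.
#'
#' @param identifiers named list of functions `run -> character labels`
#'   (see [sma_identifier()], [ml_identifier()]).
#' @param ds a [make_mixture_dataset()] result.
#' @param classes class universe for the metrics.
#' @return list: `table` (one row per identifier: precision, recall, f1,
#'   accuracy, subset_accuracy, n, skipped), `reports` (full
#'   [evaluate()] reports).
#' @export
benchmark <- function(identifiers, ds, classes = NULL) {
  stopifnot(inherits(ds, "mixture_dataset"), length(identifiers) >= 1L)
  if (is.null(names(identifiers)) || any(!nzchar(names(identifiers)))) {
    stop("identifiers must be a named list", call. = FALSE)
  }
  truths <- dataset_truths(ds)
  if (is.null(classes)) classes <- sort(unique(unlist(truths)))
  n <- nrow(ds$manifest)
  preds <- lapply(identifiers, function(.) vector("list", n))
  ok <- matrix(TRUE, n, length(identifiers),
               dimnames = list(NULL, names(identifiers)))
  for (i in seq_len(n)) {
    run <- realize_mixture(ds, i)
    for (nm in names(identifiers)) {
      res <- tryCatch(identifiers[[nm]](run), error = function(e) e)
      if (inherits(res, "error")) {
        ok[i, nm] <- FALSE
      } else {
        preds[[nm]][[i]] <- res
      }
    }
  }
  reports <- list()
  rows <- list()
  for (nm in names(identifiers)) {
    keep <- ok[, nm]
    rep <- evaluate(preds[[nm]][keep], truths[keep], classes)
    reports[[nm]] <- rep
    rows[[nm]] <- data.frame(
      identifier = nm, precision = rep$macro_precision,
      recall = rep$macro_recall, f1 = rep$macro_f1,
      accuracy = rep$hamming_accuracy,
      subset_accuracy = rep$subset_accuracy,
      n = sum(keep), skipped = sum(!keep), stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       reports = reports)
}
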