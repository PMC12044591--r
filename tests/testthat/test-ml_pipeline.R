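# EMSA augmentation, ANOVA feature selection, one-vs-rest training,
# prediction maps.

test_that("emsa_augment bookkeeping and degenerate-range identity", {
  withr::local_seed(8)
  set <- list(spectra = matrix(runif(60), 6, 10),
              temperatures = seq(300, 400, length.out = 6),
              labels = rep(c("PE", "PS", ""), each = 2))
  aug <- emsa_augment(set, 5, seed = 2)
  expect_identical(nrow(aug$spectra), 15L)       # 3 classes x 5
  expect_identical(sort(unique(aug$labels)), sort(unique(set$labels)))
  expect_error(emsa_augment(set, 0), "positive")

  # all perturbation ranges zero -> copies of source spectra
  aug0 <- emsa_augment(set, 4, seed = 3, mult_range = c(1, 1),
                       offset_max = 0, poly_frac = 0, noise_frac = 0,
                       temp_jitter = 0)
  for (i in seq_len(nrow(aug0$spectra))) {
    src <- which(apply(set$spectra, 1, function(r) {
      isTRUE(all.equal(r, aug0$spectra[i, ], tolerance = 1e-12))
    }))
    expect_length(src, 1)
    expect_identical(set$labels[src], aug0$labels[i])
    expect_equal(set$temperatures[src], aug0$temperatures[i])
  }
})

test_that("feature selection reproduces brute-force ANOVA ranking", {
  withr::local_seed(21)
  n <- 24; p <- 12
  labels <- rep(c("A", "B", "C"), each = 8)
  X <- matrix(rnorm(n * p), n, p)
  X[labels == "B", 7] <- X[labels == "B", 7] + 5  # only column 7 separates

  fs <- select_features(X, labels, k = 3, include_temperature = FALSE)
  expect_identical(fs$selected[1], 7L)

  # full ranking equals a per-column aov() oracle
  brute <- vapply(seq_len(p), function(j) {
    summary(aov(X[, j] ~ factor(labels)))[[1]]$`F value`[1]
  }, numeric(1))
  fs_all <- select_features(X, labels, k = p, include_temperature = FALSE)
  expect_identical(fs_all$selected, order(brute, decreasing = TRUE))
  expect_equal(fs_all$f_values, sort(brute, decreasing = TRUE), tolerance = 1e-9)

  # two identical classes: every between-group F is exactly zero
  X2 <- rbind(X[1:8, ], X[1:8, ])
  expect_error(
    select_features(X2, rep(c("A", "B"), each = 8), k = 2,
                    include_temperature = FALSE),
    "indistinguishable")
})

test_that("all four model kinds separate a well-separated fixture world", {
  w <- separated_world()
  for (mk in c("knn", "mlp", "rf", "svc")) {
    tm <- train(w$library, w$runs,
                train_config(model_kind = mk, seed = 11, emsa_n = 60,
                             grid = lapply(default_grid(mk), `[`, 1)))
    f1 <- tm$test_metrics$per_class$f1
    expect_true(all(f1 >= 0.95),
                info = paste(mk, "per-class F1:", paste(round(f1, 3), collapse = " ")))
    expect_gt(tm$test_metrics$subset_accuracy, 0.9)
  }
})

test_that("train validates degenerate libraries", {
  w <- separated_world()
  lib1 <- spectral_library(w$library$entries[1], w$library$grid,
                           mask = w$library$mask)
  expect_error(train(lib1), ">= 2 polymer classes")

  # class with < 3 spectra is named
  e <- w$library$entries[[1]]
  tiny <- library_entry(e$polymer_class, e$sample_id, e$roi,
                        e$spectra[1:2, , drop = FALSE], e$temperatures[1:2],
                        e$grid)
  lib2 <- spectral_library(c(list(tiny), w$library$entries[-1]),
                           w$library$grid, mask = w$library$mask)
  expect_error(train(lib2), paste0("< 3 spectra: ", e$polymer_class))
})

test_that("prediction maps behave on single-polymer, blank and mixture runs", {
  w <- separated_world()
  tm <- train(w$library, w$runs,
              train_config(model_kind = "svc", seed = 11, emsa_n = 60,
                           grid = list(cost = 1)))

  pred <- predict_run(tm, w$runs$PC)
  expect_identical(pred$labels, "PC")
  expect_true(all(pred$probabilities >= 0 & pred$probabilities <= 1))
  # its class dominates across the DTG peak, others stay low everywhere
  peak_rows <- which.max(w$runs$PC$dtg)
  expect_gt(pred$probabilities[peak_rows, "PC"], tm$prob_threshold)
  expect_true(all(pred$probabilities[, setdiff(tm$classes, "PC")] < 0.5))

  blank <- predict_run(tm, w$runs$BLANK)
  expect_length(blank$labels, 0)

  mix <- make_mixture(w$runs[c("PS", "PE", "PTFE")], c(0.4, 0.3, 0.3),
                      seed = 4)
  predm <- predict_run(tm, mix)
  expect_gte(length(intersect(predm$labels, c("PS", "PE", "PTFE"))), 3)

  # grid mismatch errors with a resample hint
  other <- mix
  other$grid <- wavenumber_grid(as.numeric(mix$grid) + 1)
  expect_error(predict_run(tm, other), "resample")
})

test_that("training is deterministic and threshold-monotone", {
  w <- separated_world()
  cfg <- train_config(model_kind = "mlp", seed = 99, emsa_n = 40,
                      grid = list(hidden = 8))
  t1 <- train(w$library, w$runs, cfg)
  t2 <- train(w$library, w$runs, cfg)
  p1 <- predict_run(t1, w$runs$PS)
  p2 <- predict_run(t2, w$runs$PS)
  expect_identical(p1$probabilities, p2$probabilities)

  # raising the threshold never enlarges the label set
  mix <- make_mixture(w$runs[c("PS", "PC")], c(0.5, 0.5), seed = 12)
  labels_at <- function(thr) {
    t1$prob_threshold <- thr
    predict_run(t1, mix)$labels
  }
  prev <- labels_at(0.2)
  for (thr in c(0.4, 0.6, 0.8, 0.95)) {
    cur <- labels_at(thr)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("EMSA augmentation does not hurt held-out performance", {
  w <- separated_world()
  base <- train(w$library, w$runs,
                train_config(model_kind = "svc", seed = 5, grid = list(cost = 1)))
  aug <- train(w$library, w$runs,
               train_config(model_kind = "svc", seed = 5, emsa_n = 40,
                            grid = list(cost = 1)))
  expect_gte(aug$test_metrics$macro_f1, base$test_metrics$macro_f1 - 0.02)
})
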