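# Minimal, deterministic binary classifiers backing the one-vs-rest
# pipeline: kNN (neighbour vote fractions), single-hidden-layer MLP
# (sigmoid output), random forest of depth-limited binned CART trees
# (tree vote fractions), and a linear squared-hinge SVC with Platt-scaled
# probabilities. No suitable classifier package ships with the runtime, so
# these are implemented here with plain matrix algebra.

#' Default hyperparameter grids per model kind
#'
#' Small documented defaults; the published tuned values are not available,
#' so grids are exposed for configuration.
#'
#' @param model_kind one of `"knn"`, `"mlp"`, `"rf"`, `"svc"`.
#' @return named list of parameter vectors (expanded by grid search).
#' @export
default_grid <- function(model_kind) {
  switch(model_kind,
    knn = list(k = c(3L, 7L)),
    mlp = list(hidden = c(8L, 16L)),
    rf  = list(max_depth = c(6L, 10L)),
    svc = list(cost = c(0.1, 1)),
    stop("unknown model kind '", model_kind, "'", call. = FALSE))
}

fit_binary <- function(model_kind, X, y, params = list(), seed = 1L) {
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)))
  fit <- switch(model_kind,
    knn = fit_knn(X, y, params),
    mlp = with_seed(seed, fit_mlp(X, y, params)),
    rf  = with_seed(seed, fit_rf(X, y, params)),
    svc = fit_svc(X, y, params),
    stop("unknown model kind '", model_kind, "'", call. = FALSE))
  fit$kind <- model_kind
  class(fit) <- c(paste0("tgaftir_", model_kind), "tgaftir_binary")
  fit
}

predict_prob <- function(model, X) {
  switch(model$kind,
    knn = predict_knn(model, X),
    mlp = predict_mlp(model, X),
    rf  = predict_rf(model, X),
    svc = predict_svc(model, X))
}

## ---- kNN -------------------------------------------------------------

fit_knn <- function(X, y, params) {
  k <- params$k %||% 5L
  list(X = X, y = y, k = min(as.integer(k), nrow(X)))
}

predict_knn <- function(m, X) {
  tr <- m$X
  # squared Euclidean distances via the expansion trick
  d2 <- outer(rowSums(X^2), rowSums(tr^2), `+`) - 2 * X %*% t(tr)
  apply(d2, 1L, function(d) {
    nn <- order(d)[seq_len(m$k)]
    mean(m$y[nn])
  })
}

## ---- MLP -------------------------------------------------------------

fit_mlp <- function(X, y, params) {
  hidden <- params$hidden %||% 16L
  epochs <- params$epochs %||% 300L
  lr <- params$lr %||% 0.01
  l2 <- params$l2 %||% 1e-4
  p <- ncol(X); n <- nrow(X)
  W1 <- matrix(stats::rnorm(p * hidden, 0, sqrt(1 / p)), p, hidden)
  b1 <- numeric(hidden)
  W2 <- stats::rnorm(hidden, 0, sqrt(1 / hidden))
  b2 <- 0
  # Adam state
  ms <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = 0)
  vs <- ms
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (ep in seq_len(epochs)) {
    Z1 <- sweep(X %*% W1, 2L, b1, `+`)
    A1 <- tanh(Z1)
    z <- drop(A1 %*% W2) + b2
    pr <- 1 / (1 + exp(-z))
    dz <- (pr - y) / n
    gW2 <- drop(crossprod(A1, dz)) + l2 * W2
    gb2 <- sum(dz)
    dA1 <- outer(dz, W2) * (1 - A1^2)
    gW1 <- crossprod(X, dA1) + l2 * W1
    gb1 <- colSums(dA1)
    upd <- function(par, g, mkey) {
      ms[[mkey]] <<- beta1 * ms[[mkey]] + (1 - beta1) * g
      vs[[mkey]] <<- beta2 * vs[[mkey]] + (1 - beta2) * g^2
      mh <- ms[[mkey]] / (1 - beta1^ep)
      vh <- vs[[mkey]] / (1 - beta2^ep)
      par - lr * mh / (sqrt(vh) + eps)
    }
    W1 <- upd(W1, gW1, "W1"); b1 <- upd(b1, gb1, "b1")
    W2 <- upd(W2, gW2, "W2"); b2 <- upd(b2, gb2, "b2")
  }
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

predict_mlp <- function(m, X) {
  A1 <- tanh(sweep(X %*% m$W1, 2L, m$b1, `+`))
  z <- drop(A1 %*% m$W2) + m$b2
  1 / (1 + exp(-z))
}

## ---- Random forest ---------------------------------------------------

# Features are discretised once into quantile bins; each tree greedily
# minimises Gini impurity over a random feature subset per node.

fit_rf <- function(X, y, params) {
  n_trees <- params$n_trees %||% 30L
  max_depth <- params$max_depth %||% 10L
  min_split <- params$min_split %||% 5L
  n_bins <- params$n_bins %||% 32L
  p <- ncol(X)
  mtry <- params$mtry %||% max(1L, floor(sqrt(p)))
  bins <- matrix(0L, nrow(X), p)
  cuts <- vector("list", p)
  for (j in seq_len(p)) {
    qs <- unique(stats::quantile(X[, j], probs = seq(0, 1, length.out = n_bins + 1L),
                                 names = FALSE))
    cuts[[j]] <- qs[-c(1L, length(qs))]
    bins[, j] <- findInterval(X[, j], cuts[[j]]) + 1L
  }
  nb <- n_bins
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    idx <- sample.int(nrow(X), nrow(X), replace = TRUE)
    trees[[t]] <- grow_tree(bins, y, idx, 0L, max_depth, min_split, mtry, nb)
  }
  list(trees = trees, cuts = cuts)
}

grow_tree <- function(bins, y, idx, depth, max_depth, min_split, mtry, nb) {
  prob <- mean(y[idx])
  if (depth >= max_depth || length(idx) < min_split ||
      prob < 1e-12 || prob > 1 - 1e-12) {
    return(list(leaf = TRUE, prob = prob))
  }
  feats <- sample.int(ncol(bins), min(mtry, ncol(bins)))
  best <- NULL
  n <- length(idx)
  npos <- sum(y[idx])
  parent_gini <- 2 * prob * (1 - prob)
  for (f in feats) {
    b <- bins[idx, f]
    tot <- tabulate(b, nb)
    pos <- numeric(nb)
    hit <- tapply(y[idx], b, sum)
    pos[as.integer(names(hit))] <- hit
    ct <- cumsum(tot); cp <- cumsum(pos)
    valid <- which(ct >= 1 & (n - ct) >= 1 & seq_len(nb) < nb)
    if (!length(valid)) next
    pl <- cp[valid] / ct[valid]
    pr <- (npos - cp[valid]) / (n - ct[valid])
    g <- (ct[valid] * 2 * pl * (1 - pl) +
          (n - ct[valid]) * 2 * pr * (1 - pr)) / n
    i <- which.min(g)
    if (is.null(best) || g[i] < best$g) {
      best <- list(g = g[i], f = f, bin = valid[i])
    }
  }
  if (is.null(best) || best$g >= parent_gini - 1e-12) {
    return(list(leaf = TRUE, prob = prob))
  }
  left <- idx[bins[idx, best$f] <= best$bin]
  right <- idx[bins[idx, best$f] > best$bin]
  list(leaf = FALSE, f = best$f, bin = best$bin,
       left = grow_tree(bins, y, left, depth + 1L, max_depth, min_split, mtry, nb),
       right = grow_tree(bins, y, right, depth + 1L, max_depth, min_split, mtry, nb))
}

predict_rf <- function(m, X) {
  p <- ncol(X)
  bins <- matrix(0L, nrow(X), p)
  for (j in seq_len(p)) bins[, j] <- findInterval(X[, j], m$cuts[[j]]) + 1L
  acc <- numeric(nrow(X))
  for (tr in m$trees) acc <- acc + predict_tree(tr, bins, seq_len(nrow(X)))
  acc / length(m$trees)
}

predict_tree <- function(node, bins, idx) {
  out <- numeric(nrow(bins))
  rec <- function(nd, ii) {
    if (!length(ii)) return()
    if (nd$leaf) { out[ii] <<- nd$prob; return() }
    go_left <- bins[ii, nd$f] <= nd$bin
    rec(nd$left, ii[go_left])
    rec(nd$right, ii[!go_left])
  }
  rec(node, idx)
  out
}

## ---- Linear SVC (squared hinge) with Platt scaling -------------------

fit_svc <- function(X, y, params) {
  cost <- params$cost %||% 1
  ys <- ifelse(y > 0.5, 1, -1)
  p <- ncol(X)
  obj <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1L]
    m <- 1 - ys * (drop(X %*% w) + b)
    0.5 * sum(w^2) + cost * sum(pmax(m, 0)^2)
  }
  grad <- function(th) {
    w <- th[seq_len(p)]; b <- th[p + 1L]
    m <- 1 - ys * (drop(X %*% w) + b)
    act <- pmax(m, 0)
    gw <- w - 2 * cost * drop(crossprod(X, ys * act))
    gb <- -2 * cost * sum(ys * act)
    c(gw, gb)
  }
  fit <- stats::optim(numeric(p + 1L), obj, grad, method = "L-BFGS-B",
                      control = list(maxit = 200L))
  w <- fit$par[seq_len(p)]; b <- fit$par[p + 1L]
  d <- drop(X %*% w) + b
  platt <- platt_fit(d, ys)
  list(w = w, b = b, platt = platt)
}

# Platt (2000) sigmoid fit with smoothed targets, by Newton iteration on
# (A, B) of P(y=1|d) = 1 / (1 + exp(A d + B)).
platt_fit <- function(d, ys) {
  n1 <- sum(ys > 0); n0 <- sum(ys < 0)
  t <- ifelse(ys > 0, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  A <- -1; B <- log((n0 + 1) / (n1 + 1))
  for (it in 1:100) {
    f <- A * d + B
    p <- 1 / (1 + exp(f))
    g <- p - t                       # d(loss)/d(f) with loss = -t f ... cross-entropy
    # gradient of NLL wrt (A, B); NLL = sum(t*f + log(1+exp(-f)))
    gA <- sum(g * -d); gB <- sum(-g)
    w <- p * (1 - p)
    hAA <- sum(w * d^2) + 1e-12; hBB <- sum(w) + 1e-12; hAB <- sum(w * d)
    det <- hAA * hBB - hAB^2
    if (abs(det) < 1e-12) break
    dA <- (hBB * gA - hAB * gB) / det
    dB <- (hAA * gB - hAB * gA) / det
    A <- A - dA; B <- B - dB
    if (abs(dA) + abs(dB) < 1e-10) break
  }
  c(A = A, B = B)
}

predict_svc <- function(m, X) {
  d <- drop(X %*% m$w) + m$b
  1 / (1 + exp(m$platt["A"] * d + m$platt["B"]))
}
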