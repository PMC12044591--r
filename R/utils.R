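# Internal numeric helpers shared across modules.

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves min ||A x - b||_2 subject to x >= 0. Used by MCR-ALS and the
#' residual-scaling step of the spectral matcher.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector (length m).
#' @return numeric vector x of length n, all entries >= 0.
#' @keywords internal
#' @noRd
nnls_solve <- function(A, b) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b - A %*% x))
  tol <- 10 * .Machine$double.eps * sum(abs(A)) * max(dim(A))
  iter <- 0L
  max_iter <- 3L * n
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      Ap <- A[, passive, drop = FALSE]
      s <- numeric(n)
      sp <- tryCatch(
        drop(solve(crossprod(Ap), crossprod(Ap, b))),
        error = function(e) rep(0, sum(passive))
      )
      s[passive] <- sp
      if (all(sp > tol)) {
        x <- s
        break
      }
      neg <- passive & (s <= tol)
      alpha <- min(x[neg] / (x[neg] - s[neg] + .Machine$double.eps))
      x <- x + alpha * (s - x)
      passive[passive] <- x[passive] > tol
      if (!any(passive)) {
        x <- numeric(n)
        break
      }
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

#' Flat Dirichlet draw via normalized exponentials
#' @noRd
rdirichlet_flat <- function(k) {
  g <- stats::rexp(k)
  g / sum(g)
}

#' Trapezoidal integral of y over x
#' @noRd
trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (utils::head(y, -1L) + utils::tail(y, -1L)) / 2)
}

#' Savitzky-Golay convolution coefficients
#'
#' Least-squares local polynomial filter coefficients for smoothing
#' (`deriv = 0`) or differentiation.
#'
#' @param window odd integer, number of points.
#' @param order polynomial order, < window.
#' @param deriv derivative order.
#' @return numeric vector of length `window`.
#' @keywords internal
#' @noRd
sg_coefficients <- function(window, order, deriv = 0L) {
  stopifnot(window %% 2L == 1L, order < window, deriv <= order)
  h <- (window - 1L) %/% 2L
  x <- seq(-h, h)
  A <- outer(x, 0:order, `^`)
  # row `deriv` of the pseudo-inverse, scaled by deriv!
  G <- solve(crossprod(A), t(A))
  G[deriv + 1L, ] * factorial(deriv)
}

#' Savitzky-Golay filter with polynomial edge handling
#'
#' @param y numeric vector.
#' @param window odd window length (shrunk if `length(y)` is small).
#' @param order polynomial order.
#' @param deriv derivative order; for `deriv > 0` the result is scaled by
#'   `1 / dx^deriv` if a spacing `dx` is given.
#' @param dx sample spacing (default 1).
#' @return filtered vector, same length as `y`.
#' @keywords internal
#' @noRd
savitzky_golay <- function(y, window = 11L, order = 2L, deriv = 0L, dx = 1) {
  n <- length(y)
  if (n < 3L) {
    if (deriv == 0L) return(y)
    return(rep(0, n))
  }
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window > n) window <- if (n %% 2L == 1L) n else n - 1L
  if (order >= window) order <- window - 1L
  h <- (window - 1L) %/% 2L
  cc <- sg_coefficients(window, order, deriv)
  mid <- stats::filter(y, rev(cc), sides = 2L)
  out <- as.numeric(mid)
  # edges: fit the polynomial on the first/last window and evaluate it there
  x_loc <- seq_len(window) - 1L
  fit_edge <- function(yy) {
    A <- outer(x_loc, 0:order, `^`)
    stats::lm.fit(A, yy)$coefficients
  }
  cf_l <- fit_edge(y[seq_len(window)])
  cf_r <- fit_edge(y[(n - window + 1L):n])
  poly_eval <- function(cf, x, d) {
    ord <- length(cf) - 1L
    if (d > ord) return(rep(0, length(x)))
    val <- numeric(length(x))
    for (p in d:ord) {
      co <- cf[p + 1L]
      if (is.na(co)) next
      val <- val + co * factorial(p) / factorial(p - d) * x^(p - d)
    }
    val
  }
  out[seq_len(h)] <- poly_eval(cf_l, x_loc[seq_len(h)], deriv)
  out[(n - h + 1L):n] <- poly_eval(cf_r, x_loc[(window - h + 1L):window] - 0, deriv)
  if (deriv > 0L && dx != 1) out <- out / dx^deriv
  out
}

#' Replace masked points by linear interpolation across the gap
#'
#' Derivative filters have finite support, so values inside masked windows
#' would otherwise bleed into the derivatives of nearby unmasked points.
#' Bridging the gaps makes every derivative a pure function of unmasked
#' data, preserving the mask-exclusion invariant.
#' @noRd
bridge_masked <- function(x, mask) {
  if (all(mask)) return(x)
  idx <- which(mask)
  out <- x
  out[!mask] <- stats::approx(idx, x[idx], xout = which(!mask), rule = 2)$y
  out
}

#' Seed helper: evaluate an expression under a local RNG seed
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
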