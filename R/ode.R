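#' Adaptive Runge-Kutta integration (pure R reference)
#'
#' A plain-R Dormand-Prince 5(4) integrator with proportional step
#' control. It is the package's reference path: slow but transparent, used
#' to cross-check the compiled production integrator and to integrate the
#' two-dimensional minimal model, where speed is irrelevant.
#'
#' @param f Derivative function `f(t, y, ...)` returning `dy/dt`.
#' @param y0 Initial state vector.
#' @param times Strictly increasing output times; integration starts at
#'   `times[1]`.
#' @param ... Further arguments passed to `f`.
#' @param rtol,atol Relative and absolute local error tolerances.
#' @param hmax Maximum step size.
#' @return Matrix with `length(times)` rows and `length(y0)` columns.
#' @export
rk45 <- function(f, y0, times, ..., rtol = 1e-9, atol = 1e-9, hmax = 1) {
  stopifnot(length(times) >= 1, all(diff(times) > 0))
  n <- length(y0)
  out <- matrix(NA_real_, length(times), n)
  out[1, ] <- y0

  # Dormand-Prince tableau
  A <- list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(44 / 45, -56 / 15, 32 / 9),
    c(19372 / 6561, -25360 / 2187, 64448 / 6561, -212 / 729),
    c(9017 / 3168, -355 / 33, 46732 / 5247, 49 / 176, -5103 / 18656),
    c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84))
  cs <- c(1 / 5, 3 / 10, 4 / 5, 8 / 9, 1, 1)
  b5 <- c(35 / 384, 0, 500 / 1113, 125 / 192, -2187 / 6784, 11 / 84, 0)
  b4 <- c(5179 / 57600, 0, 7571 / 16695, 393 / 640, -92097 / 339200,
          187 / 2100, 1 / 40)

  y <- y0
  t <- times[1]
  h <- min(hmax, 1e-2)
  k <- vector("list", 7)
  k1_fresh <- FALSE

  for (idx in seq_along(times)[-1]) {
    tend <- times[idx]
    while (t < tend) {
      h <- min(h, hmax, tend - t)
      if (h < 1e-14) stop("rk45: step size underflow at t = ", t)
      if (!k1_fresh) k[[1]] <- f(t, y, ...)
      for (s in 1:6) {
        ys <- y
        for (j in seq_len(s)) ys <- ys + h * A[[s]][j] * k[[j]]
        k[[s + 1]] <- f(t + cs[s] * h, ys, ...)
      }
      y5 <- y
      y4 <- y
      for (j in 1:7) {
        y5 <- y5 + h * b5[j] * k[[j]]
        y4 <- y4 + h * b4[j] * k[[j]]
      }
      sc <- atol + rtol * pmax(abs(y), abs(y5))
      err <- sqrt(mean(((y5 - y4) / sc)^2))
      if (err <= 1) {
        t <- t + h
        y <- y5
        k[[1]] <- k[[7]] # FSAL
        k1_fresh <- TRUE
        h <- h * min(5, 0.9 * max(err, 1e-30)^-0.2)
      } else {
        h <- h * max(0.1, 0.9 * err^-0.2)
      }
    }
    out[idx, ] <- y
  }
  out
}

#' Fixed-step explicit Euler integration
#'
#' Deliberately naive integrator used as an independent numerical oracle
#' in the test-suite: with a small enough step it brackets the production
#' integrator without sharing any code with it.
#'
#' @inheritParams rk45
#' @param h Fixed step size; output times must be (near-)multiples of `h`.
#' @return Matrix with `length(times)` rows.
#' @export
euler <- function(f, y0, times, ..., h = 1e-4) {
  stopifnot(h > 0, length(times) >= 1, all(diff(times) > 0))
  out <- matrix(NA_real_, length(times), length(y0))
  out[1, ] <- y0
  y <- y0
  t <- times[1]
  for (idx in seq_along(times)[-1]) {
    nstep <- round((times[idx] - t) / h)
    for (i in seq_len(nstep)) {
      y <- y + h * f(t, y, ...)
      t <- t + h
    }
    out[idx, ] <- y
  }
  out
}
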