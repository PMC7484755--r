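# Mono-exponential T2 relaxometry: y(t) = A * exp(-t / T2), fit per voxel by
# unweighted nonlinear least squares. The log-linear fit is used only to
# initialize (log-domain noise distortion biases T2 if used as the estimate);
# the refinement is a Levenberg-Marquardt iteration vectorized across voxels,
# with the 2x2 damped normal equations solved in closed form.

# Y: nvox x n_echo matrix; returns list of per-voxel vectors
fit_decay_matrix <- function(Y, echo_times, t2_min = 1, t2_max = 2000,
                             floor = NULL, max_iter = 80L, tol = 1e-11) {
  t <- as.numeric(echo_times)
  ne <- length(t)
  nv <- nrow(Y)
  floor <- floor %||% (max(abs(Y), 1) * .Machine$double.eps)
  ok <- rowSums(Y <= 0) == 0L  # voxels needing the log floor are not fittable

  # log-linear initialization
  ly <- log(pmax(Y, floor))
  tc <- t - mean(t)
  slope <- as.vector(ly %*% tc) / sum(tc^2)
  T2 <- ifelse(slope < 0, -1 / slope, t2_max)
  T2 <- pmin(pmax(T2, t2_min), t2_max)
  A <- exp(rowMeans(ly) - slope * mean(t))
  A[!is.finite(A) | A <= 0] <- 1

  lambda <- rep(1e-3, nv)
  converged <- rep(FALSE, nv)
  E <- exp(-outer(1 / T2, t))
  r <- Y - A * E
  sse <- rowSums(r^2)
  for (it in seq_len(max_iter)) {
    J2 <- E * outer(A / T2^2, t)
    g11 <- rowSums(E * E)
    g12 <- rowSums(E * J2)
    g22 <- rowSums(J2 * J2)
    b1 <- rowSums(E * r)
    b2 <- rowSums(J2 * r)
    h11 <- g11 * (1 + lambda)
    h22 <- g22 * (1 + lambda)
    det <- h11 * h22 - g12^2
    det[det <= 0 | !is.finite(det)] <- NA
    dA <- (h22 * b1 - g12 * b2) / det
    dT2 <- (h11 * b2 - g12 * b1) / det
    bad <- !is.finite(dA) | !is.finite(dT2)
    dA[bad] <- 0; dT2[bad] <- 0
    A_new <- pmax(A + dA, 0)
    T2_new <- pmin(pmax(T2 + dT2, t2_min), t2_max)
    E_new <- exp(-outer(1 / T2_new, t))
    r_new <- Y - A_new * E_new
    sse_new <- rowSums(r_new^2)
    accept <- is.finite(sse_new) & (sse_new <= sse) & !bad
    step <- pmax(abs(dA) / (abs(A) + 1e-12), abs(dT2) / (abs(T2) + 1e-12))
    converged <- converged | (accept & step < tol)
    A[accept] <- A_new[accept]
    T2[accept] <- T2_new[accept]
    E[accept, ] <- E_new[accept, , drop = FALSE]
    r[accept, ] <- r_new[accept, , drop = FALSE]
    sse[accept] <- sse_new[accept]
    lambda <- ifelse(accept, pmax(lambda / 3, 1e-12), pmin(lambda * 5, 1e12))
    if (all(converged | !ok)) break
  }
  eps_b <- 1e-9
  at_bound <- T2 >= t2_max * (1 - eps_b) | T2 <= t2_min * (1 + eps_b)
  valid <- ok & converged & !at_bound & is.finite(T2) & is.finite(A) & A > 0
  list(a_hat = A, t2_hat = T2, sse = sse, valid = valid)
}

#' Fit one voxel's multi-echo decay
#'
#' Estimates amplitude and T2 of `y = A exp(-t/T2)` for a single voxel by
#' log-linear initialization followed by nonlinear least squares. The fit is
#' flagged invalid when any signal is non-positive (the log initialization
#' would need flooring), when the T2 estimate pins to the `[t2_min, t2_max]`
#' bounds (e.g. a non-decaying signal), or when the solver fails to converge.
#'
#' @param signal signal values at each echo, same length as `echo_times`.
#' @param echo_times strictly increasing echo times, ms (>= 3).
#' @param t2_bounds admissible T2 interval, ms.
#' @return A list of class `voxel_fit`: `a_hat`, `t2_hat` (ms), `sse`, `valid`.
#' @export
fit_voxel_decay <- function(signal, echo_times, t2_bounds = c(1, 2000)) {
  if (length(signal) != length(echo_times))
    stopf("signal has %d values but echo_times has %d", length(signal),
          length(echo_times))
  if (length(echo_times) < 3L)
    stopf("at least 3 echoes are required, got %d", length(echo_times))
  if (any(diff(echo_times) <= 0)) stopf("`echo_times` must be strictly increasing")
  f <- fit_decay_matrix(matrix(as.numeric(signal), nrow = 1L), echo_times,
                        t2_min = t2_bounds[1], t2_max = t2_bounds[2])
  structure(list(a_hat = f$a_hat, t2_hat = f$t2_hat, sse = f$sse,
                 valid = f$valid), class = "voxel_fit")
}

#' Reconstruct a T2 map from a multi-echo series
#'
#' Applies [fit_voxel_decay()] independently to every voxel of the stack
#' (vectorized internally). Invalid voxels carry `NA` in the `t2` and `a`
#' fields and are excluded from every downstream ROI statistic.
#'
#' @param series an `echo_series` (see [generate_phantom()]); `data` is a
#'   `(echo, slice, row, col)` array.
#' @param t2_bounds admissible T2 interval, ms.
#' @param floor positive floor applied to signals before the log-linear
#'   initialization; defaults to a machine-epsilon multiple of the signal peak.
#' @return An object of class `t2_map`: arrays `t2`, `a`, `valid` over
#'   `(slice, row, col)`, plus `pixel_size` (mm) and `n_invalid`.
#' @export
reconstruct_t2_map <- function(series, t2_bounds = c(1, 2000), floor = NULL) {
  stopifnot(inherits(series, "echo_series"))
  d <- dim(series$data)
  ne <- d[1]
  spatial <- d[-1]
  Y <- t(matrix(series$data, nrow = ne))
  f <- fit_decay_matrix(Y, series$echo_times, t2_min = t2_bounds[1],
                        t2_max = t2_bounds[2], floor = floor)
  t2 <- array(ifelse(f$valid, f$t2_hat, NA_real_), spatial)
  a <- array(ifelse(f$valid, f$a_hat, NA_real_), spatial)
  valid <- array(f$valid, spatial)
  n_invalid <- sum(!f$valid)
  if (n_invalid > 0L)
    warning(sprintf("%d of %d voxels had invalid T2 fits", n_invalid, nrow(Y)),
            call. = FALSE)
  structure(list(t2 = t2, a = a, valid = valid,
                 pixel_size = series$pixel_size, n_invalid = n_invalid),
            class = "t2_map")
}
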