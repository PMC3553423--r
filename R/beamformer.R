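#' Construct a sensor array
#'
#' Point-magnetometer geometry: each sensor has a position and a unit
#' sensing orientation in the head frame (meters, right-handed).
#'
#' @param positions M x 3 numeric matrix of sensor positions (m).
#' @param orientations M x 3 numeric matrix of sensing directions; rows are
#'   normalized to unit length (an error is raised if a row is near zero).
#' @param names Optional character vector of M channel labels.
#' @return Object of class `sensor_array` with fields `positions`,
#'   `orientations`, `names`.
#' @export
sensor_array <- function(positions, orientations, names = NULL) {
  positions <- as.matrix(positions)
  orientations <- as.matrix(orientations)
  if (ncol(positions) != 3L || ncol(orientations) != 3L ||
      nrow(positions) != nrow(orientations))
    stop("'positions' and 'orientations' must be M x 3 matrices of equal M")
  M <- nrow(positions)
  if (M < 3L) stop("a sensor array needs at least 3 sensors")
  nrm <- sqrt(rowSums(orientations^2))
  if (any(nrm < 1e-12)) stop("orientation rows must be nonzero")
  orientations <- orientations / nrm
  dimnames(positions) <- NULL
  dimnames(orientations) <- NULL
  if (is.null(names)) names <- sprintf("MEG%03d", seq_len(M))
  if (length(names) != M) stop("'names' must have one label per sensor")
  structure(list(positions = positions, orientations = orientations,
                 names = names),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d point magnetometers\n", nrow(x$positions)))
  invisible(x)
}

#' Homogeneous conducting-sphere head model
#'
#' @param center 3-vector, sphere center in meters (head frame).
#' @param radius Sphere radius in meters; bounds the source domain.  The
#'   external field of the sphere model does not depend on the radius, only
#'   on the center.
#' @return Object of class `sphere_model`.
#' @export
sphere_model <- function(center = c(0, 0, 0), radius = 0.08) {
  center <- as.numeric(center)
  if (length(center) != 3L) stop("'center' must be a 3-vector (m)")
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("'radius' must be a positive number (m)")
  structure(list(center = center, radius = radius), class = "sphere_model")
}

#' Sensor covariance of a multichannel segment
#'
#' `C = (1/n) * sum_k M(k) M(k)^T` after per-channel mean removal, with
#' optional diagonal loading `C + lambda * (trace(C)/M) * I` to guarantee a
#' well-conditioned inverse (the orientation eigensystem uses `C^-2`).
#'
#' @param x A `sampled_signal` (channels in columns) or samples x channels
#'   matrix.
#' @param loading Diagonal-loading fraction `lambda` (default 0; 5e-3 is a
#'   reasonable choice for nearly rank-deficient data).
#' @return Object of class `meg_covariance`: list with `C` (M x M),
#'   `n_samples`, `loading`, and `rank_deficient` flag (TRUE when
#'   `n_samples < M`).
#' @export
compute_covariance <- function(x, loading = 0) {
  vals <- if (inherits(x, "sampled_signal")) x$values else as.matrix(x)
  if (!is.numeric(vals) || any(!is.finite(vals)))
    stop("segment values must be finite")
  n <- nrow(vals)
  if (n < 2L) stop("need at least 2 samples to estimate a covariance")
  if (!is.numeric(loading) || length(loading) != 1L || loading < 0)
    stop("'loading' must be a nonnegative fraction")
  M <- ncol(vals)
  centered <- sweep(vals, 2L, colMeans(vals))
  C <- crossprod(centered) / n
  if (loading > 0) {
    mean_diag <- sum(diag(C)) / M
    C <- C + loading * mean_diag * diag(M)
  }
  structure(list(C = C, n_samples = n, loading = loading,
                 rank_deficient = n < M),
            class = "meg_covariance")
}

#' @export
print.meg_covariance <- function(x, ...) {
  cat(sprintf("<meg_covariance> %d x %d from %d samples (loading %g)%s\n",
              nrow(x$C), ncol(x$C), x$n_samples, x$loading,
              if (x$rank_deficient) " [rank deficient]" else ""))
  invisible(x)
}

cov_matrix <- function(C) {
  if (inherits(C, "meg_covariance")) C$C else as.matrix(C)
}

# Moore-Penrose inverse of a small symmetric matrix
pinv3 <- function(A, tol = 1e-10) {
  es <- eigen((A + t(A)) / 2, symmetric = TRUE)
  keep <- abs(es$values) > tol * max(abs(es$values))
  es$vectors[, keep, drop = FALSE] %*%
    (t(es$vectors[, keep, drop = FALSE]) / es$values[keep])
}

# Sarvas closed form: magnetic field outside a homogeneous conducting
# sphere (center at origin) from a current dipole q at r0, evaluated at
# sensor position r.  Radial dipoles and dipoles at the center are silent.
sarvas_field <- function(r0, q, r) {
  a_vec <- r - r0
  a <- sqrt(sum(a_vec^2))
  rn <- sqrt(sum(r^2))
  if (a < 1e-12) stop("field point coincides with the dipole")
  Fs <- a * (rn * a + rn^2 - sum(r0 * r))
  if (abs(Fs) < 1e-300) return(c(0, 0, 0))
  ar <- sum(a_vec * r)
  gradF <- (a^2 / rn + ar / a + 2 * a + 2 * rn) * r -
    (a + 2 * rn + ar / a) * r0
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  1e-7 * (Fs * qxr0 - sum(qxr0 * r) * gradF) / Fs^2
}

#' Lead field of a source location under the sphere model
#'
#' Returns the M x 3 matrix whose columns are the sensor outputs (field
#' projected on each sensor's orientation) for unit current dipoles along
#' the cardinal x, y, z directions at location `r`, using the closed-form
#' solution for a current dipole in a homogeneously conducting sphere.
#' Radial dipole components are magnetically silent, so the matrix has rank
#' at most 2; a source at the sphere center returns an all-zero matrix.
#'
#' @param r 3-vector source location in meters; must lie strictly inside
#'   the sphere.
#' @param sensors A `sensor_array`.
#' @param model A `sphere_model`.
#' @return M x 3 lead-field matrix in Tesla per (A m).
#' @export
sphere_leadfield <- function(r, sensors, model) {
  stopifnot(inherits(sensors, "sensor_array"), inherits(model, "sphere_model"))
  r <- as.numeric(r)
  if (length(r) != 3L) stop("'r' must be a 3-vector (m)")
  rc <- r - model$center
  if (sqrt(sum(rc^2)) >= model$radius)
    stop("source location lies outside the sphere model")
  M <- nrow(sensors$positions)
  if (sqrt(sum(rc^2)) < 1e-12) return(matrix(0, M, 3L)) # central dipole silent
  P <- sweep(sensors$positions, 2L, model$center) # sensor positions, M x 3
  A <- sweep(P, 2L, rc)                           # r - r0 per sensor
  a <- sqrt(rowSums(A^2))
  rn <- sqrt(rowSums(P^2))
  Fs <- a * (rn * a + rn^2 - drop(P %*% rc))
  ar <- rowSums(A * P)
  c1 <- a^2 / rn + ar / a + 2 * a + 2 * rn
  c2 <- a + 2 * rn + ar / a
  gradF <- c1 * P - outer(c2, rc)                 # M x 3
  # cross products e_j x r0 for the three cardinal unit dipoles
  QX <- rbind(c(0, -rc[3], rc[2]),
              c(rc[3], 0, -rc[1]),
              c(-rc[2], rc[1], 0))                # row j = e_j x r0
  dotQR <- P %*% t(QX)                            # M x 3: (e_j x r0) . r
  L <- matrix(0, M, 3L)
  for (j in 1:3) {
    Bj <- (Fs %o% QX[j, ] - dotQR[, j] * gradF) / Fs^2
    L[, j] <- 1e-7 * rowSums(Bj * sensors$orientations)
  }
  L[!is.finite(L)] <- 0
  L
}

#' SNR-optimal source orientation
#'
#' Finds the dipole orientation at a voxel that maximizes the beamformer
#' output signal-to-noise ratio `(u' L' C^-1 L u) / (u' L' C^-2 L u)` (the
#' sensor noise is assumed isotropic, so its scalar level does not affect
#' the argmax).  The optimum is the generalized eigenvector of the 3 x 3
#' pair `(L' C^-1 L, L' C^-2 L)` with the largest ratio; equivalently the
#' smallest eigenvalue of the transposed pair.  For the sphere model the
#' radial direction is silent, so the problem is solved on the rank-2
#' tangential subspace of `L`.
#'
#' When the covariance is white (isotropic SNR in every direction) the
#' problem is degenerate; the leading right-singular vector of `L` is then
#' returned so the result stays deterministic.
#'
#' @param L M x 3 lead-field matrix.
#' @param C A `meg_covariance` or M x M matrix (invertible).
#' @return Unit 3-vector; sign fixed so the largest-magnitude component is
#'   positive.
#' @export
optimal_orientation <- function(L, C) {
  Cm <- cov_matrix(C)
  Ci <- tryCatch(solve(Cm), error = function(e)
    stop("covariance is singular; increase the diagonal loading"))
  snr_orientation(L, Ci %*% L)
}

# orientation from a lead field and its precomputed C^-1 L product.
# The symmetric-definite pencil (A1, A2) is solved by Cholesky whitening of
# A2: forming A2^-1 A1 directly is numerically disastrous here because both
# matrices are dominated by the same high-SNR direction (observed relative
# eigen-spreads ~1e6 wipe out the optimum under naive solve + eigen).
snr_orientation <- function(L, CiL) {
  sv <- svd(L)
  tol <- max(sv$d) * 1e-8
  rank <- sum(sv$d > tol)
  if (rank == 0L) stop("lead field is zero; the source is silent")
  V <- sv$v[, seq_len(rank), drop = FALSE] # retained source subspace
  A1 <- crossprod(V, crossprod(L, CiL) %*% V)         # L' C^-1 L, reduced
  A2 <- crossprod(V, crossprod(CiL) %*% V)            # L' C^-2 L, reduced
  A1 <- (A1 + t(A1)) / 2
  A2 <- (A2 + t(A2)) / 2
  R <- tryCatch(chol(A2), error = function(e)
    stop("orientation eigensystem is singular; increase the diagonal loading"))
  Rin <- backsolve(R, diag(rank))
  M <- crossprod(Rin, A1 %*% Rin)                     # R^-T A1 R^-1
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (es$values[1] - es$values[rank] <= 1e-9 * max(abs(es$values))) {
    u <- V[, 1L] # isotropic SNR: leading singular direction of L
  } else {
    u <- drop(V %*% (Rin %*% es$vectors[, 1L]))
  }
  u <- u / sqrt(sum(u^2))
  imax <- which.max(abs(u))
  if (u[imax] < 0) u <- -u
  unname(u)
}

#' Minimum-variance beamformer weights
#'
#' `W = C^-1 B / (B' C^-1 B)`: the spatial filter minimizing output power
#' subject to unit gain for the forward solution `B`, so `W' B = 1`.
#'
#' @param B M-vector forward solution for the chosen orientation (T/A m).
#' @param C A `meg_covariance` or M x M invertible matrix.
#' @return Object of class `beamformer_weights`: list with `w` (M-vector)
#'   and `B`.
#' @export
compute_weights <- function(B, C) {
  B <- as.numeric(B)
  if (all(abs(B) < 1e-300)) stop("forward solution is zero (silent source)")
  Cm <- cov_matrix(C)
  CiB <- solve(Cm, B)
  denom <- sum(B * CiB)
  structure(list(w = CiB / denom, B = B), class = "beamformer_weights")
}

#' Source time series from weights
#'
#' Per-sample inner product `s(k) = w' M(k)` (units A m for MEG in Tesla).
#'
#' @param w A `beamformer_weights` or plain M-vector.
#' @param x A `sampled_signal` (channels in columns) or samples x channels
#'   matrix (with `fs` then required).
#' @param fs Sample rate, needed only when `x` is a bare matrix.
#' @return Single-channel `sampled_signal` of source moment.
#' @export
source_timeseries <- function(w, x, fs = NULL) {
  wv <- if (inherits(w, "beamformer_weights")) w$w else as.numeric(w)
  if (inherits(x, "sampled_signal")) {
    vals <- x$values; fs <- x$fs; st <- x$start_time
  } else {
    vals <- as.matrix(x); st <- 0
    if (is.null(fs)) stop("'fs' required when 'x' is a bare matrix")
  }
  if (ncol(vals) != length(wv))
    stop("weight length does not match the channel count")
  sampled_signal(drop(vals %*% wv), fs = fs, start_time = st,
                 channel_names = "source")
}

#' Source and noise power of a beamformer
#'
#' Scalar form: projected source power `w' C w` and projected sensor-noise
#' power `sigma2 * w' w` for given weights.  Vector form (`B` omitted,
#' `L` given): the 3 x 3 matrices `[L' C^-1 L]^-1` (source) and
#' `[sigma2 L' C^-2 L]^-1` (noise) over cardinal orientations.
#'
#' @param w A `beamformer_weights` or M-vector (scalar form), or an M x 3
#'   lead field (vector form).
#' @param C A `meg_covariance` or M x M matrix.
#' @param sigma2 Mean per-sensor noise power (Tesla^2), default 1.
#' @return For the scalar form, `list(source, noise, snr)`; for the vector
#'   form, `list(source, noise)` of 3 x 3 matrices.
#' @export
beamformer_power <- function(w, C, sigma2 = 1) {
  Cm <- cov_matrix(C)
  if (is.matrix(w) && ncol(w) == 3L) {
    Ci <- solve(Cm)
    A1 <- crossprod(w, Ci %*% w)
    A2 <- crossprod(Ci %*% w)
    # pseudo-inverse: sphere-model lead fields are rank 2 (silent radial
    # direction), so the 3 x 3 forms are singular by construction
    return(list(source = pinv3(A1), noise = pinv3(sigma2 * A2)))
  }
  wv <- if (inherits(w, "beamformer_weights")) w$w else as.numeric(w)
  src <- drop(crossprod(wv, Cm %*% wv))
  nse <- sigma2 * sum(wv^2)
  list(source = src, noise = nse, snr = src / nse)
}

#' Regular voxel grid inside a sphere
#'
#' Axis-aligned lattice at the given spacing, clipped to strictly interior
#' points of the sphere; ordering is x-fastest, then y, then z (matching
#' the NIfTI voxel ordering used by [write_volume()]).
#'
#' @param model A `sphere_model`.
#' @param spacing Grid spacing in meters (default 0.005).
#' @return Object of class `voxel_grid`: list with `coords` (N x 3 matrix,
#'   meters), `spacing`, `origin` (coordinate of the first lattice point),
#'   `dims` (lattice extent), and `index` (N-vector of linear lattice
#'   positions for volume assembly).
#' @export
voxel_grid <- function(model, spacing = 0.005) {
  stopifnot(inherits(model, "sphere_model"))
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("'spacing' must be a positive number (m)")
  r <- model$radius
  nside <- floor(r / spacing)
  if (2 * nside + 1 < 1 || spacing >= 2 * r)
    stop("spacing too coarse for the sphere: empty grid")
  ax <- spacing * (-nside:nside)
  dims <- rep(length(ax), 3L)
  # x fastest, then y, then z
  gx <- rep(ax, times = dims[2] * dims[3])
  gy <- rep(rep(ax, each = dims[1]), times = dims[3])
  gz <- rep(ax, each = dims[1] * dims[2])
  keep <- gx^2 + gy^2 + gz^2 < r^2
  if (!any(keep)) stop("spacing too coarse for the sphere: empty grid")
  coords <- cbind(x = gx[keep], y = gy[keep], z = gz[keep])
  coords <- sweep(coords, 2L, model$center, "+")
  structure(list(coords = coords, spacing = spacing,
                 origin = model$center - nside * spacing, dims = dims,
                 index = which(keep)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d voxels at %g mm spacing (%d x %d x %d lattice)\n",
              nrow(x$coords), 1000 * x$spacing, x$dims[1], x$dims[2], x$dims[3]))
  invisible(x)
}

#' Fit a scalar LCMV beamformer over a voxel grid
#'
#' For every voxel: compute the sphere-model lead field, the SNR-optimal
#' dipole orientation, the minimum-variance weights with unit gain, and the
#' projected source power, noise power and their ratio (pseudo-SNR).  This
#' is the spatial-filtering front end for entropy or power mapping: apply
#' [predict.lcmv()] to obtain per-voxel source time series.
#'
#' @param x A `sampled_signal` (channels in columns) holding the segment
#'   from which the covariance is estimated.
#' @param sensors A `sensor_array` matching the channels of `x`.
#' @param model A `sphere_model`.
#' @param grid A `voxel_grid` (default: 5 mm grid inside `model`).
#' @param loading Diagonal-loading fraction for the covariance (default
#'   5e-3).
#' @param sigma2 Per-sensor noise power in Tesla^2 for the noise map; if
#'   `NULL`, estimated as the smallest covariance eigenvalue.
#' @return Object of class `lcmv`: list with `weights` (N x M), `orient`
#'   (N x 3), `power`, `noise`, `snr` (N-vectors), `grid`, `cov`,
#'   `sensors`, `model`, `sigma2`.
#' @examples
#' \donttest{
#' sens <- helmet_array(60, radius = 0.12)
#' mod <- sphere_model(radius = 0.07)
#' src <- source_script(position = c(0.02, 0, 0.04), orientation = c(0, 1, 0),
#'                      segments = regime_segments(noise = c(0, 10)))
#' sim <- simulate_meg(list(src), sens, mod, noise_sd = 2e-14,
#'                     fs = 600, duration = 10, seed = 1)
#' fit <- lcmv_beamform(sim$data, sens, mod, voxel_grid(mod, 0.02))
#' summary(fit)
#' }
#' @export
lcmv_beamform <- function(x, sensors, model, grid = NULL, loading = 5e-3,
                          sigma2 = NULL) {
  stopifnot(inherits(x, "sampled_signal"), inherits(sensors, "sensor_array"),
            inherits(model, "sphere_model"))
  if (ncol(x$values) != nrow(sensors$positions))
    stop("channel count of the data does not match the sensor array")
  if (is.null(grid)) grid <- voxel_grid(model, 0.005)
  cv <- compute_covariance(x, loading = loading)
  Cm <- cv$C
  Ci <- solve(Cm)
  if (is.null(sigma2)) sigma2 <- min(eigen(Cm, symmetric = TRUE,
                                           only.values = TRUE)$values)
  N <- nrow(grid$coords)
  M <- nrow(sensors$positions)
  weights <- matrix(0, N, M)
  orient <- matrix(0, N, 3L)
  power <- noise <- numeric(N)
  for (v in seq_len(N)) {
    L <- sphere_leadfield(grid$coords[v, ], sensors, model)
    if (max(abs(L)) < 1e-300) { # silent voxel (e.g., sphere center)
      power[v] <- 0; noise[v] <- NA_real_
      next
    }
    u <- snr_orientation(L, Ci %*% L)
    B <- drop(L %*% u)
    CiB <- Ci %*% B
    wv <- drop(CiB) / drop(crossprod(B, CiB))
    weights[v, ] <- wv
    orient[v, ] <- u
    power[v] <- drop(crossprod(wv, Cm %*% wv))
    noise[v] <- sigma2 * sum(wv^2)
  }
  structure(list(weights = weights, orient = orient, power = power,
                 noise = noise, snr = power / noise, grid = grid, cov = cv,
                 sensors = sensors, model = model, sigma2 = sigma2),
            class = "lcmv")
}

#' @export
print.lcmv <- function(x, ...) {
  cat(sprintf("<lcmv> scalar beamformer: %d voxels, %d sensors\n",
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' @export
summary.lcmv <- function(object, ...) {
  pk <- which.max(object$snr) # noise-normalized power localizes best
  out <- list(n_voxels = nrow(object$weights),
              n_sensors = ncol(object$weights),
              peak_voxel = object$grid$coords[pk, ],
              peak_power = object$power[pk],
              peak_orient = object$orient[pk, ],
              peak_snr = object$snr[pk])
  class(out) <- "summary.lcmv"
  out
}

#' @export
print.summary.lcmv <- function(x, ...) {
  cat(sprintf("Scalar LCMV beamformer over %d voxels (%d sensors)\n",
              x$n_voxels, x$n_sensors))
  cat(sprintf("  pseudo-Z peak at (%.3f, %.3f, %.3f) m, power %.3e (A m)^2\n",
              x$peak_voxel[1], x$peak_voxel[2], x$peak_voxel[3], x$peak_power))
  cat(sprintf("  orientation (%.3f, %.3f, %.3f), pseudo-SNR %.2f\n",
              x$peak_orient[1], x$peak_orient[2], x$peak_orient[3], x$peak_snr))
  invisible(x)
}

#' Source time series at fitted voxels
#'
#' Applies the fitted weights to (new) sensor data.
#'
#' @param object An `lcmv` fit.
#' @param newdata A `sampled_signal` with the same channels; defaults to
#'   the data the covariance was computed from is NOT retained, so
#'   `newdata` is required.
#' @param voxels Integer indices of voxels to reconstruct (default: the
#'   voxel with maximal noise-normalized power).
#' @param ... Unused.
#' @return A `sampled_signal` with one channel per requested voxel.
#' @export
predict.lcmv <- function(object, newdata, voxels = NULL, ...) {
  stopifnot(inherits(newdata, "sampled_signal"))
  if (is.null(voxels)) voxels <- which.max(object$snr)
  W <- object$weights[voxels, , drop = FALSE]
  if (ncol(newdata$values) != ncol(W))
    stop("channel count of 'newdata' does not match the fit")
  out <- newdata$values %*% t(W)
  sampled_signal(out, fs = newdata$fs, start_time = newdata$start_time,
                 channel_names = paste0("voxel", voxels))
}

#' @export
coef.lcmv <- function(object, ...) object$weights

#' @export
plot.lcmv <- function(x, what = c("power", "snr"), slice = NULL, ...) {
  what <- match.arg(what)
  vals <- x[[what]]
  z <- x$grid$coords[, 3]
  if (is.null(slice)) slice <- z[which.max(vals)]
  keep <- abs(z - slice) < x$grid$spacing / 2
  graphics::plot(x$grid$coords[keep, 1], x$grid$coords[keep, 2],
                 pch = 15, cex = 1.2,
                 col = grDevices::hcl.colors(64, "viridis")[
                   cut(vals[keep], 64, labels = FALSE)],
                 xlab = "x (m)", ylab = "y (m)",
                 main = sprintf("%s, z = %.3f m", what, slice), ...)
  invisible(x)
}
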