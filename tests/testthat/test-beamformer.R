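test_that("covariance matches hand computation and is symmetric PSD", {
  seg <- matrix(c(1, 0, -1, 0), 2, 2, byrow = TRUE)
  C <- compute_covariance(seg)
  expect_equal(C$C, matrix(c(1, 0, 0, 0), 2, 2))
  expect_false(C$rank_deficient)

  z <- compute_covariance(matrix(0, 10, 3))
  expect_equal(z$C, matrix(0, 3, 3))

  set.seed(2)
  X <- matrix(rnorm(200), 40, 5)
  C2 <- compute_covariance(X)$C
  expect_equal(C2, t(C2))
  expect_true(all(eigen(C2, symmetric = TRUE, only.values = TRUE)$values > -1e-12))
  # diagonal loading adds loading * mean(diag) to the diagonal
  C3 <- compute_covariance(X, loading = 0.1)$C
  expect_equal(diag(C3) - diag(C2), rep(0.1 * mean(diag(C2)), 5))
  expect_error(compute_covariance(X[1, , drop = FALSE]))
})

test_that("sphere lead field: silent center, silent radial dipoles", {
  sens <- tiny_helmet(40)
  model <- std_sphere()
  expect_equal(sphere_leadfield(c(0, 0, 0), sens, model), matrix(0, 40, 3))
  for (r0 in list(c(0.02, 0.02, 0.045), c(-0.03, 0.01, 0.02), c(0, 0, 0.06))) {
    L <- sphere_leadfield(r0, sens, model)
    radial <- r0 / sqrt(sum(r0^2))
    expect_lt(max(abs(L %*% radial)), 1e-15 * max(abs(L)))
  }
  expect_error(sphere_leadfield(c(0.1, 0, 0), sens, model), "outside")
})

test_that("sphere lead field matches independent closed-form routes", {
  sens <- tiny_helmet(50)
  model <- std_sphere()
  r0 <- c(0.025, -0.01, 0.04)
  q <- tangential_at(r0, c(1, 0.3, 0))
  B <- drop(sphere_leadfield(r0, sens, model) %*% q)
  # Oracle 1: for radially oriented sensors the conductor contributes no
  # field, so the output equals the free-space current-dipole law.
  free_dipole <- function(r0, q, r) {
    a <- r - r0
    1e-7 * c(q[2] * a[3] - q[3] * a[2],
             q[3] * a[1] - q[1] * a[3],
             q[1] * a[2] - q[2] * a[1]) / sum(a^2)^1.5
  }
  Bo <- vapply(seq_len(50), function(m) {
    p <- sens$positions[m, ]
    sum(free_dipole(r0, q, p) * p / sqrt(sum(p^2)))
  }, numeric(1))
  expect_equal(B, Bo, tolerance = 1e-12)
  # Oracle 2: full vector field against the scalar-form evaluation with a
  # numerical gradient of the potential term F.
  Ffun <- function(r) {
    a <- r - r0
    sqrt(sum(a^2)) * (sqrt(sum(r^2)) * sqrt(sum(a^2)) + sum(r^2) - sum(r0 * r))
  }
  r <- sens$positions[7, ]
  eps <- 1e-8
  gradF <- vapply(1:3, function(i) {
    dr <- numeric(3); dr[i] <- eps
    (Ffun(r + dr) - Ffun(r - dr)) / (2 * eps)
  }, numeric(1))
  qxr0 <- c(q[2] * r0[3] - q[3] * r0[2],
            q[3] * r0[1] - q[1] * r0[3],
            q[1] * r0[2] - q[2] * r0[1])
  Bnum <- 1e-7 * (Ffun(r) * qxr0 - sum(qxr0 * r) * gradF) / Ffun(r)^2
  expect_equal(drop(rventropy:::sarvas_field(r0, q, r)), Bnum,
               tolerance = 1e-6)
})

test_that("orientation maximizes SNR: eigen route agrees with brute force", {
  ses <- dipole_session(seed = 21, duration = 30)
  C <- compute_covariance(ses$sim$data, loading = 5e-3)
  L <- sphere_leadfield(ses$r0, ses$sensors, ses$model)
  u <- optimal_orientation(L, C)
  expect_equal(sum(u^2), 1, tolerance = 1e-12)
  # brute-force 1-D search over the tangential plane
  radial <- ses$r0 / sqrt(sum(ses$r0^2))
  t1 <- ses$q
  t2 <- c(radial[2] * t1[3] - radial[3] * t1[2],
          radial[3] * t1[1] - radial[1] * t1[3],
          radial[1] * t1[2] - radial[2] * t1[1])
  th <- seq(0, pi, length.out = 3601)
  snr <- vapply(th, function(a) {
    uu <- cos(a) * t1 + sin(a) * t2
    B <- drop(L %*% uu)
    w <- compute_weights(B, C)$w
    sum(w * (C$C %*% w)) / sum(w^2)
  }, numeric(1))
  ubest <- cos(th[which.max(snr)]) * t1 + sin(th[which.max(snr)]) * t2
  expect_lt(acos(min(1, abs(sum(u * ubest)))) * 180 / pi, 0.1)
  # and the recovered orientation is close to the simulated one
  expect_lt(acos(min(1, abs(sum(u * ses$q)))) * 180 / pi, 5)
})

test_that("white covariance is degenerate and handled deterministically", {
  sens <- tiny_helmet(40)
  model <- std_sphere()
  L <- sphere_leadfield(c(0.02, 0.01, 0.03), sens, model)
  u1 <- optimal_orientation(L, diag(40))
  u2 <- optimal_orientation(L, diag(40))
  expect_identical(u1, u2)
  expect_equal(sum(u1^2), 1, tolerance = 1e-12)
  # returned direction is tangential (lies in the lead-field row space)
  radial <- c(0.02, 0.01, 0.03) / sqrt(sum(c(0.02, 0.01, 0.03)^2))
  expect_lt(abs(sum(u1 * radial)), 1e-6)
})

test_that("weights obey the closed forms and the unit-gain constraint", {
  set.seed(7)
  B <- rnorm(6)
  wI <- compute_weights(B, diag(6))
  expect_equal(wI$w, B / sum(B^2))
  d <- runif(6, 0.5, 2)
  wD <- compute_weights(B, diag(d))
  expect_equal(wD$w, (B / d) / sum(B^2 / d))
  A <- crossprod(matrix(rnorm(120), 20, 6)) / 20
  wA <- compute_weights(B, A)
  expect_equal(sum(wA$w * B), 1, tolerance = 1e-9)
  expect_error(compute_weights(numeric(6), A), "silent")
})

test_that("source series has unit gain and is linear in the data", {
  set.seed(8)
  B <- rnorm(5)
  s <- sin(2 * pi * (1:200) / 40)
  M <- outer(s, B)
  w <- compute_weights(B, crossprod(M) / 200 + 0.01 * diag(5))
  rec <- drop(as.matrix(source_timeseries(w, M, fs = 100)))
  expect_equal(rec, s, tolerance = 1e-9)
  expect_equal(drop(as.matrix(source_timeseries(w, matrix(0, 50, 5), fs = 100))),
               rep(0, 50))
  M2 <- matrix(rnorm(1000), 200, 5)
  lhs <- drop(as.matrix(source_timeseries(w, 2 * M + 3 * M2, fs = 100)))
  rhs <- 2 * rec + 3 * drop(as.matrix(source_timeseries(w, M2, fs = 100)))
  expect_equal(lhs, rhs, tolerance = 1e-12)
  expect_error(source_timeseries(w, M[, 1:4], fs = 100), "channel")
})

test_that("scalar and 3x3 power forms are consistent", {
  expect_equal(beamformer_power(compute_weights(c(1, 0, 0, 0), diag(4)),
                                diag(4))$source, 1)
  expect_equal(beamformer_power(compute_weights(c(1, 0, 0, 0), diag(4)),
                                diag(4), sigma2 = 1)$noise, 1)
  set.seed(9)
  # full-rank lead field: the 3x3 and scalar forms obey the exact identity
  L <- matrix(rnorm(90), 30, 3)
  C <- crossprod(matrix(rnorm(30 * 60), 60, 30)) / 60 + 0.1 * diag(30)
  P <- beamformer_power(L, C)
  # vector-form source power inverts L'C^-1L; the scalar form W'CW for
  # weights built from B = L u must equal 1 / (u' [P$source]^-1 u)
  u <- c(0.3, 0.9, 0.1); u <- u / sqrt(sum(u^2))
  scal <- beamformer_power(compute_weights(drop(L %*% u), C), C)$source
  expect_equal(scal, 1 / drop(t(u) %*% solve(P$source) %*% u),
               tolerance = 1e-9)
  # sphere lead fields are rank 2; the 3x3 forms use the pseudo-inverse and
  # must be finite with a silent radial null space
  sens <- tiny_helmet(30)
  Ls <- sphere_leadfield(c(0.02, 0, 0.04), sens, std_sphere())
  Ps <- beamformer_power(Ls, C)
  expect_true(all(is.finite(Ps$source)))
  radial <- c(0.02, 0, 0.04) / sqrt(sum(c(0.02, 0, 0.04)^2))
  expect_lt(max(abs(Ps$source %*% radial)), 1e-9 * max(abs(Ps$source)))
})

test_that("voxel grid matches the brute-force lattice count", {
  model <- sphere_model(radius = 0.08)
  g <- voxel_grid(model, 0.005)
  ax <- seq(-0.08, 0.08, by = 0.005)
  brute <- expand.grid(ax, ax, ax)
  n_brute <- sum(rowSums(brute^2) < 0.08^2)
  expect_equal(nrow(g$coords), n_brute)
  expect_true(any(rowSums(abs(g$coords)) < 1e-12)) # contains the center
  # x varies fastest
  expect_true(all(diff(g$coords[1:2, 1]) != 0))
  expect_error(voxel_grid(sphere_model(radius = 0.01), 0.05), "empty")
})

test_that("lcmv fit localizes a dipole and reconstructs its time course", {
  ses <- dipole_session(seed = 31, duration = 30, r0 = c(0.02, 0.02, 0.04))
  grid <- voxel_grid(ses$model, 0.01)
  fit <- lcmv_beamform(ses$sim$data, ses$sensors, ses$model, grid)
  pk <- which.max(fit$snr) # noise-normalized power map
  expect_lt(sqrt(sum((grid$coords[pk, ] - ses$r0)^2)), 0.01 + 1e-9)
  rec <- drop(as.matrix(predict(fit, ses$sim$data, voxels = pk)))
  expect_gt(abs(cor(rec, ses$sim$truth[[1]]$series)), 0.95)
})

test_that("two uncorrelated dipoles are separated with low cross-talk", {
  sens <- tiny_helmet(80)
  model <- std_sphere()
  rA <- c(0.03, 0.02, 0.04); rB <- c(-0.03, -0.02, 0.04)
  srcA <- source_script(rA, tangential_at(rA),
                        segment_spec(0, 40, "noise", 30e-9))
  srcB <- source_script(rB, tangential_at(rB, c(1, 0, 0)),
                        segment_spec(0, 40, "noise", 30e-9))
  sim <- simulate_meg(list(srcA, srcB), sens, model, noise_sd = 2e-14,
                      fs = 600, duration = 40, seed = 17)
  C <- compute_covariance(sim$data, loading = 5e-3)
  rec_at <- function(r) {
    L <- sphere_leadfield(r, sens, model)
    w <- compute_weights(drop(L %*% optimal_orientation(L, C)), C)
    drop(as.matrix(source_timeseries(w, sim$data)))
  }
  a <- rec_at(rA); b <- rec_at(rB)
  expect_gt(abs(cor(a, sim$truth[[1]]$series)), 0.9)
  expect_gt(abs(cor(b, sim$truth[[2]]$series)), 0.9)
  expect_lt(abs(cor(a, sim$truth[[2]]$series)), 0.2)
  expect_lt(abs(cor(b, sim$truth[[1]]$series)), 0.2)
})
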