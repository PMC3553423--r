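test_that("lag follows the bandwidth rule with ceiling rounding", {
  expect_identical(compute_lag(600, 100), 3L)
  expect_identical(compute_lag(600, 150), 2L)
  expect_identical(compute_lag(600, 300), 1L)
  expect_identical(compute_lag(1000, 80), 7L) # 6.25 rounds up
  expect_error(compute_lag(600, 301), "Nyquist")
  expect_error(compute_lag(600, 0))
})

test_that("rank encoding assigns rank 1 to the largest value, stable on ties", {
  expect_identical(rank_encode(c(4.07, -3.12, 3.95, 8.51, -1.21)),
                   c(2L, 5L, 3L, 1L, 4L))
  expect_identical(rank_encode(c(5, 4, 3, 2, 1)), 1:5)
  expect_identical(rank_encode(c(1.0, 1.0, 0.0, 2.0, -1.0)),
                   c(2L, 3L, 4L, 1L, 5L))
  expect_identical(rank_encode(rep(7, 5)), 1:5) # full tie: temporal order
  expect_error(rank_encode(c(1, NA, 3)))
  expect_error(rank_encode(c(1, Inf, 3)))
})

test_that("symbol index is the 1-based lexicographic position", {
  expect_identical(symbol_index(c(2, 5, 3, 1, 4)), 45L)
  expect_identical(symbol_index(1:5), 1L)
  expect_identical(symbol_index(5:1), 120L)
  expect_identical(symbol_index(c(2, 1, 3, 4, 5)), 25L)
  expect_error(symbol_index(c(1, 1, 2)))
})

test_that("symbol indexing is a bijection matching explicit enumeration", {
  for (W in 3:4) {
    # brute-force lexicographic enumeration as the independent oracle
    perms <- as.matrix(expand.grid(rep(list(seq_len(W)), W)))[, W:1]
    perms <- perms[apply(perms, 1L, function(p) !anyDuplicated(p)), ]
    perms <- perms[do.call(order, as.data.frame(perms)), , drop = FALSE]
    for (i in seq_len(nrow(perms))) {
      p <- as.integer(perms[i, ])
      expect_identical(symbol_index(p), i)
      expect_identical(symbol_rank_vector(i, W), p)
    }
  }
})

test_that("decay multiplier and default tau follow the stated forms", {
  expect_identical(decay_multiplier(Inf, 600), 1)
  expect_equal(decay_multiplier(0.6, 600), exp(-1 / 360))
  expect_equal(decay_multiplier(0.6, 600), 0.997226, tolerance = 1e-6)
  # alpha -> 1 monotonically as tau grows
  taus <- c(0.1, 1, 10, 100)
  expect_true(all(diff(vapply(taus, decay_multiplier, 1, fs = 600)) > 0))
  expect_error(decay_multiplier(0, 600))
  expect_error(decay_multiplier(-1, 600))
  expect_equal(default_tau(5, 600), 0.6)
  expect_equal(default_tau(3, 18), 1.0)
  expect_equal(default_tau(4, 600), 0.12)
})

test_that("histogram update decays then increments, conserving mass", {
  h <- state_histogram(5, alpha = 1)
  h <- update_histogram(h, 45)
  expect_equal(h$counts[45], 2)
  expect_equal(sum(h$counts), 121)
  expect_true(all(h$counts[-45] == 1))

  h <- state_histogram(5, alpha = 0.5)
  h <- update_histogram(h, 1)
  expect_equal(h$counts[1], 1.5)
  expect_true(all(h$counts[-1] == 0.5))
  expect_equal(sum(h$counts), 0.5 * 120 + 1) # decay all, then increment

  # repeated visits converge to the geometric-series limit 1/(1 - alpha)
  h <- state_histogram(3, alpha = 0.9)
  for (i in 1:500) h <- update_histogram(h, 4)
  expect_equal(h$counts[4], 1 / (1 - 0.9), tolerance = 1e-6)

  # mass recursion sum' = alpha * sum + 1 at every step
  h <- state_histogram(4, alpha = 0.8)
  s_prev <- sum(h$counts)
  set.seed(1)
  for (sym in sample.int(24, 50, replace = TRUE)) {
    h <- update_histogram(h, sym)
    expect_equal(sum(h$counts), 0.8 * s_prev + 1, tolerance = 1e-12)
    s_prev <- sum(h$counts)
  }
  expect_error(update_histogram(h, 25))
  expect_error(update_histogram(h, 0))
})

test_that("histogram entropy is normalized Shannon entropy", {
  expect_equal(histogram_entropy(rep(3.7, 120)), 1)
  one <- numeric(120); one[17] <- 5
  expect_equal(histogram_entropy(one), 0)
  two <- numeric(120); two[c(3, 99)] <- 2.5
  expect_equal(histogram_entropy(two), 1 / log2(120))
  expect_error(histogram_entropy(numeric(24)))
})

test_that("rve emits one value per window, trailing-sample timestamps", {
  x <- sin(2 * pi * 5 * (0:599) / 600)
  r <- rve(x, fs = 600, W = 5, fc = 100)
  span <- (5 - 1) * 3 + 1
  expect_length(r$h, 600 - span + 1)
  expect_equal(r$times[1], (span - 1) / 600)
  expect_true(all(r$h >= 0 & r$h <= 1))
  expect_equal(r$xi, 3L)
  expect_error(rve(x[1:10], fs = 600, W = 5, fc = 100), "too short")
  expect_error(rve(x, fs = 600, W = 8), "between 3 and 7")
})

test_that("ramp input concentrates mass: entropy non-increasing at alpha = 1", {
  r <- rve(seq_len(400), fs = 100, W = 4, fc = 50, tau = Inf)
  expect_true(all(diff(r$h) <= 1e-12))
  # closed-form cross-check: after k identity symbols the histogram is known
  k <- length(r$h)
  counts <- rep(1, 24); counts[1] <- 1 + k
  expect_equal(r$h[k], histogram_entropy(counts), tolerance = 1e-12)
})

test_that("positive-affine amplitude transforms leave the entropy bit-identical", {
  set.seed(10)
  x <- rnorm(3000)
  r0 <- rve(x, fs = 600, W = 5, fc = 100)
  for (ab in list(c(2.5, 3), c(1e6, -40), c(1e-7, 0))) {
    r1 <- rve(ab[1] * x + ab[2], fs = 600, W = 5, fc = 100)
    expect_identical(r0$h, r1$h)
  }
})

test_that("streaming histogram equals the from-scratch exponential-weight oracle", {
  set.seed(4)
  x <- rnorm(300)
  for (prm in list(list(W = 3L, xi = 2L, tau = 0.5),
                   list(W = 4L, xi = 1L, tau = Inf))) {
    fs <- 100
    fc <- fs / (2 * prm$xi)
    r <- rve(x, fs = fs, W = prm$W, fc = fc, tau = prm$tau)
    alpha <- r$alpha
    syms <- symbols_by_window(x, prm$W, prm$xi) # independent scalar route
    expect_identical(syms, r$symbols)
    nf <- factorial(prm$W)
    for (k in c(1L, 7L, length(syms))) {
      Fk <- alpha^k * rep(1, nf)
      for (j in seq_len(k)) Fk[syms[j]] <- Fk[syms[j]] + alpha^(k - j)
      expect_equal(r$h[k], histogram_entropy(Fk), tolerance = 1e-9)
    }
  }
})

test_that("iid noise drives cumulative entropy toward 1", {
  set.seed(3)
  r <- rve(rnorm(1e4), fs = 600, W = 4, fc = 300, tau = Inf)
  expect_gt(r$h[length(r$h)], 0.99)
})

test_that("tau rescales entropy fluctuations without changing the waveform", {
  set.seed(3)
  t <- (0:(80 * 600 - 1)) / 600
  x <- 3 * (1 + cos(2 * pi * 0.05 * t)) * sin(2 * pi * 7 * t) + rnorm(length(t))
  r1 <- rve(x, fs = 600, W = 5, fc = 100, tau = 0.6)
  r2 <- rve(x, fs = 600, W = 5, fc = 100, tau = 1.2)
  ok <- r1$times > 3 * 1.2
  expect_gt(cor(r1$h[ok], r2$h[ok]), 0.95)
  # shorter tau -> larger peak-to-peak entropy fluctuation
  expect_gt(sd(r1$h[ok]), sd(r2$h[ok]))
})

test_that("oscillations carry lower entropy than broadband noise", {
  set.seed(5)
  t <- (0:11999) / 600
  r_sine <- rve(sin(2 * pi * 7 * t), fs = 600, W = 5, fc = 100)
  r_noise <- rve(rnorm(length(t)), fs = 600, W = 5, fc = 100)
  ok <- !r_sine$lead_in_mask
  expect_lt(mean(r_sine$h[ok]), mean(r_noise$h[ok]))
})

test_that("constant input is valid and maps to the identity state", {
  r <- rve(rep(2, 500), fs = 100, W = 3, fc = 50)
  expect_true(all(r$symbols == 1L))
  expect_true(all(r$h >= 0 & r$h <= 1))
  expect_true(all(diff(r$h) <= 1e-12)) # mass concentrates, entropy falls
})
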