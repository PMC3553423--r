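# Shared fixtures: tiny sensor arrays and simulated dipole sessions.

tiny_helmet <- function(n = 60, radius = 0.12) helmet_array(n, radius = radius)

std_sphere <- function() sphere_model(radius = 0.08)

# tangential unit vector at position r0 closest to the hint direction
tangential_at <- function(r0, hint = c(0, 1, 0)) {
  radial <- r0 / sqrt(sum(r0^2))
  u <- hint - sum(hint * radial) * radial
  u / sqrt(sum(u^2))
}

# single broadband tangential dipole session
dipole_session <- function(seed, amplitude = 40e-9, duration = 20,
                           noise_sd = 2e-14, n_sensors = 60, fs = 600,
                           r0 = c(0.02, 0.02, 0.045)) {
  sens <- tiny_helmet(n_sensors)
  model <- std_sphere()
  q <- tangential_at(r0)
  src <- source_script(r0, q, segment_spec(0, duration, "noise", amplitude))
  sim <- simulate_meg(list(src), sens, model, noise_sd = noise_sd, fs = fs,
                      duration = duration, seed = seed)
  list(sim = sim, sensors = sens, model = model, r0 = r0, q = q)
}

# independent per-window symbol oracle (scalar route, no vectorization)
symbols_by_window <- function(x, W, xi) {
  n <- length(x) - (W - 1L) * xi
  vapply(seq_len(n), function(k)
    symbol_index(rank_encode(x[k + (0:(W - 1L)) * xi])), integer(1))
}
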