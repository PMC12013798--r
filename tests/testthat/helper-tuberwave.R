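# Shared builders for the test suite. Fixtures are generated in code; no
# files are read.

tiny_layout <- function(positions = -2:2) electrode_layout(positions)

# quick planted recording: core-to-periphery travelling spike-waves
planted_recording <- function(model = "core_to_periphery", a = 5, b = 0,
                              n_events = 10, seed = 1, jitter_sd = 2,
                              noise_sd = 10, duration_s = NULL,
                              positions = -2:2) {
  make_travelling_spike_recording(
    electrode_layout(positions),
    planted_wave_spec(model, a = a, b = b, jitter_sd = jitter_sd,
                      noise_sd_uv = noise_sd, n_events = n_events,
                      seed = seed),
    duration_s = duration_s)
}

# analytic log evidence of the conjugate linear-Gaussian model
# y = X theta + e, e ~ N(0, exp(-lambda) I), theta ~ N(mu, diag(v))
linear_evidence <- function(X, y, mu, v, lambda) {
  n <- length(y)
  P0 <- diag(1 / v, length(mu))
  Pn <- crossprod(X) * exp(lambda) + P0
  Sn <- solve(Pn)
  mn <- Sn %*% (exp(lambda) * crossprod(X, y) + P0 %*% mu)
  as.numeric(-n / 2 * log(2 * pi) + n / 2 * lambda -
    0.5 * (exp(lambda) * sum(y^2) + t(mu) %*% P0 %*% mu - t(mn) %*% Pn %*% mn) -
    0.5 * sum(log(v)) + 0.5 * determinant(Sn)$modulus)
}

# exact conjugate posterior for the same model
linear_posterior <- function(X, y, mu, v, lambda) {
  P0 <- diag(1 / v, length(mu))
  Pn <- crossprod(X) * exp(lambda) + P0
  Sn <- solve(Pn)
  mn <- as.vector(Sn %*% (exp(lambda) * crossprod(X, y) + P0 %*% mu))
  list(mean = stats::setNames(mn, names(mu)), cov = Sn)
}

# a tapered single-IED epoch simulated from a network
simulated_epoch <- function(net, noise_sd = 1, seed = 1,
                            t_ms = seq(-100, 250, by = 1)) {
  sim <- simulate_from_cmc(net, observation_noise_sd = noise_sd,
                           n_ieds = 1, seed = seed, t_ms = t_ms)
  y <- apply_hanning(sim$epochs[[1]])
  attr(y, "t_ms") <- t_ms
  y
}
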