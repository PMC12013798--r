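# Variational-Laplace inversion, free energy and Bayesian model reduction.

test_that("epoch preparation windows, baselines and tapers correctly", {
  gen <- planted_recording(n_events = 3, seed = 2, duration_s = 8)
  rec <- gen$recording
  g <- group_spikes(detect_spikes(preprocess(rec)))[[1]]
  y <- prepare_epoch(rec, g)
  expect_equal(ncol(y), 351L)                 # -100..250 ms at 1 kHz
  expect_lt(max(abs(y[, 1])), 1e-9)           # taper endpoints ~ 0
  expect_lt(max(abs(y[, 351])), 1e-9)
  expect_error(prepare_epoch(rec, 20), "overruns")
  # constant channel: all zero after baseline removal and taper
  const <- new_recording(matrix(7, 2, 2000), 1000)
  y2 <- prepare_epoch(const, 1000)
  expect_equal(max(abs(y2)), 0)
})

test_that("variance explained behaves at its fixed points and under known noise", {
  set.seed(1)
  y <- matrix(rnorm(3 * 400), 3)
  expect_equal(variance_explained(y, y)$value, 100)
  y0 <- matrix(0, 3, 400)
  expect_equal(variance_explained(y0, y)$value, 0, tolerance = 1e-6)
  # prediction = signal, data = signal + matched-variance noise -> ~50%
  sig <- matrix(sin(seq_len(5000) / 10), 1) * 2
  noise <- matrix(rnorm(5000, 0, sqrt(mean(sig^2))), 1)
  ve <- variance_explained(sig, sig + noise)
  expect_equal(ve$value, 50, tolerance = 5)
  # negative values are floored and flagged
  vneg <- variance_explained(-5 * y, y)
  expect_equal(vneg$value, 0)
  expect_true(vneg$flagged)
  expect_error(variance_explained(y0, y0), "zero-variance")
})

test_that("free energy equals the analytic evidence on a conjugate linear model", {
  set.seed(7)
  n <- 40; d <- 3
  X <- matrix(rnorm(n * d), n, d)
  theta <- c(0.5, -1, 0.25)
  lam <- log(9)
  y <- as.vector(X %*% theta) + rnorm(n, 0, 1 / 3)
  mu0 <- stats::setNames(rep(0, d), letters[1:d]); v0 <- rep(0.5, d)
  post <- linear_posterior(X, y, mu0, v0, lam)
  Fval <- free_energy(matrix(y, 1), matrix(as.vector(X %*% post$mean), 1),
                      lam, post, list(mean = mu0, var = v0), J = X)
  expect_equal(Fval$total, linear_evidence(X, y, mu0, v0, lam),
               tolerance = 1e-8)
  # posterior = prior: complexity exactly zero
  F0 <- free_energy(matrix(y, 1), matrix(as.vector(X %*% mu0), 1), lam,
                    list(mean = mu0, cov = diag(v0)),
                    list(mean = mu0, var = v0))
  expect_equal(F0$complexity, 0, tolerance = 1e-10)
  # doubling the noise precision moves the accuracy term exactly as the
  # Gaussian log-likelihood dictates (no curvature term)
  e2 <- sum((y - as.vector(X %*% mu0))^2)
  F1 <- free_energy(matrix(y, 1), matrix(as.vector(X %*% mu0), 1), lam + log(2),
                    list(mean = mu0, cov = diag(v0)),
                    list(mean = mu0, var = v0))
  expect_equal(F1$accuracy - F0$accuracy,
               n / 2 * log(2) - (2 - 1) * exp(lam) / 2 * e2,
               tolerance = 1e-8)
})

test_that("free-energy differences equal log Bayes factors on conjugate models", {
  set.seed(8)
  n <- 50
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- as.vector(X %*% c(1, 0.8, 0)) + rnorm(n, 0, 0.5)
  lam <- log(4)
  nm <- c("b0", "b1", "b2")
  ev <- function(v) linear_evidence(X, y, stats::setNames(rep(0, 3), nm), v, lam)
  Ffun <- function(v) {
    post <- linear_posterior(X, y, stats::setNames(rep(0, 3), nm), v, lam)
    free_energy(matrix(y, 1), matrix(as.vector(X %*% post$mean), 1), lam,
                post, list(mean = stats::setNames(rep(0, 3), nm), var = v),
                J = X)$total
  }
  v_full <- rep(1, 3); v_red <- c(1, 1, 1e-6)
  expect_equal(Ffun(v_full) - Ffun(v_red), ev(v_full) - ev(v_red),
               tolerance = 1e-6)
})

test_that("Bayesian model reduction is exact on conjugate problems and sane at its fixed points", {
  set.seed(9)
  n <- 30; d <- 4
  X <- matrix(rnorm(n * d), n, d)
  y <- as.vector(X %*% c(1, -0.5, 0, 0.2)) + rnorm(n, 0, 0.5)
  lam <- log(4)
  nm <- letters[1:d]
  mu0 <- stats::setNames(rep(0, d), nm); v0 <- rep(1, d)
  post <- linear_posterior(X, y, mu0, v0, lam)
  full <- list(posterior = post, priors = list(mean = mu0, var = v0),
               F = linear_evidence(X, y, mu0, v0, lam))
  # reduced = full: no change
  same <- reduce_model(full, list(mean = mu0, var = v0))
  expect_equal(same$delta_F, 0, tolerance = 1e-8)
  expect_equal(same$posterior$mean, post$mean, tolerance = 1e-10)
  # shrinking one parameter reproduces the direct conjugate evidence
  vr <- c(1, 1, 1e-6, 1)
  red <- reduce_model(full, list(mean = mu0, var = vr))
  expect_equal(red$F, linear_evidence(X, y, mu0, vr, lam), tolerance = 1e-6)
  # shrinking a parameter with posterior far from zero costs much evidence
  vr2 <- c(1e-6, 1, 1, 1)                    # true value 1
  red2 <- reduce_model(full, list(mean = mu0, var = vr2))
  expect_lt(red2$delta_F, -10)
  # non-nested specifications are refused
  expect_error(reduce_model(full, list(mean = stats::setNames(rep(0, d),
                                                              LETTERS[1:d]),
                                       var = v0)), "non-nested")
})

test_that("self-consistent inversion recovers a high-fidelity fit with monotone F", {
  net <- build_network(electrode_layout(-1:1), "recurrent", "core")
  y <- simulated_epoch(net, noise_sd = 0.5, seed = 11)
  fit <- invert_dcm(y, net)
  expect_true(fit$converged)
  expect_gt(fit$variance_explained, 99)
  expect_true(all(diff(fit$trace) >= 0))     # accepted steps never lower F
  # posterior means stay within 3 posterior SDs of the generating (prior
  # mean) values
  sds <- sqrt(diag(fit$posterior$cov))
  dev <- abs(fit$posterior$mean - fit$priors$mean) / sds
  expect_lt(stats::median(dev), 3)
  expect_true(is.finite(fit$F))
})

test_that("inversion is deterministic for identical data and settings", {
  net <- build_network(electrode_layout(-1:1), "recurrent", "core")
  y <- simulated_epoch(net, noise_sd = 1, seed = 12)
  fit1 <- invert_dcm(y, net, settings = list(max_iter = 16L))
  fit2 <- invert_dcm(y, net, settings = list(max_iter = 16L))
  expect_equal(fit1$F, fit2$F, tolerance = 1e-12)
  expect_equal(fit1$posterior$mean, fit2$posterior$mean, tolerance = 1e-12)
  expect_true(is.matrix(fit1$prediction))
})

test_that("pure-noise epochs favour switching the inputs off", {
  set.seed(13)
  y <- matrix(rnorm(3 * 351, 0, 2), 3)
  y <- apply_hanning(y)
  attr(y, "t_ms") <- seq(-100, 250)
  net <- build_network(electrode_layout(-1:1), "recurrent", "core")
  fit <- invert_dcm(y, net, settings = list(max_iter = 32L))
  pri <- fit$priors
  off <- pri
  off$mean[c("u_superficial", "u_core", "u_deep")] <- -6
  off$var[c("u_superficial", "u_core", "u_deep")] <- 1e-4
  red <- reduce_model(fit, off)
  expect_gt(red$delta_F, 0)
})

test_that("the architecture space holds exactly the six stated members", {
  space <- build_architecture_space()
  expect_length(space, 6L)
  schemes <- vapply(space, `[[`, "", "coupling_scheme")
  sites <- vapply(space, `[[`, "", "input_target")
  expect_equal(sort(unique(schemes)), c("forward_only", "recurrent"))
  expect_equal(sort(unique(sites)), c("core", "deep", "superficial"))
  expect_equal(nrow(unique(data.frame(schemes, sites))), 6L)
  # recurrent-core leaves extrinsic gains free, shrinks only off-target inputs
  rc <- space[[which(schemes == "recurrent" & sites == "core")]]
  expect_equal(rc$priors$var[["A_backward"]], 1 / 4)
  expect_lt(rc$priors$mean[["u_superficial"]], -5)
  expect_lt(rc$priors$mean[["u_deep"]], -5)
  expect_equal(rc$priors$mean[["u_core"]], 0)
  # forward-only members shrink exactly the toward-core gain
  fc <- space[[which(schemes == "forward_only" & sites == "core")]]
  expect_lt(fc$priors$mean[["A_backward"]], -5)
  expect_equal(fc$priors$var[["A_forward"]], 1 / 4)
})

test_that("the modulation space holds the seven factor subsets", {
  net <- build_network(electrode_layout(-1:1), "recurrent", "core")
  pri <- dcm_priors(net, n_ieds = 3)
  space <- build_modulation_space(pri)
  expect_length(space, 7L)
  nms <- vapply(space, `[[`, "", "name")
  expect_setequal(nms, c("F", "B", "i", "FB", "Fi", "Bi", "FBi"))
  # the F-only member shrinks B and i modulations, leaves F free
  fo <- space[[which(nms == "F")]]
  expect_equal(fo$priors$var[["mod2_F"]], 1 / 16)
  expect_equal(fo$priors$var[["mod2_B"]], 1e-4)
  expect_equal(fo$priors$var[["mod3_i"]], 1e-4)
  # the FBi member is the full model
  fbi <- space[[which(nms == "FBi")]]
  expect_equal(fbi$priors$var, pri$var)
  expect_error(build_modulation_space(dcm_priors(net)), "no modulation")
})

test_that("joint multi-IED inversion with coupling modulations runs and ranks subsets", {
  net <- build_network(electrode_layout(c(0, 1)), "recurrent", "core")
  sim <- simulate_from_cmc(net, observation_noise_sd = 1, n_ieds = 2, seed = 4)
  eps <- lapply(sim$epochs, function(e) {
    e <- apply_hanning(e); attr(e, "t_ms") <- sim$t_ms; e
  })
  fit <- invert_dcm(eps, net, settings = list(max_iter = 24L))
  expect_true(is.finite(fit$F))
  expect_gt(fit$variance_explained, 90)
  Fs <- vapply(build_modulation_space(fit$priors),
               function(m) reduce_model(fit, m$priors)$F, numeric(1))
  expect_true(all(is.finite(Fs)))
  expect_length(Fs, 7L)
})
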