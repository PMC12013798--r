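# Cross-correlation delay estimation and BIC comparison of the linear
# spatiotemporal models.

test_that("a constructed 7-sample shift is recovered as a 7 ms delay", {
  set.seed(1)
  n <- 1000
  base <- stats::filter(rnorm(n + 7), rep(1, 5), sides = 2)
  base[is.na(base)] <- 0
  x <- as.numeric(base[1:n]); y <- as.numeric(base[8:(n + 7)])
  rec <- new_recording(rbind(x, y), 1000, positions = 0:1,
                       montage = "bipolar")
  g <- structure(list(members = data.frame(channel = 1:2),
                      reference_time_ms = 500), class = "tw_spikegroup")
  d <- estimate_delays(rec, g)
  expect_equal(abs(d$pair_lag_ms[2]), 7)
  # translation invariance: shifting both channels leaves the delay unchanged
  rec2 <- new_recording(rbind(c(rep(0, 20), x[1:(n - 20)]),
                              c(rep(0, 20), y[1:(n - 20)])), 1000,
                        positions = 0:1, montage = "bipolar")
  g2 <- structure(list(members = data.frame(channel = 1:2),
                       reference_time_ms = 520), class = "tw_spikegroup")
  expect_equal(abs(estimate_delays(rec2, g2)$pair_lag_ms[2]), 7)
})

test_that("a sign-flipped shifted pair is matched at the maximum of |correlation|", {
  set.seed(2)
  n <- 1000
  base <- as.numeric(stats::filter(rnorm(n + 5), rep(1, 7), sides = 2))
  base[is.na(base)] <- 0
  rec <- new_recording(rbind(base[1:n], -base[6:(n + 5)]), 1000,
                       positions = 0:1, montage = "bipolar")
  g <- structure(list(members = data.frame(channel = 1:2),
                      reference_time_ms = 500), class = "tw_spikegroup")
  d <- estimate_delays(rec, g)
  expect_equal(abs(d$pair_lag_ms[2]), 5)
  expect_lt(d$pair_corr[2], 0)
})

test_that("noiseless planted gradients are recovered within one sample", {
  gen <- planted_recording(n_events = 3, seed = 1, jitter_sd = 0,
                           noise_sd = 0, duration_s = 8)
  rec <- gen$recording
  g <- group_spikes(detect_spikes(preprocess(rec)))[[1]]
  d <- estimate_delays(rec, g)
  expect_equal(d$t_ms[order(d$channel)], c(10, 5, 0, 5, 10), tolerance = 1)
})

test_that("zero-variance channels are skipped with a message", {
  x <- rbind(sin(1:1000 / 20), 0, sin(1:1000 / 20 + 2))
  rec <- new_recording(x, 1000, positions = -1:1, montage = "bipolar")
  g <- structure(list(members = data.frame(channel = c(1, 3)),
                      reference_time_ms = 500), class = "tw_spikegroup")
  expect_message(d <- estimate_delays(rec, g), "zero-variance")
  expect_equal(nrow(d), 2L)
})

test_that("an exact linear relation is fitted with zero residual", {
  obs <- data.frame(position = rep(-2:2, 4))
  obs$t_ms <- 3 * abs(obs$position) + 1
  f <- fit_delay_model(obs, "core_to_periphery")
  expect_equal(f$a, 3)
  expect_equal(f$b, 1)
  expect_equal(f$sigma2, 0, tolerance = 1e-20)
  expect_equal(f$k, 3L)
  expect_equal(fit_delay_model(obs, "uniform")$k, 2L)
  expect_error(fit_delay_model(data.frame(position = rep(1, 10),
                                          t_ms = rnorm(10)),
                               "core_to_periphery"), "degenerate")
})

test_that("BIC matches an independent direct computation on every fit", {
  for (m in c("uniform", "depth_to_surface", "core_to_periphery")) {
    obs <- simulate_delay_observations(m, n = 60, seed = 5)
    f <- fit_delay_model(obs, m)
    # independent route: residuals from lm.fit, Gaussian log-likelihood
    X <- switch(m, uniform = cbind(rep(1, f$n)),
                depth_to_surface = cbind(1, obs$position),
                core_to_periphery = cbind(1, abs(obs$position)))
    res <- stats::lm.fit(X, obs$t_ms)$residuals
    s2 <- mean(res^2)
    logL <- sum(stats::dnorm(res, 0, sqrt(s2), log = TRUE))
    expect_equal(f$log_likelihood, logL, tolerance = 1e-8)
    expect_equal(f$BIC, log(f$n) * f$k - 2 * logL, tolerance = 1e-8)
  }
})

test_that("pure-noise observations favour the uniform model in most replicates", {
  wins <- 0
  for (r in 1:200) {
    obs <- simulate_delay_observations("uniform", n = 200, b = 3,
                                       jitter_sd = 2, seed = 3000 + r)
    fits <- lapply(c("uniform", "depth_to_surface", "core_to_periphery"),
                   function(m) fit_delay_model(obs, m))
    wins <- wins + (compare_delay_models(fits)$winner == "uniform")
  }
  expect_gte(wins / 200, 0.9)
})

test_that("model comparison reports the BIC table, ties and evidence thresholds", {
  mkfit <- function(model, bic) structure(list(model = model, BIC = bic,
                                               n = 100), class = "tw_delayfit")
  cmpr <- compare_delay_models(list(mkfit("uniform", 3286.3),
                                    mkfit("depth_to_surface", 3289.3),
                                    mkfit("core_to_periphery", 2461.0)))
  expect_equal(cmpr$winner, "core_to_periphery")
  expect_equal(max(cmpr$table$delta_BIC), 828.3, tolerance = 1e-9)
  expect_equal(cmpr$verdict, "very strong")
  tie <- compare_delay_models(list(mkfit("uniform", 100), mkfit("depth_to_surface", 100)))
  expect_true(is.na(tie$winner))
  expect_equal(tie$verdict, "tie")
  weak <- compare_delay_models(list(mkfit("uniform", 100), mkfit("depth_to_surface", 105)))
  expect_equal(weak$winner, "uniform")
  expect_equal(weak$verdict, "inconclusive")
  expect_error(compare_delay_models(list(mkfit("uniform", 1),
                                         structure(list(model = "x", BIC = 2, n = 50),
                                                   class = "tw_delayfit"))),
               "different observation counts")
})

test_that("gradient slopes convert to propagation speeds with the right scaling", {
  f <- structure(list(model = "core_to_periphery", a = 3.5),
                 class = "tw_delayfit")
  expect_equal(propagation_speed(f, 3.5), 100)          # mm/ms -> cm/s
  f2 <- f; f2$a <- 7
  expect_equal(propagation_speed(f2, 3.5), 50)          # slope doubled
  expect_equal(propagation_speed(f, 7), 200)            # spacing doubled
  f3 <- f; f3$a <- 0
  expect_error(propagation_speed(f3), "unbounded")
  expect_error(propagation_speed(structure(list(model = "uniform", a = NA),
                                           class = "tw_delayfit")),
               "no propagation speed")
})
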