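# Canonical-microcircuit source and network dynamics.

test_that("the origin is a fixed point of the flow", {
  net <- build_network(electrode_layout(-1:1), "recurrent", "core")
  x0 <- numeric(8 * 3)
  expect_equal(flow(x0, net, u = 0), x0)
  expect_error(flow(c(NaN, x0[-1]), net), "NaN")
})

test_that("a single uncoupled population rings down at the kernel's analytic rate", {
  # closed form for the second-order kernel: v(t) = H/tau * t * exp(-t/tau)
  # for a unit impulse in current
  net <- build_network(electrode_layout(c(-1, 0)), "forward_only", "core")
  cc <- net$canonical
  tau <- cc$tau0[["ss"]] * net$params$tau[["tau_ss"]]
  # strip all coupling so population 1 evolves freely
  net$canonical$intrinsic$weight[] <- 0
  net$canonical$a0_forward <- 0
  m <- 8L
  x <- c(numeric(m), 1, numeric(m - 1))     # unit current in source-1 ss
  dt <- 0.01
  for (i in seq_len(round(5 * tau / dt))) { # integrate 5 tau by RK4 by hand
    k1 <- flow(x, net); k2 <- flow(x + dt / 2 * k1, net)
    k3 <- flow(x + dt / 2 * k2, net); k4 <- flow(x + dt * k3, net)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  t_end <- round(5 * tau / dt) * dt
  expect_equal(x[1], t_end * exp(-t_end / tau), tolerance = 1e-6)
})

test_that("doubling H doubles the response of an uncoupled population", {
  net <- build_network(electrode_layout(c(-1, 0)), "forward_only", "core")
  # strip all coupling: the driven population is a pure second-order kernel,
  # so its response scales exactly linearly in H
  net$canonical$intrinsic$weight[] <- 0
  net$canonical$a0_forward <- 0
  sim1 <- simulate_erp(net, t_ms = seq(-20, 150), check_stability = FALSE)
  net2 <- net
  net2$canonical$H0["ss"] <- 2 * net2$canonical$H0["ss"]
  sim2 <- simulate_erp(net2, t_ms = seq(-20, 150), check_stability = FALSE)
  row_ss <- (net$core_index - 1) * 4 + 1       # driven ss population
  scale_ratio <- max(abs(sim2$states[row_ss, ])) /
    max(abs(sim1$states[row_ss, ]))
  expect_equal(scale_ratio, 2, tolerance = 1e-9)
})

test_that("chain assembly produces the stated extrinsic edge counts and orientations", {
  lay <- electrode_layout(-2:2)
  fwd <- build_network(lay, "forward_only", "core")
  rec <- build_network(lay, "recurrent", "core")
  ef <- extrinsic_edges(fwd); er <- extrinsic_edges(rec)
  expect_equal(nrow(ef), 4L)                     # 4 edges, all away from core
  expect_true(all(ef$direction == "away"))
  pos <- lay$positions
  expect_true(all(abs(pos[ef$to]) > abs(pos[ef$from])))
  expect_equal(nrow(er), 8L)
  expect_equal(sum(er$direction == "toward"), 4L)
  # two contacts: one or two edges by scheme
  lay2 <- electrode_layout(c(0, 1))
  expect_equal(nrow(extrinsic_edges(build_network(lay2, "forward_only", "core"))), 1L)
  expect_equal(nrow(extrinsic_edges(build_network(lay2, "recurrent", "core"))), 2L)
  expect_error(build_network(electrode_layout(c(1, 2)), "recurrent", "core"),
               "no core")
})

test_that("zero input gain leaves the simulated response flat", {
  net <- build_network(electrode_layout(-1:1), "recurrent", "core")
  net$params$input$gain <- 0
  sim <- simulate_erp(net)
  expect_lt(max(abs(sim$y)), 1e-12)
  expect_false(sim$diverged)
})

test_that("halving the integrator step changes the output only marginally", {
  net <- build_network(electrode_layout(-1:1), "recurrent", "core")
  a <- simulate_erp(net, dt_ms = 0.5)
  b <- simulate_erp(net, dt_ms = 0.25)
  rel <- max(abs(a$y - b$y)) / max(abs(b$y))
  expect_lt(rel, 1e-6)
})

test_that("the compiled integrator matches an adaptive ODE solver", {
  net <- build_network(electrode_layout(-1:1), "recurrent", "core")
  t_ms <- seq(-100, 250, by = 1)
  sim <- simulate_erp(net, t_ms = t_ms)
  deriv <- function(t, state, parms) {
    u <- exp(-(t - net$params$input$onset)^2 / (2 * net$params$input$width^2)) *
      net$params$input$gain * net$canonical$input_gain0
    list(flow(state, net, u = u))
  }
  ode <- deSolve::lsoda(numeric(24), t_ms, deriv, NULL,
                        rtol = 1e-9, atol = 1e-9)
  sp_rows <- 1 + c(1, 5, 9)                    # sp voltage rows (+1 time col)
  y_ode <- t(ode[, sp_rows + 1]) * net$canonical$obs_gain0
  expect_lt(max(abs(sim$y - y_ode)) / max(abs(y_ode)), 1e-4)
})

test_that("prior-mean networks are stable and a constructed positive-feedback case is not", {
  for (scheme in c("recurrent", "forward_only")) {
    lin <- linearise(build_network(electrode_layout(-1:1), scheme, "core"))
    expect_true(lin$stable, info = scheme)
    expect_equal(max(abs(lin$fixed_point)), 0)
  }
  bad <- build_network(electrode_layout(-1:1), "recurrent", "core")
  bad$canonical$intrinsic$weight[1] <- 5   # runaway ss -> sp drive
  lin <- linearise(bad)
  expect_false(lin$stable)
  expect_error(simulate_erp(bad), "unstable model: eigenvalue")
})

test_that("uncoupled sources give a block-diagonal Jacobian", {
  net <- build_network(electrode_layout(-1:1), "forward_only", "core")
  net$canonical$a0_forward <- 0
  J <- linearise(net)$jacobian
  m <- 12
  K <- J[(m + 1):(2 * m), 1:m]               # voltage-coupling block
  for (s1 in 1:3) for (s2 in 1:3) {
    if (s1 == s2) next
    blk <- K[(s1 - 1) * 4 + 1:4, (s2 - 1) * 4 + 1:4]
    expect_equal(max(abs(blk)), 0)
  }
})

test_that("forward-only and recurrent dynamics coincide when backward gains vanish", {
  lay <- electrode_layout(-1:1)
  fwd <- build_network(lay, "forward_only", "core")
  rec <- build_network(lay, "recurrent", "core")
  rec$params$A_backward <- 0
  a <- simulate_erp(fwd); b <- simulate_erp(rec)
  expect_equal(a$y, b$y, tolerance = 1e-12)
})

test_that("the linearised response matches the nonlinear one for small inputs", {
  net <- build_network(electrode_layout(-1:1), "recurrent", "core")
  small <- net; small$params$input$gain <- net$params$input$gain / 100
  y_small <- simulate_erp(small)$y * 100
  # reference: scale the standard response down -- agreement implies the
  # standard regime is mildly nonlinear, the scaled regime linear
  tiny <- net; tiny$params$input$gain <- net$params$input$gain / 1000
  y_tiny <- simulate_erp(tiny)$y * 1000
  expect_lt(max(abs(y_small - y_tiny)) / max(abs(y_tiny)), 0.01)
})

test_that("a prior recurrent core-input chain responds on all channels with the core first", {
  net <- build_network(electrode_layout(-1:1), "recurrent", "core")
  sim <- simulate_erp(net)
  peaks <- apply(abs(sim$y), 1L, max)
  expect_true(all(peaks > 1))
  tpk <- apply(abs(sim$y), 1L, which.max)
  expect_lt(tpk[net$core_index], min(tpk[-net$core_index]))
})

test_that("noise-free epochs equal the deterministic response and seeds reproduce", {
  net <- build_network(electrode_layout(-1:1), "recurrent", "core")
  s0 <- simulate_from_cmc(net, observation_noise_sd = 0, n_ieds = 2, seed = 1)
  expect_equal(s0$epochs[[1]], s0$clean)
  expect_equal(s0$epochs[[2]], s0$clean)
  s1 <- simulate_from_cmc(net, observation_noise_sd = 2, n_ieds = 1, seed = 9)
  s2 <- simulate_from_cmc(net, observation_noise_sd = 2, n_ieds = 1, seed = 9)
  expect_identical(s1$epochs[[1]], s2$epochs[[1]])
})
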