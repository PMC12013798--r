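# Canonical microcircuit (CMC) neural mass network over electrode contacts.
#
# Each source (one per SEEG contact) holds four populations -- spiny
# stellate (ss), superficial pyramidal (sp), inhibitory interneuron (ii) and
# deep pyramidal (dp) -- organised as two excitatory/inhibitory oscillator
# pairs: a fast superficial pair (ss <-> sp, generating the spike component
# and, at raised gain, gamma-band rhythms) and a slow deep pair (dp <-> ii,
# generating the wave component). Each population follows a second-order
# synaptic kernel: v' = i, i' = (H/tau) * (sum of sigmoid-transformed
# presynaptic voltages + input) - 2 i / tau - v / tau^2, with the
# zero-centred logistic sigmoid so the origin is a fixed point.
#
# All fitted parameters are dimensionless multipliers of the canonical base
# constants below; the group-average prior and posterior multipliers live in
# cmc_group_averages().

#' Canonical base constants of the CMC source model
#'
#' Base time constants (ms), maximum postsynaptic amplitudes (arbitrary
#' units mapped to microvolts by the observation gain), sigmoid slope,
#' intrinsic coupling template, extrinsic base gains, input and observation
#' scaling. Fitted parameters multiply these values. The base constants are
#' calibrated once so that the group-posterior reference network is stable
#' (damped oscillatory) at unit intrinsic gain and transitions to a
#' sustained gamma-range rhythm under the intrinsic gain sweep.
#'
#' @return named list of canonical constants.
#' @export
cmc_canonical <- function() {
  list(
    populations = c("ss", "sp", "ii", "dp"),
    tau0 = c(ss = 1.2, sp = 1.2, ii = 16, dp = 28),   # ms
    H0 = c(ss = 4, sp = 4, ii = 1, dp = 1.5),
    r0 = 2,                                            # sigmoid slope
    # intrinsic template: target <- source, signed base gain, and the named
    # gain multiplier acting on the edge (NA = fixed edge)
    intrinsic = data.frame(
      target = c("sp", "ss", "sp", "ii", "ii", "dp", "dp"),
      source = c("ss", "sp", "sp", "ss", "dp", "ii", "sp"),
      weight = c(+0.30, -0.17, -0.05, +0.20, +0.05, -0.05, +0.06),
      gamma  = c("g_sp_ss", NA, "g_sp_sp", "g_ii_ss", NA, NA, NA),
      stringsAsFactors = FALSE),
    a0_forward = 0.06,    # extrinsic away-from-core edge: sp -> ss (+)
    a0_backward = 0.04,   # extrinsic toward-core edge: dp -> sp and dp -> ii (+)
    input_gain0 = 0.05,   # Gaussian input drive into ss of the target source
    obs_gain0 = 500       # microvolts per unit sp voltage
  )
}

#' Group-level parameter table (prior and posterior multipliers)
#'
#' Prior multiplier values and group-level Bayesian-average posterior
#' estimates for the fitted CMC parameters: extrinsic coupling (A forward /
#' backward), intrinsic gains (gamma), population time constants (tau) and
#' the sigmoid slope (sigma). All values are dimensionless multipliers of
#' the canonical base constants.
#'
#' @return data frame with columns `parameter`, `prior`, `posterior`.
#' @export
cmc_group_averages <- function() {
  data.frame(
    parameter = c("A_forward", "A_backward", "g_sp_sp", "g_sp_ss", "g_ii_ss",
                  "tau_ss", "tau_sp", "tau_dp", "tau_ii", "sigma"),
    prior = c(1.00, 1.00, 1.00, 1.00, 1.00, 1.22, 0.90, 1.22, 0.90, 1.00),
    posterior = c(1.55, 1.97, 1.18, 1.04, 1.11, 2.34, 3.30, 1.68, 3.10, 1.10))
}

pop_index <- function(source, population) (source - 1L) * 4L +
  match(population, c("ss", "sp", "ii", "dp"))

#' Assemble a CMC chain network over an electrode layout
#'
#' One source per contact, arranged along the electrode from deep white
#' matter through the tuber core to superficial grey matter. Extrinsic
#' edges connect neighbouring sources only: away-from-core edges
#' ("forward", sp of the closer-to-core source onto ss of its neighbour)
#' exist in both schemes; toward-core edges ("backward", dp onto sp and ii)
#' exist only under recurrent coupling.
#'
#' @param layout an [electrode_layout()] whose positions include the core
#'   (0).
#' @param coupling_scheme `"recurrent"` (default) or `"forward_only"`.
#' @param input_target `"core"` (default), `"superficial"` or `"deep"`: the
#'   source receiving the Gaussian input that triggers the discharge.
#' @param params `"prior"` (default) or `"posterior"` to take multipliers
#'   from [cmc_group_averages()], or a named list as returned in
#'   `$params` for full control.
#' @return a `tw_network` object.
#' @export
build_network <- function(layout, coupling_scheme = c("recurrent", "forward_only"),
                          input_target = c("core", "superficial", "deep"),
                          params = "prior") {
  coupling_scheme <- match.arg(coupling_scheme)
  input_target <- match.arg(input_target)
  stopifnot(inherits(layout, "tw_layout"))
  if (!any(layout$positions == 0)) stop("layout has no core (position 0) channel")
  ns <- layout$n_channels
  if (is.character(params)) {
    col <- match.arg(params, c("prior", "posterior"))
    tab <- cmc_group_averages()
    val <- stats::setNames(tab[[col]], tab$parameter)
    params <- list(
      A_forward = unname(val["A_forward"]), A_backward = unname(val["A_backward"]),
      gamma = matrix(rep(val[c("g_sp_sp", "g_sp_ss", "g_ii_ss")], each = ns),
                     nrow = ns, dimnames = list(NULL, c("g_sp_sp", "g_sp_ss", "g_ii_ss"))),
      tau = val[c("tau_ss", "tau_sp", "tau_ii", "tau_dp")],
      sigma = unname(val["sigma"]),
      input = list(onset = 0, width = 16, gain = 1),
      obs_gain = rep(1, ns))
  }
  names(params$tau) <- c("tau_ss", "tau_sp", "tau_ii", "tau_dp")
  structure(list(layout = layout, n_sources = ns,
                 coupling_scheme = coupling_scheme,
                 input_target = input_target,
                 core_index = which(layout$positions == 0),
                 params = params,
                 canonical = cmc_canonical()),
            class = "tw_network")
}

# index of the source receiving input for a named site
input_source_index <- function(net, site) {
  switch(site,
         core = net$core_index,
         superficial = which.max(net$layout$positions),
         deep = which.min(net$layout$positions),
         stop("unknown input site: ", site))
}

#' Enumerate the extrinsic edges of a network
#'
#' @param net a `tw_network`.
#' @return data frame with `from`, `to` (source indices) and `direction`
#'   (`"away"` from core or `"toward"` it).
#' @export
extrinsic_edges <- function(net) {
  ns <- net$n_sources
  ord <- order(net$layout$positions)     # deep ... core ... superficial
  core_rank <- which(ord == net$core_index)
  edges <- NULL
  for (i in seq_len(ns - 1L)) {
    a <- ord[i]; b <- ord[i + 1L]
    # which of the pair is closer to the core along the chain?
    if (i < core_rank) {         # both at or below core: b is closer
      away <- c(b, a); toward <- c(a, b)
    } else {                     # at or above core: a is closer
      away <- c(a, b); toward <- c(b, a)
    }
    edges <- rbind(edges,
                   data.frame(from = away[1], to = away[2], direction = "away"))
    if (net$coupling_scheme == "recurrent")
      edges <- rbind(edges,
                     data.frame(from = toward[1], to = toward[2],
                                direction = "toward"))
  }
  edges
}

# build the m x m coupling matrix D, and the H, tau vectors, sigmoid slope
# and input matrix for the current parameters
network_matrices <- function(net, inputs = NULL) {
  cc <- net$canonical
  ns <- net$n_sources
  m <- 4L * ns
  p <- net$params
  tau <- H <- numeric(m)
  for (s in seq_len(ns)) {
    tau[pop_index(s, c("ss", "sp", "ii", "dp"))] <-
      cc$tau0 * p$tau[c("tau_ss", "tau_sp", "tau_ii", "tau_dp")]
    H[pop_index(s, c("ss", "sp", "ii", "dp"))] <- cc$H0
  }
  D <- matrix(0, m, m)
  for (s in seq_len(ns)) {
    for (e in seq_len(nrow(cc$intrinsic))) {
      tgt <- pop_index(s, cc$intrinsic$target[e])
      src <- pop_index(s, cc$intrinsic$source[e])
      w <- cc$intrinsic$weight[e]
      gname <- cc$intrinsic$gamma[e]
      if (!is.na(gname)) w <- w * p$gamma[s, gname]
      D[tgt, src] <- D[tgt, src] + w
    }
  }
  ee <- extrinsic_edges(net)
  for (e in seq_len(nrow(ee))) {
    if (ee$direction[e] == "away") {
      D[pop_index(ee$to[e], "ss"), pop_index(ee$from[e], "sp")] <-
        D[pop_index(ee$to[e], "ss"), pop_index(ee$from[e], "sp")] +
        cc$a0_forward * p$A_forward
    } else {
      w <- cc$a0_backward * p$A_backward
      D[pop_index(ee$to[e], "sp"), pop_index(ee$from[e], "dp")] <-
        D[pop_index(ee$to[e], "sp"), pop_index(ee$from[e], "dp")] + w
      D[pop_index(ee$to[e], "ii"), pop_index(ee$from[e], "dp")] <-
        D[pop_index(ee$to[e], "ii"), pop_index(ee$from[e], "dp")] + w
    }
  }
  if (is.null(inputs)) {
    inputs <- data.frame(source = input_source_index(net, net$input_target),
                         onset = p$input$onset, width = p$input$width,
                         gain = p$input$gain * cc$input_gain0)
  }
  C <- matrix(0, m, nrow(inputs))
  for (j in seq_len(nrow(inputs)))
    C[pop_index(inputs$source[j], "ss"), j] <- 1
  r <- cc$r0 * p$sigma
  list(D = D, H = H, tau = tau, r = r, C = C, inputs = inputs, m = m)
}

#' Flow (state derivative) of the network
#'
#' Reference R implementation of the network dynamics, used for testing and
#' linearisation; simulation uses the compiled integrator.
#'
#' @param state numeric vector of length `8 * n_sources`: voltages then
#'   currents, populations ordered ss, sp, ii, dp within each source.
#' @param net a `tw_network`.
#' @param u scalar input value applied through the network's input mapping
#'   (default 0), or vector over input columns.
#' @return derivative vector of the same length.
#' @export
flow <- function(state, net, u = 0) {
  mats <- network_matrices(net)
  m <- mats$m
  stopifnot(length(state) == 2L * m)
  if (any(!is.finite(state))) stop("NaN/Inf in state")
  v <- state[1:m]; cur <- state[(m + 1L):(2L * m)]
  sig <- 1 / (1 + exp(-mats$r * v)) - 0.5
  drive <- as.numeric(mats$D %*% sig) + as.numeric(mats$C %*% rep(u, ncol(mats$C)))
  c(cur, mats$H / mats$tau * drive - 2 * cur / mats$tau - v / mats$tau^2)
}

#' Deterministic ERP-style simulation of a network
#'
#' Integrates the network from its fixed point over a time grid (default
#' -100 to 250 ms around the input onset) with the Gaussian input, and maps
#' source states to channel predictions: each channel reads the superficial
#' pyramidal voltage of its source scaled by the observation gain.
#'
#' @param net a `tw_network` (must be stable at the fixed point unless
#'   `check_stability = FALSE`).
#' @param t_ms output time grid in ms (default `seq(-100, 250)`); must be
#'   uniformly spaced.
#' @param dt_ms integrator step in ms (default 0.25); must divide the output
#'   step.
#' @param inputs optional data frame of inputs (`source`, `onset`, `width`,
#'   `gain`) overriding the network's single input.
#' @param check_stability verify fixed-point stability first (default TRUE).
#' @return list with `y` (channels x time matrix, microvolts), `t_ms`,
#'   `states` (population voltages), `diverged` flag.
#' @export
simulate_erp <- function(net, t_ms = seq(-100, 250, by = 1), dt_ms = 0.25,
                         inputs = NULL, check_stability = TRUE) {
  stopifnot(inherits(net, "tw_network"))
  step_out <- unique(round(diff(t_ms), 10))
  if (length(step_out) != 1L) stop("t_ms must be uniformly spaced")
  out_every <- step_out / dt_ms
  if (abs(out_every - round(out_every)) > 1e-9)
    stop("dt_ms must divide the output step")
  if (check_stability) {
    lin <- linearise(net)
    if (!lin$stable)
      stop(sprintf("unstable model: eigenvalue %g + %gi has positive real part",
                   Re(lin$lambda_max), Im(lin$lambda_max)))
  }
  mats <- network_matrices(net, inputs = inputs)
  n_steps <- (length(t_ms) - 1L) * round(out_every)
  res <- .cmc_rk4(mats$D, mats$H, mats$tau, mats$r, mats$C,
                  mats$inputs$onset, mats$inputs$width, mats$inputs$gain,
                  t_ms[1], dt_ms, n_steps, as.integer(round(out_every)),
                  numeric(2L * mats$m))
  v <- res$v
  sp_rows <- vapply(seq_len(net$n_sources), pop_index, integer(1),
                    population = "sp")
  gains <- net$canonical$obs_gain0 * net$params$obs_gain
  y <- v[sp_rows, , drop = FALSE] * gains
  list(y = y, t_ms = t_ms, states = v, diverged = res$diverged,
       t_diverged = res$t_diverged)
}

#' Linearise the network at its fixed point
#'
#' With the zero-centred sigmoid and no tonic input the origin is a fixed
#' point; a Newton root solve from the origin confirms it (and would locate
#' a displaced fixed point under tonic drive). Returns the Jacobian there
#' and its eigenvalue spectrum; the network is stable when all real parts
#' are negative.
#'
#' @param net a `tw_network`.
#' @return list with `fixed_point`, `jacobian`, `eigenvalues`, `stable`,
#'   `lambda_max` (eigenvalue with largest real part).
#' @export
linearise <- function(net) {
  mats <- network_matrices(net)
  m <- mats$m
  J_at <- function(v) {
    sig_d <- mats$r * exp(-mats$r * v) / (1 + exp(-mats$r * v))^2
    K <- diag(mats$H / mats$tau) %*% (mats$D %*% diag(sig_d)) - diag(1 / mats$tau^2)
    rbind(cbind(matrix(0, m, m), diag(m)),
          cbind(K, diag(-2 / mats$tau)))
  }
  # Newton root solve for the fixed point, starting at the origin
  x <- numeric(2L * m)
  for (it in 1:50) {
    f <- flow(x, net, u = 0)
    if (max(abs(f)) < 1e-12) break
    J <- J_at(x[1:m])
    step <- tryCatch(solve(J, f), error = function(e)
      stop("fixed-point root solve diverged: singular Jacobian"))
    x <- x - step
    if (any(!is.finite(x)) || max(abs(x)) > 1e6)
      stop("fixed-point root solve diverged")
  }
  J <- J_at(x[1:m])
  ev <- eigen(J, only.values = TRUE)$values
  lmax <- ev[which.max(Re(ev))]
  list(fixed_point = x, jacobian = J, eigenvalues = ev,
       stable = all(Re(ev) < 0), lambda_max = lmax)
}

#' Simulate noisy IED epochs from a known network
#'
#' Forward-simulates the network's deterministic response and adds iid
#' Gaussian observation noise per epoch, returning the generating parameters
#' for recovery experiments.
#'
#' @param net a `tw_network`.
#' @param observation_noise_sd noise SD in microvolts.
#' @param n_ieds number of epochs.
#' @param seed integer seed.
#' @param t_ms epoch time grid (default -100..250 ms).
#' @return list with `epochs` (list of channels x time matrices), `t_ms`,
#'   `true_params` and `clean` (noise-free response).
#' @export
simulate_from_cmc <- function(net, observation_noise_sd = 5, n_ieds = 1,
                              seed = 1L, t_ms = seq(-100, 250, by = 1)) {
  sim <- simulate_erp(net, t_ms = t_ms)    # errors if unstable
  set.seed(as.integer(seed))
  epochs <- lapply(seq_len(n_ieds), function(i) {
    sim$y + matrix(stats::rnorm(length(sim$y), 0, observation_noise_sd),
                   nrow(sim$y))
  })
  list(epochs = epochs, t_ms = t_ms, true_params = net$params,
       clean = sim$y)
}
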