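# Variational-Laplace inversion of CMC networks fitted to single-IED
# epochs, with closed-form Bayesian model reduction over the architecture
# (coupling scheme x input site) and within-electrode modulation spaces.

#' Hanning-taper an epoch matrix
#'
#' @param y channels x time matrix.
#' @return the tapered matrix.
#' @export
apply_hanning <- function(y) {
  n <- ncol(y)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  sweep(y, 2L, w, `*`)
}

#' Cut, baseline-correct and taper a single-IED epoch
#'
#' Extracts the channels x time window around the group reference time
#' (the peak of the first spike), removes the pre-onset mean per channel
#' and applies a temporal Hanning window.
#'
#' @param rec a `tw_recording`.
#' @param group a `tw_spikegroup` (or a reference time in ms).
#' @param window_ms two-element window relative to the reference, in ms
#'   (default `c(-100, 250)`).
#' @return channels x time matrix with attribute `t_ms`.
#' @export
prepare_epoch <- function(rec, group, window_ms = c(-100, 250)) {
  stopifnot(inherits(rec, "tw_recording"))
  ref <- if (inherits(group, "tw_spikegroup")) group$reference_time_ms else group
  fs <- rec$sampling_rate
  i0 <- round(ref / 1000 * fs) + 1L
  lo <- i0 + round(window_ms[1] / 1000 * fs)
  hi <- i0 + round(window_ms[2] / 1000 * fs)
  if (lo < 1L || hi > n_samples(rec))
    stop("epoch window overruns the segment edge")
  y <- rec$samples[, lo:hi, drop = FALSE]
  t_ms <- (seq(lo, hi) - i0) / fs * 1000
  base <- rowMeans(y[, t_ms < 0, drop = FALSE])
  y <- y - base
  y <- apply_hanning(y)
  attr(y, "t_ms") <- t_ms
  y
}

#' Default prior density over the DCM parameter vector
#'
#' Parameters are log-multipliers of the canonical constants (Gaussian
#' priors), except `onset` which is additive in ms. Prior means for the
#' multipliers come from the group prior-value table; variances default to
#' 1/4 for coupling/gain/input parameters, 1/8 for time constants, 1/16
#' for the sigmoid slope and 1/64 for observation gains -- wide enough
#' that the group-posterior regime is reachable under the prior.
#'
#' @param net a `tw_network` (sets the number of observation channels).
#' @param n_ieds number of jointly inverted IEDs (> 1 adds per-IED coupling
#'   modulation parameters for IEDs 2..n).
#' @return list with `mean`, `var` (named vectors) defining a diagonal
#'   Gaussian.
#' @export
dcm_priors <- function(net, n_ieds = 1L) {
  tab <- cmc_group_averages()
  pv <- stats::setNames(tab$prior, tab$parameter)
  nm <- c("A_forward", "A_backward", "g_sp_sp", "g_sp_ss", "g_ii_ss",
          "tau_ss", "tau_sp", "tau_ii", "tau_dp", "sigma",
          "onset", "width", "u_superficial", "u_core", "u_deep",
          paste0("obs_", seq_len(net$n_sources)))
  mu <- c(log(pv[c("A_forward", "A_backward", "g_sp_sp", "g_sp_ss", "g_ii_ss")]),
          log(pv[c("tau_ss", "tau_sp", "tau_ii", "tau_dp")]),
          log(pv["sigma"]),
          0,                      # onset (ms)
          log(16),                # width (log ms)
          rep(0, 3),              # input log-gains per candidate site
          rep(0, net$n_sources))  # observation log-gains
  va <- c(rep(1 / 4, 5), rep(1 / 8, 4), 1 / 16,
          64,                     # onset variance (ms^2)
          1 / 16, rep(1 / 4, 3), rep(1 / 64, net$n_sources))
  names(mu) <- names(va) <- nm
  if (n_ieds > 1L) {
    mod <- as.vector(outer(c("F", "B", "i"), 2:n_ieds,
                           function(f, k) paste0("mod", k, "_", f)))
    mu <- c(mu, stats::setNames(rep(0, length(mod)), mod))
    va <- c(va, stats::setNames(rep(1 / 16, length(mod)), mod))
  }
  list(mean = mu, var = va)
}

# instantiate network parameters for one IED from the parameter vector
theta_to_params <- function(theta, net, ied = 1L) {
  ns <- net$n_sources
  modF <- modB <- modi <- 0
  if (ied > 1L) {
    modF <- theta[[paste0("mod", ied, "_F")]]
    modB <- theta[[paste0("mod", ied, "_B")]]
    modi <- theta[[paste0("mod", ied, "_i")]]
  }
  gamma <- matrix(rep(exp(c(theta[["g_sp_sp"]] + modi, theta[["g_sp_ss"]],
                            theta[["g_ii_ss"]])), each = ns),
                  nrow = ns,
                  dimnames = list(NULL, c("g_sp_sp", "g_sp_ss", "g_ii_ss")))
  list(A_forward = exp(theta[["A_forward"]] + modF),
       A_backward = exp(theta[["A_backward"]] + modB),
       gamma = gamma,
       tau = stats::setNames(exp(theta[c("tau_ss", "tau_sp", "tau_ii", "tau_dp")]),
                             c("tau_ss", "tau_sp", "tau_ii", "tau_dp")),
       sigma = exp(theta[["sigma"]]),
       input = list(onset = theta[["onset"]], width = exp(theta[["width"]]),
                    gain = 1),
       obs_gain = exp(theta[paste0("obs_", seq_len(ns))]))
}

# forward prediction (tapered), concatenated over IEDs; all three candidate
# input sites drive the network with their own gains
dcm_forward <- function(theta, net, t_ms, n_ieds = 1L, dt_ms = 0.5) {
  preds <- vector("list", n_ieds)
  for (ied in seq_len(n_ieds)) {
    p <- theta_to_params(theta, net, ied)
    net$params <- p
    inputs <- data.frame(
      source = c(input_source_index(net, "superficial"),
                 input_source_index(net, "core"),
                 input_source_index(net, "deep")),
      onset = theta[["onset"]],
      width = exp(theta[["width"]]),
      gain = net$canonical$input_gain0 *
        exp(theta[c("u_superficial", "u_core", "u_deep")]))
    sim <- simulate_erp(net, t_ms = t_ms, dt_ms = dt_ms, inputs = inputs,
                        check_stability = FALSE)
    if (sim$diverged) return(NULL)
    preds[[ied]] <- apply_hanning(sim$y)
  }
  preds
}

#' Invert a CMC network on single-IED epochs by variational Laplace
#'
#' Gauss-Newton ascent (with Levenberg-style regularisation) on the
#' variational free energy under a Gaussian (Laplace) posterior, with iid
#' Gaussian observation noise per channel whose log-precisions are updated
#' in an M-step. Input timing and width are optimised with the other
#' parameters. Accepted steps never decrease F.
#'
#' @param data channels x time epoch matrix (Hanning-tapered, e.g. from
#'   [prepare_epoch()]), or a list of such matrices for joint multi-IED
#'   inversion with per-IED coupling modulations.
#' @param net a `tw_network` template (architecture and layout).
#' @param priors optional prior list (`mean`, `var`) overriding
#'   [dcm_priors()].
#' @param settings list: `max_iter` (64), `tol` (1e-2, on successive F
#'   changes), `patience` (4), `dt_ms` (0.5), `fd_step` (1e-3),
#'   `init_jitter` (0 SD of seeded jitter on the starting point), `seed`.
#' @return a `tw_dcmfit`: `posterior` (`mean`, `cov`), `lambda` (per-channel
#'   log-precisions), `F`, `F_components`, `prediction`, `residuals`,
#'   `variance_explained`, `converged`, `trace`, `priors`, plus the data and
#'   settings needed by [reduce_model()].
#' @export
invert_dcm <- function(data, net, priors = NULL, settings = list()) {
  s <- utils::modifyList(list(max_iter = 64L, tol = 1e-2, patience = 4L,
                              dt_ms = 0.5, fd_step = 1e-3,
                              init_jitter = 0, seed = 1L), settings)
  epochs <- if (is.list(data)) data else list(data)
  n_ieds <- length(epochs)
  nch <- nrow(epochs[[1]])
  nt <- ncol(epochs[[1]])
  t_ms <- attr(epochs[[1]], "t_ms")
  if (is.null(t_ms)) t_ms <- seq(-100, by = 1, length.out = nt)
  y <- do.call(cbind, epochs)              # channels x (nt * n_ieds)
  if (any(!is.finite(y))) stop("data contains non-finite values")
  if (is.null(priors)) priors <- dcm_priors(net, n_ieds)
  mu0 <- priors$mean
  P0 <- diag(1 / priors$var, length(mu0))
  d <- length(mu0)

  m <- mu0
  if (s$init_jitter > 0) {
    set.seed(as.integer(s$seed))
    m <- m + stats::rnorm(d, 0, s$init_jitter) * sqrt(priors$var)
  }
  lambda <- rep(log(1 / max(stats::var(as.vector(y)), 1e-6)), nch)

  predict_at <- function(theta) {
    pr <- dcm_forward(stats::setNames(theta, names(mu0)), net, t_ms, n_ieds,
                      s$dt_ms)
    if (is.null(pr)) return(NULL)
    do.call(cbind, pr)
  }

  jacobian_at <- function(theta, g0) {
    J <- matrix(0, length(g0), d)
    for (j in seq_len(d)) {
      tp <- theta; tp[j] <- tp[j] + s$fd_step
      gj <- predict_at(tp)
      if (is.null(gj)) gj <- g0
      J[, j] <- (as.vector(gj) - as.vector(g0)) / s$fd_step
    }
    J
  }

  # channel index of every element of the vectorised (column-major) residual
  ch_of <- rep(seq_len(nch), times = ncol(y))

  compute_F <- function(e_vec, lambda, mdiff, S, J) {
    ntc <- ncol(y)                          # samples per channel
    acc <- 0
    for (c in seq_len(nch)) {
      idx <- which(ch_of == c)
      w <- if (is.null(J)) 0 else
        sum((J[idx, , drop = FALSE] %*% S) * J[idx, , drop = FALSE])
      acc <- acc + ntc / 2 * lambda[c] - ntc / 2 * log(2 * pi) -
        exp(lambda[c]) / 2 * (sum(e_vec[idx]^2) + w)
    }
    ldS <- determinant_psd(S)
    ldS0 <- sum(log(priors$var))
    kl <- 0.5 * (sum(diag(P0 %*% S)) + sum(mdiff * (P0 %*% mdiff)) - d +
                 ldS0 - ldS)
    list(total = acc - kl, accuracy = acc, complexity = kl)
  }

  g <- predict_at(m)
  if (is.null(g)) stop("model diverges at the prior means")
  e <- as.vector(y) - as.vector(g)
  J <- jacobian_at(m, g)
  S <- posterior_cov(J, lambda, ch_of, P0)
  lambda <- update_lambda(e, J, S, ch_of, nch, ncol(y))
  S <- posterior_cov(J, lambda, ch_of, P0)
  Fc <- compute_F(e, lambda, m - mu0, S, J)
  Fbest <- Fc$total
  best <- list(m = m, S = S, lambda = lambda, F = Fc, g = g, e = e, J = J)
  rho <- 1e-2
  trace_F <- Fbest
  stall <- 0L
  converged <- FALSE

  for (iter in seq_len(s$max_iter)) {
    Pi_e <- exp(lambda)[ch_of]
    A <- crossprod(J * Pi_e, J) + P0
    rhs <- crossprod(J, Pi_e * e) - P0 %*% (m - mu0)
    accepted <- FALSE
    for (try in 1:8) {
      Areg <- A + rho * diag(diag(A), d)
      dm <- tryCatch(solve(Areg, rhs), error = function(err) NULL)
      if (!is.null(dm)) {
        m_new <- m + as.vector(dm)
        g_new <- predict_at(m_new)
        if (!is.null(g_new)) {
          e_new <- as.vector(y) - as.vector(g_new)
          J_new <- jacobian_at(m_new, g_new)
          S_new <- posterior_cov(J_new, lambda, ch_of, P0)
          l_new <- update_lambda(e_new, J_new, S_new, ch_of, nch, ncol(y))
          S_new <- posterior_cov(J_new, l_new, ch_of, P0)
          Fc_new <- compute_F(e_new, l_new, m_new - mu0, S_new, J_new)
          if (is.finite(Fc_new$total) && Fc_new$total > Fbest) {
            m <- m_new; g <- g_new; e <- e_new; J <- J_new
            S <- S_new; lambda <- l_new; Fc <- Fc_new
            accepted <- TRUE
            break
          }
        }
      }
      rho <- rho * 8
    }
    if (accepted) {
      dF <- Fc$total - Fbest
      Fbest <- Fc$total
      best <- list(m = m, S = S, lambda = lambda, F = Fc, g = g, e = e, J = J)
      rho <- max(rho / 4, 1e-4)
      stall <- if (dF < s$tol) stall + 1L else 0L
    } else {
      stall <- stall + 1L
    }
    trace_F <- c(trace_F, Fbest)
    if (stall >= s$patience) { converged <- TRUE; break }
  }

  pred <- matrix(as.vector(best$g), nch)
  ve <- variance_explained_raw(as.vector(y), as.vector(best$g))
  structure(list(
    posterior = list(mean = stats::setNames(best$m, names(mu0)), cov = best$S),
    lambda = best$lambda,
    F = Fbest, F_components = best$F,
    prediction = pred, residuals = matrix(best$e, nch),
    variance_explained = ve$value, ve_flagged = ve$flagged,
    converged = converged, trace = trace_F,
    priors = priors, data = y, n_ieds = n_ieds, t_ms = t_ms,
    net = net, settings = s, jacobian = best$J, ch_of = ch_of),
    class = "tw_dcmfit")
}

posterior_cov <- function(J, lambda, ch_of, P0) {
  Pi_e <- exp(lambda)[ch_of]
  A <- crossprod(J * Pi_e, J) + P0
  chol2inv(chol((A + t(A)) / 2))
}

update_lambda <- function(e, J, S, ch_of, nch, ntc) {
  vapply(seq_len(nch), function(c) {
    idx <- which(ch_of == c)
    w <- sum((J[idx, , drop = FALSE] %*% S) * J[idx, , drop = FALSE])
    log(ntc / (sum(e[idx]^2) + w))
  }, numeric(1))
}

determinant_psd <- function(S) {
  2 * sum(log(diag(chol((S + t(S)) / 2 + diag(1e-12, nrow(S))))))
}

#' @export
print.tw_dcmfit <- function(x, ...) {
  cat(sprintf("<tw_dcmfit> F = %.2f, variance explained = %.1f%%, %s\n",
              x$F, x$variance_explained,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Laplace free energy of a fitted (or hypothetical) Gaussian posterior
#'
#' Returns the accuracy - complexity decomposition of the variational free
#' energy for iid Gaussian noise with per-channel log-precisions.
#'
#' @param data channels x time matrix.
#' @param prediction matching prediction matrix.
#' @param lambda per-channel log-precision vector.
#' @param posterior list with `mean` and `cov`.
#' @param priors list with `mean` and `var` (diagonal prior).
#' @param J optional Jacobian of the prediction wrt parameters (rows in
#'   column-major data order) for the curvature correction; omitted -> 0.
#' @return list with `total`, `accuracy`, `complexity` (nats).
#' @export
free_energy <- function(data, prediction, lambda, posterior, priors,
                        J = NULL) {
  nch <- nrow(data)
  e <- as.vector(data) - as.vector(prediction)
  ch_of <- rep(seq_len(nch), times = ncol(data))
  ntc <- ncol(data)
  S <- posterior$cov
  if (any(!is.finite(S))) stop("singular posterior covariance")
  acc <- 0
  for (c in seq_len(nch)) {
    idx <- which(ch_of == c)
    w <- if (is.null(J)) 0 else
      sum((J[idx, , drop = FALSE] %*% S) * J[idx, , drop = FALSE])
    acc <- acc + ntc / 2 * lambda[c] - ntc / 2 * log(2 * pi) -
      exp(lambda[c]) / 2 * (sum(e[idx]^2) + w)
  }
  d <- length(priors$mean)
  P0 <- diag(1 / priors$var, d)
  mdiff <- posterior$mean - priors$mean
  kl <- 0.5 * (sum(diag(P0 %*% S)) + sum(mdiff * (P0 %*% mdiff)) - d +
               sum(log(priors$var)) - determinant_psd(S))
  list(total = acc - kl, accuracy = acc, complexity = kl)
}

#' Bayesian model reduction
#'
#' Evaluates the evidence and posterior of a reduced model (same parameters,
#' different -- typically shrinkage -- priors) in closed form from the full
#' model's Gaussian posterior, without refitting.
#'
#' @param full_result a `tw_dcmfit` (or list with `posterior`, `priors`,
#'   `F`).
#' @param reduced_priors list with `mean` and `var` over the *same*
#'   parameter set (names must match the full priors).
#' @return list with `delta_F` (log Bayes factor reduced vs full), `F`
#'   (reduced free energy), `posterior` (`mean`, `cov`).
#' @export
reduce_model <- function(full_result, reduced_priors) {
  pr0 <- full_result$priors
  if (!identical(names(reduced_priors$mean), names(pr0$mean)))
    stop("reduced priors must cover the same parameter set (non-nested specification)")
  m <- full_result$posterior$mean
  S <- full_result$posterior$cov
  iS <- chol2inv(chol((S + t(S)) / 2))
  P0 <- diag(1 / pr0$var, length(m))
  Pr <- diag(1 / reduced_priors$var, length(m))
  Pt <- iS + Pr - P0
  Pt <- (Pt + t(Pt)) / 2
  ch <- tryCatch(chol(Pt), error = function(e)
    stop("reduced precision not positive definite"))
  St <- chol2inv(ch)
  h <- iS %*% m + (1 / reduced_priors$var) * reduced_priors$mean -
    (1 / pr0$var) * pr0$mean
  mt <- as.vector(St %*% h)
  quad <- sum(h * mt) - sum(m * (iS %*% m)) -
    sum(reduced_priors$mean^2 / reduced_priors$var) +
    sum(pr0$mean^2 / pr0$var)
  logdets <- -determinant_psd(S) - sum(log(reduced_priors$var)) +
    sum(log(pr0$var)) - 2 * sum(log(diag(ch)))
  dF <- 0.5 * (quad + logdets)
  list(delta_F = dF, F = full_result$F + dF,
       posterior = list(mean = stats::setNames(mt, names(m)), cov = St))
}

shrink_var <- 1e-4
shrink_mean <- -6      # log-multiplier: gain effectively switched off

#' The 2 x 3 architecture model space
#'
#' Reduced-prior specifications for the six candidate architectures:
#' coupling scheme (recurrent vs forward-only, the latter shrinking the
#' toward-core extrinsic gain) crossed with input site (superficial, core,
#' deep; non-target input gains shrunk).
#'
#' @param priors full-model priors ([dcm_priors()] output).
#' @return list of 6 members, each with `name`, `coupling_scheme`,
#'   `input_target` and `priors`.
#' @export
build_architecture_space <- function(priors = NULL) {
  if (is.null(priors))
    priors <- dcm_priors(build_network(electrode_layout(-1:1)))
  sites <- c("superficial", "core", "deep")
  space <- list()
  for (scheme in c("recurrent", "forward_only")) {
    for (site in sites) {
      pr <- priors
      off <- setdiff(paste0("u_", sites), paste0("u_", site))
      pr$mean[off] <- shrink_mean
      pr$var[off] <- shrink_var
      if (scheme == "forward_only") {
        pr$mean["A_backward"] <- shrink_mean
        pr$var["A_backward"] <- shrink_var
      }
      space[[length(space) + 1L]] <-
        list(name = paste(scheme, site, sep = "_"),
             coupling_scheme = scheme, input_target = site, priors = pr)
    }
  }
  space
}

#' The within-electrode modulation model space
#'
#' Seven reduced-prior specifications (all non-empty subsets of forward
#' `F`, backward `B` and intrinsic self-inhibitory `i` modulations) over
#' the per-IED coupling-modulation parameters of a joint multi-IED
#' inversion. The full `FBi` member leaves all modulations free.
#'
#' @param priors full-model joint priors (`dcm_priors(net, n_ieds >= 2)`).
#' @return list of 7 members with `name`, `factors` and `priors`.
#' @export
build_modulation_space <- function(priors) {
  facs <- c("F", "B", "i")
  mod_names <- grep("^mod", names(priors$mean), value = TRUE)
  if (!length(mod_names))
    stop("priors contain no modulation parameters; use dcm_priors(net, n_ieds >= 2)")
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(facs, k, simplify = FALSE)), recursive = FALSE)
  lapply(subsets, function(on) {
    off <- setdiff(facs, on)
    pr <- priors
    for (f in off) {
      nm <- grep(paste0("_", f, "$"), mod_names, value = TRUE)
      pr$mean[nm] <- 0
      pr$var[nm] <- shrink_var
    }
    list(name = paste(on, collapse = ""), factors = on, priors = pr)
  })
}

variance_explained_raw <- function(y, pred) {
  sst <- sum((y - mean(y))^2)
  if (sst <= 0) stop("zero-variance data")
  ve <- 100 * (1 - sum((y - pred)^2) / sst)
  if (ve < 0) list(value = 0, flagged = TRUE) else
    list(value = ve, flagged = FALSE)
}

#' Percentage of data variance explained by a prediction
#'
#' `100 (1 - SS_res / SS_tot)` over all channels and samples; negative
#' values are reported as 0 with `flagged = TRUE`.
#'
#' @param result a `tw_dcmfit`, or a prediction matrix.
#' @param data data matrix (required when `result` is a matrix).
#' @return list with `value` (percent) and `flagged`.
#' @export
variance_explained <- function(result, data = NULL) {
  if (inherits(result, "tw_dcmfit")) {
    pred <- result$prediction
    data <- matrix(result$data, nrow(pred))
  } else pred <- result
  stopifnot(!is.null(data), all(dim(pred) == dim(data)))
  variance_explained_raw(as.vector(data), as.vector(pred))
}
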