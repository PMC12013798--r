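# Packaged in-silico experiments: the reference network and the seeded
# recovery studies run by the analysis scripts and the acceptance checks.

#' The group-average reference network
#'
#' A three-contact chain (deep, core, superficial) parameterised by the
#' group-level Bayesian-average posterior multipliers, with the
#' discharge-triggering input at the tuber core. This is the
#' parameterisation used for the in-silico gain-sweep experiments.
#'
#' @param positions contact positions (default `-1:1`).
#' @param params `"posterior"` (default) or `"prior"`.
#' @param coupling_scheme `"recurrent"` (default) or `"forward_only"`.
#' @param input_onset_ms onset of the triggering input (default 100 ms,
#'   placed inside the simulation window).
#' @return a `tw_network`.
#' @export
reference_network <- function(positions = -1:1, params = "posterior",
                              coupling_scheme = "recurrent",
                              input_onset_ms = 100) {
  net <- build_network(electrode_layout(positions), coupling_scheme, "core",
                       params)
  net$params$input$onset <- input_onset_ms
  net
}

# priors for the recovery experiments: nuisance parameters (intrinsic gains,
# time constants, sigmoid) centred on the generating group-average values,
# extrinsic and input parameters at their standard prior means
recovery_priors <- function(net) {
  tab <- cmc_group_averages()
  post <- stats::setNames(tab$posterior, tab$parameter)
  pri <- dcm_priors(net)
  nm <- c("g_sp_sp", "g_sp_ss", "g_ii_ss",
          "tau_ss", "tau_sp", "tau_ii", "tau_dp", "sigma")
  pri$mean[nm] <- log(post[nm])
  pri
}

# draw a stable generating network: group-posterior parameterisation with
# the extrinsic log-gains perturbed; shrink the perturbation until stable
draw_generating_network <- function(seed, sd_log = 0.35) {
  set.seed(as.integer(seed))
  tab <- cmc_group_averages()
  post <- stats::setNames(tab$posterior, tab$parameter)
  la <- log(c(post["A_forward"], post["A_backward"])) + stats::rnorm(2, 0, sd_log)
  net <- reference_network(params = "posterior", input_onset_ms = 0)
  repeat {
    net$params$A_forward <- exp(la[1])
    net$params$A_backward <- exp(la[2])
    if (linearise(net)$stable) break
    la <- la * 0.7
  }
  list(net = net, log_gains = stats::setNames(la, c("A_forward", "A_backward")))
}

#' Extrinsic coupling recovery experiment
#'
#' Generates single-IED epochs from known recurrent core-input networks
#' whose extrinsic (forward / backward) log-gains vary across seeds, inverts
#' each epoch, and correlates the recovered posterior means with the
#' generating values. The epoch window is extended to 450 ms so the
#' reverberation carrying the backward-coupling signature is observed, and
#' observation noise is low (high SNR recovery regime).
#'
#' @param n_seeds number of seeded runs (default 10).
#' @param noise_sd observation noise SD in microvolts (default 0.5).
#' @param seed base seed; run `i` uses `seed + i`.
#' @param window_ms epoch window (default `c(-100, 450)`).
#' @return list with `table` (seed, true and estimated log-gains),
#'   `r_forward`, `r_backward`.
#' @export
extrinsic_recovery_experiment <- function(n_seeds = 10, noise_sd = 0.5,
                                          seed = 1L,
                                          window_ms = c(-100, 450)) {
  tgrid <- seq(window_ms[1], window_ms[2], by = 1)
  netp <- reference_network(params = "prior", input_onset_ms = 0)
  pri <- recovery_priors(netp)
  rows <- NULL
  for (i in seq_len(n_seeds)) {
    gen <- draw_generating_network(seed + i)
    sim <- simulate_from_cmc(gen$net, observation_noise_sd = noise_sd,
                             n_ieds = 1, seed = seed + i, t_ms = tgrid)
    y <- apply_hanning(sim$epochs[[1]])
    attr(y, "t_ms") <- tgrid
    fit <- invert_dcm(y, netp, priors = pri,
                      settings = list(max_iter = 96L))
    est <- fit$posterior$mean[c("A_forward", "A_backward")]
    rows <- rbind(rows, data.frame(
      seed = seed + i,
      true_A_forward = gen$log_gains["A_forward"],
      true_A_backward = gen$log_gains["A_backward"],
      est_A_forward = est["A_forward"], est_A_backward = est["A_backward"],
      variance_explained = fit$variance_explained, row.names = NULL))
  }
  list(table = rows,
       r_forward = stats::cor(rows$true_A_forward, rows$est_A_forward),
       r_backward = stats::cor(rows$true_A_backward, rows$est_A_backward))
}

#' Architecture recovery experiment
#'
#' Generates synthetic electrodes from the recurrent core-input model,
#' inverts the full model on each, and scores every member of the
#' architecture space by Bayesian model reduction. Reports how often the
#' generating architecture attains the highest reduced free energy.
#'
#' @param n_electrodes number of synthetic electrodes (default 20).
#' @param noise_sd observation noise SD (default 0.5).
#' @param seed base seed.
#' @param window_ms epoch window (default `c(-100, 450)`).
#' @return list with `winners` (character per electrode), `n_correct`,
#'   `fraction_correct`, `free_energies` (electrodes x models).
#' @export
architecture_recovery_experiment <- function(n_electrodes = 20,
                                             noise_sd = 0.5, seed = 1L,
                                             window_ms = c(-100, 450)) {
  tgrid <- seq(window_ms[1], window_ms[2], by = 1)
  netp <- reference_network(params = "prior", input_onset_ms = 0)
  pri <- recovery_priors(netp)
  space <- build_architecture_space(pri)
  Fs <- matrix(NA_real_, n_electrodes, length(space),
               dimnames = list(NULL, vapply(space, `[[`, "", "name")))
  for (i in seq_len(n_electrodes)) {
    gen <- draw_generating_network(seed + 100 + i, sd_log = 0.2)
    sim <- simulate_from_cmc(gen$net, observation_noise_sd = noise_sd,
                             n_ieds = 1, seed = seed + 100 + i, t_ms = tgrid)
    y <- apply_hanning(sim$epochs[[1]])
    attr(y, "t_ms") <- tgrid
    fit <- invert_dcm(y, netp, priors = pri,
                      settings = list(max_iter = 96L))
    Fs[i, ] <- vapply(space, function(m) reduce_model(fit, m$priors)$F,
                      numeric(1))
  }
  winners <- colnames(Fs)[max.col(Fs)]
  list(winners = winners,
       n_correct = sum(winners == "recurrent_core"),
       fraction_correct = mean(winners == "recurrent_core"),
       free_energies = Fs)
}

#' Delay-model recovery experiment
#'
#' For each generating model (uniform, depth-to-surface,
#' core-to-periphery), simulates pooled delay observations, fits all three
#' models and records whether the generating model attains the lowest BIC,
#' and by what margin.
#'
#' @param n_replicates seeded replicates per generating model (default 100).
#' @param n observations per replicate (default 200).
#' @param a gradient slope in ms per position unit (default 5).
#' @param jitter_sd observation noise SD in ms (default 2).
#' @param seed base seed.
#' @return data frame: `generator`, `replicate`, `winner`, `delta_BIC`
#'   (winner's margin over the runner-up).
#' @export
delay_model_recovery <- function(n_replicates = 100, n = 200, a = 5,
                                 jitter_sd = 2, seed = 1L) {
  models <- c("uniform", "depth_to_surface", "core_to_periphery")
  out <- NULL
  for (gm in models) {
    for (r in seq_len(n_replicates)) {
      obs <- simulate_delay_observations(gm, n = n, a = a,
                                         jitter_sd = jitter_sd,
                                         seed = seed + 1000L * match(gm, models) + r)
      fits <- lapply(models, function(m) fit_delay_model(obs, m))
      cmpr <- compare_delay_models(fits)
      out <- rbind(out, data.frame(generator = gm, replicate = r,
                                   winner = cmpr$winner,
                                   delta_BIC = sort(cmpr$table$delta_BIC)[2]))
    }
  }
  out
}

#' Random-effects model-selection recovery experiment
#'
#' Draws synthetic evidence matrices whose electrodes are generated by
#' models with known population frequencies, runs [rfx_bms()], and checks
#' that the dominant generating model attains the highest expected
#' probability.
#'
#' @param n_replicates replicates (default 50).
#' @param n_electrodes electrodes per replicate (default 40).
#' @param n_models models (default 6).
#' @param freq population frequencies; default puts 0.65 on model 1 and
#'   spreads the rest (gap >= 0.3 to the runner-up).
#' @param evidence_gap mean free-energy advantage of the generating model
#'   on its electrodes, in nats (default 6).
#' @param seed base seed.
#' @return list with `correct` (logical per replicate), `fraction_correct`,
#'   `mean_abs_freq_error`.
#' @export
rfx_recovery_experiment <- function(n_replicates = 50, n_electrodes = 40,
                                    n_models = 6, freq = NULL,
                                    evidence_gap = 6, seed = 1L) {
  if (is.null(freq)) freq <- c(0.65, rep(0.35 / (n_models - 1), n_models - 1))
  stopifnot(abs(sum(freq) - 1) < 1e-9, length(freq) == n_models)
  correct <- logical(n_replicates)
  err <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    gen <- sample.int(n_models, n_electrodes, replace = TRUE, prob = freq)
    L <- matrix(stats::rnorm(n_electrodes * n_models, 0, 2),
                n_electrodes, n_models)
    L[cbind(seq_len(n_electrodes), gen)] <-
      L[cbind(seq_len(n_electrodes), gen)] + evidence_gap
    res <- rfx_bms(L, seed = seed + r, n_samples = 1e5)
    correct[r] <- which.max(res$expected_prob) == which.max(freq)
    err[r] <- mean(abs(res$expected_prob - freq))
  }
  list(correct = correct, fraction_correct = mean(correct),
       mean_abs_freq_error = mean(err))
}
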