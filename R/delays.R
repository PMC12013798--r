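#' Estimate inter-channel delays for a spike group
#'
#' Within a window centred on the earliest detected spike of the group, the
#' delay between each pair of neighbouring channels is the lag maximising
#' the absolute Pearson-normalised cross-correlation (the bipolar montage
#' can invert polarity between neighbours). Ties are broken toward the
#' smallest absolute lag. Per-channel detection times are the cumulative
#' pairwise delays referenced to the earliest channel.
#'
#' @param band_rec band-filtered `tw_recording` (one band of
#'   [band_split()]).
#' @param group a `tw_spikegroup` from [group_spikes()].
#' @param window_ms analysis window length in ms (default 200), centred on
#'   the group reference time; lags range over +/- `window_ms / 2`.
#' @param usable optional data frame from [local_maxima_around_group()];
#'   channels with `NA` peak time are excluded.
#' @param subsample use parabolic interpolation around the integer-lag
#'   maximum (default FALSE).
#' @return data frame of delay observations: `channel`, `position`, `t_ms`
#'   (time relative to the earliest channel), `pair_lag_ms`, `pair_corr`.
#'   Zero-variance channels are skipped with a message.
#' @export
estimate_delays <- function(band_rec, group, window_ms = 200, usable = NULL,
                            subsample = FALSE) {
  stopifnot(inherits(band_rec, "tw_recording"), inherits(group, "tw_spikegroup"))
  fs <- band_rec$sampling_rate
  half <- round(window_ms / 2 / 1000 * fs)
  c0 <- round(group$reference_time_ms / 1000 * fs) + 1L
  lo <- max(1L, c0 - half); hi <- min(n_samples(band_rec), c0 + half)
  chans <- seq_len(n_channels(band_rec))
  if (!is.null(usable)) chans <- usable$channel[!is.na(usable$peak_time_ms)]
  if (length(chans) < 2) stop("group has fewer than 2 usable channels")
  # order neighbours along the electrode
  pos <- if (is.null(band_rec$positions)) chans else band_rec$positions[chans]
  ord <- order(pos)
  chans <- chans[ord]; pos <- pos[ord]
  segs <- lapply(chans, function(ch) band_rec$samples[ch, lo:hi])
  ok <- vapply(segs, function(s) stats::sd(s) > 0, logical(1))
  if (any(!ok)) {
    message("skipping zero-variance channel(s): ",
            paste(chans[!ok], collapse = ", "))
    chans <- chans[ok]; pos <- pos[ok]; segs <- segs[ok]
    if (length(chans) < 2) stop("group has fewer than 2 usable channels")
  }
  lags <- numeric(length(chans) - 1L)
  corrs <- numeric(length(chans) - 1L)
  max_lag <- half
  for (i in seq_len(length(chans) - 1L)) {
    cc <- xcorr_norm(segs[[i]], segs[[i + 1L]], max_lag)
    j <- pick_lag(cc$corr)
    lag <- cc$lag[j]
    if (subsample && j > 1L && j < length(cc$lag)) {
      y <- abs(cc$corr[(j - 1L):(j + 1L)])
      den <- y[1] - 2 * y[2] + y[3]
      if (abs(den) > 1e-12) lag <- lag + 0.5 * (y[1] - y[3]) / den
    }
    lags[i] <- lag / fs * 1000
    corrs[i] <- cc$corr[j]
  }
  t_cum <- c(0, cumsum(lags))          # sign: positive = channel i+1 later
  t_cum <- t_cum - min(t_cum)          # reference to earliest channel
  data.frame(channel = chans, position = pos, t_ms = t_cum,
             pair_lag_ms = c(NA, lags), pair_corr = c(NA, corrs))
}

# normalised cross-correlation of equal-length windows over integer lags;
# positive lag means y lags x (y shifted right relative to x)
xcorr_norm <- function(x, y, max_lag) {
  n <- length(x)
  lags <- -max_lag:max_lag
  corr <- vapply(lags, function(L) {
    if (L >= 0) {
      xi <- x[1:(n - L)]; yi <- y[(1 + L):n]
    } else {
      xi <- x[(1 - L):n]; yi <- y[1:(n + L)]
    }
    if (length(xi) < 8 || stats::sd(xi) == 0 || stats::sd(yi) == 0)
      return(0)
    stats::cor(xi, yi)
  }, numeric(1))
  list(lag = lags, corr = corr)
}

# argmax of |corr|; near-ties (within a small plateau tolerance, as arise on
# smooth low-band windows) break toward the smallest |lag|
pick_lag <- function(corr, tol = 1e-3) {
  a <- abs(corr)
  best <- max(a)
  cand <- which(a >= best - tol)
  lags <- seq_along(corr) - (length(corr) + 1L) / 2
  cand[which.min(abs(lags[cand]))]
}

#' Fit one linear spatiotemporal delay model
#'
#' The three candidate explanations of spike-timing structure along the
#' electrode are ordinary least squares fits of detection time `t` on:
#' a constant (`uniform`, no spatial pattern), the signed position
#' (`depth_to_surface`, a gradient along the grey-white axis), or the
#' absolute distance from the core (`core_to_periphery`). The Gaussian log
#' likelihood is evaluated at the maximum-likelihood residual variance, and
#' `BIC = log(n) k - 2 log L` with `k` counting the residual variance (2 for
#' uniform, 3 for the gradient models).
#'
#' @param observations data frame with columns `position` and `t_ms`
#'   (pooled delay observations, e.g. rows of [estimate_delays()] outputs).
#' @param model `"uniform"`, `"depth_to_surface"` or `"core_to_periphery"`.
#' @return a `tw_delayfit` list: `model`, `a`, `b`, `sigma2`,
#'   `log_likelihood`, `n`, `k`, `BIC`, `fitted`.
#' @export
fit_delay_model <- function(observations,
                            model = c("uniform", "depth_to_surface",
                                      "core_to_periphery")) {
  model <- match.arg(model)
  t <- observations$t_ms
  p <- observations$position
  stopifnot(length(t) == length(p), !anyNA(t), !anyNA(p))
  k <- if (model == "uniform") 2L else 3L
  n <- length(t)
  if (n < k + 1) stop("need at least k + 1 observations")
  x <- switch(model, uniform = NULL, depth_to_surface = p,
              core_to_periphery = abs(p))
  if (!is.null(x) && stats::var(x) == 0)
    stop("degenerate design: all predictor values equal for model ", model)
  fit <- if (is.null(x)) stats::lm(t ~ 1) else stats::lm(t ~ x)
  res <- stats::residuals(fit)
  sigma2 <- sum(res^2) / n                  # MLE variance
  logL <- -n / 2 * (log(2 * pi * sigma2) + 1)
  if (sigma2 < .Machine$double.eps) logL <- Inf
  cf <- stats::coef(fit)
  structure(list(model = model,
                 a = if (is.null(x)) NA_real_ else unname(cf[2]),
                 b = unname(cf[1]),
                 sigma2 = sigma2, log_likelihood = logL,
                 n = n, k = k,
                 BIC = log(n) * k - 2 * logL,
                 fitted = unname(stats::fitted(fit))),
            class = "tw_delayfit")
}

#' Compare the three delay models by BIC
#'
#' @param fits list of `tw_delayfit` objects fitted to identical
#'   observations.
#' @param very_strong_delta evidence threshold on the BIC difference
#'   (default 10, the conventional "very strong" level).
#' @return list with `winner` (model name, or `NA` on an exact tie),
#'   `table` (model, BIC, delta_BIC relative to the winner) and `verdict`
#'   (`"very strong"` when the runner-up delta exceeds the threshold, else
#'   `"inconclusive"`, or `"tie"`).
#' @export
compare_delay_models <- function(fits, very_strong_delta = 10) {
  stopifnot(length(fits) >= 2)
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(ns)) != 1L)
    stop("fits were made on different observation counts: ",
         paste(ns, collapse = ", "))
  bic <- vapply(fits, function(f) f$BIC, numeric(1))
  mods <- vapply(fits, function(f) f$model, "")
  tab <- data.frame(model = mods, BIC = bic, delta_BIC = bic - min(bic))
  tab <- tab[order(tab$BIC), , drop = FALSE]
  tied <- sum(abs(bic - min(bic)) < 1e-9) > 1L
  runner_delta <- sort(bic - min(bic))[2]
  list(winner = if (tied) NA_character_ else mods[which.min(bic)],
       table = tab,
       verdict = if (tied) "tie"
                 else if (runner_delta > very_strong_delta) "very strong"
                 else "inconclusive")
}

#' Convert a delay gradient to a propagation speed
#'
#' A slope of `a` ms per position unit with contacts `contact_spacing_mm`
#' apart corresponds to a wave speed of `spacing / |a|`, reported in cm/s.
#'
#' @param fit a gradient `tw_delayfit` (not uniform).
#' @param contact_spacing_mm contact spacing in mm.
#' @return speed in cm/s.
#' @export
propagation_speed <- function(fit, contact_spacing_mm = 3.5) {
  stopifnot(inherits(fit, "tw_delayfit"))
  if (fit$model == "uniform") stop("uniform model has no propagation speed")
  if (is.na(fit$a) || fit$a == 0)
    stop("zero slope: propagation speed unbounded (flagged, not returned)")
  # mm/ms == m/s; x100 gives cm/s
  contact_spacing_mm / abs(fit$a) * 100
}

#' Simulate pooled delay observations from a known generating model
#'
#' Draws `n` observations `t = a f(p) + b + noise` with positions sampled
#' uniformly from `positions`, for model-recovery experiments.
#'
#' @param model generating model name.
#' @param n number of observations (default 200).
#' @param a,b slope (ms/position) and intercept (ms).
#' @param jitter_sd Gaussian noise SD in ms (default 2).
#' @param positions position pool (default -2:2).
#' @param seed integer seed.
#' @return data frame with `position` and `t_ms`.
#' @export
simulate_delay_observations <- function(model, n = 200, a = 5, b = 0,
                                        jitter_sd = 2, positions = -2:2,
                                        seed = 1L) {
  set.seed(as.integer(seed))
  p <- sample(positions, n, replace = TRUE)
  t <- a * delay_model_f(model, p) + b + stats::rnorm(n, 0, jitter_sd)
  data.frame(position = p, t_ms = t)
}
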