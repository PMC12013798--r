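# Group-level inference over per-electrode model evidences: random-effects
# Bayesian model selection (variational Dirichlet scheme) with exceedance
# probabilities, a fixed-effects baseline, and Bayesian parameter averaging.

#' Random-effects Bayesian model selection
#'
#' Treats the model generating each electrode's data as drawn from an
#' unknown population frequency vector with a Dirichlet prior, and runs the
#' variational update scheme on the per-electrode log evidences (free
#' energies). Exceedance probabilities (the posterior probability that a
#' model is the most frequent one) are estimated by seeded Monte Carlo
#' sampling of the posterior Dirichlet, with the analytic Beta shortcut for
#' two models.
#'
#' @param evidence electrodes x models matrix of free energies (nats).
#' @param seed integer seed for the Dirichlet sampling.
#' @param alpha0 Dirichlet prior count per model (default 1).
#' @param n_samples Monte Carlo samples (default 1e6).
#' @return list with `expected_prob` (posterior expected model
#'   frequencies), `exceedance_prob`, `alpha` (Dirichlet counts),
#'   `assignment` (electrodes x models posterior membership).
#' @export
rfx_bms <- function(evidence, seed = 1L, alpha0 = 1, n_samples = 1e6) {
  stopifnot(is.matrix(evidence), ncol(evidence) >= 2, nrow(evidence) >= 2,
            all(is.finite(evidence)))
  n <- nrow(evidence); M <- ncol(evidence)
  alpha <- rep(alpha0, M)
  for (it in 1:200) {
    lg <- sweep(evidence, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- exp(lg - apply(lg, 1L, max))
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < 1e-8) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  expected <- alpha / sum(alpha)
  set.seed(as.integer(seed))
  if (M == 2) {
    # P(r1 > r2) = P(Beta(a1, a2) > 1/2)
    xp1 <- stats::pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
    xp <- c(xp1, 1 - xp1)
  } else {
    g <- matrix(stats::rgamma(n_samples * M, shape = rep(alpha, each = n_samples)),
                n_samples, M)
    xp <- tabulate(max.col(g), nbins = M) / n_samples
  }
  names(expected) <- names(xp) <- colnames(evidence)
  list(expected_prob = expected, exceedance_prob = xp, alpha = alpha,
       assignment = u)
}

#' Fixed-effects model comparison
#'
#' Sums free energies over electrodes (log group Bayes factors under the
#' assumption of one shared model) and applies a softmax.
#'
#' @param evidence electrodes x models matrix of free energies.
#' @return list with `summed_F` and `posterior_prob`.
#' @export
fixed_effects_bms <- function(evidence) {
  stopifnot(is.matrix(evidence), all(is.finite(evidence)))
  sF <- colSums(evidence)
  p <- exp(sF - max(sF))
  p <- p / sum(p)
  names(p) <- colnames(evidence)
  list(summed_F = sF, posterior_prob = p)
}

#' Bayesian parameter average over electrode posteriors
#'
#' Precision-weighted combination of Gaussian posteriors: precisions add,
#' and the mean is the precision-weighted mean. Invariant to the order of
#' the inputs.
#'
#' @param results list of `tw_dcmfit`s or of lists with `posterior$mean`
#'   and `posterior$cov` sharing one parameter naming.
#' @return list with `mean` and `cov` of the combined Gaussian.
#' @export
bayesian_parameter_average <- function(results) {
  stopifnot(length(results) >= 1)
  nm <- names(results[[1]]$posterior$mean)
  P <- 0; h <- 0
  for (r in results) {
    if (!identical(names(r$posterior$mean), nm))
      stop("mismatched parameter sets across results")
    iS <- chol2inv(chol((r$posterior$cov + t(r$posterior$cov)) / 2))
    P <- P + iS
    h <- h + iS %*% r$posterior$mean
  }
  S <- chol2inv(chol((P + t(P)) / 2))
  list(mean = stats::setNames(as.vector(S %*% h), nm), cov = S)
}
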