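# Representative-IED selection: stack spike-group epochs into a matrix,
# reduce by PCA, cluster with k-means and keep the member nearest each
# centroid.

#' Stack spike-group epochs into a groups x features matrix
#'
#' Each row is the concatenation of per-channel epochs centred on the group
#' reference time (the same window used for model inversion). Groups too
#' close to the segment edge are dropped with a message.
#'
#' @param rec a `tw_recording`.
#' @param groups list of `tw_spikegroup`s.
#' @param window_ms epoch window relative to the reference (default
#'   `c(-100, 250)`).
#' @return matrix with one row per usable group; attribute `group_ids`
#'   gives the index of each retained group.
#' @export
stack_groups <- function(rec, groups, window_ms = c(-100, 250)) {
  stopifnot(inherits(rec, "tw_recording"), length(groups) >= 1)
  fs <- rec$sampling_rate
  nw <- round((window_ms[2] - window_ms[1]) / 1000 * fs) + 1L
  rows <- list(); ids <- integer(0)
  for (i in seq_along(groups)) {
    ref <- groups[[i]]$reference_time_ms
    i0 <- round(ref / 1000 * fs) + 1L
    lo <- i0 + round(window_ms[1] / 1000 * fs)
    hi <- lo + nw - 1L
    if (lo < 1L || hi > n_samples(rec)) {
      message(sprintf("group %d too near the segment edge; dropped", i))
      next
    }
    rows[[length(rows) + 1L]] <- as.vector(t(rec$samples[, lo:hi, drop = FALSE]))
    ids <- c(ids, i)
  }
  if (!length(rows)) stop("no group fits within the segment")
  out <- do.call(rbind, rows)
  attr(out, "group_ids") <- ids
  out
}

#' PCA reduction retaining a target explained variance
#'
#' Centres the matrix (no per-feature scaling: amplitude carries signal)
#' and keeps the smallest number of leading components whose cumulative
#' explained variance reaches the threshold.
#'
#' @param mat groups x features matrix (>= 2 rows).
#' @param var_threshold cumulative explained-variance target (default 0.90).
#' @return list with `scores` (groups x components), `components`,
#'   `explained` (per-component fraction), `n_components`.
#' @export
pca_reduce <- function(mat, var_threshold = 0.90) {
  stopifnot(nrow(mat) >= 2)
  if (sum(apply(mat, 2L, stats::var)) <= 0)
    stop("zero-variance matrix")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  expl <- ev / sum(ev)
  ncomp <- which(cumsum(expl) >= var_threshold - 1e-12)[1]
  if (is.na(ncomp)) ncomp <- length(expl)
  list(scores = pc$x[, seq_len(ncomp), drop = FALSE],
       components = pc$rotation[, seq_len(ncomp), drop = FALSE],
       explained = expl, n_components = ncomp)
}

#' Select k representative spike groups by k-means
#'
#' Runs k-means (20 restarts, best inertia) in principal-component score
#' space and returns, per cluster, the member nearest the centroid by
#' Euclidean distance. Ties break toward the lowest group id. Clusters are
#' reported in order of their representative's id, so the selection is
#' invariant to row permutations of the input.
#'
#' @param scores groups x components score matrix (rownames or the
#'   `group_ids` attribute identify groups; defaults to row index).
#' @param k number of representatives (default 3).
#' @param seed integer seed for the k-means restarts.
#' @param nstart restarts (default 20).
#' @return integer vector of k selected group ids (all groups, with a
#'   warning, when fewer than k are available).
#' @export
select_representatives <- function(scores, k = 3, seed = 1L, nstart = 20) {
  ids <- attr(scores, "group_ids")
  if (is.null(ids)) ids <- seq_len(nrow(scores))
  n <- nrow(scores)
  if (n < k) {
    warning(sprintf("only %d groups for k = %d: returning all", n, k))
    return(ids)
  }
  # order rows by id so the outcome is independent of input row order
  ord <- order(ids)
  sc <- scores[ord, , drop = FALSE]
  ids <- ids[ord]
  set.seed(as.integer(seed))
  km <- stats::kmeans(sc, centers = k, nstart = nstart, iter.max = 100)
  reps <- vapply(seq_len(k), function(cl) {
    mem <- which(km$cluster == cl)
    dists <- sqrt(rowSums((sc[mem, , drop = FALSE] -
                           matrix(km$centers[cl, ], length(mem),
                                  ncol(sc), byrow = TRUE))^2))
    best <- mem[dists <= min(dists) + 1e-12]
    ids[min(best)]                      # tie-break: lowest group id
  }, numeric(1))
  sort(unname(reps))
}
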