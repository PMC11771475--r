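# Metrics: parameter and prediction RMSE, (adjusted) Rand index, and the
# particle-set-averaged adjusted Rand index.

#' RMSE for the concatenated parameter vector
#'
#' Root mean square error over the length-2N concatenation of intercepts and
#' slopes.
#'
#' @param est_alpha,est_beta estimated N-vectors.
#' @param true_alpha,true_beta true N-vectors.
#' @return scalar RMSE.
#' @export
rmse_params <- function(est_alpha, est_beta, true_alpha, true_beta) {
  if (length(est_alpha) != length(true_alpha) ||
      length(est_beta) != length(true_beta)) {
    stop("length mismatch between estimates and truth", call. = FALSE)
  }
  d <- c(est_alpha - true_alpha, est_beta - true_beta)
  sqrt(mean(d^2))
}

#' RMSE for one-step-ahead prediction
#'
#' @param y_pred predicted N-vector.
#' @param y_new realized N-vector.
#' @return scalar RMSE.
#' @export
rmse_prediction <- function(y_pred, y_new) {
  if (length(y_pred) != length(y_new)) stop("length mismatch", call. = FALSE)
  sqrt(mean((y_pred - y_new)^2))
}

#' Rand and adjusted Rand indices
#'
#' The Rand index is the proportion of unit pairs on which two partitions
#' agree (clustered together in both or separated in both); the
#' Hubert-Arabie adjusted Rand index corrects it for chance agreement, with
#' 1 for identical partitions and expectation about 0 for independent random
#' labelings.
#'
#' @param z1,z2 assignment vectors of equal length.
#' @return scalar index.
#' @export
adjusted_rand_index <- function(z1, z2) {
  ct <- rand_contingency(z1, z2)
  n <- ct$n
  exp_index <- sum(choose(ct$row_sums, 2)) * sum(choose(ct$col_sums, 2)) / choose(n, 2)
  max_index <- (sum(choose(ct$row_sums, 2)) + sum(choose(ct$col_sums, 2))) / 2
  if (max_index == exp_index) return(1)   # both partitions trivial
  (ct$sum_nij2 - exp_index) / (max_index - exp_index)
}

#' @rdname adjusted_rand_index
#' @export
rand_index <- function(z1, z2) {
  ct <- rand_contingency(z1, z2)
  n <- ct$n
  a <- ct$sum_nij2
  b <- choose(n, 2) - sum(choose(ct$row_sums, 2)) - sum(choose(ct$col_sums, 2)) + a
  (a + b) / choose(n, 2)
}

rand_contingency <- function(z1, z2) {
  if (length(z1) != length(z2)) stop("partitions must have equal length", call. = FALSE)
  tab <- table(z1, z2)
  list(
    n = length(z1),
    sum_nij2 = sum(choose(tab, 2)),
    row_sums = rowSums(tab),
    col_sums = colSums(tab)
  )
}

#' Particle-averaged adjusted Rand indices
#'
#' Approximate posterior mean ARI for each latent partition: the untempered
#' truncated-posterior-weighted average of `ARI(gamma_l, truth)` over the
#' particle set (duplicates merged).
#'
#' @param particles a `partopt_particles` object (or a `partopt_fit`).
#' @param za_true,zb_true true assignment vectors.
#' @return tibble with one row: `ari_alpha`, `ari_beta`.
#' @export
particle_averaged_ari <- function(particles, za_true, zb_true) {
  if (inherits(particles, "partopt_fit")) particles <- particles$particles
  stopifnot(inherits(particles, "partopt_particles"))
  keep <- !duplicated(particles$keys)
  w <- optimal_weights(particles$log_joints[keep], 1)
  aris_a <- vapply(particles$particles[keep], function(p) {
    adjusted_rand_index(p$za, za_true)
  }, numeric(1))
  aris_b <- vapply(particles$particles[keep], function(p) {
    adjusted_rand_index(p$zb, zb_true)
  }, numeric(1))
  tibble::tibble(ari_alpha = sum(w * aris_a), ari_beta = sum(w * aris_b))
}
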