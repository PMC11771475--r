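#' Model hyperparameters
#'
#' Collects the fixed hyperparameters of the CAR-within-clusters model:
#' within-cluster autocorrelation `rho`, CAR scale and grand-mean variance
#' multipliers (`a1`, `a2` for intercepts, `b1`, `b2` for slopes), the
#' Inverse-Gamma inputs `nu_sigma`, `lambda_sigma` for the residual variance
#' (shape `nu_sigma/2`, rate `nu_sigma*lambda_sigma/2`), and the partition
#' concentration `eta`.
#'
#' @param rho within-cluster spatial autocorrelation in [0, 1); 0.9 by
#'   default, concentrating the prior on smooth clusters while keeping the
#'   CAR precision well conditioned.
#' @param a1,a2,b1,b2 positive variance multipliers (all relative to the
#'   residual variance sigma^2).
#' @param nu_sigma,lambda_sigma positive Inverse-Gamma inputs.
#' @param eta positive Ewens-Pitman concentration, default 1.
#' @return list of class `partopt_hp`.
#' @export
model_hyperparams <- function(rho = 0.9, a1 = 1, a2 = 10, b1 = 1, b2 = 10,
                              nu_sigma = 3, lambda_sigma = 1, eta = 1) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  vals <- c(a1 = a1, a2 = a2, b1 = b1, b2 = b2,
            nu_sigma = nu_sigma, lambda_sigma = lambda_sigma, eta = eta)
  if (any(vals <= 0)) stop("all hyperparameters must be positive", call. = FALSE)
  structure(list(rho = rho, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                 nu_sigma = nu_sigma, lambda_sigma = lambda_sigma, eta = eta),
            class = "partopt_hp")
}

#' Leroux CAR covariance of a (sub)graph
#'
#' For a cluster with adjacency submatrix `subgraph_W`, the CAR covariance is
#' `[rho * Wstar + (1 - rho) * I]^{-1}` where `Wstar` is the unweighted graph
#' Laplacian; a singleton cluster has variance `1 / (1 - rho)`.
#'
#' @param subgraph_W binary symmetric adjacency matrix of the cluster.
#' @param rho autocorrelation in [0, 1).
#' @return positive-definite covariance matrix.
#' @export
car_covariance <- function(subgraph_W, rho) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
  subgraph_W <- as.matrix(subgraph_W)
  n <- nrow(subgraph_W)
  if (n == 1) return(matrix(1 / (1 - rho), 1, 1))
  P <- car_precision(subgraph_W, rho)
  chol2inv(safe_chol(P))
}

# precision rho * (D - W) + (1 - rho) * I of the Leroux CAR
car_precision <- function(subgraph_W, rho) {
  deg <- rowSums(subgraph_W)
  P <- -rho * subgraph_W
  diag(P) <- rho * deg + (1 - rho)
  P
}

# Cholesky with a single 1e-10 jitter retry before giving up
safe_chol <- function(M) {
  out <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(out)) {
    out <- chol(M + diag(1e-10, nrow(M)))
  }
  out
}

chol_solve <- function(R, b) {
  backsolve(R, forwardsolve(t(R), b))
}

# Per-cluster sufficient quantities for one side of the model.
#
# With V = scale * Sigma_CAR + gmvar * 1 1' (grand mean integrated out) and
# design norm d (T for intercepts, sum x^2 for slopes), returns
#   logdet = log det(I + d V)
#   theta  = V (I + d V)^{-1} s   (conditional posterior mean given sigma^2)
#   quad   = s' theta             (quadratic-form contribution to Q)
#   gm     = conditional posterior mean of the grand cluster mean
# Everything is computed from two Cholesky factorizations of the precision
# P = rho Wstar + (1-rho) I and of G = P + d * scale * I, plus rank-one
# corrections for the grand-mean term (matrix determinant lemma /
# Sherman-Morrison); no explicit inverses.
cluster_terms <- function(units, graph, s, d, scale, gmvar, rho) {
  n <- length(units)
  if (n == 1L) {
    V <- scale / (1 - rho) + gmvar
    z <- s / (1 + d * V)
    theta <- V * z
    P1 <- 1 - rho
    gm <- (P1 * theta / scale) / (1 / gmvar + P1 / scale)
    return(list(logdet = log1p(d * V), quad = s * theta, theta = theta, gm = gm))
  }
  Wsub <- graph$W[units, units]
  P <- car_precision(Wsub, rho)
  cP <- safe_chol(P)
  G <- P
  diag(G) <- diag(G) + d * scale
  cG <- safe_chol(G)
  # A = I + d * scale * P^{-1};  A^{-1} x = G^{-1} P x;  P 1 = (1 - rho) 1
  Ainv_s <- chol_solve(cG, P %*% s)
  Ainv_1 <- chol_solve(cG, rep(1 - rho, n))
  ldA <- 2 * sum(log(diag(cG))) - 2 * sum(log(diag(cP)))
  o1 <- sum(Ainv_1)
  os <- sum(Ainv_s)
  denom <- 1 + d * gmvar * o1
  z <- Ainv_s - (d * gmvar * os / denom) * Ainv_1   # (I + d V)^{-1} s
  theta <- scale * chol_solve(cP, z) + gmvar * sum(z)
  gm <- ((1 - rho) * sum(theta) / scale) / (1 / gmvar + (1 - rho) * n / scale)
  list(
    logdet = ldA + log(denom),
    quad = sum(s * theta),
    theta = as.numeric(theta),
    gm = gm
  )
}

# Fit context: precomputed data summaries plus a cluster-term cache.
# The cache key is the side ("a"/"b") plus the sorted unit indices; entries
# depend only on (y, x, graph, hyperparameters), all fixed within a context,
# so any candidate partition evaluation reuses terms of unchanged clusters.
po_context <- function(data, graph, hp) {
  stopifnot(inherits(data, "areal_ts"), inherits(graph, "areal_graph"))
  if (data$n != graph$n) stop("data and graph disagree on the number of units", call. = FALSE)
  x <- data$x
  nT <- data$n * data$t
  a0 <- hp$nu_sigma / 2
  b0 <- hp$nu_sigma * hp$lambda_sigma / 2
  list(
    data = data, graph = graph, hp = hp,
    s_a = rowSums(data$y),
    s_b = as.numeric(data$y %*% x),
    yss = sum(data$y^2),
    d_a = data$t,
    d_b = sum(x^2),
    # constants of the integrated-sigma^2 density, precomputed once
    b0 = b0,
    apost = a0 + nT / 2,
    mconst = -(nT / 2) * log(2 * pi) + a0 * log(b0) - lgamma(a0) +
      lgamma(a0 + nT / 2),
    cache = new.env(parent = emptyenv()),
    pcache = new.env(parent = emptyenv()),
    mcache = new.env(parent = emptyenv())
  )
}

# partition-level cache of c(logdet sum, quadratic-form sum); avoids any
# cluster-level work when a candidate partition has been scored before
partition_sums <- function(ctx, side, z, key = NULL) {
  key <- paste0(side, "|", key %||% partition_key(z))
  hit <- ctx$pcache[[key]]
  if (!is.null(hit)) return(hit)
  pt <- partition_terms(ctx, side, z)
  val <- c(pt$LD, pt$QD)
  ctx$pcache[[key]] <- val
  val
}

ctx_cluster_terms <- function(ctx, side, units) {
  key <- paste0(side, ":", paste(units, collapse = ","))
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- ctx$hp
  if (side == "a") {
    val <- cluster_terms(units, ctx$graph, ctx$s_a[units], ctx$d_a,
                         hp$a1, hp$a2, hp$rho)
  } else {
    val <- cluster_terms(units, ctx$graph, ctx$s_b[units], ctx$d_b,
                         hp$b1, hp$b2, hp$rho)
  }
  ctx$cache[[key]] <- val
  val
}

# Aggregate one partition's cluster terms: sum of logdets, sum of quads,
# per-cluster lists for estimates.
partition_terms <- function(ctx, side, z) {
  clusters <- split(seq_along(z), z)
  LD <- 0; QD <- 0
  terms <- vector("list", length(clusters))
  for (j in seq_along(clusters)) {
    tm <- ctx_cluster_terms(ctx, side, clusters[[j]])
    LD <- LD + tm$logdet
    QD <- QD + tm$quad
    terms[[j]] <- tm
  }
  list(LD = LD, QD = QD, terms = terms, clusters = clusters)
}

# Marginal log likelihood from the two partitions' aggregated terms.
marginal_from_terms <- function(ctx, LDa, QDa, LDb, QDb) {
  ctx$mconst - 0.5 * (LDa + LDb) -
    ctx$apost * log(ctx$b0 + (ctx$yss - QDa - QDb) / 2)
}

#' Exact log marginal likelihood of a particle
#'
#' Computes `log p(y | gamma)` with unit-level parameters, grand cluster
#' means, and the residual variance integrated out analytically (the result
#' is a multivariate-t log density). Because the intercept and slope designs
#' are orthogonal (`sum(x) = 0`), the computation decomposes into independent
#' per-cluster terms for each partition; see the methods vignette.
#'
#' @param data an [areal_ts()].
#' @param particle list with assignment vectors `za` (intercept partition)
#'   and `zb` (slope partition).
#' @param graph an [areal_graph()].
#' @param hp a [model_hyperparams()].
#' @return log marginal likelihood (scalar).
#' @export
log_marginal_likelihood <- function(data, particle, graph, hp) {
  ctx <- po_context(data, graph, hp)
  check_particle(particle, graph)
  pa <- partition_terms(ctx, "a", particle$za)
  pb <- partition_terms(ctx, "b", particle$zb)
  marginal_from_terms(ctx, pa$LD, pa$QD, pb$LD, pb$QD)
}

check_particle <- function(particle, graph) {
  if (!is_spatial(particle$za, graph) || !is_spatial(particle$zb, graph)) {
    stop("particle partitions must be spatial (all clusters connected)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Unnormalized log joint posterior of a particle
#'
#' `log p(y, gamma)` up to the (constant) spatial-truncation normalizer of
#' the Ewens-Pitman prior: the log marginal likelihood plus the unnormalized
#' log prior of both partitions.
#'
#' @inheritParams log_marginal_likelihood
#' @return unnormalized log joint (scalar).
#' @export
log_joint <- function(data, particle, graph, hp) {
  log_marginal_likelihood(data, particle, graph, hp) +
    log_ep_prior(particle$za, hp$eta) +
    log_ep_prior(particle$zb, hp$eta)
}

# internal fast path used by the optimizer (cached context, no re-validation)
ctx_log_joint <- function(ctx, za, zb) {
  pa <- partition_terms(ctx, "a", za)
  pb <- partition_terms(ctx, "b", zb)
  marginal_from_terms(ctx, pa$LD, pa$QD, pb$LD, pb$QD) +
    log_ep_prior(za, ctx$hp$eta) + log_ep_prior(zb, ctx$hp$eta)
}

#' Conditional posterior means given a particle
#'
#' Exact values of `E[alpha | gamma, y]`, `E[beta | gamma, y]` and the grand
#' cluster means. Because every prior covariance scales with sigma^2, the
#' means do not depend on the residual variance.
#'
#' @inheritParams log_marginal_likelihood
#' @return list with `alpha` and `beta` (N-vectors), `alpha_bar`, `beta_bar`
#'   (per-cluster vectors, in cluster-label order).
#' @export
conditional_posterior_means <- function(data, particle, graph, hp) {
  ctx <- po_context(data, graph, hp)
  check_particle(particle, graph)
  ctx_conditional_means(ctx, particle$za, particle$zb)
}

ctx_conditional_means <- function(ctx, za, zb) {
  n <- ctx$data$n
  pa <- partition_terms(ctx, "a", za)
  pb <- partition_terms(ctx, "b", zb)
  alpha <- numeric(n); beta <- numeric(n)
  for (j in seq_along(pa$clusters)) alpha[pa$clusters[[j]]] <- pa$terms[[j]]$theta
  for (j in seq_along(pb$clusters)) beta[pb$clusters[[j]]] <- pb$terms[[j]]$theta
  list(
    alpha = alpha, beta = beta,
    alpha_bar = vapply(pa$terms, `[[`, numeric(1), "gm"),
    beta_bar = vapply(pb$terms, `[[`, numeric(1), "gm")
  )
}
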