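# Independent oracles and random-instance generators shared across tests.

# Dense multivariate-t log density of the whole stacked panel: the marginal
# likelihood computed the brute-force way, with the full NT x NT scale
# matrix, no per-cluster decomposition. Stacking is unit-major.
oracle_log_marginal <- function(data, particle, graph, hp) {
  n <- data$n; tt <- data$t; x <- data$x
  Da <- kronecker(diag(n), rep(1, tt))
  Db <- kronecker(diag(n), x)
  blockV <- function(z, scale, gmvar) {
    V <- matrix(0, n, n)
    for (cl in split(seq_len(n), z)) {
      Sig <- car_covariance(graph$W[cl, cl, drop = FALSE], hp$rho)
      V[cl, cl] <- scale * Sig + gmvar
    }
    V
  }
  Va <- blockV(particle$za, hp$a1, hp$a2)
  Vb <- blockV(particle$zb, hp$b1, hp$b2)
  M <- diag(n * tt) + Da %*% Va %*% t(Da) + Db %*% Vb %*% t(Db)
  yv <- as.vector(t(data$y))
  p <- n * tt
  nu <- hp$nu_sigma
  lam <- hp$lambda_sigma
  Q <- drop(t(yv) %*% solve(M, yv))
  lgamma((nu + p) / 2) - lgamma(nu / 2) - (p / 2) * log(nu * pi) -
    0.5 * (p * log(lam) + as.numeric(determinant(M)$modulus)) -
    ((nu + p) / 2) * log(1 + Q / (lam * nu))
}

# Dense GLS oracle for the conditional posterior means:
# E[alpha | y] = Va Da' M^{-1} y (independent of sigma^2), likewise beta.
oracle_conditional_means <- function(data, particle, graph, hp) {
  n <- data$n; tt <- data$t; x <- data$x
  Da <- kronecker(diag(n), rep(1, tt))
  Db <- kronecker(diag(n), x)
  blockV <- function(z, scale, gmvar) {
    V <- matrix(0, n, n)
    for (cl in split(seq_len(n), z)) {
      Sig <- car_covariance(graph$W[cl, cl, drop = FALSE], hp$rho)
      V[cl, cl] <- scale * Sig + gmvar
    }
    V
  }
  Va <- blockV(particle$za, hp$a1, hp$a2)
  Vb <- blockV(particle$zb, hp$b1, hp$b2)
  M <- diag(n * tt) + Da %*% Va %*% t(Da) + Db %*% Vb %*% t(Db)
  yv <- as.vector(t(data$y))
  list(alpha = drop(Va %*% t(Da) %*% solve(M, yv)),
       beta = drop(Vb %*% t(Db) %*% solve(M, yv)))
}

# random connected graph: random spanning tree plus extra random edges
random_graph <- function(n, extra = n %/% 2) {
  W <- matrix(0, n, n)
  if (n > 1) {
    for (v in 2:n) {
      u <- sample.int(v - 1, 1)
      W[u, v] <- W[v, u] <- 1
    }
    for (e in seq_len(extra)) {
      uv <- sample.int(n, 2)
      if (uv[1] != uv[2]) W[uv[1], uv[2]] <- W[uv[2], uv[1]] <- 1
    }
  }
  areal_graph(W)
}

# random spatial partition: random labels repaired into connected components
random_spatial_partition <- function(graph, k) {
  z <- sample.int(k, graph$n, replace = TRUE)
  partopt:::repair_partition(z, graph)
}

random_areal_ts <- function(n, tt, sd = 1) {
  areal_ts(matrix(stats::rnorm(n * tt, sd = sd), n, tt))
}

random_hp <- function() {
  model_hyperparams(
    rho = stats::runif(1, 0.5, 0.95),
    a1 = stats::runif(1, 0.05, 2), a2 = stats::runif(1, 0.5, 5),
    b1 = stats::runif(1, 0.05, 2), b2 = stats::runif(1, 0.5, 5),
    nu_sigma = stats::runif(1, 3, 10),
    lambda_sigma = stats::runif(1, 0.3, 2)
  )
}

path_graph <- function(n) {
  graph_from_edges(cbind(seq_len(n - 1), seq_len(n - 1) + 1), n_units = n)
}

# two-cluster intercept / two-cluster slope panel on the 4-path, new noise
# draw each call
path4_data <- function(n_times = 12, sd = 0.5) {
  x <- standardize_times(n_times)
  y <- outer(c(0, 0, 3, 3), rep(1, n_times)) + outer(c(1, 1, 1, -1), x) +
    matrix(stats::rnorm(4 * n_times, sd = sd), 4, n_times)
  areal_ts(y)
}

# exact log joints of every particle on an enumerable graph
enumerate_log_joints <- function(data, graph, hp) {
  parts <- enumerate_spatial_partitions(graph)
  out <- data.frame(key = character(0), lj = numeric(0))
  keys <- character(0); ljs <- numeric(0)
  for (za in parts) {
    for (zb in parts) {
      keys <- c(keys, partopt:::particle_key(za, zb))
      ljs <- c(ljs, log_joint(data, list(za = za, zb = zb), graph, hp))
    }
  }
  data.frame(key = keys, lj = ljs, stringsAsFactors = FALSE)
}
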