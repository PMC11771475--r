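# Simulation design: grid graphs, fixed ground-truth partitions, and
# CAR-within-cluster parameter draws at three separation levels.

#' Rook-adjacency grid graph
#'
#' Units are laid out row-major: unit index `(r - 1) * cols + c` for row r,
#' column c. Edges join horizontally and vertically adjacent cells.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @return an [areal_graph()] with `rows`/`cols` stored for plotting.
#' @export
make_grid <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  idx <- function(r, c) (r - 1) * cols + c
  u <- integer(0); v <- integer(0)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      if (c < cols) { u <- c(u, idx(r, c)); v <- c(v, idx(r, c + 1)) }
      if (r < rows) { u <- c(u, idx(r, c)); v <- c(v, idx(r + 1, c)) }
    }
  }
  n <- rows * cols
  W <- matrix(0, n, n)
  if (length(u)) {
    W[cbind(u, v)] <- 1
    W[cbind(v, u)] <- 1
  }
  g <- areal_graph(W)
  g$rows <- rows
  g$cols <- cols
  g
}

# assign a rectangular block of grid cells to a cluster label
block_cells <- function(r1, r2, c1, c2, cols) {
  as.vector(outer((r1:r2 - 1) * cols, c1:c2, "+"))
}

#' Ground-truth partitions for the grid simulation design
#'
#' On the 20 x 20 grid the intercept partition has 10 connected clusters
#' with size multiset \{237, 50, 30, 25, 20, 15, 12, 6, 4, 1\} and the slope
#' partition has 4 clusters of sizes 188, 100, 100 and 12 (two 5-column
#' bands, a 3 x 4 block, and the remainder). The exact block geometry is an
#' implementation choice, fixed here; the cluster-size multisets are the
#' binding design quantities. A scaled-down 10 x 10 variant (5 intercept
#' clusters, 3 slope clusters) supports cheaper experiments.
#'
#' @param rows,cols grid dimensions; 20 x 20 (default) and 10 x 10 are
#'   supported.
#' @return list with canonical assignment vectors `za` and `zb`.
#' @export
fixture_partitions <- function(rows = 20, cols = 20) {
  if (rows == 20 && cols == 20) {
    n <- 400
    za <- rep(0L, n)
    # the singleton sits inside the 50-unit block, away from the remainder,
    # so clusters that share a grand mean are never spatially adjacent
    blocks <- list(
      setdiff(c(block_cells(1, 5, 1, 10, 20), block_cells(6, 6, 1, 1, 20)),
              block_cells(1, 1, 1, 1, 20)),  # 50
      block_cells(1, 3, 11, 20, 20),   # 30
      block_cells(7, 11, 1, 5, 20),    # 25
      block_cells(12, 15, 1, 5, 20),   # 20
      block_cells(16, 20, 1, 3, 20),   # 15
      block_cells(4, 6, 17, 20, 20),   # 12
      block_cells(19, 20, 4, 6, 20),   # 6
      block_cells(9, 10, 19, 20, 20),  # 4
      block_cells(1, 1, 1, 1, 20)      # 1
    )
    for (j in seq_along(blocks)) za[blocks[[j]]] <- j
    za[za == 0L] <- length(blocks) + 1L   # remainder: the 237-unit cluster
    zb <- rep(0L, n)
    zb[block_cells(1, 20, 1, 5, 20)] <- 1L    # 100
    zb[block_cells(1, 20, 6, 10, 20)] <- 2L   # 100
    zb[block_cells(1, 3, 11, 14, 20)] <- 3L   # 12
    zb[zb == 0L] <- 4L                        # 188
  } else if (rows == 10 && cols == 10) {
    n <- 100
    za <- rep(0L, n)
    za[block_cells(1, 5, 1, 5, 10)] <- 1L     # 25
    za[block_cells(1, 5, 6, 10, 10)] <- 2L    # 25
    za[block_cells(6, 10, 1, 5, 10)] <- 3L    # 25
    za[block_cells(6, 8, 6, 10, 10)] <- 4L    # 15
    za[block_cells(9, 10, 6, 10, 10)] <- 5L   # 10
    zb <- rep(0L, n)
    zb[block_cells(1, 10, 1, 5, 10)] <- 1L    # 50
    zb[block_cells(1, 3, 6, 8, 10)] <- 2L     # 9
    zb[zb == 0L] <- 3L                        # 41
  } else {
    stop("fixture partitions are defined for 20x20 and 10x10 grids", call. = FALSE)
  }
  list(za = canonical_partition(za), zb = canonical_partition(zb))
}

# K x K cluster adjacency induced by the unit adjacency
cluster_adjacency <- function(z, graph) {
  K <- max(z)
  adj <- matrix(FALSE, K, K)
  for (u in seq_len(graph$n)) {
    nb <- graph$nbrs[[u]]
    for (v in nb[z[nb] != z[u]]) adj[z[u], z[v]] <- TRUE
  }
  adj
}

# Assign grand means so that clusters sharing a mean are never spatially
# adjacent (else equal-mean neighbors would be unidentifiable): greedily
# pair each cluster, largest first, with its largest unpaired non-neighbor;
# clusters with no available partner keep a mean of their own. Mean values
# are `gap`-spaced and centered at zero.
pair_cluster_means <- function(z, graph, gap) {
  K <- max(z)
  adj <- cluster_adjacency(z, graph)
  ord <- order(tabulate(z), decreasing = TRUE)
  group <- integer(K)
  g <- 0L
  for (k in ord) {
    if (group[k] > 0L) next
    g <- g + 1L
    group[k] <- g
    partner <- ord[group[ord] == 0L & !adj[k, ord]]
    if (length(partner)) group[partner[1]] <- g
  }
  vals <- gap * (seq_len(g) - (g + 1) / 2)
  vals[group]
}

# draw one cluster's parameters from CAR(mean, tau2, W_k)
draw_car <- function(units, graph, mean, tau2, rho) {
  n <- length(units)
  if (n == 1) return(mean + sqrt(tau2 / (1 - rho)) * stats::rnorm(1))
  P <- car_precision(graph$W[units, units], rho)
  R <- safe_chol(P)
  mean + sqrt(tau2) * backsolve(R, stats::rnorm(n))
}

#' Simulate areal time series from the CAR-within-clusters design
#'
#' Generates Gaussian panels `y[i, t] = alpha_i + beta_i * x_t + eps` on a
#' grid with fixed ground-truth partitions ([fixture_partitions()]).
#' Intercept clusters share 5 distinct grand means — two clusters per value,
#' paired (largest first) so that equal-mean clusters are never spatially
#' adjacent, since adjacent equal-mean clusters would be indistinguishable
#' from their merge — spaced by a separation-dependent gap; slope clusters
#' get 4 distinct means. Within each cluster, parameters are drawn from a
#' CAR distribution around the cluster mean. Every unit has area 1.
#'
#' Separation gaps (intercept / slope): high 2.0 / 1.5, medium 1.0 / 0.75,
#' low 0.5 / 0.35, with residual variance 1 and within-cluster CAR scale
#' 0.01 — chosen so the cluster structure is visually obvious at high
#' separation and not at low.
#'
#' @param setting separation level: `"high"`, `"medium"` or `"low"`.
#' @param rows,cols grid dimensions (20 x 20 default, 10 x 10 supported).
#' @param n_times number of time points (default 12).
#' @param sigma2 residual variance (default 1).
#' @param car_scale within-cluster CAR scale relative to `sigma2`
#'   (default 0.01).
#' @param rho CAR autocorrelation used for the draws (default 0.9).
#' @param seed integer seed.
#' @return list with `data` (long tibble: unit, time, y, area), `graph`,
#'   and `truth` (list: `za`, `zb`, `alpha`, `beta`, `alpha_bar`,
#'   `beta_bar`, `sigma2`, `setting`).
#' @export
sim_cwc <- function(setting = c("high", "medium", "low"), rows = 20, cols = 20,
                    n_times = 12, sigma2 = 1, car_scale = 0.01, rho = 0.9,
                    seed = 1) {
  setting <- match.arg(setting)
  gaps <- list(high = c(2.0, 1.5), medium = c(1.0, 0.75), low = c(0.5, 0.35))[[setting]]
  graph <- make_grid(rows, cols)
  fx <- fixture_partitions(rows, cols)
  n <- graph$n
  x <- standardize_times(n_times)
  set.seed(seed)

  # intercepts: two clusters per mean value, paired so equal-mean clusters
  # are never adjacent (5 distinct means on the 20x20 design)
  ka <- max(fx$za)
  alpha_bar <- pair_cluster_means(fx$za, graph, gaps[1])

  kb <- max(fx$zb)
  sizes_b <- tabulate(fx$zb)
  rank_b <- order(order(sizes_b, decreasing = TRUE))
  mean_vals_b <- gaps[2] * (seq_len(kb) - (kb + 1) / 2)
  beta_bar <- mean_vals_b[rank_b]

  alpha <- numeric(n); beta <- numeric(n)
  for (k in seq_len(ka)) {
    units <- which(fx$za == k)
    alpha[units] <- draw_car(units, graph, alpha_bar[k], car_scale * sigma2, rho)
  }
  for (k in seq_len(kb)) {
    units <- which(fx$zb == k)
    beta[units] <- draw_car(units, graph, beta_bar[k], car_scale * sigma2, rho)
  }
  y <- outer(alpha, rep(1, n_times)) + outer(beta, x) +
    matrix(stats::rnorm(n * n_times, sd = sqrt(sigma2)), n, n_times)
  data <- tibble::tibble(
    unit = rep(seq_len(n), each = n_times),
    time = rep(seq_len(n_times) - 1L, n),
    y = as.vector(t(y)),
    area = 1
  )
  list(
    data = data,
    graph = graph,
    truth = list(za = fx$za, zb = fx$zb, alpha = alpha, beta = beta,
                 alpha_bar = alpha_bar, beta_bar = beta_bar,
                 sigma2 = sigma2, setting = setting)
  )
}

#' Convert simulated densities to crime-like counts
#'
#' Under the unit-area convention of the simulation design,
#' `c = round(sinh(y + log 2))`, floored at zero.
#'
#' @param y matrix (or vector) of transformed densities.
#' @return integer counts, same shape.
#' @export
simulate_counts <- function(y) {
  out <- round(sinh(y + log(2)))
  out[out < 0] <- 0
  storage.mode(out) <- "integer"
  out
}
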