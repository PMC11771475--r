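#' Fit the CAR-within-clusters model by particle optimization
#'
#' High-level pipeline: builds the data containers, selects hyperparameters
#' (data-dependently by default), runs the particle optimizer, and computes
#' model-averaged parameter estimates under the untempered truncated
#' posterior over distinct particles.
#'
#' @param data long data frame with columns `unit`, `time` and `y` (or
#'   `count` plus optional `area`), or an [areal_ts()].
#' @param adjacency an [areal_graph()], a dense 0/1 matrix, or a two-column
#'   edge data frame.
#' @param L number of particles.
#' @param lambda entropy penalty (inverse temperature).
#' @param rho,eta fixed hyperparameters, see [model_hyperparams()].
#' @param seed integer seed for the initialization draw.
#' @param hyperparams optional [model_hyperparams()]; when supplied,
#'   `hp_method` is ignored.
#' @param hp_method `"eb"` (default) or `"moments"`, see
#'   [fit_hyperparameters()].
#' @param max_sweeps,rel_tol,split_cap,island_quantile see
#'   [search_config()].
#' @param init optional list of initial particles.
#' @return object of class `partopt_fit` with components `particles`
#'   (a `partopt_particles`), `estimates` (tibble of model-averaged unit
#'   estimates and MAP cluster labels), `mle`, `data`, `graph`, `hp`.
#'   Use [generics::tidy()], [generics::glance()], `predict()` and
#'   `autoplot()` on it.
#' @export
partopt <- function(data, adjacency, L = 10, lambda = 100, rho = 0.9, eta = 1,
                    seed = 1, hyperparams = NULL,
                    hp_method = c("eb", "moments"), max_sweeps = 100,
                    rel_tol = 1e-8, split_cap = 5, island_quantile = 0.05,
                    init = NULL) {
  hp_method <- match.arg(hp_method)
  if (!inherits(data, "areal_ts")) data <- as_areal_ts(data)
  graph <- as_areal_graph(adjacency, unit_ids = data$unit_ids)
  hp <- hyperparams %||%
    fit_hyperparameters(data, graph, rho = rho, eta = eta, method = hp_method)
  config <- search_config(L = L, lam = lambda, seed = seed,
                          max_sweeps = max_sweeps, rel_tol = rel_tol,
                          split_cap = split_cap,
                          island_quantile = island_quantile)
  particles <- particle_optimize(data, graph, hp, config, init = init)
  est <- averaged_estimates(data, graph, hp, particles)
  structure(
    list(particles = particles, estimates = est, mle = compute_mle(data),
         data = data, graph = graph, hp = hp),
    class = "partopt_fit"
  )
}

as_areal_graph <- function(adjacency, unit_ids = NULL) {
  if (inherits(adjacency, "areal_graph")) return(adjacency)
  if (is.matrix(adjacency) && nrow(adjacency) == ncol(adjacency)) {
    return(areal_graph(adjacency, unit_ids = unit_ids))
  }
  graph_from_edges(adjacency, unit_ids = unit_ids)
}

# model-averaged conditional means over distinct particles
averaged_estimates <- function(data, graph, hp, particles) {
  ctx <- po_context(data, graph, hp)
  keep <- which(!duplicated(particles$keys))
  w <- optimal_weights(particles$log_joints[keep], 1)
  alpha <- numeric(data$n); beta <- numeric(data$n)
  for (j in seq_along(keep)) {
    p <- particles$particles[[keep[j]]]
    cm <- ctx_conditional_means(ctx, p$za, p$zb)
    alpha <- alpha + w[j] * cm$alpha
    beta <- beta + w[j] * cm$beta
  }
  map <- particles$particles[[1]]
  tibble::tibble(
    unit = data$unit_ids,
    alpha = alpha, beta = beta,
    cluster_alpha = map$za, cluster_beta = map$zb
  )
}

#' Model-averaged forecasts from a particle set
#'
#' Computes `E[alpha_i + beta_i * x_new | y]` approximated over the particle
#' set. Estimation and prediction use the *untempered* truncated posterior
#' weights by default (the tempered optimizer weights are also available).
#'
#' @param data an [areal_ts()].
#' @param graph an [areal_graph()].
#' @param hp a [model_hyperparams()].
#' @param particles a `partopt_particles` object.
#' @param x_new covariate value to forecast at (on the standardized time
#'   scale).
#' @param weights `"untempered"` (default) or `"tempered"`.
#' @return N-vector of forecasts.
#' @export
predict_particles <- function(data, graph, hp, particles, x_new,
                              weights = c("untempered", "tempered")) {
  weights <- match.arg(weights)
  if (length(particles$particles) == 0) stop("empty particle set", call. = FALSE)
  ctx <- po_context(data, graph, hp)
  keep <- which(!duplicated(particles$keys))
  lam <- if (weights == "untempered") 1 else particles$config$lam
  w <- optimal_weights(particles$log_joints[keep], lam)
  out <- numeric(data$n)
  for (j in seq_along(keep)) {
    p <- particles$particles[[keep[j]]]
    cm <- ctx_conditional_means(ctx, p$za, p$zb)
    out <- out + w[j] * (cm$alpha + cm$beta * x_new)
  }
  out
}

#' Standardized covariate value of a future time point
#'
#' Raw time indices 0..T-1 are standardized during fitting; this returns the
#' value the index `T - 1 + horizon` maps to on that scale.
#'
#' @param n_times number of observed time points.
#' @param horizon steps ahead (default 1).
#' @return scalar covariate value.
#' @export
future_x <- function(n_times, horizon = 1) {
  raw <- seq_len(n_times) - 1
  ((n_times - 1 + horizon) - mean(raw)) / stats::sd(raw)
}

#' @export
print.partopt_fit <- function(x, ...) {
  ps <- x$particles
  cat("CAR-within-clusters fit by particle optimization\n")
  cat("  units: ", x$data$n, ", time points: ", x$data$t, "\n", sep = "")
  cat("  particles: ", length(ps$particles), " (",
      length(unique(ps$keys)), " distinct), sweeps: ", ps$sweeps,
      if (ps$converged) " (converged)" else " (NOT converged)", "\n", sep = "")
  map <- ps$particles[[1]]
  cat("  MAP particle: ", max(map$za), " intercept clusters, ",
      max(map$zb), " slope clusters\n", sep = "")
  invisible(x)
}

#' @export
predict.partopt_fit <- function(object, x_new = NULL, horizon = 1,
                                weights = c("untempered", "tempered"), ...) {
  x_new <- x_new %||% future_x(object$data$t, horizon)
  pred <- predict_particles(object$data, object$graph, object$hp,
                            object$particles, x_new, match.arg(weights))
  tibble::tibble(unit = object$data$unit_ids, x_new = x_new, y_pred = pred)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-unit estimates of a fit
#'
#' @param x a `partopt_fit`.
#' @param ... unused.
#' @return tibble with `unit`, model-averaged `alpha` and `beta`, and the
#'   MAP particle's cluster labels.
#' @method tidy partopt_fit
#' @export
tidy.partopt_fit <- function(x, ...) {
  x$estimates
}

#' One-row summary of a fit
#'
#' @param x a `partopt_fit`.
#' @param ... unused.
#' @return tibble with problem size, particle-set diagnostics and the final
#'   objective value.
#' @method glance partopt_fit
#' @export
glance.partopt_fit <- function(x, ...) {
  ps <- x$particles
  map <- ps$particles[[1]]
  tibble::tibble(
    n_units = x$data$n,
    n_times = x$data$t,
    L = length(ps$particles),
    n_distinct = length(unique(ps$keys)),
    k_alpha_map = max(map$za),
    k_beta_map = max(map$zb),
    objective = ps$objective_trace[length(ps$objective_trace)],
    log_joint_map = ps$log_joints[1],
    sweeps = ps$sweeps,
    converged = ps$converged
  )
}

#' Map of estimates and clusters on a grid
#'
#' For fits on grid graphs (from [make_grid()]): tile map of the
#' model-averaged estimates with MAP cluster boundaries.
#'
#' @param object a `partopt_fit` on a grid graph.
#' @param which `"alpha"` or `"beta"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot partopt_fit
#' @export
autoplot.partopt_fit <- function(object, which = c("alpha", "beta"), ...) {
  which <- match.arg(which)
  g <- object$graph
  if (is.null(g$rows)) stop("autoplot requires a grid graph from make_grid()", call. = FALSE)
  est <- object$estimates
  d <- tibble::tibble(
    row = rep(seq_len(g$rows), each = g$cols),
    col = rep(seq_len(g$cols), g$rows),
    value = est[[which]],
    cluster = factor(est[[paste0("cluster_", which)]])
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$value), color = "grey30") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$cluster), size = 0.8,
                        show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = which,
                  title = paste0("Model-averaged ", which,
                                 " with MAP clusters")) +
    ggplot2::theme_minimal()
}

#' Objective trace plot
#'
#' Objective value after every accepted move of the coordinate ascent; the
#' trace is non-decreasing by construction.
#'
#' @param fit a `partopt_fit` or `partopt_particles`.
#' @return a ggplot object.
#' @export
plot_objective <- function(fit) {
  ps <- if (inherits(fit, "partopt_fit")) fit$particles else fit
  d <- tibble::tibble(step = seq_along(ps$objective_trace),
                      objective = ps$objective_trace)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::labs(x = "accepted move", y = "penalized objective") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
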