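#' Search configuration for the particle optimizer
#'
#' @param L number of particles (>= 1). 10 is a good default at simulation
#'   scale; 20 for data-analysis-scale problems.
#' @param lam entropy penalty (inverse temperature) lambda > 0. The global
#'   optimum is the same for every lambda; the local search behaves best for
#'   large values (default 100).
#' @param seed integer seed; used for the randomized initialization draw.
#' @param max_sweeps cap on coordinate-ascent sweeps.
#' @param rel_tol relative objective-improvement tolerance for convergence.
#' @param split_cap maximum number of k-means parts in split moves.
#' @param island_quantile tail probability for island-move eligibility.
#' @return list of class `partopt_config`.
#' @export
search_config <- function(L = 10, lam = 100, seed = 1, max_sweeps = 100,
                          rel_tol = 1e-8, split_cap = 5, island_quantile = 0.05) {
  if (L < 1) stop("L must be at least 1", call. = FALSE)
  if (lam <= 0) stop("lam must be positive", call. = FALSE)
  structure(list(L = as.integer(L), lam = lam, seed = as.integer(seed),
                 max_sweeps = as.integer(max_sweeps), rel_tol = rel_tol,
                 split_cap = as.integer(split_cap),
                 island_quantile = island_quantile),
            class = "partopt_config")
}

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# objective value at the optimal weights: lambda * logsumexp over the
# distinct support of log_joint / lambda
distinct_logsumexp <- function(log_joints, keys, lam) {
  lam * logsumexp(log_joints[!duplicated(keys)] / lam)
}

#' Entropy of a particle set's approximating distribution
#'
#' The approximating distribution q lives on the *distinct* particles:
#' duplicates are merged by summing their weights before computing
#' `-sum(q log q)` (natural log, with 0 log 0 = 0).
#'
#' @param weights L-vector on the simplex.
#' @param keys optional character keys identifying duplicate particles; by
#'   default all particles are treated as distinct.
#' @return entropy (nonnegative scalar).
#' @export
particle_entropy <- function(weights, keys = NULL) {
  keys <- keys %||% as.character(seq_along(weights))
  p <- vapply(split(weights, keys), sum, numeric(1))
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Optimal importance weights (tempered)
#'
#' The entropy-penalized objective is maximized in the weights at
#' `w_l` proportional to `exp(log_joint_l / lam)` over distinct particles;
#' duplicates share their merged weight equally. Computed with
#' max-subtraction for numerical stability.
#'
#' @param log_joints L-vector of unnormalized log posteriors.
#' @param lam tempering penalty lambda > 0 (lam = 1 gives the untempered
#'   truncated posterior weights).
#' @param keys optional duplicate keys, as in [particle_entropy()].
#' @return L-vector of weights summing to one.
#' @export
optimal_weights <- function(log_joints, lam, keys = NULL) {
  if (lam <= 0) stop("lam must be positive", call. = FALSE)
  keys <- keys %||% as.character(seq_along(log_joints))
  dup <- duplicated(keys)
  lw <- log_joints[!dup] / lam
  w_distinct <- exp(lw - logsumexp(lw))
  names(w_distinct) <- keys[!dup]
  mult <- table(keys)
  w <- as.numeric(w_distinct[keys] / as.numeric(mult[keys]))
  w / sum(w)
}

#' Entropy-penalized ensemble objective
#'
#' `sum_l w_l log p(y, gamma_l) + lam * H(Gamma, w)`. At the optimal weights
#' of [optimal_weights()] with distinct particles this equals
#' `lam * logsumexp(log_joints / lam)`.
#'
#' @inheritParams optimal_weights
#' @param weights L-vector on the simplex.
#' @return objective value.
#' @export
particle_objective <- function(log_joints, weights, lam, keys = NULL) {
  sum(weights * log_joints) + lam * particle_entropy(weights, keys)
}

#' Per-unit maximum likelihood estimates
#'
#' Ordinary least squares of each unit's series on the standardized time
#' covariate: intercept, slope, and residual variance (denominator T - 2).
#'
#' @param data an [areal_ts()].
#' @return tibble with columns `unit`, `alpha`, `beta`, `s2`.
#' @export
compute_mle <- function(data) {
  stopifnot(inherits(data, "areal_ts"))
  if (data$t < 3) stop("T >= 3 required for residual variance", call. = FALSE)
  x <- data$x
  alpha <- rowMeans(data$y)
  beta <- as.numeric(data$y %*% x) / sum(x^2)
  fitted <- outer(alpha, rep(1, data$t)) + outer(beta, x)
  s2 <- rowSums((data$y - fitted)^2) / (data$t - 2)
  tibble::tibble(unit = data$unit_ids, alpha = alpha, beta = beta, s2 = s2)
}

#' Data-dependent hyperparameter selection
#'
#' Sets `nu_sigma`, `lambda_sigma` by matching the Inverse-Gamma
#' (`nu/2`, `nu*lambda/2`) mean and variance to the sample moments of the
#' per-unit residual variances; initializes `a2`, `b2` from the variances of
#' the per-unit MLEs with `a1 = a2 / 10`, `b1 = b2 / 10`; and, with
#' `method = "eb"`, refines (`a1`, `a2`, `b1`, `b2`) by a coordinate-wise
#' empirical-Bayes grid search (5 log-spaced points per parameter over
#' 1e-2 to 1e2 times the initial value, 2 passes) maximizing the marginal
#' likelihood at a MAP particle found with a single-particle search.
#'
#' @param data an [areal_ts()].
#' @param graph an [areal_graph()]; required for `method = "eb"`.
#' @param rho fixed autocorrelation, default 0.9.
#' @param eta fixed partition concentration, default 1.
#' @param method `"eb"` (full procedure) or `"moments"` (skip the grid
#'   refinement).
#' @param map_sweeps sweep cap for the internal MAP search.
#' @return a [model_hyperparams()].
#' @export
fit_hyperparameters <- function(data, graph = NULL, rho = 0.9, eta = 1,
                                method = c("eb", "moments"), map_sweeps = 25) {
  method <- match.arg(method)
  mle <- compute_mle(data)
  m <- mean(mle$s2)
  v <- stats::var(mle$s2)
  if (!is.finite(v) || v <= 0) {
    nu <- 3
    lambda <- max(m, 1e-8)
  } else {
    nu <- 2 * (2 + m^2 / v)
    lambda <- m * (nu - 2) / nu
  }
  # temporary CAR scales from a k-means split of the MLEs at the expected
  # cluster count: the within-cluster spread initializes the within-cluster
  # scale (a1, b1), the overall spread the grand-mean variance (a2, b2).
  # Initializing a1 from the overall spread instead lets smooth
  # within-cluster variation absorb between-cluster jumps and biases the
  # whole procedure toward a single big cluster.
  # The raw within-cluster spread of the MLEs mixes true within-cluster
  # signal with sampling noise of known size (mean(s2)/T for intercepts,
  # mean(s2)/sum(x^2) for slopes); subtracting it leaves a moment estimate
  # of the within-cluster signal variance.
  Kinit <- max(1, floor(eta * log(nrow(mle))))
  ab_init <- function(est, noise_var) {
    km <- kmeans_1d(est, Kinit)
    within <- sum((est - stats::ave(est, km))^2) / max(length(est) - max(km), 1)
    tot <- max(stats::var(est), 1e-8)
    c(max(within - noise_var, 1e-3 * tot, 1e-8), tot)
  }
  x <- data$x
  ai <- ab_init(mle$alpha, m / data$t)
  bi <- ab_init(mle$beta, m / sum(x^2))
  hp <- model_hyperparams(rho = rho, a1 = ai[1], a2 = ai[2],
                          b1 = bi[1], b2 = bi[2],
                          nu_sigma = nu, lambda_sigma = lambda, eta = eta)
  if (method == "moments") return(hp)
  if (is.null(graph)) stop("graph is required for empirical-Bayes refinement", call. = FALSE)
  pars <- c("a1", "a2", "b1", "b2")
  # two rounds of (single-particle MAP search, coordinate-wise grid EB at
  # the MAP): re-finding the MAP under the refined hyperparameters keeps the
  # empirical-Bayes estimate and the partition it conditions on consistent
  base <- unlist(hp[pars])   # grids stay anchored at the moment-based values
  for (round in 1:2) {
    cfg <- search_config(L = 1, lam = 1, seed = 1, max_sweeps = map_sweeps)
    map <- particle_optimize(data, graph, hp, cfg)
    map_particle <- map$particles[[1]]
    for (pass in 1:2) {
      for (p in pars) {
        grid <- unique(c(hp[[p]], base[[p]] * 10^seq(-2, 2, length.out = 5)))
        vals <- vapply(grid, function(g) {
          h <- hp; h[[p]] <- g
          log_marginal_likelihood(data, map_particle, graph, h)
        }, numeric(1))
        hp[[p]] <- grid[which.max(vals)]
      }
    }
  }
  hp
}

# --- coordinate ascent -----------------------------------------------------

# build internal particle record with cached partition-level sums, keys and
# prior values for both sides
make_particle <- function(ctx, za, zb) {
  za <- canonical_partition(za)
  zb <- canonical_partition(zb)
  key_a <- partition_key(za)
  key_b <- partition_key(zb)
  sa <- partition_sums(ctx, "a", za, key_a)
  sb <- partition_sums(ctx, "b", zb, key_b)
  pr_a <- log_ep_prior(za, ctx$hp$eta)
  pr_b <- log_ep_prior(zb, ctx$hp$eta)
  lj <- marginal_from_terms(ctx, sa[1], sa[2], sb[1], sb[2]) + pr_a + pr_b
  list(za = za, zb = zb, LDa = sa[1], QDa = sa[2], LDb = sb[1], QDb = sb[2],
       pr_a = pr_a, pr_b = pr_b,
       lj = lj, key_a = key_a, key_b = key_b,
       key = paste(key_a, key_b, sep = "|"))
}

# Candidate pool for one side of one particle, from the running
# conditional-mean estimates of that side; returns candidates with their
# partition keys.
side_candidates <- function(ctx, p, side, split_cap, island_quantile) {
  z <- if (side == "a") p$za else p$zb
  pt <- partition_terms(ctx, side, z)
  est <- numeric(length(z))
  for (j in seq_along(pt$clusters)) est[pt$clusters[[j]]] <- pt$terms[[j]]$theta
  gms <- vapply(pt$terms, `[[`, numeric(1), "gm")
  with_keys(c(
    island_moves(z, ctx$graph, est, island_quantile),
    border_moves(z, ctx$graph),
    merge_moves(z, ctx$graph, gms),
    split_moves(z, ctx$graph, est, split_cap),
    split_merge_moves(z, ctx$graph, est, gms, split_cap)
  ))
}

with_keys <- function(cands) {
  keys <- vapply(cands, partition_key, character(1))
  keep <- !duplicated(keys)
  list(z = cands[keep], keys = keys[keep])
}

# Cached candidate pool for one side of a particle: candidates with their
# partition keys, sums (logdet/quadratic), priors and cluster counts — all
# independent of the other side, so the pool is keyed by the partition
# alone and reused across sweeps and particles.
side_pool <- function(ctx, p, side, split_cap, island_quantile,
                      islands_only = FALSE) {
  pkey0 <- if (side == "a") p$key_a else p$key_b
  ckey <- paste0(if (islands_only) "i" else "m", side, "|", pkey0)
  hit <- ctx$mcache[[ckey]]
  if (!is.null(hit)) return(hit)
  if (islands_only) {
    z <- if (side == "a") p$za else p$zb
    cands <- with_keys(all_island_sweep(z, ctx$graph))
  } else {
    cands <- side_candidates(ctx, p, side, split_cap, island_quantile)
  }
  m <- length(cands$z)
  LD <- numeric(m); QD <- numeric(m); pr <- numeric(m); Ks <- integer(m)
  sums <- vector("list", m)
  for (i in seq_len(m)) {
    s <- partition_sums(ctx, side, cands$z[[i]], cands$keys[[i]])
    sums[[i]] <- s
    LD[i] <- s[1]; QD[i] <- s[2]
    pr[i] <- log_ep_prior(cands$z[[i]], ctx$hp$eta)
    Ks[i] <- max(cands$z[[i]])
  }
  val <- list(z = cands$z, keys = cands$keys, sums = sums,
              LD = LD, QD = QD, pr = pr, K = Ks)
  ctx$mcache[[ckey]] <- val
  val
}

# vectorized log joints and particle keys of a pool against the other side
score_pool <- function(ctx, p, side, pool) {
  if (!length(pool$z)) return(list(lj = numeric(0), pkey = character(0)))
  if (side == "a") {
    lj <- ctx$mconst - 0.5 * (pool$LD + p$LDb) -
      ctx$apost * log(ctx$b0 + (ctx$yss - pool$QD - p$QDb) / 2) +
      pool$pr + p$pr_b
    pkey <- paste(pool$keys, p$key_b, sep = "|")
  } else {
    lj <- ctx$mconst - 0.5 * (p$LDa + pool$LD) -
      ctx$apost * log(ctx$b0 + (ctx$yss - p$QDa - pool$QD) / 2) +
      p$pr_a + pool$pr
    pkey <- paste(p$key_a, pool$keys, sep = "|")
  }
  list(lj = lj, pkey = pkey)
}

# objective value seen by particle l's update given the others fixed
others_of <- function(particles, l) {
  list(lj = vapply(particles[-l], `[[`, numeric(1), "lj"),
       key = vapply(particles[-l], `[[`, character(1), "key"))
}

# pick the best-scoring candidate under the tie rule (fewer clusters, then
# lexicographic canonical key); `K` and `key` are parallel to `score`
argbest <- function(score, K, key) {
  best <- 1L
  for (i in seq_along(score)[-1]) {
    if (score[i] > score[best] + 1e-12 ||
        (abs(score[i] - score[best]) <= 1e-12 &&
         (K[i] < K[best] || (K[i] == K[best] && key[i] < key[best])))) {
      best <- i
    }
  }
  best
}

# objective contribution of the other particles: logsumexp over their
# distinct support, for fast vectorized candidate scoring
others_base <- function(oth, lam) {
  u <- !duplicated(oth$key)
  list(base = logsumexp(oth$lj[u] / lam), keys = oth$key[u])
}

# objective value when a state with log joint `lj` (key `key`) is added to
# the others; duplicates contribute nothing beyond the base
score_against <- function(ob, lj, key, lam) {
  xl <- lj / lam
  M <- pmax(ob$base, xl)
  out <- lam * (M + log(exp(ob$base - M) + exp(xl - M)))
  out[key %in% ob$keys] <- lam * ob$base
  out
}

# Evaluate candidates for (particle l, side) against the full objective and
# return the improved particle record, or NULL if no candidate improves.
# The objective is evaluated with optimal weights over the whole set, so the
# entropy term sees duplicates: a candidate colliding with another particle
# shrinks the distinct support and is penalized automatically.
best_side_update <- function(ctx, particles, l, side, pool, lam) {
  if (!length(pool$z)) return(NULL)
  p <- particles[[l]]
  oth <- others_of(particles, l)
  ob <- others_base(oth, lam)
  cur_obj <- score_against(ob, p$lj, p$key, lam)
  sc <- score_pool(ctx, p, side, pool)
  score <- score_against(ob, sc$lj, sc$pkey, lam)
  b <- argbest(score, pool$K, sc$pkey)
  eps <- 1e-10 * max(1, abs(cur_obj))
  if (score[b] <= cur_obj + eps) return(NULL)
  p2 <- p
  if (side == "a") {
    p2$za <- pool$z[[b]]; p2$LDa <- pool$LD[b]; p2$QDa <- pool$QD[b]
    p2$pr_a <- pool$pr[b]; p2$key_a <- pool$keys[[b]]
  } else {
    p2$zb <- pool$z[[b]]; p2$LDb <- pool$LD[b]; p2$QDb <- pool$QD[b]
    p2$pr_b <- pool$pr[b]; p2$key_b <- pool$keys[[b]]
  }
  p2$lj <- sc$lj[b]
  p2$key <- sc$pkey[b]
  p2
}

# Joint escape: when neither constituent partition improves on its own, a
# particle can still be boxed in — its lj-improving single-side neighbors
# all duplicate other particles, while unoccupied high-posterior states
# differ in both partitions. Cross the top single-side candidates (ranked
# by their single-side log joints, already scored and cached) and accept
# the best jointly-changed particle if it improves the full objective.
joint_escape <- function(ctx, particles, l, pool_a, pool_b, lam, top = 10L) {
  if (!length(pool_a$z) || !length(pool_b$z)) return(NULL)
  p <- particles[[l]]
  oth <- others_of(particles, l)
  ob <- others_base(oth, lam)
  cur_obj <- score_against(ob, p$lj, p$key, lam)
  # rank each side's candidates by their single-side log joints
  lj_a <- score_pool(ctx, p, "a", pool_a)$lj
  lj_b <- score_pool(ctx, p, "b", pool_b)$lj
  ia <- order(lj_a, decreasing = TRUE)[seq_len(min(top, length(lj_a)))]
  ib <- order(lj_b, decreasing = TRUE)[seq_len(min(top, length(lj_b)))]
  # cross the top candidates: log joints follow from the cached sums
  grid <- expand.grid(i = ia, j = ib)
  lj_c <- ctx$mconst - 0.5 * (pool_a$LD[grid$i] + pool_b$LD[grid$j]) -
    ctx$apost * log(ctx$b0 +
                      (ctx$yss - pool_a$QD[grid$i] - pool_b$QD[grid$j]) / 2) +
    pool_a$pr[grid$i] + pool_b$pr[grid$j]
  key_c <- paste(unlist(pool_a$keys[grid$i]), unlist(pool_b$keys[grid$j]),
                 sep = "|")
  score <- score_against(ob, lj_c, key_c, lam)
  b <- argbest(score, pool_a$K[grid$i] + pool_b$K[grid$j], key_c)
  eps <- 1e-10 * max(1, abs(cur_obj))
  if (score[b] <= cur_obj + eps) return(NULL)
  i <- grid$i[b]; j <- grid$j[b]
  p2 <- p
  p2$za <- pool_a$z[[i]]; p2$LDa <- pool_a$LD[i]; p2$QDa <- pool_a$QD[i]
  p2$pr_a <- pool_a$pr[i]; p2$key_a <- pool_a$keys[[i]]
  p2$zb <- pool_b$z[[j]]; p2$LDb <- pool_b$LD[j]; p2$QDb <- pool_b$QD[j]
  p2$pr_b <- pool_b$pr[j]; p2$key_b <- pool_b$keys[[j]]
  p2$lj <- lj_c[b]
  p2$key <- key_c[b]
  p2
}

#' Greedy update of one partition of one particle
#'
#' Pools island, border, merge, split and split-and-merge candidates for one
#' constituent partition of a particle (using running conditional-mean
#' estimates), evaluates the full entropy-penalized objective for each, and
#' returns the argmax candidate if it strictly improves, else the unchanged
#' particle. The other particles' log joints enter through the entropy term,
#' making parallel searches mutually aware.
#'
#' @param data an [areal_ts()].
#' @param graph an [areal_graph()].
#' @param hp a [model_hyperparams()].
#' @param particle list with `za`, `zb`.
#' @param which `"alpha"` or `"beta"`: which partition to update.
#' @param others optional list with `log_joints` and `keys` of the other
#'   particles in the set (empty by default).
#' @param lam entropy penalty.
#' @param split_cap,island_quantile move heuristics, see [search_config()].
#' @return list with `za`, `zb` (possibly updated).
#' @export
greedy_partition_update <- function(data, graph, hp, particle,
                                    which = c("alpha", "beta"),
                                    others = NULL, lam = 100,
                                    split_cap = 5, island_quantile = 0.05) {
  which <- match.arg(which)
  side <- if (which == "alpha") "a" else "b"
  ctx <- po_context(data, graph, hp)
  p <- make_particle(ctx, particle$za, particle$zb)
  particles <- list(p)
  if (!is.null(others) && length(others$log_joints)) {
    for (i in seq_along(others$log_joints)) {
      particles[[i + 1]] <- list(lj = others$log_joints[i], key = others$keys[i])
    }
  }
  pool <- side_pool(ctx, p, side, split_cap, island_quantile)
  upd <- best_side_update(ctx, particles, 1L, side, pool, lam)
  if (is.null(upd)) upd <- p
  list(za = upd$za, zb = upd$zb)
}

#' Particle optimization by coordinate ascent
#'
#' Maximizes the entropy-penalized ensemble objective: sweeps over particles,
#' greedily updating the intercept partition then the slope partition of each
#' via local moves, then refreshes the (closed-form) optimal weights.
#' Terminates when a full sweep improves the objective by less than
#' `rel_tol` (relative) *and* an exhaustive all-island sweep over every
#' particle and partition yields no improvement, certifying a local optimum.
#'
#' @param data an [areal_ts()].
#' @param graph an [areal_graph()].
#' @param hp a [model_hyperparams()], e.g. from [fit_hyperparameters()].
#' @param config a [search_config()].
#' @param init optional list of initial particles (lists with `za`, `zb`);
#'   by default [initialize_particles()] is used.
#' @return object of class `partopt_particles`: particles sorted by log
#'   joint (descending) with tempered (`w_tempered`) and untempered
#'   truncated-posterior (`w_untempered`) weights, cached `log_joints`, the
#'   accepted-move objective trace, sweep count and convergence flag.
#' @export
particle_optimize <- function(data, graph, hp, config = search_config(),
                              init = NULL) {
  ctx <- po_context(data, graph, hp)
  if (is.null(init)) {
    init <- initialize_particles(data, graph, hp, config)
  }
  particles <- lapply(init, function(p) make_particle(ctx, p$za, p$zb))
  L <- length(particles)
  lam <- config$lam
  obj <- function() {
    distinct_logsumexp(vapply(particles, `[[`, numeric(1), "lj"),
                       vapply(particles, `[[`, character(1), "key"), lam)
  }
  trace <- obj()
  converged <- FALSE
  sweeps <- 0L
  while (sweeps < config$max_sweeps) {
    sweeps <- sweeps + 1L
    obj_start <- trace[length(trace)]
    for (l in seq_len(L)) {
      for (side in c("a", "b")) {
        pool <- side_pool(ctx, particles[[l]], side,
                          config$split_cap, config$island_quantile)
        upd <- best_side_update(ctx, particles, l, side, pool, lam)
        if (!is.null(upd)) {
          particles[[l]] <- upd
          trace <- c(trace, obj())
        }
      }
    }
    obj_end <- trace[length(trace)]
    if (obj_end - obj_start < config$rel_tol * max(1, abs(obj_start))) {
      # Local-convergence certification: exhaustive island moves on every
      # particle and partition, plus coordinated two-partition escapes for
      # particles whose lj-improving single-side neighbors are all occupied
      # by other particles (see joint_escape); continue sweeping if any of
      # these still improves the objective.
      improved <- FALSE
      for (l in seq_len(L)) {
        accepted <- FALSE
        for (side in c("a", "b")) {
          pool <- side_pool(ctx, particles[[l]], side,
                            config$split_cap, config$island_quantile,
                            islands_only = TRUE)
          upd <- best_side_update(ctx, particles, l, side, pool, lam)
          if (!is.null(upd)) {
            particles[[l]] <- upd
            accepted <- TRUE
            trace <- c(trace, obj())
          }
        }
        if (!accepted) {
          pa <- side_pool(ctx, particles[[l]], "a",
                          config$split_cap, config$island_quantile)
          pb <- side_pool(ctx, particles[[l]], "b",
                          config$split_cap, config$island_quantile)
          upd <- joint_escape(ctx, particles, l, pa, pb, lam)
          if (!is.null(upd)) {
            particles[[l]] <- upd
            accepted <- TRUE
            trace <- c(trace, obj())
          }
        }
        improved <- improved || accepted
      }
      if (!improved) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    warning("particle optimization hit max_sweeps before convergence", call. = FALSE)
  }
  ljs <- vapply(particles, `[[`, numeric(1), "lj")
  ord <- order(ljs, decreasing = TRUE)
  particles <- particles[ord]
  ljs <- ljs[ord]
  keys <- vapply(particles, `[[`, character(1), "key")
  structure(
    list(
      particles = lapply(particles, function(p) list(za = p$za, zb = p$zb)),
      log_joints = ljs,
      keys = keys,
      w_tempered = optimal_weights(ljs, lam, keys),
      w_untempered = optimal_weights(ljs, 1, keys),
      objective_trace = trace,
      sweeps = sweeps,
      converged = converged,
      config = unclass(config),
      hp = hp
    ),
    class = "partopt_particles"
  )
}

#' @export
print.partopt_particles <- function(x, ...) {
  cat("<partopt_particles> L = ", length(x$particles),
      " (", length(unique(x$keys)), " distinct), sweeps = ", x$sweeps,
      if (x$converged) ", converged" else ", NOT converged", "\n", sep = "")
  cat("  top log joint: ", format(x$log_joints[1]), "\n", sep = "")
  invisible(x)
}

#' Initialize a particle set from k-means on the MLEs
#'
#' Builds candidate intercept partitions by 1-D k-means on the per-unit MLE
#' intercepts with K = 1, ..., floor(eta * log N) clusters, repaired into
#' connected components to obtain spatial partitions (likewise for slopes),
#' then samples L particles with replacement from the (K, K') grid with
#' probability proportional to the (untempered) posterior mass.
#'
#' @inheritParams particle_optimize
#' @return list of L particles (lists with `za`, `zb`).
#' @export
initialize_particles <- function(data, graph, hp, config = search_config()) {
  ctx <- po_context(data, graph, hp)
  mle <- compute_mle(data)
  Kmax <- max(1, floor(hp$eta * log(data$n)))
  make_cands <- function(est) {
    zs <- lapply(seq_len(Kmax), function(K) {
      repair_partition(kmeans_1d(est, K), graph)
    })
    zs[!duplicated(vapply(zs, partition_key, character(1)))]
  }
  cands_a <- make_cands(mle$alpha)
  cands_b <- make_cands(mle$beta)
  grid <- expand.grid(a = seq_along(cands_a), b = seq_along(cands_b))
  ljs <- vapply(seq_len(nrow(grid)), function(i) {
    ctx_log_joint(ctx, cands_a[[grid$a[i]]], cands_b[[grid$b[i]]])
  }, numeric(1))
  prob <- exp(ljs - max(ljs))
  set.seed(config$seed)
  pick <- sample.int(nrow(grid), config$L, replace = TRUE, prob = prob)
  lapply(pick, function(i) {
    list(za = cands_a[[grid$a[i]]], zb = cands_b[[grid$b[i]]])
  })
}
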