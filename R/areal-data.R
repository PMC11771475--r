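#' Adjacency graph over areal units
#'
#' Builds the binary neighborhood structure used throughout the package.
#' `W` must be symmetric with zero diagonal; entries are coerced to 0/1.
#' Units with no neighbors are allowed.
#'
#' @param W square binary matrix (dense 0/1), `W[i,j] = 1` iff units i and j
#'   share a border.
#' @param unit_ids optional character vector of unit identifiers in row order.
#' @return an object of class `areal_graph`: list with elements `n`, `W`
#'   (dense 0/1 matrix) and `nbrs` (adjacency list of integer vectors).
#' @export
areal_graph <- function(W, unit_ids = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("adjacency matrix must be square", call. = FALSE)
  if (!all(W %in% c(0, 1))) stop("adjacency entries must be 0/1", call. = FALSE)
  if (!isTRUE(all.equal(W, t(W)))) stop("adjacency matrix must be symmetric", call. = FALSE)
  if (any(diag(W) != 0)) stop("adjacency matrix must have zero diagonal", call. = FALSE)
  n <- nrow(W)
  storage.mode(W) <- "double"
  dimnames(W) <- NULL
  nbrs <- lapply(seq_len(n), function(i) which(W[i, ] == 1))
  structure(
    list(n = n, W = W, nbrs = nbrs, unit_ids = unit_ids %||% as.character(seq_len(n))),
    class = "areal_graph"
  )
}

#' @export
print.areal_graph <- function(x, ...) {
  cat("<areal_graph> ", x$n, " units, ", sum(x$W) / 2, " edges\n", sep = "")
  invisible(x)
}

#' Build an adjacency graph from an undirected edge list
#'
#' @param edges two-column object (data frame or matrix) of undirected edges;
#'   entries may be arbitrary unit ids (matched against `unit_ids`) or
#'   integer indices when `unit_ids` is `NULL`.
#' @param n_units number of units (required when ids are plain indices and
#'   some units are isolated).
#' @param unit_ids optional id vector fixing the unit order.
#' @return an `areal_graph`.
#' @export
graph_from_edges <- function(edges, n_units = NULL, unit_ids = NULL) {
  edges <- as.data.frame(edges)[, 1:2]
  if (!is.null(unit_ids)) {
    u <- match(as.character(edges[[1]]), unit_ids)
    v <- match(as.character(edges[[2]]), unit_ids)
    if (anyNA(u) || anyNA(v)) stop("edge list contains unknown unit ids", call. = FALSE)
    n <- length(unit_ids)
  } else {
    u <- as.integer(edges[[1]])
    v <- as.integer(edges[[2]])
    n <- n_units %||% max(u, v)
  }
  if (any(u < 1 | u > n | v < 1 | v > n)) stop("edge endpoints out of range", call. = FALSE)
  if (any(u == v)) stop("self-loops are not allowed", call. = FALSE)
  W <- matrix(0, n, n)
  W[cbind(u, v)] <- 1
  W[cbind(v, u)] <- 1
  areal_graph(W, unit_ids = unit_ids)
}

#' Areal time-series container
#'
#' Holds the N x T response matrix of transformed densities together with the
#' standardized time covariate and unit areas. Most users construct it from a
#' long data frame via [as_areal_ts()].
#'
#' @param y N x T numeric matrix of (transformed) densities.
#' @param areas positive N-vector of unit areas (defaults to 1).
#' @param counts optional N x T matrix of raw counts.
#' @param unit_ids optional character ids in row order.
#' @return object of class `areal_ts` with fields `y`, `x` (standardized
#'   times, mean zero, unit sample variance), `areas`, `counts`, `n`, `t`.
#' @export
areal_ts <- function(y, areas = NULL, counts = NULL, unit_ids = NULL) {
  y <- as.matrix(y)
  if (anyNA(y)) stop("missing values in y are not supported", call. = FALSE)
  n <- nrow(y); tt <- ncol(y)
  if (tt < 3) stop("at least T = 3 time points are required", call. = FALSE)
  areas <- areas %||% rep(1, n)
  if (length(areas) != n || any(areas <= 0)) {
    stop("areas must be positive and match the number of units", call. = FALSE)
  }
  dimnames(y) <- NULL
  structure(
    list(
      y = y, x = standardize_times(tt), areas = as.numeric(areas),
      counts = counts, n = n, t = tt,
      unit_ids = unit_ids %||% as.character(seq_len(n))
    ),
    class = "areal_ts"
  )
}

#' @export
print.areal_ts <- function(x, ...) {
  cat("<areal_ts> ", x$n, " units x ", x$t, " time points\n", sep = "")
  invisible(x)
}

#' Convert a long data frame to an areal time-series
#'
#' Accepts either transformed densities (column `y`) or raw counts plus areas
#' (columns `count` and optionally `area`); counts are converted with
#' [transform_density()]. Units are ordered by first appearance; every unit
#' must have a complete series at the same set of times.
#'
#' @param data data frame with columns `unit`, `time`, and `y` or `count`
#'   (plus optional `area`, constant within unit).
#' @return an `areal_ts`.
#' @export
as_areal_ts <- function(data) {
  data <- as.data.frame(data)
  need <- c("unit", "time")
  if (!all(need %in% names(data))) stop("data must have columns unit, time", call. = FALSE)
  ids <- as.character(unique(data$unit))
  times <- sort(unique(data$time))
  n <- length(ids); tt <- length(times)
  if (nrow(data) != n * tt) stop("ragged panel: every unit needs every time point", call. = FALSE)
  ui <- match(as.character(data$unit), ids)
  ti <- match(data$time, times)
  if ("area" %in% names(data)) {
    per_unit <- dplyr::distinct(data.frame(ui = ui, area = data$area))
    if (nrow(per_unit) != n) stop("area must be constant within unit", call. = FALSE)
    areas <- per_unit$area[order(per_unit$ui)]
  } else {
    areas <- rep(1, n)
  }
  counts <- NULL
  if ("y" %in% names(data)) {
    y <- matrix(NA_real_, n, tt)
    y[cbind(ui, ti)] <- data$y
  } else if ("count" %in% names(data)) {
    counts <- matrix(NA_real_, n, tt)
    counts[cbind(ui, ti)] <- data$count
    if (anyNA(counts)) stop("ragged panel: missing counts", call. = FALSE)
    y <- transform_density(counts, areas)
  } else {
    stop("data must have a y or count column", call. = FALSE)
  }
  if (anyNA(y)) stop("ragged panel: missing observations", call. = FALSE)
  areal_ts(y, areas = areas, counts = counts, unit_ids = ids)
}

#' Inverse-hyperbolic-sine density transform
#'
#' Converts raw counts to transformed densities
#' `y = asinh(c / A) - log(2)`, a log-like variance stabilizing transform
#' that is well defined at zero counts.
#'
#' @param counts nonnegative count matrix/vector (N x T).
#' @param areas positive vector of unit areas, recycled across time.
#' @return matrix of transformed densities, same shape as `counts`.
#' @export
transform_density <- function(counts, areas) {
  if (any(areas <= 0)) stop("areas must be strictly positive", call. = FALSE)
  counts <- as.matrix(counts)
  asinh(counts / areas) - log(2)
}

#' Back-transform densities to counts
#'
#' Inverse of [transform_density()]: `c` is the nearest nonnegative integer to
#' `A * sinh(log(2) + y)`.
#'
#' @param ystar matrix of transformed densities.
#' @param areas positive vector of unit areas.
#' @return integer matrix of counts.
#' @export
inverse_transform <- function(ystar, areas) {
  ystar <- as.matrix(ystar)
  out <- round(areas * sinh(log(2) + ystar))
  out[out < 0] <- 0
  storage.mode(out) <- "integer"
  out
}

#' Standardized time covariate
#'
#' Maps raw time indices 0, ..., T-1 to a covariate with mean zero and unit
#' sample variance (denominator T - 1), so that `sum(x) = 0` and
#' `sum(x^2) = T - 1`.
#'
#' @param n_times number of time points (>= 2).
#' @return numeric vector of length `n_times`.
#' @export
standardize_times <- function(n_times) {
  if (n_times < 2) stop("need at least two time points", call. = FALSE)
  raw <- seq_len(n_times) - 1
  as.numeric(scale(raw))
}

#' Read areal time-series data from CSV
#'
#' Long format with columns `unit_id`, `time`, `count` (plus optional `area`)
#' or `unit_id`, `time`, `y`.
#'
#' @param path CSV file path.
#' @return an `areal_ts`.
#' @export
read_areal_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  nm <- names(d)
  nm[nm == "unit_id"] <- "unit"
  names(d) <- nm
  as_areal_ts(d)
}

#' Read an adjacency structure from file
#'
#' Accepts a two-column undirected edge list CSV (header `u,v`, arbitrary unit
#' ids) or a dense 0/1 matrix CSV with no header.
#'
#' @param path CSV file path.
#' @param unit_ids optional id vector fixing unit order (required for edge
#'   lists with non-integer ids or isolated units).
#' @param n_units optional number of units for integer edge lists.
#' @return an `areal_graph`.
#' @export
read_adjacency <- function(path, unit_ids = NULL, n_units = NULL) {
  first <- readLines(path, n = 1)
  ncol1 <- length(strsplit(first, ",")[[1]])
  if (ncol1 == 2) {
    edges <- utils::read.csv(path, header = grepl("[A-Za-z]", first))
    graph_from_edges(edges, n_units = n_units, unit_ids = unit_ids)
  } else {
    W <- as.matrix(utils::read.csv(path, header = FALSE))
    areal_graph(W, unit_ids = unit_ids)
  }
}

#' Write fit results to a directory
#'
#' Writes `estimates.csv` (per-unit estimates and MAP cluster labels),
#' `particles.json` (particle assignments, log joints, tempered and
#' untempered weights) and `manifest.json` (configuration echo).
#'
#' @param fit a `partopt_fit` object.
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_results <- function(fit, dir) {
  stopifnot(inherits(fit, "partopt_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  est_path <- file.path(dir, "estimates.csv")
  readr::write_csv(generics::tidy(fit), est_path)
  part_path <- file.path(dir, "particles.json")
  ps <- fit$particles
  jsonlite::write_json(
    list(
      gamma_alpha = lapply(ps$particles, function(p) p$za),
      gamma_beta = lapply(ps$particles, function(p) p$zb),
      log_joint = ps$log_joints,
      weight_tempered = ps$w_tempered,
      weight_untempered = ps$w_untempered
    ),
    part_path, digits = NA
  )
  man_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(
      package_version = as.character(utils::packageVersion("partopt")),
      n_units = fit$data$n, n_times = fit$data$t,
      config = fit$particles$config[c("L", "lam", "seed", "max_sweeps",
                                      "rel_tol", "split_cap", "island_quantile")],
      hyperparams = unclass(fit$hp),
      sweeps = ps$sweeps, converged = ps$converged,
      objective = ps$objective_trace[length(ps$objective_trace)]
    ),
    man_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(est_path, part_path, man_path))
}

#' Read a particle-set JSON written by [write_results()]
#'
#' @param path path to `particles.json`.
#' @return list with `gamma_alpha`, `gamma_beta` (lists of assignment
#'   vectors), `log_joint`, `weight_tempered`, `weight_untempered`.
#' @export
read_particles <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_rows <- function(m) {
    m <- rbind(m)  # matrix when all assignments share length N
    lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
  }
  list(
    gamma_alpha = as_rows(raw$gamma_alpha),
    gamma_beta = as_rows(raw$gamma_beta),
    log_joint = as.numeric(raw$log_joint),
    weight_tempered = as.numeric(raw$weight_tempered),
    weight_untempered = as.numeric(raw$weight_untempered)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
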