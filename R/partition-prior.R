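#' Connected components of a unit subset
#'
#' Breadth-first decomposition of the subgraph induced by `units`. Components
#' are returned ordered by their smallest contained index, each sorted.
#'
#' @param units nonempty integer vector of unit indices.
#' @param graph an [areal_graph()].
#' @return list of integer vectors partitioning `units`.
#' @export
connected_components <- function(units, graph) {
  units <- sort(unique(as.integer(units)))
  if (length(units) == 0) stop("units must be nonempty", call. = FALSE)
  inset <- logical(graph$n)
  inset[units] <- TRUE
  seen <- logical(graph$n)
  queue <- integer(length(units))
  comps <- list()
  for (start in units) {
    if (seen[start]) next
    queue[1] <- start
    seen[start] <- TRUE
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      nb <- graph$nbrs[[v]]
      nb <- nb[inset[nb] & !seen[nb]]
      k <- length(nb)
      if (k) {
        seen[nb] <- TRUE
        queue[(tail + 1L):(tail + k)] <- nb
        tail <- tail + k
      }
    }
    comps[[length(comps) + 1L]] <- sort(queue[seq_len(tail)])
  }
  comps
}

#' Is a partition spatial?
#'
#' A partition is spatial when every cluster induces a connected subgraph of
#' the adjacency graph.
#'
#' @param z integer assignment vector (labels 1..K).
#' @param graph an [areal_graph()].
#' @return logical scalar.
#' @export
is_spatial <- function(z, graph) {
  stopifnot(length(z) == graph$n)
  for (cl in split(seq_along(z), z)) {
    if (length(connected_components(cl, graph)) != 1L) return(FALSE)
  }
  TRUE
}

#' Canonical form of an assignment vector
#'
#' Relabels clusters in order of their smallest member index, so two
#' assignments describing the same partition get identical labels.
#'
#' @param z assignment vector.
#' @return integer vector with labels 1..K in canonical order.
#' @export
canonical_partition <- function(z) {
  match(z, unique(z))
}

# compact string key for cache lookups and duplicate detection
partition_key <- function(z) {
  paste(canonical_partition(z), collapse = ",")
}

particle_key <- function(za, zb) {
  paste(partition_key(za), partition_key(zb), sep = "|")
}

#' Log truncated Ewens-Pitman prior (unnormalized)
#'
#' `log pi(gamma) = K log(eta) + sum_k log((n_k - 1)!)` for spatial
#' partitions, `-Inf` otherwise. The intractable normalizing constant over
#' the set of spatial partitions is common to all partitions on a fixed graph
#' and is never needed: every downstream quantity uses differences.
#'
#' @param z assignment vector.
#' @param eta positive concentration parameter; larger values favor more
#'   clusters.
#' @param graph optional [areal_graph()]; when supplied the spatial
#'   constraint is checked and non-spatial partitions return `-Inf`.
#' @return unnormalized log prior mass.
#' @export
log_ep_prior <- function(z, eta, graph = NULL) {
  if (eta <= 0) stop("eta must be positive", call. = FALSE)
  if (!is.null(graph) && !is_spatial(z, graph)) return(-Inf)
  sizes <- tabulate(canonical_partition(z))
  length(sizes) * log(eta) + sum(lgamma(sizes))
}

#' Asymptotic expected cluster count of the untruncated prior
#'
#' The (untruncated) Ewens-Pitman prior induces on average about
#' `eta * log(N)` clusters among N units; this guidance value sizes the
#' k-means initialization grid.
#'
#' @param eta concentration parameter.
#' @param n_units number of units.
#' @return `eta * log(n_units)`.
#' @export
expected_clusters_untruncated <- function(eta, n_units) {
  stopifnot(n_units >= 1)
  eta * log(n_units)
}

#' Enumerate all spatial partitions of a small graph
#'
#' Exhaustive enumeration via restricted growth strings, keeping only
#' partitions whose clusters are all connected. Intended for graphs with at
#' most ~10 units (Bell numbers grow fast).
#'
#' @param graph an [areal_graph()].
#' @return list of canonical assignment vectors.
#' @export
enumerate_spatial_partitions <- function(graph) {
  n <- graph$n
  if (n > 12) stop("enumeration is limited to n <= 12 units", call. = FALSE)
  out <- list()
  rec <- function(z, k) {
    i <- length(z) + 1L
    if (i > n) {
      if (is_spatial(z, graph)) out[[length(out) + 1L]] <<- z
      return(invisible())
    }
    for (lab in seq_len(k + 1L)) {
      rec(c(z, lab), max(k, lab))
    }
  }
  rec(integer(0), 0L)
  out
}
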