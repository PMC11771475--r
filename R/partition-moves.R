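# Local transitions over spatially connected partitions.
#
# Every generator returns a list of candidate assignment vectors in canonical
# form (clusters labeled by smallest member index), deduplicated, with the
# current partition excluded. Removing a unit from a cluster can disconnect
# it; the donor is then split into its connected components, so candidates
# are always spatial by construction.

# rebuild an assignment vector from a list of cluster index sets
z_from_clusters <- function(clusters, n) {
  z <- integer(n)
  for (j in seq_along(clusters)) z[clusters[[j]]] <- j
  canonical_partition(z)
}

# Articulation points of the subgraph induced by `units` (iterative Tarjan):
# exactly the units whose removal disconnects their cluster. Precomputing
# them once per cluster lets the move generators skip the component search
# for the (typical) non-articulation removals.
art_points <- function(units, graph) {
  n <- length(units)
  if (n <= 2L) return(integer(0))
  pos <- integer(graph$n)
  pos[units] <- seq_len(n)
  adj <- lapply(units, function(u) {
    nb <- graph$nbrs[[u]]
    pos[nb[pos[nb] > 0L]]
  })
  disc <- integer(n); low <- integer(n); parent <- integer(n)
  nexti <- integer(n); ap <- logical(n)
  timer <- 0L
  stack <- integer(n)
  for (root in seq_len(n)) {
    if (disc[root] > 0L) next
    root_children <- 0L
    top <- 1L; stack[1] <- root
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    nexti[root] <- 1L
    while (top > 0L) {
      v <- stack[top]
      av <- adj[[v]]
      if (nexti[v] <= length(av)) {
        w <- av[nexti[v]]
        nexti[v] <- nexti[v] + 1L
        if (disc[w] == 0L) {
          parent[w] <- v
          if (v == root) root_children <- root_children + 1L
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          nexti[w] <- 1L
          top <- top + 1L; stack[top] <- w
        } else if (w != parent[v]) {
          if (disc[w] < low[v]) low[v] <- disc[w]
        }
      } else {
        top <- top - 1L
        if (top > 0L) {
          u <- stack[top]
          if (low[v] < low[u]) low[u] <- low[v]
          if (u != root && low[v] >= disc[u]) ap[u] <- TRUE
        }
      }
    }
    if (root_children > 1L) ap[root] <- TRUE
  }
  units[ap]
}

# remove `unit` from its cluster, splitting the remainder into components;
# returns the list of clusters with the donor replaced (unit excluded).
# `clusters` is the split() of the assignment and `art` the donor's
# precomputed articulation units (NULL to always run the component search).
remove_unit_from <- function(clusters, donor_lab, unit, graph, art = NULL) {
  donor <- setdiff(clusters[[donor_lab]], unit)
  out <- clusters[-donor_lab]
  if (length(donor)) {
    if (!is.null(art) && !(unit %in% art)) {
      out <- c(out, list(donor))
    } else {
      out <- c(out, connected_components(donor, graph))
    }
  }
  out
}

remove_unit <- function(z, unit, graph) {
  clusters <- unname(split(seq_along(z), z))
  remove_unit_from(clusters, z[unit], unit, graph)
}

dedup_candidates <- function(cands, current) {
  keys <- vapply(cands, partition_key, character(1))
  keep <- !duplicated(keys) & keys != partition_key(current)
  cands[keep]
}

#' Island moves
#'
#' Moves single units into new singleton clusters. A unit is eligible when
#' its running estimate lies in the extreme tails (at or beyond the
#' `quantile` and `1 - quantile` empirical quantiles) of the estimates within
#' its cluster; clusters of size one are skipped and clusters of size two
#' make both members eligible.
#'
#' @param z assignment vector.
#' @param graph an [areal_graph()].
#' @param estimates N-vector of running unit-level estimates.
#' @param quantile tail probability in (0, 0.5], default 0.05.
#' @return list of canonical candidate assignment vectors.
#' @export
island_moves <- function(z, graph, estimates, quantile = 0.05) {
  if (quantile <= 0 || quantile > 0.5) stop("quantile must lie in (0, 0.5]", call. = FALSE)
  n <- length(z)
  clusters <- unname(split(seq_len(n), z))
  cands <- list()
  for (lab in seq_along(clusters)) {
    cl <- clusters[[lab]]
    if (length(cl) < 2) next
    est <- estimates[cl]
    if (length(cl) == 2) {
      eligible <- cl
    } else {
      lo <- stats::quantile(est, quantile, names = FALSE)
      hi <- stats::quantile(est, 1 - quantile, names = FALSE)
      eligible <- cl[est <= lo | est >= hi]
    }
    art <- art_points(cl, graph)
    for (u in eligible) {
      pieces <- remove_unit_from(clusters, lab, u, graph, art)
      cands[[length(cands) + 1L]] <- z_from_clusters(c(pieces, list(u)), n)
    }
  }
  dedup_candidates(cands, z)
}

#' Border moves
#'
#' For every unit adjacent to a different cluster, one candidate per distinct
#' adjacent cluster reassigns the unit across the boundary, with the donor
#' cluster repaired into connected components if needed.
#'
#' @inheritParams island_moves
#' @return list of canonical candidate assignment vectors.
#' @export
border_moves <- function(z, graph) {
  n <- length(z)
  K <- max(z)
  if (K < 2) return(list())
  clusters <- unname(split(seq_len(n), z))
  arts <- vector("list", K)
  art_done <- logical(K)
  cands <- list()
  for (u in seq_len(n)) {
    foreign <- unique(z[graph$nbrs[[u]]])
    foreign <- foreign[foreign != z[u]]
    if (!length(foreign)) next
    donor <- z[u]
    if (!art_done[donor]) {
      arts[[donor]] <- art_points(clusters[[donor]], graph)
      art_done[donor] <- TRUE
    }
    for (lab in foreign) {
      pieces <- remove_unit_from(clusters, donor, u, graph, arts[[donor]])
      # donor was dropped from the list, shifting later labels down one
      recv <- if (lab < donor) lab else lab - 1L
      pieces[[recv]] <- c(pieces[[recv]], u)
      cands[[length(cands) + 1L]] <- z_from_clusters(pieces, n)
    }
  }
  dedup_candidates(cands, z)
}

#' Merge moves
#'
#' Each cluster proposes a merge with the spatially adjacent cluster whose
#' grand cluster mean is closest to its own; symmetric duplicates are
#' removed.
#'
#' @inheritParams island_moves
#' @param grand_means K-vector of grand cluster means, in cluster-label
#'   order.
#' @return list of canonical candidate assignment vectors.
#' @export
merge_moves <- function(z, graph, grand_means) {
  K <- length(unique(z))
  if (K < 2) return(list())
  n <- length(z)
  # cluster adjacency from the unit adjacency
  adj <- matrix(FALSE, K, K)
  for (u in seq_len(n)) {
    for (v in graph$nbrs[[u]]) {
      if (z[u] != z[v]) adj[z[u], z[v]] <- TRUE
    }
  }
  cands <- list()
  seen_pairs <- character(0)
  for (k in seq_len(K)) {
    nb <- which(adj[k, ])
    if (!length(nb)) next
    kk <- nb[which.min(abs(grand_means[nb] - grand_means[k]))]
    pair <- paste(sort(c(k, kk)), collapse = "-")
    if (pair %in% seen_pairs) next
    seen_pairs <- c(seen_pairs, pair)
    z2 <- z
    z2[z2 == kk] <- k
    cands[[length(cands) + 1L]] <- canonical_partition(z2)
  }
  dedup_candidates(cands, z)
}

# deterministic 1-D k-means: Lloyd iterations from two seedings — centers at
# the (j - 1/2)/m empirical quantiles and at (j - 1/2)/m of the value range
# (robust when most mass sits in one narrow mode) — keeping the lower
# within-SS solution; ties assigned to the lower center index
kmeans_1d <- function(x, m, iters = 25) {
  m <- min(m, length(unique(x)))
  if (m <= 1) return(rep(1L, length(x)))
  lloyd <- function(centers) {
    assign <- integer(length(x))
    for (it in seq_len(iters)) {
      dmat <- abs(outer(x, centers, "-"))
      new_assign <- max.col(-dmat, ties.method = "first")
      if (identical(new_assign, assign)) break
      assign <- new_assign
      for (j in seq_len(m)) {
        if (any(assign == j)) centers[j] <- mean(x[assign == j])
      }
    }
    list(assign = assign,
         wss = sum((x - stats::ave(x, assign))^2))
  }
  probs <- (seq_len(m) - 0.5) / m
  s1 <- lloyd(stats::quantile(x, probs = probs, names = FALSE))
  s2 <- lloyd(min(x) + probs * (max(x) - min(x)))
  if (s2$wss < s1$wss) s2$assign else s1$assign
}

#' Split moves
#'
#' Divides a cluster into m = 2, ..., `max_parts` sub-clusters by 1-D
#' k-means on the within-cluster unit estimates, followed by connectivity
#' repair (each estimate-based part is split into its connected components,
#' so a candidate may end up with more than m parts).
#'
#' @inheritParams island_moves
#' @param unit_estimates N-vector of running unit-level estimates.
#' @param max_parts cap on the number of k-means parts, default 5.
#' @return list of canonical candidate assignment vectors.
#' @export
split_moves <- function(z, graph, unit_estimates, max_parts = 5) {
  if (max_parts < 2) stop("max_parts must be at least 2", call. = FALSE)
  n <- length(z)
  cands <- list()
  for (cl in split(seq_len(n), z)) {
    if (length(cl) < 2) next
    for (m in 2:min(max_parts, length(cl))) {
      pieces <- split_cluster(cl, graph, unit_estimates, m)
      if (length(pieces) < 2) next
      others <- split(seq_len(n), z)
      others[[as.character(z[cl[1]])]] <- NULL
      cands[[length(cands) + 1L]] <- z_from_clusters(c(unname(others), pieces), n)
    }
  }
  dedup_candidates(cands, z)
}

# split one cluster into >= m spatially connected pieces via 1-D k-means
split_cluster <- function(cl, graph, unit_estimates, m) {
  km <- kmeans_1d(unit_estimates[cl], m)
  pieces <- list()
  for (part in split(cl, km)) {
    pieces <- c(pieces, connected_components(part, graph))
  }
  pieces
}

#' Split-and-merge moves
#'
#' Splits a cluster into pieces (as in [split_moves()]) and then merges each
#' piece into the spatially adjacent *other* cluster with the closest grand
#' mean; pieces with no foreign neighbor stay separate clusters.
#'
#' @inheritParams split_moves
#' @param grand_means K-vector of grand cluster means in cluster-label order.
#' @return list of canonical candidate assignment vectors.
#' @export
split_merge_moves <- function(z, graph, unit_estimates, grand_means, max_parts = 5) {
  n <- length(z)
  labs <- sort(unique(z))
  cands <- list()
  for (lab in labs) {
    cl <- which(z == lab)
    if (length(cl) < 2) next
    for (m in 2:min(max_parts, length(cl))) {
      pieces <- split_cluster(cl, graph, unit_estimates, m)
      if (length(pieces) < 2) next
      z2 <- z
      # pieces get provisional fresh labels, then each merges toward the
      # closest-mean adjacent original cluster
      piece_lab <- max(labs) + seq_along(pieces)
      for (j in seq_along(pieces)) z2[pieces[[j]]] <- piece_lab[j]
      for (j in seq_along(pieces)) {
        nb_units <- unique(unlist(graph$nbrs[pieces[[j]]]))
        nb_labs <- setdiff(unique(z[nb_units]), lab)   # original foreign clusters
        if (!length(nb_labs)) next
        target <- nb_labs[which.min(abs(grand_means[nb_labs] - grand_means[match(lab, labs)]))]
        z2[pieces[[j]]] <- target
      }
      # every piece is connected and merges only into an adjacent cluster,
      # so all resulting clusters are connected; only relabeling is needed
      cands[[length(cands) + 1L]] <- canonical_partition(z2)
    }
  }
  dedup_candidates(cands, z)
}

# split every disconnected cluster of z into its components
repair_partition <- function(z, graph) {
  n <- length(z)
  clusters <- list()
  for (cl in split(seq_len(n), z)) {
    clusters <- c(clusters, connected_components(cl, graph))
  }
  z_from_clusters(clusters, n)
}

#' All-island sweep
#'
#' Every single-unit-to-new-singleton move, regardless of the tail
#' heuristic. Used as the local-convergence certificate: a particle set is
#' locally optimal when none of these moves improves the objective.
#'
#' @inheritParams island_moves
#' @return list of canonical candidate assignment vectors.
#' @export
all_island_sweep <- function(z, graph) {
  n <- length(z)
  zc <- canonical_partition(z)
  sizes <- tabulate(zc)
  clusters <- unname(split(seq_len(n), zc))
  arts <- vector("list", length(sizes))
  art_done <- logical(length(sizes))
  cands <- list()
  for (u in seq_len(n)) {
    lab <- zc[u]
    if (sizes[lab] == 1) next   # already a singleton
    if (!art_done[lab]) {
      arts[[lab]] <- art_points(clusters[[lab]], graph)
      art_done[lab] <- TRUE
    }
    pieces <- remove_unit_from(clusters, lab, u, graph, arts[[lab]])
    cands[[length(cands) + 1L]] <- z_from_clusters(c(pieces, list(u)), n)
  }
  dedup_candidates(cands, z)
}
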