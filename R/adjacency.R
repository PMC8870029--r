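#' Build the electrode adjacency graph of a montage
#'
#' Neighbourhood structure over scalp sensors, required by the cluster-based
#' permutation test. Two constructions are offered: `delaunay` triangulates
#' the 2-D azimuthal-equidistant projection of the sensor positions (edges
#' longer than `max_edge_factor` times the median edge length are dropped, so
#' the convex-hull shortcuts across the scalp rim do not become neighbours);
#' `knn` links each sensor to its `k` nearest neighbours by geodesic distance
#' and symmetrizes. Degenerate geometry that defeats the triangulation falls
#' back to `knn` with a warning.
#'
#' @param montage An `eeg_montage`.
#' @param method `"delaunay"` (default) or `"knn"`.
#' @param k Neighbour count for `knn`.
#' @param max_edge_factor Edge-pruning factor for `delaunay`.
#' @return An `adjacency_graph`: list with `neighbours` (named list of
#'   character vectors), `labels`, `method`, `params`.
#' @export
electrode_adjacency <- function(montage, method = c("delaunay", "knn"),
                                k = 4, max_edge_factor = 1.5) {
  method <- match.arg(method)
  validate_montage(montage)
  if (nrow(montage) < 4) stop("need at least 4 channels with positions")
  pos <- montage_positions(montage)
  labels <- montage$channel
  edges <- NULL
  if (method == "delaunay") {
    proj <- azimuthal_projection(pos)
    edges <- tryCatch({
      dd <- deldir::deldir(proj[, 1], proj[, 2])
      e <- as.matrix(dd$delsgs[, c("ind1", "ind2")])
      len <- sqrt(rowSums((proj[e[, 1], , drop = FALSE] -
                             proj[e[, 2], , drop = FALSE])^2))
      e[len <= max_edge_factor * stats::median(len), , drop = FALSE]
    }, error = function(err) NULL)
    if (is.null(edges)) {
      warning("Delaunay triangulation failed; falling back to knn adjacency")
      method <- "knn"
    }
  }
  if (method == "knn") {
    arc <- geodesic_distances(pos)
    diag(arc) <- Inf
    nn <- t(apply(arc, 1, function(d) order(d)[seq_len(k)]))
    edges <- cbind(rep(seq_len(nrow(pos)), each = k), as.vector(t(nn)))
  }
  nb <- rep(list(character()), length(labels))
  names(nb) <- labels
  edges <- unique(rbind(edges, edges[, 2:1]))           # symmetrize
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  sp <- split(labels[edges[, 2]], factor(edges[, 1], levels = seq_along(labels)))
  for (i in seq_along(labels)) nb[[i]] <- sort(unique(sp[[i]]))
  structure(
    list(neighbours = nb, labels = labels, method = method,
         params = list(k = k, max_edge_factor = max_edge_factor)),
    class = "adjacency_graph"
  )
}

# pairwise great-circle distances (radians) between unit-sphere positions
geodesic_distances <- function(pos) {
  gram <- tcrossprod(pos)
  gram[gram > 1] <- 1
  gram[gram < -1] <- -1
  acos(gram)
}

azimuthal_projection <- function(pos) {
  theta <- acos(pmin(1, pmax(-1, pos[, 3])))
  r <- sqrt(pos[, 1]^2 + pos[, 2]^2)
  scale <- ifelse(r > 1e-12, theta / r, 0)
  cbind(pos[, 1] * scale, pos[, 2] * scale)
}

#' @export
print.adjacency_graph <- function(x, ...) {
  deg <- lengths(x$neighbours)
  cat("Electrode adjacency (", x$method, "): ", length(x$labels),
      " channels, mean degree ", round(mean(deg), 2),
      if (graph_is_connected(x)) ", connected" else ", NOT connected",
      "\n", sep = "")
  invisible(x)
}

#' Adjacency graph as a logical matrix
#' @param graph An `adjacency_graph`.
#' @return Symmetric logical matrix with channel labels as dimnames.
#' @export
adjacency_matrix <- function(graph) {
  n <- length(graph$labels)
  m <- matrix(FALSE, n, n, dimnames = list(graph$labels, graph$labels))
  for (lab in graph$labels) m[lab, graph$neighbours[[lab]]] <- TRUE
  m
}

# breadth-first reachability from the first node
graph_is_connected <- function(graph) {
  labs <- graph$labels
  if (length(labs) == 0) return(TRUE)
  seen <- structure(rep(FALSE, length(labs)), names = labs)
  queue <- labs[1]
  seen[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    nxt <- graph$neighbours[[cur]]
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    queue <- c(queue, nxt)
  }
  all(seen)
}

# chain adjacency over an ordered set of labels (1-D analogue used for
# frequency-bin clustering)
chain_adjacency <- function(labels) {
  n <- length(labels)
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    nb[[i]] <- labels[c(i - 1, i + 1)[c(i > 1, i < n)]]
  }
  names(nb) <- labels
  structure(list(neighbours = nb, labels = labels, method = "chain",
                 params = list()), class = "adjacency_graph")
}
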