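# Discrete Ricci curvature on molecular interaction graphs.
#
# Two discrete curvatures are provided: Forman-Ricci (combinatorial, from
# degrees and triangle counts) and Ollivier-Ricci (optimal transport between
# lazy random-walk measures at an edge's endpoints). Multiscale profiles are
# obtained by thresholding edge lengths at an increasing sequence of
# filtration values and recomputing the curvature inside each nested
# subgraph.

#' Forman-Ricci curvature of a graph edge
#'
#' For an undirected simple graph whose cliques are at most triangles, the
#' Forman-Ricci curvature of an edge (a1, a2) is
#' \code{4 - deg(a1) - deg(a2) + 3 * T}, where T is the number of triangles
#' containing the edge; the triangle-free form \code{4 - deg(a1) - deg(a2)}
#' is the T = 0 special case. Values are integers.
#'
#' @param graph an \code{igraph} undirected graph.
#' @param edge length-2 vector of endpoint vertex ids.
#' @return numeric(1), the curvature.
#' @export
formanCurvature <- function(graph, edge) {
  stopifnot(length(edge) == 2L)
  if (any(edge < 1L) || any(edge > igraph::vcount(graph)) ||
      !igraph::are_adjacent(graph, edge[1L], edge[2L]))
    stop("edge (", edge[1L], ", ", edge[2L], ") is not in the graph")
  deg <- unname(igraph::degree(graph, v = edge))
  tri <- length(intersect(igraph::neighbors(graph, edge[1L]),
                          igraph::neighbors(graph, edge[2L])))
  4 - deg[1L] - deg[2L] + 3 * tri
}

# Exact solver for the balanced transportation problem
#   min sum C * X  s.t. rowSums(X) = supply, colSums(X) = demand, X >= 0
# Northwest-corner start + MODI pivoting with Bland's rule on entering cells.
.solveTransport <- function(cost, supply, demand, tol = 1e-12) {
  m <- length(supply); n <- length(demand)
  stopifnot(nrow(cost) == m, ncol(cost) == n,
            abs(sum(supply) - sum(demand)) < 1e-9)
  X <- matrix(0, m, n)
  basis <- matrix(FALSE, m, n)
  a <- supply; b <- demand
  i <- 1L; j <- 1L
  repeat {
    q <- min(a[i], b[j])
    X[i, j] <- q; basis[i, j] <- TRUE
    a[i] <- a[i] - q; b[j] <- b[j] - q
    if (i == m && j == n) break
    if (a[i] <= tol && i < m) i <- i + 1L else j <- j + 1L
  }
  maxit <- 200L * (m + n)
  for (iter in seq_len(maxit)) {
    # potentials from the basis spanning tree
    u <- rep(NA_real_, m); v <- rep(NA_real_, n)
    u[1L] <- 0
    repeat {
      progress <- FALSE
      for (ii in seq_len(m)) for (jj in seq_len(n)) if (basis[ii, jj]) {
        if (!is.na(u[ii]) && is.na(v[jj])) { v[jj] <- cost[ii, jj] - u[ii]; progress <- TRUE }
        else if (is.na(u[ii]) && !is.na(v[jj])) { u[ii] <- cost[ii, jj] - v[jj]; progress <- TRUE }
      }
      if (!progress) break
    }
    red <- cost - outer(u, v, `+`)
    red[basis] <- 0
    enter <- which(red < -1e-11)
    if (length(enter) == 0L)
      return(list(cost = sum(cost * X), plan = X))
    enter <- enter[1L]  # Bland: smallest column-major index
    i0 <- (enter - 1L) %% m + 1L; j0 <- (enter - 1L) %/% m + 1L
    # unique cycle: path from row-node i0 to col-node j0 in the basis tree
    # nodes 1..m are rows, m+1..m+n are cols
    adj <- vector("list", m + n)
    for (ii in seq_len(m)) for (jj in seq_len(n)) if (basis[ii, jj]) {
      adj[[ii]] <- c(adj[[ii]], m + jj)
      adj[[m + jj]] <- c(adj[[m + jj]], ii)
    }
    parent <- rep(NA_integer_, m + n)
    parent[i0] <- 0L
    queue <- i0
    while (length(queue) > 0L) {
      x <- queue[1L]; queue <- queue[-1L]
      if (x == m + j0) break
      for (y in adj[[x]]) if (is.na(parent[y])) { parent[y] <- x; queue <- c(queue, y) }
    }
    path <- m + j0
    while (utils::tail(path, 1L) != i0)
      path <- c(path, parent[utils::tail(path, 1L)])
    # path: col j0 -> ... -> row i0; consecutive node pairs are basic cells,
    # already ordered so the first cell shares column j0 with the entering cell
    cells_i <- i0; cells_j <- j0
    for (k in seq_len(length(path) - 1L)) {
      x <- path[k]; y <- path[k + 1L]
      cells_i <- c(cells_i, min(x, y)); cells_j <- c(cells_j, max(x, y) - m)
    }
    sign <- rep_len(c(1, -1), length(cells_i))
    minus <- which(sign < 0)
    theta_pos <- minus[which.min(X[cbind(cells_i[minus], cells_j[minus])])]
    theta <- X[cells_i[theta_pos], cells_j[theta_pos]]
    for (k in seq_along(cells_i))
      X[cells_i[k], cells_j[k]] <- X[cells_i[k], cells_j[k]] + sign[k] * theta
    basis[i0, j0] <- TRUE
    basis[cells_i[theta_pos], cells_j[theta_pos]] <- FALSE
    X[cells_i[theta_pos], cells_j[theta_pos]] <- 0
  }
  stop("transportation simplex failed to converge")
}

#' Exact 1-Wasserstein distance between two finitely supported measures
#'
#' Solves the transportation linear program exactly (transportation simplex)
#' for the minimal cost of moving mass \code{mu} to mass \code{nu} under the
#' ground cost matrix \code{cost}.
#'
#' @param mu,nu nonnegative weight vectors with equal sums.
#' @param cost cost matrix, \code{length(mu)} x \code{length(nu)}.
#' @return numeric(1), the optimal transport cost.
#' @export
wassersteinDistance <- function(mu, nu, cost) {
  .solveTransport(cost, mu, nu)$cost
}

#' Ollivier-Ricci curvature of a graph edge
#'
#' The alpha-lazy random-walk measure at a node places mass \code{alpha} on
#' the node itself and \code{(1 - alpha)/deg} on each neighbour. The
#' Ollivier-Ricci curvature of edge (i, j) is
#' \code{1 - W(m_i, m_j) / d(i, j)}, where W is the exact optimal-transport
#' distance between the two measures under the graph metric and d is the
#' graph distance between the endpoints. By default the graph metric is the
#' unweighted hop count; set \code{weighted = TRUE} to use
#' distance-weighted shortest paths instead.
#'
#' @param graph an \code{igraph} undirected graph (with a \code{weight} edge
#'   attribute when \code{weighted = TRUE}).
#' @param edge length-2 vector of endpoint vertex ids.
#' @param alpha idleness parameter in [0, 1] (default 0.5).
#' @param weighted use weighted shortest-path distances (default FALSE).
#' @return numeric(1), the curvature (at most 1).
#' @export
ollivierCurvature <- function(graph, edge, alpha = 0.5, weighted = FALSE) {
  stopifnot(length(edge) == 2L, alpha >= 0, alpha <= 1)
  if (!igraph::are_adjacent(graph, edge[1L], edge[2L]))
    stop("edge (", edge[1L], ", ", edge[2L], ") is not in the graph")
  i <- edge[1L]; j <- edge[2L]
  ni <- as.integer(igraph::neighbors(graph, i))
  nj <- as.integer(igraph::neighbors(graph, j))
  si <- c(i, ni); sj <- c(j, nj)
  mi <- c(alpha, rep((1 - alpha) / length(ni), length(ni)))
  mj <- c(alpha, rep((1 - alpha) / length(nj), length(nj)))
  w <- if (weighted) igraph::E(graph)$weight else NA
  D <- igraph::distances(graph, v = si, to = sj, weights = w)
  dij <- igraph::distances(graph, v = i, to = j, weights = w)[1L, 1L]
  W <- wassersteinDistance(mi, mj, D)
  if (!is.finite(W)) stop("non-finite transport cost")
  1 - W / dij
}

#' Distance-filtration subgraphs of a weighted graph
#'
#' For each filtration value l_k the k-th subgraph keeps every node and
#' exactly the edges with weight at most l_k; the sequence is nested since
#' the filtration values increase.
#'
#' @param graph an \code{igraph} graph with a \code{weight} edge attribute.
#' @param filtrations strictly increasing numeric vector of thresholds.
#' @return List of \code{igraph} subgraphs, one per filtration value.
#' @export
filtrationSubgraphs <- function(graph, filtrations) {
  if (is.unsorted(filtrations, strictly = TRUE))
    stop("filtration values must be strictly increasing")
  w <- igraph::E(graph)$weight
  if (is.null(w)) stop("graph has no 'weight' edge attribute")
  lapply(filtrations, function(l)
    igraph::subgraph_from_edges(graph, igraph::E(graph)[w <= l],
                                delete.vertices = FALSE))
}

#' Default filtration grid for multiscale curvature
#'
#' Fifty thresholds \code{0.1 * (0:49)} Angstrom, spanning edge lengths up to
#' the default 5 Angstrom graph cutoff.
#' @return numeric(50).
#' @export
defaultFiltrations <- function() 0.1 * (0:49)

# Undirected edge list (i < j) with weights, plus the map back to the
# directed edges of an InteractionGraph.
.undirectedEdges <- function(graph) {
  e <- graphEdges(graph)
  w <- edgeDistances(graph)
  lo <- pmin(e[, 1L], e[, 2L]); hi <- pmax(e[, 1L], e[, 2L])
  key <- paste(lo, hi)
  first <- !duplicated(key)
  list(i = lo[first], j = hi[first], w = w[first],
       directed_to_undirected = match(key, key[first]))
}

#' Multiscale curvature profiles for an interaction graph
#'
#' Computes, for every edge of the interaction graph, the vector of discrete
#' curvatures of that edge inside the nested filtration subgraphs (edge
#' weights = Euclidean distances). An entry is 0 when the edge's length
#' exceeds the filtration value (the edge is absent from that subgraph).
#' Curvature is evaluated on the undirected simple graph underlying the
#' directed interaction graph, and both directed orientations of an edge
#' share the same profile.
#'
#' @param graph an \linkS4class{InteractionGraph}.
#' @param filtrations strictly increasing thresholds (default
#'   \code{defaultFiltrations()}).
#' @param kind \code{"forman"} (default) or \code{"ollivier"}.
#' @param alpha Ollivier idleness parameter (default 0.5).
#' @param weighted use weighted graph distances inside the Ollivier
#'   computation (default FALSE: hop counts).
#' @return \code{multiscaleCurvature}: numeric matrix, directed edges x
#'   filtrations. \code{attachCurvatureProfiles}: the graph with the profile
#'   matrix and filtration grid filled in.
#' @export
multiscaleCurvature <- function(graph, filtrations = defaultFiltrations(),
                                kind = c("forman", "ollivier"), alpha = 0.5,
                                weighted = FALSE) {
  kind <- match.arg(kind)
  if (is.unsorted(filtrations, strictly = TRUE))
    stop("filtration values must be strictly increasing")
  ue <- .undirectedEdges(graph)
  n <- nrow(atomTable(graph))
  nUE <- length(ue$i)
  prof <- matrix(0, nUE, length(filtrations))
  for (k in seq_along(filtrations)) {
    keep <- which(ue$w <= filtrations[k])
    if (length(keep) == 0L) next
    if (kind == "forman") {
      A <- matrix(0L, n, n)
      A[cbind(ue$i[keep], ue$j[keep])] <- 1L
      A <- A + t(A)
      deg <- rowSums(A)
      tri <- (A %*% A)[cbind(ue$i[keep], ue$j[keep])]
      prof[keep, k] <- 4 - deg[ue$i[keep]] - deg[ue$j[keep]] + 3 * tri
    } else {
      g <- igraph::graph_from_edgelist(cbind(ue$i[keep], ue$j[keep]),
                                       directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
      igraph::E(g)$weight <- ue$w[keep]
      for (idx in keep)
        prof[idx, k] <- ollivierCurvature(g, c(ue$i[idx], ue$j[idx]),
                                          alpha = alpha, weighted = weighted)
    }
  }
  prof[ue$directed_to_undirected, , drop = FALSE]
}

#' @rdname multiscaleCurvature
#' @export
attachCurvatureProfiles <- function(graph, filtrations = defaultFiltrations(),
                                    kind = c("forman", "ollivier"),
                                    alpha = 0.5, weighted = FALSE) {
  prof <- multiscaleCurvature(graph, filtrations, kind, alpha, weighted)
  graph@curvatureProfiles <- prof
  graph@filtrationValues <- as.numeric(filtrations)
  validObject(graph)
  graph
}
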