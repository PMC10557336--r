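# Complex interaction graph construction and geometric derivatives.
# Node set: ligand atoms + protein atoms within `cutoff` of some ligand atom.
# Edge set: both directions between every distinct retained pair within
# `cutoff`. All downstream quantities (distances, angles, curvatures) are
# rigid-motion invariant by construction.

.MIN_SEPARATION <- 1e-3  # Angstrom; closer distinct atoms = invalid geometry

.RAW_FEATURE_DIM <- 18L

.rawAtomFeatures <- function(atoms) {
  vocab <- ligandElements()
  onehot <- outer(atoms$element, vocab, `==`) * 1
  cbind(onehot,
        atoms$hybridization,
        atoms$n_heavy,
        atoms$n_hetero,
        atoms$hydrophobic * 1, atoms$aromatic * 1, atoms$acceptor * 1,
        atoms$donor * 1, atoms$ring * 1,
        atoms$partial_charge)
}

#' Featurize atoms as 36-dimensional vectors
#'
#' Each atom is encoded by an 18-dimensional raw block: element one-hot over
#' the 9-element ligand vocabulary (C, N, O, S, P, I, Cl, B, F), hybridization
#' (1/2/3), number of attached heavy atoms, number of attached heteroatoms,
#' five SMARTS-style flags (hydrophobic, aromatic, acceptor, donor, ring) and
#' the partial charge. To distinguish molecule of origin the block occupies
#' the first half (positions 1-18) for ligand atoms and the second half
#' (positions 19-36) for protein atoms; the other half is zero.
#'
#' @param atoms data.frame of atoms (columns as in
#'   \linkS4class{MolecularComplex}).
#' @return numeric matrix, \code{nrow(atoms)} x 36.
#' @export
atomFeatureMatrix <- function(atoms) {
  bad_p <- atoms$origin == "protein" & !(atoms$element %in% proteinElements())
  bad_l <- atoms$origin == "ligand" & !(atoms$element %in% ligandElements())
  if (any(bad_p | bad_l))
    stop("element outside origin vocabulary: ",
         paste(unique(atoms$element[bad_p | bad_l]), collapse = ", "))
  raw <- .rawAtomFeatures(atoms)
  out <- matrix(0, nrow(atoms), 2L * .RAW_FEATURE_DIM)
  lig <- atoms$origin == "ligand"
  out[lig, seq_len(.RAW_FEATURE_DIM)] <- raw[lig, , drop = FALSE]
  out[!lig, .RAW_FEATURE_DIM + seq_len(.RAW_FEATURE_DIM)] <- raw[!lig, , drop = FALSE]
  out
}

#' @rdname atomFeatureMatrix
#' @param atom a single-row atom data.frame.
#' @return \code{featurizeAtom}: numeric vector of length 36.
#' @export
featurizeAtom <- function(atom) {
  as.numeric(atomFeatureMatrix(atom[1L, , drop = FALSE]))
}

.pairwiseDistances <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

#' Build the directed complex interaction graph
#'
#' Retains all ligand atoms plus every protein atom within \code{cutoff}
#' Angstrom of at least one ligand atom, and connects every distinct retained
#' pair within \code{cutoff} by a pair of directed edges (one per direction).
#' Intramolecular edges are kept; only the interaction matrix restricts to
#' intermolecular pairs. Distinct atoms closer than 1e-3 Angstrom are
#' rejected as invalid geometry (they would break distance and angle
#' computations downstream).
#'
#' @param complex a \linkS4class{MolecularComplex}.
#' @param cutoff graph cutoff distance d in Angstrom (default 5).
#' @return An \linkS4class{InteractionGraph} (curvature profiles not yet
#'   attached).
#' @export
buildInteractionGraph <- function(complex, cutoff = 5) {
  stopifnot(is(complex, "MolecularComplex"), cutoff > 0)
  atoms <- atomTable(complex)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  D <- .pairwiseDistances(xyz)
  lig <- which(atoms$origin == "ligand")
  prot <- which(atoms$origin == "protein")
  near <- prot[apply(D[prot, lig, drop = FALSE], 1L, min) <= cutoff]
  keep <- sort(c(lig, near))
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  D <- D[keep, keep, drop = FALSE]
  n <- length(keep)
  if (n > 1L) {
    off <- D[upper.tri(D)]
    if (any(off < .MIN_SEPARATION))
      stop("invalid geometry: distinct atoms closer than ",
           .MIN_SEPARATION, " Angstrom")
  }
  idx <- which(D <= cutoff & upper.tri(D), arr.ind = TRUE)
  edges <- rbind(idx, idx[, 2:1, drop = FALSE])
  dimnames(edges) <- NULL
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  storage.mode(edges) <- "integer"
  dists <- D[edges]
  new("InteractionGraph",
      atoms = atoms,
      nodeFeatures = atomFeatureMatrix(atoms),
      edges = edges,
      edgeDistance = as.numeric(dists),
      curvatureProfiles = matrix(0, nrow(edges), 0L),
      filtrationValues = numeric(0),
      cutoff = cutoff,
      affinity = affinity(complex))
}

#' Edge-oriented neighbours of a node or directed edge
#'
#' For a node \code{a_i}, the edge-oriented neighbours are all directed edges
#' (k, i) pointing into it. For a directed edge (i, j) they are the directed
#' edges (k, i) pointing into its source atom; by default the backtracking
#' reverse edge (j, i) is excluded so that messages do not immediately flow
#' back along the edge they came from.
#'
#' @param graph an \linkS4class{InteractionGraph}.
#' @param node integer node index (give exactly one of \code{node}/\code{edge}).
#' @param edge length-2 integer vector (i, j); must be an edge of the graph.
#' @param excludeReverse drop (j, i) from the neighbours of edge (i, j)?
#' @return Integer vector of directed-edge row indices into
#'   \code{graphEdges(graph)}.
#' @export
edgeOrientedNeighbors <- function(graph, node = NULL, edge = NULL,
                                  excludeReverse = TRUE) {
  e <- graphEdges(graph)
  if (!is.null(node)) {
    if (length(node) != 1L || node < 1L || node > nrow(atomTable(graph)))
      stop("unknown node index: ", node)
    return(which(e[, 2L] == node))
  }
  if (is.null(edge) || length(edge) != 2L) stop("give a node or an edge (i, j)")
  hit <- which(e[, 1L] == edge[1L] & e[, 2L] == edge[2L])
  if (length(hit) == 0L)
    stop("edge (", edge[1L], ", ", edge[2L], ") is not in the graph")
  inc <- which(e[, 2L] == edge[1L])
  if (excludeReverse) inc <- inc[e[inc, 1L] != edge[2L]]
  inc
}

#' Compute the ground-truth interaction matrix Z
#'
#' Counts intermolecular (protein, ligand) atom pairs strictly within
#' \code{cutoff} Angstrom (a Heaviside step on \code{cutoff - d}),
#' tabulated by element-type pair (T_k, T_l) in S_P x S_L, and
#' normalizes by the total number of qualifying pairs. Uses every atom of the
#' complex (not only those retained in the interaction graph). When no pair
#' qualifies the matrix is all-zero.
#'
#' @param complex a \linkS4class{MolecularComplex}.
#' @param cutoff interaction cutoff distance in Angstrom (default 12).
#' @return An \linkS4class{InteractionMatrix}.
#' @export
computeInteractionMatrix <- function(complex, cutoff = 12) {
  stopifnot(is(complex, "MolecularComplex"), cutoff > 0)
  atoms <- atomTable(complex)
  p <- atoms[atoms$origin == "protein", , drop = FALSE]
  l <- atoms[atoms$origin == "ligand", , drop = FALSE]
  pm <- as.matrix(p[, c("x", "y", "z")])
  lm <- as.matrix(l[, c("x", "y", "z")])
  d2 <- outer(rowSums(pm^2), rowSums(lm^2), `+`) - 2 * pm %*% t(lm)
  # Heaviside step on (cutoff - d): strictly-within pairs count
  within <- cutoff - sqrt(pmax(d2, 0)) > 0
  Z <- matrix(0, length(proteinElements()), length(ligandElements()),
              dimnames = list(proteinElements(), ligandElements()))
  total <- sum(within)
  if (total > 0L) {
    hits <- which(within, arr.ind = TRUE)
    tab <- table(factor(p$element[hits[, 1L]], levels = proteinElements()),
                 factor(l$element[hits[, 2L]], levels = ligandElements()))
    Z <- unclass(tab) / total
    dimnames(Z) <- list(proteinElements(), ligandElements())
  }
  new("InteractionMatrix", values = Z, cutoff = cutoff)
}

#' Build the angle-domain line graph
#'
#' The line graph's nodes are the directed edges of the interaction graph. An
#' arc runs from edge e_ki to edge e_ij whenever e_ki points into the source
#' atom a_i of e_ij (with k != j unless \code{excludeReverse = FALSE}). The
#' arc is labelled with the angle at a_i between the vectors towards a_k and
#' a_j (degrees, in [0, 180]) and with its angle-domain index q in 1..N:
#' domain q covers the half-open interval (180(q-1)/N, 180q/N], an exact 0
#' falling into domain 1.
#'
#' @param graph an \linkS4class{InteractionGraph}.
#' @param nDomains number of angle domains N (default 6).
#' @param excludeReverse drop backtracking arcs e_ji -> e_ij (default TRUE).
#' @return An \linkS4class{AngleLineGraph}.
#' @export
buildAngleLineGraph <- function(graph, nDomains = 6L, excludeReverse = TRUE) {
  stopifnot(nDomains >= 1L)
  e <- graphEdges(graph)
  xyz <- coords(graph)
  nE <- nrow(e)
  incoming <- split(seq_len(nE), factor(e[, 2L], levels = seq_len(nrow(xyz))))
  src <- tgt <- vector("list", nE)
  for (t in seq_len(nE)) {
    i <- e[t, 1L]; j <- e[t, 2L]
    s <- incoming[[i]]
    if (excludeReverse) s <- s[e[s, 1L] != j]
    if (length(s) > 0L) {
      src[[t]] <- s
      tgt[[t]] <- rep.int(t, length(s))
    }
  }
  src <- unlist(src, use.names = FALSE)
  tgt <- unlist(tgt, use.names = FALSE)
  if (is.null(src)) src <- integer(0)
  if (is.null(tgt)) tgt <- integer(0)
  if (length(src) > 0L) {
    i <- e[tgt, 1L]; j <- e[tgt, 2L]; k <- e[src, 1L]
    u <- xyz[k, , drop = FALSE] - xyz[i, , drop = FALSE]
    v <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    if (any(nu < .MIN_SEPARATION) || any(nv < .MIN_SEPARATION))
      stop("invalid geometry: zero-length edge vector in angle computation")
    cosang <- pmin(1, pmax(-1, rowSums(u * v) / (nu * nv)))
    ang <- acos(cosang) * 180 / pi
    dom <- pmin(nDomains, pmax(1L, ceiling(ang * nDomains / 180 - 1e-9)))
  } else {
    ang <- numeric(0); dom <- integer(0)
  }
  new("AngleLineGraph",
      arcs = cbind(src, tgt, deparse.level = 0),
      angle = as.numeric(ang),
      domain = as.integer(dom),
      nDomains = as.integer(nDomains))
}
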