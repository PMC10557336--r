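#' Accessors for the core classes
#'
#' Slot access goes through these accessors rather than \code{@}.
#'
#' @param x a \linkS4class{MolecularComplex}, \linkS4class{InteractionGraph},
#'   \linkS4class{AngleLineGraph} or \linkS4class{InteractionMatrix}.
#' @return \code{atomTable}: the atom data.frame; \code{affinity}: the pK
#'   label (NA if absent); \code{nodeFeatures}: the nodes x 36 feature matrix;
#'   \code{graphEdges}: the directed edge index matrix; \code{edgeDistances}:
#'   per-edge distances (Angstrom); \code{curvatureProfiles}: the per-edge
#'   profile matrix; \code{filtrationValues}: its filtration grid;
#'   \code{interactionValues}: the 4 x 9 co-occurrence matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setGeneric("affinity", function(x) standardGeneric("affinity"))
#' @rdname accessors
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("edgeDistances", function(x) standardGeneric("edgeDistances"))
#' @rdname accessors
#' @export
setGeneric("curvatureProfiles", function(x) standardGeneric("curvatureProfiles"))
#' @rdname accessors
#' @export
setGeneric("filtrationValues", function(x) standardGeneric("filtrationValues"))
#' @rdname accessors
#' @export
setGeneric("interactionValues", function(x) standardGeneric("interactionValues"))

#' @rdname accessors
#' @export
setMethod("atomTable", "MolecularComplex", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("atomTable", "InteractionGraph", function(x) x@atoms)
#' @rdname accessors
#' @export
setMethod("affinity", "MolecularComplex", function(x) x@affinity)
#' @rdname accessors
#' @export
setMethod("affinity", "InteractionGraph", function(x) x@affinity)
#' @rdname accessors
#' @export
setMethod("nodeFeatures", "InteractionGraph", function(x) x@nodeFeatures)
#' @rdname accessors
#' @export
setMethod("graphEdges", "InteractionGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("edgeDistances", "InteractionGraph", function(x) x@edgeDistance)
#' @rdname accessors
#' @export
setMethod("curvatureProfiles", "InteractionGraph", function(x) x@curvatureProfiles)
#' @rdname accessors
#' @export
setMethod("filtrationValues", "InteractionGraph", function(x) x@filtrationValues)
#' @rdname accessors
#' @export
setMethod("interactionValues", "InteractionMatrix", function(x) x@values)

#' @rdname accessors
#' @export
coords <- function(x) {
  a <- atomTable(x)
  m <- as.matrix(a[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}
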