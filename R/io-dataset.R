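# On-disk dataset container: one JSON file per split, one record per complex
# (atom table, 36-d node features, directed edge list with distances,
# multiscale curvature profiles, interaction matrix Z, pK label). JSON keeps
# the container plain-text and language-neutral.

.DATASET_SCHEMA <- "curvagn-dataset-v1"

#' Featurize a complex into a model-ready record
#'
#' Builds the directed interaction graph at \code{cutoff}, attaches the
#' multiscale curvature profiles over \code{filtrations}, and computes the
#' ground-truth interaction matrix at \code{rho}.
#'
#' @param complex a \linkS4class{MolecularComplex}.
#' @param cutoff graph cutoff d, Angstrom (default 5).
#' @param rho interaction-matrix cutoff, Angstrom (default 12).
#' @param filtrations curvature filtration grid (default
#'   \code{defaultFiltrations()}).
#' @param kind,alpha curvature kind and Ollivier idleness (see
#'   \code{\link{multiscaleCurvature}}).
#' @return List with elements \code{graph} (\linkS4class{InteractionGraph},
#'   curvature attached) and \code{Z} (\linkS4class{InteractionMatrix}).
#' @export
featurizeComplex <- function(complex, cutoff = 5, rho = 12,
                             filtrations = defaultFiltrations(),
                             kind = c("forman", "ollivier"), alpha = 0.5) {
  kind <- match.arg(kind)
  graph <- buildInteractionGraph(complex, cutoff = cutoff)
  graph <- attachCurvatureProfiles(graph, filtrations, kind, alpha)
  list(graph = graph, Z = computeInteractionMatrix(complex, cutoff = rho))
}

#' Read and write the serialized graph dataset
#'
#' \code{writeGraphDataset} serializes a list of featurized records (as
#' returned by \code{\link{featurizeComplex}}) to a single JSON file;
#' \code{readGraphDataset} restores them. The container stores, per complex:
#' the atom table, node feature matrix, directed edge list with distances,
#' curvature profiles with their filtration grid, the interaction matrix and
#' the pK label, under a schema tag.
#'
#' @param records list of featurized records.
#' @param path file path (conventionally \code{.json}).
#' @return \code{readGraphDataset}: the list of records.
#' @export
writeGraphDataset <- function(records, path) {
  payload <- list(
    schema = .DATASET_SCHEMA,
    complexes = lapply(records, function(r) {
      g <- r$graph
      list(atoms = atomTable(g),
           nodeFeatures = nodeFeatures(g),
           edges = graphEdges(g),
           edgeDistance = edgeDistances(g),
           curvatureProfiles = curvatureProfiles(g),
           filtrationValues = filtrationValues(g),
           cutoff = g@cutoff,
           affinity = affinity(g),
           Z = interactionValues(r$Z),
           rho = r$Z@cutoff)
    }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeGraphDataset
#' @export
readGraphDataset <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, .DATASET_SCHEMA))
    stop("unrecognized dataset schema in ", path)
  cx <- payload$complexes
  n <- if (is.data.frame(cx)) nrow(cx) else length(cx)
  get_rec <- function(k) if (is.data.frame(cx)) lapply(cx, `[[`, k) else cx[[k]]
  lapply(seq_len(n), function(k) {
    r <- get_rec(k)
    atoms <- as.data.frame(r$atoms, stringsAsFactors = FALSE)
    prof <- r$curvatureProfiles
    if (is.null(prof) || length(prof) == 0L)
      prof <- matrix(0, nrow(r$edges), 0L)
    graph <- new("InteractionGraph",
                 atoms = atoms,
                 nodeFeatures = as.matrix(r$nodeFeatures),
                 edges = matrix(as.integer(r$edges), ncol = 2L),
                 edgeDistance = as.numeric(r$edgeDistance),
                 curvatureProfiles = as.matrix(prof),
                 filtrationValues = as.numeric(r$filtrationValues),
                 cutoff = as.numeric(r$cutoff),
                 affinity = as.numeric(r$affinity))
    Zv <- as.matrix(r$Z)
    dimnames(Zv) <- list(proteinElements(), ligandElements())
    list(graph = graph,
         Z = new("InteractionMatrix", values = Zv, cutoff = as.numeric(r$rho)))
  })
}
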