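#' @import methods
NULL

#' Element vocabularies for protein and ligand heavy atoms
#'
#' Heavy-atom element sets the model can represent: proteins are restricted to
#' \{C, N, O, S\}, ligands to \{C, N, O, S, P, I, Cl, B, F\}. Atoms outside the
#' vocabulary of their molecule of origin are dropped (with a warning) when a
#' complex is read or generated; hydrogens are excluded everywhere.
#'
#' @return Character vector of element symbols.
#' @export
proteinElements <- function() c("C", "N", "O", "S")

#' @rdname proteinElements
#' @export
ligandElements <- function() c("C", "N", "O", "S", "P", "I", "Cl", "B", "F")

.ATOM_COLS <- c("element", "x", "y", "z", "hybridization", "n_heavy",
                "n_hetero", "hydrophobic", "aromatic", "acceptor", "donor",
                "ring", "partial_charge", "origin")

.checkAtomTable <- function(atoms, what) {
  missing <- setdiff(.ATOM_COLS, names(atoms))
  if (length(missing) > 0L)
    return(sprintf("%s: missing atom columns: %s", what,
                   paste(missing, collapse = ", ")))
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords)))
    return(sprintf("%s: non-finite coordinates", what))
  bad_p <- atoms$origin == "protein" & !(atoms$element %in% proteinElements())
  bad_l <- atoms$origin == "ligand" & !(atoms$element %in% ligandElements())
  if (any(bad_p | bad_l))
    return(sprintf("%s: element outside origin vocabulary: %s", what,
                   paste(unique(atoms$element[bad_p | bad_l]), collapse = ", ")))
  TRUE
}

#' MolecularComplex: a protein-ligand complex as heavy-atom tables
#'
#' Holds the protein and ligand heavy atoms of one complex. Each atom carries
#' its element symbol, Cartesian coordinates in Angstrom, simple chemistry
#' descriptors (hybridization 1/2/3, heavy- and hetero-neighbour counts, five
#' SMARTS-style boolean flags: hydrophobic, aromatic, acceptor, donor, ring)
#' and a partial charge. The optional \code{affinity} is the experimental
#' binding affinity on the pK scale (-log Kd/Ki/IC50); \code{NA} when unknown.
#'
#' @slot atoms data.frame with one row per atom and columns
#'   \code{element, x, y, z, hybridization, n_heavy, n_hetero, hydrophobic,
#'   aromatic, acceptor, donor, ring, partial_charge, origin}; \code{origin}
#'   is \code{"protein"} or \code{"ligand"}.
#' @slot affinity numeric(1), pK-scale label or NA.
#' @export
setClass("MolecularComplex",
         representation(atoms = "data.frame", affinity = "numeric"),
         prototype(affinity = NA_real_))

setValidity("MolecularComplex", function(object) {
  a <- object@atoms
  if (!all(a$origin %in% c("protein", "ligand")))
    return("origin must be 'protein' or 'ligand'")
  if (sum(a$origin == "ligand") == 0L) return("ligand_atoms is empty")
  if (sum(a$origin == "protein") == 0L) return("protein_atoms is empty")
  if (length(object@affinity) != 1L) return("affinity must be length 1")
  .checkAtomTable(a, "atoms")
})

#' Construct a MolecularComplex from atom tables
#'
#' @param protein_atoms,ligand_atoms data.frames of atoms (see
#'   \linkS4class{MolecularComplex}); the \code{origin} column is overwritten.
#' @param affinity optional pK-scale affinity label.
#' @return A \linkS4class{MolecularComplex}.
#' @export
MolecularComplex <- function(protein_atoms, ligand_atoms, affinity = NA_real_) {
  protein_atoms$origin <- "protein"
  ligand_atoms$origin <- "ligand"
  atoms <- rbind(protein_atoms[, .ATOM_COLS], ligand_atoms[, .ATOM_COLS])
  rownames(atoms) <- NULL
  new("MolecularComplex", atoms = atoms, affinity = as.numeric(affinity))
}

#' InteractionGraph: directed distance-cutoff graph over a complex
#'
#' Nodes are all ligand atoms plus the protein atoms lying within
#' \code{cutoff} Angstrom of at least one ligand atom; directed edges run both
#' ways between every distinct node pair within \code{cutoff}. Edge distances
#' are Euclidean. Multiscale curvature profiles (one row per directed edge,
#' one column per filtration value) are attached by
#' \code{\link{attachCurvatureProfiles}} and are empty (0 columns) until then.
#'
#' @slot atoms data.frame of the retained atoms (same columns as
#'   \linkS4class{MolecularComplex}).
#' @slot nodeFeatures numeric matrix, nodes x 36 (ligand half / protein half).
#' @slot edges integer matrix, nEdges x 2, directed (from, to) node indices.
#' @slot edgeDistance numeric, per directed edge, Angstrom.
#' @slot curvatureProfiles numeric matrix, nEdges x nFiltrations (0 columns
#'   until attached).
#' @slot filtrationValues numeric, increasing filtration values (Angstrom).
#' @slot cutoff numeric(1), the graph cutoff distance d (Angstrom).
#' @slot affinity numeric(1), pK label carried over from the complex (or NA).
#' @export
setClass("InteractionGraph",
         representation(atoms = "data.frame", nodeFeatures = "matrix",
                        edges = "matrix", edgeDistance = "numeric",
                        curvatureProfiles = "matrix",
                        filtrationValues = "numeric",
                        cutoff = "numeric", affinity = "numeric"))

setValidity("InteractionGraph", function(object) {
  e <- object@edges
  n <- nrow(object@atoms)
  if (nrow(object@nodeFeatures) != n) return("nodeFeatures/atoms row mismatch")
  if (ncol(object@nodeFeatures) != 36L) return("nodeFeatures must have 36 columns")
  if (nrow(e) != length(object@edgeDistance))
    return("edges/edgeDistance length mismatch")
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > n)) return("edge index out of range")
    if (any(e[, 1L] == e[, 2L])) return("self-edges are not allowed")
    if (any(object@edgeDistance > object@cutoff + 1e-9))
      return("edge distance exceeds cutoff")
    key <- paste(e[, 1L], e[, 2L])
    rev <- paste(e[, 2L], e[, 1L])
    if (!all(rev %in% key)) return("edge set is not symmetric")
  }
  if (nrow(object@curvatureProfiles) > 0L &&
      nrow(object@curvatureProfiles) != nrow(e))
    return("curvatureProfiles/edges row mismatch")
  TRUE
})

#' AngleLineGraph: angle-labelled line graph of an InteractionGraph
#'
#' Nodes of the line graph are the directed edges of the interaction graph.
#' An arc (e_ki -> e_ij) exists when e_ki is an edge-oriented neighbour of
#' e_ij, i.e. it points into the source atom a_i of e_ij (the backtracking
#' edge e_ji is excluded by default). Each arc carries the planar angle at the
#' shared atom a_i between the vectors to a_k and a_j, in degrees, and its
#' angle-domain index q in 1..N where domain q is the half-open interval
#' (180(q-1)/N, 180 q/N] and an exact 0 falls in domain 1.
#'
#' @slot arcs integer matrix, nArcs x 2: (source edge index, target edge index).
#' @slot angle numeric, degrees in [0, 180].
#' @slot domain integer in 1..N.
#' @slot nDomains integer(1), N.
#' @export
setClass("AngleLineGraph",
         representation(arcs = "matrix", angle = "numeric",
                        domain = "integer", nDomains = "integer"))

setValidity("AngleLineGraph", function(object) {
  if (nrow(object@arcs) != length(object@angle) ||
      nrow(object@arcs) != length(object@domain))
    return("arcs/angle/domain length mismatch")
  if (length(object@angle) > 0L) {
    if (any(object@angle < -1e-9 | object@angle > 180 + 1e-9))
      return("angles must lie in [0, 180] degrees")
    if (any(object@domain < 1L | object@domain > object@nDomains))
      return("domain index out of 1..N")
  }
  TRUE
})

#' InteractionMatrix: atom-type co-occurrence table Z
#'
#' The |S_P| x |S_L| matrix whose (T_k, T_l) entry is the fraction of
#' intermolecular (protein, ligand) atom pairs of element types (T_k, T_l)
#' within \code{cutoff} Angstrom of each other, among all such pairs within
#' the cutoff. Entries are nonnegative and sum to 1 whenever at least one
#' pair qualifies; the matrix is all-zero otherwise.
#'
#' @slot values numeric matrix, 4 x 9, rows named by protein elements and
#'   columns by ligand elements.
#' @slot cutoff numeric(1), the interaction cutoff distance (Angstrom).
#' @export
setClass("InteractionMatrix",
         representation(values = "matrix", cutoff = "numeric"))

setValidity("InteractionMatrix", function(object) {
  v <- object@values
  if (!identical(dim(v), c(length(proteinElements()), length(ligandElements()))))
    return("values must be |S_P| x |S_L|")
  if (any(v < -1e-12)) return("entries must be nonnegative")
  s <- sum(v)
  if (s > 1e-12 && abs(s - 1) > 1e-9) return("entries must sum to 1 (or all be 0)")
  TRUE
})

setMethod("show", "MolecularComplex", function(object) {
  a <- object@atoms
  cat(sprintf("MolecularComplex: %d protein / %d ligand heavy atoms%s\n",
              sum(a$origin == "protein"), sum(a$origin == "ligand"),
              if (is.na(object@affinity)) ""
              else sprintf(", affinity (pK) = %.3f", object@affinity)))
})

setMethod("show", "InteractionGraph", function(object) {
  cat(sprintf(
    "InteractionGraph: %d nodes, %d directed edges (cutoff %.1f A)%s\n",
    nrow(object@atoms), nrow(object@edges), object@cutoff,
    if (ncol(object@curvatureProfiles) > 0L)
      sprintf(", curvature profiles over %d filtrations",
              ncol(object@curvatureProfiles)) else ", no curvature attached"))
})

setMethod("show", "AngleLineGraph", function(object) {
  cat(sprintf("AngleLineGraph: %d arcs over %d angle domains\n",
              nrow(object@arcs), object@nDomains))
})

setMethod("show", "InteractionMatrix", function(object) {
  cat(sprintf("InteractionMatrix (cutoff %.1f A), mass %.3f\n",
              object@cutoff, sum(object@values)))
  print(round(object@values, 3))
})
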