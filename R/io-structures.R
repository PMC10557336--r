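# Structure readers. Parsing of the standard formats is delegated to bio3d
# (PDB, mol2) and ChemmineR (SDF); this file only normalizes their output
# into the atom table and derives the simple chemistry descriptors. No
# protonation and no bond-order perception beyond what the reader supplies.
#
# Descriptor heuristics (documented approximations; an R environment has no
# SMARTS engine):
#   n_heavy   : heavy-atom neighbours (file bonds if present, else a
#               covalent-distance rule: <= 1.85 A, 2.1 A when S/P involved)
#   n_hetero  : neighbours that are neither C nor H
#   hybridization: from SYBYL atom types when available (C.3 -> 3 etc.),
#               else clamp(#neighbours, 1, 3)
#   hydrophobic: carbon with no heteroatom neighbour
#   aromatic  : SYBYL ".ar" types; for PDB proteins, ring atoms of
#               PHE/TYR/TRP/HIS
#   acceptor  : N or O; donor: N or O (no hydrogen information is available)
#   ring      : endpoint of a non-bridge bond (lies on a cycle), or aromatic
#   partial_charge: the file's charge column when present, else 0

.normalizeElement <- function(x) {
  x <- trimws(x)
  paste0(toupper(substr(x, 1L, 1L)), tolower(substr(x, 2L, nchar(x))))
}

.covalentBonds <- function(element, xyz) {
  n <- nrow(xyz)
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  D <- as.matrix(stats::dist(xyz))
  long <- element %in% c("S", "P")
  thresh <- ifelse(outer(long, long, `|`), 2.1, 1.85)
  idx <- which(D <= thresh & upper.tri(D), arr.ind = TRUE)
  matrix(as.integer(idx), ncol = 2L)
}

.ringAtoms <- function(n, bonds) {
  out <- rep(FALSE, n)
  if (nrow(bonds) == 0L) return(out)
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  br <- igraph::bridges(g)
  on_cycle <- setdiff(seq_len(nrow(bonds)), as.integer(br))
  out[unique(as.vector(bonds[on_cycle, ]))] <- TRUE
  out
}

.AROMATIC_RES <- c("PHE", "TYR", "TRP", "HIS")
.AROMATIC_ATOMS <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "ND1", "NE2",
                     "CE3", "CZ2", "CZ3", "CH2")

# element/xyz (+ optional bonds, sybyl types, charges) -> atom table
.buildAtomTable <- function(element, xyz, bonds = NULL, sybyl = NULL,
                            charge = NULL, aromatic = NULL) {
  n <- length(element)
  if (is.null(bonds)) bonds <- .covalentBonds(element, xyz)
  nbr <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    nbr[[bonds[k, 1L]]] <- c(nbr[[bonds[k, 1L]]], bonds[k, 2L])
    nbr[[bonds[k, 2L]]] <- c(nbr[[bonds[k, 2L]]], bonds[k, 1L])
  }
  n_heavy <- vapply(nbr, length, 0L)
  n_hetero <- vapply(nbr, function(v) sum(element[v] != "C"), 0L)
  hyb <- pmin(3L, pmax(1L, n_heavy))
  if (!is.null(sybyl)) {
    suff <- sub("^[^.]*\\.?", "", sybyl)
    hyb <- ifelse(suff %in% c("1", "2", "3"), as.integer(suff),
                  ifelse(suff == "ar", 2L, hyb))
    if (is.null(aromatic)) aromatic <- suff == "ar"
  }
  if (is.null(aromatic)) aromatic <- rep(FALSE, n)
  ring <- .ringAtoms(n, bonds) | aromatic
  data.frame(element = element,
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             hybridization = as.integer(hyb),
             n_heavy = n_heavy, n_hetero = n_hetero,
             hydrophobic = element == "C" & n_hetero == 0L,
             aromatic = aromatic,
             acceptor = element %in% c("N", "O"),
             donor = element %in% c("N", "O"),
             ring = ring,
             partial_charge = if (is.null(charge)) rep(0, n) else charge,
             stringsAsFactors = FALSE)
}

.dropOutOfVocabulary <- function(atoms, vocabulary, what) {
  keep <- atoms$element %in% vocabulary
  if (!all(keep))
    warning(sprintf("%s: dropping %d atom(s) outside the element vocabulary: %s",
                    what, sum(!keep),
                    paste(unique(atoms$element[!keep]), collapse = ", ")),
            call. = FALSE)
  atoms[keep, , drop = FALSE]
}

.readProteinPDB <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  at <- pdb$atom
  el <- .normalizeElement(ifelse(is.na(at$elesy) | at$elesy == "",
                                 substr(trimws(at$elety), 1L, 1L), at$elesy))
  heavy <- !(el %in% c("H", "D"))
  at <- at[heavy, , drop = FALSE]; el <- el[heavy]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  aromatic <- at$resid %in% .AROMATIC_RES & trimws(at$elety) %in% .AROMATIC_ATOMS
  tab <- .buildAtomTable(el, xyz, aromatic = aromatic)
  .dropOutOfVocabulary(tab, proteinElements(), basename(path))
}

.readLigandMol2 <- function(path) {
  mol <- tryCatch(bio3d::read.mol2(path),
                  error = function(e) stop("failed to parse mol2 file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  at <- mol$atom
  el <- .normalizeElement(sub("\\..*$", "", at$elety))
  bonds <- if (!is.null(mol$bond) && nrow(mol$bond) > 0L)
    cbind(match(mol$bond$origin, at$eleno), match(mol$bond$target, at$eleno))
  else NULL
  heavy <- which(!(el %in% c("H", "D")))
  remap <- match(seq_along(el), heavy)
  if (!is.null(bonds)) {
    bonds <- cbind(remap[bonds[, 1L]], remap[bonds[, 2L]])
    bonds <- bonds[stats::complete.cases(bonds), , drop = FALSE]
    bonds <- matrix(as.integer(bonds), ncol = 2L)
  }
  at <- at[heavy, , drop = FALSE]
  tab <- .buildAtomTable(el[heavy], as.matrix(at[, c("x", "y", "z")]),
                         bonds = bonds, sybyl = at$elety,
                         charge = if ("charge" %in% names(at)) at$charge)
  .dropOutOfVocabulary(tab, ligandElements(), basename(path))
}

.readLigandSDF <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE))
    stop("reading SDF ligands requires the ChemmineR package")
  sdf <- tryCatch(ChemmineR::read.SDFset(path),
                  error = function(e) stop("failed to parse SDF file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  sdf <- sdf[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- .normalizeElement(sub("_.*$", "", rownames(ab)))
  xyz <- as.matrix(ab[, 1:3, drop = FALSE])
  bonds <- if (nrow(bb) > 0L) matrix(as.integer(as.matrix(bb[, 1:2])), ncol = 2L)
  else NULL
  heavy <- which(!(el %in% c("H", "D")))
  remap <- match(seq_along(el), heavy)
  if (!is.null(bonds)) {
    bonds <- cbind(remap[bonds[, 1L]], remap[bonds[, 2L]])
    bonds <- bonds[stats::complete.cases(bonds), , drop = FALSE]
    bonds <- matrix(as.integer(bonds), ncol = 2L)
  }
  tab <- .buildAtomTable(el[heavy], xyz[heavy, , drop = FALSE], bonds = bonds)
  .dropOutOfVocabulary(tab, ligandElements(), basename(path))
}

#' Read a protein-ligand complex from structure files
#'
#' Parses the protein from PDB and the ligand from mol2 or SDF (chosen by
#' file extension), excludes hydrogens, drops atoms whose element falls
#' outside the origin vocabulary (with a warning), and derives the chemistry
#' descriptors from the parsed molecule.
#'
#' @param protein_path path to a PDB file.
#' @param ligand_path path to a mol2 or SDF file.
#' @param affinity optional pK-scale label to attach.
#' @return A \linkS4class{MolecularComplex}.
#' @export
readComplex <- function(protein_path, ligand_path, affinity = NA_real_) {
  for (p in c(protein_path, ligand_path))
    if (!file.exists(p)) stop("file not found: ", p)
  prot <- .readProteinPDB(protein_path)
  ext <- tolower(tools::file_ext(ligand_path))
  lig <- switch(ext,
                mol2 = .readLigandMol2(ligand_path),
                sdf = .readLigandSDF(ligand_path),
                sd = .readLigandSDF(ligand_path),
                stop("unsupported ligand format '.", ext, "' (use mol2 or sdf)"))
  if (nrow(lig) == 0L)
    stop("ligand '", basename(ligand_path),
         "' has no representable heavy atoms after filtering")
  if (nrow(prot) == 0L)
    stop("protein '", basename(protein_path),
         "' has no representable heavy atoms after filtering")
  MolecularComplex(prot, lig, affinity = affinity)
}
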