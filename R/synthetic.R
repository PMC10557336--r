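# Reproducible synthetic protein-ligand complexes.
#
# The generator emulates the geometry the model consumes -- a compact ligand
# atom cloud with a partial protein shell around it -- with a known,
# deterministic affinity-generating function of the geometry, so that every
# pipeline stage (graph building, curvature, attention layers, training) is
# testable without any external structure files. It makes no attempt at
# bonding topology, secondary structure or force-field realism.

#' Specification of a synthetic complex
#'
#' @param n_ligand,n_protein heavy-atom counts (defaults 8 and 40).
#' @param box_size ligand box edge length, Angstrom (default 8).
#' @param contact_scale contact distance entering the label function,
#'   Angstrom (default 4).
#' @param contact_fraction target fraction of protein atoms placed within
#'   5 Angstrom of the ligand (default 0.5); the rest sit in an outer shell.
#' @param label_weights numeric(2) \code{c(w1, w2)}: the label is
#'   \code{w1 * (number of intermolecular pairs closer than contact_scale) +
#'   w2 * (mean inverse intermolecular distance) + noise}, clipped to the pK
#'   range [2, 12] (defaults \code{c(0.12, 25)}).
#' @param noise_sd Gaussian label noise SD on the pK scale (default 0.2).
#' @param seed integer RNG seed for this complex.
#' @return A \code{SyntheticSpec} (a named list).
#' @export
syntheticSpec <- function(n_ligand = 8L, n_protein = 40L, box_size = 8,
                          contact_scale = 4, contact_fraction = 0.5,
                          label_weights = c(0.12, 25), noise_sd = 0.2,
                          seed = 1L) {
  stopifnot(n_ligand >= 1L, n_protein >= 1L, box_size > 0, noise_sd >= 0,
            contact_fraction >= 0, contact_fraction <= 1,
            length(label_weights) == 2L)
  structure(list(n_ligand = as.integer(n_ligand),
                 n_protein = as.integer(n_protein),
                 box_size = box_size, contact_scale = contact_scale,
                 contact_fraction = contact_fraction,
                 label_weights = label_weights, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

.PROTEIN_FREQ <- c(C = 0.60, N = 0.15, O = 0.15, S = 0.10)
.LIGAND_FREQ <- c(C = 0.55, N = 0.13, O = 0.13, S = 0.09, P = 0.025,
                  I = 0.01, Cl = 0.025, B = 0.01, F = 0.025)
.MIN_GEN_SEPARATION <- 1.2   # Angstrom, enforced by rejection
.CONTACT_SHELL <- c(2.0, 4.8)   # placement radii for contact protein atoms
.OUTER_SHELL <- c(5.5, 10)      # placement radii for non-contact atoms

.randomUnitVectors <- function(n) {
  v <- matrix(stats::rnorm(3L * n), n, 3L)
  v / sqrt(rowSums(v^2))
}

.randomDescriptors <- function(n, elements) {
  data.frame(element = elements,
             hybridization = sample(1:3, n, TRUE, prob = c(0.2, 0.3, 0.5)),
             n_heavy = sample(0:4, n, TRUE),
             n_hetero = sample(0:2, n, TRUE),
             hydrophobic = stats::runif(n) < 0.5,
             aromatic = stats::runif(n) < 0.3,
             acceptor = stats::runif(n) < 0.3,
             donor = stats::runif(n) < 0.3,
             ring = stats::runif(n) < 0.4,
             partial_charge = stats::runif(n, -0.5, 0.5),
             stringsAsFactors = FALSE)
}

.placeWithRejection <- function(propose, accept, n, max_tries = 500L) {
  out <- matrix(NA_real_, n, 3L)
  for (k in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      x <- propose()
      if (accept(x, out[seq_len(k - 1L), , drop = FALSE])) {
        out[k, ] <- x; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("synthetic geometry rejection failed; try a larger box_size")
  }
  out
}

.minDistTo <- function(x, pts) {
  if (nrow(pts) == 0L) return(Inf)
  sqrt(min(rowSums((pts - matrix(x, nrow(pts), 3L, byrow = TRUE))^2)))
}

#' Generate one synthetic complex
#'
#' Ligand atoms are placed uniformly in a cubic box; protein atoms are placed
#' around them, a target fraction within 5 Angstrom of the ligand (contact
#' shell) and the rest beyond it. A minimum pairwise separation of 1.2
#' Angstrom is enforced by rejection sampling. Elements are drawn from the
#' origin vocabularies with fixed C-dominant frequencies, chemistry
#' descriptors from simple categorical/uniform distributions. The affinity
#' label is the deterministic geometric signal described in
#' \code{\link{syntheticSpec}} plus optional Gaussian noise, clipped to
#' [2, 12] on the pK scale.
#'
#' @param spec a \code{\link{syntheticSpec}}.
#' @return A \linkS4class{MolecularComplex}.
#' @export
generateComplex <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  lig_xyz <- .placeWithRejection(
    propose = function() stats::runif(3L, 0, spec$box_size),
    accept = function(x, placed) .minDistTo(x, placed) >= .MIN_GEN_SEPARATION,
    n = spec$n_ligand)
  n_contact <- round(spec$contact_fraction * spec$n_protein)
  all_placed <- lig_xyz
  place_prot <- function(radii) {
    function() {
      anchor <- lig_xyz[sample.int(nrow(lig_xyz), 1L), ]
      anchor + stats::runif(1L, radii[1L], radii[2L]) * .randomUnitVectors(1L)[1L, ]
    }
  }
  accept_contact <- function(x, placed)
    .minDistTo(x, rbind(all_placed, placed)) >= .MIN_GEN_SEPARATION &&
      .minDistTo(x, lig_xyz) <= 5
  accept_outer <- function(x, placed)
    .minDistTo(x, rbind(all_placed, placed)) >= .MIN_GEN_SEPARATION &&
      .minDistTo(x, lig_xyz) > 5.2
  prot_contact <- .placeWithRejection(place_prot(.CONTACT_SHELL), accept_contact,
                                      n_contact)
  all_placed <- rbind(all_placed, prot_contact)
  prot_outer <- .placeWithRejection(place_prot(.OUTER_SHELL), accept_outer,
                                    spec$n_protein - n_contact)
  prot_xyz <- rbind(prot_contact, prot_outer)

  lig <- .randomDescriptors(spec$n_ligand,
                            sample(names(.LIGAND_FREQ), spec$n_ligand, TRUE,
                                   prob = .LIGAND_FREQ))
  lig$x <- lig_xyz[, 1L]; lig$y <- lig_xyz[, 2L]; lig$z <- lig_xyz[, 3L]
  prot <- .randomDescriptors(spec$n_protein,
                             sample(names(.PROTEIN_FREQ), spec$n_protein, TRUE,
                                    prob = .PROTEIN_FREQ))
  prot$x <- prot_xyz[, 1L]; prot$y <- prot_xyz[, 2L]; prot$z <- prot_xyz[, 3L]

  d <- sqrt(pmax(0, outer(rowSums(prot_xyz^2), rowSums(lig_xyz^2), `+`) -
                   2 * prot_xyz %*% t(lig_xyz)))
  y <- spec$label_weights[1L] * sum(d < spec$contact_scale) +
    spec$label_weights[2L] * mean(1 / d)
  if (spec$noise_sd > 0) y <- y + stats::rnorm(1L, 0, spec$noise_sd)
  y <- min(12, max(2, y))
  MolecularComplex(prot, lig, affinity = y)
}

#' Rigidly transform a complex
#'
#' Maps every coordinate x to R x + t. The rotation must be orthonormal
#' (checked to 1e-8); all non-geometric fields are untouched.
#'
#' @param complex a \linkS4class{MolecularComplex}.
#' @param rotation 3 x 3 orthonormal matrix.
#' @param translation numeric(3).
#' @return The transformed \linkS4class{MolecularComplex}.
#' @export
rigidTransform <- function(complex, rotation, translation = c(0, 0, 0)) {
  stopifnot(is.matrix(rotation), identical(dim(rotation), c(3L, 3L)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthonormal")
  atoms <- atomTable(complex)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(rotation)
  xyz <- sweep(xyz, 2L, translation, `+`)
  atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  initialize(complex, atoms = atoms)
}

#' Random rotation matrix
#'
#' Uniformly distributed proper rotation (via QR of a Gaussian matrix with
#' sign correction), handy for invariance tests.
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Generate a list of synthetic specs with derived seeds
#'
#' @param n number of complexes.
#' @param seed master seed; complex k uses seed \code{seed + k}.
#' @param ... overrides passed to \code{\link{syntheticSpec}}.
#' @return List of \code{SyntheticSpec}.
#' @export
syntheticSpecs <- function(n, seed = 1L, ...) {
  lapply(seq_len(n), function(k) syntheticSpec(..., seed = seed + k))
}

#' Generate a dataset of synthetic complexes and split it
#'
#' Generates one complex per spec and partitions them into disjoint
#' train/validation/test collections by a seeded shuffle. When \code{out} is
#' given, each split is also written in the serialized graph-dataset format
#' (see \code{\link{writeGraphDataset}}) after featurization with the default
#' cutoffs.
#'
#' @param specs list of \code{\link{syntheticSpec}}.
#' @param fractions numeric(3) summing to 1 (default \code{c(0.8, 0.1, 0.1)}).
#' @param seed shuffle seed.
#' @param out optional output directory.
#' @return List with elements \code{train}, \code{val}, \code{test}: lists of
#'   \linkS4class{MolecularComplex}.
#' @export
makeDataset <- function(specs, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                        out = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3L)
  n <- length(specs)
  sizes <- c(floor(fractions[1L] * n), floor(fractions[2L] * n))
  sizes <- c(sizes, n - sum(sizes))
  if (any(sizes == 0L)) stop("a split would be empty; use more complexes")
  complexes <- lapply(specs, generateComplex)
  set.seed(seed)
  perm <- sample.int(n)
  idx <- split(perm, rep.int(c("train", "val", "test"), sizes))
  splits <- list(train = complexes[idx$train],
                 val = complexes[idx$val],
                 test = complexes[idx$test])
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(splits)) {
      records <- lapply(splits[[nm]], featurizeComplex)
      writeGraphDataset(records, file.path(out, paste0(nm, ".json")))
    }
  }
  splits
}
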