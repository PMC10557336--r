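# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; no binary files.

make_atoms <- function(element, x, y, z, hybridization = 3L, n_heavy = 1L,
                       n_hetero = 0L, hydrophobic = FALSE, aromatic = FALSE,
                       acceptor = FALSE, donor = FALSE, ring = FALSE,
                       partial_charge = 0, origin = "ligand") {
  data.frame(element = element, x = x, y = y, z = z,
             hybridization = hybridization, n_heavy = n_heavy,
             n_hetero = n_hetero, hydrophobic = hydrophobic,
             aromatic = aromatic, acceptor = acceptor, donor = donor,
             ring = ring, partial_charge = partial_charge, origin = origin,
             stringsAsFactors = FALSE)
}

small_config <- function(...) {
  defaults <- list(n_layers = 2L, n_heads = 2L, n_domains = 3L, node_dim = 6L,
                   edge_dim = 5L, curv_dim = 4L, dist_dim = 4L, crt_dim = 5L,
                   pipool_dim = 4L, mlp_dims = c(6L, 3L), dropout = 0,
                   n_filtrations = 10L)
  do.call(curvagnConfig, utils::modifyList(defaults, list(...)))
}

small_record <- function(seed = 3L, n_ligand = 4L, n_protein = 12L) {
  cx <- generateComplex(syntheticSpec(n_ligand = n_ligand,
                                      n_protein = n_protein, seed = seed))
  featurizeComplex(cx, filtrations = 0.5 * (0:9))
}

# O(n^2) all-pairs oracle for the interaction-graph edge set
bf_edge_set <- function(xyz, cutoff) {
  n <- nrow(xyz)
  out <- character(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff)
      out <- c(out, paste(i, j))
  }
  sort(out)
}

# brute-force Eq.-style interaction matrix by direct pair enumeration
bf_interaction_matrix <- function(complex, cutoff) {
  a <- atomTable(complex)
  p <- a[a$origin == "protein", ]; l <- a[a$origin == "ligand", ]
  Z <- matrix(0, 4, 9, dimnames = list(proteinElements(), ligandElements()))
  total <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(nrow(l))) {
    d <- sqrt(sum((c(p$x[i], p$y[i], p$z[i]) - c(l$x[j], l$y[j], l$z[j]))^2))
    if (cutoff - d > 0) {
      Z[p$element[i], l$element[j]] <- Z[p$element[i], l$element[j]] + 1
      total <- total + 1
    }
  }
  if (total > 0) Z / total else Z
}

# O(n^3) triangle-enumeration Forman oracle on an adjacency matrix
bf_forman <- function(A, i, j) {
  n <- nrow(A)
  tri <- 0
  for (k in seq_len(n)) if (k != i && k != j && A[i, k] == 1 && A[j, k] == 1)
    tri <- tri + 1
  4 - sum(A[i, ]) - sum(A[j, ]) + 3 * tri
}

# independent exact-LP Wasserstein oracle via boot::simplex
lp_wasserstein <- function(mu, nu, cost) {
  m <- length(mu); n <- length(nu)
  A3 <- matrix(0, m + n, m * n)
  for (i in seq_len(m)) A3[i, (seq_len(n) - 1L) * m + i] <- 1
  for (j in seq_len(n)) A3[m + j, (j - 1L) * m + seq_len(m)] <- 1
  # drop one redundant balance constraint
  res <- boot::simplex(a = as.vector(cost), A3 = A3[-1, , drop = FALSE],
                       b3 = c(mu, nu)[-1], maxi = FALSE)
  unname(res$value)
}

# Ollivier oracle assembled from igraph hop distances + the LP oracle
bf_ollivier <- function(g, i, j, alpha) {
  ni <- as.integer(igraph::neighbors(g, i)); nj <- as.integer(igraph::neighbors(g, j))
  mi <- c(alpha, rep((1 - alpha) / length(ni), length(ni)))
  mj <- c(alpha, rep((1 - alpha) / length(nj), length(nj)))
  D <- igraph::distances(g, v = c(i, ni), to = c(j, nj), weights = NA)
  1 - lp_wasserstein(mi, mj, D) / igraph::distances(g, v = i, to = j, weights = NA)[1, 1]
}

random_connected_graph <- function(n, p, seed) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::ecount(g) > 0 && igraph::is_connected(g)) return(g)
  }
}

# --- tiny hand-written structure files -------------------------------------

write_tiny_pdb <- function(path, with_zn = FALSE) {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       1.988  -0.773  -1.199  1.00  0.00           C",
    "ATOM      6  H   ALA A   1      -0.500   0.800   0.000  1.00  0.00           H")
  if (with_zn)
    lines <- c(lines,
      "HETATM    7 ZN    ZN A   2       5.000   5.000   5.000  1.00  0.00          ZN")
  writeLines(c(lines, "END"), path)
  path
}

write_tiny_mol2 <- function(path, with_h = FALSE) {
  n <- if (with_h) 3L else 2L
  lines <- c("@<TRIPOS>MOLECULE", "tiny",
             sprintf(" %d %d 0 0 0", n, n - 1L),
             "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM",
             "      1 C1          0.0000    0.0000    0.0000 C.3     1 LIG1        0.1000",
             "      2 O1          1.4000    0.0000    0.0000 O.3     1 LIG1       -0.3000")
  if (with_h)
    lines <- c(lines,
             "      3 H1          2.0000    0.8000    0.0000 H       1 LIG1        0.2000")
  lines <- c(lines, "@<TRIPOS>BOND", "     1    1    2 1")
  if (with_h) lines <- c(lines, "     2    2    3 1")
  writeLines(lines, path)
  path
}

write_tiny_sdf <- function(path) {
  writeLines(c(
    "tiny", "  test", "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.4000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.1000    0.9000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0",
    "  2  3  1  0",
    "M  END",
    "$$$$"), path)
  path
}

# Frozen metrics oracle: computed by independent closed-form arithmetic
# (explicit sums of squares and normal-equation line fit), then frozen.
METRICS_ORACLE <- list(
  list(p = c(1, 2, 3, 4, 5), y = c(1.2, 1.9, 3.4, 3.9, 5.5),
       rmse = 0.306594194335, mae = 0.26, r = 0.988111465542,
       sd = 0.260768096208),
  list(p = c(2, 4, 6, 8, 10), y = c(10, 8, 6, 4, 2),
       rmse = 5.656854249492, mae = 4.8, r = -1, sd = 0),
  list(p = c(0.5, 1.5, 2.5, 3.0, 4.5), y = c(2.0, 2.2, 3.1, 4.8, 4.9),
       rmse = 1.140175425099, mae = 1, r = 0.914853278804,
       sd = 0.560230930646))
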