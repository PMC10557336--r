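# Forward computation. Every layer consumes only rotation/translation
# invariant inputs (node chemistry features, edge distances, angles,
# curvature profiles), so predictions are rigid-motion invariant by
# construction. Internal .fw* functions return the layer output together
# with the cache needed by the analytic backward pass; the exported wrappers
# return just the output.

.LRELU_SLOPE <- 0.01

.lrelu <- function(x) ifelse(x > 0, x, .LRELU_SLOPE * x)
.rowSoftmax <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

# aggregate rows of M into `nbuckets` rows by the integer index `idx`
.rowsumAgg <- function(M, idx, nbuckets) {
  out <- matrix(0, nbuckets, ncol(M))
  if (length(idx) > 0L) {
    rs <- rowsum(M, group = idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  out
}

#' Prepare a featurized record for the model
#'
#' Derives every index structure the network needs from a featurized record:
#' the distance one-hot bins, the angle line graph partitioned into domains,
#' and the intermolecular protein-to-ligand edges with their atom-type-pair
#' cell indices. Errors if any edge distance falls outside [0, cutoff] (its
#' one-hot bin would be undefined) or if the curvature profile length does
#' not match the configured filtration count.
#'
#' @param record list with \code{graph} and \code{Z} (see
#'   \code{\link{featurizeComplex}}).
#' @param config a \code{\link{curvagnConfig}}.
#' @return A prepared record (named list) for \code{\link{forwardPass}}.
#' @export
prepareRecord <- function(record, config) {
  g <- record$graph
  e <- graphEdges(g)
  d <- edgeDistances(g)
  if (any(d < 0 | d > config$cutoff))
    stop("edge distance outside [0, cutoff]: one-hot bin undefined")
  prof <- curvatureProfiles(g)
  if (.useCurvature(config) && ncol(prof) != config$n_filtrations)
    stop("curvature profile length ", ncol(prof), " != configured ",
         config$n_filtrations)
  lg <- buildAngleLineGraph(g, config$n_domains, config$exclude_reverse)
  arcs <- lapply(seq_len(config$n_domains), function(q) {
    k <- which(lg@domain == q)
    list(s = lg@arcs[k, 1L], t = lg@arcs[k, 2L])
  })
  atoms <- atomTable(g)
  inter <- which(atoms$origin[e[, 1L]] == "protein" &
                   atoms$origin[e[, 2L]] == "ligand")
  row_k <- match(atoms$element[e[inter, 1L]], proteinElements())
  col_l <- match(atoms$element[e[inter, 2L]], ligandElements())
  list(X = nodeFeatures(g), FC = prof, dist = d,
       bin = as.integer(floor(d)), edges = e, arcs = arcs,
       interE = inter,
       interCell = row_k + (col_l - 1L) * length(proteinElements()),
       y = affinity(g), Zvec = as.numeric(interactionValues(record$Z)),
       n = nrow(atoms), e = nrow(e))
}

.fwCurvatureBlock <- function(FC, bin, params, config) {
  S_pre <- FC %*% t(params$W_f)
  P <- .rowSoftmax(.lrelu(S_pre))
  Demb <- t(params$W_d)[bin + 1L, , drop = FALSE]
  U <- cbind(Demb, P)
  CRT_pre <- U %*% t(params$W_fd)
  list(out = pmax(CRT_pre, 0),
       cache = list(S_pre = S_pre, P = P, U = U, CRT_pre = CRT_pre, bin = bin))
}

.fwNodeToEdge <- function(Hn, crt, edges, W_ab) {
  AB <- cbind(Hn[edges[, 1L], , drop = FALSE],
              Hn[edges[, 2L], , drop = FALSE])
  if (!is.null(crt)) AB <- cbind(AB, crt)
  He_pre <- AB %*% t(W_ab)
  list(out = pmax(He_pre, 0), cache = list(AB = AB, He_pre = He_pre))
}

.fwEdgeToEdge <- function(He, arcs, domains, config) {
  ed <- ncol(He)
  nE <- nrow(He)
  caches <- vector("list", length(arcs))
  blocks <- vector("list", length(arcs))
  for (q in seq_along(arcs)) {
    s <- arcs[[q]]$s; t <- arcs[[q]]$t
    Wq <- domains[[q]]$W; bq <- domains[[q]]$b
    if (length(s) == 0L) {
      blocks[[q]] <- He
      caches[[q]] <- list(empty = TRUE)
      next
    }
    Xarc <- cbind(He[t, , drop = FALSE], He[s, , drop = FALSE])
    lin <- Xarc %*% t(Wq) + matrix(bq, length(s), nrow(Wq), byrow = TRUE)
    if (config$variant == "vanilla-gat") {
      # softmax-normalized scalar attention within each target's domain group
      sc <- drop(lin)
      gmax <- as.numeric(tapply(sc, t, max)[as.character(t)])
      ex <- exp(sc - gmax)
      gsum <- as.numeric(tapply(ex, t, sum)[as.character(t)])
      Alpha <- ex / gsum
      contrib <- Alpha * He[s, , drop = FALSE]
      caches[[q]] <- list(empty = FALSE, Xarc = Xarc, Alpha = Alpha, s = s, t = t)
    } else if (config$variant == "scalar-adaptive") {
      Alpha <- tanh(drop(lin))
      contrib <- Alpha * He[s, , drop = FALSE]
      caches[[q]] <- list(empty = FALSE, Xarc = Xarc, Alpha = Alpha, s = s, t = t)
    } else {
      Alpha <- tanh(lin)
      contrib <- Alpha * He[s, , drop = FALSE]
      caches[[q]] <- list(empty = FALSE, Xarc = Xarc, Alpha = Alpha, s = s, t = t)
    }
    blocks[[q]] <- He + .rowsumAgg(contrib, t, nE)
  }
  list(out = do.call(cbind, blocks), cache = caches)
}

.fwEdgeToNode <- function(Hee, Hn_prev, crt, edges, heads, config) {
  n <- nrow(Hn_prev)
  C <- length(heads)
  Hn_new <- matrix(0, n, config$node_dim)
  caches <- vector("list", C)
  e2 <- edges[, 2L]
  for (cc in seq_len(C)) {
    h <- heads[[cc]]
    Te <- Hee %*% t(h$W_e)
    Ta <- Hn_prev %*% t(h$W_a)
    Bin <- cbind(Te, Ta[e2, , drop = FALSE])
    if (!is.null(crt)) Bin <- cbind(Bin, crt %*% t(h$W_dr))
    bpre <- drop(Bin %*% h$v)
    Beta <- tanh(bpre)
    msg <- Beta * Te
    Hn_new <- Hn_new + (.rowsumAgg(msg, e2, n) + Ta) / C
    caches[[cc]] <- list(Te = Te, Ta = Ta, Bin = Bin, Beta = Beta)
  }
  list(out = Hn_new, cache = caches)
}

.fwPiPool <- function(Hee, interE, interCell, W_h, qvec) {
  ncell <- length(proteinElements()) * length(ligandElements())
  Hsel <- Hee[interE, , drop = FALSE]
  Hp <- Hsel %*% t(W_h)
  cellH <- .rowsumAgg(Hp, interCell, ncell)
  logits <- drop(cellH %*% qvec)
  ex <- exp(logits - max(logits))
  Zt <- ex / sum(ex)
  list(out = Zt, cache = list(Hsel = Hsel, Hp = Hp, cellH = cellH, Zt = Zt))
}

.fwOutputPool <- function(Hn, params) {
  spool <- colSums(Hn)
  z1p <- drop(params$W1 %*% spool + params$b1); z1 <- pmax(z1p, 0)
  z2p <- drop(params$W2 %*% z1 + params$b2); z2 <- pmax(z2p, 0)
  yhat <- drop(params$W3 %*% z2 + params$b3)
  list(out = yhat,
       cache = list(spool = spool, z1p = z1p, z1 = z1, z2p = z2p, z2 = z2))
}

#' Loss: affinity error plus weighted interaction-matrix discrepancy
#'
#' \code{|yhat - y| + lambda * ||flatten(Zt) - flatten(Z)||} per complex,
#' summed over a batch by the training loop. The matrix norm is Euclidean by
#' default, absolute-sum under \code{norm = "l1"}.
#'
#' @param yhat,y predicted and true affinity (pK scale).
#' @param Zt,Z predicted and ground-truth interaction matrices (or their
#'   flattened vectors; shapes must agree).
#' @param lambda trade-off weight.
#' @param norm \code{"l2"} (default) or \code{"l1"}.
#' @return numeric(1).
#' @export
curvagnLoss <- function(yhat, y, Zt, Z, lambda = 1.75, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  if (length(Zt) != length(Z)) stop("Zt and Z shapes differ")
  diff <- as.numeric(Zt) - as.numeric(Z)
  lb <- if (norm == "l2") sqrt(sum(diff^2)) else sum(abs(diff))
  abs(yhat - y) + lambda * lb
}

#' Full forward pass on a prepared record
#'
#' Runs the curvature block, L stacked attention layers (node-to-edge,
#' angle-domain edge-to-edge, multi-head edge-to-node), the interaction
#' pooling and the output pooling. Dropout is applied to node and edge
#' representations after each layer in training mode only; evaluation mode
#' is deterministic.
#'
#' @param prep a \code{\link{prepareRecord}} result.
#' @param params model parameters (\code{\link{initParams}}).
#' @param config a \code{\link{curvagnConfig}}.
#' @param training apply dropout (default FALSE).
#' @param keep_cache retain intermediate values for the backward pass.
#' @return List: \code{yhat} (predicted pK), \code{Zt} (predicted 4 x 9
#'   interaction matrix), and \code{cache} when requested.
#' @export
forwardPass <- function(prep, params, config, training = FALSE,
                        keep_cache = FALSE) {
  use_crt <- .useCurvature(config)
  drop_p <- if (training) config$dropout else 0
  Hn <- prep$X %*% t(params$W_node)
  crt <- NULL; crt_cache <- NULL
  if (use_crt) {
    cb <- .fwCurvatureBlock(prep$FC, prep$bin, params, config)
    crt <- cb$out; crt_cache <- cb$cache
  }
  L <- config$n_layers
  layer_caches <- vector("list", L)
  Hn_in <- vector("list", L)
  Hee <- NULL
  for (l in seq_len(L)) {
    pl <- params$layers[[l]]
    Hn_in[[l]] <- Hn
    n2e <- .fwNodeToEdge(Hn, crt, prep$edges, pl$W_ab)
    e2e <- .fwEdgeToEdge(n2e$out, prep$arcs, pl$domains, config)
    Hee <- e2e$out
    maskE <- NULL
    if (drop_p > 0) {
      maskE <- matrix((stats::runif(length(Hee)) >= drop_p) / (1 - drop_p),
                      nrow(Hee), ncol(Hee))
      Hee <- Hee * maskE
    }
    e2n <- .fwEdgeToNode(Hee, Hn, crt, prep$edges, pl$heads, config)
    Hn <- e2n$out
    maskN <- NULL
    if (drop_p > 0) {
      maskN <- matrix((stats::runif(length(Hn)) >= drop_p) / (1 - drop_p),
                      nrow(Hn), ncol(Hn))
      Hn <- Hn * maskN
    }
    layer_caches[[l]] <- list(n2e = n2e, e2e = e2e, e2n = e2n,
                              He = n2e$out, Hee = Hee,
                              maskE = maskE, maskN = maskN)
  }
  pp <- .fwPiPool(Hee, prep$interE, prep$interCell, params$W_h, params$q)
  op <- .fwOutputPool(Hn, params)
  Zt <- matrix(pp$out, length(proteinElements()), length(ligandElements()),
               dimnames = list(proteinElements(), ligandElements()))
  res <- list(yhat = op$out, Zt = Zt)
  if (keep_cache)
    res$cache <- list(crt = crt, crt_cache = crt_cache, Hn_in = Hn_in,
                      Hn_out = Hn, layers = layer_caches, pp = pp, op = op)
  res
}

#' Individual layer operations
#'
#' Matrix-level entry points for the network's layers, mainly useful for
#' inspection and testing; \code{\link{forwardPass}} composes them.
#' \code{nodeToEdge} fuses the two endpoint representations (and the
#' curvature-block context, when given) into a directed-edge representation;
#' \code{edgeToEdge} runs the angle-domain adaptive attention and returns the
#' N concatenated domain aggregates; \code{edgeToNode} aggregates incoming
#' edge representations into node representations with C-head tanh
#' attention; \code{piPool} pools intermolecular protein-to-ligand edge
#' representations into the predicted 4 x 9 interaction table;
#' \code{outputPool} sum-pools node representations and applies the MLP.
#'
#' @param Hn,Hn_prev node representation matrix (nodes x dim).
#' @param He,Hee edge representation matrices.
#' @param crt curvature-block context (edges x dim) or NULL.
#' @param edges directed edge index matrix.
#' @param W_ab,W_h,qvec parameter matrices (see \code{\link{initParams}}).
#' @param arcs per-domain arc lists, as built by \code{\link{prepareRecord}}.
#' @param domains,heads per-layer parameter sublists.
#' @param config a \code{\link{curvagnConfig}}.
#' @param interE,interCell intermolecular edge indices and their cell indices.
#' @param params for \code{outputPool}: the MLP parameters
#'   (\code{W1,b1,W2,b2,W3,b3}).
#' @return The layer output (matrix, vector or scalar; see above).
#' @name layers
NULL

#' @rdname layers
#' @export
nodeToEdge <- function(Hn, crt, edges, W_ab)
  .fwNodeToEdge(Hn, crt, edges, W_ab)$out

#' @rdname layers
#' @export
edgeToEdge <- function(He, arcs, domains, config)
  .fwEdgeToEdge(He, arcs, domains, config)$out

#' @rdname layers
#' @export
edgeToNode <- function(Hee, Hn_prev, crt, edges, heads, config)
  .fwEdgeToNode(Hee, Hn_prev, crt, edges, heads, config)$out

#' @rdname layers
#' @export
piPool <- function(Hee, interE, interCell, W_h, qvec) {
  out <- .fwPiPool(Hee, interE, interCell, W_h, qvec)$out
  matrix(out, length(proteinElements()), length(ligandElements()),
         dimnames = list(proteinElements(), ligandElements()))
}

#' @rdname layers
#' @export
outputPool <- function(Hn, params) .fwOutputPool(Hn, params)$out

#' @rdname layers
#' @param FC curvature profile matrix (edges x filtrations).
#' @param bin integer distance bins (floor of the edge distance).
#' @export
curvatureBlock <- function(FC, bin, params, config)
  .fwCurvatureBlock(FC, bin, params, config)$out
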