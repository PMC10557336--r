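# Model configuration and parameter initialization.
#
# Default hyper-parameters: 4 stacked attention layers, 8 heads, 6 angle
# domains, 128-dimensional node/edge/curvature/distance embeddings, dropout
# 0.2, loss trade-off lambda = 1.75, Adam with learning rate 0.001 and batch
# size 32, graph cutoff 5 A with 50 filtration values and interaction cutoff
# 12 A. Ablation variants: "no-curvature" removes the curvature-block context
# from the message passing entirely; "vanilla-gat" replaces the adaptive
# (per-attribute tanh) edge attention by softmax-normalized scalar attention;
# "scalar-adaptive" collapses the attention vector to a scalar.

#' Model configuration
#'
#' @param n_layers number of stacked attention layers L (default 4).
#' @param n_heads attention heads C in the edge-to-node layer (default 8).
#' @param n_domains angle domains N (default 6).
#' @param node_dim,edge_dim node/edge embedding dimensions (default 128).
#' @param curv_dim multiscale-curvature embedding dimension (default 128).
#' @param dist_dim distance embedding dimension n_w (default 128).
#' @param crt_dim curvature-block output dimension (default 128).
#' @param pipool_dim shared projection dimension of the interaction pooling
#'   (default 128).
#' @param mlp_dims hidden widths of the output MLP (default \code{c(128, 64)}).
#' @param dropout dropout rate on node and edge representations after each
#'   layer, in [0, 1) (default 0.2).
#' @param lambda trade-off between affinity loss and interaction-matrix loss
#'   (default 1.75).
#' @param loss_norm norm for the interaction-matrix loss: \code{"l2"}
#'   (default) or \code{"l1"}.
#' @param variant \code{"full"} (default), \code{"no-curvature"},
#'   \code{"vanilla-gat"} or \code{"scalar-adaptive"}.
#' @param cutoff graph cutoff d, Angstrom (default 5); the distance one-hot
#'   has \code{floor(cutoff) + 1} bins (integer parts 0..floor(cutoff)).
#' @param rho interaction-matrix cutoff, Angstrom (default 12).
#' @param n_filtrations length of the curvature filtration grid (default 50).
#' @param curvature_kind \code{"forman"} (default) or \code{"ollivier"}.
#' @param exclude_reverse drop backtracking line-graph arcs (default TRUE).
#' @param lr,batch_size Adam learning rate and batch size (defaults 0.001, 32).
#' @return A \code{CurvagnConfig} (named list).
#' @export
curvagnConfig <- function(n_layers = 4L, n_heads = 8L, n_domains = 6L,
                          node_dim = 128L, edge_dim = 128L, curv_dim = 128L,
                          dist_dim = 128L, crt_dim = 128L, pipool_dim = 128L,
                          mlp_dims = c(128L, 64L), dropout = 0.2,
                          lambda = 1.75, loss_norm = c("l2", "l1"),
                          variant = c("full", "no-curvature", "vanilla-gat",
                                      "scalar-adaptive"),
                          cutoff = 5, rho = 12, n_filtrations = 50L,
                          curvature_kind = c("forman", "ollivier"),
                          exclude_reverse = TRUE, lr = 0.001,
                          batch_size = 32L) {
  variant <- match.arg(variant)
  loss_norm <- match.arg(loss_norm)
  curvature_kind <- match.arg(curvature_kind)
  stopifnot(n_layers >= 1L, n_heads >= 1L, n_domains >= 1L,
            node_dim > 0L, edge_dim > 0L, curv_dim > 0L, dist_dim > 0L,
            crt_dim > 0L, pipool_dim > 0L, all(mlp_dims > 0L),
            dropout >= 0, dropout < 1, lambda >= 0, cutoff > 0,
            n_filtrations >= 1L, lr > 0, batch_size >= 1L)
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 n_domains = as.integer(n_domains),
                 node_dim = as.integer(node_dim),
                 edge_dim = as.integer(edge_dim),
                 curv_dim = as.integer(curv_dim),
                 dist_dim = as.integer(dist_dim),
                 crt_dim = as.integer(crt_dim),
                 pipool_dim = as.integer(pipool_dim),
                 mlp_dims = as.integer(mlp_dims),
                 n_bins = as.integer(floor(cutoff)) + 1L,
                 dropout = dropout, lambda = lambda,
                 loss_norm = loss_norm, variant = variant,
                 cutoff = cutoff, rho = rho,
                 n_filtrations = as.integer(n_filtrations),
                 curvature_kind = curvature_kind,
                 exclude_reverse = isTRUE(exclude_reverse),
                 lr = lr, batch_size = as.integer(batch_size)),
            class = "CurvagnConfig")
}

.glorot <- function(nout, nin) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
}

.useCurvature <- function(config) config$variant != "no-curvature"

.attnRows <- function(config) {
  # rows of the edge2edge attention map: one per attribute (adaptive vector
  # attention) or a single row (scalar/vanilla variants)
  if (config$variant %in% c("vanilla-gat", "scalar-adaptive")) 1L
  else config$edge_dim
}

#' Initialize model parameters
#'
#' Glorot-uniform matrices and zero biases under a fixed seed.
#'
#' @param config a \code{\link{curvagnConfig}}.
#' @param seed integer RNG seed.
#' @return Nested parameter list (the model state).
#' @export
initParams <- function(config, seed = 1L) {
  set.seed(seed)
  nd <- config$node_dim; ed <- config$edge_dim; cd <- config$crt_dim
  use_crt <- .useCurvature(config)
  ab_in <- 2L * nd + if (use_crt) cd else 0L
  v_in <- 2L * nd + if (use_crt) nd else 0L
  p <- list(W_node = .glorot(nd, 36L))
  if (use_crt) {
    p$W_f <- .glorot(config$curv_dim, config$n_filtrations)
    p$W_d <- .glorot(config$dist_dim, config$n_bins)
    p$W_fd <- .glorot(cd, config$dist_dim + config$curv_dim)
  }
  p$layers <- lapply(seq_len(config$n_layers), function(l) {
    list(W_ab = .glorot(ed, ab_in),
         domains = lapply(seq_len(config$n_domains), function(q)
           list(W = .glorot(.attnRows(config), 2L * ed),
                b = matrix(0, .attnRows(config), 1L))),
         heads = lapply(seq_len(config$n_heads), function(cc) {
           h <- list(W_e = .glorot(nd, config$n_domains * ed),
                     W_a = .glorot(nd, nd),
                     v = .glorot(v_in, 1L))
           if (use_crt) h$W_dr <- .glorot(nd, cd)
           h
         }))
  })
  p$W_h <- .glorot(config$pipool_dim, config$n_domains * ed)
  p$q <- .glorot(config$pipool_dim, 1L)
  m1 <- config$mlp_dims[1L]; m2 <- config$mlp_dims[2L]
  p$W1 <- .glorot(m1, nd); p$b1 <- matrix(0, m1, 1L)
  p$W2 <- .glorot(m2, m1); p$b2 <- matrix(0, m2, 1L)
  p$W3 <- .glorot(1L, m2); p$b3 <- matrix(0, 1L, 1L)
  p
}

# recursive map over parallel parameter structures (names preserved)
.paramMap <- function(f, a, b = NULL) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(k)
      .paramMap(f, a[[k]], if (!is.null(b)) b[[k]]))
    names(out) <- names(a)
    return(out)
  }
  if (is.null(b)) f(a) else f(a, b)
}

.zeroLike <- function(p) .paramMap(function(x) x * 0, p)

.paramFinite <- function(p) {
  ok <- TRUE
  rapply(p, function(x) { if (!all(is.finite(x))) ok <<- FALSE; NULL },
         how = "unlist")
  ok
}

#' CurvAGN model object
#'
#' Bundles a configuration with its parameter state.
#'
#' @slot config a \code{\link{curvagnConfig}} list.
#' @slot params nested parameter list (see \code{\link{initParams}}).
#' @export
setClass("CurvAGNModel", representation(config = "list", params = "list"))

#' @rdname CurvAGNModel-class
#' @param config a \code{\link{curvagnConfig}}.
#' @param seed RNG seed for initialization.
#' @return A \linkS4class{CurvAGNModel}.
#' @export
curvagnModel <- function(config = curvagnConfig(), seed = 1L) {
  new("CurvAGNModel", config = unclass(config),
      params = initParams(config, seed = seed))
}

setMethod("show", "CurvAGNModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "CurvAGNModel (%s): L=%d layers, C=%d heads, N=%d angle domains,\n  node/edge dims %d/%d, dropout %.2f, lambda %.2f\n",
    cfg$variant, cfg$n_layers, cfg$n_heads, cfg$n_domains,
    cfg$node_dim, cfg$edge_dim, cfg$dropout, cfg$lambda))
})

.CHECKPOINT_SCHEMA <- "curvagn-checkpoint-v1"

#' Save or load a model checkpoint
#'
#' A checkpoint is a single JSON file holding the schema tag, the full
#' configuration and every parameter array at full precision.
#'
#' @param model a \linkS4class{CurvAGNModel}.
#' @param path file path.
#' @return \code{loadCheckpoint}: the restored \linkS4class{CurvAGNModel}.
#' @export
saveCheckpoint <- function(model, path) {
  flat <- .flattenParams(model@params)
  payload <- lapply(flat, function(x)
    list(nrow = nrow(x), ncol = ncol(x), values = as.numeric(x)))
  jsonlite::write_json(list(schema = .CHECKPOINT_SCHEMA,
                            config = model@config, params = payload),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

# flatten a nested parameter list into "a/b/c"-keyed matrices
.flattenParams <- function(p, prefix = "") {
  if (!is.list(p)) {
    out <- list(p); names(out) <- prefix
    return(out)
  }
  out <- list()
  for (k in seq_along(p)) {
    nm <- if (!is.null(names(p)) && nzchar(names(p)[k])) names(p)[k]
    else as.character(k)
    key <- if (nzchar(prefix)) paste(prefix, nm, sep = "/") else nm
    out <- c(out, .flattenParams(p[[k]], key))
  }
  out
}

.assignPath <- function(target, path, value) {
  key <- path[1L]
  idx <- if (grepl("^[0-9]+$", key)) as.integer(key) else key
  if (length(path) == 1L) target[[idx]] <- value
  else target[[idx]] <- .assignPath(target[[idx]], path[-1L], value)
  target
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$schema, .CHECKPOINT_SCHEMA))
    stop("unrecognized checkpoint schema in ", path)
  raw <- lapply(payload$config, function(x)
    if (is.list(x)) unlist(x) else x)
  # re-run the constructor so every field gets its canonical type
  cfg <- unclass(do.call(curvagnConfig, raw[setdiff(names(raw), "n_bins")]))
  params <- initParams(cfg, seed = 1L)  # template for the nested shape
  for (key in names(payload$params)) {
    leaf <- payload$params[[key]]
    m <- matrix(vapply(leaf$values, as.numeric, 0), leaf$nrow, leaf$ncol)
    params <- .assignPath(params, strsplit(key, "/", fixed = TRUE)[[1L]], m)
  }
  new("CurvAGNModel", config = cfg, params = params)
}
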