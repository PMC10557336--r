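test_that("curvature block embeddings are softmax-normalized and bins floor", {
  cfg <- small_config()
  p <- initParams(cfg, seed = 4)
  rec <- small_record(seed = 3)
  prep <- prepareRecord(rec, cfg)
  cb <- curvagn:::.fwCurvatureBlock(prep$FC, prep$bin, p, cfg)
  expect_true(all(cb$cache$P > 0))
  expect_equal(rowSums(cb$cache$P), rep(1, nrow(prep$FC)))
  expect_identical(prep$bin, as.integer(floor(prep$dist)))
  # distance 3.7 with bins 0..5 -> single 1 at slot index 3 (0-based)
  expect_identical(as.integer(floor(3.7)), 3L)
  # straight-line recomputation of the composed block for one edge
  r <- 5L
  f <- as.numeric(exp_softmax <- {
    s <- p$W_f %*% prep$FC[r, ]
    s <- ifelse(s > 0, s, 0.01 * s)
    exp(s - max(s)) / sum(exp(s - max(s)))
  })
  d <- p$W_d[, prep$bin[r] + 1L]
  crt_manual <- pmax(p$W_fd %*% c(d, f), 0)
  expect_equal(as.numeric(cb$out[r, ]), as.numeric(crt_manual), tolerance = 1e-12)
})

test_that("curvature block rejects distances outside the one-hot range", {
  cfg <- small_config()
  rec <- small_record(seed = 3)
  rec$graph@edgeDistance[1] <- 7.2  # beyond cutoff 5
  expect_error(prepareRecord(rec, cfg), "one-hot bin undefined")
})

test_that("node2edge is a directed ReLU fusion of endpoint features", {
  cfg <- small_config()
  rec <- small_record(seed = 3)
  prep <- prepareRecord(rec, cfg)
  nd <- cfg$node_dim
  set.seed(5)
  Hn <- matrix(rnorm(prep$n * nd), prep$n, nd)
  crt <- matrix(rnorm(prep$e * cfg$crt_dim), prep$e, cfg$crt_dim)
  W0 <- matrix(0, cfg$edge_dim, 2 * nd + cfg$crt_dim)
  expect_equal(nodeToEdge(Hn, crt, prep$edges, W0),
               matrix(0, prep$e, cfg$edge_dim))
  W <- matrix(rnorm(length(W0), sd = 0.3), nrow(W0), ncol(W0))
  He <- nodeToEdge(Hn, crt, prep$edges, W)
  # direct per-edge recomputation
  r <- 3L
  i <- prep$edges[r, 1]; j <- prep$edges[r, 2]
  expect_equal(as.numeric(He[r, ]),
               as.numeric(pmax(W %*% c(Hn[i, ], Hn[j, ], crt[r, ]), 0)),
               tolerance = 1e-12)
  # concatenation order matters: swapping endpoints changes the output
  He_sw <- nodeToEdge(Hn, crt, prep$edges[, 2:1, drop = FALSE], W)
  expect_false(isTRUE(all.equal(He, He_sw)))
})

test_that("line-graph arcs carry correct angles and domains", {
  # collinear chain a-b-c: the arc (e_ab -> e_bc) has angle 180, domain N
  lig <- make_atoms(c("C", "C"), x = c(0, 2), y = 0, z = 0)
  prot <- make_atoms("C", x = 4, y = 0, z = 0, origin = "protein")
  g <- buildInteractionGraph(MolecularComplex(prot, lig), cutoff = 2.5)
  lg <- buildAngleLineGraph(g, nDomains = 6)
  e <- graphEdges(g)
  xs <- coords(g)[, 1]
  a <- which(xs == 0); b <- which(xs == 2); cc <- which(xs == 4)
  eab <- which(e[, 1] == a & e[, 2] == b)
  ebc <- which(e[, 1] == b & e[, 2] == cc)
  arc <- which(lg@arcs[, 1] == eab & lg@arcs[, 2] == ebc)
  expect_length(arc, 1L)
  expect_equal(lg@angle[arc], 180)
  expect_identical(lg@domain[arc], 6L)
  # right angle at the shared atom: 90 degrees lies in (60, 90], domain 3 of 6
  lig2 <- make_atoms(c("C", "C"), x = c(0, 2), y = 0, z = 0)
  prot2 <- make_atoms("C", x = 2, y = 2, z = 0, origin = "protein")
  g2 <- buildInteractionGraph(MolecularComplex(prot2, lig2), cutoff = 2.5)
  lg2 <- buildAngleLineGraph(g2, nDomains = 6)
  expect_true(any(abs(lg2@angle - 90) < 1e-9))
  expect_identical(unique(lg2@domain[abs(lg2@angle - 90) < 1e-9]), 3L)
})

test_that("arc angles match the arccos oracle on random geometry", {
  rec <- small_record(seed = 19)
  g <- rec$graph
  lg <- buildAngleLineGraph(g, nDomains = 6)
  e <- graphEdges(g); xyz <- coords(g)
  set.seed(20)
  for (r in sample(nrow(lg@arcs), min(25, nrow(lg@arcs)))) {
    s <- lg@arcs[r, 1]; t <- lg@arcs[r, 2]
    i <- e[t, 1]; j <- e[t, 2]; k <- e[s, 1]
    expect_identical(e[s, 2], i)     # arc source points into the target's source
    expect_false(k == j)             # reverse-edge exclusion
    u <- xyz[k, ] - xyz[i, ]; v <- xyz[j, ] - xyz[i, ]
    ang <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    expect_equal(lg@angle[r], ang, tolerance = 1e-9)
    q <- lg@domain[r]
    expect_true(ang <= 30 * q + 1e-9 && (q == 1 || ang > 30 * (q - 1) - 1e-9))
  }
})

test_that("zeroed attention reduces edge2edge to the N-fold repeated residual", {
  cfg <- small_config()
  rec <- small_record(seed = 3)
  prep <- prepareRecord(rec, cfg)
  set.seed(6)
  He <- matrix(rnorm(prep$e * cfg$edge_dim), prep$e, cfg$edge_dim)
  domains <- lapply(seq_len(cfg$n_domains), function(q)
    list(W = matrix(0, cfg$edge_dim, 2 * cfg$edge_dim),
         b = matrix(0, cfg$edge_dim, 1)))
  out <- edgeToEdge(He, prep$arcs, domains, cfg)
  expect_identical(out, cbind(He, He, He))
  # an edge with no incoming arcs in any domain also gets the pure residual
  # under nonzero parameters
  p <- initParams(cfg, seed = 7)
  out2 <- edgeToEdge(He, prep$arcs, p$layers[[1]]$domains, cfg)
  in_any <- unique(unlist(lapply(prep$arcs, `[[`, "t")))
  lonely <- setdiff(seq_len(prep$e), in_any)
  for (r in lonely)
    expect_identical(out2[r, ], rep(He[r, ], cfg$n_domains))
})

test_that("edge2edge matches direct per-arc summation", {
  cfg <- small_config()
  rec <- small_record(seed = 3)
  prep <- prepareRecord(rec, cfg)
  p <- initParams(cfg, seed = 8)
  set.seed(9)
  He <- matrix(rnorm(prep$e * cfg$edge_dim), prep$e, cfg$edge_dim)
  out <- edgeToEdge(He, prep$arcs, p$layers[[1]]$domains, cfg)
  ed <- cfg$edge_dim
  for (q in seq_len(cfg$n_domains)) {
    arcs <- prep$arcs[[q]]
    dom <- p$layers[[1]]$domains[[q]]
    for (r in sample(prep$e, 5)) {
      m <- He[r, ]
      hit <- which(arcs$t == r)
      for (h in hit) {
        s <- arcs$s[h]
        alpha <- tanh(dom$W %*% c(He[r, ], He[s, ]) + dom$b)
        m <- m + as.numeric(alpha) * He[s, ]
      }
      expect_equal(out[r, (q - 1) * ed + seq_len(ed)], m, tolerance = 1e-10)
    }
  }
})

test_that("zeroed attention reduces edge2node to the head-averaged projection", {
  cfg <- small_config()
  rec <- small_record(seed = 3)
  prep <- prepareRecord(rec, cfg)
  p <- initParams(cfg, seed = 10)
  heads <- p$layers[[1]]$heads
  for (cc in seq_along(heads)) heads[[cc]]$v <- heads[[cc]]$v * 0
  set.seed(11)
  Hee <- matrix(rnorm(prep$e * cfg$n_domains * cfg$edge_dim),
                prep$e, cfg$n_domains * cfg$edge_dim)
  Hn <- matrix(rnorm(prep$n * cfg$node_dim), prep$n, cfg$node_dim)
  crt <- matrix(rnorm(prep$e * cfg$crt_dim), prep$e, cfg$crt_dim)
  out <- edgeToNode(Hee, Hn, crt, prep$edges, heads, cfg)
  manual <- Reduce(`+`, lapply(heads, function(h) Hn %*% t(h$W_a))) /
    length(heads)
  expect_equal(out, manual, tolerance = 1e-12)
  # C identical heads equal the single-head layer
  same <- lapply(seq_len(2), function(k) p$layers[[1]]$heads[[1]])
  out_multi <- edgeToNode(Hee, Hn, crt, prep$edges, same, cfg)
  out_single <- edgeToNode(Hee, Hn, crt, prep$edges, same[1], cfg)
  expect_equal(out_multi, out_single, tolerance = 1e-12)
})

test_that("edge2node matches direct recomputation with two heads", {
  cfg <- small_config()
  rec <- small_record(seed = 3)
  prep <- prepareRecord(rec, cfg)
  p <- initParams(cfg, seed = 12)
  heads <- p$layers[[1]]$heads
  set.seed(13)
  Hee <- matrix(rnorm(prep$e * cfg$n_domains * cfg$edge_dim),
                prep$e, cfg$n_domains * cfg$edge_dim)
  Hn <- matrix(rnorm(prep$n * cfg$node_dim), prep$n, cfg$node_dim)
  crt <- matrix(rnorm(prep$e * cfg$crt_dim), prep$e, cfg$crt_dim)
  out <- edgeToNode(Hee, Hn, crt, prep$edges, heads, cfg)
  for (jnode in sample(prep$n, 4)) {
    acc <- rep(0, cfg$node_dim)
    for (h in heads) {
      ta <- as.numeric(h$W_a %*% Hn[jnode, ])
      contr <- ta
      for (r in which(prep$edges[, 2] == jnode)) {
        te <- as.numeric(h$W_e %*% Hee[r, ])
        beta <- tanh(sum(h$v * c(te, ta, as.numeric(h$W_dr %*% crt[r, ]))))
        contr <- contr + beta * te
      }
      acc <- acc + contr / length(heads)
    }
    expect_equal(out[jnode, ], acc, tolerance = 1e-10)
  }
})

test_that("interaction pooling is a probability table and matches enumeration", {
  cfg <- small_config()
  rec <- small_record(seed = 3)
  prep <- prepareRecord(rec, cfg)
  p <- initParams(cfg, seed = 14)
  set.seed(15)
  Hee <- matrix(rnorm(prep$e * cfg$n_domains * cfg$edge_dim),
                prep$e, cfg$n_domains * cfg$edge_dim)
  # zero pooled representations -> uniform table 1/36
  Zt0 <- piPool(Hee, prep$interE, prep$interCell, p$W_h * 0, p$q)
  expect_equal(as.numeric(Zt0), rep(1 / 36, 36))
  Zt <- piPool(Hee, prep$interE, prep$interCell, p$W_h, p$q)
  expect_true(all(Zt > 0))
  expect_equal(sum(Zt), 1)
  # direct cell-wise summation oracle
  h <- matrix(0, 36, cfg$pipool_dim)
  for (k in seq_along(prep$interE))
    h[prep$interCell[k], ] <- h[prep$interCell[k], ] +
      as.numeric(p$W_h %*% Hee[prep$interE[k], ])
  logits <- h %*% p$q
  expect_equal(as.numeric(Zt), as.numeric(exp(logits) / sum(exp(logits))),
               tolerance = 1e-10)
})

test_that("interaction pooling sees only protein-to-ligand edges, by type", {
  # complex with exactly one C(protein)-N(ligand) contact pair
  prot <- make_atoms("C", 0, 0, 0, origin = "protein")
  lig <- make_atoms("N", 0, 0, 3)
  rec <- featurizeComplex(MolecularComplex(prot, lig, affinity = 5),
                          filtrations = c(1, 4))
  cfg <- small_config(n_filtrations = 2L)
  prep <- prepareRecord(rec, cfg)
  expect_length(prep$interE, 1L)
  e <- prep$edges[prep$interE, ]
  a <- atomTable(rec$graph)
  expect_identical(a$origin[e[1]], "protein")
  expect_identical(a$origin[e[2]], "ligand")
  # cell index = (row C = 1, col N = 2) -> 1 + (2-1)*4 = 5
  expect_identical(prep$interCell, 5L)
})

test_that("output pooling is permutation invariant and zero-preserving", {
  cfg <- small_config()
  p <- initParams(cfg, seed = 16)
  mlp <- p[c("W1", "b1", "W2", "b2", "W3", "b3")]
  set.seed(17)
  Hn <- matrix(rnorm(9 * cfg$node_dim), 9, cfg$node_dim)
  y1 <- outputPool(Hn, mlp)
  y2 <- outputPool(Hn[sample(9), ], mlp)
  expect_identical(y1, y2)
  zero_mlp <- lapply(mlp, function(x) x * 0)
  expect_identical(outputPool(Hn, zero_mlp), 0)
  # manual affine chain
  s <- colSums(Hn)
  z1 <- pmax(mlp$W1 %*% s + mlp$b1, 0)
  z2 <- pmax(mlp$W2 %*% z1 + mlp$b2, 0)
  expect_equal(y1, as.numeric(mlp$W3 %*% z2 + mlp$b3), tolerance = 1e-12)
})

test_that("the joint loss combines L1 affinity and matrix norms as written", {
  Z <- matrix(1 / 36, 4, 9)
  expect_identical(curvagnLoss(5, 5, Z, Z, lambda = 1.75), 0)
  Zt <- Z; Zt[1, 1] <- Z[1, 1] + 0.1; Zt[2, 2] <- Z[2, 2] - 0.1
  expect_equal(curvagnLoss(4, 5, Zt, Z, lambda = 0), 1)
  expect_equal(curvagnLoss(4, 5, Zt, Z, lambda = 2),
               1 + 2 * sqrt(0.02), tolerance = 1e-12)
  expect_equal(curvagnLoss(4, 5, Zt, Z, lambda = 2, norm = "l1"),
               1 + 2 * 0.2, tolerance = 1e-12)
  # batch of two complexes, summed by hand
  batch <- curvagnLoss(4, 5, Zt, Z, 2) + curvagnLoss(7.5, 7, Z, Z, 2)
  expect_equal(batch, 1 + 2 * sqrt(0.02) + 0.5, tolerance = 1e-12)
  expect_error(curvagnLoss(1, 1, Z[1:2, ], Z), "shapes differ")
})

test_that("evaluation-mode forward passes are bit-identical", {
  cfg <- small_config()
  rec <- small_record(seed = 3)
  prep <- prepareRecord(rec, cfg)
  p <- initParams(cfg, seed = 18)
  f1 <- forwardPass(prep, p, cfg)
  f2 <- forwardPass(prep, p, cfg)
  expect_identical(f1$yhat, f2$yhat)
  expect_identical(f1$Zt, f2$Zt)
})

test_that("model outputs are invariant under rigid motion", {
  cfg <- small_config()
  cx <- generateComplex(syntheticSpec(n_ligand = 4L, n_protein = 12L, seed = 23))
  rec <- featurizeComplex(cx, filtrations = 0.5 * (0:9))
  p <- initParams(cfg, seed = 19)
  f0 <- forwardPass(prepareRecord(rec, cfg), p, cfg)
  set.seed(24)
  for (k in 1:3) {
    cx2 <- rigidTransform(cx, randomRotation(), rnorm(3, sd = 20))
    rec2 <- featurizeComplex(cx2, filtrations = 0.5 * (0:9))
    f2 <- forwardPass(prepareRecord(rec2, cfg), p, cfg)
    expect_equal(f2$yhat, f0$yhat, tolerance = 1e-5)
    expect_equal(f2$Zt, f0$Zt, tolerance = 1e-5)
  }
})

test_that("analytic gradients match finite differences", {
  rec <- small_record(seed = 3)
  for (variant in c("full", "vanilla-gat")) {
    cfg <- small_config(variant = variant)
    prep <- prepareRecord(rec, cfg)
    p <- initParams(cfg, seed = 20)
    fw <- forwardPass(prep, p, cfg, keep_cache = TRUE)
    bk <- curvagn:::.backwardPass(prep, p, cfg, fw)
    lossAt <- function(pp) {
      f <- forwardPass(prep, pp, cfg)
      curvagnLoss(f$yhat, prep$y, as.numeric(f$Zt), prep$Zvec,
                  cfg$lambda, cfg$loss_norm)
    }
    eps <- 1e-5
    probe <- list(list("W_node"), list("W_f"), list("layers", 1L, "W_ab"),
                  list("layers", 2L, "domains", 2L, "W"),
                  list("layers", 1L, "heads", 2L, "W_e"),
                  list("layers", 2L, "heads", 1L, "v"),
                  list("W_h"), list("q"), list("W1"), list("W3"))
    if (variant != "full") probe <- probe[-2]
    set.seed(21)
    for (path in probe) {
      leaf <- p; g <- bk$grads
      for (k in path) { leaf <- leaf[[k]]; g <- g[[k]] }
      i <- sample(length(leaf), 1)
      set_leaf <- function(val) {
        pp <- p
        expr <- paste0("pp", paste0("[[", vapply(path, function(k)
          if (is.character(k)) paste0("'", k, "'") else as.character(k), ""),
          "]]", collapse = ""))
        lf <- leaf; lf[i] <- val
        eval(parse(text = paste(expr, "<- lf")))
        pp
      }
      num <- (lossAt(set_leaf(leaf[i] + eps)) -
                lossAt(set_leaf(leaf[i] - eps))) / (2 * eps)
      denom <- max(1e-4, abs(num) + abs(g[i]))
      expect_lt(abs(num - g[i]) / denom, 1e-3)
    }
  }
})

test_that("the no-curvature ablation ignores curvature; the full model does not", {
  rec <- small_record(seed = 3)
  perturbed <- rec
  set.seed(25)
  perturbed$graph@curvatureProfiles <-
    rec$graph@curvatureProfiles +
    matrix(rnorm(length(rec$graph@curvatureProfiles)),
           nrow(rec$graph@curvatureProfiles))
  cfg_nc <- small_config(variant = "no-curvature")
  p_nc <- initParams(cfg_nc, seed = 26)
  f1 <- forwardPass(prepareRecord(rec, cfg_nc), p_nc, cfg_nc)
  f2 <- forwardPass(prepareRecord(perturbed, cfg_nc), p_nc, cfg_nc)
  expect_identical(f1$yhat, f2$yhat)
  expect_identical(f1$Zt, f2$Zt)
  cfg_full <- small_config()
  p_full <- initParams(cfg_full, seed = 27)
  g1 <- forwardPass(prepareRecord(rec, cfg_full), p_full, cfg_full)
  g2 <- forwardPass(prepareRecord(perturbed, cfg_full), p_full, cfg_full)
  expect_false(identical(g1$yhat, g2$yhat))
  expect_false(identical(g1$Zt, g2$Zt))
})

test_that("checkpoints round-trip config and parameters exactly", {
  cfg <- small_config()
  model <- curvagnModel(cfg, seed = 30)
  path <- tempfile(fileext = ".json")
  saveCheckpoint(model, path)
  back <- loadCheckpoint(path)
  expect_equal(back@config, model@config)
  expect_equal(back@params, model@params, tolerance = 1e-12)
  rec <- small_record(seed = 3)
  expect_equal(predictAffinity(back, list(rec)),
               predictAffinity(model, list(rec)), tolerance = 1e-10)
})
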