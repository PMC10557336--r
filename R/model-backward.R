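# Analytic gradients, mirroring forwardPass step by step in reverse. Each
# block consumes the cache its forward twin produced; correctness is pinned
# by finite-difference checks in the test suite.

.backwardPass <- function(prep, params, config, fw) {
  cache <- fw$cache
  use_crt <- .useCurvature(config)
  grads <- .zeroLike(params)
  nd <- config$node_dim; ed <- config$edge_dim
  n <- prep$n; nE <- prep$e
  e1 <- prep$edges[, 1L]; e2 <- prep$edges[, 2L]

  # ---- loss ----
  Ztv <- as.numeric(fw$Zt)
  diff <- Ztv - prep$Zvec
  if (config$loss_norm == "l2") {
    lb <- sqrt(sum(diff^2))
    dZt <- if (lb > 1e-12) config$lambda * diff / lb else rep(0, length(diff))
  } else {
    lb <- sum(abs(diff))
    dZt <- config$lambda * sign(diff)
  }
  la <- abs(fw$yhat - prep$y)
  dy <- sign(fw$yhat - prep$y)
  loss <- la + config$lambda * lb

  # ---- output pooling ----
  opc <- cache$op$cache
  grads$W3 <- grads$W3 + dy * matrix(opc$z2, 1L)
  grads$b3 <- grads$b3 + dy
  dz2p <- as.numeric(params$W3) * dy * (opc$z2p > 0)
  grads$W2 <- grads$W2 + outer(dz2p, opc$z1)
  grads$b2 <- grads$b2 + dz2p
  dz1p <- drop(t(params$W2) %*% dz2p) * (opc$z1p > 0)
  grads$W1 <- grads$W1 + outer(dz1p, opc$spool)
  grads$b1 <- grads$b1 + dz1p
  dspool <- drop(t(params$W1) %*% dz1p)
  dHn_cur <- matrix(dspool, n, nd, byrow = TRUE)

  # ---- interaction pooling ----
  ppc <- cache$pp$cache
  dlogits <- ppc$Zt * (dZt - sum(dZt * ppc$Zt))
  grads$q <- grads$q + t(ppc$cellH) %*% matrix(dlogits)
  dHp <- outer(dlogits, as.numeric(params$q))[prep$interCell, , drop = FALSE]
  grads$W_h <- grads$W_h + t(dHp) %*% ppc$Hsel
  dHee_pp <- dHp %*% params$W_h

  dcrt <- if (use_crt) matrix(0, nE, config$crt_dim) else NULL

  for (l in rev(seq_len(config$n_layers))) {
    pl <- params$layers[[l]]
    lc <- cache$layers[[l]]
    Hn_prev <- cache$Hn_in[[l]]
    # undo node dropout
    dHn_raw <- if (!is.null(lc$maskN)) dHn_cur * lc$maskN else dHn_cur
    dHn_prev <- matrix(0, n, nd)
    dHee <- matrix(0, nE, config$n_domains * ed)
    if (l == config$n_layers && length(prep$interE) > 0L)
      dHee[prep$interE, ] <- dHee[prep$interE, , drop = FALSE] + dHee_pp

    # ---- edge2node ----
    C <- config$n_heads
    for (cc in seq_len(C)) {
      h <- pl$heads[[cc]]; ch <- lc$e2n$cache[[cc]]
      dHead <- dHn_raw / C
      dTa <- dHead
      dmsg <- dHead[e2, , drop = FALSE]
      dBeta <- rowSums(dmsg * ch$Te)
      dTe <- ch$Beta * dmsg
      dbpre <- dBeta * (1 - ch$Beta^2)
      grads$layers[[l]]$heads[[cc]]$v <-
        grads$layers[[l]]$heads[[cc]]$v + t(ch$Bin) %*% matrix(dbpre)
      dBin <- outer(dbpre, as.numeric(h$v))
      dTe <- dTe + dBin[, seq_len(nd), drop = FALSE]
      dTa <- dTa + .rowsumAgg(dBin[, nd + seq_len(nd), drop = FALSE], e2, n)
      if (use_crt) {
        dRc <- dBin[, 2L * nd + seq_len(nd), drop = FALSE]
        grads$layers[[l]]$heads[[cc]]$W_dr <-
          grads$layers[[l]]$heads[[cc]]$W_dr + t(dRc) %*% cache$crt
        dcrt <- dcrt + dRc %*% h$W_dr
      }
      grads$layers[[l]]$heads[[cc]]$W_e <-
        grads$layers[[l]]$heads[[cc]]$W_e + t(dTe) %*% lc$Hee
      dHee <- dHee + dTe %*% h$W_e
      grads$layers[[l]]$heads[[cc]]$W_a <-
        grads$layers[[l]]$heads[[cc]]$W_a + t(dTa) %*% Hn_prev
      dHn_prev <- dHn_prev + dTa %*% h$W_a
    }

    # undo edge dropout
    dHee_raw <- if (!is.null(lc$maskE)) dHee * lc$maskE else dHee

    # ---- edge2edge ----
    He <- lc$He
    dHe <- matrix(0, nE, ed)
    for (q in seq_len(config$n_domains)) {
      dMq <- dHee_raw[, (q - 1L) * ed + seq_len(ed), drop = FALSE]
      dHe <- dHe + dMq
      cq <- lc$e2e$cache[[q]]
      if (isTRUE(cq$empty)) next
      s <- cq$s; t_ <- cq$t
      Wq <- pl$domains[[q]]$W
      dcontrib <- dMq[t_, , drop = FALSE]
      Hes <- He[s, , drop = FALSE]
      if (!(config$variant %in% c("vanilla-gat", "scalar-adaptive"))) {
        dAlpha <- dcontrib * Hes
        dHe <- dHe + .rowsumAgg(cq$Alpha * dcontrib, s, nE)
        dApre <- dAlpha * (1 - cq$Alpha^2)
        grads$layers[[l]]$domains[[q]]$W <-
          grads$layers[[l]]$domains[[q]]$W + t(dApre) %*% cq$Xarc
        grads$layers[[l]]$domains[[q]]$b <-
          grads$layers[[l]]$domains[[q]]$b + matrix(colSums(dApre))
        dXarc <- dApre %*% Wq
      } else {
        dAlphaS <- rowSums(dcontrib * Hes)
        dHe <- dHe + .rowsumAgg(cq$Alpha * dcontrib, s, nE)
        if (config$variant == "scalar-adaptive") {
          dsc <- dAlphaS * (1 - cq$Alpha^2)
        } else {  # vanilla-gat grouped softmax
          gsum <- as.numeric(tapply(dAlphaS * cq$Alpha, t_, sum)[as.character(t_)])
          dsc <- cq$Alpha * (dAlphaS - gsum)
        }
        grads$layers[[l]]$domains[[q]]$W <-
          grads$layers[[l]]$domains[[q]]$W + matrix(dsc, 1L) %*% cq$Xarc
        grads$layers[[l]]$domains[[q]]$b <-
          grads$layers[[l]]$domains[[q]]$b + sum(dsc)
        dXarc <- outer(dsc, as.numeric(Wq))
      }
      dHe <- dHe + .rowsumAgg(dXarc[, seq_len(ed), drop = FALSE], t_, nE)
      dHe <- dHe + .rowsumAgg(dXarc[, ed + seq_len(ed), drop = FALSE], s, nE)
    }

    # ---- node2edge ----
    nc <- lc$n2e$cache
    dHe_pre <- dHe * (nc$He_pre > 0)
    grads$layers[[l]]$W_ab <- grads$layers[[l]]$W_ab + t(dHe_pre) %*% nc$AB
    dAB <- dHe_pre %*% pl$W_ab
    dHn_prev <- dHn_prev + .rowsumAgg(dAB[, seq_len(nd), drop = FALSE], e1, n)
    dHn_prev <- dHn_prev + .rowsumAgg(dAB[, nd + seq_len(nd), drop = FALSE], e2, n)
    if (use_crt)
      dcrt <- dcrt + dAB[, 2L * nd + seq_len(config$crt_dim), drop = FALSE]

    dHn_cur <- dHn_prev
  }

  # ---- curvature block ----
  if (use_crt) {
    cb <- cache$crt_cache
    dCRT_pre <- dcrt * (cb$CRT_pre > 0)
    grads$W_fd <- grads$W_fd + t(dCRT_pre) %*% cb$U
    dU <- dCRT_pre %*% params$W_fd
    dDemb <- dU[, seq_len(config$dist_dim), drop = FALSE]
    dP <- dU[, config$dist_dim + seq_len(config$curv_dim), drop = FALSE]
    rs <- rowsum(dDemb, group = cb$bin)
    cols <- as.integer(rownames(rs)) + 1L
    grads$W_d[, cols] <- grads$W_d[, cols] + t(rs)
    dS_l <- cb$P * (dP - rowSums(dP * cb$P))
    dS_pre <- dS_l * ifelse(cb$S_pre > 0, 1, .LRELU_SLOPE)
    grads$W_f <- grads$W_f + t(dS_pre) %*% prep$FC
  }

  # ---- input embedding ----
  grads$W_node <- grads$W_node + t(dHn_cur) %*% prep$X

  list(grads = grads, loss = loss, la = la, lb = lb)
}
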