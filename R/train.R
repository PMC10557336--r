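# Training loop (Adam on the joint affinity + interaction-matrix loss),
# evaluation, and the four scoring-function metrics.

.adamRec <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    res <- lapply(seq_along(p), function(k)
      .adamRec(p[[k]], g[[k]], m[[k]], v[[k]], lr, t, b1, b2, eps))
    out <- list(p = lapply(res, `[[`, "p"),
                m = lapply(res, `[[`, "m"),
                v = lapply(res, `[[`, "v"))
    out <- lapply(out, `names<-`, names(p))
    return(out)
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

.prepareAll <- function(records, config) {
  lapply(records, function(r)
    if (!is.null(r$X)) r else prepareRecord(r, config))
}

#' Predict affinities (and interaction tables) for a set of complexes
#'
#' Deterministic forward passes in evaluation mode (no dropout).
#'
#' @param model a \linkS4class{CurvAGNModel}.
#' @param records list of featurized records (\code{\link{featurizeComplex}})
#'   or prepared records (\code{\link{prepareRecord}}).
#' @param with_Z also return the predicted interaction matrices.
#' @return Numeric vector of predicted pK values; with \code{with_Z}, a list
#'   \code{(yhat, Zt)}.
#' @export
predictAffinity <- function(model, records, with_Z = FALSE) {
  cfg <- model@config
  preps <- .prepareAll(records, cfg)
  outs <- lapply(preps, forwardPass, params = model@params, config = cfg)
  yhat <- vapply(outs, `[[`, 0, "yhat")
  if (with_Z) list(yhat = yhat, Zt = lapply(outs, `[[`, "Zt")) else yhat
}

#' Scoring-function metrics: RMSE, MAE, Pearson R, regression SD
#'
#' \code{sd_regression} is the residual standard deviation of the labels
#' about the least-squares line of labels on predictions (the CASF scoring
#' convention), \code{sqrt(sum((y - a - b*yhat)^2) / (n - 1))}. With
#' zero-variance predictions or labels, R and SD are reported as \code{NA}.
#'
#' @param predictions,labels numeric vectors of equal length (>= 2).
#' @return List: \code{rmse}, \code{mae}, \code{pearson_r},
#'   \code{sd_regression}, \code{n}.
#' @export
computeMetrics <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("predictions and labels differ in length")
  n <- length(labels)
  if (n < 2L) stop("need at least 2 observations")
  err <- predictions - labels
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  if (stats::sd(predictions) < 1e-12 || stats::sd(labels) < 1e-12) {
    r <- NA_real_; sdreg <- NA_real_
  } else {
    r <- stats::cor(predictions, labels)
    b <- stats::cov(labels, predictions) / stats::var(predictions)
    a <- mean(labels) - b * mean(predictions)
    res <- labels - (a + b * predictions)
    sdreg <- sqrt(sum(res^2) / (n - 1))
  }
  list(rmse = rmse, mae = mae, pearson_r = r, sd_regression = sdreg, n = n)
}

#' Evaluate a model on a dataset
#'
#' @param model a \linkS4class{CurvAGNModel}.
#' @param records featurized or prepared records with labels.
#' @return List: \code{metrics} (see \code{\link{computeMetrics}}) and
#'   \code{errors}, a data.frame with per-complex label, prediction and
#'   absolute error.
#' @export
evaluateModel <- function(model, records) {
  if (length(records) == 0L) stop("empty dataset")
  preps <- .prepareAll(records, model@config)
  yhat <- predictAffinity(model, preps)
  y <- vapply(preps, `[[`, 0, "y")
  list(metrics = computeMetrics(yhat, y),
       errors = data.frame(label = y, prediction = yhat,
                           abs_error = abs(yhat - y)))
}

#' Train a model with Adam
#'
#' Minimizes the summed batch loss \code{L_a + lambda * L_b} with Adam
#' (learning rate and batch size from the model config). Batches are drawn
#' by a seeded shuffle each epoch; with a validation set, the best state by
#' validation RMSE is kept and training stops early after \code{patience}
#' epochs without improvement. The run is deterministic given the seed and
#' single-threaded numerics. Zero steps returns the model unchanged.
#'
#' @param model a \linkS4class{CurvAGNModel}.
#' @param train,val lists of featurized or prepared records (\code{val}
#'   optional).
#' @param steps number of optimizer steps; alternatively give \code{epochs}.
#' @param epochs number of passes over the training data.
#' @param seed RNG seed for shuffling and dropout.
#' @param patience early-stopping patience in epochs (default 30; only with
#'   a validation set).
#' @param verbose log one line per epoch to stderr.
#' @return List: \code{model} (trained), \code{log} (per-epoch data.frame
#'   with mean train loss and its two components, plus validation RMSE when
#'   available).
#' @export
trainCurvAGN <- function(model, train, val = NULL, steps = NULL, epochs = NULL,
                         seed = 1L, patience = 30L, verbose = FALSE) {
  if (length(train) == 0L) stop("empty training split")
  cfg <- model@config
  preps <- .prepareAll(train, cfg)
  vpreps <- if (!is.null(val)) .prepareAll(val, cfg)
  nb <- length(preps)
  steps_per_epoch <- ceiling(nb / cfg$batch_size)
  if (is.null(steps)) {
    if (is.null(epochs)) stop("give steps or epochs")
    steps <- epochs * steps_per_epoch
  }
  if (steps == 0L) return(list(model = model, log = NULL))
  params <- model@params
  opt <- list(m = .zeroLike(params), v = .zeroLike(params), t = 0L)
  set.seed(seed)
  order_ <- sample.int(nb)
  pos <- 1L
  epoch <- 0L
  ep_losses <- c(); ep_la <- c(); ep_lb <- c()
  log <- list()
  best <- list(rmse = Inf, params = params, epoch = 0L)
  for (step in seq_len(steps)) {
    take <- min(cfg$batch_size, nb - pos + 1L)
    idx <- order_[pos:(pos + take - 1L)]
    pos <- pos + take
    gsum <- NULL; lsum <- 0; lasum <- 0; lbsum <- 0
    for (k in idx) {
      fw <- forwardPass(preps[[k]], params, cfg,
                        training = cfg$dropout > 0, keep_cache = TRUE)
      bk <- .backwardPass(preps[[k]], params, cfg, fw)
      gsum <- if (is.null(gsum)) bk$grads else .paramMap(`+`, gsum, bk$grads)
      lsum <- lsum + bk$loss; lasum <- lasum + bk$la; lbsum <- lbsum + bk$lb
    }
    if (!is.finite(lsum))
      stop("training diverged: non-finite loss at step ", step)
    upd <- .adamRec(params, gsum, opt$m, opt$v, cfg$lr, opt$t + 1L)
    params <- upd$p; opt$m <- upd$m; opt$v <- upd$v; opt$t <- opt$t + 1L
    ep_losses <- c(ep_losses, lsum); ep_la <- c(ep_la, lasum)
    ep_lb <- c(ep_lb, lbsum)
    if (pos > nb || step == steps) {
      epoch <- epoch + 1L
      row <- data.frame(epoch = epoch, step = step,
                        train_loss = sum(ep_losses) / nb,
                        train_la = sum(ep_la) / nb,
                        train_lb = sum(ep_lb) / nb,
                        val_rmse = NA_real_)
      if (!is.null(vpreps)) {
        m <- new("CurvAGNModel", config = cfg, params = params)
        vy <- vapply(vpreps, `[[`, 0, "y")
        row$val_rmse <- sqrt(mean((predictAffinity(m, vpreps) - vy)^2))
        if (row$val_rmse < best$rmse)
          best <- list(rmse = row$val_rmse, params = params, epoch = epoch)
        else if (epoch - best$epoch >= patience) {
          log[[length(log) + 1L]] <- row
          if (verbose) message(sprintf("epoch %d: early stop", epoch))
          break
        }
      }
      log[[length(log) + 1L]] <- row
      if (verbose)
        message(sprintf("epoch %3d  step %5d  loss %.4f (la %.4f, lb %.4f)%s",
                        epoch, step, row$train_loss, row$train_la, row$train_lb,
                        if (is.na(row$val_rmse)) ""
                        else sprintf("  val RMSE %.4f", row$val_rmse)))
      ep_losses <- c(); ep_la <- c(); ep_lb <- c()
      set.seed(seed + epoch)
      order_ <- sample.int(nb)
      pos <- 1L
    }
  }
  if (!is.null(vpreps) && is.finite(best$rmse)) params <- best$params
  if (!.paramFinite(params)) stop("training produced non-finite parameters")
  list(model = new("CurvAGNModel", config = cfg, params = params),
       log = do.call(rbind, log))
}
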