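#' Random train/validation split
#'
#' Draws `round(trainFraction * n)` sample indices for training; the
#' rest validate. Deterministic per seed.
#'
#' @param n number of samples (54 gives the standard 36/18 split).
#' @param trainFraction fraction in the training set (default 2/3).
#' @param seed integer seed.
#' @return `list(train =, validation =)` of integer index vectors.
#' @export
splitSamples <- function(n, trainFraction = 2 / 3, seed = 1L) {
  stopifnot(n >= 2, trainFraction > 0, trainFraction < 1)
  nTrain <- round(trainFraction * n)
  nTrain <- min(max(nTrain, 1L), n - 1L)
  set.seed(seed)
  tr <- sort(sample.int(n, nTrain))
  list(train = tr, validation = setdiff(seq_len(n), tr))
}

#' ELM hyperparameters
#'
#' Single-hidden-layer extreme learning machine: sigmoid hidden units
#' with weights and biases drawn uniformly on `weightRange`, output
#' weights by least squares (pseudoinverse). The model is refit
#' `restarts` times with fresh random hidden layers and the restart with
#' the lowest *training* RMSE is kept (validation data are never
#' consulted).
#'
#' @param hiddenNeurons hidden layer width (default 60).
#' @param restarts random restarts (default 50).
#' @param weightRange uniform draw range for hidden weights/biases.
#' @param seed integer seed.
#' @export
elmSpec <- function(hiddenNeurons = 60L, restarts = 50L,
                    weightRange = c(-1, 1), seed = 1L) {
  stopifnot(hiddenNeurons >= 1, restarts >= 1)
  structure(list(hiddenNeurons = as.integer(hiddenNeurons),
                 restarts = as.integer(restarts),
                 weightRange = weightRange, seed = as.integer(seed)),
            class = "elmSpec")
}

#' XGBoost hyperparameters
#' @param nrounds number of boosted trees (default 100).
#' @param eta learning rate (default 0.03).
#' @param maxDepth maximum tree depth (default 5).
#' @param seed integer seed.
#' @export
xgbSpec <- function(nrounds = 100L, eta = 0.03, maxDepth = 5L,
                    seed = 1L) {
  stopifnot(nrounds >= 1, eta > 0, eta <= 1, maxDepth >= 1)
  structure(list(nrounds = as.integer(nrounds), eta = eta,
                 maxDepth = as.integer(maxDepth), seed = as.integer(seed)),
            class = "xgbSpec")
}

#' BPNN (Levenberg-Marquardt) hyperparameters
#'
#' One hidden layer of `hiddenNeurons` tanh units, linear output,
#' trained on sum-of-squares loss by Levenberg-Marquardt:
#' `delta = (J'J + mu I)^{-1} J' e` with `mu` starting at `muInit`,
#' divided by `muFactor` on an accepted step and multiplied by it on a
#' rejected one (capped at `muMax`, after which training stops).
#' Training also stops when the SSE improvement stays below `tol` for
#' `patience` accepted steps, or at `maxEpochs`.
#'
#' @param hiddenNeurons hidden layer width (default 15).
#' @param maxEpochs maximum accepted LM steps (default 300).
#' @param muInit,muFactor,muMax LM damping schedule.
#' @param tol,patience early-stopping rule on training SSE.
#' @param seed integer seed for weight initialization.
#' @export
bpnnSpec <- function(hiddenNeurons = 15L, maxEpochs = 300L,
                     muInit = 1e-3, muFactor = 10, muMax = 1e10,
                     tol = 1e-8, patience = 10L, seed = 1L) {
  stopifnot(hiddenNeurons >= 1, maxEpochs >= 1, muInit > 0,
            muFactor > 1, patience >= 1)
  structure(list(hiddenNeurons = as.integer(hiddenNeurons),
                 maxEpochs = as.integer(maxEpochs), muInit = muInit,
                 muFactor = muFactor, muMax = muMax, tol = tol,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "bpnnSpec")
}

# z-score using training statistics; constant columns get scale 1
standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl,
       apply = function(M) sweep(sweep(M, 2, ctr), 2, scl, "/"))
}

#' Fit an extreme learning machine regressor
#'
#' Features are z-scored with training statistics (bounded activations
#' need comparable input scales); the hidden layer is
#' `H = sigmoid(X W + b)` with `W, b ~ U(weightRange)`, and output
#' weights solve the least-squares problem `[1 H] beta ~ y` via the
#' Moore-Penrose pseudoinverse, so rank deficiency is harmless.
#'
#' @param X training samples-by-features matrix.
#' @param y training response vector.
#' @param spec an [elmSpec()].
#' @return An object of class `elmModel` with a [predict()] method.
#' @export
fitElm <- function(X, y, spec = elmSpec()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y))
  std <- standardizer(X)
  Xs <- std$apply(X)
  p <- ncol(X); L <- spec$hiddenNeurons
  best <- NULL
  for (k in seq_len(spec$restarts)) {
    set.seed(spec$seed + k - 1L)
    W <- matrix(runif(p * L, spec$weightRange[1], spec$weightRange[2]),
                p, L)
    b <- runif(L, spec$weightRange[1], spec$weightRange[2])
    H <- cbind(1, stats::plogis(Xs %*% W + rep(b, each = nrow(Xs))))
    beta <- MASS::ginv(H) %*% y
    rm <- rmse(y, as.numeric(H %*% beta))
    if (is.null(best) || rm < best$trainRmse)
      best <- list(W = W, b = b, beta = beta, trainRmse = rm)
  }
  structure(list(W = best$W, b = best$b, beta = best$beta,
                 center = std$center, scale = std$scale,
                 trainRmse = best$trainRmse, spec = spec),
            class = "elmModel")
}

#' @export
predict.elmModel <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
              object$scale, "/")
  H <- cbind(1, stats::plogis(Xs %*% object$W +
                              rep(object$b, each = nrow(Xs))))
  as.numeric(H %*% object$beta)
}

#' Fit a gradient-boosted tree regressor
#'
#' Squared-error boosted regression trees via xgboost, single-threaded
#' for reproducibility; all parameters other than those in [xgbSpec()]
#' stay at library defaults.
#'
#' @inheritParams fitElm
#' @param spec an [xgbSpec()].
#' @return An object of class `xgbModel` with a [predict()] method.
#' @export
fitXgb <- function(X, y, spec = xgbSpec()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  set.seed(spec$seed)
  dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  bst <- xgboost::xgb.train(
    params = list(eta = spec$eta, max_depth = spec$maxDepth,
                  objective = "reg:squarederror", nthread = 1,
                  seed = spec$seed),
    data = dm, nrounds = spec$nrounds, verbose = 0)
  structure(list(booster = bst, features = colnames(X), spec = spec),
            class = "xgbModel")
}

#' @export
predict.xgbModel <- function(object, newdata, ...) {
  dm <- xgboost::xgb.DMatrix(as.matrix(newdata), nthread = 1)
  as.numeric(predict(object$booster, dm))
}

# forward pass: list(Z = tanh hidden activations (h x n), f = outputs)
bpnnForward <- function(theta, Xs, h) {
  p <- ncol(Xs); n <- nrow(Xs)
  W1 <- matrix(theta[seq_len(h * p)], h, p)
  b1 <- theta[h * p + seq_len(h)]
  w2 <- theta[h * p + h + seq_len(h)]
  b2 <- theta[h * p + 2 * h + 1]
  Z <- tanh(W1 %*% t(Xs) + b1)
  list(Z = Z, f = as.numeric(crossprod(Z, w2) + b2), W1 = W1, w2 = w2)
}

#' Fit a backpropagation network by Levenberg-Marquardt
#'
#' One hidden tanh layer, linear output. Inputs are z-scored with
#' training statistics and the response is internally standardized for
#' conditioning (predictions are returned on the original scale). Each
#' LM step is solved in the thin-SVD basis of the Jacobian, which is
#' exact and fast when parameters outnumber samples. The accepted-step
#' SSE trajectory is stored in the fitted object (`$sse`), and is
#' non-increasing by construction.
#'
#' @inheritParams fitElm
#' @param spec a [bpnnSpec()].
#' @return An object of class `bpnnModel` with a [predict()] method.
#' @export
fitBpnn <- function(X, y, spec = bpnnSpec()) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y))
  std <- standardizer(X)
  Xs <- std$apply(X)
  yc <- mean(y); ys <- sd(y); if (ys == 0) ys <- 1
  yt <- (y - yc) / ys
  n <- nrow(Xs); p <- ncol(Xs); h <- spec$hiddenNeurons
  set.seed(spec$seed)
  theta <- runif(h * p + 2 * h + 1, -0.5, 0.5)
  fw <- bpnnForward(theta, Xs, h)
  e <- yt - fw$f
  sse <- sum(e^2)
  mu <- spec$muInit
  traj <- sse
  stall <- 0L
  for (epoch in seq_len(spec$maxEpochs)) {
    # Jacobian of the network output w.r.t. theta (n x m), blocks in
    # theta order: W1 (column-major h x p), b1, w2, b2
    D <- 1 - fw$Z^2                       # h x n
    G <- D * fw$w2                        # h x n: df/db1
    JW1 <- matrix(0, n, h * p)
    tG <- t(G)
    for (j in seq_len(p))
      JW1[, (j - 1) * h + seq_len(h)] <- tG * Xs[, j]
    J <- cbind(JW1, tG, t(fw$Z), rep(1, n))
    sv <- svd(J, nu = min(n, ncol(J)), nv = min(n, ncol(J)))
    Ute <- crossprod(sv$u, e)
    accepted <- FALSE
    while (!accepted) {
      step <- sv$v %*% (sv$d / (sv$d^2 + mu) * Ute)
      thetaNew <- theta + as.numeric(step)
      fwNew <- bpnnForward(thetaNew, Xs, h)
      eNew <- yt - fwNew$f
      sseNew <- sum(eNew^2)
      if (is.finite(sseNew) && sseNew < sse) {
        accepted <- TRUE
        if (sse - sseNew < spec$tol) stall <- stall + 1L else stall <- 0L
        theta <- thetaNew; fw <- fwNew; e <- eNew; sse <- sseNew
        traj <- c(traj, sse)
        mu <- max(mu / spec$muFactor, 1e-12)
      } else {
        mu <- mu * spec$muFactor
        if (mu > spec$muMax) break
      }
    }
    if (!accepted || stall >= spec$patience) break
  }
  structure(list(theta = theta, hidden = h, center = std$center,
                 scale = std$scale, yCenter = yc, yScale = ys,
                 sse = traj, spec = spec),
            class = "bpnnModel")
}

#' @export
predict.bpnnModel <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
              object$scale, "/")
  fw <- bpnnForward(object$theta, Xs, object$hidden)
  fw$f * object$yScale + object$yCenter
}

#' Evaluate a fitted model on a data set
#' @param model a fitted `elmModel`, `xgbModel` or `bpnnModel`.
#' @param X samples-by-features matrix.
#' @param y observed response.
#' @return Named vector `c(R2, RMSE, MRE)`.
#' @export
evaluateModel <- function(model, X, y) {
  evalMetrics(y, predict(model, X))
}

#' Fit the full model-by-combination grid
#'
#' Fits ELM, XGBoost and BPNN on each feature combination, evaluating
#' training and validation sets with R2 / RMSE / MRE. Empty combinations
#' are skipped with a warning.
#'
#' @param se the feature container (vegetation indices, textures and
#'   texture indices added).
#' @param combinations named list of feature-name vectors, from
#'   [buildCombinations()].
#' @param split `list(train, validation)` from [splitSamples()].
#' @param elm,xgb,bpnn model specs.
#' @return `list(results = data.frame(model, combination, split, R2,
#'   RMSE, MRE), predictions = data.frame, models = nested list)`.
#' @export
runModelMatrix <- function(se, combinations, split,
                           elm = elmSpec(), xgb = xgbSpec(),
                           bpnn = bpnnSpec()) {
  y <- moisturePct(se)
  fitters <- list(ELM = function(X, y) fitElm(X, y, elm),
                  XGBoost = function(X, y) fitXgb(X, y, xgb),
                  BPNN = function(X, y) fitBpnn(X, y, bpnn))
  results <- list(); preds <- list(); models <- list()
  for (cn in names(combinations)) {
    cols <- combinations[[cn]]
    if (length(cols) == 0) {
      warning("skipping ", cn, ": no features")
      next
    }
    X <- featureMatrix(se, cols)
    for (mn in names(fitters)) {
      fit <- fitters[[mn]](X[split$train, , drop = FALSE], y[split$train])
      models[[cn]][[mn]] <- fit
      for (part in c("train", "validation")) {
        idx <- split[[part]]
        ph <- predict(fit, X[idx, , drop = FALSE])
        m <- evalMetrics(y[idx], ph)
        results[[length(results) + 1L]] <- data.frame(
          model = mn, combination = cn, split = part,
          R2 = m["R2"], RMSE = m["RMSE"], MRE = m["MRE"],
          row.names = NULL)
        preds[[length(preds) + 1L]] <- data.frame(
          model = mn, combination = cn, split = part,
          sample = colnames(se)[idx], observed = y[idx], predicted = ph,
          row.names = NULL)
      }
    }
  }
  list(results = do.call(rbind, results),
       predictions = do.call(rbind, preds), models = models)
}
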