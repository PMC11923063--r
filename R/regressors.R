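# Shallow regressors for kinetic parameters.
#
# The prediction module is deliberately small: embeddings and fingerprints
# carry most of the signal, and deeper networks overfit kinetic tables, so a
# single ReLU hidden layer with a linear output is fit with an RMSE loss by
# Adam. The kcat/Km model is two-stage: kcat and Km submodels are
# pre-trained on the parent labels of the ratio dataset and frozen, and a
# dense + feature-wise-attention correction network learns an additive
# adjustment to the log-ratio of their predictions,
#   prediction = a * (kcat_pred - km_pred) + b * correction,
# with the blend weights (a, b) trained jointly with the correction network.

#' Regressor training configuration
#'
#' @param hidden_dim hidden-layer width (default 256).
#' @param activation hidden nonlinearity; only \code{"relu"} is provided.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty added to the gradient.
#' @param epochs number of passes.
#' @param batch_size minibatch size; \code{Inf} trains full-batch
#'   (deterministic and fastest at desk scale).
#' @param seed integer seed governing initialization and shuffling.
#' @param num_trees tree count for the extra-trees backend.
#' @return a named list understood by the training functions.
#' @export
regressorConfig <- function(hidden_dim = 256, activation = "relu",
                            learning_rate = 0.01, weight_decay = 1e-5,
                            epochs = 300, batch_size = Inf, seed = 0,
                            num_trees = 300) {
  if (activation != "relu") stop("only 'relu' activation is provided")
  list(hidden_dim = as.integer(hidden_dim), activation = activation,
       learning_rate = learning_rate, weight_decay = weight_decay,
       epochs = as.integer(epochs), batch_size = batch_size,
       seed = as.integer(seed), num_trees = as.integer(num_trees))
}

relu <- function(x) (x > 0) * x

# One Adam update; state holds m/v moments and the step counter.
adamStep <- function(param, grad, state, lr, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  state$m <- b1 * state$m + (1 - b1) * grad
  state$v <- b2 * state$v + (1 - b2) * grad^2
  t <- state$t + 1
  mhat <- state$m / (1 - b1^t)
  vhat <- state$v / (1 - b2^t)
  state$t <- t
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

newAdamState <- function(param) list(m = param * 0, v = param * 0, t = 0)

mlpForward <- function(params, X) {
  H0 <- sweep(X %*% params$W1, 2, params$b1, "+")
  H <- relu(H0)
  pred <- as.numeric(H %*% params$W2 + params$b2)
  list(H0 = H0, H = H, pred = pred)
}

#' Train a shallow kinetic regressor
#'
#' One hidden ReLU layer, linear output, RMSE loss, Adam optimizer. Fully
#' seeded: identical data, configuration and seed give bit-identical
#' parameters and loss history.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y numeric log10 labels, one per row of \code{X}.
#' @param config list from \code{\link{regressorConfig}}.
#' @return a \code{\linkS4class{KineticRegressor}}; per-epoch training RMSE
#'   is in \code{@loss_history}.
#' @export
trainRegressor <- function(X, y, config = regressorConfig()) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("X and y must be finite")
  d <- ncol(X); h <- config$hidden_dim; n <- nrow(X)
  params <- withSeed(childSeed(config$seed, "mlp-init"), list(
    W1 = matrix(rnorm(d * h, sd = sqrt(2 / d)), d, h),
    b1 = numeric(h),
    W2 = matrix(0, h, 1),   # zero output layer: training starts at mean(y)
    b2 = mean(y)
  ))
  states <- lapply(params, newAdamState)
  wd <- config$weight_decay
  bs <- if (is.finite(config$batch_size)) min(config$batch_size, n) else n
  history <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    # linear decay to zero: RMSE-loss gradients have constant magnitude, so
    # a fixed Adam step leaves a noise floor proportional to the step size
    lr <- config$learning_rate * (1 - (epoch - 1) / config$epochs)
    batches <- if (bs >= n) list(seq_len(n)) else
      withSeed(childSeed(config$seed, paste0("shuffle", epoch)),
               split(sample.int(n), ceiling(seq_len(n) / bs)))
    for (idx in batches) {
      Xb <- X[idx, , drop = FALSE]
      fw <- mlpForward(params, Xb)
      e <- fw$pred - y[idx]
      L <- sqrt(mean(e^2))
      if (L == 0) next
      g <- e / (length(idx) * L)
      dW2 <- crossprod(fw$H, g) + wd * params$W2
      db2 <- sum(g)
      dH <- outer(g, as.numeric(params$W2)) * (fw$H0 > 0)
      dW1 <- crossprod(Xb, dH) + wd * params$W1
      db1 <- colSums(dH)
      for (nm in c("W1", "b1", "W2", "b2")) {
        gr <- switch(nm, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
        up <- adamStep(params[[nm]], gr, states[[nm]], lr)
        params[[nm]] <- up$param
        states[[nm]] <- up$state
      }
    }
    history[epoch] <- sqrt(mean((mlpForward(params, X)$pred - y)^2))
  }
  new("KineticRegressor", params = params, config = config,
      loss_history = history)
}

#' @describeIn trainRegressor predict log10 values for new feature rows.
#' @param object a trained \code{KineticRegressor}.
#' @param newdata numeric matrix (or vector for a single sample).
#' @export
setMethod("predict", "KineticRegressor", function(object, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != nrow(object@params$W1))
    stop("newdata has ", ncol(newdata), " features; model expects ",
         nrow(object@params$W1))
  mlpForward(object@params, as.matrix(newdata))$pred
})

#' Feature-wise attention gate
#'
#' Computes normalized attention weights A = softmax(W h) and the gated
#' features h_A = A (elementwise) h. \code{W} may be a d x d matrix or a
#' length-d vector (then scores are W * h elementwise).
#'
#' @param W weight matrix (d x d) or vector (length d).
#' @param h numeric feature vector of length d.
#' @return list with \code{A} (sums to 1) and \code{h_A}.
#' @export
attentionGate <- function(W, h) {
  if (is.matrix(W)) {
    if (ncol(W) != length(h) || nrow(W) != length(h))
      stop("W must be d x d for h of length d")
    s <- as.numeric(W %*% h)
  } else {
    if (length(W) != length(h)) stop("vector W must match length of h")
    s <- W * h
  }
  s <- s - max(s)
  A <- exp(s) / sum(exp(s))
  list(A = A, h_A = A * h)
}

rowSoftmax <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

correctionForward <- function(corr, X) {
  H0 <- sweep(X %*% corr$Wd, 2, corr$bd, "+")
  H <- relu(H0)
  S <- H %*% t(corr$Wa)
  A <- rowSoftmax(S)
  HA <- A * H
  out <- as.numeric(HA %*% corr$wo + corr$bo)
  list(H0 = H0, H = H, A = A, HA = HA, out = out)
}

#' Predict log10(kcat/Km) with a two-stage model
#'
#' Output is a * (kcat_pred - km_pred) + b * correction(x): the log-ratio of
#' the frozen submodels, blended with the attention-corrected adjustment.
#'
#' @param model a \code{\linkS4class{TwoStageRatioModel}}.
#' @param x feature vector or matrix.
#' @return numeric predictions.
#' @export
ratioPredict <- function(model, x) {
  stopifnot(is(model, "TwoStageRatioModel"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  diff <- predict(model@kcat_model, x) - predict(model@km_model, x)
  corr <- correctionForward(model@correction, as.matrix(x))$out
  model@blend[1] * diff + model@blend[2] * corr
}

# Train the correction network + blend on top of frozen submodel
# predictions. wo starts at zero so the optimization starts exactly at the
# raw log-difference baseline; a seeded internal validation split selects
# the epoch to keep (the initial state included), so the returned
# correction generalizes at least as well as the baseline up to the
# validation noise.
trainCorrection <- function(X, y, diff, config, val_fraction = 0.15) {
  d <- ncol(X); h <- config$hidden_dim; n_all <- nrow(X)
  n_val <- floor(val_fraction * n_all)
  val <- if (n_val >= 5)
    withSeed(childSeed(config$seed, "corr-val"), sample.int(n_all, n_val))
  else integer(0)
  tr <- setdiff(seq_len(n_all), val)
  Xv <- X[val, , drop = FALSE]; yv <- y[val]; dv <- diff[val]
  Xt <- X[tr, , drop = FALSE]; yt <- y[tr]; dt <- diff[tr]
  n <- length(tr)
  corr <- withSeed(childSeed(config$seed, "corr-init"), list(
    Wd = matrix(rnorm(d * h, sd = sqrt(2 / d)), d, h),
    bd = numeric(h),
    Wa = matrix(0, h, h),
    wo = matrix(0, h, 1),
    bo = 0
  ))
  blend <- c(a = 1, b = 1)
  states <- c(lapply(corr, newAdamState), list(blend = newAdamState(blend)))
  lr <- config$learning_rate; wd <- config$weight_decay
  valRmse <- function() {
    if (!length(val)) return(NA_real_)
    fwv <- correctionForward(corr, Xv)
    sqrt(mean((blend[1] * dv + blend[2] * fwv$out - yv)^2))
  }
  best <- list(corr = corr, blend = blend, val = valRmse())
  X <- Xt; y <- yt; diff <- dt
  for (epoch in seq_len(config$epochs)) {
    fw <- correctionForward(corr, X)
    pred <- blend[1] * diff + blend[2] * fw$out
    e <- pred - y
    L <- sqrt(mean(e^2))
    if (L == 0) break
    g <- e / (n * L)
    dblend <- c(sum(g * diff), sum(g * fw$out))
    dout <- g * blend[2]
    dwo <- crossprod(fw$HA, dout) + wd * corr$wo
    dbo <- sum(dout)
    dHA <- outer(dout, as.numeric(corr$wo))      # n x h
    dA <- dHA * fw$H
    dH_direct <- dHA * fw$A
    dS <- fw$A * (dA - rowSums(dA * fw$A))       # softmax backward per row
    dWa <- crossprod(dS, fw$H) + wd * corr$Wa
    dH <- dH_direct + dS %*% corr$Wa
    dH0 <- dH * (fw$H0 > 0)
    dWd <- crossprod(X, dH0) + wd * corr$Wd
    dbd <- colSums(dH0)
    grads <- list(Wd = dWd, bd = dbd, Wa = dWa, wo = dwo, bo = dbo)
    for (nm in names(grads)) {
      up <- adamStep(corr[[nm]], grads[[nm]], states[[nm]], lr)
      corr[[nm]] <- up$param
      states[[nm]] <- up$state
    }
    upb <- adamStep(blend, dblend, states$blend, lr)
    blend <- upb$param
    states$blend <- upb$state
    if (length(val)) {
      v <- valRmse()
      if (v < best$val) best <- list(corr = corr, blend = blend, val = v)
    } else {
      best <- list(corr = corr, blend = blend, val = NA_real_)
    }
  }
  list(correction = best$corr, blend = unname(best$blend),
       val_rmse = best$val)
}

#' Train per-fold two-stage kcat/Km models
#'
#' Stage 1 trains kcat and Km submodels on the parent labels of the ratio
#' dataset (per training fold); their parameters are then frozen. Stage 2
#' trains the dense + feature-wise-attention correction network and the
#' blend weights on the ratio labels, with the submodels untouched.
#'
#' @param dataset ratio \code{KineticDataset} whose entries carry
#'   \code{kcat_label} and \code{km_label}.
#' @param X feature matrix with rownames matching the dataset's pair keys.
#' @param assignment a \code{\linkS4class{FoldAssignment}} over the dataset.
#' @param submodel_config,correction_config \code{\link{regressorConfig}}s.
#' @return list with \code{models} (one \code{TwoStageRatioModel} per fold),
#'   \code{oof} (data.frame: key, fold, two_stage and raw-difference
#'   out-of-fold predictions, label).
#' @export
trainTwoStage <- function(dataset, X, assignment,
                          submodel_config = regressorConfig(),
                          correction_config = regressorConfig()) {
  stopifnot(is(dataset, "KineticDataset"), is(assignment, "FoldAssignment"))
  ent <- entries(dataset)
  if (!all(c("kcat_label", "km_label") %in% names(ent)))
    stop("ratio dataset must carry kcat_label and km_label parent labels")
  key <- pairKey(ent$sequence, ent$smiles)
  fold_of <- foldOf(assignment)[key]
  if (anyNA(fold_of)) stop("assignment does not cover the dataset")
  X <- as.matrix(X)[key, , drop = FALSE]
  models <- vector("list", assignment@k)
  oof <- data.frame(key = key, fold = fold_of, two_stage = NA_real_,
                    raw_diff = NA_real_, label = ent$label,
                    stringsAsFactors = FALSE)
  for (f in 0:(assignment@k - 1L)) {
    tr <- fold_of != f
    te <- !tr
    kcat_m <- trainRegressor(X[tr, , drop = FALSE], ent$kcat_label[tr],
                             submodel_config)
    km_m <- trainRegressor(X[tr, , drop = FALSE], ent$km_label[tr],
                           submodel_config)
    frozen <- list(kcat = kcat_m@params, km = km_m@params)
    diff_tr <- predict(kcat_m, X[tr, , drop = FALSE]) -
      predict(km_m, X[tr, , drop = FALSE])
    fit <- trainCorrection(X[tr, , drop = FALSE], ent$label[tr], diff_tr,
                           correction_config)
    stopifnot(identical(frozen,
                        list(kcat = kcat_m@params, km = km_m@params)))
    m <- new("TwoStageRatioModel", kcat_model = kcat_m, km_model = km_m,
             correction = fit$correction, blend = fit$blend,
             config = correction_config)
    models[[f + 1L]] <- m
    if (any(te)) {
      oof$two_stage[te] <- ratioPredict(m, X[te, , drop = FALSE])
      oof$raw_diff[te] <- predict(kcat_m, X[te, , drop = FALSE]) -
        predict(km_m, X[te, , drop = FALSE])
    }
  }
  list(models = models, oof = oof)
}

#' Cross-validated training and out-of-fold prediction
#'
#' Trains one model per fold on the complement and predicts the held-out
#' records, so every record is predicted exactly once by a model that never
#' saw it (nor, under a clustered assignment, any homolog of it above the
#' clustering threshold).
#'
#' @param X feature matrix, rownames = record keys of the assignment.
#' @param y labels named like the rownames of \code{X} (or in row order).
#' @param assignment a \code{\linkS4class{FoldAssignment}}.
#' @param config \code{\link{regressorConfig}}.
#' @param backend \code{"mlp"} or \code{"tree"}.
#' @return list with \code{oof} (named numeric vector of out-of-fold
#'   predictions in row order of \code{X}), \code{fold_metrics}
#'   (data.frame: fold, n, pcc, scc, rmse; NA where undefined) and
#'   \code{models}.
#' @export
crossValidate <- function(X, y, assignment, config = regressorConfig(),
                          backend = c("mlp", "tree")) {
  backend <- match.arg(backend)
  stopifnot(is(assignment, "FoldAssignment"))
  X <- as.matrix(X)
  keys <- rownames(X)
  if (is.null(keys)) stop("X must have rownames (record keys)")
  if (!is.null(names(y))) y <- y[keys]
  fold_of <- foldOf(assignment)[keys]
  if (anyNA(fold_of)) stop("assignment does not cover all rows of X")
  oof <- setNames(rep(NA_real_, nrow(X)), keys)
  models <- vector("list", assignment@k)
  fm <- data.frame(fold = 0:(assignment@k - 1L), n = 0L, pcc = NA_real_,
                   scc = NA_real_, rmse = NA_real_)
  for (f in 0:(assignment@k - 1L)) {
    tr <- fold_of != f
    te <- !tr
    if (!any(te)) next
    cfg <- config
    cfg$seed <- childSeed(config$seed, paste0("fold", f))
    model <- if (backend == "mlp")
      trainRegressor(X[tr, , drop = FALSE], y[tr], cfg)
    else
      trainTreeEnsemble(X[tr, , drop = FALSE], y[tr], cfg)
    models[[f + 1L]] <- model
    pred <- predict(model, X[te, , drop = FALSE])
    oof[te] <- pred
    i <- f + 1L
    fm$n[i] <- sum(te)
    if (sum(te) >= 2) {
      fm$pcc[i] <- tryCatch(pcc(pred, y[te]), error = function(e) NA_real_)
      fm$scc[i] <- tryCatch(scc(pred, y[te]), error = function(e) NA_real_)
    }
    fm$rmse[i] <- rmse(pred, y[te])
  }
  list(oof = oof, fold_metrics = fm, models = models)
}

#' Exhaustive grid search over regressor configurations
#'
#' Evaluates every combination of the supplied hyperparameter values by mean
#' out-of-fold RMSE under the given fold assignment; ties break toward the
#' earlier grid row (row-major expansion order).
#'
#' @param X,y,assignment as in \code{\link{crossValidate}}.
#' @param grid named list of value vectors (e.g.
#'   \code{list(hidden_dim = c(64, 256), learning_rate = c(1e-2, 1e-3))}).
#' @param base_config configuration supplying unsearched parameters.
#' @param backend passed to \code{\link{crossValidate}}.
#' @return list with \code{best_config} and \code{table} (one row per grid
#'   point, with mean OOF RMSE).
#' @export
gridSearch <- function(X, y, assignment, grid,
                       base_config = regressorConfig(),
                       backend = "mlp") {
  if (!length(grid) || !all(lengths(grid) > 0)) stop("grid must be nonempty")
  tab <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$mean_oof_rmse <- NA_real_
  best <- NULL
  best_rmse <- Inf
  for (i in seq_len(nrow(tab))) {
    cfg <- base_config
    for (nm in names(grid)) cfg[[nm]] <- tab[[nm]][i]
    cv <- crossValidate(X, y, assignment, cfg, backend)
    m <- rmse(cv$oof, y[names(cv$oof)])
    tab$mean_oof_rmse[i] <- m
    if (m < best_rmse) {  # strict: ties keep the earlier grid point
      best_rmse <- m
      best <- cfg
    }
  }
  list(best_config = best, table = tab)
}

#' Ensemble and multi-substrate prediction averaging
#'
#' Averages the predictions of several models on the same feature rows
#' (model ensembling, e.g. the per-fold models at inference time). With
#' \code{average_rows = TRUE} the row predictions are additionally averaged
#' into a single value, which is how a multi-substrate reaction is scored
#' from its per-substrate feature rows.
#'
#' @param models a single model or list of models with a predict contract
#'   (\code{KineticRegressor}, \code{TreeRegressor}) or
#'   \code{TwoStageRatioModel}s.
#' @param X feature matrix.
#' @param average_rows average the per-row predictions into one value.
#' @return numeric predictions (length nrow(X), or 1).
#' @export
ensemblePredict <- function(models, X, average_rows = FALSE) {
  if (!is.list(models)) models <- list(models)
  if (!length(models)) stop("empty model list")
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  preds <- vapply(models, function(m) {
    if (is(m, "TwoStageRatioModel")) ratioPredict(m, X) else predict(m, X)
  }, numeric(nrow(X)))
  out <- rowMeans(matrix(preds, nrow = nrow(X)))
  if (average_rows) {
    if (!length(out)) stop("no rows to average")
    out <- mean(out)
  }
  out
}

#' Train an extra-trees style ensemble regressor
#'
#' Randomized-tree backend (ranger with the extratrees split rule)
#' satisfying the same predict contract as the neural regressor.
#'
#' @inheritParams trainRegressor
#' @return a \code{\linkS4class{TreeRegressor}}.
#' @export
trainTreeEnsemble <- function(X, y, config = regressorConfig()) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows of X must match length of y")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("X and y must be finite")
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$.y <- as.numeric(y)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = config$num_trees, splitrule = "extratrees",
    replace = FALSE, sample.fraction = 1,
    seed = childSeed(config$seed, "extratrees"),
    num.threads = 1, verbose = FALSE)
  new("TreeRegressor", fit = fit, config = config)
}

#' @describeIn trainTreeEnsemble predict with the tree ensemble.
#' @param object a \code{TreeRegressor}.
#' @param newdata feature matrix or vector.
#' @export
setMethod("predict", "TreeRegressor", function(object, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  df <- as.data.frame(as.matrix(newdata))
  names(df) <- paste0("f", seq_len(ncol(df)))
  as.numeric(stats::predict(object@fit, data = df,
                            num.threads = 1)$predictions)
})
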