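#' Random modeling/validation split
#'
#' Uniformly random split without replacement: `round(fraction * n)` samples
#' form the modeling set (32 of 48 at the default design, the 2/3 convention
#' of the emulated trial), the remainder the validation set.
#'
#' @param ids sample identifiers.
#' @param fraction modeling fraction in (0, 1); default 2/3.
#' @param seed integer seed.
#' @param strata optional factor-like vector aligned with `ids`; when given,
#'   the split is drawn within each stratum (e.g. treatment cell) at the
#'   same fraction, rounding per stratum. Whether the emulated protocol
#'   stratified is unstated, so the plain random split is the default.
#' @return list with `modeling_ids`, `validation_ids`, `seed`.
#' @export
split_modeling_validation <- function(ids, fraction = 2 / 3, seed = 1L, strata = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- length(ids)
  if (n < 6L) stop("need at least 6 samples to split")
  mod <- with_seed(seed, {
    if (is.null(strata)) {
      sort(sample.int(n, round(fraction * n)))
    } else {
      if (length(strata) != n) stop("strata must align with ids")
      sort(unlist(lapply(split(seq_len(n), strata), function(g) {
        sample(g, max(1L, round(fraction * length(g))))
      }), use.names = FALSE))
    }
  })
  list(modeling_ids = ids[mod], validation_ids = ids[-mod], seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# PLSR (NIPALS, PLS1) with 10-fold CV choice of latent variables
# ---------------------------------------------------------------------------

# core NIPALS on standardized X, centered y; returns coefficient matrix
# B[, a] for models with 1..A components (on the standardized scale)
nipals_pls1 <- function(X, y, A) {
  p <- ncol(X)
  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  Xd <- X; yd <- y
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) { A <- a - 1L; break }
    pvec <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pvec)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pvec; q[a] <- qa
  }
  if (A == 0L) return(matrix(0, p, 1L))
  B <- matrix(0, p, A)
  for (a in seq_len(A)) {
    Wa <- W[, 1:a, drop = FALSE]
    B[, a] <- Wa %*% solve(crossprod(P[, 1:a, drop = FALSE], Wa), q[1:a])
  }
  B
}

#' Fit a partial least squares regression (PLS1)
#'
#' NIPALS PLSR of a single response on z-scored predictors. The number of
#' latent variables is chosen to minimize the k-fold cross-validated RMSE
#' over `1..min(max_lv, rank(X))` (ties to the smaller count), then the
#' model is refit on all rows.
#'
#' @param X numeric predictor matrix (rows = samples).
#' @param y numeric response.
#' @param max_lv maximum latent variables considered (default 10).
#' @param folds number of CV folds (default 10, capped at `nrow(X)`).
#' @param seed seed for the fold assignment.
#' @return object of class `plsr_fit` with the standardization constants,
#'   coefficients, chosen `ncomp` and the CV RMSE per component count.
#' @export
fit_plsr <- function(X, y, max_lv = 10L, folds = 10L, seed = 1L) {
  X <- as.matrix(X); n <- nrow(X)
  if (length(y) != n) stop("X and y sizes differ")
  folds <- min(folds, n)
  mu <- colMeans(X); sdev <- apply(X, 2L, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdev, `/`)
  ybar <- mean(y); yc <- y - ybar
  A <- max(1L, min(max_lv, qr(Xs)$rank))
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  press <- matrix(NA_real_, n, A)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (sum(tr) < 2L) next
    Af <- max(1L, min(A, qr(Xs[tr, , drop = FALSE])$rank))
    B <- nipals_pls1(Xs[tr, , drop = FALSE], yc[tr], Af)
    pred <- Xs[!tr, , drop = FALSE] %*% B            # n_test x Af
    press[!tr, seq_len(ncol(B))] <- (pred - yc[!tr])^2
  }
  cv_rmse <- sqrt(colMeans(press, na.rm = TRUE))
  ncomp <- which.min(cv_rmse)
  B <- nipals_pls1(Xs, yc, A)
  structure(list(mu = mu, sdev = sdev, ybar = ybar,
                 coef = B[, min(ncomp, ncol(B))], ncomp = ncomp,
                 cv_rmse = cv_rmse, columns = colnames(X)),
            class = "plsr_fit")
}

#' @export
predict.plsr_fit <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2L, object$mu), 2L, object$sdev, `/`)
  drop(Xs %*% object$coef) + object$ybar
}

# ---------------------------------------------------------------------------
# Random forest regression (bootstrap CART ensemble)
# ---------------------------------------------------------------------------

# grow one regression tree on (X, y); array representation
grow_tree <- function(X, y, mtry, min_node) {
  p <- ncol(X)
  var <- split <- value <- left <- right <- numeric(0)
  rows <- list(seq_along(y))
  node <- 0L
  while (length(rows) > node) {
    node <- node + 1L
    idx <- rows[[node]]
    yn <- y[idx]
    var[node] <- -1; split[node] <- NA_real_
    left[node] <- 0L; right[node] <- 0L
    value[node] <- mean(yn)
    n <- length(idx)
    if (n <= min_node || stats::var(yn) == 0) next
    feats <- if (mtry >= p) seq_len(p) else sample.int(p, mtry)
    best_gain <- 0; best_f <- -1L; best_cut <- NA_real_
    sy <- sum(yn); syy <- sum(yn^2)
    sse_parent <- syy - sy^2 / n
    for (f in feats) {
      xf <- X[idx, f]
      o <- order(xf)
      xs <- xf[o]; ys <- yn[o]
      cuts <- which(xs[-n] < xs[-1L])    # split between distinct values
      if (!length(cuts)) next
      c1 <- cumsum(ys); c2 <- cumsum(ys^2)
      k <- cuts
      sse <- (c2[k] - c1[k]^2 / k) +
             ((syy - c2[k]) - (sy - c1[k])^2 / (n - k))
      gain <- sse_parent - sse
      b <- which.max(gain)
      if (gain[b] > best_gain + 1e-12) {
        best_gain <- gain[b]; best_f <- f
        best_cut <- (xs[k[b]] + xs[k[b] + 1L]) / 2
      }
    }
    if (best_f < 0L) next
    go_left <- X[idx, best_f] <= best_cut
    var[node] <- best_f; split[node] <- best_cut
    rows[[length(rows) + 1L]] <- idx[go_left];  left[node] <- length(rows)
    rows[[length(rows) + 1L]] <- idx[!go_left]; right[node] <- length(rows)
  }
  list(var = as.integer(var), split = split, left = as.integer(left),
       right = as.integer(right), value = value)
}

predict_tree <- function(tree, X) {
  node <- rep(1L, nrow(X))
  repeat {
    v <- tree$var[node]
    active <- v > 0L
    if (!any(active)) break
    ai <- which(active)
    go_left <- X[cbind(ai, v[ai])] <= tree$split[node[ai]]
    node[ai] <- ifelse(go_left, tree$left[node[ai]], tree$right[node[ai]])
  }
  tree$value[node]
}

#' Fit a random forest regression
#'
#' Bagged ensemble of CART regression trees: each tree is grown on a
#' bootstrap resample, considering `mtry` randomly chosen predictors per
#' split, and predictions are the tree mean. The default 600 trees follows
#' the tuned forest size of the emulated analysis; `mtry` defaults to the
#' regression convention `max(1, floor(p / 3))`.
#'
#' @param X numeric predictor matrix (used raw; the forest is
#'   scale-invariant).
#' @param y numeric response.
#' @param ntree number of trees (default 600).
#' @param mtry predictors tried per split.
#' @param min_node node size below which splitting stops (default 5).
#' @param seed integer seed; fixing it makes fitting and prediction fully
#'   deterministic.
#' @return object of class `rf_fit`.
#' @export
fit_rf <- function(X, y, ntree = 600L, mtry = max(1L, floor(ncol(X) / 3)),
                   min_node = 5L, seed = 1L) {
  X <- as.matrix(X); n <- nrow(X)
  if (length(y) != n) stop("X and y sizes differ")
  trees <- with_seed(seed, lapply(seq_len(ntree), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    grow_tree(X[idx, , drop = FALSE], y[idx], mtry, min_node)
  }))
  structure(list(trees = trees, columns = colnames(X)), class = "rf_fit")
}

#' @export
predict.rf_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  acc <- numeric(nrow(X))
  for (tr in object$trees) acc <- acc + predict_tree(tr, X)
  acc / length(object$trees)
}

# ---------------------------------------------------------------------------
# Backpropagation network trained by Levenberg-Marquardt
# ---------------------------------------------------------------------------

bpnn_forward <- function(theta, X, hidden) {
  p <- ncol(X)
  W1 <- matrix(theta[seq_len(hidden * p)], hidden, p)
  b1 <- theta[hidden * p + seq_len(hidden)]
  w2 <- theta[hidden * (p + 1L) + seq_len(hidden)]
  b2 <- theta[hidden * (p + 2L) + 1L]
  Z <- tanh(X %*% t(W1) + matrix(b1, nrow(X), hidden, byrow = TRUE))
  list(yhat = drop(Z %*% w2) + b2, Z = Z, W1 = W1, w2 = w2)
}

bpnn_jacobian <- function(fw, X, hidden) {
  n <- nrow(X); p <- ncol(X)
  D <- (1 - fw$Z^2) * matrix(fw$w2, n, hidden, byrow = TRUE)  # n x h
  J <- matrix(0, n, hidden * (p + 2L) + 1L)
  for (j in seq_len(p)) {
    J[, (j - 1L) * hidden + seq_len(hidden)] <- D * X[, j]
  }
  J[, hidden * p + seq_len(hidden)] <- D
  J[, hidden * (p + 1L) + seq_len(hidden)] <- fw$Z
  J[, hidden * (p + 2L) + 1L] <- 1
  J
}

#' Fit a single-hidden-layer tanh network by Levenberg-Marquardt
#'
#' A backpropagation network with one hidden layer of `hidden` tanh units
#' and a linear output, trained in full batch by the Levenberg-Marquardt
#' algorithm (damped Gauss-Newton on the network Jacobian, the `trainlm`
#' scheme). Inputs and the response are z-scored for training and
#' predictions are mapped back to the original scale.
#'
#' @param X numeric predictor matrix.
#' @param y numeric response.
#' @param hidden hidden units (default 15, the tuned size of the emulated
#'   analysis).
#' @param max_epochs maximum LM iterations (default 120).
#' @param tol stop when the training MSE improves by less than `tol`
#'   relatively over an iteration (also stops on vanishing gradient or
#'   unbounded damping).
#' @param seed seed for the weight initialization.
#' @param method `"lm"` (Levenberg-Marquardt, the default) or `"bfgs"`, a
#'   quasi-Newton fallback via [stats::optim()] for cases where the damped
#'   normal equations behave poorly.
#' @return object of class `bpnn_fit` (best-so-far weights are kept if the
#'   iteration limit is hit before convergence, with a logged warning).
#' @export
fit_bpnn <- function(X, y, hidden = 15L, max_epochs = 120L, tol = 1e-9, seed = 1L,
                     method = c("lm", "bfgs")) {
  method <- match.arg(method)
  X <- as.matrix(X); n <- nrow(X)
  if (length(y) != n) stop("X and y sizes differ")
  mu <- colMeans(X); sdev <- apply(X, 2L, stats::sd)
  sdev[sdev == 0 | !is.finite(sdev)] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, sdev, `/`)
  ybar <- mean(y); ysd <- stats::sd(y); if (!is.finite(ysd) || ysd == 0) ysd <- 1
  ys <- (y - ybar) / ysd
  p <- ncol(Xs)
  ntheta <- hidden * (p + 2L) + 1L
  theta <- with_seed(seed, stats::rnorm(ntheta, 0, 0.5 / sqrt(p + 1)))
  if (method == "bfgs") {
    fn <- function(th) mean((ys - bpnn_forward(th, Xs, hidden)$yhat)^2)
    gr <- function(th) {
      fwt <- bpnn_forward(th, Xs, hidden)
      drop(-2 * crossprod(bpnn_jacobian(fwt, Xs, hidden), ys - fwt$yhat) / n)
    }
    opt <- stats::optim(theta, fn, gr, method = "BFGS",
                        control = list(maxit = max_epochs * 5L, reltol = tol))
    return(structure(list(theta = opt$par, hidden = hidden, mu = mu, sdev = sdev,
                          ybar = ybar, ysd = ysd, train_mse = opt$value * ysd^2,
                          columns = colnames(X)),
                     class = "bpnn_fit"))
  }
  fw <- bpnn_forward(theta, Xs, hidden)
  resid <- ys - fw$yhat
  cost <- mean(resid^2)
  lambda <- 1e-2
  converged <- FALSE
  for (epoch in seq_len(max_epochs)) {
    J <- bpnn_jacobian(fw, Xs, hidden)
    g <- crossprod(J, resid)
    if (max(abs(g)) < 1e-10) { converged <- TRUE; break }
    JtJ <- crossprod(J)
    improved <- FALSE
    while (lambda <= 1e12) {
      step <- tryCatch(solve(JtJ + diag(lambda, ntheta), g), error = function(e) NULL)
      if (!is.null(step)) {
        theta_new <- theta + drop(step)
        fw_new <- bpnn_forward(theta_new, Xs, hidden)
        resid_new <- ys - fw_new$yhat
        cost_new <- mean(resid_new^2)
        if (is.finite(cost_new) && cost_new < cost) {
          rel <- (cost - cost_new) / max(cost, 1e-30)
          theta <- theta_new; fw <- fw_new; resid <- resid_new; cost <- cost_new
          lambda <- max(lambda / 10, 1e-12)
          improved <- TRUE
          if (rel < tol) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved || converged) { converged <- converged || !improved; break }
  }
  if (!converged && cost > tol) {
    warning("Levenberg-Marquardt reached the epoch limit; returning best-so-far weights")
  }
  structure(list(theta = theta, hidden = hidden, mu = mu, sdev = sdev,
                 ybar = ybar, ysd = ysd, train_mse = cost * ysd^2,
                 columns = colnames(X)),
            class = "bpnn_fit")
}

#' @export
predict.bpnn_fit <- function(object, newdata, ...) {
  Xs <- sweep(sweep(as.matrix(newdata), 2L, object$mu), 2L, object$sdev, `/`)
  bpnn_forward(object$theta, Xs, object$hidden)$yhat * object$ysd + object$ybar
}

# ---------------------------------------------------------------------------
# Metrics and the experiment grid
# ---------------------------------------------------------------------------

#' Accuracy metrics of a prediction vector
#'
#' The three indicators of the evaluation protocol:
#' `R^2 = sum((yhat - mean(y))^2) / sum((y - mean(y))^2)` (regression sum of
#' squares over total sum of squares, as printed in the source protocol;
#' `conventional = TRUE` gives `1 - SSE/SST` instead),
#' `RMSE = sqrt(mean((yhat - y)^2))`, and
#' `MRE = 100/n * sum(|yhat - y| / y)` in percent.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @param conventional use `1 - SSE/SST` for R^2.
#' @return list with `r2`, `rmse`, `mre_percent`, `n`; `r2` is `NA` for a
#'   constant `y` and `mre_percent` is `NA` when any `y` is zero.
#' @examples
#' evaluate_predictions(c(4, 5, 6), c(5, 5, 5)) # rmse 0.8165, mre 13.89
#' @export
evaluate_predictions <- function(y, yhat, conventional = FALSE) {
  if (length(y) != length(yhat)) stop("y and yhat sizes differ")
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) NA_real_ else if (conventional) {
    1 - sum((yhat - y)^2) / sst
  } else {
    sum((yhat - mean(y))^2) / sst
  }
  mre <- if (any(y == 0)) NA_real_ else 100 * mean(abs(yhat - y) / abs(y))
  list(r2 = r2, rmse = sqrt(mean((yhat - y)^2)), mre_percent = mre, n = n)
}

#' Model registry dispatch
#'
#' Fits one of the three estimators with its configured hyperparameters.
#'
#' @param model `"PLSR"`, `"RF"` or `"BPNN"`.
#' @param X,y modeling data.
#' @param config list of per-model settings, see [default_model_config()].
#' @param seed integer seed.
#' @return a fitted predictor with a `predict` method.
#' @export
fit_model <- function(model, X, y, config = default_model_config(), seed = 1L) {
  switch(match.arg(model, c("PLSR", "RF", "BPNN")),
    PLSR = fit_plsr(X, y, max_lv = config$plsr$max_lv, folds = config$plsr$folds, seed = seed),
    RF   = fit_rf(X, y, ntree = config$rf$ntree, min_node = config$rf$min_node, seed = seed),
    BPNN = fit_bpnn(X, y, hidden = config$bpnn$hidden,
                    max_epochs = config$bpnn$max_epochs, tol = config$bpnn$tol, seed = seed))
}

#' Default hyperparameters of the estimation grid
#'
#' PLSR: up to 10 latent variables by 10-fold CV; RF: 600 trees; BPNN: 15
#' tanh hidden units trained by Levenberg-Marquardt.
#'
#' @return nested list of settings.
#' @export
default_model_config <- function() {
  list(plsr = list(max_lv = 10L, folds = 10L),
       rf = list(ntree = 600L, min_node = 5L),
       bpnn = list(hidden = 15L, max_epochs = 120L, tol = 1e-9))
}

#' Run the layer x combination x model estimation grid
#'
#' The end-to-end analysis on preprocessed data: per-layer dual-band pair
#' optimization, per-layer parameter matrices, significance screening into
#' the four combinations, a single shared modeling/validation split, and a
#' fit of every (layer, combination, model) cell with modeling and
#' validation metrics (3 x 4 x 3 = 36 cells, 72 metric rows).
#'
#' Pair search and screening use all samples pooled (the correlation stage
#' of the emulated protocol precedes the split).
#'
#' @param sp a `spectra` object (raw; smoothed internally).
#' @param lnc tidy LNC table covering the samples of `sp`.
#' @param stride search-grid stride in nm for the pair optimization
#'   (default 5; 1 searches the full grid).
#' @param alpha screening significance level.
#' @param seed master seed (split, model seeds).
#' @param models estimators to run.
#' @param model_config hyperparameters, see [default_model_config()].
#' @param window,order Savitzky-Golay settings.
#' @param fraction modeling fraction.
#' @return list with `pairs` (per-layer best-pair tables), `combos`,
#'   `split`, `metrics` (data.frame: layer, combination, label, model,
#'   split, r2 (the printed regression-SS form), r2_conv (conventional
#'   `1 - SSE/SST`), rmse, mre_percent, n, ncomp, seed) and `predictions`
#'   (per-cell data.frames of y / yhat).
#' @export
run_experiment_grid <- function(sp, lnc, stride = 5L, alpha = 0.05, seed = 1L,
                                models = c("PLSR", "RF", "BPNN"),
                                model_config = default_model_config(),
                                window = 9L, order = 4L, fraction = 2 / 3) {
  smoothed <- sg_smooth(sp, window, order)
  deriv <- first_derivative(smoothed)
  ids <- sample_ids(smoothed)
  layers <- c("CL", "LL", "RL")

  pairs_by_layer <- lapply(layers, function(ly) {
    optimize_pairs(smoothed, layer_target(lnc, ly, ids), stride = stride)
  })
  names(pairs_by_layer) <- layers

  params_by_layer <- lapply(layers, function(ly) {
    tab <- pairs_by_layer[[ly]]
    pl <- stats::setNames(lapply(seq_len(nrow(tab)), function(k) c(tab$i[k], tab$j[k])),
                          tab$formula)
    parameter_matrix(smoothed, pl, deriv)
  })
  names(params_by_layer) <- layers

  combos <- build_combinations(params_by_layer, lnc, alpha, layers)
  split <- split_modeling_validation(ids, fraction, seed)
  mod_idx <- match(split$modeling_ids, ids)
  val_idx <- match(split$validation_ids, ids)

  rows <- list(); preds <- list()
  for (ly in layers) {
    target <- layer_target(lnc, ly, ids)
    for (cb in names(combos[[ly]])) {
      members <- combos[[ly]][[cb]]$member
      label <- attr(combos[[ly]][[cb]], "label")
      if (length(members) == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          layer = ly, combination = cb, label = label, model = models,
          split = NA_character_, r2 = NA_real_, r2_conv = NA_real_, rmse = NA_real_,
          mre_percent = NA_real_, n = 0L, ncomp = NA_integer_,
          seed = split$seed, fitted = FALSE, stringsAsFactors = FALSE)
        next
      }
      Xall <- params_by_layer[[ly]][, members, drop = FALSE]
      # undefined sentinels propagate: rows with any undefined member are
      # excluded from this cell (never zero-filled)
      keep <- which(stats::complete.cases(Xall))
      cell_mod <- intersect(mod_idx, keep)
      cell_val <- intersect(val_idx, keep)
      for (mdl in models) {
        fit <- fit_model(mdl, Xall[cell_mod, , drop = FALSE], target[cell_mod],
                         model_config, seed = seed)
        for (spl in c("modeling", "validation")) {
          idx <- if (spl == "modeling") cell_mod else cell_val
          yhat <- predict(fit, Xall[idx, , drop = FALSE])
          met <- evaluate_predictions(target[idx], yhat)
          met_conv <- evaluate_predictions(target[idx], yhat, conventional = TRUE)
          rows[[length(rows) + 1L]] <- data.frame(
            layer = ly, combination = cb, label = label, model = mdl,
            split = spl, r2 = met$r2, r2_conv = met_conv$r2, rmse = met$rmse,
            mre_percent = met$mre_percent, n = met$n,
            ncomp = if (inherits(fit, "plsr_fit")) fit$ncomp else NA_integer_,
            seed = split$seed, fitted = TRUE, stringsAsFactors = FALSE)
          preds[[paste(ly, cb, mdl, spl, sep = ".")]] <- data.frame(
            sample_id = ids[idx], y = target[idx], yhat = yhat,
            split = spl, stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(pairs = pairs_by_layer, combos = combos, split = split,
       metrics = do.call(rbind, rows), predictions = preds)
}
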