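test_that("modeling/validation split respects the 2/3 convention", {
  ids <- sprintf("S%02d", 1:48)
  sp <- split_modeling_validation(ids, seed = 4)
  expect_length(sp$modeling_ids, 32L)
  expect_length(sp$validation_ids, 16L)
  expect_length(intersect(sp$modeling_ids, sp$validation_ids), 0L)
  expect_setequal(c(sp$modeling_ids, sp$validation_ids), ids)
  expect_identical(sp, split_modeling_validation(ids, seed = 4))
  expect_false(identical(sp$modeling_ids, split_modeling_validation(ids, seed = 5)$modeling_ids))
  expect_error(split_modeling_validation(ids, fraction = 1.2), "fraction")
  expect_error(split_modeling_validation(ids[1:4]), "at least 6")
})

test_that("PLSR recovers exact linear structure and reduces to OLS in 1D", {
  set.seed(10)
  n <- 40
  X <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 2 + 3 * X[, 1] - 1.5 * X[, 2]
  fit <- fit_plsr(X, y, seed = 2)
  expect_lte(fit$ncomp, 3L)
  Xv <- cbind(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  yv <- 2 + 3 * Xv[, 1] - 1.5 * Xv[, 2]
  expect_lt(max(abs(predict(fit, Xv) - yv)), 1e-6)
  expect_equal(evaluate_predictions(yv, predict(fit, Xv))$r2, 1, tolerance = 1e-6)
  # single column: predictions equal the simple regression line
  x1 <- matrix(rnorm(n), dimnames = list(NULL, "x"))
  y1 <- 1 + 0.5 * x1[, 1] + rnorm(n, 0, 0.1)
  f1 <- fit_plsr(x1, y1)
  expect_equal(f1$ncomp, 1L)
  ols <- lm(y1 ~ x1)
  expect_equal(unname(predict(f1, x1)), unname(fitted(ols)), tolerance = 1e-8)
  # constant y: constant prediction, zero rmse on the modeling set
  fc <- fit_plsr(X, rep(5, n))
  expect_equal(unname(predict(fc, X)), rep(5, n), tolerance = 1e-10)
  # rank-deficient X: latent variables capped, fit still finite
  Xr <- cbind(X, d = X[, 1] + X[, 2])
  fr <- fit_plsr(Xr, y, max_lv = 10)
  expect_true(all(is.finite(predict(fr, Xr))))
})

test_that("random forest approximates a step function and is seed-deterministic", {
  set.seed(20)
  n <- 200
  X <- cbind(x = runif(n, -1, 1), z = runif(n))
  y <- ifelse(X[, 1] > 0, 4, 1)
  tr <- sample(n, 140)
  fit <- fit_rf(X[tr, ], y[tr], ntree = 200, seed = 7)
  met <- evaluate_predictions(y[-tr], predict(fit, X[-tr, ]), conventional = TRUE)
  expect_gte(met$r2, 0.95)
  # seeded determinism
  fit2 <- fit_rf(X[tr, ], y[tr], ntree = 200, seed = 7)
  expect_identical(predict(fit, X), predict(fit2, X))
  # duplicating all rows leaves predictions essentially unchanged
  fit_dup <- fit_rf(X[tr, ][rep(1:140, 2), ], rep(y[tr], 2), ntree = 200, seed = 7)
  expect_gte(cor(predict(fit, X), predict(fit_dup, X)), 0.99)
  expect_error(fit_rf(X, y[-1]), "sizes differ")
})

test_that("BPNN fits linear and smooth nonlinear maps", {
  set.seed(30)
  n <- 80
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 1 + 2 * X[, 1] - X[, 2]
  fit <- fit_bpnn(X, y, hidden = 5, max_epochs = 200, seed = 3)
  expect_lt(mean((predict(fit, X) - y)^2), 1e-4)
  # same seed, same data: identical weights
  fit2 <- fit_bpnn(X, y, hidden = 5, max_epochs = 200, seed = 3)
  expect_identical(fit$theta, fit2$theta)
  # capacity check: sine of one feature
  set.seed(31)
  n2 <- 200
  Xs <- matrix(runif(n2, -2, 2), dimnames = list(NULL, "x"))
  ys <- sin(Xs[, 1])
  tr <- sample(n2, 140)
  fs <- suppressWarnings(fit_bpnn(Xs[tr, , drop = FALSE], ys[tr], hidden = 15,
                                  max_epochs = 300, seed = 5))
  met <- evaluate_predictions(ys[-tr], predict(fs, Xs[-tr, , drop = FALSE]),
                              conventional = TRUE)
  expect_gte(met$r2, 0.9)
})

test_that("metrics match the worked example and homogeneity identities", {
  perfect <- evaluate_predictions(c(4, 5, 6), c(4, 5, 6))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mre_percent, 0)
  m <- evaluate_predictions(c(4, 5, 6), c(5, 5, 5))
  expect_equal(m$rmse, 0.8165, tolerance = 1e-4)
  expect_equal(m$mre_percent, 13.89, tolerance = 1e-2)
  expect_equal(m$r2, 0)   # regression-SS form: constant predictions have no spread
  # scaling both y and yhat by c > 0: r2 and mre invariant, rmse scales
  y <- c(4, 5.5, 6.1, 4.8); yh <- c(4.2, 5.1, 6.4, 5.0)
  a <- evaluate_predictions(y, yh); b <- evaluate_predictions(3 * y, 3 * yh)
  expect_equal(b$r2, a$r2, tolerance = 1e-12)
  expect_equal(b$mre_percent, a$mre_percent, tolerance = 1e-12)
  expect_equal(b$rmse, 3 * a$rmse, tolerance = 1e-12)
  # sentinels
  expect_true(is.na(evaluate_predictions(c(2, 2, 2), c(1, 2, 3))$r2))
  expect_true(is.na(evaluate_predictions(c(0, 1, 2), c(1, 2, 3))$mre_percent))
})

test_that("regression-SS R2 equals squared Pearson r for OLS fits with intercept", {
  set.seed(40)
  for (k in 1:5) {
    x <- rnorm(25); y <- 1 + 0.8 * x + rnorm(25, 0, 0.5)
    yhat <- fitted(lm(y ~ x))
    expect_equal(evaluate_predictions(y, yhat)$r2, unname(cor(y, yhat))^2,
                 tolerance = 1e-10)
    # and equals the conventional form for OLS
    expect_equal(evaluate_predictions(y, yhat)$r2,
                 evaluate_predictions(y, yhat, conventional = TRUE)$r2,
                 tolerance = 1e-10)
  }
})

test_that("metrics are invariant under sample relabeling for all three models", {
  set.seed(50)
  n <- 30
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 2 + X[, 1] + 0.5 * X[, 2]^2 + rnorm(n, 0, 0.05)
  perm <- sample(n)
  for (mdl in c("PLSR", "RF", "BPNN")) {
    cfgs <- default_model_config()
    cfgs$rf$ntree <- 100L; cfgs$bpnn$max_epochs <- 50L
    fit <- fit_model(mdl, X, y, cfgs, seed = 1)
    m1 <- evaluate_predictions(y, predict(fit, X))
    m2 <- evaluate_predictions(y[perm], predict(fit, X[perm, , drop = FALSE]))
    expect_equal(m1$r2, m2$r2, tolerance = 1e-10, info = mdl)
    expect_equal(m1$mre_percent, m2$mre_percent, tolerance = 1e-10, info = mdl)
  }
})

test_that("BFGS fallback trains the same architecture to a comparable fit", {
  set.seed(60)
  n <- 60
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- 0.5 + X[, 1] - 2 * X[, 2]
  fit <- fit_bpnn(X, y, hidden = 5, max_epochs = 200, seed = 2, method = "bfgs")
  expect_lt(mean((predict(fit, X) - y)^2), 1e-3)
})

test_that("stratified split keeps the fraction within every stratum", {
  ids <- sprintf("S%02d", 1:48)
  strata <- rep(rep(c("A", "B", "C", "D"), each = 6), 2)
  sp <- split_modeling_validation(ids, seed = 11, strata = strata)
  expect_length(sp$modeling_ids, 32L)
  tab <- table(strata[match(sp$modeling_ids, ids)])
  expect_true(all(tab == 8L))  # 2/3 of each 12-sample stratum
  expect_identical(sp, split_modeling_validation(ids, seed = 11, strata = strata))
  expect_error(split_modeling_validation(ids, strata = strata[-1]), "align")
})
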