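test_that("regression metrics match their closed forms", {
  y <- c(10, 20, 30, 40)
  yhat <- c(12, 18, 33, 39)
  m <- regressionMetrics(y, yhat)
  expect_equal(m[["r2"]], 1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
  resid <- y - yhat
  expect_equal(m[["explained_variance"]],
               1 - mean((resid - mean(resid))^2) / mean((y - mean(y))^2))
  expect_equal(m[["neg_mean_absolute_error"]], -mean(abs(resid)))
  expect_equal(m[["neg_median_absolute_error"]], -median(abs(resid)))
  ## perfect prediction on constant truth
  expect_equal(regressionMetrics(c(5, 5), c(5, 5))[["r2"]], 1)
  expect_equal(regressionMetrics(c(5, 5), c(4, 6))[["r2"]], 0)
})

test_that("an unpruned tree memorizes its training data", {
  X <- matrix(seq(0, 9), ncol = 1, dimnames = list(NULL, "x"))
  y <- 3 * X[, 1] + 7
  fit <- fitSurvivalModel(modelSpec("dtr"), X, y)
  expect_equal(predictSurvival(fit, X), y, tolerance = 1e-12)
})

test_that("linear SVR recovers a noiseless linear relationship", {
  X <- matrix(1:20, ncol = 1, dimnames = list(NULL, "x"))
  y <- 2 * X[, 1]
  fit <- fitSurvivalModel(modelSpec("svr_linear"), X, y)
  m <- regressionMetrics(y, predictSurvival(fit, X))
  expect_gte(m[["r2"]], 0.99)
})

test_that("constant targets fit with a warning and predict the constant", {
  X <- matrix(rnorm(20), ncol = 2)
  colnames(X) <- c("a", "b")
  y <- rep(12, 10)
  for (fam in c("svr_rbf", "dtr")) {
    expect_warning(fit <- fitSurvivalModel(modelSpec(fam), X, y),
                   "degenerate")
    expect_equal(predictSurvival(fit, X), y, tolerance = 0.2)
  }
})

test_that("prediction respects row order and feature dimension", {
  set.seed(2)
  X <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("a", "b")))
  y <- X[, 1] + rnorm(20, 0, 0.1)
  for (fam in c("svr_rbf", "svr_linear", "svr_poly", "dtr")) {
    fit <- fitSurvivalModel(modelSpec(fam), X, y)
    pred <- predictSurvival(fit, X)
    expect_length(pred, 20L)
    expect_true(all(is.finite(pred)))
    perm <- sample(20)
    expect_equal(predictSurvival(fit, X[perm, ]), pred[perm])
    expect_identical(predictSurvival(fit, X[0, , drop = FALSE]), numeric())
    expect_error(predictSurvival(fit, X[, 1, drop = FALSE]), "dimension")
  }
})

test_that("cross-validation validates every row exactly once", {
  set.seed(4)
  X <- matrix(rnorm(60), ncol = 2,
              dimnames = list(sprintf("r%02d", 1:30), c("a", "b")))
  y <- 2 * X[, 1] - X[, 2] + rnorm(30, 0, 0.2)
  rep1 <- crossValidate(X, y, k = 5, seed = 99)
  folds <- foldAssignment(rep1)
  expect_identical(sort(names(folds)), sort(rownames(X)))
  sizes <- as.integer(table(folds))
  expect_identical(sum(sizes), 30L)
  expect_lte(max(sizes) - min(sizes), 1L)

  ## leave-one-out: n folds of size 1
  loo <- crossValidate(X[1:6, ], y[1:6],
                       specs = defaultModelSpecs()["svr_linear"],
                       k = 6, seed = 1)
  expect_identical(as.integer(table(foldAssignment(loo))), rep(1L, 6))

  expect_error(crossValidate(X[1:3, ], y[1:3], k = 5), "k <= n")
})

test_that("report aggregation matches per-fold recomputation", {
  set.seed(8)
  X <- matrix(rnorm(80), ncol = 2,
              dimnames = list(sprintf("r%02d", 1:40), c("a", "b")))
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(40, 0, 0.3)
  specs <- defaultModelSpecs()[c("svr_linear", "dtr")]
  rep1 <- crossValidate(X, y, specs = specs, k = 4, seed = 7)
  folds <- foldAssignment(rep1)
  for (nm in names(specs)) {
    perFold <- t(vapply(1:4, function(f) {
      tr <- folds != f
      fit <- fitSurvivalModel(specs[[nm]], X[tr, , drop = FALSE], y[tr])
      regressionMetrics(y[!tr], predictSurvival(fit, X[!tr, , drop = FALSE]))
    }, numeric(4)))
    m <- cvMetrics(rep1)
    m <- m[m$model == nm & m$split == "test", ]
    for (i in seq_len(nrow(m))) {
      expect_equal(m$mean[i], mean(perFold[, m$metric[i]]))
      expect_equal(m$sd[i], sd(perFold[, m$metric[i]]))
    }
  }
  ## identical seed, identical report
  rep2 <- crossValidate(X, y, specs = specs, k = 4, seed = 7)
  expect_identical(cvMetrics(rep1), cvMetrics(rep2))
  expect_identical(foldAssignment(rep1), foldAssignment(rep2))
})

test_that("validation subsets are seeded, sized and stratified", {
  tab <- data.frame(sampleId = sprintf("p%03d", 1:100),
                    stage = 2L, size = 10L, age = 30L, composite = 0,
                    normalized = seq(-2, 2, length.out = 100), group = 1L)
  ticf <- new("TICFTable", table = tab,
              state = new("NormalizationState", mean = 0, sd = 1,
                          degenerate = FALSE),
              widths = c(1L, 3L, 3L), k = 5L)
  sub <- sampleValidationSubset(ticf, fraction = 0.25, seed = 3)
  expect_identical(nrow(sub), 25L)
  expect_identical(sort(unique(sub$group)), 1:5)
  expect_identical(sampleValidationSubset(ticf, fraction = 0.25, seed = 3),
                   sub)
  full <- sampleValidationSubset(ticf, fraction = 1, seed = 3)
  expect_identical(nrow(full), 100L)
  expect_error(sampleValidationSubset(ticf, fraction = 0), "fraction")
  expect_error(sampleValidationSubset(ticf, fraction = 1.2), "fraction")
})
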