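## Survival-time regression: SVR (RBF / linear / polynomial kernels) and
## decision-tree regression over enriched cohorts, k-fold cross-validation
## with four metrics, the ablation grid, and validation subsampling.

#' Construct a model specification
#'
#' @param family `"svr_rbf"`, `"svr_linear"`, `"svr_poly"` or `"dtr"`.
#' @param ... hyperparameters: `C` (cost, default 1), `epsilon` (default
#'   0.1), `gamma` (default `1/n_features`), `degree` (default 3,
#'   polynomial kernel), `maxDepth` (default 30, decision tree; the tree
#'   is otherwise grown without pruning).
#' @param seed RNG seed applied before fitting.
#' @return A [ModelSpec-class].
#' @export
modelSpec <- function(family, ..., seed = 42L) {
  new("ModelSpec", family = family, hyperparameters = list(...),
      seed = as.integer(seed))
}

#' Default specifications of the four model families
#'
#' @param seed RNG seed shared by all four specifications.
#' @return named list of [ModelSpec-class] objects.
#' @export
defaultModelSpecs <- function(seed = 42L) {
  list(svr_rbf = modelSpec("svr_rbf", seed = seed),
       svr_linear = modelSpec("svr_linear", seed = seed),
       svr_poly = modelSpec("svr_poly", seed = seed),
       dtr = modelSpec("dtr", seed = seed))
}

hyper <- function(spec, name, default) {
  v <- spec@hyperparameters[[name]]
  if (is.null(v)) default else v
}

#' Fit a survival-time regression model
#'
#' @param spec a [ModelSpec-class].
#' @param X numeric feature matrix (no missing values).
#' @param y survival months, one per row of `X` (>= 2 rows).
#' @return fitted model object (class `SurvivalFit`) usable with
#'   [predictSurvival()].
#' @export
fitSurvivalModel <- function(spec, X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2L, !anyNA(X))
  if (anyNA(y)) stop("targets must not contain missing values")
  if (stats::var(y) == 0) {
    ## every target equal: SVR has no support vectors; fall back to the
    ## constant predictor the models would converge to anyway
    warning("degenerate all-equal targets; fitting a constant predictor")
    return(structure(list(fit = NULL, family = spec@family,
                          features = colnames(X), trainCols = NULL,
                          constant = y[1L], p = ncol(X)),
                     class = "SurvivalFit"))
  }
  set.seed(spec@seed)
  trainCols <- NULL
  fit <- if (spec@family == "dtr") {
    df <- data.frame(.y = y, X, check.names = TRUE)
    trainCols <- colnames(df)[-1L]
    rpart::rpart(.y ~ ., data = df, method = "anova",
                 control = rpart::rpart.control(
                   minsplit = 2L, minbucket = 1L, cp = 0,
                   maxdepth = hyper(spec, "maxDepth", 30L), xval = 0L))
  } else {
    kernel <- switch(spec@family, svr_rbf = "radial",
                     svr_linear = "linear", svr_poly = "polynomial")
    e1071::svm(x = X, y = y, type = "eps-regression", kernel = kernel,
               cost = hyper(spec, "C", 1.0),
               epsilon = hyper(spec, "epsilon", 0.1),
               gamma = hyper(spec, "gamma", 1 / ncol(X)),
               degree = hyper(spec, "degree", 3L),
               scale = FALSE)
  }
  structure(list(fit = fit, family = spec@family,
                 features = colnames(X), trainCols = trainCols,
                 p = ncol(X)),
            class = "SurvivalFit")
}

#' Predict survival months
#'
#' @param model a fitted model from [fitSurvivalModel()].
#' @param X feature matrix with the training feature dimension.
#' @return numeric vector, one prediction per row, in row order.
#' @export
predictSurvival <- function(model, X) {
  X <- as.matrix(X)
  if (!nrow(X)) return(numeric())
  if (ncol(X) != model$p)
    stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                 model$p, ncol(X)))
  if (is.null(model$fit)) {
    rep(model$constant, nrow(X))
  } else if (model$family == "dtr") {
    df <- data.frame(X, check.names = TRUE)
    colnames(df) <- model$trainCols
    as.numeric(stats::predict(model$fit, newdata = df))
  } else {
    as.numeric(stats::predict(model$fit, newdata = X))
  }
}

#' Regression metrics
#'
#' The four cross-validation metrics: coefficient of determination (r2),
#' explained variance, negative mean absolute error and negative median
#' absolute error. On a constant truth vector, r2 and explained variance
#' are 1 for a perfect prediction and 0 otherwise.
#'
#' @param y true survival months.
#' @param yhat predictions.
#' @return named numeric vector of the four metrics.
#' @export
regressionMetrics <- function(y, yhat) {
  ssRes <- sum((y - yhat)^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else as.numeric(ssRes == 0)
  resid <- y - yhat
  varRes <- mean((resid - mean(resid))^2)   # population variance: a
  varY <- mean((y - mean(y))^2)             # size-1 fold is defined (0)
  ev <- if (varY > 0) 1 - varRes / varY else as.numeric(ssRes == 0)
  c(r2 = r2, explained_variance = ev,
    neg_mean_absolute_error = -mean(abs(y - yhat)),
    neg_median_absolute_error = -stats::median(abs(y - yhat)))
}

METRIC_NAMES <- c("r2", "explained_variance", "neg_mean_absolute_error",
                  "neg_median_absolute_error")

#' k-fold cross-validation of the survival models
#'
#' Shuffles the rows once (seeded), cuts them into `k` folds whose sizes
#' differ by at most one, and, for every model specification and fold,
#' fits on the remaining folds and scores on the held-out fold, so every
#' row is validated exactly once. Metrics are reported as mean and SD
#' over folds, on the held-out fold (`split == "test"`) and, separately,
#' on the training folds (`split == "train"`).
#'
#' @param X feature matrix.
#' @param y survival months (no NA; filter beforehand).
#' @param specs list of [ModelSpec-class] objects.
#' @param k number of folds (default 5; `2 <= k <= n`).
#' @param seed partition seed.
#' @return A [CVReport-class].
#' @export
crossValidate <- function(X, y, specs = defaultModelSpecs(), k = 5L,
                          seed = 42L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (anyNA(y)) stop("targets must not contain missing values")
  if (k < 2L || n < k)
    stop(sprintf("need 2 <= k <= n rows; got k=%d, n=%d", k, n))
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  folds <- integer(n)
  folds[perm] <- rep(seq_len(k), times = sizes)

  if (is.null(names(specs)))
    names(specs) <- vapply(specs, function(s) s@family, character(1L))
  rows <- list()
  for (nm in names(specs)) {
    testM <- matrix(NA_real_, nrow = k, ncol = length(METRIC_NAMES),
                    dimnames = list(NULL, METRIC_NAMES))
    trainM <- testM
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- fitSurvivalModel(specs[[nm]], X[tr, , drop = FALSE], y[tr])
      testM[f, ] <- regressionMetrics(
        y[!tr], predictSurvival(fit, X[!tr, , drop = FALSE]))
      trainM[f, ] <- regressionMetrics(
        y[tr], predictSurvival(fit, X[tr, , drop = FALSE]))
    }
    sdOr0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
    for (split in c("test", "train")) {
      m <- if (split == "test") testM else trainM
      rows[[paste(nm, split)]] <- data.frame(
        model = nm, metric = METRIC_NAMES, split = split,
        mean = colMeans(m), sd = apply(m, 2L, sdOr0),
        stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  names(folds) <- rownames(X)
  new("CVReport", metrics = metrics, k = k, n = as.integer(n),
      seed = as.integer(seed), folds = folds)
}

#' Representative seed patient of a cohort
#'
#' The TICF-defined patient at the median normalized TICF (lower median;
#' ties broken by sample id) — a deterministic default for per-patient
#' enrichment demonstrations and the ablation grid.
#'
#' @param ticf a [TICFTable-class].
#' @return a sample id.
#' @export
defaultSeedPatient <- function(ticf) {
  tab <- ticf@table
  ord <- order(tab$normalized, tab$sampleId)
  tab$sampleId[ord[(nrow(tab) + 1L) %/% 2L]]
}

#' The ablation grid over the TICF and network axes
#'
#' Cross-validates the four survival models under four configurations
#' around one studied patient: the full framework (TICF composite +
#' network-enriched cohort with protein indicators), the composite
#' replaced by the separate stage/size/age columns (still enriched), and
#' both feature sets on the un-enriched ring-0 cohort with no protein
#' indicators. All configurations use the same partition seed, so
#' configurations sharing a cohort share fold partitions exactly (a
#' paired comparison); the enriched and un-enriched cohorts necessarily
#' differ in size, hence in partition.
#'
#' @param network an [IntegratedNetwork-class] (trusted flags set).
#' @param ticf a [TICFTable-class].
#' @param documents all documents.
#' @param seedPatient studied patient (default: [defaultSeedPatient()]).
#' @param specs model specifications.
#' @param k folds.
#' @param seed partition seed shared by all configurations.
#' @return named list (`main`, `separate_network`, `ticf_only`,
#'   `separate_only`), each with elements `cohort`
#'   (an [EnrichedCohort-class]) and `report` (a [CVReport-class]).
#' @export
runAblation <- function(network, ticf, documents, seedPatient = NULL,
                        specs = defaultModelSpecs(), k = 5L, seed = 42L) {
  if (is.null(seedPatient)) seedPatient <- defaultSeedPatient(ticf)
  grid <- list(
    main = list(features = "composite", expand = TRUE),
    separate_network = list(features = "separate", expand = TRUE),
    ticf_only = list(features = "composite", expand = FALSE),
    separate_only = list(features = "separate", expand = FALSE))
  lapply(grid, function(gc) {
    cohort <- enrichCohort(seedPatient, network, ticf, documents,
                           clinicalFeatures = gc$features,
                           expand = gc$expand)
    y <- survivalTargets(cohort)
    obs <- !is.na(y)
    report <- crossValidate(featureMatrix(cohort)[obs, , drop = FALSE],
                            y[obs], specs = specs, k = k, seed = seed)
    list(cohort = cohort, report = report)
  })
}

#' Held-out mean of one metric, averaged over models
#'
#' Convenience summary used to compare ablation configurations: the mean
#' over folds of a held-out metric, averaged across model families.
#'
#' @param report a [CVReport-class].
#' @param metric metric name (default `"r2"`).
#' @param models model subset (default: all in the report).
#' @return a single number.
#' @export
meanHeldOutMetric <- function(report, metric = "r2", models = NULL) {
  m <- report@metrics
  m <- m[m$split == "test" & m$metric == metric, ]
  if (!is.null(models)) m <- m[m$model %in% models, ]
  mean(m$mean)
}

#' Seeded validation subset
#'
#' Uniformly samples (without replacement) a fraction of the TICF-defined
#' patients and stratifies the subset into `k` subgroups by normalized
#' TICF.
#'
#' @param ticf a [TICFTable-class].
#' @param fraction fraction of patients to keep, in (0, 1] (default 0.25).
#' @param k number of subgroups (default 5).
#' @param seed sampling seed.
#' @return data.frame(sampleId, normalized, group), sorted by sampleId.
#' @export
sampleValidationSubset <- function(ticf, fraction = 0.25, k = 5L,
                                   seed = 42L) {
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  tab <- ticf@table
  m <- ceiling(fraction * nrow(tab))
  set.seed(seed)
  keep <- sort(sample.int(nrow(tab), m))
  sub <- tab[keep, , drop = FALSE]
  groups <- stratifyPatients(sub$normalized, sub$sampleId, k = k)
  out <- data.frame(sampleId = sub$sampleId, normalized = sub$normalized,
                    group = as.integer(groups), stringsAsFactors = FALSE)
  out[order(out$sampleId), , drop = FALSE]
}
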