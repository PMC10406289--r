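# Per-metric regression surrogates: support vector regression (e1071), a
# kernel-weighted Minkowski k-nearest-neighbour regressor, and random forests
# (ranger); random-search hyperparameter tuning under 10-fold CV, model
# selection on the test partition, final error reporting on the validation
# partition (three-way holdout).

#' Regression error metrics
#'
#' Root mean squared error, root relative squared error (RMSE of the model
#' over RMSE of the constant-mean predictor) and root mean squared logarithmic
#' error.
#'
#' @param y Truth vector (length >= 2).
#' @param yhat Prediction vector of equal length; RMSLE requires all values
#'   `> -1`.
#' @return Named vector `(rmse, rrse, rmsle)`.
#' @export
error_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  rmse <- sqrt(mean((yhat - y)^2))
  den <- sum((y - mean(y))^2)
  if (den == 0) stop("constant truth vector: RRSE undefined", call. = FALSE)
  rrse <- sqrt(sum((yhat - y)^2) / den)
  rmsle <- if (all(y > -1) && all(yhat > -1))
    sqrt(mean((log1p(yhat) - log1p(y))^2)) else NA_real_
  c(rmse = rmse, rrse = rrse, rmsle = rmsle)
}

#' Hyperparameter search space
#'
#' Ranges searched by [tune_model()]: kNN distance exponent in `[0.1, 20]`
#' with a neighbour-weighting kernel; SVR stopping tolerance in
#' `[0.001, 0.9]`, epsilon in `[0.1, 0.9]` and a kernel; random-forest depth
#' in `{0..20}` (0 = unlimited) and 1-20 trees.  `budget` random draws are
#' evaluated per model type.
#'
#' @param budget Evaluations per model type.
#' @return Named list of per-model ranges.
#' @export
hyperparameter_space <- function(budget = 200L) {
  list(
    knn = list(distance = c(0.1, 20),
               kernel = c("rectangular", "triangular", "gaussian")),
    svr = list(tolerance = c(0.001, 0.9), epsilon = c(0.1, 0.9),
               kernel = c("radial", "linear", "polynomial")),
    rf = list(max_depth = 0:20, n_trees = 1:20),
    budget = as.integer(budget)
  )
}

.draw_hp <- function(model_type, space) {
  s <- space[[model_type]]
  switch(model_type,
    knn = list(distance = stats::runif(1, s$distance[1], s$distance[2]),
               kernel = sample(s$kernel, 1)),
    svr = list(tolerance = stats::runif(1, s$tolerance[1], s$tolerance[2]),
               epsilon = stats::runif(1, s$epsilon[1], s$epsilon[2]),
               kernel = sample(s$kernel, 1)),
    rf = list(max_depth = sample(s$max_depth, 1), n_trees = sample(s$n_trees, 1)))
}

# ---- preprocessing: z-score the numeric inputs, drop constant columns ----

.make_scaler <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  keep <- which(sd_ > 0)
  list(mu = mu, sd = sd_, keep = keep)
}

.apply_scaler <- function(scaler, X) {
  X <- as.matrix(X)[, scaler$keep, drop = FALSE]
  sweep(sweep(X, 2, scaler$mu[scaler$keep]), 2, scaler$sd[scaler$keep], "/")
}

# ---- model fitting / prediction, one interface per model type ----

.fit_one <- function(model_type, hp, X, y, seed = 1L) {
  scaler <- .make_scaler(X)
  Xs <- .apply_scaler(scaler, X)
  fit <- switch(model_type,
    svr = {
      ymu <- mean(y); ysd <- max(stats::sd(y), .Machine$double.eps)
      m <- e1071::svm(x = Xs, y = (y - ymu) / ysd, type = "eps-regression",
                      kernel = hp$kernel, tolerance = hp$tolerance,
                      epsilon = hp$epsilon, scale = FALSE)
      list(model = m, ymu = ymu, ysd = ysd)
    },
    knn = list(X = Xs, y = y, distance = hp$distance, kernel = hp$kernel,
               k = min(7L, nrow(Xs) - 1L)),
    rf = {
      dat <- data.frame(Xs, .y = y, check.names = FALSE)
      ranger::ranger(dependent.variable.name = ".y", data = dat,
                     num.trees = hp$n_trees,
                     max.depth = if (hp$max_depth == 0) NULL else hp$max_depth,
                     seed = seed, num.threads = 1)
    },
    stop("unknown model type: ", model_type, call. = FALSE))
  structure(list(type = model_type, hp = hp, scaler = scaler, fit = fit),
            class = "surrogate_fit")
}

# kernel-weighted Minkowski kNN regression (kknn-style learner)
.knn_predict <- function(fit, Xs) {
  p <- fit$distance
  k <- fit$k
  apply(Xs, 1, function(q) {
    d <- (rowSums(abs(sweep(fit$X, 2, q))^p))^(1 / p)
    ord <- order(d)[seq_len(k)]
    dk <- d[ord]
    h <- max(dk[k], .Machine$double.eps)
    u <- dk / h
    w <- switch(fit$kernel,
                rectangular = rep(1, k),
                triangular = pmax(1 - u, 0),
                gaussian = exp(-0.5 * (3 * u)^2))
    if (sum(w) <= 0) w <- rep(1, k)
    sum(w * fit$y[ord]) / sum(w)
  })
}

#' @export
predict.surrogate_fit <- function(object, newdata, ...) {
  Xs <- .apply_scaler(object$scaler, newdata)
  switch(object$type,
    svr = as.numeric(stats::predict(object$fit$model, Xs)) * object$fit$ysd +
      object$fit$ymu,
    knn = .knn_predict(object$fit, Xs),
    rf = stats::predict(object$fit, data.frame(Xs, check.names = FALSE),
                        num.threads = 1)$predictions)
}

#' Random-search hyperparameter tuning under 10-fold cross-validation
#'
#' Draws `space$budget` hyperparameter sets uniformly from the ranges, scores
#' each by the mean RMSE over 10 cross-validation folds of the training rows,
#' and returns the argmin.  Deterministic under the seed.
#'
#' @param model_type `"svr"`, `"knn"` or `"rf"`.
#' @param X Training input matrix.
#' @param y Training target vector.
#' @param space [hyperparameter_space()].
#' @param seed Integer seed.
#' @param folds Number of CV folds.
#' @return List `(hp, cv_rmse)` of the best draw.
#' @export
tune_model <- function(model_type, X, y, space = hyperparameter_space(),
                       seed = 1L, folds = 10L) {
  if (space$budget < 1) stop("tuning budget must be >= 1", call. = FALSE)
  n <- nrow(X)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  folds <- min(folds, n)
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  best <- NULL
  for (b in seq_len(space$budget)) {
    hp <- .draw_hp(model_type, space)
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (sum(tr) < 2 || stats::sd(y[tr]) == 0) return(NA_real_)
      fit <- tryCatch(.fit_one(model_type, hp, X[tr, , drop = FALSE], y[tr],
                               seed = seed + b),
                      error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      yh <- predict(fit, X[!tr, , drop = FALSE])
      sqrt(mean((yh - y[!tr])^2))
    }, numeric(1))
    score <- mean(errs, na.rm = TRUE)
    if (is.finite(score) && (is.null(best) || score < best$cv_rmse))
      best <- list(hp = hp, cv_rmse = score)
  }
  if (is.null(best)) stop("all tuning draws failed", call. = FALSE)
  best
}

#' Train, select and validate per-metric surrogates
#'
#' For every metric: tune all three model types on the training partition
#' (10-fold CV random search), score the tuned models on the test partition,
#' pick the best by test RMSE, and report the winner's errors on the
#' validation partition.  Only the selected model ever touches the validation
#' rows, and validation rows never influence tuning or selection.
#'
#' @param table A split `training_table` (see [split_table()]).
#' @param space [hyperparameter_space()].
#' @param seed Integer seed.
#' @param metrics Metrics to model (default all twelve).
#' @return Object of class `surrogate_models`: per-metric list with the
#'   fitted winner, its type and hyperparameters, test errors of all
#'   candidates, and validation errors of the winner; plus the input ranges
#'   of the training table (used for goal normalization).
#' @export
select_and_validate <- function(table, space = hyperparameter_space(),
                                seed = 1L, metrics = metric_names()) {
  if (!"split" %in% names(table))
    stop("table has no split labels; run split_table() first", call. = FALSE)
  X <- as.matrix(table[, .input_names()])
  tr <- table$split == "train"
  te <- table$split == "test"
  va <- table$split == "validation"
  models <- list()
  for (m in metrics) {
    y <- table[[m]]
    cands <- list()
    for (ty in c("svr", "knn", "rf")) {
      tuned <- tune_model(ty, X[tr, , drop = FALSE], y[tr], space,
                          seed = derive_seed(seed, "tune") + match(m, metrics))
      fit <- .fit_one(ty, tuned$hp, X[tr, , drop = FALSE], y[tr],
                      seed = derive_seed(seed, "tune"))
      test_err <- error_metrics(y[te], predict(fit, X[te, , drop = FALSE]))
      cands[[ty]] <- list(fit = fit, hp = tuned$hp, cv_rmse = tuned$cv_rmse,
                          test = test_err)
    }
    test_rmse <- vapply(cands, function(c) c$test[["rmse"]], numeric(1))
    win <- names(which.min(test_rmse))
    val_err <- error_metrics(y[va], predict(cands[[win]]$fit,
                                            X[va, , drop = FALSE]))
    models[[m]] <- list(metric = m, type = win, hp = cands[[win]]$hp,
                        fit = cands[[win]]$fit,
                        test_errors = lapply(cands, `[[`, "test"),
                        validation = val_err)
  }
  ranges <- apply(X, 2, range)
  metric_ranges <- vapply(metrics, function(m) range(table[[m]]), numeric(2))
  structure(list(models = models, input_ranges = ranges,
                 metric_ranges = metric_ranges, seed = seed),
            class = "surrogate_models")
}

#' Predict all metrics for one or more sequence vectors
#'
#' @param models A [select_and_validate()] result.
#' @param x A named numeric vector from [sequence_vector()], or a matrix with
#'   those columns (one row per candidate).
#' @return Named metric vector, or a matrix with one row per candidate.
#' @export
predict_metrics <- function(models, x) {
  stopifnot(inherits(models, "surrogate_models"))
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1,
                                       dimnames = list(NULL, names(x)))
  X <- X[, .input_names(), drop = FALSE]
  out <- vapply(names(models$models), function(m)
    predict(models$models[[m]]$fit, X), numeric(nrow(X)))
  if (!is.matrix(out)) out <- matrix(out, nrow = nrow(X),
                                     dimnames = list(NULL, names(models$models)))
  if (nrow(X) == 1) out[1, ] else out
}

#' @export
print.surrogate_models <- function(x, ...) {
  cat("<surrogate_models>\n")
  for (m in names(x$models)) {
    mm <- x$models[[m]]
    cat(sprintf("  %-16s %-4s val rmse %.4g  rrse %.3g\n", m, mm$type,
                mm$validation[["rmse"]], mm$validation[["rrse"]]))
  }
  invisible(x)
}

#' Principal component analysis summary
#'
#' Standardizes the columns (constant columns are dropped with a warning) and
#' reports per-component standard deviation, proportion of variance and
#' cumulative proportion.
#'
#' @param X Numeric matrix (>= 2 rows and columns).
#' @return `data.frame` with one row per component.
#' @export
pca_summary <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2, ncol(X) >= 2)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
    X <- X[, sds > 0, drop = FALSE]
  }
  p <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  v <- p$sdev^2
  data.frame(component = seq_along(v), sd = p$sdev,
             proportion = v / sum(v), cumulative = cumsum(v) / sum(v))
}
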