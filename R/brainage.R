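#' Residualize feature columns on covariates
#'
#' Replaces every feature column with its least-squares residual on an
#' intercept plus the covariate columns, so downstream models see volume
#' variation orthogonal to the nuisance terms (sex, ethnicity, handedness,
#' BMI, alcohol, TIV, site, education in the default pipeline).
#'
#' @param features Numeric matrix / data frame, subjects x regions, no `NA`.
#' @param covariates Numeric matrix / data frame of covariates.
#' @return Numeric residual matrix with the original column names.
#' @export
residualize <- function(features, covariates) {
  f <- as.matrix(as.data.frame(features))
  storage.mode(f) <- "double"
  if (anyNA(f)) stop_bagprs("features must not contain NA.", "bagprs_invalid_config")
  cm <- covariate_matrix(covariates, nrow(f))
  res <- ls_residuals(cm, f)
  colnames(res) <- colnames(f)
  res
}

default_brainage_grid <- function() {
  expand.grid(max_depth = c(2, 4, 6), eta = c(0.05, 0.1), nrounds = c(100, 300))
}

# seeded fold assignment, stratified by age decile
make_folds <- function(age, k, seed) {
  set.seed(seed)
  fold <- integer(length(age))
  decile <- dplyr::ntile(age, 10)
  for (d in unique(decile)) {
    idx <- sample(which(decile == d))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

xgb_fit <- function(x, y, max_depth, eta, nrounds, seed) {
  set.seed(seed)
  xgboost::xgb.train(
    params = list(
      max_depth = max_depth, eta = eta, objective = "reg:squarederror",
      nthread = 1, subsample = 1, colsample_bytree = 1
    ),
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = nrounds, verbose = 0
  )
}

#' Fit a brain-age model under nested cross-validation
#'
#' Gradient-boosted tree regression of chronological age on residualized
#' regional volumes. The outer loop partitions subjects once (seeded shuffle,
#' stratified by age decile); within each outer training set an inner
#' cross-validation over `param_grid` picks the hyperparameters minimizing
#' mean inner MAE; the refit model predicts the held-out fold, so every
#' subject receives exactly one out-of-fold prediction. The per-fold models
#' are retained as an ensemble for predicting new cohorts.
#'
#' @param features Residualized feature matrix (see [residualize()]).
#' @param age Chronological age vector (years).
#' @param n_outer_folds,n_inner_folds Fold counts (default 5 and 5).
#' @param param_grid Data frame with columns `max_depth`, `eta`, `nrounds`;
#'   `NULL` uses depth \{2,4,6\} x eta \{0.05,0.1\} x rounds \{100,300\}.
#' @param seed Integer seed controlling folds and model fitting.
#' @return A `brainage_fit`: `models` (per-outer-fold boosters), `oof` tibble
#'   (`age`, `predicted`, `bag`, `fold`), `chosen_params`, `metrics`
#'   ([fit_metrics()] on the out-of-fold predictions), `feature_names`.
#' @export
fit_brainage <- function(features, age, n_outer_folds = 5, n_inner_folds = 5,
                         param_grid = NULL, seed = 1L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  stopifnot(length(age) == n)
  if (n < n_outer_folds) {
    stop_bagprs("fewer subjects than outer folds.", "bagprs_invalid_config")
  }
  if (is.null(param_grid) || nrow(as.data.frame(param_grid)) == 0) {
    param_grid <- default_brainage_grid()
  }
  param_grid <- as.data.frame(param_grid)
  seed <- as.integer(seed)

  outer <- make_folds(age, n_outer_folds, seed)
  if (min(table(outer)) < 2) {
    stop_bagprs("an outer fold has fewer than 2 subjects.", "bagprs_invalid_config")
  }
  oof <- rep(NA_real_, n)
  models <- vector("list", n_outer_folds)
  chosen <- vector("list", n_outer_folds)

  for (f in seq_len(n_outer_folds)) {
    tr <- which(outer != f)
    te <- which(outer == f)
    best_row <- 1L
    if (nrow(param_grid) > 1) {
      inner <- make_folds(age[tr], n_inner_folds, seed + 100L * f)
      maes <- vapply(seq_len(nrow(param_grid)), function(g) {
        pg <- param_grid[g, ]
        errs <- vapply(seq_len(n_inner_folds), function(i) {
          itr <- tr[inner != i]
          ite <- tr[inner == i]
          mdl <- xgb_fit(x[itr, , drop = FALSE], age[itr], pg$max_depth,
                         pg$eta, pg$nrounds, seed + 7L * f + i)
          mean(abs(predict(mdl, x[ite, , drop = FALSE]) - age[ite]))
        }, numeric(1))
        mean(errs)
      }, numeric(1))
      best_row <- which.min(maes)
    }
    pg <- param_grid[best_row, ]
    mdl <- xgb_fit(x[tr, , drop = FALSE], age[tr], pg$max_depth, pg$eta,
                   pg$nrounds, seed + 1000L * f)
    models[[f]] <- mdl
    chosen[[f]] <- tibble::tibble(fold = f, max_depth = pg$max_depth,
                                  eta = pg$eta, nrounds = pg$nrounds)
    oof[te] <- predict(mdl, x[te, , drop = FALSE])
  }

  structure(
    list(
      models = models,
      oof = tibble::tibble(age = age, predicted = oof, bag = oof - age,
                           fold = outer),
      chosen_params = dplyr::bind_rows(chosen),
      metrics = fit_metrics(oof, age),
      feature_names = colnames(x),
      seed = seed
    ),
    class = "brainage_fit"
  )
}

#' @export
print.brainage_fit <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<brainage_fit> %d folds; out-of-fold r = %.3f, RMSE = %.2f, MAE = %.2f\n",
    length(x$models), m$r, m$rmse, m$mae
  ))
  invisible(x)
}

#' Predict brain age for a new cohort
#'
#' Mean of the per-outer-fold model predictions. Feature columns must match
#' the training schema by name.
#'
#' @param object A `brainage_fit`.
#' @param newdata Feature matrix / data frame with the training columns.
#' @param ... Unused.
#' @return Numeric vector of predicted ages (empty for zero rows).
#' @export
predict.brainage_fit <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata))
  missing_cols <- setdiff(object$feature_names, colnames(x))
  extra_cols <- setdiff(colnames(x), object$feature_names)
  if (length(missing_cols) || length(extra_cols)) {
    stop_bagprs(
      sprintf("feature schema mismatch; missing: [%s], extra: [%s]",
              paste(missing_cols, collapse = ", "),
              paste(extra_cols, collapse = ", ")),
      "bagprs_schema_mismatch"
    )
  }
  x <- x[, object$feature_names, drop = FALSE]
  if (nrow(x) == 0) return(numeric(0))
  storage.mode(x) <- "double"
  preds <- vapply(object$models, function(m) predict(m, x), numeric(nrow(x)))
  rowMeans(as.matrix(preds))
}

#' @exportS3Method generics::tidy
tidy.brainage_fit <- function(x, ...) x$oof

#' @exportS3Method generics::glance
glance.brainage_fit <- function(x, ...) x$metrics

#' @describeIn fit_brainage Out-of-fold predicted vs chronological age.
#' @param object A `brainage_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.brainage_fit <- function(object, ...) {
  ggplot2::ggplot(object$oof, ggplot2::aes(x = .data$age, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "chronological age (years)",
                  y = "predicted brain age (years)") +
    ggplot2::theme_minimal()
}

#' Age-bias model for the brain-age gap
#'
#' Regression to the mean makes the raw brain-age gap (BAG = predicted -
#' chronological) correlate negatively with age. `fit_bias()` regresses the
#' training-cohort out-of-fold BAG on age; `apply_bias()` subtracts the
#' fitted trend from any cohort's BAG, leaving the fitting cohort's corrected
#' BAG exactly orthogonal to age.
#'
#' @param predicted Predicted age vector (training out-of-fold).
#' @param age Chronological age vector.
#' @return `fit_bias()`: a `bias_model` with `slope` and `intercept`.
#' @export
fit_bias <- function(predicted, age) {
  stopifnot(length(predicted) == length(age))
  if (sd(age) == 0) {
    stop_bagprs("age is constant: bias slope undefined.", "bagprs_degenerate")
  }
  bag <- predicted - age
  fit <- lm(bag ~ age)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1])),
    class = "bias_model"
  )
}

#' @export
print.bias_model <- function(x, ...) {
  cat(sprintf("<bias_model> BAG = %.4f * age + %.4f\n", x$slope, x$intercept))
  invisible(x)
}

#' @rdname fit_bias
#' @param bias A `bias_model` fitted on the training population.
#' @return `apply_bias()`: tibble with `age`, `predicted`, `bag`,
#'   `corrected_bag = bag - (slope * age + intercept)` and
#'   `corrected_predicted = age + corrected_bag`.
#' @export
apply_bias <- function(bias, predicted, age) {
  stopifnot(inherits(bias, "bias_model"), length(predicted) == length(age))
  bag <- predicted - age
  corrected_bag <- bag - (bias$slope * age + bias$intercept)
  tibble::tibble(
    age = age, predicted = predicted, bag = bag,
    corrected_bag = corrected_bag,
    corrected_predicted = age + corrected_bag
  )
}

#' Prediction fit metrics
#'
#' Pearson r with a 95% Fisher-z confidence interval (SE `1/sqrt(n-3)`),
#' root-mean-square error and mean absolute error.
#'
#' @param predicted,age Numeric vectors (n >= 4, non-constant).
#' @return Tibble (`r`, `r_lo`, `r_hi`, `rmse`, `mae`, `n`).
#' @export
fit_metrics <- function(predicted, age) {
  n <- length(age)
  stopifnot(length(predicted) == n)
  if (n < 4) stop_bagprs("need at least 4 observations.", "bagprs_invalid_config")
  if (sd(predicted) == 0 || sd(age) == 0) {
    stop_bagprs("zero variance in predictions or age.", "bagprs_degenerate")
  }
  r <- cor(predicted, age)
  z <- atanh(r)
  half <- qnorm(0.975) / sqrt(n - 3)
  err <- predicted - age
  tibble::tibble(
    r = r, r_lo = tanh(z - half), r_hi = tanh(z + half),
    rmse = sqrt(mean(err^2)), mae = mean(abs(err)), n = n
  )
}
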