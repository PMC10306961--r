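#' Repeated-split LASSO stability selection for TNR prediction
#'
#' The statistical protocol: (1) features with missing values or zero
#' variance are dropped and the remainder filtered by the significance of
#' their Pearson correlation with TNR (two-sided p < alpha, no
#' multiple-testing correction); (2) in each of `n_tests` tests the cohort
#' is split at random into 70% training / 30% test cases, predictors are
#' centered and scaled with training-split statistics, an L1-penalized
#' linear model is fit to log10(TNR) with the penalty chosen by inner
#' cross-validation, predictions are potentiated (10^x) back to the TNR
#' scale, and MAE, RMSE, Spearman correlation and the selected predictors
#' are recorded; (3) per-test results are aggregated into metric medians
#' and quartiles and per-predictor occurrence counts, shares and mean
#' absolute standardized coefficients ("significance").
#'
#' @name stability_model
NULL

#' Stability-protocol configuration
#'
#' @param n_tests number of repeated tests (default 300).
#' @param train_fraction training share of each split (default 0.7; the
#'   train size is `round(train_fraction * n)`).
#' @param filter_alpha significance level of the Pearson pre-filter.
#' @param lambda_rule `"min"` (CV-minimum, default) or `"1se"`.
#' @param nfolds inner cross-validation folds for the penalty (default 5).
#' @param filter_per_split recompute the Pearson filter inside each training
#'   split instead of once on the full cohort. Default `FALSE`: the filter
#'   is applied once to the full dataset before the split loop, which is the
#'   protocol's stated two-step order and a documented optimistic-bias
#'   source; set `TRUE` for leakage-free evaluation.
#' @param master_seed integer seeding the whole run.
#' @return A `model_config` list.
#' @export
model_config <- function(n_tests = 300L, train_fraction = 0.7,
                         filter_alpha = 0.05, lambda_rule = c("min", "1se"),
                         nfolds = 5L, filter_per_split = FALSE,
                         master_seed = 20260911L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stopf("train_fraction must be in (0, 1)")
  if (n_tests < 1L) stopf("n_tests must be >= 1")
  structure(list(n_tests = as.integer(n_tests),
                 train_fraction = train_fraction,
                 filter_alpha = filter_alpha,
                 lambda_rule = match.arg(lambda_rule),
                 nfolds = as.integer(nfolds),
                 filter_per_split = isTRUE(filter_per_split),
                 master_seed = as.integer(master_seed)),
            class = "model_config")
}

#' Pearson correlation pre-filter
#'
#' Drops features with any missing value or zero variance, computes the
#' Pearson correlation of each remaining feature with TNR, and keeps those
#' with two-sided p < alpha (t transform, n - 2 df). Deliberately applies
#' no multiple-testing correction.
#'
#' @param features numeric matrix or data frame, cases x features, with
#'   column names.
#' @param tnr numeric vector of per-case TNR values.
#' @param alpha significance level (default 0.05).
#' @return List: `kept` (feature ids), `table` (data frame feature/r/p over
#'   all testable features), `dropped` (ids removed before testing).
#' @export
correlation_filter <- function(features, tnr, alpha = 0.05) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 3L) stopf("need at least 3 complete cases")
  if (length(tnr) != n) stopf("feature table and TNR length disagree")
  bad <- apply(x, 2L, function(col) anyNA(col) || stats::var(col) == 0)
  dropped <- colnames(x)[bad]
  x <- x[, !bad, drop = FALSE]
  r <- as.vector(stats::cor(x, tnr))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tab <- data.frame(feature = colnames(x), r = r, p = p,
                    stringsAsFactors = FALSE)
  list(kept = tab$feature[tab$p < alpha], table = tab, dropped = dropped)
}

#' Center and scale a training table; reuse its parameters on new data
#'
#' Columns are centered by the training mean and scaled by the training
#' sample (n-1) standard deviation; the same parameters transform the test
#' split. Columns with zero training variance are dropped (and reported).
#'
#' @param train numeric matrix (training cases x features).
#' @return List: `transform(newdata)` closure, `train` (transformed),
#'   `center`, `scale`, `dropped`.
#' @export
standardize <- function(train) {
  train <- as.matrix(train)
  ctr <- colMeans(train)
  scl <- apply(train, 2L, stats::sd)
  keep <- scl > 0
  dropped <- colnames(train)[!keep]
  ctr <- ctr[keep]; scl <- scl[keep]
  transform <- function(newdata) {
    m <- as.matrix(newdata)[, names(ctr), drop = FALSE]
    sweep(sweep(m, 2L, ctr, `-`), 2L, scl, `/`)
  }
  list(transform = transform, train = transform(train),
       center = ctr, scale = scl, dropped = dropped)
}

#' Decimal-log target transform and its inverse (potentiation)
#'
#' @param tnr strictly positive TNR values.
#' @return `transform_target`: log10 of the input. `potentiate`: 10^x.
#' @export
transform_target <- function(tnr) {
  if (any(tnr <= 0)) stopf("TNR must be strictly positive for log10")
  log10(tnr)
}

#' @rdname transform_target
#' @param x predictions on the decimal-log scale.
#' @export
potentiate <- function(x) 10^x

#' Random 70/30 split of case indices
#'
#' @param n_cases cohort size (>= 2).
#' @param train_fraction training share; train size `round(f * n)`.
#' @param seed integer seed (split is a pure function of it).
#' @return List of disjoint sorted index vectors `train`, `test`.
#' @export
split_cases <- function(n_cases, train_fraction = 0.7, seed = 1L) {
  if (n_cases < 2L) stopf("need >= 2 cases to split")
  n_train <- round(train_fraction * n_cases)
  if (n_train < 1L || n_train >= n_cases)
    stopf("degenerate split: %d train of %d", n_train, n_cases)
  train <- with_seed(seed, sort(sample.int(n_cases, n_train)))
  list(train = train, test = setdiff(seq_len(n_cases), train))
}

#' L1-penalized linear fit with inner-CV penalty selection
#'
#' Fits the LASSO path on (already standardized) predictors against the
#' decimal-log target and picks the penalty by `nfolds`-fold
#' cross-validation on the training split (`"min"` rule by default).
#' Zero-coefficient features are "not selected". An empty feature set is
#' legal and returns the intercept-only model (protocols can select zero
#' predictors).
#'
#' @param x standardized training matrix (may have 0 columns).
#' @param y training log10(TNR).
#' @param lambda_rule `"min"` or `"1se"`.
#' @param nfolds CV folds.
#' @param seed seed for the CV fold assignment.
#' @return List: `intercept`, `coef` (named, nonzero only), `lambda`.
#' @export
fit_lasso <- function(x, y, lambda_rule = "min", nfolds = 5L, seed = 1L) {
  x <- as.matrix(x)
  if (ncol(x) == 0L)
    return(list(intercept = mean(y), coef = stats::setNames(numeric(0), character(0)),
                lambda = Inf))
  padded <- ncol(x) == 1L
  if (padded) x <- cbind(x, `.pad.` = 0)      # glmnet needs >= 2 columns
  nfolds <- max(2L, min(nfolds, length(y)))
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), length(y))))
  cv <- glmnet::cv.glmnet(x, y, alpha = 1, standardize = FALSE,
                          foldid = foldid, family = "gaussian",
                          grouped = length(y) >= 3L * nfolds)
  lam <- if (identical(lambda_rule, "1se")) cv$lambda.1se else cv$lambda.min
  cf <- as.matrix(stats::coef(cv, s = lam))[, 1]
  beta <- cf[-1]
  if (padded) beta <- beta[names(beta) != ".pad."]
  beta <- beta[beta != 0]
  list(intercept = unname(cf[1]), coef = beta, lambda = lam)
}

predict_lasso <- function(model, x) {
  x <- as.matrix(x)
  p <- rep(model$intercept, nrow(x))
  if (length(model$coef))
    p <- p + as.vector(x[, names(model$coef), drop = FALSE] %*% model$coef)
  p
}

#' Evaluate one fitted model on its test split
#'
#' Predictions are potentiated to the TNR scale before any metric: MAE and
#' RMSE are in TNR units, never log units. Spearman rho/p are missing when
#' predictions are constant.
#'
#' @param model result of [fit_lasso()].
#' @param x_test standardized test matrix.
#' @param tnr_test true TNR values of the test cases.
#' @param test_index label for the record.
#' @return A `test_result`: `test_index`, `mae`, `rmse`, `spearman_rho`,
#'   `spearman_p`, `selected` (named |coefficient| vector), `n_selected`.
#' @export
evaluate_test <- function(model, x_test, tnr_test, test_index = NA_integer_) {
  pred <- potentiate(predict_lasso(model, x_test))
  err <- pred - tnr_test
  if (stats::sd(pred) > 0) {
    ct <- suppressWarnings(stats::cor.test(tnr_test, pred, method = "spearman",
                                           exact = FALSE))
    rho <- unname(ct$estimate); pval <- ct$p.value
  } else {
    rho <- NA_real_; pval <- NA_real_
  }
  structure(list(test_index = test_index,
                 mae = mean(abs(err)),
                 rmse = sqrt(mean(err^2)),
                 spearman_rho = rho, spearman_p = pval,
                 selected = abs(model$coef),
                 n_selected = length(model$coef)),
            class = "test_result")
}

#' Run the full repeated-split protocol
#'
#' @param features cases x features numeric matrix/data frame (named cols).
#' @param tnr per-case TNR vector (> 0).
#' @param config a [model_config()].
#' @return List of `test_result` (length `n_tests`), with attributes
#'   `filter` (the pre-filter result) and `config`. Per-test failures are
#'   recorded as `NA` metrics, never abort the batch.
#' @export
run_stability <- function(features, tnr, config = model_config()) {
  features <- as.matrix(features)
  n <- nrow(features)
  y_log <- transform_target(tnr)
  filt <- correlation_filter(features, tnr, config$filter_alpha)
  seeds <- derive_seeds(config$master_seed, 2L * config$n_tests)
  results <- vector("list", config$n_tests)
  for (t in seq_len(config$n_tests)) {
    results[[t]] <- tryCatch({
      sp <- split_cases(n, config$train_fraction, seeds[2L * t - 1L])
      kept <- if (config$filter_per_split)
        correlation_filter(features[sp$train, , drop = FALSE],
                           tnr[sp$train], config$filter_alpha)$kept
      else filt$kept
      xtr <- features[sp$train, kept, drop = FALSE]
      std <- standardize(xtr)
      model <- fit_lasso(std$train, y_log[sp$train],
                         lambda_rule = config$lambda_rule,
                         nfolds = config$nfolds, seed = seeds[2L * t])
      evaluate_test(model, std$transform(features[sp$test, kept, drop = FALSE]),
                    tnr[sp$test], test_index = t)
    }, error = function(e) structure(
      list(test_index = t, mae = NA_real_, rmse = NA_real_,
           spearman_rho = NA_real_, spearman_p = NA_real_,
           selected = stats::setNames(numeric(0), character(0)),
           n_selected = NA_integer_, error = conditionMessage(e)),
      class = "test_result"))
  }
  attr(results, "filter") <- filt
  attr(results, "config") <- config
  results
}

med_iqr <- function(x) {
  q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' Aggregate per-test results across the protocol
#'
#' @param results list of `test_result` from [run_stability()].
#' @return An `aggregate_report`: `n_tests`; `metrics` (median/quartiles of
#'   MAE, RMSE, Spearman rho and p); `predictor_count` (median, quartiles,
#'   min, max of selected-predictor counts); `predictors` data frame
#'   (feature, n_models, share_pct, mean_significance) sorted by occurrence
#'   descending — features never selected are absent.
#' @export
aggregate_report <- function(results) {
  if (!length(results)) stopf("no results to aggregate")
  n_tests <- length(results)
  get <- function(f) vapply(results, function(r) r[[f]] %||% NA_real_, double(1))
  sel <- lapply(results, `[[`, "selected")
  all_ids <- unique(unlist(lapply(sel, names)))
  pred <- if (length(all_ids)) {
    cnt <- vapply(all_ids, function(id)
      sum(vapply(sel, function(s) id %in% names(s), logical(1))), double(1))
    msig <- vapply(all_ids, function(id) {
      v <- unlist(lapply(sel, function(s) s[names(s) == id]))
      mean(v)
    }, double(1))
    df <- data.frame(feature = all_ids, n_models = as.integer(cnt),
                     share_pct = 100 * cnt / n_tests,
                     mean_significance = msig, stringsAsFactors = FALSE)
    # occurrence first; ties broken by mean |coefficient|, then by name
    df[order(-df$n_models, -df$mean_significance, df$feature), , drop = FALSE]
  } else {
    data.frame(feature = character(), n_models = integer(),
               share_pct = numeric(), mean_significance = numeric())
  }
  nsel <- get("n_selected")
  structure(list(
    n_tests = n_tests,
    metrics = list(mae = med_iqr(get("mae")),
                   rmse = med_iqr(get("rmse")),
                   spearman_rho = med_iqr(get("spearman_rho")),
                   spearman_p = med_iqr(get("spearman_p"))),
    predictor_count = c(med_iqr(nsel),
                        min = suppressWarnings(min(nsel, na.rm = TRUE)),
                        max = suppressWarnings(max(nsel, na.rm = TRUE))),
    predictors = pred), class = "aggregate_report")
}

#' @export
print.aggregate_report <- function(x, ...) {
  m <- x$metrics
  fmt <- function(v) sprintf("%.3f [%.3f; %.3f]", v[1], v[2], v[3])
  cat(sprintf("<aggregate_report> %d tests\n", x$n_tests))
  cat("  MAE  ", fmt(m$mae), "   RMSE ", fmt(m$rmse), "\n")
  cat("  Spearman rho ", fmt(m$spearman_rho), "\n")
  cat(sprintf("  predictors/model %g [%g; %g] (min %g, max %g)\n",
              x$predictor_count[1], x$predictor_count[2], x$predictor_count[3],
              x$predictor_count[4], x$predictor_count[5]))
  cat(sprintf("  %d distinct predictors ever selected\n", nrow(x$predictors)))
  invisible(x)
}
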