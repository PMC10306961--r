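test_that("correlation filter keeps significant features, drops degenerate ones", {
  set.seed(71)
  n <- 40
  tnr <- runif(n, 1.9, 5)
  x <- cbind(self = tnr,
             const = rep(2, n),
             withna = c(NA, runif(n - 1)),
             noise = runif(n))
  f <- correlation_filter(x, tnr, alpha = 0.05)
  expect_true("self" %in% f$kept)
  expect_setequal(f$dropped, c("const", "withna"))
  expect_false("const" %in% f$table$feature)
  # n = 40, r = 0.44: two-sided p from the t transform ~ 0.0044 (paper-scale check)
  r <- 0.44
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-tstat, n - 2)
  expect_equal(p, 0.0044, tolerance = 0.01)
  expect_lt(p, 0.05)
  expect_error(correlation_filter(x[1:2, ], tnr[1:2]), "at least 3")
})

test_that("standardization uses train parameters on test data", {
  std <- standardize(matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "f")))
  expect_equal(as.vector(std$train), c(-1, 0, 1))   # sample (n-1) sd = 1
  expect_equal(unname(std$scale), 1)
  # idempotence: standardizing an already-standardized column is a no-op
  std2 <- standardize(std$train)
  expect_equal(std2$train, std$train)
  # test value equal to the train mean maps to 0
  expect_equal(as.vector(std$transform(matrix(2, 1, 1,
                                              dimnames = list(NULL, "f")))), 0)
  # zero-variance training column is dropped and reported
  m <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_equal(standardize(m)$dropped, "b")
})

test_that("decimal-log transform and potentiation invert each other", {
  for (v in c(1, 3.26, 10)) expect_equal(potentiate(transform_target(v)), v)
  expect_equal(transform_target(10), 1)
  expect_error(transform_target(c(2, 0)), "strictly positive")
})

test_that("splits are seeded partitions with round(f*n) training cases", {
  s <- split_cases(40, 0.7, seed = 99)
  expect_length(s$train, 28)
  expect_length(s$test, 12)
  expect_setequal(c(s$train, s$test), 1:40)
  expect_length(intersect(s$train, s$test), 0)
  expect_identical(split_cases(40, 0.7, seed = 99), s)
  expect_false(identical(split_cases(40, 0.7, seed = 100)$train, s$train))
  expect_error(split_cases(1, 0.7, 1), ">= 2")
})

test_that("lasso shrinkage limits and univariate recovery", {
  set.seed(72)
  n <- 30
  x <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "f"))
  beta <- 0.35
  y <- 0.5 + beta * x[, 1]                      # noiseless planted slope
  std <- standardize(x)
  fit <- fit_lasso(std$train, y, seed = 4)
  # cv picks a near-zero penalty on noiseless data: close to the OLS oracle
  ols <- unname(coef(lm(y ~ std$train))[2])
  expect_equal(unname(fit$coef["f"]), ols, tolerance = 0.05)
  expect_equal(ols, beta * sd(x), tolerance = 1e-12)
  # at penalty -> 0 the solver recovers the planted slope to high precision
  path <- glmnet::glmnet(cbind(std$train, 0), y, alpha = 1,
                         standardize = FALSE, lambda = c(0.1, 1e-6))
  cf0 <- as.matrix(coef(path, s = 1e-6))[2, 1]
  expect_equal(cf0, ols, tolerance = 1e-4)
  # empty feature set: intercept-only model is legal
  fit0 <- fit_lasso(x[, 0, drop = FALSE], y)
  expect_equal(fit0$intercept, mean(y))
  expect_length(fit0$coef, 0)
  # duplicated features: strong penalty keeps at most one of the pair
  xx <- cbind(a = x[, 1], b = x[, 1], c = rnorm(n))
  stdx <- standardize(xx)
  path <- glmnet::glmnet(cbind(stdx$train, 0), y, alpha = 1, standardize = FALSE)
  mid <- path$lambda[length(path$lambda) %/% 3]
  cf <- as.matrix(coef(path, s = mid))[-1, 1]
  expect_lte(sum(cf[c("a", "b")] != 0), 1)
})

test_that("test evaluation is on the TNR scale with degenerate handling", {
  x <- matrix(0, 4, 0)
  truth <- c(2, 3, 4, 5)
  # perfect model: predict log10(truth) via a fake intercept-free path
  model <- list(intercept = 0, coef = setNames(numeric(0), character(0)))
  perfect <- list(intercept = log10(2), coef = setNames(1, "f"))
  xf <- matrix(log10(truth / 2), 4, 1, dimnames = list(NULL, "f"))
  r <- evaluate_test(perfect, xf, truth)
  expect_equal(r$mae, 0)
  expect_equal(r$rmse, 0)
  expect_equal(r$spearman_rho, 1)
  # constant +1 on the TNR scale
  shifted <- list(intercept = 0, coef = setNames(1, "f"))
  xs <- matrix(log10(truth + 1), 4, 1, dimnames = list(NULL, "f"))
  rs <- evaluate_test(shifted, xs, truth)
  expect_equal(rs$mae, 1)
  expect_equal(rs$rmse, 1)
  expect_equal(rs$spearman_rho, 1)
  # intercept-only: constant predictions, rho missing, errors still valid
  ri <- evaluate_test(model, x, truth)
  expect_true(is.na(ri$spearman_rho))
  expect_equal(ri$mae, mean(abs(1 - truth)))
  # metrics differ from log-scale metrics on a constructed case
  log_mae <- mean(abs(log10(truth + 1) - log10(truth)))
  expect_false(isTRUE(all.equal(rs$mae, log_mae)))
})

test_that("run_stability is deterministic and aggregates correctly", {
  fc <- simulate_feature_cohort(30, 40, 5, seed = 8)
  cfg <- model_config(n_tests = 8, master_seed = 77)
  r1 <- run_stability(fc$features, fc$tnr, cfg)
  r2 <- run_stability(fc$features, fc$tnr, cfg)
  expect_length(r1, 8)
  expect_identical(r1, r2)
  r3 <- run_stability(fc$features, fc$tnr, model_config(n_tests = 1, master_seed = 77))
  expect_length(r3, 1)
  agg <- aggregate_report(r1)
  expect_equal(agg$n_tests, 8)
  expect_true(all(agg$predictors$n_models <= 8))
  expect_equal(agg$predictors$share_pct,
               100 * agg$predictors$n_models / 8)
  expect_true(!is.unsorted(rev(agg$predictors$n_models)))
  # occurrence counting: a feature selected in 157 of 300 models -> 52.3%
  fake <- lapply(1:300, function(i) structure(
    list(test_index = i, mae = i %% 3 + 1, rmse = 1, spearman_rho = 0.5,
         spearman_p = 0.05,
         selected = if (i <= 157) c(star = 0.1) else setNames(numeric(0), character(0)),
         n_selected = as.integer(i <= 157)), class = "test_result"))
  fagg <- aggregate_report(fake)
  expect_equal(fagg$predictors$n_models, 157L)
  expect_equal(fagg$predictors$share_pct, 52.3, tolerance = 0.05)
  expect_equal(unname(fagg$metrics$mae["median"]), 2)
})

test_that("per-split filtering mode runs and never aborts the batch", {
  fc <- simulate_feature_cohort(30, 15, 3, seed = 9)
  cfg <- model_config(n_tests = 3, master_seed = 5, filter_per_split = TRUE)
  res <- run_stability(fc$features, fc$tnr, cfg)
  expect_length(res, 3)
  expect_true(all(vapply(res, function(r) inherits(r, "test_result"), logical(1))))
})
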