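test_that("arcsine square-root transform has its closed-form values", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.5), pi / 4)
  expect_error(arcsine_sqrt(1.2), "0, 1")
  expect_error(arcsine_sqrt(-0.1), "0, 1")
})

test_that("anderson-darling detects non-normality and is affine invariant", {
  set.seed(10)
  x <- rnorm(20)
  a1 <- anderson_darling(x)
  # formula recomputation on the sorted, standardized sample
  z <- sort((x - mean(x)) / sd(x))
  n <- length(z)
  A2 <- -n - mean((2 * seq_len(n) - 1) *
                  (log(pnorm(z)) + log(1 - pnorm(rev(z)))))
  expect_equal(a1$A, A2, tolerance = 1e-10)
  expect_equal(anderson_darling(3 * x - 7)$A, a1$A, tolerance = 1e-10)
  bimodal <- c(rnorm(40, -5, 0.3), rnorm(40, 5, 0.3))
  expect_lt(anderson_darling(bimodal)$p, 0.01)
  expect_error(anderson_darling(rnorm(5)), ">= 8")
})

test_that("logistic fits reproduce closed-form intercept-only results", {
  # balanced 0/0/1/1: intercept 0, deviance -2*4*log(0.5)
  d0 <- list(y = c(0, 0, 1, 1),
             X = matrix(numeric(0), 4, 0), response = "segment_category")
  f0 <- fit_logistic(d0, cols = character(0))
  expect_equal(unname(coef(f0$model)[1]), 0, tolerance = 1e-9)
  expect_equal(f0$resid_deviance, -2 * 4 * log(0.5), tolerance = 1e-9)
  # 23 zeros / 47 ones: intercept log(47/23), null deviance ~ 88.64
  d1 <- list(y = rep(c(0, 1), c(23, 47)),
             X = matrix(numeric(0), 70, 0), response = "segment_category")
  f1 <- fit_logistic(d1, cols = character(0))
  expect_equal(unname(coef(f1$model)[1]), log(47 / 23), tolerance = 1e-8)
  expect_equal(f1$null_deviance,
               -2 * (47 * log(47 / 70) + 23 * log(23 / 70)),
               tolerance = 1e-8)
})

test_that("perfect separation raises the non-convergence flag", {
  x <- c(-3, -2, -1, 1, 2, 3)
  d <- list(y = as.numeric(x > 0), X = cbind(forest = x))
  f <- fit_logistic(d)
  expect_true(f$separated)
  expect_false(f$converged)
})

test_that("logistic and linear fits agree with independent oracles", {
  d <- synthetic_design(40, c(zero_beta(), forest = 1.5)[predictor_classes()],
                        seed = 2, noise_sd = 0.1)
  des <- model_design(d, 50, "segment_category")
  f <- fit_logistic(des, cols = c("forest", "water"))
  # IRLS oracle written independently of the package path
  Xm <- cbind(1, des$X[, c("forest", "water")])
  beta <- rep(0, 3)
  for (it in 1:50) {
    eta <- drop(Xm %*% beta); mu <- 1 / (1 + exp(-eta))
    W <- diag(as.vector(mu * (1 - mu)))
    beta <- beta + solve(t(Xm) %*% W %*% Xm, t(Xm) %*% (des$y - mu))
  }
  expect_equal(unname(coef(f$model)), as.vector(beta), tolerance = 1e-6)

  # normal-equation oracle on a 5-row fixture
  X5 <- cbind(1, c(0.1, 0.3, 0.2, 0.5, 0.4), c(0.9, 0.1, 0.4, 0.2, 0.3))
  y5 <- c(1.2, 2.1, 1.7, 3.0, 2.4)
  des5 <- list(y = y5, X = matrix(X5[, -1], 5, 2,
                                  dimnames = list(NULL, c("forest", "water"))),
               response = "transformed_probability")
  fl <- fit_linear(des5)
  oracle <- solve(t(X5) %*% X5, t(X5) %*% y5)
  expect_equal(unname(coef(fl$model)), as.vector(oracle), tolerance = 1e-9)

  # exact linear relation: R^2 = 1, residuals 0
  dex <- list(y = 2 + 3 * des5$X[, "forest"], X = des5$X,
              response = "transformed_probability")
  fex <- suppressWarnings(fit_linear(dex, cols = "forest"))  # exact fit
  expect_equal(fex$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(residuals(fex$model))), 1e-10)
})

test_that("null-noise linear fits have adjusted R-squared near zero", {
  set.seed(99)
  X <- matrix(runif(500 * 8), 500, 8, dimnames = list(NULL, predictor_classes()))
  des <- list(y = rnorm(500), X = X, response = "transformed_probability")
  f <- fit_linear(des)
  expect_lt(abs(f$adj_r_squared), 0.05)
})

test_that("stepwise selection keeps signal, drops noise, and is a local
           AIC optimum", {
  set.seed(4)
  n <- 70
  x1 <- runif(n); x2 <- runif(n)
  y <- 1 + 4 * x1 + rnorm(n, 0, 0.05)
  des <- list(y = y, X = cbind(forest = x1, urban = x2),
              response = "transformed_probability")
  sel <- stepwise_aic(des, kind = "linear")
  expect_true("forest" %in% sel$included)
  expect_false("urban" %in% sel$included)

  # the selected model's internal AIC never exceeds the full model's, and
  # no single add/drop lowers it further
  full <- permscape:::fit_cols(des$X, des$y, colnames(des$X), "linear")
  expect_lte(sel$search_aic, full$aic + 1e-9)
  for (v in sel$included) {
    f <- permscape:::fit_cols(des$X, des$y, setdiff(sel$included, v), "linear")
    expect_gte(f$aic, sel$search_aic - 1e-4)
  }
  for (v in setdiff(colnames(des$X), sel$included)) {
    f <- permscape:::fit_cols(des$X, des$y, c(sel$included, v), "linear")
    expect_gte(f$aic, sel$search_aic - 1e-4)
  }
})

test_that("duplicated predictors collapse to a single survivor", {
  set.seed(6)
  n <- 60
  x <- runif(n)
  y <- rbinom(n, 1, plogis(-1 + 3 * x))
  des <- list(y = y, X = cbind(forest = x, grassland = x, water = x),
              response = "segment_category")
  sel <- stepwise_aic(des, kind = "logistic")
  expect_equal(length(sel$included), 1L)
})

test_that("stepwise agrees with the reference implementation on full-rank
           fixtures", {
  skip_if_not_installed("MASS")
  for (s in 1:5) {
    d <- synthetic_design(
      60, c(zero_beta(), forest = 2, water = -2)[predictor_classes()],
      seed = 100 + s, noise_sd = 0.1)
    des <- model_design(d, 50, "segment_category")
    keep <- apply(des$X, 2, sd) > 0
    X <- des$X[, keep, drop = FALSE]
    sel <- permscape:::step_cols(X, des$y, "logistic")
    df <- data.frame(y = des$y, X, check.names = FALSE)
    full <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    ref <- suppressWarnings(MASS::stepAIC(full, direction = "both",
                                          trace = 0))
    expect_setequal(sel$cols, setdiff(names(coef(ref)), "(Intercept)"))

    desl <- model_design(d, 50, "transformed_probability")
    Xl <- desl$X[, keep, drop = FALSE]
    sell <- permscape:::step_cols(Xl, desl$y, "linear")
    dfl <- data.frame(y = desl$y, Xl, check.names = FALSE)
    refl <- MASS::stepAIC(lm(y ~ ., data = dfl), direction = "both",
                          trace = 0)
    expect_setequal(sell$cols, setdiff(names(coef(refl)), "(Intercept)"))
  }
})

test_that("percent deviance explained matches direct arithmetic", {
  expect_equal(round(percent_deviance(87.350, 75.112), 1), 14.0)
  expect_equal(round(percent_deviance(87.350, 62.455), 1), 28.5)
  expect_equal(percent_deviance(10, 10), 0)
  expect_error(percent_deviance(0, 0), "zero")
  expect_warning(percent_deviance(10, 11), "exceeds")
})

test_that("bootstrap summaries are deterministic and structurally sound", {
  d <- synthetic_design(
    60, c(zero_beta(), forest = 3)[predictor_classes()], seed = 11,
    noise_sd = 0.2)
  b1 <- bootstrap_models(d, 50, "segment_category", B = 40, retain = 36,
                         seed = 5)
  b2 <- bootstrap_models(d, 50, "segment_category", B = 40, retain = 36,
                         seed = 5)
  expect_identical(b1$retention, b2$retention)
  expect_identical(b1$mean_beta, b2$mean_beta)
  expect_true(all(b1$retention >= 0 & b1$retention <= 40))
  sel <- b1$selected[-1]
  expect_identical(unname(sel), unname(b1$retention[-1] >= 36))
  ok <- !is.na(b1$ci_lo)
  expect_true(all(b1$ci_lo[ok] <= b1$ci_hi[ok]))

  # linear flavor reports adjusted R-squared and total-SS null
  bl <- bootstrap_models(d, 50, "transformed_probability", B = 30,
                         retain = 27, seed = 5)
  expect_true(is.finite(bl$mean_fit_stat))
  expect_gt(bl$analytic_null_dev, 0)
})

test_that("bootstrap coefficient spread shrinks roughly like 1/sqrt(n)", {
  beta <- c(zero_beta(), forest = 2.5)[predictor_classes()]
  d70 <- synthetic_design(70, beta, seed = 21, noise_sd = 0.2)
  d280 <- synthetic_design(280, beta, seed = 22, noise_sd = 0.2)
  b70 <- bootstrap_models(d70, 50, "segment_category", B = 60, retain = 54,
                          seed = 1)
  b280 <- bootstrap_models(d280, 50, "segment_category", B = 60, retain = 54,
                           seed = 1)
  i <- match("forest", b70$variables)
  expect_lt(b280$se_beta[i], b70$se_beta[i])
})

test_that("pure-noise predictors are not systematically retained", {
  # under the null, per-variable retention averages well below the 90%
  # selection rule; occasional datasets where one of eight noise variables
  # draws a lucky Wald z can cross it, so the calibration is asserted on
  # the typical behavior, not on every replicate
  stats <- vapply(1:10, function(s) {
    d <- synthetic_design(70, zero_beta(), seed = 600 + s, noise_sd = 0.2)
    b <- bootstrap_models(d, 50, "segment_category", B = 100, retain = 90,
                          seed = s)
    c(mean_ret = mean(b$retention[-1]) / 100,
      none_selected = all(b$retention[-1] < 90))
  }, numeric(2))
  expect_lt(mean(stats["mean_ret", ]), 0.5)
  expect_gte(mean(stats["none_selected", ]), 0.6)
})
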