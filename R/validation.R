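#' Predict the segment category from a fitted logistic model
#'
#' The fitted probability of the W class is compared with the cutoff:
#' strictly greater predicts W, otherwise B (a probability of exactly 0.5 is
#' B under the strict rule).
#'
#' @param fit A logistic `ps_fit` (see [fit_logistic()]).
#' @param x A one-row data.frame / named list with the fit's predictors.
#' @param cutoff Probability cutoff (default 0.5).
#' @return `"B"` or `"W"`.
#' @export
predict_category <- function(fit, x, cutoff = 0.5) {
  if (fit$kind != "logistic") stop("fit must be a logistic model")
  x <- as.data.frame(x)
  miss <- setdiff(fit$included, names(x))
  if (length(miss)) stop("missing predictor value(s): ",
                         paste(miss, collapse = ", "))
  pr <- stats::predict(fit$model, newdata = x, type = "response")
  ifelse(pr > cutoff, "W", "B")
}

#' 95% prediction interval from a fitted linear model
#'
#' t-based interval for a NEW observation on the transformed scale:
#' \eqn{\hat y \pm t_{1-\alpha/2, df} \, s \sqrt{1 + h}} with leverage `h`,
#' via [stats::predict.lm()]. Endpoints are reported on the transformed
#' (arcsine-square-root) scale; back-transform with `sin(.)^2` if needed.
#' A zero residual variance yields a degenerate zero-width interval, flagged.
#'
#' @param fit A linear `ps_fit` (see [fit_linear()]).
#' @param x A one-row data.frame / named list with the fit's predictors.
#' @param level Coverage level (default 0.95).
#' @return Numeric `c(lower, upper)`; attribute `degenerate` is TRUE when the
#'   residual variance is zero.
#' @export
prediction_interval <- function(fit, x, level = 0.95) {
  if (fit$kind != "linear") stop("fit must be a linear model")
  if (stats::df.residual(fit$model) < 2)
    stop("need >= 2 residual degrees of freedom")
  x <- as.data.frame(x)
  pr <- stats::predict(fit$model, newdata = x, interval = "prediction",
                       level = level)
  out <- c(lower = pr[1, "lwr"], upper = pr[1, "upr"])
  attr(out, "degenerate") <- summary(fit$model)$sigma == 0
  out
}

#' Predictive validation by repeated 20% subsampling
#'
#' For every bootstrap iteration, `reps` random subsets of `fraction` of its
#' resampled segments (drawn without replacement) are scored against the
#' iteration's own fitted model: logistic correctness is the predicted
#' category (cutoff 0.5) matching the observed one; linear correctness is the
#' observed transformed probability lying inside the model's 95% prediction
#' interval. Proportions are aggregated over all validated segments with a
#' normal-approximation binomial 95% CI.
#'
#' @param boot A [bootstrap_models()] result (its per-iteration record is
#'   reused; models are refit from the stored resample indices and variable
#'   sets).
#' @param fraction Subsample fraction per rep (default 0.2).
#' @param reps Subsample draws per bootstrap iteration (default 1000).
#' @param seed Seed for the subsampling stream.
#' @param cutoff Logistic classification cutoff (default 0.5).
#' @param level Prediction-interval level (default 0.95).
#' @return Object of class `validation_report`: `proportion` (accuracy or
#'   coverage), `ci_lo`, `ci_hi`, `n_validated`, `kind`, `width`.
#' @export
validate <- function(boot, fraction = 0.2, reps = 1000, seed = 1L,
                     cutoff = 0.5, level = 0.95) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  design <- boot$design
  B <- boot$B; n <- boot$n
  correct_total <- 0; n_total <- 0
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- boot$iterations$idx[b, ]
      cols <- boot$variables[-1][boot$iterations$included[b, ]]
      Xb <- design$X[idx, , drop = FALSE]
      yb <- design$y[idx]
      if (boot$kind == "logistic") {
        cf <- boot$iterations$coef[b, c("(Intercept)", cols)]
        eta <- cf[1] + if (length(cols))
          drop(Xb[, cols, drop = FALSE] %*% cf[-1]) else 0
        ok <- (stats::plogis(eta) > cutoff) == (yb == 1)
      } else {
        df <- data.frame(.y = yb, Xb[, cols, drop = FALSE],
                         check.names = FALSE)
        m <- stats::lm(.y ~ ., data = df)
        pr <- suppressWarnings(
          stats::predict(m, newdata = df, interval = "prediction",
                         level = level))
        ok <- yb >= pr[, "lwr"] & yb <= pr[, "upr"]
      }
      m_sub <- max(1L, round(fraction * n))
      for (r in seq_len(reps)) {
        sub <- sample.int(n, m_sub)
        correct_total <- correct_total + sum(ok[sub])
        n_total <- n_total + m_sub
      }
    }
  })
  prop <- correct_total / n_total
  half <- stats::qnorm(0.975) * sqrt(prop * (1 - prop) / n_total)
  structure(list(proportion = prop, ci_lo = max(0, prop - half),
                 ci_hi = min(1, prop + half), n_validated = n_total,
                 kind = boot$kind, width = boot$width,
                 fraction = fraction, reps = reps),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  what <- if (x$kind == "logistic") "classification accuracy"
  else "prediction-interval coverage"
  cat(sprintf("validation @ %g m: %s = %.4f [%.4f, %.4f] (%d segments)\n",
              x$width, what, x$proportion, x$ci_lo, x$ci_hi, x$n_validated))
  invisible(x)
}
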