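#' The eight predictor classes
#'
#' Land-cover predictors entering the regression models: all classes except
#' agriculture, which is excluded for its strong negative correlation with
#' forest (the compositions are near-compositional in an
#' agriculture-dominated mosaic).
#'
#' @return Character vector of eight class names.
#' @export
predictor_classes <- function() {
  c("forest", "non_treed_corridor", "road", "grassland", "shrubland",
    "treed_corridor", "urban", "water")
}

#' Arcsine square-root transform
#'
#' Variance-stabilizing transform \eqn{\arcsin(\sqrt p)} for proportion-valued
#' responses; maps [0, 1] onto [0, pi/2].
#'
#' @param p Proportions in [0, 1].
#' @return Transformed values.
#' @export
arcsine_sqrt <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  asin(sqrt(p))
}

#' Anderson-Darling normality test
#'
#' A-squared statistic (with the usual small-sample factor) and p-value for
#' the composite-normality case with estimated mean and variance, as
#' implemented in the nortest package.
#'
#' @param x Numeric sample, n >= 8.
#' @return List with `A` and `p`.
#' @export
anderson_darling <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 8) stop("n must be >= 8")
  if (stats::sd(x) == 0)
    return(list(A = Inf, p = 0))     # degenerate sample: trivially non-normal
  t <- nortest::ad.test(x)
  list(A = unname(t$statistic), p = t$p.value)
}

#' Assemble a model design from a segment table
#'
#' @param segment_table Output of [build_segment_table()] or any data.frame
#'   with `width`, `category`, the nine composition columns and (for the
#'   linear response) `membership`.
#' @param width The bandwidth (m) whose rows to use.
#' @param response `"segment_category"` — logistic response coded B = 0,
#'   W = 1; or `"transformed_probability"` — arcsine-square-root transformed
#'   mean membership probability.
#' @return List of class `model_design`: `y`, `X` (n x 8 predictor matrix),
#'   `response`, `width`.
#' @export
model_design <- function(segment_table, width,
                         response = c("segment_category",
                                      "transformed_probability")) {
  response <- match.arg(response)
  rows <- segment_table[segment_table$width == width, , drop = FALSE]
  if (!nrow(rows)) stop("no segments at width ", width)
  X <- as.matrix(rows[, predictor_classes(), drop = FALSE])
  y <- if (response == "segment_category") {
    as.numeric(rows$category == "W")
  } else {
    if (is.null(rows$membership)) stop("segment table has no membership column")
    arcsine_sqrt(rows$membership)
  }
  structure(list(y = y, X = X, response = response, width = width),
            class = "model_design")
}

# ---- fast design-matrix fitting paths (used inside the bootstrap) ----------

# Logistic fit on intercept + selected columns; returns deviances and the
# column-count AIC (deviance + 2 * (|cols| + 1)). Lean IRLS over lm.fit —
# equivalent to glm.fit's maximum-likelihood solution on converged fits, but
# fast enough for the bootstrap x stepwise inner loop.
fit_cols_logistic <- function(X, y, cols, maxit = 25, tol = 1e-8,
                              beta_init = NULL) {
  Xm <- cbind(`(Intercept)` = 1, X[, cols, drop = FALSE])
  n <- length(y)
  p <- ncol(Xm)
  clamp <- function(v, lo, hi) { v[v < lo] <- lo; v[v > hi] <- hi; v }
  bin_dev <- function(mu) -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
  if (!is.null(beta_init)) {
    b0 <- numeric(p)
    m <- match(colnames(Xm), names(beta_init))
    hit <- !is.na(m)
    b0[hit] <- beta_init[m[hit]]
    b0[is.na(b0)] <- 0
    eta <- drop(Xm %*% b0)
    mu <- clamp(1 / (1 + exp(-eta)), 1e-12, 1 - 1e-12)
  } else {
    mu <- (y + 0.5) / 2
    eta <- log(mu / (1 - mu))
  }
  dev <- bin_dev(mu)
  converged <- FALSE
  beta <- rep(NA_real_, p)
  beta_num <- NULL                       # last iterate, NAs as zeros
  na_mask <- rep(FALSE, p)
  for (it in seq_len(maxit)) {
    w <- clamp(mu * (1 - mu), 1e-10, 1)
    sw <- sqrt(w)
    z <- eta + (y - mu) / w
    f <- .lm.fit(Xm * sw, z * sw)
    cf <- f$coefficients
    if (f$rank < p) cf[(f$rank + 1L):p] <- NA_real_
    beta <- rep(NA_real_, p)
    beta[f$pivot] <- cf
    na_mask <- is.na(beta)
    bn <- beta
    bn[na_mask] <- 0
    eta <- drop(Xm %*% bn)
    mu <- clamp(1 / (1 + exp(-eta)), 1e-12, 1 - 1e-12)
    dev_old <- dev
    dev <- bin_dev(mu)
    # step-halving: IRLS can overshoot under quasi-separation
    if (!is.null(beta_num) && dev > dev_old + 1e-10) {
      half <- 0L
      while (dev > dev_old + 1e-10 && half < 15L) {
        bn <- (bn + beta_num) / 2
        eta <- drop(Xm %*% bn)
        mu <- clamp(1 / (1 + exp(-eta)), 1e-12, 1 - 1e-12)
        dev <- bin_dev(mu)
        half <- half + 1L
      }
      beta <- bn
      beta[na_mask] <- NA_real_
    }
    beta_num <- bn
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1) || dev < 1e-7) {
      converged <- TRUE; break
    }
  }
  names(beta) <- colnames(Xm)
  p1 <- mean(y)
  null_dev <- if (p1 <= 0 || p1 >= 1) 0 else
    -2 * n * (p1 * log(p1) + (1 - p1) * log(1 - p1))
  list(coef = beta, dev = dev, null_dev = null_dev,
       aic = dev + 2 * (length(cols) + 1),
       weights = clamp(mu * (1 - mu), 1e-10, 1), converged = converged,
       separated = dev < 1e-6 && length(cols) > 0)
}

# Gaussian fit; AIC = n log(RSS/n) + 2 * (|cols| + 2), the profiled-variance
# form up to an additive constant shared by all submodels.
fit_cols_linear <- function(X, y, cols) {
  Xm <- cbind(`(Intercept)` = 1, X[, cols, drop = FALSE])
  f <- stats::lm.fit(Xm, y)
  rss <- sum(f$residuals^2)
  n <- length(y)
  list(coef = f$coefficients, rss = rss,
       aic = n * log(rss / n) + 2 * (length(cols) + 2), rank = f$rank)
}

fit_cols <- function(X, y, cols, kind, warm = NULL) {
  if (kind == "logistic") fit_cols_logistic(X, y, cols, beta_init = warm)
  else fit_cols_linear(X, y, cols)
}

# Bidirectional stepwise AIC over predictor columns, starting from `start`.
# At each step the single add/drop giving the largest AIC decrease is
# applied; terminates when no move lowers AIC. The move count is capped at
# max(20, 2 p^2) to guard against cycling.
step_cols <- function(X, y, kind, start = colnames(X)) {
  all_cols <- colnames(X)
  cur <- start
  cur_fit <- fit_cols(X, y, cur, kind)
  cap <- max(20L, 2L * length(all_cols)^2)
  for (move in seq_len(cap + 1L)) {
    if (move > cap) stop("stepwise selection exceeded the move cap (cycling)")
    best_aic <- cur_fit$aic; best_cols <- NULL
    warm <- cur_fit$coef
    for (v in cur) {
      f <- fit_cols(X, y, setdiff(cur, v), kind, warm = warm)
      if (f$aic < best_aic - 1e-4) { best_aic <- f$aic; best_cols <- setdiff(cur, v) }
    }
    for (v in setdiff(all_cols, cur)) {
      f <- fit_cols(X, y, c(cur, v), kind, warm = warm)
      if (f$aic < best_aic - 1e-4) { best_aic <- f$aic; best_cols <- c(cur, v) }
    }
    if (is.null(best_cols)) break
    cur <- best_cols
    cur_fit <- fit_cols(X, y, cur, kind)
  }
  cur <- cur[order(match(cur, all_cols))]
  list(cols = cur, fit = fit_cols(X, y, cur, kind))
}

# ---- user-facing fitted models ---------------------------------------------

#' Fit the logistic segment-category model
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of
#' segment category (B = 0, W = 1) on the predictor compositions. Complete
#' separation (residual deviance ~ 0 or non-convergence of IRLS) is flagged.
#'
#' @param design A [model_design()] with response `segment_category`, or any
#'   list with `y` (0/1) and `X`.
#' @param cols Predictor subset to include (default all columns of `X`).
#' @return Object of class `ps_fit`: the underlying `glm` in `$model`,
#'   `$coefficients` (estimate, SE, p), `$aic`, `$null_deviance`,
#'   `$resid_deviance`, `$converged`, `$separated`, `$included`.
#' @export
fit_logistic <- function(design, cols = colnames(design$X)) {
  df <- data.frame(.y = design$y)
  for (cl in cols) df[[cl]] <- design$X[, cl]
  m <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = list(maxit = 100)))
  separated <- m$deviance < 1e-6 && length(cols) > 0
  s <- summary(m)$coefficients
  structure(list(
    model = m, kind = "logistic", included = cols,
    coefficients = data.frame(term = rownames(s), estimate = s[, 1],
                              se = s[, 2], p = s[, 4], row.names = NULL),
    aic = m$aic, null_deviance = m$null.deviance,
    resid_deviance = m$deviance,
    converged = m$converged && !m$boundary && !separated,
    separated = separated), class = "ps_fit")
}

#' Fit the linear membership-probability model
#'
#' Ordinary least squares of the arcsine-square-root transformed mean
#' membership probability on the predictor compositions. Aliased (rank
#' deficient) columns are dropped with a warning.
#'
#' @param design A [model_design()] with response `transformed_probability`,
#'   or any list with `y` and `X`.
#' @param cols Predictor subset (default all).
#' @return `ps_fit` with `$r_squared`, `$adj_r_squared`, `$f_p` (overall
#'   F-test p-value) and Gaussian `$aic`.
#' @export
fit_linear <- function(design, cols = colnames(design$X)) {
  df <- data.frame(.y = design$y)
  for (cl in cols) df[[cl]] <- design$X[, cl]
  m <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(m)))
    warning("rank-deficient design: aliased columns dropped")
  s <- summary(m)
  f_p <- if (!is.null(s$fstatistic))
    unname(stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
                     lower.tail = FALSE)) else NA_real_
  cf <- s$coefficients
  structure(list(
    model = m, kind = "linear", included = cols,
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], p = cf[, 4], row.names = NULL),
    aic = stats::AIC(m), r_squared = s$r.squared,
    adj_r_squared = s$adj.r.squared, f_p = f_p,
    converged = TRUE, separated = FALSE), class = "ps_fit")
}

#' @export
print.ps_fit <- function(x, ...) {
  cat(sprintf("%s model, %d predictor(s), AIC %.2f%s\n", x$kind,
              length(x$included), x$aic,
              if (!x$converged) " [non-converged]" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Stepwise model selection by AIC
#'
#' Starts from the full model and repeatedly applies the single variable
#' exclusion (or re-addition of a previously excluded variable) that most
#' lowers AIC, stopping when no move improves it — so the final model is a
#' local AIC optimum and its AIC never exceeds the full model's. The
#' intercept is always retained. AIC counts one parameter per included
#' column plus the intercept (plus the error variance for Gaussian models).
#'
#' @param design A [model_design()].
#' @param kind `"logistic"` or `"linear"`; default follows the design's
#'   response.
#' @return A `ps_fit` refit of the selected predictor subset (see
#'   [fit_logistic()] / [fit_linear()]), with the selection trace AIC in
#'   `$search_aic`.
#' @export
stepwise_aic <- function(design, kind = NULL) {
  if (is.null(kind))
    kind <- if (design$response == "segment_category") "logistic" else "linear"
  sel <- step_cols(design$X, design$y, kind)
  out <- if (kind == "logistic") fit_logistic(design, sel$cols)
  else fit_linear(design, sel$cols)
  out$search_aic <- sel$fit$aic
  out
}

#' Percent deviance explained
#'
#' \eqn{100 (D_{null} - D_{resid}) / D_{null}} for a logistic model; rounding
#' happens only at presentation.
#'
#' @param null_dev Null deviance (> 0).
#' @param resid_dev Residual deviance.
#' @return Percentage (full precision).
#' @export
percent_deviance <- function(null_dev, resid_dev) {
  if (null_dev == 0) stop("null deviance is zero: percent explained undefined")
  if (resid_dev > null_dev + 1e-8)
    warning("residual deviance exceeds null deviance")
  100 * (null_dev - resid_dev) / null_dev
}

#' Bootstrap-wrapped stepwise model selection
#'
#' Resamples the segments with replacement `B` times; each iteration fits the
#' full model, runs stepwise AIC selection, and records which variables were
#' retained along with their coefficients, Wald p-values and the iteration's
#' fit statistic (percent deviance explained, or adjusted R-squared for the
#' linear response). A variable is "selected" when retained in at least
#' `retain` of the `B` iterations. Logistic iterations whose resample holds a
#' single response class are redrawn (bounded retries); iterations whose IRLS
#' flags separation are kept and counted in `n_nonconverged` (their
#' predictions remain well defined even though coefficients diverge).
#'
#' @param segment_table Output of [build_segment_table()] (or compatible).
#' @param width Bandwidth (m) to model.
#' @param response See [model_design()].
#' @param B Bootstrap iterations (default 1000).
#' @param retain Retention threshold (default 900).
#' @param seed Seed for the resampling stream.
#' @param max_redraw Bounded retries per invalid iteration (default 10).
#' @return Object of class `bootstrap_summary`: per-variable `retention`,
#'   conditional `mean_beta` (over iterations where included), `se_beta`,
#'   percentile `ci_lo`/`ci_hi`, `mean_p`, `selected`; per-model
#'   `mean_fit_stat`, `mean_null_dev` (bootstrap mean), `analytic_null_dev`
#'   (full-data null), `n_nonconverged`; and the per-iteration record needed
#'   by [validate()].
#' @export
bootstrap_models <- function(segment_table, width,
                             response = "segment_category",
                             B = 1000, retain = 900, seed = 1L,
                             max_redraw = 10) {
  if (retain > B) stop("retain must be <= B")
  design <- model_design(segment_table, width, response)
  kind <- if (design$response == "segment_category") "logistic" else "linear"
  n <- length(design$y)
  if (n < 10) stop("need >= 10 segments")
  if (kind == "logistic" && length(unique(design$y)) < 2)
    stop("both segment categories must be present")
  vars <- colnames(design$X)
  p <- length(vars)

  idx_mat <- matrix(NA_integer_, B, n)
  inc_mat <- matrix(FALSE, B, p, dimnames = list(NULL, vars))
  coef_mat <- matrix(NA_real_, B, p + 1,
                     dimnames = list(NULL, c("(Intercept)", vars)))
  p_mat <- matrix(NA_real_, B, p + 1,
                  dimnames = list(NULL, c("(Intercept)", vars)))
  fit_stat <- null_dev <- numeric(B)
  n_nonconv <- 0L; n_redrawn <- 0L

  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- NULL
      for (try in seq_len(max_redraw)) {
        cand <- sample.int(n, n, replace = TRUE)
        if (kind != "logistic" || length(unique(design$y[cand])) == 2) {
          idx <- cand; break
        }
        n_redrawn <- n_redrawn + 1L
      }
      if (is.null(idx)) idx <- cand      # shortfall: keep last draw
      idx_mat[b, ] <- idx
      Xb <- design$X[idx, , drop = FALSE]
      yb <- design$y[idx]
      sel <- step_cols(Xb, yb, kind)
      cols <- sel$cols
      inc_mat[b, cols] <- TRUE
      cf <- sel$fit$coef
      coef_mat[b, c("(Intercept)", cols)] <- cf
      # Wald standard errors on the selected fit
      se <- wald_se(Xb, yb, cols, kind, sel$fit)
      if (!is.null(se)) {
        z <- cf / se
        pv <- if (kind == "logistic") 2 * stats::pnorm(-abs(z))
        else 2 * stats::pt(-abs(z), df = n - length(cols) - 1)
        p_mat[b, c("(Intercept)", cols)] <- pv
      }
      if (kind == "logistic") {
        null_dev[b] <- sel$fit$null_dev
        fit_stat[b] <- percent_deviance(sel$fit$null_dev, sel$fit$dev)
        if (isTRUE(sel$fit$separated) || !isTRUE(sel$fit$converged))
          n_nonconv <- n_nonconv + 1L
      } else {
        k <- length(cols)
        tss <- sum((yb - mean(yb))^2)
        r2 <- 1 - sel$fit$rss / tss
        fit_stat[b] <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
        null_dev[b] <- tss
      }
    }
  })

  retention <- colSums(inc_mat)
  cond_stat <- function(f) {
    vapply(seq_len(p + 1), function(j) {
      v <- coef_mat[, j]
      if (all(is.na(v))) NA_real_ else f(v[!is.na(v)])
    }, numeric(1))
  }
  mean_beta <- cond_stat(mean)
  se_beta <- cond_stat(function(v) if (length(v) > 1) stats::sd(v) else NA_real_)
  ci_lo <- cond_stat(function(v) stats::quantile(v, 0.025, names = FALSE))
  ci_hi <- cond_stat(function(v) stats::quantile(v, 0.975, names = FALSE))
  mean_p <- vapply(seq_len(p + 1), function(j) {
    v <- p_mat[, j]; if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))

  analytic_null <- if (kind == "logistic") {
    n1 <- sum(design$y); n0 <- n - n1
    -2 * (n1 * log(n1 / n) + n0 * log(n0 / n))
  } else sum((design$y - mean(design$y))^2)

  structure(list(
    width = width, response = design$response, kind = kind, B = B,
    retain = retain, n = n, variables = c("(Intercept)", vars),
    retention = c(B, retention),
    mean_beta = mean_beta, se_beta = se_beta, ci_lo = ci_lo, ci_hi = ci_hi,
    mean_p = mean_p,
    selected = c(TRUE, retention >= retain),
    mean_fit_stat = mean(fit_stat), mean_null_dev = mean(null_dev),
    analytic_null_dev = analytic_null,
    n_nonconverged = n_nonconv, n_redrawn = n_redrawn,
    iterations = list(idx = idx_mat, included = inc_mat, coef = coef_mat),
    design = design, seed = seed), class = "bootstrap_summary")
}

# Wald SEs for the fast fits; NULL when the information matrix is singular.
wald_se <- function(X, y, cols, kind, fit) {
  Xm <- cbind(1, X[, cols, drop = FALSE])
  cov <- tryCatch({
    if (kind == "logistic") {
      w <- fit$weights
      solve(crossprod(Xm * sqrt(w)))
    } else {
      sigma2 <- fit$rss / (length(y) - length(cols) - 1)
      sigma2 * solve(crossprod(Xm))
    }
  }, error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  sqrt(diag(cov))
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf(
    "bootstrap %s models @ %g m: B = %d, retain >= %d, n = %d segments\n",
    x$kind, x$width, x$B, x$retain, x$n))
  df <- summary(x)
  print(df[df$selected | df$variable == "(Intercept)", ], digits = 4)
  cat(sprintf("mean %s = %.3f\n",
              if (x$kind == "logistic") "% deviance explained" else
                "adjusted R-squared", x$mean_fit_stat))
  invisible(x)
}

#' @export
summary.bootstrap_summary <- function(object, ...) {
  data.frame(variable = object$variables, retention = object$retention,
             mean_beta = object$mean_beta, se = object$se_beta,
             ci_lo = object$ci_lo, ci_hi = object$ci_hi,
             mean_p = object$mean_p, selected = object$selected,
             row.names = NULL)
}

#' Write a bootstrap summary as tidy CSV
#'
#' One row per variable, mirroring the layout of a published coefficient
#' table (width, variable, estimate, SE, CI bounds, mean p, retention,
#' selected), plus the model-level fit statistic columns.
#'
#' @param x A `bootstrap_summary`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_bootstrap_csv <- function(x, path) {
  df <- summary(x)
  df$width <- x$width
  df$response <- x$response
  df$mean_fit_stat <- x$mean_fit_stat
  df$mean_null_dev <- x$mean_null_dev
  df$analytic_null_dev <- x$analytic_null_dev
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
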