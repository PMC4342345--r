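#' @keywords internal
"_PACKAGE"

#' @importFrom stats aggregate as.formula binomial coef cor dist glm glm.fit
#'   lm lm.fit median pf plogis pnorm predict pt qbeta qnorm qt quantile
#'   rbinom rmultinom rnorm runif sd setNames rgamma AIC anova vcov
#' @importFrom utils combn read.csv write.csv head
NULL

# Deterministic sub-seed for a pipeline stage: mixes the master seed with a
# stage label so stages can be re-run in isolation with the same stream.
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 31 + v) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

# Run `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Largest-remainder apportionment of n units to target proportions p
# (p is normalized internally; names preserved).
largest_remainder <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0), sum(p) > 0)
  p <- p / sum(p)
  q <- n * p
  k <- floor(q)
  short <- n - sum(k)
  if (short > 0) {
    ord <- order(q - k, decreasing = TRUE)
    k[ord[seq_len(short)]] <- k[ord[seq_len(short)]] + 1
  } else if (short < 0) {
    ord <- order(q - k)
    i <- 1
    while (short < 0) {
      if (k[ord[i]] > 0) { k[ord[i]] <- k[ord[i]] - 1; short <- short + 1 }
      i <- i + 1
    }
  }
  stats::setNames(as.integer(k), names(p))
}
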