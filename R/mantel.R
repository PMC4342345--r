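#' Simple Mantel test for isolation by distance
#'
#' Correlates linearized genetic distance \eqn{F_{ST}/(1-F_{ST})} with
#' Euclidean geographic distance. `r` is the Pearson correlation of the
#' off-diagonal upper-triangle vectors; significance comes from `n_perm`
#' simultaneous row/column permutations of one matrix, one-sided (permuted
#' `r >=` observed) with the (b+1)/(m+1) small-sample correction. Pairs whose
#' theta equals 1 linearize to infinity and are excluded with a warning.
#'
#' @param fst An [pairwise_fst()] result, or a symmetric genetic-distance
#'   matrix (then used as-is unless `linearize`).
#' @param coords data.frame with `x`, `y` (site or cell centroids, meters) in
#'   matrix label order, or a precomputed symmetric distance matrix.
#' @param n_perm Number of permutations (default 999).
#' @param linearize Apply theta/(1 - theta) (default TRUE when `fst` is an
#'   `fst_matrix`).
#' @param seed Optional seed.
#' @return Object of class `mantel_result`: list with `r`, `p`, `n_perm`,
#'   `n_pairs`.
#' @export
mantel_ibd <- function(fst, coords, n_perm = 999,
                       linearize = inherits(fst, "fst_matrix"), seed = NULL) {
  gm <- if (inherits(fst, "fst_matrix")) fst$theta else as.matrix(fst)
  if (nrow(gm) != ncol(gm)) stop("genetic matrix must be square")
  if (linearize) {
    inf <- gm >= 1
    inf[is.na(inf)] <- FALSE
    diag(inf) <- FALSE
    if (any(inf)) {
      warning(sum(inf) / 2, " pair(s) with theta = 1 excluded (infinite ",
              "linearized distance)")
      gm[inf] <- NA_real_
    }
    gm <- gm / (1 - gm)
  }
  dm <- if (is.matrix(coords) || inherits(coords, "dist")) {
    as.matrix(coords)
  } else {
    as.matrix(stats::dist(coords[, c("x", "y")]))
  }
  if (!all(dim(dm) == dim(gm)))
    stop("matrices must be square with the same labels")
  n <- nrow(gm)
  ut <- upper.tri(gm)
  ok <- ut & !is.na(gm) & !is.na(dm)
  if (sum(ok) < 3) stop("fewer than 3 usable pairs")
  r_obs <- stats::cor(gm[ok], dm[ok])
  p <- NA_real_
  if (n_perm > 0) {
    p <- with_seed(seed, {
      ge <- 0L
      for (b in seq_len(n_perm)) {
        prm <- sample.int(n)
        dp <- dm[prm, prm]
        use <- ut & !is.na(gm) & !is.na(dp)
        rp <- if (sum(use) >= 3) stats::cor(gm[use], dp[use]) else NA_real_
        if (!is.na(rp) && rp >= r_obs) ge <- ge + 1L
      }
      (ge + 1) / (n_perm + 1)
    })
  }
  structure(list(r = r_obs, p = p, n_perm = n_perm, n_pairs = sum(ok)),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel IBD: r = %.3f, p = %.4g (%d permutations, %d pairs)\n",
              x$r, x$p, x$n_perm, x$n_pairs))
  invisible(x)
}
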