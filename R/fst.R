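#' Weir-Cockerham variance components and theta
#'
#' Variance-components estimator of F_ST (Weir & Cockerham 1984). For every
#' locus and allele the among-population (a), among-individuals-within-
#' population (b) and within-individual (c) components are computed from the
#' per-population allele frequencies, heterozygote frequencies and sample
#' sizes; the multilocus estimate is the ratio of sums
#' \eqn{\hat\theta = \sum a / \sum (a + b + c)} over all alleles and loci
#' (never a mean of per-locus ratios).
#'
#' @param G A [genotype_matrix()].
#' @param pops Integer vector of population labels, one per individual.
#' @return List with `theta` and the summed components `a`, `b`, `c`.
#' @export
wc_theta <- function(G, pops) {
  ap <- allele_pair(G)
  sum_a <- sum_b <- sum_c <- 0
  for (l in seq_along(G$loci)) {
    comp <- wc_locus(ap$a1[, l], ap$a2[, l], pops)
    if (is.null(comp)) next
    sum_a <- sum_a + sum(comp$a)
    sum_b <- sum_b + sum(comp$b)
    sum_c <- sum_c + sum(comp$c)
  }
  denom <- sum_a + sum_b + sum_c
  list(theta = if (denom == 0) NA_real_ else sum_a / denom,
       a = sum_a, b = sum_b, c = sum_c)
}

# Per-allele a/b/c components at one locus; NULL if < 2 populations typed
# or mean sample size <= 1.
wc_locus <- function(a1, a2, pops) {
  ok <- !is.na(a1)
  if (!any(ok)) return(NULL)
  a1 <- a1[ok]; a2 <- a2[ok]; pops <- pops[ok]
  up <- sort(unique(pops))
  r <- length(up)
  if (r < 2) return(NULL)
  n_i <- as.numeric(table(factor(pops, levels = up)))
  alleles <- sort(unique(c(a1, a2)))
  pf <- factor(pops, levels = up)
  # allele frequencies p[pop, allele]
  cnt <- table(pf, factor(a1, levels = alleles)) +
    table(pf, factor(a2, levels = alleles))
  p <- sweep(unclass(cnt), 1, 2 * n_i, "/")
  # heterozygote frequencies h[pop, allele]
  het <- a1 != a2
  hcnt <- table(pf[het], factor(a1[het], levels = alleles)) +
    table(pf[het], factor(a2[het], levels = alleles))
  h <- matrix(0, r, length(alleles))
  if (any(het)) h[match(rownames(hcnt), up), ] <- unclass(hcnt)
  h <- sweep(h, 1, n_i, "/")

  nbar <- mean(n_i)
  if (nbar <= 1) return(NULL)
  nsum <- sum(n_i)
  nc <- (nsum - sum(n_i^2) / nsum) / (r - 1)
  pbar <- colSums(n_i * p) / nsum
  s2 <- colSums(n_i * sweep(p, 2, pbar, "-")^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h) / nsum

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Pairwise Weir-Cockerham F_ST with permutation tests
#'
#' Multilocus theta for every population pair, with one-sided significance
#' from `n_perm` random reassignments of the pair's individuals to the two
#' populations (sample sizes preserved):
#' \eqn{p = (\#\{\hat\theta_{perm} \ge \hat\theta_{obs}\} + 1)/(n_{perm}+1)}.
#' Loci are dropped from a pair only where one population has no typed calls;
#' a population with no calls at any locus yields `NA` for its pairs.
#'
#' @param G A [genotype_matrix()].
#' @param partition A [population_partition()] with `individual_to_pop`.
#' @param n_perm Number of randomizations (default 1200).
#' @param seed Optional seed.
#' @return Object of class `fst_matrix`: list with symmetric matrices `theta`
#'   and `p` (dimnames = population ids) and `n_perm`.
#' @export
pairwise_fst <- function(G, partition, n_perm = 1200, seed = NULL) {
  pops <- partition$individual_to_pop[G$individuals$id]
  if (anyNA(pops)) stop("partition does not cover all individuals")
  up <- sort(unique(pops))
  if (length(up) < 2) stop("need >= 2 populations")
  k <- length(up)
  th <- pm <- matrix(NA_real_, k, k, dimnames = list(up, up))
  diag(th) <- 0
  with_seed(seed, {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      rows <- which(pops %in% c(up[i], up[j]))
      sub <- subset_genotypes(G, rows)
      lab <- pops[rows]
      typed <- vapply(c(up[i], up[j]), function(p) {
        any(sub$calls[lab == p, , drop = FALSE] != 0L)
      }, logical(1))
      if (!all(typed)) next              # population with no calls: missing
      obs <- wc_theta(sub, lab)$theta
      th[i, j] <- th[j, i] <- obs
      if (n_perm > 0 && !is.na(obs)) {
        ge <- 0L
        for (b in seq_len(n_perm)) {
          tp <- wc_theta(sub, sample(lab))$theta
          if (!is.na(tp) && tp >= obs) ge <- ge + 1L
        }
        pm[i, j] <- pm[j, i] <- (ge + 1) / (n_perm + 1)
      }
    }
  })
  structure(list(theta = th, p = pm, n_perm = n_perm), class = "fst_matrix")
}

# Row subset of a genotype_matrix. Internal.
subset_genotypes <- function(G, rows) {
  genotype_matrix(G$calls[rows, , drop = FALSE],
                  G$individuals[rows, , drop = FALSE], G$loci)
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("pairwise Weir-Cockerham F_ST (", x$n_perm, " randomizations)\n",
      sep = "")
  print(round(x$theta, 4))
  invisible(x)
}
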