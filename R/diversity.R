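#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies, computed by the hypergeometric rarefaction formula
#' \eqn{A_R(g) = \sum_a [1 - C(N - N_a, g)/C(N, g)]} over alleles `a` with
#' count \eqn{N_a} among the \eqn{N} typed gene copies.
#'
#' @param counts Named or unnamed integer vector of allele counts.
#' @param g Rarefaction size in gene copies (`g <= sum(counts)`).
#' @return Expected allele count; equals the observed allele number when
#'   `g == sum(counts)`, and is monotone nondecreasing in `g`.
#' @export
allelic_richness <- function(counts, g) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (g < 1 || g > N) stop("g must lie in 1..sum(counts)")
  # lchoose is stable; C(N - Na, g) = 0 whenever N - Na < g
  sum(1 - exp(lchoose(N - counts, g) - lchoose(N, g)))
}

# Per-locus, per-population allele count table; list over loci of named
# count vectors. Internal.
pop_allele_counts <- function(G, rows, l) {
  a <- c(G$calls[rows, 2L * l - 1L], G$calls[rows, 2L * l])
  a <- a[a != 0L]
  if (!length(a)) return(integer(0))
  table(a)
}

# F_IS = 1 - Ho/He (unbiased He); NA for monomorphic/undefined loci.
fis_one <- function(a1, a2) {
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n < 2) return(NA_real_)
  alle <- c(a1, a2)
  p <- table(alle) / (2 * n)
  he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  if (he <= 0) return(NA_real_)       # monomorphic: undefined, not 0
  ho <- mean(a1 != a2)
  1 - ho / he
}

#' Per-locus, per-population diversity summary
#'
#' Standard microsatellite diversity metrics: typed sample size N, observed
#' allele number Na, observed heterozygosity Ho, unbiased expected
#' heterozygosity He (small-sample corrected, \eqn{2n/(2n-1)(1-\sum p^2)}),
#' allelic richness rarefied to `g` gene copies, and F_IS (= 1 - Ho/He) with
#' a 95% permutation envelope obtained by re-pairing alleles at random within
#' the population (`n_perm` permutations), i.e. the interval F_IS would span
#' under Hardy-Weinberg random mating.
#'
#' @param G A [genotype_matrix()].
#' @param partition A [population_partition()] covering `G`'s individuals.
#' @param g Rarefaction size in gene copies; default twice the smallest
#'   per-population typed sample over loci.
#' @param n_perm Permutations for the F_IS envelope (default 1000).
#' @param seed Optional seed for the permutations.
#' @return data.frame with one row per locus x population: `pop`, `locus`,
#'   `N`, `Na`, `Ho`, `He`, `AR`, `Fis`, `Fis_lo`, `Fis_hi`. Monomorphic loci
#'   report `Fis` as `NA`.
#' @export
diversity_summary <- function(G, partition, g = NULL, n_perm = 1000,
                              seed = NULL) {
  if (nrow(G$calls) < 2) stop("need >= 2 individuals")
  ap <- allele_pair(G)
  pops <- partition$individual_to_pop[G$individuals$id]
  if (anyNA(pops)) stop("partition does not cover all individuals")
  L <- length(G$loci)
  upops <- sort(unique(pops))
  if (is.null(g)) {
    typed <- vapply(upops, function(p) {
      rows <- which(pops == p)
      min(vapply(seq_len(L), function(l)
        sum(!is.na(ap$a1[rows, l])), integer(1)))
    }, integer(1))
    g <- max(2L, 2L * min(typed))
  }
  with_seed(seed, {
    out <- vector("list", length(upops) * L)
    i <- 0L
    for (p in upops) {
      rows <- which(pops == p)
      for (l in seq_len(L)) {
        i <- i + 1L
        a1 <- ap$a1[rows, l]; a2 <- ap$a2[rows, l]
        ok <- !is.na(a1)
        N <- sum(ok)
        cnt <- table(c(a1[ok], a2[ok]))
        Na <- length(cnt)
        Ho <- if (N > 0) mean(a1[ok] != a2[ok]) else NA_real_
        He <- if (N > 1) {
          pr <- cnt / (2 * N)
          (2 * N / (2 * N - 1)) * (1 - sum(pr^2))
        } else NA_real_
        AR <- if (N > 0 && g <= 2 * N) allelic_richness(cnt, g) else NA_real_
        fis <- fis_one(a1, a2)
        lo <- hi <- NA_real_
        if (!is.na(fis) && n_perm > 0) {
          alle <- c(a1[ok], a2[ok])
          perm <- vapply(seq_len(n_perm), function(j) {
            s <- sample(alle)
            fis_one(s[seq_len(N)], s[N + seq_len(N)])
          }, numeric(1))
          qs <- stats::quantile(perm, c(0.025, 0.975), na.rm = TRUE,
                                names = FALSE)
          lo <- qs[1]; hi <- qs[2]
        }
        out[[i]] <- data.frame(pop = p, locus = G$loci[l], N = N, Na = Na,
                               Ho = Ho, He = He, AR = AR, Fis = fis,
                               Fis_lo = lo, Fis_hi = hi)
      }
    }
    do.call(rbind, out)
  })
}
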