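#' Construct a diploid multilocus genotype matrix
#'
#' Microsatellite-style integer genotype calls: two allele columns per locus,
#' `0` coding a missing call. Both alleles of a call must be present or both
#' missing.
#'
#' @param calls Integer matrix, one row per individual, `2 * n_loci` columns
#'   (`<locus>.1`, `<locus>.2`).
#' @param individuals data.frame with columns `id` and `site_id`.
#' @param loci Character vector of locus ids.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, individuals, loci) {
  calls <- as.matrix(calls); storage.mode(calls) <- "integer"
  if (ncol(calls) != 2L * length(loci))
    stop("calls must have two columns per locus")
  if (nrow(calls) != nrow(individuals))
    stop("one row of calls per individual")
  if (any(calls < 0L)) stop("allele codes must be nonnegative (0 = missing)")
  a1 <- calls[, seq(1L, ncol(calls), 2L), drop = FALSE]
  a2 <- calls[, seq(2L, ncol(calls), 2L), drop = FALSE]
  if (any((a1 == 0L) != (a2 == 0L)))
    stop("both alleles of a call must be present or both missing")
  colnames(calls) <- as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  rownames(calls) <- individuals$id
  structure(list(calls = calls, individuals = individuals, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.1f%% missing)\n",
              nrow(x$calls), length(x$loci), 100 * mean(x$calls == 0L)))
  invisible(x)
}

# Two allele matrices (n x L) for a genotype_matrix; NA where missing.
allele_pair <- function(G) {
  a1 <- G$calls[, seq(1L, ncol(G$calls), 2L), drop = FALSE]
  a2 <- G$calls[, seq(2L, ncol(G$calls), 2L), drop = FALSE]
  a1[a1 == 0L] <- NA_integer_; a2[a2 == 0L] <- NA_integer_
  list(a1 = a1, a2 = a2)
}

#' Simulate genotypes under the F-model
#'
#' Ancestral allele frequencies are drawn symmetric-Dirichlet(1) per locus;
#' each population's frequencies are Dirichlet-distributed around the
#' ancestral vector with concentration `(1 - theta)/theta`, so the expected
#' Weir-Cockerham differentiation equals `theta_drift`. Diploid genotypes are
#' then sampled independently from each individual's population frequencies.
#'
#' @param partition A [population_partition()] with `individual_to_pop` set.
#' @param cfg A [scenario_config()]; uses `n_loci`, `alleles_per_locus`,
#'   `theta_drift`, `seed`.
#' @return A [genotype_matrix()]; deterministic given `cfg$seed`.
#' @export
simulate_genotypes <- function(partition, cfg) {
  if (is.null(partition$individual_to_pop))
    stop("partition must carry individual_to_pop")
  if (cfg$alleles_per_locus < 2) stop("alleles_per_locus must be >= 2")
  ids <- names(partition$individual_to_pop)
  pops <- partition$individual_to_pop
  n <- length(ids); L <- cfg$n_loci; A <- cfg$alleles_per_locus
  k <- partition$k
  conc <- (1 - cfg$theta_drift) / cfg$theta_drift
  calls <- with_seed(derive_seed(cfg$seed, "genotypes"), {
    out <- matrix(0L, n, 2L * L)
    for (l in seq_len(L)) {
      anc <- stats::rgamma(A, 1); anc <- anc / sum(anc)
      pf <- matrix(0, k, A)
      for (p in seq_len(k)) {
        g <- stats::rgamma(A, anc * conc)
        if (sum(g) == 0) g <- anc          # numerical underflow guard
        pf[p, ] <- g / sum(g)
      }
      for (p in seq_len(k)) {
        rows <- which(pops == p)
        if (!length(rows)) next
        out[rows, 2L * l - 1L] <- sample.int(A, length(rows), TRUE, pf[p, ])
        out[rows, 2L * l] <- sample.int(A, length(rows), TRUE, pf[p, ])
      }
    }
    out
  })
  site_id <- sub("_i[0-9]+$", "", ids)
  genotype_matrix(calls, data.frame(id = ids, site_id = site_id,
                                    stringsAsFactors = FALSE),
                  sprintf("L%02d", seq_len(L)))
}

#' Write / read genotypes as CSV
#'
#' Layout: `id`, `site_id`, then two columns per locus; 0 = missing call.
#'
#' @param G A [genotype_matrix()].
#' @param path File path.
#' @return The path (write) or a [genotype_matrix()] (read).
#' @export
write_genotypes_csv <- function(G, path) {
  utils::write.csv(cbind(G$individuals, as.data.frame(G$calls)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_csv
#' @export
read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- df[, c("id", "site_id")]
  calls <- as.matrix(df[, setdiff(names(df), c("id", "site_id"))])
  loci <- unique(sub("\\.[12]$", "", colnames(calls)))
  genotype_matrix(calls, meta, loci)
}
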