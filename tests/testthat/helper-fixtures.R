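# Shared fixtures, built in code.

# Uniform single-class raster.
uniform_raster <- function(class = "forest", n = 40, res = 30) {
  land_raster(matrix(match(class, land_classes()), n, n), resolution = res)
}

# Three collinear populations mirroring the published segment-selection
# diagram: P1 on x = 0, P2 on x = 600 within threshold, P3 far away.
fig_sites <- function() {
  data.frame(
    id = c("A1", "A2", "A3", "B1", "B2", "C1"),
    x = c(0, 0, 0, 600, 600, 5000),
    y = c(0, 1000, 2000, 0, 1000, 0),
    cell_id = "C01", habitat_class = "forest", stringsAsFactors = FALSE)
}

fig_partition <- function() {
  population_partition(3, c(A1 = 1, A2 = 1, A3 = 1, B1 = 2, B2 = 2, C1 = 3))
}

# Tiny two-population genotype fixture with hand-computed Weir-Cockerham
# variance components (1 locus, alleles 1/2):
#   pop1: 11, 11, 12, 22   pop2: 12, 22, 22, 22
# a = 17/192 per allele, b = 1/12, c = 1/8, theta = 17/57.
wc_fixture <- function() {
  calls <- rbind(c(1, 1), c(1, 1), c(1, 2), c(2, 2),
                 c(1, 2), c(2, 2), c(2, 2), c(2, 2))
  inds <- data.frame(id = paste0("i", 1:8), site_id = rep(c("s1", "s2"), each = 4),
                     stringsAsFactors = FALSE)
  G <- genotype_matrix(calls, inds, "L1")
  pops <- rep(1:2, each = 4)
  list(G = G, pops = pops, theta = 17 / 57)
}

# Genotype matrix sampled from explicit per-population allele frequencies.
sample_genotypes <- function(freqs_by_pop, n_per_pop, n_loci, seed) {
  set.seed(seed)
  k <- length(freqs_by_pop)
  n <- k * n_per_pop
  calls <- matrix(0L, n, 2 * n_loci)
  for (p in seq_len(k)) {
    rows <- (p - 1) * n_per_pop + seq_len(n_per_pop)
    fr <- freqs_by_pop[[p]]
    for (l in seq_len(n_loci)) {
      calls[rows, 2 * l - 1] <- sample.int(length(fr), n_per_pop, TRUE, fr)
      calls[rows, 2 * l] <- sample.int(length(fr), n_per_pop, TRUE, fr)
    }
  }
  ids <- sprintf("i%03d", seq_len(n))
  G <- genotype_matrix(calls, data.frame(id = ids, site_id = ids,
                                         stringsAsFactors = FALSE),
                       sprintf("L%02d", seq_len(n_loci)))
  part <- population_partition(
    k, setNames(rep(seq_len(k), each = n_per_pop), ids),
    setNames(rep(seq_len(k), each = n_per_pop), ids))
  list(G = G, partition = part)
}

# Small segment data.frame with known composition columns for model tests.
synthetic_design <- function(n, beta, seed, noise_sd = 0, w_fraction = 0.5) {
  set.seed(seed)
  X <- matrix(abs(rnorm(n * 8, 0.2, 0.15)), n, 8,
              dimnames = list(NULL, predictor_classes()))
  X <- pmin(X, 1)
  eta <- drop(X %*% beta[predictor_classes()])
  eta <- eta - mean(eta) + qlogis(w_fraction)
  y <- rbinom(n, 1, plogis(eta))
  d <- data.frame(category = ifelse(y == 1, "W", "B"),
                  length = runif(n, 100, 1500), stringsAsFactors = FALSE)
  d <- cbind(d, as.data.frame(X))
  d$agriculture <- pmax(0, 1 - rowSums(X))
  d$membership <- plogis(eta + rnorm(n, 0, max(noise_sd, 1e-12)))
  d$width <- 50
  d
}

zero_beta <- function() setNames(numeric(8), predictor_classes())
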