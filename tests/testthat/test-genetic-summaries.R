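test_that("Weir-Cockerham theta matches the hand-computed fixture", {
  fx <- wc_fixture()
  res <- wc_theta(fx$G, fx$pops)
  # per-allele components doubled over the two alleles of the single locus
  expect_equal(res$a, 2 * 17 / 192, tolerance = 1e-9)
  expect_equal(res$b, 2 * 1 / 12, tolerance = 1e-9)
  expect_equal(res$c, 2 * 1 / 8, tolerance = 1e-9)
  expect_equal(res$theta, fx$theta, tolerance = 1e-9)
})

test_that("theta is invariant to allele relabeling and population order", {
  fx <- wc_fixture()
  base <- wc_theta(fx$G, fx$pops)$theta
  # swap allele codes 1 <-> 2
  calls <- fx$G$calls
  calls[] <- ifelse(calls == 1L, 2L, ifelse(calls == 2L, 1L, calls))
  G2 <- genotype_matrix(calls, fx$G$individuals, fx$G$loci)
  expect_equal(wc_theta(G2, fx$pops)$theta, base, tolerance = 1e-12)
  # relabel populations
  expect_equal(wc_theta(fx$G, 3L - fx$pops)$theta, base, tolerance = 1e-12)
})

test_that("fixed differences give theta = 1 and shared frequencies near 0", {
  fixed <- sample_genotypes(list(c(1, 0), c(0, 1)), 20, 3, seed = 1)
  expect_equal(
    pairwise_fst(fixed$G, fixed$partition, n_perm = 0)$theta[1, 2], 1)

  reps <- vapply(1:20, function(i) {
    sg <- sample_genotypes(list(c(0.5, 0.3, 0.2), c(0.5, 0.3, 0.2)),
                           200, 6, seed = 100 + i)
    f <- pairwise_fst(sg$G, sg$partition, n_perm = 60, seed = i)
    c(f$theta[1, 2], f$p[1, 2])
  }, numeric(2))
  expect_gte(mean(abs(reps[1, ]) < 0.01), 0.9)
  expect_gte(mean(reps[2, ] > 0.05), 0.9)
})

test_that("F-model drift parameter is recovered by theta (consistency)", {
  est <- vapply(1:50, function(i) {
    ids <- sprintf("i%03d", 1:400)
    part <- population_partition(2, setNames(rep(1:2, each = 200), ids),
                                 setNames(rep(1:2, each = 200), ids))
    cfg <- scenario_config(seed = 5000 + i, theta_drift = 0.1, n_loci = 12,
                           alleles_per_locus = 8)
    G <- simulate_genotypes(part, cfg)
    wc_theta(G, part$individual_to_pop[G$individuals$id])$theta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.1), 0.02)
})

test_that("near-zero drift yields near-zero theta, and seeds reproduce", {
  ids <- sprintf("i%03d", 1:400)
  part <- population_partition(2, setNames(rep(1:2, each = 200), ids),
                               setNames(rep(1:2, each = 200), ids))
  cfg <- scenario_config(seed = 77, theta_drift = 1e-6)
  G <- simulate_genotypes(part, cfg)
  expect_lt(abs(wc_theta(G, part$individual_to_pop[G$individuals$id])$theta),
            0.01)
  expect_identical(G$calls, simulate_genotypes(part, cfg)$calls)
  expect_error(simulate_genotypes(
    part, scenario_config(seed = 1, alleles_per_locus = 1)), "alleles")
})

test_that("rarefied allelic richness matches exhaustive enumeration", {
  # counts {A: 5, B: 3}, g = 4: enumerate all 4-gene subsamples
  genes <- c(rep("A", 5), rep("B", 3))
  subs <- combn(8, 4)
  enum <- mean(apply(subs, 2, function(ix) length(unique(genes[ix]))))
  expect_equal(allelic_richness(c(A = 5, B = 3), 4), enum, tolerance = 1e-12)
  expect_equal(enum, 27 / 14, tolerance = 1e-12)
  # rarefaction identity at full sample, and monotonicity in g
  expect_equal(allelic_richness(c(5, 3), 8), 2)
  ar <- vapply(1:8, function(g) allelic_richness(c(5, 3), g), numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
})

test_that("diversity summary handles fixed loci and reports sane metrics", {
  calls <- cbind(rep(1L, 6), rep(1L, 6),                  # L1 fixed
                 c(1L, 1L, 2L, 2L, 1L, 2L), c(2L, 1L, 2L, 1L, 1L, 2L))
  G <- genotype_matrix(calls, data.frame(id = paste0("i", 1:6),
                                         site_id = "s1"), c("L1", "L2"))
  part <- population_partition(1, c(s1 = 1),
                               setNames(rep(1L, 6), paste0("i", 1:6)))
  d <- diversity_summary(G, part, g = 4, n_perm = 100, seed = 1)
  l1 <- d[d$locus == "L1", ]
  expect_equal(l1$Ho, 0); expect_equal(l1$He, 0); expect_equal(l1$Na, 1L)
  expect_equal(l1$AR, 1)
  expect_true(is.na(l1$Fis))               # monomorphic: missing, not 0
  l2 <- d[d$locus == "L2", ]
  expect_true(l2$Ho >= 0 && l2$Ho <= 1 && l2$He >= 0 && l2$He <= 1)
  expect_true(l2$Fis >= -1 && l2$Fis <= 1)
  expect_true(l2$Fis_lo <= l2$Fis_hi)
})

test_that("mantel r equals direct Pearson on off-diagonal vectors", {
  set.seed(42)
  gm <- matrix(0, 4, 4); gm[upper.tri(gm)] <- runif(6)
  gm <- gm + t(gm)
  dm <- matrix(0, 4, 4); dm[upper.tri(dm)] <- runif(6)
  dm <- dm + t(dm)
  r <- mantel_ibd(gm, dm, n_perm = 0, linearize = FALSE)$r
  expect_equal(r, cor(gm[upper.tri(gm)], dm[upper.tri(dm)]),
               tolerance = 1e-12)
  # exact affine relation gives r = 1
  expect_equal(mantel_ibd(2 * dm + 3, dm, n_perm = 0, linearize = FALSE)$r,
               1, tolerance = 1e-12)
})

test_that("mantel r matches vegan and is invariant to matrix shifts", {
  skip_if_not_installed("vegan")
  set.seed(9)
  n <- 7
  gm <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  dm <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  ours <- mantel_ibd(gm, dm, n_perm = 0, linearize = FALSE)$r
  ref <- vegan::mantel(as.dist(gm), as.dist(dm), permutations = 0)$statistic
  expect_equal(ours, unname(ref), tolerance = 1e-12)
  shifted <- mantel_ibd(gm + 5, dm, n_perm = 0, linearize = FALSE)$r
  expect_equal(shifted, ours, tolerance = 1e-12)
  flipped <- mantel_ibd(-gm, dm, n_perm = 0, linearize = FALSE)$r
  expect_equal(flipped, -ours, tolerance = 1e-12)
})

test_that("theta = 1 pairs are excluded from the linearized mantel", {
  th <- matrix(c(0, 0.2, 1, 0.2, 0, 0.3, 1, 0.3, 0), 3, 3)
  fst <- structure(list(theta = th, p = th * 0, n_perm = 0),
                   class = "fst_matrix")
  coords <- data.frame(x = c(0, 1, 5), y = c(0, 0, 0))
  expect_warning(expect_error(mantel_ibd(fst, coords, n_perm = 0),
                              "fewer than 3"), "theta = 1")
})

test_that("assignment posteriors recover true populations when diverged", {
  hits <- vapply(1:10, function(i) {
    ids <- sprintf("i%03d", 1:60)
    part <- population_partition(2, setNames(rep(1:2, each = 30), ids),
                                 setNames(rep(1:2, each = 30), ids))
    cfg <- scenario_config(seed = 300 + i, theta_drift = 0.3, n_loci = 12)
    G <- simulate_genotypes(part, cfg)
    post <- assign_posteriors(G, part)
    mean(max.col(post) == part$individual_to_pop[rownames(post)])
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("posteriors degenerate properly: k = 1, no information, missing", {
  fx <- wc_fixture()
  part1 <- population_partition(
    1, c(s1 = 1, s2 = 1), setNames(rep(1L, 8), fx$G$individuals$id))
  post <- assign_posteriors(fx$G, part1)
  expect_true(all(post == 1))
  # monomorphic shared frequencies: uniform regardless of pseudo-count
  calls <- cbind(rep(1L, 8), rep(1L, 8))
  Gm <- genotype_matrix(calls, fx$G$individuals, "L1")
  part2 <- population_partition(
    2, c(s1 = 1, s2 = 2),
    setNames(rep(1:2, each = 4), fx$G$individuals$id))
  p1 <- assign_posteriors(Gm, part2, pseudo = 1)
  p2 <- assign_posteriors(Gm, part2, pseudo = 2)
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_true(all(abs(p1 - 0.5) < 1e-12))
  # all-missing individual gets uniform vector and a flag
  calls2 <- fx$G$calls; calls2[1, ] <- 0L
  Gmiss <- genotype_matrix(calls2, fx$G$individuals, "L1")
  pm <- assign_posteriors(Gmiss, part2)
  expect_equal(unname(pm[1, ]), c(0.5, 0.5))
  expect_equal(attr(pm, "flagged"), "i1")
})
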