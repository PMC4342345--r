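test_that("within-population median follows brute-force enumeration", {
  sites <- fig_sites(); part <- fig_partition()
  # P1 collinear at 0/1000/2000: pairwise {1000, 1000, 2000}; P2: {1000};
  # P3 single-site contributes nothing
  expect_equal(within_median(part, sites), 1000)
  one_pop <- population_partition(1, setNames(rep(1, 3), c("A1", "A2", "A3")))
  expect_equal(within_median(one_pop, sites[1:3, ]), 1000)
  # scope = pair pools only the two named populations
  expect_equal(within_median(part, sites, scope = "pair", pops = c(1, 2)),
               1000)
  # all single-site populations: undefined
  singles <- population_partition(3, c(A1 = 1, B1 = 2, C1 = 3))
  expect_error(within_median(singles, sites[c(1, 4, 6), ]), "undefined")
})

test_that("segment-selection fixture yields exactly 1 B and 2 W segments", {
  sites <- fig_sites(); part <- fig_partition()
  thr <- within_median(part, sites)
  b <- find_b_segments(part, sites, thr)
  expect_equal(nrow(b), 1L)
  expect_equal(b$site_a, "A1"); expect_equal(b$site_b, "B1")
  expect_equal(b$length, 600)
  w <- find_w_segments(part, sites, b)
  expect_equal(nrow(w), 2L)
  # P1: candidates {1000, 1000, 2000}, target 600 -> tie at 1000 broken
  # lexicographically to (A1, A2); P2 has only one pair
  w1 <- w[w$pop_a == 1, ]
  expect_equal(c(w1$site_a, w1$site_b), c("A1", "A2"))
  expect_equal(w1$length, 1000)
  w2 <- w[w$pop_a == 2, ]
  expect_equal(c(w2$site_a, w2$site_b), c("B1", "B2"))
  # endpoint-cluster consistency
  s2p <- part$site_to_pop
  expect_true(all(s2p[b$site_a] != s2p[b$site_b]))
  expect_true(all(s2p[w$site_a] == s2p[w$site_b]))
})

test_that("no B segments beyond threshold; isolated pops use the fallback", {
  sites <- fig_sites(); part <- fig_partition()
  expect_equal(nrow(find_b_segments(part, sites, 100)), 0L)
  # with no B segment, P1's W target is the fallback length
  w <- find_w_segments(part, sites, find_b_segments(part, sites, 100),
                       fallback_length = 1800)
  w1 <- w[w$pop_a == 1, ]
  expect_equal(w1$length, 2000)   # |2000 - 1800| < |1000 - 1800|
})

test_that("rectangle pixel extraction matches brute-force enumeration", {
  r <- uniform_raster(n = 30)
  ctr <- permscape:::pixel_centers(r)
  # axis-aligned 300 m segment between pixel centers, width 60 m
  seg <- list(x0 = ctr$x[5], y0 = ctr$y[15], x1 = ctr$x[15], y1 = ctr$y[15])
  px <- segment_pixels(seg, 60, r)
  expect_equal(nrow(px), 22L)      # 11 along-axis x 2 across (half-open band)

  # brute force over all pixel centers with the same closed/half-open rule
  brute <- function(seg, width) {
    L <- sqrt((seg$x1 - seg$x0)^2 + (seg$y1 - seg$y0)^2)
    ux <- (seg$x1 - seg$x0) / L; uy <- (seg$y1 - seg$y0) / L
    hits <- 0L
    for (i in seq_len(r$n_rows)) for (j in seq_len(r$n_cols)) {
      dx <- ctr$x[j] - seg$x0; dy <- ctr$y[i] - seg$y0
      t <- dx * ux + dy * uy; perp <- -dx * uy + dy * ux
      if (t >= -1e-9 && t <= L + 1e-9 &&
          perp >= -width / 2 - 1e-9 && perp < width / 2 - 1e-9)
        hits <- hits + 1L
    }
    hits
  }
  set.seed(7)
  for (rep in 1:10) {
    seg2 <- list(x0 = runif(1, 100, 800), y0 = runif(1, 100, 800),
                 x1 = runif(1, 100, 800), y1 = runif(1, 100, 800))
    wd <- sample(c(3, 10, 50, 200), 1)
    expect_equal(nrow(segment_pixels(seg2, wd, r)), brute(seg2, wd))
  }
})

test_that("thin segments never return empty pixel sets", {
  r <- uniform_raster(n = 10)
  # 3 m width, diagonal segment avoiding all pixel centers
  seg <- list(x0 = 2, y0 = 2, x1 = 8, y1 = 9)
  px <- segment_pixels(seg, 3, r)
  expect_gte(nrow(px), 1L)
})

test_that("pixel counts are monotone in width and rotation invariant", {
  r <- uniform_raster(n = 31)
  ctr <- permscape:::pixel_centers(r)
  seg <- list(x0 = ctr$x[8], y0 = ctr$y[16], x1 = ctr$x[24], y1 = ctr$y[16])
  counts <- vapply(width_set(), function(w) nrow(segment_pixels(seg, w, r)),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
  # rotate the scene by 90 degrees on the symmetric square raster
  segr <- list(x0 = ctr$x[16], y0 = ctr$y[8], x1 = ctr$x[16], y1 = ctr$y[24])
  for (w in c(3, 60, 150))
    expect_equal(nrow(segment_pixels(segr, w, r)),
                 nrow(segment_pixels(seg, w, r)))
})

test_that("composition is exact on constructed rasters", {
  rf <- uniform_raster("forest", n = 20)
  seg <- list(x0 = 100, y0 = 300, x1 = 500, y1 = 300)
  comp <- composition(seg, 100, rf)
  expect_equal(unname(comp[["forest"]]), 1)
  expect_equal(sum(comp), 1, tolerance = 1e-6)

  # half forest / half agriculture split at x = 300 with a horizontal
  # segment centered on the boundary: symmetric pixel counts, exactly 0.5
  m <- matrix(match("forest", land_classes()), 20, 20)
  m[, 11:20] <- match("agriculture", land_classes())
  rs <- land_raster(m)
  seg2 <- list(x0 = 105, y0 = 300, x1 = 495, y1 = 300)
  comp2 <- composition(seg2, 400, rs)
  expect_equal(unname(comp2[["forest"]]), 0.5, tolerance = 1e-9)
  expect_equal(unname(comp2[["agriculture"]]), 0.5, tolerance = 1e-9)
  expect_equal(sum(comp2), 1, tolerance = 1e-6)
})

test_that("compositions are invariant to joint translation", {
  cfg <- scenario_config(seed = 12, cell_side = 1500)
  r <- generate_landcover(cfg)
  seg <- list(x0 = 200, y0 = 350, x1 = 1100, y1 = 900)
  c1 <- composition(seg, 100, r)
  cfg2 <- cfg; cfg2$origin_x <- 5000; cfg2$origin_y <- -3000
  r2 <- generate_landcover(cfg2)
  seg2 <- list(x0 = seg$x0 + 5000, y0 = seg$y0 - 3000,
               x1 = seg$x1 + 5000, y1 = seg$y1 - 3000)
  expect_equal(composition(seg2, 100, r2), c1, tolerance = 1e-12)
})

test_that("mean membership equals the enumeration mean and respects
           constant grids", {
  r <- uniform_raster(n = 20)
  set.seed(5)
  raw <- array(rexp(100 * 100 * 2), c(100, 100, 2))
  probs <- sweep(raw, c(1, 2), apply(raw, c(1, 2), sum), "/")
  surf <- membership_surface(probs, c(xmin = 0, xmax = 600, ymin = 0,
                                      ymax = 600), 2)
  grid <- modal_surface(surf)
  seg <- list(x0 = 45, y0 = 45, x1 = 405, y1 = 345)
  mm <- mean_membership(seg, 100, grid, surf, r)
  # enumeration oracle: same pixel set, same nearest-neighbor lookup
  px <- segment_pixels(seg, 100, r)
  ctr <- permscape:::pixel_centers(r)
  vals <- vapply(seq_len(nrow(px)), function(i) {
    x <- ctr$x[px[i, "col"]]; y <- ctr$y[px[i, "row"]]
    ci <- min(max(round((x - 0) / surf$px + 0.5), 1), 100)
    ri <- min(max(round((600 - y) / surf$py + 0.5), 1), 100)
    grid[ri, ci]
  }, numeric(1))
  expect_equal(as.numeric(mm), mean(vals), tolerance = 1e-12)

  cprobs <- array(0, c(100, 100, 2))
  cprobs[, , 1] <- 0.8; cprobs[, , 2] <- 0.2
  const <- membership_surface(
    cprobs, c(xmin = 0, xmax = 600, ymin = 0, ymax = 600), 2)
  cgrid <- modal_surface(const)
  for (w in c(3, 50, 400))
    expect_equal(as.numeric(mean_membership(seg, w, cgrid, const, r)), 0.8)
})

test_that("segment tables carry per-width proportions that sum to 1", {
  cfg <- scenario_config(seed = 23, k_true = 2, cell_side = 2400,
                         n_sites = 16, n_ind_per_site = 2)
  sc <- suppressWarnings(generate_scenario(cfg))
  tab <- build_segment_table(sc$partition, sc$sites, sc$raster, sc$surface,
                             widths = c(25, 100))
  props <- rowSums(tab[, land_classes()])
  expect_true(all(abs(props - 1) < 1e-6))
  expect_true(all(tab$membership >= 1 / sc$partition$k - 1e-9 &
                  tab$membership <= 1 + 1e-9))
  s2p <- sc$partition$site_to_pop
  b <- tab[tab$category == "B", ]; w <- tab[tab$category == "W", ]
  if (nrow(b)) expect_true(all(s2p[b$site_a] != s2p[b$site_b]))
  if (nrow(w)) expect_true(all(s2p[w$site_a] == s2p[w$site_b]))
})
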