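#' Construct a population partition
#'
#' Maps sample sites (and optionally individuals) to genetic clusters 1..k.
#'
#' @param k Cluster count (>= 1).
#' @param site_to_pop Named integer vector, site id -> cluster id in 1..k.
#' @param individual_to_pop Optional named integer vector, individual id ->
#'   cluster id.
#' @return An object of class `population_partition`.
#' @export
population_partition <- function(k, site_to_pop, individual_to_pop = NULL) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  site_to_pop <- as.integer(site_to_pop) |> stats::setNames(names(site_to_pop))
  if (anyNA(site_to_pop) || any(site_to_pop < 1L) || any(site_to_pop > k))
    stop("every site must map to exactly one cluster id in 1..k")
  if (is.null(names(site_to_pop)) || anyDuplicated(names(site_to_pop)))
    stop("site_to_pop must be uniquely named by site id")
  if (!is.null(individual_to_pop)) {
    individual_to_pop <- as.integer(individual_to_pop) |>
      stats::setNames(names(individual_to_pop))
    if (anyNA(individual_to_pop) || any(individual_to_pop < 1L) ||
        any(individual_to_pop > k))
      stop("every individual must map to a cluster id in 1..k")
  }
  structure(list(k = k, site_to_pop = site_to_pop,
                 individual_to_pop = individual_to_pop),
            class = "population_partition")
}

#' Partition a landscape into cluster territories
#'
#' Grows `cfg$k_true` contiguous territories from mutually distant seed pixels
#' by cost-weighted shortest-path assignment (each pixel joins the territory
#' whose seed is nearest in accumulated-cost distance). Pixels of barrier
#' classes carry an elevated traversal cost (`cfg$barrier_cost`, possibly
#' `Inf`), so territory boundaries preferentially align with barrier habitat.
#'
#' @param raster A [land_raster()].
#' @param cfg A [scenario_config()].
#' @return A list with `territory_map` (integer matrix, values 1..k_true) and
#'   `seeds` (the seed pixel (row, col) matrix).
#' @export
generate_partition <- function(raster, cfg) {
  k <- cfg$k_true
  nr <- raster$n_rows; nc <- raster$n_cols
  n <- nr * nc
  if (k == 1L)
    return(list(territory_map = matrix(1L, nr, nc), seeds = NULL))
  if (k > n) stop("k_true exceeds the number of available seed pixels")

  cost <- matrix(1, nr, nc)
  bar <- match(cfg$barrier_classes, land_classes())
  cost[raster$classes %in% bar] <- cfg$barrier_cost

  with_seed(derive_seed(cfg$seed, "partition"), {
    finite_ok <- which(is.finite(cost))
    if (length(finite_ok) < k) stop("k_true exceeds available seed spacing")
    ctr <- pixel_centers(raster)
    px <- function(idx) {       # (x, y) of linear (column-major) pixel index
      r <- (idx - 1L) %% nr + 1L; c <- (idx - 1L) %/% nr + 1L
      cbind(ctr$x[c], ctr$y[r])
    }
    # farthest-point seed spacing
    seeds <- sample(finite_ok, 1L)
    cand <- if (length(finite_ok) > 4000L)
      sample(finite_ok, 4000L) else finite_ok
    cxy <- px(cand)
    for (i in seq_len(k - 1L)) {
      sxy <- px(seeds)
      dmin <- rep(Inf, length(cand))
      for (j in seq_len(nrow(sxy)))
        dmin <- pmin(dmin, (cxy[, 1] - sxy[j, 1])^2 + (cxy[, 2] - sxy[j, 2])^2)
      seeds <- c(seeds, cand[which.max(dmin)])
    }

    # 4-neighbour lattice with edge weight = mean endpoint cost
    idx <- matrix(seq_len(n), nr, nc)
    e_v <- cbind(as.vector(idx[-nr, ]), as.vector(idx[-1L, ]))
    e_h <- cbind(as.vector(idx[, -nc]), as.vector(idx[, -1L]))
    edges <- rbind(e_v, e_h)
    w <- (cost[edges[, 1L]] + cost[edges[, 2L]]) / 2 * raster$resolution
    keep <- is.finite(w)
    g <- igraph::make_empty_graph(n, directed = FALSE)
    g <- igraph::add_edges(g, t(edges[keep, , drop = FALSE]))
    dmat <- igraph::distances(g, v = seeds, weights = w[keep],
                              algorithm = "dijkstra")
    terr <- apply(dmat, 2L, which.min)
    unreach <- !is.finite(dmat[cbind(terr, seq_len(n))])
    if (any(unreach)) {         # pixels walled off by Inf barriers
      uxy <- px(which(unreach)); sxy <- px(seeds)
      for (i in seq_along(which(unreach))) {
        d2 <- (sxy[, 1] - uxy[i, 1])^2 + (sxy[, 2] - uxy[i, 2])^2
        terr[which(unreach)[i]] <- which.min(d2)
      }
    }
    list(territory_map = matrix(as.integer(terr), nr, nc),
         seeds = cbind(row = (seeds - 1L) %% nr + 1L,
                       col = (seeds - 1L) %/% nr + 1L))
  })
}

#' Derive the site/individual partition from a territory map
#'
#' Each site inherits the true cluster of the pixel it occupies; individuals
#' (`n_ind_per_site` per site, ids `<site>_i<j>`) inherit their site's cluster.
#'
#' @param territory_map Integer matrix from [generate_partition()].
#' @param raster The matching [land_raster()].
#' @param sites Site data.frame from [place_sites()].
#' @param k Cluster count of the map.
#' @param n_ind_per_site Individuals simulated per site (0 for none).
#' @return A [population_partition()].
#' @export
partition_from_sites <- function(territory_map, raster, sites, k,
                                 n_ind_per_site = 0L) {
  rc <- raster_rowcol(raster, sites$x, sites$y)
  if (anyNA(rc)) stop("every site's pixel must lie inside the raster")
  pops <- territory_map[rc]
  site_to_pop <- stats::setNames(as.integer(pops), sites$id)
  ind <- NULL
  if (n_ind_per_site > 0L) {
    ids <- as.vector(t(outer(sites$id, seq_len(n_ind_per_site),
                             function(s, j) paste0(s, "_i", j))))
    ind <- stats::setNames(rep(site_to_pop, each = n_ind_per_site), ids)
  }
  population_partition(k, site_to_pop, ind)
}
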