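#' Place sample sites by stratified-random design
#'
#' Apportions `cfg$n_sites` across five land-cover strata at the survey's
#' target proportions — forest, grassland and water 27.8% each, urban 13.9%,
#' agriculture 2.8% — by largest-remainder rounding, then samples site pixels
#' uniformly within each stratum. Forest sites are additionally stratified by
#' forest patch size (small < 5 ha, medium 5-50 ha, large > 50 ha) over the
#' size classes present. A stratum with no available pixels forfeits its quota,
#' which is reallocated proportionally over the remaining strata (with a
#' warning), preserving the total.
#'
#' @param raster A [land_raster()].
#' @param cfg A [scenario_config()]; uses `n_sites` and `seed`.
#' @return data.frame with columns `id`, `x`, `y`, `cell_id`, `habitat_class`;
#'   coordinates are pixel centers (m). Deterministic given `cfg$seed`.
#' @export
place_sites <- function(raster, cfg) {
  n <- cfg$n_sites
  if (n > 45) stop("n_sites must not exceed 45")
  target <- c(forest = 0.278, grassland = 0.278, water = 0.278,
              urban = 0.139, agriculture = 0.028)
  codes <- match(names(target), land_classes())
  avail <- vapply(codes, function(cd) sum(raster$classes == cd), integer(1))
  names(avail) <- names(target)

  present <- avail > 0
  if (!all(present)) {
    warning("empty strata reallocated: ",
            paste(names(target)[!present], collapse = ", "))
  }
  quota <- stats::setNames(integer(length(target)), names(target))
  if (!any(present)) stop("no pixels available in any sampling stratum")
  quota[present] <- largest_remainder(n, target[present])

  # cap quotas at availability, pushing overflow to strata with room
  repeat {
    over <- quota > avail
    if (!any(over)) break
    excess <- sum(quota[over] - avail[over])
    quota[over] <- avail[over]
    room <- avail - quota
    if (sum(room) == 0) { warning("fewer pixels than sites; short by ", excess); break }
    add <- largest_remainder(min(excess, sum(room)), pmin(room, excess) / sum(room))
    quota <- quota + pmin(add, room)
  }

  with_seed(derive_seed(cfg$seed, "sites"), {
    picks <- integer(0); pick_class <- character(0)
    for (st in names(target)) {
      q <- quota[[st]]
      if (q == 0) next
      cd <- match(st, land_classes())
      if (st == "forest") {
        lab <- class_patches(raster, cd)
        sizes <- tabulate(lab)
        area_ha <- sizes * raster$resolution^2 / 1e4
        size_class <- cut(area_ha, c(0, 5, 50, Inf),
                          labels = c("small", "medium", "large"))
        pix_size <- rep(NA_character_, length(lab))
        pix_size[lab > 0] <- as.character(size_class[lab[lab > 0]])
        cls_present <- levels(size_class)[tabulate(size_class, 3L) > 0]
        sq <- largest_remainder(q, stats::setNames(rep(1, length(cls_present)),
                                                   cls_present))
        got <- integer(0)
        for (sc in names(sq)) {
          pool <- which(!is.na(pix_size) & pix_size == sc)
          take <- min(sq[[sc]], length(pool))
          if (take > 0) got <- c(got, pool[sample.int(length(pool), take)])
        }
        short <- q - length(got)
        if (short > 0) {        # top up from any forest pixel not yet chosen
          pool <- setdiff(which(lab > 0), got)
          take <- min(short, length(pool))
          if (take > 0) got <- c(got, pool[sample.int(length(pool), take)])
        }
        picks <- c(picks, got); pick_class <- c(pick_class, rep(st, length(got)))
      } else {
        pool <- which(raster$classes == cd)
        take <- min(q, length(pool))
        got <- pool[sample.int(length(pool), take)]
        picks <- c(picks, got); pick_class <- c(pick_class, rep(st, length(got)))
      }
    }
    nr <- raster$n_rows
    ctr <- pixel_centers(raster)
    r <- (picks - 1L) %% nr + 1L
    cc <- (picks - 1L) %/% nr + 1L
    ord <- order(picks)
    data.frame(id = sprintf("S%02d", seq_along(picks)),
               x = ctr$x[cc][ord], y = ctr$y[r][ord],
               cell_id = "C01",
               habitat_class = pick_class[ord],
               stringsAsFactors = FALSE)
  })
}

#' Write / read sample sites as CSV
#'
#' @param sites Site data.frame ([place_sites()] layout).
#' @param path File path.
#' @return The path (write) or the data.frame (read).
#' @export
write_sites_csv <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_csv
#' @export
read_sites_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
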