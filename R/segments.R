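#' Default segment bandwidths
#'
#' The eight rectangle widths (m) at which land-cover composition and mean
#' membership probability are extracted. The 3 m width approximates a
#' straight line between sites; 1000 m bounds the plausible movement swath of
#' a small mammal traveling along the segment edge.
#'
#' @return Numeric vector `c(3, 10, 25, 50, 100, 200, 400, 1000)`.
#' @export
width_set <- function() c(3, 10, 25, 50, 100, 200, 400, 1000)

#' Median within-population site distance
#'
#' The distance threshold of the between-segment rule: the median of all
#' pairwise Euclidean distances between sample sites of the same population.
#' Populations holding a single site contribute no distances and are excluded.
#'
#' @param partition A [population_partition()].
#' @param sites Site data.frame (`id`, `x`, `y`).
#' @param scope `"global"` (default): pool distances over all multi-site
#'   populations; `"pair"`: restrict to the populations in `pops`.
#' @param pops Integer vector of population ids (required for scope
#'   `"pair"`).
#' @return Median distance in meters.
#' @export
within_median <- function(partition, sites, scope = c("global", "pair"),
                          pops = NULL) {
  scope <- match.arg(scope)
  s2p <- partition$site_to_pop[sites$id]
  use_pops <- if (scope == "pair") {
    if (is.null(pops)) stop("scope = 'pair' requires pops")
    pops
  } else sort(unique(s2p))
  d <- numeric(0)
  for (p in use_pops) {
    rows <- which(s2p == p)
    if (length(rows) < 2) next
    d <- c(d, as.vector(stats::dist(sites[rows, c("x", "y")])))
  }
  if (!length(d))
    stop("no population holds two or more sample sites: threshold undefined")
  stats::median(d)
}

# Canonical unordered site pair: ids sorted so site_a < site_b.
canonical_pair <- function(id1, id2) {
  if (id1 <= id2) c(id1, id2) else c(id2, id1)
}

#' Find between-population (B) segments
#'
#' For every unordered population pair, the minimum-distance site pair is
#' located; if that distance is strictly below the threshold, the pair forms
#' the single B segment joining those populations (genetic clustering despite
#' proximity indicates a barrier other than distance). Ties between site
#' pairs at equal minimum distance resolve to the lexicographically lowest
#' (site_a, site_b) id pair. At most one B segment per population pair.
#'
#' @param partition A [population_partition()].
#' @param sites Site data.frame.
#' @param threshold Distance threshold in meters (from [within_median()]).
#' @return data.frame of segments (possibly 0 rows): `site_a`, `site_b`,
#'   `pop_a`, `pop_b`, `category` ("B"), `length`, `x0`, `y0`, `x1`, `y1`.
#' @export
find_b_segments <- function(partition, sites, threshold) {
  s2p <- partition$site_to_pop[sites$id]
  up <- sort(unique(s2p))
  out <- list()
  if (length(up) >= 2) {
    d <- as.matrix(stats::dist(sites[, c("x", "y")]))
    for (i in seq_len(length(up) - 1)) for (j in (i + 1):length(up)) {
      ra <- which(s2p == up[i]); rb <- which(s2p == up[j])
      sub <- d[ra, rb, drop = FALSE]
      dmin <- min(sub)
      if (dmin >= threshold) next
      hits <- which(sub == dmin, arr.ind = TRUE)
      pairs <- t(apply(hits, 1, function(h)
        canonical_pair(sites$id[ra[h[1]]], sites$id[rb[h[2]]])))
      ord <- order(pairs[, 1], pairs[, 2])
      pick <- pairs[ord[1], ]
      ia <- match(pick[1], sites$id); ib <- match(pick[2], sites$id)
      out[[length(out) + 1L]] <- data.frame(
        site_a = pick[1], site_b = pick[2],
        pop_a = s2p[ia], pop_b = s2p[ib], category = "B",
        length = dmin, x0 = sites$x[ia], y0 = sites$y[ia],
        x1 = sites$x[ib], y1 = sites$y[ib], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(site_a = character(0), site_b = character(0),
                      pop_a = integer(0), pop_b = integer(0),
                      category = character(0), length = numeric(0),
                      x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Find within-population (W) segments
#'
#' One W segment per multi-site population: the site pair whose distance most
#' closely matches the target length — the length of the joining B segment
#' for populations touched by one (the shortest such segment if several), or
#' `fallback_length` for multi-site populations joined by no B segment (the
#' study-wide mean B-segment length, default 776 m). Single-site populations
#' yield no W segment. Ties resolve lexicographically as in
#' [find_b_segments()].
#'
#' @param partition A [population_partition()].
#' @param sites Site data.frame.
#' @param b_segments Output of [find_b_segments()].
#' @param fallback_length Target length (m) for populations without a B
#'   segment.
#' @return data.frame of W segments in the [find_b_segments()] layout
#'   (`pop_a == pop_b`).
#' @export
find_w_segments <- function(partition, sites, b_segments,
                            fallback_length = 776) {
  s2p <- partition$site_to_pop[sites$id]
  up <- sort(unique(s2p))
  out <- list()
  for (p in up) {
    rows <- which(s2p == p)
    if (length(rows) < 2) next                 # single-site: no W segment
    touching <- b_segments[b_segments$pop_a == p | b_segments$pop_b == p, ]
    target <- if (nrow(touching)) min(touching$length) else fallback_length
    d <- as.matrix(stats::dist(sites[rows, c("x", "y")]))
    ut <- which(upper.tri(d), arr.ind = TRUE)
    miss <- abs(d[ut] - target)
    best <- which(miss == min(miss))
    pairs <- t(apply(ut[best, , drop = FALSE], 1, function(h)
      canonical_pair(sites$id[rows[h[1]]], sites$id[rows[h[2]]])))
    ord <- order(pairs[, 1], pairs[, 2])
    pick <- pairs[ord[1], ]
    ia <- match(pick[1], sites$id); ib <- match(pick[2], sites$id)
    out[[length(out) + 1L]] <- data.frame(
      site_a = pick[1], site_b = pick[2], pop_a = p, pop_b = p,
      category = "W",
      length = sqrt((sites$x[ia] - sites$x[ib])^2 +
                    (sites$y[ia] - sites$y[ib])^2),
      x0 = sites$x[ia], y0 = sites$y[ia],
      x1 = sites$x[ib], y1 = sites$y[ib], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(b_segments[0, ])
  do.call(rbind, out)
}

#' Raster pixels covered by a segment rectangle
#'
#' The set of raster pixels whose centers fall inside the rectangle of the
#' given width centered on the segment axis. The along-axis interval `[0, L]`
#' is closed (the rectangle runs exactly site-to-site, no end caps); the
#' perpendicular band is half-open, `[-w/2, w/2)`, so a pixel center lying
#' exactly on the upper edge is excluded — the deterministic raster-GIS
#' tie-break. If no pixel center falls inside (very thin short segments), the
#' pixels containing the two endpoints are used instead.
#'
#' @param seg One segment row (needs `x0`, `y0`, `x1`, `y1`) or a list with
#'   those fields.
#' @param width Rectangle width in meters.
#' @param raster A [land_raster()].
#' @return Integer matrix with columns `row`, `col` (one row per pixel).
#' @export
segment_pixels <- function(seg, width, raster) {
  if (width <= 0) stop("width must be positive")
  x0 <- seg$x0; y0 <- seg$y0; x1 <- seg$x1; y1 <- seg$y1
  L <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  if (L == 0) stop("segment length must be positive")
  ux <- (x1 - x0) / L; uy <- (y1 - y0) / L
  ctr <- pixel_centers(raster)
  # candidate window: bounding box of the rectangle, padded one pixel
  hw <- width / 2
  pad <- hw + raster$resolution
  xmin <- min(x0, x1) - pad; xmax <- max(x0, x1) + pad
  ymin <- min(y0, y1) - pad; ymax <- max(y0, y1) + pad
  cols <- which(ctr$x >= xmin & ctr$x <= xmax)
  rows <- which(ctr$y >= ymin & ctr$y <= ymax)
  if (length(cols) && length(rows)) {
    cx <- rep(ctr$x[cols], each = length(rows))
    cy <- rep(ctr$y[rows], times = length(cols))
    dx <- cx - x0; dy <- cy - y0
    t_ax <- dx * ux + dy * uy
    perp <- dx * (-uy) + dy * ux
    eps <- 1e-9 * max(1, L)
    inside <- t_ax >= -eps & t_ax <= L + eps &
      perp >= -hw - eps & perp < hw - eps
    if (any(inside)) {
      ri <- rep(rows, times = length(cols))[inside]
      ci <- rep(cols, each = length(rows))[inside]
      return(cbind(row = ri, col = ci))
    }
  }
  # fallback: the pixels containing the two endpoints
  rc <- raster_rowcol(raster, c(x0, x1), c(y0, y1))
  if (anyNA(rc)) {
    warning("segment endpoint outside raster extent; clipped")
    rc <- rc[!is.na(rc[, 1]), , drop = FALSE]
    if (!nrow(rc)) stop("segment entirely outside raster extent")
  }
  unique(rc)
}

#' Land-cover composition of a segment
#'
#' Proportional area of each of the nine habitat classes within the segment
#' rectangle at the given width: per-class pixel count over total pixel
#' count, all nine classes reported (zeros included), summing to 1.
#'
#' @inheritParams segment_pixels
#' @return Named numeric vector over [land_classes()].
#' @export
composition <- function(seg, width, raster) {
  px <- segment_pixels(seg, width, raster)
  cls <- raster$classes[px]
  stats::setNames(tabulate(cls, 9L) / nrow(px), land_classes())
}

# composition() for a bare coordinate list (internal fast path)
composition_xy <- composition

#' Mean membership probability over a segment
#'
#' Arithmetic mean of the modal membership probability over the segment's
#' raster pixels; each land-cover pixel center is mapped to its
#' nearest-neighbor surface pixel (clamped to the surface edge, with a flag,
#' when the segment leaves the surface bounding box).
#'
#' @inheritParams segment_pixels
#' @param modal_grid 100 x 100 matrix from [modal_surface()].
#' @param surface The [membership_surface()] the grid came from (for its
#'   bounding box).
#' @return Mean probability (scalar); attribute `clamped` counts pixels that
#'   fell outside the surface bounding box.
#' @export
mean_membership <- function(seg, width, modal_grid, surface, raster) {
  px <- segment_pixels(seg, width, raster)
  ctr <- pixel_centers(raster)
  x <- ctr$x[px[, "col"]]; y <- ctr$y[px[, "row"]]
  ci <- round((x - surface$bbox[["xmin"]]) / surface$px + 0.5)
  ri <- round((surface$bbox[["ymax"]] - y) / surface$py + 0.5)
  clamped <- sum(ci < 1 | ci > 100 | ri < 1 | ri > 100)
  ci <- pmin(pmax(ci, 1), 100); ri <- pmin(pmax(ri, 1), 100)
  out <- mean(modal_grid[cbind(ri, ci)])
  attr(out, "clamped") <- clamped
  out
}

#' Build the full segment table
#'
#' Runs the complete segment pipeline for one cell: threshold from
#' [within_median()], B segments, W segments, then per-width land-cover
#' composition and (optionally) mean modal membership probability.
#'
#' @param partition A [population_partition()].
#' @param sites Site data.frame.
#' @param raster A [land_raster()].
#' @param surface Optional [membership_surface()] (adds `membership`).
#' @param widths Bandwidths in meters (default [width_set()]).
#' @param scope Threshold scope, see [within_median()].
#' @param fallback_length Fallback W target length (m), default 776.
#' @return data.frame, one row per segment x width: segment columns, `width`,
#'   the nine composition proportions, and `membership` when a surface is
#'   given.
#' @export
build_segment_table <- function(partition, sites, raster, surface = NULL,
                                widths = width_set(), scope = "global",
                                fallback_length = 776) {
  thr <- within_median(partition, sites, scope = scope)
  b <- find_b_segments(partition, sites, thr)
  w <- find_w_segments(partition, sites, b, fallback_length)
  segs <- rbind(b, w)
  if (!nrow(segs)) stop("no segments produced")
  modal <- if (!is.null(surface)) modal_surface(surface)
  rows <- list()
  for (i in seq_len(nrow(segs))) for (wd in widths) {
    comp <- composition(segs[i, ], wd, raster)
    row <- cbind(segs[i, ], width = wd, as.data.frame(t(comp)))
    if (!is.null(surface))
      row$membership <- as.numeric(
        mean_membership(segs[i, ], wd, modal, surface, raster))
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write segments as CSV / GeoJSON
#'
#' CSV: one row per segment x width (ids, category, length, nine proportions,
#' membership when present). GeoJSON: one rectangle polygon per segment x
#' width for visual inspection.
#'
#' @param segment_table Output of [build_segment_table()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_segments_csv <- function(segment_table, path) {
  utils::write.csv(segment_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_csv
#' @export
write_segments_geojson <- function(segment_table, path) {
  feats <- lapply(seq_len(nrow(segment_table)), function(i) {
    s <- segment_table[i, ]
    L <- s$length; hw <- s$width / 2
    ux <- (s$x1 - s$x0) / L; uy <- (s$y1 - s$y0) / L
    nx <- -uy; ny <- ux
    ring <- list(c(s$x0 + nx * hw, s$y0 + ny * hw),
                 c(s$x1 + nx * hw, s$y1 + ny * hw),
                 c(s$x1 - nx * hw, s$y1 - ny * hw),
                 c(s$x0 - nx * hw, s$y0 - ny * hw),
                 c(s$x0 + nx * hw, s$y0 + ny * hw))
    list(type = "Feature",
         properties = list(site_a = s$site_a, site_b = s$site_b,
                           category = s$category, width = s$width),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
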