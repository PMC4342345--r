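#' The nine land-cover classes
#'
#' Class labels used throughout the package, in legend order (integer codes
#' 1-9). Wetland and open water are merged into the single `water` class at
#' generation, matching the analysis variable.
#'
#' @return Character vector of the nine class names.
#' @export
land_classes <- function() {
  c("forest", "non_treed_corridor", "treed_corridor", "grassland",
    "shrubland", "water", "urban", "road", "agriculture")
}

#' Construct a categorical land-cover raster
#'
#' A minimal in-memory raster: an integer matrix of class codes (1-9, legend
#' [land_classes()]) indexed row-major from the top-left, with a lower-left
#' origin in projected meters and a square pixel size.
#'
#' @param classes Integer matrix of class codes in 1..9; row 1 is the top
#'   (northernmost) row.
#' @param origin_x,origin_y Coordinates (m) of the lower-left raster corner.
#' @param resolution Pixel edge length in meters (default 30).
#' @return An object of class `land_raster`.
#' @export
land_raster <- function(classes, origin_x = 0, origin_y = 0, resolution = 30) {
  classes <- as.matrix(classes)
  storage.mode(classes) <- "integer"
  if (resolution <= 0) stop("resolution must be positive")
  if (anyNA(classes) || any(classes < 1L) || any(classes > 9L))
    stop("every pixel must carry exactly one of the 9 class codes (1-9)")
  structure(
    list(classes = classes, origin_x = origin_x, origin_y = origin_y,
         resolution = resolution, n_rows = nrow(classes),
         n_cols = ncol(classes), legend = land_classes()),
    class = "land_raster")
}

#' @export
print.land_raster <- function(x, ...) {
  cat(sprintf("land_raster: %d x %d pixels @ %g m, origin (%g, %g)\n",
              x$n_rows, x$n_cols, x$resolution, x$origin_x, x$origin_y))
  f <- class_fractions(x)
  f <- f[f > 0]
  cat("  composition:",
      paste(sprintf("%s %.1f%%", names(f), 100 * f), collapse = ", "), "\n")
  invisible(x)
}

#' Realized per-class area fractions of a raster
#'
#' @param raster A [land_raster()].
#' @return Named numeric vector over all nine classes (zeros included),
#'   summing to 1.
#' @export
class_fractions <- function(raster) {
  tab <- tabulate(raster$classes, nbins = 9L)
  stats::setNames(tab / sum(tab), land_classes())
}

# Pixel-center coordinates; rows top-to-bottom, columns left-to-right.
pixel_centers <- function(raster) {
  res <- raster$resolution
  x <- raster$origin_x + (seq_len(raster$n_cols) - 0.5) * res
  y <- raster$origin_y + (raster$n_rows - seq_len(raster$n_rows) + 0.5) * res
  list(x = x, y = y)
}

# Map coordinates to (row, col); NA outside the extent.
raster_rowcol <- function(raster, x, y) {
  res <- raster$resolution
  col <- floor((x - raster$origin_x) / res) + 1
  row <- raster$n_rows - floor((y - raster$origin_y) / res)
  bad <- col < 1 | col > raster$n_cols | row < 1 | row > raster$n_rows
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Generate a patch-mosaic land-cover raster
#'
#' Grows contiguous habitat patches by quota-constrained region growing on a
#' coarse lattice: coarse cells are apportioned to classes by largest-remainder
#' rounding of the target mix, seeded at random cells, and grown by repeatedly
#' claiming an unassigned cell adjacent to an already-assigned cell of a class
#' with remaining quota. The coarse assignment is then expanded to pixels, so
#' realized class fractions track the targets closely (exactly at coarse-cell
#' granularity) while patches stay contiguous and segment compositions vary
#' smoothly with bandwidth.
#'
#' @param cfg A [scenario_config()]; uses `class_mix`, `cell_side`,
#'   `resolution`, `lattice_step`, `patch_cells` and `seed`.
#' @return A [land_raster()]. Deterministic given `cfg$seed`.
#' @export
generate_landcover <- function(cfg) {
  mix <- cfg$class_mix
  if (abs(sum(mix) - 1) > 1e-8) stop("class_mix must sum to 1")
  if (any(mix < 0)) stop("class_mix fractions must be nonnegative")
  mix <- mix[land_classes()]
  mix[is.na(mix)] <- 0
  names(mix) <- land_classes()

  n_pix <- max(1L, round(cfg$cell_side / cfg$resolution))
  step <- max(1L, as.integer(cfg$lattice_step))
  nc <- ceiling(n_pix / step)           # coarse lattice is nc x nc
  n_cells <- nc * nc

  coarse <- with_seed(derive_seed(cfg$seed, "landcover"), {
    quota <- largest_remainder(n_cells, mix)
    assign <- integer(n_cells)          # 0 = unassigned
    remaining <- quota
    active <- which(quota > 0)
    if (length(active) == 1L) {
      assign[] <- active
    } else {
      # seed each class with ~quota/patch_cells patches
      n_seed <- pmax(1L, round(quota[active] / cfg$patch_cells))
      n_seed <- pmin(n_seed, quota[active])
      seed_class <- rep(active, n_seed)
      seed_cell <- sample.int(n_cells, length(seed_class))
      nbrs <- function(cell) {
        r <- (cell - 1L) %% nc + 1L; c <- (cell - 1L) %/% nc + 1L
        out <- c(if (r > 1L) cell - 1L, if (r < nc) cell + 1L,
                 if (c > 1L) cell - nc, if (c < nc) cell + nc)
        out
      }
      cand_cell <- integer(0); cand_class <- integer(0)
      for (i in seq_along(seed_cell)) {
        cl <- seed_class[i]; ce <- seed_cell[i]
        if (assign[ce] != 0L || remaining[cl] == 0L) next
        assign[ce] <- cl; remaining[cl] <- remaining[cl] - 1L
        nb <- nbrs(ce)
        cand_cell <- c(cand_cell, nb)
        cand_class <- c(cand_class, rep(cl, length(nb)))
      }
      n_unassigned <- sum(assign == 0L)
      while (n_unassigned > 0L) {
        if (length(cand_cell) == 0L) {
          # quotas of all adjacent classes exhausted: plant a fresh seed
          cl <- which(remaining > 0L)[1L]
          open <- which(assign == 0L)
          ce <- open[sample.int(length(open), 1L)]
          assign[ce] <- cl; remaining[cl] <- remaining[cl] - 1L
          n_unassigned <- n_unassigned - 1L
          nb <- nbrs(ce); nb <- nb[assign[nb] == 0L]
          cand_cell <- nb; cand_class <- rep(cl, length(nb))
          next
        }
        i <- if (length(cand_cell) == 1L) 1L else sample.int(length(cand_cell), 1L)
        ce <- cand_cell[i]; cl <- cand_class[i]
        cand_cell <- cand_cell[-i]; cand_class <- cand_class[-i]
        if (assign[ce] != 0L || remaining[cl] == 0L) next
        assign[ce] <- cl; remaining[cl] <- remaining[cl] - 1L
        n_unassigned <- n_unassigned - 1L
        nb <- nbrs(ce); nb <- nb[assign[nb] == 0L]
        if (length(nb)) {
          cand_cell <- c(cand_cell, nb)
          cand_class <- c(cand_class, rep(cl, length(nb)))
        }
      }
    }
    matrix(assign, nrow = nc, ncol = nc)
  })

  pixels <- coarse[rep(seq_len(nc), each = step), rep(seq_len(nc), each = step)]
  pixels <- pixels[seq_len(n_pix), seq_len(n_pix), drop = FALSE]
  land_raster(pixels, origin_x = cfg$origin_x, origin_y = cfg$origin_y,
              resolution = cfg$resolution)
}

# Connected components (4-neighbour) of pixels whose class is `code`.
# Returns an integer matrix: 0 off-class, 1..n patch labels.
class_patches <- function(raster, code) {
  m <- raster$classes == code
  nr <- nrow(m); ncl <- ncol(m)
  lab <- matrix(0L, nr, ncl)
  cur <- 0L
  idx <- which(m & lab == 0L)
  while (length(idx)) {
    cur <- cur + 1L
    stack <- idx[1L]
    lab[stack] <- cur
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
      nb <- c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
              if (cc > 1L) p - nr, if (cc < ncl) p + nr)
      nb <- nb[m[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      stack <- c(stack, nb)
    }
    idx <- which(m & lab == 0L)
  }
  lab
}

#' Write / read a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format for the integer class grid (code 1-9;
#' legend [land_classes()]).
#'
#' @param raster A [land_raster()].
#' @param path Output (input) file path.
#' @return `write_esri_ascii` returns `path` invisibly; `read_esri_ascii`
#'   returns a [land_raster()].
#' @export
write_esri_ascii <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", raster$n_cols),
    sprintf("nrows %d", raster$n_rows),
    sprintf("xllcorner %.6f", raster$origin_x),
    sprintf("yllcorner %.6f", raster$origin_y),
    sprintf("cellsize %.6f", raster$resolution),
    "NODATA_value -9999"), con)
  for (i in seq_len(raster$n_rows))
    writeLines(paste(raster$classes[i, ], collapse = " "), con)
  invisible(path)
}

#' @rdname write_esri_ascii
#' @export
read_esri_ascii <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)],
                 function(l) as.integer(strsplit(trimws(l), "\\s+")[[1L]]))
  m <- do.call(rbind, vals)
  land_raster(m, origin_x = hdr$xllcorner, origin_y = hdr$yllcorner,
              resolution = hdr$cellsize)
}
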