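#' Construct a membership-probability surface
#'
#' A 100 x 100 grid spanning the bounding box of a cell's sample sites; each
#' pixel carries a probability vector over the k genetic clusters (the
#' per-pixel posterior probability of population membership).
#'
#' @param probs Numeric array `100 x 100 x k`; rows top-to-bottom. Each
#'   pixel's vector must lie on the simplex (sum 1 within 1e-6).
#' @param bbox Named numeric: `xmin`, `xmax`, `ymin`, `ymax` (m).
#' @param k Cluster count.
#' @return Object of class `membership_surface` (fields `probs`, `bbox`, `k`,
#'   `px` / `py` pixel sizes in m).
#' @export
membership_surface <- function(probs, bbox, k) {
  probs <- array(probs, dim = c(dim(probs)[1], dim(probs)[2], k))
  if (dim(probs)[1] != 100L || dim(probs)[2] != 100L)
    stop("grid dimensions must be exactly 100 x 100")
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9))
    stop("probabilities must lie in [0, 1]")
  s <- apply(probs, c(1, 2), sum)
  if (any(abs(s - 1) > 1e-6))
    stop("per-pixel probabilities must sum to 1 (tolerance 1e-6)")
  structure(list(probs = probs, bbox = bbox, k = as.integer(k),
                 px = (bbox[["xmax"]] - bbox[["xmin"]]) / 100,
                 py = (bbox[["ymax"]] - bbox[["ymin"]]) / 100),
            class = "membership_surface")
}

# Surface pixel-center coordinates (x by column, y by row, row 1 = top).
surface_centers <- function(surface) {
  list(x = surface$bbox[["xmin"]] + (seq_len(100) - 0.5) * surface$px,
       y = surface$bbox[["ymax"]] - (seq_len(100) - 0.5) * surface$py)
}

#' Per-individual assignment posteriors from allele frequencies
#'
#' A deterministic stand-in for MCMC-based individual assignment: population
#' allele frequencies are estimated with an additive pseudo-count per allele,
#' and each individual's posterior over the k clusters is proportional to a
#' uniform prior times the product over loci of its genotype likelihood under
#' each population's frequencies. Frequencies for the focal individual's own
#' population are computed leave-one-out (its alleles removed) so that
#' self-assignment is not inflated.
#'
#' @param G A [genotype_matrix()].
#' @param partition A [population_partition()] with `individual_to_pop`.
#' @param pseudo Additive pseudo-count per allele (> 0, default 1).
#' @return Matrix `n x k` of posterior probabilities (rows sum to 1), row
#'   names = individual ids, with attribute `flagged` naming individuals with
#'   all loci missing (assigned the uniform vector 1/k).
#' @export
assign_posteriors <- function(G, partition, pseudo = 1) {
  if (pseudo <= 0) stop("pseudo must be > 0")
  pops <- partition$individual_to_pop[G$individuals$id]
  if (anyNA(pops)) stop("partition must cover all individuals")
  k <- partition$k
  n <- nrow(G$calls)
  L <- length(G$loci)
  ap <- allele_pair(G)
  post <- matrix(NA_real_, n, k, dimnames = list(G$individuals$id, NULL))
  # per-locus allele count tables per population
  for (l in seq_len(L)) {
    alleles <- sort(unique(c(ap$a1[, l], ap$a2[, l])))
    alleles <- alleles[!is.na(alleles)]
    if (!length(alleles)) next
    A <- length(alleles)
    cnt <- matrix(0, k, A)
    for (p in seq_len(k)) {
      rows <- which(pops == p)
      aa <- c(ap$a1[rows, l], ap$a2[rows, l])
      cnt[p, ] <- tabulate(match(aa[!is.na(aa)], alleles), A)
    }
    i1 <- match(ap$a1[, l], alleles); i2 <- match(ap$a2[, l], alleles)
    for (i in seq_len(n)) {
      if (is.na(i1[i])) next
      ll <- numeric(k)
      for (p in seq_len(k)) {
        cp <- cnt[p, ]
        if (p == pops[i]) {                    # leave-one-out
          cp[i1[i]] <- cp[i1[i]] - 1
          cp[i2[i]] <- cp[i2[i]] - 1
        }
        fr <- (cp + pseudo) / (sum(cp) + pseudo * A)
        ll[p] <- log(fr[i1[i]]) + log(fr[i2[i]]) +
          if (i1[i] != i2[i]) log(2) else 0
      }
      post[i, ] <- if (anyNA(post[i, ])) ll else post[i, ] + ll
    }
  }
  flagged <- rownames(post)[is.na(post[, 1])]
  out <- t(apply(post, 1, function(v) {
    if (anyNA(v)) return(rep(1 / k, k))
    e <- exp(v - max(v)); e / sum(e)
  }))
  if (k == 1L) out <- matrix(1, n, 1, dimnames = list(G$individuals$id, NULL))
  attr(out, "flagged") <- flagged
  out
}

#' Interpolate individual posteriors to a membership surface
#'
#' Inverse-distance-weighted (power 2) smoothing of per-individual posterior
#' vectors onto the 100 x 100 grid bound by the outer sample points, with
#' per-pixel renormalization. A pixel coincident with an individual takes that
#' individual's vector (the IDW limit).
#'
#' @param assignments `n x k` posterior matrix (rows sum to 1), row names =
#'   individual ids.
#' @param coords data.frame with `x`, `y` for each row of `assignments`.
#' @param k Cluster count.
#' @return A [membership_surface()].
#' @export
build_surface <- function(assignments, coords, k) {
  n <- nrow(assignments)
  if (n < 1) stop("need at least one individual with coordinates")
  xr <- range(coords$x); yr <- range(coords$y)
  if (diff(xr) == 0) xr <- xr + c(-0.5, 0.5)   # all points on a vertical line
  if (diff(yr) == 0) yr <- yr + c(-0.5, 0.5)
  bbox <- c(xmin = xr[1], xmax = xr[2], ymin = yr[1], ymax = yr[2])
  cx <- bbox[["xmin"]] + (seq_len(100) - 0.5) * (diff(xr) / 100)
  cy <- bbox[["ymax"]] - (seq_len(100) - 0.5) * (diff(yr) / 100)
  probs <- array(0, c(100, 100, k))
  A <- as.matrix(assignments)
  for (i in seq_len(100)) {                    # rows (y)
    dy2 <- (coords$y - cy[i])^2
    for (j in seq_len(100)) {
      d2 <- (coords$x - cx[j])^2 + dy2
      hit <- d2 < 1e-12
      v <- if (any(hit)) colMeans(A[hit, , drop = FALSE])
      else {
        w <- 1 / d2
        colSums(A * w) / sum(w)
      }
      probs[i, j, ] <- v / sum(v)
    }
  }
  membership_surface(probs, bbox, k)
}

#' Modal-probability grid of a surface
#'
#' Per-pixel maximum over the k cluster probabilities — the single-valued
#' reduction consumed by segment averaging. Values lie in [1/k, 1] and the
#' reduction commutes with cluster relabeling.
#'
#' @param surface A [membership_surface()].
#' @return 100 x 100 numeric matrix.
#' @export
modal_surface <- function(surface) {
  apply(surface$probs, c(1, 2), max)
}

#' Simulate a ground-truth membership surface
#'
#' Builds the 100 x 100 surface over the site bounding box from the true
#' territory map: base probabilities are a softmax of negative cost-free
#' distance to each territory (scale `cfg$surface_scale`), then the logit of
#' the modal probability is shifted by the habitat-effect term
#' \eqn{\sum_h \beta_h \cdot comp_h} (local land-cover composition within
#' `cfg$surface_window` of the pixel) plus Gaussian noise (`cfg$noise_sd`),
#' and the vector is renormalized.
#'
#' @param territory_map Integer matrix from [generate_partition()].
#' @param raster The matching [land_raster()].
#' @param sites Site data.frame (defines the bounding box).
#' @param cfg A [scenario_config()].
#' @return A [membership_surface()] with `k = cfg$k_true`.
#' @export
simulate_surface <- function(territory_map, raster, sites, cfg) {
  k <- cfg$k_true
  xr <- range(sites$x); yr <- range(sites$y)
  if (diff(xr) == 0) xr <- xr + c(-0.5, 0.5)
  if (diff(yr) == 0) yr <- yr + c(-0.5, 0.5)
  bbox <- c(xmin = xr[1], xmax = xr[2], ymin = yr[1], ymax = yr[2])
  if (k == 1L)
    return(membership_surface(array(1, c(100, 100, 1)), bbox, 1L))

  cx <- bbox[["xmin"]] + (seq_len(100) - 0.5) * (diff(xr) / 100)
  cy <- bbox[["ymax"]] - (seq_len(100) - 0.5) * (diff(yr) / 100)
  ctr <- pixel_centers(raster)
  nr <- raster$n_rows

  with_seed(derive_seed(cfg$seed, "surface"), {
    # subsample each territory's pixels for the distance computation
    terr_pts <- lapply(seq_len(k), function(t) {
      idx <- which(territory_map == t)
      if (length(idx) > 400L) idx <- idx[sample.int(length(idx), 400L)]
      cbind(ctr$x[(idx - 1L) %/% nr + 1L], ctr$y[(idx - 1L) %% nr + 1L])
    })
    X <- matrix(rep(cx, each = 100), 100, 100)   # X[i, j] = cx[j]
    Y <- matrix(rep(cy, times = 100), 100, 100)  # Y[i, j] = cy[i]
    D <- array(0, c(100, 100, k))
    for (t in seq_len(k)) {
      pts <- terr_pts[[t]]
      dmin <- matrix(Inf, 100, 100)
      for (m in seq_len(nrow(pts)))
        dmin <- pmin(dmin, (X - pts[m, 1])^2 + (Y - pts[m, 2])^2)
      D[, , t] <- sqrt(dmin)
    }
    E <- exp(-D / cfg$surface_scale)
    S <- apply(E, c(1, 2), sum)
    probs <- sweep(E, c(1, 2), S, "/")

    # habitat-effect shift on the modal probability's logit
    eff <- cfg$effect_coefficients
    rad <- cfg$surface_window
    comp_shift <- matrix(0, 100, 100)
    if (any(eff != 0) || cfg$noise_sd > 0) {
      rpix <- max(0L, floor(rad / raster$resolution))
      for (i in seq_len(100)) for (j in seq_len(100)) {
        rc <- raster_rowcol(raster, X[i, j], Y[i, j])
        if (is.na(rc[1])) next
        r0 <- max(1L, rc[1] - rpix); r1 <- min(raster$n_rows, rc[1] + rpix)
        c0 <- max(1L, rc[2] - rpix); c1 <- min(raster$n_cols, rc[2] + rpix)
        win <- raster$classes[r0:r1, c0:c1]
        comp <- tabulate(win, 9L) / length(win)
        comp_shift[i, j] <- sum(eff * comp)
      }
      noise <- matrix(stats::rnorm(1e4, 0, cfg$noise_sd), 100, 100)
      modal_idx <- apply(probs, c(1, 2), which.max)
      for (i in seq_len(100)) for (j in seq_len(100)) {
        v <- probs[i, j, ]
        m <- modal_idx[i, j]
        pm <- min(max(v[m], 1e-12), 1 - 1e-12)
        lg <- log(pm / (1 - pm)) + comp_shift[i, j] + noise[i, j]
        pm2 <- 1 / (1 + exp(-lg))
        if (1 - pm > 0) v[-m] <- v[-m] * (1 - pm2) / (1 - pm)
        v[m] <- pm2
        probs[i, j, ] <- v / sum(v)
      }
    }
    membership_surface(probs, bbox, k)
  })
}

#' Serialize / read a membership surface
#'
#' One plain-text band per cluster (decimal probabilities, whitespace
#' separated, 100 rows top-to-bottom) plus a JSON sidecar recording `k` and
#' the bounding box. The reader accepts
#' any set of per-cluster probability bands laid out this way, so externally
#' produced surfaces can be slotted in.
#'
#' @param surface A [membership_surface()].
#' @param stem Path stem; writes `<stem>_band<i>.txt` and `<stem>.json`.
#' @return The stem (write) or a [membership_surface()] (read).
#' @export
write_surface <- function(surface, stem) {
  for (b in seq_len(surface$k)) {
    m <- surface$probs[, , b]
    con <- file(sprintf("%s_band%d.txt", stem, b), "w")
    for (i in seq_len(nrow(m)))
      writeLines(paste(format(m[i, ], digits = 10), collapse = " "), con)
    close(con)
  }
  jsonlite::write_json(list(k = surface$k, bbox = as.list(surface$bbox)),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_surface
#' @export
read_surface <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  k <- meta$k
  probs <- array(0, c(100, 100, k))
  for (b in seq_len(k)) {
    lines <- readLines(sprintf("%s_band%d.txt", stem, b))
    probs[, , b] <- do.call(rbind, lapply(lines, function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  }
  membership_surface(probs, unlist(meta$bbox), k)
}
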