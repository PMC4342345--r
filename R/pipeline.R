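#' Run configuration for the end-to-end pipeline
#'
#' @param scenario A [scenario_config()] describing the synthetic inputs (or
#'   NULL when `raster`/`sites`/`genotypes` paths are given).
#' @param out_dir Output directory (created if absent).
#' @param widths Bandwidths (m), default [width_set()].
#' @param bootstrap_B,retain_threshold Bootstrap size and retention rule
#'   (defaults 1000 / 900).
#' @param validation_fraction,validation_reps Validation subsample fraction
#'   and reps (defaults 0.2 / 1000).
#' @param median_scope `"global"` or `"pair"` threshold scope.
#' @param fallback_w_length Fallback W-segment target length (m), default 776.
#' @param n_cells Number of independent study cells to generate and pool
#'   segments over (the regression models pool segments across cells, as a
#'   single cell yields only a handful).
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(scenario = scenario_config(), out_dir = tempfile("run"),
                       widths = width_set(), bootstrap_B = 1000,
                       retain_threshold = 900, validation_fraction = 0.2,
                       validation_reps = 1000, median_scope = "global",
                       fallback_w_length = 776, n_cells = 8L, seed = 1L) {
  if (retain_threshold > bootstrap_B)
    stop("retain_threshold must be <= bootstrap_B")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must lie in (0, 1)")
  structure(list(scenario = scenario, out_dir = out_dir, widths = widths,
                 bootstrap_B = bootstrap_B,
                 retain_threshold = retain_threshold,
                 validation_fraction = validation_fraction,
                 validation_reps = validation_reps,
                 median_scope = median_scope,
                 fallback_w_length = fallback_w_length,
                 n_cells = as.integer(n_cells),
                 seed = as.integer(seed)), class = "run_config")
}

#' Run the full pipeline
#'
#' Generates `cfg$n_cells` synthetic study cells, pools their segment tables
#' (segments are the analysis units and are pooled across cells), computes
#' population-genetic summaries, fits the bootstrap-wrapped stepwise
#' regressions at every width for both response frameworks, and runs
#' predictive validation — writing segments, per-width model summaries, a
#' validation report and a run manifest to `cfg$out_dir`. All stage outputs
#' are pure functions of (inputs, config, seed).
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory results (`scenario`,
#'   `segments`, `boots`, `validations`, `fst`, `mantel`, paths).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  # generate the study cells and pool their segment tables
  cells <- vector("list", cfg$n_cells)
  seg_list <- vector("list", cfg$n_cells)
  for (ci in seq_len(cfg$n_cells)) {
    ccfg <- cfg$scenario
    ccfg$seed <- derive_seed(cfg$scenario$seed, paste0("cell", ci))
    sc <- generate_scenario(ccfg)
    cells[[ci]] <- sc
    st <- tryCatch(
      build_segment_table(sc$partition, sc$sites, sc$raster, sc$surface,
                          widths = cfg$widths, scope = cfg$median_scope,
                          fallback_length = cfg$fallback_w_length),
      error = function(e) NULL)
    if (!is.null(st)) {
      st$cell_id <- sprintf("C%02d", ci)
      seg_list[[ci]] <- st
    }
  }
  segs <- do.call(rbind, seg_list)
  if (is.null(segs) || !nrow(segs)) stop("no segments produced in any cell")
  write_segments_csv(segs, file.path(cfg$out_dir, "segments.csv"))

  # popgen summaries on the first cell's true partition
  sc <- cells[[1L]]
  fst <- tryCatch(
    pairwise_fst(sc$genotypes, sc$partition, n_perm = 200,
                 seed = derive_seed(cfg$seed, "fst")),
    error = function(e) NULL)
  mant <- NULL
  if (!is.null(fst) && sc$partition$k >= 3) {
    cent <- pop_centroids(sc$sites, sc$partition)
    mant <- tryCatch(
      mantel_ibd(fst, cent, n_perm = 999,
                 seed = derive_seed(cfg$seed, "mantel")),
      error = function(e) NULL)
  }

  boots <- list(); vals <- list()
  for (w in cfg$widths) {
    for (resp in c("segment_category", "transformed_probability")) {
      has_both <- length(unique(segs$category[segs$width == w])) == 2
      if (resp == "segment_category" && !has_both) next
      key <- sprintf("%s_%gm", if (resp == "segment_category") "logistic"
                     else "linear", w)
      bt <- tryCatch(
        bootstrap_models(segs, w, resp, B = cfg$bootstrap_B,
                         retain = cfg$retain_threshold,
                         seed = derive_seed(cfg$seed, key)),
        error = function(e) NULL)
      if (is.null(bt)) next
      boots[[key]] <- bt
      write_bootstrap_csv(bt, file.path(cfg$out_dir, paste0(key, ".csv")))
      vals[[key]] <- validate(bt, fraction = cfg$validation_fraction,
                              reps = cfg$validation_reps,
                              seed = derive_seed(cfg$seed, paste0("val_", key)))
    }
  }
  if (length(vals)) {
    vr <- do.call(rbind, lapply(names(vals), function(k) {
      v <- vals[[k]]
      data.frame(model = k, kind = v$kind, width = v$width,
                 proportion = v$proportion, ci_lo = v$ci_lo,
                 ci_hi = v$ci_hi, n_validated = v$n_validated)
    }))
    utils::write.csv(vr, file.path(cfg$out_dir, "validation.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    seed = cfg$seed, scenario_seed = cfg$scenario$seed,
    widths = cfg$widths, bootstrap_B = cfg$bootstrap_B,
    retain_threshold = cfg$retain_threshold,
    validation_fraction = cfg$validation_fraction,
    validation_reps = cfg$validation_reps,
    median_scope = cfg$median_scope,
    fallback_w_length = cfg$fallback_w_length,
    n_segments = length(unique(paste(segs$site_a, segs$site_b))),
    n_b = sum(segs$category == "B" & segs$width == cfg$widths[1]),
    n_w = sum(segs$category == "W" & segs$width == cfg$widths[1]),
    segment_hash = content_hash(segs))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(cells = cells, segments = segs, boots = boots,
                 validations = vals, fst = fst, mantel = mant,
                 out_dir = cfg$out_dir))
}

# Population centroids from site coordinates. Internal.
pop_centroids <- function(sites, partition) {
  s2p <- partition$site_to_pop[sites$id]
  agg <- stats::aggregate(sites[, c("x", "y")], list(pop = s2p), mean)
  agg[order(agg$pop), c("x", "y")]
}

# Order-insensitive numeric content hash for manifests (not cryptographic).
content_hash <- function(df) {
  v <- unlist(lapply(df, function(col)
    if (is.numeric(col)) round(col, 6) else as.character(col)))
  s <- paste(v, collapse = "|")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}
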