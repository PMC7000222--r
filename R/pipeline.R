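#' Pipeline configuration
#'
#' Bundles inputs and stage toggles for [run_pipeline()].  Channels come
#' either from TIFF paths (`donor_path`/`fret_path`/`acceptor_path`) or from
#' an in-memory [fret_frameset()] / synthetic [scene_config()].
#'
#' @param frames a [fret_frameset()], or NULL to read/simulate.
#' @param scene a [scene_config()] to simulate from (used when `frames` and
#'   paths are absent).
#' @param donor_path,fret_path,acceptor_path TIFF inputs.
#' @param alpha_D,alpha_A bleed-through slopes used for the FRET index.
#' @param threshold,min_area_px,erosion_radius_px segmentation parameters.
#' @param median_filter apply the 2 x 2 median filter to the FRET index.
#' @param analyses character subset of `c("quadrant", "psd", "sector",
#'   "morpho", "motility")`.
#' @param seed seed recorded and used for any stochastic stage.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(frames = NULL, scene = NULL,
                            donor_path = NULL, fret_path = NULL, acceptor_path = NULL,
                            alpha_D = 0.55, alpha_A = 0.028,
                            threshold = "otsu", min_area_px = 50,
                            erosion_radius_px = 0, median_filter = FALSE,
                            analyses = c("quadrant", "psd", "sector", "morpho", "motility"),
                            seed = 1L) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  paths <- list(donor = donor_path, fret = fret_path, acceptor = acceptor_path)
  have_paths <- !vapply(paths, is.null, logical(1))
  if (is.null(frames) && is.null(scene)) {
    if (!all(have_paths))
      stop(sprintf("config error: missing channel stack(s): %s",
                   paste(names(paths)[!have_paths], collapse = ", ")))
    missing <- unlist(paths)[!file.exists(unlist(paths))]
    if (length(missing))
      stop("config error: file(s) not found: ", paste(missing, collapse = ", "))
  }
  structure(list(frames = frames, scene = scene, paths = paths,
                 alpha_D = alpha_D, alpha_A = alpha_A,
                 threshold = threshold, min_area_px = min_area_px,
                 erosion_radius_px = erosion_radius_px,
                 median_filter = median_filter,
                 analyses = analyses, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full imaging pipeline
#'
#' Stages, in order: acquire channels (read/simulate), segment the acceptor
#' channel, compute the FRET index, then the requested analyses — quadrant
#' traces with HFQ/LFQ summary, dominant pulse periods per quadrant, sector
#' kymograph, morphodynamics, and the boundary-motility/near-membrane-signal
#' correlation.  Deterministic given inputs and seed.  When `out_dir` is
#' given, per-stage CSVs and a JSON summary (with package version, config
#' hash and seed) are written.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with the stage results and the `summary` list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  frames <- config$frames
  truth <- NULL
  if (is.null(frames)) {
    if (!is.null(config$scene)) {
      sc <- config$scene
      if (is.null(sc$seed)) sc$seed <- config$seed
      scn <- generate_scene(sc)
      frames <- scn$frames
      truth <- scn$truth
    } else {
      d <- read_stack(config$paths$donor)
      frames <- fret_frameset(
        d, read_stack(config$paths$fret), read_stack(config$paths$acceptor),
        pixel_size_um = attr(d, "pixel_size_um"),
        frame_interval_min = attr(d, "frame_interval_min"))
    }
  }
  mask <- build_mask(frames$acceptor, threshold = config$threshold,
                     min_area_px = config$min_area_px,
                     erosion_radius_px = config$erosion_radius_px,
                     pixel_size_um = frames$pixel_size_um)
  mask$frame_interval_min <- frames$frame_interval_min
  coeffs <- bleedthrough_coefficients(config$alpha_D, config$alpha_A)
  fret_t <- compute_fret_index(frames, coeffs, median_filter = config$median_filter)
  out <- list(frames = frames, truth = truth, mask = mask, fret_index = fret_t)
  summary <- list(package_version = as.character(utils::packageVersion("fretscope")),
                  seed = config$seed,
                  config_hash = config_hash(config),
                  n_frames = dim(fret_t)[3],
                  alpha_D = config$alpha_D, alpha_A = config$alpha_A)
  if ("quadrant" %in% config$analyses || "psd" %in% config$analyses) {
    quads <- quadrant_labels(mask)
    traces <- quadrant_mean_traces(fret_t, quads, frames$frame_interval_min)
    out$quadrant_traces <- traces
    cs <- compartment_summary(traces)
    out$compartment_summary <- cs
    summary$max_fret_hfq <- cs$max_fret_hfq
    summary$hfq_id <- cs$hfq_id
    summary$lfq_at_same_time <- cs$lfq_at_same_time
    if ("psd" %in% config$analyses) {
      pd <- dominant_period_cell(traces)
      out$dominant_period <- pd
      summary$dominant_period_min <- pd$mean_period_min
      summary$dominant_period_per_quadrant <- pd$period_per_quadrant_min
    }
  }
  if ("sector" %in% config$analyses) {
    out$kymograph <- sector_kymograph(fret_t, mask)
    summary$kymograph_arc_length_px <- out$kymograph$arc_length_px
  }
  if ("morpho" %in% config$analyses) {
    mo <- fractional_changes(mask)
    out$morpho <- mo
    summary$mean_fractional_area_change <- mo$mean_fractional_area_change
    summary$mean_fractional_perimeter_change <- mo$mean_fractional_perimeter_change
  }
  if ("motility" %in% config$analyses && dim(fret_t)[3] >= 2) {
    vmap <- boundary_velocity_map(mask, frames$pixel_size_um, frames$frame_interval_min)
    sig <- near_membrane_signal(fret_t, mask)
    out$motility_map <- vmap
    out$near_membrane_signal <- sig
    corr <- tryCatch(motility_fret_correlation(vmap, sig), error = function(e) NULL)
    out$motility_correlation <- corr
    if (!is.null(corr)) {
      summary$motility_fit_r2 <- corr$fit_r2
      summary$motility_spearman_rho <- corr$spearman_rho
      summary$motility_cubic_coefficients <- as.list(corr$cubic_coefficients)
    }
  }
  out$summary <- summary
  if (!is.null(out_dir)) write_pipeline_outputs(out, config, out_dir)
  out
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  cfg <- config
  cfg$frames <- if (is.null(config$frames)) NULL else "in-memory frameset"
  yaml::write_yaml(lapply(cfg, function(x) if (is.function(x)) "fn" else x), tf)
  unname(tools::md5sum(tf))
}

write_pipeline_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    attr(df, "provenance") <- out$summary[c("package_version", "config_hash", "seed")]
    df
  }
  hdr <- sprintf("# fretscope %s | config %s | seed %d",
                 out$summary$package_version, out$summary$config_hash, out$summary$seed)
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    writeLines(hdr, p)
    suppressWarnings(write.table(df, p, append = TRUE, sep = ",",
                                 row.names = FALSE, qmethod = "double"))
  }
  if (!is.null(out$quadrant_traces)) {
    tr <- out$quadrant_traces
    wcsv(data.frame(time_min = tr$time_min, t(tr$mean_intensity)), "quadrant_traces.csv")
  }
  if (!is.null(out$morpho))
    wcsv(data.frame(frame = seq_along(out$morpho$areas_px2),
                    area_px2 = out$morpho$areas_px2,
                    perimeter_px = out$morpho$perimeters_px), "morphodynamics.csv")
  if (!is.null(out$kymograph))
    wcsv(data.frame(distance_px = out$kymograph$distance_bins_px,
                    out$kymograph$mean_intensity), "sector_kymograph.csv")
  if (!is.null(out$motility_correlation))
    wcsv(out$motility_correlation$bins, "motility_bins.csv")
  jsonlite::write_json(out$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
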