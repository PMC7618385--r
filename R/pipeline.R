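# End-to-end pipeline runners: preprocess -> segment -> extract -> detect ->
# group -> quantify -> correlate, for each of the three scene kinds, plus
# the configuration object and the table writers. Every tunable named in
# the module documentation is a config field with its default; unknown keys
# are rejected so typos cannot silently fall back to defaults.

pipeline_defaults <- function() {
  list(
    scene_kind = "ihc",
    movie_path = NULL,          # TIFF + JSON sidecar, or NULL when `scene`
    scene = NULL,               # a scene_config to simulate instead
    masks_path = NULL,          # optional external ROI label TIFF
    out_dir = NULL,
    seed = 1L,
    # preprocessing
    preprocess = TRUE,
    focus_rel_threshold = 0.35,
    focus_window = 101L,
    denoise_fwhm_px = 2,
    denoise_fwhm_t = 0,
    drift_correction = TRUE,
    # dF/F0
    baseline_window_s = 30,
    baseline_percentile = 8,
    # segmentation
    erosion_px = 1L,
    wave_threshold = NULL,
    wave_min_area_um2 = 150,
    tophat_radius_px = 15L,
    assign_margin_um = 2,
    sector_radius_fraction = 1 / 3,
    pillar_positive = TRUE,
    # detection / grouping
    min_amp_sd = 2,
    min_fwhm_s = 0.2,
    prominence_sd = 1.5,
    detrend_window_s = 20,
    min_separation_s = 2,
    ihc_window_s = 2,
    sgn_window_s = 1,
    max_gap_cells = 4L,
    # frequency / correlation gates
    min_duration_s = 300,
    corr_bin_um = 10)
}

#' Pipeline configuration
#'
#' Builds a validated configuration holding every tunable of the analysis
#' chain. Unknown keys are rejected; the object round-trips losslessly
#' through JSON (see [write_pipeline_config()]).
#'
#' @param ... named overrides of the defaults (see
#'   `cochleaCa:::pipeline_defaults()`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown pipeline_config keys: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  if (!cfg$scene_kind %in% c("ihc", "supporting", "sgn")) {
    stop("scene_kind must be ihc, supporting or sgn")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Serialize / restore a pipeline configuration
#'
#' @param config a [pipeline_config()].
#' @param path JSON path.
#' @export
write_pipeline_config <- function(config, path) {
  plain <- unclass(config)
  plain$scene <- if (!is.null(config$scene)) {
    s <- unclass(config$scene)
    s$ihc_polyline <- unname(s$ihc_polyline)   # matrix -> array of rows
    s
  }
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  plain <- jsonlite::read_json(path, simplifyVector = TRUE)
  scene <- NULL
  if (!is.null(plain$scene)) {
    s <- plain$scene
    poly <- as.matrix(s$ihc_polyline)
    colnames(poly) <- c("x", "y")
    args <- s[setdiff(names(s), "ihc_polyline")]
    args <- args[!vapply(args, is.null, logical(1))]
    args$ihc_polyline <- poly
    scene <- do.call(scene_config, args)
  }
  plain$scene <- NULL
  cfg <- do.call(pipeline_config, plain)
  cfg$scene <- scene
  cfg
}

# Tiny stable polynomial hash of a config for the run log.
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> segment -> extract -> detect -> group ->
#' quantify -> statistics for the configured scene kind, either on a movie
#' loaded from disk or on a freshly simulated scene. Stage failures
#' propagate with the stage name. When `config$out_dir` is set, all result
#' tables and a machine-readable run log (R version, package version,
#' seed, config hash) are written there.
#'
#' @param config a [pipeline_config()].
#' @return a result bundle (list); components depend on the scene kind.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  truth <- NULL
  rois_in <- NULL
  if (!is.null(config$scene)) {
    scene <- stage("simulate", {
      switch(config$scene_kind,
             ihc = generate_ihc_scene(config$scene),
             supporting = generate_supporting_scene(config$scene),
             sgn = generate_sgn_scene(config$scene))
    })
    movie <- scene$movie
    truth <- scene$truth
    rois_in <- scene$rois
    polyline <- ihc_polyline(config$scene$ihc_polyline)
  } else {
    movie <- stage("read_movie", read_movie(config$movie_path))
    polyline <- NULL
  }
  pp <- NULL
  if (isTRUE(config$preprocess)) {
    pp <- stage("preprocess", preprocess_movie(
      movie, rel_threshold = config$focus_rel_threshold,
      window = config$focus_window,
      denoise_fwhm_px = config$denoise_fwhm_px,
      denoise_fwhm_t = config$denoise_fwhm_t,
      drift = config$drift_correction))
    movie <- pp$movie
  }
  result <- switch(
    config$scene_kind,
    ihc = run_ihc_stages(movie, config, rois_in, polyline, stage),
    supporting = run_wave_stages(movie, config, polyline, stage),
    sgn = run_sgn_stages(movie, config, rois_in, polyline, stage))
  result$preprocessing <- list(
    flagged = if (is.null(pp)) integer() else pp$flagged,
    shifts = if (is.null(pp)) NULL else pp$shifts)
  result$truth <- truth
  result$config <- config
  if (!is.null(config$out_dir)) write_tables(result, config$out_dir)
  result
}

run_ihc_stages <- function(movie, config, rois_in, polyline, stage) {
  rois <- stage("segment", {
    avg <- apply(movie$data, c(1, 2), mean)
    masks <- if (!is.null(rois_in)) rois_in$label_image else
      if (!is.null(config$masks_path)) {
        m <- tiff::readTIFF(config$masks_path)
        matrix(as.integer(round(m * 65535)), nrow(m))
      } else NULL
    segment_ihc(avg, erosion_px = config$erosion_px,
                px_size = movie$px_size, masks = masks)
  })
  traces <- stage("extract", {
    tr <- extract_traces(movie, rois)
    lapply(tr, compute_dff, baseline_window_s = config$baseline_window_s,
           baseline_percentile = config$baseline_percentile)
  })
  peaks <- stage("detect", do.call(rbind, lapply(traces, detect_peaks,
    min_amp_sd = config$min_amp_sd, min_fwhm_s = config$min_fwhm_s,
    prominence_sd = config$prominence_sd,
    detrend_window_s = config$detrend_window_s,
    min_separation_s = config$min_separation_s)))
  cell_order <- stage("order_cells", {
    s_along <- vapply(seq_len(nrow(rois$centroids)), function(i) {
      polyline_nearest(polyline, c(rois$centroids$x_um[i],
                                   rois$centroids$y_um[i]))$s
    }, numeric(1))
    stats::setNames(rank(s_along, ties.method = "first"),
                    rois$centroids$label)
  })
  grouped <- stage("group", group_ihc_events(
    peaks, cell_order, window_s = config$ihc_window_s,
    max_gap_cells = config$max_gap_cells))
  duration <- movie_duration_s(movie)
  freq <- stage("quantify", {
    per_cell <- vapply(roi_labels(rois), function(l) {
      compute_frequency(sum(peaks$roi_label == l), duration,
                        config$min_duration_s)
    }, numeric(1))
    data.frame(roi_label = roi_labels(rois),
               peaks = vapply(roi_labels(rois), function(l)
                 sum(peaks$roi_label == l), numeric(1)),
               frequency_per_min = per_cell)
  })
  corr <- stage("stats", {
    if (length(traces) >= 2L && duration >= config$min_duration_s) {
      cm <- pairwise_correlations(traces,
                                  detrend_window_s = config$detrend_window_s,
                                  min_overlap_s = config$min_duration_s)
      cvd <- tryCatch(
        correlation_vs_distance(cm, rois$centroids,
                                bin_um = config$corr_bin_um),
        error = function(e) NULL)
      list(matrix = cm, vs_distance = cvd)
    } else NULL
  })
  list(kind = "ihc", rois = rois, traces = traces, peaks = grouped$peaks,
       events = grouped$events,
       classification = event_classification_summary(grouped$events),
       frequencies = freq, correlations = corr)
}

run_wave_stages <- function(movie, config, polyline, stage) {
  dffm <- stage("normalize", movie_dff(movie))
  rois <- stage("segment", segment_waves(
    dffm, threshold = config$wave_threshold,
    min_area_um2 = config$wave_min_area_um2))
  binned <- stage("bin", bin_movie(dffm, 2L))
  records <- stage("quantify", summarize_waves(
    rois, binned, polyline, movie$frame_rate))
  duration <- movie_duration_s(movie)
  list(kind = "supporting", rois = rois, waves = records,
       wave_frequency_per_min = wave_frequency(records, duration))
}

run_sgn_stages <- function(movie, config, rois_in, polyline, stage) {
  seg <- stage("segment", {
    if (!is.null(rois_in)) {
      rois_in
    } else {
      avg <- apply(movie$data, c(1, 2), mean)
      list(terminals = segment_sgn_terminals(
        avg, tophat_radius_px = config$tophat_radius_px,
        px_size = movie$px_size), ihcs = NULL)
    }
  })
  traces <- stage("extract", {
    tr <- extract_traces(movie, seg$terminals)
    lapply(tr, compute_dff, baseline_window_s = config$baseline_window_s,
           baseline_percentile = config$baseline_percentile)
  })
  assignment <- stage("assign", {
    prox <- assign_terminals(seg$terminals, seg$ihcs, traces = NULL,
                             margin_um = -1)   # pure proximity first pass
    ihc_traces <- lapply(split(prox$terminal_label, prox$ihc_label),
                         function(tl) {
                           sgn_ihc_average_trace(traces[as.character(tl)])
                         })
    tr_lists <- list(
      terminal = stats::setNames(lapply(traces, function(t) t$dff),
                                 names(traces)),
      ihc = stats::setNames(lapply(ihc_traces, function(t) t$dff),
                            names(ihc_traces)))
    # correlation tie-break needs a trace for every IHC; IHCs with no
    # proximal terminal fall back to the global mean trace
    all_ihcs <- as.character(roi_labels(seg$ihcs))
    missing <- setdiff(all_ihcs, names(tr_lists$ihc))
    if (length(missing)) {
      pool <- rowMeans(vapply(traces, function(t) t$dff,
                              numeric(length(traces[[1]]$dff))))
      for (mi in missing) tr_lists$ihc[[mi]] <- pool
    }
    a <- assign_terminals(seg$terminals, seg$ihcs, traces = tr_lists,
                          margin_um = config$assign_margin_um)
    annotate_sector(seg$terminals, seg$ihcs, polyline, a,
                    radius_fraction = config$sector_radius_fraction,
                    pillar_positive = config$pillar_positive)
  })
  peaks <- stage("detect", do.call(rbind, lapply(traces, detect_peaks,
    min_amp_sd = config$min_amp_sd, min_fwhm_s = config$min_fwhm_s,
    prominence_sd = config$prominence_sd,
    detrend_window_s = config$detrend_window_s,
    min_separation_s = config$min_separation_s)))
  duration <- movie_duration_s(movie)
  per_ihc <- stage("group", {
    by_ihc <- split(assignment$terminal_label, assignment$ihc_label)
    lapply(by_ihc, function(tl) {
      group_sgn_events(peaks[peaks$roi_label %in% tl, , drop = FALSE],
                       window_s = config$sgn_window_s)
    })
  })
  freq <- stage("quantify", {
    data.frame(ihc_label = as.integer(names(per_ihc)),
               events = vapply(per_ihc, function(g) nrow(g$events),
                               numeric(1)),
               frequency_per_min = vapply(per_ihc, function(g) {
                 compute_frequency(nrow(g$events), duration,
                                   config$min_duration_s)
               }, numeric(1)))
  })
  list(kind = "sgn", rois = seg, traces = traces, peaks = peaks,
       assignment = assignment, events_per_ihc = per_ihc,
       frequencies = freq)
}

#' Write the result tables of a pipeline run
#'
#' CSV tables (peaks, events, waves, assignments, frequencies) plus a JSON
#' run log with versions, seed and config hash.
#'
#' @param result bundle from [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_tables <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    if (!is.null(df) && is.data.frame(df)) {
      utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  wr(result$peaks, "peaks")
  wr(result$events, "events")
  wr(result$waves, "waves")
  wr(result$assignment, "assignments")
  wr(result$frequencies, "frequencies")
  if (!is.null(result$correlations) &&
      !is.null(result$correlations$vs_distance)) {
    wr(result$correlations$vs_distance$profile, "correlation_vs_distance")
  }
  log <- list(r_version = as.character(getRversion()),
              package_version = as.character(
                utils::packageVersion("cochleaCa")),
              seed = result$config$seed,
              scene_kind = result$config$scene_kind,
              config_hash = config_hash(result$config),
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Write ground truth or any plain result list as JSON
#'
#' @param x a list of data.frames / vectors (e.g. a scene's ground truth).
#' @param path JSON path.
#' @export
write_ground_truth <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
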