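#' Full per-movie trace analysis
#'
#' Runs the complete single-movie pipeline on extracted traces: smoothing,
#' support-line detrending (KCl window excluded from the fit), event
#' detection at `k` baseline SDs, KCl viability and slow-event glia
#' filtering, population PCA of the retained detrended traces, SE
#' component selection, SE/participation/burst detection and the per-movie
#' summary. All population statistics are computed on the analysis window
#' (frames before the KCl challenge) and use the retained-cell denominator.
#'
#' @param traces a [cell_traces()] object.
#' @param kcl_window `c(first, last)` frame range of the KCl challenge, or
#'   `NULL` if the movie has none (viability filtering is then skipped).
#' @param smoothing_cutoff_hz low-pass cutoff for [smooth_trace()].
#' @param k event threshold in baseline SDs.
#' @param extraction an [extraction_params()] (viability/glia thresholds).
#' @param synchrony a [synchrony_params()].
#' @return list of class `movie_analysis`: `summary` (one-row data.frame),
#'   `events` (per retained cell), `all_events` (per cell, pre-filter),
#'   `retained` (logical mask), `viable`, `non_glia`, `raster`, `pca`,
#'   `se_component`, `ses`, `bursts`, `detrended` (matrix), `duration_s`.
#' @export
analyze_traces <- function(traces, kcl_window = NULL,
                           smoothing_cutoff_hz = 0.5, k = 3,
                           extraction = extraction_params(),
                           synchrony = synchrony_params()) {
  stopifnot(inherits(traces, "cell_traces"))
  fp <- traces$frame_period_s
  n <- nrow(traces$traces); nf <- ncol(traces$traces)

  detr <- vector("list", n)
  all_events <- vector("list", n)
  for (i in seq_len(n)) {
    sm <- smooth_trace(traces$traces[i, ], smoothing_cutoff_hz, fp)
    sl <- fit_support_line(sm, exclude = kcl_window)
    detr[[i]] <- detrend_trace(traces$traces[i, ], sl)
    all_events[[i]] <- if (detr[[i]]$baseline_sd > 0)
      detect_events(detr[[i]], k = k, frame_period_s = fp)
    else data.frame(onset = integer(0), peak = integer(0),
                    offset = integer(0), amplitude_sd = numeric(0),
                    duration_s = numeric(0))
  }

  viable <- if (is.null(kcl_window)) rep(TRUE, n)
            else filter_viable(detr, kcl_window, extraction)
  non_glia <- filter_glia(all_events, extraction$glia_max_event_duration_s)
  retained <- viable & non_glia
  if (sum(retained) < 2)
    stop("fewer than 2 retained cells; cannot analyse population synchrony")

  last <- if (is.null(kcl_window)) nf else kcl_window[1] - 1L
  duration_s <- last * fp
  events <- all_events[retained]
  events <- lapply(events, function(ev) ev[ev$peak <= last, , drop = FALSE])
  raster <- event_raster(events, last, fp,
                         cell_ids = traces$cell_ids[retained])

  D <- do.call(rbind, lapply(detr[retained],
                             function(d) d$filtered[seq_len(last)]))
  pca <- population_pca(D)
  sel <- select_se_component(pca, raster, synchrony$pc_candidates)
  pc_trace <- pca$timecourses[sel$index, ]
  ses <- detect_ses(pc_trace, raster, synchrony)
  bursts <- detect_bursts(pc_trace, ses$peak_frame, synchrony)

  structure(list(summary = summarize_movie(raster, ses, bursts, duration_s),
                 events = events, all_events = all_events,
                 retained = retained, viable = viable, non_glia = non_glia,
                 raster = raster, pca = pca, se_component = sel,
                 ses = ses, bursts = bursts, detrended = D,
                 duration_s = duration_s),
            class = "movie_analysis")
}

#' @export
print.movie_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<movie_analysis> %.0f s, %d retained cells | %d SEs",
                     " (%.2f/min), %d events, %.1f%% cells/SE, %.1f%% active,",
                     " %.1f%% SEs in bursts\n"),
              x$duration_s, sum(x$retained), s$n_se, s$se_per_min,
              s$total_events, s$pct_cells_per_se, s$pct_active_cells,
              s$pct_se_in_bursts))
  invisible(x)
}
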