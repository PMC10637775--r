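#' Parameters for PCA/ICA cell extraction
#'
#' @param n_principal_components PCs retained before ICA; a practical choice
#'   is ~1.5 x the expected cell count.
#' @param ica_spatiotemporal_weight_mu weight of the temporal block in the
#'   spatiotemporal ICA (0 = purely spatial, 1 = purely temporal).
#' @param spatial_threshold_sd z-score threshold applied to each independent
#'   component's spatial filter when carving ROIs.
#' @param min_roi_pixels minimum connected-component size kept as an ROI.
#' @param kcl_response_threshold_sd viability criterion: detrended response
#'   inside the KCl window must exceed this multiple of the baseline SD.
#' @param glia_max_event_duration_s cells with any event strictly longer
#'   than this are excluded as putative glia (default 5 s).
#' @param max_iter,tol ICA fixed-point iteration controls.
#' @param seed RNG seed for the ICA initialisation.
#' @return validated list of class `extraction_params`.
#' @export
extraction_params <- function(n_principal_components = 15,
                              ica_spatiotemporal_weight_mu = 0.5,
                              spatial_threshold_sd = 3,
                              min_roi_pixels = 5,
                              kcl_response_threshold_sd = 5,
                              glia_max_event_duration_s = 5,
                              max_iter = 500, tol = 1e-6, seed = 1L) {
  p <- as.list(environment())
  stopifnot(n_principal_components >= 1,
            ica_spatiotemporal_weight_mu >= 0, ica_spatiotemporal_weight_mu <= 1,
            spatial_threshold_sd > 0, min_roi_pixels >= 1,
            kcl_response_threshold_sd > 0, glia_max_event_duration_s > 0)
  class(p) <- "extraction_params"
  p
}

#' Region of interest
#'
#' @param pixels linear pixel indices into an `h x w` frame (column-major).
#' @param weights non-negative weights, normalized to sum to 1.
#' @param dim frame dimensions `c(h, w)`.
#' @return object of class `roi`.
#' @export
roi <- function(pixels, weights = NULL, dim) {
  stopifnot(length(pixels) >= 1, all(pixels >= 1), all(pixels <= prod(dim)))
  if (is.null(weights)) weights <- rep(1, length(pixels))
  stopifnot(length(weights) == length(pixels), all(weights >= 0),
            sum(weights) > 0)
  structure(list(pixels = as.integer(pixels),
                 weights = weights / sum(weights),
                 dim = as.integer(dim)),
            class = "roi")
}

#' Extract weighted ROI-average traces from a movie
#'
#' `trace(c, t) = sum_p w_p * movie(t, p)` -- a linear operation in the
#' movie.
#'
#' @param movie a [fluorescence_movie()].
#' @param rois list of [roi()] objects.
#' @return a [cell_traces()] object, one row per ROI.
#' @export
extract_roi_traces <- function(movie, rois) {
  stopifnot(inherits(movie, "fluorescence_movie"), length(rois) >= 1)
  d <- dim(movie$data)
  flat <- matrix(movie$data, nrow = d[1])     # frames x pixels (column-major)
  tr <- t(vapply(rois, function(r) {
    stopifnot(inherits(r, "roi"), all(r$dim == d[2:3]))
    as.numeric(flat[, r$pixels, drop = FALSE] %*% r$weights)
  }, numeric(d[1])))
  cell_traces(tr, movie$frame_period_s)
}

# Fixed-point ICA by skewness maximization on whitened signals.
# Z: observations x k (whitened, unit-variance columns). Returns k x k
# orthogonal rotation R maximizing sum_j skewness of columns of Z %*% R.
skew_ica_rotation <- function(Z, max_iter = 500, tol = 1e-6, seed = 1L) {
  k <- ncol(Z)
  set.seed(seed)
  W <- qr.Q(qr(matrix(rnorm(k * k), k, k)))
  sym_orth <- function(W) {
    s <- svd(W); s$u %*% t(s$v)
  }
  for (it in seq_len(max_iter)) {
    Y <- Z %*% W
    W_new <- sym_orth(crossprod(Z, Y^2) / nrow(Z))
    delta <- 1 - min(abs(colSums(W_new * W)))
    W <- W_new
    if (delta < tol) break
  }
  W
}

# 4-connected component labelling of a logical h x w mask.
label_components <- function(mask) {
  EBImage::bwlabel(matrix(as.numeric(mask), nrow = nrow(mask)))
}

#' Identify cells in a movie by spatiotemporal PCA/ICA
#'
#' Pixels x frames data are reduced by PCA; independent components are then
#' found by skewness-maximizing fixed-point ICA on the mu-weighted
#' concatenation of the (whitened) spatial and temporal principal
#' components -- the standard automated cell-sorting approach for calcium
#' movies. Each component's spatial filter is z-scored, thresholded at
#' `spatial_threshold_sd`, split into connected components of at least
#' `min_roi_pixels` pixels, and de-duplicated at IoU 0.5. Traces are the
#' weighted ROI means of the raw movie.
#'
#' A movie with no structured activity yields zero ROIs (not an error).
#'
#' @param movie a [fluorescence_movie()].
#' @param params an [extraction_params()].
#' @return list with `rois` (list of [roi()]) and `traces` (a
#'   [cell_traces()], zero rows if no cells were found).
#' @export
pca_ica_segment <- function(movie, params = extraction_params()) {
  stopifnot(inherits(movie, "fluorescence_movie"),
            inherits(params, "extraction_params"))
  d <- dim(movie$data)
  nf <- d[1]; npx <- d[2] * d[3]
  k <- min(params$n_principal_components, nf - 1, npx)
  X <- t(matrix(movie$data, nrow = nf))       # pixels x frames
  X <- X - rowMeans(X)

  empty <- list(rois = list(), traces = NULL)
  C <- crossprod(X) / npx                     # frames x frames
  ev <- eigen(C, symmetric = TRUE)
  pos <- ev$values > max(ev$values[1], 0) * 1e-10
  if (!any(pos) || ev$values[1] <= 0) return(empty)
  k <- min(k, sum(pos))
  V <- ev$vectors[, seq_len(k), drop = FALSE]            # temporal PCs
  sv <- sqrt(ev$values[seq_len(k)] * npx)
  U <- X %*% V %*% diag(1 / sv, k)                        # spatial PCs (unit norm)

  mu <- params$ica_spatiotemporal_weight_mu
  Z <- rbind((1 - mu) * U, mu * V)
  R <- skew_ica_rotation(Z, params$max_iter, params$tol, params$seed)
  S <- U %*% R                                            # spatial filters

  h <- d[2]; w <- d[3]
  rois <- list()
  for (j in seq_len(k)) {
    f <- S[, j]
    if (skewness(f) < 0) f <- -f                          # cells are bright
    z <- (f - median(f)) / max(robust_sd(f), .Machine$double.eps)
    mask <- matrix(z > params$spatial_threshold_sd, h, w)
    if (!any(mask)) next
    lab <- label_components(mask)
    for (cc in setdiff(unique(as.integer(lab)), 0L)) {
      px <- which(lab == cc)
      if (length(px) < params$min_roi_pixels) next
      rois[[length(rois) + 1L]] <- roi(px, pmax(f[px], 0) + 1e-12, c(h, w))
    }
  }
  if (!length(rois)) return(empty)

  # de-duplicate ROIs found by several components (IoU >= 0.5, keep larger)
  ord <- order(vapply(rois, function(r) length(r$pixels), 0), decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    dup <- any(vapply(kept, function(r) {
      inter <- length(intersect(r$pixels, rois[[i]]$pixels))
      inter / length(union(r$pixels, rois[[i]]$pixels)) >= 0.5
    }, logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- rois[[i]]
  }
  list(rois = kept, traces = extract_roi_traces(movie, kept))
}

#' Viability filter: response to the terminal KCl depolarization
#'
#' A cell is retained iff its detrended trace rises at least
#' `kcl_response_threshold_sd` x its baseline SD above the local baseline
#' inside the KCl window -- cells that do not answer the depolarization are
#' considered non-viable and dropped from every downstream denominator.
#' The local baseline is the median of the ~10 s preceding the window (the
#' support line is fitted with the window excluded, so its extrapolation
#' there must not be trusted as a reference level).
#'
#' @param detrended list of [detrend_trace()] results (one per cell).
#' @param kcl_window `c(first, last)` frame range of the KCl challenge.
#' @param params an [extraction_params()].
#' @return logical vector, `TRUE` = viable.
#' @export
filter_viable <- function(detrended, kcl_window, params = extraction_params()) {
  stopifnot(length(kcl_window) == 2, kcl_window[1] <= kcl_window[2])
  vapply(detrended, function(dt) {
    nf <- length(dt$filtered)
    if (kcl_window[1] > nf) stop("KCl window outside trace")
    win <- seq(max(1, kcl_window[1]), min(nf, kcl_window[2]))
    if (!length(win)) stop("empty KCl window")
    pre <- seq(max(1, kcl_window[1] - 30), max(1, kcl_window[1] - 1))
    ref <- median(dt$filtered[pre])
    sdv <- dt$baseline_sd
    is.finite(sdv) && sdv > 0 &&
      max(dt$filtered[win]) - ref >= params$kcl_response_threshold_sd * sdv
  }, logical(1))
}

#' Glia filter: exclude cells with very slow calcium responses
#'
#' Cells showing any event strictly longer than `max_duration_s` (default
#' 5 s) are excluded as putative glia; a 5.0 s event is kept (strict
#' inequality).
#'
#' @param events_per_cell list of [detect_events()] data.frames.
#' @param max_duration_s exclusion threshold in seconds.
#' @return logical vector, `TRUE` = kept (not glia-like).
#' @export
filter_glia <- function(events_per_cell, max_duration_s = 5) {
  vapply(events_per_cell, function(ev) {
    nrow(ev) == 0 || !any(ev$duration_s > max_duration_s)
  }, logical(1))
}
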