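#' Read and write cell traces as delimited text
#'
#' Traces are stored as CSV with one row per cell (first column `cell_id`,
#' then one column per frame) and the frame period in a `# frame_period_s=`
#' comment on the first line.
#'
#' @param traces a [cell_traces()] object.
#' @param path file path.
#' @return `write_traces_csv()` returns `path` invisibly;
#'   `read_traces_csv()` returns a [cell_traces()].
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "cell_traces"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# frame_period_s=%.10g", traces$frame_period_s), con)
  df <- data.frame(cell_id = traces$cell_ids, traces$traces)
  names(df) <- c("cell_id", paste0("f", seq_len(ncol(traces$traces))))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  first <- readLines(path, n = 1)
  fp <- as.numeric(sub("^#\\s*frame_period_s=", "", first))
  if (!is.finite(fp)) stop("missing '# frame_period_s=' header in ", path)
  df <- read.csv(path, comment.char = "#")
  cell_traces(as.matrix(df[, -1, drop = FALSE]), fp, cell_ids = df$cell_id)
}

#' Read and write fluorescence movies as multi-page TIFF
#'
#' Frames are written frame-major as 16-bit unsigned pages; values are
#' scaled by `max_value` into the 16-bit range on write and rescaled on
#' read, so `read_movie_tiff(write_movie_tiff(m))` reproduces the movie up
#' to 16-bit quantization.
#'
#' @param movie a [fluorescence_movie()].
#' @param path file path.
#' @param max_value fluorescence value mapped to the top of the 16-bit
#'   range.
#' @param frame_period_s frame period to attach on read (TIFF does not
#'   carry it).
#' @return `write_movie_tiff()` returns `path` invisibly;
#'   `read_movie_tiff()` returns a [fluorescence_movie()].
#' @export
write_movie_tiff <- function(movie, path, max_value = max(movie$data)) {
  stopifnot(inherits(movie, "fluorescence_movie"), max_value > 0)
  pages <- lapply(seq_len(dim(movie$data)[1]), function(t_)
    pmin(pmax(movie$data[t_, , ] / max_value, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path, frame_period_s = 0.328,
                            max_value = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  data <- array(0, dim = c(length(pages), d[1], d[2]))
  for (t_ in seq_along(pages)) data[t_, , ] <- pages[[t_]] * max_value
  fluorescence_movie(data, frame_period_s)
}

#' Write an event table as CSV
#'
#' @param events_per_cell list of [detect_events()] data.frames.
#' @param path file path.
#' @param cell_ids optional identifiers (defaults to list position).
#' @return the combined data.frame (columns `cell_id`, `onset`, `peak`,
#'   `offset`, `amplitude_sd`, `duration_s`), invisibly written to `path`.
#' @export
write_events_csv <- function(events_per_cell, path, cell_ids = NULL) {
  cell_ids <- cell_ids %||% seq_along(events_per_cell)
  rows <- lapply(seq_along(events_per_cell), function(i) {
    ev <- events_per_cell[[i]]
    if (nrow(ev) == 0) return(NULL)
    cbind(cell_id = cell_ids[i], ev)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(cell_id = integer(0), onset = integer(0),
                     peak = integer(0), offset = integer(0),
                     amplitude_sd = numeric(0), duration_s = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a two-column delimited EEG recording
#'
#' Expects columns `time_s` and `uv` (header optional); the sampling rate
#' is inferred from the median sample interval.
#'
#' @param path file path.
#' @param injection_time_s injection time, seconds from recording start.
#' @return an [eeg_signal()].
#' @export
read_eeg_txt <- function(path, injection_time_s = 0) {
  df <- read.csv(path, header = TRUE)
  if (!is.numeric(df[[1]])) df <- read.csv(path, header = FALSE)
  t <- df[[1]]; v <- df[[2]]
  fs <- 1 / median(diff(t))
  eeg_signal(v, fs, injection_time_s = injection_time_s)
}
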