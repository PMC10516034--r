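#' Construct a spike raster
#'
#' A spike raster is a binary channels x time-bins matrix `r(n, t)`: entry 1
#' means the channel fired at least one spike in that time bin. It is the
#' object every downstream computation (triple correlation, motif spectra,
#' entropy) consumes.
#'
#' @param data Matrix of 0/1 values, one row per channel, one column per time
#'   bin.
#' @param bin_width Width of one time bin, in milliseconds.
#' @param channel_ids Character vector of channel labels, one per row.
#'   Defaults to row names, or `"ch1"`, `"ch2"`, ... when absent.
#' @param t0 Time of the left edge of the first bin, in milliseconds.
#'
#' @return A `spike_raster`: an integer matrix with attributes `bin_width`,
#'   `channel_ids` and `t0`.
#' @examples
#' r <- spike_raster(matrix(c(1, 0, 0, 1), nrow = 2))
#' spike_count(r)
#' @export
spike_raster <- function(data, bin_width = 1, channel_ids = NULL, t0 = 0) {
  if (!is.matrix(data)) {
    data <- as.matrix(data)
  }
  if (nrow(data) < 1L || ncol(data) < 1L) {
    abort("a spike raster needs at least one channel and one time bin",
          class = "tricorr_input_error")
  }
  if (anyNA(data) || !all(data == 0L | data == 1L)) {
    abort("spike raster entries must all be 0 or 1",
          class = "tricorr_input_error")
  }
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    abort("`bin_width` must be a single positive number (ms)",
          class = "tricorr_input_error")
  }
  channel_ids <- channel_ids %||% rownames(data) %||%
    paste0("ch", seq_len(nrow(data)))
  if (length(channel_ids) != nrow(data) || anyDuplicated(channel_ids)) {
    abort("`channel_ids` must be unique labels, one per raster row",
          class = "tricorr_input_error")
  }
  mode(data) <- "integer"
  dimnames(data) <- NULL
  structure(data,
            bin_width = as.numeric(bin_width),
            channel_ids = as.character(channel_ids),
            t0 = as.numeric(t0),
            class = c("spike_raster", "matrix", "array"))
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf(
    "<spike_raster> %d channels x %d bins (%.3g ms/bin), %d spikes\n",
    n_channels(x), n_bins(x), bin_width(x), spike_count(x)))
  invisible(x)
}

#' Raster dimensions and counts
#'
#' @param raster A [spike_raster()].
#' @return `n_channels()` and `n_bins()` return the raster dimensions;
#'   `spike_count()` the total number of 1 entries; `bin_width()` the bin
#'   width in ms; `channel_ids()` the channel labels.
#' @export
n_channels <- function(raster) nrow(raster)

#' @rdname n_channels
#' @export
n_bins <- function(raster) ncol(raster)

#' @rdname n_channels
#' @export
spike_count <- function(raster) sum(raster)

#' @rdname n_channels
#' @export
bin_width <- function(raster) attr(raster, "bin_width")

#' @rdname n_channels
#' @export
channel_ids <- function(raster) attr(raster, "channel_ids")

#' Bin an event list into a spike raster
#'
#' Events are (channel, time) records, unordered and possibly duplicated.
#' Time bins are half-open intervals `[t, t + bin_width)` starting at `t0`;
#' multiple events falling into the same channel/bin clip to a single 1,
#' because the raster is binary by definition.
#'
#' @param events Data frame with columns `channel` and `time_ms`.
#' @param bin_width Bin width in milliseconds (> 0).
#' @param channel_order Character vector giving the raster's channel order;
#'   every event channel must appear here. Channels without events become
#'   all-zero rows.
#' @param duration Recording duration in milliseconds (> 0); the raster gets
#'   `ceiling(duration / bin_width)` bins.
#' @param t0 Time of the first bin edge (ms); events before `t0` are an error.
#'
#' @return A [spike_raster()].
#' @examples
#' ev <- data.frame(channel = "c1", time_ms = c(0.2, 0.7))
#' bin_events(ev, bin_width = 1, channel_order = c("c1", "c2"), duration = 10)
#' @export
bin_events <- function(events, bin_width, channel_order, duration, t0 = 0) {
  if (!all(c("channel", "time_ms") %in% names(events))) {
    abort("`events` needs columns `channel` and `time_ms`",
          class = "tricorr_input_error")
  }
  if (bin_width <= 0 || duration <= 0) {
    abort("`bin_width` and `duration` must be positive",
          class = "tricorr_input_error")
  }
  ch <- as.character(events$channel)
  tm <- as.numeric(events$time_ms)
  if (length(tm) && (anyNA(tm) || any(!is.finite(tm)) || any(tm < t0))) {
    abort("event times must be finite and >= t0",
          class = "tricorr_input_error")
  }
  unknown <- setdiff(ch, channel_order)
  if (length(unknown)) {
    abort(paste0("event channel(s) not in `channel_order`: ",
                 paste(unique(unknown), collapse = ", ")),
          class = "tricorr_input_error")
  }
  if (any(tm - t0 >= duration)) {
    abort("event time at or beyond `duration`",
          class = "tricorr_input_error")
  }
  n_bin <- as.integer(ceiling(duration / bin_width))
  mat <- matrix(0L, nrow = length(channel_order), ncol = n_bin)
  if (length(tm)) {
    row <- match(ch, channel_order)
    col <- floor((tm - t0) / bin_width) + 1L
    mat[cbind(row, col)] <- 1L # duplicates clip to 1
  }
  spike_raster(mat, bin_width = bin_width, channel_ids = channel_order,
               t0 = t0)
}

#' @export
tidy.spike_raster <- function(x, ...) {
  idx <- which(x == 1L, arr.ind = TRUE)
  tibble::tibble(
    channel = channel_ids(x)[idx[, 1L]],
    channel_index = as.integer(idx[, 1L]),
    bin = as.integer(idx[, 2L]),
    time_ms = attr(x, "t0") + (idx[, 2L] - 0.5) * bin_width(x)
  ) |>
    dplyr::arrange(.data$channel_index, .data$bin)
}

#' @export
glance.spike_raster <- function(x, ...) {
  tibble::tibble(
    n_channels = n_channels(x), n_bins = n_bins(x),
    bin_width_ms = bin_width(x), spike_count = spike_count(x),
    spike_density = spike_count(x) / (n_channels(x) * n_bins(x))
  )
}

#' @export
autoplot.spike_raster <- function(object, ...) {
  ev <- tidy(object)
  ggplot2::ggplot(ev, ggplot2::aes(.data$time_ms, .data$channel_index)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::scale_y_continuous(breaks = seq_len(n_channels(object))) +
    ggplot2::labs(x = "time (ms)", y = "channel",
                  title = sprintf("%d spikes on %d channels",
                                  spike_count(object), n_channels(object))) +
    ggplot2::theme_minimal()
}
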