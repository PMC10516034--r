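#' Read and write spike rasters
#'
#' Two plain-text interchange dialects are supported:
#' * `"dense"` — whitespace-delimited 0/1 integers, one channel per row,
#'   one column per time bin;
#' * `"events"` — CSV with header `channel,time_ms`, one spike per row
#'   (written at bin centers; read back through [bin_events()]).
#'
#' A dense write/read round trip is bit-exact for any binary raster.
#'
#' @param path File path.
#' @param format `"dense"` or `"events"`.
#' @param bin_width,channel_ids,t0 Raster metadata, needed because the dense
#'   dialect stores only the binary matrix. For `"events"`,
#'   `channel_ids` defaults to the labels seen in the file (sorted).
#' @param duration Recording duration in ms for `"events"` input; defaults to
#'   the end of the last occupied bin.
#' @return `read_raster()` returns a [spike_raster()]; `write_raster()`
#'   invisibly returns `path`.
#' @export
read_raster <- function(path, format = c("dense", "events"), bin_width = 1,
                        channel_ids = NULL, duration = NULL, t0 = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "tricorr_input_error")
  }
  if (format == "dense") {
    mat <- tryCatch(
      as.matrix(read.table(path, header = FALSE, colClasses = "numeric")),
      error = function(e) {
        abort(paste0("cannot parse dense raster file: ", conditionMessage(e)),
              class = "tricorr_format_error")
      })
    if (anyNA(mat) || !all(mat == 0 | mat == 1)) {
      abort("dense raster file contains non-binary entries",
            class = "tricorr_format_error")
    }
    spike_raster(mat, bin_width = bin_width, channel_ids = channel_ids,
                 t0 = t0)
  } else {
    ev <- read.csv(path, colClasses = c("character", "numeric"))
    if (!all(c("channel", "time_ms") %in% names(ev))) {
      abort("event CSV must have header `channel,time_ms`",
            class = "tricorr_format_error")
    }
    channel_ids <- channel_ids %||% sort(unique(ev$channel))
    duration <- duration %||%
      (ceiling((max(ev$time_ms) - t0) / bin_width) * bin_width)
    bin_events(ev, bin_width = bin_width, channel_order = channel_ids,
               duration = duration, t0 = t0)
  }
}

#' @rdname read_raster
#' @param raster A [spike_raster()].
#' @export
write_raster <- function(raster, path, format = c("dense", "events")) {
  format <- match.arg(format)
  if (format == "dense") {
    write.table(unclass(raster), path, row.names = FALSE, col.names = FALSE)
  } else {
    ev <- tidy(raster)[, c("channel", "time_ms")]
    write.csv(ev, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read and write lag tensors as flat CSV
#'
#' The flat layout has one row per lag quadruple: columns
#' `n1,t1,n2,t2,value`, preceded by `#`-comment header lines recording the
#' window, spike count and bin width. Intended for the small windows where a
#' full 4D table is practical.
#'
#' @param tensor A [lag_tensor][triple_correlation()].
#' @param path File path.
#' @return `read_tensor_csv()` returns a `lag_tensor`; `write_tensor_csv()`
#'   invisibly returns `path`.
#' @export
write_tensor_csv <- function(tensor, path) {
  w <- attr(tensor, "window")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# S=%d", w$S),
    sprintf("# T=%d", w$T),
    sprintf("# spike_count=%d", attr(tensor, "spike_count")),
    sprintf("# bin_width=%.17g", attr(tensor, "bin_width") %||% 1)
  ), con)
  long <- tidy(tensor)
  write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tensor_csv
#' @export
read_tensor_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_num <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    as.numeric(sub(".*=", "", ln[1]))
  }
  S <- as.integer(get_num("S")); Tt <- as.integer(get_num("T"))
  long <- read.csv(path, comment.char = "#")
  w <- lag_window(S, Tt)
  arr <- array(0, dim = tensor_dim(w), dimnames = tensor_dimnames(w))
  arr[cbind(long$n1 + S + 1L, long$t1 + Tt + 1L,
            long$n2 + S + 1L, long$t2 + Tt + 1L)] <- long$value
  if (all(long$value == round(long$value))) mode(arr) <- "integer"
  new_lag_tensor(arr, window = w,
                 spike_count = as.integer(get_num("spike_count")),
                 bin_width = get_num("bin_width"))
}
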