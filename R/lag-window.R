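#' Define a spatiotemporal lag window
#'
#' The lag window bounds the lag quadruples `(n1, t1, n2, t2)` over which the
#' triple correlation is accumulated: spatial lags `n1, n2` range over
#' `-S..S` channels and temporal lags `t1, t2` over `-T..T` bins, so the 4D
#' lag tensor has `(2S+1)^2 (2T+1)^2` cells.
#'
#' @param spatial Maximum spatial lag `S` in channels (>= 0).
#' @param temporal Maximum temporal lag `T` in bins (>= 0).
#' @return A `lag_window` (list with elements `S` and `T`).
#' @examples
#' lag_window(5, 4)             # the worked-example window
#' lag_window_ms(50, bin_width = 1, spatial = 7) # -50..50 ms at 1 ms bins
#' @export
lag_window <- function(spatial, temporal) {
  if (length(spatial) != 1L || length(temporal) != 1L ||
      spatial < 0 || temporal < 0 ||
      spatial != round(spatial) || temporal != round(temporal)) {
    abort("lag window bounds must be single non-negative integers",
          class = "tricorr_input_error")
  }
  structure(list(S = as.integer(spatial), T = as.integer(temporal)),
            class = "lag_window")
}

#' @rdname lag_window
#' @param temporal_ms Maximum temporal lag in milliseconds; converted to bins
#'   as `round(temporal_ms / bin_width)`.
#' @param bin_width Bin width in ms.
#' @export
lag_window_ms <- function(temporal_ms, bin_width, spatial) {
  lag_window(spatial, round(temporal_ms / bin_width))
}

#' @export
print.lag_window <- function(x, ...) {
  cat(sprintf("<lag_window> spatial -%d..%d channels, temporal -%d..%d bins (%d cells)\n",
              x$S, x$S, x$T, x$T, n_lag_cells(x)))
  invisible(x)
}

#' @rdname lag_window
#' @param window A `lag_window`.
#' @export
n_lag_cells <- function(window) {
  (2L * window$S + 1L)^2 * (2L * window$T + 1L)^2
}

tensor_dim <- function(window) {
  c(2L * window$S + 1L, 2L * window$T + 1L,
    2L * window$S + 1L, 2L * window$T + 1L)
}

tensor_dimnames <- function(window) {
  n <- as.character(-window$S:window$S)
  t <- as.character(-window$T:window$T)
  list(n1 = n, t1 = t, n2 = n, t2 = t)
}

same_window <- function(a, b) identical(a$S, b$S) && identical(a$T, b$T)
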