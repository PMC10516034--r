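#' Triple correlation of a spike raster
#'
#' For every admissible lag quadruple `(n1, t1, n2, t2)` within the window,
#' accumulates
#' \deqn{c_3(n_1,t_1,n_2,t_2) = \sum_{n,t} r(n,t)\, r(n+n_1, t+t_1)\,
#'   r(n+n_2, t+t_2)}
#' over all raster positions, with factors outside the raster treated as 0
#' (zero padding) so that every cell can serve as a reference point. The
#' result is the 4D spatiotemporal lag distribution: raw summed contributions
#' (integers for a binary raster), not averages. Key identities for binary
#' rasters: the zero-lag cell equals the spike count, and
#' `c3(n1,t1,n2,t2) == c3(n2,t2,n1,t1)` (the two lagged factors commute).
#'
#' The production path iterates over spikes and their in-window spike
#' neighborhoods rather than over all raster cells; it is exactly equal (not
#' just numerically close) to the literal five-loop evaluation in
#' [triple_correlation_oracle()].
#'
#' @param raster A [spike_raster()].
#' @param window A [lag_window()].
#' @param boundary `"zero"` (default) zero-pads beyond the raster edge;
#'   `"valid"` restricts reference positions to the interior where the whole
#'   window fits, so no padding is ever touched.
#' @param average If `TRUE`, divide the sums by the number of reference
#'   positions (`channels * bins`), giving the averaged form of the
#'   definition. The PDF and entropy are invariant to this constant factor.
#' @return A `lag_tensor`: 4D array indexed `[n1, t1, n2, t2]` with dimnames
#'   giving signed lags, plus attributes `window`, `spike_count`,
#'   `boundary`, `averaged` and `bin_width`.
#' @examples
#' r <- spike_raster(matrix(c(1, 0, 0, 1), nrow = 2))
#' tc <- triple_correlation(r, lag_window(1, 1))
#' tc["0", "0", "0", "0"] # == spike_count(r)
#' @seealso [tensor_slice()], [motif_spectrum()], [estimate_pdf()]
#' @export
triple_correlation <- function(raster, window,
                               boundary = c("zero", "valid"),
                               average = FALSE) {
  boundary <- match.arg(boundary)
  check_raster(raster)
  stopifnot(inherits(window, "lag_window"))
  S <- window$S; Tt <- window$T
  N <- nrow(raster); TT <- ncol(raster)
  if (S >= N || Tt >= TT) {
    warn("lag window is as large as the raster in at least one axis; the tensor will be edge-dominated")
  }
  P <- (2L * S + 1L) * (2L * Tt + 1L)
  sp <- which(raster == 1L, arr.ind = TRUE)
  ch <- sp[, 1L]; tb <- sp[, 2L]
  if (boundary == "valid") {
    interior <- ch > S & ch <= N - S & tb > Tt & tb <= TT - Tt
    refs <- which(interior)
  } else {
    refs <- seq_along(ch)
  }
  counts <- integer(P * P)
  for (i in refs) {
    sel <- abs(ch - ch[i]) <= S & abs(tb - tb[i]) <= Tt
    # offset ids, 0-based, temporal lag fastest
    oid <- (ch[sel] - ch[i] + S) * (2L * Tt + 1L) + (tb[sel] - tb[i] + Tt)
    pid <- as.vector(outer(oid * P, oid, `+`)) + 1L
    counts <- counts + tabulate(pid, nbins = P * P)
  }
  # linear order is t2 fastest, then n2, t1, n1
  arr <- array(counts, dim = c(2L * Tt + 1L, 2L * S + 1L,
                               2L * Tt + 1L, 2L * S + 1L))
  arr <- aperm(arr, c(4L, 3L, 2L, 1L))
  if (average) arr <- arr / (N * TT)
  dimnames(arr) <- tensor_dimnames(window)
  new_lag_tensor(arr, window = window, spike_count = sum(raster),
                 bin_width = attr(raster, "bin_width"),
                 boundary = boundary, averaged = average)
}

new_lag_tensor <- function(arr, window, spike_count, bin_width = 1,
                           boundary = "zero", averaged = FALSE) {
  structure(arr,
            window = window,
            spike_count = as.integer(spike_count),
            bin_width = bin_width,
            boundary = boundary,
            averaged = averaged,
            class = c("lag_tensor", "array"))
}

check_raster <- function(raster) {
  if (!inherits(raster, "spike_raster")) {
    abort("expected a `spike_raster`", class = "tricorr_input_error")
  }
  if (!all(raster == 0L | raster == 1L)) {
    abort("raster is not binary", class = "tricorr_input_error")
  }
  invisible(raster)
}

#' Brute-force triple-correlation oracle
#'
#' Literal evaluation of the definition: one explicit loop over every lag
#' quadruple, summing the triple product of the raster with its two shifted
#' copies (zero-padded). Quadratic-to-cubic cost in the raster size - this is
#' a verification oracle for small inputs, kept deliberately independent of
#' the optimized path in [triple_correlation()], which it must match exactly.
#'
#' @inheritParams triple_correlation
#' @return A `lag_tensor`.
#' @export
triple_correlation_oracle <- function(raster, window,
                                      boundary = c("zero", "valid")) {
  boundary <- match.arg(boundary)
  check_raster(raster)
  S <- window$S; Tt <- window$T
  r <- unclass(raster)
  ref <- r
  if (boundary == "valid") {
    mask <- matrix(0L, nrow(r), ncol(r))
    if (nrow(r) > 2 * S && ncol(r) > 2 * Tt) {
      mask[(S + 1L):(nrow(r) - S), (Tt + 1L):(ncol(r) - Tt)] <- 1L
    }
    ref <- r * mask
  }
  shift2 <- function(m, dn, dt) {
    out <- matrix(0L, nrow(m), ncol(m))
    rows <- seq_len(nrow(m)); cols <- seq_len(ncol(m))
    src_r <- rows + dn; src_c <- cols + dt
    ok_r <- src_r >= 1L & src_r <= nrow(m)
    ok_c <- src_c >= 1L & src_c <= ncol(m)
    out[rows[ok_r], cols[ok_c]] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
    out
  }
  out <- array(0L, dim = tensor_dim(window), dimnames = tensor_dimnames(window))
  for (n1 in -S:S) {
    for (t1 in -Tt:Tt) {
      sh1 <- shift2(r, n1, t1)
      for (n2 in -S:S) {
        for (t2 in -Tt:Tt) {
          sh2 <- shift2(r, n2, t2)
          out[n1 + S + 1L, t1 + Tt + 1L, n2 + S + 1L, t2 + Tt + 1L] <-
            sum(ref * sh1 * sh2)
        }
      }
    }
  }
  new_lag_tensor(out, window = window, spike_count = sum(raster),
                 bin_width = attr(raster, "bin_width"), boundary = boundary)
}

#' Slice a lag tensor at two fixed lags
#'
#' Returns the 2D sub-array obtained by fixing exactly two of the four lag
#' axes (a slice, not a marginal: nothing is summed). The customary view
#' fixes `n2 = 0, t2 = 0`, showing the pairwise (second-order) structure.
#'
#' @param tensor A `lag_tensor`.
#' @param n1,t1,n2,t2 Fix a lag axis by giving its signed lag value; exactly
#'   two must be supplied.
#' @return A 2D matrix over the two free axes, dimnames = signed lags.
#' @examples
#' r <- spike_raster(matrix(c(1, 0, 0, 1), nrow = 2))
#' tensor_slice(triple_correlation(r, lag_window(1, 1)), n2 = 0, t2 = 0)
#' @export
tensor_slice <- function(tensor, n1 = NULL, t1 = NULL, n2 = NULL, t2 = NULL) {
  w <- attr(tensor, "window")
  fixed <- list(n1 = n1, t1 = t1, n2 = n2, t2 = t2)
  is_fixed <- !vapply(fixed, is.null, logical(1))
  if (sum(is_fixed) != 2L) {
    abort("exactly two of n1, t1, n2, t2 must be fixed",
          class = "tricorr_input_error")
  }
  lims <- list(n1 = w$S, t1 = w$T, n2 = w$S, t2 = w$T)
  idx <- vector("list", 4L)
  for (k in seq_along(fixed)) {
    if (is_fixed[k]) {
      v <- fixed[[k]]
      if (abs(v) > lims[[k]]) {
        abort(sprintf("fixed lag %s = %d outside window", names(fixed)[k], v),
              class = "tricorr_index_error")
      }
      idx[[k]] <- v + lims[[k]] + 1L
    } else {
      idx[[k]] <- seq_len(2L * lims[[k]] + 1L)
    }
  }
  out <- tensor[idx[[1]], idx[[2]], idx[[3]], idx[[4]], drop = FALSE]
  dn <- dimnames(tensor)
  out <- array(out, dim = dim(out)[!is_fixed],
               dimnames = dn[!is_fixed])
  out
}

#' Read one tensor cell by signed lags
#'
#' @param tensor A `lag_tensor`.
#' @param n1,t1,n2,t2 Signed lags of the cell.
#' @return The cell value.
#' @export
tensor_cell <- function(tensor, n1, t1, n2, t2) {
  w <- attr(tensor, "window")
  if (abs(n1) > w$S || abs(n2) > w$S || abs(t1) > w$T || abs(t2) > w$T) {
    abort("lag outside window", class = "tricorr_index_error")
  }
  tensor[n1 + w$S + 1L, t1 + w$T + 1L, n2 + w$S + 1L, t2 + w$T + 1L]
}

#' @export
print.lag_tensor <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf(
    "<lag_tensor> S=%d, T=%d (%d cells), total %s, spike_count %d, zero-lag %s\n",
    w$S, w$T, n_lag_cells(w), format(sum(x)), attr(x, "spike_count"),
    format(tensor_cell(x, 0, 0, 0, 0))))
  invisible(x)
}

#' @export
tidy.lag_tensor <- function(x, ...) {
  w <- attr(x, "window")
  grid <- expand.grid(n1 = -w$S:w$S, t1 = -w$T:w$T,
                      n2 = -w$S:w$S, t2 = -w$T:w$T,
                      KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies n1 fastest; the array is stored [n1, t1, n2, t2]
  tibble::tibble(n1 = grid$n1, t1 = grid$t1, n2 = grid$n2, t2 = grid$t2,
                 value = as.vector(x))
}

#' @export
glance.lag_tensor <- function(x, ...) {
  w <- attr(x, "window")
  tibble::tibble(
    S = w$S, T = w$T, n_cells = n_lag_cells(w),
    tensor_total = sum(x), spike_count = attr(x, "spike_count"),
    zero_lag = tensor_cell(x, 0, 0, 0, 0),
    support_size = sum(x > 0)
  )
}

#' Plot the pairwise slice of a lag tensor
#'
#' Heat map of the `(n2, t2) = (0, 0)` slice (or any other two-axis slice
#' passed through `...` to [tensor_slice()]).
#'
#' @param object A `lag_tensor`.
#' @param ... Fixed lags forwarded to [tensor_slice()]; defaults to
#'   `n2 = 0, t2 = 0`.
#' @return A ggplot object.
#' @export
autoplot.lag_tensor <- function(object, ...) {
  fixed <- list(...)
  if (!length(fixed)) fixed <- list(n2 = 0, t2 = 0)
  sl <- do.call(tensor_slice, c(list(object), fixed))
  df <- expand.grid(a = as.integer(rownames(sl)), b = as.integer(colnames(sl)),
                    KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(sl)
  ax <- names(dimnames(sl))
  ggplot2::ggplot(df, ggplot2::aes(.data$b, .data$a, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = paste(ax[2], "(lag)"), y = paste(ax[1], "(lag)"),
                  fill = "summed\ncontribution") +
    ggplot2::theme_minimal()
}
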