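#' Estimate the 4D lag probability distribution
#'
#' Maximum-likelihood histogram normalization of a lag tensor: each cell's
#' summed contribution divided by the tensor total. The support is the full
#' lag window; no smoothing or pseudocounts are applied, and structurally
#' impossible cells are kept (with probability 0). Because the PDF is scale
#' invariant, it is identical for summed and averaged tensors.
#'
#' @param tensor A [lag_tensor][triple_correlation()] with positive total.
#' @return A `lag_pdf`: 4D array of probabilities congruent to the tensor,
#'   summing to 1, with attributes `window`, `tensor_total`, `spike_count`.
#' @examples
#' r <- spike_raster(matrix(c(1, 0, 0, 1), nrow = 2))
#' p <- estimate_pdf(triple_correlation(r, lag_window(1, 1)))
#' sum(p)
#' @export
estimate_pdf <- function(tensor) {
  total <- sum(tensor)
  if (total <= 0) {
    abort("lag tensor is all zero (empty raster); the PDF is undefined",
          class = "tricorr_degenerate_error")
  }
  probs <- unclass(tensor) / total
  attributes(probs) <- attributes(unclass(tensor))[c("dim", "dimnames")]
  structure(probs,
            window = attr(tensor, "window"),
            tensor_total = total,
            spike_count = attr(tensor, "spike_count"),
            class = c("lag_pdf", "array"))
}

#' Shannon entropy of a lag PDF
#'
#' The plug-in estimate \eqn{H = -\sum_i p_i \log_2 p_i} over the 4D lag
#' PDF, in bits; cells with `p = 0` contribute 0 (`0 log 0 := 0`). `H` is
#' bounded by `log2(support_size)`, attained exactly for a uniform PDF.
#'
#' @param pdf A [lag_pdf][estimate_pdf()].
#' @param unit `"bits"` (base-2 logarithm, default) or `"nats"`.
#' @return An `entropy_value`: list with `H`, `unit`, `support_size` (count
#'   of nonzero cells), `n_cells` and `window`.
#' @examples
#' r <- spike_raster(diag(1, 4))
#' shannon_entropy(estimate_pdf(triple_correlation(r, lag_window(1, 1))))
#' @export
shannon_entropy <- function(pdf, unit = c("bits", "nats")) {
  unit <- match.arg(unit)
  if (!inherits(pdf, "lag_pdf")) {
    abort("expected a `lag_pdf` from estimate_pdf()",
          class = "tricorr_input_error")
  }
  p <- as.vector(pdf)
  p <- p[p > 0]
  lg <- if (unit == "bits") log2 else log
  structure(
    list(H = -sum(p * lg(p)), unit = unit, support_size = length(p),
         n_cells = length(as.vector(pdf)), window = attr(pdf, "window")),
    class = "entropy_value")
}

#' @export
print.entropy_value <- function(x, ...) {
  cat(sprintf("<entropy_value> H = %.4f %s over %d occupied / %d window cells\n",
              x$H, x$unit, x$support_size, x$n_cells))
  invisible(x)
}

#' @export
glance.entropy_value <- function(x, ...) {
  tibble::tibble(H = x$H, unit = x$unit, support_size = x$support_size,
                 n_cells = x$n_cells, H_max = log2(x$n_cells))
}

#' Entropy of a raster in one call
#'
#' Convenience chain raster -> triple correlation -> PDF -> entropy.
#'
#' @inheritParams triple_correlation
#' @inheritParams shannon_entropy
#' @return An [entropy_value][shannon_entropy()].
#' @export
raster_entropy <- function(raster, window, boundary = c("zero", "valid"),
                           unit = c("bits", "nats")) {
  tensor <- triple_correlation(raster, window, boundary = match.arg(boundary))
  shannon_entropy(estimate_pdf(tensor), unit = match.arg(unit))
}

#' Write an entropy report as JSON
#'
#' @param entropy An [entropy_value][shannon_entropy()].
#' @param tensor The source [lag_tensor][triple_correlation()].
#' @param path Output path.
#' @return Invisibly, the report list.
#' @export
write_entropy_json <- function(entropy, tensor, path) {
  w <- attr(tensor, "window")
  report <- list(
    H_bits = if (entropy$unit == "bits") entropy$H else entropy$H / log(2),
    support_size = entropy$support_size,
    window = list(S = w$S, T = w$T),
    spike_count = attr(tensor, "spike_count"),
    tensor_total = sum(tensor)
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(report)
}
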