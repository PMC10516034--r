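#' Motif classes of three-node spatiotemporal configurations
#'
#' A triplet of (possibly coincident) spikes is reduced to its
#' *configuration*: the pair of weak orders of its three node times
#' `(0, t1, t2)` and three node channels `(0, n1, n2)`. There are 13 weak
#' orders of three items per axis, hence 169 configurations, including all
#' node-overlap cases. Configurations collapse into 14 motif classes, labeled
#' with Roman numerals 0-XIII:
#'
#' * `0` - all three nodes coincide (spike rate)
#' * `I` - two distinct spikes on one channel (autocorrelation)
#' * `II` - three distinct spikes on one channel
#' * `III` - two channels, one time (pairwise synchrony)
#' * `IV` - three channels, one time (triplet synchrony)
#' * `V` - two distinct spikes on different channels at different times
#'   (cross-correlation)
#' * `VI`/`VII` - two channels, two times: a synchronous pair plus a second
#'   spike on one of the channels, later (`VI`) or earlier (`VII`) than the
#'   synchronous moment
#' * `VIII`/`X` - two channels, three times: one channel spikes twice, the
#'   other channel's single spike comes first (`VIII`) or last (`X`)
#' * `IX` - two channels, three times, single spike in the middle (feedback,
#'   A then B then A)
#' * `XI` - one spike followed by a synchronous pair on two other channels
#'   (divergence)
#' * `XII` - a synchronous pair followed by one spike on a third channel
#'   (convergence)
#' * `XIII` - three channels, three times (feedforward chain)
#'
#' The collapse keeps temporal direction (XI and XII, VI and VII, VIII and X
#' are swapped by time reversal) and is invariant to spatial reflection,
#' since channel ordering in a raster is arbitrary. The 169-row
#' configuration-to-class table ships with the package
#' (`inst/extdata/motif_configurations.csv`) and is validated on first use.
#'
#' @return `motif_configurations()` returns the full table as a tibble with
#'   columns `config_id`, `temporal_order_code`, `spatial_order_code`,
#'   `class_label`. `motif_class_levels` is the ordered vector of the 14
#'   class labels.
#' @examples
#' motif_configurations()
#' classify_lags(1, 1, 2, 3) # a feedforward chain, class XIII
#' @export
motif_configurations <- function() {
  if (is.null(the$config_table)) {
    path <- system.file("extdata", "motif_configurations.csv",
                        package = "tricorr", mustWork = TRUE)
    tab <- tibble::as_tibble(read.csv(path, colClasses = c(
      "integer", "character", "character", "character")))
    validate_config_table(tab)
    the$config_table <- tab
    key <- paste(tab$temporal_order_code, tab$spatial_order_code)
    the$config_lookup <- stats::setNames(seq_len(nrow(tab)), key)
  }
  the$config_table
}

#' @rdname motif_configurations
#' @export
#' @format NULL
motif_class_levels <- c("0", "I", "II", "III", "IV", "V", "VI", "VII",
                        "VIII", "IX", "X", "XI", "XII", "XIII")

validate_config_table <- function(tab) {
  ok <- nrow(tab) == 169L &&
    !anyDuplicated(tab[, c("temporal_order_code", "spatial_order_code")]) &&
    setequal(unique(tab$class_label), motif_class_levels) &&
    sum(tab$class_label == "0") == 1L
  if (!ok) {
    abort("shipped motif configuration table fails partition validation",
          class = "tricorr_internal_error")
  }
  invisible(tab)
}

# weak-order code of (0, a, b): the three pairwise comparison signs
weak_order_code <- function(a, b) {
  sym <- c("-", "0", "+")
  paste0(sym[sign(a) + 2L], sym[sign(b) + 2L], sym[sign(b - a) + 2L])
}

#' Classify lag quadruples into configurations and motif classes
#'
#' Maps each lag quadruple `(n1, t1, n2, t2)` to its three-node
#' configuration and motif class. Only the sign and tie structure of the
#' lags matters: `(1, 1, 2, 3)` and `(4, 2, 7, 9)` share a configuration.
#' Vectorized over the four arguments.
#'
#' @param n1,t1,n2,t2 Integer lag vectors (recycled to a common length).
#' @return A tibble with columns `n1, t1, n2, t2, config_id, class`
#'   (`class` is a factor with the 14 levels in `motif_class_levels`).
#' @export
classify_lags <- function(n1, t1, n2, t2) {
  tab <- motif_configurations()
  args <- vctrs_recycle(n1, t1, n2, t2)
  key <- paste(weak_order_code(args$t1, args$t2),
               weak_order_code(args$n1, args$n2))
  row <- unname(the$config_lookup[key])
  tibble::tibble(
    n1 = args$n1, t1 = args$t1, n2 = args$n2, t2 = args$t2,
    config_id = tab$config_id[row],
    class = factor(tab$class_label[row], levels = motif_class_levels)
  )
}

vctrs_recycle <- function(n1, t1, n2, t2) {
  len <- max(length(n1), length(t1), length(n2), length(t2))
  list(n1 = rep_len(n1, len), t1 = rep_len(t1, len),
       n2 = rep_len(n2, len), t2 = rep_len(t2, len))
}

#' Motif-class spectrum of a lag tensor
#'
#' Sums the tensor's contributions within each of the 14 motif classes. The
#' spectrum conserves mass: `sum(M)` equals the tensor total, and `M` for
#' class 0 equals the spike count (the zero-lag cell is the only member of
#' class 0).
#'
#' @param tensor A [lag_tensor][triple_correlation()].
#' @return A `motif_spectrum`: tibble with columns `class` (factor, 14
#'   levels) and `M` (summed contributions), with attributes `window`,
#'   `spike_count` and `tensor_total`.
#' @examples
#' r <- spike_raster(matrix(c(1, 0, 0, 1), nrow = 2))
#' motif_spectrum(triple_correlation(r, lag_window(1, 1)))
#' @export
motif_spectrum <- function(tensor) {
  long <- tidy(tensor)
  cls <- classify_lags(long$n1, long$t1, long$n2, long$t2)$class
  spec <- tibble::tibble(class = cls, M = long$value) |>
    dplyr::group_by(.data$class, .drop = FALSE) |>
    dplyr::summarise(M = sum(.data$M), .groups = "drop")
  new_motif_spectrum(spec, window = attr(tensor, "window"),
                     spike_count = attr(tensor, "spike_count"),
                     tensor_total = sum(tensor))
}

new_motif_spectrum <- function(spec, window, spike_count, tensor_total) {
  structure(spec,
            window = window,
            spike_count = spike_count,
            tensor_total = tensor_total,
            class = c("motif_spectrum", class(tibble::tibble())))
}

#' @export
autoplot.motif_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$class, .data$M)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "motif class", y = "summed contribution M") +
    ggplot2::theme_minimal()
}
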