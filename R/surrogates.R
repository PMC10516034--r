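#' Spike-rate-matched surrogate raster
#'
#' Shuffles all spikes uniformly over the whole channel x time grid: spike
#' positions are a uniform sample without replacement of all cells, so the
#' surrogate has exactly the source's spike count and shape, each cell holds
#' at most one spike, and any spatiotemporal structure beyond the overall
#' rate is abolished.
#'
#' @param raster A [spike_raster()].
#' @param seed Optional integer seed; when given, the shuffle is performed
#'   under a local RNG state and is bit-reproducible.
#' @return A [spike_raster()] of identical shape and spike count.
#' @export
shuffle_raster <- function(raster, seed = NULL) {
  check_raster(raster)
  k <- spike_count(raster)
  n_cell <- n_channels(raster) * n_bins(raster)
  if (k > n_cell) {
    abort("spike count exceeds cell count; cannot shuffle without collisions",
          class = "tricorr_input_error")
  }
  do_shuffle <- function() {
    mat <- matrix(0L, n_channels(raster), n_bins(raster))
    mat[sample.int(n_cell, k)] <- 1L
    mat
  }
  mat <- if (is.null(seed)) do_shuffle() else
    withr::with_seed(seed, do_shuffle())
  spike_raster(mat, bin_width = bin_width(raster),
               channel_ids = channel_ids(raster), t0 = attr(raster, "t0"))
}

#' Surrogate ensemble: empirical chance-level reference
#'
#' Runs the full tensor -> spectrum -> PDF -> entropy chain on `n`
#' spike-rate-matched shuffles of `raster`, and summarizes per-class mean
#' contributions (the empirical chance expectation `mu`), their quartiles,
#' the per-iteration entropies, and the mean lag tensor.
#'
#' @param raster A [spike_raster()].
#' @param window A [lag_window()].
#' @param n Number of surrogate iterations (default 100).
#' @param seed Integer seed for the ensemble's RNG; the whole ensemble is
#'   reproducible from it.
#' @return A `surrogate_ensemble` with elements `n`, `seed`, `window`,
#'   `spike_count`, `entropies` (length-`n` numeric, bits), `spectra`
#'   (tibble: iteration, class, M), `class_summary` (tibble: class, mu and
#'   quartiles), `mean_tensor` (numeric `lag_tensor`).
#' @examples
#' r <- generate_random_raster(c(6, 40), p = 0.1, seed = 1)
#' ens <- surrogate_ensemble(r, lag_window(2, 2), n = 5, seed = 1)
#' glance(ens)
#' @export
surrogate_ensemble <- function(raster, window, n = 100, seed = NULL) {
  check_raster(raster)
  if (n < 1) abort("`n` must be >= 1", class = "tricorr_input_error")
  run <- function() {
    mean_tensor <- NULL
    entropies <- numeric(n)
    spectra <- vector("list", n)
    for (i in seq_len(n)) {
      surr <- shuffle_raster(raster)
      tensor <- triple_correlation(surr, window)
      spec <- motif_spectrum(tensor)
      entropies[i] <- shannon_entropy(estimate_pdf(tensor))$H
      spectra[[i]] <- tibble::tibble(iteration = i, class = spec$class,
                                     M = spec$M)
      mean_tensor <- if (is.null(mean_tensor)) unclass(tensor) / n else
        mean_tensor + unclass(tensor) / n
    }
    list(entropies = entropies, spectra = dplyr::bind_rows(spectra),
         mean_tensor = mean_tensor)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  class_summary <- res$spectra |>
    dplyr::group_by(.data$class, .drop = FALSE) |>
    dplyr::summarise(
      mu = mean(.data$M),
      q25 = quantile(.data$M, 0.25, names = FALSE),
      q50 = quantile(.data$M, 0.50, names = FALSE),
      q75 = quantile(.data$M, 0.75, names = FALSE),
      min = min(.data$M), max = max(.data$M),
      .groups = "drop")
  structure(
    list(n = n, seed = seed, window = window,
         spike_count = spike_count(raster),
         entropies = res$entropies,
         spectra = res$spectra,
         class_summary = class_summary,
         mean_tensor = new_lag_tensor(res$mean_tensor, window = window,
                                      spike_count = spike_count(raster),
                                      bin_width = bin_width(raster))),
    class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf(
    "<surrogate_ensemble> n = %d shuffles of %d spikes; entropy %.3f [%.3f, %.3f] bits\n",
    x$n, x$spike_count, median(x$entropies), min(x$entropies),
    max(x$entropies)))
  invisible(x)
}

#' @export
tidy.surrogate_ensemble <- function(x, ...) x$class_summary

#' @export
glance.surrogate_ensemble <- function(x, ...) {
  tibble::tibble(
    n = x$n, spike_count = x$spike_count,
    entropy_mean = mean(x$entropies),
    entropy_q25 = quantile(x$entropies, 0.25, names = FALSE),
    entropy_median = median(x$entropies),
    entropy_q75 = quantile(x$entropies, 0.75, names = FALSE),
    entropy_min = min(x$entropies), entropy_max = max(x$entropies)
  )
}

#' Box-and-whisker view of surrogate entropies
#'
#' @param object A [surrogate_ensemble()].
#' @param observed Optional observed [entropy_value][shannon_entropy()] to
#'   overlay as a point.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surrogate_ensemble <- function(object, observed = NULL, ...) {
  df <- tibble::tibble(H = object$entropies)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = "surrogates", y = .data$H)) +
    ggplot2::geom_boxplot(width = 0.3) +
    ggplot2::labs(x = NULL, y = "4D Shannon entropy (bits)") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::annotate("point", x = "surrogates", y = observed$H,
                               colour = "red", size = 3)
  }
  p
}

#' Normalized motif-class prevalence M/mu - 1
#'
#' Compares an observed motif-class spectrum with a chance-level expectation:
#' `M / mu - 1`, where `mu` is the surrogate-ensemble mean contribution per
#' class (or any per-class expectation table supplied instead). Values above
#' 0 indicate network structure beyond chance; values at or below 0 indicate
#' activity at chance level. Classes whose expectation is 0 are returned as
#' `NA` (undefined), never infinity.
#'
#' @param spectrum A [motif_spectrum()].
#' @param expectation A [surrogate_ensemble()] (its per-class mean is used),
#'   or a data frame with columns `class` and `mu` (the hook for analytic
#'   expectations).
#' @return A tibble with columns `class`, `M`, `mu`, `prevalence`.
#' @export
normalized_prevalence <- function(spectrum, expectation) {
  if (inherits(expectation, "surrogate_ensemble")) {
    if (!same_window(attr(spectrum, "window"), expectation$window)) {
      abort("spectrum and ensemble were computed with different lag windows",
            class = "tricorr_input_error")
    }
    mu_tab <- expectation$class_summary[, c("class", "mu")]
  } else {
    mu_tab <- tibble::as_tibble(expectation)[, c("class", "mu")]
  }
  tibble::tibble(class = spectrum$class, M = spectrum$M) |>
    dplyr::left_join(mu_tab, by = "class") |>
    dplyr::mutate(prevalence = dplyr::if_else(
      .data$mu > 0, .data$M / .data$mu - 1, NA_real_))
}
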