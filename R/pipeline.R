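#' Epoch plan for a long recording
#'
#' Describes how analysis epochs are cut from a recording: `n_epochs`
#' epochs of `epoch_length_ms`, placed contiguously from the start, evenly
#' spaced across the recording, or at listed offsets. Epochs must fit within
#' the recording and not overlap.
#'
#' @param epoch_length_ms Epoch length in milliseconds (the longitudinal
#'   convention is 1000 ms).
#' @param n_epochs Number of epochs (longitudinal convention: 60).
#' @param placement `"evenly_spaced"` (default), `"contiguous"`, or
#'   `"listed"` with explicit `offsets_ms`.
#' @param offsets_ms Start times (ms) of each epoch when `placement =
#'   "listed"`.
#' @return An `epoch_plan`.
#' @export
epoch_plan <- function(epoch_length_ms, n_epochs,
                       placement = c("evenly_spaced", "contiguous", "listed"),
                       offsets_ms = NULL) {
  placement <- match.arg(placement)
  if (epoch_length_ms <= 0 || n_epochs < 1) {
    abort("`epoch_length_ms` must be positive and `n_epochs` >= 1",
          class = "tricorr_input_error")
  }
  if (placement == "listed" &&
      (is.null(offsets_ms) || length(offsets_ms) != n_epochs)) {
    abort("`listed` placement needs one offset per epoch",
          class = "tricorr_input_error")
  }
  structure(list(epoch_length_ms = epoch_length_ms, n_epochs = n_epochs,
                 placement = placement, offsets_ms = offsets_ms),
            class = "epoch_plan")
}

# bin ranges (1-based, inclusive) of each epoch within a raster
epoch_bounds <- function(plan, raster) {
  len <- plan$epoch_length_ms / bin_width(raster)
  if (abs(len - round(len)) > 1e-9) {
    abort("epoch length is not a whole number of bins",
          class = "tricorr_plan_error")
  }
  len <- as.integer(round(len))
  total <- n_bins(raster)
  n <- plan$n_epochs
  starts <- switch(plan$placement,
    contiguous = (seq_len(n) - 1L) * len,
    evenly_spaced = if (n == 1L) 0L else
      as.integer(round(seq(0L, total - len, length.out = n))),
    listed = as.integer(round((plan$offsets_ms - attr(raster, "t0")) /
                                bin_width(raster)))
  )
  if (any(starts < 0L) || any(starts + len > total)) {
    abort("epoch plan does not fit within the recording",
          class = "tricorr_plan_error")
  }
  if (n > 1L && any(diff(sort(starts)) < len)) {
    abort("epochs overlap", class = "tricorr_plan_error")
  }
  tibble::tibble(epoch = seq_len(n), start_bin = starts + 1L,
                 end_bin = starts + len)
}

#' Analyze one recording epoch by epoch
#'
#' Cuts the raster into epochs, computes the triple-correlation lag tensor
#' of each epoch, and *sums* the per-epoch tensors into one recording-level
#' tensor before normalizing it once into a PDF and a single entropy - so
#' epochs are weighted by their activity. From the summed tensor it derives
#' the motif-class spectrum and, against a per-epoch-shuffled surrogate
#' ensemble, the normalized prevalence `M/mu - 1`. Per-epoch diagnostics
#' (spike count, tensor total, optional per-epoch entropy) are retained.
#'
#' @param raster A [spike_raster()].
#' @param window A [lag_window()].
#' @param plan An [epoch_plan()], or `NULL` for a single epoch spanning the
#'   whole recording.
#' @param n_surrogates Surrogate iterations for the chance reference
#'   (0 skips surrogates; `prevalence` is then `NULL`).
#' @param seed Integer seed governing the surrogate ensemble.
#' @param per_epoch_entropy If `TRUE`, also compute each epoch's own
#'   entropy (`NA` for silent epochs) into the diagnostics table.
#' @return A `recording_report`: list with `tensor`, `spectrum`,
#'   `prevalence`, `entropy`, `epochs` (diagnostics tibble),
#'   `surrogate_entropies`, and `params`.
#' @examples
#' r <- generate_feedforward_raster(4, shape = c(26, 96), seed = 1)
#' rep <- analyze_recording(r, lag_window(5, 4), n_surrogates = 5, seed = 1)
#' glance(rep)
#' @export
analyze_recording <- function(raster, window, plan = NULL,
                              n_surrogates = 100, seed = NULL,
                              per_epoch_entropy = FALSE) {
  check_raster(raster)
  if (is.null(plan)) {
    plan <- epoch_plan(n_bins(raster) * bin_width(raster), 1L,
                       placement = "contiguous")
  }
  bounds <- epoch_bounds(plan, raster)
  sub_rasters <- purrr::map(seq_len(nrow(bounds)), function(i) {
    cols <- bounds$start_bin[i]:bounds$end_bin[i]
    spike_raster(unclass(raster)[, cols, drop = FALSE],
                 bin_width = bin_width(raster),
                 channel_ids = channel_ids(raster))
  })
  tensors <- purrr::map(sub_rasters, triple_correlation, window = window)
  total_tensor <- Reduce(`+`, purrr::map(tensors, unclass))
  total_tensor <- new_lag_tensor(total_tensor, window = window,
                                 spike_count = spike_count(raster),
                                 bin_width = bin_width(raster))
  diag <- bounds |>
    dplyr::mutate(
      spikes = purrr::map_int(sub_rasters, spike_count),
      tensor_total = purrr::map_dbl(tensors, sum))
  if (per_epoch_entropy) {
    diag$entropy <- purrr::map_dbl(tensors, function(tt) {
      if (sum(tt) == 0) NA_real_ else shannon_entropy(estimate_pdf(tt))$H
    })
  }
  spectrum <- motif_spectrum(total_tensor)
  entropy <- if (sum(total_tensor) > 0) {
    shannon_entropy(estimate_pdf(total_tensor))
  } else {
    NULL
  }
  prevalence <- NULL
  surrogate_entropies <- NULL
  if (n_surrogates > 0) {
    run <- function() {
      mus <- matrix(0, nrow = length(motif_class_levels),
                    ncol = n_surrogates)
      hs <- numeric(n_surrogates)
      for (j in seq_len(n_surrogates)) {
        surr_tensor <- Reduce(`+`, purrr::map(sub_rasters, function(sr) {
          unclass(triple_correlation(shuffle_raster(sr), window))
        }))
        surr_tensor <- new_lag_tensor(surr_tensor, window = window,
                                      spike_count = spike_count(raster))
        mus[, j] <- motif_spectrum(surr_tensor)$M
        hs[j] <- if (sum(surr_tensor) > 0) {
          shannon_entropy(estimate_pdf(surr_tensor))$H
        } else {
          NA_real_
        }
      }
      list(mu = rowMeans(mus), hs = hs)
    }
    res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    mu_tab <- tibble::tibble(
      class = factor(motif_class_levels, levels = motif_class_levels),
      mu = res$mu)
    prevalence <- normalized_prevalence(spectrum, mu_tab)
    surrogate_entropies <- res$hs
  }
  structure(
    list(tensor = total_tensor, spectrum = spectrum,
         prevalence = prevalence, entropy = entropy, epochs = diag,
         surrogate_entropies = surrogate_entropies,
         params = list(window = window, plan = plan,
                       n_surrogates = n_surrogates, seed = seed,
                       bin_width = bin_width(raster))),
    class = "recording_report")
}

#' @export
print.recording_report <- function(x, ...) {
  cat(sprintf(
    "<recording_report> %d epochs, %d spikes, tensor total %s, H = %s bits\n",
    nrow(x$epochs), attr(x$tensor, "spike_count"), format(sum(x$tensor)),
    if (is.null(x$entropy)) "NA" else sprintf("%.4f", x$entropy$H)))
  invisible(x)
}

#' @export
tidy.recording_report <- function(x, ...) {
  if (!is.null(x$prevalence)) {
    x$prevalence
  } else {
    tibble::tibble(class = x$spectrum$class, M = x$spectrum$M,
                   mu = NA_real_, prevalence = NA_real_)
  }
}

#' @export
glance.recording_report <- function(x, ...) {
  tibble::tibble(
    n_epochs = nrow(x$epochs),
    spike_count = attr(x$tensor, "spike_count"),
    tensor_total = sum(x$tensor),
    H = if (is.null(x$entropy)) NA_real_ else x$entropy$H,
    support_size = if (is.null(x$entropy)) NA_integer_ else
      x$entropy$support_size,
    n_surrogates = x$params$n_surrogates
  )
}

#' Aggregate recording reports across wells and ages
#'
#' Builds the longitudinal cohort table: for every (age, motif class), the
#' box-whisker summary (quartiles and range) of normalized prevalence
#' `M/mu - 1` across contributing wells, and likewise for entropy per age.
#' A well contributes at an age when its tensor total is nonzero
#' (sufficient spike activity); the median trace is reported as shown only
#' when contributing wells exceed `min_wells` (strictly), otherwise it is
#' marked suppressed.
#'
#' @param reports List of [analyze_recording()] reports.
#' @param manifest Data frame with one row per report: columns `well` and
#'   `div` (day in vitro, or any ordered age/condition label). `(well, div)`
#'   pairs must be unique.
#' @param min_wells Suppression threshold: the median is shown only when
#'   `n_contributing > min_wells` (default 7).
#' @return A `cohort_summary`: list of two tibbles, `classes` (div, class,
#'   n_wells, n_contributing, q25, median, q75, min, max, median_shown) and
#'   `entropy` (same summary of per-well entropies).
#' @export
aggregate_cohort <- function(reports, manifest, min_wells = 7) {
  manifest <- tibble::as_tibble(manifest)
  if (!all(c("well", "div") %in% names(manifest))) {
    abort("`manifest` needs columns `well` and `div`",
          class = "tricorr_input_error")
  }
  if (nrow(manifest) != length(reports)) {
    abort("one manifest row per report required",
          class = "tricorr_input_error")
  }
  if (anyDuplicated(manifest[, c("well", "div")])) {
    abort("duplicate (well, div) pair in manifest",
          class = "tricorr_manifest_error")
  }
  per_well <- purrr::map2_dfr(reports, seq_along(reports), function(rep, i) {
    tidy(rep) |>
      dplyr::mutate(well = manifest$well[i], div = manifest$div[i],
                    contributing = sum(rep$tensor) > 0,
                    H = if (is.null(rep$entropy)) NA_real_ else rep$entropy$H)
  })
  summarise_vals <- function(df, value_col) {
    df |>
      dplyr::summarise(
        n_wells = dplyr::n_distinct(.data$well),
        n_contributing = dplyr::n_distinct(.data$well[.data$contributing]),
        q25 = quantile(.data[[value_col]][.data$contributing], 0.25,
                       na.rm = TRUE, names = FALSE),
        median = median(.data[[value_col]][.data$contributing], na.rm = TRUE),
        q75 = quantile(.data[[value_col]][.data$contributing], 0.75,
                       na.rm = TRUE, names = FALSE),
        min = suppressWarnings(min(.data[[value_col]][.data$contributing],
                                   na.rm = TRUE)),
        max = suppressWarnings(max(.data[[value_col]][.data$contributing],
                                   na.rm = TRUE)),
        .groups = "drop") |>
      dplyr::mutate(median_shown = .data$n_contributing > min_wells,
                    median = dplyr::if_else(.data$median_shown, .data$median,
                                            NA_real_))
  }
  classes <- per_well |>
    dplyr::group_by(.data$div, .data$class) |>
    summarise_vals("prevalence")
  entropy <- per_well |>
    dplyr::distinct(.data$div, .data$well, .data$contributing, .data$H) |>
    dplyr::group_by(.data$div) |>
    summarise_vals("H")
  structure(list(classes = classes, entropy = entropy,
                 min_wells = min_wells),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d ages x %d classes (median shown when > %d wells contribute)\n",
              dplyr::n_distinct(x$classes$div), dplyr::n_distinct(x$classes$class),
              x$min_wells))
  invisible(x)
}

#' @export
tidy.cohort_summary <- function(x, ...) x$classes

#' Longitudinal motif-class profiles
#'
#' @param object A [aggregate_cohort()] result.
#' @param ... Unused.
#' @return A ggplot: one facet per motif class, interquartile ribbon and
#'   median trace (where shown) of `M/mu - 1` across ages.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  ggplot2::ggplot(object$classes,
                  ggplot2::aes(.data$div, .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         alpha = 0.3, fill = "steelblue") +
    ggplot2::geom_line(colour = "steelblue", linewidth = 0.8, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~class, scales = "free_y") +
    ggplot2::labs(x = "day in vitro", y = "M / mu - 1") +
    ggplot2::theme_minimal()
}
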