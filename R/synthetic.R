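#' Three-spike motif template
#'
#' A template lists the three (channel, bin) offsets of one planted motif,
#' with the reference spike at (0, 0). The default is a feedforward chain
#' (motif class XIII): three distinct channels, strictly increasing times,
#' and - deliberately - three *distinct* pairwise lag vectors
#' ((1,1), (1,2), (2,3)), so each within-motif spike pair occupies its own
#' pairwise-lag cell. A uniform chain such as (0,0),(1,1),(2,2) would fold
#' two pairs onto the same lag cell and split the pairwise counts unevenly.
#'
#' @param offsets Integer matrix with 3 rows and columns `channel`, `bin`.
#' @return A `motif_template`.
#' @export
motif_template <- function(offsets = cbind(channel = c(0L, 1L, 2L),
                                           bin = c(0L, 1L, 3L))) {
  offsets <- as.matrix(offsets)
  if (nrow(offsets) != 3L || ncol(offsets) != 2L) {
    abort("a motif template has exactly three (channel, bin) offsets",
          class = "tricorr_input_error")
  }
  if (anyDuplicated(offsets)) {
    abort("template offsets must be distinct points",
          class = "tricorr_input_error")
  }
  storage.mode(offsets) <- "integer"
  colnames(offsets) <- c("channel", "bin")
  structure(offsets, class = c("motif_template", "matrix", "array"))
}

# TRUE when the three pairwise lag vectors are pairwise distinct
has_distinct_pair_lags <- function(template) {
  d <- rbind(template[2, ] - template[1, ],
             template[3, ] - template[1, ],
             template[3, ] - template[2, ])
  !anyDuplicated(d)
}

#' Generate a raster of isolated planted motifs
#'
#' Places `n_motifs` copies of a three-spike motif template into an
#' otherwise silent raster such that (i) every spike lies at least `margin`
#' channels/bins from the raster edges and (ii) spikes of different motifs
#' are never simultaneously within `margin` channels *and* `margin` bins of
#' each other. With `margin` set to the analysis lag window `(S, T)`, every
#' triple-correlation contribution then involves spikes of a single motif,
#' so the motif-class spectrum has support exactly {0, V, XIII} for the
#' default feedforward template.
#'
#' Placement styles:
#' * `"spaced"` (default) - a seeded random draw of `n_motifs` anchor slots
#'   from the maximal isolation-respecting slot grid; always succeeds when
#'   the grid has enough slots, otherwise errors.
#' * `"random"` - uniform rejection sampling of anchors with a bounded
#'   number of attempts; errors deterministically when placement fails.
#'
#' @param n_motifs Number of motif copies (16 reproduces the canonical
#'   worked example: 48 spikes).
#' @param template A [motif_template()].
#' @param shape `c(channels, bins)` of the raster; default `c(26, 96)`.
#' @param margin `c(channels, bins)` edge margin and isolation distance;
#'   default `c(5, 4)`, matching the worked example's lag window.
#' @param placement `"spaced"` or `"random"`.
#' @param seed Optional integer seed (placement is reproducible from it).
#' @param bin_width Bin width in ms for the returned raster.
#' @param max_attempts Attempt budget per motif for `"random"` placement.
#' @param n_background Number of additional unstructured spikes sprinkled
#'   uniformly over the remaining empty cells (default 0). Background spikes
#'   ignore the isolation constraint - they model ongoing activity around
#'   the planted motifs, so with `n_background > 0` the spectrum support is
#'   no longer confined to {0, V, XIII}. Useful for holding a cohort's total
#'   spike count fixed while varying how much of it is organized into
#'   motifs.
#' @return A [spike_raster()] with `3 * n_motifs + n_background` spikes;
#'   anchor positions are recorded in attribute `anchors`.
#' @examples
#' r <- generate_feedforward_raster(16, seed = 1)
#' spike_count(r)
#' @export
generate_feedforward_raster <- function(n_motifs = 16,
                                        template = motif_template(),
                                        shape = c(channels = 26, bins = 96),
                                        margin = c(channels = 5, bins = 4),
                                        placement = c("spaced", "random"),
                                        seed = NULL, bin_width = 1,
                                        max_attempts = 500,
                                        n_background = 0) {
  placement <- match.arg(placement)
  stopifnot(inherits(template, "motif_template"))
  N <- as.integer(shape[1]); TT <- as.integer(shape[2])
  m_ch <- as.integer(margin[1]); m_t <- as.integer(margin[2])
  ext_ch <- max(template[, "channel"]) - min(template[, "channel"]) + 1L
  ext_t <- max(template[, "bin"]) - min(template[, "bin"]) + 1L
  # anchor = position of the template's (0,0) offset, 0-based
  base_ch <- -min(template[, "channel"]); base_t <- -min(template[, "bin"])
  lo_ch <- m_ch + base_ch; hi_ch <- N - m_ch - ext_ch + base_ch
  lo_t <- m_t + base_t; hi_t <- TT - m_t - ext_t + base_t
  if (n_motifs > 0 && (hi_ch < lo_ch || hi_t < lo_t)) {
    abort("raster too small for the template and margins",
          class = "tricorr_placement_error")
  }
  # two anchors are safely isolated when their motifs' spikes can never be
  # within `margin` of each other in both axes simultaneously
  min_dch <- m_ch + ext_ch; min_dt <- m_t + ext_t
  isolated <- function(a, b) {
    abs(a[1] - b[1]) >= min_dch || abs(a[2] - b[2]) >= min_dt
  }
  place <- function() {
    if (n_motifs == 0L) return(matrix(integer(0), ncol = 2))
    if (placement == "spaced") {
      slots_ch <- seq(lo_ch, hi_ch, by = min_dch)
      slots_t <- seq(lo_t, hi_t, by = min_dt)
      slots <- as.matrix(expand.grid(ch = slots_ch, t = slots_t))
      if (nrow(slots) < n_motifs) {
        abort(sprintf(
          "cannot place %d isolated motifs: only %d slots in a %dx%d raster",
          n_motifs, nrow(slots), N, TT), class = "tricorr_placement_error")
      }
      slots[sample.int(nrow(slots), n_motifs), , drop = FALSE]
    } else {
      anchors <- matrix(integer(0), ncol = 2)
      for (i in seq_len(n_motifs)) {
        placed <- FALSE
        for (a in seq_len(max_attempts)) {
          cand <- c(sample(lo_ch:hi_ch, 1), sample(lo_t:hi_t, 1))
          if (nrow(anchors) == 0 ||
              all(apply(anchors, 1, isolated, b = cand))) {
            anchors <- rbind(anchors, cand)
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          abort(sprintf(
            "random placement failed for motif %d of %d after %d attempts",
            i, n_motifs, max_attempts), class = "tricorr_placement_error")
        }
      }
      anchors
    }
  }
  build <- function() {
    anchors <- place()
    mat <- matrix(0L, N, TT)
    for (i in seq_len(nrow(anchors))) {
      rows <- anchors[i, 1] + template[, "channel"] + 1L
      cols <- anchors[i, 2] + template[, "bin"] + 1L
      mat[cbind(rows, cols)] <- 1L
    }
    if (n_background > 0) {
      free <- which(mat == 0L)
      if (n_background > length(free)) {
        abort("not enough empty cells for the requested background spikes",
              class = "tricorr_placement_error")
      }
      mat[sample(free, n_background)] <- 1L
    }
    list(mat = mat, anchors = anchors)
  }
  res <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  mat <- res$mat
  anchors <- res$anchors
  out <- spike_raster(mat, bin_width = bin_width)
  attr(out, "anchors") <- anchors
  attr(out, "template") <- template
  out
}

#' Generate a Bernoulli random raster
#'
#' Independent Bernoulli(`p`) cells; the null-model input for property
#' tests and oracle comparisons.
#'
#' @param shape `c(channels, bins)`.
#' @param p Spike probability per cell, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param bin_width Bin width in ms.
#' @return A [spike_raster()].
#' @export
generate_random_raster <- function(shape, p, seed = NULL, bin_width = 1) {
  if (p < 0 || p > 1) {
    abort("`p` must be in [0, 1]", class = "tricorr_input_error")
  }
  N <- as.integer(shape[1]); TT <- as.integer(shape[2])
  draw <- function() matrix(rbinom(N * TT, 1L, p), N, TT)
  mat <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  spike_raster(mat, bin_width = bin_width)
}
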