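# independent predicate oracle: classify a quadruple from the geometry of its
# three points, without the shipped table
predicate_class <- function(n1, t1, n2, t2) {
  pts <- unique(list(c(0, 0), as.numeric(c(n1, t1)), as.numeric(c(n2, t2))))
  if (length(pts) == 1) return("0")
  if (length(pts) == 2) {
    d <- pts[[2]] - pts[[1]]
    if (d[1] == 0) return("I")
    if (d[2] == 0) return("III")
    return("V")
  }
  ch <- vapply(pts, `[`, 0, 1); tt <- vapply(pts, `[`, 0, 2)
  nch <- length(unique(ch)); nt <- length(unique(tt))
  if (nch == 1) return("II")
  if (nt == 1) return("IV")
  if (nch == 3 && nt == 3) return("XIII")
  if (nch == 3) { # synchronous pair + lone spike
    lone <- tt[!(duplicated(tt) | duplicated(tt, fromLast = TRUE))]
    return(if (lone < tt[duplicated(tt)][1]) "XI" else "XII")
  }
  dup_ch <- ch[duplicated(ch)][1]
  lone_t <- tt[ch != dup_ch]; pair_t <- tt[ch == dup_ch]
  if (nt == 3) {
    if (lone_t > min(pair_t) && lone_t < max(pair_t)) return("IX")
    return(if (lone_t < min(pair_t)) "VIII" else "X")
  }
  if (lone_t == min(pair_t)) "VI" else "VII"
}

sweep_grid <- function(k = 2) {
  expand.grid(n1 = -k:k, t1 = -k:k, n2 = -k:k, t2 = -k:k,
              KEEP.OUT.ATTRS = FALSE)
}

test_that("the configuration table is a 169-into-14 partition", {
  tab <- motif_configurations()
  expect_identical(nrow(tab), 169L)
  expect_identical(length(unique(tab$class_label)), 14L)
  expect_identical(
    anyDuplicated(tab[, c("temporal_order_code", "spatial_order_code")]), 0L)
  expect_identical(sum(table(tab$class_label)), 169L)
  # class 0 contains exactly the all-coincident configuration
  expect_identical(sum(tab$class_label == "0"), 1L)
  zero_row <- tab[tab$class_label == "0", ]
  expect_identical(zero_row$temporal_order_code, "000")
  expect_identical(zero_row$spatial_order_code, "000")
})

test_that("an exhaustive |n|<=2, |t|<=2 sweep reaches all 169 configurations", {
  g <- sweep_grid(2)
  cls <- classify_lags(g$n1, g$t1, g$n2, g$t2)
  expect_identical(length(unique(cls$config_id)), 169L)
  expect_identical(length(unique(cls$class)), 14L)
})

test_that("named anchor quadruples map to their text-pinned classes", {
  cases <- list(
    list(c(0, 0, 0, 0), "0"),     # all three nodes coincide: spike rate
    list(c(0, 2, 0, 0), "I"),     # one channel, two times: autocorrelation
    list(c(0, 1, 0, 3), "II"),    # one channel, three times
    list(c(1, 0, 0, 0), "III"),   # two channels, same time: synchrony
    list(c(1, 0, 2, 0), "IV"),    # three channels, same time
    list(c(2, 3, 0, 0), "V"),     # cross-correlation
    list(c(0, 2, 1, 1), "IX"),    # A at 0 and 2, B at 1: feedback
    list(c(1, 1, 2, 1), "XI"),    # one spike then a synchronous pair
    list(c(1, -1, 2, -1), "XII"), # synchronous pair then one spike
    list(c(1, 1, 2, 3), "XIII")   # feedforward chain
  )
  for (case in cases) {
    got <- do.call(classify_lags, as.list(case[[1]]))$class
    expect_identical(as.character(got), case[[2]])
  }
})

test_that("classification agrees with the geometric predicate oracle", {
  g <- sweep_grid(2)
  got <- as.character(classify_lags(g$n1, g$t1, g$n2, g$t2)$class)
  want <- mapply(predicate_class, g$n1, g$t1, g$n2, g$t2)
  expect_identical(got, unname(want))
})

test_that("class depends only on sign/tie structure, not lag magnitude", {
  pairs <- list(
    list(c(1, 1, 2, 3), c(4, 2, 7, 9)),
    list(c(0, 2, 0, 0), c(0, 9, 0, 0)),
    list(c(1, 0, 2, 0), c(3, 0, 9, 0)),
    list(c(-1, -2, 1, 2), c(-5, -9, 2, 4)))
  for (p in pairs) {
    a <- do.call(classify_lags, as.list(p[[1]]))
    b <- do.call(classify_lags, as.list(p[[2]]))
    expect_identical(a$config_id, b$config_id)
  }
})

test_that("reference-node relabeling preserves the class", {
  g <- sweep_grid(2)
  base <- as.character(classify_lags(g$n1, g$t1, g$n2, g$t2)$class)
  # same three points seen from node 1: lags (-n1,-t1) and (n2-n1, t2-t1)
  alt <- as.character(classify_lags(-g$n1, -g$t1,
                                    g$n2 - g$n1, g$t2 - g$t1)$class)
  expect_identical(base, alt)
})

test_that("spatial reflection is collapsed; time reversal swaps paired classes", {
  g <- sweep_grid(2)
  base <- as.character(classify_lags(g$n1, g$t1, g$n2, g$t2)$class)
  refl <- as.character(classify_lags(-g$n1, g$t1, -g$n2, g$t2)$class)
  expect_identical(base, refl)
  # temporal direction is NOT collapsed: reversal acts as exactly the
  # involution XI<->XII, VI<->VII, VIII<->X, all other classes fixed
  trev <- as.character(classify_lags(g$n1, -g$t1, g$n2, -g$t2)$class)
  swap <- c("0" = "0", I = "I", II = "II", III = "III", IV = "IV", V = "V",
            VI = "VII", VII = "VI", VIII = "X", IX = "IX", X = "VIII",
            XI = "XII", XII = "XI", XIII = "XIII")
  expect_identical(unname(swap[base]), trev)
})

test_that("motif spectrum conserves tensor mass and resolves simple rasters", {
  # single spike: all mass in class 0
  one <- raster_with_spikes(5, 8, list(c(3, 4)))
  spec1 <- motif_spectrum(triple_correlation(one, lag_window(2, 2)))
  expect_identical(spec1$M[spec1$class == "0"], 1L)
  expect_identical(sum(spec1$M), 1L)

  # isolated feedforward motifs: support exactly {0, V, XIII}
  spec2 <- motif_spectrum(triple_correlation(fig_fixture(), fig_window()))
  expect_identical(as.character(spec2$class[spec2$M > 0]),
                   c("0", "V", "XIII"))
  expect_identical(spec2$M[spec2$class == "0"], 48L)
  expect_identical(spec2$M[spec2$class == "V"], 288L)
  expect_identical(spec2$M[spec2$class == "XIII"], 96L)

  # conservation on random rasters
  withr::local_seed(303)
  for (i in 1:5) {
    tc <- triple_correlation(generate_random_raster(c(6, 20), 0.2),
                             lag_window(2, 2))
    expect_identical(sum(motif_spectrum(tc)$M), sum(tc))
  }
})
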