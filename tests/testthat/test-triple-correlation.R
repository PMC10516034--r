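test_that("a single spike admits only the triply-coincident triplet", {
  r <- raster_with_spikes(6, 10, list(c(3, 5)))
  tc <- triple_correlation(r, lag_window(1, 1))
  expect_identical(tensor_cell(tc, 0, 0, 0, 0), 1L)
  expect_identical(sum(tc), 1L)
})

test_that("two-spike raster matches hand enumeration", {
  # spikes at (0,0) and (1,1) in 0-based coordinates; S = T = 1
  r <- raster_with_spikes(4, 6, list(c(1, 1), c(2, 2)))
  tc <- triple_correlation(r, lag_window(1, 1))
  # reference (0,0): offsets {(0,0),(1,1)}; reference (1,1): {(0,0),(-1,-1)}
  expect_identical(tensor_cell(tc, 0, 0, 0, 0), 2L)
  for (cell in list(c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 1, 1, 1),
                    c(-1, -1, 0, 0), c(0, 0, -1, -1), c(-1, -1, -1, -1))) {
    expect_identical(do.call(tensor_cell, c(list(tc), as.list(cell))), 1L)
  }
  expect_identical(sum(tc), 8L)
})

test_that("optimized path equals the brute-force oracle on random rasters", {
  withr::local_seed(202)
  for (i in 1:12) {
    p <- sample(c(0.05, 0.1, 0.2), 1)
    r <- generate_random_raster(c(sample(3:8, 1), sample(5:20, 1)), p)
    w <- lag_window(sample(0:2, 1), sample(0:2, 1))
    expect_tensor_equal(triple_correlation(r, w),
                        triple_correlation_oracle(r, w))
  }
})

test_that("valid-boundary mode equals the oracle with restricted references", {
  withr::local_seed(203)
  for (i in 1:5) {
    r <- generate_random_raster(c(7, 15), p = 0.2)
    w <- lag_window(2, 2)
    expect_tensor_equal(triple_correlation(r, w, boundary = "valid"),
                        triple_correlation_oracle(r, w, boundary = "valid"))
  }
})

test_that("zero-lag cell equals spike count on random rasters", {
  withr::local_seed(204)
  for (i in 1:10) {
    r <- generate_random_raster(c(6, 25), p = runif(1, 0, 0.3))
    tc <- triple_correlation(r, lag_window(2, 2))
    expect_identical(tensor_cell(tc, 0, 0, 0, 0), spike_count(r))
  }
})

test_that("exchange symmetry holds: c3(n1,t1,n2,t2) == c3(n2,t2,n1,t1)", {
  withr::local_seed(205)
  for (i in 1:5) {
    r <- generate_random_raster(c(6, 15), p = 0.2)
    tc <- triple_correlation(r, lag_window(2, 2))
    swapped <- aperm(unclass(tc), c(3, 4, 1, 2))
    expect_identical(as.vector(unclass(tc)), as.vector(swapped))
  }
})

test_that("pairwise slice is mirror symmetric for interior spikes", {
  r <- fig_fixture()
  sl <- tensor_slice(triple_correlation(r, fig_window()), n2 = 0, t2 = 0)
  flipped <- sl[rev(seq_len(nrow(sl))), rev(seq_len(ncol(sl)))]
  expect_identical(as.vector(sl), as.vector(flipped))
})

test_that("adding a spike never decreases any tensor cell", {
  withr::local_seed(206)
  for (i in 1:5) {
    r <- generate_random_raster(c(6, 15), p = 0.15)
    zeros <- which(unclass(r) == 0L)
    m2 <- unclass(r)
    m2[sample(zeros, 1)] <- 1L
    w <- lag_window(2, 2)
    before <- triple_correlation(r, w)
    after <- triple_correlation(spike_raster(m2), w)
    expect_true(all(unclass(after) >= unclass(before)))
  }
})

test_that("all-zero raster gives an all-zero tensor (oracle and fast path)", {
  r <- spike_raster(matrix(0L, 4, 8))
  expect_identical(sum(triple_correlation(r, lag_window(1, 2))), 0L)
  expect_identical(sum(triple_correlation_oracle(r, lag_window(1, 2))), 0L)
})

test_that("averaged form is the summed form scaled by the position count", {
  r <- fig_fixture()
  w <- lag_window(2, 2)
  summed <- triple_correlation(r, w)
  avg <- triple_correlation(r, w, average = TRUE)
  expect_equal(as.vector(unclass(avg)),
               as.vector(unclass(summed)) / (n_channels(r) * n_bins(r)))
})

test_that("tensor_slice demands exactly two fixed axes and in-window lags", {
  tc <- triple_correlation(raster_with_spikes(4, 6, list(c(2, 3))),
                           lag_window(1, 1))
  expect_error(tensor_slice(tc, n1 = 0), class = "tricorr_input_error")
  expect_error(tensor_slice(tc, n1 = 0, t1 = 0, n2 = 0),
               class = "tricorr_input_error")
  expect_error(tensor_slice(tc, n2 = 5, t2 = 0),
               class = "tricorr_index_error")
  sl <- tensor_slice(tc, n2 = 0, t2 = 0)
  expect_identical(dim(sl), c(3L, 3L))
  # slice of an all-zero tensor is all zero
  z <- triple_correlation(spike_raster(matrix(0L, 4, 6)), lag_window(1, 1))
  expect_true(all(tensor_slice(z, n2 = 0, t2 = 0) == 0L))
})

test_that("oversized window warns but still computes", {
  r <- raster_with_spikes(3, 4, list(c(1, 1), c(2, 2)))
  expect_warning(tc <- triple_correlation(r, lag_window(3, 5)))
  expect_identical(tensor_cell(tc, 0, 0, 0, 0), 2L)
})

test_that("tensor CSV round trip preserves values and metadata", {
  r <- fig_fixture()
  tc <- triple_correlation(r, lag_window(2, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tensor_csv(tc, path)
  back <- read_tensor_csv(path)
  expect_tensor_equal(tc, back)
  expect_identical(attr(back, "spike_count"), attr(tc, "spike_count"))
  expect_true(same_window(attr(back, "window"), attr(tc, "window")))
})

test_that("non-binary input is rejected by both paths", {
  bad <- matrix(c(0L, 1L), 2, 4)
  class(bad) <- c("spike_raster", "matrix", "array")
  bad[1, 1] <- 3L
  expect_error(triple_correlation(bad, lag_window(1, 1)),
               class = "tricorr_input_error")
  expect_error(triple_correlation_oracle(bad, lag_window(1, 1)),
               class = "tricorr_input_error")
})
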