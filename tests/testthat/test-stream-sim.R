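test_that("generate_stream builds the requested FIFO composition", {
  s <- generate_stream(3, cell_marker_ratio = 0, seed = 1)
  expect_equal(nrow(s), 3L)
  expect_true(all(s$kind == "marker"))

  s2 <- generate_stream(100, cell_marker_ratio = 2, seed = 1)
  expect_equal(sum(s2$kind == "marker"), 100L)
  expect_equal(sum(s2$kind == "cell"), 200L)
  expect_equal(s2$source_index, seq_len(300))
  expect_false(anyDuplicated(s2$uid) > 0)
  # symbols only on markers
  expect_true(all(is.na(s2$symbol[s2$kind == "cell"])))
  expect_true(all(s2$symbol[s2$kind == "marker"] %in% c("A", "T", "C")))

  expect_identical(generate_stream(50, 2, seed = 9),
                   generate_stream(50, 2, seed = 9))
  expect_false(identical(generate_stream(50, 2, seed = 9),
                         generate_stream(50, 2, seed = 10)))

  expect_error(generate_stream(0), "n_markers")
  expect_error(generate_stream(10, -1), "cell_marker_ratio")
  expect_error(generate_stream(10, NaN), "cell_marker_ratio")
  expect_error(generate_stream(10, 2, symbol_weights = c(1, 1)),
               "symbol_weights")
  expect_error(generate_stream(10, 2, p_out_of_focus = 2),
               "p_out_of_focus")
})

test_that("marker symbols follow the symbol weights", {
  s <- generate_stream(1000, 0, symbol_weights = c(1, 0, 0), seed = 3)
  expect_true(all(s$symbol == "A"))

  w <- c(0.5, 0.3, 0.2)
  n <- 3000
  s2 <- generate_stream(n, 0, symbol_weights = w, seed = 4)
  counts <- table(factor(s2$symbol, c("A", "T", "C")))
  for (i in 1:3) {
    sigma <- sqrt(n * w[i] * (1 - w[i]))
    expect_lt(abs(counts[[i]] - n * w[i]), 3 * sigma)
  }
})

test_that("out-of-focus flags are sampled on cells only", {
  s <- generate_stream(50, 2, p_out_of_focus = 1, seed = 2)
  expect_true(all(s$out_of_focus[s$kind == "cell"]))
  expect_true(all(is.na(s$out_of_focus[s$kind == "marker"])))
  s0 <- generate_stream(50, 2, p_out_of_focus = 0, seed = 2)
  expect_false(any(s0$out_of_focus[s0$kind == "cell"]))
})

test_that("interior gap counts average the design ratio", {
  s <- generate_stream(10000, cell_marker_ratio = 2, seed = 11)
  m <- encode_markers(s)
  interior <- m$gap_counts[2:(length(m$symbols))]
  expect_lt(abs(mean(interior) - 2), 0.05)
})

test_that("apply_deletion removes each event independently at the rate", {
  s <- generate_stream(30, 2, seed = 5)
  z0 <- apply_deletion(s, 0, seed = 1)
  expect_identical(as.data.frame(z0$stream), as.data.frame(s))
  expect_equal(nrow(z0$truth), 0L)

  z1 <- apply_deletion(s, 1, seed = 1)
  expect_equal(nrow(z1$stream), 0L)
  expect_equal(nrow(z1$truth), nrow(s))

  big <- generate_stream(10000, 0, seed = 6)
  zb <- apply_deletion(big, 0.01, seed = 7)
  # Binomial(10000, 0.01): 3 sigma band around 100
  expect_gt(nrow(zb$truth), 70)
  expect_lt(nrow(zb$truth), 130)
  # survivors keep their relative order
  expect_true(!is.unsorted(match(zb$stream$uid, big$uid)))
  expect_equal(nrow(big) - nrow(zb$stream), nrow(zb$truth))

  expect_error(apply_deletion(s, 1.2), "rate")
  expect_error(apply_deletion(s, -0.1), "rate")
})

test_that("apply_misplacement conserves events and matches its records", {
  s <- generate_stream(40, 2, seed = 8)
  z0 <- apply_misplacement(s, 0, seed = 1)
  expect_identical(as.data.frame(z0$stream), as.data.frame(s))
  expect_equal(nrow(z0$truth), 0L)

  replay <- getFromNamespace("replay_misplacement", "beadmap")
  for (seed in 1:8) {
    z <- apply_misplacement(s, 0.25, max_shift = 1, seed = seed)
    expect_setequal(z$stream$uid, s$uid)
    expect_true(all(z$truth$from_index != z$truth$to_index))
    # max_shift = 1 moves land next to their origin (up to collisions)
    expect_true(all(abs(z$truth$to_index - z$truth$from_index) <= 2))
    # replaying the truth records reconstructs the corrupted stream
    expect_identical(as.data.frame(replay(s, z$truth)),
                     as.data.frame(z$stream))
  }
  for (seed in 1:4) {
    z <- apply_misplacement(s, 0.1, max_shift = 5, seed = seed)
    expect_setequal(z$stream$uid, s$uid)
    expect_identical(as.data.frame(replay(s, z$truth)),
                     as.data.frame(z$stream))
  }
  zi <- apply_misplacement(s, 0.1, max_shift = Inf, seed = 3)
  expect_setequal(zi$stream$uid, s$uid)

  expect_error(apply_misplacement(s, 0.1, max_shift = 0), "max_shift")
  expect_error(apply_misplacement(s, 2), "rate")
})

test_that("zero-rate corruption composes to the identity", {
  s <- generate_stream(25, 2, seed = 12)
  out <- apply_misplacement(apply_deletion(s, 0, seed = 1)$stream, 0,
                            seed = 2)$stream
  expect_identical(as.data.frame(out), as.data.frame(s))
})

test_that("event streams round-trip through CSV", {
  s <- generate_stream(20, 2, p_out_of_focus = 0.3, seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream_csv(s, path)
  back <- read_stream_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(s),
               ignore_attr = TRUE)
})

test_that("seeded calls do not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_stream(10, 2, seed = 5))
  expect_identical(runif(1), before)
})
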