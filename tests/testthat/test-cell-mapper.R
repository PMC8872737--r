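# run the matching stage on two prepared streams and return everything
match_pair <- function(stream_a, stream_b, drop_rule = "both",
                       positions = NULL) {
  ma <- encode_markers(stream_a)
  mb <- encode_markers(stream_b)
  aln <- global_align(ma, mb)
  rep <- classify_errors(aln)
  segs <- match_segments(ma, mb, aln, rep, drop_rule = drop_rule)
  if (is.null(positions)) positions <- dispense_layout(stream_b)
  tab <- build_mapping(segs, ma, mb, positions)
  list(ma = ma, mb = mb, segs = segs, tab = tab,
       stats = retention_stats(tab, ma))
}

test_that("identical readouts keep interior segments and drop flanks", {
  s <- make_stream(c("cell", "A", "cell", "cell", "T"))
  res <- match_pair(s, s)
  expect_equal(res$segs$status,
               c("dropped_flanking", "matched", "dropped_flanking"))
  expect_equal(res$segs$count_a[2], 2L)
  cells <- res$tab[res$tab$entity == "cell", ]
  expect_equal(nrow(cells), 2L)
  expect_equal(cells$image_uid, cells$plate_uid)
  expect_equal(res$stats$retention_fraction, 1.0)
  expect_equal(res$stats$misassignment_rate, 0.0)
})

test_that("a count mismatch drops the whole gap", {
  a <- make_stream(c("cell", "A", "cell", "cell", "T"))
  b <- make_stream(c("cell", "A", "cell", "T"))   # one cell lost in the gap
  res <- match_pair(a, b)
  expect_equal(res$segs$status[2], "dropped_count_mismatch")
  expect_equal(sum(res$tab$entity == "cell"), 0L)
  expect_equal(res$stats$retention_fraction, 0.0)
})

test_that("an erroneous marker drops its adjacent gaps", {
  # middle marker T missing on the plate side
  a <- make_stream(c("A", "cell", "T", "cell", "C"))
  b <- make_stream(c("A", "cell", "cell", "C"))
  res <- match_pair(a, b)
  interior <- res$segs[!is.na(res$segs$a_left) & !is.na(res$segs$a_right), ]
  expect_true(all(interior$status == "dropped_marker_error"))
  expect_equal(res$stats$retention_fraction, 0.0)
})

test_that("drop_rule 'following' keeps the gap before a mismatched marker", {
  # plate side reads the middle marker as a different symbol (misplaced
  # bead): gap 1 precedes the error, gap 2 follows it
  a <- make_stream(c("A", "cell", "T", "cell", "C"))
  b <- make_stream(c("A", "cell", "A", "cell", "C"))
  both <- match_pair(a, b, drop_rule = "both")
  interior_b <- both$segs[!is.na(both$segs$a_left) &
                            !is.na(both$segs$a_right), ]
  expect_true(all(interior_b$status == "dropped_marker_error"))

  fol <- match_pair(a, b, drop_rule = "following")
  interior_f <- fol$segs[!is.na(fol$segs$a_left) &
                           !is.na(fol$segs$a_right), ]
  expect_equal(interior_f$status,
               c("matched", "dropped_marker_error"))
})

test_that("out-of-focus cells map with usable = FALSE", {
  a <- make_stream(c("A", "cell", "cell", "T"),
                   oof = c(NA, TRUE, FALSE, NA))
  b <- make_stream(c("A", "cell", "cell", "T"))
  res <- match_pair(a, b)
  cells <- res$tab[res$tab$entity == "cell", ]
  expect_equal(cells$usable, c(FALSE, TRUE))
  expect_equal(res$stats$usable_fraction, 0.5)
})

test_that("every interior cell lands in exactly one segment status", {
  set.seed(77)
  for (i in 1:10) {
    g <- generate_stream(60, 2)
    plate <- apply_misplacement(apply_deletion(g, 0.03)$stream, 0.03)$stream
    res <- match_pair(g, plate)
    interior <- res$segs[!is.na(res$segs$a_left) &
                           !is.na(res$segs$a_right), ]
    # the interior gaps partition the interior cells
    expect_equal(sum(interior$count_a),
                 res$stats$n_interior)
    # mapped cells are exactly those of matched segments
    expect_equal(res$stats$n_mapped,
                 sum(interior$count_a[interior$status == "matched"]))
  }
})

test_that("deleting one cell only costs its own gap", {
  g <- generate_stream(40, 2, seed = 101)
  cells <- which(g$kind == "cell")
  victim <- cells[10]
  plate <- g[-victim, , drop = FALSE]
  plate$source_index <- seq_len(nrow(plate))
  res <- match_pair(g, as.data.frame(plate))
  # exactly one interior gap lost (the victim's), everything else mapped
  interior <- res$segs[!is.na(res$segs$a_left) & !is.na(res$segs$a_right), ]
  lost <- interior[interior$status != "matched", ]
  expect_lte(nrow(lost), 1L)
  expect_equal(res$stats$misassignment_rate, 0.0)
  expect_equal(res$stats$n_mapped,
               res$stats$n_interior - sum(lost$count_a))
})

test_that("build_mapping validates its inputs", {
  s <- make_stream(c("cell", "A", "cell", "T"))
  ma <- encode_markers(s)
  aln <- global_align(ma, ma)
  segs <- match_segments(ma, ma, aln, classify_errors(aln))
  expect_error(build_mapping(segs, ma, ma,
                             data.frame(uid = 1L, x = 0, y = 0)),
               "missing plate positions")
  # structurally inconsistent alignment is rejected
  mb <- encode_markers(make_stream(c("A", "T", "C")))
  expect_error(match_segments(ma, mb, aln, classify_errors(aln)),
               "do not match")
})

test_that("dispense_layout lays objects on a serpentine grid", {
  lay <- dispense_layout(7, pitch_x = 10, pitch_y = 20, per_row = 3)
  expect_equal(lay$x, c(0, 10, 20, 20, 10, 0, 0))
  expect_equal(lay$y, c(0, 0, 0, 20, 20, 20, 40))
  lay2 <- dispense_layout(4, pitch_x = 10, pitch_y = 20, per_row = 3,
                          serpentine = FALSE)
  expect_equal(lay2$x, c(0, 10, 20, 0))
})
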