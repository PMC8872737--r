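#' Partition inter-marker gaps into matched and dropped segments
#'
#' Applies the error-isolation drop rules to the aligned marker sequences of
#' the imaging readout (`mseq_a`) and the plate readout (`mseq_b`). A gap
#' between two adjacent imaged markers becomes a verifiable segment only
#' when its flanking markers align as clean, column-adjacent matches; its
#' imaged and plate cell counts are then compared. Statuses:
#'
#' * `matched` — clean flanks and equal cell counts on both sides;
#' * `dropped_count_mismatch` — clean flanks but unequal counts (cells in
#'   the gap were deleted or scrambled, so the whole gap is disregarded);
#' * `dropped_marker_error` — a flanking marker is involved in a reported
#'   deletion/insertion/misplacement, so the cells next to it are skipped;
#' * `dropped_flanking` — the gaps before the first and after the last
#'   marker, which have no verifying marker pair.
#'
#' `drop_rule = "both"` (conservative default) drops the gaps on both sides
#' of an erroneous marker. `drop_rule = "following"` drops only the gap that
#' follows it, keeping the preceding gap when the erroneous marker is at
#' least physically present (a mismatch, not a missing bead) so the gap
#' boundary is still defined.
#'
#' @param mseq_a,mseq_b `marker_sequence` objects for the imaging and plate
#'   readouts.
#' @param alignment Alignment of their symbol tracks from [global_align()].
#' @param report Error report from [classify_errors()] on that alignment.
#' @param drop_rule `"both"` or `"following"`.
#' @return A `segment_table` data frame with columns `gap_a` (index into
#'   `mseq_a$gap_counts`), `a_left`, `a_right`, `b_left`, `b_right` (marker
#'   indices, `NA` where undefined), `count_a`, `count_b` and `status`.
#' @export
match_segments <- function(mseq_a, mseq_b, alignment, report,
                           drop_rule = c("both", "following")) {
  validate_mseq(mseq_a); validate_mseq(mseq_b)
  validate_alignment(alignment)
  drop_rule <- match.arg(drop_rule)
  if (!identical(alignment$a, mseq_a$symbols) ||
      !identical(alignment$b, mseq_b$symbols))
    stop("alignment tracks do not match the two marker sequences",
         call. = FALSE)
  La <- length(mseq_a$symbols)
  ai <- alignment$a_idx; bi <- alignment$b_idx
  col_a <- match(seq_len(La), ai)
  clean <- vapply(seq_len(La), function(i) {
    ci <- col_a[i]
    !is.na(bi[ci]) && alignment$a[i] == alignment$b[bi[ci]]
  }, logical(1))

  rows <- list()
  if (La >= 1L) {
    rows[[length(rows) + 1L]] <- data.frame(
      gap_a = 1L, a_left = NA_integer_, a_right = 1L,
      b_left = NA_integer_, b_right = NA_integer_,
      count_a = mseq_a$gap_counts[1L], count_b = NA_integer_,
      status = "dropped_flanking", stringsAsFactors = FALSE)
  }
  for (g in seq_len(max(La - 1L, 0L))) {
    cL <- col_a[g]; cR <- col_a[g + 1L]
    both_present <- !is.na(bi[cL]) && !is.na(bi[cR])
    adjacent <- cR == cL + 1L
    ok <- adjacent && both_present && clean[g] &&
      (if (drop_rule == "both") clean[g + 1L] else TRUE)
    bL <- if (!is.na(bi[cL])) bi[cL] else NA_integer_
    bR <- if (!is.na(bi[cR])) bi[cR] else NA_integer_
    if (ok) {
      count_a <- mseq_a$gap_counts[g + 1L]
      count_b <- mseq_b$gap_counts[bL + 1L]
      status <- if (count_a == count_b) "matched"
                else "dropped_count_mismatch"
    } else {
      count_a <- mseq_a$gap_counts[g + 1L]
      count_b <- if (adjacent && both_present)
        mseq_b$gap_counts[bL + 1L] else NA_integer_
      status <- "dropped_marker_error"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gap_a = g + 1L, a_left = g, a_right = g + 1L,
      b_left = bL, b_right = bR, count_a = count_a, count_b = count_b,
      status = status, stringsAsFactors = FALSE)
  }
  if (La >= 1L) {
    rows[[length(rows) + 1L]] <- data.frame(
      gap_a = La + 1L, a_left = La, a_right = NA_integer_,
      b_left = NA_integer_, b_right = NA_integer_,
      count_a = mseq_a$gap_counts[La + 1L], count_b = NA_integer_,
      status = "dropped_flanking", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("segment_table", "data.frame")
  out
}

#' Build the image-to-position mapping table
#'
#' Within each matched segment the i-th imaged cell is paired with the i-th
#' plate cell (FIFO within the segment) and receives that object's plate
#' coordinates. Out-of-focus cells are kept in the table — their position in
#' the order is informative — but flagged `usable = FALSE`. Matched marker
#' beads are included as registration anchors.
#'
#' @param segments A `segment_table` from [match_segments()].
#' @param mseq_a,mseq_b The two `marker_sequence` objects.
#' @param plate_positions Data frame with columns `uid`, `x`, `y` giving the
#'   micron coordinates of every plate-side object (see
#'   [dispense_layout()]).
#' @return A `mapping_table` data frame with columns `entity` (`"cell"` or
#'   the marker symbol), `image_uid`, `plate_uid`, `x`, `y`, `usable` and
#'   `segment` (the `gap_a` of the originating segment, `NA` for markers).
#' @export
build_mapping <- function(segments, mseq_a, mseq_b, plate_positions) {
  stopifnot(inherits(segments, "segment_table"))
  validate_mseq(mseq_a); validate_mseq(mseq_b)
  if (!all(c("uid", "x", "y") %in% names(plate_positions)))
    stop("`plate_positions` needs columns uid, x, y", call. = FALSE)
  pos_at <- function(uid) {
    i <- match(uid, plate_positions$uid)
    if (anyNA(i))
      stop("missing plate positions for uid(s): ",
           paste(head(uid[is.na(i)], 5L), collapse = ", "), call. = FALSE)
    plate_positions[i, c("x", "y"), drop = FALSE]
  }
  rows <- list()
  matched <- segments[segments$status == "matched", , drop = FALSE]
  # marker anchors: clean flanking pairs of matched segments
  if (nrow(matched)) {
    mk <- unique(rbind(
      data.frame(a = matched$a_left, b = matched$b_left),
      data.frame(a = matched$a_right, b = matched$b_right)))
    mk <- mk[!is.na(mk$a) & !is.na(mk$b), , drop = FALSE]
    if (nrow(mk)) {
      xy <- pos_at(mseq_b$marker_uids[mk$b])
      rows[[length(rows) + 1L]] <- data.frame(
        entity = mseq_a$symbols[mk$a],
        image_uid = mseq_a$marker_uids[mk$a],
        plate_uid = mseq_b$marker_uids[mk$b],
        x = xy$x, y = xy$y, usable = TRUE, segment = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  for (r in seq_len(nrow(matched))) {
    g <- matched$gap_a[r]
    members_a <- mseq_a$gap_members[[g]]
    oof_a <- mseq_a$gap_oof[[g]]
    members_b <- mseq_b$gap_members[[matched$b_left[r] + 1L]]
    if (length(members_a) != length(members_b))
      stop("matched segment with unequal member counts (corrupt input)",
           call. = FALSE)
    if (!length(members_a)) next
    xy <- pos_at(members_b)
    usable <- if (is.null(oof_a)) rep(TRUE, length(members_a)) else !oof_a
    usable[is.na(usable)] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      entity = "cell", image_uid = members_a, plate_uid = members_b,
      x = xy$x, y = xy$y, usable = usable, segment = g,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(entity = character(0), image_uid = integer(0),
                         plate_uid = integer(0), x = numeric(0),
                         y = numeric(0), usable = logical(0),
                         segment = integer(0), stringsAsFactors = FALSE)
  if (any(!is.finite(out$x)) || any(!is.finite(out$y)))
    stop("non-finite plate positions", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("mapping_table", "data.frame")
  out
}

#' Retention and misassignment statistics for a mapping
#'
#' Quantifies, against simulation ground truth, how much the drop rules
#' cost and how safe the surviving assignments are. The denominator for
#' retention is the imaged cells in interior gaps (the flanking gaps are
#' unverifiable by construction and always dropped).
#'
#' @param table A `mapping_table` from [build_mapping()].
#' @param mseq_a The imaging-side `marker_sequence` (defines the interior
#'   cell population).
#' @param truth Ground-truth pairing: `NULL` (default) for shared-uid
#'   simulations, where the correct plate partner of an imaged cell is the
#'   object with the same `uid`, or a data frame with columns `image_uid`,
#'   `plate_uid`.
#' @return List with `retention_fraction` (mapped / interior imaged cells;
#'   1 when there are no interior cells), `misassignment_rate` (wrongly
#'   paired / mapped; 0 when nothing is mapped), `usable_fraction` (mapped
#'   cells with usable images), `n_mapped` and `n_interior`.
#' @export
retention_stats <- function(table, mseq_a, truth = NULL) {
  stopifnot(inherits(table, "mapping_table"))
  validate_mseq(mseq_a)
  La <- length(mseq_a$symbols)
  interior <- if (La >= 2L)
    unlist(mseq_a$gap_members[2:La], use.names = FALSE) else integer(0)
  cells <- table[table$entity == "cell", , drop = FALSE]
  if (!all(cells$image_uid %in% interior))
    stop("mapping table contains cells outside the interior gaps",
         call. = FALSE)
  retention <- if (length(interior)) nrow(cells) / length(interior) else 1.0
  if (nrow(cells) == 0L) {
    mis <- 0.0
  } else if (is.null(truth)) {
    mis <- mean(cells$image_uid != cells$plate_uid)
  } else {
    want <- truth$plate_uid[match(cells$image_uid, truth$image_uid)]
    if (anyNA(want))
      stop("truth pairing does not cover all mapped cells", call. = FALSE)
    mis <- mean(cells$plate_uid != want)
  }
  usable <- if (nrow(cells)) mean(cells$usable) else 1.0
  list(retention_fraction = retention, misassignment_rate = mis,
       usable_fraction = usable, n_mapped = nrow(cells),
       n_interior = length(interior))
}

#' Serpentine dispensing layout
#'
#' Plate coordinates for objects dispensed in FIFO order: a spacing of
#' `pitch_x` microns along the line of travel, `pitch_y` microns between
#' adjacent lines, with the travel direction reversing on every line
#' (serpentine) as a robotic dispenser scans the membrane.
#'
#' @param stream An `event_stream`, or an integer number of objects.
#' @param pitch_x Spacing along the line of travel, microns.
#' @param pitch_y Spacing between adjacent lines, microns.
#' @param per_row Objects per line.
#' @param serpentine Reverse direction on odd lines.
#' @return Data frame with columns `uid`, `x`, `y` (microns).
#' @export
dispense_layout <- function(stream, pitch_x = 250, pitch_y = 500,
                            per_row = 100, serpentine = TRUE) {
  uid <- if (is.numeric(stream) && length(stream) == 1L)
    seq_len(check_count(stream, "stream", min = 0L))
  else as_event_stream(stream)$uid
  per_row <- check_count(per_row, "per_row")
  i <- seq_along(uid) - 1L
  row <- i %/% per_row
  col <- i %% per_row
  if (serpentine) {
    odd <- row %% 2L == 1L
    col[odd] <- per_row - 1L - col[odd]
  }
  data.frame(uid = uid, x = col * pitch_x, y = row * pitch_y)
}

#' Write a mapping table as CSV
#'
#' Column order mirrors the registration tables used to drive cell pickup:
#' entity, plate position, image reference, then any feature / cluster
#' columns present.
#'
#' @param table A `mapping_table`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_mapping_csv <- function(table, path) {
  stopifnot(inherits(table, "mapping_table"))
  first <- c("entity", "x", "y", "image_uid", "plate_uid", "usable",
             "segment")
  cols <- c(first, setdiff(names(table), first))
  write.csv(as.data.frame(table)[, cols], path, row.names = FALSE,
            na = "")
  invisible(path)
}
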