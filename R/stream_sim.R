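#' Generate a ground-truth FIFO event stream
#'
#' Simulates the ordered stream of cells and marker beads that both
#' instruments observe: the imaging cytometer as it records each object in
#' flow, and the plate reader after the robotic dispenser has placed the same
#' objects on the membrane in first-in-first-out (FIFO) order. Marker beads
#' come in three sizes encoded as the symbols `A`, `T` and `C`; the cells
#' between two markers are the payload that the marker "introns" anchor.
#'
#' Cells are interleaved among the markers uniformly at random (all
#' arrangements of the `n_markers + n_cells` positions equally likely), which
#' makes the number of cells in an inter-marker gap exchangeable with mean
#' `cell_marker_ratio`. At the design ratio of 2:1 the mean interior gap
#' holds 2 cells.
#'
#' @param n_markers Number of marker beads (>= 1).
#' @param cell_marker_ratio Ratio of cells to markers; the stream contains
#'   `round(cell_marker_ratio * n_markers)` cells. The dispensing design uses
#'   2 (two cells per marker bead on average).
#' @param symbol_weights Probabilities for drawing each marker symbol
#'   `A`/`T`/`C` i.i.d.; any non-negative weights, normalized internally.
#' @param p_out_of_focus Probability that a cell's flow image is too blurred
#'   to use ("O" objects). Out-of-focus cells still occupy their position in
#'   the FIFO order; they are flagged, not removed.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#'
#' @return An `event_stream`: a data frame with columns `source_index`
#'   (1-based position in the stream), `uid` (stable identity), `kind`
#'   (`"cell"` or `"marker"`), `symbol` (`A`/`T`/`C` for markers, `NA` for
#'   cells) and `out_of_focus` (logical for cells, `NA` for markers), plus a
#'   `metadata` attribute recording the generation parameters.
#' @examples
#' s <- generate_stream(10, cell_marker_ratio = 2, seed = 1)
#' table(s$kind)
#' @export
generate_stream <- function(n_markers, cell_marker_ratio = 2,
                            symbol_weights = c(A = 1, T = 1, C = 1) / 3,
                            p_out_of_focus = 0, seed = NULL) {
  n_markers <- check_count(n_markers, "n_markers")
  if (!is.numeric(cell_marker_ratio) || length(cell_marker_ratio) != 1L ||
      !is.finite(cell_marker_ratio) || cell_marker_ratio < 0)
    stop("`cell_marker_ratio` must be a single finite non-negative number",
         call. = FALSE)
  if (!is.numeric(symbol_weights) || length(symbol_weights) != 3L ||
      any(!is.finite(symbol_weights)) || any(symbol_weights < 0) ||
      sum(symbol_weights) <= 0)
    stop("`symbol_weights` must be 3 non-negative weights with positive sum",
         call. = FALSE)
  check_prob(p_out_of_focus, "p_out_of_focus")

  n_cells <- as.integer(round(cell_marker_ratio * n_markers))
  n <- n_markers + n_cells
  with_seed(seed, {
    marker_pos <- sort(sample.int(n, n_markers))
    kind <- rep("cell", n)
    kind[marker_pos] <- "marker"
    symbol <- rep(NA_character_, n)
    symbol[marker_pos] <- sample(c("A", "T", "C"), n_markers, replace = TRUE,
                                 prob = symbol_weights / sum(symbol_weights))
    oof <- rep(NA, n)
    oof[kind == "cell"] <- runif(n_cells) < p_out_of_focus
    out <- data.frame(source_index = seq_len(n), uid = seq_len(n),
                      kind = kind, symbol = symbol, out_of_focus = oof,
                      stringsAsFactors = FALSE)
    attr(out, "metadata") <- list(
      n_markers = n_markers, cell_marker_ratio = cell_marker_ratio,
      symbol_weights = unname(symbol_weights / sum(symbol_weights)),
      p_out_of_focus = p_out_of_focus, seed = seed)
    class(out) <- c("event_stream", "data.frame")
    out
  })
}

as_event_stream <- function(df) {
  need <- c("source_index", "uid", "kind", "symbol", "out_of_focus")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event stream is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.unsorted(df$source_index, strictly = TRUE))
    stop("`source_index` must be strictly increasing", call. = FALSE)
  if (anyDuplicated(df$uid))
    stop("`uid` must be unique within a stream", call. = FALSE)
  bad <- df$kind == "marker" & (is.na(df$symbol) |
                                  !df$symbol %in% c("A", "T", "C"))
  if (any(bad))
    stop("marker events must carry a symbol in {A, T, C}", call. = FALSE)
  if (!all(df$kind %in% c("cell", "marker")))
    stop("`kind` must be 'cell' or 'marker'", call. = FALSE)
  class(df) <- c("event_stream", "data.frame")
  df
}

reindex_stream <- function(df, metadata = NULL) {
  rownames(df) <- NULL
  df$source_index <- seq_len(nrow(df))
  if (!is.null(metadata)) attr(df, "metadata") <- metadata
  class(df) <- c("event_stream", "data.frame")
  df
}

#' @export
print.event_stream <- function(x, ...) {
  nm <- sum(x$kind == "marker")
  nc <- sum(x$kind == "cell")
  cat(sprintf("<event_stream> %d events: %d markers, %d cells\n",
              nrow(x), nm, nc))
  if (nm > 0) {
    sy <- table(factor(x$symbol[x$kind == "marker"], c("A", "T", "C")))
    cat(sprintf("  symbols: A=%d T=%d C=%d\n", sy[["A"]], sy[["T"]],
                sy[["C"]]))
  }
  if (nc > 0)
    cat(sprintf("  out-of-focus cells: %d\n",
                sum(x$out_of_focus[x$kind == "cell"])))
  invisible(x)
}

#' Remove events at random (deletion error process)
#'
#' Each event is independently removed with probability `rate`, emulating
#' objects trapped in the fluidics between imaging and dispensing so that
#' they never reach the plate. The surviving events keep their relative FIFO
#' order and are re-indexed 1..k; `uid` preserves identity across the
#' corruption.
#'
#' @param stream An `event_stream`.
#' @param rate Per-event deletion probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return A list with `stream` (the corrupted `event_stream`) and `truth`,
#'   a data frame of ground-truth error records with columns `error_type`
#'   (`"deletion"`), `uid`, `from_index` (position in the input stream) and
#'   `to_index` (`NA` for deletions).
#' @examples
#' s <- generate_stream(20, seed = 1)
#' del <- apply_deletion(s, 0.1, seed = 2)
#' nrow(s) - nrow(del$stream) == nrow(del$truth)
#' @export
apply_deletion <- function(stream, rate, seed = NULL) {
  stream <- as_event_stream(stream)
  check_prob(rate, "rate")
  with_seed(seed, {
    drop <- runif(nrow(stream)) < rate
    truth <- data.frame(
      error_type = rep("deletion", sum(drop)),
      uid = stream$uid[drop],
      from_index = stream$source_index[drop],
      to_index = rep(NA_integer_, sum(drop)),
      stringsAsFactors = FALSE)
    out <- reindex_stream(stream[!drop, , drop = FALSE],
                          metadata = attr(stream, "metadata"))
    list(stream = out, truth = truth)
  })
}

#' Relocate events at random (misplacement error process)
#'
#' Each event is independently selected with probability `rate`; every
#' selected event is removed from its position and re-inserted at a uniformly
#' drawn nonzero offset within `max_shift` positions (clamped to the stream
#' bounds), emulating local order scrambling when laminar flow is disturbed.
#' No event is lost: the output is a permutation of the input.
#'
#' Mechanically, each selected event receives a sort key `target +
#' 0.25*sign(offset)` while unselected events keep their original index, and
#' the stream is stably re-sorted; for sparse selections this reproduces
#' literal remove-and-reinsert, and it remains well defined when moves
#' collide. Selected events whose net position ends up unchanged (possible
#' only through collisions or boundary clamping) introduced no order error
#' and are omitted from the truth records.
#'
#' `max_shift = Inf` gives the long-range variant: the destination is drawn
#' uniformly over the whole stream. This models objects held up for an
#' arbitrary time before re-entering the line rather than local scrambling.
#'
#' @param stream An `event_stream`.
#' @param rate Per-event selection probability in \[0, 1\].
#' @param max_shift Maximum displacement in positions (integer >= 1), or
#'   `Inf` for a uniform random destination.
#' @param seed Optional integer seed.
#' @return A list with `stream` (the permuted `event_stream`, re-indexed)
#'   and `truth`, a data frame with columns `error_type` (`"misplacement"`),
#'   `uid`, `from_index` (position in the input stream) and `to_index`
#'   (position in the output stream).
#' @examples
#' s <- generate_stream(20, seed = 1)
#' mis <- apply_misplacement(s, 0.2, max_shift = 1, seed = 2)
#' setequal(mis$stream$uid, s$uid)
#' @export
apply_misplacement <- function(stream, rate, max_shift = 5, seed = NULL) {
  stream <- as_event_stream(stream)
  check_prob(rate, "rate")
  if (!(identical(max_shift, Inf) ||
        (is.numeric(max_shift) && length(max_shift) == 1L &&
         is.finite(max_shift) && max_shift >= 1 &&
         max_shift == floor(max_shift))))
    stop("`max_shift` must be an integer >= 1, or Inf", call. = FALSE)
  n <- nrow(stream)
  with_seed(seed, {
    sel <- which(runif(n) < rate)
    if (n < 2L) sel <- integer(0)
    key <- as.numeric(seq_len(n))
    if (length(sel)) {
      if (is.infinite(max_shift)) {
        target <- vapply(sel, function(i)
          sample(seq_len(n)[-i], 1L), integer(1))
      } else {
        off <- sample(c(-seq_len(max_shift), seq_len(max_shift)),
                      length(sel), replace = TRUE)
        target <- pmin(pmax(sel + off, 1L), n)
        # clamping at the ends can null the move; push one step inward
        target[target == sel & sel == 1L] <- 2L
        target[target == sel & sel == n] <- n - 1L
      }
      key[sel] <- target + 0.25 * sign(target - sel)
    }
    ord <- order(key, seq_len(n))
    out <- reindex_stream(stream[ord, , drop = FALSE],
                          metadata = attr(stream, "metadata"))
    to_index <- match(stream$uid[sel], out$uid)
    moved <- to_index != sel
    truth <- data.frame(
      error_type = rep("misplacement", sum(moved)),
      uid = stream$uid[sel][moved],
      from_index = stream$source_index[sel][moved],
      to_index = to_index[moved],
      stringsAsFactors = FALSE)
    list(stream = out, truth = truth)
  })
}

# Reconstruct the output of apply_misplacement from its truth records:
# place each moved uid at its recorded to_index and fill the remaining
# slots with the unmoved events in their original order.
replay_misplacement <- function(stream, truth) {
  stream <- as_event_stream(stream)
  n <- nrow(stream)
  out_rows <- integer(n)
  out_rows[truth$to_index] <- match(truth$uid, stream$uid)
  rest <- setdiff(seq_len(n), match(truth$uid, stream$uid))
  out_rows[out_rows == 0L] <- rest
  reindex_stream(stream[out_rows, , drop = FALSE],
                 metadata = attr(stream, "metadata"))
}

#' Read and write event streams as CSV
#'
#' The on-disk format is the five-column CSV
#' `source_index,uid,kind,symbol,out_of_focus`, one row per event in FIFO
#' order; `symbol` is empty for cells and `out_of_focus` empty for markers.
#'
#' @param stream An `event_stream`.
#' @param path File path.
#' @return `read_stream_csv` returns an `event_stream`;
#'   `write_stream_csv` returns `path` invisibly.
#' @export
write_stream_csv <- function(stream, path) {
  stream <- as_event_stream(stream)
  write.csv(as.data.frame(stream)[, c("source_index", "uid", "kind",
                                      "symbol", "out_of_focus")],
            path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_index", "uid", "kind", "symbol", "out_of_focus")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("event stream is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$source_index <- as.integer(df$source_index)
  df$uid <- as.integer(df$uid)
  df$kind <- as.character(df$kind)
  df$symbol <- as.character(df$symbol)
  df$symbol[!is.na(df$symbol) & df$symbol == ""] <- NA_character_
  df$out_of_focus <- as.logical(df$out_of_focus)
  as_event_stream(df)
}
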