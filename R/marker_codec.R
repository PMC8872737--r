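#' Encode an event stream as a marker sequence with inter-marker cell counts
#'
#' Converts the discrete event log into the representation the matching
#' stage works on: the string of marker symbols in stream order ("introns")
#' plus, for each of the `L + 1` gaps (before the first marker, between each
#' adjacent pair, after the last), the ordered cells it contains ("exons").
#' The two flanking gaps have no verifying marker pair on one side and are
#' flagged unverifiable; the mapping stage always drops them.
#'
#' @param stream An `event_stream`.
#' @return A `marker_sequence`: a list with `symbols` (character vector over
#'   `A`/`T`/`C`), `marker_uids`, `gap_counts` (integer, length
#'   `length(symbols) + 1`), `gap_members` (list of cell uid vectors),
#'   `gap_oof` (list of logical out-of-focus flags parallel to
#'   `gap_members`) and `gap_oof_counts`.
#' @examples
#' s <- generate_stream(5, seed = 1)
#' m <- encode_markers(s)
#' sum(m$gap_counts) == sum(s$kind == "cell")
#' @export
encode_markers <- function(stream) {
  stream <- as_event_stream(stream)
  mk <- stream$kind == "marker"
  mpos <- which(mk)
  cpos <- which(!mk)
  L <- length(mpos)
  gap_of_cell <- findInterval(cpos, mpos) + 1L  # gap 1 precedes marker 1
  gap_members <- lapply(seq_len(L + 1L), function(g)
    stream$uid[cpos[gap_of_cell == g]])
  gap_oof <- lapply(seq_len(L + 1L), function(g)
    stream$out_of_focus[cpos[gap_of_cell == g]])
  out <- list(symbols = stream$symbol[mpos],
              marker_uids = stream$uid[mpos],
              gap_counts = lengths(gap_members),
              gap_members = gap_members,
              gap_oof = gap_oof,
              gap_oof_counts = vapply(gap_oof, function(z)
                sum(z, na.rm = TRUE), integer(1)))
  class(out) <- "marker_sequence"
  out
}

validate_mseq <- function(m) {
  if (!inherits(m, "marker_sequence")) stop("not a marker_sequence",
                                            call. = FALSE)
  L <- length(m$symbols)
  if (length(m$gap_counts) != L + 1L)
    stop("gap_counts must have length(symbols) + 1 entries", call. = FALSE)
  if (!identical(as.integer(m$gap_counts),
                 as.integer(lengths(m$gap_members))))
    stop("gap_counts inconsistent with gap_members", call. = FALSE)
  if (!all(m$symbols %in% c("A", "T", "C")))
    stop("symbols must be over {A, T, C}", call. = FALSE)
  invisible(m)
}

#' Decode a marker sequence back into an event stream
#'
#' Inverse of [encode_markers()]: rebuilds the event log whose encoding is
#' `mseq`. Kind, symbol, order, cell uids and out-of-focus flags round-trip
#' exactly.
#'
#' @param mseq A `marker_sequence`.
#' @return An `event_stream`.
#' @export
decode_markers <- function(mseq) {
  validate_mseq(mseq)
  L <- length(mseq$symbols)
  marker_uids <- mseq$marker_uids
  if (is.null(marker_uids)) {
    used <- unlist(mseq$gap_members, use.names = FALSE)
    marker_uids <- setdiff(seq_len(L + length(used) + L), used)[seq_len(L)]
  }
  kind <- character(0); symbol <- character(0)
  uid <- integer(0); oof <- logical(0)
  for (g in seq_len(L + 1L)) {
    k <- mseq$gap_counts[g]
    uid <- c(uid, mseq$gap_members[[g]])
    kind <- c(kind, rep("cell", k))
    symbol <- c(symbol, rep(NA_character_, k))
    fl <- mseq$gap_oof[[g]]
    if (is.null(fl)) fl <- rep(FALSE, k)
    oof <- c(oof, fl)
    if (g <= L) {
      uid <- c(uid, marker_uids[g])
      kind <- c(kind, "marker")
      symbol <- c(symbol, mseq$symbols[g])
      oof <- c(oof, NA)
    }
  }
  as_event_stream(data.frame(source_index = seq_along(uid), uid = uid,
                             kind = kind, symbol = symbol,
                             out_of_focus = oof, stringsAsFactors = FALSE))
}

#' @export
print.marker_sequence <- function(x, ...) {
  L <- length(x$symbols)
  cat(sprintf("<marker_sequence> %d markers, %d cells\n", L,
              sum(x$gap_counts)))
  cat("  symbols: ", paste(x$symbols, collapse = ""), "\n", sep = "")
  cat("  gap counts: ", paste(x$gap_counts, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.marker_sequence <- function(x, ...)
  paste(x$symbols, collapse = "")

#' Serialize marker sequences
#'
#' `write_mseq_json`/`read_mseq_json` round-trip the full structure through
#' JSON. `write_mseq_fasta` exports the symbol string as a single FASTA
#' record (the alphabet is DNA-compatible) so external alignment tools can
#' be used for cross-checks; it uses Biostrings when available and plain
#' text otherwise.
#'
#' @param mseq A `marker_sequence`.
#' @param path File path.
#' @param name FASTA record name.
#' @return The path, invisibly (writers); a `marker_sequence` (reader).
#' @export
write_mseq_json <- function(mseq, path) {
  validate_mseq(mseq)
  jsonlite::write_json(unclass(mseq), path, auto_unbox = FALSE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_mseq_json
#' @export
read_mseq_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  L <- length(raw$symbols)
  fix_list <- function(z, cast) {
    if (is.null(z)) return(rep(list(cast(integer(0))), L + 1L))
    z <- as.list(z)
    lapply(z, function(v) if (is.null(v) || length(v) == 0) cast(integer(0))
           else cast(v))
  }
  out <- list(symbols = as.character(raw$symbols),
              marker_uids = as.integer(raw$marker_uids),
              gap_counts = as.integer(raw$gap_counts),
              gap_members = fix_list(raw$gap_members, as.integer),
              gap_oof = fix_list(raw$gap_oof, as.logical),
              gap_oof_counts = as.integer(raw$gap_oof_counts))
  class(out) <- "marker_sequence"
  validate_mseq(out)
  out
}

#' @rdname write_mseq_json
#' @export
write_mseq_fasta <- function(mseq, path, name = "markers") {
  validate_mseq(mseq)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(as.character(mseq))
    names(x) <- name
    Biostrings::writeXStringSet(x, path)
  } else {
    writeLines(c(paste0(">", name), as.character(mseq)), path)
  }
  invisible(path)
}

#' Write ground-truth error records as JSON lines
#'
#' @param truth A truth data frame from [apply_deletion()] or
#'   [apply_misplacement()].
#' @param path File path.
#' @return The path invisibly; `read_truth_jsonl` returns the data frame.
#' @export
write_truth_jsonl <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(truth)))
    writeLines(jsonlite::toJSON(as.list(truth[i, ]), auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  invisible(path)
}

#' @rdname write_truth_jsonl
#' @export
read_truth_jsonl <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    return(data.frame(error_type = character(0), uid = integer(0),
                      from_index = integer(0), to_index = integer(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    data.frame(error_type = x$error_type, uid = x$uid,
               from_index = x$from_index,
               to_index = if (is.null(x$to_index)) NA_integer_
                          else x$to_index,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
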