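#' Scoring scheme for global marker-sequence alignment
#'
#' Linear (per-symbol) gap penalties. The defaults, match +5 / mismatch -4 /
#' gap -8, mirror the NUC44 substitution values and default gap penalty of
#' the classic nucleotide global aligners that this marker matching is
#' modeled on; bead losses are treated as independent events, so no affine
#' gap-open/extend distinction is made.
#'
#' @param match Score for an identical symbol pair (must exceed `mismatch`).
#' @param mismatch Score for a differing symbol pair.
#' @param gap Per-symbol gap penalty (must be negative).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 5, mismatch = -4, gap = -8) {
  stopifnot(is.numeric(match), is.numeric(mismatch), is.numeric(gap),
            length(match) == 1L, length(mismatch) == 1L, length(gap) == 1L,
            is.finite(match), is.finite(mismatch), is.finite(gap))
  if (!(match > mismatch)) stop("`match` must exceed `mismatch`",
                                call. = FALSE)
  if (!(gap < 0)) stop("`gap` must be negative", call. = FALSE)
  structure(list(match = match, mismatch = mismatch, gap = gap),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> match %+g, mismatch %+g, gap %+g (linear)\n",
              x$match, x$mismatch, x$gap))
  invisible(x)
}

as_symbols <- function(x, alphabet = c("A", "T", "C")) {
  if (inherits(x, "marker_sequence")) x <- x$symbols
  if (is.character(x) && length(x) == 1L && (nchar(x) > 1L || nchar(x) == 0L))
    x <- strsplit(x, "")[[1]]
  x <- as.character(x)
  bad <- !x %in% alphabet
  if (any(bad))
    stop("symbols outside the alphabet {", paste(alphabet, collapse = ", "),
         "}: ", paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  x
}

#' Globally align two marker-symbol sequences
#'
#' Maximum-score global (Needleman-Wunsch) alignment with linear gap
#' penalties, computed by dynamic programming in C. The traceback tie-break
#' is fixed (diagonal, then gap-in-second, then gap-in-first), so the result
#' is deterministic. For long sequences the DP is restricted to a diagonal
#' band; the band half-width starts at
#' `max(64, |n - m| + 4 * sqrt(min(n, m)))` and is doubled until the optimal
#' path no longer touches the band boundary, so the returned alignment is
#' the unrestricted optimum.
#'
#' @param seq_a,seq_b Symbol sequences over `{A, T, C}`: character vectors,
#'   single strings, or `marker_sequence` objects. Either may be empty.
#' @param scoring A [scoring_scheme()].
#' @param band `NULL` (automatic: full matrix for small problems, verified
#'   band otherwise), a positive integer half-width to start from, or `-1`
#'   to force the full matrix.
#' @return An `alignment`: list with `a`, `b` (the input symbol vectors),
#'   `a_idx`, `b_idx` (1-based index of the consumed symbol per alignment
#'   column, `NA` at gaps), `score`, and the `scoring` used.
#' @examples
#' aln <- global_align("ATC", "AC")
#' aln$score
#' print(aln)
#' @export
global_align <- function(seq_a, seq_b, scoring = scoring_scheme(),
                         band = NULL) {
  a <- as_symbols(seq_a)
  b <- as_symbols(seq_b)
  stopifnot(inherits(scoring, "scoring_scheme"))
  ca <- match(a, c("A", "T", "C"))
  cb <- match(b, c("A", "T", "C"))
  n <- length(a); m <- length(b)
  if (is.null(band)) {
    band <- if ((n + 1) * (m + 1) <= 4e6) -1L
            else max(64L, abs(n - m) + as.integer(ceiling(4 * sqrt(min(n, m)))))
  }
  band <- as.integer(band)
  repeat {
    res <- .nw_align_c(ca, cb, scoring$match, scoring$mismatch,
                       scoring$gap, band)
    if (band < 0 || !res$band_hit || band >= max(n, m)) break
    band <- band * 2L
  }
  out <- list(a = a, b = b, a_idx = res$ai, b_idx = res$bi,
              score = res$score, scoring = scoring,
              band = if (band < 0) NA_integer_ else band)
  class(out) <- "alignment"
  out
}

validate_alignment <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  ai <- aln$a_idx; bi <- aln$b_idx
  if (any(is.na(ai) & is.na(bi)))
    stop("alignment has an all-gap column", call. = FALSE)
  if (!identical(ai[!is.na(ai)], seq_along(aln$a)))
    stop("gap-projection violated on track a", call. = FALSE)
  if (!identical(bi[!is.na(bi)], seq_along(aln$b)))
    stop("gap-projection violated on track b", call. = FALSE)
  invisible(aln)
}

#' Render an alignment as pairwise text
#'
#' Three-line blocks (first sequence / consensus marks / second sequence):
#' `|` marks a match, `.` a mismatch, a space a gap — the consensus-map view
#' used to eyeball where the two instrument readouts disagree.
#'
#' @param aln An `alignment`.
#' @param width Columns per block.
#' @return Character vector of lines.
#' @export
alignment_text <- function(aln, width = 60) {
  validate_alignment(aln)
  ta <- ifelse(is.na(aln$a_idx), "-", aln$a[aln$a_idx])
  tb <- ifelse(is.na(aln$b_idx), "-", aln$b[aln$b_idx])
  mk <- ifelse(is.na(aln$a_idx) | is.na(aln$b_idx), " ",
               ifelse(ta == tb, "|", "."))
  n <- length(ta)
  lines <- character(0)
  for (s in seq(1L, max(n, 1L), by = width)) {
    e <- min(s + width - 1L, n)
    if (s > e) break
    lines <- c(lines,
               paste0(ta[s:e], collapse = ""),
               paste0(mk[s:e], collapse = ""),
               paste0(tb[s:e], collapse = ""), "")
  }
  lines
}

#' @export
print.alignment <- function(x, width = 60, ...) {
  nmatch <- sum(!is.na(x$a_idx) & !is.na(x$b_idx) &
                  x$a[pmax(x$a_idx, 1)] == x$b[pmax(x$b_idx, 1)], na.rm = TRUE)
  cat(sprintf("<alignment> %d x %d symbols, %d columns, score %g\n",
              length(x$a), length(x$b), length(x$a_idx), x$score))
  if (length(x$a_idx) <= 300)
    cat(alignment_text(x, width), sep = "\n")
  else
    cat("  (use alignment_text() to render)\n")
  invisible(x)
}

# Ambiguity region of a gapped symbol: the maximal homopolymer run of `sym`
# containing position p in symbol vector `s` (a gap inside a run is only
# localizable to the run). Positions in `skip` (other gapped symbols of the
# same alignment) are stepped over when extending: once those symbols are
# absent from the other readout, the runs they separated merge into one
# ambiguity region.
run_region <- function(s, p, sym, skip = integer(0)) {
  l <- p; r <- p
  j <- p - 1L
  while (j >= 1L) {
    if (s[j] == sym) { l <- j; j <- j - 1L }
    else if (j %in% skip) j <- j - 1L
    else break
  }
  j <- r + 1L
  while (j <= length(s)) {
    if (s[j] == sym) { r <- j; j <- j + 1L }
    else if (j %in% skip) j <- j + 1L
    else break
  }
  c(l, r)
}

# Reported positions for a set of gapped symbols at positions `pos` in
# symbol vector `s`. The true origin of a gap is uniform over its ambiguity
# region, so g gaps sharing one region are reported at the rounded g-tiles
# l + (r - l) * (2i - 1) / (2g), which spreads the reports to minimize the
# worst-case distance to any admissible true position (the single-gap case
# reduces to the region midpoint).
site_positions <- function(s, pos) {
  if (!length(pos)) return(numeric(0))
  regs <- t(vapply(seq_along(pos), function(i)
    run_region(s, pos[i], s[pos[i]], skip = pos[-i]), numeric(2)))
  out <- numeric(length(pos))
  key <- paste(regs[, 1], regs[, 2], s[pos])
  for (kk in unique(key)) {
    id <- which(key == kk)
    id <- id[order(pos[id])]
    l <- regs[id[1], 1]; r <- regs[id[1], 2]; g <- length(id)
    out[id] <- round(l + (r - l) * (2 * seq_len(g) - 1) / (2 * g))
  }
  out
}

# template (track-a) coordinate for every column: the consumed a index, or
# halfway between the surrounding a indices for insertion columns.
col_a_coord <- function(aln) {
  ai <- aln$a_idx
  prog <- cummax(ifelse(is.na(ai), 0L, ai))
  ifelse(is.na(ai), prog + 0.5, as.numeric(ai))
}

# map positions in sequence b to template (a) coordinates via the alignment
b_to_a_map <- function(aln) {
  coord <- col_a_coord(aln)
  out <- numeric(length(aln$b))
  keep <- !is.na(aln$b_idx)
  out[aln$b_idx[keep]] <- coord[keep]
  out
}

#' Classify alignment discrepancies as deletion, insertion or misplacement
#'
#' Walks the consensus map of an alignment between the imaging-side sequence
#' (track a, the template) and the plate-side sequence (track b) and turns
#' every gap or mismatch column into exactly one error record:
#'
#' * a symbol over a gap in track b is a candidate deletion (bead imaged,
#'   missing on the plate); a gap over a symbol is a candidate insertion;
#' * adjacent complementary mismatch columns `(x,y)(y,x)` merge into one
#'   misplacement (a local transposition);
#' * a candidate deletion and insertion of the same symbol within
#'   `pair_window` columns merge into one misplacement (bead removed here,
#'   re-surfaced there);
#' * remaining isolated mismatches are reported as misplacements; remaining
#'   unpaired candidates keep class deletion / insertion.
#'
#' Gap positions inside a homopolymer run are reported at the run midpoint:
#' which symbol of the run was lost is not identifiable, and the midpoint
#' minimizes the worst-case localization error.
#'
#' @param alignment An `alignment` from [global_align()].
#' @param pair_window Maximum column separation for merging a deletion /
#'   insertion pair into a misplacement.
#' @return An `error_report` data frame with columns `error_class`
#'   (`deletion`, `insertion`, `misplacement`), `pos_a` (template
#'   coordinate, possibly half-integer), `pos_b`, `site2_a` (template
#'   coordinate of the second site of a misplacement, `NA` otherwise),
#'   `symbol` and `col` (alignment column).
#' @examples
#' rep <- classify_errors(global_align("ATC", "AC"))
#' rep$error_class
#' @export
classify_errors <- function(alignment, pair_window = 10) {
  validate_alignment(alignment)
  pair_window <- check_count(pair_window, "pair_window")
  a <- alignment$a; b <- alignment$b
  ai <- alignment$a_idx; bi <- alignment$b_idx
  coord <- col_a_coord(alignment)

  empty <- data.frame(error_class = character(0), pos_a = numeric(0),
                      pos_b = numeric(0), site2_a = numeric(0),
                      symbol = character(0), col = integer(0),
                      stringsAsFactors = FALSE)
  type <- ifelse(is.na(bi), "del",
                 ifelse(is.na(ai), "ins",
                        ifelse(a[pmax(ai, 1)] == b[pmax(bi, 1)],
                               "match", "mism")))
  out <- empty

  add <- function(cls, pos_a, pos_b, site2, sym, col) {
    rbind(out, data.frame(error_class = cls, pos_a = pos_a, pos_b = pos_b,
                          site2_a = site2, symbol = sym, col = col,
                          stringsAsFactors = FALSE))
  }

  # complementary adjacent mismatch pairs -> transposition misplacement
  mis_cols <- which(type == "mism")
  used_mism <- logical(length(mis_cols))
  k <- 1L
  while (k < length(mis_cols)) {
    c1 <- mis_cols[k]; c2 <- mis_cols[k + 1L]
    if (!used_mism[k] && c2 == c1 + 1L &&
        a[ai[c1]] == b[bi[c2]] && b[bi[c1]] == a[ai[c2]]) {
      out <- add("misplacement", coord[c1], as.numeric(bi[c1]),
                 coord[c2], a[ai[c1]], c1)
      used_mism[k] <- used_mism[k + 1L] <- TRUE
      k <- k + 2L
    } else k <- k + 1L
  }

  # deletion / insertion candidates
  del_cols <- which(type == "del")
  ins_cols <- which(type == "ins")
  del_pos <- ai[del_cols]
  ins_pos <- bi[ins_cols]
  del_site <- site_positions(a, del_pos)          # template coordinates
  ins_site_b <- site_positions(b, ins_pos)        # b coordinates
  del_used <- logical(length(del_cols))
  ins_used <- logical(length(ins_cols))
  if (length(del_cols) && length(ins_cols)) {
    cand <- expand.grid(d = seq_along(del_cols), i = seq_along(ins_cols))
    cand$dist <- abs(del_cols[cand$d] - ins_cols[cand$i])
    cand <- cand[cand$dist <= pair_window, , drop = FALSE]
    cand <- cand[a[ai[del_cols[cand$d]]] == b[bi[ins_cols[cand$i]]], ,
                 drop = FALSE]
    cand <- cand[order(cand$dist, del_cols[cand$d]), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      d <- cand$d[r]; i <- cand$i[r]
      if (del_used[d] || ins_used[i]) next
      dc <- del_cols[d]; ic <- ins_cols[i]
      sym <- a[ai[dc]]
      p_del <- del_site[d]
      # insertion site in b coordinates, mapped to template coordinates
      p_ins <- coord[ic] + (ins_site_b[i] - bi[ic])
      out <- add("misplacement", p_del, as.numeric(bi[ic]), p_ins, sym, dc)
      del_used[d] <- ins_used[i] <- TRUE
    }
  }

  # residual isolated mismatches -> single-site misplacement
  for (k in which(!used_mism)) {
    c1 <- mis_cols[k]
    out <- add("misplacement", coord[c1], as.numeric(bi[c1]), NA_real_,
               a[ai[c1]], c1)
  }
  # residual unpaired candidates
  for (d in which(!del_used)) {
    dc <- del_cols[d]
    out <- add("deletion", del_site[d], NA_real_, NA_real_, a[ai[dc]], dc)
  }
  for (i in which(!ins_used)) {
    ic <- ins_cols[i]
    out <- add("insertion", coord[ic] + (ins_site_b[i] - bi[ic]),
               as.numeric(bi[ic]), NA_real_, b[bi[ic]], ic)
  }

  out <- out[order(out$col), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("error_report", "data.frame")
  out
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> %d error(s)", nrow(x)))
  if (nrow(x)) {
    tb <- table(x$error_class)
    cat(": ", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
        sep = "")
  }
  cat("\n")
  if (nrow(x)) print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Score an error report against ground truth
#'
#' A true error counts as detected when the report contains any error whose
#' template-coordinate position lies within `tolerance` symbols of the true
#' site; for misplacements either the removal or the reinsertion site may be
#' hit. Truth positions must already be expressed in the template (track-a)
#' coordinate system — `from_index` for the removal site and, when present
#' and non-missing, `to_index` for the reinsertion site (callers aligning a
#' corrupted sequence can map its coordinates through the alignment first).
#'
#' @param truth Data frame of ground-truth errors (`error_type`,
#'   `from_index`, optional `to_index`), in template coordinates.
#' @param report An `error_report` from [classify_errors()].
#' @param tolerance Non-negative localization tolerance in symbols.
#' @return List with `detected` (logical per truth row),
#'   `detection_probability` (defined as 1 when there are no true errors),
#'   `n_errors` and `tolerance`.
#' @export
match_truth <- function(truth, report, tolerance = 2) {
  if (!is.numeric(tolerance) || length(tolerance) != 1L ||
      !is.finite(tolerance) || tolerance < 0)
    stop("`tolerance` must be a single non-negative number", call. = FALSE)
  n <- nrow(truth)
  if (n == 0L)
    return(list(detected = logical(0), detection_probability = 1.0,
                n_errors = 0L, tolerance = tolerance))
  rpts <- sort(c(report$pos_a[!is.na(report$pos_a)],
                 report$site2_a[!is.na(report$site2_a)]))
  near <- function(p) {
    if (!length(rpts) || is.na(p)) return(FALSE)
    i <- findInterval(p, rpts)
    lo <- if (i >= 1L) abs(p - rpts[i]) else Inf
    hi <- if (i < length(rpts)) abs(rpts[i + 1L] - p) else Inf
    min(lo, hi) <= tolerance
  }
  site2 <- if ("to_index" %in% names(truth)) truth$to_index
           else rep(NA_real_, n)
  detected <- vapply(seq_len(n), function(i)
    near(truth$from_index[i]) || near(site2[i]), logical(1))
  list(detected = detected, detection_probability = mean(detected),
       n_errors = n, tolerance = tolerance)
}

#' Export an alignment as JSON
#'
#' @param aln An `alignment`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_alignment_json <- function(aln, path) {
  validate_alignment(aln)
  jsonlite::write_json(list(a = aln$a, b = aln$b, a_idx = aln$a_idx,
                            b_idx = aln$b_idx, score = aln$score,
                            scoring = unclass(aln$scoring)),
                       path, auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}
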