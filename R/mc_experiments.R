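#' Monte Carlo detection probability versus error rate
#'
#' Reproduces the simulation design behind the error-detection study: a
#' random template sequence of `n_symbols` marker symbols over `{A, T, C}`
#' is corrupted by the chosen error process at each rate, the corrupted
#' sequence is globally aligned back to the template, the discrepancies are
#' classified, and an injected error counts as detected when the report
#' localizes an error within `tolerance` symbols of its true site (either
#' site, for misplacements). Results are averaged over seeded replicates.
#'
#' Misplacement displacements are drawn uniformly from the nonzero offsets
#' within `max_shift` positions (see [apply_misplacement()]); any quoted
#' misplacement detection probability is conditional on that displacement
#' model and on `tolerance`, and both are carried in the returned object.
#' Note that a local move whose path crosses only symbols identical to the
#' moved one leaves the sequence unchanged and is undetectable in principle;
#' under uniform symbol weights and `max_shift = 5` this caps misplacement
#' detection near 0.90 (see the package vignette).
#'
#' @param error_kind `"deletion"`, `"misplacement"` or `"both"` (both
#'   processes applied at the given rate, deletion first).
#' @param rates Error rates to sweep.
#' @param n_symbols Template length (the headline study uses 10,000).
#' @param replicates Monte Carlo replicates per rate.
#' @param scoring A [scoring_scheme()].
#' @param tolerance Localization tolerance in symbols.
#' @param max_shift Misplacement displacement bound (or `Inf`).
#' @param seed Optional integer seed.
#' @return A `detection_curve` data frame with columns `error_kind`, `rate`,
#'   `detection_probability`, `sd`, `se`, `n_errors` (mean injected errors
#'   per replicate), `replicates`, `n_symbols`, `tolerance`.
#' @examples
#' detection_curve("deletion", rates = 0.05, n_symbols = 300,
#'                 replicates = 2, seed = 1)
#' @export
detection_curve <- function(error_kind = c("deletion", "misplacement",
                                           "both"),
                            rates = c(0.005, 0.01, 0.02, 0.05, 0.10),
                            n_symbols = 10000, replicates = 20,
                            scoring = scoring_scheme(), tolerance = 2,
                            max_shift = 5, seed = NULL) {
  error_kind <- match.arg(error_kind)
  for (r in rates) check_prob(r, "rates")
  n_symbols <- check_count(n_symbols, "n_symbols")
  replicates <- check_count(replicates, "replicates")
  with_seed(seed, {
    rows <- lapply(rates, function(rate) {
      probs <- numeric(replicates)
      nerr <- numeric(replicates)
      for (rep_i in seq_len(replicates)) {
        res <- run_detection_once(rate, error_kind, n_symbols, scoring,
                                  tolerance, max_shift)
        probs[rep_i] <- res$detection_probability
        nerr[rep_i] <- res$n_errors
      }
      data.frame(error_kind = error_kind, rate = rate,
                 detection_probability = mean(probs),
                 sd = stats::sd(probs),
                 se = stats::sd(probs) / sqrt(replicates),
                 n_errors = mean(nerr), replicates = replicates,
                 n_symbols = n_symbols, tolerance = tolerance,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "max_shift") <- max_shift
    attr(out, "scoring") <- scoring
    attr(out, "seed") <- seed
    class(out) <- c("detection_curve", "data.frame")
    out
  })
}

# one replicate of the symbol-level error-detection experiment
run_detection_once <- function(rate, error_kind, n_symbols, scoring,
                               tolerance, max_shift) {
  template <- generate_stream(n_symbols, cell_marker_ratio = 0)
  truths <- list()
  cur <- template
  if (error_kind %in% c("deletion", "both")) {
    z <- apply_deletion(cur, rate)
    # deletion truth is already in template coordinates
    truths$del <- z$truth
    cur <- z$stream
  }
  if (error_kind %in% c("misplacement", "both")) {
    z <- apply_misplacement(cur, rate, max_shift = max_shift)
    t2 <- z$truth
    # positions recorded in the intermediate stream; express the removal
    # site in template coordinates via the uid
    t2$from_index <- match(t2$uid, template$uid)
    truths$mis <- t2
    cur <- z$stream
  }
  aln <- global_align(encode_markers(template), encode_markers(cur),
                      scoring = scoring)
  report <- classify_errors(aln)
  truth <- do.call(rbind, truths)
  if (is.null(truth) || nrow(truth) == 0L)
    return(list(detection_probability = 1.0, n_errors = 0L))
  # reinsertion sites live in corrupted coordinates; map them through the
  # alignment into template coordinates
  bmap <- b_to_a_map(aln)
  has_to <- !is.na(truth$to_index)
  truth$to_index[has_to] <- bmap[truth$to_index[has_to]]
  mt <- match_truth(truth, report, tolerance = tolerance)
  list(detection_probability = mt$detection_probability,
       n_errors = mt$n_errors)
}

#' @export
print.detection_curve <- function(x, ...) {
  cat(sprintf("<detection_curve> %s, n_symbols=%d, %d replicate(s)\n",
              paste(unique(x$error_kind), collapse = "+"),
              x$n_symbols[1], x$replicates[1]))
  print.data.frame(as.data.frame(
    x[, c("rate", "detection_probability", "se", "n_errors")]),
    row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.detection_curve <- function(x, ...) {
  graphics::plot(x$rate, x$detection_probability, type = "b", pch = 19,
                 ylim = c(0, 1), xlab = "error rate",
                 ylab = "detection probability",
                 main = paste("Error detection:",
                              paste(unique(x$error_kind), collapse = "+")),
                 ...)
  graphics::arrows(x$rate, x$detection_probability - x$se, x$rate,
                   x$detection_probability + x$se, angle = 90, code = 3,
                   length = 0.03)
  invisible(x)
}

#' Cell retention and misassignment versus error rate
#'
#' Runs the full pipeline per replicate — stream generation, plate-side
#' corruption (deletion then misplacement applied to all events, cells and
#' markers alike), sequence encoding, alignment, error classification,
#' segment matching and mapping — and averages [retention_stats()] across
#' replicates for each `(deletion_rate, misplacement_rate)` pair. Rates are
#' recycled to a common length.
#'
#' @param deletion_rates,misplacement_rates Paired per-event rates.
#' @param n_markers Markers per simulated run.
#' @param cell_marker_ratio Cells per marker (design value 2).
#' @param replicates Replicates per rate pair.
#' @param p_out_of_focus Out-of-focus probability for generated cells.
#' @param max_shift Misplacement displacement bound.
#' @param drop_rule Passed to [match_segments()].
#' @param scoring A [scoring_scheme()].
#' @param seed Optional integer seed.
#' @return A `retention_curve` data frame with per-pair means of retention,
#'   misassignment and usable fractions (plus their standard errors).
#' @examples
#' retention_curve(0, 0, n_markers = 50, replicates = 2, seed = 1)
#' @export
retention_curve <- function(deletion_rates, misplacement_rates = 0,
                            n_markers = 1000, cell_marker_ratio = 2,
                            replicates = 20, p_out_of_focus = 0,
                            max_shift = 5, drop_rule = "both",
                            scoring = scoring_scheme(), seed = NULL) {
  k <- max(length(deletion_rates), length(misplacement_rates))
  dr <- rep_len(deletion_rates, k)
  mr <- rep_len(misplacement_rates, k)
  for (r in c(dr, mr)) check_prob(r, "rates")
  replicates <- check_count(replicates, "replicates")
  with_seed(seed, {
    rows <- lapply(seq_len(k), function(i) {
      ret <- mis <- usa <- numeric(replicates)
      for (rep_i in seq_len(replicates)) {
        st <- run_pipeline_once(dr[i], mr[i], n_markers, cell_marker_ratio,
                                p_out_of_focus, max_shift, drop_rule,
                                scoring)
        ret[rep_i] <- st$retention_fraction
        mis[rep_i] <- st$misassignment_rate
        usa[rep_i] <- st$usable_fraction
      }
      data.frame(deletion_rate = dr[i], misplacement_rate = mr[i],
                 retention = mean(ret), retention_se = stats::sd(ret) /
                   sqrt(replicates),
                 misassignment = mean(mis), misassignment_se =
                   stats::sd(mis) / sqrt(replicates),
                 usable_fraction = mean(usa), replicates = replicates,
                 n_markers = n_markers, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "seed") <- seed
    class(out) <- c("retention_curve", "data.frame")
    out
  })
}

# one full-pipeline replicate; returns retention_stats()
run_pipeline_once <- function(deletion_rate, misplacement_rate, n_markers,
                              cell_marker_ratio, p_out_of_focus, max_shift,
                              drop_rule, scoring) {
  truth_stream <- generate_stream(n_markers, cell_marker_ratio,
                                  p_out_of_focus = p_out_of_focus)
  plate <- apply_deletion(truth_stream, deletion_rate)$stream
  plate <- apply_misplacement(plate, misplacement_rate,
                              max_shift = max_shift)$stream
  mseq_a <- encode_markers(truth_stream)
  mseq_b <- encode_markers(plate)
  if (!length(mseq_b$symbols))
    return(list(retention_fraction = 0, misassignment_rate = 0,
                usable_fraction = 1, n_mapped = 0L, n_interior = NA))
  aln <- global_align(mseq_a, mseq_b, scoring = scoring)
  report <- classify_errors(aln)
  segs <- match_segments(mseq_a, mseq_b, aln, report,
                         drop_rule = drop_rule)
  positions <- dispense_layout(plate)
  tab <- build_mapping(segs, mseq_a, mseq_b, positions)
  retention_stats(tab, mseq_a)
}

#' Write a detection or retention curve as CSV
#'
#' @param curve A `detection_curve` or `retention_curve`.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
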