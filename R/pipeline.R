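#' Run configuration
#'
#' One bag of parameters driving the matching pipeline and the simulation
#' experiments, serializable to YAML/JSON and echoed (with a content hash)
#' into every output artifact for provenance.
#'
#' @param seed Integer seed recorded in every artifact.
#' @param match,mismatch,gap Alignment scores (see [scoring_scheme()]).
#' @param pair_window Deletion/insertion pairing window
#'   ([classify_errors()]).
#' @param tolerance Localization tolerance in symbols ([match_truth()]).
#' @param drop_rule `"both"` or `"following"` ([match_segments()]).
#' @param deletion_rate,misplacement_rate Error rates for pipeline
#'   simulation.
#' @param max_shift Misplacement displacement bound.
#' @param rates Rate sweep for Monte Carlo curves.
#' @param n_symbols Symbol-sequence length for detection curves.
#' @param n_markers Markers per pipeline simulation.
#' @param cell_marker_ratio Cells per marker.
#' @param replicates Monte Carlo replicates.
#' @param pitch_x,pitch_y,per_row Dispensing layout ([dispense_layout()]).
#' @param k,n_init k-means settings.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, match = 5, mismatch = -4, gap = -8,
                       pair_window = 10, tolerance = 2,
                       drop_rule = "both", deletion_rate = 0.01,
                       misplacement_rate = 0.01, max_shift = 5,
                       rates = c(0.005, 0.01, 0.02, 0.05, 0.10),
                       n_symbols = 10000, n_markers = 1000,
                       cell_marker_ratio = 2, replicates = 20,
                       pitch_x = 250, pitch_y = 500, per_row = 100,
                       k = 2, n_init = 10) {
  cfg <- list(seed = seed, match = match, mismatch = mismatch, gap = gap,
              pair_window = pair_window, tolerance = tolerance,
              drop_rule = drop_rule, deletion_rate = deletion_rate,
              misplacement_rate = misplacement_rate, max_shift = max_shift,
              rates = rates, n_symbols = n_symbols, n_markers = n_markers,
              cell_marker_ratio = cell_marker_ratio,
              replicates = replicates, pitch_x = pitch_x,
              pitch_y = pitch_y, per_row = per_row, k = k, n_init = n_init)
  scoring_scheme(cfg$match, cfg$mismatch, cfg$gap)  # validates
  check_prob(cfg$deletion_rate, "deletion_rate")
  check_prob(cfg$misplacement_rate, "misplacement_rate")
  if (!cfg$drop_rule %in% c("both", "following"))
    stop("`drop_rule` must be 'both' or 'following'", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Read and write run configurations
#'
#' Format follows the file extension: `.yaml`/`.yml` or `.json`. Partial
#' files are completed with the [run_config()] defaults, so configs
#' round-trip losslessly.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return The path invisibly; `read_config` returns a `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(unclass(config), path)
  else if (ext == "json")
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA)
  else stop("config path must end in .yaml, .yml or .json", call. = FALSE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config path must end in .yaml, .yml or .json", call. = FALSE)
  do.call(run_config, raw)
}

# content hash of a config, for artifact provenance
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

cfg_scoring <- function(config)
  scoring_scheme(config$match, config$mismatch, config$gap)

#' Match two event-log readouts and build the mapping table
#'
#' The full matching workflow on recorded (or simulated) event logs:
#' encode both streams as marker sequences, globally align the symbol
#' tracks, classify the discrepancies, apply the drop rules, verify per-gap
#' cell counts, and pair the surviving cells with their plate coordinates.
#'
#' @param ifc_events Imaging-side event log: path to a stream CSV (see
#'   [write_stream_csv()]) or an `event_stream`.
#' @param cpp_events Plate-side event log, likewise.
#' @param config A [run_config()].
#' @param plate_positions Optional plate coordinates: a data frame or CSV
#'   path with columns `uid`, `x`, `y`. Default: the serpentine
#'   [dispense_layout()] implied by the plate stream order and the
#'   config's pitches.
#' @param out_dir Optional output directory; writes `mapping.csv` and
#'   `report.json` (segment statuses, error list, retention summary,
#'   config echo with hash).
#' @return Invisibly, a list with `mapping`, `segments`, `errors`,
#'   `alignment` and `stats`.
#' @export
run_matching <- function(ifc_events, cpp_events, config = run_config(),
                         plate_positions = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  load_stream <- function(x, what) {
    if (is.character(x)) {
      out <- tryCatch(read_stream_csv(x), error = function(e)
        stop("failed to parse ", what, " event log '", x, "': ",
             conditionMessage(e), call. = FALSE))
      out
    } else as_event_stream(x)
  }
  sa <- load_stream(ifc_events, "imaging")
  sb <- load_stream(cpp_events, "plate")
  mseq_a <- encode_markers(sa)
  mseq_b <- encode_markers(sb)
  if (!length(mseq_a$symbols) || !length(mseq_b$symbols))
    stop("empty marker sequence: cannot match readouts without markers",
         call. = FALSE)
  aln <- global_align(mseq_a, mseq_b, scoring = cfg_scoring(config))
  errors <- classify_errors(aln, pair_window = config$pair_window)
  segs <- match_segments(mseq_a, mseq_b, aln, errors,
                         drop_rule = config$drop_rule)
  pos <- if (is.null(plate_positions)) {
    dispense_layout(sb, pitch_x = config$pitch_x, pitch_y = config$pitch_y,
                    per_row = config$per_row)
  } else if (is.character(plate_positions)) {
    read.csv(plate_positions, stringsAsFactors = FALSE)
  } else plate_positions
  mapping <- build_mapping(segs, mseq_a, mseq_b, pos)
  stats <- retention_stats(mapping, mseq_a)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mapping_csv(mapping, file.path(out_dir, "mapping.csv"))
    report <- list(
      config = c(unclass(config), list(hash = config_hash(config))),
      segments = as.list(table(segs$status)),
      n_errors = nrow(errors),
      errors = as.data.frame(errors),
      retention = stats)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  }
  invisible(list(mapping = mapping, segments = segs, errors = errors,
                 alignment = aln, stats = stats))
}

#' Run the Monte Carlo simulation experiments from a config
#'
#' Detection-probability curves for deletion and misplacement errors over
#' the config's rate sweep, and/or the full-pipeline retention curve at
#' paired rates, all seeded from the config.
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; writes one CSV per curve and a
#'   `config.json` echo (with hash) for provenance.
#' @param what Any of `"detection"`, `"retention"`.
#' @return Invisibly, a named list of curves.
#' @export
run_simulation <- function(config = run_config(), out_dir = NULL,
                           what = c("detection", "retention")) {
  stopifnot(inherits(config, "run_config"))
  what <- match.arg(what, several.ok = TRUE)
  out <- list()
  if ("detection" %in% what) {
    for (kind in c("deletion", "misplacement")) {
      out[[paste0("detection_", kind)]] <- detection_curve(
        kind, rates = config$rates, n_symbols = config$n_symbols,
        replicates = config$replicates, scoring = cfg_scoring(config),
        tolerance = config$tolerance, max_shift = config$max_shift,
        seed = config$seed)
    }
  }
  if ("retention" %in% what) {
    out$retention <- retention_curve(
      deletion_rates = config$rates, misplacement_rates = config$rates,
      n_markers = config$n_markers,
      cell_marker_ratio = config$cell_marker_ratio,
      replicates = config$replicates, max_shift = config$max_shift,
      drop_rule = config$drop_rule, scoring = cfg_scoring(config),
      seed = config$seed)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out))
      write_curve_csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    jsonlite::write_json(c(unclass(config),
                           list(hash = config_hash(config))),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}

#' @importFrom utils str
NULL
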