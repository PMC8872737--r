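# Shared fixtures and independent oracles, built in code at test time.

# Exhaustive global-alignment oracle: recursively enumerates every gapped
# alignment of a and b and returns the maximum total score. Exponential on
# purpose -- only for short sequences.
bf_align_score <- function(a, b, sc = scoring_scheme()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L) +
                    if (av[i] == bv[j]) sc$match else sc$mismatch)
    if (i > 0L) best <- max(best, rec(i - 1L, j) + sc$gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + sc$gap)
    best
  }
  rec(length(av), length(bv))
}

rand_seq <- function(n) paste(sample(c("A", "T", "C"), n, replace = TRUE),
                              collapse = "")

# all symbol strings over {A,T,C} of length 0..max_len
all_seqs <- function(max_len) {
  out <- ""
  for (l in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(c("A", "T", "C")), l))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# hand-built event stream from a compact spec like c("cell","A","cell")
make_stream <- function(kinds, oof = NULL) {
  is_marker <- kinds %in% c("A", "T", "C")
  if (is.null(oof)) oof <- rep(FALSE, length(kinds))
  as_event_stream <- getFromNamespace("as_event_stream", "beadmap")
  as_event_stream(data.frame(
    source_index = seq_along(kinds), uid = seq_along(kinds),
    kind = ifelse(is_marker, "marker", "cell"),
    symbol = ifelse(is_marker, kinds, NA_character_),
    out_of_focus = ifelse(is_marker, NA, oof),
    stringsAsFactors = FALSE))
}

# rasterized disk / ellipse / ball masks for analytic feature checks
disk_mask <- function(r, pad = 2) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - c0)^2 + (j - c0)^2 <= r^2)
}

ellipse_mask <- function(a, b, pad = 2) {
  n <- 2 * (max(a, b) + pad) + 1
  c0 <- max(a, b) + pad + 1
  outer(seq_len(n), seq_len(n),
        function(i, j) ((i - c0) / b)^2 + ((j - c0) / a)^2 <= 1)
}

ball_mask <- function(r, pad = 1) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  arr <- array(FALSE, c(n, n, n))
  for (k in seq_len(n))
    arr[, , k] <- outer(seq_len(n), seq_len(n), function(i, j)
      (i - c0)^2 + (j - c0)^2 + (k - c0)^2 <= r^2)
  arr
}
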