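#' Plate image container
#'
#' A grayscale image of the dispensing membrane as seen by the low-
#' resolution, wide field-of-view plate camera, with its micron calibration.
#' Pixel-center convention: pixel `[i, j]` (row i, column j) has its center
#' at `x = (j - 0.5) * pixel_size`, `y = (i - 0.5) * pixel_size`.
#'
#' @param pixels Numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_size Microns per pixel (> 0).
#' @param origin Plate coordinate of the image origin, microns.
#' @return A `plate_image` object.
#' @export
plate_image <- function(pixels, pixel_size, origin = c(0, 0)) {
  stopifnot(is.matrix(pixels), is.numeric(pixels),
            is.numeric(pixel_size), length(pixel_size) == 1L,
            pixel_size > 0, all(is.finite(pixels)))
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 origin = origin), class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  cat(sprintf("<plate_image> %d x %d px @ %.3g um/px (%.0f x %.0f um)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              ncol(x$pixels) * x$pixel_size,
              nrow(x$pixels) * x$pixel_size))
  invisible(x)
}

# render an anti-aliased bright disk into a pixel matrix (in place value
# combine by max, so pores under an object do not add up)
render_disk <- function(px, cx, cy, r, amp, s) {
  nr <- nrow(px); nc <- ncol(px)
  j0 <- max(1L, floor((cx - r) / s)); j1 <- min(nc, ceiling((cx + r) / s) + 1L)
  i0 <- max(1L, floor((cy - r) / s)); i1 <- min(nr, ceiling((cy + r) / s) + 1L)
  if (j0 > j1 || i0 > i1) return(px)
  xs <- (j0:j1 - 0.5) * s
  ys <- (i0:i1 - 0.5) * s
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))
  cov <- pmin(1, pmax(0, (r - d) / s + 0.5))
  px[i0:i1, j0:j1] <- pmax(px[i0:i1, j0:j1], amp * cov)
  px
}

#' Synthesize a plate image with pore background
#'
#' Renders beads and cells as anti-aliased bright disks on the membrane
#' background: a transparent porous film whose pores image as many small,
#' dimmer disks, plus additive Gaussian noise. This emulates what the plate
#' camera must cope with — the objects of interest sit on a dense texture of
#' few-micron pores that the detection step has to remove.
#'
#' @param layout Data frame with columns `x`, `y` (centers, microns),
#'   `diameter` (microns) and `class` (ground-truth label, e.g. `marker_A`,
#'   `cell`).
#' @param pore_density Pores per mm^2 of membrane.
#' @param pore_diameter Maximum pore diameter, microns (pores are drawn
#'   uniformly between half this and this).
#' @param noise_sd Additive Gaussian noise, intensity units (objects render
#'   at 1, pores at `pore_intensity`).
#' @param pixel_size Microns per pixel.
#' @param seed Optional integer seed.
#' @param dims Image size in microns `c(width, height)`; default fits the
#'   layout plus `margin`.
#' @param margin Margin around the layout, microns.
#' @param allow_overlap Permit overlapping objects (for doublet fixtures).
#' @param pore_intensity Rendered pore brightness.
#' @return List with `image` (a [plate_image()]) and `truth` (the layout
#'   with a `uid` column — the ground truth for synthetic benchmarks).
#' @examples
#' lay <- data.frame(x = 50, y = 50, diameter = 30, class = "marker_C")
#' sp <- synth_plate(lay, pore_density = 0, noise_sd = 0, seed = 1)
#' sp$image
#' @export
synth_plate <- function(layout, pore_density = 200, pore_diameter = 5,
                        noise_sd = 0.02, pixel_size = 2.5, seed = NULL,
                        dims = NULL, margin = 50, allow_overlap = FALSE,
                        pore_intensity = 0.45) {
  stopifnot(is.data.frame(layout))
  if (nrow(layout) && !all(c("x", "y", "diameter", "class") %in%
                           names(layout)))
    stop("`layout` needs columns x, y, diameter, class", call. = FALSE)
  if (nrow(layout) && any(layout$diameter <= pixel_size))
    stop("object diameters must exceed the pixel size", call. = FALSE)
  if (!allow_overlap && nrow(layout) > 1L) {
    d <- as.matrix(stats::dist(layout[, c("x", "y")]))
    rad <- layout$diameter / 2
    lim <- outer(rad, rad, "+")
    diag(d) <- Inf
    if (any(d < lim))
      stop("layout contains overlapping objects ",
           "(use allow_overlap = TRUE for doublet fixtures)", call. = FALSE)
  }
  if (is.null(dims)) {
    if (nrow(layout)) {
      dims <- c(max(layout$x + layout$diameter / 2) + margin,
                max(layout$y + layout$diameter / 2) + margin)
    } else dims <- c(20 * pixel_size, 20 * pixel_size)
  }
  nc <- as.integer(ceiling(dims[1] / pixel_size))
  nr <- as.integer(ceiling(dims[2] / pixel_size))
  with_seed(seed, {
    px <- matrix(0, nr, nc)
    area_mm2 <- (nc * pixel_size) * (nr * pixel_size) * 1e-6
    n_pores <- rpois(1, pore_density * area_mm2)
    if (n_pores > 0) {
      pore_x <- runif(n_pores, 0, nc * pixel_size)
      pore_y <- runif(n_pores, 0, nr * pixel_size)
      pore_d <- runif(n_pores, pore_diameter / 2, pore_diameter)
      for (i in seq_len(n_pores))
        px <- render_disk(px, pore_x[i], pore_y[i], pore_d[i] / 2,
                          pore_intensity, pixel_size)
    }
    for (i in seq_len(nrow(layout)))
      px <- render_disk(px, layout$x[i], layout$y[i],
                        layout$diameter[i] / 2, 1.0, pixel_size)
    if (noise_sd > 0)
      px <- px + matrix(rnorm(nr * nc, 0, noise_sd), nr, nc)
    truth <- layout
    if (nrow(truth)) truth$uid <- seq_len(nrow(truth))
    list(image = plate_image(px, pixel_size), truth = truth)
  })
}

#' Remove the pore background and threshold a plate image
#'
#' Gaussian blur, global threshold (Otsu by default), then removal of every
#' connected component whose equivalent diameter does not exceed
#' `max_pore_diameter` — the pores are far smaller than the smallest object
#' of interest (a 10-micron bead), so a size filter cleanly separates the
#' membrane texture from beads and cells.
#'
#' @param image A [plate_image()].
#' @param max_pore_diameter Largest component treated as a pore, microns
#'   (must stay below 10, the smallest object of interest; the default 9
#'   also absorbs occasional clusters of merged pores; `0` disables
#'   removal).
#' @param threshold `"otsu"` or a fixed numeric intensity threshold.
#' @param blur_sigma Gaussian blur sigma in pixels (`0` to skip).
#' @return A logical foreground mask (matrix) with attributes `pixel_size`
#'   and class `plate_mask`.
#' @export
remove_pores <- function(image, max_pore_diameter = 9, threshold = "otsu",
                         blur_sigma = 1) {
  stopifnot(inherits(image, "plate_image"))
  if (max_pore_diameter >= 10)
    stop("`max_pore_diameter` must stay below the smallest object (10 um)",
         call. = FALSE)
  raw <- image$pixels
  px <- raw
  if (blur_sigma > 0)
    px <- as.matrix(EBImage::gblur(px, sigma = blur_sigma))
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(pmin(pmax(px, 0), 1)))
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    threshold
  } else stop("`threshold` must be \"otsu\" or a number", call. = FALSE)
  mask <- px > thr
  if (max_pore_diameter > 0 && any(mask)) {
    lab <- EBImage::bwlabel(mask)
    # size each component by its half-peak (FWHM) footprint in the
    # unblurred image: the blur halo and the sub-threshold skirt stabilize
    # connectivity but must not count toward object size, and a half-peak
    # criterion is invariant to overall intensity scaling
    ids <- which(lab > 0)
    l <- lab[ids]
    peak <- tapply(raw[ids], l, max)
    level <- pmax(thr, 0.5 * peak[as.character(l)])
    core <- tapply(raw[ids] > level, l, sum)
    eqd <- 2 * sqrt(as.numeric(core) / pi) * image$pixel_size
    drop_ids <- as.integer(names(core))[eqd <= max_pore_diameter]
    if (length(drop_ids)) mask[lab %in% drop_ids] <- FALSE
  }
  structure(mask, pixel_size = image$pixel_size, class = "plate_mask")
}

#' Detect objects in a foreground mask
#'
#' One detected object per connected component: the centroid (intensity-
#' weighted over the component when the source image is supplied, geometric
#' otherwise) in microns under the pixel-center convention, and the
#' equivalent diameter of the equal-area circle.
#'
#' @param mask A `plate_mask` from [remove_pores()] (or any logical matrix
#'   with a `pixel_size` attribute).
#' @param image Optional source [plate_image()] for intensity weighting.
#' @param pixel_size Microns per pixel; defaults to the mask attribute.
#' @return A `plate_objects` data frame: `object`, `x`, `y` (microns),
#'   `equivalent_diameter` (microns), `area` (square microns),
#'   `object_class` (`"unknown"` until [classify_by_size()]).
#' @export
detect_objects <- function(mask, image = NULL,
                           pixel_size = attr(mask, "pixel_size")) {
  if (is.null(pixel_size))
    stop("`pixel_size` missing (not a plate_mask?)", call. = FALSE)
  m <- unclass(mask)
  empty <- data.frame(object = integer(0), x = numeric(0), y = numeric(0),
                      equivalent_diameter = numeric(0), area = numeric(0),
                      object_class = character(0), stringsAsFactors = FALSE)
  if (!any(m)) return(structure(empty, pixel_size = pixel_size,
                                class = c("plate_objects", "data.frame")))
  lab <- EBImage::bwlabel(m)
  idx <- which(lab > 0)
  l <- lab[idx]
  ri <- (idx - 1L) %% nrow(m) + 1L
  ci <- (idx - 1L) %/% nrow(m) + 1L
  w <- if (!is.null(image)) pmax(image$pixels[idx], 0) else rep(1, length(idx))
  wsum <- as.numeric(tapply(w, l, sum))
  cx <- as.numeric(tapply(w * (ci - 0.5), l, sum)) / wsum * pixel_size
  cy <- as.numeric(tapply(w * (ri - 0.5), l, sum)) / wsum * pixel_size
  area <- tabulate(l) * pixel_size^2
  out <- data.frame(object = seq_along(area), x = cx, y = cy,
                    equivalent_diameter = 2 * sqrt(area / pi), area = area,
                    object_class = "unknown", stringsAsFactors = FALSE)
  structure(out, pixel_size = pixel_size,
            class = c("plate_objects", "data.frame"))
}

#' Default size bands for marker-bead classification
#'
#' Half-open diameter bands `[min, max)` in microns. The three marker bead
#' sizes (10, 20, 30 microns encoding `A`, `T`, `C`) get generous bands;
#' cells must be given an experiment-specific band because real cell sizes
#' overlap the bead sizes — synthetic fixtures use separable sizes.
#'
#' @param ... Named bands `name = c(min, max)` added to or overriding the
#'   marker defaults.
#' @return Named list of bands.
#' @export
size_bands <- function(...) {
  bands <- list(marker_A = c(7, 14), marker_T = c(16, 24),
                marker_C = c(26, 36))
  extra <- list(...)
  for (nm in names(extra)) bands[[nm]] <- extra[[nm]]
  lims <- do.call(rbind, bands)
  if (any(lims[, 1] >= lims[, 2]))
    stop("each band must satisfy min < max", call. = FALSE)
  ord <- order(lims[, 1])
  if (any(lims[ord, 2][-length(ord)] > lims[ord, 1][-1]))
    stop("size bands overlap", call. = FALSE)
  bands
}

#' Classify detected objects by size
#'
#' Assigns each object the class of the band `[min, max)` containing its
#' equivalent diameter; objects outside every band stay `"unknown"`.
#'
#' @param objects A `plate_objects` data frame.
#' @param bands Named list of bands from [size_bands()].
#' @return The objects with `object_class` filled in.
#' @export
classify_by_size <- function(objects, bands = size_bands()) {
  lims <- do.call(rbind, bands)
  if (any(lims[, 1] >= lims[, 2]))
    stop("each band must satisfy min < max", call. = FALSE)
  ord <- order(lims[, 1])
  if (nrow(lims) > 1 && any(lims[ord, 2][-nrow(lims)] > lims[ord, 1][-1]))
    stop("size bands overlap", call. = FALSE)
  for (nm in names(bands)) {
    b <- bands[[nm]]
    hit <- objects$equivalent_diameter >= b[1] &
      objects$equivalent_diameter < b[2]
    objects$object_class[hit] <- nm
  }
  objects
}

#' Register plate coordinates to the first marker bead
#'
#' Re-expresses all coordinates relative to the first detected marker bead
#' in dispensing-scan order (ascending x, then y), which becomes the origin
#' `(0, 0)` of the registration table. Pure translation: pairwise distances
#' are preserved exactly.
#'
#' @param objects A classified `plate_objects` data frame.
#' @return The objects with translated `x`, `y` and a `reference` attribute
#'   recording the reference object and its original coordinates.
#' @export
register_coordinates <- function(objects) {
  is_marker <- grepl("^marker_", objects$object_class)
  if (!any(is_marker))
    stop("no marker bead found: cannot register coordinates", call. = FALSE)
  mk <- objects[is_marker, , drop = FALSE]
  ref <- mk[order(mk$x, mk$y)[1L], , drop = FALSE]
  out <- objects
  out$x <- objects$x - ref$x
  out$y <- objects$y - ref$y
  attr(out, "reference") <- list(object = ref$object,
                                 x = ref$x, y = ref$y,
                                 object_class = ref$object_class)
  out
}

#' Read and write plate images with a micron-calibration sidecar
#'
#' Images go to PNG/TIFF via EBImage (clamped to \[0, 1\]); the pixel size
#' and origin go to a JSON sidecar at `<path>.json` so the calibration
#' survives the round trip.
#'
#' @param image A [plate_image()].
#' @param path Image file path (`.png` or `.tif`).
#' @return The path, invisibly; `read_plate_image` returns a
#'   [plate_image()].
#' @export
write_plate_image <- function(image, path) {
  stopifnot(inherits(image, "plate_image"))
  EBImage::writeImage(EBImage::Image(t(pmin(pmax(image$pixels, 0), 1))),
                      path)
  jsonlite::write_json(list(pixel_size = image$pixel_size,
                            origin = image$origin),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_plate_image
#' @export
read_plate_image <- function(path) {
  px <- EBImage::readImage(path)
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  dat <- EBImage::imageData(px)
  if (length(dim(dat)) > 2) dat <- dat[, , 1]
  plate_image(t(as.matrix(dat)), meta$pixel_size,
              origin = as.numeric(meta$origin))
}

#' Export detections as a plate-positions CSV
#'
#' Columns `entity`, `class`, `x`, `y`, `diameter` plus a `uid` column in
#' detection order, compatible with the `plate_positions` input of
#' [build_mapping()].
#'
#' @param objects A `plate_objects` data frame.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_detections_csv <- function(objects, path) {
  df <- data.frame(entity = ifelse(grepl("^marker_", objects$object_class),
                                   "marker", "cell"),
                   class = objects$object_class,
                   x = objects$x, y = objects$y,
                   diameter = objects$equivalent_diameter,
                   uid = objects$object)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
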