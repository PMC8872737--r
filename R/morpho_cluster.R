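#' 2D morphological features from a binary mask
#'
#' The transmission-image features tabulated per cell: projected area,
#' major and minor axis of the second-moment equivalent ellipse, and a
#' Crofton-style perimeter estimate (boundary crossings counted along the
#' horizontal and vertical directions, scaled by pi/4 — exact in
#' expectation for smooth convex shapes).
#'
#' @param mask Logical (or 0/1) matrix with at least one foreground pixel.
#' @param pixel_size Microns per pixel.
#' @param extras Also compute eccentricity and extent (optional features,
#'   off by default).
#' @return Named list: `area_2d` (um^2), `major_axis`, `minor_axis`,
#'   `perimeter` (um), plus extras when requested.
#' @examples
#' m <- outer(1:41, 1:41, function(i, j) (i - 21)^2 + (j - 21)^2 <= 400)
#' f <- features_2d(m, pixel_size = 1)
#' abs(f$area_2d - 400 * pi) / (400 * pi) < 0.02
#' @export
features_2d <- function(mask, pixel_size = 1, extras = FALSE) {
  m <- mask > 0
  n <- sum(m)
  if (n == 0L) stop("empty mask", call. = FALSE)
  s <- pixel_size
  idx <- which(m)
  ri <- (idx - 1L) %% nrow(m) + 1L
  ci <- (idx - 1L) %/% nrow(m) + 1L
  area <- n * s^2
  # second-moment equivalent ellipse
  mu_rr <- sum((ri - mean(ri))^2) / n
  mu_cc <- sum((ci - mean(ci))^2) / n
  mu_rc <- sum((ri - mean(ri)) * (ci - mean(ci))) / n
  ev <- eigen(matrix(c(mu_rr, mu_rc, mu_rc, mu_cc), 2), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1]) * s
  minor <- 4 * sqrt(ev[2]) * s
  # Crofton 2-direction perimeter: foreground/background crossings
  padded_h <- cbind(FALSE, m, FALSE)
  padded_v <- rbind(FALSE, m, FALSE)
  ch <- sum(padded_h[, -1] != padded_h[, -ncol(padded_h)])
  cv <- sum(padded_v[-1, ] != padded_v[-nrow(padded_v), ])
  perim <- (pi / 4) * (ch + cv) * s
  out <- list(area_2d = area, major_axis = major, minor_axis = minor,
              perimeter = perim)
  if (extras) {
    out$eccentricity <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
    bbox <- (diff(range(ri)) + 1) * (diff(range(ci)) + 1)
    out$extent <- n / bbox
  }
  out
}

#' 3D morphological features from a voxel mask
#'
#' The side-scatter-image features tabulated per cell: volume as the voxel
#' count and surface area as the count of exposed voxel faces — exact for
#' axis-aligned shapes; on smooth shapes the face-count estimator is biased
#' upward by a known factor (~1.5 for a sphere), which is acceptable for
#' relative morphometry and keeps the measure exactly testable.
#'
#' @param voxels Logical (or 0/1) 3D array with at least one foreground
#'   voxel.
#' @param voxel_size Microns per voxel edge.
#' @param extras Also compute sphericity and extent.
#' @return Named list: `volume_3d` (um^3), `surface_area_3d` (um^2), plus
#'   extras when requested.
#' @examples
#' cube <- array(TRUE, c(10, 10, 10))
#' features_3d(cube, voxel_size = 1)  # volume 1000, surface 600
#' @export
features_3d <- function(voxels, voxel_size = 1, extras = FALSE) {
  v <- voxels > 0
  if (length(dim(v)) != 3L) stop("`voxels` must be a 3D array",
                                 call. = FALSE)
  n <- sum(v)
  if (n == 0L) stop("empty mask", call. = FALSE)
  s <- voxel_size
  d <- dim(v)
  adj <- 0L
  if (d[1] > 1) adj <- adj + sum(v[-1, , ] & v[-d[1], , ])
  if (d[2] > 1) adj <- adj + sum(v[, -1, ] & v[, -d[2], ])
  if (d[3] > 1) adj <- adj + sum(v[, , -1] & v[, , -d[3]])
  volume <- n * s^3
  surface <- (6 * n - 2 * adj) * s^2
  out <- list(volume_3d = volume, surface_area_3d = surface)
  if (extras) {
    out$sphericity <- (pi^(1 / 3) * (6 * volume)^(2 / 3)) / surface
    w <- which(v, arr.ind = TRUE)
    ext <- apply(w, 2, function(z) diff(range(z)) + 1)
    out$extent <- n / prod(ext)
    out$aspect_ratio_3d <- max(ext) / min(ext)
  }
  out
}

#' Feature table for a set of cells
#'
#' Combines per-cell 2D and 3D features into one row per cell, in the
#' column order of the registration tables (2D transmission features, then
#' 3D side-scatter features).
#'
#' @param masks_2d List of 2D masks (or `NULL` entries for cells without a
#'   usable transmission image).
#' @param voxels_3d List of 3D masks (or `NULL` entries), same length.
#' @param pixel_size,voxel_size Micron calibrations.
#' @return Data frame with columns `area_2d`, `major_axis`, `minor_axis`,
#'   `perimeter`, `volume_3d`, `surface_area_3d` (`NA` where no mask).
#' @export
feature_table <- function(masks_2d, voxels_3d, pixel_size = 1,
                          voxel_size = 1) {
  stopifnot(length(masks_2d) == length(voxels_3d))
  one <- function(i) {
    f2 <- if (!is.null(masks_2d[[i]]))
      features_2d(masks_2d[[i]], pixel_size)
    else list(area_2d = NA_real_, major_axis = NA_real_,
              minor_axis = NA_real_, perimeter = NA_real_)
    f3 <- if (!is.null(voxels_3d[[i]]))
      features_3d(voxels_3d[[i]], voxel_size)
    else list(volume_3d = NA_real_, surface_area_3d = NA_real_)
    as.data.frame(c(f2, f3))
  }
  out <- do.call(rbind, lapply(seq_along(masks_2d), one))
  rownames(out) <- NULL
  out
}

#' Fit k-means with k-means++ seeding (from scratch)
#'
#' Lloyd's algorithm on z-score standardized features, with k-means++
#' initialization, `n_init` restarts keeping the lowest-inertia solution,
#' and convergence when the largest centroid shift drops below `tol` (in
#' standardized units). The stored standardization is reapplied by
#' `predict`, supporting the fit-on-one-sample / predict-on-another
#' workflow used to type cells from a diseased sample and score a control
#' sample against the same model.
#'
#' @param data Numeric matrix or data frame (rows = cells, columns =
#'   features); all values finite.
#' @param k Number of clusters (1 <= k <= rows).
#' @param n_init Independent restarts.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Convergence threshold on centroid movement.
#' @param seed Optional integer seed.
#' @return A `km_model`: `k`, `centers` (standardized space), `scaling`
#'   (per-feature mean and sd), `cluster` (fit labels), `inertia`,
#'   `inertia_history` (per accepted iteration of the winning restart),
#'   `iterations`, `degenerate` flag.
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 6), 20))
#' m <- kmeans_fit(x, k = 2, seed = 1)
#' table(m$cluster)
#' @export
kmeans_fit <- function(data, k = 2, n_init = 10, max_iter = 100,
                       tol = 1e-8, seed = NULL) {
  x <- as.matrix(data)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("`data` must be finite", call. = FALSE)
  n <- nrow(x); p <- ncol(x)
  k <- check_count(k, "k")
  if (k > n) stop("`k` cannot exceed the number of points", call. = FALSE)
  n_init <- check_count(n_init, "n_init")
  max_iter <- check_count(max_iter, "max_iter")
  mu <- colMeans(x)
  sig <- apply(x, 2, stats::sd)
  sig[!is.finite(sig) | sig == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sig, "/")
  degenerate <- all(apply(xs, 2, function(z) length(unique(z)) == 1L))
  if (degenerate)
    warning("all data points identical: centroids are replicated",
            call. = FALSE)

  sq <- rowSums(xs^2)
  dist2 <- function(centers) {
    d <- matrix(sq, n, nrow(centers)) +
      matrix(rowSums(centers^2), n, nrow(centers), byrow = TRUE) -
      2 * xs %*% t(centers)
    pmax(d, 0)
  }
  run_once <- function() {
    # k-means++ seeding
    centers <- matrix(0, k, p)
    centers[1, ] <- xs[sample.int(n, 1L), ]
    if (k > 1) {
      d2 <- rowSums(sweep(xs, 2, centers[1, ])^2)
      for (j in 2:k) {
        pick <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2)
                else sample.int(n, 1L)
        centers[j, ] <- xs[pick, ]
        d2 <- pmin(d2, rowSums(sweep(xs, 2, centers[j, ])^2))
      }
    }
    history <- numeric(0)
    labels <- rep(1L, n)
    for (it in seq_len(max_iter)) {
      d <- dist2(centers)
      labels <- max.col(-d, ties.method = "first")
      history <- c(history, sum(d[cbind(seq_len(n), labels)]))
      newc <- centers
      cnt <- tabulate(labels, k)
      agg <- rowsum(xs, labels)
      newc[as.integer(rownames(agg)), ] <- agg / cnt[cnt > 0]
      for (j in which(cnt == 0)) {          # revive empty clusters
        far <- which.max(d[cbind(seq_len(n), labels)])
        newc[j, ] <- xs[far, ]
      }
      shift <- sqrt(max(rowSums((newc - centers)^2)))
      centers <- newc
      if (shift < tol) break
    }
    d <- dist2(centers)
    labels <- max.col(-d, ties.method = "first")
    inertia <- sum(d[cbind(seq_len(n), labels)])
    list(centers = centers, labels = labels, inertia = inertia,
         history = history, iterations = length(history))
  }
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      cand <- run_once()
      if (is.null(best) || cand$inertia < best$inertia) best <- cand
    }
    structure(list(k = k, centers = best$centers,
                   scaling = list(mean = mu, sd = sig),
                   cluster = best$labels, inertia = best$inertia,
                   inertia_history = best$history,
                   iterations = best$iterations, n_init = n_init,
                   features = colnames(x), degenerate = degenerate,
                   seed = seed),
              class = "km_model")
  })
}

#' @export
print.km_model <- function(x, ...) {
  cat(sprintf("<km_model> k=%d on %d feature(s), inertia %.4g (%d restarts)\n",
              x$k, ncol(x$centers), x$inertia, x$n_init))
  cat("  cluster sizes:", paste(tabulate(x$cluster, x$k), collapse = " "),
      "\n")
  invisible(x)
}

#' Predict cluster labels from a fitted k-means model
#'
#' New data are standardized with the scaling stored at fit time and each
#' point is labeled by its nearest centroid (ties broken toward the lowest
#' cluster index).
#'
#' @param object A `km_model`.
#' @param newdata Matrix or data frame with the model's feature columns.
#' @param ... Unused.
#' @return Integer cluster labels.
#' @export
predict.km_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != ncol(object$centers))
    stop("`newdata` has ", ncol(x), " feature(s); model expects ",
         ncol(object$centers), call. = FALSE)
  xs <- sweep(sweep(x, 2, object$scaling$mean), 2, object$scaling$sd, "/")
  d <- matrix(rowSums(xs^2), nrow(xs), object$k) +
    matrix(rowSums(object$centers^2), nrow(xs), object$k, byrow = TRUE) -
    2 * xs %*% t(object$centers)
  max.col(-d, ties.method = "first")
}

#' Persist a k-means model as JSON
#'
#' @param model A `km_model`.
#' @param path File path.
#' @return The path, invisibly; `read_km_model` returns the model.
#' @export
write_km_model <- function(model, path) {
  stopifnot(inherits(model, "km_model"))
  out <- list(k = model$k, centers = model$centers,
              scaling = model$scaling, inertia = model$inertia,
              features = model$features, seed = model$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_km_model
#' @export
read_km_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- raw$centers
  if (!is.matrix(centers))
    centers <- matrix(unlist(centers), nrow = raw$k, byrow = TRUE)
  structure(list(k = as.integer(raw$k), centers = centers,
                 scaling = list(mean = as.numeric(raw$scaling$mean),
                                sd = as.numeric(raw$scaling$sd)),
                 cluster = NULL, inertia = raw$inertia,
                 inertia_history = NULL, iterations = NULL,
                 n_init = NA_integer_, features = raw$features,
                 degenerate = FALSE, seed = raw$seed),
            class = "km_model")
}
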