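test_that("2D features match analytic shapes", {
  # single pixel at 1 um/px
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  f1 <- features_2d(one, pixel_size = 1)
  expect_equal(f1$area_2d, 1)

  # disk radius 20 px
  fd <- features_2d(disk_mask(20), pixel_size = 1)
  expect_lt(abs(fd$area_2d - 400 * pi) / (400 * pi), 0.02)
  expect_lt(abs(fd$major_axis - fd$minor_axis) / fd$major_axis, 0.02)
  expect_lt(abs(fd$major_axis - 40) / 40, 0.05)
  expect_lt(abs(fd$perimeter - 2 * pi * 20) / (2 * pi * 20), 0.05)

  # 2:1 ellipse
  fe <- features_2d(ellipse_mask(30, 15), pixel_size = 1)
  expect_lt(abs(fe$major_axis / fe$minor_axis - 2), 0.05 * 2)

  expect_error(features_2d(matrix(FALSE, 3, 3)), "empty")
})

test_that("3D features are exact on axis-aligned solids", {
  cube <- array(TRUE, c(10, 10, 10))
  fc <- features_3d(cube, voxel_size = 1)
  expect_equal(fc$volume_3d, 1000)
  expect_equal(fc$surface_area_3d, 600)

  two <- array(FALSE, c(3, 3, 5))
  two[2, 2, 2] <- TRUE; two[2, 2, 4] <- TRUE
  ft <- features_3d(two, voxel_size = 1)
  expect_equal(ft$volume_3d, 2)
  expect_equal(ft$surface_area_3d, 12)

  fb <- features_3d(ball_mask(10), voxel_size = 1)
  expect_lt(abs(fb$volume_3d - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000),
            0.05)

  expect_error(features_3d(array(FALSE, c(2, 2, 2))), "empty")
  expect_error(features_3d(matrix(TRUE, 2, 2)), "3D")
})

test_that("features scale with pixel and voxel size and ignore translation", {
  m <- disk_mask(12)
  f1 <- features_2d(m, pixel_size = 1)
  f2 <- features_2d(m, pixel_size = 2.5)
  expect_equal(f2$area_2d, f1$area_2d * 2.5^2)
  expect_equal(f2$perimeter, f1$perimeter * 2.5)
  expect_equal(f2$major_axis, f1$major_axis * 2.5)

  shifted <- rbind(matrix(FALSE, 4, ncol(m) + 7),
                   cbind(matrix(FALSE, nrow(m), 7), m))
  fs <- features_2d(shifted, pixel_size = 1)
  expect_equal(fs$area_2d, f1$area_2d)
  expect_equal(fs$perimeter, f1$perimeter)

  v <- ball_mask(6)
  g1 <- features_3d(v, voxel_size = 1)
  g2 <- features_3d(v, voxel_size = 3)
  expect_equal(g2$volume_3d, g1$volume_3d * 27)
  expect_equal(g2$surface_area_3d, g1$surface_area_3d * 9)
})

test_that("feature_table combines 2D and 3D features per cell", {
  tab <- feature_table(list(disk_mask(5), NULL),
                       list(NULL, array(TRUE, c(2, 2, 2))))
  expect_equal(nrow(tab), 2L)
  expect_true(is.na(tab$volume_3d[1]))
  expect_true(is.na(tab$area_2d[2]))
  expect_equal(tab$volume_3d[2], 8)
})

test_that("kmeans_fit recovers structure and behaves deterministically", {
  # k = 1: the centroid is the feature mean (origin in scaled space)
  x <- matrix(rnorm(60), 30, 2)
  m1 <- kmeans_fit(x, k = 1, seed = 1)
  expect_equal(as.numeric(m1$centers), c(0, 0), tolerance = 1e-8)

  # two 10-sigma separated blobs: exact recovery
  set.seed(2)
  blob <- rbind(matrix(rnorm(100, 0, 1), 50, 2),
                matrix(rnorm(100, 10, 1), 50, 2))
  truth <- rep(1:2, each = 50)
  m2 <- kmeans_fit(blob, k = 2, seed = 3)
  expect_equal(length(unique(m2$cluster[truth == 1])), 1L)
  expect_equal(length(unique(m2$cluster[truth == 2])), 1L)
  expect_false(m2$cluster[1] == m2$cluster[100])

  # agreement with the reference implementation on the same data
  ref <- stats::kmeans(scale(blob), centers = 2, nstart = 5)
  expect_equal(length(unique(paste(m2$cluster, ref$cluster))), 2L)

  # inertia is non-increasing across accepted Lloyd iterations
  expect_true(all(diff(m2$inertia_history) <= 1e-9))

  # determinism under a fixed seed
  expect_identical(kmeans_fit(blob, k = 2, seed = 9)$cluster,
                   kmeans_fit(blob, k = 2, seed = 9)$cluster)

  expect_error(kmeans_fit(blob, k = 101), "exceed")
  expect_error(kmeans_fit(matrix(c(1, NA), 2, 1), k = 1), "finite")
  expect_warning(kmeans_fit(matrix(1, 5, 2), k = 2, seed = 1),
                 "identical")
})

test_that("predict reproduces fit labels and breaks ties to low index", {
  set.seed(4)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  m <- kmeans_fit(x, k = 2, seed = 5)
  expect_identical(predict(m, x), m$cluster)

  # a point exactly on centroid j gets label j
  raw_center <- sweep(sweep(m$centers, 2, m$scaling$sd, "*"), 2,
                      m$scaling$mean, "+")
  expect_equal(predict(m, raw_center), 1:2)

  # exactly equidistant point -> lowest cluster index
  tie <- m
  tie$centers <- matrix(c(-1, -1, 1, 1), 2, byrow = TRUE)
  tie$scaling <- list(mean = c(0, 0), sd = c(1, 1))
  expect_equal(predict(tie, matrix(0, 1, 2)), 1L)

  expect_error(predict(m, matrix(0, 2, 3)), "feature")
})

test_that("k-means models persist through JSON", {
  set.seed(6)
  x <- rbind(matrix(rnorm(30, 0), 15, 2), matrix(rnorm(30, 6), 15, 2))
  m <- kmeans_fit(x, k = 2, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_km_model(m, path)
  back <- read_km_model(path)
  expect_equal(back$centers, m$centers)
  expect_identical(predict(back, x), predict(m, x))
})
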