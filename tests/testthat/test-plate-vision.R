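test_that("synth_plate renders layouts with exact ground truth", {
  # empty layout, no pores, no noise -> uniform background
  sp0 <- synth_plate(data.frame(), pore_density = 0, noise_sd = 0,
                     seed = 1)
  expect_true(all(sp0$image$pixels == 0))

  # one 30 um disk: the rendered blob's intensity centroid sits at the
  # requested center to sub-pixel accuracy
  lay <- data.frame(x = 60, y = 45, diameter = 30, class = "marker_C")
  sp <- synth_plate(lay, pore_density = 0, noise_sd = 0, pixel_size = 2.5,
                    seed = 1)
  px <- sp$image$pixels
  idx <- which(px > 0)
  w <- px[idx]
  cx <- sum(w * (((idx - 1) %/% nrow(px)) + 0.5)) / sum(w) * 2.5
  cy <- sum(w * (((idx - 1) %% nrow(px)) + 0.5)) / sum(w) * 2.5
  expect_lt(abs(cx - 60), 1.25)
  expect_lt(abs(cy - 45), 1.25)

  expect_equal(sp$truth$class, "marker_C")
  expect_error(synth_plate(data.frame(x = c(0, 5), y = c(0, 0),
                                      diameter = c(20, 20),
                                      class = c("cell", "cell"))),
               "overlapping")
  expect_silent(synth_plate(data.frame(x = c(100, 105), y = c(100, 100),
                                       diameter = c(20, 20),
                                       class = c("cell", "cell")),
                            allow_overlap = TRUE, pore_density = 0,
                            seed = 1))
})

test_that("remove_pores keeps objects and drops the membrane texture", {
  # pores only -> empty mask
  sp <- synth_plate(data.frame(), pore_density = 400, pore_diameter = 5,
                    noise_sd = 0.02, pixel_size = 2.5, seed = 2,
                    dims = c(500, 500))
  m0 <- remove_pores(sp$image)
  expect_false(any(m0))

  # pores plus one 20 um bead -> exactly one component survives
  lay <- data.frame(x = 250, y = 250, diameter = 20, class = "marker_T")
  sp1 <- synth_plate(lay, pore_density = 400, pore_diameter = 5,
                     noise_sd = 0.02, pixel_size = 2.5, seed = 3,
                     dims = c(500, 500))
  m1 <- remove_pores(sp1$image)
  obj <- detect_objects(m1, image = sp1$image)
  expect_equal(nrow(obj), 1L)
  expect_lt(abs(obj$equivalent_diameter - 20) / 20, 0.10)

  # max_pore_diameter = 0 disables the size filter entirely (on the
  # pores-only image the threshold keeps the pores in the mask)
  m_all <- remove_pores(sp$image, max_pore_diameter = 0)
  expect_gt(nrow(detect_objects(m_all, image = sp$image)), 1L)

  expect_error(remove_pores(sp1$image, max_pore_diameter = 12),
               "smallest object")
})

test_that("detect_objects counts and sizes disjoint disks", {
  empty <- structure(matrix(FALSE, 10, 10), pixel_size = 2.5,
                     class = "plate_mask")
  expect_equal(nrow(detect_objects(empty)), 0L)

  lay <- data.frame(x = c(50, 150, 250), y = c(60, 60, 60),
                    diameter = c(10, 20, 30),
                    class = c("marker_A", "marker_T", "marker_C"))
  sp <- synth_plate(lay, pore_density = 0, noise_sd = 0, pixel_size = 2.5,
                    seed = 4)
  obj <- detect_objects(remove_pores(sp$image), image = sp$image)
  expect_equal(nrow(obj), 3L)
  obj <- obj[order(obj$x), ]
  for (i in 1:3)
    expect_lt(abs(obj$equivalent_diameter[i] - lay$diameter[i]) /
                lay$diameter[i], 0.10)
})

test_that("size bands classify by diameter and reject overlaps", {
  obj <- data.frame(object = 1:4, x = 0, y = 0,
                    equivalent_diameter = c(10, 30, 55, 20),
                    area = 1, object_class = "unknown")
  out <- classify_by_size(obj)
  expect_equal(out$object_class,
               c("marker_A", "marker_C", "unknown", "marker_T"))
  out2 <- classify_by_size(obj, c(size_bands(), list(cell = c(14, 16))))
  expect_equal(out2$object_class[1], "marker_A")
  expect_error(classify_by_size(obj, list(a = c(5, 15), b = c(10, 20))),
               "overlap")
  expect_error(classify_by_size(obj, list(a = c(15, 5))), "min < max")
})

test_that("registration translates to the first marker and preserves distances", {
  obj <- data.frame(object = 1:3, x = c(400, 120, 300),
                    y = c(50, 80, 90),
                    equivalent_diameter = c(18, 20, 30), area = 1,
                    object_class = c("cell", "marker_T", "marker_C"))
  reg <- register_coordinates(obj)
  # the scan-first marker (lowest x among markers) becomes the origin
  expect_equal(reg$x[2], 0)
  expect_equal(reg$y[2], 0)
  d_before <- dist(obj[, c("x", "y")])
  d_after <- dist(reg[, c("x", "y")])
  expect_equal(as.numeric(d_after), as.numeric(d_before))

  no_marker <- obj[1, ]
  expect_error(register_coordinates(no_marker), "no marker")
})

test_that("classification is invariant to translation and intensity scale", {
  lay <- data.frame(x = c(60, 160), y = c(60, 60), diameter = c(10, 30),
                    class = c("marker_A", "marker_C"))
  sp <- synth_plate(lay, pore_density = 0, noise_sd = 0, pixel_size = 2.5,
                    seed = 5)
  classify <- function(img) {
    m <- remove_pores(img, threshold = "otsu")
    classify_by_size(detect_objects(m, image = img))$object_class
  }
  base <- classify(sp$image)
  lay2 <- lay
  lay2$x <- lay2$x + 100; lay2$y <- lay2$y + 75
  sp2 <- synth_plate(lay2, pore_density = 0, noise_sd = 0,
                     pixel_size = 2.5, seed = 5)
  dimmed <- plate_image(sp$image$pixels * 0.6, 2.5)
  expect_equal(sort(classify(sp2$image)), sort(base))
  expect_equal(classify(dimmed), base)
})

test_that("end-to-end plate detection registers every object within 10 um", {
  lay <- data.frame(
    x = rep(seq(100, 800, by = 100), 1),
    y = rep(100, 8),
    diameter = c(10, 18, 20, 30, 18, 10, 30, 20),
    class = c("marker_A", "cell", "marker_T", "marker_C", "cell",
              "marker_A", "marker_C", "marker_T"))
  sp <- synth_plate(lay, pore_density = 200, pore_diameter = 5,
                    noise_sd = 0.02, pixel_size = 2.5, seed = 6)
  obj <- detect_objects(remove_pores(sp$image), image = sp$image)
  obj <- classify_by_size(obj, c(size_bands(), list(cell = c(14, 16))))
  expect_equal(nrow(obj), nrow(lay))          # 100% recall and precision
  # pair detections to truth by nearest neighbor
  pair <- vapply(seq_len(nrow(obj)), function(i)
    which.min((sp$truth$x - obj$x[i])^2 + (sp$truth$y - obj$y[i])^2),
    integer(1))
  expect_equal(sort(pair), seq_len(nrow(lay)))
  err <- sqrt((obj$x - sp$truth$x[pair])^2 + (obj$y - sp$truth$y[pair])^2)
  expect_lt(max(err), 10)
})

test_that("plate images round-trip through PNG with their calibration", {
  lay <- data.frame(x = 40, y = 40, diameter = 20, class = "marker_T")
  sp <- synth_plate(lay, pore_density = 0, noise_sd = 0, pixel_size = 2.5,
                    seed = 7)
  path <- withr::local_tempfile(fileext = ".png")
  write_plate_image(sp$image, path)
  back <- read_plate_image(path)
  expect_equal(back$pixel_size, 2.5)
  expect_equal(dim(back$pixels), dim(sp$image$pixels))
  # 8-bit quantization at most
  expect_lt(max(abs(back$pixels - pmin(pmax(sp$image$pixels, 0), 1))),
            1 / 255)
})
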