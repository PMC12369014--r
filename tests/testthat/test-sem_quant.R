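test_that("preprocessing invents no structure and normalizes range", {
  const <- image_record(matrix(0.5, 256, 256), 0.05)
  out <- preprocess(const)
  expect_equal(diff(range(out$pixels)), 0)
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))
  expect_error(preprocess(image_record(matrix(0.5, 32, 32), 0.05),
                          bg_radius = 40), "kernel")
})

test_that("background subtraction flattens an illumination gradient", {
  n <- 256
  xs <- seq(0, 0.4, length.out = n)
  grad <- outer(xs, xs, `+`) / 2
  img <- grad + disk_mask(n, cbind(runif(5, 40, 216), runif(5, 40, 216)), 8) * 0.5
  rec <- image_record(pmin(img, 1), 0.05)
  out <- preprocess(rec, clahe_clip = 0)  # isolate the background correction
  # interior background region (the opening is clipped at the borders),
  # excluding a halo around each particle blurred in by the smoothing step
  core <- 45:211
  halo <- EBImage::imageData(EBImage::dilate(
    EBImage::Image((img - grad > 0.25) * 1), EBImage::makeBrush(15, "disc")))
  mask <- (halo > 0)[core, core]
  # variance of the background region drops by >= 10x after correction
  v_in <- stats::var(as.vector(rec$pixels[core, core][!mask]))
  v_out <- stats::var(as.vector(out$pixels[core, core][!mask]))
  expect_lt(v_out, v_in / 10)
})

test_that("adaptive thresholding with area filtering keeps only real particles", {
  set.seed(42)
  n <- 512
  # preprocessed-style field: 20 disks of radius 6 (~113 px) plus 30
  # three-pixel speckles on a quiet background
  cx <- 40 + 60 * (0:4); centers <- as.matrix(expand.grid(cx, cx))[1:20, ]
  big <- disk_mask(n, centers, 6)
  spk <- matrix(0, n, n)
  idx <- as.matrix(expand.grid(seq(340, 500, by = 8), seq(340, 500, by = 8)))[1:30, ]
  spk[idx] <- 1; spk[idx + 1L] <- 1
  spk[cbind(idx[, 1] + 1L, idx[, 2])] <- 1
  img <- image_record(pmin(0.05 + 0.8 * pmax(big, spk), 1), 0.05)
  mask <- binarize(img, min_area = 20)
  expect_equal(max(label_components(mask)), 20)
  # ... while a permissive area filter keeps the speckles too
  expect_equal(max(label_components(binarize(img, min_area = 1))), 50)

  # pure noise with amplitude below the offset yields an empty mask
  quiet <- image_record(matrix(0.5 + rnorm(256^2, 0, 0.005), 256, 256), 0.05)
  expect_true(all(binarize(quiet) == 0))

  expect_error(binarize(img, block_size = 4), "odd")
  expect_error(binarize(img, block_size = 1), "odd")
})

test_that("watershed splits touching disks and respects label conservation", {
  # disjoint disks stay two labels
  apart <- two_disk_mask(sep_radii = 3)
  expect_equal(max(split_touching(apart, 8)), 2)
  # centers 1.2 radii apart: one blob, split along the neck into 2
  blob <- two_disk_mask(sep_radii = 1.2)
  expect_equal(max(label_components(blob)), 1)
  lab <- split_touching(blob, 8)
  expect_equal(max(lab), 2)
  expect_true(all((lab > 0) == (blob > 0)))   # every fg pixel labeled once
  expect_true(all(tabulate(lab[lab > 0]) > 0))
  # a single convex disk is never split
  single <- disk_mask(96, cbind(48, 48), 20)
  expect_equal(max(split_touching(single, 8)), 1)
  # an empty mask has no labels
  expect_equal(max(split_touching(matrix(0, 32, 32), 8)), 0)
})

test_that("morphometrics recover analytic disk properties", {
  single <- disk_mask(96, cbind(48, 48), 20)
  m <- measure(label_components(single), pixel_size = 0.05)
  expect_equal(nrow(m), 1)
  expect_equal(m$area_px, sum(single), tolerance = 0.05)  # closing may fill
  expect_equal(m$area_um2, m$area_px * 0.05^2)
  expect_gt(m$circularity, 0.9); expect_lt(m$circularity, 1.1)
  expect_gte(m$solidity, 0.95)
  expect_equal(m$centroid_x, 48, tolerance = 0.01)

  # a two-disk dumbbell is non-convex: solidity drops below 0.9
  dumbbell <- two_disk_mask(sep_radii = 1.9)
  md <- measure(label_components(dumbbell), pixel_size = 0.05)
  expect_equal(nrow(md), 1)
  expect_lt(md$solidity, 0.9)

  # empty mask gives an empty table
  expect_equal(nrow(measure(matrix(0L, 32, 32), 0.05)), 0)
})

test_that("classification applies inclusive thresholds per the tie-break rule", {
  cell_area <- pi * 0.4^2
  p <- data.frame(label = 1:4,
                  area_px = 1, perimeter = 1,
                  area_um2 = c(cell_area, 3 * cell_area, cell_area, cell_area),
                  circularity = c(0.95, 0.95, 0.5, 0.7),
                  solidity = c(0.97, 0.97, 0.97, 0.9),
                  centroid_x = 0, centroid_y = 0)
  cls <- classify(p, area_single_max = 1.5 * cell_area)$morphology_class
  expect_equal(as.character(cls), c("single", "aggregate", "aggregate", "single"))
})

test_that("coverage scaling converts area fraction to bacterial count", {
  mask <- matrix(0, 100, 100)
  mask[1:7, 1:11] <- 1  # 77 of 1e4 pixels = 0.77% coverage
  p <- classify(measure(label_components(mask), 0.05))
  s <- summarize_adhesion(p, mask)
  expect_equal(s$coverage_fraction, 77 / 1e4)
  expect_equal(s$scaled_count, (77 / 1e4) / 7.7e-5)  # = 100
  expect_equal(s$n_total, s$n_single + s$n_aggregate)

  empty <- summarize_adhesion(p[0, ], matrix(0, 10, 10))
  expect_equal(empty$scaled_count, 0)
  expect_error(summarize_adhesion(p, mask, per_bacterium_fraction = 0),
               "positive")
})

test_that("areas are scale-equivariant under pixel size", {
  single <- disk_mask(96, cbind(48, 48), 20)
  lab <- label_components(single)
  m1 <- measure(lab, pixel_size = 0.05)
  m2 <- measure(lab, pixel_size = 0.10)
  expect_equal(m2$area_um2, 4 * m1$area_um2)
  expect_equal(m2$area_px, m1$area_px)
  expect_equal(m2$circularity, m1$circularity)
})
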