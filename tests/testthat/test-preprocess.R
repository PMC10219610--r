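# Max-pool downscaling, center cropping and the joint image/mask
# augmentation recipe.

test_that("max-pool downscaling reduces the lattice window-wise", {
  expect_equal(downscale_maxpool(matrix(3, 9, 9), 3), matrix(3, 3, 3))
  # single bright pixel at (5, 6): lands in output window (2, 2)
  m <- matrix(0, 6, 6); m[5, 6] <- 9
  out <- downscale_maxpool(m, 3)
  expect_equal(dim(out), c(2L, 2L))
  expect_equal(out[2, 2], 9)
  expect_equal(sum(out), 9)
  # kernel 1 is the identity
  r <- matrix(runif(20), 4)
  expect_equal(downscale_maxpool(r, 1), r)
  # trailing rows/cols that do not fill a window are dropped
  expect_equal(dim(downscale_maxpool(matrix(0, 7, 8), 3)), c(2L, 2L))
  expect_error(downscale_maxpool(matrix(0, 2, 2), 3), "exceeds")
})

test_that("pooling preserves local maxima and scales spacing", {
  set.seed(2)
  img <- matrix(runif(30 * 30), 30)
  spacing_cm(img) <- 0.05
  out <- downscale_maxpool(img, 3)
  expect_equal(spacing_cm(out), 0.15)
  expect_equal(max(out), max(img[1:30, 1:30]))
  # every output pixel is the max of its source window
  for (q in 1:5) {
    i <- sample(10, 1); j <- sample(10, 1)
    expect_equal(out[i, j], max(img[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]))
  }
})

test_that("center crop places the floor-centred window on image and mask", {
  img <- matrix(rep(seq_len(10) - 1, 10), 10)   # pixel value = 0-based row
  msk <- (img %% 2 == 0) * 1
  cr <- center_crop(img, msk, 4)
  expect_equal(cr$image[, 1], c(3, 4, 5, 6))    # 0-based rows 3..6 retained
  expect_equal(cr$offset, c(3L, 3L))
  expect_equal(cr$mask, msk[4:7, 4:7])
  # full-size crop is the identity
  cr2 <- center_crop(img, msk, c(10, 10))
  expect_equal(cr2$image, img)
  expect_equal(cr2$offset, c(0L, 0L))
  expect_error(center_crop(img, msk, 11), "exceeds")
  # a tip inside the window shifts by exactly the top-left offset
  ph <- generate_phantom(phantom_params(image_size = c(64, 64),
                                        tip_row_frac = c(0.5, 0.6)), seed = 4)
  cr3 <- center_crop(ph$image, ph$mask, 48)
  tip2 <- extract_tip(cr3$mask, spacing = 0.05)
  expect_equal(tip2$row, ph$tip$row - cr3$offset[1])
  expect_equal(tip2$col, ph$tip$col - cr3$offset[2])
})

test_that("identity augmentation parameters leave the pair unchanged", {
  ph <- generate_phantom(phantom_params(), seed = 10)
  id <- augment_params(hflip_prob = 0, scale_range = c(1, 1), rotate_deg = 0,
                       shift_frac = 0, clahe_prob = 0)
  a <- augment(ph$image, ph$mask, id)
  expect_equal(a$image, ph$image, ignore_attr = TRUE)
  expect_equal(a$mask, ph$mask, ignore_attr = TRUE)
})

test_that("augmentation is reproducible per seed and keeps masks binary", {
  ph <- generate_phantom(phantom_params(), seed = 20)
  pars <- augment_params(seed = 77)
  a1 <- augment(ph$image, ph$mask, pars)
  a2 <- augment(ph$image, ph$mask, pars)
  expect_identical(a1, a2)
  expect_true(all(a1$mask %in% c(0, 1)))
  expect_true(all(a1$image >= 0 & a1$image <= 1))
  # different seeds produce different transforms
  a3 <- augment(ph$image, ph$mask, augment_params(seed = 78))
  expect_false(identical(a1$mask, a3$mask))
  # an empty mask never grows foreground
  e <- augment(ph$image, ph$mask * 0, pars)
  expect_equal(sum(e$mask), 0)
})

test_that("image and mask receive the identical geometric transform", {
  ph <- generate_phantom(phantom_params(), seed = 30)
  # pure flip: exact equality when the mask rides along as the image
  flip_only <- augment_params(hflip_prob = 1, scale_range = c(1, 1),
                              rotate_deg = 0, shift_frac = 0, clahe_prob = 0,
                              seed = 5)
  a <- augment(ph$mask, ph$mask, flip_only)
  expect_equal(a$image, a$mask, ignore_attr = TRUE)
  # general affine: bilinear(image)/nearest(mask) may differ only on the
  # component boundary, so thresholding the warped mask-as-image must agree
  # with the warped mask away from a thin rim
  gen <- augment_params(hflip_prob = 0.5, clahe_prob = 0, seed = 6)
  b <- augment(ph$mask, ph$mask, gen)
  bin <- (b$image > 0.5) * 1
  disagree <- sum(bin != b$mask)
  expect_lt(disagree, 0.25 * sum(b$mask) + 5)
  # foreground survives the transform
  expect_gt(sum(b$mask), 0.5 * sum(ph$mask))
})

test_that("tip coordinates track the pool-then-crop composition", {
  for (sd in 1:5) {
    ph <- generate_phantom(phantom_params(image_size = c(90, 90)), seed = sd)
    pooled <- downscale_maxpool(ph$mask, 3)
    cr <- center_crop(pooled, pooled, c(28, 28))
    tip_direct <- extract_tip(cr$mask, spacing = 0.15)
    # map the original tip: 1-based pooling then crop-offset arithmetic
    mapped_row <- floor((ph$tip$row - 1) / 3) + 1 - cr$offset[1]
    mapped_col <- floor((ph$tip$col - 1) / 3) + 1 - cr$offset[2]
    expect_lte(abs(tip_direct$row - mapped_row), 1)
    expect_lte(abs(tip_direct$col - mapped_col), 1)
  }
})

test_that("manifests round-trip through CSV with resolved paths", {
  dir <- file.path(tempdir(), "man_rt")
  man <- generate_dataset(3, phantom_params(image_size = c(48, 48)), dir,
                          seed = 3)
  expect_true(all(file.exists(man$image_path)))
  man2 <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(man2$tip_row, man$tip_row)
  expect_equal(man2$spacing_cm, rep(0.05, 3))
  s <- load_sample(man2[2, ])
  expect_true(all(s$mask %in% c(0, 1)))
  expect_equal(spacing_cm(s$image), 0.05)
  unlink(dir, recursive = TRUE)
})
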