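test_that("intensity transform hits its closed-form anchor points", {
  expect_identical(intensity_transform(0, 1, 30), 0)
  for (k in c(30, 8, 2))
    expect_equal(intensity_transform(5, 5, k), 1 - exp(-k), tolerance = 1e-15)
  expect_equal(intensity_transform(0.5, 1, 30), 1 - exp(-15), tolerance = 1e-15)
  expect_error(intensity_transform(1, 0, 30), "dmax")
  expect_error(intensity_transform(1, -2, 30), "dmax")
  expect_error(intensity_transform(1, 1, 0), "k")
  expect_error(intensity_transform(-1, 1, 2), "nonnegative")
})

test_that("intensity transform is strictly increasing and rescale-invariant", {
  set.seed(41)
  d <- sort(runif(2000, 0, 10))
  for (k in c(30, 8, 2)) {
    v <- intensity_transform(d, 10, k)
    # strictly increasing up to double-precision saturation at 1
    expect_true(all(diff(v) >= 0))
    expect_true(all(diff(v)[v[-length(v)] < 1 - 1e-12] > 0))
    expect_true(all(v >= 0 & v < 1))
    c_scale <- 7.3
    expect_equal(intensity_transform(c_scale * d, c_scale * 10, k), v,
                 tolerance = 1e-12)
  }
})

test_that("RGB composition maps class densities to the documented channels", {
  counts <- array(0L, c(6, 6, 6, 4))
  counts[2, 2, 2, 2] <- 4L                    # commissural only -> pure red
  counts[3, 3, 3, 1] <- 2L; counts[3, 3, 3, 2] <- 2L  # equal proj/comm
  counts[4, 4, 4, 3] <- 1L; counts[4, 4, 4, 4] <- 2L  # association
  d <- structure(list(counts = counts, affine = diag(4),
                      channels = TDRM_CLASSES), class = "tdrm_density")
  rgb <- compose_rgb(d)
  expect_gt(rgb$rgb[2, 2, 2, 1], 0)
  expect_identical(rgb$rgb[2, 2, 2, 2], 0)
  expect_identical(rgb$rgb[2, 2, 2, 3], 0)
  expect_identical(rgb$rgb[3, 3, 3, 1], rgb$rgb[3, 3, 3, 2])  # yellowish
  # association channel is short+long summed before the transform
  expect_equal(rgb$rgb[4, 4, 4, 3], intensity_transform(3, 4, 30))
  expect_identical(rgb$assignment$B, c("short_assoc", "long_assoc"))

  # association mode normalises over its own displayed channels (max = 2)
  assoc <- compose_rgb(d, mode = "association")
  expect_equal(assoc$rgb[4, 4, 4, 1], intensity_transform(1, 2, 30))
  expect_equal(assoc$rgb[4, 4, 4, 2], intensity_transform(2, 2, 30))
  expect_identical(max(assoc$rgb[, , , 3]), 0)

  expect_warning(z <- compose_rgb(structure(list(counts = array(0L, c(3, 3, 3, 4)),
                                                 affine = diag(4),
                                                 channels = TDRM_CLASSES),
                                            class = "tdrm_density")),
                 "all-zero")
  expect_identical(max(z$rgb), 0)
})

test_that("global dmax preserves the ordinal relation between class densities", {
  ph <- small_phantom()
  d <- voxel_density(small_classified(), ph$tracks, ph$tissue)
  rgb <- compose_rgb(d, dmax_mode = "global")
  comm <- d$counts[, , , 2]; proj <- d$counts[, , , 1]
  gt <- comm > proj
  expect_true(all(rgb$rgb[, , , 1][gt] > rgb$rgb[, , , 2][gt]))
})

test_that("grayscale total map has equal channels and the k = 2 anchor", {
  counts <- array(0L, c(5, 5, 5, 4))
  counts[2, 2, 2, ] <- c(1L, 2L, 0L, 1L)     # total 4 = max
  counts[3, 3, 3, 1] <- 2L
  d <- structure(list(counts = counts, affine = diag(4),
                      channels = TDRM_CLASSES), class = "tdrm_density")
  g <- grayscale_total(d)
  expect_identical(g$rgb[, , , 1], g$rgb[, , , 2])
  expect_identical(g$rgb[, , , 2], g$rgb[, , , 3])
  expect_equal(g$rgb[2, 2, 2, 1], 1 - exp(-2), tolerance = 1e-15)
  expect_identical(g$rgb[1, 1, 1, 1], 0)
})

test_that("slice stacking obeys the painter's rule and the exclusion threshold", {
  counts <- array(0L, c(8, 8, 8, 4))
  counts[3, 4, 2, 1] <- 1L         # two voxels on the same superior ray
  counts[3, 4, 6, 2] <- 3L
  d <- structure(list(counts = counts, affine = diag(4),
                      channels = TDRM_CLASSES), class = "tdrm_density")
  rgb <- compose_rgb(d)
  sup <- stack_projection(rgb, "superior")    # later slice (higher z) wins
  expect_equal(sup$image[3, 4, ],
               c(rgb$rgb[3, 4, 6, 1], rgb$rgb[3, 4, 6, 2], rgb$rgb[3, 4, 6, 3]))
  inf <- stack_projection(rgb, "inferior")    # traversal reversed
  expect_equal(inf$image[3, 4, ],
               c(rgb$rgb[3, 4, 2, 1], rgb$rgb[3, 4, 2, 2], rgb$rgb[3, 4, 2, 3]))
  # raising the threshold above the low-density voxel changes the winner
  inf2 <- stack_projection(rgb, "inferior", threshold = 1)
  expect_equal(inf2$image[3, 4, 2], rgb$rgb[3, 4, 6, 2])
  expect_error(stack_projection(rgb, "oblique"), "unknown view")
})

test_that("a single nonzero voxel paints exactly one pixel in each whole-volume view", {
  counts <- array(0L, c(9, 9, 9, 4))
  counts[3, 5, 6, 2] <- 2L          # world x < 0 under a centred affine
  aff <- diag(4); aff[1:3, 4] <- -4
  d <- structure(list(counts = counts, affine = aff,
                      channels = TDRM_CLASSES), class = "tdrm_density")
  rgb <- compose_rgb(d)
  for (v in c("superior", "inferior", "anterior", "posterior",
              "left-lateral", "right-lateral")) {
    img <- stack_projection(rgb, v)$image
    expect_equal(sum(apply(img, 1:2, max) > 0), 1L, info = v)
  }
  # the voxel sits on the left; only the left medial view shows it
  expect_equal(sum(stack_projection(rgb, "medial-L")$image > 0), 1L)
  expect_equal(sum(stack_projection(rgb, "medial-R")$image > 0), 0L)
})

test_that("projections ignore slices containing only sub-threshold voxels", {
  counts <- array(0L, c(8, 8, 8, 4))
  counts[4, 4, 4, 1] <- 5L
  d1 <- structure(list(counts = counts, affine = diag(4),
                       channels = TDRM_CLASSES), class = "tdrm_density")
  counts2 <- counts
  counts2[1:8, 1:8, 7, 2] <- 1L     # an extra slice, all below threshold 2
  d2 <- structure(list(counts = counts2, affine = diag(4),
                       channels = TDRM_CLASSES), class = "tdrm_density")
  r1 <- compose_rgb(d1); r2 <- compose_rgb(d2)
  p1 <- stack_projection(r1, "superior", threshold = 2)
  p2 <- stack_projection(r2, "superior", threshold = 2)
  expect_equal(p2$image[4, 4, ], p1$image[4, 4, ])
  expect_equal(sum(apply(p2$image, 1:2, max) > 0), 1L)
})

test_that("superior and inferior views of a z-mirror-symmetric volume coincide", {
  ph <- small_phantom()
  d <- voxel_density(small_classified(), ph$tracks, ph$tissue)
  sym <- d$counts + d$counts[, , dim(d$counts)[3]:1, , drop = FALSE]
  ds <- structure(list(counts = sym, affine = d$affine, channels = d$channels),
                  class = "tdrm_density")
  rgb <- compose_rgb(ds)
  sup <- stack_projection(rgb, "superior")$image
  inf <- stack_projection(rgb, "inferior")$image
  expect_equal(sup, inf)
})

test_that("parcel maps paint each parcel uniformly with its transformed densities", {
  ph <- small_phantom()
  cl <- small_classified()
  pd <- parcel_density(cl, ph$tracks, ph$parcellation, ph$lookup)
  pm <- render_parcel_map(pd, ph$parcellation, k = 8)
  parc <- pd[pd$label > 0L, ]
  dmax <- max(c(parc$density_commissural, parc$density_projection,
                parc$density_short_assoc + parc$density_long_assoc))
  lab1 <- parc$label[1]
  vox <- which(ph$parcellation$labels == lab1)
  red <- pm$rgb[, , , 1][vox]
  expect_equal(unique(red),
               intensity_transform(parc$density_commissural[1], dmax, 8))
  blue <- pm$rgb[, , , 3][vox]
  expect_equal(unique(blue),
               intensity_transform(parc$density_short_assoc[1] +
                                   parc$density_long_assoc[1], dmax, 8))
  # a parcel with zero density stays black; missing labels warn
  pd0 <- pd
  for (col in grep("^density_", names(pd0), value = TRUE)) pd0[[col]][1] <- 0
  pm0 <- render_parcel_map(pd0, ph$parcellation)
  expect_identical(max(pm0$rgb[, , , 1][vox], pm0$rgb[, , , 2][vox],
                       pm0$rgb[, , , 3][vox]), 0)
  pd_extra <- rbind(pd, pd[1, ])
  pd_extra$label[nrow(pd_extra)] <- 99L
  pd_extra$name[nrow(pd_extra)] <- "ghost"
  expect_warning(render_parcel_map(pd_extra, ph$parcellation), "missing")
})

test_that("projection PNGs are written deterministically at 8-bit depth", {
  ph <- small_phantom()
  d <- voxel_density(small_classified(), ph$tracks, ph$tissue)
  pr <- stack_projection(compose_rgb(d), "superior")
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  write_projection_png(pr, f1)
  write_projection_png(pr, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  img <- png::readPNG(f1)
  expect_equal(dim(img)[1:2], dim(pr$image)[2:1])
  expect_true(all(abs(img * 255 - round(img * 255)) < 1e-9))
})
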