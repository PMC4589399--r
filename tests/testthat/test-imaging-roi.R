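test_that("ellipsoid ROIs select voxel centers inside the ellipsoid", {
  vol <- uniformVolume(nf = 2L, d = c(9L, 9L, 9L))
  tiny <- ellipsoidROI(vol, center = c(5, 5, 5), semiAxes = rep(0.4, 3))
  expect_equal(maskCoords(tiny), cbind(z = 5L, y = 5L, x = 5L),
               ignore_attr = TRUE)
  all9 <- ellipsoidROI(vol, center = c(5, 5, 5), semiAxes = rep(100, 3))
  expect_equal(roiSize(all9), 9L^3)
  expect_error(ellipsoidROI(vol, center = c(-30, -30, -30),
                            semiAxes = rep(0.4, 3)), "intersect")
})

test_that("a 2.5-voxel sphere contains exactly the 81 lattice points of the oracle", {
  vol <- uniformVolume(nf = 1L, d = c(15L, 15L, 15L))
  roi <- ellipsoidROI(vol, center = c(8, 8, 8), semiAxes = rep(2.5, 3))
  # independent brute-force count of x^2+y^2+z^2 <= 2.5^2
  g <- expand.grid(z = -7:7, y = -7:7, x = -7:7)
  oracle <- sum(g$z^2 + g$y^2 + g$x^2 <= 6.25)
  expect_equal(oracle, 81L)
  expect_equal(roiSize(roi), oracle)
})

test_that("region growing floods the whole component of a uniform image", {
  vol <- uniformVolume(value = 2, nf = 1L, d = c(5L, 5L, 5L))
  init <- roiMask(cbind(3, 3, 3), c(5L, 5L, 5L))
  grown <- regionGrowRefine(vol, init)
  expect_equal(roiSize(grown), 125L)
})

test_that("region growing returns the seed alone when nothing else is in band", {
  vol <- uniformVolume(value = 0.1, nf = 1L, d = c(5L, 5L, 5L))
  vol@data[1, 3, 3, 3] <- 1          # seed in band, neighbours far below it
  init <- roiMask(cbind(3, 3, 3), c(5L, 5L, 5L))
  grown <- regionGrowRefine(vol, init)
  expect_equal(maskCoords(grown), cbind(z = 3L, y = 3L, x = 3L),
               ignore_attr = TRUE)
})

test_that("region growing flags a seed that falls outside its own band", {
  # hot seed over a large dim initial ROI: the band hugs the ROI mean
  vol <- uniformVolume(value = 1, nf = 1L, d = c(7L, 7L, 7L))
  vol@data[1, 4, 4, 4] <- 100
  init <- ellipsoidROI(vol, center = c(4, 4, 4), semiAxes = rep(3, 3))
  expect_warning(grown <- regionGrowRefine(vol, init), "band")
  expect_equal(roiSize(grown), 1L)
})

test_that("region growing recovers a hot sphere exactly, matching a flood-fill oracle", {
  d <- c(20L, 20L, 20L)
  vol <- uniformVolume(value = 1, nf = 2L, d = d)
  sphere <- ellipsoidROI(vol, center = c(10, 10, 10), semiAxes = rep(3.2, 3))
  for (i in seq_len(nrow(maskCoords(sphere)))) {
    cc <- maskCoords(sphere)[i, ]
    vol@data[, cc[1], cc[2], cc[3]] <- 10
  }
  # manual ROI straddles the lesion edge: sphere plus a background shell
  init <- ellipsoidROI(vol, center = c(10, 10, 10), semiAxes = rep(3.5, 3))
  grown <- regionGrowRefine(vol, init)
  img <- dynFDG:::.timeAveragedImage(vol)
  m <- mean(img[dynFDG:::.linIndex(maskCoords(init), d)])
  oracle <- floodFillOracle(img, c(10, 10, 10), 0.6 * m, 1.4 * m)
  o <- oracle[order(oracle[, 1], oracle[, 2], oracle[, 3]), ]
  expect_equal(unname(maskCoords(grown)), unname(o))
  expect_equal(unname(maskCoords(grown)), unname(maskCoords(sphere)))
})

test_that("grown regions are connected supersets of the seed inside the band", {
  set.seed(8)
  d <- c(12L, 12L, 12L)
  vol <- uniformVolume(nf = 1L, d = d)
  vol@data[] <- runif(length(vol@data), 0.5, 1.5)
  init <- ellipsoidROI(vol, center = c(6, 6, 6), semiAxes = rep(2, 3))
  # keep the manual ROI itself homogeneous so its hottest voxel sits in band
  for (i in seq_len(roiSize(init))) {
    cc <- maskCoords(init)[i, ]
    vol@data[1, cc[1], cc[2], cc[3]] <- runif(1, 0.9, 1.1)
  }
  grown <- regionGrowRefine(vol, init)
  img <- dynFDG:::.timeAveragedImage(vol)
  lin <- dynFDG:::.linIndex(maskCoords(init), d)
  m <- mean(img[lin])
  seed <- lin[which.max(img[lin])]
  glin <- dynFDG:::.linIndex(maskCoords(grown), d)
  expect_true(seed %in% glin)
  expect_true(all(img[glin] >= 0.6 * m & img[glin] <= 1.4 * m))
  # connectivity: flood fill from the seed over the grown set returns it all
  inset <- array(FALSE, d); inset[maskCoords(grown)] <- TRUE
  sc <- dynFDG:::.coordsFromLin(seed, d)
  reach <- floodFillOracle(ifelse(inset, 1, 0), as.integer(sc), 0.5, 1.5)
  expect_equal(nrow(reach), roiSize(grown))
})

test_that("TAC extraction is a per-frame ROI mean and linear in intensities", {
  vol <- uniformVolume(value = 5)
  one <- roiMask(cbind(2, 3, 4), c(6L, 6L, 6L))
  vol@data[, 2, 3, 4] <- c(1, 2, 3, 4)
  expect_equal(activity(extractTAC(vol, one)), c(1, 2, 3, 4))
  set.seed(1)
  vol@data[] <- runif(length(vol@data))
  roi <- ellipsoidROI(vol, center = c(3, 3, 3), semiAxes = rep(1.5, 3))
  a <- activity(extractTAC(vol, roi))
  vol2 <- vol; vol2@data <- 2 * vol@data
  expect_equal(activity(extractTAC(vol2, roi)), 2 * a)
})

test_that("SUV normalizes concentration by dose per body weight", {
  expect_equal(computeSUV(1, 10, 10), 1)
  expect_equal(computeSUV(0, 5, 20), 0)
  expect_equal(computeSUV(0.5, 5.55, 21.1), 0.5 / (5.55 / 21.1))
  expect_error(computeSUV(1, 0, 10), "positive")
  expect_error(computeSUV(1, 10, -1), "positive")
})

test_that("SUVmax analysis reads the final frame and ignores added cold voxels", {
  vol <- uniformVolume(value = 1)
  roi <- ellipsoidROI(vol, center = c(3, 3, 3), semiAxes = rep(1.5, 3))
  rec <- suvmaxStatic(vol, roi, injectedDose = 10, bodyWeight = 10)
  expect_equal(rec@suvMax, rec@suvMean)
  vol@data[4, 3, 3, 3] <- 2          # hot voxel on the last frame only
  rec2 <- suvmaxStatic(vol, roi, 10, 10)
  expect_equal(rec2@suvMax, 2)
  big <- ellipsoidROI(vol, center = c(3, 3, 3), semiAxes = rep(10, 3))
  rec3 <- suvmaxStatic(vol, big, 10, 10)
  expect_equal(rec3@suvMax, 2)       # invariant to colder voxels
  expect_lt(rec3@suvMean, rec2@suvMean)
  expect_equal(rec2@frameWindow, c(3, 4))
})
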