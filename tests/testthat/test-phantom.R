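test_that("segmentation generation is deterministic and fraction-valid", {
  cfg <- tinyConfig(seed = 42)
  seg1 <- makeSegmentation(cfg)
  seg2 <- makeSegmentation(cfg)
  expect_identical(mapData(seg1), mapData(seg2))

  s <- mapData(seg1)
  set.seed(1)
  ix <- sample(length(s$gm), 1000, replace = TRUE)
  sums <- s$gm[ix] + s$wm[ix] + s$csf[ix] + s$tm[ix]
  expect_true(all(sums <= 1 + 1e-9))
  expect_true(all(sums >= -1e-9))
})

test_that("a zero tumor count yields an identically-zero tumor map", {
  seg <- makeSegmentation(phantomConfig(gridDim = c(32, 32), tumorCount = 0,
                                        seed = 5))
  expect_true(all(mapData(seg)$tm == 0))
})

test_that("grids not divisible by the factor are rejected", {
  expect_error(phantomConfig(gridDim = c(30, 30), factor = 4),
               "not divisible")
})

test_that("composition applies the fixed tissue weights before normalization", {
  seg <- pureSegmentation()
  raw <- mapData(composeVHR(seg, 0.8, normalize = FALSE))
  expect_equal(raw[2, 2], 0.10)        # pure GM
  expect_equal(raw[3, 3], 0.12)        # pure WM
  expect_equal(raw[4, 4], 0)           # CSF contributes nothing
  expect_equal(raw[5, 5], 0.8)         # pure tumor at tau
  expect_equal(raw[6, 6], 0.5 * 0.10 + 0.5 * 0.12)  # partial volume

  norm <- mapData(composeVHR(seg, 0.8))
  expect_equal(max(norm), 1)           # map max normalized to 1
  expect_equal(norm[5, 5], 1)          # the pure-tumor voxel is the max
})

test_that("composition is linear in tau on tumor voxels", {
  seg <- makeSegmentation(tinyConfig(seed = 9))
  m2 <- mapData(composeVHR(seg, 0.2, normalize = FALSE))
  m4 <- mapData(composeVHR(seg, 0.4, normalize = FALSE))
  tm <- mapData(seg)$tm
  vox <- which(tm > 0.5)
  set.seed(2)
  vox <- vox[sample(length(vox), min(100, length(vox)))]
  # difference of the two maps isolates the tumor term: (0.4-0.2)*tm
  expect_lt(max(abs((m4[vox] - m2[vox]) - 0.2 * tm[vox])), 1e-12)
})

test_that("degenerate compositions warn and tau is validated", {
  z <- array(0, c(8, 8))
  seg0 <- new("TissueSegmentation", gm = z, wm = z, csf = z, tm = z,
              voxelSize = c(1, 1))
  expect_warning(m <- composeVHR(seg0, 0.2), "all-zero")
  expect_true(all(mapData(m) == 0))
  expect_error(composeVHR(pureSegmentation(), 0.25), "allowed grid")
})

test_that("kspace_sharp truth preserves constants and shows ringing on disks", {
  const <- MetabolicMap(matrix(0.6, 64, 64), tier = "VHR")
  hr <- makeHRTruth(const, "kspace_sharp", targetDim = c(32, 32))
  expect_lt(max(abs(mapData(hr) - 0.6)), 1e-10)

  disk <- MetabolicMap(diskImage(64), tier = "VHR")
  hr2 <- makeHRTruth(disk, "kspace_sharp", targetDim = c(32, 32))
  decim <- diskImage(64)[seq(1, 64, by = 2), seq(1, 64, by = 2)]
  expect_gt(max(abs(mapData(hr2) - decim)), 0.01)   # Gibbs ringing present

  # full-scale shape mapping
  big <- MetabolicMap(matrix(rnorm(256 * 256), 256), tier = "VHR")
  expect_identical(dim(makeHRTruth(big, "kspace_sharp",
                                   targetDim = c(184, 184))),
                   c(184L, 184L))
})

test_that("fnlm_smooth truth requires priors and differs from the sharp one", {
  ds <- tinyDataset()
  p <- ds$pairs[[1]]
  vhr <- hrMap(p)
  expect_error(makeHRTruth(vhr, "fnlm_smooth", lr = lrMap(p)), "prior")
  sm <- makeHRTruth(vhr, "fnlm_smooth", lr = lrMap(p), prior = priorMaps(p))
  expect_identical(dim(sm), dim(vhr))
  expect_gt(max(abs(mapData(sm) - mapData(vhr))), 1e-4)
})

test_that("augmentation identities hold and crops stay LR/HR consistent", {
  ds <- tinyDataset()
  p <- ds$pairs[[1]]
  same <- augmentPair(p, cropSize = NULL, flip = FALSE)
  expect_identical(mapData(lrMap(same)), mapData(lrMap(p)))
  expect_identical(mapData(hrMap(same)), mapData(hrMap(p)))

  # flips are involutions: flipping twice along fixed axes is the identity
  flipBoth <- function(a) a[rev(seq_len(nrow(a))), rev(seq_len(ncol(a)))]
  expect_identical(flipBoth(flipBoth(mapData(hrMap(p)))), mapData(hrMap(p)))

  set.seed(3)
  ap <- augmentPair(p, cropSize = 4L, flip = TRUE)
  expect_identical(dim(lrMap(ap)), c(4L, 4L))
  expect_identical(dim(hrMap(ap)), c(16L, 16L))
  # interior of degrade(HR crop) matches the LR crop up to a boundary band
  deg <- fftDownsample(mapData(hrMap(ap)), 4)
  err <- abs(deg - mapData(lrMap(ap)))[2:3, 2:3]
  expect_lt(max(err), 0.25 * diff(range(mapData(lrMap(p)))))
  expect_error(augmentPair(p, cropSize = 99L), "larger")
})

test_that("dataset generation cycles tau, is deterministic and consistent", {
  ds <- generateDataset(7, tinyConfig(seed = 2), seed = 30,
                        validationFraction = 0)
  expect_equal(sort(ds$manifest$tau), tauGrid())

  ds2 <- generateDataset(7, tinyConfig(seed = 2), seed = 30,
                         validationFraction = 0)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(mapData(hrMap(ds$pairs[[3]])),
                   mapData(hrMap(ds2$pairs[[3]])))

  for (p in ds$pairs)   # Fourier round-trip consistency of kspace_sharp pairs
    expect_lt(max(abs(fftDownsample(mapData(hrMap(p)), 4) -
                        mapData(lrMap(p)))), 1e-8)
})

test_that("written datasets carry a manifest and voxel-size-correct volumes", {
  out <- withr::local_tempdir()
  ds <- generateDataset(2, tinyConfig(seed = 4), seed = 7, outDir = out)
  expect_true(file.exists(file.path(out, "manifest.tsv")))
  lr <- readVolume(ds$manifest$lr_path[1])
  hr <- readVolume(ds$manifest$hr_path[1], tier = "HR")
  expect_equal(voxelSize(lr)[1], 4 * voxelSize(hr)[1], tolerance = 1e-5)
})
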