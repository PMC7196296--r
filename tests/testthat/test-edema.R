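test_that("the Gaussian histogram fit recovers generator parameters", {
  set.seed(21)
  hm <- makeHemiMRI(c(60L, 60L, 60L), vox = 0.4,
                    intensities = function(n) rnorm(n, 100, 10))
  fit <- fitBackgroundGaussian(hm$mri, hm$labels)
  expect_gt(fit@nVoxels, 1e5)
  expect_lt(abs(fit@mu - 100), 1)      # within 1%
  expect_lt(abs(fit@sigma - 10), 0.1)  # within 1%
})

test_that("a minority bright component does not drag the parenchymal fit", {
  set.seed(22)
  mix <- function(n) {
    bright <- runif(n) < 0.024
    ifelse(bright, rnorm(n, 200, 10), rnorm(n, 100, 10))
  }
  hm <- makeHemiMRI(c(60L, 60L, 60L), intensities = mix)
  fit <- fitBackgroundGaussian(hm$mri, hm$labels)
  expect_lt(abs(fit@mu - 100), 2)      # within 2%
})

test_that("degenerate hemispheres are rejected", {
  hm <- makeHemiMRI(c(20L, 20L, 20L), intensities = function(n) rep(5, n))
  expect_error(fitBackgroundGaussian(hm$mri, hm$labels), "constant")
  tiny <- makeHemiMRI(c(8L, 8L, 8L))
  expect_error(fitBackgroundGaussian(tiny$mri, tiny$labels), "too few")
})

test_that("the threshold is two fitted SDs on the bright side", {
  fit <- new("GaussianFit", mu = 100, sigma = 10, binWidth = 1, rss = 0,
             nVoxels = 1000L)
  expect_equal(as.numeric(edemaThreshold(fit)), 120)
  expect_equal(as.numeric(edemaThreshold(fit, direction = "below")), 80)
})

test_that("a pure-Gaussian hemisphere excludes the Phi(2) fraction", {
  set.seed(23)
  hm <- makeHemiMRI(c(60L, 60L, 60L))
  fit <- fitBackgroundGaussian(hm$mri, hm$labels)
  res <- quantifyEdema(hm$mri, hm$labels, fit)
  expect_equal(res@excludedFractionContra, pnorm(2), tolerance = 0.005)
})

test_that("a designed hyperintense blob is recovered within a voxel layer", {
  set.seed(24)
  hm <- makeHemiMRI(c(40L, 44L, 40L), vox = 0.4)
  vv <- voxelVolume(hm$mri)
  vals <- voxelData(hm$mri)
  ## 40 mm^3 blob in the ipsilesional hemisphere
  nBlob <- round(40 / vv)
  blobIdx <- which(hemisphereIDs(hm$labels) == 1L)[seq_len(nBlob)]
  vals[blobIdx] <- rnorm(nBlob, 200, 10)
  mri <- VolumeGrid(vals, spacing = 0.4, modality = "MRI")
  fit <- fitBackgroundGaussian(mri, hm$labels)
  res <- quantifyEdema(mri, hm$labels, fit)
  ## the contralesional subtraction removes the symmetric Gaussian tail
  expect_lt(abs(res@correctedInfarctVolume - nBlob * vv), 10)
  expect_false(res@ventricleMissing)
})

test_that("hemispheric swelling is subtracted from the edema volume", {
  set.seed(25)
  dm <- c(40L, 44L, 40L); vox <- 0.4
  hemi <- array(2L, dm)
  hemi[1:20, , ] <- 1L
  vals <- array(rnorm(prod(dm), 100, 10), dm)
  ## swell the ipsilesional hemisphere by ~10 mm^3 of extra voxels taken
  ## from outside the brain: mark a 21st slab column as ipsilesional
  extra <- round(10 / vox^3)
  swellIdx <- which(hemi == 2L)[seq_len(extra)]
  hemi[swellIdx] <- 1L
  lab <- LabelVolume(array(0L, dm), hemi, spacing = vox)
  nBlob <- round(40 / vox^3)
  blobIdx <- which(hemi == 1L)[seq_len(nBlob)]
  vals[blobIdx] <- rnorm(nBlob, 200, 10)
  mri <- VolumeGrid(vals, spacing = vox, modality = "MRI")
  fit <- fitBackgroundGaussian(mri, lab)
  res <- quantifyEdema(mri, lab, fit)
  swell <- res@hemisphereVolumes[["ipsi"]] - res@hemisphereVolumes[["contra"]]
  expect_equal(swell, 2 * extra * vox^3, tolerance = 1e-9)
  expect_equal(res@correctedInfarctVolume,
               res@rawEdemaVolume - res@ventricleVolume - swell,
               tolerance = 1e-9)
})

test_that("raising the threshold never increases the raw edema volume", {
  set.seed(26)
  hm <- makeHemiMRI(c(30L, 30L, 30L))
  fit <- fitBackgroundGaussian(hm$mri, hm$labels)
  r2 <- quantifyEdema(hm$mri, hm$labels, fit, nSD = 2)
  r3 <- quantifyEdema(hm$mri, hm$labels, fit, nSD = 3)
  expect_lte(r3@rawEdemaVolume, r2@rawEdemaVolume)
})

test_that("affine intensity transforms shift the fit and leave volumes fixed", {
  set.seed(27)
  hm <- makeHemiMRI(c(30L, 32L, 30L))
  fit1 <- fitBackgroundGaussian(hm$mri, hm$labels, binWidth = 2)
  r1 <- quantifyEdema(hm$mri, hm$labels, fit1)
  mri2 <- VolumeGrid(3 * voxelData(hm$mri) + 7, spacing = voxelSize(hm$mri),
                     modality = "MRI")
  fit2 <- fitBackgroundGaussian(mri2, hm$labels, binWidth = 6)
  r2 <- quantifyEdema(mri2, hm$labels, fit2)
  expect_lt(abs(fit2@mu - (3 * fit1@mu + 7)), 0.5)
  expect_lt(abs(fit2@sigma - 3 * fit1@sigma), 0.3)
  expect_lt(abs(r2@threshold - (3 * r1@threshold + 7)), 1)
  expect_lt(abs(r2@rawEdemaVolume - r1@rawEdemaVolume), 1)
})

test_that("the phantom edema pipeline reports every correction term", {
  st <- smallStudy()
  mriV <- st@mri$treated$t1$d7
  fit <- fitBackgroundGaussian(mriV, st@mriLabels)
  res <- quantifyEdema(mriV, st@mriLabels, fit)
  expect_gt(res@rawEdemaVolume, 0)
  expect_gt(res@ventricleVolume, 0)
  swell <- res@hemisphereVolumes[["ipsi"]] - res@hemisphereVolumes[["contra"]]
  expect_equal(swell, st@truth$edema$swellingMM3, tolerance = 1e-6)
  expect_equal(res@correctedInfarctVolume,
               res@rawEdemaVolume - res@ventricleVolume - swell,
               tolerance = 1e-9)
})
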