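test_that("volumes round-trip exactly through NIfTI, including NaN masking", {
  set.seed(1)
  a <- array(rnorm(10 * 9 * 8), c(10, 9, 8))
  a[1, 1, ] <- NaN
  vg <- VolumeGrid(a, spacing = c(0.33, 0.33, 0.5),
                   origin = c(-1.65, -1.5, 0.25), modality = "SPECT")
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(vg, f)
  back <- readVolume(f, modality = "SPECT")
  expect_identical(voxelData(back), voxelData(vg))
  expect_equal(voxelSize(back), voxelSize(vg), tolerance = 1e-7)
  expect_equal(worldOrigin(back), worldOrigin(vg), tolerance = 1e-6)
  expect_equal(voxelVolume(back), 0.33 * 0.33 * 0.5, tolerance = 1e-7)
})

test_that("readVolume rejects missing files, 4-D inputs and hidden NaN", {
  expect_error(readVolume(tempfile()), "not found")
  f <- tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(1, c(4, 4, 4, 2)))
  RNifti::writeNifti(img, f)
  expect_error(readVolume(f), "3-D")
  vg <- VolumeGrid(array(c(NaN, rep(1, 511)), c(8, 8, 8)))
  f2 <- tempfile(fileext = ".nii.gz")
  writeVolume(vg, f2)
  expect_error(readVolume(f2, allowNaN = FALSE), "non-finite")
  expect_silent(readVolume(f2))
})

test_that("phantom SPECT output reads back with the designed spacing", {
  co <- smallCohort()
  f <- tempfile(fileext = ".nii.gz")
  writeVolume(co$volumes[[1]], f)
  expect_equal(voxelSize(readVolume(f)), rep(0.33, 3), tolerance = 1e-7)
})

test_that("congruence is a strict lattice predicate", {
  a <- VolumeGrid(array(0, c(8, 8, 8)), spacing = 0.33)
  expect_true(checkCongruent(a, a))
  b <- VolumeGrid(array(0, c(8, 8, 8)), spacing = 0.33 + 0.1)
  expect_false(checkCongruent(a, b))
  d <- VolumeGrid(array(0, c(8, 8, 9)), spacing = 0.33)
  expect_false(checkCongruent(a, d))
  co <- smallCohort()
  expect_true(checkCongruent(co$volumes[[1]], co$labels))
})

test_that("label volumes round-trip through the NIfTI trio", {
  co <- smallCohort()
  stem <- tempfile()
  writeLabelVolume(co$labels, stem)
  back <- readLabelVolume(stem)
  expect_identical(regionIDs(back), regionIDs(co$labels))
  expect_identical(hemisphereIDs(back), hemisphereIDs(co$labels))
  expect_identical(ventricleMask(back), ventricleMask(co$labels))
})

test_that("region tables validate, round-trip and expose active counts", {
  co <- smallCohort()
  expect_equal(nrow(co$regionTable), 77L)
  expect_equal(activeRegionCount(co$regionTable), 72L)
  f <- tempfile(fileext = ".tsv")
  writeRegionTable(co$regionTable, f)
  back <- readRegionTable(f)
  expect_equal(back$region_id, co$regionTable$region_id)
  expect_equal(back$excluded, co$regionTable$excluded)

  dup <- co$regionTable; dup$region_id[2] <- dup$region_id[1]
  expect_error(validateRegionTable(dup), "duplicated")
  bad <- co$regionTable; bad$hemisphere[1] <- "medial"
  expect_error(validateRegionTable(bad), "hemisphere")
  expect_error(validateRegionTable(co$regionTable[0, ]), "no regions")
})

test_that("healthy reference and score sheets round-trip as TSV", {
  co <- smallCohort()
  f <- tempfile(fileext = ".tsv")
  writeHealthyReference(co$reference, f)
  back <- readHealthyReference(f)
  expect_equal(referenceTable(back)$mean, referenceTable(co$reference)$mean,
               tolerance = 1e-12)

  sheet <- rbind(scoreRow(animal = "a1", posture = 2L),
                 scoreRow(animal = "a2", gait = 3L))
  f2 <- tempfile(fileext = ".csv")
  writeScoreSheet(sheet, f2)
  expect_equal(readScoreSheet(f2)$posture, sheet$posture)
})
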