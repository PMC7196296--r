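## small hand-built lattice: two hemispheres, two regions per hemisphere
toyLabels <- function(dm = c(10L, 10L, 10L)) {
  hemi <- array(2L, dm); hemi[seq_len(dm[1] %/% 2), , ] <- 1L
  reg <- array(1L, dm); reg[, seq_len(dm[2] %/% 2), ] <- 2L
  LabelVolume(reg, hemi, spacing = 0.5)
}

toyReference <- function(mean = c(1, 1), sd = c(0.05, 0.08), n = 15L) {
  HealthyReference(data.frame(
    region_id = rep(1:2, each = 2), hemisphere = rep(c("left", "right"), 2),
    mean = rep(mean, each = 2), sd = rep(sd, each = 2), n = n))
}

test_that("uniform activity maps to rCBF 1 and is scale invariant", {
  lab <- toyLabels()
  vol <- VolumeGrid(array(250, dim(regionIDs(lab))), spacing = 0.5)
  pm <- parametricMap(vol, lab)
  expect_equal(range(voxelData(pm)), c(1, 1))
  set.seed(4)
  vol2 <- VolumeGrid(array(rlnorm(1000, 0, 0.1), dim(regionIDs(lab))),
                     spacing = 0.5)
  pmA <- parametricMap(vol2, lab)
  vol10 <- VolumeGrid(voxelData(vol2) * 10, spacing = 0.5)
  pmB <- parametricMap(vol10, lab)
  expect_equal(voxelData(pmA), voxelData(pmB), tolerance = 1e-12)
  expect_equal(lassenAlpha(pmA), 0.5)
})

test_that("zero-noise phantom maps recover the designed rCBF exactly", {
  sp <- smallSpec(noiseSD = 0, animalSD = 0, nHealthy = 2)
  co <- generateHealthyCohort(sp)
  pm <- parametricMap(co$volumes[[1]], co$labels)
  des <- co$truth$designedMeans
  reg <- regionIDs(co$labels); hem <- hemisphereIDs(co$labels)
  ipsi <- hem == 1L & reg > 0L & is.finite(voxelData(pm))
  expect_equal(voxelData(pm)[ipsi], des[reg[ipsi]], tolerance = 1e-10)
})

test_that("voxel classification honours per-region bands and conserves volume", {
  lab <- toyLabels()
  ref <- toyReference()
  vals <- array(1, dim(regionIDs(lab)))
  vals[1, 1, 1] <- 1 - 3 * 0.08   # region 2 (left), 3 SD below -> hypo
  vals[1, 6, 1] <- 1 - 0.04       # region 1, inside its band -> normal
  vals[6, 6, 1] <- 1 + 3 * 0.05   # region 1 right, above -> hyper
  vals[2, 2, 2] <- NaN
  r <- lassenInvert(vals, 0.5)
  act <- r / mean(r[hemisphereIDs(lab) == 2L & is.finite(r)])
  pm <- parametricMap(VolumeGrid(act * 100, spacing = 0.5), lab)
  cl <- classifyPerfusion(pm, ref, lab)
  expect_equal(cl@classes[1, 1, 1], 1L)
  expect_equal(cl@classes[1, 6, 1], 2L)
  expect_equal(cl@classes[6, 6, 1], 3L)
  expect_equal(cl@classes[2, 2, 2], 0L)   # masked voxel is outside
  v <- classVolumes(cl)
  brain <- sum(cl@classes > 0L) * voxelVolume(cl)
  expect_equal(sum(v), brain)
  expect_equal(sum(classVolumes(cl, "left")) + sum(classVolumes(cl, "right")),
               brain)
})

test_that("classification matches a brute-force per-voxel oracle", {
  set.seed(7)
  dm <- c(8L, 8L, 8L)
  hemi <- array(sample(c(0L, 1L, 2L), prod(dm), replace = TRUE), dm)
  reg <- array(sample(0:3, prod(dm), replace = TRUE), dm)
  reg[hemi == 0L] <- 0L
  lab <- LabelVolume(reg, hemi, spacing = 1)
  ref <- HealthyReference(data.frame(
    region_id = rep(1:3, each = 2), hemisphere = rep(c("left", "right"), 3),
    mean = runif(6, 0.9, 1.1), sd = runif(6, 0.02, 0.1), n = 15L))
  vals <- array(runif(prod(dm), 0.6, 1.4), dm)
  pm <- new("ParametricMap", values = vals, spacing = rep(1, 3),
            origin = rep(0, 3), modality = "PARAMETRIC", alpha = 0.5,
            referenceMean = 1, referenceRegion = "right hemisphere",
            nClamped = 0L)
  cl <- classifyPerfusion(pm, ref, lab)

  tb <- referenceTable(ref)
  oracle <- array(0L, dm)
  for (i in 1:dm[1]) for (j in 1:dm[2]) for (k in 1:dm[3]) {
    r <- reg[i, j, k]; h <- hemi[i, j, k]
    if (r == 0L || h == 0L) next
    row <- tb[tb$region_id == r &
                tb$hemisphere == c("left", "right")[h], ]
    v <- vals[i, j, k]
    oracle[i, j, k] <-
      if (v < row$mean - 2 * row$sd - 1e-8) 1L
      else if (v > row$mean + 2 * row$sd + 1e-8) 3L else 2L
  }
  expect_identical(cl@classes, oracle)
})

test_that("a labelled region without a reference row is named in the error", {
  lab <- toyLabels()
  ref <- HealthyReference(data.frame(region_id = 1L,
                                     hemisphere = c("left", "right"),
                                     mean = 1, sd = 0.05, n = 15L))
  vol <- VolumeGrid(array(100, dim(regionIDs(lab))), spacing = 0.5)
  pm <- parametricMap(vol, lab)
  expect_error(classifyPerfusion(pm, ref, lab), "region\\(s\\): 2")
})

test_that("hypoperfused volume is monotone under pointwise rCBF increase", {
  st <- smallStudy()
  pm <- parametricMap(st@spect$treated$t1$d0, st@labels)
  cl0 <- classifyPerfusion(pm, st@healthyRef, st@labels)
  up <- new("ParametricMap", values = voxelData(pm) + 0.05,
            spacing = voxelSize(pm), origin = worldOrigin(pm),
            modality = "PARAMETRIC", alpha = 0.5, referenceMean = 1,
            referenceRegion = "right hemisphere", nClamped = 0L)
  cl1 <- classifyPerfusion(up, st@healthyRef, st@labels)
  expect_lte(hypoperfusedVolume(cl1, "both"), hypoperfusedVolume(cl0, "both"))
})

test_that("voxel-wise and roi-wise mask means agree on homogeneous masks", {
  lab <- toyLabels()
  vals <- array(80, dim(regionIDs(lab)))
  mask <- array(FALSE, dim(regionIDs(lab)))
  mask[2:4, 2:4, 2:4] <- TRUE
  vals[mask] <- 55  # constant activity inside the mask
  vol <- VolumeGrid(vals, spacing = 0.5)
  pm <- parametricMap(vol, lab)
  tc <- trackDay0Mask(list(pm), list(vol), mask, lab, days = 0)
  expect_equal(tc@voxelMean, tc@roiMean, tolerance = 1e-12)
  expect_equal(tc@maskVolume, sum(mask) * 0.125)
  expect_error(trackDay0Mask(list(pm), list(vol),
                             array(FALSE, dim(vals)), lab, days = 0),
               "empty")
})

test_that("the day-0 mask mean sits below the healthy band at day 0", {
  st <- smallStudy()
  cls <- studyClassifications(st, days = c(0, 7))
  tcs <- studyMaskTimeCourses(st, cls)
  tb <- referenceTable(st@healthyRef)
  minLower <- min(tb$mean - 2 * tb$sd)
  tc <- tcs$treated$t1
  expect_lt(tc@voxelMean[tc@days == 0], minLower)
  expect_gt(tc@voxelMean[tc@days == 7], tc@voxelMean[tc@days == 0])
})
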