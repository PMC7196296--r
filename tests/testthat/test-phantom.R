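test_that("identical (spec, seed) pairs reproduce byte-identical outputs", {
  s1 <- generateHealthyCohort(smallSpec(nHealthy = 2))
  s2 <- generateHealthyCohort(smallSpec(nHealthy = 2))
  expect_identical(voxelData(s1$volumes[[1]]), voxelData(s2$volumes[[1]]))
  expect_identical(referenceTable(s1$reference), referenceTable(s2$reference))
  st1 <- generateStudy(smallSpec(nPerGroup = 2, timepointsDays = c(0, 7)),
                       "reference_mcao")
  st2 <- generateStudy(smallSpec(nPerGroup = 2, timepointsDays = c(0, 7)),
                       "reference_mcao")
  expect_identical(voxelData(st1@spect$treated$t1$d7),
                   voxelData(st2@spect$treated$t1$d7))
  expect_identical(voxelData(st1@mri$control$c2$d7),
                   voxelData(st2@mri$control$c2$d7))
  expect_identical(st1@truth$designedShrinkPct, st2@truth$designedShrinkPct)
  ## a different seed changes the data
  s3 <- generateHealthyCohort(smallSpec(nHealthy = 2, seed = 99))
  expect_false(identical(voxelData(s1$volumes[[1]]),
                         voxelData(s3$volumes[[1]])))
})

test_that("zero-noise cohorts reproduce designed means with zero SD", {
  co <- generateHealthyCohort(smallSpec(noiseSD = 0, animalSD = 0,
                                        nHealthy = 3))
  tb <- referenceTable(co$reference)
  expect_lt(max(tb$sd), 1e-12)
  left <- tb[tb$hemisphere == "left", ]
  expect_equal(left$mean, co$truth$designedMeans[left$region_id],
               tolerance = 1e-10)
})

test_that("noisy cohorts recover designed means within 3 standard errors", {
  n <- 40L
  co <- generateHealthyCohort(smallSpec(nHealthy = n, seed = 13))
  tb <- referenceTable(co$reference)
  left <- tb[tb$hemisphere == "left", ]
  se <- left$sd / sqrt(left$n)
  dev <- abs(left$mean - co$truth$designedMeans[left$region_id])
  ## per-region deviations behave like sampling error of the cohort mean
  expect_gt(mean(dev <= 3 * se), 0.95)
  expect_lt(max(dev), 0.05)
})

test_that("the reference scenario's ground truth encodes the designed study", {
  st <- smallStudy()
  tr <- st@truth
  expect_equal(unname(tr$affectedCounts), c(65, 67))
  expect_equal(unname(tr$recoveredCounts), c(32, 8))
  expect_equal(tr$sharedCount, 5)
  expect_equal(tr$exclusiveTreatedCount, 27)
  expect_length(tr$hyperAfterRecoveryIDs, 3)
  expect_true(all(tr$recoveredIDs$treated %in% tr$affectedIDs$treated))
  expect_true(all(tr$recoveredIDs$control %in% tr$affectedIDs$control))
  ## designed day-7 outcomes sit at the configured targets
  expect_lt(abs(tr$designedShrinkPct[["treated"]] - 67), 1.5)
  expect_lt(abs(tr$designedShrinkPct[["control"]] - 1), 0.5)
  expect_equal(tr$designedMaskContrastPct, 41)
  ## all seven default timepoints exist in a default-timepoint study
  expect_setequal(names(st@spect$treated$t1), paste0("d", c(0, 3, 7)))
})

test_that("lesion-free datasets carry an empty lesion truth", {
  st <- generateStudy(smallSpec(nPerGroup = 2, timepointsDays = c(0, 7)),
                      "lesion_free")
  expect_equal(unname(st@truth$affectedCounts), c(0, 0))
  expect_equal(st@truth$designedMeans,
               generateHealthyCohort(smallSpec())$truth$designedMeans)
})

test_that("invalid specs and scenarios are rejected", {
  expect_error(phantomSpec(gridShape = c(4, 56, 32)), "degenerate")
  expect_error(phantomSpec(nHealthy = 1), "at least 2")
  expect_error(generateStudy(smallSpec(), "volcano"), "arg")
  expect_error(generateStudy(smallSpec(), "custom"), "customDesign")
  expect_error(generateStudy(smallSpec(nRegions = 20), "reference_mcao"),
               "77-region")
})

test_that("all emitted lattices are congruent within their modality", {
  st <- smallStudy()
  expect_true(checkCongruent(st@spect$treated$t1$d0, st@labels))
  expect_true(checkCongruent(st@spect$control$c3$d7, st@labels))
  expect_true(checkCongruent(st@mri$treated$t2$d3, st@mriLabels))
  expect_true(checkCongruent(st@healthyVolumes[[1]], st@labels))
  ## behavioural sheets validate against the scoring scheme
  expect_silent(validateScoreSheet(st@scores))
  expect_true(all(st@cylinder$impaired >= 0 & st@cylinder$unimpaired >= 0))
})

test_that("incomplete and no-data regions carry the designed NaN coding", {
  co <- smallCohort()
  v <- voxelData(co$volumes[[1]])
  reg <- regionIDs(co$labels)
  for (r in c(4, 13, 75))
    expect_true(all(is.nan(v[reg == r])))
  for (r in c(56, 71)) {
    frac <- mean(is.nan(v[reg == r]))
    expect_gt(frac, 0.3); expect_lt(frac, 0.7)
  }
})
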