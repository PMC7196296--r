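freshTable <- function(n = 77L)
  data.frame(region_id = seq_len(n), name = sprintf("r%02d", seq_len(n)),
             hemisphere = "both", cortical = TRUE, excluded = FALSE,
             stringsAsFactors = FALSE)

test_that("region exclusions are explicit and leave 72 of 77 active", {
  tb <- applyRegionExclusions(freshTable(), noData = c(4, 13, 75),
                              incomplete = c(56, 71))
  expect_equal(nrow(tb), 77L)
  expect_equal(activeRegionCount(tb), 72L)
  expect_setequal(tb$region_id[tb$excluded], c(4, 13, 56, 71, 75))
  expect_equal(activeRegionCount(applyRegionExclusions(freshTable())), 77L)
  expect_error(applyRegionExclusions(freshTable(), noData = 999), "999")
})

test_that("region means are exact on uniform and zero-noise inputs", {
  st <- smallStudy()
  uni <- new("ParametricMap", values = array(1, dim(regionIDs(st@labels))),
             spacing = voxelSize(st@labels), origin = worldOrigin(st@labels),
             modality = "PARAMETRIC", alpha = 0.5, referenceMean = 1,
             referenceRegion = "right hemisphere", nClamped = 0L)
  rr <- regionRcbf(uni, st@labels, st@regionTable)
  expect_true(all(abs(rr$rcbf[!rr$missing] - 1) < 1e-12))
  ## excluded regions never appear
  expect_false(any(rr$region_id %in% c(4, 13, 56, 71, 75)))

  sp0 <- smallSpec(noiseSD = 0, animalSD = 0, nHealthy = 2)
  co <- generateHealthyCohort(sp0)
  pm <- parametricMap(co$volumes[[1]], co$labels)
  rr0 <- regionRcbf(pm, co$labels, co$regionTable)
  left <- rr0[rr0$hemisphere == "left" & !rr0$missing, ]
  expect_equal(left$rcbf, co$truth$designedMeans[left$region_id],
               tolerance = 1e-10)
})

test_that("recovery classification matches a raw-data t.test oracle", {
  set.seed(31)
  nReg <- 12L
  healthyRaw <- matrix(rnorm(nReg * 15, 1, 0.05), nReg, 15)
  ref <- HealthyReference(data.frame(
    region_id = rep(seq_len(nReg), each = 2),
    hemisphere = rep(c("left", "right"), nReg),
    mean = rep(rowMeans(healthyRaw), each = 2),
    sd = rep(apply(healthyRaw, 1, sd), each = 2), n = 15L))
  ## regions 1-6 lesioned at day 0; 1-3 recover by day 7, 4-6 stay low
  mk <- function(day) do.call(rbind, lapply(seq_len(nReg), function(r) {
    mu <- if (day == 0 && r <= 6) 0.5 else if (day == 7 && r %in% 4:6) 0.55
          else mean(healthyRaw[r, ])
    data.frame(region_id = r, group = "treated", day = day,
               animal = paste0("a", 1:6), rcbf = rnorm(6, mu, 0.01))
  }))
  rm <- rbind(mk(0), mk(7))
  rep1 <- classifyRecovery(rm, ref)
  tab7 <- rep1@table[rep1@table$day == 7, ]

  ## oracle: Welch t.test of the raw groups against the raw healthy cohort
  for (r in seq_len(nReg)) {
    g <- rm$rcbf[rm$day == 7 & rm$region_id == r]
    tt <- t.test(g, healthyRaw[r, ])
    expect_equal(tab7$p_value[tab7$region_id == r], tt$p.value,
                 tolerance = 1e-9)
  }
  expect_setequal(tab7$region_id[tab7$status %in%
                                   c("recovered", "hyper_after_recovery")],
                  1:3)
  expect_setequal(tab7$region_id[tab7$status == "non_regenerated"], 4:6)
  expect_setequal(tab7$region_id[tab7$status == "unaffected"], 7:12)
})

test_that("a stricter significance level never increases the recovered count", {
  set.seed(32)
  nReg <- 20L
  ref <- HealthyReference(data.frame(
    region_id = rep(seq_len(nReg), each = 2),
    hemisphere = rep(c("left", "right"), nReg), mean = 1, sd = 0.05, n = 15L))
  mk <- function(day, shift) do.call(rbind, lapply(seq_len(nReg),
    function(r) data.frame(region_id = r, group = "g", day = day,
                           animal = paste0("a", 1:6),
                           rcbf = rnorm(6, 1 + shift, 0.05))))
  rm <- rbind(mk(0, -0.5), mk(7, -0.035))  # day 7 hovers near significance
  nRec <- function(sig) {
    tb <- classifyRecovery(rm, ref, sigLevel = sig)@table
    sum(tb$day == 7 & tb$status %in% c("recovered", "hyper_after_recovery"))
  }
  expect_gte(nRec(0.05), nRec(0.5))   # larger alpha = stricter recovery call
  expect_gte(nRec(0.01), nRec(0.05))
})

test_that("degenerate group sizes and unknown regions are rejected", {
  ref <- HealthyReference(data.frame(region_id = 1L, hemisphere = "left",
                                     mean = 1, sd = 0.05, n = 15L))
  one <- data.frame(region_id = 1L, group = "g", day = c(0, 7),
                    animal = "a1", rcbf = 1)
  expect_error(classifyRecovery(one, ref), "degenerate")
  rm <- data.frame(region_id = 2L, group = "g", day = rep(c(0, 7), each = 2),
                   animal = rep(c("a1", "a2"), 2), rcbf = 1)
  expect_error(classifyRecovery(rm, ref), "region")
})

test_that("shell profiles bin by voxel-centre distance and conserve volume", {
  dm <- c(20L, 20L, 20L)
  cls <- array(2L, dm)
  hemi <- array(1L, dm)
  pc <- new("PerfusionClassification", classes = cls, hemispheres = hemi,
            regionStats = data.frame(), thresholds = data.frame(),
            spacing = rep(1, 3), origin = c(0, 0, 0))
  ## single affected voxel whose centre is the site
  pc@classes[3, 3, 3] <- 1L
  site <- c(2.5, 2.5, 2.5)
  prof <- shellProfile(pc, site)
  expect_equal(prof@affected[1], 1)
  expect_equal(sum(prof@affected), 1)
  expect_equal(sum(prof@total), prod(dm))
  expect_error(shellProfile(pc, c(100, 0, 0)), "outside")
})

test_that("a uniformly affected sphere matches analytic shell volumes", {
  dm <- c(40L, 40L, 40L); vox <- 0.5
  ctrs <- as.matrix(expand.grid((1:40 - 0.5) * vox, (1:40 - 0.5) * vox,
                                (1:40 - 0.5) * vox))
  site <- c(10, 10, 10)
  d <- sqrt(rowSums(sweep(ctrs, 2, site)^2))
  cls <- array(2L, dm)
  cls[d <= 3] <- 1L
  pc <- new("PerfusionClassification", classes = cls,
            hemispheres = array(1L, dm), regionStats = data.frame(),
            thresholds = data.frame(), spacing = rep(vox, 3),
            origin = c(0, 0, 0))
  prof <- shellProfile(pc, site, binWidthMM = 1)
  analytic <- function(r0, r1) 4 / 3 * pi * (min(r1, 3)^3 - min(r0, 3)^3)
  for (s in 1:4) {
    layer <- 4 * pi * min(s, 3)^2 * vox  # one-voxel-layer slack
    expect_lt(abs(prof@affected[s] - analytic(s - 1, s)), layer + 1)
  }
  expect_equal(sum(prof@affected), sum(cls == 1L) * vox^3, tolerance = 1e-9)
})

test_that("shell recovery differences require identical edges", {
  st <- smallStudy()
  cls <- studyClassifications(st, days = c(0, 7))
  pt <- groupShellProfile(cls, "treated", 7, st@spec@injectionSiteMM, 1)
  pc <- groupShellProfile(cls, "control", 7, st@spec@injectionSiteMM, 1)
  dd <- shellRecoveryDifference(pt, pc)
  expect_equal(dd@affected, pc@affected - pt@affected, tolerance = 1e-9)
  ## identical profiles difference to zero
  z <- shellRecoveryDifference(pt, pt)
  expect_true(all(abs(z@affected) < 1e-12))
  bad <- new("ShellProfile", edges = pt@edges[-length(pt@edges)] ,
             affected = pt@affected[-1], total = pt@total[-1],
             site = pt@site)
  expect_error(shellRecoveryDifference(pt, bad), "edges")
})

test_that("treated-vs-control recovery concentrates away from the core", {
  st <- smallStudy()
  cls <- studyClassifications(st, days = c(0, 7))
  pt <- groupShellProfile(cls, "treated", 7, st@spec@injectionSiteMM, 1)
  pc <- groupShellProfile(cls, "control", 7, st@spec@injectionSiteMM, 1)
  dd <- shellRecoveryDifference(pt, pc)
  ## the non-recovering core around the injection site shows ~no difference
  expect_lt(sum(dd@affected[1:2]), 0.05 * sum(dd@affected))
  expect_gt(sum(dd@affected), 0)
})
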