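## Seeded generator of synthetic healthy cohorts and MCAO study datasets
## with known ground truth. The phantom emulates the statistical structure
## the analysis assumes -- per-region healthy rCBF distributions, a
## hemispherically asymmetric lesion centred at the injection site with
## distance-dependent recovery, T2 edema hyperintensity with ventricles and
## ipsilesional swelling -- not the imaging physics (no photon transport,
## collimators, partial-volume or registration effects).

.defaultLesionProfile <- function() list(
  alpha = 0.5,                  # HMPAO retention nonlinearity used forward
  day0Level = 0.45,             # affected-region day-0 rCBF, x healthy mean
  controlDay7Level = 0.60,      # control non-recovered day-7 level
  maskContrastPct = 41,         # designed day-7 treated-vs-control mask mean
  volumeShrinkTreatedPct = 67,  # designed day0->day7 hypo volume shrink
  volumeShrinkControlPct = 1,
  halftimeTreatedDays = 2,      # recovery-curve shape parameters
  halftimeControlDays = 3.5,
  hyperOvershootSD = 2.5,       # overshoot of hyper-after-recovery regions
  relapseFraction = 0)          # optional post-day-14 relapse, off by default

.defaultEdemaParams <- function() list(
  edemaVolumeMM3 = 60, intensityOffset = 60, ventricleFraction = 0.024,
  swellingMM3 = 12, parenchymaMean = 100, parenchymaSD = 10,
  ventricleMean = 200)

#' Construct a phantom specification
#'
#' Defaults encode the study conditions the phantom emulates: 0.33 mm SPECT
#' isovoxels, 0.46 mm MRI voxels, a 77-region atlas (of which 72 are
#' analysable), 15 healthy animals, 6 animals per arm, imaging at days 0,
#' 3, 7, 10, 14, 17 and 21 after occlusion, and an injection site at
#' bregma-relative (AP +0.3, ML -4.0, DV +4.8) mm.
#'
#' @param gridShape,voxelSizeSPECT SPECT lattice (voxels) and spacing (mm).
#' @param mriShape,voxelSizeMRI MRI lattice and spacing.
#' @param nRegions atlas region count (77 activates the structured
#'   reference atlas with its exclusion bookkeeping; other values produce a
#'   near-equal partition).
#' @param nHealthy healthy cohort size (>= 2).
#' @param nPerGroup animals per study arm (>= 2).
#' @param timepointsDays imaging days.
#' @param injectionSiteMM injection site, world mm (x = ML with left
#'   negative, y = AP, z = DV down from bregma at the dorsal midline).
#' @param lesionProfile named list overriding entries of the default lesion
#'   design (see Details).
#' @param edemaParams named list overriding the default MRI edema design.
#' @param noiseSD voxel-level rCBF noise SD (dimensionless rCBF units).
#' @param animalSD between-animal per-region rCBF SD.
#' @param regionOffsetRange half-range of the deterministic region-specific
#'   healthy-mean offsets around 1.
#' @param seed integer; identical (spec, seed) pairs reproduce
#'   byte-identical outputs.
#' @details \code{lesionProfile} fields: \code{day0Level} (affected-region
#'   day-0 rCBF as a fraction of the healthy mean), \code{controlDay7Level},
#'   \code{maskContrastPct}, \code{volumeShrinkTreatedPct},
#'   \code{volumeShrinkControlPct} (designed day-7 outcomes),
#'   \code{halftimeTreatedDays}/\code{halftimeControlDays} (recovery-curve
#'   shape), \code{hyperOvershootSD}, \code{relapseFraction}, \code{alpha}.
#' @return a \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(gridShape = c(48L, 56L, 32L), voxelSizeSPECT = 0.33,
                        mriShape = c(36L, 42L, 24L), voxelSizeMRI = 0.46,
                        nRegions = 77L, nHealthy = 15L, nPerGroup = 6L,
                        timepointsDays = c(0, 3, 7, 10, 14, 17, 21),
                        injectionSiteMM = c(-4, 0.3, 4.8),
                        lesionProfile = list(), edemaParams = list(),
                        noiseSD = 0.01, animalSD = 0.05,
                        regionOffsetRange = 0.06, seed = 1L) {
  lp <- utils::modifyList(.defaultLesionProfile(), lesionProfile)
  ep <- utils::modifyList(.defaultEdemaParams(), edemaParams)
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSizeSPECT = voxelSizeSPECT, mriShape = as.integer(mriShape),
      voxelSizeMRI = voxelSizeMRI, nRegions = as.integer(nRegions),
      nHealthy = as.integer(nHealthy), nPerGroup = as.integer(nPerGroup),
      timepointsDays = as.numeric(timepointsDays),
      injectionSiteMM = as.numeric(injectionSiteMM), lesionProfile = lp,
      edemaParams = ep, noiseSD = noiseSD, animalSD = animalSD,
      regionOffsetRange = regionOffsetRange, seed = as.integer(seed))
}

## Deterministic region-specific healthy means around 1 (golden-angle
## sequence: bounded, mean approximately zero, no two regions equal).
.designedRegionMeans <- function(spec)
  1 + spec@regionOffsetRange * sin(seq_len(spec@nRegions) * 2.399963)

## Synthesise one SPECT activity volume from a per-voxel rCBF target field.
## The ipsilesional activity is anchored to the animal's contralesional
## mean so the analysis pipeline recovers the designed ipsilesional rCBF
## values exactly; the contralesional side carries the ratio-normalisation
## residual (< 0.2%), exactly as a real reference region does.
.synthActivity <- function(Ffield, geom, alpha, dose) {
  r <- lassenInvert(Ffield, alpha)
  contraSel <- geom$hemi == 2L & !geom$nanMask
  mbar <- mean(r[contraSel])
  ipsi <- geom$hemi == 1L & !geom$nanMask
  act <- r
  act[ipsi] <- r[ipsi] * mbar
  act <- act * dose
  act[geom$nanMask | geom$hemi == 0L] <- NaN
  act
}

## rCBF target field for one animal: per-(region, hemisphere) values plus
## voxel noise; NaN outside the brain and in masked regions.
.targetField <- function(valL, valR, geom, spec) {
  f <- array(NA_real_, dim(geom$regions))
  ipsi <- geom$hemi == 1L & !geom$nanMask
  contra <- geom$hemi == 2L & !geom$nanMask
  f[ipsi] <- valL[geom$regions[ipsi]]
  f[contra] <- valR[geom$regions[contra]]
  n <- sum(ipsi) + sum(contra)
  if (spec@noiseSD > 0) {
    eps <- stats::rnorm(n, 0, spec@noiseSD)
    f[ipsi] <- f[ipsi] + eps[seq_len(sum(ipsi))]
    f[contra] <- f[contra] + eps[sum(ipsi) + seq_len(sum(contra))]
  }
  pmax(f, 0.02)
}

.phantomRegionTable <- function(spec) {
  tb <- data.frame(region_id = seq_len(spec@nRegions),
                   name = sprintf("region_%02d", seq_len(spec@nRegions)),
                   hemisphere = "both", cortical = FALSE, excluded = FALSE,
                   stringsAsFactors = FALSE)
  if (spec@nRegions == 77L) {
    sets <- .referenceSets()
    tb$cortical[tb$region_id %in% utils::head(sets$active, 50L)] <- TRUE
    tb <- applyRegionExclusions(tb, noData = sets$noData,
                                incomplete = sets$incomplete)
  }
  tb
}

.buildHealthyReference <- function(volumes, labels, tb, alpha) {
  tbAll <- tb; tbAll$excluded <- FALSE   # measure every region that has data
  rows <- lapply(volumes, function(v) {
    pm <- parametricMap(v, labels, alpha = alpha)
    regionRcbf(pm, labels, tbAll)
  })
  long <- do.call(rbind, rows)
  long <- long[!long$missing, ]
  agg <- stats::aggregate(rcbf ~ region_id + hemisphere, long,
                          function(x) c(mean(x), stats::sd(x), length(x)))
  out <- data.frame(region_id = agg$region_id, hemisphere = agg$hemisphere,
                    mean = agg$rcbf[, 1], sd = agg$rcbf[, 2],
                    n = as.integer(agg$rcbf[, 3]))
  out <- out[out$n >= 2, ]
  out$sd[is.na(out$sd)] <- 0
  HealthyReference(out[order(out$region_id, out$hemisphere), ])
}

.cohortImpl <- function(spec, geom) {
  set.seed(spec@seed)
  h <- .designedRegionMeans(spec)
  lat <- geom$lattice
  vols <- vector("list", spec@nHealthy)
  for (i in seq_len(spec@nHealthy)) {
    a <- matrix(stats::rnorm(spec@nRegions * 2, 0, spec@animalSD),
                spec@nRegions, 2)
    f <- .targetField(h + a[, 1], h + a[, 2], geom, spec)
    dose <- 100 * stats::runif(1, 0.8, 1.2)
    vols[[i]] <- VolumeGrid(.synthActivity(f, geom, spec@lesionProfile$alpha,
                                           dose),
                            spacing = lat$sp, origin = lat$origin,
                            modality = "SPECT")
  }
  labels <- LabelVolume(geom$regions, geom$hemi, NULL,
                        spacing = lat$sp, origin = lat$origin)
  tb <- .phantomRegionTable(spec)
  ref <- .buildHealthyReference(vols, labels, tb, spec@lesionProfile$alpha)
  list(volumes = vols, labels = labels, regionTable = tb, reference = ref,
       truth = list(designedMeans = h))
}

#' Generate a synthetic healthy cohort
#'
#' Emits per-animal SPECT-like activity volumes whose per-region uptake,
#' after Lassen correction against the right hemisphere, is distributed
#' around designed region means (near 1 with deterministic region-specific
#' offsets), together with the shared atlas \linkS4class{LabelVolume}, the
#' region table, and the \linkS4class{HealthyReference} computed from the
#' cohort through the package's own parametric-map path.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return list with elements \code{volumes}, \code{labels},
#'   \code{regionTable}, \code{reference}, \code{truth} (designed region
#'   means).
#' @examples
#' hc <- generateHealthyCohort(phantomSpec(nHealthy = 3, seed = 7))
#' referenceTable(hc$reference)[1:3, ]
#' @export
generateHealthyCohort <- function(spec) {
  validObject(spec)
  .cohortImpl(spec, .spectGeometry(spec))
}

## recovery-curve shape: 0 at day 0, 1 at day 7, exponential-like between,
## held after day 7 (optional relapse after day 14)
.recoveryCurve <- function(t, halftime, relapse = 0) {
  g <- ifelse(t <= 0, 0,
       ifelse(t >= 7, 1,
              (1 - 2^(-t / halftime)) / (1 - 2^(-7 / halftime))))
  if (relapse > 0) g <- ifelse(t > 14, 1 - relapse * pmin(1, (t - 14) / 7), g)
  g
}

## Designed per-region day-0 and day-7 ipsilesional targets for the
## reference_mcao scenario, in healthy-reference (pipeline) rCBF units.
.designReferenceMCAO <- function(spec, geom, ref) {
  lp <- spec@lesionProfile
  sets <- geom$sets
  tbL <- ref@table[ref@table$hemisphere == "left", ]
  m <- s <- rep(NA_real_, spec@nRegions)
  m[tbL$region_id] <- tbL$mean
  s[tbL$region_id] <- tbL$sd
  V <- geom$ipsiRegionVolVox

  affT <- sort(c(sets$coreNR, sets$ctrlOnlyRec, sets$sharedRec,
                 sets$treatExclRec))
  affC <- sort(c(affT, sets$ctrlExtraAff))
  recT <- sort(c(sets$treatExclRec, sets$sharedRec))
  recC <- sort(c(sets$sharedRec, sets$ctrlOnlyRec))
  nonRecT <- setdiff(affT, recT)          # core + control-only regions
  nonRecC <- setdiff(affC, recC)
  hyper <- sets$hyper
  recTnormal <- setdiff(recT, hyper)

  ## control day-7 mask mean, then solve the treated non-recovered level so
  ## the designed day-7 mask-mean contrast holds exactly
  y <- lp$controlDay7Level
  A_t <- sum(V[affT]); A_c <- sum(V[affC])
  m_c <- (sum(V[recC] * m[recC]) + y * sum(V[nonRecC] * m[nonRecC])) / A_c
  m_tTarget <- (1 + lp$maskContrastPct / 100) * m_c
  x <- (m_tTarget * A_t - sum(V[recTnormal] * m[recTnormal]) -
          sum(V[hyper] * (m[hyper] + lp$hyperOvershootSD * s[hyper]))) /
    sum(V[nonRecT] * m[nonRecT])
  if (!is.finite(x) || x <= 0.05)
    stop("lesion profile is not realisable: treated residual level ", x)
  if (x >= 1 - 2.5 * max(s[nonRecT] / m[nonRecT]))
    warning("treated residual day-7 level sits close to the healthy band; ",
            "designed counts may not be recovered")

  v0 <- v7 <- list(treated = m, control = m)   # default: healthy at all days
  v0$treated[affT] <- lp$day0Level * m[affT]
  v0$control[affC] <- lp$day0Level * m[affC]
  v7$treated[recTnormal] <- m[recTnormal]
  v7$treated[hyper] <- m[hyper] + lp$hyperOvershootSD * s[hyper]
  v7$treated[nonRecT] <- x * m[nonRecT]
  v7$control[recC] <- m[recC]
  v7$control[nonRecC] <- y * m[nonRecC]

  lo <- m - 2 * s
  desVol <- function(v, aff) sum(V[aff][v[aff] < lo[aff]])
  truth <- list(
    scenario = "reference_mcao",
    affectedIDs = list(treated = affT, control = affC),
    affectedCounts = c(treated = length(affT), control = length(affC)),
    recoveredIDs = list(treated = recT, control = recC),
    recoveredCounts = c(treated = length(recT), control = length(recC)),
    sharedIDs = sort(intersect(recT, recC)),
    sharedCount = length(intersect(recT, recC)),
    exclusiveTreatedCount = length(setdiff(recT, recC)),
    hyperAfterRecoveryIDs = hyper,
    treatedResidualLevel = x,
    designedHypoVolVox = list(
      treated = c(d0 = desVol(v0$treated, affT), d7 = desVol(v7$treated, affT)),
      control = c(d0 = desVol(v0$control, affC), d7 = desVol(v7$control, affC))),
    designedMaskContrastPct = lp$maskContrastPct)
  truth$designedShrinkPct <- c(
    treated = 100 * (1 - truth$designedHypoVolVox$treated[["d7"]] /
                       truth$designedHypoVolVox$treated[["d0"]]),
    control = 100 * (1 - truth$designedHypoVolVox$control[["d7"]] /
                       truth$designedHypoVolVox$control[["d0"]]))
  list(v0 = v0, v7 = v7, truth = truth)
}

.generateBehavior <- function(spec, scenario) {
  days <- c(4, 8, 11, 15, 18, 21)
  groups <- c("treated", "control")
  lesioned <- scenario != "lesion_free"
  gmax <- .generalItems; fmax <- .focalItems
  sev <- function(t, start, end, ht) end + (start - end) * 2^(-(t - 4) / ht)
  rows <- list(); cyl <- list()
  for (g in groups) {
    ht <- if (g == "treated") 4 else 10
    endG <- if (g == "treated") 0.18 else 0.45
    endC <- if (g == "treated") 0.62 else 0.80
    for (i in seq_len(spec@nPerGroup)) {
      an <- paste0(substr(g, 1, 1), i)
      for (t in days) {
        item <- function(mx, sv)
          max(0L, min(mx, as.integer(round(mx * sv + stats::rnorm(1, 0, 0.4)))))
        sG <- if (lesioned) sev(t, 0.6, endG, ht) else 0
        sF <- if (lesioned) sev(t, 0.6, endG, ht) else 0
        sE <- if (lesioned && t <= 4) 0.35 else 0.02
        rows[[length(rows) + 1L]] <- data.frame(
          animal = an, group = g, day = t,
          posture = item(gmax[["posture"]], sG),
          activity = item(gmax[["activity"]], sG),
          hair = item(gmax[["hair"]], sG),
          eyes = item(gmax[["eyes"]], sE),
          body_symmetry = item(fmax[["body_symmetry"]], sF),
          gait = item(fmax[["gait"]], sF),
          limb_symmetry = item(fmax[["limb_symmetry"]], sF),
          circling = item(fmax[["circling"]], sF),
          whisker = item(fmax[["whisker"]], sF))
        frac <- if (lesioned) sev(t, 0.85, endC, ht) else 0.5
        total <- 14L + stats::rpois(1, 8)
        un <- stats::rbinom(1, total, frac)
        cyl[[length(cyl) + 1L]] <- data.frame(
          animal = an, group = g, day = t,
          impaired = total - un, unimpaired = un)
      }
    }
  }
  list(scores = do.call(rbind, rows), cylinder = do.call(rbind, cyl))
}

#' Generate a full synthetic study with ground truth
#'
#' Emits SPECT and MRI volumes per animal per timepoint for two arms
#' (treated, control), the shared label volumes, the healthy cohort and its
#' reference, behavioural sheets, and a ground-truth record of every
#' designed quantity.
#'
#' Scenarios: \describe{
#'   \item{reference_mcao}{the paper-matched design: 65 treated-arm and 67
#'     control-arm regions perturbed below the healthy band at day 0; by
#'     day 7, 32 treated-arm regions (5 shared with control, 3 overshooting
#'     into hyperperfusion) and 8 control-arm regions return; the designed
#'     ipsilesional hypoperfused volume shrinks 67% (treated) vs 1%
#'     (control) and the day-7 mask-mean rCBF is 41% higher in the treated
#'     arm. Study-arm region effects are centred within each group so the
#'     realized group means equal the designed targets exactly.}
#'   \item{lesion_free}{both arms drawn from the healthy distribution; the
#'     true lesion mask is empty. Used for null calibration.}
#'   \item{custom}{user-designed day-0/day-7 level multipliers via
#'     \code{customDesign} (data.frame region_id, group, day0Level,
#'     day7Level).}}
#'
#' @param spec a \linkS4class{PhantomSpec}; the reference_mcao scenario
#'   requires the default 77-region atlas.
#' @param scenario scenario name.
#' @param customDesign design table for \code{scenario = "custom"}.
#' @return a \linkS4class{StudyDataset}.
#' @export
generateStudy <- function(spec,
                          scenario = c("reference_mcao", "lesion_free",
                                       "custom"),
                          customDesign = NULL) {
  scenario <- match.arg(scenario)
  validObject(spec)
  geom <- .spectGeometry(spec)
  cohort <- .cohortImpl(spec, geom)
  ref <- cohort$reference
  lp <- spec@lesionProfile
  h <- .designedRegionMeans(spec)
  days <- spec@timepointsDays
  lat <- geom$lattice

  if (scenario == "reference_mcao") {
    if (spec@nRegions != 77L)
      stop("reference_mcao requires the default 77-region atlas")
    des <- .designReferenceMCAO(spec, geom, ref)
  } else if (scenario == "custom") {
    if (is.null(customDesign))
      stop("scenario 'custom' needs a customDesign table")
    tbL <- ref@table[ref@table$hemisphere == "left", ]
    m <- rep(NA_real_, spec@nRegions); m[tbL$region_id] <- tbL$mean
    v0 <- v7 <- list(treated = m, control = m)
    for (g in c("treated", "control")) {
      cd <- customDesign[customDesign$group == g, ]
      v0[[g]][cd$region_id] <- cd$day0Level * m[cd$region_id]
      v7[[g]][cd$region_id] <- cd$day7Level * m[cd$region_id]
    }
    des <- list(v0 = v0, v7 = v7, truth = list(scenario = "custom"))
  } else {
    des <- list(v0 = list(treated = h, control = h),
                v7 = list(treated = h, control = h),
                truth = list(scenario = "lesion_free",
                             affectedCounts = c(treated = 0, control = 0),
                             designedMeans = h))
  }

  groups <- c("treated", "control")
  centreEffects <- scenario != "lesion_free"
  set.seed(spec@seed + 1L)
  spect <- list()
  for (g in groups) {
    halft <- if (g == "treated") lp$halftimeTreatedDays else
      lp$halftimeControlDays
    eff <- array(stats::rnorm(spec@nRegions * 2 * spec@nPerGroup, 0,
                              spec@animalSD),
                 c(spec@nRegions, 2, spec@nPerGroup))
    if (centreEffects && spec@nPerGroup > 1)
      eff <- sweep(eff, c(1, 2), apply(eff, c(1, 2), mean))
    arm <- list()
    for (i in seq_len(spec@nPerGroup)) {
      series <- list()
      for (t in days) {
        gcv <- .recoveryCurve(t, halft, lp$relapseFraction)
        vL <- des$v0[[g]] + (des$v7[[g]] - des$v0[[g]]) * gcv + eff[, 1, i]
        vR <- h + eff[, 2, i]
        f <- .targetField(vL, vR, geom, spec)
        dose <- 100 * stats::runif(1, 0.8, 1.2)
        series[[paste0("d", t)]] <- VolumeGrid(
          .synthActivity(f, geom, lp$alpha, dose),
          spacing = lat$sp, origin = lat$origin, modality = "SPECT")
      }
      arm[[paste0(substr(g, 1, 1), i)]] <- series
    }
    spect[[g]] <- arm
  }

  ## MRI side
  mg <- .mriGeometry(spec)
  ep <- spec@edemaParams
  set.seed(spec@seed + 2L)
  mri <- list()
  for (g in groups) {
    arm <- list()
    for (i in seq_len(spec@nPerGroup)) {
      series <- list()
      for (t in days) {
        withEdema <- scenario != "lesion_free" && t >= 3
        mask <- if (withEdema) mg$swollen else mg$base
        vals <- array(NA_real_, mg$lattice$dim)
        n <- sum(mask)
        vals[mask] <- stats::rnorm(n, ep$parenchymaMean, ep$parenchymaSD)
        vent <- mg$ventricles & mask
        vals[vent] <- stats::rnorm(sum(vent), ep$ventricleMean,
                                   ep$parenchymaSD)
        if (withEdema) {
          ed <- mg$edema & mask
          vals[ed] <- stats::rnorm(sum(ed),
                                   ep$parenchymaMean + ep$intensityOffset,
                                   ep$parenchymaSD)
        }
        series[[paste0("d", t)]] <- VolumeGrid(
          vals, spacing = mg$lattice$sp, origin = mg$lattice$origin,
          modality = "MRI")
      }
      arm[[paste0(substr(g, 1, 1), i)]] <- series
    }
    mri[[g]] <- arm
  }
  mriLabels <- LabelVolume(array(0L, mg$lattice$dim), mg$hemiSwollen,
                           mg$ventricles, spacing = mg$lattice$sp,
                           origin = mg$lattice$origin)

  set.seed(spec@seed + 3L)
  beh <- .generateBehavior(spec, scenario)

  truth <- des$truth
  truth$designedRegionTargets <- list(v0 = des$v0, v7 = des$v7)
  truth$edema <- c(mg$achieved,
                   list(present = scenario != "lesion_free"))
  truth$injectionSiteMM <- spec@injectionSiteMM
  truth$ipsiRegionVolVox <- geom$ipsiRegionVolVox

  new("StudyDataset", spect = spect, mri = mri, labels = cohort$labels,
      mriLabels = mriLabels, healthyVolumes = cohort$volumes,
      healthyRef = ref, regionTable = cohort$regionTable,
      scores = beh$scores, cylinder = beh$cylinder, truth = truth,
      spec = spec, scenario = scenario)
}

#' Labels matching the pre-stroke (unswollen) MRI anatomy
#'
#' The day-0 MRI carries no edema or swelling; its hemisphere masks differ
#' from the post-stroke ones. This helper returns the label volume matching
#' the day-0 anatomy of a study's MRI grid.
#'
#' @param study a \linkS4class{StudyDataset}.
#' @return a \linkS4class{LabelVolume}.
#' @export
mriBaselineLabels <- function(study) {
  mg <- .mriGeometry(study@spec)
  LabelVolume(array(0L, mg$lattice$dim), mg$hemiBase, mg$ventricles,
              spacing = mg$lattice$sp, origin = mg$lattice$origin)
}
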