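## Internal geometry builders for the phantom: brain masks, hemisphere and
## atlas-region lattices on the SPECT grid, and the MRI-side masks
## (ventricles, edema blob, swollen ipsilesional hemisphere).
##
## Coordinate convention: bregma sits at the grid's dorsal midline point
## (0, 0, 0); x = mediolateral (left negative, the ipsilesional side),
## y = anteroposterior, z = dorsoventral (down positive). The brain is an
## ellipsoid whose top touches z = 0.

.brainSemiAxesMM <- function(spec) {
  vox <- floor(c(0.46, 0.47, 0.44) * spec@gridShape)
  vox * spec@voxelSizeSPECT
}

.spectLattice <- function(spec) {
  d <- spec@gridShape
  sp <- rep(spec@voxelSizeSPECT, 3)
  semi <- .brainSemiAxesMM(spec)
  origin <- c(-d[1] * sp[1] / 2, -d[2] * sp[2] / 2, semi[3] - d[3] * sp[3] / 2)
  list(dim = d, sp = sp, origin = origin, centre = c(0, 0, semi[3]),
       semi = semi)
}

.mriLattice <- function(spec) {
  d <- spec@mriShape
  sp <- rep(spec@voxelSizeMRI, 3)
  semi <- .brainSemiAxesMM(spec)   # same anatomy in world mm
  origin <- c(-d[1] * sp[1] / 2, -d[2] * sp[2] / 2, semi[3] - d[3] * sp[3] / 2)
  list(dim = d, sp = sp, origin = origin, centre = c(0, 0, semi[3]),
       semi = semi)
}

.insideEllipsoid <- function(ctr, centre, semi) {
  ((ctr[, 1] - centre[1]) / semi[1])^2 +
    ((ctr[, 2] - centre[2]) / semi[2])^2 +
    ((ctr[, 3] - centre[3]) / semi[3])^2 <= 1
}

## The reference_mcao design partitions the ipsilesional hemisphere, in
## order of distance from the injection site, into:
##   30 core regions (size u)        non-recovering in either arm
##    3 tiny regions (size e)        recover only in the control arm
##    5 tiny regions (size e)        recover in both arms (shared)
##   27 large regions (size w)       recover only in the treated arm
##    2 regions (size u)             affected only in the control arm
##    5 regions (size u)             unaffected in both arms
##    2 regions (size u)             incomplete data (half the voxels NaN)
##    3 regions (leftover, all NaN)  no measurement data
## Region sizes u, w, e are solved so that the recovered-region volume
## shares equal the designed hypoperfused-volume shrinkages.
.referenceSets <- function() {
  excluded <- c(4L, 13L, 75L)   # no data
  incomplete <- c(56L, 71L)
  active <- setdiff(1:77, c(excluded, incomplete))
  hyper <- c(33L, 36L, 61L)     # hyperperfused after recovery
  rest <- setdiff(active, hyper)
  list(coreNR = rest[1:30],
       ctrlOnlyRec = rest[31:33],
       sharedRec = rest[34:38],
       treatExclRec = c(hyper, rest[39:62]),
       ctrlExtraAff = rest[63:64],
       unaffected = rest[65:69],
       incomplete = incomplete,
       noData = excluded,
       hyper = hyper,
       active = active)
}

.solveRegionSizes <- function(nIpsi, shrinkTreated, shrinkControl) {
  st <- shrinkTreated / 100; sc <- shrinkControl / 100
  ## per unit core-region size u, solve for w and e from the two designed
  ## volume-share equations (see vignette)
  M <- rbind(c(27 * (1 - st), 5 - 8 * st),
             c(-27 * sc, 8 * (1 - sc)))
  rhs <- c(30 * st, 32 * sc)
  we <- solve(M, rhs)
  wr <- we[1]; er <- we[2]
  if (wr <= 0 || er <= 0)
    stop("lesion profile shrink targets are not geometrically realisable")
  reserve <- 3L * max(10L, nIpsi %/% 300L)
  u <- max(8L, floor((nIpsi - reserve) / (27 * wr + 39 + 8 * er)))
  list(u = u, w = max(u, round(wr * u)), e = max(3L, round(er * u)))
}

## Build the full SPECT-grid geometry. Independent of scenario so that the
## healthy cohort and every study share one atlas.
.spectGeometry <- function(spec) {
  lat <- .spectLattice(spec)
  ctr <- .latticeCentres(lat$dim, lat$sp, lat$origin)
  brain <- .insideEllipsoid(ctr, lat$centre, lat$semi)
  hemi <- integer(nrow(ctr))
  hemi[brain & ctr[, 1] < 0] <- 1L
  hemi[brain & ctr[, 1] > 0] <- 2L

  regions <- integer(nrow(ctr))
  nanMask <- logical(nrow(ctr))
  ipsiIdx <- which(hemi == 1L)
  d2site <- sqrt((ctr[ipsiIdx, 1] - spec@injectionSiteMM[1])^2 +
                 (ctr[ipsiIdx, 2] - spec@injectionSiteMM[2])^2 +
                 (ctr[ipsiIdx, 3] - spec@injectionSiteMM[3])^2)
  ord <- ipsiIdx[order(d2site)]

  if (spec@nRegions == 77L) {
    sets <- .referenceSets()
    sz <- .solveRegionSizes(length(ord),
                            spec@lesionProfile$volumeShrinkTreatedPct,
                            spec@lesionProfile$volumeShrinkControlPct)
    ids <- c(sets$coreNR, sets$ctrlOnlyRec, sets$sharedRec,
             sets$treatExclRec, sets$ctrlExtraAff, sets$unaffected,
             sets$incomplete)
    sizes <- c(rep(sz$u, 30), rep(sz$e, 3), rep(sz$e, 5), rep(sz$w, 27),
               rep(sz$u, 2), rep(sz$u, 5), rep(sz$u, 2))
    stopifnot(sum(sizes) < length(ord))
    left <- length(ord) - sum(sizes)
    nd <- sets$noData
    sizes <- c(sizes, rep(left %/% 3L, 2), left - 2L * (left %/% 3L))
    ids <- c(ids, nd)
  } else {
    ## generic near-equal partition for non-default atlases
    sets <- list(active = seq_len(spec@nRegions), noData = integer(),
                 incomplete = integer(), hyper = integer())
    base <- length(ord) %/% spec@nRegions
    sizes <- rep(base, spec@nRegions)
    sizes[spec@nRegions] <- length(ord) - base * (spec@nRegions - 1L)
    ids <- seq_len(spec@nRegions)
  }
  stopifnot(sum(sizes) == length(ord))
  regions[ord] <- rep(ids, times = sizes)

  ## NaN-coding: no-data regions entirely, incomplete regions their distal
  ## half (within the ipsilesional assignment order, mirrored to the right)
  if (length(sets$noData))
    nanMask[ord][regions[ord] %in% sets$noData] <- TRUE
  for (r in sets$incomplete) {
    vr <- which(regions[ord] == r)
    nanMask[ord][vr[seq(ceiling(length(vr) / 2) + 1L, length(vr))]] <- TRUE
  }

  ## mirror ipsilesional labels onto the contralesional hemisphere
  dm <- lat$dim
  arr <- function(x) array(x, dm)
  regA <- arr(regions); nanA <- arr(nanMask); hemA <- arr(hemi)
  flip <- dm[1]:1
  mirror <- regA[flip, , ]
  mirrorNaN <- nanA[flip, , ]
  contra <- hemA == 2L
  regA[contra] <- mirror[contra]
  nanA[contra] <- mirrorNaN[contra]

  vols <- tabulate(regA[hemA == 1L & !nanA], nbins = max(1L, spec@nRegions))
  list(lattice = lat, brain = arr(brain), hemi = hemA, regions = regA,
       nanMask = nanA, sets = sets,
       ipsiRegionVolVox = vols,
       sizes = if (spec@nRegions == 77L) sz else NULL)
}

## Scale factor search so a parametric mask hits a target voxel count.
.scaleToCount <- function(countFor, target, sLo = 0.2, sHi = 6) {
  f <- function(s) countFor(s) - target
  if (f(sHi) < 0) return(sHi)
  stats::uniroot(f, c(sLo, sHi), tol = 1e-3)$root
}

## MRI-side geometry; the swollen ipsilesional hemisphere and the edema
## blob exist from the first post-stroke imaging day (day >= 3) onward.
.mriGeometry <- function(spec) {
  lat <- .mriLattice(spec)
  ctr <- .latticeCentres(lat$dim, lat$sp, lat$origin)
  base <- .insideEllipsoid(ctr, lat$centre, lat$semi)
  vv <- prod(lat$sp)
  ep <- spec@edemaParams

  ## ipsilesional swelling: stretch the left-side x semi-axis
  halfVol <- sum(base & ctr[, 1] < 0) * vv
  fx0 <- 1 + ep$swellingMM3 / halfVol
  swollenAt <- function(fx) {
    semiX <- ifelse(ctr[, 1] < 0, lat$semi[1] * fx, lat$semi[1])
    ((ctr[, 1] - lat$centre[1]) / semiX)^2 +
      ((ctr[, 2] - lat$centre[2]) / lat$semi[2])^2 +
      ((ctr[, 3] - lat$centre[3]) / lat$semi[3])^2 <= 1
  }
  fx <- .scaleToCount(function(s) sum(swollenAt(s)) - sum(base),
                      round(ep$swellingMM3 / vv), sLo = 1, sHi = 1.5)
  swollen <- swollenAt(fx)

  ## ventricles: one ellipsoid per hemisphere, scaled to the designed
  ## fraction of hemispheric voxels
  ventAt <- function(s, sign) {
    c0 <- c(sign * 2.2, 0, lat$centre[3] - 0.2)
    .insideEllipsoid(ctr, c0, c(0.9, 2.2, 0.7) * s) & base
  }
  targetVent <- round(ep$ventricleFraction * sum(base & ctr[, 1] > 0))
  s <- .scaleToCount(function(s) sum(ventAt(s, +1)), targetVent)
  vent <- ventAt(s, +1) | ventAt(s, -1)

  ## edema blob: sphere at the injection site, clipped to the ipsilesional
  ## hemisphere and excluding ventricles
  rE <- (3 * ep$edemaVolumeMM3 / (4 * pi))^(1 / 3)
  edema <- sqrt((ctr[, 1] - spec@injectionSiteMM[1])^2 +
                (ctr[, 2] - spec@injectionSiteMM[2])^2 +
                (ctr[, 3] - spec@injectionSiteMM[3])^2) <= rE &
    swollen & ctr[, 1] < 0 & !vent

  arr <- function(x) array(x, lat$dim)
  hemiOf <- function(mask) {
    h <- integer(length(mask))
    h[mask & ctr[, 1] < 0] <- 1L
    h[mask & ctr[, 1] > 0] <- 2L
    arr(h)
  }
  list(lattice = lat, base = arr(base), swollen = arr(swollen),
       hemiBase = hemiOf(base), hemiSwollen = hemiOf(swollen),
       ventricles = arr(vent & base), edema = arr(edema),
       achieved = list(
         swellingMM3 = (sum(swollen) - sum(base)) * vv,
         ventricleFraction = sum(vent & base & ctr[, 1] > 0) /
           sum(base & ctr[, 1] > 0),
         edemaVolumeMM3 = sum(edema) * vv))
}
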