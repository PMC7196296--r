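## Voxel-wise rCBF parametric mapping and +/-2SD perfusion classification.

.hemiCode <- c(left = 1L, right = 2L)

#' Build a Lassen-corrected relative rCBF parametric map
#'
#' Each voxel's uptake ratio R = activity / mean(reference-region activity)
#' is transformed with [lassenCorrect()]. The reference region is the set of
#' finite voxels of the chosen hemisphere (the contralesional/right
#' hemisphere by default); by construction the mean relative uptake over the
#' reference region maps to rCBF 1.
#'
#' @param spect a SPECT \linkS4class{VolumeGrid} (MBq/ml).
#' @param labels a congruent \linkS4class{LabelVolume}.
#' @param alpha Lassen parameter in (0, 1], default 0.5.
#' @param referenceHemisphere \code{"right"} (default) or \code{"left"}.
#' @param referenceStat \code{"mean"} (default) or \code{"median"} of the
#'   reference-region activity.
#' @return a \linkS4class{ParametricMap}.
#' @examples
#' ph <- phantomSpec(seed = 1)
#' hc <- generateHealthyCohort(phantomSpec(seed = 1, nHealthy = 2))
#' pm <- parametricMap(hc$volumes[[1]], hc$labels)
#' @export
parametricMap <- function(spect, labels, alpha = 0.5,
                          referenceHemisphere = c("right", "left"),
                          referenceStat = c("mean", "median")) {
  referenceHemisphere <- match.arg(referenceHemisphere)
  referenceStat <- match.arg(referenceStat)
  .stopIfNotCongruent(spect, labels, "SPECT and labels")
  refSel <- labels@hemispheres == .hemiCode[[referenceHemisphere]] &
    is.finite(spect@values)
  if (!any(refSel)) stop("reference region is empty")
  refMean <- if (referenceStat == "mean") mean(spect@values[refSel])
             else stats::median(spect@values[refSel])
  if (!is.finite(refMean) || refMean <= 0)
    stop("reference-region mean activity is zero or not finite")
  R <- spect@values / refMean
  f <- withCallingHandlers(
    lassenCorrect(R, alpha),
    warning = function(w) invokeRestart("muffleWarning"))
  nClamped <- attr(f, "nClamped")
  attr(f, "nClamped") <- NULL
  new("ParametricMap", values = f, spacing = spect@spacing,
      origin = spect@origin, modality = "PARAMETRIC", alpha = alpha,
      referenceMean = refMean,
      referenceRegion = paste(referenceHemisphere, "hemisphere"),
      nClamped = as.integer(nClamped))
}

## Vectorised lookup of per-(region, hemisphere) reference rows; errors if a
## labelled region lacks a reference row.
.bandLookup <- function(regions, hemis, ref, finiteMask = TRUE) {
  tb <- ref@table
  key <- tb$region_id * 4L + ifelse(tb$hemisphere == "left", 1L, 2L)
  qkey <- regions * 4L + hemis
  idx <- match(qkey, key)
  missing <- is.na(idx) & regions > 0L & hemis %in% c(1L, 2L) & finiteMask
  if (any(missing)) {
    bad <- sort(unique(regions[missing]))
    stop("no healthy reference row for region(s): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  }
  idx
}

#' Classify voxels and regions against the healthy 2-SD bands
#'
#' A voxel is hypoperfused iff its rCBF lies strictly below
#' mean_r - 2*SD_r of its own atlas region (and hemisphere), hyperperfused
#' iff strictly above mean_r + 2*SD_r, normal otherwise; the bands derive
#' only from the healthy reference, never from study data. Voxels outside
#' any atlas region, or masked out (NaN), are classed \code{outside} and
#' excluded from all volumes. Each region's own class is assigned by its
#' mean rCBF against the same band.
#'
#' @param map a \linkS4class{ParametricMap}.
#' @param healthy a \linkS4class{HealthyReference} covering every labelled
#'   region (an error names any region without a reference row).
#' @param labels a congruent \linkS4class{LabelVolume}.
#' @param nSD band half-width in reference SDs (default 2, the 95% band).
#' @return a \linkS4class{PerfusionClassification}.
#' @export
classifyPerfusion <- function(map, healthy, labels, nSD = 2) {
  .stopIfNotCongruent(map, labels, "map and labels")
  regions <- labels@regions
  hemis <- labels@hemispheres
  vals <- map@values
  idx <- .bandLookup(regions, hemis, healthy, is.finite(vals))
  tb <- healthy@table
  ## small absolute tolerance so that degenerate (zero-SD) bands classify
  ## values numerically equal to the mean as normal; negligible against any
  ## real band half-width
  tol <- 1e-8
  lo <- tb$mean[idx] - nSD * tb$sd[idx] - tol
  hi <- tb$mean[idx] + nSD * tb$sd[idx] + tol
  cls <- array(0L, dim(vals))
  inBrain <- !is.na(idx) & is.finite(vals) & is.finite(lo)
  cls[inBrain] <- 2L
  cls[inBrain & vals < lo] <- 1L
  cls[inBrain & vals > hi] <- 3L

  ## per-region statistics on the same bands
  sel <- inBrain
  fk <- paste(regions[sel], hemis[sel], sep = ":")
  mean_rcbf <- tapply(vals[sel], fk, mean)
  n_voxels <- tapply(vals[sel], fk, length)
  parts <- strsplit(names(mean_rcbf), ":", fixed = TRUE)
  rid <- vapply(parts, function(p) as.integer(p[1]), integer(1))
  hid <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  ridx <- match(rid * 4L + hid, tb$region_id * 4L +
                  ifelse(tb$hemisphere == "left", 1L, 2L))
  rlo <- tb$mean[ridx] - nSD * tb$sd[ridx] - tol
  rhi <- tb$mean[ridx] + nSD * tb$sd[ridx] + tol
  rcls <- ifelse(mean_rcbf < rlo, "hypo",
                 ifelse(mean_rcbf > rhi, "hyper", "normal"))
  ord <- order(rid, hid)
  regionStats <- data.frame(region_id = rid, hemisphere = ifelse(hid == 1L,
                            "left", "right"), mean_rcbf = as.numeric(mean_rcbf),
                            n_voxels = as.integer(n_voxels), class = rcls,
                            row.names = NULL)[ord, ]
  thresholds <- data.frame(region_id = tb$region_id,
                           hemisphere = tb$hemisphere,
                           lower = tb$mean - nSD * tb$sd,
                           upper = tb$mean + nSD * tb$sd)
  new("PerfusionClassification", classes = cls, hemispheres = hemis,
      regionStats = regionStats, thresholds = thresholds,
      spacing = map@spacing, origin = map@origin)
}

#' @rdname classVolumes
#' @export
setMethod("classVolumes", "PerfusionClassification",
  function(x, hemisphere = "both") {
    sel <- switch(hemisphere,
                  both = x@hemispheres %in% c(1L, 2L),
                  left = x@hemispheres == 1L,
                  right = x@hemispheres == 2L,
                  stop("hemisphere must be both/left/right"))
    cl <- x@classes[sel]
    vv <- prod(x@spacing)
    c(hypo = sum(cl == 1L) * vv, normal = sum(cl == 2L) * vv,
      hyper = sum(cl == 3L) * vv)
  })

#' Hypoperfused volume of a classification
#'
#' @param x a \linkS4class{PerfusionClassification}.
#' @param hemisphere \code{"both"}, \code{"left"} (ipsilesional) or
#'   \code{"right"}.
#' @return volume in mm^3.
#' @export
hypoperfusedVolume <- function(x, hemisphere = "left")
  unname(classVolumes(x, hemisphere)["hypo"])

#' Logical mask of hypoperfused voxels
#' @param x a \linkS4class{PerfusionClassification}.
#' @return 3-D logical array.
#' @export
hypoMask <- function(x) x@classes == 1L

#' Track the day-0 hypoperfused mask across a time series
#'
#' The day-0 hypoperfused volume of one animal is fixed as a 3-D mask and
#' applied to every timepoint of the same animal's series. Mean rCBF inside
#' the mask is computed voxel-wise (average the parametric-map voxels) and
#' roi-wise (average the raw SPECT activity inside the mask, form the ratio
#' to the reference-region mean, then apply Lassen's correction once); both
#' modes are reported for every timepoint, and agree exactly on spatially
#' homogeneous masks.
#'
#' @param maps list of \linkS4class{ParametricMap}, one per timepoint.
#' @param spectSeries list of raw SPECT \linkS4class{VolumeGrid}s, aligned
#'   with \code{maps}.
#' @param day0Class the animal's day-0 \linkS4class{PerfusionClassification}
#'   (its hypoperfused voxels define the mask), or a 3-D logical mask.
#' @param labels the shared \linkS4class{LabelVolume}.
#' @param days numeric timepoints (days) aligned with \code{maps}.
#' @param healthy optional \linkS4class{HealthyReference}; when given, the
#'   per-timepoint ipsilesional hypoperfused volume is also reported.
#' @param referenceHemisphere reference for the roi-wise ratio.
#' @return a \linkS4class{MaskTimeCourse}.
#' @export
trackDay0Mask <- function(maps, spectSeries, day0Class, labels, days,
                          healthy = NULL,
                          referenceHemisphere = c("right", "left")) {
  referenceHemisphere <- match.arg(referenceHemisphere)
  mask <- if (is(day0Class, "PerfusionClassification")) hypoMask(day0Class)
          else day0Class
  if (!any(mask)) stop("empty day-0 hypoperfused mask")
  stopifnot(length(maps) == length(spectSeries),
            length(maps) == length(days))
  refSel <- labels@hemispheres == .hemiCode[[referenceHemisphere]]
  vv <- prod(labels@spacing)
  n <- length(maps)
  voxelMean <- roiMean <- hypoVol <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    m <- maps[[i]]; s <- spectSeries[[i]]
    .stopIfNotCongruent(m, labels, "series and labels")
    inMask <- mask & is.finite(m@values)
    voxelMean[i] <- mean(m@values[inMask])
    sMask <- mask & is.finite(s@values)
    ratio <- mean(s@values[sMask]) /
      mean(s@values[refSel & is.finite(s@values)])
    roiMean[i] <- as.numeric(lassenCorrect(ratio, m@alpha))
    if (!is.null(healthy))
      hypoVol[i] <- hypoperfusedVolume(
        classifyPerfusion(m, healthy, labels), "left")
  }
  new("MaskTimeCourse", days = as.numeric(days), voxelMean = voxelMean,
      roiMean = roiMean, hypoVolume = hypoVol,
      maskVolume = sum(mask) * vv)
}
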