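#' Construct a VolumeGrid
#'
#' @param values 3-D numeric array; \code{NaN} marks masked-out voxels.
#' @param spacing per-axis voxel spacing in mm (scalar recycled to 3).
#' @param origin world coordinate (mm) of the corner of voxel (0,0,0).
#' @param modality \code{"SPECT"}, \code{"MRI"} or \code{"PARAMETRIC"}.
#' @return a \linkS4class{VolumeGrid}.
#' @examples
#' vg <- VolumeGrid(array(1, c(8, 8, 8)), spacing = 0.33)
#' voxelVolume(vg)
#' @export
VolumeGrid <- function(values, spacing = 1, origin = c(0, 0, 0),
                       modality = "SPECT") {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("expected 3-D volume")
  storage.mode(values) <- "double"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("VolumeGrid", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), modality = modality)
}

#' Construct a LabelVolume
#'
#' @param regions 3-D integer array of atlas region ids (0 = none).
#' @param hemispheres 3-D integer array (1 = left/ipsi, 2 = right/contra,
#'   0 = outside).
#' @param ventricles optional 3-D logical array of ventricle voxels.
#' @param spacing,origin lattice geometry as in [VolumeGrid()].
#' @return a \linkS4class{LabelVolume}.
#' @export
LabelVolume <- function(regions, hemispheres, ventricles = NULL,
                        spacing = 1, origin = c(0, 0, 0)) {
  storage.mode(regions) <- "integer"
  storage.mode(hemispheres) <- "integer"
  if (is.null(ventricles)) ventricles <- array(FALSE, dim(regions))
  storage.mode(ventricles) <- "logical"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  new("LabelVolume", regions = regions, hemispheres = hemispheres,
      ventricles = ventricles, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a HealthyReference
#'
#' @param table data.frame with columns region_id, hemisphere ("left" or
#'   "right"), mean, sd, n.
#' @return a \linkS4class{HealthyReference}.
#' @export
HealthyReference <- function(table) {
  table$region_id <- as.integer(table$region_id)
  table$hemisphere <- as.character(table$hemisphere)
  new("HealthyReference", table = table)
}

## ---- accessors -------------------------------------------------------------

#' @rdname voxelSize
#' @export
setMethod("voxelSize", "VolumeGrid", function(x) x@spacing)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "LabelVolume", function(x) x@spacing)
#' @rdname voxelSize
#' @export
setMethod("voxelSize", "PerfusionClassification", function(x) x@spacing)

#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "VolumeGrid", function(x) prod(x@spacing))
#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "LabelVolume", function(x) prod(x@spacing))
#' @rdname voxelVolume
#' @export
setMethod("voxelVolume", "PerfusionClassification", function(x) prod(x@spacing))

#' @rdname worldOrigin
#' @export
setMethod("worldOrigin", "VolumeGrid", function(x) x@origin)
#' @rdname worldOrigin
#' @export
setMethod("worldOrigin", "LabelVolume", function(x) x@origin)
#' @rdname worldOrigin
#' @export
setMethod("worldOrigin", "PerfusionClassification", function(x) x@origin)

#' @rdname voxelData
#' @export
setMethod("voxelData", "VolumeGrid", function(x) x@values)

#' @rdname modality
#' @export
setMethod("modality", "VolumeGrid", function(x) x@modality)

#' @rdname regionIDs
#' @export
setMethod("regionIDs", "LabelVolume", function(x) x@regions)
#' @rdname hemisphereIDs
#' @export
setMethod("hemisphereIDs", "LabelVolume", function(x) x@hemispheres)
#' @rdname ventricleMask
#' @export
setMethod("ventricleMask", "LabelVolume", function(x) x@ventricles)

#' @rdname lassenAlpha
#' @export
setMethod("lassenAlpha", "ParametricMap", function(x) x@alpha)
#' @rdname referenceMean
#' @export
setMethod("referenceMean", "ParametricMap", function(x) x@referenceMean)
#' @rdname referenceTable
#' @export
setMethod("referenceTable", "HealthyReference", function(x) x@table)

## ---- show ------------------------------------------------------------------

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s volume: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              object@modality, d[1], d[2], d[3],
              object@spacing[1], object@spacing[2], object@spacing[3]))
  v <- object@values[is.finite(object@values)]
  cat(sprintf("  %d finite voxels, range [%.4g, %.4g]\n",
              length(v), if (length(v)) min(v) else NA,
              if (length(v)) max(v) else NA))
})

setMethod("show", "ParametricMap", function(object) {
  callNextMethod()
  cat(sprintf("  Lassen alpha = %g, reference = %s (mean %.4g MBq/ml), %d clamped\n",
              object@alpha, object@referenceRegion, object@referenceMean,
              object@nClamped))
})

setMethod("show", "LabelVolume", function(object) {
  ids <- sort(unique(object@regions[object@regions > 0L]))
  cat(sprintf("LabelVolume: %s voxels, %d regions, %d ventricle voxels\n",
              paste(dim(object@regions), collapse = " x "), length(ids),
              sum(object@ventricles)))
})

setMethod("show", "HealthyReference", function(object) {
  tb <- object@table
  cat(sprintf("HealthyReference: %d region/hemisphere rows, cohort n = %s\n",
              nrow(tb), paste(unique(tb$n), collapse = "/")))
})

setMethod("show", "PerfusionClassification", function(object) {
  v <- classVolumes(object)
  cat(sprintf(
    "PerfusionClassification: hypo %.1f / normal %.1f / hyper %.1f mm^3\n",
    v["hypo"], v["normal"], v["hyper"]))
})

setMethod("show", "GaussianFit", function(object) {
  cat(sprintf("GaussianFit: mu = %.4g, sigma = %.4g (%d voxels, bin %.3g)\n",
              object@mu, object@sigma, object@nVoxels, object@binWidth))
})

setMethod("show", "EdemaResult", function(object) {
  cat(sprintf(paste0(
    "EdemaResult: corrected infarct %.2f mm^3\n",
    "  raw edema %.2f - ventricles %.2f - swelling %.2f mm^3%s\n"),
    object@correctedInfarctVolume, object@rawEdemaVolume,
    object@ventricleVolume,
    max(0, object@hemisphereVolumes["ipsi"] - object@hemisphereVolumes["contra"]),
    if (object@clamped) " [clamped at 0]" else ""))
})

setMethod("show", "MaskTimeCourse", function(object) {
  cat(sprintf("MaskTimeCourse over %d timepoints, mask %.1f mm^3\n",
              length(object@days), object@maskVolume))
  print(data.frame(day = object@days, voxel_mean = object@voxelMean,
                   roi_mean = object@roiMean, hypo_mm3 = object@hypoVolume))
})

setMethod("show", "ShellProfile", function(object) {
  cat(sprintf("ShellProfile: %d shells, affected %.1f of %.1f mm^3\n",
              length(object@affected), sum(object@affected),
              sum(object@total)))
})

setMethod("show", "RecoveryReport", function(object) {
  cat(sprintf("RecoveryReport (%s, alpha = %g): %d region x group x day rows\n",
              object@method, object@sigLevel, nrow(object@table)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0(
    "PhantomSpec: SPECT %s @ %.2f mm, MRI %s @ %.2f mm, %d regions\n",
    "  %d healthy, %d per arm, days %s, seed %d\n"),
    paste(object@gridShape, collapse = "x"), object@voxelSizeSPECT,
    paste(object@mriShape, collapse = "x"), object@voxelSizeMRI,
    object@nRegions, object@nHealthy, object@nPerGroup,
    paste(object@timepointsDays, collapse = ","), object@seed))
})

setMethod("show", "StudyDataset", function(object) {
  cat(sprintf("StudyDataset (%s): %d animals x 2 arms x %d timepoints\n",
              object@scenario, object@spec@nPerGroup,
              length(object@spec@timepointsDays)))
})

## ---- congruence ------------------------------------------------------------

.gridGeom <- function(x) {
  d <- if (is(x, "LabelVolume")) dim(x@regions)
       else if (is(x, "PerfusionClassification")) dim(x@classes)
       else dim(x@values)
  list(dim = d, spacing = voxelSize(x), origin = worldOrigin(x))
}

#' Check that two gridded objects live on the same lattice
#'
#' Pure predicate: TRUE iff shapes match exactly and spacings and origins
#' match within 1e-6 mm. No resampling is ever performed; congruence is a
#' requirement of every multi-volume operation in the package.
#'
#' @param a,b \linkS4class{VolumeGrid}, \linkS4class{LabelVolume} or
#'   \linkS4class{PerfusionClassification} objects.
#' @return logical scalar.
#' @export
checkCongruent <- function(a, b) {
  ga <- .gridGeom(a); gb <- .gridGeom(b)
  identical(ga$dim, gb$dim) &&
    all(abs(ga$spacing - gb$spacing) <= 1e-6) &&
    all(abs(ga$origin - gb$origin) <= 1e-6)
}

.stopIfNotCongruent <- function(a, b, what = "inputs") {
  if (!checkCongruent(a, b))
    stop("incongruent ", what,
         ": shapes, spacings and origins must match (no resampling is done)")
  invisible(TRUE)
}

## World coordinates (mm) of every voxel centre, as an n x 3 matrix in
## column-major lattice order.
.latticeCentres <- function(d, sp, o) {
  ii <- (seq_len(d[1]) - 0.5) * sp[1] + o[1]
  jj <- (seq_len(d[2]) - 0.5) * sp[2] + o[2]
  kk <- (seq_len(d[3]) - 0.5) * sp[3] + o[3]
  cbind(rep(ii, times = d[2] * d[3]),
        rep(rep(jj, each = d[1]), times = d[3]),
        rep(kk, each = d[1] * d[2]))
}

.voxelCentres <- function(x) {
  g <- .gridGeom(x)
  .latticeCentres(g$dim, g$spacing, g$origin)
}
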