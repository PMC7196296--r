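#' @import methods
NULL

#' Voxel spacing of a gridded volume
#'
#' @param x a \linkS4class{VolumeGrid}, \linkS4class{LabelVolume} or
#'   \linkS4class{PerfusionClassification}.
#' @return numeric vector of length 3, spacing per axis in mm.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Volume of one voxel in cubic millimetres
#'
#' Derived quantity: the product of the per-axis spacings.
#'
#' @param x an object with a voxel lattice.
#' @return scalar, mm^3.
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))

#' World coordinate of the lattice corner
#'
#' World position (mm) of the corner of voxel (0,0,0); the centre of voxel
#' (i,j,k) lies at \code{worldOrigin(x) + (c(i,j,k) + 0.5) * voxelSize(x)}
#' (0-based indices).
#'
#' @param x an object with a voxel lattice.
#' @return numeric vector of length 3 (mm).
#' @export
setGeneric("worldOrigin", function(x) standardGeneric("worldOrigin"))

#' Raw voxel values of a volume
#'
#' @param x a \linkS4class{VolumeGrid} or subclass.
#' @return 3-D numeric array; masked-out voxels are \code{NaN}.
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' Modality tag of a volume
#' @param x a \linkS4class{VolumeGrid}.
#' @return one of \code{"SPECT"}, \code{"MRI"}, \code{"PARAMETRIC"}.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Atlas region labels of a label volume
#' @param x a \linkS4class{LabelVolume}.
#' @return 3-D integer array of region ids (0 = unlabelled).
#' @export
setGeneric("regionIDs", function(x) standardGeneric("regionIDs"))

#' Hemisphere labels of a label volume
#'
#' Coding: 1 = left (ipsilesional), 2 = right (contralesional), 0 = outside
#' the brain mask.
#'
#' @param x a \linkS4class{LabelVolume}.
#' @return 3-D integer array.
#' @export
setGeneric("hemisphereIDs", function(x) standardGeneric("hemisphereIDs"))

#' Ventricle mask of a label volume
#' @param x a \linkS4class{LabelVolume}.
#' @return 3-D logical array.
#' @export
setGeneric("ventricleMask", function(x) standardGeneric("ventricleMask"))

#' Lassen alpha parameter recorded with a parametric map
#' @param x a \linkS4class{ParametricMap}.
#' @return scalar alpha.
#' @export
setGeneric("lassenAlpha", function(x) standardGeneric("lassenAlpha"))

#' Reference-region mean activity used to normalise a parametric map
#' @param x a \linkS4class{ParametricMap}.
#' @return scalar activity (MBq/ml).
#' @export
setGeneric("referenceMean", function(x) standardGeneric("referenceMean"))

#' Per-region healthy reference table
#' @param x a \linkS4class{HealthyReference}.
#' @return data.frame with columns region_id, hemisphere, mean, sd, n.
#' @export
setGeneric("referenceTable", function(x) standardGeneric("referenceTable"))

#' Class volumes of a perfusion classification
#'
#' Volumes (mm^3) of the hypoperfused, normal and hyperperfused partitions,
#' optionally restricted to one hemisphere.
#'
#' @param x a \linkS4class{PerfusionClassification}.
#' @param hemisphere \code{"both"}, \code{"left"} or \code{"right"}.
#' @return named numeric vector \code{c(hypo=, normal=, hyper=)} in mm^3.
#' @export
setGeneric("classVolumes", function(x, hemisphere = "both")
  standardGeneric("classVolumes"))
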