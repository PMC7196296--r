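## Central S4 data carriers. All lattices are plain 3-D arrays in voxel
## (i,j,k) order; world coordinates follow the corner-origin convention
## documented in ?worldOrigin.

.validVolumeGrid <- function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    msg <- c(msg, "values must be a 3-D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive finite values (mm)")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be 3 finite values (mm)")
  if (length(object@modality) != 1L ||
      !object@modality %in% c("SPECT", "MRI", "PARAMETRIC"))
    msg <- c(msg, "modality must be one of SPECT, MRI, PARAMETRIC")
  if (length(msg)) msg else TRUE
}

#' VolumeGrid: a 3-D scalar lattice with physical geometry
#'
#' The carrier for SPECT activity volumes (MBq/ml), T2 MRI volumes and
#' parametric rCBF maps. Masked-out (extrameningeal) voxels are encoded as
#' \code{NaN} and are excluded from every statistic in the package.
#'
#' @slot values 3-D numeric array.
#' @slot spacing per-axis voxel spacing in mm (strictly positive).
#' @slot origin world coordinate (mm) of the corner of voxel (0,0,0).
#' @slot modality \code{"SPECT"}, \code{"MRI"} or \code{"PARAMETRIC"}.
#' @seealso [VolumeGrid()], [readVolume()], [checkCongruent()]
#' @export
setClass("VolumeGrid",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 modality = "character"),
  validity = .validVolumeGrid)

.validLabelVolume <- function(object) {
  msg <- character()
  d <- dim(object@regions)
  if (length(d) != 3L) msg <- c(msg, "regions must be a 3-D array")
  if (!identical(dim(object@hemispheres), d))
    msg <- c(msg, "hemispheres lattice not congruent with regions")
  if (!identical(dim(object@ventricles), d))
    msg <- c(msg, "ventricle mask not congruent with regions")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 strictly positive values")
  if (any(!object@hemispheres %in% c(0L, 1L, 2L)))
    msg <- c(msg, "hemisphere codes must be 0 (outside), 1 (left) or 2 (right)")
  if (length(msg)) msg else TRUE
}

#' LabelVolume: atlas regions, hemispheres and ventricles on a lattice
#'
#' Integer-valued lattices congruent with the `VolumeGrid`s they annotate.
#' Hemisphere coding: 1 = left (ipsilesional), 2 = right (contralesional),
#' 0 = outside the brain mask.
#'
#' @slot regions 3-D integer array of atlas region ids (0 = none).
#' @slot hemispheres 3-D integer array of hemisphere codes.
#' @slot ventricles 3-D logical array marking ventricle voxels.
#' @slot spacing,origin lattice geometry as in \linkS4class{VolumeGrid}.
#' @export
setClass("LabelVolume",
  representation(regions = "array", hemispheres = "array",
                 ventricles = "array", spacing = "numeric",
                 origin = "numeric"),
  validity = .validLabelVolume)

#' HealthyReference: per-region normal rCBF bands
#'
#' Per region and hemisphere, the mean, SD and cohort size of relative rCBF
#' in healthy animals. mean +/- 2*SD defines the 95% normality band used by
#' the voxel and region classifiers; thresholds derive only from this table,
#' never from study data.
#'
#' @slot table data.frame with columns \code{region_id}, \code{hemisphere}
#'   ("left"/"right"), \code{mean}, \code{sd}, \code{n}.
#' @export
setClass("HealthyReference", representation(table = "data.frame"),
  validity = function(object) {
    tb <- object@table
    need <- c("region_id", "hemisphere", "mean", "sd", "n")
    if (!all(need %in% names(tb)))
      return(paste("reference table must have columns:",
                   paste(need, collapse = ", ")))
    if (anyDuplicated(tb[c("region_id", "hemisphere")]))
      return("duplicated (region_id, hemisphere) rows")
    if (any(stats::na.omit(tb$sd) < 0)) return("negative reference SD")
    TRUE
  })

#' ParametricMap: Lassen-corrected relative rCBF volume
#'
#' A \linkS4class{VolumeGrid} (modality \code{"PARAMETRIC"}) of dimensionless
#' relative rCBF values together with the metadata that produced it: the
#' Lassen alpha, the reference-region descriptor and its mean activity. The
#' mean uptake over the reference region maps to rCBF 1 by construction.
#' Maps with different alpha must never be pooled.
#'
#' @slot alpha Lassen linearization parameter (default 0.5).
#' @slot referenceMean mean reference-region activity (MBq/ml).
#' @slot referenceRegion descriptor of the reference region.
#' @slot nClamped number of voxels whose uptake ratio was clamped below the
#'   Lassen pole at R = 1/(1-alpha).
#' @export
setClass("ParametricMap", contains = "VolumeGrid",
  representation(alpha = "numeric", referenceMean = "numeric",
                 referenceRegion = "character", nClamped = "integer"),
  validity = function(object) {
    if (length(object@alpha) != 1L || object@alpha <= 0 || object@alpha > 1)
      return("alpha must lie in (0, 1]")
    if (object@modality != "PARAMETRIC")
      return("a ParametricMap must have modality PARAMETRIC")
    TRUE
  })

#' PerfusionClassification: voxel-wise hypo/normal/hyper partition
#'
#' Voxel classes against the healthy per-region 2-SD bands. Coding:
#' 0 = outside (unlabelled or NaN voxel), 1 = hypoperfused, 2 = normal,
#' 3 = hyperperfused. The three tissue classes partition the brain mask, so
#' their volumes sum to the total classified brain volume.
#'
#' @slot classes 3-D integer array of voxel classes.
#' @slot hemispheres 3-D integer array of hemisphere codes, copied from the
#'   \linkS4class{LabelVolume} so hemispheric volumes can be reported.
#' @slot regionStats data.frame of per-region summaries (region_id,
#'   hemisphere, mean_rcbf, n_voxels, class).
#' @slot thresholds data.frame of the bands used (region_id, hemisphere,
#'   lower, upper).
#' @slot spacing,origin lattice geometry.
#' @export
setClass("PerfusionClassification",
  representation(classes = "array", hemispheres = "array",
                 regionStats = "data.frame",
                 thresholds = "data.frame", spacing = "numeric",
                 origin = "numeric"),
  validity = function(object) {
    if (length(dim(object@classes)) != 3L) return("classes must be 3-D")
    if (any(!object@classes %in% 0:3)) return("voxel classes must be 0..3")
    TRUE
  })

#' GaussianFit: least-squares Gaussian fit to an intensity histogram
#'
#' @slot mu fitted mean intensity.
#' @slot sigma fitted SD (strictly positive).
#' @slot binWidth histogram bin width used.
#' @slot rss residual sum of squares of the fit (normalised density scale).
#' @slot nVoxels number of finite voxels entering the histogram.
#' @export
setClass("GaussianFit",
  representation(mu = "numeric", sigma = "numeric", binWidth = "numeric",
                 rss = "numeric", nVoxels = "integer"),
  validity = function(object)
    if (object@sigma <= 0) "fitted sigma must be positive" else TRUE)

#' EdemaResult: edema volumetry with every correction term
#'
#' corrected = raw - ventricle - max(0, V_ipsi - V_contra), clamped at zero
#' with a flag when clamping occurred; every term is separately inspectable.
#'
#' @slot threshold absolute intensity threshold used.
#' @slot rawEdemaVolume above-threshold ipsilesional volume (mm^3).
#' @slot ventricleVolume contralesional above-threshold volume (mm^3),
#'   the ventricle proxy that is subtracted.
#' @slot hemisphereVolumes named vector c(ipsi=, contra=) of hemispheric
#'   brain volumes (mm^3).
#' @slot correctedInfarctVolume final infarct volume (mm^3, >= 0).
#' @slot excludedFractionContra fraction of contralesional voxels not passing
#'   the threshold.
#' @slot clamped TRUE if the corrected volume was clamped at zero.
#' @slot ventricleMissing TRUE if no contralesional ventricle signal was
#'   available and zero was subtracted.
#' @export
setClass("EdemaResult",
  representation(threshold = "numeric", rawEdemaVolume = "numeric",
                 ventricleVolume = "numeric", hemisphereVolumes = "numeric",
                 correctedInfarctVolume = "numeric",
                 excludedFractionContra = "numeric", clamped = "logical",
                 ventricleMissing = "logical"))

#' ShellProfile: affected volume by distance from the injection site
#'
#' Voxels are binned by the Euclidean distance of their centres from the
#' injection site; per shell the affected (hypo + hyper) and total brain
#' volumes are reported. Shells partition the brain, so per-shell totals sum
#' to the brain volume and per-shell affected volumes sum to the total
#' affected volume.
#'
#' @slot edges shell edges (mm), length nShells + 1.
#' @slot affected per-shell affected volume (mm^3).
#' @slot total per-shell brain volume (mm^3).
#' @slot site injection site, world mm.
#' @export
setClass("ShellProfile",
  representation(edges = "numeric", affected = "numeric", total = "numeric",
                 site = "numeric"),
  validity = function(object) {
    if (length(object@affected) != length(object@edges) - 1L ||
        length(object@total) != length(object@affected))
      return("edges must be one longer than the per-shell vectors")
    if (any(object@affected > object@total + 1e-9))
      return("per-shell affected volume exceeds per-shell total")
    TRUE
  })

#' MaskTimeCourse: day-0 hypoperfused mask tracked over a series
#'
#' The day-0 hypoperfused volume of one animal, applied as a fixed 3-D mask
#' to every timepoint of the same animal. Mean rCBF inside the mask is
#' computed in two modes: voxel-wise (average the parametric-map voxels) and
#' roi-wise (average the raw SPECT signal, form the uptake ratio, then apply
#' Lassen's correction once).
#'
#' @slot days timepoints (days).
#' @slot voxelMean per-timepoint voxel-wise mean rCBF inside the mask.
#' @slot roiMean per-timepoint roi-wise mean rCBF inside the mask.
#' @slot hypoVolume per-timepoint hypoperfused volume (mm^3) inside the brain.
#' @slot maskVolume volume of the fixed day-0 mask (mm^3).
#' @export
setClass("MaskTimeCourse",
  representation(days = "numeric", voxelMean = "numeric", roiMean = "numeric",
                 hypoVolume = "numeric", maskVolume = "numeric"),
  validity = function(object) {
    n <- length(object@days)
    if (length(object@voxelMean) != n || length(object@roiMean) != n ||
        length(object@hypoVolume) != n)
      return("per-timepoint slots must align with days")
    TRUE
  })

#' RecoveryReport: regenerated/non-regenerated region classification
#'
#' Per region x group x timepoint: the group mean rCBF, its SE, whether the
#' region was affected at day 0 (group day-0 mean outside the healthy 95%
#' band) and its recovery status. Statuses: \code{unaffected},
#' \code{recovered}, \code{non_regenerated}, \code{hyper_after_recovery}
#' (recovered but above the upper band). A recovered region is always one
#' that was affected at day 0.
#'
#' @slot table long data.frame (region_id, group, day, mean, se, n, p_value,
#'   affected_day0, status).
#' @slot sigLevel significance level of the recovery test.
#' @slot method \code{"ttest"} (Welch vs healthy cohort) or \code{"band"}
#'   (within mean +/- 2 SD).
#' @export
setClass("RecoveryReport",
  representation(table = "data.frame", sigLevel = "numeric",
                 method = "character"))

#' PhantomSpec: parameters of the synthetic study generator
#'
#' Defaults reproduce the acquisition and cohort structure of a longitudinal
#' rodent MCAO SPECT/MRI study: 0.33 mm SPECT isovoxels, 0.46 mm MRI voxels,
#' a 77-region atlas, 15 healthy animals, 6 animals per study arm, imaging at
#' days 0, 3, 7, 10, 14, 17 and 21, and an injection site at bregma-relative
#' stereotaxic coordinates (AP +0.3, ML -4.0, DV +4.8) mm in the left
#' hemisphere. See [phantomSpec()] for the user constructor.
#'
#' @slot gridShape SPECT lattice dimensions (voxels).
#' @slot voxelSizeSPECT isotropic SPECT spacing (mm).
#' @slot mriShape MRI lattice dimensions (voxels).
#' @slot voxelSizeMRI isotropic MRI spacing (mm).
#' @slot nRegions atlas region count.
#' @slot nHealthy healthy cohort size.
#' @slot nPerGroup animals per study arm.
#' @slot timepointsDays imaging days.
#' @slot injectionSiteMM world coordinates (mm) of the injection site;
#'   bregma maps to the grid's dorsal midline point (0, 0, 0), x = ML
#'   (left negative), y = AP, z = DV (down positive).
#' @slot lesionProfile named list of lesion design values (see
#'   [phantomSpec()]).
#' @slot edemaParams named list of MRI edema design values.
#' @slot noiseSD voxel-level rCBF noise SD.
#' @slot animalSD between-animal per-region rCBF SD.
#' @slot regionOffsetRange half-range of deterministic region-specific
#'   offsets of the healthy mean around 1.
#' @slot seed integer seed; identical (spec, seed) pairs reproduce
#'   byte-identical outputs.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSizeSPECT = "numeric",
                 mriShape = "integer", voxelSizeMRI = "numeric",
                 nRegions = "integer", nHealthy = "integer",
                 nPerGroup = "integer", timepointsDays = "numeric",
                 injectionSiteMM = "numeric", lesionProfile = "list",
                 edemaParams = "list", noiseSD = "numeric",
                 animalSD = "numeric", regionOffsetRange = "numeric",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (any(object@gridShape < 8L) || any(object@mriShape < 8L))
      msg <- c(msg, "degenerate grid: every axis must have at least 8 voxels")
    if (object@nRegions < 1L || object@nRegions > 10000L)
      msg <- c(msg, "n_regions exceeds label capacity")
    if (object@nHealthy < 2L)
      msg <- c(msg, "healthy cohort needs at least 2 animals")
    if (object@nPerGroup < 2L)
      msg <- c(msg, "study arms need at least 2 animals")
    if (object@noiseSD < 0 || object@animalSD < 0)
      msg <- c(msg, "noise SDs must be non-negative")
    if (length(object@injectionSiteMM) != 3L)
      msg <- c(msg, "injection site must be a 3-vector (mm)")
    if (length(msg)) msg else TRUE
  })

#' StudyDataset: a full synthetic study with ground truth
#'
#' Animals x groups (control/treated) x timepoints of co-registered SPECT and
#' MRI volumes, the shared label volumes, the healthy cohort and its
#' reference table, behavioural sheets, and a ground-truth record of every
#' designed quantity (lesion masks, per-region day-wise target rCBF, designed
#' recovery sets and contrasts, edema volumes).
#'
#' @slot spect nested list: spect[[group]][[animal]][[timepoint]] VolumeGrid.
#' @slot mri nested list, same shape, MRI VolumeGrids.
#' @slot labels SPECT-grid \linkS4class{LabelVolume}.
#' @slot mriLabels MRI-grid \linkS4class{LabelVolume} (hemispheres and
#'   ventricles; region ids 0).
#' @slot healthyVolumes list of healthy-cohort SPECT VolumeGrids.
#' @slot healthyRef \linkS4class{HealthyReference} computed from the cohort
#'   through the package's own parametric-map path.
#' @slot regionTable region table data.frame (see [readRegionTable()]).
#' @slot scores behavioural score sheet data.frame.
#' @slot cylinder cylinder-test record data.frame.
#' @slot truth named list of designed ground truth.
#' @slot spec the generating \linkS4class{PhantomSpec}.
#' @slot scenario scenario name.
#' @export
setClass("StudyDataset",
  representation(spect = "list", mri = "list", labels = "LabelVolume",
                 mriLabels = "LabelVolume", healthyVolumes = "list",
                 healthyRef = "HealthyReference", regionTable = "data.frame",
                 scores = "data.frame", cylinder = "data.frame",
                 truth = "list", spec = "PhantomSpec", scenario = "character"))
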