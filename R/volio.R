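## On-disk formats: NIfTI-1 for volumes (via RNifti), TSV for tables, JSON
## sidecars. This file is the single place format dialects are decided.
## Volumes are consumed as stored: no reorientation, no resampling.

.sformFrom <- function(spacing, origin) {
  M <- diag(c(spacing, 1))
  M[1:3, 4] <- origin + 0.5 * spacing   # NIfTI maps 0-based indices to centres
  M
}

#' Write a volume to a NIfTI-1 file
#'
#' Values, spacing and origin round-trip exactly through [readVolume()]
#' (data are stored as float64). The lattice geometry is encoded in the
#' qform/sform as a diagonal affine under the package's corner-origin,
#' centre-of-voxel convention.
#'
#' @param vol a \linkS4class{VolumeGrid}.
#' @param path output file, conventionally ending in \code{.nii} or
#'   \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "VolumeGrid"))
  img <- RNifti::asNifti(vol@values)
  RNifti::pixdim(img) <- vol@spacing
  M <- .sformFrom(vol@spacing, vol@origin)
  img <- RNifti::`qform<-`(img, structure(M, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a 3-D NIfTI-1 file.
#' @param modality modality tag to attach (\code{"SPECT"}, \code{"MRI"},
#'   \code{"PARAMETRIC"}).
#' @param allowNaN if FALSE, non-finite voxels raise an error; the default
#'   TRUE treats NaN as the masked-out-voxel code.
#' @return a \linkS4class{VolumeGrid}.
#' @export
readVolume <- function(path, modality = "SPECT", allowNaN = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))   # plain array, no niftiImage class
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1L, drop = TRUE]
  if (length(dim(a)) != 3L) stop("expected 3-D volume, got ",
                                 length(dim(a)), "-D")
  if (!allowNaN && any(!is.finite(a)))
    stop("volume contains non-finite voxels (use allowNaN = TRUE for masked data)")
  sp <- RNifti::pixdim(img)[1:3]
  M <- RNifti::xform(img)
  origin <- M[1:3, 4] - 0.5 * sp
  VolumeGrid(a, spacing = sp, origin = origin, modality = modality)
}

#' Write a LabelVolume as a trio of NIfTI files
#'
#' Emits \code{<stem>_regions.nii.gz}, \code{<stem>_hemispheres.nii.gz} and
#' \code{<stem>_ventricles.nii.gz}.
#'
#' @param lab a \linkS4class{LabelVolume}.
#' @param stem output path stem.
#' @return the three paths, invisibly.
#' @export
writeLabelVolume <- function(lab, stem) {
  paths <- paste0(stem, c("_regions.nii.gz", "_hemispheres.nii.gz",
                          "_ventricles.nii.gz"))
  parts <- list(lab@regions, lab@hemispheres, lab@ventricles + 0L)
  for (i in 1:3) {
    vg <- VolumeGrid(parts[[i]], spacing = lab@spacing, origin = lab@origin,
                     modality = "PARAMETRIC")
    writeVolume(vg, paths[i])
  }
  invisible(paths)
}

#' Read a LabelVolume written by [writeLabelVolume()]
#' @param stem the path stem used when writing.
#' @return a \linkS4class{LabelVolume}.
#' @export
readLabelVolume <- function(stem) {
  reg <- readVolume(paste0(stem, "_regions.nii.gz"), "PARAMETRIC")
  hem <- readVolume(paste0(stem, "_hemispheres.nii.gz"), "PARAMETRIC")
  ven <- readVolume(paste0(stem, "_ventricles.nii.gz"), "PARAMETRIC")
  LabelVolume(round(hem@values) * 0L + round(reg@values),
              round(hem@values), round(ven@values) > 0,
              spacing = reg@spacing, origin = reg@origin)
}

.hemiCodes <- c("left", "right", "both")

#' Read a region table
#'
#' TSV with columns \code{region_id}, \code{name}, \code{hemisphere}
#' (\code{left}/\code{right}/\code{both}), \code{cortical} (logical) and
#' \code{excluded} (logical). Exclusions are explicit rows, never silent
#' deletions; the number of active (non-excluded) regions is reported by
#' [activeRegionCount()].
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
readRegionTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateRegionTable(tb)
}

#' Validate a region table
#' @param tb data.frame candidate.
#' @return the table with normalised column types.
#' @export
validateRegionTable <- function(tb) {
  if (nrow(tb) == 0L) stop("no regions")
  need <- c("region_id", "name", "hemisphere", "cortical", "excluded")
  if (!all(need %in% names(tb)))
    stop("region table must have columns: ", paste(need, collapse = ", "))
  tb$region_id <- as.integer(tb$region_id)
  if (anyDuplicated(tb$region_id))
    stop("duplicated region_id in region table")
  if (!all(tb$hemisphere %in% .hemiCodes))
    stop("unknown hemisphere code (expected left/right/both)")
  tb$cortical <- as.logical(tb$cortical)
  tb$excluded <- as.logical(tb$excluded)
  tb
}

#' Write a region table as TSV
#' @param tb region table data.frame.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeRegionTable <- function(tb, path) {
  utils::write.table(tb, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Number of active (non-excluded) regions
#' @param tb a region table.
#' @return integer count.
#' @export
activeRegionCount <- function(tb) sum(!tb$excluded)

#' Read a healthy-reference table
#'
#' TSV with columns \code{region_id}, \code{hemisphere}, \code{mean},
#' \code{sd}, \code{n}.
#'
#' @param path TSV file.
#' @return a \linkS4class{HealthyReference}.
#' @export
readHealthyReference <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  HealthyReference(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Write a healthy-reference table as TSV
#' @param ref a \linkS4class{HealthyReference}.
#' @param path output TSV.
#' @return \code{path}, invisibly.
#' @export
writeHealthyReference <- function(ref, path) {
  utils::write.table(ref@table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a behavioural score sheet
#'
#' CSV/TSV (delimiter auto-detected from the extension) with columns
#' \code{animal}, \code{group}, \code{day} and the nine score items; see
#' [validateScoreSheet()] for ranges.
#'
#' @param path input file (.csv or .tsv).
#' @return validated data.frame.
#' @export
readScoreSheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  validateScoreSheet(utils::read.table(path, sep = sep, header = TRUE,
                                       stringsAsFactors = FALSE))
}

#' Write a behavioural score sheet
#' @param sheet score sheet data.frame.
#' @param path output file (.csv or .tsv decides the delimiter).
#' @return \code{path}, invisibly.
#' @export
writeScoreSheet <- function(sheet, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(sheet, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
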