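## VolumeGrid: a 3D scalar field with voxel spacing, modality and units.
## Stored on disk as NIfTI-1 (float32), RAS orientation, with
## "<modality>;<units>" carried in the header description field.

#' Construct a volume grid
#'
#' @param data Numeric 3D array (CT in Hounsfield units, PET in kBq/mL).
#' @param spacing Voxel spacing in mm, length 3, all > 0.
#' @param modality `"CT"` or `"PET"`.
#' @param units `"HU"` for CT, `"kBq/mL"` for PET.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(data, spacing, modality = c("CT", "PET"), units = NULL) {
  modality <- match.arg(modality)
  if (is.null(units)) units <- if (modality == "CT") "HU" else "kBq/mL"
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacing must be three positive values (mm)")
  if (modality == "CT" && units != "HU")
    stop("CT volumes carry Hounsfield units ('HU')")
  if (modality == "PET" && units != "kBq/mL")
    stop("PET volumes carry activity concentration ('kBq/mL')")
  structure(
    list(data = data, spacing = spacing, modality = modality,
         units = units, orientation = "RAS"),
    class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s [%s]  %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$modality, x$units, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel volume in millilitres
#' @param x A `volume_grid` or a spacing vector (mm).
#' @export
voxel_volume_ml <- function(x) {
  sp <- if (inherits(x, "volume_grid")) x$spacing else as.numeric(x)
  prod(sp) / 1000
}

#' Write a volume to NIfTI-1
#'
#' Values are stored as float32; spacing goes in the header `pixdim` and
#' modality/units in the description field so that [read_volume()] can
#' restore them.
#'
#' @param vol A `volume_grid`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_grid"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(
    vol$data,
    reference = list(pixdim = c(-1, vol$spacing, 1, 1, 1, 1),
                     descrip = paste(vol$modality, vol$units, sep = ";")),
    datatype = "float")
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a volume from NIfTI-1
#'
#' @param path Path to a NIfTI file.
#' @param modality,units Used only when the file's description field does
#'   not carry them (e.g. volumes written by other software).
#' @return A `volume_grid`.
#' @export
read_volume <- function(path, modality = NULL, units = NULL) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("cannot read NIfTI volume '", path, "': ",
                                           conditionMessage(e)))
  if (length(dim(img)) != 3) stop("expected a 3D volume: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("missing or invalid voxel spacing in ", path)
  descrip <- RNifti::niftiHeader(img)$descrip
  tag <- strsplit(descrip, ";", fixed = TRUE)[[1]]
  if (is.null(modality)) {
    if (length(tag) >= 1 && tag[1] %in% c("CT", "PET")) modality <- tag[1]
    else stop("modality not recorded in ", path, "; pass `modality=`")
  }
  if (is.null(units) && length(tag) >= 2 && nzchar(tag[2])) units <- tag[2]
  volume_grid(array(as.numeric(img), dim(img)), sp, modality, units)
}

#' Write an integer label volume (masks, class maps) as NIfTI
#' @param labels Integer or logical 3D array.
#' @param spacing Voxel spacing in mm.
#' @param path Output path.
#' @export
write_labels <- function(labels, spacing, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  img <- RNifti::asNifti(array(as.integer(labels), dim(labels)),
                         reference = list(pixdim = c(-1, spacing, 1, 1, 1, 1),
                                          descrip = "LABELS;"),
                         datatype = "int16")
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' Read an integer label volume written by [write_labels()]
#' @param path Path to the label NIfTI.
#' @return Integer array with attribute `spacing`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  img <- RNifti::readNifti(path)
  out <- array(as.integer(img), dim(img))
  attr(out, "spacing") <- RNifti::pixdim(img)[1:3]
  out
}
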