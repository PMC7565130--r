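#' SUV volume container
#'
#' A 3-D grid of standardized uptake values (SUV, dimensionless body-weight
#' normalisation) together with its voxel spacing in mm. All downstream
#' volumetrics use the voxel volume in cm^3, the product of the spacings
#' divided by 1000, so anisotropic grids are handled transparently; the study
#' grid is isotropic 4 x 4 x 4 mm (voxel volume 0.064 cm^3).
#'
#' @param data numeric 3-D array of SUVs; all values must be finite and >= 0.
#' @param spacing numeric length-3, voxel edge lengths in mm per axis (> 0).
#' @param origin numeric length-3, physical offset in mm (informational).
#' @return An object of class `suv_volume` with elements `data`, `spacing`,
#'   `origin` and the precomputed `voxel_volume` (cm^3).
#' @examples
#' vol <- suv_volume(array(1, c(5, 5, 5)), spacing = c(4, 4, 4))
#' vol$voxel_volume  # 0.064 cm^3
#' @export
suv_volume <- function(data, spacing = c(4, 4, 4), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array, got ", length(dim(data)), " dimension(s)")
  if (anyNA(data) || any(!is.finite(data)))
    stop("SUV values must be finite and non-missing")
  if (any(data < 0)) stop("SUV values must be >= 0")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel edge lengths in mm")
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin),
         voxel_volume = prod(spacing) / 1000),
    class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("SUV volume: %s voxels, spacing %s mm (voxel %.4g cm^3), SUVmax %.3g\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              x$voxel_volume, max(x$data)))
  invisible(x)
}

#' Read a PET SUV volume from a NIfTI file
#'
#' Reads a 3-D NIfTI-1 image (`.nii` / `.nii.gz`); voxel values are passed
#' through unchanged (they are assumed to already be SUVs — use
#' [suv_from_activity()] for activity-concentration images) and the spacing is
#' taken from the header `pixdim` fields.
#'
#' @param path path to a readable NIfTI file containing a 3-D image.
#' @return An [suv_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D image, got ", length(d), " dimensions in ", path)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (any(spacing <= 0))
    stop("non-positive voxel spacing in header of ", path)
  suv_volume(array(as.numeric(img), dim = d), spacing = spacing)
}

#' Write an SUV volume to a NIfTI file
#'
#' @param vol an [suv_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "suv_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Injection record for SUV normalisation
#'
#' @param injected_dose injected activity in MBq (> 0).
#' @param body_weight patient body weight in kg (> 0).
#' @param uptake_time minutes from injection to acquisition (informational;
#'   the study protocol used 60 min after 3.7 MBq/kg).
#' @return An object of class `injection_record`.
#' @export
injection_record <- function(injected_dose, body_weight, uptake_time = 60) {
  if (!is.numeric(injected_dose) || injected_dose <= 0) stop("injected dose must be > 0 MBq")
  if (!is.numeric(body_weight) || body_weight <= 0) stop("body weight must be > 0 kg")
  structure(list(injected_dose = injected_dose, body_weight = body_weight,
                 uptake_time = uptake_time),
            class = "injection_record")
}

#' Convert an activity-concentration volume to SUV
#'
#' Standard body-weight SUV: `SUV = activity [kBq/mL] * weight [kg] /
#' dose [MBq]` (the kBq/mL-per-MBq/kg units cancel, SUV is dimensionless).
#'
#' @param activity numeric 3-D array of activity concentration in kBq/mL (>= 0).
#' @param spacing voxel spacing in mm, length 3.
#' @param injection an [injection_record()].
#' @return An [suv_volume()].
#' @examples
#' inj <- injection_record(injected_dose = 222, body_weight = 60)
#' suv_from_activity(array(5, c(2, 2, 2)), c(4, 4, 4), inj)$data[1]  # 1.3514
#' @export
suv_from_activity <- function(activity, spacing, injection) {
  stopifnot(inherits(injection, "injection_record"))
  if (any(activity < 0)) stop("activity values must be >= 0")
  suv_volume(activity * injection$body_weight / injection$injected_dose,
             spacing = spacing)
}
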