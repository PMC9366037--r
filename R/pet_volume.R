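#' PET volume container
#'
#' A minimal 3D container for a PET scan expressed in standardized uptake
#' value (SUV) units: a numeric array plus anisotropic voxel spacing, the
#' physical position of the first voxel, and an optional organ label mask
#' (0 = none, 1 = liver, 2 = spleen, 3 = bone marrow).
#'
#' Physical coordinates refer to voxel centers: voxel `(i, j, k)` (1-based R
#' indices) sits at `origin + (c(i, j, k) - 1) * spacing` in mm.
#'
#' @param values 3D numeric array of SUV (all values must be >= 0).
#' @param spacing Numeric length-3, per-axis voxel size in mm (> 0).
#' @param origin Numeric length-3, physical position (mm) of voxel (1,1,1).
#' @param labels Optional integer array, same shape as `values`, with organ
#'   codes as above.
#'
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(values, spacing, origin = c(0, 0, 0), labels = NULL) {
  if (length(dim(values)) != 3L) {
    abort("`values` must be a 3D array.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel sizes in mm.")
  }
  if (any(values < 0, na.rm = TRUE)) {
    abort("SUV values must be non-negative.")
  }
  if (!is.null(labels) && !identical(dim(labels), dim(values))) {
    abort("`labels` must have the same shape as `values`.")
  }
  structure(
    list(
      values = values,
      spacing = spacing,
      origin = as.numeric(origin),
      labels = labels
    ),
    class = "pet_volume"
  )
}

#' @export
print.pet_volume <- function(x, ...) {
  cat(
    "<pet_volume> ", paste(dim(x$values), collapse = " x "),
    " voxels, spacing ", paste(format(x$spacing), collapse = " x "), " mm\n",
    "  SUV range [", format(min(x$values)), ", ", format(max(x$values)), "]",
    if (!is.null(x$labels)) ", organ labels present" else "", "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$values)

#' Volume of one voxel in cm^3
#' @param vol A `pet_volume`.
#' @return Scalar voxel volume in cm^3.
#' @export
voxel_volume_cm3 <- function(vol) prod(vol$spacing) / 1000

#' Physical coordinates (mm) of voxel indices
#'
#' @param vol A `pet_volume`.
#' @param idx Integer matrix (n x 3) of 1-based voxel indices.
#' @return n x 3 matrix of voxel-center coordinates in mm.
#' @export
voxel_to_mm <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Convert an activity-concentration grid to body-weight SUV
#'
#' SUV normalizes the measured activity concentration by the injected dose
#' per unit body mass, assuming tissue density 1 g/mL (so Bq/mL and Bq/g are
#' interchangeable) and dose already decay-corrected:
#' `SUV = activity (Bq/mL) / (dose (Bq) / weight (g))`.
#'
#' @param activity_bq_ml 3D numeric array of activity concentration (Bq/mL).
#' @param injected_dose_mbq Injected dose in MBq (> 0).
#' @param body_weight_kg Body weight in kg (> 0).
#' @param spacing,origin,labels Passed to [pet_volume()].
#' @return A `pet_volume` in SUV units.
#' @export
to_suv <- function(activity_bq_ml, injected_dose_mbq, body_weight_kg,
                   spacing, origin = c(0, 0, 0), labels = NULL) {
  if (!is.numeric(injected_dose_mbq) || length(injected_dose_mbq) != 1L ||
      !is.finite(injected_dose_mbq) || injected_dose_mbq <= 0) {
    abort("`injected_dose_mbq` must be a positive scalar.")
  }
  if (!is.numeric(body_weight_kg) || length(body_weight_kg) != 1L ||
      !is.finite(body_weight_kg) || body_weight_kg <= 0) {
    abort("`body_weight_kg` must be a positive scalar.")
  }
  suv <- activity_bq_ml / (injected_dose_mbq * 1e6 / (body_weight_kg * 1e3))
  pet_volume(suv, spacing = spacing, origin = origin, labels = labels)
}
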