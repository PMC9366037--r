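#' Write a PET volume as NIfTI with a JSON sidecar
#'
#' @param vol A [pet_volume()].
#' @param path Output NIfTI path (`.nii` or `.nii.gz`).
#' @param sidecar Optional path for a JSON sidecar recording spacing,
#'   origin and any extra metadata.
#' @param labels_path Optional path for the organ label mask as NIfTI.
#' @param extra Named list merged into the sidecar (e.g. dose, weight,
#'   seed, spec echo).
#' @return `path`, invisibly.
#' @export
write_pet_volume <- function(vol, path, sidecar = NULL, labels_path = NULL,
                             extra = list()) {
  stopifnot(inherits(vol, "pet_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  if (!is.null(labels_path) && !is.null(vol$labels)) {
    lab <- RNifti::asNifti(vol$labels)
    RNifti::pixdim(lab) <- vol$spacing
    RNifti::writeNifti(lab, labels_path)
  }
  if (!is.null(sidecar)) {
    meta <- c(list(spacing_mm = vol$spacing, origin_mm = vol$origin), extra)
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a PET volume from NIfTI
#'
#' Spacing comes from the NIfTI header; a JSON sidecar, when supplied,
#' overrides it (the override is messaged). A volume whose header carries
#' no positive spacing and no sidecar is an error.
#'
#' @param path NIfTI path.
#' @param sidecar Optional JSON sidecar path with `spacing_mm` (and
#'   optionally `origin_mm`, `injected_dose_mbq`, `body_weight_kg`).
#' @param labels_path Optional organ-label NIfTI of the same shape.
#' @return A [pet_volume()]. If the sidecar carries dose and weight, the
#'   voxel data are interpreted as activity (Bq/mL) and converted to SUV.
#' @export
read_pet_volume <- function(path, sidecar = NULL, labels_path = NULL) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  origin <- c(0, 0, 0)
  meta <- NULL
  if (!is.null(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$spacing_mm)) {
      if (any(abs(as.numeric(meta$spacing_mm) - spacing) > 1e-6)) {
        message("sidecar spacing overrides NIfTI header spacing")
      }
      spacing <- as.numeric(meta$spacing_mm)
    }
    if (!is.null(meta$origin_mm)) origin <- as.numeric(meta$origin_mm)
  }
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("no positive voxel spacing in header or sidecar")
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    labels <- array(as.integer(RNifti::readNifti(labels_path)),
                    dim = dim(img))
  }
  arr <- array(as.numeric(img), dim = dim(img))
  if (!is.null(meta$injected_dose_mbq) && !is.null(meta$body_weight_kg)) {
    return(to_suv(arr, meta$injected_dose_mbq, meta$body_weight_kg,
                  spacing = spacing, origin = origin, labels = labels))
  }
  pet_volume(arr, spacing = spacing, origin = origin, labels = labels)
}

# column dictionary of the cohort CSV (gen_cohort's output schema)
cohort_required_cols <- function() {
  c("time_months", "event")
}

cohort_known_cols <- function() {
  c("patient_id", "age_years", "sex", "b_symptoms", "grade_3a",
    "bm_involved", "ann_arbor_34", "n_nodal_sites", "lodlin_cm", "hb_g_dl",
    "platelet_1e9_l", "ldh_elevated", "b2mg_elevated", "immunochemo",
    "suv_max", "tmtv_cm3", "tlg", "d_max_cm", "time_months", "event",
    "n_factors", "risk_category", "flipi", "flipi2", "prima_pi")
}

#' Read a cohort CSV with schema validation
#'
#' @param path CSV path.
#' @param required Columns that must be present (default: `time_months`,
#'   `event`). Missing columns raise an itemized error; columns outside the
#'   documented dictionary are reported with a message but kept.
#' @return A tibble.
#' @export
read_cohort <- function(path, required = cohort_required_cols()) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("cohort CSV is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(df), cohort_known_cols())
  if (length(extra) > 0) {
    message("cohort CSV has columns outside the documented dictionary: ",
            paste(extra, collapse = ", "))
  }
  df
}

#' Write a cohort CSV
#' @param data Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Write / read an analysis report as JSON
#'
#' Reports round-trip: writing and re-reading a list of scalar and tabular
#' results returns an equal structure.
#'
#' @param report Named list of results (scalars, vectors, data frames).
#' @param path JSON path.
#' @return `path`, invisibly (writer); the parsed list (reader).
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
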