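#' @title Lesion detection and 41% SUVmax delineation
#' @description Internal engine: 26-connected components of supra-threshold
#'   voxels, labelled via an igraph components pass over the voxel adjacency.
#' @noRd
label_components_26 <- function(dim3, fg_lin) {
  n_fg <- length(fg_lin)
  if (n_fg == 0L) return(integer(0))
  id <- array(0L, dim = dim3)
  id[fg_lin] <- seq_len(n_fg)
  coords <- arrayInd(fg_lin, dim3)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & (offs[, 3] > 0 |
           (offs[, 3] == 0 & (offs[, 2] > 0 | (offs[, 2] == 0 & offs[, 1] > 0)))), ,
           drop = FALSE]  # 13 half-offsets; each unordered pair visited once
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dim3[1] &
          nb[, 2] >= 1 & nb[, 2] <= dim3[2] &
          nb[, 3] >= 1 & nb[, 3] <= dim3[3]
    if (!any(ok)) next
    nb_lin <- (nb[ok, 3] - 1L) * (dim3[1] * dim3[2]) +
              (nb[ok, 2] - 1L) * dim3[1] + nb[ok, 1]
    nb_id <- id[nb_lin]
    hit <- nb_id > 0L
    if (any(hit)) {
      edges[[k]] <- cbind(which(ok)[hit], nb_id[hit])
    }
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n_fg, directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  igraph::components(g)$membership
}

#' Detect candidate lesions above an absolute SUV threshold
#'
#' First pass of the two-pass delineation scheme: voxels with SUV at or
#' above `detect_suv` are grouped into 26-connected components; components
#' smaller than `min_volume_cm3` and voxels inside the exclusion mask (e.g.
#' user-supplied brain/bladder boxes) are dropped. Components are ordered by
#' their SUVmax descending, ties broken by the column-major scan order of
#' the peak voxel. Per-physician lesion picking on a clinical workstation is
#' replaced by this reproducible automation; manual seeds can be mimicked by
#' supplying an exclusion mask around unwanted structures.
#'
#' @param vol A [pet_volume()].
#' @param detect_suv Absolute detection threshold in SUV (> 0; default 2.5).
#' @param min_volume_cm3 Minimum component volume retained (default 0).
#' @param exclusion Optional logical array, same shape as the volume; `TRUE`
#'   voxels are never part of a component.
#' @return A tibble with one row per candidate component: `component`,
#'   `n_voxels`, `volume_cm3`, `suv_max`, `peak_i/j/k` (1-based voxel
#'   indices) and a `voxels` list-column of linear voxel indices. Zero rows
#'   when nothing exceeds the threshold.
#' @export
detect_lesions <- function(vol, detect_suv = 2.5, min_volume_cm3 = 0,
                           exclusion = NULL) {
  stopifnot(inherits(vol, "pet_volume"))
  if (!is_scalar_number(detect_suv) || detect_suv <= 0) {
    abort("`detect_suv` must be a positive SUV.")
  }
  v <- vol$values
  fg <- v >= detect_suv
  if (!is.null(exclusion)) {
    if (!identical(dim(exclusion), dim(v))) {
      abort("`exclusion` must match the volume's shape.")
    }
    fg <- fg & !exclusion
  }
  fg_lin <- which(fg)
  empty <- tibble::tibble(
    component = integer(), n_voxels = integer(), volume_cm3 = numeric(),
    suv_max = numeric(), peak_i = integer(), peak_j = integer(),
    peak_k = integer(), voxels = list()
  )
  if (length(fg_lin) == 0L) return(empty)

  memb <- label_components_26(dim(v), fg_lin)
  voxvol <- voxel_volume_cm3(vol)
  comps <- split(fg_lin, memb)
  rows <- purrr::map(comps, function(vox) {
    suv <- v[vox]
    peak_lin <- vox[which.max(suv)]  # first max in scan order breaks ties
    pk <- arrayInd(peak_lin, dim(v))
    tibble::tibble(
      n_voxels = length(vox), volume_cm3 = length(vox) * voxvol,
      suv_max = max(suv), peak_i = pk[1], peak_j = pk[2], peak_k = pk[3],
      peak_lin = peak_lin, voxels = list(vox)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::filter(out, .data$volume_cm3 >= min_volume_cm3)
  if (nrow(out) == 0L) return(empty)
  out <- dplyr::arrange(out, dplyr::desc(.data$suv_max), .data$peak_lin)
  out$component <- seq_len(nrow(out))
  dplyr::select(out, "component", "n_voxels", "volume_cm3", "suv_max",
                "peak_i", "peak_j", "peak_k", "voxels")
}

#' Delineate one lesion with the 41%-of-SUVmax isocontour
#'
#' Within a candidate component's voxels, keeps those with SUV at or above
#' 41% of the component's own SUVmax (closed threshold: a voxel exactly at
#' 41% is included), then restricts to the 26-connected piece containing the
#' peak voxel. The threshold is per lesion — each lesion is delineated
#' against its own SUVmax, not the patient's. The lesion's position is the
#' physical center of its SUVmax voxel (ties broken by column-major scan
#' order).
#'
#' @param vol A [pet_volume()].
#' @param component One row of the [detect_lesions()] tibble (or a tibble
#'   with the same columns and a single row).
#' @param threshold_frac Isocontour fraction of lesion SUVmax (default 0.41).
#' @return A one-row tibble: `suv_max`, `suv_mean`, `mtv_cm3`, `tlg`,
#'   `n_voxels`, `peak_x_mm`/`peak_y_mm`/`peak_z_mm`, `organ_tag` (from the
#'   organ label at the peak voxel: `"spleen"`, `"bone_marrow"`, `"liver"`,
#'   else `"node"`), `focal` (always `TRUE` for detected components) and the
#'   `voxels` list-column of the delineated mask.
#' @export
delineate_41 <- function(vol, component, threshold_frac = 0.41) {
  stopifnot(inherits(vol, "pet_volume"))
  if (nrow(component) != 1L) abort("`component` must be a single row.")
  vox <- component$voxels[[1]]
  if (length(vox) == 0L) abort("component has no voxels")
  v <- vol$values
  suv_max <- max(v[vox])
  thr <- threshold_frac * suv_max
  keep <- vox[v[vox] >= thr]
  # restrict to the connected piece holding the peak
  memb <- label_components_26(dim(v), keep)
  peak_lin <- keep[which.max(v[keep])]
  keep <- keep[memb == memb[match(peak_lin, keep)]]

  suv <- v[keep]
  voxvol <- voxel_volume_cm3(vol)
  mtv <- length(keep) * voxvol
  suv_mean <- mean(suv)
  pk <- arrayInd(peak_lin, dim(v))
  pos <- voxel_to_mm(vol, pk)
  organ <- "node"
  if (!is.null(vol$labels)) {
    organ <- c("node", "liver", "spleen", "bone_marrow")[vol$labels[peak_lin] + 1L]
    if (is.na(organ)) organ <- "other"
  }
  tibble::tibble(
    suv_max = suv_max, suv_mean = suv_mean, mtv_cm3 = mtv,
    tlg = mtv * suv_mean, n_voxels = length(keep),
    peak_x_mm = pos[1], peak_y_mm = pos[2], peak_z_mm = pos[3],
    organ_tag = organ, focal = TRUE, voxels = list(keep)
  )
}

#' Spleen involvement rule
#'
#' The spleen counts as involved if there is focal uptake inside it (a
#' detected component whose peak voxel lies in the spleen mask) or if its
#' diffuse uptake exceeds 150% of the liver background (mean spleen SUV >
#' 1.5 x mean liver SUV).
#'
#' @param vol A [pet_volume()] whose `labels` carry liver (1) and spleen (2),
#'   unless explicit masks are given.
#' @param lesions Optional tibble from [detect_lesions()]; detected fresh at
#'   `detect_suv` when omitted.
#' @param spleen_mask,liver_mask Optional logical arrays overriding the
#'   label mask.
#' @param detect_suv Detection threshold for the focal rule.
#' @return A one-row tibble: `involved` (logical, `NA` when undetermined),
#'   `reason`, `spleen_mean_suv`, `liver_mean_suv`.
#' @export
spleen_involved <- function(vol, lesions = NULL, spleen_mask = NULL,
                            liver_mask = NULL, detect_suv = 2.5) {
  stopifnot(inherits(vol, "pet_volume"))
  if (is.null(spleen_mask) && !is.null(vol$labels)) spleen_mask <- vol$labels == 2L
  if (is.null(liver_mask) && !is.null(vol$labels)) liver_mask <- vol$labels == 1L
  if (is.null(spleen_mask) || !any(spleen_mask) ||
      is.null(liver_mask) || !any(liver_mask)) {
    warn("spleen or liver mask missing; involvement undetermined")
    return(tibble::tibble(involved = NA, reason = "undetermined: missing masks",
                          spleen_mean_suv = NA_real_, liver_mean_suv = NA_real_))
  }
  if (is.null(lesions)) lesions <- detect_lesions(vol, detect_suv = detect_suv)
  spleen_mean <- mean(vol$values[spleen_mask])
  liver_mean <- mean(vol$values[liver_mask])

  focal <- FALSE
  if (nrow(lesions) > 0) {
    peak_lin <- (lesions$peak_k - 1L) * prod(dim(vol)[1:2]) +
                (lesions$peak_j - 1L) * dim(vol)[1] + lesions$peak_i
    focal <- any(spleen_mask[peak_lin])
  }
  diffuse <- spleen_mean > 1.5 * liver_mean
  reason <- if (focal) "focal uptake in spleen" else if (diffuse)
    "diffuse uptake > 150% of liver background" else "no focal or diffuse criterion met"
  tibble::tibble(involved = focal || diffuse, reason = reason,
                 spleen_mean_suv = spleen_mean, liver_mean_suv = liver_mean)
}

#' Bone-marrow volume rule
#'
#' Bone-marrow uptake contributes to volume measurements only when focal:
#' lesions whose peak lies in the marrow mask are kept only if flagged
#' `focal` (every component found by [detect_lesions()] is focal by
#' construction; diffuse marrow signal never forms a discrete component and
#' so contributes nothing). Without a marrow mask the list passes through
#' unchanged with a warning.
#'
#' @param lesions Tibble of delineated lesions ([delineate_41()] rows).
#' @param vol The source [pet_volume()] (for its label mask), or `NULL`.
#' @return The filtered lesion tibble.
#' @export
bone_marrow_filter <- function(lesions, vol = NULL) {
  has_bm <- !is.null(vol) && !is.null(vol$labels) && any(vol$labels == 3L)
  if (!has_bm) {
    warn("no bone-marrow mask provided; lesions pass through unchanged")
    return(lesions)
  }
  focal <- lesions$focal %||% rep(TRUE, nrow(lesions))
  dplyr::filter(lesions, .data$organ_tag != "bone_marrow" | focal)
}

#' Lesion dissemination Dmax
#'
#' The largest physical distance between any two lesions of a patient,
#' reported in cm. Positions default to each lesion's SUVmax voxel; the
#' mask centroid is available as an option. Patients with zero or one
#' lesion have Dmax 0 cm by convention.
#'
#' @param lesions Tibble of delineated lesions with `peak_*_mm` columns (and
#'   `centroid_*_mm` columns when `position = "centroid"` is requested and
#'   present).
#' @param position `"peak"` (default) or `"centroid"`.
#' @return Dmax in cm.
#' @export
compute_dmax <- function(lesions, position = c("peak", "centroid")) {
  position <- match.arg(position)
  if (is.null(lesions) || nrow(lesions) <= 1L) return(0)
  cols <- if (position == "peak") {
    c("peak_x_mm", "peak_y_mm", "peak_z_mm")
  } else {
    c("centroid_x_mm", "centroid_y_mm", "centroid_z_mm")
  }
  if (!all(cols %in% names(lesions))) {
    abort(paste0("lesion table lacks columns: ",
                 paste(setdiff(cols, names(lesions)), collapse = ", ")))
  }
  max_pairwise_cm(as.matrix(lesions[cols]))
}

#' Patient-level PET summary
#'
#' Aggregates delineated lesions: patient SUVmax is the highest lesion
#' SUVmax, TMTV the sum of lesion MTVs, TLG the sum of per-lesion MTV x
#' SUVmean products, and Dmax the largest pairwise lesion distance.
#'
#' @param lesions Tibble of delineated lesions.
#' @param position Passed to [compute_dmax()].
#' @return One-row tibble: `n_lesions`, `suv_max`, `tmtv_cm3`, `tlg`,
#'   `d_max_cm`. An empty lesion list yields all zeros with a warning.
#' @export
summarize_patient <- function(lesions, position = "peak") {
  if (is.null(lesions) || nrow(lesions) == 0L) {
    warn("no lesions; all patient metrics set to 0")
    return(tibble::tibble(n_lesions = 0L, suv_max = 0, tmtv_cm3 = 0,
                          tlg = 0, d_max_cm = 0))
  }
  tibble::tibble(
    n_lesions = nrow(lesions),
    suv_max = max(lesions$suv_max),
    tmtv_cm3 = sum(lesions$mtv_cm3),
    tlg = sum(lesions$tlg),
    d_max_cm = compute_dmax(lesions, position)
  )
}

#' Full per-patient quantification pipeline
#'
#' Runs detection, per-lesion 41% delineation, the bone-marrow focal-uptake
#' filter and the patient summary in one call; also evaluates the spleen
#' rule when liver and spleen masks are available.
#'
#' @param vol A [pet_volume()].
#' @param detect_suv,min_volume_cm3,exclusion Passed to [detect_lesions()].
#' @param threshold_frac Passed to [delineate_41()].
#' @param position Passed to [compute_dmax()].
#' @return A list of class `fl_patient_pet`: `lesions` (per-lesion tibble),
#'   `patient` (one-row summary tibble), `spleen` (rule result or `NULL`).
#' @export
quantify_patient <- function(vol, detect_suv = 2.5, min_volume_cm3 = 0,
                             exclusion = NULL, threshold_frac = 0.41,
                             position = "peak") {
  comps <- detect_lesions(vol, detect_suv, min_volume_cm3, exclusion)
  lesions <- if (nrow(comps) > 0) {
    purrr::map_dfr(seq_len(nrow(comps)), function(i) {
      delineate_41(vol, comps[i, ], threshold_frac)
    }) |>
      dplyr::mutate(lesion = dplyr::row_number(), .before = 1)
  } else {
    tibble::tibble()
  }
  spleen <- NULL
  if (!is.null(vol$labels) && any(vol$labels == 2L) && any(vol$labels == 1L)) {
    spleen <- spleen_involved(vol, lesions = comps, detect_suv = detect_suv)
  }
  if (nrow(lesions) > 0 && !is.null(vol$labels) && any(vol$labels == 3L)) {
    lesions <- bone_marrow_filter(lesions, vol)
  }
  patient <- if (nrow(lesions) > 0) summarize_patient(lesions, position) else
    suppressWarnings(summarize_patient(lesions))
  structure(list(lesions = lesions, patient = patient, spleen = spleen),
            class = "fl_patient_pet")
}

#' @export
print.fl_patient_pet <- function(x, ...) {
  cat("<fl_patient_pet> ", nrow(x$lesions), " lesion(s)\n", sep = "")
  print(x$patient)
  invisible(x)
}
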