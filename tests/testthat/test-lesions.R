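test_that("SUV conversion follows the body-weight formula", {
  act <- array(5000, dim = c(4, 4, 4))
  v <- to_suv(act, injected_dose_mbq = 185, body_weight_kg = 70,
              spacing = c(4, 4, 4))
  expect_equal(v$values[1], 5000 / (185e6 / 70e3), tolerance = 1e-12)
  expect_true(all(abs(v$values - 1.8919) < 1e-3))
  # zero activity maps to SUV 0; doubling weight doubles SUV
  expect_equal(to_suv(array(0, dim = c(2, 2, 2)), 185, 70, c(1, 1, 1))$values[1], 0)
  v2 <- to_suv(act, 185, 140, c(4, 4, 4))
  expect_equal(v2$values[1], 2 * v$values[1])
  expect_error(to_suv(act, 0, 70, c(4, 4, 4)), "positive")
  expect_error(to_suv(act, 185, -1, c(4, 4, 4)), "positive")
})

test_that("detection finds each well-separated lesion once", {
  ph <- gen_phantom(two_sphere_phantom())
  comps <- detect_lesions(ph$volume, detect_suv = 2.5)
  expect_equal(nrow(comps), 2)
  # ordered by component SUVmax descending
  expect_equal(comps$suv_max, c(10, 6))
  # nothing above threshold -> empty table, not an error
  empty <- detect_lesions(ph$volume, detect_suv = 50)
  expect_equal(nrow(empty), 0)
})

test_that("connectivity matches a brute-force 26-neighborhood flood fill", {
  set.seed(31)
  for (rep in 1:3) {
    mask <- array(runif(9 * 9 * 9) < 0.25, dim = c(9, 9, 9))
    vol <- pet_volume(array(ifelse(mask, 5, 0), dim = dim(mask)), c(2, 2, 2))
    comps <- detect_lesions(vol, detect_suv = 2.5)
    lab <- bf_components(mask)
    expect_equal(nrow(comps), max(lab))
    # identical partition: each detected component is exactly one oracle label
    got <- sort(vapply(comps$voxels, function(v) paste(sort(v), collapse = ","),
                       character(1)))
    want <- sort(vapply(seq_len(max(lab)), function(l) {
      paste(sort(which(lab == l)), collapse = ",")
    }, character(1)))
    expect_identical(got, want)
  }
})

test_that("diagonally touching voxels are one component, separated ones two", {
  v <- array(0, dim = c(6, 6, 6))
  v[2, 2, 2] <- 5
  v[3, 3, 3] <- 5  # 26-neighbor of the first
  vol <- pet_volume(v, c(2, 2, 2))
  expect_equal(nrow(detect_lesions(vol, 2.5)), 1)
  v[3, 3, 3] <- 0
  v[5, 5, 5] <- 5  # separated by background
  expect_equal(nrow(detect_lesions(pet_volume(v, c(2, 2, 2)), 2.5)), 2)
})

test_that("41% isocontour keeps a uniform lesion whole", {
  ph <- gen_phantom(two_sphere_phantom())
  comps <- detect_lesions(ph$volume, 2.5)
  les <- delineate_41(ph$volume, comps[1, ])
  expect_equal(les$suv_max, 10)
  expect_equal(les$suv_mean, 10)
  expect_equal(les$mtv_cm3, ph$truth$lesions$volume_cm3[1])
  expect_equal(les$tlg, ph$truth$lesions$tlg[1])
  # every masked voxel passes the 41% threshold
  expect_true(all(ph$volume$values[les$voxels[[1]]] >= 0.41 * les$suv_max))
})

test_that("isocontour on a radial-falloff lesion matches an exhaustive scan", {
  gs <- c(21, 21, 21)
  sp <- c(2, 2, 2)
  v <- array(0, dim = gs)
  ctr <- c(20, 20, 20)
  for (i in 1:21) for (j in 1:21) for (k in 1:21) {
    d <- sqrt(sum(((c(i, j, k) - 1) * 2 - ctr)^2))
    if (d <= 16) v[i, j, k] <- 10 - 8 * d / 16  # 10 at center to 2 at rim
  }
  vol <- pet_volume(v, sp)
  comps <- detect_lesions(vol, detect_suv = 1)
  les <- delineate_41(vol, comps[1, ])
  # oracle: exhaustive voxel scan at the 41% threshold
  expect_equal(sort(les$voxels[[1]]), sort(which(v >= 0.41 * max(v))))
  expect_equal(les$mtv_cm3, sum(v >= 0.41 * max(v)) * prod(sp) / 1000)
  # delineation is idempotent: rerunning on the delineated mask changes nothing
  again <- delineate_41(vol, les)
  expect_equal(sort(again$voxels[[1]]), sort(les$voxels[[1]]))
  expect_equal(again$mtv_cm3, les$mtv_cm3)
})

test_that("tied SUVmax voxels resolve to the first in scan order", {
  v <- array(0, dim = c(5, 5, 5))
  v[4, 2, 2] <- 8
  v[2, 4, 4] <- 8  # same SUV, later in column-major scan order
  v[3, 3, 3] <- 4  # bridge so both maxima share one component
  vol <- pet_volume(v, c(1, 1, 1))
  comps <- detect_lesions(vol, 2)
  expect_equal(nrow(comps), 1)
  expect_equal(c(comps$peak_i, comps$peak_j, comps$peak_k), c(4L, 2L, 2L))
})

test_that("Dmax follows the pairwise-distance definition", {
  one <- tibble::tibble(peak_x_mm = 0, peak_y_mm = 0, peak_z_mm = 0)
  expect_equal(compute_dmax(one), 0)
  expect_equal(compute_dmax(one[0, ]), 0)
  two <- tibble::tibble(peak_x_mm = c(0, 300), peak_y_mm = c(0, 400),
                        peak_z_mm = c(0, 0))
  expect_equal(compute_dmax(two), 50.0)
  set.seed(8)
  pts <- matrix(runif(15, 0, 500), 5, 3)
  many <- tibble::tibble(peak_x_mm = pts[, 1], peak_y_mm = pts[, 2],
                         peak_z_mm = pts[, 3])
  expect_equal(compute_dmax(many), bf_dmax_cm(pts))
  # rigid translation leaves Dmax unchanged; uniform scaling is linear
  shifted <- many |> dplyr::mutate(peak_x_mm = peak_x_mm + 123,
                                   peak_y_mm = peak_y_mm - 40)
  expect_equal(compute_dmax(shifted), compute_dmax(many))
  scaled <- many |> dplyr::mutate(dplyr::across(dplyr::everything(), ~ .x * 3))
  expect_equal(compute_dmax(scaled), 3 * compute_dmax(many))
})

test_that("patient summary aggregates additively", {
  les <- tibble::tibble(
    suv_max = c(9, 5), suv_mean = c(5, 2), mtv_cm3 = c(10, 20),
    tlg = c(50, 40),
    peak_x_mm = c(0, 100), peak_y_mm = c(0, 0), peak_z_mm = c(0, 0)
  )
  s <- summarize_patient(les)
  expect_equal(s$tmtv_cm3, 30)
  expect_equal(s$tlg, 90)
  expect_equal(s$suv_max, 9)
  expect_equal(s$d_max_cm, 10)
  # removing a lesion removes exactly its contribution
  s1 <- summarize_patient(les[1, ])
  expect_equal(s$tmtv_cm3 - s1$tmtv_cm3, les$mtv_cm3[2])
  expect_equal(s$tlg - s1$tlg, les$tlg[2])
  expect_warning(empty <- summarize_patient(les[0, ]), "no lesions")
  expect_equal(empty$tmtv_cm3, 0)
  expect_equal(empty$d_max_cm, 0)
})

test_that("spleen involvement follows the focal and 150% diffuse rules", {
  mk <- function(spleen_suv, lesion = FALSE) {
    v <- array(1, dim = c(12, 12, 12))
    lab <- array(0L, dim = c(12, 12, 12))
    lab[2:4, 2:4, 2:4] <- 1L   # liver, mean SUV 2
    v[2:4, 2:4, 2:4] <- 2
    lab[8:10, 8:10, 8:10] <- 2L  # spleen
    v[8:10, 8:10, 8:10] <- spleen_suv
    if (lesion) v[9, 9, 9] <- 6
    pet_volume(v, c(4, 4, 4), labels = lab)
  }
  # diffuse rule in isolation: supply an empty lesion table so automatic
  # detection of the uniformly avid spleen does not trip the focal rule
  none <- tibble::tibble()
  d_hi <- spleen_involved(mk(3.2), lesions = none)
  expect_true(d_hi$involved)                          # 3.2 > 1.5 * 2
  expect_match(d_hi$reason, "diffuse")
  expect_false(spleen_involved(mk(2.9), lesions = none)$involved)  # 2.9 < 3.0
  r <- spleen_involved(mk(1.0, lesion = TRUE))
  expect_true(r$involved)
  expect_match(r$reason, "focal")
  # missing masks -> undetermined, flagged
  plain <- pet_volume(array(1, dim = c(5, 5, 5)), c(4, 4, 4))
  expect_warning(u <- spleen_involved(plain), "missing")
  expect_true(is.na(u$involved))
})

test_that("bone-marrow uptake contributes volume only when focal", {
  v <- array(1, dim = c(12, 12, 12))
  lab <- array(0L, dim = c(12, 12, 12))
  lab[2:6, 2:6, 2:6] <- 3L
  v[3:4, 3:4, 3:4] <- 6  # focal marrow lesion
  vol <- pet_volume(v, c(4, 4, 4), labels = lab)
  q <- quantify_patient(vol, detect_suv = 2.5)
  expect_equal(nrow(q$lesions), 1)
  expect_equal(q$lesions$organ_tag, "bone_marrow")
  expect_gt(q$patient$tmtv_cm3, 0)  # focal uptake retained
  # a diffuse (non-focal) marrow lesion is dropped by the filter
  les <- q$lesions
  les$focal <- FALSE
  expect_equal(nrow(bone_marrow_filter(les, vol)), 0)
  # without a marrow mask the list passes through with a warning
  vol2 <- pet_volume(v, c(4, 4, 4))
  expect_warning(kept <- bone_marrow_filter(les, vol2), "no bone-marrow mask")
  expect_equal(nrow(kept), 1)
})
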