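#' Three-factor TLG/Dmax/LDH scoring system
#'
#' Defines the prognostic score built from the three independent PFS risk
#' factors: high TLG, high Dmax, and elevated serum LDH. A patient's count
#' of adverse factors (strict `>` at the cutoffs: a value exactly at a
#' cutoff is not adverse) maps to low (0–1 factors), intermediate (2) or
#' high (3) risk.
#'
#' @param tlg_cutoff TLG cutoff (default 1446.98).
#' @param dmax_cutoff_cm Dmax cutoff in cm (default 56.73).
#' @return A `scoring_system` list.
#' @export
scoring_system <- function(tlg_cutoff = fl_cutoffs()$tlg,
                           dmax_cutoff_cm = fl_cutoffs()$d_max_cm) {
  stopifnot(tlg_cutoff > 0, dmax_cutoff_cm > 0)
  structure(list(tlg_cutoff = tlg_cutoff, dmax_cutoff_cm = dmax_cutoff_cm),
            class = "scoring_system")
}

risk_levels <- c("low", "intermediate", "high")

#' Apply the three-factor score to a cohort
#'
#' Counts adverse factors (TLG > cutoff, Dmax > cutoff, LDH elevated) per
#' patient and assigns the risk category. Patients with any missing input
#' get `NA` in both columns, with a warning.
#'
#' @param data Data frame with columns `tlg`, `d_max_cm`, `ldh_elevated`.
#' @param system A [scoring_system()].
#' @return The data with `n_factors` (0–3) and `risk_category` (ordered
#'   factor low < intermediate < high) appended.
#' @export
score_patients <- function(data, system = scoring_system()) {
  stopifnot(inherits(system, "scoring_system"))
  f <- cbind(
    data$tlg > system$tlg_cutoff,
    data$d_max_cm > system$dmax_cutoff_cm,
    data$ldh_elevated == 1
  )
  n_factors <- as.integer(rowSums(f))
  if (anyNA(n_factors)) warn("missing score inputs; risk category undetermined for some patients")
  data$n_factors <- n_factors
  data$risk_category <- factor(
    ifelse(is.na(n_factors), NA_character_,
           ifelse(n_factors <= 1, "low",
                  ifelse(n_factors == 2, "intermediate", "high"))),
    levels = risk_levels, ordered = TRUE
  )
  tibble::as_tibble(data)
}

count_to_cat <- function(n, breaks) {
  # breaks = c(upper bound of low, upper bound of intermediate)
  factor(ifelse(is.na(n), NA_character_,
                ifelse(n <= breaks[1], "low",
                       ifelse(n <= breaks[2], "intermediate", "high"))),
         levels = risk_levels, ordered = TRUE)
}

#' FLIPI risk group
#'
#' Five adverse factors: age >= 60, Ann Arbor stage III–IV, Hb < 12 g/dl,
#' more than 4 nodal sites, elevated LDH. 0–1 factors low, 2 intermediate,
#' >= 3 high. Patients with a missing input get `NA` with a warning.
#'
#' @param data Data frame with columns `age_years` (or `age_ge60`),
#'   `ann_arbor_34`, `hb_g_dl` (or `hb_lt12`), `n_nodal_sites` (or
#'   `nodal_gt4`), `ldh_elevated`.
#' @return The data with a `flipi` ordered-factor column appended.
#' @export
flipi <- function(data) {
  n <- as.integer(
    flag_of(data, "age_ge60", "age_years", function(x) x >= 60) +
    as_flag(data$ann_arbor_34) +
    flag_of(data, "hb_lt12", "hb_g_dl", function(x) x < 12) +
    flag_of(data, "nodal_gt4", "n_nodal_sites", function(x) x > 4) +
    as_flag(data$ldh_elevated)
  )
  if (anyNA(n)) warn("missing FLIPI inputs; category undetermined for some patients")
  data$flipi <- count_to_cat(n, c(1, 2))
  tibble::as_tibble(data)
}

#' FLIPI2 risk group
#'
#' Five adverse factors: age > 60, elevated beta2-microglobulin, Hb < 12
#' g/dl, longest diameter of the largest involved node (LodLIN) > 6 cm,
#' bone-marrow involvement. 0 factors low, 1–2 intermediate, 3–5 high.
#'
#' @param data Data frame with columns `age_years` (or `age_gt60`),
#'   `b2mg_elevated`, `hb_g_dl` (or `hb_lt12`), `lodlin_cm` (or
#'   `lodlin_gt6`), `bm_involved`.
#' @return The data with a `flipi2` ordered-factor column appended.
#' @export
flipi2 <- function(data) {
  n <- as.integer(
    flag_of(data, "age_gt60", "age_years", function(x) x > 60) +
    as_flag(data$b2mg_elevated) +
    flag_of(data, "hb_lt12", "hb_g_dl", function(x) x < 12) +
    flag_of(data, "lodlin_gt6", "lodlin_cm", function(x) x > 6) +
    as_flag(data$bm_involved)
  )
  if (anyNA(n)) warn("missing FLIPI2 inputs; category undetermined for some patients")
  data$flipi2 <- count_to_cat(n, c(0, 2))
  tibble::as_tibble(data)
}

#' PRIMA-PI risk group
#'
#' Elevated beta2-microglobulin puts a patient in the high-risk group
#' regardless of anything else; otherwise bone-marrow involvement gives
#' intermediate risk, and its absence low risk. The elevated flag is taken
#' as input (a lab-reference flag or a user-thresholded value), since only
#' normal/elevated status is required.
#'
#' @param data Data frame with columns `b2mg_elevated` and `bm_involved`.
#' @return The data with a `prima_pi` ordered-factor column appended.
#' @export
prima_pi <- function(data) {
  b2 <- as_flag(data$b2mg_elevated)
  bm <- as_flag(data$bm_involved)
  cat <- ifelse(is.na(b2), NA_character_,
                ifelse(b2 == 1, "high",
                       ifelse(is.na(bm), NA_character_,
                              ifelse(bm == 1, "intermediate", "low"))))
  if (anyNA(cat)) warn("missing PRIMA-PI inputs; category undetermined for some patients")
  data$prima_pi <- factor(cat, levels = risk_levels, ordered = TRUE)
  tibble::as_tibble(data)
}

#' Append every risk index at once
#'
#' Convenience wrapper: [score_patients()], [flipi()], [flipi2()] and
#' [prima_pi()] in sequence.
#'
#' @param data Data frame carrying the columns each index needs.
#' @param system A [scoring_system()].
#' @return The data with `n_factors`, `risk_category`, `flipi`, `flipi2`,
#'   `prima_pi` appended.
#' @export
add_risk_indices <- function(data, system = scoring_system()) {
  data |>
    score_patients(system) |>
    flipi() |>
    flipi2() |>
    prima_pi()
}

# a 0/1 flag, tolerating logical input; NULL propagates NA
as_flag <- function(x) {
  if (is.null(x)) return(NA_integer_)
  as.integer(x)
}

# prefer an explicit flag column, else derive from the raw value
flag_of <- function(data, flag_col, value_col, pred) {
  if (!is.null(data[[flag_col]])) return(as.integer(data[[flag_col]]))
  v <- data[[value_col]]
  if (is.null(v)) return(rep(NA_integer_, nrow(data)))
  as.integer(pred(v))
}
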