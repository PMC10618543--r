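#' Socio-demographic vocabularies
#'
#' The four categorical patient attributes and their closed vocabularies.
#' Ages are bucketed as printed on intake forms (adults only; patients
#' under 19 are rejected); weight groups follow the CDC BMI categories.
#'
#' @return Named list of character vectors (`age_group`, `gender`,
#'   `smoking`, `weight_group`), in the package's canonical level order.
#' @export
profile_levels <- function() {
  list(age_group = c("19-25", "26-35", "36-45", "46-55", "56-65", "66+"),
       gender = c("female", "male"),
       smoking = c("non-smoker", "smoker"),
       weight_group = c("underweight", "normal", "overweight"))
}

PROFILE_FIELDS <- c("age_group", "gender", "smoking", "weight_group")

#' Construct patient profiles
#'
#' A profile is the immutable socio-demographic tuple
#' `(age group, gender, smoking, weight group)`; the arguments recycle, so
#' vectors build several profiles at once.
#'
#' @param age_group,gender,smoking,weight_group labels from
#'   [profile_levels()].
#' @return A data frame of class `patient_profile` with the four columns.
#' @export
#' @examples
#' patient_profile("66+", "male", "smoker", "overweight")
patient_profile <- function(age_group, gender, smoking, weight_group) {
  prof <- data.frame(age_group = age_group, gender = gender,
                     smoking = smoking, weight_group = weight_group,
                     stringsAsFactors = FALSE)
  validate_profiles(prof)
  class(prof) <- c("patient_profile", "data.frame")
  prof
}

validate_profiles <- function(prof) {
  lv <- profile_levels()
  for (f in PROFILE_FIELDS) {
    if (!f %in% names(prof)) stop("missing profile column: ", f, call. = FALSE)
    bad <- !prof[[f]] %in% lv[[f]]
    if (any(bad)) {
      stop("unknown ", f, " label(s): ",
           paste(unique(prof[[f]][bad]), collapse = ", "), call. = FALSE)
    }
  }
  invisible(prof)
}

#' Enumerate the 72 socio-demographic groups
#'
#' The Cartesian product of the four vocabularies: 6 age groups x 2
#' genders x 2 smoking statuses x 3 weight groups = 72 pairwise-disjoint,
#' exhaustive groups. Ordering is deterministic and lexicographic with age
#' most significant and weight least, each field in its canonical level
#' order, so the first group is (19-25, female, non-smoker, underweight)
#' and the last (66+, male, smoker, overweight).
#'
#' @return A data frame with columns `group_id` (1..72) and the four
#'   label columns.
#' @export
enumerate_groups <- function() {
  lv <- profile_levels()
  g <- expand.grid(weight_group = lv$weight_group, smoking = lv$smoking,
                   gender = lv$gender, age_group = lv$age_group,
                   stringsAsFactors = FALSE)
  g <- g[, rev(names(g))]
  g <- data.frame(group_id = seq_len(nrow(g)), g,
                  row.names = NULL, stringsAsFactors = FALSE)
  g
}

#' Map profiles to their socio-demographic group
#'
#' @param profiles a data frame with the four profile columns.
#' @return Integer vector of group ids (1..72) matching
#'   [enumerate_groups()].
#' @export
#' @examples
#' group_of(patient_profile("19-25", "female", "non-smoker", "underweight"))
group_of <- function(profiles) {
  validate_profiles(profiles)
  lv <- profile_levels()
  ai <- match(profiles$age_group, lv$age_group)
  gi <- match(profiles$gender, lv$gender)
  si <- match(profiles$smoking, lv$smoking)
  wi <- match(profiles$weight_group, lv$weight_group)
  as.integer(((ai - 1) * 2 + (gi - 1)) * 6 + (si - 1) * 3 + wi)
}

#' One-hot feature encoding of profiles
#'
#' Encodes each profile as a 13-dimensional 0/1 vector: one block per
#' field (6 + 2 + 2 + 3 columns) with exactly one 1 per block, columns
#' ordered as in [profile_levels()]. The encoding is injective on
#' profiles.
#'
#' @param profiles a data frame with the four profile columns.
#' @return Numeric matrix, one row per profile, 13 named columns.
#' @export
encode_features <- function(profiles) {
  validate_profiles(profiles)
  lv <- profile_levels()
  blocks <- lapply(PROFILE_FIELDS, function(f) {
    m <- outer(profiles[[f]], lv[[f]], `==`) * 1
    colnames(m) <- paste(f, lv[[f]], sep = ".")
    m
  })
  do.call(cbind, blocks)
}

#' Default bladder-capacity coefficients
#'
#' Shipped calibration for [estimate_hm()]: an affine model in the age
#' midpoint (years) and a weight-group BMI midpoint, with a gender offset,
#' centred so that the mean over a balanced population equals the
#' protocol-average capacity of 1.84e9 cells.
#'
#' @return Named list: `intercept`, `age_slope` (cells per year),
#'   `bmi_slope` (cells per BMI unit), `male_offset` (cells, applied +/-
#'   half to each gender), `age_mid`, `bmi_mid` (per-level midpoints).
#' @export
default_hm_coeffs <- function() {
  age_mid <- c("19-25" = 22, "26-35" = 30.5, "36-45" = 40.5,
               "46-55" = 50.5, "56-65" = 60.5, "66+" = 71)
  bmi_mid <- c(underweight = 17, normal = 21.7, overweight = 29)
  list(intercept = 1.84e9,
       age_slope = -4e6,
       bmi_slope = 2.5e7,
       male_offset = 8e7,
       age_mid = age_mid - mean(age_mid),
       bmi_mid = bmi_mid - mean(bmi_mid))
}

#' Estimate per-patient bladder capacity
#'
#' Bladder cell count as an affine function of the age-group and
#' weight-group midpoints with a gender offset. With the shipped
#' coefficients the balanced-population average equals 1.84e9 cells.
#'
#' @param profiles a data frame with the four profile columns.
#' @param coeffs coefficient list as from [default_hm_coeffs()].
#' @return Numeric vector of capacities (cells, all positive).
#' @export
#' @examples
#' estimate_hm(patient_profile("66+", "female", "smoker", "underweight"))
estimate_hm <- function(profiles, coeffs = default_hm_coeffs()) {
  validate_profiles(profiles)
  hm <- coeffs$intercept +
    coeffs$age_slope * coeffs$age_mid[profiles$age_group] +
    coeffs$bmi_slope * coeffs$bmi_mid[profiles$weight_group] +
    ifelse(profiles$gender == "male", 0.5, -0.5) * coeffs$male_offset
  hm <- unname(hm)
  if (any(hm <= 0)) stop("estimated capacity must be positive", call. = FALSE)
  hm
}

#' Convert polyp volume to cell count and back
#'
#' Clinical records report polyp volumes; the model works in cell counts.
#' Conversion divides by the average bladder-cancer cell volume and rounds
#' to a whole count; the inverse multiplies back.
#'
#' @param volume_mm3 polyp volume(s) in cubic millimetres (>= 0).
#' @param cells cell count(s).
#' @param cell_volume average cancer-cell volume in cubic millimetres
#'   (> 0; default 1e-6).
#' @return `volume_to_cells()`: integer-valued cell counts;
#'   `cells_to_volume()`: volumes in cubic millimetres.
#' @export
#' @examples
#' volume_to_cells(1)          # 1 mm^3 at 1e-6 mm^3 per cell
volume_to_cells <- function(volume_mm3, cell_volume = 1e-6) {
  if (cell_volume <= 0) stop("cell_volume must be positive", call. = FALSE)
  if (any(volume_mm3 < 0)) stop("volume must be non-negative", call. = FALSE)
  round(volume_mm3 / cell_volume)
}

#' @rdname volume_to_cells
#' @export
cells_to_volume <- function(cells, cell_volume = 1e-6) {
  if (cell_volume <= 0) stop("cell_volume must be positive", call. = FALSE)
  cells * cell_volume
}

COHORT_COLUMNS <- c("patient_id", PROFILE_FIELDS,
                    "T_start_cells", "T_end_cells", "t_f_hours",
                    "b", "N", "tau")

validate_cohort <- function(records) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  validate_profiles(records)
  bad <- which(records$T_start_cells <= 0 | !is.finite(records$T_start_cells))
  if (length(bad)) {
    stop("non-positive T_start_cells in row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(records$T_end_cells <= 0 | !is.finite(records$T_end_cells))
  if (length(bad)) {
    stop("non-positive T_end_cells in row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- which(records$t_f_hours <= 0)
  if (length(bad)) {
    stop("non-positive t_f_hours in row(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

#' Read and write patient cohorts
#'
#' Cohorts are stored as UTF-8 CSV with a header row and one row per
#' patient: `patient_id`, the four profile columns, tumor burdens at the
#' start and end of treatment (cells), the treatment end time `t_f_hours`,
#' and the protocol constants `b`, `N`, `tau`. Optional companion columns
#' (e.g. source polyp volumes) are preserved. Validation errors name the
#' offending rows.
#'
#' @param path file path.
#' @param records a cohort data frame.
#' @return `read_cohort()`: a validated cohort data frame of class
#'   `bcg_cohort` (empty file yields an empty cohort with a warning).
#' @export
read_cohort <- function(path) {
  records <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(records) == 0) {
    warning("cohort file '", path, "' contains no patients", call. = FALSE)
    class(records) <- c("bcg_cohort", "data.frame")
    return(records)
  }
  validate_cohort(records)
  class(records) <- c("bcg_cohort", "data.frame")
  records
}

#' @rdname read_cohort
#' @export
write_cohort <- function(records, path) {
  validate_cohort(records)
  write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

record_schedule <- function(record) {
  dose_schedule(b = record$b, n_doses = record$N, tau = record$tau)
}
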