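#' Functional jaw-adductor muscle groups and default pennation angles
#'
#' Archosaur jaw adductors are pooled into three functional groups for lever
#' modelling: the temporal group `mTemp` (mAME + mPSTs), the quadrate group
#' `mQuad` (mPSTp + mAMP) and the pterygoid group `mPt` (mPT). The default
#' pennation angles applied when correcting gross cross-sections in fossil
#' reconstructions are 45, 0 and 30 degrees respectively (averages over
#' extant archosaur samples; 0 means parallel-fibred).
#'
#' @return A tibble with columns `muscle_group` and `pennation_deg`.
#' @export
muscle_groups <- function() {
  tibble::tibble(
    muscle_group = c("mTemp", "mQuad", "mPt"),
    pennation_deg = c(45, 0, 30)
  )
}

#' Muscle specific density (g/mm^3)
#'
#' Default wet-muscle specific density used in the physiological
#' cross-sectional area formula.
#' @export
MUSCLE_DENSITY <- 1.056e-3

#' Physiological cross-sectional area from muscle architecture
#'
#' Computes `A_Phys = M * cos(theta) / (rho * L)` per row, where `M` is wet
#' muscle mass (g), `theta` the mean pennation angle (degrees; `cos(0) = 1`
#' for parallel fibres), `rho` the specific density (g/mm^3) and `L` the mean
#' fibre length (mm). The result is in mm^2.
#'
#' @param data A data frame with columns `mass_g`, `pennation_deg`,
#'   `fibre_length_mm` (additional columns such as `taxon`, `muscle_group`
#'   are carried through).
#' @param rho Specific density in g/mm^3 (default [MUSCLE_DENSITY]).
#' @return The input as a tibble with an added `aphys_mm2` column.
#' @examples
#' aphys_from_architecture(
#'   data.frame(mass_g = 10, pennation_deg = 30, fibre_length_mm = 20)
#' )
#' @export
aphys_from_architecture <- function(data, rho = MUSCLE_DENSITY) {
  require_columns(data, c("mass_g", "pennation_deg", "fibre_length_mm"),
                  "architecture table")
  check_number(data$mass_g, "mass_g", lower = 0, strict_lower = TRUE)
  check_number(data$fibre_length_mm, "fibre_length_mm", lower = 0,
               strict_lower = TRUE)
  check_number(data$pennation_deg, "pennation_deg", lower = 0, upper = 90)
  if (any(data$pennation_deg >= 90)) {
    stop_phybite("`pennation_deg` must lie in [0, 90).")
  }
  check_number(rho, "rho", lower = 0, strict_lower = TRUE)
  dplyr::mutate(
    tibble::as_tibble(data),
    aphys_mm2 = .data$mass_g * cos(.data$pennation_deg * pi / 180) /
      (rho * .data$fibre_length_mm)
  )
}

#' Physiological from gross cross-sectional area (pennation correction)
#'
#' Approximates `A_Phys` for fossil reconstructions from the gross
#' cross-section `A_Gross` by dividing by `sin(theta)`; parallel-fibred
#' muscles (`theta = 0`) are left uncorrected (factor 1), since the sine
#' correction is undefined there. With the group defaults this multiplies
#' `mTemp` areas by sqrt(2), leaves `mQuad` unchanged and doubles `mPt`.
#'
#' @param data A data frame with column `agross_mm2` and either a
#'   `pennation_deg` column or a `muscle_group` column (in which case the
#'   group default angles from [muscle_groups()] are joined in).
#' @return The input as a tibble with added `pennation_deg` (if joined) and
#'   `aphys_mm2` columns.
#' @examples
#' aphys_from_gross(data.frame(muscle_group = "mPt", agross_mm2 = 100))
#' @export
aphys_from_gross <- function(data) {
  require_columns(data, "agross_mm2", "gross-area table")
  data <- tibble::as_tibble(data)
  if (!"pennation_deg" %in% names(data)) {
    require_columns(data, "muscle_group", "gross-area table")
    data <- dplyr::left_join(data, muscle_groups(), by = "muscle_group")
    if (anyNA(data$pennation_deg)) {
      bad <- unique(data$muscle_group[is.na(data$pennation_deg)])
      stop_phybite(sprintf(
        "Unknown muscle group%s (no default pennation angle): %s",
        if (length(bad) > 1) "s" else "", paste(bad, collapse = ", ")))
    }
  }
  check_number(data$agross_mm2, "agross_mm2", lower = 0, strict_lower = TRUE)
  check_number(data$pennation_deg, "pennation_deg", lower = 0, upper = 90)
  if (any(data$pennation_deg >= 90)) {
    stop_phybite("`pennation_deg` must lie in [0, 90).")
  }
  theta <- data$pennation_deg * pi / 180
  factor <- ifelse(data$pennation_deg == 0, 1, 1 / sin(theta))
  dplyr::mutate(data, aphys_mm2 = .data$agross_mm2 * factor)
}

#' Average left and right gross cross-sections
#'
#' The final gross cross-sectional area of a muscle is the mean of the left
#' and right sides; when only one side is measurable (fossil damage or
#' asymmetry) that side is used alone.
#'
#' @param data A data frame with columns `area_left_mm2` and
#'   `area_right_mm2` (either may be `NA` per row, not both).
#' @return The input as a tibble with an added `agross_mm2` column.
#' @export
mean_bilateral_gross <- function(data) {
  require_columns(data, c("area_left_mm2", "area_right_mm2"),
                  "bilateral-area table")
  l <- data$area_left_mm2
  r <- data$area_right_mm2
  if (any(is.na(l) & is.na(r))) {
    stop_phybite("Both sides absent for at least one row.")
  }
  for (v in list(l[!is.na(l)], r[!is.na(r)])) {
    if (length(v)) check_number(v, "area", lower = 0, strict_lower = TRUE)
  }
  dplyr::mutate(tibble::as_tibble(data),
                agross_mm2 = rowMeans(cbind(l, r), na.rm = TRUE))
}

#' Read a muscle-architecture CSV
#'
#' Expects header `taxon,muscle_group,mass_g,pennation_deg,fibre_length_mm`.
#' @param file Path to the CSV file.
#' @return A tibble.
#' @export
read_architecture <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(taxon = "character"))
  require_columns(df, c("taxon", "muscle_group", "mass_g", "pennation_deg",
                        "fibre_length_mm"), "architecture CSV")
  tibble::as_tibble(df)
}

#' Read a gross cross-section CSV
#'
#' Expects header `taxon,muscle_group,area_left_mm2,area_right_mm2`.
#' @param file Path to the CSV file.
#' @return A tibble.
#' @export
read_gross_areas <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(taxon = "character"))
  require_columns(df, c("taxon", "muscle_group", "area_left_mm2",
                        "area_right_mm2"), "gross-area CSV")
  tibble::as_tibble(df)
}
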