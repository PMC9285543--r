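#' Default tetanic muscle stress (N/mm^2)
#'
#' Isometric force per unit physiological cross-sectional area; 0.3 N/mm^2
#' (300 kPa).
#' @export
TETANIC_STRESS <- 0.3

#' Muscle force from physiological cross-sectional area
#'
#' `F_Musc = sigma * A_Phys`, with sigma the tetanic stress.
#'
#' @param data A data frame with column `aphys_mm2` (other columns carried
#'   through).
#' @param sigma Tetanic stress in N/mm^2 (default [TETANIC_STRESS]).
#' @return The input as a tibble with an added `force_n` column.
#' @export
muscle_force <- function(data, sigma = TETANIC_STRESS) {
  require_columns(data, "aphys_mm2", "area table")
  check_number(data$aphys_mm2, "aphys_mm2", lower = 0, strict_lower = TRUE)
  check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  dplyr::mutate(tibble::as_tibble(data), force_n = sigma * .data$aphys_mm2)
}

validate_geometry <- function(geometry) {
  require_columns(geometry,
                  c("taxon", "arm_mTemp_mm", "arm_mQuad_mm", "arm_mPt_mm",
                    "outlever_ant_mm", "outlever_post_mm"),
                  "lever-geometry table")
  geometry <- tibble::as_tibble(geometry)
  geometry$taxon <- norm_label(geometry$taxon)
  num <- c("arm_mTemp_mm", "arm_mQuad_mm", "arm_mPt_mm",
           "outlever_ant_mm", "outlever_post_mm")
  for (v in num) {
    ok <- geometry[[v]][!is.na(geometry[[v]])]
    if (length(ok)) check_number(ok, v, lower = 0, strict_lower = TRUE)
  }
  bad <- geometry$outlever_ant_mm < geometry$outlever_post_mm
  if (any(bad, na.rm = TRUE)) {
    stop_phybite(sprintf(
      "Anterior out-lever must be >= posterior out-lever; violated for: %s",
      paste(geometry$taxon[which(bad)], collapse = ", ")))
  }
  geometry
}

#' Bilateral bite force from muscle forces and lever geometry
#'
#' Static 2-D lever model: each muscle force is multiplied by its moment
#' arm (in-lever) to give a torque about the jaw joint; torques are summed,
#' divided by the out-lever (joint to bite point) and doubled for bilateral
#' action: `F_Bite = 2 * sum(F_i * r_i) / d`. Computed at the anterior-most
#' and posterior-most bite positions; the posterior bite force is always the
#' larger because its out-lever is the shorter.
#'
#' @param forces A data frame with columns `taxon`, `muscle_group`
#'   (`mTemp`, `mQuad`, `mPt`) and `force_n`.
#' @param geometry A data frame with columns `taxon`, `arm_mTemp_mm`,
#'   `arm_mQuad_mm`, `arm_mPt_mm`, `outlever_ant_mm`, `outlever_post_mm`.
#' @param detail If `TRUE`, also return the per-muscle torque table.
#' @return A tibble `taxon, F_BAnt_N, F_BPost_N` (full precision; round at
#'   the reporting layer), or with `detail = TRUE` a list with `$bite` and
#'   `$torques`.
#' @examples
#' bite_force(
#'   data.frame(taxon = "T", muscle_group = c("mTemp", "mQuad", "mPt"),
#'              force_n = c(100, 50, 30)),
#'   data.frame(taxon = "T", arm_mTemp_mm = 40, arm_mQuad_mm = 60,
#'              arm_mPt_mm = 20, outlever_ant_mm = 200,
#'              outlever_post_mm = 100)
#' )
#' @export
bite_force <- function(forces, geometry, detail = FALSE) {
  require_columns(forces, c("taxon", "muscle_group", "force_n"),
                  "force table")
  forces <- tibble::as_tibble(forces)
  forces$taxon <- norm_label(forces$taxon)
  check_number(forces$force_n, "force_n", lower = 0)
  geometry <- validate_geometry(geometry)
  arms <- tidyr::pivot_longer(
    geometry[, c("taxon", "arm_mTemp_mm", "arm_mQuad_mm", "arm_mPt_mm")],
    -"taxon", names_to = "muscle_group", values_to = "moment_arm_mm",
    names_pattern = "arm_(.*)_mm"
  )
  torques <- dplyr::left_join(forces, arms,
                              by = c("taxon", "muscle_group"))
  if (anyNA(torques$moment_arm_mm)) {
    miss <- torques[is.na(torques$moment_arm_mm), ]
    stop_phybite(sprintf(
      "Missing moment arm for: %s",
      paste(sprintf("%s (%s)", miss$muscle_group, miss$taxon),
            collapse = ", ")))
  }
  torques <- dplyr::mutate(torques,
                           torque_nmm = .data$force_n * .data$moment_arm_mm)
  bite <- torques |>
    dplyr::summarise(total_torque_nmm = sum(.data$torque_nmm),
                     .by = "taxon") |>
    dplyr::left_join(geometry[, c("taxon", "outlever_ant_mm",
                                  "outlever_post_mm")], by = "taxon") |>
    dplyr::transmute(
      taxon = .data$taxon,
      F_BAnt_N = 2 * .data$total_torque_nmm / .data$outlever_ant_mm,
      F_BPost_N = 2 * .data$total_torque_nmm / .data$outlever_post_mm
    )
  if (detail) list(bite = bite, torques = torques) else bite
}

#' Bite force from posterior predictive area distributions
#'
#' Converts per-muscle-group posterior predictive distributions of log10
#' A_Phys into bite forces: for each taxon and group the predictive median
#' is taken and back-transformed (`A_Phys = 10^median`; by monotonicity this
#' equals the median of the back-transformed draws), muscle force is
#' `sigma * A_Phys`, and the static lever model is applied.
#'
#' @param predictions A named list with elements `mTemp`, `mQuad` and `mPt`,
#'   each a `ppm_prediction` object on the log10 area scale covering the
#'   same taxa.
#' @param geometry Lever geometry table (see [bite_force()]).
#' @param sigma Tetanic stress in N/mm^2.
#' @param detail Passed to [bite_force()].
#' @return As [bite_force()], plus an `aphys_mm2` column in the detail
#'   torque table.
#' @export
bite_force_from_predictions <- function(predictions, geometry,
                                        sigma = TETANIC_STRESS,
                                        detail = FALSE) {
  groups <- muscle_groups()$muscle_group
  missing <- setdiff(groups, names(predictions))
  if (length(missing) > 0) {
    stop_phybite(sprintf("Missing predictions for muscle group%s: %s",
                         if (length(missing) > 1) "s" else "",
                         paste(missing, collapse = ", ")))
  }
  areas <- purrr::map_dfr(groups, function(g) {
    p <- predictions[[g]]
    stopifnot(inherits(p, "ppm_prediction"))
    tibble::tibble(taxon = p$summary$taxon, muscle_group = g,
                   aphys_mm2 = 10^p$summary$median)
  })
  forces <- muscle_force(areas, sigma = sigma)
  bite_force(forces, geometry, detail = detail)
}

#' Read a lever-geometry CSV
#'
#' Expects header `taxon,arm_mTemp_mm,arm_mQuad_mm,arm_mPt_mm,
#' outlever_ant_mm,outlever_post_mm`.
#' @param file Path to the CSV file.
#' @return A validated tibble.
#' @export
read_lever_geometry <- function(file) {
  validate_geometry(utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c(taxon = "character")))
}
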