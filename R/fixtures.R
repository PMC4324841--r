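#' Packaged annual-mean temperature table
#'
#' Reads the packaged transcription of the study's annual means of daily
#' maximum and minimum air temperature at the six peanut-growing locations
#' (Bhubaneswar, Jalgaon, Junagadh, Raichur, Tirupathi, Vridhachalam), for the
#' 1975 baseline and for each emission scenario (A2, A1B, B1) at the 2020,
#' 2050 and 2080 period slices.
#'
#' @param path Path to a CSV with columns `location`, `variable`
#'   (`"tmax"`/`"tmin"`), `scenario` (`"BL"`, `"A2"`, `"A1B"`, `"B1"`),
#'   `period` (representative year) and `value` (degree C). Defaults to the
#'   packaged table.
#' @return A data frame with those five columns.
#' @seealso [table2_deltas()], [default_location_climates()]
#' @export
read_annual_means <- function(path = system.file("extdata", "table2_annual_means.csv",
                                                 package = "voltigen")) {
  stopifnot(file.exists(path))
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("location", "variable", "scenario", "period", "value")
  if (!all(need %in% names(x))) {
    stop("annual-means table must have columns: ", paste(need, collapse = ", "))
  }
  x
}

#' Packaged printed prediction tables
#'
#' Reads the packaged transcriptions of the study's published replicate
#' summaries for the ensemble climate model: mean +/- standard error of the
#' number of generations, or of the generation time in days, for each
#' location x scenario x period cell.
#'
#' @param which `"generations"` or `"generation_time"`.
#' @return A data frame with columns `location`, `scenario` (`"BL"` for the
#'   baseline row), `period` (representative year), `mean`, `se` and `sig`
#'   (significance marker as printed).
#' @export
read_printed_predictions <- function(which = c("generations", "generation_time")) {
  which <- match.arg(which)
  file <- if (which == "generations") "table3_generations.csv" else "table4_generation_time.csv"
  path <- system.file("extdata", file, package = "voltigen")
  stopifnot(file.exists(path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}
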