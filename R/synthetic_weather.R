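#' Location climate parameters for the weather surrogate
#'
#' Bundles the per-location parameters of the sinusoid-plus-noise daily
#' temperature surrogate: annual means of daily Tmax/Tmin, seasonal
#' amplitudes, the day-of-year of the warmest day, and the daily noise
#' standard deviation that differentiates stochastic replicates.
#'
#' @param name Location label.
#' @param baseline_tmax_mean,baseline_tmin_mean Annual means of daily maximum
#'   and minimum temperature (degree C) in the baseline period.
#' @param seasonal_amplitude_tmax,seasonal_amplitude_tmin Half-range of the
#'   seasonal cosine cycle (degree C), `>= 0`.
#' @param peak_day Day-of-year of the warmest day (1-365).
#' @param daily_noise_sd Standard deviation (degree C) of the independent
#'   Gaussian day-to-day noise added to each of Tmax and Tmin, `>= 0`.
#' @return An object of class `"location_climate"`.
#' @examples
#' location_climate("Bhubaneswar", 31.34, 22.77)
#' @export
location_climate <- function(name, baseline_tmax_mean, baseline_tmin_mean,
                             seasonal_amplitude_tmax = 4,
                             seasonal_amplitude_tmin = 4,
                             peak_day = 135,
                             daily_noise_sd = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(baseline_tmax_mean) || !is.finite(baseline_tmin_mean) ||
      baseline_tmax_mean <= baseline_tmin_mean) {
    stop("baseline_tmax_mean must exceed baseline_tmin_mean")
  }
  if (seasonal_amplitude_tmax < 0 || seasonal_amplitude_tmin < 0) {
    stop("seasonal amplitudes must be >= 0")
  }
  if (peak_day < 1 || peak_day > 365) stop("peak_day must be in 1..365")
  if (daily_noise_sd < 0) stop("daily_noise_sd must be >= 0")
  structure(
    list(
      name = name,
      baseline_tmax_mean = baseline_tmax_mean,
      baseline_tmin_mean = baseline_tmin_mean,
      seasonal_amplitude_tmax = seasonal_amplitude_tmax,
      seasonal_amplitude_tmin = seasonal_amplitude_tmin,
      peak_day = peak_day,
      daily_noise_sd = daily_noise_sd
    ),
    class = "location_climate"
  )
}

#' @export
print.location_climate <- function(x, ...) {
  cat(sprintf(
    "<location_climate> %s\n  annual mean Tmax %.2f C, Tmin %.2f C\n  seasonal amplitude (%.1f, %.1f) C, peak day %d, noise sd %.2f C\n",
    x$name, x$baseline_tmax_mean, x$baseline_tmin_mean,
    x$seasonal_amplitude_tmax, x$seasonal_amplitude_tmin,
    as.integer(x$peak_day), x$daily_noise_sd
  ))
  invisible(x)
}

#' Scenario/period temperature offset
#'
#' An additive shift (degree C) applied uniformly to all daily maxima and
#' minima of a location, encoding how much warmer a scenario x period slice
#' is than the 1975 baseline. The baseline period must carry zero offsets.
#'
#' @param scenario `"A2"`, `"A1B"` or `"B1"` (ignored and stored as `"BL"`
#'   when `period` is `"BL"`).
#' @param period `"BL"`, `"NF"`, `"DF"` or `"VDF"` (baseline 1975, near
#'   future 2020, distant future 2050, very distant future 2080).
#' @param delta_tmax,delta_tmin Offsets in degree C; may be negative.
#' @return An object of class `"scenario_offset"`.
#' @export
scenario_offset <- function(scenario, period, delta_tmax = 0, delta_tmin = 0) {
  stopifnot(length(period) == 1L)
  if (!period %in% period_table()$period) {
    stop("period must be one of ", paste(period_table()$period, collapse = ", "))
  }
  if (period == "BL") {
    if (delta_tmax != 0 || delta_tmin != 0) {
      stop("baseline (BL) offsets must be zero")
    }
    scenario <- "BL"
  } else {
    check_scenario(scenario)
  }
  structure(
    list(scenario = scenario, period = period,
         delta_tmax = delta_tmax, delta_tmin = delta_tmin),
    class = "scenario_offset"
  )
}

#' @export
print.scenario_offset <- function(x, ...) {
  cat(sprintf("<scenario_offset> %s/%s: dTmax %+.2f C, dTmin %+.2f C\n",
              x$scenario, x$period, x$delta_tmax, x$delta_tmin))
  invisible(x)
}

#' Per-location offsets from two annual-mean rows
#'
#' Column-wise subtraction of a baseline row of per-location annual means from
#' a scenario row, giving the additive temperature offset per location for one
#' variable. Deltas may be negative.
#'
#' @param baseline_row,scenario_row Named numeric vectors of annual means
#'   (degree C), names = locations. Both must cover the same location set.
#' @return Named numeric vector of offsets, `scenario - baseline`, in the
#'   order of `baseline_row`.
#' @examples
#' offsets_from_table2(c(Junagadh = 29.93), c(Junagadh = 33.68)) # +3.75
#' @export
offsets_from_table2 <- function(baseline_row, scenario_row) {
  if (is.null(names(baseline_row)) || is.null(names(scenario_row))) {
    stop("both rows must be named by location")
  }
  missing_in_scen <- setdiff(names(baseline_row), names(scenario_row))
  missing_in_base <- setdiff(names(scenario_row), names(baseline_row))
  if (length(missing_in_scen) || length(missing_in_base)) {
    stop("location sets differ: missing ",
         paste(c(missing_in_scen, missing_in_base), collapse = ", "))
  }
  scenario_row[names(baseline_row)] - baseline_row
}

#' All scenario/period offsets implied by an annual-means table
#'
#' Expands a full annual-means table (baseline plus scenario x period rows)
#' into one offset per (location, scenario, period), combining the Tmax and
#' Tmin deltas. Baseline rows yield zero offsets.
#'
#' @param annual_means Data frame as returned by [read_annual_means()].
#' @return Data frame with columns `location`, `scenario`, `period` (label),
#'   `year`, `delta_tmax`, `delta_tmin`.
#' @export
all_scenario_offsets <- function(annual_means = read_annual_means()) {
  base <- annual_means[annual_means$scenario == "BL", ]
  fut <- annual_means[annual_means$scenario != "BL", ]
  key <- function(d) paste(d$location, d$variable)
  b <- base$value[match(key(fut), key(base))]
  if (anyNA(b)) {
    stop("no baseline value for: ",
         paste(unique(key(fut)[is.na(b)]), collapse = ", "))
  }
  fut$delta <- fut$value - b
  wide <- stats::reshape(
    fut[, c("location", "scenario", "period", "variable", "delta")],
    idvar = c("location", "scenario", "period"),
    timevar = "variable", direction = "wide"
  )
  names(wide)[names(wide) == "delta.tmax"] <- "delta_tmax"
  names(wide)[names(wide) == "delta.tmin"] <- "delta_tmin"
  out <- data.frame(
    location = wide$location,
    scenario = wide$scenario,
    period = period_label(wide$period),
    year = as.integer(wide$period),
    delta_tmax = wide$delta_tmax,
    delta_tmin = wide$delta_tmin,
    stringsAsFactors = FALSE
  )
  bl <- unique(base$location)
  out <- rbind(
    data.frame(location = bl, scenario = "BL", period = "BL", year = 1975L,
               delta_tmax = 0, delta_tmin = 0, stringsAsFactors = FALSE),
    out
  )
  rownames(out) <- NULL
  out
}

#' Default location climates from the packaged annual means
#'
#' Builds one [location_climate()] per location, with baseline annual means
#' taken from the packaged table and shared seasonal-cycle/noise defaults.
#'
#' @param annual_means Data frame as returned by [read_annual_means()].
#' @inheritParams location_climate
#' @return Named list of `"location_climate"` objects.
#' @export
default_location_climates <- function(annual_means = read_annual_means(),
                                      seasonal_amplitude_tmax = 4,
                                      seasonal_amplitude_tmin = 4,
                                      peak_day = 135,
                                      daily_noise_sd = 1) {
  base <- annual_means[annual_means$scenario == "BL", ]
  locs <- unique(base$location)
  out <- lapply(locs, function(l) {
    location_climate(
      name = l,
      baseline_tmax_mean = base$value[base$location == l & base$variable == "tmax"],
      baseline_tmin_mean = base$value[base$location == l & base$variable == "tmin"],
      seasonal_amplitude_tmax = seasonal_amplitude_tmax,
      seasonal_amplitude_tmin = seasonal_amplitude_tmin,
      peak_day = peak_day,
      daily_noise_sd = daily_noise_sd
    )
  })
  names(out) <- locs
  out
}

#' Generate one replicate-year of daily Tmax/Tmin
#'
#' Draws a seeded daily weather series from the surrogate model: a cosine
#' seasonal cycle around the location's annual means, shifted by the
#' scenario/period offset, plus independent Gaussian day-to-day noise on each
#' of Tmax and Tmin. Any day on which the drawn minimum exceeds the drawn
#' maximum is repaired by swapping the two values, preserving the day count
#' and seed determinism.
#'
#' The cosine grid sums exactly to zero over the year, so with zero noise the
#' realized annual mean equals `baseline mean + delta` to machine precision,
#' and with noise it converges there as replicates accumulate.
#'
#' @param climate A [location_climate()].
#' @param offset A [scenario_offset()] (default: zero-offset baseline).
#' @param year_length Days in the year, 365 or 366.
#' @param seed Integer seed; identical inputs reproduce the series exactly.
#' @param year Calendar year used for the `date` column (default: the
#'   period's representative year).
#' @return A data frame of class `"weather_series"` with columns `date`,
#'   `doy`, `tmax`, `tmin`, `srad`, `rain` (the last two `NA`: the surrogate
#'   generates temperature only) and attributes `station_id`, `scenario`,
#'   `period`, `seed`.
#' @examples
#' cl <- location_climate("Bhubaneswar", 31.34, 22.77, daily_noise_sd = 0)
#' s <- generate_weather_series(cl, seed = 1)
#' mean(s$tmax) # 31.34
#' @export
generate_weather_series <- function(climate,
                                    offset = scenario_offset("BL", "BL"),
                                    year_length = 365,
                                    seed = 1L,
                                    year = period_year(offset$period)) {
  stopifnot(inherits(climate, "location_climate"),
            inherits(offset, "scenario_offset"))
  if (length(year_length) != 1L || year_length <= 0) {
    stop("year_length must be a positive day count")
  }
  if (!year_length %in% c(365, 366)) {
    stop("year_length must be 365 or 366")
  }
  d <- seq_len(year_length)
  phase <- 2 * pi * (d - climate$peak_day) / year_length
  m_tmax <- climate$baseline_tmax_mean + climate$seasonal_amplitude_tmax * cos(phase)
  m_tmin <- climate$baseline_tmin_mean + climate$seasonal_amplitude_tmin * cos(phase)
  # remove the (tiny) discrete-grid mean of the cosine so annual means close
  # exactly on baseline + delta
  m_tmax <- m_tmax - climate$seasonal_amplitude_tmax * mean(cos(phase))
  m_tmin <- m_tmin - climate$seasonal_amplitude_tmin * mean(cos(phase))
  set.seed(as.integer(seed))
  eps_max <- stats::rnorm(year_length, 0, climate$daily_noise_sd)
  eps_min <- stats::rnorm(year_length, 0, climate$daily_noise_sd)
  tmax <- m_tmax + offset$delta_tmax + eps_max
  tmin <- m_tmin + offset$delta_tmin + eps_min
  swap <- tmin > tmax
  if (any(swap)) {
    tmp <- tmax[swap]
    tmax[swap] <- tmin[swap]
    tmin[swap] <- tmp
  }
  out <- data.frame(
    date = as.Date(d - 1, origin = as.Date(sprintf("%d-01-01", year))),
    doy = d,
    tmax = tmax,
    tmin = tmin,
    srad = NA_real_,
    rain = NA_real_
  )
  attr(out, "station_id") <- climate$name
  attr(out, "scenario") <- offset$scenario
  attr(out, "period") <- offset$period
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("weather_series", "data.frame")
  out
}

#' Generate a set of stochastic weather replicates
#'
#' Produces `n_replicates` independent realizations of the same location x
#' scenario x period climate, differing only in their noise draws. Replicate
#' `r` uses a child seed derived deterministically from `(seed, r)`, so the
#' whole set (and any subset) is reproducible.
#'
#' @inheritParams generate_weather_series
#' @param n_replicates Number of replicates, `>= 1` (study default 20).
#' @param model Optional climate-model code stored with the set.
#' @return An object of class `"replicate_set"`: a list with elements `cell`
#'   (location/model/scenario/period identifiers), `replicates` (list of
#'   `"weather_series"`), `n_replicates` and `seed`.
#' @export
generate_replicate_set <- function(climate,
                                   offset = scenario_offset("BL", "BL"),
                                   n_replicates = 20,
                                   seed = 1L,
                                   year_length = 365,
                                   model = NA_character_) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  reps <- lapply(seq_len(n_replicates), function(r) {
    generate_weather_series(climate, offset,
                            year_length = year_length,
                            seed = mix_seed(seed, r))
  })
  structure(
    list(
      cell = list(location = climate$name, model = model,
                  scenario = offset$scenario, period = offset$period),
      replicates = reps,
      n_replicates = as.integer(n_replicates),
      seed = as.integer(seed)
    ),
    class = "replicate_set"
  )
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("<replicate_set> %s / %s / %s / %s: %d replicates of %d days (seed %d)\n",
              x$cell$location, x$cell$model %||% NA, x$cell$scenario, x$cell$period,
              x$n_replicates, nrow(x$replicates[[1]]), x$seed))
  invisible(x)
}
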