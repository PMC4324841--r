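# Shared fixture builders; everything is generated in code.

# A full replicate-year at constant temperatures.
constant_series <- function(tmax, tmin, days = 365) {
  data.frame(doy = seq_len(days), tmax = tmax, tmin = tmin)
}

# A random but valid replicate-year: tmax >= tmin everywhere.
random_series <- function(days = 365) {
  tmin <- runif(days, 5, 30)
  data.frame(doy = seq_len(days), tmax = tmin + runif(days, 0, 15), tmin = tmin)
}

# Literal day-by-day reference implementation of the accumulation engine,
# kept independent of the package internals: explicit loop, running total,
# boundary recorded when the next multiple of K is first reached.
loop_accumulate <- function(series, window = season_window(),
                            params = gdd_params()) {
  span <- standard_week_days(window)
  idx <- match(span$first_day:span$last_day, series$doy)
  total <- 0
  boundaries <- integer(0)
  next_gen <- 1L
  day_index <- 0L
  for (i in idx) {
    day_index <- day_index + 1L
    m <- (series$tmax[i] + series$tmin[i]) / 2
    m <- min(m, params$t_upper)
    dd <- max(0, m - params$t0)
    total <- total + dd
    while (total >= next_gen * params$k - 1e-9) {
      boundaries <- c(boundaries, day_index)
      next_gen <- next_gen + 1L
    }
  }
  list(tdd = total, n_generations = total / params$k, boundary_days = boundaries)
}

# Small two-location climate for fast pipeline runs.
tiny_config <- function(seed = 1, n_replicates = 2, ...) {
  study_config(
    locations = list(
      A = location_climate("A", 30, 20, daily_noise_sd = 0.5),
      B = location_climate("B", 33, 23, daily_noise_sd = 0.5)
    ),
    models = data.frame(code = c("M1", "M2"), warming_factor = c(0.9, 1.1)),
    offsets = expand.grid(
      location = c("A", "B"), scenario = c("A2", "A1B", "B1"),
      period = c("NF", "DF", "VDF"), stringsAsFactors = FALSE
    ) |> transform(
      year = unname(c(NF = 2020L, DF = 2050L, VDF = 2080L)[period]),
      delta_tmax = ifelse(period == "NF", 1, ifelse(period == "DF", 2, 3)),
      delta_tmin = ifelse(period == "NF", 1, ifelse(period == "DF", 2, 3))
    ),
    n_replicates = n_replicates,
    seed = seed,
    ...
  )
}
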