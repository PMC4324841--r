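#' Degree-day model parameters
#'
#' The three constants of the degree-day model for *S. litura* on peanut: the
#' lower developmental threshold below which no development accrues, the
#' upper threshold at which the horizontal cut-off caps the effective daily
#' mean, and the thermal constant (degree-days per completed generation,
#' egg to adult).
#'
#' @param t0 Lower developmental threshold, degree C (default 10).
#' @param t_upper Upper cut-off, degree C (default 37); must exceed `t0`.
#' @param k Degree-days per generation (default 522.7); must be positive.
#' @return An object of class `"gdd_params"`.
#' @export
gdd_params <- function(t0 = 10, t_upper = 37, k = 522.7) {
  if (!is.finite(t0) || !is.finite(t_upper) || t0 >= t_upper) {
    stop("t0 must be below t_upper")
  }
  if (!is.finite(k) || k <= 0) stop("k must be positive")
  structure(list(t0 = t0, t_upper = t_upper, k = k), class = "gdd_params")
}

#' @export
print.gdd_params <- function(x, ...) {
  cat(sprintf("<gdd_params> t0 %.1f C, horizontal cut-off %.1f C, K %.1f DD/generation\n",
              x$t0, x$t_upper, x$k))
  invisible(x)
}

#' Crop-season window in standard weeks
#'
#' The accumulation window expressed in standard meteorological weeks, where
#' week 1 is Jan 1-7 and week `w` covers days `7(w-1)+1 ... 7w` (days 365/366
#' fall outside the 52-week grid). The peanut-season default, weeks 26-44,
#' spans 133 days.
#'
#' @param start_week,end_week Inclusive standard-week bounds, in 1..52.
#' @return An object of class `"season_window"` with fields `start_week`,
#'   `end_week` and `n_days`.
#' @examples
#' season_window()$n_days # 133
#' @export
season_window <- function(start_week = 26, end_week = 44) {
  if (start_week < 1 || end_week > 52 || start_week > end_week) {
    stop("need 1 <= start_week <= end_week <= 52")
  }
  structure(
    list(start_week = as.integer(start_week), end_week = as.integer(end_week),
         n_days = 7L * (as.integer(end_week) - as.integer(start_week) + 1L)),
    class = "season_window"
  )
}

#' @export
print.season_window <- function(x, ...) {
  d <- standard_week_days(x)
  cat(sprintf("<season_window> standard weeks %d-%d: days %d-%d (%d days)\n",
              x$start_week, x$end_week, d$first_day, d$last_day, d$n_days))
  invisible(x)
}

#' Day-of-year span of a standard-week window
#'
#' @param window A [season_window()].
#' @return A list with `first_day`, `last_day` (inclusive day-of-year bounds)
#'   and `n_days`.
#' @examples
#' standard_week_days(season_window(26, 44)) # days 176-308, 133 days
#' @export
standard_week_days <- function(window = season_window()) {
  stopifnot(inherits(window, "season_window"))
  list(
    first_day = 7L * (window$start_week - 1L) + 1L,
    last_day = 7L * window$end_week,
    n_days = window$n_days
  )
}

#' Daily heat units with lower threshold and horizontal cut-off
#'
#' Computes the degree-days accrued in one day from the simple-average daily
#' mean: `m = (tmax + tmin) / 2`, capped at the upper threshold (horizontal
#' cut-off: accumulation above `t_upper` does not count), minus the lower
#' threshold, floored at zero (sub-threshold days contribute nothing, never
#' negative accumulation). Vectorized over days.
#'
#' @param tmax,tmin Daily maximum/minimum temperature, degree C (`tmax >=
#'   tmin` elementwise).
#' @param params A [gdd_params()].
#' @return Numeric vector of degree-days, each in `[0, t_upper - t0]`.
#' @examples
#' daily_degree_days(30, 20) # 15
#' daily_degree_days(12, 4)  # 0: daily mean below threshold
#' daily_degree_days(42, 38) # 27: mean 40 capped at 37
#' @export
daily_degree_days <- function(tmax, tmin, params = gdd_params()) {
  stopifnot(inherits(params, "gdd_params"), length(tmax) == length(tmin))
  if (anyNA(tmax) || anyNA(tmin)) stop("tmax/tmin must not contain NA")
  if (any(tmax < tmin)) {
    stop("tmax < tmin at position(s): ",
         paste(utils::head(which(tmax < tmin), 5), collapse = ", "))
  }
  m <- (tmax + tmin) / 2
  pmax(0, pmin(m, params$t_upper) - params$t0)
}

#' Accumulate degree-days and count generations over the season
#'
#' Runs the core voltinism computation on one replicate-year: daily heat
#' units over the window are summed cumulatively (`H = sum of D-D`); the
#' fractional number of generations is `TDD / K`; a generation boundary is
#' recorded at the first window day on which each whole multiple of `K` is
#' attained; the mean GDD per completed generation is reported as an
#' accumulation self-check (it should sit near `K`).
#'
#' @param series A `"weather_series"` data frame covering every day of the
#'   window (matched on `doy`).
#' @param window A [season_window()].
#' @param params A [gdd_params()].
#' @return An object of class `"generation_prediction"`: `n_generations`
#'   (fractional), `generation_time` (days, window-length / N; `NA` when no
#'   degree-days accrue), `tdd`, `mean_gdd` (`NA` when no generation
#'   completes), `boundary_days` (window-relative day indices, strictly
#'   increasing), `n_complete`, plus the window and parameters used.
#' @examples
#' s <- data.frame(doy = 1:365, tmax = 30, tmin = 20)
#' p <- accumulate_generations(s, season_window(26, 44), gdd_params())
#' p$tdd            # 133 * 15 = 1995
#' p$n_generations  # 1995 / 522.7
#' @export
accumulate_generations <- function(series, window = season_window(),
                                   params = gdd_params()) {
  stopifnot(is.data.frame(series), all(c("doy", "tmax", "tmin") %in% names(series)))
  span <- standard_week_days(window)
  want <- span$first_day:span$last_day
  idx <- match(want, series$doy)
  if (anyNA(idx)) {
    stop("window days missing from series: ",
         paste(utils::head(want[is.na(idx)], 10), collapse = ", "),
         if (sum(is.na(idx)) > 10) " ..." else "")
  }
  dd <- daily_degree_days(series$tmax[idx], series$tmin[idx], params)
  H <- cumsum(dd)
  tdd <- H[length(H)]
  n_gen <- tdd / params$k
  n_complete <- floor(n_gen + 1e-12)
  if (n_complete >= 1) {
    thresholds <- params$k * seq_len(n_complete)
    boundary_days <- vapply(thresholds,
                            function(th) which(H >= th - 1e-9)[1], integer(1))
    gen_dd <- diff(c(0, H[boundary_days]))
    mean_gdd <- mean(gen_dd)
  } else {
    boundary_days <- integer(0)
    mean_gdd <- NA_real_
  }
  structure(
    list(
      n_generations = n_gen,
      generation_time = if (n_gen > 0) span$n_days / n_gen else NA_real_,
      tdd = tdd,
      mean_gdd = mean_gdd,
      boundary_days = boundary_days,
      n_complete = as.integer(n_complete),
      window = window,
      params = params
    ),
    class = "generation_prediction"
  )
}

#' @export
print.generation_prediction <- function(x, ...) {
  cat(sprintf("<generation_prediction> N %.3f (%d complete), GT %s d, TDD %.1f DD, mean GDD %s\n",
              x$n_generations, x$n_complete,
              ifelse(is.na(x$generation_time), "NA", sprintf("%.2f", x$generation_time)),
              x$tdd,
              ifelse(is.na(x$mean_gdd), "NA", sprintf("%.1f", x$mean_gdd))))
  invisible(x)
}

#' Generation time of a prediction
#'
#' The average development time per generation over the season window. The
#' default (`"window"`) definition divides the window length by the
#' fractional number of generations, so `GT * N` equals the window length
#' identically; it is the definition consistent with the published
#' location-level tables. The alternative (`"boundary"`) definition averages
#' the day intervals between successive completed-generation boundaries.
#'
#' @param prediction An [accumulate_generations()] result.
#' @param window A [season_window()] (defaults to the one stored in the
#'   prediction).
#' @param definition `"window"` or `"boundary"`.
#' @return Days per generation, or `NA` when undefined (no generations under
#'   `"window"`; no completed generation under `"boundary"`).
#' @export
generation_time <- function(prediction, window = prediction$window,
                            definition = c("window", "boundary")) {
  stopifnot(inherits(prediction, "generation_prediction"))
  definition <- match.arg(definition)
  if (definition == "window") {
    if (prediction$n_generations <= 0) return(NA_real_)
    window$n_days / prediction$n_generations
  } else {
    if (prediction$n_complete < 1) return(NA_real_)
    mean(diff(c(0L, prediction$boundary_days)))
  }
}

#' Replicate-level cell summary
#'
#' Mean and standard error of the number of generations and of the
#' generation time over the stochastic replicates of one location x model x
#' scenario x period cell, the form in which the published tables report
#' results (`mean +/- SE` over 20 replicates; a single-replicate cell reports
#' SE 0, the baseline convention).
#'
#' @param predictions A list of `"generation_prediction"` objects, or a data
#'   frame with columns `n_generations` and `generation_time`.
#' @return One-row data frame of class `"cell_summary"`: `mean_n`, `se_n`,
#'   `mean_gt`, `se_gt`, `n_replicates`.
#' @export
summarize_cell <- function(predictions) {
  if (is.data.frame(predictions)) {
    n <- predictions$n_generations
    gt <- predictions$generation_time
  } else {
    if (!length(predictions)) stop("no predictions supplied")
    stopifnot(all(vapply(predictions, inherits, logical(1), "generation_prediction")))
    n <- vapply(predictions, `[[`, numeric(1), "n_generations")
    gt <- vapply(predictions, `[[`, numeric(1), "generation_time")
  }
  if (!length(n)) stop("no predictions supplied")
  se <- function(v) if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v))
  out <- data.frame(
    mean_n = mean(n), se_n = se(n),
    mean_gt = mean(gt), se_gt = se(gt),
    n_replicates = length(n)
  )
  if (length(n) < 2L) attr(out, "note") <- "single replicate: SE reported as 0"
  class(out) <- c("cell_summary", "data.frame")
  out
}
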