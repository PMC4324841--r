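test_that("daily heat units follow the threshold/cut-off formula", {
  expect_equal(daily_degree_days(30, 20), 15)          # (30+20)/2 - 10
  expect_equal(daily_degree_days(12, 4), 0)            # mean 8 below threshold
  expect_equal(daily_degree_days(42, 38), 27)          # mean 40 capped at 37
  expect_equal(daily_degree_days(c(30, 12), c(20, 4)), c(15, 0))
  expect_error(daily_degree_days(20, 25), "tmax < tmin")
})

test_that("daily heat units stay inside [0, t_upper - t0] for any valid day", {
  set.seed(1)
  p <- gdd_params()
  for (i in 1:200) {
    tmin <- runif(1, -20, 45)
    tmax <- tmin + runif(1, 0, 25)
    dd <- daily_degree_days(tmax, tmin, p)
    expect_gte(dd, 0)
    expect_lte(dd, p$t_upper - p$t0)
  }
})

test_that("standard weeks map to the documented day-of-year spans", {
  d <- standard_week_days(season_window(26, 44))
  expect_equal(d$first_day, 176)
  expect_equal(d$last_day, 308)
  expect_equal(d$n_days, 133)
  expect_equal(standard_week_days(season_window(1, 1)),
               list(first_day = 1L, last_day = 7L, n_days = 7L))
  expect_equal(season_window(26, 26)$n_days, 7L)
  expect_equal(season_window(26, 44)$n_days, 19L * 7L)
  expect_error(season_window(0, 44), "start_week")
  expect_error(season_window(26, 53), "start_week")
})

test_that("constant-temperature seasons accumulate in closed form", {
  p <- accumulate_generations(constant_series(30, 20))
  expect_equal(p$tdd, 133 * 15)
  expect_equal(p$n_generations, 1995 / 522.7, tolerance = 1e-12)
  expect_equal(p$n_generations, p$tdd / 522.7, tolerance = 1e-12)

  cold <- accumulate_generations(constant_series(9, 5))
  expect_equal(cold$tdd, 0)
  expect_equal(cold$n_generations, 0)
  expect_identical(cold$boundary_days, integer(0))
  expect_true(is.na(cold$generation_time))
  expect_true(is.na(cold$mean_gdd))
})

test_that("one generation per week puts boundaries on every 7th day", {
  m <- 10 + 522.7 / 7 # daily DD of exactly K/7
  p <- accumulate_generations(constant_series(m + 5, m - 5),
                              params = gdd_params(t_upper = 200))
  expect_equal(p$n_complete, 19L)
  expect_equal(p$boundary_days, seq(7L, 133L, by = 7L))
  expect_equal(p$mean_gdd, 522.7, tolerance = 1e-9)
})

test_that("vectorized accumulation matches a literal day-by-day loop", {
  set.seed(99)
  for (i in 1:100) {
    s <- random_series()
    got <- accumulate_generations(s)
    ref <- loop_accumulate(s)
    expect_equal(got$tdd, ref$tdd, tolerance = 1e-9)
    expect_equal(got$n_generations, ref$n_generations, tolerance = 1e-9)
    expect_identical(got$boundary_days, ref$boundary_days)
  }
})

test_that("missing window days are reported by date", {
  s <- constant_series(30, 20)[-(200:210), ]
  expect_error(accumulate_generations(s), "200")
})

test_that("uniform warming never lowers and generically raises generations", {
  set.seed(7)
  p <- gdd_params()
  for (i in 1:50) {
    s <- random_series()
    warm <- s
    warm$tmax <- warm$tmax + 1
    warm$tmin <- warm$tmin + 1
    n0 <- accumulate_generations(s, params = p)$n_generations
    n1 <- accumulate_generations(warm, params = p)$n_generations
    expect_gte(n1, n0)
  }
  # strict increase when no day is capped or clamped
  s <- constant_series(30, 22)
  n0 <- accumulate_generations(s)$n_generations
  s$tmax <- s$tmax + 1
  s$tmin <- s$tmin + 1
  expect_gt(accumulate_generations(s)$n_generations, n0)
})

test_that("generation time divides the window by fractional generations", {
  p <- accumulate_generations(constant_series(30, 20))
  expect_equal(generation_time(p), 133 / (1995 / 522.7), tolerance = 1e-9)
  expect_equal(generation_time(p), 34.843, tolerance = 1e-3)
  # product identity holds exactly for any series with development
  set.seed(3)
  for (i in 1:20) {
    pr <- accumulate_generations(random_series())
    if (pr$n_generations > 0) {
      expect_equal(generation_time(pr) * pr$n_generations, 133, tolerance = 1e-9)
    }
  }
})

test_that("boundary-interval generation time averages completed cycles", {
  m <- 10 + 522.7 / 7
  p <- accumulate_generations(constant_series(m + 5, m - 5),
                              params = gdd_params(t_upper = 200))
  expect_equal(generation_time(p, definition = "boundary"), 7)
  cold <- accumulate_generations(constant_series(9, 5))
  expect_true(is.na(generation_time(cold, definition = "boundary")))
})

test_that("one generation per day gives unit generation time", {
  m <- 10 + 522.7 # daily DD = K
  p <- accumulate_generations(constant_series(m, m),
                              params = gdd_params(t_upper = 1000))
  expect_equal(p$n_generations, 133)
  expect_equal(generation_time(p), 1)
})

test_that("cell summaries report the mean and sd/sqrt(n) standard error", {
  preds <- replicate(20, accumulate_generations(constant_series(30, 20)),
                     simplify = FALSE)
  cs <- summarize_cell(preds)
  expect_equal(cs$mean_n, 1995 / 522.7, tolerance = 1e-12)
  expect_equal(cs$se_n, 0)
  expect_equal(cs$n_replicates, 20)

  df <- data.frame(n_generations = c(4, 5), generation_time = c(33.25, 26.6))
  cs2 <- summarize_cell(df)
  expect_equal(cs2$mean_n, 4.5)
  expect_equal(cs2$se_n, 0.5) # sd 0.7071 / sqrt(2)
  # degenerate single-replicate cell: SE reported as 0, as in baseline rows
  cs1 <- summarize_cell(df[1, ])
  expect_equal(cs1$se_n, 0)
  expect_match(attr(cs1, "note"), "single replicate")
  expect_error(summarize_cell(list()), "no predictions")
})

test_that("printed location tables broadly obey N x GT = window length", {
  t3 <- read_printed_predictions("generations")
  t4 <- read_printed_predictions("generation_time")
  m <- merge(t3, t4, by = c("location", "scenario", "period"),
             suffixes = c("_n", "_gt"))
  dev <- abs(m$mean_n * m$mean_gt - 133) / 133
  # the window definition of GT explains the bulk of the printed cells
  expect_lte(median(dev), 0.02)
  expect_gte(mean(dev <= 0.02), 0.80)
  # and the baseline rows reconstruct to well under the printing precision
  expect_lte(max(dev[m$scenario == "BL"]), 0.025)
})
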