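test_that("delta summary reproduces subtraction and flags missing cells", {
  ds <- table2_deltas()
  expect_equal(nrow(ds$deltas), 108) # 6 locations x 2 vars x 9 cells
  jun <- ds$deltas[ds$deltas$location == "Junagadh" &
                     ds$deltas$scenario == "A2" & ds$deltas$year == 2050, ]
  expect_equal(jun$delta[jun$variable == "tmax"], 3.75)
  # a table whose scenario rows equal its baseline has all-zero deltas
  am <- read_annual_means()
  base <- am[am$scenario == "BL", ]
  flat <- am
  flat$value <- base$value[match(paste(flat$location, flat$variable),
                                 paste(base$location, base$variable))]
  expect_true(all(table2_deltas(flat)$deltas$delta == 0))
  expect_error(table2_deltas(am[-10, ]), "missing cell")
})

test_that("percent change in generation time is relative to baseline", {
  expect_equal(percent_change_gt(24, 30), 20)
  expect_equal(percent_change_gt(30, 30), 0)
  # substitution of two printed cells: Bhubaneswar baseline vs A2/2080
  t4 <- read_printed_predictions("generation_time")
  bl <- t4$mean[t4$location == "Bhubaneswar" & t4$scenario == "BL"]
  vdf <- t4$mean[t4$location == "Bhubaneswar" & t4$scenario == "A2" &
                   t4$period == 2080]
  expect_equal(percent_change_gt(vdf, bl), 12.24, tolerance = 0.005)
  expect_error(percent_change_gt(24, 0), "positive")
  # lengthening is negative, shortening positive
  expect_lt(percent_change_gt(35, 30), 0)
})

test_that("pooled t-test matches hand computation and is antisymmetric", {
  tt <- two_sample_t_equal_var(c(4, 5, 6), c(4, 5, 6))
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)

  tt2 <- two_sample_t_equal_var(c(1, 2, 3), c(3, 4, 5))
  expect_equal(tt2$t, -sqrt(6), tolerance = 1e-9) # pooled var 1, se sqrt(2/3)
  expect_equal(tt2$t, -2.449, tolerance = 1e-3)
  expect_equal(tt2$df, 4)

  set.seed(5)
  a <- rnorm(20, 5, 0.3)
  b <- rnorm(20, 4.7, 0.3)
  fwd <- two_sample_t_equal_var(a, b)
  rev <- two_sample_t_equal_var(b, a)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, rev$p)
  expect_equal(fwd$df, 38)
})

test_that("degenerate zero-variance baselines use the documented fallback", {
  a <- c(4.2, 4.4, 4.1, 4.3)
  b <- rep(3.9, 4) # baseline replicated without variance
  tt <- two_sample_t_equal_var(a, b)
  expect_true(tt$degenerate)
  # direct pooled formula with the zero-variance sample contributing nothing
  sp2 <- (3 * var(a) + 3 * 0) / 6
  expect_equal(tt$t, (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4)),
               tolerance = 1e-12)
  expect_equal(tt$df, 6)

  both <- two_sample_t_equal_var(rep(1, 3), rep(1, 3))
  expect_true(is.na(both$t) && is.na(both$p))
  expect_error(two_sample_t_equal_var(1, c(1, 2)), "at least 2")
})

test_that("a 2x2 design with planted effects partitions in closed form", {
  d <- expand.grid(location = c("L1", "L2"), period = c("P1", "P2"),
                   stringsAsFactors = FALSE)
  d$y <- 2 * (d$location == "L2") + 1 * (d$period == "P2")
  vp <- anova_partition(d, "y", sources = c("location", "period"),
                        interactions = list(c("location", "period")))
  ss <- setNames(vp$ss, vp$source)
  expect_equal(unname(ss["location"] / ss["period"]), 4)
  expect_equal(unname(ss["location:period"]), 0)
  expect_equal(sum(vp$proportion), 100, tolerance = 1e-9)
})

test_that("sums of squares conserve the total and ignore source order", {
  set.seed(21)
  d <- expand.grid(location = paste0("L", 1:3), period = paste0("P", 1:2),
                   model = paste0("M", 1:2), scenario = paste0("S", 1:2),
                   replicate = 1:5, stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + 2 * (d$location == "L2") + (d$period == "P2")
  vp <- anova_partition(d, "y")
  # conservation against the raw total sum of squares
  expect_equal(sum(vp$ss), sum((d$y - mean(d$y))^2), tolerance = 1e-6)
  expect_equal(sum(vp$proportion), 100, tolerance = 1e-6)
  # permuting the sources leaves every SS unchanged on a balanced design
  vp2 <- anova_partition(d, "y", sources = c("scenario", "model", "period", "location"))
  expect_equal(sort(vp2$ss), sort(vp$ss), tolerance = 1e-9)
})

test_that("unbalanced and degenerate designs are refused or flagged", {
  d <- expand.grid(location = c("L1", "L2"), period = c("P1", "P2"),
                   replicate = 1:3, stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d))
  expect_error(anova_partition(d[-1, ], "y", sources = c("location", "period")),
               "unbalanced")
  d$y <- 1
  expect_warning(
    vp <- anova_partition(d, "y", sources = c("location", "period")),
    "constant"
  )
  expect_true(all(is.na(vp$proportion)))
  expect_true(attr(vp, "undefined"))
  d$one <- "A"
  expect_error(anova_partition(d, "y", sources = c("location", "one")),
               "fewer than 2")
})

test_that("planted effect rankings are recovered across seeded runs", {
  grid <- expand.grid(location = paste0("L", 1:6), period = paste0("P", 1:3),
                      model = paste0("M", 1:2), scenario = paste0("S", 1:2),
                      replicate = 1:5, stringsAsFactors = FALSE)
  a <- seq(-1.5, 1.5, length.out = 6) # location: largest
  b <- c(-0.8, 0, 0.8)                # period: second
  c3 <- c(-0.25, 0.25)                # model: third
  d4 <- c(-0.1, 0.1)                  # scenario: smallest
  mu <- a[as.integer(factor(grid$location))] +
    b[as.integer(factor(grid$period))] +
    c3[as.integer(factor(grid$model))] +
    d4[as.integer(factor(grid$scenario))]
  hits <- 0L
  set.seed(1234)
  for (run in 1:200) {
    grid$y <- mu + rnorm(nrow(grid), 0, 0.4)
    vp <- anova_partition(grid, "y", interactions = list())
    p <- setNames(vp$proportion, vp$source)
    ok <- p["location"] > p["period"] &&
      p["period"] > p["model"] && p["model"] > p["scenario"]
    hits <- hits + as.integer(ok)
  }
  expect_gte(hits / 200, 0.95)
})
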