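# Internal helpers shared across modules.

# Deterministic 31-bit seed mixing. Constants keep a*m below 2^53 so every
# intermediate is exact in double arithmetic; results are valid set.seed()
# inputs on any platform.
mix_seed <- function(...) {
  m <- 2147483629
  x <- 0
  for (v in c(...)) {
    x <- (1664525 * ((x + as.numeric(v)) %% m) + 1013904223) %% m
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Scenario and period vocabularies (SRES scenarios; period labels with their
# representative years).
scenario_levels <- function() c("A2", "A1B", "B1")

period_table <- function() {
  data.frame(
    period = c("BL", "NF", "DF", "VDF"),
    year = c(1975L, 2020L, 2050L, 2080L),
    stringsAsFactors = FALSE
  )
}

period_label <- function(year) {
  pt <- period_table()
  i <- match(as.integer(year), pt$year)
  if (anyNA(i)) {
    stop("unknown period year(s): ", paste(unique(year[is.na(i)]), collapse = ", "))
  }
  pt$period[i]
}

period_year <- function(period) {
  pt <- period_table()
  i <- match(period, pt$period)
  if (anyNA(i)) {
    stop("unknown period label(s): ", paste(unique(period[is.na(i)]), collapse = ", "))
  }
  pt$year[i]
}

check_scenario <- function(scenario, allow_bl = FALSE) {
  ok <- scenario_levels()
  if (allow_bl) ok <- c("BL", ok)
  if (!all(scenario %in% ok)) {
    stop("scenario must be one of ", paste(ok, collapse = ", "),
         "; got: ", paste(setdiff(scenario, ok), collapse = ", "))
  }
  invisible(scenario)
}
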