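#' Climate models of the study ensemble
#'
#' The six GCMs whose downscaled temperatures drive the study, plus their
#' ensemble average (`AVG`). Because the packaged annual-means table reports
#' scenario-level (ensemble) means only, the surrogate differentiates models
#' by a fixed multiplicative factor on the scenario warming offset: models
#' documented as projecting warmer futures (CNR, ECH, CSI) scale the offset
#' up, the cooler ones (BCC, INM, MIR) scale it down, and the factors average
#' to exactly 1 so the ensemble reproduces the table's deltas. Baseline
#' offsets are zero, so all models coincide at baseline up to noise.
#'
#' @return Data frame with columns `code` and `warming_factor` for the six
#'   GCMs (the `AVG` ensemble is computed, not parameterized).
#' @export
gcm_models <- function() {
  data.frame(
    code = c("BCC", "CNR", "CSI", "ECH", "INM", "MIR"),
    warming_factor = c(0.88, 1.12, 1.06, 1.08, 0.92, 0.94),
    stringsAsFactors = FALSE
  )
}

#' Ensemble-average a set of model replicate sets
#'
#' Builds the `AVG` ensemble cell from the six per-model cells of one
#' location x scenario x period coordinate. The default averages the weather
#' itself -- per replicate index, the day-by-day mean of Tmax and of Tmin
#' across models -- and is what the degree-day engine then consumes; the
#' alternative averages the models' *predictions* instead (the two differ
#' whenever the cut-off or threshold binds on some models only).
#'
#' @param model_sets Named list of `"replicate_set"` objects, one per model,
#'   all with the same replicate count and date span.
#' @param models Character vector of required model codes; an absent model is
#'   an error naming it.
#' @return For the weather method, a `"replicate_set"` with model `"AVG"`.
#' @export
ensemble_average <- function(model_sets, models = gcm_models()$code) {
  absent <- setdiff(models, names(model_sets))
  if (length(absent)) {
    stop("missing model cell(s) for ensemble: ", paste(absent, collapse = ", "))
  }
  sets <- model_sets[models]
  n_rep <- unique(vapply(sets, `[[`, integer(1), "n_replicates"))
  if (length(n_rep) != 1L) stop("models have differing replicate counts")
  reps <- lapply(seq_len(n_rep), function(r) {
    s <- sets[[1]]$replicates[[r]]
    tmax <- rowMeans(vapply(sets, function(m) m$replicates[[r]]$tmax,
                            numeric(nrow(s))))
    tmin <- rowMeans(vapply(sets, function(m) m$replicates[[r]]$tmin,
                            numeric(nrow(s))))
    out <- s
    out$tmax <- tmax
    out$tmin <- tmin
    out
  })
  structure(
    list(
      cell = utils::modifyList(sets[[1]]$cell, list(model = "AVG")),
      replicates = reps,
      n_replicates = n_rep,
      seed = sets[[1]]$seed
    ),
    class = "replicate_set"
  )
}

#' Study configuration
#'
#' Assembles every knob of the end-to-end study: locations (with surrogate
#' climate parameters), climate models, emission scenarios, period slices,
#' degree-day parameters, season window, replicate count and master seed.
#' Defaults reproduce the study design: 6 locations x (6 GCMs + ensemble) x
#' 3 scenarios x 4 periods, 20 replicates per cell.
#'
#' @param locations Named list of [location_climate()] objects.
#' @param models Data frame as from [gcm_models()].
#' @param scenarios Character vector of emission scenarios.
#' @param periods Named integer vector mapping period labels to
#'   representative years.
#' @param gdd A [gdd_params()].
#' @param window A [season_window()].
#' @param n_replicates Replicates per cell.
#' @param seed Master integer seed.
#' @param offsets Offset table as from [all_scenario_offsets()].
#' @param include_baseline_in_anova Should the baseline period enter the
#'   variance partition? Default `FALSE`: the quantities of interest are
#'   changes relative to baseline, and the baseline is common to all
#'   scenarios.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(locations = default_location_climates(),
                         models = gcm_models(),
                         scenarios = scenario_levels(),
                         periods = c(BL = 1975L, NF = 2020L, DF = 2050L, VDF = 2080L),
                         gdd = gdd_params(),
                         window = season_window(),
                         n_replicates = 20,
                         seed = 1L,
                         offsets = all_scenario_offsets(),
                         include_baseline_in_anova = FALSE) {
  stopifnot(length(locations) >= 1L,
            all(vapply(locations, inherits, logical(1), "location_climate")),
            inherits(gdd, "gdd_params"), inherits(window, "season_window"))
  check_scenario(scenarios)
  if (anyDuplicated(periods) || is.null(names(periods))) {
    stop("periods must be a named vector of distinct representative years")
  }
  structure(
    list(locations = locations, models = models, scenarios = scenarios,
         periods = periods, gdd = gdd, window = window,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         offsets = offsets,
         include_baseline_in_anova = isTRUE(include_baseline_in_anova)),
    class = "study_config"
  )
}

#' Read a study configuration from a YAML file
#'
#' Accepts a YAML document whose top-level keys mirror the [study_config()]
#' arguments: scalar `n_replicates`, `seed`, lists `scenarios`, `gdd`
#' (`t0`/`t_upper`/`k`), `window` (`start_week`/`end_week`), and an optional
#' `locations` map of per-location climate blocks (fields as in
#' [location_climate()]). Omitted keys fall back to the study defaults.
#'
#' @param path Path to the YAML file.
#' @return A `"study_config"` object.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$locations)) {
    args$locations <- lapply(names(y$locations), function(nm) {
      do.call(location_climate, c(list(name = nm), y$locations[[nm]]))
    })
    names(args$locations) <- names(y$locations)
  }
  if (!is.null(y$scenarios)) args$scenarios <- unlist(y$scenarios)
  if (!is.null(y$gdd)) args$gdd <- do.call(gdd_params, y$gdd)
  if (!is.null(y$window)) args$window <- do.call(season_window, y$window)
  if (!is.null(y$n_replicates)) args$n_replicates <- y$n_replicates
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$include_baseline_in_anova)) {
    args$include_baseline_in_anova <- y$include_baseline_in_anova
  }
  do.call(study_config, args)
}

# deterministic per-cell seed from the factor coordinates; callers pass
# scen_i = 0 for the baseline period so its weather is one shared dataset
cell_seed <- function(seed, loc_i, scen_i, per_i, model_i) {
  mix_seed(seed, loc_i, scen_i, per_i, model_i)
}

#' Run the full voltinism study
#'
#' End-to-end driver: for every location x model x scenario x period cell,
#' acquires replicate weather from the surrogate generator (the ensemble
#' `AVG` cell averages the six model weathers per replicate), runs the
#' degree-day engine on each replicate over the season window, and emits
#' replicate predictions, cell summaries with equal-variance t-tests against
#' baseline, the percent change in generation time, and ANOVA variance
#' partitions for both responses. Fully deterministic under `config$seed`.
#'
#' @param config A [study_config()].
#' @param quiet Suppress the per-location progress messages.
#' @return A list of class `"study_results"`:
#' \describe{
#'   \item{predictions}{replicate-level data frame (`location`, `model`,
#'     `scenario`, `period`, `year`, `replicate`, `n_generations`,
#'     `generation_time`, `tdd`, `mean_gdd`).}
#'   \item{summaries}{one row per cell: means, SEs, and `t`, `df`, `p`,
#'     `sig_p01` versus the baseline cell of the same location and model.}
#'   \item{gt_percent_change}{percent change in generation time vs baseline
#'     per model x scenario x future period (location-averaged).}
#'   \item{partition_n, partition_gt}{[anova_partition()] results for the
#'     number of generations and the generation time.}
#'   \item{manifest}{seed, cell/row counts, package version, config echo.}
#' }
#' @export
run_study <- function(config = study_config(), quiet = TRUE) {
  stopifnot(inherits(config, "study_config"))
  per_labels <- names(config$periods)
  model_codes <- c(config$models$code, "AVG")
  off <- config$offsets
  rows <- vector("list", 0L)
  cells <- vector("list", 0L)

  predict_set <- function(set) {
    lapply(set$replicates, accumulate_generations,
           window = config$window, params = config$gdd)
  }
  as_rows <- function(set, preds, scenario) {
    data.frame(
      location = set$cell$location, model = set$cell$model,
      scenario = scenario, period = set$cell$period,
      year = unname(config$periods[set$cell$period]),
      replicate = seq_along(preds),
      n_generations = vapply(preds, `[[`, numeric(1), "n_generations"),
      generation_time = vapply(preds, `[[`, numeric(1), "generation_time"),
      tdd = vapply(preds, `[[`, numeric(1), "tdd"),
      mean_gdd = vapply(preds, `[[`, numeric(1), "mean_gdd"),
      stringsAsFactors = FALSE
    )
  }

  for (li in seq_along(config$locations)) {
    clim <- config$locations[[li]]
    if (!quiet) message("location ", clim$name)
    for (pi in seq_along(per_labels)) {
      per <- per_labels[pi]
      scen_list <- if (per == "BL") "BL" else config$scenarios
      for (si in seq_along(scen_list)) {
        scen <- scen_list[si]
        if (per == "BL") {
          offset <- scenario_offset("BL", "BL")
        } else {
          hit <- off[off$location == clim$name & off$scenario == scen &
                       off$period == per, ]
          if (nrow(hit) != 1L) {
            stop("no offset for ", clim$name, " ", scen, "/", per)
          }
          offset <- scenario_offset(scen, per, hit$delta_tmax, hit$delta_tmin)
        }
        model_sets <- lapply(seq_len(nrow(config$models)), function(mi) {
          f <- config$models$warming_factor[mi]
          m_off <- if (per == "BL") offset else
            scenario_offset(scen, per, offset$delta_tmax * f, offset$delta_tmin * f)
          generate_replicate_set(
            clim, m_off, n_replicates = config$n_replicates,
            seed = cell_seed(config$seed, li, if (per == "BL") 0L else si, pi, mi),
            model = config$models$code[mi]
          )
        })
        names(model_sets) <- config$models$code
        model_sets$AVG <- ensemble_average(model_sets, config$models$code)
        # the baseline weather is scenario-independent; replicate its rows
        # under each scenario label so the factorial design stays complete
        scen_out <- if (per == "BL") config$scenarios else scen
        for (set in model_sets) {
          preds <- predict_set(set)
          for (so in scen_out) {
            rows[[length(rows) + 1L]] <- as_rows(set, preds, so)
          }
        }
      }
    }
  }
  predictions <- do.call(rbind, rows)

  key <- function(d) paste(d$location, d$model, d$scenario, d$period)
  summaries <- do.call(rbind, lapply(split(predictions, key(predictions)), function(d) {
    cs <- summarize_cell(d)
    cbind(d[1L, c("location", "model", "scenario", "period", "year")], cs,
          row.names = NULL)
  }))
  rownames(summaries) <- NULL
  summaries <- summaries[order(summaries$location, summaries$model,
                               summaries$scenario, summaries$year), ]
  rownames(summaries) <- NULL

  # t-tests of each future cell against its location/model baseline
  bl <- predictions[predictions$period == "BL", ]
  tcols <- lapply(seq_len(nrow(summaries)), function(i) {
    s <- summaries[i, ]
    if (s$period == "BL") {
      return(data.frame(t = NA_real_, t_df = NA_integer_, p = NA_real_,
                        sig_p01 = NA))
    }
    fut <- predictions[predictions$location == s$location &
                         predictions$model == s$model &
                         predictions$scenario == s$scenario &
                         predictions$period == s$period, "n_generations"]
    base <- bl[bl$location == s$location & bl$model == s$model &
                 bl$scenario == s$scenario, "n_generations"]
    if (length(fut) < 2L || length(base) < 2L) {
      return(data.frame(t = NA_real_, t_df = NA_integer_, p = NA_real_,
                        sig_p01 = NA))
    }
    tt <- two_sample_t_equal_var(fut, base)
    data.frame(t = tt$t, t_df = tt$df, p = tt$p,
               sig_p01 = is.finite(tt$p) && tt$p < 0.01)
  })
  summaries <- cbind(summaries, do.call(rbind, tcols))

  # percent change in generation time, location-averaged, per model x
  # scenario x future period
  cellgt <- stats::aggregate(mean_gt ~ model + scenario + period, summaries, mean)
  blgt <- cellgt[cellgt$period == "BL", ]
  futgt <- cellgt[cellgt$period != "BL", ]
  base_gt <- blgt$mean_gt[match(paste(futgt$model, futgt$scenario),
                                paste(blgt$model, blgt$scenario))]
  gt_percent_change <- data.frame(
    model = futgt$model, scenario = futgt$scenario, period = futgt$period,
    gt_baseline = base_gt, gt_future = futgt$mean_gt,
    pct_change = percent_change_gt(futgt$mean_gt, base_gt),
    stringsAsFactors = FALSE
  )

  adat <- if (config$include_baseline_in_anova) predictions else
    predictions[predictions$period != "BL", ]
  sources <- c("location", "period", "model", "scenario")
  partitionable <- nrow(adat) > 0L &&
    all(vapply(sources, function(s) length(unique(adat[[s]])) >= 2L, logical(1)))
  if (partitionable) {
    partition_n <- anova_partition(adat, "n_generations")
    partition_gt <- anova_partition(adat, "generation_time")
  } else {
    partition_n <- partition_gt <- NULL
  }

  n_cells <- length(config$locations) * length(model_codes) *
    length(config$scenarios) * length(per_labels)
  manifest <- list(
    seed = config$seed,
    n_locations = length(config$locations),
    n_models = length(model_codes),
    n_scenarios = length(config$scenarios),
    n_periods = length(per_labels),
    n_cells = n_cells,
    n_replicates = config$n_replicates,
    n_prediction_rows = nrow(predictions),
    include_baseline_in_anova = config$include_baseline_in_anova,
    package_version = as.character(utils::packageVersion("voltigen"))
  )
  structure(
    list(predictions = predictions, summaries = summaries,
         gt_percent_change = gt_percent_change,
         partition_n = partition_n, partition_gt = partition_gt,
         manifest = manifest, config = config),
    class = "study_results"
  )
}

#' @export
print.study_results <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0(
    "<study_results> %d cells (%d locations x %d models x %d scenarios x %d periods), ",
    "%d replicates/cell\n  %d prediction rows (seed %d)\n"),
    m$n_cells, m$n_locations, m$n_models, m$n_scenarios, m$n_periods,
    m$n_replicates, m$n_prediction_rows, m$seed))
  if (!is.null(x$partition_n) && !isTRUE(attr(x$partition_n, "undefined"))) {
    p <- x$partition_n
    cat("  variance partition (number of generations):\n")
    for (i in seq_len(nrow(p))) {
      cat(sprintf("    %-18s %6.2f %%\n", p$source[i], p$proportion[i]))
    }
  }
  invisible(x)
}
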