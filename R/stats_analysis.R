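#' Temperature deltas over baseline from an annual-means table
#'
#' Subtracts the 1975 baseline annual means from every scenario x period cell
#' of an annual-means table, per location and per variable, and summarizes
#' the result: largest Tmax and Tmin increases, smallest positive increases,
#' and the mean very-distant-future (2080) delta per scenario over all 12
#' location x variable combinations.
#'
#' @param annual_means Data frame as returned by [read_annual_means()]; must
#'   contain all 6 locations x 2 variables x (baseline + 9 scenario-period)
#'   cells.
#' @return A list of class `"delta_summary"`: `deltas` (data frame
#'   `location`, `scenario`, `period`, `year`, `variable`, `delta`) and
#'   `aggregates` (`max_tmax`, `max_tmin`, `min_positive_tmax`,
#'   `min_positive_tmin`, `vdf_mean` -- named per scenario).
#' @export
table2_deltas <- function(annual_means = read_annual_means()) {
  locs <- unique(annual_means$location)
  vars <- c("tmax", "tmin")
  grid <- expand.grid(
    location = locs, variable = vars,
    cell = c("BL.1975", "A2.2020", "A2.2050", "A2.2080",
             "A1B.2020", "A1B.2050", "A1B.2080",
             "B1.2020", "B1.2050", "B1.2080"),
    stringsAsFactors = FALSE
  )
  have <- paste(annual_means$location, annual_means$variable,
                annual_means$scenario, annual_means$period, sep = ".")
  want <- paste(grid$location, grid$variable, grid$cell, sep = ".")
  if (!all(want %in% have)) {
    stop("annual-means table is missing cell(s): ",
         paste(utils::head(setdiff(want, have), 5), collapse = ", "))
  }
  base <- annual_means[annual_means$scenario == "BL", ]
  fut <- annual_means[annual_means$scenario != "BL", ]
  b <- base$value[match(paste(fut$location, fut$variable),
                        paste(base$location, base$variable))]
  deltas <- data.frame(
    location = fut$location,
    scenario = fut$scenario,
    period = period_label(fut$period),
    year = as.integer(fut$period),
    variable = fut$variable,
    delta = fut$value - b,
    stringsAsFactors = FALSE
  )
  dmax <- deltas$delta[deltas$variable == "tmax"]
  dmin <- deltas$delta[deltas$variable == "tmin"]
  vdf <- deltas[deltas$period == "VDF", ]
  vdf_mean <- vapply(scenario_levels(),
                     function(s) mean(vdf$delta[vdf$scenario == s]), numeric(1))
  structure(
    list(
      deltas = deltas,
      aggregates = list(
        max_tmax = max(dmax),
        max_tmin = max(dmin),
        min_positive_tmax = if (any(dmax > 0)) min(dmax[dmax > 0]) else NA_real_,
        min_positive_tmin = if (any(dmin > 0)) min(dmin[dmin > 0]) else NA_real_,
        vdf_mean = vdf_mean
      )
    ),
    class = "delta_summary"
  )
}

#' @export
print.delta_summary <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf(
    paste0("<delta_summary> %d deltas over baseline\n",
           "  Tmax increase: %.2f to %.2f C; Tmin increase: %.2f to %.2f C\n",
           "  VDF (2080) mean delta: %s\n"),
    nrow(x$deltas),
    a$min_positive_tmax, a$max_tmax, a$min_positive_tmin, a$max_tmin,
    paste(sprintf("%s %.2f C", names(a$vdf_mean), a$vdf_mean), collapse = ", ")))
  invisible(x)
}

#' Percent change in generation time over baseline
#'
#' `100 * (gt_baseline - gt_future) / gt_baseline`: positive values mean the
#' generation time shortens under the future climate.
#'
#' @param gt_future,gt_baseline Generation times in days; `gt_baseline` must
#'   be positive. Vectorized with recycling.
#' @return Percent change (positive = shortening).
#' @examples
#' percent_change_gt(24, 30) # 20
#' @export
percent_change_gt <- function(gt_future, gt_baseline) {
  if (any(!is.finite(gt_baseline)) || any(gt_baseline <= 0)) {
    stop("gt_baseline must be positive")
  }
  100 * (gt_baseline - gt_future) / gt_baseline
}

#' Two-sample t-test assuming equal variances
#'
#' Pooled-variance two-sided t-test with `df = n_a + n_b - 2`, the form used
#' to compare each future cell's replicate predictions against the baseline
#' cell. When one sample has zero variance (a degenerate baseline cell), the
#' pooled variance reduces to the contribution of the other sample alone and
#' the result is flagged; when both variances are zero the statistic is
#' undefined and reported as `NA` (with `p = 1` for equal means, `p = 0`
#' otherwise is not asserted -- both are returned `NA`).
#'
#' @param a,b Numeric vectors of replicate values, each of length `>= 2`.
#' @return A list of class `"pooled_t"`: `t`, `df`, `p`, `mean_a`, `mean_b`,
#'   `degenerate` (`TRUE` when at least one sample variance is zero).
#' @examples
#' two_sample_t_equal_var(c(1, 2, 3), c(3, 4, 5)) # t = -2.449, df = 4
#' @export
two_sample_t_equal_var <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 values")
  }
  va <- stats::var(a); vb <- stats::var(b)
  degenerate <- va == 0 || vb == 0
  df <- length(a) + length(b) - 2L
  if (va == 0 && vb == 0) {
    out <- list(t = NA_real_, df = df, p = NA_real_,
                mean_a = mean(a), mean_b = mean(b), degenerate = TRUE)
  } else if (degenerate) {
    # pooled variance with the zero-variance sample contributing nothing
    sp2 <- ((length(a) - 1L) * va + (length(b) - 1L) * vb) / df
    tval <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    out <- list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
                mean_a = mean(a), mean_b = mean(b), degenerate = TRUE)
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    out <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value, mean_a = mean(a), mean_b = mean(b),
                degenerate = FALSE)
  }
  class(out) <- "pooled_t"
  out
}

#' @export
print.pooled_t <- function(x, ...) {
  cat(sprintf("<pooled_t> t = %s, df = %d, p = %s%s\n",
              ifelse(is.na(x$t), "NA", sprintf("%.3f", x$t)), x$df,
              ifelse(is.na(x$p), "NA", format.pval(x$p, digits = 3)),
              if (x$degenerate) " [zero-variance sample]" else ""))
  invisible(x)
}

#' ANOVA sum-of-squares variance partition
#'
#' Decomposes the variance of replicate-level predictions across the design
#' factors by fixed-effects ANOVA and expresses each source's sum of squares
#' as a percent of the total. The design must be balanced (equal replicate
#' counts in every cell spanned by the listed sources), where sequential
#' sums of squares are order-independent -- this is asserted internally by
#' refitting with the source order reversed. Interactions not listed are
#' left in the residual, which is reported as `"others"`.
#'
#' @param data Data frame of replicate-level responses with factor columns.
#' @param response Name of the response column (e.g. `"n_generations"`).
#' @param sources Character vector of main-effect column names.
#' @param interactions List of character pairs to report separately
#'   (default: the location x period interaction).
#' @return A data frame of class `"variance_partition"` with columns
#'   `source`, `df`, `ss`, `proportion` (percent of total SS; rows sum to
#'   100). When the response is constant the proportions are `NA` and the
#'   attribute `undefined` is `TRUE`.
#' @examples
#' d <- expand.grid(location = c("L1", "L2"), period = c("P1", "P2"))
#' d$y <- 2 * (d$location == "L2") + 1 * (d$period == "P2")
#' anova_partition(d, "y", c("location", "period"), interactions = list())
#' @export
anova_partition <- function(data, response,
                            sources = c("location", "period", "model", "scenario"),
                            interactions = list(c("location", "period"))) {
  stopifnot(is.data.frame(data), response %in% names(data))
  if (!all(sources %in% names(data))) {
    stop("missing source column(s): ",
         paste(setdiff(sources, names(data)), collapse = ", "))
  }
  df <- data
  for (s in sources) {
    df[[s]] <- factor(df[[s]])
    if (nlevels(df[[s]]) < 2L) stop("source '", s, "' has fewer than 2 levels")
  }
  counts <- table(df[sources])
  if (length(unique(as.vector(counts))) != 1L) {
    tab <- as.data.frame(counts)
    bad <- tab[tab$Freq != stats::median(tab$Freq), , drop = FALSE]
    stop("design is unbalanced across ", paste(sources, collapse = " x "),
         "; offending cell counts:\n",
         paste(utils::capture.output(print(utils::head(bad, 10))), collapse = "\n"))
  }
  terms <- c(sources,
             vapply(interactions, function(p) paste(p, collapse = ":"), character(1)))
  # lm labels an interaction by the factors' appearance order in the
  # formula; normalize to the order the caller listed so fits with permuted
  # sources stay comparable
  canon <- function(labels) {
    vapply(labels, function(l) {
      parts <- strsplit(l, ":", fixed = TRUE)[[1]]
      if (length(parts) > 1L) {
        parts <- parts[order(match(parts, sources))]
      }
      paste(parts, collapse = ":")
    }, character(1))
  }
  ss_for <- function(term_order) {
    f <- stats::reformulate(term_order, response = response)
    # only the sums of squares are consumed; silence the F-test caveat that
    # anova.lm raises on perfect (zero-residual) fits
    an <- suppressWarnings(stats::anova(stats::lm(f, data = df)))
    ss <- an[["Sum Sq"]]
    names(ss) <- canon(rownames(an))
    list(ss = ss, df = an[["Df"]])
  }
  fit <- ss_for(terms)
  # balanced design: sequential SS must not depend on the order of sources
  refit <- ss_for(rev(terms))
  common <- setdiff(names(fit$ss), "Residuals")
  rel <- abs(fit$ss[common] - refit$ss[common]) / max(sum(fit$ss), .Machine$double.eps)
  if (any(rel > 1e-8)) {
    stop("sequential sums of squares depend on source order; design not balanced enough")
  }
  ss <- fit$ss
  dfree <- fit$df
  names(dfree) <- names(ss)
  total <- sum(ss)
  out <- data.frame(
    source = c(setdiff(names(ss), "Residuals"), "others"),
    df = c(dfree[setdiff(names(ss), "Residuals")], dfree[["Residuals"]]),
    ss = c(ss[setdiff(names(ss), "Residuals")], ss[["Residuals"]]),
    row.names = NULL
  )
  if (total <= .Machine$double.eps * nrow(df)) {
    out$proportion <- NA_real_
    attr(out, "undefined") <- TRUE
    warning("response is constant: variance partition undefined")
  } else {
    out$proportion <- 100 * out$ss / total
    attr(out, "undefined") <- FALSE
  }
  attr(out, "total_ss") <- total
  attr(out, "response") <- response
  class(out) <- c("variance_partition", "data.frame")
  out
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("<variance_partition> response: %s (total SS %.4g)\n",
              attr(x, "response"), attr(x, "total_ss")))
  if (isTRUE(attr(x, "undefined"))) {
    cat("  constant response: partition undefined\n")
  } else {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  %-20s %6.2f %%\n", x$source[i], x$proportion[i]))
    }
  }
  invisible(x)
}
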