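#' Read a DSSAT-dialect daily weather file
#'
#' Parses daily weather text in the DSSAT dialect (as emitted by GCM
#' downscaling tools): free header lines, then a column header starting with
#' `@DATE`, then one whitespace-delimited row per day with columns `DATE`,
#' `SRAD`, `TMAX`, `TMIN`, `RAIN`. Date tokens may be `YYDDD` or `YYYYDDD`.
#' The sentinel `-99` (or `-99.0`) marks a missing value: missing `SRAD` or
#' `RAIN` becomes `NA`; a row missing `TMAX` or `TMIN` is dropped with a
#' warning reporting the count. Columns beyond the standard five are kept
#' verbatim.
#'
#' @param path Path to the file.
#' @return A `"weather_series"` data frame (columns `date`, `doy`, `tmax`,
#'   `tmin`, `srad`, `rain`, plus any extra columns), with a `station_id`
#'   attribute taken from a `*...` title line when present.
#' @export
read_wtg <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*@\\s*DATE", toupper(lines))
  if (!length(hdr)) {
    stop("not a DSSAT daily weather file (no @DATE header line): ", path)
  }
  hdr <- hdr[1]
  station <- NA_character_
  title <- grep("^\\*", lines[seq_len(hdr - 1)], value = TRUE)
  if (length(title)) {
    station <- trimws(sub("^\\*+\\s*(WEATHER( DATA)?\\s*:?)?\\s*", "", title[1],
                          ignore.case = TRUE))
    if (!nzchar(station)) station <- NA_character_
  }
  cols <- toupper(strsplit(trimws(sub("^\\s*@", "", lines[hdr])), "\\s+")[[1]])
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(trimws(body)) & !grepl("^\\s*[*!@]", body)]
  if (!length(body)) stop("no data rows in ", path)
  toks <- strsplit(trimws(body), "\\s+")
  nfield <- lengths(toks)
  if (any(nfield < length(cols))) {
    stop("malformed data row(s) at line(s): ",
         paste(utils::head(which(nfield < length(cols)), 5), collapse = ", "))
  }
  mat <- t(vapply(toks, function(t) t[seq_along(cols)], character(length(cols))))
  colnames(mat) <- cols
  need <- c("DATE", "TMAX", "TMIN")
  if (!all(need %in% cols)) {
    stop("header lacks required column(s): ",
         paste(setdiff(need, cols), collapse = ", "))
  }
  tok <- mat[, "DATE"]
  if (!all(grepl("^[0-9]{5}$|^[0-9]{7}$", tok))) {
    stop("unparseable DATE token(s), expected YYDDD or YYYYDDD: ",
         paste(utils::head(tok[!grepl("^[0-9]{5}$|^[0-9]{7}$", tok)], 3), collapse = ", "))
  }
  long <- nchar(tok) == 7L
  year <- integer(length(tok))
  doy <- integer(length(tok))
  year[long] <- as.integer(substr(tok[long], 1, 4))
  doy[long] <- as.integer(substr(tok[long], 5, 7))
  yy <- as.integer(substr(tok[!long], 1, 2))
  year[!long] <- ifelse(yy < 30, 2000L + yy, 1900L + yy)
  doy[!long] <- as.integer(substr(tok[!long], 3, 5))

  num <- function(col) {
    if (!col %in% cols) return(rep(NA_real_, nrow(mat)))
    v <- suppressWarnings(as.numeric(mat[, col]))
    v[!is.na(v) & v <= -99] <- NA_real_
    v
  }
  tmax <- num("TMAX")
  tmin <- num("TMIN")
  drop <- is.na(tmax) | is.na(tmin)
  if (any(drop)) {
    warning(sum(drop), " row(s) rejected for missing TMAX/TMIN")
  }
  bad <- !drop & tmax < tmin
  if (any(bad)) {
    stop("TMAX < TMIN on date(s): ",
         paste(utils::head(tok[bad], 5), collapse = ", "))
  }
  keep <- !drop
  out <- data.frame(
    date = as.Date(doy[keep] - 1,
                   origin = as.Date(sprintf("%d-01-01", year[keep]))),
    doy = doy[keep],
    tmax = tmax[keep],
    tmin = tmin[keep],
    srad = num("SRAD")[keep],
    rain = num("RAIN")[keep]
  )
  extra <- setdiff(cols, c("DATE", "SRAD", "TMAX", "TMIN", "RAIN"))
  for (e in extra) out[[tolower(e)]] <- mat[keep, e]
  attr(out, "station_id") <- station
  class(out) <- c("weather_series", "data.frame")
  out
}

#' Write a daily weather series as a DSSAT-dialect file
#'
#' Emits one row per day with fixed column order `DATE SRAD TMAX TMIN RAIN`,
#' `YYDDD` date tokens and temperatures at one decimal place (the DSSAT
#' convention). `NA` values are written as the `-99.0` sentinel. Columns
#' other than the standard five are dropped, with a single message.
#'
#' @param series A `"weather_series"` data frame (needs `date` or `doy`,
#'   `tmax`, `tmin`; optional `srad`, `rain`).
#' @param path Output path.
#' @param station_id Title-line label; defaults to the series attribute.
#' @return `path`, invisibly.
#' @export
write_wtg <- function(series, path, station_id = attr(series, "station_id")) {
  if (!is.data.frame(series) || nrow(series) == 0L) {
    stop("series must be a non-empty data frame")
  }
  stopifnot(all(c("tmax", "tmin") %in% names(series)))
  if ("date" %in% names(series)) {
    date <- as.Date(series$date)
    year <- as.integer(format(date, "%Y"))
    doy <- as.integer(format(date, "%j"))
  } else if ("doy" %in% names(series)) {
    doy <- as.integer(series$doy)
    year <- rep(0L, length(doy))
  } else {
    stop("series needs a 'date' or 'doy' column")
  }
  extra <- setdiff(names(series), c("date", "doy", "tmax", "tmin", "srad", "rain"))
  if (length(extra)) {
    message("dropping non-standard column(s) on write: ",
            paste(extra, collapse = ", "))
  }
  fmt <- function(v) {
    v <- if (is.null(v)) rep(NA_real_, nrow(series)) else as.numeric(v)
    ifelse(is.na(v), "-99.0", sprintf("%.1f", v))
  }
  rows <- sprintf("%02d%03d %5s %5s %5s %5s",
                  year %% 100L, doy,
                  fmt(series$srad), fmt(series$tmax), fmt(series$tmin),
                  fmt(series$rain))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("*WEATHER DATA : %s", if (is.null(station_id) || is.na(station_id)) "" else station_id),
    "@DATE  SRAD  TMAX  TMIN  RAIN",
    rows
  ), con)
  invisible(path)
}

#' Flatten weather replicates into long and wide tables
#'
#' Mirrors the post-processing of downloaded weather replicates into flat
#' tables: a long table with one row per (replicate, day), plus two wide
#' pivots (days x replicates) for Tmax and Tmin.
#'
#' @param x A [generate_replicate_set()] result, or a list of
#'   `"weather_series"` data frames aligned on the same dates.
#' @return A list of class `"replicate_table"`: `long` (columns `replicate`,
#'   `date`, `tmax`, `tmin`), `tmax` and `tmin` (data frames `date` +
#'   `rep_1` ... `rep_n`).
#' @export
replicates_to_table <- function(x) {
  reps <- if (inherits(x, "replicate_set")) x$replicates else x
  if (!is.list(reps) || !length(reps)) stop("no replicates supplied")
  ref <- reps[[1]]$date
  for (i in seq_along(reps)) {
    di <- reps[[i]]$date
    if (length(di) != length(ref) || any(di != ref)) {
      stop("replicate ", i, " has a mismatched date span")
    }
  }
  n <- length(reps)
  long <- data.frame(
    replicate = rep(seq_len(n), each = length(ref)),
    date = rep(ref, n),
    tmax = unlist(lapply(reps, `[[`, "tmax"), use.names = FALSE),
    tmin = unlist(lapply(reps, `[[`, "tmin"), use.names = FALSE)
  )
  wide <- function(var) {
    w <- data.frame(date = ref)
    for (i in seq_len(n)) w[[sprintf("rep_%d", i)]] <- reps[[i]][[var]]
    w
  }
  structure(list(long = long, tmax = wide("tmax"), tmin = wide("tmin")),
            class = "replicate_table")
}
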