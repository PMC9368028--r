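#' Multi-station, multi-indicator measurement panel
#'
#' An `indicator_panel` holds a cube of weekly measurements indexed
#' (station, time, indicator), together with its timestamps, station
#' identifiers and indicator names.  It is the common input of the windowing,
#' scaling and modelling functions.
#'
#' @param values numeric array of dimension (stations, times, indicators).
#'   `NA` entries mark missing measurements; [impute_missing()] removes them.
#' @param timestamps vector of class `Date` (or coercible), strictly
#'   increasing, one per time slice.
#' @param station_ids character vector of unique station identifiers.
#' @param indicator_names character vector of unique indicator names,
#'   defaulting to `c("pH", "DO", "CODMn", "NH3N")`.
#' @param units named character vector of measurement units per indicator.
#'
#' @return An object of class `indicator_panel`.
#' @export
indicator_panel <- function(values, timestamps, station_ids = NULL,
                            indicator_names = WQ_INDICATORS,
                            units = NULL) {
  values <- as.array(values)
  wq_assert(length(dim(values)) == 3L,
            "`values` must be a 3-d array (station, time, indicator)")
  timestamps <- as.Date(timestamps)
  ns <- dim(values)[1L]; nt <- dim(values)[2L]; ni <- dim(values)[3L]
  if (is.null(station_ids)) station_ids <- sprintf("S%03d", seq_len(ns))
  wq_assert(length(timestamps) == nt, "timestamp count must match time dimension")
  wq_assert(length(station_ids) == ns, "station id count must match station dimension")
  wq_assert(length(indicator_names) == ni,
            "indicator name count must match indicator dimension")
  wq_assert(!anyDuplicated(indicator_names), "indicator names must be unique")
  wq_assert(!anyDuplicated(station_ids), "station ids must be unique")
  if (nt > 1L) {
    wq_assert(all(diff(as.numeric(timestamps)) > 0),
              "timestamps must be strictly increasing", "aquamtl_time_error")
  }
  if (is.null(units)) {
    units <- setNames(ifelse(indicator_names == "pH", "1", "mg/L"),
                      indicator_names)
  }
  dimnames(values) <- list(station_ids, NULL, indicator_names)
  structure(
    list(values = values, timestamps = timestamps, station_ids = station_ids,
         indicator_names = indicator_names, units = units),
    class = "indicator_panel"
  )
}

#' @export
print.indicator_panel <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<indicator_panel> %d stations x %d weeks x %d indicators\n",
              d[1L], d[2L], d[3L]))
  cat("  indicators:", paste(x$indicator_names, collapse = ", "), "\n")
  cat(sprintf("  span: %s .. %s\n", min(x$timestamps), max(x$timestamps)))
  nmiss <- sum(is.na(x$values))
  if (nmiss > 0) cat(sprintf("  missing entries: %d\n", nmiss))
  invisible(x)
}

#' Number of time points in a panel
#' @param panel an [indicator_panel()].
#' @return integer length of the time axis.
#' @export
n_times <- function(panel) dim(panel$values)[2L]

#' Drop heavily missing stations and interpolate remaining gaps
#'
#' Stations whose missing fraction in any indicator exceeds
#' `max_missing_fraction` are dropped.  Remaining internal gaps are filled by
#' linear interpolation along time; gaps at the series edges take the nearest
#' observed value.
#'
#' @param panel an [indicator_panel()], possibly with `NA` entries.
#' @param max_missing_fraction stations with a larger per-indicator missing
#'   fraction are removed (default 0.2).
#' @return A complete (no `NA`) `indicator_panel` on the retained stations.
#' @export
impute_missing <- function(panel, max_missing_fraction = 0.2) {
  v <- panel$values
  nt <- dim(v)[2L]
  miss_frac <- apply(v, c(1L, 3L), function(x) mean(is.na(x)))
  keep <- apply(miss_frac, 1L, function(f) all(f <= max_missing_fraction))
  if (!any(keep)) {
    wq_stop("all stations exceed the missing-data threshold",
            "aquamtl_missing_error")
  }
  v <- v[keep, , , drop = FALSE]
  for (s in seq_len(dim(v)[1L])) {
    for (i in seq_len(dim(v)[3L])) {
      x <- v[s, , i]
      if (anyNA(x)) {
        obs <- which(!is.na(x))
        wq_assert(length(obs) >= 1L, "a retained series has no observations")
        # rule = 2 extends edge gaps with the nearest observed value
        x <- stats::approx(obs, x[obs], xout = seq_len(nt), rule = 2)$y
        v[s, , i] <- x
      }
    }
  }
  indicator_panel(v, panel$timestamps, panel$station_ids[keep],
                  panel$indicator_names, panel$units)
}
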