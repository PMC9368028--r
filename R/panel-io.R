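# Default aliases accepted for indicator names in long CSV files.
WQ_ALIASES <- c("pH" = "pH", "ph" = "pH",
                "DO" = "DO", "do" = "DO",
                "CODMn" = "CODMn", "COD_Mn" = "CODMn", "COD" = "CODMn",
                "NH3N" = "NH3N", "NH3-N" = "NH3N", "NHN" = "NH3N")

#' Read a long-format panel CSV
#'
#' Expects the header `station_id,date,indicator,value` with ISO-8601 dates.
#' The rows are pivoted into the (station, time, indicator) cube; cells
#' absent from the file become missing entries (see [impute_missing()]).
#'
#' @param path CSV file path.
#' @param indicators indicator names expected in the panel.
#' @param aliases named character vector mapping file spellings to canonical
#'   indicator names.
#' @return An [indicator_panel()]; per-station missingness is reported via
#'   `attr(panel, "missingness")`.
#' @export
read_panel_csv <- function(path, indicators = WQ_INDICATORS, aliases = WQ_ALIASES) {
  if (!file.exists(path)) {
    wq_stop(sprintf("panel file not found: %s", path), "aquamtl_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "date", "indicator", "value")
  if (!all(need %in% names(df))) {
    wq_stop(sprintf("panel CSV must have columns %s", paste(need, collapse = ",")),
            "aquamtl_io_error")
  }
  known <- df$indicator %in% names(aliases)
  if (!all(known)) {
    wq_stop(sprintf("unknown indicator name(s): %s",
                    paste(unique(df$indicator[!known]), collapse = ", ")),
            "aquamtl_io_error")
  }
  df$indicator <- unname(aliases[df$indicator])
  key <- paste(df$station_id, df$date, df$indicator, sep = "|")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    wq_stop(sprintf("duplicate (station, date, indicator) rows: %s%s",
                    paste(head(dup, 5L), collapse = "; "),
                    if (length(dup) > 5L) "; ..." else ""),
            "aquamtl_io_error")
  }
  stations <- sort(unique(df$station_id))
  dates <- sort(unique(as.Date(df$date)))
  v <- array(NA_real_, dim = c(length(stations), length(dates), length(indicators)))
  si <- match(df$station_id, stations)
  ti <- match(as.Date(df$date), dates)
  ii <- match(df$indicator, indicators)
  v[cbind(si, ti, ii)] <- df$value
  panel <- indicator_panel(v, dates, stations, indicators)
  attr(panel, "missingness") <- apply(v, 1L, function(x) mean(is.na(x)))
  panel
}

#' Write a panel as a long-format CSV
#'
#' @param panel an [indicator_panel()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  d <- dim(panel$values)
  grid <- expand.grid(station = seq_len(d[1L]), time = seq_len(d[2L]),
                      ind = seq_len(d[3L]))
  df <- data.frame(
    station_id = panel$station_ids[grid$station],
    date = as.character(panel$timestamps[grid$time]),
    indicator = panel$indicator_names[grid$ind],
    value = panel$values[cbind(grid$station, grid$time, grid$ind)]
  )
  df <- df[order(df$station_id, df$date, df$indicator), ]
  df <- df[!is.na(df$value), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a panel as a wide CSV (one row per station-date)
#'
#' @inheritParams write_panel_csv
#' @export
write_panel_wide <- function(panel, path) {
  d <- dim(panel$values)
  rows <- expand.grid(station = seq_len(d[1L]), time = seq_len(d[2L]))
  df <- data.frame(station_id = panel$station_ids[rows$station],
                   date = as.character(panel$timestamps[rows$time]))
  for (i in seq_len(d[3L])) {
    df[[panel$indicator_names[i]]] <- panel$values[cbind(rows$station, rows$time, i)]
  }
  df <- df[order(df$station_id, df$date), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
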