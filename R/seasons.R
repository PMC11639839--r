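#' Season calendar
#'
#' The study calendar splits each year into a summer rainfall season
#' (1 May - 31 October) and a winter rainfall season (1 November - 30 April)
#' that spans the calendar-year boundary.  Timestamps are stored as UTC
#' seconds; the season rule is applied after shifting by a configurable UTC
#' offset (default -8 h, i.e. local study time in the desert Southwest).
#'
#' @param timestamp numeric vector, UTC seconds since 1970-01-01.
#' @param utc_offset_hours hours added to UTC to obtain local time.
#' @return data.frame with columns \code{season} ("summer"/"winter"),
#'   \code{season_year} (the starting calendar year of the season), and
#'   \code{year_label} (e.g. "summer 2020", "winter 2019-2020").
#' @export
season_of <- function(timestamp, utc_offset_hours = -8) {
  lt <- as.POSIXlt(timestamp + utc_offset_hours * 3600,
                   origin = "1970-01-01", tz = "UTC")
  mon <- lt$mon + 1L
  yr <- lt$year + 1900L
  season <- ifelse(mon >= 5 & mon <= 10, "summer", "winter")
  season_year <- ifelse(season == "summer", yr,
                        ifelse(mon >= 11, yr, yr - 1L))
  year_label <- ifelse(season == "summer",
                       sprintf("summer %d", season_year),
                       sprintf("winter %d-%d", season_year, season_year + 1L))
  data.frame(season = season, season_year = as.integer(season_year),
             year_label = year_label)
}

#' Season window bounds in UTC seconds
#'
#' @param season "summer" or "winter".
#' @param season_year starting calendar year of the season (winter 2019-2020
#'   has \code{season_year = 2019}).
#' @param utc_offset_hours as in \code{\link{season_of}}.
#' @return numeric \code{c(start, end)}: UTC seconds, start-inclusive and
#'   end-exclusive.
#' @export
season_window <- function(season, season_year, utc_offset_hours = -8) {
  season <- match.arg(season, c("summer", "winter"))
  loc <- function(y, m) as.numeric(ISOdatetime(y, m, 1, 0, 0, 0, tz = "UTC"))
  if (season == "summer") {
    w <- c(loc(season_year, 5), loc(season_year, 11))
  } else {
    w <- c(loc(season_year, 11), loc(season_year + 1, 5))
  }
  w - utc_offset_hours * 3600
}

#' Enumerate season windows overlapping a time range
#'
#' @param from,to UTC seconds.
#' @inheritParams season_of
#' @return data.frame season, season_year, year_label, start, end.
#' @export
season_windows <- function(from, to, utc_offset_hours = -8) {
  stopifnot(to > from)
  s0 <- season_of(from, utc_offset_hours)
  rows <- list()
  season <- s0$season; yr <- s0$season_year
  repeat {
    w <- season_window(season, yr, utc_offset_hours)
    lbl <- if (season == "summer") sprintf("summer %d", yr) else
      sprintf("winter %d-%d", yr, yr + 1L)
    rows[[length(rows) + 1]] <- data.frame(
      season = season, season_year = yr, year_label = lbl,
      start = w[1], end = w[2])
    if (w[2] >= to) break
    if (season == "summer") {
      season <- "winter"                 # summer Y -> winter Y
    } else {
      season <- "summer"; yr <- yr + 1L  # winter Y -> summer Y+1
    }
  }
  do.call(rbind, rows)
}

#' Split a track into season-by-year sub-tracks
#'
#' Each fix is assigned to exactly one season window; winter windows span the
#' calendar-year boundary and carry a two-year label.
#'
#' @param track data.frame with at least a \code{timestamp_utc} column
#'   (numeric UTC seconds).
#' @inheritParams season_of
#' @return named list of data.frames, one per season-by-year stratum present.
#' @export
split_by_season <- function(track, utc_offset_hours = -8) {
  stopifnot(is.data.frame(track), "timestamp_utc" %in% names(track))
  s <- season_of(track$timestamp_utc, utc_offset_hours)
  out <- split(track, s$year_label)
  # keep chronological order of strata
  first_ts <- vapply(out, function(d) min(d$timestamp_utc), numeric(1))
  out[order(first_ts)]
}

#' Read and write track CSV files
#'
#' Tracks are exchanged as CSV with columns \code{individual_id},
#' \code{species}, \code{timestamp_utc} (ISO-8601), \code{x_m}, \code{y_m}.
#' In memory, timestamps are numeric UTC seconds.
#'
#' @param file path to a CSV file.
#' @return \code{read_tracks}: data.frame with numeric \code{timestamp_utc}.
#' @export
read_tracks <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("individual_id", "species", "timestamp_utc", "x_m", "y_m")
  if (!all(need %in% names(d)))
    stop("track CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d$timestamp_utc <- iso_to_epoch(d$timestamp_utc)
  d
}

#' @rdname read_tracks
#' @param tracks data.frame as returned by \code{read_tracks}.
#' @export
write_tracks <- function(tracks, file) {
  tracks$timestamp_utc <- epoch_to_iso(tracks$timestamp_utc)
  utils::write.csv(tracks, file, row.names = FALSE)
  invisible(file)
}

iso_to_epoch <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- as.numeric(as.POSIXct(x, tz = "UTC",
                               tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                              "%Y-%m-%d %H:%M:%S",
                                              "%Y-%m-%d")))
  if (anyNA(out) && !anyNA(x))
    stop("unparseable ISO-8601 timestamps in input", call. = FALSE)
  out
}

epoch_to_iso <- function(x) {
  format(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%S")
}
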