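#' Standardize photo records to a minimum inter-burst interval
#'
#' Greedy forward pass per camera-by-species stream: the first record is
#' kept; any record closer than \code{min_interval} seconds to the last kept
#' record is dropped.  Used to subset fast-trigger (30 s) camera programmes
#' to the one-minute interval of the slower programme so the two placement
#' types are comparable.
#'
#' @param records photo records data.frame: \code{camera_id}, \code{species},
#'   \code{timestamp_utc} (UTC s).
#' @param min_interval minimum retained gap (s); default 60.
#' @return the standardized records, sorted by camera, species, time.
#' @export
standardize_bursts <- function(records, min_interval = 60) {
  stopifnot(min_interval > 0)
  if (nrow(records) == 0) return(records)
  records <- records[order(records$camera_id, records$species,
                           records$timestamp_utc), , drop = FALSE]
  keep_one <- function(ts) {
    keep <- logical(length(ts))
    last <- -Inf
    for (i in seq_along(ts)) {
      if (ts[i] - last >= min_interval) {
        keep[i] <- TRUE
        last <- ts[i]
      }
    }
    keep
  }
  grp <- interaction(records$camera_id, records$species, drop = TRUE)
  keep <- unsplit(lapply(split(records$timestamp_utc, grp), keep_one), grp)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group photo records into independent detection events
#'
#' Per camera-by-species stream, a new detection event starts whenever the
#' gap from the previous record is strictly greater than the species'
#' discrimination threshold; records at or under the threshold are merged
#' into the ongoing event (likely successive detections of the same
#' individual).  Default thresholds: 1800 s (30 min) for the predator and
#' 600 s (10 min) for the prey; a scalar threshold applies to all species.
#'
#' @param records standardized photo records.
#' @param threshold discrimination threshold (s): a single number, or a named
#'   vector/list keyed by species.
#' @return detection events data.frame: \code{camera_id}, \code{species},
#'   \code{start_timestamp} (UTC s), \code{n_photos_merged}.
#' @export
group_detections <- function(records,
                             threshold = c(predator = 1800, prey = 600,
                                           coyote = 1800, jackrabbit = 600)) {
  if (nrow(records) == 0)
    return(data.frame(camera_id = character(0), species = character(0),
                      start_timestamp = numeric(0),
                      n_photos_merged = integer(0)))
  records <- records[order(records$camera_id, records$species,
                           records$timestamp_utc), , drop = FALSE]
  thr_of <- function(sp) {
    if (length(threshold) == 1 && is.null(names(threshold)))
      return(as.numeric(threshold))
    if (!sp %in% names(threshold))
      stop("no discrimination threshold for species '", sp, "'",
           call. = FALSE)
    as.numeric(threshold[[sp]])
  }
  grp <- interaction(records$camera_id, records$species, drop = TRUE)
  pieces <- lapply(split(records, grp), function(d) {
    th <- thr_of(d$species[1])
    stopifnot(th > 0)
    ts <- d$timestamp_utc
    new_event <- c(TRUE, diff(ts) > th)
    ev <- cumsum(new_event)
    data.frame(
      camera_id = d$camera_id[1], species = d$species[1],
      start_timestamp = as.numeric(tapply(ts, ev, min)),
      n_photos_merged = as.integer(tapply(ts, ev, length))
    )
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$camera_id, out$species, out$start_timestamp), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Camera operating effort per season-by-year stratum
#'
#' Sums each camera's active intervals intersected with every season window
#' they overlap, in fractional days.  Deployments may carry repeated rows per
#' camera for outage-split intervals; overlapping intervals for one camera
#' are an error.
#'
#' @param deployments deployments data.frame with \code{camera_id},
#'   \code{active_from}, \code{active_to} (UTC s).
#' @param seasons season windows as from \code{\link{season_windows}}; by
#'   default derived from the deployment time range.
#' @param utc_offset_hours see \code{\link{season_of}}.
#' @return data.frame: \code{camera_id}, \code{season}, \code{year_label},
#'   \code{effort_days}.
#' @export
camera_effort <- function(deployments, seasons = NULL,
                          utc_offset_hours = -8) {
  stopifnot(all(c("camera_id", "active_from", "active_to") %in%
                  names(deployments)))
  dep <- deployments[is.finite(deployments$active_from) &
                       is.finite(deployments$active_to), , drop = FALSE]
  stopifnot(nrow(dep) > 0, all(dep$active_to > dep$active_from))
  for (cid in unique(dep$camera_id)) {
    iv <- dep[dep$camera_id == cid, , drop = FALSE]
    iv <- iv[order(iv$active_from), , drop = FALSE]
    if (nrow(iv) > 1 &&
        any(iv$active_from[-1] < iv$active_to[-nrow(iv)]))
      stop("overlapping active intervals for camera ", cid, call. = FALSE)
  }
  if (is.null(seasons))
    seasons <- season_windows(min(dep$active_from), max(dep$active_to),
                              utc_offset_hours)
  rows <- list()
  for (si in seq_len(nrow(seasons))) {
    ov <- pmin(dep$active_to, seasons$end[si]) -
      pmax(dep$active_from, seasons$start[si])
    ov <- pmax(ov, 0)
    t_days <- tapply(ov, dep$camera_id, sum) / 86400
    rows[[si]] <- data.frame(
      camera_id = names(t_days),
      season = seasons$season[si],
      year_label = seasons$year_label[si],
      effort_days = as.numeric(t_days)
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detection count table for REM input
#'
#' Joins detection events to camera effort and placement labels, producing
#' one row per camera within each species-by-season-by-year-by-placement
#' stratum: the event count \code{y} and effort \code{t} (camera-days).
#' Cameras with effort but no events are retained as zero-count rows.
#'
#' @param events detection events (see \code{\link{group_detections}}).
#' @param efforts camera effort (see \code{\link{camera_effort}}).
#' @param deployments deployments data.frame supplying \code{placement} per
#'   camera.
#' @param utc_offset_hours see \code{\link{season_of}}.
#' @param species species to tabulate; defaults to those present in
#'   \code{events}.  Species without any event get all-zero rows.
#' @return data.frame: \code{species}, \code{season}, \code{year_label},
#'   \code{placement}, \code{camera_id}, \code{y}, \code{t}.
#' @export
count_table <- function(events, efforts, deployments,
                        utc_offset_hours = -8,
                        species = unique(events$species)) {
  placement <- unique(deployments[, c("camera_id", "placement")])
  unknown <- setdiff(events$camera_id, placement$camera_id)
  if (length(unknown) > 0)
    stop("events at unknown cameras: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  ev <- events
  if (nrow(ev) > 0) {
    s <- season_of(ev$start_timestamp, utc_offset_hours)
    ev$season <- s$season; ev$year_label <- s$year_label
  }
  base <- merge(efforts, placement, by = "camera_id")
  base <- base[base$effort_days > 0, , drop = FALSE]
  rows <- list()
  for (sp in species) {
    b <- base
    b$species <- sp
    key_b <- paste(b$camera_id, b$season, b$year_label)
    e <- ev[ev$species == sp, , drop = FALSE]
    cnt <- table(paste(e$camera_id, e$season, e$year_label))
    b$y <- as.integer(cnt[key_b])
    b$y[is.na(b$y)] <- 0L
    miss <- setdiff(unique(paste(e$camera_id, e$season, e$year_label)),
                    key_b)
    if (length(miss) > 0)
      stop("detection events outside any camera effort stratum: ",
           paste(miss, collapse = "; "), call. = FALSE)
    rows[[sp]] <- b
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(species = character(0), season = character(0),
                      year_label = character(0), placement = character(0),
                      camera_id = character(0), y = integer(0),
                      t = numeric(0)))
  out <- data.frame(species = out$species, season = out$season,
                    year_label = out$year_label, placement = out$placement,
                    camera_id = out$camera_id, y = out$y,
                    t = out$effort_days)
  out <- out[order(out$species, out$year_label, out$placement,
                   out$camera_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise a seasonal detection table
#'
#' Computes, from a table of detection totals by species, season-by-year and
#' placement, the per-placement species totals, the strategic:random ratios,
#' and the seasonal totals combined across placements.
#'
#' @param detections data.frame with columns \code{species}, \code{season},
#'   \code{year_label}, \code{placement}, \code{detections} (or per-camera
#'   \code{y} rows, which are summed).
#' @return list with \code{placement_totals} (species x placement),
#'   \code{strategic_random_ratio} (named by species), and
#'   \code{season_totals} (species x year_label).
#' @export
detection_summary <- function(detections) {
  cnt <- if ("detections" %in% names(detections)) detections$detections
  else detections$y
  stopifnot(!is.null(cnt), all(cnt >= 0))
  pt <- tapply(cnt, list(detections$species, detections$placement), sum)
  pt[is.na(pt)] <- 0
  ratio <- if (all(c("random", "strategic") %in% colnames(pt)))
    pt[, "strategic"] / pt[, "random"] else NULL
  st <- tapply(cnt, list(detections$species, detections$year_label), sum)
  st[is.na(st)] <- 0
  list(placement_totals = pt, strategic_random_ratio = ratio,
       season_totals = st)
}

#' Load the bundled Mojave Desert seasonal detection totals
#'
#' Seasonal totals of unique coyote and jackrabbit detections at randomly and
#' strategically placed camera-traps from a four-year Mojave Desert
#' predator-prey survey, as printed in the source survey's summary table.
#'
#' @return data.frame: \code{species}, \code{season}, \code{year_label},
#'   \code{placement}, \code{detections}.
#' @export
mojave_detections <- function() {
  f <- system.file("extdata", "mojave_detection_summary.csv",
                   package = "remeval", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
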