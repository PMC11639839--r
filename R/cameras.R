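#' Photo burst specification
#'
#' @param photos_per_burst photographs per triggered burst (>= 1).
#' @param interburst_interval minimum gap (s) between successive bursts while
#'   an animal remains inside the detection zone.
#' @return a \code{burst_spec} object.
#' @export
burst_spec <- function(photos_per_burst = 6, interburst_interval = 60) {
  stopifnot(photos_per_burst >= 1, interburst_interval > 0)
  structure(list(photos_per_burst = as.integer(photos_per_burst),
                 interburst_interval = interburst_interval),
            class = "burst_spec")
}

#' Place cameras on random sampling grids
#'
#' Cameras are arranged in clusters of four (the corners of a square with
#' side \code{within_cluster_spacing}); cluster centres sit on a lattice with
#' spacing \code{cluster_spacing} inside each grid, and grids are tiled side
#' by side.  The default configuration is two grids of 20 cameras: 40 cameras
#' in 10 clusters, 1 km between clusters and 500 m between the cameras of a
#' cluster.  Placement ignores corridors entirely (completely random
#' sampling); camera headings are drawn uniformly on [0, 2pi).
#'
#' @param extent arena \code{c(xmin, xmax, ymin, ymax)} (m).
#' @param n_grids number of grids.
#' @param cameras_per_grid cameras per grid; must be a multiple of 4.
#' @param cluster_spacing distance (m) between cluster centres.
#' @param within_cluster_spacing side (m) of the square of cameras within a
#'   cluster.
#' @param active_from,active_to optional deployment interval (UTC s) applied
#'   to every camera.
#' @param seed integer seed for the headings (and grid anchor jitter).
#' @return deployments data.frame: \code{camera_id}, \code{x_m}, \code{y_m},
#'   \code{placement} ("random"), \code{heading_rad}, \code{active_from},
#'   \code{active_to}.
#' @export
place_cameras_random <- function(extent, n_grids = 2, cameras_per_grid = 20,
                                 cluster_spacing = 1000,
                                 within_cluster_spacing = 500,
                                 active_from = NA_real_,
                                 active_to = NA_real_, seed = NULL) {
  stopifnot(length(extent) == 4, n_grids >= 1, cameras_per_grid >= 4,
            cameras_per_grid %% 4 == 0, cluster_spacing > 0,
            within_cluster_spacing > 0)
  if (!is.null(seed)) set.seed(seed)
  n_clusters <- cameras_per_grid %/% 4L
  ncol_cl <- ceiling(sqrt(n_clusters))
  nrow_cl <- ceiling(n_clusters / ncol_cl)
  gw <- ncol_cl * cluster_spacing          # grid footprint incl. margin
  gh <- nrow_cl * cluster_spacing
  W <- extent[2] - extent[1]; H <- extent[4] - extent[3]
  if (n_grids * gw > W || gh > H)
    stop("camera grids do not fit in the extent: need at least ",
         n_grids * gw, " x ", gh, " m", call. = FALSE)
  half <- within_cluster_spacing / 2
  rows <- list()
  cam <- 0L
  for (g in seq_len(n_grids)) {
    gx0 <- extent[1] + (g - 1) * gw + cluster_spacing / 2
    gy0 <- extent[3] + cluster_spacing / 2
    placed <- 0L
    for (rr in seq_len(nrow_cl)) {
      for (cc in seq_len(ncol_cl)) {
        if (placed >= n_clusters) break
        cx <- gx0 + (cc - 1) * cluster_spacing
        cy <- gy0 + (rr - 1) * cluster_spacing
        for (q in 1:4) {
          cam <- cam + 1L
          rows[[cam]] <- c(cx + half * c(-1, 1, 1, -1)[q],
                           cy + half * c(-1, -1, 1, 1)[q])
        }
        placed <- placed + 1L
      }
    }
  }
  xy <- do.call(rbind, rows)
  if (any(xy[, 1] < extent[1] | xy[, 1] > extent[2] |
          xy[, 2] < extent[3] | xy[, 2] > extent[4]))
    stop("camera positions fall outside the extent", call. = FALSE)
  n <- nrow(xy)
  data.frame(
    camera_id = sprintf("R%02d", seq_len(n)),
    x_m = xy[, 1], y_m = xy[, 2],
    placement = "random",
    heading_rad = stats::runif(n, 0, 2 * pi),
    active_from = active_from, active_to = active_to
  )
}

#' Place cameras strategically along travel corridors
#'
#' Cameras are dropped at points sampled uniformly by arc length along the
#' landscape's corridor polylines (targeting travel routes, i.e. non-random
#' sampling).  Headings uniform on [0, 2pi).
#'
#' @param land a \code{\link{landscape}} with at least one corridor.
#' @param n_cameras number of cameras (default 43).
#' @inheritParams place_cameras_random
#' @return deployments data.frame as in \code{\link{place_cameras_random}}
#'   with \code{placement = "strategic"} and ids \code{S01, S02, ...}.
#' @export
place_cameras_strategic <- function(land, n_cameras = 43,
                                    active_from = NA_real_,
                                    active_to = NA_real_, seed = NULL) {
  stopifnot(inherits(land, "landscape"), n_cameras > 0)
  segs <- corridor_segments(land)
  if (nrow(segs) == 0)
    stop("landscape has no corridors to place strategic cameras on",
         call. = FALSE)
  seg_len <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
  if (sum(seg_len) <= 0)
    stop("corridor set has zero total length", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s <- stats::runif(n_cameras, 0, sum(seg_len))
  cum <- cumsum(seg_len)
  seg_i <- findInterval(s, c(0, cum), rightmost.closed = TRUE)
  seg_i[seg_i > length(seg_len)] <- length(seg_len)
  frac <- (s - c(0, cum)[seg_i]) / seg_len[seg_i]
  data.frame(
    camera_id = sprintf("S%02d", seq_len(n_cameras)),
    x_m = segs[seg_i, 1] + frac * (segs[seg_i, 3] - segs[seg_i, 1]),
    y_m = segs[seg_i, 2] + frac * (segs[seg_i, 4] - segs[seg_i, 2]),
    placement = "strategic",
    heading_rad = stats::runif(n_cameras, 0, 2 * pi),
    active_from = active_from, active_to = active_to
  )
}

#' Simulate photo records from fine paths crossing camera viewsheds
#'
#' A camera's detection zone is the circular sector with apex at the camera,
#' radius \code{r}, central angle \code{theta} centred on the camera heading.
#' Detection inside the sector is perfect (the ideal-gas assumption): a burst
#' is emitted at the moment of sector entry and every
#' \code{interburst_interval} seconds while the animal remains inside.  One
#' record is returned per burst; timestamps are rounded to whole seconds.
#'
#' @param paths a fine path data.frame (\code{time_s, x_m, y_m}, spacing
#'   <= 10 s) or a list of such paths (one per animal).
#' @param deployments deployments data.frame (see
#'   \code{\link{place_cameras_random}}).
#' @param r detection radius (m).
#' @param theta detection arc (radians, in (0, 2pi)).
#' @param burst a \code{\link{burst_spec}}.
#' @param species species label stamped on the records.
#' @return photo records data.frame: \code{camera_id}, \code{species},
#'   \code{timestamp_utc} (UTC s).
#' @export
simulate_photos <- function(paths, deployments, r = 5, theta = 0.7661,
                            burst = burst_spec(), species = "animal") {
  stopifnot(r > 0, theta > 0, theta < 2 * pi,
            inherits(burst, "burst_spec"))
  if (is.data.frame(paths)) paths <- list(paths)
  out <- list()
  for (path in paths) {
    tt <- path$time_s
    if (length(tt) > 1 && max(diff(tt)) > 10)
      stop("fine path spacing must be <= 10 s", call. = FALSE)
    for (ci in seq_len(nrow(deployments))) {
      # cheap bounding-box prefilter: anything outside the r-box is outside
      cand <- which(abs(path$x_m - deployments$x_m[ci]) <= r &
                      abs(path$y_m - deployments$y_m[ci]) <= r)
      if (length(cand) == 0) next
      dx <- path$x_m[cand] - deployments$x_m[ci]
      dy <- path$y_m[cand] - deployments$y_m[ci]
      d2 <- dx * dx + dy * dy
      ang <- atan2(dy, dx)
      dang <- (ang - deployments$heading_rad[ci] + pi) %% (2 * pi) - pi
      ok <- d2 <= r * r & abs(dang) <= theta / 2 & d2 > 0
      ins <- cand[ok]
      if (length(ins) == 0) next
      # maximal runs of consecutive fine-grid indices inside the sector
      brk <- which(diff(ins) > 1L)
      starts <- ins[c(1L, brk + 1L)]
      ends <- ins[c(brk, length(ins))]
      for (k in seq_along(starts)) {
        bt <- seq(tt[starts[k]], tt[ends[k]],
                  by = burst$interburst_interval)
        out[[length(out) + 1L]] <- data.frame(
          camera_id = deployments$camera_id[ci],
          species = species,
          timestamp_utc = round(bt)
        )
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(camera_id = character(0), species = character(0),
                      timestamp_utc = numeric(0)))
  recs <- do.call(rbind, out)
  recs <- recs[order(recs$camera_id, recs$timestamp_utc), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Expected ideal-gas encounter rate at one camera
#'
#' Under uniform (ideal-gas) animal movement at density \code{D}
#' (animals/m^2) and mean speed \code{v} (m/s), the expected rate of sector
#' entries per camera is \code{D * v * r * (2 + theta) / pi} per second --
#' the encounter-rate kernel the random encounter model inverts.
#'
#' @param density animals per m^2.
#' @param speed mean scalar speed (m/s).
#' @param r detection radius (m).
#' @param theta detection arc (radians).
#' @return expected encounters per second per camera.
#' @export
expected_encounter_rate <- function(density, speed, r, theta) {
  density * speed * r * (2 + theta) / pi
}
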