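#' Random encounter model parameters
#'
#' The REM's camera-level inputs: detection radius \code{r} (km; the field
#' default is 5 m), detection arc \code{theta} (radians; default 0.7661) and
#' day range \code{v} (km/day).
#'
#' @param v day range (km/day), > 0.
#' @param r radial detection distance in km (default 0.005 = 5 m).
#' @param theta detection arc in radians, in (0, 2pi).
#' @return a \code{rem_params} object.
#' @export
rem_params <- function(v, r = 0.005, theta = 0.7661) {
  stopifnot(is.numeric(v), v > 0, r > 0, theta > 0, theta < 2 * pi)
  structure(list(v = v, r = r, theta = theta), class = "rem_params")
}

#' REM point density
#'
#' The ideal-gas encounter-rate inversion
#' \deqn{D = \frac{y}{t} \cdot \frac{\pi}{v\, r\, (2 + \theta)}}
#' converting a trap rate \code{y/t} (detections per camera-day) into an
#' animal density (animals/km^2) given day range \code{v} (km/day),
#' detection radius \code{r} (km) and arc \code{theta} (radians).
#'
#' @param y number of independent detections (>= 0).
#' @param t camera effort (camera-days, > 0).
#' @param params a \code{\link{rem_params}}.
#' @return density in animals/km^2.
#' @export
rem_density <- function(y, t, params) {
  stopifnot(inherits(params, "rem_params"))
  if (any(t <= 0)) stop("camera effort t must be positive", call. = FALSE)
  if (any(y < 0)) stop("detection count y must be non-negative",
                       call. = FALSE)
  (y / t) * pi / (params$v * params$r * (2 + params$theta))
}

#' Percent relative difference from a baseline estimate
#'
#' \code{100 * (estimate - baseline) / baseline}.
#'
#' @param estimate,baseline density estimates; \code{baseline} must be > 0.
#' @return percent relative difference.
#' @export
percent_rd <- function(estimate, baseline) {
  if (any(baseline <= 0))
    stop("percent relative difference is undefined for baseline <= 0",
         call. = FALSE)
  100 * (estimate - baseline) / baseline
}

#' Bootstrap REM density with camera-level resampling
#'
#' Point estimate: REM density of the pooled counts and effort
#' (\code{sum(y)/sum(t)}, i.e. effort-weighted cameras); optionally the
#' unweighted mean of per-camera densities.  Confidence interval: 2.5/97.5
#' percentiles of the statistic recomputed on \code{n_iter} resamples of
#' whole cameras drawn with replacement (percentile bootstrap).  With a
#' single camera the point estimate is returned and the CI flagged
#' unavailable.
#'
#' @param per_camera data.frame with one row per camera: \code{y}, \code{t}.
#' @param params a \code{\link{rem_params}}.
#' @param n_iter bootstrap iterations (default 1000).
#' @param seed integer RNG seed (required for reproducibility).
#' @param statistic \code{"pooled"} (default) or \code{"mean"} of per-camera
#'   densities.
#' @param conf confidence level (default 0.95).
#' @return one-row data.frame: \code{point}, \code{ci_low}, \code{ci_high},
#'   \code{n_cameras}, \code{n_bootstrap}, \code{ci_ok}.
#' @export
bootstrap_rem <- function(per_camera, params, n_iter = 1000, seed,
                          statistic = c("pooled", "mean"), conf = 0.95) {
  statistic <- match.arg(statistic)
  stopifnot(all(c("y", "t") %in% names(per_camera)),
            all(per_camera$t > 0), all(per_camera$y >= 0),
            n_iter >= 1)
  stat <- function(y, t) {
    if (statistic == "pooled") rem_density(sum(y), sum(t), params)
    else mean(rem_density(y, t, params))
  }
  nc <- nrow(per_camera)
  point <- stat(per_camera$y, per_camera$t)
  if (nc < 2) {
    return(data.frame(point = point, ci_low = NA_real_, ci_high = NA_real_,
                      n_cameras = nc, n_bootstrap = 0L, ci_ok = FALSE))
  }
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  boot <- vapply(seq_len(n_iter), function(b) {
    idx <- sample.int(nc, nc, replace = TRUE)
    stat(per_camera$y[idx], per_camera$t[idx])
  }, numeric(1))
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, type = 7)
  data.frame(point = point, ci_low = qs[1], ci_high = qs[2],
             n_cameras = nc, n_bootstrap = as.integer(n_iter),
             ci_ok = TRUE)
}

#' The six placement-by-velocity REM scenarios
#'
#' @return data.frame describing the scenario grid: \code{scenario},
#'   \code{camera_subset} ("random", "strategic" or "both"),
#'   \code{velocity_multiplier}.  Borrowed-velocity scenarios carry both the
#'   0.8 and 1.2 multipliers (day range 20 percent below/above the stratum
#'   mean); the others use the stratum mean unchanged.
#' @export
rem_scenarios <- function() {
  data.frame(
    scenario = c("Baseline", "Strategic", "Hybrid",
                 "Random+Borrowed", "Random+Borrowed",
                 "Strategic+Borrowed", "Strategic+Borrowed",
                 "Hybrid+Borrowed", "Hybrid+Borrowed"),
    camera_subset = c("random", "strategic", "both",
                      "random", "random", "strategic", "strategic",
                      "both", "both"),
    velocity_multiplier = c(1, 1, 1, 0.8, 1.2, 0.8, 1.2, 0.8, 1.2)
  )
}

#' Run the REM scenario analysis
#'
#' For every species-by-season-by-year stratum with a day-range estimate,
#' fits the REM with bootstrap CIs under the six camera-placement by
#' velocity-specification scenarios and reports each scenario's percent
#' relative difference from the Baseline (random cameras, stratum-mean
#' velocity).
#'
#' @param counts per-camera count table from \code{\link{count_table}}.
#' @param speeds data.frame with \code{species}, \code{year_label} and
#'   \code{mean_day_range_km} (km/day) per stratum (e.g. from
#'   \code{\link{aggregate_speeds}} plus a species column).
#' @param r,theta REM detection-zone parameters (km, radians).
#' @param n_iter bootstrap iterations.
#' @param seed integer seed; each stratum-by-scenario bootstrap derives its
#'   own substream deterministically.
#' @param statistic passed to \code{\link{bootstrap_rem}}.
#' @return data.frame with one row per stratum-by-scenario-by-multiplier:
#'   density point estimate, CI, and \code{percent_rd} vs Baseline.
#' @export
run_scenarios <- function(counts, speeds, r = 0.005, theta = 0.7661,
                          n_iter = 1000, seed = 1,
                          statistic = c("pooled", "mean")) {
  statistic <- match.arg(statistic)
  specs <- rem_scenarios()
  strata <- unique(counts[, c("species", "season", "year_label")])
  out <- list()
  sub_seed <- seed
  for (i in seq_len(nrow(strata))) {
    sp <- strata$species[i]; yl <- strata$year_label[i]
    v_row <- speeds[speeds$species == sp & speeds$year_label == yl, ,
                    drop = FALSE]
    if (nrow(v_row) == 0) {
      warning("no day-range estimate for ", sp, " ", yl,
              "; stratum skipped")
      next
    }
    v0 <- v_row$mean_day_range_km[1]
    cc <- counts[counts$species == sp & counts$year_label == yl, ,
                 drop = FALSE]
    for (j in seq_len(nrow(specs))) {
      subset_cc <- switch(specs$camera_subset[j],
        random = cc[cc$placement == "random", , drop = FALSE],
        strategic = cc[cc$placement == "strategic", , drop = FALSE],
        both = cc)
      sub_seed <- sub_seed + 1L
      if (nrow(subset_cc) == 0) {
        warning("no ", specs$camera_subset[j], " cameras for ", sp, " ",
                yl, "; scenario ", specs$scenario[j], " skipped")
        next
      }
      mult <- specs$velocity_multiplier[j]
      params <- rem_params(v = mult * v0, r = r, theta = theta)
      est <- bootstrap_rem(subset_cc, params, n_iter = n_iter,
                           seed = sub_seed, statistic = statistic)
      out[[length(out) + 1L]] <- cbind(
        data.frame(species = sp, season = strata$season[i],
                   year_label = yl, scenario = specs$scenario[j],
                   camera_subset = specs$camera_subset[j],
                   velocity_multiplier = mult),
        est)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no stratum could be analysed", call. = FALSE)
  # percent relative difference from the Baseline of the same stratum
  res$percent_rd <- NA_real_
  key <- paste(res$species, res$year_label)
  for (kk in unique(key)) {
    rows <- key == kk
    base <- res$point[rows & res$scenario == "Baseline"]
    if (length(base) == 1 && base > 0)
      res$percent_rd[rows] <- percent_rd(res$point[rows], base)
  }
  rownames(res) <- NULL
  res
}
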