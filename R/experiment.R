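#' Run the end-to-end camera-placement experiment from a config
#'
#' Orchestrates the full pipeline: simulate movement over a corridor
#' landscape, deploy random and strategic cameras, simulate photo records,
#' filter them to independent detections, estimate day ranges by
#' continuous-time movement model selection, and fit the REM under the six
#' placement-by-velocity scenarios.  All randomness derives from the single
#' config seed through a per-stage counter (stage i uses seed + i), so
#' stages are individually reproducible and a rerun of the same config is
#' byte-identical.
#'
#' @param config a config list or the path of a YAML file (see the package
#'   vignette for the schema).
#' @param output_dir directory for the CSV/JSON outputs; overrides the
#'   config's \code{output_dir}.
#' @return (invisibly) a list with the main tables: \code{deployments},
#'   \code{counts}, \code{speeds}, \code{densities}, and \code{manifest}.
#' @export
run_experiment <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_experiment_config(config)
  out_dir <- output_dir %||% cfg$output_dir
  if (is.null(out_dir)) stop("no output_dir given", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  stage <- function(i) as.integer(seed + i)

  land <- landscape(extent = as.numeric(unlist(cfg$landscape$extent)),
                    corridors = lapply(cfg$landscape$corridors,
                                       function(m) matrix(unlist(m),
                                                          ncol = 2,
                                                          byrow = TRUE)),
                    attraction_strength = cfg$landscape$attraction_strength,
                    attraction_range = cfg$landscape$attraction_range %||% Inf)
  t0 <- iso_to_epoch(cfg$survey$start)
  t1 <- t0 + cfg$survey$duration_days * 86400
  fine_dt <- cfg$survey$fine_dt %||% 1

  ## stage 1-2: cameras -----------------------------------------------------
  rc <- cfg$cameras$random
  deployments <- NULL
  if (!is.null(rc)) {
    deployments <- place_cameras_random(
      land$extent, n_grids = rc$n_grids %||% 2,
      cameras_per_grid = rc$cameras_per_grid %||% 20,
      cluster_spacing = rc$cluster_spacing %||% 1000,
      within_cluster_spacing = rc$within_cluster_spacing %||% 500,
      active_from = t0, active_to = t1, seed = stage(1))
  }
  sc <- cfg$cameras$strategic
  if (!is.null(sc) && (sc$n_cameras %||% 0) > 0) {
    strat <- place_cameras_strategic(land, n_cameras = sc$n_cameras,
                                     active_from = t0, active_to = t1,
                                     seed = stage(2))
    deployments <- rbind(deployments, strat)
  }
  if (is.null(deployments)) stop("config defines no cameras", call. = FALSE)

  ## stage 3: movement ------------------------------------------------------
  burst <- burst_spec(cfg$burst$photos_per_burst %||% 6,
                      cfg$burst$interburst_interval %||% 60)
  photos <- list(); all_fixes <- list()
  sp_names <- names(cfg$species)
  counter <- 10L
  for (sp in sp_names) {
    spc <- cfg$species[[sp]]
    mv <- spc$movement
    n_ind <- spc$n_individuals %||% 1
    sched <- fix_schedule(t0, t1, spc$fix_interval,
                          spc$fix_dropout %||% 0)
    for (ind in seq_len(n_ind)) {
      counter <- counter + 2L
      set.seed(stage(counter - 1L))
      ctr <- c(stats::runif(1, land$extent[1], land$extent[2]),
               stats::runif(1, land$extent[3], land$extent[4]))
      params <- movement_params(mv$family, sigma_p2 = mv$sigma_p2,
                                tau_p = mv$tau_p, tau_v = mv$tau_v,
                                diffusion = mv$diffusion, center = ctr)
      sim <- if (land$attraction_strength > 0 &&
                   params$family %in% c("IOU", "OUF"))
        sample_biased_track(params, land, duration = t1 - t0,
                            fine_dt = fine_dt, schedule = sched,
                            start_time = t0, seed = stage(counter))
      else
        sample_track(params, duration = t1 - t0, fine_dt = fine_dt,
                     schedule = sched, start_time = t0,
                     seed = stage(counter))
      id <- sprintf("%s_%02d", sp, ind)
      fx <- sim$fixes
      all_fixes[[id]] <- data.frame(individual_id = id, species = sp,
                                    timestamp_utc = fx$time_s,
                                    x_m = fx$x_m, y_m = fx$y_m)
      photos[[id]] <- simulate_photos(sim$path, deployments,
                                      r = cfg$rem$r_m %||% 5,
                                      theta = cfg$rem$theta %||% 0.7661,
                                      burst = burst, species = sp)
    }
  }
  tracks <- do.call(rbind, all_fixes)
  rownames(tracks) <- NULL
  records <- do.call(rbind, photos)
  rownames(records) <- NULL

  ## stage 4: detections ----------------------------------------------------
  records <- standardize_bursts(records, min_interval = 60)
  thr <- vapply(sp_names, function(sp)
    cfg$species[[sp]]$discrimination_threshold %||% 600, numeric(1))
  events <- group_detections(records, threshold = thr)
  efforts <- camera_effort(deployments,
                           utc_offset_hours = cfg$utc_offset_hours %||% -8)
  counts <- count_table(events, efforts, deployments,
                        utc_offset_hours = cfg$utc_offset_hours %||% -8,
                        species = sp_names)

  ## stage 5: day ranges ----------------------------------------------------
  speed_rows <- list()
  for (id in unique(tracks$individual_id)) {
    tr <- tracks[tracks$individual_id == id, , drop = FALSE]
    sp <- tr$species[1]
    role <- cfg$species[[sp]]$role %||% sp
    seas <- split_by_season(tr, cfg$utc_offset_hours %||% -8)
    seas <- filter_min_fixes(seas, role)
    for (lbl in names(seas)) {
      d <- seas[[lbl]]
      fits <- lapply(c("BM", "OU", "IOU", "OUF"), function(f)
        try(fit_ctmm(d, f), silent = TRUE))
      fits <- Filter(function(f) inherits(f, "ctmm_fit"), fits)
      if (length(fits) == 0) next
      sel <- select_model(fits)
      if (!sel$velocity_ok) next
      sl <- season_of(d$timestamp_utc[1], cfg$utc_offset_hours %||% -8)
      sr <- mean_speed(sel$fit, individual_id = id, season = sl$season,
                       year_label = lbl)
      sr$species <- sp
      speed_rows[[length(speed_rows) + 1L]] <- sr
    }
  }
  speed_tbl <- do.call(rbind, speed_rows)
  if (is.null(speed_tbl))
    stop("no season-by-year stratum yielded a velocity-estimable movement ",
         "model; cannot run REM scenarios", call. = FALSE)
  speeds <- do.call(rbind, lapply(split(speed_tbl, speed_tbl$species),
                                  function(d) {
    ag <- aggregate_speeds(d)
    ag$species <- d$species[1]
    ag
  }))
  rownames(speeds) <- NULL

  ## stage 6: REM scenarios -------------------------------------------------
  densities <- run_scenarios(counts, speeds,
                             r = (cfg$rem$r_m %||% 5) / 1000,
                             theta = cfg$rem$theta %||% 0.7661,
                             n_iter = cfg$rem$n_bootstrap %||% 1000,
                             seed = stage(1000))

  ## outputs ----------------------------------------------------------------
  paths <- list(
    deployments = file.path(out_dir, "deployments.csv"),
    tracks = file.path(out_dir, "tracks.csv"),
    events = file.path(out_dir, "events.csv"),
    counts = file.path(out_dir, "counts.csv"),
    speeds = file.path(out_dir, "speeds.csv"),
    densities = file.path(out_dir, "densities.csv")
  )
  utils::write.csv(deployments, paths$deployments, row.names = FALSE)
  write_tracks(tracks, paths$tracks)
  utils::write.csv(events, paths$events, row.names = FALSE)
  utils::write.csv(counts, paths$counts, row.names = FALSE)
  utils::write.csv(speeds, paths$speeds, row.names = FALSE)
  utils::write.csv(densities, paths$densities, row.names = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package = "remeval",
    version = as.character(utils::packageVersion("remeval")),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = lapply(paths, basename)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(deployments = deployments, tracks = tracks,
                 events = events, counts = counts, speeds = speeds,
                 densities = densities, manifest = manifest))
}

validate_experiment_config <- function(cfg) {
  for (f in c("seed", "landscape", "species", "survey"))
    if (is.null(cfg[[f]]))
      stop("experiment config missing field '", f, "'", call. = FALSE)
  stopifnot(is.numeric(cfg$seed), length(cfg$landscape$extent) == 4)
  if (length(cfg$species) == 0)
    stop("config must define at least one species", call. = FALSE)
  for (sp in names(cfg$species)) {
    spc <- cfg$species[[sp]]
    if (is.null(spc$movement) || is.null(spc$movement$family))
      stop("species '", sp, "' has no movement parameters", call. = FALSE)
    if (is.null(spc$fix_interval))
      stop("species '", sp, "' has no fix_interval", call. = FALSE)
  }
  if (is.null(cfg$survey$start) || is.null(cfg$survey$duration_days))
    stop("survey needs 'start' and 'duration_days'", call. = FALSE)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
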