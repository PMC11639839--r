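# Shared fixtures and independent oracles used across test files.

# Brute-force detection grouping: connected components of the graph joining
# records whose gap is <= threshold (transitive chaining), per camera x
# species.  Independent of the sequential implementation.
oracle_group_events <- function(records, threshold) {
  grp <- interaction(records$camera_id, records$species, drop = TRUE)
  pieces <- lapply(split(records, grp), function(d) {
    ts <- sort(d$timestamp_utc)
    n <- length(ts)
    adj <- abs(outer(ts, ts, "-")) <= threshold
    comp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        nb <- which(adj[i, ])
        newc <- min(comp[nb])
        if (newc < comp[i]) {
          comp[comp == comp[i]] <- newc
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    data.frame(camera_id = d$camera_id[1], species = d$species[1],
               start_timestamp = as.numeric(tapply(ts, comp, min)),
               n_photos_merged = as.integer(tapply(ts, comp, length)))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$camera_id, out$species, out$start_timestamp), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Direct grid-search Poisson maximum likelihood for count ~ exp(b0 + b1 * x),
# refined over three zoom stages.
oracle_poisson_ml <- function(x, y, b0_range = c(-5, 5),
                              b1_range = c(-2, 2)) {
  ll <- function(b0, b1) {
    mu <- exp(b0 + b1 * x)
    sum(stats::dpois(y, mu, log = TRUE))
  }
  for (stage in 1:6) {
    b0s <- seq(b0_range[1], b0_range[2], length.out = 61)
    b1s <- seq(b1_range[1], b1_range[2], length.out = 61)
    grid <- expand.grid(b0 = b0s, b1 = b1s)
    vals <- mapply(ll, grid$b0, grid$b1)
    best <- grid[which.max(vals), ]
    w0 <- diff(b0_range) / 20; w1 <- diff(b1_range) / 20
    b0_range <- c(best$b0 - w0, best$b0 + w0)
    b1_range <- c(best$b1 - w1, best$b1 + w1)
  }
  c(b0 = best$b0, b1 = best$b1)
}

# Ideal-gas arena replicate: ballistic movers with Poisson turning in a
# reflecting box, counts of sector entries per camera.  Returns a per-camera
# (y, t) table; the true density is n_animals / arena area.
ideal_gas_counts <- function(rep_seed, n_animals = 50, n_cameras = 30,
                             arena = c(0, 1000, 0, 1000), speed = 1,
                             r = 20, theta = 0.7661, duration = 2.5 * 3600,
                             fine_dt = 0.5, turn_rate = 1 / 250) {
  set.seed(rep_seed)
  cams <- data.frame(
    camera_id = sprintf("C%02d", seq_len(n_cameras)),
    x_m = stats::runif(n_cameras, arena[1] + 30, arena[2] - 30),
    y_m = stats::runif(n_cameras, arena[3] + 30, arena[4] - 30),
    placement = "random",
    heading_rad = stats::runif(n_cameras, 0, 2 * pi),
    active_from = 0, active_to = duration)
  y <- integer(n_cameras)
  for (a in seq_len(n_animals)) {
    s <- sample_ballistic_track(speed, arena, duration, fine_dt = fine_dt,
                                turn_rate = turn_rate,
                                seed = rep_seed * 1000 + a)
    rec <- simulate_photos(s$path, cams, r = r, theta = theta,
                           burst = burst_spec(1, 1e9), species = "x")
    if (nrow(rec) > 0) {
      tab <- table(rec$camera_id)
      i <- match(names(tab), cams$camera_id)
      y[i] <- y[i] + as.integer(tab)
    }
  }
  data.frame(y = y, t = duration / 86400)
}

# Corridor-attraction replicate: one prey-like OUF population over a
# two-corridor landscape, detections split by camera placement.
strategic_replicate <- function(rep_seed, attraction = 0.002,
                                n_animals = 6, duration = 24 * 3600,
                                r = 25) {
  ext <- c(0, 3000, 0, 3000)
  corr <- list(rbind(c(200, 500), c(2800, 900)),
               rbind(c(500, 2800), c(1500, 1500), c(2800, 2500)))
  land <- landscape(ext, corr, attraction_strength = attraction,
                    attraction_range = 1000)
  set.seed(rep_seed)
  n_r <- 12L
  rnd <- data.frame(camera_id = sprintf("R%02d", seq_len(n_r)),
                    x_m = stats::runif(n_r, 100, 2900),
                    y_m = stats::runif(n_r, 100, 2900),
                    placement = "random",
                    heading_rad = stats::runif(n_r, 0, 2 * pi),
                    active_from = 0, active_to = duration)
  str <- place_cameras_strategic(land, n_cameras = 12, active_from = 0,
                                 active_to = duration,
                                 seed = rep_seed + 5000)
  cams <- rbind(rnd, str)
  recs <- list()
  for (a in seq_len(n_animals)) {
    ctr <- c(stats::runif(1, 500, 2500), stats::runif(1, 500, 2500))
    p <- movement_params("OUF", sigma_p2 = 4e5, tau_p = 2e4, tau_v = 600,
                         center = ctr)
    s <- sample_biased_track(p, land, duration = duration, fine_dt = 10,
                             seed = rep_seed * 100 + a)
    recs[[a]] <- simulate_photos(s$path, cams, r = r, theta = 0.7661,
                                 burst = burst_spec(1, 1e9),
                                 species = "prey")
  }
  recs <- do.call(rbind, recs)
  t_each <- duration / 86400
  list(
    y_random = sum(recs$camera_id %in% rnd$camera_id),
    y_strategic = sum(recs$camera_id %in% str$camera_id),
    t_random = n_r * t_each,
    t_strategic = 12 * t_each
  )
}

# timestamps: local study time (UTC-8) to UTC epoch seconds
local_epoch <- function(y, m, d, h = 0, mi = 0, s = 0,
                        utc_offset_hours = -8) {
  as.numeric(ISOdatetime(y, m, d, h, mi, s, tz = "UTC")) -
    utc_offset_hours * 3600
}
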