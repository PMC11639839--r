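#' Simulation landscape with travel corridors
#'
#' A rectangular arena plus an optional set of polyline corridors toward which
#' biased movement drifts (desert washes used as travel routes, say).
#'
#' @param extent numeric length 4: \code{c(xmin, xmax, ymin, ymax)} (m).
#' @param corridors list of two-column matrices; each matrix is the vertex
#'   sequence of one corridor polyline (m).  All vertices must lie inside
#'   \code{extent}.
#' @param attraction_strength drift coefficient toward the nearest corridor
#'   point (1/s); 0 recovers spatially unbiased movement.
#' @param attraction_range distance (m) beyond which the attraction is zero.
#' @return a \code{landscape} object.
#' @export
landscape <- function(extent, corridors = list(), attraction_strength = 0,
                      attraction_range = Inf) {
  stopifnot(is.numeric(extent), length(extent) == 4,
            extent[2] > extent[1], extent[4] > extent[3],
            attraction_strength >= 0, attraction_range > 0)
  corridors <- lapply(corridors, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 2, nrow(m) >= 2)
    if (any(m[, 1] < extent[1] | m[, 1] > extent[2] |
            m[, 2] < extent[3] | m[, 2] > extent[4]))
      stop("corridor vertices must lie within the extent", call. = FALSE)
    unname(m)
  })
  structure(list(extent = as.numeric(extent), corridors = corridors,
                 attraction_strength = attraction_strength,
                 attraction_range = attraction_range),
            class = "landscape")
}

# corridor polylines flattened to segment arrays for fast nearest-point search
corridor_segments <- function(land) {
  segs <- do.call(rbind, lapply(land$corridors, function(m) {
    n <- nrow(m)
    cbind(m[-n, 1], m[-n, 2], m[-1, 1], m[-1, 2])
  }))
  if (is.null(segs)) segs <- matrix(numeric(0), 0, 4)
  segs
}

# For points (x, y) return nearest point on any segment and its distance.
# x, y vectors; segs as from corridor_segments().
nearest_on_corridor <- function(x, y, segs) {
  n <- length(x)
  if (nrow(segs) == 0)
    return(list(px = rep(NA_real_, n), py = rep(NA_real_, n),
                dist = rep(Inf, n)))
  best_d2 <- rep(Inf, n); px <- numeric(n); py <- numeric(n)
  for (i in seq_len(nrow(segs))) {
    ax <- segs[i, 1]; ay <- segs[i, 2]
    dx <- segs[i, 3] - ax; dy <- segs[i, 4] - ay
    L2 <- dx * dx + dy * dy
    t <- if (L2 > 0) pmin(1, pmax(0, ((x - ax) * dx + (y - ay) * dy) / L2)) else 0
    qx <- ax + t * dx; qy <- ay + t * dy
    d2 <- (x - qx)^2 + (y - qy)^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]; px[upd] <- qx[upd]; py[upd] <- qy[upd]
  }
  list(px = px, py = py, dist = sqrt(best_d2))
}

#' Distance from points to the nearest corridor
#'
#' @param land a \code{\link{landscape}}.
#' @param x,y point coordinates (m).
#' @return vector of distances (m); \code{Inf} when the landscape has no
#'   corridors.
#' @export
corridor_distance <- function(land, x, y) {
  nearest_on_corridor(x, y, corridor_segments(land))$dist
}

# One axis of an exact stationary/conditional sample on a regular fine grid.
# Returns n x d matrix of states.  Uses the eigen-decoupled AR(1) recursion so
# the loop runs in C (stats::filter).
sample_axis_exact <- function(params, n, dt, x0 = NULL) {
  tr <- ctmm_transition(params, dt)
  fam <- params$family
  if (fam == "BM") {
    inc <- stats::rnorm(n - 1, 0, sqrt(2 * params$diffusion * dt))
    return(matrix(cumsum(c(x0, inc)), ncol = 1))
  }
  if (fam == "OU") {
    phi <- tr$Phi[1, 1]
    e <- stats::rnorm(n - 1, 0, sqrt(tr$Q[1, 1]))
    z0 <- if (is.null(x0)) stats::rnorm(1, 0, sqrt(params$sigma_p2)) else x0
    z <- c(z0, as.numeric(stats::filter(e, phi, method = "recursive",
                                        init = z0)))
    return(matrix(z, ncol = 1))
  }
  # 2-state families: decouple through the eigenbasis of the drift matrix
  if (fam == "IOU") {
    lam <- c(0, 1 / params$tau_v)
    V <- matrix(c(1, 0, 1, -1 / params$tau_v), 2, 2)
    z0 <- c(if (is.null(x0)) 0 else x0,
            stats::rnorm(1, 0, sqrt(params$diffusion / params$tau_v)))
  } else { # OUF
    lam <- c(1 / params$tau_p, 1 / params$tau_v)
    V <- matrix(c(1, -lam[1], 1, -lam[2]), 2, 2)
    z0 <- as.numeric(chol_sqrt(tr$Sinf) %*% stats::rnorm(2))
  }
  Vinv <- solve(V)
  phis <- exp(-lam * dt)
  Qw <- Vinv %*% tr$Q %*% t(Vinv)
  Lw <- chol_sqrt(Qw)
  eta <- matrix(stats::rnorm(2 * (n - 1)), ncol = 2) %*% t(Lw)
  w0 <- as.numeric(Vinv %*% z0)
  w <- matrix(0, n, 2)
  for (j in 1:2) {
    wj <- as.numeric(stats::filter(eta[, j], phis[j], method = "recursive",
                                   init = w0[j]))
    w[, j] <- c(w0[j], wj)
  }
  w %*% t(V) # states (x, v) by row
}

# lower-triangular square root tolerant of zero eigenvalues
chol_sqrt <- function(S) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S)) %*% t(ev$vectors)
}

#' Simulate a movement track by exact Gaussian transition sampling
#'
#' Samples one individual's latent fine-scale path on a regular grid using the
#' family's exact discrete-time Gaussian transition (no Euler discretisation
#' bias), then optionally subsamples GPS fixes on a coarser schedule.
#' Stationary families (OU, OUF) are initialised from their stationary
#' distribution; the nonstationary BM and IOU families start from
#' \code{params$center} and reject a stationary initialisation request.
#'
#' @param params a \code{\link{movement_params}}.
#' @param duration length of the simulated path (s).
#' @param fine_dt fine grid spacing (s); must be <= 10.
#' @param schedule optional \code{\link{fix_schedule}} used to subsample fixes.
#' @param init \code{"stationary"} (OU/OUF default) or \code{"point"}
#'   (start at \code{center}; required for BM/IOU).
#' @param start_time timestamp (UTC s) of the first path point.
#' @param seed optional integer seed; identical seeds give identical tracks.
#' @return list with elements \code{path} (data.frame \code{time_s, x_m, y_m}
#'   on the fine grid) and \code{fixes} (same columns, subsampled per
#'   \code{schedule}; equal to \code{path} when \code{schedule} is NULL).
#' @export
sample_track <- function(params, duration, fine_dt = 1, schedule = NULL,
                         init = NULL, start_time = 0, seed = NULL) {
  stopifnot(inherits(params, "movement_params"), duration > 0,
            fine_dt > 0, fine_dt <= 10)
  nonstat <- params$family %in% c("BM", "IOU")
  if (is.null(init)) init <- if (nonstat) "point" else "stationary"
  init <- match.arg(init, c("stationary", "point"))
  if (nonstat && init == "stationary")
    stop(params$family,
         " has no stationary distribution; use init = \"point\"",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration / fine_dt) + 1
  x0 <- if (init == "point") params$center else NULL
  sx <- sample_axis_exact(params, n, fine_dt,
                          x0 = if (is.null(x0)) NULL else 0)
  sy <- sample_axis_exact(params, n, fine_dt,
                          x0 = if (is.null(x0)) NULL else 0)
  path <- data.frame(
    time_s = start_time + (seq_len(n) - 1) * fine_dt,
    x_m = params$center[1] + sx[, 1],
    y_m = params$center[2] + sy[, 1]
  )
  fixes <- if (is.null(schedule)) path else subsample_fixes(path, schedule)
  list(path = path, fixes = fixes)
}

#' Subsample a fine path on a GPS fix schedule
#'
#' Keeps the fine-path point nearest to each scheduled fix time (within half a
#' fine step) and applies independent fix dropout.
#'
#' @param path data.frame \code{time_s, x_m, y_m}.
#' @param schedule a \code{\link{fix_schedule}}.
#' @return data.frame of retained fixes.
#' @export
subsample_fixes <- function(path, schedule) {
  stopifnot(inherits(schedule, "fix_schedule"))
  times <- seq(schedule$start, schedule$end, by = schedule$interval)
  times <- times[times >= path$time_s[1] & times <= path$time_s[nrow(path)]]
  idx <- findInterval(times + 1e-9, path$time_s)
  keep <- abs(path$time_s[idx] - times) <= (path$time_s[2] - path$time_s[1]) / 2 + 1e-9
  idx <- unique(idx[keep])
  out <- path[idx, , drop = FALSE]
  if (schedule$dropout_prob > 0) {
    out <- out[stats::runif(nrow(out)) >= schedule$dropout_prob, ,
               drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Simulate a corridor-biased movement track
#'
#' Euler-Maruyama integration of the movement model's stochastic differential
#' form with an added acceleration toward the nearest corridor point:
#' within \code{attraction_range} of a corridor the velocity equation gains a
#' drift \code{attraction_strength * sigma_v} (m/s^2) pointing at the nearest
#' corridor point, where \code{sigma_v} is the model's per-axis stationary
#' velocity scale.  With \code{attraction_strength = 0} the integrator targets
#' the same law as \code{\link{sample_track}} (up to Euler discretisation
#' error).  Only the correlated-velocity families (IOU, OUF) are supported,
#' since the drift acts on velocity.
#'
#' @inheritParams sample_track
#' @param land a \code{\link{landscape}}.
#' @return as \code{\link{sample_track}}.
#' @export
sample_biased_track <- function(params, land, duration, fine_dt = 1,
                                schedule = NULL, start_time = 0, seed = NULL) {
  stopifnot(inherits(params, "movement_params"), inherits(land, "landscape"),
            duration > 0, fine_dt > 0)
  if (!params$family %in% c("IOU", "OUF"))
    stop("corridor-biased simulation requires a correlated-velocity family ",
         "(IOU or OUF)", call. = FALSE)
  if (fine_dt > params$tau_v / 10)
    stop("fine_dt > tau_v/10: Euler step too coarse for the velocity ",
         "autocorrelation timescale", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration / fine_dt) + 1
  segs <- corridor_segments(land)
  a <- land$attraction_strength
  rng <- land$attraction_range

  if (params$family == "OUF") {
    g <- 1 / params$tau_p + 1 / params$tau_v
    k <- 1 / (params$tau_p * params$tau_v)
    sv2 <- params$sigma_p2 * k
  } else {
    g <- 1 / params$tau_v
    k <- 0
    sv2 <- params$diffusion / params$tau_v
  }
  b <- sqrt(2 * g * sv2)       # continuous-time velocity noise intensity
  sv <- sqrt(sv2)
  x <- numeric(n); y <- numeric(n)
  if (params$family == "OUF") {
    x[1] <- stats::rnorm(1, params$center[1], sqrt(params$sigma_p2))
    y[1] <- stats::rnorm(1, params$center[2], sqrt(params$sigma_p2))
  } else {
    x[1] <- params$center[1]; y[1] <- params$center[2]
  }
  vx <- stats::rnorm(1, 0, sv); vy <- stats::rnorm(1, 0, sv)
  sq <- sqrt(fine_dt)
  ex <- stats::rnorm(n - 1); ey <- stats::rnorm(n - 1)
  for (i in 2:n) {
    ax_drift <- 0; ay_drift <- 0
    if (a > 0 && nrow(segs) > 0) {
      np <- nearest_on_corridor(x[i - 1], y[i - 1], segs)
      if (np$dist <= rng && np$dist > 1e-9) {
        ax_drift <- a * sv * (np$px - x[i - 1]) / np$dist
        ay_drift <- a * sv * (np$py - y[i - 1]) / np$dist
      }
    }
    vx <- vx + fine_dt * (-g * vx - k * (x[i - 1] - params$center[1]) +
                            ax_drift) + b * sq * ex[i - 1]
    vy <- vy + fine_dt * (-g * vy - k * (y[i - 1] - params$center[2]) +
                            ay_drift) + b * sq * ey[i - 1]
    x[i] <- x[i - 1] + fine_dt * vx
    y[i] <- y[i - 1] + fine_dt * vy
  }
  path <- data.frame(time_s = start_time + (seq_len(n) - 1) * fine_dt,
                     x_m = x, y_m = y)
  fixes <- if (is.null(schedule)) path else subsample_fixes(path, schedule)
  list(path = path, fixes = fixes)
}

#' Simulate an ideal-gas (ballistic) mover in a reflecting box
#'
#' Constant scalar speed, uniformly random initial position and heading, and
#' specular reflection at the box walls: the stationary position distribution
#' is uniform over the box and the direction distribution uniform on the
#' circle, i.e. exactly the ideal-gas movement regime the random encounter
#' model assumes.  Used to validate the encounter-rate formula and the REM
#' estimator against a known true density.
#'
#' @param speed scalar speed (m/s).
#' @param extent box \code{c(xmin, xmax, ymin, ymax)} (m).
#' @param turn_rate rate (1/s) of direction redraws: headings are resampled
#'   uniformly at Poisson times, keeping speed constant.  0 (default) gives a
#'   purely ballistic mover; either way the stationary position distribution
#'   is uniform and direction uniform, so the ideal-gas encounter rate is
#'   unchanged.
#' @inheritParams sample_track
#' @return as \code{\link{sample_track}}.
#' @export
sample_ballistic_track <- function(speed, extent, duration, fine_dt = 1,
                                   schedule = NULL, start_time = 0,
                                   turn_rate = 0, seed = NULL) {
  stopifnot(speed > 0, length(extent) == 4, duration > 0, fine_dt > 0,
            turn_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration / fine_dt) + 1
  Lx <- extent[2] - extent[1]; Ly <- extent[4] - extent[3]
  x0 <- stats::runif(1, 0, Lx); y0 <- stats::runif(1, 0, Ly)
  tt <- (seq_len(n) - 1) * fine_dt
  if (turn_rate == 0) {
    th <- stats::runif(1, 0, 2 * pi)
    ux <- x0 + speed * cos(th) * tt
    uy <- y0 + speed * sin(th) * tt
  } else {
    # piecewise-ballistic: exponential leg durations, uniform headings
    n_legs <- max(10, ceiling(2 * duration * turn_rate) + 10)
    repeat {
      legs <- stats::rexp(n_legs, turn_rate)
      if (sum(legs) > duration) break
      n_legs <- n_legs * 2
    }
    bounds <- c(0, cumsum(legs))
    th <- stats::runif(length(legs), 0, 2 * pi)
    leg_i <- findInterval(tt, bounds, rightmost.closed = TRUE)
    # displacement accumulated at each leg boundary
    leg_dt <- diff(bounds)
    cx <- c(0, cumsum(speed * cos(th) * leg_dt))
    cy <- c(0, cumsum(speed * sin(th) * leg_dt))
    ux <- x0 + cx[leg_i] + speed * cos(th[leg_i]) * (tt - bounds[leg_i])
    uy <- y0 + cy[leg_i] + speed * sin(th[leg_i]) * (tt - bounds[leg_i])
  }
  # fold the unreflected line back into the box (specular reflection)
  fold <- function(u, L) {
    u <- u %% (2 * L)
    ifelse(u > L, 2 * L - u, u)
  }
  path <- data.frame(
    time_s = start_time + tt,
    x_m = extent[1] + fold(ux, Lx),
    y_m = extent[3] + fold(uy, Ly)
  )
  fixes <- if (is.null(schedule)) path else subsample_fixes(path, schedule)
  list(path = path, fixes = fixes)
}
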