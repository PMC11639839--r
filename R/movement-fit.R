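#' Thin a track to a target fix interval
#'
#' Greedy forward pass: the first fix is kept, then every subsequent fix whose
#' gap from the last kept fix is at least \code{target_interval - tolerance}.
#' Output gaps are therefore never smaller than that bound; already-regular
#' data at the target interval pass through unchanged.
#'
#' @param track data.frame with a \code{timestamp_utc} column (UTC s),
#'   sorted in time.
#' @param target_interval desired fix spacing (s).
#' @param tolerance slack (s) subtracted from the target when testing gaps.
#' @return the thinned track.
#' @export
thin_track <- function(track, target_interval, tolerance = 0) {
  stopifnot(target_interval > 0, tolerance >= 0)
  ts <- track$timestamp_utc
  stopifnot(!is.unsorted(ts, strictly = TRUE))
  keep <- logical(length(ts))
  last <- -Inf
  bound <- target_interval - tolerance
  for (i in seq_along(ts)) {
    if (ts[i] - last >= bound) {
      keep[i] <- TRUE
      last <- ts[i]
    }
  }
  out <- track[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimum seasonal fix-count filter
#'
#' Season-by-year tracks are retained only when they carry at least the
#' species-role minimum number of locations: 200 for the predator
#' ("predator"/"coyote") and 100 for the prey ("prey"/"jackrabbit"), both
#' inclusive.
#'
#' @param tracks named list of season-by-year tracks (as from
#'   \code{\link{split_by_season}}).
#' @param species species or role label.
#' @return the retained sub-list; dropped strata are reported via
#'   \code{message()}.
#' @export
filter_min_fixes <- function(tracks, species) {
  thr <- min_fix_threshold(species)
  n <- vapply(tracks, nrow, integer(1))
  drop <- n < thr
  for (nm in names(tracks)[drop])
    message(sprintf("dropping %s: %d fixes < minimum %d", nm,
                    n[[nm]], thr))
  tracks[!drop]
}

min_fix_threshold <- function(species) {
  key <- tolower(species)
  if (key %in% c("predator", "coyote")) return(200L)
  if (key %in% c("prey", "jackrabbit")) return(100L)
  stop("unknown species role '", species,
       "'; expected predator/coyote or prey/jackrabbit", call. = FALSE)
}

#' Empirical semivariance of a movement track
#'
#' The semivariance at lag bin \eqn{\tau} is the mean over all fix pairs in
#' the bin of \eqn{\|\Delta r\|^2 / 4}: the per-axis average of half the
#' squared displacement.  Mixed sampling rates are handled by caller-supplied
#' bin breaks.
#'
#' @param track data.frame with \code{timestamp_utc}, \code{x_m}, \code{y_m}.
#' @param bin_width scalar lag bin width (s); default is the median fix
#'   interval.
#' @param breaks optional vector of lag-bin breakpoints (s) overriding
#'   \code{bin_width}; use it to aggregate mixed fix rates.
#' @param max_lag optional largest lag (s) considered.
#' @return data.frame of class \code{variogram}: \code{lag} (bin centre, s),
#'   \code{semivariance} (m^2), \code{n_pairs}, \code{bin_width}.
#' @export
empirical_variogram <- function(track, bin_width = NULL, breaks = NULL,
                                max_lag = NULL) {
  ts <- track$timestamp_utc
  stopifnot(length(ts) >= 2)
  n <- length(ts)
  ij <- utils::combn(n, 2L)
  lag <- ts[ij[2, ]] - ts[ij[1, ]]
  sq <- ((track$x_m[ij[2, ]] - track$x_m[ij[1, ]])^2 +
           (track$y_m[ij[2, ]] - track$y_m[ij[1, ]])^2) / 4
  if (!is.null(max_lag)) {
    keep <- lag <= max_lag
    lag <- lag[keep]; sq <- sq[keep]
  }
  if (is.null(breaks)) {
    if (is.null(bin_width)) bin_width <- stats::median(diff(ts))
    breaks <- seq(0, max(lag) + bin_width, by = bin_width)
  }
  bin <- cut(lag, breaks, include.lowest = TRUE)
  sv <- tapply(sq, bin, mean)
  np <- tapply(sq, bin, length)
  keep <- !is.na(sv)
  out <- data.frame(
    lag = (breaks[-length(breaks)] + diff(breaks) / 2)[keep],
    semivariance = as.numeric(sv[keep]),
    n_pairs = as.integer(np[keep]),
    bin_width = diff(breaks)[keep]
  )
  class(out) <- c("variogram", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Exact Gaussian likelihood via Kalman filtering
#
# All families are evaluated conditional on the first fix so that AICc is
# comparable between the stationary (OU, OUF) and nonstationary (BM, IOU)
# families.  The overall variance parameter (sigma_p2 for OU/OUF, the
# velocity variance for IOU, the diffusion for BM) and the home-range centre
# (OU/OUF) are profiled out in closed form; optimisation is only over the
# log timescales.
# ---------------------------------------------------------------------------

# Unit-variance profile likelihood for OU/OUF/IOU, conditional on the first
# fix.  Positions are observed without error, so after every update the
# position state is known exactly: the filter reduces to an AR(1) innovation
# form for OU and to a scalar recursion over the latent velocity for the
# 2-state families.  Returns -2 log L (profiled) plus the profiled sigma2
# and centre.
kalman_profile <- function(tvec, xy, family, tau_p = NULL, tau_v = NULL) {
  n <- length(tvec)
  dts <- diff(tvec)
  use_mean <- family %in% c("OU", "OUF")
  n_eff <- n - 1L

  if (family == "OU") {
    # exact AR(1) innovations: e_t = z_t - phi_t z_{t-1}, F_t = 1 - phi_t^2
    phi <- exp(-dts / tau_p)
    Fv <- 1 - phi^2
    if (any(Fv <= 0)) return(list(n2ll = Inf))
    E <- cbind(xy[-1, 1] - phi * xy[-n, 1],
               xy[-1, 2] - phi * xy[-n, 2],
               1 - phi)
  } else {
    params <- if (family == "OUF")
      list(family = "OUF", sigma_p2 = 1, tau_p = tau_p, tau_v = tau_v)
    else list(family = "IOU", diffusion = tau_v, tau_v = tau_v) # sv2 = 1
    ud <- unique(dts)
    trs <- lapply(ud, function(dd) ctmm_transition(params, dd))
    tridx <- match(dts, ud)
    nz <- if (use_mean) 3L else 2L
    Z <- cbind(xy, if (use_mean) rep(1, n))
    # state after conditioning on the first fix: position known exactly,
    # velocity at its prior mean with variance v0
    m1 <- Z[1, ]
    m2 <- rep(0, nz)
    p22 <- if (family == "OUF") 1 / (tau_p * tau_v) else 1
    E <- matrix(0, n_eff, nz)
    Fv <- numeric(n_eff)
    for (t in 2:n) {
      tr <- trs[[tridx[t - 1L]]]
      f11 <- tr$Phi[1, 1]; f12 <- tr$Phi[1, 2]
      f21 <- tr$Phi[2, 1]; f22 <- tr$Phi[2, 2]
      a1 <- f11 * m1 + f12 * m2
      a2 <- f21 * m1 + f22 * m2
      p11 <- f12 * f12 * p22 + tr$Q[1, 1]
      p12 <- f12 * f22 * p22 + tr$Q[1, 2]
      p22n <- f22 * f22 * p22 + tr$Q[2, 2]
      if (!is.finite(p11) || p11 <= 0) return(list(n2ll = Inf))
      e <- Z[t, ] - a1
      E[t - 1L, ] <- e
      Fv[t - 1L] <- p11
      g <- p12 / p11
      m1 <- Z[t, ]
      m2 <- a2 + g * e
      p22 <- p22n - p12 * g
    }
  }
  mu <- c(NA_real_, NA_real_)
  if (use_mean) {
    rc <- E[, 3]
    wr <- sum(rc^2 / Fv)
    resid2 <- 0
    for (ax in 1:2) {
      mu[ax] <- if (wr > 0) sum(E[, ax] * rc / Fv) / wr else 0
      resid2 <- resid2 + sum((E[, ax] - mu[ax] * rc)^2 / Fv)
    }
  } else {
    resid2 <- sum(E[, 1]^2 / Fv) + sum(E[, 2]^2 / Fv)
  }
  sigma2 <- resid2 / (2 * n_eff)
  if (!is.finite(sigma2) || sigma2 <= 0) return(list(n2ll = Inf))
  n2ll <- 2 * sum(log(Fv)) + 2 * n_eff * log(sigma2) +
    2 * n_eff * (1 + log(2 * pi))
  list(n2ll = n2ll, sigma2 = sigma2, mu = mu, n_eff = n_eff)
}

# closed-form BM fit conditional on the first fix
fit_bm <- function(tvec, xy) {
  dts <- diff(tvec)
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  N <- length(dts)
  D <- sum(dx^2 / (2 * dts) + dy^2 / (2 * dts)) / (2 * N)
  ll <- -0.5 * (sum(log(2 * pi * 2 * D * dts)) * 2 +
                  sum(dx^2 / (2 * D * dts)) + sum(dy^2 / (2 * D * dts)))
  list(diffusion = D, log_lik = ll)
}

#' Fit a continuous-time movement model to a track
#'
#' Maximises the exact Gaussian likelihood of the position series (both axes
#' independent with shared parameters, evaluated by Kalman filtering,
#' conditional on the first fix).  The overall variance and the home-range
#' centre are profiled out; the remaining log-timescales are optimised by
#' quasi-Newton iteration from multiple log-spaced starting points spanning
#' roughly [fix interval / 10, track duration].
#'
#' @param track data.frame with \code{timestamp_utc} (strictly increasing),
#'   \code{x_m}, \code{y_m}.
#' @param family "BM", "OU", "IOU" or "OUF".
#' @param n_starts number of multi-start points for the timescale search.
#' @return an object of class \code{ctmm_fit}: fields \code{family},
#'   \code{params} (a \code{\link{movement_params}}), \code{log_lik},
#'   \code{k}, \code{n}, \code{aicc}, \code{converged}.
#' @export
fit_ctmm <- function(track, family = c("BM", "OU", "IOU", "OUF"),
                     n_starts = 8) {
  family <- match.arg(family)
  tvec <- track$timestamp_utc
  stopifnot(!is.unsorted(tvec, strictly = TRUE))
  xy <- cbind(track$x_m, track$y_m)
  stopifnot(all(is.finite(xy)))
  n <- length(tvec)
  k <- c(BM = 1L, OU = 4L, IOU = 2L, OUF = 5L)[[family]]
  if (n < k + 2) stop("too few fixes (", n, ") to fit ", family,
                      call. = FALSE)

  if (family == "BM") {
    f <- fit_bm(tvec, xy)
    params <- movement_params("BM", diffusion = f$diffusion)
    return(new_ctmm_fit(family, params, f$log_lik, k, n, TRUE))
  }

  dt_med <- stats::median(diff(tvec))
  span <- tvec[n] - tvec[1]
  lo <- log(dt_med / 20); hi <- log(20 * span)
  starts1 <- seq(log(dt_med / 10), log(span), length.out = n_starts)

  best <- NULL
  if (family %in% c("OU", "IOU")) {
    obj <- function(u) {
      tau <- exp(u)
      r <- if (family == "OU")
        kalman_profile(tvec, xy, "OU", tau_p = tau)
      else kalman_profile(tvec, xy, "IOU", tau_v = tau)
      if (!is.finite(r$n2ll)) 1e12 else r$n2ll
    }
    for (s in starts1) {
      o <- try(stats::optim(s, obj, method = "L-BFGS-B", lower = lo,
                            upper = hi), silent = TRUE)
      if (inherits(o, "try-error")) next
      if (is.null(best) || o$value < best$value) best <- o
    }
    if (is.null(best)) return(new_ctmm_fit(family, NULL, NA, k, n, FALSE))
    tau <- exp(best$par)
    r <- if (family == "OU") kalman_profile(tvec, xy, "OU", tau_p = tau)
    else kalman_profile(tvec, xy, "IOU", tau_v = tau)
    params <- if (family == "OU")
      movement_params("OU", sigma_p2 = r$sigma2, tau_p = tau,
                      center = r$mu)
    else movement_params("IOU", diffusion = r$sigma2 * tau, tau_v = tau)
    return(new_ctmm_fit(family, params, -best$value / 2, k, n, TRUE))
  }

  # OUF: optimise (log tau_v, log(tau_p - tau_v)) so tau_p > tau_v always
  obj <- function(par) {
    tv <- exp(par[1]); tp <- tv + exp(par[2])
    r <- kalman_profile(tvec, xy, "OUF", tau_p = tp, tau_v = tv)
    if (!is.finite(r$n2ll)) 1e12 else r$n2ll
  }
  qs <- seq(0.15, 0.85, length.out = n_starts)
  starts <- cbind(stats::quantile(starts1, qs),
                  rev(stats::quantile(starts1, qs)))
  for (i in seq_len(nrow(starts))) {
    o <- try(stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                          lower = c(lo, lo), upper = c(hi, hi)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) return(new_ctmm_fit(family, NULL, NA, k, n, FALSE))
  tv <- exp(best$par[1]); tp <- tv + exp(best$par[2])
  r <- kalman_profile(tvec, xy, "OUF", tau_p = tp, tau_v = tv)
  params <- movement_params("OUF", sigma_p2 = r$sigma2, tau_p = tp,
                            tau_v = tv, center = r$mu)
  new_ctmm_fit(family, params, -best$value / 2, k, n, TRUE)
}

new_ctmm_fit <- function(family, params, log_lik, k, n, converged) {
  structure(list(family = family, params = params, log_lik = log_lik,
                 k = k, n = n, aicc = aicc(log_lik, k, n),
                 converged = converged),
            class = "ctmm_fit")
}

#' @export
print.ctmm_fit <- function(x, ...) {
  cat("<ctmm_fit>", x$family,
      if (!x$converged) "(NOT CONVERGED)" else "", "\n")
  cat(sprintf("  logLik = %.3f  k = %d  n = %d  AICc = %.3f\n",
              x$log_lik, x$k, x$n, x$aicc))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Small-sample-corrected Akaike information criterion
#'
#' \code{AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)}.
#'
#' @param log_lik maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size.
#' @export
aicc <- function(log_lik, k, n) {
  if (is.na(log_lik)) return(NA_real_)
  if (n - k - 1 <= 0) return(Inf)
  -2 * log_lik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Select the best movement model by AICc
#'
#' Non-converged fits are excluded (with a warning).  Ties are broken toward
#' the family with fewer parameters.  Velocity (day range) is estimable only
#' when the winning family carries autocorrelated velocity (IOU or OUF);
#' a winning OU or BM fit means the fix rate was too coarse.
#'
#' @param fits list of \code{ctmm_fit} objects.
#' @return list with \code{fit} (the winner) and \code{velocity_ok}
#'   (logical).
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1)
  conv <- Filter(function(f) isTRUE(f$converged) && is.finite(f$aicc), fits)
  if (length(conv) < length(fits))
    warning(length(fits) - length(conv),
            " non-converged fit(s) excluded from model selection")
  if (length(conv) == 0) stop("no converged movement-model fits",
                              call. = FALSE)
  a <- vapply(conv, function(f) f$aicc, numeric(1))
  kk <- vapply(conv, function(f) f$k, numeric(1))
  best <- conv[[order(a, kk)[1]]]
  list(fit = best, velocity_ok = best$family %in% c("IOU", "OUF"))
}

#' Mean scalar speed and day range from a correlated-velocity fit
#'
#' For an isotropic Gaussian velocity with per-axis variance
#' \eqn{\sigma_v^2}, the scalar speed is Rayleigh distributed with mean
#' \eqn{\sigma_v \sqrt{\pi/2}}.  The day range converts m/s to km/day
#' (factor 86.4).  \eqn{\sigma_v^2} is \code{sigma_p2/(tau_p tau_v)} for OUF
#' and \code{diffusion/tau_v} for IOU; OU and BM fits carry no velocity and
#' are rejected.
#'
#' @param fit a \code{ctmm_fit} with family IOU or OUF (or a
#'   \code{movement_params} of those families).
#' @param individual_id,season,year_label optional labels attached to the
#'   returned row.
#' @return one-row data.frame: \code{individual_id}, \code{season},
#'   \code{year_label}, \code{source_family}, \code{n_fixes},
#'   \code{speed_ms}, \code{day_range_km} (km/day).
#' @export
mean_speed <- function(fit, individual_id = NA_character_,
                       season = NA_character_, year_label = NA_character_) {
  params <- if (inherits(fit, "ctmm_fit")) fit$params else fit
  if (!params$family %in% c("IOU", "OUF"))
    stop("velocity is undefined for family ", params$family,
         "; day range requires IOU or OUF", call. = FALSE)
  sv2 <- velocity_variance(params)
  speed_ms <- sqrt(sv2) * sqrt(pi / 2)
  data.frame(
    individual_id = individual_id, season = season, year_label = year_label,
    source_family = params$family,
    n_fixes = if (inherits(fit, "ctmm_fit")) fit$n else NA_integer_,
    speed_ms = speed_ms,
    day_range_km = speed_ms * 86.4
  )
}

#' Aggregate individual day ranges within a season-by-year stratum
#'
#' @param estimates data.frame of \code{\link{mean_speed}} rows.
#' @return data.frame per season-by-year stratum with the across-individual
#'   arithmetic mean day range, its standard error (SD/sqrt(n); 0 with a
#'   flag when n = 1), and n.
#' @export
aggregate_speeds <- function(estimates) {
  stopifnot(nrow(estimates) >= 1)
  agg <- function(d) {
    n <- nrow(d)
    data.frame(
      season = d$season[1], year_label = d$year_label[1],
      n_individuals = n,
      mean_day_range_km = mean(d$day_range_km),
      se_day_range_km = if (n > 1) stats::sd(d$day_range_km) / sqrt(n) else 0,
      se_defined = n > 1
    )
  }
  out <- do.call(rbind, lapply(split(estimates, estimates$year_label), agg))
  rownames(out) <- NULL
  out
}
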