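#' Continuous-time movement model parameters
#'
#' Constructs and validates the parameter set of one of the four Gaussian
#' movement process families used throughout the package:
#' \describe{
#'   \item{BM}{Brownian motion; unbounded diffusion, no home range, no
#'     velocity autocorrelation.  Parameter: \code{diffusion} (m^2/s per
#'     axis; per-axis increment variance over a lag \eqn{\Delta} is
#'     \eqn{2 D \Delta}).}
#'   \item{OU}{Ornstein-Uhlenbeck position process; a stationary home range
#'     with position autocorrelation timescale \code{tau_p} but uncorrelated
#'     velocity.  Parameters: \code{sigma_p2} (m^2, per-axis position
#'     variance), \code{tau_p} (s), \code{center}.}
#'   \item{IOU}{Integrated OU; autocorrelated velocity with timescale
#'     \code{tau_v} but no home-range reversion.  Parameters:
#'     \code{diffusion} (m^2/s), \code{tau_v} (s).  The per-axis stationary
#'     velocity variance is \code{diffusion/tau_v}.}
#'   \item{OUF}{OU-foraging; a stationary home range with autocorrelated
#'     velocity, position autocovariance
#'     \eqn{\sigma_p^2 (\tau_p e^{-t/\tau_p} - \tau_v e^{-t/\tau_v}) /
#'     (\tau_p - \tau_v)}.  Parameters: \code{sigma_p2}, \code{tau_p},
#'     \code{tau_v} with \code{tau_p > tau_v}, \code{center}.}
#' }
#' Movement is isotropic: both axes share the same parameters.
#'
#' @param family one of \code{"BM"}, \code{"OU"}, \code{"IOU"}, \code{"OUF"}.
#' @param sigma_p2 per-axis stationary position variance (m^2); OU/OUF only.
#' @param tau_p position autocorrelation timescale (s); OU/OUF only.
#' @param tau_v velocity autocorrelation timescale (s); IOU/OUF only.
#' @param diffusion per-axis diffusion rate (m^2/s); BM/IOU only.
#' @param center home-range center / start location, numeric length 2 (m).
#' @return an object of class \code{movement_params}.
#' @examples
#' movement_params("OUF", sigma_p2 = 1e6, tau_p = 1e5, tau_v = 1e3)
#' @export
movement_params <- function(family = c("BM", "OU", "IOU", "OUF"),
                            sigma_p2 = NULL, tau_p = NULL, tau_v = NULL,
                            diffusion = NULL, center = c(0, 0)) {
  family <- match.arg(family)
  stopifnot(is.numeric(center), length(center) == 2, all(is.finite(center)))
  chk_pos <- function(x, nm) {
    if (is.null(x) || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a positive finite number for family %s",
                   nm, family), call. = FALSE)
    x
  }
  p <- list(family = family, center = as.numeric(center))
  if (family %in% c("OU", "OUF")) {
    p$sigma_p2 <- chk_pos(sigma_p2, "sigma_p2")
    p$tau_p <- chk_pos(tau_p, "tau_p")
  }
  if (family %in% c("IOU", "OUF")) p$tau_v <- chk_pos(tau_v, "tau_v")
  if (family %in% c("BM", "IOU")) p$diffusion <- chk_pos(diffusion, "diffusion")
  if (family == "OUF" && p$tau_p <= p$tau_v)
    stop("OUF requires tau_p > tau_v", call. = FALSE)
  if (family %in% c("BM", "OU") && !is.null(tau_v))
    stop(sprintf("tau_v is not a parameter of the %s family", family),
         call. = FALSE)
  class(p) <- "movement_params"
  p
}

#' @export
print.movement_params <- function(x, ...) {
  cat("<movement_params>", x$family, "\n")
  flds <- setdiff(names(x), c("family", "center"))
  for (f in flds) cat(" ", f, "=", format(x[[f]]), "\n")
  cat("  center = (", x$center[1], ",", x$center[2], ")\n")
  invisible(x)
}

#' Per-axis stationary velocity variance of a movement model
#'
#' Defined for the correlated-velocity families only:
#' \code{sigma_p2/(tau_p*tau_v)} for OUF and \code{diffusion/tau_v} for IOU.
#'
#' @param params a \code{movement_params} object (or a fitted
#'   \code{ctmm_fit}).
#' @return velocity variance (m^2/s^2 per axis).
#' @export
velocity_variance <- function(params) {
  switch(params$family,
    OUF = params$sigma_p2 / (params$tau_p * params$tau_v),
    IOU = params$diffusion / params$tau_v,
    stop("velocity variance is undefined for family ", params$family,
         call. = FALSE)
  )
}

#' GPS fix schedule
#'
#' @param start,end schedule limits (UTC seconds).
#' @param interval fix spacing (s), > 0.
#' @param dropout_prob probability that any scheduled fix is missing,
#'   in [0, 1).
#' @return a \code{fix_schedule} object.
#' @export
fix_schedule <- function(start, end, interval, dropout_prob = 0) {
  stopifnot(is.numeric(start), is.numeric(end), end > start,
            is.numeric(interval), interval > 0,
            dropout_prob >= 0, dropout_prob < 1)
  structure(list(start = start, end = end, interval = interval,
                 dropout_prob = dropout_prob),
            class = "fix_schedule")
}

# Exact discrete-time transition for one axis of a movement family.
# Returns list(Phi, Q, Sinf, d) where d is the state dimension; all
# covariances use the family's *actual* variance parameters.  Setting the
# variance parameter to 1 yields the unit-variance structure used when the
# variance is profiled out of a likelihood.
ctmm_transition <- function(params, dt) {
  fam <- params$family
  if (fam == "BM") {
    return(list(d = 1, Phi = matrix(1, 1, 1),
                Q = matrix(2 * params$diffusion * dt, 1, 1),
                Sinf = NULL))
  }
  if (fam == "OU") {
    phi <- exp(-dt / params$tau_p)
    s <- params$sigma_p2
    return(list(d = 1, Phi = matrix(phi, 1, 1),
                Q = matrix(s * (1 - phi^2), 1, 1),
                Sinf = matrix(s, 1, 1)))
  }
  if (fam == "IOU") {
    tv <- params$tau_v
    sv <- params$diffusion / tv
    phi <- exp(-dt / tv)
    Phi <- matrix(c(1, 0, tv * (1 - phi), phi), 2, 2)
    Q <- sv * matrix(c(
      tv^2 * (2 * dt / tv - 3 + 4 * phi - phi^2), tv * (1 - phi)^2,
      tv * (1 - phi)^2, 1 - phi^2), 2, 2)
    return(list(d = 2, Phi = Phi, Q = Q, Sinf = NULL))
  }
  # OUF: companion-form state (position, velocity)
  tp <- params$tau_p; tv <- params$tau_v; s <- params$sigma_p2
  l1 <- 1 / tp; l2 <- 1 / tv
  V <- matrix(c(1, -l1, 1, -l2), 2, 2)
  Phi <- V %*% diag(c(exp(-l1 * dt), exp(-l2 * dt))) %*% solve(V)
  Sinf <- diag(c(s, s / (tp * tv)))
  Q <- Sinf - Phi %*% Sinf %*% t(Phi)
  list(d = 2, Phi = Phi, Q = Q, Sinf = Sinf)
}

# Stationary position autocovariance (per axis) at lag tau >= 0.
ctmm_autocov <- function(params, tau) {
  switch(params$family,
    OU = params$sigma_p2 * exp(-tau / params$tau_p),
    OUF = {
      tp <- params$tau_p; tv <- params$tau_v
      params$sigma_p2 * (tp * exp(-tau / tp) - tv * exp(-tau / tv)) / (tp - tv)
    },
    stop("stationary autocovariance undefined for family ", params$family,
         call. = FALSE)
  )
}
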