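test_that("thinning keeps the greedy subset of fixes", {
  mk <- function(ts) data.frame(timestamp_utc = ts, x_m = 0, y_m = 0)
  # regular 30-min fixes thinned to 3 h: every 6th fix kept
  tr <- mk(seq(0, 36 * 1800, by = 1800))
  th <- thin_track(tr, 10800)
  expect_equal(th$timestamp_utc, seq(0, 36 * 1800, by = 10800))
  # already at the target interval: unchanged (idempotence)
  expect_equal(thin_track(th, 10800)$timestamp_utc, th$timestamp_utc)
  # irregular gaps, greedy oracle: keep {0, 3.5 h, 8 h}
  tr <- mk(c(0, 1, 3.5, 4, 8) * 3600)
  expect_equal(thin_track(tr, 3 * 3600)$timestamp_utc,
               c(0, 3.5, 8) * 3600)
  # output gaps never smaller than target - tolerance
  set.seed(4)
  ts <- cumsum(stats::rexp(300, 1 / 1800))
  th <- thin_track(mk(ts), 7200, tolerance = 300)
  expect_true(all(diff(th$timestamp_utc) >= 7200 - 300))
})

test_that("minimum seasonal fix counts are inclusive per species role", {
  mk <- function(n) data.frame(timestamp_utc = seq_len(n), x_m = 0, y_m = 0)
  tracks <- list("winter 2019-2020" = mk(199), "summer 2020" = mk(200))
  expect_message(kept <- filter_min_fixes(tracks, "coyote"), "dropping")
  expect_equal(names(kept), "summer 2020")
  kept <- filter_min_fixes(list(a = mk(100), b = mk(99)), "jackrabbit")
  expect_equal(names(kept), "a")
  expect_error(filter_min_fixes(tracks, "badger"), "unknown species")
})

test_that("variogram semivariance follows the movement model", {
  # no movement: semivariance identically zero
  tr <- data.frame(timestamp_utc = seq(0, 5000, 100), x_m = 7, y_m = -3)
  v <- empirical_variogram(tr)
  expect_true(all(v$semivariance == 0))
  # two fixes: a single pair in a single bin
  tr2 <- data.frame(timestamp_utc = c(0, 60), x_m = c(0, 4), y_m = c(0, 3))
  v2 <- empirical_variogram(tr2)
  expect_equal(nrow(v2), 1)
  expect_equal(v2$n_pairs, 1L)
  expect_equal(v2$semivariance, (16 + 9) / 4)
  # Brownian motion: semivariance linear in lag with slope = diffusion
  D <- 5
  s <- sample_track(movement_params("BM", diffusion = D),
                    duration = 500 * 100, fine_dt = 10, seed = 5,
                    schedule = fix_schedule(0, 500 * 100, 100))
  tr3 <- data.frame(timestamp_utc = s$fixes$time_s, x_m = s$fixes$x_m,
                    y_m = s$fixes$y_m)
  v3 <- empirical_variogram(tr3)
  v3 <- v3[seq_len(10), ]
  fit <- stats::lm(semivariance ~ lag, data = v3)
  expect_gt(summary(fit)$r.squared, 0.95)
  expect_lt(abs(stats::coef(fit)[["lag"]] - D) / D, 0.2)
})

test_that("AICc arithmetic matches the small-sample formula", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7)
  # reduces to AIC as n grows
  expect_equal(aicc(-10, 3, 1e8), 26, tolerance = 1e-6)
})

test_that("model selection takes the lowest AICc, ties to fewer parameters", {
  mk <- function(aicc_val, k, fam = "OU") {
    f <- list(family = fam, params = NULL, log_lik = 0, k = k, n = 50,
              aicc = aicc_val, converged = TRUE)
    class(f) <- "ctmm_fit"
    f
  }
  fits <- list(mk(100, 1, "BM"), mk(90, 4, "OU"), mk(95, 2, "IOU"),
               mk(91, 5, "OUF"))
  sel <- select_model(fits)
  expect_equal(sel$fit$aicc, 90)
  expect_false(sel$velocity_ok)
  # exact tie: fewer parameters wins
  sel <- select_model(list(mk(90, 5, "OUF"), mk(90, 2, "IOU")))
  expect_equal(sel$fit$family, "IOU")
  expect_true(sel$velocity_ok)
  # non-converged fits are excluded with a warning
  bad <- mk(10, 2, "IOU"); bad$converged <- FALSE
  expect_warning(sel <- select_model(list(bad, mk(90, 4, "OU"))),
                 "non-converged")
  expect_equal(sel$fit$family, "OU")
  expect_error(suppressWarnings(select_model(list(bad))), "no converged")
})

test_that("OU parameters are recovered from simulated data", {
  p <- movement_params("OU", sigma_p2 = 1e5, tau_p = 2e4,
                       center = c(50, -30))
  s <- sample_track(p, duration = 1000 * 2000, fine_dt = 10, seed = 11,
                    schedule = fix_schedule(0, 1000 * 2000, 2000))
  tr <- data.frame(timestamp_utc = s$fixes$time_s, x_m = s$fixes$x_m,
                   y_m = s$fixes$y_m)
  f <- fit_ctmm(tr, "OU")
  expect_true(f$converged)
  expect_lt(abs(f$params$sigma_p2 - 1e5) / 1e5, 0.15)
  expect_lt(abs(f$params$tau_p - 2e4) / 2e4, 0.15)
  expect_lt(abs(f$params$center[1] - 50), 3 * sqrt(1e5 / 10))
})

test_that("white-noise positions drive the OU timescale to the lower bound", {
  set.seed(21)
  tr <- data.frame(timestamp_utc = seq(0, 300 * 100, 100),
                   x_m = stats::rnorm(301, 0, 10),
                   y_m = stats::rnorm(301, 0, 10))
  f <- fit_ctmm(tr, "OU")
  expect_lt(f$params$tau_p, 100 / 2)   # far below the fix interval
})

test_that("BM likelihood maximiser equals the closed-form MLE", {
  s <- sample_track(movement_params("BM", diffusion = 3),
                    duration = 400 * 60, fine_dt = 10, seed = 6,
                    schedule = fix_schedule(0, 400 * 60, 60))
  tr <- data.frame(timestamp_utc = s$fixes$time_s, x_m = s$fixes$x_m,
                   y_m = s$fixes$y_m)
  f <- fit_ctmm(tr, "BM")
  dts <- diff(tr$timestamp_utc)
  D_hat <- sum(diff(tr$x_m)^2 / (2 * dts) + diff(tr$y_m)^2 / (2 * dts)) /
    (2 * length(dts))
  expect_equal(f$params$diffusion, D_hat, tolerance = 1e-12)
  expect_lt(abs(f$params$diffusion - 3) / 3, 0.2)
})

test_that("nested families agree in the limit", {
  # OUF likelihood at vanishing tau_v approaches the OU likelihood
  p <- movement_params("OU", sigma_p2 = 1e4, tau_p = 2000)
  s <- sample_track(p, duration = 300 * 100, fine_dt = 10, seed = 8,
                    schedule = fix_schedule(0, 300 * 100, 100))
  tvec <- s$fixes$time_s
  xy <- cbind(s$fixes$x_m, s$fixes$y_m)
  n2_ou <- remeval:::kalman_profile(tvec, xy, "OU", tau_p = 2000)$n2ll
  n2_ouf <- remeval:::kalman_profile(tvec, xy, "OUF", tau_p = 2000,
                                     tau_v = 1e-3)$n2ll
  expect_lt(abs(n2_ou - n2_ouf), 0.01)
})

test_that("OUF fits recover parameters and day range on one replicate", {
  p <- movement_params("OUF", sigma_p2 = 1e6, tau_p = 5e3, tau_v = 1e3)
  true_dr <- sqrt(1e6 / (5e3 * 1e3)) * sqrt(pi / 2) * 86.4
  s <- sample_track(p, duration = 2000 * 200, fine_dt = 10, seed = 13,
                    schedule = fix_schedule(0, 2000 * 200, 200))
  tr <- data.frame(timestamp_utc = s$fixes$time_s, x_m = s$fixes$x_m,
                   y_m = s$fixes$y_m)
  f <- fit_ctmm(tr, "OUF", n_starts = 4)
  expect_true(f$converged)
  expect_gt(f$params$tau_p, f$params$tau_v)
  expect_lt(abs(mean_speed(f)$day_range_km - true_dr) / true_dr, 0.10)
})

test_that("correlated-velocity families are selected when resolvable", {
  # OUF data sampled at tau_v / 5: IOU or OUF must top the AICc ranking in
  # at least 90% of replicates
  p <- movement_params("OUF", sigma_p2 = 1e6, tau_p = 5e3, tau_v = 1e3)
  fams <- vapply(1:20, function(b) {
    s <- sample_track(p, duration = 500 * 200, fine_dt = 10, seed = 100 + b,
                      schedule = fix_schedule(0, 500 * 200, 200))
    tr <- data.frame(timestamp_utc = s$fixes$time_s, x_m = s$fixes$x_m,
                     y_m = s$fixes$y_m)
    fits <- lapply(c("BM", "OU", "IOU", "OUF"), function(fam)
      fit_ctmm(tr, fam, n_starts = 4))
    select_model(fits)$fit$family
  }, character(1))
  expect_gte(mean(fams %in% c("IOU", "OUF")), 0.9)
})

test_that("thinning high-rate data reproduces the native coarse sampling", {
  # 30-min fixes thinned to 3 h coincide with a native 3-h schedule of the
  # same latent path, so the fitted movement models agree
  p <- movement_params("OUF", sigma_p2 = 1e6, tau_p = 5e4, tau_v = 5e3)
  dur <- 400 * 10800
  s <- sample_track(p, duration = dur, fine_dt = 10, seed = 17)
  fx30 <- subsample_fixes(s$path, fix_schedule(0, dur, 1800))
  fx3h <- subsample_fixes(s$path, fix_schedule(0, dur, 10800))
  tr30 <- data.frame(timestamp_utc = fx30$time_s, x_m = fx30$x_m,
                     y_m = fx30$y_m)
  thinned <- thin_track(tr30, 10800)
  expect_equal(thinned$timestamp_utc, fx3h$time_s)
  f_thin <- fit_ctmm(thinned, "OUF", n_starts = 4)
  f_native <- fit_ctmm(data.frame(timestamp_utc = fx3h$time_s,
                                  x_m = fx3h$x_m, y_m = fx3h$y_m),
                       "OUF", n_starts = 4)
  expect_equal(f_thin$params$tau_v, f_native$params$tau_v,
               tolerance = 1e-6)
  expect_equal(f_thin$log_lik, f_native$log_lik, tolerance = 1e-8)
})

test_that("mean speed follows the Rayleigh closed form", {
  # sigma_v^2 = 1e-4 m^2/s^2 per axis: 0.012533 m/s, 1.0829 km/day
  p <- movement_params("OUF", sigma_p2 = 1e-4 * 2e4 * 1e3, tau_p = 2e4,
                       tau_v = 1e3)
  expect_equal(velocity_variance(p), 1e-4, tolerance = 1e-12)
  sp <- mean_speed(p)
  expect_equal(sp$speed_ms, sqrt(1e-4) * sqrt(pi / 2), tolerance = 1e-9)
  expect_equal(sp$speed_ms, 0.012533, tolerance = 1e-4)
  expect_equal(sp$day_range_km, 1.0829, tolerance = 1e-4)
  # IOU variant: diffusion / tau_v
  p2 <- movement_params("IOU", diffusion = 0.1, tau_v = 1000)
  expect_equal(velocity_variance(p2), 1e-4)
  # velocity undefined for uncorrelated-velocity families
  expect_error(mean_speed(movement_params("OU", sigma_p2 = 1, tau_p = 1)),
               "undefined")
  expect_error(mean_speed(movement_params("BM", diffusion = 1)),
               "undefined")
})

test_that("day ranges aggregate with mean and standard error", {
  est <- data.frame(individual_id = c("a", "b"), season = "summer",
                    year_label = "summer 2020", source_family = "OUF",
                    n_fixes = 100, speed_ms = 1,
                    day_range_km = c(4, 6))
  ag <- aggregate_speeds(est)
  expect_equal(ag$mean_day_range_km, 5)
  expect_equal(ag$se_day_range_km, 1)
  expect_true(ag$se_defined)
  # single estimate: SE zero by convention, flagged
  ag1 <- aggregate_speeds(est[1, ])
  expect_equal(ag1$mean_day_range_km, 4)
  expect_equal(ag1$se_day_range_km, 0)
  expect_false(ag1$se_defined)
})
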