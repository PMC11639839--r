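test_that("discrete transitions match the Van Loan block-exponential oracle", {
  skip_if_not_installed("Matrix")
  vanloan <- function(A, L, dt) {
    d <- nrow(A)
    M <- rbind(cbind(-A, L %*% t(L)), cbind(matrix(0, d, d), t(A)))
    E <- as.matrix(Matrix::expm(M * dt))
    Phi <- t(E[(d + 1):(2 * d), (d + 1):(2 * d)])
    list(Phi = Phi, Q = Phi %*% E[1:d, (d + 1):(2 * d)])
  }
  # IOU: velocity OU integrated into position
  tv <- 300; D <- 2
  sv2 <- D / tv
  A <- matrix(c(0, 1, 0, -1 / tv), 2, 2, byrow = TRUE)
  L <- matrix(c(0, sqrt(2 * sv2 / tv)), 2, 1)
  vl <- vanloan(A, L, 50)
  tr <- remeval:::ctmm_transition(movement_params("IOU", diffusion = D,
                                                  tau_v = tv), 50)
  expect_lt(max(abs(vl$Phi - tr$Phi)), 1e-10)
  expect_lt(max(abs(vl$Q - tr$Q)), 1e-9)
  # OUF: damped position with correlated velocity
  tp <- 5000; tv <- 200; s <- 1e4
  A <- matrix(c(0, 1, -1 / (tp * tv), -(1 / tp + 1 / tv)), 2, 2,
              byrow = TRUE)
  sv2 <- s / (tp * tv)
  L <- matrix(c(0, sqrt(2 * (1 / tp + 1 / tv) * sv2)), 2, 1)
  vl <- vanloan(A, L, 120)
  tr <- remeval:::ctmm_transition(movement_params("OUF", sigma_p2 = s,
                                                  tau_p = tp, tau_v = tv),
                                  120)
  expect_lt(max(abs(vl$Phi - tr$Phi)), 1e-10)
  expect_lt(max(abs(vl$Q - tr$Q)), 1e-6)
})

test_that("stationary sampler reproduces closed-form variance and autocovariance", {
  p <- movement_params("OUF", sigma_p2 = 1e6, tau_p = 1e5, tau_v = 1e3)
  interval <- 1000
  s <- sample_track(p, duration = 5000 * interval, fine_dt = 10, seed = 1,
                    schedule = fix_schedule(0, 5000 * interval, interval))
  expect_equal(nrow(s$fixes), 5001)
  # per-axis position variance within 15% of sigma_p2
  v_emp <- (stats::var(s$fixes$x_m) + stats::var(s$fixes$y_m)) / 2
  expect_lt(abs(v_emp - 1e6) / 1e6, 0.15)
  # empirical autocovariance tracks the OUF kernel at lags {1, 2, 5} steps
  x <- s$fixes$x_m; y <- s$fixes$y_m; n <- length(x)
  for (lag in c(1, 2, 5)) {
    emp <- (stats::cov(x[1:(n - lag)], x[(1 + lag):n]) +
              stats::cov(y[1:(n - lag)], y[(1 + lag):n])) / 2
    expect_lt(abs(emp - ctmm_autocov(p, lag * interval)) / 1e6, 0.15)
  }
})

test_that("OU is the small-tau_v limit of OUF", {
  # with tau_v = 1 s and 100 s sampling the OUF lag-1 autocorrelation
  # matches the OU value e^(-dt/tau_p) within Monte-Carlo error
  interval <- 100
  p_ou <- movement_params("OU", sigma_p2 = 1e4, tau_p = 2000)
  p_ouf <- movement_params("OUF", sigma_p2 = 1e4, tau_p = 2000, tau_v = 1)
  acf1 <- function(s) {
    x <- s$fixes$x_m; n <- length(x)
    stats::cor(x[-n], x[-1])
  }
  s_ou <- sample_track(p_ou, 4000 * interval, fine_dt = 10, seed = 2,
                       schedule = fix_schedule(0, 4000 * interval, interval))
  s_ouf <- sample_track(p_ouf, 4000 * interval, fine_dt = 1, seed = 3,
                        schedule = fix_schedule(0, 4000 * interval, interval))
  theo <- exp(-interval / 2000)
  expect_lt(abs(acf1(s_ou) - theo), 0.03)
  expect_lt(abs(acf1(s_ouf) - theo), 0.03)
  expect_lt(abs(acf1(s_ou) - acf1(s_ouf)), 0.05)
})

test_that("same seed and parameters give identical tracks", {
  p <- movement_params("OUF", sigma_p2 = 1e5, tau_p = 5e3, tau_v = 500)
  s1 <- sample_track(p, duration = 1e4, fine_dt = 5, seed = 42)
  s2 <- sample_track(p, duration = 1e4, fine_dt = 5, seed = 42)
  expect_identical(s1$path, s2$path)
  b1 <- sample_biased_track(p, landscape(c(-5e3, 5e3, -5e3, 5e3)),
                            duration = 1e4, fine_dt = 5, seed = 7)
  b2 <- sample_biased_track(p, landscape(c(-5e3, 5e3, -5e3, 5e3)),
                            duration = 1e4, fine_dt = 5, seed = 7)
  expect_identical(b1$path, b2$path)
})

test_that("nonstationary families reject stationary initialisation", {
  p <- movement_params("BM", diffusion = 1)
  expect_error(sample_track(p, 1000, init = "stationary"),
               "no stationary distribution")
  p <- movement_params("IOU", diffusion = 1, tau_v = 100)
  expect_error(sample_track(p, 1000, init = "stationary"),
               "no stationary distribution")
  # point init works
  expect_silent(s <- sample_track(p, 1000, fine_dt = 5, seed = 1))
  expect_equal(unname(s$path$x_m[1]), 0)
})

test_that("Euler step guard rejects steps coarser than tau_v/10", {
  p <- movement_params("OUF", sigma_p2 = 1e5, tau_p = 5e3, tau_v = 40)
  land <- landscape(c(-5e3, 5e3, -5e3, 5e3))
  expect_error(sample_biased_track(p, land, 1000, fine_dt = 10, seed = 1),
               "too coarse")
})

test_that("zero attraction reproduces the unbiased law", {
  # thinned positions (2.5 tau_p apart, effectively independent) from the
  # Euler integrator at a = 0 vs the exact sampler: the stationary marginal
  # must agree (two-sample KS not rejected at alpha = 0.01, n = 2000)
  p <- movement_params("OUF", sigma_p2 = 1e4, tau_p = 2000, tau_v = 100)
  land <- landscape(c(-1e4, 1e4, -1e4, 1e4),
                    corridors = list(rbind(c(-5e3, 0), c(5e3, 0))),
                    attraction_strength = 0, attraction_range = 500)
  spacing <- 5000
  n_pts <- 2000
  dur <- n_pts * spacing
  sch <- fix_schedule(0, dur, spacing)
  s_euler <- sample_biased_track(p, land, dur, fine_dt = 10,
                                 schedule = sch, seed = 11)
  s_exact <- sample_track(p, dur, fine_dt = 10, schedule = sch, seed = 12)
  ks <- suppressWarnings(
    stats::ks.test(s_euler$fixes$x_m, s_exact$fixes$x_m))
  expect_gt(ks$p.value, 0.01)
  ks_y <- suppressWarnings(
    stats::ks.test(s_euler$fixes$y_m, s_exact$fixes$y_m))
  expect_gt(ks_y$p.value, 0.01)
})

test_that("corridor attraction pulls movement toward corridors", {
  corr <- list(rbind(c(200, 500), c(2800, 900)),
               rbind(c(500, 2800), c(1500, 1500), c(2800, 2500)))
  mk_land <- function(a) landscape(c(0, 3000, 0, 3000), corr,
                                   attraction_strength = a,
                                   attraction_range = 600)
  p <- movement_params("OUF", sigma_p2 = 4e5, tau_p = 2e4, tau_v = 600,
                       center = c(1500, 1500))
  mean_dist <- function(a, seeds) {
    land <- mk_land(a)
    mean(vapply(seeds, function(b) {
      s <- sample_biased_track(p, land, duration = 43200, fine_dt = 30,
                               seed = b)
      mean(corridor_distance(land, s$path$x_m, s$path$y_m))
    }, numeric(1)))
  }
  util_frac <- function(a, seeds) {
    land <- mk_land(a)
    mean(vapply(seeds, function(b) {
      s <- sample_biased_track(p, land, duration = 43200, fine_dt = 30,
                               seed = b)
      mean(corridor_distance(land, s$path$x_m, s$path$y_m) < 50)
    }, numeric(1)))
  }
  seeds <- 1:20
  expect_lt(mean_dist(0.001, seeds), mean_dist(0, seeds))
  # utilisation increases monotonically over the strength grid {0, a, 2a}
  u <- vapply(c(0, 0.001, 0.002), util_frac, numeric(1), seeds = 1:6)
  expect_true(all(diff(u) > 0))
})

test_that("fix schedules subsample and drop fixes as configured", {
  p <- movement_params("OU", sigma_p2 = 1e4, tau_p = 1000)
  s <- sample_track(p, duration = 10000, fine_dt = 5,
                    schedule = fix_schedule(0, 10000, 500), seed = 1)
  expect_equal(s$fixes$time_s, seq(0, 10000, by = 500))
  set.seed(9)
  sub <- subsample_fixes(s$path, fix_schedule(0, 10000, 500,
                                              dropout_prob = 0.5))
  expect_lt(nrow(sub), 21)
  expect_true(all(sub$time_s %% 500 == 0))
})
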