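test_that("logistic closed form matches its fixed points and an independent ODE solve", {
  K <- 10^3.2
  # fixed point and absorbing state, across times
  tt <- c(0, 0.5, 3, 12, 100)
  expect_equal(logistic_solution(K, 0.6, K, tt), rep(K, 5))
  expect_equal(logistic_solution(0, 0.6, K, tt), rep(0, 5))
  # Runge-Kutta oracle (deSolve) at the spec's worked point
  skip_if_not_installed("deSolve")
  sol <- deSolve::ode(y = c(N = 100), times = c(0, 6),
                      func = function(t, y, p) list(0.6 * y * (1 - y / K)),
                      parms = NULL, method = "ode45",
                      atol = 1e-10, rtol = 1e-10)
  expect_equal(logistic_solution(100, 0.6, K, 6), unname(sol[2, "N"]),
               tolerance = 1e-6)
})

test_that("logistic solution rejects invalid inputs and is overflow-safe", {
  expect_error(logistic_solution(-1, 0.6, 100, 1), "non-negative")
  expect_error(logistic_solution(10, 0, 100, 1), "positive")
  expect_error(logistic_solution(10, 0.6, 100, -1), "non-negative")
  expect_error(logistic_solution(NaN, 0.6, 100, 1), "non-finite")
  # large r*t must not overflow to NaN
  expect_equal(logistic_solution(1, 2, 1e5, 1e4), 1e5)
})

test_that("collapse intensity z is the unrounded product -p_c * log10(f)", {
  expect_equal(compute_z(0.07, -1.9), 0.133)
  expect_equal(round(compute_z(0.07, -1.9), 2), 0.13)
  expect_equal(compute_z(0, -1.9), 0)
  expect_equal(compute_z(0.04, -1.6), 0.064)
  expect_error(compute_z(0.07, 0.5), "<= 0")
  expect_error(compute_z(-0.01, -1), "non-negative")
})

test_that("parameter constructor enforces the model's invariants", {
  expect_error(collapse_params(r = 0), "positive")
  expect_error(collapse_params(K = 0.5), "at least 1")
  expect_error(collapse_params(mu_logf = 0.2), "f cannot exceed 1")
  expect_error(collapse_params(sigma_logf = -1), "non-negative")
  expect_error(collapse_params(p_c = Inf), "finite")
  p <- collapse_params()
  expect_s3_class(p, "collapse_params")
  expect_gte(compute_z(p$p_c, p$mu_logf), 0)
})

test_that("with no collapses the simulated trajectory is the logistic closed form", {
  p <- collapse_params(p_c = 0, mu_logf = 0)
  tr <- simulate_trajectory(p, n0 = 100, horizon = 15, output_dt = 1/3,
                            seed = 1)
  expect_identical(nrow(tr$events), 0L)
  exact <- logistic_solution(100, p$r, p$K, tr$times)
  expect_lt(max(abs(tr$abundance - exact) / pmax(exact, 1e-300)), 1e-12)
})

test_that("trajectories respect non-negativity, absorption and event bookkeeping", {
  p <- collapse_params(p_c = 0.3, mu_logf = -2, sigma_logf = 1)
  for (s in 1:25) {
    tr <- simulate_trajectory(p, n0 = 1e4, horizon = 24, output_dt = 0.5,
                              seed = s)
    expect_true(all(is.finite(tr$abundance)))
    expect_true(all(tr$abundance >= 0))
    # absorption: once zero, always zero
    z <- which(tr$abundance == 0)
    if (length(z)) expect_true(all(tr$abundance[min(z):length(tr$abundance)] == 0))
    if (nrow(tr$events)) {
      expect_true(all(tr$events$n_after <= tr$events$n_before))
      expect_true(all(tr$events$f >= 0 & tr$events$f <= 1))
    }
  }
})

test_that("simulation is reproducible and per-host streams are prefix-stable", {
  p <- collapse_params(p_c = 0.1, mu_logf = -1.5, sigma_logf = 0.5)
  t1 <- simulate_trajectory(p, 1e4, 14, 1/3, seed = 99)
  t2 <- simulate_trajectory(p, 1e4, 14, 1/3, seed = 99)
  expect_identical(t1$abundance, t2$abundance)
  expect_identical(t1$events, t2$events)
  e5 <- simulate_ensemble(p, 1e4, 24, n_hosts = 5, seed = 7)
  e10 <- simulate_ensemble(p, 1e4, 24, n_hosts = 10, seed = 7)
  expect_identical(e5$abundances, e10$abundances[1:5])
})

test_that("collapse counts follow the Poisson law and waits average to 1/p_c", {
  p <- collapse_params(p_c = 0.2, mu_logf = -0.05,
                       extinction_threshold = 0)  # mild drops: no absorption
  horizon <- 14
  counts <- vapply(1:2000, function(i) {
    nrow(simulate_trajectory(p, 1e4, horizon, horizon,
                             seed = split_seed(3, i))$events)
  }, integer(1))
  lam <- p$p_c * horizon
  expect_lt(abs(mean(counts) - lam), 3 * sqrt(lam / length(counts)))
  expect_lt(abs(var(counts) - lam), 4 * lam / sqrt(length(counts)) * 2)
})

test_that("rate and fraction parameterizations sharing z order endpoint means the same way", {
  # the qualitative half of the z-reduction: at matched (r, K, horizon) the
  # ensemble mean of log10(N+1) decreases in z under either (p_c, f) split
  means <- sapply(c(-1, -2), function(lf) {
    sapply(c(0.05, 0.13, 0.3), function(z) {
      p <- collapse_params(r = 0.6, K = 10^3.2, p_c = -z / lf, mu_logf = lf)
      e <- simulate_ensemble(p, 1e4, 24, 1500, seed = 42 + round(z * 100))
      mean(log10(e$abundances + 1))
    })
  })
  expect_true(all(diff(means[, 1]) < 0))
  expect_true(all(diff(means[, 2]) < 0))
})

test_that("endpoint mean is monotone: non-increasing in z, non-decreasing in K", {
  zs <- c(0.05, 0.13, 0.3)
  Ks <- c(2.5, 3.2, 4.0)
  m <- matrix(NA_real_, 3, 3)
  for (iz in 1:3) for (ik in 1:3) {
    p <- collapse_params(r = 0.6, K = 10^Ks[ik], p_c = 0.07,
                         mu_logf = -zs[iz] / 0.07)
    e <- simulate_ensemble(p, 1e4, 24, 5000, seed = 1000 + iz)
    m[iz, ik] <- mean(log10(e$abundances + 1))
  }
  slack <- 0.05  # Monte-Carlo allowance at 5000 trajectories/point
  for (ik in 1:3) expect_true(all(diff(m[, ik]) <= slack))
  for (iz in 1:3) expect_true(all(diff(m[iz, ]) >= -slack))
})

test_that("the growth rate barely moves endpoint spread or the fitted parameters", {
  # SD of the endpoint ensemble is insensitive to r at the challenge fit
  stats <- sapply(c(0.5, 0.8, 1.0), function(r) {
    p <- collapse_params(r = r, K = 10^3.2, p_c = 0.07, mu_logf = -1.9,
                         sigma_logf = 1)
    e <- simulate_ensemble(p, 1e4, 24, 2000, seed = 5 + round(10 * r))
    sd(log10(e$abundances + 1))
  })
  expect_lt(diff(range(stats)), 0.2)
  # and the inference does not care which r in [0.5, 1.0] is assumed
  truth <- collapse_params(r = 0.6, K = 10^3.2, p_c = 0.07,
                           mu_logf = -0.13 / 0.07)
  g <- gen_endpoint_ensemble(synthetic_spec(truth, n_hosts = 30, horizon = 24,
                                            n0 = 1e4, noise_cv = 0.2,
                                            seed = 55), 24)
  fits <- sapply(c(0.5, 0.8, 1.0), function(r) {
    coef(suppressWarnings(fit_collapse_model(g$ensemble, r = r, n_sim = 1500,
                                             seed = 2)))
  })
  expect_lt(diff(range(fits["log10_K", ])), 0.3)
  expect_lt(diff(range(fits["z", ])), 0.05)
})

test_that("per-host carrying-capacity variability widens a collapse-free ensemble", {
  p0 <- collapse_params(p_c = 0, mu_logf = 0, sigma_logK = 0)
  pv <- collapse_params(p_c = 0, mu_logf = 0, sigma_logK = 0.5)
  e0 <- simulate_ensemble(p0, 10^3.2, 24, 200, seed = 3)
  ev <- simulate_ensemble(pv, 10^3.2, 24, 200, seed = 3)
  expect_equal(sd(log10(e0$abundances + 1)), 0)
  expect_gt(sd(log10(ev$abundances + 1)), 0.3)
  # K is drawn once per trajectory: a collapse-free trajectory stays smooth
  tr <- simulate_trajectory(pv, 10, 24, 0.5, seed = 8)
  expect_true(all(diff(tr$abundance) >= -1e-9))
})

test_that("simulator argument validation catches misuse", {
  p <- collapse_params()
  expect_error(simulate_trajectory(p, -5, 10, 1), "non-negative")
  expect_error(simulate_trajectory(p, 10, 10, 20), "exceed")
  expect_error(simulate_trajectory(p, 10, 0, 1), "positive")
  expect_error(simulate_ensemble(p, 10, 10, 0), "at least 1")
})
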