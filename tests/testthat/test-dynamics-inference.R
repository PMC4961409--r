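test_that("a >=10-fold drop within the window is one event with the right magnitude", {
  s <- abundance_series("f1", "aero", c(0, 1/3, 2/3), c(1000, 50, 55))
  ev <- detect_collapses(s)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$n_before, 1000)
  expect_equal(ev$n_after, 50)
  expect_equal(ev$f, 0.05)
})

test_that("small pre-collapse populations and smooth growth yield no events", {
  s <- abundance_series("f1", "aero", c(0, 1/3), c(80, 5))
  expect_identical(nrow(detect_collapses(s)), 0L)
  expect_identical(nrow(detect_collapses(logistic_series(10, 0.6, 1e4))), 0L)
  # all-zero series: empty, not an error
  z <- abundance_series("f1", "aero", c(0, 1/3, 2/3), c(0, 0, 0))
  expect_identical(nrow(detect_collapses(z)), 0L)
})

test_that("overlapping pair triggers describing one decline merge into one event", {
  s <- abundance_series("f1", "aero", c(0, 1/3, 2/3, 1),
                        c(1000, 200, 50, 60))
  ev <- detect_collapses(s)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$n_before, 1000)
  expect_equal(ev$n_after, 50)
  # two declines separated by a recovery beyond the window stay distinct
  tt <- seq(0, 4, by = 1/3)
  ab <- c(2000, 100, 150, 400, 900, 2000, 2100, 2000, 90, 80, 100, 120, 150)
  ev2 <- detect_collapses(abundance_series("f1", "aero", tt, ab))
  expect_identical(nrow(ev2), 2L)
})

test_that("detection is scale-invariant when min_pre is rescaled with the data", {
  set.seed(14)
  tt <- seq(0, 14, by = 1/3)
  ab <- 10^runif(length(tt), 1, 4)
  s1 <- abundance_series("f1", "aero", tt, ab)
  s2 <- abundance_series("f1", "aero", tt, 7 * ab)
  e1 <- detect_collapses(s1, min_pre = 100)
  e2 <- detect_collapses(s2, min_pre = 700)
  expect_equal(e1$time, e2$time)
  expect_equal(e1$f, e2$f)
  expect_equal(7 * e1$n_before, e2$n_before)
})

test_that("merged events always drop by at least the trigger factor", {
  set.seed(21)
  for (rep in 1:20) {
    tt <- seq(0, 14, by = 1/3)
    ab <- 10^runif(length(tt), 0, 4.5)
    ev <- detect_collapses(abundance_series("f1", "aero", tt, ab))
    if (nrow(ev)) {
      expect_true(all(ev$n_after <= ev$n_before / 10 + 1e-9))
      expect_true(all(ev$f <= 0.1 + 1e-9))
    }
  }
})

test_that("a drop to zero is kept, flagged, and given a finite log magnitude", {
  s <- abundance_series("f1", "aero", c(0, 1/3), c(1000, 0))
  ev <- detect_collapses(s)
  expect_identical(nrow(ev), 1L)
  expect_true(ev$zero_after)
  expect_equal(ev$f, 1 / 1000)
  st <- collapse_statistics(ev, total_time = 10)
  expect_true(is.finite(st$mean_log10_f))
})

test_that("collapse statistics follow the Poisson estimator arithmetic", {
  ev <- data.frame(f = 10^seq(-2.5, -1.1, length.out = 7))
  st <- collapse_statistics(ev, total_time = 100)
  expect_equal(st$p_c_hat, 0.07)
  expect_equal(st$p_c_se, sqrt(7) / 100, tolerance = 1e-12)
  expect_equal(st$mean_log10_f, mean(log10(ev$f)))
  # no events: rate zero with the rule-of-three upper bound
  st0 <- collapse_statistics(ev[0, , drop = FALSE], total_time = 50)
  expect_equal(st0$p_c_hat, 0)
  expect_equal(st0$p_c_upper95, 0.06)
  expect_error(collapse_statistics(ev, total_time = -1), "positive")
})

test_that("observation time discounts QC gaps longer than the detection window", {
  s1 <- abundance_series("f1", "a", seq(0, 14, by = 1/3), rep(10, 43))
  expect_equal(observation_time(s1), 14)
  # remove 2 h of points in the middle: that span cannot contribute exposure
  tt <- c(seq(0, 6, by = 1/3), seq(8, 14, by = 1/3))
  s2 <- abundance_series("f1", "a", tt, rep(10, length(tt)))
  expect_equal(observation_time(s2), 12)
  expect_equal(observation_time(list(s1, s2)), 26)
})

test_that("detector and estimator recover the collapse rate across replicate cohorts", {
  # fixed-f conditions chosen so post-collapse populations stay detectable
  truth <- collapse_params(r = 0.6, K = 10^4.2, p_c = 0.04, mu_logf = -1.5)
  n_batches <- 100
  per_batch <- 20
  covered <- logical(n_batches)
  lf_all <- numeric(0)
  for (b in seq_len(n_batches)) {
    spec <- synthetic_spec(truth, n_hosts = per_batch, horizon = 14,
                           n0 = 1e4, noise_cv = 0, seed = 5000 + b)
    g <- gen_timeseries(spec)
    ev <- do.call(rbind, lapply(g$series, detect_collapses))
    st <- collapse_statistics(ev, observation_time(g$series))
    covered[b] <- !is.na(st$p_c_se) &&
      abs(st$p_c_hat - truth$p_c) <= 2 * st$p_c_se
    if (st$n_events > 0) lf_all <- c(lf_all, log10(ev$f))
  }
  expect_gte(mean(covered), 0.90)  # nominal 2-SE coverage ~95%
  expect_lt(abs(mean(lf_all) - truth$mu_logf), 0.1)
})

test_that("with spread-out magnitudes the detected mean log10(f) is biased downward", {
  # only drops of a factor >= 10 are detectable, so the estimator sees the
  # negative tail of the magnitude distribution
  truth <- collapse_params(r = 0.6, K = 10^4.2, p_c = 0.06, mu_logf = -1.0,
                           sigma_logf = 1.0)
  spec <- synthetic_spec(truth, n_hosts = 60, horizon = 14, n0 = 1e4,
                         noise_cv = 0, seed = 31)
  g <- gen_timeseries(spec)
  ev <- do.call(rbind, lapply(g$series, detect_collapses))
  expect_gt(nrow(ev), 10)
  expect_lt(mean(log10(ev$f)), truth$mu_logf)
})

test_that("growth-rate estimation is exact on exponentials and near-exact below K", {
  tt <- seq(0, 5, by = 1/3)
  s <- abundance_series("f1", "vib", tt, 50 * exp(0.8 * tt))
  g <- suppressWarnings(estimate_growth_rate(s))  # lm warns on a perfect fit
  expect_equal(g$rate, 0.8, tolerance = 1e-10)
  expect_lt(g$se, 1e-8)
  # logistic far below K behaves exponentially over its first hours
  s2 <- logistic_series(n0 = 10, r = 0.6, K = 1e4, horizon = 2)
  g2 <- estimate_growth_rate(s2, 0, 2)
  expect_equal(g2$rate, 0.6, tolerance = 0.02)
  expect_error(estimate_growth_rate(s, 4.5, 4.9), "window")
})

test_that("noisy growth-rate fits cover the truth at their nominal rate", {
  r <- 0.6
  tt <- seq(0, 14 / 3, by = 1/3)  # 15 points
  sdlog <- sqrt(log(1 + 0.2^2))
  set.seed(77)
  hits <- vapply(1:500, function(i) {
    ab <- 50 * exp(r * tt) * rlnorm(length(tt), -sdlog^2 / 2, sdlog)
    g <- estimate_growth_rate(abundance_series("f", "v", tt, ab))
    abs(g$rate - r) <= qt(0.975, g$n_used - 2) * g$se
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("companion ratios reflect the companion's own dynamics across events", {
  ev <- detect_collapses(abundance_series("f1", "aero", c(0, 1/3, 2/3),
                                          c(1000, 50, 55)))
  tt <- seq(0, 2, by = 1/3)
  const <- abundance_series("f1", "vib", tt, rep(1e4, length(tt)))
  expect_equal(companion_response(ev, const)$ratio_companion, 1)
  grow <- abundance_series("f1", "vib", tt, 1e3 * exp(0.8 * tt))
  expect_equal(companion_response(ev, grow)$ratio_companion, exp(0.8 / 3),
               tolerance = 1e-10)
  # events outside the companion's coverage are skipped with a warning
  short <- abundance_series("f1", "vib", c(1, 1.5), c(10, 10))
  expect_warning(out <- companion_response(ev, short), "skipped")
  expect_identical(nrow(out), 0L)
})

test_that("a companion independent of focal collapses shows growth-only ratios", {
  truth <- collapse_params(r = 0.6, K = 10^4.2, p_c = 0.06, mu_logf = -1.5)
  spec <- synthetic_spec(truth, n_hosts = 40, horizon = 14, n0 = 1e4,
                         noise_cv = 0, seed = 91)
  g <- gen_timeseries(spec)
  ratios <- unlist(lapply(g$series, function(s) {
    ev <- detect_collapses(s)
    if (!nrow(ev)) return(NULL)
    comp <- abundance_series(s$host_id, "vib", s$times,
                             logistic_solution(100, 0.8, 1e4, s$times))
    companion_response(ev, comp)$ratio_companion
  }))
  expect_gt(length(ratios), 10)
  # companion keeps growing (or saturates) through focal collapses: all
  # ratios at or above 1, none collapsing
  expect_true(all(ratios >= 1 - 1e-9))
  expect_lt(abs(median(ratios) - 1) , 0.35)
})
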