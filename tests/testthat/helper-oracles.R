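# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own simulation code paths.

# Fixed-step Euler simulator for the collapse-logistic model: dt-discretized
# logistic increments with per-step collapse probability p_c * dt (fixed-f
# only). Vectorized over trajectories; uses the current RNG stream.
euler_endpoints <- function(params, n0, horizon, dt = 0.001, n_traj = 400) {
  stopifnot(params$sigma_logf == 0, params$sigma_logK == 0)
  N <- rep(n0, n_traj)
  f_fix <- 10^params$mu_logf
  r <- params$r; K <- params$K
  p_step <- params$p_c * dt
  ext <- params$extinction_threshold
  for (s in seq_len(round(horizon / dt))) {
    alive <- N > 0
    N[alive] <- N[alive] + dt * r * N[alive] * (1 - N[alive] / K)
    hit <- alive & (stats::runif(n_traj) < p_step)
    N[hit] <- N[hit] * f_fix
    N[N < ext] <- 0
  }
  N
}

# analytic CDF of the distance to the wall for points uniform in a disk of
# radius R: P(d <= x) = 1 - (1 - x/R)^2
disk_wall_cdf <- function(x, R) 1 - (1 - pmin(x, R) / R)^2

# challenge-condition best-fit parameters (fixed-f form)
challenge_params <- function(sigma_logf = 0) {
  collapse_params(r = 0.6, K = 10^3.2, p_c = 0.07, mu_logf = -1.9,
                  sigma_logf = sigma_logf, extinction_threshold = 1)
}

# a logistic abundance series sampled on the imaging grid
logistic_series <- function(n0, r, K, horizon = 14, dt = 1/3,
                            host = "f1", species = "focal") {
  tt <- seq(0, horizon, by = dt)
  abundance_series(host, species, tt, logistic_solution(n0, r, K, tt))
}
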