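# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# exact two-sided Mann-Whitney p by enumerating all C(n+m, n) labelings
mw_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_stat <- function(idx) {
    xx <- pooled[idx]
    yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- u_stat(seq_len(n))
  us <- combn(length(pooled), n, FUN = u_stat)
  mu <- n * (length(y)) / 2
  # two-sided: distance of U from its null mean
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# one-sided hypergeometric upper tail by explicit combinatorial sums
hyper_tail_oracle <- function(k, K, n, N) {
  if (k > min(K, n)) return(0)
  i <- k:min(K, n)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# CA surface root by two-stage grid scan + linear interpolation on the
# implicit equation sum(c_i / EC_{y,i}) = exp(G)
ca_grid_oracle <- function(params, c1, c2) {
  tm <- params$theta_max
  tu1 <- c1 / params$ec50_1
  tu2 <- c2 / params$ec50_2
  tu <- tu1 + tu2
  if (tu == 0) return(tm)
  z1 <- tu1 / tu
  z2 <- tu2 / tu
  g <- deviation_g(a = params$a %||% 0, b = params$b, z1 = z1, z2 = z2,
                   tu_total = tu, kind = params$deviation_kind)
  f <- function(y) {
    tu1 * (y / (tm - y))^(1 / params$beta_1) +
      tu2 * (y / (tm - y))^(1 / params$beta_2) - exp(g)
  }
  scan <- function(lo, hi, n_pts) {
    ys <- seq(lo, hi, length.out = n_pts)
    fv <- vapply(ys, f, numeric(1))
    i <- which(fv[-1] * fv[-n_pts] <= 0)[1]
    c(ys[i], ys[i + 1], fv[i], fv[i + 1])
  }
  b1 <- scan(tm * 1e-9, tm * (1 - 1e-9), 20000)
  b2 <- scan(b1[1], b1[2], 20000)
  # linear interpolation inside the final bracket
  b2[1] - b2[3] * (b2[2] - b2[1]) / (b2[4] - b2[3])
}

`%||%` <- rlang::`%||%`

random_surface_params <- function(deviation_kind = "none", a = NULL, b = NULL) {
  surface_params(
    theta_max = runif(1, 50, 150),
    ec50_1 = exp(runif(1, -1, 1)), beta_1 = runif(1, 0.8, 3),
    ec50_2 = exp(runif(1, -1, 1)), beta_2 = runif(1, 0.8, 3),
    deviation_kind = deviation_kind, a = a, b = b
  )
}

# study-condition surface used across the simulation tests: per-cent scale
# endpoint, two chemicals with distinct potencies and slopes, 7 x 7
# factorial grid (n = 49) and 5%-of-theta_max response noise
sim_surface <- function(deviation_kind = "none", a = NULL, b = NULL) {
  surface_params(100, 1, 2, 2, 1.5, deviation_kind = deviation_kind,
                 a = a, b = b)
}

sim_grid <- function(params, noise_sd, seed, model_type = "CA") {
  gen_mixture_grid(params, model_type,
                   c1_levels = c(0.25, 0.5, 1, 2, 4, 8),
                   c2_levels = c(0.5, 1, 2, 4, 8, 16),
                   noise_sd = noise_sd, seed = seed)
}
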