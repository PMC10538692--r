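# Fixtures built in code: small amplitude-modulated signals and an exact
# transfer-entropy oracle for finite-state Markov chains.

# AM white-noise signal: (1 + depth*sin(2*pi*f*t)) * N(0,1), z-scored.
am_noise_signal <- function(duration_s = 10, rate_hz = 1000, f = 2,
                            depth = 0.9, seed = 1) {
  set.seed(seed)
  t <- seq_len(duration_s * rate_hz) / rate_hz
  env <- 1 + depth * sin(2 * pi * f * t)
  y <- env * rnorm(length(t))
  y <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  list(y = y, env = env, t = t, rate_hz = rate_hz)
}

quick_sample <- function(seed = 1, duration_s = 10, kappa = 0.8) {
  synth_generate(synth_spec(duration_s = duration_s, rate_hz = 2000,
                            coupling_kappa = kappa, seed = seed))
}

# ---- exact transfer entropy for a joint Markov chain -------------------
#
# The pair process (X_t, Y_t) is Markov with X' ~ px[x, ] and
# Y' ~ py[(x-1)*ny + y, ] (next Y depends on current X and Y). Exact
# one-step transfer entropy X -> Y follows from the stationary distribution
# by enumeration.
exact_te_markov <- function(px, py, nx, ny) {
  ns <- nx * ny
  Tm <- matrix(0, ns, ns)
  sid <- function(x, y) (x - 1) * ny + y
  for (x in 1:nx) for (y in 1:ny) {
    for (xp in 1:nx) for (yp in 1:ny) {
      Tm[sid(x, y), sid(xp, yp)] <- px[x, xp] * py[sid(x, y), yp]
    }
  }
  ev <- eigen(t(Tm))
  i <- which.min(abs(ev$values - 1))
  pi_ <- Re(ev$vectors[, i]); pi_ <- pi_ / sum(pi_)
  te <- 0
  # p(y'|y) = sum_x pi(x,y) p(y'|x,y) / pi(y)
  for (y in 1:ny) {
    py_marg <- sum(pi_[sid(1:nx, y)])
    if (py_marg <= 0) next
    cond_y <- rep(0, ny)
    for (x in 1:nx) cond_y <- cond_y + pi_[sid(x, y)] * py[sid(x, y), ]
    cond_y <- cond_y / py_marg
    for (x in 1:nx) {
      pxy <- pi_[sid(x, y)]
      if (pxy <= 0) next
      for (ypn in 1:ny) {
        p3 <- pxy * py[sid(x, y), ypn]
        if (p3 > 0) te <- te + p3 * log2(py[sid(x, y), ypn] / cond_y[ypn])
      }
    }
  }
  te
}

# Sample a realization of the same chain.
sim_te_markov <- function(px, py, nx, ny, n, seed) {
  set.seed(seed)
  x <- integer(n); y <- integer(n)
  x[1] <- 1L; y[1] <- 1L
  sid <- function(x, y) (x - 1) * ny + y
  for (t in 2:n) {
    y[t] <- sample.int(ny, 1, prob = py[sid(x[t - 1], y[t - 1]), ])
    x[t] <- sample.int(nx, 1, prob = px[x[t - 1], ])
  }
  list(x = x, y = y)
}

# Random row-stochastic matrix.
rand_stoch <- function(nrow, ncol, seed) {
  set.seed(seed)
  m <- matrix(rgamma(nrow * ncol, 1), nrow)
  m / rowSums(m)
}
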