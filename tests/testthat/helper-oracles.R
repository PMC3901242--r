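# Independent oracles used across the suite. These deliberately re-derive
# quantities by the most elementary route available (long-hand arithmetic,
# closed forms, fixed-step integration, brute-force search) so the package
# code under test never checks itself.

# Published parameter values (point estimates) used as ground truth in
# round-trip experiments.
PGI_TRUTH <- c(vf = 3.551, k_G6P = 0.550, k_F6P = 0.152, keq = 0.286)
PFK_TRUTH <- c(vf = 0.4435, k_F6P = 0.4174, k_ATP = 0.5444, k_PEP = 0.0863,
               alpha = 0.3797, h = 1.883)

# Long-hand scalar evaluation of the uni-uni reversible Hill/MM rate,
# written out term by term (independent of the vectorized implementation).
oracle_rev_mm <- function(s, p, vf, ks, kp, keq, h = 1) {
  sigma <- s / ks
  pii <- p / kp
  gamma <- if (s == 0 && p == 0) 0 else p / s
  num <- vf * sigma * (1 - gamma / keq) * (sigma + pii)^(h - 1)
  den <- 1 + (sigma + pii)^h
  num / den
}

# Long-hand scalar evaluation of the bi-substrate irreversible Hill rate.
oracle_bi_hill <- function(s1, s2, m, vf, k1, k2, km, alpha, h) {
  o1 <- (s1 / k1)^h
  o2 <- (s2 / k2)^h
  mu <- (m / km)^h
  M <- (1 + mu) / (1 + alpha * mu)
  vf * o1 * o2 / (M + o1 + o2 + o1 * o2)
}

# Fixed-step classical RK4, independent of deSolve.
oracle_rk4 <- function(deriv, y0, times) {
  out <- matrix(NA_real_, length(times), length(y0),
                dimnames = list(NULL, names(y0)))
  out[1L, ] <- y <- y0
  nm <- names(y0)  # align derivative components by name, not position
  for (i in seq_len(length(times) - 1L)) {
    h <- times[i + 1L] - times[i]
    k1 <- deriv(times[i], y)[nm]
    k2 <- deriv(times[i] + h / 2, y + h / 2 * k1)[nm]
    k3 <- deriv(times[i] + h / 2, y + h / 2 * k2)[nm]
    k4 <- deriv(times[i] + h, y + h * k3)[nm]
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    out[i + 1L, ] <- y
  }
  out
}

# Unit-area Lorentzian and its CDF (for integration-window truncation).
oracle_lorentz <- function(x, x0, w, area = 1)
  area * (w / 2) / pi / ((x - x0)^2 + (w / 2)^2)
oracle_lorentz_mass <- function(half_window, w)
  (2 / pi) * atan(2 * half_window / w)

# Small noiseless PGI rate dataset computed directly from the rate law on a
# concentration grid (no splines involved) - for fitter-only tests.
pgi_grid_dataset <- function(vf = 3.551, ks = 0.55, kp = 0.152, keq = 0.286) {
  grid <- expand.grid(G6P = c(0.2, 0.5, 1, 2, 5, 10),
                      F6P = c(0, 0.05, 0.2, 0.5, 1, 2))
  v <- mapply(oracle_rev_mm, grid$G6P, grid$F6P,
              MoreArgs = list(vf = vf, ks = ks, kp = kp, keq = keq))
  cbind(data.frame(rate = v, weight = 1), grid)
}

# Brute-force lattice search over two free parameters (log-spaced), followed
# by a Nelder-Mead polish - the grid-search oracle for fit_global.
oracle_grid_fit <- function(dat, free_names, fixed, lower, upper, nlat = 200L) {
  rss <- function(th) {
    theta <- c(th, fixed)
    v <- nmrkin::law_rate("pgi", dat, theta)
    sum((v - dat$rate)^2)
  }
  g1 <- exp(seq(log(lower[1L]), log(upper[1L]), length.out = nlat))
  g2 <- exp(seq(log(lower[2L]), log(upper[2L]), length.out = nlat))
  best <- c(NA, NA); best_rss <- Inf
  for (a in g1) {
    for (b in g2) {
      th <- stats::setNames(c(a, b), free_names)
      r <- rss(th)
      if (r < best_rss) { best_rss <- r; best <- th }
    }
  }
  polish <- stats::optim(log(best), function(lg) {
    rss(stats::setNames(exp(lg), free_names))
  }, method = "Nelder-Mead", control = list(reltol = 1e-12, maxit = 2000))
  stats::setNames(exp(polish$par), free_names)
}
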