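## Independent oracles. Deliberately naive implementations that share no code
## with the package paths they check.

# Ordinary least squares by explicit normal equations.
ols_oracle <- function(x, y) {
  solve(t(x) %*% x) %*% t(x) %*% y
}

# Connected-component labelling by depth-first flood fill with an explicit
# per-voxel stack and triple-loop neighbourhood scan.
floodfill_oracle <- function(binary, connectivity = 26) {
  d <- dim(binary)
  lab <- array(0L, dim = d)
  nxt <- 0L
  is_nbr <- function(dx, dy, dz) {
    s <- abs(dx) + abs(dy) + abs(dz)
    if (s == 0) return(FALSE)
    switch(as.character(connectivity),
           "6" = s == 1, "18" = s <= 2, "26" = TRUE)
  }
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!binary[i, j, k] || lab[i, j, k] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j, k))
    lab[i, j, k] <- nxt
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (!is_nbr(dx, dy, dz)) next
        p <- v + c(dx, dy, dz)
        if (any(p < 1L) || any(p > d)) next
        if (binary[p[1], p[2], p[3]] && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- nxt
          stack[[length(stack) + 1L]] <- p
        }
      }
    }
  }
  lab
}

# Composite Simpson quadrature on [a, b] with n (even) panels.
simpson_oracle <- function(f, a, b, n = 2000L) {
  if (n %% 2L) n <- n + 1L
  x <- seq(a, b, length.out = n + 1L)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  h <- (b - a) / n
  sum(w * f(x)) * h / 3
}

# Brute-force quadrature of the JZS two-sample Bayes factor: integral over
# g substituted as g = u / (1 - u), u in (0, 1), inverse-gamma(1/2, r^2/2)
# prior density written out directly.
jzs_bf10_oracle <- function(t, n1, n2, r = 1 / sqrt(2), n_panels = 40000L) {
  nu <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  lik <- function(g) (1 + neff * g)^(-1 / 2) *
    (1 + t^2 / ((1 + neff * g) * nu))^(-(nu + 1) / 2)
  prior <- function(g) (r^2 / 2)^(1 / 2) / gamma(1 / 2) *
    g^(-3 / 2) * exp(-r^2 / (2 * g))
  f <- function(u) {
    g <- u / (1 - u)
    lik(g) * prior(g) / (1 - u)^2
  }
  num <- simpson_oracle(function(u) ifelse(u <= 0 | u >= 1, 0, f(u)),
                        1e-12, 1 - 1e-12, n_panels)
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# Gauss hypergeometric 2F1(1/2, 1/2; c; z) through its Euler integral after
# the substitution t = s^2 (removes the endpoint singularity):
# 2F1 = Gamma(c) / (Gamma(1/2) Gamma(c - 1/2)) *
#       2 * int_0^1 (1 - s^2)^(c - 3/2) (1 - z s^2)^(-1/2) ds
hyp2f1_half_oracle <- function(c_par, z, n_panels = 20000L) {
  f <- function(s) (1 - s^2)^(c_par - 1.5) * (1 - z * s^2)^(-0.5)
  exp(lgamma(c_par) - lgamma(0.5) - lgamma(c_par - 0.5)) *
    2 * simpson_oracle(f, 0, 1 - 1e-10, n_panels)
}

# Brute-force quadrature of the stretched-beta (width kappa) Pearson BF10.
pearson_bf10_oracle <- function(r, n, kappa = 1, n_panels = 4000L) {
  a <- 1 / kappa
  ratio <- function(rho) {
    (1 - rho^2)^((n - 1) / 2) * (1 - rho * r)^(-(n - 1.5)) *
      hyp2f1_half_oracle(n - 0.5, (1 + rho * r) / 2, 4000L) /
      hyp2f1_half_oracle(n - 0.5, 0.5, 4000L)
  }
  f <- function(rho) vapply(rho, function(p)
    ratio(p) * dbeta((p + 1) / 2, a, a) / 2, numeric(1))
  simpson_oracle(f, -1 + 1e-9, 1 - 1e-9, n_panels)
}

# Amplitude of a sinusoidal component at frequency f_hz in a series sampled
# at interval tr: least-squares projection on sin/cos.
sinusoid_amplitude_oracle <- function(x, f_hz, tr) {
  t_sec <- (seq_along(x) - 1) * tr
  b <- stats::coef(stats::lm(x ~ sin(2 * pi * f_hz * t_sec) +
                               cos(2 * pi * f_hz * t_sec)))
  sqrt(b[2]^2 + b[3]^2)
}

# FWHM of a (separable Gaussian) impulse response from the second moment of
# the central axis profile.
fitted_fwhm_oracle <- function(response, centre, voxel_mm) {
  prof <- response[, centre[2], centre[3]]
  x <- (seq_along(prof) - centre[1]) * voxel_mm
  prof <- pmax(prof, 0)
  mu <- sum(x * prof) / sum(prof)
  sigma <- sqrt(sum((x - mu)^2 * prof) / sum(prof))
  2 * sqrt(2 * log(2)) * sigma
}

# Spearman rank correlation from first principles.
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y))
}
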