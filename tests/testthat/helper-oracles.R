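# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written from first principles (explicit
# sums, loops, grid search) so it shares no code path with the package.

# Simulated power-law pairs; independent of simulate_relationship().
make_powerlaw_pairs <- function(n, a, b, noise_sd, x_range = c(10, 1000),
                                seed = 1L) {
  set.seed(seed)
  lx <- runif(n, log10(x_range[1]), log10(x_range[2]))
  ly <- a + b * lx + rnorm(n, 0, noise_sd)
  data.frame(x = 10^lx, y = 10^ly)
}

# Closed-form normal equations on log10 pairs, computed term by term.
oracle_normal_equations <- function(pairs) {
  u <- log10(pairs$x)
  v <- log10(pairs$y)
  n <- length(u)
  su <- 0; sv <- 0; suu <- 0; suv <- 0
  for (i in seq_len(n)) {
    su <- su + u[i]; sv <- sv + v[i]
    suu <- suu + u[i]^2; suv <- suv + u[i] * v[i]
  }
  b <- (n * suv - su * sv) / (n * suu - su^2)
  a <- (sv - b * su) / n
  c(a = a, b = b)
}

# Brute-force minimiser of the summed squared log10 residuals: coarse grid
# around a neighbourhood followed by Nelder-Mead refinement of the SSE.
oracle_grid_fit <- function(pairs, a_window = c(-8, 8), b_window = c(-5, 5)) {
  u <- log10(pairs$x)
  v <- log10(pairs$y)
  sse <- function(p) sum((v - p[1] - p[2] * u)^2)
  grid_a <- seq(a_window[1], a_window[2], length.out = 41)
  grid_b <- seq(b_window[1], b_window[2], length.out = 41)
  best <- c(grid_a[1], grid_b[1]); best_sse <- Inf
  for (ga in grid_a) for (gb in grid_b) {
    s <- sse(c(ga, gb))
    if (s < best_sse) { best <- c(ga, gb); best_sse <- s }
  }
  opt <- optim(best, sse, control = list(reltol = 1e-14, maxit = 5000))
  opt <- optim(opt$par, sse, control = list(reltol = 1e-14, maxit = 5000))
  c(a = opt$par[1], b = opt$par[2])
}

# Textbook product-moment correlation, term by term.
oracle_pearson <- function(u, v) {
  n <- length(u)
  mu <- sum(u) / n
  mv <- sum(v) / n
  num <- 0; du <- 0; dv <- 0
  for (i in seq_len(n)) {
    num <- num + (u[i] - mu) * (v[i] - mv)
    du <- du + (u[i] - mu)^2
    dv <- dv + (v[i] - mv)^2
  }
  num / sqrt(du * dv)
}

# Reference coefficient set used when tests need the published values
# without going through published_chain().
ref_coefs <- function() {
  data.frame(
    stage = c("svl", "ttl", "bm", "bf"),
    a = c(-0.56913, 0.41689, -5.1240, 2.21779),
    b = c(1.10776, 0.91905, 2.9221, 0.66776)
  )
}
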