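# Independent brute-force oracles, written against the component definitions
# directly (plain loops, no shared code with the package internals).

# tortuosity components of a point path, by definition
oracle_vti <- function(pts, step = 2, eps = 1e-6) {
  n <- nrow(pts)
  la <- 0
  for (i in 2:n)
    la <- la + sqrt((pts[i, 1] - pts[i - 1, 1])^2 +
                    (pts[i, 2] - pts[i - 1, 2])^2)
  lc <- sqrt((pts[n, 1] - pts[1, 1])^2 + (pts[n, 2] - pts[1, 2])^2)
  chord_ang <- atan2(pts[n, 1] - pts[1, 1], pts[n, 2] - pts[1, 2])
  angs <- numeric(0)
  for (i in (step + 1):(n - step)) {
    a <- atan2(pts[i + step, 1] - pts[i - step, 1],
               pts[i + step, 2] - pts[i - step, 2]) - chord_ang
    while (a > pi) a <- a - 2 * pi
    while (a <= -pi) a <- a + 2 * pi
    angs <- c(angs, a)
  }
  sd_theta <- sqrt(sum((angs - mean(angs))^2) / (length(angs) - 1))
  ux <- (pts[n, 2] - pts[1, 2]) / lc
  uy <- (pts[n, 1] - pts[1, 1]) / lc
  dev <- numeric(n)
  for (i in 1:n)
    dev[i] <- (pts[i, 1] - pts[1, 1]) * ux - (pts[i, 2] - pts[1, 2]) * uy
  crit <- integer(0)
  last <- 0
  for (i in 1:(n - 1)) {
    dd <- dev[i + 1] - dev[i]
    s <- if (abs(dd) < eps) 0 else sign(dd)
    if (s == 0) next
    if (last != 0 && s != last) crit <- c(crit, i)
    last <- s
  }
  ncrit <- length(crit)
  m <- if (ncrit) mean(abs(dev[crit])) / lc else 0
  lapply(list(vti = if (ncrit) 0.1 * sd_theta * ncrit * m * la / lc else 0,
              sd_theta = sd_theta, n_critical = ncrit, m_amplitude = m,
              l_a = la, l_c = lc), unname)
}

# random smooth open curve: correlated random walk with drift (continuous
# coordinates, so no rounding ties in the deviation profile)
random_smooth_centerline <- function(seed, n = 120) {
  set.seed(seed)
  turn <- cumsum(rnorm(n - 1, 0, 0.06))
  th <- runif(1, 0, 2 * pi) + turn
  pts <- rbind(c(0, 0), cbind(cumsum(sin(th)), cumsum(cos(th))))
  pts + matrix(runif(2, -50, 50), n, 2, byrow = TRUE)
}

# two-sided Fisher exact p by exhaustive enumeration over tables with the
# observed margins
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, c1, r1 + r2 - c1, r1)
  p_obs <- dhyper(a, c1, r1 + r2 - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
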