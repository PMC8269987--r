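# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the geometric fit minimizes true orthogonal distances
# numerically, the Fisher oracle enumerates tables with factorial weights,
# and the t/chi-square oracles are the closed-form textbook expressions.

# Sum of squared orthogonal distances from points to the ellipse
# (cx, cy, a, b, psi_deg), approximated on a dense parametric grid.
geom_ss <- function(par, xy, n_grid = 720L) {
  cx <- par[1]; cy <- par[2]; a <- par[3]; b <- par[4]
  psi <- par[5] * pi / 180
  if (a <= 0 || b <= 0) return(Inf)
  tt <- 2 * pi * (seq_len(n_grid) - 1L) / n_grid
  ex <- cx + a * cos(tt) * cos(psi) - b * sin(tt) * sin(psi)
  ey <- cy + a * cos(tt) * sin(psi) + b * sin(tt) * cos(psi)
  d2 <- outer(xy[, 1], ex, "-")^2 + outer(xy[, 2], ey, "-")^2
  sum(d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))])
}

# Grid-refined least-squares geometric fit: Nelder-Mead on the orthogonal
# distance objective from a given start (typically the simulation truth).
oracle_geometric_fit <- function(xy, start) {
  ps <- c(0.5, 0.5, 0.5, 0.5, 0.1)   # sensible step sizes in px / degrees
  fit <- stats::optim(start, geom_ss, xy = xy,
                      control = list(maxit = 700, reltol = 1e-10,
                                     parscale = ps))
  # Nelder-Mead benefits from a restart; polish on a finer grid
  fit <- stats::optim(fit$par, geom_ss, xy = xy, n_grid = 1440L,
                      control = list(maxit = 400, reltol = 1e-11,
                                     parscale = 0.2 * ps))
  par <- fit$par
  if (par[3] < par[4]) {   # enforce a >= b, rotate psi by 90
    par[3:4] <- par[4:3]
    par[5] <- par[5] + 90
  }
  par[5] <- ((par[5] + 90) %% 180) - 90
  if (par[5] <= -90) par[5] <- par[5] + 180
  names(par) <- c("cx", "cy", "a", "b", "psi")
  par
}

# Two-sided Fisher exact p by brute enumeration of all tables with the
# observed margins, masses via binomial coefficients.
oracle_fisher_enum <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(m[, 2]) == 0) return(1)
  ks <- max(0, c1 - r2):min(c1, r1)
  mass <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  obs <- choose(r1, m[1, 1]) * choose(r2, c1 - m[1, 1]) / choose(n, c1)
  min(1, sum(mass[mass <= obs * (1 + 1e-7)]))
}

# Closed-form paired t: t = dbar / (s_d / sqrt(n)), two-sided p.
oracle_paired_t <- function(a, b) {
  d <- b - a
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df = n - 1))
}

# Hand chi-square: sum (O - E)^2 / E, df 1 for a 2x2 table.
oracle_chisq_2x2 <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - e)^2 / e)
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

# Implicit conic residual of points against a geometric ellipse; zero iff
# the point lies on the ellipse.
ellipse_implicit_residual <- function(e, xy) {
  psi <- e$orientation_deg * pi / 180
  dx <- xy[, 1] - e$center$x
  dy <- xy[, 2] - e$center$y
  u <- dx * cos(psi) + dy * sin(psi)
  v <- -dx * sin(psi) + dy * cos(psi)
  (u / e$semi_major_px)^2 + (v / e$semi_minor_px)^2 - 1
}
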