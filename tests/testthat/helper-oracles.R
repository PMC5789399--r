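# Independent oracles used across the suite.  These deliberately take a
# different computational route from the package implementation.

# scenario with every stochastic ingredient switched off
noiseless_scenario <- function(...) {
  sealing_scenario(base_drift_amplitude = 0, coordinate_noise_sd = 0,
                   subject_sd = 0, ...)
}

# brute-force sums-of-squares oracle for the fully within-subject two-way
# design: explicit loops over cell and marginal means
oracle_rm_anova <- function(tab, value = "gamma_deg") {
  s <- factor(tab$subject); a <- factor(tab$condition)
  b <- factor(tab$time_min); y <- tab[[value]]
  N <- nlevels(s); A <- nlevels(a); B <- nlevels(b)
  gm <- mean(y)
  m_s <- tapply(y, s, mean); m_a <- tapply(y, a, mean); m_b <- tapply(y, b, mean)
  m_ab <- tapply(y, list(a, b), mean)
  m_sa <- tapply(y, list(s, a), mean)
  m_sb <- tapply(y, list(s, b), mean)
  ss_a <- N * B * sum((m_a - gm)^2)
  ss_b <- N * A * sum((m_b - gm)^2)
  ss_ab <- 0
  for (i in seq_len(A)) for (j in seq_len(B))
    ss_ab <- ss_ab + N * (m_ab[i, j] - m_a[i] - m_b[j] + gm)^2
  ss_as <- 0
  for (k in seq_len(N)) for (i in seq_len(A))
    ss_as <- ss_as + B * (m_sa[k, i] - m_s[k] - m_a[i] + gm)^2
  ss_bs <- 0
  for (k in seq_len(N)) for (j in seq_len(B))
    ss_bs <- ss_bs + A * (m_sb[k, j] - m_s[k] - m_b[j] + gm)^2
  ss_abs <- 0
  for (r in seq_len(nrow(tab))) {
    k <- as.integer(s[r]); i <- as.integer(a[r]); j <- as.integer(b[r])
    ss_abs <- ss_abs + (y[r] - m_sa[k, i] - m_sb[k, j] - m_ab[i, j] +
                          m_s[k] + m_a[i] + m_b[j] - gm)^2
  }
  df <- c(A - 1, (A - 1) * (N - 1), B - 1, (B - 1) * (N - 1),
          (A - 1) * (B - 1), (A - 1) * (B - 1) * (N - 1))
  data.frame(effect = c("condition", "time", "condition:time"),
             df1 = df[c(1, 3, 5)], df2 = df[c(2, 4, 6)],
             F = (c(ss_a, ss_b, ss_ab) / df[c(1, 3, 5)]) /
                 (c(ss_as, ss_bs, ss_abs) / df[c(2, 4, 6)]))
}

# random fully crossed within-subject table
random_rm_table <- function(n, a, b, seed, round_digits = NULL) {
  set.seed(seed)
  tab <- expand.grid(subject = sprintf("s%d", seq_len(n)),
                     condition = letters[seq_len(a)],
                     time_min = seq_len(b),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  y <- stats::rnorm(nrow(tab)) + as.integer(factor(tab$condition)) * 0.5
  if (!is.null(round_digits)) y <- round(y, round_digits)  # induces ties
  tab$gamma_deg <- y
  tab
}

# exhaustive-window oracle for the elastic-modulus scan: per prefix, lm fit
oracle_window_scan <- function(curve, min_points = 10, r2_threshold = 1 - 1e-6) {
  n <- nrow(curve)
  best <- NULL
  for (k in seq(min_points, n)) {
    fit <- stats::lm(stress_Pa ~ strain, data = curve[seq_len(k), ])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits warn
    if (!is.na(r2) && r2 >= r2_threshold)
      best <- list(E = unname(stats::coef(fit)[2]), k = k,
                   hi = curve$strain[k])
  }
  best
}

# type-7 quantile by the textbook order-statistic interpolation formula
oracle_quantile7 <- function(x, p) {
  xs <- sort(x); n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, n)] - xs[lo])
}

# rigid motion of all points of a track series
transform_track <- function(tr, angle_deg = 0, dx = 0, dy = 0, scale = 1) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  mv <- function(x, y) {
    p <- scale * (R %*% rbind(x, y))
    list(x = p[1, ] + dx, y = p[2, ] + dy)
  }
  a <- mv(tr$x1, tr$y1); b <- mv(tr$x2, tr$y2); c3 <- mv(tr$x3, tr$y3)
  track_series(tr$time_s, cbind(a$x, a$y), cbind(b$x, b$y),
               cbind(c3$x, c3$y),
               units = attr(tr, "units"), convention = attr(tr, "convention"),
               leaf_id = attr(tr, "leaf_id"),
               condition = attr(tr, "condition"))
}
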