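# Shared fixtures: random pose generators and small geometric helpers used
# across the suite. All randomness is locally seeded.

sind <- cupver:::sind
cosd <- cupver:::cosd
tand <- cupver:::tand
asind <- cupver:::asind
atan2d <- cupver:::atan2d

random_poses <- function(n, seed, av_range = c(5, 35), incl_range = c(30, 55),
                         radius_range = c(23, 30)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    cup_pose(anteversion_deg = runif(1, av_range[1], av_range[2]),
             inclination_deg = runif(1, incl_range[1], incl_range[2]),
             radius_mm = runif(1, radius_range[1], radius_range[2]),
             side = sample(c("left", "right"), 1))
  })
}

# minimum distance from each point in `pts` to a densely sampled curve
min_dist_to_curve <- function(pts, curve) {
  vapply(seq_len(nrow(pts)), function(i) {
    sqrt(min((curve[, 1] - pts[i, 1])^2 + (curve[, 2] - pts[i, 2])^2))
  }, numeric(1))
}

dense_ellipse <- function(e, n = 1500) {
  ellipse_boundary(e, seq(0, 2 * pi, length.out = n))
}

dense_circle <- function(centre, r, n = 1500) {
  th <- seq(0, 2 * pi, length.out = n)
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

# exact distance from points to an ellipse: coarse parametric scan followed
# by Newton steps on d(theta)^2
dist_to_ellipse_exact <- function(pts, e) {
  ax <- cupver:::ellipse_axes(e)
  a <- e$semi_major_mm; b <- e$semi_minor_mm
  rel <- sweep(pts, 2, e$centre_film_mm)
  xi <- rel %*% ax$major; eta <- rel %*% ax$minor
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (a * cos(th) - xi[i])^2 + (b * sin(th) - eta[i])^2
    t0 <- th[which.min(d2)]
    for (it in 1:4) {
      ct <- cos(t0); st <- sin(t0)
      ex <- a * ct - xi[i]; ey <- b * st - eta[i]
      g <- -ex * a * st + ey * b * ct
      h <- -ex * a * ct + a^2 * st^2 - ey * b * st + b^2 * ct^2
      if (abs(h) < 1e-12) break
      t0 <- t0 - g / h
    }
    sqrt((a * cos(t0) - xi[i])^2 + (b * sin(t0) - eta[i])^2)
  }, numeric(1))
}

# distance from points to the analytic cup silhouette (open-side rim
# ellipse union dome circle): exact circle term, Newton-refined ellipse term
dist_to_cup_silhouette <- function(pts, e, radius_mm) {
  d_circ <- abs(sqrt((pts[, 1] - e$centre_film_mm[1])^2 +
                       (pts[, 2] - e$centre_film_mm[2])^2) - radius_mm)
  pmin(d_circ, dist_to_ellipse_exact(pts, e))
}

# independent ICC(2,1) oracle: mean squares from stats::aov rather than the
# package's direct row/column-mean decomposition
icc21_aov_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]; msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}
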