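# Edge-detection reference standard: circle fits to the prosthetic head and
# the cup shell, followed by a centre-constrained reconstruction of the
# opening-rim ellipse and anteversion from the axis ratio. Mirrors the
# user-guided stepwise procedure of commercial edge-detection software
# (best-fitting head circle, best-fitting shell circle, opening ellipse
# reconstructed about the centre of rotation).

#' Best-fitting circle through film points
#'
#' Three points give the exact circumcircle; more than three are fitted by
#' the Kasa algebraic least-squares circle and then refined by geometric
#' (orthogonal-distance) Gauss-Newton iterations.
#'
#' @param points matrix-like with >= 3 rows of film points (x, y), mm.
#' @return a `circle_fit` list: `centre_film_mm`, `radius_mm`,
#'   `rms_residual_mm`, `n_points`.
#' @export
#' @examples
#' fit_circle(rbind(c(0, 0), c(2, 0), c(1, 1)))  # centre (1, 0), radius 1
fit_circle <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 3L) stop("need at least 3 points to fit a circle", call. = FALSE)
  x <- P[, 1]; y <- P[, 2]
  # collinearity check via the rank of centred coordinates
  M <- cbind(x - mean(x), y - mean(y))
  sv <- svd(M, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1)) stop("points are collinear: no circle fit", call. = FALSE)
  # Kasa: x^2 + y^2 + D x + E y + F = 0, linear least squares
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  coef <- qr.coef(qr(A), b)
  cx <- -coef[1] / 2; cy <- -coef[2] / 2
  r <- sqrt(max(0, cx^2 + cy^2 - coef[3]))
  if (nrow(P) > 3L) {
    # geometric refinement: minimise sum (|p - c| - r)^2
    for (it in 1:25) {
      dx <- x - cx; dy <- y - cy
      di <- sqrt(dx^2 + dy^2)
      if (any(di < 1e-12)) break
      r_new <- mean(di)
      J <- cbind(-dx / di, -dy / di, -1)
      res <- di - r_new
      step <- tryCatch(qr.coef(qr(J), -res), error = function(e) rep(0, 3))
      cx <- cx + step[1]; cy <- cy + step[2]; r_new <- r_new + step[3]
      conv <- sqrt(sum(step^2)) < 1e-12
      r <- r_new
      if (conv) break
    }
  }
  di <- sqrt((x - cx)^2 + (y - cy)^2)
  cx <- unname(cx); cy <- unname(cy); r <- unname(r)
  structure(list(centre_film_mm = c(cx, cy), radius_mm = r,
                 rms_residual_mm = sqrt(mean((di - r)^2)), n_points = nrow(P)),
            class = "circle_fit")
}

# Direct least-squares conic fit through >= 5 points, returned as
# ellipse_params. Exact (up to conditioning) when the points lie on a true
# ellipse, which is how the point-source rim projection is recovered.
fit_ellipse_direct <- function(points) {
  P <- as.matrix(points)
  if (nrow(P) < 5L) stop("need at least 5 points for a conic fit", call. = FALSE)
  mx <- mean(P[, 1]); my <- mean(P[, 2])
  sc <- max(stats::sd(P[, 1]), stats::sd(P[, 2]), 1e-9)
  x <- (P[, 1] - mx) / sc; y <- (P[, 2] - my) / sc
  D <- cbind(x^2, x * y, y^2, x, y, 1)
  v <- svd(D)$v[, 6]
  A <- v[1]; B <- v[2] / 2; C <- v[3]; Dd <- v[4] / 2; E <- v[5] / 2; FF <- v[6]
  det2 <- A * C - B^2
  if (det2 <= 0) stop("conic fit is not an ellipse", call. = FALSE)
  cx <- (B * E - C * Dd) / det2
  cy <- (B * Dd - A * E) / det2
  mu <- A * cx^2 + 2 * B * cx * cy + C * cy^2 + 2 * Dd * cx + 2 * E * cy + FF
  Q <- matrix(c(A, B, B, C), 2, 2) / (-mu)
  ei <- eigen(Q, symmetric = TRUE)
  if (any(ei$values <= 0)) stop("conic fit is not an ellipse", call. = FALSE)
  axes <- 1 / sqrt(ei$values)          # descending eigenvalues -> ascending axes
  a <- max(axes) * sc; b <- min(axes) * sc
  major_vec <- ei$vectors[, which.min(ei$values)]
  ellipse_params(c(cx * sc + mx, cy * sc + my), a, b,
                 fold_orientation(atan2d(major_vec[2], major_vec[1])))
}

#' Unconstrained 5-parameter ellipse fit
#'
#' Free direct least-squares conic fit (no centre or axis constraint); the
#' comparison baseline for the centre-constrained reconstruction.
#'
#' @param points matrix-like with >= 5 rows of film points (x, y), mm.
#' @return an [ellipse_params()].
#' @export
fit_ellipse_free <- function(points) fit_ellipse_direct(points)

#' Reconstruct the opening-rim ellipse about the centre of rotation
#'
#' Constrained reconstruction used by the reference standard: the ellipse
#' centre is pinned to the fitted head centre (the centre of rotation) and
#' the semi-major axis to the fitted shell radius; orientation and semi-minor
#' axis are estimated from the rim edge points by least squares on the
#' implicit ellipse equation.
#'
#' @param head,shell [fit_circle()] results for the prosthetic head and the
#'   cup shell outline.
#' @param rim_points matrix-like with >= 3 rows of film points on the
#'   opening-rim edge, mm.
#' @return an [ellipse_params()].
#' @export
reconstruct_opening_ellipse <- function(head, shell, rim_points) {
  P <- as.matrix(rim_points)
  if (nrow(P) < 3L) stop("need at least 3 rim points", call. = FALSE)
  if (shell$radius_mm <= head$radius_mm) {
    stop("shell radius must exceed head radius", call. = FALSE)
  }
  ctr <- head$centre_film_mm
  a <- shell$radius_mm
  dx <- P[, 1] - ctr[1]; dy <- P[, 2] - ctr[2]
  # rim points collinear through the pinned centre leave the semi-minor
  # axis unidentifiable
  sv <- svd(cbind(dx, dy), nu = 0, nv = 0)$d
  if (sv[2] < 1e-3 * sv[1]) {
    stop("rim points lie on a single diameter: semi-minor axis unidentifiable (degenerate)",
         call. = FALSE)
  }

  # given the major-axis angle phi, the optimal q = 1/b^2 solves a linear
  # least-squares problem in the implicit equation (xi/a)^2 + q eta^2 = 1
  fit_b <- function(phi) {
    co <- cos(phi); si <- sin(phi)
    xi <- dx * co + dy * si
    eta <- -dx * si + dy * co
    rhs <- 1 - (xi / a)^2
    denom <- sum(eta^4)
    if (denom < 1e-12) return(list(sse = Inf, b = NA_real_))
    q <- sum(eta^2 * rhs) / denom
    if (q <= 0) return(list(sse = Inf, b = NA_real_))
    list(sse = sum((q * eta^2 - rhs)^2), b = 1 / sqrt(q))
  }
  phis <- seq(0, pi, length.out = 73L)[-73L]
  sses <- vapply(phis, function(p) fit_b(p)$sse, numeric(1))
  if (!any(is.finite(sses))) {
    stop("rim points do not determine a semi-minor axis (degenerate: all on the major axis?)",
         call. = FALSE)
  }
  p0 <- phis[which.min(sses)]
  opt <- stats::optimize(function(p) fit_b(p)$sse, c(p0 - pi / 36, p0 + pi / 36))
  best <- fit_b(opt$minimum)
  if (!is.finite(best$sse) || is.na(best$b)) {
    stop("rim points inconsistent with an ellipse about the head centre", call. = FALSE)
  }
  b <- best$b
  if (b > a * (1 + 1e-6)) {
    stop("rim points imply semi-minor > semi-major: inconsistent with the shell radius",
         call. = FALSE)
  }
  ellipse_params(ctr, a, min(b, a), fold_orientation(opt$minimum * 180 / pi))
}

#' Reference-standard anteversion from the reconstructed ellipse
#'
#' The reference reading is `arcsin(semi_minor / semi_major)` in degrees. An
#' AP film alone cannot distinguish ante- from retroversion, so the value is
#' unsigned unless a lateral disambiguation flag is supplied.
#'
#' @param e an [ellipse_params()].
#' @param retroverted optional logical from the lateral film; `TRUE` negates
#'   the reading.
#' @return a `version_reading` (see [version_reading()]).
#' @export
version_reference <- function(e, retroverted = NA) {
  val <- asind(clamp_unit(e$semi_minor_mm / e$semi_major_mm))
  if (isTRUE(retroverted)) val <- -val
  version_reading(val, "reference")
}

#' Full edge-detection pipeline on a ray-traced silhouette image
#'
#' Emulates the operator-guided procedure on a rendered image: extract
#' boundary pixels of the head and cup channels, fit the head circle,
#' classify cup boundary pixels into dome-outline pixels (at shell-radius
#' distance from the head centre) and rim-edge pixels (strictly inside the
#' shell outline), fit the shell circle, and reconstruct the constrained
#' opening ellipse.
#'
#' @param img a [ray_trace_oracle()] result.
#' @return list with `head`, `shell` ([fit_circle()] results), `ellipse`
#'   ([ellipse_params()]) and `reading` (`version_reading`).
#' @export
reference_from_image <- function(img) {
  hb <- boundary_points(img$head, img$x_mm, img$y_mm)
  cb <- boundary_points(img$cup, img$x_mm, img$y_mm)
  if (nrow(hb) < 3L || nrow(cb) < 3L) stop("image contains no implant boundary", call. = FALSE)
  head <- fit_circle(hb)
  d <- sqrt((cb[, 1] - head$centre_film_mm[1])^2 + (cb[, 2] - head$centre_film_mm[2])^2)
  rmax <- max(d)
  tol <- 2.5 * img$pixel_mm
  dome <- cb[d > rmax - tol, , drop = FALSE]
  shell <- fit_circle(dome)
  rim <- cb[d < shell$radius_mm - tol, , drop = FALSE]
  if (nrow(rim) < 3L) stop("too few rim-edge pixels: opening not visible", call. = FALSE)
  ell <- reconstruct_opening_ellipse(head, shell, rim)
  list(head = head, shell = shell, ellipse = ell, reading = version_reference(ell))
}
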