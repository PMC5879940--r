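#' Projected opening-rim ellipse parameters
#'
#' Film-plane parameters of the elliptical projection of the cup opening rim:
#' centre, semi-axes, and major-axis orientation.
#'
#' @param centre_film_mm numeric length-2, film coordinates of the ellipse
#'   centre, mm.
#' @param semi_major_mm,semi_minor_mm semi-axes, mm; `0 <= b <= a`.
#' @param orientation_deg angle of the major axis to the film x-axis,
#'   degrees, folded to `[0, 180)`.
#' @return an object of class `ellipse_params`.
#' @export
ellipse_params <- function(centre_film_mm, semi_major_mm, semi_minor_mm,
                           orientation_deg = 0) {
  stopifnot_scalar(semi_major_mm, "semi_major_mm", positive = TRUE)
  stopifnot_scalar(semi_minor_mm, "semi_minor_mm")
  if (semi_minor_mm < -1e-12 || semi_minor_mm > semi_major_mm * (1 + 1e-9)) {
    stop("semi_minor_mm must lie in [0, semi_major_mm]", call. = FALSE)
  }
  structure(
    list(centre_film_mm = as.numeric(centre_film_mm),
         semi_major_mm = semi_major_mm,
         semi_minor_mm = max(0, min(semi_minor_mm, semi_major_mm)),
         orientation_deg = fold_orientation(orientation_deg)),
    class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("<ellipse_params> centre (%.2f, %.2f) mm, a %.3f mm, b %.3f mm, theta %.2f deg\n",
              x$centre_film_mm[1], x$centre_film_mm[2],
              x$semi_major_mm, x$semi_minor_mm, x$orientation_deg))
  invisible(x)
}

# Unit direction of the ellipse major / minor axes on the film.
ellipse_axes <- function(e) {
  u <- c(cosd(e$orientation_deg), sind(e$orientation_deg))
  list(major = u, minor = c(-u[2], u[1]))
}

#' Points on an ellipse boundary
#'
#' @param e an [ellipse_params()].
#' @param theta parametric angles, radians.
#' @return a 2-column matrix of film points.
#' @export
ellipse_boundary <- function(e, theta) {
  ax <- ellipse_axes(e)
  t(e$centre_film_mm +
      e$semi_major_mm * outer(ax$major, cos(theta)) +
      e$semi_minor_mm * outer(ax$minor, sin(theta)))
}

# Central projection of 3-D points (3 x n) onto the AP film plane z = 0,
# source on the anterior side at z = -sfd.
point_source_project <- function(P, sfd) {
  S <- c(0, 0, -sfd)
  denom <- P[3, ] + sfd
  if (any(denom <= 0)) {
    stop("object lies at or behind the X-ray source: cannot project", call. = FALSE)
  }
  t <- sfd / denom
  rbind(S[1] + (P[1, ] - S[1]) * t,
        S[2] + (P[2, ] - S[2]) * t)
}

check_beam_cone <- function(pose, beam) {
  sfd <- beam$source_film_distance_mm
  C <- pose$centre_mm
  if (C[3] <= -sfd || C[3] >= 0) {
    stop("cup centre must lie strictly between the point source and the film",
         call. = FALSE)
  }
  cp <- point_source_project(matrix(C, 3, 1), sfd)
  if (any(abs(cp) > beam$film_half_extent_mm)) {
    stop("cup centre projects outside the beam cone (film half-extent ",
         beam$film_half_extent_mm, " mm)", call. = FALSE)
  }
  invisible(TRUE)
}

# Exact ellipse from a parallel projection of the rim circle: the projected
# rim is {c' + r cos(t) E1 + r sin(t) E2}; the singular values of [E1 E2]
# scaled by r are the semi-axes and the left singular vectors the axis
# directions.
ellipse_from_span <- function(centre2, E1, E2, r) {
  s <- svd(cbind(E1, E2) * r)
  theta <- atan2d(s$u[2, 1], s$u[1, 1])
  ellipse_params(centre2, s$d[1], max(0, s$d[2]), fold_orientation(theta))
}

#' Project the cup opening rim onto the AP film
#'
#' Under a parallel beam the projected rim is an exact ellipse with
#' `semi_major = radius_mm` and `semi_minor = radius_mm * sin(|anteversion|)`.
#' Under a point source the rim circle maps to a conic which is recovered by
#' an exact direct least-squares conic fit through densely projected rim
#' points.
#'
#' @param pose a [cup_pose()].
#' @param beam a [beam_geometry()] with `film = "ap"`.
#' @param tilt_deg,rot_deg pelvic nuisance rotations applied to the implant
#'   directions (tilt about the transverse axis, rotation about the
#'   longitudinal axis), degrees.
#' @return an [ellipse_params()].
#' @export
#' @examples
#' project_rim(cup_pose(19.4, 45, 25), beam_geometry())
project_rim <- function(pose, beam = beam_geometry(), tilt_deg = 0, rot_deg = 0) {
  if (beam$film != "ap") stop("project_rim requires an AP beam geometry", call. = FALSE)
  fr <- cup_frame(pose, tilt_deg, rot_deg)
  r <- pose$radius_mm
  if (beam$mode == "parallel") {
    ellipse_from_span(fr$C[1:2], fr$e1[1:2], fr$e2[1:2], r)
  } else {
    check_beam_cone(pose, beam)
    P <- rim_points_3d(pose, n_points = 180, tilt_deg = tilt_deg, rot_deg = rot_deg)
    xy <- point_source_project(P, beam$source_film_distance_mm)
    fit_ellipse_direct(t(xy))
  }
}

# Silhouette circle of a sphere (C, R) under a point source at S: the
# terminator circle on the sphere, centred at C - (R^2/d) vhat with radius
# R sqrt(1 - R^2/d^2) in the plane perpendicular to v = C - S.
sphere_terminator_points <- function(C, R, S, theta) {
  v <- C - S
  d <- sqrt(sum(v^2))
  if (d <= R) stop("source inside sphere", call. = FALSE)
  vhat <- v / d
  ref <- if (abs(vhat[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  a1 <- cross3(vhat, ref); a1 <- a1 / sqrt(sum(a1^2))
  a2 <- cross3(vhat, a1)
  Cc <- C - (R^2 / d) * vhat
  Rc <- R * sqrt(1 - (R / d)^2)
  Cc + Rc * (outer(a1, cos(theta)) + outer(a2, sin(theta)))
}

#' Silhouette point sets of the projected implant
#'
#' Generates film points on the projected opening rim, on the dome-side arc
#' of the cup's sphere silhouette, and on the prosthetic-head border,
#' optionally jittered with isotropic Gaussian noise.
#'
#' @inheritParams project_rim
#' @param n_points points per curve (>= 3).
#' @param head_radius_mm prosthetic-head radius, mm; the head is modelled
#'   concentric with the centre of rotation.
#' @param noise_sd_mm isotropic Gaussian jitter, mm (0 = exact points).
#' @param rng_seed integer seed making the jitter reproducible.
#' @return a `silhouette_points` list with matrices `rim_points`,
#'   `dome_points`, `head_points` (columns `x_mm`, `y_mm`).
#' @export
project_silhouette <- function(pose, beam = beam_geometry(), n_points = 100,
                               head_radius_mm = 14, noise_sd_mm = 0,
                               rng_seed = 1L, tilt_deg = 0, rot_deg = 0) {
  if (beam$film != "ap") stop("project_silhouette requires an AP beam geometry", call. = FALSE)
  if (n_points < 3) stop("n_points must be >= 3 per curve", call. = FALSE)
  fr <- cup_frame(pose, tilt_deg, rot_deg)
  r <- pose$radius_mm
  th <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]

  if (beam$mode == "parallel") {
    e <- project_rim(pose, beam, tilt_deg, rot_deg)
    rim <- ellipse_boundary(e, th)
    # dome-side arc of the sphere-outline circle: half circle centred on the
    # direction opposite the in-plane opening direction
    n2 <- fr$n[1:2]
    apex_dir <- if (sqrt(sum(n2^2)) < 1e-12) c(0, 1) else -n2 / sqrt(sum(n2^2))
    alpha0 <- atan2(apex_dir[2], apex_dir[1])
    al <- alpha0 + seq(-pi / 2, pi / 2, length.out = n_points)
    dome <- cbind(fr$C[1] + r * cos(al), fr$C[2] + r * sin(al))
    head <- cbind(fr$C[1] + head_radius_mm * cos(th), fr$C[2] + head_radius_mm * sin(th))
  } else {
    check_beam_cone(pose, beam)
    sfd <- beam$source_film_distance_mm
    S <- c(0, 0, -sfd)
    rim <- t(point_source_project(
      rim_points_3d(pose, tilt_deg = tilt_deg, rot_deg = rot_deg, theta = th), sfd))
    dome3 <- sphere_terminator_points(fr$C, r, S, th)
    # keep the dome-side half only
    n2 <- fr$n[1:2]
    apex_dir <- if (sqrt(sum(n2^2)) < 1e-12) c(0, 1) else -n2 / sqrt(sum(n2^2))
    d2 <- t(point_source_project(dome3, sfd))
    ctr <- t(point_source_project(matrix(fr$C, 3, 1), sfd))
    keep <- as.numeric((d2[, 1] - ctr[1]) * apex_dir[1] + (d2[, 2] - ctr[2]) * apex_dir[2]) >= 0
    dome <- d2[keep, , drop = FALSE]
    head3 <- sphere_terminator_points(fr$C, head_radius_mm, S, th)
    head <- t(point_source_project(head3, sfd))
  }

  if (noise_sd_mm > 0) {
    jitter_mat <- function(m, seed_tag) {
      with_seed(derive_seed(rng_seed, seed_tag), {
        m + matrix(stats::rnorm(length(m), 0, noise_sd_mm), nrow(m), ncol(m))
      })
    }
    rim <- jitter_mat(rim, 1L); dome <- jitter_mat(dome, 2L); head <- jitter_mat(head, 3L)
  }
  colnames(rim) <- colnames(dome) <- colnames(head) <- c("x_mm", "y_mm")
  structure(list(rim_points = rim, dome_points = dome, head_points = head,
                 head_radius_mm = head_radius_mm),
            class = "silhouette_points")
}

#' Cross-table lateral projection and the Woo-Morrey raw reading
#'
#' Projects the cup opening rim along the horizontal, cephalad-tilted lateral
#' beam onto the cassette. The cassette is held perpendicular to the
#' examination table against the patient's flank, i.e. its plane contains
#' the vertical (table-perpendicular) direction and the patient's long axis;
#' the 45-degree cephalad beam therefore strikes it obliquely, which
#' stretches the longitudinal film direction by `1 / cos(cephalad)` and is
#' the geometric source of the systematic overestimation of the lateral
#' reading (`tan(reading) ~ tan(anteversion) / cos(cephalad)` at ideal
#' positioning).
#'
#' The "line touching the opening surface" is the chord through the two
#' silhouette-extreme rim points; the reference line is the projected
#' table-perpendicular. The signed angle between them is the raw Woo-Morrey
#' reading, positive for anteversion, negative for retroversion.
#'
#' @inheritParams project_rim
#' @param beam a [beam_geometry()] with `film = "crosstable_lateral"`.
#' @return a `lateral_measures` list: `opening_line` and `reference_line`
#'   (2 x 2 matrices of film points, mm) and `angle_deg`.
#' @export
project_lateral <- function(pose, beam = beam_geometry(film = "crosstable_lateral"),
                            tilt_deg = 0, rot_deg = 0) {
  if (beam$film != "crosstable_lateral") {
    stop("project_lateral requires a cross-table lateral beam geometry", call. = FALSE)
  }
  if (beam$mode != "parallel") {
    stop("the lateral branch supports the parallel beam model only", call. = FALSE)
  }
  g <- beam$crosstable_cephalad_deg
  s <- if (pose$side == "left") 1 else -1
  # horizontal beam tilted g degrees toward the head, entering from the
  # contralateral-medial side and crossing the table toward the operated
  # hip (cassette on the affected lateral flank)
  d <- c(s * sind(g), cosd(g), 0)
  u1 <- c(0, -1, 0)                      # in-film longitudinal axis (caudad;
                                         # fixed so anteversion reads positive
                                         # on either side)
  u2 <- c(0, 0, -1)                      # in-film vertical axis (anterior up)
  fr <- cup_frame(pose, tilt_deg, rot_deg)
  r <- pose$radius_mm
  # oblique parallel projection onto the plane x = C_x
  proj <- function(P) {
    Pp <- P - d * ((P[1] - fr$C[1]) / d[1])
    c(sum(Pp * u1), sum(Pp * u2))
  }
  w <- cross3(fr$n, d)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("degenerate lateral projection: beam parallel to the cup axis",
                       call. = FALSE)
  w <- w / nw
  p1 <- proj(fr$C - r * w)
  p2 <- proj(fr$C + r * w)
  opening <- rbind(p1, p2)
  ctr <- proj(fr$C)
  reference <- rbind(ctr, ctr + c(0, r))
  colnames(opening) <- colnames(reference) <- c("x_mm", "y_mm")
  out <- structure(list(opening_line = opening, reference_line = reference,
                        angle_deg = NA_real_),
                   class = "lateral_measures")
  out$angle_deg <- version_woo_morrey(out)$value_deg
  out
}

#' Brute-force ray-traced silhouette image
#'
#' Independent rasterisation oracle: casts one ray per film pixel (parallel
#' or from the point source) and tests intersection with the solid
#' hemispherical cup (half-ball bounded by the opening plane) and with the
#' prosthetic-head sphere. Boundaries extracted from the image agree with the
#' analytic projections to within one pixel.
#'
#' @inheritParams project_silhouette
#' @param pixel_mm pixel size, mm (> 0).
#' @param margin_mm film margin beyond the projected implant, mm.
#' @param extent_mm optional half-extent of the rendered film window about
#'   the projected centre; an extent smaller than the projected implant is an
#'   error.
#' @return a `ray_trace_image` list: logical matrices `cup`, `head`, `both`
#'   (rows = y, columns = x), pixel-centre coordinates `x_mm`, `y_mm`, and
#'   `pixel_mm`.
#' @export
ray_trace_oracle <- function(pose, beam = beam_geometry(), pixel_mm = 0.2,
                             head_radius_mm = 14, margin_mm = 8,
                             extent_mm = NULL, tilt_deg = 0, rot_deg = 0) {
  if (beam$film != "ap") stop("ray_trace_oracle renders the AP film only", call. = FALSE)
  stopifnot_scalar(pixel_mm, "pixel_mm", positive = TRUE)
  fr <- cup_frame(pose, tilt_deg, rot_deg)
  C <- fr$C; n <- fr$n; R <- pose$radius_mm
  mag <- if (beam$mode == "point_source") {
    check_beam_cone(pose, beam)
    beam$source_film_distance_mm / (C[3] + beam$source_film_distance_mm)
  } else 1
  ctr2 <- if (beam$mode == "point_source") {
    as.numeric(point_source_project(matrix(C, 3, 1), beam$source_film_distance_mm))
  } else C[1:2]
  need <- (max(R, head_radius_mm)) * mag + margin_mm
  half <- if (is.null(extent_mm)) need else extent_mm
  if (half < need - 1e-9) {
    stop("image extent (", half, " mm) smaller than the projected implant (",
         round(need, 2), " mm)", call. = FALSE)
  }
  xs <- seq(ctr2[1] - half, ctr2[1] + half, by = pixel_mm)
  ys <- seq(ctr2[2] - half, ctr2[2] + half, by = pixel_mm)
  px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  py <- matrix(ys, length(ys), length(xs))

  if (beam$mode == "parallel") {
    dx <- px - C[1]; dy <- py - C[2]
    rho2 <- dx^2 + dy^2
    head_img <- rho2 <= head_radius_mm^2
    inside <- rho2 <= R^2
    w <- sqrt(pmax(0, R^2 - rho2))
    # sphere z-interval [Cz - w, Cz + w]; half-space (P-C).n <= 0
    g <- dx * n[1] + dy * n[2]
    if (abs(n[3]) < 1e-12) {
      cup_img <- inside & (g <= 0)
    } else if (n[3] > 0) {
      cup_img <- inside & ((C[3] - g / n[3]) >= C[3] - w)
    } else {
      cup_img <- inside & ((C[3] - g / n[3]) <= C[3] + w)
    }
  } else {
    S <- c(0, 0, -beam$source_film_distance_mm)
    vx <- px - S[1]; vy <- py - S[2]; vz <- 0 - S[3]
    nv <- sqrt(vx^2 + vy^2 + vz^2)
    dx_ <- vx / nv; dy_ <- vy / nv; dz_ <- vz / nv
    oc <- S - C
    b <- dx_ * oc[1] + dy_ * oc[2] + dz_ * oc[3]
    cc <- sum(oc^2)
    hit2 <- function(rad) {
      disc <- b^2 - (cc - rad^2)
      ok <- disc >= 0
      sq <- sqrt(pmax(0, disc))
      list(ok = ok, t1 = -b - sq, t2 = -b + sq)
    }
    hh <- hit2(head_radius_mm)
    head_img <- hh$ok
    ch <- hit2(R)
    # half-space (S + t d - C).n <= 0  =>  a0 + t * dn <= 0
    a0 <- sum(oc * n)
    dn <- dx_ * n[1] + dy_ * n[2] + dz_ * n[3]
    tcut <- -a0 / dn
    cup_img <- ch$ok & ifelse(dn > 0, ch$t1 <= tcut, ch$t2 >= tcut)
  }
  structure(list(cup = cup_img, head = head_img, both = cup_img | head_img,
                 x_mm = xs, y_mm = ys, pixel_mm = pixel_mm),
            class = "ray_trace_image")
}

#' Boundary pixel centres of a binary mask
#'
#' A pixel is a boundary pixel when it is on and at least one 4-neighbour is
#' off (or it touches the image border).
#'
#' @param mask logical matrix (rows = y, columns = x).
#' @param x_mm,y_mm pixel-centre coordinates.
#' @return a 2-column matrix of film points (`x_mm`, `y_mm`).
#' @export
boundary_points <- function(mask, x_mm, y_mm) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  nb <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  edge <- core & !nb
  idx <- which(edge, arr.ind = TRUE)
  cbind(x_mm = x_mm[idx[, 2]], y_mm = y_mm[idx[, 1]])
}
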