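#' Ground-truth implant state
#'
#' A `cup_pose` describes the true three-dimensional state of an acetabular
#' component: its radiographic anteversion (angle between the opening-plane
#' axis and the coronal/film plane, positive for an anteriorly facing
#' opening), its inclination (angle of the projected opening-plane major axis
#' to the transverse film axis), its outer radius, the 3-D position of the
#' centre of rotation, and the operated side.
#'
#' Coordinate frame (AP acquisition, supine): the film is the coronal plane,
#' x runs transverse toward the patient's left, y superior, and the beam
#' travels along +z from anterior to posterior. All lengths are millimetres,
#' all angles degrees.
#'
#' Anteversion is accepted as a signed value in (-90, 90): the AP projection
#' cannot distinguish ante- from retroversion, but the cross-table lateral
#' branch can, and retroverted poses are needed to exercise that sign
#' convention.
#'
#' @param anteversion_deg signed radiographic anteversion, degrees, in
#'   (-90, 90).
#' @param inclination_deg inclination of the projected major axis to the
#'   transverse film axis, degrees, in (0, 90).
#' @param radius_mm cup outer radius, mm (> 0).
#' @param centre_mm numeric length-3, 3-D centre of rotation (x, y, z), mm.
#'   The default places the implant 150 mm anterior to the film.
#' @param side `"left"` or `"right"`.
#' @return an object of class `cup_pose`.
#' @export
#' @examples
#' cup_pose(anteversion_deg = 19.4, inclination_deg = 45, radius_mm = 25)
cup_pose <- function(anteversion_deg, inclination_deg = 45, radius_mm = 25,
                     centre_mm = c(0, 0, -150), side = c("right", "left")) {
  stopifnot_scalar(anteversion_deg, "anteversion_deg")
  stopifnot_scalar(inclination_deg, "inclination_deg")
  stopifnot_scalar(radius_mm, "radius_mm", positive = TRUE)
  side <- match.arg(side)
  if (abs(anteversion_deg) >= 90) {
    stop("anteversion_deg must lie in (-90, 90)", call. = FALSE)
  }
  if (inclination_deg <= 0 || inclination_deg >= 90) {
    stop("inclination_deg must lie in (0, 90)", call. = FALSE)
  }
  if (!is.numeric(centre_mm) || length(centre_mm) != 3L || anyNA(centre_mm)) {
    stop("centre_mm must be a numeric length-3 vector", call. = FALSE)
  }
  structure(
    list(anteversion_deg = anteversion_deg,
         inclination_deg = inclination_deg,
         radius_mm = radius_mm,
         centre_mm = as.numeric(centre_mm),
         side = side),
    class = "cup_pose")
}

#' @export
print.cup_pose <- function(x, ...) {
  cat(sprintf("<cup_pose> %s side: AV %.2f deg, inclination %.2f deg, radius %.1f mm\n",
              x$side, x$anteversion_deg, x$inclination_deg, x$radius_mm))
  invisible(x)
}

#' X-ray beam and film geometry
#'
#' @param mode `"parallel"` (default; the published AP formulas implicitly
#'   assume a parallel beam) or `"point_source"`.
#' @param source_film_distance_mm source-to-film distance, mm; the clinical
#'   acquisition default is 1150 mm (115 cm).
#' @param film `"ap"` or `"crosstable_lateral"`.
#' @param crosstable_cephalad_deg cephalad tilt of the horizontal lateral
#'   beam from the patient's long axis, degrees, in (0, 90); default 45.
#' @param film_half_extent_mm half-width of the usable film/beam field, mm;
#'   a point-source projection whose cup centre falls outside this field
#'   (outside the beam cone) is an error. Default 215 (35 x 43 cm cassette).
#' @return an object of class `beam_geometry`.
#' @export
beam_geometry <- function(mode = c("parallel", "point_source"),
                          source_film_distance_mm = 1150,
                          film = c("ap", "crosstable_lateral"),
                          crosstable_cephalad_deg = 45,
                          film_half_extent_mm = 215) {
  mode <- match.arg(mode)
  film <- match.arg(film)
  stopifnot_scalar(source_film_distance_mm, "source_film_distance_mm", positive = TRUE)
  stopifnot_scalar(crosstable_cephalad_deg, "crosstable_cephalad_deg")
  if (crosstable_cephalad_deg <= 0 || crosstable_cephalad_deg >= 90) {
    stop("crosstable_cephalad_deg must lie strictly in (0, 90): 0 or 90 gives a degenerate projection",
         call. = FALSE)
  }
  structure(
    list(mode = mode,
         source_film_distance_mm = source_film_distance_mm,
         film = film,
         crosstable_cephalad_deg = crosstable_cephalad_deg,
         film_half_extent_mm = film_half_extent_mm),
    class = "beam_geometry")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rot_x <- function(deg) {
  c_ <- cosd(deg); s <- sind(deg)
  matrix(c(1, 0, 0, 0, c_, -s, 0, s, c_), 3, 3, byrow = TRUE)
}

rot_y <- function(deg) {
  c_ <- cosd(deg); s <- sind(deg)
  matrix(c(c_, 0, s, 0, 1, 0, -s, 0, c_), 3, 3, byrow = TRUE)
}

# Orthonormal frame of the cup opening plane, after optional pelvic
# nuisance rotations (tilt about the transverse x axis, rotation about the
# longitudinal y axis, both applied to the implant directions about the cup
# centre).
#
# Returns: C (centre), n (opening-plane unit axis, anterior-facing for
# positive anteversion), e1 (rim-circle direction projecting onto the film
# major axis), e2 = n x e1, m3 (opening-side minor direction in the film
# plane, pre-rotation convention).
cup_frame <- function(pose, tilt_deg = 0, rot_deg = 0) {
  s <- if (pose$side == "left") 1 else -1
  phi <- pose$inclination_deg
  u3 <- c(s * cosd(phi), sind(phi), 0)          # film major-axis direction
  m3 <- cross3(c(0, 0, 1), u3)                  # in-plane minor direction
  if (pose$side == "left") m3 <- -m3            # opening faces latero-inferior
  av <- pose$anteversion_deg
  n <- cosd(av) * m3 - sind(av) * c(0, 0, 1)    # opening axis, anterior for av > 0
  e1 <- u3
  e2 <- cross3(n, e1)
  if (tilt_deg != 0 || rot_deg != 0) {
    R <- rot_y(rot_deg) %*% rot_x(tilt_deg)
    n <- as.numeric(R %*% n)
    e1 <- as.numeric(R %*% e1)
    e2 <- as.numeric(R %*% e2)
  }
  list(C = pose$centre_mm, n = n, e1 = e1, e2 = e2)
}

# Points (3 x n matrix) on the opening rim circle.
rim_points_3d <- function(pose, n_points = 64, tilt_deg = 0, rot_deg = 0,
                          theta = NULL) {
  fr <- cup_frame(pose, tilt_deg, rot_deg)
  if (is.null(theta)) theta <- seq(0, 2 * pi, length.out = n_points + 1L)[-(n_points + 1L)]
  r <- pose$radius_mm
  fr$C + r * (outer(fr$e1, cos(theta)) + outer(fr$e2, sin(theta)))
}
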