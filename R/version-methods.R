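# The published formulas mapping film landmarks/measurements to acetabular
# anteversion in degrees. On an exact projected ellipse with semi-axes
# (a, b) the four AP ellipse methods (Liaw, Lewinnek, Hassan, Ackland) are
# algebraically identical to arcsin(b / a); Widmer's linear approximation
# and the lateral Woo-Morrey reading deviate by construction.

METHOD_IDS <- c("reference", "liaw", "lewinnek", "widmer", "hassan",
                "ackland", "woo_morrey")

#' A single anteversion reading
#'
#' @param value_deg signed anteversion, degrees, in (-90, 90].
#' @param method method identifier (one of `"reference"`, `"liaw"`,
#'   `"lewinnek"`, `"widmer"`, `"hassan"`, `"ackland"`, `"woo_morrey"`).
#' @param in_validity_range logical flag; only meaningful for Widmer's
#'   linear formula (`NA` otherwise).
#' @return object of class `version_reading`.
#' @export
version_reading <- function(value_deg, method, in_validity_range = NA) {
  value_deg <- unname(value_deg)
  stopifnot_scalar(value_deg, "value_deg")
  if (!method %in% METHOD_IDS) {
    stop("unknown method id '", method, "'; valid ids: ",
         paste(METHOD_IDS, collapse = ", "), call. = FALSE)
  }
  structure(list(value_deg = value_deg, method = method,
                 in_validity_range = in_validity_range),
            class = "version_reading")
}

#' @export
print.version_reading <- function(x, ...) {
  flag <- if (isFALSE(x$in_validity_range)) " [out of validity range]" else ""
  cat(sprintf("<version_reading> %s: %.2f deg%s\n", x$method, x$value_deg, flag))
  invisible(x)
}

#' @export
as.numeric.version_reading <- function(x, ...) x$value_deg

#' Anteversion by the trigonometric beta-angle method (Liaw)
#'
#' `Version = arcsin(tan(beta))`, where beta is the angle at one end of the
#' component's long axis AB between AB and the line to the minor-axis
#' end-point of the ellipse. On an exact ellipse `tan(beta) = b / a`.
#'
#' @param lm a `liaw_landmarks` object from [extract_landmarks()], or `NULL`
#'   when `beta_deg` is given directly.
#' @param beta_deg the beta angle in degrees (must satisfy
#'   `tan(beta) <= 1`, i.e. beta <= 45 degrees).
#' @return a [version_reading()].
#' @export
version_liaw <- function(lm = NULL, beta_deg = NULL) {
  if (is.null(beta_deg)) {
    if (!inherits(lm, "liaw_landmarks")) stop("lm must be liaw_landmarks", call. = FALSE)
    AB <- lm$points$B - lm$points$A
    AE <- lm$points$E - lm$points$A
    beta_deg <- acos(clamp_unit(
      sum(AB * AE) / (sqrt(sum(AB^2)) * sqrt(sum(AE^2))), what = "cos(beta)")) * 180 / pi
  }
  tb <- tand(beta_deg)
  version_reading(asind(clamp_unit(tb, what = "tan(beta)")), "liaw")
}

#' Anteversion from the ellipse axis ratio (Lewinnek)
#'
#' `Version = arcsin(D1 / D2)`, D1 the full short axis of the projected
#' ellipse, D2 the full long axis (maximum implant diameter).
#'
#' @param lm a `lewinnek_measures` object, or `NULL` with `D1`, `D2` given.
#' @param D1,D2 short- and long-axis lengths, mm.
#' @return a [version_reading()].
#' @export
version_lewinnek <- function(lm = NULL, D1 = NULL, D2 = NULL) {
  if (is.null(D1)) { D1 <- lm$D1; D2 <- lm$D2 }
  stopifnot_scalar(D1, "D1"); stopifnot_scalar(D2, "D2", positive = TRUE)
  if (D1 < 0) stop("D1 must be >= 0", call. = FALSE)
  if (D1 > D2 * (1 + 1e-9)) stop("D1 > D2: inconsistent landmarks", call. = FALSE)
  version_reading(asind(clamp_unit(D1 / D2)), "lewinnek")
}

#' Anteversion from the short-axis / total-length ratio (Widmer)
#'
#' Canonical linear form `Version = 48.05 * (S / TL) - 0.3`, valid for
#' `0.2 < S/TL < 0.6`; outside that window the linear value is still
#' returned but flagged `in_validity_range = FALSE`. S is the full short
#' axis (identical to Lewinnek's D1); TL extends the short axis to the dome
#' apex of the component silhouette.
#'
#' @param lm a `widmer_measures` object, or `NULL` with `S`, `TL` given.
#' @param S,TL short axis and total length, mm (`0 < S < TL`).
#' @param form `"linear"` (canonical) or `"arcsin"` (the alternative printed
#'   form `arcsin(S/TL)`; the two are mutually inconsistent and the linear
#'   one carries the validity window).
#' @return a [version_reading()].
#' @export
#' @examples
#' version_widmer(S = 1, TL = 2)  # 48.05 * 0.5 - 0.3 = 23.725
version_widmer <- function(lm = NULL, S = NULL, TL = NULL,
                           form = c("linear", "arcsin")) {
  form <- match.arg(form)
  if (is.null(S)) { S <- lm$S; TL <- lm$TL }
  stopifnot_scalar(S, "S", positive = TRUE); stopifnot_scalar(TL, "TL", positive = TRUE)
  if (S >= TL) stop("S must be smaller than TL", call. = FALSE)
  ratio <- S / TL
  ok <- ratio > 0.2 && ratio < 0.6
  val <- if (form == "linear") 48.05 * ratio - 0.3 else asind(clamp_unit(ratio))
  version_reading(val, "widmer", in_validity_range = ok)
}

#' Anteversion from the head-uncovered rim point (Hassan)
#'
#' `Version = arcsin((h/D) / sqrt(m/D - m^2/D^2)) = arcsin(h / sqrt(m (D - m)))`,
#' D the maximum component diameter, m the long-axis distance to the point
#' where the rim emerges uncovered by the femoral head (the larger of the
#' two candidates), h the perpendicular distance from that point to the rim.
#'
#' @param lm a `hassan_measures` object, or `NULL` with `D`, `m`, `h` given.
#' @param D,m,h measurements in mm (`0 < m < D`, `h >= 0`).
#' @return a [version_reading()].
#' @export
version_hassan <- function(lm = NULL, D = NULL, m = NULL, h = NULL) {
  if (is.null(D)) { D <- lm$D; m <- lm$m; h <- lm$h }
  stopifnot_scalar(D, "D", positive = TRUE)
  stopifnot_scalar(m, "m"); stopifnot_scalar(h, "h")
  if (m <= 0 || m >= D) stop("m must lie strictly in (0, D)", call. = FALSE)
  if (h < 0) stop("h must be >= 0", call. = FALSE)
  version_reading(asind(clamp_unit(h / sqrt(m * (D - m)))), "hassan")
}

#' Anteversion from an arbitrary perpendicular tangent (Ackland)
#'
#' `Version = arcsin(2y / (2 sqrt(2ax - x^2))) = arcsin(y / sqrt(2ax - x^2))`,
#' a the semi-major axis, x the distance from the ellipse end along the
#' diametrical line to the tangent crossing, y the perpendicular half-chord
#' from the diametrical line to the rim at that tangent. On an exact ellipse
#' the reading is invariant to the choice of x.
#'
#' @param lm an `ackland_measures` object, or `NULL` with `a`, `x`, `y` given.
#' @param a,x,y measurements in mm (`0 < x < 2a`, `y >= 0`).
#' @return a [version_reading()].
#' @export
version_ackland <- function(lm = NULL, a = NULL, x = NULL, y = NULL) {
  if (is.null(a)) { a <- lm$a; x <- lm$x; y <- lm$y }
  stopifnot_scalar(a, "a", positive = TRUE)
  stopifnot_scalar(x, "x"); stopifnot_scalar(y, "y")
  if (x <= 0 || x >= 2 * a) stop("x must lie strictly in (0, 2a)", call. = FALSE)
  if (y < 0) stop("y must be >= 0", call. = FALSE)
  version_reading(asind(clamp_unit(y / sqrt(2 * a * x - x^2))), "ackland")
}

#' Anteversion measured on the cross-table lateral film (Woo-Morrey)
#'
#' The signed angle between the line touching the opening surface of the
#' component and the line drawn perpendicular to the table, measured
#' directly on the lateral film. Positive values indicate anteversion,
#' negative retroversion.
#'
#' @param lm a `lateral_measures` object (from [project_lateral()] or
#'   [perturb()]).
#' @return a [version_reading()].
#' @export
version_woo_morrey <- function(lm) {
  if (!inherits(lm, "lateral_measures")) stop("lm must be lateral_measures", call. = FALSE)
  ov <- lm$opening_line[2, ] - lm$opening_line[1, ]
  rv <- lm$reference_line[2, ] - lm$reference_line[1, ]
  no <- sqrt(sum(ov^2)); nr <- sqrt(sum(rv^2))
  if (no < 1e-9 || nr < 1e-9) stop("degenerate line in lateral measures", call. = FALSE)
  if (sum(ov * rv) < 0) ov <- -ov           # orient toward the reference end
  ang <- atan2d(ov[1] * rv[2] - ov[2] * rv[1], sum(ov * rv))
  if (ang > 90) ang <- ang - 180
  if (ang < -90) ang <- ang + 180
  if (abs(abs(ang) - 90) < 1e-9) {
    stop("opening line perpendicular to the reference line: sign ambiguous", call. = FALSE)
  }
  # film x-axis handedness makes a positive cross product the anteverted
  # direction in the lateral frame of project_lateral
  version_reading(-ang, "woo_morrey")
}

#' Apply a measurement method to its landmark object
#'
#' Dispatches on the landmark class produced by [extract_landmarks()],
#' [project_lateral()] or [perturb()].
#'
#' @param lm a landmark/measures object.
#' @return a [version_reading()].
#' @export
measure_version <- function(lm) {
  switch(class(lm)[1],
         liaw_landmarks = version_liaw(lm),
         lewinnek_measures = version_lewinnek(lm),
         widmer_measures = version_widmer(lm),
         hassan_measures = version_hassan(lm),
         ackland_measures = version_ackland(lm),
         lateral_measures = version_woo_morrey(lm),
         stop("no measurement method for class ", class(lm)[1], call. = FALSE))
}
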