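# Per-method landmark extraction from the projected geometry, plus the
# observer-noise model used to emulate intra- and inter-observer variation.
#
# Every landmark object stores the defining film POINTS; scalar measurements
# (D1, D2, S, TL, ...) are derived from the points, so observer jitter is
# applied to points and the scalars inherit it, as a human marking a film
# would produce.

new_landmarks <- function(class, points, extra = list()) {
  structure(c(list(points = points), extra), class = c(class, "method_landmarks"))
}

dist2 <- function(p, q) sqrt(sum((p - q)^2))

# Derive the scalar measurements of each landmark class from its points.
finalize_landmarks <- function(lm) {
  p <- lm$points
  switch(class(lm)[1],
    liaw_landmarks = lm,
    lewinnek_measures = { lm$D1 <- dist2(p$S1, p$S2); lm$D2 <- dist2(p$A, p$B); lm },
    widmer_measures = { lm$S <- dist2(p$S1, p$S2); lm$TL <- dist2(p$S1, p$apex); lm },
    hassan_measures = {
      lm$D <- dist2(p$A, p$B); lm$m <- dist2(p$A, p$U); lm$h <- dist2(p$U, p$rim); lm
    },
    ackland_measures = {
      lm$a <- dist2(p$A, p$B) / 2; lm$x <- dist2(p$A, p$X); lm$y <- dist2(p$X, p$rim); lm
    },
    lateral_measures = lm,
    stop("unknown landmark class", call. = FALSE))
}

valid_landmarks <- function(lm) {
  ok <- switch(class(lm)[1],
    liaw_landmarks = TRUE,
    lewinnek_measures = lm$D1 >= 0 && lm$D1 <= lm$D2 && lm$D2 > 0,
    widmer_measures = lm$S > 0 && lm$S < lm$TL,
    hassan_measures = lm$m > 0 && lm$m < lm$D && lm$h >= 0 &&
      lm$h <= sqrt(lm$m * (lm$D - lm$m)),
    ackland_measures = lm$x > 0 && lm$x < 2 * lm$a && lm$y >= 0 &&
      lm$y <= sqrt(2 * lm$a * lm$x - lm$x^2),
    lateral_measures = dist2(lm$opening_line[1, ], lm$opening_line[2, ]) > 1e-9 &&
      dist2(lm$reference_line[1, ], lm$reference_line[2, ]) > 1e-9,
    FALSE)
  isTRUE(ok)
}

#' Extract a method's landmarks from the projected ellipse
#'
#' Places the film points each published method requires on the analytic
#' projected geometry: ellipse axis end-points, the dome apex of the
#' component silhouette (for Widmer's total length), the rim point emerging
#' uncovered by the femoral head (Hassan), or an arbitrary perpendicular
#' tangent crossing (Ackland). Noise-free extraction satisfies
#' `D1 = 2 b`, `D2 = 2 a`, `S = D1`, `TL = a + b`, and the half-chord
#' identities that make the four AP ellipse methods agree exactly.
#'
#' @param ellipse an [ellipse_params()] (the AP rim projection).
#' @param method one of `"liaw"`, `"lewinnek"`, `"widmer"`, `"hassan"`,
#'   `"ackland"`.
#' @param silhouette optional [project_silhouette()] result (not required;
#'   the dome apex is placed at shell radius = `semi_major` under the
#'   parallel-beam model).
#' @param head_radius_mm prosthetic-head radius, mm; required by Hassan's
#'   method, where the uncovered rim point exists only when the head radius
#'   is smaller than the cup radius.
#' @param ackland_x_fraction position of Ackland's arbitrary tangent along
#'   the diametrical line, as a fraction of `2a` in (0, 1); the noise-free
#'   reading is invariant to it.
#' @param opening_side `+1` or `-1`: which minor-axis direction faces the
#'   cup opening (affects point placement only, not the noise-free scalars).
#' @return a landmark object of the method's class.
#' @export
extract_landmarks <- function(ellipse, method = c("liaw", "lewinnek", "widmer",
                                                  "hassan", "ackland"),
                              silhouette = NULL, head_radius_mm = 14,
                              ackland_x_fraction = 0.5, opening_side = 1) {
  method <- match.arg(method)
  ax <- ellipse_axes(ellipse)
  ctr <- ellipse$centre_film_mm
  a <- ellipse$semi_major_mm; b <- ellipse$semi_minor_mm
  u <- ax$major; mo <- ax$minor * sign(opening_side)
  A <- ctr - a * u; B <- ctr + a * u

  switch(method,
    liaw = new_landmarks("liaw_landmarks",
      list(A = A, B = B, E = ctr + b * mo)),
    lewinnek = finalize_landmarks(new_landmarks("lewinnek_measures",
      list(S1 = ctr + b * mo, S2 = ctr - b * mo, A = A, B = B))),
    widmer = finalize_landmarks(new_landmarks("widmer_measures",
      # S1 = rim-side end of the short axis (opening side); apex = dome apex
      # of the sphere silhouette, at shell radius opposite the opening
      list(S1 = ctr + b * mo, S2 = ctr - b * mo, apex = ctr - a * mo))),
    hassan = {
      if (head_radius_mm >= a) {
        stop("femoral head (radius ", head_radius_mm,
             " mm) covers the whole rim: Hassan's uncovered point is unidentifiable",
             call. = FALSE)
      }
      # the long axis leaves the head shadow at distance head_radius from the
      # centre; take the candidate giving the LARGER m, ties toward the
      # superior rim (positive film-y end)
      end_sup <- if ((B - A)[2] >= 0) "B" else "A"
      U <- ctr + head_radius_mm * u
      Astart <- A
      if (dist2(Astart, U) < dist2(Astart, ctr - head_radius_mm * u)) {
        U <- ctr - head_radius_mm * u
      }
      h <- b * sqrt(max(0, 1 - (head_radius_mm / a)^2))
      finalize_landmarks(new_landmarks("hassan_measures",
        list(A = Astart, B = B, U = U, rim = U + h * mo)))
    },
    ackland = {
      if (ackland_x_fraction <= 0 || ackland_x_fraction >= 1) {
        stop("ackland_x_fraction must lie in (0, 1)", call. = FALSE)
      }
      xlen <- ackland_x_fraction * 2 * a
      X <- A + xlen * u
      t <- xlen - a
      y <- b * sqrt(max(0, 1 - (t / a)^2))
      finalize_landmarks(new_landmarks("ackland_measures",
        list(A = A, B = B, X = X, rim = X + y * mo)))
    })
}

#' Observer noise model
#'
#' Emulates a human observer marking landmarks on film: isotropic Gaussian
#' jitter on every landmark point, plus a systematic per-observer offset per
#' landmark role (drawn once per observer, constant across patients and
#' sessions) that separates inter- from intra-observer variability.
#'
#' @param landmark_sd_mm isotropic jitter standard deviation, mm (>= 0).
#' @param observer_bias_mm standard deviation of the per-observer systematic
#'   offset, mm (>= 0).
#' @param seed integer base seed; all noise is a deterministic function of
#'   (seed, observer_id, session, patient, landmark role).
#' @param observer_id integer observer label.
#' @return an `observer_model` object.
#' @export
observer_model <- function(landmark_sd_mm = 0.5, observer_bias_mm = 0.3,
                           seed = 1L, observer_id = 1L) {
  stopifnot_scalar(landmark_sd_mm, "landmark_sd_mm")
  stopifnot_scalar(observer_bias_mm, "observer_bias_mm")
  if (landmark_sd_mm < 0 || observer_bias_mm < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  structure(list(landmark_sd_mm = landmark_sd_mm,
                 observer_bias_mm = observer_bias_mm,
                 seed = as.integer(seed), observer_id = as.integer(observer_id)),
            class = "observer_model")
}

observer_bias_offset <- function(observer, role_index) {
  if (observer$observer_bias_mm == 0) return(c(0, 0))
  with_seed(derive_seed(observer$seed, 7919L, observer$observer_id, role_index),
            stats::rnorm(2, 0, observer$observer_bias_mm))
}

perturb_points <- function(points, observer, session, patient_id, method_tag,
                           attempt) {
  sd <- observer$landmark_sd_mm
  nm <- names(points)
  out <- points
  for (i in seq_along(points)) {
    bias <- observer_bias_offset(observer, i)
    jit <- with_seed(
      derive_seed(observer$seed, observer$observer_id, session, patient_id,
                  method_tag, i, attempt),
      stats::rnorm(2, 0, sd))
    out[[i]] <- points[[i]] + bias + jit
  }
  names(out) <- nm
  out
}

#' Corrupt landmarks with observer noise
#'
#' Jitters every defining film point with the observer's Gaussian model and
#' re-derives the scalar measurements. Deterministic for fixed
#' (seed, observer, session, patient); landmark-type invariants are
#' re-checked after jittering and violating draws are resampled (bounded
#' retries).
#'
#' @param landmarks a landmark object from [extract_landmarks()] or
#'   [project_lateral()].
#' @param observer an [observer_model()].
#' @param session integer session index (repeat readings).
#' @param patient_id integer patient index.
#' @param max_retries retry budget for invariant-violating draws.
#' @return a landmark object of the same class.
#' @export
perturb <- function(landmarks, observer, session = 1L, patient_id = 1L,
                    max_retries = 100L) {
  if (!inherits(landmarks, "method_landmarks") &&
      !inherits(landmarks, "lateral_measures")) {
    stop("landmarks must come from extract_landmarks() or project_lateral()",
         call. = FALSE)
  }
  if (observer$landmark_sd_mm == 0 && observer$observer_bias_mm == 0) {
    return(landmarks)
  }
  cls <- class(landmarks)[1]
  method_tag <- sum(utf8ToInt(cls))
  for (attempt in seq_len(max_retries)) {
    cand <- landmarks
    if (cls == "lateral_measures") {
      pts <- list(o1 = landmarks$opening_line[1, ], o2 = landmarks$opening_line[2, ],
                  r1 = landmarks$reference_line[1, ], r2 = landmarks$reference_line[2, ])
      # the reference line is a drawn vertical, not an anatomical landmark:
      # jitter its free end only, keeping it a plausible hand-drawn line
      pp <- perturb_points(pts, observer, session, patient_id, method_tag, attempt)
      cand$opening_line <- rbind(pp$o1, pp$o2)
      colnames(cand$opening_line) <- c("x_mm", "y_mm")
    } else {
      cand$points <- perturb_points(landmarks$points, observer, session,
                                    patient_id, method_tag, attempt)
      cand <- finalize_landmarks(cand)
    }
    if (valid_landmarks(cand)) {
      ok <- tryCatch({ measure_version_maybe(cand); TRUE }, error = function(e) FALSE)
      if (ok) return(cand)
    }
  }
  stop("perturb(): retry budget exhausted (landmark sd too large for this geometry)",
       call. = FALSE)
}

# liaw landmarks have no applicable scalar check beyond the formula itself
measure_version_maybe <- function(lm) {
  if (inherits(lm, "lateral_measures")) version_woo_morrey(lm) else measure_version(lm)
}
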