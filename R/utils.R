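# Degree-based trigonometry and small shared helpers.

sind <- function(x) sin(x * pi / 180)
cosd <- function(x) cos(x * pi / 180)
tand <- function(x) tan(x * pi / 180)
asind <- function(x) asin(x) * 180 / pi
atan2d <- function(y, x) atan2(y, x) * 180 / pi

#' Clamp an arcsine argument that is out of range by floating-point noise only
#'
#' Arguments within `tol` of [-1, 1] are clamped to the boundary; anything
#' further out signals inconsistent landmarks and raises an error.
#' @keywords internal
clamp_unit <- function(x, tol = 1e-9, what = "arcsin argument") {
  if (is.na(x)) stop(what, " is NA", call. = FALSE)
  if (x > 1 + tol || x < -1 - tol) {
    stop(what, " = ", format(x), " is outside [-1, 1]: inconsistent landmarks",
         call. = FALSE)
  }
  min(1, max(-1, x))
}

# Deterministic sub-stream seed from a base seed and integer tags.
# Kept below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, ...) {
  tags <- c(seed, ...)
  h <- 0
  for (t in tags) h <- (h * 69069 + (as.numeric(t) %% 2147483647) + 1) %% 2147483647
  as.integer(h)
}

# Run expr with a local RNG state seeded from `seed` (restores caller's RNG).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("`", name, "` must be a single non-missing number", call. = FALSE)
  }
  if (positive && x <= 0) stop("`", name, "` must be > 0", call. = FALSE)
  invisible(x)
}

fold_orientation <- function(theta_deg) {
  out <- theta_deg %% 180
  if (out < 0) out <- out + 180
  if (out >= 180 - 1e-12) out <- 0
  out
}
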