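# Landmark extraction per method and the observer-noise model.

test_that("noise-free extraction reproduces the defining measurement identities", {
  e <- ellipse_params(c(0, 0), 25, 12.5, 30)
  lw <- extract_landmarks(e, "lewinnek")
  expect_equal(lw$D1, 25)
  expect_equal(lw$D2, 50)
  wd <- extract_landmarks(e, "widmer")
  expect_equal(wd$S, 25)
  expect_equal(wd$TL, 37.5)      # short-axis rim edge through centre to apex
  ak <- extract_landmarks(e, "ackland", ackland_x_fraction = 0.5)
  expect_equal(ak$a, 25)
  expect_equal(ak$x, 25)
  expect_equal(ak$y, 12.5)       # chord through the centre has half-width b
  hs <- extract_landmarks(e, "hassan", head_radius_mm = 14)
  expect_equal(hs$D, 50)
  expect_equal(hs$m, 25 + 14)    # the larger candidate distance
  expect_equal(hs$h, 12.5 * sqrt(1 - (14 / 25)^2))
  li <- extract_landmarks(e, "liaw")
  expect_equal(cupver:::dist2(li$points$A, li$points$B), 50)
})

test_that("landmark points honour the ellipse geometry for any orientation", {
  for (p in random_poses(10, seed = 21)) {
    e <- project_rim(p)
    lw <- extract_landmarks(e, "lewinnek")
    expect_equal(lw$D1, 2 * e$semi_minor_mm, tolerance = 1e-9)
    expect_equal(lw$D2, 2 * e$semi_major_mm, tolerance = 1e-9)
    wd <- extract_landmarks(e, "widmer")
    expect_equal(wd$TL, e$semi_major_mm + e$semi_minor_mm, tolerance = 1e-9)
  }
})

test_that("Hassan identifiability: error exactly when the head covers the rim", {
  e <- ellipse_params(c(0, 0), 25, 10, 0)
  expect_silent(extract_landmarks(e, "hassan", head_radius_mm = 24.9))
  expect_error(extract_landmarks(e, "hassan", head_radius_mm = 25), "unidentifiable")
  expect_error(extract_landmarks(e, "hassan", head_radius_mm = 26), "unidentifiable")
})

test_that("Ackland extraction is invariant to the tangent position on exact data", {
  e <- ellipse_params(c(3, -2), 27, 9, 70)
  vals <- sapply(c(0.1, 0.25, 0.5, 0.8, 0.95), function(fr) {
    version_ackland(extract_landmarks(e, "ackland", ackland_x_fraction = fr))$value_deg
  })
  expect_lt(max(vals) - min(vals), 1e-9)
  expect_error(extract_landmarks(e, "ackland", ackland_x_fraction = 1), "fraction")
})

test_that("perturb is the identity at zero noise and deterministic otherwise", {
  e <- ellipse_params(c(0, 0), 25, 8, 40)
  lm <- extract_landmarks(e, "lewinnek")
  obs0 <- observer_model(0, 0, seed = 1, observer_id = 1)
  expect_identical(perturb(lm, obs0, 1, 1), lm)
  obs <- observer_model(0.5, 0.2, seed = 9, observer_id = 2)
  a <- perturb(lm, obs, session = 1, patient_id = 4)
  b <- perturb(lm, obs, session = 1, patient_id = 4)
  c2 <- perturb(lm, obs, session = 2, patient_id = 4)
  expect_identical(a, b)
  expect_false(identical(a$D1, c2$D1))
  expect_false(identical(a$D1, lm$D1))
})

test_that("perturbed landmarks keep their type invariants; pathological sd errors", {
  e <- ellipse_params(c(0, 0), 25, 8, 40)
  obs <- observer_model(1.5, 0, seed = 2, observer_id = 1)
  for (m in c("lewinnek", "widmer", "hassan", "ackland")) {
    for (s in 1:20) {
      lm <- perturb(extract_landmarks(e, m), obs, session = s, patient_id = 1)
      expect_true(cupver:::valid_landmarks(lm))
    }
  }
  # landmarks whose invariant cannot survive small jitter exhaust the budget
  impossible <- cupver:::finalize_landmarks(cupver:::new_landmarks(
    "widmer_measures",
    list(S1 = c(0, 0), S2 = c(50, 0), apex = c(0.05, 0))))  # S >> TL
  obs_small <- observer_model(0.1, 0, seed = 3, observer_id = 1)
  expect_error(perturb(impossible, obs_small, 1, 1, max_retries = 25),
               "retry budget")
})

test_that("0.5 mm landmark jitter maps to degree-scale reading noise (delta method)", {
  e <- ellipse_params(c(0, 0), 25, 25 * sind(19.4), 45)
  obs <- observer_model(0.5, 0, seed = 4, observer_id = 1)
  lm0 <- extract_landmarks(e, "lewinnek")
  vals <- sapply(1:300, function(s) {
    version_lewinnek(perturb(lm0, obs, session = s, patient_id = 1))$value_deg
  })
  # analytic delta method: var = (dv/dD1)^2 var(D1) + (dv/dD2)^2 var(D2),
  # each full-axis length jittered by two endpoints -> sd 0.5 * sqrt(2)
  a <- 25; b <- 25 * sind(19.4)
  dv1 <- (180 / pi) / (2 * a * cosd(19.4))
  dv2 <- (180 / pi) * 2 * b / ((2 * a)^2 * cosd(19.4))
  sd_pred <- sqrt((dv1^2 + dv2^2) * (0.5^2 * 2))
  expect_equal(sd(vals), sd_pred, tolerance = 0.2)
  expect_gt(sd(vals), 0.5); expect_lt(sd(vals), 2)
})

test_that("per-observer bias is constant within an observer, differs between them", {
  e <- ellipse_params(c(0, 0), 25, 10, 0)
  lm0 <- extract_landmarks(e, "lewinnek")
  o1 <- observer_model(0, 0.4, seed = 6, observer_id = 1)
  o2 <- observer_model(0, 0.4, seed = 6, observer_id = 2)
  a1 <- perturb(lm0, o1, session = 1, patient_id = 1)
  a2 <- perturb(lm0, o1, session = 2, patient_id = 9)
  b1 <- perturb(lm0, o2, session = 1, patient_id = 1)
  expect_equal(a1$D1, a2$D1, tolerance = 1e-12)  # pure bias: same everywhere
  expect_false(isTRUE(all.equal(a1$D1, b1$D1)))
})
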