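# AP and lateral projection geometry, silhouettes, and the ray-trace oracle.

test_that("parallel-beam rim projection obeys the sin(anteversion) closed form", {
  for (p in random_poses(40, seed = 11)) {
    e <- project_rim(p)
    expect_equal(e$semi_major_mm, p$radius_mm, tolerance = 1e-9)
    expect_equal(e$semi_minor_mm / e$semi_major_mm, sind(abs(p$anteversion_deg)),
                 tolerance = 1e-9)
  }
  # degenerate poses at the domain edges
  expect_equal(project_rim(cup_pose(1e-12, 45, 25))$semi_minor_mm, 0,
               tolerance = 1e-9)
  e90 <- project_rim(cup_pose(89.999999, 45, 25))
  expect_equal(e90$semi_minor_mm / e90$semi_major_mm, 1, tolerance = 1e-6)
})

test_that("rotation about the beam axis rotates the ellipse, axes unchanged", {
  base <- cup_pose(22, 40, 26)
  e0 <- project_rim(base)
  for (delta in c(5, 12.5)) {
    e1 <- project_rim(cup_pose(22, 40 + delta, 26))
    expect_equal(e1$semi_major_mm, e0$semi_major_mm, tolerance = 1e-9)
    expect_equal(e1$semi_minor_mm, e0$semi_minor_mm, tolerance = 1e-9)
    rot <- (e1$orientation_deg - e0$orientation_deg) %% 180
    expect_equal(min(rot, 180 - rot), delta, tolerance = 1e-9)
  }
})

test_that("left/right mirroring mirrors film x-coordinates only", {
  pr <- cup_pose(19.4, 45, 25, centre_mm = c(40, 10, -150), side = "right")
  pl <- cup_pose(19.4, 45, 25, centre_mm = c(-40, 10, -150), side = "left")
  er <- project_rim(pr); el <- project_rim(pl)
  expect_equal(el$centre_film_mm, er$centre_film_mm * c(-1, 1))
  expect_equal(el$semi_major_mm, er$semi_major_mm)
  expect_equal(el$semi_minor_mm, er$semi_minor_mm)
  expect_equal(el$orientation_deg %% 180, (180 - er$orientation_deg) %% 180,
               tolerance = 1e-9)
  sr <- project_silhouette(pr, n_points = 17)
  sl <- project_silhouette(pl, n_points = 17)
  for (curve in c("dome_points", "rim_points")) {
    expect_equal(range(sl[[curve]][, "x_mm"]), -rev(range(sr[[curve]][, "x_mm"])),
                 tolerance = 1e-9, label = curve)
    expect_equal(range(sl[[curve]][, "y_mm"]), range(sr[[curve]][, "y_mm"]),
                 tolerance = 1e-9, label = curve)
  }
  # head circle sampling phase differs between sides; check the mirrored
  # analytic constraint instead
  hd <- sweep(sl$head_points, 2, c(-40, 10))
  expect_lt(max(abs(sqrt(rowSums(hd^2)) - 14)), 1e-9)
})

test_that("noise-free silhouette points lie on the analytic conics", {
  p <- cup_pose(30, 45, 25)
  e <- project_rim(p)
  sp <- project_silhouette(p, n_points = 100, head_radius_mm = 14)
  ax <- cupver:::ellipse_axes(e)
  rel <- sweep(sp$rim_points, 2, e$centre_film_mm)
  xi <- rel %*% ax$major; eta <- rel %*% ax$minor
  expect_lt(max(abs((xi / e$semi_major_mm)^2 + (eta / e$semi_minor_mm)^2 - 1)), 1e-9)
  hd <- sweep(sp$head_points, 2, e$centre_film_mm)
  expect_lt(max(abs(sqrt(rowSums(hd^2)) - 14)), 1e-9)
  dd <- sweep(sp$dome_points, 2, e$centre_film_mm)
  expect_lt(max(abs(sqrt(rowSums(dd^2)) - p$radius_mm)), 1e-9)
})

test_that("dome apex sits at shell radius along the minor axis from the centre", {
  for (p in random_poses(10, seed = 3)) {
    e <- project_rim(p)
    sp <- project_silhouette(p, n_points = 101)
    ax <- cupver:::ellipse_axes(e)
    rel <- sweep(sp$dome_points, 2, e$centre_film_mm)
    proj_minor <- abs(rel %*% ax$minor)
    # the apex (extreme point along the minor direction) is at full radius
    expect_equal(max(proj_minor), p$radius_mm, tolerance = 1e-6)
  }
})

test_that("silhouette jitter is reproducible and seed-sensitive", {
  p <- cup_pose(25, 45, 25)
  s1 <- project_silhouette(p, n_points = 10, noise_sd_mm = 0.5, rng_seed = 42)
  s2 <- project_silhouette(p, n_points = 10, noise_sd_mm = 0.5, rng_seed = 42)
  s3 <- project_silhouette(p, n_points = 10, noise_sd_mm = 0.5, rng_seed = 43)
  expect_identical(s1$rim_points, s2$rim_points)
  expect_false(identical(s1$rim_points, s3$rim_points))
})

test_that("point-source projection: near-parallel at clinical distance, errors outside cone", {
  p <- cup_pose(20, 45, 25, centre_mm = c(0, 0, -150))
  e_par <- project_rim(p, beam_geometry())
  e_ps <- project_rim(p, beam_geometry(mode = "point_source"))
  r_par <- e_par$semi_minor_mm / e_par$semi_major_mm
  r_ps <- e_ps$semi_minor_mm / e_ps$semi_major_mm
  expect_lt(abs(r_par - r_ps), 0.01)
  expect_gt(e_ps$semi_major_mm, e_par$semi_major_mm)  # magnification > 1
  # centre outside the film field -> beam-cone error
  p_out <- cup_pose(20, 45, 25, centre_mm = c(400, 0, -150))
  expect_error(project_rim(p_out, beam_geometry(mode = "point_source")),
               "beam cone")
  p_behind <- cup_pose(20, 45, 25, centre_mm = c(0, 0, 10))
  expect_error(project_rim(p_behind, beam_geometry(mode = "point_source")),
               "between")
})

test_that("lateral projection: sign convention and standardized overestimation", {
  # zero anteversion with axis in the table-perpendicular plane reads zero
  expect_equal(project_lateral(cup_pose(1e-9, 45, 25))$angle_deg, 0,
               tolerance = 1e-6)
  # retroverted cups read negative on either side
  expect_lt(project_lateral(cup_pose(-12, 45, 25, side = "right"))$angle_deg, 0)
  expect_lt(project_lateral(cup_pose(-12, 45, 25, side = "left"))$angle_deg, 0)
  # the standardized 45-degree cephalad beam overestimates: reading exceeds
  # truth across the clinical inclination range
  for (incl in c(30, 37.5, 45, 52.5, 55)) {
    reading <- project_lateral(cup_pose(19.4, incl, 25))$angle_deg
    expect_gt(reading, 19.4)
  }
  # ideal positioning closed form: tan(reading) = tan(av) / cos(cephalad)
  got <- project_lateral(cup_pose(19.4, 45, 25))$angle_deg
  expect_equal(got, atan2d(tand(19.4) / cosd(45), 1), tolerance = 1e-6)
  # degenerate cephalad angles are rejected at construction
  expect_error(beam_geometry(film = "crosstable_lateral", crosstable_cephalad_deg = 0),
               "degenerate")
  expect_error(beam_geometry(film = "crosstable_lateral", crosstable_cephalad_deg = 90),
               "degenerate")
})

test_that("ray-traced boundary agrees with the analytic projection within a pixel", {
  px <- 0.2
  for (p in random_poses(4, seed = 5)) {
    img <- ray_trace_oracle(p, pixel_mm = px, head_radius_mm = 14)
    bp <- boundary_points(img$cup, img$x_mm, img$y_mm)
    e <- project_rim(p)
    expect_lt(max(dist_to_cup_silhouette(bp, e, p$radius_mm)), px * 1.0001)
    # fitted axis ratio from the full image pipeline close to sin(av)
    rf <- reference_from_image(img)
    expect_lt(abs(rf$ellipse$semi_minor_mm / rf$ellipse$semi_major_mm -
                    sind(abs(p$anteversion_deg))), 0.01)
  }
})

test_that("ray-trace oracle rejects an image extent smaller than the implant", {
  expect_error(ray_trace_oracle(cup_pose(20, 45, 25), extent_mm = 10),
               "extent")
})

test_that("parallel and point-source renderings nearly coincide at 115 cm", {
  p <- cup_pose(20, 45, 25, centre_mm = c(0, 0, -20))
  i1 <- ray_trace_oracle(p, beam_geometry(), pixel_mm = 0.25)
  i2 <- ray_trace_oracle(p, beam_geometry(mode = "point_source"), pixel_mm = 0.25)
  r1 <- reference_from_image(i1)$reading$value_deg
  r2 <- reference_from_image(i2)$reading$value_deg
  expect_lt(abs(sind(r1) - sind(r2)), 0.01)
})
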