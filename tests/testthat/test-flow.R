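# flow_analysis module: plane flow, phases, volumes, subsection, traces,
# centerline, VNR, perturbations

test_that("plane flow of a uniform field equals area x speed", {
  fld <- uniform_field(v = c(0, 0, 10), gs = c(24, 24, 24))
  # 1 cm^2 circular roi: r = sqrt(100/pi) mm
  pl <- analysis_plane(c(17, 17, 17), c(0, 0, 1),
                       roi_radius_mm = sqrt(100 / pi))
  tr <- compute_flow_trace(fld, pl)
  expect_equal(tr$flow_ml_s[1], 10, tolerance = 0.03)
  # zero field: identically zero
  z <- uniform_field(v = c(0, 0, 0), gs = c(24, 24, 24))
  expect_equal(compute_flow_trace(z, pl)$flow_ml_s, 0)
  # flipping antegrade_sign negates the trace
  pl2 <- analysis_plane(c(17, 17, 17), c(0, 0, 1), sqrt(100 / pi),
                        antegrade_sign = -1)
  expect_equal(compute_flow_trace(fld, pl2)$flow_ml_s, -tr$flow_ml_s)
  # an oblique plane sees v . n
  pl3 <- analysis_plane(c(17, 17, 17), c(0, 1, 1), sqrt(100 / pi))
  expect_equal(compute_flow_trace(fld, pl3)$flow_ml_s[1], 10 / sqrt(2),
               tolerance = 0.03)
  # roi entirely outside the volume errors
  pl4 <- analysis_plane(c(500, 500, 500), c(0, 0, 1), 5)
  expect_error(compute_flow_trace(fld, pl4), "does not intersect")
})

test_that("cardiac phase detection follows the 10%-onset / zero-crossing rule", {
  n <- 20
  q <- c(sin(pi * (0:9) / 10), rep(0, 10))
  tr <- flow_trace((0:(n - 1)) * 0.05, q)
  ph <- detect_cardiac_phases(tr)
  expect_equal(range(ph$systole), c(1, 10))
  expect_equal(sort(ph$diastole), 11:20)
  # pure positive constant flow: fallback to the post-peak minimum
  trc <- flow_trace((0:9) * 0.1, rep(3, 10))
  expect_silent(phc <- detect_cardiac_phases(trc))
  expect_true(length(phc$systole) >= 1)
  expect_error(detect_cardiac_phases(flow_trace((0:9) * 0.1, rep(0, 10))),
               "all-zero")
  # phantom with prescribed systolic fraction 0.35 of a 20-frame cycle:
  # detected systole length 7 +/- 1 frames
  wf <- waveform_spec(period_s = 1, n_frames = 20, systolic_fraction = 0.35,
                      antegrade_tear_volume_ml = 10,
                      diastolic_retrograde_volume_ml = 0)
  gt_q <- flumen:::tear_flow_samples(wf)
  trp <- flow_trace(gt_q$time_s, gt_q$flow_ml_s)
  php <- detect_cardiac_phases(trp)
  expect_lte(abs(length(php$systole) - 7), 1)
})

test_that("antegrade / retrograde volumes integrate the prescribed trace", {
  wf <- waveform_spec(n_frames = 21, antegrade_tear_volume_ml = 10,
                      diastolic_retrograde_volume_ml = 4.9)
  gt <- flumen:::tear_flow_samples(wf)
  tr <- flow_trace(gt$time_s, gt$flow_ml_s, period_s = wf$period_s)
  ph <- cardiac_phases(gt$systole_frames, wf$n_frames)
  vols <- antegrade_retrograde_volumes(tr, ph)
  expect_equal(vols$antegrade_ml, 10, tolerance = 1e-10)
  expect_equal(vols$retrograde_diastolic_ml, 4.9, tolerance = 1e-10)
  # doubling the trace doubles both
  tr2 <- flow_trace(gt$time_s, 2 * gt$flow_ml_s, period_s = wf$period_s)
  vols2 <- antegrade_retrograde_volumes(tr2, ph)
  expect_equal(vols2$antegrade_ml, 20, tolerance = 1e-10)
  expect_equal(vols2$retrograde_diastolic_ml, 9.8, tolerance = 1e-10)
  # non-negative trace: zero retrograde
  tr3 <- flow_trace(gt$time_s, pmax(gt$flow_ml_s, 0),
                    period_s = wf$period_s)
  expect_equal(antegrade_retrograde_volumes(tr3, ph)$retrograde_diastolic_ml,
               0)
})

test_that("FL subsection extraction follows the landmark / 5 cm rules", {
  mask <- make_dissection_mask(small_geometry(c(40, 32, 64)))
  hz <- mask$voxel_size[3]
  fl_z <- function(m) {
    ks <- which(apply(m$labels == 2L, 3, any))
    ((range(ks)) - 1) * hz
  }
  # no landmark: +/- 2.5 cm around the tear
  sub <- extract_fl_subsection(mask, tear_axial_position_mm = 80)
  expect_equal(fl_z(sub), c(55, 105), tolerance = hz)
  expect_true(all(sub$labels %in% c(0L, 2L)))
  # landmark bounds the span
  sub2 <- extract_fl_subsection(mask, 80, 60)
  expect_equal(fl_z(sub2), c(60, 80), tolerance = hz)
  # tear near the domain edge: truncated with a warning
  expect_warning(sub3 <- extract_fl_subsection(mask, 10), "truncated")
  expect_equal(fl_z(sub3)[1], 0, tolerance = hz)
  expect_error(extract_fl_subsection(
    lumen_mask(array(1L, c(4, 4, 4)), rep(1, 3)), 2), "no FL")
})

test_that("mean speed and cyclic differentiation behave as calculus says", {
  mf <- msdr_field(V = 40, P = 1.0, n = 20)
  tr <- mean_speed_trace(mf$field, mf$sub)
  expect_equal(tr$mean_speed_cm_s,
               40 * (1 + sin(2 * pi * tr$time_s / 1.0)), tolerance = 1e-10)
  tr <- differentiate_trace(tr)
  # acceleration integrates (cyclically) to ~ 0 over a period
  dt <- tr$time_s[2] - tr$time_s[1]
  expect_lt(abs(sum(tr$acceleration_cm_s2) * dt), 1e-9)
  # constant field: zero acceleration
  cf <- uniform_field(v = c(0, 0, 25), gs = c(6, 6, 6), nt = 5)
  trc <- differentiate_trace(mean_speed_trace(cf, array(TRUE, c(6, 6, 6))))
  expect_equal(trc$acceleration_cm_s2, rep(0, 5))
  # exact discrete identity: cumulative re-integration of the cyclic central
  # difference reconstructs the two-frame midpoint average of the speed
  s <- tr$mean_speed_cm_s
  n <- length(s)
  mid <- (s + s[c(2:n, 1)]) / 2
  rec <- cumsum(tr$acceleration_cm_s2) * dt
  expect_equal(rec - rec[1], mid - mid[1], tolerance = 1e-9)
  # single-frame fields cannot be differentiated
  one <- uniform_field(nt = 1, gs = c(6, 6, 6))
  expect_error(differentiate_trace(mean_speed_trace(
    one, array(TRUE, c(6, 6, 6)))), "3 frames")
  # sinusoid: peak acceleration ~ 2 pi V / P (up to the sinc factor of the
  # central-difference operator at this sampling)
  a_pk <- max(tr$acceleration_cm_s2)
  sinc_fac <- sin(2 * pi / 20) / (2 * pi / 20)
  expect_equal(a_pk, 2 * pi * 40 / 1.0 * sinc_fac, tolerance = 0.01)
})

test_that("centerline length is geodesic", {
  # straight 200 mm tube
  ph <- small_tube(h_in = 3, hz = 5, R = 9, L = 205)
  p1 <- analysis_plane(c(0, 0, 0), c(0, 0, 1), 9)
  p2 <- analysis_plane(c(0, 0, 200), c(0, 0, 1), 9)
  len <- centerline_length(ph$mask, "TL", p1, p2)
  expect_equal(len, 0.200, tolerance = 0.05 * 0.200)
  # start = end: zero
  expect_equal(centerline_length(ph$mask, "TL", p1, p1), 0)
  # U-bend: longer than the end-to-end chord
  gs <- c(30, 10, 30); vox <- c(2, 2, 2)
  lab <- array(0L, gs)
  lab[3:6, 4:7, 3:26] <- 1L          # up arm
  lab[24:27, 4:7, 3:26] <- 1L        # down arm
  lab[3:27, 4:7, 24:26] <- 1L        # connector
  um <- lumen_mask(lab, vox)
  a <- analysis_plane(c(7, 10, 4) , c(0, 0, 1), 4)
  b <- analysis_plane(c(49, 10, 4), c(0, 0, 1), 4)
  ulen <- centerline_length(um, "TL", a, b)
  chord <- sqrt(sum((c(49, 10, 4) - c(7, 10, 4))^2)) / 1000
  expect_gt(ulen, chord)
  # disconnected lumen errors
  lab2 <- lab; lab2[, , 20] <- 0L; lab2[15, 5, 20] <- 1L  # keep label present
  lab2[15, 5, 20] <- 0L; lab2[, , 24:26] <- 0L
  dm <- lumen_mask(lab2, vox)
  expect_error(centerline_length(dm, "TL", a, b), "disconnected")
})

test_that("VNR estimation recovers the generating noise level", {
  fld <- uniform_field(v = c(0, 0, 0), gs = c(24, 24, 12), nt = 3)
  noisy <- add_velocity_noise(fld, vnr = 40, seed = 21)
  roi <- array(FALSE, c(24, 24, 12)); roi[1:10, 1:10, ] <- TRUE
  vnr <- estimate_vnr(noisy, roi)
  expect_equal(vnr, 40, tolerance = 40 * 0.05)
  # roi-size invariance within sampling error
  roi2 <- array(FALSE, c(24, 24, 12)); roi2[1:20, 1:20, ] <- TRUE
  expect_equal(estimate_vnr(noisy, roi2), vnr, tolerance = vnr * 0.10)
  # noise-free: infinite with a warning
  expect_warning(v0 <- estimate_vnr(fld, roi), "noise-free")
  expect_identical(v0, Inf)
  expect_error(estimate_vnr(noisy, array(FALSE, c(24, 24, 12))), "empty")
})

test_that("mask perturbations are set-monotone, seeded, and safe", {
  mask <- make_dissection_mask(small_geometry())
  sm <- perturb_mask(mask, "smaller", 1)
  lg <- perturb_mask(mask, "larger", 1)
  for (lab in 1:2) {
    expect_true(all(mask$labels[sm$labels == lab] == lab))   # sm subset
    expect_true(all(lg$labels[mask$labels == lab] == lab))   # input subset lg
  }
  # lumens never overlap after dilation
  expect_equal(sum(lg$labels == 1L & lg$labels == 2L), 0)
  expect_true(flumen:::is_connected6(lg$labels == 1L))
  # mixed is deterministic by seed and differs across seeds
  m1 <- perturb_mask(mask, "mixed", 1, seed = 4)
  m2 <- perturb_mask(mask, "mixed", 1, seed = 4)
  m3 <- perturb_mask(mask, "mixed", 1, seed = 5)
  expect_identical(m1$labels, m2$labels)
  expect_false(identical(m1$labels, m3$labels))
  # mixed output lies between erosion and dilation per slab
  expect_true(all(m1$labels[sm$labels == 1L] == 1L |
                    m1$labels[sm$labels == 1L] == 0L))
  # eroding a 1-voxel-thin lumen empties it: explicit error
  thin <- array(0L, c(8, 8, 8)); thin[4, 4, ] <- 1L
  expect_error(perturb_mask(lumen_mask(thin, rep(1, 3)), "smaller", 1),
               "emptied")
  expect_error(perturb_mask(mask, "smaller", 0), "magnitude")
})

test_that("plane perturbation respects its bounds and seed", {
  pl <- analysis_plane(c(10, 10, 50), c(0, 0, 1), 5)
  # zero bounds: identical plane
  p0 <- perturb_plane(pl, 0, 0, seed = 1)
  expect_equal(p0$origin_mm, pl$origin_mm)
  expect_equal(p0$normal, pl$normal)
  # bounds honoured over many seeds
  for (s in 1:25) {
    pp <- perturb_plane(pl, max_tilt_deg = 5, max_shift_mm = 2, seed = s)
    tilt <- acos(min(1, sum(pp$normal * pl$normal))) * 180 / pi
    expect_lte(tilt, 5 + 1e-9)
    expect_lte(sqrt(sum((pp$origin_mm - pl$origin_mm)^2)), 2 + 1e-9)
    expect_equal(sqrt(sum(pp$normal^2)), 1, tolerance = 1e-12)
  }
  expect_identical(perturb_plane(pl, 5, 2, seed = 3),
                   perturb_plane(pl, 5, 2, seed = 3))
})

test_that("two cross-sections of an unbranched lumen carry the same flux", {
  wf <- waveform_spec(diastolic_retrograde_volume_ml = 2)
  geom <- small_geometry()
  fld <- make_pulsatile_field(geom, wf)
  mask <- make_dissection_mask(geom)
  gt <- attr(make_dissection_mask(geom), "ground_truth")
  # two TL cross-sections away from the tear
  r_roi <- geom$lumen_radius_tl + 2
  o1 <- c(gt$tl_center_mm, 10); o2 <- c(gt$tl_center_mm, 70)
  q1 <- compute_flow_trace(fld, analysis_plane(o1, c(0, 0, 1), r_roi))
  q2 <- compute_flow_trace(fld, analysis_plane(o2, c(0, 0, 1), r_roi))
  expect_equal(q1$flow_ml_s, q2$flow_ml_s, tolerance = 0.02)
})
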