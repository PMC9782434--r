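test_that("gravity is cancelled in the world frame for static orientations", {
  # identity orientation
  s <- make_static_stream(yaw_deg = 0)
  free <- world_linear_acceleration(s)
  expect_equal(max(abs(c(free$ap, free$ml, free$up))), 0, tolerance = 1e-9)
  # yawed orientation
  s <- make_static_stream(yaw_deg = 57)
  free <- world_linear_acceleration(s)
  expect_equal(max(abs(c(free$ap, free$ml, free$up))), 0, tolerance = 1e-9)
})

test_that("a vertical excess over gravity appears as world-frame up acceleration", {
  s <- make_static_stream(yaw_deg = 0)
  s$az <- s$az + 1
  free <- world_linear_acceleration(s)
  expect_equal(free$up, rep(1, nrow(s)), tolerance = 1e-9)
  expect_equal(free$ap, rep(0, nrow(s)), tolerance = 1e-9)
})

test_that("gravity sensed under a 90-degree roll cancels after rotation to the world frame", {
  n <- 100
  # body rolled 90 deg about X (AP): world Z maps onto body -Y, so the
  # accelerometer senses gravity on -Y in the body frame
  q_roll <- posturebench:::quat_axis(rep(90, n), "x")
  g_body <- posturebench:::quat_rotate_inverse(q_roll,
                                               cbind(0, 0, rep(9.81, n)))
  s <- tibble::tibble(
    segment = "trunk", time_s = (seq_len(n) - 1) / 100,
    qw = q_roll[, 1], qx = q_roll[, 2], qy = q_roll[, 3], qz = q_roll[, 4],
    ax = g_body[, 1], ay = g_body[, 2], az = g_body[, 3],
    gx = 0, gy = 0, gz = 0
  )
  free <- world_linear_acceleration(s)
  expect_equal(max(abs(c(free$ap, free$ml, free$up))), 0, tolerance = 1e-9)
})

test_that("non-unit quaternions beyond tolerance are rejected", {
  s <- make_static_stream()
  s$qw <- s$qw * 1.2
  expect_error(world_linear_acceleration(s), "unit norm")
})

test_that("double integration recovers a sinusoidal displacement at the chain's analytic attenuation", {
  fs <- 100; f <- 1; A <- 0.02  # 20 mm displacement amplitude
  t <- (0:5999) / fs
  accel <- -A * (2 * pi * f)^2 * sin(2 * pi * f * t)
  disp <- displacement_from_acceleration(accel, fs)
  w <- 1000:5000  # avoid filter edge transients (~5 time constants)
  expected <- A * 1000 * displacement_chain_gain(f, fs)
  expect_equal(max(abs(disp[w])), expected, tolerance = 0.01)
})

test_that("zero acceleration integrates to zero displacement", {
  disp <- displacement_from_acceleration(rep(0, 3000), 100)
  expect_equal(disp, rep(0, 3000))
})

test_that("a constant acceleration bias does not produce quadratic drift", {
  fs <- 100
  disp <- displacement_from_acceleration(rep(1, 60 * fs), fs)
  # naive double integration of 1 m/s^2 over 60 s reaches 1800 m; the
  # high-passed chain settles below slope/omega_c^2 = 1/(2*pi*0.2)^2
  # ~ 0.63 m; allow 3x for the forward-backward filter transients
  expect_lt(max(abs(disp)), 3 * 0.633 * 1000)
  expect_lt(max(abs(disp)), 1.8e6 / 500)
})

test_that("series shorter than the filter warm-up are rejected", {
  expect_error(displacement_from_acceleration(rep(0, 100), 100),
               "warm-up")
})

test_that("the zero-lag high-pass introduces no phase shift", {
  fs <- 100
  t <- (0:2999) / fs
  x <- sin(2 * pi * 0.7 * t)
  y <- posturebench:::highpass_zero_lag(x, fs)
  cc <- stats::ccf(x, y, lag.max = 50, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("range of motion is the peak-to-peak excursion over the window", {
  t <- (0:2999) / 100
  x <- 5 * sin(2 * pi * 0.5 * t)
  expect_equal(range_of_motion(x), 10, tolerance = 1e-6)
  expect_equal(range_of_motion(rep(3.2, 100)), 0)
  # a step confined to the excluded ramp region does not leak in
  x2 <- x
  x2[1:100] <- x2[1:100] + 50
  expect_equal(range_of_motion(x2, window = 200:2800), 10,
               tolerance = 1e-6)
  expect_error(range_of_motion(x, window = integer(0)), "empty")
  expect_error(range_of_motion(x, window = 2990:3010), "outside")
})

test_that("coupling indices recover identity, scaling and quarter-period delay", {
  fs <- 100
  t <- (0:2999) / fs  # 30 s, integer cycles of 0.5 Hz
  p <- 20 * sin(2 * pi * 0.5 * t)
  expect_equal(coupling_indices(p, p, fs)$gain_ratio, 1, tolerance = 1e-9)
  expect_equal(coupling_indices(p, p, fs)$phase_shift_deg, 0,
               tolerance = 1e-9)
  cp <- coupling_indices(0.8 * p, p, fs)
  expect_equal(cp$gain_ratio, 0.8, tolerance = 1e-9)
  expect_equal(cp$phase_shift_deg, 0, tolerance = 1e-9)
  # quarter-period delay -> +90 deg (delay is positive phase)
  d <- 20 * sin(2 * pi * 0.5 * (t - 0.5))
  cp <- coupling_indices(d, p, fs)
  expect_equal(cp$phase_shift_deg, 90, tolerance = 1e-6)
  # anticipation -> negative phase
  a <- 20 * sin(2 * pi * 0.5 * (t + 0.5))
  expect_equal(coupling_indices(a, p, fs)$phase_shift_deg, -90,
               tolerance = 1e-6)
})

test_that("coupling rejects a proximal signal with no fundamental", {
  expect_error(coupling_indices(rnorm(100), rep(0, 100), 100),
               "fundamental")
})

test_that("phase wrapping maps to (-180, 180]", {
  expect_equal(wrap_degrees(c(270, -270, 180, -180, 540)),
               c(-90, 90, 180, 180, 180))
})

test_that("assemble_features averages repetitions into 72 deterministically named features", {
  grid <- tidyr::crossing(
    level = c("LP", "MP", "HP"), start_side = c("right", "left"),
    rep = 1:3, segment = c("pelvis", "trunk", "head")
  )
  set.seed(1)
  tf <- dplyr::mutate(grid, rom_ml = rnorm(dplyr::n(), 20),
                      rom_ap = rnorm(dplyr::n(), 15),
                      gain = runif(dplyr::n()),
                      phase = rnorm(dplyr::n(), 10))
  fv <- assemble_features(tf)
  expect_equal(ncol(fv), 72)
  expect_true(all(grepl("^(rom_ml|rom_ap|gain|phase)_(pelvis|trunk|head)_(LP|MP|HP)_(right|left)$",
                        names(fv))))
  # averaging: the assembled value equals the mean over repetitions
  manual <- mean(tf$gain[tf$level == "LP" & tf$start_side == "right" &
                           tf$segment == "head"])
  expect_equal(fv$gain_head_LP_right, manual)
  # idempotent on identical repetitions
  tf1 <- dplyr::mutate(tf, rom_ml = 20, rom_ap = 15, gain = 0.5, phase = 5)
  fv1 <- assemble_features(tf1)
  expect_true(all(fv1[grep("^gain", names(fv1))] == 0.5))
  # invariant to row order
  fv2 <- assemble_features(tf[sample(nrow(tf)), ])
  expect_equal(fv2, fv)
})

test_that("assemble_features reports which test types are missing", {
  grid <- tidyr::crossing(level = c("LP", "MP"),
                          start_side = c("right", "left"),
                          segment = c("pelvis", "trunk", "head"))
  tf <- dplyr::mutate(grid, rom_ml = 1, rom_ap = 1, gain = 1, phase = 0)
  expect_error(assemble_features(tf), "HP/right")
})

test_that("noise-free end-to-end extraction recovers the profile's link gains, phases and sway ROM", {
  profile <- make_profile(g_pelvis = 0.65, g_trunk = 0.8, g_head = 0.92,
                          phi_pelvis = 12, phi_trunk = 7, phi_head = 4)
  for (lvl in c("LP", "HP")) {
    spec <- perturbation_spec(lvl)
    session <- simulate_session(profile, spec, duration = 30,
                                noise = FALSE)
    feats <- extract_session_features(session)
    truth_gain <- c(pelvis = 0.65, trunk = 0.8, head = 0.92)
    truth_phase <- c(pelvis = 12, trunk = 7, head = 4)
    for (seg in c("pelvis", "trunk", "head")) {
      row <- feats[feats$segment == seg, ]
      expect_equal(row$gain, truth_gain[[seg]], tolerance = 0.01,
                   info = paste(lvl, seg))
      expect_equal(row$phase, truth_phase[[seg]], tolerance = 1,
                   info = paste(lvl, seg))
    }
    # ROM against ground truth passed through the chain's analytic
    # attenuation at the sway frequency
    g_ml <- displacement_chain_gain(0.8, 100)
    g_ap <- displacement_chain_gain(1.0, 100)
    expect_equal(feats$rom_ml[feats$segment == "trunk"],
                 2 * profile$a_ml_trunk * g_ml, tolerance = 0.02)
    expect_equal(feats$rom_ap[feats$segment == "head"],
                 2 * profile$a_ap_head * g_ap, tolerance = 0.02)
  }
})

test_that("features are invariant to a uniform time shift of the session", {
  profile <- make_profile()
  session <- simulate_session(profile, perturbation_spec("MP"),
                              duration = 30, noise = FALSE)
  f1 <- extract_session_features(session)
  shifted <- session
  shifted$trajectory$time_s <- shifted$trajectory$time_s + 5
  for (seg in names(shifted$streams)) {
    shifted$streams[[seg]]$time_s <- shifted$streams[[seg]]$time_s + 5
  }
  f2 <- extract_session_features(shifted)
  expect_equal(f2, f1, tolerance = 1e-9)
})

test_that("a fixed sensor-to-segment yaw misalignment is removed by static calibration", {
  kin_static <- tibble::tibble(
    time_s = (0:499) / 100, segment = "trunk", yaw_deg = 0,
    disp_ml_mm = 0, disp_ap_mm = 0, acc_ml_ms2 = 0, acc_ap_ms2 = 0
  )
  static <- render_imu(kin_static, misalignment_deg = 15)
  cal <- static_calibration(static)
  expect_equal(cal$yaw_offset_deg, 15, tolerance = 1e-6)
  expect_equal(cal$gravity_dir[[3]], 1, tolerance = 1e-6)
  corrected <- apply_calibration(static, cal)
  expect_equal(max(abs(posturebench:::quat_yaw_deg(
    as.matrix(corrected[, c("qw", "qx", "qy", "qz")])
  ))), 0, tolerance = 1e-6)
})

test_that("feature tables round-trip through CSV", {
  feats <- make_blob_features(2, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(feats, path)
  back <- read_features_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(feats),
               tolerance = 1e-12)
})
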