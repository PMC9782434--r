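# Virtual cohort: subject profiles with PD/HC contrasts and ON/OFF states,
# segment yaw transmission, sway kinematics, and virtual IMU rendering.
# Frames: world Z up, X antero-posterior (AP), Y medio-lateral (ML);
# gravity is +9.81 m/s^2 on world Z as sensed by a static accelerometer.

GRAVITY <- 9.81

# population means and between-subject SDs of the healthy-control group.
# Yaw transmission gains decrease up the chain (partial head stabilization
# in space); small positive phases encode distal delay; sway amplitudes in
# mm and sway frequencies chosen above twice the 0.2 Hz high-pass cutoff
# so simulated sway survives the displacement-estimation filter chain.
cohort_base_parameters <- function() {
  tibble::tibble(
    parameter = c(
      "g_pelvis", "g_trunk", "g_head",
      "phi_pelvis", "phi_trunk", "phi_head",
      "a_ml_pelvis", "a_ml_trunk", "a_ml_head",
      "a_ap_pelvis", "a_ap_trunk", "a_ap_head"
    ),
    mean = c(0.70, 0.85, 0.90, 10, 8, 5, 18, 20, 22, 12, 14, 16),
    sd = c(0.10, 0.08, 0.08, 4, 4, 4, 5, 5, 5, 4, 4, 4)
  )
}

# group-level parameter means under a given effect configuration.
# PD contrasts (qualitative pattern: larger ML displacement, reduced
# lumbo-sacral yaw transmission) act on the ML sway amplitudes (up) and
# the pelvis-link gain (down), in units of the between-subject SD.
cohort_group_means <- function(effect_a_ml = 1.5, effect_g_pelvis = 1.5) {
  base <- cohort_base_parameters()
  shift <- numeric(nrow(base))
  ml <- grepl("^a_ml_", base$parameter)
  shift[ml] <- effect_a_ml * base$sd[ml]
  gp <- base$parameter == "g_pelvis"
  shift[gp] <- -effect_g_pelvis * base$sd[gp]
  dplyr::mutate(base, hc_mean = .data$mean, pd_mean = .data$mean + shift,
                .keep = "unused")
}

#' Sample a virtual cohort of subject profiles
#'
#' Draws per-subject kinematic parameters for `n_pd` Parkinson's disease
#' (PD) patients and `n_hc` healthy controls (HC). Each PD patient gets a
#' paired OFF-state (off dopaminergic medication) and ON-state profile;
#' the ON profile is the OFF profile shifted by `on_normalization` times
#' the PD-HC group mean difference on the affected parameters (balance
#' responses are largely refractory to medication, so the default shift is
#' partial). HC subjects get a single profile.
#'
#' Group contrasts are applied to the medio-lateral sway amplitudes
#' (larger in PD) and the pelvis-from-platform yaw gain (smaller in PD),
#' each scaled by the between-subject SD via the effect sizes.
#'
#' @param n_pd,n_hc number of PD patients and healthy controls.
#' @param effect_a_ml,effect_g_pelvis standardized effect sizes (in
#'   between-subject SDs) of the PD contrasts.
#' @param on_normalization fraction of the PD-HC mean difference removed
#'   in the ON state (0 = ON identical to OFF, 1 = fully normalized).
#' @param between_sd_scale multiplier on the between-subject SDs (0 makes
#'   every subject sit exactly at its group mean).
#' @param noise_accel accelerometer noise SD, m/s^2.
#' @param noise_gyro gyroscope noise SD, deg/s.
#' @param noise_orient orientation (attitude) noise SD, degrees.
#' @param sway_freq_ml,sway_freq_ap sway frequencies, Hz.
#' @param seed integer seed.
#' @return a tibble with one row per subject-state: `subject_id`, `group`
#'   (`"PD"`/`"HC"`), `state` (`"OFF"`/`"ON"`/`"none"`), the 12 kinematic
#'   parameters, sway frequencies and noise levels.
#' @examples
#' cohort <- sample_cohort(n_pd = 2, n_hc = 2, seed = 1)
#' cohort[, 1:5]
#' @export
sample_cohort <- function(n_pd = 20, n_hc = 15,
                          effect_a_ml = 1.5, effect_g_pelvis = 1.5,
                          on_normalization = 0.3,
                          between_sd_scale = 1,
                          noise_accel = 0.02, noise_gyro = 0.2,
                          noise_orient = 0.2,
                          sway_freq_ml = 0.8, sway_freq_ap = 1.0,
                          seed = 0L) {
  if (n_pd < 0 || n_hc < 0) {
    stop("cohort sizes must be non-negative", call. = FALSE)
  }
  means <- cohort_group_means(effect_a_ml, effect_g_pelvis)
  npar <- nrow(means)
  draw_group <- function(n, mu) {
    m <- matrix(stats::rnorm(n * npar, mean = rep(mu, each = n),
                             sd = rep(means$sd * between_sd_scale, each = n)),
                nrow = n, ncol = npar)
    colnames(m) <- means$parameter
    m
  }
  draws <- with_seed(seed, {
    list(pd = draw_group(n_pd, means$pd_mean),
         hc = draw_group(n_hc, means$hc_mean))
  })
  clamp <- function(m) {
    nonneg <- grepl("^(g_|a_)", colnames(m))
    m[, nonneg] <- pmax(m[, nonneg], 0)
    m
  }
  pd_off <- clamp(draws$pd)
  # group-level partial normalization: shift each OFF profile by a fraction
  # of the PD-HC mean difference (zero when the effect sizes are zero)
  on_shift <- on_normalization * (means$hc_mean - means$pd_mean)
  pd_on <- clamp(sweep(draws$pd, 2, on_shift, `+`))
  hc <- clamp(draws$hc)

  mk <- function(m, ids, group, state) {
    if (nrow(m) == 0) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(subject_id = ids, group = group, state = state),
      tibble::as_tibble(m)
    )
  }
  pd_ids <- sprintf("PD%02d", seq_len(n_pd))
  hc_ids <- sprintf("HC%02d", seq_len(n_hc))
  out <- dplyr::bind_rows(
    mk(pd_off, pd_ids, "PD", "OFF"),
    mk(pd_on, pd_ids, "PD", "ON"),
    mk(hc, hc_ids, "HC", "none")
  )
  dplyr::mutate(
    out,
    sway_freq_ml = sway_freq_ml, sway_freq_ap = sway_freq_ap,
    noise_accel = noise_accel, noise_gyro = noise_gyro,
    noise_orient = noise_orient
  )
}

#' Simulate segment yaw and sway kinematics for one trial
#'
#' Propagates the platform yaw up the kinematic chain: the pelvis follows
#' the platform with gain `g_pelvis` and delay `phi_pelvis` (a phase in
#' degrees at the perturbation frequency), the trunk follows the pelvis,
#' and the head follows the trunk. Medio-lateral and antero-posterior
#' sway of each segment is sinusoidal at the profile's sway frequencies
#' with per-segment amplitudes; sway accelerations are carried
#' analytically alongside the displacements.
#'
#' @param profile a one-row subject profile, see [sample_cohort()].
#' @param trajectory a `platform_trajectory`, see [make_trajectory()].
#' @return a tibble with one row per sample and segment: `time_s`,
#'   `segment`, `yaw_deg`, `disp_ml_mm`, `disp_ap_mm`, `acc_ml_ms2`,
#'   `acc_ap_ms2`.
#' @export
simulate_segment_kinematics <- function(profile, trajectory) {
  stopifnot(nrow(profile) == 1)
  spec <- attr(trajectory, "spec")
  f <- spec$frequency_hz[1]
  t <- trajectory$time_s
  # delay in seconds realized by each link's phase at the perturbation
  # frequency; a zero-frequency (static) trajectory has no delay
  delay <- function(phi_deg) if (f > 0) phi_deg / (360 * f) else 0
  shift_series <- function(x, tau) {
    if (tau == 0) return(x)
    stats::approx(t, x, xout = t - tau, rule = 2)$y
  }
  yaw <- list()
  yaw$pelvis <- profile$g_pelvis *
    shift_series(trajectory$yaw_deg, delay(profile$phi_pelvis))
  yaw$trunk <- profile$g_trunk *
    shift_series(yaw$pelvis, delay(profile$phi_trunk))
  yaw$head <- profile$g_head *
    shift_series(yaw$trunk, delay(profile$phi_head))

  # fixed per-segment sway phase offsets de-synchronize the segments
  sway_phase <- c(pelvis = 0, trunk = pi / 3, head = 2 * pi / 3)
  w_ml <- 2 * pi * profile$sway_freq_ml
  w_ap <- 2 * pi * profile$sway_freq_ap
  purrr::map_dfr(SEGMENTS, function(seg) {
    a_ml <- profile[[paste0("a_ml_", seg)]]  # mm
    a_ap <- profile[[paste0("a_ap_", seg)]]
    ph <- sway_phase[[seg]]
    tibble::tibble(
      time_s = t,
      segment = seg,
      yaw_deg = yaw[[seg]],
      disp_ml_mm = a_ml * sin(w_ml * t + ph),
      disp_ap_mm = a_ap * sin(w_ap * t + ph / 2),
      acc_ml_ms2 = -(a_ml / 1000) * w_ml^2 * sin(w_ml * t + ph),
      acc_ap_ms2 = -(a_ap / 1000) * w_ap^2 * sin(w_ap * t + ph / 2)
    )
  })
}

#' Render a virtual IMU stream from segment kinematics
#'
#' Converts one segment's kinematics into the signals a body-worn inertial
#' sensor would output: a unit orientation quaternion (yaw about world Z),
#' body-frame acceleration including gravity, and body-frame angular rate.
#' Accelerometer, gyroscope and orientation noise are added as white
#' Gaussian noise with the given SDs; orientation noise perturbs yaw,
#' pitch and roll by small angles before re-normalization.
#'
#' @param kin kinematics for a single segment (uniform time grid), as one
#'   segment's rows from [simulate_segment_kinematics()].
#' @param noise_accel,noise_gyro,noise_orient noise SDs (m/s^2, deg/s,
#'   deg).
#' @param misalignment_deg fixed sensor-to-segment yaw misalignment,
#'   degrees (estimated and removed by [static_calibration()]).
#' @param seed integer seed for the noise draws.
#' @return a tibble of class `sensor_stream`: `segment`, `time_s`, `qw`,
#'   `qx`, `qy`, `qz`, `ax`, `ay`, `az` (m/s^2), `gx`, `gy`, `gz` (deg/s).
#' @export
render_imu <- function(kin, noise_accel = 0, noise_gyro = 0,
                       noise_orient = 0, misalignment_deg = 0, seed = 0L) {
  t <- kin$time_s
  n <- length(t)
  dt <- diff(t)
  if (n < 3 || any(abs(dt - dt[1]) > 1e-9)) {
    stop("kinematics must be on a uniform time grid", call. = FALSE)
  }
  dt <- dt[1]
  yaw <- kin$yaw_deg + misalignment_deg
  q <- quat_axis(yaw, "z")
  noise <- with_seed(seed, list(
    acc = matrix(stats::rnorm(3 * n, sd = noise_accel), ncol = 3),
    gyr = matrix(stats::rnorm(3 * n, sd = noise_gyro), ncol = 3),
    ori = matrix(stats::rnorm(3 * n, sd = noise_orient), ncol = 3)
  ))
  if (noise_orient > 0) {
    q <- quat_multiply(q, quat_axis(noise$ori[, 1], "z"))
    q <- quat_multiply(q, quat_axis(noise$ori[, 2], "y"))
    q <- quat_multiply(q, quat_axis(noise$ori[, 3], "x"))
    q <- quat_normalize(q)
  }
  # world-frame kinematic acceleration (X = AP, Y = ML, Z vertical) plus
  # the gravity reaction sensed by the accelerometer
  a_world <- cbind(kin$acc_ap_ms2, kin$acc_ml_ms2, rep(GRAVITY, n))
  a_body <- quat_rotate_inverse(q, a_world) + noise$acc
  # angular rate: yaw-only orientation, so the body rate is the yaw rate
  # about the body Z axis
  gz <- centered_gradient(yaw, dt)
  g_body <- cbind(0, 0, gz) + noise$gyr
  out <- tibble::tibble(
    segment = kin$segment[1],
    time_s = t,
    qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
    ax = a_body[, 1], ay = a_body[, 2], az = a_body[, 3],
    gx = g_body[, 1], gy = g_body[, 2], gz = g_body[, 3]
  )
  structure(out, class = c("sensor_stream", class(out)))
}

#' Simulate a full three-sensor recording session for one trial
#'
#' @param profile one-row subject profile.
#' @param spec perturbation spec, see [perturbation_spec()].
#' @param duration,fs,ramp_duration trajectory parameters, see
#'   [make_trajectory()].
#' @param trajectory optionally a pre-built trajectory for `spec` (saves
#'   regenerating it across subjects).
#' @param noise logical; `FALSE` renders noise-free streams.
#' @param seed integer seed for sensor noise.
#' @return a list of class `recording_session`: `subject_id`, `state`,
#'   `spec`, `trajectory`, `streams` (named list of `sensor_stream`s),
#'   `seed`.
#' @export
simulate_session <- function(profile, spec, duration = 30, fs = 100,
                             ramp_duration = 2, trajectory = NULL,
                             noise = TRUE, seed = 0L) {
  if (is.null(trajectory)) {
    trajectory <- make_trajectory(spec, duration, fs, ramp_duration)
  }
  kin <- simulate_segment_kinematics(profile, trajectory)
  streams <- purrr::imap(
    split(kin, kin$segment)[SEGMENTS],
    function(k, seg) {
      render_imu(
        k,
        noise_accel = if (noise) profile$noise_accel else 0,
        noise_gyro = if (noise) profile$noise_gyro else 0,
        noise_orient = if (noise) profile$noise_orient else 0,
        seed = seed + match(seg, SEGMENTS)
      )
    }
  )
  structure(
    list(
      subject_id = profile$subject_id %||% "anonymous",
      state = profile$state %||% "none",
      spec = spec,
      trajectory = trajectory,
      streams = streams,
      seed = seed
    ),
    class = "recording_session"
  )
}

#' @export
print.recording_session <- function(x, ...) {
  cat("<recording_session>", x$subject_id,
      sprintf("[%s]", x$state),
      sprintf("level %s, side %s, %d samples\n",
              x$spec$level[1], x$spec$start_side[1],
              nrow(x$trajectory)))
  invisible(x)
}

#' Write / read a recording session as plain-text CSV files
#'
#' One CSV per sensor (`<prefix>_<segment>.csv` with columns `time_s`,
#' `qw`, `qx`, `qy`, `qz`, `ax`, `ay`, `az`, `gx`, `gy`, `gz`), the
#' platform trajectory (`<prefix>_platform.csv`) and a JSON manifest with
#' the trial metadata. The same schema is accepted for real sensor
#' exports.
#'
#' @param session a `recording_session`.
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return `write_session_csv()` returns the manifest path invisibly;
#'   `read_session_csv()` rebuilds the `recording_session`.
#' @export
write_session_csv <- function(session, dir, prefix = "session") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (seg in names(session$streams)) {
    readr::write_csv(
      dplyr::select(tibble::as_tibble(session$streams[[seg]]), -"segment"),
      file.path(dir, sprintf("%s_%s.csv", prefix, seg))
    )
  }
  write_trajectory_csv(session$trajectory,
                       file.path(dir, sprintf("%s_platform.csv", prefix)))
  manifest <- list(
    subject_id = session$subject_id,
    state = session$state,
    spec = as.list(session$spec[1, ]),
    fs = attr(session$trajectory, "fs"),
    ramp_duration = attr(session$trajectory, "ramp_duration"),
    steady_start = attr(session$trajectory, "steady_start"),
    steady_end = attr(session$trajectory, "steady_end"),
    seed = session$seed
  )
  mpath <- file.path(dir, sprintf("%s_manifest.json", prefix))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}

#' @rdname write_session_csv
#' @export
read_session_csv <- function(dir, prefix = "session") {
  manifest <- jsonlite::read_json(
    file.path(dir, sprintf("%s_manifest.json", prefix))
  )
  spec <- tibble::as_tibble(manifest$spec)
  traj <- read_trajectory_csv(
    file.path(dir, sprintf("%s_platform.csv", prefix))
  )
  traj <- structure(
    traj,
    class = c("platform_trajectory", class(traj)),
    spec = spec,
    fs = manifest$fs,
    ramp_duration = manifest$ramp_duration,
    steady_start = manifest$steady_start,
    steady_end = manifest$steady_end
  )
  streams <- purrr::map(rlang::set_names(SEGMENTS), function(seg) {
    s <- readr::read_csv(file.path(dir, sprintf("%s_%s.csv", prefix, seg)),
                         show_col_types = FALSE)
    s <- dplyr::mutate(s, segment = seg, .before = 1)
    structure(s, class = c("sensor_stream", class(s)))
  })
  structure(
    list(
      subject_id = manifest$subject_id,
      state = manifest$state,
      spec = spec,
      trajectory = traj,
      streams = streams,
      seed = manifest$seed
    ),
    class = "recording_session"
  )
}
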