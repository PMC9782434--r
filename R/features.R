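# Feature extraction: gravity-compensated world-frame acceleration,
# double-integrated displacement with zero-lag high-pass filtering, range
# of motion, and FFT-based inter-segment gain ratio / phase shift.

#' Gravity-compensated world-frame acceleration
#'
#' Rotates each body-frame accelerometer sample into the world frame via
#' the quaternion-derived rotation matrix, then subtracts the constant
#' gravity vector (+9.81 m/s^2 on world Z), leaving the free linear
#' acceleration of the segment.
#'
#' @param stream a `sensor_stream` (columns `qw`..`qz`, `ax`..`az`).
#' @param tol maximum tolerated deviation of the quaternion norm from 1.
#' @return a tibble with columns `time_s`, `ap` (world X), `ml` (world
#'   Y), `up` (world Z), in m/s^2.
#' @export
world_linear_acceleration <- function(stream, tol = 1e-3) {
  q <- as.matrix(stream[, c("qw", "qx", "qy", "qz")])
  norms <- sqrt(rowSums(q^2))
  if (any(abs(norms - 1) > tol)) {
    stop("orientation quaternions deviate from unit norm beyond tolerance",
         call. = FALSE)
  }
  q <- q / norms
  a_world <- quat_rotate(q, as.matrix(stream[, c("ax", "ay", "az")]))
  tibble::tibble(
    time_s = stream$time_s,
    ap = a_world[, 1],
    ml = a_world[, 2],
    up = a_world[, 3] - GRAVITY
  )
}

# first-order Butterworth high-pass applied forward-backward (zero lag);
# the effective magnitude response is the squared one-pass response.
# Odd-reflection padding of ~2 filter time constants suppresses the edge
# transients of the low cutoff before the pad is trimmed away.
highpass_zero_lag <- function(x, fs, cutoff = 0.2) {
  bf <- signal::butter(1, cutoff / (fs / 2), type = "high")
  n <- length(x)
  np <- min(n - 1, round(2 / cutoff * fs))
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(np + 1):(np + n)]
}

#' Analytic magnitude response of the displacement filter chain
#'
#' Magnitude gain, at frequency `f`, of the full displacement-estimation
#' chain applied to an acceleration sinusoid: two trapezoidal
#' integrations, each followed by the zero-lag (forward-backward)
#' first-order Butterworth high-pass, relative to ideal double
#' integration. Used as the independent oracle in recovery tests and to
#' interpret attenuated range-of-motion values.
#'
#' @param f frequency, Hz (vectorized).
#' @param fs sampling rate, Hz.
#' @param cutoff high-pass cutoff, Hz.
#' @return numeric gain (1 = no attenuation).
#' @export
displacement_chain_gain <- function(f, fs, cutoff = 0.2) {
  bf <- signal::butter(1, cutoff / (fs / 2), type = "high")
  w <- 2 * pi * f / fs  # digital angular frequency
  z1 <- exp(-1i * w)
  h_hp <- (bf$b[1] + bf$b[2] * z1) / (bf$a[1] + bf$a[2] * z1)
  # trapezoidal integrator vs ideal 1/(j*omega): amplitude ratio
  h_int_ratio <- (w / 2) / tan(w / 2)
  (Mod(h_hp)^2 * h_int_ratio)^2
}

#' Displacement from free acceleration by double integration
#'
#' Integrates a free-acceleration axis to velocity (cumulative trapezoid),
#' removes integration drift with a zero-lag first-order Butterworth
#' high-pass at `cutoff`, integrates again to displacement and high-passes
#' once more. Output is in millimetres.
#'
#' @param accel free acceleration series, m/s^2.
#' @param fs sampling rate, Hz.
#' @param cutoff high-pass cutoff frequency, Hz.
#' @return displacement series, mm, zero-mean by construction.
#' @export
displacement_from_acceleration <- function(accel, fs, cutoff = 0.2) {
  stopifnot(cutoff > 0, fs > 0)
  warmup <- 3 / cutoff
  if (length(accel) / fs < warmup) {
    stop(sprintf(
      "series of %.3g s is shorter than the filter warm-up (%.3g s)",
      length(accel) / fs, warmup
    ), call. = FALSE)
  }
  dt <- 1 / fs
  vel <- drop(pracma::cumtrapz(seq_along(accel) * dt, accel))
  vel <- highpass_zero_lag(vel, fs, cutoff)
  disp <- drop(pracma::cumtrapz(seq_along(accel) * dt, vel))
  disp <- highpass_zero_lag(disp, fs, cutoff)
  disp * 1000
}

#' Range of motion over a steady-state window
#'
#' @param disp displacement series, mm.
#' @param window integer sample indices delimiting the window.
#' @return max minus min of `disp` over the window, mm.
#' @export
range_of_motion <- function(disp, window = seq_along(disp)) {
  if (length(window) == 0) {
    stop("empty range-of-motion window", call. = FALSE)
  }
  if (min(window) < 1 || max(window) > length(disp)) {
    stop("range-of-motion window outside the series", call. = FALSE)
  }
  x <- disp[window]
  max(x) - min(x)
}

#' Inter-segment coupling: gain ratio and phase shift
#'
#' The fundamental bin is the maximum-magnitude FFT bin of the proximal
#' signal (DC excluded, restricted to `band`, ties toward the lower
#' frequency). The gain ratio is the distal/proximal magnitude ratio at
#' that bin. The phase shift is the Fourier phase-angle difference at the
#' same bin, reported in degrees wrapped to (-180, 180], with positive
#' values meaning the distal segment lags (is delayed relative to) the
#' proximal one and negative values meaning it anticipates.
#'
#' @param distal,proximal equal-length yaw-angle series (detrended
#'   internally), degrees.
#' @param fs sampling rate, Hz.
#' @param band fundamental search band, Hz.
#' @return a one-row tibble: `fundamental_hz`, `gain_ratio`,
#'   `phase_shift_deg`.
#' @export
coupling_indices <- function(distal, proximal, fs, band = c(0.05, 2)) {
  stopifnot(length(distal) == length(proximal))
  proximal <- proximal - mean(proximal)
  distal <- distal - mean(distal)
  if (all(abs(proximal) < .Machine$double.eps * 100)) {
    stop("proximal signal has no fundamental component (all-zero spectrum)",
         call. = FALSE)
  }
  n <- length(proximal)
  freqs <- (seq_len(n) - 1) * fs / n
  keep <- which(freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2)
  sp_p <- stats::fft(proximal)
  sp_d <- stats::fft(distal)
  mag_p <- Mod(sp_p[keep])
  i_star <- keep[which.max(mag_p)]
  gain <- Mod(sp_d[i_star]) / Mod(sp_p[i_star])
  # positive phase = distal delayed: for distal(t) = proximal(t - tau) the
  # distal Fourier angle is smaller by omega*tau, so take prox - dist
  phase <- wrap_degrees((Arg(sp_p[i_star]) - Arg(sp_d[i_star])) * 180 / pi)
  tibble::tibble(
    fundamental_hz = freqs[i_star],
    gain_ratio = gain,
    phase_shift_deg = phase
  )
}

#' Static sensor-to-segment calibration
#'
#' Estimates a fixed heading (yaw) offset and the sensed gravity direction
#' from a quiet standing recording, as a simplified static-alignment step.
#' [apply_calibration()] removes the heading offset from a stream's
#' orientation.
#'
#' @param stream a `sensor_stream` recorded during quiet standing.
#' @return a list with `yaw_offset_deg` (mean yaw during the static pose)
#'   and `gravity_dir` (unit mean accelerometer direction, body frame).
#' @export
static_calibration <- function(stream) {
  q <- as.matrix(stream[, c("qw", "qx", "qy", "qz")])
  acc <- colMeans(as.matrix(stream[, c("ax", "ay", "az")]))
  list(
    yaw_offset_deg = mean(quat_yaw_deg(q)),
    gravity_dir = acc / sqrt(sum(acc^2))
  )
}

#' @rdname static_calibration
#' @param calibration result of [static_calibration()].
#' @export
apply_calibration <- function(stream, calibration) {
  q <- as.matrix(stream[, c("qw", "qx", "qy", "qz")])
  q_corr <- quat_multiply(
    quat_axis(rep(-calibration$yaw_offset_deg, nrow(q)), "z"), q
  )
  stream$qw <- q_corr[, 1]; stream$qx <- q_corr[, 2]
  stream$qy <- q_corr[, 3]; stream$qz <- q_corr[, 4]
  stream
}

# steady-state analysis window: trajectory steady indices minus a one
# second guard on each side against filter edge effects
steady_window <- function(trajectory, guard_s = 1) {
  fs <- attr(trajectory, "fs")
  i0 <- attr(trajectory, "steady_start") + round(guard_s * fs)
  i1 <- attr(trajectory, "steady_end") - round(guard_s * fs)
  if (i1 <= i0) stop("steady-state window collapsed by the edge guard",
                     call. = FALSE)
  i0:i1
}

# crop a window to an integer number of cycles of frequency f so the
# fundamental falls exactly on an FFT bin (no leakage)
integer_cycle_window <- function(window, fs, f) {
  if (!is.finite(f) || f <= 0) return(window)
  samples_per_cycle <- fs / f
  n_cycles <- floor(length(window) / samples_per_cycle)
  if (n_cycles < 1) return(window)
  window[seq_len(round(n_cycles * samples_per_cycle))]
}

#' Extract the four kinematic features per segment from one session
#'
#' For each of the three segments: range of motion of the high-passed,
#' double-integrated displacement in the ML and AP directions over the
#' guarded steady-state window, and the spectral gain ratio / phase shift
#' of the segment's yaw relative to its proximal reference (pelvis vs
#' platform, trunk vs pelvis, head vs trunk), evaluated over a window
#' cropped to an integer number of perturbation cycles.
#'
#' @param session a `recording_session`.
#' @param cutoff displacement high-pass cutoff, Hz.
#' @param rom_guard_s edge guard of the range-of-motion window, seconds.
#'   The double high-pass at 0.2 Hz leaves edge transients that decay
#'   over a few filter time constants, so the displacement window starts
#'   well inside the steady state; the yaw coupling window, which
#'   involves no filtering, keeps a 1 s guard.
#' @return a tibble with one row per segment: `segment`, `rom_ml`,
#'   `rom_ap` (mm), `gain`, `phase` (deg).
#' @export
extract_session_features <- function(session, cutoff = 0.2,
                                     rom_guard_s = 5) {
  traj <- session$trajectory
  fs <- attr(traj, "fs")
  f_pert <- session$spec$frequency_hz[1]
  win <- steady_window(traj, guard_s = rom_guard_s)
  cwin <- integer_cycle_window(steady_window(traj, guard_s = 1), fs,
                               f_pert)

  yaws <- purrr::map(session$streams, function(s) {
    quat_yaw_deg(as.matrix(s[, c("qw", "qx", "qy", "qz")]))
  })
  reference <- list(
    pelvis = traj$yaw_deg,
    trunk = yaws$pelvis,
    head = yaws$trunk
  )
  purrr::map_dfr(SEGMENTS, function(seg) {
    s <- session$streams[[seg]]
    free <- world_linear_acceleration(s)
    disp_ml <- displacement_from_acceleration(free$ml, fs, cutoff)
    disp_ap <- displacement_from_acceleration(free$ap, fs, cutoff)
    cp <- coupling_indices(yaws[[seg]][cwin], reference[[seg]][cwin], fs)
    tibble::tibble(
      segment = seg,
      rom_ml = range_of_motion(disp_ml, win),
      rom_ap = range_of_motion(disp_ap, win),
      gain = cp$gain_ratio,
      phase = cp$phase_shift_deg
    )
  })
}

#' Assemble the 72-feature vector for one subject-state
#'
#' Takes per-trial, per-segment features for one subject in one state
#' (all 18 trials: 3 levels x 2 sides x 3 repetitions), averages the
#' repetitions of each of the 6 test types, and pivots to a single wide
#' row of 72 features named `{feature}_{segment}_{level}_{side}`.
#'
#' @param trial_features tibble with columns `level`, `start_side`,
#'   `segment`, `rom_ml`, `rom_ap`, `gain`, `phase` (one row per trial
#'   and segment; repeated test types are averaged).
#' @return a one-row tibble with 72 feature columns.
#' @export
assemble_features <- function(trial_features) {
  grid <- tidyr::crossing(
    level = PERTURBATION_TABLE$level,
    start_side = c("right", "left")
  )
  have <- dplyr::distinct(trial_features, .data$level, .data$start_side)
  missing <- dplyr::anti_join(grid, have, by = c("level", "start_side"))
  if (nrow(missing) > 0) {
    stop("missing test types: ",
         paste(missing$level, missing$start_side, sep = "/",
               collapse = ", "),
         call. = FALSE)
  }
  long <- trial_features |>
    dplyr::group_by(.data$level, .data$start_side, .data$segment) |>
    dplyr::summarise(dplyr::across(c("rom_ml", "rom_ap", "gain", "phase"),
                                   mean),
                     .groups = "drop") |>
    tidyr::pivot_longer(c("rom_ml", "rom_ap", "gain", "phase"),
                        names_to = "feature") |>
    dplyr::mutate(name = paste(.data$feature, .data$segment, .data$level,
                               .data$start_side, sep = "_")) |>
    dplyr::arrange(.data$name)
  tidyr::pivot_wider(long[, c("name", "value")], names_from = "name")
}

#' Extract the full feature table for a cohort
#'
#' Simulates all 18 protocol trials for every subject-state in the cohort
#' (seeded per-subject schedules and sensor noise), extracts the per-trial
#' features and assembles one 72-feature row per subject-state.
#'
#' @param cohort subject-profile tibble from [sample_cohort()].
#' @param duration,fs,ramp_duration trajectory parameters.
#' @param noise logical; `FALSE` simulates noise-free sessions.
#' @param seed integer seed (per-trial noise seeds are derived from it).
#' @param progress print a line per subject-state.
#' @return a tibble: `subject_id`, `group`, `state`, then 72 feature
#'   columns.
#' @examples
#' \donttest{
#' cohort <- sample_cohort(n_pd = 1, n_hc = 1, seed = 1)
#' feats <- extract_cohort_features(cohort, seed = 1)
#' dim(feats)
#' }
#' @export
extract_cohort_features <- function(cohort, duration = 30, fs = 100,
                                    ramp_duration = 2, noise = TRUE,
                                    seed = 0L, progress = FALSE) {
  # the six distinct trajectories are shared across subjects and trials
  specs <- tidyr::crossing(level = PERTURBATION_TABLE$level,
                           start_side = c("right", "left"))
  traj_cache <- purrr::pmap(specs, function(level, start_side) {
    make_trajectory(perturbation_spec(level, start_side),
                    duration, fs, ramp_duration)
  })
  names(traj_cache) <- paste(specs$level, specs$start_side, sep = "_")

  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    profile <- cohort[i, ]
    schedule <- make_schedule(seed = (seed + i * 131L) %% .Machine$integer.max)
    if (progress) {
      message(sprintf("extracting %s [%s] (%d/%d)", profile$subject_id,
                      profile$state, i, nrow(cohort)))
    }
    trial_feats <- purrr::map_dfr(seq_len(nrow(schedule)), function(j) {
      tr <- schedule[j, ]
      key <- paste(tr$level, tr$start_side, sep = "_")
      session <- simulate_session(
        profile, perturbation_spec(tr$level, tr$start_side),
        duration = duration, fs = fs, ramp_duration = ramp_duration,
        trajectory = traj_cache[[key]], noise = noise,
        seed = (seed + i * 1009L + j * 17L) %% .Machine$integer.max
      )
      dplyr::mutate(extract_session_features(session),
                    level = tr$level, start_side = tr$start_side)
    })
    dplyr::bind_cols(
      profile[, c("subject_id", "group", "state")],
      assemble_features(trial_feats)
    )
  })
  dplyr::bind_rows(rows)
}

#' Feature-column names of a feature table
#'
#' @param features a feature table.
#' @return character vector of the 72 feature column names (everything
#'   except `subject_id`, `group`, `state`).
#' @export
feature_columns <- function(features) {
  setdiff(names(features), c("subject_id", "group", "state"))
}

#' Write / read a feature table as CSV
#'
#' One row per subject-state: `subject_id`, `group`, `state`, then the 72
#' feature columns.
#'
#' @param features feature table from [extract_cohort_features()].
#' @param path file path.
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject_id = readr::col_character(),
                    group = readr::col_character(),
                    state = readr::col_character(),
                    .default = readr::col_double()
                  ))
}
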