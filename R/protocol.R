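# Platform perturbation protocol: yaw trajectories and the randomized
# 18-trial schedule (3 intensity levels x 2 starting sides x 3 repetitions).

# canonical (level, frequency, amplitude) conditions of the protocol
PERTURBATION_TABLE <- tibble::tibble(
  level = c("LP", "MP", "HP"),
  frequency_hz = c(0.2, 0.3, 0.5),
  peak_amplitude_deg = c(55, 55, 35)
)

SEGMENTS <- c("pelvis", "trunk", "head")

#' Perturbation condition specification
#'
#' Builds the specification of one sinusoidal yaw perturbation condition.
#' The three levels are fixed protocol conditions: low (LP, 0.2 Hz, +/-55
#' deg), medium (MP, 0.3 Hz, +/-55 deg) and high (HP, 0.5 Hz, +/-35 deg).
#' The starting side decides the sign of the initial sinusoid phase (right
#' = +sin, left = -sin).
#'
#' @param level one of `"LP"`, `"MP"`, `"HP"`.
#' @param start_side `"right"` or `"left"`.
#' @return a one-row tibble with columns `level`, `frequency_hz`,
#'   `peak_amplitude_deg`, `start_side`.
#' @examples
#' perturbation_spec("HP")
#' @export
perturbation_spec <- function(level = c("LP", "MP", "HP"),
                              start_side = c("right", "left")) {
  level <- match.arg(level)
  start_side <- match.arg(start_side)
  dplyr::mutate(
    dplyr::filter(PERTURBATION_TABLE, .data$level == !!level),
    start_side = !!start_side
  )
}

# unvalidated constructor, used internally and by tests exercising
# off-protocol conditions (e.g. zero amplitude)
new_perturbation_spec <- function(frequency_hz, peak_amplitude_deg,
                                  level = NA_character_,
                                  start_side = "right") {
  tibble::tibble(
    level = level,
    frequency_hz = frequency_hz,
    peak_amplitude_deg = peak_amplitude_deg,
    start_side = start_side
  )
}

#' Generate a ramped sinusoidal platform yaw trajectory
#'
#' The steady-state segment is `A * sin(2*pi*f*t + s0)` with `s0 = 0`
#' (right start) or `pi` (left start). A logistic amplitude envelope,
#' rescaled to run exactly from 0 to 1 over `ramp_duration`, ramps the
#' sinusoid on and off so the platform starts and ends at rest.
#'
#' @param spec a perturbation spec, see [perturbation_spec()].
#' @param duration steady-state duration in seconds; must cover at least 5
#'   full periods of the perturbation frequency.
#' @param fs sampling rate, Hz; must be at least 20 x the perturbation
#'   frequency.
#' @param ramp_duration duration of each sigmoidal ramp, seconds.
#' @return a tibble of class `platform_trajectory` with columns `time_s`
#'   and `yaw_deg`, and attributes `spec`, `fs`, `ramp_duration`,
#'   `steady_start`, `steady_end` (sample indices delimiting the un-ramped
#'   portion).
#' @examples
#' traj <- make_trajectory(perturbation_spec("LP"), duration = 30)
#' range(traj$yaw_deg)
#' @export
make_trajectory <- function(spec, duration = 30, fs = 100,
                            ramp_duration = 2) {
  f <- spec$frequency_hz[1]
  amp <- spec$peak_amplitude_deg[1]
  side <- spec$start_side[1]
  if (!is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  }
  if (f > 0 && fs < 20 * f) {
    stop("`fs` must be at least 20 times the perturbation frequency",
         call. = FALSE)
  }
  if (f > 0 && duration < 5 / f) {
    stop(sprintf(
      "steady-state duration %.3g s is too short: at least 5 full periods (%.3g s) of the %.3g Hz perturbation are required",
      duration, 5 / f, f
    ), call. = FALSE)
  }
  total <- 2 * ramp_duration + duration
  time_s <- seq(0, total, by = 1 / fs)
  s0 <- if (identical(side, "left")) pi else 0
  yaw <- amp * sin(2 * pi * f * (time_s - ramp_duration) + s0)
  env <- ramp_envelope(time_s, ramp_duration, total)
  steady_start <- which(time_s >= ramp_duration)[1]
  steady_end <- max(which(time_s <= total - ramp_duration))
  out <- tibble::tibble(time_s = time_s, yaw_deg = env * yaw)
  structure(
    out,
    class = c("platform_trajectory", class(out)),
    spec = spec,
    fs = fs,
    ramp_duration = ramp_duration,
    steady_start = steady_start,
    steady_end = steady_end
  )
}

# logistic envelope rescaled to hit exactly 0 at the trajectory ends and
# exactly 1 at the steady-state boundaries; steepness 12/ramp keeps the
# slope mismatch at the boundaries ~1% of the peak sinusoid slope
ramp_envelope <- function(time_s, ramp_duration, total) {
  if (ramp_duration <= 0) return(rep(1, length(time_s)))
  k <- 12 / ramp_duration
  logi <- function(u) 1 / (1 + exp(-k * (u - ramp_duration / 2)))
  lo <- logi(0); hi <- logi(ramp_duration)
  rescale <- function(u) (logi(u) - lo) / (hi - lo)
  env <- rep(1, length(time_s))
  up <- time_s < ramp_duration
  down <- time_s > total - ramp_duration
  env[up] <- rescale(time_s[up])
  env[down] <- rescale(total - time_s[down])
  pmin(pmax(env, 0), 1)
}

#' Randomized trial schedule for one recording session
#'
#' Each of the six test types (3 perturbation levels x 2 starting sides)
#' is repeated three times, for a total of 18 trials, in a seeded random
#' order so that subjects cannot anticipate the perturbation.
#'
#' @param seed integer seed for the shuffle.
#' @return a tibble with columns `trial`, `level`, `frequency_hz`,
#'   `peak_amplitude_deg`, `start_side`, plus attribute `seed`.
#' @examples
#' make_schedule(seed = 1)
#' @export
make_schedule <- function(seed = 0L) {
  grid <- tidyr::crossing(
    PERTURBATION_TABLE,
    start_side = c("right", "left"),
    rep = 1:3
  )
  ord <- with_seed(seed, sample.int(nrow(grid)))
  out <- dplyr::select(grid[ord, ], -"rep")
  out <- dplyr::mutate(out, trial = dplyr::row_number(), .before = 1)
  structure(out, seed = seed)
}

#' Write / read a platform trajectory as CSV
#'
#' Two-column CSV (`time_s`, `yaw_deg`) with a header. Reading returns a
#' plain tibble (steady-state indices are not stored in the file).
#'
#' @param trajectory a `platform_trajectory`.
#' @param path file path.
#' @return `write_trajectory_csv()` returns `path` invisibly;
#'   `read_trajectory_csv()` returns a tibble.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  readr::write_csv(tibble::as_tibble(trajectory)[, c("time_s", "yaw_deg")],
                   path)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @method autoplot platform_trajectory
#' @export
autoplot.platform_trajectory <- function(object, ...) {
  i0 <- attr(object, "steady_start")
  i1 <- attr(object, "steady_end")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data$yaw_deg)) +
    ggplot2::annotate(
      "rect",
      xmin = object$time_s[i0], xmax = object$time_s[i1],
      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "steelblue"
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time (s)", y = "platform yaw (deg)",
      title = "Platform yaw trajectory",
      subtitle = "shaded region: steady-state (un-ramped) segment"
    )
}
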