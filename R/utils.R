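# Internal numeric helpers: angle wrapping, spectra, quaternions.

#' Wrap angles to the interval (-180, 180] degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of the same length, wrapped to (-180, 180].
#' @examples
#' wrap_degrees(c(270, -180, 90))
#' @export
wrap_degrees <- function(x) {
  x - 360 * ceiling((x - 180) / 360)
}

#' Dominant spectral frequency of a uniformly sampled signal
#'
#' Locates the maximum-magnitude FFT bin of `x` (DC excluded) inside a
#' frequency band, breaking ties toward the lower frequency. This is the
#' fundamental-frequency detector used both to verify generated platform
#' trajectories and to pick the bin at which inter-segment gain and phase
#' are evaluated.
#'
#' @param x numeric signal (mean is removed before the transform).
#' @param fs sampling rate, Hz.
#' @param band two-element numeric, frequency search band in Hz.
#' @return frequency of the maximum-magnitude bin, Hz.
#' @export
dominant_frequency <- function(x, fs, band = c(0.05, 2)) {
  stopifnot(is.numeric(x), length(x) > 3, fs > 0)
  x <- x - mean(x)
  n <- length(x)
  sp <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- seq_len(floor(n / 2) + 1L)
  mag <- Mod(sp[half])
  freqs <- freqs[half]
  keep <- freqs >= band[1] & freqs <= band[2] & freqs > 0
  if (!any(keep)) stop("no spectral bins inside the requested band")
  mag <- mag[keep]
  freqs <- freqs[keep]
  # which.max returns the first maximum; freqs ascend, so ties resolve low
  freqs[which.max(mag)]
}

# --- quaternion helpers (scalar-first w,x,y,z; body -> world rotation) ---

# quaternion for a rotation about a single axis, angle in degrees; vectorized
quat_axis <- function(angle_deg, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  h <- angle_deg * pi / 360  # half angle in radians
  z <- numeric(length(h))
  q <- cbind(w = cos(h), x = z, y = z, z = z)
  q[, switch(axis, x = "x", y = "y", z = "z")] <- sin(h)
  q
}

# Hamilton product of two n x 4 quaternion matrices (rowwise)
quat_multiply <- function(a, b) {
  cbind(
    w = a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    x = a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    y = a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    z = a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

quat_normalize <- function(q) {
  q / sqrt(rowSums(q^2))
}

# rotate body-frame vectors v (n x 3) into the world frame by quaternions q
# (n x 4): v_w = v + 2*w*(u x v) + 2*(u x (u x v)), u the vector part
quat_rotate <- function(q, v) {
  ux <- q[, 2]; uy <- q[, 3]; uz <- q[, 4]; w <- q[, 1]
  vx <- v[, 1]; vy <- v[, 2]; vz <- v[, 3]
  # t = 2 * (u x v)
  tx <- 2 * (uy * vz - uz * vy)
  ty <- 2 * (uz * vx - ux * vz)
  tz <- 2 * (ux * vy - uy * vx)
  cbind(
    vx + w * tx + (uy * tz - uz * ty),
    vy + w * ty + (uz * tx - ux * tz),
    vz + w * tz + (ux * ty - uy * tx)
  )
}

# inverse rotation (world -> body): conjugate quaternion
quat_rotate_inverse <- function(q, v) {
  quat_rotate(cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4]), v)
}

# yaw angle (rotation about world Z) in degrees from quaternions, ZYX
# convention; continuous for |yaw| < 180
quat_yaw_deg <- function(q) {
  atan2(2 * (q[, 1] * q[, 4] + q[, 2] * q[, 3]),
        1 - 2 * (q[, 3]^2 + q[, 4]^2)) * 180 / pi
}

# centered first derivative on a uniform grid (one-sided at the ends)
centered_gradient <- function(x, dt) {
  n <- length(x)
  g <- numeric(n)
  g[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  g[1] <- (x[2] - x[1]) / dt
  g[n] <- (x[n] - x[n - 1]) / dt
  g
}

# small wrapper so every seeded draw in the package goes through one place
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
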