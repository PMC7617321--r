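#' Angle conventions
#'
#' All orientations in this package are axial quantities: defined modulo 180
#' degrees, measured from the +x image axis toward +y (pixel coordinates,
#' 0-based, x rightward, y downward). After normalization against the sensory
#' organ precursor (SOP) reference axis, 0 degrees is the proximodistal (PD)
#' wing axis and 90 degrees the anteroposterior (AP) axis.
#'
#' @name angle-conventions
NULL

#' Reference axis given by the SOP cell line
#'
#' The line formed by the sensory organ precursor cells defines the 0-degree
#' (proximodistal) reference; every orientation in the pipeline is reported
#' relative to it.
#'
#' @param sop_angle_raw Image-frame angle of the SOP line, in degrees.
#' @return An object of class `reference_axis`.
#' @export
reference_axis <- function(sop_angle_raw = 0) {
  stopifnot(is.numeric(sop_angle_raw), length(sop_angle_raw) == 1L,
            is.finite(sop_angle_raw))
  structure(list(sop_angle_raw = as.numeric(sop_angle_raw)),
            class = "reference_axis")
}

#' @export
print.reference_axis <- function(x, ...) {
  cat(sprintf("Reference axis: SOP line at %.3f deg (image frame)\n",
              x$sop_angle_raw))
  invisible(x)
}

as_axis <- function(axis) {
  if (inherits(axis, "reference_axis")) return(axis)
  reference_axis(axis)
}

#' Normalize an image-frame angle against the SOP axis
#'
#' @param raw_angle Angle(s) in degrees, image frame.
#' @param axis A [reference_axis()] (or a bare numeric SOP angle).
#' @return Angle(s) in `[0, 180)` with 0 = PD axis, 90 = AP axis.
#' @export
normalize_angle <- function(raw_angle, axis = reference_axis(0)) {
  axis <- as_axis(axis)
  stopifnot(all(is.finite(raw_angle)))
  (raw_angle - axis$sop_angle_raw) %% 180
}

#' Classify an orientation as PD or AP
#'
#' Angles in `[45, 135)` are AP-oriented; the rest of `[0, 180)` is
#' PD-oriented. The same partition is used for junctions, divisions and T1s.
#'
#' @param orientation SOP-normalized angle(s) in `[0, 180)`.
#' @return Character vector of `"PD"` / `"AP"`.
#' @export
classify_orientation <- function(orientation) {
  stopifnot(all(orientation >= 0 & orientation < 180))
  ifelse(orientation >= 45 & orientation < 135, "AP", "PD")
}

## Angle of the vector (dx, dy) in the package axial convention, degrees
## in [0, 180). dy is in image coordinates (downward); orientation increases
## counterclockwise on screen, i.e. from +x toward -y.
axial_angle <- function(dx, dy) {
  (atan2(-dy, dx) * 180 / pi) %% 180
}

## Unit direction vector (dx, dy) of an axial angle in degrees.
axial_unit <- function(theta_deg) {
  t <- theta_deg * pi / 180
  cbind(dx = cos(t), dy = -sin(t))
}

## Smallest axial (mod-180) difference between two angles, in [0, 90].
axial_diff <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Nematic (double-angle) mean of axial orientations
#'
#' Averages axial angles as nematic tensors:
#' `Q = mean(weight * (cos 2 theta, sin 2 theta))`, returning the mean
#' direction `atan2(Qy, Qx) / 2` mod 180 and the resultant magnitude `|Q|`.
#' This is the correct average for orientations defined modulo 180 degrees;
#' orthogonal axes of equal weight cancel to magnitude 0 (angle reported 0).
#'
#' @param theta_deg Axial angles in degrees.
#' @param weight Nonnegative weights (e.g. polarity magnitudes).
#' @return List with `angle` (degrees in `[0, 180)`) and `magnitude`.
#' @export
nematic_mean <- function(theta_deg, weight = rep(1, length(theta_deg))) {
  stopifnot(length(theta_deg) == length(weight))
  t2 <- 2 * theta_deg * pi / 180
  qx <- mean(weight * cos(t2))
  qy <- mean(weight * sin(t2))
  mag <- sqrt(qx^2 + qy^2)
  ang <- if (mag < .Machine$double.eps^0.75) 0 else
    (atan2(qy, qx) * 90 / pi) %% 180
  list(angle = ang, magnitude = mag)
}

#' Sample axial von Mises orientations
#'
#' Axial orientations (period 180 degrees) are drawn by sampling a circular
#' von Mises distribution on `[0, 360)` and halving the angle (the standard
#' doubling trick for axial data). `kappa = 0` gives the uniform axial
#' distribution; large `kappa` concentrates angles at `mu`.
#'
#' @param n Number of samples.
#' @param mu Axial mean direction, degrees in `[0, 180)`.
#' @param kappa Concentration parameter, `>= 0`.
#' @return Angles in degrees, in `[0, 180)`.
#' @export
rvonmises_axial <- function(n, mu, kappa) {
  stopifnot(kappa >= 0, n >= 0)
  if (n == 0) return(numeric(0))
  theta2 <- rvonmises_circ(n, 2 * mu * pi / 180, kappa)
  ((theta2 * 180 / pi) / 2) %% 180
}

## Circular von Mises sampler (Best & Fisher rejection), mean mu_rad, conc kappa.
rvonmises_circ <- function(n, mu_rad, kappa) {
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- (mu_rad + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}
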