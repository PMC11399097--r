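# hc in eV * Angstrom; reproduces 1.55 A at 8000 eV to 2 d.p.
HC_EV_ANGSTROM <- 12398.42

#' Convert photon energy to X-ray wavelength
#'
#' \eqn{\lambda = hc/E} with \eqn{hc = 12398.42} eV·Å, so 8,000 eV maps to
#' 1.55 Å.
#'
#' @param photon_energy Photon energy in eV. Must be positive.
#' @return Wavelength in Å.
#' @examples
#' wavelength_from_energy(8000)  # 1.5498 A
#' @export
wavelength_from_energy <- function(photon_energy) {
  if (!is.numeric(photon_energy) || any(!is.finite(photon_energy)) ||
      any(photon_energy <= 0)) {
    stop("photon_energy must be a positive finite number (eV)")
  }
  HC_EV_ANGSTROM / photon_energy
}

#' Momentum transfer from scattering half-angle
#'
#' \eqn{q = 4\pi \sin\theta / \lambda}, where \eqn{2\theta} is the full
#' scattering angle and \eqn{\lambda} the X-ray wavelength.
#'
#' @param theta Half the scattering angle, in radians, in \eqn{[0, \pi/2)}.
#' @param wavelength X-ray wavelength in Å.
#' @return Momentum transfer q in Å\eqn{^{-1}}.
#' @seealso [theta_from_q()] for the inverse, [resolution_from_q()].
#' @export
q_from_scattering_angle <- function(theta, wavelength) {
  if (!is.numeric(theta) || any(!is.finite(theta)) ||
      any(theta < 0) || any(theta >= pi / 2)) {
    stop("theta must lie in [0, pi/2)")
  }
  if (!is.numeric(wavelength) || any(wavelength <= 0)) {
    stop("wavelength must be positive (Angstrom)")
  }
  4 * pi * sin(theta) / wavelength
}

#' Scattering half-angle from momentum transfer
#'
#' Inverse of [q_from_scattering_angle()]: \eqn{\theta = \arcsin(q\lambda/4\pi)}.
#'
#' @param q Momentum transfer in Å\eqn{^{-1}}.
#' @param wavelength X-ray wavelength in Å.
#' @return Half scattering angle in radians.
#' @export
theta_from_q <- function(q, wavelength) {
  s <- q * wavelength / (4 * pi)
  if (any(s < 0) || any(s >= 1)) stop("q out of reachable range for this wavelength")
  asin(s)
}

#' Real-space resolution corresponding to a momentum transfer
#'
#' \eqn{d = 2\pi/q}: q = 1.5 Å\eqn{^{-1}} corresponds to 4.2 Å.
#'
#' @param q Momentum transfer in Å\eqn{^{-1}}, positive.
#' @return Spatial resolution d in Å.
#' @export
resolution_from_q <- function(q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0)) {
    stop("q must be positive (1/Angstrom)")
  }
  2 * pi / q
}

#' Intra-train pulse delay grid
#'
#' Delay times of the probe pulses within one train: \eqn{t_j = j/\nu},
#' j = 0..n-1, returned in microseconds. At the 564 kHz intra-train rate the
#' spacing is 1.77 µs and 175 pulses span ~308.5 µs.
#'
#' @param n_pulses Number of pulses per train (>= 1).
#' @param intra_train_rate Intra-train repetition rate in Hz.
#' @return Numeric vector of delay times in µs.
#' @export
pulse_time_grid <- function(n_pulses, intra_train_rate) {
  if (n_pulses < 1 || n_pulses != round(n_pulses)) stop("n_pulses must be a positive integer")
  if (intra_train_rate <= 0) stop("intra_train_rate must be positive (Hz)")
  (seq_len(n_pulses) - 1) * 1e6 / intra_train_rate
}

#' Momentum-transfer grid
#'
#' A strictly increasing q grid with half-open bin edges \code{[lo, hi)}.
#' The default analysis grid is 170 linear points in 0.08–1.5 Å\eqn{^{-1}};
#' a wider reduction grid up to 2.1 Å\eqn{^{-1}} can be requested.
#'
#' @param q_min,q_max Grid span in Å\eqn{^{-1}}.
#' @param n Number of bin centers.
#' @return An object of class \code{q_grid} with elements \code{values}
#'   (bin centers) and \code{edges} (length n + 1).
#' @export
q_grid <- function(q_min = 0.08, q_max = 1.5, n = 170) {
  if (q_min <= 0 || q_max <= q_min) stop("need 0 < q_min < q_max")
  if (n < 1) stop("n must be >= 1")
  values <- seq(q_min, q_max, length.out = n)
  half <- if (n > 1) diff(values)[1] / 2 else (q_max - q_min) / 2 + 1e-6
  edges <- c(values - half, values[n] + half)
  structure(list(values = values, edges = edges), class = "q_grid")
}

#' @export
print.q_grid <- function(x, ...) {
  cat(sprintf("q grid: %d bins, %.4g - %.4g 1/A\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

as_q_grid <- function(q) {
  if (inherits(q, "q_grid")) return(q)
  if (is.numeric(q) && length(q) >= 1 && all(diff(q) > 0)) {
    n <- length(q)
    mids <- if (n > 1) (q[-1] + q[-n]) / 2 else numeric(0)
    lo <- if (n > 1) q[1] - (mids[1] - q[1]) else q[1] * 0.99
    hi <- if (n > 1) q[n] + (q[n] - mids[n - 1]) else q[1] * 1.01
    return(structure(list(values = q, edges = c(lo, mids, hi)), class = "q_grid"))
  }
  stop("q must be a q_grid or a strictly increasing numeric vector")
}

#' Beamline geometry description
#'
#' Detector and beam parameters needed to map detector pixels to momentum
#' transfer. Defaults mirror a MHz XFEL solution-scattering setup: 8,000 eV
#' photons (1.55 Å) and a detector 0.281 m downstream. Pixel indexing is
#' 0-based in (row, column) order.
#'
#' @param photon_energy Photon energy in eV.
#' @param detector_distance Sample–detector distance in m.
#' @param pixel_pitch Pixel size in m.
#' @param beam_center Length-2 numeric, beam center in pixels (row, column),
#'   0-based.
#' @param mask Logical matrix, \code{TRUE} = usable pixel, or \code{NULL}.
#' @param wavelength Optional wavelength in Å; must agree with
#'   \code{photon_energy} via \eqn{\lambda = hc/E} within 0.5%.
#' @return An object of class \code{beamline_geometry}.
#' @export
beamline_geometry <- function(photon_energy = 8000,
                              detector_distance = 0.281,
                              pixel_pitch = 200e-6,
                              beam_center = c(0, 0),
                              mask = NULL,
                              wavelength = NULL) {
  lambda <- wavelength_from_energy(photon_energy)
  if (!is.null(wavelength)) {
    if (abs(wavelength - lambda) / lambda > 0.005) {
      stop("wavelength inconsistent with photon_energy (lambda = hc/E) beyond 0.5%")
    }
    lambda <- wavelength
  }
  if (detector_distance <= 0) stop("detector_distance must be positive (m)")
  if (pixel_pitch <= 0) stop("pixel_pitch must be positive (m)")
  if (length(beam_center) != 2) stop("beam_center must be (row, column)")
  structure(list(photon_energy = photon_energy, wavelength = lambda,
                 detector_distance = detector_distance,
                 pixel_pitch = pixel_pitch, beam_center = beam_center,
                 mask = mask),
            class = "beamline_geometry")
}

#' Per-pixel momentum transfer of a detector image
#'
#' q at each pixel center given the geometry: the in-plane radius r gives
#' \eqn{2\theta = \arctan(r/D)} and \eqn{q = 4\pi\sin\theta/\lambda}.
#'
#' @param dims Image dimensions (rows, cols).
#' @param geometry A [beamline_geometry()].
#' @return Matrix of q values, Å\eqn{^{-1}}.
#' @export
pixel_q_map <- function(dims, geometry) {
  rows <- matrix(seq_len(dims[1]) - 1, dims[1], dims[2])
  cols <- matrix(seq_len(dims[2]) - 1, dims[1], dims[2], byrow = TRUE)
  dr <- (rows - geometry$beam_center[1]) * geometry$pixel_pitch
  dc <- (cols - geometry$beam_center[2]) * geometry$pixel_pitch
  r <- sqrt(dr^2 + dc^2)
  two_theta <- atan2(r, geometry$detector_distance)
  4 * pi * sin(two_theta / 2) / geometry$wavelength
}

#' Azimuthal integration of a detector image
#'
#' Bins unmasked pixels into rings of momentum transfer: each q bin receives
#' the mean of the pixel values whose pixel-center q falls inside the bin's
#' half-open interval \code{[lo, hi)}. Bins with no usable pixels are flagged
#' (\code{NA} intensity), never silently zero.
#'
#' @param image Numeric matrix of photon counts.
#' @param geometry A [beamline_geometry()]; its \code{mask} (if any) must
#'   match the image dimensions.
#' @param grid A [q_grid()].
#' @return A \code{radial_profile}: list with \code{q} (grid), \code{intensity}
#'   (per-bin mean, \code{NA} where empty) and \code{counts_per_bin}.
#' @export
azimuthal_integrate <- function(image, geometry, grid) {
  grid <- as_q_grid(grid)
  mask <- geometry$mask
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  if (!all(dim(mask) == dim(image))) stop("mask dimensions must match image")
  if (!any(mask)) stop("mask removes every pixel")
  qmap <- pixel_q_map(dim(image), geometry)
  idx <- findInterval(qmap[mask], grid$edges, left.open = FALSE,
                      rightmost.closed = FALSE)
  vals <- image[mask]
  nb <- length(grid$values)
  inside <- idx >= 1 & idx <= nb
  counts <- tabulate(idx[inside], nbins = nb)
  sums <- rep(0, nb)
  if (any(inside)) {
    agg <- rowsum(vals[inside], idx[inside])
    sums[as.integer(rownames(agg))] <- agg[, 1]
  }
  intensity <- ifelse(counts > 0, sums / pmax(counts, 1), NA_real_)
  radial_profile(grid, intensity, counts_per_bin = counts)
}

#' Radial (1D) scattering profile
#'
#' @param q A [q_grid()] or increasing numeric vector.
#' @param intensity Per-bin intensity (photons or normalized); \code{NA} marks
#'   bins with no usable pixels.
#' @param counts_per_bin Optional integer pixel tally per bin.
#' @return Object of class \code{radial_profile}.
#' @export
radial_profile <- function(q, intensity, counts_per_bin = NULL) {
  q <- as_q_grid(q)
  if (length(intensity) != length(q$values)) stop("intensity length must match q grid")
  if (any(is.infinite(intensity))) stop("intensity must be finite or NA")
  if (!is.null(counts_per_bin) && any(counts_per_bin < 0)) {
    stop("counts_per_bin must be non-negative")
  }
  structure(list(q = q, intensity = as.numeric(intensity),
                 counts_per_bin = counts_per_bin),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("radial profile: %d q bins (%.3g - %.3g 1/A), %d empty\n",
              length(x$q$values), min(x$q$values), max(x$q$values),
              sum(is.na(x$intensity))))
  invisible(x)
}
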