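#' Scaled-grating stimulus catalog
#'
#' Scaled gratings are log-polar patterns
#' \deqn{I(r, \theta) = \cos(\omega_r \ln r + \omega_a \theta + \phi)}
#' whose local spatial frequency falls off as 1/eccentricity, so a single
#' image probes every retinotopic location near its sensitive range. A class
#' is defined by its frequency vector \eqn{(\omega_r, \omega_a)}:
#' \eqn{\omega_r} is the radial frequency (radians per unit increase in
#' \eqn{\ln r}) and \eqn{\omega_a} the angular frequency (cycles per
#' revolution; constrained to integers to avoid edge artifacts).
#'
#' The `"nsd"` design is the 28-class set used in the NSD synthetic session:
#' six pinwheels (\eqn{\omega_r = 0}), six annuli (\eqn{\omega_a = 0}), six
#' forward and six reverse spirals (\eqn{|\omega_r| = |\omega_a|}), and four
#' intermediate "mixture" classes, each shown at four phases
#' (0, 1.57, 3.14, 4.71 rad). Base frequencies
#' \eqn{\sqrt{\omega_r^2 + \omega_a^2}} are matched across shapes only
#' approximately, because the integer constraint on \eqn{\omega_a} forces
#' slight discrepancies between the annulus/pinwheel and spiral sets.
#'
#' @param design `"nsd"` for the 28-class NSD set, or `"custom"`.
#' @param custom_vectors for `design = "custom"`, a data.frame with columns
#'   `omega_r`, `omega_a` and optionally `shape`.
#' @param phases phase offsets (radians) shared by every class.
#' @return A data.frame with one row per stimulus class: `class_id`, `shape`,
#'   `omega_r`, `omega_a`, `base_frequency`, and the phase vector stored in
#'   the `"phases"` attribute.
#' @examples
#' cat28 <- make_catalog()
#' nrow(cat28)                      # 28
#' table(cat28$shape)
#' @export
make_catalog <- function(design = c("nsd", "custom"), custom_vectors = NULL,
                         phases = c(0, 1.57, 3.14, 4.71)) {
  design <- match.arg(design)
  if (design == "nsd") {
    pin <- data.frame(shape = "pinwheel", omega_r = 0,
                      omega_a = c(-6, -11, -20, -37, -69, -128))
    ann <- data.frame(shape = "annulus", omega_r = c(6, 11, 20, 37, 69, 128),
                      omega_a = 0)
    k <- c(4, 7, 14, 26, 49, 91)
    fwd <- data.frame(shape = "forward_spiral", omega_r = k, omega_a = -k)
    rev <- data.frame(shape = "reverse_spiral", omega_r = k, omega_a = k)
    mix <- data.frame(shape = "mixture",
                      omega_r = c(14, 34, 34, 14),
                      omega_a = c(-34, -14, 14, 34))
    tab <- rbind(pin, ann, fwd, rev, mix)
  } else {
    if (is.null(custom_vectors))
      stop("custom design requires `custom_vectors`")
    tab <- as.data.frame(custom_vectors)
    stopifnot(all(c("omega_r", "omega_a") %in% names(tab)))
    if (is.null(tab$shape)) tab$shape <- classify_shape(tab$omega_r, tab$omega_a)
  }
  if (any(tab$omega_a != round(tab$omega_a)))
    stop("angular frequencies omega_a must be integers")
  if (any(tab$omega_r == 0 & tab$omega_a == 0))
    stop("invalid stimulus class: omega_r and omega_a are both zero")
  tab$base_frequency <- sqrt(tab$omega_r^2 + tab$omega_a^2)
  tab <- data.frame(class_id = seq_len(nrow(tab)), tab, stringsAsFactors = FALSE)
  attr(tab, "phases") <- phases
  tab
}

classify_shape <- function(omega_r, omega_a) {
  out <- rep("mixture", length(omega_r))
  out[omega_r == 0] <- "pinwheel"
  out[omega_a == 0] <- "annulus"
  sp <- abs(omega_r) == abs(omega_a) & omega_r != 0
  out[sp & sign(omega_r) != sign(omega_a)] <- "forward_spiral"
  out[sp & sign(omega_r) == sign(omega_a)] <- "reverse_spiral"
  out
}

#' Expand a catalog into (class, phase) exemplars
#'
#' @param catalog a catalog from [make_catalog()].
#' @return A data.frame with one row per (class, phase) pair.
#' @export
catalog_exemplars <- function(catalog) {
  phases <- attr(catalog, "phases")
  out <- catalog[rep(seq_len(nrow(catalog)), each = length(phases)), ]
  out$phase <- rep(phases, times = nrow(catalog))
  rownames(out) <- NULL
  out
}

#' Local spatial frequency and orientation of a scaled grating
#'
#' At visual-field position \eqn{(r, \theta)}, the local spatial frequency of
#' the grating is \eqn{\sqrt{\omega_r^2 + \omega_a^2} / r} in radians per
#' degree, i.e. \eqn{\sqrt{\omega_r^2+\omega_a^2} / (2\pi r)} cycles per
#' degree, and the local orientation is
#' \eqn{\theta_l = \theta + \arctan(\omega_a / \omega_r)}, reduced mod
#' \eqn{\pi}. Under this convention an annulus on the right horizontal
#' meridian (\eqn{\theta = 0}) has \eqn{\theta_l = 0} and vertically oriented
#' contours; \eqn{\theta_l} is the direction of the local phase gradient.
#'
#' @param r_deg eccentricity (degrees), > 0. Vectorized.
#' @param theta_rad polar angle (radians, counterclockwise from the positive
#'   x-axis).
#' @param omega_r,omega_a the frequency vector.
#' @return A data.frame with `sf_cpd` (cycles/degree), `period_dpc`
#'   (degrees/cycle) and `ori_rad` (radians in `[0, pi)`).
#' @examples
#' local_stimulus(1, 0, omega_r = 6, omega_a = 0)  # sf = 6 / (2*pi)
#' @export
local_stimulus <- function(r_deg, theta_rad, omega_r, omega_a) {
  if (any(r_deg <= 0)) stop("r_deg must be > 0")
  base <- sqrt(omega_r^2 + omega_a^2)
  if (any(base == 0)) stop("degenerate frequency vector (0, 0)")
  sf <- base / (2 * pi * r_deg)
  ori <- mod_pi(theta_rad + atan2(omega_a, omega_r))
  data.frame(sf_cpd = sf, period_dpc = 1 / sf, ori_rad = ori)
}

#' Anti-aliasing mask radius for a scaled grating
#'
#' The local spatial frequency of a scaled grating diverges toward the image
#' center; inside the radius where it exceeds the display's renderable cutoff
#' the stimulus is replaced by mean luminance. The radius at which the local
#' frequency equals `cutoff_cpd` is
#' \eqn{\sqrt{\omega_r^2+\omega_a^2} / (2\pi \cdot \mathrm{cutoff})}.
#'
#' @param omega_r,omega_a the frequency vector.
#' @param cutoff_cpd highest renderable spatial frequency (cycles/degree).
#' @return Mask radius in degrees; increases with base frequency.
#' @export
mask_radius <- function(omega_r, omega_a, cutoff_cpd) {
  stopifnot(cutoff_cpd > 0)
  sqrt(omega_r^2 + omega_a^2) / (2 * pi * cutoff_cpd)
}

#' Render a scaled grating image
#'
#' Evaluates \eqn{\cos(\omega_r \ln r + \omega_a \theta + \phi)} on a square
#' pixel grid in visual-field coordinates (x rightward, y upward, theta
#' counterclockwise from +x). Pixels inside the anti-aliasing mask radius —
#' by default the radius where the local frequency reaches the grid Nyquist
#' limit, `ppd / 2` — are set to 0 (mean luminance), which also covers the
#' \eqn{r = 0} singularity of \eqn{\ln r} whenever the mask is non-empty.
#'
#' @param omega_r,omega_a frequency vector of the class.
#' @param phase phase offset (radians).
#' @param n_px image width in pixels (>= 16).
#' @param extent_deg image width in degrees of visual angle.
#' @param cutoff_cpd anti-aliasing cutoff; default `ppd / 2` (grid Nyquist).
#' @param outer_radius_deg optional circular outer aperture (degrees); pixels
#'   beyond it are set to 0. `NULL` (default) keeps the full square extent.
#' @return An object of class `grating_image`: list with `pixels` (n_px x
#'   n_px matrix, rows = y from top), `extent_deg`, `ppd`, `mask_radius_deg`.
#' @export
render_grating <- function(omega_r, omega_a, phase = 0, n_px = 512,
                           extent_deg = 8.4, cutoff_cpd = NULL,
                           outer_radius_deg = NULL) {
  stopifnot(n_px >= 16, extent_deg > 0)
  ppd <- n_px / extent_deg
  if (is.null(cutoff_cpd)) cutoff_cpd <- ppd / 2
  rmask <- mask_radius(omega_r, omega_a, cutoff_cpd)

  half <- extent_deg / 2
  px <- extent_deg / n_px
  coord <- (seq_len(n_px) - 0.5) * px - half   # pixel centers
  x <- matrix(coord, n_px, n_px, byrow = TRUE)
  y <- matrix(rev(coord), n_px, n_px)          # row 1 = top = +y
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)

  radial <- if (omega_r == 0) 0 else omega_r * log(r)
  img <- cos(radial + omega_a * th + phase)
  img[r < rmask] <- 0
  if (!is.null(outer_radius_deg)) img[r > outer_radius_deg] <- 0
  img[is.na(img)] <- 0   # r = 0 with omega_r != 0 and empty mask

  structure(list(pixels = img, extent_deg = extent_deg, ppd = ppd,
                 mask_radius_deg = rmask),
            class = "grating_image")
}

#' @export
print.grating_image <- function(x, ...) {
  cat(sprintf("<grating_image %dx%d px, %.2f deg, ppd %.1f, mask %.3f deg>\n",
              nrow(x$pixels), ncol(x$pixels), x$extent_deg, x$ppd,
              x$mask_radius_deg))
  invisible(x)
}

#' Measure the local phase-gradient field of a rendered grating
#'
#' Independent numerical measurement of a rendered stimulus: the local phase
#' is recovered in quadrature from two renders of the same class at `phase`
#' and `phase + pi/2` (\eqn{\psi = \mathrm{atan2}(-I_{\pi/2}, I_0)}), and its
#' gradient is estimated by centered finite differences with per-step phase
#' unwrapping. Used to validate the analytic local-frequency and orientation
#' fields against what the images actually contain.
#'
#' @inheritParams render_grating
#' @param r_deg,theta_rad polar positions (vectorized) at which to sample the
#'   measured field; snapped to the nearest pixel.
#' @return data.frame with `sf_cpd_measured` and `ori_rad_measured`.
#' @export
measure_local_frequency <- function(omega_r, omega_a, r_deg, theta_rad,
                                    n_px = 512, extent_deg = 8.4) {
  g0 <- render_grating(omega_r, omega_a, phase = 0, n_px = n_px,
                       extent_deg = extent_deg)
  gq <- render_grating(omega_r, omega_a, phase = pi / 2, n_px = n_px,
                       extent_deg = extent_deg)
  psi <- atan2(-gq$pixels, g0$pixels)
  px <- extent_deg / n_px

  wrap <- function(d) atan2(sin(d), cos(d))  # principal value of a phase step
  # centered differences over 2 pixels; columns index x, rows index y (top=+y)
  n <- n_px
  dpsi_dx <- matrix(NA_real_, n, n)
  dpsi_dx[, 2:(n - 1)] <- wrap(psi[, 3:n] - psi[, 1:(n - 2)]) / (2 * px)
  dpsi_dy <- matrix(NA_real_, n, n)
  dpsi_dy[2:(n - 1), ] <- wrap(psi[1:(n - 2), ] - psi[3:n, ]) / (2 * px)

  half <- extent_deg / 2
  xs <- r_deg * cos(theta_rad)
  ys <- r_deg * sin(theta_rad)
  col <- pmin(pmax(round((xs + half) / px + 0.5), 1), n)
  row <- pmin(pmax(round((half - ys) / px + 0.5), 1), n)
  idx <- cbind(row, col)
  gx <- dpsi_dx[idx]
  gy <- dpsi_dy[idx]
  data.frame(sf_cpd_measured = sqrt(gx^2 + gy^2) / (2 * pi),
             ori_rad_measured = mod_pi(atan2(gy, gx)))
}

#' Write a stimulus set to disk
#'
#' Renders every (class, phase) exemplar of a catalog as an 8-bit grayscale
#' PNG (intensity mapped from \[-1, 1\] to \[0, 255\]) and writes a sidecar
#' CSV catalog (`class_id, shape, omega_r, omega_a, phase, base_frequency,
#' mask_radius_deg, filename`).
#'
#' @param catalog catalog from [make_catalog()].
#' @param dir output directory (created if missing).
#' @inheritParams render_grating
#' @return Invisibly, the sidecar catalog data.frame.
#' @export
write_stimulus_set <- function(catalog, dir, n_px = 512, extent_deg = 8.4,
                               cutoff_cpd = NULL, outer_radius_deg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ex <- catalog_exemplars(catalog)
  ex$mask_radius_deg <- NA_real_
  ex$filename <- sprintf("class%02d_phase%03.0f.png", ex$class_id,
                         ex$phase * 100)
  for (i in seq_len(nrow(ex))) {
    g <- render_grating(ex$omega_r[i], ex$omega_a[i], ex$phase[i],
                        n_px = n_px, extent_deg = extent_deg,
                        cutoff_cpd = cutoff_cpd,
                        outer_radius_deg = outer_radius_deg)
    ex$mask_radius_deg[i] <- g$mask_radius_deg
    png::writePNG((g$pixels + 1) / 2, file.path(dir, ex$filename[i]))
  }
  out <- ex[, c("class_id", "shape", "omega_r", "omega_a", "phase",
                "base_frequency", "mask_radius_deg", "filename")]
  utils::write.csv(out, file.path(dir, "catalog.csv"), row.names = FALSE)
  invisible(out)
}
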