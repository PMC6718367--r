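# Dual-source model: focal point source plus a radially symmetric Gaussian
# extra-focal source at the flattening-filter plane, and a monitor-backscatter
# term linear in the blocked jaw area.  The extra-focal contribution is the
# Gaussian mass over the detector's-eye-view (DEV) back-projection of the
# collimator openings onto the source plane.

#' Dual-source model parameters
#'
#' @param k_ff extra-focal amplitude: the scatter-to-primary ratio for an
#'   unobstructed view of the source plane (dimensionless, >= 0).
#' @param sigma_ff radial width (cm) of the Gaussian extra-focal source at
#'   its own plane (> 0).
#' @param k_b monitor-backscatter slope per cm2 of blocked jaw area
#'   (dimensionless, >= 0).
#' @return An object of class \code{dsm_params}.
#' @export
dsm_params <- function(k_ff, sigma_ff, k_b) {
  if (k_ff < 0 || sigma_ff <= 0 || k_b < 0)
    stop("dsm_params requires k_ff >= 0, sigma_ff > 0, k_b >= 0")
  structure(list(k_ff = k_ff, sigma_ff = sigma_ff, k_b = k_b),
            class = "dsm_params")
}

#' Representative dual-source parameters
#'
#' Synthetic defaults chosen to give a realistic 6 MV in-air output ratio
#' range (about 0.97 at 4 x 4 cm2 to 1.02 at 40 x 40 cm2).  They are the
#' truth set of the synthetic campaign generator, not a fit to any
#' measured machine.
#'
#' @return A \code{\link{dsm_params}}.
#' @export
reference_dsm_params <- function() dsm_params(0.05, 1.5, 6e-6)

# back-projection magnification: isocenter-scale coordinate on the plane at
# distance dc, seen from the on-axis detector at SAD, lands at the ff plane
# scaled by (dc/sad) * (sad - ff) / (sad - dc)
dev_magnification <- function(geom, dc) {
  (dc / geom$sad) * (geom$sad - geom$ff_dist) / (geom$sad - dc)
}

#' Detector's-eye-view region on the extra-focal source plane
#'
#' Back-projects every collimator opening (X jaws, Y jaws and, when present,
#' the MLC leaf gaps) from the on-axis detector point to the extra-focal
#' plane and intersects them, together with the circular primary-collimator
#' cap.  The cap circle is clipped by chord subdivision of the y slabs
#' (inscribed approximation at step \code{cap_step}); with the default cap
#' radius it never binds for jaw-defined fields up to 40 x 40 cm2.
#'
#' @param field a \code{\link{field_spec}}; the detector sits on the beam
#'   axis at the isocenter distance.
#' @param geom a \code{\link{machine_geometry}}.
#' @param include_mlc include the MLC leaves as DEV blockers (default TRUE;
#'   irrelevant for retracted banks).
#' @param gap_tol closed-pair tolerance (cm at isocenter).
#' @param cap_step slab subdivision step (cm) for the circular cap clip.
#' @return An \code{aperture_poly} at the extra-focal plane; empty when the
#'   view is fully blocked.
#' @export
dev_region <- function(field, geom, include_mlc = TRUE, gap_tol = 0.05,
                       cap_step = 0.1) {
  jaw <- field$jaw
  mx <- dev_magnification(geom, geom$scd_x)
  my <- dev_magnification(geom,
                          if (is.null(geom$scd_y)) geom$scd_x else geom$scd_y)
  jx <- c(jaw$x1, jaw$x2) * mx
  jy <- c(jaw$y1, jaw$y2) * my
  bank <- if (include_mlc) field$bank else NULL
  if (is.null(bank)) {
    slabs <- data.frame(y_lo = jy[1], y_hi = jy[2], x_lo = jx[1], x_hi = jx[2])
    if (jx[2] - jx[1] <= 0 || jy[2] - jy[1] <= 0) slabs <- slabs[0, ]
  } else {
    mm <- dev_magnification(geom, geom$smd)
    lo <- bank$edges[-(bank$n_pairs + 1L)] * mm
    hi <- bank$edges[-1L] * mm
    x_lo <- pmax(bank$left * mm, jx[1]); x_hi <- pmin(bank$right * mm, jx[2])
    y_lo <- pmax(lo, jy[1]); y_hi <- pmin(hi, jy[2])
    keep <- (bank$right - bank$left > gap_tol) & (y_hi - y_lo > 1e-12) &
      (x_hi - x_lo > 1e-12)
    slabs <- data.frame(y_lo = y_lo[keep], y_hi = y_hi[keep],
                        x_lo = x_lo[keep], x_hi = x_hi[keep])
    slabs <- slabs[order(slabs$y_lo), , drop = FALSE]
  }
  slabs <- clip_slabs_to_cap(slabs, geom$cap_radius, cap_step)
  rownames(slabs) <- NULL
  new_aperture_poly(slabs, geom$ff_dist)
}

clip_slabs_to_cap <- function(slabs, R, cap_step) {
  if (nrow(slabs) == 0) return(slabs)
  # fast path: bounding box inside the circle
  r2 <- max(abs(c(slabs$x_lo, slabs$x_hi)))^2 +
    max(abs(c(slabs$y_lo, slabs$y_hi)))^2
  if (r2 <= R^2) return(slabs)
  out <- list()
  for (i in seq_len(nrow(slabs))) {
    ys <- seq(slabs$y_lo[i], slabs$y_hi[i],
              length.out = max(2L, ceiling((slabs$y_hi[i] - slabs$y_lo[i]) /
                                             cap_step) + 1L))
    for (k in seq_len(length(ys) - 1L)) {
      yf <- max(abs(ys[k]), abs(ys[k + 1L]))
      if (yf >= R) next
      half <- sqrt(R^2 - yf^2)
      x1 <- max(slabs$x_lo[i], -half); x2 <- min(slabs$x_hi[i], half)
      if (x2 - x1 > 1e-12)
        out[[length(out) + 1L]] <- data.frame(y_lo = ys[k], y_hi = ys[k + 1L],
                                              x_lo = x1, x_hi = x2)
    }
  }
  if (length(out) == 0) slabs[0, , drop = FALSE] else do.call(rbind, out)
}

# exact bivariate-Gaussian mass over a slab-form region (products of
# one-dimensional normal CDF differences per rectangle)
gaussian_mass <- function(slabs, sigma) {
  if (nrow(slabs) == 0) return(0)
  sum((stats::pnorm(slabs$x_hi / sigma) - stats::pnorm(slabs$x_lo / sigma)) *
        (stats::pnorm(slabs$y_hi / sigma) - stats::pnorm(slabs$y_lo / sigma)))
}

#' Extra-focal scatter ratio
#'
#' \eqn{F_{efs} = k_{ff} \int\int_{DEV} N(0, \sigma_{ff}^2 I)\,dx\,dy},
#' evaluated exactly per rectangle of the DEV decomposition.
#'
#' @param field a \code{\link{field_spec}}.
#' @param params a \code{\link{dsm_params}}.
#' @param geom a \code{\link{machine_geometry}}.
#' @param include_mlc passed to \code{\link{dev_region}}.
#' @return A value in \code{[0, k_ff]}.
#' @export
f_efs <- function(field, params, geom, include_mlc = TRUE) {
  poly <- dev_region(field, geom, include_mlc = include_mlc)
  params$k_ff * gaussian_mass(poly$slabs, params$sigma_ff)
}

#' Monitor-backscatter ratio
#'
#' \eqn{F_{mbs} = k_b (A_{max} - A_{jaw})} with \eqn{A_{max} = 1600} cm2
#' (the fully open 40 x 40 jaw field) and the jaw area at the isocenter;
#' clipped to [0, 1).
#'
#' @param jaw a \code{\link{jaw_setting}}.
#' @param params a \code{\link{dsm_params}}.
#' @param a_max fully open jaw area (cm2).
#' @return A value in [0, 1).
#' @export
f_mbs <- function(jaw, params, a_max = 1600) {
  min(max(params$k_b * (a_max - jaw_area(jaw)), 0), 1 - 1e-12)
}

#' In-air output ratio from the dual-source model
#'
#' \deqn{S_{c,DSM}(fs) = \frac{(1 + F_{efs}(fs))(1 - F_{mbs}(fs))}
#'   {(1 + F_{efs}(fs_{ref}))(1 - F_{mbs}(fs_{ref}))}}
#' with the reference field a 10 x 10 cm2 jaw setting, MLC retracted.
#'
#' @param field a \code{\link{field_spec}}.
#' @param params a \code{\link{dsm_params}}.
#' @param geom a \code{\link{machine_geometry}}.
#' @param include_mlc include MLC leaves as DEV blockers for the numerator
#'   field.
#' @return Dimensionless Sc; exactly 1 at the reference field.
#' @export
sc_dsm <- function(field, params, geom, include_mlc = TRUE) {
  ref <- reference_field()
  num <- (1 + f_efs(field, params, geom, include_mlc)) *
    (1 - f_mbs(field$jaw, params))
  den <- (1 + f_efs(ref, params, geom, include_mlc = FALSE)) *
    (1 - f_mbs(ref$jaw, params))
  num / den
}

#' Fit dual-source parameters to a measured-Sc table
#'
#' Constrained nonlinear least squares (Levenberg-Marquardt with box
#' bounds) on the chi-square objective
#' \eqn{\sum ((S_{c,calc} - S_{c,meas})/SD)^2} over the jaw-only
#' (MLC-retracted) rows, with an iteration cap of 400 and a function
#' tolerance of 1e-6.  DEV geometry is independent of the parameters and is
#' precomputed once per field.
#'
#' @param measurements a measurement table (see
#'   \code{\link{read_measurements}}); only rows with
#'   \code{mlc_spec == "retracted"} enter the fit, and at least three
#'   distinct jaw settings including the 10 x 10 reference are required.
#' @param geom a \code{\link{machine_geometry}}.
#' @param start optional \code{\link{dsm_params}} starting point.
#' @param maxiter,ftol optimizer controls.
#' @return An object of class \code{dsm_fit}: \code{params}
#'   (\code{\link{dsm_params}}), \code{objective}, \code{iterations},
#'   \code{converged}, \code{message}, \code{n}.
#' @export
fit_dsm <- function(measurements, geom, start = NULL, maxiter = 400,
                    ftol = 1e-6) {
  m <- measurements[measurements$mlc_spec == "retracted", , drop = FALSE]
  if (nrow(m) < 3)
    stop("DSM fitting needs at least 3 jaw-only fields (got ", nrow(m), ")")
  key <- paste(m$jaw_x1, m$jaw_x2, m$jaw_y1, m$jaw_y2)
  if (length(unique(key)) < 3)
    stop("DSM fitting needs at least 3 distinct jaw settings")
  has_ref <- any(abs(m$jaw_x1 + 5) < 1e-6 & abs(m$jaw_x2 - 5) < 1e-6 &
                   abs(m$jaw_y1 + 5) < 1e-6 & abs(m$jaw_y2 - 5) < 1e-6)
  if (!has_ref)
    stop("DSM fitting requires the 10 x 10 cm2 reference field")
  fields <- lapply(seq_len(nrow(m)), function(i)
    field_spec(jaw_setting(m$jaw_x1[i], m$jaw_x2[i], m$jaw_y1[i], m$jaw_y2[i])))
  devs <- lapply(fields, function(f) dev_region(f, geom)$slabs)
  ref_dev <- dev_region(reference_field(), geom)$slabs
  areas <- vapply(fields, function(f) jaw_area(f$jaw), numeric(1))
  a_ref <- 100
  sc_fast <- function(k_ff, sigma_ff, k_b) {
    masses <- vapply(devs, gaussian_mass, numeric(1), sigma = sigma_ff)
    mref <- gaussian_mass(ref_dev, sigma_ff)
    num <- (1 + k_ff * masses) * (1 - pmin(pmax(k_b * (1600 - areas), 0), 1 - 1e-12))
    den <- (1 + k_ff * mref) * (1 - min(max(k_b * (1600 - a_ref), 0), 1 - 1e-12))
    num / den
  }
  if (is.null(start)) start <- dsm_params(0.1, 2.0, 1e-5)
  # zero-SD rows (noise-free tables) fall back to a nominal 0.1% weight
  sd_w <- ifelse(m$sd > 0, m$sd, 1e-3 * pmax(abs(m$sc), 1))
  # k_b carried in units of 1e-5 for optimizer conditioning
  p0 <- c(start$k_ff, start$sigma_ff, start$k_b * 1e5)
  resid <- function(p) (sc_fast(p[1], p[2], p[3] * 1e-5) - m$sc) / sd_w
  fit <- minpack.lm::nls.lm(par = p0, fn = resid,
                            lower = c(0, 0.2, 0), upper = c(1, 10, 100),
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ftol = ftol,
                              maxfev = (maxiter + 2) * 4))
  p <- fit$par
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("DSM fit did not converge: ", fit$message)
  structure(list(params = dsm_params(p[1], p[2], p[3] * 1e-5),
                 objective = fit$deviance, iterations = fit$niter,
                 converged = converged, message = fit$message,
                 n = nrow(m)),
            class = "dsm_fit")
}

#' @export
print.dsm_fit <- function(x, ...) {
  cat(sprintf(
    "Dual-source fit (n = %d): k_ff = %.5f, sigma_ff = %.4f cm, k_b = %.3e\n",
    x$n, x$params$k_ff, x$params$sigma_ff, x$params$k_b))
  cat(sprintf("  chi-square %.4g after %d iterations (%s)\n",
              x$objective, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}
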