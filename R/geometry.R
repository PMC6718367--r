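#' Machine geometry for a linac treatment head
#'
#' Bundles the axial distances (all in cm from the X-ray target) that the
#' head-scatter model needs: the source-to-axis distance, the mid-MLC plane,
#' the upper edges of the X and Y jaws, and the plane of the extra-focal
#' (flattening-filter) source.
#'
#' Exactly one of \code{scd_x} and \code{alpha} must be given.  When
#' \code{alpha} is supplied, \code{scd_x} is derived by inverting the
#' scatter-interface coefficient
#' \deqn{\alpha = \frac{SCD_x (SAD - SMD)}{SMD (SAD - SCD_x)}}
#' in closed form, \eqn{SCD_x = \alpha\,SMD\,SAD / (SAD - SMD + \alpha\,SMD)}.
#'
#' @param sad source-to-axis distance (cm).
#' @param smd source to mid-MLC plane distance (cm).
#' @param scd_x source to upper edge of the X jaw (cm), or \code{NULL} to
#'   derive it from \code{alpha}.
#' @param alpha scatter-interface coefficient, or \code{NULL} to compute it
#'   from \code{scd_x}.
#' @param scd_y source to upper edge of the Y jaw (cm); optional.  When
#'   \code{NULL} (default) the X-jaw plane is used for both axes and a single
#'   \eqn{\alpha} applies to both interface dimensions.
#' @param ff_dist distance from the source to the extra-focal source plane at
#'   the bottom of the flattening filter (cm).
#' @param cap_radius radius (cm) of the primary-collimator field-of-view cap
#'   at the extra-focal plane.  The default is large enough that jaw-defined
#'   detector's-eye views up to 40 x 40 cm2 are never clipped.
#' @return An object of class \code{machine_geometry}.
#' @examples
#' g <- machine_geometry()           # default: alpha = 0.577, SMD = 51 cm
#' g$scd_x                           # derived X-jaw distance
#' compute_alpha(g)
#' @export
machine_geometry <- function(sad = 100, smd = 51.0, scd_x = NULL,
                             alpha = 0.577, scd_y = NULL,
                             ff_dist = 12.5, cap_radius = 15) {
  if (!is.null(scd_x) && !is.null(alpha) && !missing(alpha) && !missing(scd_x))
    stop("give exactly one of 'scd_x' and 'alpha'")
  if (is.null(scd_x)) {
    if (is.null(alpha)) stop("give exactly one of 'scd_x' and 'alpha'")
    if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
    scd_x <- alpha * smd * sad / (sad - smd + alpha * smd)
  }
  if (!(scd_x > 0 && scd_x <= smd && smd < sad))
    stop("geometry requires 0 < scd_x <= smd < sad")
  if (!(ff_dist > 0 && ff_dist < scd_x))
    stop("geometry requires 0 < ff_dist < scd_x")
  if (!is.null(scd_y) && !(scd_y > 0 && scd_y < smd))
    stop("geometry requires 0 < scd_y < smd")
  g <- structure(list(sad = sad, smd = smd, scd_x = scd_x, scd_y = scd_y,
                      ff_dist = ff_dist, cap_radius = cap_radius),
                 class = "machine_geometry")
  g
}

#' @export
print.machine_geometry <- function(x, ...) {
  cat("Machine geometry (cm from source):\n")
  cat(sprintf("  SAD %.2f | SMD %.2f | SCD_x %.4f | ff plane %.2f\n",
              x$sad, x$smd, x$scd_x, x$ff_dist))
  cat(sprintf("  alpha = %.4f", compute_alpha(x)))
  if (!is.null(x$scd_y))
    cat(sprintf("  (y-axis alpha = %.4f)", compute_alpha(x, axis = "y")))
  cat("\n")
  invisible(x)
}

#' Scatter-interface coefficient
#'
#' \eqn{\alpha = SCD_x (SAD - SMD) / (SMD (SAD - SCD_x))}: the ratio of the
#' scatter-interface size to the jaw-defined field size at the mid-MLC plane.
#' It is the demagnification a ray from the field edge at the upper X-jaw
#' edge experiences when traced from the detector plane back to the mid-MLC
#' plane.
#'
#' @param geom a \code{\link{machine_geometry}}.
#' @param axis \code{"x"} (default) or \code{"y"}; \code{"y"} uses
#'   \code{scd_y} when present.
#' @return The dimensionless coefficient in \eqn{(0, 1]} for
#'   \eqn{SCD \le SMD}.
#' @export
compute_alpha <- function(geom, axis = c("x", "y")) {
  axis <- match.arg(axis)
  scd <- if (axis == "y" && !is.null(geom$scd_y)) geom$scd_y else geom$scd_x
  if (scd >= geom$sad) stop("jaw plane must be above the detector plane")
  scd * (geom$sad - geom$smd) / (geom$smd * (geom$sad - scd))
}

#' Project a length or rectangle between planes
#'
#' Similar-triangle magnification about the beam axis: a length \code{x}
#' defined at distance \code{d1} from the source maps to \code{x * d2 / d1}
#' at distance \code{d2}.
#'
#' @param x a numeric length (cm) or a \code{\link{rect}}.
#' @param d1,d2 source distances (cm) of the origin and target planes; for a
#'   \code{rect}, \code{d1} defaults to its own plane.
#' @return The projected length, or a \code{rect} at plane \code{d2}.
#' @export
project <- function(x, d1, d2) {
  if (inherits(x, "rect")) {
    if (missing(d2)) { d2 <- d1; d1 <- x$plane_dist }
    stopifnot(d1 > 0, d2 > 0)
    f <- d2 / d1
    return(rect(x$x_lo * f, x$x_hi * f, x$y_lo * f, x$y_hi * f, d2))
  }
  if (!(d1 > 0 && d2 > 0)) stop("plane distances must be positive")
  x * d2 / d1
}

#' Axis-aligned rectangle in a named plane
#'
#' @param x_lo,x_hi,y_lo,y_hi corner coordinates (cm), beam-axis centered.
#' @param plane_dist distance of the plane from the source (cm).
#' @return An object of class \code{rect} with derived \code{width},
#'   \code{height}, \code{area} and \code{perimeter} accessors via
#'   \code{\link{rect_area}} and \code{\link{rect_perimeter}}.
#' @export
rect <- function(x_lo, x_hi, y_lo, y_hi, plane_dist) {
  if (x_lo > x_hi || y_lo > y_hi) stop("degenerate rect: lo > hi")
  structure(list(x_lo = x_lo, x_hi = x_hi, y_lo = y_lo, y_hi = y_hi,
                 plane_dist = plane_dist), class = "rect")
}

#' @rdname rect
#' @param r a \code{rect}.
#' @export
rect_area <- function(r) (r$x_hi - r$x_lo) * (r$y_hi - r$y_lo)

#' @rdname rect
#' @export
rect_perimeter <- function(r) 2 * ((r$x_hi - r$x_lo) + (r$y_hi - r$y_lo))

#' Scatter interface for a jaw setting
#'
#' Projects the jaw-defined field to the mid-MLC plane and shrinks both
#' dimensions about the beam axis by the coefficient \eqn{\alpha}
#' (\code{\link{compute_alpha}}).  The resulting rectangle is the border
#' between the "in" and "out" regimes of the MLC scatter source: leaf
#' structure inside it perturbs the detector's-eye view, structure outside
#' it contributes head scatter only.
#'
#' @param geom a \code{\link{machine_geometry}}.
#' @param jaw a \code{\link{jaw_setting}} (isocenter-plane coordinates).
#' @return A \code{\link{rect}} at the mid-MLC plane.
#' @examples
#' scatter_interface(machine_geometry(), jaw_square(20))  # 5.885 cm sides
#' @export
scatter_interface <- function(geom, jaw) {
  f <- geom$smd / geom$sad
  ax <- compute_alpha(geom, "x")
  ay <- compute_alpha(geom, "y")
  rect(jaw$x1 * f * ax, jaw$x2 * f * ax,
       jaw$y1 * f * ay, jaw$y2 * f * ay, geom$smd)
}

#' Read or write a machine configuration file
#'
#' Plain YAML with keys \code{sad_cm}, \code{smd_cm}, exactly one of
#' \code{scd_x_cm} / \code{alpha}, and optional \code{scd_y_cm},
#' \code{ff_dist_cm}, \code{cap_radius_cm}.
#'
#' @param path file path.
#' @return \code{read_machine_config}: a \code{\link{machine_geometry}}.
#' @export
read_machine_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("sad_cm", "smd_cm")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("machine config missing key(s): ",
                         paste(miss, collapse = ", "))
  has_scd <- !is.null(cfg$scd_x_cm); has_alpha <- !is.null(cfg$alpha)
  if (has_scd == has_alpha)
    stop("machine config needs exactly one of 'scd_x_cm' and 'alpha'")
  machine_geometry(sad = cfg$sad_cm, smd = cfg$smd_cm,
                   scd_x = cfg$scd_x_cm,
                   alpha = if (has_alpha) cfg$alpha else NULL,
                   scd_y = cfg$scd_y_cm,
                   ff_dist = if (is.null(cfg$ff_dist_cm)) 12.5 else cfg$ff_dist_cm,
                   cap_radius = if (is.null(cfg$cap_radius_cm)) 15 else cfg$cap_radius_cm)
}

#' @rdname read_machine_config
#' @param geom a \code{\link{machine_geometry}} to write.
#' @export
write_machine_config <- function(geom, path) {
  yaml::write_yaml(list(sad_cm = geom$sad, smd_cm = geom$smd,
                        scd_x_cm = geom$scd_x, scd_y_cm = geom$scd_y,
                        ff_dist_cm = geom$ff_dist,
                        cap_radius_cm = geom$cap_radius), path, precision = 12)
  invisible(path)
}
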