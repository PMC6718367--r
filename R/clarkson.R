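# Clarkson sector integration: scatter-dependent dosimetric factors for an
# irregular aperture are the average of radial-table values over angular
# sectors about the calculation point.

#' Radial dosimetric lookup tables
#'
#' Phantom scatter factor Sp as a function of the equivalent circular field
#' radius, and tissue maximum ratio TMR on a (depth, radius) grid.  Linear
#' interpolation inside the tabulated range; extrapolation is an error.
#'
#' @param sp data frame with columns \code{radius} (cm, strictly
#'   increasing) and \code{sp}.
#' @param tmr data frame in long format with columns \code{depth},
#'   \code{radius}, \code{tmr}; every depth must tabulate the same radii.
#' @return An object of class \code{radial_table}.
#' @export
radial_table <- function(sp, tmr = NULL) {
  stopifnot(all(c("radius", "sp") %in% names(sp)))
  if (any(diff(sp$radius) <= 0)) stop("Sp radii must be strictly increasing")
  if (!is.null(tmr)) {
    stopifnot(all(c("depth", "radius", "tmr") %in% names(tmr)))
    rads <- sort(unique(tmr$radius))
    for (d in unique(tmr$depth))
      if (!isTRUE(all.equal(sort(tmr$radius[tmr$depth == d]), rads)))
        stop("TMR grid must tabulate the same radii at every depth")
  }
  structure(list(sp = sp[order(sp$radius), ], tmr = tmr),
            class = "radial_table")
}

#' Synthetic radial tables for testing
#'
#' Smooth, monotone Sp and TMR curves with physically plausible shapes
#' (saturating scatter build-up in radius, exponential depth attenuation
#' beyond the build-up depth).  Synthetic: they match no particular
#' machine's beam data.
#'
#' @param radii tabulated radii (cm).
#' @param depths tabulated depths (cm).
#' @return A \code{\link{radial_table}}.
#' @export
synthetic_radial_tables <- function(radii = seq(0.5, 30, by = 0.5),
                                    depths = c(1.5, 5, 10, 15, 20)) {
  sp <- data.frame(radius = radii,
                   sp = (1 - 0.25 * exp(-radii / 6)) /
                     (1 - 0.25 * exp(-5.64 / 6)))
  tmr <- do.call(rbind, lapply(depths, function(d) {
    scat <- 1 + 0.11 * (1 - exp(-radii / 7)) * pmax(d - 1.5, 0) / 10
    data.frame(depth = d, radius = radii,
               tmr = exp(-0.0585 * pmax(d - 1.5, 0)) * scat /
                 (1 + 0.11 * (1 - exp(-5.64 / 7)) * pmax(d - 1.5, 0) / 10))
  }))
  radial_table(sp, tmr)
}

interp_sp <- function(table, r) {
  rng <- range(table$sp$radius)
  if (any(r < rng[1] - 1e-9 | r > rng[2] + 1e-9))
    stop(sprintf("radius outside the Sp table range [%g, %g]",
                 rng[1], rng[2]))
  stats::approx(table$sp$radius, table$sp$sp, xout = r, rule = 1)$y
}

interp_tmr <- function(table, r, depth) {
  if (is.null(table$tmr)) stop("no TMR grid in this radial_table")
  depths <- sort(unique(table$tmr$depth))
  if (depth < depths[1] - 1e-9 || depth > depths[length(depths)] + 1e-9)
    stop(sprintf("depth outside the TMR table range [%g, %g]",
                 depths[1], depths[length(depths)]))
  rads <- sort(unique(table$tmr$radius))
  if (any(r < rads[1] - 1e-9 | r > rads[length(rads)] + 1e-9))
    stop("radius outside the TMR table range")
  at_depth <- function(d) {
    sub <- table$tmr[abs(table$tmr$depth - d) < 1e-9, ]
    stats::approx(sub$radius, sub$tmr, xout = r, rule = 1)$y
  }
  i <- findInterval(depth, depths, all.inside = TRUE)
  d1 <- depths[i]; d2 <- depths[i + 1L]
  if (abs(d2 - d1) < 1e-12) return(at_depth(d1))
  w <- (depth - d1) / (d2 - d1)
  (1 - w) * at_depth(d1) + w * at_depth(d2)
}

#' Sector radii of an aperture about a point
#'
#' Casts one ray per angular sector (through the sector's angular center)
#' from the calculation point and records the distance to the first
#' boundary crossing of the aperture.  Non-convex apertures use the first
#' crossing only, consistent with primary-aperture Clarkson integration.
#'
#' @param poly an \code{aperture_poly} at the isocenter plane.
#' @param point numeric (x, y) calculation point (cm); must lie strictly
#'   inside the aperture.
#' @param sector_deg sector width in degrees; must divide 360.
#' @return Numeric vector of \code{360 / sector_deg} radii (cm).
#' @export
sector_radii <- function(poly, point = c(0, 0), sector_deg = 1) {
  n_sect <- 360 / sector_deg
  if (abs(n_sect - round(n_sect)) > 1e-9)
    stop("sector width must divide 360 degrees")
  n_sect <- as.integer(round(n_sect))
  s <- poly$slabs
  # strict interior test robust to slab seams: the point must be covered
  # with strict x clearance just below and just above its own y
  eps <- 1e-9
  covered <- function(y) any(s$y_lo <= y & y <= s$y_hi &
                               s$x_lo < point[1] - eps &
                               point[1] + eps < s$x_hi)
  if (!(covered(point[2] - eps) && covered(point[2] + eps)))
    stop("calculation point must lie strictly inside the aperture")
  seg <- poly_segments(poly)
  ang <- (seq_len(n_sect) - 0.5) * sector_deg * pi / 180
  vapply(ang, function(th) {
    dx <- cos(th); dy <- sin(th)
    t_min <- Inf
    for (i in seq_len(nrow(seg))) {
      if (seg$orient[i] == "v") {
        if (abs(dx) < 1e-14) next
        t <- (seg$x1[i] - point[1]) / dx
        if (t <= 1e-12) next
        y <- point[2] + t * dy
        if (y >= min(seg$y1[i], seg$y2[i]) - 1e-12 &&
            y <= max(seg$y1[i], seg$y2[i]) + 1e-12)
          t_min <- min(t_min, t)
      } else {
        if (abs(dy) < 1e-14) next
        t <- (seg$y1[i] - point[2]) / dy
        if (t <= 1e-12) next
        x <- point[1] + t * dx
        if (x >= min(seg$x1[i], seg$x2[i]) - 1e-12 &&
            x <= max(seg$x1[i], seg$x2[i]) + 1e-12)
          t_min <- min(t_min, t)
      }
    }
    if (!is.finite(t_min))
      stop("ray found no aperture boundary; aperture may be degenerate")
    t_min
  }, numeric(1))
}

#' Clarkson sector average of a radial table
#'
#' The mean of the table value at each sector's radius (360 terms for the
#' default 1-degree sectors).
#'
#' @param radii sector radii (cm), e.g. from \code{\link{sector_radii}}.
#' @param table a \code{\link{radial_table}}.
#' @param depth depth (cm) for a TMR lookup; omit for Sp.
#' @return The sector-averaged Sp or TMR value.
#' @export
clarkson_value <- function(radii, table, depth = NULL) {
  if (is.null(depth)) mean(interp_sp(table, radii))
  else mean(interp_tmr(table, radii, depth))
}

#' Factor-based point dose
#'
#' \eqn{D = MU \cdot k_{cal} \cdot S_c \cdot S_p \cdot TMR}.
#'
#' @param mu monitor units (>= 0).
#' @param k_cal calibration dose per MU at reference conditions (cGy/MU).
#' @param sc in-air output ratio.
#' @param sp phantom scatter factor.
#' @param tmr tissue maximum ratio.
#' @return Dose in cGy.
#' @export
dose_at_point <- function(mu, k_cal, sc, sp, tmr) {
  if (mu < 0 || k_cal <= 0) stop("require mu >= 0 and k_cal > 0")
  if (any(c(sc, sp, tmr) <= 0)) stop("dosimetric factors must be positive")
  mu * k_cal * sc * sp * tmr
}
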