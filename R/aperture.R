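# Rectilinear aperture geometry.
#
# Apertures are unions of axis-aligned rectangles.  Because every leaf pair
# opens a single x interval on its own y strip, any jaw+MLC aperture
# decomposes exactly into disjoint y slabs each carrying one x interval
# ("slab form"); areas, perimeters, boundary segments and clipping against
# the scatter interface are all exact interval arithmetic on that form.

#' Jaw settings at the isocenter plane
#'
#' @param x1,x2,y1,y2 signed jaw positions at the isocenter (cm),
#'   \code{x1 <= x2}, \code{y1 <= y2}.  x is the cross-plane axis.
#' @return An object of class \code{jaw_setting}.
#' @export
jaw_setting <- function(x1, x2, y1, y2) {
  if (x1 > x2 || y1 > y2) stop("jaw setting requires x1 <= x2 and y1 <= y2")
  structure(list(x1 = x1, x2 = x2, y1 = y1, y2 = y2), class = "jaw_setting")
}

#' @rdname jaw_setting
#' @param side side of a beam-axis-centered square field (cm).
#' @export
jaw_square <- function(side) jaw_setting(-side / 2, side / 2, -side / 2, side / 2)

#' @rdname jaw_setting
#' @param jaw a \code{jaw_setting}.
#' @export
jaw_area <- function(jaw) (jaw$x2 - jaw$x1) * (jaw$y2 - jaw$y1)

#' @rdname jaw_setting
#' @export
jaw_perimeter <- function(jaw) 2 * ((jaw$x2 - jaw$x1) + (jaw$y2 - jaw$y1))

#' Area-to-perimeter ratio of a jaw-defined field
#'
#' The covariate of the quadratic parameter model for the MLC scatter
#' source; computed at the isocenter plane.  A square field of side s has
#' AP ratio s/4 (2.5 for 10 x 10, 7.5 for 30 x 30).
#'
#' @param jaw a \code{\link{jaw_setting}}.
#' @return Area / perimeter (cm).
#' @export
ap_ratio <- function(jaw) jaw_area(jaw) / jaw_perimeter(jaw)

#' Leaf-boundary coordinates of the Millennium 120 MLC
#'
#' 60 leaf pairs: 10 outer pairs of 1.0 cm width on each side and 40
#' central pairs of 0.5 cm, covering y in [-20, 20] cm at the isocenter.
#'
#' @return A strictly increasing vector of 61 y coordinates (cm).
#' @export
millennium120_edges <- function() {
  c(seq(-20, -10, by = 1), seq(-9.5, 9.5, by = 0.5), seq(10, 20, by = 1))
}

#' An MLC bank of opposed leaf pairs
#'
#' @param left,right leaf-tip x positions at the isocenter (cm) for each of
#'   the \code{length(edges) - 1} pairs; \code{left <= right}.  The open gap
#'   of pair i spans x in (left[i], right[i]) on the y strip
#'   (edges[i], edges[i+1]).  A pair with \code{right - left <= gap_tol}
#'   (0.05 cm at isocenter by default) is treated as closed.
#' @param edges strictly increasing leaf-boundary y coordinates (cm at
#'   isocenter); default \code{\link{millennium120_edges}}.
#' @return An object of class \code{mlc_bank} with \code{n_pairs} pairs.
#' @export
mlc_bank <- function(left, right, edges = millennium120_edges()) {
  n <- length(edges) - 1L
  if (any(diff(edges) <= 0)) stop("leaf edges must be strictly increasing")
  if (length(left) != n || length(right) != n)
    stop("need one left/right position per leaf pair (", n, ")")
  if (any(left > right)) stop("leaf positions require left <= right")
  structure(list(n_pairs = n, edges = edges, left = left, right = right),
            class = "mlc_bank")
}

#' @rdname mlc_bank
#' @param extent retraction position (cm); all pairs open from -extent to
#'   extent.
#' @export
mlc_bank_retracted <- function(extent = 20, edges = millennium120_edges()) {
  n <- length(edges) - 1L
  mlc_bank(rep(-extent, n), rep(extent, n), edges)
}

#' @rdname mlc_bank
#' @param side side (cm) of a beam-axis-centered MLC square; pairs whose
#'   strip overlaps the square are opened to (-side/2, side/2), the rest are
#'   closed (abutted at x = 0).
#' @export
mlc_bank_square <- function(side, edges = millennium120_edges()) {
  n <- length(edges) - 1L
  lo <- edges[-(n + 1L)]; hi <- edges[-1L]
  open <- pmin(hi, side / 2) - pmax(lo, -side / 2) > 1e-9
  mlc_bank(ifelse(open, -side / 2, 0), ifelse(open, side / 2, 0), edges)
}

is_retracted <- function(bank, jaw, gap_tol = 0.05) {
  lo <- bank$edges[-(bank$n_pairs + 1L)]; hi <- bank$edges[-1L]
  over <- pmin(hi, jaw$y2) - pmax(lo, jaw$y1) > 1e-9
  # a tip exactly on the jaw edge counts as intruding (rounded end on the
  # field border is irradiated), so clearance must be strict
  clear <- (bank$right - bank$left > gap_tol) &
    (bank$left < jaw$x1 - 1e-9) & (bank$right > jaw$x2 + 1e-9)
  all(clear[over])
}

# ---- slab-form aperture polygons -------------------------------------------

new_aperture_poly <- function(slabs, plane_dist) {
  structure(list(slabs = slabs, plane_dist = plane_dist),
            class = "aperture_poly")
}

#' Aperture polygon from an MLC bank clipped by the jaws
#'
#' Union of the open leaf gaps intersected with the jaw rectangle, projected
#' from the isocenter plane to \code{plane_dist} by similar triangles.
#' Closed pairs (gap below \code{gap_tol}) contribute nothing, and their
#' abutment line carries no perimeter.
#'
#' @param bank an \code{\link{mlc_bank}}, or \code{NULL} for a jaw-only
#'   (retracted-MLC) field.
#' @param jaw a \code{\link{jaw_setting}}.
#' @param plane_dist target plane distance from the source (cm).
#' @param gap_tol closed-pair gap tolerance (cm at isocenter).
#' @param iso_dist distance of the isocenter plane (cm); apertures are
#'   specified there.
#' @return An \code{aperture_poly}: disjoint y slabs, each with one open x
#'   interval, at \code{plane_dist}.  An empty aperture has zero slabs and
#'   zero area, not an error.
#' @export
mlc_polygon <- function(bank, jaw, plane_dist = 100, gap_tol = 0.05,
                        iso_dist = 100) {
  f <- plane_dist / iso_dist
  if (is.null(bank)) {
    slabs <- data.frame(y_lo = jaw$y1, y_hi = jaw$y2,
                        x_lo = jaw$x1, x_hi = jaw$x2)
    if (jaw_area(jaw) <= 0) slabs <- slabs[0, , drop = FALSE]
    slabs[] <- lapply(slabs, function(v) v * f)
    return(new_aperture_poly(slabs, plane_dist))
  }
  lo <- bank$edges[-(bank$n_pairs + 1L)]; hi <- bank$edges[-1L]
  y_lo <- pmax(lo, jaw$y1); y_hi <- pmin(hi, jaw$y2)
  x_lo <- pmax(bank$left, jaw$x1); x_hi <- pmin(bank$right, jaw$x2)
  keep <- (bank$right - bank$left > gap_tol) & (y_hi - y_lo > 1e-12) &
    (x_hi - x_lo > 1e-12)
  slabs <- data.frame(y_lo = y_lo[keep], y_hi = y_hi[keep],
                      x_lo = x_lo[keep], x_hi = x_hi[keep])
  slabs <- slabs[order(slabs$y_lo), , drop = FALSE]
  rownames(slabs) <- NULL
  slabs[] <- lapply(slabs, function(v) v * f)
  new_aperture_poly(slabs, plane_dist)
}

#' @rdname poly_metrics
#' @export
poly_area <- function(poly) {
  s <- poly$slabs
  if (nrow(s) == 0) return(0)
  sum((s$x_hi - s$x_lo) * (s$y_hi - s$y_lo))
}

#' Boundary segments of a slab-form aperture polygon
#'
#' Vertical edges are the open flanks of every slab; horizontal edges at a
#' shared slab boundary are the set difference of the two x intervals, so
#' abutting identical slabs contribute no interior wall.
#'
#' @param poly an \code{aperture_poly}.
#' @return A data frame of segments (\code{x1, y1, x2, y2, orient}) with
#'   \code{orient} "h" or "v"; coordinates at the polygon's plane.
#' @export
poly_segments <- function(poly) {
  s <- poly$slabs
  out <- list()
  n <- nrow(s)
  if (n == 0)
    return(data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), orient = character()))
  add <- function(x1, y1, x2, y2, orient)
    out[[length(out) + 1L]] <<- data.frame(x1 = x1, y1 = y1, x2 = x2,
                                           y2 = y2, orient = orient)
  eps <- 1e-9
  for (i in seq_len(n)) {
    add(s$x_lo[i], s$y_lo[i], s$x_lo[i], s$y_hi[i], "v")
    add(s$x_hi[i], s$y_lo[i], s$x_hi[i], s$y_hi[i], "v")
    below <- if (i > 1 && abs(s$y_hi[i - 1] - s$y_lo[i]) < eps) i - 1L else 0L
    above <- if (i < n && abs(s$y_lo[i + 1] - s$y_hi[i]) < eps) i + 1L else 0L
    for (p in interval_diff(s$x_lo[i], s$x_hi[i],
                            if (below) s$x_lo[below] else NA,
                            if (below) s$x_hi[below] else NA))
      add(p[1], s$y_lo[i], p[2], s$y_lo[i], "h")
    for (p in interval_diff(s$x_lo[i], s$x_hi[i],
                            if (above) s$x_lo[above] else NA,
                            if (above) s$x_hi[above] else NA))
      add(p[1], s$y_hi[i], p[2], s$y_hi[i], "h")
  }
  do.call(rbind, out)
}

# pieces of [a1, a2] not covered by [b1, b2]; NA b means no neighbour
interval_diff <- function(a1, a2, b1, b2) {
  if (is.na(b1)) return(list(c(a1, a2)))
  pieces <- list()
  if (b1 > a1) pieces[[length(pieces) + 1L]] <- c(a1, min(a2, b1))
  if (b2 < a2) pieces[[length(pieces) + 1L]] <- c(max(a1, b2), a2)
  Filter(function(p) p[2] - p[1] > 1e-12, pieces)
}

#' Area and perimeter of an aperture polygon
#'
#' @param poly an \code{aperture_poly}.
#' @return \code{poly_area}: total open area (cm2); \code{poly_perimeter}:
#'   total boundary length (cm), both at the polygon's plane.
#' @name poly_metrics
#' @export
poly_perimeter <- function(poly) {
  seg <- poly_segments(poly)
  if (nrow(seg) == 0) return(0)
  sum(abs(seg$x2 - seg$x1) + abs(seg$y2 - seg$y1))
}

#' Exposed MLC area
#'
#' The radiation-exposed leaf face area: jaw-defined field area minus the
#' MLC-defined field area, both evaluated at \code{plane_dist}.
#'
#' @param jaw a \code{\link{jaw_setting}} (isocenter coordinates).
#' @param mlc_field an \code{aperture_poly} already clipped inside the jaw
#'   rectangle.
#' @param plane_dist evaluation plane (cm); defaults to the polygon's own
#'   plane.
#' @param iso_dist isocenter plane distance (cm).
#' @return Area in cm2 at \code{plane_dist}.
#' @export
exposed_mlc_area <- function(jaw, mlc_field, plane_dist = NULL,
                             iso_dist = 100) {
  if (is.null(plane_dist)) plane_dist <- mlc_field$plane_dist
  f <- plane_dist / iso_dist
  a_jaw <- jaw_area(jaw) * f^2
  a_mlc <- poly_area(mlc_field) * (plane_dist / mlc_field$plane_dist)^2
  out <- a_jaw - a_mlc
  if (out < -1e-6) stop("MLC field exceeds the jaw rectangle; clip first")
  max(out, 0)
}

#' Split aperture metrics by the scatter interface
#'
#' Clips the aperture-boundary segments and the exposed MLC area against the
#' scatter-interface rectangle.  Boundary pieces lying exactly on the
#' interface edge count as inside (ties broken inward).
#'
#' @param poly the MLC-defined \code{aperture_poly} at the mid-MLC plane.
#' @param jaw the \code{\link{jaw_setting}} (isocenter coordinates).
#' @param interface the scatter-interface \code{\link{rect}} at the same
#'   plane (see \code{\link{scatter_interface}}).
#' @param ra_in_iso side-squared reference area for the in region, cm2 at
#'   the isocenter (default 3 x 3); projected to the evaluation plane.
#' @param iso_dist isocenter plane distance (cm).
#' @return An object of class \code{region_metrics} with fields
#'   \code{fp_in}, \code{fp_out} (perimeter split, cm), \code{ma_in},
#'   \code{ma_out} (exposed-area split, cm2), \code{rp} (interface
#'   perimeter), \code{ra_in}, \code{ra_out} (reference areas), all at the
#'   interface plane.
#' @export
split_by_interface <- function(poly, jaw, interface, ra_in_iso = 9,
                               iso_dist = 100) {
  if (abs(poly$plane_dist - interface$plane_dist) > 1e-9)
    stop("polygon and interface must live in the same plane")
  d <- interface$plane_dist
  f <- d / iso_dist
  seg <- poly_segments(poly)
  fp_in <- 0; fp_tot <- 0
  if (nrow(seg) > 0) {
    for (i in seq_len(nrow(seg))) {
      if (seg$orient[i] == "h") {
        len <- abs(seg$x2[i] - seg$x1[i]); fp_tot <- fp_tot + len
        if (seg$y1[i] >= interface$y_lo - 1e-12 &&
            seg$y1[i] <= interface$y_hi + 1e-12)
          fp_in <- fp_in + max(0, min(max(seg$x1[i], seg$x2[i]), interface$x_hi) -
                                  max(min(seg$x1[i], seg$x2[i]), interface$x_lo))
      } else {
        len <- abs(seg$y2[i] - seg$y1[i]); fp_tot <- fp_tot + len
        if (seg$x1[i] >= interface$x_lo - 1e-12 &&
            seg$x1[i] <= interface$x_hi + 1e-12)
          fp_in <- fp_in + max(0, min(max(seg$y1[i], seg$y2[i]), interface$y_hi) -
                                  max(min(seg$y1[i], seg$y2[i]), interface$y_lo))
      }
    }
  }
  exp_strips <- exposed_strips(poly, jaw, f)
  ma_tot <- 0; ma_in <- 0
  for (st in exp_strips) {
    h <- st$y_hi - st$y_lo
    oy <- max(0, min(st$y_hi, interface$y_hi) - max(st$y_lo, interface$y_lo))
    for (p in st$pieces) {
      ma_tot <- ma_tot + h * (p[2] - p[1])
      ma_in <- ma_in + oy * max(0, min(p[2], interface$x_hi) -
                                   max(p[1], interface$x_lo))
    }
  }
  structure(list(fp_in = fp_in, fp_out = fp_tot - fp_in,
                 ma_in = ma_in, ma_out = ma_tot - ma_in,
                 rp = rect_perimeter(interface),
                 ra_in = ra_in_iso * f^2,
                 ra_out = rect_area(interface)),
            class = "region_metrics")
}

# y strips of (jaw rect minus aperture) at the polygon's plane; jaw given at
# isocenter, f = plane/iso scale.  Each strip carries <= 2 exposed x pieces.
exposed_strips <- function(poly, jaw, f) {
  jx1 <- jaw$x1 * f; jx2 <- jaw$x2 * f
  jy1 <- jaw$y1 * f; jy2 <- jaw$y2 * f
  s <- poly$slabs
  cuts <- sort(unique(c(jy1, jy2, pmax(pmin(c(s$y_lo, s$y_hi), jy2), jy1))))
  strips <- list()
  for (k in seq_len(length(cuts) - 1L)) {
    lo <- cuts[k]; hi <- cuts[k + 1L]
    if (hi - lo <= 1e-12) next
    mid <- (lo + hi) / 2
    idx <- which(s$y_lo <= mid & s$y_hi >= mid)
    pieces <- if (length(idx) == 0) list(c(jx1, jx2)) else
      interval_diff(jx1, jx2, s$x_lo[idx[1]], s$x_hi[idx[1]])
    strips[[length(strips) + 1L]] <- list(y_lo = lo, y_hi = hi,
                                          pieces = pieces)
  }
  strips
}

#' @export
print.region_metrics <- function(x, ...) {
  cat(sprintf("Region metrics at the mid-MLC plane (cm, cm2):\n"))
  cat(sprintf("  FP in/out: %.4f / %.4f   (RP %.4f)\n", x$fp_in, x$fp_out, x$rp))
  cat(sprintf("  MA in/out: %.4f / %.4f   (RA in %.4f, RA out %.4f)\n",
              x$ma_in, x$ma_out, x$ra_in, x$ra_out))
  invisible(x)
}

#' Classify a field against the jaw BEV and the scatter interface
#'
#' Category 1: leaves retracted strictly clear of the jaw-defined beam's-eye
#' view (no leaf material on or inside the field edge); the MLC scatter
#' correction is unity.  Category 2: leaves shape the field but its boundary
#' stays outside the scatter interface.  Category 3: the MLC boundary enters
#' the interface (and so perturbs the detector's-eye view).
#'
#' @param jaw a \code{\link{jaw_setting}}.
#' @param bank an \code{\link{mlc_bank}} (or \code{NULL} for retracted).
#' @param interface the scatter-interface \code{\link{rect}} at the mid-MLC
#'   plane.
#' @param gap_tol closed-pair tolerance (cm at isocenter).
#' @param iso_dist isocenter plane distance (cm).
#' @return Integer 1, 2 or 3.
#' @export
classify_category <- function(jaw, bank, interface, gap_tol = 0.05,
                              iso_dist = 100) {
  if (is.null(bank) || is_retracted(bank, jaw, gap_tol)) return(1L)
  poly <- mlc_polygon(bank, jaw, interface$plane_dist, gap_tol, iso_dist)
  m <- split_by_interface(poly, jaw, interface, iso_dist = iso_dist)
  if (m$fp_in > 1e-9) 3L else 2L
}

# ---- field specs and field files -------------------------------------------

#' A complete field specification
#'
#' @param jaw a \code{\link{jaw_setting}}.
#' @param bank an \code{\link{mlc_bank}} or \code{NULL} for a retracted MLC.
#' @param id optional identifier string.
#' @return An object of class \code{field_spec}.
#' @export
field_spec <- function(jaw, bank = NULL, id = NULL) {
  structure(list(jaw = jaw, bank = bank, id = id), class = "field_spec")
}

#' Reference field: jaw 10 x 10 cm2, MLC retracted
#' @return A \code{\link{field_spec}}.
#' @export
reference_field <- function() field_spec(jaw_square(10), NULL, id = "ref_10x10")

#' Read or write a field definition file
#'
#' YAML with a \code{jaw} block (\code{x1, x2, y1, y2}, cm at isocenter) and
#' an \code{mlc} block: the string \code{"retracted"}, a shorthand
#' \code{mlc_square: side_cm}, a template
#' (\code{template: cross|mirrored_e|maze}), or explicit \code{left} /
#' \code{right} vectors (optionally \code{edges}).
#'
#' @param path file path.
#' @return \code{read_field_file}: a \code{\link{field_spec}}.
#' @export
read_field_file <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$jaw)) stop("field file missing 'jaw' block")
  jaw <- jaw_setting(x$jaw$x1, x$jaw$x2, x$jaw$y1, x$jaw$y2)
  bank <- parse_mlc_block(x$mlc, jaw)
  field_spec(jaw, bank, id = x$id)
}

parse_mlc_block <- function(m, jaw) {
  if (is.null(m) || identical(m, "retracted")) return(NULL)
  if (!is.null(m$mlc_square)) return(mlc_bank_square(m$mlc_square))
  if (!is.null(m$template))
    return(mlc_bank_template(m$template, jaw$x2 - jaw$x1))
  if (is.null(m$left) || is.null(m$right))
    stop("mlc block needs 'left' and 'right' (or a shorthand)")
  edges <- if (is.null(m$edges)) millennium120_edges() else m$edges
  mlc_bank(m$left, m$right, edges)
}

#' @rdname read_field_file
#' @param field a \code{\link{field_spec}} to write.
#' @export
write_field_file <- function(field, path) {
  mlc <- if (is.null(field$bank)) "retracted" else
    list(left = field$bank$left, right = field$bank$right,
         edges = field$bank$edges)
  yaml::write_yaml(list(id = field$id,
                        jaw = list(x1 = field$jaw$x1, x2 = field$jaw$x2,
                                   y1 = field$jaw$y1, y2 = field$jaw$y2),
                        mlc = mlc), path, precision = 12)
  invisible(path)
}
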