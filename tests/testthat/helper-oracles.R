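# Independent oracles used across the suite.  None of these share code with
# the package's slab-form geometry: areas and perimeters come from a generic
# rectangle-union sweep, perimeter splits from midpoint classification of
# subdivided segments, and Gaussian masses from dense midpoint quadrature.

# union area and perimeter of arbitrary axis-aligned rectangles
# rects: data.frame(x_lo, x_hi, y_lo, y_hi)
union_intervals <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  out_lo <- c(); out_hi <- c()
  cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi + 1e-12) cur_hi <- max(cur_hi, hi[i])
    else { out_lo <- c(out_lo, cur_lo); out_hi <- c(out_hi, cur_hi)
           cur_lo <- lo[i]; cur_hi <- hi[i] }
  }
  cbind(c(out_lo, cur_lo), c(out_hi, cur_hi))
}

rect_union_metrics <- function(rects) {
  if (nrow(rects) == 0) return(list(area = 0, perimeter = 0))
  cuts <- sort(unique(c(rects$y_lo, rects$y_hi)))
  area <- 0; vert <- 0
  strip_ivs <- list()
  for (k in seq_len(length(cuts) - 1)) {
    lo <- cuts[k]; hi <- cuts[k + 1]
    idx <- which(rects$y_lo <= lo + 1e-12 & rects$y_hi >= hi - 1e-12)
    if (length(idx) == 0) { strip_ivs[[k]] <- cbind(numeric(0), numeric(0)); next }
    iv <- union_intervals(rects$x_lo[idx], rects$x_hi[idx])
    strip_ivs[[k]] <- iv
    area <- area + (hi - lo) * sum(iv[, 2] - iv[, 1])
    vert <- vert + 2 * nrow(iv) * (hi - lo)
  }
  iv_len_diff <- function(a, b) {
    # length of the symmetric difference of two interval unions
    pts <- sort(unique(c(a, b)))
    if (length(pts) < 2) return(0)
    mids <- (pts[-1] + pts[-length(pts)]) / 2
    ina <- vapply(mids, function(m)
      nrow(a) > 0 && any(a[, 1] <= m & m <= a[, 2]), logical(1))
    inb <- vapply(mids, function(m)
      nrow(b) > 0 && any(b[, 1] <= m & m <= b[, 2]), logical(1))
    sum((pts[-1] - pts[-length(pts)])[xor(ina, inb)])
  }
  horiz <- 0
  empty <- cbind(numeric(0), numeric(0))
  for (k in seq_len(length(cuts))) {
    below <- if (k > 1) strip_ivs[[k - 1]] else empty
    above <- if (k <= length(strip_ivs)) strip_ivs[[k]] else empty
    horiz <- horiz + iv_len_diff(rbind(below), rbind(above))
  }
  list(area = area, perimeter = vert + horiz)
}

poly_to_rects <- function(poly) {
  s <- poly$slabs
  data.frame(x_lo = s$x_lo, x_hi = s$x_hi, y_lo = s$y_lo, y_hi = s$y_hi)
}

# perimeter split oracle: subdivide every boundary segment at the interface
# rectangle's edge lines, classify each piece by its midpoint (closed rect)
segment_clip_oracle <- function(poly, interface) {
  seg <- poly_segments(poly)
  fp_in <- 0; fp_out <- 0
  inside <- function(x, y)
    x >= interface$x_lo - 1e-12 && x <= interface$x_hi + 1e-12 &&
    y >= interface$y_lo - 1e-12 && y <= interface$y_hi + 1e-12
  for (i in seq_len(nrow(seg))) {
    if (seg$orient[i] == "h") {
      a <- min(seg$x1[i], seg$x2[i]); b <- max(seg$x1[i], seg$x2[i])
      cuts <- sort(unique(c(a, b,
                            pmin(pmax(c(interface$x_lo, interface$x_hi), a), b))))
      for (k in seq_len(length(cuts) - 1)) {
        len <- cuts[k + 1] - cuts[k]
        if (len <= 0) next
        if (inside((cuts[k] + cuts[k + 1]) / 2, seg$y1[i]))
          fp_in <- fp_in + len else fp_out <- fp_out + len
      }
    } else {
      a <- min(seg$y1[i], seg$y2[i]); b <- max(seg$y1[i], seg$y2[i])
      cuts <- sort(unique(c(a, b,
                            pmin(pmax(c(interface$y_lo, interface$y_hi), a), b))))
      for (k in seq_len(length(cuts) - 1)) {
        len <- cuts[k + 1] - cuts[k]
        if (len <= 0) next
        if (inside(seg$x1[i], (cuts[k] + cuts[k + 1]) / 2))
          fp_in <- fp_in + len else fp_out <- fp_out + len
      }
    }
  }
  list(fp_in = fp_in, fp_out = fp_out)
}

# dense midpoint quadrature of the centered bivariate Gaussian over a
# slab-form region; cells aligned to each slab so only smoothness error
# remains
gaussian_grid_oracle <- function(slabs, sigma, cell = 0.04) {
  total <- 0
  for (i in seq_len(nrow(slabs))) {
    nx <- max(2L, ceiling((slabs$x_hi[i] - slabs$x_lo[i]) / (cell * sigma)))
    ny <- max(2L, ceiling((slabs$y_hi[i] - slabs$y_lo[i]) / (cell * sigma)))
    xs <- seq(slabs$x_lo[i], slabs$x_hi[i], length.out = nx + 1)
    ys <- seq(slabs$y_lo[i], slabs$y_hi[i], length.out = ny + 1)
    xm <- (xs[-1] + xs[-length(xs)]) / 2
    ym <- (ys[-1] + ys[-length(ys)]) / 2
    w <- outer(stats::dnorm(xm, sd = sigma) * diff(xs),
               stats::dnorm(ym, sd = sigma) * diff(ys))
    total <- total + sum(w)
  }
  total
}

# shoelace area of an ordered simple polygon
shoelace_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# random rectilinear apertures for property tests
random_aperture <- function() {
  jaw_w <- stats::runif(1, 6, 30); jaw_h <- stats::runif(1, 6, 30)
  jaw <- jaw_setting(-jaw_w / 2, jaw_w / 2, -jaw_h / 2, jaw_h / 2)
  edges <- millennium120_edges()
  n <- length(edges) - 1L
  left <- rep(0, n); right <- rep(0, n)
  open <- stats::runif(n) < 0.8
  for (i in which(open)) {
    c0 <- stats::runif(1, -jaw_w / 2, jaw_w / 2)
    hw <- stats::runif(1, 0.2, jaw_w / 2)
    left[i] <- c0 - hw; right[i] <- c0 + hw
  }
  list(jaw = jaw, bank = mlc_bank(left, right, edges))
}

# independent Sp lookup for the circular-consistency check
interp_sp_for_test <- function(table, r) {
  stats::approx(table$sp$radius, table$sp$sp, xout = r)$y
}
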