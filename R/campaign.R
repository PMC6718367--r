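# Synthetic measurement campaign: the standard modeling design (jaw squares
# and rectangles for the dual-source stage; per-jaw MLC-square series and
# irregular template fields for the MLC scatter stage) with multiplicative
# Gaussian reading noise, so fitting and evaluation run without external
# data.

#' Campaign design
#'
#' The default design mirrors the standard measurement campaign: jaw-defined
#' squares 4 to 40 cm in 1 cm steps plus rectangles with one jaw pair fixed
#' at 4, 10 or 40 cm (dual-source stage, MLC retracted); centered MLC-square
#' series from 4 x 4 cm2 up to the jaw size for square jaw settings of 10,
#' 15, 20, 25 and 30 cm; and three irregular leaf templates (cross, mirrored
#' E, maze) at jaw settings 15, 20 and 25 cm.  The reference 10 x 10 field
#' appears exactly once.
#'
#' @param jaw_squares jaw-square sides (cm) for the dual-source stage.
#' @param rect_fixed fixed jaw-pair values (cm) for the rectangle series.
#' @param rect_varied varied jaw-pair values (cm).
#' @param mlc_jaws square jaw settings (cm) carrying MLC-square series.
#' @param irregular_jaws square jaw settings (cm) for the template fields.
#' @param shapes irregular template names.
#' @param noise_sd relative reading SD (multiplicative); must lie in
#'   [0, 0.005].  The default 0.002 is the repeat-reading SD bound of a
#'   careful Sc campaign.
#' @param seed RNG seed used by \code{\link{simulate_campaign}}.
#' @return An object of class \code{campaign_design}.
#' @export
campaign_design <- function(jaw_squares = 4:40, rect_fixed = c(4, 10, 40),
                            rect_varied = 4:40,
                            mlc_jaws = c(10, 15, 20, 25, 30),
                            irregular_jaws = c(15, 20, 25),
                            shapes = c("cross", "mirrored_e", "maze"),
                            noise_sd = 0.002, seed = 1L) {
  if (noise_sd < 0 || noise_sd > 0.005)
    stop("noise_sd must lie in [0, 0.005]")
  structure(list(jaw_squares = jaw_squares, rect_fixed = rect_fixed,
                 rect_varied = rect_varied, mlc_jaws = mlc_jaws,
                 irregular_jaws = irregular_jaws, shapes = shapes,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "campaign_design")
}

#' Irregular leaf-position templates
#'
#' Versioned leaf templates (v1) scaled to the jaw size J, approximating the
#' classic cross / mirrored-E / maze verification shapes; exact published
#' leaf coordinates for such shapes do not exist, so these are declared
#' approximations.  All bands are single leaf-gap intervals:
#' \itemize{
#'   \item \code{cross}: central band of height J/3 fully open, outer bands
#'     open only over the central third.
#'   \item \code{mirrored_e}: five equal bands; odd bands fully open, even
#'     bands open only along a spine of width J/5 at the +x edge.
#'   \item \code{maze}: seven equal bands; odd bands fully open, corridors of
#'     width J/7 alternating between the -x and +x edges in between.  The
#'     beam axis is blocked by design (band 4 is a +x corridor).
#' }
#'
#' @param shape one of \code{"cross"}, \code{"mirrored_e"}, \code{"maze"}.
#' @param jaw_size square jaw side J (cm at the isocenter).
#' @param edges leaf-boundary coordinates.
#' @return An \code{\link{mlc_bank}}; pairs outside the jaw, and blocked
#'   bands, are closed (abutted at x = 0).
#' @export
mlc_bank_template <- function(shape = c("cross", "mirrored_e", "maze"),
                              jaw_size, edges = millennium120_edges()) {
  shape <- match.arg(shape)
  J <- jaw_size
  h <- J / 2
  band_interval <- switch(shape,
    cross = function(yc) {
      if (abs(yc) > h) return(NULL)
      if (abs(yc) <= J / 6) c(-h, h) else c(-J / 6, J / 6)
    },
    mirrored_e = function(yc) {
      if (abs(yc) > h) return(NULL)
      band <- pmin(floor((yc + h) / (J / 5)) + 1, 5)
      if (band %% 2 == 1) c(-h, h) else c(h - J / 5, h)
    },
    maze = function(yc) {
      if (abs(yc) > h) return(NULL)
      band <- pmin(floor((yc + h) / (J / 7)) + 1, 7)
      if (band %% 2 == 1) return(c(-h, h))
      if (band %in% c(2, 6)) c(-h, -h + J / 7) else c(h - J / 7, h)
    })
  n <- length(edges) - 1L
  yc <- (edges[-(n + 1L)] + edges[-1L]) / 2
  left <- rep(0, n); right <- rep(0, n)
  for (i in seq_len(n)) {
    iv <- band_interval(yc[i])
    if (!is.null(iv)) { left[i] <- iv[1]; right[i] <- iv[2] }
  }
  mlc_bank(left, right, edges)
}

#' Enumerate the fields of a campaign design
#'
#' Deterministic enumeration; duplicate jaw settings (e.g. the 10 x 10
#' square recurring in the rectangle series) are kept once, so the
#' reference field appears exactly once.
#'
#' @param design a \code{\link{campaign_design}}.
#' @return A list of entries, each with \code{field}
#'   (\code{\link{field_spec}}) and \code{mlc_spec} (the measurement-table
#'   shorthand: \code{"retracted"}, \code{"square:<side>"} or
#'   \code{"template:<shape>"}).
#' @export
build_design <- function(design) {
  out <- list(); seen <- character()
  add <- function(jaw, bank, mlc_spec, id) {
    key <- paste(jaw$x1, jaw$x2, jaw$y1, jaw$y2, mlc_spec)
    if (key %in% seen) return(invisible())
    seen <<- c(seen, key)
    out[[length(out) + 1L]] <<- list(field = field_spec(jaw, bank, id = id),
                                     mlc_spec = mlc_spec)
  }
  for (s in design$jaw_squares)
    add(jaw_square(s), NULL, "retracted", sprintf("jaw_%gx%g", s, s))
  for (fx in design$rect_fixed) for (v in design$rect_varied) {
    add(jaw_setting(-fx / 2, fx / 2, -v / 2, v / 2), NULL, "retracted",
        sprintf("jaw_%gx%g", fx, v))
    add(jaw_setting(-v / 2, v / 2, -fx / 2, fx / 2), NULL, "retracted",
        sprintf("jaw_%gx%g", v, fx))
  }
  for (J in design$mlc_jaws) {
    if (J < 4)
      stop("MLC squares start at 4 cm; jaw ", J, " x ", J, " cannot hold one")
    for (s in seq(4, J))
      add(jaw_square(J), mlc_bank_square(s), sprintf("square:%g", s),
          sprintf("mlc_%gx%g_jaw_%gx%g", s, s, J, J))
  }
  for (J in design$irregular_jaws) for (sh in design$shapes)
    add(jaw_square(J), mlc_bank_template(sh, J), sprintf("template:%s", sh),
        sprintf("%s_jaw_%gx%g", sh, J, J))
  out
}

#' Simulate a measurement campaign
#'
#' Evaluates the forward model \eqn{S_c = S_{c,DSM} S_{c,MLC}} for every
#' design field and applies multiplicative Gaussian reading noise with
#' relative SD \code{noise_sd}.  The \code{sd} column carries
#' \code{noise_sd * Sc} (the quoted repeat-reading SD).  Reproducible under
#' a fixed seed.
#'
#' @param design a \code{\link{campaign_design}} or the output of
#'   \code{\link{build_design}}.
#' @param truth list with elements \code{dsm} (a \code{\link{dsm_params}})
#'   and \code{mlc} (an \code{\link{apratio_model}},
#'   \code{\link{mlc_scatter_params}} or \code{mlc_fit}); default the
#'   shipped reference calibration.
#' @param geom a \code{\link{machine_geometry}}.
#' @param noise_sd,seed override the design's values.
#' @return A measurement table (data frame with columns \code{field_id},
#'   \code{jaw_x1..jaw_y2}, \code{mlc_spec}, \code{sc}, \code{sd}) with a
#'   \code{truth} attribute holding the noise-free values.
#' @export
simulate_campaign <- function(design = campaign_design(),
                              truth = list(dsm = reference_dsm_params(),
                                           mlc = reference_apratio_model()),
                              geom = machine_geometry(),
                              noise_sd = NULL, seed = NULL) {
  if (inherits(design, "campaign_design")) {
    if (is.null(noise_sd)) noise_sd <- design$noise_sd
    if (is.null(seed)) seed <- design$seed
    entries <- build_design(design)
  } else {
    entries <- design
    if (is.null(noise_sd)) noise_sd <- 0.002
    if (is.null(seed)) seed <- 1L
  }
  sc_true <- vapply(entries, function(e)
    sc_total(e$field, truth$dsm, truth$mlc, geom), numeric(1))
  set.seed(seed)
  n <- length(entries)
  sc_noisy <- sc_true * (1 + stats::rnorm(n, 0, noise_sd))
  tab <- data.frame(
    field_id = vapply(entries, function(e) e$field$id, character(1)),
    jaw_x1 = vapply(entries, function(e) e$field$jaw$x1, numeric(1)),
    jaw_x2 = vapply(entries, function(e) e$field$jaw$x2, numeric(1)),
    jaw_y1 = vapply(entries, function(e) e$field$jaw$y1, numeric(1)),
    jaw_y2 = vapply(entries, function(e) e$field$jaw$y2, numeric(1)),
    mlc_spec = vapply(entries, function(e) e$mlc_spec, character(1)),
    sc = sc_noisy, sd = noise_sd * sc_true,
    stringsAsFactors = FALSE)
  attr(tab, "truth") <- sc_true
  tab
}

#' Rebuild the field of a measurement-table row
#'
#' @param row one row of a measurement table.
#' @return A \code{\link{field_spec}}.
#' @export
field_from_row <- function(row) {
  jaw <- jaw_setting(row$jaw_x1, row$jaw_x2, row$jaw_y1, row$jaw_y2)
  spec <- row$mlc_spec
  bank <- if (identical(spec, "retracted")) NULL
  else if (grepl("^square:", spec))
    mlc_bank_square(as.numeric(sub("^square:", "", spec)))
  else if (grepl("^template:", spec))
    mlc_bank_template(sub("^template:", "", spec), jaw$x2 - jaw$x1)
  else stop("unrecognized mlc_spec: ", spec)
  field_spec(jaw, bank, id = row$field_id)
}
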