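# Measurement-table CSV and parameter-file input/output.  Output files carry
# a provenance comment header (tool version, content hash, optional seed).

meas_required_cols <- c("field_id", "jaw_x1", "jaw_x2", "jaw_y1", "jaw_y2",
                        "mlc_spec", "sc", "sd")

content_hash <- function(x) {
  raw <- as.integer(charToRaw(paste(x, collapse = "\n")))
  # polynomial rolling hash in double arithmetic (exact below 2^53)
  h <- 17
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

provenance_header <- function(kind, seed = NULL, extra = NULL) {
  v <- as.character(utils::packageVersion("mlcscatter"))
  c(sprintf("# mlcscatter %s | %s", v, kind),
    if (!is.null(seed)) sprintf("# seed %s", seed),
    if (!is.null(extra)) paste("#", extra))
}

#' Read or write a measurement table
#'
#' CSV with columns \code{field_id}, \code{jaw_x1}, \code{jaw_x2},
#' \code{jaw_y1}, \code{jaw_y2}, \code{mlc_spec}, \code{sc}, \code{sd};
#' unknown columns are preserved and round-trip losslessly.  Leading
#' \code{#} comment lines (the provenance header) are skipped on read.
#'
#' @param path file path.
#' @return \code{read_measurements}: the measurement data frame.
#' @export
read_measurements <- function(path) {
  m <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(meas_required_cols, names(m))
  if (length(miss))
    stop("measurement table missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("jaw_x1", "jaw_x2", "jaw_y1", "jaw_y2", "sc", "sd"))
    if (!is.numeric(m[[col]]))
      stop("measurement column '", col, "' must be numeric")
  m
}

#' @rdname read_measurements
#' @param measurements the measurement data frame to write.
#' @param seed optional seed recorded in the provenance header.
#' @param overwrite allow replacing an existing file.
#' @export
write_measurements <- function(measurements, path, seed = NULL,
                               overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; pass overwrite = TRUE to replace it")
  body <- utils::capture.output(
    utils::write.csv(measurements, row.names = FALSE))
  hdr <- provenance_header("measurement table", seed,
                           paste("content", content_hash(body)))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read or write dual-source parameters
#'
#' YAML with \code{k_ff}, \code{sigma_ff}, \code{k_b} and, for fits, the
#' objective / iteration / convergence metadata.
#'
#' @param path file path.
#' @return \code{read_dsm_params}: a \code{\link{dsm_params}} with a
#'   \code{fit} attribute when fit metadata is present.
#' @export
read_dsm_params <- function(path) {
  x <- yaml::read_yaml(path)
  for (k in c("k_ff", "sigma_ff", "k_b"))
    if (is.null(x[[k]])) stop("dsm params file missing '", k, "'")
  p <- dsm_params(x$k_ff, x$sigma_ff, x$k_b)
  if (!is.null(x$fit)) attr(p, "fit") <- x$fit
  p
}

#' @rdname read_dsm_params
#' @param params a \code{\link{dsm_params}} or \code{dsm_fit}.
#' @param overwrite allow replacing an existing file.
#' @export
write_dsm_params <- function(params, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; pass overwrite = TRUE to replace it")
  fit <- NULL
  if (inherits(params, "dsm_fit")) {
    fit <- list(objective = params$objective, iterations = params$iterations,
                converged = params$converged, n = params$n)
    params <- params$params
  }
  yaml::write_yaml(list(k_ff = params$k_ff, sigma_ff = params$sigma_ff,
                        k_b = params$k_b, fit = fit), path, precision = 12)
  invisible(path)
}

#' Read or write MLC scatter parameters
#'
#' YAML with a \code{jaws} block (one entry per square jaw setting with the
#' six region parameters), an optional \code{apratio_model} block
#' (quadratic coefficients with per-parameter scale), and a
#' \code{provenance} field (\code{"fitted"} or \code{"reference"}).  The
#' parameter convention (FP, RP in cm and MA, RA in cm2 at the mid-MLC
#' plane) is recorded so fitted parameter files are self-describing.
#'
#' @param path file path.
#' @return \code{read_mlc_params}: an \code{mlc_fit}-like list with
#'   \code{per_jaw} and \code{model}.
#' @export
read_mlc_params <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$jaws)) stop("mlc params file missing 'jaws' block")
  per_jaw <- do.call(rbind, lapply(x$jaws, as.data.frame))
  model <- NULL
  if (!is.null(x$apratio_model)) {
    cf <- do.call(rbind, lapply(x$apratio_model$coefficients, as.data.frame))
    model <- structure(list(coefficients = cf,
                            range = unlist(x$apratio_model$range)),
                       class = "apratio_model")
  }
  structure(list(per_jaw = per_jaw, model = model,
                 provenance = x$provenance), class = "mlc_fit")
}

#' @rdname read_mlc_params
#' @param fit an \code{mlc_fit} (from \code{\link{fit_mlc_params}}) or a
#'   per-jaw data frame such as \code{\link{reference_mlc_params}()}.
#' @param provenance \code{"fitted"} or \code{"reference"}.
#' @param overwrite allow replacing an existing file.
#' @export
write_mlc_params <- function(fit, path, provenance = "fitted",
                             overwrite = FALSE) {
  if (file.exists(path) && !overwrite)
    stop("'", path, "' exists; pass overwrite = TRUE to replace it")
  if (is.data.frame(fit))
    fit <- list(per_jaw = fit, model = apratio_model_from_params(fit))
  jaws <- lapply(seq_len(nrow(fit$per_jaw)), function(i)
    as.list(fit$per_jaw[i, , drop = FALSE]))
  model <- NULL
  if (!is.null(fit$model))
    model <- list(coefficients = lapply(
      seq_len(nrow(fit$model$coefficients)),
      function(i) as.list(fit$model$coefficients[i, , drop = FALSE])),
      range = fit$model$range)
  yaml::write_yaml(list(provenance = provenance,
                        convention = "FP/RP cm, MA/RA cm2, mid-MLC plane",
                        jaws = jaws, apratio_model = model), path,
                   precision = 12)
  invisible(path)
}

#' Read or write radial dosimetric tables
#'
#' Sp as a two-column CSV (\code{radius, sp}); TMR as a long-format
#' three-column CSV (\code{depth, radius, tmr}).
#'
#' @param sp_path,tmr_path file paths; \code{tmr_path} optional on read.
#' @return \code{read_radial_tables}: a \code{\link{radial_table}}.
#' @export
read_radial_tables <- function(sp_path, tmr_path = NULL) {
  sp <- utils::read.csv(sp_path, comment.char = "#")
  tmr <- if (is.null(tmr_path)) NULL else
    utils::read.csv(tmr_path, comment.char = "#")
  radial_table(sp, tmr)
}

#' @rdname read_radial_tables
#' @param table a \code{\link{radial_table}} to write.
#' @export
write_radial_tables <- function(table, sp_path, tmr_path = NULL) {
  utils::write.csv(table$sp, sp_path, row.names = FALSE)
  if (!is.null(tmr_path) && !is.null(table$tmr))
    utils::write.csv(table$tmr, tmr_path, row.names = FALSE)
  invisible(sp_path)
}
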