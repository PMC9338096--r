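#' Force curve objects
#'
#' An approach force curve is the raw record of an AFM force measurement:
#' the photodetector (PSD) signal in volts versus the sample vertical
#' position in nanometres. `force_curve()` builds and validates such a
#' curve; [contact_label()] attaches a ground-truth or hand-assigned
#' contact point and [labeled_curve()] bundles the two.
#'
#' In the canonical orientation the index increases as probe and sample
#' approach: `z` is strictly increasing and the contact region sits at the
#' high-index end. [canonicalize()] projects any monotonic curve onto this
#' orientation.
#'
#' @param z Numeric vector, sample vertical position per sample (nm),
#'   strictly monotonic.
#' @param psd Numeric vector, photodetector signal per sample (V).
#' @param ramp_length Ramp length (nm); defaults to `diff(range(z))`.
#' @param ramp_velocity Ramp velocity (nm/s) or `NULL` if unknown.
#' @param spring_constant Cantilever normal spring constant (N/m) or `NULL`.
#' @param sensitivity Photodetector sensitivity (V/nm) or `NULL`.
#' @param medium Free-text medium label, e.g. `"NaCl_100mM"`.
#' @param surface Free-text surface label, e.g. `"mica"` or `"pellicle"`.
#' @return An object of class `fp_curve` with fields `z`, `psd`,
#'   `n_points` and `meta`.
#' @examples
#' z <- seq(0, 100, length.out = 64)
#' fc <- force_curve(z, ifelse(z < 80, 0, z - 80) * 0.05)
#' fc
#' @export
force_curve <- function(z, psd, ramp_length = NULL, ramp_velocity = NULL,
                        spring_constant = NULL, sensitivity = NULL,
                        medium = NA_character_, surface = NA_character_) {
  z <- as.numeric(z); psd <- as.numeric(psd)
  if (length(z) != length(psd))
    stop_fp("z and psd have different lengths (%d vs %d)",
            length(z), length(psd), class = "fp_validation_error")
  if (length(z) < 16L)
    stop_fp("a force curve needs at least 16 samples, got %d", length(z),
            class = "fp_validation_error")
  if (!all(is.finite(z)) || !all(is.finite(psd)))
    stop_fp("non-finite values in curve data", class = "fp_validation_error")
  dz <- diff(z)
  if (!(all(dz > 0) || all(dz < 0)))
    stop_fp("z must be strictly monotonic", class = "fp_validation_error")
  meta <- list(
    ramp_length = ramp_length %||% abs(diff(range(z))),
    ramp_velocity = ramp_velocity,
    sampling_points = length(z),
    spring_constant = spring_constant,
    sensitivity = sensitivity,
    medium = medium,
    surface = surface
  )
  structure(list(z = z, psd = psd, n_points = length(z), meta = meta),
            class = "fp_curve")
}

#' Contact-point label
#'
#' A contact point is stored both as a sample position `zc` (nm) and as the
#' continuous, 0-based fractional index where `zc` falls on the curve's z
#' axis; the two are consistent under linear interpolation.
#'
#' @param zc Contact-point sample position (nm), inside `range(curve$z)`.
#' @param curve The [force_curve()] the label belongs to.
#' @return An object of class `fp_contact_label` with fields `zc` and
#'   `frac_index`.
#' @export
contact_label <- function(zc, curve) {
  stopifnot(inherits(curve, "fp_curve"))
  zc <- as.numeric(zc)
  if (length(zc) != 1L || !is.finite(zc))
    stop_fp("zc must be a single finite number", class = "fp_validation_error")
  zr <- range(curve$z)
  if (zc < zr[1] - 1e-9 || zc > zr[2] + 1e-9)
    stop_fp("zc = %g nm lies outside the curve's z range [%g, %g]",
            zc, zr[1], zr[2], class = "fp_validation_error")
  zc <- min(max(zc, zr[1]), zr[2])
  fi <- stats::approx(curve$z, seq_along(curve$z) - 1, xout = zc)$y
  structure(list(zc = zc, frac_index = fi), class = "fp_contact_label")
}

#' @rdname contact_label
#' @param label A [contact_label()].
#' @param truth_source `"simulated"` or `"hand_labelled"`.
#' @export
labeled_curve <- function(curve, label,
                          truth_source = c("simulated", "hand_labelled")) {
  stopifnot(inherits(curve, "fp_curve"), inherits(label, "fp_contact_label"))
  truth_source <- match.arg(truth_source)
  # re-validate the label against this curve
  label <- contact_label(label$zc, curve)
  structure(list(curve = curve, label = label, truth_source = truth_source),
            class = c("fp_labeled_curve"))
}

is_labeled <- function(x) inherits(x, "fp_labeled_curve")

# Pull the bare fp_curve out of either curve flavour.
as_curve <- function(x) {
  if (is_labeled(x)) x$curve
  else if (inherits(x, "fp_curve")) x
  else stop_fp("not a force curve object", class = "fp_validation_error")
}

#' Canonical curve orientation
#'
#' Reorders a curve so that `z` is strictly increasing with index, i.e.
#' larger index means closer approach / deeper contact. Idempotent and
#' preserves the multiset of `(z, psd)` pairs. Labels survive unchanged
#' (`zc` is a position, not an index).
#'
#' @param curve A [force_curve()] or [labeled_curve()].
#' @return The same type of object, in canonical orientation.
#' @export
canonicalize <- function(curve) {
  if (is_labeled(curve)) {
    cc <- canonicalize(curve$curve)
    return(labeled_curve(cc, contact_label(curve$label$zc, cc),
                         curve$truth_source))
  }
  stopifnot(inherits(curve, "fp_curve"))
  dz <- diff(curve$z)
  if (all(dz > 0)) return(curve)
  if (!all(dz < 0))
    stop_fp("z must be strictly monotonic", class = "fp_validation_error")
  out <- curve
  out$z <- rev(curve$z)
  out$psd <- rev(curve$psd)
  out
}

# ---- on-disk format -------------------------------------------------------
# UTF-8 text; "# key: value" header lines, then two whitespace-separated
# columns (z_nm, psd_V), one row per sample.

.header_keys <- c(
  n_points = "n_points", ramp_length = "ramp_length_nm",
  ramp_velocity = "ramp_velocity_nm_per_s",
  spring_constant = "spring_constant_N_per_m",
  sensitivity = "sensitivity_V_per_nm",
  medium = "medium", surface = "surface"
)

#' Read and write curve files
#'
#' The on-disk curve format is plain UTF-8 text: header lines of the form
#' `# key: value` (keys `n_points`, `ramp_length_nm`,
#' `spring_constant_N_per_m`, `sensitivity_V_per_nm`, `medium`, `surface`,
#' and optionally `contact_point_nm` and `truth_source`), followed by two
#' whitespace-separated numeric columns `z_nm`, `psd_V`. A read/write round
#' trip reproduces all numeric fields to better than 1e-9 relative
#' tolerance.
#'
#' @param path File path.
#' @return `read_curve()` returns a [labeled_curve()] when the
#'   `contact_point_nm` header is present, otherwise a [force_curve()].
#' @export
read_curve <- function(path) {
  if (!file.exists(path))
    stop_fp("no such file: %s", path, class = "fp_io_error")
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- list()
  i <- 1L
  while (i <= length(lines) && grepl("^#", lines[i])) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3L)
      stop_fp("malformed header at line %d: '%s'", i, lines[i],
              class = "fp_format_error")
    hdr[[m[2]]] <- trimws(m[3])
    i <- i + 1L
  }
  body <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  body <- body[nzchar(trimws(body))]
  toks <- strsplit(trimws(body), "\\s+")
  nt <- lengths(toks)
  if (any(nt != 2L))
    stop_fp("data row %d does not have exactly two columns",
            which(nt != 2L)[1], class = "fp_format_error")
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals))
    stop_fp("non-numeric value in data rows", class = "fp_format_error")
  m <- matrix(vals, ncol = 2L, byrow = TRUE)
  num <- function(key) {
    v <- hdr[[key]]
    if (is.null(v) || identical(v, "NA")) NULL else as.numeric(v)
  }
  chr <- function(key) {
    v <- hdr[[key]]
    if (is.null(v) || identical(v, "NA")) NA_character_ else v
  }
  np <- num("n_points")
  if (!is.null(np) && as.integer(np) != nrow(m))
    stop_fp("header says n_points = %d but file has %d rows",
            as.integer(np), nrow(m), class = "fp_format_error")
  fc <- force_curve(m[, 1], m[, 2],
                    ramp_length = num("ramp_length_nm"),
                    ramp_velocity = num("ramp_velocity_nm_per_s"),
                    spring_constant = num("spring_constant_N_per_m"),
                    sensitivity = num("sensitivity_V_per_nm"),
                    medium = chr("medium"), surface = chr("surface"))
  zc <- num("contact_point_nm")
  if (is.null(zc)) return(fc)
  ts <- hdr[["truth_source"]] %||% "hand_labelled"
  labeled_curve(fc, contact_label(zc, fc), ts)
}

#' @rdname read_curve
#' @param curve A [force_curve()] or [labeled_curve()].
#' @export
write_curve <- function(curve, path) {
  lc <- if (is_labeled(curve)) curve else NULL
  fc <- as_curve(curve)
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  hdr <- c(
    sprintf("# n_points: %d", fc$n_points),
    sprintf("# ramp_length_nm: %s", fmt(fc$meta$ramp_length)),
    if (!is.null(fc$meta$ramp_velocity))
      sprintf("# ramp_velocity_nm_per_s: %s", fmt(fc$meta$ramp_velocity)),
    if (!is.null(fc$meta$spring_constant))
      sprintf("# spring_constant_N_per_m: %s", fmt(fc$meta$spring_constant)),
    if (!is.null(fc$meta$sensitivity))
      sprintf("# sensitivity_V_per_nm: %s", fmt(fc$meta$sensitivity)),
    sprintf("# medium: %s", fc$meta$medium),
    sprintf("# surface: %s", fc$meta$surface),
    if (!is.null(lc)) sprintf("# contact_point_nm: %s", fmt(lc$label$zc)),
    if (!is.null(lc)) sprintf("# truth_source: %s", lc$truth_source)
  )
  rows <- paste(fmt(fc$z), fmt(fc$psd))
  ok <- tryCatch({
    writeLines(c(hdr, rows), path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_fp("cannot write to %s", path, class = "fp_io_error")
  invisible(path)
}

#' @export
print.fp_curve <- function(x, ...) {
  cat(sprintf("<force curve: %d points, z in [%.3g, %.3g] nm, psd in [%.3g, %.3g] V>\n",
              x$n_points, min(x$z), max(x$z), min(x$psd), max(x$psd)))
  if (!is.na(x$meta$surface))
    cat(sprintf("  surface: %s, medium: %s\n", x$meta$surface, x$meta$medium))
  invisible(x)
}

#' @export
print.fp_labeled_curve <- function(x, ...) {
  print(x$curve)
  cat(sprintf("  contact point: zc = %.4g nm (frac index %.2f, %s)\n",
              x$label$zc, x$label$frac_index, x$truth_source))
  invisible(x)
}

#' @export
plot.fp_curve <- function(x, ...) {
  graphics::plot(x$z, x$psd, type = "l", xlab = "sample position z (nm)",
                 ylab = "PSD signal (V)", ...)
  invisible(x)
}

#' @export
plot.fp_labeled_curve <- function(x, ...) {
  plot(x$curve, ...)
  graphics::abline(v = x$label$zc, col = 2, lty = 2)
  invisible(x)
}
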