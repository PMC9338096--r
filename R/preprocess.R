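#' Axis transform
#'
#' Records the per-curve axis ranges used by min-max normalization, so
#' that normalized network outputs can be mapped back to sample positions
#' in nm.
#'
#' @param z_min,z_max Horizontal (sample position) range, nm.
#' @param psd_min,psd_max Vertical (PSD signal) range, V.
#' @return A list of class `fp_axis_transform`.
#' @export
axis_transform <- function(z_min, z_max, psd_min, psd_max) {
  if (!(z_max > z_min))
    stop_fp("degenerate z range", class = "fp_degenerate_error")
  if (!(psd_max > psd_min))
    stop_fp("degenerate psd range (constant signal)", class = "fp_degenerate_error")
  structure(list(z_min = z_min, z_max = z_max,
                 psd_min = psd_min, psd_max = psd_max),
            class = "fp_axis_transform")
}

#' Resample a curve to a fixed length
#'
#' Linear interpolation of the PSD signal onto `L` positions uniformly
#' spaced over the curve's z range. The endpoints are preserved exactly.
#' Curves both shorter and longer than `L` are resampled; the operation is
#' the identity on an already-uniform curve of length `L`.
#'
#' @param curve A [force_curve()] (or [labeled_curve()]) in canonical
#'   orientation.
#' @param L Target length (default 5120, larger than typical experimental
#'   curves).
#' @return A list with vectors `z` (nm) and `psd` (V), each of length `L`.
#' @export
resample_curve <- function(curve, L = 5120L) {
  fc <- as_curve(curve)
  if (L < 2L) stop_fp("L must be at least 2", class = "fp_domain_error")
  if (is.unsorted(fc$z, strictly = TRUE))
    fc <- as_curve(canonicalize(fc))
  zout <- seq(fc$z[1], fc$z[fc$n_points], length.out = L)
  psd <- stats::approx(fc$z, fc$psd, xout = zout)$y
  psd[1] <- fc$psd[1]; psd[L] <- fc$psd[fc$n_points]
  list(z = zout, psd = psd)
}

#' Min-max normalization of a resampled curve
#'
#' Maps the PSD signal to \[0, 1\] by per-curve min-max scaling and the z
#' axis to the implicit uniform \[0, 1\] grid, recording the
#' [axis_transform()] needed to invert predictions. Invariant to positive
#' affine rescalings of the PSD signal.
#'
#' @param z Sample positions (nm), uniform ascending grid.
#' @param psd PSD values (V), same length.
#' @return A list of class `fp_prepared` with `signal` (in \[0, 1\], min
#'   exactly 0 and max exactly 1), `transform`, and `label_norm` (`NULL`
#'   here; filled by [prepare_curve()]).
#' @export
normalize_signal <- function(z, psd) {
  stopifnot(length(z) == length(psd))
  tr <- axis_transform(z[1], z[length(z)], min(psd), max(psd))
  signal <- (psd - tr$psd_min) / (tr$psd_max - tr$psd_min)
  structure(list(signal = signal, transform = tr, label_norm = NULL),
            class = "fp_prepared")
}

#' Label codec: normalized sample position
#'
#' The labelled contact point is encoded as the normalized sample position
#' at which it occurs; `decode_prediction()` is the exact algebraic
#' inverse, mapping a network output back to nm on the curve's own z axis.
#' Out-of-\[0, 1\] predictions are decoded by extrapolation (not clipped)
#' and flagged via the `"out_of_range"` attribute.
#'
#' @param label A [contact_label()] or a numeric `zc` (nm).
#' @param transform An [axis_transform()].
#' @return `encode_label()`: the normalized position in \[0, 1\].
#'   `decode_prediction()`: positions in nm with a logical
#'   `"out_of_range"` attribute.
#' @export
encode_label <- function(label, transform) {
  stopifnot(inherits(transform, "fp_axis_transform"))
  zc <- if (inherits(label, "fp_contact_label")) label$zc else as.numeric(label)
  if (any(zc < transform$z_min - 1e-9) || any(zc > transform$z_max + 1e-9))
    stop_fp("zc outside the transform's z range", class = "fp_validation_error")
  (zc - transform$z_min) / (transform$z_max - transform$z_min)
}

#' @rdname encode_label
#' @param pred_norm Normalized position(s) as produced by a model.
#' @export
decode_prediction <- function(pred_norm, transform) {
  stopifnot(inherits(transform, "fp_axis_transform"))
  zc <- transform$z_min + pred_norm * (transform$z_max - transform$z_min)
  attr(zc, "out_of_range") <- pred_norm < 0 | pred_norm > 1
  zc
}

#' Prepare a curve for the network
#'
#' Canonicalize, resample to length `L` and min-max normalize; when the
#' curve carries a label, it is encoded as the normalized sample position.
#'
#' @param curve A [force_curve()] or [labeled_curve()].
#' @param L Network input length.
#' @return An `fp_prepared` list: `signal` (length `L`), `transform`,
#'   `label_norm` (or `NULL` for unlabeled curves).
#' @export
prepare_curve <- function(curve, L = 5120L) {
  curve <- canonicalize(curve)
  rs <- resample_curve(curve, L)
  prep <- normalize_signal(rs$z, rs$psd)
  if (is_labeled(curve))
    prep$label_norm <- encode_label(curve$label, prep$transform)
  prep
}

#' Prepare a list of curves as a design matrix
#'
#' @param curves List of curves ([labeled_curve()] or [force_curve()]).
#' @param L Network input length.
#' @return A list with `x` (matrix, one row per curve), `y` (normalized
#'   labels, `NA` for unlabeled curves), `transforms` (per-curve
#'   [axis_transform()]s) and `zc` (true positions in nm, `NA` if
#'   unlabeled).
#' @export
prepare_dataset <- function(curves, L = 5120L) {
  stopifnot(is.list(curves), length(curves) >= 1L)
  preps <- lapply(curves, prepare_curve, L = L)
  x <- do.call(rbind, lapply(preps, `[[`, "signal"))
  y <- vapply(preps, function(p) p$label_norm %||% NA_real_, numeric(1))
  zc <- vapply(curves, function(cv)
    if (is_labeled(cv)) cv$label$zc else NA_real_, numeric(1))
  list(x = x, y = y, transforms = lapply(preps, `[[`, "transform"), zc = zc)
}
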