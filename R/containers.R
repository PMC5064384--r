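#' Multi-echo MRI series
#'
#' Container for a 4-D multi-echo acquisition (gradient-echo or spin-echo),
#' pairing the signal volume with its echo-time vector.
#'
#' @param signal 4-D numeric array with dimensions (x, y, z, echo).
#' @param echo_times_ms Numeric vector of echo times in ms, strictly
#'   increasing and positive; length must match the 4th array dimension.
#' @param kind Either `"gradient_echo"` or `"spin_echo"`.
#' @return An object of class `echo_series`.
#' @export
echo_series <- function(signal, echo_times_ms, kind = c("gradient_echo", "spin_echo")) {
  kind <- match.arg(kind)
  if (length(dim(signal)) != 4L)
    stop("`signal` must be a 4-D array (x, y, z, echo)")
  if (dim(signal)[4] != length(echo_times_ms))
    stop("echo count mismatch: 4th dimension is ", dim(signal)[4],
         " but ", length(echo_times_ms), " echo times supplied")
  if (any(echo_times_ms <= 0))
    stop("echo times must be positive")
  if (any(diff(echo_times_ms) <= 0))
    stop("echo times must be strictly increasing")
  structure(list(signal = signal, echo_times_ms = as.numeric(echo_times_ms),
                 kind = kind),
            class = "echo_series")
}

#' Dynamic susceptibility contrast (DSC) series
#'
#' 4-D bolus-tracking acquisition: repeated T2*-weighted volumes during
#' contrast-agent passage.
#'
#' @param signal 4-D numeric array (x, y, z, dynamic).
#' @param tr_ms Repetition time in ms (dynamic spacing).
#' @param te_ms Echo time in ms; must be positive.
#' @param n_baseline Number of pre-bolus baseline dynamics (>= 3).
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(signal, tr_ms, te_ms, n_baseline) {
  if (length(dim(signal)) != 4L)
    stop("`signal` must be a 4-D array (x, y, z, dynamic)")
  if (te_ms <= 0) stop("`te_ms` must be positive")
  if (tr_ms <= 0) stop("`tr_ms` must be positive")
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 3L) stop("`n_baseline` must be at least 3")
  if (n_baseline >= dim(signal)[4])
    stop("`n_baseline` must be smaller than the number of dynamics")
  structure(list(signal = signal, tr_ms = tr_ms, te_ms = te_ms,
                 n_baseline = n_baseline),
            class = "dynamic_series")
}

#' Quantitative parameter map
#'
#' A 3-D map (e.g. T2*, T2, R2', rCBV, rOEF or a z-scored contrast) with a
#' validity mask marking voxels where the value is meaningful.
#'
#' @param values 3-D numeric array.
#' @param name Short map name, e.g. `"T2star_ms"`.
#' @param units Unit string, e.g. `"ms"`, `"s^-1"`, `"percent"`, `""`.
#' @param valid_mask Logical 3-D array, same shape as `values`; defaults to
#'   all finite voxels.
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(values, name, units = "", valid_mask = NULL) {
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (is.null(valid_mask)) valid_mask <- is.finite(values)
  if (!identical(dim(valid_mask), dim(values)))
    stop("`valid_mask` shape must match `values`")
  valid_mask <- array(as.logical(valid_mask) & is.finite(values), dim(values))
  structure(list(values = values, name = name, units = units,
                 valid_mask = valid_mask),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("<parameter_map '%s' [%s]> %s voxels, %d valid; range %s\n",
              x$name, x$units, paste(dim(x$values), collapse = "x"),
              sum(x$valid_mask),
              if (length(v)) sprintf("[%.4g, %.4g]", min(v), max(v)) else "[]"))
  invisible(x)
}

#' Physical constants for the rOEF model
#'
#' The relative oxygen extraction fraction is computed as
#' rOEF = R2' / (c * rCBV) with rCBV as a blood-volume fraction. The
#' proportionality constant c = 4/3 * pi * gamma * d_chi * B0 collapses the
#' gyromagnetic ratio and the susceptibility difference between oxygenated and
#' deoxygenated blood into a single field-strength-dependent number; at 3 T it
#' is 317 Hz. Only the product is configured here.
#'
#' @param field_strength_T Static field strength in tesla (default 3).
#' @param c_hz The constant c in Hz. Defaults to 317 * field_strength_T / 3,
#'   i.e. the 3 T literature value scaled linearly with B0.
#' @return An object of class `physics_constants`.
#' @export
physics_constants <- function(field_strength_T = 3, c_hz = 317 * field_strength_T / 3) {
  if (c_hz <= 0) stop("`c_hz` must be positive")
  if (field_strength_T <= 0) stop("`field_strength_T` must be positive")
  structure(list(c_hz = c_hz, field_strength_T = field_strength_T),
            class = "physics_constants")
}
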