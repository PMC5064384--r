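# Quantitative BOLD / perfusion parameter mapping.
#
# The mapping chain is: multi-gradient-echo -> T2*; multi-spin-echo -> T2
# (even echoes only); R2' = 1/T2* - 1/T2; DSC -> deltaR2*(t) -> rCBV
# (normalized to 1.5% in healthy white matter); rOEF = R2' / (c * rCBV).

# Vectorized log-linear mono-exponential fit over selected echoes, weighted
# by squared signal: taking the log turns additive noise of variance s^2
# into noise of variance (s/S)^2, so inverse-variance weights are S^2. This
# keeps the late, decayed echoes from dominating the fit error while
# remaining exact on noise-free exponentials.
# Returns list(s0, tau_ms, ok) per voxel; `ok` FALSE where any signal <= 0.
loglinear_fit <- function(sig_mat, te_ms) {
  ok <- rowSums(!is.finite(sig_mat) | sig_mat <= 0) == 0
  s <- pmax(sig_mat, .Machine$double.xmin)
  logs <- log(s)
  w <- s^2
  sw <- rowSums(w)
  st <- as.vector(w %*% te_ms)
  stt <- as.vector(w %*% te_ms^2)
  sl <- rowSums(w * logs)
  stl <- as.vector((w * logs) %*% te_ms)
  denom <- sw * stt - st^2
  slope <- (sw * stl - st * sl) / denom
  intercept <- (sl - slope * st) / sw
  tau <- -1 / slope          # ms; negative or infinite where no decay
  tau[!is.finite(tau)] <- Inf
  list(s0 = exp(intercept), tau_ms = tau, ok = ok)
}

#' Fit a T2* map from a multi-gradient-echo series
#'
#' Voxelwise mono-exponential fit S(TE) = S0 exp(-TE/T2*) by log-linear least
#' squares. Voxels with any non-positive signal, a non-decaying signal, or a
#' fitted T2* outside `bounds_ms` are marked invalid.
#'
#' @param series An [echo_series] of kind `"gradient_echo"` with >= 3 echoes.
#' @param bounds_ms Plausibility bounds for T2* in ms.
#' @return A [parameter_map] named `"T2star_ms"`.
#' @export
fit_t2star <- function(series, bounds_ms = c(1, 2000)) {
  stopifnot(inherits(series, "echo_series"))
  if (series$kind != "gradient_echo")
    stop("fit_t2star() requires a gradient-echo series")
  if (length(series$echo_times_ms) < 3L)
    stop("at least 3 echoes are required for the T2* fit")
  fit_relaxometry(series$signal, series$echo_times_ms, "T2star_ms", bounds_ms)
}

#' Fit a T2 map from a multi-spin-echo series
#'
#' Mono-exponential log-linear fit restricted to the even-numbered echoes
#' (2nd, 4th, ...), which suppresses the alternating stimulated-echo bias of
#' multi-echo turbo-spin-echo trains.
#'
#' @param series An [echo_series] of kind `"spin_echo"` with >= 4 echoes.
#' @param bounds_ms Plausibility bounds for T2 in ms.
#' @return A [parameter_map] named `"T2_ms"`.
#' @export
fit_t2 <- function(series, bounds_ms = c(1, 3000)) {
  stopifnot(inherits(series, "echo_series"))
  if (series$kind != "spin_echo")
    stop("fit_t2() requires a spin-echo series")
  n <- length(series$echo_times_ms)
  even <- seq(2L, n, by = 2L)
  if (n < 4L || length(even) < 2L)
    stop("at least 4 echoes (2 even echoes) are required for the T2 fit")
  fit_relaxometry(series$signal[, , , even, drop = FALSE],
                  series$echo_times_ms[even], "T2_ms", bounds_ms)
}

fit_relaxometry <- function(signal, te_ms, name, bounds_ms) {
  d <- dim(signal)
  fit <- loglinear_fit(flatten4d(signal), te_ms)
  ok <- fit$ok & is.finite(fit$tau_ms) &
    fit$tau_ms >= bounds_ms[1] & fit$tau_ms <= bounds_ms[2]
  vals <- fit$tau_ms
  vals[!ok] <- NA_real_
  parameter_map(array(vals, d[1:3]), name = name, units = "ms",
                valid_mask = array(ok, d[1:3]))
}

#' Reversible transverse relaxation rate R2'
#'
#' R2' = 1/T2* - 1/T2, in s^-1 (inputs are in ms, hence the factor 1000).
#' Negative values (possible with noisy fits, unphysical for the
#' susceptibility model) are clamped to 0; the number of clamped voxels is
#' attached as attribute `"n_clamped"` for quality control.
#'
#' @param t2star,t2 [parameter_map]s on the same grid, in ms.
#' @return A [parameter_map] named `"R2prime_s-1"`, valid where both inputs
#'   are valid.
#' @export
compute_r2prime <- function(t2star, t2) {
  stopifnot(inherits(t2star, "parameter_map"), inherits(t2, "parameter_map"))
  if (!identical(dim(t2star$values), dim(t2$values)))
    stop("T2* and T2 maps must share one grid")
  ok <- t2star$valid_mask & t2$valid_mask
  r2p <- 1000 / t2star$values - 1000 / t2$values
  n_clamped <- sum(r2p < 0 & ok, na.rm = TRUE)
  r2p[r2p < 0] <- 0
  r2p[!ok] <- NA_real_
  out <- parameter_map(r2p, name = "R2prime_s-1", units = "s^-1", valid_mask = ok)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Bolus-induced relaxation-rate change deltaR2*(t)
#'
#' Converts a DSC signal time course to the concentration-proportional
#' deltaR2*(t) = -(1000/TE) ln(S(t)/S0). S0 is the mean over the baseline
#' window, skipping the first two dynamics which have not reached the T1
#' steady state. Voxels with non-positive signal anywhere are invalid.
#'
#' @param dsc A [dynamic_series].
#' @return List with `delta_r2star` (4-D array, s^-1), `valid_mask` (3-D
#'   logical), `t_s` (time of each dynamic, s), and `n_baseline`.
#' @export
compute_delta_r2star <- function(dsc) {
  stopifnot(inherits(dsc, "dynamic_series"))
  d <- dim(dsc$signal)
  sig <- flatten4d(dsc$signal)
  base_idx <- seq(3L, dsc$n_baseline)
  if (length(base_idx) < 1L)
    stop("baseline window is empty after discarding saturation dynamics")
  s0 <- rowMeans(sig[, base_idx, drop = FALSE])
  ok <- rowSums(!is.finite(sig) | sig <= 0) == 0 & is.finite(s0) & s0 > 0
  ratio <- sig / pmax(s0, .Machine$double.xmin)  # row-wise recycling
  ratio[ratio <= 0] <- .Machine$double.xmin      # invalid rows masked below
  dr2s <- -(1000 / dsc$te_ms) * log(ratio)
  dr2s[!ok, ] <- NA_real_
  list(delta_r2star = array(dr2s, d),
       valid_mask = array(ok, d[1:3]),
       t_s = (seq_len(d[4]) - 1) * dsc$tr_ms / 1000,
       n_baseline = dsc$n_baseline)
}

#' Relative cerebral blood volume, normalized to healthy white matter
#'
#' rCBV is the trapezoidal time-integral of deltaR2*(t) over the post-baseline
#' dynamics, scaled so that the mean over a healthy white-matter reference
#' mask equals exactly 1.5 (percent blood volume).
#'
#' @param dr2s Output of [compute_delta_r2star()].
#' @param wm_mask Logical 3-D array marking healthy white matter.
#' @param wm_reference_percent White-matter blood volume assumed for
#'   normalization, in percent (default 1.5).
#' @return A [parameter_map] named `"rCBV_percent"`.
#' @export
compute_rcbv <- function(dr2s, wm_mask, wm_reference_percent = 1.5) {
  d <- dim(dr2s$delta_r2star)
  if (!identical(dim(wm_mask), d[1:3])) stop("WM mask shape mismatch")
  post <- seq(dr2s$n_baseline + 1L, d[4])
  curves <- flatten4d(dr2s$delta_r2star)[, post, drop = FALSE]
  t_post <- dr2s$t_s[post]
  # trapezoid with uniform spacing, vectorized across voxels
  w <- diff(t_post)
  weights <- c(w / 2, 0) + c(0, w / 2)
  raw <- as.vector(curves %*% weights)
  ok <- as.vector(dr2s$valid_mask) & is.finite(raw)
  wm_sel <- as.vector(wm_mask) & ok
  if (!any(wm_sel)) stop("white-matter reference mask is empty or fully invalid")
  wm_mean <- mean(raw[wm_sel])
  if (!is.finite(wm_mean) || wm_mean <= 0)
    stop("white-matter mean deltaR2* integral is non-positive; cannot normalize")
  vals <- wm_reference_percent * raw / wm_mean
  ok <- ok & vals >= 0   # negative integrals (noise) are excluded, not clamped
  vals[!ok] <- NA_real_
  parameter_map(array(vals, d[1:3]), name = "rCBV_percent", units = "percent",
                valid_mask = array(ok, d[1:3]))
}

#' Relative oxygen extraction fraction
#'
#' rOEF = R2' / (c * rCBV) with rCBV entered as a blood-volume fraction
#' (percent / 100), giving a dimensionless value in a physiological 0-1 range
#' for c = 317 s^-1 at 3 T. Voxels where the blood-volume fraction falls
#' below `cbv_floor` are marked invalid rather than divided.
#'
#' @param r2prime [parameter_map] in s^-1.
#' @param rcbv [parameter_map] in percent.
#' @param constants A [physics_constants] object.
#' @param cbv_floor Minimum blood-volume fraction for a valid rOEF (default 1e-4).
#' @return A [parameter_map] named `"rOEF"`.
#' @export
compute_roef <- function(r2prime, rcbv, constants = physics_constants(),
                         cbv_floor = 1e-4) {
  stopifnot(inherits(r2prime, "parameter_map"), inherits(rcbv, "parameter_map"),
            inherits(constants, "physics_constants"))
  if (!identical(dim(r2prime$values), dim(rcbv$values)))
    stop("R2' and rCBV maps must share one grid")
  if (constants$c_hz <= 0) stop("`c_hz` must be positive")
  frac <- rcbv$values / 100
  ok <- r2prime$valid_mask & rcbv$valid_mask & frac >= cbv_floor
  vals <- r2prime$values / (constants$c_hz * frac)
  vals[!ok] <- NA_real_
  parameter_map(vals, name = "rOEF", units = "", valid_mask = ok)
}
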