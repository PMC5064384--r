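# Synthetic multimodal-MRI cohort generator.
#
# Each subject is a digital phantom of nested ellipsoidal tissue classes
# (healthy WM / GM, FLAIR-abnormal edema, solid T2-visible tumor, enhancing
# core, high-OEF rim) with voxelwise ground-truth T2*, T2, blood-volume
# fraction and oxygen extraction fraction. Raw multi-gradient-echo,
# multi-spin-echo, DSC and anatomical volumes are simulated from that truth,
# so every downstream fit can be checked against a known answer. The
# between-grade signal is carried by three per-subject parameters calibrated
# to target Cohen's d values: contrast-enhanced T1w heterogeneity, blood
# volume heterogeneity, and the oxygen extraction level of the tumor rim.

TISSUE_CLASSES <- c(background = 0L, wm = 1L, gm = 2L, edema = 3L,
                    t2t = 4L, cet = 5L, rim = 6L)

# class-wise ground-truth tissue parameters (healthy rim OEF is per-subject)
TISSUE_TABLE <- data.frame(
  class  = c("wm", "gm", "edema", "t2t", "cet", "rim"),
  oef    = c(0.40, 0.42, 0.28, 0.38, 0.35, NA),
  cbv    = c(0.015, 0.025, 0.020, 0.028, 0.035, 0.025),
  t2_ms  = c(70, 85, 110, 120, 95, 90),
  row.names = c("wm", "gm", "edema", "t2t", "cet", "rim")
)

# anatomical contrast model: class means (arb. units) and acquisition noise SD
CONTRAST_TABLE <- list(
  t1ce   = list(sd = 50, mean = c(wm = 1000, gm = 990, edema = 1000,
                                  t2t = 1010, cet = 1150, rim = 1000)),
  flair  = list(sd = 30, mean = c(wm = 500, gm = 510, edema = 660,
                                  t2t = 680, cet = 670, rim = 660)),
  t2     = list(sd = 40, mean = c(wm = 800, gm = 820, edema = 860,
                                  t2t = 970, cet = 960, rim = 850)),
  t2star = list(sd = 35, mean = c(wm = 600, gm = 610, edema = 640,
                                  t2t = 645, cet = 600, rim = 520))
)

# calibration of the grade-carrying per-subject parameters: the between-grade
# mean gap is d_target * sd * kappa, where kappa is a fixed constant absorbing
# the variance the image-level statistic adds on top of the parameter itself
PLANTED_FEATURES <- list(
  t1ce__flair__sd      = list(param = "t1ce_het", base = 1.00, sd = 0.35,
                              kappa = 1.19, trunc = c(0.10, Inf)),
  cbv__flair__sd       = list(param = "cbv_het", base = 0.30, sd = 0.12,
                              kappa = 1.07, trunc = c(0.02, Inf)),
  roef__high_roef__max = list(param = "rim_oef", base = 0.70, sd = 0.06,
                              kappa = 1.45, trunc = c(0.62, 0.92))
)

#' Simulation configuration for the synthetic cohort
#'
#' Defines the study conditions the generator emulates: acquisition timing of
#' the multi-echo and DSC protocols, cohort size and grade balance, noise
#' level, and the target between-grade effect sizes of the three planted
#' discriminative features.
#'
#' @param grid_shape Integer 3-vector, voxels per axis (>= 16 each).
#' @param voxel_size_mm Numeric 3-vector, voxel edge lengths in mm.
#' @param n_subjects Number of subjects (>= 2).
#' @param class_balance Fraction of grade-IV subjects, in (0, 1).
#' @param snr Magnitude signal-to-noise ratio of the echo and DSC series
#'   (reference signal 1000); `Inf` for noise-free data.
#' @param effect_sizes Named vector of target Cohen's d values between grade
#'   IV and grade II/III for the planted features; names must be a subset of
#'   `t1ce__flair__sd`, `cbv__flair__sd`, `roef__high_roef__max`.
#' @param cet_empty_prob Probability that a grade II/III subject has no
#'   contrast-enhancing tumor at all (forces the empty-VOI code path).
#' @param gre_echo_times_ms Gradient-echo TEs (default 12 echoes, 5 ms step).
#' @param tse_echo_times_ms Spin-echo TEs (default 8 echoes, 16 ms step).
#' @param odd_echo_bias Multiplicative bias applied to odd spin echoes
#'   (stimulated-echo contamination); 1 = unbiased.
#' @param dsc_tr_ms,dsc_te_ms,dsc_n_dynamics,dsc_n_baseline DSC timing.
#' @param bolus_shape,bolus_scale_s Gamma-variate bolus shape parameter and
#'   time scale (s); bolus arrival is at the end of the baseline window.
#' @param bolus_strength Time-integral of deltaR2* per unit blood-volume
#'   fraction (s^-1 s).
#' @param seed Master seed; fully determines the cohort.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(24L, 24L, 24L),
                       voxel_size_mm = c(2, 2, 3),
                       n_subjects = 37L,
                       class_balance = 27 / 37,
                       snr = 150,
                       effect_sizes = c(t1ce__flair__sd = 2.798253,
                                        cbv__flair__sd = 0.9144929,
                                        roef__high_roef__max = 0.839689),
                       cet_empty_prob = 0.05,
                       gre_echo_times_ms = 5 * (1:12),
                       tse_echo_times_ms = 16 * (1:8),
                       odd_echo_bias = 1.0,
                       dsc_tr_ms = 1500, dsc_te_ms = 30,
                       dsc_n_dynamics = 60L, dsc_n_baseline = 10L,
                       bolus_shape = 3, bolus_scale_s = 4,
                       bolus_strength = 12000,
                       seed = 1L) {
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("`grid_shape` must have 3 axes of at least 16 voxels each")
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("`n_subjects` must be at least 2")
  if (class_balance <= 0 || class_balance >= 1)
    stop("`class_balance` must lie strictly between 0 and 1")
  if (!is.infinite(snr) && snr <= 0) stop("`snr` must be positive (or Inf)")
  if (length(effect_sizes) > 0) {
    bad <- setdiff(names(effect_sizes), names(PLANTED_FEATURES))
    if (length(bad))
      stop("unknown effect-size feature(s): ", paste(bad, collapse = ", "))
  }
  if (dsc_n_dynamics < 20L || dsc_n_baseline < 5L)
    stop("DSC needs >= 20 dynamics with >= 5 baseline dynamics")
  structure(list(
    grid_shape = as.integer(grid_shape), voxel_size_mm = voxel_size_mm,
    n_subjects = n_subjects, class_balance = class_balance, snr = snr,
    effect_sizes = effect_sizes, cet_empty_prob = cet_empty_prob,
    gre_echo_times_ms = gre_echo_times_ms,
    tse_echo_times_ms = tse_echo_times_ms,
    odd_echo_bias = odd_echo_bias,
    dsc_tr_ms = dsc_tr_ms, dsc_te_ms = dsc_te_ms,
    dsc_n_dynamics = as.integer(dsc_n_dynamics),
    dsc_n_baseline = as.integer(dsc_n_baseline),
    bolus_shape = bolus_shape, bolus_scale_s = bolus_scale_s,
    bolus_strength = bolus_strength,
    seed = as.integer(seed)), class = "sim_config")
}

ellipsoid_mask <- function(grid_shape, center, semi_axes) {
  ix <- (seq_len(grid_shape[1]) - center[1]) / semi_axes[1]
  iy <- (seq_len(grid_shape[2]) - center[2]) / semi_axes[2]
  iz <- (seq_len(grid_shape[3]) - center[3]) / semi_axes[3]
  outer(outer(ix^2, iy^2, "+"), iz^2, "+") <= 1
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Draw the grade-carrying per-subject parameters. Grade IV gets the base
# value plus d * sd * kappa; grade II/III gets the base value.
draw_subject_params <- function(config, grade) {
  p <- list()
  for (feat in names(PLANTED_FEATURES)) {
    cal <- PLANTED_FEATURES[[feat]]
    d <- unname(config$effect_sizes[feat])
    gap <- if (!is.na(d) && grade == "IV") d * cal$sd * cal$kappa else 0
    p[[cal$param]] <- rnorm_trunc(1, cal$base + gap, cal$sd,
                                  cal$trunc[1], cal$trunc[2])
  }
  # grade-independent physiological state, varying between subjects: the
  # baseline oxygenation of edema and rim and the amplitude of voxel-level
  # metabolic jitter. These scramble the composition of the threshold-
  # defined high-rOEF VOI and dominate VOI-level mean/SD statistics of the
  # oxygenation maps, leaving the focal hotspot peak as the clean grade
  # readout (hypoxia in practice is focal, not a uniform shell).
  p$edema_oef_shift <- stats::runif(1, -0.05, 0.02)
  p$rim_base_oef <- stats::rnorm(1, 0.54, 0.03)
  p$oef_jit_amp <- stats::runif(1, 0.02, 0.04)
  p$fm_coupling <- stats::runif(1, 0.3, 1.0)
  p$rim_cbv_jit <- stats::runif(1, 0.05, 0.15)
  p$cet_present <- grade == "IV" || stats::runif(1) >= config$cet_empty_prob
  p
}

#' Generate one subject's ground-truth tissue phantom
#'
#' Builds the tissue-class label volume (nested ellipsoids) and the
#' voxelwise ground-truth maps: T2*, T2, blood-volume fraction and oxygen
#' extraction fraction. T2* is derived from OEF, blood volume and T2 through
#' the static-dephasing relation R2' = OEF * c * CBV, so the ground truth is
#' self-consistent with the rOEF model used downstream.
#'
#' @param config A [sim_config].
#' @param grade `"IV"` or `"II_III"`.
#' @param subject_seed Integer seed for this subject's random draws.
#' @param constants [physics_constants] used in the OEF -> R2' relation.
#' @return An object of class `tissue_phantom` with elements `label_volume`,
#'   `true_t2star_ms`, `true_t2_ms`, `true_cbv_fraction`, `true_oef`,
#'   `true_contrasts` (noise-free anatomical volumes), `voxel_size_mm`,
#'   `grade` and `params`.
#' @export
make_phantom <- function(config, grade, subject_seed,
                         constants = physics_constants()) {
  stopifnot(inherits(config, "sim_config"))
  if (!grade %in% c("IV", "II_III"))
    stop("`grade` must be \"IV\" or \"II_III\"")
  gs <- config$grid_shape
  withr::with_seed(as.integer(subject_seed), {
    params <- draw_subject_params(config, grade)

    center <- (gs + 1) / 2
    brain_semi <- 0.42 * gs
    brain <- ellipsoid_mask(gs, center, brain_semi)
    wm <- ellipsoid_mask(gs, center, 0.70 * brain_semi)

    tumor_center <- center + stats::runif(3, -0.08, 0.08) * gs
    rf <- stats::runif(1, 0.18, 0.26) * min(gs)
    flair_m <- ellipsoid_mask(gs, tumor_center, rep(rf, 3)) & brain
    rim_m <- flair_m & !ellipsoid_mask(gs, tumor_center, rep(0.88 * rf, 3))
    t2t_m <- ellipsoid_mask(gs, tumor_center, rep(0.55 * rf, 3)) & flair_m
    cet_m <- if (params$cet_present)
      ellipsoid_mask(gs, tumor_center, rep(0.28 * rf, 3)) & t2t_m
    else array(FALSE, gs)
    t2t_m <- t2t_m & !cet_m & !rim_m

    # healthy tissue keeps a 1-voxel margin from the tumor
    margin <- ellipsoid_mask(gs, tumor_center, rep(rf + 1, 3))
    labels <- array(TISSUE_CLASSES[["background"]], gs)
    labels[brain & !margin & !wm] <- TISSUE_CLASSES[["gm"]]
    labels[wm & !margin] <- TISSUE_CLASSES[["wm"]]
    labels[flair_m] <- TISSUE_CLASSES[["edema"]]
    labels[rim_m] <- TISSUE_CLASSES[["rim"]]
    labels[t2t_m] <- TISSUE_CLASSES[["t2t"]]
    labels[cet_m] <- TISSUE_CLASSES[["cet"]]

    inside <- labels > 0
    tumor <- labels >= TISSUE_CLASSES[["edema"]]
    edema_sel <- labels == TISSUE_CLASSES[["edema"]]
    rim_sel <- labels == TISSUE_CLASSES[["rim"]]
    solid_sel <- tumor & !edema_sel & !rim_sel
    gm_sel <- labels == TISSUE_CLASSES[["gm"]]

    t2 <- array(NA_real_, gs)
    cbv <- array(NA_real_, gs)
    oef_level <- array(NA_real_, gs)
    for (cls in rownames(TISSUE_TABLE)) {
      sel <- labels == TISSUE_CLASSES[[cls]]
      if (!any(sel)) next
      t2[sel] <- TISSUE_TABLE[cls, "t2_ms"]
      cbv[sel] <- TISSUE_TABLE[cls, "cbv"]
      oef_level[sel] <- if (cls == "rim")
                          params$rim_base_oef +
                            stats::runif(sum(sel), -0.09, 0.09)
                        else if (cls == "edema")
                          TISSUE_TABLE[cls, "oef"] + params$edema_oef_shift
                        else TISSUE_TABLE[cls, "oef"]
    }

    # Blood-volume heterogeneity. The grade-dependent component lives in the
    # infiltrative edema compartment; solid tumor and enhancing core carry a
    # fixed moderate heterogeneity of their own so sub-VOI statistics do not
    # simply duplicate the FLAIR-level signal, and the rim is kept near
    # vascularly uniform (its rOEF is a level signal). Truncation keeps
    # tumor blood volume away from zero: near-necrotic voxels are outside
    # the VOIs this pipeline emulates. The WM reference stays exactly at its
    # nominal value.
    e_cbv <- array(0, gs)
    e_cbv[edema_sel] <- rnorm_trunc(sum(edema_sel), 0, params$cbv_het, -0.6, 0.6)
    e_cbv[solid_sel] <- rnorm_trunc(sum(solid_sel), 0, 0.25, -0.6, 0.6)
    e_cbv[rim_sel] <- rnorm_trunc(sum(rim_sel), 0, params$rim_cbv_jit, -0.4, 0.4)
    e_cbv[gm_sel] <- rnorm_trunc(sum(gm_sel), 0, 0.05, -0.3, 0.3)
    cbv <- cbv * (1 + e_cbv)

    # Voxel-level oxygen extraction: flow-metabolism coupling makes OEF vary
    # inversely with the local blood-volume excess, with a coupling strength
    # that is itself a per-subject physiological state, plus an independent
    # metabolic jitter whose amplitude is a per-subject state; healthy
    # tissue and rim are tighter.
    oef_jit <- array(0.02, gs)
    oef_jit[edema_sel | solid_sel] <- params$oef_jit_amp
    oef <- oef_level * (1 - params$fm_coupling * e_cbv)
    oef <- pmin(pmax(oef + stats::rnorm(length(oef), 0, 1) * oef_jit, 0.05), 0.95)
    # the hypoxic hotspot: a small focal patch of the rim whose peak oxygen
    # extraction carries the grade signal. The hotspot is hypoxic because it
    # is hypoperfused: its blood volume is scaled down so that R2' stays at
    # the rim-typical level and only the extraction fraction is elevated.
    rim_idx <- which(rim_sel)
    if (length(rim_idx) >= 2L) {
      hs <- sample(rim_idx, max(2L, ceiling(0.06 * length(rim_idx))))
      oef[hs] <- rnorm_trunc(length(hs), params$rim_oef, 0.01, 0.05, 0.95)
      # the excess extraction is realized half as reduced perfusion and half
      # as elevated R2', so neither map carries the full hotspot signature
      excess <- sqrt(oef[hs] / params$rim_base_oef)
      cbv[hs] <- TISSUE_TABLE["rim", "cbv"] / excess
    }
    oef[!inside] <- NA_real_

    # every tumor contains a few traversing macro-vessels (very high blood
    # volume, strong enhancement) and hemosiderin/calcification voxels (very
    # low blood volume, dark enhancement). They are grade-independent and
    # pin the within-VOI extrema of the T1ce, CBV and R2' maps in all
    # subjects alike, as such physical outliers do in practice.
    ed_idx <- which(edema_sel)
    ves_hi <- ves_lo <- integer(0)
    if (length(ed_idx) >= 4L) {
      n_ves <- max(2L, round(0.015 * length(ed_idx) / 2) * 2L)
      ves <- sample(ed_idx, min(n_ves, length(ed_idx)))
      half <- length(ves) %/% 2L
      ves_hi <- ves[seq_len(half)]
      ves_lo <- ves[(half + 1L):length(ves)]
      cbv[ves_hi] <- 0.09
      cbv[ves_lo] <- 0.006
      oef[c(ves_hi, ves_lo)] <- 0.30
    }

    r2prime <- oef * constants$c_hz * cbv            # s^-1
    t2star <- 1000 / (r2prime + 1000 / t2)           # ms; always <= t2

    contrasts <- lapply(names(CONTRAST_TABLE), function(cn) {
      spec <- CONTRAST_TABLE[[cn]]
      img <- array(0, gs)
      for (cls in names(spec$mean)) {
        sel <- labels == TISSUE_CLASSES[[cls]]
        img[sel] <- spec$mean[[cls]]
      }
      if (cn == "t1ce") {
        # grade-dependent heterogeneity in the edema compartment only
        img[edema_sel] <- img[edema_sel] +
          stats::rnorm(sum(edema_sel), 0, spec$sd * params$t1ce_het)
        img[solid_sel] <- img[solid_sel] +
          stats::rnorm(sum(solid_sel), 0, spec$sd)
        img[ves_hi] <- spec$mean[["edema"]] + 9 * spec$sd
        img[ves_lo] <- spec$mean[["edema"]] - 9 * spec$sd
      } else {
        img[tumor] <- img[tumor] + stats::rnorm(sum(tumor), 0, spec$sd * 0.5)
      }
      img
    })
    names(contrasts) <- names(CONTRAST_TABLE)

    structure(list(label_volume = labels,
                   true_t2star_ms = t2star, true_t2_ms = t2,
                   true_cbv_fraction = cbv, true_oef = oef,
                   true_contrasts = contrasts,
                   voxel_size_mm = config$voxel_size_mm,
                   grade = grade, params = params,
                   brain_mask = inside),
              class = "tissue_phantom")
  })
}

#' Tissue-class masks of a phantom
#'
#' Ground-truth VOI masks in the layout the feature pipeline consumes.
#'
#' @param phantom A [make_phantom()] result.
#' @return Named list of logical 3-D arrays: `flair` (all tumor classes),
#'   `t2t`, `cet`, `healthy_brain`, `healthy_wm`.
#' @export
phantom_masks <- function(phantom) {
  lab <- phantom$label_volume
  list(flair = lab >= TISSUE_CLASSES[["edema"]],
       t2t = lab == TISSUE_CLASSES[["t2t"]],
       cet = lab == TISSUE_CLASSES[["cet"]],
       healthy_brain = lab == TISSUE_CLASSES[["wm"]] | lab == TISSUE_CLASSES[["gm"]],
       healthy_wm = lab == TISSUE_CLASSES[["wm"]])
}

add_magnitude_noise <- function(signal, snr, s_ref = 1000) {
  if (is.infinite(snr)) return(signal)
  signal + stats::rnorm(length(signal), 0, s_ref / snr)
}

#' Simulate a multi-gradient-echo acquisition
#'
#' Voxelwise S(TE) = S0 exp(-TE / T2*) with S0 = 1000 inside the head and 0
#' outside, plus zero-mean Gaussian magnitude noise of SD 1000 / snr.
#'
#' @param phantom A [tissue_phantom][make_phantom].
#' @param echo_times_ms Echo times in ms, strictly increasing, positive.
#' @param snr Signal-to-noise ratio; `Inf` for noise-free.
#' @param seed Integer seed for the noise realization.
#' @return An [echo_series] of kind `"gradient_echo"`.
#' @export
simulate_gradient_echo <- function(phantom, echo_times_ms, snr = Inf, seed = 1L) {
  simulate_decay(phantom, phantom$true_t2star_ms, echo_times_ms, snr, seed,
                 kind = "gradient_echo", odd_echo_bias = 1)
}

#' Simulate a multi-spin-echo acquisition
#'
#' As [simulate_gradient_echo()] but decaying with the ground-truth T2, and
#' with a configurable multiplicative bias on the odd-numbered echoes
#' emulating stimulated-echo contamination (the reason T2 fitting is
#' restricted to even echoes).
#'
#' @inheritParams simulate_gradient_echo
#' @param odd_echo_bias Factor applied to echoes 1, 3, 5, ...; 1 = none.
#' @return An [echo_series] of kind `"spin_echo"`.
#' @export
simulate_spin_echo <- function(phantom, echo_times_ms, snr = Inf, seed = 1L,
                               odd_echo_bias = 1.0) {
  simulate_decay(phantom, phantom$true_t2_ms, echo_times_ms, snr, seed,
                 kind = "spin_echo", odd_echo_bias = odd_echo_bias)
}

simulate_decay <- function(phantom, tau_ms, echo_times_ms, snr, seed, kind,
                           odd_echo_bias) {
  if (any(echo_times_ms <= 0)) stop("echo times must be positive")
  s0 <- ifelse(phantom$label_volume > 0, 1000, 0)
  rate <- ifelse(is.finite(tau_ms) & tau_ms > 0, 1 / tau_ms, 0)
  withr::with_seed(as.integer(seed), {
    echoes <- lapply(seq_along(echo_times_ms), function(i) {
      s <- s0 * exp(-echo_times_ms[i] * rate)
      if (i %% 2L == 1L) s <- s * odd_echo_bias
      add_magnitude_noise(s, snr)
    })
    echo_series(stack4d(echoes), echo_times_ms, kind = kind)
  })
}

#' Simulate a DSC bolus-tracking acquisition
#'
#' The bolus induces deltaR2*(t) = k * CBV * g(t), where g is a unit-area
#' gamma-variate starting at the end of the baseline window and k is
#' `config$bolus_strength`. The emitted signal is
#' S(t) = S0 exp(-TE/1000 * deltaR2*(t)) plus magnitude noise; the time
#' integral of deltaR2* is therefore exactly proportional to the ground-truth
#' blood volume.
#'
#' @param phantom A [tissue_phantom][make_phantom].
#' @param config A [sim_config] supplying timing, bolus and noise settings.
#' @param seed Integer seed for the noise realization.
#' @return A [dynamic_series].
#' @export
simulate_dsc <- function(phantom, config, seed = 1L) {
  if (config$dsc_te_ms <= 0) stop("`dsc_te_ms` must be positive")
  n <- config$dsc_n_dynamics
  t_s <- (seq_len(n) - 1) * config$dsc_tr_ms / 1000
  t0 <- config$dsc_n_baseline * config$dsc_tr_ms / 1000
  g <- ifelse(t_s > t0,
              (t_s - t0)^(config$bolus_shape - 1) *
                exp(-(t_s - t0) / config$bolus_scale_s), 0)
  g <- g / pracma::trapz(t_s, g)       # unit area on the sampled grid
  s0 <- ifelse(phantom$label_volume > 0, 1000, 0)
  amp <- config$bolus_strength * ifelse(is.na(phantom$true_cbv_fraction), 0,
                                        phantom$true_cbv_fraction)
  withr::with_seed(as.integer(seed), {
    dyn <- lapply(seq_len(n), function(i) {
      s <- s0 * exp(-config$dsc_te_ms / 1000 * amp * g[i])
      add_magnitude_noise(s, config$snr)
    })
    dynamic_series(stack4d(dyn), tr_ms = config$dsc_tr_ms,
                   te_ms = config$dsc_te_ms,
                   n_baseline = config$dsc_n_baseline)
  })
}

simulate_anatomical <- function(phantom, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    out <- lapply(names(CONTRAST_TABLE), function(cn) {
      img <- phantom$true_contrasts[[cn]] +
        stats::rnorm(length(phantom$label_volume), 0, CONTRAST_TABLE[[cn]]$sd)
      img[phantom$label_volume == 0] <- 0
      img
    })
    names(out) <- names(CONTRAST_TABLE)
    out
  })
}

#' Generate one complete synthetic subject
#'
#' @param config A [sim_config].
#' @param grade `"IV"` or `"II_III"`.
#' @param subject_seed Integer seed; every volume of the subject is a pure
#'   function of (config, grade, subject_seed).
#' @param subject_id Identifier string.
#' @return A `subject_record` list: `phantom`, `gre` / `tse` [echo_series],
#'   `dsc` [dynamic_series], `anat` (4 anatomical volumes), `masks`
#'   (ground-truth VOIs), `grade`, `subject_id`.
#' @export
make_subject <- function(config, grade, subject_seed,
                         subject_id = sprintf("sub-%03d", subject_seed %% 1000L)) {
  phantom <- make_phantom(config, grade, derive_seed(subject_seed, 1L))
  structure(list(
    subject_id = subject_id, grade = grade, phantom = phantom,
    gre = simulate_gradient_echo(phantom, config$gre_echo_times_ms,
                                 config$snr, derive_seed(subject_seed, 2L)),
    tse = simulate_spin_echo(phantom, config$tse_echo_times_ms, config$snr,
                             derive_seed(subject_seed, 3L),
                             odd_echo_bias = config$odd_echo_bias),
    dsc = simulate_dsc(phantom, config, derive_seed(subject_seed, 4L)),
    anat = simulate_anatomical(phantom, derive_seed(subject_seed, 5L)),
    masks = phantom_masks(phantom)), class = "subject_record")
}

cohort_grades <- function(config) {
  n <- config$n_subjects
  n_iv <- max(1L, min(n - 1L, as.integer(round(config$class_balance * n))))
  c(rep("IV", n_iv), rep("II_III", n - n_iv))
}

#' Generate a full synthetic cohort
#'
#' Materializes every subject's raw volumes in memory (about 9 MB per
#' subject at the default grid); for feature extraction over large cohorts
#' prefer the streaming [simulate_features()].
#'
#' @param config A [sim_config]; `config$seed` determines everything.
#' @return A `cohort` list with `subjects` (list of subject records) and
#'   `labels` (data.frame with `subject_id`, `grade`).
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  grades <- cohort_grades(config)
  subjects <- lapply(seq_len(n), function(i) {
    make_subject(config, grades[i], derive_seed(config$seed, 100L + i),
                 subject_id = sprintf("sub-%03d", i))
  })
  labels <- data.frame(subject_id = vapply(subjects, `[[`, "", "subject_id"),
                       grade = grades, stringsAsFactors = FALSE)
  structure(list(subjects = subjects, labels = labels, config = config),
            class = "cohort")
}
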