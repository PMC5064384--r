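# VOI construction and first-order feature extraction.
#
# Anatomical contrasts are normalized to healthy-brain standard scores; four
# tumor VOIs (comprehensive FLAIR-hyperintense tumor, solid T2-visible tumor,
# contrast-enhancing tumor, high-rOEF areas) are built by thresholding and
# set operations, or taken verbatim from supplied masks; 4 statistics + the
# volume are extracted per map and VOI, giving 7 * 4 * 4 + 4 = 116 features.

FEATURE_MAPS <- c("t1ce", "flair", "t2", "t2star", "r2prime", "roef", "cbv")
FEATURE_VOIS <- c("flair", "t2t", "cet", "high_roef")
FEATURE_STATS <- c("mean", "sd", "min", "max")

#' Canonical feature names
#'
#' The fixed order of the 116 per-subject features: for each map (z-scored
#' T1ce, FLAIR, T2, T2* plus R2', rOEF, CBV), for each VOI (FLAIR, T2T, CET,
#' high-rOEF), the mean, SD, min and max, followed by the four VOI volumes.
#'
#' @return Character vector of length 116.
#' @export
feature_names <- function() {
  stats_part <- as.vector(vapply(FEATURE_MAPS, function(m)
    vapply(FEATURE_VOIS, function(v)
      paste(m, v, FEATURE_STATS, sep = "__"), character(4)), character(16)))
  c(stats_part, paste0("volume__", FEATURE_VOIS))
}

#' Standard-score normalization against healthy brain
#'
#' Rescales an image so that the healthy, non-tumorous brain has mean 0 and
#' standard deviation 1: z = (x - mean_healthy) / sd_healthy.
#'
#' @param image A [parameter_map] or 3-D array.
#' @param healthy_mask Logical 3-D array with >= 2 voxels of nonzero spread.
#' @return A [parameter_map] with name prefixed `"z_"`.
#' @export
zscore_normalize <- function(image, healthy_mask) {
  if (!inherits(image, "parameter_map"))
    image <- parameter_map(image, name = "image")
  sel <- healthy_mask & image$valid_mask
  if (sum(sel) < 2L) stop("healthy mask must contain at least 2 valid voxels")
  m <- mean(image$values[sel])
  s <- stats::sd(image$values[sel])
  if (!is.finite(s) || s == 0)
    stop("healthy-tissue standard deviation is zero; cannot normalize")
  parameter_map((image$values - m) / s, name = paste0("z_", image$name),
                units = "z", valid_mask = image$valid_mask)
}

#' Construct the tumor VOI set
#'
#' Builds the four tumor VOIs. Supplied masks (the equivalent of manually
#' edited VOIs) are used verbatim where given; otherwise deterministic
#' z-score threshold rules apply:
#' FLAIR = z(FLAIR) > `flair_z` inside the brain; CET = z(T1ce) > `cet_z`
#' inside FLAIR; T2T = z(T2) > `t2t_z` inside FLAIR minus CET (CET takes
#' precedence, keeping the two mutually exclusive). The high-rOEF VOI is
#' always computed from the rOEF map: rOEF greater than mean + 1 SD of
#' healthy tissue, by default restricted to the FLAIR VOI (the automated
#' stand-in for the manual exclusion of artifacts outside the tumor).
#'
#' @param maps Named list of [parameter_map]s; needs `roef`, plus `z_flair`,
#'   `z_t1ce`, `z_t2` for any VOI not supplied.
#' @param supplied Named list of logical masks taken verbatim: any of
#'   `flair`, `t2t`, `cet`; must include `healthy_brain` and `healthy_wm`.
#' @param thresholds Named list of z cutoffs `flair_z`, `cet_z`, `t2t_z`
#'   (default 2 each).
#' @param high_roef_within_flair Restrict the high-rOEF VOI to FLAIR
#'   (default TRUE).
#' @return An object of class `voi_set`: `masks` (named logical arrays
#'   `flair`, `t2t`, `cet`, `high_roef`, `healthy_brain`, `healthy_wm`) and
#'   `roef_threshold`.
#' @export
define_vois <- function(maps, supplied = list(),
                        thresholds = list(flair_z = 2, cet_z = 2, t2t_z = 2),
                        high_roef_within_flair = TRUE) {
  hb <- supplied$healthy_brain
  if (is.null(hb)) stop("a `healthy_brain` mask must be supplied")
  hw <- supplied$healthy_wm %||% hb
  gs <- dim(hb)

  flair <- supplied$flair
  if (is.null(flair)) {
    z <- maps$z_flair
    if (is.null(z)) stop("need `z_flair` map or a supplied FLAIR mask")
    flair <- z$values > thresholds$flair_z & z$valid_mask & !hb
  }
  if (!any(flair)) stop("FLAIR VOI is empty: no tumor to featurize")

  cet <- supplied$cet
  if (is.null(cet)) {
    z <- maps$z_t1ce
    if (is.null(z)) stop("need `z_t1ce` map or a supplied CET mask")
    cet <- z$values > thresholds$cet_z & z$valid_mask & flair
  }
  cet <- cet & flair

  t2t <- supplied$t2t
  if (is.null(t2t)) {
    z <- maps$z_t2
    if (is.null(z)) stop("need `z_t2` map or a supplied T2T mask")
    t2t <- z$values > thresholds$t2t_z & z$valid_mask & flair
  }
  t2t <- t2t & flair & !cet   # CET precedence: mutually exclusive inside FLAIR

  roef <- maps$roef
  if (is.null(roef)) stop("an `roef` map is required for the high-rOEF VOI")
  healthy_vals <- roef$values[hb & roef$valid_mask]
  if (length(healthy_vals) < 2L)
    stop("too few valid healthy voxels for the rOEF threshold")
  thr <- mean(healthy_vals) + stats::sd(healthy_vals)
  high_roef <- roef$values > thr & roef$valid_mask
  high_roef[is.na(high_roef)] <- FALSE
  if (high_roef_within_flair) high_roef <- high_roef & flair

  masks <- list(flair = flair, t2t = t2t, cet = cet, high_roef = high_roef,
                healthy_brain = hb & !flair, healthy_wm = hw & hb & !flair)
  masks <- lapply(masks, function(m) array(as.logical(m), gs))
  out <- structure(list(masks = masks, roef_threshold = thr), class = "voi_set")
  validate_voi_set(out)
  out
}

validate_voi_set <- function(v) {
  m <- v$masks
  if (any(m$cet & m$t2t)) stop("invariant violated: CET and T2T overlap")
  if (any(m$cet & !m$flair)) stop("invariant violated: CET outside FLAIR")
  if (any(m$t2t & !m$flair)) stop("invariant violated: T2T outside FLAIR")
  if (any(m$healthy_brain & m$flair))
    stop("invariant violated: healthy brain overlaps FLAIR")
  if (any(m$healthy_wm & !m$healthy_brain))
    stop("invariant violated: healthy WM outside healthy brain")
  invisible(v)
}

voi_stats <- function(values, valid, voi) {
  sel <- voi & valid
  n <- sum(sel)
  if (n == 0L) return(c(mean = 0, sd = 0, min = 0, max = 0))
  x <- values[sel]
  c(mean = mean(x), sd = if (n > 1L) stats::sd(x) else 0,
    min = min(x), max = max(x))
}

#' Extract the 116-entry feature vector of one subject
#'
#' For each of the 7 maps and 4 tumor VOIs, the mean, standard deviation
#' (n - 1 denominator), minimum and maximum over valid voxels, plus the
#' volume of each VOI in ml. Empty VOIs yield zeros for their statistics and
#' volume (with a warning), keeping the feature matrix complete.
#'
#' @param maps Named list of exactly the maps in [feature_names()] order:
#'   `t1ce`, `flair`, `t2`, `t2star` (z-scored), `r2prime`, `roef`, `cbv`.
#' @param vois A [voi_set][define_vois].
#' @param voxel_size_mm Voxel edge lengths in mm (for volumes).
#' @return Named numeric vector of length 116 in canonical order.
#' @export
extract_features <- function(maps, vois, voxel_size_mm = c(2, 2, 3)) {
  if (!all(FEATURE_MAPS %in% names(maps)))
    stop("`maps` must contain: ", paste(FEATURE_MAPS, collapse = ", "))
  stopifnot(inherits(vois, "voi_set"))
  empties <- FEATURE_VOIS[vapply(FEATURE_VOIS, function(v)
    !any(vois$masks[[v]]), logical(1))]
  if (length(empties))
    warning("empty VOI(s): ", paste(empties, collapse = ", "),
            "; their features are set to 0", call. = FALSE)
  out <- numeric(0)
  for (mp in FEATURE_MAPS) {
    pm <- maps[[mp]]
    for (voi in FEATURE_VOIS) {
      st <- voi_stats(pm$values, pm$valid_mask, vois$masks[[voi]])
      names(st) <- paste(mp, voi, FEATURE_STATS, sep = "__")
      out <- c(out, st)
    }
  }
  voxel_ml <- prod(voxel_size_mm) / 1000
  vols <- vapply(FEATURE_VOIS, function(v) sum(vois$masks[[v]]) * voxel_ml,
                 numeric(1))
  names(vols) <- paste0("volume__", FEATURE_VOIS)
  out <- c(out, vols)
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Stack per-subject feature vectors into a cohort matrix
#'
#' @param features List of named feature vectors (identical canonical order).
#' @param labels Data frame with `subject_id` and `grade` (`"IV"` positive).
#' @return A `cohort_matrix`: `X` (n x 116 matrix), `y` (0/1 integer,
#'   grade IV = 1), `subject_id`.
#' @export
build_cohort_matrix <- function(features, labels) {
  if (length(features) != nrow(labels))
    stop("feature list and label table differ in length")
  nm <- feature_names()
  for (f in features)
    if (!identical(names(f), nm))
      stop("inconsistent feature names across subjects")
  X <- do.call(rbind, features)
  rownames(X) <- labels$subject_id
  structure(list(X = X, y = as.integer(labels$grade == "IV"),
                 subject_id = labels$subject_id),
            class = "cohort_matrix")
}

#' Write / read a cohort matrix as CSV
#'
#' Full-precision CSV round trip (values serialized with 17 significant
#' digits, so read-back is bit-exact).
#'
#' @param cm A [cohort_matrix][build_cohort_matrix].
#' @param path Output CSV path.
#' @export
write_cohort_csv <- function(cm, path) {
  df <- data.frame(subject_id = cm$subject_id,
                   grade = ifelse(cm$y == 1L, "IV", "II_III"),
                   cm$X, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @return `read_cohort_csv()` returns a `cohort_matrix`.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, feature_names(), drop = FALSE])
  rownames(X) <- df$subject_id
  structure(list(X = X, y = as.integer(df$grade == "IV"),
                 subject_id = df$subject_id), class = "cohort_matrix")
}
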