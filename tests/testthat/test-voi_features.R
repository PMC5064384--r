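test_that("standard-score normalization centers healthy tissue at (0, 1)", {
  grid <- c(3, 1, 1)
  img <- parameter_map(array(c(10, 20, 30), grid), "t1ce")
  hm <- array(TRUE, grid)
  z <- zscore_normalize(img, hm)
  expect_equal(mean(z$values[hm]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z$values[hm]), 1, tolerance = 1e-12)
  expect_equal(z$values[2, 1, 1], 0)   # voxel at the healthy mean

  flat <- parameter_map(array(5, grid), "t1ce")
  expect_error(zscore_normalize(flat, hm), "zero")
})

make_voi_inputs <- function(grid = c(12, 12, 12)) {
  hb <- array(FALSE, grid); hb[1:4, , ] <- TRUE
  hw <- array(FALSE, grid); hw[1:2, , ] <- TRUE
  flair <- array(FALSE, grid); flair[7:11, 5:9, 5:9] <- TRUE
  none <- array(FALSE, grid)
  list(grid = grid, hb = hb, hw = hw, flair = flair,
       roef_vals = array(0.4, grid),
       base_masks = list(flair = flair, t2t = none, cet = none,
                         healthy_brain = hb, healthy_wm = hw))
}

test_that("high-rOEF threshold is healthy mean + one SD", {
  v <- make_voi_inputs()
  # healthy rOEF mean 0.4, SD 0.1 -> threshold exactly 0.5
  healthy_idx <- which(v$hb)
  v$roef_vals[healthy_idx] <- rep(c(0.3, 0.5), length.out = length(healthy_idx))
  sd_h <- stats::sd(v$roef_vals[v$hb])
  v$roef_vals[8, 6, 6] <- 0.75
  vois <- define_vois(list(roef = parameter_map(v$roef_vals, "rOEF")),
                      supplied = v$base_masks)
  expect_equal(vois$roef_threshold, 0.4 + sd_h, tolerance = 1e-12)
  expect_true(vois$masks$high_roef[8, 6, 6])
  expect_equal(sum(vois$masks$high_roef), 1)
})

test_that("CET takes precedence over T2T and empty CET is allowed", {
  v <- make_voi_inputs()
  z1 <- array(0, v$grid); z1[8:9, 6:7, 6:7] <- 5       # enhancing
  z2 <- array(0, v$grid); z2[8:10, 6:8, 6:8] <- 5      # T2-solid, overlapping
  zf <- array(0, v$grid); zf[v$flair] <- 5
  maps <- list(roef = parameter_map(v$roef_vals, "rOEF"),
               z_flair = parameter_map(zf, "flair"),
               z_t1ce = parameter_map(z1, "t1ce"),
               z_t2 = parameter_map(z2, "t2"))
  vois <- define_vois(maps, supplied = list(healthy_brain = v$hb,
                                            healthy_wm = v$hw))
  expect_true(all(vois$masks$flair[v$flair]))
  expect_false(any(vois$masks$cet & vois$masks$t2t))
  expect_true(all(vois$masks$cet[z1 > 2 & vois$masks$flair]))
  # the overlap voxels went to CET, not T2T
  expect_false(any(vois$masks$t2t[8:9, 6:7, 6:7]))

  # phantom with no enhancement: CET empty, no error
  maps$z_t1ce <- parameter_map(array(0, v$grid), "t1ce")
  vois2 <- define_vois(maps, supplied = list(healthy_brain = v$hb,
                                             healthy_wm = v$hw))
  expect_equal(sum(vois2$masks$cet), 0)

  # empty FLAIR is rejected
  maps$z_flair <- parameter_map(array(0, v$grid), "flair")
  expect_error(define_vois(maps, supplied = list(healthy_brain = v$hb,
                                                 healthy_wm = v$hw)),
               "FLAIR VOI is empty")
})

test_that("feature extraction yields 116 canonically named, hand-checkable values", {
  expect_length(feature_names(), 116)
  v <- make_voi_inputs()
  vals <- array(0, v$grid)
  vals[v$flair] <- 7
  vals[7, 5, 5] <- 1; vals[8, 5, 5] <- 2; vals[9, 5, 5] <- 3
  t2t <- array(FALSE, v$grid); t2t[7:9, 5, 5] <- TRUE   # exactly {1,2,3}
  supplied <- v$base_masks
  supplied$t2t <- t2t
  vois <- define_vois(list(roef = parameter_map(v$roef_vals, "rOEF")),
                      supplied = supplied)
  pm <- parameter_map(vals, "x")
  maps <- list(t1ce = pm, flair = pm, t2 = pm, t2star = pm, r2prime = pm,
               roef = pm, cbv = pm)
  feats <- suppressWarnings(extract_features(maps, vois,
                                             voxel_size_mm = c(2, 2, 3)))
  expect_length(feats, 116)
  expect_identical(names(feats), feature_names())
  expect_equal(unname(feats["t2__t2t__mean"]), 2)
  expect_equal(unname(feats["t2__t2t__sd"]), 1)
  expect_equal(unname(feats["t2__t2t__min"]), 1)
  expect_equal(unname(feats["t2__t2t__max"]), 3)
  expect_equal(unname(feats["volume__t2t"]), 3 * 12 / 1000)  # ml

  # empty CET: its statistics and volume are zero, with a warning
  expect_warning(f2 <- extract_features(maps, vois), "empty VOI")
  cet_feats <- f2[grepl("__cet__|volume__cet", names(f2))]
  expect_true(all(cet_feats == 0))
})

test_that("feature extraction is invariant to voxel reordering", {
  v <- make_voi_inputs()
  withr::with_seed(4, vals <- array(rnorm(prod(v$grid)), v$grid))
  vois <- define_vois(list(roef = parameter_map(v$roef_vals, "rOEF")),
                      supplied = v$base_masks)
  pm <- parameter_map(vals, "x")
  maps <- rep(list(pm), 7)
  names(maps) <- c("t1ce", "flair", "t2", "t2star", "r2prime", "roef", "cbv")
  f1 <- suppressWarnings(extract_features(maps, vois))

  # permute all volumes (values and masks) with one shared permutation
  withr::with_seed(9, perm <- sample(prod(v$grid)))
  permute <- function(a) array(a[perm], dim(a))
  vois_p <- vois
  vois_p$masks <- lapply(vois$masks, permute)
  pm_p <- parameter_map(permute(vals), "x")
  maps_p <- rep(list(pm_p), 7); names(maps_p) <- names(maps)
  f2 <- suppressWarnings(extract_features(maps_p, vois_p))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("cohort matrix stacking and CSV round trip preserve everything", {
  nm <- feature_names()
  withr::with_seed(2, {
    f1 <- stats::setNames(rnorm(116), nm)
    f2 <- stats::setNames(rnorm(116), nm)
    f3 <- stats::setNames(rnorm(116), nm)
  })
  labels <- data.frame(subject_id = c("s1", "s2", "s3"),
                       grade = c("IV", "II_III", "IV"))
  cm <- build_cohort_matrix(list(f1, f2, f3), labels)
  expect_equal(dim(cm$X), c(3, 116))
  expect_equal(cm$y, c(1L, 0L, 1L))

  cm1 <- build_cohort_matrix(list(f1), labels[1, , drop = FALSE])
  expect_equal(dim(cm1$X), c(1, 116))

  bad <- f2; names(bad)[1] <- "wrong"
  expect_error(build_cohort_matrix(list(f1, bad, f3), labels), "inconsistent")

  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cm, path)
  back <- read_cohort_csv(path)
  expect_identical(back$X[, nm], cm$X[, nm])
  expect_identical(back$y, cm$y)
})
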