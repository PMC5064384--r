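test_that("T2* fit recovers an exact exponential and flags bad voxels", {
  es <- exact_echo_series(50, te_ms = 5 * (1:12))
  fit <- fit_t2star(es)
  expect_equal(fit$values[1, 1, 1], 50, tolerance = 1e-9)
  expect_true(all(fit$valid_mask))

  # constant signal: zero decay rate, T2* out of bounds -> invalid
  sig <- array(100, c(2, 2, 2, 4))
  fit_const <- fit_t2star(echo_series(sig, c(5, 10, 15, 20), "gradient_echo"))
  expect_false(any(fit_const$valid_mask))

  # zero-signal voxel: invalid, no error
  sig2 <- array(1000 * exp(-rep(c(5, 10, 15, 20), each = 8) / 50), c(2, 2, 2, 4))
  sig2[1, 1, 1, ] <- 0
  fit2 <- fit_t2star(echo_series(sig2, c(5, 10, 15, 20), "gradient_echo"))
  expect_false(fit2$valid_mask[1, 1, 1])
  expect_true(fit2$valid_mask[2, 2, 2])

  expect_error(fit_t2star(exact_echo_series(50, c(5, 10))), "3 echoes")
  expect_error(fit_t2star(exact_echo_series(50, c(16, 32, 48, 64),
                                            kind = "spin_echo")),
               "gradient-echo")
})

test_that("T2 fit uses only even echoes, so odd-echo bias does not move it", {
  te <- 16 * (1:8)
  clean <- exact_echo_series(80, te, kind = "spin_echo")
  expect_equal(fit_t2(clean)$values[1, 1, 1], 80, tolerance = 1e-9)

  biased <- exact_echo_series(80, te, kind = "spin_echo", odd_bias = 1.1)
  fit <- fit_t2(biased)
  expect_equal(fit$values[1, 1, 1], 80, tolerance = 1e-9)

  expect_error(fit_t2(exact_echo_series(80, c(16, 32, 48), kind = "spin_echo")),
               "4 echoes")
})

test_that("R2' arithmetic, clamping and grid checks behave as specified", {
  grid <- c(2, 2, 2)
  pm <- function(v) parameter_map(array(v, grid), "T", "ms")
  r <- compute_r2prime(pm(50), pm(80))
  expect_equal(r$values[1, 1, 1], 1000 / 50 - 1000 / 80, tolerance = 1e-12)
  expect_equal(r$values[1, 1, 1], 7.5)

  expect_equal(compute_r2prime(pm(80), pm(80))$values[2, 2, 2], 0)

  clamped <- compute_r2prime(pm(100), pm(80))
  expect_true(all(clamped$values[clamped$valid_mask] == 0))
  expect_equal(attr(clamped, "n_clamped"), prod(grid))

  expect_error(compute_r2prime(pm(50), parameter_map(array(80, c(3, 2, 2)), "T")),
               "grid")
})

test_that("deltaR2* conversion inverts the DSC forward model", {
  grid <- c(2, 2, 2)
  n_dyn <- 24
  sig <- array(1000, c(grid, n_dyn))
  ds <- dynamic_series(sig, tr_ms = 1500, te_ms = 30, n_baseline = 8)
  dr <- compute_delta_r2star(ds)
  expect_equal(max(abs(dr$delta_r2star)), 0)

  sig2 <- sig
  sig2[, , , 12] <- 1000 * exp(-0.03 * 5)   # deltaR2* = 5 s^-1 at TE = 30 ms
  dr2 <- compute_delta_r2star(dynamic_series(sig2, 1500, 30, 8))
  expect_equal(dr2$delta_r2star[1, 1, 1, 12], 5, tolerance = 1e-12)

  sig3 <- sig
  sig3[1, 1, 1, 15] <- -2
  dr3 <- compute_delta_r2star(dynamic_series(sig3, 1500, 30, 8))
  expect_false(dr3$valid_mask[1, 1, 1])
  expect_true(dr3$valid_mask[2, 2, 2])
})

test_that("rCBV normalization pins the WM mean at 1.5% and is linear", {
  cfg <- sim_config(snr = Inf, seed = 1)
  ph <- flat_phantom(cbv_fraction = 0.015)
  ph$true_cbv_fraction[5, 5, 5] <- 0.030   # twice the WM average
  wm <- array(TRUE, c(16, 16, 16)); wm[5, 5, 5] <- FALSE
  dr <- compute_delta_r2star(simulate_dsc(ph, cfg))
  rcbv <- compute_rcbv(dr, wm)
  expect_equal(mean(rcbv$values[wm]), 1.5, tolerance = 1e-12)
  expect_equal(rcbv$values[5, 5, 5], 3.0, tolerance = 1e-9)

  # renormalizing an already-normalized map is the identity
  renorm <- 1.5 * rcbv$values / mean(rcbv$values[wm])
  expect_equal(renorm, rcbv$values, tolerance = 1e-12)

  # all-zero curves: zero normalizer is an error
  flat <- dynamic_series(array(1000, c(2, 2, 2, 24)), 1500, 30, 8)
  expect_error(compute_rcbv(compute_delta_r2star(flat), array(TRUE, c(2, 2, 2))),
               "non-positive")
  expect_error(compute_rcbv(dr, array(FALSE, c(16, 16, 16))), "empty")
})

test_that("global DSC signal scaling leaves normalized rCBV unchanged", {
  cfg <- sim_config(snr = Inf, seed = 1)
  ph <- flat_phantom()
  ph$true_cbv_fraction[2, 2, 2] <- 0.04
  wm <- array(TRUE, dim(ph$label_volume)); wm[2, 2, 2] <- FALSE
  dsc <- simulate_dsc(ph, cfg)
  r1 <- compute_rcbv(compute_delta_r2star(dsc), wm)
  dsc_scaled <- dynamic_series(dsc$signal * 3.7, dsc$tr_ms, dsc$te_ms,
                               dsc$n_baseline)
  r2 <- compute_rcbv(compute_delta_r2star(dsc_scaled), wm)
  expect_equal(r1$values, r2$values, tolerance = 1e-10)
})

test_that("rOEF follows R2'/(c * rCBV) with the 3 T constant", {
  grid <- c(2, 2, 2)
  r2p <- parameter_map(array(7.5, grid), "R2prime_s-1", "s^-1")
  rcbv <- parameter_map(array(3.0, grid), "rCBV_percent", "percent")
  roef <- compute_roef(r2p, rcbv, physics_constants())
  expect_equal(roef$values[1, 1, 1], 7.5 / (317 * 0.03), tolerance = 1e-12)
  expect_equal(roef$values[1, 1, 1], 0.78864, tolerance = 1e-4)

  zero <- compute_roef(parameter_map(array(0, grid), "R2prime_s-1"), rcbv)
  expect_equal(zero$values[1, 1, 1], 0)

  novol <- compute_roef(r2p, parameter_map(array(0, grid), "rCBV_percent"))
  expect_false(any(novol$valid_mask))
  expect_error(compute_roef(r2p, rcbv, physics_constants(c_hz = -1)), "positive")
})

test_that("noise-free synthetic maps match phantom ground truth to 1e-6", {
  cfg <- sim_config(snr = Inf, seed = 31)
  s <- make_subject(cfg, "IV", 64L)
  ph <- s$phantom
  sm <- subject_maps(s)
  inside <- ph$brain_mask

  t2s <- fit_t2star(s$gre)
  sel <- inside & t2s$valid_mask
  expect_lt(max(abs(t2s$values[sel] - ph$true_t2star_ms[sel]) /
                  ph$true_t2star_ms[sel]), 1e-6)

  t2 <- fit_t2(s$tse)
  sel <- inside & t2$valid_mask
  expect_lt(max(abs(t2$values[sel] - ph$true_t2_ms[sel]) / ph$true_t2_ms[sel]),
            1e-6)

  cbv <- sm$maps$cbv
  sel <- inside & cbv$valid_mask
  true_pct <- 100 * ph$true_cbv_fraction
  expect_lt(max(abs(cbv$values[sel] - true_pct[sel]) / true_pct[sel]), 1e-6)

  roef <- sm$maps$roef
  sel <- inside & roef$valid_mask
  expect_lt(max(abs(roef$values[sel] - ph$true_oef[sel]) / ph$true_oef[sel]),
            1e-6)
})
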