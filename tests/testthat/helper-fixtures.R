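# Shared fixtures: all built in code at test time.

# Minimal hand-built phantom with spatially constant tissue parameters, for
# testing the acquisition simulators against closed forms.
flat_phantom <- function(t2star_ms = 50, t2_ms = 80, cbv_fraction = 0.015,
                         grid = c(16, 16, 16)) {
  structure(list(
    label_volume = array(1L, grid),
    true_t2star_ms = array(t2star_ms, grid),
    true_t2_ms = array(t2_ms, grid),
    true_cbv_fraction = array(cbv_fraction, grid),
    true_oef = array(0.4, grid),
    voxel_size_mm = c(2, 2, 3),
    brain_mask = array(TRUE, grid)),
    class = "tissue_phantom")
}

# Echo series with a known mono-exponential decay in every voxel.
exact_echo_series <- function(tau_ms, te_ms, s0 = 1000, grid = c(4, 4, 4),
                              kind = "gradient_echo", odd_bias = 1) {
  echoes <- lapply(seq_along(te_ms), function(i) {
    s <- array(s0 * exp(-te_ms[i] / tau_ms), grid)
    if (i %% 2 == 1) s * odd_bias else s
  })
  echo_series(array(unlist(echoes), c(grid, length(te_ms))), te_ms, kind)
}

# Small two-class dataset, linearly separable in two features.
separable_data <- function(n = 40, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(0:1, each = n / 2)
    X <- cbind(rnorm(n, mean = 3 * y), rnorm(n, mean = -2 * y), rnorm(n))
    colnames(X) <- c("a", "b", "noise")
    list(X = X, y = y)
  })
}

# Tiny cohort config used by the slower end-to-end tests.
tiny_sim_config <- function(n_subjects = 20, seed = 11, ...) {
  sim_config(grid_shape = c(16, 16, 16), n_subjects = n_subjects,
             seed = seed, ...)
}

expect_same_array <- function(a, b, tol = 0) {
  if (tol == 0) expect_identical(a, b) else expect_equal(a, b, tolerance = tol)
}
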