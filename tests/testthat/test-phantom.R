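test_that("generation is bitwise deterministic for a fixed spec", {
  sp <- quiet_phantom_spec(noise_sd = 20, bloom_sigma = 1, seed = 123)
  g1 <- generate_phantom(sp)
  g2 <- generate_phantom(sp)
  expect_identical(g1$volume$data, g2$volume$data)
  sp2 <- respec(sp, seed = 124)
  expect_false(identical(g1$volume$data, generate_phantom(sp2)$volume$data))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_phantom(quiet_phantom_spec(noise_sd = 10)))
  after <- rnorm(1)
  expect_identical(before, after)
})

test_that("with zero streak amplitude the contour HU is constant", {
  sp <- quiet_phantom_spec()
  vol <- generate_phantom(sp)$volume
  tr <- extract_metal_contour(vol, 15, 800, 3)
  expect_lt(diff(range(tr$hu_samples)), 1e-6)
})

test_that("the streak field modulates the contour at the requested order", {
  sp <- quiet_phantom_spec(
    streak = list(list(amplitude = 50, order = 3, phase = 0, decay = 1e6)))
  vol <- generate_phantom(sp)$volume
  amp <- compute_spectrum(extract_metal_contour(vol, 15, 800, 3))$amplitudes
  # energy sits in bin 3, not bins 1-2
  expect_gt(amp[4], 100 * (amp[2] + amp[3]))
})

test_that("implants that do not fit inside the grid are rejected", {
  expect_error(
    generate_phantom(quiet_phantom_spec(grid_shape = c(10, 20, 20),
                                        radius_mm = 15, height_mm = 4)),
    "fit")
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(phantom_spec(metal_hu = 100), "metal_hu")
})

test_that("case batteries sweep parameters with recorded covariates", {
  base <- quiet_phantom_spec(seed = 5)
  bat <- generate_case_battery(base, list(bloom_sigma = c(0, 1, 2)))
  expect_length(bat$cases, 3L)
  expect_equal(bat$table$bloom_sigma, c(0, 1, 2))
  vols <- vapply(bat$cases, function(cs)
    compute_bloom_vol(cs$volume, 800)$volume_cm3, numeric(1))
  expect_true(all(diff(vols) >= 0))     # blooming monotonicity
  expect_equal(bat$table$true_volume_cm3,
               rep(base$implant$radius_mm^2 * pi *
                     base$implant$height_mm / 1000, 3))
})

test_that("streak sweeps raise the low-frequency amplitude monotonically", {
  base <- quiet_phantom_spec(
    streak = list(list(amplitude = 0, order = 1, phase = 0.2, decay = 1e6)))
  bat <- generate_case_battery(base,
                               list(streak_amplitude = c(10, 30, 60)))
  alf <- vapply(bat$cases, function(cs)
    compute_amplitude_low_freq(cs$volume, 15)$amplitude_low_freq,
    numeric(1))
  expect_true(all(diff(alf) > 0))
})

test_that("empty or unknown sweeps are errors", {
  base <- quiet_phantom_spec()
  expect_error(generate_case_battery(base, list()), "non-empty")
  expect_error(generate_case_battery(base, list(bananas = 1)), "unknown")
})
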