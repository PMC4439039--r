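# Tissue masking, path-length maps, coefficient estimation and the
# multiplicative correction field.

test_that("background threshold implements the interpolated 99th percentile", {
  # constant window: degenerate, returns the constant with a warning
  vol <- brain_volume(array(100, c(4, 40, 40)))
  expect_warning(thr <- background_threshold(vol, list(y = c(1, 40),
                                                       x = c(1, 40)),
                                             min_area = 100), "degenerate")
  expect_equal(as.numeric(thr), 100)
  # window holding each integer 0..999 exactly once: sort-and-interpolate
  # oracle gives 989.01
  a <- array(0, c(1, 40, 25))
  a[1, , ] <- sample(0:999)   # order must not matter
  vol2 <- brain_volume(a)
  thr2 <- background_threshold(vol2, list(y = c(1, 40), x = c(1, 25)),
                               min_area = 100)
  expect_equal(as.numeric(thr2), 989.01, tolerance = 1e-12)
  # Gaussian window: matches the normal quantile Monte-Carlo
  set.seed(42)
  g <- array(stats::rnorm(250000, 100, 5), c(10, 500, 50))
  volg <- brain_volume(g)
  thr3 <- background_threshold(volg, list(y = c(1, 500), x = c(1, 50)),
                               min_area = 100)
  expect_lt(abs(as.numeric(thr3) - (100 + 5 * stats::qnorm(0.99))), 0.2)
  # window must be big enough
  expect_error(background_threshold(vol2, list(y = c(1, 2), x = c(1, 2))),
               "min_area")
})

test_that("about 1% of background-window voxels exceed the threshold", {
  set.seed(7)
  vol <- brain_volume(array(stats::rnorm(10 * 200 * 200, 50, 6),
                            c(10, 200, 200)))
  thr <- background_threshold(vol, list(y = c(1, 200), x = c(1, 200)),
                              min_area = 100)
  n <- length(vol$data)
  frac <- mean(vol$data > as.numeric(thr))
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / n) + 1 / n)
})

test_that("tissue mask recovers the phantom ellipsoid and rejects specks", {
  ph <- plain_phantom(shape = c(24, 40, 40))
  vol <- ph$channels$green
  expect_warning(thr <- background_threshold(vol, list(y = c(1, 6),
                                                       x = c(1, 6)),
                                             min_area = 16))
  mask <- compute_tissue_mask(vol, thr)
  expect_identical(mask$data, ph$mask$data)
  # salt noise outside the brain (kept clear of the tissue surface so the
  # specks stay disconnected): largest-component filter removes it
  salted <- vol
  set.seed(1)
  corner <- array(FALSE, dim(vol$data))
  corner[, 1:4, ] <- TRUE; corner[, , 1:4] <- TRUE
  bg <- which(!ph$mask$data & corner)
  specks <- sample(bg, length(bg) %/% 100)
  salted$data[specks] <- 4000
  m_on <- compute_tissue_mask(salted, 10, largest_component = TRUE)
  expect_identical(m_on$data, ph$mask$data)
  m_off <- compute_tissue_mask(salted, 10, largest_component = FALSE)
  expect_true(all(m_off$data[ph$mask$data]))
  expect_gt(sum(m_off$data), sum(ph$mask$data))
  # nothing above threshold is an error
  expect_error(compute_tissue_mask(vol, 1e9), "empty mask")
})

test_that("path lengths follow the half-voxel convention and skip holes", {
  pitch <- c(2, 1.61, 2)
  # solid run of 10 along y
  m <- array(FALSE, c(3, 14, 3))
  m[2, 3:12, 2] <- TRUE
  mask <- structure(list(data = m, pitch = pitch), class = "tissue_mask")
  dep <- compute_path_lengths(mask)
  expect_equal(dep$dy[2, 12, 2], 9.5 * 1.61, tolerance = 1e-12)
  expect_equal(dep$dy[2, 3, 2], 0.5 * 1.61, tolerance = 1e-12)
  expect_true(all(dep$dy[!m] == 0))
  # run 5, hole 3, run 4: last voxel (5 + 4 - 0.5) * pitch
  m2 <- array(FALSE, c(1, 12, 1))
  m2[1, c(1:5, 9:12), 1] <- TRUE
  mask2 <- structure(list(data = m2, pitch = pitch), class = "tissue_mask")
  dep2 <- compute_path_lengths(mask2)
  expect_equal(dep2$dy[1, 12, 1], (5 + 4 - 0.5) * 1.61, tolerance = 1e-12)
  # cross-check every voxel against the brute-force ray walk
  line <- m2[1, , 1]
  for (i in seq_along(line))
    expect_equal(dep2$dy[1, i, 1], oracle_path(line, i, 1.61),
                 tolerance = 1e-12)
  # dz accumulates from the detection-side (+z) face
  m3 <- array(TRUE, c(6, 1, 1))
  mask3 <- structure(list(data = m3, pitch = c(3, 1, 1)),
                     class = "tissue_mask")
  dep3 <- compute_path_lengths(mask3)
  expect_equal(dep3$dz[, 1, 1], (c(6, 5, 4, 3, 2, 1) - 0.5) * 3,
               tolerance = 1e-12)
  # monotone along the propagation direction within a contiguous run
  ph <- plain_phantom(shape = c(16, 24, 24))
  dd <- compute_path_lengths(ph$mask)
  dy <- dd$dy
  run <- ph$mask$data[8, , 12]
  expect_true(all(diff(dy[8, run, 12]) >= 0))
})

test_that("coefficient estimation inverts the forward model", {
  ph <- plain_phantom(shape = c(48, 72, 72), ky = 5e-4, kz = 3e-4)
  m <- estimate_coefficients(ph$channels$green, ph$mask)
  expect_rel_error(m$ky, 5e-4, 0.02)
  expect_rel_error(m$kz, 3e-4, 0.02)
  expect_gt(m$diagnostics$r2_y, 0.99)
  # zero-attenuation phantom: estimates vanish to rounding noise, clamped
  # non-negative
  ph0 <- plain_phantom(shape = c(24, 36, 36), ky = 0, kz = 0)
  m0 <- suppressWarnings(estimate_coefficients(ph0$channels$green, ph0$mask))
  expect_lt(m0$ky, 1e-10)
  expect_lt(m0$kz, 1e-10)
  expect_gte(m0$ky, 0)
  # insufficient depth range errors naming the axis
  thin <- structure(list(data = array(TRUE, c(2, 50, 8)),
                         pitch = c(1, 1, 1)), class = "tissue_mask")
  vol <- brain_volume(array(100, c(2, 50, 8)), pitch = c(1, 1, 1))
  expect_error(estimate_coefficients(vol, thin, min_bin_voxels = 1),
               "along z")
})

test_that("noisy coefficient estimation stays within 10% (median)", {
  errs <- sapply(1:20, function(s) {
    ph <- generate_phantom(phantom_spec(shape = c(40, 64, 64),
                                        cells = list(), rim_um = 0,
                                        rim_gain = 0, ky = 5e-4, kz = 3e-4,
                                        poisson_gain = 1, read_sd = 4,
                                        seed = s))
    m <- estimate_coefficients(ph$channels$green, ph$mask)
    c(abs(m$ky / 5e-4 - 1), abs(m$kz / 3e-4 - 1))
  })
  expect_lt(stats::median(errs[1, ]), 0.10)
  expect_lt(stats::median(errs[2, ]), 0.10)
})

test_that("correction field realises the closed-form factors", {
  # dy = dz = 0 voxels get factor 1 pre-smoothing
  ph <- plain_phantom(shape = c(16, 24, 24))
  fld <- correction_field(ph$mask, ph$truth$depths, ph$truth$model,
                          sigma = 0, clamp = 20)
  expect_true(all(fld$factors[!ph$mask$data] == 1))
  expect_true(all(fld$factors >= 1 - 1e-12))
  # factor e for ky*dy = 1
  m <- array(TRUE, c(2, 10, 2))
  mask <- structure(list(data = m, pitch = c(1, 1000 / 9.5, 1)),
                    class = "tissue_mask")
  dep <- compute_path_lengths(mask)
  f2 <- correction_field(mask, dep, attenuation_model(1e-3, 0), sigma = 0,
                         clamp = Inf)
  expect_equal(max(f2$factors), exp(1), tolerance = 1e-12)
  # Gaussian smoothing leaves a constant-depth slab interior unchanged
  flat <- structure(list(factors = array(2.5, c(12, 12, 12))))
  sm <- gaussian_filter3(array(2.5, c(12, 12, 12)), c(2, 2, 2))
  expect_equal(sm, array(2.5, c(12, 12, 12)), tolerance = 1e-12)
  expect_error(correction_field(ph$mask, ph$truth$depths, ph$truth$model,
                                clamp = 0.5), "clamp")
})

test_that("correction factors are monotone in depth and clamp-safe", {
  # rectangular slab: dz is constant along y, so the pre-smoothing factor
  # must be non-decreasing in dy along every illumination ray (and vice
  # versa along z)
  m <- array(TRUE, c(10, 40, 10))
  mask <- structure(list(data = m, pitch = c(3.23, 1.61, 1.61)),
                    class = "tissue_mask")
  dep <- compute_path_lengths(mask)
  model <- attenuation_model(2e-3, 1e-3)
  fld <- correction_field(mask, dep, model, sigma = 0, clamp = 4)
  expect_true(all(apply(fld$factors, c(1, 3), function(v) all(diff(v) >= 0))))
  expect_true(all(apply(fld$factors, c(2, 3),
                        function(v) all(diff(rev(v)) >= 0))))
  expect_lte(max(fld$factors), 4)
  vol <- brain_volume(array(500, dim(m)), pitch = mask$pitch)
  corrected <- apply_correction(vol, fld)
  expect_lte(max(corrected$data), 4 * max(vol$data) + 1e-9)
})

test_that("correction flattens the depth profile over phantom seeds", {
  for (s in c(1, 2, 3)) {
    ph <- plain_phantom(shape = c(24, 48, 48), ky = 1e-3, kz = 5e-4,
                        seed = s)
    fld <- correction_field(ph$mask, ph$truth$depths, ph$truth$model,
                            sigma = 0, clamp = Inf)
    rec <- apply_correction(ph$channels$green, fld)
    inm <- which(ph$mask$data)
    dyv <- ph$truth$depths$dy[inm]
    fit <- stats::lm.fit(cbind(1, dyv), log(rec$data[inm]))
    expect_lt(abs(fit$coefficients[2]), 0.05 * 1e-3)
  }
})
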