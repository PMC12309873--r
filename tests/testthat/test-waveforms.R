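lim <- hardware_limits()

test_that("RF amplitude scaling follows the small-tip flip integral", {
  # hard pulse: B1 = flip_rad / (2 pi gamma tau) = 0.25/(gamma * 1 ms)
  rf <- make_rf("hard", 1, 90)
  expect_equal(rf$amplitude_uT, 0.25 / (GAMMA_HZ_PER_T * 1e-3) * 1e6,
               tolerance = 1e-9)
  expect_equal(rf$amplitude_uT, 5.87, tolerance = 0.01)
  # sinc bandwidth = TBW / duration
  rf2 <- make_rf("sinc", 2, 30, time_bandwidth = 4)
  expect_equal(rf2$bandwidth_hz, 2000)
  # zero flip: identically zero envelope
  rf0 <- make_rf("sinc", 2, 0)
  expect_true(all(Mod(rf0$samples) == 0))
  expect_equal(rf0$amplitude_uT, 0)
  # B1 ceiling enforced
  expect_error(make_rf("hard", 0.05, 180), "ceiling")
})

test_that("trapezoid synthesis honors area identities and is shortest", {
  g <- make_trapezoid("read", amplitude_mT_m = 10, flat_ms = 1,
                      limits = hardware_limits(slew_mT_m_ms = 100))
  expect_equal(g$rise_ns, 1e5)         # 0.1 ms ramp at 100 mT/m/ms
  expect_equal(mrforge:::grad_area_mT_ms_m(g), 11)  # amp * (flat + rise)
  expect_null(make_trapezoid("read", area_mT_ms_m = 0))

  # brute-force minimal-duration oracle over raster-quantized trapezoids
  lims <- hardware_limits(g_max_mT_m = 20, slew_mT_m_ms = 100)
  A <- 5
  raster_ms <- lims$grad_raster_ns / 1e6
  best <- Inf
  for (rise in seq(raster_ms, 2, by = raster_ms)) {
    amp_max <- min(lims$g_max, lims$slew * rise)
    flat <- max(0, ceiling((A / amp_max - rise) / raster_ms) * raster_ms)
    best <- min(best, 2 * rise + flat)
  }
  got <- make_trapezoid("read", area_mT_ms_m = A, limits = lims)
  expect_equal(got$duration_ns / 1e6, best)
  expect_equal(mrforge:::grad_area_mT_ms_m(got), A, tolerance = 1e-9)
})

test_that("slice-select gradient and rephaser follow the closed forms", {
  rf <- make_rf("hann_sinc", 2, 30, time_bandwidth = 4)  # BW 2 kHz
  ss <- make_slice_select(rf, 5)
  expect_equal(ss$plateau_mT_m, 2000 / (GAMMA_HZ_PER_T * 5e-3) * 1e3,
               tolerance = 1e-9)
  expect_equal(ss$plateau_mT_m, 9.40, tolerance = 0.01)
  # symmetric pulse: rephaser area = -(plateau area)/2 - ramp-down half
  plateau_area <- ss$plateau_mT_m * ss$select$flat_ns / 1e6
  ramp_area <- ss$plateau_mT_m * ss$select$fall_ns / 1e6 / 2
  expect_equal(ss$rephaser_area, -(plateau_area / 2 + ramp_area))
  expect_equal(mrforge:::grad_area_mT_ms_m(ss$rephaser), ss$rephaser_area,
               tolerance = 1e-9)
  # thickness -> infinity gives a vanishing gradient
  ss_inf <- make_slice_select(rf, 1e6)
  expect_lt(ss_inf$plateau_mT_m, 1e-3)
  expect_error(make_slice_select(rf, 0.1), "Gmax")
})

test_that("encoding tables give the published train lengths", {
  expect_equal(nrow(encoding_table(60, 1, 2)), 30)           # EPI diffusion
  expect_equal(nrow(encoding_table(48, 1, 2)), 24)           # GRASE phase
  expect_equal(nrow(encoding_table(32, 0.75, 2)), 12)        # GRASE partition
  t1 <- encoding_table(16, 1, 1)
  expect_equal(t1$index, 0:15)                               # identity case
  expect_false(any(t1$is_reference))
  expect_error(encoding_table(8, reference_lines = 16), "wider")
})

test_that("encoding-table count formula holds on a property sweep", {
  set.seed(7)
  for (case in 1:200) {
    N <- sample(4:96, 1)
    pf <- sample(c(1, 0.875, 0.75, 0.625), 1)
    acc <- sample(1:4, 1)
    tab <- encoding_table(N, pf, acc)
    # brute-force: acquired band is the last ceil(N*pf) indices, strided
    band <- seq(N - ceiling(N * pf), N - 1)
    expect_identical(tab$index[!tab$is_reference], band[seq(1, length(band), by = acc)])
    expect_equal(sum(!tab$is_reference), ceiling(N * pf / acc))
    expect_true(all(tab$index >= 0 & tab$index < N))
    expect_false(any(duplicated(tab$index)))
    # reference band fully sampled and centered
    tabr <- encoding_table(N, pf, acc, reference_lines = min(4, N))
    allidx <- sort(tabr$index)
    ctr <- floor(N / 2)
    expect_true(all((ctr - 2):(ctr + 1) %in% allidx))
  }
})

test_that("numeric b-value matches the closed form for rectangular lobes", {
  # two rectangular lobes amplitude G, duration delta, no gap:
  # b = (2/3) (2 pi gamma)^2 G^2 delta^3
  G <- 20; delta_ms <- 8
  m <- delta_ms * 1e6 / GRAD_RASTER_NS
  samples <- c(rep(G, m), rep(-G, m))
  b_num <- b_value(samples)
  b_cf <- (2 / 3) * (2 * pi * GAMMA_HZ_PER_T)^2 * (G * 1e-3)^2 *
    (delta_ms * 1e-3)^3 * 1e-6
  expect_equal(b_num, b_cf, tolerance = 1e-6)
  # quadratic homogeneity
  expect_equal(b_value(2 * samples), 4 * b_num, tolerance = 1e-12)
  expect_equal(b_value(0 * samples), 0)
})

test_that("bipolar diffusion amplitude solves the target b within 0.1%", {
  spec <- bipolar_diffusion(300, 16)
  expect_equal(b_value(spec$samples), 300, tolerance = 1e-3)
  expect_equal(bipolar_diffusion(0, 16)$G_mT_m, 0)
  expect_error(bipolar_diffusion(600, 4), "Gmax")
})

test_that("radial directions: calibration planes and golden-angle uniformity", {
  d <- radial_directions(1, "calibration_planes", n_angles = 180)
  expect_equal(nrow(d), 540)
  expect_equal(rowSums(d^2), rep(1, 540), tolerance = 1e-12)
  # each direction lies exactly in one coordinate plane
  n_zero <- rowSums(abs(d) < 1e-12)
  expect_true(all(n_zero >= 1))
  expect_equal(unname(table(attr(d, "plane"))), rep(180L, 3), ignore_attr = TRUE)
  expect_equal(attr(d, "angle_deg")[1:3], c(0, 2, 4))

  expect_equal(sum(radial_directions(1, "golden_3d")^2), 1, tolerance = 1e-12)
  g <- radial_directions(2000, "golden_3d")
  expect_equal(rowSums(g^2), rep(1, 2000), tolerance = 1e-9)
  # spherical-cap counting: P(z > 0.5) = 0.25 for uniform sampling
  frac <- mean(g[, "z"] > 0.5)
  expect_lt(abs(frac - 0.25) / 0.25, 0.15)
  # determinism
  expect_identical(g, radial_directions(2000, "golden_3d"))
})
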