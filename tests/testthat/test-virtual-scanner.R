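test_that("a hard 90-degree pulse tips equilibrium fully transverse", {
  blk <- execution_block(0, rf = make_rf("hard", 1, 90))
  iso <- list(pos_mm = matrix(0, 1, 3))
  r <- bloch_simulate(list(blk), iso, return_magnetization = TRUE)
  expect_equal(sqrt(sum(r$magnetization[1, 1:2]^2)), 1, tolerance = 1e-9)
  expect_equal(r$magnetization[1, 3], 0, tolerance = 1e-6)
})

test_that("a spin echo refocuses off-resonance dispersion at 2 tau", {
  tau_ns <- 5e6
  hi <- hardware_limits(b1_max_uT = 200)
  b90 <- execution_block(0, rf = make_rf("hard", 0.2, 90, limits = hi),
                         duration_ns = 2e5)
  # 90 center at 0.1 ms; 180 center must sit tau after it
  gap1 <- execution_block(2e5, duration_ns = tau_ns - 2e5)
  b180 <- execution_block(tau_ns, rf = make_rf("hard", 0.2, 180, phase_rad = pi / 2,
                                               limits = hi),
                          duration_ns = 2e5)
  # echo at 180-center + tau = 2 tau + 0.1 ms absolute
  gap2 <- execution_block(tau_ns + 2e5, duration_ns = tau_ns - 1e5)
  iso <- list(pos_mm = matrix(0, 9, 3),
              off_hz = seq(-200, 200, length.out = 9))
  r <- bloch_simulate(list(b90, gap1, b180, gap2), iso,
                      return_magnetization = TRUE)
  mxy <- complex(real = r$magnetization[, 1], imaginary = r$magnetization[, 2])
  # at t = 2 tau the dispersion (12.6 rad unrefocused) re-converges up to
  # the finite pulse widths
  expect_lt(diff(range(Arg(mxy))), 0.1)
  expect_equal(Mod(mean(mxy)), 1, tolerance = 5e-3)
})

test_that("small-tip sinc slice profile has FWHM within 5% of nominal", {
  lims <- hardware_limits()
  rf <- make_rf("hann_sinc", 2, 10, time_bandwidth = 4)
  ss <- make_slice_select(rf, 5, lims)
  rf$start_ns <- ss$rf_start_ns
  reph <- ss$rephaser; reph$start_ns <- mrforge:::event_end_ns(ss$select)
  blk <- execution_block(0, rf = rf, gradients = list(ss$select, reph))
  z <- seq(-8, 8, length.out = 321)
  iso <- list(pos_mm = cbind(0, 0, z))
  r <- bloch_simulate(list(blk), iso, return_magnetization = TRUE)
  prof <- sqrt(r$magnetization[, 1]^2 + r$magnetization[, 2]^2)
  half <- max(prof) / 2
  above <- range(z[prof >= half])
  fwhm <- diff(above)
  expect_lt(abs(fwhm - 5) / 5, 0.05)
})

test_that("k-space trajectories follow the gradient integral bookkeeping", {
  # zero gradients -> k stays zero
  b <- execution_block(0, rf = make_rf("hard", 0.1, 10),
                       adc = adc_event(2e5, 16, 1e4))
  tr <- kspace_trajectory(list(b))
  expect_equal(tr[[1]]$k, matrix(0, 16, 3))

  # prephaser -A/2 then readout A: k crosses zero at the readout center
  lims <- hardware_limits()
  ro <- mrforge:::ro_template(32, 128, 1e4, lims)
  pre <- make_trapezoid("read", area_mT_ms_m = ro$preph_area, limits = lims)
  exc <- execution_block(0, rf = make_rf("hard", 0.1, 10))
  enc <- execution_block(exc$duration_ns, gradients = list(pre))
  rob <- execution_block(enc$start_ns + enc$duration_ns,
                         gradients = list(grad_trap("read", 0, ro$rise, ro$flat,
                                                    ro$rise, ro$g)),
                         adc = adc_event(ro$rise, 32, 1e4))
  tr2 <- kspace_trajectory(list(exc, enc, rob))
  kx <- tr2[[1]]$k[, 1]
  expect_lt(kx[1], 0); expect_gt(kx[32], 0)
  expect_equal(which(diff(sign(kx)) > 0), 16)  # sign change at the center
  expect_equal(abs(kx[1]), abs(kx[32]), tolerance = 1e-9)

  # center-out UTE spoke: ramp samples follow the quadratic integral
  g <- grad_trap("read", 0, 2e5, 4e5, 2e5, 10)
  ub <- execution_block(0, rf = make_rf("hard", 0.05, 10), duration_ns = 1e5)
  rb <- execution_block(1e5, gradients = list(g), adc = adc_event(0, 40, 1e4))
  tr3 <- kspace_trajectory(list(ub, rb))
  t_mid <- (seq_len(20) - 0.5) * 1e4          # within the 0.2 ms ramp
  k_ana <- GAMMA_HZ_PER_T * 0.5 * (10e-3 / 2e5) * (t_mid * 1e-9)^2 * 1e9
  expect_equal(tr3[[1]]$k[1:20, 1], k_ana, tolerance = 1e-6)

  # refocusing negates accumulated k
  ref <- execution_block(rb$start_ns + rb$duration_ns,
                         rf = make_rf("hard", 0.1, 180, purpose = "refocusing",
                                      limits = hardware_limits(b1_max_uT = 200)))
  post <- execution_block(ref$start_ns + ref$duration_ns,
                          adc = adc_event(0, 1, 1e4))
  tr4 <- kspace_trajectory(list(ub, rb, ref, post))
  k_end <- GAMMA_HZ_PER_T * mrforge:::grad_area_mT_ms_m(g) * 1e-3 * 1e-3
  expect_equal(tr4[[2]]$k[1, 1], -k_end, tolerance = 1e-6)
})

test_that("gridding matches the direct FFT on Cartesian data", {
  N <- 32; fov <- 200
  ph <- virtual_phantom(data.frame(type = "ellipsoid", x = c(0, 20),
                                   y = c(5, -15), z = 0, a = c(60, 15),
                                   b = c(70, 12), c = 1, pd = c(1, 0.5),
                                   T1 = 1000, T2 = 80, off_hz = 0, D = 1e-3),
                        fov_mm = c(fov, fov, 1), ndim = 2)
  k <- as.matrix(expand.grid(kx = ((1:N) - 1 - N / 2) / (fov * 1e-3),
                             ky = ((1:N) - 1 - N / 2) / (fov * 1e-3)))
  smp <- kspace_of_phantom(ph, k)
  img_grid <- grid_reconstruct(smp, k, N, fov)
  img_fft <- mrforge:::fftshift_nd(stats::fft(mrforge:::ifftshift_nd(
    matrix(smp, N, N)), inverse = TRUE))
  expect_lt(nrmse(img_grid, img_fft), 0.01)
  # a lone DC sample deapodizes to a flat image proportional to it
  dc <- grid_reconstruct(complex(real = 3), matrix(0, 1, 2), N, fov)
  expect_equal(Re(dc), matrix(3, N, N), tolerance = 1e-9)
  expect_error(grid_reconstruct(complex(0), matrix(0, 0, 2), N, fov), "empty")
})

test_that("fully sampled radial disk reconstructs uniformly", {
  N <- 32; fov <- 200
  disk <- virtual_phantom(data.frame(type = "ellipsoid", x = 0, y = 0, z = 0,
                                     a = 60, b = 60, c = 1, pd = 1, T1 = 1000,
                                     T2 = 80, off_hz = 0, D = 1e-3),
                          fov_mm = c(fov, fov, 1), ndim = 2)
  nsp <- 128
  ks <- do.call(rbind, lapply(seq_len(nsp), function(i) {
    th <- (i - 1) * pi / nsp
    spoke_k(c(cos(th), sin(th), 0), 96, N / 2 / (fov * 1e-3), 5e3)[, 1:2]
  }))
  img <- grid_reconstruct(kspace_of_phantom(disk, ks), ks, N, fov,
                          dcf = "radial")
  interior <- Mod(img[(N / 2 - 3):(N / 2 + 4), (N / 2 - 3):(N / 2 + 4)])
  expect_lt(stats::sd(interior) / mean(interior), 0.05)
})

test_that("trajectory-corrected radial recon beats the uncorrected one", {
  N <- 32; fov <- 200
  disk <- virtual_phantom(data.frame(type = "ellipsoid", x = 8, y = -5, z = 0,
                                     a = 50, b = 60, c = 1, pd = 1, T1 = 1000,
                                     T2 = 80, off_hz = 0, D = 1e-3),
                          fov_mm = c(fov, fov, 1), ndim = 2)
  nsp <- 96
  mk <- function(del) do.call(rbind, lapply(seq_len(nsp), function(i) {
    th <- (i - 1) * pi / nsp
    spoke_k(c(cos(th), sin(th), 0), 96, N / 2 / (fov * 1e-3), 5e3,
            delays_us = del)[, 1:2]
  }))
  ref <- grid_reconstruct(kspace_of_phantom(disk, mk(c(0, 0, 0))),
                          mk(c(0, 0, 0)), N, fov, dcf = "radial")
  for (d_us in c(5, 10, 20)) {
    del <- c(d_us, d_us, 0)
    acq <- kspace_of_phantom(disk, mk(del))       # what the scanner measured
    unc <- grid_reconstruct(acq, mk(c(0, 0, 0)), N, fov, dcf = "radial")
    cor <- grid_reconstruct(acq, mk(del), N, fov, dcf = "radial")
    expect_lt(nrmse(cor, ref), nrmse(unc, ref))
  }
})

test_that("gradient delays are recovered from opposed-spoke prescans", {
  ph <- phantom_gaussians(4, seed = 2)
  e0 <- simulate_calibration_echoes(ph, c(0, 0, 0), n_angles = 36)
  d0 <- estimate_gradient_delay(e0)$delays_us
  expect_lt(max(abs(d0)), 2.5)                    # within half a dwell (5 us)
  d10 <- estimate_gradient_delay(
    simulate_calibration_echoes(ph, c(10, 10, 10), n_angles = 36))$delays_us
  expect_equal(unname(d10), c(10, 10, 10), tolerance = 0.1)
  dx <- estimate_gradient_delay(
    simulate_calibration_echoes(ph, c(10, 0, 0), n_angles = 36))$delays_us
  expect_equal(unname(dx[1]), 10, tolerance = 0.1)
  expect_lt(max(abs(dx[2:3])), 1)
})

test_that("ADC fitting is exact without noise and errors on one b-value", {
  S0 <- array(c(2, 1, 3, 4), c(2, 2))
  D <- array(c(0.5, 0.8, 1.0, 1.2) * 1e-3, c(2, 2))
  vols <- lapply(c(0, 500), function(b) S0 * exp(-b * D))
  fit <- fit_adc(vols, c(0, 500))
  expect_equal(fit$D, D, tolerance = 1e-12)
  expect_equal(fit$S0, S0, tolerance = 1e-12)
  expect_error(fit_adc(vols[1], 0), "at least 2")
  # nonpositive signals masked
  vols[[2]][1, 1] <- 0
  fit2 <- fit_adc(vols, c(0, 500))
  expect_true(is.na(fit2$D[1, 1]))
  expect_false(any(is.na(fit2$D[-1])))
})

test_that("geometric-mean trace images recover the ADC at SNR 50", {
  set.seed(9)
  n <- 24
  D_true <- 0.80e-3
  S0 <- 1
  b <- c(0, 300, 600)
  snr <- 50
  vols <- lapply(b, function(bb) {
    lapply(1:3, function(ax)
      array(S0 * exp(-bb * D_true) + stats::rnorm(n^2, 0, S0 / snr), c(n, n)))
  })
  fit <- fit_adc(vols, b)
  expect_lt(abs(mean(fit$D, na.rm = TRUE) - D_true) / D_true, 0.02)
})

test_that("Hadamard decoding is the exact left-inverse and halves the noise", {
  H <- hadamard_walsh(8)
  n <- 16
  set.seed(5)
  subs <- lapply(1:7, function(j) array(stats::runif(n^2), c(n, n)))
  M0 <- array(10, c(n, n))
  encode <- lapply(1:8, function(i) {
    acc <- M0
    for (j in 1:7) if (H[i, j + 1] > 0) acc <- acc - subs[[j]]
    acc
  })
  dec <- hadamard_decode(encode, H)
  expect_length(dec, 7)
  for (j in 1:7) expect_equal(dec[[j]], subs[[j]], tolerance = 1e-12)
  # identical volumes (no labeling) decode to zero maps
  zero <- hadamard_decode(lapply(1:8, function(i) M0), H)
  for (j in 1:7) expect_equal(zero[[j]], array(0, c(n, n)))
  expect_error(hadamard_decode(encode[1:5], H), "expected 8")
  # noise propagation: per-subbolus sd = sigma / sqrt(2)
  sigma <- 1
  reps <- 300
  vals <- replicate(reps, {
    noisy <- lapply(1:8, function(i) array(stats::rnorm(4, 0, sigma), c(2, 2)))
    hadamard_decode(noisy, H)[[3]][1, 1]
  })
  expect_equal(stats::sd(vals), sigma / sqrt(2), tolerance = 0.12)
})

test_that("labeling subtracts subbolus signal with label-control > 0", {
  H <- hadamard_walsh(8)
  perf <- 0.5
  # uniform subbolus contribution per column; labeling reduces the signal
  encode <- lapply(1:8, function(i) 10 - sum((H[i, -1] > 0) * perf))
  dec <- hadamard_decode(lapply(encode, function(x) array(x, c(1, 1))), H)
  for (j in 1:7) expect_gt(dec[[j]][1, 1], 0)
})

test_that("rigid registration recovers known transforms to 0.1 mm / 0.1 deg", {
  ph <- phantom_gaussians(5, seed = 4)
  fix <- phantom_render(ph, 24)
  vox <- 200 / 24
  expect_equal(unclass(rigid_register(fix, fix, voxel_mm = vox))[c("t", "r")],
               list(t = c(0, 0, 0), r = c(0, 0, 0)))
  tr_t <- rigid_transform(c(3, 0, 0))
  est_t <- rigid_register(phantom_render(ph, 24, transform = tr_t), fix,
                          voxel_mm = vox)
  expect_equal(est_t$t, invert_transform(tr_t)$t, tolerance = 0.1)
  tr_r <- rigid_transform(rotation_deg = c(0, 0, 2))
  est_r <- rigid_register(phantom_render(ph, 24, transform = tr_r), fix,
                          voxel_mm = vox)
  expect_equal(est_r$r, invert_transform(tr_r)$r, tolerance = 0.1)
})

test_that("mean voxel displacement follows the norm identities", {
  expect_equal(mean_voxel_displacement(rigid_transform()), 0)
  # pure translation: MVD = |t| for any mask
  expect_equal(mean_voxel_displacement(rigid_transform(c(1, 2, 2))), 3)
  mask <- array(FALSE, c(16, 16, 16)); mask[1:4, 1:4, 1:4] <- TRUE
  expect_equal(mean_voxel_displacement(rigid_transform(c(1, 2, 2)), n = 16,
                                       mask = mask), 3)
  expect_error(mean_voxel_displacement(rigid_transform(), mask = array(FALSE, c(16,16,16))),
               "empty mask")
  # small rotation about the centroid: MVD ~ mean |omega x r|
  ang <- 0.5
  got <- mean_voxel_displacement(rigid_transform(rotation_deg = c(0, 0, ang)),
                                 n = 24, fov_mm = c(200, 200, 200))
  g <- mrforge:::phantom_grid_mm(24, c(200, 200, 200), 3)
  pts <- as.matrix(expand.grid(x = g$x, y = g$y, z = g$z))
  w <- ang * pi / 180
  ana <- mean(sqrt(pts[, 1]^2 + pts[, 2]^2)) * 2 * sin(w / 2)
  expect_equal(got, ana, tolerance = 0.01 * ana)
})

test_that("closed-loop motion correction reduces the mean voxel displacement", {
  ph <- phantom_gaussians(5, seed = 4)
  # static phantom: corrected arm identical to uncorrected
  static <- motion_correction_demo(ph, function(v) rigid_transform(),
                                   n_volumes = 3, n = 16)
  expect_equal(static$mean_mvd_corrected, static$mean_mvd_uncorrected)
  expect_equal(static$volumes[[3]], static$volumes[[1]])

  # scripted 4 mm drift over the run: strict improvement
  drift <- lapply(1:7, function(v)
    rigid_transform(c(4 * (v - 1) / 6, 0, 0.5 * (v - 1) / 6)))
  dm <- motion_correction_demo(ph, drift, n_volumes = 7, n = 16)
  expect_lt(dm$mean_mvd_corrected, dm$mean_mvd_uncorrected)
  expect_true(all(dm$feedback_log$name == "geometry"))

  # step displacement at volume 3: volumes from 5 on are realigned
  step <- lapply(1:6, function(v)
    if (v >= 3) rigid_transform(c(3, 0, 0)) else rigid_transform())
  sm <- motion_correction_demo(ph, step, n_volumes = 6, n = 16)
  expect_gt(sm$mvd_corrected[3], 2.5)    # latency: step not yet corrected
  expect_lt(max(sm$mvd_corrected[5:6]), 0.3)
})
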