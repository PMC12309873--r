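lim <- hardware_limits()

test_that("execution blocks enforce containment and raster rounding", {
  # pure delay: 1 ms block, no events
  d <- execution_block(0, duration_ns = 1e6)
  expect_equal(d$duration_ns, 1e6)
  expect_null(d$rf); expect_length(d$gradients, 0)
  # duration defaults to the rounded-up latest event end
  rf <- make_rf("hann_sinc", 2.56, 20, time_bandwidth = 4)
  ss <- make_slice_select(rf, 5)
  rf$start_ns <- ss$rf_start_ns
  b <- execution_block(0, rf = rf, gradients = list(ss$select))
  expect_gte(b$duration_ns, mrforge:::event_end_ns(ss$select))
  expect_equal(b$duration_ns %% lim$block_raster_ns, 0)
  # events must fit the stated duration
  expect_error(execution_block(0, duration_ns = 1e5, rf = make_rf("hard", 1, 10)),
               "exceeds block duration")
  expect_error(rf_event(-5, 1, 1), "start_ns >= 0")
})

test_that("validate_block reports overlaps and hardware-limit violations", {
  good <- execution_block(0, rf = make_rf("hard", 0.5, 10),
                          gradients = list(grad_trap("read", 5e5, 1e5, 5e5, 1e5, 10)))
  expect_length(validate_block(good), 0)
  # RF overlapping ADC
  bad <- execution_block(0, rf = make_rf("hard", 1, 10),
                         adc = adc_event(5e5, 64, 1e4))
  expect_match(validate_block(bad), "overlap", all = FALSE)
  # amplitude over Gmax names the axis
  amp <- execution_block(0, gradients = list(grad_trap("read", 0, 3e5, 1e5, 3e5, 45)))
  expect_match(validate_block(amp), "read axis exceeds Gmax", all = FALSE)
  # slew over limit
  slew <- execution_block(0, gradients = list(grad_trap("phase", 0, 1e4, 1e5, 1e4, 30)))
  expect_match(validate_block(slew), "slew", all = FALSE)
})

test_that("header counters flow from enclosing loops into ADC headers", {
  reg <- bp_registry()
  bp_register(reg, blueprint("acq", atomic = TRUE, rules = list(
    raw = rule(character(), function()
      list(duration_ns = 1e5, adc = adc_event(0, 8, 1e4))))))
  bp_register(reg, blueprint("line_loop", loop = list(counter = "line", count = 6),
                             children = "acq"))
  bp_register(reg, blueprint("root", children = "line_loop"))
  seq <- assemble(reg, "root", mr_protocol(TR_ms = 10, TE_ms = 5))
  blocks <- stream_collect(seq)
  expect_equal(vapply(blocks, function(b) b$adc$header$line, numeric(1)), 0:5)
})

test_that("identity geometry leaves a block unchanged", {
  b <- execution_block(0, rf = make_rf("hard", 0.5, 10),
                       gradients = list(grad_trap("read", 0, 1e5, 5e5, 1e5, 10)))
  expect_identical(logical_to_physical(b, diag(3), c(0, 0, 0)), b)
  expect_error(logical_to_physical(b, diag(c(1, 1, -1))), "proper rotation")
})

test_that("a 90-degree z-rotation maps the read waveform onto physical y", {
  b <- execution_block(0, gradients = list(grad_trap("read", 0, 1e5, 5e5, 1e5, 10)))
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)  # +90 deg about z
  p <- logical_to_physical(b, Rz)
  axes <- vapply(p$gradients, function(g) g$axis, character(1))
  expect_equal(axes, "y")
  expect_equal(p$gradients[[1]]$amp_mT_m, 10)
})

test_that("slice offset shifts the RF frequency by gamma G dz", {
  rf <- make_rf("hann_sinc", 2, 30, time_bandwidth = 4)
  ss <- make_slice_select(rf, 5)          # plateau ~9.4 mT/m
  sel <- ss$select
  sel$amp_mT_m <- 9.4                     # the worked value
  rf$start_ns <- ss$rf_start_ns
  b <- execution_block(0, rf = rf, gradients = list(sel))
  p <- logical_to_physical(b, diag(3), offset_mm = c(0, 0, 10))
  expect_equal(p$rf$freq_hz, GAMMA_HZ_PER_T * 9.4e-3 * 0.01, tolerance = 1e-9)
  expect_equal(p$rf$freq_hz, 4002, tolerance = 1)
})

test_that("rotation preserves the gradient vector norm at every raster point", {
  set.seed(11)
  for (case in 1:10) {
    gl <- list(grad_trap("read", 0, 1e5, 4e5, 1e5, stats::runif(1, -20, 20)),
               grad_trap("phase", 0, 1e5, 4e5, 1e5, stats::runif(1, -20, 20)),
               grad_trap("slice", 2e5, 2e5, 2e5, 2e5, stats::runif(1, -20, 20)))
    b <- execution_block(0, gradients = gl)
    th <- stats::runif(3, 0, 2 * pi)
    R <- mrforge:::rot_matrix(th * 180 / pi)
    p <- logical_to_physical(b, R)
    rast <- function(bl) {
      t1 <- max(vapply(bl$gradients, mrforge:::event_end_ns, numeric(1)))
      nt <- ceiling(t1 / 1e4)
      M <- matrix(0, 3, nt)
      ax <- c(read = 1, phase = 2, slice = 3, x = 1, y = 2, z = 3)
      for (g in bl$gradients) {
        s <- mrforge:::grad_samples(g, 1e4)
        i0 <- round(g$start_ns / 1e4)
        M[ax[[g$axis]], seq_along(s) + i0] <-
          M[ax[[g$axis]], seq_along(s) + i0] + s
      }
      M
    }
    n0 <- sqrt(colSums(rast(b)^2))
    n1 <- sqrt(colSums(rast(p)^2))
    expect_equal(n1, n0, tolerance = 1e-12)
  }
})
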