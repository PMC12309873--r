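test_that("Walsh-ordered Hadamard-8 satisfies the sequency invariants", {
  H <- hadamard_walsh(8)
  expect_equal(H %*% t(H), 8 * diag(8), ignore_attr = TRUE)
  expect_true(all(H[1, ] == 1))
  sc <- apply(H, 1, function(r) sum(diff(r) != 0))
  expect_true(all(diff(sc) > 0))
  # every row beyond the first balances label and control
  expect_true(all(rowSums(H[-1, ] > 0) == 4))
})

test_that("label trains map encoding rows onto timed subboli", {
  spec <- asl_spec()
  tr1 <- hadamard_label_train(spec, 1)
  expect_equal(nrow(tr1), 7)
  expect_true(all(tr1$role == "label"))
  expect_equal(sum(tr1$duration_s), 2.8)
  expect_equal(tr1$start_s, (0:6) * 0.4)
  tr5 <- hadamard_label_train(spec, 5)
  expect_setequal(unique(tr5$role), c("label", "control"))
})

test_that("inflow times ladder from PLD + subbolus to PLD + train length", {
  ti <- asl_inflow_times(asl_spec())
  expect_setequal(round(ti, 6), c(1.0, 1.4, 1.8, 2.2, 2.6, 3.0, 3.4))
  expect_equal(sort(diff(sort(ti))), rep(0.4, 6), tolerance = 1e-12)
  one <- asl_inflow_times(asl_spec(encoding = hadamard_walsh(2),
                                   subbolus_s = 0.5, pld_s = 0.7))
  expect_equal(one, 1.2)
})

test_that("spectroscopy presets reproduce the published scan times", {
  st <- build_sequence("steam", protocol_preset("steam"))
  expect_equal(scan_duration(st), (2 + 96) * 2.0)   # 3:16
  expect_equal(st$meta$n_repetitions, 98)
  pr <- build_sequence("press", protocol_preset("press"))
  expect_equal(scan_duration(pr), 196)
  # prescan flagging and average counters
  blocks <- adc_blocks(stream_collect(build_sequence("steam", toy_protocol("steam"))))
  flags <- lapply(blocks, function(b) b$adc$header$flags)
  expect_equal(vapply(flags, function(f) "is_prescan" %in% f, logical(1)),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(vapply(blocks, function(b) b$adc$header$average, numeric(1)),
               c(0, 0, 0, 1, 2))
})

test_that("radial UTE counts calibration and imaging excitations", {
  seq <- build_sequence("radial_ute", protocol_preset("radial_ute"))
  expect_equal(seq$meta$n_cal, 540)
  expect_equal(seq$meta$n_spokes + seq$meta$n_cal, 20540)
  # toy traversal: every spoke excited once, prescans flagged
  toy <- build_sequence("radial_ute", toy_protocol("radial_ute"))
  blocks <- stream_collect(toy)
  n_exc <- sum(vapply(blocks, function(b)
    !is.null(b$rf) && b$rf$purpose == "excitation", logical(1)))
  expect_equal(n_exc, 16 + 3 * 4)
  adc <- adc_blocks(blocks)
  pres <- vapply(adc, function(b) "is_prescan" %in% b$adc$header$flags, logical(1))
  expect_equal(sum(pres), 12)
  # ADC starts with the gradient ramp (ultrashort TE)
  img <- adc[!pres][[1]]
  gstart <- min(vapply(img$gradients, function(g) g$start_ns, numeric(1)))
  expect_equal(img$adc$start_ns, gstart)
})

test_that("k-space coverage is complete and unique for Cartesian families", {
  for (fam in c("flash", "bssfp", "mprage", "rare", "flair",
                "se_epi_diffusion", "grase_pcasl")) {
    seq <- build_sequence(fam, toy_protocol(fam))
    adc <- adc_blocks(stream_collect(seq))
    hdr <- do.call(rbind, lapply(adc, function(b) {
      h <- b$adc$header
      data.frame(line = h$line, partition = h$partition, slice = h$slice,
                 average = h$average, contrast = h$contrast)
    }))
    expect_false(any(duplicated(hdr)), info = fam)
    enc <- seq$meta$encoding
    exp_lines <- sort(enc$phase$index)
    got_lines <- sort(unique(hdr$line))
    expect_equal(got_lines, exp_lines, info = fam)
    if (!is.null(enc$partition))
      expect_setequal(unique(hdr$partition), enc$partition$index)
    # every demanded (line, partition, slice, contrast) combination once
    per_cell <- table(hdr$line, hdr$partition, hdr$slice, hdr$contrast)
    expect_true(all(per_cell[per_cell > 0] == 1), info = fam)
  }
})

test_that("realized TE matches the protocol within one gradient raster", {
  for (fam in c("flash", "rare", "se_epi_diffusion", "grase_pcasl")) {
    p <- toy_protocol(fam)
    seq <- build_sequence(fam, p)
    blocks <- stream_collect(seq)
    is_exc <- vapply(blocks, function(b)
      !is.null(b$rf) && b$rf$purpose == "excitation", logical(1))
    big <- vapply(blocks, function(b)
      !is.null(b$rf) && identical(b$rf$purpose, "excitation") &&
        isTRUE(b$rf$flip_deg >= 45), logical(1))
    exc_i <- if (any(big)) which(big)[1] else which(is_exc)[1]
    t_exc <- rf_center_abs(blocks[[exc_i]])
    adc_i <- which(vapply(blocks, function(b) !is.null(b$adc), logical(1)))
    adc_i <- adc_i[adc_i > exc_i]
    centers <- vapply(blocks[adc_i], adc_center_abs, numeric(1)) - t_exc
    te_ns <- p$TE_ms * 1e6
    # the echo defining TE: first echo (RARE), center echo (EPI/GRASE),
    # the gradient echo (FLASH) -- one acquired echo center must land on TE
    expect_lte(min(abs(centers - te_ns)), GRAD_RASTER_NS + 1,
               label = paste(fam, "TE"))
  }
})

test_that("bSSFP alternates excitation phase by pi, including ramp prescans", {
  seq <- build_sequence("bssfp", toy_protocol("bssfp"))
  blocks <- stream_collect(seq)
  rfb <- Filter(function(b) !is.null(b$rf) && b$rf$purpose == "excitation", blocks)
  phases <- vapply(rfb, function(b) b$rf$phase_rad, numeric(1))
  expect_equal(abs(diff(phases)) %% (2 * pi), rep(pi, length(phases) - 1),
               tolerance = 1e-12)
  # ramp preparation scales the flip linearly
  flips <- vapply(rfb, function(b) b$rf$flip_deg, numeric(1))
  expect_equal(flips[1:4], 10 * ((0:3) + 0.5) / 4)
  expect_true(all(flips[-(1:4)] == 10))
})

test_that("GRASE encodes the published train and labels per the encoding row", {
  seq <- build_sequence("grase_pcasl", protocol_preset("grase_pcasl"))
  expect_equal(seq$meta$train_length, c(24, 12))
  toy <- build_sequence("grase_pcasl", toy_protocol("grase_pcasl"))
  blocks <- stream_collect(toy)
  lbl <- Filter(function(b) !is.null(b$tags$role), blocks)
  expect_equal(length(lbl), 8 * 7)   # 8 encodes x 7 subboli
  H <- hadamard_walsh(8)
  roles <- vapply(lbl, function(b) b$tags$role, character(1))
  expect_equal(roles, as.vector(t(ifelse(H[, -1] > 0, "label", "control"))))
  # background-suppression inversions present per TR
  inv <- Filter(function(b) !is.null(b$rf) && b$rf$purpose == "inversion", blocks)
  expect_equal(length(inv), 2 * 8)
})

test_that("diffusion volumes schedule one b0 plus each b on three axes", {
  seq <- build_sequence("se_epi_diffusion", toy_protocol("se_epi_diffusion"))
  vols <- seq$meta$volumes
  expect_equal(nrow(vols), 7)
  expect_equal(sum(vols$b == 0), 1)
  expect_equal(unname(table(vols$axis)), rep(2L, 3), ignore_attr = TRUE)
  blocks <- stream_collect(seq)
  dw <- Filter(function(b) !is.null(b$tags$b) && b$tags$b > 0, blocks)
  # two diffusion blocks (before/after refocusing) per slice per DW volume
  expect_equal(length(dw), 6 * 2 * 2)
  # each pair carries half the volume's b
  g <- dw[[1]]$gradients[[1]]
  expect_equal(b_value(g$samples_mT_m), dw[[1]]$tags$b / 2, tolerance = 1e-3)
})

test_that("scan duration equals repetitions times TR with only TR fill", {
  for (fam in c("flash", "mprage", "steam")) {
    p <- toy_protocol(fam)
    seq <- build_sequence(fam, p)
    n_tr <- switch(fam, flash = 16, mprage = 2, steam = 5)
    expect_equal(scan_duration(seq), n_tr * p$TR_ms / 1000, info = fam)
  }
  expect_equal(scan_duration(build_sequence("flash",
    mr_protocol(TR_ms = 12, TE_ms = 5, matrix_size = c(8L, 1L, 1L),
                averages = 0L))), 0)
})

test_that("describe_sequence summarizes derived timing", {
  d <- describe_sequence(build_sequence("rare", toy_protocol("rare")))
  expect_equal(d$train_length[1], 4)
  expect_gt(d$min_TE_ms, 0)
  expect_equal(d$n_readouts, 16)
  expect_output(print(d), "rare")
})
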