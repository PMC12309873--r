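# Diffusion-weighted spin-echo EPI, Hadamard-encoded pCASL GRASE, 3D
# radial UTE, and the single-voxel spectroscopy families.

build_se_epi_diffusion <- function(protocol, limits) {
  train <- protocol$train_length[1]
  if (is.na(train)) stop("SE-EPI needs train_length[1]", call. = FALSE)
  N <- protocol$matrix_size; fov <- protocol$fov_mm
  tabP <- encoding_table(N[2], protocol$partial_fourier[1],
                         protocol$acceleration[1])
  nl <- nrow(tabP)
  if (nl != train)
    stop(sprintf("single-shot EPI: train length %d must equal encoded lines %d",
                 train, nl), call. = FALSE)
  nsl <- N[3]
  b_list <- protocol$extras$diff_b %||% c(0, 300, 600)
  delta_ms <- protocol$extras$diff_delta_ms %||% 16
  b_nonzero <- b_list[b_list > 0]
  # volume schedule: one b = 0, then each nonzero b on each of 3 axes
  vols <- rbind(data.frame(b = 0, axis = NA_integer_),
                expand.grid(axis = 1:3, b = b_nonzero)[, c("b", "axis")])
  n_vol <- nrow(vols)
  # one bipolar pair on each side of the refocusing pulse: each pair
  # carries half the target b (first moments vanish pairwise, so b adds)
  pairs <- lapply(unique(vols$b), function(b)
    bipolar_diffusion(b / 2, delta_ms, limits))
  names(pairs) <- as.character(unique(vols$b))
  pair_len <- length(pairs[[1]]$samples)
  pair_dur <- pair_len * limits$grad_raster_ns
  axis_names <- c("read", "phase", "slice")

  dwell_ns <- 5e3
  ro <- ro_template(N[1], fov[1], dwell_ns, limits)
  ro_dur <- ro$rise + ro$flat + ro$rise
  De <- ceil_raster(ro_dur, limits$block_raster_ns)
  ec_in <- ro$rise + ro$flat / 2
  ic <- floor(nl / 2)
  a_of <- function(i) pe_area(tabP$index[i + 1L], N[2], fov[2], limits$gamma)
  a_max <- max(abs(pe_area(0, N[2], fov[2], limits$gamma)), abs(ro$preph_area))
  pe_dur_ns <- make_trapezoid("phase", area_mT_ms_m = a_max,
                              limits = limits)$duration_ns

  reg <- bp_registry()
  fs <- bp_spectral_sat("fatsat", limits, fat_offset_hz(limits))
  slice_off <- list(deps = "slice_i",
                    fn = local({ nsl <- nsl; gap <- fov[3] / max(1, nsl)
                      function(s) (s - (nsl - 1) / 2) * gap }))
  exc <- bp_selective_rf("exc", "protocol.flip_deg", protocol$slice_thickness_mm,
                         duration_ms = 2, limits = limits,
                         offset_rule = slice_off, sync_marked = TRUE)
  refoc <- bp_selective_rf("refoc", "protocol.refocus_deg",
                           protocol$slice_thickness_mm, duration_ms = 3,
                           limits = limits,
                           purpose = "refocusing", crusher_area = 12,
                           rephase = FALSE, offset_rule = slice_off,
                           phase_rule = list(deps = character(), fn = function() pi / 2))
  diff_bp <- function(name) blueprint(name, atomic = TRUE, rules = list(
    raw = rule("vol_i", local({
      vols <- vols; pairs <- pairs; axis_names <- axis_names
      raster <- limits$grad_raster_ns; pair_dur <- pair_dur
      function(v) {
        row <- vols[v + 1L, ]
        g <- if (row$b > 0)
          list(grad_wave(axis_names[row$axis], 0,
                         pairs[[as.character(row$b)]]$samples, raster))
        list(duration_ns = pair_dur, gradients = g,
             tags = list(b = row$b, axis = row$axis))
      }
    }))))
  epi_pre <- blueprint("epi_pre", atomic = TRUE, rules = list(
    raw = rule(character(), local({
      ro <- ro; pe_dur_ns <- pe_dur_ns; a0 <- a_of(0); limits <- limits
      function() list(duration_ns = pe_dur_ns,
                      gradients = list(
                        trap_or_null("read", ro$preph_area, pe_dur_ns, limits),
                        trap_or_null("phase", a0, pe_dur_ns, limits)))
    }))))
  epi_echo <- blueprint("epi_echo", atomic = TRUE, rules = list(
    raw = rule(c("echo_i", "vol_i", "slice_i"), local({
      tabP <- tabP; ro <- ro; De <- De; nl <- nl; N <- N
      dwell_ns <- dwell_ns; limits <- limits; a_of <- a_of
      function(e, v, sl) {
        pol <- if (e %% 2 == 0) 1 else -1
        g_ro <- grad_trap("read", 0, ro$rise, ro$flat, ro$rise, pol * ro$g)
        blip <- if (e < nl - 1)
          trap_or_null("phase", a_of(e + 1) - a_of(e), ro$rise, limits,
                       ro$rise + ro$flat)
        adc <- adc_event(ro$rise, N[1], dwell_ns,
                         header = acq_header(line = tabP$index[e + 1L],
                                             slice = sl, contrast = v,
                                             segment = e %% 2))
        list(duration_ns = De, gradients = list(g_ro, blip), adc = adc)
      }
    }))))
  raster <- limits$block_raster_ns
  left_fixed <- (exc$dur_ns - exc$rf_center_ns) + pair_dur + refoc$rf_center_ns
  right_fixed <- (refoc$dur_ns - refoc$rf_center_ns) + pair_dur + pe_dur_ns +
    ic * De + ec_in
  min_te_ns <- 2 * ceil_raster(max(left_fixed, right_fixed), raster)
  unit_fixed <- fs$dur_ns + exc$dur_ns + 2 * pair_dur + refoc$dur_ns +
    pe_dur_ns + nl * De
  for (b in list(fs$bp, exc$bp, refoc$bp, diff_bp("diffA"), diff_bp("diffB"),
                 epi_pre, epi_echo))
    bp_register(reg, b)
  bp_register(reg, bp_fill("f1", "f1_ns", function(x) x))
  bp_register(reg, bp_fill("f2", "f2_ns", function(x) x))
  bp_register(reg, bp_fill("tr_fill", "tr_fill_ns", function(x) x))
  bp_register(reg, blueprint("echo_loop", loop = list(counter = "echo_i", count = nl),
                             children = "epi_echo"))
  bp_register(reg, blueprint("slice_unit",
                             children = c("fatsat", "exc", "diffA", "f1", "refoc",
                                          "diffB", "f2", "epi_pre", "echo_loop")))
  bp_register(reg, blueprint("slice_loop",
                             loop = list(counter = "slice_i", count = nsl),
                             children = "slice_unit"))
  bp_register(reg, blueprint("vol_unit", children = c("slice_loop", "tr_fill")))
  bp_register(reg, blueprint("vol_loop", loop = list(counter = "vol_i", count = n_vol),
                             children = "vol_unit"))
  root_rules <- list(
    min_te_ms = rule(character(), local({ v <- ns_to_ms(min_te_ns); function() v })),
    f1_ns = rule("protocol.TE_ms", local({
      lf <- left_fixed; r <- raster
      function(te) round((ms_to_ns(te) / 2 - lf) / r) * r
    })),
    f2_ns = rule("protocol.TE_ms", local({
      rf_ <- right_fixed; r <- raster
      function(te) round((ms_to_ns(te) / 2 - rf_) / r) * r
    })),
    min_tr_ms = rule(c("f1_ns", "f2_ns"), local({
      u <- unit_fixed; nsl <- nsl
      function(f1, f2) ns_to_ms(nsl * (u + max(f1, 0) + max(f2, 0)))
    })),
    tr_fill_ns = rule(c("protocol.TR_ms", "f1_ns", "f2_ns"), local({
      u <- unit_fixed; nsl <- nsl
      function(tr, f1, f2) ms_to_ns(tr) - nsl * (u + f1 + f2)
    })))
  bp_register(reg, blueprint("root", rules = root_rules, children = "vol_loop"))
  assemble(reg, "root", protocol, limits,
           meta = list(min_te_node = "root.min_te_ms",
                       min_tr_node = "root.min_tr_ms",
                       train_length = c(nl, NA),
                       volumes = vols, b_values = b_list,
                       encoding = list(phase = tabP)))
}

build_grase_pcasl <- function(protocol, limits) {
  N <- protocol$matrix_size; fov <- protocol$fov_mm
  tabP <- encoding_table(N[2], protocol$partial_fourier[1],
                         protocol$acceleration[1])
  tabS <- encoding_table(N[3], protocol$partial_fourier[2],
                         protocol$acceleration[2])
  nl <- nrow(tabP); np <- nrow(tabS)
  spec <- asl_spec(subbolus_s = protocol$extras$asl_subbolus_s %||% 0.4,
                   pld_s = protocol$extras$asl_pld_s %||% 0.6,
                   bs_T1_ms = protocol$extras$asl_bs_T1_ms %||% c(700, 1400))
  m0 <- isTRUE(protocol$extras$m0)
  n_enc <- if (m0) 1L else nrow(spec$encoding)
  n_sub <- ncol(spec$encoding) - 1L
  sub_ns <- round(spec$subbolus_s * 1e9)
  pld_ns <- round(spec$pld_s * 1e9)

  dwell_ns <- 5e3
  ro <- ro_template(N[1], fov[1], dwell_ns, limits)
  ro_dur <- ro$rise + ro$flat + ro$rise
  De <- ceil_raster(ro_dur, limits$block_raster_ns)
  ec_in <- ro$rise + ro$flat / 2
  ic <- floor(nl / 2)
  a_of <- function(i) pe_area(tabP$index[i + 1L], N[2], fov[2], limits$gamma)
  aS_of <- function(r) pe_area(tabS$index[r + 1L], N[3], fov[3], limits$gamma)
  a_max <- max(abs(pe_area(0, N[2], fov[2], limits$gamma)),
               abs(pe_area(0, N[3], fov[3], limits$gamma)),
               abs(ro$preph_area), abs(ro$area))
  pe_dur_ns <- make_trapezoid("phase", area_mT_ms_m = a_max,
                              limits = limits)$duration_ns

  reg <- bp_registry()
  fs <- bp_spectral_sat("fatsat", limits, fat_offset_hz(limits))
  exc <- bp_selective_rf("exc", "protocol.flip_deg", fov[3], duration_ms = 2,
                         limits = limits, sync_marked = TRUE)
  refoc <- bp_selective_rf("refoc", "protocol.refocus_deg", fov[3],
                           duration_ms = 3, limits = limits,
                           purpose = "refocusing",
                           crusher_area = 12, rephase = FALSE,
                           phase_rule = list(deps = character(), fn = function() pi / 2))
  inv <- bp_hard_rf("bs_inv", "bs_flip", 10, limits, purpose = "inversion")

  label_bp <- blueprint("label", atomic = TRUE, rules = list(
    raw = rule(c("enc_i", "sub_i"), local({
      H <- spec$encoding; sub_ns <- sub_ns; m0 <- m0
      function(enc, sub) {
        role <- if (m0) "none" else
          if (H[enc + 1L, sub + 2L] > 0) "label" else "control"
        list(duration_ns = sub_ns, tags = list(role = role, subbolus = sub + 1L))
      }
    }))))
  # background suppression inversion times before the excitation center,
  # solved for nulling of the stated T1s, constrained into the PLD
  window_s <- n_sub * spec$subbolus_s + spec$pld_s
  inv_tail0 <- inv$dur_ns - inv$rf_center_ns
  head_ns <- fs$dur_ns + exc$rf_center_ns + inv$dur_ns
  t_bs <- if (m0) c(0, 0) else
    bs_inversion_times(spec$bs_T1_ms, window_s,
                       max_before_s = (pld_ns - head_ns - 2e7) / 1e9,
                       min_before_s = (inv_tail0 + fs$dur_ns +
                                         exc$rf_center_ns + 4e7) / 1e9,
                       gap_s = (inv$dur_ns + 4e7) / 1e9)
  t1_ns <- ceil_raster(round(t_bs[1] * 1e9), limits$block_raster_ns)
  t2_ns <- ceil_raster(round(t_bs[2] * 1e9), limits$block_raster_ns)
  inv_c <- inv$rf_center_ns; inv_tail <- inv$dur_ns - inv_c
  # [pf1, inv, pf2, inv, pf3, fatsat, exc]: exc center lands PLD after labeling
  pf1 <- pld_ns - t1_ns - inv_c
  pf2 <- t1_ns - t2_ns - inv_tail - inv_c
  pf3 <- t2_ns - inv_tail - fs$dur_ns - exc$rf_center_ns
  if (!m0 && (pf1 < 0 || pf2 < 0 || pf3 < 0))
    stop("post-labeling delay too short for background suppression", call. = FALSE)
  if (m0) { pf1 <- pld_ns - fs$dur_ns - exc$rf_center_ns; pf2 <- 0; pf3 <- 0 }

  epi_pre <- blueprint("epi_pre", atomic = TRUE, rules = list(
    raw = rule("refoc_i", local({
      ro <- ro; pe_dur_ns <- pe_dur_ns; a0 <- a_of(0); aS_of <- aS_of
      limits <- limits
      function(r) list(duration_ns = pe_dur_ns, gradients = list(
        trap_or_null("read", ro$preph_area, pe_dur_ns, limits),
        trap_or_null("phase", a0, pe_dur_ns, limits),
        trap_or_null("slice", aS_of(r), pe_dur_ns, limits)))
    }))))
  epi_post <- blueprint("epi_post", atomic = TRUE, rules = list(
    raw = rule("refoc_i", local({
      ro <- ro; pe_dur_ns <- pe_dur_ns; aS_of <- aS_of; limits <- limits
      nl <- nl; a_last <- a_of(nl - 1)
      read_acc <- ro$preph_area + (if (nl %% 2 == 1) ro$area else 0)
      function(r) list(duration_ns = pe_dur_ns, gradients = list(
        trap_or_null("read", -read_acc, pe_dur_ns, limits),
        trap_or_null("phase", -a_last, pe_dur_ns, limits),
        trap_or_null("slice", -aS_of(r), pe_dur_ns, limits)))
    }))))
  gecho <- blueprint("gecho", atomic = TRUE, rules = list(
    raw = rule(c("echo_i", "refoc_i", "enc_i"), local({
      tabP <- tabP; tabS <- tabS; ro <- ro; De <- De; nl <- nl; N <- N
      dwell_ns <- dwell_ns; limits <- limits; a_of <- a_of
      function(e, r, enc) {
        pol <- if (e %% 2 == 0) 1 else -1
        g_ro <- grad_trap("read", 0, ro$rise, ro$flat, ro$rise, pol * ro$g)
        blip <- if (e < nl - 1)
          trap_or_null("phase", a_of(e + 1) - a_of(e), ro$rise, limits,
                       ro$rise + ro$flat)
        adc <- adc_event(ro$rise, N[1], dwell_ns,
                         header = acq_header(line = tabP$index[e + 1L],
                                             partition = tabS$index[r + 1L],
                                             contrast = enc, segment = e %% 2))
        list(duration_ns = De, gradients = list(g_ro, blip), adc = adc)
      }
    }))))

  raster <- limits$block_raster_ns
  group_dur <- pe_dur_ns + nl * De + pe_dur_ns
  gc_off <- pe_dur_ns + ic * De + ec_in
  exc_tail <- exc$dur_ns - exc$rf_center_ns
  refoc_c <- refoc$rf_center_ns; refoc_tail <- refoc$dur_ns - refoc_c
  half_min <- max(exc_tail + refoc_c,
                  refoc_tail + gc_off,
                  (group_dur - gc_off) + refoc_c)
  min_te_ns <- 2 * ceil_raster(half_min, raster)
  label_total <- n_sub * sub_ns
  chain_to_exc_end <- label_total + pld_ns + exc_tail  # label start -> exc end

  for (b in list(fs$bp, exc$bp, refoc$bp, inv$bp, label_bp, epi_pre, epi_post,
                 gecho))
    bp_register(reg, b)
  bp_register(reg, bp_fill("pf1", "pf1_ns", function(x) x))
  bp_register(reg, bp_fill("pf2", "pf2_ns", function(x) x))
  bp_register(reg, bp_fill("pf3", "pf3_ns", function(x) x))
  bp_register(reg, bp_fill("gfillA", c("refoc_i", "esp_ns"), local({
    exc_tail <- exc_tail; refoc_c <- refoc_c
    grp_tail <- group_dur - gc_off
    function(r, esp) if (r == 0) esp / 2 - exc_tail - refoc_c else
      esp / 2 - grp_tail - refoc_c
  })))
  bp_register(reg, bp_fill("gfillB", "esp_ns", local({
    refoc_tail <- refoc_tail; gc_off <- gc_off
    function(esp) esp / 2 - refoc_tail - gc_off
  })))
  bp_register(reg, bp_fill("tr_fill", "tr_fill_ns", function(x) x))
  bp_register(reg, blueprint("sub_loop", loop = list(counter = "sub_i", count = n_sub),
                             children = "label"))
  bp_register(reg, blueprint("gecho_loop", loop = list(counter = "echo_i", count = nl),
                             children = "gecho"))
  bp_register(reg, blueprint("refoc_unit",
                             children = c("gfillA", "refoc", "gfillB", "epi_pre",
                                          "gecho_loop", "epi_post")))
  bp_register(reg, blueprint("refoc_loop", loop = list(counter = "refoc_i", count = np),
                             children = "refoc_unit"))
  bs_children <- if (m0) c("pf1", "fatsat", "exc") else
    c("pf1", "bs_inv", "pf2", "bs_inv", "pf3", "fatsat", "exc")
  bp_register(reg, blueprint("tr_unit",
                             children = c("sub_loop", bs_children,
                                          "refoc_loop", "tr_fill")))
  bp_register(reg, blueprint("enc_loop", loop = list(counter = "enc_i", count = n_enc),
                             children = "tr_unit"))
  bp_register(reg, blueprint("avg_loop",
                             loop = list(counter = "average", count = "protocol.averages"),
                             children = "enc_loop"))
  root_rules <- list(
    bs_flip = rule(character(), function() 180),
    esp_ns = rule("protocol.TE_ms", function(te) ms_to_ns(te)),
    min_te_ms = rule(character(), local({ v <- ns_to_ms(min_te_ns); function() v })),
    pf1_ns = rule(character(), local({ v <- pf1; function() v })),
    pf2_ns = rule(character(), local({ v <- pf2; function() v })),
    pf3_ns = rule(character(), local({ v <- pf3; function() v })),
    min_tr_ms = rule("esp_ns", local({
      fixed <- chain_to_exc_end; np <- np
      refoc_d <- refoc$dur_ns; grp <- group_dur
      refoc_c <- refoc_c; refoc_tail <- refoc_tail; gc_off <- gc_off
      exc_tail2 <- exc_tail; grp_tail <- group_dur - gc_off
      function(esp) {
        fA0 <- esp / 2 - exc_tail2 - refoc_c
        fA <- esp / 2 - grp_tail - refoc_c
        fB <- esp / 2 - refoc_tail - gc_off
        ns_to_ms(fixed + (fA0 + refoc_d + fB + grp) +
                   (np - 1) * (fA + refoc_d + fB + grp))
      }
    })),
    tr_fill_ns = rule(c("protocol.TR_ms", "min_tr_ms"),
                      function(tr, mtr) ms_to_ns(tr - mtr)))
  bp_register(reg, blueprint("root", rules = root_rules, children = "avg_loop"))
  assemble(reg, "root", protocol, limits,
           meta = list(min_te_node = "root.min_te_ms",
                       min_tr_node = "root.min_tr_ms",
                       train_length = c(nl, np), asl = spec,
                       encoding = list(phase = tabP, partition = tabS)))
}

build_radial_ute <- function(protocol, limits) {
  n_spokes <- protocol$extras$spokes %||% stop("radial_ute needs extras$spokes")
  cal_angles <- protocol$extras$cal_angles %||% 180
  N <- protocol$matrix_size; fov <- protocol$fov_mm
  dirs_img <- radial_directions(n_spokes, "golden_3d")
  dirs_cal <- radial_directions(1, "calibration_planes", n_angles = cal_angles)
  n_cal <- nrow(dirs_cal)
  dwell_ns <- 5e3
  n_samp <- ceiling(N[1] / 2)                       # center-out: kmax in N/2 samples
  g_T_m <- 1 / ((fov[1] * 1e-3) * limits$gamma * dwell_ns * 1e-9)
  g <- g_T_m * 1e3
  if (g > limits$g_max) stop("readout gradient exceeds Gmax", call. = FALSE)
  rise <- ceil_raster(ms_to_ns(g / limits$slew), limits$grad_raster_ns)
  flat <- ceil_raster(n_samp * dwell_ns, limits$grad_raster_ns)
  reg <- bp_registry()
  exc <- bp_hard_rf("exc", "protocol.flip_deg", 0.1, limits)
  axes <- c("read", "phase", "slice")
  ro_bp <- function(name, dirs, cal) blueprint(name, atomic = TRUE, rules = list(
    raw = rule(if (cal) "cal_i" else "spoke_i", local({
      dirs <- dirs; g <- g; rise <- rise; flat <- flat; axes <- axes
      dwell_ns <- dwell_ns; limits <- limits; cal <- cal
      n_adc <- if (cal) 2L * n_samp else n_samp
      deph_area <- -(g * ns_to_ms(rise) / 2 + g * ns_to_ms(flat) / 2)
      deph <- if (cal) make_trapezoid("read", area_mT_ms_m = deph_area,
                                      limits = limits)
      deph_dur <- if (cal) deph$duration_ns else 0
      function(i) {
        u <- dirs[i + 1L, ]
        grads <- list()
        for (a in 1:3) if (abs(u[a]) > 1e-12) {
          if (cal) {
            d <- deph; d$axis <- axes[a]; d$amp_mT_m <- d$amp_mT_m * u[a]
            d$start_ns <- 0
            grads <- c(grads, list(d))
          }
          grads <- c(grads, list(grad_trap(axes[a], deph_dur, rise, flat, rise,
                                           g * u[a])))
        }
        adc <- adc_event(deph_dur, n_adc, dwell_ns,
                         header = acq_header(line = i,
                                             flags = if (cal) "is_prescan" else character(),
                                             trajectory_id = i))
        list(gradients = grads, adc = adc,
             tags = list(direction = u, spoke = i, calibration = cal))
      }
    }))))
  ro_cal_dur <- {
    deph_area <- -(g * ns_to_ms(rise) / 2 + g * ns_to_ms(flat) / 2)
    dd <- make_trapezoid("read", area_mT_ms_m = deph_area, limits = limits)$duration_ns
    ceil_raster(dd + rise + flat + rise, limits$block_raster_ns)
  }
  ro_img_dur <- ceil_raster(rise + flat + rise, limits$block_raster_ns)
  bp_register(reg, exc$bp)
  bp_register(reg, ro_bp("ro_img", dirs_img, FALSE))
  bp_register(reg, ro_bp("ro_cal", dirs_cal, TRUE))
  bp_register(reg, bp_fill("fill_img", "fill_img_ns", function(x) x))
  bp_register(reg, bp_fill("fill_cal", "fill_cal_ns", function(x) x))
  bp_register(reg, blueprint("img_unit", children = c("exc", "ro_img", "fill_img")))
  bp_register(reg, blueprint("cal_unit", children = c("exc", "ro_cal", "fill_cal")))
  bp_register(reg, blueprint("spoke_loop",
                             loop = list(counter = "spoke_i", count = n_spokes),
                             children = "img_unit"))
  bp_register(reg, blueprint("cal_loop",
                             loop = list(counter = "cal_i", count = n_cal),
                             children = "cal_unit"))
  root_rules <- list(
    min_te_ms = rule(character(), local({
      v <- ns_to_ms(exc$dur_ns - exc$rf_center_ns); function() v
    })),
    min_tr_ms = rule(character(), local({
      v <- ns_to_ms(exc$dur_ns + ro_cal_dur); function() v
    })),
    fill_img_ns = rule("protocol.TR_ms", local({
      u <- exc$dur_ns + ro_img_dur
      function(tr) ms_to_ns(tr) - u
    })),
    fill_cal_ns = rule("protocol.TR_ms", local({
      u <- exc$dur_ns + ro_cal_dur
      function(tr) ms_to_ns(tr) - u
    })))
  bp_register(reg, blueprint("root", rules = root_rules,
                             children = c("cal_loop", "spoke_loop")))
  assemble(reg, "root", protocol, limits,
           meta = list(min_te_node = "root.min_te_ms",
                       min_tr_node = "root.min_tr_ms",
                       n_spokes = n_spokes, n_cal = n_cal,
                       directions = dirs_img, cal_directions = dirs_cal,
                       readout = list(g = g, rise_ns = rise, flat_ns = flat,
                                      dwell_ns = dwell_ns, n_samp = n_samp)))
}

# single-voxel spectroscopy: STEAM (90-90-90, stimulated echo at TE with a
# TM mixing period) and PRESS (90-180-180, spin echo at TE)
svs_common <- function(protocol, limits) {
  bw <- protocol$extras$spectral_bw_hz %||% 2000
  npts <- protocol$extras$data_points %||% 2048
  dwell_ns <- round(1e9 / bw)
  list(bw = bw, npts = npts, dwell_ns = dwell_ns,
       ws = bp_spectral_sat("wsup", limits, 0, duration_ms = 12))
}

svs_acq_bp <- function(name, npts, dwell_ns, prescans) {
  blueprint(name, atomic = TRUE, rules = list(
    raw = rule("repetition", local({
      npts <- npts; dwell_ns <- dwell_ns; prescans <- prescans
      function(rep) {
        flags <- if (rep < prescans) "is_prescan" else character()
        adc <- adc_event(0, npts, dwell_ns,
                         header = acq_header(average = max(0L, rep - prescans),
                                             flags = flags))
        list(adc = adc)
      }
    }))))
}

build_steam <- function(protocol, limits) {
  sv <- svs_common(protocol, limits)
  tm_ms <- protocol$extras$mixing_ms %||% 10
  vox <- protocol$fov_mm
  reg <- bp_registry()
  p1 <- bp_selective_rf("p1", "protocol.flip_deg", vox[1], duration_ms = 2,
                        limits = limits, axis = "read", sync_marked = TRUE)
  p2 <- bp_selective_rf("p2", "protocol.flip_deg", vox[2], duration_ms = 2,
                        limits = limits, axis = "phase")
  p3 <- bp_selective_rf("p3", "protocol.flip_deg", vox[3], duration_ms = 2,
                        limits = limits, axis = "slice")
  raster <- limits$block_raster_ns
  acq_dur <- ceil_raster(sv$npts * sv$dwell_ns, raster)
  min_te_ns <- 2 * ceil_raster(max((p1$dur_ns - p1$rf_center_ns) + p2$rf_center_ns,
                                   p3$dur_ns - p3$rf_center_ns), raster)
  min_tm_ns <- (p2$dur_ns - p2$rf_center_ns) + p3$rf_center_ns
  unit_fixed <- sv$ws$dur_ns + p1$dur_ns + p2$dur_ns + p3$dur_ns + acq_dur
  n_rep <- protocol$prescans + protocol$averages
  for (b in list(sv$ws$bp, p1$bp, p2$bp, p3$bp)) bp_register(reg, b)
  bp_register(reg, svs_acq_bp("acq", sv$npts, sv$dwell_ns, protocol$prescans))
  bp_register(reg, bp_fill("f1", "f1_ns", function(x) x))
  bp_register(reg, bp_fill("f_tm", "f_tm_ns", function(x) x))
  bp_register(reg, bp_fill("f2", "f2_ns", function(x) x))
  bp_register(reg, bp_fill("tr_fill", "tr_fill_ns", function(x) x))
  bp_register(reg, blueprint("rep_unit",
                             children = c("wsup", "p1", "f1", "p2", "f_tm", "p3",
                                          "f2", "acq", "tr_fill")))
  bp_register(reg, blueprint("rep_loop",
                             loop = list(counter = "repetition", count = n_rep),
                             children = "rep_unit"))
  root_rules <- list(
    min_te_ms = rule(character(), local({ v <- ns_to_ms(min_te_ns); function() v })),
    f1_ns = rule("protocol.TE_ms", local({
      off <- (p1$dur_ns - p1$rf_center_ns) + p2$rf_center_ns; r <- raster
      function(te) round((ms_to_ns(te) / 2 - off) / r) * r
    })),
    f_tm_ns = rule(character(), local({
      v <- max(0, round((ms_to_ns(tm_ms) - min_tm_ns) / raster) * raster)
      function() v
    })),
    f2_ns = rule("protocol.TE_ms", local({
      off <- p3$dur_ns - p3$rf_center_ns; r <- raster
      function(te) round((ms_to_ns(te) / 2 - off) / r) * r
    })),
    min_tr_ms = rule(c("f1_ns", "f_tm_ns", "f2_ns"), local({
      u <- unit_fixed
      function(f1, ftm, f2) ns_to_ms(u + max(f1, 0) + ftm + max(f2, 0))
    })),
    tr_fill_ns = rule(c("protocol.TR_ms", "f1_ns", "f_tm_ns", "f2_ns"), local({
      u <- unit_fixed
      function(tr, f1, ftm, f2) ms_to_ns(tr) - u - f1 - ftm - f2
    })))
  bp_register(reg, blueprint("root", rules = root_rules, children = "rep_loop"))
  assemble(reg, "root", protocol, limits,
           meta = list(min_te_node = "root.min_te_ms",
                       min_tr_node = "root.min_tr_ms",
                       n_repetitions = n_rep))
}

build_press <- function(protocol, limits) {
  sv <- svs_common(protocol, limits)
  vox <- protocol$fov_mm
  reg <- bp_registry()
  p1 <- bp_selective_rf("p1", "protocol.flip_deg", vox[1], duration_ms = 2,
                        limits = limits, axis = "read", sync_marked = TRUE)
  r1 <- bp_selective_rf("r1", "protocol.refocus_deg", vox[2], duration_ms = 3,
                        limits = limits, axis = "phase", purpose = "refocusing",
                        crusher_area = 10, rephase = FALSE,
                        phase_rule = list(deps = character(), fn = function() pi / 2))
  r2 <- bp_selective_rf("r2", "protocol.refocus_deg", vox[3], duration_ms = 3,
                        limits = limits, axis = "slice", purpose = "refocusing",
                        crusher_area = 10, rephase = FALSE,
                        phase_rule = list(deps = character(), fn = function() pi / 2))
  raster <- limits$block_raster_ns
  acq_dur <- ceil_raster(sv$npts * sv$dwell_ns, raster)
  # 90 at 0, first 180 at TE/4, echo1 at TE/2, second 180 at 3TE/4, echo at TE
  min_quarter <- max((p1$dur_ns - p1$rf_center_ns) + r1$rf_center_ns,
                     (r2$dur_ns - r2$rf_center_ns),
                     ((r1$dur_ns - r1$rf_center_ns) + r2$rf_center_ns) / 2)
  min_te_ns <- 4 * ceil_raster(min_quarter, raster)
  unit_fixed <- sv$ws$dur_ns + p1$dur_ns + r1$dur_ns + r2$dur_ns + acq_dur
  n_rep <- protocol$prescans + protocol$averages
  for (b in list(sv$ws$bp, p1$bp, r1$bp, r2$bp)) bp_register(reg, b)
  bp_register(reg, svs_acq_bp("acq", sv$npts, sv$dwell_ns, protocol$prescans))
  bp_register(reg, bp_fill("f1", "f1_ns", function(x) x))
  bp_register(reg, bp_fill("f2", "f2_ns", function(x) x))
  bp_register(reg, bp_fill("f3", "f3_ns", function(x) x))
  bp_register(reg, bp_fill("tr_fill", "tr_fill_ns", function(x) x))
  bp_register(reg, blueprint("rep_unit",
                             children = c("wsup", "p1", "f1", "r1", "f2", "r2",
                                          "f3", "acq", "tr_fill")))
  bp_register(reg, blueprint("rep_loop",
                             loop = list(counter = "repetition", count = n_rep),
                             children = "rep_unit"))
  root_rules <- list(
    min_te_ms = rule(character(), local({ v <- ns_to_ms(min_te_ns); function() v })),
    f1_ns = rule("protocol.TE_ms", local({
      off <- (p1$dur_ns - p1$rf_center_ns) + r1$rf_center_ns; r <- raster
      function(te) round((ms_to_ns(te) / 4 - off) / r) * r
    })),
    f2_ns = rule("protocol.TE_ms", local({
      off <- (r1$dur_ns - r1$rf_center_ns) + r2$rf_center_ns; r <- raster
      function(te) round((ms_to_ns(te) / 2 - off) / r) * r
    })),
    f3_ns = rule("protocol.TE_ms", local({
      off <- r2$dur_ns - r2$rf_center_ns; r <- raster
      function(te) round((ms_to_ns(te) / 4 - off) / r) * r
    })),
    min_tr_ms = rule(c("f1_ns", "f2_ns", "f3_ns"), local({
      u <- unit_fixed
      function(f1, f2, f3) ns_to_ms(u + max(f1, 0) + max(f2, 0) + max(f3, 0))
    })),
    tr_fill_ns = rule(c("protocol.TR_ms", "f1_ns", "f2_ns", "f3_ns"), local({
      u <- unit_fixed
      function(tr, f1, f2, f3) ms_to_ns(tr) - u - f1 - f2 - f3
    })))
  bp_register(reg, blueprint("root", rules = root_rules, children = "rep_loop"))
  assemble(reg, "root", protocol, limits,
           meta = list(min_te_node = "root.min_te_ms",
                       min_tr_node = "root.min_tr_ms",
                       n_repetitions = n_rep))
}
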