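# Family builders. Each composes shared blueprints (selective excitation,
# encoding, readout, spoiler, inversion, fat saturation, labeling) into a
# hierarchy and wires the per-iteration quantities (encoding amplitudes,
# fills, headers, RF phases) through the parameter graph, so loop counters
# and protocol/feedback updates invalidate exactly what they influence.
# Waveform shapes are synthesized once per assembly from the protocol.

trap_or_null <- function(axis, area, dur_ns, limits, start_ns = 0) {
  if (abs(area) < 1e-12) return(NULL)
  g <- make_trapezoid(axis, area_mT_ms_m = area, duration_ms = ns_to_ms(dur_ns),
                      limits = limits)
  g$start_ns <- start_ns
  g
}

# slice/slab-selective RF atomic with optional crushers, rephaser, extra
# gradients, per-iteration phase and position offset rules
bp_selective_rf <- function(name, flip_dep, thickness_mm, duration_ms = 1,
                            tbw = 4, limits, purpose = "excitation",
                            phase_rule = NULL, offset_rule = NULL,
                            crusher_area = 0, rephase = purpose == "excitation",
                            axis = "slice", extra_grads = list(),
                            sync_marked = FALSE) {
  rf0 <- make_rf("hann_sinc", duration_ms, 1, time_bandwidth = tbw,
                 purpose = purpose, limits = limits)
  ss <- make_slice_select(rf0, thickness_mm, limits = limits)
  crush <- if (crusher_area != 0)
    make_trapezoid(axis, area_mT_ms_m = crusher_area, limits = limits)
  crush_dur <- if (!is.null(crush)) crush$duration_ns else 0
  sel_start <- crush_dur
  rf_start <- sel_start + ss$rf_start_ns
  sel_end <- sel_start + ss$select$duration_ns
  tail_start <- sel_end   # rephaser / post-crusher / extra gradients
  tail_dur <- max(0,
                  if (rephase && !is.null(ss$rephaser)) ss$rephaser$duration_ns else 0,
                  crush_dur,
                  if (length(extra_grads))
                    max(vapply(extra_grads, function(g) g$start_ns + g$duration_ns,
                               numeric(1))) else 0)
  dur <- ceil_raster(tail_start + tail_dur, limits$block_raster_ns)
  n_phase <- length(phase_rule$deps %||% character())
  deps <- c(flip_dep, "protocol.slice_offset_mm",
            phase_rule$deps %||% character(), offset_rule$deps %||% character())
  raw_fn <- local({
    ss <- ss; limits <- limits; duration_ms <- duration_ms; tbw <- tbw
    purpose <- purpose; crush <- crush; sel_start <- sel_start
    rf_start <- rf_start; tail_start <- tail_start; dur <- dur
    rephase <- rephase; axis <- axis; extra_grads <- extra_grads
    phase_fn <- phase_rule$fn; offset_fn <- offset_rule$fn
    n_phase <- n_phase
    function(...) {
      a <- list(...)
      flip <- a[[1]]; off_mm <- a[[2]]
      if (!is.null(offset_fn)) {
        oa <- if (length(a) > 2 + n_phase) a[(3 + n_phase):length(a)] else list()
        off_mm <- off_mm + do.call(offset_fn, oa)
      }
      rf <- make_rf("hann_sinc", duration_ms, flip, time_bandwidth = tbw,
                    purpose = purpose, limits = limits)
      rf$start_ns <- rf_start
      rf$freq_hz <- limits$gamma * ss$plateau_mT_m * 1e-3 * off_mm * 1e-3
      if (!is.null(phase_fn)) {
        pa <- if (n_phase > 0) a[3:(2 + n_phase)] else list()
        rf$phase_rad <- do.call(phase_fn, pa)
      }
      sel <- ss$select; sel$axis <- axis; sel$start_ns <- sel_start
      grads <- list(sel)
      if (!is.null(crush)) {
        c1 <- crush; c1$start_ns <- 0
        c2 <- crush; c2$start_ns <- tail_start
        grads <- c(grads, list(c1, c2))
      }
      if (rephase && !is.null(ss$rephaser)) {
        rp <- ss$rephaser; rp$axis <- axis; rp$start_ns <- tail_start
        grads <- c(grads, list(rp))
      }
      for (g in extra_grads) {
        g$start_ns <- g$start_ns + tail_start
        grads <- c(grads, list(g))
      }
      list(duration_ns = dur, rf = rf, gradients = grads)
    }
  })
  list(bp = blueprint(name, rules = list(raw = rule(deps, raw_fn)),
                      atomic = TRUE, sync_marked = sync_marked),
       rf_center_ns = rf_start + rf0$center_frac * rf0$duration_ns,
       dur_ns = dur)
}

# Cartesian gradient-echo readout atomic: simultaneous prephasers, plateau
# with centered ADC, then rewinders ("balance") or spoiler ("spoil")
gre_readout_bp <- function(name, tabP, tabS, protocol, ro, dwell_ns, pe_dur_ns,
                           mode = c("spoil", "balance"), limits) {
  mode <- match.arg(mode)
  N <- protocol$matrix_size; fov <- protocol$fov_mm
  ro_dur <- ro$rise + ro$flat + ro$rise
  dur <- ceil_raster(2 * pe_dur_ns + ro_dur, limits$block_raster_ns)
  raw_fn <- local({
    tabP <- tabP; tabS <- tabS; N <- N; fov <- fov; ro <- ro
    dwell_ns <- dwell_ns; pe_dur_ns <- pe_dur_ns; mode <- mode
    limits <- limits; dur <- dur; ro_dur <- ro_dur
    function(li, pi_) {
      lrow <- tabP[li + 1L, ]; prow <- tabS[pi_ + 1L, ]
      aP <- pe_area(lrow$index, N[2], fov[2], limits$gamma)
      aS <- if (N[3] > 1) pe_area(prow$index, N[3], fov[3], limits$gamma) else 0
      t1 <- pe_dur_ns
      g_ro <- grad_trap("read", t1, ro$rise, ro$flat, ro$rise, ro$g)
      t2 <- t1 + ro_dur
      read_back <- if (mode == "spoil") ro$area else ro$preph_area
      flags <- character()
      if (isTRUE(lrow$is_reference) || isTRUE(prow$is_reference))
        flags <- "is_reference"
      adc <- adc_event(t1 + ro$rise, N[1], dwell_ns,
                       header = acq_header(line = lrow$index,
                                           partition = prow$index,
                                           flags = flags))
      list(duration_ns = dur,
           gradients = list(
             trap_or_null("read", ro$preph_area, pe_dur_ns, limits),
             trap_or_null("phase", aP, pe_dur_ns, limits),
             trap_or_null("slice", aS, pe_dur_ns, limits),
             g_ro,
             trap_or_null("read", read_back, pe_dur_ns, limits, t2),
             trap_or_null("phase", -aP, pe_dur_ns, limits, t2),
             trap_or_null("slice", -aS, pe_dur_ns, limits, t2)),
           adc = adc)
    }
  })
  list(bp = blueprint(name, rules = list(raw = rule(c("line_i", "part_i"), raw_fn)),
                      atomic = TRUE),
       dur_ns = dur, echo_center_ns = pe_dur_ns + ro$rise + ro$flat / 2)
}

# common geometry for the Cartesian gradient-echo families
gre_geometry <- function(protocol, limits, dwell_ns = 1e4) {
  N <- protocol$matrix_size; fov <- protocol$fov_mm
  tabP <- encoding_table(N[2], protocol$partial_fourier[1], protocol$acceleration[1],
                         reference_lines = protocol$extras$reference_lines %||% 0)
  tabS <- encoding_table(N[3], protocol$partial_fourier[2], protocol$acceleration[2],
                         reference_lines = 0)
  ro <- ro_template(N[1], fov[1], dwell_ns, limits)
  a_max <- max(abs(pe_area(0, N[2], fov[2], limits$gamma)),
               if (N[3] > 1) abs(pe_area(0, N[3], fov[3], limits$gamma)) else 0,
               abs(ro$preph_area), abs(ro$area))
  probe <- make_trapezoid("phase", area_mT_ms_m = a_max, limits = limits)
  pe_dur_ns <- probe$duration_ns
  list(tabP = tabP, tabS = tabS, ro = ro, pe_dur_ns = pe_dur_ns,
       nl = nrow(tabP), np = nrow(tabS), dwell_ns = dwell_ns)
}

build_cartesian_gre <- function(protocol, limits, mode, prep = FALSE) {
  g <- gre_geometry(protocol, limits)
  reg <- bp_registry()
  thickness <- if (protocol$matrix_size[3] > 1) protocol$fov_mm[3] else
    protocol$slice_thickness_mm
  phase_rule <- NULL
  if (mode == "balance") {
    nl <- g$nl; np <- g$np; presc <- protocol$prescans
    phase_rule <- list(deps = c("line_i", "part_i", "average"),
                       fn = function(l, p, a) {
                         pi * ((presc + ((a * np) + p) * nl + l) %% 2)
                       })
  }
  exc <- bp_selective_rf("exc", "protocol.flip_deg", thickness, limits = limits,
                         phase_rule = phase_rule, sync_marked = TRUE)
  rdo <- gre_readout_bp("readout", g$tabP, g$tabS, protocol, g$ro, g$dwell_ns,
                        g$pe_dur_ns, mode = mode, limits = limits)
  min_te_ns <- (exc$dur_ns - exc$rf_center_ns) + rdo$echo_center_ns
  unit_fixed_ns <- exc$dur_ns + rdo$dur_ns
  raster <- limits$block_raster_ns
  bp_register(reg, exc$bp)
  bp_register(reg, rdo$bp)
  bp_register(reg, bp_fill("te_fill", "te_fill_ns", function(x) x))
  bp_register(reg, bp_fill("tr_fill", "tr_fill_ns", function(x) x))
  bp_register(reg, blueprint("tr_unit",
                             children = c("exc", "te_fill", "readout", "tr_fill")))
  bp_register(reg, blueprint("line_loop", loop = list(counter = "line_i", count = g$nl),
                             children = "tr_unit"))
  bp_register(reg, blueprint("part_loop", loop = list(counter = "part_i", count = g$np),
                             children = "line_loop"))
  bp_register(reg, blueprint("avg_loop",
                             loop = list(counter = "average", count = "protocol.averages"),
                             children = "part_loop"))
  children <- "avg_loop"
  if (prep && protocol$prescans > 0) {
    npre <- protocol$prescans
    prep_exc <- bp_selective_rf("prep_exc", "prep_flip", thickness, limits = limits,
                                phase_rule = list(deps = "prep_i",
                                                  fn = function(i) pi * (i %% 2)))
    bp_register(reg, prep_exc$bp)
    bp_register(reg, bp_fill("prep_fill", c("protocol.TR_ms"), local({
      d <- prep_exc$dur_ns
      function(tr) ms_to_ns(tr) - d
    })))
    bp_register(reg, blueprint("prep_unit",
                               rules = list(prep_flip = rule(c("prep_i", "protocol.flip_deg"),
                                                            local({
                                                              npre <- npre
                                                              function(i, flip) flip * (i + 0.5) / npre
                                                            }))),
                               children = c("prep_exc", "prep_fill")))
    bp_register(reg, blueprint("prep_loop",
                               loop = list(counter = "prep_i", count = npre),
                               children = "prep_unit"))
    children <- c("prep_loop", children)
  }
  root_rules <- list(
    min_te_ms = rule(character(), local({
      v <- ns_to_ms(min_te_ns); function() v
    })),
    te_fill_ns = rule("protocol.TE_ms", local({
      m <- min_te_ns; r <- raster
      function(te) round((ms_to_ns(te) - m) / r) * r
    })),
    min_tr_ms = rule("te_fill_ns", local({
      u <- unit_fixed_ns; function(tf) ns_to_ms(u + max(tf, 0))
    })),
    tr_fill_ns = rule(c("protocol.TR_ms", "te_fill_ns"), local({
      u <- unit_fixed_ns
      function(tr, tf) ms_to_ns(tr) - u - tf
    })))
  bp_register(reg, blueprint("root", rules = root_rules, children = children))
  assemble(reg, "root", protocol, limits,
           meta = list(min_te_node = "root.min_te_ms",
                       min_tr_node = "root.min_tr_ms",
                       encoding = list(phase = g$tabP, partition = g$tabS)))
}

build_flash <- function(protocol, limits) {
  build_cartesian_gre(protocol, limits, mode = "spoil")
}

build_bssfp <- function(protocol, limits) {
  build_cartesian_gre(protocol, limits, mode = "balance", prep = TRUE)
}

build_mprage <- function(protocol, limits) {
  if (is.null(protocol$TI_ms)) stop("MPRAGE needs TI", call. = FALSE)
  g <- gre_geometry(protocol, limits)
  reg <- bp_registry()
  thickness <- protocol$fov_mm[3]
  exc <- bp_selective_rf("exc", "protocol.flip_deg", thickness, limits = limits,
                         sync_marked = TRUE)
  rdo <- gre_readout_bp("readout", g$tabP, g$tabS, protocol, g$ro, g$dwell_ns,
                        g$pe_dur_ns, mode = "spoil", limits = limits)
  inv <- bp_hard_rf("inv", "inv_flip", 5, limits, purpose = "inversion")
  min_te_ns <- (exc$dur_ns - exc$rf_center_ns) + rdo$echo_center_ns
  unit_fixed_ns <- exc$dur_ns + rdo$dur_ns
  raster <- limits$block_raster_ns
  nl <- g$nl
  bp_register(reg, exc$bp); bp_register(reg, rdo$bp); bp_register(reg, inv$bp)
  bp_register(reg, bp_fill("te_fill", "te_fill_ns", function(x) x))
  bp_register(reg, bp_fill("ti_fill", "ti_fill_ns", function(x) x))
  bp_register(reg, bp_fill("shot_fill", "shot_fill_ns", function(x) x))
  bp_register(reg, blueprint("flash_unit", children = c("exc", "te_fill", "readout")))
  bp_register(reg, blueprint("line_loop", loop = list(counter = "line_i", count = nl),
                             children = "flash_unit"))
  bp_register(reg, blueprint("shot_unit",
                             children = c("inv", "ti_fill", "line_loop", "shot_fill")))
  bp_register(reg, blueprint("part_loop", loop = list(counter = "part_i", count = g$np),
                             children = "shot_unit"))
  bp_register(reg, blueprint("avg_loop",
                             loop = list(counter = "average", count = "protocol.averages"),
                             children = "part_loop"))
  root_rules <- list(
    inv_flip = rule(character(), function() 180),
    min_te_ms = rule(character(), local({ v <- ns_to_ms(min_te_ns); function() v })),
    te_fill_ns = rule("protocol.TE_ms", local({
      m <- min_te_ns; r <- raster
      function(te) round((ms_to_ns(te) - m) / r) * r
    })),
    ti_fill_ns = rule("protocol.TI_ms", local({
      # TI: inversion center to first excitation center
      off <- (inv$dur_ns - inv$rf_center_ns) + exc$rf_center_ns; r <- raster
      function(ti) round((ms_to_ns(ti) - off) / r) * r
    })),
    min_tr_ms = rule(c("te_fill_ns", "ti_fill_ns"), local({
      u <- unit_fixed_ns; nl <- nl; inv_d <- inv$dur_ns
      function(tf, tif) ns_to_ms(inv_d + tif + nl * (u + tf))
    })),
    shot_fill_ns = rule(c("protocol.TR_ms", "te_fill_ns", "ti_fill_ns"), local({
      u <- unit_fixed_ns; nl <- nl; inv_d <- inv$dur_ns
      function(tr, tf, tif) ms_to_ns(tr) - inv_d - tif - nl * (u + tf)
    })))
  bp_register(reg, blueprint("root", rules = root_rules, children = "avg_loop"))
  assemble(reg, "root", protocol, limits,
           meta = list(min_te_node = "root.min_te_ms",
                       min_tr_node = "root.min_tr_ms",
                       encoding = list(phase = g$tabP, partition = g$tabS)))
}

# spin-echo train core shared by RARE and FLAIR: per slice, one excitation
# followed by `train` refocused echoes with per-echo phase encoding
se_train_parts <- function(protocol, limits, train) {
  N <- protocol$matrix_size; fov <- protocol$fov_mm
  tabP <- encoding_table(N[2], protocol$partial_fourier[1],
                         protocol$acceleration[1])
  nl <- nrow(tabP)
  nshots <- ceiling(nl / train)
  ro <- ro_template(N[1], fov[1], 1e4, limits)
  a_max <- max(abs(pe_area(0, N[2], fov[2], limits$gamma)), abs(ro$area))
  pe_dur_ns <- make_trapezoid("phase", area_mT_ms_m = a_max, limits = limits)$duration_ns
  nsl_total <- N[3]
  list(tabP = tabP, nl = nl, nshots = nshots, ro = ro, pe_dur_ns = pe_dur_ns,
       nsl_total = nsl_total)
}

# readout atomic of one spin echo: PE prephase, plateau + ADC, PE rewind
se_readout_bp <- function(name, parts, protocol, limits, slice_field = "slice_i") {
  N <- protocol$matrix_size; fov <- protocol$fov_mm
  ro <- parts$ro; pe_dur_ns <- parts$pe_dur_ns
  ro_dur <- ro$rise + ro$flat + ro$rise
  dur <- ceil_raster(2 * pe_dur_ns + ro_dur, limits$block_raster_ns)
  deps <- c("shot_i", "echo_i", slice_field)  # slice_field: physical slice id
  raw_fn <- local({
    tabP <- parts$tabP; train <- parts$train; N <- N; fov <- fov
    ro <- ro; pe_dur_ns <- pe_dur_ns; ro_dur <- ro_dur; dur <- dur
    limits <- limits; nl <- parts$nl; tl <- parts$train_len
    function(sh, e, sl) {
      li <- sh * tl + e
      lrow <- tabP[li + 1L, ]
      aP <- pe_area(lrow$index, N[2], fov[2], limits$gamma)
      t1 <- pe_dur_ns
      g_ro <- grad_trap("read", t1, ro$rise, ro$flat, ro$rise, ro$g)
      t2 <- t1 + ro_dur
      adc <- adc_event(t1 + ro$rise, N[1], 1e4,
                       header = acq_header(line = lrow$index, slice = sl,
                                           segment = e))
      list(duration_ns = dur,
           gradients = list(trap_or_null("phase", aP, pe_dur_ns, limits),
                            g_ro,
                            trap_or_null("phase", -aP, pe_dur_ns, limits, t2)),
           adc = adc)
    }
  })
  list(bp = blueprint(name, rules = list(raw = rule(deps, raw_fn)), atomic = TRUE),
       dur_ns = dur, echo_center_ns = pe_dur_ns + ro$rise + ro$flat / 2)
}

# Assemble the per-slice echo train: exc + read prephaser, then
# train x [fillA, refoc, fillB, readout]. Returns registration plus timing.
register_se_train <- function(reg, protocol, limits, parts, train,
                              slice_offset_rule, prefix = "",
                              slice_id_rule = rule("slice_i", function(s) s)) {
  parts$train <- train; parts$train_len <- train
  thickness <- protocol$slice_thickness_mm
  ro_pre <- make_trapezoid("read", area_mT_ms_m = -parts$ro$preph_area,
                           limits = limits)  # +A/2: refocusing flips it
  exc <- bp_selective_rf(paste0(prefix, "exc"), "protocol.flip_deg", thickness,
                         duration_ms = 2, limits = limits,
                         offset_rule = slice_offset_rule,
                         extra_grads = list(ro_pre), sync_marked = TRUE)
  refoc <- bp_selective_rf(paste0(prefix, "refoc"), "protocol.refocus_deg",
                           thickness, duration_ms = 3, limits = limits,
                           purpose = "refocusing",
                           crusher_area = 12, rephase = FALSE,
                           offset_rule = slice_offset_rule,
                           phase_rule = list(deps = character(), fn = function() pi / 2))
  rdo <- se_readout_bp(paste0(prefix, "readout"), parts, protocol, limits,
                       slice_field = "slice_id")
  raster <- limits$block_raster_ns
  exc_tail <- exc$dur_ns - exc$rf_center_ns
  half_min <- max(exc_tail + refoc$rf_center_ns,
                  (refoc$dur_ns - refoc$rf_center_ns) + rdo$echo_center_ns,
                  (rdo$dur_ns - rdo$echo_center_ns) + refoc$rf_center_ns)
  min_te_ns <- 2 * ceil_raster(half_min, raster)
  bp_register(reg, exc$bp); bp_register(reg, refoc$bp); bp_register(reg, rdo$bp)
  bp_register(reg, bp_fill(paste0(prefix, "fillA"),
                           c("echo_i", "esp_ns"), local({
    exc_tail <- exc_tail; rc <- refoc$rf_center_ns
    rt <- rdo$dur_ns - rdo$echo_center_ns
    function(e, esp) {
      if (e == 0) esp / 2 - exc_tail - rc else esp / 2 - rt - rc
    }
  })))
  bp_register(reg, bp_fill(paste0(prefix, "fillB"), "esp_ns", local({
    rtail <- refoc$dur_ns - refoc$rf_center_ns; ec <- rdo$echo_center_ns
    function(esp) esp / 2 - rtail - ec
  })))
  bp_register(reg, blueprint(paste0(prefix, "echo_unit"),
                             children = paste0(prefix, c("fillA", "refoc", "fillB", "readout"))))
  bp_register(reg, blueprint(paste0(prefix, "echo_loop"),
                             loop = list(counter = "echo_i", count = paste0(prefix, "n_echo")),
                             children = paste0(prefix, "echo_unit")))
  bp_register(reg, blueprint(paste0(prefix, "slice_unit"),
                             rules = list(slice_id = slice_id_rule),
                             children = paste0(prefix, c("exc", "echo_loop"))))
  # duration of one slice unit as a function of esp (for TR fill rules)
  unit_dur <- local({
    exc_d <- exc$dur_ns; refoc_d <- refoc$dur_ns; rdo_d <- rdo$dur_ns
    exc_tail <- exc_tail; rc <- refoc$rf_center_ns
    rt <- rdo$dur_ns - rdo$echo_center_ns
    rtail <- refoc$dur_ns - refoc$rf_center_ns; ec <- rdo$echo_center_ns
    train <- train
    function(esp, n_echo = train) {
      fA0 <- esp / 2 - exc_tail - rc
      fA <- esp / 2 - rt - rc
      fB <- esp / 2 - rtail - ec
      exc_d + (fA0 + refoc_d + fB + rdo_d) +
        (n_echo - 1) * (fA + refoc_d + fB + rdo_d)
    }
  })
  list(min_te_ns = min_te_ns, unit_dur = unit_dur,
       slice_unit = paste0(prefix, "slice_unit"))
}

build_rare <- function(protocol, limits) {
  train <- protocol$train_length[1]
  if (is.na(train)) stop("RARE needs train_length[1]", call. = FALSE)
  parts <- se_train_parts(protocol, limits, train)
  reg <- bp_registry()
  nsl <- parts$nsl_total
  gap <- protocol$fov_mm[3] / max(1, nsl)
  slice_off <- list(deps = "slice_i",
                    fn = local({ nsl <- nsl; gap <- gap
                      function(s) (s - (nsl - 1) / 2) * gap }))
  tr <- register_se_train(reg, protocol, limits, parts, train, slice_off)
  raster <- limits$block_raster_ns
  bp_register(reg, bp_fill("tr_fill", "tr_fill_ns", function(x) x))
  bp_register(reg, blueprint("slice_loop",
                             loop = list(counter = "slice_i", count = nsl),
                             children = tr$slice_unit))
  shot_rules <- list(
    n_echo = rule("shot_i", local({
      nl <- parts$nl; train <- train
      function(sh) min(train, nl - sh * train)
    })),
    tr_fill_ns = rule(c("protocol.TR_ms", "esp_ns", "n_echo"), local({
      f <- tr$unit_dur; nsl <- nsl
      function(tr_ms, esp, ne) ms_to_ns(tr_ms) - nsl * f(esp, ne)
    })))
  bp_register(reg, blueprint("shot_unit", rules = shot_rules,
                             children = c("slice_loop", "tr_fill")))
  bp_register(reg, blueprint("shot_loop",
                             loop = list(counter = "shot_i", count = parts$nshots),
                             children = "shot_unit"))
  bp_register(reg, blueprint("avg_loop",
                             loop = list(counter = "average", count = "protocol.averages"),
                             children = "shot_loop"))
  root_rules <- list(
    esp_ns = rule("protocol.TE_ms", function(te) ms_to_ns(te)),
    min_te_ms = rule(character(), local({
      v <- ns_to_ms(tr$min_te_ns); function() v
    })),
    min_tr_ms = rule("esp_ns", local({
      f <- tr$unit_dur; nsl <- nsl
      function(esp) ns_to_ms(nsl * f(esp))
    })))
  bp_register(reg, blueprint("root", rules = root_rules, children = "avg_loop"))
  assemble(reg, "root", protocol, limits,
           meta = list(min_te_node = "root.min_te_ms",
                       min_tr_node = "root.min_tr_ms",
                       train_length = c(train, NA),
                       encoding = list(phase = parts$tabP)))
}

build_flair <- function(protocol, limits) {
  train <- protocol$train_length[1]
  if (is.na(train) || is.null(protocol$TI_ms))
    stop("FLAIR needs train_length[1] and TI", call. = FALSE)
  n_concat <- protocol$extras$concatenations %||% 2
  parts <- se_train_parts(protocol, limits, train)
  reg <- bp_registry()
  nsl <- parts$nsl_total
  nslg <- ceiling(nsl / n_concat)
  gap <- protocol$fov_mm[3] / max(1, nsl)
  # interleaved slice groups: slice id = concat + n_concat * within-group
  slice_off <- list(deps = c("slice_i", "concat_i"),
                    fn = local({ nsl <- nsl; gap <- gap; nc <- n_concat
                      function(s, cc) ((cc + nc * s) - (nsl - 1) / 2) * gap }))
  tr <- register_se_train(reg, protocol, limits, parts, train, slice_off,
                          slice_id_rule = rule(c("slice_i", "concat_i"),
                                               local({ nc <- n_concat
                                                 function(s, cc) cc + nc * s })))
  inv <- bp_hard_rf("inv", "inv_flip", 10, limits, purpose = "inversion")
  bp_register(reg, inv$bp)
  bp_register(reg, bp_fill("ti_fill", "ti_fill_ns", function(x) x))
  bp_register(reg, bp_fill("tr_fill", "tr_fill_ns", function(x) x))
  bp_register(reg, blueprint("slice_loop",
                             loop = list(counter = "slice_i", count = "n_slice_grp"),
                             children = tr$slice_unit))
  bp_register(reg, blueprint("concat_unit",
                             rules = list(n_slice_grp = rule("concat_i", local({
                               nsl <- nsl; nc <- n_concat
                               function(cc) length(seq(cc, nsl - 1, by = nc))
                             }))),
                             children = c("inv", "ti_fill", "slice_loop")))
  bp_register(reg, blueprint("concat_loop",
                             loop = list(counter = "concat_i", count = n_concat),
                             children = "concat_unit"))
  shot_rules <- list(
    n_echo = rule("shot_i", local({
      nl <- parts$nl; train <- train
      function(sh) min(train, nl - sh * train)
    })),
    tr_fill_ns = rule(c("protocol.TR_ms", "esp_ns", "ti_fill_ns", "n_echo"), local({
      f <- tr$unit_dur; nsl <- nsl; nc <- n_concat; inv_d <- inv$dur_ns
      function(tr_ms, esp, tif, ne) ms_to_ns(tr_ms) - nc * (inv_d + tif) -
        nsl * f(esp, ne)
    })))
  bp_register(reg, blueprint("shot_unit", rules = shot_rules,
                             children = c("concat_loop", "tr_fill")))
  bp_register(reg, blueprint("shot_loop",
                             loop = list(counter = "shot_i", count = parts$nshots),
                             children = "shot_unit"))
  exc_center <- local({  # inversion center -> first excitation center
    inv_tail <- inv$dur_ns - inv$rf_center_ns
    inv_tail
  })
  raster <- limits$block_raster_ns
  root_rules <- list(
    inv_flip = rule(character(), function() 180),
    esp_ns = rule("protocol.TE_ms", function(te) ms_to_ns(te)),
    min_te_ms = rule(character(), local({
      v <- ns_to_ms(tr$min_te_ns); function() v
    })),
    ti_fill_ns = rule("protocol.TI_ms", local({
      off <- exc_center; r <- raster
      function(ti) round((ms_to_ns(ti) - off) / r) * r
    })),
    min_tr_ms = rule(c("esp_ns", "ti_fill_ns"), local({
      f <- tr$unit_dur; nsl <- nsl; nc <- n_concat; inv_d <- inv$dur_ns
      function(esp, tif) ns_to_ms(nc * (inv_d + tif) + nsl * f(esp))
    })))
  bp_register(reg, blueprint("root", rules = root_rules, children = "shot_loop"))
  assemble(reg, "root", protocol, limits,
           meta = list(min_te_node = "root.min_te_ms",
                       min_tr_node = "root.min_tr_ms",
                       train_length = c(train, NA),
                       encoding = list(phase = parts$tabP)))
}
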