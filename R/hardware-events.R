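#' Hardware event records
#'
#' The raw representation of one execution block is a small set of typed
#' hardware events: at most one RF pulse, up to three gradients on the
#' logical axes (read/phase/slice), and at most one ADC readout with its
#' acquisition header. All event times are block-relative integer
#' nanoseconds; block start times are absolute.
#'
#' @param start_ns event start, ns, relative to the block start.
#' @param samples complex (or real) envelope sampled on the RF raster,
#'   normalized so that `max(Mod(samples)) <= 1`.
#' @param amplitude_uT peak B1 amplitude in microtesla that scales `samples`.
#' @param freq_hz transmitter frequency offset, Hz.
#' @param phase_rad transmitter phase offset, rad.
#' @param center_frac position of the pulse's isodelay point as a fraction
#'   of its duration (0.5 for symmetric pulses).
#' @param purpose one of "excitation", "refocusing", "inversion",
#'   "saturation"; drives k-space bookkeeping in the virtual scanner.
#' @param flip_deg nominal on-resonance flip angle, degrees.
#' @param bandwidth_hz pulse bandwidth, Hz (used for slice-select scaling).
#' @param raster_ns RF sample raster, ns.
#' @return typed event records (`rf_event`, `gradient_event`, `adc_event`)
#'   or an `execution_block`.
#' @name hardware_events
NULL

#' @rdname hardware_events
#' @export
rf_event <- function(start_ns, samples, amplitude_uT, freq_hz = 0,
                     phase_rad = 0, center_frac = 0.5,
                     purpose = "excitation", flip_deg = NA_real_,
                     bandwidth_hz = NA_real_, raster_ns = RF_RASTER_NS) {
  samples <- as.complex(samples)
  stopifnot(start_ns >= 0, length(samples) >= 1)
  if (max(Mod(samples)) > 1 + 1e-12)
    stop("RF envelope must be normalized to |envelope| <= 1", call. = FALSE)
  structure(list(type = "rf", start_ns = round(start_ns),
                 duration_ns = length(samples) * raster_ns,
                 samples = samples, amplitude_uT = amplitude_uT,
                 freq_hz = freq_hz, phase_rad = phase_rad,
                 center_frac = center_frac, purpose = purpose,
                 flip_deg = flip_deg, bandwidth_hz = bandwidth_hz,
                 raster_ns = raster_ns),
            class = c("rf_event", "hw_event"))
}

#' @rdname hardware_events
#' @param axis logical axis: "read", "phase" or "slice" (or physical "x",
#'   "y", "z" after [logical_to_physical()]).
#' @param rise_ns,flat_ns,fall_ns trapezoid segment durations, ns, multiples
#'   of the gradient raster.
#' @param amp_mT_m plateau amplitude, mT/m.
#' @export
grad_trap <- function(axis, start_ns, rise_ns, flat_ns, fall_ns, amp_mT_m) {
  stopifnot(start_ns >= 0, rise_ns >= 0, flat_ns >= 0, fall_ns >= 0)
  structure(list(type = "grad", kind = "trap", axis = axis,
                 start_ns = round(start_ns), rise_ns = round(rise_ns),
                 flat_ns = round(flat_ns), fall_ns = round(fall_ns),
                 amp_mT_m = amp_mT_m,
                 duration_ns = round(rise_ns + flat_ns + fall_ns)),
            class = c("gradient_event", "hw_event"))
}

#' @rdname hardware_events
#' @param samples_mT_m arbitrary waveform sampled on the gradient raster.
#' @export
grad_wave <- function(axis, start_ns, samples_mT_m, raster_ns = GRAD_RASTER_NS) {
  stopifnot(start_ns >= 0, length(samples_mT_m) >= 1)
  structure(list(type = "grad", kind = "wave", axis = axis,
                 start_ns = round(start_ns), samples_mT_m = samples_mT_m,
                 raster_ns = raster_ns,
                 duration_ns = length(samples_mT_m) * raster_ns),
            class = c("gradient_event", "hw_event"))
}

#' @rdname hardware_events
#' @param n number of ADC samples.
#' @param dwell_ns dwell time per sample, ns.
#' @param header an [acq_header()].
#' @export
adc_event <- function(start_ns, n, dwell_ns, freq_hz = 0, phase_rad = 0,
                      header = acq_header()) {
  stopifnot(start_ns >= 0, n >= 1, dwell_ns > 0)
  structure(list(type = "adc", start_ns = round(start_ns), n = as.integer(n),
                 dwell_ns = dwell_ns, duration_ns = round(n * dwell_ns),
                 freq_hz = freq_hz, phase_rad = phase_rad, header = header),
            class = c("adc_event", "hw_event"))
}

#' Acquisition header
#'
#' Per-readout counters and flags exposed to the reconstruction, following
#' the ISMRMRD counter vocabulary (line, partition, slice, average, set,
#' repetition, contrast, segment).
#'
#' @param line,partition,slice,average,set,repetition,contrast,segment
#'   non-negative integer counters.
#' @param flags character vector, e.g. "is_prescan", "is_reference",
#'   "first_in_slice", "last_in_measurement".
#' @param trajectory_id integer id linking the readout to a trajectory
#'   description (e.g. radial spoke index).
#' @export
acq_header <- function(line = 0, partition = 0, slice = 0, average = 0,
                       set = 0, repetition = 0, contrast = 0, segment = 0,
                       flags = character(), trajectory_id = 0) {
  h <- list(line = line, partition = partition, slice = slice,
            average = average, set = set, repetition = repetition,
            contrast = contrast, segment = segment, flags = flags,
            trajectory_id = trajectory_id)
  cnt <- unlist(h[c("line", "partition", "slice", "average", "set",
                    "repetition", "contrast", "segment")])
  if (any(cnt < 0)) stop("header counters must be >= 0", call. = FALSE)
  # record which fields the caller set explicitly, so loop counters only
  # fill the rest at block-build time
  set_fields <- setdiff(names(as.list(match.call()))[-1], "")
  structure(h, class = "acq_header", set_fields = set_fields)
}

event_end_ns <- function(ev) ev$start_ns + ev$duration_ns

#' Execution block
#'
#' One atomic sequence element compiled to hardware: an absolute start time,
#' a duration rounded up to the block raster, and the contained events. The
#' `sync` flag marks the block as a feedback sync point of interest (e.g.
#' slice excitation under motion feedback).
#'
#' @param start_ns absolute start time, ns.
#' @param duration_ns block duration, ns; defaults to the latest event end,
#'   rounded up to the block raster.
#' @param rf an [rf_event()] or NULL.
#' @param gradients list of gradient events.
#' @param adc an [adc_event()] or NULL.
#' @param sync logical sync-point marker.
#' @param tags free-form named list of metadata (labeling role, diffusion
#'   weighting, spoke direction, ...); not part of the hardware contract.
#' @param block_raster_ns block duration granularity, ns.
#' @export
execution_block <- function(start_ns, duration_ns = NULL, rf = NULL,
                            gradients = list(), adc = NULL, sync = FALSE,
                            tags = list(), block_raster_ns = BLOCK_RASTER_NS) {
  gradients <- gradients[!vapply(gradients, is.null, logical(1))]
  evs <- c(if (!is.null(rf)) list(rf), gradients, if (!is.null(adc)) list(adc))
  if (any(vapply(evs, function(e) e$start_ns < 0, logical(1))))
    stop("event with negative start time", call. = FALSE)
  ev_end <- if (length(evs)) max(vapply(evs, event_end_ns, numeric(1))) else 0
  if (is.null(duration_ns)) {
    duration_ns <- ceil_raster(ev_end, block_raster_ns)
  } else {
    duration_ns <- ceil_raster(duration_ns, block_raster_ns)
    if (ev_end > duration_ns + 1e-6)
      stop("event exceeds block duration (", ev_end, " > ", duration_ns, " ns)",
           call. = FALSE)
  }
  structure(list(start_ns = round(start_ns), duration_ns = duration_ns,
                 rf = rf, gradients = gradients, adc = adc, sync = isTRUE(sync),
                 tags = tags),
            class = "execution_block")
}

#' @export
print.execution_block <- function(x, ...) {
  cat(sprintf("<execution_block> t = %.3f ms, dur = %.3f ms%s%s%s%s\n",
              ns_to_ms(x$start_ns), ns_to_ms(x$duration_ns),
              if (!is.null(x$rf)) sprintf(", RF %s %.0f deg", x$rf$purpose, x$rf$flip_deg) else "",
              if (length(x$gradients)) sprintf(", %d grad", length(x$gradients)) else "",
              if (!is.null(x$adc)) sprintf(", ADC %d", x$adc$n) else "",
              if (x$sync) ", sync" else ""))
  invisible(x)
}

# rasterized gradient samples of one event on its raster, mT/m (sample i
# covers [start + (i-1) raster, start + i raster); trapezoids evaluated at
# mid-sample)
grad_samples <- function(g, raster_ns = GRAD_RASTER_NS) {
  if (g$kind == "wave") return(g$samples_mT_m)
  nt <- round(g$duration_ns / raster_ns)
  if (nt == 0) return(numeric())
  t_mid <- (seq_len(nt) - 0.5) * raster_ns
  amp_at <- function(t) {
    ifelse(t < g$rise_ns,
           if (g$rise_ns > 0) g$amp_mT_m * t / g$rise_ns else g$amp_mT_m,
           ifelse(t < g$rise_ns + g$flat_ns, g$amp_mT_m,
                  ifelse(t < g$duration_ns & g$fall_ns > 0,
                         g$amp_mT_m * (g$duration_ns - t) / g$fall_ns, 0)))
  }
  amp_at(t_mid)
}

# exact integral of a gradient event over absolute times [t0, t1] (ns),
# result in mT/m * ns; event placed at block-relative start, caller passes
# block-relative t0/t1
grad_area_ns <- function(g, t0, t1) {
  t0 <- max(t0, g$start_ns); t1 <- min(t1, g$start_ns + g$duration_ns)
  if (t1 <= t0) return(0)
  if (g$kind == "wave") {
    # piecewise-constant samples
    s0 <- t0 - g$start_ns; s1 <- t1 - g$start_ns
    i0 <- floor(s0 / g$raster_ns); i1 <- ceiling(s1 / g$raster_ns)
    a <- 0
    for (i in seq(i0, i1 - 1)) {
      lo <- max(s0, i * g$raster_ns); hi <- min(s1, (i + 1) * g$raster_ns)
      if (hi > lo) a <- a + g$samples_mT_m[i + 1] * (hi - lo)
    }
    return(a)
  }
  # trapezoid: integrate the piecewise-linear amplitude exactly
  amp_at <- function(t) {
    if (t <= 0) return(0)
    if (t < g$rise_ns) return(g$amp_mT_m * t / g$rise_ns)
    if (t <= g$rise_ns + g$flat_ns) return(g$amp_mT_m)
    if (t < g$duration_ns) return(g$amp_mT_m * (g$duration_ns - t) / g$fall_ns)
    0
  }
  s0 <- t0 - g$start_ns; s1 <- t1 - g$start_ns
  brk <- sort(unique(pmin(pmax(c(s0, g$rise_ns, g$rise_ns + g$flat_ns,
                                 g$duration_ns, s1), s0), s1)))
  a <- 0
  for (i in seq_len(length(brk) - 1)) {
    lo <- brk[i]; hi <- brk[i + 1]
    a <- a + (amp_at(lo) + amp_at(hi)) / 2 * (hi - lo)  # linear within piece
  }
  a
}

#' Validate one execution block against hardware limits
#'
#' Checks event containment, gradient amplitude and slew-rate limits, raster
#' alignment, and RF/ADC overlap. Violations are reported, not raised.
#'
#' @param block an [execution_block()].
#' @param limits a [hardware_limits()].
#' @return character vector of violation messages; empty when compliant.
#' @export
validate_block <- function(block, limits = hardware_limits()) {
  v <- character()
  evs <- c(if (!is.null(block$rf)) list(block$rf), block$gradients,
           if (!is.null(block$adc)) list(block$adc))
  for (e in evs) {
    if (event_end_ns(e) > block$duration_ns + 1e-6)
      v <- c(v, sprintf("%s event ends after block end", e$type))
  }
  for (g in block$gradients) {
    if (g$kind == "trap") {
      if (abs(g$amp_mT_m) > limits$g_max + 1e-9)
        v <- c(v, sprintf("gradient amplitude %.3f mT/m on %s axis exceeds Gmax %.3f",
                          abs(g$amp_mT_m), g$axis, limits$g_max))
      for (r in c(g$rise_ns, g$fall_ns)) {
        if (r > 0 && abs(g$amp_mT_m) / ns_to_ms(r) > limits$slew + 1e-9)
          v <- c(v, sprintf("gradient slew %.1f mT/m/ms on %s axis exceeds limit %.1f",
                            abs(g$amp_mT_m) / ns_to_ms(r), g$axis, limits$slew))
      }
      if (g$rise_ns == 0 && g$flat_ns > 0 && abs(g$amp_mT_m) > 0)
        v <- c(v, sprintf("instantaneous gradient step on %s axis", g$axis))
    } else {
      s <- g$samples_mT_m
      if (max(abs(s)) > limits$g_max + 1e-9)
        v <- c(v, sprintf("gradient amplitude %.3f mT/m on %s axis exceeds Gmax %.3f",
                          max(abs(s)), g$axis, limits$g_max))
      sl <- max(abs(diff(c(0, s, 0)))) / ns_to_ms(g$raster_ns)
      if (sl > limits$slew + 1e-9)
        v <- c(v, sprintf("gradient slew %.1f mT/m/ms on %s axis exceeds limit %.1f",
                          sl, g$axis, limits$slew))
    }
  }
  if (!is.null(block$rf) && !is.null(block$adc)) {
    r <- block$rf; a <- block$adc
    if (r$start_ns < event_end_ns(a) && a$start_ns < event_end_ns(r))
      v <- c(v, "RF and ADC events overlap in time")
  }
  if (!is.null(block$rf) && block$rf$amplitude_uT > limits$b1_max_uT + 1e-9)
    v <- c(v, sprintf("RF amplitude %.2f uT exceeds B1 ceiling %.2f uT",
                      block$rf$amplitude_uT, limits$b1_max_uT))
  v
}

#' Rotate a block from logical to physical axes
#'
#' Applies the slice orientation (a proper rotation) and off-isocenter
#' position. Gradient vectors are rotated; the RF frequency is offset by
#' gamma * G_slice * offset_along_slice so the excited slab follows the
#' requested position; the ADC demodulation frequency is offset analogously
#' for the readout axis (off-center FOV handled at the receiver, not baked
#' into raw samples).
#'
#' @param block an [execution_block()] with gradients on logical axes.
#' @param rotation 3x3 proper rotation matrix (columns: physical directions
#'   of the logical read/phase/slice axes).
#' @param offset_mm off-isocenter position, mm, in physical coordinates.
#' @param gamma gyromagnetic ratio, Hz/T.
#' @return the block with gradients on physical axes "x","y","z".
#' @export
logical_to_physical <- function(block, rotation = diag(3), offset_mm = c(0, 0, 0),
                                gamma = GAMMA_HZ_PER_T) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 || abs(det(rotation) - 1) > 1e-9)
    stop("orientation must be a proper rotation (orthonormal, det = +1)", call. = FALSE)
  if (identical(dim(rotation), c(3L, 3L)) && max(abs(rotation - diag(3))) == 0 &&
      all(offset_mm == 0))
    return(block)
  ax_index <- c(read = 1L, phase = 2L, slice = 3L)
  offset_logical_mm <- as.numeric(crossprod(rotation, offset_mm))

  rf <- block$rf
  slice_amp <- 0
  for (g in block$gradients) if (identical(g$axis, "slice") && g$kind == "trap")
    slice_amp <- g$amp_mT_m
  if (!is.null(rf) && slice_amp != 0) {
    # f = gamma [Hz/T] * G [T/m] * dz [m]
    rf$freq_hz <- rf$freq_hz + gamma * slice_amp * 1e-3 * offset_logical_mm[3] * 1e-3
  }
  adc <- block$adc
  read_amp <- 0
  for (g in block$gradients) if (identical(g$axis, "read") && g$kind == "trap")
    read_amp <- g$amp_mT_m
  if (!is.null(adc) && read_amp != 0) {
    adc$freq_hz <- adc$freq_hz + gamma * read_amp * 1e-3 * offset_logical_mm[1] * 1e-3
  }

  gl <- block$gradients
  if (!length(gl)) {
    out <- block; out$rf <- rf; out$adc <- adc
    return(out)
  }
  # identical-timing trapezoids rotate exactly; otherwise rasterize
  timings <- unique(lapply(gl, function(g)
    if (g$kind == "trap") c(g$start_ns, g$rise_ns, g$flat_ns, g$fall_ns) else NULL))
  phys <- list()
  if (length(timings) == 1 && !is.null(timings[[1]])) {
    amps <- c(0, 0, 0)
    for (g in gl) amps[ax_index[[g$axis]]] <- g$amp_mT_m
    pa <- as.numeric(rotation %*% amps)
    for (i in 1:3) if (abs(pa[i]) > 0) {
      g0 <- gl[[1]]
      phys[[length(phys) + 1]] <- grad_trap(c("x", "y", "z")[i], g0$start_ns,
                                            g0$rise_ns, g0$flat_ns, g0$fall_ns, pa[i])
    }
  } else {
    raster <- GRAD_RASTER_NS
    t0 <- min(vapply(gl, function(g) g$start_ns, numeric(1)))
    t0 <- floor(t0 / raster) * raster
    t1 <- max(vapply(gl, event_end_ns, numeric(1)))
    nt <- ceiling((t1 - t0) / raster)
    L <- matrix(0, 3, nt)
    for (g in gl) {
      s <- grad_samples(g, raster)
      i0 <- round((g$start_ns - t0) / raster)
      idx <- seq_len(length(s)) + i0
      L[ax_index[[g$axis]], idx] <- L[ax_index[[g$axis]], idx] + s
    }
    P <- rotation %*% L
    for (i in 1:3) if (any(abs(P[i, ]) > 1e-12)) {
      phys[[length(phys) + 1]] <- grad_wave(c("x", "y", "z")[i], t0, P[i, ], raster)
    }
  }
  out <- block
  out$rf <- rf; out$adc <- adc; out$gradients <- phys
  out
}
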