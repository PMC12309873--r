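#' Walsh-ordered Hadamard matrix
#'
#' Sylvester-Hadamard matrix with rows reordered by sign-change count
#' (sequency order): the first row is all +1 and the number of sign changes
#' increases strictly down the rows. Rows 2..n time-encode n-1 subboli in n
#' label/control acquisitions.
#'
#' @param n order (power of 2).
#' @export
hadamard_walsh <- function(n = 8) {
  stopifnot(n >= 1, bitwAnd(n, n - 1L) == 0)
  H <- matrix(1, 1, 1)
  while (nrow(H) < n) H <- rbind(cbind(H, H), cbind(H, -H))
  sc <- apply(H, 1, function(r) sum(diff(r) != 0))
  H[order(sc), , drop = FALSE]
}

#' Hadamard time-encoded ASL specification
#'
#' @param encoding Walsh-ordered +/-1 matrix, default Hadamard-8.
#' @param subbolus_s subbolus duration, s.
#' @param pld_s post-labeling delay, s.
#' @param bs_T1_ms T1 values nulled by background suppression, ms.
#' @export
asl_spec <- function(encoding = hadamard_walsh(8), subbolus_s = 0.4,
                     pld_s = 0.6, bs_T1_ms = c(700, 1400)) {
  H <- encoding
  if (max(abs(H %*% t(H) - nrow(H) * diag(nrow(H)))) > 1e-9)
    stop("encoding matrix must be orthogonal with H t(H) = n I", call. = FALSE)
  if (any(H[1, ] != 1)) stop("first encoding row must be all +1", call. = FALSE)
  structure(list(encoding = H, subbolus_s = subbolus_s, pld_s = pld_s,
                 bs_T1_ms = bs_T1_ms), class = "asl_spec")
}

#' Labeling train for one Hadamard encode
#'
#' Maps columns 2..n of the chosen encoding row onto the temporal subboli
#' (earliest subbolus first). +1 segments label, -1 segments act as
#' control; the train is followed by the post-labeling delay.
#'
#' @param spec an [asl_spec()].
#' @param encode_index row of the encoding matrix (1..n).
#' @return data.frame with `subbolus`, `start_s`, `duration_s`, `role`.
#' @export
hadamard_label_train <- function(spec, encode_index) {
  H <- spec$encoding
  stopifnot(encode_index >= 1, encode_index <= nrow(H))
  n_sub <- ncol(H) - 1L
  sgn <- H[encode_index, -1L]
  data.frame(subbolus = seq_len(n_sub),
             start_s = (seq_len(n_sub) - 1) * spec$subbolus_s,
             duration_s = spec$subbolus_s,
             role = ifelse(sgn > 0, "label", "control"))
}

#' Inflow times of the Hadamard subboli
#'
#' Subbolus k (k = 1 the earliest labeled) finishes `(n_sub - k)` subbolus
#' durations before the end of the train, so its inflow time at readout is
#' `PLD + (n_sub - k + 1) * subbolus` — a ladder from
#' `PLD + subbolus` up to `PLD + n_sub * subbolus` in subbolus steps.
#'
#' @param spec an [asl_spec()].
#' @return numeric vector of inflow times, s, for subbolus k = 1..n_sub.
#' @export
asl_inflow_times <- function(spec) {
  n_sub <- ncol(spec$encoding) - 1L
  spec$pld_s + (n_sub - seq_len(n_sub) + 1) * spec$subbolus_s
}

# two-inversion background suppression: times (s before readout) at which
# ideal inversions null both stated T1 species at readout, solved from the
# closed-form longitudinal recovery with label-train start as saturation
bs_inversion_times <- function(T1_ms, window_s, max_before_s = window_s,
                               min_before_s = 0, gap_s = 0) {
  T1 <- T1_ms / 1000
  f <- function(ti) {
    vapply(T1, function(t1) {
      m <- 1 - exp(-(window_s - ti[1]) / t1)   # recovery after saturation
      m <- 1 - (1 + m) * exp(-(ti[1] - ti[2]) / t1)  # inversion, recovery
      m <- 1 - (1 + m) * exp(-ti[2] / t1)            # inversion, recovery
      m
    }, numeric(1))
  }
  lo <- min_before_s / max_before_s
  gap <- gap_s / max_before_s
  opt <- stats::optim(c(min(0.8, lo + 3 * gap + 0.3), lo + gap + 0.1),
                      function(x) {
    if (x[1] <= x[2] + gap || x[2] <= lo || x[1] >= 1) return(1e6)
    sum(f(x * max_before_s)^2)
  }, method = "Nelder-Mead")
  opt$par * max_before_s
}

# ---- shared geometry helpers ------------------------------------------

# phase-encode area (mT/m*ms) putting k at (index - N/2)/FOV
pe_area <- function(index, n, fov_mm, gamma = GAMMA_HZ_PER_T) {
  k <- (index - n / 2) / (fov_mm * 1e-3)   # 1/m
  k / gamma * 1e6
}

# readout template: prephaser + plateau with centered ADC
ro_template <- function(n_samples, fov_mm, dwell_ns, limits) {
  g_T_m <- 1 / ((fov_mm * 1e-3) * limits$gamma * dwell_ns * 1e-9)
  g <- g_T_m * 1e3
  if (g > limits$g_max)
    stop(sprintf("readout gradient %.1f mT/m exceeds Gmax (increase dwell)", g),
         call. = FALSE)
  rise <- ceil_raster(ms_to_ns(g / limits$slew), limits$grad_raster_ns)
  flat <- ceil_raster(n_samples * dwell_ns, limits$grad_raster_ns)
  area <- g * ns_to_ms(flat + rise)
  list(g = g, rise = rise, flat = flat, area = area,
       preph_area = -(g * ns_to_ms(flat) / 2 + g * ns_to_ms(rise) / 2))
}

seq_error_extras <- function(protocol, needed, family) {
  missing <- setdiff(needed, names(protocol$extras))
  if (length(missing))
    stop("protocol misses ", family, " extras: ", paste(missing, collapse = ", "),
         call. = FALSE)
}

#' Build a sequence of a library family
#'
#' Assembles the blueprint hierarchy of one of the implemented sequence
#' families for a protocol, shares the excitation / encoding / readout /
#' spoiler / inversion / fat-saturation / labeling building blocks across
#' families, and verifies feasibility. If the requested TR is below the
#' feasible minimum it is extended to the minimum with a warning (the one
#' built-in solve handler).
#'
#' @param family one of "flash", "bssfp", "mprage", "rare", "flair",
#'   "se_epi_diffusion", "grase_pcasl", "radial_ute", "steam", "press".
#' @param protocol an [mr_protocol()]; family-specific extras are listed in
#'   the vignette.
#' @param limits a [hardware_limits()].
#' @return an `mr_sequence`.
#' @export
build_sequence <- function(family = c("flash", "bssfp", "mprage", "rare",
                                      "flair", "se_epi_diffusion",
                                      "grase_pcasl", "radial_ute", "steam",
                                      "press"),
                           protocol, limits = hardware_limits()) {
  family <- match.arg(family)
  builder <- switch(family,
    flash = build_flash, bssfp = build_bssfp, mprage = build_mprage,
    rare = build_rare, flair = build_flair,
    se_epi_diffusion = build_se_epi_diffusion,
    grase_pcasl = build_grase_pcasl, radial_ute = build_radial_ute,
    steam = build_steam, press = build_press)
  seq <- builder(protocol, limits)
  seq$meta$family <- family
  # solve handler: extend an infeasible TR to the minimum
  if (!is.null(seq$meta$min_tr_node)) {
    min_tr <- pg_eval(seq$graph, seq$meta$min_tr_node)
    if (protocol$TR_ms < min_tr - 1e-9) {
      warning(sprintf("TR %.3f ms below minimum; extended to %.3f ms",
                      protocol$TR_ms, min_tr), call. = FALSE)
      pg_update(seq$graph, "protocol.TR_ms", min_tr)
      seq$protocol$TR_ms <- min_tr
    }
  }
  seq
}

# slice/slab-selective excitation atomic; freq responds to the exposed
# slice offset so geometry feedback reaches the hardware events
bp_excite <- function(name, flip_dep = "protocol.flip_deg", thickness_mm,
                      duration_ms = 1, tbw = 4, limits, purpose = "excitation",
                      phase_rule = NULL, sync_marked = FALSE,
                      axis = "slice") {
  rf0 <- make_rf("hann_sinc", duration_ms, 1, time_bandwidth = tbw,
                 purpose = purpose, limits = limits)
  ss <- make_slice_select(rf0, thickness_mm, limits = limits)
  deps <- c(flip_dep, "protocol.slice_offset_mm")
  if (!is.null(phase_rule)) deps <- c(deps, phase_rule$deps)
  rules <- list(raw = rule(deps, local({
    ss <- ss; limits <- limits; duration_ms <- duration_ms; tbw <- tbw
    purpose <- purpose; phase_fn <- phase_rule$fn; axis <- axis
    function(flip, offset_mm, ...) {
      rf <- make_rf("hann_sinc", duration_ms, flip, time_bandwidth = tbw,
                    purpose = purpose, limits = limits)
      rf$start_ns <- ss$rf_start_ns
      rf$freq_hz <- limits$gamma * ss$plateau_mT_m * 1e-3 * offset_mm * 1e-3
      if (!is.null(phase_fn)) rf$phase_rad <- phase_fn(...)
      sel <- ss$select; reph <- ss$rephaser
      sel$axis <- axis
      t1 <- event_end_ns(sel)
      if (!is.null(reph)) { reph$axis <- axis; reph$start_ns <- t1 }
      dur <- if (!is.null(reph)) event_end_ns(reph) else t1
      list(duration_ns = dur, rf = rf, gradients = list(sel, reph))
    }
  })))
  list(bp = blueprint(name, rules = rules, atomic = TRUE,
                      sync_marked = sync_marked),
       rf_center_ns = ss$rf_start_ns + 0.5 * rf0$duration_ns,
       dur_ns = ceil_raster(event_end_ns(ss$select) +
                              (if (!is.null(ss$rephaser)) ss$rephaser$duration_ns else 0),
                            limits$block_raster_ns))
}

# hard-pulse atomic (non-selective excitation / refocusing / inversion)
bp_hard_rf <- function(name, flip_dep, duration_ms, limits,
                       purpose = "excitation", phase_rad = 0) {
  rules <- list(raw = rule(flip_dep, local({
    duration_ms <- duration_ms; limits <- limits
    purpose <- purpose; phase_rad <- phase_rad
    function(flip) {
      rf <- make_rf("hard", duration_ms, flip, purpose = purpose,
                    phase_rad = phase_rad, limits = limits)
      list(duration_ns = rf$duration_ns, rf = rf)
    }
  })))
  list(bp = blueprint(name, rules = rules, atomic = TRUE),
       rf_center_ns = 0.5 * ms_to_ns(duration_ms),
       dur_ns = ceil_raster(ms_to_ns(duration_ms), limits$block_raster_ns))
}

# pure delay atomic whose duration comes from a rule
bp_fill <- function(name, deps, fn) {
  blueprint(name, atomic = TRUE,
            rules = list(raw = rule(deps, local({
              fn <- fn
              function(...) list(duration_ns = fn(...))
            }))))
}

# spectrally selective saturation (fat sat at -3.35 ppm, or water
# suppression at 0 offset) followed by a spoiler
bp_spectral_sat <- function(name, limits, freq_hz, duration_ms = 8) {
  rf <- make_rf("gauss", duration_ms, 90, time_bandwidth = 2,
                purpose = "saturation", limits = limits)
  rf$freq_hz <- freq_hz
  spoil <- make_trapezoid("slice", area_mT_ms_m = 30, limits = limits)
  spoil$start_ns <- ceil_raster(rf$duration_ns, limits$grad_raster_ns)
  dur <- event_end_ns(spoil)
  list(bp = blueprint(name, atomic = TRUE,
                      rules = list(raw = rule(character(), local({
                        rf <- rf; spoil <- spoil; dur <- dur
                        function() list(duration_ns = dur, rf = rf,
                                        gradients = list(spoil))
                      })))),
       dur_ns = ceil_raster(dur, limits$block_raster_ns))
}

fat_offset_hz <- function(limits, b0_T = 3) -3.35e-6 * limits$gamma * b0_T

fov_of <- function(protocol, i) protocol$fov_mm[i]

#' Derived timing summary
#'
#' Prints and returns the derived quantities of an assembled sequence:
#' minimum TE/TR, total duration, number of blocks and readouts, and the
#' train lengths where defined.
#'
#' @param seq an `mr_sequence`.
#' @export
describe_sequence <- function(seq) {
  out <- list(family = seq$meta$family)
  if (!is.null(seq$meta$min_te_node))
    out$min_TE_ms <- pg_eval(seq$graph, seq$meta$min_te_node)
  if (!is.null(seq$meta$min_tr_node))
    out$min_TR_ms <- pg_eval(seq$graph, seq$meta$min_tr_node)
  out$train_length <- seq$meta$train_length
  blocks <- stream_collect(seq)
  out$n_blocks <- length(blocks)
  out$n_readouts <- sum(vapply(blocks, function(b) !is.null(b$adc), logical(1)))
  out$duration_s <- ns_to_s(utils::tail(blocks, 1)[[1]]$start_ns +
                              utils::tail(blocks, 1)[[1]]$duration_ns)
  class(out) <- "sequence_description"
  out
}

#' @export
print.sequence_description <- function(x, ...) {
  cat("<", x$family, "> ", x$n_blocks, " blocks, ", x$n_readouts,
      " readouts, ", sprintf("%.3f s", x$duration_s), "\n", sep = "")
  if (!is.null(x$min_TE_ms)) cat("  min TE: ", sprintf("%.3f ms", x$min_TE_ms), "\n", sep = "")
  if (!is.null(x$min_TR_ms)) cat("  min TR: ", sprintf("%.3f ms", x$min_TR_ms), "\n", sep = "")
  if (!is.null(x$train_length))
    cat("  train length: ", paste(x$train_length, collapse = "/"), "\n", sep = "")
  invisible(x)
}
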