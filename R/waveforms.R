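#' Synthesize an RF pulse envelope
#'
#' Builds a sampled RF envelope on the RF raster and scales its peak
#' amplitude so that the on-resonance small-tip flip angle equals
#' `flip = 2 pi gamma integral(B1 dt)`. Sinc pulses are Hanning-apodized by
#' default (vendor definitions of "the" sinc pulse differ; the apodization
#' is exposed as an option). The pulse bandwidth is
#' `time_bandwidth / duration`.
#'
#' @param shape "sinc", "hann_sinc", "gauss" or "hard".
#' @param duration_ms pulse duration, ms.
#' @param flip_deg nominal flip angle, degrees.
#' @param time_bandwidth dimensionless time-bandwidth product.
#' @param apodization "hanning" or "none" (sinc shapes only; "hann_sinc"
#'   forces Hanning).
#' @param phase_rad,freq_hz transmitter phase/frequency offsets.
#' @param purpose see [rf_event()].
#' @param limits a [hardware_limits()]; the required peak B1 must stay
#'   below `limits$b1_max_uT`.
#' @return an [rf_event()] starting at 0 (block-relative).
#' @export
make_rf <- function(shape = c("sinc", "hann_sinc", "gauss", "hard"),
                    duration_ms, flip_deg, time_bandwidth = 4,
                    apodization = c("hanning", "none"),
                    phase_rad = 0, freq_hz = 0, purpose = "excitation",
                    limits = hardware_limits()) {
  shape <- match.arg(shape)
  apodization <- match.arg(apodization)
  stopifnot(duration_ms > 0, flip_deg >= 0, time_bandwidth > 0)
  n <- max(1L, round(duration_ms * 1e6 / limits$rf_raster_ns))
  tau <- (seq_len(n) - 0.5) / n - 0.5  # centered fraction in (-0.5, 0.5)
  env <- switch(shape,
    hard = rep(1, n),
    gauss = exp(-0.5 * (tau * time_bandwidth * 2.355)^2),
    sinc = ,
    hann_sinc = {
      x <- time_bandwidth * tau
      s <- ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
      if (shape == "hann_sinc" || apodization == "hanning")
        s <- s * (0.5 + 0.5 * cos(2 * pi * tau))
      s
    })
  if (flip_deg == 0) {
    return(rf_event(0, rep(0 + 0i, n), amplitude_uT = 0, freq_hz = freq_hz,
                    phase_rad = phase_rad, purpose = purpose, flip_deg = 0,
                    bandwidth_hz = time_bandwidth / (duration_ms * 1e-3),
                    raster_ns = limits$rf_raster_ns))
  }
  env <- env / max(abs(env))
  dt_s <- limits$rf_raster_ns * 1e-9
  area_s <- sum(env) * dt_s                       # normalized envelope area
  flip_rad <- flip_deg * pi / 180
  b1_peak_T <- flip_rad / (2 * pi * limits$gamma * area_s)
  if (abs(b1_peak_T) * 1e6 > limits$b1_max_uT)
    stop(sprintf("required peak B1 %.2f uT exceeds ceiling %.2f uT",
                 abs(b1_peak_T) * 1e6, limits$b1_max_uT), call. = FALSE)
  rf_event(0, env, amplitude_uT = b1_peak_T * 1e6, freq_hz = freq_hz,
           phase_rad = phase_rad, purpose = purpose, flip_deg = flip_deg,
           bandwidth_hz = time_bandwidth / (duration_ms * 1e-3),
           raster_ns = limits$rf_raster_ns)
}

#' Shortest trapezoidal gradient for a specification
#'
#' Three calling modes: `{amplitude, flat}` (ramps added at the slew limit),
#' `{area}` (shortest raster-quantized trapezoid or triangle achieving the
#' area), and `{area, duration}` (area realized within a fixed total
#' duration). Area convention: `amplitude * (flat + rise)` with equal
#' rise/fall ramps, in mT/m*ms.
#'
#' @param axis logical axis name.
#' @param amplitude_mT_m plateau amplitude, mT/m.
#' @param flat_ms flat-top duration, ms.
#' @param area_mT_ms_m requested area, mT/m*ms (signed).
#' @param duration_ms fixed total duration (with `area`).
#' @param start_ns block-relative start, ns.
#' @param limits a [hardware_limits()].
#' @return a [grad_trap()], or NULL for zero area.
#' @export
make_trapezoid <- function(axis, amplitude_mT_m = NULL, flat_ms = NULL,
                           area_mT_ms_m = NULL, duration_ms = NULL,
                           start_ns = 0, limits = hardware_limits()) {
  raster <- limits$grad_raster_ns
  if (!is.null(amplitude_mT_m) && !is.null(flat_ms)) {
    if (abs(amplitude_mT_m) > limits$g_max + 1e-9)
      stop("amplitude exceeds Gmax", call. = FALSE)
    if (amplitude_mT_m == 0) return(NULL)
    rise <- ceil_raster(ms_to_ns(abs(amplitude_mT_m) / limits$slew), raster)
    flat <- ceil_raster(ms_to_ns(flat_ms), raster)
    return(grad_trap(axis, start_ns, rise, flat, rise, amplitude_mT_m))
  }
  if (is.null(area_mT_ms_m)) stop("specify {amplitude, flat} or {area[, duration]}",
                                  call. = FALSE)
  A <- area_mT_ms_m
  if (A == 0) return(NULL)
  sgn <- sign(A); Aa <- abs(A)
  if (is.null(duration_ms)) {
    # shortest: try triangle, else Gmax-limited trapezoid
    amp_tri <- sqrt(Aa * limits$slew)             # mT/m, with area = amp*rise
    if (amp_tri <= limits$g_max) {
      rise <- ceil_raster(ms_to_ns(amp_tri / limits$slew), raster)
      amp <- Aa / ns_to_ms(rise)
      return(grad_trap(axis, start_ns, rise, 0, rise, sgn * amp))
    }
    rise <- ceil_raster(ms_to_ns(limits$g_max / limits$slew), raster)
    flat <- ceil_raster(ms_to_ns((Aa - limits$g_max * ns_to_ms(rise)) / limits$g_max),
                        raster)
    amp <- Aa / (ns_to_ms(rise) + ns_to_ms(flat))
    return(grad_trap(axis, start_ns, rise, flat, rise, sgn * amp))
  }
  total <- ceil_raster(ms_to_ns(duration_ms), raster)
  # smallest rise (largest flat) that satisfies slew and Gmax
  for (rise in seq(raster, floor(total / 2 / raster) * raster, by = raster)) {
    flat <- total - 2 * rise
    amp <- Aa / (ns_to_ms(rise) + ns_to_ms(flat))
    if (amp <= limits$g_max + 1e-12 && amp / ns_to_ms(rise) <= limits$slew + 1e-12)
      return(grad_trap(axis, start_ns, rise, flat, rise, sgn * amp))
  }
  stop(sprintf("area %.3f mT/m*ms infeasible within %.3f ms under limits",
               A, duration_ms), call. = FALSE)
}

grad_area_mT_ms_m <- function(g) {
  if (is.null(g)) return(0)
  if (g$kind == "trap")
    return(g$amp_mT_m * (ns_to_ms(g$flat_ns) + (ns_to_ms(g$rise_ns) + ns_to_ms(g$fall_ns)) / 2))
  sum(g$samples_mT_m) * ns_to_ms(g$raster_ns)
}

#' Slice-selection gradient for an RF pulse
#'
#' Plateau amplitude `G = BW / (gamma * thickness)`; the slice gradient
#' spans the pulse plus ramps, and the rephaser cancels the phase accrued
#' from the pulse's isodelay point to the end of the gradient (plateau
#' remainder plus the full ramp-down contribution).
#'
#' @param rf an [rf_event()] with finite bandwidth.
#' @param thickness_mm slice thickness, mm.
#' @param limits a [hardware_limits()].
#' @return list with `select` (gradient, starts at 0; RF should start after
#'   its ramp-up), `rephaser` (negative-area trapezoid, start unset),
#'   `rf_start_ns` and `rephaser_area`.
#' @export
make_slice_select <- function(rf, thickness_mm, limits = hardware_limits()) {
  stopifnot(is.finite(rf$bandwidth_hz), rf$bandwidth_hz > 0, thickness_mm > 0)
  g_T_m <- rf$bandwidth_hz / (limits$gamma * thickness_mm * 1e-3)
  g_mT_m <- g_T_m * 1e3
  if (g_mT_m > limits$g_max)
    stop(sprintf("slice gradient %.2f mT/m exceeds Gmax %.2f", g_mT_m, limits$g_max),
         call. = FALSE)
  rise <- ceil_raster(ms_to_ns(g_mT_m / limits$slew), limits$grad_raster_ns)
  flat <- ceil_raster(rf$duration_ns, limits$grad_raster_ns)
  sel <- grad_trap("slice", 0, rise, flat, rise, g_mT_m)
  # area from the RF isodelay point to the end of the gradient
  reph_area <- -(g_mT_m * ns_to_ms(flat) * (1 - rf$center_frac) +
                   g_mT_m * ns_to_ms(rise) / 2)
  reph <- make_trapezoid("slice", area_mT_ms_m = reph_area, limits = limits)
  list(select = sel, rephaser = reph, rf_start_ns = rise,
       rephaser_area = reph_area, plateau_mT_m = g_mT_m)
}

#' Phase/partition encoding table
#'
#' Deterministic list of sampled k-space positions along one encoded
#' dimension under partial Fourier and regular undersampling. The sampled
#' non-reference positions are the accelerated pattern over the acquired
#' (late-echo, center-containing) partial-Fourier portion; their count is
#' `ceiling(matrix_dim * partial_fourier / acceleration)`. Reference
#' (calibration) positions form a fully sampled centered band and are
#' integrated: positions already on the pattern are not duplicated.
#'
#' @param matrix_dim number of k-space positions (matrix size).
#' @param partial_fourier fraction in (0, 1].
#' @param acceleration integer undersampling factor >= 1.
#' @param reference_lines width of the fully sampled center band.
#' @param ordering "linear" (ascending) or "centric" (center-out).
#' @return data.frame with columns `index` (0-based) and `is_reference`.
#' @export
encoding_table <- function(matrix_dim, partial_fourier = 1, acceleration = 1,
                           reference_lines = 0,
                           ordering = c("linear", "centric")) {
  ordering <- match.arg(ordering)
  stopifnot(matrix_dim >= 1, partial_fourier > 0, partial_fourier <= 1,
            acceleration >= 1)
  acceleration <- as.integer(acceleration)
  n_acq <- ceiling(matrix_dim * partial_fourier)
  first <- matrix_dim - n_acq                      # skip early (high-k) lines
  pattern <- seq(first, matrix_dim - 1, by = acceleration)
  center <- floor(matrix_dim / 2)
  refs <- integer()
  if (reference_lines > 0) {
    r0 <- center - floor(reference_lines / 2)
    refs <- seq(r0, r0 + reference_lines - 1)
    if (any(refs < 0 | refs >= matrix_dim))
      stop("reference band wider than matrix", call. = FALSE)
    refs <- setdiff(refs, pattern)
  }
  tab <- rbind(data.frame(index = as.integer(pattern), is_reference = FALSE),
               if (length(refs)) data.frame(index = as.integer(refs),
                                            is_reference = TRUE))
  tab <- tab[order(tab$index), , drop = FALSE]
  if (ordering == "centric")
    tab <- tab[order(abs(tab$index - center), -sign(tab$index - center)), ,
               drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Numeric b-value of a gradient waveform
#'
#' `b = (2 pi gamma)^2 * integral( (integral G dt')^2 dt )`, evaluated on
#' the rasterized waveform. Units: input mT/m on the gradient raster,
#' output s/mm^2.
#'
#' @param samples_mT_m gradient samples on the raster.
#' @param raster_ns sample raster, ns.
#' @param gamma gyromagnetic ratio, Hz/T.
#' @export
b_value <- function(samples_mT_m, raster_ns = GRAD_RASTER_NS,
                    gamma = GAMMA_HZ_PER_T) {
  dt <- raster_ns * 1e-9                            # s
  G <- samples_mT_m * 1e-3                          # T/m
  # first moment F(t) = integral G dt' at sample ends, piecewise-constant G
  Fv <- cumsum(G) * dt                              # T s / m
  # integral F^2 dt with F linear within each sample: Simpson on segments
  F0 <- c(0, Fv[-length(Fv)])
  seg <- (F0^2 + F0 * Fv + Fv^2) / 3 * dt
  b_si <- (2 * pi * gamma)^2 * sum(seg)             # s/m^2
  b_si * 1e-6                                       # s/mm^2
}

#' Bipolar diffusion-gradient pair for a target b-value
#'
#' Two opposed trapezoidal lobes of duration `delta` each (no gap). The
#' ramp time is fixed at the slew-limited ramp of Gmax so the numeric
#' b-value scales exactly with amplitude squared, and the amplitude is
#' solved so the rasterized waveform's numeric b equals `b_target` (well
#' within 0.1 percent).
#'
#' @param b_target target b-value, s/mm^2.
#' @param lobe_duration_ms duration delta of each lobe, ms.
#' @param limits a [hardware_limits()].
#' @param axes matrix of unit direction vectors (rows), default the three
#'   orthogonal physical axes.
#' @return a `diffusion_spec`: b, delta, amplitude G (mT/m), scheme, axes,
#'   and `samples` (the rasterized one-axis waveform, mT/m).
#' @export
bipolar_diffusion <- function(b_target, lobe_duration_ms,
                              limits = hardware_limits(), axes = diag(3)) {
  stopifnot(b_target >= 0, lobe_duration_ms > 0)
  rise <- ceil_raster(ms_to_ns(limits$g_max / limits$slew), limits$grad_raster_ns)
  lobe_ns <- ceil_raster(ms_to_ns(lobe_duration_ms), limits$grad_raster_ns)
  if (lobe_ns < 2 * rise) stop("lobe too short for slew-limited ramps", call. = FALSE)
  shape_one <- function(G) {
    lobe <- grad_samples(grad_trap("x", 0, rise, lobe_ns - 2 * rise, rise, G),
                         limits$grad_raster_ns)
    c(lobe, -lobe)
  }
  if (b_target == 0) {
    return(structure(list(b = 0, delta_ms = lobe_duration_ms, G_mT_m = 0,
                          scheme = "bipolar", axes = axes,
                          samples = shape_one(0)),
                     class = "diffusion_spec"))
  }
  b_unit <- b_value(shape_one(1), limits$grad_raster_ns, limits$gamma)
  G <- sqrt(b_target / b_unit)                      # b scales as G^2 exactly
  if (G > limits$g_max + 1e-9)
    stop(sprintf("b = %.0f s/mm^2 needs %.1f mT/m > Gmax %.1f for delta = %.2f ms",
                 b_target, G, limits$g_max, lobe_duration_ms), call. = FALSE)
  structure(list(b = b_target, delta_ms = lobe_duration_ms, G_mT_m = G,
                 scheme = "bipolar", axes = axes, samples = shape_one(G)),
            class = "diffusion_spec")
}

#' Radial view directions
#'
#' `golden_3d` produces a deterministic pseudo-uniform sequence of unit
#' vectors from the two-dimensional golden means (increments 0.4656 of the
#' polar range, taken uniformly in z, and 0.6823 of the azimuthal range).
#' `calibration_planes` produces `n_angles` evenly spaced in-plane
#' directions (2-degree increments for the default 180) for each of the
#' xy, xz and yz planes, used by the gradient-delay calibration prescan.
#'
#' @param n_spokes number of golden-angle directions.
#' @param mode "golden_3d" or "calibration_planes".
#' @param n_angles angles per plane in calibration mode.
#' @return matrix with one unit row vector per direction; calibration mode
#'   carries `plane` and `angle_deg` attributes.
#' @export
radial_directions <- function(n_spokes, mode = c("golden_3d", "calibration_planes"),
                              n_angles = 180) {
  mode <- match.arg(mode)
  if (mode == "golden_3d") {
    stopifnot(n_spokes >= 1)
    phi1 <- 0.4656; phi2 <- 0.6823
    m <- seq_len(n_spokes) - 1
    z <- 2 * ((m * phi1) %% 1) - 1
    az <- 2 * pi * ((m * phi2) %% 1)
    r <- sqrt(pmax(0, 1 - z^2))
    return(cbind(x = r * cos(az), y = r * sin(az), z = z))
  }
  th <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  c1 <- cos(th); s1 <- sin(th); z0 <- numeric(n_angles)
  d <- rbind(cbind(c1, s1, z0),     # xy
             cbind(c1, z0, s1),     # xz
             cbind(z0, c1, s1))     # yz
  colnames(d) <- c("x", "y", "z")
  attr(d, "plane") <- rep(c("xy", "xz", "yz"), each = n_angles)
  attr(d, "angle_deg") <- rep(th * 180 / pi, 3)
  d
}
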