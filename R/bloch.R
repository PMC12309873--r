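#' Bloch simulation of an execution-block stream
#'
#' Isochromat-summation Bloch engine: magnetization at a set of spatial
#' positions is evolved through the block stream using the hard-pulse
#' approximation for shaped RF (sub-rotations capped at ~5 degrees, with
#' exact piecewise gradient/off-resonance precession and T1/T2 relaxation
#' between sub-pulses). ADC samples record the proton-density-weighted
#' complex transverse sum, demodulated with the ADC frequency/phase;
#' optional per-contrast diffusion weighting applies exp(-b D) per voxel.
#' Deterministic for a given input.
#'
#' @param blocks list of [execution_block()]s (chronological).
#' @param iso isochromat set: list with `pos_mm` (n x 3), `pd`, `T1_ms`,
#'   `T2_ms`, `off_hz`, `D` (vectors length n). Use [phantom_isochromats()].
#' @param b_of_contrast optional numeric vector: diffusion b (s/mm^2)
#'   applied to readouts by their `contrast` header counter (1-based).
#' @param gamma gyromagnetic ratio, Hz/T.
#' @param max_step_deg cap on the per-sub-pulse rotation.
#' @param return_magnetization also return the final magnetization.
#' @return list with `samples` (list of complex vectors, one per ADC),
#'   `headers`, and optionally `magnetization` (n x 3).
#' @export
bloch_simulate <- function(blocks, iso, b_of_contrast = NULL,
                           gamma = GAMMA_HZ_PER_T, max_step_deg = 5,
                           return_magnetization = FALSE) {
  pos <- iso$pos_mm * 1e-3                       # m
  n <- nrow(pos)
  pd <- iso$pd %||% rep(1, n)
  T1 <- (iso$T1_ms %||% rep(1e9, n)) * 1e-3
  T2 <- (iso$T2_ms %||% rep(1e9, n)) * 1e-3
  off <- iso$off_hz %||% rep(0, n)
  D <- iso$D %||% rep(0, n)
  M <- cbind(mx = numeric(n), my = numeric(n), mz = rep(1, n))
  samples <- list(); headers <- list()
  ax_index <- c(read = 1L, phase = 2L, slice = 3L, x = 1L, y = 2L, z = 3L)

  precess <- function(M, grads, t0, t1) {
    dt <- (t1 - t0) * 1e-9
    if (dt <= 0) return(M)
    area <- c(0, 0, 0)                           # mT/m * ns per axis
    for (g in grads) {
      a <- grad_area_ns(g, t0, t1)
      if (a != 0) area[ax_index[[g$axis]]] <- area[ax_index[[g$axis]]] + a
    }
    phi <- 2 * pi * (off * dt + gamma * (pos %*% (area * 1e-12))[, 1])
    e2 <- exp(-dt / T2)
    mxy <- complex(real = M[, 1], imaginary = M[, 2]) * exp(-1i * phi) * e2
    mz <- 1 + (M[, 3] - 1) * exp(-dt / T1)
    cbind(Re(mxy), Im(mxy), mz)
  }

  for (b in blocks) {
    t_cur <- 0
    acts <- list()
    if (!is.null(b$rf) && b$rf$amplitude_uT > 0) {
      r <- b$rf
      nsamp <- length(r$samples)
      dt_s <- r$raster_ns * 1e-9
      step_flip <- 2 * pi * gamma * r$amplitude_uT * 1e-6 * dt_s * 180 / pi
      # cap sub-pulses by flip (hard-pulse approximation) AND by duration,
      # so gradient/off-resonance precession stays finely interleaved
      grp <- max(1L, min(floor(max_step_deg / max(step_flip, 1e-9)),
                         ceiling(1e4 / r$raster_ns)))
      idx <- split(seq_len(nsamp), ceiling(seq_len(nsamp) / grp))
      for (ii in idx) {
        tm <- r$start_ns + (mean(ii) - 0.5) * r$raster_ns
        b1 <- r$amplitude_uT * 1e-6 * sum(r$samples[ii]) * dt_s  # T*s
        ph <- r$phase_rad + 2 * pi * r$freq_hz * (tm - r$start_ns) * 1e-9
        acts[[length(acts) + 1L]] <- list(time = tm, type = "rot",
                                          b1_ts = b1, phase = ph)
      }
    }
    if (!is.null(b$adc)) {
      a <- b$adc
      for (s in seq_len(a$n)) {
        ts <- a$start_ns + (s - 0.5) * a$dwell_ns
        acts[[length(acts) + 1L]] <- list(time = ts, type = "adc", s = s)
      }
    }
    if (length(acts)) {
      ord <- order(vapply(acts, function(x) x$time, numeric(1)))
      acts <- acts[ord]
    }
    adc_buf <- if (!is.null(b$adc)) complex(b$adc$n)
    for (a in acts) {
      M <- precess(M, b$gradients, t_cur, a$time)
      t_cur <- a$time
      if (a$type == "rot") {
        alpha <- 2 * pi * gamma * Mod(a$b1_ts)
        phi <- a$phase + Arg(a$b1_ts)
        ca <- cos(alpha); sa <- sin(alpha)
        cp <- cos(phi); sp <- sin(phi)
        # rotation about transverse axis (cos phi, sin phi, 0) by alpha
        R <- matrix(c(
          cp * cp + sp * sp * ca, cp * sp * (1 - ca),      sp * sa,
          cp * sp * (1 - ca),     sp * sp + cp * cp * ca,  -cp * sa,
          -sp * sa,               cp * sa,                 ca), 3, byrow = TRUE)
        M <- M %*% t(R)
      } else {
        w <- pd
        if (!is.null(b_of_contrast) && !is.null(b$adc)) {
          bv <- b_of_contrast[b$adc$header$contrast + 1L]
          if (!is.na(bv) && bv > 0) w <- w * exp(-bv * D)
        }
        dem <- exp(-1i * (2 * pi * b$adc$freq_hz *
                            (a$time - b$adc$start_ns) * 1e-9 + b$adc$phase_rad))
        adc_buf[a$s] <- sum(w * complex(real = M[, 1], imaginary = M[, 2])) * dem
      }
    }
    M <- precess(M, b$gradients, t_cur, b$duration_ns)
    if (!is.null(b$adc)) {
      samples[[length(samples) + 1L]] <- adc_buf
      headers[[length(headers) + 1L]] <- b$adc$header
    }
  }
  out <- list(samples = samples, headers = headers)
  if (return_magnetization) out$magnetization <- M
  out
}

#' Isochromats from a phantom
#'
#' Samples a [virtual_phantom()]'s property maps at voxel centers of a
#' regular grid to produce the isochromat set for [bloch_simulate()].
#'
#' @param phantom a [virtual_phantom()].
#' @param n grid size (scalar or length-3).
#' @param fov_mm sampled extent, mm.
#' @param transform optional rigid motion of the phantom.
#' @export
phantom_isochromats <- function(phantom, n, fov_mm = phantom$fov_mm,
                                transform = NULL) {
  g <- phantom_grid_mm(n, fov_mm, phantom$ndim)
  pts <- as.matrix(expand.grid(x = g$x, y = g$y, z = g$z))
  keep_pd <- phantom_values(phantom, pts, "pd", transform)
  list(pos_mm = pts, pd = keep_pd,
       T1_ms = phantom_values(phantom, pts, "T1", transform),
       T2_ms = phantom_values(phantom, pts, "T2", transform),
       off_hz = phantom_values(phantom, pts, "off_hz", transform),
       D = phantom_values(phantom, pts, "D", transform))
}
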