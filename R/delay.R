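# Gradient-delay calibration from plane-wise radial prescans: opposed-angle
# spokes sample the same k-space line in opposite directions, so a per-axis
# gradient-to-ADC delay shifts their echoes apart; cross-correlating each
# echo with its time-reversed opposite yields twice the projected delay,
# and a least-squares fit of tau(theta) = dx cos^2 + dy sin^2 over all
# angles of all three planes separates the axes.

#' Spoke k-space sample positions under per-axis gradient delays
#'
#' Symmetric full spoke: the parallel coordinate runs linearly from -kmax
#' to +kmax over the readout; a delayed gradient on axis `a` shifts that
#' axis' component by `delay * dk/dt`.
#'
#' @param direction unit vector (length 3).
#' @param n_samp samples per spoke.
#' @param kmax maximum |k| (1/m).
#' @param dwell_ns ADC dwell, ns.
#' @param delays_us per-axis delays (x, y, z), microseconds.
#' @return n x 3 matrix of k locations (1/m).
#' @export
spoke_k <- function(direction, n_samp, kmax, dwell_ns, delays_us = c(0, 0, 0)) {
  s <- seq_len(n_samp) - 0.5
  kpar <- (s - n_samp / 2) / (n_samp / 2) * kmax    # 1/m
  slope <- kmax / (n_samp / 2) / dwell_ns * 1e3      # per us
  k <- outer(kpar, direction)
  for (a in 1:3) k[, a] <- k[, a] - direction[a] * slope * delays_us[a]
  k
}

#' Simulate the delay-calibration prescan
#'
#' Analytic echoes of a phantom along plane-wise evenly rotated spokes
#' (the 2-degree-increment prescan in the xy, xz and yz planes), with
#' per-axis gradient delays applied and optional complex noise.
#'
#' @param phantom a [virtual_phantom()].
#' @param delays_us true per-axis delays, microseconds.
#' @param n_angles angles per plane.
#' @param n_samp samples per spoke.
#' @param kmax maximum |k| (1/m).
#' @param dwell_ns ADC dwell, ns.
#' @param noise_sd complex noise sd relative to the DC signal.
#' @param seed RNG seed for the noise.
#' @return list of echoes: `plane`, `angle_deg`, `direction`, `samples`.
#' @export
simulate_calibration_echoes <- function(phantom, delays_us = c(0, 0, 0),
                                        n_angles = 180, n_samp = 256,
                                        kmax = 250, dwell_ns = 5e3,
                                        noise_sd = 0, seed = 1) {
  dirs <- radial_directions(1, "calibration_planes", n_angles = n_angles)
  planes <- attr(dirs, "plane"); angles <- attr(dirs, "angle_deg")
  set.seed(seed)
  s0 <- Mod(kspace_of_phantom(phantom, matrix(0, 1, 3)))
  lapply(seq_len(nrow(dirs)), function(i) {
    k <- spoke_k(dirs[i, ], n_samp, kmax, dwell_ns, delays_us)
    smp <- kspace_of_phantom(phantom, k)
    if (noise_sd > 0)
      smp <- smp + complex(real = stats::rnorm(n_samp, 0, noise_sd * s0),
                           imaginary = stats::rnorm(n_samp, 0, noise_sd * s0))
    list(plane = planes[i], angle_deg = angles[i], direction = dirs[i, ],
         samples = smp, dwell_ns = dwell_ns, kmax = kmax)
  })
}

# sub-sample peak of the cross-correlation of two magnitude echoes
xcorr_lag <- function(a, b) {
  n <- length(a)
  a <- a - mean(a); b <- b - mean(b)
  nf <- 2^ceiling(log2(2 * n))
  A <- stats::fft(c(a, numeric(nf - n)))
  B <- stats::fft(c(b, numeric(nf - n)))
  cc <- Re(stats::fft(A * Conj(B), inverse = TRUE))
  lags <- c(0:(nf / 2 - 1), -(nf / 2):-1)
  i <- which.max(cc)
  # parabolic interpolation around the peak
  im <- if (i == 1) nf else i - 1
  ip <- if (i == nf) 1 else i + 1
  y0 <- cc[im]; y1 <- cc[i]; y2 <- cc[ip]
  den <- y0 - 2 * y1 + y2
  frac <- if (abs(den) > 0) 0.5 * (y0 - y2) / den else 0
  lags[i] + frac
}

#' Estimate per-axis gradient delays from calibration echoes
#'
#' @param echoes output of [simulate_calibration_echoes()] (or measured
#'   echoes in the same structure).
#' @return list: `delays_us` (x, y, z), `tau_us` per-angle projected
#'   delays, `fit` the least-squares fit object.
#' @export
estimate_gradient_delay <- function(echoes) {
  planes <- vapply(echoes, function(e) e$plane, character(1))
  angles <- vapply(echoes, function(e) e$angle_deg, numeric(1))
  rows <- list(); taus <- numeric()
  plane_axes <- list(xy = c(1, 2), xz = c(1, 3), yz = c(2, 3))
  for (pl in unique(planes)) {
    idx <- which(planes == pl)
    ang <- angles[idx]
    half <- idx[ang < 180]
    for (i in half) {
      j <- idx[which.min(abs((angles[idx] - (echoes[[i]]$angle_deg + 180)) %% 360))]
      if (identical(i, j)) next
      ea <- Mod(echoes[[i]]$samples)
      eb <- rev(Mod(echoes[[j]]$samples))
      if (max(ea) <= 0 || max(eb) <= 0)
        stop("echo signal too low for peak finding", call. = FALSE)
      lag <- xcorr_lag(ea, eb)
      tau_us <- lag / 2 * echoes[[i]]$dwell_ns * 1e-3
      th <- echoes[[i]]$angle_deg * pi / 180
      r <- numeric(3)
      r[plane_axes[[pl]]] <- c(cos(th)^2, sin(th)^2)
      rows[[length(rows) + 1L]] <- r
      taus <- c(taus, tau_us)
    }
  }
  X <- do.call(rbind, rows)
  fit <- stats::lsfit(X, taus, intercept = FALSE)
  delays <- fit$coefficients
  names(delays) <- c("x", "y", "z")
  list(delays_us = delays, tau_us = taus, fit = fit)
}
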