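#' k-space trajectory of a block stream
#'
#' Cumulative gradient integral `k(t) = gamma * integral(G dt)` evaluated
#' at each ADC sample time (center-of-dwell convention). Bookkeeping: k is
#' reset to zero at each excitation-pulse center and negated at each
#' refocusing-pulse center.
#'
#' @param blocks list of [execution_block()]s.
#' @param gamma gyromagnetic ratio, Hz/T.
#' @return list per ADC: `k` (n x 3 matrix, 1/m), `header`, `t_ns` sample
#'   times (absolute).
#' @export
kspace_trajectory <- function(blocks, gamma = GAMMA_HZ_PER_T) {
  ax_index <- c(read = 1L, phase = 2L, slice = 3L, x = 1L, y = 2L, z = 3L)
  grads <- list()
  marks <- list()
  adcs <- list()
  for (b in blocks) {
    for (g in b$gradients) {
      g$start_ns <- g$start_ns + b$start_ns
      grads[[length(grads) + 1L]] <- g
    }
    if (!is.null(b$rf) && b$rf$purpose %in% c("excitation", "refocusing")) {
      tc <- b$start_ns + b$rf$start_ns + b$rf$center_frac * b$rf$duration_ns
      marks[[length(marks) + 1L]] <- list(time = tc, type = b$rf$purpose)
    }
    if (!is.null(b$adc)) {
      a <- b$adc
      adcs[[length(adcs) + 1L]] <-
        list(t = b$start_ns + a$start_ns + (seq_len(a$n) - 0.5) * a$dwell_ns,
             header = a$header)
    }
  }
  area_between <- function(t0, t1) {
    a <- c(0, 0, 0)
    for (g in grads) {
      if (g$start_ns >= t1 || g$start_ns + g$duration_ns <= t0) next
      a[ax_index[[g$axis]]] <- a[ax_index[[g$axis]]] + grad_area_ns(g, t0, t1)
    }
    a
  }
  # sweep all event times in order, maintaining the running k state
  ev_times <- vapply(marks, function(m) m$time, numeric(1))
  out <- list()
  for (ad in adcs) {
    out[[length(out) + 1L]] <- list(k = matrix(0, length(ad$t), 3),
                                    header = ad$header, t_ns = ad$t)
  }
  # global chronological sweep
  sample_stream <- do.call(rbind, lapply(seq_along(adcs), function(i)
    cbind(t = adcs[[i]]$t, adc = i, s = seq_along(adcs[[i]]$t))))
  events <- rbind(
    if (length(marks)) cbind(t = ev_times, adc = 0,
                             s = vapply(marks, function(m)
                               if (m$type == "excitation") -1 else -2,
                               numeric(1))),
    sample_stream)
  if (is.null(events) || !nrow(events)) return(out)
  events <- events[order(events[, "t"]), , drop = FALSE]
  k <- c(0, 0, 0); t_state <- 0
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    k <- k + gamma * area_between(t_state, e[["t"]]) * 1e-12  # 1/m
    t_state <- e[["t"]]
    if (e[["adc"]] == 0) {
      if (e[["s"]] == -1) k <- c(0, 0, 0) else k <- -k
    } else {
      out[[e[["adc"]]]]$k[e[["s"]], ] <- k
    }
  }
  out
}

kb_kernel <- function(u, width, beta) {
  # Kaiser-Bessel, u in grid units, support |u| <= width/2
  x <- 2 * u / width
  out <- numeric(length(u))
  ok <- abs(x) <= 1
  out[ok] <- besselI(beta * sqrt(1 - x[ok]^2), 0) / besselI(beta, 0)
  out
}

kb_deapod <- function(n_img, n_grid, width, beta) {
  # discrete transform of the raster-sampled kernel at image positions --
  # the exact deapodizer for grid convolution (a unit DC sample recovers a
  # flat unit image; Cartesian data matches the direct FFT to rounding)
  j <- seq(-ceiling(width / 2), ceiling(width / 2))
  kj <- kb_kernel(j, width, beta)
  x <- ((seq_len(n_img) - 1) - n_img / 2) / n_grid
  vapply(x, function(xi) sum(kj * cos(2 * pi * j * xi)), numeric(1))
}

fftshift_nd <- function(a) {
  d <- dim(a)
  idx <- lapply(d, function(n) ((seq_len(n) - 1 + floor(n / 2)) %% n) + 1)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

ifftshift_nd <- function(a) {
  d <- dim(a)
  idx <- lapply(d, function(n) ((seq_len(n) - 1 + ceiling(n / 2)) %% n) + 1)
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Gridding reconstruction with a Kaiser-Bessel kernel
#'
#' Density-compensated convolution gridding of arbitrary k-space samples
#' onto a 2x-oversampled Cartesian grid, inverse FFT, deapodization by the
#' kernel transform, and crop to the requested matrix. The default kernel
#' (2x oversampling, window width 4.0) follows standard gridding practice.
#'
#' @param samples complex k-space samples.
#' @param k sample locations (n x d matrix, 1/m; d = 2 or 3).
#' @param matrix_size image matrix (scalar or length-d).
#' @param fov_mm field of view, mm (scalar or length-d).
#' @param oversampling grid oversampling factor.
#' @param kernel_width kernel window width in oversampled grid cells.
#' @param dcf density compensation: "none", "radial" (|k|^(d-1) ramp with a
#'   Nyquist plateau), or a numeric vector of weights.
#' @return complex image array of dimension `matrix_size`.
#' @export
grid_reconstruct <- function(samples, k, matrix_size, fov_mm,
                             oversampling = 2.0, kernel_width = 4.0,
                             dcf = "none") {
  if (!length(samples)) stop("empty sample set", call. = FALSE)
  d <- ncol(k)
  N <- rep(matrix_size, length.out = d)
  fov_m <- rep(fov_mm, length.out = d) * 1e-3
  G <- round(oversampling * N)
  W <- kernel_width
  beta <- pi * sqrt((W / oversampling)^2 * (oversampling - 0.5)^2 - 0.8)
  u <- sweep(k, 2, fov_m, "*")                  # grid units, in [-N/2, N/2]
  w <- if (is.numeric(dcf)) dcf
  else if (identical(dcf, "radial")) {
    kr <- sqrt(rowSums(u^2))
    pmax(pmin(kr, min(N) / 2), 0.25)^(d - 1)
  } else rep(1, nrow(k))
  grid <- array(0i, dim = G)
  half <- W / 2
  offs <- as.matrix(expand.grid(rep(list(seq(-ceiling(half), ceiling(half))), d)))
  ug <- sweep(u, 2, oversampling, "*")          # oversampled-grid units
  base <- floor(ug)
  val <- samples * w
  for (r in seq_len(nrow(offs))) {
    tgt <- base + rep(offs[r, ], each = nrow(ug))
    du <- tgt - ug
    wt <- rep(1, nrow(ug))
    for (j in seq_len(d)) wt <- wt * kb_kernel(du[, j], W, beta)
    idx_ok <- wt > 0
    if (!any(idx_ok)) next
    pos <- sweep(tgt[idx_ok, , drop = FALSE], 2, G / 2, "+")      # 0-based
    # periodic wrap: the oversampled grid is implicitly periodic under the
    # FFT, and with 2x oversampling the wrap lands in the guard band
    for (j in seq_len(d)) pos[, j] <- pos[, j] %% G[j]
    lin <- pos[, 1] + 1
    mul <- 1
    for (j in seq_len(d - 1)) {
      mul <- mul * G[j]
      lin <- lin + pos[, j + 1] * mul
    }
    add <- val[idx_ok] * wt[idx_ok]
    # accumulate (duplicated linear indices must sum)
    acc <- rowsum(cbind(Re(add), Im(add)), lin)
    ii <- as.integer(rownames(acc))
    grid[ii] <- grid[ii] + complex(real = acc[, 1], imaginary = acc[, 2])
  }
  img_big <- fftshift_nd(stats::fft(ifftshift_nd(grid), inverse = TRUE))
  # crop central N and deapodize
  idx <- lapply(seq_len(d), function(j) {
    i0 <- G[j] / 2 - N[j] / 2 + 1
    seq(i0, i0 + N[j] - 1)
  })
  img <- do.call(`[`, c(list(img_big), idx, list(drop = FALSE)))
  for (j in seq_len(d)) {
    dap <- kb_deapod(N[j], G[j], W, beta)
    shape <- rep(1, d); shape[j] <- N[j]
    img <- img / array(rep(dap, each = prod(N[seq_len(j - 1)])), dim = N)
  }
  # convention: a unit DC sample yields a flat image of amplitude 1 (the
  # deapodizer's DC gain equals the kernel sum)
  img
}

#' Normalized root-mean-square error
#'
#' `sqrt(mean(|a - ref|^2) / mean(|ref|^2))`.
#'
#' @param a,ref arrays of equal size.
#' @export
nrmse <- function(a, ref) {
  sqrt(mean(Mod(a - ref)^2) / mean(Mod(ref)^2))
}
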