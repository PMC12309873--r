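#' Digital phantoms
#'
#' A virtual phantom is a list of geometric components (ellipsoids with
#' sharp edges, or Gaussian blobs for smooth test objects), each carrying
#' tissue properties: proton density, T1/T2 (ms), off-resonance (Hz) and
#' diffusion coefficient D (mm^2/s). Components are evaluated in order;
#' inside an ellipsoid the later component overrides earlier values, which
#' allows nested structures (a synthetic stand-in for anatomy). Rigid
#' motion is modeled by rendering through a [rigid_transform()].
#'
#' @param components data.frame with columns `type` ("ellipsoid" or
#'   "gaussian"), `x,y,z` (center, mm), `a,b,c` (semi-axes or sigma, mm),
#'   `pd`, `T1`, `T2`, `off_hz`, `D`.
#' @param fov_mm length-3 field of view the phantom nominally fills.
#' @param ndim 2 or 3 (2D phantoms ignore z).
#' @export
virtual_phantom <- function(components, fov_mm = c(200, 200, 200), ndim = 3) {
  need <- c("type", "x", "y", "z", "a", "b", "c", "pd", "T1", "T2", "off_hz", "D")
  for (nm in setdiff(need, names(components)))
    components[[nm]] <- switch(nm, T1 = 1000, T2 = 80, off_hz = 0, D = 1e-3,
                               pd = 1, z = 0, c = 1, 0)
  stopifnot(all(components$T1 > 0), all(components$T2 > 0))
  structure(list(components = components, fov_mm = fov_mm, ndim = ndim),
            class = "virtual_phantom")
}

#' @rdname virtual_phantom
#' @param seed integer seed for the randomized inner structure.
#' @export
phantom_brain <- function(seed = 1, fov_mm = c(200, 200, 200)) {
  set.seed(seed)
  comp <- data.frame(
    type = "ellipsoid",
    x = c(0, 0, -15, 15, 0),
    y = c(0, 8, -8, -8, -25),
    z = c(0, 0, 0, 0, 0),
    a = c(80, 12, 9, 9, 14),
    b = c(95, 28, 11, 11, 10),
    c = c(75, 12, 9, 9, 10),
    pd = c(1, 0.65, 1.4, 1.4, 0.8),
    T1 = c(900, 1200, 3500, 3500, 700),
    T2 = c(80, 95, 250, 250, 60),
    off_hz = c(0, 5, -10, 10, 0),
    D = c(0.8e-3, 0.9e-3, 3.0e-3, 3.0e-3, 0.7e-3))
  jig <- stats::runif(nrow(comp), -2, 2); comp$x <- comp$x + jig
  virtual_phantom(comp, fov_mm)
}

#' @rdname virtual_phantom
#' @param n_blobs number of Gaussian blobs.
#' @export
phantom_gaussians <- function(n_blobs = 5, seed = 1, fov_mm = c(200, 200, 200)) {
  set.seed(seed)
  comp <- data.frame(
    type = "gaussian",
    x = stats::runif(n_blobs, -0.22, 0.22) * fov_mm[1],
    y = stats::runif(n_blobs, -0.22, 0.22) * fov_mm[2],
    z = stats::runif(n_blobs, -0.22, 0.22) * fov_mm[3],
    a = stats::runif(n_blobs, 0.06, 0.14) * fov_mm[1],
    b = stats::runif(n_blobs, 0.06, 0.14) * fov_mm[2],
    c = stats::runif(n_blobs, 0.06, 0.14) * fov_mm[3],
    pd = stats::runif(n_blobs, 0.5, 1))
  virtual_phantom(comp, fov_mm)
}

phantom_grid_mm <- function(n, fov_mm, ndim = 3) {
  n <- rep(n, length.out = 3)
  ax <- lapply(1:3, function(d) {
    if (d > ndim || n[d] == 1) return(0)
    ((seq_len(n[d]) - 1) - n[d] / 2 + 0.5) / n[d] * fov_mm[d]
  })
  list(x = ax[[1]], y = ax[[2]], z = ax[[3]], n = n)
}

#' Render a phantom property on a voxel grid
#'
#' @param phantom a [virtual_phantom()].
#' @param n grid size (scalar or length-3).
#' @param fov_mm rendered field of view, mm.
#' @param property one of "pd", "T1", "T2", "off_hz", "D".
#' @param transform optional [rigid_transform()] moving the phantom.
#' @return numeric array (dimensions dropped for singleton z).
#' @export
phantom_render <- function(phantom, n, fov_mm = phantom$fov_mm,
                           property = "pd", transform = NULL) {
  g <- phantom_grid_mm(n, fov_mm, phantom$ndim)
  pts <- as.matrix(expand.grid(x = g$x, y = g$y, z = g$z))
  vals <- phantom_values(phantom, pts, property, transform)
  nn <- c(length(g$x), length(g$y), length(g$z))
  dims <- nn[nn > 1]
  if (length(dims) < 2) dims <- nn[1:2]
  array(vals, dim = dims)
}

# property values at arbitrary points (mm); override semantics for
# ellipsoids, additive for gaussians
phantom_values <- function(phantom, pts_mm, property = "pd", transform = NULL) {
  if (!is.null(transform))
    pts_mm <- transform_points(invert_transform(transform), pts_mm)
  bg <- if (property == "pd") 0 else
    switch(property, T1 = 1000, T2 = 80, off_hz = 0, D = 0)
  out <- rep(bg, nrow(pts_mm))
  for (i in seq_len(nrow(phantom$components))) {
    cp <- phantom$components[i, ]
    dx <- (pts_mm[, 1] - cp$x) / cp$a
    dy <- (pts_mm[, 2] - cp$y) / cp$b
    dz <- if (phantom$ndim == 3) (pts_mm[, 3] - cp$z) / cp$c else 0
    r2 <- dx^2 + dy^2 + dz^2
    if (cp$type == "ellipsoid") {
      inside <- r2 <= 1
      out[inside] <- cp[[property]]
    } else {
      if (property == "pd") out <- out + cp$pd * exp(-r2 / 2)
      else out[r2 <= 4] <- cp[[property]]
    }
  }
  out
}

#' Analytic k-space of a phantom
#'
#' Closed-form Fourier transform of the proton-density map (ellipsoids via
#' the jinc/ball transforms, Gaussians analytically), evaluated at given
#' k-space locations. Used to synthesize ideal acquisitions without
#' gridding or Bloch simulation.
#'
#' @param phantom a [virtual_phantom()].
#' @param k matrix of k-space locations (1/m), 2 or 3 columns.
#' @param transform optional [rigid_transform()] applied to the phantom.
#' @return complex vector of k-space values.
#' @export
kspace_of_phantom <- function(phantom, k, transform = NULL) {
  if (ncol(k) == 2) k <- cbind(k, 0)
  out <- complex(nrow(k))
  two_pi <- 2 * pi
  for (i in seq_len(nrow(phantom$components))) {
    cp <- phantom$components[i, ]
    ctr <- c(cp$x, cp$y, cp$z) * 1e-3
    if (!is.null(transform)) {
      ctr <- transform_points(transform, matrix(ctr * 1e3, 1)) * 1e-3
      # NB: rotation of non-spherical components about their own center is
      # not applied analytically; keep blobs near-isotropic for motion sims
    }
    sab <- c(cp$a, cp$b, cp$c) * 1e-3
    ph <- exp(-2i * pi * (k %*% as.numeric(ctr))[, 1])
    if (cp$type == "gaussian") {
      s2 <- (sab[1] * k[, 1])^2 + (sab[2] * k[, 2])^2 + (sab[3] * k[, 3])^2
      dimfac <- if (phantom$ndim == 3) prod(sab) * (2 * pi)^1.5 else
        sab[1] * sab[2] * 2 * pi
      out <- out + cp$pd * dimfac * exp(-2 * pi^2 * s2) * ph
    } else {
      z <- two_pi * sqrt((sab[1] * k[, 1])^2 + (sab[2] * k[, 2])^2 +
                           (sab[3] * k[, 3])^2)
      if (phantom$ndim == 3) {
        f <- ifelse(z < 1e-8, 1, 3 * (sin(z) - z * cos(z)) / z^3)
        out <- out + cp$pd * (4 / 3) * pi * prod(sab) * f * ph
      } else {
        f <- ifelse(z < 1e-8, 1, 2 * besselJ(z, 1) / z)
        out <- out + cp$pd * pi * sab[1] * sab[2] * f * ph
      }
    }
  }
  out
}
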