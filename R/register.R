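#' Rigid transforms
#'
#' Proper rigid-body transforms parameterized by three rotation angles
#' (degrees, applied as Rz Ry Rx about a center) and a translation (mm).
#'
#' @param translation_mm length-3 translation.
#' @param rotation_deg length-3 rotation angles about x, y, z.
#' @param center_mm rotation center.
#' @export
rigid_transform <- function(translation_mm = c(0, 0, 0),
                            rotation_deg = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  structure(list(t = as.numeric(translation_mm),
                 r = as.numeric(rotation_deg),
                 center = as.numeric(center_mm)),
            class = "rigid_transform")
}

rot_matrix <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' @rdname rigid_transform
#' @param tr a `rigid_transform`.
#' @param pts n x 3 matrix of points (mm).
#' @export
transform_points <- function(tr, pts) {
  R <- rot_matrix(tr$r)
  sweep(sweep(pts, 2, tr$center) %*% t(R), 2, tr$center + tr$t, "+")
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(tr) {
  R <- rot_matrix(tr$r)
  # inverse as matrix + offset; recover angles from R^T
  Ri <- t(R)
  ang <- c(atan2(Ri[3, 2], Ri[3, 3]),
           atan2(-Ri[3, 1], sqrt(Ri[3, 2]^2 + Ri[3, 3]^2)),
           atan2(Ri[2, 1], Ri[1, 1])) * 180 / pi
  # solve offset so that inv(T)(T(p)) = p with same center
  t_new <- -as.numeric(Ri %*% tr$t)
  rigid_transform(t_new, ang, tr$center)
}

#' @rdname rigid_transform
#' @param a,b transforms; returns the transform equivalent to applying `b`
#'   first, then `a` (shared center required).
#' @export
compose_transforms <- function(a, b) {
  stopifnot(max(abs(a$center - b$center)) < 1e-9)
  R <- rot_matrix(a$r) %*% rot_matrix(b$r)
  ang <- c(atan2(R[3, 2], R[3, 3]),
           atan2(-R[3, 1], sqrt(R[3, 2]^2 + R[3, 3]^2)),
           atan2(R[2, 1], R[1, 1])) * 180 / pi
  t_new <- as.numeric(rot_matrix(a$r) %*% b$t) + a$t
  rigid_transform(t_new, ang, a$center)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> t = (%.2f, %.2f, %.2f) mm, r = (%.2f, %.2f, %.2f) deg\n",
              x$t[1], x$t[2], x$t[3], x$r[1], x$r[2], x$r[3]))
  invisible(x)
}

# trilinear interpolation of a 3D array at fractional voxel coordinates
# (1-based); outside values -> 0
interp3 <- function(arr, coords) {
  d <- dim(arr)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- numeric(nrow(coords))
  get_at <- function(ix, iy, iz) {
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    v <- numeric(length(ix))
    idx <- ((iz[ok] - 1) * d[2] + (iy[ok] - 1)) * d[1] + ix[ok]
    v[ok] <- arr[idx]
    v
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) fx else 1 - fx) * (if (dy) fy else 1 - fy) *
      (if (dz) fz else 1 - fz)
    val <- val + w * get_at(x0 + dx, y0 + dy, z0 + dz)
  }
  val
}

resample_rigid <- function(arr, par, voxel_mm, pts_mm = NULL) {
  d <- dim(arr)
  tr <- rigid_transform(par[1:3], par[4:6])
  ctr <- (d + 1) / 2
  if (is.null(pts_mm)) pts_mm <- resample_grid_mm(d, voxel_mm)
  src_mm <- transform_points(invert_transform(tr), pts_mm)
  src_vox <- sweep(src_mm / rep(voxel_mm, each = nrow(src_mm)), 2, ctr, "+")
  array(interp3(arr, src_vox), dim = d)
}

resample_grid_mm <- function(d, voxel_mm) {
  grid <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                z = seq_len(d[3])))
  sweep(grid, 2, (d + 1) / 2) * rep(voxel_mm, each = nrow(grid))
}

#' Rigid volume-to-volume registration
#'
#' Least-squares (sum of squared intensity differences) rigid registration
#' with a multi-resolution pyramid and Nelder-Mead optimization over the 6
#' rigid parameters. Returns the transform mapping the moving volume onto
#' the fixed volume.
#'
#' @param moving,fixed 3D arrays on the same grid.
#' @param voxel_mm voxel size (scalar or length-3), mm.
#' @param levels number of resolution levels.
#' @return a [rigid_transform()] with attributes `converged` and `ssd`.
#' @export
rigid_register <- function(moving, fixed, voxel_mm = 1, levels = 3) {
  stopifnot(identical(dim(moving), dim(fixed)), length(dim(moving)) == 3)
  voxel_mm <- rep(voxel_mm, length.out = 3)
  if (sum((moving - fixed)^2) == 0)
    return(structure(rigid_transform(), converged = TRUE, ssd = 0))
  down2 <- function(a) {
    d <- dim(a); d2 <- pmax(1, d %/% 2)
    i <- function(k, n) pmin(2 * seq_len(k), n)
    (a[i(d2[1], d[1]) - 1, i(d2[2], d[2]) - 1, i(d2[3], d[3]) - 1, drop = FALSE] +
       a[i(d2[1], d[1]), i(d2[2], d[2]), i(d2[3], d[3]), drop = FALSE]) / 2
  }
  pyr_m <- list(moving); pyr_f <- list(fixed); vox <- list(voxel_mm)
  for (l in seq_len(levels - 1)) {
    if (min(dim(pyr_m[[l]])) < 8) break
    pyr_m[[l + 1]] <- down2(pyr_m[[l]])
    pyr_f[[l + 1]] <- down2(pyr_f[[l]])
    vox[[l + 1]] <- vox[[l]] * dim(pyr_m[[l]]) / dim(pyr_m[[l + 1]])
  }
  par <- rep(0, 6)
  conv <- TRUE
  for (l in rev(seq_along(pyr_m))) {
    m <- pyr_m[[l]]; f <- pyr_f[[l]]; v <- vox[[l]]
    pts <- resample_grid_mm(dim(m), v)
    obj <- function(p) sum((resample_rigid(m, p, v, pts) - f)^2)
    # restart the simplex at each level: Nelder-Mead simplices collapse
    # near the optimum, a fresh start recovers the last fraction of a voxel
    for (round in 1:2) {
      o <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-12,
                                       parscale = c(1, 1, 1, 0.5, 0.5, 0.5)))
      par <- o$par
    }
    conv <- conv && o$convergence == 0
  }
  structure(rigid_transform(par[1:3], par[4:6]),
            converged = conv, ssd = o$value)
}

#' Mean voxel displacement of a rigid transform
#'
#' Mean over masked voxel centers of the displacement magnitude
#' `||T(r) - r||` — the motion-severity metric used to compare corrected
#' and uncorrected acquisitions.
#'
#' @param transform a [rigid_transform()].
#' @param n grid size (scalar or length-3).
#' @param fov_mm grid extent, mm.
#' @param mask logical array selecting voxels (default: all).
#' @return mean displacement, mm.
#' @export
mean_voxel_displacement <- function(transform, n = 16, fov_mm = c(200, 200, 200),
                                    mask = NULL) {
  g <- phantom_grid_mm(n, fov_mm, 3)
  pts <- as.matrix(expand.grid(x = g$x, y = g$y, z = g$z))
  if (!is.null(mask)) {
    stopifnot(length(mask) == nrow(pts))
    pts <- pts[as.logical(mask), , drop = FALSE]
  }
  if (!nrow(pts)) stop("empty mask", call. = FALSE)
  d <- transform_points(transform, pts) - pts
  mean(sqrt(rowSums(d^2)))
}
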