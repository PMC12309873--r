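#' Pixelwise ADC fitting
#'
#' The diffusion signal model is `S(b) = S0 exp(-b D)`. Per b-value the
#' geometric mean over the diffusion axes yields isotropic trace-weighted
#' images; a pixelwise least-squares line fit of `log S` against `b`
#' returns the apparent diffusion coefficient map `D` and `S0`. Voxels with
#' nonpositive signal at any b are masked out.
#'
#' @param volumes list over b-values; each element either one array or a
#'   list of per-axis arrays (geometric-mean combined).
#' @param b_values numeric vector, s/mm^2, same length as `volumes`.
#' @return list with arrays `D` (mm^2/s), `S0`, and logical `mask`.
#' @export
fit_adc <- function(volumes, b_values) {
  if (length(b_values) < 2) stop("need at least 2 distinct b-values", call. = FALSE)
  stopifnot(length(volumes) == length(b_values))
  gm <- lapply(volumes, function(v) {
    if (!is.list(v)) return(v)
    lg <- Reduce(`+`, lapply(v, function(a) log(pmax(a, .Machine$double.eps))))
    exp(lg / length(v))
  })
  dm <- dim(gm[[1]])
  S <- vapply(gm, as.numeric, numeric(length(gm[[1]])))   # voxels x b
  mask <- apply(S > 0, 1, all)
  y <- log(pmax(S, .Machine$double.eps))
  b <- b_values
  bm <- mean(b)
  denom <- sum((b - bm)^2)
  slope <- as.numeric(y %*% (b - bm)) / denom
  inter <- rowMeans(y) - slope * bm
  D <- -slope; D[!mask] <- NA_real_
  S0 <- exp(inter); S0[!mask] <- NA_real_
  list(D = array(D, dm), S0 = array(S0, dm), mask = array(mask, dm))
}

#' Decode Hadamard time-encoded ASL volumes
#'
#' With a Walsh-ordered n x n encoding, the n acquired volumes are combined
#' into n-1 subbolus perfusion-weighted volumes:
#' `P_j = -(1/(n/2)) * sum_i H[i, j+1] * V_i`, the exact left-inverse of
#' the encoding (sign convention: labeling reduces signal, so decoded
#' label-control perfusion is positive). Independent noise of sd sigma per
#' volume propagates to sigma/sqrt(n/4)/... = sigma * sqrt(2/n) per
#' subbolus (sigma/sqrt(2) for n = 8).
#'
#' @param volumes list of n arrays (acquired encodes, in row order of `H`).
#' @param H the encoding matrix (default Walsh-ordered Hadamard-8).
#' @return list of n-1 decoded subbolus volumes (earliest subbolus first).
#' @export
hadamard_decode <- function(volumes, H = hadamard_walsh(8)) {
  n <- nrow(H)
  if (length(volumes) != n)
    stop("expected ", n, " encoded volumes, got ", length(volumes), call. = FALSE)
  lapply(seq_len(n - 1), function(j) {
    acc <- 0
    for (i in seq_len(n)) acc <- acc + H[i, j + 1] * volumes[[i]]
    -acc / (n / 2)
  })
}
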