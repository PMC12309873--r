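#' Gyromagnetic ratio of the proton
#'
#' In Hz/T (i.e. gamma/2pi). Used for RF amplitude scaling, slice-select
#' gradient strength, k-space trajectories and b-values. Configurable in
#' every function that needs it.
#'
#' @export
GAMMA_HZ_PER_T <- 42.577478518e6

# raster defaults (ns): RF 1 us, gradient 10 us, block granularity 10 us
RF_RASTER_NS <- 1e3
GRAD_RASTER_NS <- 1e4
BLOCK_RASTER_NS <- 1e4

#' Hardware limits
#'
#' First-class description of the scanner hardware a sequence must respect:
#' maximum gradient amplitude, maximum slew rate, the event rasters, and the
#' peak B1 the transmit chain can produce. All generated waveforms are
#' checked against these limits.
#'
#' @param g_max_mT_m maximum gradient amplitude per axis, mT/m.
#' @param slew_mT_m_ms maximum slew rate, mT/m/ms.
#' @param rf_raster_ns RF sample raster, ns.
#' @param grad_raster_ns gradient raster, ns.
#' @param block_raster_ns execution-block duration granularity, ns.
#' @param b1_max_uT peak RF amplitude ceiling, microtesla.
#' @param gamma_hz_t gyromagnetic ratio, Hz/T.
#' @return an object of class `"hardware_limits"`.
#' @export
hardware_limits <- function(g_max_mT_m = 40, slew_mT_m_ms = 150,
                            rf_raster_ns = RF_RASTER_NS,
                            grad_raster_ns = GRAD_RASTER_NS,
                            block_raster_ns = BLOCK_RASTER_NS,
                            b1_max_uT = 25,
                            gamma_hz_t = GAMMA_HZ_PER_T) {
  stopifnot(g_max_mT_m > 0, slew_mT_m_ms > 0, rf_raster_ns > 0,
            grad_raster_ns > 0, block_raster_ns > 0, b1_max_uT > 0)
  structure(list(g_max = g_max_mT_m, slew = slew_mT_m_ms,
                 rf_raster_ns = rf_raster_ns, grad_raster_ns = grad_raster_ns,
                 block_raster_ns = block_raster_ns, b1_max_uT = b1_max_uT,
                 gamma = gamma_hz_t),
            class = "hardware_limits")
}

# round a duration up to the next raster multiple (times are ns in doubles,
# exact for integers below 2^53)
ceil_raster <- function(t_ns, raster_ns) ceiling(round(t_ns, 6) / raster_ns) * raster_ns

ms_to_ns <- function(ms) round(ms * 1e6)
ns_to_ms <- function(ns) ns / 1e6
ns_to_s <- function(ns) ns / 1e9
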