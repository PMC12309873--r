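#' In-vivo protocol presets
#'
#' The whole-brain measurement protocols shipped with the package, one per
#' sequence family (TR/TE/TI, flip angles, FOV, matrix, partial Fourier,
#' acceleration, train lengths, averages, prescans and the family-specific
#' extras). These drive the protocol-arithmetic checks (durations, train
#' lengths, spoke counts, inflow times) and serve as templates for custom
#' protocols.
#'
#' @param family a [build_sequence()] family, or "grase_pcasl_m0" for the
#'   unlabeled M0 variant.
#' @return an [mr_protocol()].
#' @export
protocol_preset <- function(family = c("flash", "bssfp", "mprage", "rare",
                                       "flair", "se_epi_diffusion",
                                       "grase_pcasl", "grase_pcasl_m0",
                                       "radial_ute", "steam", "press")) {
  family <- match.arg(family)
  geom3d <- list(fov = c(256, 192, 160), mat = c(256L, 192L, 160L))
  switch(family,
    flash = mr_protocol(TR_ms = 10, TE_ms = 5, flip_deg = 10,
                        fov_mm = geom3d$fov, matrix_size = geom3d$mat,
                        partial_fourier = c(1, 0.75), acceleration = c(2L, 1L)),
    bssfp = mr_protocol(TR_ms = 5, TE_ms = 2.5, flip_deg = 10,
                        fov_mm = geom3d$fov, matrix_size = geom3d$mat,
                        partial_fourier = c(1, 0.75), acceleration = c(2L, 1L),
                        prescans = 10L),
    mprage = mr_protocol(TR_ms = 2200, TE_ms = 2.9, TI_ms = 900, flip_deg = 8,
                         fov_mm = geom3d$fov, matrix_size = geom3d$mat,
                         partial_fourier = c(1, 0.75), acceleration = c(2L, 1L)),
    rare = mr_protocol(TR_ms = 6000, TE_ms = 48, flip_deg = 90,
                       refocus_deg = 150, fov_mm = c(256, 192, 160),
                       matrix_size = c(256L, 192L, 32L),
                       partial_fourier = c(1, 1), acceleration = c(2L, 1L),
                       train_length = c(8L, NA), slice_thickness_mm = 5),
    flair = mr_protocol(TR_ms = 9000, TE_ms = 84, TI_ms = 2600, flip_deg = 90,
                        refocus_deg = 150, fov_mm = c(256, 192, 160),
                        matrix_size = c(256L, 192L, 32L),
                        partial_fourier = c(1, 1), acceleration = c(2L, 1L),
                        train_length = c(12L, NA), slice_thickness_mm = 5,
                        extras = list(concatenations = 2L)),
    se_epi_diffusion = mr_protocol(TR_ms = 8000, TE_ms = 100, flip_deg = 90,
                                   refocus_deg = 180,
                                   fov_mm = c(240, 180, 162),
                                   matrix_size = c(80L, 60L, 54L),
                                   partial_fourier = c(1, 1),
                                   acceleration = c(2L, 1L),
                                   train_length = c(30L, NA),
                                   slice_thickness_mm = 3,
                                   extras = list(diff_b = c(0, 300, 600),
                                                 diff_delta_ms = 16)),
    grase_pcasl = mr_protocol(TR_ms = 4000, TE_ms = 17.9, flip_deg = 90,
                              refocus_deg = 120, fov_mm = c(256, 192, 160),
                              matrix_size = c(64L, 48L, 32L),
                              partial_fourier = c(1, 0.75),
                              acceleration = c(2L, 2L),
                              train_length = c(24L, 12L), averages = 4L,
                              prescans = 1L,
                              extras = list(asl_subbolus_s = 0.4,
                                            asl_pld_s = 0.6,
                                            asl_bs_T1_ms = c(700, 1400))),
    grase_pcasl_m0 = mr_protocol(TR_ms = 5000, TE_ms = 17.9, flip_deg = 90,
                                 refocus_deg = 120, fov_mm = c(256, 192, 160),
                                 matrix_size = c(64L, 48L, 32L),
                                 partial_fourier = c(1, 0.75),
                                 acceleration = c(2L, 2L),
                                 train_length = c(24L, 12L), averages = 1L,
                                 prescans = 1L,
                                 extras = list(asl_subbolus_s = 0.4,
                                               asl_pld_s = 0.6, m0 = TRUE)),
    radial_ute = mr_protocol(TR_ms = 6, TE_ms = 0.1, flip_deg = 10,
                             fov_mm = c(256, 256, 256),
                             matrix_size = c(192L, 192L, 192L),
                             extras = list(spokes = 20000L, cal_angles = 180L)),
    steam = mr_protocol(TR_ms = 2000, TE_ms = 20, flip_deg = 90,
                        fov_mm = c(25, 25, 25), matrix_size = c(1L, 1L, 1L),
                        averages = 96L, prescans = 2L,
                        extras = list(data_points = 2048L,
                                      spectral_bw_hz = 2000, mixing_ms = 10)),
    press = mr_protocol(TR_ms = 2000, TE_ms = 32, flip_deg = 90,
                        refocus_deg = 180, fov_mm = c(25, 25, 25),
                        matrix_size = c(1L, 1L, 1L),
                        averages = 96L, prescans = 2L,
                        extras = list(data_points = 2048L,
                                      spectral_bw_hz = 2000)))
}
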