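# Toy protocols: small matrices so full traversals stay fast while every
# structural feature (loops, trains, encodes, labeling) is exercised.

toy_protocol <- function(family) {
  switch(family,
    flash = mr_protocol(TR_ms = 12, TE_ms = 5, flip_deg = 10,
                        fov_mm = c(128, 128, 32), matrix_size = c(16L, 8L, 2L)),
    bssfp = mr_protocol(TR_ms = 12, TE_ms = 6, flip_deg = 10,
                        fov_mm = c(128, 128, 32), matrix_size = c(16L, 8L, 2L),
                        prescans = 4L),
    mprage = mr_protocol(TR_ms = 200, TE_ms = 5, TI_ms = 50, flip_deg = 8,
                         fov_mm = c(128, 128, 32), matrix_size = c(16L, 8L, 2L)),
    rare = mr_protocol(TR_ms = 400, TE_ms = 14, flip_deg = 90, refocus_deg = 150,
                       fov_mm = c(128, 128, 20), matrix_size = c(16L, 8L, 2L),
                       train_length = c(4L, NA), slice_thickness_mm = 5),
    flair = mr_protocol(TR_ms = 900, TE_ms = 14, TI_ms = 100, flip_deg = 90,
                        refocus_deg = 150, fov_mm = c(128, 128, 20),
                        matrix_size = c(16L, 8L, 4L), train_length = c(4L, NA),
                        slice_thickness_mm = 4,
                        extras = list(concatenations = 2L)),
    se_epi_diffusion = mr_protocol(TR_ms = 400, TE_ms = 80, flip_deg = 90,
                                   refocus_deg = 180, fov_mm = c(128, 128, 20),
                                   matrix_size = c(16L, 8L, 2L),
                                   train_length = c(8L, NA),
                                   slice_thickness_mm = 5,
                                   extras = list(diff_b = c(0, 60, 120),
                                                 diff_delta_ms = 14)),
    grase_pcasl = mr_protocol(TR_ms = 1500, TE_ms = 16, flip_deg = 90,
                              refocus_deg = 120, fov_mm = c(128, 128, 32),
                              matrix_size = c(16L, 8L, 4L),
                              partial_fourier = c(1, 1),
                              acceleration = c(1L, 1L),
                              train_length = c(8L, 4L), averages = 1L,
                              extras = list(asl_subbolus_s = 0.1,
                                            asl_pld_s = 0.35)),
    radial_ute = mr_protocol(TR_ms = 6, TE_ms = 0.1, flip_deg = 10,
                             fov_mm = c(128, 128, 128),
                             matrix_size = c(32L, 32L, 32L),
                             extras = list(spokes = 16L, cal_angles = 4L)),
    steam = mr_protocol(TR_ms = 100, TE_ms = 20, flip_deg = 90,
                        fov_mm = c(25, 25, 25), matrix_size = c(1L, 1L, 1L),
                        averages = 3L, prescans = 2L,
                        extras = list(data_points = 64L, spectral_bw_hz = 2000,
                                      mixing_ms = 10)),
    press = mr_protocol(TR_ms = 100, TE_ms = 32, flip_deg = 90,
                        refocus_deg = 180, fov_mm = c(25, 25, 25),
                        matrix_size = c(1L, 1L, 1L), averages = 3L,
                        prescans = 2L,
                        extras = list(data_points = 64L, spectral_bw_hz = 2000)))
}

toy_families <- c("flash", "bssfp", "mprage", "rare", "flair",
                  "se_epi_diffusion", "grase_pcasl", "radial_ute",
                  "steam", "press")

# random DAG on a fresh parameter graph; sources feed arithmetic rules.
# Returns the graph plus a mirror of the structure for a naive oracle.
random_dag_graph <- function(n_nodes = 30, p_source = 0.3) {
  g <- param_graph()
  kind <- character(n_nodes)
  deps <- vector("list", n_nodes)
  coefs <- vector("list", n_nodes)
  vals <- numeric(n_nodes)
  for (i in seq_len(n_nodes)) {
    id <- paste0("n", i)
    if (i <= 2 || stats::runif(1) < p_source) {
      kind[i] <- "source"
      vals[i] <- stats::rnorm(1)
      pg_source(g, id, vals[i])
    } else {
      kind[i] <- "rule"
      nd <- sample(seq_len(min(i - 1, 4)), 1)
      dd <- sample(seq_len(i - 1), nd)
      cf <- stats::rnorm(nd + 1)
      deps[[i]] <- dd
      coefs[[i]] <- cf
      pg_add(g, id, local({
        cf <- cf
        function(...) cf[1] + sum(cf[-1] * unlist(list(...)))
      }), deps = paste0("n", dd))
    }
  }
  list(graph = g, kind = kind, deps = deps, coefs = coefs, vals = vals)
}

# naive full recomputation oracle over the mirrored structure
naive_eval_all <- function(dag) {
  n <- length(dag$kind)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- if (dag$kind[i] == "source") dag$vals[i] else
      dag$coefs[[i]][1] + sum(dag$coefs[[i]][-1] * out[dag$deps[[i]]])
  }
  out
}

adc_blocks <- function(blocks) Filter(function(b) !is.null(b$adc), blocks)

rf_center_abs <- function(b) b$start_ns + b$rf$start_ns +
  b$rf$center_frac * b$rf$duration_ns

adc_center_abs <- function(b) b$start_ns + b$adc$start_ns +
  b$adc$n * b$adc$dwell_ns / 2
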