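#' Line-oriented debug dump of a block stream
#'
#' One line per execution block with start/duration and a compact event
#' summary — a human-readable view of exactly what would be sent to the
#' hardware, useful for diffing and debugging.
#'
#' @param blocks list of [execution_block()]s (or an `mr_sequence`, which
#'   is traversed first).
#' @return character vector of lines.
#' @export
dump_blocks <- function(blocks) {
  if (inherits(blocks, "mr_sequence")) blocks <- stream_collect(blocks)
  vapply(blocks, function(b) {
    parts <- sprintf("t=%12.3fms dur=%9.3fms", ns_to_ms(b$start_ns),
                     ns_to_ms(b$duration_ns))
    if (!is.null(b$rf))
      parts <- c(parts, sprintf("RF[%s %.1fdeg f=%+.0fHz ph=%.2f]",
                                b$rf$purpose, b$rf$flip_deg, b$rf$freq_hz,
                                b$rf$phase_rad))
    for (g in b$gradients) {
      amp <- if (g$kind == "trap") g$amp_mT_m else max(abs(g$samples_mT_m))
      parts <- c(parts, sprintf("G%s[%+.2fmT/m %s]", substr(g$axis, 1, 2),
                                amp, g$kind))
    }
    if (!is.null(b$adc)) {
      h <- b$adc$header
      parts <- c(parts, sprintf("ADC[%dx%.1fus lin=%d par=%d slc=%d avg=%d ctr=%d]",
                                b$adc$n, b$adc$dwell_ns / 1e3, h$line,
                                h$partition, h$slice, h$average, h$contrast))
    }
    if (b$sync) parts <- c(parts, "SYNC")
    paste(parts, collapse = " ")
  }, character(1))
}
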