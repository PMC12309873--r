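#' Sequence protocol
#'
#' User-facing acquisition parameters: timing (TR/TE/TI, ms), flip angles,
#' geometry (FOV, matrix), partial Fourier and parallel-imaging
#' acceleration per encoded direction, echo-train lengths, averages and
#' prescans, plus an open set of sequence-specific extras (b-values,
#' subbolus duration, post-labeling delay, spokes, spectral points,
#' bandwidth, mixing time, concatenations, ...).
#'
#' @param TR_ms,TE_ms,TI_ms repetition/echo/inversion times, ms; `TI_ms`
#'   may be NULL when the sequence has no inversion.
#' @param flip_deg excitation flip angle, degrees.
#' @param refocus_deg refocusing flip angle, degrees (NA if unused).
#' @param fov_mm length-3 field of view, mm.
#' @param matrix_size length-3 integer matrix (read, phase, partition/slices).
#' @param partial_fourier length-2 fraction (phase, slice/partition).
#' @param acceleration length-2 integer (phase, slice/partition).
#' @param train_length length-2 echo-train length (phase, partition); NA
#'   where not applicable.
#' @param averages,prescans non-negative integers.
#' @param slice_thickness_mm excited slice/slab thickness, mm.
#' @param extras named list of sequence-specific parameters.
#' @return an object of class `"mr_protocol"` (a validated named list).
#' @export
mr_protocol <- function(TR_ms, TE_ms, TI_ms = NULL, flip_deg = 90,
                        refocus_deg = NA_real_, fov_mm = c(256, 256, 256),
                        matrix_size = c(64, 64, 1),
                        partial_fourier = c(1, 1), acceleration = c(1L, 1L),
                        train_length = c(NA_integer_, NA_integer_),
                        averages = 1L, prescans = 0L,
                        slice_thickness_mm = 5, extras = list()) {
  stopifnot(TR_ms > 0, TE_ms > 0, is.null(TI_ms) || TI_ms > 0,
            length(fov_mm) == 3, all(fov_mm > 0),
            length(matrix_size) == 3, all(matrix_size >= 1),
            length(partial_fourier) == 2,
            all(partial_fourier > 0), all(partial_fourier <= 1),
            length(acceleration) == 2, all(acceleration >= 1),
            averages >= 0, prescans >= 0, slice_thickness_mm > 0)
  structure(list(TR_ms = TR_ms, TE_ms = TE_ms, TI_ms = TI_ms,
                 flip_deg = flip_deg, refocus_deg = refocus_deg,
                 fov_mm = fov_mm, matrix_size = as.integer(matrix_size),
                 partial_fourier = partial_fourier,
                 acceleration = as.integer(acceleration),
                 train_length = train_length,
                 averages = as.integer(averages),
                 prescans = as.integer(prescans),
                 slice_thickness_mm = slice_thickness_mm,
                 extras = extras),
            class = "mr_protocol")
}

#' @export
print.mr_protocol <- function(x, ...) {
  cat(sprintf("<mr_protocol> TR/TE%s = %g/%g%s ms, flip %g deg, matrix %s, FOV %s mm\n",
              if (!is.null(x$TI_ms)) "/TI" else "",
              x$TR_ms, x$TE_ms,
              if (!is.null(x$TI_ms)) paste0("/", x$TI_ms) else "",
              x$flip_deg, paste(x$matrix_size, collapse = "x"),
              paste(x$fov_mm, collapse = "x")))
  if (length(x$extras))
    cat("  extras:", paste(names(x$extras), collapse = ", "), "\n")
  invisible(x)
}

# flatten protocol into graph source nodes "protocol.<name>"
protocol_sources <- function(graph, protocol) {
  scal <- c("TR_ms", "TE_ms", "TI_ms", "flip_deg", "refocus_deg", "averages",
            "prescans", "slice_thickness_mm")
  for (s in scal) {
    if (!is.null(protocol[[s]])) pg_source(graph, paste0("protocol.", s), protocol[[s]])
  }
  pg_source(graph, "protocol.fov_mm", protocol$fov_mm)
  pg_source(graph, "protocol.matrix_size", protocol$matrix_size)
  pg_source(graph, "protocol.partial_fourier", protocol$partial_fourier)
  pg_source(graph, "protocol.acceleration", protocol$acceleration)
  pg_source(graph, "protocol.train_length", protocol$train_length)
  for (nm in names(protocol$extras))
    pg_source(graph, paste0("protocol.", nm), protocol$extras[[nm]])
  # geometry exposed for feedback (slice position/orientation)
  if (!pg_exists(graph, "protocol.slice_offset_mm"))
    pg_source(graph, "protocol.slice_offset_mm", 0)
  invisible(graph)
}
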