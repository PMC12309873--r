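#' Pulseq interchange
#'
#' Bidirectional translation between the internal execution-block stream
#' and the open Pulseq text sequence format (1.4.x dialect). Export
#' traverses the sequence exactly as the runtime does and translates each
#' block; logical axes read/phase/slice map to the gx/gy/gz channels.
#' Acquisition-header counters have no Pulseq representation and are
#' carried in a JSON sidecar (`<file>.labels.json`); pure-Pulseq consumers
#' lose them.
#'
#' @param x an `mr_sequence` or a list of [execution_block()]s.
#' @param file optional path; when given, the document text (and the label
#'   sidecar) is written there.
#' @param name sequence name for the definitions section.
#' @param limits a [hardware_limits()] supplying rasters and gamma.
#' @return a `pulseq_document` (invisibly when `file` is given).
#' @export
export_pulseq <- function(x, file = NULL, name = "mrforge",
                          limits = hardware_limits()) {
  blocks <- if (inherits(x, "mr_sequence")) stream_collect(x) else x
  fmt <- function(v) sprintf("%.9g", v)
  shapes <- list(); shape_key <- character()
  shape_id <- function(samples) {
    key <- paste(fmt(samples), collapse = ",")
    i <- match(key, shape_key)
    if (!is.na(i)) return(i)
    shapes[[length(shapes) + 1L]] <<- samples
    shape_key[length(shape_key) + 1L] <<- key
    length(shapes)
  }
  rf_tab <- list(); rf_key <- character()
  trap_tab <- list(); trap_key <- character()
  grad_tab <- list(); grad_key <- character()
  adc_tab <- list(); adc_key <- character()
  intern <- function(tab, keys, key, row, env) {
    i <- match(key, get(keys, envir = env))
    if (!is.na(i)) return(i)
    assign(tab, c(get(tab, envir = env), list(row)), envir = env)
    assign(keys, c(get(keys, envir = env), key), envir = env)
    length(get(tab, envir = env))
  }
  env <- environment()
  gamma <- limits$gamma
  rows <- list()
  labels <- list()
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    rf_id <- 0L
    if (!is.null(b$rf)) {
      r <- b$rf
      mag <- Mod(r$samples)
      ph <- (Arg(r$samples) / (2 * pi)) %% 1
      mid <- shape_id(mag); pid <- shape_id(ph)
      amp_hz <- gamma * r$amplitude_uT * 1e-6
      row <- c(amp = amp_hz, mag_id = mid, phase_id = pid, time_id = 0,
               delay = round(r$start_ns / 1e3), freq = r$freq_hz,
               phase = r$phase_rad)
      rf_id <- intern("rf_tab", "rf_key", paste(fmt(row), collapse = " "),
                      row, env)
    }
    g_ids <- c(gx = 0L, gy = 0L, gz = 0L)
    ax_map <- c(read = "gx", phase = "gy", slice = "gz",
                x = "gx", y = "gy", z = "gz")
    for (g in merge_block_gradients(b$gradients, limits$grad_raster_ns)) {
      ch <- ax_map[[g$axis]]
      # trapezoids and arbitrary gradients share one id space (Pulseq
      # convention); rows are stored at their id with holes in the other
      # table
      if (g$kind == "trap") {
        amp <- gamma * g$amp_mT_m * 1e-3
        row <- c(amp = amp, rise = round(g$rise_ns / 1e3),
                 flat = round(g$flat_ns / 1e3), fall = round(g$fall_ns / 1e3),
                 delay = round(g$start_ns / 1e3))
        key <- paste("T", paste(fmt(row), collapse = " "))
        i <- match(key, grad_key)
        if (is.na(i)) {
          grad_key <- c(grad_key, key)
          i <- length(grad_key)
          trap_tab[[i]] <- row
        }
        g_ids[[ch]] <- i
      } else {
        pk <- max(abs(g$samples_mT_m))
        norm <- if (pk > 0) g$samples_mT_m / pk else g$samples_mT_m
        sid <- shape_id(norm)
        row <- c(amp = gamma * pk * 1e-3, shape_id = sid, time_id = 0,
                 delay = round(g$start_ns / 1e3))
        key <- paste("G", paste(fmt(row), collapse = " "))
        i <- match(key, grad_key)
        if (is.na(i)) {
          grad_key <- c(grad_key, key)
          i <- length(grad_key)
          grad_tab[[i]] <- row
        }
        g_ids[[ch]] <- i
      }
    }
    adc_id <- 0L
    if (!is.null(b$adc)) {
      a <- b$adc
      row <- c(num = a$n, dwell = a$dwell_ns, delay = round(a$start_ns / 1e3),
               freq = a$freq_hz, phase = a$phase_rad)
      adc_id <- intern("adc_tab", "adc_key", paste(fmt(row), collapse = " "),
                       row, env)
      labels[[length(labels) + 1L]] <-
        c(list(block = bi), unclass(a$header)[c("line", "partition", "slice",
                                                "average", "set", "repetition",
                                                "contrast", "segment",
                                                "trajectory_id")],
          list(flags = as.list(a$header$flags)))
    }
    rows[[bi]] <- c(id = bi, dur = round(b$duration_ns / limits$block_raster_ns),
                    rf = rf_id, gx = g_ids[["gx"]], gy = g_ids[["gy"]],
                    gz = g_ids[["gz"]], adc = adc_id, ext = 0)
  }
  doc <- structure(list(
    version = c(1, 4, 1),
    definitions = list(AdcRasterTime = 1e-7,
                       BlockDurationRaster = limits$block_raster_ns * 1e-9,
                       GradientRasterTime = limits$grad_raster_ns * 1e-9,
                       RadiofrequencyRasterTime = limits$rf_raster_ns * 1e-9,
                       Name = name),
    blocks = do.call(rbind, rows),
    rf = rf_tab, trap = trap_tab, grad = grad_tab, adc = adc_tab,
    shapes = shapes, labels = labels), class = "pulseq_document")
  if (!is.null(file)) {
    writeLines(format_pulseq(doc), file)
    jsonlite::write_json(doc$labels,
                         paste0(tools::file_path_sans_ext(file), ".labels.json"),
                         auto_unbox = TRUE)
    return(invisible(doc))
  }
  doc
}

# Pulseq permits one gradient event per channel and block; sequential
# events on the same logical axis are merged into a single sampled
# waveform on the gradient raster
merge_block_gradients <- function(gl, raster_ns) {
  if (!length(gl)) return(gl)
  axes <- vapply(gl, function(g) g$axis, character(1))
  out <- list()
  for (ax in unique(axes)) {
    gs <- gl[axes == ax]
    if (length(gs) == 1) { out <- c(out, gs); next }
    t0 <- floor(min(vapply(gs, function(g) g$start_ns, numeric(1))) / raster_ns) * raster_ns
    t1 <- max(vapply(gs, event_end_ns, numeric(1)))
    nt <- ceiling((t1 - t0) / raster_ns)
    w <- numeric(nt)
    for (g in gs) {
      s <- grad_samples(g, raster_ns)
      i0 <- round((g$start_ns - t0) / raster_ns)
      idx <- seq_along(s) + i0
      w[idx] <- w[idx] + s
    }
    out <- c(out, list(grad_wave(ax, t0, w, raster_ns)))
  }
  out
}

#' @rdname export_pulseq
#' @param doc a `pulseq_document`.
#' @export
format_pulseq <- function(doc) {
  fmt <- function(v) sprintf("%.9g", v)
  out <- c("# Pulseq sequence file", "")
  out <- c(out, "[VERSION]", paste("major", doc$version[1]),
           paste("minor", doc$version[2]), paste("revision", doc$version[3]), "")
  out <- c(out, "[DEFINITIONS]")
  for (nm in sort(names(doc$definitions))) {
    v <- doc$definitions[[nm]]
    out <- c(out, paste(nm, if (is.numeric(v)) fmt(v) else v))
  }
  out <- c(out, "")
  out <- c(out, "[BLOCKS]")
  for (i in seq_len(nrow(doc$blocks) %||% 0))
    out <- c(out, paste(fmt(doc$blocks[i, ]), collapse = " "))
  out <- c(out, "")
  emit_tab <- function(section, tab) {
    ids <- which(!vapply(tab, is.null, logical(1)))
    if (!length(ids)) return(character())
    c(paste0("[", section, "]"),
      vapply(ids, function(i)
        paste(c(fmt(i), fmt(tab[[i]])), collapse = " "), character(1)),
      "")
  }
  out <- c(out, emit_tab("RF", doc$rf), emit_tab("TRAP", doc$trap),
           emit_tab("GRADIENTS", doc$grad), emit_tab("ADC", doc$adc))
  if (length(doc$shapes)) {
    out <- c(out, "[SHAPES]", "")
    for (i in seq_along(doc$shapes)) {
      out <- c(out, paste("shape_id", i),
               paste("num_samples", length(doc$shapes[[i]])),
               fmt(doc$shapes[[i]]), "")
    }
  }
  out
}

#' Parse a Pulseq text document
#'
#' @param lines character vector of file lines, or a file path.
#' @return a `pulseq_document`.
#' @export
parse_pulseq <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  lines_raw <- lines
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  sec <- NULL
  doc <- list(version = c(NA, NA, NA), definitions = list(),
              blocks = NULL, rf = list(), trap = list(), grad = list(),
              adc = list(), shapes = list(), labels = list())
  block_rows <- list()
  shape_cur <- NULL; shape_vals <- list()
  flush_shape <- function() {
    if (!is.null(shape_cur))
      doc$shapes[[shape_cur]] <<- as.numeric(unlist(shape_vals))
    shape_cur <<- NULL; shape_vals <<- list()
  }
  for (li in seq_along(lines)) {
    ln <- lines[[li]]
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      flush_shape()
      sec <- toupper(gsub("\\[|\\]", "", ln))
      if (!sec %in% c("VERSION", "DEFINITIONS", "BLOCKS", "RF", "TRAP",
                      "GRADIENTS", "ADC", "SHAPES"))
        stop("unknown Pulseq section '", sec, "' at line ", li, call. = FALSE)
      next
    }
    if (is.null(sec))
      stop("content before first section at line ", li, call. = FALSE)
    tok <- strsplit(ln, "\\s+")[[1]]
    if (sec == "VERSION") {
      i <- match(tok[1], c("major", "minor", "revision"))
      if (is.na(i)) stop("bad version line ", li, call. = FALSE)
      doc$version[i] <- as.numeric(tok[2])
    } else if (sec == "DEFINITIONS") {
      v <- suppressWarnings(as.numeric(tok[2]))
      doc$definitions[[tok[1]]] <- if (is.na(v)) tok[2] else v
    } else if (sec == "BLOCKS") {
      v <- as.numeric(tok)
      if (length(v) < 7 || anyNA(v)) stop("bad block line ", li, call. = FALSE)
      block_rows[[length(block_rows) + 1L]] <-
        c(id = v[1], dur = v[2], rf = v[3], gx = v[4], gy = v[5], gz = v[6],
          adc = v[7], ext = if (length(v) >= 8) v[8] else 0)
    } else if (sec %in% c("RF", "TRAP", "GRADIENTS", "ADC")) {
      v <- as.numeric(tok)
      if (anyNA(v)) stop("bad ", sec, " line ", li, call. = FALSE)
      id <- v[1]
      row <- v[-1]
      names(row) <- switch(sec,
        RF = c("amp", "mag_id", "phase_id", "time_id", "delay", "freq", "phase"),
        TRAP = c("amp", "rise", "flat", "fall", "delay"),
        GRADIENTS = c("amp", "shape_id", "time_id", "delay"),
        ADC = c("num", "dwell", "delay", "freq", "phase"))
      slot <- switch(sec, RF = "rf", TRAP = "trap", GRADIENTS = "grad",
                     ADC = "adc")
      doc[[slot]][[id]] <- row
    } else if (sec == "SHAPES") {
      if (tok[1] == "shape_id") { flush_shape(); shape_cur <- as.integer(tok[2]) }
      else if (tok[1] == "num_samples") { }
      else shape_vals[[length(shape_vals) + 1L]] <- as.numeric(tok)
    }
  }
  flush_shape()
  if (anyNA(doc$version)) stop("missing [VERSION] section", call. = FALSE)
  doc$blocks <- do.call(rbind, block_rows)
  structure(doc, class = "pulseq_document")
}

#' Import a Pulseq document as a static block list
#'
#' Translates Pulseq blocks back to execution blocks (a flat list of static
#' atomics without loops or rules). Streaming the import reproduces the
#' document's event timeline exactly; [register_static_blocks()] embeds the
#' imported blocks as children of a native blueprint hierarchy.
#'
#' @param doc a `pulseq_document`, file path, or lines.
#' @param labels optional sidecar labels (list, path, or NULL).
#' @param limits a [hardware_limits()].
#' @return object of class `"pulseq_import"` with `$blocks`.
#' @export
import_pulseq <- function(doc, labels = NULL, limits = hardware_limits()) {
  if (!inherits(doc, "pulseq_document")) doc <- parse_pulseq(doc)
  if (is.character(labels) && length(labels) == 1 && file.exists(labels))
    labels <- jsonlite::fromJSON(labels, simplifyVector = FALSE)
  gamma <- limits$gamma
  raster_blk <- (doc$definitions$BlockDurationRaster %||% 1e-5) * 1e9
  raster_grad <- (doc$definitions$GradientRasterTime %||% 1e-5) * 1e9
  raster_rf <- (doc$definitions$RadiofrequencyRasterTime %||% 1e-6) * 1e9
  lab_by_block <- list()
  for (l in labels %||% list()) lab_by_block[[as.character(l$block)]] <- l
  blocks <- list()
  t_ns <- 0
  ax_name <- c(gx = "read", gy = "phase", gz = "slice")
  for (i in seq_len(nrow(doc$blocks) %||% 0)) {
    r <- doc$blocks[i, ]
    rf <- NULL
    if (r[["rf"]] > 0) {
      e <- doc$rf[[r[["rf"]]]]
      mag <- doc$shapes[[e[["mag_id"]]]]
      ph <- doc$shapes[[e[["phase_id"]]]]
      samples <- mag * exp(2i * pi * ph)
      b1_T <- e[["amp"]] / gamma
      flip <- 360 * e[["amp"]] * sum(mag) * raster_rf * 1e-9
      rf <- rf_event(e[["delay"]] * 1e3, samples, amplitude_uT = b1_T * 1e6,
                     freq_hz = e[["freq"]], phase_rad = e[["phase"]],
                     center_frac = (which.max(mag) - 0.5) / length(mag),
                     purpose = if (flip > 135) "refocusing" else "excitation",
                     flip_deg = flip, raster_ns = raster_rf)
    }
    grads <- list()
    for (ch in c("gx", "gy", "gz")) {
      gid <- r[[ch]]
      if (gid == 0) next
      if (length(doc$trap) >= gid && !is.null(doc$trap[[gid]])) {
        e <- doc$trap[[gid]]
        grads <- c(grads, list(grad_trap(ax_name[[ch]], e[["delay"]] * 1e3,
                                         e[["rise"]] * 1e3, e[["flat"]] * 1e3,
                                         e[["fall"]] * 1e3,
                                         e[["amp"]] / gamma * 1e3)))
      } else if (length(doc$grad) >= gid && !is.null(doc$grad[[gid]])) {
        e <- doc$grad[[gid]]
        s <- doc$shapes[[e[["shape_id"]]]] * e[["amp"]] / gamma * 1e3
        grads <- c(grads, list(grad_wave(ax_name[[ch]], e[["delay"]] * 1e3, s,
                                         raster_ns = raster_grad)))
      } else stop("block ", i, " references missing gradient id ", gid,
                  call. = FALSE)
    }
    adc <- NULL
    if (r[["adc"]] > 0) {
      e <- doc$adc[[r[["adc"]]]]
      l <- lab_by_block[[as.character(i)]]
      hdr <- if (is.null(l)) acq_header() else
        acq_header(line = l$line, partition = l$partition, slice = l$slice,
                   average = l$average, set = l$set, repetition = l$repetition,
                   contrast = l$contrast, segment = l$segment,
                   flags = as.character(unlist(l$flags)),
                   trajectory_id = l$trajectory_id)
      adc <- adc_event(e[["delay"]] * 1e3, e[["num"]], e[["dwell"]],
                       freq_hz = e[["freq"]], phase_rad = e[["phase"]],
                       header = hdr)
    }
    dur <- r[["dur"]] * raster_blk
    blocks[[i]] <- execution_block(t_ns, dur, rf = rf, gradients = grads,
                                   adc = adc, block_raster_ns = raster_blk)
    t_ns <- t_ns + dur
  }
  structure(list(blocks = blocks, definitions = doc$definitions),
            class = "pulseq_import")
}

#' @rdname import_pulseq
#' @param registry a [bp_registry()] to register into.
#' @param name module name under which the static atomics are grouped.
#' @param blocks list of execution blocks (e.g. from a `pulseq_import`).
#' @return the module blueprint name, ready to reference as a child.
#' @export
register_static_blocks <- function(registry, name, blocks) {
  kids <- character(length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    kids[i] <- paste0(name, "_blk", i)
    bp_register(registry, blueprint(kids[i], atomic = TRUE, rules = list(
      raw = rule(character(), local({
        b <- b
        function() list(duration_ns = b$duration_ns, rf = b$rf,
                        gradients = b$gradients, adc = b$adc)
      })))))
  }
  bp_register(registry, blueprint(name, children = kids))
  name
}
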