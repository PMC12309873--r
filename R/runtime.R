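#' Runtime configuration
#'
#' The stream is cut into time buffers of `buffer_ms` of sequence time
#' (typical values 30-300 ms). Feedback sync points sit at every buffer
#' boundary, and additionally before sync-marked atomics when
#' `sync_policy = "at_marked_atomics"`. The runtime is clocked by sequence
#' time (virtual), which keeps runs deterministic.
#'
#' @param buffer_ms buffer window, ms; must lie in [30, 300] unless
#'   `allow_any_window` is set.
#' @param sync_policy "every_buffer" or "at_marked_atomics".
#' @param seed integer seed for any stochastic consumer.
#' @param allow_any_window override the window range check.
#' @export
runtime_config <- function(buffer_ms = 100,
                           sync_policy = c("every_buffer", "at_marked_atomics"),
                           seed = 1L, allow_any_window = FALSE) {
  sync_policy <- match.arg(sync_policy)
  if (!allow_any_window && (buffer_ms < 30 || buffer_ms > 300))
    stop("buffer window must lie within 30-300 ms (set allow_any_window to override)",
         call. = FALSE)
  structure(list(buffer_ms = buffer_ms, sync_policy = sync_policy,
                 seed = as.integer(seed)),
            class = "runtime_config")
}

#' Feedback parameter state
#'
#' Holds the parameters a sequence exposes for real-time update, each with
#' a pending value, a version, and the last applied version. Updates are
#' acknowledged immediately but only take effect atomically at the next
#' sync point; between sync points the last writer wins. A log records
#' every set, apply, and rejection.
#'
#' @param exposed named list mapping exposed parameter names to the graph
#'   node ids they drive (e.g. `list(slice_offset_mm =
#'   "protocol.slice_offset_mm")`).
#' @return an object of class `"feedback_state"`.
#' @export
feedback_state <- function(exposed = list()) {
  e <- new.env(parent = emptyenv())
  e$params <- new.env(parent = emptyenv())
  for (nm in names(exposed)) {
    p <- new.env(parent = emptyenv())
    p$node <- exposed[[nm]]
    p$pending <- NULL
    p$applied <- NULL
    p$version <- 0L
    p$applied_version <- 0L
    assign(nm, p, envir = e$params)
  }
  e$queue <- list()    # scheduled (time_ns, name, value) arrivals
  e$log <- list()
  structure(list(env = e), class = "feedback_state")
}

fb_param <- function(state, name) get0(name, envir = state$env$params, inherits = FALSE)

#' @rdname feedback_state
#' @param state a `feedback_state`.
#' @export
fb_list <- function(state) ls(state$env$params, sorted = TRUE)

#' @rdname feedback_state
#' @param name exposed parameter name.
#' @param value new value (pending until the next sync point).
#' @param time_ns arrival time, ns of sequence time (for the log).
#' @return `fb_set` returns TRUE if accepted, FALSE (with a log entry) for
#'   an unknown name.
#' @export
fb_set <- function(state, name, value, time_ns = NA_real_) {
  p <- fb_param(state, name)
  if (is.null(p)) {
    fb_log(state, time_ns, name, value, "rejected: unknown parameter")
    return(invisible(FALSE))
  }
  p$pending <- value
  p$version <- p$version + 1L
  fb_log(state, time_ns, name, value, "set")
  invisible(TRUE)
}

#' @rdname feedback_state
#' @export
fb_get <- function(state, name) {
  p <- fb_param(state, name)
  if (is.null(p)) stop("unknown feedback parameter '", name, "'", call. = FALSE)
  list(applied = p$applied, pending = if (p$version > p$applied_version) p$pending,
       version = p$version, applied_version = p$applied_version)
}

#' @rdname feedback_state
#' @description `fb_schedule` queues an update to arrive at a given
#'   sequence time; it becomes pending once the stream reaches that time
#'   (models an external device sending during the scan).
#' @export
fb_schedule <- function(state, time_ns, name, value) {
  state$env$queue[[length(state$env$queue) + 1L]] <-
    list(time_ns = time_ns, name = name, value = value)
  invisible(TRUE)
}

fb_deliver_due <- function(state, now_ns) {
  q <- state$env$queue
  if (!length(q)) return(invisible())
  due <- vapply(q, function(x) x$time_ns <= now_ns, logical(1))
  for (x in q[due]) fb_set(state, x$name, x$value, time_ns = x$time_ns)
  state$env$queue <- q[!due]
  invisible()
}

fb_log <- function(state, time_ns, name, value, what) {
  state$env$log[[length(state$env$log) + 1L]] <-
    list(time_ns = time_ns, name = name, value = value, event = what)
  invisible()
}

#' @rdname feedback_state
#' @export
fb_log_df <- function(state) {
  l <- state$env$log
  data.frame(time_ns = vapply(l, function(x) as.numeric(x$time_ns[1]), numeric(1)),
             name = vapply(l, function(x) as.character(x$name[1]), character(1)),
             event = vapply(l, function(x) x$event, character(1)))
}

#' Apply pending feedback updates to the parameter graph
#'
#' Invoked at sync points. Every exposed parameter whose version is ahead
#' of its applied version is written into the graph via [pg_update()],
#' invalidating exactly its dependents; blocks generated afterwards reflect
#' the new values, blocks already delivered are never touched. With no
#' pending updates nothing is invalidated and the stream is unchanged.
#'
#' @param state a [feedback_state()].
#' @param graph the sequence's `param_graph`.
#' @param time_ns sync-point time for the log.
#' @return character vector of applied parameter names.
#' @export
apply_feedback <- function(state, graph, time_ns = NA_real_) {
  applied <- character()
  for (nm in fb_list(state)) {
    p <- fb_param(state, nm)
    if (p$version > p$applied_version) {
      pg_update(graph, p$node, p$pending)
      p$applied <- p$pending
      p$applied_version <- p$version
      applied <- c(applied, nm)
      fb_log(state, time_ns, nm, p$pending, "applied")
    }
  }
  applied
}

#' Stream a sequence in bounded time buffers
#'
#' Pulls blocks from [block_iterator()] in strict chronological order and
#' groups them into buffers of `config$buffer_ms` of sequence time. At each
#' buffer boundary (a sync point) scheduled feedback arrivals up to that
#' time are delivered and pending updates applied, so all later blocks
#' reflect them. A block longer than the window is delivered whole in one
#' buffer (logged, not an error). With silent feedback the concatenated
#' buffers equal the eager traversal bit-exactly, and at most one buffer
#' plus the single look-ahead block is materialized at any instant.
#'
#' @param seq an `mr_sequence`.
#' @param config a [runtime_config()].
#' @param feedback optional [feedback_state()].
#' @param on_buffer optional callback `function(blocks, index, t_end_ns)`.
#' @param collect keep and return all blocks (set FALSE for long sequences
#'   when only the callback matters).
#' @return list: `buffers` (list of block lists), `blocks` (their
#'   concatenation, when collected), `sync_times_ns`, `long_blocks` (log),
#'   `peak_materialized` (instrumented bound).
#' @export
stream_blocks <- function(seq, config = runtime_config(), feedback = NULL,
                          on_buffer = NULL, collect = TRUE) {
  window_ns <- ms_to_ns(config$buffer_ms)
  pre_atomic <- NULL
  if (!is.null(feedback) && config$sync_policy == "at_marked_atomics") {
    pre_atomic <- function(el, t_ns) {
      fb_deliver_due(feedback, t_ns)
      sync_times <<- c(sync_times, t_ns)
      apply_feedback(feedback, seq$graph, time_ns = t_ns)
    }
  }
  it <- block_iterator(seq, pre_atomic = pre_atomic)
  buffers <- list(); all_blocks <- list()
  cur <- list(); cur_idx <- 0L
  sync_times <- numeric(); long_blocks <- list()
  peak <- 0L
  flush <- function(t_end_ns) {
    if (!is.null(on_buffer) && length(cur)) on_buffer(cur, cur_idx, t_end_ns)
    if (collect && length(cur)) {
      buffers[[length(buffers) + 1L]] <<- cur
      all_blocks <<- c(all_blocks, cur)
    }
    cur <<- list()
    if (!is.null(feedback)) {
      fb_deliver_due(feedback, t_end_ns)
      sync_times <<- c(sync_times, t_end_ns)
      apply_feedback(feedback, seq$graph, time_ns = t_end_ns)
    }
  }
  t_next <- 0  # blocks are contiguous: the next block starts where the last ended
  repeat {
    # apply sync points for every boundary before the next block is built,
    # so feedback takes effect on all blocks after the sync time
    while (t_next >= (cur_idx + 1L) * window_ns) {
      flush((cur_idx + 1L) * window_ns)
      cur_idx <- cur_idx + 1L
    }
    b <- it()
    if (is.null(b)) break
    if (b$duration_ns > window_ns)
      long_blocks[[length(long_blocks) + 1L]] <-
        list(start_ns = b$start_ns, duration_ns = b$duration_ns)
    cur[[length(cur) + 1L]] <- b
    peak <- max(peak, length(cur) + 1L)
    t_next <- b$start_ns + b$duration_ns
  }
  flush((cur_idx + 1L) * window_ns)
  list(buffers = buffers, blocks = all_blocks, sync_times_ns = sync_times,
       long_blocks = long_blocks, peak_materialized = peak)
}

#' In-process feedback service endpoint
#'
#' The message-level contract of the synchronization server: JSON messages
#' `{"op": "set"|"get"|"list", "name": ..., "value": ..., "timestamp": ...}`
#' handled against a [feedback_state()]. `set` is acknowledged immediately
#' and applied at the next sync point; `get` returns last applied and
#' pending values; `list` returns the predeclared exposed names. Malformed
#' messages get an error reply and change no state.
#'
#' @param state a [feedback_state()].
#' @return object of class `"feedback_service"` with a `handle` function
#'   (JSON string in, JSON string out).
#' @export
feedback_service <- function(state) {
  handle <- function(msg_json) {
    msg <- tryCatch(jsonlite::fromJSON(msg_json), error = function(e) NULL)
    if (is.null(msg) || is.null(msg$op))
      return(jsonlite::toJSON(list(error = "malformed message"), auto_unbox = TRUE))
    if (msg$op == "list")
      return(jsonlite::toJSON(list(names = fb_list(state))))
    if (is.null(msg$name))
      return(jsonlite::toJSON(list(error = "missing name"), auto_unbox = TRUE))
    if (msg$op == "get") {
      p <- fb_param(state, msg$name)
      if (is.null(p))
        return(jsonlite::toJSON(list(error = "unknown parameter"), auto_unbox = TRUE))
      g <- fb_get(state, msg$name)
      return(jsonlite::toJSON(list(name = msg$name, applied = g$applied,
                                   pending = g$pending,
                                   version = g$version,
                                   applied_version = g$applied_version),
                              auto_unbox = TRUE, null = "null"))
    }
    if (msg$op == "set") {
      if (is.null(msg$value))
        return(jsonlite::toJSON(list(error = "missing value"), auto_unbox = TRUE))
      ok <- fb_set(state, msg$name, msg$value,
                   time_ns = if (!is.null(msg$timestamp)) msg$timestamp else NA_real_)
      return(jsonlite::toJSON(list(ok = ok, name = msg$name), auto_unbox = TRUE))
    }
    jsonlite::toJSON(list(error = paste0("unknown op '", msg$op, "'")),
                     auto_unbox = TRUE)
  }
  structure(list(handle = handle, state = state), class = "feedback_service")
}
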