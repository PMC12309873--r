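#' Blueprints: declarative sequence building blocks
#'
#' A blueprint names a reusable sequence module. It carries parameter
#' rules (pure functions over other parameters and protocol values, with
#' declared dependency names), an ordered list of child blueprint
#' references, and flags: a *loop* repeats its children while a named
#' counter ascends, and an *atomic* is a flagged leaf module that compiles
#' to one hardware execution block via its `raw` rule. Rules never state
#' calculation order; the assembly derives it.
#'
#' @param name blueprint identifier.
#' @param rules named list of [rule()] objects. Atomics must define a rule
#'   named `"raw"` returning `list(duration_ns = , rf = , gradients = ,
#'   adc = , sync = )` (all but one of the fields may be absent).
#' @param children character vector of child blueprint names.
#' @param loop NULL, or `list(counter = <name>, count = <number or
#'   dependency name>)`.
#' @param atomic logical; atomics must be leaves.
#' @param sync_marked logical; marks an atomic as a point of interest for
#'   feedback sync (e.g. slice excitation).
#' @return an object of class `"blueprint"`.
#' @export
blueprint <- function(name, rules = list(), children = character(),
                      loop = NULL, atomic = FALSE, sync_marked = FALSE) {
  stopifnot(is.character(name), length(name) == 1)
  if (atomic && length(children))
    stop("atomic blueprint '", name, "' must be a leaf", call. = FALSE)
  if (atomic && !"raw" %in% names(rules))
    stop("atomic blueprint '", name, "' needs a 'raw' rule", call. = FALSE)
  if (!is.null(loop))
    stopifnot(is.list(loop), !is.null(loop$counter), !is.null(loop$count))
  structure(list(name = name, rules = rules, children = children,
                 loop = loop, atomic = atomic, sync_marked = sync_marked),
            class = "blueprint")
}

#' @rdname blueprint
#' @param deps character vector of parameter names the rule reads. Each is
#'   resolved at assembly: `protocol.*` names hit the protocol element;
#'   bare names resolve to rules of the same element, then to ancestor
#'   rules and enclosing loop counters (nearest first).
#' @param fn pure function, called with one positional argument per dep.
#' @export
rule <- function(deps, fn) {
  stopifnot(is.character(deps) || length(deps) == 0, is.function(fn))
  list(deps = as.character(deps), fn = fn)
}

#' @rdname blueprint
#' @export
bp_registry <- function() {
  structure(list(env = new.env(parent = emptyenv())), class = "bp_registry")
}

#' @rdname blueprint
#' @param registry a `bp_registry`.
#' @param bp a `blueprint` to register.
#' @export
bp_register <- function(registry, bp) {
  stopifnot(inherits(bp, "blueprint"))
  assign(bp$name, bp, envir = registry$env)
  invisible(bp$name)
}

bp_get <- function(registry, name) {
  bp <- get0(name, envir = registry$env, inherits = FALSE)
  if (is.null(bp)) stop("unknown blueprint reference '", name, "'", call. = FALSE)
  bp
}

HEADER_COUNTERS <- c("line", "partition", "slice", "average", "set",
                     "repetition", "contrast", "segment")

#' Assemble a blueprint hierarchy into a sequence
#'
#' Instantiates the element tree (modules, loops, atomics) rooted at
#' `root`, registers every rule as a node of a fresh parameter graph with
#' its dependencies resolved, adds protocol values and loop counters as
#' source nodes, and proves the graph acyclic. No hardware events are
#' evaluated; the first evaluation happens when a block is requested.
#'
#' @param registry a [bp_registry()] holding all referenced blueprints.
#' @param root name of the root blueprint.
#' @param protocol an [mr_protocol()].
#' @param limits a [hardware_limits()].
#' @param meta free-form metadata list (sequence families store derived
#'   node ids such as the minimum-TE rule here).
#' @return an object of class `"mr_sequence"`: `tree` (element hierarchy),
#'   `graph` (parameter graph), `protocol`, `limits`, `meta`.
#' @export
assemble <- function(registry, root, protocol, limits = hardware_limits(),
                     meta = list()) {
  graph <- param_graph()
  protocol_sources(graph, protocol)
  inst <- function(name, path, scope) {
    bp <- bp_get(registry, name)
    el <- list(id = path, blueprint = name,
               kind = if (bp$atomic) "atomic" else if (!is.null(bp$loop)) "loop" else "module",
               sync_marked = isTRUE(bp$sync_marked))
    if (el$kind == "loop") {
      cid <- paste0(path, ".#", bp$loop$counter)
      pg_source(graph, cid, 0L)
      scope[[bp$loop$counter]] <- cid
      el$counter_name <- bp$loop$counter
      el$counter_node <- cid
      cnt <- bp$loop$count
      if (is.numeric(cnt)) {
        cntid <- paste0(path, ".#count")
        pg_source(graph, cntid, as.integer(cnt))
        el$count_node <- cntid
      } else {
        el$count_node <- resolve_dep(graph, cnt, character(), scope, path)
      }
    }
    # register local rules, ordered by their local dependencies
    pending <- bp$rules
    local_ids <- structure(paste0(path, ".", names(pending)), names = names(pending))
    while (length(pending)) {
      added <- FALSE
      for (rn in names(pending)) {
        r <- pending[[rn]]
        local_deps <- intersect(r$deps, names(bp$rules))
        if (!any(local_deps %in% names(pending))) {
          ids <- vapply(r$deps, function(d)
            resolve_dep(graph, d, local_ids, scope, path), character(1))
          pg_add(graph, local_ids[[rn]], r$fn, deps = unname(ids))
          pending[[rn]] <- NULL
          added <- TRUE
        }
      }
      if (!added)
        stop("cyclic parameter dependency: {",
             paste(sort(unname(local_ids[names(pending)])), collapse = ", "),
             "} in blueprint '", name, "'", call. = FALSE)
    }
    for (rn in names(bp$rules)) scope[[rn]] <- local_ids[[rn]]
    if (bp$atomic) el$raw_node <- local_ids[["raw"]]
    el$counter_scope <- scope[names(scope) %in% HEADER_COUNTERS &
                                grepl("\\.#", unlist(scope))]
    el$children <- lapply(seq_along(bp$children), function(i)
      inst(bp$children[[i]], paste0(path, "/", bp$children[[i]], i), scope))
    el
  }
  tree <- inst(root, root, list())
  pg_check_acyclic(graph)
  structure(list(tree = tree, graph = graph, protocol = protocol,
                 limits = limits, meta = meta, registry = registry,
                 root = root),
            class = "mr_sequence")
}

resolve_dep <- function(graph, d, local_ids, scope, path) {
  if (startsWith(d, "protocol.")) {
    if (!pg_exists(graph, d))
      stop("unknown protocol reference '", d, "' in element '", path, "'",
           call. = FALSE)
    return(d)
  }
  if (d %in% names(local_ids)) return(local_ids[[d]])
  if (d %in% names(scope)) return(scope[[d]])
  if (pg_exists(graph, d)) return(d)
  stop("unresolved parameter reference '", d, "' in element '", path, "'",
       call. = FALSE)
}

#' @export
print.mr_sequence <- function(x, ...) {
  census <- traversal_census(x$tree)
  cat(sprintf("<mr_sequence> %s: %d elements (%d atomics visited per pass unknown until traversal), %d graph nodes\n",
              x$tree$blueprint, census$elements, census$atomics,
              length(pg_ids(x$graph))))
  invisible(x)
}

traversal_census <- function(el) {
  n <- 1L; a <- as.integer(el$kind == "atomic")
  for (ch in el$children) {
    c2 <- traversal_census(ch)
    n <- n + c2$elements; a <- a + c2$atomics
  }
  list(elements = n, atomics = a)
}

# ---- traversal ---------------------------------------------------------

loop_count <- function(seq, el) {
  n <- pg_eval(seq$graph, el$count_node)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 ||
      abs(n - round(n)) > 1e-9)
    stop("loop count of '", el$id, "' is not a nonnegative integer: ",
         deparse(n), call. = FALSE)
  as.integer(round(n))
}

#' Compile one atomic element to an execution block
#'
#' Evaluates the atomic's `raw` rule through the parameter graph (pulling
#' exactly its dependency closure) and wraps the events into an
#' [execution_block()] at the given absolute start time. Acquisition-header
#' counters not set explicitly by the rule are filled from the enclosing
#' loop counters.
#'
#' @param seq an `mr_sequence`.
#' @param el an atomic element of `seq$tree`.
#' @param t_ns absolute block start, ns.
#' @export
build_block <- function(seq, el, t_ns = 0) {
  raw <- pg_eval(seq$graph, el$raw_node)
  if (!is.null(raw$duration_ns) && raw$duration_ns < 0)
    stop("negative duration in atomic '", el$id, "' (",
         ns_to_ms(raw$duration_ns), " ms): timing infeasible", call. = FALSE)
  adc <- raw$adc
  if (!is.null(adc) && length(el$counter_scope)) {
    set_fields <- attr(adc$header, "set_fields") %||% character()
    for (nm in names(el$counter_scope)) {
      if (!nm %in% set_fields)
        adc$header[[nm]] <- pg_eval(seq$graph, el$counter_scope[[nm]])
    }
  }
  execution_block(start_ns = t_ns, duration_ns = raw$duration_ns,
                  rf = raw$rf, gradients = raw$gradients %||% list(),
                  adc = adc,
                  sync = isTRUE(raw$sync) || el$sync_marked,
                  tags = raw$tags %||% list(),
                  block_raster_ns = seq$limits$block_raster_ns)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Lazy chronological block iterator
#'
#' Returns a function that yields the next [execution_block()] of the
#' sequence on each call (NULL when exhausted). Blocks are produced in
#' strict chronological order; loop counters are written into the
#' parameter graph as iteration proceeds, so cached parameters are
#' invalidated exactly when their inputs change.
#'
#' @param seq an `mr_sequence`.
#' @param pre_atomic optional hook `function(el, t_ns)` invoked before a
#'   sync-marked atomic's raw representation is evaluated (the runtime uses
#'   it to apply feedback right before slice excitation).
#' @return a generator function.
#' @export
block_iterator <- function(seq, pre_atomic = NULL) {
  new_frame <- function(el) {
    f <- new.env(parent = emptyenv())
    f$el <- el; f$ci <- 1L; f$li <- -1L
    f
  }
  stack <- list(new_frame(seq$tree))
  t_ns <- 0
  function() {
    while (length(stack)) {
      f <- stack[[length(stack)]]
      el <- f$el
      if (el$kind == "atomic") {
        if (!is.null(pre_atomic) && el$sync_marked) pre_atomic(el, t_ns)
        blk <- build_block(seq, el, t_ns)
        t_ns <<- t_ns + blk$duration_ns
        stack[[length(stack)]] <<- NULL
        return(blk)
      }
      if (el$kind == "loop" && f$li < 0L) {
        f$n <- loop_count(seq, el)
        f$li <- 0L
        if (f$n > 0L) pg_update(seq$graph, el$counter_node, 0L)
      }
      if (el$kind == "loop" && f$li >= f$n) {
        stack[[length(stack)]] <<- NULL
        next
      }
      if (f$ci <= length(el$children)) {
        ch <- el$children[[f$ci]]
        f$ci <- f$ci + 1L
        stack[[length(stack) + 1L]] <<- new_frame(ch)
        next
      }
      # children exhausted
      if (el$kind == "loop") {
        f$li <- f$li + 1L
        if (f$li < f$n) {
          pg_update(seq$graph, el$counter_node, f$li)
          f$ci <- 1L
          next
        }
      }
      stack[[length(stack)]] <<- NULL
    }
    NULL
  }
}

#' Eagerly traverse a sequence
#'
#' Drains [block_iterator()] into a list — the reference against which
#' buffered streaming is compared bit-exactly.
#'
#' @param seq an `mr_sequence`.
#' @param max_blocks stop after this many blocks.
#' @export
stream_collect <- function(seq, max_blocks = Inf) {
  it <- block_iterator(seq)
  out <- list()
  repeat {
    b <- it()
    if (is.null(b) || length(out) >= max_blocks) break
    out[[length(out) + 1L]] <- b
  }
  out
}

#' Total scan duration
#'
#' Sum of all block durations (equal to the last block's end since blocks
#' are contiguous), in seconds.
#'
#' @param seq an `mr_sequence`.
#' @export
scan_duration <- function(seq) {
  it <- block_iterator(seq)
  end <- 0
  repeat {
    b <- it()
    if (is.null(b)) break
    end <- b$start_ns + b$duration_ns
  }
  ns_to_s(end)
}

#' Check protocol validity
#'
#' Reports (never raises) protocol violations: echo/repetition times below
#' the sequence's feasible minimum, hardware-limit violations of any
#' generated block, and traversal failures. An empty report means the
#' sequence is streamable as configured.
#'
#' @param seq an `mr_sequence`.
#' @param limits a [hardware_limits()]; defaults to the assembly limits.
#' @param max_blocks cap on the number of blocks examined.
#' @return data.frame with columns `kind` and `message` (zero rows when
#'   valid).
#' @export
check_protocol <- function(seq, limits = seq$limits, max_blocks = Inf) {
  rep <- list()
  add <- function(kind, msg) rep[[length(rep) + 1L]] <<- data.frame(kind = kind, message = msg)
  if (!is.null(seq$meta$min_te_node)) {
    min_te <- try(pg_eval(seq$graph, seq$meta$min_te_node), silent = TRUE)
    if (!inherits(min_te, "try-error") && seq$protocol$TE_ms < min_te - 1e-9)
      add("TE", sprintf("TE below minimum (requested %.3f ms, minimum %.3f ms)",
                        seq$protocol$TE_ms, min_te))
  }
  if (!is.null(seq$meta$min_tr_node)) {
    min_tr <- try(pg_eval(seq$graph, seq$meta$min_tr_node), silent = TRUE)
    if (!inherits(min_tr, "try-error") && seq$protocol$TR_ms < min_tr - 1e-9)
      add("TR", sprintf("TR below minimum (requested %.3f ms, minimum %.3f ms)",
                        seq$protocol$TR_ms, min_tr))
  }
  n <- 0
  res <- tryCatch({
    it <- block_iterator(seq)
    repeat {
      b <- it()
      if (is.null(b) || n >= max_blocks) break
      n <- n + 1
      for (v in validate_block(b, limits))
        add("hardware", sprintf("block %d (t = %.3f ms): %s", n, ns_to_ms(b$start_ns), v))
    }
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(res)) add("error", res)
  if (length(rep)) do.call(rbind, rep) else data.frame(kind = character(),
                                                       message = character())
}
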