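#' Parameter dependency graphs
#'
#' A `param_graph` is a directed acyclic graph of named parameters. Each
#' node is either a *source* (a protocol value or a loop counter, set
#' directly) or a *rule* (a pure function of other parameters). Values are
#' evaluated lazily and cached; a cached value is reused until one of its
#' transitive dependencies changes. This is the compilation target of
#' blueprint rules: requesting an atomic's raw representation pulls exactly
#' the dependency closure it needs, so only essential calculations are
#' performed.
#'
#' @return `param_graph()` returns an empty graph of class `"param_graph"`.
#' @examples
#' g <- param_graph()
#' pg_source(g, "protocol.TE", 5)
#' pg_add(g, "fill", function(te) te - 2.88, deps = "protocol.TE")
#' pg_eval(g, "fill")
#' pg_update(g, "protocol.TE", 6)  # invalidates "fill"
#' pg_eval(g, "fill")
#' @export
param_graph <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- new.env(parent = emptyenv())
  e$n_eval <- 0
  structure(list(env = e), class = "param_graph")
}

node_of <- function(graph, id) {
  n <- get0(id, envir = graph$env$nodes, inherits = FALSE)
  if (is.null(n)) stop("unknown parameter '", id, "'", call. = FALSE)
  n
}

#' @rdname param_graph
#' @param graph a `param_graph`.
#' @param id parameter identifier (character scalar).
#' @param rule pure function; called with one positional argument per
#'   entry of `deps`, in order.
#' @param deps character vector of parameter ids this rule reads.
#' @export
pg_add <- function(graph, id, rule, deps = character()) {
  stopifnot(is.function(rule), is.character(deps))
  if (pg_exists(graph, id)) stop("parameter '", id, "' already defined", call. = FALSE)
  n <- new.env(parent = emptyenv())
  n$rule <- rule
  n$deps <- deps
  n$dependents <- character()
  n$value <- NULL
  n$dirty <- TRUE
  n$source <- FALSE
  assign(id, n, envir = graph$env$nodes)
  for (d in deps) {
    if (!pg_exists(graph, d))
      stop("parameter '", id, "' depends on unknown parameter '", d, "'", call. = FALSE)
    dn <- node_of(graph, d)
    dn$dependents <- union(dn$dependents, id)
  }
  invisible(id)
}

#' @rdname param_graph
#' @param value value to store at a source node.
#' @export
pg_source <- function(graph, id, value) {
  if (pg_exists(graph, id)) stop("parameter '", id, "' already defined", call. = FALSE)
  n <- new.env(parent = emptyenv())
  n$rule <- NULL
  n$deps <- character()
  n$dependents <- character()
  n$value <- value
  n$dirty <- FALSE
  n$source <- TRUE
  assign(id, n, envir = graph$env$nodes)
  invisible(id)
}

#' @rdname param_graph
#' @export
pg_exists <- function(graph, id) {
  !is.null(get0(id, envir = graph$env$nodes, inherits = FALSE))
}

#' @rdname param_graph
#' @export
pg_ids <- function(graph) ls(graph$env$nodes, sorted = TRUE)

#' Evaluate a parameter lazily
#'
#' Returns the node's value, computing (and caching) it and any dirty
#' dependencies first. Nodes outside the dependency closure are never
#' touched; [pg_eval_count()] exposes the number of rule executions for
#' instrumentation.
#'
#' @inheritParams pg_add
#' @export
pg_eval <- function(graph, id) {
  pg_eval_path(graph, id, character())
}

pg_eval_path <- function(graph, id, path) {
  n <- node_of(graph, id)
  if (!n$dirty) return(n$value)
  if (n$source) stop("source parameter '", id, "' has no value", call. = FALSE)
  vals <- lapply(n$deps, function(d) pg_eval_path(graph, d, c(path, id)))
  n$value <- tryCatch(
    do.call(n$rule, vals),
    error = function(e) {
      stop("evaluation of parameter '", id, "' failed (path: ",
           paste(c(path, id), collapse = " -> "), "): ",
           conditionMessage(e), call. = FALSE)
    }
  )
  n$dirty <- FALSE
  graph$env$n_eval <- graph$env$n_eval + 1
  n$value
}

#' @rdname pg_eval
#' @export
pg_eval_count <- function(graph) graph$env$n_eval

#' @rdname pg_eval
#' @export
pg_reset_evals <- function(graph) {
  graph$env$n_eval <- 0
  invisible(graph)
}

#' Update a source parameter and invalidate its dependents
#'
#' Writes a new value into a source node (protocol parameter or loop
#' counter) and marks exactly the transitive dependents dirty, so that the
#' next [pg_eval()] recomputes them. Updating with an identical value is a
#' no-op.
#'
#' @inheritParams pg_add
#' @param value the new value.
#' @return character vector of invalidated node ids (including `id`),
#'   invisibly empty when the value is unchanged.
#' @export
pg_update <- function(graph, id, value) {
  n <- node_of(graph, id)
  if (!n$source) stop("parameter '", id, "' is rule-defined and cannot be set", call. = FALSE)
  if (identical(n$value, value)) return(invisible(character()))
  n$value <- value
  invalidated <- id
  stack <- n$dependents
  while (length(stack)) {
    cur <- stack[[1L]]; stack <- stack[-1L]
    cn <- node_of(graph, cur)
    if (cn$dirty) next  # already invalid: its dependents were handled when it went dirty
    cn$dirty <- TRUE
    invalidated <- c(invalidated, cur)
    stack <- c(stack, cn$dependents)
  }
  invalidated
}

#' Dependency closure in evaluation order
#'
#' The calculation strategy for a node: the topological order of its
#' dependency closure (dependencies first). Also used at assembly to prove
#' acyclicity.
#'
#' @inheritParams pg_add
#' @export
pg_strategy <- function(graph, id) {
  order <- character()
  mark <- new.env(parent = emptyenv())  # 1 = visiting, 2 = done
  visit <- function(v, path) {
    m <- get0(v, envir = mark, inherits = FALSE)
    if (identical(m, 2L)) return()
    if (identical(m, 1L)) {
      cyc <- path[seq(match(v, path), length(path))]
      stop("cyclic parameter dependency: {", paste(sort(cyc), collapse = ", "), "}",
           call. = FALSE)
    }
    assign(v, 1L, envir = mark)
    for (d in node_of(graph, v)$deps) visit(d, c(path, d))
    assign(v, 2L, envir = mark)
    order <<- c(order, v)
  }
  visit(id, id)
  order
}

#' Check the whole graph is acyclic
#'
#' Called once per assembly; raises an error naming the cycle members if a
#' cycle exists.
#'
#' @inheritParams pg_add
#' @export
pg_check_acyclic <- function(graph) {
  mark <- new.env(parent = emptyenv())
  for (id in pg_ids(graph)) {
    if (identical(get0(id, envir = mark, inherits = FALSE), 2L)) next
    visit <- function(v, path) {
      m <- get0(v, envir = mark, inherits = FALSE)
      if (identical(m, 2L)) return()
      if (identical(m, 1L)) {
        cyc <- path[seq(match(v, path), length(path))]
        stop("cyclic parameter dependency: {", paste(sort(cyc), collapse = ", "), "}",
             call. = FALSE)
      }
      assign(v, 1L, envir = mark)
      for (d in node_of(graph, v)$deps) visit(d, c(path, d))
      assign(v, 2L, envir = mark)
    }
    visit(id, id)
  }
  invisible(TRUE)
}

#' @export
print.param_graph <- function(x, ...) {
  ids <- pg_ids(x)
  n_src <- sum(vapply(ids, function(i) node_of(x, i)$source, logical(1)))
  cat("<param_graph> ", length(ids), " nodes (", n_src, " sources, ",
      length(ids) - n_src, " rules), ", pg_eval_count(x),
      " rule evaluations so far\n", sep = "")
  invisible(x)
}
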