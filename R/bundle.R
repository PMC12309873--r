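#' Sequence bundle serialization
#'
#' A sequence bundle is a JSON document with sections `blueprints`
#' (structure, loop/atomic flags and parameter rules, including the data
#' each rule closes over), `hierarchy` (root reference), `parameter_rules`
#' (an index of rule names per blueprint), and `protocol`. It captures the
#' *definition* of a sequence — not a static event dump — so reading it
#' back re-assembles an equivalent element hierarchy and parameter graph
#' whose streamed blocks are bit-identical to the original's.
#'
#' Rule functions are stored as source plus the values they reference from
#' their enclosing environments (resolved with `codetools`); package
#' functions resolve against the package namespace at load. Objects that
#' cannot be represented (connections, environments) raise an error naming
#' the offending rule.
#'
#' @param seq an `mr_sequence` (from [assemble()] or [build_sequence()]).
#' @param file optional path for the JSON text.
#' @return `seq_bundle_write` returns the JSON string (invisibly when
#'   written to a file); `seq_bundle_read` returns a re-assembled
#'   `mr_sequence`.
#' @export
seq_bundle_write <- function(seq, file = NULL) {
  reg <- seq$registry
  bps <- lapply(sort(ls(reg$env)), function(nm) {
    bp <- bp_get(reg, nm)
    list(name = bp$name,
         children = as.list(bp$children),
         loop = if (!is.null(bp$loop))
           list(counter = bp$loop$counter, count = enc_robj(bp$loop$count)),
         atomic = bp$atomic, sync_marked = bp$sync_marked,
         rules = lapply(bp$rules, function(r)
           list(deps = as.list(r$deps), fn = enc_fun(r$fn))))
  })
  names(bps) <- sort(ls(reg$env))
  doc <- list(
    format = "mr-sequence-bundle-1",
    blueprints = bps,
    hierarchy = list(root = seq$root),
    parameter_rules = lapply(bps, function(b) names(b$rules)),
    protocol = enc_robj(seq$protocol),
    limits = enc_robj(seq$limits))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' @rdname seq_bundle_write
#' @param x JSON text, a file path, or a parsed bundle list.
#' @export
seq_bundle_read <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x))
    x <- paste(readLines(x), collapse = "\n")
  doc <- if (is.list(x)) x else
    jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (!identical(doc$format, "mr-sequence-bundle-1"))
    stop("not a sequence bundle document", call. = FALSE)
  reg <- bp_registry()
  for (b in doc$blueprints) {
    rules <- lapply(b$rules, function(r)
      rule(unlist(r$deps) %||% character(), dec_fun(r$fn)))
    bp_register(reg, blueprint(
      b$name, rules = rules,
      children = as.character(unlist(b$children)),
      loop = if (!is.null(b$loop))
        list(counter = b$loop$counter, count = dec_robj(b$loop$count)),
      atomic = isTRUE(b$atomic), sync_marked = isTRUE(b$sync_marked)))
  }
  assemble(reg, doc$hierarchy$root, dec_robj(doc$protocol),
           limits = dec_robj(doc$limits))
}

# ---- R-object <-> JSON-able codec --------------------------------------

enc_robj <- function(x) {
  if (is.null(x)) return(list(t = "null"))
  if (is.function(x)) return(enc_fun(x))
  at <- attributes(x)
  if (is.data.frame(x)) {
    at$row.names <- NULL; at$names <- NULL; at$class <- NULL
    return(list(t = "df", cols = lapply(as.list(x), enc_robj),
                attr = enc_attrs(at)))
  }
  if (is.list(x)) {
    at$names <- NULL
    return(list(t = "list", names = as.list(names(x) %||% character()),
                items = lapply(unname(x), enc_robj), attr = enc_attrs(at)))
  }
  if (is.environment(x)) stop("environment is not bundle-serializable",
                              call. = FALSE)
  if (!is.atomic(x)) stop("cannot serialize object of type ", typeof(x),
                          call. = FALSE)
  at$names <- NULL
  # doubles as %.17g strings: bit-exact round-trip; I() keeps length-1
  # vectors as JSON arrays
  dbl_str <- function(v) I(ifelse(is.na(v) & !is.nan(v), "NA",
                                  sprintf("%.17g", v)))
  flat <- x
  attributes(flat) <- NULL   # plain column-major vector (dim kept in attrs)
  data <- if (is.complex(x)) list(re = dbl_str(Re(flat)), im = dbl_str(Im(flat)))
  else if (is.double(x)) dbl_str(flat)
  else I(flat)
  list(t = typeof(x), data = data, names = as.list(names(x) %||% character()),
       attr = enc_attrs(at))
}

enc_attrs <- function(at) {
  at <- at[!vapply(at, is.null, logical(1))]
  if (!length(at)) return(NULL)
  lapply(at, enc_robj)
}

dec_robj <- function(e) {
  if (is.null(e)) return(NULL)
  t <- e$t
  if (identical(t, "null")) return(NULL)
  if (identical(t, "fn")) return(dec_fun(e))
  out <- if (identical(t, "df")) {
    df <- as.data.frame(lapply(e$cols, dec_robj), stringsAsFactors = FALSE)
    names(df) <- names(e$cols)
    df
  } else if (identical(t, "list")) {
    l <- lapply(e$items, dec_robj)
    if (length(e$names)) names(l) <- as.character(unlist(e$names))
    l
  } else if (identical(t, "complex")) {
    num_of <- function(l) {
      v <- unlist(lapply(l, function(x) if (is.null(x) || identical(x, "NA")) NA else x))
      as.numeric(v)
    }
    complex(real = num_of(e$data$re), imaginary = num_of(e$data$im))
  } else {
    items <- e$data
    # jsonlite writes NA/NaN/Inf of numeric vectors as strings; nulls mark
    # NA of other types -- map both back, keeping positions aligned
    numeric_t <- t %in% c("double", "integer")
    special <- function(x) {
      if (is.null(x)) return(NA)
      if (numeric_t) {
        if (identical(x, "NA")) return(NA)
        if (identical(x, "NaN")) return(NaN)
        if (identical(x, "Inf")) return(Inf)
        if (identical(x, "-Inf")) return(-Inf)
      }
      x
    }
    v <- if (is.list(items)) unlist(lapply(items, special)) else items
    if (is.null(v)) v <- vector(t, 0)
    v <- switch(t, integer = as.integer(v), double = as.numeric(v),
                logical = as.logical(v), character = as.character(v), v)
    v
  }
  if (length(e$names) && !is.data.frame(out))
    names(out) <- as.character(unlist(e$names))
  for (an in names(e$attr %||% list()))
    attr(out, an) <- dec_robj(e$attr[[an]])
  out
}

enc_fun <- function(fn) {
  src <- deparse(fn, control = c("keepInteger", "keepNA"))
  fg <- codetools::findGlobals(fn, merge = FALSE)
  globs <- unique(c(fg$variables, fg$functions))
  env <- environment(fn)
  captured <- list()
  ns <- asNamespace("mrforge")
  for (g in globs) {
    e <- env
    while (!identical(e, emptyenv())) {
      if (identical(e, ns) || identical(e, globalenv()) ||
          identical(e, baseenv())) break
      if (exists(g, envir = e, inherits = FALSE)) {
        captured[[g]] <- enc_robj(get(g, envir = e))
        break
      }
      e <- parent.env(e)
    }
  }
  list(t = "fn", src = paste(src, collapse = "\n"), env = captured)
}

dec_fun <- function(e) {
  env <- new.env(parent = asNamespace("mrforge"))
  for (nm in names(e$env %||% list())) assign(nm, dec_robj(e$env[[nm]]), envir = env)
  fn <- eval(parse(text = e$src)[[1]], envir = env)
  environment(fn) <- env
  fn
}
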