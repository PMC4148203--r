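#' Create a gating set
#'
#' A `GatingSet` ties a disk-backed [create_store()] sample store to a single
#' population tree shared across samples. Each non-root population carries a
#' gate (one shared gate, or one gate per sample when gates are data-driven);
#' event-membership index vectors are computed lazily per (sample, population)
#' and cached, so repeated population statistics and Boolean combination
#' queries do not re-read or re-gate the data.
#'
#' @param store a `SampleStore`.
#' @return A `GatingSet` (reference semantics: populations are added in place).
#' @export
gating_set <- function(store) {
  stopifnot(inherits(store, "SampleStore"))
  gs <- new.env(parent = emptyenv())
  gs$store <- store
  gs$nodes <- list("/" = list(name = "root", path = "/", parent = NA_character_,
                              gate = NULL, children = character(0)))
  gs$cache <- new.env(parent = emptyenv())      # (sample, path) -> logical
  gs$missing <- new.env(parent = emptyenv())    # (sample, path) -> TRUE
  gs$evcache <- new.env(parent = emptyenv())    # one transformed sample at a time
  class(gs) <- "GatingSet"
  gs
}

#' @export
print.GatingSet <- function(x, ...) {
  cat(sprintf("GatingSet: %d samples, %d populations\n",
              length(sample_ids(x$store)), length(x$nodes) - 1))
  for (p in gs_node_paths(x)) {
    depth <- if (p == "/") 0 else lengths(regmatches(p, gregexpr("/", p)))
    cat(strrep("  ", depth), if (p == "/") "root" else x$nodes[[p]]$name, "\n",
        sep = "")
  }
  invisible(x)
}

#' Population paths of a gating set
#' @param gs a `GatingSet`.
#' @return Character vector of paths in definition order (root first).
#' @export
gs_node_paths <- function(gs) names(gs$nodes)

join_path <- function(parent, name) {
  if (parent == "/") paste0("/", name) else paste0(parent, "/", name)
}

#' Resolve a population reference to a full path
#'
#' Accepts a full `/`-separated path, or a bare population name which must be
#' unique across the tree.
#' @param gs a `GatingSet`.
#' @param ref path or unique population name (`"root"` or `"/"` for the root).
#' @return The full path.
#' @export
resolve_path <- function(gs, ref) {
  ref <- trimws(ref)
  if (ref %in% c("/", "root", "")) return("/")
  if (startsWith(ref, "/")) {
    if (!ref %in% names(gs$nodes))
      stop(fcs_condition(paste0("unknown population path: ", ref),
                         "cytogate_lookup_error"))
    return(ref)
  }
  hits <- names(gs$nodes)[vapply(gs$nodes, function(n)
    identical(n$name, ref), logical(1))]
  if (length(hits) == 1) return(hits)
  if (length(hits) == 0)
    stop(fcs_condition(paste0("unknown population: ", ref),
                       "cytogate_lookup_error"))
  stop(fcs_condition(paste0("ambiguous population name '", ref, "': ",
                            paste(hits, collapse = ", ")),
                     "cytogate_lookup_error"))
}

#' Add a population to the tree
#'
#' @param gs a `GatingSet`.
#' @param parent parent path (or unique name; `"root"` for the root).
#' @param name population name, unique among its siblings.
#' @param gate a `Gate`, or a named list of gates keyed by sample id (a
#'   missing/`NULL` entry marks the population missing for that sample), or
#'   `NULL` to attach gates later via [set_gate()].
#' @return The gating set, invisibly (modified in place).
#' @export
add_population <- function(gs, parent, name, gate = NULL) {
  stopifnot(inherits(gs, "GatingSet"))
  parent_path <- resolve_path(gs, parent)
  if (grepl("[/&|!()]", name))
    stop("population names may not contain /,&,|,!,()", call. = FALSE)
  path <- join_path(parent_path, name)
  if (path %in% names(gs$nodes))
    stop(fcs_condition(paste0("duplicate population: ", path),
                       "cytogate_schema_error"))
  gs$nodes[[path]] <- list(name = name, path = path, parent = parent_path,
                           gate = gate, children = character(0))
  gs$nodes[[parent_path]]$children <-
    c(gs$nodes[[parent_path]]$children, path)
  invalidate_indices(gs, path)
  invisible(gs)
}

#' Set or replace a population's gate
#'
#' @param gs a `GatingSet`.
#' @param path population path.
#' @param gate a `Gate`, or named list of per-sample gates.
#' @param sample_id if given, set the gate for this sample only.
#' @return The gating set, invisibly. Cached indices for the population and
#'   its descendants are invalidated.
#' @export
set_gate <- function(gs, path, gate, sample_id = NULL) {
  path <- resolve_path(gs, path)
  if (path == "/") stop("the root has no gate", call. = FALSE)
  if (is.null(sample_id)) {
    gs$nodes[[path]]$gate <- gate
  } else {
    cur <- gs$nodes[[path]]$gate
    if (inherits(cur, "Gate") || is.null(cur)) cur <- list()
    cur[[sample_id]] <- gate
    gs$nodes[[path]]$gate <- cur
  }
  invalidate_indices(gs, path)
  invisible(gs)
}

descendant_paths <- function(gs, path) {
  out <- character(0)
  stack <- gs$nodes[[path]]$children
  while (length(stack)) {
    p <- stack[1]; stack <- stack[-1]
    out <- c(out, p)
    stack <- c(stack, gs$nodes[[p]]$children)
  }
  out
}

invalidate_indices <- function(gs, path) {
  targets <- c(path, descendant_paths(gs, path))
  for (key in ls(gs$cache)) {
    p <- sub("^[^\r]*\r", "", key)
    if (p %in% targets) rm(list = key, envir = gs$cache)
  }
  for (key in ls(gs$missing)) {
    p <- sub("^[^\r]*\r", "", key)
    if (p %in% targets) rm(list = key, envir = gs$missing)
  }
  invisible(gs)
}

cache_key <- function(sample_id, path) paste0(sample_id, "\r", path)

# events of one sample, memoised one sample at a time (memory contract)
gs_events <- function(gs, sample_id) {
  if (!identical(gs$evcache$id, sample_id)) {
    gs$evcache$id <- sample_id
    gs$evcache$ev <- get_sample(gs$store, sample_id)
  }
  gs$evcache$ev
}

sample_gate <- function(node, sample_id) {
  g <- node$gate
  if (is.null(g)) return(NULL)
  if (inherits(g, "Gate")) return(g)
  g[[sample_id]]
}

#' Compute (cached) event membership indices for a population
#'
#' `indices(child) = indices(parent) & apply_gate(child gate, events)`.
#' Results are memoised per (sample, path); repeated calls return identical
#' vectors. A population whose gate is missing for the sample yields all-FALSE
#' indices and is flagged (see [population_stats()]).
#'
#' @param gs a `GatingSet`.
#' @param sample_id sample identifier.
#' @param path population path (or unique name).
#' @return Logical vector over the sample's events.
#' @export
compute_indices <- function(gs, sample_id, path) {
  stopifnot(inherits(gs, "GatingSet"))
  check_store(gs$store, sample_id)
  path <- resolve_path(gs, path)
  key <- cache_key(sample_id, path)
  hit <- get0(key, envir = gs$cache)
  if (!is.null(hit)) return(hit)

  if (path == "/") {
    idx <- rep(TRUE, gs$store$samples[[sample_id]]$nrow)
  } else {
    node <- gs$nodes[[path]]
    parent_idx <- compute_indices(gs, sample_id, node$parent)
    g <- sample_gate(node, sample_id)
    if (is.null(g)) {
      idx <- rep(FALSE, length(parent_idx))
      assign(key, TRUE, envir = gs$missing)
    } else if (inherits(g, "gate_boolean")) {
      idx <- parent_idx &
        eval_boolean_expression(gs, sample_id, g$expression)
    } else {
      idx <- parent_idx & apply_gate(g, gs_events(gs, sample_id))
    }
  }
  assign(key, idx, envir = gs$cache)
  idx
}

# ---- boolean combination evaluation -----------------------------------------

eval_boolean_expression <- function(gs, sample_id, expression) {
  refs <- regmatches(expression,
                     gregexpr("[^&|!()[:space:]]+", expression))[[1]]
  refs <- unique(refs)
  refs <- refs[order(-nchar(refs))]  # longest first so no ref eats a substring
  if (!length(refs))
    stop(fcs_condition("boolean expression references no populations",
                       "cytogate_schema_error"))
  env <- new.env(parent = baseenv())
  expr <- expression
  for (i in seq_along(refs)) {
    var <- paste0(".pop", i)
    assign(var, compute_indices(gs, sample_id, refs[i]), envir = env)
    expr <- gsub(refs[i], var, expr, fixed = TRUE)
  }
  parsed <- tryCatch(parse(text = expr)[[1]], error = function(e)
    stop(fcs_condition(paste0("malformed boolean expression: ", expression),
                       "cytogate_schema_error")))
  out <- eval(parsed, envir = env)
  if (!is.logical(out))
    stop(fcs_condition("boolean expression did not yield a logical vector",
                       "cytogate_schema_error"))
  out
}

#' Evaluate a Boolean combination over gated populations
#'
#' Elementwise `&`, `|`, `!` over the cached index vectors of the referenced
#' populations, restricted to the declared parent's indices.
#'
#' @param gs a `GatingSet`.
#' @param sample_id sample identifier.
#' @param expression e.g. `"IFNg+ & !IL2+"`; references are paths or unique
#'   population names.
#' @param parent parent population the result is restricted to (default root).
#' @return Logical vector over the sample's events.
#' @export
boolean_gate_eval <- function(gs, sample_id, expression, parent = "/") {
  parent_idx <- compute_indices(gs, sample_id, parent)
  parent_idx & eval_boolean_expression(gs, sample_id, expression)
}

# ---- statistics --------------------------------------------------------------

#' Per-population counts and proportions
#'
#' One row per (sample, population). `proportion_of_parent` is
#' `count / parent_count`, defined as 0 (and flagged) when the parent is
#' empty; `proportion_of_root` is relative to all events in the sample.
#'
#' @param gs a `GatingSet`.
#' @param samples sample ids (default: all).
#' @return A data.frame with columns `sample_id`, `path`, `count`,
#'   `proportion_of_parent`, `proportion_of_root`, `flag`.
#' @export
population_stats <- function(gs, samples = sample_ids(gs$store)) {
  paths <- gs_node_paths(gs)
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    sid <- samples[si]
    counts <- vapply(paths, function(p)
      sum(compute_indices(gs, sid, p)), numeric(1))
    parent_counts <- vapply(paths, function(p) {
      par <- gs$nodes[[p]]$parent
      if (is.na(par)) counts[[p]] else counts[[par]]
    }, numeric(1))
    prop_par <- ifelse(parent_counts > 0, counts / parent_counts, 0)
    prop_par[paths == "/"] <- 1
    root_n <- counts[[1]]
    flags <- vapply(paths, function(p) {
      if (isTRUE(get0(cache_key(sid, p), envir = gs$missing))) "missing"
      else ""
    }, character(1))
    flags[parent_counts == 0 & paths != "/"] <-
      paste0(flags[parent_counts == 0 & paths != "/"], "|empty_parent")
    out[[si]] <- data.frame(
      sample_id = sid, path = paths, count = as.integer(counts),
      proportion_of_parent = as.numeric(prop_par),
      proportion_of_root = if (root_n > 0) counts / root_n else
        ifelse(paths == "/", 1, 0),
      flag = sub("^\\|", "", flags),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# ---- serialization -----------------------------------------------------------

gate_to_list <- function(g) {
  if (is.null(g)) return(NULL)
  if (inherits(g, "Gate")) {
    out <- unclass(g)
    if (!is.null(out$vertices)) out$vertices <- unname(as.matrix(out$vertices))
    if (!is.null(out$covariance)) out$covariance <- unname(as.matrix(out$covariance))
    c(list(variant = class(g)[1]), out)
  } else {
    list(variant = "per_sample", gates = lapply(g, gate_to_list))
  }
}

gate_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  v <- x$variant
  if (identical(v, "per_sample"))
    return(lapply(x$gates, gate_from_list))
  switch(v,
    gate_threshold = threshold_gate(x$channel, x$min, x$max),
    gate_rectangle = rectangle_gate(x$ch_x, x$ch_y, x$xmin, x$xmax,
                                    x$ymin, x$ymax),
    gate_polygon = polygon_gate(x$ch_x, x$ch_y,
                                matrix(unlist(x$vertices), ncol = 2,
                                       byrow = is.list(x$vertices))),
    gate_ellipse = ellipse_gate(x$ch_x, x$ch_y, unlist(x$center),
                                matrix(unlist(x$covariance), 2, 2), x$level),
    gate_boolean = boolean_gate(x$expression),
    stop("unknown gate variant: ", v))
}

#' Serialize a gating set to a sidecar JSON
#'
#' The event data stay in the binary store; the JSON records the tree, every
#' gate (shared or per-sample) and the currently cached population counts.
#'
#' @param gs a `GatingSet`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_gating_set <- function(gs, path) {
  stats <- population_stats(gs)
  nodes <- lapply(gs$nodes, function(n)
    list(name = n$name, path = n$path,
         parent = if (is.na(n$parent)) NULL else n$parent,
         gate = gate_to_list(n$gate)))
  obj <- list(store = basename(gs$store$path), nodes = unname(nodes),
              counts = stats[, c("sample_id", "path", "count")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Rebuild a gating set from a store and sidecar JSON
#' @param store a `SampleStore` (already opened).
#' @param path JSON produced by [save_gating_set()].
#' @return A `GatingSet` with gates attached (indices recomputed lazily).
#' @export
load_gating_set <- function(store, path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  gs <- gating_set(store)
  for (n in obj$nodes) {
    if (identical(n$path, "/")) next
    add_population(gs, n$parent, n$name, gate_from_list(n$gate))
  }
  gs
}
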