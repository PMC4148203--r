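#' @name template_engine
#' @title CSV gating templates
#'
#' @description
#' A gating template is a CSV with eight columns -- `alias`, `pop`, `parent`,
#' `dims`, `gating_method`, `gating_args`, `collapseDataForGating`, `groupBy`
#' -- one row per population (before sign expansion). Rows execute strictly in
#' file order; a parent must be defined by an earlier row (or be `root`).
#' Templates are staining-panel specific but data agnostic: marker names in
#' `dims` are resolved against each data set's marker map at application time,
#' case-insensitively and ignoring punctuation.
NULL

TEMPLATE_COLUMNS <- c("alias", "pop", "parent", "dims", "gating_method",
                      "gating_args", "collapseDataForGating", "groupBy")

norm_marker <- function(x) gsub("[^a-z0-9]", "", tolower(x))

#' Parse a `gating_args` cell
#'
#' Comma-separated `key=value` pairs with typed coercion: numbers become
#' numeric, `a:b` becomes a length-2 numeric range, TRUE/FALSE become logical,
#' everything else stays character.
#'
#' @param s the cell contents (may be empty).
#' @return Named list.
#' @export
parse_gating_args <- function(s) {
  s <- trimws(s %||% "")
  if (s == "" || is.na(s)) return(list())
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop(fcs_condition(paste0("malformed gating_args entry: '", p, "'"),
                         "cytogate_schema_error"))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    out[[key]] <- coerce_arg(val)
  }
  out
}

coerce_arg <- function(val) {
  if (grepl("^-?[0-9.eE+]+:-?[0-9.eE+]+$", val)) {
    rng <- suppressWarnings(as.numeric(strsplit(val, ":", fixed = TRUE)[[1]]))
    if (!anyNA(rng)) return(rng)
  }
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  if (toupper(val) %in% c("TRUE", "FALSE")) return(as.logical(toupper(val)))
  val
}

# parse a pop spec like "cd4+/-cd8+/-" against its dims; returns per-dim signs
parse_pop_spec <- function(pop, dims) {
  pop <- trimws(pop)
  if (pop %in% c("+", "-", "+/-"))
    return(list(markers = dims, signs = rep(pop, length(dims))))
  signs <- character(length(dims))
  rest <- pop
  for (i in seq_along(dims)) {
    nd <- norm_marker(dims[i])
    hit <- 0L
    for (l in seq_len(nchar(rest))) {
      if (norm_marker(substr(rest, 1, l)) == nd) { hit <- l; break }
    }
    if (hit == 0L)
      stop(fcs_condition(sprintf(
        "pop '%s' does not match dims '%s' (expected marker '%s')",
        pop, paste(dims, collapse = ","), dims[i]), "cytogate_schema_error"))
    rest <- substr(rest, hit + 1, nchar(rest))
    sign <- if (startsWith(rest, "+/-")) "+/-"
            else if (startsWith(rest, "+")) "+"
            else if (startsWith(rest, "-")) "-"
            else stop(fcs_condition(sprintf(
              "pop '%s': expected +, - or +/- after marker '%s'", pop, dims[i]),
              "cytogate_schema_error"))
    signs[i] <- sign
    rest <- substr(rest, nchar(sign) + 1, nchar(rest))
  }
  if (nchar(rest))
    stop(fcs_condition(sprintf("pop '%s': trailing text '%s'", pop, rest),
                       "cytogate_schema_error"))
  list(markers = dims, signs = signs)
}

#' Expand a template row into its populations
#'
#' `"A+/-"` on one dim expands to two rows (`A+`, `A-`) sharing one fitted
#' threshold; `"A+/-B+/-"` on two dims expands to the four quadrants sharing
#' two thresholds. Rows with fixed signs expand to themselves.
#'
#' @param row named list or one-row data.frame with the template columns.
#' @return List of expanded rows; each has `alias`, `signs` (named by dim) and
#'   the inherited columns. Rows from one source row share a `share_id`.
#' @export
expand_pop <- function(row) {
  row <- as.list(row)
  dims <- trimws(strsplit(row$dims, ",", fixed = TRUE)[[1]])
  if (!length(dims) %in% 1:2)
    stop(fcs_condition(paste0("dims must name 1 or 2 markers, got: ", row$dims),
                       "cytogate_schema_error"))
  spec <- parse_pop_spec(row$pop, dims)
  choice <- lapply(spec$signs, function(s)
    if (s == "+/-") c("+", "-") else s)
  grid <- expand.grid(choice, stringsAsFactors = FALSE)
  expanded <- length(choice) && any(spec$signs == "+/-")
  out <- lapply(seq_len(nrow(grid)), function(i) {
    signs <- as.character(grid[i, ])
    names(signs) <- dims
    alias <- if (!expanded && nzchar(trimws(row$alias %||% "")))
      trimws(row$alias) else paste0(dims, signs, collapse = "")
    modifyList(row, list(alias = alias, signs = list(signs), dims = list(dims)))
  })
  out
}

#' Parse and validate a CSV gating template
#'
#' @param csv_path path to the template CSV (header row with the 8 columns).
#' @return A `GatingTemplate`: the expanded rows (with resolved parent paths)
#'   plus the implied tree.
#' @export
parse_template <- function(csv_path) {
  df <- utils::read.csv(csv_path, colClasses = "character",
                        check.names = FALSE, strip.white = TRUE)
  missing_cols <- setdiff(TEMPLATE_COLUMNS, names(df))
  if (length(missing_cols))
    stop(fcs_condition(paste0("template is missing column(s): ",
                              paste(missing_cols, collapse = ", ")),
                       "cytogate_schema_error"))
  alias_path <- list(root = "/")
  entries <- list()
  share <- 0L
  for (r in seq_len(nrow(df))) {
    row <- as.list(df[r, TEMPLATE_COLUMNS])
    fail <- function(msg) stop(fcs_condition(
      sprintf("template row %d (alias '%s'): %s", r, row$alias, msg),
      "cytogate_schema_error"))
    parent_ref <- trimws(row$parent)
    if (parent_ref == "") parent_ref <- "root"
    parent_path <- alias_path[[parent_ref]]
    if (is.null(parent_path))
      fail(paste0("parent '", parent_ref, "' is not defined by an earlier row"))
    if (is.na(parent_path))
      fail(paste0("parent alias '", parent_ref,
                  "' is ambiguous; use its full path"))
    method <- trimws(row$gating_method)
    fitter <- tryCatch(get_fitter(method), error = function(e) fail(conditionMessage(e)))
    args <- tryCatch(parse_gating_args(row$gating_args),
                     error = function(e) fail(conditionMessage(e)))
    collapse <- toupper(trimws(row$collapseDataForGating %||% "")) %in%
      c("TRUE", "T", "YES", "1")
    group_by <- trimws(strsplit(row$groupBy %||% "", ":", fixed = TRUE)[[1]])
    group_by <- group_by[nzchar(group_by)]
    ex <- tryCatch(expand_pop(row), error = function(e) fail(conditionMessage(e)))
    share <- share + 1L
    if (length(ex) > 1 && !fitter$threshold)
      fail(paste0("method '", method, "' does not support +/- expansion"))
    if (length(ex) == 1 && !fitter$threshold &&
        any(ex[[1]]$signs[[1]] == "-") && method != "refGate")
      fail(paste0("method '", method, "' cannot gate a negative population"))
    for (e in ex) {
      path <- join_path(parent_path, e$alias)
      if (path %in% alias_path) fail(paste0("duplicate population ", path))
      if (e$alias %in% names(alias_path)) {
        # same name elsewhere in the tree: keep it addressable by path only
        alias_path[[e$alias]] <- NA_character_
      } else {
        alias_path[[e$alias]] <- path
      }
      alias_path[[path]] <- path
      entries[[length(entries) + 1]] <- list(
        alias = e$alias, path = path, parent = parent_path,
        dims = e$dims[[1]], signs = e$signs[[1]], method = method,
        args = args, collapse = collapse, group_by = group_by,
        share_id = share, row = r)
    }
  }
  structure(list(entries = entries, source = df), class = "GatingTemplate")
}

#' @export
print.GatingTemplate <- function(x, ...) {
  cat(sprintf("GatingTemplate: %d source rows, %d populations\n",
              nrow(x$source), length(x$entries)))
  for (e in x$entries)
    cat(sprintf("  %-28s <- %s [%s]\n", e$path, e$parent, e$method))
  invisible(x)
}

#' Render a template's tree as DOT graph text
#' @param tpl a `GatingTemplate`.
#' @return Character scalar of DOT source (one node per population plus root).
#' @export
template_to_dot <- function(tpl) {
  stopifnot(inherits(tpl, "GatingTemplate"))
  lines <- c("digraph gating_template {",
             "  \"/\" [label=\"root\"];")
  for (e in tpl$entries) {
    lines <- c(lines,
               sprintf("  \"%s\" [label=\"%s\"];", e$path, e$alias),
               sprintf("  \"%s\" -> \"%s\";", e$parent, e$path))
  }
  paste(c(lines, "}"), collapse = "\n")
}

# resolve a marker name to one channel, consistently across all store samples
resolve_dim_channel <- function(store, marker) {
  nm <- norm_marker(marker)
  resolve_one <- function(rec) {
    mk <- unlist(rec$markers)
    hit <- names(mk)[norm_marker(mk) == nm]
    if (length(hit) == 1) return(hit)
    hit <- store$channels[norm_marker(store$channels) == nm]
    if (length(hit) == 1) return(hit)
    NA_character_
  }
  ch <- vapply(store$samples, resolve_one, character(1))
  if (anyNA(ch))
    stop(fcs_condition(paste0(
      "marker '", marker, "' does not resolve to a channel in sample(s): ",
      paste(names(ch)[is.na(ch)], collapse = ", ")), "cytogate_schema_error"))
  if (length(unique(ch)) > 1)
    stop(fcs_condition(paste0("marker '", marker,
                              "' resolves to different channels across samples"),
                       "cytogate_schema_error"))
  ch[[1]]
}

sample_group_keys <- function(store, samples, group_by) {
  if (!length(group_by)) return(setNames(rep("", length(samples)), samples))
  keys <- vapply(samples, function(sid) {
    md <- store$samples[[sid]]$metadata
    vals <- vapply(group_by, function(k) {
      v <- md[[k]]
      if (is.null(v))
        stop(fcs_condition(paste0("sample '", sid,
                                  "' lacks groupBy metadata key '", k, "'"),
                           "cytogate_schema_error"))
      as.character(v)
    }, character(1))
    paste(vals, collapse = "\r")
  }, character(1))
  keys
}

pooled_parent_events <- function(gs, samples, parent_path) {
  mats <- lapply(samples, function(sid) {
    idx <- compute_indices(gs, sid, parent_path)
    gs_events(gs, sid)$events[idx, , drop = FALSE]
  })
  event_matrix(do.call(rbind, mats), channels = gs$store$channels,
               sample_id = "pooled")
}

threshold_gates_for_signs <- function(channels, signs, thresholds) {
  channels <- unname(channels); thresholds <- unname(thresholds)
  if (length(channels) == 1) {
    if (signs[1] == "+") threshold_gate(channels[1], thresholds[1], Inf)
    else threshold_gate(channels[1], -Inf, thresholds[1])
  } else {
    b <- lapply(seq_along(channels), function(i)
      if (signs[i] == "+") c(thresholds[i], Inf) else c(-Inf, thresholds[i]))
    rectangle_gate(channels[1], channels[2],
                   xmin = b[[1]][1], xmax = b[[1]][2],
                   ymin = b[[2]][1], ymax = b[[2]][2])
  }
}

#' Apply a gating template to a gating set
#'
#' Rows execute in file order. For each row, samples are partitioned by the
#' `groupBy` metadata keys; with `collapseDataForGating` the group members'
#' parent-population events are pooled, one gate is fitted per group, and that
#' same gate is attached to every member, guaranteeing a shared threshold for
#' samples that must be compared directly (e.g. stimulations and controls of
#' one subject-visit). Without collapsing, one gate is fitted per sample. A
#' failed fit marks the population missing for the affected sample(s) with a
#' warning; it does not abort the pipeline.
#'
#' `refGate` rows copy a gate fitted on designated source samples: gating_args
#' `ref_key`/`ref_value` select the source member(s) within each group (e.g.
#' `ref_key=STIM, ref_value=negctrl`), `method` names the fitter run on the
#' pooled source events (default `quantileGate`), and `offset` optionally
#' shifts the copied thresholds.
#'
#' @param gs a `GatingSet` over an ungated (or partially gated) store.
#' @param tpl a `GatingTemplate` from [parse_template()].
#' @param seed integer seed forwarded to every fitter.
#' @return The gating set, invisibly (populations added in place).
#' @export
apply_template <- function(gs, tpl, seed = 1L) {
  stopifnot(inherits(gs, "GatingSet"), inherits(tpl, "GatingTemplate"))
  samples <- sample_ids(gs$store)
  share_ids <- vapply(tpl$entries, `[[`, integer(1), "share_id")
  for (sid_group in unique(share_ids)) {
    entries <- tpl$entries[share_ids == sid_group]
    e0 <- entries[[1]]
    channels <- vapply(e0$dims, function(m) resolve_dim_channel(gs$store, m),
                       character(1))
    keys <- sample_group_keys(gs$store, samples, e0$group_by)
    groups <- split(samples, keys)

    # fitted result per sample: either per-dim thresholds or a Gate
    fits <- setNames(vector("list", length(samples)), samples)
    fitter <- get_fitter(e0$method)

    for (members in groups) {
      fit_one <- function(train_samples) {
        ev <- pooled_parent_events(gs, train_samples, e0$parent)
        if (e0$method == "refGate") {
          inner_name <- arg_or(e0$args, "method", "quantileGate")
          inner <- get_fitter(inner_name)
          res <- inner$fit(ev, channels, e0$args, seed)
          if (is.numeric(res) && !is.null(e0$args$offset))
            res <- res + e0$args$offset
          res
        } else {
          fitter$fit(ev, channels, e0$args, seed)
        }
      }
      assign_fit <- function(sids, res) for (s in sids) fits[[s]] <<- res
      warn_fail <- function(sids, msg) {
        warning(sprintf(
          "template row %d ('%s'): fit failed for sample(s) %s: %s; population marked missing",
          e0$row, e0$alias, paste(sids, collapse = ","), msg), call. = FALSE)
      }
      if (e0$method == "refGate") {
        rk <- e0$args$ref_key; rv <- as.character(e0$args$ref_value)
        if (is.null(rk))
          stop(fcs_condition("refGate requires gating_args ref_key and ref_value",
                             "cytogate_schema_error"))
        src <- members[vapply(members, function(s) {
          v <- gs$store$samples[[s]]$metadata[[rk]]
          !is.null(v) && identical(as.character(v), rv)
        }, logical(1))]
        if (!length(src)) {
          warn_fail(members, paste0("no source sample with ", rk, "=", rv))
          next
        }
        res <- tryCatch(fit_one(src), error = function(e) e)
        if (inherits(res, "error")) warn_fail(members, conditionMessage(res))
        else assign_fit(members, res)
      } else if (e0$collapse) {
        res <- tryCatch(fit_one(members), error = function(e) e)
        if (inherits(res, "error")) warn_fail(members, conditionMessage(res))
        else assign_fit(members, res)
      } else {
        for (s in members) {
          res <- tryCatch(fit_one(s), error = function(e) e)
          if (inherits(res, "error")) warn_fail(s, conditionMessage(res))
          else assign_fit(s, res)
        }
      }
    }

    for (e in entries) {
      gates <- lapply(fits, function(res) {
        if (is.null(res)) return(NULL)
        if (inherits(res, "Gate")) res
        else threshold_gates_for_signs(channels, e$signs, res)
      })
      add_population(gs, e$parent, e$alias, gate = gates)
    }
  }
  invisible(gs)
}
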