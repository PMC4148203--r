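#' @name boolean_poly
#' @title Boolean combination subsets
#'
#' @description
#' Given k binary (threshold-type) marker gates under a parent population,
#' every event belongs to exactly one of the 2^k Boolean combinations (the
#' gates' half-open thresholds make `+`/`-` disjoint and exhaustive). The
#' enumeration works off the gating set's cached event indices, so no event
#' data are re-read: per sample a k-bit code is assembled (bit i set = event
#' inside the i-th marker gate, in declared order) and tabulated over all
#' 2^k codes, zero-count combinations included.
NULL

combo_labels <- function(marker_names, k) {
  codes <- 0:(2^k - 1)
  vapply(codes, function(code) {
    paste0(marker_names, ifelse(bitwAnd(code, 2^(seq_len(k) - 1)) > 0,
                                "+", "-"), collapse = "")
  }, character(1))
}

popcount <- function(code) {
  vapply(code, function(x) sum(bitwAnd(x, 2^(0:30)) > 0), integer(1))
}

#' Enumerate all Boolean combination subsets of k marker gates
#'
#' @param gs a gated `GatingSet`.
#' @param parent_path parent population (path or unique name).
#' @param marker_gate_paths character vector of k threshold-gated populations
#'   under (descendants of) the parent.
#' @param samples sample ids (default all).
#' @return A `subset_table` data.frame with one row per (sample, combo):
#'   `sample_id`, `parent_path`, `combo_code` (0..2^k-1), `combo_label`
#'   (e.g. `"IFNg+IL2-TNFa+"`), `count`, `proportion_of_parent`, `degree`.
#' @export
enumerate_subsets <- function(gs, parent_path, marker_gate_paths,
                              samples = sample_ids(gs$store)) {
  stopifnot(inherits(gs, "GatingSet"))
  parent_path <- resolve_path(gs, parent_path)
  paths <- vapply(marker_gate_paths, function(p) resolve_path(gs, p),
                  character(1))
  k <- length(paths)
  stopifnot(k >= 1, k <= 30)
  under <- c(parent_path, descendant_paths(gs, parent_path))
  for (p in paths) {
    if (!p %in% under)
      stop(fcs_condition(paste0(p, " is not a descendant of ", parent_path),
                         "cytogate_schema_error"))
    node <- gs$nodes[[p]]
    gate1 <- if (inherits(node$gate, "Gate")) node$gate else node$gate[[1]]
    if (!inherits(gate1, c("gate_threshold", "gate_rectangle")))
      stop(fcs_condition(paste0(p, " is not a binary threshold-type gate"),
                         "cytogate_schema_error"))
  }
  marker_names <- vapply(paths, function(p) gs$nodes[[p]]$name, character(1))
  labels <- combo_labels(marker_names, k)
  codes <- 0:(2^k - 1)
  degrees <- popcount(codes)

  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    sid <- samples[si]
    parent_idx <- compute_indices(gs, sid, parent_path)
    n_parent <- sum(parent_idx)
    code_per_event <- integer(n_parent)
    for (i in seq_len(k)) {
      gi <- compute_indices(gs, sid, paths[i])[parent_idx]
      code_per_event <- code_per_event + as.integer(gi) * 2L^(i - 1L)
    }
    counts <- tabulate(code_per_event + 1L, nbins = 2^k)
    out[[si]] <- data.frame(
      sample_id = sid, parent_path = parent_path,
      combo_code = codes, combo_label = labels,
      count = counts,
      proportion_of_parent = if (n_parent > 0) counts / n_parent else 0,
      degree = degrees,
      row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("subset_table", "data.frame")
  res
}

#' Degree-of-functionality distribution
#'
#' Groups a subset table's proportions by the number of positive markers
#' (popcount of the combination code); per (sample, parent) the masses sum
#' to 1.
#'
#' @param tbl a `subset_table`.
#' @param parent_path restrict to this parent (default: all parents in `tbl`).
#' @return data.frame with `sample_id`, `parent_path`, `degree`, `proportion`.
#' @export
degree_distribution <- function(tbl, parent_path = NULL) {
  stopifnot(inherits(tbl, "data.frame"))
  if (!is.null(parent_path)) tbl <- tbl[tbl$parent_path == parent_path, ]
  if (!nrow(tbl)) stop("no rows for requested parent", call. = FALSE)
  agg <- stats::aggregate(proportion_of_parent ~ sample_id + parent_path + degree,
                          data = tbl, FUN = sum)
  names(agg)[names(agg) == "proportion_of_parent"] <- "proportion"
  agg[order(agg$sample_id, agg$parent_path, agg$degree), , drop = FALSE]
}

#' Drop combinations that are rare in every sample
#'
#' A (parent, combination) is kept if its proportion of parent reaches
#' `threshold` in at least one sample; otherwise all its rows are removed.
#'
#' @param tbl a `subset_table`.
#' @param threshold proportion cutoff (the CyTOF analysis used 0.01).
#' @return The filtered `subset_table`.
#' @export
filter_low_frequency <- function(tbl, threshold = 0.01) {
  stopifnot(inherits(tbl, "data.frame"))
  if (threshold <= 0) return(tbl)
  key <- paste(tbl$parent_path, tbl$combo_code)
  keep_key <- unique(key[tbl$proportion_of_parent >= threshold])
  res <- tbl[key %in% keep_key, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Audit a subset table against the marginal gate counts
#'
#' For each marker m, the sum of combination counts with bit m set must equal
#' the marginal m+ count from the gating set's cached indices (restricted to
#' the parent). A mismatch indicates a corrupted table.
#'
#' @param gs the `GatingSet` the table came from.
#' @param tbl a `subset_table`.
#' @param parent_path parent population used in the enumeration.
#' @param marker_gate_paths the k marker gates, in the order used.
#' @return data.frame report (`sample_id`, `marker`, `combo_sum`,
#'   `marginal_count`, `pass`); attribute `pass` is the overall verdict.
#' @export
marginal_to_combo_check <- function(gs, tbl, parent_path, marker_gate_paths) {
  parent_path <- resolve_path(gs, parent_path)
  paths <- vapply(marker_gate_paths, function(p) resolve_path(gs, p),
                  character(1))
  tbl <- tbl[tbl$parent_path == parent_path, ]
  samples <- unique(tbl$sample_id)
  rows <- list()
  for (sid in samples) {
    tt <- tbl[tbl$sample_id == sid, ]
    parent_idx <- compute_indices(gs, sid, parent_path)
    for (i in seq_along(paths)) {
      marginal <- sum(compute_indices(gs, sid, paths[i]) & parent_idx)
      combo_sum <- sum(tt$count[bitwAnd(tt$combo_code, 2^(i - 1)) > 0])
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = sid, marker = gs$nodes[[paths[i]]]$name,
        combo_sum = combo_sum, marginal_count = marginal,
        pass = combo_sum == marginal, stringsAsFactors = FALSE)
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(0), marker = character(0),
               combo_sum = integer(0), marginal_count = integer(0),
               pass = logical(0))
  attr(report, "pass") <- all(report$pass)
  report
}
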