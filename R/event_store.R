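#' @name event_store
#' @title Disk-backed sample store
#'
#' @description
#' Studies with hundreds of FCS files do not fit comfortably in memory, so
#' gating operates against an on-disk container from which one sample's events
#' are materialised at a time. The container is a single binary file: a magic
#' string, a JSON index (shared channel list plus per-sample byte offset, row
#' count, markers and metadata), then one row-major float32 blob per sample.
#' Reads are idempotent; a store reopened after a restart yields bit-identical
#' float32 data.
NULL

STORE_MAGIC <- "CYTOGATE-STORE-1\n"

#' Create a sample store on disk
#'
#' @param samples non-empty list of [event_matrix()] objects sharing one
#'   ordered channel list.
#' @param path file to create (overwritten).
#' @return An open `SampleStore` handle.
#' @export
create_store <- function(samples, path) {
  if (!length(samples)) stop("empty sample list", call. = FALSE)
  stopifnot(all(vapply(samples, inherits, logical(1), "EventMatrix")))
  channels <- samples[[1]]$channels
  for (s in samples) {
    if (!identical(s$channels, channels))
      stop(fcs_condition(paste0("channel mismatch for sample ", s$sample_id),
                         "cytogate_schema_error"))
  }
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)

  offset <- 0
  index <- list(channels = channels, samples = list())
  for (s in samples) {
    n <- nrow(s$events)
    index$samples[[s$sample_id]] <- list(
      offset = offset, nrow = n,
      markers = as.list(s$markers),
      metadata = lapply(s$metadata, as.character))
    offset <- offset + n * length(channels) * 4
  }
  idx_json <- charToRaw(jsonlite::toJSON(index, auto_unbox = TRUE, digits = NA))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(STORE_MAGIC, con, eos = NULL)
  writeBin(length(idx_json), con, size = 4, endian = "little")
  writeBin(idx_json, con)
  for (s in samples) {
    if (nrow(s$events) > 0)
      writeBin(as.vector(t(s$events)), con, size = 4, endian = "little")
  }
  close(con); on.exit()
  open_store(path)
}

#' Open an existing sample store
#' @param path store file created by [create_store()].
#' @return An open `SampleStore` handle.
#' @export
open_store <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchar(STORE_MAGIC), useBytes = TRUE)
  if (!identical(magic, STORE_MAGIC))
    stop(fcs_condition("not a cytogate store file", "cytogate_format_error"))
  n <- readBin(con, "integer", size = 4, endian = "little")
  idx <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = n)),
                            simplifyVector = FALSE)
  st <- new.env(parent = emptyenv())
  st$path <- normalizePath(path)
  st$channels <- unlist(idx$channels)
  st$samples <- idx$samples
  st$data_start <- nchar(STORE_MAGIC) + 4 + n
  st$open <- TRUE
  class(st) <- "SampleStore"
  st
}

#' Close a store handle
#' @param store a `SampleStore`.
#' @export
close_store <- function(store) {
  store$open <- FALSE
  invisible(store)
}

#' @export
print.SampleStore <- function(x, ...) {
  cat(sprintf("SampleStore (%s): %d samples x %d channels [%s]\n",
              basename(x$path), length(x$samples), length(x$channels),
              if (x$open) "open" else "closed"))
  invisible(x)
}

#' Sample identifiers in a store
#' @param store a `SampleStore`.
#' @return Character vector in storage order.
#' @export
sample_ids <- function(store) names(store$samples)

check_store <- function(store, sample_id = NULL) {
  stopifnot(inherits(store, "SampleStore"))
  if (!isTRUE(store$open))
    stop(fcs_condition("store is closed", "cytogate_state_error"))
  if (!is.null(sample_id) && !sample_id %in% names(store$samples))
    stop(fcs_condition(paste0("unknown sample id: ", sample_id),
                       "cytogate_lookup_error"))
}

#' Retrieve one sample from a store
#'
#' Only this sample's events are materialised; values are bit-identical at
#' float32 to what was written.
#'
#' @param store a `SampleStore`.
#' @param sample_id sample identifier.
#' @return An [event_matrix()].
#' @export
get_sample <- function(store, sample_id) {
  check_store(store, sample_id)
  rec <- store$samples[[sample_id]]
  k <- length(store$channels)
  con <- file(store$path, "rb")
  on.exit(close(con))
  seek(con, store$data_start + rec$offset)
  vals <- readBin(con, "numeric", n = rec$nrow * k, size = 4, endian = "little")
  ev <- matrix(vals, nrow = rec$nrow, ncol = k, byrow = TRUE)
  event_matrix(ev, channels = store$channels,
               markers = unlist(rec$markers),
               sample_id = sample_id,
               metadata = rec$metadata)
}

#' Row-subset of one stored sample
#'
#' @param store a `SampleStore`.
#' @param sample_id sample identifier.
#' @param mask logical vector of length equal to the sample's row count.
#' @return An [event_matrix()] holding the masked rows in original order.
#' @export
subset_rows <- function(store, sample_id, mask) {
  check_store(store, sample_id)
  rec <- store$samples[[sample_id]]
  if (length(mask) != rec$nrow)
    stop(fcs_condition(sprintf("mask length %d != sample rows %d",
                               length(mask), rec$nrow),
                       "cytogate_schema_error"))
  s <- get_sample(store, sample_id)
  s$events <- s$events[as.logical(mask), , drop = FALSE]
  s
}

#' Number of events per stored sample
#' @param store a `SampleStore`.
#' @return Named integer vector.
#' @export
store_counts <- function(store) {
  vapply(store$samples, function(r) as.integer(r$nrow), integer(1))
}
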