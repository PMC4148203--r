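#' Construct an event matrix
#'
#' The in-memory representation of one cytometry sample: an events x channels
#' matrix of float intensities plus the channel -> marker map and free-form
#' sample metadata (e.g. `PTID`, `VISITNO`, `STIM`).
#'
#' @param events numeric matrix, rows = cells, columns = channels.
#' @param channels character vector of unique channel names (defaults to
#'   `colnames(events)`).
#' @param markers optional named character vector mapping channel names to
#'   marker names; may cover only a subset of channels.
#' @param sample_id scalar character identifier.
#' @param metadata named list/character vector of sample-level keywords.
#' @return An object of class `EventMatrix`.
#' @export
event_matrix <- function(events, channels = colnames(events), markers = NULL,
                         sample_id = "sample", metadata = list()) {
  events <- as.matrix(events)
  storage.mode(events) <- "double"
  if (is.null(channels)) stop("channel names are required", call. = FALSE)
  channels <- as.character(channels)
  if (length(channels) != ncol(events))
    stop("length(channels) != ncol(events)", call. = FALSE)
  if (anyDuplicated(channels))
    stop("channel names must be unique", call. = FALSE)
  if (nrow(events) > 0 && !all(is.finite(events)))
    stop("events contain non-finite values", call. = FALSE)
  markers <- if (is.null(markers)) character(0) else unlist(markers)
  if (length(markers) && !all(names(markers) %in% channels))
    stop("markers map onto unknown channels: ",
         paste(setdiff(names(markers), channels), collapse = ", "), call. = FALSE)
  colnames(events) <- channels
  metadata <- as.list(metadata)
  structure(list(events = events, channels = channels,
                 markers = markers, sample_id = as.character(sample_id),
                 metadata = metadata),
            class = "EventMatrix")
}

#' @export
print.EventMatrix <- function(x, ...) {
  cat(sprintf("EventMatrix '%s': %d events x %d channels\n",
              x$sample_id, nrow(x$events), length(x$channels)))
  mk <- ifelse(x$channels %in% names(x$markers),
               paste0(" <", x$markers[x$channels], ">"), "")
  cat("  ", paste0(x$channels, mk, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.EventMatrix <- function(x) dim(x$events)

# round-trip a numeric vector/matrix through IEEE-754 single precision,
# which is what FCS $DATATYPE F and the event store hold on disk
as_float32 <- function(x) {
  d <- dim(x)
  r <- writeBin(as.vector(as.numeric(x)), raw(), size = 4, endian = "little")
  out <- readBin(r, "numeric", n = length(x), size = 4, endian = "little")
  dim(out) <- d
  out
}

fcs_condition <- function(msg, class) {
  structure(class = c(class, "cytogate_error", "error", "condition"),
            list(message = msg, call = NULL))
}

# ---- FCS 3.0/3.1 writer ------------------------------------------------------

#' Write an FCS 3.1 file
#'
#' Events are stored as little-endian IEEE single precision (`$DATATYPE F`,
#' `$MODE L`). Channel names go to `$PnN`, markers to `$PnS`, and sample
#' metadata entries become additional TEXT-segment keywords.
#'
#' @param sample an [event_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(sample, path) {
  stopifnot(inherits(sample, "EventMatrix"))
  ev <- sample$events
  if (nrow(ev) > 0 && !all(is.finite(ev)))
    stop(fcs_condition("cannot write non-finite events", "cytogate_format_error"))
  np <- length(sample$channels)
  nt <- nrow(ev)

  esc <- function(x) gsub("/", "//", as.character(x), fixed = TRUE)
  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0", "$NEXTDATA" = "0",
    "$MODE" = "L", "$DATATYPE" = "F", "$BYTEORD" = "1,2,3,4",
    "$TOT" = as.character(nt), "$PAR" = as.character(np)
  )
  for (i in seq_len(np)) {
    ch <- sample$channels[i]
    rng <- if (nt > 0) max(ev[, i], 1) else 1
    kw[[sprintf("$P%dN", i)]] <- ch
    kw[[sprintf("$P%dB", i)]] <- "32"
    kw[[sprintf("$P%dE", i)]] <- "0,0"
    kw[[sprintf("$P%dR", i)]] <- as.character(ceiling(rng) + 1)
    if (ch %in% names(sample$markers))
      kw[[sprintf("$P%dS", i)]] <- sample$markers[[ch]]
  }
  md <- sample$metadata
  md <- md[!grepl("^\\$", names(md))]
  for (nm in names(md)) kw[[nm]] <- as.character(md[[nm]])
  kw[["GUID"]] <- sample$sample_id

  # data offsets depend on TEXT length; fixed-width placeholders close the loop
  kw[["$BEGINDATA"]] <- sprintf("%012d", 0L)
  kw[["$ENDDATA"]] <- sprintf("%012d", 0L)
  text_of <- function(kw) paste0("/", paste0(esc(names(kw)), "/", esc(unname(kw)),
                                             "/", collapse = ""))
  txt <- text_of(kw)
  text_begin <- 58L
  text_end <- text_begin + nchar(txt, type = "bytes") - 1L
  data_begin <- text_end + 1L
  n_bytes <- nt * np * 4L
  data_end <- if (n_bytes > 0) data_begin + n_bytes - 1L else data_begin
  kw[["$BEGINDATA"]] <- sprintf("%012d", data_begin)
  kw[["$ENDDATA"]] <- sprintf("%012d", data_end)
  txt <- text_of(kw)

  hdr_num <- function(x) {
    if (x > 99999999) "       0" else sprintf("%8d", x)
  }
  header <- paste0("FCS3.1    ",
                   hdr_num(text_begin), hdr_num(text_end),
                   hdr_num(data_begin), hdr_num(data_end),
                   sprintf("%8d", 0L), sprintf("%8d", 0L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  if (nt > 0)
    writeBin(as.vector(t(ev)), con, size = 4, endian = "little")
  invisible(path)
}

# ---- FCS 3.0/3.1 reader ------------------------------------------------------

parse_fcs_text <- function(raw_txt) {
  txt <- rawToChar(raw_txt)
  delim <- substr(txt, 1, 1)
  body <- substr(txt, 2, nchar(txt))
  # doubled delimiters are escapes; protect them before splitting
  sentinel <- "\x01"
  body <- gsub(paste0(delim, delim), sentinel, body, fixed = TRUE)
  toks <- strsplit(body, delim, fixed = TRUE)[[1]]
  toks <- gsub(sentinel, delim, toks, fixed = TRUE)
  if (length(toks) %% 2 == 1) toks <- toks[-length(toks)]
  kw <- as.list(toks[seq(2, length(toks), by = 2)])
  names(kw) <- toks[seq(1, length(toks), by = 2)]
  kw
}

#' Read an FCS 3.0/3.1 file
#'
#' Supports list-mode files with `$DATATYPE` `F` (32-bit float) or `I`
#' (16/32-bit unsigned integer); `D` (double) is rejected with a format error.
#' All TEXT-segment keywords are retained in the returned object's metadata,
#' channel names come from `$PnN` and markers from `$PnS`.
#'
#' @param path path to an FCS file.
#' @param sample_id identifier for the returned sample; defaults to the file
#'   base name.
#' @return An [event_matrix()].
#' @export
read_fcs <- function(path, sample_id = NULL) {
  if (!file.exists(path))
    stop(fcs_condition(paste0("no such file: ", path), "cytogate_format_error"))
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  rawdat <- readBin(con, "raw", n = sz)
  if (length(rawdat) < 58)
    stop(fcs_condition("file too short for an FCS header", "cytogate_integrity_error"))

  version <- rawToChar(rawdat[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop(fcs_condition(paste0("unsupported FCS version: ", version),
                       "cytogate_format_error"))
  off <- function(i) {
    s <- trimws(rawToChar(rawdat[(10 + 8 * (i - 1) + 1):(10 + 8 * i)]))
    v <- suppressWarnings(as.numeric(s))
    if (is.na(v) || v < 0)
      stop(fcs_condition("corrupt byte-offset header", "cytogate_integrity_error"))
    v
  }
  text_begin <- off(1); text_end <- off(2)
  data_begin <- off(3); data_end <- off(4)
  if (text_begin < 58 || text_end > sz || text_end < text_begin)
    stop(fcs_condition("corrupt byte-offset header", "cytogate_integrity_error"))

  kw <- parse_fcs_text(rawdat[(text_begin + 1):(text_end + 1)])
  kwget <- function(key, default = NULL) {
    hit <- which(toupper(names(kw)) == toupper(key))
    if (length(hit)) kw[[hit[1]]] else default
  }
  need <- function(key) {
    v <- kwget(key)
    if (is.null(v))
      stop(fcs_condition(paste0("missing required keyword ", key),
                         "cytogate_format_error"))
    v
  }
  dtype <- toupper(need("$DATATYPE"))
  if (dtype == "D")
    stop(fcs_condition("$DATATYPE D (double) is not supported", "cytogate_format_error"))
  if (!dtype %in% c("F", "I"))
    stop(fcs_condition(paste0("unsupported $DATATYPE ", dtype), "cytogate_format_error"))
  if (toupper(need("$MODE")) != "L")
    stop(fcs_condition("only list-mode ($MODE L) files are supported",
                       "cytogate_format_error"))
  byteord <- need("$BYTEORD")
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else stop(fcs_condition(paste0("unsupported $BYTEORD ", byteord),
                                    "cytogate_format_error"))
  tot <- as.integer(need("$TOT"))
  par <- as.integer(need("$PAR"))

  channels <- character(par)
  markers <- character(0)
  bits <- integer(par)
  for (i in seq_len(par)) {
    channels[i] <- need(sprintf("$P%dN", i))
    bits[i] <- as.integer(need(sprintf("$P%dB", i)))
    s <- kwget(sprintf("$P%dS", i))
    if (!is.null(s)) markers[channels[i]] <- s
  }

  if (data_begin == 0) data_begin <- as.numeric(need("$BEGINDATA"))
  if (data_end == 0) data_end <- as.numeric(need("$ENDDATA"))
  n_values <- tot * par
  if (n_values > 0) {
    bytes_per <- bits[1] / 8
    if (dtype == "F" && any(bits != 32))
      stop(fcs_condition("$DATATYPE F requires $PnB = 32", "cytogate_format_error"))
    if (dtype == "I" && (any(bits != bits[1]) || !bits[1] %in% c(16L, 32L)))
      stop(fcs_condition("$DATATYPE I supports uniform $PnB of 16 or 32",
                         "cytogate_format_error"))
    expected <- n_values * bytes_per
    if (data_end > sz || data_end - data_begin + 1 < expected)
      stop(fcs_condition("truncated DATA segment", "cytogate_integrity_error"))
    blob <- rawdat[(data_begin + 1):(data_begin + expected)]
    vals <- if (dtype == "F") {
      readBin(blob, "numeric", n = n_values, size = 4, endian = endian)
    } else if (bytes_per == 2) {
      as.numeric(readBin(blob, "integer", n = n_values, size = 2,
                         endian = endian, signed = FALSE))
    } else {
      v <- as.numeric(readBin(blob, "integer", n = n_values, size = 4,
                              endian = endian))
      ifelse(v < 0, v + 2^32, v)  # stored unsigned
    }
    ev <- matrix(vals, nrow = tot, ncol = par, byrow = TRUE)
  } else {
    ev <- matrix(numeric(0), nrow = 0, ncol = par)
  }
  if (nrow(ev) > 0 && !all(is.finite(ev)))
    stop(fcs_condition("DATA segment contains non-finite values",
                       "cytogate_integrity_error"))
  if (is.null(sample_id))
    sample_id <- kwget("GUID", default = basename(path))
  event_matrix(ev, channels = channels, markers = markers,
               sample_id = sample_id, metadata = kw)
}

# ---- compensation ------------------------------------------------------------

#' Read a spillover matrix from CSV
#'
#' The CSV header row names the fluorescence channels; the body is the square
#' matrix of unitless spillover fractions (diagonal 1).
#'
#' @param path CSV file path.
#' @return A square numeric matrix with channel dimnames.
#' @export
read_spillover_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  validate_spillover(m)
  m
}

validate_spillover <- function(spill) {
  if (nrow(spill) != ncol(spill))
    stop(fcs_condition("spillover matrix must be square", "cytogate_schema_error"))
  if (is.null(colnames(spill)))
    stop(fcs_condition("spillover matrix must have channel names", "cytogate_schema_error"))
  if (any(abs(diag(spill) - 1) > 1e-8))
    stop(fcs_condition("spillover diagonal must be 1", "cytogate_schema_error"))
  if (!all(is.finite(spill)) || rcond(spill) < 1e-12)
    stop(fcs_condition("spillover matrix is singular or ill-conditioned",
                       "cytogate_numeric_error"))
  invisible(spill)
}

#' Apply spillover compensation
#'
#' Solves `observed = true %*% spill` for the true intensities, i.e. multiplies
#' the named fluorescence columns by `solve(spill)`. Channels absent from the
#' spillover matrix (scatter, time, DNA) are untouched.
#'
#' @param sample an [event_matrix()].
#' @param spill square spillover matrix with channel dimnames.
#' @return The compensated [event_matrix()].
#' @export
compensate <- function(sample, spill) {
  stopifnot(inherits(sample, "EventMatrix"))
  validate_spillover(spill)
  chans <- colnames(spill)
  missing_ch <- setdiff(chans, sample$channels)
  if (length(missing_ch))
    stop(fcs_condition(paste0("spillover channels not in sample: ",
                              paste(missing_ch, collapse = ", ")),
                       "cytogate_schema_error"))
  ev <- sample$events
  if (nrow(ev) > 0)
    ev[, chans] <- ev[, chans, drop = FALSE] %*% solve(spill)
  sample$events <- ev
  sample
}

# ---- transformation ----------------------------------------------------------

#' Channel transformation specification
#'
#' @param kind one of `"arcsinh"` (`y = asinh(x / cofactor)`), `"linear"`
#'   (`y = x / cofactor`) or `"none"`.
#' @param cofactor positive scale divisor; the community defaults are 150 for
#'   fluorescence and 5 for mass-cytometry channels.
#' @param channels channels the transform applies to.
#' @return A `TransformSpec` object.
#' @export
transform_spec <- function(kind = c("arcsinh", "linear", "none"),
                           cofactor = 150, channels = character(0)) {
  kind <- match.arg(kind)
  if (kind != "none" && (!is.finite(cofactor) || cofactor <= 0))
    stop(fcs_condition("cofactor must be > 0", "cytogate_parameter_error"))
  structure(list(kind = kind, cofactor = cofactor,
                 channels = as.character(channels)),
            class = "TransformSpec")
}

#' Default transform assignment for a sample
#'
#' Assigns an arcsinh transform to every channel except forward/side scatter
#' and time, which by convention stay on the linear instrument scale.
#'
#' @param sample an [event_matrix()].
#' @param cofactor arcsinh cofactor (150 fluorescence, 5 mass cytometry).
#' @return A [transform_spec()].
#' @export
default_transform_spec <- function(sample, cofactor = 150) {
  scatter <- grepl("^(FSC|SSC)", sample$channels) |
    tolower(sample$channels) == "time"
  transform_spec("arcsinh", cofactor, sample$channels[!scatter])
}

#' Apply a channel transformation
#'
#' @param sample an [event_matrix()].
#' @param spec a [transform_spec()].
#' @return The transformed [event_matrix()]; event order is preserved.
#' @export
transform_channels <- function(sample, spec) {
  stopifnot(inherits(sample, "EventMatrix"), inherits(spec, "TransformSpec"))
  chans <- intersect(spec$channels, sample$channels)
  if (spec$kind == "none" || length(chans) == 0 || nrow(sample$events) == 0)
    return(sample)
  x <- sample$events[, chans, drop = FALSE]
  sample$events[, chans] <- switch(spec$kind,
    arcsinh = asinh(x / spec$cofactor),
    linear = x / spec$cofactor)
  sample
}

#' Read a transform specification from a JSON config
#'
#' The config is an object with fields `kind`, `cofactor`, `channels`.
#' @param path JSON file path.
#' @return A [transform_spec()].
#' @export
read_transform_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform_spec(kind = cfg$kind %||% "arcsinh",
                 cofactor = cfg$cofactor %||% 150,
                 channels = cfg$channels %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
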