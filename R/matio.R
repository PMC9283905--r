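# Minimal MAT v5 (Level 5 MAT-file) reader/writer covering the subset used by
# the published session files and this package's own exports: double / char /
# cell / struct arrays, little- or big-endian, normal and small element tags,
# and zlib-compressed (miCOMPRESSED) top-level elements. Sparse, complex,
# logical and object arrays are out of scope.

.MI <- list(INT8 = 1L, UINT8 = 2L, INT16 = 3L, UINT16 = 4L, INT32 = 5L,
            UINT32 = 6L, SINGLE = 7L, DOUBLE = 9L, INT64 = 12L,
            UINT64 = 13L, MATRIX = 14L, COMPRESSED = 15L, UTF8 = 16L)
.MX <- list(CELL = 1L, STRUCT = 2L, CHAR = 4L, DOUBLE = 6L, SINGLE = 7L,
            INT8 = 8L, UINT8 = 9L, INT16 = 10L, UINT16 = 11L, INT32 = 12L,
            UINT32 = 13L)

# ---- writing ---------------------------------------------------------------

.raw_le <- function(x, size) writeBin(x, raw(), size = size, endian = "little")

.pad8 <- function(r) {
  rem <- length(r) %% 8
  if (rem) c(r, raw(8 - rem)) else r
}

.mat_tag <- function(type, payload) {
  c(.raw_le(as.integer(c(type, length(payload))), 4L), .pad8(payload))
}

.mat_flags <- function(mx_class) {
  .mat_tag(.MI$UINT32, .raw_le(c(as.integer(mx_class), 0L), 4L))
}

.mat_dims <- function(dims) .mat_tag(.MI$INT32, .raw_le(as.integer(dims), 4L))

.mat_name <- function(name) .mat_tag(.MI$INT8, charToRaw(name))

.mat_double_array <- function(values, dims, name = "") {
  body <- c(.mat_flags(.MX$DOUBLE), .mat_dims(dims), .mat_name(name),
            .mat_tag(.MI$DOUBLE, .raw_le(as.numeric(values), 8L)))
  .mat_tag(.MI$MATRIX, body)
}

.mat_char_array <- function(s, name = "") {
  bytes <- charToRaw(s)
  body <- c(.mat_flags(.MX$CHAR), .mat_dims(c(1L, length(bytes))),
            .mat_name(name), .mat_tag(.MI$UINT8, bytes))
  .mat_tag(.MI$MATRIX, body)
}

.mat_cell_array <- function(elements, dims, name = "") {
  body <- c(.mat_flags(.MX$CELL), .mat_dims(dims), .mat_name(name),
            do.call(c, elements))
  .mat_tag(.MI$MATRIX, body)
}

.mat_struct <- function(fields, name = "") {
  fnames <- names(fields)
  maxlen <- 32L
  name_block <- do.call(c, lapply(fnames, function(fn) {
    r <- charToRaw(fn)
    c(r, raw(maxlen - length(r)))
  }))
  body <- c(.mat_flags(.MX$STRUCT), .mat_dims(c(1L, 1L)), .mat_name(name),
            .mat_tag(.MI$INT32, .raw_le(maxlen, 4L)),
            .mat_tag(.MI$INT8, name_block),
            do.call(c, unname(fields)))
  .mat_tag(.MI$MATRIX, body)
}

.mat_header <- function(description = "MATLAB 5.0 MAT-file, written by egml") {
  txt <- charToRaw(description)
  if (length(txt) > 116) txt <- txt[1:116]
  hdr <- c(txt, rep(charToRaw(" "), 116 - length(txt)))
  c(hdr, raw(8), as.raw(c(0x00, 0x01)), charToRaw("IM"))
}

# ---- reading ---------------------------------------------------------------

.rd_int <- function(r, pos, size, endian, signed = TRUE, n = 1) {
  readBin(r[pos:(pos + size * n - 1)], "integer", n = n, size = size,
          signed = signed, endian = endian)
}

# Returns list(type, payload raw, next position). Handles small element tags.
.rd_tag <- function(r, pos, endian) {
  word1 <- .rd_int(r, pos, 4L, endian)
  small_len <- bitwAnd(bitwShiftR(word1, 16), 0xFFFF)
  if (small_len != 0) {
    type <- bitwAnd(word1, 0xFFFF)
    payload <- if (small_len > 0) r[(pos + 4):(pos + 4 + small_len - 1)] else raw()
    return(list(type = type, payload = payload, next_pos = pos + 8))
  }
  type <- word1
  nbytes <- .rd_int(r, pos + 4L, 4L, endian)
  payload <- if (nbytes > 0) r[(pos + 8):(pos + 8 + nbytes - 1)] else raw()
  adv <- nbytes + (8 - nbytes %% 8) %% 8
  list(type = type, payload = payload, next_pos = pos + 8 + adv)
}

.rd_numeric_payload <- function(type, payload, endian) {
  switch(as.character(type),
    "9" = readBin(payload, "numeric", n = length(payload) / 8, size = 8,
                  endian = endian),
    "7" = readBin(payload, "numeric", n = length(payload) / 4, size = 4,
                  endian = endian),
    "5" = readBin(payload, "integer", n = length(payload) / 4, size = 4,
                  endian = endian),
    "6" = readBin(payload, "integer", n = length(payload) / 4, size = 4,
                  endian = endian),
    "3" = readBin(payload, "integer", n = length(payload) / 2, size = 2,
                  endian = endian),
    "4" = readBin(payload, "integer", n = length(payload) / 2, size = 2,
                  signed = FALSE, endian = endian),
    "1" = readBin(payload, "integer", n = length(payload), size = 1,
                  endian = endian),
    "2" = as.integer(payload),
    "16" = as.integer(payload),
    stop("unsupported MAT data type: ", type, call. = FALSE))
}

.rd_matrix <- function(payload, endian) {
  pos <- 1L
  tg <- .rd_tag(payload, pos, endian)           # array flags
  flags <- .rd_int(tg$payload, 1L, 4L, endian)
  mx_class <- bitwAnd(flags, 0xFF)
  pos <- tg$next_pos
  tg <- .rd_tag(payload, pos, endian)           # dimensions
  dims <- readBin(tg$payload, "integer", n = length(tg$payload) / 4,
                  size = 4, endian = endian)
  pos <- tg$next_pos
  tg <- .rd_tag(payload, pos, endian)           # name
  name <- rawToChar(tg$payload)
  pos <- tg$next_pos

  value <- if (mx_class %in% c(.MX$DOUBLE, .MX$SINGLE, .MX$INT8, .MX$UINT8,
                               .MX$INT16, .MX$UINT16, .MX$INT32, .MX$UINT32)) {
    tg <- .rd_tag(payload, pos, endian)
    v <- as.numeric(.rd_numeric_payload(tg$type, tg$payload, endian))
    if (length(dims) == 2) matrix(v, dims[1], dims[2]) else array(v, dims)
  } else if (mx_class == .MX$CHAR) {
    tg <- .rd_tag(payload, pos, endian)
    codes <- .rd_numeric_payload(tg$type, tg$payload, endian)
    intToUtf8(codes[codes > 0])
  } else if (mx_class == .MX$CELL) {
    out <- vector("list", prod(dims))
    for (i in seq_along(out)) {
      tg <- .rd_tag(payload, pos, endian)
      if (tg$type != .MI$MATRIX)
        stop("malformed cell array: expected miMATRIX child", call. = FALSE)
      child <- .rd_matrix(tg$payload, endian)
      out[[i]] <- child$value
      pos <- tg$next_pos
    }
    out
  } else if (mx_class == .MX$STRUCT) {
    tg <- .rd_tag(payload, pos, endian)         # field name length
    flen <- .rd_int(tg$payload, 1L, 4L, endian)
    pos <- tg$next_pos
    tg <- .rd_tag(payload, pos, endian)         # field names
    nfield <- length(tg$payload) / flen
    fnames <- vapply(seq_len(nfield), function(i) {
      chunk <- tg$payload[((i - 1) * flen + 1):(i * flen)]
      rawToChar(chunk[chunk != as.raw(0)])
    }, character(1))
    pos <- tg$next_pos
    out <- stats::setNames(vector("list", nfield), fnames)
    for (i in seq_len(nfield)) {
      tg <- .rd_tag(payload, pos, endian)
      if (tg$type != .MI$MATRIX)
        stop("malformed struct: expected miMATRIX field", call. = FALSE)
      child <- .rd_matrix(tg$payload, endian)
      out[[i]] <- child$value
      pos <- tg$next_pos
    }
    out
  } else {
    stop("unsupported MAT array class: ", mx_class, call. = FALSE)
  }
  list(name = name, value = value)
}

.mat_inflate <- function(payload) {
  for (fmt in c("gzip", "unknown")) {
    out <- tryCatch(memDecompress(payload, type = fmt),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("failed to decompress miCOMPRESSED element", call. = FALSE)
}

# Parse a whole MAT v5 file into a named list of top-level variables.
.read_mat5 <- function(path) {
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 128)
    stop("file too short to be a MAT v5 file: ", path, call. = FALSE)
  endian_ind <- rawToChar(r[127:128])
  endian <- if (endian_ind == "IM") "little" else if (endian_ind == "MI")
    "big" else stop("not a MAT v5 file (bad endian indicator): ", path,
                    call. = FALSE)
  pos <- 129L
  vars <- list()
  while (pos <= length(r)) {
    tg <- .rd_tag(r, pos, endian)
    if (tg$type == .MI$COMPRESSED) {
      inner <- .mat_inflate(tg$payload)
      itg <- .rd_tag(inner, 1L, endian)
      if (itg$type != .MI$MATRIX)
        stop("unexpected element inside compressed block", call. = FALSE)
      el <- .rd_matrix(itg$payload, endian)
    } else if (tg$type == .MI$MATRIX) {
      el <- .rd_matrix(tg$payload, endian)
    } else {
      stop("unexpected top-level MAT element type: ", tg$type, call. = FALSE)
    }
    vars[[if (nzchar(el$name)) el$name else length(vars) + 1]] <- el$value
    pos <- tg$next_pos
  }
  vars
}

# ---- recording-level interface --------------------------------------------

#' Write a recording as a MAT-dialect session file
#'
#' Produces an uncompressed MAT v5 file holding a scalar struct `o` with
#' fields `id` (char), `sampFreq` (1x1), `marker` (T x 1; the class integer at
#' each onset sample, 0 elsewhere), `data` (T x 21, samples x channels), and
#' `chnames` (21 x 1 cell of channel names) — the layout used by the public
#' FreeForm session files.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_freeform_mat <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  Tn <- ncol(rec$signals)
  marker <- numeric(Tn)
  marker[rec$onsets] <- rec$labels
  fields <- list(
    id = .mat_char_array("synthetic FreeForm session"),
    sampFreq = .mat_double_array(rec$fs, c(1L, 1L)),
    marker = .mat_double_array(marker, c(Tn, 1L)),
    data = .mat_double_array(t(rec$signals), c(Tn, 21L)),
    chnames = .mat_cell_array(lapply(rec$channels, .mat_char_array),
                              c(21L, 1L))
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.mat_header(), con)
  writeBin(.mat_struct(fields, name = "o"), con)
  invisible(path)
}

#' Read a MAT-dialect session file into a recording
#'
#' Expects the FreeForm session layout: a struct (any top-level name) with
#' fields `data` (samples x channels), `marker`, `sampFreq`, and `chnames`.
#' Onsets are the rising edges of the marker channel (a nonzero sample whose
#' predecessor is zero); the marker value at the onset gives the class
#' ("d" = 1, "l" = 2). Channels are reordered to the fixed
#' [eeg_channels()] list; extra channels are dropped.
#'
#' @param path file path.
#' @param allow_empty if `FALSE` (default), a marker with no events is an
#'   error.
#' @return an [eeg_recording()].
#' @export
read_freeform_mat <- function(path, allow_empty = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vars <- .read_mat5(path)
  is_session <- vapply(vars, function(v) {
    is.list(v) && all(c("data", "marker", "sampFreq", "chnames") %in% names(v))
  }, logical(1))
  if (!any(is_session))
    stop("no session struct with fields data/marker/sampFreq/chnames found in ",
         path, call. = FALSE)
  o <- vars[[which(is_session)[1]]]
  fs <- as.numeric(o$sampFreq)[1]
  data <- o$data
  chnames <- unlist(o$chnames)
  if (ncol(data) != length(chnames))
    stop("channel-name count (", length(chnames),
         ") does not match data columns (", ncol(data), ")", call. = FALSE)
  want <- eeg_channels()
  missing <- setdiff(want, chnames)
  if (length(missing))
    stop("file is missing required channel(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  signals <- t(data[, match(want, chnames), drop = FALSE])
  marker <- as.numeric(o$marker)
  nz <- marker != 0
  rising <- which(nz & !c(FALSE, nz[-length(nz)]))
  if (length(rising) == 0 && !allow_empty)
    stop("marker channel contains no events", call. = FALSE)
  labels <- as.integer(marker[rising])
  if (length(labels) && !all(labels %in% c(1, 2)))
    stop("marker values must encode classes 1 ('d') or 2 ('l')", call. = FALSE)
  eeg_recording(signals, fs = fs, onsets = rising, labels = labels)
}
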