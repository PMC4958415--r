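# MetaImage (.mha / .mhd) I/O.
#
# Minimal, self-contained implementation of the MetaIO image format used by
# ITK-family tools: an ASCII key = value header followed by raw binary voxel
# data, either appended to the same file (.mha, ElementDataFile = LOCAL) or
# in a sidecar .raw (.mhd). Constraints honoured here:
#   - TransformMatrix lists the direction cosines of each image axis
#     consecutively, i.e. the direction matrix in column-major order;
#   - voxel data are stored x-fastest, matching R's array layout;
#   - Offset is the world position of the first voxel *center*;
#   - only uncompressed data are supported (CompressedData = True errors).

mha_types <- list(
  MET_DOUBLE = list(what = "double", size = 8L, signed = TRUE),
  MET_FLOAT  = list(what = "double", size = 4L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE)
)

write_metaimage <- function(volume, path, datatype = "double") {
  dims <- dim(volume$data)
  local <- grepl("\\.mha$", tolower(path))
  elt <- if (datatype == "float") "MET_FLOAT" else "MET_DOUBLE"
  size <- if (datatype == "float") 4L else 8L
  datafile <- if (local) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                 ignore.case = TRUE), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =",
          paste(format(as.vector(volume$direction), digits = 17),
                collapse = " ")),
    paste("Offset =", paste(format(volume$origin, digits = 17),
                            collapse = " ")),
    paste("ElementSpacing =", paste(format(volume$spacing, digits = 17),
                                    collapse = " ")),
    paste("DimSize =", paste(dims, collapse = " ")),
    paste("ElementType =", elt),
    paste("ElementDataFile =", datafile)
  )
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop(sprintf("cannot write MetaImage to '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  on.exit(close(con), add = TRUE)
  writLines_ok <- tryCatch({
    writeLines(header, con)
    if (local)
      writeBin(as.numeric(volume$data), con, size = size, endian = "little")
    TRUE
  }, error = function(e) FALSE)
  if (!writLines_ok)
    stop(sprintf("failed to write MetaImage '%s'", path), call. = FALSE)
  if (!local) {
    rawpath <- file.path(dirname(path), datafile)
    rcon <- file(rawpath, "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(volume$data), rcon, size = size, endian = "little")
  }
  invisible(path)
}

parse_mha_header <- function(raw) {
  # header is ASCII up to (and including) the newline after ElementDataFile
  nl <- which(raw == as.raw(10L))
  header_end <- NA_integer_
  fields <- list()
  start <- 1L
  for (pos in nl) {
    line <- rawToChar(raw[start:(pos - 1L)])
    line <- sub("\r$", "", line)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[kv[2]]] <- trimws(kv[3])
    start <- pos + 1L
    if (length(kv) == 3L && kv[2] == "ElementDataFile") {
      header_end <- pos
      break
    }
  }
  if (is.na(header_end))
    stop("not a MetaImage file: missing ElementDataFile field", call. = FALSE)
  list(fields = fields, data_offset = header_end)
}

num_field <- function(fields, key, n, default = NULL) {
  if (is.null(fields[[key]])) {
    if (is.null(default))
      stop(sprintf("MetaImage header is missing required field '%s'", key),
           call. = FALSE)
    return(default)
  }
  vals <- suppressWarnings(as.numeric(strsplit(fields[[key]], "\\s+")[[1]]))
  if (length(vals) != n || any(!is.finite(vals)))
    stop(sprintf("MetaImage field '%s' is malformed", key), call. = FALSE)
  vals
}

read_metaimage <- function(path) {
  raw <- tryCatch(readBin(path, "raw", n = file.size(path)),
                  error = function(e)
                    stop(sprintf("cannot read MetaImage '%s'", path),
                         call. = FALSE))
  hdr <- tryCatch(parse_mha_header(raw), error = function(e)
    stop(sprintf("cannot parse MetaImage '%s': %s", path,
                 conditionMessage(e)), call. = FALSE))
  f <- hdr$fields
  if (!identical(f[["NDims"]], "3"))
    stop(sprintf("MetaImage '%s' is not 3D", path), call. = FALSE)
  if (identical(toupper(f[["CompressedData"]] %||% "FALSE"), "TRUE"))
    stop(sprintf("MetaImage '%s' uses compressed data (unsupported)", path),
         call. = FALSE)
  dims <- as.integer(num_field(f, "DimSize", 3L))
  spacing <- num_field(f, "ElementSpacing", 3L, default = c(1, 1, 1))
  origin <- num_field(f, "Offset", 3L, default = c(0, 0, 0))
  direction <- matrix(num_field(f, "TransformMatrix", 9L,
                                default = as.vector(diag(3))), 3L, 3L)
  type <- mha_types[[f[["ElementType"]] %||% ""]]
  if (is.null(type))
    stop(sprintf("MetaImage '%s': unsupported ElementType '%s'", path,
                 f[["ElementType"]] %||% "(missing)"), call. = FALSE)
  msb <- identical(toupper(f[["BinaryDataByteOrderMSB"]] %||% "FALSE"), "TRUE")
  n <- prod(dims)

  datafile <- f[["ElementDataFile"]]
  if (identical(toupper(datafile), "LOCAL")) {
    payload <- raw[(hdr$data_offset + 1L):length(raw)]
  } else {
    rawpath <- file.path(dirname(path), datafile)
    if (!file.exists(rawpath))
      stop(sprintf("MetaImage '%s': data file '%s' not found", path, rawpath),
           call. = FALSE)
    payload <- readBin(rawpath, "raw", n = file.size(rawpath))
  }
  if (length(payload) < n * type$size)
    stop(sprintf("MetaImage '%s' is truncated: expected %d data bytes, found %d",
                 path, n * type$size, length(payload)), call. = FALSE)
  vals <- readBin(payload, type$what, n = n, size = type$size,
                  signed = type$signed,
                  endian = if (msb) "big" else "little")
  check_direction(direction)
  voxel_volume(array(as.numeric(vals), dim = dims), spacing = spacing,
               origin = origin, direction = direction)
}
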