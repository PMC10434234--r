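# Minimal MATLAB level-5 (.mat v5) I/O for numeric arrays.
#
# Scope: named real numeric N-D arrays (double/single/ints), little- or
# big-endian files, zlib-compressed (miCOMPRESSED) elements. This covers the
# public SSVEP dataset layouts. The v7.3/HDF5 dialect is NOT supported.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_DOUBLE <- 6L

mi_numeric_info <- function(type) {
  switch(as.character(type),
    "1" = list(size = 1L, what = "integer", signed = TRUE),
    "2" = list(size = 1L, what = "integer", signed = FALSE),
    "3" = list(size = 2L, what = "integer", signed = TRUE),
    "4" = list(size = 2L, what = "integer", signed = FALSE),
    "5" = list(size = 4L, what = "integer", signed = TRUE),
    "6" = list(size = 4L, what = "integer", signed = FALSE),
    "7" = list(size = 4L, what = "double", signed = TRUE),
    "9" = list(size = 8L, what = "double", signed = TRUE),
    NULL)
}

#' Write numeric arrays to a MATLAB v5 file
#'
#' Writes each element of a named list as a real double-precision MATLAB
#' array. Used to build synthetic fixture files in the public datasets'
#' layouts and to export epoch tensors for MATLAB tooling.
#'
#' @param arrays named list of numeric vectors/matrices/arrays.
#' @param path output `.mat` path.
#' @return The path, invisibly.
#' @export
write_mat5 <- function(arrays, path) {
  if (is.null(names(arrays)) || any(names(arrays) == ""))
    stop("all arrays must be named")
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by ssvepuac on %s",
                  format(Sys.time(), "%Y-%m-%d"))
  hdr <- charToRaw(desc)
  length(hdr) <- 116L
  hdr[is.na(hdr)] <- as.raw(32L)
  writeBin(hdr, con)
  writeBin(raw(8L), con)                                    # subsys offset
  writeBin(c(as.raw(0L), as.raw(1L)), con)                  # version 0x0100 LE
  writeBin(charToRaw("IM"), con)                            # endian indicator
  for (nm in names(arrays)) writeBin(mat5_matrix_element(arrays[[nm]], nm), con)
  invisible(path)
}

pad8 <- function(r) c(r, raw((8L - length(r) %% 8L) %% 8L))

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")

mat5_sub <- function(type, data_raw) {
  c(u32(type), u32(length(data_raw)), pad8(data_raw))
}

mat5_matrix_element <- function(a, name) {
  dims <- dim(a)
  if (is.null(dims)) dims <- length(a)
  body <- c(
    mat5_sub(MI_UINT32, c(u32(MX_DOUBLE), u32(0L))),
    mat5_sub(MI_INT32, writeBin(as.integer(dims), raw(), size = 4L, endian = "little")),
    mat5_sub(MI_INT8, charToRaw(name)),
    mat5_sub(MI_DOUBLE, writeBin(as.double(a), raw(), size = 8L, endian = "little"))
  )
  c(u32(MI_MATRIX), u32(length(body)), body)
}

#' Read numeric arrays from a MATLAB v5 file
#'
#' Parses real numeric arrays (any integer/float storage type, including
#' zlib-compressed elements) into a named list of R arrays in MATLAB
#' column-major dimension order. Non-numeric elements (cells, structs,
#' strings) are skipped with a warning. MATLAB v7.3/HDF5 files are not
#' supported.
#'
#' @param path `.mat` file path.
#' @return Named list of numeric arrays.
#' @export
read_mat5 <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 128L) stop("not a MAT v5 file (too short): ", path)
  if (identical(rawToChar(raw_all[1:8]), "MATLAB 7")
      || grepl("^MATLAB 7\\.3", rawToChar(raw_all[1:19])))
    stop("MATLAB v7.3 (HDF5) files are not supported: ", path)
  endian_tag <- rawToChar(raw_all[127:128])
  endian <- if (endian_tag == "IM") "little" else if (endian_tag == "MI") "big"
            else stop("not a MAT v5 file (bad endian indicator): ", path)
  out <- list()
  pos <- 129L
  n <- length(raw_all)
  while (pos + 7L <= n) {
    tag <- parse_tag(raw_all, pos, endian)
    payload <- raw_all[tag$data_start:(tag$data_start + tag$nbytes - 1L)]
    if (tag$type == MI_COMPRESSED) {
      inner <- memDecompress(payload, type = "gzip")
      el <- parse_element(inner, 1L, endian)
      if (!is.null(el)) out[[el$name]] <- el$value
    } else if (tag$type == MI_MATRIX) {
      el <- parse_matrix(payload, endian)
      if (!is.null(el)) out[[el$name]] <- el$value
    }
    pos <- tag$next_pos
  }
  out
}

parse_tag <- function(r, pos, endian) {
  type <- readBin(r[pos:(pos + 3L)], "integer", size = 4L, endian = endian)
  small_len <- bitwAnd(bitwShiftR(type, 16L), 0xFFFFL)
  if (small_len > 0L) {                                    # small data element
    list(type = bitwAnd(type, 0xFFFFL), nbytes = small_len,
         data_start = pos + 4L, next_pos = pos + 8L)
  } else {
    nbytes <- readBin(r[(pos + 4L):(pos + 7L)], "integer", size = 4L, endian = endian)
    padded <- nbytes + (8L - nbytes %% 8L) %% 8L
    list(type = type, nbytes = nbytes,
         data_start = pos + 8L, next_pos = pos + 8L + padded)
  }
}

parse_element <- function(r, pos, endian) {
  tag <- parse_tag(r, pos, endian)
  if (tag$type != MI_MATRIX) return(NULL)
  parse_matrix(r[tag$data_start:(tag$data_start + tag$nbytes - 1L)], endian)
}

parse_matrix <- function(r, endian) {
  pos <- 1L
  flags_tag <- parse_tag(r, pos, endian)
  flags <- readBin(r[flags_tag$data_start:(flags_tag$data_start + 3L)],
                   "integer", size = 4L, endian = endian)
  mx_class <- bitwAnd(flags, 0xFFL)
  is_complex <- bitwAnd(bitwShiftR(flags, 11L), 1L) == 1L
  pos <- flags_tag$next_pos
  dims_tag <- parse_tag(r, pos, endian)
  dims <- readBin(r[dims_tag$data_start:(dims_tag$data_start + dims_tag$nbytes - 1L)],
                  "integer", size = 4L, n = dims_tag$nbytes %/% 4L, endian = endian)
  pos <- dims_tag$next_pos
  name_tag <- parse_tag(r, pos, endian)
  name <- if (name_tag$nbytes > 0L)
    rawToChar(r[name_tag$data_start:(name_tag$data_start + name_tag$nbytes - 1L)])
  else ""
  pos <- name_tag$next_pos
  if (!mx_class %in% 6:13) {
    warning(sprintf("skipping non-numeric MATLAB array '%s' (class %d)", name, mx_class))
    return(NULL)
  }
  data_tag <- parse_tag(r, pos, endian)
  info <- mi_numeric_info(data_tag$type)
  if (is.null(info))
    stop(sprintf("unsupported storage type %d in array '%s'", data_tag$type, name))
  nvals <- data_tag$nbytes %/% info$size
  vals <- readBin(r[data_tag$data_start:(data_tag$data_start + data_tag$nbytes - 1L)],
                  info$what, size = info$size, n = nvals,
                  signed = if (info$size < 4L) info$signed else TRUE, endian = endian)
  vals <- as.double(vals)
  if (is_complex) warning(sprintf("imaginary part of '%s' discarded", name))
  if (length(dims) > 1L) dim(vals) <- dims
  list(name = name, value = vals)
}
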