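#' Read a 2-D NPY array
#'
#' Minimal reader for the NPY serialization format (version 1.0), covering
#' the cases probability maps use: little-endian float32/float64 and
#' int8/uint8, 2-D shape, C or Fortran order. No installed R package reads
#' this format, so the header parsing is done here.
#'
#' @param path Path to a `.npy` file.
#' @return Numeric matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59))))
    stop("not an NPY file: bad magic", call. = FALSE)
  ver <- readBin(con, "raw", 2)
  hlen <- if (as.integer(ver[1]) >= 2) {
    readBin(con, "integer", 1, size = 4, endian = "little")
  } else {
    readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order'\\s*:\\s*True", header)
  shape_s <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  if (length(shape) != 2)
    stop("only 2-D NPY arrays are supported", call. = FALSE)
  n <- prod(shape)
  vals <- switch(descr,
    "<f4" = readBin(con, "numeric", n, size = 4, endian = "little"),
    "<f8" = readBin(con, "numeric", n, size = 8, endian = "little"),
    "|i1" = as.numeric(readBin(con, "integer", n, size = 1)),
    "|u1" = as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE)),
    stop(sprintf("unsupported NPY dtype '%s'", descr), call. = FALSE))
  if (fortran) matrix(vals, shape[1], shape[2])
  else t(matrix(vals, shape[2], shape[1]))
}

#' Write a matrix as a 2-D NPY array
#'
#' Writes NPY version 1.0, C-order, little-endian.
#'
#' @param x Numeric matrix.
#' @param path Output path.
#' @param dtype `"float32"` (default) or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_npy <- function(x, path, dtype = c("float32", "float64")) {
  dtype <- match.arg(dtype)
  stopifnot(is.matrix(x))
  descr <- if (dtype == "float32") "<f4" else "<f8"
  size <- if (dtype == "float32") 4L else 8L
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': (%d, %d), }",
                    descr, nrow(x), ncol(x))
  # total header block (magic 6 + version 2 + len 2 + text) padded to 64 bytes
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.vector(t(x)), con, size = size, endian = "little")
  invisible(path)
}
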