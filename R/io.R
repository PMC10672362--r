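#' Read and write tomogram images
#'
#' Supported formats, chosen by file extension:
#' \describe{
#'   \item{\code{.npy}}{2D float64 array of raw dB values; the lossless
#'     round-trip format. A JSON sidecar (\code{<path>.json}) carries pixel
#'     pitches and dynamic range.}
#'   \item{\code{.tiff} / \code{.tif}}{32-bit float samples. Values are
#'     affinely mapped to \code{[0, 1]} on write (libtiff clamps
#'     out-of-range float samples); the sidecar records the dB affine, so the
#'     round trip is exact to float32 quantization.}
#'   \item{\code{.png}}{8-bit grayscale after dynamic-range mapping; the
#'     sidecar records the affine. Round trip is exact to one quantization
#'     step.}
#' }
#' Reading a file without its sidecar fails for PNG/TIFF (the affine is
#' required); NPY falls back to unit pitches.
#'
#' @param path File path; the extension selects the format.
#' @return \code{read_image}: a [log_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  side <- read_sidecar(path)
  if (ext == "npy") {
    v <- read_npy_matrix(path)
    return(log_image(v,
                     pitch_z = side$pitch_z %||% 1,
                     pitch_x = side$pitch_x %||% 1,
                     dynamic_range = side$dynamic_range %||% NULL))
  }
  if (ext %in% c("tif", "tiff", "png")) {
    if (is.null(side$lo) || is.null(side$hi)) {
      stop("missing or incomplete sidecar (", path, ".json): cannot restore dB affine")
    }
    v01 <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
    if (length(dim(v01)) == 3L) v01 <- v01[, , 1L]
    v <- side$lo + v01 * (side$hi - side$lo)
    return(log_image(v, pitch_z = side$pitch_z %||% 1,
                     pitch_x = side$pitch_x %||% 1,
                     dynamic_range = side$dynamic_range %||% NULL))
  }
  stop("unknown image format: .", ext, " (use .npy, .tiff or .png)")
}

#' @param image A [log_image()] to write.
#' @rdname read_image
#' @return \code{write_image}: \code{path}, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "log_image"))
  ext <- tolower(tools::file_ext(path))
  v <- image$values
  if (ext == "npy") {
    write_npy_matrix(v, path)
    write_sidecar(image, path, lo = NULL, hi = NULL)
    return(invisible(path))
  }
  lo <- min(v); hi <- max(v)
  if (hi <= lo) hi <- lo + 1
  v01 <- (v - lo) / (hi - lo)
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(v01, path, bits.per.sample = 32L)
  } else if (ext == "png") {
    png::writePNG(v01, path)
  } else {
    stop("unknown image format: .", ext, " (use .npy, .tiff or .png)")
  }
  write_sidecar(image, path, lo = lo, hi = hi)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_sidecar <- function(image, path, lo, hi) {
  meta <- list(pitch_z = image$pitch_z, pitch_x = image$pitch_x,
               dynamic_range = image$dynamic_range,
               shape = dim(image$values))
  if (!is.null(lo)) { meta$lo <- lo; meta$hi <- hi }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}

read_sidecar <- function(path) {
  sc <- paste0(path, ".json")
  if (!file.exists(sc)) return(list())
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

# ---- minimal NPY (version 1.0) reader/writer for 2D float arrays ----------
# The NPY format is a 6-byte magic, version, little-endian header length,
# a Python-dict header (descr/fortran_order/shape) padded to 64 bytes, then
# raw array data. Only 2D '<f8'/'<f4' arrays are handled here.

write_npy_matrix <- function(m, path) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  header <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': (%d, %d), }",
                    nrow(m), ncol(m))
  total <- 10L + nchar(header) + 1L           # magic(6)+ver(2)+len(2)+hdr+\n
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(m), con, size = 8L, endian = "little")
  invisible(path)
}

read_npy_matrix <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, c(as.raw(0x93), charToRaw("NUMPY")))) {
    stop("not an NPY file: ", path)
  }
  ver <- readBin(con, "raw", 2L)
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  shape <- shape[!is.na(shape)]
  if (length(shape) != 2L) {
    stop(sprintf("expected a 2D NPY array, got %d dimension(s)", length(shape)))
  }
  n <- prod(shape)
  vals <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    stop("unsupported NPY dtype: ", descr, " (only <f8 and <f4)"))
  if (length(vals) != n) stop("truncated NPY payload")
  if (fortran) matrix(vals, shape[1], shape[2])
  else t(matrix(vals, shape[2], shape[1]))
}
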