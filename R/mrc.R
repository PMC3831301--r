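## Minimal MRC2014 single-image reader/writer.
##
## Only what a diffraction camera produces is supported: 2D images in mode 1
## (int16), mode 2 (float32) or mode 6 (uint16), little-endian, no extended
## header on write (extended headers are skipped on read). Pixels are stored
## x-fastest as the standard requires; in R the image is a matrix indexed
## [y + 1, x + 1] (row = y = slow axis, col = x = fast axis, 0-based detector
## coordinates elsewhere in the package).

MRC_HEADER_BYTES <- 1024L

#' Read a 2D MRC image
#'
#' @param path file path of an MRC2014 image (modes 1, 2 or 6; nz must be 1).
#' @return numeric matrix with `ny` rows and `nx` columns; pixel (x, y) of the
#'   detector is `m[y + 1, x + 1]`.
#' @seealso [write_mrc()]
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  if (nx <= 0 || ny <= 0 || nz != 1)
    stop("unsupported MRC geometry: nx=", nx, " ny=", ny, " nz=", nz)
  seek(con, 92)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  seek(con, MRC_HEADER_BYTES + nsymbt)
  n <- nx * ny
  v <- switch(as.character(mode),
    "1" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             signed = TRUE, endian = "little")),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n, size = 2,
                             signed = FALSE, endian = "little")),
    stop("unsupported MRC mode: ", mode))
  if (length(v) != n) stop("truncated MRC data in ", path)
  ## stored x-fastest -> fill a nx x ny matrix then transpose to [y, x]
  t(matrix(v, nrow = nx, ncol = ny))
}

#' Write a 2D MRC image
#'
#' @param img numeric matrix, `m[y + 1, x + 1]` indexing.
#' @param path output file path.
#' @param mode 2 (float32, default) or 6 (uint16; values are rounded and must
#'   lie in 0..65535).
#' @export
write_mrc <- function(img, path, mode = 2L) {
  stopifnot(is.matrix(img), mode %in% c(2L, 6L))
  nx <- ncol(img); ny <- nrow(img)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, 1L, mode))          # nx ny nz mode
  wi(c(0L, 0L, 0L))                # nxstart nystart nzstart
  wi(c(nx, ny, 1L))                # mx my mz
  wf(c(nx, ny, 1, 90, 90, 90))     # cella, cellb
  wi(c(1L, 2L, 3L))                # mapc mapr maps
  wf(c(min(img), max(img), mean(img)))  # dmin dmax dmean
  wi(c(0L, 0L))                    # ispg nsymbt
  writeBin(raw(100), con)          # extra
  wf(c(0, 0, 0))                   # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(as.numeric(img)))   # rms
  wi(1L)                           # nlabl
  lab <- sprintf("%-80s", "red3d simulated ED frame")
  writeChar(lab, con, 80, eos = NULL)
  writeBin(raw(9 * 80), con)
  v <- as.numeric(t(img))          # x-fastest order
  if (mode == 2L) {
    writeBin(v, con, size = 4, endian = "little")
  } else {
    iv <- as.integer(round(v))
    if (any(iv < 0L) || any(iv > 65535L))
      stop("uint16 MRC: values outside 0..65535")
    iv[iv > 32767L] <- iv[iv > 32767L] - 65536L   # reinterpret as signed
    writeBin(iv, con, size = 2, endian = "little")
  }
  invisible(path)
}
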