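# Image input/output. PNG and TIFF go through the png and tiff packages;
# uncompressed 24-bit Windows bitmaps (the native capture format of many
# microscope cameras) are read and written directly, since no installed
# package handles BMP.

#' Read an RGB image
#'
#' Dispatches on the file extension: `.png`, `.tif`/`.tiff` or `.bmp`.
#' Grayscale input is replicated to three channels; an alpha channel is
#' dropped.
#'
#' @param path image file.
#' @return numeric array `h x w x 3` with values in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    bmp = read_bmp(path),
    stopf("unsupported image format '.%s' (use png, tiff or bmp)", ext))
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a binary mask as PNG
#'
#' @param mask logical matrix; written as an 8-bit grayscale PNG with
#'   foreground white.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Read a binary mask from a grayscale PNG
#'
#' @param path file written by [write_mask()] (any pixel > 0.5 is
#'   foreground).
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (!is.matrix(img)) img <- img[, , 1]
  img > 0.5
}

# ---- minimal BMP codec (24-bit uncompressed BI_RGB) -----------------------

read_u <- function(con, n) {
  b <- readBin(con, "integer", n = n, size = 1, signed = FALSE)
  sum(b * 256^(seq_len(n) - 1))
}

read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(as.integer(magic), c(0x42L, 0x4DL)))
    stopf("%s is not a BMP file", path)
  invisible(read_u(con, 4)); invisible(read_u(con, 4))
  offset <- read_u(con, 4)
  hdr_size <- read_u(con, 4)
  if (hdr_size < 40) stopf("unsupported BMP header")
  width <- read_u(con, 4)
  height <- read_u(con, 4)   # positive height = bottom-up rows
  invisible(read_u(con, 2))
  bpp <- read_u(con, 2)
  compression <- read_u(con, 4)
  if (bpp != 24 || compression != 0)
    stopf("only uncompressed 24-bit BMP is supported (got %d bpp)", bpp)
  seek(con, offset)
  row_bytes <- ((width * 3 + 3) %/% 4) * 4
  raw <- readBin(con, "raw", row_bytes * height)
  px <- as.integer(raw)
  img <- array(0, dim = c(height, width, 3))
  for (r in seq_len(height)) {
    row0 <- (r - 1) * row_bytes
    cols <- seq_len(width)
    b <- px[row0 + (cols - 1) * 3 + 1]
    g <- px[row0 + (cols - 1) * 3 + 2]
    rr <- px[row0 + (cols - 1) * 3 + 3]
    img[height - r + 1, , 1] <- rr / 255   # rows are stored bottom-up
    img[height - r + 1, , 2] <- g / 255
    img[height - r + 1, , 3] <- b / 255
  }
  img
}

write_bmp <- function(img, path) {
  check_rgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  row_bytes <- ((w * 3 + 3) %/% 4) * 4
  data_size <- row_bytes * h
  u <- function(x, n) as.raw((x %/% 256^(seq_len(n) - 1)) %% 256)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x42, 0x4D)), con)
  writeBin(u(54 + data_size, 4), con)       # file size
  writeBin(u(0, 4), con)                    # reserved
  writeBin(u(54, 4), con)                   # pixel-data offset
  writeBin(u(40, 4), con)                   # BITMAPINFOHEADER
  writeBin(u(w, 4), con); writeBin(u(h, 4), con)
  writeBin(u(1, 2), con); writeBin(u(24, 2), con)
  writeBin(u(0, 4), con)                    # BI_RGB
  writeBin(u(data_size, 4), con)
  writeBin(u(2835, 4), con); writeBin(u(2835, 4), con)  # 72 dpi
  writeBin(u(0, 4), con); writeBin(u(0, 4), con)
  bytes <- raw(data_size)
  q <- function(v) as.integer(round(pmin(pmax(v, 0), 1) * 255))
  for (r in seq_len(h)) {
    src <- h - r + 1                        # bottom-up storage
    row0 <- (r - 1) * row_bytes
    cols <- seq_len(w)
    bytes[row0 + (cols - 1) * 3 + 1] <- as.raw(q(img[src, , 3]))
    bytes[row0 + (cols - 1) * 3 + 2] <- as.raw(q(img[src, , 2]))
    bytes[row0 + (cols - 1) * 3 + 3] <- as.raw(q(img[src, , 1]))
  }
  writeBin(bytes, con)
  invisible(path)
}
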