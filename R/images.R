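# Raster image decoding for document backgrounds.
#
# PNG, JPEG and TIFF go through their dedicated readers. BMP is decoded by
# a minimal built-in reader (uncompressed 24/32-bit, the common export
# flavour of schematic drawings); GIF, WMF and SVG backgrounds are not
# supported.

decode_image_bytes <- function(bytes, format) {
  format <- tolower(format)
  switch(format,
    png = png::readPNG(bytes),
    jpeg = ,
    jpg = jpeg::readJPEG(bytes),
    tiff = ,
    tif = tiff::readTIFF(bytes),
    bmp = read_bmp_bytes(bytes),
    stop("unsupported background image format '", format, "'")
  )
}

image_format_from_name <- function(filename) {
  ext <- tolower(tools::file_ext(filename))
  if (!ext %in% c("png", "jpeg", "jpg", "tiff", "tif", "bmp")) {
    stop("unsupported background image format '.", ext, "'")
  }
  ext
}

# Uncompressed 24/32-bit BMP (BITMAPINFOHEADER), bottom-up or top-down.
read_bmp_bytes <- function(bytes) {
  u16 <- function(i) sum(as.integer(bytes[i + 0:1]) * c(1, 256))
  u32 <- function(i) sum(as.numeric(bytes[i + 0:3]) * 256^(0:3))
  i32 <- function(i) {
    v <- u32(i)
    if (v >= 2^31) v - 2^32 else v
  }
  if (rawToChar(bytes[1:2]) != "BM") stop("not a BMP stream")
  offset <- u32(11)
  width <- i32(19)
  height <- i32(23)
  bpp <- u16(29)
  compression <- u32(31)
  if (compression != 0) stop("compressed BMP not supported")
  if (!bpp %in% c(24, 32)) stop("only 24/32-bit BMP supported")
  topdown <- height < 0
  height <- abs(height)
  nch <- bpp / 8
  stride <- 4 * ceiling(width * nch / 4)
  out <- array(0, dim = c(height, width, 3))
  for (row in seq_len(height)) {
    src_row <- if (topdown) row else height - row + 1
    base <- offset + (src_row - 1) * stride
    px <- as.integer(bytes[base + seq_len(width * nch)])
    px <- matrix(px, nrow = nch)
    # BMP stores B, G, R [, A]
    out[row, , 1] <- px[3, ] / 255
    out[row, , 2] <- px[2, ] / 255
    out[row, , 3] <- px[1, ] / 255
  }
  out
}

# Nearest-neighbour resize; adequate for schematic backgrounds.
resize_nearest <- function(img, width, height) {
  d <- dim(img)
  if (d[1] == height && d[2] == width) return(img)
  ry <- pmin(d[1], floor((seq_len(height) - 0.5) * d[1] / height) + 1)
  rx <- pmin(d[2], floor((seq_len(width) - 0.5) * d[2] / width) + 1)
  if (length(d) == 2) img[ry, rx, drop = FALSE] else img[ry, rx, , drop = FALSE]
}
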