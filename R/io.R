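## Image input/output. PNG and TIFF go through the png and tiff packages;
## portable greymap (PGM, both ASCII P2 and binary P5) is parsed here.
## Colour inputs are reduced to grey with the standard Rec.601 luminance
## weights before anything else happens.

.luminance <- c(0.299, 0.587, 0.114)

.flattenColour <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  if (length(dim(a)) == 3L) {
    ch <- min(dim(a)[3], 3L)
    if (ch == 1L) return(a[, , 1L])
    w <- .luminance[seq_len(ch)] / sum(.luminance[seq_len(ch)])
    out <- matrix(0, dim(a)[1], dim(a)[2])
    for (k in seq_len(ch)) out <- out + w[k] * a[, , k]
    return(out)
  }
  stop("unsupported image array layout")
}

.readPGM <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  isSpace <- function(b) b %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d, 0x0c, 0x0b))
  pos <- 1L
  nextToken <- function() {
    repeat {
      while (pos <= length(raw) && isSpace(raw[pos])) pos <<- pos + 1L
      if (pos <= length(raw) && raw[pos] == as.raw(0x23)) {  # '#' comment
        while (pos <= length(raw) && raw[pos] != as.raw(0x0a)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= length(raw) && !isSpace(raw[pos])) pos <<- pos + 1L
    rawToChar(raw[start:(pos - 1L)])
  }
  magic <- nextToken()
  if (!magic %in% c("P2", "P5")) stop("not a PGM file (expected P2 or P5)")
  w <- as.integer(nextToken())
  h <- as.integer(nextToken())
  maxval <- as.integer(nextToken())
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval <= 0 || maxval > 255)
    stop("malformed PGM header (8-bit greymaps only)")
  if (magic == "P2") {
    txt <- rawToChar(raw[pos:length(raw)])
    vals <- as.integer(strsplit(trimws(txt), "\\s+")[[1]])
  } else {
    pos <- pos + 1L  # single whitespace after maxval
    vals <- as.integer(raw[pos:(pos + w * h - 1L)])
  }
  if (length(vals) < w * h) stop("truncated PGM pixel data")
  matrix(vals[seq_len(w * h)] * (255 / maxval), h, w, byrow = TRUE)
}

.writePGM <- function(img, path, ascii = TRUE) {
  img <- round(img)
  h <- nrow(img); w <- ncol(img)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(w, h), "255"), con)
    write(t(img), con, ncolumns = min(w, 16L))
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(as.vector(t(img))), con)
  }
  invisible(path)
}

#' Read a greyscale image
#'
#' Reads PNG, PGM (P2/P5) or TIFF by file extension. Colour images are
#' converted to grey with Rec.601 luminance weights (0.299 R + 0.587 G +
#' 0.114 B); an alpha channel is ignored.
#'
#' @param path file path ending in .png, .pgm, .tif or .tiff.
#' @return a [GreyImage-class].
#' @export
readGreyImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = .flattenColour(png::readPNG(path)) * 255,
    pgm = .readPGM(path),
    tif = ,
    tiff = .flattenColour(tiff::readTIFF(path)) * 255,
    stop("unsupported image format: .", ext, " (use PNG, PGM or TIFF)"))
  greyImage(clampGrey(img))
}

#' Write a greyscale image
#'
#' Format is chosen by extension: PNG, PGM (ASCII P2 by default) or TIFF.
#'
#' @param image a [GreyImage-class] or numeric matrix.
#' @param path destination path.
#' @param ascii for PGM output, write ASCII P2 (default) or binary P5.
#' @return the path, invisibly.
#' @export
writeGreyImage <- function(image, path, ascii = TRUE) {
  img <- .asGreyMatrix(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img / 255, path),
    pgm = .writePGM(img, path, ascii = ascii),
    tif = ,
    tiff = tiff::writeTIFF(img / 255, path),
    stop("unsupported image format: .", ext, " (use PNG, PGM or TIFF)"))
  invisible(path)
}

#' Write an edge map as a bilevel image
#'
#' Edge pixels are written white (255) on black (0).
#'
#' @param map an [EdgeMap-class] or logical matrix.
#' @param path destination path (.png or .pgm or .tiff).
#' @return the path, invisibly.
#' @export
writeEdgeMap <- function(map, path) {
  writeGreyImage(greyImage(.asEdgeMatrix(map)), path)
}

#' Read a bilevel image back into an edge map
#'
#' @param path image path.
#' @param cut grey level at or above which a pixel counts as an edge.
#' @return an [EdgeMap-class].
#' @export
readEdgeMap <- function(path, cut = 128) {
  edgeMap(readGreyImage(path)@.Data >= cut)
}
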