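#' Construct a SlideRaster from a pixel array
#'
#' @param pixels numeric array height x width x 3, values in [0, 1] (a
#'   height x width matrix is replicated across channels).
#' @param slideId slide identifier.
#' @param source free-form tag for provenance.
#' @return a \linkS4class{SlideRaster}.
#' @export
SlideRaster <- function(pixels, slideId, source = "memory") {
  if (is.matrix(pixels))
    pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  new("SlideRaster", slideId = as.character(slideId),
      pixels = pixels, source = source)
}

#' Read a slide image file into a SlideRaster
#'
#' Supports plain PNG and (tiled or striped) TIFF. Grayscale images are
#' expanded to RGB; an alpha channel, if present, is dropped. The full level-0
#' raster is loaded into memory -- appropriate for the desk-scale slides this
#' package targets.
#'
#' @param path path to a .png, .tif or .tiff file.
#' @param slideId identifier; defaults to the file name without extension.
#' @return a \linkS4class{SlideRaster}.
#' @export
readSlide <- function(path, slideId = NULL) {
  if (!file.exists(path)) stop("slide file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported slide format: .", ext, " (expected png/tif/tiff)"))
  if (is.matrix(px)) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  if (is.null(slideId)) slideId <- tools::file_path_sans_ext(basename(path))
  SlideRaster(px, slideId, source = ext)
}

#' Write a SlideRaster to disk
#'
#' @param raster a \linkS4class{SlideRaster}.
#' @param path output path; format chosen by extension (.png or .tif/.tiff).
#' @return the path, invisibly.
#' @export
writeSlide <- function(raster, path) {
  ext <- tolower(tools::file_ext(path))
  px <- raster@pixels
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, compression = "LZW"),
    stop("unsupported slide format: .", ext))
  invisible(path)
}

#' Reduced-magnification thumbnail of a slide
#'
#' @param raster a \linkS4class{SlideRaster}.
#' @param scale linear downscale factor relative to the stored raster
#'   (default 0.5, the single-magnification review thumbnail).
#' @return numeric array of the resized image.
#' @export
slideThumbnail <- function(raster, scale = 0.5) {
  stopifnot(scale > 0, scale <= 1)
  h <- max(1L, round(slideHeight(raster) * scale))
  as.array(EBImage::resize(EBImage::Image(aperm(raster@pixels, c(2, 1, 3)),
                                          colormode = "Color"),
                           w = max(1L, round(slideWidth(raster) * scale)),
                           h = h)) |> aperm(c(2, 1, 3))
}
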