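#' Phase labels
#'
#' The closed set of cell cycle phase labels the pipeline discriminates:
#' G (G1/G2, homogeneous PCNA), early S (many small uniform foci), mid S
#' (peripheral foci) and late S (few large central foci).
#'
#' @return character vector of the four canonical labels, in fixed order.
#' @export
phase_levels <- function() c("G", "EARLY_S", "MID_S", "LATE_S")

#' Parse phase label strings
#'
#' Case-insensitive parsing into the closed phase enumeration; `"early s"`,
#' `"early-s"` and `"EARLY_S"` are all accepted.
#'
#' @param x character vector of labels.
#' @return factor with levels [phase_levels()].
#' @export
parse_phase <- function(x) {
  canon <- toupper(gsub("[ -]", "_", trimws(as.character(x))))
  bad <- which(!canon %in% phase_levels())
  if (length(bad))
    stop("unknown phase label ", sQuote(x[bad[1]]), " at row ", bad[1],
         "; expected one of ", paste(phase_levels(), collapse = ", "))
  factor(canon, levels = phase_levels())
}

#' Intensity image container
#'
#' A single-channel raster of non-negative finite intensities. Pixels are
#' stored as a numeric matrix indexed `[y + 1, x + 1]` under the package's
#' `(x, y) = (column, row)`, 0-based convention.
#'
#' @param pixels numeric matrix, at least 2x2, finite, non-negative.
#' @param id identifier string carried through logs and outputs.
#' @param bit_depth_hint `8`, `16` or `"float"`; advisory only.
#' @return object of class `pcna_image`.
#' @export
pcna_image <- function(pixels, id = "image", bit_depth_hint = "float") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2x2 pixels")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("image intensities must be finite and non-negative")
  structure(list(pixels = pixels, id = id, bit_depth_hint = bit_depth_hint),
            class = "pcna_image")
}

#' @export
print.pcna_image <- function(x, ...) {
  cat(sprintf("pcna_image '%s': %d x %d (w x h), range [%g, %g], depth hint %s\n",
              x$id, ncol(x$pixels), nrow(x$pixels),
              min(x$pixels), max(x$pixels), x$bit_depth_hint))
  invisible(x)
}

as_pixel_matrix <- function(image) {
  if (inherits(image, "pcna_image")) image$pixels else {
    m <- as.matrix(image)
    storage.mode(m) <- "double"
    m
  }
}

#' Read a single-channel image
#'
#' Reads a grayscale TIFF (8/16-bit or float) or PNG, preserving the original
#' dynamic range: integer TIFFs come back on their native integer scale
#' (0..255 or 0..65535), not rescaled to `[0, 1]`. Multi-channel images are
#' rejected; users convert proprietary stacks to single-plane TIFF first.
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param id image identifier; defaults to the file name.
#' @return a [pcna_image()].
#' @export
read_image <- function(path, id = basename(path)) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3L) stop("single channel required: ", path)
    # png values are scaled to [0,1]; restore the 8-bit integer scale
    return(pcna_image(round(px * 255), id = id, bit_depth_hint = 8))
  }
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("unsupported image format (want .tif/.tiff/.png): ", path)
  px <- tiff::readTIFF(path, as.is = TRUE, all = FALSE)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] != 1L) stop("single channel required: ", path)
    px <- px[, , 1]
  }
  hint <- if (is.integer(px)) (if (max(px) > 255) 16 else 8) else "float"
  pcna_image(px, id = id, bit_depth_hint = hint)
}

#' Write a single-channel image
#'
#' Integer data are written as 8- or 16-bit grayscale TIFF so that a
#' [read_image()] round trip is pixel-identical; other data are written as
#' 32-bit float TIFF.
#'
#' @param image a [pcna_image()] or numeric/integer matrix.
#' @param path output path (`.tif`).
#' @param bits 8, 16 or `"float"`; default chooses from the data.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = NULL) {
  px <- as_pixel_matrix(image)
  if (is.null(bits)) {
    bits <- if (all(px == round(px))) (if (max(px) > 255) 16 else 8) else "float"
  }
  if (identical(bits, "float")) {
    tiff::writeTIFF(px, path, bits.per.sample = 32L)
  } else {
    scale <- 2^bits - 1
    if (max(px) > scale) stop("image exceeds ", bits, "-bit range")
    tiff::writeTIFF(px / scale, path, bits.per.sample = as.integer(bits))
  }
  invisible(path)
}

#' Read point annotations
#'
#' Reads a comma-separated annotation table with mandatory header columns
#' `x,y,label`: one annotated nucleus per row, `(x, y)` the 0-based pixel
#' position of the annotation point and `label` its phase, parsed
#' case-insensitively into the closed phase set. When an image is supplied
#' the coordinates are validated against its bounds.
#'
#' @param path CSV file path.
#' @param image optional [pcna_image()] (or matrix) for bounds checking.
#' @return data.frame with columns `x`, `y` (numeric) and `label` (factor
#'   with levels [phase_levels()]); zero rows for a header-only file.
#' @export
read_annotations <- function(path, image = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "label")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have header columns x,y,label")
  if (nrow(df) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0),
                      label = factor(character(0), levels = phase_levels())))
  ann <- data.frame(x = as.numeric(df$x), y = as.numeric(df$y),
                    label = parse_phase(df$label))
  if (anyNA(ann$x) || anyNA(ann$y))
    stop("annotation coordinates must be numeric")
  if (!is.null(image)) {
    px <- as_pixel_matrix(image)
    out <- which(ann$x < 0 | ann$x > ncol(px) - 1 |
                 ann$y < 0 | ann$y > nrow(px) - 1)
    if (length(out))
      stop("annotation out of image bounds at row ", out[1],
           ": (", ann$x[out[1]], ", ", ann$y[out[1]], ")")
  }
  ann
}

#' Write point annotations
#'
#' @param annotations data.frame with columns `x`, `y`, `label`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations[, c("x", "y", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write label masks
#'
#' Label masks (0 = background, 1..K = objects) are stored as 16-bit TIFF.
#'
#' @param path TIFF path.
#' @return integer matrix label mask.
#' @export
read_labels <- function(path) {
  m <- as_pixel_matrix(read_image(path))
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_labels
#' @param labels integer matrix label mask.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels cannot be written")
  write_image(labels, path, bits = 16)
}
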