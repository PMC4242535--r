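#' Gray-level image with a field-of-view mask
#'
#' A `gray_image` holds an 8-bit gray raster (usually the blue color plane of
#' a hemispherical canopy photograph) together with a logical mask marking the
#' pixels that belong to the analyzed circular fisheye area. Gray values are
#' integers in \[0, 255\]; the mask has the same dimensions as the values.
#'
#' Matrices are stored row = image row (y), column = image column (x).
#' All user-facing pixel coordinates are 0-based with origin at the top-left
#' corner, `x` running along columns and `y` along rows.
#'
#' @param values Integer matrix of gray values in \[0, 255\].
#' @param mask Optional logical matrix of the same dimensions; `TRUE` marks
#'   pixels inside the analyzed area. Defaults to all-`TRUE`.
#' @return An object of class `gray_image` with elements `values` and `mask`.
#' @export
gray_image <- function(values, mask = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "integer"
  if (anyNA(values) || any(values < 0L) || any(values > 255L)) {
    stop("gray values must be integers in [0, 255]")
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(values), ncol(values))
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(values))) {
    stop("`mask` must be a logical matrix with the same dimensions as `values`")
  }
  if (!any(mask)) stop("mask excludes every pixel")
  structure(list(values = values, mask = mask), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d pixels, %d inside mask, gray range [%d, %d]\n",
    ncol(x$values), nrow(x$values), sum(x$mask),
    min(x$values[x$mask]), max(x$values[x$mask])
  ))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$values)

#' Read a raster image as a gray plane
#'
#' Reads an 8-bit PNG, TIFF or JPEG raster and returns either its blue color
#' plane (the conventional input for canopy binarization, because leaves
#' scatter little blue light and the vegetation/sky contrast is maximal
#' there) or a single gray channel. The mask is initialized all-`TRUE`;
#' restrict it afterwards with [circular_mask()] if only the fisheye disc
#' should be analyzed.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @param channel `"blue"` (requires >= 3 channels) or `"gray"` (single-channel
#'   input passed through; multi-channel input converted by averaging).
#' @return A [gray_image()].
#' @export
read_canopy_image <- function(path, channel = c("blue", "gray")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, " (expected png/tiff/jpeg)")
  )
  # readers return values in [0,1]; recover 8-bit levels
  to8 <- function(m) {
    v <- round(m * 255)
    storage.mode(v) <- "integer"
    v
  }
  if (length(dim(arr)) == 2L) {
    if (channel == "blue") stop("no blue plane: image has a single channel")
    return(gray_image(to8(arr)))
  }
  nch <- dim(arr)[3]
  if (channel == "blue") {
    if (nch < 3L) stop("no blue plane: image has ", nch, " channel(s)")
    return(gray_image(to8(arr[, , 3L])))
  }
  # gray from multi-channel: plain mean over color channels (alpha dropped)
  ncol_use <- min(nch, 3L)
  g <- arr[, , 1L]
  if (ncol_use > 1L) for (k in 2:ncol_use) g <- g + arr[, , k]
  gray_image(to8(g / ncol_use))
}

#' Restrict the analysis mask to a circular fisheye area
#'
#' Sets the mask `TRUE` exactly where \eqn{(px-x)^2 + (py-y)^2 \le r^2},
#' using 0-based pixel-center coordinates. Gray values are unchanged.
#'
#' @param image A [gray_image()].
#' @param center Numeric length-2 vector `(x, y)`, 0-based.
#' @param radius Circle radius in pixels (> 0).
#' @return The image with its mask restricted to the disc.
#' @export
circular_mask <- function(image, center, radius) {
  stopifnot(inherits(image, "gray_image"), length(center) == 2L)
  if (radius <= 0) stop("radius must be > 0")
  h <- nrow(image$values); w <- ncol(image$values)
  px <- matrix(rep(0:(w - 1L), each = h), h, w)   # x = column index
  py <- matrix(rep(0:(h - 1L), times = w), h, w)  # y = row index
  inside <- (px - center[1])^2 + (py - center[2])^2 <= radius^2
  if (!any(inside)) stop("circle lies fully outside the image (empty mask)")
  image$mask <- inside
  image
}

#' 256-bin gray-value histogram over the analyzed area
#'
#' Counts the mask-true pixels at each gray value 0..255. Pixels outside
#' the mask never enter the histogram, so histogram-based thresholds are
#' computed over the hemisphere only.
#'
#' @param image A [gray_image()].
#' @return An object of class `gray_histogram`: integer vector of length 256
#'   (named "0".."255") with attribute `total`, the mask-true pixel count.
#' @export
gray_histogram <- function(image) {
  stopifnot(inherits(image, "gray_image"))
  counts <- tabulate(image$values[image$mask] + 1L, nbins = 256L)
  as_gray_histogram(counts)
}

#' Construct a gray histogram from raw counts
#'
#' @param counts Non-negative integer vector of length 256 (counts for gray
#'   values 0..255).
#' @return A `gray_histogram`.
#' @export
as_gray_histogram <- function(counts) {
  if (inherits(counts, "gray_histogram")) return(counts)
  if (length(counts) != 256L) stop("histogram must have exactly 256 bins")
  counts <- as.integer(counts)
  if (anyNA(counts) || any(counts < 0L)) stop("counts must be non-negative integers")
  total <- sum(counts)
  if (total <= 0L) stop("histogram is empty")
  structure(counts, names = 0:255, total = total, class = "gray_histogram")
}

#' @export
print.gray_histogram <- function(x, ...) {
  nz <- which(unclass(x) > 0L) - 1L
  cat(sprintf(
    "<gray_histogram> %d pixels, %d occupied gray values in [%d, %d]\n",
    attr(x, "total"), length(nz), min(nz), max(nz)
  ))
  invisible(x)
}

#' Export a histogram as a two-column data frame
#'
#' @param hist A `gray_histogram`.
#' @return `data.frame(gray_value, count)` with 256 rows, suitable for
#'   `write.csv`.
#' @export
histogram_table <- function(hist) {
  hist <- as_gray_histogram(hist)
  data.frame(gray_value = 0:255, count = as.integer(hist))
}

# file codes for binary masks: vegetation 0, sky 255, outside 128
.binary_file_codes <- c(vegetation = 0L, sky = 255L, outside = 128L)

#' Write a binary vegetation/sky map to a PNG file
#'
#' Pixels are written vegetation = 0, sky = 255 and outside-mask = 128; the
#' convention is also recorded in a small JSON sidecar (`<path>.json`) so
#' files remain self-describing. The round trip through
#' [read_binary_map()] is lossless.
#'
#' @param binary A [binary_map()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_binary_map <- function(binary, path) {
  stopifnot(inherits(binary, "binary_map"))
  codes <- .binary_file_codes[unclass(binary)]
  img <- matrix(codes / 255, nrow(binary), ncol(binary))
  png::writePNG(img, target = path)
  sidecar <- list(
    format = "hemibin binary map",
    coding = list(vegetation = 0L, sky = 255L, outside = 128L)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a binary vegetation/sky map written by [write_binary_map()]
#'
#' @param path PNG path using the 0/128/255 coding.
#' @return A [binary_map()].
#' @export
read_binary_map <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  codes <- round(arr * 255)
  cls <- matrix(NA_integer_, nrow(codes), ncol(codes))
  cls[codes == 0] <- 1L
  cls[codes == 255] <- 2L
  cls[codes == 128] <- 3L
  if (anyNA(cls)) stop("file is not a vegetation/sky map (unexpected gray levels)")
  new_binary_map(cls)
}
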