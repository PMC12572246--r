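#' 2D MPOD map
#'
#' Wraps a 2D array of MPOD values together with the sub-pixel foveolar
#' centre and the angular scale, as needed for circular-path profile
#' extraction. Pixel coordinates are R-native 1-based (row, col); the centre
#' may be fractional.
#'
#' @param pixels numeric matrix of MPOD values (a.u.).
#' @param center numeric length 2, (row, col) of the foveolar centre,
#'   inside the image bounds.
#' @param scale degrees of visual angle per pixel, > 0.
#' @return An object of class `mpod_map`.
#' @export
mpod_map <- function(pixels, center, scale) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || any(!is.finite(pixels)))
    stop("'pixels' must be a finite numeric matrix", call. = FALSE)
  if (length(center) != 2L || anyNA(center))
    stop("'center' must be (row, col)", call. = FALSE)
  if (center[1] < 1 || center[1] > nrow(pixels) ||
      center[2] < 1 || center[2] > ncol(pixels))
    stop("'center' lies outside the image", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("'scale' (degrees per pixel) must be a positive number",
         call. = FALSE)
  structure(list(pixels = pixels, center = as.numeric(center),
                 scale = as.numeric(scale)), class = "mpod_map")
}

#' @export
print.mpod_map <- function(x, ...) {
  cat("MPOD map:", nrow(x$pixels), "x", ncol(x$pixels), "px,",
      x$scale, "deg/px, centre (", x$center[1], ",", x$center[2], ")\n")
  invisible(x)
}

## bilinear interpolation of matrix M at fractional (row, col) coordinates;
## callers guarantee 1 <= r <= nrow, 1 <= c <= ncol
.bilinear <- function(M, r, c) {
  r0 <- pmin(floor(r), nrow(M) - 1L); c0 <- pmin(floor(c), ncol(M) - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  M[i00] * (1 - fr) * (1 - fc) + M[i10] * fr * (1 - fc) +
    M[i01] * (1 - fr) * fc + M[i11] * fr * fc
}

#' Extract a radial MPOD profile by circular-path averaging
#'
#' For each requested radius the map is sampled at `n_angles` equally spaced
#' angles on the circle of that radius around the foveolar centre (bilinear
#' interpolation); the circumferential mean becomes the profile value and
#' the circumferential standard deviation the profile SD. A radius of 0 is
#' the centre value with SD 0.
#'
#' @param map an [mpod_map()].
#' @param radii numeric vector of radii (degrees), non-negative, strictly
#'   increasing; every circle must lie inside the image.
#' @param n_angles number of angular samples per circle (>= 8).
#' @return An [mpod_profile()] with the circumferential SD in `sd`.
#' @export
extract_radial_profile <- function(map, radii = default_grid(),
                                   n_angles = 360L) {
  stopifnot(inherits(map, "mpod_map"))
  radii <- as.numeric(radii)
  if (any(radii < 0)) stop("radii must be non-negative", call. = FALSE)
  if (n_angles < 8L) stop("'n_angles' must be at least 8", call. = FALSE)
  r_px <- radii / map$scale
  max_r <- min(map$center[1] - 1, nrow(map$pixels) - map$center[1],
               map$center[2] - 1, ncol(map$pixels) - map$center[2])
  bad <- radii[r_px > max_r]
  if (length(bad))
    stop("circle exits image bounds at radius ",
         paste(signif(bad, 4), collapse = ", "), " deg", call. = FALSE)
  theta <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  st <- sin(theta); ct <- cos(theta)
  mp <- numeric(length(radii)); sdv <- numeric(length(radii))
  for (k in seq_along(radii)) {
    if (r_px[k] == 0) {
      mp[k] <- .bilinear(map$pixels, map$center[1], map$center[2])
      sdv[k] <- 0
    } else {
      v <- .bilinear(map$pixels,
                     map$center[1] + r_px[k] * st,
                     map$center[2] + r_px[k] * ct)
      mp[k] <- mean(v)
      sdv[k] <- stats::sd(v)
    }
  }
  mpod_profile(radii, mp, sd = sdv)
}

#' Read a 2D MPOD map from a grayscale PNG or TIFF image
#'
#' Thin wrapper for file-based workflows: reads the raster (first channel if
#' multi-channel) and attaches the centre and scale supplied alongside the
#' image.
#'
#' @param path image path ending in `.png`, `.tif` or `.tiff`.
#' @param center,scale as in [mpod_map()].
#' @return An [mpod_map()].
#' @export
read_map <- function(path, center, scale) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG maps requires the 'png' package", call. = FALSE)
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF maps requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else stop("unsupported image format '", ext, "'", call. = FALSE)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  mpod_map(px, center, scale)
}
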