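# Pixel masks: beam-stop shadow, dead pixels, and morphological dilation.

#' Pixel exclusion mask
#'
#' A logical matrix marking detector pixels to ignore during integration,
#' with a per-pixel provenance tag: `"beamstop"`, `"dead"`, `"dilated"` or
#' `"user"` (empty string for included pixels).
#'
#' @param excluded logical matrix, `TRUE` = pixel ignored.
#' @param provenance optional character matrix of the same shape; defaults to
#'   `"user"` at excluded pixels.
#' @return an object of class `pixel_mask`.
#' @export
pixel_mask <- function(excluded, provenance = NULL) {
  stopifnot(is.logical(excluded), is.matrix(excluded))
  if (is.null(provenance)) {
    provenance <- matrix("", nrow(excluded), ncol(excluded))
    provenance[excluded] <- "user"
  }
  stopifnot(is.character(provenance), all(dim(provenance) == dim(excluded)))
  if (any(excluded & provenance == ""))
    stop("every excluded pixel needs a provenance tag", call. = FALSE)
  structure(list(excluded = excluded, provenance = provenance),
            class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  tab <- table(x$provenance[x$excluded])
  cat(sprintf("<pixel_mask> %d x %d, %d excluded",
              nrow(x$excluded), ncol(x$excluded), sum(x$excluded)))
  if (length(tab))
    cat(" (", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Build a pixel mask from beam-stop radius and dead-pixel list
#'
#' Excludes every pixel whose center lies within `beamstop_radius_mm` of the
#' beam center (distance measured in mm via the pixel pitch), plus any listed
#' dead pixels.
#'
#' @param shape integer length-2, detector (rows, cols).
#' @param geometry a [detector_geometry()] carrying the beam center.
#' @param beamstop_radius_mm beam-stop shadow radius in mm (>= 0).
#' @param dead_pixels optional two-column matrix (or data.frame) of 1-based
#'   (row, col) indices of non-responsive pixels; duplicates allowed.
#' @return a [pixel_mask()] with provenance `"beamstop"` / `"dead"` (dead
#'   wins where both apply, matching the order artifacts are masked).
#' @export
build_mask <- function(shape, geometry, beamstop_radius_mm = 0,
                       dead_pixels = NULL) {
  stopifnot(inherits(geometry, "detector_geometry"),
            length(shape) == 2L, all(shape >= 1))
  if (beamstop_radius_mm < 0)
    stop("`beamstop_radius_mm` must be non-negative", call. = FALSE)
  excl <- if (beamstop_radius_mm > 0)
    pixel_radii_mm(shape, geometry) <= beamstop_radius_mm
  else matrix(FALSE, shape[1], shape[2])
  prov <- matrix("", shape[1], shape[2])
  prov[excl] <- "beamstop"
  if (!is.null(dead_pixels)) {
    dp <- as.matrix(dead_pixels)
    if (ncol(dp) != 2L) stop("`dead_pixels` needs (row, col) pairs",
                             call. = FALSE)
    storage.mode(dp) <- "integer"
    if (any(dp[, 1] < 1 | dp[, 1] > shape[1] |
            dp[, 2] < 1 | dp[, 2] > shape[2]))
      stop("dead pixel index out of detector bounds", call. = FALSE)
    excl[dp] <- TRUE
    prov[dp] <- "dead"
  }
  pixel_mask(excl, prov)
}

#' Dilate a pixel mask with a disk structuring element
#'
#' Morphological dilation: a pixel becomes excluded if any already-excluded
#' pixel lies within `radius_px` of it (Euclidean distance in pixels,
#' `di^2 + dj^2 <= radius_px^2`). Dilation only adds exclusions; newly
#' excluded pixels are tagged `"dilated"`.
#'
#' @param mask a [pixel_mask()].
#' @param radius_px integer dilation radius in pixels (>= 0); 0 returns the
#'   mask unchanged.
#' @return a [pixel_mask()] with `output >= input` pixelwise.
#' @export
dilate_mask <- function(mask, radius_px) {
  stopifnot(inherits(mask, "pixel_mask"))
  if (length(radius_px) != 1L || radius_px < 0 || radius_px != round(radius_px))
    stop("`radius_px` must be a single non-negative integer", call. = FALSE)
  if (radius_px == 0 || !any(mask$excluded)) return(mask)
  ex <- mask$excluded
  nr <- nrow(ex); nc <- ncol(ex)
  out <- ex
  idx <- which(ex, arr.ind = TRUE)
  offs <- expand.grid(di = -radius_px:radius_px, dj = -radius_px:radius_px)
  offs <- offs[offs$di^2 + offs$dj^2 <= radius_px^2, , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    i <- idx[, 1] + offs$di[k]
    j <- idx[, 2] + offs$dj[k]
    keep <- i >= 1 & i <= nr & j >= 1 & j <= nc
    out[cbind(i[keep], j[keep])] <- TRUE
  }
  prov <- mask$provenance
  prov[out & !ex] <- "dilated"
  pixel_mask(out, prov)
}
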