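# 2D detector frames: container, monitor/exposure normalization, averaging,
# and TIFF round-trip.

#' Detector frame container
#'
#' Holds one 2D exposure: photon counts, exposure time, a beam-monitor
#' reading, and a cumulative `scale` factor recording any normalization
#' applied to the raw counts (1 for a raw frame). The scale lets downstream
#' Poisson error propagation recover raw-count statistics from normalized
#' counts.
#'
#' @param counts numeric matrix of photon counts (non-negative at live
#'   pixels; `NA` allowed at masked pixels).
#' @param exposure_s exposure time in seconds (> 0).
#' @param monitor beam-monitor reading, arbitrary units (> 0).
#' @param scale cumulative multiplicative factor applied to raw counts.
#' @param id optional identifier carried through the pipeline.
#' @return an object of class `waxs_frame`.
#' @export
waxs_frame <- function(counts, exposure_s = 0.1, monitor = 1, scale = 1,
                       id = NULL) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  stop_if_not_scalar_pos(exposure_s, "exposure_s")
  stop_if_not_scalar_pos(monitor, "monitor")
  stop_if_not_scalar_pos(scale, "scale")
  if (any(counts < 0, na.rm = TRUE))
    stop("counts must be non-negative", call. = FALSE)
  structure(list(counts = counts, exposure_s = exposure_s, monitor = monitor,
                 scale = scale, id = id),
            class = "waxs_frame")
}

#' @export
print.waxs_frame <- function(x, ...) {
  cat(sprintf("<waxs_frame> %d x %d, exposure %.3g s, monitor %.4g, scale %.4g\n",
              nrow(x$counts), ncol(x$counts), x$exposure_s, x$monitor, x$scale))
  invisible(x)
}

#' Normalize a frame by beam monitor and exposure time
#'
#' Scales counts by `(reference_monitor / monitor) / exposure_s` to correct
#' for beam-flux fluctuations and acquisition time, so frames taken under
#' different flux are comparable. The applied factor is folded into the
#' frame's `scale` field.
#'
#' @param frame a [waxs_frame()].
#' @param reference_monitor monitor reading to normalize to (> 0).
#' @return a [waxs_frame()] with scaled counts and updated `scale`.
#' @export
normalize_frame <- function(frame, reference_monitor = 1) {
  stopifnot(inherits(frame, "waxs_frame"))
  stop_if_not_scalar_pos(reference_monitor, "reference_monitor")
  k <- (reference_monitor / frame$monitor) / frame$exposure_s
  out <- frame
  out$counts <- frame$counts * k
  out$scale <- frame$scale * k
  out$monitor <- reference_monitor
  out
}

#' Average repeated frames at one measurement position
#'
#' Pixelwise mean of repeat exposures (the standard acquisition records
#' several short frames per position to tame shot noise). The result's
#' exposure time is the sum of the inputs', and its `scale` becomes
#' `scale / n` so that Poisson error propagation still refers to the total
#' raw counts accumulated.
#'
#' @param frames list of [waxs_frame()] objects of identical shape and scale.
#' @return one [waxs_frame()].
#' @export
average_frames <- function(frames) {
  if (!length(frames)) stop("need at least one frame", call. = FALSE)
  stopifnot(all(vapply(frames, inherits, logical(1), "waxs_frame")))
  dims <- vapply(frames, function(f) dim(f$counts), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have mismatched shapes", call. = FALSE)
  scales <- vapply(frames, `[[`, numeric(1), "scale")
  if (diff(range(scales)) > 1e-12 * scales[1])
    stop("frames have mismatched scales; normalize consistently first",
         call. = FALSE)
  n <- length(frames)
  acc <- Reduce(`+`, lapply(frames, `[[`, "counts")) / n
  waxs_frame(acc,
             exposure_s = sum(vapply(frames, `[[`, numeric(1), "exposure_s")),
             monitor = mean(vapply(frames, `[[`, numeric(1), "monitor")),
             scale = scales[1] / n,
             id = frames[[1]]$id)
}

#' Write a frame as a single-page grayscale TIFF with a JSON sidecar
#'
#' Counts are stored as 32-bit samples; exposure, monitor, scale and
#' (optionally) geometry and mask go to `<path>.json`.
#'
#' @param frame a [waxs_frame()].
#' @param path output TIFF path.
#' @param geometry optional [detector_geometry()] stored in the sidecar.
#' @param mask optional [pixel_mask()] stored (as indices) in the sidecar.
#' @return `path`, invisibly.
#' @export
write_frame_tiff <- function(frame, path, geometry = NULL, mask = NULL) {
  stopifnot(inherits(frame, "waxs_frame"))
  mx <- max(frame$counts, 1, na.rm = TRUE)
  img <- frame$counts
  img[!is.finite(img)] <- 0
  tiff::writeTIFF(img / mx, path, bits.per.sample = 32L, compression = "none")
  side <- list(exposure_s = frame$exposure_s, monitor = frame$monitor,
               scale = frame$scale, id = frame$id, counts_max = mx)
  if (!is.null(geometry)) side$geometry <- unclass(geometry)
  if (!is.null(mask)) {
    idx <- which(mask$excluded, arr.ind = TRUE)
    side$mask <- list(shape = dim(mask$excluded),
                      excluded = unname(as.data.frame(idx)),
                      provenance = mask$provenance[mask$excluded])
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a frame written by [write_frame_tiff()]
#'
#' @param path TIFF path (expects `<path>.json` sidecar alongside).
#' @return a list with `frame` ([waxs_frame()]), and `geometry` / `mask` when
#'   present in the sidecar.
#' @export
read_frame_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing sidecar: ", side_path, call. = FALSE)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  counts <- img * side$counts_max
  frame <- waxs_frame(counts, exposure_s = side$exposure_s,
                      monitor = side$monitor, scale = side$scale,
                      id = side$id)
  out <- list(frame = frame)
  if (!is.null(side$geometry))
    out$geometry <- detector_geometry(side$geometry$distance_mm,
                                      side$geometry$pixel_mm,
                                      unlist(side$geometry$beam_center),
                                      side$geometry$energy_kev)
  if (!is.null(side$mask)) {
    ex <- matrix(FALSE, side$mask$shape[1], side$mask$shape[2])
    prov <- matrix("", side$mask$shape[1], side$mask$shape[2])
    if (length(side$mask$provenance)) {
      idx <- as.matrix(side$mask$excluded)
      ex[idx] <- TRUE
      prov[idx] <- side$mask$provenance
    }
    out$mask <- pixel_mask(ex, prov)
  }
  out
}
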