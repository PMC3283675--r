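#' Terminal velocity from a position-time track
#'
#' A cell released into the field (or dragged by the stage) reaches terminal
#' speed within milliseconds at these Reynolds numbers, so after discarding a
#' leading transient — a camera/recapture artifact rather than physics — the
#' track is linear and the velocity is the ordinary least-squares slope of
#' position against time.
#'
#' @param track Data frame with columns `t_s` (timestamps, s, strictly
#'   increasing) and `x_m` (signed displacement along the motion axis, m).
#' @param transient_fraction Fraction of leading samples to discard before
#'   fitting (default 0.1). At least 3 samples must remain.
#' @return One-row tibble: `velocity_m_s` (the slope), `intercept_m`,
#'   `pearson_r`, `residual_rms_m`, `n_used`.
#' @examples
#' tr <- tibble::tibble(t_s = (0:9) / 10, x_m = 5e-5 * (0:9) / 10)
#' terminal_velocity(tr, transient_fraction = 0)
#' @export
terminal_velocity <- function(track, transient_fraction = 0.1) {
  stopifnot(is.data.frame(track), all(c("t_s", "x_m") %in% names(track)),
            is.numeric(transient_fraction), length(transient_fraction) == 1L,
            transient_fraction >= 0, transient_fraction < 1)
  t <- track$t_s; x <- track$x_m
  if (any(!is.finite(t)) || any(!is.finite(x)))
    stop("track contains non-finite values", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("timestamps must be strictly increasing", call. = FALSE)
  drop <- floor(transient_fraction * length(t))
  if (drop > 0L) { t <- t[-seq_len(drop)]; x <- x[-seq_len(drop)] }
  if (length(t) < 3L)
    stop("insufficient data: need at least 3 samples after the transient",
         call. = FALSE)
  if (diff(range(t)) == 0)
    stop("degenerate track: zero time span", call. = FALSE)
  fit <- stats::lm(x ~ t)
  co <- stats::coef(fit)
  r <- if (stats::sd(x) > 0) stats::cor(t, x) else 0
  tibble::tibble(
    velocity_m_s = unname(co[["t"]]),
    intercept_m = unname(co[["(Intercept)"]]),
    pearson_r = r,
    residual_rms_m = sqrt(mean(stats::residuals(fit)^2)),
    n_used = length(t)
  )
}

#' Segment a single bright cell in an intensity frame
#'
#' Thresholds the frame (Otsu by default, or a fixed intensity quantile),
#' labels connected components, keeps the largest, and summarises it by the
#' second-moment-equivalent ellipse: the component's pixel-coordinate
#' covariance is eigendecomposed and the major/minor axis lengths are
#' `4 * sqrt(eigenvalue)` — exact for a filled ellipse.
#'
#' @param frame Numeric matrix of intensities (one frame).
#' @param threshold_strategy `"otsu"` (default) or `"quantile"`.
#' @param quantile Intensity quantile used when `threshold_strategy =
#'   "quantile"` (default 0.5).
#' @return A list: `mask` (logical matrix of the kept component), `centroid`
#'   (x, y in pixel units), `major_axis_px`, `minor_axis_px`,
#'   `orientation_rad`.
#' @examples
#' fr <- render_cell_frame(major_px = 40, minor_px = 20, dim = c(96, 96))
#' segment_cell(fr)$major_axis_px
#' @export
segment_cell <- function(frame, threshold_strategy = c("otsu", "quantile"),
                         quantile = 0.5) {
  threshold_strategy <- match.arg(threshold_strategy)
  stopifnot(is.matrix(frame), is.numeric(frame))
  rng <- range(frame)
  if (!all(is.finite(rng)))
    stop("frame contains non-finite intensities", call. = FALSE)
  if (rng[1] == rng[2])
    stop("no cell found: frame has constant intensity", call. = FALSE)
  norm <- (frame - rng[1]) / (rng[2] - rng[1])
  thr <- switch(threshold_strategy,
                otsu = EBImage::otsu(EBImage::Image(norm)),
                quantile = stats::quantile(norm, quantile))
  mask <- norm > thr
  if (!any(mask))
    stop("no cell found: empty mask after thresholding", call. = FALSE)
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- EBImage::imageData(lab)
  sizes <- tabulate(lab[lab > 0])
  main <- which.max(sizes)
  if (length(sizes) > 1L && sort(sizes, decreasing = TRUE)[2L] >= 0.5 * sizes[main])
    stop("ambiguous scene: multiple components of comparable size",
         call. = FALSE)
  keep <- lab == main
  idx <- which(keep, arr.ind = TRUE)
  # pixel-center coordinates; add the 1/12 variance of a unit pixel so a
  # one-pixel-wide component has a finite axis
  cov <- if (nrow(idx) == 1L) diag(1 / 12, 2)
         else stats::cov(idx) * (nrow(idx) - 1) / nrow(idx) + diag(1 / 12, 2)
  eig <- eigen(cov, symmetric = TRUE)
  centroid <- colMeans(idx)
  v <- eig$vectors[, 1L]
  list(mask = keep,
       centroid = c(x = unname(centroid[2L]), y = unname(centroid[1L])),
       major_axis_px = 4 * sqrt(eig$values[1L]),
       minor_axis_px = 4 * sqrt(eig$values[2L]),
       orientation_rad = atan2(v[2L], v[1L]))
}

#' Cell length per frame from an image stack
#'
#' Segments every frame of a stack ([segment_cell()]) and converts the
#' major-axis length to metres. When `step` labels are supplied, a
#' steady-state length per step is also available via the median (robust to
#' occasional segmentation blips); use `aggregate = TRUE` for that.
#'
#' @param stack A list of numeric matrices, or a 3-D array with frames along
#'   the third dimension.
#' @param pixel_size_m Pixel size, m per pixel.
#' @param step Optional vector of step identifiers, one per frame.
#' @param aggregate If `TRUE` and `step` is given, return the per-step median
#'   length instead of per-frame lengths.
#' @inheritParams segment_cell
#' @return Tibble with `frame`, (`step`,) `major_axis_px`, `length_m`, or the
#'   per-step medians when aggregating.
#' @export
cell_length <- function(stack, pixel_size_m, step = NULL, aggregate = FALSE,
                        threshold_strategy = c("otsu", "quantile"),
                        quantile = 0.5) {
  threshold_strategy <- match.arg(threshold_strategy)
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3L]), function(i) stack[, , i])
  stopifnot(is.list(stack), length(stack) >= 1L,
            is.numeric(pixel_size_m), pixel_size_m > 0)
  dims <- vapply(stack, dim, integer(2L))
  if (any(dims != dims[, 1L]))
    stop("all frames must have the same shape", call. = FALSE)
  lens <- vapply(stack, function(fr)
    segment_cell(fr, threshold_strategy, quantile)$major_axis_px, numeric(1L))
  out <- tibble::tibble(frame = seq_along(stack),
                        major_axis_px = lens,
                        length_m = lens * pixel_size_m)
  if (!is.null(step)) {
    stopifnot(length(step) == length(stack))
    out$step <- step
    out <- out[, c("frame", "step", "major_axis_px", "length_m")]
    if (aggregate) {
      out <- dplyr::summarise(dplyr::group_by(out, .data$step),
                              n_frames = dplyr::n(),
                              length_m = stats::median(.data$length_m),
                              .groups = "drop")
    }
  }
  out
}

#' Read and write grayscale frame stacks as multi-page TIFF
#'
#' Frame stacks travel as multi-page grayscale TIFF plus a JSON sidecar
#' holding the pixel size and timestamps, so image data from other tools can
#' enter the pipeline at the tracking stage.
#'
#' @param stack List of numeric matrices with values in `[0, 1]`.
#' @param path TIFF file path; the sidecar is written at `<path>.json`.
#' @param pixel_size_m Pixel size, m.
#' @param timestamps_s Optional per-frame timestamps, s.
#' @return `write_frame_stack()` returns `path` invisibly;
#'   `read_frame_stack()` returns a list with `frames`, `pixel_size_m`,
#'   `timestamps_s`.
#' @export
write_frame_stack <- function(stack, path, pixel_size_m, timestamps_s = NULL) {
  stopifnot(is.list(stack), length(stack) >= 1L)
  tiff::writeTIFF(stack, path, bits.per.sample = 16L)
  meta <- list(pixel_size_m = pixel_size_m, n_frames = length(stack))
  if (!is.null(timestamps_s)) meta$timestamps_s <- timestamps_s
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(frames = frames, pixel_size_m = meta$pixel_size_m,
       timestamps_s = meta$timestamps_s)
}
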