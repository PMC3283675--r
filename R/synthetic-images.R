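#' Render a synthetic frame of a single elliptical cell
#'
#' Ground-truth renderer used to exercise the segmentation path: a filled
#' ellipse of known axes, orientation and position on a dark background,
#' optionally with Gaussian intensity noise. The renderer and the measurer
#' share the equivalent-ellipse convention, so recovery of the major axis
#' within about a pixel is the expected behaviour, not a coincidence.
#'
#' @param major_px,minor_px Full axis lengths, pixels.
#' @param dim Frame dimensions `c(rows, cols)`.
#' @param center Ellipse center `c(row, col)`; default frame center.
#' @param angle_deg Major-axis orientation, degrees from the column axis.
#' @param fg,bg Foreground/background intensity in `[0, 1]`.
#' @param noise_sd Gaussian intensity noise SD (0 = noiseless).
#' @param seed Seed used when `noise_sd > 0`.
#' @return Numeric matrix with values clipped to `[0, 1]`.
#' @export
render_cell_frame <- function(major_px, minor_px, dim = c(96L, 96L),
                              center = (dim + 1) / 2, angle_deg = 0,
                              fg = 0.9, bg = 0.1, noise_sd = 0, seed = 1L) {
  stopifnot(major_px > 0, minor_px > 0, all(dim >= 8L))
  a <- major_px / 2; b <- minor_px / 2
  th <- angle_deg * pi / 180
  rows <- matrix(seq_len(dim[1L]), dim[1L], dim[2L])
  cols <- matrix(seq_len(dim[2L]), dim[1L], dim[2L], byrow = TRUE)
  dr <- rows - center[1L]; dc <- cols - center[2L]
  # rotate into the ellipse frame: major axis along +col at angle 0
  u <- dc * cos(th) + dr * sin(th)
  w <- -dc * sin(th) + dr * cos(th)
  inside <- (u / a)^2 + (w / b)^2 <= 1
  frame <- matrix(bg, dim[1L], dim[2L])
  frame[inside] <- fg
  if (noise_sd > 0) {
    set.seed(seed)
    frame <- frame + matrix(stats::rnorm(length(frame), 0, noise_sd),
                            dim[1L], dim[2L])
  }
  pmin(pmax(frame, 0), 1)
}

#' Render an image stack for an elongation sweep
#'
#' Turns the per-step steady-state lengths of one cell's elongation sweep
#' into a synthetic camera stack: each velocity step contributes
#' `frames_per_step` frames of an ellipse whose major axis is that step's
#' length (in pixels at `pixel_size_m`) and whose minor axis is fixed, as a
#' membrane of conserved width would appear.
#'
#' @param lengths_m Steady-state cell length per velocity step, m.
#' @param pixel_size_m Pixel size, m (default 0.2 um).
#' @param minor_m Fixed minor axis, m (default 4 um).
#' @param frames_per_step Frames rendered per step.
#' @param dim Frame dimensions.
#' @param noise_sd Intensity noise SD passed to [render_cell_frame()].
#' @param seed Root seed for the per-frame noise.
#' @return List with `frames` (list of matrices), `step` (step id per
#'   frame), `pixel_size_m`.
#' @export
render_elongation_stack <- function(lengths_m, pixel_size_m = 0.2e-6,
                                    minor_m = 4e-6, frames_per_step = 3L,
                                    dim = c(96L, 96L), noise_sd = 0,
                                    seed = 1L) {
  stopifnot(all(lengths_m > 0), pixel_size_m > 0, frames_per_step >= 1L)
  frames <- list(); step <- integer(0)
  k <- 0L
  for (s in seq_along(lengths_m)) {
    for (f in seq_len(frames_per_step)) {
      k <- k + 1L
      frames[[k]] <- render_cell_frame(
        major_px = lengths_m[s] / pixel_size_m,
        minor_px = minor_m / pixel_size_m,
        dim = dim, noise_sd = noise_sd, seed = seed + 1000L * s + f)
      step[k] <- s
    }
  }
  list(frames = frames, step = step, pixel_size_m = pixel_size_m)
}
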