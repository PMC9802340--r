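#' Prescribed substrate displacement model
#'
#' The displacement of the gel surface at rest position `x` and frame `f` is
#' the superposition of three terms:
#'
#' * a slow inward **contractile** term directed toward `contractile_center`,
#'   accruing linearly with frame index: its magnitude at radius r is
#'   `f * A * (r/L) * exp((1 - (r/L)^2) / 2)`, which peaks at exactly
#'   `f * A` um at `r = L`;
#' * transient localized **hotspot** events: Gaussian bumps of spatial scale
#'   `scale` um (the ~20 um transient pulses seen near expanding colony
#'   edges) active for frames `onset <= f < onset + duration`, displacing by
#'   `amplitude * exp(-d^2 / (2 scale^2))` along a fixed unit direction per
#'   event (default: from the contractile center toward the event center);
#' * rigid stage **drift**, `f * drift_per_frame`.
#'
#' Frame 0 always evaluates to zero displacement, matching the convention
#' that the first bead frame is the unstressed reference.
#'
#' @param contractile_amplitude peak inward displacement accrued per frame,
#'   um/frame.
#' @param contractile_center center of contraction, um `(x, y)`.
#' @param contractile_length_scale radius L of peak contraction, um (> 0).
#' @param hotspots a data frame (or NULL) with columns `x`, `y` (center,
#'   um), `scale` (um, > 0), `amplitude` (peak, um), `onset` (first active
#'   frame), `duration` (frames), and optionally `dir_x`, `dir_y` (unit
#'   direction; normalized internally).
#' @param drift_per_frame rigid drift per frame, um `(x, y)`.
#' @param seed integer seed (kept with the model for provenance; evaluation
#'   itself is deterministic).
#' @return A `displacement_model` list.
#' @export
displacement_model <- function(contractile_amplitude = 0,
                               contractile_center = c(0, 0),
                               contractile_length_scale = 100,
                               hotspots = NULL,
                               drift_per_frame = c(0, 0),
                               seed = 1L) {
  if (!is_num1(contractile_amplitude) || contractile_amplitude < 0)
    stopf("`contractile_amplitude` must be >= 0")
  if (!is_num2(contractile_center)) stopf("`contractile_center` must be (x, y)")
  if (!is_num1(contractile_length_scale) || contractile_length_scale <= 0)
    stopf("`contractile_length_scale` must be > 0")
  if (!is_num2(drift_per_frame)) stopf("`drift_per_frame` must be (x, y)")
  if (!is.null(hotspots)) {
    hotspots <- as_tibble(hotspots)
    need <- c("x", "y", "scale", "amplitude", "onset", "duration")
    if (!all(need %in% names(hotspots)))
      stopf("`hotspots` needs columns %s", paste(need, collapse = ", "))
    if (any(hotspots$scale <= 0)) stopf("hotspot `scale` must be > 0")
    if (!all(c("dir_x", "dir_y") %in% names(hotspots))) {
      dx <- hotspots$x - contractile_center[1]
      dy <- hotspots$y - contractile_center[2]
      nrm <- sqrt(dx^2 + dy^2)
      deg <- nrm < .Machine$double.eps
      hotspots$dir_x <- ifelse(deg, 1, dx / pmax(nrm, .Machine$double.eps))
      hotspots$dir_y <- ifelse(deg, 0, dy / pmax(nrm, .Machine$double.eps))
    } else {
      nrm <- sqrt(hotspots$dir_x^2 + hotspots$dir_y^2)
      hotspots$dir_x <- hotspots$dir_x / nrm
      hotspots$dir_y <- hotspots$dir_y / nrm
    }
  }
  structure(
    list(contractile_amplitude = contractile_amplitude,
         contractile_center = contractile_center,
         contractile_length_scale = contractile_length_scale,
         hotspots = hotspots, drift_per_frame = drift_per_frame,
         seed = as.integer(seed)),
    class = "displacement_model"
  )
}

#' Evaluate a displacement model at given points and frame
#'
#' @param model a [displacement_model()].
#' @param points a data frame with columns `x`, `y` (um) or a 2-column
#'   matrix.
#' @param frame 0-based frame index.
#' @return A tibble with columns `x`, `y`, `ux`, `uy` (um).
#' @export
evaluate_displacement_model <- function(model, points, frame) {
  stopifnot(inherits(model, "displacement_model"))
  if (is.matrix(points)) points <- tibble(x = points[, 1], y = points[, 2])
  points <- as_tibble(points)
  if (!all(is.finite(points$x)) || !all(is.finite(points$y)))
    stopf("`points` must be finite")
  n <- nrow(points)
  ux <- numeric(n); uy <- numeric(n)

  if (frame > 0 && model$contractile_amplitude > 0) {
    dx <- points$x - model$contractile_center[1]
    dy <- points$y - model$contractile_center[2]
    r <- sqrt(dx^2 + dy^2)
    s <- r / model$contractile_length_scale
    mag <- frame * model$contractile_amplitude * s * exp((1 - s^2) / 2)
    safe_r <- pmax(r, .Machine$double.eps)
    ux <- ux - mag * dx / safe_r
    uy <- uy - mag * dy / safe_r
  }
  if (!is.null(model$hotspots) && frame > 0) {
    hs <- model$hotspots
    for (i in seq_len(nrow(hs))) {
      if (frame >= hs$onset[i] && frame < hs$onset[i] + hs$duration[i]) {
        d2 <- (points$x - hs$x[i])^2 + (points$y - hs$y[i])^2
        g <- hs$amplitude[i] * exp(-d2 / (2 * hs$scale[i]^2))
        ux <- ux + g * hs$dir_x[i]
        uy <- uy + g * hs$dir_y[i]
      }
    }
  }
  if (frame > 0) {
    ux <- ux + frame * model$drift_per_frame[1]
    uy <- uy + frame * model$drift_per_frame[2]
  }
  tibble(x = points$x, y = points$y, ux = ux, uy = uy)
}

#' Synthetic fluorescent-bead scenario
#'
#' Tracer beads embedded in the gel surface, rendered as pixel-integrated
#' Gaussian spots so subpixel positions are meaningful. The effective spot
#' width combines the optical point-spread width with the finite bead size
#' (`sigma_eff^2 = psf_sd^2 + (diameter / pixel_size / 4)^2`).
#'
#' @param bead_density beads per square micrometre. The default (0.004)
#'   yields ~16 beads in a 32 px interrogation window at 2 um/px, above the
#'   ~10 beads/window needed for reliable cross-correlation.
#' @param bead_diameter physical bead diameter, um (default 4.8, the tracer
#'   size used in gel-embedded experiments).
#' @param psf_sd optical blur standard deviation, px.
#' @param image_shape frame shape in px `c(height, width)`.
#' @param bead_intensity peak intensity of a centered bead, grayscale.
#' @param background background intensity level, grayscale.
#' @param noise_sd additive Gaussian noise, grayscale.
#' @param pixel_size um/px.
#' @param seed integer RNG seed.
#' @return A `bead_scenario` list.
#' @export
bead_scenario <- function(bead_density = 0.004,
                          bead_diameter = 4.8,
                          psf_sd = 1.2,
                          image_shape = c(256, 256),
                          bead_intensity = 30000,
                          background = 2000,
                          noise_sd = 0,
                          pixel_size = 2,
                          seed = 1L) {
  if (!is_num1(bead_diameter) || bead_diameter <= 0)
    stopf("`bead_diameter` must be > 0")
  if (!is_num1(bead_density) || bead_density <= 0)
    stopf("`bead_density` must be > 0")
  structure(
    list(bead_density = bead_density, bead_diameter = bead_diameter,
         psf_sd = psf_sd, image_shape = as.integer(image_shape),
         bead_intensity = bead_intensity, background = background,
         noise_sd = noise_sd, pixel_size = pixel_size, seed = as.integer(seed)),
    class = "bead_scenario"
  )
}

# render Gaussian spots (pixel-integrated) onto a zero canvas; pos_px is an
# n x 2 matrix of (x, y) pixel positions, 0-based
render_beads <- function(pos_px, shape, sigma_px, amplitude) {
  H <- shape[1]; W <- shape[2]
  canvas <- matrix(0, H, W)
  half <- ceiling(4 * sigma_px)
  # normalization so a perfectly centered bead peaks at `amplitude`
  peak_w <- (stats::pnorm(0.5 / sigma_px) - stats::pnorm(-0.5 / sigma_px))^2
  for (i in seq_len(nrow(pos_px))) {
    bx <- pos_px[i, 1]; by <- pos_px[i, 2]
    if (bx < -half || bx > W - 1 + half || by < -half || by > H - 1 + half)
      next
    ix <- max(0, floor(bx) - half):min(W - 1, ceiling(bx) + half)
    iy <- max(0, floor(by) - half):min(H - 1, ceiling(by) + half)
    if (!length(ix) || !length(iy)) next
    wx <- stats::pnorm((ix + 0.5 - bx) / sigma_px) -
      stats::pnorm((ix - 0.5 - bx) / sigma_px)
    wy <- stats::pnorm((iy + 0.5 - by) / sigma_px) -
      stats::pnorm((iy - 0.5 - by) / sigma_px)
    canvas[iy + 1, ix + 1] <- canvas[iy + 1, ix + 1] +
      amplitude / peak_w * outer(wy, wx)
  }
  canvas
}

#' Render a synthetic bead image stack advected by a displacement model
#'
#' Beads are seeded uniformly at rest positions `x0` and drawn in frame `f`
#' at `x0 + u(x0, f)` — pure advection with the substrate surface, the
#' tracer assumption of traction force microscopy. Frame 0 uses `u = 0`.
#' Beads displaced outside the frame are silently clipped from the image but
#' flagged in the ground truth.
#'
#' @param beads a [bead_scenario()].
#' @param model a [displacement_model()].
#' @param n_frames number of frames (>= 2).
#' @param frame_interval minutes between frames.
#' @param truth_grid_spacing spacing of the ground-truth displacement grid,
#'   px.
#' @return A list with `stack` (an [image_stack()]) and `truth` (list:
#'   `positions` tibble of rest positions, `grid` tibble of the true field
#'   per frame, `clipped` tibble of clipped bead/frame pairs,
#'   `displacement_fn(points, frame)`, and the scenario/model).
#' @export
generate_bead_stack <- function(beads, model, n_frames,
                                frame_interval = 10,
                                truth_grid_spacing = 16) {
  stopifnot(inherits(beads, "bead_scenario"),
            inherits(model, "displacement_model"))
  if (n_frames < 2) stopf("`n_frames` must be >= 2")
  H <- beads$image_shape[1]; W <- beads$image_shape[2]
  px <- beads$pixel_size
  area_um2 <- (H * px) * (W * px)
  n_beads <- round(beads$bead_density * area_um2)
  if (n_beads < 1) stopf("bead density yields zero beads for this field")

  set.seed(beads$seed)
  pos0 <- tibble(
    bead = seq_len(n_beads),
    x = stats::runif(n_beads, 0, (W - 1) * px),
    y = stats::runif(n_beads, 0, (H - 1) * px)
  )
  sigma_px <- sqrt(beads$psf_sd^2 + (beads$bead_diameter / px / 4)^2)

  gx <- seq(0, (W - 1), by = truth_grid_spacing) * px
  gy <- seq(0, (H - 1), by = truth_grid_spacing) * px
  grid0 <- tidyr::expand_grid(y = gy, x = gx)[, c("x", "y")]

  frames <- vector("list", n_frames)
  grids <- vector("list", n_frames)
  clipped <- list()
  for (f in seq_len(n_frames) - 1L) {
    u <- evaluate_displacement_model(model, pos0[, c("x", "y")], f)
    pos <- cbind((pos0$x + u$ux) / px, (pos0$y + u$uy) / px)
    out <- pos[, 1] < 0 | pos[, 1] > W - 1 | pos[, 2] < 0 | pos[, 2] > H - 1
    if (any(out))
      clipped[[length(clipped) + 1L]] <-
        tibble(frame = f, bead = pos0$bead[out])
    img <- beads$background +
      render_beads(pos, c(H, W), sigma_px, beads$bead_intensity)
    if (beads$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, beads$noise_sd)
    frames[[f + 1L]] <- quantize16(matrix(img, H, W))
    ug <- evaluate_displacement_model(model, grid0, f)
    grids[[f + 1L]] <- tibble(frame = f, x_um = ug$x, y_um = ug$y,
                              ux_um = ug$ux, uy_um = ug$uy)
  }

  stack <- image_stack(frames, px, frame_interval, "beads")
  truth <- list(
    positions = pos0,
    grid = dplyr::bind_rows(grids),
    clipped = if (length(clipped)) dplyr::bind_rows(clipped)
              else tibble(frame = integer(), bead = integer()),
    displacement_fn = function(points, frame)
      evaluate_displacement_model(model, points, frame),
    beads = beads, model = model
  )
  list(stack = stack, truth = truth)
}
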