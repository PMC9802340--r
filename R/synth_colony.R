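#' Synthetic colony scenario
#'
#' Describes an expanding, roughly circular colony rendered as a bright-field
#' time-lapse: a filled region of distinct intensity whose boundary at frame
#' time t is `r(theta, t) = R(t) + a * cos(k * theta + phase)`, with
#' `R(t) = initial_radius + integral of radial_speed`. The boundary roughness
#' is a fixed low-order Fourier perturbation so the true radius stays well
#' defined per frame.
#'
#' Defaults emulate wide-field imaging of a young colony: 10-minute frame
#' interval, 2 um/px on a 512 px field (~1 mm), and a radial speed of
#' 5 um/min (0.3 mm/hour, the saturation scale of colony-front speeds on
#' stiff elastic gels). Pixel size and field of view are generator choices,
#' documented here, not measurements.
#'
#' @param initial_radius colony radius at frame 0, um (> 0).
#' @param radial_speed front speed in um/min: a single non-negative number or
#'   a vectorized function of time (minutes) returning um/min.
#' @param roughness_amplitude amplitude `a` of the boundary perturbation, um.
#' @param roughness_wavenumber integer angular wavenumber `k` of the
#'   perturbation.
#' @param roughness_phase phase of the perturbation, radians.
#' @param interior_intensity,exterior_intensity grayscale levels of colony
#'   interior and background, within `[0, 65535]`.
#' @param noise_sd additive Gaussian imaging noise, grayscale units.
#' @param pixel_size um per pixel.
#' @param frame_interval minutes between frames.
#' @param n_frames number of frames (>= 2).
#' @param image_shape frame shape in px as `c(height, width)`.
#' @param center colony center in um `(x, y)`; default the field center.
#' @param seed integer RNG seed; identical scenarios give bit-identical
#'   stacks.
#' @return A `colony_scenario` list.
#' @export
colony_scenario <- function(initial_radius = 200,
                            radial_speed = 5,
                            roughness_amplitude = 0,
                            roughness_wavenumber = 0,
                            roughness_phase = 0,
                            interior_intensity = 45000,
                            exterior_intensity = 15000,
                            noise_sd = 0,
                            pixel_size = 2,
                            frame_interval = 10,
                            n_frames = 7,
                            image_shape = c(512, 512),
                            center = NULL,
                            seed = 1L) {
  if (!is_num1(initial_radius) || initial_radius <= 0)
    stopf("`initial_radius` must be > 0")
  if (!is.function(radial_speed)) {
    if (!is_num1(radial_speed) || radial_speed < 0)
      stopf("`radial_speed` must be >= 0 or a function of time")
  }
  if (!is_num1(n_frames) || n_frames < 2)
    stopf("`n_frames` must be >= 2")
  for (v in c(interior_intensity, exterior_intensity))
    if (v < 0 || v > BIT_DEPTH_MAX)
      stopf("intensities must lie within the 16-bit range [0, %d]", BIT_DEPTH_MAX)
  if (is.null(center))
    center <- c(image_shape[2] - 1, image_shape[1] - 1) / 2 * pixel_size
  sc <- list(initial_radius = initial_radius, radial_speed = radial_speed,
             roughness_amplitude = roughness_amplitude,
             roughness_wavenumber = as.integer(roughness_wavenumber),
             roughness_phase = roughness_phase,
             interior_intensity = interior_intensity,
             exterior_intensity = exterior_intensity,
             noise_sd = noise_sd, pixel_size = pixel_size,
             frame_interval = frame_interval, n_frames = as.integer(n_frames),
             image_shape = as.integer(image_shape), center = center,
             seed = as.integer(seed))
  class(sc) <- "colony_scenario"
  sc
}

# true mean radius R(t) at each frame time, um
colony_radius_series <- function(scenario) {
  times <- (seq_len(scenario$n_frames) - 1) * scenario$frame_interval
  if (!is.function(scenario$radial_speed))
    return(scenario$initial_radius + scenario$radial_speed * times)
  # integrate a time-varying speed on a fine grid (20 substeps per frame)
  tt <- seq(0, max(times), length.out = (scenario$n_frames - 1) * 20 + 1)
  v <- vapply(tt, scenario$radial_speed, numeric(1))
  if (any(v < 0)) stopf("`radial_speed` must be >= 0 at all sampled times")
  R <- scenario$initial_radius + cumtrapz(tt, v)
  stats::approx(tt, R, xout = times)$y
}

# boundary radius r(theta) for one frame, um
colony_boundary_radius <- function(scenario, R, theta) {
  R + scenario$roughness_amplitude *
    cos(scenario$roughness_wavenumber * theta + scenario$roughness_phase)
}

#' Render a synthetic colony image stack with exact ground truth
#'
#' Each frame depicts a filled colony with a soft one-pixel intensity ramp at
#' the boundary (so subpixel contouring is meaningful), plus optional
#' Gaussian imaging noise. The returned ground truth carries exactly the
#' radii and center used for rendering — nothing is re-estimated.
#'
#' @param scenario a [colony_scenario()].
#' @return A list with elements `stack` (an [image_stack()]) and `truth`
#'   (list: tibble `boundary` with per-frame `frame`, `time_min`,
#'   `radius_um`, `center_x_um`, `center_y_um`; function
#'   `boundary_radius_fn(theta, frame)`; and the scenario).
#' @export
generate_colony_stack <- function(scenario) {
  stopifnot(inherits(scenario, "colony_scenario"))
  H <- scenario$image_shape[1]; W <- scenario$image_shape[2]
  px <- scenario$pixel_size
  R_series <- colony_radius_series(scenario)

  # fail early if the colony outgrows the field of view
  margin_x <- min(scenario$center[1], (W - 1) * px - scenario$center[1])
  margin_y <- min(scenario$center[2], (H - 1) * px - scenario$center[2])
  lim <- min(margin_x, margin_y)
  over <- which(R_series + abs(scenario$roughness_amplitude) > lim)
  if (length(over))
    stopf("colony radius exceeds image bounds at frame %d (radius %.1f um, limit %.1f um)",
          over[1] - 1, R_series[over[1]], lim, class = "biofilmtfm_bounds_error")

  xs <- (seq_len(W) - 1) * px - scenario$center[1]
  ys <- (seq_len(H) - 1) * px - scenario$center[2]
  X <- matrix(xs, H, W, byrow = TRUE)
  Y <- matrix(ys, H, W)
  r <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X)
  edge_w <- px  # one-pixel linear ramp

  set.seed(scenario$seed)
  frames <- vector("list", scenario$n_frames)
  for (t in seq_len(scenario$n_frames)) {
    rb <- colony_boundary_radius(scenario, R_series[t], theta)
    inside <- clamp(0.5 - (r - rb) / edge_w, 0, 1)
    img <- scenario$exterior_intensity +
      (scenario$interior_intensity - scenario$exterior_intensity) * inside
    if (scenario$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, scenario$noise_sd)
    frames[[t]] <- quantize16(matrix(img, H, W))
  }

  stack <- image_stack(frames, px, scenario$frame_interval, "brightfield")
  truth <- list(
    boundary = tibble(
      frame = seq_len(scenario$n_frames) - 1L,
      time_min = (seq_len(scenario$n_frames) - 1) * scenario$frame_interval,
      radius_um = R_series,
      center_x_um = scenario$center[1],
      center_y_um = scenario$center[2]
    ),
    boundary_radius_fn = function(theta, frame) {
      colony_boundary_radius(scenario, R_series[frame + 1L], theta)
    },
    scenario = scenario
  )
  list(stack = stack, truth = truth)
}
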