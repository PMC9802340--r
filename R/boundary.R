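#' Detect the colony boundary in a single frame
#'
#' Deterministic stand-in for supervised boundary tracing: the frame is
#' contrast-normalized, Gaussian-smoothed, thresholded by the between-class
#' variance (Otsu) criterion, reduced to its largest connected component,
#' morphologically closed, and the boundary is extracted as a subpixel
#' marching-squares contour of the smoothed intensity at the threshold
#' level. When a `prior` boundary is supplied the candidate contour nearest
#' the prior is chosen, reproducing the supervised preference for temporal
#' continuity.
#'
#' @param frame numeric matrix, `[row = y, col = x]`, any intensity scale
#'   (contrast normalization is internal).
#' @param pixel_size um/px (recorded on the result).
#' @param prior optional previous boundary (tibble with `x_px`, `y_px`).
#' @param interior `"bright"`, `"dark"`, or `"auto"` (minority-area phase).
#' @param smooth_sigma Gaussian smoothing sd, px.
#' @param closing_radius morphological closing radius, px.
#' @param min_points minimum polyline length to accept a contour.
#' @return A tibble with columns `x_px`, `y_px` (ordered subpixel boundary
#'   points, 0-based pixel-center coordinates) and attribute `pixel_size`.
#' @export
detect_boundary <- function(frame, pixel_size, prior = NULL,
                            interior = c("auto", "bright", "dark"),
                            smooth_sigma = 1, closing_radius = 3,
                            min_points = 8) {
  interior <- match.arg(interior)
  if (!is.matrix(frame) || !length(frame)) stopf("`frame` must be a matrix")
  rng <- range(frame)
  if (!is.finite(diff(rng)) || diff(rng) < .Machine$double.eps)
    stopf("no colony detected: frame has no intensity contrast",
          class = "biofilmtfm_no_colony")
  img <- (frame - rng[1]) / diff(rng)
  H <- nrow(img); W <- ncol(img)

  sm <- if (smooth_sigma > 0) {
    EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = smooth_sigma))
  } else img
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))

  bright_mask <- sm >= thr
  mask <- switch(interior,
    bright = bright_mask,
    dark = !bright_mask,
    auto = if (mean(bright_mask) <= 0.5) bright_mask else !bright_mask)
  if (!any(mask) || all(mask))
    stopf("no colony detected: threshold produced an empty segmentation",
          class = "biofilmtfm_no_colony")

  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  areas <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  comp <- EBImage::imageData(lab) == which.max(areas)
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    comp <- EBImage::imageData(EBImage::closing(EBImage::Image(comp * 1), brush)) > 0.5
  }

  # subpixel contours of the smoothed intensity at the threshold level;
  # contourLines treats rows as x and columns as y, so swap on the way out
  cls <- grDevices::contourLines(x = 0:(H - 1), y = 0:(W - 1), z = sm,
                                 levels = thr)
  cands <- list()
  for (cl in cls) {
    poly <- tibble(x_px = cl$y, y_px = cl$x)
    if (nrow(poly) < min_points) next
    # keep contours adjacent to the selected component
    i <- clamp(round(poly$y_px), 0, H - 1) + 1
    j <- clamp(round(poly$x_px), 0, W - 1) + 1
    if (mean(comp[cbind(i, j)]) < 0.25) next
    cands[[length(cands) + 1L]] <- poly
  }
  if (!length(cands))
    stopf("no colony detected: no boundary contour found",
          class = "biofilmtfm_no_colony")

  pick <- if (!is.null(prior) && nrow(prior)) {
    ds <- vapply(cands, function(p) {
      k <- seq(1, nrow(p), length.out = min(nrow(p), 50))
      pk <- p[round(k), ]
      mean(vapply(seq_len(nrow(pk)), function(m)
        min(sqrt((prior$x_px - pk$x_px[m])^2 + (prior$y_px - pk$y_px[m])^2)),
        numeric(1)))
    }, numeric(1))
    which.min(ds)
  } else which.max(vapply(cands, nrow, integer(1)))

  out <- cands[[pick]]
  attr(out, "pixel_size") <- pixel_size
  out
}

#' Least-squares circular-arc fit
#'
#' Fits a circle to boundary points by the algebraic (Kasa) least-squares
#' solution, refined by geometric minimization of the orthogonal radial
#' misfit. Exact on noiseless circle data (including short arcs) and stable
#' under isotropic point noise.
#'
#' @param points data frame with columns `x_px`, `y_px` (or `x`, `y`), in
#'   px; at least 3 non-collinear points.
#' @return An `arc_fit` object: list with `center` (px), `radius` (px),
#'   `residual` (RMS radial misfit, px), `n`, `theta_start`, `theta_width`
#'   (angular span of the data about the fitted center, radians), and the
#'   points used. Supports [generics::tidy()] and [generics::glance()].
#' @export
fit_arc <- function(points) {
  points <- as_tibble(points)
  if (all(c("x_px", "y_px") %in% names(points)))
    points <- dplyr::rename(points, x = "x_px", y = "y_px")
  if (!all(c("x", "y") %in% names(points)))
    stopf("`points` needs columns x_px/y_px or x/y")
  x <- points$x; y <- points$y
  n <- length(x)
  if (n < 3) stopf("need at least 3 points to fit an arc")
  sv <- svd(cbind(x - mean(x), y - mean(y)))$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    stopf("degenerate arc fit: points are collinear",
          class = "biofilmtfm_degenerate_fit")

  # Kasa: x^2 + y^2 + D x + E y + F = 0
  A <- cbind(x, y, 1)
  b <- -(x^2 + y^2)
  coef <- qr.solve(A, b)
  cx <- -coef[1] / 2; cy <- -coef[2] / 2
  R <- sqrt(cx^2 + cy^2 - coef[3])

  # geometric refinement: minimize var of radial distances about the center
  obj <- function(c0) {
    r <- sqrt((x - c0[1])^2 + (y - c0[2])^2)
    sum((r - mean(r))^2)
  }
  opt <- stats::optim(c(cx, cy), obj, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 200))
  cx <- opt$par[1]; cy <- opt$par[2]
  r <- sqrt((x - cx)^2 + (y - cy)^2)
  R <- mean(r)
  residual <- sqrt(mean((r - R)^2))

  ang <- sort(atan2(y - cy, x - cx))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  gi <- which.max(gaps)
  theta_start <- if (gi == n) ang[1] else ang[gi + 1]
  theta_width <- 2 * pi - gaps[gi]

  structure(
    list(center = c(x = cx, y = cy), radius = R, residual = residual,
         n = n, theta_start = theta_start, theta_width = theta_width,
         points = points),
    class = "arc_fit"
  )
}

#' @export
print.arc_fit <- function(x, ...) {
  cat(sprintf(
    "<arc_fit> center (%.2f, %.2f) px, radius %.2f px, RMS residual %.3g px (%d points, span %.0f deg)\n",
    x$center[1], x$center[2], x$radius, x$residual, x$n,
    x$theta_width * 180 / pi))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.arc_fit <- function(x, ...) {
  tibble(term = c("center_x", "center_y", "radius"),
         estimate = c(unname(x$center), x$radius))
}

#' @export
glance.arc_fit <- function(x, ...) {
  tibble(radius_px = x$radius, residual_rms_px = x$residual,
         n_points = x$n, theta_start = x$theta_start,
         theta_width = x$theta_width)
}

# does angle `a` (radians) fall within the arc's angular span?
angle_in_span <- function(a, theta_start, theta_width) {
  if (theta_width >= 2 * pi * 0.98) return(rep(TRUE, length(a)))
  d <- (a - theta_start) %% (2 * pi)
  d <= theta_width
}

#' Radial expansion velocity between two fitted arcs
#'
#' Casts rays from the earlier arc's center across its angular span and
#' averages the radial distance from the earlier arc to its intersection
#' with the later arc's circle; rays whose intersection falls outside the
#' later arc's angular span are excluded. The mean advance divided by the
#' time increment gives the front velocity in mm/hour.
#'
#' @param arc_a,arc_b [fit_arc()] results at times t and t + `dt_min` (px).
#' @param dt_min time increment, minutes (> 0).
#' @param pixel_size um/px.
#' @param n_rays number of rays (>= 1).
#' @return Velocity in mm/hour (negative if the front recedes).
#' @export
radial_velocity <- function(arc_a, arc_b, dt_min, pixel_size, n_rays = 50) {
  stopifnot(inherits(arc_a, "arc_fit"), inherits(arc_b, "arc_fit"))
  if (dt_min <= 0) stopf("`dt_min` must be > 0")
  if (n_rays < 1) stopf("`n_rays` must be >= 1")
  th <- arc_a$theta_start + seq(0, arc_a$theta_width, length.out = n_rays)
  ex <- cos(th); ey <- sin(th)
  # ray c_a + s e; intersect circle b: |c_a + s e - c_b| = R_b (outer root)
  dx <- arc_b$center[1] - arc_a$center[1]
  dy <- arc_b$center[2] - arc_a$center[2]
  proj <- ex * dx + ey * dy
  perp2 <- (dx^2 + dy^2) - proj^2
  disc <- arc_b$radius^2 - perp2
  ok <- disc >= 0
  s <- proj + sqrt(pmax(disc, 0))
  ok <- ok & s > 0
  # intersection point's angle about center b must lie in b's span
  ix <- arc_a$center[1] + s * ex - arc_b$center[1]
  iy <- arc_a$center[2] + s * ey - arc_b$center[2]
  ok <- ok & angle_in_span(atan2(iy, ix), arc_b$theta_start, arc_b$theta_width)
  if (!any(ok))
    stopf("all rays miss the later arc's angular span",
          class = "biofilmtfm_no_rays")
  adv_px <- mean(s[ok] - arc_a$radius)
  adv_px * pixel_size / 1000 / (dt_min / 60)
}

# default imaging windows: squares centered on the frame-0 boundary at
# diagonal angles, mimicking periphery fields of view
default_windows <- function(stack, n_windows = 4, ...) {
  d <- dim(stack$frames[[1]])
  b0 <- detect_boundary(stack$frames[[1]], stack$pixel_size, ...)
  a0 <- fit_arc(b0)
  side <- floor(min(d) / 2)
  ang <- pi / 4 + 2 * pi * (seq_len(n_windows) - 1) / n_windows
  lapply(ang, function(th) {
    cx <- unname(a0$center[1]) + a0$radius * cos(th)
    cy <- unname(a0$center[2]) + a0$radius * sin(th)
    x0 <- clamp(round(cx - side / 2), 0, d[2] - 2)
    y0 <- clamp(round(cy - side / 2), 0, d[1] - 2)
    c(x0 = x0, y0 = y0,
      x1 = min(x0 + side, d[2] - 1), y1 = min(y0 + side, d[1] - 1))
  })
}

#' Colony expansion-velocity curve from an image stack
#'
#' Tracks the colony boundary independently in several imaging windows along
#' the colony periphery, fits circular arcs per frame, and computes radial
#' front velocities over consecutive time increments of `dt_min` (default
#' 20 minutes), assigning each velocity to the interval midpoint. Windows in
#' which detection fails on a needed frame are dropped with a warning.
#'
#' @param stack an [image_stack()] spanning at least `dt_min` minutes.
#' @param windows list of windows `c(x0, y0, x1, y1)` in px, or NULL to
#'   place `n_windows` default windows on the frame-0 boundary.
#' @param n_windows number of default windows.
#' @param dt_min velocity time increment, minutes; must be a multiple of the
#'   stack's frame interval.
#' @param n_rays rays per velocity estimate (see [radial_velocity()]).
#' @param colony_id label recorded in the output.
#' @param ... further arguments to [detect_boundary()].
#' @return A tibble of `ExpansionRecord`s: `colony`, `window`, `time_min`
#'   (increment midpoint), `velocity_mm_per_h`. Summarize across windows
#'   with [expansion_summary()].
#' @export
expansion_curve <- function(stack, windows = NULL, n_windows = 4,
                            dt_min = 20, n_rays = 50,
                            colony_id = "colony", ...) {
  if (n_frames(stack) < 2) stopf("stack must have >= 2 frames")
  total_min <- (n_frames(stack) - 1) * stack$frame_interval
  if (total_min < dt_min)
    stopf("stack spans %g min; need at least `dt_min` = %g min",
          total_min, dt_min)
  k <- dt_min / stack$frame_interval
  if (abs(k - round(k)) > 1e-9)
    stopf("`dt_min` must be a multiple of the frame interval")
  k <- as.integer(round(k))
  if (is.null(windows)) windows <- default_windows(stack, n_windows, ...)

  recs <- list()
  for (w in seq_along(windows)) {
    win <- windows[[w]]
    arcs <- vector("list", n_frames(stack))
    prior <- NULL
    ok <- TRUE
    for (t in seq_len(n_frames(stack))) {
      crop <- stack$frames[[t]][(win["y0"]:win["y1"]) + 1,
                                (win["x0"]:win["x1"]) + 1, drop = FALSE]
      res <- tryCatch({
        b <- detect_boundary(crop, stack$pixel_size, prior = prior, ...)
        a <- fit_arc(b)
        a$center <- a$center + c(win["x0"], win["y0"])
        a
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warn(sprintf("window %d dropped: detection failed at frame %d (%s)",
                     w, t - 1, conditionMessage(res)))
        ok <- FALSE
        break
      }
      arcs[[t]] <- res
      # prior stays in crop coordinates (fit_arc stored the crop-frame points)
      prior <- tibble(x_px = res$points$x, y_px = res$points$y)
    }
    if (!ok) next
    starts <- seq(1, n_frames(stack) - k, by = k)
    for (s in starts) {
      v <- tryCatch(
        radial_velocity(arcs[[s]], arcs[[s + k]], dt_min,
                        stack$pixel_size, n_rays),
        error = function(e) NA_real_)
      recs[[length(recs) + 1L]] <- tibble(
        colony = colony_id, window = w,
        time_min = (s - 1) * stack$frame_interval + dt_min / 2,
        velocity_mm_per_h = v)
    }
  }
  out <- dplyr::bind_rows(recs)
  if (!nrow(out) || dplyr::n_distinct(out$window) < 2)
    stopf("fewer than 2 windows survived boundary detection")
  out
}

#' Mean and SEM of expansion velocity across windows
#'
#' @param records output of [expansion_curve()].
#' @return A tibble with `colony`, `time_min`, `mean_velocity_mm_per_h`,
#'   `sem_velocity_mm_per_h`, `n_windows`.
#' @export
expansion_summary <- function(records) {
  records |>
    dplyr::filter(is.finite(.data$velocity_mm_per_h)) |>
    dplyr::group_by(.data$colony, .data$time_min) |>
    dplyr::summarise(
      mean_velocity_mm_per_h = mean(.data$velocity_mm_per_h),
      sem_velocity_mm_per_h = stats::sd(.data$velocity_mm_per_h) /
        sqrt(dplyr::n()),
      n_windows = dplyr::n(), .groups = "drop")
}
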