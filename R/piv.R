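new_displacement_field <- function(tbl, pixel_size, window_size, overlap,
                                   reference, drift = NULL) {
  tbl <- as_tibble(tbl)
  attr(tbl, "pixel_size") <- pixel_size
  attr(tbl, "window_size") <- window_size
  attr(tbl, "overlap") <- overlap
  attr(tbl, "reference") <- reference
  if (!is.null(drift)) attr(tbl, "drift") <- drift
  class(tbl) <- unique(c("displacement_field", class(tbl)))
  tbl
}

# signed circular shift values for an n-point DFT axis
signed_shifts <- function(n) ((seq_len(n) - 1 + floor(n / 2)) %% n) - floor(n / 2)

# 3-point subpixel peak offset along one axis; Gaussian interpolation with a
# parabolic fallback when a log is undefined
subpixel_offset <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0 && (c0 > cm || c0 > cp)) {
    lm_ <- log(cm); l0 <- log(c0); lp <- log(cp)
    den <- 2 * (lm_ + lp - 2 * l0)
    if (abs(den) > .Machine$double.eps) return((lm_ - lp) / den)
  }
  den <- 2 * (cm + cp - 2 * c0)
  if (abs(den) > .Machine$double.eps) (cm - cp) / den else 0
}

# extract a w x w window with circular indexing (0-based origin y0, x0)
extract_window <- function(frame, y0, x0, w) {
  i <- ((y0 + seq_len(w) - 1) %% nrow(frame)) + 1
  j <- ((x0 + seq_len(w) - 1) %% ncol(frame)) + 1
  frame[i, j]
}

# normalized circular cross-correlation plane of two mean-removed windows
ncc_plane <- function(A, B) {
  w <- nrow(A)
  sa <- stats::sd(A); sb <- stats::sd(B)
  A <- A - mean(A); B <- B - mean(B)
  corr <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B),
                        inverse = TRUE)) / (w * w)
  corr / (w * w * sa * sb)
}

# peak of an ncc plane restricted to |shift| <= max_shift, with quality and
# subpixel interpolation against a local ring baseline
ncc_peak <- function(ncc, max_shift) {
  w <- nrow(ncc)
  sft <- signed_shifts(w)
  allowed <- abs(sft) <= max_shift
  search <- ncc
  search[!allowed, ] <- -Inf
  search[, !allowed] <- -Inf
  pk <- arrayInd(which.max(search), dim(search))
  py <- pk[1]; px_ <- pk[2]
  c1 <- search[py, px_]
  wrap <- function(i) ((i - 1) %% w) + 1
  # second peak outside the primary peak's support
  ny <- wrap((py - 4):(py + 2)); nx <- wrap((px_ - 4):(px_ + 2))
  excl <- search
  excl[ny, nx] <- -Inf
  c2 <- max(excl)
  quality <- if (is.finite(c2) && c2 > 1e-12) c1 / c2 else Inf
  # local clutter baseline: ring of radius 3..5 px about the peak, so the
  # three-point log-Gaussian fit sees the bare peak above its surroundings
  offs <- expand.grid(dy = -5:5, dx = -5:5)
  rr <- sqrt(offs$dy^2 + offs$dx^2)
  ring <- offs[rr >= 3 & rr <= 5, ]
  base <- mean(ncc[cbind(wrap(py + ring$dy), wrap(px_ + ring$dx))])
  cc <- ncc - base
  dy <- sft[py] + subpixel_offset(cc[wrap(py - 1), px_], cc[py, px_],
                                  cc[wrap(py + 1), px_])
  dx <- sft[px_] + subpixel_offset(cc[py, wrap(px_ - 1)], cc[py, px_],
                                   cc[py, wrap(px_ + 1)])
  list(dx = dx, dy = dy, quality = quality)
}

#' Windowed cross-correlation displacement field (PIV)
#'
#' Splits both frames into interrogation windows, cross-correlates each pair
#' via the FFT after mean removal, and locates the correlation peak with
#' three-point Gaussian subpixel interpolation per axis. Vector quality is
#' the ratio of the primary correlation peak to the second-highest peak
#' outside its immediate neighborhood; low-quality or signal-free windows
#' are masked, never fabricated.
#'
#' @param ref,cur numeric matrices of identical shape (reference and current
#'   frame).
#' @param pixel_size um/px.
#' @param window_size interrogation window side, px (>= 16).
#' @param overlap fraction of window overlap in `[0, 1)`.
#' @param max_shift largest detectable shift, px (default `window_size / 4`).
#' @param quality_threshold minimum peak ratio for a vector to pass.
#' @param min_variance minimum window intensity standard deviation (in units
#'   of the frame's intensity range) below which a window is masked.
#' @param median_filter apply the normalized median outlier test across the
#'   vector grid (masks vectors inconsistent with their neighbors).
#' @param median_threshold threshold of the normalized median test.
#' @return A `displacement_field` tibble: `x_um`, `y_um` (window centers),
#'   `ux_um`, `uy_um`, `quality`, `masked`; grid/window metadata in
#'   attributes.
#' @export
piv_displacement <- function(ref, cur, pixel_size, window_size = 32,
                             overlap = 0.5, max_shift = NULL,
                             quality_threshold = 1.5,
                             min_variance = 1e-4,
                             median_filter = TRUE,
                             median_threshold = 2) {
  if (!identical(dim(ref), dim(cur))) stopf("frames must share a shape")
  if (window_size < 16) stopf("`window_size` must be >= 16 px")
  if (overlap < 0 || overlap >= 1) stopf("`overlap` must be in [0, 1)")
  H <- nrow(ref); W <- ncol(ref)
  w <- as.integer(window_size)
  if (w > min(H, W)) stopf("window larger than the frame")
  max_shift <- max_shift %||% floor(w / 4)
  step <- max(1L, as.integer(round(w * (1 - overlap))))
  xs <- seq(0L, W - w, by = step)
  ys <- seq(0L, H - w, by = step)
  range_ref <- diff(range(ref)); range_cur <- diff(range(cur))
  scale0 <- max(range_ref, range_cur, 1)

  rows <- vector("list", length(xs) * length(ys))
  idx <- 0L
  for (y0 in ys) for (x0 in xs) {
    idx <- idx + 1L
    A <- ref[(y0 + 1):(y0 + w), (x0 + 1):(x0 + w)]
    B <- cur[(y0 + 1):(y0 + w), (x0 + 1):(x0 + w)]
    sa <- stats::sd(A); sb <- stats::sd(B)
    cx_um <- (x0 + (w - 1) / 2) * pixel_size
    cy_um <- (y0 + (w - 1) / 2) * pixel_size
    if (!is.finite(sa) || !is.finite(sb) ||
        sa < min_variance * scale0 || sb < min_variance * scale0) {
      rows[[idx]] <- tibble(x_um = cx_um, y_um = cy_um, ux_um = NA_real_,
                            uy_um = NA_real_, quality = NA_real_,
                            masked = TRUE)
      next
    }
    # multi-pass with integer window offset: re-extract the current window
    # at the integer displacement estimate (circular indexing at frame
    # edges) until the residual integer is zero, so the final correlation
    # peak is symmetric about the true subpixel residual
    ox <- 0L; oy <- 0L
    p <- ncc_peak(ncc_plane(A, B), max_shift)
    for (pass in 1:3) {
      rx <- round(p$dx); ry <- round(p$dy)
      if (rx == 0 && ry == 0) break
      ox <- ox + rx; oy <- oy + ry
      B2 <- extract_window(cur, y0 + oy, x0 + ox, w)
      p <- ncc_peak(ncc_plane(A, B2), max_shift)
    }
    dx <- ox + p$dx; dy <- oy + p$dy
    quality <- p$quality
    # near-half-pixel residuals carry the largest interpolation bias, which
    # is antisymmetric in the residual: average with the estimate taken from
    # the neighboring integer offset to cancel it
    if (abs(p$dx) > 0.25 && abs(p$dx) < 0.75) {
      s <- sign(p$dx)
      p2 <- ncc_peak(ncc_plane(A, extract_window(cur, y0 + oy, x0 + ox + s, w)),
                     max_shift)
      if (abs(p2$dx + s - p$dx) < 0.5) dx <- (dx + ox + s + p2$dx) / 2
    }
    if (abs(p$dy) > 0.25 && abs(p$dy) < 0.75) {
      s <- sign(p$dy)
      p2 <- ncc_peak(ncc_plane(A, extract_window(cur, y0 + oy + s, x0 + ox, w)),
                     max_shift)
      if (abs(p2$dy + s - p$dy) < 0.5) dy <- (dy + oy + s + p2$dy) / 2
    }
    bad <- quality < quality_threshold
    rows[[idx]] <- tibble(
      x_um = cx_um, y_um = cy_um,
      ux_um = if (bad) NA_real_ else dx * pixel_size,
      uy_um = if (bad) NA_real_ else dy * pixel_size,
      quality = quality, masked = bad)
  }
  out <- dplyr::bind_rows(rows)
  if (median_filter)
    out <- median_validate(out, length(xs), length(ys), pixel_size,
                           median_threshold)
  new_displacement_field(out, pixel_size, w, overlap, reference = "pair")
}

# normalized median test (Westerweel-Scarano): mask vectors whose residual
# against the median of their 3x3 neighbors, normalized by the median
# absolute neighbor fluctuation plus a noise floor (0.1 px), exceeds the
# threshold; ambiguous correlation peaks in sparse windows show up here
median_validate <- function(tb, nx, ny, pixel_size, threshold,
                            noise_floor_px = 0.1) {
  U <- matrix(tb$ux_um, ny, nx, byrow = TRUE) / pixel_size
  V <- matrix(tb$uy_um, ny, nx, byrow = TRUE) / pixel_size
  flag <- matrix(FALSE, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    if (is.na(U[i, j])) next
    ii <- max(1, i - 1):min(ny, i + 1)
    jj <- max(1, j - 1):min(nx, j + 1)
    for (M in list(U, V)) {
      nb <- M[ii, jj]
      nb <- nb[!is.na(nb)]
      nb <- nb[-which.min(abs(nb - M[i, j]))]  # drop self (closest value)
      if (length(nb) < 3) next
      med <- stats::median(nb)
      fluct <- stats::median(abs(nb - med))
      if (abs(M[i, j] - med) / (fluct + noise_floor_px) > threshold)
        flag[i, j] <- TRUE
    }
  }
  bad <- as.vector(t(flag))
  tb$masked[bad] <- TRUE
  tb$ux_um[bad] <- NA_real_
  tb$uy_um[bad] <- NA_real_
  tb
}

#' Displacement-field series from an image stack
#'
#' In `"first_frame"` (accumulated) mode each frame is correlated directly
#' against frame 0 — no integration of instantaneous fields is performed. In
#' `"previous_frame"` (instantaneous) mode each frame is correlated against
#' its predecessor.
#'
#' @param stack an [image_stack()] with >= 2 frames.
#' @param mode `"first_frame"` or `"previous_frame"`.
#' @param decorrelation_quality frames whose median vector quality falls
#'   below this are flagged in the `flagged_frames` attribute.
#' @inheritParams piv_displacement
#' @param ... further arguments to [piv_displacement()].
#' @return A `displacement_field` tibble with a `frame` column (one block
#'   per frame `1 .. n-1`), reference mode in attributes.
#' @export
accumulate_series <- function(stack, mode = c("first_frame", "previous_frame"),
                              window_size = 32, overlap = 0.5,
                              decorrelation_quality = 1.2, ...) {
  mode <- match.arg(mode)
  n <- n_frames(stack)
  if (n < 2) stopf("stack must have >= 2 frames")
  out <- vector("list", n - 1)
  flagged <- integer()
  for (t in seq_len(n - 1)) {
    ref <- if (mode == "first_frame") stack$frames[[1]] else stack$frames[[t]]
    f <- piv_displacement(ref, stack$frames[[t + 1]], stack$pixel_size,
                          window_size, overlap, ...)
    mq <- stats::median(f$quality, na.rm = TRUE)
    if (!is.finite(mq) || mq < decorrelation_quality) flagged <- c(flagged, t)
    out[[t]] <- dplyr::mutate(f, frame = t, .before = 1)
  }
  res <- new_displacement_field(dplyr::bind_rows(out), stack$pixel_size,
                                window_size, overlap, reference = mode)
  attr(res, "flagged_frames") <- flagged
  res
}

#' Subtract stage drift measured in a stress-free region
#'
#' Estimates rigid stage drift as the mean displacement vector over a
#' rectangular region far from the colony (per frame, if the field carries a
#' `frame` column) and subtracts it from every vector. The subtracted drift
#' is recorded in the result's `drift` attribute.
#'
#' @param field a `displacement_field` tibble.
#' @param stress_free_region rectangle `c(x0, y0, x1, y1)` in um.
#' @return The corrected field, with attribute `drift` (tibble `frame`,
#'   `drift_x_um`, `drift_y_um`).
#' @export
drift_correct <- function(field, stress_free_region) {
  r <- stress_free_region
  if (length(r) != 4) stopf("`stress_free_region` must be c(x0, y0, x1, y1)")
  has_frame <- "frame" %in% names(field)
  fr_col <- if (has_frame) field$frame else rep(0L, nrow(field))
  in_region <- field$x_um >= r[1] & field$x_um <= r[3] &
    field$y_um >= r[2] & field$y_um <= r[4] & !field$masked
  drifts <- list()
  out <- field
  for (f in unique(fr_col)) {
    sel <- in_region & fr_col == f
    if (sum(sel) < 4)
      stopf("stress-free region holds %d valid vectors in frame %s; need >= 4",
            sum(sel), f)
    dx <- mean(field$ux_um[sel]); dy <- mean(field$uy_um[sel])
    rows <- fr_col == f
    out$ux_um[rows] <- field$ux_um[rows] - dx
    out$uy_um[rows] <- field$uy_um[rows] - dy
    drifts[[length(drifts) + 1L]] <-
      tibble(frame = f, drift_x_um = dx, drift_y_um = dy)
  }
  attr(out, "drift") <- dplyr::bind_rows(drifts)
  out
}

# reshape one frame of a field into matrices on its regular grid
field_matrices <- function(field) {
  xs <- sort(unique(field$x_um)); ys <- sort(unique(field$y_um))
  U <- matrix(NA_real_, length(ys), length(xs))
  V <- U
  i <- match(field$y_um, ys); j <- match(field$x_um, xs)
  U[cbind(i, j)] <- field$ux_um
  V[cbind(i, j)] <- field$uy_um
  list(xs = xs, ys = ys, U = U, V = V)
}

#' Divergence of a displacement field
#'
#' Computes `div u = d(ux)/dx + d(uy)/dy` by central finite differences on
#' interior grid nodes and one-sided differences at the grid edges (flagged
#' `boundary = TRUE`). Both u and the grid are in um, so the divergence is
#' unitless.
#'
#' @param field a `displacement_field` tibble on a regular grid (a `frame`
#'   column is handled per frame); masked vectors propagate NA.
#' @return A `divergence_field` tibble: `frame` (if present), `x_um`,
#'   `y_um`, `div`, `boundary`.
#' @export
divergence <- function(field) {
  has_frame <- "frame" %in% names(field)
  split_fields <- if (has_frame) split(field, field$frame) else list(field)
  out <- lapply(split_fields, function(fd) {
    m <- field_matrices(fd)
    nx <- length(m$xs); ny <- length(m$ys)
    if (nx < 3 || ny < 3) stopf("divergence needs at least a 3 x 3 grid")
    dx <- diff(m$xs[1:2]); dy <- diff(m$ys[1:2])
    dudx <- matrix(NA_real_, ny, nx)
    dvdy <- matrix(NA_real_, ny, nx)
    dudx[, 2:(nx - 1)] <- (m$U[, 3:nx] - m$U[, 1:(nx - 2)]) / (2 * dx)
    dudx[, 1] <- (m$U[, 2] - m$U[, 1]) / dx
    dudx[, nx] <- (m$U[, nx] - m$U[, nx - 1]) / dx
    dvdy[2:(ny - 1), ] <- (m$V[3:ny, ] - m$V[1:(ny - 2), ]) / (2 * dy)
    dvdy[1, ] <- (m$V[2, ] - m$V[1, ]) / dy
    dvdy[ny, ] <- (m$V[ny, ] - m$V[ny - 1, ]) / dy
    bnd <- matrix(FALSE, ny, nx)
    bnd[c(1, ny), ] <- TRUE; bnd[, c(1, nx)] <- TRUE
    g <- tidyr::expand_grid(y_um = m$ys, x_um = m$xs)
    res <- tibble(x_um = g$x_um, y_um = g$y_um,
                  div = as.vector(t(dudx + dvdy)),
                  boundary = as.vector(t(bnd)))
    if (has_frame) res <- dplyr::mutate(res, frame = fd$frame[1], .before = 1)
    res
  })
  res <- dplyr::bind_rows(out)
  class(res) <- unique(c("divergence_field", class(res)))
  attr(res, "pixel_size") <- attr(field, "pixel_size")
  res
}

#' Radial divergence profile about the colony edge
#'
#' Azimuthally averages the divergence as a function of signed distance from
#' the colony edge (negative inside the colony), per frame — the natural
#' coordinate for a divergence wave co-moving with the expanding front.
#'
#' @param div_field a `divergence_field` (see [divergence()]) with a `frame`
#'   column or a single frame.
#' @param boundary tibble with per-frame `frame`, `radius_um`,
#'   `center_x_um`, `center_y_um` (e.g. generator ground truth, or arc fits
#'   converted to um).
#' @param bin_width_um radial bin width; defaults to the divergence grid
#'   spacing.
#' @return A tibble `frame`, `dist_um` (bin center), `div_mean`, `n`.
#' @export
divergence_wave_profile <- function(div_field, boundary, bin_width_um = NULL) {
  has_frame <- "frame" %in% names(div_field)
  if (!has_frame) div_field <- dplyr::mutate(div_field, frame = 0L)
  if (!"frame" %in% names(boundary)) boundary <- dplyr::mutate(boundary, frame = 0L)
  if (is.null(bin_width_um)) {
    xs <- sort(unique(div_field$x_um))
    bin_width_um <- if (length(xs) > 1) diff(xs[1:2]) else 1
  }
  dplyr::inner_join(div_field, boundary, by = "frame") |>
    dplyr::mutate(
      dist_um = sqrt((.data$x_um - .data$center_x_um)^2 +
                     (.data$y_um - .data$center_y_um)^2) - .data$radius_um,
      bin = round(.data$dist_um / bin_width_um)) |>
    dplyr::filter(is.finite(.data$div)) |>
    dplyr::group_by(.data$frame, .data$bin) |>
    dplyr::summarise(dist_um = .data$bin[1] * bin_width_um,
                     div_mean = mean(.data$div), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::select(!"bin")
}

#' Peak of the divergence wave per frame
#'
#' @param profile output of [divergence_wave_profile()].
#' @return A tibble `frame`, `peak_dist_um` (signed distance of the peak
#'   from the colony edge), `peak_div` (signed value at the peak).
#' @export
divergence_wave_peaks <- function(profile) {
  profile |>
    dplyr::group_by(.data$frame) |>
    dplyr::slice_max(abs(.data$div_mean), n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("frame", peak_dist_um = "dist_um", peak_div = "div_mean")
}
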