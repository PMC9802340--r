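# shared fixture builders; everything is generated in code at test time

# circular shift of a matrix: content moves by (+dx, +dy) in pixel coords
shift_mat <- function(m, dx, dy) {
  i <- ((seq_len(nrow(m)) - 1 - dy) %% nrow(m)) + 1
  j <- ((seq_len(ncol(m)) - 1 - dx) %% ncol(m)) + 1
  m[i, j]
}

# smooth random texture with correlation length ~sigma px
blurred_noise <- function(n, seed, sigma = 1.5) {
  set.seed(seed)
  raw <- matrix(stats::rnorm(n * n), n)
  sm <- EBImage::imageData(EBImage::gblur(EBImage::Image(raw), sigma = sigma))
  matrix(sm, n) * 1000 + 20000
}

# displacement field tibble from closed-form component functions (um)
mkfield <- function(xs, fx, fy) {
  g <- tidyr::expand_grid(y_um = xs, x_um = xs)
  tibble::tibble(x_um = g$x_um, y_um = g$y_um,
                 ux_um = fx(g$x_um, g$y_um), uy_um = fy(g$x_um, g$y_um),
                 quality = 2, masked = FALSE)
}

# force-balanced contractile traction patch with Gaussian envelope:
# traction points inward toward the patch center, magnitude amp * envelope
contractile_patch <- function(n = 48, spacing = 8, amp = 60, sigma = 40) {
  xs <- (seq_len(n) - 1) * spacing
  cx <- max(xs) / 2
  g <- tidyr::expand_grid(y_um = xs, x_um = xs)
  r <- sqrt((g$x_um - cx)^2 + (g$y_um - cx)^2)
  env <- amp * exp(-r^2 / (2 * sigma^2))
  rs <- pmax(r, 1e-9)
  tau <- tibble::tibble(
    x_um = g$x_um, y_um = g$y_um,
    tx_pa = -env * (g$x_um - cx) / rs,
    ty_pa = -env * (g$y_um - cx) / rs)
  tau$tmag_pa <- sqrt(tau$tx_pa^2 + tau$ty_pa^2)
  tau
}

# radial displacement field whose divergence is a Gaussian annulus of
# magnitude A at radius r_edge (width w um): u_r = (1/r) \int_0^r s D(s) ds
annulus_field <- function(xs, center, r_edge, A = 0.015, w = 30) {
  rr <- seq(0, max(xs) * 1.6, by = 0.5)
  D <- A * exp(-(rr - r_edge)^2 / (2 * w^2))
  integ <- cumsum(c(0, diff(rr) *
                      (rr[-1] * D[-1] + rr[-length(rr)] * D[-length(rr)]) / 2))
  urf <- stats::approxfun(rr, ifelse(rr < 1e-9, 0, integ / pmax(rr, 1e-9)))
  g <- tidyr::expand_grid(y_um = xs, x_um = xs)
  r <- sqrt((g$x_um - center)^2 + (g$y_um - center)^2)
  ur <- urf(r)
  tibble::tibble(
    x_um = g$x_um, y_um = g$y_um,
    ux_um = ifelse(r < 1e-9, 0, ur * (g$x_um - center) / r),
    uy_um = ifelse(r < 1e-9, 0, ur * (g$y_um - center) / r),
    quality = 2, masked = FALSE)
}

field_rms_px <- function(ux_um, uy_um, pixel_size) {
  sqrt(mean((ux_um / pixel_size)^2 + (uy_um / pixel_size)^2))
}

rel_rms <- function(est_x, est_y, true_x, true_y) {
  sqrt(mean((est_x - true_x)^2 + (est_y - true_y)^2)) /
    sqrt(mean(true_x^2 + true_y^2))
}
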