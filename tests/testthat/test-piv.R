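# one bead stack reused across several blocks (rendered once for speed)
beads_drift04 <- local({
  bs <- bead_scenario(seed = 3)
  m <- displacement_model(drift_per_frame = c(0.8, 0))  # 0.4 px at 2 um/px
  generate_bead_stack(bs, m, 2)
})

test_that("identical frames give an exactly zero field", {
  ref <- blurred_noise(128, seed = 7)
  f <- piv_displacement(ref, ref, pixel_size = 1)
  expect_true(all(!f$masked))
  expect_lt(max(abs(c(f$ux_um, f$uy_um))), 1e-12)
})

test_that("integer circular shifts are recovered within 0.05 px everywhere", {
  for (tex in list(blurred_noise(256, seed = 7),
                   beads_drift04$stack$frames[[1]])) {
    cur <- shift_mat(tex, 3, -2)
    f <- piv_displacement(tex, cur, pixel_size = 1)
    ok <- !f$masked
    expect_gt(mean(ok), 0.9)
    expect_lt(max(abs(f$ux_um[ok] - 3)), 0.05)
    expect_lt(max(abs(f$uy_um[ok] + 2)), 0.05)
  }
})

test_that("flat windows are masked, not fabricated", {
  flat <- matrix(5000, 64, 64)
  f <- piv_displacement(flat, flat, pixel_size = 1)
  expect_true(all(f$masked))
  expect_true(all(is.na(f$ux_um)))
})

test_that("a rendered 0.4 px uniform displacement is recovered to 0.1 px RMS", {
  g <- beads_drift04
  f <- piv_displacement(g$stack$frames[[1]], g$stack$frames[[2]],
                        pixel_size = 2)
  ok <- !f$masked
  expect_gt(mean(ok), 0.95)
  err <- field_rms_px(f$ux_um[ok] - 0.8, f$uy_um[ok], 2)
  expect_lt(err, 0.1)
})

test_that("PIV is equivariant under frame translation", {
  ref <- beads_drift04$stack$frames[[1]]
  # translating both frames leaves the field unchanged
  f0 <- piv_displacement(ref, shift_mat(ref, 2, 1), pixel_size = 1)
  f1 <- piv_displacement(shift_mat(ref, 5, -4),
                         shift_mat(shift_mat(ref, 2, 1), 5, -4),
                         pixel_size = 1)
  both <- !f0$masked & !f1$masked
  expect_gt(mean(both), 0.9)
  expect_equal(f1$ux_um[both], f0$ux_um[both], tolerance = 0.05)
  expect_equal(f1$uy_um[both], f0$uy_um[both], tolerance = 0.05)
  # translating only `cur` adds that vector
  f2 <- piv_displacement(ref, shift_mat(ref, 3, 0), pixel_size = 1)
  ok <- !f2$masked
  expect_lt(max(abs(f2$ux_um[ok] - 3)), 0.05)
})

test_that("accumulated and instantaneous series behave per reference mode", {
  ref <- beads_drift04$stack$frames[[1]]
  d <- c(2, -1)
  stack <- image_stack(list(ref, shift_mat(ref, d[1], d[2]),
                            shift_mat(ref, 2 * d[1], 2 * d[2])),
                       pixel_size = 1, frame_interval = 10, channel = "beads")
  acc <- accumulate_series(stack, "first_frame")
  ins <- accumulate_series(stack, "previous_frame")
  for (fr in 1:2) {
    a <- dplyr::filter(acc, frame == fr, !masked)
    expect_lt(max(abs(a$ux_um - fr * d[1])), 0.05)
    expect_lt(max(abs(a$uy_um - fr * d[2])), 0.05)
    i <- dplyr::filter(ins, frame == fr, !masked)
    expect_lt(max(abs(i$ux_um - d[1])), 0.05)
    expect_lt(max(abs(i$uy_um - d[2])), 0.05)
  }
  # the two modes agree on a 2-frame stack
  two <- image_stack(stack$frames[1:2], 1, 10, "beads")
  fa <- accumulate_series(two, "first_frame")
  fp <- accumulate_series(two, "previous_frame")
  expect_equal(fa$ux_um, fp$ux_um)
  expect_equal(fa$uy_um, fp$uy_um)
  expect_equal(fa$quality, fp$quality)
})

test_that("a static stack yields zero fields in both modes", {
  ref <- blurred_noise(128, seed = 11)
  stack <- image_stack(list(ref, ref, ref), 1, 10, "beads")
  for (mode in c("first_frame", "previous_frame")) {
    f <- accumulate_series(stack, mode)
    expect_lt(max(abs(c(f$ux_um, f$uy_um))), 1e-12)
  }
})

test_that("accumulated fields track a contractile model within 0.1 px RMS", {
  m <- displacement_model(contractile_amplitude = 0.5,
                          contractile_center = c(255, 255),
                          contractile_length_scale = 150)
  g <- generate_bead_stack(bead_scenario(seed = 6), m, 3)
  s <- accumulate_series(g$stack, "first_frame")
  for (fr in 1:2) {
    sel <- dplyr::filter(s, frame == fr, !masked)
    tr <- g$truth$displacement_fn(data.frame(x = sel$x_um, y = sel$y_um), fr)
    expect_lt(field_rms_px(sel$ux_um - tr$ux, sel$uy_um - tr$uy, 2), 0.1)
  }
})

test_that("drift correction subtracts the stress-free mean and is idempotent", {
  xs <- seq(0, 310, by = 10)
  f <- mkfield(xs, function(x, y) 0.8 + 0 * x, function(x, y) -0.3 + 0 * x)
  c1 <- drift_correct(f, c(0, 0, 100, 100))
  expect_lt(max(abs(c(c1$ux_um, c1$uy_um))), 1e-12)
  expect_equal(attr(c1, "drift")$drift_x_um, 0.8)
  expect_equal(attr(c1, "drift")$drift_y_um, -0.3)
  c2 <- drift_correct(c1, c(0, 0, 100, 100))
  expect_lt(max(abs(attr(c2, "drift")$drift_x_um)), 1e-12)
  expect_error(drift_correct(f, c(1000, 1000, 1100, 1100)), "valid vectors")
})

test_that("pure-drift stacks reduce to < 0.05 px residual after correction", {
  m <- displacement_model(drift_per_frame = c(1.5, 0))
  g <- generate_bead_stack(bead_scenario(seed = 5), m, 3)
  s <- accumulate_series(g$stack, "first_frame", window_size = 64)
  dc <- drift_correct(s, c(0, 0, 510, 510))
  ok <- !dc$masked
  expect_lt(field_rms_px(dc$ux_um[ok], dc$uy_um[ok], 2), 0.05)
  dr <- attr(dc, "drift")
  expect_lt(max(abs(dr$drift_x_um - 1.5 * dr$frame) / 2), 0.05)  # px units
  expect_lt(max(abs(dr$drift_y_um) / 2), 0.05)
})

test_that("drift correction recovers the drift-free field of a mixed model", {
  m <- displacement_model(contractile_amplitude = 0.4,
                          contractile_center = c(255, 255),
                          contractile_length_scale = 120,
                          drift_per_frame = c(0.9, -0.6))
  g <- generate_bead_stack(bead_scenario(seed = 12), m, 3)
  m0 <- displacement_model(contractile_amplitude = 0.4,
                           contractile_center = c(255, 255),
                           contractile_length_scale = 120)
  s <- accumulate_series(g$stack, "first_frame", window_size = 64)
  # stress-free corner: contraction there is negligible but not exactly zero,
  # mirroring the 'far from the biofilm' region of real assays
  dc <- drift_correct(s, c(0, 0, 160, 160))
  for (fr in 1:2) {
    sel <- dplyr::filter(dc, frame == fr, !masked)
    tr <- evaluate_displacement_model(m0, data.frame(x = sel$x_um,
                                                     y = sel$y_um), fr)
    resid <- cbind(sel$ux_um - tr$ux, sel$uy_um - tr$uy)
    # allow the residual constant offset equal to the (small) true
    # contraction averaged over the reference region
    resid <- sweep(resid, 2, colMeans(resid))
    expect_lt(field_rms_px(resid[, 1], resid[, 2], 2), 0.1)
  }
})

test_that("divergence matches closed forms and flags edges", {
  xs <- seq(0, 310, by = 10)
  d1 <- divergence(mkfield(xs, function(x, y) x, function(x, y) y))
  expect_true(all(abs(d1$div - 2) < 1e-12))
  expect_equal(sum(d1$boundary), 4 * length(xs) - 4)
  # rigid motions: translation and small rotation
  d2 <- divergence(mkfield(xs, function(x, y) 5 + 0 * x,
                           function(x, y) -3 + 0 * x))
  expect_lt(max(abs(d2$div)), 1e-12)
  d3 <- divergence(mkfield(xs, function(x, y) -0.01 * y,
                           function(x, y) 0.01 * x))
  expect_lt(max(abs(d3$div)), 1e-12)
  expect_error(divergence(mkfield(c(0, 10), function(x, y) x,
                                  function(x, y) y)), "3 x 3")
})

test_that("divergence is linear and second-order accurate on a Gaussian", {
  xs <- seq(0, 400, by = 8)
  cx <- 200; s <- 60
  fx <- function(x, y) exp(-((x - cx)^2 + (y - cx)^2) / (2 * s^2)) * (x - cx)
  fy <- function(x, y) exp(-((x - cx)^2 + (y - cx)^2) / (2 * s^2)) * (y - cx)
  fd <- mkfield(xs, fx, fy)
  dv <- divergence(fd)
  r2 <- (dv$x_um - cx)^2 + (dv$y_um - cx)^2
  analytic <- exp(-r2 / (2 * s^2)) * (2 - r2 / s^2)
  interior <- !dv$boundary
  h <- 8
  # second-order central differences: error bounded by h^2/6 * max|f'''|
  max_f3 <- max(abs(analytic)) * 3 / s  # loose scale bound for the bound
  expect_lt(max(abs(dv$div[interior] - analytic[interior])),
            h^2 * max_f3)
  # linearity in the field
  fd2 <- mkfield(xs, function(x, y) 2 * fx(x, y) + 10,
                 function(x, y) 2 * fy(x, y) - 4)
  dv2 <- divergence(fd2)
  expect_equal(dv2$div, 2 * dv$div, tolerance = 1e-12)
})

test_that("the divergence wave profile finds an edge-locked annulus", {
  xs <- seq(0, 1000, by = 16)
  center <- 500
  peaks <- purrr::map_dfr(1:3, function(i) {
    r_edge <- 200 + 50 * i
    fd <- annulus_field(xs, center, r_edge)
    fd$frame <- i
    dv <- divergence(fd)
    prof <- divergence_wave_profile(
      dv, tibble::tibble(frame = i, radius_um = r_edge,
                         center_x_um = center, center_y_um = center))
    divergence_wave_peaks(prof)
  })
  expect_true(all(abs(peaks$peak_div - 0.015) / 0.015 < 0.1))
  expect_true(all(abs(peaks$peak_dist_um) <= 16))  # within one grid spacing
})

test_that("a divergence-free field gives a flat profile", {
  xs <- seq(0, 640, by = 16)
  fd <- mkfield(xs, function(x, y) -0.02 * (y - 320),
                function(x, y) 0.02 * (x - 320))
  prof <- divergence_wave_profile(
    divergence(fd), tibble::tibble(radius_um = 150, center_x_um = 320,
                                   center_y_um = 320))
  expect_lt(max(abs(prof$div_mean)), 1e-12)
})

test_that("a static annulus recedes linearly from an advancing edge", {
  xs <- seq(0, 1000, by = 16)
  center <- 500
  fd0 <- annulus_field(xs, center, r_edge = 250)
  dv0 <- divergence(fd0)
  dists <- vapply(0:3, function(i) {
    edge <- 250 + 40 * i
    prof <- divergence_wave_profile(
      dv0, tibble::tibble(radius_um = edge, center_x_um = center,
                          center_y_um = center))
    divergence_wave_peaks(prof)$peak_dist_um
  }, numeric(1))
  steps <- diff(dists)
  expect_true(all(abs(steps + 40) <= 16))
})
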