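test_that("static colony with no noise renders identical frames", {
  sc <- colony_scenario(radial_speed = 0, noise_sd = 0, n_frames = 3,
                        image_shape = c(128, 128), initial_radius = 60,
                        pixel_size = 2)
  g <- generate_colony_stack(sc)
  expect_identical(g$stack$frames[[1]], g$stack$frames[[2]])
  expect_identical(g$stack$frames[[1]], g$stack$frames[[3]])
})

test_that("true radius grows by radial_speed * frame_interval per frame", {
  sc <- colony_scenario(initial_radius = 100, radial_speed = 5,
                        frame_interval = 10, n_frames = 4)
  g <- generate_colony_stack(sc)
  expect_equal(g$truth$boundary$radius_um, c(100, 150, 200, 250))
})

test_that("a time-varying speed integrates to the correct radius", {
  sc <- colony_scenario(initial_radius = 100,
                        radial_speed = function(t) 2 + 0.1 * t,
                        frame_interval = 10, n_frames = 3)
  g <- generate_colony_stack(sc)
  # R(t) = 100 + 2 t + 0.05 t^2
  expect_equal(g$truth$boundary$radius_um, c(100, 125, 160), tolerance = 1e-6)
})

test_that("rendered boundary reproduces the Fourier roughness within 0.5 um", {
  sc <- colony_scenario(initial_radius = 200, radial_speed = 0,
                        roughness_amplitude = 5, roughness_wavenumber = 8,
                        noise_sd = 0, n_frames = 2, pixel_size = 2,
                        image_shape = c(512, 512))
  g <- generate_colony_stack(sc)
  img <- g$stack$frames[[1]]
  cx <- g$truth$boundary$center_x_um[1]; cy <- g$truth$boundary$center_y_um[1]
  mid <- (sc$interior_intensity + sc$exterior_intensity) / 2
  # brute-force radial scan of the rendered image, bilinear-sampled
  bilin <- function(px, py) {
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    img[cbind(y0 + 1, x0 + 1)] * (1 - fx) * (1 - fy) +
      img[cbind(y0 + 1, x0 + 2)] * fx * (1 - fy) +
      img[cbind(y0 + 2, x0 + 1)] * (1 - fx) * fy +
      img[cbind(y0 + 2, x0 + 2)] * fx * fy
  }
  thetas <- seq(0, 2 * pi, length.out = 181)[-181]
  dev <- vapply(thetas, function(th) {
    rs <- seq(150, 250, by = 0.2)
    vals <- bilin((cx + rs * cos(th)) / sc$pixel_size,
                  (cy + rs * sin(th)) / sc$pixel_size)
    i <- which(vals < mid)[1]
    # subpixel crossing of the mid level between samples i-1 and i
    f <- (vals[i - 1] - mid) / (vals[i - 1] - vals[i])
    rs[i - 1] + f * 0.2 - 200
  }, numeric(1))
  expect_equal(max(abs(dev)), 5, tolerance = 0.5 / 5)
  # and the rasterized boundary tracks r(theta) everywhere within 1 px
  rb <- g$truth$boundary_radius_fn(thetas, 0)
  expect_lt(max(abs(dev - (rb - 200))), 2 * sc$pixel_size / 2)
})

test_that("identical scenarios and seeds give bit-identical stacks", {
  sc <- colony_scenario(noise_sd = 500, n_frames = 3, seed = 9, radial_speed = 2,
                        image_shape = c(128, 128), initial_radius = 60)
  g1 <- generate_colony_stack(sc)
  g2 <- generate_colony_stack(sc)
  expect_identical(g1$stack$frames, g2$stack$frames)

  bs <- bead_scenario(noise_sd = 100, image_shape = c(128, 128), seed = 4)
  m <- displacement_model(drift_per_frame = c(0.3, -0.2))
  b1 <- generate_bead_stack(bs, m, 3)
  b2 <- generate_bead_stack(bs, m, 3)
  expect_identical(b1$stack$frames, b2$stack$frames)
})

test_that("a colony outgrowing the field fails with the offending frame", {
  sc <- colony_scenario(initial_radius = 100, radial_speed = 20,
                        frame_interval = 10, n_frames = 5,
                        image_shape = c(128, 128), pixel_size = 2)
  expect_error(generate_colony_stack(sc), class = "biofilmtfm_bounds_error")
  expect_error(generate_colony_stack(sc), "frame")
})

test_that("displacement model superposes and matches its closed forms", {
  hs <- data.frame(x = 100, y = 80, scale = 20, amplitude = 2,
                   onset = 1, duration = 2)
  full <- displacement_model(contractile_amplitude = 0.5,
                             contractile_center = c(50, 50),
                             contractile_length_scale = 80,
                             hotspots = hs, drift_per_frame = c(0.8, -0.3))
  only_c <- displacement_model(contractile_amplitude = 0.5,
                               contractile_center = c(50, 50),
                               contractile_length_scale = 80)
  only_h <- displacement_model(hotspots = hs, contractile_center = c(50, 50))
  only_d <- displacement_model(drift_per_frame = c(0.8, -0.3))
  pts <- data.frame(x = c(0, 30, 100, 120), y = c(0, 70, 80, 10))
  for (f in 0:2) {
    u <- evaluate_displacement_model(full, pts, f)
    us <- evaluate_displacement_model(only_c, pts, f)
    uh <- evaluate_displacement_model(only_h, pts, f)
    ud <- evaluate_displacement_model(only_d, pts, f)
    expect_equal(u$ux, us$ux + uh$ux + ud$ux)
    expect_equal(u$uy, us$uy + uh$uy + ud$uy)
  }
  # drift-only model returns the drift at any point, zero at frame 0
  u0 <- evaluate_displacement_model(only_d, pts, 0)
  expect_true(all(u0$ux == 0 & u0$uy == 0))
  u1 <- evaluate_displacement_model(only_d, pts, 1)
  expect_true(all(u1$ux == 0.8 & u1$uy == -0.3))
  # all-zero model is identically zero
  z <- evaluate_displacement_model(displacement_model(), pts, 3)
  expect_true(all(z$ux == 0 & z$uy == 0))
})

test_that("contractile term is centrally symmetric", {
  m <- displacement_model(contractile_amplitude = 1,
                          contractile_center = c(100, 100),
                          contractile_length_scale = 50)
  pts <- data.frame(x = c(160, 40), y = c(100, 100))  # mirror pair
  u <- evaluate_displacement_model(m, pts, 1)
  expect_equal(u$ux[1], -u$ux[2])
  expect_equal(u$uy[1], u$uy[2])
  expect_equal(sqrt(u$ux[1]^2 + u$uy[1]^2), sqrt(u$ux[2]^2 + u$uy[2]^2))
  # magnitude peaks at exactly the amplitude at r = L
  upk <- evaluate_displacement_model(m, data.frame(x = 150, y = 100), 1)
  expect_equal(sqrt(upk$ux^2 + upk$uy^2), 1)
  expect_equal(upk$ux, -1)
})

test_that("a zero model with no noise gives bit-identical bead frames", {
  bs <- bead_scenario(noise_sd = 0, image_shape = c(128, 128), seed = 5)
  g <- generate_bead_stack(bs, displacement_model(), 3)
  expect_identical(g$stack$frames[[1]], g$stack$frames[[2]])
  expect_identical(g$stack$frames[[1]], g$stack$frames[[3]])
})

test_that("pure drift shows up at the full-frame cross-correlation peak", {
  # 1.5 um/frame at 1.5 um/px = exactly 1 px/frame
  bs <- bead_scenario(pixel_size = 1.5, image_shape = c(256, 256), seed = 6)
  m <- displacement_model(drift_per_frame = c(1.5, 0))
  g <- generate_bead_stack(bs, m, 2)
  A <- g$stack$frames[[1]]; B <- g$stack$frames[[2]]
  A <- A - mean(A); B <- B - mean(B)
  corr <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE))
  pk <- arrayInd(which.max(corr), dim(corr))
  n <- nrow(A)
  sgn <- function(i) ((i - 1 + floor(n / 2)) %% n) - floor(n / 2)
  expect_identical(c(sgn(pk[2]), sgn(pk[1])), c(1, 0))
})

test_that("hotspots reach their amplitude at the center only when active", {
  bs <- bead_scenario(image_shape = c(128, 128), seed = 7)
  # center on a ground-truth grid node (spacing 16 px * 2 um/px = 32 um)
  hs <- data.frame(x = 128, y = 128, scale = 20, amplitude = 2,
                   onset = 1, duration = 2)
  m <- displacement_model(hotspots = hs)
  g <- generate_bead_stack(bs, m, 4)
  mag <- function(f) {
    gg <- dplyr::filter(g$truth$grid, frame == f)
    max(sqrt(gg$ux_um^2 + gg$uy_um^2))
  }
  expect_equal(mag(0), 0)
  expect_equal(mag(1), 2)
  expect_equal(mag(2), 2)
  expect_equal(mag(3), 0)
  at_center <- dplyr::filter(g$truth$grid, frame == 1,
                             x_um == 128, y_um == 128)
  expect_equal(sqrt(at_center$ux_um^2 + at_center$uy_um^2), 2)
})

test_that("beads displaced out of frame are clipped but flagged", {
  bs <- bead_scenario(image_shape = c(64, 64), seed = 8)
  m <- displacement_model(drift_per_frame = c(40, 0))
  g <- generate_bead_stack(bs, m, 3)
  expect_gt(nrow(g$truth$clipped), 0)
  expect_true(all(g$truth$clipped$frame > 0))
})

test_that("degenerate bead scenarios error", {
  tiny <- bead_scenario(bead_density = 1e-9, image_shape = c(64, 64))
  expect_error(generate_bead_stack(tiny, displacement_model(), 2), "zero beads")
  bs <- bead_scenario(image_shape = c(64, 64))
  expect_error(generate_bead_stack(bs, displacement_model(), 1), "n_frames")
  expect_error(bead_scenario(bead_diameter = 0), "bead_diameter")
})

test_that("stacks round-trip through 16-bit TIFF", {
  sc <- colony_scenario(n_frames = 2, image_shape = c(64, 64), radial_speed = 2,
                        initial_radius = 30, noise_sd = 300, pixel_size = 2)
  g <- generate_colony_stack(sc)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack(g$stack, path)
  rt <- read_stack(path, 2, 10)
  expect_equal(n_frames(rt), 2)
  expect_equal(rt$frames[[1]], g$stack$frames[[1]], tolerance = 1e-9)
})
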