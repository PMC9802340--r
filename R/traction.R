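#' Elastic substrate specification
#'
#' Material description of the gel: shear storage modulus G' (the quantity
#' measured by oscillatory rheometry and used in all computations), loss
#' modulus G'' (metadata only — a purely elastic substrate is assumed),
#' Poisson ratio, and thickness. The default Poisson ratio 0.5 treats the
#' gel as incompressible; Young's modulus where needed is
#' `E = 2 G' (1 + nu)`.
#'
#' @param shear_modulus_pa G', Pa (> 0).
#' @param loss_modulus_pa G'', Pa (recorded, unused in computation).
#' @param poisson_ratio nu in `[0, 0.5]`.
#' @param thickness_um gel thickness, um (> 0); default 800 um. The
#'   half-space traction model assumes thickness far exceeds the observed
#'   displacements, which holds for these ~1 mm gels.
#' @return A `substrate_spec` list.
#' @export
substrate_spec <- function(shear_modulus_pa, loss_modulus_pa = 0,
                           poisson_ratio = 0.5, thickness_um = 800) {
  if (!is_num1(shear_modulus_pa) || shear_modulus_pa <= 0)
    stopf("`shear_modulus_pa` must be > 0")
  if (!is_num1(poisson_ratio) || poisson_ratio < 0 || poisson_ratio > 0.5)
    stopf("`poisson_ratio` must be in [0, 0.5]")
  if (!is_num1(thickness_um) || thickness_um <= 0)
    stopf("`thickness_um` must be > 0")
  structure(
    list(shear_modulus_pa = shear_modulus_pa,
         loss_modulus_pa = loss_modulus_pa,
         poisson_ratio = poisson_ratio, thickness_um = thickness_um),
    class = "substrate_spec"
  )
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat(sprintf("<substrate_spec> G' = %g Pa, G'' = %g Pa, nu = %g, thickness %g um\n",
              x$shear_modulus_pa, x$loss_modulus_pa, x$poisson_ratio,
              x$thickness_um))
  invisible(x)
}

# Fourier-domain tangential Green tensor of the elastic half-space
# (Boussinesq/Cerruti surface solution): u_hat = G_hat %*% tau_hat, with
# G_hat = [ (1-nu) k^2 + nu ky^2 , -nu kx ky ;
#           -nu kx ky , (1-nu) k^2 + nu kx^2 ] / (G' k^3).
# k in 1/um, tau in Pa, u in um. The k = 0 mode carries no information
# (a uniform traction on an unbounded surface has unbounded displacement)
# and is zeroed, so fields are implicitly mean-free.
green_hat <- function(nx, ny, dx, dy, G, nu) {
  kx <- 2 * pi * fft_freq(nx, dx)
  ky <- 2 * pi * fft_freq(ny, dy)
  KX <- matrix(kx, ny, nx, byrow = TRUE)
  KY <- matrix(ky, ny, nx)
  k2 <- KX^2 + KY^2
  k3 <- k2^(3 / 2)
  pre <- 1 / (G * k3)
  pre[1, 1] <- 0
  list(xx = pre * ((1 - nu) * k2 + nu * KY^2),
       yy = pre * ((1 - nu) * k2 + nu * KX^2),
       xy = -pre * nu * KX * KY)
}

# largest singular value of the Green tensor over the grid (the operator
# norm scale against which regularization is expressed)
green_norm <- function(gh) {
  tr2 <- (gh$xx + gh$yy) / 2
  dd <- sqrt(((gh$xx - gh$yy) / 2)^2 + gh$xy^2)
  max(abs(tr2) + dd)
}

# embed a matrix in a pad-times-larger zero canvas / crop back
pad_matrix <- function(m, pad) {
  if (pad <= 1) return(m)
  out <- matrix(0, nrow(m) * pad, ncol(m) * pad)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}
crop_matrix <- function(m, ny, nx) m[seq_len(ny), seq_len(nx)]

traction_grid <- function(traction) {
  xs <- sort(unique(traction$x_um)); ys <- sort(unique(traction$y_um))
  TX <- matrix(0, length(ys), length(xs)); TY <- TX
  i <- match(traction$y_um, ys); j <- match(traction$x_um, xs)
  TX[cbind(i, j)] <- traction$tx_pa
  TY[cbind(i, j)] <- traction$ty_pa
  list(xs = xs, ys = ys, TX = TX, TY = TY)
}

#' Surface displacement generated by a traction field (forward model)
#'
#' Convolves a tangential surface traction with the elastic half-space
#' Green tensor in the Fourier domain. The operator is linear in the
#' traction and scales as 1 / G', so doubling the shear modulus exactly
#' halves the displacements. The default treats the grid as periodic
#' (classical Fourier-transform traction microscopy); `pad > 1` embeds the
#' field in a zero canvas `pad` times larger to approximate free space,
#' e.g. for far-field decay checks.
#'
#' @param traction tibble with `x_um`, `y_um` (regular grid), `tx_pa`,
#'   `ty_pa`.
#' @param substrate a [substrate_spec()].
#' @param pad integer padding factor (>= 1).
#' @return A `displacement_field` tibble (`ux_um`, `uy_um`, um) on the same
#'   grid.
#' @export
forward_displacement <- function(traction, substrate, pad = 1) {
  stopifnot(inherits(substrate, "substrate_spec"))
  g <- traction_grid(traction)
  nx <- length(g$xs); ny <- length(g$ys)
  if (nx < 4 || ny < 4)
    stopf("grid too small for the convolution support (need >= 4 x 4 nodes)")
  dx <- diff(g$xs[1:2]); dy <- diff(g$ys[1:2])
  pad <- max(1L, as.integer(pad))
  TX <- pad_matrix(g$TX, pad); TY <- pad_matrix(g$TY, pad)
  gh <- green_hat(nx * pad, ny * pad, dx, dy,
                  substrate$shear_modulus_pa, substrate$poisson_ratio)
  thx <- stats::fft(TX); thy <- stats::fft(TY)
  np <- length(TX)
  U <- Re(stats::fft(gh$xx * thx + gh$xy * thy, inverse = TRUE)) / np
  V <- Re(stats::fft(gh$xy * thx + gh$yy * thy, inverse = TRUE)) / np
  U <- crop_matrix(U, ny, nx); V <- crop_matrix(V, ny, nx)
  grid <- tidyr::expand_grid(y_um = g$ys, x_um = g$xs)
  out <- tibble(x_um = grid$x_um, y_um = grid$y_um,
                ux_um = as.vector(t(U)), uy_um = as.vector(t(V)),
                quality = NA_real_, masked = FALSE)
  new_displacement_field(out, pixel_size = NA_real_, window_size = NA,
                         overlap = NA, reference = "forward_model")
}

# fill masked/NA vectors by iterative neighbor averaging (or zeros)
fill_missing <- function(M, how) {
  if (!anyNA(M)) return(M)
  if (how == "zero") { M[is.na(M)] <- 0; return(M) }
  for (it in 1:200) {
    na <- which(is.na(M), arr.ind = TRUE)
    if (!nrow(na)) break
    Mp <- rbind(NA, cbind(NA, M, NA), NA)
    est <- vapply(seq_len(nrow(na)), function(r) {
      i <- na[r, 1] + 1; j <- na[r, 2] + 1
      nb <- c(Mp[i - 1, j], Mp[i + 1, j], Mp[i, j - 1], Mp[i, j + 1])
      if (all(is.na(nb))) NA_real_ else mean(nb, na.rm = TRUE)
    }, numeric(1))
    M[na[!is.na(est), , drop = FALSE]] <- est[!is.na(est)]
    if (all(is.na(est))) { M[is.na(M)] <- 0; break }
  }
  M[is.na(M)] <- 0
  M
}

# Tikhonov solve in the Fourier domain for one relative reg value;
# returns traction spectra and the (Parseval-scaled) residual/solution norms
tikhonov_solve <- function(gh, uhx, uhy, lambda2) {
  a <- gh$xx; b <- gh$xy; d <- gh$yy
  m11 <- a^2 + b^2 + lambda2
  m22 <- b^2 + d^2 + lambda2
  m12 <- b * (a + d)
  det <- m11 * m22 - m12^2
  r1 <- a * uhx + b * uhy
  r2 <- b * uhx + d * uhy
  thx <- (m22 * r1 - m12 * r2) / det
  thy <- (m11 * r2 - m12 * r1) / det
  resx <- a * thx + b * thy - uhx
  resy <- b * thx + d * thy - uhy
  # remove the uninformative k = 0 mode from the misfit
  resx[1, 1] <- 0; resy[1, 1] <- 0
  np <- length(a)
  list(thx = thx, thy = thy,
       rho = sqrt(sum(Mod(resx)^2 + Mod(resy)^2) / np),
       eta = sqrt(sum(Mod(thx)^2 + Mod(thy)^2) / np))
}

# L-curve corner by maximum Menger curvature on (log rho, log eta)
lcurve_corner <- function(regs, rho, eta) {
  x <- log10(pmax(rho, .Machine$double.xmin))
  y <- log10(pmax(eta, .Machine$double.xmin))
  n <- length(regs)
  curv <- rep(-Inf, n)
  for (i in 2:(n - 1)) {
    a <- c(x[i - 1], y[i - 1]); b <- c(x[i], y[i]); cc <- c(x[i + 1], y[i + 1])
    ab <- sqrt(sum((b - a)^2)); bc <- sqrt(sum((cc - b)^2))
    ac <- sqrt(sum((cc - a)^2))
    # corner convexity: rho increases while eta falls with growing reg, so
    # the corner has a negative (clockwise) cross product
    cross <- (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1])
    if (ab * bc * ac > 0) curv[i] <- -2 * cross / (ab * bc * ac)
  }
  regs[which.max(curv)]
}

#' Reconstruct tangential surface traction from a displacement field
#'
#' Tikhonov-regularized inversion of the elastic half-space forward
#' operator: the traction minimizes
#' `|| forward(tau) - u ||^2 + reg * ||tau||^2`, solved independently per
#' Fourier mode. The regularization parameter is expressed relative to the
#' squared operator norm of the Green tensor, which makes the reconstructed
#' stress exactly proportional to G' for a fixed displacement field. With
#' `reg = "lcurve"` the parameter is chosen at the corner of the L-curve
#' (residual norm vs. solution norm) computed on the data at hand.
#'
#' @param field a `displacement_field` tibble on a regular grid (um); a
#'   `frame` column is inverted per frame. Masked vectors are filled per
#'   `fill` before inversion.
#' @param substrate a [substrate_spec()].
#' @param reg `"lcurve"` or a non-negative number (relative to the squared
#'   operator norm).
#' @param pad integer padding factor; must match the convention used for
#'   the displacement data (default periodic).
#' @param fill `"interpolate"` (iterative neighbor averaging) or `"zero"`.
#' @return A `traction_field` tibble: `x_um`, `y_um`, `tx_pa`, `ty_pa`,
#'   `tmag_pa`; attributes `reg_used`, `lambda2`, `reference`, and per-frame
#'   `diagnostics` (residual and solution norms). Supports
#'   [generics::glance()].
#' @export
reconstruct_traction <- function(field, substrate, reg = "lcurve", pad = 1,
                                 fill = c("interpolate", "zero")) {
  stopifnot(inherits(substrate, "substrate_spec"))
  fill <- match.arg(fill)
  if (is.numeric(reg) && reg < 0) stopf("`reg` must be >= 0")
  has_frame <- "frame" %in% names(field)
  split_fields <- if (has_frame) split(field, field$frame) else list(field)

  out <- list(); diags <- list()
  for (fd in split_fields) {
    m <- field_matrices(fd)
    nx <- length(m$xs); ny <- length(m$ys)
    if (nx < 4 || ny < 4)
      stopf("grid too small for the convolution support (need >= 4 x 4 nodes)")
    dx <- diff(m$xs[1:2]); dy <- diff(m$ys[1:2])
    U <- fill_missing(m$U, fill); V <- fill_missing(m$V, fill)
    pad <- max(1L, as.integer(pad))
    Up <- pad_matrix(U, pad); Vp <- pad_matrix(V, pad)
    gh <- green_hat(nx * pad, ny * pad, dx, dy,
                    substrate$shear_modulus_pa, substrate$poisson_ratio)
    gmax <- green_norm(gh)
    if (!is.finite(gmax) || gmax <= 0)
      stopf("singular traction inversion: degenerate Green tensor")
    uhx <- stats::fft(Up); uhy <- stats::fft(Vp)

    reg_used <- reg
    if (identical(reg, "lcurve")) {
      regs <- 10^seq(-8, -1, length.out = 30)
      rho <- eta <- numeric(length(regs))
      for (i in seq_along(regs)) {
        s <- tikhonov_solve(gh, uhx, uhy, regs[i] * gmax^2)
        rho[i] <- s$rho; eta[i] <- s$eta
      }
      reg_used <- lcurve_corner(regs, rho, eta)
    } else if (!is.numeric(reg)) {
      stopf("`reg` must be \"lcurve\" or a non-negative number")
    }
    sol <- tikhonov_solve(gh, uhx, uhy, reg_used * gmax^2)
    if (!all(is.finite(Mod(sol$thx))) || !all(is.finite(Mod(sol$thy))))
      stopf("singular traction inversion: non-finite solution")
    np <- (nx * pad) * (ny * pad)
    TX <- crop_matrix(Re(stats::fft(sol$thx, inverse = TRUE)) / np, ny, nx)
    TY <- crop_matrix(Re(stats::fft(sol$thy, inverse = TRUE)) / np, ny, nx)
    grid <- tidyr::expand_grid(y_um = m$ys, x_um = m$xs)
    tb <- tibble(x_um = grid$x_um, y_um = grid$y_um,
                 tx_pa = as.vector(t(TX)), ty_pa = as.vector(t(TY)))
    tb$tmag_pa <- sqrt(tb$tx_pa^2 + tb$ty_pa^2)
    fr <- if (has_frame) fd$frame[1] else NA_integer_
    if (has_frame) tb <- dplyr::mutate(tb, frame = fr, .before = 1)
    out[[length(out) + 1L]] <- tb
    diags[[length(diags) + 1L]] <- tibble(
      frame = fr, reg_used = reg_used, residual_norm = sol$rho,
      solution_norm = sol$eta)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- unique(c("traction_field", class(res)))
  attr(res, "reg_used") <- diags[[1]]$reg_used
  attr(res, "reference") <- attr(field, "reference") %||% NA_character_
  attr(res, "substrate") <- substrate
  attr(res, "diagnostics") <- dplyr::bind_rows(diags)
  res
}

#' @export
glance.traction_field <- function(x, ...) {
  d <- attr(x, "diagnostics")
  s <- attr(x, "substrate")
  dplyr::mutate(d, shear_modulus_pa = s$shear_modulus_pa,
                reference = attr(x, "reference"))
}

#' Box–whisker summary of stress magnitude over map nodes
#'
#' Quartiles, whiskers, and mean of `|tau|` over the analysis region at each
#' timepoint — the summary behind per-hour stress box plots. The whisker
#' convention is config-exposed: `"minmax"` (default) or `"tukey"`
#' (1.5 IQR, clamped to the data range).
#'
#' @param traction a `traction_field` tibble (a `frame` column groups
#'   timepoints).
#' @param region optional region restricting the nodes: a rectangle
#'   `c(x0, y0, x1, y1)` in um, or a predicate `function(x_um, y_um)`
#'   returning a logical.
#' @param whisker `"minmax"` or `"tukey"`.
#' @return A tibble per timepoint: `frame`, `n_nodes`, `whisker_lo_pa`,
#'   `q1_pa`, `median_pa`, `q3_pa`, `whisker_hi_pa`, `mean_pa`.
#' @export
stress_summary <- function(traction, region = NULL,
                           whisker = c("minmax", "tukey")) {
  whisker <- match.arg(whisker)
  if (!nrow(traction)) stopf("empty traction series")
  tb <- as_tibble(traction)
  if (!"frame" %in% names(tb)) tb$frame <- 0L
  if (!is.null(region)) {
    keep <- if (is.function(region)) region(tb$x_um, tb$y_um)
    else tb$x_um >= region[1] & tb$x_um <= region[3] &
      tb$y_um >= region[2] & tb$y_um <= region[4]
    tb <- tb[keep, ]
  }
  if (!nrow(tb)) stopf("analysis region contains no stress-map nodes")
  tb |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(
      n_nodes = dplyr::n(),
      q1_pa = stats::quantile(.data$tmag_pa, 0.25, names = FALSE),
      median_pa = stats::median(.data$tmag_pa),
      q3_pa = stats::quantile(.data$tmag_pa, 0.75, names = FALSE),
      min_pa = min(.data$tmag_pa),
      max_pa = max(.data$tmag_pa),
      mean_pa = mean(.data$tmag_pa),
      .groups = "drop") |>
    dplyr::mutate(
      whisker_lo_pa = if (whisker == "minmax") .data$min_pa
        else pmax(.data$min_pa, .data$q1_pa - 1.5 * (.data$q3_pa - .data$q1_pa)),
      whisker_hi_pa = if (whisker == "minmax") .data$max_pa
        else pmin(.data$max_pa, .data$q3_pa + 1.5 * (.data$q3_pa - .data$q1_pa))) |>
    dplyr::select("frame", "n_nodes", "whisker_lo_pa", "q1_pa", "median_pa",
                  "q3_pa", "whisker_hi_pa", "mean_pa")
}

#' Surface shear strain from stress
#'
#' Applies the linear constitutive identity `epsilon = tau / G'` — the
#' relation `tau = G epsilon` inverted for strain, with G' the shear
#' storage modulus from rheometry.
#'
#' @param tau stress in Pa: a numeric vector, or a `traction_field` tibble
#'   (in which case a `strain` column computed from `tmag_pa` is appended).
#' @param substrate a [substrate_spec()].
#' @return Unitless strain, same shape as the input (or the tibble with a
#'   `strain` column).
#' @export
strain_from_stress <- function(tau, substrate) {
  stopifnot(inherits(substrate, "substrate_spec"))
  if (is.data.frame(tau)) {
    if (!"tmag_pa" %in% names(tau)) stopf("tibble input needs `tmag_pa`")
    return(dplyr::mutate(tau, strain = .data$tmag_pa / substrate$shear_modulus_pa))
  }
  tau / substrate$shear_modulus_pa
}
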