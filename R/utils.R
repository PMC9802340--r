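#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# numeric scalar check
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# numeric length-2 vector check
is_num2 <- function(x) is.numeric(x) && length(x) == 2L && all(is.finite(x))

stopf <- function(fmt, ..., class = NULL) {
  abort(sprintf(fmt, ...), class = class)
}

# clamp values into [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# 16-bit grayscale depth used throughout
BIT_DEPTH_MAX <- 65535

# quantize a real-valued raster to the 16-bit container
quantize16 <- function(m) {
  m <- clamp(round(m), 0, BIT_DEPTH_MAX)
  storage.mode(m) <- "double"
  m
}

# signed FFT frequencies (cycles per unit), like numpy's fftfreq
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# trapezoidal cumulative integral of y over x
cumtrapz <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(0)
  c(0, cumsum(diff(x) * (y[-n] + y[-1]) / 2))
}
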