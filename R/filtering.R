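# Zero-phase Butterworth low-pass filtering.
#
# No DSP package is assumed: the digital Butterworth is designed by bilinear
# transform of the analog prototype, and applied forward-backward with
# odd-reflection padding and steady-state initial conditions, so a constant
# input passes through exactly and the net filter has zero phase lag.

# Design a digital low-pass Butterworth. Wn = cutoff / (fs/2) in (0, 1).
butter_lowpass <- function(order, Wn) {
  stopifnot(order >= 1, Wn > 0, Wn < 1)
  # analog prototype poles on the unit circle (left half-plane), prewarped
  k <- seq_len(order)
  theta <- pi * (2 * k - 1 + order) / (2 * order)
  warped <- tan(pi * Wn / 2)
  p <- warped * complex(real = cos(theta), imaginary = sin(theta))
  # bilinear transform (fs normalised so that z = (1 + p)/(1 - p))
  zp <- (1 + p) / (1 - p)
  a <- Re(poly_from_roots(zp))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  # unity gain at DC (z = 1)
  gain <- Re(prod(1 - zp)) / 2^order
  list(b = b * gain, a = a)
}

# monic polynomial coefficients from roots, highest order first
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (root in r) coefs <- c(coefs, 0) - c(0, coefs * root)
  coefs
}

# direct-form-II-transposed IIR filter with initial state zi
iir_filter <- function(b, a, x, zi = NULL) {
  n <- length(a) - 1L
  z <- if (is.null(zi)) numeric(n) else zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (n > 1L) {
      for (j in seq_len(n - 1L)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    }
    z[n] <- b[n + 1] * xi - a[n + 1] * yi
    y[i] <- yi
  }
  y
}

# steady-state filter state for a unit-step input (scipy lfilter_zi analogue)
filter_zi <- function(b, a) {
  n <- length(a) - 1L
  # solve z = A z + B with the DF2T companion structure via linear system
  A <- matrix(0, n, n)
  for (j in seq_len(n)) A[j, 1] <- -a[j + 1]
  if (n > 1L) for (j in seq_len(n - 1L)) A[j, j + 1] <- 1
  Bv <- b[-1] - a[-1] * b[1]
  solve(diag(n) - A, Bv)
}

# zero-phase application: odd-reflection padding, forward and backward pass
filtfilt_butter <- function(b, a, x) {
  n <- length(x)
  padlen <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= padlen)
    stop(sprintf("lowpass: series too short to filter (%d <= %d samples)",
                 n, padlen), call. = FALSE)
  pre <- 2 * x[1] - x[seq(padlen + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - padlen)]
  ext <- c(pre, x, post)
  zi <- filter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[seq(padlen + 1L, padlen + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Filters an angle series forward and backward (zero net phase) with a
#' Butterworth low-pass of the given order per pass. Length and timing are
#' preserved; a constant series passes through unchanged.
#'
#' @param series an [angle_series()].
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist frequency.
#' @param order Butterworth order per pass (default 4).
#' @return a filtered `angle_series`.
#' @export
lowpass <- function(series, cutoff = 15, order = 4L) {
  stopifnot(inherits(series, "angle_series"))
  nyq <- series$sample_rate / 2
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= nyq)
    stop(sprintf("lowpass: cutoff must be in (0, %g) Hz (Nyquist)", nyq),
         call. = FALSE)
  ba <- butter_lowpass(order, cutoff / nyq)
  out <- series
  out$values <- filtfilt_butter(ba$b, ba$a, series$values)
  out
}

# apply the configured low-pass to every series of a trial (NA cutoff = skip)
filter_trial <- function(trial, config = analysis_config()) {
  if (is.na(config$lowpass_cutoff)) return(trial)
  trial$series <- lapply(trial$series, lowpass,
                         cutoff = config$lowpass_cutoff,
                         order = config$filter_order)
  trial
}
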