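# Low-pass filtering and numerical differentiation for 100 Hz kinematic data.
#
# A zero-phase Butterworth filter is conventional for marker trajectories;
# coefficients are designed here via the bilinear transform (no external DSP
# dependency in the environment).

#' Filter specification for kinematic processing
#'
#' @param cutoff low-pass cutoff frequency (Hz); must be below Nyquist.
#' @param order Butterworth order (applied forward and backward, so the
#'   effective attenuation is doubled).
#' @param diff differentiation scheme; only `"central"` is implemented.
#' @param crossing_cutoff cutoff (Hz) of the lighter filter used for the
#'   instantaneous crossing kinematics (toe clearance, crossing velocity),
#'   whose transients the heavy smoothing band would bias; must be >=
#'   `cutoff`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff = 6, order = 4L, diff = "central",
                        crossing_cutoff = 15) {
  stopifnot(cutoff > 0, order >= 1L, crossing_cutoff >= cutoff)
  structure(list(cutoff = cutoff, order = as.integer(order), diff = diff,
                 crossing_cutoff = crossing_cutoff),
            class = "filter_spec")
}

# Butterworth low-pass coefficients (b, a) by bilinear transform.
butter_lowpass <- function(order, cutoff, rate) {
  if (cutoff >= rate / 2)
    stop("butter_lowpass: cutoff must be below the Nyquist frequency")
  wc <- 2 * rate * tan(pi * cutoff / rate)     # pre-warped analog cutoff
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p_analog <- wc * complex(modulus = 1, argument = theta)
  z_poles <- (2 * rate + p_analog) / (2 * rate - p_analog)
  poly_from_roots <- function(r) {
    cf <- 1
    for (ri in r) cf <- c(cf, 0) - c(0, cf * ri)
    cf
  }
  a <- Re(poly_from_roots(z_poles))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)                      # unit gain at DC
  list(b = b, a = a)
}

# Single-pass IIR filter using stats::filter for speed.  The signal is
# filtered about its first sample (unit DC gain), so a constant input passes
# through exactly and start-up transients act only on the deviation.
iir_pass <- function(x, b, a) {
  x0 <- x[1L]
  xd <- x - x0
  v <- stats::filter(c(rep(0, length(b) - 1L), xd), b, sides = 1L,
                     method = "convolution")
  v <- as.numeric(v)[-seq_len(length(b) - 1L)]
  y <- as.numeric(stats::filter(v, -a[-1L] / a[1L],
                                method = "recursive")) / a[1L]
  y + x0
}

# Zero-phase (forward-backward) filtering with odd-reflection padding.
filtfilt_vec <- function(x, b, a) {
  n <- length(x)
  p <- min(n - 1L, 3L * (max(length(a), length(b)) - 1L) * 4L)
  if (p < 1L) return(x)
  xp <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- iir_pass(xp, b, a)
  y <- rev(iir_pass(rev(y), b, a))
  y[(p + 1L):(p + n)]
}

#' Zero-phase low-pass filter a marker trajectory
#'
#' @param traj a [marker_trajectory()]; must be gap-free (run
#'   [interpolate_gaps()] first); trajectories containing `NA` are returned
#'   unfiltered with a warning so that downstream flags can propagate.
#' @param spec a [filter_spec()].
#' @return the filtered [marker_trajectory()], same length and rate.
#' @export
lowpass <- function(traj, spec = filter_spec()) {
  if (spec$cutoff >= traj$rate / 2)
    stop("lowpass: cutoff must be below the Nyquist frequency")
  if (anyNA(traj$xyz)) {
    warning(sprintf("lowpass: marker %s has unfilled gaps; left unfiltered",
                    traj$name))
    return(traj)
  }
  ba <- butter_lowpass(spec$order, spec$cutoff, traj$rate)
  xyz <- apply(traj$xyz, 2L, filtfilt_vec, b = ba$b, a = ba$a)
  marker_trajectory(traj$name, xyz, traj$rate)
}

#' Central-difference derivative of a sampled signal
#'
#' Interior samples use `(x[i+1] - x[i-1]) / (2 dt)`; the end points use
#' one-sided differences.
#'
#' @param x numeric vector.
#' @param rate sampling rate (Hz).
#' @return numeric vector of the same length.
#' @export
central_diff <- function(x, rate) {
  n <- length(x)
  if (n < 2L) stop("central_diff: need at least 2 samples")
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) * rate
  d[n] <- (x[n] - x[n - 1L]) * rate
  if (n > 2L) d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) * rate / 2
  d
}

# Linear interpolation of a sampled signal at arbitrary times.
interp_at <- function(x, rate, t) {
  stats::approx(x = (seq_along(x) - 1L) / rate, y = x, xout = t, rule = 2)$y
}
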