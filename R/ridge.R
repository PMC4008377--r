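# Oriented filter bank and ridge-orientation reliability.
#
# The operator divides the print into small analysis windows, measures the
# energy of a bank of even-symmetric Gabor filters tuned to the ridge
# wavelength at several orientations, and calls a window "high reliability"
# when one orientation clearly dominates. The reliability score is the
# proportion of such windows.

#' Build an even-symmetric Gabor filter bank
#'
#' `n_orient` zero-mean cosine-phase Gabor kernels spanning \[0, pi).
#' The carrier is modulated across the ridge direction, so a kernel at
#' orientation theta responds maximally to ridges flowing along theta.
#' Each kernel carries its matched-grating response amplitude `r_amp`
#' (per-pixel response to an ideal full-contrast grating of amplitude 127.5
#' at the kernel's own frequency and orientation) and its absolute response
#' bound `r_bound` (largest per-pixel response any 8-bit image can evoke),
#' used to put window energies on an absolute scale.
#'
#' @param n_orient Number of orientations (default 8).
#' @param wavelength Carrier wavelength in pixels (default 9, a typical
#'   ridge period at 500 dpi scaled to the synthetic canvas).
#' @param sigma Gaussian envelope SD in pixels (default 4).
#' @return List of kernels, each `list(kernel =, theta =, r_amp =)`.
#' @export
gabor_bank <- function(n_orient = 8, wavelength = 9, sigma = 4) {
  half <- ceiling(2 * sigma)
  xs <- -half:half
  grid <- expand.grid(x = xs, y = xs)
  lapply(seq_len(n_orient), function(k) {
    theta <- (k - 1) * pi / n_orient
    # coordinate across the ridges for ridges flowing along theta
    u <- -grid$x * sin(theta) + grid$y * cos(theta)
    env <- exp(-(grid$x^2 + grid$y^2) / (2 * sigma^2))
    g <- env * cos(2 * pi * u / wavelength)
    g <- g - mean(g)                      # zero DC: constant images -> 0
    kern <- matrix(g, nrow = length(xs))
    # matched ideal grating 127.5 + 127.5*cos(2*pi*u/lambda + phase):
    # response amplitude over phase is 127.5 * sqrt(c^2 + s^2)
    cc <- sum(g * cos(2 * pi * u / wavelength))
    ss <- sum(g * sin(2 * pi * u / wavelength))
    list(kernel = kern, theta = theta,
         r_amp = 127.5 * sqrt(cc^2 + ss^2),
         # absolute per-pixel response bound for an 8-bit image
         r_bound = 127.5 * sum(abs(g)))
  })
}

# 2-D 'same' convolution via FFT with zero padding.
conv2_same <- function(image, kernel) {
  di <- dim(image); dk <- dim(kernel)
  dp <- di + dk - 1L
  pi_ <- matrix(0, dp[1], dp[2]); pi_[seq_len(di[1]), seq_len(di[2])] <- image
  pk <- matrix(0, dp[1], dp[2]); pk[seq_len(dk[1]), seq_len(dk[2])] <- kernel
  full <- Re(stats::fft(stats::fft(pi_) * stats::fft(pk), inverse = TRUE)) /
    prod(dp)
  off <- (dk - 1L) %/% 2L
  full[off[1] + seq_len(di[1]), off[2] + seq_len(di[2])]
}

#' Ridge-orientation reliability of a print
#'
#' The segmented region is tiled into `window` x `window` analysis windows
#' (anchored at the mask bounding box, a window kept iff >= 50% in-mask).
#' In each window the energy of every oriented filter response is summed
#' over in-mask pixels. The window's dominant ridge orientation counts as
#' uniquely specified -- "high reliability" -- iff the top orientation's
#' energy is at least `tau` times that of the best non-adjacent orientation
#' and at least `epsilon` of the maximum energy any 8-bit image could put
#' into that filter over the same pixels. The score is the proportion of
#' high-reliability windows and lies in \[0,1\].
#'
#' @inheritParams intensity_stats
#' @param window Analysis window side in pixels (default 16).
#' @param n_orient,wavelength,sigma Filter-bank parameters (see
#'   [gabor_bank]).
#' @param tau Dominance ratio: top orientation energy over the best
#'   non-adjacent orientation's energy (default 1.5). Adjacent bins are
#'   excluded from the runner-up because an orientation midway between two
#'   bin centers necessarily splits energy between them.
#' @param epsilon Minimum top energy as a fraction of the maximum possible
#'   window energy (default 0.01; a matched full-contrast grating reaches
#'   about 30% of that maximum, unoriented noise well under 1%).
#' @return Proportion in \[0, 1\].
#' @export
ridge_reliability <- function(image, mask, window = 16, n_orient = 8,
                              wavelength = 9, sigma = 4,
                              tau = 1.5, epsilon = 0.01) {
  px <- if (inherits(image, "print_image")) image$pixels else image
  if (!identical(dim(px), dim(mask))) stop("image and mask dimensions differ")
  windows <- block_partition(mask, block_size = window)
  bank <- gabor_bank(n_orient = n_orient, wavelength = wavelength,
                     sigma = sigma)
  centered <- px - mean(px)  # reduce zero-padding edge response
  responses <- lapply(bank, function(b) conv2_same(centered, b$kernel))
  n_reliable <- 0L
  for (w in windows) {
    energies <- vapply(seq_along(bank), function(k) {
      r <- responses[[k]][w$rows, w$cols][w$inside]
      sum(r^2)
    }, numeric(1))
    k_top <- which.max(energies)
    top <- energies[k_top]
    # A true orientation midway between two bin centers splits its energy
    # between the adjacent bins, so the runner-up for the dominance ratio
    # is the best orientation NOT adjacent (mod pi) to the winner.
    neighbors <- c(k_top, (k_top %% n_orient) + 1L,
                   ((k_top - 2L) %% n_orient) + 1L)
    second <- max(energies[-neighbors])
    # maximum possible window energy: every pixel at the filter's absolute
    # response bound (a matched full-contrast grating reaches ~30% of it)
    e_max <- bank[[k_top]]$r_bound^2 * sum(w$inside)
    if (top >= epsilon * e_max && (second == 0 || top / second >= tau)) {
      n_reliable <- n_reliable + 1L
    }
  }
  n_reliable / length(windows)
}
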