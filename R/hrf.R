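#' Canonical hemodynamic response function
#'
#' Double-gamma HRF with a positive lobe peaking at 6 s and an undershoot
#' peaking at 16 s (gamma densities with modes 6 and 16, undershoot ratio
#' 1/6), rescaled so the peak value is exactly 1. This is the impulse
#' response used by the synthetic BOLD generator and by the reaction-time
#' mechanism simulations.
#'
#' @param t numeric vector of times in seconds (values below 0 return 0).
#' @param undershootRatio relative amplitude of the undershoot gamma.
#' @return numeric vector of HRF values, unit peak.
#' @examples
#' h <- canonicalHrf(seq(0, 30, by = 1.5))
#' @export
canonicalHrf <- function(t, undershootRatio = 1/6) {
    raw <- function(x) {
        v <- numeric(length(x))
        ok <- x >= 0
        v[ok] <- dgamma(x[ok], shape = 7, rate = 1) -
            undershootRatio * dgamma(x[ok], shape = 17, rate = 1)
        v
    }
    ## unit-peak normalization on a fine grid (shape is fixed, so this is
    ## a deterministic constant)
    peak <- max(raw(seq(0, 32, by = 0.001)))
    raw(t) / peak
}

#' Sampled HRF kernel
#'
#' @param dt sampling interval in seconds (1.5 for TR-resolution work,
#'   0.060 for the reaction-time simulations).
#' @param duration kernel support in seconds.
#' @return numeric vector of \code{canonicalHrf} values at
#'   \code{seq(0, duration, by = dt)}.
#' @export
hrfKernel <- function(dt, duration = 30) {
    canonicalHrf(seq(0, duration, by = dt))
}

## Convolve per-TR event amplitudes with the HRF kernel, truncated to the
## event series length.
convolveEvents <- function(events, kernel) {
    n <- length(events)
    out <- numeric(n + length(kernel) - 1L)
    idx <- which(events != 0)
    for (i in idx)
        out[i:(i + length(kernel) - 1L)] <-
            out[i:(i + length(kernel) - 1L)] + events[i] * kernel
    out[seq_len(n)]
}
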