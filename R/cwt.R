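# Dense CWT kernel matrices for a finite, uniformly sampled signal.
# For scale a and shift tau the coefficient is
#   W(a, tau) = sum_t x[t] * Conj(psi((t - tau) / a)) / sqrt(a)
# so the transform of a length-L signal is one (n_scales*L) x L matrix
# product per real/imaginary part. Kernels are cached per (L, scales,
# wavelet) within a session.
cwt_mother <- function(u, wavelet) {
  switch(wavelet,
    morlet = pi^(-0.25) * exp(1i * 6 * u) * exp(-u^2 / 2),
    ricker = (2 / (sqrt(3) * pi^0.25)) * (1 - u^2) * exp(-u^2 / 2) + 0i,
    abort(paste0("Unknown wavelet: ", wavelet,
                 " (available: morlet, ricker)"))
  )
}

cwt_kernel_cache <- new.env(parent = emptyenv())

cwt_kernels <- function(len, scales, wavelet) {
  key <- paste(len, paste(scales, collapse = ","), wavelet, sep = "|")
  if (!is.null(cwt_kernel_cache[[key]])) return(cwt_kernel_cache[[key]])
  t <- seq_len(len)
  blocks <- lapply(scales, function(a) {
    u <- outer(-t, t, `+`) / a          # (t - tau)/a, rows tau, cols t
    Conj(cwt_mother(u, wavelet)) / sqrt(a)
  })
  M <- do.call(rbind, blocks)
  out <- list(re = Re(M), im = Im(M))
  cwt_kernel_cache[[key]] <- out
  out
}

check_scales <- function(scales) {
  if (length(scales) == 0 || any(!is.finite(scales)) || any(scales <= 0)) {
    abort("`scales` must be a non-empty vector of positive numbers.")
  }
}

#' Continuous wavelet transform scaleogram of one sequence
#'
#' Computes the channel-wise CWT magnitude of a multichannel sequence: for
#' each channel, a `length(scales)` x `nrow(sequence)` image of
#' `|CWT|` values. The default mother wavelet is the analytic Morlet
#' (centre frequency 6); a real Ricker ("Mexican hat") wavelet is also
#' available. The transform is linear, so scaleograms are absolutely
#' homogeneous (`scaleogram(a * x) = |a| * scaleogram(x)`) and vanish on
#' all-zero input.
#'
#' @param sequence A `target_len` x 4 numeric matrix (time x channels).
#' @param scales Positive dilation factors in sample units (default 1:8).
#' @param wavelet `"morlet"` (default) or `"ricker"`.
#' @return An `n_scales` x `target_len` x 4 array of magnitudes.
#' @export
scaleogram <- function(sequence, scales = 1:8, wavelet = "morlet") {
  check_scales(scales)
  sequence <- as.matrix(sequence)
  if (any(!is.finite(sequence))) abort("`sequence` must be finite.")
  ker <- cwt_kernels(nrow(sequence), scales, wavelet)
  re <- ker$re %*% sequence
  im <- ker$im %*% sequence
  mag <- sqrt(re^2 + im^2)
  # mag rows are (scale block x tau), tau fastest; reorder to scales x time
  aperm(array(mag, dim = c(nrow(sequence), length(scales), ncol(sequence))),
        c(2, 1, 3))
}

#' @rdname scaleogram
#' @param sequences An [sequence_features()] object; scaleograms should be
#'   computed on *standardised* sequences so the image branch sees a common
#'   scale across folds.
#' @return For `batch_scaleograms()`: an object of class `hc_scaleograms`
#'   with `data` (N x n_scales x target_len x 4 array), `scales`, `wavelet`
#'   and `labels`.
#' @export
batch_scaleograms <- function(sequences, scales = 1:8, wavelet = "morlet") {
  stopifnot(inherits(sequences, "hc_sequences"))
  check_scales(scales)
  d <- dim(sequences$data)          # N x L x C
  n <- d[1]; len <- d[2]; nc <- d[3]
  ker <- cwt_kernels(len, scales, wavelet)
  x <- matrix(aperm(sequences$data, c(2, 1, 3)), len, n * nc)  # col = (n, c)
  re <- ker$re %*% x
  im <- ker$im %*% x
  mag <- sqrt(re^2 + im^2)          # (n_scales*L) x (N*C), row tau fastest
  arr <- array(mag, dim = c(len, length(scales), n, nc))
  structure(
    list(
      data = aperm(arr, c(3, 2, 1, 4)),  # N x scales x time x channels
      scales = scales, wavelet = wavelet,
      labels = sequences$labels
    ),
    class = "hc_scaleograms"
  )
}

#' @export
print.hc_scaleograms <- function(x, ...) {
  d <- dim(x$data)
  cat("<hc_scaleograms> ", d[1], " x ", d[2], " scales x ", d[3],
      " steps x ", d[4], " channels (", x$wavelet, ")\n", sep = "")
  invisible(x)
}
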