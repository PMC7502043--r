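# Centred orthonormal FFT helpers.  k-space convention: DC at the matrix
# centre index floor(n/2)+1, k in cycles/mm; image voxel indices 0-based in
# the maths, 1-based in R arrays.

fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    h <- floor(n / 2)
    c((h + 1):n, seq_len(h))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

ifftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    h <- ceiling(n / 2)
    c((h + 1):n, seq_len(h))
  })
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# orthonormal centred FFT (image -> k-space) and its inverse
fft_c <- function(x) fftshift(fft(ifftshift(x))) / sqrt(length(x))
ifft_c <- function(k) fftshift(fft(ifftshift(k), inverse = TRUE)) / sqrt(length(k))

# k-axis in cycles/mm for n voxels of size v mm, DC at floor(n/2)+1
k_axis <- function(n, v) (seq_len(n) - (floor(n / 2) + 1)) / (n * v)
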