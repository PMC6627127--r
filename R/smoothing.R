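# Separable Gaussian smoothing for 3D arrays. Sigma is given per axis in
# voxel units; kernels are truncated at 3 sigma and renormalised, so the
# filter preserves the mean of a constant array exactly.

gauss_kernel_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((0:half) / sigma)^2)  # kernel value by |offset|
  idx <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- matrix(0, n, n)
  sel <- idx <= half
  K[sel] <- k[idx[sel] + 1L]
  # renormalise rows (edge rows lose kernel mass)
  K / rowSums(K)
}

smooth_gaussian3d <- function(a, sigma) {
  d <- dim(a)
  sigma <- rep_len(sigma, 3L)
  if (sigma[1] > 0) {
    K <- gauss_kernel_matrix(d[1], sigma[1])
    a <- array(K %*% matrix(a, d[1]), d)
  }
  if (sigma[2] > 0) {
    K <- gauss_kernel_matrix(d[2], sigma[2])
    a <- aperm(array(K %*% matrix(aperm(a, c(2, 1, 3)), d[2]),
                     d[c(2, 1, 3)]), c(2, 1, 3))
  }
  if (sigma[3] > 0) {
    K <- gauss_kernel_matrix(d[3], sigma[3])
    a <- aperm(array(K %*% matrix(aperm(a, c(3, 1, 2)), d[3]),
                     d[c(3, 1, 2)]), c(2, 3, 1))
  }
  a
}

pad_array3d <- function(a, pad, value = 0) {
  d <- dim(a)
  out <- array(value, d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- a
  out
}
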