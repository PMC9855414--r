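# Undecimated (stationary) wavelet transform, Daubechies-4, circular
# boundary, operating column-wise on a matrix of beats. Analysis uses the
# a-trous dilation of the orthonormal filter pair; synthesis averages the two
# polyphase branches, which gives perfect reconstruction:
#   a_{j-1} = (hbar * a_j + gbar * d_j) / 2.

db4_lowpass <- function() {
  c(0.230377813308855, 0.714846570552542, 0.630880767929590,
    -0.027983769416984, -0.187034811718881, 0.030841381835987,
    0.032883011666983, -0.010597401784997)
}

db4_highpass <- function() {
  h <- db4_lowpass()
  L <- length(h)
  (-1)^(0:(L - 1)) * h[L:1]
}

# y[n] = sum_k h[k+1] x[n - dil*k]  (circular), columns independent
circ_conv_mat <- function(X, h, dil) {
  N <- nrow(X)
  Y <- matrix(0, N, ncol(X))
  idx0 <- seq_len(N) - 1L
  for (k in seq_along(h)) {
    rows <- ((idx0 - dil * (k - 1L)) %% N) + 1L
    Y <- Y + h[k] * X[rows, , drop = FALSE]
  }
  Y
}

# adjoint: y[n] = sum_k h[k+1] x[n + dil*k]
circ_corr_mat <- function(X, h, dil) {
  N <- nrow(X)
  Y <- matrix(0, N, ncol(X))
  idx0 <- seq_len(N) - 1L
  for (k in seq_along(h)) {
    rows <- ((idx0 + dil * (k - 1L)) %% N) + 1L
    Y <- Y + h[k] * X[rows, , drop = FALSE]
  }
  Y
}

swt_decompose <- function(X, levels = 3L) {
  h <- db4_lowpass(); g <- db4_highpass()
  a <- X
  details <- vector("list", levels)
  for (j in seq_len(levels)) {
    dil <- 2L^(j - 1L)
    details[[j]] <- circ_conv_mat(a, g, dil)
    a <- circ_conv_mat(a, h, dil)
  }
  list(approx = a, details = details, levels = levels)
}

swt_reconstruct <- function(dec) {
  h <- db4_lowpass(); g <- db4_highpass()
  a <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    dil <- 2L^(j - 1L)
    a <- (circ_corr_mat(a, h, dil) + circ_corr_mat(dec$details[[j]], g, dil)) / 2
  }
  a
}

# Per-beat hard-threshold denoising: the noise scale is estimated per beat
# from the MAD of the finest detail band and applied as a universal threshold
# to every detail level. Hard (keep-or-kill) thresholding is used because it
# leaves retained coefficients unshrunk, so fiducial peak amplitudes are not
# biased. Also returns the low-frequency reconstruction (approximation +
# coarsest detail only), used to locate the smooth P wave.
swt_denoise <- function(X, levels = 3L) {
  one_col <- is.null(dim(X))
  if (one_col) X <- matrix(X, ncol = 1)
  dec <- swt_decompose(X, levels)
  N <- nrow(X)
  sigma <- apply(dec$details[[1]], 2, mad)  # mad() includes the 1/0.6745 factor
  lambda <- sigma * sqrt(2 * log(N))
  hard <- function(D) D * (abs(D) > rep(lambda, each = N))
  dn <- dec
  dn$details <- lapply(dec$details, hard)
  lowp <- dec
  for (j in seq_len(levels - 1L)) lowp$details[[j]][] <- 0
  out <- list(denoised = swt_reconstruct(dn), lowpass = swt_reconstruct(lowp))
  if (one_col) out <- lapply(out, as.numeric)
  out
}
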