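## Discrete prolate spheroidal sequences (Slepian tapers).
##
## Computed from the standard symmetric tridiagonal eigenproblem
## (Percival & Walden 1993, ch. 8): for sequence length n and normalized
## half-bandwidth w (cycles/sample), the k-th taper is the eigenvector of
##   diag_i   = ((n - 1 - 2i)/2)^2 * cos(2*pi*w),  i = 0..n-1
##   offdiag_i = i (n - i) / 2,                    i = 1..n-1
## belonging to the k-th largest eigenvalue.  Tapers are normalized to unit
## energy; sign convention: the first element whose modulus exceeds 1e-7 of
## the maximum is positive (an unambiguous rule even for antisymmetric
## tapers; sign is irrelevant for power estimates).

.dpssCache <- new.env(parent = emptyenv())

#' DPSS (Slepian) tapers
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (n * w, dimensionless); the package's
#'   frequency-adaptive plan uses nw = 1.6 (two cycles, smoothing 80\% of the
#'   bin frequency).
#' @param k number of tapers to return.
#' @return n x k matrix; columns are orthonormal tapers ordered by decreasing
#'   spectral concentration.
#' @export
dpssTapers <- function(n, nw, k = 2L) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (n < 2L) stop("taper length must be at least 2 samples")
  if (k < 1L || k > n) stop("invalid number of tapers")
  key <- sprintf("%d_%.10g_%d", n, nw, k)
  hit <- .dpssCache[[key]]
  if (!is.null(hit)) return(hit)
  w <- nw / n
  i <- 0:(n - 1L)
  dv <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  ev <- (1:(n - 1L)) * (n - (1:(n - 1L))) / 2
  A <- matrix(0, n, n)
  A[cbind(seq_len(n), seq_len(n))] <- dv
  A[cbind(1:(n - 1L), 2:n)] <- ev
  A[cbind(2:n, 1:(n - 1L))] <- ev
  vec <- eigen(A, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- vec[, j]
    v <- v / sqrt(sum(v^2))
    lead <- which(abs(v) > 1e-7 * max(abs(v)))[1L]
    if (v[lead] < 0) v <- -v
    vec[, j] <- v
  }
  .dpssCache[[key]] <- vec
  vec
}
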