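# Shared fixtures: random states and an independent matrix exponential.

# random complex matrix with independent normal entries
random_complex_matrix <- function(d) {
  matrix(complex(real = rnorm(d * d), imaginary = rnorm(d * d)), d, d)
}

# random full-rank density matrix (Wishart-like construction)
random_density <- function(d) {
  G <- random_complex_matrix(d)
  rho <- G %*% Conj(t(G))
  rho / Re(sum(diag(rho)))
}

# random pure-state density matrix
random_pure_density <- function(d) {
  v <- complex(real = rnorm(d), imaginary = rnorm(d))
  v <- v / sqrt(sum(Mod(v)^2))
  v %*% Conj(t(v))
}

# independent matrix exponential: scaling-and-squaring on a Taylor series.
# Deliberately not the eigendecomposition route used by the package.
expm_taylor <- function(A, order = 24L) {
  d <- nrow(A)
  nrm <- max(rowSums(Mod(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))) + 2L)
  As <- A / 2^s
  out <- diag(1 + 0i, d)
  term <- diag(1 + 0i, d)
  for (j in seq_len(order)) {
    term <- term %*% As / j
    out <- out + term
  }
  for (j in seq_len(s)) out <- out %*% out
  out
}

max_abs <- function(m) max(abs(m))
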