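#' Angular-momentum operators for a single spin
#'
#' Builds the standard spin matrices `sx`, `sy`, `sz` for a spin quantum
#' number `I` in the `|I, m>` basis ordered `m = +I, ..., -I`, with
#' `hbar = 1` (all operators dimensionless, Hamiltonian terms in rad/s).
#'
#' @param I Spin quantum number; a positive half-integer (1/2, 1, 3/2, ...).
#'
#' @return An object of class `spin_operators`: a list with complex matrices
#'   `sx`, `sy`, `sz` of dimension `2I + 1` and the spin `I`.
#'
#' @examples
#' s <- spin_operators(1/2)
#' s$sz                       # diag(1/2, -1/2)
#' s$sx %*% s$sy - s$sy %*% s$sx  # equals 1i * s$sz
#' @export
spin_operators <- function(I) {
  if (length(I) != 1L || !is.numeric(I) || is.na(I) || I <= 0 ||
      abs(2 * I - round(2 * I)) > 1e-12) {
    stop("`I` must be a positive half-integer (1/2, 1, 3/2, ...)",
         call. = FALSE)
  }
  m <- seq(I, -I, by = -1)
  d <- length(m)
  # ladder operator: <m+1| J+ |m> = sqrt(I(I+1) - m(m+1)), index 1 is m = +I
  jp <- matrix(0 + 0i, d, d)
  if (d > 1L) {
    for (i in 2:d) jp[i - 1L, i] <- sqrt(I * (I + 1) - m[i] * (m[i] + 1))
  }
  sx <- (jp + Conj(t(jp))) / 2
  sy <- (jp - Conj(t(jp))) / 2i
  sz <- diag(complex(real = m), nrow = d)
  structure(list(sx = sx, sy = sy, sz = sz, I = I), class = "spin_operators")
}

#' Embed a single-subsystem operator into a tensor-product space
#'
#' Places `op` on subsystem `slot` of a composite Hilbert space and the
#' identity on every other factor.  The subsystem convention throughout the
#' package is `[electron 1, electron 2, nucleus 1, ..., nucleus N]`.
#'
#' @param op Square (complex) matrix acting on one subsystem.
#' @param slot 1-based index of the subsystem `op` acts on.
#' @param dims Integer vector of subsystem dimensions.
#'
#' @return A complex matrix of dimension `prod(dims)`.
#'
#' @examples
#' s <- spin_operators(1/2)
#' embed_operator(s$sz, 1, c(2, 2))   # S1z on a two-electron space
#' @export
embed_operator <- function(op, slot, dims) {
  op <- as.matrix(op)
  if (length(slot) != 1L || slot < 1L || slot > length(dims))
    stop("`slot` must index into `dims`", call. = FALSE)
  if (nrow(op) != ncol(op) || nrow(op) != dims[slot])
    stop(sprintf("`op` is %dx%d but dims[%d] = %d",
                 nrow(op), ncol(op), slot, dims[slot]), call. = FALSE)
  out <- matrix(1 + 0i, 1L, 1L)
  for (j in seq_along(dims)) {
    blk <- if (j == slot) op else diag(1 + 0i, dims[j])
    out <- out %x% blk
  }
  out
}

# ---- internal linear-algebra helpers -------------------------------------

# Frobenius-norm Hermiticity defect
herm_defect <- function(m) max(abs(m - Conj(t(m))))

is_density_matrix <- function(rho, tol = 1e-8) {
  if (!is.matrix(rho) || nrow(rho) != ncol(rho)) return(FALSE)
  if (herm_defect(rho) > tol) return(FALSE)
  if (abs(sum(diag(rho)) - 1) > tol) return(FALSE)
  ev <- eigen((rho + Conj(t(rho))) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  min(ev) > -tol
}

assert_density_matrix <- function(rho, d = NULL, tol = 1e-8,
                                  what = "rho") {
  if (!is.null(d) && (!is.matrix(rho) || any(dim(rho) != d)))
    stop(sprintf("`%s` must be a %dx%d density matrix", what, d, d),
         call. = FALSE)
  if (!is_density_matrix(rho, tol))
    stop(sprintf("`%s` is not a valid density matrix (Hermitian, unit trace, positive semidefinite)",
                 what), call. = FALSE)
  invisible(rho)
}

# trace out the nuclear factor of a state on (4 x nd)-dimensional space,
# ordering kron(electrons, nuclei)
partial_trace_nuclear <- function(rho_full, nd) {
  de <- nrow(rho_full) / nd
  out <- matrix(0 + 0i, de, de)
  for (a in seq_len(de)) {
    ia <- (a - 1L) * nd + seq_len(nd)
    for (b in seq_len(de)) {
      ib <- (b - 1L) * nd + seq_len(nd)
      out[a, b] <- sum(rho_full[cbind(ia, ib)])
    }
  }
  out
}
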