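#' Precomputed propagator for a radical-pair model
#'
#' Diagonalizes the (Hermitian) Hamiltonian once so that evolution to any
#' time reduces to applying phases; all closed-system dynamics and yield
#' integrals in the package run through this object.
#'
#' @param model An [rp_model()].
#' @return Object of class `rp_propagator`: eigenvalues (rad/s),
#'   eigenvectors, and the model.
#' @export
rp_propagator <- function(model) {
  H <- build_hamiltonian(model)
  e <- eigen(H, symmetric = TRUE)
  structure(list(values = e$values, vectors = e$vectors, model = model),
            class = "rp_propagator")
}

# full-space initial state: electrons in rho_e, nuclei maximally mixed
full_initial_state <- function(model, rho_e) {
  nd <- nuclear_dim(model)
  rho_e %x% (diag(1 + 0i, nd) / nd)
}

# unitary at time t from the spectral decomposition
propagator_unitary <- function(prop, t) {
  V <- prop$vectors
  V %*% (exp(-1i * prop$values * t) * Conj(t(V)))
}

#' Reduced electron state after closed-system evolution
#'
#' Evolves `rho0 (x) (identity / nd)` (nuclei initially maximally mixed)
#' under `U(t) = exp(-i H t)` and traces out the nuclei.
#'
#' @param model An [rp_model()].
#' @param rho0 Initial 4x4 electron density matrix.
#' @param t Time in seconds, `t >= 0`.
#' @param prop Optional cached [rp_propagator()] for `model`.
#' @return The reduced 4x4 electron density matrix at time `t`.
#' @export
evolve_reduced <- function(model, rho0, t, prop = NULL) {
  stopifnot(inherits(model, "rp_model"))
  assert_density_matrix(rho0, d = 4L, what = "rho0")
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("`t` must be a single non-negative time", call. = FALSE)
  if (is.null(prop)) prop <- rp_propagator(model)
  U <- propagator_unitary(prop, t)
  rho_full <- full_initial_state(model, rho0)
  partial_trace_nuclear(U %*% rho_full %*% Conj(t(U)), nuclear_dim(model))
}

#' Kraus operators of the reduced electron channel
#'
#' The reduced dynamics with a maximally mixed nuclear bath form the
#' channel `rho -> sum_ij K_ij rho K_ij^+` with
#' `K_ij = <psi_j| U(t) |psi_i> / sqrt(nd)` over the nuclear product basis
#' (`nd^2` operators; 4 for one spin-1/2 nucleus).
#'
#' @inheritParams evolve_reduced
#' @return Object of class `kraus_set`: list with `operators` (list of 4x4
#'   complex matrices) and `time`.
#' @export
kraus_operators <- function(model, t, prop = NULL) {
  stopifnot(inherits(model, "rp_model"))
  if (!is.numeric(t) || length(t) != 1L || t < 0)
    stop("`t` must be a single non-negative time", call. = FALSE)
  if (is.null(prop)) prop <- rp_propagator(model)
  U <- propagator_unitary(prop, t)
  nd <- nuclear_dim(model)
  ops <- vector("list", nd * nd)
  idx <- 1L
  for (i in seq_len(nd)) {
    for (j in seq_len(nd)) {
      rows <- (seq_len(4L) - 1L) * nd + j
      cols <- (seq_len(4L) - 1L) * nd + i
      ops[[idx]] <- U[rows, cols, drop = FALSE] / sqrt(nd)
      idx <- idx + 1L
    }
  }
  structure(list(operators = ops, time = t), class = "kraus_set")
}

#' Apply a Kraus set to an electron state
#'
#' @param kraus A [kraus_operators()] result.
#' @param rho 4x4 electron density matrix.
#' @return The output density matrix `sum_ij K_ij rho K_ij^+`.
#' @export
apply_kraus <- function(kraus, rho) {
  stopifnot(inherits(kraus, "kraus_set"))
  out <- matrix(0 + 0i, nrow(rho), ncol(rho))
  for (K in kraus$operators) out <- out + K %*% rho %*% Conj(t(K))
  out
}

#' Dark-state population and coherence of an electron state
#'
#' Splits the singlet population `<S|rho|S>` into the dark-state population
#' `f_p = (<D1|rho|D1> + <D2|rho|D2>) / 2` and the dark-state coherence
#' `f_c = -Re <D1|rho|D2>`.  Because `|S> = (D1 - D2)/sqrt(2)` in the
#' phase convention of [dark_basis()], `f_p + f_c = <S|rho|S>` is an exact
#' algebraic identity.
#'
#' @param rho 4x4 electron density matrix.
#' @param basis A [dark_basis()] built for the same field angle as the
#'   dynamics that produced `rho`.
#' @return Named numeric vector `c(f_p = ..., f_c = ...)`.
#' @export
dark_decomposition <- function(rho, basis) {
  stopifnot(inherits(basis, "dark_basis"))
  d1 <- basis$D1
  d2 <- basis$D2
  f_p <- Re(Conj(d1) %*% rho %*% d1 + Conj(d2) %*% rho %*% d2)[1] / 2
  f_c <- -Re(Conj(d1) %*% rho %*% d2)[1]
  c(f_p = f_p, f_c = f_c)
}

#' Remove the dark-state coherence from an electron state
#'
#' Zeroes the `D1`-`D2` off-diagonal elements in the dark/bright basis,
#' leaving every population and every other coherence untouched.  Applied
#' to the singlet projector this gives the incoherent mixture
#' `(|D1><D1| + |D2><D2|) / 2`, which has the same dark-state population as
#' the singlet but no dark-state coherence and no entanglement.
#'
#' @inheritParams dark_decomposition
#' @return The dephased 4x4 density matrix.
#' @export
remove_dark_coherence <- function(rho, basis) {
  stopifnot(inherits(basis, "dark_basis"))
  Tm <- cbind(basis$D1, basis$D2, basis$Bplus, basis$Bminus)
  rb <- Conj(t(Tm)) %*% rho %*% Tm
  rb[1, 2] <- 0
  rb[2, 1] <- 0
  Tm %*% rb %*% Conj(t(Tm))
}

#' The canonical incoherent counterpart of the singlet state
#'
#' @param theta Field polar angle in radians.
#' @return `(|D1><D1| + |D2><D2|)/2` for the dark basis at `theta`.
#' @export
incoherent_dark_state <- function(theta) {
  remove_dark_coherence(singlet_projector(), dark_basis(theta))
}

# ---- spectral machinery shared by traces and yields ----------------------

# electron-space observables whose expectations give p_singlet, f_p, f_c
dark_observables <- function(basis) {
  d1 <- basis$D1
  d2 <- basis$D2
  list(
    p_singlet = singlet_projector(),
    f_p = (d1 %*% Conj(t(d1)) + d2 %*% Conj(t(d2))) / 2,
    f_c = -(d1 %*% Conj(t(d2)) + d2 %*% Conj(t(d1))) / 2
  )
}

# For observable W (electron space) and full initial state rho_full0,
# returns coefficients c and frequencies w with
#   Tr[(W (x) 1) rho(t)] = Re sum(c * exp(-1i w t)).
spectral_terms <- function(prop, rho_full0, W_e) {
  V <- prop$vectors
  nd <- length(prop$values) / 4L
  rho_eig <- Conj(t(V)) %*% rho_full0 %*% V
  W_eig <- Conj(t(V)) %*% (W_e %x% diag(1 + 0i, nd)) %*% V
  list(c = as.vector(t(W_eig) * rho_eig),
       w = as.vector(outer(prop$values, prop$values, "-")))
}

# evaluate a spectral-term expectation on a vector of times (chunked)
spectral_expectation <- function(terms, times, chunk = 65536L) {
  out <- numeric(length(times))
  for (start in seq(1L, length(times), by = chunk)) {
    i <- start:min(start + chunk - 1L, length(times))
    out[i] <- Re(exp(outer(times[i], terms$w, function(t, w) -1i * w * t)) %*%
                   terms$c)
  }
  out
}

#' Time series of the dark-state decomposition
#'
#' Samples `f_p(t)`, `f_c(t)` and the singlet population on a uniform time
#' grid under closed-system evolution.  Defaults resolve the fastest
#' coherent oscillations at the reference parameters (about 4e7 rad/s) with
#' several points per period while covering 12 recombination lifetimes.
#'
#' @inheritParams evolve_reduced
#' @param t_max End of the grid in seconds (default `12 / model$k`).
#' @param n_steps Number of grid points (default 4096).
#' @param basis Optional [dark_basis()]; defaults to the model's own angle.
#' @return Object of class `coherence_trace`: a data.frame with columns
#'   `time_s`, `f_p`, `f_c`, `p_singlet` satisfying
#'   `f_p + f_c = p_singlet` pointwise.
#' @export
trace_series <- function(model, rho0, t_max = 12 / model$k, n_steps = 4096L,
                         prop = NULL, basis = NULL) {
  stopifnot(inherits(model, "rp_model"))
  assert_density_matrix(rho0, d = 4L, what = "rho0")
  if (t_max <= 0) stop("`t_max` must be positive", call. = FALSE)
  if (n_steps < 2L) stop("`n_steps` must be at least 2", call. = FALSE)
  if (is.null(prop)) prop <- rp_propagator(model)
  if (is.null(basis)) basis <- dark_basis(model$theta)
  times <- seq(0, t_max, length.out = n_steps)
  rho_full0 <- full_initial_state(model, rho0)
  obs <- dark_observables(basis)
  cols <- lapply(obs, function(W) {
    spectral_expectation(spectral_terms(prop, rho_full0, W), times)
  })
  out <- data.frame(time_s = times, f_p = cols$f_p, f_c = cols$f_c,
                    p_singlet = cols$p_singlet)
  class(out) <- c("coherence_trace", "data.frame")
  out
}
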