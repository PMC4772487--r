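#' Verify that the reduced dynamics is an incoherent operation
#'
#' The reduced electron channel (Kraus form, maximally mixed nuclear bath)
#' should map every state that is diagonal in the dark basis to another
#' dark-diagonal state, i.e. never create dark-state coherence from an
#' incoherent input.  For each requested time this applies the channel to
#' `|D1><D1|`, `|D2><D2|` and mixtures of them, and records the largest
#' dark-state off-diagonal magnitude generated, alongside the Kraus
#' completeness defect `max |sum K^+ K - 1|`.
#'
#' @param model An [rp_model()].
#' @param times Times in seconds at which the channel is checked.
#' @param tol_coherence,tol_completeness Pass thresholds for the two
#'   recorded magnitudes.
#' @param mixture_weights Weights `p1` of the tested mixtures
#'   `p1 |D1><D1| + (1 - p1) |D2><D2|`.
#' @return Object of class `incoherence_report`: `times_checked`,
#'   `max_generated_coherence`, `kraus_completeness_defect`, `passed`.
#' @export
check_incoherent_operation <- function(model, times = c(0.1, 1, 5) / model$k,
                                       tol_coherence = 1e-10,
                                       tol_completeness = 1e-10,
                                       mixture_weights = c(0, 0.3, 0.5, 1)) {
  stopifnot(inherits(model, "rp_model"))
  if (length(times) == 0L) stop("`times` must be non-empty", call. = FALSE)
  basis <- dark_basis(model$theta)
  prop <- rp_propagator(model)
  d1 <- basis$D1
  d2 <- basis$D2
  P1 <- d1 %*% Conj(t(d1))
  P2 <- d2 %*% Conj(t(d2))
  max_coh <- 0
  max_defect <- 0
  for (t in times) {
    ks <- kraus_operators(model, t, prop = prop)
    csum <- Reduce(`+`, lapply(ks$operators,
                               function(K) Conj(t(K)) %*% K))
    max_defect <- max(max_defect, max(abs(csum - diag(1 + 0i, 4))))
    for (p1 in mixture_weights) {
      out <- apply_kraus(ks, p1 * P1 + (1 - p1) * P2)
      max_coh <- max(max_coh, abs((Conj(d1) %*% out %*% d2)[1]))
    }
  }
  structure(list(times_checked = times,
                 max_generated_coherence = max_coh,
                 kraus_completeness_defect = max_defect,
                 passed = max_coh <= tol_coherence &&
                   max_defect <= tol_completeness),
            class = "incoherence_report")
}

#' @export
print.incoherence_report <- function(x, ...) {
  cat("<incoherence_report>\n")
  cat(sprintf("  times checked: %s s\n",
              paste(signif(x$times_checked, 3), collapse = ", ")))
  cat(sprintf("  max generated dark coherence: %.3g\n",
              x$max_generated_coherence))
  cat(sprintf("  Kraus completeness defect:    %.3g\n",
              x$kraus_completeness_defect))
  cat(sprintf("  passed: %s\n", x$passed))
  invisible(x)
}

#' Wootters concurrence of a two-qubit state
#'
#' `C = max(0, l1 - l2 - l3 - l4)` where `l_i` are the decreasing square
#' roots of the eigenvalues of `rho (sy x sy) conj(rho) (sy x sy)`.  Zero
#' for separable states, one for Bell states.
#'
#' @param rho 4x4 density matrix.
#' @return Concurrence in `[0, 1]`.
#' @export
concurrence <- function(rho) {
  if (!is.matrix(rho) || any(dim(rho) != 4L))
    stop("`rho` must be a 4x4 two-qubit density matrix", call. = FALSE)
  assert_density_matrix(rho, d = 4L)
  sy <- matrix(c(0, 1i, -1i, 0), 2, 2)
  YY <- sy %x% sy
  R <- rho %*% YY %*% Conj(rho) %*% YY
  ev <- sort(pmax(Re(eigen(R, only.values = TRUE)$values), 0),
             decreasing = TRUE)
  l <- sqrt(ev)
  max(0, l[1] - l[2] - l[3] - l[4])
}

#' Concurrence along a reduced-dynamics trajectory
#'
#' @param model An [rp_model()].
#' @param rho0 Initial 4x4 electron density matrix.
#' @param times Times in seconds.
#' @return Numeric vector of concurrences, one per time.
#' @export
entanglement_trace <- function(model, rho0, times) {
  stopifnot(inherits(model, "rp_model"))
  assert_density_matrix(rho0, d = 4L, what = "rho0")
  prop <- rp_propagator(model)
  vapply(times, function(t) {
    rho <- evolve_reduced(model, rho0, t, prop = prop)
    # symmetrize away round-off before the eigen computation
    concurrence((rho + Conj(t(rho))) / 2)
  }, numeric(1))
}

# operator Schmidt rank of a 4x4 operator across the 2x2 electron split;
# rank 1 means K = A (x) B (a local operator).  Internal, used to verify
# that the channel is local.
operator_schmidt_values <- function(K) {
  # reshuffle K[(a1 a2), (b1 b2)] -> R[(a1 b1), (a2 b2)]
  R <- matrix(0 + 0i, 4, 4)
  for (a1 in 0:1) for (a2 in 0:1) for (b1 in 0:1) for (b2 in 0:1) {
    R[a1 * 2 + b1 + 1, a2 * 2 + b2 + 1] <- K[a1 * 2 + a2 + 1, b1 * 2 + b2 + 1]
  }
  svd(R)$d
}
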