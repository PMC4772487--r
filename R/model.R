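#' Electron gyromagnetic ratio used by the radical-pair model
#'
#' Returns `gamma = mu_B * g_s / (2 * hbar)` with `g_s = 2`, i.e. the
#' proportionality between the magnetic field and the electron Zeeman
#' angular frequency in this model's convention (`H_B = gamma * B . (S1 + S2)`
#' with spin-1/2 operators).  Numerically `gamma / (2*pi)` is about
#' 14 GHz/T.  Note that some references write `gamma = mu_B g_s / 2`
#' without the explicit `hbar`; the rad s^-1 T^-1 value returned here is
#' that expression divided by `hbar`, which is what a Hamiltonian in
#' angular-frequency units requires.
#'
#' @return Gyromagnetic ratio in rad s^-1 T^-1.
#' @export
electron_gamma <- function() {
  mu_B <- 9.2740100783e-24   # J/T
  hbar <- 1.054571817e-34    # J s
  g_s <- 2
  mu_B * g_s / (2 * hbar)
}

#' Reference hyperfine energy scale Lambda
#'
#' The electron Zeeman angular frequency in a 46 uT field (the geomagnetic
#' intensity in Frankfurt), `Lambda = gamma * 46e-6 T`, used as the unit in
#' which hyperfine couplings are specified.
#'
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1.
#' @return Energy scale in rad/s (about 4.05e6 rad/s at the default gamma).
#' @export
lambda_scale <- function(gamma = electron_gamma()) {
  gamma * 46e-6
}

#' Construct a radical-pair model
#'
#' Full parameterization of the radical-pair spin system: two electron
#' spins in an external static field of intensity `B0_uT` whose direction
#' makes polar angle `theta` (and azimuth `phi`) with the hyperfine
#' principal z axis, with electron 1 hyperfine-coupled to `N` nuclei, and
#' spin-independent recombination at rate `k` (equal singlet and triplet
#' rates).  Hyperfine principal values are given in units of the reference
#' scale [lambda_scale()].
#'
#' @param theta Polar angle of the field in radians, in `[0, pi]`.
#' @param B0_uT Field intensity in microtesla (default 46, the reference
#'   geomagnetic intensity).
#' @param phi Azimuth of the field in radians (default 0; with an axially
#'   symmetric hyperfine tensor the dynamics do not depend on it).
#' @param A_Lambda Hyperfine principal values `(Ax, Ay, Az)` in units of
#'   Lambda; a numeric length-3 vector for one nucleus or a list of such
#'   vectors for several.
#' @param nuclear_spins Half-integer spins of the nuclei (default all 1/2).
#' @param k Recombination rate in s^-1 (default 1e4).
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1.
#'
#' @return An object of class `rp_model` with fields `B0` (tesla), `theta`,
#'   `phi`, `A` (list of rad/s principal-value vectors), `A_Lambda`,
#'   `nuclear_spins`, `k`, `gamma`, `omega0 = gamma * B0`, `Lambda`, `N`,
#'   and `dims` (subsystem dimensions, electrons first).
#'
#' @examples
#' m <- rp_model(theta = pi / 4)        # the reference parameter set
#' m$omega0 / m$k                       # ~ 405: slow recombination
#' @export
rp_model <- function(theta = 0, B0_uT = 46, phi = 0,
                     A_Lambda = c(3, 3, 5),
                     nuclear_spins = NULL, k = 1e4,
                     gamma = electron_gamma()) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > pi)
    stop("`theta` must be a single angle in [0, pi]", call. = FALSE)
  if (!is.numeric(B0_uT) || length(B0_uT) != 1L || B0_uT < 0)
    stop("`B0_uT` must be a single non-negative intensity", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("`k` must be a single positive rate", call. = FALSE)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be a single positive rate", call. = FALSE)
  if (is.numeric(A_Lambda)) A_Lambda <- list(A_Lambda)
  if (!is.list(A_Lambda) ||
      !all(vapply(A_Lambda, function(a) is.numeric(a) && length(a) == 3L,
                  logical(1))))
    stop("`A_Lambda` must be a length-3 numeric vector or a list of them",
         call. = FALSE)
  N <- length(A_Lambda)
  if (is.null(nuclear_spins)) nuclear_spins <- rep(1 / 2, N)
  if (length(nuclear_spins) != N)
    stop("`nuclear_spins` must have one entry per hyperfine tensor",
         call. = FALSE)
  for (I in nuclear_spins) {
    if (I <= 0 || abs(2 * I - round(2 * I)) > 1e-12)
      stop("nuclear spins must be positive half-integers", call. = FALSE)
  }
  Lambda <- lambda_scale(gamma)
  structure(list(
    B0 = B0_uT * 1e-6,
    theta = theta,
    phi = phi,
    A = lapply(A_Lambda, function(a) a * Lambda),
    A_Lambda = A_Lambda,
    nuclear_spins = nuclear_spins,
    k = k,
    gamma = gamma,
    omega0 = gamma * B0_uT * 1e-6,
    Lambda = Lambda,
    N = N,
    dims = c(2L, 2L, vapply(nuclear_spins,
                            function(I) as.integer(round(2 * I + 1)),
                            integer(1)))
  ), class = "rp_model")
}

#' @export
print.rp_model <- function(x, ...) {
  cat("<rp_model>\n")
  cat(sprintf("  B0 = %.3g uT, theta = %.4f rad, phi = %.4f rad\n",
              x$B0 * 1e6, x$theta, x$phi))
  cat(sprintf("  omega0 = %.4g rad/s, Lambda = %.4g rad/s, k = %.3g 1/s\n",
              x$omega0, x$Lambda, x$k))
  for (n in seq_len(x$N)) {
    cat(sprintf("  nucleus %d: I = %g, A/Lambda = (%g, %g, %g)\n",
                n, x$nuclear_spins[n],
                x$A_Lambda[[n]][1], x$A_Lambda[[n]][2], x$A_Lambda[[n]][3]))
  }
  invisible(x)
}

# dimension of the nuclear factor
nuclear_dim <- function(model) prod(model$dims[-(1:2)])

#' Static field vector
#'
#' @param model An [rp_model()].
#' @return Length-3 numeric vector `(Bx, By, Bz)` in tesla:
#'   `B0 * (sin(theta) cos(phi), sin(theta) sin(phi), cos(theta))`.
#' @export
field_vector <- function(model) {
  stopifnot(inherits(model, "rp_model"))
  model$B0 * c(sin(model$theta) * cos(model$phi),
               sin(model$theta) * sin(model$phi),
               cos(model$theta))
}

#' Radical-pair Hamiltonian on the full electron-nuclear space
#'
#' `H = gamma * B . (S1 + S2) + sum_n In . A_n . S1` in rad/s, with the
#' hyperfine tensors diagonal in the molecular frame and every nucleus
#' coupled to electron 1 only.
#'
#' @param model An [rp_model()].
#' @return Hermitian complex matrix of dimension `prod(model$dims)`
#'   (8 for one spin-1/2 nucleus).
#' @export
build_hamiltonian <- function(model) {
  stopifnot(inherits(model, "rp_model"))
  dims <- model$dims
  s <- spin_operators(1 / 2)
  ax <- c("sx", "sy", "sz")
  S1 <- lapply(ax, function(a) embed_operator(s[[a]], 1L, dims))
  S2 <- lapply(ax, function(a) embed_operator(s[[a]], 2L, dims))
  B <- field_vector(model)
  H <- matrix(0 + 0i, prod(dims), prod(dims))
  for (a in 1:3) H <- H + model$gamma * B[a] * (S1[[a]] + S2[[a]])
  for (n in seq_len(model$N)) {
    In <- spin_operators(model$nuclear_spins[n])
    for (a in 1:3) {
      H <- H + model$A[[n]][a] *
        (embed_operator(In[[ax[a]]], n + 2L, dims) %*% S1[[a]])
    }
  }
  H
}

#' Dimensionless two-electron Zeeman matrix M(theta)
#'
#' `M(theta) = 2 * (sin(theta) (S1x + S2x) + cos(theta) (S1z + S2z))` on the
#' two-electron space, so that the Zeeman Hamiltonian is
#' `H_B = (gamma * B0 / 2) * M(theta)` (with `phi = 0`).  Its spectrum is
#' `{2, -2, 0, 0}` for every `theta`; the two zero modes are the dark
#' states.
#'
#' @param theta Polar angle of the field in radians, in `[0, pi]`.
#' @return A real symmetric 4x4 matrix in the basis
#'   `{|uu>, |ud>, |du>, |dd>}`.
#' @export
zeeman_matrix <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > pi)
    stop("`theta` must be a single angle in [0, pi]", call. = FALSE)
  s <- spin_operators(1 / 2)
  d2 <- c(2L, 2L)
  m <- 2 * (sin(theta) * (embed_operator(s$sx, 1L, d2) +
                            embed_operator(s$sx, 2L, d2)) +
              cos(theta) * (embed_operator(s$sz, 1L, d2) +
                              embed_operator(s$sz, 2L, d2)))
  Re(m)
}

#' Dark and bright basis of the two-electron Zeeman operator
#'
#' The four eigenvectors of `M(theta)`, built analytically as products of
#' the single-electron Zeeman eigenvectors along the field:
#' `|up_theta> = cos(theta/2)|u> + sin(theta/2)|d>` and
#' `|dn_theta> = -sin(theta/2)|u> + cos(theta/2)|d>`.  The dark states
#' `D1 = |up_theta, dn_theta>` and `D2 = |dn_theta, up_theta>` carry
#' eigenvalue 0, the bright states `Bplus = |up_theta, up_theta>` and
#' `Bminus = |dn_theta, dn_theta>` eigenvalues +2 and -2.  With this phase
#' convention the singlet is exactly `(D1 - D2)/sqrt(2)` for every theta.
#' The rotated-product construction (rather than a numerical eigensolver)
#' resolves the two-fold degeneracy of the zero eigenvalue uniquely, which
#' the population/coherence decomposition requires.
#'
#' @param theta Polar angle of the field in radians, in `[0, pi]`.
#' @return An object of class `dark_basis`: list with unit vectors `D1`,
#'   `D2`, `Bplus`, `Bminus` (length 4, complex) and `theta`.
#' @export
dark_basis <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > pi)
    stop("`theta` must be a single angle in [0, pi]", call. = FALSE)
  up <- c(cos(theta / 2), sin(theta / 2)) + 0i
  dn <- c(-sin(theta / 2), cos(theta / 2)) + 0i
  structure(list(
    D1 = as.vector(up %x% dn),
    D2 = as.vector(dn %x% up),
    Bplus = as.vector(up %x% up),
    Bminus = as.vector(dn %x% dn),
    theta = theta
  ), class = "dark_basis")
}

#' Two-electron singlet state and projector
#'
#' @return `singlet_state()`: the vector `(|ud> - |du>)/sqrt(2)`;
#'   `singlet_projector()`: the corresponding 4x4 projector.
#' @export
singlet_state <- function() {
  c(0, 1, -1, 0) / sqrt(2) + 0i
}

#' @rdname singlet_state
#' @export
singlet_projector <- function() {
  s <- singlet_state()
  s %*% Conj(t(s))
}
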