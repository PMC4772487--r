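#' Effective fields of the single-nucleus, axial-coupling model
#'
#' With one spin-1/2 nucleus and `Ax = Ay = 0`, the nuclear z projection is
#' conserved and each nuclear sector merely shifts the axial field seen by
#' electron 1: the transverse component is `B_x = B0 sin(theta)` and the
#' axial component `B0 cos(theta) +/- Az / (2 gamma)` for nuclear up/down.
#' Electron 1 then precesses about a tilted effective field `B_+` or `B_-`
#' while electron 2 precesses about the bare field.
#'
#' @param B0 Field intensity in tesla.
#' @param theta Field polar angle in radians.
#' @param Az Axial hyperfine coupling in rad/s.
#' @param gamma Gyromagnetic ratio in rad s^-1 T^-1.
#' @return Object of class `effective_fields`: `B_plus`, `B_minus` (tesla),
#'   `omega_plus`, `omega_minus` (rad/s), `theta_plus`, `theta_minus`
#'   (radians, measured from the hyperfine z axis), `B_x`, plus the inputs
#'   `theta` and `omega0 = gamma * B0` needed downstream.
#' @export
effective_fields <- function(B0, theta, Az, gamma = electron_gamma()) {
  stopifnot(is.numeric(B0), B0 >= 0, is.numeric(theta),
            theta >= 0, theta <= pi, is.numeric(Az), gamma > 0)
  B_x <- B0 * sin(theta)
  Bz_p <- B0 * cos(theta) + Az / (2 * gamma)
  Bz_m <- B0 * cos(theta) - Az / (2 * gamma)
  B_p <- sqrt(B_x^2 + Bz_p^2)
  B_m <- sqrt(B_x^2 + Bz_m^2)
  structure(list(
    B_plus = B_p, B_minus = B_m,
    omega_plus = gamma * B_p, omega_minus = gamma * B_m,
    theta_plus = atan2(B_x, Bz_p), theta_minus = atan2(B_x, Bz_m),
    B_x = B_x, theta = theta, omega0 = gamma * B0
  ), class = "effective_fields")
}

#' Closed-form dark-state population and coherence (single nucleus, Ax=Ay=0)
#'
#' Exact solution for a singlet initial electron pair and a maximally mixed
#' spin-1/2 nucleus.  In the frame aligned with the static field, electron
#' 2 precesses at `omega0` about the field axis while electron 1 precesses
#' at `omega_pm` about an axis tilted by `alpha_pm = theta_pm - theta`;
#' writing the diagonal element of the electron-1 propagator as
#' `u = cos(omega_pm t / 2) - i cos(alpha_pm) sin(omega_pm t / 2)`, the two
#' nuclear sectors give
#' \deqn{f_p = (1 - \sin^2\alpha_\pm \sin^2(\omega_\pm t/2)) / 2, \quad
#'       f_c = \mathrm{Re}(u^2 e^{i \omega_0 t}) / 2,}
#' averaged with weight 1/2 each.  `f_p` therefore oscillates at
#' `omega_pm` and `f_c` at `omega0` and `omega_pm +/- omega0`, all far
#' above the recombination rate in the compass regime.  These forms are
#' validated against the numerical propagator in the test-suite.
#'
#' @param params An [effective_fields()] object.
#' @param t Time(s) in seconds (vectorized).
#' @return List with numeric vectors `f_p` and `f_c`.
#' @export
analytic_fpfc <- function(params, t) {
  stopifnot(inherits(params, "effective_fields"))
  omega0 <- params$omega0
  sector <- function(omega, alpha) {
    ca <- cos(alpha)
    sa2 <- sin(alpha)^2
    f_p <- (1 - sa2 * sin(omega * t / 2)^2) / 2
    # u^2 = sa2/2 + (1 + ca^2) cos(omega t)/2 - i ca sin(omega t)
    re_u2 <- sa2 / 2 + (1 + ca^2) * cos(omega * t) / 2
    im_u2 <- -ca * sin(omega * t)
    f_c <- (cos(omega0 * t) * re_u2 - sin(omega0 * t) * im_u2) / 2
    list(f_p = f_p, f_c = f_c)
  }
  p <- sector(params$omega_plus, params$theta_plus - params$theta)
  m <- sector(params$omega_minus, params$theta_minus - params$theta)
  list(f_p = (p$f_p + m$f_p) / 2, f_c = (p$f_c + m$f_c) / 2)
}

#' Rotating-wave singlet yield of the single-nucleus, Ax=Ay=0 model
#'
#' In the compass regime every oscillation frequency of `f_p` and `f_c`
#' (`omega_pm`, `omega0`, `omega_pm +/- omega0`) greatly exceeds the
#' recombination rate `k`, so the `k e^{-kt}`-weighted integrals of the
#' oscillatory terms are negligible.  Dropping them leaves
#' `Phi_c = 0` identically and
#' `Phi_p = 1/2 - (sin^2 alpha_+ + sin^2 alpha_-) / 8` with
#' `alpha_pm = theta_pm - theta`: the yield is carried entirely by the
#' time-averaged dark-state population.
#'
#' @param params An [effective_fields()] object.
#' @param k Recombination rate in s^-1.
#' @return List with `phi_p`, `phi_c` (always 0), and `regime_ok`
#'   (FALSE when some retained frequency is below `10 k`, i.e. the
#'   approximation is not guaranteed accurate).
#' @export
rwa_yield <- function(params, k) {
  stopifnot(inherits(params, "effective_fields"), is.numeric(k), k > 0)
  freqs <- c(params$omega0, params$omega_plus, params$omega_minus,
             abs(params$omega_plus - params$omega0),
             abs(params$omega_plus + params$omega0),
             abs(params$omega_minus - params$omega0),
             abs(params$omega_minus + params$omega0))
  regime_ok <- all(freqs >= 10 * k)
  if (!regime_ok)
    warning("rotating-wave regime violated: an oscillation frequency is below 10 k",
            call. = FALSE)
  a_p <- params$theta_plus - params$theta
  a_m <- params$theta_minus - params$theta
  list(phi_p = 1 / 2 - (sin(a_p)^2 + sin(a_m)^2) / 8,
       phi_c = 0,
       regime_ok = regime_ok)
}
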