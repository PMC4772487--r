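#' Reference single-nucleus compass model
#'
#' The parameter set used throughout the package's worked examples:
#' `B0 = 46 uT`, one spin-1/2 nucleus with `Ax = Ay = 3 Lambda`,
#' `Az = 5 Lambda`, `k = 1e4 s^-1`.
#'
#' @param theta Field polar angle in radians.
#' @return An [rp_model()].
#' @export
reference_model <- function(theta = 0) {
  rp_model(theta = theta, B0_uT = 46, A_Lambda = c(3, 3, 5), k = 1e4)
}

# write a data.frame as CSV plus a JSON metadata sidecar
write_run_output <- function(table, meta, out_dir, stem) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(table, file.path(out_dir, paste0(stem, ".csv")),
                   row.names = FALSE)
  jsonlite::write_json(meta, file.path(out_dir, paste0(stem, "_meta.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

model_metadata <- function(model) {
  list(B0_uT = model$B0 * 1e6, phi = model$phi,
       A_Lambda = model$A_Lambda, nuclear_spins = model$nuclear_spins,
       k_per_s = model$k, gamma_rad_per_s_per_T = model$gamma,
       Lambda_rad_per_s = model$Lambda)
}

#' Noiseless yield profile with dark-state decomposition
#'
#' Sweeps the field direction for the noiseless model and reports the
#' yield decomposition per angle together with the summary magnitudes
#' `max |Phi_c|` and `max |Phi_p - Phi_s|` (both of which should be
#' indistinguishable from zero: the dark-state population carries the
#' whole yield).
#'
#' @param model An [rp_model()] (default [reference_model()]).
#' @param init Initial electron state (`"singlet"`, `"incoherent_dark"`
#'   or a matrix).
#' @param theta_grid Angles in radians (default 91 points on `[0, pi/2]`).
#' @param out_dir Optional directory for CSV + JSON sidecar output.
#' @return List with `table` (theta_rad, phi_s, phi_p, phi_c) and
#'   `summary` (max_abs_phi_c, max_abs_phi_p_minus_phi_s, anisotropy).
#' @export
run_profile <- function(model = reference_model(), init = "singlet",
                        theta_grid = seq(0, pi / 2, length.out = 91L),
                        out_dir = NULL) {
  tab <- yield_vs_theta(model, init = init, theta_grid = theta_grid)
  summary <- list(
    max_abs_phi_c = max(abs(tab$phi_c)),
    max_abs_phi_p_minus_phi_s = max(abs(tab$phi_p - tab$phi_s)),
    anisotropy = anisotropy(tab)
  )
  meta <- c(model_metadata(model),
            list(run = "profile", init = if (is.matrix(init)) "custom" else init,
                 n_theta = length(theta_grid), summary = summary))
  write_run_output(tab, meta, out_dir, "profile")
  list(table = tab, summary = summary)
}

#' Yield profiles under magnetic white noise
#'
#' Sweeps the field direction for vertical (`vartheta = theta + pi/2`) and
#' parallel (`vartheta = theta`) magnetic white noise across a set of
#' rates, reporting per-rate profiles and anisotropies.
#'
#' @param model An [rp_model()] (default [reference_model()]).
#' @param vertical_rates,parallel_rates Noise rates in units of `model$k`.
#' @param theta_grid Angles in radians (default 31 points on `[0, pi/2]`).
#' @param out_dir Optional directory for CSV + JSON sidecar output.
#' @return List with `vertical` and `parallel` [noise_sweep()] objects and
#'   `noiseless_anisotropy`.
#' @export
run_magnetic_noise <- function(model = reference_model(),
                               vertical_rates = c(0.01, 0.1, 1),
                               parallel_rates = c(0.1, 1, 10, 100),
                               theta_grid = seq(0, pi / 2,
                                                length.out = 31L),
                               out_dir = NULL) {
  base <- noise_sweep(model, noise_config("magnetic", 0, "perpendicular"),
                      rates = 0, theta_grid = theta_grid)
  vert <- noise_sweep(model, noise_config("magnetic", 0, "perpendicular"),
                      rates = vertical_rates * model$k,
                      theta_grid = theta_grid)
  parl <- noise_sweep(model, noise_config("magnetic", 0, "parallel"),
                      rates = parallel_rates * model$k,
                      theta_grid = theta_grid)
  a0 <- base$summary$anisotropy[1]
  if (!is.null(out_dir)) {
    tab <- rbind(cbind(mode = "vertical", vert$profiles),
                 cbind(mode = "parallel", parl$profiles))
    meta <- c(model_metadata(model),
              list(run = "magnetic_noise",
                   noiseless_anisotropy = a0,
                   vertical = vert$summary, parallel = parl$summary))
    write_run_output(tab, meta, out_dir, "magnetic_noise")
  }
  list(vertical = vert, parallel = parl, noiseless_anisotropy = a0)
}

#' Yield profiles under hyperfine-coupling white noise
#'
#' @param model An [rp_model()] (default [reference_model()]); must have a
#'   single nucleus.
#' @param rates Noise rates in units of `model$k`.
#' @param theta_grid Angles in radians (default 31 points on `[0, pi/2]`).
#' @param out_dir Optional directory for CSV + JSON sidecar output.
#' @return List with `sweep` (a [noise_sweep()]) and
#'   `noiseless_anisotropy`.
#' @export
run_hyperfine_noise <- function(model = reference_model(),
                                rates = c(0, 0.1, 1, 10),
                                theta_grid = seq(0, pi / 2,
                                                 length.out = 31L),
                                out_dir = NULL) {
  if (model$N != 1L)
    stop("hyperfine-coupling noise is defined for the single-nucleus model only",
         call. = FALSE)
  sw <- noise_sweep(model, noise_config("hyperfine", 0),
                    rates = rates * model$k, theta_grid = theta_grid)
  a0 <- if (0 %in% rates) {
    sw$summary$anisotropy[sw$summary$rate_per_s == 0][1]
  } else {
    anisotropy(yield_vs_theta(model, theta_grid = theta_grid))
  }
  if (!is.null(out_dir)) {
    meta <- c(model_metadata(model),
              list(run = "hyperfine_noise", noiseless_anisotropy = a0,
                   summary = sw$summary))
    write_run_output(sw$profiles, meta, out_dir, "hyperfine_noise")
  }
  list(sweep = sw, noiseless_anisotropy = a0)
}

#' Headline claim checks, as a machine-readable report
#'
#' Runs the package's full claim suite at the given model parameters:
#' the `{2, -2, 0, 0}` spectrum of `M(theta)`; `Phi_c ~ 0` and
#' `Phi_p ~ Phi_s` along the direction sweep; equality of the singlet and
#' incoherent-initial-state yields; the incoherence of the reduced channel;
#' and the absence of entanglement along the incoherent trajectory.
#'
#' @param model An [rp_model()] (default [reference_model()]).
#' @param theta_grid Angles for the yield sweep (default 19 points on
#'   `[0, pi/2]`).
#' @param out_dir Optional directory; the report is written as JSON.
#' @return A nested list report; each claim has measured values and a
#'   `pass` flag.
#' @export
run_claims <- function(model = reference_model(),
                       theta_grid = seq(0, pi / 2, length.out = 19L),
                       out_dir = NULL) {
  ev <- sort(eigen(zeeman_matrix(pi / 3), symmetric = TRUE,
                   only.values = TRUE)$values)
  claim_eigen <- list(eigenvalues = ev,
                      pass = max(abs(ev - c(-2, 0, 0, 2))) < 1e-12)

  tab_s <- yield_vs_theta(model, init = "singlet", theta_grid = theta_grid)
  tab_i <- yield_vs_theta(model, init = "incoherent_dark",
                          theta_grid = theta_grid)
  claim_dark <- list(
    max_abs_phi_c = max(abs(tab_s$phi_c)),
    max_abs_phi_p_minus_phi_s = max(abs(tab_s$phi_p - tab_s$phi_s)),
    pass = max(abs(tab_s$phi_c)) <= 0.01 &&
      max(abs(tab_s$phi_p - tab_s$phi_s)) <= 0.01
  )
  claim_equal <- list(
    max_abs_yield_difference = max(abs(tab_s$phi_s - tab_i$phi_s)),
    max_abs_incoherent_phi_c = max(abs(tab_i$phi_c)),
    pass = max(abs(tab_s$phi_s - tab_i$phi_s)) <= 0.01
  )

  inc <- check_incoherent_operation(model)
  mid <- stats::median(seq(0, pi / 2, length.out = 3L))
  m_mid <- model
  m_mid$theta <- mid
  conc <- entanglement_trace(m_mid, incoherent_dark_state(mid),
                             times = c(0.1, 0.5, 1, 2, 5) / model$k)
  claim_local <- list(max_concurrence_incoherent = max(conc),
                      pass = max(conc) <= 1e-8)

  report <- list(
    model = model_metadata(model),
    zeeman_spectrum = claim_eigen,
    dark_state_determines_yield = claim_dark,
    initial_state_equivalence = claim_equal,
    incoherent_operation = list(
      max_generated_coherence = inc$max_generated_coherence,
      kraus_completeness_defect = inc$kraus_completeness_defect,
      pass = inc$passed
    ),
    no_entanglement_generation = claim_local,
    all_pass = claim_eigen$pass && claim_dark$pass && claim_equal$pass &&
      inc$passed && claim_local$pass
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "claims.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Build a model from a configuration list
#'
#' Accepts the nested list produced by reading a YAML/JSON run
#' configuration.  Recognized keys under `model`: `B0_uT`, `theta_rad` or
#' `theta_deg`, `phi_rad`/`phi_deg`, `A_per_nucleus_Lambda` (vector or list
#' of vectors), `nuclear_spins`, `k_per_s`, `gamma_rad_per_s_per_T`.
#'
#' @param config A named list (e.g. `yaml::read_yaml(path)`).
#' @return An [rp_model()].
#' @export
model_from_config <- function(config) {
  mc <- config$model
  if (is.null(mc)) mc <- list()
  angle <- function(rad, deg, default) {
    if (!is.null(mc[[rad]])) return(mc[[rad]])
    if (!is.null(mc[[deg]])) return(mc[[deg]] * pi / 180)
    default
  }
  A <- mc$A_per_nucleus_Lambda
  if (is.null(A)) A <- c(3, 3, 5)
  if (is.list(A)) A <- lapply(A, unlist)
  rp_model(
    theta = angle("theta_rad", "theta_deg", 0),
    B0_uT = if (is.null(mc$B0_uT)) 46 else mc$B0_uT,
    phi = angle("phi_rad", "phi_deg", 0),
    A_Lambda = A,
    nuclear_spins = if (is.null(mc$nuclear_spins)) NULL
                    else unlist(mc$nuclear_spins),
    k = if (is.null(mc$k_per_s)) 1e4 else mc$k_per_s,
    gamma = if (is.null(mc$gamma_rad_per_s_per_T)) electron_gamma()
            else mc$gamma_rad_per_s_per_T
  )
}
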