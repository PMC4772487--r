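test_that("noise operators have the stated geometry", {
  m <- reference_model(0.7)
  # parallel magnetic noise annihilates the dark states at the same angle
  Vp <- noise_operator(m, noise_config("magnetic", 1, "parallel"))
  b <- dark_basis(0.7)
  for (d in list(b$D1, b$D2)) {
    expect_lt(max_abs(Vp %*% (d %x% c(1, 0 + 0i))), 1e-13)
    expect_lt(max_abs(Vp %*% (d %x% c(0, 1 + 0i))), 1e-13)
  }
  # spectrum of the electron part is {1, -1, 0, 0} (nuclear degeneracy 2)
  ev <- sort(eigen(Vp, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev, c(-1, -1, 0, 0, 0, 0, 1, 1), tolerance = 1e-13)
  # Hermitian for all kinds/modes
  for (nc in list(noise_config("magnetic", 1, "perpendicular"),
                  noise_config("magnetic", 1, "absolute", vartheta = 2.2),
                  noise_config("hyperfine", 1))) {
    V <- noise_operator(m, nc)
    expect_lt(max_abs(V - Conj(t(V))), 1e-13)
  }
  # perpendicular mode at theta = 0 gives the transverse Zeeman operator
  m0 <- reference_model(0)
  Vx <- noise_operator(m0, noise_config("magnetic", 1, "perpendicular"))
  s <- spin_operators(1 / 2)
  ref <- embed_operator(s$sx, 1L, m0$dims) + embed_operator(s$sx, 2L, m0$dims)
  expect_lt(max_abs(Vx - ref), 1e-13)
})

test_that("hyperfine noise requires the single-nucleus model", {
  m2 <- rp_model(theta = 0.3, A_Lambda = list(c(3, 3, 5), c(1, 1, 2)))
  expect_error(noise_operator(m2, noise_config("hyperfine", 1)),
               "single-nucleus")
})

test_that("the Liouvillian preserves the trace and reduces to unitary dynamics", {
  m <- reference_model(0.8)
  nc <- noise_config("magnetic", 0.3 * m$k, "perpendicular")
  lv <- build_liouvillian(m, nc)
  D <- lv$D
  # vec(identity) is a left null vector (trace preservation)
  vid <- as.vector(diag(1 + 0i, D))
  expect_lt(max(Mod(Conj(vid) %*% lv$matrix)), 1e-9 * m$omega0)
  set.seed(40)
  t <- 0.8 / m$k
  P <- expm_taylor(lv$matrix * t)
  for (i in 1:5) {
    rho0 <- random_density(4L) %x% (diag(1 + 0i, 2) / 2)
    rho_t <- matrix(P %*% as.vector(rho0), D, D)
    expect_equal(Re(sum(diag(rho_t))), 1, tolerance = 1e-9)
    expect_lt(max_abs(rho_t - Conj(t(rho_t))), 1e-9)
    ev <- eigen((rho_t + Conj(t(rho_t))) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-9)
  }
  # Gamma = 0: exp(L t) equals the unitary conjugation
  lv0 <- build_liouvillian(m, noise_config("magnetic", 0, "perpendicular"))
  H <- build_hamiltonian(m)
  U <- expm_taylor(-1i * H * t)
  rho0 <- random_density(4L) %x% (diag(1 + 0i, 2) / 2)
  rho_u <- U %*% rho0 %*% Conj(t(U))
  rho_l <- matrix(expm_taylor(lv0$matrix * t) %*% as.vector(rho0), D, D)
  expect_lt(max_abs(rho_l - rho_u), 1e-8)
})

test_that("the resolvent yield matches the spectral yield when noise is off", {
  m <- reference_model(pi / 4)
  for (nc in list(noise_config("magnetic", 0, "parallel"),
                  noise_config("hyperfine", 0))) {
    y <- noisy_yield(m, nc, singlet_projector())
    ref <- singlet_yield_spectral(m, singlet_projector())
    expect_equal(y$phi_s, ref$phi_s, tolerance = 1e-8)
    expect_equal(y$phi_p, ref$phi_p, tolerance = 1e-8)
    expect_equal(y$phi_c, ref$phi_c, tolerance = 1e-8)
  }
})

test_that("the resolvent yield matches time-domain integration under noise", {
  m <- reference_model(pi / 4)
  configs <- list(noise_config("magnetic", 0.5 * m$k, "perpendicular"),
                  noise_config("magnetic", 2 * m$k, "parallel"),
                  noise_config("hyperfine", m$k))
  for (nc in configs) {
    yr <- noisy_yield(m, nc, singlet_projector())
    yo <- noisy_yield_ode(m, nc, singlet_projector())
    expect_lt(abs(yr$phi_s - yo$phi_s), 1e-6)
    expect_lt(abs(yr$phi_p - yo$phi_p), 1e-6)
    expect_lt(abs(yr$phi_c - yo$phi_c), 1e-6)
  }
})

test_that("the dark subspace is immune to parallel noise without hyperfine coupling", {
  m <- rp_model(theta = 0.9, A_Lambda = c(0, 0, 0))
  for (rate_k in c(0.5, 5, 50)) {
    nc <- noise_config("magnetic", rate_k * m$k, "parallel")
    y <- noisy_yield(m, nc, singlet_projector())
    expect_equal(y$phi_s, 1, tolerance = 1e-8)
  }
})

test_that("vertical noise erodes the anisotropy monotonically; parallel noise can enhance it", {
  m <- reference_model()
  grid <- seq(0, pi / 2, length.out = 16L)
  vert <- noise_sweep(m, noise_config("magnetic", 0, "perpendicular"),
                      rates = c(0, 0.01, 0.1, 1) * m$k, theta_grid = grid)
  a <- vert$summary$anisotropy
  expect_equal(vert$summary$rate_in_k, c(0, 0.01, 0.1, 1))
  expect_true(all(diff(a) < 0))
  a0 <- a[1]
  parl <- noise_sweep(m, noise_config("magnetic", 0, "parallel"),
                      rates = c(0.1, 1, 10) * m$k, theta_grid = grid)
  expect_true(any(parl$summary$anisotropy >= a0))
  expect_true(all(parl$summary$anisotropy > 0.05 * a0))
})

test_that("the compass is robust to hyperfine-coupling noise at Gamma = k", {
  m <- reference_model()
  grid <- seq(0, pi / 2, length.out = 16L)
  sw <- noise_sweep(m, noise_config("hyperfine", 0),
                    rates = c(0, 1) * m$k, theta_grid = grid)
  a <- sw$summary$anisotropy
  expect_gte(a[2], 0.5 * a[1])
})

test_that("a noise sweep at rate zero reproduces the noiseless profile", {
  m <- reference_model()
  grid <- seq(0, pi / 2, length.out = 9L)
  sw <- noise_sweep(m, noise_config("magnetic", 0, "perpendicular"),
                    rates = 0, theta_grid = grid)
  ref <- yield_vs_theta(m, theta_grid = grid)
  expect_equal(sw$profiles$phi_s, ref$phi_s, tolerance = 1e-9)
})
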