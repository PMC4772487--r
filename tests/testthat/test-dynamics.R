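test_that("evolution at t = 0 is the identity and preserves state validity", {
  m <- reference_model(pi / 5)
  set.seed(10)
  rho0 <- random_density(4L)
  expect_lt(max_abs(evolve_reduced(m, rho0, 0) - rho0), 1e-12)
  prop <- rp_propagator(m)
  for (t in runif(4, 0, 5 / m$k)) {
    rho <- evolve_reduced(m, rho0, t, prop = prop)
    expect_lt(max_abs(rho - Conj(t(rho))), 1e-12)
    expect_equal(Re(sum(diag(rho))), 1, tolerance = 1e-12)
    ev <- eigen((rho + Conj(t(rho))) / 2, symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
  expect_error(evolve_reduced(m, rho0, -1), "non-negative")
})

test_that("spectral propagation agrees with a brute-force matrix exponential", {
  m <- reference_model(0.7)
  H <- build_hamiltonian(m)
  prop <- rp_propagator(m)
  set.seed(12)
  rho0 <- random_density(4L)
  rho_full <- rho0 %x% (diag(1 + 0i, 2) / 2)
  for (t in runif(10, 0, 3 / m$k)) {
    U_ref <- expm_taylor(-1i * H * t)
    ref <- rpcompass:::partial_trace_nuclear(
      U_ref %*% rho_full %*% Conj(t(U_ref)), 2L)
    expect_lt(max_abs(evolve_reduced(m, rho0, t, prop = prop) - ref), 1e-10)
  }
})

test_that("Kraus set is complete, has nd^2 members, and reproduces the channel", {
  m <- reference_model(1.0)
  prop <- rp_propagator(m)
  set.seed(13)
  for (t in c(0, 0.3 / m$k, 2 / m$k)) {
    ks <- kraus_operators(m, t, prop = prop)
    expect_length(ks$operators, 4L)
    csum <- Reduce(`+`, lapply(ks$operators, function(K) Conj(t(K)) %*% K))
    expect_lt(max_abs(csum - diag(1 + 0i, 4)), 1e-10)
  }
  ks <- kraus_operators(m, 1.7 / m$k, prop = prop)
  for (i in 1:20) {
    rho0 <- random_density(4L)
    expect_lt(max_abs(apply_kraus(ks, rho0) -
                        evolve_reduced(m, rho0, 1.7 / m$k, prop = prop)),
              1e-10)
  }
})

test_that("dark decomposition splits the singlet population exactly", {
  b <- dark_basis(0.9)
  d <- dark_decomposition(singlet_projector(), b)
  expect_equal(unname(d["f_p"]), 1 / 2, tolerance = 1e-13)
  expect_equal(unname(d["f_c"]), 1 / 2, tolerance = 1e-13)
  mix <- (b$D1 %*% Conj(t(b$D1)) + b$D2 %*% Conj(t(b$D2))) / 2
  d <- dark_decomposition(mix, b)
  expect_equal(unname(d["f_p"]), 1 / 2, tolerance = 1e-13)
  expect_equal(unname(d["f_c"]), 0, tolerance = 1e-13)
  set.seed(14)
  s <- singlet_state()
  for (i in 1:20) {
    rho <- random_density(4L)
    d <- dark_decomposition(rho, b)
    p_s <- Re(Conj(s) %*% rho %*% s)[1]
    expect_equal(unname(d["f_p"] + d["f_c"]), p_s, tolerance = 1e-12)
  }
})

test_that("removing the dark coherence is idempotent and preserves f_p", {
  b <- dark_basis(1.2)
  inc <- remove_dark_coherence(singlet_projector(), b)
  target <- (b$D1 %*% Conj(t(b$D1)) + b$D2 %*% Conj(t(b$D2))) / 2
  expect_lt(max_abs(inc - target), 1e-13)
  set.seed(15)
  for (i in 1:10) {
    rho <- random_density(4L)
    once <- remove_dark_coherence(rho, b)
    expect_lt(max_abs(remove_dark_coherence(once, b) - once), 1e-13)
    expect_equal(dark_decomposition(once, b)[["f_p"]],
                 dark_decomposition(rho, b)[["f_p"]], tolerance = 1e-12)
    expect_equal(abs(dark_decomposition(once, b)[["f_c"]]), 0,
                 tolerance = 1e-13)
  }
})

test_that("trace series satisfies its pointwise identities", {
  m <- reference_model(0.6)
  tr <- trace_series(m, singlet_projector(), t_max = 3 / m$k,
                     n_steps = 512L)
  expect_equal(nrow(tr), 512L)
  expect_lt(max(abs(tr$f_p + tr$f_c - tr$p_singlet)), 1e-10)
  expect_true(all(tr$f_p >= -1e-10 & tr$f_p <= 1 + 1e-10))
  d0 <- dark_decomposition(singlet_projector(), dark_basis(0.6))
  expect_equal(tr$f_p[1], d0[["f_p"]], tolerance = 1e-10)
  expect_equal(tr$f_c[1], d0[["f_c"]], tolerance = 1e-10)
})

test_that("the singlet is stationary under a pure Zeeman Hamiltonian", {
  m <- rp_model(theta = 0.8, A_Lambda = c(0, 0, 0))
  tr <- trace_series(m, singlet_projector(), t_max = 5 / m$k,
                     n_steps = 256L)
  expect_lt(max(abs(tr$p_singlet - 1)), 1e-10)
})

test_that("the incoherent state develops no dark coherence, and f_p matches the singlet's", {
  m <- reference_model(0.95)
  b <- dark_basis(0.95)
  inc <- incoherent_dark_state(0.95)
  tr_i <- trace_series(m, inc, t_max = 6 / m$k, n_steps = 1024L)
  expect_lt(max(abs(tr_i$f_c)), 1e-10)
  tr_s <- trace_series(m, singlet_projector(), t_max = 6 / m$k,
                       n_steps = 1024L)
  expect_lt(max(abs(tr_i$f_p - tr_s$f_p)), 1e-10)
})
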