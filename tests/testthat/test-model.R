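test_that("field vector has the stated geometry and norm", {
  m <- rp_model(theta = 0, B0_uT = 46)
  expect_equal(field_vector(m), c(0, 0, 46e-6))
  m <- rp_model(theta = pi / 2, B0_uT = 46)
  expect_equal(field_vector(m), c(46e-6, 0, 0))
  set.seed(1)
  for (th in runif(5, 0, pi)) {
    m <- rp_model(theta = th, B0_uT = 33)
    expect_equal(sqrt(sum(field_vector(m)^2)), 33e-6)
  }
})

test_that("Zeeman-only Hamiltonian has eigenvalues {0, +/- omega0} with nuclear degeneracy", {
  m <- rp_model(theta = 0.9, A_Lambda = c(0, 0, 0))
  H <- build_hamiltonian(m)
  expect_lt(max_abs(H - Conj(t(H))), 1e-8)
  ev <- sort(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  w0 <- m$omega0
  expect_equal(ev, c(-w0, -w0, 0, 0, 0, 0, w0, w0), tolerance = 1e-12)
})

test_that("Hamiltonian is Hermitian for random parameters", {
  set.seed(2)
  for (i in 1:5) {
    m <- rp_model(theta = runif(1, 0, pi), B0_uT = runif(1, 10, 80),
                  A_Lambda = rnorm(3, 0, 4))
    expect_lt(max_abs(build_hamiltonian(m) - Conj(t(build_hamiltonian(m)))),
              1e-6)
  }
})

test_that("axial hyperfine coupling conserves the nuclear z projection", {
  m <- rp_model(theta = 0.6, A_Lambda = c(0, 0, 5))
  H <- build_hamiltonian(m)
  Iz <- embed_operator(spin_operators(1 / 2)$sz, 3L, m$dims)
  expect_lt(max_abs(H %*% Iz - Iz %*% H), 1e-6)
})

test_that("hyperfine list and nuclear spin list must agree in length", {
  expect_error(rp_model(A_Lambda = list(c(1, 1, 2), c(0, 0, 1)),
                        nuclear_spins = 1 / 2),
               "one entry per")
})

test_that("two-nucleus model has dimension 16 and a Hermitian Hamiltonian", {
  m <- rp_model(theta = 0.3, A_Lambda = list(c(3, 3, 5), c(1, 1, 2)))
  H <- build_hamiltonian(m)
  expect_equal(dim(H), c(16L, 16L))
  expect_lt(max_abs(H - Conj(t(H))), 1e-6)
})

test_that("M(theta) has spectrum {2, -2, 0, 0} at every angle", {
  for (th in c(0, pi / 3, pi / 2, 2.6)) {
    M <- zeeman_matrix(th)
    expect_equal(max_abs(M - t(M)), 0)
    expect_equal(sum(diag(M)), 0, tolerance = 1e-14)
    ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(ev, c(-2, 0, 0, 2), tolerance = 1e-13)
  }
  expect_equal(zeeman_matrix(0), diag(c(2, 0, 0, -2)))
})

test_that("Zeeman Hamiltonian equals (gamma B0 / 2) M(theta)", {
  m1 <- rp_model(theta = 1.1, A_Lambda = c(0, 0, 0))
  H <- build_hamiltonian(m1)
  HB <- (m1$gamma * m1$B0 / 2) * (zeeman_matrix(1.1) %x% diag(1 + 0i, 2))
  expect_lt(max_abs(H - HB), 1e-8)
})

test_that("dark basis diagonalizes M(theta) with the right eigenvalues", {
  set.seed(3)
  for (th in c(0, pi / 2, runif(4, 0, pi))) {
    b <- dark_basis(th)
    M <- zeeman_matrix(th)
    expect_lt(max_abs(M %*% b$D1), 1e-12)
    expect_lt(max_abs(M %*% b$D2), 1e-12)
    expect_lt(max_abs(M %*% b$Bplus - 2 * b$Bplus), 1e-12)
    expect_lt(max_abs(M %*% b$Bminus + 2 * b$Bminus), 1e-12)
    # orthonormal
    Tm <- cbind(b$D1, b$D2, b$Bplus, b$Bminus)
    expect_lt(max_abs(Conj(t(Tm)) %*% Tm - diag(1 + 0i, 4)), 1e-13)
  }
})

test_that("the singlet is (D1 - D2)/sqrt(2) at every angle", {
  set.seed(4)
  for (th in runif(6, 0, pi)) {
    b <- dark_basis(th)
    overlap <- abs(sum(Conj(singlet_state()) * (b$D1 - b$D2) / sqrt(2)))
    expect_equal(overlap, 1, tolerance = 1e-13)
  }
})

test_that("dark and bright states are products of the two electrons", {
  b <- dark_basis(0.8)
  for (v in list(b$D1, b$D2, b$Bplus, b$Bminus)) {
    # Schmidt rank 1 <=> the 2x2 reshaping has one nonzero singular value
    sv <- svd(matrix(v, 2, 2, byrow = TRUE))$d
    expect_lt(sv[2], 1e-13)
    expect_equal(sv[1], 1, tolerance = 1e-13)
  }
})

test_that("dark basis is continuous in theta", {
  grid <- seq(0, pi, length.out = 200L)
  prev <- dark_basis(grid[1])
  for (th in grid[-1]) {
    cur <- dark_basis(th)
    expect_gt(abs(sum(Conj(prev$D1) * cur$D1)), 0.99)
    expect_gt(abs(sum(Conj(prev$D2) * cur$D2)), 0.99)
    prev <- cur
  }
})

test_that("model constructor validates its inputs", {
  expect_error(rp_model(theta = -0.1), "theta")
  expect_error(rp_model(theta = 4), "theta")
  expect_error(rp_model(k = 0), "k")
  expect_error(rp_model(A_Lambda = c(1, 2)), "length-3")
  expect_error(rp_model(nuclear_spins = 0.3), "half-integer")
})
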