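# Constitutive model: closed-form energies, stress and tangent against
# numerical differentiation, frame indifference.

test_that("energy vanishes in the reference state and under rotation", {
  expect_equal(ogden_energy(diag(3), 0.68, 6.6), 0)
  expect_equal(ogden_energy(diag(2), 0.34, 3.3), 0)
  th <- 0.62
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(ogden_energy(R, 0.68, 6.6), 0, tolerance = 1e-12)
  expect_equal(max(abs(ogden_stress(R, 0.68, 6.6))), 0, tolerance = 1e-10)
})

test_that("pure dilatation and simple shear match the closed forms", {
  # volumetric term only: kappa/4 (J^2 - 1 - 2 log J) at J = 1.1
  J <- 1.1
  expected <- 3.3 / 4 * (J^2 - 1 - 2 * log(J))
  expect_equal(ogden_energy(J^(1 / 3) * diag(3), mu = 1, kappa = 3.3),
               expected, tolerance = 1e-12)
  expect_equal(expected, 0.01599, tolerance = 1e-3)
  # simple shear gamma: isochoric, I1 = 3 + gamma^2, Psi = mu gamma^2 / 2
  gam <- 0.1
  F <- diag(3); F[1, 2] <- gam
  expect_equal(ogden_energy(F, 0.34, 6.6), 0.34 * gam^2 / 2,
               tolerance = 1e-12)
  expect_equal(ogden_energy(F, 0.34, 6.6), 0.0017, tolerance = 1e-12)
})

test_that("element inversion is signalled", {
  F <- diag(3); F[1, 1] <- -0.5
  expect_error(ogden_energy(F, 1, 1), "inversion")
  expect_error(ogden_stress(F, 1, 1), "inversion")
})

test_that("stress matches the finite-difference energy gradient", {
  set.seed(11)
  h <- 1e-6
  for (rep in 1:5) {
    F <- diag(3) + matrix(rnorm(9, sd = 0.15), 3, 3)
    if (det(F) < 0.3) next
    P <- ogden_stress(F, 0.68, 6.6)
    Pfd <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      Pfd[i, j] <- (ogden_energy(Fp, 0.68, 6.6) -
                      ogden_energy(Fm, 0.68, 6.6)) / (2 * h)
    }
    expect_lt(max(abs(P - Pfd)) / max(abs(P)), 1e-6)
  }
})

test_that("tangent matches the finite-difference stress derivative and is
           major-symmetric", {
  set.seed(12)
  h <- 1e-6
  F <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3)
  A <- ogden_tangent(F, 0.68, 6.6)
  Afd <- array(0, c(3, 3, 3, 3))
  for (k in 1:3) for (l in 1:3) {
    Fp <- F; Fp[k, l] <- Fp[k, l] + h
    Fm <- F; Fm[k, l] <- Fm[k, l] - h
    Afd[, , k, l] <- (ogden_stress(Fp, 0.68, 6.6) -
                        ogden_stress(Fm, 0.68, 6.6)) / (2 * h)
  }
  expect_lt(max(abs(A - Afd)) / max(abs(A)), 1e-5)
  expect_equal(A, aperm(A, c(3, 4, 1, 2)), tolerance = 1e-12)
})

test_that("vectorized plane-strain kernel agrees with the dense routines", {
  set.seed(13)
  n <- 20
  Fv <- list(F11 = 1 + rnorm(n, sd = 0.08), F12 = rnorm(n, sd = 0.08),
             F21 = rnorm(n, sd = 0.08), F22 = 1 + rnorm(n, sd = 0.08))
  ps <- ventmech:::planestrain_pk1(Fv, 0.68, 6.6)
  for (e in sample(n, 5)) {
    F2 <- matrix(c(Fv$F11[e], Fv$F21[e], Fv$F12[e], Fv$F22[e]), 2, 2)
    Pd <- ogden_stress(F2, 0.68, 6.6)
    expect_equal(c(ps$P$P11[e], ps$P$P12[e], ps$P$P21[e], ps$P$P22[e]),
                 c(Pd[1, 1], Pd[1, 2], Pd[2, 1], Pd[2, 2]),
                 tolerance = 1e-12)
    Ad <- ogden_tangent(F2, 0.68, 6.6)
    for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
      v <- ps$A[[(((i - 1) * 2 + j) - 1) * 4 + ((k - 1) * 2 + l)]][e]
      expect_equal(v, Ad[i, j, k, l], tolerance = 1e-12)
    }
  }
})

test_that("unit conversions follow the pressure contract", {
  expect_equal(round(pa_to_mmhg(20), 2), 0.15)
  expect_equal(pa_to_mmhg(1), 0.0075, tolerance = 1e-4)
  expect_equal(pa_to_mmhg(0), 0)
})

test_that("material defaults encode the tissue constants", {
  mat <- material_params()
  expect_equal(unname(mat$mu[c("white_matter", "gray_matter")]),
               c(0.68, 0.34))
  expect_equal(unname(mat$kappa[c("white_matter", "gray_matter")]),
               c(6.6, 3.3))
  expect_equal(unname(mat$mu["white_matter"] / mat$mu["gray_matter"]), 2)
  # CSF surrogate: E = 0.1 kPa, nu = 0.3
  expect_equal(unname(mat$mu["csf"]), 0.1 / (2 * 1.3))
  expect_equal(unname(mat$kappa["csf"]), 0.1 / (3 * 0.4))
  ld <- load_case()
  expect_true(ld$p_sas <= ld$p_lv)
})
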