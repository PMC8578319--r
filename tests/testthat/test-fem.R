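# Finite-element solver: unloaded body, affine reproduction, energy
# consistency, patch test, load linearity, symmetry, kinematic identities.

test_that("zero pressure gives exactly zero displacement", {
  ac <- annulus_case()
  sol <- solve_quasistatic(ac$mesh, material_params(),
                           load_case(p_lv = 0, p_sas = 0))
  expect_equal(max(abs(sol$u)), 0)
})

test_that("linear elements reproduce an affine displacement exactly", {
  mr <- mesh_rectangle(10, 6, 6, 4)
  pre <- ventmech:::fem_precompute(mr, material_params(
    mu_gm = 0.68, kappa_gm = 6.6))
  u <- cbind(0.01 * mr$nodes[, 1], 0 * mr$nodes[, 2])
  Fv <- ventmech:::element_F(pre, u)
  expect_equal(Fv$F11, rep(1.01, nrow(mr$tri)), tolerance = 1e-14)
  expect_equal(max(abs(Fv$F12)), 0, tolerance = 1e-14)
  expect_equal(max(abs(Fv$F21)), 0, tolerance = 1e-14)
  expect_equal(Fv$F22, rep(1, nrow(mr$tri)), tolerance = 1e-14)
})

test_that("assembled internal force equals the finite-difference gradient
           of the total strain energy on a coarse mesh", {
  mesh <- mesh_geometry(annulus_geometry(6, 12, n = 24), 3,
                        refine_factor = 1)
  mat <- material_params()
  pre <- ventmech:::fem_precompute(mesh, mat)
  set.seed(21)
  n <- nrow(mesh$nodes)
  u <- matrix(rnorm(2 * n, sd = 0.05), n, 2)
  total_energy <- function(u) {
    Fv <- ventmech:::element_F(pre, u)
    J <- Fv$F11 * Fv$F22 - Fv$F12 * Fv$F21
    I1 <- Fv$F11^2 + Fv$F12^2 + Fv$F21^2 + Fv$F22^2 + 1
    psi <- pre$mu / 2 * (J^(-2 / 3) * I1 - 3) +
      pre$kappa / 4 * (J^2 - 1 - 2 * log(J))
    sum(pre$area * psi)
  }
  f <- ventmech:::assemble_internal(pre, u, tangent = FALSE)$f
  h <- 1e-6
  idx <- sample(2 * n, 25)
  for (d in idx) {
    up <- u; up[ceiling(d / 2), 2 - d %% 2] <- up[ceiling(d / 2),
                                                  2 - d %% 2] + h
    um <- u; um[ceiling(d / 2), 2 - d %% 2] <- um[ceiling(d / 2),
                                                  2 - d %% 2] - h
    fd <- (total_energy(up) - total_energy(um)) / (2 * h)
    expect_equal(f[d], fd, tolerance = 1e-5)
  }
})

test_that("two-region patch test produces a spatially constant state", {
  mr <- mesh_rectangle(10, 6, 8, 5)
  mat <- material_params(mu_wm = 0.5, kappa_wm = 5,
                         mu_gm = 0.5, kappa_gm = 5)
  fixed <- c(2 * (mr$left_nodes - 1) + 1, 2 * (mr$bottom_nodes - 1) + 2)
  sol <- solve_quasistatic(
    mr, mat,
    pressure_loads = list(list(edges = mr$edge_sets$right, p = 0.05)),
    fixed_dofs = fixed)
  kin <- kinematics(sol, mr)
  expect_lt(diff(range(kin$F11)), 1e-10)
  expect_lt(diff(range(kin$F22)), 1e-10)
  expect_lt(max(abs(kin$F12)), 1e-10)
  expect_lt(max(abs(kin$F21)), 1e-10)
})

test_that("displacements are linear in pressure in the small-load limit", {
  ac <- annulus_case()
  s1 <- solve_quasistatic(ac$mesh, material_params(),
                          load_case(p_lv = 2, p_sas = 0))
  s2 <- solve_quasistatic(ac$mesh, material_params(),
                          load_case(p_lv = 4, p_sas = 0))
  expect_equal(max(sqrt(rowSums(s2$u^2))) / max(sqrt(rowSums(s1$u^2))),
               2, tolerance = 0.01)
})

test_that("kinematic identities hold on a converged subject solve", {
  run <- default_subject_run()
  kin <- run$state
  expect_lt(max(abs(kin$det_Cbar - 1)), 1e-10)
  expect_true(all(kin$J > 0))
  expect_true(all(kin$I1bar >= 3 - 1e-12))
  # zero-displacement kinematics: C = I, E = 0, I1bar = 3
  mesh <- run$mesh
  sol0 <- list(u = matrix(0, nrow(mesh$nodes), 2))
  kin0 <- kinematics(sol0, mesh)
  expect_equal(max(abs(kin0$C11 - 1)), 0)
  expect_equal(max(abs(kin0$C12)), 0)
  expect_equal(max(abs(kin0$mps)), 0)
  expect_equal(max(abs(kin0$I1bar - 3)), 0)
})

test_that("a mirror-symmetric subject solves to a mirror-symmetric field
           at discretization accuracy", {
  run <- default_subject_run()
  # the mesh itself is not mirror symmetric, so compare physical outputs:
  # left/right horn peak tensions agree to a fraction of the peak excess
  peaks <- detect_horn_peaks(run$profile)
  post <- sort(peaks$lambda_t[sign(peaks$y) < 0])
  ant <- sort(peaks$lambda_t[sign(peaks$y) > 0])
  expect_equal(post[1], post[2],
               tolerance = 0.1 * (max(peaks$lambda_t) - 1))
  expect_equal(ant[1], ant[2],
               tolerance = 0.1 * (max(peaks$lambda_t) - 1))
  # and the x-displacement on the midline is a small fraction of max |u|
  mid <- which(abs(run$mesh$nodes[, 1]) < 1e-8)
  if (length(mid) > 0) {
    expect_lt(max(abs(run$solution$u[mid, 1])),
              0.02 * max(abs(run$solution$u)))
  }
})

test_that("the skull constraint pins the outer boundary", {
  run <- default_subject_run()
  sk <- run$mesh$bsets$skull_nodes
  expect_equal(max(abs(run$solution$u[sk, ])), 0)
  expect_lt(utils::tail(run$solution$residuals, 1), 1e-9)
})

test_that("missing skull constraint is rejected", {
  ac <- annulus_case()
  mesh <- ac$mesh
  mesh$bsets$skull_nodes <- integer(0)
  expect_error(solve_quasistatic(mesh), "skull")
})
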