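# Mechanomarkers: stretch projection identities, peak detection on
# constructed profiles, the circumcircle, and the elevated-wall fraction.

make_profile <- function(arclength, lambda_t, x = NULL, y = NULL) {
  k <- length(arclength)
  if (is.null(x)) {
    # place the nodes on a closed circle so segment lengths match the
    # arclength spacing (including the closing segment)
    L <- max(arclength) + (arclength[2] - arclength[1])
    R <- L / (2 * pi)
    th <- 2 * pi * arclength / L
    x <- R * cos(th); y <- R * sin(th)
  }
  prof <- data.frame(arclength = arclength, lambda_t = lambda_t,
                     lambda_c = rep(1, k), x = x, y = y,
                     n0x = 0, n0y = 1, t0x = 1, t0y = 0,
                     C11 = lambda_t^2, C12 = 0, C22 = 1)
  attr(prof, "total_length") <- max(arclength) +
    (arclength[2] - arclength[1])
  class(prof) <- c("wall_profile", "data.frame")
  prof
}

test_that("projection returns unit stretches for C = I and picks out an
           aligned eigenbasis", {
  # direct check of the projection formula on synthetic frames
  C <- diag(2)
  t0 <- c(1, 0); n0 <- c(0, 1)
  expect_equal(sqrt(drop(t0 %*% C %*% t0)), 1)
  lam <- 1.07
  R <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  for (a in c(0, 0.4, 1.1)) {
    t0 <- R(a) %*% c(1, 0); n0 <- R(a) %*% c(0, 1)
    C <- lam^2 * (t0 %*% t(t0)) + 1 * (n0 %*% t(n0))
    expect_equal(sqrt(drop(t(t0) %*% C %*% t0)), lam, tolerance = 1e-12)
    expect_equal(sqrt(drop(t(n0) %*% C %*% n0)), 1, tolerance = 1e-12)
  }
})

test_that("wall stretches satisfy the Rayleigh eigenvalue bounds on a
           full subject", {
  run <- default_subject_run()
  prof <- run$profile
  lo <- (prof$C11 + prof$C22) / 2 -
    sqrt((prof$C11 - prof$C22)^2 / 4 + prof$C12^2)
  hi <- (prof$C11 + prof$C22) / 2 +
    sqrt((prof$C11 - prof$C22)^2 / 4 + prof$C12^2)
  expect_true(all(prof$lambda_t^2 >= lo - 1e-12))
  expect_true(all(prof$lambda_t^2 <= hi + 1e-12))
  expect_true(all(prof$lambda_c^2 >= lo - 1e-12))
  expect_true(all(prof$lambda_c^2 <= hi + 1e-12))
  expect_true(all(prof$lambda_t > 0) && all(prof$lambda_c > 0))
})

test_that("zero load gives unit stretches along the whole wall", {
  ac <- annulus_case()
  sol <- solve_quasistatic(ac$mesh, material_params(),
                           load_case(p_lv = 0, p_sas = 0))
  kin <- kinematics(sol, ac$mesh)
  T <- solve_laplace(ac$mesh)
  fr <- wall_frames(T, ac$mesh, ac$wall)
  prof <- project_wall_stretches(kin, fr, ac$wall, ac$mesh)
  expect_equal(prof$lambda_t, rep(1, nrow(prof)))
  expect_equal(prof$lambda_c, rep(1, nrow(prof)))
  expect_error(detect_horn_peaks(prof), "unloaded|maxima")
})

test_that("four planted Gaussian bumps are recovered at their centers", {
  s <- seq(0, 199, by = 1)
  centers <- c(30, 80, 120, 170)
  lt <- 1 + 0.002 +
    rowSums(vapply(centers, function(c0) {
      0.06 * exp(-(s - c0)^2 / (2 * 4^2))
    }, numeric(length(s))))
  prof <- make_profile(s, lt)
  pk <- detect_horn_peaks(prof)
  expect_equal(pk$arclength, centers, tolerance = 1e-9)
  # fewer than four separated maxima -> error with the count
  lt2 <- 1 + 0.06 * exp(-(s - 100)^2 / (2 * 4^2))
  expect_error(detect_horn_peaks(make_profile(s, lt2)), "1")
})

test_that("circumcircle is exact on constructed triples", {
  cc <- circumcircle(c(0, 1), c(1, 0), c(-1, 0))
  expect_equal(cc$radius, 1, tolerance = 1e-12)
  expect_equal(cc$center, c(0, 0), tolerance = 1e-12)
  cc2 <- circumcircle(c(0, 2), c(2, 0), c(0, -2))
  expect_equal(cc2$radius, 2, tolerance = 1e-12)
  expect_error(circumcircle(c(0, 0), c(1, 1), c(2, 2)), "collinear")
})

test_that("horn circle fit recovers the generating circle when the
           profile flanks lie on it", {
  # construct a wall that IS a circle of radius 3 near the peak, with a
  # stretch bump whose 10 percent drop points stay on the circular part
  r <- 3
  th <- seq(-pi / 2, pi / 2, length.out = 201)
  s <- r * (th - th[1])
  x <- r * cos(th); y <- r * sin(th)
  lt <- 1 + 0.05 * exp(-(s - max(s) / 2)^2 / (2 * 1.5^2))
  prof <- make_profile(s, lt, x = x, y = y)
  attr(prof, "total_length") <- max(s) + diff(s)[1]
  fit <- horn_circle_fit(prof, which.max(lt))
  expect_equal(fit$radius, r, tolerance = 1e-3)
})

test_that("elevated wall fraction follows the excess-stretch convention", {
  s <- seq(0, 99, by = 1)
  # excess above threshold on exactly half the loop
  lt <- ifelse(s < 50, 1.05, 1.0)
  prof <- make_profile(s, lt)
  expect_equal(wall_fraction_elevated(prof), 0.5, tolerance = 0.02)
  # a single hot node contributes (almost) nothing
  lt2 <- rep(1, 100); lt2[10] <- 1.08
  expect_lt(wall_fraction_elevated(make_profile(s, lt2)), 0.03)
  # unloaded wall: zero fraction
  expect_equal(wall_fraction_elevated(make_profile(s, rep(1, 100))), 0)
})

test_that("subject horn metrics are complete and physically sane", {
  run <- default_subject_run()
  hm <- run$horns
  expect_equal(nrow(hm$horns), 4)
  expect_identical(hm$horns$label, c("A", "B", "C", "D"))
  expect_true(all(hm$horns$radius > 0))
  expect_gte(hm$wall_fraction_elevated, 0)
  expect_lte(hm$wall_fraction_elevated, 1)
  # peak lambda_t in the physiologic band at reference load
  expect_gt(max(hm$horns$lambda_t), 1.03)
  expect_lt(max(hm$horns$lambda_t), 1.10)
  # tension peak co-localizes with the wall-adjacent MPS maximum
  wall_nodes <- run$wall$nodes
  tri <- run$mesh$tri
  is_wm <- run$mesh$region == "white_matter"
  touches <- is_wm & (tri[, 1] %in% wall_nodes | tri[, 2] %in% wall_nodes |
                        tri[, 3] %in% wall_nodes)
  el <- which(touches)[which.max(run$state$mps[touches])]
  cen <- colMeans(run$mesh$nodes[tri[el, ], ])
  d2 <- (run$profile$x - cen[1])^2 + (run$profile$y - cen[2])^2
  s_mps <- run$profile$arclength[which.min(d2)]
  L <- run$wall$total_length
  gap <- min(abs(s_mps - hm$horns$arclength),
             L - abs(s_mps - hm$horns$arclength))
  expect_lt(gap, 0.05 * L)
})
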