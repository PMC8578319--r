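# Synthetic subject generator: geometry construction, determinism, image
# synthesis, and the embedded subject table.

test_that("spec invariants are enforced", {
  expect_error(subject_spec(horn_radius_anterior = -1), "positive")
  expect_error(subject_spec(horn_radius_anterior = 25,
                            ventricle_halfwidth = 22), "halfwidth")
  expect_error(subject_spec(csf_thickness = 0), "positive")
})

test_that("mirror-symmetric spec yields a mirror-symmetric cavity", {
  g <- make_geometry(subject_spec(horn_radius_anterior = 2.5,
                                  horn_radius_posterior = 2.5))
  P <- g$region_polygons$cavity
  Pm <- cbind(-P[, 1], P[, 2])
  # every mirrored vertex must coincide with some original vertex
  d <- vapply(seq_len(nrow(P)), function(i) {
    min(sqrt((Pm[, 1] - P[i, 1])^2 + (Pm[, 2] - P[i, 2])^2))
  }, numeric(1))
  expect_lt(max(d), 1e-9)
})

test_that("tip arcs are exact circles with the prescribed radii", {
  g <- make_geometry(subject_spec(horn_radius_anterior = 2,
                                  horn_radius_posterior = 4))
  fit_circle <- function(pts) {
    A <- cbind(2 * pts[, 1], 2 * pts[, 2], 1)
    b <- pts[, 1]^2 + pts[, 2]^2
    s <- qr.solve(A, b)
    sqrt(s[3] + s[1]^2 + s[2]^2)
  }
  for (arc in c("ant_L", "ant_R")) {
    idx <- g$arcs[[arc]]
    expect_gte(diff(idx), 32)  # discretization floor per arc
    expect_equal(fit_circle(g$region_polygons$cavity[idx[1]:idx[2], ]),
                 2, tolerance = 1e-9, ignore_attr = TRUE)
  }
  for (arc in c("post_L", "post_R")) {
    idx <- g$arcs[[arc]]
    expect_equal(fit_circle(g$region_polygons$cavity[idx[1]:idx[2], ]),
                 4, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("geometry is deterministic and independent of the seed", {
  g1 <- make_geometry(subject_spec(seed = 1))
  g2 <- make_geometry(subject_spec(seed = 99))
  expect_identical(g1$region_polygons, g2$region_polygons)
})

test_that("cavity curvature maxima sit on the four tip arcs", {
  g <- make_geometry(subject_spec())
  P <- g$region_polygons$cavity
  turn <- ventmech:::polygon_turn_angles(P)
  on_arc <- rep(FALSE, nrow(P))
  for (a in g$arcs) on_arc[a[1]:a[2]] <- TRUE
  # strongest positive (convex) turning must happen on the arcs, and each
  # arc must carry a local curvature plateau well above the straight parts
  off_arc_max <- max(turn[!on_arc & turn > -0.1])  # exclude notch corners
  for (a in g$arcs) {
    expect_gt(max(turn[a[1]:a[2]]), off_arc_max)
  }
})

test_that("infeasible geometries are rejected with a diagnosis", {
  expect_error(
    make_geometry(subject_spec(horn_radius_anterior = 15,
                               horn_radius_posterior = 15,
                               ventricle_halfheight = 18,
                               ventricle_halfwidth = 20)),
    "overlap")
  expect_error(
    make_geometry(subject_spec(cortex_semiaxes = c(26, 34))),
    "annulus")
})

test_that("flair synthesis is reproducible and respects its contracts", {
  cf <- clean_flair_case()
  g <- cf$geometry
  f1 <- make_flair(g, contrast = 0.8, noise_sd = 0.03)
  expect_identical(f1$intensity, cf$flair$intensity)   # fixed seed, bitwise
  f2 <- make_flair(g, contrast = 0.8, noise_sd = 0.03, seed = 7L)
  expect_false(identical(f1$intensity, f2$intensity))
  expect_identical(dim(f1$intensity), dim(f1$labels))
  expect_identical(dim(f1$intensity), dim(f1$truth))
  # truth lesions lie in white matter
  expect_true(all(f1$labels[f1$truth] == 2L))
  expect_error(make_flair(g, contrast = 0), "contrast")
  expect_error(make_flair(g, lesion_centers = rbind(c(0, 0))),
               "white matter")
})

test_that("noiseless high-contrast image segments to the exact truth", {
  g <- clean_flair_case()$geometry
  f <- make_flair(g, contrast = 0.8, noise_sd = 0)
  seg <- segment_wmh(f$intensity, f$labels)
  expect_identical(seg$mask, f$truth)
  # the septum surrogate was present in the raw mask and pruned
  expect_gt(sum(seg$raw_mask), sum(seg$mask))
  expect_true(any(seg$components$removed))
})

test_that("zero-contrast-like noise floor recovers essentially nothing", {
  g <- clean_flair_case()$geometry
  # tiny contrast drowned in noise: segmentation keeps (almost) no truth
  f <- make_flair(g, contrast = 0.011, noise_sd = 0.2)
  seg <- segment_wmh(f$intensity, f$labels)
  expect_lt(sum(seg$mask & f$truth) / sum(f$truth), 0.1)
})

test_that("the subject table matches the printed reference values", {
  tab <- table1_fixture()
  expect_equal(nrow(tab), 8)
  f80 <- tab[tab$id == "F80", ]
  expect_equal(unlist(f80[c("age", "vCSF", "vLV", "vWMH", "FS")]),
               c(age = 77.6, vCSF = 579.0, vLV = 74.1, vWMH = 20.7,
                 FS = 3))
  expect_equal(tab$vWMH[tab$id == "F20"], 1.1)
  expect_equal(tab$FS[tab$id == "F20"], 0L)
  expect_equal(tab$vLV[tab$id == "M80"], 61.4)
  expect_equal(tab$FS[tab$id == "M80"], 3L)
})
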