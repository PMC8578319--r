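# Laplacian direction fields on the ventricular wall.
#
# The reference wall normal n0 and tangent t0 are defined through a
# diffusion ("temperature") problem: Dirichlet values 1.0 on the
# ventricular wall, 0.2 on the gray/white interface, 0.0 on the gray/CSF
# interface, Laplace's equation in between (white and gray matter only;
# the CSF ring carries no equation). The steepest-gradient direction at
# the wall gives n0, the isotherm direction gives t0.

#' Solve the wall-direction Laplace problem
#'
#' P1 finite-element solution of \eqn{\nabla^2 T = 0} on the white and
#' gray matter triangles with Dirichlet boundary conditions: `T = 1` on
#' ventricular wall nodes, `T = 0.2` on the gray/white interface, and
#' `T = 0` on the gray/CSF interface. Values are reported in the same
#' dimensionless "degrees" used for the boundary data. The discrete
#' solution respects the maximum principle, so `0 <= T <= 1`.
#'
#' @param mesh a [mesh_geometry()] mesh. For generic single-region meshes
#'   (e.g. an annulus) the wall takes `T = 1` and the outermost ring
#'   `T = 0`, and the equation is solved on all triangles.
#' @param bc optional named Dirichlet values, default
#'   `c(wall = 1, gm_wm = 0.2, gm_csf = 0)`.
#' @return numeric vector of nodal temperatures (NA on nodes that carry no
#'   equation, i.e. CSF interior).
#' @export
solve_laplace <- function(mesh, bc = c(wall = 1, gm_wm = 0.2, gm_csf = 0)) {
  full <- !is.null(mesh$bsets$gm_wm_edges)
  keep_regions <- if (full) c("white_matter", "gray_matter") else
    unique(mesh$region)
  el <- mesh$region %in% keep_regions
  tri <- mesh$tri[el, , drop = FALSE]
  n <- nrow(mesh$nodes)
  wall_nodes <- sort(unique(as.vector(mesh$bsets$wall_edges)))
  if (length(wall_nodes) == 0) stop("solve_laplace: empty wall set")
  if (full) {
    gmwm_nodes <- sort(unique(as.vector(mesh$bsets$gm_wm_edges)))
    gmcsf_nodes <- sort(unique(as.vector(mesh$bsets$gm_csf_edges)))
    if (length(gmwm_nodes) == 0) stop("solve_laplace: empty gm_wm set")
    if (length(gmcsf_nodes) == 0) stop("solve_laplace: empty gm_csf set")
    dir_nodes <- c(wall_nodes, gmwm_nodes, gmcsf_nodes)
    dir_vals <- c(rep(bc[["wall"]], length(wall_nodes)),
                  rep(bc[["gm_wm"]], length(gmwm_nodes)),
                  rep(bc[["gm_csf"]], length(gmcsf_nodes)))
  } else {
    outer_nodes <- mesh$bsets$skull_nodes
    dir_nodes <- c(wall_nodes, outer_nodes)
    dir_vals <- c(rep(bc[["wall"]], length(wall_nodes)),
                  rep(bc[["gm_csf"]], length(outer_nodes)))
  }
  if (anyDuplicated(dir_nodes)) {
    stop("solve_laplace: Dirichlet sets are not disjoint")
  }
  # P1 stiffness on the kept triangles
  X1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  X2 <- mesh$nodes[tri[, 2], , drop = FALSE]
  X3 <- mesh$nodes[tri[, 3], , drop = FALSE]
  d1x <- X2[, 1] - X1[, 1]; d1y <- X2[, 2] - X1[, 2]
  d2x <- X3[, 1] - X1[, 1]; d2y <- X3[, 2] - X1[, 2]
  detD <- d1x * d2y - d2x * d1y
  area <- detD / 2
  g2x <- d2y / detD; g2y <- -d2x / detD
  g3x <- -d1y / detD; g3y <- d1x / detD
  g1x <- -(g2x + g3x); g1y <- -(g2y + g3y)
  gx <- cbind(g1x, g2x, g3x); gy <- cbind(g1y, g2y, g3y)
  Ki <- integer(0); Kj <- integer(0); Kx <- numeric(0)
  for (a in 1:3) for (b in 1:3) {
    Ki <- c(Ki, tri[, a]); Kj <- c(Kj, tri[, b])
    Kx <- c(Kx, area * (gx[, a] * gx[, b] + gy[, a] * gy[, b]))
  }
  K <- Matrix::sparseMatrix(i = Ki, j = Kj, x = Kx, dims = c(n, n))
  active <- sort(unique(as.vector(tri)))
  T <- rep(NA_real_, n)
  T[dir_nodes] <- dir_vals
  freen <- setdiff(active, dir_nodes)
  rhs <- -K[freen, dir_nodes, drop = FALSE] %*% dir_vals
  T[freen] <- as.numeric(
    Matrix::solve(K[freen, freen, drop = FALSE], rhs)
  )
  T
}

#' Reference wall frames from the temperature field
#'
#' Recovers the nodal gradient of `T` by averaging the constant element
#' gradients over the white-matter elements adjacent to each wall node,
#' weighted by the interior angle each element subtends at the node (the
#' standard angle-weighted normal recovery, which is noticeably more
#' accurate on boundary nodes than area weighting), then sets the
#' reference normal `n0` to the unit
#' steepest-descent direction (pointing from the wall into the tissue,
#' i.e. away from the cavity) and the tangent `t0` to `n0` rotated by
#' +90 degrees, which aligns with the counter-clockwise wall traversal.
#' Degenerate gradients fall back to the geometric wall-edge normal.
#'
#' @param T nodal temperatures from [solve_laplace()].
#' @param mesh the mesh.
#' @param wall a [order_wall()] path.
#' @return Object of class `wall_frames`: list with `n0`, `t0` (k x 2 unit
#'   vectors per ordered wall node) and `T` (the input field).
#' @export
wall_frames <- function(T, mesh, wall) {
  first_region <- if ("white_matter" %in% mesh$region) "white_matter" else
    unique(mesh$region)[1]
  el <- which(mesh$region == first_region)
  tri <- mesh$tri[el, , drop = FALSE]
  X1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  X2 <- mesh$nodes[tri[, 2], , drop = FALSE]
  X3 <- mesh$nodes[tri[, 3], , drop = FALSE]
  d1x <- X2[, 1] - X1[, 1]; d1y <- X2[, 2] - X1[, 2]
  d2x <- X3[, 1] - X1[, 1]; d2y <- X3[, 2] - X1[, 2]
  detD <- d1x * d2y - d2x * d1y
  area <- detD / 2
  g2x <- d2y / detD; g2y <- -d2x / detD
  g3x <- -d1y / detD; g3y <- d1x / detD
  g1x <- -(g2x + g3x); g1y <- -(g2y + g3y)
  gTx <- T[tri[, 1]] * g1x + T[tri[, 2]] * g2x + T[tri[, 3]] * g3x
  gTy <- T[tri[, 1]] * g1y + T[tri[, 2]] * g2y + T[tri[, 3]] * g3y
  wn <- wall$nodes
  k <- length(wn)
  n0 <- matrix(0, k, 2)
  # angle-weighted average of element gradients around each wall node
  Xl <- list(X1, X2, X3)
  angs <- matrix(0, nrow(tri), 3)
  for (kk in 1:3) {
    A <- Xl[[kk]]; B <- Xl[[kk %% 3 + 1]]; C <- Xl[[(kk + 1) %% 3 + 1]]
    uu <- B - A; vv <- C - A
    angs[, kk] <- acos(pmin(1, pmax(-1, rowSums(uu * vv) /
                                      sqrt(rowSums(uu^2) * rowSums(vv^2)))))
  }
  acc_x <- numeric(k); acc_y <- numeric(k); acc_a <- numeric(k)
  pos <- match(as.vector(tri), wn)          # 3*nel, NA if not a wall node
  wts <- as.vector(angs)
  gx3 <- rep(gTx, 3); gy3 <- rep(gTy, 3)
  sel <- !is.na(pos)
  if (any(sel)) {
    sx <- rowsum(gx3[sel] * wts[sel], pos[sel])
    sy <- rowsum(gy3[sel] * wts[sel], pos[sel])
    sa <- rowsum(wts[sel], pos[sel])
    ids <- as.integer(rownames(sx))
    acc_x[ids] <- sx[, 1]; acc_y[ids] <- sy[, 1]; acc_a[ids] <- sa[, 1]
  }
  gn <- cbind(acc_x, acc_y) / pmax(acc_a, .Machine$double.eps)
  nrm <- sqrt(rowSums(gn^2))
  P <- mesh$nodes[wn, , drop = FALSE]
  nxt <- P[c(2:k, 1), , drop = FALSE]
  prv <- P[c(k, 1:(k - 1)), , drop = FALSE]
  tan_geo <- nxt - prv
  tan_geo <- tan_geo / sqrt(rowSums(tan_geo^2))
  # geometric outward normal (CCW loop, tissue on the right): rotate the
  # tangent by -90 degrees
  n_geo <- cbind(tan_geo[, 2], -tan_geo[, 1])
  degen <- nrm < 1e-12
  # steepest descent of T points away from the wall (T is maximal there)
  n0 <- -gn / pmax(nrm, .Machine$double.eps)
  n0[degen, ] <- n_geo[degen, , drop = FALSE]
  # safety: orient outward from the cavity
  flip <- rowSums(n0 * n_geo) < 0
  n0[flip, ] <- -n0[flip, , drop = FALSE]
  t0 <- cbind(-n0[, 2], n0[, 1])
  out <- list(n0 = n0, t0 = t0, T = T)
  class(out) <- "wall_frames"
  out
}
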