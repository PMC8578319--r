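# Total-Lagrangian plane-strain hyperelastic FEM on linear triangles.
#
# Displacement-based P1 elements with one-point quadrature (the energy is
# constant per element since F is), analytic first Piola-Kirchhoff stress
# and consistent tangent of the one-term Ogden energy, follower pressure
# on boundary edge sets (with load stiffness, so Newton stays quadratic),
# and homogeneous Dirichlet constraints. Units: mm, kPa, so pressures in
# Pa are converted by 1e-3 and nodal forces are kPa mm (per mm thickness).

# Precompute reference shape-function gradients and areas.
fem_precompute <- function(mesh, materials) {
  tri <- mesh$tri
  X1 <- mesh$nodes[tri[, 1], , drop = FALSE]
  X2 <- mesh$nodes[tri[, 2], , drop = FALSE]
  X3 <- mesh$nodes[tri[, 3], , drop = FALSE]
  d1x <- X2[, 1] - X1[, 1]; d1y <- X2[, 2] - X1[, 2]
  d2x <- X3[, 1] - X1[, 1]; d2y <- X3[, 2] - X1[, 2]
  detD <- d1x * d2y - d2x * d1y          # 2 * area
  if (any(detD <= 0)) stop("fem_precompute: non-positive element area")
  # rows of inv(D): shape gradients of N2, N3; N1 = -(N2 + N3)
  g2x <- d2y / detD; g2y <- -d2x / detD
  g3x <- -d1y / detD; g3y <- d1x / detD
  g1x <- -(g2x + g3x); g1y <- -(g2y + g3y)
  mu <- unname(materials$mu[mesh$region])
  kappa <- unname(materials$kappa[mesh$region])
  if (any(is.na(mu)) || any(is.na(kappa))) {
    stop("fem_precompute: materials missing for region(s) ",
         paste(setdiff(unique(mesh$region), names(materials$mu)),
               collapse = ", "))
  }
  list(tri = tri, area = detD / 2,
       gx = cbind(g1x, g2x, g3x), gy = cbind(g1y, g2y, g3y),
       mu = mu, kappa = kappa, nnode = nrow(mesh$nodes))
}

# In-plane deformation gradient per element for nodal displacements u
# (matrix n x 2).
element_F <- function(pre, u) {
  tri <- pre$tri
  u1x <- u[tri[, 1], 1]; u1y <- u[tri[, 1], 2]
  u2x <- u[tri[, 2], 1]; u2y <- u[tri[, 2], 2]
  u3x <- u[tri[, 3], 1]; u3y <- u[tri[, 3], 2]
  list(
    F11 = 1 + u1x * pre$gx[, 1] + u2x * pre$gx[, 2] + u3x * pre$gx[, 3],
    F12 = u1x * pre$gy[, 1] + u2x * pre$gy[, 2] + u3x * pre$gy[, 3],
    F21 = u1y * pre$gx[, 1] + u2y * pre$gx[, 2] + u3y * pre$gx[, 3],
    F22 = 1 + u1y * pre$gy[, 1] + u2y * pre$gy[, 2] + u3y * pre$gy[, 3]
  )
}

# Internal force vector (length 2n) and, optionally, tangent triplets.
assemble_internal <- function(pre, u, tangent = TRUE) {
  Fv <- element_F(pre, u)
  ps <- planestrain_pk1(Fv, pre$mu, pre$kappa, tangent = tangent)
  tri <- pre$tri
  A <- pre$area
  G <- list(x = pre$gx, y = pre$gy)
  f <- numeric(2 * pre$nnode)
  idx_all <- integer(0); val_all <- numeric(0)
  Pm <- list(list(ps$P$P11, ps$P$P12), list(ps$P$P21, ps$P$P22))
  for (a in 1:3) {
    for (i in 1:2) {
      v <- A * (Pm[[i]][[1]] * G$x[, a] + Pm[[i]][[2]] * G$y[, a])
      idx_all <- c(idx_all, 2L * (tri[, a] - 1L) + i)
      val_all <- c(val_all, v)
    }
  }
  acc <- rowsum(val_all, idx_all)
  f[as.integer(rownames(acc))] <- acc[, 1]
  if (!tangent) {
    return(list(f = f, J = ps$J))
  }
  nel <- nrow(tri)
  Klen <- 36 * nel
  Ki <- integer(Klen); Kj <- integer(Klen); Kx <- numeric(Klen)
  pos <- 0L
  Aidx <- function(i, j, k, l) (((i - 1) * 2 + j) - 1) * 4 + ((k - 1) * 2 + l)
  for (a in 1:3) for (b in 1:3) for (i in 1:2) for (k in 1:2) {
    kv <- A * (
      ps$A[[Aidx(i, 1, k, 1)]] * G$x[, a] * G$x[, b] +
        ps$A[[Aidx(i, 1, k, 2)]] * G$x[, a] * G$y[, b] +
        ps$A[[Aidx(i, 2, k, 1)]] * G$y[, a] * G$x[, b] +
        ps$A[[Aidx(i, 2, k, 2)]] * G$y[, a] * G$y[, b]
    )
    Ki[pos + seq_len(nel)] <- 2L * (tri[, a] - 1L) + i
    Kj[pos + seq_len(nel)] <- 2L * (tri[, b] - 1L) + k
    Kx[pos + seq_len(nel)] <- kv
    pos <- pos + nel
  }
  list(f = f, K = list(i = Ki, j = Kj, x = Kx), J = ps$J)
}

# Follower pressure on oriented edges: the pressurized fluid lies on the
# LEFT of each edge a -> b, so the nodal force (p/2) * (e_y, -e_x) with
# e = x_b - x_a in CURRENT coordinates pushes the tissue to the right.
# Returns external force and load-stiffness triplets.
assemble_pressure <- function(mesh, u, edge_loads, tangent = TRUE) {
  n <- nrow(mesh$nodes)
  f <- numeric(2 * n)
  Ki <- integer(0); Kj <- integer(0); Kx <- numeric(0)
  for (ld in edge_loads) {
    if (abs(ld$p) < .Machine$double.eps) next
    E <- ld$edges
    p <- ld$p
    xa <- mesh$nodes[E[, 1], , drop = FALSE] + u[E[, 1], , drop = FALSE]
    xb <- mesh$nodes[E[, 2], , drop = FALSE] + u[E[, 2], , drop = FALSE]
    ex <- xb[, 1] - xa[, 1]; ey <- xb[, 2] - xa[, 2]
    fx <- p / 2 * ey; fy <- -p / 2 * ex
    for (col in 1:2) {
      nd <- E[, col]
      acc <- rowsum(fx, nd); f[2 * (as.integer(rownames(acc)) - 1) + 1] <-
        f[2 * (as.integer(rownames(acc)) - 1) + 1] + acc[, 1]
      acc <- rowsum(fy, nd); f[2 * (as.integer(rownames(acc)) - 1) + 2] <-
        f[2 * (as.integer(rownames(acc)) - 1) + 2] + acc[, 1]
    }
    if (tangent) {
      # d f_a / d x_b = (p/2) [[0, 1], [-1, 0]], d f_a / d x_a = -same,
      # for both receiving nodes a in {E1, E2}
      ne <- nrow(E)
      for (recv in 1:2) for (src in 1:2) {
        sgn <- if (src == 2) 1 else -1
        Ki <- c(Ki, 2L * (E[, recv] - 1L) + 1L, 2L * (E[, recv] - 1L) + 2L)
        Kj <- c(Kj, 2L * (E[, src] - 1L) + 2L, 2L * (E[, src] - 1L) + 1L)
        Kx <- c(Kx, rep(sgn * p / 2, ne), rep(-sgn * p / 2, ne))
      }
    }
  }
  list(f = f, K = list(i = Ki, j = Kj, x = Kx))
}

#' Solve the quasistatic pressurization boundary-value problem
#'
#' Newton solution of plane-strain equilibrium under follower pressure
#' loads: the ventricular pressure acts normal to the (deforming)
#' ventricular wall, the subarachnoid pressure acts normal to the outer
#' gray matter surface pushing the cortex inward, and the outer CSF
#' periphery is held fixed (skull). Convergence is declared at a relative
#' residual below `tol`; if the full-load Newton solve diverges, the load
#' is reapplied in up to 10 uniform increments.
#'
#' @param mesh a [mesh_geometry()] mesh (or a mesh with custom edge sets
#'   when `pressure_loads` is supplied).
#' @param materials a [material_params()] object.
#' @param loads a [load_case()] object (Pa); ignored when `pressure_loads`
#'   is given.
#' @param pressure_loads optional explicit list of follower loads, each
#'   `list(edges =, p =)` with `p` in kPa and edges oriented with the
#'   fluid on the left; replaces the default wall/SAS loads.
#' @param fixed_dofs optional integer dof indices (`2*(node-1)+comp`) to
#'   clamp; defaults to both components of the skull nodes.
#' @param tol relative residual tolerance.
#' @param max_iter Newton iterations per load step.
#' @return Object of class `vent_solution`: `u` (n x 2 displacements, mm),
#'   `converged`, `residuals` (per-iteration relative norms, last step),
#'   `steps` (load increments used), plus the inputs needed downstream.
#' @export
solve_quasistatic <- function(mesh, materials = material_params(),
                              loads = load_case(),
                              pressure_loads = NULL, fixed_dofs = NULL,
                              tol = 1e-9, max_iter = 30) {
  pre <- fem_precompute(mesh, materials)
  n <- nrow(mesh$nodes)
  ndof <- 2L * n
  if (is.null(pressure_loads)) {
    pressure_loads <- list()
    if (!is.null(mesh$bsets$wall_edges)) {
      pressure_loads <- c(pressure_loads,
                          list(list(edges = mesh$bsets$wall_edges,
                                    p = loads$p_lv * 1e-3)))
    }
    if (!is.null(mesh$bsets$gm_csf_edges) && loads$p_sas != 0) {
      # SAS film outside the cortex: reverse the CCW interface edges so the
      # fluid is on the left and the push is inward onto the brain
      E <- mesh$bsets$gm_csf_edges[, 2:1, drop = FALSE]
      pressure_loads <- c(pressure_loads,
                          list(list(edges = E, p = loads$p_sas * 1e-3)))
    }
  }
  if (is.null(fixed_dofs)) {
    sk <- mesh$bsets$skull_nodes
    if (is.null(sk) || length(sk) == 0) {
      stop("solve_quasistatic: no skull nodes to constrain")
    }
    fixed_dofs <- c(2L * (sk - 1L) + 1L, 2L * (sk - 1L) + 2L)
  }
  free <- setdiff(seq_len(ndof), fixed_dofs)

  residual_and_K <- function(u, scale, tangent = TRUE) {
    int <- assemble_internal(pre, u, tangent = tangent)
    ldl <- lapply(pressure_loads, function(ld) {
      ld$p <- ld$p * scale; ld
    })
    ext <- assemble_pressure(mesh, u, ldl, tangent = tangent)
    r <- int$f - ext$f
    if (!tangent) return(list(r = r, fext = ext$f))
    K <- Matrix::sparseMatrix(
      i = c(int$K$i, ext$K$i), j = c(int$K$j, ext$K$j),
      x = c(int$K$x, -ext$K$x), dims = c(ndof, ndof)
    )
    list(r = r, K = K, fext = ext$f)
  }

  newton_run <- function(u0, scales) {
    u <- u0
    hist <- NULL
    for (sc in scales) {
      rk <- residual_and_K(u, sc)
      fref <- max(sqrt(sum(rk$fext^2)), 1e-12)
      rn <- sqrt(sum(rk$r[free]^2)) / fref
      hist <- c(rn)
      it <- 0
      while (rn > tol) {
        it <- it + 1
        if (it > max_iter) return(list(ok = FALSE, u = u, hist = hist))
        du <- numeric(ndof)
        du[free] <- as.numeric(
          Matrix::solve(rk$K[free, free, drop = FALSE], -rk$r[free])
        )
        step <- 1
        repeat {
          u_try <- u + step * matrix(du, ncol = 2, byrow = TRUE)
          rn_try <- tryCatch({
            rt <- residual_and_K(u_try, sc, tangent = FALSE)
            sqrt(sum(rt$r[free]^2)) / fref
          }, error = function(e) Inf)
          if (rn_try < rn * (1 - 1e-4 * step) || rn_try < tol) break
          step <- step / 2
          if (step < 1 / 1024) return(list(ok = FALSE, u = u, hist = hist))
        }
        u <- u_try
        rk <- residual_and_K(u, sc)
        rn <- sqrt(sum(rk$r[free]^2)) / fref
        hist <- c(hist, rn)
      }
    }
    list(ok = TRUE, u = u, hist = hist)
  }

  u0 <- matrix(0, n, 2)
  steps_used <- 1L
  res <- newton_run(u0, 1)
  if (!res$ok) {
    for (nstep in c(5L, 10L)) {
      res <- newton_run(u0, seq_len(nstep) / nstep)
      steps_used <- nstep
      if (res$ok) break
    }
  }
  if (!res$ok) {
    stop("solve_quasistatic: Newton did not converge (last residuals: ",
         paste(signif(utils::tail(res$hist, 4), 3), collapse = ", "), ")")
  }
  out <- list(
    u = res$u, converged = TRUE, residuals = res$hist,
    steps = steps_used, materials = materials, loads = loads,
    fixed_dofs = fixed_dofs
  )
  class(out) <- "vent_solution"
  out
}

#' @export
print.vent_solution <- function(x, ...) {
  cat("<vent_solution> ", nrow(x$u), " nodes, ",
      "max |u| = ", signif(max(sqrt(rowSums(x$u^2))), 4), " mm, ",
      "final residual ", signif(utils::tail(x$residuals, 1), 3),
      " (", x$steps, " load step(s))\n", sep = "")
  invisible(x)
}

#' Per-element finite-strain kinematics of a converged solution
#'
#' Computes, per element, the plane-strain deformation gradient
#' \eqn{F} (out-of-plane stretch 1), \eqn{J = \det F}, the right
#' Cauchy-Green tensor \eqn{C = F^T F} and its isochoric part
#' \eqn{\bar C = J^{-2/3} C}, the isochoric invariants \eqn{\bar I_1,
#' \bar I_2}, isochoric principal stretches, the Green-Lagrange strain
#' \eqn{E = (C - I)/2}, and the maximum principal strain (largest
#' eigenvalue of \eqn{E}; the out-of-plane eigenvalue is 0).
#'
#' @param solution a [solve_quasistatic()] result.
#' @param mesh the mesh the solution was computed on.
#' @return Object of class `vent_kinematics`: list of per-element vectors
#'   (`F11`, `F12`, `F21`, `F22`, `J`, `C11`, `C12`, `C22`, `I1bar`,
#'   `I2bar`, `lambda_bar1`, `lambda_bar2`, `lambda_bar3`, `mps`,
#'   `det_Cbar`).
#' @export
kinematics <- function(solution, mesh) {
  pre <- fem_precompute(mesh, material_params())  # materials unused here
  Fv <- element_F(pre, solution$u)
  J <- Fv$F11 * Fv$F22 - Fv$F12 * Fv$F21
  if (any(J <= 0)) stop("kinematics: element inversion (J <= 0)")
  C11 <- Fv$F11^2 + Fv$F21^2
  C12 <- Fv$F11 * Fv$F12 + Fv$F21 * Fv$F22
  C22 <- Fv$F12^2 + Fv$F22^2
  # in-plane eigenvalues of C; out-of-plane C33 = 1
  tr2 <- C11 + C22
  disc <- sqrt(pmax(0, (C11 - C22)^2 / 4 + C12^2))
  c_hi <- tr2 / 2 + disc
  c_lo <- tr2 / 2 - disc
  Jm23 <- J^(-2 / 3)
  I1 <- tr2 + 1
  C2sq_tr <- C11^2 + 2 * C12^2 + C22^2 + 1
  I1b <- Jm23 * I1
  I2b <- (I1b^2 - Jm23^2 * C2sq_tr) / 2
  mps <- pmax((c_hi - 1) / 2, 0)   # E eigenvalues: (lam_C - 1)/2, and 0
  out <- list(
    F11 = Fv$F11, F12 = Fv$F12, F21 = Fv$F21, F22 = Fv$F22,
    J = J, C11 = C11, C12 = C12, C22 = C22,
    I1bar = I1b, I2bar = I2b,
    lambda_bar1 = sqrt(Jm23 * c_hi),
    lambda_bar2 = sqrt(Jm23 * c_lo),
    lambda_bar3 = sqrt(Jm23),
    mps = mps,
    det_Cbar = Jm23^3 * (C11 * C22 - C12^2)
  )
  class(out) <- "vent_kinematics"
  out
}
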