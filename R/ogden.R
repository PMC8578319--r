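#' One-term Ogden strain energy density
#'
#' Evaluates the nearly incompressible one-term Ogden energy used for brain
#' tissue,
#' \deqn{\Psi = \frac{\mu}{2}\left[\bar\lambda_1^2 + \bar\lambda_2^2 +
#'   \bar\lambda_3^2 - 3\right] + \frac{\kappa}{4}\left[J^2 - 1 -
#'   2\log J\right],}
#' where \eqn{\bar\lambda_i} are the isochoric principal stretches and
#' \eqn{J = \det F}. With squared isochoric stretches this is the
#' \eqn{\alpha = 2} member of the Ogden family, i.e. an isochoric
#' neo-Hookean term plus a volumetric penalty.
#'
#' @param F deformation gradient, a 2x2 (interpreted as plane strain with
#'   out-of-plane stretch 1) or 3x3 matrix with positive determinant.
#' @param mu shear modulus (kPa).
#' @param kappa bulk modulus (kPa).
#' @return Energy density in kPa.
#' @seealso [ogden_stress()], [ogden_tangent()], [material_params()]
#' @export
#' @examples
#' ogden_energy(diag(3), mu = 0.68, kappa = 6.6)        # 0 at reference
#' ogden_energy(1.1^(1/3) * diag(3), mu = 1, kappa = 3.3) # pure dilatation
ogden_energy <- function(F, mu, kappa) {
  F <- expand_F(F)
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    stop("ogden_energy: det(F) = ", format(J), " <= 0 (element inversion)")
  }
  I1 <- sum(F * F)                 # tr(C) = F:F
  I1bar <- J^(-2 / 3) * I1
  mu / 2 * (I1bar - 3) + kappa / 4 * (J^2 - 1 - 2 * log(J))
}

#' First Piola-Kirchhoff stress of the Ogden energy
#'
#' Analytic derivative \eqn{P = \partial\Psi/\partial F} of the energy in
#' [ogden_energy()]:
#' \deqn{P = \mu J^{-2/3}\left(F - \tfrac{I_1}{3} F^{-T}\right) +
#'   \tfrac{\kappa}{2}(J^2 - 1) F^{-T}.}
#'
#' @inheritParams ogden_energy
#' @return 3x3 (or 2x2 when the input was 2x2) first Piola-Kirchhoff stress
#'   in kPa.
#' @export
ogden_stress <- function(F, mu, kappa) {
  d <- nrow(F)
  F <- expand_F(F)
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    stop("ogden_stress: det(F) = ", format(J), " <= 0 (element inversion)")
  }
  I1 <- sum(F * F)
  H <- t(solve(F))                 # F^{-T}
  P <- mu * J^(-2 / 3) * (F - (I1 / 3) * H) + kappa / 2 * (J^2 - 1) * H
  if (d == 2) P[1:2, 1:2] else P
}

#' Consistent material tangent of the Ogden energy
#'
#' Fourth-order tangent \eqn{A_{ijkl} = \partial P_{ij}/\partial F_{kl}}
#' of the stress in [ogden_stress()], returned as a full array. The tangent
#' has major symmetry \eqn{A_{ijkl} = A_{klij}}.
#'
#' @inheritParams ogden_energy
#' @return numeric array of dimension `c(d, d, d, d)` where `d` matches the
#'   input dimension (2 for plane strain blocks, 3 otherwise), in kPa.
#' @export
ogden_tangent <- function(F, mu, kappa) {
  d <- nrow(F)
  F3 <- expand_F(F)
  J <- det(F3)
  if (!is.finite(J) || J <= 0) {
    stop("ogden_tangent: det(F) = ", format(J), " <= 0 (element inversion)")
  }
  I1 <- sum(F3 * F3)
  H <- t(solve(F3))
  Jm23 <- J^(-2 / 3)
  A <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    A[i, j, k, l] <-
      mu * Jm23 * ((i == k) * (j == l) -
                     (2 / 3) * (F3[i, j] * H[k, l] + H[i, j] * F3[k, l]) +
                     (2 / 9) * I1 * H[i, j] * H[k, l] +
                     (I1 / 3) * H[i, l] * H[k, j]) +
      kappa * J^2 * H[i, j] * H[k, l] -
      kappa / 2 * (J^2 - 1) * H[i, l] * H[k, j]
  }
  if (d == 2) A[1:2, 1:2, 1:2, 1:2, drop = FALSE] else A
}

# Promote a 2x2 plane-strain deformation gradient to 3x3 (out-of-plane
# stretch fixed at 1). 3x3 inputs pass through.
expand_F <- function(F) {
  if (is.matrix(F) && all(dim(F) == c(2, 2))) {
    F3 <- diag(3)
    F3[1:2, 1:2] <- F
    F3
  } else if (is.matrix(F) && all(dim(F) == c(3, 3))) {
    F
  } else {
    stop("F must be a 2x2 or 3x3 matrix")
  }
}

# Vectorized plane-strain stress + tangent over many elements.
# Fv: list with numeric vectors F11, F12, F21, F22 (row-major components of
# the in-plane deformation gradient per element); mu, kappa vectors recycled
# per element. Returns in-plane P components and the 16 in-plane tangent
# components as a named list of vectors. Out-of-plane stretch is 1, so
# J = det(F2) and I1 = tr(C2) + 1.
planestrain_pk1 <- function(Fv, mu, kappa, tangent = TRUE) {
  F11 <- Fv$F11; F12 <- Fv$F12; F21 <- Fv$F21; F22 <- Fv$F22
  J <- F11 * F22 - F12 * F21
  if (any(!is.finite(J)) || any(J <= 0)) {
    bad <- which(!is.finite(J) | J <= 0)
    stop("element inversion: det(F) <= 0 in element(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  I1 <- F11^2 + F12^2 + F21^2 + F22^2 + 1
  Jm23 <- J^(-2 / 3)
  H11 <- F22 / J; H12 <- -F21 / J; H21 <- -F12 / J; H22 <- F11 / J
  vol <- kappa / 2 * (J^2 - 1)
  P <- list(
    P11 = mu * Jm23 * (F11 - I1 / 3 * H11) + vol * H11,
    P12 = mu * Jm23 * (F12 - I1 / 3 * H12) + vol * H12,
    P21 = mu * Jm23 * (F21 - I1 / 3 * H21) + vol * H21,
    P22 = mu * Jm23 * (F22 - I1 / 3 * H22) + vol * H22
  )
  if (!tangent) {
    return(list(P = P, J = J, I1 = I1))
  }
  Fm <- list(F11, F12, F21, F22)
  Hm <- list(H11, H12, H21, H22)
  idx <- function(i, j) (i - 1) * 2 + j
  A <- vector("list", 16)
  kJ2 <- kappa * J^2
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
    Aijkl <- mu * Jm23 *
      ((i == k) * (j == l) -
         (2 / 3) * (Fm[[idx(i, j)]] * Hm[[idx(k, l)]] +
                      Hm[[idx(i, j)]] * Fm[[idx(k, l)]]) +
         (2 / 9) * I1 * Hm[[idx(i, j)]] * Hm[[idx(k, l)]] +
         (I1 / 3) * Hm[[idx(i, l)]] * Hm[[idx(k, j)]]) +
      kJ2 * Hm[[idx(i, j)]] * Hm[[idx(k, l)]] -
      vol * Hm[[idx(i, l)]] * Hm[[idx(k, j)]]
    A[[(idx(i, j) - 1) * 4 + idx(k, l)]] <- Aijkl
  }
  list(P = P, A = A, J = J, I1 = I1)
}

#' Default material parameters for brain tissue and the CSF surrogate
#'
#' Region-wise shear and bulk moduli (kPa). Defaults follow experimentally
#' informed brain constants with a white/gray stiffness ratio of 2 and a
#' Poisson ratio of 0.45: gray matter \eqn{\mu = 0.34}, \eqn{\kappa = 3.3};
#' white matter \eqn{\mu = 0.68}, \eqn{\kappa = 6.6}. The subarachnoid /
#' ventricular CSF is approximated as an ultrasoft compressible solid with
#' Young's modulus 0.1 kPa and Poisson ratio 0.3, converted to
#' \eqn{\mu = E / (2(1+\nu))}, \eqn{\kappa = E / (3(1-2\nu))} so one
#' material routine serves all regions.
#'
#' @param mu_wm,kappa_wm white matter moduli (kPa).
#' @param mu_gm,kappa_gm gray matter moduli (kPa).
#' @param csf_E,csf_nu Young's modulus (kPa) and Poisson ratio of the CSF
#'   surrogate.
#' @param stiffness_scale multiplier applied to the white matter moduli
#'   (sensitivity sweeps).
#' @return Object of class `vent_materials`: a list with per-region `mu` and
#'   `kappa` (kPa).
#' @export
material_params <- function(mu_wm = 0.68, kappa_wm = 6.6,
                            mu_gm = 0.34, kappa_gm = 3.3,
                            csf_E = 0.1, csf_nu = 0.3,
                            stiffness_scale = 1) {
  stopifnot(mu_wm > 0, kappa_wm > 0, mu_gm > 0, kappa_gm > 0,
            csf_E > 0, csf_nu > -1, csf_nu < 0.5, stiffness_scale > 0)
  out <- list(
    mu = c(white_matter = mu_wm * stiffness_scale,
           gray_matter = mu_gm,
           csf = csf_E / (2 * (1 + csf_nu))),
    kappa = c(white_matter = kappa_wm * stiffness_scale,
              gray_matter = kappa_gm,
              csf = csf_E / (3 * (1 - 2 * csf_nu)))
  )
  class(out) <- "vent_materials"
  out
}

#' Ventricular and subarachnoid pressure load case
#'
#' Peak hemodynamic loading: a lateral-ventricle pressure applied as a
#' follower load normal to the ventricular wall and a subarachnoid space
#' (SAS) pressure acting normal to the outer gray matter surface. Defaults
#' are 20 Pa (0.15 mmHg) for the ventricle and 1 Pa for the SAS, consistent
#' with SAS pressure being 10-20 percent of ventricular pressure.
#'
#' @param p_lv ventricular pressure (Pa).
#' @param p_sas subarachnoid pressure (Pa).
#' @param pressure_scale multiplier applied to both pressures (sensitivity
#'   sweeps).
#' @return Object of class `vent_loads` with pressures in Pa.
#' @export
load_case <- function(p_lv = 20, p_sas = 1, pressure_scale = 1) {
  stopifnot(is.finite(p_lv), is.finite(p_sas), pressure_scale >= 0)
  out <- list(p_lv = p_lv * pressure_scale, p_sas = p_sas * pressure_scale)
  class(out) <- "vent_loads"
  out
}

#' Convert pressure from pascal to millimetres of mercury
#'
#' @param p pressure in Pa.
#' @return pressure in mmHg (`p / 133.322`).
#' @export
#' @examples
#' pa_to_mmhg(20) # 0.15 mmHg
pa_to_mmhg <- function(p) {
  p / 133.322
}
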