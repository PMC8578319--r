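# Wall-level mechanomarkers: ependymal cell tension/compression profiles,
# horn detection, the three-point circle fit for horn radius, and the
# elevated-stretch wall fraction.

#' Project wall stretches from the deformation state
#'
#' Interpolates the right Cauchy-Green tensor to the ordered wall nodes
#' (angle-weighted averaging over wall-adjacent white-matter elements; the
#' ependyma belongs to the tissue side, so only tissue elements
#' contribute) and projects it onto the reference wall frames:
#' \deqn{\lambda_t = \sqrt{t_0 \cdot C\, t_0}, \qquad
#'       \lambda_c = \sqrt{n_0 \cdot C\, n_0},}
#' the ependymal cell tension (tangential stretch) and compression
#' (normal stretch).
#'
#' @param state a [kinematics()] object.
#' @param frames a [wall_frames()] object.
#' @param wall a [order_wall()] path.
#' @param mesh the mesh.
#' @return Object of class `wall_profile`: data frame with `arclength`
#'   (mm), `lambda_t`, `lambda_c`, `x`, `y`, `n0x`, `n0y`, `t0x`, `t0y`
#'   per ordered wall node, with attributes `total_length` and `nodes`.
#' @export
project_wall_stretches <- function(state, frames, wall, mesh) {
  first_region <- if ("white_matter" %in% mesh$region) "white_matter" else
    unique(mesh$region)[1]
  el <- which(mesh$region == first_region)
  tri <- mesh$tri[el, , drop = FALSE]
  wn <- wall$nodes
  k <- length(wn)
  # angle weights per element corner
  X <- lapply(1:3, function(a) mesh$nodes[tri[, a], , drop = FALSE])
  angs <- matrix(0, nrow(tri), 3)
  for (kk in 1:3) {
    A <- X[[kk]]; B <- X[[kk %% 3 + 1]]; C <- X[[(kk + 1) %% 3 + 1]]
    uu <- B - A; vv <- C - A
    angs[, kk] <- acos(pmin(1, pmax(-1, rowSums(uu * vv) /
                                      sqrt(rowSums(uu^2) * rowSums(vv^2)))))
  }
  pos <- match(as.vector(tri), wn)
  sel <- !is.na(pos)
  w <- as.vector(angs)[sel]
  p <- pos[sel]
  avg <- function(v_all) {
    v3 <- rep(v_all[el], 3)[sel]          # per-corner element values
    s <- rowsum(v3 * w, p)
    out <- numeric(k)
    out[as.integer(rownames(s))] <- s[, 1]
    out
  }
  wsum <- numeric(k)
  s <- rowsum(w, p); wsum[as.integer(rownames(s))] <- s[, 1]
  C11 <- avg(state$C11) / wsum
  C12 <- avg(state$C12) / wsum
  C22 <- avg(state$C22) / wsum
  t0 <- frames$t0; n0 <- frames$n0
  lt2 <- t0[, 1]^2 * C11 + 2 * t0[, 1] * t0[, 2] * C12 + t0[, 2]^2 * C22
  lc2 <- n0[, 1]^2 * C11 + 2 * n0[, 1] * n0[, 2] * C12 + n0[, 2]^2 * C22
  prof <- data.frame(
    arclength = wall$arclength,
    lambda_t = sqrt(pmax(lt2, 0)),
    lambda_c = sqrt(pmax(lc2, 0)),
    x = mesh$nodes[wn, 1], y = mesh$nodes[wn, 2],
    n0x = n0[, 1], n0y = n0[, 2], t0x = t0[, 1], t0y = t0[, 2],
    C11 = C11, C12 = C12, C22 = C22
  )
  attr(prof, "total_length") <- wall$total_length
  attr(prof, "nodes") <- wn
  class(prof) <- c("wall_profile", "data.frame")
  prof
}

#' Detect the four horn peaks of the tension profile
#'
#' Finds local maxima of \eqn{\lambda_t} on the closed wall profile,
#' enforces a minimum arclength separation (default 5 percent of the wall
#' length), and returns the four highest in traversal order (labels A-D:
#' starting between the posterior horns the traversal meets posterior,
#' anterior, anterior, posterior horns). Ties are broken towards smaller
#' arclength so reports are deterministic.
#'
#' @param profile a [project_wall_stretches()] profile.
#' @param min_separation minimum peak separation as a fraction of total
#'   wall length.
#' @param min_excess peaks need `lambda_t > 1 + min_excess` to count as
#'   loaded (guards the unloaded case).
#' @return data.frame with columns `label`, `index`, `arclength`,
#'   `lambda_t`, `x`, `y`, ordered by arclength.
#' @export
detect_horn_peaks <- function(profile, min_separation = 0.05,
                              min_excess = 1e-6) {
  lt <- profile$lambda_t
  k <- length(lt)
  L <- attr(profile, "total_length")
  nxt <- c(2:k, 1); prv <- c(k, 1:(k - 1))
  is_max <- lt >= lt[nxt] & lt > lt[prv] & lt > 1 + min_excess
  cand <- which(is_max)
  if (length(cand) == 0) {
    stop("detect_horn_peaks: no local maxima above 1 (unloaded profile?)")
  }
  # greedy selection by height, tie towards smaller arclength
  cand <- cand[order(-lt[cand], profile$arclength[cand])]
  chosen <- integer(0)
  sep <- min_separation * L
  circ_dist <- function(s1, s2) {
    d <- abs(s1 - s2)
    pmin(d, L - d)
  }
  for (i in cand) {
    if (all(circ_dist(profile$arclength[i],
                      profile$arclength[chosen]) >= sep) ||
          length(chosen) == 0) {
      chosen <- c(chosen, i)
    }
    if (length(chosen) == 4) break
  }
  if (length(chosen) < 4) {
    stop("detect_horn_peaks: only ", length(chosen),
         " separated maxima found (expected 4); degenerate geometry ",
         "or load")
  }
  chosen <- chosen[order(profile$arclength[chosen])]
  data.frame(
    label = c("A", "B", "C", "D"),
    index = chosen,
    arclength = profile$arclength[chosen],
    lambda_t = lt[chosen],
    x = profile$x[chosen],
    y = profile$y[chosen]
  )
}

#' Circumcircle through three points
#'
#' @param p1,p2,p3 length-2 numeric vectors.
#' @return list with `center` and `radius`.
#' @export
circumcircle <- function(p1, p2, p3) {
  ax <- p1[1]; ay <- p1[2]; bx <- p2[1]; by <- p2[2]; cx <- p3[1]; cy <- p3[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12 * max(1, abs(ax), abs(ay), abs(bx), abs(by))) {
    stop("circumcircle: points are (nearly) collinear, radius is infinite")
  }
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  list(center = c(ux, uy), radius = sqrt((ax - ux)^2 + (ay - uy)^2))
}

# Walk the closed profile from a peak in direction dir (+1/-1) and find
# the first crossing where excess tension drops to `target`; linear
# interpolation between wall nodes, in both the profile value and the
# wall coordinates. Returns list(s, xy) or NULL after half a loop.
excess_crossing <- function(profile, peak_idx, target, dir) {
  lt <- profile$lambda_t - 1
  k <- length(lt)
  x <- profile$x; y <- profile$y; s <- profile$arclength
  L <- attr(profile, "total_length")
  i <- peak_idx
  travelled <- 0
  while (travelled < L / 2) {
    j <- ((i - 1 + dir) %% k) + 1
    if (lt[j] <= target) {
      f <- (lt[i] - target) / (lt[i] - lt[j])
      xy <- c(x[i] + f * (x[j] - x[i]), y[i] + f * (y[j] - y[i]))
      return(list(xy = xy))
    }
    seg <- sqrt((x[j] - x[i])^2 + (y[j] - y[i])^2)
    travelled <- travelled + seg
    i <- j
  }
  NULL
}

#' Horn radius from the three-point circle fit
#'
#' Fits the exact circumcircle through the wall point of maximum cell
#' tension and the two flanking points, left and right of the peak, where
#' the excess tension \eqn{\lambda_t - 1} has first dropped to 10 percent
#' of the peak excess (crossings located by linear interpolation between
#' wall nodes). The drop rule is applied to the excess stretch because
#' \eqn{\lambda_t} itself is bounded below by about 1, so a drop to 10
#' percent of a raw stretch value near 1.07 could never occur.
#'
#' @param profile a [project_wall_stretches()] profile.
#' @param peak_index profile row index of the peak (from
#'   [detect_horn_peaks()]).
#' @param drop_fraction flank threshold as a fraction of peak excess.
#' @return list with `radius` (mm), `center`, and the three fit points.
#' @export
horn_circle_fit <- function(profile, peak_index, drop_fraction = 0.1) {
  exc <- profile$lambda_t[peak_index] - 1
  if (exc <= 0) stop("horn_circle_fit: peak has no excess tension")
  target <- drop_fraction * exc
  pk <- c(profile$x[peak_index], profile$y[peak_index])
  lft <- excess_crossing(profile, peak_index, target, -1L)
  rgt <- excess_crossing(profile, peak_index, target, +1L)
  if (is.null(lft) || is.null(rgt)) {
    stop("horn_circle_fit: no 10 percent drop found on both sides of the ",
         "peak before half the wall loop")
  }
  cc <- circumcircle(lft$xy, pk, rgt$xy)
  list(radius = cc$radius, center = cc$center,
       points = rbind(left = lft$xy, peak = pk, right = rgt$xy))
}

#' Fraction of the ventricular wall under elevated cell stretch
#'
#' Measures the total arclength of wall sections whose excess tension
#' \eqn{\lambda_t - 1} exceeds `drop_fraction` (default 10 percent) of the
#' global peak excess, divided by the total wall length. Segment
#' crossings are located by linear interpolation, and the same excess
#' convention as [horn_circle_fit()] is used.
#'
#' @param profile a [project_wall_stretches()] profile.
#' @param drop_fraction threshold as a fraction of the peak excess.
#' @return dimensionless fraction in `[0, 1]`.
#' @export
wall_fraction_elevated <- function(profile, drop_fraction = 0.1) {
  exc <- profile$lambda_t - 1
  pk <- max(exc)
  if (pk <= 0) return(0)
  thr <- drop_fraction * pk
  k <- length(exc)
  x <- profile$x; y <- profile$y
  nxt <- c(2:k, 1)
  seg <- sqrt((x[nxt] - x)^2 + (y[nxt] - y)^2)
  e1 <- exc; e2 <- exc[nxt]
  above1 <- e1 > thr; above2 <- e2 > thr
  frac <- ifelse(
    above1 & above2, 1,
    ifelse(!above1 & !above2, 0,
           abs(pmax(e1, e2) - thr) / pmax(abs(e2 - e1),
                                          .Machine$double.eps))
  )
  sum(seg * frac) / sum(seg)
}

#' Horn metrics of one subject
#'
#' Composition of [detect_horn_peaks()], [horn_circle_fit()] and
#' [wall_fraction_elevated()]: per horn the fitted radius and peak
#' tension, plus the subject-level elevated-stretch wall fraction.
#'
#' @param profile a [project_wall_stretches()] profile.
#' @param drop_fraction excess threshold used for both the circle fit and
#'   the wall fraction.
#' @return Object of class `horn_metrics`: list with `horns` (data.frame:
#'   label, arclength, peak lambda_t, radius), `wall_fraction_elevated`,
#'   and `drop_fraction`.
#' @export
horn_metrics <- function(profile, drop_fraction = 0.1) {
  peaks <- detect_horn_peaks(profile)
  fits <- lapply(peaks$index, function(i) {
    horn_circle_fit(profile, i, drop_fraction)
  })
  out <- list(
    horns = data.frame(
      label = peaks$label,
      arclength = peaks$arclength,
      lambda_t = peaks$lambda_t,
      radius = vapply(fits, function(f) f$radius, numeric(1))
    ),
    wall_fraction_elevated = wall_fraction_elevated(profile, drop_fraction),
    drop_fraction = drop_fraction
  )
  class(out) <- "horn_metrics"
  out
}

#' @export
print.horn_metrics <- function(x, ...) {
  cat("<horn_metrics> four horns (excess-stretch drop rule ",
      x$drop_fraction * 100, "%)\n", sep = "")
  print(x$horns, row.names = FALSE, digits = 4)
  cat(sprintf("wall fraction under elevated stretch: %.3f\n",
              x$wall_fraction_elevated))
  invisible(x)
}
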