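#' Parametric specification of a synthetic subject
#'
#' Defines one synthetic axial slice: a butterfly-shaped lateral-ventricle
#' cavity (two wings joined by a thin septal channel) whose four horn-like
#' tips are circular arcs of prescribed radius, surrounded by a white matter
#' annulus, a gray matter rim, and an outer CSF (subarachnoid) layer bounded
#' by the skull. All lengths in mm.
#'
#' @param horn_radius_anterior,horn_radius_posterior radii of the anterior /
#'   posterior horn tip arcs (mm).
#' @param ventricle_halfwidth,ventricle_halfheight half extents of the
#'   cavity in x (left-right) and y (posterior-anterior) (mm).
#' @param cortex_semiaxes semi-axes of the elliptical cortical (gray matter
#'   outer) boundary (mm pair).
#' @param gm_thickness gray matter rim thickness (mm).
#' @param csf_thickness subarachnoid CSF layer thickness (mm).
#' @param septum_gap height of the septal channel joining the two wings (mm).
#' @param seed integer seed; affects only image noise downstream, never the
#'   geometry.
#' @return Object of class `subject_spec`.
#' @export
subject_spec <- function(horn_radius_anterior = 2.5,
                         horn_radius_posterior = 3,
                         ventricle_halfwidth = 22,
                         ventricle_halfheight = 30,
                         cortex_semiaxes = c(55, 65),
                         gm_thickness = 4,
                         csf_thickness = 4,
                         septum_gap = 3,
                         seed = 1L) {
  spec <- list(
    horn_radius_anterior = horn_radius_anterior,
    horn_radius_posterior = horn_radius_posterior,
    ventricle_halfwidth = ventricle_halfwidth,
    ventricle_halfheight = ventricle_halfheight,
    cortex_semiaxes = cortex_semiaxes,
    gm_thickness = gm_thickness,
    csf_thickness = csf_thickness,
    septum_gap = septum_gap,
    seed = as.integer(seed)
  )
  lens <- unlist(spec[1:8])
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("subject_spec: all lengths must be positive and finite")
  }
  if (max(horn_radius_anterior, horn_radius_posterior) >=
        ventricle_halfwidth) {
    stop("subject_spec: horn radii must be smaller than ventricle_halfwidth")
  }
  if (length(cortex_semiaxes) != 2) {
    stop("subject_spec: cortex_semiaxes must be a length-2 vector")
  }
  class(spec) <- "subject_spec"
  spec
}

# --- polygon utilities ------------------------------------------------------

# Signed area of a closed polygon (rows = vertices, no repeated endpoint).
# Positive for counter-clockwise orientation.
polygon_area <- function(P) {
  x <- P[, 1]; y <- P[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(P, closed = TRUE) {
  Q <- if (closed) rbind(P, P[1, , drop = FALSE]) else P
  sum(sqrt(rowSums(diff(Q)^2)))
}

# Discrete turn angle (exterior angle, radians) at each vertex of a closed
# polygon; positive = left turn for CCW traversal. A curvature proxy:
# angle / mean adjacent edge length.
polygon_turn_angles <- function(P) {
  n <- nrow(P)
  prv <- P[c(n, 1:(n - 1)), , drop = FALSE]
  nxt <- P[c(2:n, 1), , drop = FALSE]
  e1 <- P - prv
  e2 <- nxt - P
  a1 <- atan2(e1[, 2], e1[, 1])
  a2 <- atan2(e2[, 2], e2[, 1])
  d <- a2 - a1
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  d
}

# Vectorized point-in-polygon (sp backend). P closed polygon matrix.
points_in_polygon <- function(x, y, P) {
  sp::point.in.polygon(x, y, P[, 1], P[, 2]) > 0
}

ellipse_polygon <- function(a, b, n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(th), b * sin(th))
}

# Resample an open polyline at approximately uniform spacing, keeping both
# endpoints. Returns matrix including endpoints.
resample_polyline <- function(P, spacing) {
  seg <- sqrt(rowSums(diff(P)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  n <- max(1L, round(L / spacing))
  st <- seq(0, L, length.out = n + 1)
  cbind(stats::approx(s, P[, 1], xout = st)$y,
        stats::approx(s, P[, 2], xout = st)$y)
}

# Minimum distance from points (x, y) to a closed polygon boundary.
dist_to_polygon <- function(x, y, P) {
  A <- P
  B <- P[c(2:nrow(P), 1), , drop = FALSE]
  d2 <- rep(Inf, length(x))
  for (i in seq_len(nrow(A))) {
    ax <- A[i, 1]; ay <- A[i, 2]
    vx <- B[i, 1] - ax; vy <- B[i, 2] - ay
    vv <- vx * vx + vy * vy
    t <- if (vv > 0) pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / vv)) else 0
    dx <- x - (ax + t * vx); dy <- y - (ay + t * vy)
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# Tangent point from external point P to circle (C, r). Of the two tangent
# points, returns the one for which the circle center lies to the left of
# the ray P -> T when `side = "left"`, to the right otherwise.
tangent_point <- function(P, C, r, side = c("left", "right")) {
  side <- match.arg(side)
  v <- C - P
  d <- sqrt(sum(v^2))
  if (d <= r) {
    stop("tangent_point: point lies inside the circle (distance ",
         format(d), " <= radius ", format(r), ")")
  }
  L <- sqrt(d^2 - r^2)
  beta <- asin(r / d)
  ang <- atan2(v[2], v[1])
  cand <- lapply(c(-1, 1), function(sgn) {
    th <- ang + sgn * beta
    P + L * c(cos(th), sin(th))
  })
  crossz <- vapply(cand, function(T) {
    dir <- T - P
    dir[1] * (C[2] - P[2]) - dir[2] * (C[1] - P[1])
  }, numeric(1))
  if (side == "left") cand[[which.max(crossz)]] else cand[[which.min(crossz)]]
}

# Arc points on circle (C, r) from point T1 to point T2 travelling CCW,
# with >= nseg segments. Excludes T1, includes T2.
arc_points <- function(C, r, T1, T2, nseg = 32) {
  a1 <- atan2(T1[2] - C[2], T1[1] - C[1])
  a2 <- atan2(T2[2] - C[2], T2[1] - C[1])
  if (a2 <= a1) a2 <- a2 + 2 * pi
  th <- seq(a1, a2, length.out = max(nseg, 32) + 1)[-1]
  cbind(C[1] + r * cos(th), C[2] + r * sin(th))
}

# --- butterfly cavity -------------------------------------------------------

# Construct the left wing tangency data; the right wing is its mirror image.
wing_construction <- function(spec) {
  ra <- spec$horn_radius_anterior
  rp <- spec$horn_radius_posterior
  W <- spec$ventricle_halfwidth
  H <- spec$ventricle_halfheight
  g2 <- spec$septum_gap / 2
  rmax <- max(ra, rp)
  xc <- W - rmax                      # wing axis |x|
  xi <- 0.45 * xc                     # channel half-length
  Ca <- c(-xc, H - ra)                # anterior tip circle (left wing)
  Cp <- c(-xc, -(H - rp))             # posterior tip circle (left wing)
  dcent <- Ca[2] - Cp[2]
  if (dcent <= ra + rp) {
    stop("make_geometry: tip arcs overlap (halfheight too small for radii)")
  }
  # outer common tangent on the -x side: unit normal n with n . C_i - c = r_i
  ny <- (ra - rp) / dcent
  n <- c(-sqrt(1 - ny^2), ny)
  Ta_out <- Ca + ra * n
  Tp_out <- Cp + rp * n
  P_up <- c(-xi, g2)
  P_low <- c(-xi, -g2)
  if (sqrt(sum((P_up - Ca)^2)) <= ra || sqrt(sum((P_low - Cp)^2)) <= rp) {
    stop("make_geometry: septal channel corner lies inside a tip arc; ",
         "increase ventricle_halfwidth or reduce horn radii")
  }
  # inner tangents: interior of the wing (containing the circle centre)
  # must lie left of the upward traversal P_up -> Ta_in, and left of the
  # downward traversal Tp_in -> P_low.
  Ta_in <- tangent_point(P_up, Ca, ra, side = "left")
  Tp_in <- tangent_point(P_low, Cp, rp, side = "right")
  list(Ca = Ca, Cp = Cp, ra = ra, rp = rp, xc = xc, xi = xi, g2 = g2,
       Ta_out = Ta_out, Tp_out = Tp_out, Ta_in = Ta_in, Tp_in = Tp_in,
       P_up = P_up, P_low = P_low)
}

mirror_x <- function(P) cbind(-P[, 1], P[, 2])

# Build the closed CCW cavity polygon. Returns list(poly, arcs, tips,
# corner_idx) where arcs give per-horn vertex index ranges in traversal
# order and tips the four apex points.
butterfly_polygon <- function(spec, seg_len = 0.75, arc_segments = 40) {
  w <- wing_construction(spec)
  nseg_a <- max(32, arc_segments)
  nseg_p <- max(32, arc_segments)
  line <- function(A, B) resample_polyline(rbind(A, B), seg_len)
  pieces <- list()
  kind <- character(0)
  add <- function(pts, what) {
    pieces[[length(pieces) + 1]] <<- pts
    kind[length(kind) + 1] <<- what
  }
  mir <- function(p) c(-p[1], p[2])
  # CCW traversal, starting at the channel bottom-left corner (-xi, -g2):
  add(line(w$P_low, mir(w$P_low))[-1, , drop = FALSE], "channel_bottom")
  add(line(mir(w$P_low), mir(w$Tp_in))[-1, , drop = FALSE], "line")
  add(arc_points(mir(w$Cp), w$rp, mir(w$Tp_in), mir(w$Tp_out), nseg_p),
      "arc_post_R")
  add(line(mir(w$Tp_out), mir(w$Ta_out))[-1, , drop = FALSE], "line")
  add(arc_points(mir(w$Ca), w$ra, mir(w$Ta_out), mir(w$Ta_in), nseg_a),
      "arc_ant_R")
  add(line(mir(w$Ta_in), mir(w$P_up))[-1, , drop = FALSE], "line")
  add(line(mir(w$P_up), w$P_up)[-1, , drop = FALSE], "channel_top")
  add(line(w$P_up, w$Ta_in)[-1, , drop = FALSE], "line")
  add(arc_points(w$Ca, w$ra, w$Ta_in, w$Ta_out, nseg_a), "arc_ant_L")
  add(line(w$Ta_out, w$Tp_out)[-1, , drop = FALSE], "line")
  add(arc_points(w$Cp, w$rp, w$Tp_out, w$Tp_in, nseg_p), "arc_post_L")
  add(line(w$Tp_in, w$P_low)[-1, , drop = FALSE], "line")
  start <- matrix(w$P_low, 1, 2)
  poly <- start
  arcs <- list()
  for (i in seq_along(pieces)) {
    i0 <- nrow(poly) + 1
    poly <- rbind(poly, pieces[[i]])
    if (startsWith(kind[i], "arc_")) {
      arcs[[sub("^arc_", "", kind[i])]] <- c(i0, nrow(poly))
    }
  }
  poly <- poly[-nrow(poly), , drop = FALSE]  # drop repeated closing vertex
  if (polygon_area(poly) < 0) {
    stop("internal error: cavity polygon is not counter-clockwise")
  }
  tips <- rbind(
    post_R = c(w$xc, -spec$ventricle_halfheight),
    ant_R = c(w$xc, spec$ventricle_halfheight),
    ant_L = c(-w$xc, spec$ventricle_halfheight),
    post_L = c(-w$xc, -spec$ventricle_halfheight)
  )
  list(poly = poly, arcs = arcs, tips = tips, construction = w)
}

#' Generate the labelled slice geometry of a synthetic subject
#'
#' Builds the region polygons of one axial slice: a single connected
#' butterfly-shaped ventricular cavity (two wings joined by a thin septal
#' channel, so one closed wall path passes through all four horns), nested
#' inside white matter, a gray matter rim, and an outer CSF layer whose
#' outer boundary stands in for the skull. The four horn tips are exact
#' circular arcs with the prescribed anterior/posterior radii, discretized
#' with at least 32 segments per arc. Geometry is fully deterministic: the
#' spec's seed only affects image noise in [make_flair()].
#'
#' @param spec a [subject_spec()].
#' @param seg_len straight-segment discretization length (mm).
#' @param arc_segments segments per tip arc (minimum 32 enforced).
#' @return Object of class `vent_geometry`: list with `region_polygons`
#'   (named list `cavity`, `white_matter`, `gray_matter`, `csf`, each a
#'   closed CCW polygon matrix in mm), `tips` (4x2 horn apex coordinates in
#'   traversal order), `arcs` (vertex index ranges of the tip arcs on the
#'   cavity polygon), `horn_radii`, and `provenance`.
#' @export
make_geometry <- function(spec, seg_len = 0.75, arc_segments = 40) {
  stopifnot(inherits(spec, "subject_spec"))
  bf <- butterfly_polygon(spec, seg_len = seg_len,
                          arc_segments = arc_segments)
  ca <- spec$cortex_semiaxes
  a_wm <- ca[1] - spec$gm_thickness
  b_wm <- ca[2] - spec$gm_thickness
  if (a_wm <= spec$ventricle_halfwidth + 2 ||
        b_wm <= spec$ventricle_halfheight + 2) {
    stop("make_geometry: white matter annulus too thin (cavity extent ",
         spec$ventricle_halfwidth, " x ", spec$ventricle_halfheight,
         " mm vs inner cortex ellipse ", round(a_wm, 1), " x ",
         round(b_wm, 1), " mm); enlarge cortex_semiaxes")
  }
  npts <- function(a, b) max(96L, round(pi * (a + b) / seg_len))
  geom <- list(
    region_polygons = list(
      cavity = bf$poly,
      white_matter = ellipse_polygon(a_wm, b_wm, npts(a_wm, b_wm)),
      gray_matter = ellipse_polygon(ca[1], ca[2], npts(ca[1], ca[2])),
      csf = ellipse_polygon(ca[1] + spec$csf_thickness,
                            ca[2] + spec$csf_thickness,
                            npts(ca[1] + spec$csf_thickness,
                                 ca[2] + spec$csf_thickness))
    ),
    tips = bf$tips,
    arcs = bf$arcs,
    horn_radii = c(anterior = spec$horn_radius_anterior,
                   posterior = spec$horn_radius_posterior),
    spec = spec,
    provenance = "subject_spec"
  )
  class(geom) <- "vent_geometry"
  geom
}

#' Annulus geometry for verification problems
#'
#' A homogeneous thick-walled annulus (inner radius `a`, outer radius `b`)
#' expressed in the same labelled-geometry container used for subjects:
#' the cavity is the inner disk (unmeshed, pressure-loaded) and a single
#' `white_matter` region fills `a <= r <= b`. Used for closed-form
#' verification (plane-strain Lame solution, log-radial Laplace solution).
#'
#' @param a,b inner and outer radii (mm), `0 < a < b`.
#' @param n boundary vertices on each circle.
#' @return Object of class `vent_geometry` with regions `cavity` and
#'   `white_matter`.
#' @export
annulus_geometry <- function(a, b, n = 128) {
  stopifnot(a > 0, b > a)
  geom <- list(
    region_polygons = list(
      cavity = ellipse_polygon(a, a, n),
      white_matter = ellipse_polygon(b, b, n)
    ),
    tips = NULL,
    arcs = NULL,
    horn_radii = NULL,
    spec = NULL,
    provenance = "annulus"
  )
  class(geom) <- "vent_geometry"
  geom
}

#' @export
print.vent_geometry <- function(x, ...) {
  regs <- names(x$region_polygons)
  cat("<vent_geometry> (", x$provenance, ")\n", sep = "")
  for (r in regs) {
    P <- x$region_polygons[[r]]
    cat(sprintf("  %-13s %4d vertices, area %8.1f mm^2\n",
                r, nrow(P), abs(polygon_area(P))))
  }
  if (!is.null(x$horn_radii)) {
    cat("  horn radii: anterior ", x$horn_radii[["anterior"]],
        " mm, posterior ", x$horn_radii[["posterior"]], " mm\n", sep = "")
  }
  invisible(x)
}
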