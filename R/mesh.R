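# Unstructured triangulation of the labelled slice geometry.
#
# Strategy: each annular region (between two consecutive region polygons) is
# meshed independently on a shared boundary discretization -- boundary nodes
# are generated once per interface and reused by both neighbouring regions,
# so the assembled mesh is conforming by construction once every boundary
# segment is present as a triangle edge (checked, and repaired by deleting
# interior seeds that block a segment). Interior nodes come from a hex grid
# thinned to the local target size, relaxed by a few Delaunay smoothing
# sweeps. Delaunay triangulation itself is delegated to interp::tri.mesh.

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

delaunay_triangles <- function(pts) {
  # break exact collinearity/cocircularity (straight tangent lines, arcs,
  # hex grids) with a tiny deterministic jitter; only the connectivity is
  # taken from the jittered cloud, node coordinates stay exact.
  scale <- max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  jit <- with_local_seed(
    97531L,
    matrix(stats::runif(2 * nrow(pts), -1, 1), ncol = 2) * scale * 1e-6
  )
  pj <- pts + jit
  tm <- interp::tri.mesh(pj[, 1], pj[, 2], duplicate = "error")
  tri <- interp::triangles(tm)[, 1:3, drop = FALSE]
  # enforce CCW orientation
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  s <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
  # jitter can triangulate exactly collinear runs (straight wall segments)
  # into zero-area slivers; remove them in exact coordinates
  tri <- tri[abs(s) > 1e-10 * scale^2, , drop = FALSE]
  s <- s[abs(s) > 1e-10 * scale^2]
  flip <- s < 0
  if (any(flip)) tri[flip, 2:3] <- tri[flip, 3:2]
  tri
}

tri_areas <- function(pts, tri) {
  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  ((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
}

tri_min_angles <- function(pts, tri) {
  ang <- matrix(0, nrow(tri), 3)
  for (k in 1:3) {
    a <- pts[tri[, k], , drop = FALSE]
    b <- pts[tri[, (k %% 3) + 1], , drop = FALSE]
    c <- pts[tri[, ((k + 1) %% 3) + 1], , drop = FALSE]
    u <- b - a; v <- c - a
    cosang <- rowSums(u * v) /
      (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
    ang[, k] <- acos(pmin(1, pmax(-1, cosang)))
  }
  apply(ang, 1, min) * 180 / pi
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Resample a closed polygon at spacing `h`, preserving anchor vertices
# (indices into P). Returns vertex matrix in original traversal order,
# without a repeated end vertex.
# Resample an open polyline at locally varying spacing given by hfun
# (a function of an n x 2 point matrix), keeping both endpoints. Points
# are placed greedily at the local target spacing, then positions are
# rescaled so the last point lands exactly on the endpoint.
resample_polyline_var <- function(P, hfun) {
  seg <- sqrt(rowSums(diff(P)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  at <- function(t) {
    cbind(stats::approx(s, P[, 1], xout = t)$y,
          stats::approx(s, P[, 2], xout = t)$y)
  }
  t <- 0
  ts <- 0
  repeat {
    h <- hfun(at(t))[1]
    t <- t + h
    if (t >= L - h / 2) break
    ts <- c(ts, t)
  }
  ts <- c(ts, L) / 1
  ts <- ts / max(ts) * L
  at(ts)
}

# `h` may be a number (uniform spacing) or a size function of points.
resample_closed <- function(P, h, anchors = integer(0)) {
  hfun_given <- is.function(h)
  n <- nrow(P)
  anchors <- sort(unique(anchors))
  if (length(anchors) == 0) anchors <- 1L
  # rotate so the first anchor is vertex 1
  rot <- c(anchors[1]:n, seq_len(anchors[1] - 1))
  P <- P[rot, , drop = FALSE]
  anchors <- sort((anchors - anchors[1]) %% n + 1)
  cuts <- c(anchors, n + 1L)
  out <- NULL
  for (i in seq_len(length(cuts) - 1)) {
    piece <- P[cuts[i]:min(cuts[i + 1], n), , drop = FALSE]
    if (cuts[i + 1] == n + 1L) piece <- rbind(piece, P[1, ])
    rs <- if (hfun_given) resample_polyline_var(piece, h) else
      resample_polyline(piece, h)
    out <- rbind(out, rs[-nrow(rs), , drop = FALSE])
  }
  out
}

# Hex-grid interior seeds for the region between polygons `outer` and
# `inner` (inner may be NULL), thinned to the local size `sizefun(pts)`
# (target edge length per point) with distmesh-style rejection, keeping a
# clear band of 0.65 * local size around both boundaries. Multi-level:
# grids at pitch hmax, hmax/2, hmax/4, ... down to hmin, each level
# populating the band where the local size calls for it, so strong local
# refinement (horn tips) stays affordable.
seed_interior <- function(outer, inner, sizefun, hmin, hmax = hmin,
                          focus = NULL) {
  xr <- range(outer[, 1]); yr <- range(outer[, 2])
  hex <- function(p) {
    xs <- seq(xr[1], xr[2], by = p)
    ys <- seq(yr[1], yr[2], by = p * sqrt(3) / 2)
    pts <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
    odd <- rep(seq_along(ys) %% 2 == 0, each = length(xs))
    pts[odd, 1] <- pts[odd, 1] + p / 2
    pts
  }
  levels <- hmax
  while (utils::tail(levels, 1) > hmin * 1.42) {
    levels <- c(levels, utils::tail(levels, 1) / 2)
  }
  pts_all <- NULL
  for (li in seq_along(levels)) {
    p <- levels[li] * 0.95
    pts <- hex(p)
    if (li > 1) {
      # fine levels only live near the refinement foci
      if (!is.null(focus)) {
        near <- rep(FALSE, nrow(pts))
        for (fi in seq_len(nrow(focus))) {
          near <- near |
            (pts[, 1] - focus[fi, 1])^2 + (pts[, 2] - focus[fi, 2])^2 <
              focus[fi, 3]^2
        }
        pts <- pts[near, , drop = FALSE]
      }
    }
    if (nrow(pts) == 0) next
    keep <- points_in_polygon(pts[, 1], pts[, 2], outer)
    pts <- pts[keep, , drop = FALSE]
    if (!is.null(inner) && nrow(pts) > 0) {
      keep <- !points_in_polygon(pts[, 1], pts[, 2], inner)
      pts <- pts[keep, , drop = FALSE]
    }
    if (nrow(pts) == 0) next
    h <- sizefun(pts)
    lo <- if (li == length(levels)) 0 else levels[li] / 2
    hi <- if (li == 1) Inf else levels[li]
    band <- h >= lo & h < hi
    pts <- pts[band, , drop = FALSE]; h <- h[band]
    if (nrow(pts) == 0) next
    keep <- stats::runif(nrow(pts)) < pmin(1, (levels[li] / h))^2
    pts <- pts[keep, , drop = FALSE]
    pts_all <- rbind(pts_all, pts)
  }
  if (is.null(pts_all) || nrow(pts_all) == 0) {
    return(matrix(numeric(0), 0, 2))
  }
  h <- sizefun(pts_all)
  d <- dist_to_polygon(pts_all[, 1], pts_all[, 2], outer)
  if (!is.null(inner)) {
    d <- pmin(d, dist_to_polygon(pts_all[, 1], pts_all[, 2], inner))
  }
  pts_all[d > 0.65 * h, , drop = FALSE]
}

# Mesh one annular region. boundary_idx: global indices of its boundary
# nodes (outer then inner rings, already in `nodes`). Returns list with
# updated nodes, the region's triangles (global indices), interior index
# range.
mesh_region <- function(nodes, outer_idx, inner_idx, outer_poly, inner_poly,
                        sizefun, hmin, region, smooth_iters = 3,
                        min_angle_floor = 25, hmax = hmin, focus = NULL) {
  bnd_idx <- c(outer_idx, inner_idx)
  int_pts <- with_local_seed(
    1234L + nchar(region) * 7L,
    seed_interior(outer_poly, inner_poly, sizefun, hmin, hmax = hmax,
                  focus = focus)
  )
  inside_region <- function(px, py) {
    ok <- points_in_polygon(px, py, outer_poly)
    if (!is.null(inner_poly)) {
      ok <- ok & !points_in_polygon(px, py, inner_poly)
    }
    ok
  }
  no <- length(outer_idx)
  ni <- length(inner_idx)
  ring_pairs <- function(first, n) {
    idx <- first + seq_len(n) - 1L
    cbind(idx, idx[c(2:n, 1)])
  }
  outer_pairs <- ring_pairs(1L, no)
  inner_pairs <- if (ni > 0) ring_pairs(no + 1L, ni) else NULL
  triangulate_now <- function(pts) {
    tri <- delaunay_triangles(pts)
    cx <- (pts[tri[, 1], 1] + pts[tri[, 2], 1] + pts[tri[, 3], 1]) / 3
    cy <- (pts[tri[, 1], 2] + pts[tri[, 2], 2] + pts[tri[, 3], 2]) / 3
    tri <- tri[inside_region(cx, cy), , drop = FALSE]
    # side-consistency: a triangle adjacent to a boundary segment must lie
    # on the region side of that segment (the centroid test alone can keep
    # triangles that cross a concave boundary, e.g. at the septal notch)
    cx <- (pts[tri[, 1], 1] + pts[tri[, 2], 1] + pts[tri[, 3], 1]) / 3
    cy <- (pts[tri[, 1], 2] + pts[tri[, 2], 2] + pts[tri[, 3], 2]) / 3
    tkeys <- c(edge_key(tri[, 1], tri[, 2]), edge_key(tri[, 2], tri[, 3]),
               edge_key(tri[, 3], tri[, 1]))
    tid <- rep(seq_len(nrow(tri)), 3)
    drop <- rep(FALSE, nrow(tri))
    flag_side <- function(pairs, bad_side) {
      # bad_side +1: drop triangles left of a->b; -1: drop right of a->b
      pk <- edge_key(pairs[, 1], pairs[, 2])
      hit <- tkeys %in% pk
      if (!any(hit)) return(invisible())
      m <- match(tkeys[hit], pk)
      a <- pairs[m, 1]; b <- pairs[m, 2]
      tt <- tid[hit]
      s <- (pts[b, 1] - pts[a, 1]) * (cy[tt] - pts[a, 2]) -
        (pts[b, 2] - pts[a, 2]) * (cx[tt] - pts[a, 1])
      drop[tt[sign(s) == bad_side]] <<- TRUE
    }
    # outer ring CCW: region interior on the left; inner ring CCW: hole on
    # the left
    flag_side(outer_pairs, -1)
    if (!is.null(inner_pairs)) flag_side(inner_pairs, +1)
    tri[!drop, , drop = FALSE]
  }
  bnd_pts <- nodes[bnd_idx, , drop = FALSE]
  nb <- nrow(bnd_pts)
  # smoothing sweep: move interior points to the centroid of their
  # triangulation neighbours, dropping points that stray out of the region
  # or too close to a boundary
  smooth_once <- function(int_pts) {
    pts <- rbind(bnd_pts, int_pts)
    tri <- triangulate_now(pts)
    ii <- c(tri[, 1], tri[, 2], tri[, 3], tri[, 1], tri[, 2], tri[, 3])
    jj <- c(tri[, 2], tri[, 3], tri[, 1], tri[, 3], tri[, 1], tri[, 2])
    sel <- ii > nb
    ii <- ii[sel]; jj <- jj[sel]
    sx <- rowsum(pts[jj, 1], ii)
    sy <- rowsum(pts[jj, 2], ii)
    cnt <- rowsum(rep(1, length(ii)), ii)
    who <- as.integer(rownames(sx)) - nb
    prop <- int_pts
    prop[who, 1] <- sx / cnt
    prop[who, 2] <- sy / cnt
    h <- sizefun(prop)
    d <- dist_to_polygon(prop[, 1], prop[, 2], outer_poly)
    if (!is.null(inner_poly)) {
      d <- pmin(d, dist_to_polygon(prop[, 1], prop[, 2], inner_poly))
    }
    ok <- inside_region(prop[, 1], prop[, 2]) & d > 0.55 * h
    prop[ok, , drop = FALSE]
  }
  if (nrow(int_pts) > 0) {
    for (it in seq_len(smooth_iters)) int_pts <- smooth_once(int_pts)
  }
  # quality pass: dissolve slivers by deleting the most crowded interior
  # vertex of each triangle below the angle floor, then re-smooth locally
  for (q in 1:4) {
    pts <- rbind(bnd_pts, int_pts)
    tri <- triangulate_now(pts)
    ang <- tri_min_angles(pts, tri)
    bad <- which(ang < min_angle_floor)
    if (length(bad) == 0) break
    drop <- integer(0)
    for (t in bad) {
      v <- tri[t, ]
      iv <- v[v > nb]
      if (length(iv) == 0) next
      dmin <- vapply(iv, function(a) {
        oth <- setdiff(v, a)
        min(sqrt((pts[oth, 1] - pts[a, 1])^2 +
                   (pts[oth, 2] - pts[a, 2])^2))
      }, numeric(1))
      drop <- c(drop, iv[which.min(dmin)])
    }
    if (length(drop) == 0) break
    int_pts <- int_pts[-(unique(drop) - nb), , drop = FALSE]
    int_pts <- smooth_once(int_pts)
  }
  # conformity repair: every consecutive boundary pair must be an edge
  ring_edges <- function(idx_local) {
    n <- length(idx_local)
    cbind(idx_local, idx_local[c(2:n, 1)])
  }
  required <- ring_edges(seq_len(length(outer_idx)))
  if (length(inner_idx) > 0) {
    required <- rbind(required,
                      ring_edges(length(outer_idx) +
                                   seq_len(length(inner_idx))))
  }
  for (rep_it in 1:6) {
    pts <- rbind(bnd_pts, int_pts)
    tri <- triangulate_now(pts)
    keys <- c(edge_key(tri[, 1], tri[, 2]), edge_key(tri[, 2], tri[, 3]),
              edge_key(tri[, 3], tri[, 1]))
    missing <- !(edge_key(required[, 1], required[, 2]) %in% keys)
    if (!any(missing)) break
    if (rep_it == 6) {
      stop("mesh_region: could not recover ", sum(missing),
           " boundary segment(s) in region '", region, "'")
    }
    # delete interior seeds blocking the missing segments
    bad <- required[missing, , drop = FALSE]
    drop <- rep(FALSE, nrow(int_pts))
    for (i in seq_len(nrow(bad))) {
      a <- bnd_pts[bad[i, 1], ]; b <- bnd_pts[bad[i, 2], ]
      mid <- (a + b) / 2
      rad <- sqrt(sum((a - b)^2))
      dd <- sqrt((int_pts[, 1] - mid[1])^2 + (int_pts[, 2] - mid[2])^2)
      drop <- drop | dd < rad
    }
    int_pts <- int_pts[!drop, , drop = FALSE]
  }
  n0 <- nrow(nodes)
  nodes <- rbind(nodes, int_pts)
  # map local triangulation indices to global node ids
  loc2glob <- c(bnd_idx, n0 + seq_len(nrow(int_pts)))
  tri_g <- matrix(loc2glob[tri], ncol = 3)
  list(nodes = nodes, tri = tri_g, n_interior = nrow(int_pts))
}

#' Triangulate a labelled geometry into a region-tagged mesh
#'
#' Builds a conforming triangle mesh of every tissue region (the ventricular
#' cavity is left unmeshed; it is loaded by pressure on its wall). Nodes on
#' each region interface are shared by both neighbouring regions, and the
#' named boundary sets are extracted: ventricular wall edges (a single
#' closed loop, oriented counter-clockwise around the cavity), the
#' gray/white interface, the gray/CSF interface, and the fixed outer
#' ("skull") nodes. The mesh is graded: the target edge length shrinks to
#' `refine_factor * target_edge_length` at the ventricular wall and grows
#' linearly back to `target_edge_length` at distance `refine_dist`.
#'
#' @param geometry a [make_geometry()] or [annulus_geometry()] object.
#' @param target_edge_length characteristic edge length away from the wall
#'   (mm).
#' @param refine_factor wall refinement factor in (0, 1]; 1 disables
#'   grading.
#' @param refine_dist grading distance from the cavity wall (mm).
#' @param smooth_iters Delaunay smoothing sweeps per region.
#' @param min_angle_floor triangle quality floor (degrees) targeted by the
#'   sliver-dissolving pass.
#' @return Object of class `vent_mesh`: list with `nodes` (n x 2, mm),
#'   `tri` (m x 3, counter-clockwise), `region` (character per triangle),
#'   `h`, node `origin`, `bsets` (list `wall_edges`, `gm_wm_edges`,
#'   `gm_csf_edges`, `skull_nodes`), `tips`, and `min_angle` (degrees).
#' @export
mesh_geometry <- function(geometry, target_edge_length = 2.2,
                          refine_factor = 0.35, refine_dist = 12,
                          smooth_iters = 3, min_angle_floor = 25) {
  stopifnot(inherits(geometry, "vent_geometry"))
  h0 <- target_edge_length
  stopifnot(h0 > 0, refine_factor > 0, refine_factor <= 1)
  polys <- geometry$region_polygons
  regs <- names(polys)
  if (regs[1] != "cavity" || length(regs) < 2) {
    stop("mesh_geometry: geometry must contain a cavity followed by at ",
         "least one tissue region")
  }
  cav <- polys$cavity
  # tip refinement: resolve each horn arc at about radius/5 (scaled with
  # h0 relative to the 2.2 mm reference so mesh-convergence studies
  # refine the tips too), blending back to the graded background size
  tips <- geometry$tips
  tip_r <- NULL
  if (!is.null(tips) && !is.null(geometry$horn_radii)) {
    tip_r <- ifelse(grepl("^ant", rownames(tips)),
                    geometry$horn_radii[["anterior"]],
                    geometry$horn_radii[["posterior"]])
  }
  scale_f <- h0 / 2.2
  sizefun <- function(pts) {
    h <- if (refine_factor >= 1) rep(h0, nrow(pts)) else {
      d <- dist_to_polygon(pts[, 1], pts[, 2], cav)
      pmin(h0, h0 * (refine_factor + (1 - refine_factor) * d / refine_dist))
    }
    if (!is.null(tip_r)) {
      for (i in seq_along(tip_r)) {
        di <- sqrt((pts[, 1] - tips[i, 1])^2 + (pts[, 2] - tips[i, 2])^2)
        hi <- scale_f * tip_r[i] / 5 + 0.6 * pmax(0, di - 1.5 * tip_r[i])
        h <- pmin(h, hi)
      }
    }
    h
  }
  hw <- refine_factor * h0
  hmin <- if (is.null(tip_r)) hw else
    min(hw, scale_f * min(tip_r) / 5)
  focus <- if (is.null(tip_r)) NULL else
    cbind(tips, 1.5 * tip_r + 2 * hw)
  # boundary discretizations (shared between neighbouring regions)
  anchors <- integer(0)
  if (!is.null(geometry$arcs)) {
    # keep the septal channel corners: vertices with strongly negative turn
    ta <- polygon_turn_angles(cav)
    anchors <- which(ta < -0.2)
  }
  rings <- vector("list", length(regs))
  names(rings) <- regs
  rings$cavity <- resample_closed(cav, function(p) pmin(sizefun(p), hw),
                                  anchors)
  for (r in regs[-1]) {
    # interface spacing: local size at the polygon
    P <- polys[[r]]
    hloc <- stats::median(sizefun(P))
    rings[[r]] <- resample_closed(P, hloc)
  }
  # global node table: boundary rings first, in region order
  nodes <- NULL
  origin <- character(0)
  ring_idx <- list()
  ring_names <- c("wall", paste0("iface_", regs[-1]))
  for (i in seq_along(regs)) {
    ring <- rings[[regs[i]]]
    n0 <- if (is.null(nodes)) 0L else nrow(nodes)
    ring_idx[[ring_names[i]]] <- n0 + seq_len(nrow(ring))
    nodes <- rbind(nodes, ring)
    origin <- c(origin, rep(ring_names[i], nrow(ring)))
  }
  tri <- NULL
  region_tag <- character(0)
  for (i in seq_along(regs[-1])) {
    r <- regs[i + 1]
    inner_r <- regs[i]
    res <- mesh_region(
      nodes,
      outer_idx = ring_idx[[ring_names[i + 1]]],
      inner_idx = ring_idx[[ring_names[i]]],
      outer_poly = polys[[r]],
      inner_poly = polys[[inner_r]],
      sizefun = sizefun,
      hmin = hmin,
      hmax = hw,
      focus = if (r == regs[2]) focus else NULL,
      region = r,
      smooth_iters = smooth_iters,
      min_angle_floor = min_angle_floor
    )
    origin <- c(origin, rep(paste0("int_", r), res$n_interior))
    nodes <- res$nodes
    tri <- rbind(tri, res$tri)
    region_tag <- c(region_tag, rep(r, nrow(res$tri)))
  }
  if (any(tri_areas(nodes, tri) <= 0)) {
    stop("mesh_geometry: non-positive triangle produced")
  }
  ring_edges <- function(idx) cbind(idx, idx[c(2:length(idx), 1)])
  bsets <- list(wall_edges = ring_edges(ring_idx$wall))
  if (all(c("white_matter", "gray_matter", "csf") %in% regs)) {
    bsets$gm_wm_edges <- ring_edges(ring_idx$iface_white_matter)
    bsets$gm_csf_edges <- ring_edges(ring_idx$iface_gray_matter)
    bsets$skull_nodes <- ring_idx$iface_csf
  } else {
    # generic nested geometry: outermost ring is the fixed boundary
    bsets$skull_nodes <- ring_idx[[ring_names[length(ring_names)]]]
  }
  mesh <- list(
    nodes = nodes,
    tri = tri,
    region = region_tag,
    h = h0,
    origin = origin,
    bsets = bsets,
    tips = geometry$tips,
    min_angle = min(tri_min_angles(nodes, tri))
  )
  class(mesh) <- "vent_mesh"
  validate_mesh(mesh)
  mesh
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structural checks: interface edge symmetry, wall edge adjacency.
validate_mesh <- function(mesh) {
  tri <- mesh$tri
  keys <- c(edge_key(tri[, 1], tri[, 2]), edge_key(tri[, 2], tri[, 3]),
            edge_key(tri[, 3], tri[, 1]))
  tri_of_edge <- rep(seq_len(nrow(tri)), 3)
  adj <- split(tri_of_edge, keys)
  check_edges <- function(E, want_regions) {
    k <- edge_key(E[, 1], E[, 2])
    for (i in seq_along(k)) {
      t_adj <- adj[[k[i]]]
      if (is.null(t_adj)) {
        stop("mesh: boundary edge ", k[i], " missing from triangulation")
      }
      got <- sort(mesh$region[t_adj])
      if (!identical(got, sort(want_regions))) {
        stop("mesh: edge ", k[i], " adjacent to regions [",
             paste(got, collapse = ", "), "], expected [",
             paste(want_regions, collapse = ", "), "]")
      }
    }
    invisible(TRUE)
  }
  first_region <- unique(mesh$region)[1]
  check_edges(mesh$bsets$wall_edges, first_region)
  if (!is.null(mesh$bsets$gm_wm_edges)) {
    check_edges(mesh$bsets$gm_wm_edges, c("white_matter", "gray_matter"))
    check_edges(mesh$bsets$gm_csf_edges, c("gray_matter", "csf"))
  }
  invisible(mesh)
}

#' @export
print.vent_mesh <- function(x, ...) {
  cat("<vent_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$tri),
      " triangles\n", sep = "")
  tab <- table(x$region)
  for (r in names(tab)) cat(sprintf("  %-13s %6d triangles\n", r, tab[[r]]))
  cat(sprintf("  target h %.2f mm, min angle %.1f deg, wall edges %d\n",
              x$h, x$min_angle, nrow(x$bsets$wall_edges)))
  invisible(x)
}

#' Order the ventricular wall into a closed counter-clockwise path
#'
#' Chains the wall edges into a single closed loop, orients it
#' counter-clockwise with respect to the cavity interior (positive signed
#' area), and starts the traversal at the wall node nearest the midpoint
#' between the two posterior horn tips (ties broken towards smaller x, then
#' smaller y). Arclength is accumulated on reference coordinates.
#'
#' @param mesh a [mesh_geometry()] mesh.
#' @param bsets boundary sets; defaults to `mesh$bsets`.
#' @return Object of class `wall_path`: list with `nodes` (ordered global
#'   node indices), `arclength` (cumulative, mm, starting at 0), and
#'   `total_length` (mm).
#' @export
order_wall <- function(mesh, bsets = mesh$bsets) {
  E <- bsets$wall_edges
  nb <- sort(unique(as.vector(E)))
  adjl <- list()
  for (i in seq_len(nrow(E))) {
    a <- as.character(E[i, 1]); b <- as.character(E[i, 2])
    adjl[[a]] <- c(adjl[[a]], E[i, 2])
    adjl[[b]] <- c(adjl[[b]], E[i, 1])
  }
  deg <- vapply(adjl, length, integer(1))
  if (any(deg != 2)) {
    stop("order_wall: wall edges do not form a closed loop (",
         sum(deg != 2), " node(s) with degree != 2)")
  }
  loop <- integer(length(nb))
  loop[1] <- nb[1]
  loop[2] <- adjl[[as.character(nb[1])]][1]
  for (i in 3:length(nb)) {
    nxt <- adjl[[as.character(loop[i - 1])]]
    loop[i] <- nxt[nxt != loop[i - 2]][1]
  }
  if (length(unique(loop)) != length(nb)) {
    n_loops <- length(nb) - length(unique(loop)) + 1
    stop("order_wall: wall edges form more than one loop (about ",
         n_loops, ")")
  }
  P <- mesh$nodes[loop, , drop = FALSE]
  if (polygon_area(P) < 0) {
    loop <- rev(loop)
    P <- P[rev(seq_len(nrow(P))), , drop = FALSE]
  }
  # start node: nearest to the midpoint between the posterior horn tips
  target <- if (!is.null(mesh$tips)) {
    post <- mesh$tips[grepl("^post", rownames(mesh$tips)), , drop = FALSE]
    colMeans(post)
  } else {
    c(mean(range(P[, 1])), min(P[, 2]))
  }
  d <- (P[, 1] - target[1])^2 + (P[, 2] - target[2])^2
  cand <- which(d < min(d) + 1e-9)
  cand <- cand[order(P[cand, 1], P[cand, 2])]
  k <- cand[1]
  loop <- c(loop[k:length(loop)], loop[seq_len(k - 1)])
  P <- mesh$nodes[loop, , drop = FALSE]
  seg <- sqrt(rowSums((P[c(2:nrow(P), 1), ] - P)^2))
  out <- list(
    nodes = loop,
    arclength = c(0, cumsum(seg))[seq_len(nrow(P))],
    total_length = sum(seg)
  )
  class(out) <- "wall_path"
  out
}

#' Structured two-region rectangle mesh for verification
#'
#' A `nx` by `ny` crossed-triangle rectangle `[0, L] x [0, H]` split into
#' two material regions at `x = L/2` (used by the patch test). Edge sets
#' `left`, `right`, `top`, `bottom` are oriented so that a follower
#' pressure applied to them pushes into the rectangle.
#'
#' @param L,H rectangle size (mm).
#' @param nx,ny element divisions per direction.
#' @return A `vent_mesh` with regions `white_matter` (x < L/2) and
#'   `gray_matter`, plus `edge_sets` with the four sides and node index
#'   vectors `left_nodes`, `right_nodes`, `top_nodes`, `bottom_nodes`.
#' @export
mesh_rectangle <- function(L = 10, H = 6, nx = 10, ny = 6) {
  xs <- seq(0, L, length.out = nx + 1)
  ys <- seq(0, H, length.out = ny + 1)
  nid <- function(i, j) (j - 1) * (nx + 1) + i
  nodes <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
  tri <- NULL
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- nid(i, j); b <- nid(i + 1, j)
    c <- nid(i + 1, j + 1); d <- nid(i, j + 1)
    tri <- rbind(tri, c(a, b, c), c(a, c, d))
  }
  cx <- (nodes[tri[, 1], 1] + nodes[tri[, 2], 1] + nodes[tri[, 3], 1]) / 3
  region <- ifelse(cx < L / 2, "white_matter", "gray_matter")
  side_edges <- function(idx) cbind(idx[-length(idx)], idx[-1])
  bottom <- nid(seq_len(nx + 1), 1)
  top <- nid(seq_len(nx + 1), ny + 1)
  left <- nid(1, seq_len(ny + 1))
  right <- nid(nx + 1, seq_len(ny + 1))
  mesh <- list(
    nodes = nodes, tri = tri, region = region,
    h = max(L / nx, H / ny),
    origin = rep("grid", nrow(nodes)),
    bsets = list(),
    edge_sets = list(
      # oriented so the pushed-on fluid sits on the left of each edge:
      bottom = side_edges(bottom),           # pushes +y (up, inward)
      right = side_edges(rev(right)),        # pushes -x (inward)
      top = side_edges(rev(top)),            # pushes -y (inward)
      left = side_edges(left)                # pushes +x (inward)
    ),
    left_nodes = left, right_nodes = right,
    top_nodes = top, bottom_nodes = bottom,
    tips = NULL,
    min_angle = NA_real_
  )
  class(mesh) <- "vent_mesh"
  mesh
}
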