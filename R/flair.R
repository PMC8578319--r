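# Synthetic FLAIR-like images: rasterized region labels, planted bright
# white-matter lesions, a septum-like bright structure surrounded by
# ventricular CSF (to exercise the CSF-adjacency pruning rule), and
# Gaussian background noise.

#' Rasterize a labelled geometry into a 2D label image
#'
#' Pixel labels: 0 background (outside the model), 1 CSF (subarachnoid
#' layer and ventricular cavity), 2 white matter, 3 gray matter. The
#' image is stored as a matrix indexed `[ix, iy]` with pixel-centre
#' coordinates `origin + (index - 1) * pixel_size`.
#'
#' @param geometry a [make_geometry()] object.
#' @param pixel_size pixel edge (mm).
#' @param margin extra border around the outermost region (mm).
#' @return list with `labels` (integer matrix), `origin`, `pixel_size`.
#' @export
rasterize_labels <- function(geometry, pixel_size = 0.7, margin = 2) {
  polys <- geometry$region_polygons
  outer <- polys[[length(polys)]]
  xr <- range(outer[, 1]) + c(-margin, margin)
  yr <- range(outer[, 2]) + c(-margin, margin)
  xs <- seq(xr[1], xr[2], by = pixel_size)
  ys <- seq(yr[1], yr[2], by = pixel_size)
  nx <- length(xs); ny <- length(ys)
  px <- rep(xs, times = ny); py <- rep(ys, each = nx)
  lab <- integer(nx * ny)
  paint <- function(lab, poly, value) {
    ifelse(points_in_polygon(px, py, poly), value, lab)
  }
  if (!is.null(polys$csf)) lab <- paint(lab, polys$csf, 1L)
  if (!is.null(polys$gray_matter)) lab <- paint(lab, polys$gray_matter, 3L)
  if (!is.null(polys$white_matter)) lab <- paint(lab, polys$white_matter, 2L)
  lab <- paint(lab, polys$cavity, 1L)      # ventricular CSF
  list(labels = matrix(lab, nx, ny), origin = c(xs[1], ys[1]),
       pixel_size = pixel_size)
}

#' Generate a synthetic FLAIR-like image with planted lesions
#'
#' White and gray matter take unit background intensity, CSF a distinct
#' low intensity, and lesions (disks of `lesion_radius` around
#' `lesion_centers`, clipped to white matter) the elevated intensity
#' `1 + contrast`. A septum-like bright strip is placed across the septal
#' channel: it is labelled as brain tissue (so it enters the segmentation
#' mask) but is bordered almost everywhere by ventricular CSF, exercising
#' the >50 percent CSF-adjacency pruning rule. Gaussian noise of standard
#' deviation `noise_sd` (relative to the unit background) is added to all
#' tissue and CSF pixels; images are reproducible under a fixed seed.
#'
#' @param geometry a [make_geometry()] object (butterfly subject).
#' @param lesion_centers matrix of lesion centres (mm); default: one
#'   periventricular cap per horn, centred half a `lesion_radius`
#'   outward of the tip apex so the cap straddles the ventricular wall
#'   (the part inside the cavity is clipped away).
#' @param lesion_radius lesion disk radius (mm).
#' @param contrast lesion excess intensity (dimensionless, > 0).
#' @param noise_sd Gaussian noise standard deviation (dimensionless).
#' @param seed integer; defaults to the generating spec's seed.
#' @param pixel_size pixel edge (mm).
#' @param septum add the CSF-adjacent septum surrogate (default TRUE).
#' @return Object of class `synthetic_flair`: list with `intensity`,
#'   `labels`, `truth` (logical lesion mask), `origin`, `pixel_size`,
#'   `lesion_centers`.
#' @export
make_flair <- function(geometry, lesion_centers = NULL, lesion_radius = 3.5,
                       contrast = 0.6, noise_sd = 0.08, seed = NULL,
                       pixel_size = 0.7, septum = TRUE) {
  stopifnot(inherits(geometry, "vent_geometry"))
  if (contrast <= 0) stop("make_flair: contrast must be > 0")
  if (noise_sd < 0) stop("make_flair: noise_sd must be >= 0")
  if (is.null(seed)) {
    seed <- if (!is.null(geometry$spec)) geometry$spec$seed else 1L
  }
  ras <- rasterize_labels(geometry, pixel_size)
  lab <- ras$labels
  nx <- nrow(lab); ny <- ncol(lab)
  xs <- ras$origin[1] + (seq_len(nx) - 1) * pixel_size
  ys <- ras$origin[2] + (seq_len(ny) - 1) * pixel_size
  px <- rep(xs, times = ny); py <- rep(ys, each = nx)
  if (is.null(lesion_centers)) {
    tips <- geometry$tips
    if (is.null(tips)) stop("make_flair: no tips; supply lesion_centers")
    u <- tips / sqrt(rowSums(tips^2))
    lesion_centers <- tips + u * (lesion_radius / 2)
  }
  wm <- lab == 2L
  truth <- matrix(FALSE, nx, ny)
  for (i in seq_len(nrow(lesion_centers))) {
    cx <- lesion_centers[i, 1]; cy <- lesion_centers[i, 2]
    if (!points_in_polygon(cx, cy, geometry$region_polygons$white_matter) ||
          points_in_polygon(cx, cy, geometry$region_polygons$cavity)) {
      stop("make_flair: lesion centre (", round(cx, 1), ", ", round(cy, 1),
           ") is not inside white matter")
    }
    disk <- (px - cx)^2 + (py - cy)^2 <= lesion_radius^2
    truth <- truth | (matrix(disk, nx, ny) & wm)
  }
  img <- matrix(0, nx, ny)
  img[lab == 2L | lab == 3L] <- 1
  img[lab == 1L] <- 0.25
  img[truth] <- 1 + contrast
  if (septum && !is.null(geometry$spec)) {
    g2 <- geometry$spec$septum_gap / 2
    strip <- abs(px) <= max(pixel_size, 0.7) &
      abs(py) <= g2 + pixel_size / 2
    strip <- matrix(strip, nx, ny) & lab == 1L
    lab[strip] <- 2L          # septum counts as brain tissue in the mask
    img[strip] <- 1 + contrast
  }
  if (noise_sd > 0) {
    with_local_seed(seed, {
      noise <- matrix(stats::rnorm(nx * ny, sd = noise_sd), nx, ny)
      img[lab > 0L] <- img[lab > 0L] + noise[lab > 0L]
    })
  }
  out <- list(intensity = img, labels = lab, truth = truth,
              origin = ras$origin, pixel_size = pixel_size,
              lesion_centers = lesion_centers)
  class(out) <- "synthetic_flair"
  out
}

#' @export
print.synthetic_flair <- function(x, ...) {
  cat("<synthetic_flair> ", nrow(x$intensity), " x ", ncol(x$intensity),
      " pixels (", x$pixel_size, " mm), ",
      sum(x$truth), " truth lesion pixels\n", sep = "")
  invisible(x)
}
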