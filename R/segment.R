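# Automatic WMH segmentation: global intensity threshold inside the brain
# mask, then removal of connected components whose boundary is mostly
# adjacent to CSF (septum / choroid plexus surrogates).

#' Threshold a FLAIR image inside the brain mask
#'
#' Segments all pixels \eqn{v \in \Omega} with \eqn{s(v) > \mu + k\sigma}
#' where \eqn{\mu} and \eqn{\sigma} are the mean and standard deviation of
#' the intensity distribution in the brain mask \eqn{\Omega}. The strict
#' inequality means a constant image (\eqn{\sigma = 0}) yields an empty
#' mask. The population convention (denominator N) is the default for
#' \eqn{\sigma}.
#'
#' @param image numeric intensity matrix.
#' @param omega logical brain mask (same shape).
#' @param k threshold multiplier (default 2.5).
#' @param sd_type `"population"` (1/N, default) or `"sample"` (1/(N-1)).
#' @return list with `mask` (logical), `mu`, `sigma`, `threshold`.
#' @export
threshold_mask <- function(image, omega, k = 2.5,
                           sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(identical(dim(image), dim(omega)))
  vals <- image[omega]
  if (length(vals) == 0) stop("threshold_mask: empty brain mask")
  mu <- mean(vals)
  n <- length(vals)
  sigma <- if (sd_type == "population") {
    sqrt(sum((vals - mu)^2) / n)
  } else {
    stats::sd(vals)
  }
  thr <- mu + k * sigma
  list(mask = omega & (image > thr), mu = mu, sigma = sigma,
       threshold = thr)
}

# Connected-component labelling of a logical mask (two-pass union-find).
# connectivity 4 (face adjacency, default) or 8.
label_components <- function(mask, connectivity = 4) {
  stopifnot(connectivity %in% c(4, 8))
  nx <- nrow(mask); ny <- ncol(mask)
  lab <- matrix(0L, nx, ny)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]   # path compression
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      if (!mask[i, j]) next
      nb <- integer(0)
      if (i > 1 && mask[i - 1, j]) nb <- c(nb, lab[i - 1, j])
      if (j > 1 && mask[i, j - 1]) nb <- c(nb, lab[i, j - 1])
      if (connectivity == 8) {
        if (i > 1 && j > 1 && mask[i - 1, j - 1]) {
          nb <- c(nb, lab[i - 1, j - 1])
        }
        if (i < nx && j > 1 && mask[i + 1, j - 1]) {
          nb <- c(nb, lab[i + 1, j - 1])
        }
      }
      if (length(nb) == 0) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else {
        m <- min(nb)
        lab[i, j] <- m
        for (o in nb) {
          ra <- find(o); rb <- find(m)
          if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
        }
      }
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  pos <- which(lab > 0L)
  lab[pos] <- remap[lab[pos]]
  lab
}

#' Prune connected components with majority-CSF boundary
#'
#' Finds connected components of the thresholded mask (4-connectivity by
#' default), takes each component's boundary as the set of face-adjacent
#' exterior pixels, and removes the component if more than half of those
#' boundary pixels carry the CSF label -- the septum and choroid plexus
#' surrogates, which are bright but surrounded by ventricular CSF.
#'
#' @param mask logical mask from [threshold_mask()].
#' @param csf logical CSF mask (same shape).
#' @param connectivity 4 (default) or 8, used for the components; the
#'   boundary is always face adjacency.
#' @return list with `mask` (pruned), `components` (data.frame: id, size,
#'   boundary, csf_boundary, removed).
#' @export
prune_csf_adjacent <- function(mask, csf, connectivity = 4) {
  stopifnot(identical(dim(mask), dim(csf)))
  lab <- label_components(mask, connectivity)
  ncomp <- max(lab)
  if (ncomp == 0L) {
    return(list(mask = mask,
                components = data.frame(id = integer(0), size = integer(0),
                                        boundary = integer(0),
                                        csf_boundary = integer(0),
                                        removed = logical(0))))
  }
  nx <- nrow(mask); ny <- ncol(mask)
  # face-adjacent exterior pixels per component: shift the labels in the
  # four directions and collect exterior hits
  shift <- function(m, di, dj) {
    out <- matrix(0L, nx, ny)
    si <- seq_len(nx) - di; sj <- seq_len(ny) - dj
    oki <- si >= 1 & si <= nx; okj <- sj >= 1 & sj <= ny
    out[oki, okj] <- m[si[oki], sj[okj]]
    out
  }
  bnd <- numeric(ncomp); bnd_csf <- numeric(ncomp)
  # a boundary PIXEL may touch the same component on several faces; count
  # pixels once per component via a per-direction union
  ext_id <- array(0L, c(nx, ny, 4))
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (d in seq_along(dirs)) {
    ext_id[, , d] <- shift(lab, dirs[[d]][1], dirs[[d]][2]) *
      (!mask)          # exterior pixels only
  }
  for (cid in seq_len(ncomp)) {
    touch <- (ext_id[, , 1] == cid) | (ext_id[, , 2] == cid) |
      (ext_id[, , 3] == cid) | (ext_id[, , 4] == cid)
    bnd[cid] <- sum(touch)
    bnd_csf[cid] <- sum(touch & csf)
  }
  removed <- bnd > 0 & (bnd_csf / pmax(bnd, 1)) > 0.5
  out_mask <- mask & !(matrix(removed[pmax(lab, 1)], nx, ny) & lab > 0L)
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  list(mask = out_mask,
       components = data.frame(id = seq_len(ncomp), size = sizes,
                               boundary = as.integer(bnd),
                               csf_boundary = as.integer(bnd_csf),
                               removed = removed))
}

#' Segment white matter hyperintensities
#'
#' Pipeline composition: the brain mask \eqn{\Omega} is the union of the
#' white and gray matter labels, the image is thresholded at
#' \eqn{\mu + k\sigma} over \eqn{\Omega}, and components with majority-CSF
#' boundary are pruned.
#'
#' @param image intensity matrix (e.g. `$intensity` of [make_flair()]).
#' @param label_image integer label matrix (0 background, 1 CSF, 2 white
#'   matter, 3 gray matter).
#' @param k threshold multiplier.
#' @param connectivity component connectivity (4 or 8).
#' @param sd_type passed to [threshold_mask()].
#' @return Object of class `wmh_segmentation`: list with `mask` (final),
#'   `raw_mask`, `omega`, `mu`, `sigma`, `threshold`, `components`.
#' @export
segment_wmh <- function(image, label_image, k = 2.5, connectivity = 4,
                        sd_type = "population") {
  stopifnot(identical(dim(image), dim(label_image)))
  omega <- label_image == 2L | label_image == 3L
  if (!any(omega)) stop("segment_wmh: empty brain mask")
  th <- threshold_mask(image, omega, k, sd_type)
  pr <- prune_csf_adjacent(th$mask, label_image == 1L, connectivity)
  out <- list(mask = pr$mask, raw_mask = th$mask, omega = omega,
              mu = th$mu, sigma = th$sigma, threshold = th$threshold,
              components = pr$components)
  class(out) <- "wmh_segmentation"
  out
}

#' @export
print.wmh_segmentation <- function(x, ...) {
  cat("<wmh_segmentation> threshold ", signif(x$threshold, 4),
      " (mu ", signif(x$mu, 4), ", sigma ", signif(x$sigma, 4), ")\n",
      "  ", sum(x$raw_mask), " raw pixels in ", nrow(x$components),
      " component(s); ", sum(x$components$removed),
      " pruned (CSF-adjacent); ", sum(x$mask), " final pixels\n",
      sep = "")
  invisible(x)
}

#' Dice overlap of two masks
#'
#' @param a,b logical matrices.
#' @return `2|a & b| / (|a| + |b|)`; 1 when both are empty.
#' @export
dice <- function(a, b) {
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
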