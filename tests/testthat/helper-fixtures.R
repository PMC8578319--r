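# Shared fixtures, memoized so expensive solves run once per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

default_subject_run <- function() {
  fixture("default_run", run_subject(run_config()))
}

annulus_case <- function() {
  fixture("annulus", {
    a <- 10; b <- 30
    mesh <- mesh_geometry(annulus_geometry(a, b), 1.5, refine_factor = 1)
    list(a = a, b = b, mesh = mesh, wall = order_wall(mesh))
  })
}

# small deterministic FLAIR bundle at high contrast / low noise
clean_flair_case <- function() {
  fixture("clean_flair", {
    g <- make_geometry(subject_spec())
    list(geometry = g,
         flair = make_flair(g, contrast = 0.8, noise_sd = 0.03))
  })
}

# brute-force flood-fill + boundary-count segmentation pruning oracle
prune_oracle <- function(mask, csf) {
  nx <- nrow(mask); ny <- ncol(mask)
  seen <- matrix(FALSE, nx, ny)
  out <- mask
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!mask[i, j] || seen[i, j]) next
    comp <- matrix(FALSE, nx, ny)
    stack <- list(c(i, j))
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > nx || p[2] < 1 || p[2] > ny) next
      if (comp[p[1], p[2]] || !mask[p[1], p[2]]) next
      comp[p[1], p[2]] <- TRUE
      stack <- c(stack, list(p + c(1, 0), p + c(-1, 0),
                             p + c(0, 1), p + c(0, -1)))
    }
    seen <- seen | comp
    # boundary: exterior pixels face-adjacent to the component
    bnd <- matrix(FALSE, nx, ny)
    for (jj in seq_len(ny)) for (ii in seq_len(nx)) {
      if (!comp[ii, jj]) next
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- c(ii, jj) + d
        if (q[1] >= 1 && q[1] <= nx && q[2] >= 1 && q[2] <= ny &&
              !mask[q[1], q[2]]) {
          bnd[q[1], q[2]] <- TRUE
        }
      }
    }
    if (sum(bnd) > 0 && sum(bnd & csf) / sum(bnd) > 0.5) {
      out <- out & !comp
    }
  }
  out
}

# brute-force statistics oracles (plain formula evaluations)
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(r = r, p = p)
}

ols_oracle <- function(x, y) {
  a <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b <- mean(y) - a * mean(x)
  yhat <- a * x + b
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(a = a, b = b, r_squared = r2)
}

welch_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df = df)
  list(t = t, df = df, p = p)
}
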