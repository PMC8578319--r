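# Statistics layer: the embedded subject table, Pearson correlations,
# linear and reciprocal least-squares fits, equidistant wall sampling and
# the Welch two-sample test comparing stretch at lesion-positive versus
# lesion-negative wall points.

#' Subject table: age, CSF/LV/WMH volumes and Fazekas score
#'
#' The eight cognitively normal reference subjects (male and female at the
#' 20th/40th/60th/80th percentile of total intracranial CSF volume):
#' subject id, sex, age (years), CSF volume `vCSF` (cm^3), lateral
#' ventricle volume `vLV` (cm^3), white matter hyperintensity volume
#' `vWMH` (cm^3), and periventricular Fazekas score `FS` (0-3).
#'
#' @return data.frame with 8 rows.
#' @export
table1_fixture <- function() {
  data.frame(
    id = c("F20", "F40", "F60", "F80", "M20", "M40", "M60", "M80"),
    sex = rep(c("F", "M"), each = 4),
    age = c(65.1, 68.5, 75.3, 77.6, 68.5, 81.1, 79.9, 71.4),
    vCSF = c(421.0, 473.0, 519.0, 579.0, 451.0, 493.0, 519.0, 581.0),
    vLV = c(30.2, 34.2, 40.1, 74.1, 33.4, 35.3, 56.9, 61.4),
    vWMH = c(1.1, 5.2, 4.0, 20.7, 6.2, 7.8, 7.0, 16.4),
    FS = c(0L, 1L, 1L, 3L, 1L, 2L, 1L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson correlation with the usual t-based two-sided p-value,
#' \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on \eqn{n-2} degrees of freedom
#' (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-constant.
#' @return list with `r`, `p`, `n`, `df`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("pearson_test: need equal lengths >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_test: zero variance")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}

fit_metrics <- function(fit, y) {
  yhat <- stats::fitted(fit)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  list(coef = stats::coef(fit), r_squared = r2)
}

#' Linear least-squares fit y = a x + b
#'
#' Ordinary least squares with intercept via [stats::lm()], reporting the
#' coefficients, R^2, and the Pearson correlation of the raw pair.
#'
#' @param x,y numeric vectors.
#' @return Object of class `vent_fit`: list with `model` ("linear"),
#'   `a` (slope), `b` (intercept), `r_squared`, `rho`, `p`.
#' @export
fit_linear <- function(x, y) {
  if (length(unique(x)) < 2) stop("fit_linear: degenerate design")
  fit <- stats::lm(y ~ x)
  fm <- fit_metrics(fit, y)
  ct <- if (stats::sd(y) > 0) pearson_test(x, y) else
    list(r = NA_real_, p = NA_real_)
  out <- list(model = "linear", a = unname(fm$coef[2]),
              b = unname(fm$coef[1]), r_squared = fm$r_squared,
              rho = ct$r, p = ct$p, fit = fit)
  class(out) <- "vent_fit"
  out
}

#' Reciprocal least-squares fit y = a / x + b
#'
#' Ordinary least squares on the transformed regressor 1/x (all x > 0),
#' with R^2 reported on the original scale. This is the model form used
#' for peak cell stretch as a function of horn radius.
#'
#' @param x numeric vector of radii (> 0).
#' @param y numeric response.
#' @return Object of class `vent_fit` with `model = "reciprocal"`,
#'   `a`, `b`, `r_squared`, `rho` (Pearson of y vs 1/x), `p`.
#' @export
fit_reciprocal <- function(x, y) {
  if (any(x <= 0)) stop("fit_reciprocal: radii must be positive")
  if (length(unique(x)) < 2) stop("fit_reciprocal: degenerate design")
  xi <- 1 / x
  fit <- stats::lm(y ~ xi)
  fm <- fit_metrics(fit, y)
  ct <- if (stats::sd(y) > 0) pearson_test(xi, y) else
    list(r = NA_real_, p = NA_real_)
  out <- list(model = "reciprocal", a = unname(fm$coef[2]),
              b = unname(fm$coef[1]), r_squared = fm$r_squared,
              rho = ct$r, p = ct$p, fit = fit)
  class(out) <- "vent_fit"
  out
}

#' @export
print.vent_fit <- function(x, ...) {
  form <- if (x$model == "linear") "y = a*x + b" else "y = a/x + b"
  cat("<vent_fit> ", form, ": a = ", signif(x$a, 4), ", b = ",
      signif(x$b, 4), ", R^2 = ", signif(x$r_squared, 3), "\n", sep = "")
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom
#' (via [stats::t.test()]); the pooled-variance test is not used because
#' the wall-sampling comparison has strongly unbalanced groups.
#'
#' @param a,b numeric vectors (length >= 2 each).
#' @return list with `t`, `df` (unrounded), `df_floor`, `p`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`.
#' @export
welch_ttest <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("welch_ttest: both groups need >= 2 observations")
  }
  eps <- 1e-12 * max(1, abs(mean(a)), abs(mean(b)))
  if (stats::sd(a) <= eps && stats::sd(b) <= eps) {
    if (abs(mean(a) - mean(b)) <= eps) {
      return(list(t = 0, df = length(a) + length(b) - 2,
                  df_floor = length(a) + length(b) - 2, p = 1,
                  n_a = length(a), n_b = length(b),
                  mean_a = mean(a), mean_b = mean(b)))
    }
    stop("welch_ttest: degenerate (zero variance in both groups)")
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       df_floor = floor(unname(tt$parameter)), p = tt$p.value,
       n_a = length(a), n_b = length(b),
       mean_a = mean(a), mean_b = mean(b))
}

#' Sample the wall profile at equidistant points
#'
#' Takes `n_points` points equally spaced in arclength along the closed
#' wall, starting at the wall-path origin (the posterior midline), with
#' \eqn{\lambda_t} linearly interpolated between wall nodes. Each point is
#' labelled lesion-positive when its nearest wall node abuts a segmented
#' lesion component (see [wall_lesion_labels()]).
#'
#' @param profile a [project_wall_stretches()] profile.
#' @param positive logical per wall node (lesion adjacency labels).
#' @param n_points number of equidistant samples (default 30).
#' @return data.frame with `arclength`, `lambda_t`, `positive`.
#' @export
sample_wall_points <- function(profile, positive, n_points = 30) {
  L <- attr(profile, "total_length")
  k <- nrow(profile)
  stopifnot(length(positive) == k)
  s_nodes <- c(profile$arclength, L)
  lt <- c(profile$lambda_t, profile$lambda_t[1])
  s <- (seq_len(n_points) - 1) * L / n_points
  lam <- stats::approx(s_nodes, lt, xout = s)$y
  # nearest node on the circle
  near <- vapply(s, function(si) {
    d <- abs(profile$arclength - si)
    which.min(pmin(d, L - d))
  }, integer(1))
  data.frame(arclength = s, lambda_t = lam,
             positive = positive[near])
}

#' Label wall nodes by lesion adjacency
#'
#' A wall node is lesion-positive when the centre of a segmented lesion
#' pixel lies within `dist_mm` of the node (default 1.5 mm, about two
#' pixels), i.e. the node abuts a lesion component of the final mask.
#'
#' @param profile a [project_wall_stretches()] profile.
#' @param seg a [segment_wmh()] result.
#' @param flair the [make_flair()] image the segmentation ran on (for the
#'   pixel grid).
#' @param dist_mm adjacency distance (mm).
#' @return logical vector per ordered wall node.
#' @export
wall_lesion_labels <- function(profile, seg, flair, dist_mm = 1.5) {
  idx <- which(seg$mask)
  if (length(idx) == 0) return(rep(FALSE, nrow(profile)))
  nx <- nrow(seg$mask)
  ix <- (idx - 1) %% nx + 1
  iy <- (idx - 1) %/% nx + 1
  lx <- flair$origin[1] + (ix - 1) * flair$pixel_size
  ly <- flair$origin[2] + (iy - 1) * flair$pixel_size
  vapply(seq_len(nrow(profile)), function(i) {
    any((lx - profile$x[i])^2 + (ly - profile$y[i])^2 <= dist_mm^2)
  }, logical(1))
}

#' Summary statistics of the subject table
#'
#' Means, sample standard deviations (1/(n-1)) and ranges of the volume
#' and age columns, plus male/female WMH subgroup means and their ratio.
#'
#' @param table a [table1_fixture()]-shaped data.frame.
#' @return list of summaries.
#' @export
summarize_table1 <- function(table = table1_fixture()) {
  col <- function(v) {
    list(mean = mean(table[[v]]), sd = stats::sd(table[[v]]),
         range = range(table[[v]]))
  }
  male <- table$vWMH[table$sex == "M"]
  female <- table$vWMH[table$sex == "F"]
  list(
    n = nrow(table),
    age = col("age"), vCSF = col("vCSF"), vLV = col("vLV"),
    vWMH = col("vWMH"),
    vWMH_male_mean = mean(male), vWMH_female_mean = mean(female),
    vWMH_male_female_ratio = mean(male) / mean(female),
    cor_vLV_FS = pearson_test(table$vLV, table$FS),
    cor_vWMH_FS = pearson_test(table$vWMH, table$FS)
  )
}
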