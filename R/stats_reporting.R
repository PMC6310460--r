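# Statistical layer: autocorrelation-based frame decimation, pooled-variance
# two-sample t-tests, Gaussian fits of dihedral histograms, and normalized
# conformational heat maps.

#' Autocorrelation function and decorrelated frame extraction
#'
#' Computes the mean-removed, normalized autocovariance of a descriptor
#' series, estimates a decimation stride N from it, and extracts an
#' (approximately) independent subsample: frames spaced at least N apart,
#' restricted to `mask` when given (e.g. frames with at least one bound
#' monovalent cation).
#'
#' Two stride criteria are available. `"1/e"` (default) takes the smallest
#' lag at which the ACF drops below 1/e, which for an AR(1) process with
#' persistence phi equals ceil(-1/log(phi)). `"integrated"` uses the
#' integrated autocorrelation time 1 + 2*sum(ACF) summed to the first
#' non-positive lag.
#'
#' @param series numeric vector.
#' @param mask optional logical vector (same length): frames eligible for the
#'   extracted sample.
#' @param criterion `"1/e"` or `"integrated"`.
#' @param lag_max maximal lag for the ACF (default `min(n - 1, 10 * sqrt(n))`).
#' @return object of class `decorrelation_result`: `acf` (lag 0..lag_max),
#'   `stride`, `indices` of the extracted frames, `sample` values.
#' @export
autocorr_decimate <- function(series, mask = NULL,
                              criterion = c("1/e", "integrated"),
                              lag_max = NULL) {
  criterion <- match.arg(criterion)
  n <- length(series)
  if (n < 2L) stop("series too short for an ACF", call. = FALSE)
  if (stats::sd(series) == 0) {
    stop("constant series: autocorrelation undefined", call. = FALSE)
  }
  if (is.null(lag_max)) lag_max <- min(n - 1L, ceiling(10 * sqrt(n)))
  ac <- as.numeric(stats::acf(series, lag.max = lag_max, plot = FALSE,
                              demean = TRUE)$acf)
  if (criterion == "1/e") {
    below <- which(ac < exp(-1)) - 1L # lags are 0-based
    stride <- if (length(below)) max(1L, below[1L]) else lag_max
  } else {
    stop_at <- which(ac[-1L] <= 0)
    upto <- if (length(stop_at)) stop_at[1L] - 1L else lag_max
    tau <- 1 + 2 * sum(ac[1L + seq_len(upto)])
    stride <- max(1L, ceiling(tau))
  }
  eligible <- if (is.null(mask)) seq_len(n) else which(mask)
  if (length(eligible) == 0L) {
    stop("empty sample: mask excludes all frames", call. = FALSE)
  }
  idx <- integer(0)
  last <- -Inf
  for (i in eligible) {
    if (i - last >= stride) {
      idx <- c(idx, i)
      last <- i
    }
  }
  structure(list(acf = ac, stride = stride, indices = idx,
                 sample = series[idx]),
            class = "decorrelation_result")
}

#' Pooled-variance two-sample t-test
#'
#' Two-sided test of equal means assuming equal (unknown) variances: the
#' sample standard deviations are replaced by the pooled standard deviation
#' and the statistic follows Student's t with n + m - 2 degrees of freedom
#' under the null. The null is rejected at the 5% level.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param alpha significance level (default 0.05).
#' @return list of class `pooled_t_result`: `t`, `dof`, `p`, `reject`,
#'   `mean_a`, `mean_b`, `pooled_sd`.
#' @export
two_sample_t <- function(a, b, alpha = 0.05) {
  n <- length(a); m <- length(b)
  if (n < 2L || m < 2L) stop("both samples need >= 2 observations", call. = FALSE)
  dof <- n + m - 2L
  sp2 <- ((n - 1) * stats::var(a) + (m - 1) * stats::var(b)) / dof
  diff <- mean(a) - mean(b)
  if (sp2 == 0) {
    # zero pooled variance: identical constants give t = 0, different
    # constants an infinitely significant difference
    tstat <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    tstat <- diff / sqrt(sp2 * (1 / n + 1 / m))
  }
  p <- if (is.infinite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df = dof)
  structure(list(t = tstat, dof = dof, p = p, reject = p < alpha,
                 mean_a = mean(a), mean_b = mean(b),
                 pooled_sd = sqrt(sp2)),
            class = "pooled_t_result")
}

#' @export
print.pooled_t_result <- function(x, ...) {
  cat(sprintf("pooled two-sample t-test: t = %.4f, dof = %d, p = %.4g (%s at 5%%)\n",
              x$t, x$dof, x$p,
              if (x$reject) "rejected" else "not rejected"))
  invisible(x)
}

gaussian_mix <- function(x, w, mu, sigma) {
  y <- 0
  for (k in seq_along(w)) {
    y <- y + w[k] * exp(-((x - mu[k])^2) / (2 * sigma[k]^2))
  }
  y
}

#' Fit one- or two-term Gaussians to an angle histogram
#'
#' Histograms the input angles (default 2-degree bins) and least-squares
#' fits a sum of `n_terms` Gaussian terms to the normalized bin heights,
#' using multi-start optimization (deterministic restarts) to avoid local
#' minima in two-term fits. For two-term fits the higher-weight term is
#' reported as the main peak.
#'
#' @param angles numeric vector of angles in degrees, or a list with
#'   elements `mids` and `density` for a pre-binned histogram.
#' @param n_terms 1 or 2.
#' @param binwidth histogram bin width in degrees (default 2).
#' @param restarts number of perturbed restarts (default 5).
#' @return object of class `gaussian_fit`: `weights`, `centroids`, `sigmas`,
#'   `main` (index of dominant term), `rss`, `n_terms`.
#' @export
fit_gaussians <- function(angles, n_terms = 1L, binwidth = 2, restarts = 5L) {
  stopifnot(n_terms %in% c(1L, 2L))
  if (is.list(angles) && !is.null(angles$mids)) {
    mids <- angles$mids
    dens <- angles$density
  } else {
    rng <- range(angles)
    breaks <- seq(floor(rng[1L] / binwidth) * binwidth,
                  ceiling(rng[2L] / binwidth) * binwidth + binwidth,
                  by = binwidth)
    h <- graphics::hist(angles, breaks = breaks, plot = FALSE)
    mids <- h$mids
    dens <- h$density
  }
  occupied <- sum(dens > 0)
  if (occupied < 5L * n_terms) {
    stop(sprintf("too few occupied bins (%d) for a %d-term Gaussian fit",
                 occupied, n_terms), call. = FALSE)
  }
  # moment-based initial guesses
  wsum <- sum(dens)
  mu0 <- sum(mids * dens) / wsum
  sd0 <- sqrt(sum((mids - mu0)^2 * dens) / wsum)
  peak <- mids[which.max(dens)]
  obj <- function(p) {
    k <- n_terms
    w <- exp(p[seq_len(k)])
    mu <- p[k + seq_len(k)]
    sg <- exp(p[2L * k + seq_len(k)])
    sum((dens - gaussian_mix(mids, w, mu, sg))^2)
  }
  inits <- list()
  if (n_terms == 1L) {
    inits[[1L]] <- c(log(max(dens)), peak, log(max(sd0, binwidth)))
    inits[[2L]] <- c(log(max(dens)), mu0, log(max(sd0, binwidth)))
  } else {
    ord <- order(dens, decreasing = TRUE)
    # two highest well-separated bins as centers
    c1 <- mids[ord[1L]]
    far <- ord[abs(mids[ord] - c1) > 3 * binwidth]
    c2 <- if (length(far)) mids[far[1L]] else mu0
    inits[[1L]] <- c(log(max(dens)), log(max(dens) / 2), c1, c2,
                     log(max(sd0 / 2, binwidth)), log(max(sd0 / 2, binwidth)))
    inits[[2L]] <- c(log(max(dens)), log(max(dens)), mu0 - sd0, mu0 + sd0,
                     log(max(sd0 / 2, binwidth)), log(max(sd0 / 2, binwidth)))
  }
  # deterministic restart perturbations without touching the global RNG
  perturb <- matrix(sin(seq_len(restarts * 6L) * 12.9898) * 2, nrow = restarts)
  best <- NULL
  for (ini in inits) {
    for (r in seq_len(restarts)) {
      p0 <- ini + perturb[r, seq_along(ini)] * c(rep(0.2, n_terms),
                                                 rep(2, n_terms),
                                                 rep(0.2, n_terms))
      fit <- tryCatch(
        stats::optim(p0, obj, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
  }
  if (is.null(best)) {
    stop("Gaussian fit failed to converge after restarts", call. = FALSE)
  }
  k <- n_terms
  w <- exp(best$par[seq_len(k)])
  mu <- best$par[k + seq_len(k)]
  sg <- exp(best$par[2L * k + seq_len(k)])
  main <- which.max(w)
  structure(list(weights = w, centroids = mu, sigmas = sg, main = main,
                 rss = best$value, n_terms = k),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  for (k in seq_len(x$n_terms)) {
    cat(sprintf("term %d%s: centroid %.2f deg, sigma %.2f deg, weight %.3g\n",
                k, if (k == x$main && x$n_terms > 1L) " (main)" else "",
                x$centroids[k], x$sigmas[k], x$weights[k]))
  }
  invisible(x)
}

#' Normalized conformational heat map
#'
#' Bins (PA-PG distance, bridge angle) pairs on a regular 2D grid; cell
#' values are normalized frequencies summing to one over the occupied grid.
#' When `cation_mask` is supplied only frames with at least one cation within
#' the chain-proximity radius enter the map. Overlay point sets (e.g.
#' crystal-structure analog classes from [collect_overlay_sets()]) are stored
#' with their convex-hull outlines for plotting.
#'
#' @param d numeric vector of PA-PG distances (Angstrom).
#' @param theta numeric vector of bridge angles (degrees).
#' @param d_breaks,theta_breaks grid break points; defaults cover the data
#'   range with 0.1 A x 1 degree cells.
#' @param cation_mask optional logical vector: frames to include.
#' @param overlays optional named list of data.frames with columns `d`,
#'   `theta`.
#' @return object of class `conformation_heatmap`: `grid` (matrix of
#'   normalized frequency, rows = d bins), `d_breaks`, `theta_breaks`,
#'   `overlays` (each with a `hull` index vector), `n`.
#' @export
build_heatmap <- function(d, theta, d_breaks = NULL, theta_breaks = NULL,
                          cation_mask = NULL, overlays = NULL) {
  stopifnot(length(d) == length(theta))
  if (!is.null(cation_mask)) {
    d <- d[cation_mask]
    theta <- theta[cation_mask]
  }
  if (length(d) == 0L) stop("no conformations to map", call. = FALSE)
  if (is.null(d_breaks)) {
    d_breaks <- seq(floor(min(d) * 10) / 10, ceiling(max(d) * 10) / 10 + 0.1,
                    by = 0.1)
  }
  if (is.null(theta_breaks)) {
    theta_breaks <- seq(floor(min(theta)), ceiling(max(theta)) + 1, by = 1)
  }
  if (min(d) < min(d_breaks) || max(d) > max(d_breaks) ||
      min(theta) < min(theta_breaks) || max(theta) > max(theta_breaks)) {
    stop("grid does not cover the data range", call. = FALSE)
  }
  di <- cut(d, d_breaks, include.lowest = TRUE, labels = FALSE)
  ti <- cut(theta, theta_breaks, include.lowest = TRUE, labels = FALSE)
  grid <- matrix(0, length(d_breaks) - 1L, length(theta_breaks) - 1L)
  for (i in seq_along(di)) grid[di[i], ti[i]] <- grid[di[i], ti[i]] + 1
  grid <- grid / sum(grid)
  ov <- NULL
  if (!is.null(overlays)) {
    ov <- lapply(overlays, function(o) {
      o <- as.data.frame(o)
      hull <- if (nrow(o) >= 3L) grDevices::chull(o$d, o$theta) else
        seq_len(nrow(o))
      list(points = o, hull = hull)
    })
  }
  structure(list(grid = grid, d_breaks = d_breaks,
                 theta_breaks = theta_breaks, overlays = ov,
                 n = length(d)),
            class = "conformation_heatmap")
}

#' Plot a conformational heat map
#'
#' Renders the normalized-frequency grid with `image()` and draws overlay
#' convex hulls as dashed outlines.
#'
#' @param x a `conformation_heatmap`.
#' @param ... passed to `image()`.
#' @export
plot.conformation_heatmap <- function(x, ...) {
  graphics::image(x = x$d_breaks, y = x$theta_breaks, z = x$grid,
                  xlab = "P(A)-P(G) distance (A)",
                  ylab = "P(B)-O(3B)-P(G) angle (deg)",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  if (!is.null(x$overlays)) {
    cols <- c("magenta", "blue", "darkgreen", "black")
    i <- 0L
    for (nm in names(x$overlays)) {
      i <- i + 1L
      o <- x$overlays[[nm]]
      if (length(o$hull) >= 3L) {
        graphics::polygon(o$points$d[o$hull], o$points$theta[o$hull],
                          border = cols[(i - 1L) %% 4L + 1L], lty = 2)
      }
    }
  }
  invisible(x)
}
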