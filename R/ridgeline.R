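# Accept either a one-row tibble from estimate_bivariate() or a plain list
# with elements mu, sigma, n.
as_biv_estimate <- function(est, arg = "est") {
  if (is.data.frame(est)) {
    if (nrow(est) != 1) {
      abort(paste0("`", arg, "` must be a single-species estimate (one row)."))
    }
    out <- list(species = est$species[[1]], mu = est$mu[[1]],
                sigma = est$sigma[[1]], n = est$n[[1]],
                degenerate = isTRUE(est$degenerate[[1]]))
  } else if (is.list(est) && all(c("mu", "sigma") %in% names(est))) {
    out <- list(species = est$species %||% arg, mu = est$mu,
                sigma = est$sigma, n = est$n %||% NA_integer_,
                degenerate = isTRUE(est$degenerate))
  } else {
    abort(paste0("`", arg, "` must be an estimate row or a list(mu, sigma, n)."))
  }
  if (out$degenerate || is_degenerate_cov(out$sigma)) {
    abort(paste0("Covariance for `", out$species,
                 "` is degenerate; the ridgeline is undefined."))
  }
  out
}

# density of N(mu, sigma) in two dimensions, vectorised over rows of x
dmvnorm2 <- function(x, mu, sigma) {
  a <- sigma[1, 1]; b <- sigma[1, 2]; d <- sigma[2, 2]
  det <- a * d - b^2
  dx <- x[, 1] - mu[1]; dy <- x[, 2] - mu[2]
  q <- (d * dx^2 - 2 * b * dx * dy + a * dy^2) / det
  exp(-q / 2) / (2 * pi * sqrt(det))
}

# squared Mahalanobis distance of rows of x from mu under sigma
mahalanobis2 <- function(x, mu, sigma) {
  a <- sigma[1, 1]; b <- sigma[1, 2]; d <- sigma[2, 2]
  det <- a * d - b^2
  dx <- x[, 1] - mu[1]; dy <- x[, 2] - mu[2]
  (d * dx^2 - 2 * b * dx * dy + a * dy^2) / det
}

# x*(alpha) for a vector of alphas: the Ray-Lindsay blend
# [(1-a) S1^-1 + a S2^-1]^-1 [(1-a) S1^-1 mu1 + a S2^-1 mu2]
ridgeline_points <- function(alpha, mu1, sigma1, mu2, sigma2) {
  A1 <- solve(sigma1); A2 <- solve(sigma2)
  r1 <- A1 %*% mu1; r2 <- A2 %*% mu2
  w1 <- 1 - alpha; w2 <- alpha
  Ba <- w1 * A1[1, 1] + w2 * A2[1, 1]
  Bb <- w1 * A1[1, 2] + w2 * A2[1, 2]
  Bd <- w1 * A1[2, 2] + w2 * A2[2, 2]
  det <- Ba * Bd - Bb^2
  if (any(det <= 0 | !is.finite(det))) {
    bad <- alpha[which(det <= 0 | !is.finite(det))[1]]
    abort(paste0("Blend matrix numerically singular at alpha = ",
                 format(bad), "."))
  }
  rx <- w1 * r1[1] + w2 * r2[1]
  ry <- w1 * r1[2] + w2 * r2[2]
  cbind(x = (Bd * rx - Bb * ry) / det,
        y = (Ba * ry - Bb * rx) / det)
}

#' Ridgeline manifold of a two-component bivariate normal mixture
#'
#' The ridgeline is the one-parameter curve `x*(alpha)`, `alpha` in `[0, 1]`,
#' running from the first component mean (`alpha = 0`) to the second
#' (`alpha = 1`), that contains every critical point — modes, antimodes and
#' saddles — of any mixture of the two components regardless of mixing
#' weight. When the two covariances are equal it collapses to the straight
#' segment between the means.
#'
#' @param est1,est2 Single-species estimates (one-row tibbles from
#'   [estimate_bivariate()] or lists with `mu`, `sigma`, `n`).
#' @param grid_size Number of evenly spaced `alpha` values, endpoints
#'   included (default 513).
#' @param weight Mixing proportion of component 1 used for the diagnostic
#'   mixture density evaluated along the curve (default 0.5). The gap
#'   decision itself does not depend on this.
#'
#' @return A tibble of class `ridgeline_curve` with columns `alpha`, `x`,
#'   `y`, `density`; the component parameters travel along as attributes.
#' @export
#' @examples
#' e1 <- list(mu = c(0, 0), sigma = diag(2), n = 10)
#' e2 <- list(mu = c(3, 1), sigma = matrix(c(1, .5, .5, 1), 2), n = 12)
#' ridgeline_manifold(e1, e2, grid_size = 65)
ridgeline_manifold <- function(est1, est2, grid_size = 513, weight = 0.5) {
  e1 <- as_biv_estimate(est1, "est1")
  e2 <- as_biv_estimate(est2, "est2")
  stopifnot(grid_size >= 3)
  check_prob(weight, "weight")
  alpha <- seq(0, 1, length.out = grid_size)
  pts <- ridgeline_points(alpha, e1$mu, e1$sigma, e2$mu, e2$sigma)
  dens <- weight * dmvnorm2(pts, e1$mu, e1$sigma) +
    (1 - weight) * dmvnorm2(pts, e2$mu, e2$sigma)
  out <- tibble(alpha = alpha, x = pts[, 1], y = pts[, 2], density = dens)
  class(out) <- c("ridgeline_curve", class(out))
  attr(out, "est1") <- e1
  attr(out, "est2") <- e2
  attr(out, "weight") <- weight
  out
}

#' Critical points of the mixture density along a ridgeline
#'
#' Locates the interior critical points of the two-component mixture density
#' restricted to the ridgeline: sign changes of the along-curve derivative
#' are bracketed on the grid and refined by golden-section search, then
#' classified as `mode` (local maximum) or `antimode` (local minimum /
#' saddle of the full density) from the second difference.
#'
#' @param curve A `ridgeline_curve` from [ridgeline_manifold()].
#' @param weight Mixing proportion of component 1 (default: the curve's).
#'
#' @return A tibble with columns `alpha`, `x`, `y`, `density`, `type`.
#'   Coincident components yield a single interior `mode` row.
#' @export
ridgeline_critical_points <- function(curve, weight = NULL) {
  e1 <- attr(curve, "est1"); e2 <- attr(curve, "est2")
  if (is.null(e1) || is.null(e2)) {
    abort("`curve` must come from ridgeline_manifold().")
  }
  weight <- weight %||% attr(curve, "weight")
  dens_at <- function(a) {
    p <- ridgeline_points(a, e1$mu, e1$sigma, e2$mu, e2$sigma)
    weight * dmvnorm2(p, e1$mu, e1$sigma) +
      (1 - weight) * dmvnorm2(p, e2$mu, e2$sigma)
  }
  alpha <- curve$alpha
  dens <- if (identical(weight, attr(curve, "weight"))) curve$density else dens_at(alpha)

  rng <- diff(range(dens))
  if (rng <= 1e-12 * max(dens)) {
    # coincident components: density constant along a zero-length curve
    a <- 0.5
    p <- ridgeline_points(a, e1$mu, e1$sigma, e2$mu, e2$sigma)
    return(tibble(alpha = a, x = p[1], y = p[2], density = dens_at(a),
                  type = "mode"))
  }

  d1 <- diff(dens)
  sgn <- sign(d1)
  nz <- which(sgn != 0)
  flips <- nz[which(diff(sgn[nz]) != 0)]
  refine <- function(lo, hi, falling) {
    opt <- optimize(dens_at, c(lo, hi), maximum = falling,
                    tol = .Machine$double.eps^0.4)
    a <- if (falling) opt$maximum else opt$minimum
    p <- ridgeline_points(a, e1$mu, e1$sigma, e2$mu, e2$sigma)
    tibble(alpha = a, x = p[1], y = p[2], density = dens_at(a),
           type = if (falling) "mode" else "antimode")
  }
  res <- purrr::map(flips, function(i) {
    refine(alpha[max(i - 1, 1)], alpha[min(i + 2, length(alpha))],
           falling = sgn[i] > 0) # rising then falling => maximum
  })
  # For well-separated components the mode adjacent to each component mean
  # sits a tiny distance inside the curve, often within the first or last
  # grid interval where no sign change is visible. Density falling away from
  # an endpoint marks such a mode; refine it within the boundary interval.
  m <- length(alpha)
  if (length(nz) > 0 && sgn[nz[1]] < 0) {
    res <- c(list(refine(alpha[1], alpha[min(3, m)], falling = TRUE)), res)
  }
  if (length(nz) > 0 && sgn[nz[length(nz)]] > 0) {
    res <- c(res, list(refine(alpha[max(m - 2, 1)], alpha[m], falling = TRUE)))
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(alpha = numeric(), x = numeric(), y = numeric(),
                  density = numeric(), type = character())
  }
  dplyr::arrange(out, .data$alpha)
}
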