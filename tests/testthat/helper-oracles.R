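# Small Monte Carlo settings for unit tests; acceptance tests use larger ones.
test_ctl <- function(n_rep = 1500, n_inner = 800, seed = 1234L) {
  tol_control(n_rep = n_rep, n_inner = n_inner, seed = seed)
}

# Independent oracle: exact content of the ellipsoid
# {x : (x - xbar)' S^-1 (x - xbar) <= k} under the true N(0, I2) population,
# by eigendecomposition and 1-D quadrature over the conditioning normal.
# Used to verify tolerance factors through their defining coverage property,
# by a different route than the package's empirical-quantile calibration.
oracle_content <- function(k, xbar, S, m = 400) {
  e <- eigen(S, symmetric = TRUE)
  l <- e$values
  b <- drop(crossprod(e$vectors, xbar))
  s <- sqrt(k * l[2])
  u <- seq(b[2] - s, b[2] + s, length.out = m)
  du <- u[2] - u[1]
  rem <- pmax(k - (u - b[2])^2 / l[2], 0)
  half <- sqrt(rem * l[1])
  inner <- pnorm(b[1] + half) - pnorm(b[1] - half)
  sum(inner * dnorm(u)) * du
}

# Independent oracle: density of the 50:50 two-component bivariate normal
# mixture, written out long-hand.
oracle_mixture_density <- function(x, y, mu1, S1, mu2, S2, w = 0.5) {
  comp <- function(x, y, mu, S) {
    Si <- solve(S)
    dx <- x - mu[1]; dy <- y - mu[2]
    q <- Si[1, 1] * dx^2 + 2 * Si[1, 2] * dx * dy + Si[2, 2] * dy^2
    exp(-q / 2) / (2 * pi * sqrt(det(S)))
  }
  w * comp(x, y, mu1, S1) + (1 - w) * comp(x, y, mu2, S2)
}

# Analytic gradient of the two-component mixture at a point.
oracle_mixture_grad <- function(p, mu1, S1, mu2, S2, w = 0.5) {
  g <- function(p, mu, S) {
    Si <- solve(S)
    d <- p - mu
    f <- exp(-drop(t(d) %*% Si %*% d) / 2) / (2 * pi * sqrt(det(S)))
    -f * drop(Si %*% d)
  }
  w * g(p, mu1, S1) + (1 - w) * g(p, mu2, S2)
}

# Brute-force critical points of the 50:50 mixture: a 2-D lattice scan for
# cells where both partial derivatives (analytic) change sign, each candidate
# then polished by damped Newton iteration on the gradient. Candidates that
# do not converge to a genuine critical point (nullclines passing close
# without crossing, or flat far-field cells) are discarded. Knows nothing of
# the ridgeline construction.
oracle_critical_points <- function(mu1, S1, mu2, S2, w = 0.5, m = 301,
                                   pad = 3.5) {
  cand <- oracle_critical_cells(mu1, S1, mu2, S2, w, m, pad)
  if (nrow(cand) == 0) return(matrix(numeric(), ncol = 2))
  fref <- max(oracle_mixture_density(mu1[1], mu1[2], mu1, S1, mu2, S2, w),
              oracle_mixture_density(mu2[1], mu2[2], mu1, S1, mu2, S2, w))
  box_x <- range(mu1[1], mu2[1]) + c(-4, 4)
  box_y <- range(mu1[2], mu2[2]) + c(-4, 4)
  kept <- list()
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    ok <- FALSE
    for (it in 1:60) {
      g <- oracle_mixture_grad(p, mu1, S1, mu2, S2, w)
      h <- 1e-5
      J <- cbind((oracle_mixture_grad(p + c(h, 0), mu1, S1, mu2, S2, w) - g) / h,
                 (oracle_mixture_grad(p + c(0, h), mu1, S1, mu2, S2, w) - g) / h)
      step <- tryCatch(solve(J, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      if (sqrt(sum(step^2)) > 1) step <- step / sqrt(sum(step^2))
      p <- p - step
      f <- oracle_mixture_density(p[1], p[2], mu1, S1, mu2, S2, w)
      gn <- sqrt(sum(oracle_mixture_grad(p, mu1, S1, mu2, S2, w)^2))
      if (gn < 1e-9 * max(f, 1e-300) && f > 1e-9 * fref) {
        ok <- TRUE
        break
      }
    }
    if (ok && p[1] > box_x[1] && p[1] < box_x[2] &&
        p[2] > box_y[1] && p[2] < box_y[2]) {
      kept[[length(kept) + 1]] <- p
    }
  }
  if (length(kept) == 0) return(matrix(numeric(), ncol = 2))
  unique(round(do.call(rbind, kept), 6))
}

oracle_critical_cells <- function(mu1, S1, mu2, S2, w = 0.5, m = 301,
                                  pad = 3.5) {
  sds <- sqrt(c(diag(S1), diag(S2)))
  xr <- range(mu1[1], mu2[1]) + c(-1, 1) * pad * max(sds)
  yr <- range(mu1[2], mu2[2]) + c(-1, 1) * pad * max(sds)
  xs <- seq(xr[1], xr[2], length.out = m)
  ys <- seq(yr[1], yr[2], length.out = m)
  grad_comp <- function(X, Y, mu, S) {
    Si <- solve(S)
    dx <- X - mu[1]; dy <- Y - mu[2]
    q <- Si[1, 1] * dx^2 + 2 * Si[1, 2] * dx * dy + Si[2, 2] * dy^2
    f <- exp(-q / 2) / (2 * pi * sqrt(det(S)))
    list(gx = -f * (Si[1, 1] * dx + Si[1, 2] * dy),
         gy = -f * (Si[1, 2] * dx + Si[2, 2] * dy))
  }
  X <- matrix(xs, m, m); Y <- matrix(ys, m, m, byrow = TRUE)
  g1 <- grad_comp(X, Y, mu1, S1); g2 <- grad_comp(X, Y, mu2, S2)
  gx <- w * g1$gx + (1 - w) * g2$gx
  gy <- w * g1$gy + (1 - w) * g2$gy
  sx <- sign(gx); sy <- sign(gy)
  flip_x <- (sx[-m, -m] * sx[-1, -m] < 0) | (sx[-m, -m] * sx[-m, -1] < 0) |
    (sx[-m, -m] * sx[-1, -1] < 0)
  flip_y <- (sy[-m, -m] * sy[-1, -m] < 0) | (sy[-m, -m] * sy[-m, -1] < 0) |
    (sy[-m, -m] * sy[-1, -1] < 0)
  hits <- which(flip_x & flip_y, arr.ind = TRUE)
  if (nrow(hits) == 0) return(matrix(numeric(), ncol = 2))
  pts <- cbind(xs[hits[, 1]] + diff(xs[1:2]) / 2,
               ys[hits[, 2]] + diff(ys[1:2]) / 2)
  # cluster neighbouring hits to one candidate each
  cell <- sqrt(diff(xs[1:2])^2 + diff(ys[1:2])^2)
  cl <- rep(NA_integer_, nrow(pts))
  k <- 0L
  for (i in seq_len(nrow(pts))) {
    if (is.na(cl[i])) {
      k <- k + 1L
      d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
      cl[d < 4 * cell & is.na(cl)] <- k
    }
  }
  out <- t(sapply(split(seq_len(nrow(pts)), cl), function(ix) {
    c(mean(pts[ix, 1]), mean(pts[ix, 2]))
  }))
  attr(out, "cell") <- cell
  out
}

# A tiny three-species specimen table: two near-identical species plus one
# far away in both leaf space and flower number.
three_species_panel <- function(seed = 7, n = 12) {
  dplyr::bind_rows(
    generate_species("near one", n, c(3.0, 2.0), diag(0.02, 2), 2.0, 0.3,
                     seed = seed),
    generate_species("near two", n, c(3.05, 2.02), diag(0.02, 2), 2.1, 0.3,
                     seed = seed + 1),
    generate_species("far away", n, c(5.5, 4.0), diag(0.02, 2), 6.5, 0.3,
                     seed = seed + 2)
  )
}
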